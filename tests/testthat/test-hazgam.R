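# single-stratum life table with prescribed (D, E) per bin
toy_table <- function(D, E, bin_width = 3) {
  lt <- data.frame(isoline = "iso01", sex = "female", treatment = "control",
                   age_bin_start = (seq_along(D) - 1) * bin_width,
                   D = D, E = E, stringsAsFactors = FALSE)
  attr(lt, "bin_width") <- bin_width
  class(lt) <- c("lifetable", "data.frame")
  lt
}

one_group_spec <- function() hazgam_spec(fixed = character(0),
                                         smooth = "shared",
                                         isoline = "none")

test_that("constant-hazard data yield a flat fit at log(sum D / sum E)", {
  lt <- toy_table(D = rep(12, 8), E = rep(300, 8))
  for (lam in c(1e-2, 1, 1e4)) {
    f <- hazgam(lt, one_group_spec(), k = 8,
                lambda = c(smooth = lam))
    cv <- predict(f, ages = seq(2, 22, by = 2))
    expect_equal(cv$log_mu, rep(log(sum(lt$D) / sum(lt$E)), length(cv$age)),
                 tolerance = 1e-6)
  }
})

test_that("an unpenalized saturated fit reproduces D/E per bin", {
  lt <- toy_table(D = c(4, 7, 11, 16, 25), E = c(500, 450, 380, 300, 200))
  f <- hazgam(lt, one_group_spec(), k = 5, lambda = c(smooth = 1e-10))
  mids <- lt$age_bin_start + 1.5
  cv <- predict(f, ages = mids)
  expect_equal(exp(cv$log_mu), lt$D / lt$E, tolerance = 1e-6)
})

test_that("heavy smoothing converges to the Poisson-GLM Gompertz line", {
  set.seed(31)
  ages <- (0:19) * 3
  E <- rep(400, 20)
  D <- rpois(20, E * exp(-6 + 0.07 * (ages + 1.5)))
  lt <- toy_table(D = D, E = E)
  f <- hazgam(lt, one_group_spec(), k = 10, lambda = c(smooth = 1e9))
  glmfit <- glm(D ~ I(ages + 1.5), family = poisson, offset = log(E))
  grid <- seq(2, 58, by = 1)
  cv <- predict(f, ages = grid)
  line <- coef(glmfit)[1] + coef(glmfit)[2] * grid
  expect_lt(max(abs(cv$log_mu - unname(line))), 1e-4)
})

test_that("EDF is monotone non-increasing in lambda and brackets the
           null-space dimension", {
  lt <- build_lifetable(small_cohort(seed = 21, n_isolines = 3,
                                     n_per_group = 40))
  lams <- 10^seq(-2, 8, by = 2)
  edf <- vapply(lams, function(l)
    hazgam(lt, hazgam_spec(isoline = "none"), k = 8,
           lambda = c(smooth = l))$edf, 0)
  expect_true(all(diff(edf) < 1e-6))
  # fixed part (4 coefs) + 4 smooths each at least linear (1 centered df)
  expect_gte(min(edf), 4 + 4 - 1e-6)
  expect_lte(max(edf), 4 + 4 * 7 + 1e-6)
})

test_that("the intercept score equation reproduces total deaths", {
  lt <- build_lifetable(small_cohort(seed = 22, n_isolines = 4,
                                     n_per_group = 30))
  f <- hazgam(lt, hazgam_spec(isoline = "intercept"), k = 8)
  expect_equal(sum(f$fitted_mu), sum(lt$D), tolerance = 1e-6)
  expect_true(f$converged)
  expect_equal(f$aic, -2 * f$loglik + 2 * f$edf)
})

test_that("fitted smooths agree with an independent mgcv fit", {
  skip_if_not_installed("mgcv")
  # a death-rich single stratum: with the curve pinned by the data, the
  # AIC- and REML-selected smoothers must agree on the same estimate
  lt <- build_lifetable(small_cohort(seed = 23, n_isolines = 3,
                                     n_per_group = 400, hump_height = 0,
                                     log_a = rep(-6.5, 4)))
  lt1 <- lt[lt$sex == "female" & lt$treatment == "control", ]
  attr(lt1, "bin_width") <- 3
  f <- hazgam(lt1, one_group_spec(), k = 10)
  mid <- lt1$age_bin_start + 1.5
  g <- mgcv::gam(lt1$D ~ s(mid, k = 10, bs = "ps"),
                 family = poisson, offset = log(lt1$E), method = "REML")
  # compare where the data inform the fit: central death ages
  drange <- quantile(rep(mid, lt1$D), c(0.1, 0.9))
  grid <- seq(drange[1], drange[2], length.out = 30)
  ours <- predict(f, ages = grid)$log_mu
  theirs <- as.numeric(predict(g, newdata = data.frame(mid = grid)))
  expect_lt(max(abs(ours - theirs)), 0.01)
})

test_that("Gompertz slope is recovered from a clean simulated cohort", {
  rec <- simulate_cohort(
    cohort_design(n_isolines = 4, n_per_group = 500,
                  censor_prob_per_check = 0, max_age = 300),
    gompertz_frailty_params(sigma_frailty = 0, hump_height = 0, b = 0.08),
    seed = 24)
  f <- hazgam(build_lifetable(rec), hazgam_spec(isoline = "none"), k = 10)
  sl <- gompertz_slope(f)
  expect_true(all(sl > 0.07 & sl < 0.09))
})

test_that("model selection ranks by AIC and breaks ties toward fewer EDF", {
  lt <- build_lifetable(small_cohort(seed = 25, n_isolines = 3,
                                     n_per_group = 30))
  cands <- list(a = hazgam_spec(smooth = "shared", isoline = "none"),
                b = hazgam_spec(smooth = "by_sex", isoline = "none"),
                a2 = hazgam_spec(smooth = "shared", isoline = "none"))
  sel <- select_hazgam(lt, cands, k = 8)
  expect_equal(nrow(sel$table), 3)
  expect_true(all(diff(sel$table$aic) >= 0))
  expect_equal(sel$table$delta_aic[1], 0)
  # duplicated spec: identical AIC, deterministic order
  dup <- sel$table[sel$table$model %in% c("a", "a2"), ]
  expect_equal(dup$aic[1], dup$aic[2], tolerance = 1e-9)
  sel2 <- select_hazgam(lt, cands, k = 8)
  expect_identical(sel$table$model, sel2$table$model)
})

test_that("strong isoline frailty is detected by AIC", {
  wins <- 0L
  for (s in 1:10) {
    rec <- simulate_cohort(
      cohort_design(n_isolines = 8, n_per_group = 40, max_age = 250),
      gompertz_frailty_params(sigma_frailty = 0.5, hump_height = 0),
      seed = 300 + s)
    lt <- build_lifetable(rec)
    f_re <- hazgam(lt, hazgam_spec(smooth = "shared", isoline = "intercept"),
                   k = 8)
    f_no <- hazgam(lt, hazgam_spec(smooth = "shared", isoline = "none"),
                   k = 8)
    if (f_re$aic < f_no$aic) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("conditional and per-isoline predictions coincide without
           random effects, and extrapolation is refused", {
  lt <- build_lifetable(small_cohort(seed = 26, n_isolines = 3,
                                     n_per_group = 20))
  f <- hazgam(lt, hazgam_spec(isoline = "none"), k = 8)
  ages <- seq(5, 40, by = 5)
  cz <- predict(f, ages = ages, sex = "male", treatment = "rapamycin")
  pi <- predict(f, ages = ages, sex = "male", treatment = "rapamycin",
                isoline = "each")
  expect_identical(attr(cz, "flavor"), "conditional")
  expect_equal(cz$log_mu, pi$log_mu)  # degenerate: same curve back
  expect_error(predict(f, ages = c(5, 1e4)), "extrapolation|range")
})

test_that("factor-smooth deviations average to the conditional curve", {
  lt <- build_lifetable(small_cohort(seed = 27, n_isolines = 5,
                                     n_per_group = 30))
  f <- hazgam(lt, hazgam_spec(isoline = "fs"), k = 8)
  ages <- seq(6, 48, by = 3)
  per <- predict(f, ages = ages, sex = "female", treatment = "control",
                 isoline = "each")
  avg <- rowMeans(vapply(per, function(cv) cv$log_mu,
                         numeric(length(ages))))
  cz <- predict(f, ages = ages, sex = "female", treatment = "control")
  expect_equal(avg, cz$log_mu, tolerance = 1e-8)
})

test_that("a Gompertz fit is monotone over the central range at the
           selected smoothing", {
  rec <- simulate_cohort(
    cohort_design(n_isolines = 4, n_per_group = 200,
                  censor_prob_per_check = 0, max_age = 300),
    gompertz_frailty_params(sigma_frailty = 0, hump_height = 0),
    seed = 28)
  f <- hazgam(build_lifetable(rec), hazgam_spec(isoline = "none"), k = 10)
  rng <- f$age_range
  grid <- seq(rng[1] + 0.1 * diff(rng), rng[2] - 0.1 * diff(rng),
              length.out = 50)
  cv <- predict(f, ages = grid, sex = "male", treatment = "control")
  expect_true(all(diff(cv$log_mu) > 0))
})

test_that("simulate() and residuals() are consistent with the fit", {
  lt <- build_lifetable(small_cohort(seed = 29, n_isolines = 3,
                                     n_per_group = 30))
  f <- hazgam(lt, hazgam_spec(isoline = "intercept"), k = 8)
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_equal(mean(vapply(sims, function(s) sum(s$D), 0)),
               sum(f$fitted_mu), tolerance = 0.1 * sum(f$fitted_mu))
  r <- residuals(f, type = "pearson")
  expect_equal(length(r), nrow(f$lifetable))
  expect_lt(abs(mean(r)), 0.5)
  ll <- logLik(f)
  expect_equal(AIC(f), f$aic)
})
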