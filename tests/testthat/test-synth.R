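test_that("record count, factor levels and the check grid are exact", {
  des <- cohort_design(n_isolines = 5, n_per_group = 17, max_age = 250)
  par <- gompertz_frailty_params()
  rec <- simulate_cohort(des, par, seed = 3)
  expect_equal(nrow(rec), 5 * 2 * 2 * 17)
  expect_setequal(unique(rec$sex), c("female", "male"))
  expect_setequal(unique(rec$treatment), c("control", "rapamycin"))
  expect_equal(length(unique(rec$isoline)), 5)
  expect_true(all(rec$observed_age > 0))
  expect_true(all(rec$observed_age %% des$check_interval == 0))
  expect_equal(as.vector(table(rec$isoline, rec$sex)),
               rep(2 * 17, 10))
})

test_that("identical (design, params, seed) gives identical records", {
  des <- cohort_design(n_isolines = 3, n_per_group = 20, max_age = 250)
  par <- gompertz_frailty_params()
  expect_identical(simulate_cohort(des, par, seed = 99),
                   simulate_cohort(des, par, seed = 99))
  r2 <- simulate_cohort(des, par, seed = 100)
  expect_false(identical(r2$observed_age,
                         simulate_cohort(des, par, seed = 99)$observed_age))
})

test_that("constant unit hazard collapses onto the first check", {
  des <- cohort_design(n_isolines = 1, n_per_group = 10,
                       censor_prob_per_check = 0, max_age = 300)
  par <- gompertz_frailty_params(log_a = rep(log(1), 4), b = 0,
                                 sigma_frailty = 0, hump_height = 0)
  rec <- simulate_cohort(des, par, seed = 1)
  # exponential(1) deaths essentially all before day 3; discretization
  # forces every observation to the first transfer
  expect_true(all(rec$observed_age %% 3 == 0))
  expect_true(mean(rec$observed_age == 3) > 0.9)
  expect_true(all(rec$event[rec$observed_age == 3] == "death"))
})

test_that("an implausibly short horizon is rejected", {
  des <- cohort_design(n_isolines = 2, n_per_group = 15, max_age = 6)
  par <- gompertz_frailty_params()  # hardly anything dies by day 6
  expect_error(simulate_cohort(des, par, seed = 1), "truncates")
})

test_that("zero frailty makes isolines exchangeable", {
  # two isolines, rank test between them; at alpha = 0.01 under the null
  # the rejection count over 100 seeds should be small
  rejections <- 0L
  for (s in 1:100) {
    rec <- simulate_cohort(
      cohort_design(n_isolines = 2, n_per_group = 15,
                    censor_prob_per_check = 0, max_age = 400),
      gompertz_frailty_params(sigma_frailty = 0, hump_height = 0),
      seed = s)
    rec <- rec[rec$sex == "female" & rec$treatment == "control", ]
    p <- suppressWarnings(wilcox.test(
      observed_age ~ isoline, data = rec)$p.value)
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 5L)
})

test_that("the treatment hump raises early deaths in the treated group", {
  hits <- 0L
  for (s in 1:200) {
    rec <- simulate_cohort(
      cohort_design(n_isolines = 8, n_per_group = 90,
                    censor_prob_per_check = 0, max_age = 300),
      gompertz_frailty_params(hump_height = 1.2, hump_decay = 10),
      seed = 1000 + s)
    early <- rec$observed_age <= 15 & rec$event == "death"
    p_tr <- mean(early[rec$treatment == "rapamycin"])
    p_ct <- mean(early[rec$treatment == "control"])
    if (p_tr > p_ct) hits <- hits + 1L
  }
  expect_gte(hits, 190L)  # >= 95% of replicates
})

test_that("empirical survivorship converges to the analytic frailty mixture", {
  # 500 lines x 10 flies per cell with identical group baselines:
  # 20000 exchangeable flies; compare the pooled empirical survivorship
  # at check times with the quadrature mixture survival
  des <- cohort_design(n_isolines = 500, n_per_group = 10,
                       censor_prob_per_check = 0, max_age = 400)
  par <- gompertz_frailty_params(log_a = rep(-8, 4), hump_height = 0)
  rec <- simulate_cohort(des, par, seed = 5)
  expect_equal(nrow(rec), 20000)
  expect_lt(mean(rec$event == "censored"), 0.001)
  at <- seq(3, 150, by = 3)
  emp <- vapply(at, function(t) mean(rec$observed_age > t), 0)
  theo <- true_marginal_survival(par, "female", "control", at)
  expect_lt(max(abs(emp - theo)), 0.02)
})

test_that("the quadrature oracle reduces to the conditional hazard at sigma = 0", {
  par <- gompertz_frailty_params(sigma_frailty = 0, hump_height = 0)
  ages <- seq(0, 120, by = 2)
  mh <- true_marginal_hazard(par, "male", "control", ages)
  expect_equal(mh$log_mu, par$log_a[["male.control"]] + par$b * ages,
               tolerance = 1e-10)
  expect_identical(attr(mh, "flavor"), "marginal")
})

test_that("frailty decelerates the marginal hazard below the Gompertz slope", {
  par <- gompertz_frailty_params(sigma_frailty = 0.5, hump_height = 0)
  ages <- seq(0, 120, by = 1)
  mh <- true_marginal_hazard(par, "female", "control", ages)
  slope <- diff(mh$log_mu) / diff(ages)
  expect_true(all(slope < par$b))
  # gap to the conditional line is non-increasing in age
  gap <- mh$log_mu - (par$log_a[["female.control"]] + par$b * ages)
  expect_true(all(diff(gap) <= 1e-10))
})

test_that("gamma and log-normal frailty mixtures agree qualitatively", {
  par <- gompertz_frailty_params(sigma_frailty = 0.4, hump_height = 0)
  # compare over ages the population actually survives to (S > 0.1)
  ages <- seq(0, 45, by = 2.5)
  ln <- true_marginal_hazard(par, "female", "control", ages)
  ga <- true_marginal_hazard(par, "female", "control", ages,
                             frailty = "gamma")
  # variance-matched mixtures: same deceleration, close agreement while
  # the survivor pool is non-negligible (they diverge in the far tail)
  expect_lt(max(abs(ln$log_mu - ga$log_mu)), 0.1)
  # both decelerate: the excess over the Gompertz line shrinks with age
  cond <- par$log_a[["female.control"]] + par$b * ages
  expect_true(all(diff(ga$log_mu - cond) <= 1e-9))
  expect_true(all(diff(ln$log_mu - cond) <= 1e-9))
})

test_that("records round-trip through CSV", {
  rec <- small_cohort(seed = 2, n_isolines = 2, n_per_group = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, path)
  back <- read_records(path)
  expect_equal(back, rec)
})

test_that("malformed records are rejected with the offending row", {
  rec <- make_records(c(3, 6, 9))
  rec$sex[2] <- "unknown"
  expect_error(build_lifetable(rec), "row")
  rec2 <- make_records(c(3, 6, 9))
  rec2$observed_age[3] <- -1
  expect_error(build_lifetable(rec2), "positive")
})
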