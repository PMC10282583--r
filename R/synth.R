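#' Cohort design for synthetic fly mortality experiments
#'
#' Describes the experimental layout of a demographic assay on inbred
#' isolines: a fully crossed isoline x sex x developmental-treatment design
#' with a fixed number of flies per cell, dead/escaped flies recorded at
#' periodic transfer checks, and escapes treated as right-censoring.
#'
#' @param n_isolines number of inbred lines (default 14, the usual panel
#'   size for this assay).
#' @param n_per_group flies started per isoline x sex x treatment cell
#'   (default 90, i.e. three vials of ~30 pooled).
#' @param check_interval days between transfers to fresh vials; deaths and
#'   escapes are only observed at these checks (default 3).
#' @param censor_prob_per_check probability that a live fly escapes or is
#'   accidentally killed at any one check, independently across checks.
#' @param max_age observation horizon in days; flies alive at the horizon
#'   are censored at the last check.
#'
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_isolines = 14L, n_per_group = 90L,
                          check_interval = 3, censor_prob_per_check = 0.002,
                          max_age = 200) {
  n_isolines <- as.integer(n_isolines)
  n_per_group <- as.integer(n_per_group)
  stopifnot(n_isolines >= 1L, n_per_group >= 1L, check_interval > 0,
            censor_prob_per_check >= 0, censor_prob_per_check < 1,
            max_age > check_interval)
  structure(list(n_isolines = n_isolines, n_per_group = n_per_group,
                 check_interval = check_interval,
                 censor_prob_per_check = censor_prob_per_check,
                 max_age = max_age),
            class = "cohort_design")
}

#' Gompertz hazard parameters with isoline frailty and a treatment hump
#'
#' Parameterizes the individual hazard used by [simulate_cohort()]:
#' \deqn{\mu_{i,s,t}(x) = \exp\{\log a_{s,t} + b x + z_i +
#'   h \, 1[t = \mathrm{treated}] e^{-x/d}\}}
#' where \eqn{z_i \sim N(0, \sigma^2)} is a line-level log-frailty shared by
#' all flies of isoline \eqn{i}, \eqn{b} is the Gompertz ageing slope
#' (shared by all groups, so all groups age at the same exponential rate),
#' and the last term is an early-adult excess-mortality hump of height
#' \eqn{h} on the log scale at eclosion, decaying with e-folding age
#' \eqn{d} days, applied to the treated group only.
#'
#' @param log_a named numeric of length 4 giving the log baseline hazard at
#'   age 0 for each sex x treatment group; names must be
#'   `"female.control"`, `"female.rapamycin"`, `"male.control"`,
#'   `"male.rapamycin"`.
#' @param b Gompertz slope per day (>= 0).
#' @param sigma_frailty standard deviation of the isoline log-frailty.
#' @param hump_height additive log-hazard excess at age 0 in the treated
#'   (rapamycin) group.
#' @param hump_decay e-folding age of the hump, days.
#'
#' @return An object of class `gompertz_frailty_params`.
#' @export
gompertz_frailty_params <- function(log_a = c(female.control = -5.3,
                                              female.rapamycin = -5.3,
                                              male.control = -5.0,
                                              male.rapamycin = -5.0),
                                    b = 0.08, sigma_frailty = 0.3,
                                    hump_height = 0.7, hump_decay = 10) {
  grp <- c("female.control", "female.rapamycin",
           "male.control", "male.rapamycin")
  if (is.null(names(log_a)) && length(log_a) == 4L) names(log_a) <- grp
  stopifnot(setequal(names(log_a), grp), all(is.finite(log_a)),
            b >= 0, sigma_frailty >= 0, hump_height >= 0, hump_decay > 0)
  structure(list(log_a = log_a[grp], b = b, sigma_frailty = sigma_frailty,
                 hump_height = hump_height, hump_decay = hump_decay),
            class = "gompertz_frailty_params")
}

group_key <- function(sex, treatment) paste(sex, treatment, sep = ".")

# Cumulative baseline hazard H0(x) = int_0^x exp(log_a + b u + hump(u)) du
# for one sex x treatment group (frailty excluded: H(x|z) = e^z H0(x)).
# Closed form when there is no hump; fine-grid trapezoid otherwise.
cum_baseline_hazard <- function(params, sex, treatment, x) {
  la <- params$log_a[[group_key(sex, treatment)]]
  b <- params$b
  h <- if (treatment == "rapamycin") params$hump_height else 0
  if (h == 0) {
    if (b == 0) exp(la) * x else exp(la) * (exp(b * x) - 1) / b
  } else {
    xmax <- max(x)
    grid <- seq(0, xmax, length.out = max(2000L, ceiling(xmax / 0.05) + 1L))
    mu <- exp(la + b * grid + h * exp(-grid / params$hump_decay))
    if (!all(is.finite(mu))) stop("non-finite hazard on the age grid")
    H <- pracma::cumtrapz(grid, mu)[, 1L]
    stats::approx(grid, H, xout = x, rule = 2)$y
  }
}

baseline_log_hazard <- function(params, sex, treatment, x) {
  la <- params$log_a[[group_key(sex, treatment)]]
  h <- if (treatment == "rapamycin") params$hump_height else 0
  la + params$b * x + h * exp(-x / params$hump_decay)
}

#' Simulate a fly cohort with Gompertz mortality and isoline frailty
#'
#' Draws one log-frailty per isoline, shared by all its flies; draws each
#' fly's latent death age by inverting the group's cumulative hazard at an
#' Exp(1) deviate; discretizes deaths upward to the next transfer check
#' (deaths are discovered at transfers); and censors flies independently at
#' each check before death with the design's escape probability.  Flies
#' whose latent death age exceeds the horizon are censored at the last
#' check.
#'
#' @param design a [cohort_design()].
#' @param params a [gompertz_frailty_params()].
#' @param seed integer seed; the same (design, params, seed) triple always
#'   yields identical records.
#'
#' @return A `data.frame` with one row per fly and columns `fly_id`,
#'   `isoline`, `sex`, `treatment`, `observed_age` (a positive multiple of
#'   `check_interval`) and `event` (`"death"` or `"censored"`).
#' @export
simulate_cohort <- function(design, params, seed = 1L) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(params, "gompertz_frailty_params"))
  set.seed(as.integer(seed))
  iv <- design$check_interval
  n_checks_max <- floor(design$max_age / iv)
  if (n_checks_max < 1L) stop("max_age admits no complete check interval")

  z <- stats::rnorm(design$n_isolines, 0, params$sigma_frailty)
  sexes <- c("female", "male")
  treatments <- c("control", "rapamycin")

  # invert H(x|z) = e^z H0(x) at Exp(1) deviates per group, via a shared
  # monotone interpolation table for H0
  xg <- seq(0, design$max_age,
            length.out = max(4000L, ceiling(design$max_age / 0.05) + 1L))
  out <- vector("list", 4L * design$n_isolines)
  idx <- 0L
  for (s in sexes) for (tr in treatments) {
    H0 <- cum_baseline_hazard(params, s, tr, xg)
    if (!all(is.finite(H0))) stop("non-finite cumulative hazard")
    for (i in seq_len(design$n_isolines)) {
      n <- design$n_per_group
      e <- stats::rexp(n) * exp(-z[i])        # target H0 value per fly
      latent <- stats::approx(H0, xg, xout = pmin(e, max(H0)),
                              ties = "ordered")$y
      truncated <- e > max(H0)
      # death discovered at the first check at or after the latent age
      death_check <- pmin(ceiling(latent / iv), n_checks_max)
      death_check[truncated] <- n_checks_max
      # independent escape at each earlier check
      if (design$censor_prob_per_check > 0) {
        g <- stats::rgeom(n, design$censor_prob_per_check) + 1L
      } else {
        g <- rep(Inf, n)
      }
      escaped <- g < death_check
      check <- ifelse(escaped, g, death_check)
      event <- ifelse(escaped | truncated, "censored", "death")
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        isoline = sprintf("iso%02d", i), sex = s, treatment = tr,
        observed_age = check * iv, event = event,
        latent_trunc = truncated, stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, out)
  if (mean(rec$latent_trunc) > 0.5)
    stop("max_age truncates more than half of all latent deaths; ",
         "implausible design")
  rec$latent_trunc <- NULL
  rec <- data.frame(fly_id = sprintf("fly%06d", seq_len(nrow(rec))), rec,
                    stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  rec
}

#' Exact marginal hazard of the simulated population
#'
#' Quadrature oracle for the population-level (marginal) mortality rate of
#' one sex x treatment group under the generator's continuous log-normal
#' frailty mixture:
#' \deqn{\bar\mu(x) = \frac{\int \mu(x|z) S(x|z)\, dF(z)}
#'                         {\int S(x|z)\, dF(z)}}
#' with \eqn{S(x|z) = \exp\{-e^z H_0(x)\}} and \eqn{z \sim N(0,\sigma^2)}.
#' Selection of robust lines among survivors makes \eqn{\bar\mu} rise more
#' slowly than any individual line's hazard.  With `sigma_frailty = 0` the
#' marginal hazard equals the conditional (z = 0) hazard exactly.
#'
#' Gauss-Hermite quadrature is used; the node count is doubled until the
#' log-scale result is stable to `tol`, and non-convergence is reported
#' with the offending age.  A gamma frailty mixture (matched to the same
#' variance of the frailty e^z) is available for cross-checks.
#'
#' @param params a [gompertz_frailty_params()].
#' @param sex,treatment group selectors.
#' @param ages numeric vector of ages (days).
#' @param frailty `"lognormal"` (the generator's distribution) or
#'   `"gamma"` (variance-matched, closed-form Laplace transform).
#' @param n_nodes initial Gauss-Hermite node count.
#' @param tol log-scale convergence tolerance for node doubling.
#'
#' @return A `hazard_curve` data.frame with columns `age` and `log_mu`,
#'   flavor `"marginal"`.
#' @export
true_marginal_hazard <- function(params, sex, treatment, ages,
                                 frailty = c("lognormal", "gamma"),
                                 n_nodes = 40L, tol = 1e-8) {
  stopifnot(inherits(params, "gompertz_frailty_params"), all(ages >= 0))
  frailty <- match.arg(frailty)
  sig <- params$sigma_frailty
  H0 <- cum_baseline_hazard(params, sex, treatment, ages)
  mu0 <- exp(baseline_log_hazard(params, sex, treatment, ages))
  if (sig == 0) {
    log_mu <- log(mu0)
  } else if (frailty == "gamma") {
    # gamma frailty w = e^z with E w matched to lognormal mean and
    # Var w matched: shape k, scale theta with k theta = m, k theta^2 = v
    m <- exp(sig^2 / 2); v <- (exp(sig^2) - 1) * exp(sig^2)
    k <- m^2 / v; theta <- v / m
    # E[w S]/E[S] under w ~ Gamma: closed form k*theta/(1+theta H0)
    log_mu <- log(mu0) + log(k * theta) - log1p(theta * H0)
  } else {
    marg <- function(nn) {
      gh <- pracma::gaussHermite(nn)
      w <- gh$w / sqrt(pi)
      zz <- sqrt(2) * sig * gh$x
      ez <- exp(zz)
      # rows = ages, cols = nodes; use log-sum-exp for stability
      lS <- -outer(H0, ez)                       # log S(x|z)
      lnum <- sweep(lS, 2L, zz, "+")             # log[e^z S]
      lw <- log(w)
      num <- apply(sweep(lnum, 2L, lw, "+"), 1L, logsumexp)
      den <- apply(sweep(lS, 2L, lw, "+"), 1L, logsumexp)
      log(mu0) + num - den
    }
    log_mu <- marg(n_nodes)
    nn <- n_nodes
    repeat {
      nn <- nn * 2L
      log_mu2 <- marg(nn)
      gap <- max(abs(log_mu2 - log_mu))
      log_mu <- log_mu2
      if (gap < tol) break
      if (nn > 640L)
        stop("frailty quadrature did not converge at age ",
             ages[which.max(abs(log_mu2 - log_mu))])
    }
  }
  hazard_curve(ages, log_mu, flavor = "marginal",
               stratum = group_key(sex, treatment))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Exact marginal survivorship of the simulated population
#'
#' Companion oracle to [true_marginal_hazard()]: the population survival
#' \eqn{\bar S(x) = \int \exp\{-e^z H_0(x)\} dF(z)} under the generator's
#' log-normal frailty mixture, by Gauss-Hermite quadrature.
#'
#' @inheritParams true_marginal_hazard
#' @return numeric vector of survival probabilities at `ages`.
#' @export
true_marginal_survival <- function(params, sex, treatment, ages,
                                   n_nodes = 80L) {
  stopifnot(inherits(params, "gompertz_frailty_params"))
  H0 <- cum_baseline_hazard(params, sex, treatment, ages)
  sig <- params$sigma_frailty
  if (sig == 0) return(exp(-H0))
  gh <- pracma::gaussHermite(n_nodes)
  w <- gh$w / sqrt(pi)
  ez <- exp(sqrt(2) * sig * gh$x)
  as.vector(exp(-outer(H0, ez)) %*% w)
}

#' Write or read individual fly records as CSV
#'
#' Plain-text interchange for the record schema used throughout the
#' package: columns `fly_id,isoline,sex,treatment,observed_age,event`.
#'
#' @param records a record data.frame as produced by [simulate_cohort()].
#' @param path file path.
#' @return `read_records()` returns the validated record data.frame.
#' @export
write_records <- function(records, path) {
  utils::write.csv(validate_records(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  validate_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

validate_records <- function(records) {
  need <- c("fly_id", "isoline", "sex", "treatment", "observed_age", "event")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  bad <- which(!(records$sex %in% c("female", "male")) |
               !(records$treatment %in% c("control", "rapamycin")) |
               !(records$event %in% c("death", "censored")))
  if (length(bad))
    stop("unknown factor level in record row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (any(!is.finite(records$observed_age)) || any(records$observed_age <= 0))
    stop("observed_age must be positive and finite; offending row(s) ",
         paste(utils::head(which(!is.finite(records$observed_age) |
                                 records$observed_age <= 0), 5L),
               collapse = ", "))
  records[need]
}
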