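#' Hazard curve container
#'
#' A log mortality rate over an age grid, tagged with its flavor —
#' `"conditional"` (line random effects removed from the prediction),
#' `"marginal"` (population-level, frailty-weighted), or
#' `"per_isoline"` — and the sex x treatment stratum it belongs to.
#' Flavors are propagated to differences and must match when two curves
#' are compared.
#'
#' @param age strictly increasing age grid (days).
#' @param log_mu finite log hazard values.
#' @param flavor one of `"conditional"`, `"marginal"`, `"per_isoline"`.
#' @param stratum label such as `"female.control"`.
#' @param isoline optional line label for per-isoline curves.
#' @return a `hazard_curve` data.frame with attributes `flavor`,
#'   `stratum`, `isoline`.
#' @export
hazard_curve <- function(age, log_mu, flavor, stratum, isoline = NA) {
  stopifnot(length(age) == length(log_mu), all(is.finite(age)),
            all(diff(age) > 0), all(is.finite(log_mu)))
  flavor <- match.arg(flavor, c("conditional", "marginal", "per_isoline"))
  structure(data.frame(age = age, log_mu = log_mu),
            flavor = flavor, stratum = stratum, isoline = isoline,
            class = c("hazard_curve", "data.frame"))
}

#' @export
print.hazard_curve <- function(x, ...) {
  cat(attr(x, "flavor"), "hazard curve,", attr(x, "stratum"),
      if (!is.na(attr(x, "isoline"))) paste0("(", attr(x, "isoline"), ")"),
      "over ages", min(x$age), "-", max(x$age), "days\n")
  invisible(x)
}

#' Marginal (population-level) hazard from a fitted model
#'
#' Aggregates the fitted per-isoline hazards into the population-level
#' mortality rate that an observer pooling all lines would see.  Lines
#' with higher frailty die out earlier, so survivors are progressively
#' enriched in robust lines and the marginal hazard rises more slowly
#' than any line's own (conditional) hazard:
#' \deqn{\bar\mu(x) = \sum_i w_i(x)\,\mu_i(x), \qquad
#'   w_i(x) = S_i(x) \big/ \sum_j S_j(x)}
#' with \eqn{S_i(x) = \exp\{-\int_0^x \mu_i(u)\,du\}} accumulated by the
#' trapezoid rule on the age grid (weights uniform at the grid start).
#' Lines are weighted equally at the start, matching equal initial group
#' sizes per line.
#'
#' @param fit a [hazgam()] fit.  If it has no isoline random effects the
#'   marginal hazard equals the conditional one and that curve is
#'   returned.
#' @param sex,treatment stratum selectors.
#' @param ages age grid; defaults to the life-table bin midpoints.
#' @return a [hazard_curve()] with flavor `"marginal"`.
#' @export
marginal_hazard <- function(fit, sex = "female", treatment = "control",
                            ages = NULL) {
  if (is.null(ages))
    ages <- sort(unique(fit$lifetable$age_bin_start)) + fit$bin_width / 2
  cond <- predict(fit, ages = ages, sex = sex, treatment = treatment)
  if (fit$spec$isoline == "none")
    return(hazard_curve(ages, cond$log_mu, flavor = "marginal",
                        stratum = attr(cond, "stratum")))
  percurve <- predict(fit, ages = ages, sex = sex, treatment = treatment,
                      isoline = "each")
  L <- vapply(percurve, function(cv) cv$log_mu, numeric(length(ages)))
  if (any(abs(diff(L)) > 2))
    warning("age grid may be too coarse for stable survivorship ",
            "integration (adjacent log-hazard jump > 2)")
  Mu <- exp(L)                               # ages x isolines
  H <- apply(Mu, 2L, function(m) pracma::cumtrapz(ages, m)[, 1L])
  S <- exp(-H)                               # survivorship from grid start
  w <- S / rowSums(S)
  mbar <- rowSums(w * Mu)
  hazard_curve(ages, log(mbar), flavor = "marginal",
               stratum = paste(sex, treatment, sep = "."))
}

#' Bootstrap refits of a fitted hazard model
#'
#' Resamples individual flies with replacement within each
#' isoline x sex x treatment cell (preserving the design and each line's
#' sample size), rebuilds the life table at the original bin width, and
#' refits the model with smoothing parameters frozen at the original
#' fit's values.  Replicates that fail to converge are dropped and
#' counted; more than 10% failures aborts.
#'
#' @param records the individual records the original life table was
#'   built from.
#' @param fit the original [hazgam()] fit.
#' @param n_boot number of replicates (>= 200 for percentile bands).
#' @param seed integer seed.
#' @return A `hazgam_boot` object: list with `fits` (list of `hazgam`),
#'   `n_failed`, `seed`, and the original `fit`.
#' @export
bootstrap_refits <- function(records, fit, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "hazgam"), n_boot >= 1L)
  records <- validate_records(records)
  set.seed(as.integer(seed))
  cell <- interaction(records$isoline, records$sex, records$treatment,
                      drop = TRUE)
  idx_by_cell <- split(seq_len(nrow(records)), cell)

  # per-fly (D, E) contributions to each life-table row: a resampled
  # cohort's life table is T %*% multiplicities, so the design matrix is
  # built once and only the Poisson working fit is repeated
  ct <- lifetable_contributions(records, fit$bin_width,
                                fit$endpoint_exposure)
  lt <- fit$lifetable
  row_id <- paste(lt$isoline, lt$sex, lt$treatment, lt$age_bin_start,
                  sep = "\r")
  ct_row <- match(paste(ct$isoline, ct$sex, ct$treatment,
                        ct$bin * fit$bin_width, sep = "\r"), row_id)
  keep_ct <- !is.na(ct_row)   # contributions to rows present in the fit
  TD <- Matrix::sparseMatrix(i = ct_row[keep_ct], j = ct$fly[keep_ct],
                             x = ct$D[keep_ct],
                             dims = c(nrow(lt), nrow(records)))
  TE <- Matrix::sparseMatrix(i = ct_row[keep_ct], j = ct$fly[keep_ct],
                             x = ct$E[keep_ct],
                             dims = c(nrow(lt), nrow(records)))

  des <- fit$design
  fits <- vector("list", n_boot)
  failed <- 0L
  m <- numeric(nrow(records))
  for (b in seq_len(n_boot)) {
    m[] <- 0
    for (ix in idx_by_cell) {
      s <- ix[sample.int(length(ix), length(ix), replace = TRUE)]
      tb <- tabulate(s, nbins = length(m))
      m <- m + tb
    }
    Dn <- as.numeric(TD %*% m)
    En <- as.numeric(TE %*% m)
    rows <- En > 0
    f <- tryCatch(
      pirls(des$X[rows, , drop = FALSE], Dn[rows], log(En[rows]),
            des$blocks, fit$lambda, beta0 = fit$coefficients),
      error = function(e) NULL)
    if (is.null(f) || !f$converged) { failed <- failed + 1L; next }
    rep_fit <- fit
    rep_fit$coefficients <- f$beta
    rep_fit$edf <- f$edf; rep_fit$loglik <- f$loglik; rep_fit$aic <- f$aic
    rep_fit$fitted_mu <- f$mu
    rep_fit$lifetable <- lt[rows, , drop = FALSE]
    rep_fit$lifetable$D <- Dn[rows]; rep_fit$lifetable$E <- En[rows]
    fits[[b]] <- rep_fit
  }
  fits <- Filter(Negate(is.null), fits)
  if (failed > 0.1 * n_boot)
    stop(failed, " of ", n_boot, " bootstrap refits failed")
  structure(list(fits = fits, n_failed = failed, seed = seed, fit = fit),
            class = "hazgam_boot")
}

#' @export
print.hazgam_boot <- function(x, ...) {
  cat("Bootstrap refits:", length(x$fits), "successful,", x$n_failed,
      "failed (seed", x$seed, ")\n")
  invisible(x)
}

curve_for <- function(fit, stratum, flavor, ages) {
  st <- strsplit(stratum, ".", fixed = TRUE)[[1L]]
  if (flavor == "marginal")
    marginal_hazard(fit, sex = st[1L], treatment = st[2L], ages = ages)
  else predict(fit, ages = ages, sex = st[1L], treatment = st[2L])
}

# age-bin midpoints with positive exposure in a stratum
observable_midpoints <- function(lt, stratum, bw) {
  st <- strsplit(stratum, ".", fixed = TRUE)[[1L]]
  r <- lt$sex == st[1L] & lt$treatment == st[2L] & lt$E > 0
  sort(unique(lt$age_bin_start[r])) + bw / 2
}

#' Log-mortality difference between two strata with bootstrap band
#'
#' Pointwise difference \eqn{\Delta(x) = \log\mu_A(x) - \log\mu_B(x)}
#' between two sex x treatment strata, with a bootstrap percentile
#' confidence band: at each grid age the bounds are the \eqn{\alpha/2}
#' and \eqn{1-\alpha/2} empirical quantiles of the replicate differences.
#' Significant age windows are the maximal runs of consecutive grid ages
#' whose interval excludes zero, signed by the direction of the
#' difference there.  Both curves must carry the same flavor; marginal
#' and conditional curves are never mixed.  The grid is restricted to
#' ages observable (positive exposure) in both strata; the bands are
#' pointwise — no familywise correction is applied.
#'
#' @param boot a [bootstrap_refits()] result (at least 200 successful
#'   replicates).
#' @param stratum_A,stratum_B labels like `"female.control"`; the
#'   difference is A minus B.
#' @param flavor `"marginal"` or `"conditional"`.
#' @param alpha two-sided miscoverage level (default 0.05).
#' @param ages optional grid; defaults to bin midpoints observable in
#'   both strata.
#' @return A `difference_band` object: data.frame with `age`, `delta`,
#'   `lo`, `hi`, `significant`, plus attributes `windows` (data.frame of
#'   maximal significant intervals with their signs), `flavor`, `alpha`.
#' @export
difference_band <- function(boot, stratum_A, stratum_B,
                            flavor = c("marginal", "conditional"),
                            alpha = 0.05, ages = NULL) {
  stopifnot(inherits(boot, "hazgam_boot"))
  flavor <- match.arg(flavor)
  if (length(boot$fits) < 200L)
    stop("need >= 200 successful bootstrap refits, have ",
         length(boot$fits))
  fit <- boot$fit
  if (is.null(ages)) {
    a1 <- observable_midpoints(fit$lifetable, stratum_A, fit$bin_width)
    a2 <- observable_midpoints(fit$lifetable, stratum_B, fit$bin_width)
    ages <- intersect(a1, a2)
    if (!length(ages)) stop("strata have no overlapping observable ages")
  }
  delta <- curve_delta(fit, stratum_A, stratum_B, flavor, ages)
  reps <- vapply(boot$fits, function(f)
    curve_delta(f, stratum_A, stratum_B, flavor, ages),
    numeric(length(ages)))
  if (length(ages) == 1L) reps <- matrix(reps, nrow = 1L)
  lo <- apply(reps, 1L, stats::quantile, probs = alpha / 2, names = FALSE)
  hi <- apply(reps, 1L, stats::quantile, probs = 1 - alpha / 2,
              names = FALSE)
  sig <- lo > 0 | hi < 0
  band <- data.frame(age = ages, delta = delta, lo = lo, hi = hi,
                     significant = sig)
  structure(band, windows = significant_windows(ages, delta, sig),
            flavor = flavor, alpha = alpha,
            stratum_A = stratum_A, stratum_B = stratum_B,
            class = c("difference_band", "data.frame"))
}

# difference of two same-flavor curves on a shared grid
curve_delta <- function(fit, stratum_A, stratum_B, flavor, ages) {
  cA <- curve_for(fit, stratum_A, flavor, ages)
  cB <- curve_for(fit, stratum_B, flavor, ages)
  diff_curves(cA, cB)
}

#' Difference of two hazard curves (flavor-checked)
#' @param a,b [hazard_curve()]s on the same age grid and of the same
#'   flavor.
#' @return numeric vector `a$log_mu - b$log_mu`.
#' @export
diff_curves <- function(a, b) {
  if (!identical(attr(a, "flavor"), attr(b, "flavor")))
    stop("cannot difference curves of different flavors: ",
         attr(a, "flavor"), " vs ", attr(b, "flavor"))
  if (!isTRUE(all.equal(a$age, b$age)))
    stop("curves are on different age grids")
  a$log_mu - b$log_mu
}

# maximal runs of significant grid ages, signed
significant_windows <- function(ages, delta, sig) {
  if (!any(sig))
    return(data.frame(start = numeric(0), end = numeric(0),
                      sign = character(0)))
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = ages[starts[keep]], end = ages[ends[keep]],
             sign = vapply(keep, function(i) {
               if (mean(delta[starts[i]:ends[i]]) > 0) "positive"
               else "negative"
             }, ""))
}

#' @export
print.difference_band <- function(x, ...) {
  cat(sprintf("%s log-mortality difference: %s - %s (alpha = %g)\n",
              attr(x, "flavor"), attr(x, "stratum_A"),
              attr(x, "stratum_B"), attr(x, "alpha")))
  w <- attr(x, "windows")
  if (nrow(w) == 0) cat("  no significant age windows\n")
  else for (i in seq_len(nrow(w)))
    cat(sprintf("  %s window: %g-%g days\n", w$sign[i], w$start[i],
                w$end[i]))
  invisible(x)
}

#' @export
plot.difference_band <- function(x, ..., xlab = "age (days)",
                                 ylab = "log mortality difference") {
  graphics::plot(x$age, x$delta, type = "l", ylim = range(x$lo, x$hi, 0),
                 xlab = xlab, ylab = ylab, ...)
  graphics::lines(x$age, x$lo, lty = 2)
  graphics::lines(x$age, x$hi, lty = 2)
  graphics::abline(h = 0, col = "grey")
  w <- attr(x, "windows")
  for (i in seq_len(nrow(w)))
    graphics::segments(w$start[i], 0, w$end[i], 0,
                       col = if (w$sign[i] == "negative") "blue" else "red",
                       lwd = 3)
  invisible(x)
}

#' Write a difference band as CSV
#' @param band a [difference_band()].
#' @param path file path.
#' @export
write_band <- function(band, path) {
  utils::write.csv(as.data.frame(band), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
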