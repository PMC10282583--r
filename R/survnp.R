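#' Kaplan-Meier survivorship curves per group
#'
#' Product-limit estimates of survivorship honoring right censoring, one
#' curve per level of the grouping factor(s).  Censored flies with time
#' tied to a death are counted at risk at that time (deaths processed
#' before censorings), the standard convention.  Computation is delegated
#' to [survival::survfit()].
#'
#' @param records record data.frame (see [simulate_cohort()]).
#' @param group_by character vector of record columns defining groups,
#'   e.g. `c("sex", "treatment")`; `NULL` pools everything.
#'
#' @return A `km_curves` object: a list of data.frames (one per group)
#'   with columns `time`, `n_risk`, `d` (deaths), `S` (survivorship step
#'   function value at `time`).
#' @export
km_fit <- function(records, group_by = c("sex", "treatment")) {
  records <- validate_records(records)
  grp <- if (is.null(group_by)) rep("all", nrow(records)) else
    interaction(records[group_by], drop = TRUE, sep = ".", lex.order = TRUE)
  out <- list()
  for (g in levels(factor(grp))) {
    r <- records[grp == g, , drop = FALSE]
    if (nrow(r) == 0L) stop("empty group: ", g)
    sf <- survival::survfit(
      survival::Surv(r$observed_age, r$event == "death") ~ 1)
    keep <- sf$n.event > 0
    out[[g]] <- data.frame(time = sf$time[keep], n_risk = sf$n.risk[keep],
                           d = sf$n.event[keep], S = sf$surv[keep])
  }
  structure(out, class = "km_curves")
}

#' @export
print.km_curves <- function(x, ...) {
  cat("Kaplan-Meier curves for", length(x), "group(s)\n")
  for (g in names(x)) {
    med <- km_quantile(x[[g]], 0.5)
    cat(sprintf("  %-28s events %4d   median %s days\n", g, sum(x[[g]]$d),
                ifelse(is.na(med), "not reached", format(med))))
  }
  invisible(x)
}

# smallest event time with S <= 1 - p (NA if never reached)
km_quantile <- function(curve, p = 0.5) {
  i <- which(curve$S <= 1 - p)
  if (length(i)) curve$time[min(i)] else NA_real_
}

#' @export
plot.km_curves <- function(x, ..., xlab = "age (days)",
                           ylab = "survivorship") {
  cols <- seq_along(x)
  xmax <- max(vapply(x, function(d) max(d$time), 0))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1), xlab = xlab,
                 ylab = ylab, ...)
  for (i in seq_along(x)) {
    d <- x[[i]]
    graphics::lines(stats::stepfun(d$time, c(1, d$S)), col = cols[i],
                    do.points = FALSE)
  }
  graphics::legend("bottomleft", legend = names(x), col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}

#' Write Kaplan-Meier curves as CSV
#' @param km a [km_fit()] result.
#' @param path file path.
#' @export
write_km <- function(km, path) {
  rows <- do.call(rbind, lapply(names(km), function(g)
    data.frame(group = g, km[[g]])))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Gehan scores for right-censored data.  Pairwise convention: observation
# i scores +1 against j when i is known to outlive j (x_i > x_j with j a
# death, or tied times with j a death and i censored), -1 in the reverse
# case, 0 when the ordering is not determined (both censored, tied
# deaths, or a censoring before a death).  u_i is the row sum; scores sum
# to zero within the sample they are computed in.
gehan_scores <- function(time, death) {
  n <- length(time)
  u <- numeric(n)
  for (i in seq_len(n)) {
    known_before <- death & (time < time[i] | (time == time[i] & !death[i]))
    if (death[i]) {
      known_after <- time > time[i] | (time == time[i] & !death)
      known_after[i] <- FALSE
    } else known_after <- rep(FALSE, n)
    u[i] <- sum(known_before) - sum(known_after)
  }
  u
}

#' Stratified Gehan-Breslow two-sample test
#'
#' Generalized Wilcoxon (Gehan) test for a survival difference between the
#' two levels of `compare`, stratified by `strata`: Gehan scores are
#' computed within each stratum and the statistic is the sum of the scores
#' of the first `compare` level, summed across strata.  Weighting deaths
#' by the number at risk makes the test sensitive to early survival
#' differences and tolerant of non-proportional hazards and crossing
#' curves.  The null distribution is obtained by permuting group labels
#' within strata: exact enumeration (per-stratum subset sums convolved
#' across strata) when the total number of arrangements is small, seeded
#' Monte-Carlo otherwise, or a normal approximation using the exact
#' permutation variance.  Ties are handled by the pairwise scoring itself
#' (tied deaths are unordered) and enter the variance through the scores.
#'
#' @param records record data.frame.
#' @param compare name of the two-level record column to test
#'   (`"treatment"` or `"sex"`).
#' @param strata name(s) of stratifying columns, or `NULL` for none.
#' @param method `"exact"`, `"monte_carlo"`, or `"asymptotic"`;
#'   `"auto"` (default) uses exact enumeration when at most `max_exact`
#'   arrangements exist and Monte-Carlo otherwise.
#' @param n_permutations Monte-Carlo sample size.
#' @param max_exact arrangement-count bound for the automatic exact path.
#' @param seed seed for the Monte-Carlo path.
#'
#' @return A `gehan_test` object with elements `statistic` (raw score
#'   sum), `z` (standardized), `p_value` (two-sided, one-sided tail
#'   doubled and capped at 1), `method`, `n_permutations`, `strata_used`.
#' @export
gehan_breslow_test <- function(records, compare = "treatment",
                               strata = "sex",
                               method = c("auto", "exact", "monte_carlo",
                                          "asymptotic"),
                               n_permutations = 10000L, max_exact = 1e6,
                               seed = 1L) {
  method <- match.arg(method)
  records <- validate_records(records)
  g <- factor(records[[compare]])
  if (nlevels(g) != 2L)
    stop("'", compare, "' must have exactly 2 levels, found ", nlevels(g))
  st <- if (is.null(strata)) factor(rep("all", nrow(records))) else
    interaction(records[strata], drop = TRUE, sep = ".")
  level_A <- levels(g)[1L]

  per <- list()
  for (s in levels(st)) {
    r <- records[st == s, , drop = FALSE]
    gs <- g[st == s]
    if (nlevels(droplevels(gs)) != 2L)
      stop("stratum '", s, "' lacks one level of '", compare, "'")
    u <- gehan_scores(r$observed_age, r$event == "death")
    nA <- sum(gs == level_A); n <- length(u)
    # exact permutation variance of sum of nA scores drawn without
    # replacement from u (scores sum to 0 within the stratum)
    v <- nA * (n - nA) / (n * (n - 1)) * sum(u^2)
    per[[s]] <- list(u = u, inA = gs == level_A, nA = nA, n = n, var = v)
  }
  stat <- sum(vapply(per, function(p) sum(p$u[p$inA]), 0))
  vtot <- sum(vapply(per, function(p) p$var, 0))
  z <- if (vtot > 0) stat / sqrt(vtot) else 0

  n_arr <- prod(vapply(per, function(p) choose(p$n, p$nA), 0))
  if (method == "auto")
    method <- if (n_arr <= max_exact) "exact" else "monte_carlo"

  n_perm_used <- NA_integer_
  if (method == "exact") {
    if (n_arr > max_exact)
      stop("exact enumeration infeasible: ", format(n_arr), " arrangements")
    # per-stratum exact null of the score sum, convolved across strata
    dist <- data.frame(value = 0, prob = 1)
    for (p in per) {
      sums <- utils::combn(p$u, p$nA, sum)
      tab <- table(sums)
      d <- data.frame(value = as.numeric(names(tab)),
                      prob = as.vector(tab) / length(sums))
      grid <- expand.grid(a = seq_len(nrow(dist)), b = seq_len(nrow(d)))
      val <- dist$value[grid$a] + d$value[grid$b]
      pr <- dist$prob[grid$a] * d$prob[grid$b]
      agg <- rowsum(pr, round(val, 9))
      dist <- data.frame(value = as.numeric(rownames(agg)), prob = agg[, 1L])
    }
    eps <- 1e-9
    p_lo <- sum(dist$prob[dist$value <= stat + eps])
    p_hi <- sum(dist$prob[dist$value >= stat - eps])
    p <- min(1, 2 * min(p_lo, p_hi))
  } else if (method == "monte_carlo") {
    set.seed(as.integer(seed))
    m <- as.integer(n_permutations)
    tstar <- numeric(m)
    for (p in per) {
      u <- p$u; nA <- p$nA
      tstar <- tstar + vapply(seq_len(m), function(i)
        sum(u[sample.int(p$n, nA)]), 0)
    }
    eps <- 1e-9
    p_lo <- sum(tstar <= stat + eps) / m
    p_hi <- sum(tstar >= stat - eps) / m
    p <- min(1, 2 * min(p_lo, p_hi))
    n_perm_used <- m
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = stat, z = z, p_value = p, method = method,
                 n_permutations = n_perm_used, compare = compare,
                 level_A = level_A, strata_used = levels(st),
                 n_arrangements = n_arr),
            class = "gehan_test")
}

#' @export
print.gehan_test <- function(x, ...) {
  cat("Stratified Gehan-Breslow test on '", x$compare, "' (",
      x$method, ")\n", sep = "")
  cat(sprintf("  score sum (%s) = %g, z = %.3f, p = %.4g\n",
              x$level_A, x$statistic, x$z, x$p_value))
  cat("  strata:", paste(x$strata_used, collapse = ", "), "\n")
  invisible(x)
}
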