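#' Cubic B-spline basis with difference penalty (P-splines)
#'
#' Equally spaced cubic B-splines over an age range with a second-order
#' difference penalty on adjacent coefficients, the Eilers-Marx
#' construction.  The basis rows sum to one on `[xmin, xmax]` (partition
#' of unity) and the penalty's null space spans constants and linear
#' trends in age, so unpenalized structure up to a straight line in log
#' hazard (a Gompertz trend) always survives heavy smoothing.
#'
#' @param xmin,xmax age range covered without extrapolation.
#' @param k basis dimension (number of B-spline columns), default 10.
#' @param degree spline degree, default 3 (cubic).
#' @param penalty_order difference order of the penalty, default 2.
#'
#' @return A `smooth_basis` object with elements `knots`, `k`, `degree`,
#'   `penalty_order`, `P` (k x k penalty matrix) and the range.
#' @export
smooth_basis <- function(xmin, xmax, k = 10L, degree = 3L,
                         penalty_order = 2L) {
  stopifnot(xmax > xmin, k > degree + 1L, penalty_order >= 1L,
            penalty_order < k)
  ndx <- k - degree
  # hit the boundaries exactly (seq(by=) drifts in floating point)
  knots <- xmin + (xmax - xmin) * ((-degree):(ndx + degree)) / ndx
  D <- diff(diag(k), differences = penalty_order)
  structure(list(knots = knots, k = as.integer(k), degree = as.integer(degree),
                 penalty_order = as.integer(penalty_order),
                 P = crossprod(D), xmin = xmin, xmax = xmax),
            class = "smooth_basis")
}

#' Evaluate a smooth basis
#' @param basis a [smooth_basis()].
#' @param x ages within `[xmin, xmax]`.
#' @return matrix with `length(x)` rows and `basis$k` columns.
#' @export
eval_basis <- function(basis, x) {
  if (any(x < basis$xmin - 1e-8) || any(x > basis$xmax + 1e-8))
    stop("age outside the basis range [", basis$xmin, ", ", basis$xmax,
         "]; no extrapolation")
  x <- pmin(pmax(x, basis$xmin), basis$xmax)
  splines::splineDesign(basis$knots, x, ord = basis$degree + 1L,
                        outer.ok = TRUE)
}

# orthonormal basis of the penalty null space (constants, linear, ...)
penalty_nullspace <- function(basis) {
  U <- stats::poly(seq_len(basis$k), degree = basis$penalty_order - 1L,
                   raw = FALSE)
  cbind(1 / sqrt(basis$k), U)
}

# sum-to-zero reparameterization of a basis block over its active rows:
# returns Z (k x (k-1)) with colSums(B %*% Z) = 0 for the given B rows,
# plus the transformed penalty.
center_constraint <- function(B, P) {
  C <- matrix(colSums(B), nrow = 1L)
  Z <- qr.Q(qr(t(C)), complete = TRUE)[, -1L, drop = FALSE]
  list(Z = Z, P = crossprod(Z, P %*% Z))
}
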