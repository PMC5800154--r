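#' Cubic B-spline basis over calendar time
#'
#' Builds the temporal design matrix shared by the fixed curves S_j(t) and
#' the random-spline fields RS_0i(t), RS_ji(t). The basis is the clamped
#' cubic B-spline family on boundary knots at the range of the wave years
#' (each repeated degree + 1 times) with L interior knots, giving L + 4
#' functions that sum to one everywhere on the interior. Identifiability of
#' the gender intercepts requires a basis without an intercept: the first
#' basis function is dropped and the remaining K = L + 3 columns are
#' centered to mean zero across the wave years, so no coefficient vector can
#' reproduce a non-zero constant curve.
#'
#' @param times strictly increasing calendar years of the waves.
#' @param interior_knots years strictly inside \code{range(times)}; may be
#'   empty (K = 3).
#' @return An object of class \code{spline_basis}: list with \code{times},
#'   \code{interior_knots}, \code{degree} (3), \code{K}, \code{B} (T x K
#'   centered matrix) and \code{col_centers} (the subtracted column means,
#'   needed to evaluate the basis at off-wave times consistently).
#' @export
spline_basis <- function(times, interior_knots = numeric(0)) {
  times <- as.numeric(times)
  interior_knots <- sort(as.numeric(interior_knots))
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (anyDuplicated(interior_knots)) stop("duplicate knots")
  if (length(interior_knots) &&
      (min(interior_knots) <= min(times) || max(interior_knots) >= max(times)))
    stop("interior knots must lie strictly inside the time range")
  raw <- splines::bs(times, knots = interior_knots, degree = 3L,
                     intercept = FALSE, Boundary.knots = range(times))
  B <- unclass(raw)[, , drop = FALSE]
  centers <- colMeans(B)
  B <- sweep(B, 2L, centers)
  K <- ncol(B)
  stopifnot(K == length(interior_knots) + 3L)
  dimnames(B) <- list(times, paste0("B", seq_len(K)))
  structure(list(times = times, interior_knots = interior_knots, degree = 3L,
                 K = K, B = B, col_centers = centers),
            class = "spline_basis")
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf("<spline_basis> cubic, %d interior knot(s) {%s}, K = %d, T = %d\n",
              length(x$interior_knots), paste(x$interior_knots, collapse = ", "),
              x$K, length(x$times)))
  invisible(x)
}

#' Evaluate a spline curve at the wave times
#'
#' Computes S(t) = sum_k a_k B_k(t) at every wave, i.e. the matrix-vector
#' product B a.
#'
#' @param basis a \code{\link{spline_basis}}.
#' @param coefficients numeric vector of length K.
#' @return Numeric vector of curve values, one per wave, named by year.
#' @export
evaluate_curve <- function(basis, coefficients) {
  stopifnot(inherits(basis, "spline_basis"))
  if (length(coefficients) != basis$K)
    stop(sprintf("expected %d coefficients, got %d", basis$K, length(coefficients)))
  drop(basis$B %*% coefficients)
}
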