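#' B-spline basis for the log intercept function
#'
#' Builds the basis \eqn{B(t)} used to parameterize the intercept function
#' \eqn{\mu_0(t) = \exp\{B(t)'\alpha\}}. Interior knots are placed at the
#' \eqn{j/(k+1)} quantiles of the supplied (pooled visit) times for
#' \eqn{j = 1, \dots, k}; with the default `n_interior_knots = 4` these are
#' the quintiles (20/40/60/80th percentiles). Because the raw B-spline
#' columns form a partition of unity, the first raw column is dropped and an
#' explicit intercept column is prepended, giving a full-rank basis of
#' dimension `K = 1 + (n_interior_knots + degree)`.
#'
#' @param times pooled visit times used to place the interior knots
#' @param degree spline degree (default 3, cubic)
#' @param n_interior_knots number of interior knots (default 4)
#' @param boundary boundary knot pair; defaults to `c(0, max(times))` — pass
#'   `c(0, tau)` to cover the whole observation window
#' @return an object of class `spline_basis` with fields `degree`, `knots`,
#'   `boundary`, `K`
#' @export
spline_basis <- function(times, degree = 3, n_interior_knots = 4,
                         boundary = NULL) {
  stopifnot(degree >= 0, n_interior_knots >= 0)
  if (is.null(boundary)) boundary <- c(0, max(times))
  if (degree == 0) {
    # intercept-only basis: mu0(t) constant (used e.g. as a deliberately
    # inflexible fit in misspecification diagnostics)
    if (n_interior_knots > 0)
      stop("degree 0 supports no interior knots")
    return(structure(list(degree = 0L, knots = numeric(0),
                          boundary = boundary, K = 1L),
                     class = "spline_basis"))
  }
  if (length(unique(times)) <= n_interior_knots)
    stop("fewer distinct times (", length(unique(times)),
         ") than interior knots (", n_interior_knots, ")")
  knots <- if (n_interior_knots > 0)
    stats::quantile(times, probs = seq_len(n_interior_knots) /
                      (n_interior_knots + 1), names = FALSE, type = 7)
  else numeric(0)
  if (any(knots <= boundary[1] | knots >= boundary[2]))
    stop("interior knots must lie strictly inside the boundary")
  structure(list(degree = degree, knots = knots, boundary = boundary,
                 K = 1L + n_interior_knots + degree),
            class = "spline_basis")
}

#' Evaluate a spline basis
#'
#' @param basis a [spline_basis]
#' @param t times within the basis boundary
#' @param raw if `TRUE`, return the raw (partition-of-unity) B-spline columns
#'   of dimension `n_interior_knots + degree + 1` instead of the
#'   intercept-plus-dropped-column parameterization
#' @return matrix with `length(t)` rows and `basis$K` columns (or the raw
#'   dimension when `raw = TRUE`)
#' @export
eval_basis <- function(basis, t, raw = FALSE) {
  if (any(t < basis$boundary[1] | t > basis$boundary[2]))
    stop("evaluation time outside basis boundary [",
         basis$boundary[1], ", ", basis$boundary[2], "]")
  if (basis$degree == 0) {
    out <- matrix(1, nrow = length(t), ncol = 1,
                  dimnames = list(NULL, "(Intercept)"))
    return(out)
  }
  B <- splines::bs(t, knots = basis$knots, degree = basis$degree,
                   intercept = raw, Boundary.knots = basis$boundary)
  B <- matrix(as.numeric(B), nrow = length(t))
  if (raw) {
    colnames(B) <- paste0("rawB", seq_len(ncol(B)))
    return(B)
  }
  out <- cbind(1, B)
  colnames(out) <- c("(Intercept)", paste0("B", seq_len(ncol(B))))
  out
}

#' @export
print.spline_basis <- function(x, ...) {
  cat("B-spline basis: degree", x$degree, ", interior knots {",
      paste(signif(x$knots, 5), collapse = ", "), "}, boundary [",
      x$boundary[1], ",", x$boundary[2], "], K =", x$K, "\n")
  invisible(x)
}
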