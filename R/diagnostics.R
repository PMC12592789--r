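#' Subject-level residual process for the intercept's functional form
#'
#' For subject \eqn{i},
#' \deqn{R_i(t) = \sum_{u \le t} \Delta_i(u) e^{-Z_i(u)'\hat\eta -
#'   X_i'\hat\gamma} Y_i(u)\,dN_i(u) - \hat\Omega_i \hat\Lambda_0(C_i \wedge t),}
#' which has mean approximately zero under a correctly specified intercept
#' basis. Visits with unrecorded outcomes are excluded, and a subject with no
#' visits has \eqn{\hat\Omega_i = 0} so \eqn{R_i \equiv 0}.
#'
#' @param ds a [longdata] object
#' @param id subject identifier (character) present in `ds`
#' @param fit an `extended_fit`
#' @param intensity an `intensity_fit`
#' @param moments frailty moments from [frailty_moments]
#' @param t evaluation times in `[0, tau]` (vectorized)
#' @return numeric vector of `R_i(t)` values
#' @export
residual_process <- function(ds, id, fit, intensity, moments, t) {
  if (any(t < 0 | t > ds$tau)) stop("t must lie in [0, tau]")
  i <- match(as.character(id), ds$subjects$id)
  if (is.na(i)) stop("unknown subject id '", id, "'")
  v <- outcome_visits(ds)
  v <- v[v$id == ds$subjects$id[i], , drop = FALSE]
  Xi <- covariate_matrix(ds)[i, ]
  term1 <- if (nrow(v)) {
    Z <- visit_design(ds, fit$basis, v)
    r <- v$y * exp(-as.vector(Z %*% fit$eta) - sum(Xi * intensity$gamma))
    vapply(t, function(tt) sum(r[v$time <= tt]), numeric(1))
  } else rep(0, length(t))
  Ci <- ds$subjects$C[i]
  term1 - moments$Omega_hat[i] * eval_stepfun(intensity$Lambda0, pmin(Ci, t))
}

#' Averaged residual curve Res(t)
#'
#' Averages the subject residual processes \eqn{R_i(t)} over subjects on a
#' time grid. Under a correctly specified intercept basis the average
#' converges to zero in probability, so plotting the curve against time is a
#' diagnostic for the functional form of the intercept; systematic excursions
#' indicate that the basis cannot capture \eqn{\mu_0(t)}. This is a
#' diagnostic, not a formal test.
#'
#' @inheritParams residual_process
#' @param grid evaluation grid in `[0, tau]`; default 100 equally spaced
#'   points on `[0, tau]`
#' @return object of class `residual_curve`: data.frame-like list with
#'   `grid`, `values`, `n`
#' @export
residual_curve <- function(ds, fit, intensity, moments, grid = NULL) {
  if (is.null(grid)) grid <- seq(0, ds$tau, length.out = 100)
  if (length(grid) == 0) stop("empty grid")
  if (any(grid < 0 | grid > ds$tau)) stop("grid must lie in [0, tau]")
  n <- nrow(ds$subjects)
  v <- outcome_visits(ds)
  # term 1: (1/n) sum over visits with time <= t of the standardized outcome
  if (nrow(v)) {
    Z <- visit_design(ds, fit$basis, v)
    Xg <- as.vector(covariate_matrix(ds) %*% intensity$gamma)
    r <- v$y * exp(-as.vector(Z %*% fit$eta) -
                     Xg[match(v$id, ds$subjects$id)])
    ord <- order(v$time)
    cr <- cumsum(r[ord])
    k <- findInterval(grid, v$time[ord])
    t1 <- c(0, cr)[k + 1] / n
  } else t1 <- rep(0, length(grid))
  # term 2: (1/n) sum_i Omega_i Lambda0(C_i ^ t)
  C <- ds$subjects$C
  Om <- moments$Omega_hat
  ordC <- order(C)
  LC <- eval_stepfun(intensity$Lambda0, C[ordC])
  cOL <- cumsum(Om[ordC] * LC)          # subjects with C <= t, full Lambda0(C)
  cO <- cumsum(Om[ordC])
  kk <- findInterval(grid, C[ordC])     # count C_i <= t
  t2 <- (c(0, cOL)[kk + 1] +
           eval_stepfun(intensity$Lambda0, grid) * (sum(Om) - c(0, cO)[kk + 1])) / n
  structure(list(grid = grid, values = t1 - t2, n = n),
            class = "residual_curve")
}

#' Write a residual curve as two-column delimited text
#' @param curve a `residual_curve`
#' @param path output CSV path
#' @param plot_path optional PNG path for a simple diagnostic plot
#' @return invisibly, `path`
#' @export
write_residual_curve <- function(curve, path, plot_path = NULL) {
  utils::write.csv(data.frame(t = curve$grid, Res = curve$values), path,
                   row.names = FALSE)
  if (!is.null(plot_path)) {
    grDevices::png(plot_path, width = 800, height = 500)
    plot(curve$grid, curve$values, type = "l", xlab = "t", ylab = "Res(t)",
         main = "Intercept residual diagnostic")
    graphics::abline(h = 0, lty = 2)
    grDevices::dev.off()
  }
  invisible(path)
}

#' @export
print.residual_curve <- function(x, ...) {
  cat("Residual curve on", length(x$grid), "grid points; max |Res| =",
      format(max(abs(x$values))), "(n =", x$n, ")\n")
  invisible(x)
}
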