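# Per-visit design matrix Z_i(t) = (X_i, B(t)): covariates first, then the
# K basis columns (explicit intercept + dropped-first-column B-splines).
visit_design <- function(ds, basis, visits = NULL) {
  if (is.null(visits)) visits <- outcome_visits(ds)
  X <- covariate_matrix(ds)
  Xi <- X[match(visits$id, ds$subjects$id), , drop = FALSE]
  Z <- cbind(Xi, eval_basis(basis, visits$time))
  colnames(Z) <- c(ds$covariate_names,
                   colnames(Z)[(ncol(X) + 1):ncol(Z)])
  Z
}

# eta-free offset S(t) of the extended estimating equation, evaluated at each
# outcome-visit time:
#   S(t) = sum_j D_j(t) Omega_j e^{X_j'g} Z_j(t) / sum_j D_j(t) omega_j e^{X_j'g}
# The basis block of Z_j(t) does not depend on j, so S(t) factors into a
# covariate part and B(t) times a scalar ratio.
extended_offsets <- function(ds, fit, moments, basis, times) {
  X <- covariate_matrix(ds)
  expXg <- as.vector(exp(X %*% fit$gamma))
  wOmega <- moments$Omega_hat * expXg
  womega <- moments$omega_hat * expXg
  num <- risk_sum(ds$subjects$C, cbind(X * wOmega, wOmega), times)
  den <- as.vector(risk_sum(ds$subjects$C, womega, times))
  if (any(den <= 0))
    stop("zero risk-set weight in S(t) at some visit time")
  p <- ncol(X)
  ratio <- num[, p + 1] / den
  S <- cbind(num[, seq_len(p), drop = FALSE] / den,
             eval_basis(basis, times) * ratio)
  colnames(S) <- c(ds$covariate_names, colnames(eval_basis(basis, times[1])))
  S
}

#' Extended estimating function L(eta)
#'
#' Evaluates the joint estimating function for \eqn{\eta = (\beta, \alpha)}:
#' \deqn{L(\eta) = \sum_i \int_0^\tau \left\{ Z_i(t) Y_i(t) e^{-Z_i(t)'\eta}
#'   - S(t) \right\} \Delta_i(t)\, dN_i(t),}
#' where \eqn{Z_i(t) = (X_i, B(t))} and the inner average
#' \deqn{S(t) = \frac{\sum_j \Delta_j(t) \hat\Omega_j e^{X_j'\hat\gamma}
#'   Z_j(t)}{\sum_j \Delta_j(t) \hat\omega_j e^{X_j'\hat\gamma}}}
#' does not involve \eqn{\eta} and is computed once per visit time.
#'
#' @param eta parameter vector `(beta, alpha)` of length `p + basis$K`
#' @param ds a [longdata] object
#' @param fit intensity fit from [fit_visit_model]
#' @param moments frailty moments from [frailty_moments]
#' @param basis a [spline_basis] covering all visit times
#' @return numeric vector of length `length(eta)`
#' @export
extended_ee <- function(eta, ds, fit, moments, basis) {
  v <- outcome_visits(ds)
  p <- length(ds$covariate_names)
  if (length(eta) != p + basis$K)
    stop("eta must have length ", p + basis$K)
  if (nrow(v) == 0) return(numeric(p + basis$K))
  Z <- visit_design(ds, basis, v)
  S <- extended_offsets(ds, fit, moments, basis, v$time)
  drop(crossprod(Z, v$y * exp(-as.vector(Z %*% eta)))) - colSums(S)
}

#' Joint estimation of relative effects and the intercept function
#'
#' Solves the extended estimating equation \eqn{L(\eta) = 0} (see
#' [extended_ee]) for \eqn{\eta = (\beta, \alpha)}, where the intercept
#' function is parameterized as \eqn{\mu_0(t) = \exp\{B(t)'\alpha\}} on a
#' B-spline basis. Because the offset \eqn{S(t)} is free of \eqn{\eta}, the
#' Jacobian is the explicitly negative semidefinite matrix
#' \eqn{-\sum Z Z' Y e^{-Z'\eta}} and Newton iteration with step-halving is
#' used. The basis columns are centered over the observed visits before
#' solving (folded back into the intercept afterwards) to keep the iteration
#' well conditioned.
#'
#' @inheritParams extended_ee
#' @param init starting value for `eta` (default 0)
#' @param tol tolerance on `max(abs(L))` (default 1e-8)
#' @param max_iter maximum Newton iterations (default 100)
#' @return object of class `extended_fit`: `eta`, `beta`, `alpha`, `basis`,
#'   `gamma` (copied from `fit`), `converged`, `equation_norm`, `iterations`
#' @export
fit_sun_extended <- function(ds, fit, moments, basis, init = NULL,
                             tol = 1e-8, max_iter = 100) {
  v <- outcome_visits(ds)
  if (nrow(v) == 0) stop("no outcome visits")
  p <- length(ds$covariate_names)
  K <- basis$K
  Z <- visit_design(ds, basis, v)
  pos <- v$y > 0
  qrz <- qr(Z[pos, , drop = FALSE])
  if (qrz$rank < ncol(Z)) {
    dep <- colnames(Z)[qrz$pivot[(qrz$rank + 1):ncol(Z)]]
    stop("design over positive-outcome visits is rank deficient; ",
         "dependent column(s): ", paste(dep, collapse = ", "))
  }
  S <- extended_offsets(ds, fit, moments, basis, v$time)
  # center the spline columns (not the intercept, not the covariates) and
  # absorb the means into the intercept column
  ctr_cols <- if (K > 1) seq.int(p + 2, p + K) else integer(0)
  mu <- colMeans(Z[, ctr_cols, drop = FALSE])
  Zc <- Z
  Sc <- S
  if (length(ctr_cols)) {
    Zc[, ctr_cols] <- sweep(Z[, ctr_cols, drop = FALSE], 2, mu)
    # S's intercept column equals the scalar ratio at each visit time, so the
    # centered spline block of S shifts by ratio * mu
    Sc[, ctr_cols] <- S[, ctr_cols, drop = FALSE] -
      tcrossprod(S[, p + 1], mu)
  }
  Ssum <- colSums(Sc)

  eta <- if (is.null(init)) numeric(p + K) else {
    ic <- init
    ic[p + 1] <- ic[p + 1] + sum(mu * init[ctr_cols])
    ic
  }
  Lfun <- function(e) drop(crossprod(Zc, v$y * exp(-as.vector(Zc %*% e)))) - Ssum
  L <- Lfun(eta)
  iter <- 0L
  while (max(abs(L)) >= tol && iter < max_iter) {
    w <- v$y * exp(-as.vector(Zc %*% eta))
    J <- -crossprod(Zc, Zc * w)
    step <- tryCatch(solve(J, -L), error = function(e)
      stop("singular Jacobian in the extended estimating equation"))
    lambda <- 1
    repeat {
      L_new <- Lfun(eta + lambda * step)
      if (max(abs(L_new)) < max(abs(L)) || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    eta <- eta + lambda * step
    L <- L_new
    iter <- iter + 1L
  }
  if (max(abs(L)) >= tol)
    stop("extended estimating equation did not converge; final norm ",
         format(max(abs(L))))
  # un-center: alpha_1 absorbs -sum(mu * alpha_rest)
  eta_out <- eta
  eta_out[p + 1] <- eta[p + 1] - sum(mu * eta[ctr_cols])
  names(eta_out) <- colnames(Z)
  structure(list(
    eta = eta_out,
    beta = eta_out[seq_len(p)],
    alpha = eta_out[(p + 1):(p + K)],
    basis = basis, gamma = fit$gamma,
    converged = TRUE,
    equation_norm = max(abs(extended_ee(eta_out, ds, fit, moments, basis))),
    iterations = iter), class = "extended_fit")
}

#' Predicted mean outcome trajectory
#'
#' Evaluates \eqn{\hat E(Y(t) \mid X) = \exp\{B(t)'\hat\alpha + X'\hat\beta\}}
#' over a time grid. With `X = 0` this is the estimated intercept (mean
#' outcome) trajectory \eqn{\hat\mu_0(t)}.
#'
#' @param fit an `extended_fit`
#' @param times evaluation times within the basis boundary
#' @param X covariate profile (default all zero)
#' @return nonnegative numeric vector of length `length(times)`
#' @export
predict_trajectory <- function(fit, times, X = NULL) {
  p <- length(fit$beta)
  if (is.null(X)) X <- numeric(p)
  stopifnot(length(X) == p)
  B <- eval_basis(fit$basis, times)
  exp(as.vector(B %*% fit$alpha) + sum(X * fit$beta))
}

#' Export an extended fit as flat text
#'
#' Writes the coefficient table and a basis-specification block sufficient to
#' re-evaluate trajectories exactly.
#'
#' @param fit an `extended_fit`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_extended_fit <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coefficients", con)
  writeLines(sprintf("%s\t%.17g", names(fit$eta), fit$eta), con)
  writeLines("# basis", con)
  writeLines(sprintf("degree\t%d", fit$basis$degree), con)
  writeLines(sprintf("knots\t%s",
                     paste(sprintf("%.17g", fit$basis$knots), collapse = ",")),
             con)
  writeLines(sprintf("boundary\t%.17g,%.17g", fit$basis$boundary[1],
                     fit$basis$boundary[2]), con)
  invisible(path)
}

#' @export
print.extended_fit <- function(x, ...) {
  cat("Extended joint fit: relative effects and intercept function\n")
  cat("beta:\n"); print(x$beta)
  cat("alpha (", length(x$alpha), " spline coefficients), ", sep = "")
  cat("converged:", x$converged, " ||L|| =", format(x$equation_norm), "\n")
  invisible(x)
}
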