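# visits with a recorded outcome (rows with y = NA are intensity-only)
outcome_visits <- function(ds) {
  ds$visits[!is.na(ds$visits$y), , drop = FALSE]
}

# For each time u in `times`, sum w[j] over subjects with C[j] >= u.
# w may be a matrix (one column per weight vector); returns a matrix with
# one row per element of `times`. O((n + length(times)) log n).
risk_sum <- function(C, w, times) {
  w <- as.matrix(w)
  ord <- order(C)
  pc <- rbind(0, apply(w[ord, , drop = FALSE], 2, cumsum))
  tot <- pc[nrow(pc), ]
  k <- findInterval(times, C[ord], left.open = TRUE)  # count of C < u
  out <- matrix(rep(tot, each = length(times)), nrow = length(times))
  out - pc[k + 1, , drop = FALSE]
}

#' Cumulative step function
#'
#' Right-continuous nondecreasing step function with value 0 before the first
#' jump, used for cumulative baseline intensities.
#'
#' @param times increasing jump times
#' @param values cumulative values at and after each jump
#' @return an object of class `cum_stepfun`
#' @export
cum_stepfun <- function(times, values) {
  stopifnot(length(times) == length(values))
  if (is.unsorted(times, strictly = TRUE)) stop("jump times must be increasing")
  if (any(diff(c(0, values)) < -1e-12)) stop("values must be nondecreasing")
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "cum_stepfun")
}

#' Evaluate a cumulative step function
#' @param sf a [cum_stepfun]
#' @param t times at which to evaluate (right-continuous lookup)
#' @return numeric vector, 0 before the first jump
#' @export
eval_stepfun <- function(sf, t) {
  c(0, sf$values)[findInterval(t, sf$times) + 1]
}

#' @export
print.cum_stepfun <- function(x, ...) {
  cat("cum_stepfun with", length(x$times), "jumps on [",
      format(min(x$times)), ",", format(max(x$times)), "], final value",
      format(x$values[length(x$values)]), "\n")
  invisible(x)
}

#' Fit the visit-intensity model by Andersen-Gill partial likelihood
#'
#' Fits the proportional visit-intensity model
#' \eqn{\lambda(t \mid X, \nu) = \nu \lambda_0(t) \exp(X'\gamma)}
#' treating visits as recurrent events in counting-process form. With
#' `frailty = "none"` (the default used by the estimating-equation stage) the
#' multiplicative frailty is left unmodelled and \eqn{\gamma} is estimated by
#' the ordinary Andersen-Gill partial likelihood with Breslow tie handling;
#' this remains consistent for \eqn{\gamma} because the frailty has unit
#' conditional mean. With `frailty = "gamma"` a shared gamma frailty is
#' fitted by penalized partial likelihood (the case-study recipe).
#'
#' The returned cumulative baseline \eqn{\hat\Lambda_0} is the Breslow
#' estimator with unit frailty weight in the risk-set denominator (see
#' [breslow_baseline]), which is the convention the frailty-moment estimators
#' require.
#'
#' @param ds a [longdata] object with at least one visit
#' @param frailty `"none"` or `"gamma"`
#' @return an object of class `intensity_fit`: `gamma` (named coefficient
#'   vector), `Lambda0` (a [cum_stepfun]), `converged`, `iterations`, and for
#'   `frailty = "gamma"` the estimated frailty variance `frailty_variance`.
#' @export
fit_visit_model <- function(ds, frailty = c("none", "gamma")) {
  frailty <- match.arg(frailty)
  if (nrow(ds$visits) == 0) stop("no visit events in dataset")
  X <- covariate_matrix(ds)
  const <- apply(X, 2, function(col) max(col) - min(col) == 0)
  if (ncol(X) >= 1 && any(const))
    stop("covariate(s) constant across subjects (unidentifiable): ",
         paste(colnames(X)[const], collapse = ", "))

  cp <- counting_process_frame(ds)
  fmla_rhs <- paste(c(ds$covariate_names, if (frailty == "gamma")
    "survival::frailty(id)"), collapse = " + ")
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(tstart, tstop, event) ~", fmla_rhs)),
    data = cp, ties = "breslow",
    control = survival::coxph.control(eps = 1e-9, iter.max = 50))
  gamma <- fit$coefficients[ds$covariate_names]
  if (any(!is.finite(gamma)))
    stop("Andersen-Gill fit did not converge: non-finite coefficients")
  structure(list(
    gamma = gamma,
    Lambda0 = breslow_baseline(ds, gamma),
    converged = TRUE,
    iterations = fit$iter[1],
    frailty = frailty,
    frailty_variance = if (frailty == "gamma")
      fit$history[["survival::frailty(id)"]]$theta else NULL),
    class = "intensity_fit")
}

# counting-process (start, stop, event] representation of the visit process
counting_process_frame <- function(ds) {
  vi <- visit_subject_index(ds)  # visits sorted by subject then time
  tv <- ds$visits$time
  n <- nrow(ds$subjects)
  first <- !duplicated(vi)
  tstart_v <- c(0, tv[-length(tv)])
  tstart_v[first] <- 0
  # time of last visit per subject (0 if none)
  last_time <- numeric(n)
  if (length(vi)) {
    idx_last <- which(!duplicated(vi, fromLast = TRUE))
    last_time[vi[idx_last]] <- tv[idx_last]
  }
  trail <- which(last_time < ds$subjects$C)
  cp <- data.frame(
    idx = c(vi, trail),
    tstart = c(tstart_v, last_time[trail]),
    tstop = c(tv, ds$subjects$C[trail]),
    event = rep(c(1L, 0L), c(length(vi), length(trail))))
  cp$id <- ds$subjects$id[cp$idx]
  for (nm in ds$covariate_names)
    cp[[nm]] <- ds$subjects[[nm]][cp$idx]
  cp
}

#' Breslow estimator of the cumulative baseline visit intensity
#'
#' Computes \eqn{\hat\Lambda_0(t) = \sum_{u \le t} d(u) / \sum_j
#' \Delta_j(u)\exp(X_j'\gamma)} where \eqn{d(u)} is the number of visits at
#' time \eqn{u} and \eqn{\Delta_j(u) = I(C_j \ge u)}. The risk-set
#' denominator uses unit frailty weight; the frailty-moment estimators are
#' defined with respect to this baseline.
#'
#' @param ds a [longdata] object
#' @param gamma coefficient vector of the intensity model (finite)
#' @return a [cum_stepfun] jumping only at observed visit times
#' @export
breslow_baseline <- function(ds, gamma) {
  if (any(!is.finite(gamma))) stop("gamma must be finite")
  if (nrow(ds$visits) == 0) return(cum_stepfun(numeric(0), numeric(0)))
  X <- covariate_matrix(ds)
  expXg <- as.vector(exp(X %*% gamma))
  tab <- table(ds$visits$time)
  u <- as.numeric(names(tab))
  d <- as.numeric(tab)
  denom <- as.vector(risk_sum(ds$subjects$C, expXg, u))
  if (any(denom <= 0)) stop("empty risk set at an event time")
  cum_stepfun(u, cumsum(d / denom))
}

#' Method-of-moments frailty estimates
#'
#' Given the visit counts \eqn{m_i} and the fitted intensity model, the
#' conditional Poisson moments of \eqn{m_i} yield plug-in estimates of the
#' subject frailty and its square:
#' \deqn{\hat\omega_i = m_i / \{\hat\Lambda_0(C_i) e^{X_i'\hat\gamma}\},
#'  \qquad
#'  \hat\Omega_i = m_i(m_i-1) / \{\hat\Lambda_0(C_i)^2 e^{2X_i'\hat\gamma}\}.}
#' \eqn{\hat\Omega_i} is zero whenever \eqn{m_i \le 1} and both are zero for
#' subjects with no visits.
#'
#' @param ds a [longdata] object
#' @param fit an `intensity_fit` from [fit_visit_model], or a list with
#'   elements `gamma` and `Lambda0`
#' @return data.frame with columns `id`, `m`, `omega_hat`, `Omega_hat`
#' @export
frailty_moments <- function(ds, fit) {
  X <- covariate_matrix(ds)
  expXg <- as.vector(exp(X %*% fit$gamma))
  L <- eval_stepfun(fit$Lambda0, ds$subjects$C)
  m <- ds$subjects$m
  if (any(L == 0 & m >= 1))
    stop("Lambda0(C_i) = 0 for a subject with visits: inconsistent fit/data")
  denom <- L * expXg
  omega <- ifelse(m == 0, 0, m / denom)
  Omega <- ifelse(m <= 1, 0, m * (m - 1) / denom^2)
  data.frame(id = ds$subjects$id, m = m, omega_hat = omega, Omega_hat = Omega)
}

#' Write an intensity fit to a JSON checkpoint file
#' @param fit an `intensity_fit`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_intensity_fit <- function(fit, path) {
  jsonlite::write_json(
    list(gamma = as.list(fit$gamma),
         Lambda0 = list(times = fit$Lambda0$times, values = fit$Lambda0$values),
         converged = fit$converged, iterations = fit$iterations,
         frailty = fit$frailty),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an intensity fit from a JSON checkpoint file
#' @param path file written by [write_intensity_fit]
#' @return an `intensity_fit`
#' @export
read_intensity_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    gamma = unlist(obj$gamma),
    Lambda0 = cum_stepfun(obj$Lambda0$times, obj$Lambda0$values),
    converged = obj$converged, iterations = obj$iterations,
    frailty = obj$frailty, frailty_variance = NULL),
    class = "intensity_fit")
}

#' @export
print.intensity_fit <- function(x, ...) {
  cat("Visit-intensity fit (Andersen-Gill",
      if (x$frailty == "gamma") "with gamma frailty" else "", ")\n")
  print(x$gamma)
  cat("Breslow Lambda0:", length(x$Lambda0$times), "jumps, Lambda0(max) =",
      format(max(c(0, x$Lambda0$values))), "\n")
  invisible(x)
}
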