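# resample subjects with replacement, keeping each drawn subject's visits;
# drawn subjects get fresh ids so duplicates stay distinct
resample_longdata <- function(ds, idx) {
  subj <- ds$subjects[idx, , drop = FALSE]
  new_id <- sprintf("b%06d", seq_along(idx))
  rows <- split(seq_len(nrow(ds$visits)),
                factor(ds$visits$id, levels = ds$subjects$id))[idx]
  visits <- ds$visits[unlist(rows, use.names = FALSE), , drop = FALSE]
  visits$id <- rep(new_id, lengths(rows))
  subj$id <- new_id
  longdata(subj[, c("id", "C", ds$covariate_names)], visits,
           tau = ds$tau, covariate_names = ds$covariate_names)
}

# one full pipeline fit; returns named coefficient vector for the covariates
# (and, for the extended estimator, optionally a trajectory)
pipeline_fit <- function(ds, estimator, degree, n_interior_knots, frailty,
                         trajectory_times = NULL, X_profile = NULL) {
  basis <- spline_basis(ds$visits$time, degree = degree,
                        n_interior_knots = n_interior_knots,
                        boundary = c(0, ds$tau))
  if (estimator == "gee") {
    f <- fit_gee_spline(ds, basis)
    traj <- if (!is.null(trajectory_times)) {
      th <- f$coefficients
      exp(as.vector(eval_basis(basis, trajectory_times) %*%
                      th[seq_len(basis$K)]) +
            sum((if (is.null(X_profile)) numeric(length(f$beta)) else
              X_profile) * f$beta))
    }
    return(list(coef = f$beta, fit = f, trajectory = traj))
  }
  vf <- fit_visit_model(ds, frailty = frailty)
  mom <- frailty_moments(ds, vf)
  if (estimator == "sun") {
    f <- fit_sun(ds, vf, mom)
    return(list(coef = f$beta, fit = f, trajectory = NULL))
  }
  f <- fit_sun_extended(ds, vf, mom, basis)
  traj <- if (!is.null(trajectory_times))
    predict_trajectory(f, trajectory_times, X_profile)
  list(coef = f$beta, fit = f, trajectory = traj)
}

#' Nonparametric subject-level bootstrap for joint-model fits
#'
#' Resamples subjects with replacement (keeping all of a subject's visits
#' together), refits the entire pipeline on each resample — visit-intensity
#' model, Breslow baseline, frailty moments, spline basis (knots recomputed
#' from the resample's pooled visit times), and the requested estimator — and
#' summarizes the covariate coefficients by their bootstrap standard
#' deviation and percentile 95% confidence intervals, on both the coefficient
#' and the mean-outcome-ratio (exponentiated) scale. Optionally returns a
#' pointwise percentile confidence band for the mean outcome trajectory at a
#' reference covariate profile (extended estimator and GEE only).
#'
#' Resamples on which the estimator fails are dropped; an error is raised if
#' more than 10% fail.
#'
#' @param ds a [longdata] object
#' @param estimator `"extended"`, `"sun"` or `"gee"`
#' @param B number of resamples (case-study default 600)
#' @param seed master seed; per-resample seeds are derived from it, so the
#'   result is reproducible
#' @param degree,n_interior_knots spline configuration (ignored by `"sun"`)
#' @param frailty passed to [fit_visit_model]
#' @param trajectory_times optional grid for a trajectory band
#' @param X_profile covariate profile for the trajectory (default zero)
#' @return object of class `bootstrap_result`: `table` (parameter, estimate,
#'   SE, CI, ratio, ratio CI), `B`, `n_failed`, `seed`, `draws` (matrix of
#'   resampled coefficients), optional `trajectory_band`
#' @export
bootstrap_fit <- function(ds, estimator = c("extended", "sun", "gee"),
                          B = 600, seed = 1, degree = 3,
                          n_interior_knots = 4, frailty = c("none", "gamma"),
                          trajectory_times = NULL, X_profile = NULL) {
  estimator <- match.arg(estimator)
  frailty <- match.arg(frailty)
  stopifnot(B >= 2)
  point <- pipeline_fit(ds, estimator, degree, n_interior_knots, frailty,
                        trajectory_times, X_profile)
  n <- nrow(ds$subjects)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, B)
  draws <- matrix(NA_real_, B, length(point$coef),
                  dimnames = list(NULL, names(point$coef)))
  traj_draws <- if (!is.null(trajectory_times))
    matrix(NA_real_, B, length(trajectory_times))
  n_failed <- 0L
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch(
      pipeline_fit(resample_longdata(ds, idx), estimator, degree,
                   n_interior_knots, frailty, trajectory_times, X_profile),
      error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    draws[b, ] <- res$coef
    if (!is.null(traj_draws)) traj_draws[b, ] <- res$trajectory
  }
  if (n_failed > 0.10 * B)
    stop("more than 10% of bootstrap resamples failed (", n_failed, " of ",
         B, ")")
  ok <- stats::complete.cases(draws)
  se <- apply(draws[ok, , drop = FALSE], 2, stats::sd)
  ci <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975))
  tab <- data.frame(parameter = names(point$coef),
                    estimate = as.numeric(point$coef),
                    se = as.numeric(se),
                    ci_low = ci[1, ], ci_high = ci[2, ],
                    ratio = exp(as.numeric(point$coef)),
                    ratio_low = exp(ci[1, ]), ratio_high = exp(ci[2, ]))
  rownames(tab) <- NULL
  band <- if (!is.null(traj_draws)) {
    q <- apply(traj_draws[ok, , drop = FALSE], 2, stats::quantile,
               probs = c(0.025, 0.975))
    data.frame(t = trajectory_times, estimate = point$trajectory,
               lower = q[1, ], upper = q[2, ])
  }
  structure(list(table = tab, B = B, n_failed = n_failed, seed = seed,
                 estimator = estimator, draws = draws,
                 trajectory_band = band), class = "bootstrap_result")
}

#' Write a bootstrap result table as delimited text
#' @param res a `bootstrap_result`
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_bootstrap_result <- function(res, path) {
  utils::write.csv(res$table, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Bootstrap (", x$estimator, "), B = ", x$B, ", failed = ", x$n_failed,
      "\n", sep = "")
  print(x$table, digits = 3)
  invisible(x)
}
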