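#' Intercept functions available to the simulation generator
#'
#' Registry of log-scale intercept functions \eqn{m_0(t)} (so the
#' multiplicative intercept is \eqn{\mu_0(t) = e^{m_0(t)}}):
#' * `"loglinear"`: \eqn{\log(1+t) + 2(t+1)}
#' * `"sinelinear"`: \eqn{\sin(t) + 2(t+1)}
#' * `"sinusoidal"`: \eqn{\sin(4t)} (rapidly fluctuating, bounded)
#'
#' The first two grow linearly in \eqn{t} on the log scale, so late-time
#' outcomes are orders of magnitude larger than early ones; this is what
#' separates the estimators' efficiency (see the methods vignette). A
#' user-supplied function of time may be passed wherever a registry name is
#' accepted.
#'
#' @param form registry name or a function of time
#' @return a function of time
#' @export
mu0_log_intercept <- function(form) {
  if (is.function(form)) return(form)
  switch(form,
    loglinear = function(t) log(1 + t) + 2 * (t + 1),
    sinelinear = function(t) sin(t) + 2 * (t + 1),
    sinusoidal = function(t) sin(4 * t),
    stop("unknown intercept form '", form,
         "'; use loglinear, sinelinear, sinusoidal, or a function"))
}

#' Simulation scenario specification
#'
#' Bundles the parameters of the frailty-coupled visit/outcome generator:
#' subjects carry a covariate \eqn{X} (Bernoulli(1/2) or Normal(0, 0.25)), a
#' covariate-dependent frailty \eqn{\nu} with \eqn{E(\nu \mid X) = 1}, a
#' censoring time \eqn{C \sim U(1, 1.1\tau)} truncated administratively at
#' \eqn{\tau}, visit times from a homogeneous Poisson process with rate
#' \eqn{\nu e^{0.5 X}} on \eqn{(0, C]}, and at each visit a log-normal
#' multiplicative outcome \eqn{\log Y = \log\nu + m_0(t) + X\beta_0 +
#' \varepsilon}, \eqn{\varepsilon \sim N(-0.0625, 0.1225)}.
#'
#' @param n number of subjects
#' @param beta0 true relative effect (default 1)
#' @param mu0 intercept form, see [mu0_log_intercept] (default `"loglinear"`)
#' @param tau maximum follow-up time, must exceed 1 (default 5)
#' @param covariate `"bernoulli"` (Ber(1/2)) or `"normal"` (N(0, 0.25))
#' @param n_reps replicates for [run_scenario] (default 505)
#' @param seed master seed (default 1)
#' @return object of class `scenario_spec`
#' @export
scenario_spec <- function(n, beta0 = 1, mu0 = "loglinear", tau = 5,
                          covariate = c("bernoulli", "normal"),
                          n_reps = 505, seed = 1) {
  covariate <- match.arg(covariate)
  stopifnot(n >= 2, tau > 1, n_reps >= 1)
  structure(list(n = as.integer(n), beta0 = beta0, mu0 = mu0, tau = tau,
                 covariate = covariate, n_reps = as.integer(n_reps),
                 seed = as.integer(seed)), class = "scenario_spec")
}

#' Draw covariate-dependent frailties
#'
#' The frailty mixture: with group indicator \eqn{g = x} for a binary
#' covariate or \eqn{g = I(x \ge 0)} for a continuous one,
#' \eqn{\nu = e^{-\log(2.75) g}\,\nu^*} with \eqn{\nu^* \sim U(0.5, 1.5)} when
#' \eqn{g = 0} and \eqn{\nu^* \sim U(1.5, 4)} when \eqn{g = 1}. Both branches
#' have conditional mean one.
#'
#' @param x covariate values (vectorized)
#' @param dist `"bernoulli"` or `"normal"` (determines the group indicator)
#' @return positive frailty draws, one per element of `x`
#' @export
draw_frailty <- function(x, dist = c("bernoulli", "normal")) {
  dist <- match.arg(dist)
  g <- if (dist == "bernoulli") x else as.numeric(x >= 0)
  nu_star <- ifelse(g == 1, stats::runif(length(x), 1.5, 4),
                    stats::runif(length(x), 0.5, 1.5))
  exp(-log(2.75) * g) * nu_star
}

#' Generate one dataset from a simulation scenario
#'
#' Draws, per subject in id order: covariate, frailty, censoring time, visit
#' gaps (exponential, giving a homogeneous Poisson visit process of rate
#' \eqn{\nu e^{0.5X}} on \eqn{(0, C]}), then the outcome errors — a fixed
#' draw order so results are reproducible from the seed.
#'
#' @param spec a [scenario_spec]
#' @param seed optional seed; defaults to `spec$seed`
#' @return a [longdata] object with covariate column `x` and attribute
#'   `"truth"` (data.frame of per-subject `nu`)
#' @export
generate_dataset <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed) else set.seed(spec$seed)
  m0 <- mu0_log_intercept(spec$mu0)
  n <- spec$n
  id <- sprintf("s%05d", seq_len(n))
  x <- numeric(n); nu <- numeric(n); C <- numeric(n)
  vis_id <- vector("list", n); vis_t <- vector("list", n)
  vis_y <- vector("list", n)
  for (i in seq_len(n)) {
    x[i] <- if (spec$covariate == "bernoulli") stats::rbinom(1, 1, 0.5)
      else stats::rnorm(1, 0, sqrt(0.25))
    nu[i] <- draw_frailty(x[i], spec$covariate)
    C[i] <- min(stats::runif(1, 1, 1.1 * spec$tau), spec$tau)
    rate <- nu[i] * exp(0.5 * x[i])
    t <- 0; times <- numeric(0)
    repeat {
      t <- t + stats::rexp(1, rate)
      if (t > C[i]) break
      times <- c(times, t)
    }
    if (length(times)) {
      eps <- stats::rnorm(length(times), -0.0625, sqrt(0.1225))
      vis_id[[i]] <- rep(id[i], length(times))
      vis_t[[i]] <- times
      vis_y[[i]] <- exp(log(nu[i]) + m0(times) + x[i] * spec$beta0 + eps)
    }
  }
  subjects <- data.frame(id = id, C = C, x = x)
  visits <- data.frame(id = unlist(vis_id),
                       time = unlist(vis_t), y = unlist(vis_y))
  if (nrow(visits) == 0) visits <- data.frame(id = character(0),
                                              time = numeric(0),
                                              y = numeric(0))
  ds <- longdata(subjects, visits, tau = spec$tau)
  attr(ds, "truth") <- data.frame(id = id, nu = nu)
  ds
}

#' Run a simulation scenario across replicates
#'
#' Generates `spec$n_reps` datasets, fits the requested estimators to each
#' (visit-intensity model without frailty, Breslow baseline, frailty moments,
#' then the estimator; the spline basis is rebuilt per dataset from its own
#' pooled visit times), and summarizes the relative-effect estimates by their
#' empirical bias and standard error (ESE). Replicates where an estimator
#' fails are excluded from that estimator's summary; a warning is attached if
#' more than 5% fail.
#'
#' @param spec a [scenario_spec]
#' @param estimators subset of `c("extended", "sun", "gee")`
#' @param degree,n_interior_knots spline configuration (default cubic with 4
#'   quantile interior knots)
#' @param progress print a dot every 50 replicates
#' @return object of class `scenario_summary`: `summary` data.frame
#'   (estimator, bias, ese, n_completed), `estimates` matrix (reps x
#'   estimators), `spec`
#' @export
run_scenario <- function(spec, estimators = c("extended", "sun", "gee"),
                         degree = 3, n_interior_knots = 4, progress = FALSE) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  set.seed(spec$seed)
  rep_seeds <- sample.int(.Machine$integer.max, spec$n_reps)
  est <- matrix(NA_real_, spec$n_reps, length(estimators),
                dimnames = list(NULL, estimators))
  for (r in seq_len(spec$n_reps)) {
    ds <- generate_dataset(spec, seed = rep_seeds[r])
    res <- tryCatch({
      basis <- spline_basis(ds$visits$time, degree = degree,
                            n_interior_knots = n_interior_knots,
                            boundary = c(0, spec$tau))
      vf <- NULL; mom <- NULL
      if (any(estimators %in% c("extended", "sun"))) {
        vf <- fit_visit_model(ds, frailty = "none")
        mom <- frailty_moments(ds, vf)
      }
      out <- rep(NA_real_, length(estimators))
      names(out) <- estimators
      for (e in estimators) {
        out[e] <- tryCatch(switch(e,
          extended = fit_sun_extended(ds, vf, mom, basis)$beta[["x"]],
          sun = fit_sun(ds, vf, mom)$beta[["x"]],
          gee = fit_gee_spline(ds, basis)$beta[["x"]]),
          error = function(err) NA_real_)
      }
      out
    }, error = function(err) rep(NA_real_, length(estimators)))
    est[r, ] <- res
    if (progress && r %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  summ <- data.frame(
    estimator = estimators,
    bias = apply(est, 2, function(z) mean(z, na.rm = TRUE)) - spec$beta0,
    ese = apply(est, 2, function(z) if (sum(!is.na(z)) > 1)
      stats::sd(z, na.rm = TRUE) else NA_real_),
    n_completed = apply(est, 2, function(z) sum(!is.na(z))))
  rownames(summ) <- NULL
  warn <- summ$estimator[summ$n_completed < 0.95 * spec$n_reps]
  structure(list(summary = summ, estimates = est, spec = spec,
                 warning_estimators = warn), class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  s <- x$spec
  cat("Scenario: n =", s$n, ", beta0 =", s$beta0, ", mu0 =",
      if (is.function(s$mu0)) "<function>" else s$mu0,
      ", tau =", s$tau, ",", s$covariate, "covariate,", s$n_reps, "reps\n")
  print(x$summary, digits = 3)
  if (length(x$warning_estimators))
    cat("warning: >5% failed replicates for:",
        paste(x$warning_estimators, collapse = ", "), "\n")
  invisible(x)
}

#' Read a scenario specification from a key-value text file
#'
#' Keys mirror the arguments of [scenario_spec] (one `key: value` per line).
#' @param path config file
#' @return a [scenario_spec]
#' @export
read_scenario_spec <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, ":")
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(z) paste(z[-1], collapse = ":"), ""))
  args <- stats::setNames(as.list(vals), keys)
  for (nm in intersect(names(args), c("n", "beta0", "tau", "n_reps", "seed")))
    args[[nm]] <- as.numeric(args[[nm]])
  do.call(scenario_spec, args)
}
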