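ext_setup <- local({
  ds <- six_longdata()
  fit <- fit_visit_model(ds)
  mom <- frailty_moments(ds, fit)
  basis <- spline_basis(ds$visits$time, degree = 2, n_interior_knots = 1,
                        boundary = c(0, ds$tau))
  list(ds = ds, fit = fit, mom = mom, basis = basis)
})

test_that("estimating function is zero on a dataset with no visits", {
  subj <- data.frame(id = c("a", "b"), C = c(2, 3), x = c(0, 1))
  ds0 <- longdata(subj, data.frame(id = character(0), time = numeric(0),
                                   y = numeric(0)), tau = 4)
  mom0 <- data.frame(id = c("a", "b"), m = c(0, 0),
                     omega_hat = c(0, 0), Omega_hat = c(0, 0))
  fit0 <- list(gamma = 0, Lambda0 = cum_stepfun(numeric(0), numeric(0)))
  basis <- spline_basis(c(0.5, 1, 1.5, 2.5), degree = 2,
                        n_interior_knots = 0, boundary = c(0, 4))
  L <- extended_ee(rep(0, 1 + basis$K), ds0, fit0, mom0, basis)
  expect_equal(L, rep(0, 1 + basis$K))
})

test_that("estimating function matches the brute-force triple loop", {
  s <- ext_setup
  p <- 1; K <- s$basis$K
  for (eta in list(rep(0, p + K),
                   seq(-0.3, 0.3, length.out = p + K))) {
    fast <- extended_ee(eta, s$ds, s$fit, s$mom, s$basis)
    slow <- brute_L(eta, s$ds, s$fit, s$mom, s$basis)
    expect_equal(as.vector(fast), as.vector(slow), tolerance = 1e-12)
  }
})

test_that("the eta-free offset cancels in differences of L", {
  s <- ext_setup
  eta1 <- rep(0.1, 1 + s$basis$K)
  eta2 <- rep(-0.2, 1 + s$basis$K)
  v <- s$ds$visits
  Z <- sunjoint:::visit_design(s$ds, s$basis)
  first <- function(e) drop(crossprod(Z, v$y * exp(-as.vector(Z %*% e))))
  dL <- extended_ee(eta1, s$ds, s$fit, s$mom, s$basis) -
    extended_ee(eta2, s$ds, s$fit, s$mom, s$basis)
  expect_equal(as.vector(dL), as.vector(first(eta1) - first(eta2)),
               tolerance = 1e-10)
})

test_that("solver satisfies its own equation and 1-D subproblems match bisection", {
  s <- ext_setup
  ext <- fit_sun_extended(s$ds, s$fit, s$mom, s$basis)
  expect_true(ext$converged)
  expect_lt(max(abs(extended_ee(ext$eta, s$ds, s$fit, s$mom, s$basis))), 1e-7)

  # hold all but the covariate coordinate at the solution, bisect that one
  k <- 1
  g <- function(b) {
    e <- ext$eta; e[k] <- b
    extended_ee(e, s$ds, s$fit, s$mom, s$basis)[k]
  }
  root <- stats::uniroot(g, c(ext$eta[k] - 2, ext$eta[k] + 2),
                         tol = 1e-12)$root
  expect_lt(abs(ext$eta[k] - root), 1e-8)
})

test_that("intercept-only model has the closed-form solution", {
  # no covariates, constant basis: alpha = log(sum y / sum S)
  subj <- data.frame(id = paste0("s", 1:4), C = c(2, 3, 3, 4))
  vis <- data.frame(id = c("s1", "s2", "s2", "s3", "s4", "s4"),
                    time = c(1, 1.5, 2.5, 2, 1.2, 3.5),
                    y = c(2, 1, 3, 2, 4, 1))
  ds <- longdata(subj, vis, tau = 5, covariate_names = character(0))
  Lb <- breslow_baseline(ds, numeric(0))
  fit <- list(gamma = numeric(0), Lambda0 = Lb)
  mom <- frailty_moments(ds, fit)
  basis <- spline_basis(vis$time, degree = 0, n_interior_knots = 0,
                        boundary = c(0, 5))
  ext <- fit_sun_extended(ds, fit, mom, basis)
  S <- sunjoint:::extended_offsets(ds, fit, mom, basis, ds$visits$time)
  closed <- log(sum(ds$visits$y) / sum(S[, 1]))
  expect_equal(unname(ext$alpha[1]), closed, tolerance = 1e-10)
})

test_that("Jacobian of L is symmetric negative semidefinite (finite differences)", {
  s <- ext_setup
  q <- 1 + s$basis$K
  for (eta0 in list(rep(0, q), seq(0.2, -0.2, length.out = q))) {
    J <- matrix(0, q, q)
    h <- 1e-6
    for (k in seq_len(q)) {
      e <- numeric(q); e[k] <- h
      J[, k] <- (extended_ee(eta0 + e, s$ds, s$fit, s$mom, s$basis) -
                 extended_ee(eta0 - e, s$ds, s$fit, s$mom, s$basis)) / (2 * h)
    }
    expect_lt(max(abs(J - t(J))), 1e-4 * max(abs(J)))
    ev <- eigen((J + t(J)) / 2, only.values = TRUE)$values
    expect_lt(max(ev), 1e-6 * max(abs(ev)))
  }
})

test_that("covariate location shifts move only the intercept block", {
  s <- ext_setup
  e1 <- fit_sun_extended(s$ds, s$fit, s$mom, s$basis)
  subj2 <- s$ds$subjects[, c("id", "C", "x")]
  subj2$x <- subj2$x + 2
  ds2 <- longdata(subj2, s$ds$visits, tau = s$ds$tau)
  fit2 <- fit_visit_model(ds2)
  mom2 <- frailty_moments(ds2, fit2)
  e2 <- fit_sun_extended(ds2, fit2, mom2, s$basis)
  expect_equal(e2$beta[["x"]], e1$beta[["x"]], tolerance = 1e-6)
  # trajectory at the shifted covariate value is unchanged
  tt <- seq(0.5, 4.5, length.out = 7)
  expect_equal(predict_trajectory(e2, tt, X = 1 + 2),
               predict_trajectory(e1, tt, X = 1), tolerance = 1e-5)
})

test_that("trajectory predictions: identity and multiplicativity", {
  s <- ext_setup
  ext <- fit_sun_extended(s$ds, s$fit, s$mom, s$basis)
  tt <- seq(0, 5, length.out = 9)
  # alpha = 0, X = 0 -> trajectory 1
  flat <- ext
  flat$alpha[] <- 0
  flat$eta[] <- 0
  expect_equal(predict_trajectory(flat, tt), rep(1, 9))
  # ratio of trajectories equals exp(x beta) at every t
  r <- predict_trajectory(ext, tt, X = 0.8) / predict_trajectory(ext, tt)
  expect_equal(r, rep(exp(0.8 * ext$beta[["x"]]), 9), tolerance = 1e-12)
  expect_error(predict_trajectory(ext, 7), "boundary")
})

test_that("log-trajectory error shrinks with sample size", {
  # integrated squared error of the fitted log-intercept against the true
  # log-linear intercept, averaged over replicates, decreases in n
  ns <- c(100, 200, 500)
  m0 <- mu0_log_intercept("loglinear")
  grid <- seq(0.25, 4.75, length.out = 60)
  mise <- sapply(seq_along(ns), function(j) {
    spec <- scenario_spec(n = ns[j], seed = 700 + j)
    set.seed(spec$seed)
    seeds <- sample.int(.Machine$integer.max, 100)
    ise <- vapply(seeds, function(sd) {
      ds <- generate_dataset(spec, seed = sd)
      vf <- fit_visit_model(ds)
      mom <- frailty_moments(ds, vf)
      basis <- spline_basis(ds$visits$time, boundary = c(0, 5))
      ext <- fit_sun_extended(ds, vf, mom, basis)
      mean((log(predict_trajectory(ext, grid)) - m0(grid))^2)
    }, numeric(1))
    mean(ise)
  })
  expect_true(all(diff(mise) < 0))
})

test_that("fit export re-evaluates trajectories exactly", {
  s <- ext_setup
  ext <- fit_sun_extended(s$ds, s$fit, s$mom, s$basis)
  path <- tempfile()
  write_extended_fit(ext, path)
  lines <- readLines(path)
  coefs <- utils::read.delim(text = lines[2:(1 + length(ext$eta))],
                             header = FALSE)
  expect_equal(coefs$V2, unname(ext$eta))
})
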