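diag_setup <- local({
  ds <- six_longdata()
  fit <- fit_visit_model(ds)
  mom <- frailty_moments(ds, fit)
  basis <- spline_basis(ds$visits$time, degree = 2, n_interior_knots = 1,
                        boundary = c(0, ds$tau))
  ext <- fit_sun_extended(ds, fit, mom, basis)
  list(ds = ds, fit = fit, mom = mom, ext = ext)
})

test_that("residual process trivial values", {
  s <- diag_setup
  # subject with m = 0 has Omega = 0 and no visits: R_i identically 0
  subj <- rbind(s$ds$subjects[, c("id", "C", "x")],
                data.frame(id = "empty", C = 4, x = 1))
  ds2 <- longdata(subj, s$ds$visits, tau = s$ds$tau)
  fit2 <- fit_visit_model(ds2)
  mom2 <- frailty_moments(ds2, fit2)
  ext2 <- fit_sun_extended(ds2, fit2, mom2, s$ext$basis)
  tt <- c(0, 1, 2.5, 5)
  expect_equal(residual_process(ds2, "empty", ext2, fit2, mom2, tt),
               rep(0, 4))
  # any subject at t = 0
  expect_equal(residual_process(ds2, "s3", ext2, fit2, mom2, 0), 0)
  expect_error(residual_process(ds2, "s3", ext2, fit2, mom2, -1), "tau")
})

test_that("residual process matches hand arithmetic on a 2-visit subject", {
  # hand-set eta, gamma, Lambda0 on a tiny dataset
  subj <- data.frame(id = c("a", "b"), C = c(3, 4), x = c(1, 0))
  vis <- data.frame(id = c("a", "a", "b"), time = c(1, 2, 1.5),
                    y = c(2, 3, 1))
  ds <- longdata(subj, vis, tau = 5)
  basis <- spline_basis(vis$time, degree = 0, n_interior_knots = 0,
                        boundary = c(0, 5))
  eta <- c(0.5, 0.2)  # (beta_x, alpha_const)
  gamma <- 0.3
  Lambda0 <- cum_stepfun(c(1, 1.5, 2), c(0.4, 0.7, 1.1))
  fit <- list(eta = eta, beta = eta[1], alpha = eta[2], basis = basis,
              gamma = gamma)
  intensity <- list(gamma = gamma, Lambda0 = Lambda0)
  mom <- data.frame(id = c("a", "b"), m = c(2, 1),
                    omega_hat = c(1.2, 0.8), Omega_hat = c(0.9, 0))
  # R_a(t) at t = 2.5: both visits counted, Lambda0(min(3, 2.5)) = 1.1
  hand <- 2 * exp(-(0.5 * 1 + 0.2) - 0.3 * 1) +
    3 * exp(-(0.5 * 1 + 0.2) - 0.3 * 1) - 0.9 * 1.1
  expect_equal(residual_process(ds, "a", fit, intensity, mom, 2.5), hand,
               tolerance = 1e-14)
  # at t = 1.2 only the first visit counts and Lambda0(1.2) = 0.4
  hand2 <- 2 * exp(-0.7 - 0.3) - 0.9 * 0.4
  expect_equal(residual_process(ds, "a", fit, intensity, mom, 1.2), hand2,
               tolerance = 1e-14)
})

test_that("residual curve equals the subject average and is grid-consistent", {
  s <- diag_setup
  grid <- seq(0, s$ds$tau, length.out = 23)
  curve <- residual_curve(s$ds, s$ext, s$fit, s$mom, grid)
  direct <- rowMeans(sapply(s$ds$subjects$id, function(id)
    residual_process(s$ds, id, s$ext, s$fit, s$mom, grid)))
  expect_equal(curve$values, direct, tolerance = 1e-12)
  # refining the grid never changes values at shared points
  grid2 <- sort(unique(c(grid, seq(0, s$ds$tau, length.out = 101))))
  curve2 <- residual_curve(s$ds, s$ext, s$fit, s$mom, grid2)
  expect_equal(curve2$values[match(grid, grid2)], curve$values,
               tolerance = 1e-12)
})

test_that("single-subject curve equals that subject's residual process", {
  subj <- data.frame(id = "a", C = 3, x = 0.5)
  vis <- data.frame(id = "a", time = c(1, 2), y = c(2, 1))
  ds <- longdata(subj, vis, tau = 4)
  basis <- spline_basis(vis$time, degree = 0, n_interior_knots = 0,
                        boundary = c(0, 4))
  fit <- list(eta = c(0.1, 0.3), beta = 0.1, alpha = 0.3, basis = basis,
              gamma = 0.2)
  intensity <- list(gamma = 0.2, Lambda0 = cum_stepfun(c(1, 2), c(0.5, 1)))
  mom <- data.frame(id = "a", m = 2, omega_hat = 1, Omega_hat = 1.4)
  grid <- seq(0, 4, length.out = 9)
  curve <- residual_curve(ds, fit, intensity, mom, grid)
  expect_equal(curve$values,
               residual_process(ds, "a", fit, intensity, mom, grid),
               tolerance = 1e-14)
  expect_error(residual_curve(ds, fit, intensity, mom, numeric(0)), "grid")
})

test_that("Res(t) shrinks with sample size under correct specification", {
  maxres <- sapply(c(200, 500, 2000), function(n) {
    spec <- scenario_spec(n = n, seed = 40 + n)
    set.seed(spec$seed)
    seeds <- sample.int(.Machine$integer.max, 6)
    mean(vapply(seeds, function(sd) {
      ds <- generate_dataset(spec, seed = sd)
      vf <- fit_visit_model(ds)
      mom <- frailty_moments(ds, vf)
      basis <- spline_basis(ds$visits$time, boundary = c(0, 5))
      ext <- fit_sun_extended(ds, vf, mom, basis)
      max(abs(residual_curve(ds, ext, vf, mom)$values))
    }, numeric(1)))
  })
  expect_true(all(diff(maxres) < 0))
})

test_that("a too-rigid intercept basis inflates the residual curve", {
  spec <- scenario_spec(n = 400, seed = 88, mu0 = "sinusoidal")
  ds <- generate_dataset(spec)
  vf <- fit_visit_model(ds)
  mom <- frailty_moments(ds, vf)
  flexible <- spline_basis(ds$visits$time, boundary = c(0, 5))
  rigid <- spline_basis(ds$visits$time, degree = 0, n_interior_knots = 0,
                        boundary = c(0, 5))
  m_flex <- max(abs(residual_curve(
    ds, fit_sun_extended(ds, vf, mom, flexible), vf, mom)$values))
  m_rigid <- max(abs(residual_curve(
    ds, fit_sun_extended(ds, vf, mom, rigid), vf, mom)$values))
  expect_gt(m_rigid, m_flex)
})

test_that("curve export writes the grid and values", {
  s <- diag_setup
  curve <- residual_curve(s$ds, s$ext, s$fit, s$mom)
  path <- tempfile(fileext = ".csv")
  write_residual_curve(curve, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 100)
  expect_equal(tab$Res, curve$values)
})
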