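# Small hand-built datasets and brute-force oracles used across test files.

# n-subject fixture with one covariate, deterministic visit layout
toy_longdata <- function() {
  subjects <- data.frame(id = c("s1", "s2", "s3"),
                         C = c(3, 3, 3),
                         x = c(0, 1, 2))
  visits <- data.frame(id = c("s1", "s1", "s2"),
                       time = c(1.0, 2.5, 2.0),
                       y = c(2.0, 1.5, 3.0))
  longdata(subjects, visits, tau = 4)
}

# richer fixture: 6 subjects, binary covariate, varied censoring
six_longdata <- function() {
  subjects <- data.frame(id = paste0("s", 1:6),
                         C = c(2.0, 3.0, 4.0, 4.0, 5.0, 5.0),
                         x = c(0, 1, 0, 1, 0, 1))
  visits <- data.frame(
    id = c("s1", "s2", "s2", "s3", "s3", "s3", "s4", "s5", "s5", "s6"),
    time = c(1.2, 0.8, 2.1, 1.0, 2.0, 3.5, 3.0, 1.5, 4.2, 2.2),
    y = c(1.1, 2.3, 0.7, 1.9, 2.4, 0.4, 3.1, 0.9, 1.3, 2.8))
  longdata(subjects, visits, tau = 6)
}

# brute-force U(beta): direct double loop over subjects and visits
brute_U <- function(beta, ds, moments, gamma) {
  X <- as.matrix(ds$subjects[, ds$covariate_names, drop = FALSE])
  n <- nrow(ds$subjects)
  p <- ncol(X)
  U <- numeric(p)
  for (i in seq_len(n)) {
    vi <- ds$visits[ds$visits$id == ds$subjects$id[i] & !is.na(ds$visits$y), ]
    if (nrow(vi) == 0) next
    for (r in seq_len(nrow(vi))) {
      t <- vi$time[r]
      num <- numeric(p); den <- 0
      for (j in seq_len(n)) {
        if (ds$subjects$C[j] >= t) {
          w <- moments$Omega_hat[j] * exp(sum(X[j, ] * (beta + gamma)))
          num <- num + w * X[j, ]
          den <- den + w
        }
      }
      U <- U + (X[i, ] - num / den) * vi$y[r]
    }
  }
  U / n
}

# brute-force L(eta): direct triple loop from the estimating-equation display
brute_L <- function(eta, ds, fit, moments, basis) {
  X <- as.matrix(ds$subjects[, ds$covariate_names, drop = FALSE])
  n <- nrow(ds$subjects)
  p <- ncol(X)
  K <- basis$K
  L <- numeric(p + K)
  for (i in seq_len(n)) {
    vi <- ds$visits[ds$visits$id == ds$subjects$id[i] & !is.na(ds$visits$y), ]
    if (nrow(vi) == 0) next
    for (r in seq_len(nrow(vi))) {
      t <- vi$time[r]
      Zi <- c(X[i, ], eval_basis(basis, t)[1, ])
      Snum <- numeric(p + K); Sden <- 0
      for (j in seq_len(n)) {
        if (ds$subjects$C[j] >= t) {
          eXg <- exp(sum(X[j, ] * fit$gamma))
          Zj <- c(X[j, ], eval_basis(basis, t)[1, ])
          Snum <- Snum + moments$Omega_hat[j] * eXg * Zj
          Sden <- Sden + moments$omega_hat[j] * eXg
        }
      }
      L <- L + Zi * vi$y[r] * exp(-sum(Zi * eta)) - Snum / Sden
    }
  }
  L
}

# hand-written Breslow-ties log partial likelihood for a single covariate,
# evaluated directly from the dataset (independent of the fitting code)
toy_log_partial_lik <- function(g, ds) {
  X <- ds$subjects[[ds$covariate_names[1]]]
  sapply(g, function(gg) {
    ll <- 0
    for (r in seq_len(nrow(ds$visits))) {
      t <- ds$visits$time[r]
      xi <- X[match(ds$visits$id[r], ds$subjects$id)]
      atrisk <- ds$subjects$C >= t
      ll <- ll + xi * gg - log(sum(exp(X[atrisk] * gg)))
    }
    ll
  })
}

# simulate a simple homogeneous-Poisson visit dataset with nu = 1, rate
# exp(0.5 x), constant outcome; used for baseline-recovery oracles
poisson_visits_longdata <- function(n, C = 5, x = NULL, rate0 = 1,
                                    seed = 1) {
  set.seed(seed)
  if (is.null(x)) x <- rep(0, n)
  id <- sprintf("p%05d", seq_len(n))
  vid <- vt <- vector("list", n)
  for (i in seq_len(n)) {
    rate <- rate0 * exp(0.5 * x[i])
    t <- 0; times <- numeric(0)
    repeat {
      t <- t + stats::rexp(1, rate)
      if (t > C) break
      times <- c(times, t)
    }
    vid[[i]] <- rep(id[i], length(times)); vt[[i]] <- times
  }
  visits <- data.frame(id = unlist(vid), time = unlist(vt),
                       y = rep(1, length(unlist(vt))))
  longdata(data.frame(id = id, C = rep(C, n), x = x), visits, tau = C + 1)
}
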