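test_that("PCA matches a brute-force eigendecomposition and decorrelates", {
  set.seed(51)
  Z <- matrix(rnorm(600 * 8), 600) %*% matrix(rnorm(64), 8)
  p <- fit_pca(Z)
  ev <- eigen(stats::cov(scale(Z, scale = FALSE)), symmetric = TRUE)
  expect_equal(p$eigenvalues, pmax(ev$values, 0), tolerance = 1e-10)
  scores <- estimate_states(p, Z)
  cv <- stats::cov(scores)
  expect_lt(max(abs(cv - diag(diag(cv)))), 1e-9)
  # exact rank-2 data: trailing eigenvalues vanish
  Z2 <- matrix(rnorm(400), 200, 2) %*% matrix(rnorm(12), 2, 6)
  p2 <- fit_pca(Z2)
  expect_lt(max(abs(p2$eigenvalues[3:6])), 1e-9)
})

test_that("FA EM recovers a planted factor subspace with monotone likelihood", {
  set.seed(52)
  m <- 20; q <- 3; n <- 5000
  L <- matrix(rnorm(m * q), m)
  Z <- matrix(rnorm(n * q), n) %*% t(L) + matrix(rnorm(n * m, sd = 0.5), n)
  fa <- fit_fa(Z, q)
  expect_true(all(diff(fa$loglik_trace) > -1e-6))
  expect_true(all(fa$uniquenesses > 0))
  principal_angles <- function(A, B) {
    qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
    acos(pmin(svd(crossprod(qa, qb))$d, 1)) * 180 / pi
  }
  expect_lt(max(principal_angles(L, fa$loadings)), 10)
  # independent cross-check: ML factor analysis from stats finds the same
  # subspace (up to rotation) on the correlation-scaled data
  fstats <- stats::factanal(Z, factors = q, rotation = "none")
  L_stats <- diag(apply(Z, 2, stats::sd)) %*% fstats$loadings
  expect_lt(max(principal_angles(L_stats, fa$loadings)), 10)
  expect_error(fit_fa(Z, 0), "at least 1")
})

test_that("LDS EM tracks a planted dynamical system", {
  A <- matrix(c(0.9, 0.1, -0.1, 0.9), 2)
  C <- matrix(rnorm(20, sd = 1), 10, 2)
  sim <- simulate_lds(2000, A, C, q_sd = 0.3, r_sd = 0.2, seed = 53)
  lds <- fit_lds(sim$Z, 2, max_iter = 30)
  expect_true(all(diff(lds$loglik_trace) > -1e-4))
  states <- estimate_states(lds, sim$Z)
  cc <- stats::cancor(states, sim$x)$cor
  expect_true(all(cc > 0.95))
  # one-step-ahead prediction error close to the generating noise floor
  # (process noise propagated through C plus observation noise)
  pred <- states[-nrow(states), ] %*% t(lds$A) %*% t(lds$C)
  obs <- sweep(sim$Z, 2, lds$mean, "-")[-1, ]
  noise_floor <- sqrt(mean(diag(C %*% (0.3^2 * diag(2)) %*% t(C))) + 0.2^2)
  one_step <- sqrt(mean((obs - pred)^2))
  expect_lt(one_step, 1.1 * noise_floor)
  # determinism
  lds2 <- fit_lds(sim$Z, 2, max_iter = 30)
  expect_identical(lds$A, lds2$A)
})

test_that("near-noiseless LDS observations give near-true filtered states", {
  A <- matrix(c(0.95, 0, 0, 0.9), 2)
  C <- rbind(diag(2), diag(2))
  sim <- simulate_lds(800, A, C, q_sd = 0.5, r_sd = 0.01, seed = 54)
  lds <- fit_lds(sim$Z, 2, max_iter = 40)
  states <- estimate_states(lds, sim$Z)
  # up to an invertible linear map: regress truth on states
  fit <- stats::lm.fit(cbind(1, states), sim$x)
  expect_lt(sqrt(mean(fit$residuals^2)) / stats::sd(sim$x), 0.05)
})

test_that("latent-state estimation is causal (filtered, not smoothed)", {
  set.seed(55)
  sim <- simulate_lds(400, matrix(c(0.9, 0, 0, 0.8), 2),
                      matrix(rnorm(12), 6, 2), 0.4, 0.3, seed = 56)
  lds <- fit_lds(sim$Z, 2, max_iter = 10)
  full <- estimate_states(lds, sim$Z)
  trunc <- estimate_states(lds, sim$Z[1:200, ])
  expect_equal(full[1:200, ], trunc, tolerance = 1e-12)
})

test_that("held-out reconstruction error selects the planted dimensionality", {
  set.seed(57)
  m <- 15; n <- 3000
  L <- matrix(rnorm(m * 5), m)
  Z <- matrix(rnorm(n * 5), n) %*% t(L) + matrix(rnorm(n * m, sd = 0.3), n)
  tr <- Z[1:2400, ]; te <- Z[2401:3000, ]
  sel <- select_dimensionality("pca", tr, te, candidates = c(2, 5, 8, 11))
  expect_identical(sel$q, 5L)
  # full-basis projection reconstruction is exact
  selp <- select_dimensionality("pca", tr, te, candidates = c(5, m),
                                error = "projection")
  expect_lt(selp$errors[["15"]], 1e-9)
  # single candidate is returned trivially
  sel1 <- select_dimensionality("pca", tr, te, candidates = 5)
  expect_identical(sel1$q, 5L)
  expect_error(select_dimensionality("pca", tr, te, candidates = integer(0)),
               "no candidate")
  # FA agrees on the same data
  self <- select_dimensionality("fa", tr, te, candidates = c(2, 5, 8),
                                max_iter = 40)
  expect_identical(self$q, 5L)
})

test_that("PCA training reconstruction error is non-increasing in q", {
  set.seed(58)
  Z <- matrix(rnorm(500 * 10), 500)
  p <- fit_pca(Z)
  errs <- vapply(1:10, function(q)
    mean(abs(reconstruct_rates(p, Z, q = q) - Z)), numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})
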