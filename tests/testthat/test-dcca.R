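test_that("correlation-objective gradient matches finite differences", {
  set.seed(71)
  N <- 30; k <- 3
  H1 <- matrix(rnorm(N * k), N)
  H2 <- matrix(rnorm(N * k), N) + 0.5 * H1
  g <- canokin:::cca_corr_grad(H1, H2, 0.01, 0.02)
  corr_at <- function(A, B)
    canokin:::cca_corr_grad(A, B, 0.01, 0.02, want_grad = FALSE)$corr
  eps <- 1e-6
  for (idx in sample(length(H1), 20)) {
    Hp <- H1; Hp[idx] <- Hp[idx] + eps
    Hm <- H1; Hm[idx] <- Hm[idx] - eps
    expect_equal(g$G1[idx], (corr_at(Hp, H2) - corr_at(Hm, H2)) / (2 * eps),
                 tolerance = 1e-5)
  }
  for (idx in sample(length(H2), 10)) {
    Hp <- H2; Hp[idx] <- Hp[idx] + eps
    Hm <- H2; Hm[idx] <- Hm[idx] - eps
    expect_equal(g$G2[idx], (corr_at(H1, Hp) - corr_at(H1, Hm)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("denoising-autoencoder pretraining reduces reconstruction loss", {
  set.seed(72)
  dat <- matrix(rnorm(800 * 10), 800) %*% matrix(rnorm(100), 10)
  pre <- pretrain_dae(dat, layer_sizes = c(12, 8), noise_frac = 0.2,
                      epochs = 4, seed = 3)
  expect_true(all(pre$recon_loss[, "final"] < pre$recon_loss[, "initial"]))
  expect_length(pre$W, 2L)
  # same seed, same weights
  pre2 <- pretrain_dae(dat, layer_sizes = c(12, 8), noise_frac = 0.2,
                       epochs = 4, seed = 3)
  expect_identical(pre$W, pre2$W)
  # noise_frac = 0 behaves as a plain autoencoder and still trains
  pre0 <- pretrain_dae(dat, layer_sizes = 6, noise_frac = 0, epochs = 1)
  expect_lt(pre0$recon_loss[1, "final"], pre0$recon_loss[1, "initial"])
})

test_that("hyperparameter schema accepts published values, rejects bad ones", {
  # the center-out dataset's published architecture
  th <- dcca_theta(nodes_z = 1024, layers_z = 2, rcov_z = 0.04,
                   nodes_x = 1024, layers_x = 3, rcov_x = 0.04,
                   batch = 256, batch_ae = 256, lr = 0.01, l2 = 6.8e-4,
                   lambda = 0.01, strict = TRUE)
  expect_s3_class(th, "canokin_dcca_theta")
  expect_error(dcca_theta(nodes_z = 8, strict = TRUE), "outside search range")
  expect_error(dcca_theta(rcov_z = -1), "non-negative")
  expect_error(dcca_theta(layers_z = 0), "out of range")
})

test_that("identity-activation deep CCA attains the linear CCA optimum", {
  set.seed(73)
  n <- 4000; m <- 8
  Z <- matrix(rnorm(n * m), n)
  X <- Z[, 1:3] %*% matrix(rnorm(9), 3) + matrix(rnorm(n * 3, sd = 0.7), n)
  lc <- fit_lcca(Z, X)
  th <- dcca_theta(nodes_z = 8, layers_z = 1, nodes_x = 8, layers_x = 1,
                   rcov_z = 1e-4, rcov_x = 1e-4, lambda = 0, l2 = 0,
                   lr = 5e-3, epochs = 60, activation = "identity")
  dc <- fit_dcca(Z, X, th, seed = 5)
  expect_equal(sum(dc$rho), sum(lc$rho), tolerance = 1e-3)
})

test_that("training objective improves and transforms are consistent", {
  set.seed(74)
  n <- 2000
  Z <- matrix(rnorm(n * 6), n)
  X <- tanh(Z %*% matrix(rnorm(18), 6)) + matrix(rnorm(n * 3, sd = 0.2), n)
  th <- dcca_theta(nodes_z = 16, layers_z = 2, nodes_x = 16, layers_x = 2,
                   rcov_z = 1e-3, rcov_x = 1e-3, lr = 2e-3, epochs = 10,
                   batch = 256, pretrain_epochs = 1)
  dc <- fit_dcca(Z, X, th, seed = 6)
  tr <- dc$objective_trace
  expect_gt(tr[length(tr)], tr[1])
  tf <- transform_dcca(dc, Z, X)
  expect_equal(canonical_correlations(tf$Z_cv, tf$X_cv), dc$rho,
               tolerance = 1e-6)
  # pointwise map: permuting rows permutes outputs identically
  perm <- sample(n)
  tfp <- transform_dcca(dc, Z[perm, ], X[perm, ])
  expect_equal(tfp$Z_cv, tf$Z_cv[perm, ], tolerance = 1e-12)
  # held-out correlations remain valid correlations
  expect_true(all(abs(canonical_correlations(tf$Z_cv, tf$X_cv)) <= 1 + 1e-9))
  # determinism under the same seed
  dc2 <- fit_dcca(Z, X, th, seed = 6)
  expect_identical(dc$rho, dc2$rho)
})

test_that("deep CCA beats linear CCA on a squashed-linear benchmark", {
  set.seed(75)
  n <- 20000; m <- 5
  Z <- matrix(rnorm(n * m), n)
  X <- tanh(Z %*% matrix(rnorm(m * 3), m)) + matrix(rnorm(n * 3, sd = 0.1), n)
  tr <- 1:16000; te <- 16001:20000
  lc <- fit_lcca(Z[tr, ], X[tr, ])
  lcc <- total_correlation(lc, Z[te, ], X[te, ])
  th <- dcca_theta(nodes_z = 32, layers_z = 2, nodes_x = 32, layers_x = 2,
                   rcov_z = 1e-3, rcov_x = 1e-3, lambda = 1e-3, l2 = 1e-5,
                   lr = 2e-3, batch = 256, epochs = 20, pretrain_epochs = 2)
  dc <- fit_dcca(Z[tr, ], X[tr, ], th, seed = 6)
  dcc <- total_correlation(dc, Z[te, ], X[te, ])
  expect_gte(dcc, lcc + 0.05)
  # and no harm in the linear regime (linear-Gaussian data)
  Xlin <- Z[tr, ] %*% matrix(rnorm(m * 3), m) +
    matrix(rnorm(length(tr) * 3, sd = 0.5), length(tr))
  lcl <- fit_lcca(Z[tr, ], Xlin)
  dcl <- fit_dcca(Z[tr, ], Xlin, th, seed = 7)
  expect_gte(sum(dcl$rho), sum(lcl$rho) - 0.02)
})

test_that("an identity network inverts back to the linear reconstruction", {
  set.seed(76)
  n <- 1500
  X <- cbind(rnorm(n), rnorm(n))
  X <- cbind(X, sqrt(rowSums(X^2)))
  Z <- X %*% matrix(rnorm(12), 3, 4) + matrix(rnorm(n * 4, sd = 0.05), n)
  th <- dcca_theta(nodes_z = 4, layers_z = 1, nodes_x = 3, layers_x = 1,
                   rcov_z = 1e-6, rcov_x = 1e-6, lambda = 0, l2 = 0,
                   lr = 5e-3, epochs = 50, activation = "identity")
  dc <- fit_dcca(Z, X, th, seed = 8)
  tf <- transform_dcca(dc, Z, X)
  vhat <- invert_cca_velocity(dc, tf$Z_cv, tf$X_cv, tf$Z_cv)
  expect_lt(sqrt(mean((vhat - X[, 1:2])^2)) / stats::sd(X[, 1:2]), 0.1)
})

test_that("random hyperparameter search is deterministic and bounded", {
  set.seed(77)
  n <- 1200
  Z <- matrix(rnorm(n * 4), n)
  X <- Z[, 1:3] + matrix(rnorm(n * 3, sd = 0.5), n)
  pin <- list(nodes_z = 16, layers_z = 1, nodes_x = 16, layers_x = 1,
              rcov_z = 1e-3, rcov_x = 1e-3, batch = 128, batch_ae = 64,
              lr = 1e-3, l2 = 1e-5, lambda = 1e-4)
  one <- search_hyperparams(Z, X, space = pin, budget = 1, seed = 2,
                            epochs = 5)
  expect_identical(one$theta$nodes_z, 16)
  expect_true(is.finite(one$score))
  two <- search_hyperparams(Z, X, space = pin, budget = 1, seed = 2,
                            epochs = 5)
  expect_identical(one$score, two$score)
  expect_error(search_hyperparams(Z, X, space = list(lr = numeric(0)),
                                  budget = 2), "empty search space")
  expect_error(search_hyperparams(Z, X, budget = 0), "at least 1")
})
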