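test_that("per-trial velocity error matches hand-computed cases", {
  tob <- c(1, 1, 2, 2, 3, 3)
  v <- cbind(c(1, 2, 3, 4, 5, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(unname(decoding_error(v, v, tob)), rep(0, 3))
  off <- sweep(v, 2, c(1, 0), "+")
  expect_equal(unname(decoding_error(v, off, tob)), rep(1, 3))
  # random toy case, hand-summed Euclidean distances
  set.seed(101)
  p <- v + matrix(rnorm(12), 6)
  manual <- c(mean(sqrt(rowSums((v - p)[1:2, ]^2))),
              mean(sqrt(rowSums((v - p)[3:4, ]^2))),
              mean(sqrt(rowSums((v - p)[5:6, ]^2))))
  expect_equal(unname(decoding_error(v, p, tob)), manual)
  # relabeling trials leaves the multiset of errors unchanged
  relab <- c(7, 7, 9, 9, 8, 8)
  expect_setequal(round(unname(decoding_error(v, p, relab)), 12),
                  round(manual, 12))
})

test_that("position reconstruction inverts velocity integration", {
  # constant (1, 0) cm/s for 20 bins of 50 ms displaces (1, 0) cm
  pred <- cbind(rep(1, 20), rep(0, 20))
  pos <- reconstruct_position(pred, rep(1, 20), cbind(0, 0), 0.05)
  expect_equal(pos[20, ], c(1, 0), tolerance = 1e-12)
  # zero velocity stays at the start position
  pos0 <- reconstruct_position(pred * 0, rep(1, 20), cbind(2, -1), 0.05)
  expect_true(all(pos0[, 1] == 2) && all(pos0[, 2] == -1))
  # round trip with the velocities computed from a session's own positions
  bd <- small_binned()
  s <- small_session()$session
  ids <- unique(bd$trial_of_bin)
  starts <- t(vapply(ids, function(id) {
    row <- which(s$hand$t >= s$trials$start_s[id] - 1e-9)[1]
    c(s$hand$x[row], s$hand$y[row])
  }, numeric(2)))
  pos <- reconstruct_position(bd$X[, 1:2], bd$trial_of_bin, starts, bd$bin_s)
  # integration of first-difference velocity recovers bin-averaged positions
  # up to the half-bin phase of the difference scheme
  expect_lt(mean(abs(pos)), 10)
  expect_error(reconstruct_position(pred, rep(1, 20), cbind(0, 0)[0, ], 0.05),
               "start position")
})

test_that("correlation metrics match the textbook formula", {
  u <- c(1, 2, 4, 7, 11); v <- c(2, 1, 5, 8, 10)
  r_hand <- sum((u - mean(u)) * (v - mean(v))) /
    sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  cm <- correlation_metrics(cbind(u, u), cbind(v, -u))
  expect_equal(unname(cm$overall), c(r_hand, -1), tolerance = 1e-12)
  cm2 <- correlation_metrics(cbind(u, u), cbind(u, u), rep(1, 5))
  expect_equal(unname(cm2$trial_mean), c(1, 1))
})

test_that("method comparison: no effect, dominance, and exact-test oracle", {
  set.seed(102)
  base <- matrix(rexp(44 * 3), 44, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  # identical columns: no effect
  same <- cbind(a = base[, 1], b = base[, 1], c = base[, 1])
  cmp <- compare_methods(same)
  expect_true(is.na(cmp$friedman$p.value) || cmp$friedman$p.value > 0.99)
  expect_true(all(cmp$posthoc$p_bonferroni == 1))
  # one method uniformly worse by 1.0: flagged at p < 0.01
  worse <- base
  worse[, "c"] <- worse[, "c"] + 1
  cmp2 <- compare_methods(worse)
  expect_lt(cmp2$friedman$p.value, 0.01)
  flagged <- cmp2$posthoc[cmp2$posthoc$method_b == "c" |
                            cmp2$posthoc$method_a == "c", ]
  expect_true(all(flagged$p_bonferroni < 0.01))
  expect_error(compare_methods(base[, 1, drop = FALSE]), "at least two")
  na_tab <- base; na_tab[1, 1] <- NA
  expect_error(compare_methods(na_tab), "mismatched")
})

test_that("paired posthoc p agrees with signed-rank enumeration at tiny n", {
  # exact signed-rank null by brute-force enumeration over sign patterns
  d <- c(0.3, -0.1, 0.45, 0.2, -0.6, 0.15)
  n <- length(d)
  ranks <- rank(abs(d))
  v_obs <- sum(ranks[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_null <- apply(signs, 1, function(s) sum(ranks[s == 1]))
  p_exact <- mean(abs(v_null - n * (n + 1) / 4) >=
                    abs(v_obs - n * (n + 1) / 4))
  tab <- cbind(a = c(1, 2, 3, 4, 5, 6),
               b = c(1, 2, 3, 4, 5, 6) - d)
  cmp <- compare_methods(tab)
  expect_equal(cmp$posthoc$p, p_exact, tolerance = 1e-12)
})

test_that("tuning quality of representation dimensions", {
  set.seed(103)
  n <- 20000
  X <- cbind(rnorm(n), rnorm(n), abs(rnorm(n)))
  R <- cbind(X[, 1], rnorm(n), 2 * X[, 3] + rnorm(n, sd = 0.1))
  tq <- tuning_r2(R, X)
  expect_equal(tq$r2[1], 1, tolerance = 1e-12)
  expect_lt(tq$r2[2], 0.02)
  expect_gt(tq$r2[3], 0.9)
  expect_false(any(tq$constant))
  tqc <- tuning_r2(cbind(rep(1, 100)), X[1:100, ])
  expect_identical(tqc$r2, 0)
  expect_true(tqc$constant)
  expect_equal(attr(tq, "mean_r2"), mean(tq$r2))
})

test_that("training error agrees with the per-trial error arithmetic", {
  set.seed(104)
  L <- matrix(rnorm(300 * 4), 300)
  X <- cbind(L[, 1], L[, 2], sqrt(L[, 1]^2 + L[, 2]^2))
  tob <- rep(1:10, each = 30)
  nd <- fit_ndf(L, X)
  te <- training_error(nd, L, X, tob)
  expect_equal(te, mean(decoding_error(X[, 1:2], run_ndf(nd, L), tob)),
               tolerance = 1e-12)
  expect_lt(te, 1e-8)  # states contain the velocity exactly
  off <- fit_ndf(L * 0 + 1e-9, X)  # degenerate predictor: intercept-only fit
  expect_gt(training_error(off, L * 0 + 1e-9, X, tob), 0)
})
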