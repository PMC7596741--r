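test_that("spike binning counts events in half-open 50-ms windows", {
  hand <- data.frame(t = seq(0, 0.1, by = 0.01), x = 0, y = 0)
  s <- new_session(list(c(0.01, 0.04, 0.06)), hand,
                   data.frame(start_s = 0, end_s = 0.1, label = "T1"),
                   duration_s = 0.1)
  b <- bin_spikes(s, 0.05)
  expect_equal(b$counts[, 1], c(2, 1))
  expect_equal(b$t, c(0.025, 0.075))
  expect_error(bin_spikes(s, 0.2), "longer than")
  expect_error(bin_spikes(s, 0), "positive")
  # conservation over a realistic session
  s2 <- small_session()$session
  b2 <- bin_spikes(s2, 0.05)
  in_range <- vapply(s2$units, function(st)
    sum(st < nrow(b2$counts) * 0.05), numeric(1))
  expect_equal(colSums(b2$counts), unname(in_range))
})

test_that("square-root transform is elementwise and rejects negatives", {
  expect_equal(sqrt_transform(c(0, 16)), c(0, 4))
  expect_error(sqrt_transform(-1), "non-negative")
  # variance stabilisation: sqrt reduces skewness of Poisson counts (for
  # counts large enough that the atom at zero does not dominate)
  set.seed(8)
  x <- rpois(20000, 9)
  sk <- function(v) mean((v - mean(v))^3) / stats::sd(v)^3
  expect_lt(abs(sk(sqrt(x))), abs(sk(x)))
})

test_that("Gaussian smoothing: identity at sd 0, mass-preserving, closed form", {
  M <- matrix(rnorm(200), 50)
  expect_identical(smooth_gaussian(M, 0, 0.05), M)
  cst <- matrix(3, 40, 2)
  expect_equal(smooth_gaussian(cst, 0.08, 0.05), cst, tolerance = 1e-12)
  # delta input reproduces the normalised discrete Gaussian
  n <- 41
  delta <- numeric(n); delta[21] <- 1
  out <- smooth_gaussian(delta, 0.08, 0.05)
  sd_bins <- 0.08 / 0.05
  half <- ceiling(4 * sd_bins)
  ker <- exp(-((-half):half)^2 / (2 * sd_bins^2))
  ker <- ker / sum(ker)
  expect_equal(out[(21 - half):(21 + half)], ker, tolerance = 1e-12)
  expect_error(smooth_gaussian(M, -1, 0.05), "non-negative")
})

test_that("kinematic differentiation recovers known velocities", {
  # linear motion x = 2t
  hand <- data.frame(t = seq(0, 2, by = 0.01))
  hand$x <- 2 * hand$t; hand$y <- 0
  t_bins <- seq(0.025, 1.975, by = 0.05)
  X <- compute_kinematics(hand, t_bins, 0.05)
  expect_equal(unname(X[, 1]), rep(2, length(t_bins)), tolerance = 1e-9)
  expect_equal(unname(X[, 3]), rep(2, length(t_bins)), tolerance = 1e-9)
  # stationary hand
  hand$x <- 1; hand$y <- -1
  X0 <- compute_kinematics(hand, t_bins, 0.05)
  expect_true(all(X0 == 0))
  # minimum-jerk reach: peak speed within 2% of 1.875 d / T
  kin <- generate_center_out_kinematics(4, reach_time_s = 0.6, radius_cm = 8,
                                        dt_s = 0.01, seed = 1)
  tb <- seq(0.025, max(kin$hand$t) - 0.05, by = 0.05)
  Xmj <- compute_kinematics(kin$hand, tb, 0.05)
  expect_equal(max(Xmj[, 3]), 1.875 * 8 / 0.6, tolerance = 0.02)
})

test_that("linear tuning fit: exact fit, null data, direction recovery", {
  set.seed(21)
  n <- 2000
  X <- cbind(vx = rnorm(n), vy = rnorm(n), speed = abs(rnorm(n)))
  z <- 1.5 + 2 * X[, 1] - X[, 2] + 0.5 * X[, 3]
  f <- fit_linear_tuning(z, X)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$beta1, c(2, -1), tolerance = 1e-9)
  # independent noise: r2 -> 0 at large n
  set.seed(22)
  Xn <- cbind(rnorm(20000), rnorm(20000), abs(rnorm(20000)))
  fn <- fit_linear_tuning(rnorm(20000), Xn)
  expect_lt(fn$r2, 0.02)
  # constant regressand
  fc <- fit_linear_tuning(rep(2, 100), X[1:100, ])
  expect_identical(fc$r2, 0)
  expect_error(fit_linear_tuning(1:5, X[1:5, ]), "at least 10")
})

test_that("preferred direction of a simulated 90-degree unit is recovered", {
  kin <- generate_sequential_kinematics(n_trials = 300, seed = 12)
  hand <- kin$hand
  dt <- 0.01
  vx <- c(diff(hand$x), 0) / dt; vy <- c(diff(hand$y), 0) / dt
  lam <- pmax(0, 12 + 1.0 * vy + 0.2 * sqrt(vx^2 + vy^2))  # phi = 90 deg
  set.seed(13)
  n_cand <- rpois(1, max(lam) * max(hand$t))
  tt <- sort(runif(n_cand, 0, max(hand$t)))
  keep <- runif(n_cand) < approx(hand$t, lam, xout = tt, rule = 2)$y / max(lam)
  s <- new_session(list(tt[keep]), hand, kin$trials)
  bd <- preprocess_session(s)
  f <- fit_linear_tuning(bd$Z[, 1], bd$X)
  expect_lt(abs(f$pref_direction_rad * 180 / pi - 90), 10)
})

test_that("unit selection keeps super-threshold units in order, monotone", {
  fits <- data.frame(r2 = c(0.005, 0.02, 0.5))
  expect_identical(select_units(fits, 0.01), c(2L, 3L))
  expect_identical(select_units(fits, 0), 1:3)
  expect_error(select_units(fits, 0.9), "no unit passed")
  expect_error(select_units(fits[0, , drop = FALSE]), "no tuning fits")
  set.seed(30)
  r2s <- data.frame(r2 = runif(40))
  thresholds <- sort(runif(6))
  kept <- lapply(thresholds, function(th)
    tryCatch(select_units(r2s, th), error = function(e) integer(0)))
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
})

test_that("preprocessing is deterministic and produces aligned, finite output", {
  bd <- small_binned()
  bd2 <- preprocess_session(small_session()$session)
  expect_identical(bd, bd2)
  expect_identical(nrow(bd$Z), nrow(bd$X))
  expect_identical(nrow(bd$Z), length(bd$trial_of_bin))
  expect_false(anyNA(bd$Z))
  expect_false(anyNA(bd$X))
  expect_equal(bd$X[, 3], sqrt(bd$X[, 1]^2 + bd$X[, 2]^2), tolerance = 1e-9)
})
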