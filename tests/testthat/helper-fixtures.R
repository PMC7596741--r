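# Shared fixtures, built in code and cached per test run.

fixture_env <- new.env(parent = emptyenv())

# A small center-out session with mixed linear/nonlinear units.
small_session <- function() {
  if (is.null(fixture_env$small)) {
    fixture_env$small <- make_synthetic_session(
      synth_config(n_units = 15, n_trials = 24, frac_nonlinear = 0.4),
      seed = 101)
  }
  fixture_env$small
}

small_binned <- function() {
  if (is.null(fixture_env$small_bd)) {
    fixture_env$small_bd <- preprocess_session(small_session()$session)
  }
  fixture_env$small_bd
}

# Random LDS simulator used by latent/decoder tests.
simulate_lds <- function(n, A, C, q_sd, r_sd, seed = 1) {
  set.seed(seed)
  q <- nrow(A); m <- nrow(C)
  x <- matrix(0, n, q)
  for (t in 2:n) x[t, ] <- A %*% x[t - 1, ] + rnorm(q, sd = q_sd)
  list(x = x, Z = x %*% t(C) + matrix(rnorm(n * m, sd = r_sd), n))
}
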