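# Internal helpers shared across modules.

#' canokin: canonical neural representations and kinematic decoding
#'
#' Offline decoding pipeline for motor-cortex population recordings paired
#' with 2D hand kinematics: linear and deep canonical correlation analysis,
#' PCA/FA/LDS latent baselines, steady-state Kalman and LSTM decoders, and a
#' synthetic reaching-session simulator with known cosine-tuned ground truth.
#'
#' @name canokin-package
#' @importFrom MASS ginv
#' @importFrom jsonlite write_json
#' @importFrom stats rnorm runif rpois cor sd cov lm.fit coef approx
#'   friedman.test wilcox.test
#' @importFrom utils modifyList combn write.csv
#' @importFrom tools md5sum
#' @keywords internal
"_PACKAGE"

# Derive a stage-specific 32-bit seed from a master seed and a label.
# Uses a small multiplicative string hash; keeps results below 2^31.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(label)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Run an expression under a local RNG state so library code never
# clobbers the caller's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Symmetric inverse square root of a positive-definite matrix.
mat_inv_sqrt <- function(S, ridge = 0) {
  S <- (S + t(S)) / 2
  if (ridge > 0) S <- S + diag(ridge, nrow(S))
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values <= 0)) {
    stop("covariance matrix is singular; supply a positive ridge", call. = FALSE)
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

# Column-center a matrix, returning the centered matrix and the means used.
center_cols <- function(M, means = NULL) {
  M <- as.matrix(M)
  if (is.null(means)) means <- colMeans(M)
  list(M = sweep(M, 2L, means, "-"), means = means)
}

logistic <- function(x) 1 / (1 + exp(-x))

logit <- function(p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}
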