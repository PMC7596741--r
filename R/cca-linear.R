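# Linear canonical correlation analysis between population firing rates and
# kinematics. Both views are centred, whitened with a (ridged) inverse
# square-root covariance, and the whitened cross-covariance is decomposed by
# SVD: its singular values are the canonical correlations and the rotated
# whitening maps are the canonical coefficient matrices.

#' Fit a linear CCA between firing rates and kinematics
#'
#' Finds coefficient matrices `alpha` (units) and `beta` (kinematics) whose
#' projections have maximal pairwise correlation under the unit-variance
#' constraint `alpha' S_Z alpha = beta' S_X beta = I`. The number of pairs is
#' `min(m, d)` (3 pairs for the usual velocity + speed kinematic view). Each
#' pair's sign is fixed so its training correlation is non-negative.
#'
#' @param Z_train bins x m matrix (neural view).
#' @param X_train bins x d matrix (kinematic view; d = 3 downstream).
#' @param ridge ridge added to both view covariances before whitening,
#'   default 1e-8. Increase when a view is numerically singular.
#' @return a `canokin_lcca`: `alpha` (m x k), `beta` (d x k), `rho`
#'   (descending canonical correlations), `mean_z`, `mean_x`, `k`.
#' @export
fit_lcca <- function(Z_train, X_train, ridge = 1e-8) {
  Z_train <- as.matrix(Z_train); X_train <- as.matrix(X_train)
  if (nrow(Z_train) != nrow(X_train)) stop("views must have equal rows", call. = FALSE)
  m <- ncol(Z_train); d <- ncol(X_train)
  if (nrow(Z_train) < m + d)
    stop("need at least m + d training bins", call. = FALSE)
  cz <- center_cols(Z_train); cx <- center_cols(X_train)
  n <- nrow(Z_train)
  Szz <- crossprod(cz$M) / (n - 1)
  Sxx <- crossprod(cx$M) / (n - 1)
  Szx <- crossprod(cz$M, cx$M) / (n - 1)
  Wz <- tryCatch(mat_inv_sqrt(Szz, ridge),
                 error = function(e) stop("neural covariance singular; increase ridge",
                                          call. = FALSE))
  Wx <- tryCatch(mat_inv_sqrt(Sxx, ridge),
                 error = function(e) stop("kinematic covariance singular; increase ridge",
                                          call. = FALSE))
  sv <- svd(Wz %*% Szx %*% Wx)
  k <- min(m, d)
  alpha <- Wz %*% sv$u[, seq_len(k), drop = FALSE]
  beta <- Wx %*% sv$v[, seq_len(k), drop = FALSE]
  structure(list(alpha = alpha, beta = beta,
                 rho = pmin(sv$d[seq_len(k)], 1),
                 mean_z = cz$means, mean_x = cx$means, k = k,
                 ridge = ridge),
            class = "canokin_lcca")
}

#' Project data onto linear canonical variables
#'
#' Centres both views with the training means and applies the fitted
#' canonical coefficients, yielding the neural (Z_LCV) and kinematic (X_LCV)
#' canonical variable series.
#'
#' @param model a `canokin_lcca`.
#' @param Z,X matrices with the training dimensionalities (either may be
#'   NULL to skip that view).
#' @return list with `Z_cv` and `X_cv` (bins x k), NULL where skipped.
#' @export
transform_lcca <- function(model, Z = NULL, X = NULL) {
  out <- list(Z_cv = NULL, X_cv = NULL)
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (ncol(Z) != length(model$mean_z)) stop("neural view width mismatch", call. = FALSE)
    out$Z_cv <- sweep(Z, 2L, model$mean_z, "-") %*% model$alpha
  }
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (ncol(X) != length(model$mean_x)) stop("kinematic view width mismatch", call. = FALSE)
    out$X_cv <- sweep(X, 2L, model$mean_x, "-") %*% model$beta
  }
  out
}

#' Per-pair Pearson correlations of canonical variables
#'
#' @param U,V matrices with matching dimensions; column j of U is correlated
#'   with column j of V.
#' @return numeric vector of correlations.
#' @export
canonical_correlations <- function(U, V) {
  U <- as.matrix(U); V <- as.matrix(V)
  if (!all(dim(U) == dim(V))) stop("U and V must match in shape", call. = FALSE)
  vapply(seq_len(ncol(U)), function(j) stats::cor(U[, j], V[, j]), numeric(1))
}

#' Reconstruct velocity through the canonical space alone
#'
#' A deliberately simple readout used as a baseline: each kinematic canonical
#' variable is predicted from its paired neural canonical variable by
#' per-pair linear regression fitted on training data, and the kinematic
#' canonical map is then inverted back to velocity. For the linear model the
#' inversion is `x = (beta')^{-1} u + mean_x`; for the deep model the output
#' rotation, linear output layer and each sigmoid hidden layer are inverted
#' in turn (logit + pseudo-inverse), clipping activations into (eps, 1-eps).
#' Expected to trail a proper decoder.
#'
#' @param model a `canokin_lcca` or `canokin_dcca`.
#' @param Z_cv_train,X_cv_train training canonical variables (for the
#'   per-pair regressions).
#' @param Z_cv_test test neural canonical variables.
#' @param eps clipping margin for the logit inversion, default 1e-6.
#' @return bins x 2 matrix of reconstructed `[vx, vy]`.
#' @export
invert_cca_velocity <- function(model, Z_cv_train, X_cv_train, Z_cv_test,
                                eps = 1e-6) {
  k <- ncol(Z_cv_train)
  X_cv_hat <- vapply(seq_len(k), function(j) {
    co <- stats::coef(stats::lm.fit(cbind(1, Z_cv_train[, j]), X_cv_train[, j]))
    co[1] + co[2] * Z_cv_test[, j]
  }, numeric(nrow(Z_cv_test)))
  X_cv_hat <- matrix(X_cv_hat, nrow = nrow(Z_cv_test))
  X_hat <- invert_kinematic_map(model, X_cv_hat, eps = eps)
  X_hat[, 1:2, drop = FALSE]
}

# Invert the kinematic-view canonical map of a fitted model, back to the
# original kinematic coordinates. Methods in cca-linear.R / cca-deep.R.
invert_kinematic_map <- function(model, X_cv, eps = 1e-6) {
  UseMethod("invert_kinematic_map")
}

#' @export
invert_kinematic_map.canokin_lcca <- function(model, X_cv, eps = 1e-6) {
  Binv <- if (nrow(model$beta) == ncol(model$beta)) solve(t(model$beta))
          else MASS::ginv(t(model$beta))
  sweep(X_cv %*% t(Binv), 2L, model$mean_x, "+")
}
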