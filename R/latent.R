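# Unsupervised latent representations of population firing: PCA, factor
# analysis (EM), and a linear dynamical system (EM with Kalman smoothing).
# Dimensionality is chosen by held-out reconstruction error.

#' Principal component analysis of population rates
#'
#' Eigendecomposition of the training covariance of the smoothed rates,
#' components sorted by descending eigenvalue. Performed on single-trial
#' (bin-by-bin) data, not trial averages.
#'
#' @param Z_train bins x units matrix of smoothed sqrt-rates.
#' @return a `canokin_latent` with method `"pca"`: `loadings` (units x
#'   components, orthonormal), `eigenvalues`, `mean`.
#' @export
fit_pca <- function(Z_train) {
  ctr <- center_cols(Z_train)
  S <- stats::cov(ctr$M)
  e <- eigen(S, symmetric = TRUE)
  r <- min(nrow(Z_train) - 1L, ncol(Z_train))
  if (r < ncol(Z_train))
    warning(sprintf("fewer bins than units; keeping %d rank components", r))
  structure(list(method = "pca",
                 loadings = e$vectors[, seq_len(r), drop = FALSE],
                 eigenvalues = pmax(e$values[seq_len(r)], 0),
                 mean = ctr$means, q = r),
            class = "canokin_latent")
}

#' Factor analysis by expectation-maximisation
#'
#' Fits `z = mean + L f + eps` with isotropic factors `f ~ N(0, I)` and
#' diagonal uniquenesses, by EM on the training covariance. The log-likelihood
#' is non-decreasing across iterations (tracked in `loglik_trace`). Factor
#' scores are extracted by the posterior mean operator.
#'
#' @param Z_train bins x units matrix.
#' @param q number of factors (>= 1).
#' @param max_iter EM iteration cap, default 200.
#' @param tol relative log-likelihood change for convergence, default 1e-6.
#' @return a `canokin_latent` with method `"fa"`: `loadings` (m x q),
#'   `uniquenesses`, `mean`, `score_operator` (q x m posterior-mean map),
#'   `loglik_trace`, `converged`.
#' @export
fit_fa <- function(Z_train, q, max_iter = 200, tol = 1e-6) {
  if (q < 1) stop("q must be at least 1", call. = FALSE)
  m <- ncol(Z_train)
  n <- nrow(Z_train)
  if (q > m) stop("q cannot exceed the number of units", call. = FALSE)
  ctr <- center_cols(Z_train)
  S <- crossprod(ctr$M) / n
  # PCA-based init, uniqueness floor keeps Psi positive.
  e <- eigen(S, symmetric = TRUE)
  L <- e$vectors[, seq_len(q), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(q)], 1e-8)), q)
  psi <- pmax(diag(S) - rowSums(L^2), 1e-6)
  ll <- function(L, psi) {
    C <- tcrossprod(L) + diag(psi, m)
    ch <- chol(C)
    -n / 2 * (2 * sum(log(diag(ch))) +
                sum(diag(chol2inv(ch) %*% S)) + m * log(2 * pi))
  }
  trace <- ll(L, psi)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    C <- tcrossprod(L) + diag(psi, m)
    B <- t(L) %*% chol2inv(chol(C))          # q x m posterior-mean operator
    Ef2 <- diag(q) - B %*% L + B %*% S %*% t(B)
    SB <- S %*% t(B)
    L_new <- SB %*% solve(Ef2)
    psi_new <- pmax(diag(S - L_new %*% t(SB)), 1e-6)
    L <- L_new; psi <- psi_new
    trace <- c(trace, ll(L, psi))
    k <- length(trace)
    if (abs(trace[k] - trace[k - 1]) < tol * (abs(trace[k - 1]) + 1e-12)) {
      converged <- TRUE
      break
    }
  }
  C <- tcrossprod(L) + diag(psi, m)
  structure(list(method = "fa", loadings = L, uniquenesses = psi,
                 mean = ctr$means,
                 score_operator = t(L) %*% chol2inv(chol(C)),
                 loglik_trace = trace, converged = converged, q = q),
            class = "canokin_latent")
}

# Kalman filter for an LDS (A, C, Q, R diagonal, mu0, V0) on rows of Zc
# (already centred). Returns filtered means/covariances, predicted ones, and
# the innovations log-likelihood.
lds_kalman_filter <- function(A, C, Q, R, mu0, V0, Zc) {
  n <- nrow(Zc); q <- length(mu0); m <- ncol(Zc)
  xf <- matrix(0, n, q); Vf <- array(0, c(q, q, n))
  xp <- matrix(0, n, q); Vp <- array(0, c(q, q, n))
  ll <- 0
  x <- mu0; V <- V0
  for (t in seq_len(n)) {
    if (t > 1) {
      x <- A %*% x
      V <- A %*% V %*% t(A) + Q
    }
    xp[t, ] <- x; Vp[, , t] <- V
    Sg <- C %*% V %*% t(C) + diag(R, m)
    ch <- chol((Sg + t(Sg)) / 2)
    innov <- Zc[t, ] - as.numeric(C %*% x)
    si <- backsolve(ch, forwardsolve(t(ch), innov))
    ll <- ll - 0.5 * (2 * sum(log(diag(ch))) + sum(innov * si) + m * log(2 * pi))
    K <- V %*% t(C) %*% chol2inv(ch)
    x <- x + K %*% innov
    V <- V - K %*% C %*% V
    V <- (V + t(V)) / 2
    xf[t, ] <- x; Vf[, , t] <- V
  }
  list(xf = xf, Vf = Vf, xp = xp, Vp = Vp, loglik = ll)
}

# Rauch-Tung-Striebel smoother; also returns lag-one covariance sums needed
# by the EM M-step.
lds_smooth <- function(A, filt) {
  n <- nrow(filt$xf); q <- ncol(filt$xf)
  xs <- filt$xf; Vs <- filt$Vf
  J <- array(0, c(q, q, n))
  for (t in (n - 1):1) {
    J[, , t] <- filt$Vf[, , t] %*% t(A) %*% solve(filt$Vp[, , t + 1])
    xs[t, ] <- filt$xf[t, ] +
      as.numeric(J[, , t] %*% (xs[t + 1, ] - filt$xp[t + 1, ]))
    Vs[, , t] <- filt$Vf[, , t] +
      J[, , t] %*% (Vs[, , t + 1] - filt$Vp[, , t + 1]) %*% t(J[, , t])
  }
  # lag-one smoothed covariances V_{t,t-1}
  V1 <- array(0, c(q, q, n))
  for (t in 2:n) {
    V1[, , t] <- Vs[, , t] %*% t(J[, , t - 1])
  }
  list(xs = xs, Vs = Vs, V1 = V1)
}

#' Linear dynamical system fit by EM
#'
#' Treats the population rates as noisy linear observations of a
#' low-dimensional dynamical neural state: `x_t = A x_{t-1} + w`,
#' `z_t = C x_t + v` with diagonal observation noise. Parameters are
#' estimated by EM (Kalman filter + RTS smoother E-step); the innovations
#' log-likelihood is non-decreasing across iterations.
#'
#' @param Z_train bins x units matrix.
#' @param q state dimensionality.
#' @param max_iter EM iteration cap, default 50.
#' @param tol relative log-likelihood tolerance, default 1e-5.
#' @return a `canokin_latent` with method `"lds"`: `A`, `C`, `Q`, `R`
#'   (diagonal, as a vector), `mu0`, `V0`, `mean`, `loglik_trace`,
#'   `converged`.
#' @export
fit_lds <- function(Z_train, q, max_iter = 50, tol = 1e-5) {
  if (q < 1) stop("q must be at least 1", call. = FALSE)
  m <- ncol(Z_train)
  if (q > m) stop("q cannot exceed the number of units", call. = FALSE)
  ctr <- center_cols(Z_train)
  Zc <- ctr$M
  n <- nrow(Zc)
  # init from PCA projections
  p <- fit_pca(Z_train)
  C <- p$loadings[, seq_len(q), drop = FALSE]
  xs0 <- Zc %*% C
  A <- t(stats::lm.fit(xs0[-n, , drop = FALSE], xs0[-1, , drop = FALSE])$coefficients)
  A <- matrix(A, q, q)
  resid <- xs0[-1, , drop = FALSE] - xs0[-n, , drop = FALSE] %*% t(A)
  Q <- crossprod(resid) / (n - 1) + diag(1e-6, q)
  R <- pmax(diag(stats::cov(Zc - xs0 %*% t(C))), 1e-6)
  mu0 <- rep(0, q); V0 <- diag(1, q)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    filt <- lds_kalman_filter(A, C, Q, R, mu0, V0, Zc)
    trace <- c(trace, filt$loglik)
    if (it > 1 && abs(trace[it] - trace[it - 1]) <
        tol * (abs(trace[it - 1]) + 1e-12)) {
      converged <- TRUE
      break
    }
    sm <- lds_smooth(A, filt)
    xs <- sm$xs
    Ptt <- array(0, c(q, q, n))
    for (t in seq_len(n)) Ptt[, , t] <- sm$Vs[, , t] + tcrossprod(xs[t, ])
    S11 <- apply(Ptt[, , 2:n, drop = FALSE], c(1, 2), sum)
    S00 <- apply(Ptt[, , 1:(n - 1), drop = FALSE], c(1, 2), sum)
    S10 <- matrix(0, q, q)
    for (t in 2:n) S10 <- S10 + sm$V1[, , t] + xs[t, ] %*% t(xs[t - 1, ])
    A <- S10 %*% solve(S00)
    Q <- (S11 - A %*% t(S10)) / (n - 1)
    Q <- (Q + t(Q)) / 2 + diag(1e-9, q)
    Sxx <- S11 + Ptt[, , 1]
    Szx <- crossprod(Zc, xs)
    C <- Szx %*% solve(Sxx)
    R <- pmax((colSums(Zc^2) - rowSums(C * Szx)) / n, 1e-6)
    mu0 <- xs[1, ]
    V0 <- sm$Vs[, , 1] + diag(1e-9, q)
  }
  if (max(Mod(eigen(A, only.values = TRUE)$values)) > 1.05)
    warning("estimated state transition is unstable (spectral radius > 1.05)")
  structure(list(method = "lds", A = A, C = C, Q = Q, R = R, mu0 = mu0,
                 V0 = V0, mean = ctr$means, loadings = C,
                 loglik_trace = trace, converged = converged, q = q),
            class = "canokin_latent")
}

#' Extract latent states from a fitted model
#'
#' PCA: projection on the leading `q` eigenvectors. FA: posterior-mean factor
#' scores. LDS: causally filtered states (forward Kalman filter only, no
#' smoothing), so truncating the future never changes past states.
#'
#' @param model a `canokin_latent`.
#' @param Z bins x units matrix (same units as training).
#' @param q number of components to keep (PCA only; defaults to the fitted q).
#' @return bins x q matrix of latent series.
#' @export
estimate_states <- function(model, Z, q = NULL) {
  Zc <- sweep(as.matrix(Z), 2L, model$mean, "-")
  switch(model$method,
    pca = {
      if (is.null(q)) q <- model$q
      Zc %*% model$loadings[, seq_len(q), drop = FALSE]
    },
    fa = Zc %*% t(model$score_operator),
    lds = lds_kalman_filter(model$A, model$C, model$Q, model$R, model$mu0,
                            model$V0, Zc)$xf,
    stop("unknown latent method")
  )
}

#' Reconstruct rates from latent states
#'
#' @param model a `canokin_latent`.
#' @param Z bins x units matrix to encode and decode.
#' @param q components kept (PCA only).
#' @return bins x units matrix of reconstructed rates.
#' @export
reconstruct_rates <- function(model, Z, q = NULL) {
  states <- estimate_states(model, Z, q = q)
  W <- switch(model$method,
    pca = {
      if (is.null(q)) q <- model$q
      t(model$loadings[, seq_len(q), drop = FALSE])
    },
    fa = t(model$loadings),
    lds = t(model$C)
  )
  sweep(states %*% W, 2L, model$mean, "+")
}

# Leave-one-neuron-out reconstruction error: each unit is predicted from all
# the others through the q-dimensional model, so the error has a genuine
# minimum at the true latent dimensionality (naive projection error is
# monotone in q and would always select q = m for PCA).
lono_error <- function(model, Z) {
  Z <- as.matrix(Z)
  m <- ncol(Z)
  err <- 0
  for (j in seq_len(m)) {
    Zc <- sweep(Z[, -j, drop = FALSE], 2L, model$mean[-j], "-")
    pred_j <- switch(model$method,
      pca = {
        L <- model$loadings[, seq_len(model$q), drop = FALSE]
        co <- stats::lm.fit(L[-j, , drop = FALSE], t(Zc))$coefficients
        co[is.na(co)] <- 0  # rank-deficient when q >= m: drop aliased comps
        model$mean[j] + t(co) %*% L[j, ]
      },
      fa = {
        L <- model$loadings
        Cj <- tcrossprod(L[-j, , drop = FALSE]) +
          diag(model$uniquenesses[-j], m - 1)
        B <- t(L[-j, , drop = FALSE]) %*% chol2inv(chol(Cj))
        model$mean[j] + (Zc %*% t(B)) %*% L[j, ]
      },
      lds = {
        f <- lds_kalman_filter(model$A, model$C[-j, , drop = FALSE],
                               model$Q, model$R[-j], model$mu0, model$V0, Zc)
        model$mean[j] + f$xf %*% model$C[j, ]
      })
    err <- err + sum(abs(Z[, j] - pred_j))
  }
  err / length(Z)
}

#' Held-out reconstruction-error dimensionality selection
#'
#' For each candidate dimensionality, fits the model on training rates,
#' reconstructs the held-out rates, and scores the mean absolute error; the
#' selected dimensionality minimises that error. For PCA a single fit is
#' reused across candidates (nested components). By default the held-out
#' error is leave-one-neuron-out (each unit predicted from the others through
#' the latent space), which has a genuine minimum at the underlying
#' dimensionality; `error = "projection"` scores plain own-data
#' reconstruction instead (monotone in q for PCA, reaching 0 at q = m).
#'
#' @param method `"pca"`, `"fa"` or `"lds"`.
#' @param Z_train,Z_test training and held-out rate matrices.
#' @param candidates ascending candidate dimensionalities. Defaults: PCA
#'   `seq(5, m, 5)`; FA/LDS `seq(5, min(m, 40), 5)`.
#' @param error held-out error flavour, `"lono"` (default) or `"projection"`.
#' @param ... passed to the fitting function (e.g. `max_iter`).
#' @return list with `q` (the argmin), `errors` (named MAE per candidate) and
#'   `models` (fitted models; for PCA a single model).
#' @export
select_dimensionality <- function(method = c("pca", "fa", "lds"), Z_train,
                                  Z_test, candidates = NULL,
                                  error = c("lono", "projection"), ...) {
  method <- match.arg(method)
  error <- match.arg(error)
  m <- ncol(Z_train)
  if (is.null(candidates)) {
    candidates <- if (method == "pca") unique(c(seq(5, m, 5), m))
                  else seq(5, min(m, 40), 5)
    candidates <- candidates[candidates >= 1 & candidates <= m]
  }
  if (!length(candidates)) stop("no candidate dimensionalities", call. = FALSE)
  candidates <- sort(unique(as.integer(candidates)))
  errs <- numeric(length(candidates))
  models <- list()
  score <- function(mod, q = NULL) {
    if (error == "lono") {
      if (!is.null(q)) { mod$q <- q }
      lono_error(mod, Z_test)
    } else {
      mean(abs(reconstruct_rates(mod, Z_test, q = q) - Z_test))
    }
  }
  if (method == "pca") {
    mod <- fit_pca(Z_train)
    for (i in seq_along(candidates)) errs[i] <- score(mod, q = candidates[i])
    models <- mod
  } else {
    fitter <- if (method == "fa") fit_fa else fit_lds
    for (i in seq_along(candidates)) {
      mod <- fitter(Z_train, candidates[i], ...)
      errs[i] <- score(mod)
      models[[i]] <- mod
    }
  }
  names(errs) <- candidates
  list(q = candidates[which.min(errs)], errors = errs, models = models)
}
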