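# Velocity decoders: a steady-state linear Kalman filter over the kinematic
# state [vx, vy, speed], a neural dynamical filter (ridge regression from LDS
# latent states), and a single-layer LSTM sequence regressor trained by Adam
# with backpropagation through time.

# ---- linear Kalman filter ----------------------------------------------

#' Fit a linear Kalman filter decoder
#'
#' Generative model: state transition `x_t = A x_{t-1} + w`, observation
#' `o_t = H x_t + v`, with `x = [vx, vy, speed]`. A and H are estimated by
#' least squares on the training set (transition pairs never straddle trial
#' boundaries), Q and V as residual covariances, and the steady-state gain
#' `K` as the fixed point of the Riccati gain recursion (sup-norm change
#' below `tol`, capped at `max_iter` iterations).
#'
#' @param X_train bins x 3 kinematic state matrix.
#' @param O_train bins x p observation matrix (any neural representation).
#' @param trial_of_bin optional trial index per bin; transition pairs across
#'   trial changes are dropped.
#' @param tol Riccati fixed-point tolerance, default 1e-10.
#' @param max_iter Riccati iteration cap, default 1e4.
#' @return a `canokin_lkf`: `A`, `H`, `Q`, `V`, `K` (steady-state gain),
#'   `P` (converged prior covariance), `n_iter`.
#' @export
fit_lkf <- function(X_train, O_train, trial_of_bin = NULL, tol = 1e-10,
                    max_iter = 1e4) {
  X_train <- as.matrix(X_train); O_train <- as.matrix(O_train)
  n <- nrow(X_train)
  if (n != nrow(O_train)) stop("state and observation rows must align", call. = FALSE)
  keep <- rep(TRUE, n - 1)
  if (!is.null(trial_of_bin))
    keep <- trial_of_bin[-1] == trial_of_bin[-n]
  X1 <- X_train[-n, , drop = FALSE][keep, , drop = FALSE]
  X2 <- X_train[-1, , drop = FALSE][keep, , drop = FALSE]
  A <- t(stats::lm.fit(X1, X2)$coefficients)
  A <- matrix(A, ncol(X_train), ncol(X_train))
  resA <- X2 - X1 %*% t(A)
  Q <- crossprod(resA) / max(1, nrow(X1) - ncol(X_train))
  H <- t(stats::lm.fit(X_train, O_train)$coefficients)
  H <- matrix(H, ncol(O_train), ncol(X_train))
  resH <- O_train - X_train %*% t(H)
  V <- crossprod(resH) / max(1, n - ncol(X_train))
  d <- ncol(X_train); p <- ncol(O_train)
  P <- Q
  K <- matrix(0, d, p)
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    P_pred <- A %*% P %*% t(A) + Q
    S <- H %*% P_pred %*% t(H) + V
    K_new <- P_pred %*% t(H) %*% solve(S)
    P <- (diag(d) - K_new %*% H) %*% P_pred
    if (max(abs(K_new - K)) < tol) { K <- K_new; break }
    K <- K_new
    if (n_iter >= max_iter) {
      stop(sprintf(
        "Riccati recursion did not converge in %d iterations (spectral radius of A = %.3f)",
        as.integer(max_iter), max(Mod(eigen(A, only.values = TRUE)$values))),
        call. = FALSE)
    }
  }
  structure(list(A = A, H = H, Q = Q, V = V, K = K, P = A %*% P %*% t(A) + Q,
                 n_iter = n_iter),
            class = "canokin_lkf")
}

#' Run the steady-state Kalman filter
#'
#' Applies `x_t = A x_{t-1} + K (o_t - H A x_{t-1})` with the converged gain,
#' resetting the state to zero at the start of every trial. The decoded speed
#' column is dropped; evaluation uses velocity only.
#'
#' @param model a `canokin_lkf`.
#' @param O_test bins x p observation matrix.
#' @param trial_of_bin trial index per bin (state resets where it changes);
#'   NULL treats the whole series as one trial.
#' @return bins x 2 matrix of decoded `[vx, vy]`.
#' @export
run_lkf <- function(model, O_test, trial_of_bin = NULL) {
  O_test <- as.matrix(O_test)
  n <- nrow(O_test)
  d <- nrow(model$A)
  out <- matrix(0, n, d)
  if (n == 0L) return(out[, 1:2, drop = FALSE])
  if (is.null(trial_of_bin)) trial_of_bin <- rep(1L, n)
  if (length(trial_of_bin) != n) stop("trial index length mismatch", call. = FALSE)
  x <- rep(0, d)
  for (t in seq_len(n)) {
    if (t == 1L || trial_of_bin[t] != trial_of_bin[t - 1]) x <- rep(0, d)
    xp <- model$A %*% x
    x <- xp + model$K %*% (O_test[t, ] - model$H %*% xp)
    out[t, ] <- x
  }
  out[, 1:2, drop = FALSE]
}

# ---- neural dynamical filter -------------------------------------------

#' Fit a neural dynamical filter
#'
#' Ridge regression (with intercept) from latent states to the kinematic
#' state, used in place of the Kalman filter for LDS representations, whose
#' latent dynamics already embody the temporal model.
#'
#' @param latent_train bins x q latent matrix.
#' @param X_train bins x 3 kinematic matrix.
#' @param ridge ridge penalty, default 1e-8.
#' @return a `canokin_ndf` with `W` ((q+1) x 3 coefficients incl. intercept).
#' @export
fit_ndf <- function(latent_train, X_train, ridge = 1e-8) {
  Y <- cbind(1, as.matrix(latent_train))
  G <- crossprod(Y) + diag(c(0, rep(ridge, ncol(Y) - 1L)))
  if (ridge <= 0 && kappa(G) > 1e12)
    stop("singular design; use a positive ridge", call. = FALSE)
  W <- solve(G, crossprod(Y, as.matrix(X_train)))
  structure(list(W = W), class = "canokin_ndf")
}

#' Predict velocity with a neural dynamical filter
#'
#' @param model a `canokin_ndf`.
#' @param latent_test bins x q latent matrix.
#' @return bins x 2 matrix of `[vx, vy]`.
#' @export
run_ndf <- function(model, latent_test) {
  out <- cbind(1, as.matrix(latent_test)) %*% model$W
  out[, 1:2, drop = FALSE]
}

# ---- LSTM sequence regressor -------------------------------------------

lstm_init <- function(n_in, l, seed = 1) {
  with_seed(seed, {
    mk <- function(r, c) matrix(stats::rnorm(r * c, sd = 1 / sqrt(c)), r, c)
    list(
      Wz = list(f = mk(l, n_in), i = mk(l, n_in), o = mk(l, n_in),
                c = mk(l, n_in)),
      Wl = list(f = mk(l, l), i = mk(l, l), o = mk(l, l), c = mk(l, l)),
      b = list(f = rep(1, l), i = rep(0, l), o = rep(0, l), c = rep(0, l)),
      Wy = mk(2, l), by = rep(0, 2), l = l, n_in = n_in
    )
  })
}

# Batched forward pass over sequences of equal length `steps`.
# Y: array steps x b x n_in. Returns gate/cell activations for BPTT.
lstm_forward <- function(par, Y) {
  steps <- dim(Y)[1]; b <- dim(Y)[2]; l <- par$l
  H <- array(0, c(steps + 1, b, l)); C <- array(0, c(steps + 1, b, l))
  Fg <- array(0, c(steps, b, l)); Ig <- Fg; Og <- Fg; Cu <- Fg; Tc <- Fg
  pred <- array(0, c(steps, b, 2))
  for (t in seq_len(steps)) {
    Yt <- matrix(Y[t, , ], b)
    Hp <- matrix(H[t, , ], b)
    f <- logistic(Yt %*% t(par$Wz$f) + Hp %*% t(par$Wl$f) +
                    matrix(par$b$f, b, l, byrow = TRUE))
    i <- logistic(Yt %*% t(par$Wz$i) + Hp %*% t(par$Wl$i) +
                    matrix(par$b$i, b, l, byrow = TRUE))
    o <- logistic(Yt %*% t(par$Wz$o) + Hp %*% t(par$Wl$o) +
                    matrix(par$b$o, b, l, byrow = TRUE))
    cu <- tanh(Yt %*% t(par$Wz$c) + Hp %*% t(par$Wl$c) +
                 matrix(par$b$c, b, l, byrow = TRUE))
    cc <- f * matrix(C[t, , ], b) + i * cu
    tc <- tanh(cc)
    h <- o * tc
    H[t + 1, , ] <- h; C[t + 1, , ] <- cc
    Fg[t, , ] <- f; Ig[t, , ] <- i; Og[t, , ] <- o; Cu[t, , ] <- cu
    Tc[t, , ] <- tc
    pred[t, , ] <- h %*% t(par$Wy) + matrix(par$by, b, 2, byrow = TRUE)
  }
  list(H = H, C = C, Fg = Fg, Ig = Ig, Og = Og, Cu = Cu, Tc = Tc, pred = pred)
}

# Batched BPTT. dPred: steps x b x 2 gradient of loss wrt predictions.
# mask: steps x b (1 inside a sequence, 0 in padding).
lstm_backward <- function(par, Y, fw, dPred, mask) {
  steps <- dim(Y)[1]; b <- dim(Y)[2]; l <- par$l
  zW <- function(M) M * 0
  g <- list(Wz = lapply(par$Wz, zW), Wl = lapply(par$Wl, zW),
            b = lapply(par$b, function(v) v * 0),
            Wy = zW(par$Wy), by = par$by * 0)
  dH <- matrix(0, b, l); dC <- matrix(0, b, l)
  for (t in steps:1) {
    mk <- mask[t, ]
    dp <- matrix(dPred[t, , ], b) * mk
    h <- matrix(fw$H[t + 1, , ], b)
    g$Wy <- g$Wy + crossprod(dp, h)
    g$by <- g$by + colSums(dp)
    dH <- dH + dp %*% par$Wy
    f <- matrix(fw$Fg[t, , ], b); i <- matrix(fw$Ig[t, , ], b)
    o <- matrix(fw$Og[t, , ], b); cu <- matrix(fw$Cu[t, , ], b)
    tc <- matrix(fw$Tc[t, , ], b)
    cprev <- matrix(fw$C[t, , ], b)
    dO <- dH * tc
    dC <- dC + dH * o * (1 - tc^2)
    dF <- dC * cprev
    dI <- dC * cu
    dCu <- dC * i
    dC_next <- dC * f
    da <- list(f = dF * f * (1 - f) * mk, i = dI * i * (1 - i) * mk,
               o = dO * o * (1 - o) * mk, c = dCu * (1 - cu^2) * mk)
    Yt <- matrix(Y[t, , ], b)
    Hp <- matrix(fw$H[t, , ], b)
    dH_new <- matrix(0, b, l)
    for (gate in c("f", "i", "o", "c")) {
      g$Wz[[gate]] <- g$Wz[[gate]] + crossprod(da[[gate]], Yt)
      g$Wl[[gate]] <- g$Wl[[gate]] + crossprod(da[[gate]], Hp)
      g$b[[gate]] <- g$b[[gate]] + colSums(da[[gate]])
      dH_new <- dH_new + da[[gate]] %*% par$Wl[[gate]]
    }
    dH <- dH_new
    dC <- dC_next * mk
  }
  g
}

lstm_flatten <- function(x) {
  c(unlist(x$Wz), unlist(x$Wl), unlist(x$b), as.numeric(x$Wy), x$by)
}

lstm_unflatten_like <- function(template, v) {
  out <- template
  pos <- 1L
  assign_next <- function(p) {
    n <- length(p)
    r <- v[pos:(pos + n - 1L)]
    pos <<- pos + n
    if (is.matrix(p)) matrix(r, nrow(p), ncol(p)) else r
  }
  for (gate in c("f", "i", "o", "c")) out$Wz[[gate]] <- assign_next(template$Wz[[gate]])
  for (gate in c("f", "i", "o", "c")) out$Wl[[gate]] <- assign_next(template$Wl[[gate]])
  for (gate in c("f", "i", "o", "c")) out$b[[gate]] <- assign_next(template$b[[gate]])
  out$Wy <- assign_next(template$Wy)
  out$by <- assign_next(template$by)
  out
}

# Split bins into per-trial sequences; returns list of (Y, X) matrices.
split_sequences <- function(Y, X, trial_of_bin) {
  ids <- unique(trial_of_bin)
  lapply(ids, function(id) {
    rows <- which(trial_of_bin == id)
    list(Y = Y[rows, , drop = FALSE],
         X = if (is.null(X)) NULL else X[rows, , drop = FALSE],
         id = id)
  })
}

# Pack a list of sequences into padded arrays (steps x b x dim) + mask.
pack_sequences <- function(seqs, dim_y, dim_x = 2L) {
  lens <- vapply(seqs, function(s) nrow(s$Y), integer(1))
  steps <- max(lens); b <- length(seqs)
  Y <- array(0, c(steps, b, dim_y))
  X <- array(0, c(steps, b, dim_x))
  mask <- matrix(0, steps, b)
  for (j in seq_len(b)) {
    Y[seq_len(lens[j]), j, ] <- seqs[[j]]$Y
    if (!is.null(seqs[[j]]$X))
      X[seq_len(lens[j]), j, ] <- seqs[[j]]$X[, seq_len(dim_x), drop = FALSE]
    mask[seq_len(lens[j]), j] <- 1
  }
  list(Y = Y, X = X, mask = mask, lens = lens)
}

#' LSTM hyperparameters
#'
#' @param nodes hidden units `l`, default 32.
#' @param batch trials per minibatch, default 32.
#' @param lr Adam learning rate, default 1e-3.
#' @param rcov L2 regularisation strength on all weights, default 0.01.
#' @param epochs maximum epochs, default 100.
#' @param patience epochs without inner-validation improvement before early
#'   stop, default 10.
#' @param val_frac fraction of training trials held out for early stopping,
#'   default 0.1.
#' @return plain list of settings.
#' @export
lstm_theta <- function(nodes = 32, batch = 32, lr = 1e-3, rcov = 0.01,
                       epochs = 100, patience = 10, val_frac = 0.1) {
  list(nodes = nodes, batch = batch, lr = lr, rcov = rcov, epochs = epochs,
       patience = patience, val_frac = val_frac)
}

#' Fit an LSTM velocity decoder
#'
#' Single LSTM layer plus a linear readout to `[vx, vy]`, trained per-trial
#' (each trial is one sequence, hidden and cell state starting at zero) with
#' squared-error loss and Adam (gradient decay 0.95, squared-gradient decay
#' 0.99); trial order is reshuffled every epoch. The last `val_frac` of
#' training trials is held out for early stopping on the validation-loss
#' plateau.
#'
#' @param Y_train bins x p representation matrix.
#' @param X_train bins x >=2 kinematics (first two columns are decoded).
#' @param trial_of_bin trial index per bin.
#' @param theta an [lstm_theta()].
#' @param seed RNG seed (weights and shuffling).
#' @return a `canokin_lstm`: `par` (all gate weights), `theta`,
#'   `loss_trace` (per-epoch training loss), `val_trace`, `epochs_run`.
#' @export
fit_lstm <- function(Y_train, X_train, trial_of_bin, theta = lstm_theta(),
                     seed = 1) {
  Y_train <- as.matrix(Y_train); X_train <- as.matrix(X_train)
  seqs <- split_sequences(Y_train, X_train, trial_of_bin)
  n_seq <- length(seqs)
  n_val <- max(1L, floor(theta$val_frac * n_seq))
  if (n_seq < 3L) n_val <- 0L
  train_seqs <- if (n_val > 0) seqs[seq_len(n_seq - n_val)] else seqs
  val_seqs <- if (n_val > 0) seqs[seq.int(n_seq - n_val + 1L, n_seq)] else list()
  par <- lstm_init(ncol(Y_train), theta$nodes, derive_seed(seed, "lstm-init"))
  mstate <- lstm_flatten(par) * 0
  vstate <- mstate
  tstep <- 0L
  batch_loss <- function(pk, seq_set) {
    if (!length(seq_set)) return(NA_real_)
    pk2 <- pack_sequences(seq_set, ncol(Y_train))
    fw <- lstm_forward(pk, pk2$Y)
    err <- (fw$pred - pk2$X) * array(pk2$mask, dim(fw$pred))
    sum(err^2) / (2 * sum(pk2$mask))
  }
  loss_trace <- numeric(0); val_trace <- numeric(0)
  best_val <- Inf; best_par <- par; stall <- 0L
  with_seed(derive_seed(seed, "lstm-train"), {
    for (ep in seq_len(theta$epochs)) {
      ord <- sample.int(length(train_seqs))
      ep_loss <- 0; ep_n <- 0
      for (start in seq(1, length(ord), by = theta$batch)) {
        take <- ord[start:min(start + theta$batch - 1L, length(ord))]
        pk <- pack_sequences(train_seqs[take], ncol(Y_train))
        fw <- lstm_forward(par, pk$Y)
        err <- (fw$pred - pk$X) * array(pk$mask, dim(fw$pred))
        denom <- sum(pk$mask)
        dPred <- err / denom
        if (!all(is.finite(err)))
          stop("LSTM training diverged (non-finite loss)", call. = FALSE)
        g <- lstm_backward(par, pk$Y, fw, dPred, pk$mask)
        gv <- lstm_flatten(g) + theta$rcov * lstm_flatten(par)
        tstep <- tstep + 1L
        mstate <- 0.95 * mstate + 0.05 * gv
        vstate <- 0.99 * vstate + 0.01 * gv^2
        mh <- mstate / (1 - 0.95^tstep)
        vh <- vstate / (1 - 0.99^tstep)
        pv <- lstm_flatten(par) - theta$lr * mh / (sqrt(vh) + 1e-8)
        par <- lstm_unflatten_like(par, pv)
        ep_loss <- ep_loss + sum(err^2) / 2
        ep_n <- ep_n + denom
      }
      loss_trace <- c(loss_trace, ep_loss / ep_n)
      if (n_val > 0) {
        vl <- batch_loss(par, val_seqs)
        val_trace <- c(val_trace, vl)
        if (vl < best_val * (1 - 1e-3)) {
          best_val <- vl; best_par <- par; stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= theta$patience) break
        }
      }
    }
  })
  if (n_val > 0) par <- best_par
  structure(list(par = par, theta = theta, loss_trace = loss_trace,
                 val_trace = val_trace, epochs_run = length(loss_trace),
                 seed = seed),
            class = "canokin_lstm")
}

#' Run a fitted LSTM decoder
#'
#' Stateful per-trial forward pass: hidden and cell state reset to zero at
#' each trial start. Purely causal.
#'
#' @param model a `canokin_lstm`.
#' @param Y_test bins x p representation matrix.
#' @param trial_of_bin trial index per bin; NULL treats all bins as one
#'   sequence.
#' @return bins x 2 matrix of `[vx, vy]` predictions.
#' @export
run_lstm <- function(model, Y_test, trial_of_bin = NULL) {
  Y_test <- as.matrix(Y_test)
  if (ncol(Y_test) != model$par$n_in)
    stop("representation width differs from training", call. = FALSE)
  n <- nrow(Y_test)
  if (is.null(trial_of_bin)) trial_of_bin <- rep(1L, n)
  out <- matrix(0, n, 2)
  for (s in split_sequences(Y_test, NULL, trial_of_bin)) {
    rows <- which(trial_of_bin == s$id)
    pk <- array(0, c(nrow(s$Y), 1, ncol(Y_test)))
    pk[, 1, ] <- s$Y
    fw <- lstm_forward(model$par, pk)
    out[rows, ] <- matrix(fw$pred[, 1, ], length(rows))
  }
  out
}
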