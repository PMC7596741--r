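# Deep canonical correlation analysis: two feedforward networks (one per
# view) trained by minibatch gradient ascent on the total canonical
# correlation of their outputs — the sum of singular values of the
# rcov-regularised whitened cross-covariance — minus an autoencoder
# reconstruction penalty (trade-off lambda) and L2 weight decay. Hidden
# layers are logistic sigmoid, output layers linear, output width fixed to
# the number of kinematic variables (3). A final linear CCA on the network
# outputs supplies the canonical rotation.

# ---- small feedforward net primitives ----------------------------------

# sizes: c(in, hidden..., out). Hidden layers use `act`; output layer linear.
net_init <- function(sizes, act = "sigmoid", seed = 1) {
  L <- length(sizes) - 1L
  with_seed(seed, {
    W <- lapply(seq_len(L), function(l) {
      matrix(stats::rnorm(sizes[l + 1] * sizes[l],
                          sd = 1 / sqrt(sizes[l])), sizes[l + 1], sizes[l])
    })
    b <- lapply(seq_len(L), function(l) rep(0, sizes[l + 1]))
    list(W = W, b = b, act = act, sizes = sizes)
  })
}

net_act <- function(x, act) if (act == "sigmoid") logistic(x) else x

net_act_grad <- function(a, act) if (act == "sigmoid") a * (1 - a) else 1

# Forward pass on rows-as-samples input; returns all layer activations
# (acts[[1]] is the input, acts[[L+1]] the linear output).
net_forward <- function(net, A0) {
  L <- length(net$W)
  acts <- vector("list", L + 1L)
  acts[[1]] <- A0
  for (l in seq_len(L)) {
    pre <- sweep(acts[[l]] %*% t(net$W[[l]]), 2L, net$b[[l]], "+")
    acts[[l + 1]] <- if (l < L) net_act(pre, net$act) else pre
  }
  acts
}

# Backward pass: dOut is dLoss/dOutput (N x out). Returns weight/bias grads
# and dLoss/dInput for chaining.
net_backward <- function(net, acts, dOut) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dOut
  for (l in L:1) {
    gW[[l]] <- crossprod(delta, acts[[l]])
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% net$W[[l]]) * net_act_grad(acts[[l]], net$act)
    } else {
      delta <- delta %*% net$W[[l]]
    }
  }
  list(gW = gW, gb = gb, dInput = delta)
}

# Adam state handling for a list-of-matrices parameter set.
adam_init <- function(net) {
  list(W = lapply(net$W, function(p) p * 0),
       b = lapply(net$b, function(p) p * 0))
}

adam_step <- function(params, grads, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(params$W)) {
    for (nm in c("W", "b")) {
      g <- grads[[nm]][[i]]
      m[[nm]][[i]] <- beta1 * m[[nm]][[i]] + (1 - beta1) * g
      v[[nm]][[i]] <- beta2 * v[[nm]][[i]] + (1 - beta2) * g^2
      mhat <- m[[nm]][[i]] / (1 - beta1^t)
      vhat <- v[[nm]][[i]] / (1 - beta2^t)
      params[[nm]][[i]] <- params[[nm]][[i]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, m = m, v = v)
}

# ---- correlation objective ---------------------------------------------

# Total canonical correlation of two output batches (rows = samples) and its
# gradient with respect to each (raw, uncentred) output matrix.
# rcov_{1,2} are the per-view covariance ridges.
cca_corr_grad <- function(H1, H2, rcov1, rcov2, want_grad = TRUE) {
  N <- nrow(H1)
  k <- ncol(H1)
  H1c <- scale(H1, scale = FALSE)
  H2c <- scale(H2, scale = FALSE)
  S11 <- crossprod(H1c) / (N - 1) + diag(rcov1, k)
  S22 <- crossprod(H2c) / (N - 1) + diag(rcov2, k)
  S12 <- crossprod(H1c, H2c) / (N - 1)
  W1 <- mat_inv_sqrt(S11)
  W2 <- mat_inv_sqrt(S22)
  Tm <- W1 %*% S12 %*% W2
  sv <- svd(Tm)
  corr <- sum(sv$d)
  if (!want_grad) return(list(corr = corr))
  UDU <- sv$u %*% (sv$d * t(sv$u))
  VDV <- sv$v %*% (sv$d * t(sv$v))
  D11 <- -0.5 * W1 %*% UDU %*% W1
  D22 <- -0.5 * W2 %*% VDV %*% W2
  D12 <- W1 %*% sv$u %*% t(sv$v) %*% W2
  G1 <- (2 * H1c %*% D11 + H2c %*% t(D12)) / (N - 1)
  G2 <- (2 * H2c %*% D22 + H1c %*% D12) / (N - 1)
  # outputs enter only through centred values: project out the column means
  G1 <- sweep(G1, 2L, colMeans(G1), "-")
  G2 <- sweep(G2, 2L, colMeans(G2), "-")
  list(corr = corr, G1 = G1, G2 = G2)
}

# ---- denoising autoencoder pretraining ---------------------------------

#' Layerwise denoising-autoencoder pretraining
#'
#' Initialises a stack of sigmoid encoder layers by training each layer, in
#' turn, as a one-hidden-layer denoising autoencoder: the layer input is
#' corrupted by masking a fraction of entries to zero, encoded through the
#' sigmoid layer, linearly decoded, and trained to reconstruct the clean
#' input by squared-error minibatch Adam.
#'
#' @param view_data samples x features matrix (already standardised).
#' @param layer_sizes hidden widths, outermost first.
#' @param noise_frac masking probability in [0, 1), default 0.2.
#' @param epochs passes per layer, default 5.
#' @param batch minibatch size, default 64.
#' @param lr learning rate, default 1e-2.
#' @param seed RNG seed (weights, masks, shuffling).
#' @return list with `W`, `b` (one entry per hidden layer) and
#'   `recon_loss` (initial and final reconstruction loss per layer).
#' @export
pretrain_dae <- function(view_data, layer_sizes, noise_frac = 0.2, epochs = 5,
                         batch = 64, lr = 1e-2, seed = 1) {
  A <- as.matrix(view_data)
  W <- list(); b <- list()
  losses <- matrix(NA_real_, length(layer_sizes), 2,
                   dimnames = list(NULL, c("initial", "final")))
  for (li in seq_along(layer_sizes)) {
    h <- layer_sizes[li]
    net <- net_init(c(ncol(A), h, ncol(A)), act = "sigmoid",
                    seed = derive_seed(seed, paste0("dae", li)))
    st <- adam_init(net)
    mv <- list(m = st, v = st)
    tstep <- 0L
    recon_loss <- function(nn) {
      out <- net_forward(nn, A)[[3]]
      mean((out - A)^2)
    }
    losses[li, 1] <- recon_loss(net)
    with_seed(derive_seed(seed, paste0("dae-run", li)), {
      for (ep in seq_len(epochs)) {
        idx <- sample.int(nrow(A))
        for (start in seq(1, length(idx), by = batch)) {
          rows <- idx[start:min(start + batch - 1L, length(idx))]
          if (length(rows) < 2) next
          clean <- A[rows, , drop = FALSE]
          corrupt <- clean
          if (noise_frac > 0) {
            mask <- matrix(stats::runif(length(clean)) < noise_frac,
                           nrow(clean))
            corrupt[mask] <- 0
          }
          acts <- net_forward(net, corrupt)
          dOut <- 2 * (acts[[3]] - clean) / length(clean)
          gr <- net_backward(net, acts, dOut)
          tstep <- tstep + 1L
          upd <- adam_step(net, list(W = gr$gW, b = gr$gb), mv$m, mv$v, lr, tstep)
          net$W <- upd$params$W; net$b <- upd$params$b
          mv <- list(m = upd$m, v = upd$v)
        }
      }
    })
    losses[li, 2] <- recon_loss(net)
    W[[li]] <- net$W[[1]]; b[[li]] <- net$b[[1]]
    A <- net_forward(net, A)[[2]]  # feed encoded layer to the next DAE
  }
  list(W = W, b = b, recon_loss = losses)
}

# ---- hyperparameter container ------------------------------------------

#' Deep CCA hyperparameters
#'
#' Assembles (and optionally range-checks) the hyperparameter set: per-view
#' hidden width and depth, per-view covariance regularisation (rcov),
#' encoder/autoencoder batch sizes, learning rate, L2 weight decay, and the
#' trade-off parameter `lambda` weighting the autoencoder reconstruction
#' penalty against the correlation objective.
#'
#' @param nodes_z,layers_z,rcov_z neural-view architecture and ridge.
#' @param nodes_x,layers_x,rcov_x kinematic-view architecture and ridge.
#' @param batch minibatch size for correlation updates.
#' @param batch_ae minibatch size for DAE pretraining.
#' @param lr learning rate (eta).
#' @param l2 L2 weight-decay coefficient.
#' @param lambda reconstruction trade-off.
#' @param epochs training epochs, default 60.
#' @param pretrain_epochs DAE passes per layer, default 5.
#' @param activation `"sigmoid"` (default) or `"identity"` (linear network,
#'   used to check the linear-CCA limit).
#' @param strict if TRUE, reject values outside the published search ranges
#'   (nodes 2^4..2^10, layers 1..4, batches 2^5..2^8, lr 1e-5..1e-2, rcov /
#'   L2 / lambda 1e-6..1e-1).
#' @return validated list of class `canokin_dcca_theta`.
#' @export
dcca_theta <- function(nodes_z = 64, layers_z = 2, rcov_z = 1e-2,
                       nodes_x = 32, layers_x = 2, rcov_x = 1e-2,
                       batch = 128, batch_ae = 64, lr = 1e-3, l2 = 1e-4,
                       lambda = 1e-2, epochs = 60, pretrain_epochs = 5,
                       activation = c("sigmoid", "identity"),
                       strict = FALSE) {
  activation <- match.arg(activation)
  th <- list(nodes_z = nodes_z, layers_z = layers_z, rcov_z = rcov_z,
             nodes_x = nodes_x, layers_x = layers_x, rcov_x = rcov_x,
             batch = batch, batch_ae = batch_ae, lr = lr, l2 = l2,
             lambda = lambda, epochs = epochs,
             pretrain_epochs = pretrain_epochs, activation = activation)
  if (any(vapply(th[c("rcov_z", "rcov_x")], function(v) v < 0, logical(1))))
    stop("rcov must be non-negative", call. = FALSE)
  if (th$layers_z < 1 || th$layers_x < 1 || th$layers_z > 10 || th$layers_x > 10)
    stop("layer counts out of range", call. = FALSE)
  if (strict) {
    chk <- function(v, lo, hi, nm) {
      if (v < lo || v > hi)
        stop(sprintf("%s = %g outside search range [%g, %g]", nm, v, lo, hi),
             call. = FALSE)
    }
    chk(nodes_z, 2^4, 2^10, "nodes_z"); chk(nodes_x, 2^4, 2^10, "nodes_x")
    chk(layers_z, 1, 4, "layers_z"); chk(layers_x, 1, 4, "layers_x")
    chk(batch, 2^5, 2^8, "batch"); chk(batch_ae, 2^5, 2^8, "batch_ae")
    chk(lr, 1e-5, 1e-2, "lr")
    chk(rcov_z, 1e-6, 1e-1, "rcov_z"); chk(rcov_x, 1e-6, 1e-1, "rcov_x")
    chk(l2, 1e-6, 1e-1, "l2"); chk(lambda, 1e-6, 1e-1, "lambda")
  }
  structure(th, class = "canokin_dcca_theta")
}

# ---- DCCA training ------------------------------------------------------

#' Fit a deep CCA between firing rates and kinematics
#'
#' Both views are standardised with training statistics and passed through
#' per-view feedforward networks (sigmoid hidden layers, linear 3-unit
#' output). Encoder layers are initialised by denoising-autoencoder
#' pretraining; mirrored decoders supply the reconstruction penalty. Training
#' maximises, by minibatch Adam, the total canonical correlation of the two
#' output batches (rcov-ridged whitening, trace norm) minus
#' `lambda * (reconstruction MSE of both views)` and L2 weight decay. The
#' full-training-set objective is recorded each epoch. A linear CCA fitted on
#' the final network outputs supplies the canonical rotation and training
#' correlations.
#'
#' @param Z_train bins x m neural matrix.
#' @param X_train bins x 3 kinematic matrix.
#' @param theta a [dcca_theta()].
#' @param seed master seed for initialisation, pretraining, masking and
#'   minibatch order.
#' @param k number of canonical pairs (output width), default
#'   `min(ncol(Z_train), ncol(X_train))`, i.e. 3 in the standard pipeline.
#' @param n_restarts number of independent initialisations; the run with the
#'   highest final training objective is kept. Default 1.
#' @return a `canokin_dcca`: networks `net_z`, `net_x`, decoders, input
#'   standardisation, output-layer CCA rotation (`out_cca`), per-epoch
#'   `objective_trace`, training `rho`, `theta`, `seed`.
#' @export
fit_dcca <- function(Z_train, X_train, theta = dcca_theta(), seed = 1,
                     k = NULL, n_restarts = 1) {
  if (n_restarts > 1) {
    runs <- lapply(seq_len(n_restarts), function(r) {
      fit_dcca(Z_train, X_train, theta,
               seed = derive_seed(seed, paste0("restart", r)), k = k)
    })
    scores <- vapply(runs, function(m)
      m$objective_trace[length(m$objective_trace)], numeric(1))
    best <- runs[[which.max(scores)]]
    best$seed <- seed
    return(best)
  }
  Z_train <- as.matrix(Z_train); X_train <- as.matrix(X_train)
  N <- nrow(Z_train)
  if (N != nrow(X_train)) stop("views must have equal rows", call. = FALSE)
  if (is.null(k)) k <- min(ncol(Z_train), ncol(X_train))
  std <- function(M) {
    mu <- colMeans(M); sd <- apply(M, 2, stats::sd)
    sd[sd < 1e-12] <- 1
    list(M = sweep(sweep(M, 2, mu, "-"), 2, sd, "/"), mu = mu, sd = sd)
  }
  sz <- std(Z_train); sx <- std(X_train)
  sizes_z <- c(ncol(Z_train), rep(theta$nodes_z, theta$layers_z), k)
  sizes_x <- c(ncol(X_train), rep(theta$nodes_x, theta$layers_x), k)
  net_z <- net_init(sizes_z, theta$activation, derive_seed(seed, "net_z"))
  net_x <- net_init(sizes_x, theta$activation, derive_seed(seed, "net_x"))
  if (theta$activation == "sigmoid" && theta$pretrain_epochs > 0) {
    for (side in c("z", "x")) {
      dat <- if (side == "z") sz$M else sx$M
      hid <- if (side == "z") rep(theta$nodes_z, theta$layers_z)
             else rep(theta$nodes_x, theta$layers_x)
      pre <- pretrain_dae(dat, hid, epochs = theta$pretrain_epochs,
                          batch = theta$batch_ae,
                          seed = derive_seed(seed, paste0("dae-", side)))
      for (l in seq_along(pre$W)) {
        if (side == "z") { net_z$W[[l]] <- pre$W[[l]]; net_z$b[[l]] <- pre$b[[l]] }
        else { net_x$W[[l]] <- pre$W[[l]]; net_x$b[[l]] <- pre$b[[l]] }
      }
    }
  }
  # decoders mirror the encoders (for the reconstruction penalty)
  dec_z <- net_init(rev(sizes_z), theta$activation, derive_seed(seed, "dec_z"))
  dec_x <- net_init(rev(sizes_x), theta$activation, derive_seed(seed, "dec_x"))
  nets <- list(net_z = net_z, net_x = net_x, dec_z = dec_z, dec_x = dec_x)
  adam <- lapply(nets, function(nn) list(m = adam_init(nn), v = adam_init(nn)))
  tstep <- 0L
  full_objective <- function() {
    H1 <- net_forward(nets$net_z, sz$M)[[length(nets$net_z$W) + 1]]
    H2 <- net_forward(nets$net_x, sx$M)[[length(nets$net_x$W) + 1]]
    cca_corr_grad(H1, H2, theta$rcov_z, theta$rcov_x, want_grad = FALSE)$corr
  }
  trace <- numeric(theta$epochs + 1)
  trace[1] <- full_objective()
  with_seed(derive_seed(seed, "train"), {
    for (ep in seq_len(theta$epochs)) {
      idx <- sample.int(N)
      for (start in seq(1, N, by = theta$batch)) {
        rows <- idx[start:min(start + theta$batch - 1L, N)]
        if (length(rows) <= k + 1) next
        Zb <- sz$M[rows, , drop = FALSE]
        Xb <- sx$M[rows, , drop = FALSE]
        az <- net_forward(nets$net_z, Zb)
        ax <- net_forward(nets$net_x, Xb)
        Lz <- length(nets$net_z$W); Lx <- length(nets$net_x$W)
        cg <- cca_corr_grad(az[[Lz + 1]], ax[[Lx + 1]],
                            theta$rcov_z, theta$rcov_x)
        if (!is.finite(cg$corr))
          stop("DCCA objective became non-finite; increase rcov", call. = FALSE)
        # maximise corr => descend on -corr
        dH1 <- -cg$G1; dH2 <- -cg$G2
        grad_recon <- function(enc_acts, dec, clean) {
          code <- enc_acts[[length(enc_acts)]]
          dacts <- net_forward(dec, code)
          out <- dacts[[length(dec$W) + 1]]
          dOut <- 2 * (out - clean) / length(clean)
          gr_dec <- net_backward(dec, dacts, dOut)
          list(gr_dec = gr_dec, dCode = gr_dec$dInput,
               mse = mean((out - clean)^2))
        }
        gz_rec <- grad_recon(az, nets$dec_z, Zb)
        gx_rec <- grad_recon(ax, nets$dec_x, Xb)
        gr_z <- net_backward(nets$net_z, az,
                             dH1 + theta$lambda * gz_rec$dCode)
        gr_x <- net_backward(nets$net_x, ax,
                             dH2 + theta$lambda * gx_rec$dCode)
        tstep <- tstep + 1L
        upd1 <- list(W = gr_z$gW, b = gr_z$gb)
        upd2 <- list(W = gr_x$gW, b = gr_x$gb)
        updd1 <- list(W = lapply(gz_rec$gr_dec$gW, function(g) theta$lambda * g),
                      b = lapply(gz_rec$gr_dec$gb, function(g) theta$lambda * g))
        updd2 <- list(W = lapply(gx_rec$gr_dec$gW, function(g) theta$lambda * g),
                      b = lapply(gx_rec$gr_dec$gb, function(g) theta$lambda * g))
        all_upd <- list(net_z = upd1, net_x = upd2, dec_z = updd1,
                        dec_x = updd2)
        for (nm in names(nets)) {
          gr <- all_upd[[nm]]
          # L2 weight decay on weights only
          gr$W <- lapply(seq_along(gr$W), function(i)
            gr$W[[i]] + theta$l2 * nets[[nm]]$W[[i]])
          st <- adam_step(nets[[nm]], gr, adam[[nm]]$m, adam[[nm]]$v,
                          theta$lr, tstep)
          nets[[nm]]$W <- st$params$W; nets[[nm]]$b <- st$params$b
          adam[[nm]] <- list(m = st$m, v = st$v)
        }
      }
      trace[ep + 1] <- full_objective()
    }
  })
  H1 <- net_forward(nets$net_z, sz$M)[[length(nets$net_z$W) + 1]]
  H2 <- net_forward(nets$net_x, sx$M)[[length(nets$net_x$W) + 1]]
  # final rotation uses a minimal stabilising ridge (not rcov) so the stored
  # training correlations equal the empirical ones of the projections
  out_cca <- NULL
  for (rg in c(1e-8, 1e-6, 1e-4)) {
    out_cca <- tryCatch(fit_lcca(H1, H2, ridge = rg), error = function(e) NULL)
    if (!is.null(out_cca)) break
  }
  if (is.null(out_cca))
    stop("network outputs are degenerate; increase rcov", call. = FALSE)
  structure(list(net_z = nets$net_z, net_x = nets$net_x,
                 dec_z = nets$dec_z, dec_x = nets$dec_x,
                 std_z = sz[c("mu", "sd")], std_x = sx[c("mu", "sd")],
                 out_cca = out_cca, rho = out_cca$rho,
                 objective_trace = trace, theta = theta, seed = seed, k = k),
            class = "canokin_dcca")
}

#' Project data onto deep canonical variables
#'
#' Standardises each view with the training statistics, applies the fitted
#' network, and rotates the outputs by the output-layer CCA, yielding Z_DCV
#' and X_DCV.
#'
#' @param model a `canokin_dcca`.
#' @param Z,X matrices (either may be NULL).
#' @return list with `Z_cv`, `X_cv`.
#' @export
transform_dcca <- function(model, Z = NULL, X = NULL) {
  run_side <- function(M, std, net) {
    M <- sweep(sweep(as.matrix(M), 2, std$mu, "-"), 2, std$sd, "/")
    net_forward(net, M)[[length(net$W) + 1]]
  }
  H1 <- if (!is.null(Z)) run_side(Z, model$std_z, model$net_z) else NULL
  H2 <- if (!is.null(X)) run_side(X, model$std_x, model$net_x) else NULL
  tf <- transform_lcca(model$out_cca, Z = H1, X = H2)
  list(Z_cv = tf$Z_cv, X_cv = tf$X_cv)
}

#' Total canonical correlation of two views under a fitted model
#'
#' Convenience wrapper: transforms both views and sums the per-pair Pearson
#' correlations of the canonical variables.
#'
#' @param model a `canokin_lcca` or `canokin_dcca`.
#' @param Z,X data matrices.
#' @return scalar total correlation.
#' @export
total_correlation <- function(model, Z, X) {
  tf <- if (inherits(model, "canokin_dcca")) transform_dcca(model, Z, X)
        else transform_lcca(model, Z, X)
  sum(canonical_correlations(tf$Z_cv, tf$X_cv))
}

#' @export
invert_kinematic_map.canokin_dcca <- function(model, X_cv, eps = 1e-6) {
  # undo the output CCA rotation (centred in output space)
  oc <- model$out_cca
  Binv <- if (nrow(oc$beta) == ncol(oc$beta)) solve(t(oc$beta))
          else MASS::ginv(t(oc$beta))
  O <- sweep(X_cv %*% t(Binv), 2L, oc$mean_x, "+")
  net <- model$net_x
  L <- length(net$W)
  U <- O
  for (l in L:1) {
    U <- sweep(U, 2L, net$b[[l]], "-")
    Wl <- net$W[[l]]
    Winv <- if (nrow(Wl) == ncol(Wl)) solve(Wl) else MASS::ginv(Wl)
    U <- U %*% t(Winv)
    if (l > 1 && net$act == "sigmoid") {
      # the next inversion target is a sigmoid activation: apply logit
      U <- logit(U, eps = eps)
    }
  }
  sweep(sweep(U, 2L, model$std_x$sd, "*"), 2L, model$std_x$mu, "+")
}

#' Budgeted random search over deep CCA hyperparameters
#'
#' Samples hyperparameter sets uniformly from the published search grid
#' (nodes 2^4..2^10, layers 1..4, batch sizes 2^5..2^8, learning rate
#' 1e-5..1e-2, rcov / L2 / lambda 1e-6..1e-1), trains each on an inner
#' 80/20 chronological split of the training bins, and returns the set with
#' the highest inner-validation total correlation. Deterministic given the
#' seed.
#'
#' @param Z,X training matrices.
#' @param space named list of candidate vectors overriding any dimension of
#'   the default grid (a single-element vector pins that dimension).
#' @param budget number of sampled configurations, default 50.
#' @param seed RNG seed.
#' @param epochs training epochs per candidate (kept small during search).
#' @return list with `theta` (best [dcca_theta()]), `score` (its validation
#'   total correlation) and `trace` (data.frame of all candidates).
#' @export
search_hyperparams <- function(Z, X, space = list(), budget = 50, seed = 1,
                               epochs = 20) {
  if (budget < 1) stop("budget must be at least 1", call. = FALSE)
  grid <- utils::modifyList(list(
    nodes_z = 2^(4:10), layers_z = 1:4, rcov_z = 10^(-6:-1),
    nodes_x = 2^(4:10), layers_x = 1:4, rcov_x = 10^(-6:-1),
    batch = 2^(5:8), batch_ae = 2^(5:8), lr = 10^(-5:-2),
    l2 = 10^(-6:-1), lambda = 10^(-6:-1)), space)
  if (any(!lengths(grid))) stop("empty search space", call. = FALSE)
  n <- nrow(Z)
  n_in <- floor(0.8 * n)
  Zi <- Z[seq_len(n_in), , drop = FALSE]; Xi <- X[seq_len(n_in), , drop = FALSE]
  Zv <- Z[-seq_len(n_in), , drop = FALSE]; Xv <- X[-seq_len(n_in), , drop = FALSE]
  rows <- list(); best <- NULL; best_score <- -Inf
  for (i in seq_len(budget)) {
    draw <- with_seed(derive_seed(seed, paste0("hp", i)), {
      lapply(grid, function(v) v[sample.int(length(v), 1)])
    })
    th <- dcca_theta(nodes_z = draw$nodes_z, layers_z = draw$layers_z,
                     rcov_z = draw$rcov_z, nodes_x = draw$nodes_x,
                     layers_x = draw$layers_x, rcov_x = draw$rcov_x,
                     batch = draw$batch, batch_ae = draw$batch_ae,
                     lr = draw$lr, l2 = draw$l2, lambda = draw$lambda,
                     epochs = epochs, pretrain_epochs = 2)
    score <- tryCatch({
      fit <- fit_dcca(Zi, Xi, th, seed = derive_seed(seed, paste0("fit", i)))
      total_correlation(fit, Zv, Xv)
    }, error = function(e) NA_real_)
    rows[[i]] <- data.frame(i = i, as.data.frame(draw), score = score)
    if (is.finite(score) && score > best_score) {
      best_score <- score; best <- th
    }
  }
  if (is.null(best)) stop("no hyperparameter candidate trained successfully",
                          call. = FALSE)
  list(theta = best, score = best_score, trace = do.call(rbind, rows))
}
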