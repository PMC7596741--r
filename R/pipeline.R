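# End-to-end orchestration: simulate/load -> preprocess -> represent ->
# decode -> evaluate, from a single config, with per-stage seeds derived
# from one master seed and a hashed artifact manifest.

#' Normalise and validate a pipeline configuration
#'
#' Fills defaults (50-ms bins, 80-ms smoothing, r2 threshold 0.01, 75/25
#' chronological split, all six representations, both decoder families) and
#' checks ranges. Deep-CCA node counts outside the published search range
#' are rejected when `strict = TRUE`.
#'
#' @param config named list; any subset of `session`, `preprocess`,
#'   `representations`, `latent`, `dcca`, `lstm`, `decoders`, `seed`,
#'   `out_dir`.
#' @param strict enforce hyperparameter search ranges, default FALSE.
#' @return the normalised config (class `canokin_config`).
#' @export
validate_config <- function(config = list(), strict = FALSE) {
  defaults <- list(
    session = list(synthetic = synth_config()),
    preprocess = list(bin_ms = 50, smooth_sd_ms = 80, r2_threshold = 0.01,
                      train_frac = 0.75),
    representations = c("efr", "pca", "fa", "lds", "lcca", "dcca"),
    latent = list(q_pca = 5, q_fa = 20, q_lds = 20),
    dcca = list(),
    dcca_restarts = 1,
    lstm = list(),
    decoders = c("linear", "lstm"),
    seed = 1,
    out_dir = NULL
  )
  cfg <- utils::modifyList(defaults, config)
  if (cfg$preprocess$bin_ms <= 0) stop("bin_ms must be positive", call. = FALSE)
  if (cfg$preprocess$smooth_sd_ms < 0) stop("smooth_sd_ms must be >= 0", call. = FALSE)
  if (cfg$preprocess$train_frac <= 0 || cfg$preprocess$train_frac >= 1)
    stop("train_frac must be in (0, 1)", call. = FALSE)
  known <- c("efr", "pca", "fa", "lds", "lcca", "dcca")
  bad <- setdiff(cfg$representations, known)
  if (length(bad))
    stop("unknown representation(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!all(cfg$decoders %in% c("linear", "lstm")))
    stop("decoders must be a subset of {linear, lstm}", call. = FALSE)
  if (!is.null(cfg$session$file) && !file.exists(cfg$session$file))
    stop("session file does not exist: ", cfg$session$file, call. = FALSE)
  cfg$dcca_theta <- do.call(dcca_theta, c(cfg$dcca, list(strict = strict)))
  cfg$lstm_theta <- do.call(lstm_theta, cfg$lstm)
  structure(cfg, class = "canokin_config")
}

#' Run the full decoding pipeline
#'
#' Builds (or loads) a session, applies the fixed preprocessing chain with
#' tuning-based unit selection on the training trials, fits each requested
#' neural representation on the training set, decodes held-out velocity with
#' the linear family (steady-state Kalman filter; neural dynamical filter
#' for LDS states) and/or an LSTM, and evaluates per-trial errors,
#' correlations and reconstructed positions. PCA scores are re-smoothed
#' before decoding. When `out_dir` is set, predictions and summary tables
#' are written as CSV together with a JSON manifest of md5 hashes and seeds.
#'
#' @param config list accepted by [validate_config()].
#' @return a `canokin_result` list: `config`, `selected_units`,
#'   `representations` (per name: train/test series and tuning r2),
#'   `decodings` (per representation x decoder: predictions, per-trial
#'   velocity and position errors, correlations), `error_tables`,
#'   `comparisons` (Friedman + post-hoc per decoder), `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "canokin_config")) config else validate_config(config)
  seed <- cfg$seed
  # --- session ----------------------------------------------------------
  gt <- NULL
  if (!is.null(cfg$session$file)) {
    session <- read_session(cfg$session$file)
  } else {
    sim <- make_synthetic_session(cfg$session$synthetic,
                                  seed = derive_seed(seed, "simulate"))
    session <- sim$session
    gt <- sim$ground_truth
  }
  # --- preprocess -------------------------------------------------------
  bin_s <- cfg$preprocess$bin_ms / 1000
  bd <- preprocess_session(session, bin_s = bin_s,
                           smooth_sd_s = cfg$preprocess$smooth_sd_ms / 1000)
  split <- split_trials(session, cfg$preprocess$train_frac)
  tr <- subset_binned(bd, split$train_ids)
  te <- subset_binned(bd, split$test_ids)
  fits <- fit_population_tuning(tr$Z, tr$X)
  sel <- select_units(fits, cfg$preprocess$r2_threshold)
  Ztr <- tr$Z[, sel, drop = FALSE]; Zte <- te$Z[, sel, drop = FALSE]
  # --- representations --------------------------------------------------
  reps <- list()
  for (nm in cfg$representations) {
    reps[[nm]] <- switch(nm,
      efr = list(train = Ztr, test = Zte, model = NULL),
      pca = {
        mod <- fit_pca(Ztr)
        q <- min(cfg$latent$q_pca, mod$q)
        sm <- function(M) smooth_gaussian(M, cfg$preprocess$smooth_sd_ms / 1000,
                                          bin_s)
        list(train = sm(estimate_states(mod, Ztr, q = q)),
             test = sm(estimate_states(mod, Zte, q = q)), model = mod)
      },
      fa = {
        mod <- fit_fa(Ztr, min(cfg$latent$q_fa, ncol(Ztr) - 1L))
        list(train = estimate_states(mod, Ztr),
             test = estimate_states(mod, Zte), model = mod)
      },
      lds = {
        mod <- fit_lds(Ztr, min(cfg$latent$q_lds, ncol(Ztr) - 1L),
                       max_iter = 15)
        list(train = estimate_states(mod, Ztr),
             test = estimate_states(mod, Zte), model = mod)
      },
      lcca = {
        mod <- fit_lcca(Ztr, tr$X)
        tf_tr <- transform_lcca(mod, Ztr, tr$X)
        tf_te <- transform_lcca(mod, Zte, te$X)
        list(train = tf_tr$Z_cv, test = tf_te$Z_cv, model = mod,
             X_cv_train = tf_tr$X_cv, X_cv_test = tf_te$X_cv)
      },
      dcca = {
        mod <- fit_dcca(Ztr, tr$X, cfg$dcca_theta,
                        seed = derive_seed(seed, "dcca"),
                        n_restarts = cfg$dcca_restarts)
        tf_tr <- transform_dcca(mod, Ztr, tr$X)
        tf_te <- transform_dcca(mod, Zte, te$X)
        list(train = tf_tr$Z_cv, test = tf_te$Z_cv, model = mod,
             X_cv_train = tf_tr$X_cv, X_cv_test = tf_te$X_cv)
      })
    reps[[nm]]$tuning <- tuning_r2(reps[[nm]]$test, te$X)
  }
  # --- decode + evaluate ------------------------------------------------
  start_pos <- trial_start_positions(session, te$trial_of_bin, te$t)
  true_pos <- reconstruct_position(te$X[, 1:2], te$trial_of_bin, start_pos,
                                   bin_s)
  decodings <- list()
  for (nm in names(reps)) {
    for (dec in cfg$decoders) {
      key <- paste(nm, dec, sep = "_")
      pred <- if (dec == "linear") {
        if (nm == "lds") {
          ndf <- fit_ndf(reps[[nm]]$train, tr$X)
          run_ndf(ndf, reps[[nm]]$test)
        } else {
          lkf <- fit_lkf(tr$X, reps[[nm]]$train, tr$trial_of_bin)
          run_lkf(lkf, reps[[nm]]$test, te$trial_of_bin)
        }
      } else {
        lstm <- fit_lstm(reps[[nm]]$train, tr$X, tr$trial_of_bin,
                         cfg$lstm_theta,
                         seed = derive_seed(seed, paste0("lstm-", nm)))
        run_lstm(lstm, reps[[nm]]$test, te$trial_of_bin)
      }
      pos <- reconstruct_position(pred, te$trial_of_bin, start_pos, bin_s)
      decodings[[key]] <- list(
        representation = nm, decoder = dec, pred_v = pred,
        velocity_error = decoding_error(te$X[, 1:2], pred, te$trial_of_bin),
        position_error = decoding_error(true_pos, pos, te$trial_of_bin),
        correlations = correlation_metrics(te$X[, 1:2], pred,
                                           te$trial_of_bin))
    }
  }
  error_tables <- list()
  comparisons <- list()
  for (dec in cfg$decoders) {
    keys <- names(decodings)[vapply(decodings, function(d) d$decoder == dec,
                                    logical(1))]
    M <- vapply(keys, function(k) decodings[[k]]$velocity_error,
                numeric(length(split$test_ids)))
    colnames(M) <- vapply(keys, function(k) decodings[[k]]$representation,
                          character(1))
    error_tables[[dec]] <- M
    if (ncol(M) >= 2) comparisons[[dec]] <- compare_methods(M)
  }
  res <- structure(list(config = cfg, session_meta = session$meta,
                        split = split, selected_units = sel,
                        tuning_fits = fits, ground_truth = gt,
                        representations = reps, decodings = decodings,
                        error_tables = error_tables,
                        comparisons = comparisons,
                        test_kinematics = te),
                   class = "canokin_result")
  if (!is.null(cfg$out_dir)) res$manifest <- write_result(res, cfg$out_dir)
  res
}

#' Kalman-decoding error of raw rates vs linear vs deep canonical variables
#'
#' Runs the full pipeline on one strongly nonlinear benchmark session
#' ([nonlinear_benchmark_config()]) with the steady-state Kalman decoder and
#' returns the mean per-trial velocity error for the raw smoothed rates
#' (`efr`), the linear canonical variables (`lcca`) and the deep canonical
#' variables (`dcca`). Used to check that the error ordering
#' `dcca <= lcca <= efr` emerges when the population code saturates.
#'
#' @param seed master seed for the session and all model fits.
#' @param n_trials,n_units benchmark session size (defaults 200 / 30).
#' @param epochs deep-CCA training epochs, default 60.
#' @return named numeric vector with elements `efr`, `lcca`, `dcca` (cm/s).
#' @export
benchmark_lkf_ordering <- function(seed, n_trials = 200, n_units = 30,
                                   epochs = 60) {
  cfg <- list(
    session = list(synthetic = nonlinear_benchmark_config(n_trials, n_units)),
    representations = c("efr", "lcca", "dcca"),
    dcca = list(nodes_z = 32, layers_z = 2, nodes_x = 32, layers_x = 2,
                rcov_z = 1e-2, rcov_x = 1e-2, lr = 2e-3, epochs = epochs,
                batch = 128, pretrain_epochs = 2),
    dcca_restarts = 2,
    decoders = "linear",
    seed = seed)
  res <- run_pipeline(cfg)
  colMeans(res$error_tables$linear)[c("efr", "lcca", "dcca")]
}

# True start position of each test trial (hand position at the first hand
# sample inside the trial).
trial_start_positions <- function(session, trial_of_bin, t_bins) {
  ids <- unique(trial_of_bin)
  t(vapply(ids, function(id) {
    t0 <- session$trials$start_s[id]
    row <- which(session$hand$t >= t0 - 1e-9)[1]
    c(session$hand$x[row], session$hand$y[row])
  }, numeric(2)))
}

#' Export binned data as CSV
#'
#' One row per bin: time, trial, one column per unit, then vx, vy, speed.
#'
#' @param bd a `canokin_binned`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
export_binned_csv <- function(bd, path) {
  df <- data.frame(t = bd$t, trial = bd$trial_of_bin)
  Z <- as.data.frame(bd$Z)
  names(Z) <- sprintf("unit%03d", seq_len(ncol(bd$Z)))
  df <- cbind(df, Z, vx = bd$X[, 1], vy = bd$X[, 2], speed = bd$X[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Write result CSVs and a manifest with md5 hashes; returns the manifest.
write_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
    p
  }
  err_rows <- do.call(rbind, lapply(res$decodings, function(d) {
    data.frame(representation = d$representation, decoder = d$decoder,
               trial = names(d$velocity_error),
               velocity_error = unname(d$velocity_error),
               position_error = unname(d$position_error))
  }))
  wr(err_rows, "per_trial_errors.csv")
  summ <- do.call(rbind, lapply(res$decodings, function(d) {
    data.frame(representation = d$representation, decoder = d$decoder,
               velocity_error_mean = mean(d$velocity_error),
               velocity_error_sd = stats::sd(d$velocity_error),
               position_error_mean = mean(d$position_error),
               position_error_sd = stats::sd(d$position_error),
               r_x = d$correlations$trial_mean["x"],
               r_y = d$correlations$trial_mean["y"],
               r_x_sd = d$correlations$trial_sd["x"],
               r_y_sd = d$correlations$trial_sd["y"])
  }))
  wr(summ, "summary.csv")
  rho_rows <- do.call(rbind, lapply(names(res$representations), function(nm) {
    mod <- res$representations[[nm]]$model
    if (is.null(mod$rho)) return(NULL)
    data.frame(representation = nm, pair = seq_along(mod$rho), rho = mod$rho)
  }))
  if (!is.null(rho_rows)) wr(rho_rows, "canonical_correlations.csv")
  tun <- do.call(rbind, lapply(names(res$representations), function(nm) {
    tq <- res$representations[[nm]]$tuning
    data.frame(representation = nm, dim = tq$dim, r2 = tq$r2)
  }))
  wr(tun, "tuning_r2.csv")
  manifest <- list(
    seed = res$config$seed,
    session = res$session_meta,
    n_selected_units = length(res$selected_units),
    files = lapply(files, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' @export
print.canokin_result <- function(x, ...) {
  cat(sprintf("<canokin_result> %d representations x %d decoder families, %d test trials\n",
              length(x$representations), length(x$config$decoders),
              length(x$split$test_ids)))
  for (key in names(x$decodings)) {
    d <- x$decodings[[key]]
    cat(sprintf("  %-12s %-6s velocity error %.3f cm/s, position error %.3f cm\n",
                d$representation, d$decoder, mean(d$velocity_error),
                mean(d$position_error)))
  }
  invisible(x)
}
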