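# Decoding evaluation: tuning quality of representations, per-trial velocity
# error, position reconstruction by velocity integration, correlation
# metrics, and Friedman/Wilcoxon method comparisons.

#' Velocity-tuning quality of a representation
#'
#' Regresses each dimension of a neural representation on `[vx, vy, speed]`
#' by OLS and reports the goodness of fit. Constant dimensions get r2 = 0
#' and are flagged.
#'
#' @param R_series bins x q representation matrix.
#' @param X bins x 3 kinematic matrix.
#' @return data.frame with `dim`, `r2`, `constant`; attribute `mean_r2`.
#' @export
tuning_r2 <- function(R_series, X) {
  R_series <- as.matrix(R_series)
  if (nrow(R_series) != nrow(X)) stop("rows must align", call. = FALSE)
  rows <- lapply(seq_len(ncol(R_series)), function(j) {
    z <- R_series[, j]
    sst <- sum((z - mean(z))^2)
    if (sst < .Machine$double.eps)
      return(data.frame(dim = j, r2 = 0, constant = TRUE))
    fit <- stats::lm.fit(cbind(1, X[, 1:3]), z)
    data.frame(dim = j, r2 = max(0, 1 - sum(fit$residuals^2) / sst),
               constant = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_r2") <- mean(out$r2)
  out
}

#' Per-trial velocity decoding error
#'
#' The error of trial i is the mean over its bins of the Euclidean distance
#' between true and predicted velocity vectors.
#'
#' @param true_v,pred_v bins x 2 matrices.
#' @param trial_of_bin trial index per bin.
#' @return named numeric vector of per-trial errors (cm/s), one per trial in
#'   order of first appearance.
#' @export
decoding_error <- function(true_v, pred_v, trial_of_bin) {
  true_v <- as.matrix(true_v)[, 1:2, drop = FALSE]
  pred_v <- as.matrix(pred_v)[, 1:2, drop = FALSE]
  if (!all(dim(true_v) == dim(pred_v))) stop("shape mismatch", call. = FALSE)
  e_t <- sqrt(rowSums((true_v - pred_v)^2))
  ids <- unique(trial_of_bin)
  out <- vapply(ids, function(id) {
    rows <- trial_of_bin == id
    if (!any(rows)) stop("empty trial", call. = FALSE)
    mean(e_t[rows])
  }, numeric(1))
  names(out) <- ids
  out
}

#' Reconstruct position by integrating predicted velocity
#'
#' Within each trial, position is the trial's start position plus the
#' cumulative sum of predicted velocity times the bin width; integration
#' restarts at every trial boundary.
#'
#' @param pred_v bins x 2 velocity matrix (cm/s).
#' @param trial_of_bin trial index per bin.
#' @param start_positions matrix/data.frame with one `[x, y]` row per trial
#'   (in order of first appearance in `trial_of_bin`).
#' @param bin_s bin width (s).
#' @return bins x 2 matrix of reconstructed positions (cm).
#' @export
reconstruct_position <- function(pred_v, trial_of_bin, start_positions,
                                 bin_s = 0.05) {
  pred_v <- as.matrix(pred_v)
  start_positions <- as.matrix(start_positions)
  ids <- unique(trial_of_bin)
  if (nrow(start_positions) != length(ids))
    stop("need one start position per trial", call. = FALSE)
  out <- matrix(0, nrow(pred_v), 2)
  for (i in seq_along(ids)) {
    rows <- which(trial_of_bin == ids[i])
    out[rows, 1] <- start_positions[i, 1] + cumsum(pred_v[rows, 1]) * bin_s
    out[rows, 2] <- start_positions[i, 2] + cumsum(pred_v[rows, 2]) * bin_s
  }
  out
}

#' Per-axis correlation of true and decoded velocity
#'
#' @param true_v,pred_v bins x 2 matrices.
#' @param trial_of_bin optional trial index; when given, per-trial
#'   correlations are summarised as mean and SD per axis.
#' @return list with `overall` (length-2 vector, x and y axes) and, when
#'   trials are given, `per_trial` (data.frame) plus `trial_mean`,
#'   `trial_sd`.
#' @export
correlation_metrics <- function(true_v, pred_v, trial_of_bin = NULL) {
  true_v <- as.matrix(true_v); pred_v <- as.matrix(pred_v)
  overall <- c(x = stats::cor(true_v[, 1], pred_v[, 1]),
               y = stats::cor(true_v[, 2], pred_v[, 2]))
  out <- list(overall = overall)
  if (!is.null(trial_of_bin)) {
    ids <- unique(trial_of_bin)
    # axis-aligned reaches have zero variance on one axis: correlation is
    # undefined there, reported as NA and dropped from the summaries
    safe_cor <- function(a, b) {
      if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
      stats::cor(a, b)
    }
    per <- t(vapply(ids, function(id) {
      rows <- trial_of_bin == id
      c(safe_cor(true_v[rows, 1], pred_v[rows, 1]),
        safe_cor(true_v[rows, 2], pred_v[rows, 2]))
    }, numeric(2)))
    per <- data.frame(trial = ids, r_x = per[, 1], r_y = per[, 2])
    out$per_trial <- per
    out$trial_mean <- c(x = mean(per$r_x, na.rm = TRUE),
                        y = mean(per$r_y, na.rm = TRUE))
    out$trial_sd <- c(x = stats::sd(per$r_x, na.rm = TRUE),
                      y = stats::sd(per$r_y, na.rm = TRUE))
  }
  out
}

#' Compare methods on matched per-trial errors
#'
#' Friedman test for a main effect of method over trials (each trial is a
#' block), followed by post-hoc pairwise Wilcoxon signed-rank tests with
#' Bonferroni correction, and pairwise rank-sum statistics for unpaired
#' contrasts.
#'
#' @param error_table trials x methods matrix or data.frame of per-trial
#'   errors on an identical trial set (>= 2 columns).
#' @return list with `friedman` (statistic, df, p.value), `posthoc`
#'   (data.frame: method pair, signed-rank V, raw and Bonferroni-adjusted p)
#'   and `ranksum` (data.frame with rank-sum W and p per pair).
#' @export
compare_methods <- function(error_table) {
  M <- as.matrix(error_table)
  if (ncol(M) < 2) stop("need at least two methods", call. = FALSE)
  if (is.null(colnames(M))) colnames(M) <- paste0("method", seq_len(ncol(M)))
  if (anyNA(M)) stop("mismatched trial sets (NA errors)", call. = FALSE)
  fr <- stats::friedman.test(M)
  pairs <- utils::combn(colnames(M), 2)
  ph <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- M[, a] - M[, b]
    if (all(d == 0)) {
      w <- list(statistic = c(V = NA_real_), p.value = 1)
      rs <- list(statistic = c(W = NA_real_), p.value = 1)
    } else {
      w <- suppressWarnings(stats::wilcox.test(M[, a], M[, b], paired = TRUE))
      rs <- suppressWarnings(stats::wilcox.test(M[, a], M[, b]))
    }
    data.frame(method_a = a, method_b = b,
               V = unname(w$statistic), p = w$p.value,
               W = unname(rs$statistic), p_ranksum = rs$p.value)
  })
  ph <- do.call(rbind, ph)
  ph$p_bonferroni <- pmin(1, ph$p * nrow(ph))
  list(friedman = list(statistic = unname(fr$statistic),
                       df = unname(fr$parameter), p.value = fr$p.value),
       posthoc = ph[, c("method_a", "method_b", "V", "p", "p_bonferroni")],
       ranksum = ph[, c("method_a", "method_b", "W", "p_ranksum")])
}

#' Training-set decoding error of a representation/decoder chain
#'
#' Decodes the training set with the supplied decoder and reports the mean
#' absolute (Euclidean) velocity error, the quantity used to assess how well
#' a representation supports the decoder it trains.
#'
#' @param decoder a fitted decoder (`canokin_lkf`, `canokin_ndf` or
#'   `canokin_lstm`).
#' @param O_train training representation.
#' @param X_train training kinematics (first two columns = velocity).
#' @param trial_of_bin trial index per bin.
#' @return scalar mean absolute velocity error.
#' @export
training_error <- function(decoder, O_train, X_train, trial_of_bin) {
  pred <- if (inherits(decoder, "canokin_lkf")) {
    run_lkf(decoder, O_train, trial_of_bin)
  } else if (inherits(decoder, "canokin_ndf")) {
    run_ndf(decoder, O_train)
  } else if (inherits(decoder, "canokin_lstm")) {
    run_lstm(decoder, O_train, trial_of_bin)
  } else stop("unknown decoder class", call. = FALSE)
  mean(decoding_error(X_train[, 1:2, drop = FALSE], pred, trial_of_bin))
}
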