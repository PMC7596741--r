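# Spike-train preprocessing: 50-ms binning, square-root transform, Gaussian
# kernel smoothing, kinematic differentiation, cosine-tuning fits and
# r^2-thresholded unit selection. The pipeline order is fixed:
# bin -> sqrt -> smooth, with tuning fitted on the smoothed rates.

#' Bin spike trains into a count matrix
#'
#' Counts each unit's spikes in non-overlapping windows `[t_i, t_i + bin_s)`
#' spanning the session. Firing rates are counts divided by the bin width.
#'
#' @param session a `canokin_session`.
#' @param bin_s bin width in seconds, default 0.05 (50 ms).
#' @return list with `counts` (n_bins x n_units integer matrix), `t` (bin
#'   centres, s) and `bin_s`.
#' @export
bin_spikes <- function(session, bin_s = 0.05) {
  if (bin_s <= 0) stop("bin_s must be positive", call. = FALSE)
  dur <- session$meta$duration_s
  n_bins <- floor(dur / bin_s + 1e-9)
  if (n_bins < 1) stop("bin_s longer than the session", call. = FALSE)
  edges <- (0:n_bins) * bin_s
  counts <- vapply(session$units, function(st) {
    if (!length(st)) return(integer(n_bins))
    idx <- findInterval(st, edges, left.open = FALSE)
    idx <- idx[idx >= 1 & idx <= n_bins]
    tabulate(idx, nbins = n_bins)
  }, integer(n_bins))
  counts <- matrix(counts, nrow = n_bins)
  list(counts = counts, t = edges[-length(edges)] + bin_s / 2, bin_s = bin_s)
}

#' Square-root transform of firing rates
#'
#' Elementwise square root, applied to binned rates to stabilise Poisson-like
#' variance and reduce skewness before linear modelling.
#'
#' @param FR non-negative numeric matrix or vector.
#' @return transformed object of the same shape.
#' @export
sqrt_transform <- function(FR) {
  if (any(FR < 0)) stop("firing rates must be non-negative", call. = FALSE)
  sqrt(FR)
}

#' Gaussian kernel smoothing of binned rates
#'
#' Convolves each column with a discrete Gaussian of standard deviation
#' `sd_s` seconds (`sd_s / bin_s` bins), truncated at +/- 4 SD and
#' renormalised at the series edges so constant inputs are preserved.
#' `sd_s = 0` is the identity.
#'
#' @param FR numeric matrix (bins x units) or vector.
#' @param sd_s kernel standard deviation in seconds (80 ms for center-out
#'   style sessions, 140 ms for sequential ones in the defaults downstream).
#' @param bin_s bin width in seconds.
#' @return smoothed object of the same shape.
#' @export
smooth_gaussian <- function(FR, sd_s, bin_s = 0.05) {
  if (sd_s < 0) stop("sd_s must be non-negative", call. = FALSE)
  if (sd_s == 0) return(FR)
  vec_in <- is.null(dim(FR))
  M <- as.matrix(FR)
  sd_bins <- sd_s / bin_s
  half <- max(1L, ceiling(4 * sd_bins))
  offs <- (-half):half
  ker <- exp(-offs^2 / (2 * sd_bins^2))
  ker <- ker / sum(ker)
  n <- nrow(M)
  # Edge-renormalised convolution: zero-pad, then divide by the kernel mass
  # actually inside the series (convolution of a ones vector).
  mass <- stats::filter(rep(1, n), ker, method = "convolution", sides = 2)
  # stats::filter leaves NA where the kernel overhangs; recompute edges.
  edge <- which(is.na(mass))
  mass <- as.numeric(mass)
  for (i in edge) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mass[i] <- sum(ker[(lo - i + half + 1L):(hi - i + half + 1L)])
  }
  out <- apply(M, 2L, function(col) {
    num <- stats::filter(col, ker, method = "convolution", sides = 2)
    num <- as.numeric(num)
    for (i in edge) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      num[i] <- sum(col[lo:hi] * ker[(lo - i + half + 1L):(hi - i + half + 1L)])
    }
    num / mass
  })
  out <- matrix(out, nrow = n)
  if (vec_in) drop(out) else out
}

#' Bin-aligned velocity and speed from hand position
#'
#' Averages hand position within each bin, then differentiates: velocity at
#' bin i is the first difference of bin-averaged position divided by the bin
#' width; the first bin of each trial (and of the session) uses a forward
#' difference. Speed is the Euclidean norm of velocity.
#'
#' @param hand data.frame `t`, `x`, `y` covering the bin grid.
#' @param t_bins bin centres from [bin_spikes()].
#' @param bin_s bin width (s).
#' @param trial_of_bin optional integer vector marking each bin's trial (NA
#'   outside trials); trial starts switch to forward differences.
#' @return n_bins x 3 matrix with columns `vx`, `vy`, `speed` (cm/s).
#' @export
compute_kinematics <- function(hand, t_bins, bin_s = 0.05,
                               trial_of_bin = NULL) {
  lo <- t_bins - bin_s / 2
  hi <- t_bins + bin_s / 2
  if (min(hand$t) > min(lo) + bin_s || max(hand$t) < max(hi) - bin_s)
    stop("hand data does not cover the bin grid", call. = FALSE)
  # uniform-grid assignment with a rounding guard so edge samples land in a
  # unique bin (samples at a bin's upper edge belong to the next bin)
  idx <- floor((hand$t - lo[1] + 1e-9) / bin_s) + 1L
  keep <- idx >= 1 & idx <= length(t_bins)
  px <- as.numeric(tapply(hand$x[keep], factor(idx[keep], levels = seq_along(t_bins)), mean))
  py <- as.numeric(tapply(hand$y[keep], factor(idx[keep], levels = seq_along(t_bins)), mean))
  if (anyNA(px) || anyNA(py))
    stop("gaps in hand data over the bin grid", call. = FALSE)
  n <- length(t_bins)
  vx <- c(NA, diff(px)) / bin_s
  vy <- c(NA, diff(py)) / bin_s
  fwd <- rep(FALSE, n)
  fwd[1] <- TRUE
  if (!is.null(trial_of_bin) && n > 1) {
    tb <- trial_of_bin
    fwd[which(c(FALSE, tb[-1] != tb[-n] | (is.na(tb[-n]) & !is.na(tb[-1]))))] <- TRUE
  }
  fwd_ok <- fwd & c(rep(TRUE, n - 1), FALSE)
  vx[fwd_ok] <- (px[which(fwd_ok) + 1] - px[which(fwd_ok)]) / bin_s
  vy[fwd_ok] <- (py[which(fwd_ok) + 1] - py[which(fwd_ok)]) / bin_s
  if (n >= 2 && fwd[n]) { vx[n] <- vx[n - 1]; vy[n] <- vy[n - 1] }
  cbind(vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2))
}

# Trial index of each bin centre (NA when the centre falls outside all trials).
assign_bins_to_trials <- function(t_bins, trials) {
  out <- rep(NA_integer_, length(t_bins))
  for (i in seq_len(nrow(trials))) {
    out[t_bins >= trials$start_s[i] & t_bins < trials$end_s[i]] <- i
  }
  out
}

#' Preprocess a session into aligned firing-rate and kinematic matrices
#'
#' Runs the fixed pipeline bin -> sqrt -> smooth on the spike trains, computes
#' bin-aligned velocity and speed, and restricts to bins whose centres fall
#' inside a trial. Deterministic: re-running on an identical session gives
#' bit-identical output.
#'
#' @param session a `canokin_session`.
#' @param bin_s bin width (s), default 0.05.
#' @param smooth_sd_s Gaussian smoothing SD (s), default 0.08.
#' @return a `canokin_binned` list: `t` (bin centres), `Z` (bins x units
#'   smoothed sqrt-rates), `X` (bins x 3 kinematics), `trial_of_bin`,
#'   `bin_s`, `smooth_sd_s`.
#' @export
preprocess_session <- function(session, bin_s = 0.05, smooth_sd_s = 0.08) {
  b <- bin_spikes(session, bin_s)
  FR <- b$counts / bin_s
  Z <- smooth_gaussian(sqrt_transform(FR), smooth_sd_s, bin_s)
  trial_of_bin <- assign_bins_to_trials(b$t, session$trials)
  X <- compute_kinematics(session$hand, b$t, bin_s, trial_of_bin)
  keep <- !is.na(trial_of_bin) & !is.na(X[, 1])
  structure(list(t = b$t[keep], Z = matrix(Z[keep, , drop = FALSE], sum(keep)),
                 X = X[keep, , drop = FALSE],
                 trial_of_bin = trial_of_bin[keep], bin_s = bin_s,
                 smooth_sd_s = smooth_sd_s),
            class = "canokin_binned")
}

#' @export
print.canokin_binned <- function(x, ...) {
  cat(sprintf("<canokin_binned> %d bins x %d units, %d trials, bin %.0f ms\n",
              nrow(x$Z), ncol(x$Z), length(unique(x$trial_of_bin)),
              1000 * x$bin_s))
  invisible(x)
}

# Restrict a binned object to a set of trial ids.
subset_binned <- function(bd, trial_ids) {
  keep <- bd$trial_of_bin %in% trial_ids
  out <- bd
  out$t <- bd$t[keep]
  out$Z <- bd$Z[keep, , drop = FALSE]
  out$X <- bd$X[keep, , drop = FALSE]
  out$trial_of_bin <- bd$trial_of_bin[keep]
  out
}

#' Linear velocity-tuning fit for one unit
#'
#' Ordinary least squares of a unit's (smoothed, sqrt-transformed) rate on
#' velocity and speed: `z = b0 + b1x vx + b1y vy + b2 speed + e`. This is the
#' linearised cosine tuning model; the preferred direction is
#' `atan2(b1y, b1x)` and the goodness of fit gates unit selection.
#'
#' @param z_k numeric vector, one unit's rate series.
#' @param X kinematic matrix with columns vx, vy, speed.
#' @return list with `beta0`, `beta1` (length-2), `beta2`, `r2`,
#'   `resid_var`, `pref_direction_rad`.
#' @export
fit_linear_tuning <- function(z_k, X) {
  if (length(z_k) < 10) stop("need at least 10 bins to fit tuning", call. = FALSE)
  sst <- sum((z_k - mean(z_k))^2)
  if (sst < .Machine$double.eps) {
    return(list(beta0 = mean(z_k), beta1 = c(0, 0), beta2 = 0, r2 = 0,
                resid_var = 0, pref_direction_rad = NA_real_))
  }
  fit <- stats::lm.fit(cbind(1, X[, 1:3]), z_k)
  ssr <- sum(fit$residuals^2)
  b <- unname(fit$coefficients)
  b[is.na(b)] <- 0
  list(beta0 = b[1], beta1 = b[2:3], beta2 = b[4],
       r2 = max(0, 1 - ssr / sst),
       resid_var = ssr / max(1, length(z_k) - 4),
       pref_direction_rad = atan2(b[3], b[2]))
}

#' Tuning fits for a whole population
#'
#' @param Z rate matrix (bins x units).
#' @param X kinematic matrix (bins x 3).
#' @return data.frame, one row per unit: beta0, beta1x, beta1y, beta2, r2,
#'   resid_var, pref_direction_rad.
#' @export
fit_population_tuning <- function(Z, X) {
  rows <- lapply(seq_len(ncol(Z)), function(k) {
    f <- fit_linear_tuning(Z[, k], X)
    data.frame(unit = k, beta0 = f$beta0, beta1x = f$beta1[1],
               beta1y = f$beta1[2], beta2 = f$beta2, r2 = f$r2,
               resid_var = f$resid_var,
               pref_direction_rad = f$pref_direction_rad)
  })
  do.call(rbind, rows)
}

#' Select tuned units by r-squared threshold
#'
#' Keeps units whose linear tuning fit exceeds the threshold, preserving the
#' original unit order. Raising the threshold can only remove units.
#'
#' @param fits data.frame from [fit_population_tuning()] (needs column `r2`).
#' @param threshold inclusion threshold on r2, default 0.01.
#' @return integer vector of kept unit indices.
#' @export
select_units <- function(fits, threshold = 0.01) {
  if (!nrow(fits)) stop("no tuning fits supplied", call. = FALSE)
  keep <- which(fits$r2 > threshold)
  if (!length(keep))
    stop("no unit passed the tuning threshold; nothing to decode", call. = FALSE)
  keep
}
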