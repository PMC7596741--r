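#' Reaching-session container
#'
#' A `canokin_session` bundles the three ingredients of an offline decoding
#' experiment: per-unit spike event times, uniformly sampled 2D hand position,
#' and a chronologically ordered trial table. Times are in seconds, positions
#' in centimetres; unit and trial indices are 1-based (R convention).
#'
#' @param units list of numeric vectors, one per unit, of ascending spike
#'   times (s) within `[0, duration_s]`.
#' @param hand data.frame with columns `t`, `x`, `y`: hand position samples on
#'   a strictly increasing, uniform time grid whose sampling period must not
#'   exceed the analysis bin width (50 ms by default downstream).
#' @param trials data.frame with columns `start_s`, `end_s`, `label`:
#'   non-overlapping, chronologically ordered trial windows. `label` is a
#'   target identifier (e.g. `"T1"`) or `"sequence"`.
#' @param id character session identifier.
#' @param duration_s session length in seconds.
#'
#' @return An object of class `canokin_session`.
#' @seealso [read_session()], [write_session()], [split_trials()],
#'   [make_synthetic_session()]
#' @export
new_session <- function(units, hand, trials, id = "session", duration_s = NULL) {
  if (is.null(duration_s)) duration_s <- max(hand$t) + diff(hand$t[1:2])
  s <- structure(
    list(
      units = lapply(units, as.numeric),
      hand = data.frame(t = as.numeric(hand$t), x = as.numeric(hand$x),
                        y = as.numeric(hand$y)),
      trials = data.frame(start_s = as.numeric(trials$start_s),
                          end_s = as.numeric(trials$end_s),
                          label = as.character(trials$label),
                          stringsAsFactors = FALSE),
      meta = list(id = as.character(id), duration_s = as.numeric(duration_s),
                  schema = "canokin-session-v1")
    ),
    class = "canokin_session"
  )
  validate_session(s)
}

#' Validate a session container
#'
#' Checks all structural invariants: spike times in-bounds and non-decreasing
#' per unit, trials non-overlapping and within session bounds, hand timestamps
#' strictly increasing and uniform to within 1e-9 s.
#'
#' @param s a `canokin_session`.
#' @return `s`, invisibly unchanged, if valid; otherwise an error naming the
#'   offending field (and unit index for spike-time violations).
#' @export
validate_session <- function(s) {
  if (!inherits(s, "canokin_session")) stop("not a canokin_session", call. = FALSE)
  need <- c("units", "hand", "trials", "meta")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop("schema error: missing field(s) ", paste(miss, collapse = ", "),
                         call. = FALSE)
  dur <- s$meta$duration_s
  if (!is.numeric(dur) || dur <= 0) stop("schema error: invalid duration_s", call. = FALSE)
  for (k in seq_along(s$units)) {
    st <- s$units[[k]]
    if (length(st)) {
      if (any(diff(st) < 0))
        stop(sprintf("validation error: non-monotone spike times in unit %d", k),
             call. = FALSE)
      if (st[1] < 0 || st[length(st)] > dur)
        stop(sprintf("validation error: spike times out of [0, duration] in unit %d", k),
             call. = FALSE)
    }
  }
  tr <- s$trials
  if (nrow(tr) == 0L) stop("validation error: session has no trials", call. = FALSE)
  if (any(tr$end_s <= tr$start_s))
    stop("validation error: trial with non-positive length", call. = FALSE)
  if (nrow(tr) > 1L && any(tr$start_s[-1] < tr$end_s[-nrow(tr)] - 1e-12))
    stop("validation error: overlapping or unordered trials", call. = FALSE)
  if (min(tr$start_s) < -1e-12 || max(tr$end_s) > dur + 1e-9)
    stop("validation error: trials outside session bounds", call. = FALSE)
  ht <- s$hand$t
  if (length(ht) < 2L) stop("validation error: hand series too short", call. = FALSE)
  dts <- diff(ht)
  if (any(dts <= 0)) stop("validation error: hand timestamps not increasing", call. = FALSE)
  if (max(dts) - min(dts) > 1e-9)
    stop("validation error: hand sampling grid not uniform", call. = FALSE)
  invisible(s)
}

#' Write a session to a single container file
#'
#' Serialises the session to one hierarchical binary file (R serialisation
#' format version 3, uncompressed, so identical sessions produce byte-identical
#' files).
#'
#' @param session a valid `canokin_session`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  con <- file(path, "wb")
  on.exit(close(con))
  saveRDS(unclass(session), con, version = 3L)
  invisible(path)
}

#' Read a session container file
#'
#' @param path file written by [write_session()].
#' @return the `canokin_session`, re-validated on load.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readRDS(path)
  if (!is.list(raw) || !identical(raw$meta$schema, "canokin-session-v1"))
    stop("schema error: unrecognised session container", call. = FALSE)
  validate_session(structure(raw, class = "canokin_session"))
}

#' @export
print.canokin_session <- function(x, ...) {
  cat(sprintf("<canokin_session> %s: %d units, %d trials, %.1f s\n",
              x$meta$id, length(x$units), nrow(x$trials), x$meta$duration_s))
  invisible(x)
}

#' Chronological train/test split of trials
#'
#' Partitions trials into a training block (the first `floor(train_frac * n)`
#' trials in chronological order) and a test block (the remainder). All model
#' fitting downstream uses the training block only.
#'
#' @param session a `canokin_session` (or anything with a `trials` table).
#' @param train_frac fraction of trials assigned to training, in (0, 1).
#'   Default 0.75.
#' @return list with integer vectors `train_ids` and `test_ids` (1-based trial
#'   indices; disjoint, union covering all trials, train preceding test).
#' @examples
#' s <- make_synthetic_session(synth_config(n_trials = 8), seed = 1)$session
#' split_trials(s, 0.75)
#' @export
split_trials <- function(session, train_frac = 0.75) {
  n <- if (inherits(session, "canokin_session")) nrow(session$trials)
       else as.integer(session)
  if (!is.finite(train_frac) || train_frac <= 0 || train_frac >= 1)
    stop("train_frac must lie strictly between 0 and 1", call. = FALSE)
  if (n < 2L) stop("need at least 2 trials to split", call. = FALSE)
  n_train <- floor(train_frac * n)
  if (n_train < 1L || n_train >= n)
    stop("split leaves an empty partition", call. = FALSE)
  list(train_ids = seq_len(n_train), test_ids = seq.int(n_train + 1L, n))
}
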