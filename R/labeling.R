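#' EMG labeling configuration
#'
#' Defaults follow the hand-squeeze protocol: 500 ms sliding RMS windows, a
#' manually set per-side threshold, a 300 ms refractory period, epochs from
#' 100 ms before to 300 ms after onset (0.4 s total), and rest epochs drawn
#' from quiet stretches at least 500 ms clear of any movement.
#'
#' @param threshold_left,threshold_right Per-side RMS thresholds in
#'   microvolts (> 0); a manual choice, see [suggest_threshold()] for a
#'   reproducible default.
#' @param rms_window_s RMS window length in seconds (default 0.5).
#' @param refractory_s Dead time after a detection (default 0.3).
#' @param pre_s,post_s Epoch extent before/after onset in seconds
#'   (defaults 0.1 and 0.3).
#' @param quiet_min_s Minimum clearance around movements for rest epochs
#'   (default 0.5).
#' @return A list of class `labeling_config`.
#' @export
labeling_config <- function(threshold_left, threshold_right = threshold_left,
                            rms_window_s = 0.5, refractory_s = 0.3,
                            pre_s = 0.1, post_s = 0.3, quiet_min_s = 0.5) {
  if (threshold_left <= 0 || threshold_right <= 0) {
    stopf("thresholds must be > 0")
  }
  stopifnot(rms_window_s > 0, refractory_s > 0, pre_s > 0, post_s > 0,
            quiet_min_s > 0)
  structure(list(threshold_left = threshold_left,
                 threshold_right = threshold_right,
                 rms_window_s = rms_window_s, refractory_s = refractory_s,
                 pre_s = pre_s, post_s = post_s, quiet_min_s = quiet_min_s),
            class = "labeling_config")
}

#' Causal sliding-window RMS of a signal
#'
#' Trailing (causal) root-mean-square per sample; the first
#' `window_s * fs - 1` samples use the partial window available so far, so
#' the output has the same length as the input.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds (`window_s * fs >= 1`).
#' @return Numeric vector of RMS values, same length as `x`.
#' @export
sliding_rms <- function(x, fs, window_s = 0.5) {
  n <- length(x)
  if (n == 0) stopf("empty input signal")
  w <- max(1L, as.integer(round(window_s * fs)))
  cs <- cumsum(x^2)
  sums <- cs - c(rep(0, min(w, n)), cs[seq_len(max(0L, n - w))])
  counts <- pmin(seq_len(n), w)
  sqrt(sums / counts)
}

#' Suggest an EMG detection threshold from a baseline segment
#'
#' The protocol uses a manually set threshold; as a reproducible default
#' this returns a high quantile of the sliding RMS of a user-marked
#' movement-free baseline stretch.
#'
#' @param baseline Numeric EMG signal known to contain no movements.
#' @param fs Sampling rate in Hz.
#' @param window_s RMS window (default 0.5 s).
#' @param quantile Baseline RMS quantile (default 0.99).
#' @return Suggested threshold (microvolts).
#' @export
suggest_threshold <- function(baseline, fs, window_s = 0.5,
                              quantile = 0.99) {
  stats::quantile(sliding_rms(baseline, fs, window_s), quantile,
                  names = FALSE)
}

#' Detect movement onsets from left/right EMG RMS traces
#'
#' An event is registered at the first sample where a trace rises above its
#' threshold (a causal rising-edge crossing).  After any event, further
#' crossings on either side are suppressed for `refractory_s` so one clench
#' is never detected twice.  If both sides cross at the same sample the
#' left wins (logged as a message).
#'
#' @param rms_left,rms_right RMS traces of equal length (see
#'   [sliding_rms()]).
#' @param fs Sampling rate in Hz.
#' @param cfg A [labeling_config()].
#' @return Data frame of movement events with columns `onset_s` and `side`
#'   (`"LEFT"`/`"RIGHT"`), ordered in time.
#' @export
detect_onsets <- function(rms_left, rms_right, fs, cfg) {
  stopifnot(inherits(cfg, "labeling_config"))
  if (length(rms_left) != length(rms_right)) {
    stopf("RMS traces must have equal length")
  }
  above_l <- rms_left > cfg$threshold_left
  above_r <- rms_right > cfg$threshold_right
  edge_l <- above_l & !c(FALSE, above_l[-length(above_l)])
  edge_r <- above_r & !c(FALSE, above_r[-length(above_r)])
  refractory <- round(cfg$refractory_s * fs)
  onsets <- numeric(0)
  sides <- character(0)
  last <- -Inf
  for (i in which(edge_l | edge_r)) {
    if (i - last < refractory) next
    if (edge_l[i] && edge_r[i]) {
      message("simultaneous left/right crossing at sample ", i,
              "; assigning LEFT")
    }
    sides <- c(sides, if (edge_l[i]) "LEFT" else "RIGHT")
    onsets <- c(onsets, (i - 1) / fs)
    last <- i
  }
  data.frame(onset_s = onsets, side = sides, stringsAsFactors = FALSE)
}

eeg_channels <- function(rec) which(rec$channel_kinds == "EEG")

# Extract one epoch (channels x samples) starting at 1-based sample
# `start` of length `len` from the EEG channels; NULL if out of bounds.
cut_epoch <- function(rec, chans, start, len) {
  if (start < 1 || start + len - 1 > ncol(rec$data)) return(NULL)
  rec$data[chans, start:(start + len - 1), drop = FALSE]
}

#' Extract labeled movement epochs around detected onsets
#'
#' Cuts EEG-channel windows covering `[onset - pre_s, onset + post_s)` for
#' every event; events whose window would cross the recording bounds are
#' dropped with a warning.
#'
#' @param rec A [recording()] containing at least one EEG channel.
#' @param events Event data frame from [detect_onsets()] (columns
#'   `onset_s`, `side`).
#' @param cfg A [labeling_config()].
#' @return An [epoch_set()] with classes `c("LEFT", "RIGHT")`.
#' @export
extract_movement_epochs <- function(rec, events, cfg) {
  stopifnot(inherits(rec, "recording"), inherits(cfg, "labeling_config"))
  chans <- eeg_channels(rec)
  if (length(chans) == 0) stopf("recording has no EEG channels")
  len <- round((cfg$pre_s + cfg$post_s) * rec$fs)
  keep <- list()
  labels <- integer(0)
  dropped <- 0L
  for (i in seq_len(nrow(events))) {
    start <- round((events$onset_s[i] - cfg$pre_s) * rec$fs) + 1L
    ep <- cut_epoch(rec, chans, start, len)
    if (is.null(ep)) {
      dropped <- dropped + 1L
      next
    }
    keep[[length(keep) + 1L]] <- ep
    labels <- c(labels, if (events$side[i] == "LEFT") 1L else 2L)
  }
  if (dropped > 0) {
    warning(sprintf("%d event(s) dropped: epoch window outside recording",
                    dropped))
  }
  epochs <- array(0, dim = c(length(keep), length(chans), len))
  for (i in seq_along(keep)) epochs[i, , ] <- keep[[i]]
  epoch_set(epochs, labels, c("LEFT", "RIGHT"), rec$fs,
            c(cfg$pre_s, cfg$post_s), rec$channel_names[chans])
}

# Quiet intervals: [0, duration] minus (event +/- quiet_min_s), in seconds.
quiet_intervals <- function(duration_s, onsets_s, quiet_min_s) {
  if (length(onsets_s) == 0) return(matrix(c(0, duration_s), 1))
  onsets_s <- sort(onsets_s)
  lo <- c(0, onsets_s + quiet_min_s)
  hi <- c(onsets_s - quiet_min_s, duration_s)
  keep <- hi - lo > 0
  cbind(lo[keep], hi[keep])
}

#' Extract no-movement (rest) epochs from quiet stretches
#'
#' Non-overlapping windows of the movement epoch length are tiled from the
#' start of every stretch that is at least `quiet_min_s` long and contains
#' no event within `quiet_min_s` on either side.  Optionally the candidate
#' windows are subsampled to a target count with a seeded RNG.
#'
#' @inheritParams extract_movement_epochs
#' @param max_epochs Optional cap on the number of rest epochs (seeded
#'   subsample); `NULL` keeps all candidates.
#' @param seed Seed used only when subsampling.
#' @return An [epoch_set()] with the single class `"NO_MOVEMENT"` (possibly
#'   empty).
#' @export
extract_rest_epochs <- function(rec, events, cfg, max_epochs = NULL,
                                seed = 1) {
  stopifnot(inherits(rec, "recording"), inherits(cfg, "labeling_config"))
  chans <- eeg_channels(rec)
  if (length(chans) == 0) stopf("recording has no EEG channels")
  len <- round((cfg$pre_s + cfg$post_s) * rec$fs)
  epoch_s <- cfg$pre_s + cfg$post_s
  duration_s <- ncol(rec$data) / rec$fs
  intervals <- quiet_intervals(duration_s, events$onset_s, cfg$quiet_min_s)
  starts <- numeric(0)
  for (r in seq_len(nrow(intervals))) {
    if (intervals[r, 2] - intervals[r, 1] < cfg$quiet_min_s) next
    s <- seq(intervals[r, 1], intervals[r, 2] - epoch_s + 1e-9,
             by = epoch_s)
    s <- s[s + epoch_s <= intervals[r, 2] + 1e-9]
    starts <- c(starts, s)
  }
  if (!is.null(max_epochs) && length(starts) > max_epochs) {
    starts <- sort(with_seed(seed, sample(starts, max_epochs)))
  }
  epochs <- array(0, dim = c(length(starts), length(chans), len))
  for (i in seq_along(starts)) {
    ep <- cut_epoch(rec, chans, round(starts[i] * rec$fs) + 1L, len)
    if (is.null(ep)) ep <- matrix(0, length(chans), len)
    epochs[i, , ] <- ep
  }
  epoch_set(epochs, rep(1L, length(starts)), "NO_MOVEMENT", rec$fs,
            c(cfg$pre_s, cfg$post_s), rec$channel_names[chans])
}

#' Combine movement and rest epochs into a 2- or 3-class set
#'
#' Class order is fixed as (LEFT, RIGHT) or (LEFT, RIGHT, NO_MOVEMENT).
#'
#' @param movement Movement [epoch_set()] (classes LEFT, RIGHT).
#' @param rest Rest [epoch_set()] (class NO_MOVEMENT); required when
#'   `include_rest = TRUE`.
#' @param include_rest Build the three-class set (default `FALSE`).
#' @return The combined [epoch_set()].
#' @export
build_epochset <- function(movement, rest = NULL, include_rest = FALSE) {
  stopifnot(inherits(movement, "epoch_set"))
  if (!include_rest) {
    return(epoch_set(movement$epochs, movement$labels, c("LEFT", "RIGHT"),
                     movement$fs, movement$window, movement$channel_names))
  }
  if (is.null(rest) || dim(rest$epochs)[1] == 0) {
    stopf(paste("no rest epochs available for the three-class set;",
                "record more movement-free data"))
  }
  if (!identical(movement$channel_names, rest$channel_names)) {
    stopf("movement and rest epochs use different channel sets")
  }
  if (movement$fs != rest$fs || !identical(movement$window, rest$window)) {
    stopf("movement and rest epochs have different geometry")
  }
  n_m <- dim(movement$epochs)[1]
  n_r <- dim(rest$epochs)[1]
  epochs <- array(0, dim = c(n_m + n_r, dim(movement$epochs)[2],
                             dim(movement$epochs)[3]))
  if (n_m > 0) epochs[seq_len(n_m), , ] <- movement$epochs
  if (n_r > 0) epochs[n_m + seq_len(n_r), , ] <- rest$epochs
  epoch_set(epochs, c(movement$labels, rep(3L, n_r)),
            c("LEFT", "RIGHT", "NO_MOVEMENT"), movement$fs,
            movement$window, movement$channel_names)
}

#' Label a continuous EEG+EMG recording into epochs
#'
#' Convenience pipeline: sliding RMS on the two EMG channels, onset
#' detection, movement-epoch extraction, and (optionally) rest-epoch
#' extraction, combined into a 2- or 3-class [epoch_set()].
#'
#' @param rec A [recording()] whose `channel_kinds` tag exactly two
#'   channels as `"EMG"` (left first, right second).
#' @param cfg A [labeling_config()].
#' @param include_rest Build the three-class set (default `FALSE`).
#' @param max_rest_epochs Optional cap passed to [extract_rest_epochs()].
#' @param seed Seed for rest-epoch subsampling.
#' @return List with `epochs` (the combined set) and `events` (the
#'   detected onsets).
#' @export
label_recording <- function(rec, cfg, include_rest = FALSE,
                            max_rest_epochs = NULL, seed = 1) {
  emg <- which(rec$channel_kinds == "EMG")
  if (length(emg) != 2) {
    stopf("expected exactly 2 EMG channels, found %d", length(emg))
  }
  rms_l <- sliding_rms(rec$data[emg[1], ], rec$fs, cfg$rms_window_s)
  rms_r <- sliding_rms(rec$data[emg[2], ], rec$fs, cfg$rms_window_s)
  events <- detect_onsets(rms_l, rms_r, rec$fs, cfg)
  movement <- extract_movement_epochs(rec, events, cfg)
  rest <- if (include_rest) {
    extract_rest_epochs(rec, events, cfg, max_rest_epochs, seed)
  }
  list(epochs = build_epochset(movement, rest, include_rest),
       events = events)
}
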