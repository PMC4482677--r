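#' Configuration of the synthetic epoch/stream generators
#'
#' The generators emulate the hand-squeeze study conditions: 0.4 s epochs
#' at 250 Hz, a class-specific low-frequency evoked component planted on a
#' small set of "motor" channels, embedded in pink (1/f) background noise.
#' Defaults: 8 channels, an 8 Hz Hann-enveloped carrier of 2 uV amplitude
#' on channels 3-4 (LEFT) and 6-7 (RIGHT), pink noise of 2 uV SD
#' (single-trial SNR of 1), and 50 epochs per class.
#'
#' @param n_channels Number of EEG channels (default 8).
#' @param fs Sampling rate in Hz (default 250).
#' @param epoch_s Epoch length in seconds (default 0.4).
#' @param n_classes 2 (LEFT, RIGHT) or 3 (adds NO_MOVEMENT, which carries
#'   no planted component).
#' @param planted_channels List of channel-index vectors, one per effect
#'   class (LEFT, RIGHT).
#' @param effect_amplitude Peak amplitude of the planted component in
#'   microvolts (default 2; 0 plants nothing).
#' @param carrier_hz Carrier frequency of the evoked component (default 8).
#' @param noise_model `"PINK"` (default) or `"WHITE"`.
#' @param noise_sd Noise standard deviation in microvolts (default 2).
#' @param n_epochs Epochs per class (default 50).
#' @param seed Integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 8, fs = 250, epoch_s = 0.4,
                         n_classes = 2,
                         planted_channels = list(c(3, 4), c(6, 7)),
                         effect_amplitude = 2, carrier_hz = 8,
                         noise_model = c("PINK", "WHITE"), noise_sd = 2,
                         n_epochs = 50, seed = 1) {
  noise_model <- match.arg(noise_model)
  if (!n_classes %in% 2:3) stopf("n_classes must be 2 or 3")
  if (length(planted_channels) < 2) {
    stopf("planted_channels needs entries for LEFT and RIGHT")
  }
  if (any(unlist(planted_channels) < 1 |
          unlist(planted_channels) > n_channels)) {
    stopf("planted channels out of range 1..%d", n_channels)
  }
  stopifnot(effect_amplitude >= 0, noise_sd > 0, n_epochs >= 1,
            carrier_hz < fs / 2)
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 epoch_s = epoch_s, n_classes = as.integer(n_classes),
                 planted_channels = planted_channels,
                 effect_amplitude = effect_amplitude,
                 carrier_hz = carrier_hz, noise_model = noise_model,
                 noise_sd = noise_sd, n_epochs = as.integer(n_epochs),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Pink (1/f amplitude) or white noise, sd-normalized, n samples.
gen_noise <- function(n, model, sd_target) {
  x <- stats::rnorm(n)
  if (model == "PINK" && n >= 4) {
    X <- stats::fft(x)
    f <- c(1, seq_len(n - 1))              # avoid 1/0 at DC
    f <- pmin(f, n - f + 1)                # symmetric frequency index
    X <- X / sqrt(f)
    X[1] <- 0
    x <- Re(stats::fft(X, inverse = TRUE)) / n
  }
  x / stats::sd(x) * sd_target
}

# Hann-enveloped sinusoid of the epoch length, peak amplitude `amp`.
evoked_component <- function(n_samples, fs, carrier_hz, amp) {
  t <- (seq_len(n_samples) - 1) / fs
  env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_samples) - 1) / (n_samples - 1))
  amp * env * sin(2 * pi * carrier_hz * t)
}

#' Generate class-conditional synthetic epochs
#'
#' Every epoch is channel noise; epochs of an effect class additionally
#' carry an onset-locked Hann-enveloped `carrier_hz` oscillation of peak
#' amplitude `effect_amplitude` on that class's planted channels.  The
#' NO_MOVEMENT class (when `n_classes = 3`) has no added component.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return An [epoch_set()] with `cfg$n_epochs` epochs per class.
#' @export
synth_epochs <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  S <- round(cfg$epoch_s * cfg$fs)
  n_total <- cfg$n_epochs * cfg$n_classes
  epochs <- array(0, dim = c(n_total, cfg$n_channels, S))
  labels <- rep(seq_len(cfg$n_classes), each = cfg$n_epochs)
  component <- evoked_component(S, cfg$fs, cfg$carrier_hz,
                                cfg$effect_amplitude)
  with_seed(cfg$seed, {
    for (i in seq_len(n_total)) {
      for (ch in seq_len(cfg$n_channels)) {
        epochs[i, ch, ] <- gen_noise(S, cfg$noise_model, cfg$noise_sd)
      }
      if (labels[i] <= 2) {
        for (ch in cfg$planted_channels[[labels[i]]]) {
          epochs[i, ch, ] <- epochs[i, ch, ] + component
        }
      }
    }
  })
  class_names <- c("LEFT", "RIGHT", "NO_MOVEMENT")[seq_len(cfg$n_classes)]
  epoch_set(epochs, labels, class_names, cfg$fs,
            c(0.1, cfg$epoch_s - 0.1),
            sprintf("CH%02d", seq_len(cfg$n_channels)))
}

#' Generate a continuous EEG+EMG stream with known squeeze onsets
#'
#' Builds a recording of `cfg$n_channels` EEG channels plus two EMG
#' channels (`EMG_LEFT`, `EMG_RIGHT`).  At each requested onset the
#' matching EMG channel carries a 200 ms burst of band-limited noise at
#' `burst_amplitude` times the EMG baseline SD, and the EEG channels carry
#' the class-conditional evoked component time-locked to the onset.
#' Ground-truth events are returned for testing the labeling pipeline.
#'
#' @param duration_s Total duration in seconds.
#' @param squeeze_times List with numeric vectors `left` and `right` of
#'   onset times in seconds; all onsets (pooled) must be separated by at
#'   least the burst duration, or an error is raised.
#' @param cfg A [synth_config()].
#' @param burst_amplitude EMG burst amplitude as a multiple of the EMG
#'   baseline SD (default 40; the baseline SD is 1 uV).  Surface EMG
#'   during a clench is typically two to three orders of magnitude above
#'   the relaxed baseline; a strong burst also keeps the causal
#'   sliding-RMS crossing latency within a few samples.
#' @param burst_s EMG burst duration (default 0.2 s).
#' @return List with `recording` and the ground-truth `events` data frame
#'   (`onset_s`, `side`).
#' @export
synth_stream <- function(duration_s, squeeze_times, cfg = synth_config(),
                         burst_amplitude = 40, burst_s = 0.2) {
  stopifnot(inherits(cfg, "synth_config"))
  left <- sort(squeeze_times$left %||% numeric(0))
  right <- sort(squeeze_times$right %||% numeric(0))
  all_onsets <- sort(c(left, right))
  if (length(all_onsets) > 1 && min(diff(all_onsets)) < burst_s) {
    stopf("overlapping EMG bursts: onsets closer than %g s", burst_s)
  }
  if (length(all_onsets) > 0 &&
      (min(all_onsets) < 0.1 ||
       max(all_onsets) + burst_s > duration_s)) {
    stopf("onsets must lie within the recording (>= 0.1 s from the start)")
  }
  n <- round(duration_s * cfg$fs)
  S <- round(cfg$epoch_s * cfg$fs)
  n_eeg <- cfg$n_channels
  data <- matrix(0, n_eeg + 2L, n)
  component <- evoked_component(S, cfg$fs, cfg$carrier_hz,
                                cfg$effect_amplitude)
  burst_len <- round(burst_s * cfg$fs)
  with_seed(cfg$seed, {
    for (ch in seq_len(n_eeg)) {
      data[ch, ] <- gen_noise(n, cfg$noise_model, cfg$noise_sd)
    }
    data[n_eeg + 1L, ] <- stats::rnorm(n)   # EMG baselines, SD 1
    data[n_eeg + 2L, ] <- stats::rnorm(n)
    add_events <- function(onsets, side_idx, emg_row) {
      for (on in onsets) {
        i0 <- round(on * cfg$fs) + 1L
        burst <- stats::rnorm(burst_len) * burst_amplitude
        j <- i0:min(i0 + burst_len - 1L, n)
        data[emg_row, j] <<- data[emg_row, j] + burst[seq_along(j)]
        for (ch in cfg$planted_channels[[side_idx]]) {
          jj <- i0:min(i0 + S - 1L, n)
          data[ch, jj] <<- data[ch, jj] + component[seq_along(jj)]
        }
      }
    }
    add_events(left, 1L, n_eeg + 1L)
    add_events(right, 2L, n_eeg + 2L)
  })
  rec <- recording(
    data, cfg$fs,
    c(sprintf("CH%02d", seq_len(n_eeg)), "EMG_LEFT", "EMG_RIGHT"),
    c(rep("EEG", n_eeg), "EMG", "EMG"))
  events <- data.frame(
    onset_s = c(left, right),
    side = c(rep("LEFT", length(left)), rep("RIGHT", length(right))),
    stringsAsFactors = FALSE)
  events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL
  list(recording = rec, events = events)
}
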