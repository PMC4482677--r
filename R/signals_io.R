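#' Continuous multichannel recording
#'
#' @param data Numeric matrix, channels x samples, in physical units
#'   (microvolts for EEG/EMG).
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_names Unique channel names, one per row of `data`.
#' @param channel_kinds Per-channel tag, one of `"EEG"`, `"EMG"`, `"OTHER"`
#'   (default all `"EEG"`).
#' @param start_time Recording start offset in seconds (default 0).
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, channel_names,
                      channel_kinds = rep("EEG", nrow(data)),
                      start_time = 0) {
  data <- as.matrix(data)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stopf("fs must be > 0")
  if (length(channel_names) != nrow(data)) {
    stopf("channel_names length (%d) != number of channels (%d)",
          length(channel_names), nrow(data))
  }
  if (anyDuplicated(channel_names)) stopf("channel names must be unique")
  channel_kinds <- match.arg(channel_kinds, c("EEG", "EMG", "OTHER"),
                             several.ok = TRUE)
  channel_kinds <- rep_len(channel_kinds, nrow(data))
  structure(list(data = data, fs = fs,
                 channel_names = as.character(channel_names),
                 channel_kinds = channel_kinds,
                 start_time = start_time),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Labeled set of fixed-length epochs
#'
#' The classifier's input unit: fixed-length multichannel windows, each
#' time-locked to an event and labeled with a class.
#'
#' @param epochs Numeric array, `n_epochs x channels x samples_per_epoch`.
#' @param labels Integer class labels in `1:length(class_names)`, one per
#'   epoch.
#' @param class_names Class names, e.g. `c("LEFT", "RIGHT")`.
#' @param fs Sampling rate in Hz.
#' @param window Length-2 numeric `(pre_s, post_s)`: seconds before/after
#'   the locking event; `samples_per_epoch` must equal
#'   `round((pre_s + post_s) * fs)`.
#' @param channel_names Channel names, one per channel.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, labels, class_names, fs, window,
                      channel_names) {
  if (length(dim(epochs)) != 3) {
    stopf("epochs must be a 3-d array (epochs x channels x samples)")
  }
  labels <- as.integer(labels)
  if (dim(epochs)[1] != length(labels)) {
    stopf("number of epochs (%d) != number of labels (%d)",
          dim(epochs)[1], length(labels))
  }
  if (length(labels) > 0 &&
      (min(labels) < 1L || max(labels) > length(class_names))) {
    stopf("labels must lie in 1..%d", length(class_names))
  }
  if (length(window) != 2 || any(window < 0)) {
    stopf("window must be (pre_s, post_s), both >= 0")
  }
  expected <- round(sum(window) * fs)
  if (dim(epochs)[3] != expected) {
    stopf("samples_per_epoch (%d) != round((pre_s + post_s) * fs) = %d",
          dim(epochs)[3], expected)
  }
  if (dim(epochs)[2] != length(channel_names)) {
    stopf("channel_names length mismatch")
  }
  structure(list(epochs = epochs, labels = labels,
                 class_names = as.character(class_names), fs = fs,
                 window = as.numeric(window),
                 channel_names = as.character(channel_names)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("epoch_set: %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  counts <- tabulate(x$labels, nbins = length(x$class_names))
  cat("  classes:", paste(sprintf("%s (%d)", x$class_names, counts),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Select a subset of epochs
#' @param es An [epoch_set()].
#' @param idx Integer epoch indices to keep.
#' @return An [epoch_set()] with the selected epochs.
#' @export
subset_epochs <- function(es, idx) {
  epoch_set(es$epochs[idx, , , drop = FALSE], es$labels[idx],
            es$class_names, es$fs, es$window, es$channel_names)
}

#' Flatten epochs to a design matrix
#'
#' Each epoch becomes one row in channel-major order: all samples of
#' channel 1 first, then channel 2, and so on.  This fixed order is what
#' the networks are trained on and what the weight analyses invert.
#'
#' @param es An [epoch_set()].
#' @return Matrix `n_epochs x (channels * samples_per_epoch)`.
#' @export
flatten_epochs <- function(es) {
  d <- dim(es$epochs)
  if (d[1] == 0) return(matrix(numeric(0), 0, d[2] * d[3]))
  t(matrix(aperm(es$epochs, c(3, 2, 1)), nrow = d[2] * d[3], ncol = d[1]))
}

# ---- EDF ------------------------------------------------------------------

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

# Format a number to fit an 8-character EDF ASCII field; returns the string.
# The writer must quantize against the value actually written, so callers
# re-parse this string.
num8 <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, format = "g", width = 1)
    if (nchar(s) <= 8) return(s)
  }
  substr(s, 1, 8)
}

read_ascii <- function(con, width) {
  trimws(rawToChar(readBin(con, "raw", width)))
}

#' Write a recording as plain EDF
#'
#' Minimal continuous EDF (16-bit), one data record spanning the whole
#' recording, same sampling rate on all channels.  Physical scaling is set
#' from the per-channel data range, so values round-trip to within 16-bit
#' quantization of that range.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  ns <- nrow(rec$data)
  n <- ncol(rec$data)
  con <- file(path, "wb")
  on.exit(close(con))
  header_bytes <- 256L + 256L * ns
  writeChar(paste0(
    pad_ascii("0", 8), pad_ascii("X", 80), pad_ascii("X", 80),
    pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
    pad_ascii(header_bytes, 8), pad_ascii("", 44),
    pad_ascii(1L, 8), pad_ascii(format(n / rec$fs, digits = 8), 8),
    pad_ascii(ns, 4)), con, eos = NULL)
  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  flat <- phys_max - phys_min <= 0
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  # widen slightly so the 8-character ASCII values still bracket the data
  pad <- (phys_max - phys_min) * 1e-4
  min_str <- vapply(phys_min - pad, num8, "")
  max_str <- vapply(phys_max + pad, num8, "")
  phys_min <- as.numeric(min_str)
  phys_max <- as.numeric(max_str)
  fields <- function(vals, width) {
    paste(vapply(vals, pad_ascii, "", width = width), collapse = "")
  }
  writeChar(paste0(
    fields(rec$channel_names, 16),
    fields(rep("", ns), 80),
    fields(rep("uV", ns), 8),
    fields(min_str, 8),
    fields(max_str, 8),
    fields(rep(-32768L, ns), 8),
    fields(rep(32767L, ns), 8),
    fields(rep("", ns), 80),
    fields(rep(n, ns), 8),
    fields(rep("", ns), 32)), con, eos = NULL)
  for (ch in seq_len(ns)) {
    dig <- round((rec$data[ch, ] - phys_min[ch]) /
                   (phys_max[ch] - phys_min[ch]) * 65535 - 32768)
    dig <- pmin(pmax(dig, -32768), 32767)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a plain EDF/EDF+ file
#'
#' Supports continuous EDF with a common sampling rate across channels.
#' Values are returned in physical units using the per-channel scaling in
#' the header.
#'
#' @param path EDF file path.
#' @param channel_kinds Optional per-channel kinds; by default channels
#'   whose label contains "EMG" are tagged `"EMG"`, all others `"EEG"`.
#' @return A [recording()].
#' @export
read_edf <- function(path, channel_kinds = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (file.size(path) < 256) stopf("EDF format error: truncated header")
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii(con, 8)                      # version
  read_ascii(con, 80); read_ascii(con, 80)
  read_ascii(con, 8); read_ascii(con, 8)
  header_bytes <- suppressWarnings(as.integer(read_ascii(con, 8)))
  read_ascii(con, 44)
  n_records <- suppressWarnings(as.integer(read_ascii(con, 8)))
  rec_dur <- suppressWarnings(as.numeric(read_ascii(con, 8)))
  ns <- suppressWarnings(as.integer(read_ascii(con, 4)))
  if (is.na(ns) || ns < 1) stopf("EDF format error: bad signal count field")
  if (is.na(n_records) || n_records < 1) {
    stopf("EDF format error: bad record count field")
  }
  if (is.na(rec_dur) || rec_dur <= 0) {
    stopf("EDF format error: bad record duration field")
  }
  if (is.na(header_bytes) || file.size(path) < 256 + 256 * ns) {
    stopf("EDF format error: truncated signal headers")
  }
  sfield <- function(width) {
    vapply(seq_len(ns), function(i) read_ascii(con, width), "")
  }
  labels <- sfield(16)
  sfield(80); sfield(8)
  phys_min <- as.numeric(sfield(8))
  phys_max <- as.numeric(sfield(8))
  dig_min <- as.numeric(sfield(8))
  dig_max <- as.numeric(sfield(8))
  sfield(80)
  spr <- suppressWarnings(as.integer(sfield(8)))
  sfield(32)
  if (anyDuplicated(labels)) {
    stopf("EDF format error: duplicate channel labels (%s)",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (any(is.na(spr) | spr < 1)) {
    stopf("EDF format error: bad samples-per-record field")
  }
  if (length(unique(spr)) != 1) {
    stopf("EDF format error: per-channel sampling rates differ")
  }
  if (any(is.na(phys_min) | is.na(phys_max) | is.na(dig_min) | is.na(dig_max)) ||
      any(dig_max <= dig_min)) {
    stopf("EDF format error: bad physical/digital scaling fields")
  }
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, spr[1] * n_records)
  for (r in seq_len(n_records)) {
    for (ch in seq_len(ns)) {
      raw <- readBin(con, "integer", spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      if (length(raw) < spr[ch]) stopf("EDF format error: truncated data record")
      cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
      data[ch, cols] <- phys_min[ch] + (raw - dig_min[ch]) *
        (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
    }
  }
  if (is.null(channel_kinds)) {
    channel_kinds <- ifelse(grepl("EMG", labels, ignore.case = TRUE),
                            "EMG", "EEG")
  }
  recording(data, fs, labels, channel_kinds)
}

# ---- epoch container ------------------------------------------------------

EPOCHS_MAGIC <- "BCINET-EPOCHSET-1\n"

#' Write an epoch set to a self-describing container
#'
#' Single-file layout: an ASCII magic line, an 8-byte little-endian integer
#' giving the byte length of a JSON header (dims, labels, class names,
#' sampling rate, window, channel names), then the epoch array as raw
#' little-endian float64 in R's native column-major order for dims
#' `(n_epochs, channels, samples)`.  The round-trip is bit-exact.
#'
#' @param es An [epoch_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(es, path) {
  stopifnot(inherits(es, "epoch_set"))
  header <- jsonlite::toJSON(list(
    dims = dim(es$epochs), labels = es$labels,
    class_names = es$class_names, fs = es$fs, window = es$window,
    channel_names = es$channel_names), auto_unbox = FALSE, digits = NA)
  hraw <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(EPOCHS_MAGIC, con, eos = NULL)
  writeBin(as.numeric(length(hraw)), con, size = 8, endian = "little")
  writeBin(hraw, con)
  writeBin(as.vector(es$epochs), con, size = 8, endian = "little")
  invisible(path)
}

#' Read an epoch set written by [write_epochs()]
#' @param path Container file path.
#' @return An [epoch_set()].
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(EPOCHS_MAGIC)))
  if (!identical(magic, EPOCHS_MAGIC)) {
    stopf("epoch container format error: bad magic")
  }
  hlen <- readBin(con, "double", 1, size = 8, endian = "little")
  meta <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                             simplifyVector = TRUE)
  required <- c("dims", "labels", "class_names", "fs", "window",
                "channel_names")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    stopf("epoch container format error: missing field(s) %s",
          paste(missing, collapse = ", "))
  }
  n_values <- prod(meta$dims)
  values <- readBin(con, "double", n_values, size = 8, endian = "little")
  if (length(values) < n_values) {
    stopf("epoch container format error: truncated payload")
  }
  epoch_set(array(values, dim = meta$dims), as.integer(meta$labels),
            meta$class_names, meta$fs, meta$window, meta$channel_names)
}

# ---- filtering ------------------------------------------------------------

# Apply an odd-length symmetric FIR kernel with zero phase: the signal is
# reflection-padded at both edges and convolved forward and backward, so the
# effective response is the squared magnitude of the kernel's.
apply_zero_phase <- function(x, kernel) {
  m <- length(kernel)
  half <- (m - 1) %/% 2
  n <- length(x)
  pad <- min(m, n - 1)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  fwd <- stats::filter(xp, kernel, sides = 2)
  bwd <- rev(stats::filter(rev(fwd), kernel, sides = 2))
  out <- bwd[(pad + 1):(pad + n)]
  out[is.na(out)] <- 0
  out
}

design_fir <- function(order, w, type, window_fn) {
  # signal::fir1 order N gives N+1 taps; keep N even for an odd-length
  # symmetric (type-I linear-phase) kernel.
  if (order %% 2 == 1) order <- order + 1
  as.numeric(signal::fir1(order, w, type = type,
                          window = window_fn(order + 1)))
}

#' Band-pass and notch filter a recording (zero phase)
#'
#' Windowed-sinc FIR filters (Hann window) applied with zero phase by
#' forward-backward convolution with reflection padding.  The band-pass
#' kernel order is `3 * fs / low_hz` (rounded to even, capped at a third of
#' the signal length); the notch is a band-stop of half-width
#' `notch_halfwidth_hz` around `notch_hz`.
#'
#' @param rec A [recording()].
#' @param low_hz,high_hz Pass-band edges, `0 < low_hz < high_hz < fs/2`.
#' @param notch_hz Mains frequency to suppress, `< fs/2`; `NULL` skips the
#'   notch.
#' @param notch_halfwidth_hz Half-width of the stop band (default 2 Hz).
#' @return Filtered [recording()], same shape and sampling rate.
#' @export
bandpass_notch <- function(rec, low_hz, high_hz, notch_hz = 50,
                           notch_halfwidth_hz = 2) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stopf("need 0 < low_hz < high_hz < fs/2 = %g", nyq)
  }
  if (!is.null(notch_hz) && notch_hz >= nyq) {
    stopf("notch_hz must be below fs/2 = %g", nyq)
  }
  n <- ncol(rec$data)
  max_order <- max(4, 2 * ((n - 1) %/% 6))
  bp_order <- min(round(3 * rec$fs / low_hz), max_order)
  bp <- design_fir(bp_order, c(low_hz, high_hz) / nyq, "pass",
                   signal::hanning)
  kernels <- list(bp)
  if (!is.null(notch_hz)) {
    nt_order <- min(round(3 * rec$fs / notch_halfwidth_hz), max_order)
    lo <- max(notch_hz - notch_halfwidth_hz, 1e-3)
    hi <- min(notch_hz + notch_halfwidth_hz, nyq * 0.999)
    kernels <- c(kernels, list(design_fir(nt_order, c(lo, hi) / nyq, "stop",
                                          signal::hanning)))
  }
  out <- rec$data
  for (ch in seq_len(nrow(out))) {
    x <- out[ch, ]
    for (k in kernels) x <- apply_zero_phase(x, k)
    out[ch, ] <- x
  }
  recording(out, rec$fs, rec$channel_names, rec$channel_kinds,
            rec$start_time)
}

#' Decimate a recording to a lower sampling rate
#'
#' Anti-alias low-pass (zero-phase windowed-sinc FIR with cut-off at 80% of
#' the new Nyquist frequency, DC gain exactly 1) followed by subsampling.
#' `fs / target_fs` must be a positive integer; `target_fs == fs` is the
#' identity.
#'
#' @param rec A [recording()].
#' @param target_fs Target sampling rate in Hz.
#' @return A [recording()] at `target_fs` with `floor(n / factor)` samples.
#' @export
decimate_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "recording"))
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9 || factor < 1) {
    stopf("fs / target_fs = %g is not a positive integer factor", factor)
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  n <- ncol(rec$data)
  order <- min(20L * factor, max(4, 2 * ((n - 1) %/% 6)))
  kernel <- design_fir(order, 0.8 / factor, "low", signal::hamming)
  kernel <- kernel / sum(kernel)  # exact unit DC gain
  keep <- seq(1, n, by = factor)[seq_len(n %/% factor)]
  out <- matrix(0, nrow(rec$data), length(keep))
  for (ch in seq_len(nrow(out))) {
    out[ch, ] <- apply_zero_phase(rec$data[ch, ], kernel)[keep]
  }
  recording(out, target_fs, rec$channel_names, rec$channel_kinds,
            rec$start_time)
}

#' Remove the mean of each epoch
#'
#' Subtracts, within every epoch, each channel's own mean (default) or the
#' epoch's global mean.  The variance is deliberately not rescaled: epoch
#' variance is treated as task-related information.
#'
#' @param es An [epoch_set()].
#' @param per_channel Subtract per-channel means (default `TRUE`); if
#'   `FALSE` a single mean over all channels and samples of the epoch is
#'   removed.
#' @return An [epoch_set()] with zero-mean epochs, variances untouched.
#' @export
demean_epochs <- function(es, per_channel = TRUE) {
  stopifnot(inherits(es, "epoch_set"))
  ep <- es$epochs
  if (dim(ep)[1] > 0) {
    if (per_channel) {
      means <- apply(ep, c(1, 2), mean)          # n x channels
      ep <- ep - array(means, dim = dim(ep))     # recycles over samples
    } else {
      means <- apply(ep, 1, mean)
      ep <- ep - array(means, dim = dim(ep))
    }
  }
  epoch_set(ep, es$labels, es$class_names, es$fs, es$window,
            es$channel_names)
}
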