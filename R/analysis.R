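#' Spatial map of first-layer input weights
#'
#' For each channel, the absolute weights between that channel's input
#' samples and every neuron of the first hidden layer are averaged over
#' time points and neurons, giving one relative-importance value per
#' electrode.  The map is then min-max normalized to `[0, 1]`.  A constant
#' map (all channels equal) has no ordering information and is returned as
#' all 0.5 with a warning.
#'
#' @param model A `network_model` trained on epochs flattened in
#'   channel-major order (see [flatten_epochs()]).
#' @param n_channels,samples_per_epoch Epoch geometry;
#'   `n_channels * samples_per_epoch` must equal `model$input_dim`.
#' @param channel_names Optional names for the output.
#' @param normalize Min-max normalize (default `TRUE`); `FALSE` returns the
#'   raw per-channel mean absolute weights (useful before fold-averaging).
#' @return Named numeric vector of per-channel weights.
#' @export
spatial_weight_map <- function(model, n_channels, samples_per_epoch,
                               channel_names = NULL, normalize = TRUE) {
  stopifnot(inherits(model, "network_model"))
  if (n_channels * samples_per_epoch != model$input_dim) {
    stopf("n_channels * samples_per_epoch (%d) != input_dim (%d)",
          n_channels * samples_per_epoch, model$input_dim)
  }
  W1 <- abs(model$weights[[1]])
  per_channel <- vapply(seq_len(n_channels), function(ch) {
    rows <- ((ch - 1) * samples_per_epoch + 1):(ch * samples_per_epoch)
    mean(W1[rows, ])
  }, numeric(1))
  if (!is.null(channel_names)) names(per_channel) <- channel_names
  if (!normalize) return(per_channel)
  rng <- range(per_channel)
  if (diff(rng) < .Machine$double.eps * max(abs(rng), 1)) {
    warning("all channels carry equal weight; normalization undefined")
    per_channel[] <- 0.5
    return(per_channel)
  }
  (per_channel - rng[1]) / diff(rng)
}

#' Power spectral density of the temporal first-layer weights
#'
#' The signed first-layer weights are averaged over channels and neurons to
#' a single weight time series of length `samples_per_epoch`, interpreted
#' as FIR filter coefficients acting on the input.  Its mean (DC) is
#' removed and a one-sided rectangular-window periodogram is returned.
#' The scaling satisfies Parseval's identity:
#' `sum(power) * fs / samples_per_epoch == mean(w_demeaned^2)`.
#'
#' @inheritParams spatial_weight_map
#' @param fs Sampling rate in Hz.
#' @param signed Average signed weights (default `TRUE`, preserving
#'   oscillatory structure); `FALSE` averages absolute weights.
#' @return List with `freq_hz` (0 to fs/2) and `power`.
#' @export
temporal_weight_psd <- function(model, n_channels, samples_per_epoch, fs,
                                signed = TRUE) {
  stopifnot(inherits(model, "network_model"))
  if (n_channels * samples_per_epoch != model$input_dim) {
    stopf("n_channels * samples_per_epoch (%d) != input_dim (%d)",
          n_channels * samples_per_epoch, model$input_dim)
  }
  if (samples_per_epoch < 4) stopf("need at least 4 samples per epoch")
  W1 <- model$weights[[1]]
  if (!signed) W1 <- abs(W1)
  w_time <- vapply(seq_len(samples_per_epoch), function(s) {
    mean(W1[s + (seq_len(n_channels) - 1) * samples_per_epoch, ])
  }, numeric(1))
  w_time <- w_time - mean(w_time)
  S <- samples_per_epoch
  X <- stats::fft(w_time)
  p2 <- Mod(X)^2 / (S * fs)            # two-sided periodogram
  half <- floor(S / 2)
  power <- p2[1:(half + 1)]
  dbl <- 2:(if (S %% 2 == 0) half else half + 1)  # interior bins
  power[dbl] <- 2 * power[dbl]
  list(freq_hz = (0:half) * fs / S, power = power)
}

#' Wilcoxon rank-sum comparison of two groups of layer counts
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum with midranks for ties.  When
#' both groups have at most 10 observations the p-value is computed by
#' exact enumeration of all group assignments (valid under ties); larger
#' groups use the normal approximation with tie correction.
#'
#' @param group_a,group_b Numeric vectors (e.g. hidden-layer counts of the
#'   selected networks under two conditions), both non-empty.
#' @return List with the rank-sum statistic `W` (sum of group-a midranks),
#'   `p_value`, and the `method` used.
#' @export
compare_layer_counts <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stopf("both groups must be non-empty")
  }
  na <- length(group_a)
  nb <- length(group_b)
  ranks <- rank(c(group_a, group_b))   # midranks
  W <- sum(ranks[seq_len(na)])
  EW <- na * (na + nb + 1) / 2
  if (na <= 10 && nb <= 10) {
    combos <- utils::combn(na + nb, na)
    stats_all <- colSums(matrix(ranks[combos], nrow = na))
    p <- mean(abs(stats_all - EW) >= abs(W - EW) - 1e-9)
    return(list(W = W, p_value = p, method = "exact enumeration"))
  }
  n <- na + nb
  tie_counts <- table(ranks)
  tie_term <- sum(tie_counts^3 - tie_counts) / ((n) * (n - 1))
  varW <- na * nb / 12 * ((n + 1) - tie_term)
  if (varW <= 0) return(list(W = W, p_value = 1, method = "normal"))
  z <- (W - EW) / sqrt(varW)
  list(W = W, p_value = 2 * stats::pnorm(-abs(z)), method = "normal")
}

#' Inter-subject transfer comparison of two fitted classifiers
#'
#' Given cross-validation results (fitted with `keep_models = TRUE`) for
#' two subjects recorded with the same montage and epoch geometry, each
#' subject's per-fold model is evaluated on its own held-out fold and on
#' the corresponding test fold of the other subject.  Own-vs-cross kappas
#' are compared with a two-tailed paired t-test over folds.
#'
#' @param cv_a,cv_b `eval_report`s from [crossval()] with
#'   `keep_models = TRUE`.
#' @param data_a,data_b The corresponding [epoch_set()]s.
#' @return List with per-subject own/cross kappa vectors, their means and
#'   SDs, and `p_value`.
#' @export
transfer_test <- function(cv_a, data_a, cv_b, data_b) {
  if (!identical(data_a$channel_names, data_b$channel_names)) {
    only_a <- setdiff(data_a$channel_names, data_b$channel_names)
    only_b <- setdiff(data_b$channel_names, data_a$channel_names)
    stopf("montage mismatch (only in A: %s; only in B: %s)",
          paste(only_a, collapse = ","), paste(only_b, collapse = ","))
  }
  if (dim(data_a$epochs)[3] != dim(data_b$epochs)[3] ||
      data_a$fs != data_b$fs) {
    stopf("epoch geometry differs between subjects")
  }
  if (is.null(cv_a$fold_models) || is.null(cv_b$fold_models)) {
    stopf("crossval() must be run with keep_models = TRUE")
  }
  k <- length(cv_a$fold_models)
  if (length(cv_b$fold_models) != k) stopf("fold counts differ")
  eval_on <- function(model, es, idx) {
    sub <- subset_epochs(es, idx)
    cohens_kappa(confusion_matrix(sub$labels,
                                  predict_class(model, flatten_epochs(sub)),
                                  length(es$class_names)))
  }
  own_a <- vapply(cv_a$per_fold, `[[`, numeric(1), "kappa")
  own_b <- vapply(cv_b$per_fold, `[[`, numeric(1), "kappa")
  cross_a <- vapply(seq_len(k), function(f) {
    eval_on(cv_a$fold_models[[f]], data_b, cv_b$folds[[f]])
  }, numeric(1))
  cross_b <- vapply(seq_len(k), function(f) {
    eval_on(cv_b$fold_models[[f]], data_a, cv_a$folds[[f]])
  }, numeric(1))
  own <- c(own_a, own_b)
  cross <- c(cross_a, cross_b)
  p <- if (stats::sd(own - cross) < 1e-15) 1 else
    stats::t.test(own, cross, paired = TRUE)$p.value
  list(own_kappa_a = own_a, cross_kappa_a = cross_a,
       own_kappa_b = own_b, cross_kappa_b = cross_b,
       own_mean = mean(own), own_sd = stats::sd(own),
       cross_mean = mean(cross), cross_sd = stats::sd(cross),
       p_value = p)
}
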