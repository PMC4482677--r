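#' Load an experiment configuration from YAML
#'
#' The YAML mirrors the module configurations (`synth`, `labeling`,
#' `train`, `sa`, `ga`) plus top-level fields `seed`, `k_folds`,
#' `include_rest`, `search` (`"ga"` or `"fixed"`), and `hidden_sizes`
#' (used when `search: fixed`).  Missing fields take the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A named list of class `experiment_config`.
#' @export
load_experiment_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  experiment_config(yaml::read_yaml(path))
}

#' Build an experiment configuration
#'
#' @param cfg Named list of overrides (see [load_experiment_config()]).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(cfg = list()) {
  base <- list(seed = 1L, k_folds = 5L, include_rest = FALSE,
               search = "fixed", hidden_sizes = c(16),
               duration_s = NULL, squeeze_times = NULL,
               input_path = NULL,
               synth = list(), labeling = list(), train = list(),
               sa = list(), ga = list())
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  base$synth <- do.call(synth_config, base$synth)
  if (!is.null(base$labeling$threshold_left)) {
    base$labeling <- do.call(labeling_config, base$labeling)
  }
  base$train <- do.call(train_config, base$train)
  base$sa <- do.call(sa_config, base$sa)
  base$ga <- do.call(ga_config, base$ga)
  structure(base, class = "experiment_config")
}

#' Run the full decoding experiment
#'
#' Pipeline: obtain a continuous recording (from `cfg$input_path`, an EDF
#' file, or simulated via [synth_stream()] when `cfg$duration_s` is set),
#' label it from the EMG channels, build the epoch set, demean epochs,
#' cross-validate the classifier (a fixed architecture or a per-fold
#' genetic-algorithm structure search), and run the post-hoc weight
#' analyses.  All randomness derives from `cfg$seed`.  When `out_dir` is
#' given, writes `report.json`, per-fold confusion matrices, the
#' GA fitness history, and the spatial/temporal weight analyses as CSV.
#'
#' @param cfg An [experiment_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return The `eval_report` from [crossval()], with the labeling events,
#'   spatial map, and temporal PSD attached.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  seeds <- derive_seeds(cfg$seed, 4L)

  if (!is.null(cfg$input_path)) {
    if (!file.exists(cfg$input_path)) {
      stopf("input stage: input path does not exist: %s", cfg$input_path)
    }
    rec <- read_edf(cfg$input_path)
    truth <- NULL
  } else if (!is.null(cfg$duration_s)) {
    sim <- synth_stream(cfg$duration_s, cfg$squeeze_times,
                        replace_seed(cfg$synth, seeds[[1L]]))
    rec <- sim$recording
    truth <- sim$events
  } else {
    stopf("input stage: provide either input_path or duration_s")
  }

  if (!inherits(cfg$labeling, "labeling_config")) {
    emg <- which(rec$channel_kinds == "EMG")
    thr <- suggest_threshold(rec$data[emg[1], seq_len(min(
      ncol(rec$data), round(rec$fs)))], rec$fs)
    cfg$labeling <- labeling_config(threshold_left = thr)
  }
  labeled <- label_recording(rec, cfg$labeling, cfg$include_rest,
                             seed = seeds[[2L]])
  es <- demean_epochs(labeled$epochs)

  pipeline <- make_pipeline(cfg)
  report <- crossval(es, cfg$k_folds, pipeline, seed = seeds[[3L]],
                     keep_models = TRUE)

  d <- dim(es$epochs)
  maps <- lapply(report$fold_models, spatial_weight_map, n_channels = d[2],
                 samples_per_epoch = d[3], channel_names = es$channel_names,
                 normalize = FALSE)
  raw_mean <- Reduce(`+`, maps) / length(maps)
  rng <- range(raw_mean)
  report$spatial_map <- if (diff(rng) > 0) {
    (raw_mean - rng[1]) / diff(rng)
  } else raw_mean * 0 + 0.5
  psds <- lapply(report$fold_models, temporal_weight_psd,
                 n_channels = d[2], samples_per_epoch = d[3], fs = es$fs)
  report$temporal_psd <- list(
    freq_hz = psds[[1]]$freq_hz,
    power_mean = Reduce(`+`, lapply(psds, `[[`, "power")) / length(psds),
    power_min = do.call(pmin, lapply(psds, `[[`, "power")),
    power_max = do.call(pmax, lapply(psds, `[[`, "power")))
  report$events <- labeled$events
  report$truth_events <- truth

  if (!is.null(out_dir)) write_experiment(report, es, out_dir)
  report
}

replace_seed <- function(cfg, seed) {
  cfg$seed <- as.integer(seed)
  cfg
}

make_pipeline <- function(cfg) {
  if (identical(cfg$search, "ga")) {
    function(train_es, seed) {
      run_ga(flatten_epochs(train_es), train_es$labels,
             replace_seed(cfg$ga, seed), cfg$train, cfg$sa)$best_model
    }
  } else {
    function(train_es, seed) {
      X <- flatten_epochs(train_es)
      model <- init_network(ncol(X), cfg$hidden_sizes,
                            length(train_es$class_names), seed = seed)
      sa_train(model, X, train_es$labels, replace_seed(cfg$train, seed),
               replace_seed(cfg$sa, seed))$model
    }
  }
}

write_experiment <- function(report, es, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    accuracy = report$accuracy, kappa = report$kappa,
    kappa_se0 = report$kappa_se0, p_value = report$p_value,
    kappa_mean = report$kappa_mean, kappa_sd = report$kappa_sd,
    accuracy_mean = report$accuracy_mean, accuracy_sd = report$accuracy_sd,
    per_fold_kappa = vapply(report$per_fold, `[[`, numeric(1), "kappa"),
    confusion = report$confusion,
    class_names = es$class_names)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(report$confusion),
                   file.path(out_dir, "confusion.csv"))
  utils::write.csv(data.frame(channel = names(report$spatial_map),
                              weight = as.numeric(report$spatial_map)),
                   file.path(out_dir, "spatial_map.csv"), row.names = FALSE)
  utils::write.csv(data.frame(freq_hz = report$temporal_psd$freq_hz,
                              power_mean = report$temporal_psd$power_mean,
                              power_min = report$temporal_psd$power_min,
                              power_max = report$temporal_psd$power_max),
                   file.path(out_dir, "temporal_psd.csv"),
                   row.names = FALSE)
  if (!is.null(report$events)) {
    utils::write.csv(report$events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}
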