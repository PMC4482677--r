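# Shared fixtures: everything is generated in code at test time.

# Random labeled epoch set with given geometry.
rand_epoch_set <- function(n = 6, n_channels = 3, n_samples = 10,
                           n_classes = 2, fs = 25, seed = 1) {
  set.seed(seed)
  epoch_set(array(rnorm(n * n_channels * n_samples),
                  dim = c(n, n_channels, n_samples)),
            labels = rep_len(seq_len(n_classes), n),
            class_names = paste0("C", seq_len(n_classes)),
            fs = fs, window = c(0, n_samples / fs),
            channel_names = paste0("CH", seq_len(n_channels)))
}

# Independent kappa oracle (library route, not our formula).
kappa_oracle <- function(cm) e1071::classAgreement(cm)$kappa

# Random confusion matrix with positive total count.
rand_cm <- function(k = 2, lambda = 10) {
  repeat {
    cm <- matrix(rpois(k * k, lambda), k, k)
    if (sum(cm) > 0) return(cm)
  }
}

# Quick training pipeline for cross-validation tests.
quick_pipeline <- function(hidden = 8, iters = 40, patience = 8) {
  function(train_es, seed) {
    X <- flatten_epochs(train_es)
    scg_train(init_network(ncol(X), hidden, length(train_es$class_names),
                           seed = seed),
              X, train_es$labels,
              train_config(max_iterations = iters, patience = patience,
                           seed = seed))$model
  }
}
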