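#' Confusion matrix from true and predicted labels
#'
#' Rows index the true class, columns the predicted class.
#'
#' @param y_true,y_pred Integer class labels in `1:n_classes` (equal length).
#' @param n_classes Number of classes (default: largest label seen).
#' @param class_names Optional character vector of class names used as
#'   dimnames.
#' @return An `n_classes x n_classes` integer matrix of counts with the true
#'   class on rows.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = NULL,
                             class_names = NULL) {
  if (length(y_true) != length(y_pred)) {
    stopf("y_true and y_pred have different lengths (%d vs %d)",
          length(y_true), length(y_pred))
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (is.null(n_classes)) n_classes <- max(y_true, y_pred, 1L)
  if (any(y_true < 1L | y_true > n_classes) ||
      any(y_pred < 1L | y_pred > n_classes)) {
    stopf("labels out of range 1..%d", n_classes)
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  if (!is.null(class_names)) dimnames(cm) <- list(true = class_names,
                                                  predicted = class_names)
  cm
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o = trace/N` and expected-by-chance agreement
#' `p_e = sum_i row_i * col_i / N^2`.  Returns 0 in the degenerate case
#' `p_e == 1` (all mass in one row and column).
#'
#' @param cm Square count matrix (true classes on rows).
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stopf("confusion matrix must be square")
  n <- sum(cm)
  if (n < 1) stopf("empty confusion matrix")
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps) return(0)
  (p_o - p_e) / (1 - p_e)
}

#' Large-sample significance test of Cohen's kappa against chance
#'
#' Tests H0: kappa = 0 using the null standard error
#' `SE0 = sqrt(p_e + p_e^2 - sum_i p_i. p.i (p_i. + p.i)) / ((1 - p_e) sqrt(N))`
#' and a two-sided normal p-value.
#'
#' @param cm Square count matrix, total N >= 2.
#' @return List with `kappa`, `se0`, `z` and `p_value`.
#' @export
kappa_significance <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n < 2) stopf("need at least 2 observations")
  k <- cohens_kappa(cm)
  pr <- rowSums(cm) / n
  pc <- colSums(cm) / n
  p_e <- sum(pr * pc)
  if (abs(1 - p_e) < .Machine$double.eps) {
    warning("degenerate marginals (p_e = 1); kappa significance undefined")
    return(list(kappa = k, se0 = NA_real_, z = NA_real_, p_value = NA_real_))
  }
  se0 <- sqrt(p_e + p_e^2 - sum(pr * pc * (pr + pc))) / ((1 - p_e) * sqrt(n))
  z <- k / se0
  list(kappa = k, se0 = se0, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Detection and laterality accuracies of a three-class classifier
#'
#' For a movement task with classes ordered (LEFT, RIGHT, NO_MOVEMENT):
#' detection accuracy is the fraction of true movement trials predicted as
#' movement (either side); laterality accuracy is the fraction of correct
#' sides among movement trials that were predicted as movement.
#'
#' @param cm 3x3 count matrix with classes ordered (LEFT, RIGHT,
#'   NO_MOVEMENT).
#' @return List with `acc_laterality_given_detected` and `acc_detection`
#'   (either is `NA` with a warning when its denominator is zero).
#' @export
detection_and_laterality <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != 3 || ncol(cm) != 3) {
    stopf("expected a 3x3 confusion matrix ordered (LEFT, RIGHT, NO_MOVEMENT)")
  }
  movement_rows <- cm[1:2, , drop = FALSE]
  n_movement <- sum(movement_rows)
  detected <- sum(movement_rows[, 1:2])
  acc_detection <- if (n_movement > 0) detected / n_movement else {
    warning("no movement trials; detection accuracy undefined")
    NA_real_
  }
  acc_lat <- if (detected > 0) (cm[1, 1] + cm[2, 2]) / detected else {
    warning("no movement trials predicted as movement; laterality undefined")
    NA_real_
  }
  list(acc_laterality_given_detected = acc_lat, acc_detection = acc_detection)
}

fold_report <- function(cm) {
  sig <- suppressWarnings(kappa_significance(cm))
  list(confusion = cm,
       accuracy = sum(diag(cm)) / sum(cm),
       kappa = sig$kappa,
       kappa_se0 = sig$se0,
       p_value = sig$p_value)
}

#' Stratified k-fold cross-validation of a training pipeline
#'
#' Partitions the epochs into `k` disjoint, class-stratified test folds.
#' For each fold the `pipeline` is fitted on the remaining epochs only (any
#' internal train/validation split the pipeline performs is drawn from that
#' 80%; the test fold is never seen during fitting) and evaluated on the
#' held-out fold.
#'
#' @param es An [epoch_set()].
#' @param k Number of folds (default 5); every class must have at least `k`
#'   members.
#' @param pipeline Function `(train_es, seed)` returning a fitted
#'   `network_model` (or any object accepted by [predict_class()]).
#' @param seed Integer seed controlling fold allocation and per-fold
#'   pipeline seeds.
#' @param keep_models Keep the fitted per-fold models in the report
#'   (needed by [transfer_test()] and fold-averaged weight analyses).
#' @return An object of class `eval_report`: pooled confusion matrix,
#'   accuracy, kappa, null SE, p-value, per-fold reports, fold index sets,
#'   and mean/sd of per-fold kappa and accuracy.
#' @export
crossval <- function(es, k = 5, pipeline, seed = 1, keep_models = FALSE) {
  stopifnot(inherits(es, "epoch_set"))
  if (k < 2) stopf("k must be >= 2")
  y <- es$labels
  counts <- tabulate(y, nbins = length(es$class_names))
  if (any(counts < k)) {
    stopf("every class needs >= k = %d epochs (have: %s)", k,
          paste(counts, collapse = ", "))
  }
  seeds <- derive_seeds(seed, k + 1L)
  folds <- stratified_folds(y, k, seeds[[1L]])
  per_fold <- vector("list", k)
  models <- vector("list", k)
  n_classes <- length(es$class_names)
  pooled <- matrix(0L, n_classes, n_classes)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_es <- subset_epochs(es, setdiff(seq_along(y), test_idx))
    test_es <- subset_epochs(es, test_idx)
    model <- pipeline(train_es, seeds[[f + 1L]])
    pred <- predict_class(model, flatten_epochs(test_es))
    cm <- confusion_matrix(test_es$labels, pred, n_classes, es$class_names)
    per_fold[[f]] <- fold_report(cm)
    pooled <- pooled + cm
    if (keep_models) models[[f]] <- model
  }
  dimnames(pooled) <- list(true = es$class_names, predicted = es$class_names)
  rep <- fold_report(pooled)
  rep$per_fold <- per_fold
  rep$folds <- folds
  rep$kappa_mean <- mean(vapply(per_fold, `[[`, numeric(1), "kappa"))
  rep$kappa_sd <- stats::sd(vapply(per_fold, `[[`, numeric(1), "kappa"))
  rep$accuracy_mean <- mean(vapply(per_fold, `[[`, numeric(1), "accuracy"))
  rep$accuracy_sd <- stats::sd(vapply(per_fold, `[[`, numeric(1), "accuracy"))
  if (keep_models) rep$fold_models <- models
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Cross-validated evaluation\n")
  cat(sprintf("  pooled accuracy: %.3f   kappa: %.3f (p = %.3g)\n",
              x$accuracy, x$kappa, x$p_value))
  if (!is.null(x$kappa_mean)) {
    cat(sprintf("  per-fold kappa: %.3f +/- %.3f over %d folds\n",
                x$kappa_mean, x$kappa_sd, length(x$per_fold)))
  }
  invisible(x)
}
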