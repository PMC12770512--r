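#' Confusion matrix from label vectors
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param class_names Ordered class set; defaults to the sorted union of the
#'   labels.
#' @return A `confusion_matrix` object: integer `K x K` matrix, rows = true
#'   class, columns = predicted class.
#' @export
confusion_from_predictions <- function(true_labels, predicted_labels,
                                       class_names = NULL) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    abort_data("label vectors must have equal length")
  }
  if (is.null(class_names)) {
    class_names <- sort(unique(c(true_labels, predicted_labels)))
  }
  unknown <- setdiff(unique(c(true_labels, predicted_labels)), class_names)
  if (length(unknown) > 0L) {
    abort_data(sprintf("unknown label(s): %s", paste(unknown, collapse = ", ")))
  }
  k <- length(class_names)
  counts <- matrix(0L, k, k, dimnames = list(true = class_names,
                                             predicted = class_names))
  if (length(true_labels) > 0L) {
    tab <- table(factor(true_labels, levels = class_names),
                 factor(predicted_labels, levels = class_names))
    counts[] <- as.integer(tab)
  }
  structure(counts, class = c("confusion_matrix", "matrix", "array"))
}

#' Build a confusion matrix from explicit counts
#'
#' @param counts `K x K` matrix of non-negative integers (rows = true).
#' @param class_names Class names (defaults to existing dimnames).
#' @return A `confusion_matrix` object.
#' @export
as_confusion_matrix <- function(counts, class_names = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || any(counts < 0)) {
    abort_input("counts must be a square non-negative matrix")
  }
  if (is.null(class_names)) {
    class_names <- rownames(counts) %||% paste0("class", seq_len(nrow(counts)))
  }
  dimnames(counts) <- list(true = class_names, predicted = class_names)
  structure(counts, class = c("confusion_matrix", "matrix", "array"))
}

#' Per-class and overall metrics from a confusion matrix
#'
#' One-vs-rest decomposition per class: `Tp` the diagonal entry, `Fp` the
#' column sum minus `Tp`, `Fn` the row sum minus `Tp`, `Tn` the remainder.
#' Precision `Tp/(Tp+Fp)`, recall `Tp/(Tp+Fn)`, F1 the harmonic mean of the
#' two; overall accuracy is the trace over the total. Ratios with a zero
#' denominator are reported as `NA` (undefined), never silently as 0.
#'
#' @param cm A `confusion_matrix`.
#' @return Object of class `class_metrics` with `per_class` (tibble:
#'   `class`, `tp`, `fp`, `fn`, `tn`, `support`, `precision`, `recall`,
#'   `f1`), `accuracy`, and macro averages.
#' @export
metrics_from_confusion <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) cm <- as_confusion_matrix(cm)
  total <- sum(cm)
  if (total == 0) abort_input("confusion matrix is empty")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  per_class <- tibble::tibble(
    class = rownames(cm), tp = as.integer(tp), fp = as.integer(fp),
    fn = as.integer(fn), tn = as.integer(tn),
    support = as.integer(rowSums(cm)),
    precision = unname(precision), recall = unname(recall), f1 = unname(f1))
  structure(list(per_class = per_class,
                 accuracy = sum(tp) / total,
                 macro_precision = mean(precision),
                 macro_recall = mean(recall),
                 macro_f1 = mean(f1),
                 confusion = cm),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.6f\n", x$accuracy))
  print(x$per_class, ...)
  cat("Note: exact 1.0 is reported as 1.0 (no 0.999999-style capping).\n")
  invisible(x)
}

#' @export
tidy.class_metrics <- function(x, ...) x$per_class

#' @export
glance.class_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall, macro_f1 = x$macro_f1,
                 n = sum(x$confusion))
}

#' Summarise per-fold metric values
#'
#' Mean, sample (n-1) standard deviation, standard error `sd/sqrt(n)`,
#' coefficient of variation `sd/mean`, and a normal-quantile confidence
#' interval `mean +/- z * se` (`z = 1.96` for 95%). Values are kept at full
#' precision; any rounding is left to the presentation layer.
#'
#' @param values Numeric per-fold metric values (percent scale typical).
#' @param z Normal quantile for the confidence interval (default 1.96).
#' @return Object of class `fold_summary`.
#' @export
summarize_folds <- function(values, z = 1.96) {
  values <- as.numeric(values)
  if (length(values) < 2L) abort_stats("need at least two fold values")
  m <- mean(values)
  s <- stats::sd(values)
  se <- s / sqrt(length(values))
  structure(list(values = values, n = length(values), mean = m, sd = s,
                 se = se,
                 cov = if (is.finite(m) && m != 0) s / m else NA_real_,
                 ci_low = m - z * se, ci_high = m + z * se, z = z),
            class = "fold_summary")
}

#' @export
print.fold_summary <- function(x, ...) {
  cat(sprintf("folds: %d  mean %.2f  sd %.2f  se %.4f  CI[%.2f, %.2f]\n",
              x$n, x$mean, x$sd, x$se, x$ci_low, x$ci_high))
  invisible(x)
}

#' @export
tidy.fold_summary <- function(x, ...) {
  tibble::tibble(fold = seq_len(x$n), value = x$values)
}

#' @export
glance.fold_summary <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd, se = x$se, cov = x$cov,
                 ci_low = x$ci_low, ci_high = x$ci_high, n = x$n)
}

#' Stratified cross-validation driver
#'
#' For each fold: fit on the union of the other folds, predict the held-out
#' fold, and compute accuracy plus macro precision/recall/F1 (percent
#' scale). Fitting and prediction are pluggable so the driver works with
#' the hybrid model, a mock predictor, or any other classifier.
#'
#' @param manifest Manifest tibble with `fold` assignments (see
#'   [stratified_kfold()]).
#' @param fit_fun `function(train_manifest) -> fitted object`.
#' @param predict_fun `function(fitted, test_manifest) -> character labels`.
#' @return List of class `cv_result`: `per_fold` (tibble of fold metrics),
#'   `summaries` (named list of [summarize_folds()] objects for accuracy,
#'   precision, recall, f1), and `confusions` (per-fold confusion matrices).
#' @export
run_cross_validation <- function(manifest, fit_fun, predict_fun) {
  manifest <- assert_manifest(manifest)
  if (anyNA(manifest$fold)) abort_data("manifest rows lack fold assignments")
  folds <- sort(unique(manifest$fold))
  class_names <- sort(unique(manifest$label))

  rows <- vector("list", length(folds))
  confusions <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    f <- folds[i]
    train_m <- dplyr::filter(manifest, .data$fold != f)
    test_m <- dplyr::filter(manifest, .data$fold == f)
    fitted <- fit_fun(train_m)
    pred <- as.character(predict_fun(fitted, test_m))
    cm <- confusion_from_predictions(test_m$label, pred, class_names)
    met <- metrics_from_confusion(cm)
    confusions[[i]] <- cm
    rows[[i]] <- tibble::tibble(
      fold = f,
      accuracy = 100 * met$accuracy,
      precision = 100 * met$macro_precision,
      recall = 100 * met$macro_recall,
      f1 = 100 * met$macro_f1)
  }
  per_fold <- dplyr::bind_rows(rows)
  summaries <- lapply(c(accuracy = "accuracy", precision = "precision",
                        recall = "recall", f1 = "f1"),
                      function(col) summarize_folds(per_fold[[col]]))
  structure(list(per_fold = per_fold, summaries = summaries,
                 confusions = confusions),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  print(x$per_fold, ...)
  print(x$summaries$accuracy)
  invisible(x)
}

#' External-test summary table
#'
#' @param rows Tibble/data frame with columns `class`, `n_tested`,
#'   `n_correct` (and optionally `n_misclassified`, validated when given).
#' @return Tibble with per-class `accuracy_pct` plus an `overall` row.
#' @export
external_test_report <- function(rows) {
  rows <- tibble::as_tibble(rows)
  need <- c("class", "n_tested", "n_correct")
  if (!all(need %in% names(rows))) {
    abort_input(sprintf("rows must have columns: %s", paste(need, collapse = ", ")))
  }
  if (any(rows$n_tested <= 0)) abort_input("`n_tested` must be positive")
  if (any(rows$n_correct < 0 | rows$n_correct > rows$n_tested)) {
    abort_input("`n_correct` must lie in [0, n_tested]")
  }
  if ("n_misclassified" %in% names(rows) &&
      any(rows$n_correct + rows$n_misclassified != rows$n_tested)) {
    abort_input("n_correct + n_misclassified must equal n_tested")
  }
  rows$n_misclassified <- rows$n_tested - rows$n_correct
  rows$accuracy_pct <- 100 * rows$n_correct / rows$n_tested
  overall <- tibble::tibble(
    class = "overall", n_tested = sum(rows$n_tested),
    n_correct = sum(rows$n_correct),
    n_misclassified = sum(rows$n_misclassified),
    accuracy_pct = 100 * sum(rows$n_correct) / sum(rows$n_tested))
  dplyr::bind_rows(rows[, names(overall)], overall)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
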