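# Classification metrics from 3x3 confusion matrices (per-class and macro
# precision / recall / specificity / F1, accuracy), one-vs-rest ROC-AUC, and
# maximum-softmax confidence analysis.

#' Confusion matrix from truth/prediction vectors
#'
#' @param truth,prediction character or factor vectors over the class levels
#'   (Normal, SCLC, NSCLC by default).
#' @param levels class order (rows = truth, cols = prediction).
#' @return 3x3 integer matrix.
#' @export
confusion_matrix <- function(truth, prediction, levels = CLASS_LEVELS) {
  t_f <- factor(truth, levels = levels)
  p_f <- factor(prediction, levels = levels)
  as.matrix(table(truth = t_f, prediction = p_f))
}

safe_ratio <- function(num, den) ifelse(den == 0, NA_real_, num / den)

#' Classification metrics from a confusion matrix
#'
#' One-vs-rest TP/FP/FN/TN per class; precision, recall (sensitivity),
#' specificity = TN/(TN+FP) and F1, plus accuracy and unweighted macro
#' averages.  All values are percentages; a zero denominator yields `NA`
#' (reported as undefined, never silently 0).
#'
#' @param cm square confusion matrix (rows = truth, cols = prediction).
#' @return object of class `metrics_bundle`: list with `per_class` and
#'   `overall` tibbles (percent scale, unrounded).
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  classes <- rownames(cm)
  if (is.null(classes)) classes <- CLASS_LEVELS[seq_len(nrow(cm))]
  total <- sum(cm)
  tp <- unname(diag(cm))
  fp <- unname(colSums(cm)) - tp
  fn <- unname(rowSums(cm)) - tp
  tn <- total - tp - fp - fn
  precision <- safe_ratio(tp, tp + fp)
  recall <- safe_ratio(tp, tp + fn)
  specificity <- safe_ratio(tn, tn + fp)
  f1 <- safe_ratio(2 * precision * recall, precision + recall)
  per_class <- tibble::tibble(
    class = classes,
    tp = as.integer(tp), fp = as.integer(fp),
    fn = as.integer(fn), tn = as.integer(tn),
    precision = 100 * precision, recall = 100 * recall,
    specificity = 100 * specificity, f1 = 100 * f1
  )
  overall <- tibble::tibble(
    accuracy = 100 * sum(tp) / total,
    macro_precision = 100 * mean(precision),
    macro_recall = 100 * mean(recall),
    macro_specificity = 100 * mean(specificity),
    macro_f1 = 100 * mean(f1)
  )
  structure(list(per_class = per_class, overall = overall, cm = cm),
            class = "metrics_bundle")
}

#' @export
print.metrics_bundle <- function(x, ...) {
  cat("Per-class metrics (%):\n")
  pc <- x$per_class
  pc[, 6:9] <- round(pc[, 6:9], 2)
  print(as.data.frame(pc))
  cat("\nOverall (%):\n")
  print(as.data.frame(round(x$overall, 2)))
  invisible(x)
}

#' Tidy per-class metrics of a bundle
#' @param x a `metrics_bundle`.
#' @param ... unused.
#' @export
tidy.metrics_bundle <- function(x, ...) x$per_class

#' One-row overall summary of a bundle
#' @param x a `metrics_bundle`.
#' @param ... unused.
#' @export
glance.metrics_bundle <- function(x, ...) x$overall

#' One-vs-rest ROC-AUC per class
#'
#' @param truth class labels.
#' @param probabilities matrix (cases x classes) of predicted probabilities,
#'   columns ordered as `levels`; rows should sum to 1.
#' @param levels class order.
#' @return tibble `(class, auc)`; a class absent from (or filling) the truth
#'   vector gets `NA` with a warning.
#' @export
roc_auc <- function(truth, probabilities, levels = CLASS_LEVELS) {
  stopifnot(nrow(probabilities) == length(truth))
  if (max(abs(rowSums(probabilities) - 1)) > 1e-6) {
    stop("probability rows must sum to 1")
  }
  aucs <- vapply(seq_along(levels), function(k) {
    pos <- truth == levels[k]
    if (all(pos) || !any(pos)) {
      warning(sprintf("AUC undefined for class %s (single-class truth)",
                      levels[k]))
      return(NA_real_)
    }
    as.numeric(pROC::auc(pROC::roc(
      response = pos, predictor = probabilities[, k],
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
    )))
  }, numeric(1))
  tibble::tibble(class = levels, auc = aucs)
}

#' Maximum-softmax confidence analysis
#'
#' Per-case maximum softmax probability with correctness, and summary
#' statistics for the correctly and incorrectly classified groups.
#'
#' @param predictions list of [classify()] results, or a tibble with
#'   `predicted_class` and `max_confidence` columns.
#' @param truth true class labels.
#' @return list with `cases` (per-case tibble) and `summary` (per-group mean,
#'   min, max, n).
#' @export
confidence_analysis <- function(predictions, truth) {
  if (!is.data.frame(predictions)) {
    predictions <- dplyr::bind_rows(lapply(predictions, function(p) {
      tibble::tibble(predicted_class = p$predicted_class,
                     max_confidence = p$max_confidence)
    }))
  }
  cases <- dplyr::mutate(predictions,
    truth = truth, correct = .data$predicted_class == truth
  )
  summary <- dplyr::summarise(
    dplyr::group_by(cases, .data$correct),
    n = dplyr::n(),
    mean_confidence = mean(.data$max_confidence),
    min_confidence = min(.data$max_confidence),
    max_confidence = max(.data$max_confidence),
    .groups = "drop"
  )
  list(cases = tibble::as_tibble(cases), summary = summary)
}
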