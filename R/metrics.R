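#' @include AllClasses.R
NULL

#' Confusion-matrix metrics for three-class predictions
#'
#' Accuracy is the confusion-matrix trace over the total. Specificity and
#' F1 are computed one-versus-rest per class and macro-averaged (the
#' symmetric choice for a three-class task). Zero-denominator conventions:
#' precision, recall and F1 are 0 when undefined; specificity is 1 when no
#' negatives exist or none were predicted positive.
#'
#' @param labels true labels (factor/character over LEFT/RIGHT/REST).
#' @param predictions predicted labels, same length.
#' @return a [MetricsReport-class].
#' @export
computeMetrics <- function(labels, predictions) {
  labels <- factor(as.character(labels), levels = CLASS_LEVELS)
  predictions <- factor(as.character(predictions), levels = CLASS_LEVELS)
  if (length(labels) != length(predictions))
    stop("data error: labels and predictions differ in length", call. = FALSE)
  n <- length(labels)
  if (n == 0L)
    stop("undefined metrics: empty input", call. = FALSE)
  if (anyNA(labels) || anyNA(predictions))
    stop("labels/predictions outside the LEFT/RIGHT/REST alphabet", call. = FALSE)
  conf <- table(true = labels, predicted = predictions)
  conf <- matrix(as.integer(conf), 3, 3,
                 dimnames = list(true = CLASS_LEVELS, predicted = CLASS_LEVELS))
  perClass <- data.frame(class = CLASS_LEVELS, recall = NA_real_,
                         specificity = NA_real_, precision = NA_real_,
                         f1 = NA_real_)
  for (k in seq_along(CLASS_LEVELS)) {
    tp <- conf[k, k]
    fn <- sum(conf[k, ]) - tp
    fp <- sum(conf[, k]) - tp
    tn <- n - tp - fn - fp
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    specificity <- if (tn + fp > 0) tn / (tn + fp) else 1
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    perClass[k, -1L] <- c(recall, specificity, precision, f1)
  }
  new("MetricsReport", confusion = conf,
      accuracy = sum(diag(conf)) / n,
      specificity = mean(perClass$specificity),
      f1 = mean(perClass$f1),
      perClass = perClass, n = as.integer(n))
}

#' Convert a metrics report to a plain list (JSON-ready)
#' @param report a [MetricsReport-class].
#' @return nested list with `n`, `confusion`, `accuracy`,
#'   `specificity_macro`, `f1_macro` and `per_class`.
#' @export
metricsToList <- function(report) {
  stopifnot(is(report, "MetricsReport"))
  list(n = report@n,
       confusion = unname(apply(report@confusion, 1L, as.integer, simplify = FALSE)),
       accuracy = report@accuracy,
       specificity_macro = report@specificity,
       f1_macro = report@f1,
       per_class = report@perClass)
}
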