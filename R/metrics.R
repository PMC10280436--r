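#' Confusion counts for binary predictions
#'
#' @param labels Integer/logical vector of true classes (1/TRUE = positive).
#' @param predicted Vector of predicted classes, same coding and length.
#' @return A list of class `confusion_counts` with fields `tp`, `fp`, `tn`,
#'   `fn`; the four counts partition the instances.
#' @export
confusion <- function(labels, predicted) {
  y <- as_binary_labels(labels)
  p <- as_binary_labels(predicted)
  if (length(y) != length(p)) stop("labels and predictions differ in length", call. = FALSE)
  out <- list(
    tp = sum(y == 1L & p == 1L),
    fp = sum(y == 0L & p == 1L),
    tn = sum(y == 0L & p == 0L),
    fn = sum(y == 1L & p == 0L)
  )
  class(out) <- "confusion_counts"
  out
}

# Coerce the accepted label encodings (0/1, logical, "positive"/"negative",
# factor) to integer 0/1.
as_binary_labels <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    bad <- setdiff(unique(x), c("positive", "negative"))
    if (length(bad) > 0L) stop("unknown label value: ", bad[1L], call. = FALSE)
    return(as.integer(x == "positive"))
  }
  if (is.logical(x)) return(as.integer(x))
  x <- as.integer(x)
  if (!all(x %in% c(0L, 1L))) stop("labels must be binary (0/1)", call. = FALSE)
  x
}

counts_total <- function(counts) counts$tp + counts$fp + counts$tn + counts$fn

check_counts <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts_total(counts) == 0L) stop("no evaluated instances (N = 0)", call. = FALSE)
}

# Ratio with the zero-denominator convention: returns 0 and marks the value
# with attr "undefined" instead of erroring, matching the near-zero scores
# degenerate classifiers receive on imbalanced data.
safe_ratio <- function(num, den) {
  if (den == 0) return(structure(0, undefined = TRUE))
  num / den
}

#' Confusion-derived metrics
#'
#' Accuracy (TP+TN)/N, precision TP/(TP+FP), recall = sensitivity
#' TP/(TP+FN), F1 = 2PR/(P+R), specificity TN/(FP+TN). Zero-denominator
#' cases return 0 carrying an `undefined` attribute rather than erroring.
#'
#' @param counts A `confusion_counts` object from [confusion()].
#' @return A numeric scalar.
#' @export
accuracy <- function(counts) {
  check_counts(counts)
  (counts$tp + counts$tn) / counts_total(counts)
}

#' @rdname accuracy
#' @export
precision <- function(counts) {
  check_counts(counts)
  safe_ratio(counts$tp, counts$tp + counts$fp)
}

#' @rdname accuracy
#' @export
recall <- function(counts) {
  check_counts(counts)
  safe_ratio(counts$tp, counts$tp + counts$fn)
}

#' @rdname accuracy
#' @export
sensitivity <- function(counts) recall(counts)

#' @rdname accuracy
#' @export
specificity <- function(counts) {
  check_counts(counts)
  safe_ratio(counts$tn, counts$fp + counts$tn)
}

#' @rdname accuracy
#' @export
f1_score <- function(counts) {
  p <- precision(counts)
  r <- recall(counts)
  if (p + r == 0) return(structure(0, undefined = TRUE))
  2 * p * r / (p + r)
}

#' Binary cross-entropy
#'
#' Mean negative log-likelihood of binary labels under predicted
#' probabilities, natural logarithm, with probabilities clipped to
#' `[clip_eps, 1 - clip_eps]` before taking logs (so perfectly confident
#' wrong predictions yield large finite values rather than infinities).
#'
#' @param labels Binary labels (any accepted coding).
#' @param probabilities Predicted probabilities of the positive class in
#'   `[0, 1]`.
#' @param clip_eps Clipping bound, default `1e-15`.
#' @return Non-negative scalar.
#' @export
binary_cross_entropy <- function(labels, probabilities, clip_eps = 1e-15) {
  y <- as_binary_labels(labels)
  p <- as.numeric(probabilities)
  if (length(y) != length(p)) stop("labels and probabilities differ in length", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  p <- pmin(pmax(p, clip_eps), 1 - clip_eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a randomly chosen positive
#' instance outscores a randomly chosen negative one, ties counted one half
#' (midrank formula); equivalent to the trapezoidal area under the ROC
#' curve and invariant under strictly monotone transforms of the scores.
#'
#' @param labels Binary labels; both classes must be present.
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(labels, scores) {
  y <- as_binary_labels(labels)
  s <- as.numeric(scores)
  if (length(y) != length(s)) stop("labels and scores differ in length", call. = FALSE)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC requires both classes to be present", call. = FALSE)
  }
  r <- rank(s, ties.method = "average")
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full evaluation report
#'
#' Thresholds probabilities at `threshold` to obtain hard labels for the
#' confusion-matrix metrics; uses the probabilities directly for binary
#' cross-entropy and AUC-ROC.
#'
#' @param labels Binary labels.
#' @param probabilities Predicted probabilities of the positive class.
#' @param threshold Classification threshold, default 0.5.
#' @return An object of class `eval_report`: list with `accuracy`,
#'   `binary_cross_entropy`, `precision`, `recall`, `f1`, `sensitivity`,
#'   `specificity`, `auc_roc`, `confusion`, `n_instances`, `n_positive`.
#' @export
evaluate <- function(labels, probabilities, threshold = 0.5) {
  y <- as_binary_labels(labels)
  p <- as.numeric(probabilities)
  counts <- confusion(y, as.integer(p > threshold))
  rep <- list(
    accuracy = accuracy(counts),
    binary_cross_entropy = binary_cross_entropy(y, p),
    precision = as.numeric(precision(counts)),
    recall = as.numeric(recall(counts)),
    f1 = as.numeric(f1_score(counts)),
    sensitivity = as.numeric(sensitivity(counts)),
    specificity = as.numeric(specificity(counts)),
    auc_roc = auc_roc(y, p),
    confusion = counts,
    n_instances = length(y),
    n_positive = sum(y == 1L)
  )
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: n=%d (positives=%d)\n", x$n_instances, x$n_positive))
  cat(sprintf("  Acc=%.4f  BC=%.4f  F1=%.4f  AUC=%.4f  Sn=%.4f  Sp=%.4f\n",
              x$accuracy, x$binary_cross_entropy, x$f1, x$auc_roc,
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `eval_report`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  obj <- list(
    accuracy = report$accuracy, bc = report$binary_cross_entropy,
    f1 = report$f1, auc_roc = report$auc_roc,
    precision = report$precision, recall = report$recall,
    sensitivity = report$sensitivity, specificity = report$specificity,
    confusion = list(tp = report$confusion$tp, fp = report$confusion$fp,
                     tn = report$confusion$tn, fn = report$confusion$fn),
    n = report$n_instances, n_positive = report$n_positive
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
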