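# Mask-aware pooled confusion-matrix metrics.
#
# All F1-style metrics work on a single pooled 4x4 confusion matrix
# (rows = truth, columns = prediction, classes intergenic/UTR/CDS/intron).
# Per-class TP/FP/FN are summed over the considered class subset
# (micro-averaging) before precision, recall and F1 are formed, so a base
# whose true class and predicted class are both inside the subset but
# disagree counts as one FP and one FN. The Genic F1 pools {UTR, CDS,
# intron}; the Subgenic F1 pools {CDS, intron}; neither looks at correct
# intergenic calls. Accuracy is trace/total over all four classes.

#' Convert per-base class probabilities to hard class calls
#'
#' Applies an argmax per base. Ties are broken deterministically: the
#' probabilities are rounded to 1e-9 first and the lowest class index among
#' the maxima wins.
#'
#' @param probs numeric matrix, one row per base, one column per class
#'   (intergenic, UTR, CDS, intron).
#' @return integer vector of class indices in 1..ncol(probs).
#' @export
argmax_classes <- function(probs) {
  stopifnot(is.matrix(probs))
  max.col(round(probs, 9), ties.method = "first")
}

#' Pooled confusion matrix over unmasked bases
#'
#' Bases with sample weight 0 (annotation errors, padding) are excluded;
#' every remaining base increments exactly one cell.
#'
#' @param pred predicted classes: an integer vector of class indices (1..4),
#'   or a probability matrix (rows = bases) which is argmax-ed first.
#' @param truth true classes as an integer vector of class indices, or a
#'   label track as produced by [encode_labels()].
#' @param weights per-base weights in `{0, 1}`; defaults to the track's
#'   weights when `truth` is a label track, else all 1.
#' @return 4x4 integer matrix of class `"confusion_matrix4"`, rows = truth.
#' @export
confusion <- function(pred, truth, weights = NULL) {
  if (inherits(truth, "label_track")) {
    if (is.null(weights)) weights <- truth$weights
    truth <- truth$classes
  }
  if (is.matrix(pred)) pred <- argmax_classes(pred)
  if (length(pred) != length(truth))
    stopf("length mismatch: %d predictions vs %d truth bases",
          length(pred), length(truth))
  if (is.null(weights)) weights <- rep(1L, length(truth))
  if (length(weights) != length(truth))
    stopf("weights length does not match track length")
  keep <- weights > 0
  cm <- table(factor(truth[keep], levels = 1:4),
              factor(pred[keep], levels = 1:4))
  cm <- matrix(as.integer(cm), 4, 4,
               dimnames = list(truth = CLASS_NAMES, pred = CLASS_NAMES))
  structure(cm, class = c("confusion_matrix4", "matrix", "array"))
}

class_indices <- function(classes) {
  if (is.character(classes)) {
    idx <- match(tolower(classes), CLASS_NAMES)
    if (anyNA(idx)) stopf("unknown class name(s): %s",
                          paste(classes[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(classes)
}

#' Micro-averaged precision, recall and F1 over a class subset
#'
#' TP, FP and FN are summed over the subset, then combined. The degenerate
#' case TP+FP = 0 and TP+FN = 0 yields all three values 0 with a warning.
#'
#' @param cm a 4x4 confusion matrix from [confusion()].
#' @param classes class subset, by index (1..4) or name.
#' @return named list with `precision`, `recall`, `f1`.
#' @export
pooled_f1 <- function(cm, classes) {
  idx <- class_indices(classes)
  if (length(idx) == 0) stopf("class subset must be non-empty")
  tp <- sum(diag(cm)[idx])
  fp <- sum(colSums(cm)[idx]) - tp
  fn <- sum(rowSums(cm)[idx]) - tp
  if (tp + fp == 0 && tp + fn == 0) {
    warnf("no bases of the considered classes were observed or predicted; metrics defined as 0")
    return(list(precision = 0, recall = 0, f1 = 0))
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1)
}

#' @rdname pooled_f1
#' @export
genic_f1 <- function(cm) pooled_f1(cm, c("utr", "cds", "intron"))$f1

#' @rdname pooled_f1
#' @export
subgenic_f1 <- function(cm) pooled_f1(cm, c("cds", "intron"))$f1

#' Base-wise accuracy over all four classes
#'
#' @param cm a 4x4 confusion matrix from [confusion()].
#' @return correctly predicted bases / total evaluated bases.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stopf("empty confusion matrix: no unmasked bases evaluated")
  sum(diag(cm)) / total
}

#' Full per-class metrics report
#'
#' One row per class with TP/FP/FN, precision, recall and F1, followed by
#' the pooled `genic_f1`, `subgenic_f1` and `accuracy` rows.
#'
#' @param cm a 4x4 confusion matrix from [confusion()].
#' @return data.frame suitable for writing as TSV.
#' @export
metrics_report <- function(cm) {
  rows <- lapply(1:4, function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    m <- suppressWarnings(pooled_f1(cm, i))
    data.frame(class = CLASS_NAMES[i], TP = tp, FP = fp, FN = fn,
               precision = m$precision, recall = m$recall, F1 = m$f1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pooled <- data.frame(
    class = c("genic_f1", "subgenic_f1", "accuracy"),
    TP = NA, FP = NA, FN = NA, precision = NA, recall = NA,
    F1 = c(suppressWarnings(genic_f1(cm)),
           suppressWarnings(subgenic_f1(cm)),
           accuracy(cm)),
    stringsAsFactors = FALSE)
  rbind(out, pooled)
}
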