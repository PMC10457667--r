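#' Flag cells as novel types by confidence threshold
#'
#' A cell is called novel when its prediction confidence e (max softmax
#' probability over the K reference types) falls strictly below the
#' threshold; a cell exactly at the threshold is called known.
#'
#' @param result an \code{"nclt_prediction"} (or any list with a
#'   \code{confidence} vector).
#' @param threshold confidence cutoff in (0, 1); default 0.5.
#' @return Logical vector, \code{TRUE} = novel.
#' @export
call_novel <- function(result, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  result$confidence < threshold
}

#' Accuracy over cells of common (in-vocabulary) types
#'
#' Cells whose true label is not in the reference vocabulary are novel
#' ground truth and are excluded from the denominator.
#'
#' @param true_labels character vector of true type labels.
#' @param predicted_codes 0-based predicted class codes.
#' @param vocab the reference \code{"label_vocab"}.
#' @return Fraction correct among in-vocabulary cells, or \code{NA} if no
#'   cell has an in-vocabulary label.
#' @export
common_type_accuracy <- function(true_labels, predicted_codes, vocab) {
  truth <- label_codes(vocab, true_labels)
  common <- !is.na(truth)
  if (!any(common)) return(NA_real_)
  mean(predicted_codes[common] == truth[common])
}

#' Per-type F1 scores over common-type cells
#'
#' For each reference class i, F1 = 2 P R / (P + R) with precision
#' P = TP/(TP+FP) and recall R = TP/(TP+FN), counted over cells whose true
#' label is in the vocabulary. A class that is never predicted and never
#' true among the evaluated cells is reported as \code{NA} (absent); a
#' class with zero precision- or recall-denominator gets F1 = 0 and is
#' flagged.
#'
#' @inheritParams common_type_accuracy
#' @return A data.frame with columns \code{class}, \code{f1}, \code{tp},
#'   \code{fp}, \code{fn}, \code{degenerate}.
#' @export
per_type_f1 <- function(true_labels, predicted_codes, vocab) {
  truth <- label_codes(vocab, true_labels)
  common <- !is.na(truth)
  yt <- truth[common]; yp <- predicted_codes[common]
  K <- length(vocab$classes)
  out <- data.frame(class = vocab$classes, f1 = NA_real_,
                    tp = 0L, fp = 0L, fn = 0L, degenerate = FALSE)
  for (k in seq_len(K) - 1L) {
    tp <- sum(yp == k & yt == k)
    fp <- sum(yp == k & yt != k)
    fn <- sum(yp != k & yt == k)
    i <- k + 1L
    out$tp[i] <- tp; out$fp[i] <- fp; out$fn[i] <- fn
    if (tp + fp == 0L && tp + fn == 0L) next     # absent from evaluation
    if (tp + fp == 0L || tp + fn == 0L) {
      out$f1[i] <- 0; out$degenerate[i] <- TRUE
    } else {
      prec <- tp / (tp + fp); rec <- tp / (tp + fn)
      out$f1[i] <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    }
  }
  out
}

#' AUROC for novel-type detection
#'
#' Treats novel-type detection as binary classification scored by the
#' novel-type confidence (1 - e): the AUROC is the probability that a
#' uniformly chosen novel cell scores higher than a uniformly chosen common
#' cell, with ties counting one half (the Mann-Whitney statistic, computed
#' via ranks).
#'
#' @param novel_confidences numeric scores, higher = more likely novel.
#' @param is_novel_truth logical ground truth.
#' @return AUROC in [0, 1], or \code{NA} if either group is empty.
#' @export
novel_auroc <- function(novel_confidences, is_novel_truth) {
  is_novel_truth <- as.logical(is_novel_truth)
  n1 <- sum(is_novel_truth); n0 <- sum(!is_novel_truth)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(novel_confidences, ties.method = "average")
  (sum(r[is_novel_truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Open-set classification rate (OSCR)
#'
#' Area under the curve of the correct classification rate
#' CCR(t) = #\{common cells with correct prediction and e > t\} / #common
#' against the false positive rate
#' FPR(t) = #\{novel cells with e > t\} / #novel, as the threshold t sweeps
#' the confidence values. Computed by the discrete sum
#' \code{sum_j CCR(e_j) / n_novel} over novel cells j: each novel cell
#' contributes the correct-classification rate at a threshold equal to its
#' own confidence (strict inequality on both rates).
#'
#' @param confidences prediction confidences e for every evaluated cell.
#' @param predicted_codes 0-based predicted class codes.
#' @param true_labels character true labels.
#' @param is_novel_truth logical; \code{TRUE} for cells whose true type is
#'   absent from the reference vocabulary.
#' @param vocab the reference \code{"label_vocab"}.
#' @return OSCR in [0, 1], or \code{NA} if either group is empty.
#' @export
oscr <- function(confidences, predicted_codes, true_labels, is_novel_truth,
                 vocab) {
  is_novel_truth <- as.logical(is_novel_truth)
  n_novel <- sum(is_novel_truth); n_common <- sum(!is_novel_truth)
  if (n_novel == 0L || n_common == 0L) return(NA_real_)
  truth <- label_codes(vocab, true_labels)
  correct <- !is_novel_truth & !is.na(truth) & predicted_codes == truth
  # CCR at threshold t: fraction of common cells correct with e > t;
  # evaluated at each novel cell's own confidence via a sorted sweep
  ec <- sort(confidences[correct])
  en <- confidences[is_novel_truth]
  # count of correct common cells with e > t = n_correct - (# <= t)
  ccr_at <- (length(ec) - findInterval(en, ec)) / n_common
  sum(ccr_at) / n_novel
}

#' Full evaluation report for a prediction
#'
#' Combines common-type accuracy, per-type F1, novel-type AUROC and OSCR
#' into one report. Novel ground truth is defined as a true label absent
#' from the reference vocabulary; AUROC and OSCR are reported as absent
#' (\code{NA}) when the evaluated cells contain no novel (or no common)
#' cells.
#'
#' @param result an \code{"nclt_prediction"}.
#' @param true_labels character true labels aligned to
#'   \code{result$cell_ids}.
#' @param vocab the reference \code{"label_vocab"}; defaults to the
#'   prediction's own class set.
#' @return An object of class \code{"nclt_eval"}: list with
#'   \code{common_accuracy}, \code{per_type_f1} (data.frame),
#'   \code{macro_f1}, \code{novel_auroc}, \code{oscr}, \code{n_common},
#'   \code{n_novel}.
#' @export
evaluate_transfer <- function(result, true_labels, vocab = NULL) {
  if (is.null(vocab))
    vocab <- structure(list(classes = result$classes), class = "label_vocab")
  if (length(true_labels) != length(result$cell_ids))
    stop("need one true label per predicted cell")
  truth_codes <- label_codes(vocab, true_labels)
  is_novel <- is.na(truth_codes)
  f1 <- per_type_f1(true_labels, result$predicted_code, vocab)
  structure(list(
    common_accuracy = common_type_accuracy(true_labels,
                                           result$predicted_code, vocab),
    per_type_f1 = f1,
    macro_f1 = mean(f1$f1, na.rm = TRUE),
    novel_auroc = novel_auroc(result$novel_confidence, is_novel),
    oscr = oscr(result$confidence, result$predicted_code, true_labels,
                is_novel, vocab),
    n_common = sum(!is_novel), n_novel = sum(is_novel)),
    class = "nclt_eval")
}

#' @export
print.nclt_eval <- function(x, ...) {
  cat("Label-transfer evaluation\n")
  cat(sprintf("  cells: %d common, %d novel\n", x$n_common, x$n_novel))
  cat(sprintf("  common-type accuracy: %.4f\n", x$common_accuracy))
  cat(sprintf("  macro F1: %.4f\n", x$macro_f1))
  if (!is.na(x$novel_auroc))
    cat(sprintf("  novel-type AUROC: %.4f\n", x$novel_auroc))
  if (!is.na(x$oscr))
    cat(sprintf("  OSCR: %.4f\n", x$oscr))
  invisible(x)
}

#' Serialize an evaluation report as JSON
#'
#' Novel-type metrics are omitted from the JSON when absent.
#'
#' @param report an \code{"nclt_eval"}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_eval_report <- function(report, path) {
  f1 <- report$per_type_f1
  keep <- !is.na(f1$f1)
  out <- list(common_accuracy = report$common_accuracy,
              macro_f1 = report$macro_f1,
              per_type_f1 = stats::setNames(as.list(f1$f1[keep]),
                                            f1$class[keep]),
              n_common = report$n_common, n_novel = report$n_novel)
  if (!is.na(report$novel_auroc)) out$novel_auroc <- report$novel_auroc
  if (!is.na(report$oscr)) out$oscr <- report$oscr
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Confidence histogram summary by truth group
#'
#' Bins the prediction confidences of common-truth and novel-truth cells on
#' shared bin edges, supporting density-style comparisons of the two
#' confidence distributions.
#'
#' @param confidences prediction confidences e.
#' @param is_novel_truth logical ground truth.
#' @param n_bins number of equal-width bins over [0, 1] (default 20).
#' @return A data.frame with \code{bin_lo}, \code{bin_hi},
#'   \code{count_common}, \code{count_novel}.
#' @export
confidence_histogram <- function(confidences, is_novel_truth, n_bins = 20) {
  edges <- seq(0, 1, length.out = n_bins + 1L)
  cut_idx <- function(x) pmin(pmax(findInterval(x, edges,
                                                rightmost.closed = TRUE), 1L),
                              n_bins)
  tab <- function(x) tabulate(cut_idx(x), nbins = n_bins)
  data.frame(bin_lo = edges[-(n_bins + 1L)], bin_hi = edges[-1L],
             count_common = tab(confidences[!is_novel_truth]),
             count_novel = tab(confidences[is_novel_truth]))
}
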