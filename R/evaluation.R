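#' Confusion-count metrics
#'
#' Builds an `eval_report` from confusion counts with abnormal as the
#' positive class: sensitivity `100*TP/(TP+FN)` (abnormal recordings
#' correctly flagged), specificity `100*TN/(TN+FP)` (normal recordings
#' correctly cleared) and accuracy `100*(TP+TN)/(TP+TN+FP+FN)`.
#'
#' @param TP,TN,FP,FN non-negative confusion counts.
#' @return an `eval_report` with the counts and the three percentages.
#' @examples
#' compute_metrics(TP = 107, TN = 138, FP = 12, FN = 19)
#' @export
compute_metrics <- function(TP, TN, FP, FN) {
  for (v in c(TP, TN, FP, FN))
    if (!is_count(v)) stop_eegwave("counts must be non-negative integers",
                                   "eegwave_parameter_error")
  if (TP + FN == 0)
    stop_eegwave("sensitivity undefined: no positive (abnormal) truths",
                 "eegwave_undefined_metric")
  if (TN + FP == 0)
    stop_eegwave("specificity undefined: no negative (normal) truths",
                 "eegwave_undefined_metric")
  structure(list(
    TP = TP, TN = TN, FP = FP, FN = FN,
    sensitivity = 100 * TP / (TP + FN),
    specificity = 100 * TN / (TN + FP),
    accuracy = 100 * (TP + TN) / (TP + TN + FP + FN)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>  (positive class: abnormal)\n")
  cat(sprintf("  confusion     TP %4d  FN %4d\n                FP %4d  TN %4d\n",
              x$TP, x$FN, x$FP, x$TN))
  cat(sprintf("  sensitivity %6.2f%%  specificity %6.2f%%  accuracy %6.2f%%\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Tidy an evaluation report
#' @param x an `eval_report`.
#' @param ... unused.
#' @return a one-row tibble of counts and metrics.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(TP = x$TP, TN = x$TN, FP = x$FP, FN = x$FN,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 accuracy = x$accuracy)
}

#' Evaluate a model on a segment set
#'
#' Predicts every segment (argmax of the softmax output; a probability tie
#' breaks toward normal) and tallies confusion counts with abnormal as the
#' positive class.  For recording-level evaluation pass original-provenance
#' segments only (see [filter_original()]); reversed augmentations are
#' training-only.
#'
#' @param model a `wavenet_model`.
#' @param segs a non-empty [segment_set()].
#' @return an `eval_report`.
#' @export
evaluate_model <- function(model, segs) {
  stopifnot(inherits(model, "wavenet_model"), inherits(segs, "segment_set"))
  if (n_segments(segs) == 0L)
    stop_eegwave("cannot evaluate an empty segment set",
                 "eegwave_parameter_error")
  pred <- predict(model, segs, type = "class")
  truth <- segs$labels
  compute_metrics(TP = sum(pred == "abnormal" & truth == "abnormal"),
                  TN = sum(pred == "normal" & truth == "normal"),
                  FP = sum(pred == "abnormal" & truth == "normal"),
                  FN = sum(pred == "normal" & truth == "abnormal"))
}

#' Keep original-provenance segments only
#' @param segs a [segment_set()].
#' @return the [segment_set()] restricted to provenance `"original"`.
#' @export
filter_original <- function(segs) {
  subset_segments(segs, segs$provenance == "original")
}

#' Reconstruct accuracy from published per-class rates
#'
#' Given a published sensitivity and specificity (percent) and the class
#' sizes of the evaluation set, recovers the integer confusion counts by
#' nearest-integer rounding (`TP = round(sens * n_pos / 100)`,
#' `TN = round(spec * n_neg / 100)`) and returns the implied overall
#' accuracy `100 * (TP + TN) / (n_pos + n_neg)` - a consistency check
#' between per-class rates and the reported accuracy.
#'
#' @param sensitivity,specificity published rates in percent.
#' @param n_pos,n_neg number of positive (abnormal) and negative (normal)
#'   recordings in the evaluation set.
#' @return implied accuracy in percent.
#' @examples
#' reconstruct_accuracy(84.92, 92, n_pos = 126, n_neg = 150) # ~88.77
#' @export
reconstruct_accuracy <- function(sensitivity, specificity, n_pos, n_neg) {
  stopifnot(sensitivity >= 0, sensitivity <= 100,
            specificity >= 0, specificity <= 100,
            is_count(n_pos), n_pos >= 1, is_count(n_neg), n_neg >= 1)
  TP <- round(sensitivity * n_pos / 100)
  TN <- round(specificity * n_neg / 100)
  100 * (TP + TN) / (n_pos + n_neg)
}

#' Published reference results
#'
#' Published evaluation results used as inputs by the consistency checks:
#' `published_model_results()` gives the per-variant rates of the dual-path
#' model (and its ablations) on the abnormality-screening evaluation set
#' (126 abnormal / 150 normal recordings) plus the epilepsy-screening
#' transfer result (172 abnormal / 64 normal); `published_benchmarks()`
#' lists the accuracies of prior end-to-end methods on the same screening
#' benchmark.
#'
#' @return a tibble.
#' @export
published_model_results <- function() {
  tibble::tibble(
    dataset = c(rep("tuab", 5L), "tuep"),
    variant = c("baseline", "ablation1", "ablation2", "ablation3", "full",
                "full"),
    accuracy = c(83.69, 86.231, 84.06, 78.26, 88.76, 97.45),
    sensitivity = c(80.95, 84.126, 87.3, 73.809, 84.92, 97.09),
    specificity = c(86, 88, 81.33, 82, 92, 98.43),
    n_pos = c(rep(126L, 5L), 172L),
    n_neg = c(rep(150L, 5L), 64L))
}

#' @rdname published_model_results
#' @export
published_benchmarks <- function() {
  tibble::tibble(
    study = c("Yildirim", "Roy (CNN-RNN)", "Schirrmeister", "Khan", "Gemein",
              "Roy (ChronoNet)", "Kiessner", "Amin", "dual-path model"),
    year = c(2020L, 2018L, 2017L, 2023L, 2021L, 2019L, 2023L, 2019L, 2023L),
    accuracy = c(79.34, 82.27, 85.4, 85, 86.1, 86.57, 86.59, 87.32, 88.76))
}
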