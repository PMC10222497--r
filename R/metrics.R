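#' Confusion counts for a binary classifier
#'
#' @param observed,predicted Vectors of 0/1 labels, equal length.
#' @return Object of class \code{"confusion_counts"}: list with integer
#'   fields \code{tp}, \code{tn}, \code{fp}, \code{fn}.
#' @export
confusion_counts <- function(observed, predicted) {
  o <- as.integer(observed); p <- as.integer(predicted)
  if (length(o) != length(p)) stop("length mismatch")
  if (length(o) && (!all(o %in% 0:1) || !all(p %in% 0:1)))
    stop("labels must be 0 or 1")
  structure(list(
    tp = sum(o == 1L & p == 1L),
    tn = sum(o == 0L & p == 0L),
    fp = sum(o == 0L & p == 1L),
    fn = sum(o == 1L & p == 0L)), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  TN %d  FP %d  FN %d  (N = %d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' Classification statistics from confusion counts
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), accuracy (tp+tn)/N and
#' the Matthews correlation coefficient
#' (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)).
#' A zero denominator makes sensitivity/specificity \code{NA} (undefined)
#' and MCC 0 by the usual convention; affected statistics are listed in the
#' \code{degenerate} field.
#'
#' @param counts A \code{"confusion_counts"} object (or a list with fields
#'   tp, tn, fp, fn).
#' @return List with \code{sensitivity}, \code{specificity},
#'   \code{accuracy}, \code{mcc} and a character vector \code{degenerate}.
#' @export
classification_stats <- function(counts) {
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  n <- tp + tn + fp + fn
  degenerate <- character(0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    degenerate <- c(degenerate, "sensitivity"); NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    degenerate <- c(degenerate, "specificity"); NA_real_
  }
  acc <- if (n > 0) (tp + tn) / n else NA_real_
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else {
    degenerate <- c(degenerate, "mcc"); 0
  }
  list(sensitivity = sens, specificity = spec, accuracy = acc, mcc = mcc,
       degenerate = degenerate)
}

#' Matthews correlation coefficient of two 0/1 label vectors
#'
#' Convenience composition of [confusion_counts()] and
#' [classification_stats()].
#'
#' @inheritParams confusion_counts
#' @return MCC in \[-1, 1\] (0 when undefined).
#' @export
mcc_score <- function(observed, predicted) {
  classification_stats(confusion_counts(observed, predicted))$mcc
}

# Half-up rounding to 'digits' decimals (the reporting convention:
# 0.78125 -> 0.7813, where round() would give 0.7812).
round_half_up <- function(x, digits = 4L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Per-set classification report
#'
#' One row per evaluation set plus a Total row, mirroring the usual layout
#' of published semi-correlation models: confusion counts, N and the four
#' derived statistics, rounded half-up to 4 decimal places.
#'
#' @param observed,predicted 0/1 label vectors over all compounds.
#' @param set Character/factor vector assigning each compound to a set.
#' @param set_order Optional ordering of the set names in the report.
#' @return Data frame with columns Set, TP, TN, FP, FN, N, Sensitivity,
#'   Specificity, Accuracy, MCC.
#' @export
classification_report <- function(observed, predicted, set,
                                  set_order = NULL) {
  stopifnot(length(observed) == length(predicted),
            length(observed) == length(set))
  set <- as.character(set)
  sets <- if (is.null(set_order)) unique(set) else set_order
  one_row <- function(name, idx) {
    cc <- confusion_counts(observed[idx], predicted[idx])
    st <- classification_stats(cc)
    data.frame(Set = name, TP = cc$tp, TN = cc$tn, FP = cc$fp, FN = cc$fn,
               N = cc$tp + cc$tn + cc$fp + cc$fn,
               Sensitivity = round_half_up(st$sensitivity),
               Specificity = round_half_up(st$specificity),
               Accuracy = round_half_up(st$accuracy),
               MCC = round_half_up(st$mcc),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(sets, function(s) one_row(s, set == s))
  rows <- c(rows, list(one_row("Total", rep(TRUE, length(set)))))
  do.call(rbind, rows)
}
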