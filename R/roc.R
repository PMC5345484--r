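# ROC analysis of complexity as a QA-failure predictor.
#
# Convention, used consistently with the cohort module: a plan is flagged
# positive when its complexity is strictly greater than the threshold.
# A positive that failed QA is a true positive; a positive that passed QA is
# a false positive.

labeled_records <- function(records) {
  rec <- records[!is.na(records$qa_pass), , drop = FALSE]
  if (nrow(rec) == 0L || all(rec$qa_pass) || all(!rec$qa_pass)) {
    abort("single-class cohort: ROC analysis needs both failing and passing plans")
  }
  rec
}

#' Confusion counts at a complexity threshold
#'
#' @param records labeled cohort data.frame (rows with `NA` qa_pass are
#'   dropped; both classes must remain)
#' @param threshold complexity threshold in 1/mm; positive means strictly
#'   above
#' @return a `confusion_counts` object: `tp`, `fp`, `tn`, `fn`, `tpr`, `fpr`,
#'   `threshold`
#' @export
confusion_at_threshold <- function(records, threshold) {
  rec <- labeled_records(records)
  pos <- rec$complexity_mm_inv > threshold
  fail <- !rec$qa_pass
  tp <- sum(pos & fail); fp <- sum(pos & !fail)
  fn <- sum(!pos & fail); tn <- sum(!pos & !fail)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         tpr = tp / (tp + fn), fpr = fp / (fp + tn),
         threshold = threshold),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> at threshold ", format(x$threshold), " mm^-1: TP ",
      x$tp, ", FP ", x$fp, ", TN ", x$tn, ", FN ", x$fn,
      " | TPR ", as_percent(x$tpr), "%, FPR ", as_percent(x$fpr), "%\n",
      sep = "")
  invisible(x)
}

#' Empirical ROC curve
#'
#' Threshold sweep over all distinct complexities plus `-Inf`/`+Inf`
#' sentinels; each row agrees with [confusion_at_threshold()] at that
#' threshold.  AUC by the trapezoid rule over the step curve (equivalent to
#' the Mann-Whitney statistic with ties counted half).  No smoothing or
#' binormal fit: the curve is the data.
#'
#' @inheritParams confusion_at_threshold
#' @return a `roc_curve` object: `points` (data.frame threshold, fpr, tpr)
#'   ordered by decreasing threshold, and `auc`
#' @export
roc_curve <- function(records) {
  rec <- labeled_records(records)
  thresholds <- c(Inf, sort(unique(rec$complexity_mm_inv), decreasing = TRUE),
                  -Inf)
  fail <- !rec$qa_pass
  n_fail <- sum(fail); n_pass <- sum(!fail)
  pts <- do.call(rbind, lapply(thresholds, function(t) {
    pos <- rec$complexity_mm_inv > t
    data.frame(threshold = t,
               fpr = sum(pos & !fail) / n_pass,
               tpr = sum(pos & fail) / n_fail)
  }))
  # trapezoid over the curve ordered by increasing fpr
  ord <- order(pts$fpr, pts$tpr)
  fpr <- pts$fpr[ord]; tpr <- pts$tpr[ord]
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> ", nrow(x$points), " thresholds, AUC ",
      formatC(x$auc, format = "f", digits = 3), "\n", sep = "")
  invisible(x)
}

#' Recommend a complexity threshold under a false-positive-rate constraint
#'
#' Both TPR and FPR are non-increasing in the threshold, so the smallest
#' threshold whose FPR is strictly below `max_fpr` also has the largest TPR
#' among compliant thresholds.  Candidates are midpoints between adjacent
#' distinct complexities plus sentinels below the minimum and above the
#' maximum, so no datum ever sits exactly at the recommended threshold.
#'
#' @inheritParams confusion_at_threshold
#' @param max_fpr maximum tolerated false-positive rate (default 0.10)
#' @return list with `threshold`, `confusion` (its [confusion_at_threshold()]
#'   counts) and `degenerate` (TRUE when the recommendation flags nothing,
#'   i.e. TPR = 0)
#' @export
recommend_threshold <- function(records, max_fpr = 0.10) {
  rec <- labeled_records(records)
  x <- sort(unique(rec$complexity_mm_inv))
  gap <- if (length(x) > 1L) min(diff(x)) else x[1] * 0.1
  candidates <- c(x[1] - gap / 2,
                  if (length(x) > 1L) (x[-length(x)] + x[-1]) / 2,
                  x[length(x)] + gap / 2)
  for (t in candidates) {
    cc <- confusion_at_threshold(rec, t)
    # max_fpr >= 1 disables the constraint (every rate qualifies)
    if (cc$fpr < max_fpr || max_fpr >= 1) {
      return(list(threshold = t, confusion = cc, degenerate = cc$tpr == 0))
    }
  }
  # unreachable: the top sentinel always has fpr = 0 < max_fpr for max_fpr > 0
  t <- candidates[length(candidates)]
  cc <- confusion_at_threshold(rec, t)
  list(threshold = t, confusion = cc, degenerate = cc$tpr == 0)
}

#' Write an ROC curve as CSV
#'
#' @param roc a [roc_curve()] result
#' @param path output CSV path (columns threshold, fpr, tpr)
#' @return `path`, invisibly
#' @export
write_roc_csv <- function(roc, path) {
  stopifnot(inherits(roc, "roc_curve"))
  write.csv(roc$points, path, row.names = FALSE)
  invisible(path)
}
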