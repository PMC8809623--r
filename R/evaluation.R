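#' Confusion counts
#'
#' Container for true/false positive/negative counts at a chosen
#' aggregation level (\code{bioset} or \code{study}).
#' @param tp,fp,tn,fn non-negative integer counts.
#' @param level aggregation level, \code{"bioset"} or \code{"study"}.
#' @return Object of class \code{confusion_counts}.
#' @export
confusion_counts <- function(tp, fp, tn, fn, level = c("bioset", "study")) {
  level <- match.arg(level)
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn), level = level),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> (%s level) TP=%d FP=%d TN=%d FN=%d\n",
              x$level, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Predictive-accuracy metrics from confusion counts
#'
#' Applies the standard formulas: sensitivity = TP/(TP+FN), specificity =
#' TN/(FP+TN), PPV = TP/(TP+FP), NPV = TN/(TN+FN), balanced accuracy =
#' (sensitivity + specificity)/2. A metric whose denominator is zero is
#' reported as \code{NA} (undefined), never as 0; balanced accuracy is
#' \code{NA} unless both sensitivity and specificity are defined.
#'
#' @param counts a \code{\link{confusion_counts}}.
#' @return list with \code{sensitivity}, \code{specificity}, \code{ppv},
#'   \code{npv}, \code{balanced_accuracy} as ratios in [0, 1], plus a
#'   \code{percent} sub-list with each ratio formatted as a percentage
#'   rounded half away from zero to one decimal.
#' @examples
#' confusion_metrics(confusion_counts(43, 0, 0, 3))$sensitivity  # 0.9348
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(counts$tp, counts$tp + counts$fn)
  spec <- ratio(counts$tn, counts$fp + counts$tn)
  ppv <- ratio(counts$tp, counts$tp + counts$fp)
  npv <- ratio(counts$tn, counts$tn + counts$fn)
  ba <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  out <- list(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
              balanced_accuracy = ba)
  out$percent <- lapply(out, function(r)
    if (is.na(r)) NA_real_ else round_half_away(100 * r, 1L))
  out
}

# round half away from zero (R's round() rounds half to even)
round_half_away <- function(x, digits = 0L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Evaluate calls against truth labels
#'
#' Compares per-bioset activator/suppressor/inconclusive calls against
#' truth labels, with the positive class being activation (by default).
#' Biosets whose truth label is the positive class are the positives; every
#' other labelled bioset (\code{negative}, or the opposite modulation
#' class) is a negative. An inconclusive or suppressor call on a true
#' positive counts as a false negative; an activator call on a true
#' negative counts as a false positive. Biosets labelled \code{unknown}
#' are excluded.
#'
#' At \code{level = "study"}, calls are first collapsed per
#' \code{study_id} with the any-positive rule of
#' \code{\link{study_level_call}}; a study's truth label must be
#' homogeneous across its biosets.
#'
#' @param calls data.frame with columns \code{bioset_id}, \code{call}, and
#'   \code{study_id} when \code{level = "study"} (the \code{biosets} table
#'   of a \code{screen_report} works directly; a \code{factor} column is
#'   used for study grouping when present).
#' @param truth data.frame with columns \code{bioset_id},
#'   \code{truth_label} (activator / suppressor / negative / unknown).
#' @param level \code{"bioset"} or \code{"study"}.
#' @param positive_class truth class treated as positive
#'   (default \code{"activator"}).
#' @return list with \code{counts} (\code{\link{confusion_counts}}) and
#'   \code{metrics} (\code{\link{confusion_metrics}} output).
#' @export
evaluate_predictions <- function(calls, truth, level = c("bioset", "study"),
                                 positive_class = "activator") {
  level <- match.arg(level)
  stopifnot(positive_class %in% c("activator", "suppressor"))
  missing <- setdiff(calls$bioset_id, truth$bioset_id)
  if (length(missing) > 0L) {
    stop(sprintf("missing truth label for bioset(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  merged <- merge(calls, truth, by = "bioset_id")
  merged <- merged[merged$truth_label != "unknown", , drop = FALSE]

  if (level == "study") {
    if (!"study_id" %in% names(merged)) {
      stop("study-level evaluation requires a study_id column", call. = FALSE)
    }
    if (!"factor" %in% names(merged)) merged$factor <- ""
    studies <- study_level_call(merged)
    key <- paste(merged$study_id, normalize_factor(merged$factor), sep = "\r")
    tl <- tapply(merged$truth_label, key, function(x) {
      u <- unique(x)
      if (length(u) > 1L) {
        stop("study has mixed truth labels; cannot evaluate at study level",
             call. = FALSE)
      }
      u
    })
    skey <- paste(studies$study_id, studies$factor, sep = "\r")
    merged <- data.frame(
      call = c(positive = "activator", negative = "suppressor",
               inconclusive = "inconclusive")[studies$call],
      truth_label = as.character(tl[skey]), stringsAsFactors = FALSE)
  }

  is_pos <- merged$truth_label == positive_class
  called_pos <- merged$call == positive_class
  counts <- confusion_counts(
    tp = sum(is_pos & called_pos), fp = sum(!is_pos & called_pos),
    tn = sum(!is_pos & !called_pos), fn = sum(is_pos & !called_pos),
    level = level)
  list(counts = counts, metrics = confusion_metrics(counts))
}
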