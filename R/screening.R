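#' Screen a compendium of biosets against a biomarker
#'
#' Scores every bioset with \code{\link{signed_correlation_score}} and
#' aggregates the activator/suppressor/inconclusive calls at the chemical
#' level (by the normalized \code{factor} string) and at the study level
#' (by \code{study_id} x \code{factor}, any-positive rule). An unreadable or
#' invalid bioset is recorded as an error entry and the screen continues.
#'
#' @param biomarker a \code{\link{biomarker}}.
#' @param compendium list of \code{\link{bioset}} objects.
#' @param threshold significance threshold on the signed score (default 4).
#' @param N optional universe-size override applied to every bioset.
#' @return Object of class \code{screen_report} with components:
#'   \describe{
#'     \item{biosets}{data.frame, one row per bioset ordered by descending
#'       signed score: id, study, factor, score, call, capped.}
#'     \item{chemicals}{data.frame per chemical: bioset counts by call and
#'       the chemical-level label (activator / suppressor / mixed /
#'       inconclusive).}
#'     \item{studies}{data.frame per study x factor: the any-positive
#'       study-level call and a conflict flag.}
#'     \item{errors}{data.frame of biosets that failed to score.}
#'   }
#' @export
screen_compendium <- function(biomarker, compendium, threshold = 4, N = NULL) {
  stopifnot(inherits(biomarker, "biomarker"), length(compendium) > 0L)
  rows <- list()
  errors <- list()
  for (i in seq_along(compendium)) {
    b <- compendium[[i]]
    res <- tryCatch(
      signed_correlation_score(biomarker, b, N = N, threshold = threshold),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      id <- if (inherits(b, "bioset")) b$bioset_id else sprintf("entry %d", i)
      errors[[length(errors) + 1L]] <-
        data.frame(bioset_id = id, message = conditionMessage(res),
                   stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      bioset_id = b$bioset_id, study_id = b$study_id, factor = b$factor,
      signed_score = res$signed_score, call = res$call, capped = res$capped,
      stringsAsFactors = FALSE)
  }
  biosets <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bioset_id = character(0), study_id = character(0),
               factor = character(0), signed_score = numeric(0),
               call = character(0), capped = logical(0))
  biosets <- biosets[order(-biosets$signed_score, biosets$bioset_id), ,
                     drop = FALSE]
  rownames(biosets) <- NULL
  structure(list(
    biosets = biosets,
    chemicals = aggregate_chemical(biosets),
    studies = study_level_call(biosets),
    errors = if (length(errors)) do.call(rbind, errors) else
      data.frame(bioset_id = character(0), message = character(0)),
    threshold = threshold
  ), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  calls <- table(factor(x$biosets$call,
                        levels = c("activator", "suppressor", "inconclusive")))
  cat(sprintf(
    "<screen_report> %d biosets (%d activator, %d suppressor, %d inconclusive), %d chemicals, %d studies\n",
    nrow(x$biosets), calls[["activator"]], calls[["suppressor"]],
    calls[["inconclusive"]], nrow(x$chemicals), nrow(x$studies)))
  if (nrow(x$errors) > 0L) cat(sprintf("  %d bioset error(s)\n", nrow(x$errors)))
  invisible(x)
}

normalize_factor <- function(x) {
  tolower(trimws(gsub("\\s+", " ", x)))
}

#' Aggregate per-bioset calls to a per-chemical label
#'
#' Chemical identity is the \code{factor} string after whitespace and case
#' normalization. A chemical is an \code{activator} when it has at least
#' one positive and no negative biosets, a \code{suppressor} in the mirror
#' case, \code{mixed} when both signs are significant, and
#' \code{inconclusive} when neither is.
#'
#' @param biosets per-bioset call data.frame (as in a
#'   \code{screen_report}), with columns \code{factor} and \code{call}.
#' @return data.frame with one row per chemical: counts of activator /
#'   suppressor / inconclusive biosets and the chemical label.
#' @export
aggregate_chemical <- function(biosets) {
  if (nrow(biosets) == 0L) {
    return(data.frame(chemical = character(0), n_biosets = integer(0),
                      n_activator = integer(0), n_suppressor = integer(0),
                      n_inconclusive = integer(0), label = character(0)))
  }
  chem <- normalize_factor(biosets$factor)
  out <- do.call(rbind, lapply(sort(unique(chem)), function(cc) {
    calls <- biosets$call[chem == cc]
    na <- sum(calls == "activator")
    ns <- sum(calls == "suppressor")
    label <- if (na > 0 && ns == 0) "activator"
             else if (ns > 0 && na == 0) "suppressor"
             else if (na > 0 && ns > 0) "mixed"
             else "inconclusive"
    data.frame(chemical = cc, n_biosets = length(calls), n_activator = na,
               n_suppressor = ns, n_inconclusive = sum(calls == "inconclusive"),
               label = label, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Collapse per-bioset calls to study-level calls (any-positive rule)
#'
#' Groups biosets by \code{study_id} x normalized \code{factor}. A study is
#' \code{positive} when any of its biosets is called an activator — time
#' courses often activate the pathway during only part of the exposure
#' window, so one significant timepoint suffices. It is \code{negative}
#' when at least one bioset is a suppressor and none is an activator, and
#' \code{inconclusive} otherwise. A study with both activator and
#' suppressor biosets resolves to positive with \code{conflict = TRUE}.
#'
#' @param biosets per-bioset call data.frame with columns \code{study_id},
#'   \code{factor}, \code{call}.
#' @return data.frame with one row per study x factor: call and conflict
#'   flag.
#' @export
study_level_call <- function(biosets) {
  if (nrow(biosets) == 0L) {
    return(data.frame(study_id = character(0), factor = character(0),
                      n_biosets = integer(0), call = character(0),
                      conflict = logical(0)))
  }
  key <- paste(biosets$study_id, normalize_factor(biosets$factor), sep = "\r")
  out <- do.call(rbind, lapply(sort(unique(key)), function(kk) {
    sel <- biosets[key == kk, , drop = FALSE]
    any_pos <- any(sel$call == "activator")
    any_neg <- any(sel$call == "suppressor")
    call <- if (any_pos) "positive" else if (any_neg) "negative" else "inconclusive"
    data.frame(study_id = sel$study_id[1L],
               factor = normalize_factor(sel$factor[1L]),
               n_biosets = nrow(sel), call = call,
               conflict = any_pos && any_neg, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a screen report to a directory
#'
#' Emits per-bioset, per-chemical and per-study TSV tables plus a JSON
#' summary with the call counts.
#' @param report a \code{screen_report}.
#' @param dir output directory (created if needed).
#' @export
write_screen_report <- function(report, dir) {
  stopifnot(inherits(report, "screen_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$biosets, file.path(dir, "biosets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$chemicals, file.path(dir, "chemicals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$studies, file.path(dir, "studies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    n_biosets = nrow(report$biosets),
    n_activator = sum(report$biosets$call == "activator"),
    n_suppressor = sum(report$biosets$call == "suppressor"),
    n_inconclusive = sum(report$biosets$call == "inconclusive"),
    n_chemicals = nrow(report$chemicals),
    n_studies = nrow(report$studies),
    n_errors = nrow(report$errors),
    threshold = report$threshold
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
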