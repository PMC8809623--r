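#' Derive a signed biomarker from treatment and control biosets
#'
#' Weight-of-evidence derivation. A gene enters the biomarker when three
#' conditions hold:
#' \enumerate{
#'   \item it is differentially expressed with the same sign in at least
#'     \code{min_support} of the treatment biosets;
#'   \item it appears with that same sign in at most
#'     \code{control_exclusion_max} of the control biosets (default 0: a
#'     single same-sign appearance in a genetic-control bioset disqualifies
#'     it — the control genotype acts as a hard filter);
#'   \item the mean signed fold-change over the treatment biosets in which
#'     the gene appears has magnitude at least \code{avg_fc_threshold}.
#' }
#' The mean is taken over only the treatment biosets where the gene passed
#' the statistical filter (no zero-imputation over absent biosets), on the
#' signed linear scale, and is stored as the gene's weight. Output is sorted
#' by descending weight magnitude, ties broken by symbol.
#'
#' Opposite-sign appearances in control biosets do not disqualify a gene:
#' only same-direction appearances count against it.
#'
#' @param treatment list of filtered \code{\link{bioset}} objects from the
#'   pathway-active condition (e.g. replicate timepoints).
#' @param control list of filtered \code{bioset} objects from the
#'   pathway-blocked genetic control; may be empty.
#' @param min_support minimum number of same-sign treatment appearances
#'   (default 2, i.e. "at least 2 of 3 replicates").
#' @param avg_fc_threshold minimum magnitude of the mean fold-change
#'   (default 1.5).
#' @param control_exclusion_max maximum tolerated same-sign control
#'   appearances (default 0).
#' @param name name given to the resulting biomarker.
#' @return A \code{\link{biomarker}} whose \code{"build_report"} attribute
#'   records, per candidate gene, its support, control hits, mean
#'   fold-change and the filter outcome.
#' @examples
#' g <- function(sym, fc) data.frame(symbol = sym, fold_change = fc,
#'                                   p_value = 0.01)
#' tr <- lapply(1:3, function(i) bioset(g("TNFAIP3", 2 - 0.2 * i),
#'                                      bioset_id = paste0("t", i)))
#' build_biomarker(tr, list())  # one gene, weight mean(1.8, 1.6, 1.4) = 1.6
#' @export
build_biomarker <- function(treatment, control = list(), min_support = 2L,
                            avg_fc_threshold = 1.5,
                            control_exclusion_max = 0L,
                            name = "biomarker") {
  if (length(treatment) == 0L) {
    stop("at least one treatment bioset is required", call. = FALSE)
  }
  stopifnot(all(vapply(treatment, inherits, logical(1), "bioset")),
            all(vapply(control, inherits, logical(1), "bioset")))
  min_support <- as.integer(min_support)
  if (min_support < 1L || min_support > length(treatment)) {
    stop(sprintf("min_support must be in [1, %d]", length(treatment)),
         call. = FALSE)
  }
  if (avg_fc_threshold < 1) stop("avg_fc_threshold must be >= 1", call. = FALSE)

  stack <- function(biosets) {
    do.call(rbind, lapply(biosets, function(b) {
      if (nrow(b$genes) == 0L) return(NULL)
      data.frame(symbol = b$genes$symbol, fold_change = b$genes$fold_change,
                 stringsAsFactors = FALSE)
    }))
  }
  tr <- stack(treatment)
  if (is.null(tr) || nrow(tr) == 0L) {
    out <- biomarker(data.frame(symbol = character(0), fold_change = numeric(0)),
                     name = name)
    attr(out, "build_report") <- empty_build_report()
    return(out)
  }
  ct <- stack(control)

  tr$sign <- sign(tr$fold_change)
  # per-symbol, per-sign support and mean fold-change in treatment biosets
  key <- paste(tr$symbol, tr$sign, sep = "\r")
  support <- tapply(tr$fold_change, key, length)
  mean_fc <- tapply(tr$fold_change, key, mean)
  ks <- strsplit(names(support), "\r", fixed = TRUE)
  cand <- data.frame(symbol = vapply(ks, `[`, character(1), 1L),
                     sgn = as.numeric(vapply(ks, `[`, character(1), 2L)),
                     support = as.integer(support),
                     mean_fc = as.numeric(mean_fc),
                     stringsAsFactors = FALSE)

  # a gene reaching support in both directions is pathological input
  sup_ok <- cand[cand$support >= min_support, , drop = FALSE]
  both <- unique(sup_ok$symbol[duplicated(sup_ok$symbol)])
  if (length(both) > 0L) {
    stop(sprintf(
      "gene(s) supported in both directions across treatment biosets: %s",
      paste(sort(both), collapse = ", ")), call. = FALSE)
  }

  ctrl_hits <- function(symbol, sgn) {
    if (is.null(ct) || nrow(ct) == 0L) return(0L)
    sum(ct$symbol == symbol & sign(ct$fold_change) == sgn)
  }
  cand$control_hits <- mapply(ctrl_hits, cand$symbol, cand$sgn)
  cand$pass_support <- cand$support >= min_support
  cand$pass_control <- cand$control_hits <= control_exclusion_max
  cand$pass_avg_fc <- abs(cand$mean_fc) >= avg_fc_threshold
  cand$included <- cand$pass_support & cand$pass_control & cand$pass_avg_fc

  sel <- cand[cand$included, , drop = FALSE]
  sel <- sel[order(-abs(sel$mean_fc), sel$symbol), , drop = FALSE]
  out <- biomarker(data.frame(symbol = sel$symbol, fold_change = sel$mean_fc,
                              stringsAsFactors = FALSE), name = name)
  report <- cand[order(-abs(cand$mean_fc), cand$symbol),
                 c("symbol", "sgn", "support", "control_hits", "mean_fc",
                   "pass_support", "pass_control", "pass_avg_fc", "included")]
  rownames(report) <- NULL
  attr(out, "build_report") <- report
  out
}

empty_build_report <- function() {
  data.frame(symbol = character(0), sgn = numeric(0), support = integer(0),
             control_hits = integer(0), mean_fc = numeric(0),
             pass_support = logical(0), pass_control = logical(0),
             pass_avg_fc = logical(0), included = logical(0))
}
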