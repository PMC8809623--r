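#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing \code{k} or more successes when drawing \code{K}
#' items without replacement from a universe of \code{N} genes containing
#' \code{n} target genes — the elemental one-sided Fisher exact test that
#' the Running Fisher scan iterates over rank cutoffs.
#'
#' @param k observed overlap count.
#' @param K number of drawn genes (the rank-prefix size).
#' @param n target-set size.
#' @param N universe size.
#' @return \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, n, K).
#' @examples
#' hypergeometric_enrichment_p(5, 10, 10, 100)  # 6.716277e-04
#' @export
hypergeometric_enrichment_p <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (k < 0 || K < 0 || n < 0 || N < 1 || k > min(K, n) || K > N || n > N) {
    stop(sprintf(
      "invalid hypergeometric bounds: k=%s K=%s n=%s N=%s (need 0 <= k <= min(K, n); K, n <= N)",
      k, K, n, N), call. = FALSE)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, m = n, n = N - n, k = K, lower.tail = FALSE)
}

#' Rank a gene table by fold-change magnitude
#'
#' Deterministic ranking used for the Running Fisher scan: descending
#' \code{|fold_change|}, ties broken by ascending \code{p_value}, then by
#' symbol. The result is invariant to the input order.
#'
#' @param genes data.frame with columns \code{symbol}, \code{fold_change}
#'   and optionally \code{p_value} (taken as 1 when absent, e.g. for
#'   biomarker weights).
#' @return The same rows, reordered.
#' @export
rank_by_magnitude <- function(genes) {
  if (nrow(genes) == 0L) return(genes)
  p <- if ("p_value" %in% names(genes)) genes$p_value else rep(1, nrow(genes))
  out <- genes[order(-abs(genes$fold_change), p, genes$symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Running Fisher scan for one directional pair
#'
#' Scans every prefix of the ranked query list: for prefix length \code{j}
#' it computes the upper-tail hypergeometric p-value of the overlap between
#' the first \code{j} query genes and the target set, against a universe of
#' \code{N} genes. The pair p-value is the minimum over prefixes,
#' Bonferroni-corrected by the number of prefixes scanned (capped at 1).
#' Ties in the minimum resolve to the smallest prefix.
#'
#' An empty query or target yields \code{p_raw = p_corrected = 1} with zero
#' overlap: absence of evidence, not an error.
#'
#' @param query character vector of gene symbols, already ranked (see
#'   \code{\link{rank_by_magnitude}}).
#' @param target character vector of gene symbols (a set; order ignored).
#' @param N universe size.
#' @return list with \code{p_raw}, \code{p_corrected},
#'   \code{best_prefix_length}, \code{overlap_at_best}.
#' @export
running_fisher_pair <- function(query, target, N) {
  query <- as.character(query)
  target <- unique(as.character(target))
  if (anyDuplicated(query)) {
    stop("query contains duplicated symbols", call. = FALSE)
  }
  if (length(query) > N || length(target) > N) {
    stop("query or target larger than the universe", call. = FALSE)
  }
  if (length(query) == 0L || length(target) == 0L) {
    return(list(p_raw = 1, p_corrected = 1, best_prefix_length = 0L,
                overlap_at_best = 0L))
  }
  hits <- cumsum(query %in% target)
  j <- seq_along(query)
  # vectorised upper tail: P(X >= k_j) at prefix size j
  p <- ifelse(hits == 0, 1,
              stats::phyper(hits - 1, m = length(target),
                            n = N - length(target), k = j,
                            lower.tail = FALSE))
  best <- which.min(p) # first index on ties -> smallest prefix
  list(p_raw = p[best],
       p_corrected = min(1, p[best] * length(query)),
       best_prefix_length = as.integer(best),
       overlap_at_best = as.integer(hits[best]))
}

# Fisher's combination of two p-values (chi-square, 4 df), in log space so
# that extremely small inputs do not underflow to a combined p of 0.
fisher_combine_log10 <- function(p1, p2) {
  x <- -2 * (log(p1) + log(p2))
  stats::pchisq(x, df = 4, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Signed directional correlation between a biomarker and a bioset
#'
#' Splits the biomarker into up/down query sets (ranked by weight
#' magnitude) and the bioset into up/down target sets, runs the Running
#' Fisher scan for the four ordered directional pairs (up-up, down-down,
#' up-down, down-up), combines the two concordant corrected p-values and
#' the two discordant corrected p-values with Fisher's method (chi-square,
#' 4 degrees of freedom), and reports
#' \deqn{score = \log_{10} p_{disc} - \log_{10} p_{conc}}
#' in signed \eqn{-\log_{10} p} units: large positive scores mean the
#' bioset moves the biomarker genes in the biomarker's direction
#' (activation-like), large negative scores mean it moves them opposite
#' (suppression-like). The construction is antisymmetric: flipping every
#' fold-change sign in the bioset exactly negates the score.
#'
#' A bioset is called an \code{activator} when \code{score >= threshold},
#' a \code{suppressor} when \code{score <= -threshold}, otherwise
#' \code{inconclusive}. The conventional significance threshold is
#' \eqn{|-\log_{10} p| \ge 4}. Scores are capped at ±300 (flagged via
#' \code{capped}) to avoid \code{-log10(0)} from floating-point underflow.
#'
#' @param biomarker a \code{\link{biomarker}}.
#' @param bioset a \code{\link{bioset}}; its own \code{universe_size} is
#'   used unless \code{N} is given.
#' @param N optional universe-size override.
#' @param threshold significance threshold on \code{|score|}, inclusive.
#' @return Object of class \code{correlation_result}: the four directional
#'   pair results, \code{signed_score}, \code{call}, \code{capped}.
#' @export
signed_correlation_score <- function(biomarker, bioset, N = NULL,
                                     threshold = 4) {
  stopifnot(inherits(biomarker, "biomarker"), inherits(bioset, "bioset"),
            threshold > 0)
  if (is.null(N)) N <- bioset$universe_size
  bm <- biomarker$genes
  bs <- bioset$genes
  q_up <- rank_by_magnitude(bm[bm$fold_change > 0, , drop = FALSE])$symbol
  q_dn <- rank_by_magnitude(bm[bm$fold_change < 0, , drop = FALSE])$symbol
  t_up <- bs$symbol[bs$fold_change > 0]
  t_dn <- bs$symbol[bs$fold_change < 0]

  pairs <- list(
    "++" = running_fisher_pair(q_up, t_up, N),
    "--" = running_fisher_pair(q_dn, t_dn, N),
    "+-" = running_fisher_pair(q_up, t_dn, N),
    "-+" = running_fisher_pair(q_dn, t_up, N)
  )
  log10_p_conc <- fisher_combine_log10(pairs[["++"]]$p_corrected,
                                       pairs[["--"]]$p_corrected)
  log10_p_disc <- fisher_combine_log10(pairs[["+-"]]$p_corrected,
                                       pairs[["-+"]]$p_corrected)
  score <- log10_p_disc - log10_p_conc
  capped <- FALSE
  if (abs(score) > 300) {
    score <- sign(score) * 300
    capped <- TRUE
  }
  call <- if (score >= threshold) "activator"
          else if (score <= -threshold) "suppressor"
          else "inconclusive"
  structure(list(
    pairs = pairs,
    p_concordant = 10^log10_p_conc,
    p_discordant = 10^log10_p_disc,
    signed_score = score,
    call = call,
    capped = capped,
    threshold = threshold,
    universe_size = N,
    bioset_id = bioset$bioset_id
  ), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s: signed score %.3f -> %s%s\n",
              x$bioset_id, x$signed_score, x$call,
              if (x$capped) " (capped)" else ""))
  for (lab in names(x$pairs)) {
    p <- x$pairs[[lab]]
    cat(sprintf("  %s  p_corrected %.3g (best prefix %d, overlap %d)\n",
                lab, p$p_corrected, p$best_prefix_length, p$overlap_at_best))
  }
  invisible(x)
}

#' Flip the direction of every gene in a bioset
#'
#' Utility for antisymmetry checks and suppressor construction: negates
#' every fold-change, leaving symbols, p-values and metadata unchanged.
#' @param x a \code{bioset}.
#' @return The sign-flipped \code{bioset}.
#' @export
flip_bioset <- function(x) {
  stopifnot(inherits(x, "bioset"))
  x$genes$fold_change <- -x$genes$fold_change
  x
}
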