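# Shared validator for (symbol, fold_change, p_value) gene tables.
# Fold-changes use the signed-linear convention: a value of -1.5 means
# 1.5-fold down-regulated, so magnitudes below 1 are invalid by definition.
validate_gene_table <- function(genes, require_unique = TRUE, context = "gene table") {
  stopifnot(is.data.frame(genes))
  required <- c("symbol", "fold_change", "p_value")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing column(s): %s", context,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(genes) == 0L) return(invisible(genes))
  if (!is.character(genes$symbol)) {
    stop(sprintf("%s: 'symbol' must be character", context), call. = FALSE)
  }
  if (anyNA(genes$symbol) || any(!nzchar(genes$symbol))) {
    stop(sprintf("%s: empty or missing gene symbols", context), call. = FALSE)
  }
  if (!all(is.finite(genes$fold_change)) || !all(is.finite(genes$p_value))) {
    stop(sprintf("%s: non-finite fold_change or p_value", context), call. = FALSE)
  }
  if (any(abs(genes$fold_change) < 1)) {
    bad <- genes$symbol[abs(genes$fold_change) < 1][1L]
    stop(sprintf(
      "%s: |fold_change| < 1 for gene %s (signed-linear convention: k-fold down is -k, not 1/k)",
      context, bad), call. = FALSE)
  }
  if (any(genes$p_value <= 0 | genes$p_value > 1)) {
    stop(sprintf("%s: p_value outside (0, 1]", context), call. = FALSE)
  }
  if (require_unique && anyDuplicated(genes$symbol)) {
    dup <- unique(genes$symbol[duplicated(genes$symbol)])
    stop(sprintf("%s: duplicated gene symbol(s): %s", context,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  invisible(genes)
}

#' Construct a bioset
#'
#' A bioset is one statistically filtered differential-expression comparison:
#' a table of gene symbols with signed linear fold-changes and unadjusted
#' p-values, plus metadata identifying the study, the chemical or cytokine
#' (the "factor"), the cell type, and the size of the gene universe measured
#' on the underlying platform. Fold-changes follow the signed-linear
#' convention: \code{-1.5} means 1.5-fold down-regulated, so every magnitude
#' is at least 1.
#'
#' @param genes data.frame with columns \code{symbol}, \code{fold_change},
#'   \code{p_value}. Symbols are uppercased and must be unique.
#' @param bioset_id character identifier for the comparison.
#' @param study_id accession-style study identifier (e.g. a GEO series).
#' @param factor chemical/cytokine label for the treatment.
#' @param cell_type cell line or tissue label.
#' @param time_hr optional exposure time in hours.
#' @param concentration optional concentration string.
#' @param universe_size number of genes measured on the platform; background
#'   for all hypergeometric tests. Defaults to 20000 when unknown.
#' @return An object of class \code{bioset}.
#' @export
bioset <- function(genes, bioset_id = "bioset", study_id = NA_character_,
                   factor = NA_character_, cell_type = NA_character_,
                   time_hr = NA_real_, concentration = NA_character_,
                   universe_size = 20000L) {
  if (nrow(genes) > 0L) {
    genes$symbol <- toupper(genes$symbol)
  }
  validate_gene_table(genes, context = sprintf("bioset '%s'", bioset_id))
  universe_size <- as.integer(universe_size)
  if (is.na(universe_size) || universe_size < 1L) {
    stop("universe_size must be a positive integer", call. = FALSE)
  }
  if (nrow(genes) > universe_size) {
    stop(sprintf("bioset '%s' has more genes (%d) than its universe (%d)",
                 bioset_id, nrow(genes), universe_size), call. = FALSE)
  }
  structure(list(
    bioset_id = as.character(bioset_id),
    study_id = as.character(study_id),
    factor = as.character(factor),
    cell_type = as.character(cell_type),
    time_hr = as.numeric(time_hr),
    concentration = as.character(concentration),
    genes = genes[, c("symbol", "fold_change", "p_value")],
    universe_size = universe_size
  ), class = "bioset")
}

#' @export
print.bioset <- function(x, ...) {
  cat(sprintf("<bioset> %s  (study %s, factor %s)\n", x$bioset_id,
              x$study_id, x$factor))
  cat(sprintf("  %d genes (%d up, %d down), universe %d\n",
              nrow(x$genes), sum(x$genes$fold_change > 0),
              sum(x$genes$fold_change < 0), x$universe_size))
  invisible(x)
}

#' Apply the statistical filtering rule to a gene table
#'
#' Retains exactly the genes with \code{|fold_change| >= fc_threshold}
#' (inclusive) and \code{p_value < p_threshold} (strict), preserving input
#' order. This is the rule used to define biosets: an absolute fold-change
#' magnitude of at least 1.2 and p below 0.05.
#'
#' @param genes data.frame with columns \code{symbol}, \code{fold_change},
#'   \code{p_value}, in the signed-linear convention.
#' @param fc_threshold minimum fold-change magnitude, inclusive. Default 1.2.
#' @param p_threshold p-value cutoff, strict. Default 0.05.
#' @return The surviving rows, in their original order.
#' @examples
#' g <- data.frame(symbol = c("A", "B", "C"),
#'                 fold_change = c(1.2, -1.19, 2.0),
#'                 p_value = c(0.049, 0.001, 0.05))
#' filter_gene_table(g)  # only A survives
#' @export
filter_gene_table <- function(genes, fc_threshold = 1.2, p_threshold = 0.05) {
  stopifnot(fc_threshold >= 1, p_threshold > 0, p_threshold <= 1)
  validate_gene_table(genes, require_unique = FALSE)
  keep <- abs(genes$fold_change) >= fc_threshold & genes$p_value < p_threshold
  out <- genes[keep, , drop = FALSE]
  if (anyDuplicated(out$symbol)) {
    dup <- unique(out$symbol[duplicated(out$symbol)])
    stop(sprintf("duplicated gene symbol(s) among filtered genes: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Read a bioset from a tab-separated file
#'
#' The file must have header columns \code{symbol}, \code{fold_change} and
#' \code{p_value}; lines starting with \code{#} are ignored. Symbols are
#' uppercased. No statistical filtering is applied on read: call
#' \code{\link{filter_gene_table}} explicitly if the file is unfiltered.
#'
#' @param path path to the TSV file.
#' @param ... metadata fields passed to \code{\link{bioset}} (e.g.
#'   \code{bioset_id}, \code{study_id}, \code{factor}, \code{universe_size}).
#' @return A \code{bioset}.
#' @export
read_bioset <- function(path, ...) {
  tab <- read_tsv_checked(path, c("symbol", "fold_change", "p_value"))
  tab$symbol <- as.character(tab$symbol)
  tab$fold_change <- parse_numeric_column(tab$fold_change, "fold_change", path)
  tab$p_value <- parse_numeric_column(tab$p_value, "p_value", path)
  bioset(tab, ...)
}

#' Write a bioset's gene table to a tab-separated file
#' @param x a \code{bioset}.
#' @param path output path.
#' @export
write_bioset <- function(x, path) {
  stopifnot(inherits(x, "bioset"))
  utils::write.table(x$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tab
}

parse_numeric_column <- function(x, name, path) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) {
    bad <- x[is.na(out)][1L]
    stop(sprintf("%s: unparseable %s value '%s'", path, name, bad),
         call. = FALSE)
  }
  out
}

#' Construct a signed biomarker
#'
#' A biomarker is a signed gene set: unique symbols, each carrying a mean
#' signed linear fold-change ("weight"). The sign partitions the biomarker
#' into an up-regulated and a down-regulated subset used as the directional
#' query sets when scoring biosets.
#'
#' @param genes data.frame with columns \code{symbol} and \code{fold_change}
#'   (signed linear mean fold-changes, magnitude >= 1).
#' @param name biomarker label.
#' @return Object of class \code{biomarker} with fields \code{name},
#'   \code{genes}, \code{up_count}, \code{down_count}.
#' @export
biomarker <- function(genes, name = "biomarker") {
  stopifnot(is.data.frame(genes), all(c("symbol", "fold_change") %in% names(genes)))
  genes$symbol <- toupper(as.character(genes$symbol))
  if (anyDuplicated(genes$symbol)) {
    dup <- unique(genes$symbol[duplicated(genes$symbol)])
    stop(sprintf("biomarker '%s': duplicated symbol(s): %s", name,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  if (nrow(genes) > 0L) {
    if (!all(is.finite(genes$fold_change))) {
      stop(sprintf("biomarker '%s': non-finite fold-change", name), call. = FALSE)
    }
    if (any(abs(genes$fold_change) < 1)) {
      bad <- genes$symbol[abs(genes$fold_change) < 1][1L]
      stop(sprintf("biomarker '%s': |fold_change| < 1 for gene %s", name, bad),
           call. = FALSE)
    }
  }
  rownames(genes) <- NULL
  structure(list(
    name = as.character(name),
    genes = genes[, c("symbol", "fold_change")],
    up_count = sum(genes$fold_change > 0),
    down_count = sum(genes$fold_change < 0)
  ), class = "biomarker")
}

#' @export
print.biomarker <- function(x, ...) {
  cat(sprintf("<biomarker> %s: %d genes (%d up, %d down)\n", x$name,
              nrow(x$genes), x$up_count, x$down_count))
  invisible(x)
}

#' Read a biomarker from a two-column TSV (symbol, fold_change)
#' @param path input path.
#' @param name biomarker label; defaults to the file name without extension.
#' @return A \code{biomarker}.
#' @export
read_biomarker <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  tab <- read_tsv_checked(path, c("symbol", "fold_change"))
  tab$symbol <- as.character(tab$symbol)
  tab$fold_change <- parse_numeric_column(tab$fold_change, "fold_change", path)
  biomarker(tab, name = name)
}

#' Write a biomarker to a two-column TSV
#' @param x a \code{biomarker}.
#' @param path output path.
#' @export
write_biomarker <- function(x, path) {
  stopifnot(inherits(x, "biomarker"))
  utils::write.table(x$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a biomarker as a two-line GMT file
#'
#' Writes the up- and down-regulated members as two gene sets named
#' \code{<name>_UP} and \code{<name>_DOWN} in the standard GMT dialect
#' (set name, description, then member symbols, tab-separated).
#'
#' @param x a \code{biomarker}.
#' @param path output path.
#' @export
write_biomarker_gmt <- function(x, path) {
  stopifnot(inherits(x, "biomarker"))
  up <- x$genes$symbol[x$genes$fold_change > 0]
  dn <- x$genes$symbol[x$genes$fold_change < 0]
  lines <- c(
    paste(c(paste0(x$name, "_UP"), "up-regulated members", up), collapse = "\t"),
    paste(c(paste0(x$name, "_DOWN"), "down-regulated members", dn), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a compendium manifest and its biosets
#'
#' The manifest is a TSV with columns \code{bioset_id}, \code{study_id},
#' \code{factor}, \code{cell_type}, \code{time_hr}, \code{concentration},
#' \code{truth_label}, \code{path}; \code{path} is resolved relative to the
#' manifest's directory. \code{truth_label} must come from the closed
#' vocabulary \code{activator}, \code{suppressor}, \code{negative},
#' \code{unknown}.
#'
#' @param path manifest path.
#' @param universe_size universe size applied to every bioset.
#' @return A list with \code{biosets} (list of \code{bioset}) and
#'   \code{truth} (data.frame of bioset_id and truth_label).
#' @export
read_compendium <- function(path, universe_size = 20000L) {
  cols <- c("bioset_id", "study_id", "factor", "cell_type", "time_hr",
            "concentration", "truth_label", "path")
  tab <- read_tsv_checked(path, cols)
  bad <- setdiff(unique(tab$truth_label),
                 c("activator", "suppressor", "negative", "unknown"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown truth label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  base <- dirname(path)
  biosets <- lapply(seq_len(nrow(tab)), function(i) {
    read_bioset(file.path(base, tab$path[i]),
                bioset_id = tab$bioset_id[i], study_id = tab$study_id[i],
                factor = tab$factor[i], cell_type = tab$cell_type[i],
                time_hr = suppressWarnings(as.numeric(tab$time_hr[i])),
                concentration = tab$concentration[i],
                universe_size = universe_size)
  })
  list(biosets = biosets,
       truth = data.frame(bioset_id = tab$bioset_id,
                          truth_label = tab$truth_label,
                          stringsAsFactors = FALSE))
}
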