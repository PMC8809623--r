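#' Parameters for the synthetic bioset generators
#'
#' Describes one simulated filtered gene list: a universe of \code{N}
#' genes (symbols \code{G000001 ...}), \code{n_de} differentially expressed
#' genes per bioset, a fraction \code{signal_fraction} of biomarker genes
#' planted, a concordance probability that a planted gene keeps the
#' biomarker's sign, and the lognormal spread of fold-change magnitudes.
#' Generated biosets always satisfy the statistical filter (|FC| >= 1.2,
#' p < 0.05): magnitudes are drawn as \code{1.2 * exp(|N(0, fc_log_sd)|)}
#' and p-values uniformly on (1e-6, 0.05), independent of the magnitude.
#'
#' @param universe_size universe size N (default 20000).
#' @param n_de number of genes per bioset (default 300).
#' @param signal_fraction fraction of biomarker genes planted, in [0, 1].
#' @param concordance probability a planted gene keeps the biomarker sign,
#'   in [0, 1].
#' @param fc_log_sd log-scale spread of fold-change magnitudes (default 0.5).
#' @param seed integer seed; every generator is deterministic given it.
#' @return list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(universe_size = 20000L, n_de = 300L,
                           signal_fraction = 0.8, concordance = 1,
                           fc_log_sd = 0.5, seed = 1L) {
  stopifnot(universe_size >= 1, n_de >= 0, n_de <= universe_size,
            signal_fraction >= 0, signal_fraction <= 1,
            concordance >= 0, concordance <= 1, fc_log_sd >= 0)
  structure(list(universe_size = as.integer(universe_size),
                 n_de = as.integer(n_de),
                 signal_fraction = signal_fraction,
                 concordance = concordance,
                 fc_log_sd = fc_log_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

universe_symbols <- function(N) sprintf("G%06d", seq_len(N))

# Deterministic per-bioset seed derived from a master seed and an index;
# kept below 2^31 so it is always a valid R integer.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807) %% 2147483647)
}

rand_magnitude <- function(n, min_fc, fc_log_sd) {
  min_fc * exp(abs(stats::rnorm(n, 0, fc_log_sd)))
}

#' Simulate one bioset with planted biomarker signal
#'
#' In \code{activator} mode, \code{round(signal_fraction * nrow)} biomarker
#' genes are planted; each keeps the biomarker's sign with probability
#' \code{concordance} and is flipped otherwise. \code{suppressor} mode
#' mirrors this (the biomarker sign is flipped with probability
#' \code{concordance}). \code{null} mode plants nothing. Remaining slots
#' are filled with non-biomarker genes sampled without replacement from the
#' universe; their signs are symmetric coin flips.
#'
#' @param biomarker a \code{\link{biomarker}} whose symbols lie in the
#'   spec's universe.
#' @param spec a \code{\link{synthetic_spec}}.
#' @param mode \code{"activator"}, \code{"suppressor"} or \code{"null"}.
#' @param bioset_id,study_id,factor metadata for the generated bioset.
#' @return list with the \code{bioset} and a \code{manifest} data.frame
#'   recording every planted gene and the sign it was planted with.
#' @export
simulate_bioset <- function(biomarker, spec,
                            mode = c("activator", "suppressor", "null"),
                            bioset_id = "sim", study_id = "SIM1",
                            factor = "simulated") {
  mode <- match.arg(mode)
  stopifnot(inherits(biomarker, "biomarker"), inherits(spec, "synthetic_spec"))
  if (spec$n_de > spec$universe_size) {
    stop("n_de exceeds the universe size", call. = FALSE)
  }
  set.seed(spec$seed)
  universe <- universe_symbols(spec$universe_size)
  bm <- biomarker$genes
  if (!all(bm$symbol %in% universe)) {
    stop("biomarker symbols must belong to the synthetic universe", call. = FALSE)
  }

  n_plant <- if (mode == "null") 0L else
    min(round(spec$signal_fraction * nrow(bm)), spec$n_de)
  planted_idx <- if (n_plant > 0L)
    sample(nrow(bm), n_plant) else integer(0)
  planted <- bm[planted_idx, , drop = FALSE]
  base_sign <- sign(planted$fold_change)
  keep <- if (n_plant > 0L) stats::runif(n_plant) < spec$concordance else logical(0)
  planted_sign <- ifelse(keep, base_sign, -base_sign)

  n_noise <- spec$n_de - n_plant
  pool <- setdiff(universe, bm$symbol)
  if (n_noise > length(pool)) {
    stop("not enough non-biomarker genes in the universe", call. = FALSE)
  }
  noise <- if (n_noise > 0L) sample(pool, n_noise) else character(0)
  noise_sign <- if (n_noise > 0L) sample(c(-1, 1), n_noise, replace = TRUE) else numeric(0)

  symbols <- c(planted$symbol, noise)
  signs <- c(planted_sign, noise_sign)
  # suppressor biosets are the exact sign-flip of the activator bioset the
  # same seed would generate, so paired scores negate exactly
  if (mode == "suppressor") {
    signs <- -signs
    planted_sign <- -planted_sign
  }
  genes <- data.frame(
    symbol = symbols,
    fold_change = signs * rand_magnitude(length(symbols), 1.2, spec$fc_log_sd),
    p_value = stats::runif(length(symbols), 1e-6, 0.05),
    stringsAsFactors = FALSE)

  manifest <- data.frame(symbol = planted$symbol,
                         planted_sign = as.numeric(planted_sign),
                         biomarker_sign = sign(planted$fold_change),
                         stringsAsFactors = FALSE)
  list(bioset = bioset(genes, bioset_id = bioset_id, study_id = study_id,
                       factor = factor, universe_size = spec$universe_size),
       manifest = manifest)
}

#' Simulate a training study for biomarker derivation
#'
#' Mirrors the replicate-plus-genetic-control design used for biomarker
#' construction: each treatment bioset carries the planted core gene set
#' (minus per-bioset dropouts) with consistent signs and magnitudes of at
#' least 1.5-fold, plus bioset-private noise genes; control biosets carry
#' only noise genes drawn from outside the core. Noise genes are sampled
#' without replacement across all biosets of the study, so no noise gene
#' recurs — recovery by \code{\link{build_biomarker}} is then determined
#' entirely by the dropout pattern recorded in the manifest.
#'
#' @param core data.frame with columns \code{symbol}, \code{fold_change}
#'   defining the planted signed core set (|fold_change| >= 1.5).
#' @param spec a \code{\link{synthetic_spec}}; \code{n_de} is the number of
#'   noise genes added per bioset.
#' @param n_treatment,n_control numbers of treatment and control biosets
#'   (defaults 3 and 3).
#' @param dropout per-bioset probability that a core gene is omitted.
#' @return list with \code{treatment} and \code{control} (lists of
#'   \code{bioset}) and \code{manifest}, a logical presence matrix of core
#'   genes (rows) by treatment bioset (columns).
#' @export
simulate_training_study <- function(core, spec, n_treatment = 3L,
                                    n_control = 3L, dropout = 0) {
  stopifnot(is.data.frame(core), all(c("symbol", "fold_change") %in% names(core)),
            inherits(spec, "synthetic_spec"), dropout >= 0, dropout <= 1)
  if (any(abs(core$fold_change) < 1.5)) {
    stop("core fold-changes must have magnitude >= 1.5", call. = FALSE)
  }
  core$symbol <- toupper(core$symbol)
  set.seed(spec$seed)
  universe <- universe_symbols(spec$universe_size)
  if (!all(core$symbol %in% universe)) {
    stop("core symbols must belong to the synthetic universe", call. = FALSE)
  }
  pool <- setdiff(universe, core$symbol)
  n_bio <- n_treatment + n_control
  if (n_bio * spec$n_de > length(pool)) {
    stop("not enough non-core genes for private noise", call. = FALSE)
  }
  noise_all <- sample(pool, n_bio * spec$n_de)
  noise_for <- function(i) noise_all[((i - 1L) * spec$n_de + 1L):(i * spec$n_de)]

  present <- matrix(stats::runif(nrow(core) * n_treatment) >= dropout,
                    nrow = nrow(core), ncol = n_treatment,
                    dimnames = list(core$symbol, paste0("treatment_", seq_len(n_treatment))))

  make_genes <- function(core_rows, noise_syms, core_min_fc) {
    n_core <- nrow(core_rows)
    n_noise <- length(noise_syms)
    core_fc <- if (n_core > 0L)
      sign(core_rows$fold_change) *
        pmax(abs(core_rows$fold_change) *
               exp(stats::rnorm(n_core, 0, spec$fc_log_sd / 4)), core_min_fc)
      else numeric(0)
    data.frame(
      symbol = c(core_rows$symbol, noise_syms),
      fold_change = c(core_fc,
                      sample(c(-1, 1), n_noise, replace = TRUE) *
                        rand_magnitude(n_noise, 1.2, spec$fc_log_sd)),
      p_value = stats::runif(n_core + n_noise, 1e-6, 0.05),
      stringsAsFactors = FALSE)
  }

  treatment <- lapply(seq_len(n_treatment), function(i) {
    rows <- core[present[, i], , drop = FALSE]
    bioset(make_genes(rows, noise_for(i), 1.5),
           bioset_id = sprintf("treatment_%d", i), study_id = "TRAIN",
           factor = "treatment", universe_size = spec$universe_size)
  })
  control <- lapply(seq_len(n_control), function(i) {
    bioset(make_genes(core[0, , drop = FALSE], noise_for(n_treatment + i), 1.5),
           bioset_id = sprintf("control_%d", i), study_id = "TRAIN",
           factor = "treatment", universe_size = spec$universe_size)
  })
  list(treatment = treatment, control = control, manifest = present,
       core = core)
}

#' Simulate a compendium with known truth labels
#'
#' Concatenates seeded activator, suppressor and null biosets. Each
#' bioset's seed is derived deterministically from the spec's master seed
#' and the bioset index, so any subset is reproducible in isolation.
#' Biosets are assigned to studies in blocks of \code{biosets_per_study}
#' within each truth class.
#'
#' @param biomarker a \code{\link{biomarker}}.
#' @param n_activators,n_suppressors,n_null class sizes.
#' @param spec a \code{\link{synthetic_spec}} (master seed and shared
#'   generation parameters).
#' @param biosets_per_study biosets grouped under one study id (default 1).
#' @return list with \code{biosets}, \code{truth} (data.frame of
#'   bioset_id, study_id, truth_label) and \code{manifests}.
#' @export
simulate_compendium <- function(biomarker, n_activators, n_suppressors,
                                n_null, spec, biosets_per_study = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"), biosets_per_study >= 1L)
  modes <- c(rep("activator", n_activators), rep("suppressor", n_suppressors),
             rep("null", n_null))
  biosets <- vector("list", length(modes))
  manifests <- vector("list", length(modes))
  truth <- vector("list", length(modes))
  study_counter <- c(activator = 0L, suppressor = 0L, null = 0L)
  within <- c(activator = 0L, suppressor = 0L, null = 0L)
  for (i in seq_along(modes)) {
    mode <- modes[i]
    if (within[[mode]] == 0L) study_counter[[mode]] <- study_counter[[mode]] + 1L
    within[[mode]] <- (within[[mode]] + 1L) %% biosets_per_study
    study_id <- sprintf("SIM_%s_%03d", toupper(substr(mode, 1, 3)),
                        study_counter[[mode]])
    sub <- spec
    sub$seed <- derive_seed(spec$seed, i)
    sim <- simulate_bioset(biomarker, sub, mode = mode,
                           bioset_id = sprintf("bioset_%03d_%s", i, mode),
                           study_id = study_id,
                           factor = sprintf("chem_%s_%03d", mode,
                                            study_counter[[mode]]))
    biosets[[i]] <- sim$bioset
    manifests[[i]] <- sim$manifest
    truth[[i]] <- data.frame(
      bioset_id = sim$bioset$bioset_id, study_id = study_id,
      truth_label = if (mode == "null") "negative" else mode,
      stringsAsFactors = FALSE)
  }
  list(biosets = biosets, truth = do.call(rbind, truth),
       manifests = manifests)
}

#' Write a simulated compendium to disk in the compendium-manifest dialect
#' @param compendium output of \code{\link{simulate_compendium}}.
#' @param dir output directory (created if needed).
#' @return the manifest path.
#' @export
write_compendium <- function(compendium, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(compendium$biosets), function(i) {
    b <- compendium$biosets[[i]]
    file <- sprintf("%s.tsv", b$bioset_id)
    write_bioset(b, file.path(dir, file))
    data.frame(bioset_id = b$bioset_id, study_id = b$study_id,
               factor = b$factor, cell_type = b$cell_type,
               time_hr = b$time_hr, concentration = b$concentration,
               truth_label = compendium$truth$truth_label[i], path = file,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Generate a synthetic signed biomarker inside the simulation universe
#'
#' Convenience constructor for tests and demonstrations: draws \code{n_up}
#' up- and \code{n_down} down-regulated genes from the synthetic universe
#' with mean fold-change magnitudes of at least 1.5.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param n_up,n_down numbers of up- and down-regulated genes
#'   (defaults 63 and 45, the shape of the published signature).
#' @param name biomarker name.
#' @return A \code{\link{biomarker}}.
#' @export
simulate_biomarker <- function(spec, n_up = 63L, n_down = 45L,
                               name = "synthetic_biomarker") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  universe <- universe_symbols(spec$universe_size)
  symbols <- sample(universe, n_up + n_down)
  fc <- c(rand_magnitude(n_up, 1.5, spec$fc_log_sd),
          -rand_magnitude(n_down, 1.5, spec$fc_log_sd))
  biomarker(data.frame(symbol = symbols, fold_change = fc,
                       stringsAsFactors = FALSE), name = name)
}
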