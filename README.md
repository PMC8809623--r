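# biosetscreen

Signed gene-signature screening of filtered differential-expression gene
lists ("biosets"), for predictive-toxicology and pathway-activity screening
of transcriptomic compendia.

## The problem

High-throughput transcriptomics screens ask, for thousands of chemical
exposures at once: did this treatment activate or suppress a signalling
pathway? One proven answer is a signed gene-expression biomarker — a set of
genes, each carrying the mean fold-change it shows when the pathway is
switched on — scored against each experiment's filtered gene list. The
motivating application is the canonical NF-κB pathway (activated by TNFα,
IL-1 and LPS through IκB degradation), where a 108-gene signature screened
a compendium of >12,000 microarray comparisons for chemical modulators.
`biosetscreen` implements that workflow end to end and supplies seeded
synthetic data so every stage is testable offline.

## What the package does

1. **Bioset model and filtering** (`bioset`, `filter_gene_table`,
   `read_bioset`): a bioset is one treatment-vs-control comparison — unique
   gene symbols, signed linear fold-changes (−k means k-fold down), p-values
   — filtered at |FC| ≥ 1.2 (inclusive) and p < 0.05 (strict), with a
   platform universe size N (default 20,000).
2. **Biomarker derivation** (`build_biomarker`): weight-of-evidence rule — a
   gene is kept when it moves the same direction in ≥ `min_support` (default
   2) treatment biosets, never moves that direction in a genetic-control
   bioset, and its mean fold-change over the supporting biosets has
   magnitude ≥ 1.5. The mean is the gene's weight.
3. **Signed Running Fisher correlation** (`signed_correlation_score`): the
   biomarker's up- and down-sets (ranked by |weight|) are scanned against
   the bioset's up- and down-sets. For each of the four directional pairs
   and every rank prefix `j`, the overlap is tested with the one-sided
   Fisher exact (hypergeometric upper-tail) test

       p_j = P(X ≥ k_j),  X ~ Hypergeom(N, |target|, j)

   the minimum over prefixes is Bonferroni-corrected by the number of
   prefixes, the two concordant and two discordant corrected p-values are
   each combined by Fisher's method (χ², 4 df), and the score is

       score = log10(p_discordant) − log10(p_concordant)

   in signed −log10 p units. `score ≥ 4` calls an **activator**,
   `score ≤ −4` a **suppressor** (the conventional |−log p| ≥ 4 cutoff);
   the construction is exactly antisymmetric under sign-flip of the bioset.
4. **Compendium screening and aggregation** (`screen_compendium`,
   `aggregate_chemical`, `study_level_call`): per-bioset calls, per-chemical
   labels (activator / suppressor / mixed / inconclusive), and any-positive
   study-level calls for time-course studies.
5. **Evaluation** (`confusion_counts`, `confusion_metrics`,
   `evaluate_predictions`): sensitivity, specificity, PPV, NPV and balanced
   accuracy = (sensitivity + specificity)/2, at bioset or study level, with
   undefined (not zero) metrics on empty denominators.
6. **Synthetic data** (`synthetic_spec`, `simulate_bioset`,
   `simulate_training_study`, `simulate_compendium`): seeded generators with
   planted, quantifiable signal and truth manifests.
7. **CLI** (`bs_main`, `inst/scripts/biosetscreen`): subcommands
   `build-biomarker`, `score`, `screen`, `evaluate`, `simulate`.

## Worked example

```r
library(biosetscreen)

# the bundled S1-style signature stand-in (synthetic membership,
# published shape: 108 genes, 63 up / 45 down)
bm <- read_biomarker(system.file("extdata",
  "synthetic_nfkb_biomarker_s1_style.tsv", package = "biosetscreen"))
bm
#> <biomarker> synthetic_nfkb_biomarker_s1_style: 108 genes (63 up, 45 down)

# a synthetic activator bioset: 80% of the biomarker planted concordantly
spec <- synthetic_spec(universe_size = 20000, n_de = 300,
                       signal_fraction = 0.8, concordance = 1, seed = 1)
sbm <- simulate_biomarker(spec)
sim <- simulate_bioset(sbm, spec, mode = "activator",
                       bioset_id = "demo_activator")
signed_correlation_score(sbm, sim$bioset)
#> <correlation_result> demo_activator: signed score 161.861 -> activator
#>   ++  p_corrected 5.75e-87 (best prefix 63, overlap 47)
#>   --  p_corrected 6.31e-79 (best prefix 44, overlap 39)
#>   +-  p_corrected 1 (best prefix 1, overlap 0)
#>   -+  p_corrected 1 (best prefix 1, overlap 0)
```

The concordant pairs (biomarker-up vs bioset-up, down vs down) reach
corrected p-values around 10⁻⁸⁰ while the discordant pairs stay at 1, so
the signed score is hugely positive and the bioset is called an activator.
A screen over a small planted compendium recovers the truth exactly:

```r
comp <- simulate_compendium(sbm, n_activators = 5, n_suppressors = 5,
                            n_null = 10, spec = spec)
report <- screen_compendium(sbm, comp$biosets)
report
#> <screen_report> 20 biosets (5 activator, 5 suppressor, 10 inconclusive),
#>                 20 chemicals, 20 studies
ev <- evaluate_predictions(report$biosets,
                           comp$truth[, c("bioset_id", "truth_label")])
ev$counts
#> <confusion_counts> (bioset level) TP=5 FP=0 TN=15 FN=0
ev$metrics$balanced_accuracy
#> [1] 1
```

Feeding published confusion counts straight into the metric formulas:

```r
confusion_metrics(confusion_counts(tp = 43, fp = 0, tn = 0,
                                   fn = 3))$percent$sensitivity
#> [1] 93.5
```

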