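---
title: "Methods: signed signature screening of filtered gene lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed signature screening of filtered gene lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biosetscreen)
```

## The data model

The unit of analysis is the **bioset**: one statistically filtered
treatment-vs-control differential-expression comparison, represented as a
table of unique gene symbols with signed linear fold-changes and unadjusted
p-values, plus study/chemical metadata and a platform universe size `N`.
Fold-changes use the signed-linear convention throughout: `-1.5` means
1.5-fold down-regulated, so every valid magnitude is at least 1. The
filtering rule that defines a bioset is `|FC| >= 1.2` (inclusive) and
`p < 0.05` (strict); `filter_gene_table()` applies exactly these
comparisons and is idempotent.

Two modelling assumptions are baked in and worth stating:

* **Gene identity is the symbol**, matched case-insensitively and stored
  uppercase. No alias or ortholog resolution is attempted; cross-platform
  comparisons therefore only see genes whose symbols agree.
* **The universe size defaults to 20,000** when the platform size is
  unknown. `N` enters every hypergeometric test, so scores computed under
  different universe sizes are not directly comparable; the default keeps a
  screen internally consistent, and it can be overridden per bioset.

## Biomarker derivation

`build_biomarker()` implements a weight-of-evidence rule over replicate
treatment biosets (the pathway-active condition) and genetic-control
biosets (the same treatment with the pathway blocked). A gene is included
iff:

1. it appears with the same sign in at least `min_support` treatment
   biosets (default 2 — "at least 2 of 3 replicate timepoints");
2. it appears with that sign in at most `control_exclusion_max` control
   biosets (default 0); and
3. the mean signed fold-change over the treatment biosets *in which it
   appears* has magnitude at least `avg_fc_threshold` (default 1.5).

Design choices where the design was genuinely open:

* **Strict control exclusion.** A single same-sign appearance in any
  control bioset disqualifies a gene. The genetic control is meant as a
  hard filter — it is what makes the signature pathway-specific rather
  than treatment-specific — and control biosets in the motivating design
  overlap the final signature by only a handful of genes. The tolerance is
  configurable for sensitivity analysis.
* **Opposite-sign control appearances do not exclude.** The derivation
  rule constrains only same-direction appearances; a gene up in the active
  condition and down in the control is, if anything, stronger evidence.
* **The mean is taken over supporting biosets only**, not zero-imputed
  over all replicates, and **on the signed linear scale** rather than in
  log space. Both are the most literal reading of the derivation rule; the
  averaging scale only matters near the 1.5 threshold and is documented so
  it can be switched.
* **A gene reaching support in both directions raises an error** instead
  of being silently dropped: such a gene indicates inconsistent replicate
  labelling or sign conventions, which the user should see.

## The signed Running Fisher correlation

`signed_correlation_score()` measures how strongly, and in which
direction, a bioset recapitulates the biomarker. The biomarker is split
into its up-set and down-set, ranked by weight magnitude (the per-gene
mean fold-change is the only magnitude a biomarker carries); the bioset is
split by fold-change sign into up/down target sets. For each of the four
ordered pairs (up-up, down-down, up-down, down-up), `running_fisher_pair()`
scans every rank prefix `j = 1..|query|` of the query and computes the
one-sided Fisher exact (hypergeometric upper-tail) p-value of the overlap
between the prefix and the target at universe size `N`. The pair p-value
is the minimum over prefixes, Bonferroni-corrected by the number of
prefixes scanned; ties in the minimum resolve to the smallest prefix,
making the reported best prefix deterministic.

The two concordant corrected p-values are combined by Fisher's method
(chi-square with 4 degrees of freedom), likewise the two discordant ones,
and the signed score is `log10(p_disc) - log10(p_conc)`. A bioset is
called an **activator** at `score >= 4`, a **suppressor** at
`score <= -4` (both inclusive, matching the conventional
`|-log10 p| >= 4` significance rule), otherwise **inconclusive**.

This scan is a documented variant of a statistic whose reference
implementation is proprietary: the published description fixes the
elemental test, the rank-scanning idea, the signed −log p output and the
threshold, but not the cutoff grid, multiplicity correction or directional
combination. The variant here — full prefix scan on the biomarker side,
Bonferroni over prefixes, chi-square-4 combination, log-ratio score — was
chosen because every piece is exactly testable: the scan has a brute-force
enumeration oracle, the combination has a closed form, and the whole is
antisymmetric by construction (swapping the bioset's up and down sets
swaps the concordant and discordant pairs, so the score negates exactly).
Consequences worth knowing:

* Absolute score magnitudes are **not** comparable to scores from other
  implementations of the same idea; only within-screen comparisons and
  sign/threshold semantics carry over.
* The Bonferroni correction over prefixes is conservative, which is the
  safe direction for a screening statistic (it deflates, never inflates,
  significance).

### Numerical choices

* The hypergeometric upper tail is `stats::phyper(k - 1, ..., lower.tail =
  FALSE)`, exact to well beyond 10 significant digits for the universe
  sizes used; `k = 0` short-circuits to `p = 1`.
* Fisher's combination is evaluated in log space
  (`pchisq(..., log.p = TRUE)`), so corrected p-values that underflow to
  double-precision 0 still produce a finite log10 rather than `-Inf`.
* Scores are capped at ±300 and flagged `capped`; a 108-gene signature
  scored against itself in a 20,000-gene universe exceeds any
  representable p-value, and the cap makes that case explicit instead of
  returning infinity.
* Empty query or target sets contribute `p = 1` (no evidence, not an
  error); an empty bioset therefore scores exactly 0 and is inconclusive.
* Ranking ties break by ascending p-value, then symbol, so every ordering
  in the package is reproducible to the byte.

## Screening and aggregation

`screen_compendium()` scores every bioset, sorts the report by descending
signed score, and aggregates twice. Per **chemical** (the normalized
`factor` string; no synonym resolution): activator if ≥ 1 positive and 0
negative biosets, suppressor in the mirror case, `mixed` when both signs
occur — reported separately rather than forced into either class — and
inconclusive otherwise. Per **study × factor**: the any-positive rule —
one significant activator bioset makes the study positive, because
pathway activation in time courses is often confined to a window of the
exposure; a study with both activator and suppressor biosets resolves to
positive with an explicit `conflict` flag, preserving the information the
bare rule would discard. Study positivity is monotone: adding biosets can
never un-positive a study. Unreadable compendium entries become error
records and the screen continues.

## Evaluation

`confusion_metrics()` applies sensitivity = TP/(TP+FN), specificity =
TN/(FP+TN), PPV = TP/(TP+FP), NPV = TN/(TN+FN), balanced accuracy =
(sensitivity + specificity)/2. A zero denominator yields an undefined
(`NA`) metric, never 0. Report percentages round half away from zero to
one decimal; the raw ratios are always carried alongside, and recomputing
from the emitted counts reproduces the metrics bit-for-bit.

`evaluate_predictions()` is one-vs-rest with activation as the default
positive class: on an activation truth set, a suppressor call counts as a
miss (false negative), not a third outcome, because the truth sets this
evaluation is designed for are activation-only. At study level, calls are
first collapsed with the any-positive rule and studies are counted
instead of biosets.

Two published figures are deliberately not asserted anywhere: a prose
sensitivity of 85% for one factor is inconsistent with its own printed
counts (90 of 107 = 84.1%), and the package reports the computed value;
and the pooling rule behind a pooled balanced-accuracy figure is unstated,
so both natural poolings (count-pooled and factor-averaged) are computed
and reported without asserting either.

## The synthetic generators

The unit of simulation is the *filtered gene list*, matching what the
method consumes — not raw expression matrices. `synthetic_spec()` fixes
the study conditions: universe `N = 20000`, `n_de = 300` genes per bioset
(a typical filtered-list size for a strong treatment), planted signal
fraction `signal_fraction`, sign-concordance probability `concordance`,
and fold-change spread `fc_log_sd = 0.5`.

* `simulate_bioset()` plants `round(signal_fraction * |biomarker|)`
  biomarker genes (keeping each sign with probability `concordance`) and
  fills the rest with non-biomarker genes. Magnitudes are
  `1.2 * exp(|N(0, fc_log_sd)|)` — a half-normal in log space, so every
  generated gene passes the 1.2 filter bound by construction (a plain
  lognormal would put mass below the bound and violate the generator's
  own contract that its output survives filtering unchanged). P-values
  are uniform on (10⁻⁶, 0.05), independent of the magnitude, so the
  scorer cannot exploit a p/FC coupling that real filtered lists are not
  guaranteed to have.
* Suppressor biosets are the exact global sign-flip of the activator
  bioset the same seed would generate. Flipping only the planted genes
  would leave the noise genes' up/down split unmirrored and the
  activator/suppressor pair would not negate exactly; the global flip
  makes the negation an identity, and noise signs are symmetric coin
  flips either way.
* `simulate_training_study()` mirrors the replicate-plus-genetic-control
  derivation design: treatment biosets carry the core (minus per-bioset
  dropouts) at magnitudes ≥ 1.5 with consistent signs; noise genes are
  sampled without replacement *across the whole study*, so they are
  bioset-private and recovery is exactly predictable from the dropout
  manifest; control biosets draw noise from outside the core.
* `simulate_compendium()` derives per-bioset seeds from the master seed
  and the bioset index by a fixed linear-congruential mix kept below
  2³¹, so any subset regenerates identically on any platform.

What the generators do **not** emulate — and hence what passing tests do
not show about real data: gene–gene correlation (co-regulated modules make
real null overlaps heavier-tailed than independent sampling), partial or
off-pathway signatures, platform-specific universes, symbol drift between
annotation versions, and fold-change/p dependence. In particular, the null
calibration result (no null bioset reaching the threshold) reflects nulls
drawn from outside the biomarker, which is the generator's definition of
"no signal"; real negative treatments can graze the signature through
shared downstream biology, which is why the published negative-control
specificity is below 100%.

## Problem sizes

Unit tests run in universes of 2,000–8,000 genes with 50–200-gene
biosets; the oracle-equivalence checks use 500 random instances with
query length ≤ 25 and `N ≤ 200`, where exhaustive prefix enumeration is
itself exact. Acceptance-level checks use the study conditions: `N =
20000`, 300-gene biosets, 1,000 null biosets, and a 200-bioset compendium
(50 activators, 50 suppressors, 100 nulls at 80% planted signal,
two biosets per study). The full suite and the acceptance script each
finish in about a minute on a single core.

## Known limitations

* Score magnitudes are implementation-specific (see above); use the sign,
  the threshold and within-screen ranks, not cross-implementation values.
* Symbol-based matching silently ignores genes absent from a platform's
  universe; a bioset from a small targeted panel should set
  `universe_size` to the panel size or scores will be anti-conservative.
* The chemical aggregation treats the normalized `factor` string as
  identity; salts, hydrates and synonyms of one compound count as
  distinct chemicals unless harmonized upstream.
* `control_exclusion_max > 0` weakens the genetic filter and is intended
  for sensitivity analysis, not production derivation.
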