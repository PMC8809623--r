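Package: biosetscreen
Title: Signed Gene-Signature Screening of Filtered Differential-Expression Gene Lists
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives signed transcriptomic biomarkers from replicate
    treatment and genetic-control comparisons by a weight-of-evidence rule,
    scores statistically filtered gene lists ("biosets") against a biomarker
    with a signed, directional, rank-based Running Fisher correlation,
    screens compendia of biosets to classify chemicals as pathway activators
    or suppressors at |-log10 p| >= 4, and evaluates predictive accuracy
    (sensitivity, specificity, PPV, NPV, balanced accuracy) at the bioset
    and study level. Includes seeded generators of synthetic biosets,
    training studies and compendia with planted, quantifiable signal, and a
    command-line interface for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
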