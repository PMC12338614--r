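Package: dmsmap
Title: Scoring and Clinical Calibration of Deep Mutational Scanning Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for turning per-tile variant sequencing counts from
    saturation-mutagenesis (TileSeq-style) growth selections into
    quality-filtered amino-acid functional scores, and for calibrating those
    scores into clinically interpretable ACMG evidence strengths. Implements
    wild-type-control-corrected enrichment log-ratios, synonymous/nonsense
    rescaling, regularized bootstrap standard errors, replicate-divergence and
    well-measured filters, codon- and biological-replicate merging with the
    above-one squash transform, kernel-density log-likelihood-ratio
    calibration with uniform regularization and Tavtigian-derived thresholds,
    balanced precision-recall evaluation, and descriptive map statistics
    (moving-window medians, motif/region summaries, coverage accounting).
    Includes a synthetic experiment generator with known ground-truth scores
    so every stage can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
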