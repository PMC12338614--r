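---
title: "From tiled variant counts to clinically calibrated functional scores"
author: "dmsmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tiled variant counts to clinically calibrated functional scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmsmap)
```

## The experiment the package models

dmsmap implements the analysis of a tiled deep mutational scan read out by
growth selection. A codon-randomized library of a coding sequence is
integrated one-variant-per-cell at a genomic landing pad; the population is
grown under selection; and short, deeply sequenced tiles spanning the cDNA
are counted before and after selection. The motivating assay is a HeLa-cell
proliferation readout of the tumour suppressor kinase STK11, in which
expression of functional protein *suppresses* growth — so loss-of-function
variants *gain* fitness and enrich during selection. Nothing in the scoring
machinery is specific to that gene: the coding sequence, tiling, and region
annotations are all inputs.

The pipeline entry point is the per-tile count table: for each codon
variant, condition (pre-selection, post-selection, and the matched
non-mutagenized wild-type control libraries for both), tile, biological
replicate (independent transfection) and technical replicate (separate
lineage of one transfection), a *marginal count* — the number of reads
carrying the change irrespective of co-occurring variants — and an
*effective sequencing depth*, the number of read pairs of sufficient
quality at that position. Read alignment and base-call posterior filtering
are upstream of this package.

## Scoring model

For each variant the frequency is the marginal count over the effective
depth. Because sequencing error is variant-specific and shared with the
non-mutagenized wild-type control library, the control frequency is
subtracted from both the pre- and post-selection frequencies before the
enrichment log-ratio is formed:

$$\mathrm{lr} = \ln\frac{f_\mathrm{sel} - f^{wt}_\mathrm{sel}}
                        {f_\mathrm{pre} - f^{wt}_\mathrm{pre}}.$$

A corrected frequency at or below zero is floored at half a read
(`0.5 / depth`) and the record flagged `floored`; this keeps the log
defined without silently discarding data. Natural log is used internally;
the choice is irrelevant because the subsequent rescaling

$$s = \frac{\mathrm{lr} - \mathrm{median}(\mathrm{lr}_\mathrm{nonsense})}
           {\mathrm{median}(\mathrm{lr}_\mathrm{synonymous}) -
            \mathrm{median}(\mathrm{lr}_\mathrm{nonsense})}$$

is invariant to the log base and to affine shifts (a tested property).
After rescaling the synonymous median is exactly 1 (wild-type-like) and
the nonsense median exactly 0 (null-like). Rescaling anchors are computed
per tile, because selection strength as seen through a tile can vary with
tile-specific sequencing behaviour; a tile with fewer than 5 well-measured
synonymous or 5 nonsense variants falls back to region-wide anchors. The
per-tile default matches the tiled design; with per-tile anchors the
*pooled* class medians are exact only when all tiles share anchors, and
within ±0.05 otherwise (also tested).

### Quality filters

* `low_frequency`: corrected pre-selection frequency below 2×10⁻⁵
  (the boundary value is kept). Applied to the *corrected* frequency — the
  quantity actually entering the log-ratio — and configurable.
* `wt_indistinguishable`: a one-sided exact rate comparison (conditional
  binomial test of the variant pre-selection count against the control
  count given their depth ratio) that fails to show excess over the
  control at α = 0.05. The test is the standard exact comparison of two
  Poisson rates; the α and one-sidedness are configurable.
* `replicate_divergent`: technical replicates, which share the biological
  fitness draw and differ only by sampling, are each scored provisionally
  and flagged when they differ by more than 3× the score difference
  expected from Poisson counting noise,
  `sqrt(sd₁² + sd₂²)` with `sd ≈ sqrt(1/m_pre + 1/m_sel)` mapped through
  the rescale slope (delta method). The inequality is strict: exactly 3×
  is kept. Non-divergent technical replicates are combined by summing
  counts and depths.

Flagged records keep their values but are marked not `well_measured`;
downstream merging uses only well-measured records, so every filter
decision remains visible in the output.

### Measurement error

Per-variant standard errors come from a parametric bootstrap: each of the
four condition counts is resampled as Poisson(observed count), the score
recomputed per draw with the normalization medians held fixed (the
uncertainty quantified is variant-level, not map-level), B = 1000 draws by
default. Raw bootstrap variances are then regularized toward a depth-trend
prior: a log–log regression of bootstrap variance on the Poisson
information `1/m_pre + 1/m_sel` across variants predicts a prior variance
per variant, and each variant's variance is shrunk toward it with a prior
weight of 3 pseudo-observations against the 4 observed condition counts.
This encodes the expectation that variants of similar depth have similar
error, stabilizing the small number of wild bootstrap outliers while
leaving typical variants nearly unchanged (a tested property). The exact
shrinkage weights are a package design choice; the bootstrap se agrees
with the delta-method sd within 25% at high counts.

## Merging

Pathogenic variation in a pure loss-of-function gene can only lose
activity, so scores above 1 carry no additional mechanistic meaning.
Before averaging, above-1 scores are compressed with the rank-preserving
transform `x' = 1 + (x − 1)/x` (identity at or below 1, bounded above
by 2). Standard errors are carried through the transform by the delta
method (scaled by `1/x²` for `x > 1`); the paper trail of raw values
remains in the per-replicate files, and `n_codons`/`n_bioreps` make merged
records traceable.

Codon-level scores for the same amino-acid change are merged within each
biological replicate: one codon passes through; two codons are dropped if
they disagree on damaging (< 0.5) versus tolerated (> 0.5) *and* differ by
more than 0.3, otherwise averaged; three or more take the median. The same
rule merges biological replicates, except a variant well-measured in only
one transfection is removed outright. Combined standard errors use the se
of the mean, inflated by 1.2533 (the asymptotic efficiency of the median)
when the median is used — a package choice where the source procedure is
silent.

The *high-confidence* subset used for clinical work removes variants whose
closed interval `score ± se` contains the intermediate score 0.5.

## Clinical calibration

The reference set takes variants with ≥ 6 pathogenic points into the
positive class and ≥ 2 benign points into the negative class (or
pre-resolved labels). Class-conditional score densities are estimated with
Gaussian-kernel KDE, bandwidth by biased cross-validation with a fallback
to Silverman's rule when BCV fails to bracket a minimum (recorded in the
model metadata). The support is the pooled score range padded by three
bandwidths so both densities are proper. Each density is regularized
toward the uniform distribution on the support,
`f̃ = (n·f + w·u)/(n + w)` with `w = 1` pseudo-observation by default,
so the log₁₀ likelihood ratio of pathogenicity
`LLR = log₁₀(f̃_path / f̃_benign)` stays finite and tends to 0 in score
ranges empty of reference variants (for balanced reference sets). The
pseudo-observation mixture is this package's explicit regularization
choice; the published description requires regularization toward uniform
without fixing the functional form.

LLRs map to ACMG evidence strengths through Tavtigian-style thresholds:
with odds of pathogenicity 350 for very-strong evidence and the exponent
halving per level, `log₁₀(350^(1/2^k))` gives 2.544, 1.272, 0.636, 0.318 —
conventionally printed as 2.5, 1.3, 0.64 and 0.32. The benign-side
cutpoints −0.32 and −1.32 are taken as printed constants, preserving the
published pathogenic/benign asymmetry (1.3 vs −1.32) rather than
re-deriving them. Interval boundaries follow the published phrasing
("above 2.5" is very strong, so 2.5 itself is strong; the benign
boundaries include their endpoints on the benign side).

Evaluation uses *balanced precision* — precision as if the reference
classes were equally sized, `BP = R/(R + F)` with R the recall and F the
benign false-positive rate at a score threshold (pathogenic calls are
scores at or below the threshold; ties are called together; −∞/+∞
endpoints included, with BP defined as 1 at the R = 0, F = 0 endpoint).
AUBPRC is the trapezoidal area of BP versus R and R90BP the maximum recall
with BP ≥ 0.90.

## The synthetic experiment generator

The generator exists so every stage can be validated against known ground
truth. Its defaults are the full study conditions: a 433-codon ORF, 12
tiles (~110 nt each), 2×10⁶ reads per tile per condition, 3 biological × 2
technical replicates, and a selection strength of `log(8)` so that null
variants enrich about 8-fold — the published work does not quantify its
fold enrichment, and 8-fold over a two-week selection is a realistic
effective value for a strong growth phenotype. Each amino-acid variant
draws a latent true score from a two-component mixture (tolerated
N(1, 0.15), damaging N(0, 0.15), missense damaging with probability 0.2 —
bracketing the observed 16.5% overall and 23.5% in-core damaging
fractions); nonsense variants are null inside a configurable sensitive
core (default residues 22–311) and tolerated outside it, emulating
tolerated terminal truncations. Selection is collapsed into a single
multiplicative fitness per variant (`exp(γT(1 − s))` with per-replicate
N(0, 0.1) log-fitness jitter): the scoring method only ever sees start and
end frequencies, so multi-passage dynamics would be unidentifiable anyway.
Sequencing error is per-variant, log-normal with mean 2×10⁻⁶ (duplex
sequencing scale) and log-sd 1, shared *exactly* between the mutagenized
and control libraries, making wild-type subtraction exactly the right
correction in expectation. Clone abundances are log-normal around a mean
variant frequency of 2×10⁻⁴ (≈ 50+ clones per codon change in a 500k-clone
library). Counts are Poisson; technical replicates share the biological
draw and differ only by counting noise. All randomness flows from one
master seed through deterministic per-stage substreams.

What the generator does **not** emulate: read-level artifacts (alignment,
base-calling), multi-variant clones, bottleneck/drift dynamics beyond the
log-normal jitter, tile-boundary edge effects, and any correlation of
error rates between variants. Passing tests on synthetic data therefore
demonstrate the correctness and statistical behaviour of the *pipeline*,
not the fidelity of any particular real experiment.

The test suite exercises the pipeline at a scaled-down size chosen to keep
a full run in seconds: an 80-codon sequence, 3 tiles at 2×10⁵ reads, 8
alternate codons per position (640 codon variants, ~545 amino-acid
variants), bootstrap B = 200. At these sizes the seeded runs recover the
ground truth with Spearman ρ ≥ 0.9, keep the merged synonymous median
within 1 ± 0.05 and the in-core nonsense median within 0 ± 0.05, and show
biological-replicate agreement above 80% — the same qualitative behaviour
expected at full scale.

## Numerical and degenerate-input choices

* Flooring constant 0.5/depth for non-positive corrected frequencies,
  always flagged.
* Rescaling errors out when the synonymous and nonsense anchor medians
  coincide (an unselected or failed experiment has no score scale; this
  is also why a zero-selection simulation cannot be rescaled).
* KDE bandwidth fallbacks: BCV → Silverman → a 0.05 score-scale constant
  for degenerate (zero-spread) reference classes.
* Scores outside the calibration support evaluate at the nearest endpoint
  and are flagged `clamped`.
* Classification at exactly 0.5 is "unclassified"; damaging and tolerated
  are strict inequalities.
* Moving windows at position p span `[p, p + width − 1]`; trailing windows
  keep their actual shorter span; empty windows are NA.
* Wilcoxon comparisons use the normal approximation (`exact = FALSE`) for
  robustness to ties.

## Known limitations

* SNV-reachability counts depend on the codon usage of the supplied CDS;
  the package never hard-codes a gene sequence, and reachability on a
  codon-optimized construct differs from the native gene.
* The biological-replicate correlation observed in real data (Pearson
  ~0.5) reflects noise sources the generator does not model; the
  generator's replicate agreement is optimistic.
* Calibration quality is bounded by the reference set; with few pathogenic
  references the regularizer dominates and evidence strengths saturate
  near "supporting".
* The pipeline starts at the count table: base-call posterior filtering,
  alignment artifacts and library composition biases are out of scope.
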