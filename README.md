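# dmsmap

Scoring and clinical calibration of deep mutational scanning (DMS) maps.

Multiplexed assays of variant effect measure thousands of coding variants
of one gene at once: a codon-randomized library is integrated
one-variant-per-cell, the population is put under growth selection, and
short deeply-sequenced tiles of the cDNA are counted before and after
selection. `dmsmap` turns those per-tile counts into quality-filtered
amino-acid functional scores, and turns the scores into ACMG-style
clinical evidence strengths. It is written for analysts of TileSeq-style
growth selections — in particular the configuration where the assayed
protein *suppresses* growth (as with the tumour suppressor kinase STK11 in
HeLa cells), so loss-of-function variants enrich during selection.

## The method in brief

For each codon variant, condition, tile and replicate, the input is a
marginal count m and an effective sequencing depth d. The pipeline
computes, per biological replicate:

1. **Error-corrected enrichment log-ratio.** Frequencies f = m/d; the
   matched non-mutagenized wild-type control frequency is subtracted from
   both the pre- and post-selection frequencies (sequencing error is
   variant-specific and shared with the control), then
   `lr = ln[(f_sel − f_wt_sel)/(f_pre − f_wt_pre)]`, with non-positive
   corrected frequencies floored at half a read and flagged.
2. **Rescaling.** `score = (lr − median(lr_nonsense)) /
   (median(lr_synonymous) − median(lr_nonsense))`, per tile, so the
   synonymous median is 1 (wild-type-like) and the nonsense median is 0
   (null-like).
3. **QC filters.** Corrected pre-selection frequency ≥ 2×10⁻⁵; one-sided
   exact excess over the wild-type control (α = 0.05); technical
   replicates within 3× the Poisson-expected score difference (then
   combined by count summation).
4. **Error model.** Parametric (Poisson) bootstrap of the four condition
   counts, B = 1000, with variances regularized toward a depth-trend
   prior.
5. **Merging.** Above-1 scores squashed with `x' = 1 + (x−1)/x`; codons of
   the same amino-acid change merged (mean/median, with a 0.3
   damaging-versus-tolerated conflict rule); biological replicates merged
   the same way, single-replicate variants removed; high-confidence =
   `score ± se` excludes 0.5.
6. **Calibration.** Gaussian-kernel densities of pathogenic (≥ 6
   pathogenic points) and benign (≥ 2 benign points) reference scores,
   bandwidth by biased cross-validation, regularized toward uniform;
   `LLR = log10` density ratio; ACMG evidence strengths at the
   Tavtigian-derived cutpoints `log10(350^(1/2^k))` ≈ 2.5 / 1.3 / 0.64 /
   0.32 (and −0.32 / −1.32 on the benign side); evaluation by balanced
   precision–recall (AUBPRC, R90BP).

A synthetic experiment generator (`simulation_config()`,
`simulate_experiment()`) emulates the full design — tiled Poisson counts,
log-normal clone abundances and error rates shared with the control
library, 3×2 replicate structure — with known ground-truth scores, so the
whole pipeline is testable end to end. See the vignette
(`vignettes/dms-scoring-and-calibration.Rmd`) for the model, parameter
meanings and design choices.

## Worked example

```r
library(dmsmap)

cds <- read_cds(system.file("extdata", "demo_cds_synthetic.fasta",
                            package = "dmsmap"))
cfg <- simulation_config(seed = 7, n_positions = 90, n_tiles = 3,
                         depth_per_tile = 2e5, core_range = c(5, 80))
sim <- simulate_experiment(cfg, cds, n_alt_codons = 8)   # 17,280 count rows

rs <- score_replicates(sim$counts, B = 200, seed = 7)
table(rs$well_measured)
#> FALSE  TRUE
#>    75  2085

map <- merge_map(rs)$map
nrow(map)                                                  # 592 aa variants
median(map$score[map$vclass == "synonymous"])              # 1
median(map$score[map$vclass == "nonsense" &
                 map$position >= 5 & map$position <= 80])  # -0.04
```

The merged map recovers the generator's ground truth with Spearman
ρ = 0.90, and 545 of the 592 variants pass the high-confidence interval
filter. Calibrating against a reference set drawn from the simulated truth
(25 pathogenic, 99 benign):

```r
cal <- calibrate_map(map, ref)       # ref: hgvs_pro + label
cal$evaluation$aubprc                # 0.957
cal$evaluation$r90bp                 # 1
table(cal$scores$evidence)
#>     moderate_path              none       strong_path supporting_benign
#>                16                 5               120               400
#>   supporting_path
#>                 4
```

Scores of 1 mean wild-type-like function, 0 null-like; the nonsense median
of −0.04 inside the sensitive core confirms the null anchor, and the
evidence table shows how scores convert to ACMG strengths (damaging scores
gather strong pathogenic evidence, wild-type-like scores supporting-benign
evidence). `coverage_report(map, cds)` accounts for scored variants
against the 19·(L−1) possible substitutions and the subset reachable by
single-nucleotide change; `moving_window_median()`, `region_summary()` and
`stk11_regions()` summarize positional structure (kinase domain, catalytic
motifs).

`run_pipeline(pipeline_config(...))` drives the whole chain and writes
every intermediate (counts, per-replicate scores, map, LLRs, coverage,
window medians, run log) to an output directory.

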