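# Per-replicate scoring: counts -> frequencies -> wild-type-corrected
# enrichment log-ratios -> rescaled scores with regularized bootstrap
# standard errors, plus the well-measured and replicate-divergence filters.

#' Variant frequency from marginal count and effective depth
#'
#' @param marginal_count Non-negative read counts supporting the variant.
#' @param effective_depth Positive sequencing depths (reads with sufficient
#'   quality at the variant position).
#' @return `marginal_count / effective_depth`, in `[0, 1]`.
#' @export
variant_frequency <- function(marginal_count, effective_depth) {
  if (any(effective_depth <= 0)) stop("effective_depth must be positive")
  if (any(marginal_count < 0)) stop("marginal_count must be non-negative")
  if (any(marginal_count > effective_depth)) {
    stop("marginal_count exceeds effective_depth")
  }
  marginal_count / effective_depth
}

#' Wild-type-corrected enrichment log-ratio
#'
#' The per-variant sequencing-error frequency estimated from the
#' non-mutagenized wild-type control library is subtracted from both the
#' pre- and post-selection frequencies before taking the natural-log ratio.
#' A corrected frequency that is zero or negative is floored at half a read
#' (`0.5 / depth_floor`) and the record is flagged, keeping the log defined
#' without silently discarding data.
#'
#' @param f_pre,f_sel Pre- and post-selection variant frequencies.
#' @param f_wt_pre,f_wt_sel Matching wild-type control frequencies.
#' @param depth_floor Effective depth used for the half-read floor.
#' @return Data.frame with `logratio` (natural log) and logical `floored`.
#' @examples
#' error_corrected_logratio(1e-4, 1e-3, 0, 0, depth_floor = 1e6)
#' @export
error_corrected_logratio <- function(f_pre, f_sel, f_wt_pre, f_wt_sel,
                                     depth_floor) {
  stopifnot(all(depth_floor > 0))
  floor_val <- 0.5 / depth_floor
  fp <- f_pre - f_wt_pre
  fs <- f_sel - f_wt_sel
  floored <- fp <= 0 | fs <= 0
  fp <- pmax(fp, floor_val)
  fs <- pmax(fs, floor_val)
  data.frame(logratio = log(fs / fp), floored = floored)
}

#' Rescale log-ratios to the synonymous/nonsense score scale
#'
#' Scores are a linear rescaling of the enrichment log-ratio anchored so
#' that the synonymous median maps to 1 (wild-type-like) and the nonsense
#' median maps to 0 (null-like):
#' `score = (lr - median(non)) / (median(syn) - median(non))`.
#' The result is invariant to adding a constant to all log-ratios and to
#' the log base.
#'
#' @param logratios Per-variant log-ratios to rescale.
#' @param syn_lrs,non_lrs Log-ratios of the synonymous and nonsense anchor
#'   classes (typically the well-measured ones).
#' @return Numeric scores with attributes `syn_median` and `non_median`.
#' @export
rescale_scores <- function(logratios, syn_lrs, non_lrs) {
  if (length(syn_lrs) < 1L || length(non_lrs) < 1L) {
    stop("need synonymous and nonsense log-ratios to rescale")
  }
  ms <- stats::median(syn_lrs)
  mn <- stats::median(non_lrs)
  if (ms == mn) {
    stop("degenerate normalization: synonymous and nonsense medians are equal")
  }
  structure((logratios - mn) / (ms - mn), syn_median = ms, non_median = mn)
}

#' Delta-method score standard deviation from Poisson count variance
#'
#' Under Poisson counts, `var(log m) ~ 1/m`, so the log-ratio sd is
#' approximately `sqrt(1/m_pre + 1/m_sel)`; dividing by the rescale span
#' `|median(syn) - median(non)|` puts it on the score scale. Counts below
#' half a read are floored at 0.5.
#'
#' @param m_pre,m_sel Marginal counts pre- and post-selection.
#' @param syn_median,non_median Rescaling anchor medians (log-ratio scale).
#' @return Score-scale standard deviations.
#' @export
delta_method_score_sd <- function(m_pre, m_sel, syn_median, non_median) {
  sd_lr <- sqrt(1 / pmax(m_pre, 0.5) + 1 / pmax(m_sel, 0.5))
  sd_lr / abs(syn_median - non_median)
}

#' Bootstrap standard error of rescaled scores
#'
#' Each of the four condition counts is resampled as
#' Poisson(observed count) `B` times; frequencies, the wild-type-corrected
#' log-ratio (with the half-read floor), and the rescaled score are
#' recomputed per draw with the normalization medians held fixed, and the
#' standard deviation across draws is returned. Deterministic given `seed`.
#'
#' @param m_pre,m_sel,m_wt_pre,m_wt_sel Observed marginal counts
#'   (vectorized over variants).
#' @param d_pre,d_sel,d_wt_pre,d_wt_sel Matching effective depths.
#' @param syn_median,non_median Fixed rescaling anchors (log-ratio scale;
#'   scalars or per-variant vectors when anchors differ by tile).
#' @param B Number of bootstrap iterations (at least 100).
#' @param seed Seed for the resampling stream.
#' @return Per-variant bootstrap standard errors on the score scale.
#' @export
bootstrap_se <- function(m_pre, d_pre, m_sel, d_sel,
                         m_wt_pre, d_wt_pre, m_wt_sel, d_wt_sel,
                         syn_median, non_median, B = 1000L, seed = 1L) {
  if (B < 100L) stop("B must be at least 100")
  nv <- length(m_pre)
  syn_median <- rep_len(syn_median, nv)
  non_median <- rep_len(non_median, nv)
  span <- syn_median - non_median
  out <- numeric(nv)
  with_seed(seed, {
    # chunk variants to bound the B x n resampling matrices
    chunk <- 2000L
    for (lo in seq(1L, nv, by = chunk)) {
      hi <- min(lo + chunk - 1L, nv)
      idx <- lo:hi
      n <- length(idx)
      draw <- function(m) matrix(stats::rpois(n * B, rep(m, B)), nrow = n)
      fp <- draw(m_pre[idx]) / d_pre[idx] - draw(m_wt_pre[idx]) / d_wt_pre[idx]
      fs <- draw(m_sel[idx]) / d_sel[idx] - draw(m_wt_sel[idx]) / d_wt_sel[idx]
      fp <- pmax(fp, 0.5 / d_pre[idx])
      fs <- pmax(fs, 0.5 / d_sel[idx])
      sc <- (log(fs / fp) - non_median[idx]) / span[idx]
      out[idx] <- apply(sc, 1L, stats::sd)
    }
  })
  out
}

#' Regularize bootstrap variances toward a depth-trend prior
#'
#' Per-variant bootstrap variances are noisy; variants of similar sequencing
#' depth should have similar measurement error. A log-log regression of the
#' bootstrap variance on the Poisson information `1/m_pre + 1/m_sel` gives a
#' depth-trend prior variance, toward which each variant's bootstrap
#' variance is shrunk with `prior_weight` pseudo-observations against the
#' four observed condition counts.
#'
#' @param var_boot Per-variant bootstrap variances.
#' @param m_pre,m_sel Marginal counts used for the depth trend.
#' @param prior_weight Pseudo-observation weight of the trend prior.
#' @return Regularized variances.
#' @export
regularize_variance <- function(var_boot, m_pre, m_sel, prior_weight = 3) {
  x <- 1 / pmax(m_pre, 0.5) + 1 / pmax(m_sel, 0.5)
  ok <- is.finite(var_boot) & var_boot > 0
  if (sum(ok) < 3L) return(var_boot)
  fit <- stats::lm(log(var_boot[ok]) ~ log(x[ok]))
  prior <- exp(fit$coefficients[1] + fit$coefficients[2] * log(x))
  n_obs <- 4
  (prior_weight * prior + n_obs * var_boot) / (prior_weight + n_obs)
}

#' Well-measured filter: frequency threshold and wild-type excess
#'
#' A variant is flagged `low_frequency` when its wild-type-corrected
#' pre-selection frequency falls below `freq_threshold` (default 2e-5; the
#' boundary value is kept). It is flagged `wt_indistinguishable` when a
#' one-sided exact rate comparison (conditional binomial test of the variant
#' count against the wild-type control count given their depth ratio) fails
#' to show excess over the control at level `alpha`.
#'
#' @param f_pre_corrected Wild-type-corrected pre-selection frequencies.
#' @param m_pre,d_pre Pre-selection marginal counts and depths.
#' @param m_wt_pre,d_wt_pre Wild-type control counts and depths.
#' @param freq_threshold Frequency cutoff (kept when >= threshold).
#' @param alpha One-sided test level.
#' @return Data.frame with logicals `low_frequency`, `wt_indistinguishable`
#'   and the test `p_value`.
#' @export
filter_well_measured <- function(f_pre_corrected, m_pre, d_pre,
                                 m_wt_pre, d_wt_pre,
                                 freq_threshold = 2e-5, alpha = 0.05) {
  low <- f_pre_corrected < freq_threshold
  n <- m_pre + m_wt_pre
  p0 <- d_pre / (d_pre + d_wt_pre)
  # P(X >= m_pre) for X ~ Binom(n, p0): exact conditional test of two
  # Poisson rates, one-sided toward variant excess
  pval <- stats::pbinom(m_pre - 1L, n, p0, lower.tail = FALSE)
  pval[n == 0L] <- 1
  data.frame(low_frequency = low,
             wt_indistinguishable = pval > alpha,
             p_value = pval)
}

#' Technical-replicate divergence filter
#'
#' Flags variant measurements whose two technical replicates differ by more
#' than `multiplier` times the expected score difference under Poisson
#' counting noise, `sqrt(sd_1^2 + sd_2^2)` with each sd from
#' [delta_method_score_sd()]. The comparison is a strict inequality, so a
#' divergence of exactly `multiplier` standard deviations is kept. A missing
#' replicate passes unpaired, flagged.
#'
#' @param score_1,score_2 Technical-replicate scores (NA when missing).
#' @param sd_1,sd_2 Delta-method score sds of the two replicates.
#' @param multiplier Divergence multiplier (default 3).
#' @return Data.frame with logicals `replicate_divergent` and `unpaired`.
#' @export
filter_replicate_divergence <- function(score_1, score_2, sd_1, sd_2,
                                        multiplier = 3) {
  unpaired <- is.na(score_1) | is.na(score_2)
  gap <- abs(score_1 - score_2)
  lim <- multiplier * sqrt(sd_1^2 + sd_2^2)
  divergent <- !unpaired & gap > lim
  divergent[is.na(divergent)] <- FALSE
  data.frame(replicate_divergent = divergent, unpaired = unpaired)
}

# Per-variant rescaling anchors: per-tile synonymous/nonsense medians over
# anchor-eligible records, falling back to region-wide medians for tiles
# with fewer than min_n eligible variants in either class.
class_medians <- function(logratio, vclass, tile, eligible, min_n = 5L) {
  syn_g <- logratio[eligible & vclass == "synonymous"]
  non_g <- logratio[eligible & vclass == "nonsense"]
  if (length(syn_g) < 1L || length(non_g) < 1L) {
    stop("rescaling requires well-measured synonymous and nonsense variants")
  }
  ms_g <- stats::median(syn_g)
  mn_g <- stats::median(non_g)
  syn_med <- rep(ms_g, length(logratio))
  non_med <- rep(mn_g, length(logratio))
  for (tl in unique(tile)) {
    in_tile <- tile == tl
    syn_t <- logratio[in_tile & eligible & vclass == "synonymous"]
    non_t <- logratio[in_tile & eligible & vclass == "nonsense"]
    if (length(syn_t) >= min_n && length(non_t) >= min_n) {
      syn_med[in_tile] <- stats::median(syn_t)
      non_med[in_tile] <- stats::median(non_t)
    }
  }
  if (any(syn_med == non_med)) {
    stop("degenerate normalization: synonymous and nonsense medians are equal")
  }
  data.frame(syn_median = syn_med, non_median = non_med)
}

# Pivot a long count table into one row per (bio_rep, tech_rep, variant)
# with the four condition count/depth pairs as columns. Missing wild-type
# control rows default to count 0 at the pre/select depth.
pivot_counts <- function(counts) {
  need <- c("tile", "bio_rep", "tech_rep", "condition", "position",
            "wt_codon", "alt_codon", "count", "depth")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols) > 0) {
    stop("count table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  ok_cond <- c("preselect", "select", "wtctrl_pre", "wtctrl_sel")
  if (!all(counts$condition %in% ok_cond)) {
    stop("unknown condition value: ",
         setdiff(unique(counts$condition), ok_cond)[1])
  }
  id_cols <- c("tile", "bio_rep", "tech_rep", "position", "wt_codon",
               "alt_codon")
  base <- unique(counts[id_cols])
  for (cond in ok_cond) {
    sub <- counts[counts$condition == cond, c(id_cols, "count", "depth")]
    names(sub)[names(sub) == "count"] <- paste0("m_", cond)
    names(sub)[names(sub) == "depth"] <- paste0("d_", cond)
    base <- merge(base, sub, by = id_cols, all.x = TRUE, sort = FALSE)
  }
  if (anyNA(base$m_preselect) || anyNA(base$m_select)) {
    stop("every variant needs preselect and select counts in each replicate")
  }
  for (cond in c("wtctrl_pre", "wtctrl_sel")) {
    m <- paste0("m_", cond)
    d <- paste0("d_", cond)
    miss <- is.na(base[[m]])
    base[[m]][miss] <- 0L
    base[[d]][miss] <- base$d_preselect[miss]
  }
  base
}

# Sum counts and depths across technical replicates.
sum_tech_reps <- function(wide) {
  id_cols <- c("tile", "bio_rep", "position", "wt_codon", "alt_codon")
  num <- c("m_preselect", "d_preselect", "m_select", "d_select",
           "m_wtctrl_pre", "d_wtctrl_pre", "m_wtctrl_sel", "d_wtctrl_sel")
  agg <- stats::aggregate(wide[num], wide[id_cols], sum)
  agg
}

#' Score codon variants within each biological replicate
#'
#' The per-replicate scoring chain: technical replicates are individually
#' scored (provisional per-tile rescaling) and checked for divergence beyond
#' `divergence_multiplier` times the Poisson expectation, then combined by
#' count summation; combined counts give wild-type-corrected log-ratios,
#' the well-measured filter (frequency threshold and one-sided wild-type
#' excess test) is applied, scores are rescaled per tile so the synonymous
#' median is 1 and the nonsense median is 0 (falling back to region-wide
#' anchors for tiles with fewer than `min_class_per_tile` well-measured
#' variants in either class), and a regularized bootstrap standard error is
#' attached. Flagged records keep their values but are marked not
#' `well_measured`; downstream merging uses only well-measured records.
#'
#' @param counts Long count table (see [simulate_counts()] or
#'   [read_count_table()]) with conditions preselect/select/wtctrl_pre/
#'   wtctrl_sel.
#' @param freq_threshold Corrected pre-selection frequency cutoff
#'   (default 2e-5).
#' @param divergence_multiplier Technical-replicate divergence multiplier
#'   (default 3).
#' @param alpha Level of the one-sided wild-type excess test.
#' @param B Bootstrap iterations (default 1000).
#' @param seed Seed for the bootstrap stream.
#' @param min_class_per_tile Minimum well-measured synonymous and nonsense
#'   variants for per-tile rescaling anchors.
#' @return Data.frame with one row per (bio_rep, codon variant): identity
#'   columns, `f_pre_corrected`, `logratio`, `score`, `se`, flag columns
#'   (`flag_floored`, `flag_low_frequency`, `flag_wt_indistinguishable`,
#'   `flag_replicate_divergent`, `flag_unpaired`) and `well_measured`.
#' @export
score_replicates <- function(counts,
                             freq_threshold = 2e-5,
                             divergence_multiplier = 3,
                             alpha = 0.05,
                             B = 1000L,
                             seed = 1L,
                             min_class_per_tile = 5L) {
  wide <- pivot_counts(counts)
  wt_aa <- translate_codons(wide$wt_codon)
  alt_aa <- translate_codons(wide$alt_codon)
  wide$vclass <- variant_class(wt_aa, alt_aa)
  wide$wt_aa <- wt_aa
  wide$alt_aa <- alt_aa

  # --- technical-replicate divergence, per biological replicate ---
  tech_score <- function(sub) {
    fp <- sub$m_preselect / sub$d_preselect - sub$m_wtctrl_pre / sub$d_wtctrl_pre
    lr <- error_corrected_logratio(
      sub$m_preselect / sub$d_preselect, sub$m_select / sub$d_select,
      sub$m_wtctrl_pre / sub$d_wtctrl_pre, sub$m_wtctrl_sel / sub$d_wtctrl_sel,
      depth_floor = pmin(sub$d_preselect, sub$d_select)
    )
    eligible <- fp >= freq_threshold
    med <- class_medians(lr$logratio, sub$vclass, sub$tile, eligible,
                         min_class_per_tile)
    score <- (lr$logratio - med$non_median) /
      (med$syn_median - med$non_median)
    sdv <- delta_method_score_sd(sub$m_preselect, sub$m_select,
                                 med$syn_median, med$non_median)
    data.frame(score = score, sd = sdv)
  }

  vkey <- paste(wide$bio_rep, wide$position, wide$wt_codon, wide$alt_codon,
                sep = "|")
  div_flag <- rep(FALSE, length(unique(vkey)))
  names(div_flag) <- unique(vkey)
  unp_flag <- div_flag
  for (br in unique(wide$bio_rep)) {
    rows_b <- wide$bio_rep == br
    techs <- unique(wide$tech_rep[rows_b])
    ts <- list()
    for (tr in techs) {
      rows <- rows_b & wide$tech_rep == tr
      sub <- wide[rows, ]
      sc <- tech_score(sub)
      key <- vkey[rows]
      ts[[tr]] <- data.frame(key = key, score = sc$score, sd = sc$sd,
                             stringsAsFactors = FALSE)
    }
    keys_b <- unique(vkey[rows_b])
    if (length(techs) < 2L) {
      unp_flag[keys_b] <- TRUE
      next
    }
    smat <- sapply(ts, function(d) d$score[match(keys_b, d$key)])
    dmat <- sapply(ts, function(d) d$sd[match(keys_b, d$key)])
    n_obs <- rowSums(!is.na(smat))
    unp_flag[keys_b] <- unp_flag[keys_b] | n_obs < 2L
    # pairwise check across all technical replicates
    div <- rep(FALSE, length(keys_b))
    nt <- ncol(smat)
    for (i in seq_len(nt - 1L)) {
      for (j in seq(i + 1L, nt)) {
        fd <- filter_replicate_divergence(smat[, i], smat[, j],
                                          dmat[, i], dmat[, j],
                                          divergence_multiplier)
        div <- div | fd$replicate_divergent
      }
    }
    div_flag[keys_b] <- div_flag[keys_b] | div
  }

  # --- combine technical replicates by count summation ---
  comb <- sum_tech_reps(wide)
  wt_aa <- translate_codons(comb$wt_codon)
  alt_aa <- translate_codons(comb$alt_codon)
  comb$wt_aa <- wt_aa
  comb$alt_aa <- alt_aa
  comb$vclass <- variant_class(wt_aa, alt_aa)
  comb$hgvs_pro <- format_hgvs_pro(comb$position, wt_aa, alt_aa)
  ckey <- paste(comb$bio_rep, comb$position, comb$wt_codon, comb$alt_codon,
                sep = "|")
  comb$flag_replicate_divergent <- unname(div_flag[ckey])
  comb$flag_unpaired <- unname(unp_flag[ckey])

  comb$f_pre_corrected <- comb$m_preselect / comb$d_preselect -
    comb$m_wtctrl_pre / comb$d_wtctrl_pre
  lr <- error_corrected_logratio(
    comb$m_preselect / comb$d_preselect, comb$m_select / comb$d_select,
    comb$m_wtctrl_pre / comb$d_wtctrl_pre,
    comb$m_wtctrl_sel / comb$d_wtctrl_sel,
    depth_floor = pmin(comb$d_preselect, comb$d_select)
  )
  comb$logratio <- lr$logratio
  comb$flag_floored <- lr$floored
  wm <- filter_well_measured(comb$f_pre_corrected,
                             comb$m_preselect, comb$d_preselect,
                             comb$m_wtctrl_pre, comb$d_wtctrl_pre,
                             freq_threshold, alpha)
  comb$flag_low_frequency <- wm$low_frequency
  comb$flag_wt_indistinguishable <- wm$wt_indistinguishable
  comb$well_measured <- !comb$flag_low_frequency &
    !comb$flag_wt_indistinguishable & !comb$flag_replicate_divergent

  comb$score <- NA_real_
  comb$se <- NA_real_
  bio_levels <- unique(comb$bio_rep)
  for (b in seq_along(bio_levels)) {
    rows <- comb$bio_rep == bio_levels[b]
    sub <- comb[rows, ]
    med <- class_medians(sub$logratio, sub$vclass, sub$tile,
                         sub$well_measured, min_class_per_tile)
    score <- (sub$logratio - med$non_median) /
      (med$syn_median - med$non_median)
    vb <- bootstrap_se(sub$m_preselect, sub$d_preselect,
                       sub$m_select, sub$d_select,
                       sub$m_wtctrl_pre, sub$d_wtctrl_pre,
                       sub$m_wtctrl_sel, sub$d_wtctrl_sel,
                       syn_median = med$syn_median,
                       non_median = med$non_median,
                       B = B, seed = seed + b)^2
    se <- sqrt(regularize_variance(vb, sub$m_preselect, sub$m_select))
    comb$score[rows] <- score
    comb$se[rows] <- se
  }
  keep <- c("bio_rep", "tile", "position", "wt_codon", "alt_codon",
            "wt_aa", "alt_aa", "vclass", "hgvs_pro",
            "m_preselect", "m_select", "f_pre_corrected", "logratio",
            "score", "se", "flag_floored", "flag_low_frequency",
            "flag_wt_indistinguishable", "flag_replicate_divergent",
            "flag_unpaired", "well_measured")
  res <- comb[keep]
  rownames(res) <- NULL
  res
}
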