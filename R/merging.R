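# Aggregation of codon-level scores to amino-acid level within biological
# replicates, combination of biological replicates, and the high-confidence
# subset used for clinical calibration.

#' Squash scores above one
#'
#' Under a loss-of-function mechanism only the distance below wild-type is
#' mechanistically meaningful, so above-1 outliers are compressed while
#' preserving rank order: `x' = 1 + (x - 1)/x` for `x > 1`, identity
#' otherwise. The transform is strictly increasing, idempotent at or below
#' 1, and bounded above by 2.
#'
#' @param x Scores.
#' @return Transformed scores.
#' @examples
#' squash_above_one(c(0.3, 1, 2)) # 0.3, 1, 1.5
#' @export
squash_above_one <- function(x) {
  ifelse(!is.na(x) & x > 1, 1 + (x - 1) / x, x)
}

# Derivative of the squash transform, for delta-method SE propagation.
squash_derivative <- function(x) {
  ifelse(!is.na(x) & x > 1, 1 / x^2, 1)
}

# Shared merge rule for a small set of replicate measurements of the same
# variant: 1 value -> itself; 2 values -> dropped iff they straddle the
# damaging/tolerated midpoint AND differ by more than conflict_delta, else
# their mean; >= 3 values -> median. se combined as se of the mean, scaled
# by 1.2533 (normal median efficiency) when the median is used.
merge_values <- function(scores, ses, conflict_delta = 0.3,
                         threshold = 0.5) {
  n <- length(scores)
  se_mean <- sqrt(sum(ses^2)) / n
  if (n == 1L) {
    return(list(score = scores, se = ses, n = 1L, dropped = FALSE))
  }
  if (n == 2L) {
    straddle <- (scores[1] - threshold) * (scores[2] - threshold) < 0
    if (straddle && abs(scores[1] - scores[2]) > conflict_delta) {
      return(list(score = NA_real_, se = NA_real_, n = 2L, dropped = TRUE))
    }
    return(list(score = mean(scores), se = se_mean, n = 2L, dropped = FALSE))
  }
  list(score = stats::median(scores), se = 1.2533 * se_mean, n = n,
       dropped = FALSE)
}

#' Merge codon-level scores for one amino-acid change
#'
#' Scores must already be on the squashed scale ([squash_above_one()]).
#' One codon: that score. Two codons: dropped if they disagree on damaging
#' versus tolerated (straddle `threshold`) by more than `conflict_delta`,
#' otherwise their mean. Three or more codons: the median.
#'
#' @param scores Per-codon (transformed) scores for a single amino-acid
#'   change.
#' @param ses Matching standard errors (default 0 when unknown).
#' @param conflict_delta Disagreement cutoff (default 0.3).
#' @param threshold Damaging/tolerated midpoint (default 0.5).
#' @return List with `score`, `se`, `n`, and logical `dropped`.
#' @examples
#' merge_codons(c(0.2, 0.9))$dropped   # TRUE: straddle and differ by 0.7
#' merge_codons(c(0.45, 0.55))$score   # 0.5
#' @export
merge_codons <- function(scores, ses = rep(0, length(scores)),
                         conflict_delta = 0.3, threshold = 0.5) {
  if (length(scores) < 1L) stop("at least one codon score required")
  merge_values(scores, ses, conflict_delta, threshold)
}

#' Merge biological-replicate scores for one amino-acid change
#'
#' Same agreement rule as [merge_codons()], except a variant measured in
#' only one biological replicate is removed (`dropped = TRUE`).
#'
#' @inheritParams merge_codons
#' @return List with `score`, `se`, `n`, and logical `dropped`.
#' @export
merge_bioreplicates <- function(scores, ses = rep(0, length(scores)),
                                conflict_delta = 0.3, threshold = 0.5) {
  if (length(scores) < 1L) stop("at least one replicate score required")
  if (length(scores) == 1L) {
    return(list(score = NA_real_, se = NA_real_, n = 1L, dropped = TRUE))
  }
  merge_values(scores, ses, conflict_delta, threshold)
}

#' High-confidence filter on the score confidence interval
#'
#' A record is high confidence when the closed interval
#' `[score - se, score + se]` excludes the intermediate score 0.5; an
#' interval touching 0.5 counts as overlapping.
#'
#' @param score,se Combined score and standard error.
#' @param threshold Intermediate score (default 0.5).
#' @return Logical vector.
#' @examples
#' high_confidence_filter(c(0.6, 0.55, 0.45), c(0.05, 0.10, 0.05))
#' @export
high_confidence_filter <- function(score, se, threshold = 0.5) {
  stopifnot(all(se >= 0, na.rm = TRUE))
  (score - se > threshold) | (score + se < threshold)
}

#' Merge per-replicate codon scores into the final variant effect map
#'
#' Takes the output of [score_replicates()] (possibly several biological
#' replicates), keeps well-measured records, squashes above-1 scores,
#' merges codons per amino-acid change within each biological replicate,
#' then merges biological replicates (removing variants seen in only one),
#' and marks the high-confidence subset whose score interval excludes 0.5.
#'
#' @param replicate_scores Data.frame from [score_replicates()].
#' @param conflict_delta Damaging/tolerated disagreement cutoff.
#' @param threshold Damaging/tolerated midpoint.
#' @param squash Apply [squash_above_one()] before merging (default TRUE).
#' @return List with `map` (columns `hgvs_pro`, `position`, `wt_aa`,
#'   `alt_aa`, `vclass`, `score`, `se`, `n_codons`, `n_bioreps`,
#'   `high_confidence`) and `audit` (data.frames of codon-conflict,
#'   biological-replicate-conflict, and single-replicate removals).
#' @export
merge_map <- function(replicate_scores, conflict_delta = 0.3,
                      threshold = 0.5, squash = TRUE) {
  rs <- replicate_scores[replicate_scores$well_measured &
                           !is.na(replicate_scores$score), ]
  if (nrow(rs) == 0L) stop("no well-measured replicate scores to merge")
  if (squash) {
    rs$se <- rs$se * squash_derivative(rs$score)
    rs$score <- squash_above_one(rs$score)
  }

  # codon merge within each biological replicate
  key <- paste(rs$bio_rep, rs$hgvs_pro, sep = "|")
  groups <- split(seq_len(nrow(rs)), key)
  per_rep <- lapply(groups, function(idx) {
    m <- merge_codons(rs$score[idx], rs$se[idx], conflict_delta, threshold)
    data.frame(bio_rep = rs$bio_rep[idx[1]], hgvs_pro = rs$hgvs_pro[idx[1]],
               position = rs$position[idx[1]], wt_aa = rs$wt_aa[idx[1]],
               alt_aa = rs$alt_aa[idx[1]], vclass = rs$vclass[idx[1]],
               score = m$score, se = m$se, n_codons = m$n,
               dropped = m$dropped, stringsAsFactors = FALSE)
  })
  per_rep <- do.call(rbind, per_rep)
  codon_conflicts <- per_rep[per_rep$dropped, c("bio_rep", "hgvs_pro")]
  per_rep <- per_rep[!per_rep$dropped, ]

  # biological-replicate merge
  groups <- split(seq_len(nrow(per_rep)), per_rep$hgvs_pro)
  merged <- lapply(groups, function(idx) {
    m <- merge_bioreplicates(per_rep$score[idx], per_rep$se[idx],
                             conflict_delta, threshold)
    data.frame(hgvs_pro = per_rep$hgvs_pro[idx[1]],
               position = per_rep$position[idx[1]],
               wt_aa = per_rep$wt_aa[idx[1]],
               alt_aa = per_rep$alt_aa[idx[1]],
               vclass = per_rep$vclass[idx[1]],
               score = m$score, se = m$se,
               n_codons = sum(per_rep$n_codons[idx]),
               n_bioreps = m$n, dropped = m$dropped,
               singleton = length(idx) == 1L,
               stringsAsFactors = FALSE)
  })
  merged <- do.call(rbind, merged)
  singletons <- merged[merged$singleton, "hgvs_pro", drop = FALSE]
  biorep_conflicts <- merged[merged$dropped & !merged$singleton,
                             "hgvs_pro", drop = FALSE]
  map <- merged[!merged$dropped, ]
  map$high_confidence <- high_confidence_filter(map$score, map$se, threshold)
  map$dropped <- NULL
  map$singleton <- NULL
  map <- map[order(map$position, map$alt_aa), ]
  rownames(map) <- NULL
  list(map = map,
       audit = list(codon_conflicts = codon_conflicts,
                    biorep_conflicts = biorep_conflicts,
                    singletons = singletons))
}
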