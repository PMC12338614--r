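# Clinical calibration: reference-set construction, kernel-density
# log-likelihood ratios regularized toward the uniform distribution, ACMG
# evidence-strength mapping via Tavtigian-derived thresholds, and balanced
# precision-recall evaluation.

#' Build the clinical reference set from classification points
#'
#' Variants with at least `path_points_min` pathogenic points (default 6,
#' covering pathogenic and likely-pathogenic) enter the positive set;
#' variants with at least `benign_points_min` benign points (default 2)
#' enter the negative set. Variants meeting neither threshold are excluded;
#' a variant qualifying for both is a data-consistency error.
#'
#' @param table Data.frame with `hgvs_pro` and either a `label` column
#'   (pathogenic/benign) or `pathogenic_points` and `benign_points`.
#' @param path_points_min,benign_points_min Inclusion thresholds.
#' @return Data.frame with `hgvs_pro` and `label`.
#' @export
build_reference <- function(table, path_points_min = 6,
                            benign_points_min = 2) {
  stopifnot("hgvs_pro" %in% names(table))
  if ("label" %in% names(table)) {
    ok <- table$label %in% c("pathogenic", "benign")
    if (!all(ok)) stop("unknown reference label: ", table$label[!ok][1])
    out <- table[c("hgvs_pro", "label")]
    rownames(out) <- NULL
    return(out)
  }
  if (!all(c("pathogenic_points", "benign_points") %in% names(table))) {
    stop("reference table needs either a label column or ",
         "pathogenic_points and benign_points")
  }
  is_path <- table$pathogenic_points >= path_points_min
  is_ben <- table$benign_points >= benign_points_min
  both <- is_path & is_ben
  if (any(both)) {
    stop("variant qualifies for both reference sets: ",
         table$hgvs_pro[both][1])
  }
  keep <- is_path | is_ben
  data.frame(hgvs_pro = table$hgvs_pro[keep],
             label = ifelse(is_path[keep], "pathogenic", "benign"),
             stringsAsFactors = FALSE)
}

#' Gaussian kernel density with biased cross-validation bandwidth
#'
#' Bandwidth is chosen by biased cross-validation (`stats::bw.bcv`); when
#' BCV fails to bracket a minimum or yields a non-finite value (common at
#' small n), Silverman's rule (`stats::bw.nrd0`) is used, and when that is
#' degenerate (zero spread) a small constant on the score scale is used.
#' The method actually used is recorded in the result.
#'
#' @param scores Numeric scores for one reference class (>= 2 values).
#' @return List with `bw`, `bw_method`, `n`, and the input `scores`.
#' @export
fit_kde <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2L) {
    stop("kernel density estimation needs at least 2 scores")
  }
  bw <- suppressWarnings(
    tryCatch(stats::bw.bcv(scores), error = function(e) NA_real_)
  )
  method <- "bcv"
  if (!is.finite(bw) || bw <= 0) {
    bw <- tryCatch(stats::bw.nrd0(scores), error = function(e) NA_real_)
    method <- "nrd0"
  }
  if (!is.finite(bw) || bw <= 0) {
    bw <- 0.05
    method <- "constant"
  }
  list(bw = bw, bw_method = method, n = length(scores), scores = scores)
}

# Evaluate a Gaussian-kernel density on a grid over `support` and return an
# interpolating function normalized to integrate to 1 over the support.
kde_density_fun <- function(kde, support) {
  d <- stats::density(kde$scores, bw = kde$bw, kernel = "gaussian",
                      from = support[1], to = support[2], n = 512L)
  dx <- diff(d$x[1:2])
  mass <- sum(d$y) * dx
  y <- d$y / mass
  stats::approxfun(d$x, y, rule = 2L)
}

#' Fit the score-to-evidence calibration model
#'
#' Pathogenic and benign reference score densities are estimated separately
#' with [fit_kde()]. The support is the pooled score range extended by three
#' times the larger bandwidth on each side, so both densities are proper on
#' it. The ACMG log10 likelihood-ratio thresholds default to the printed
#' constants derived from the Tavtigian framework (see
#' [tavtigian_thresholds()]): 2.5/1.3/0.64/0.32 on the pathogenic side and
#' -0.32/-1.32 on the benign side.
#'
#' @param path_scores,benign_scores Functional scores of the pathogenic and
#'   benign reference variants.
#' @param w Uniform-regularization weight in pseudo-observations per class.
#' @param thresholds Named numeric LLR cutpoints.
#' @return A `calibration_model` object.
#' @export
fit_calibration <- function(path_scores, benign_scores, w = 1,
                            thresholds = c(very_strong_path = 2.5,
                                           strong_path = 1.3,
                                           moderate_path = 0.64,
                                           supporting_path = 0.32,
                                           supporting_benign = -0.32,
                                           strong_benign = -1.32)) {
  kp <- fit_kde(path_scores)
  kb <- fit_kde(benign_scores)
  h <- max(kp$bw, kb$bw)
  pooled <- c(kp$scores, kb$scores)
  support <- c(min(pooled) - 3 * h, max(pooled) + 3 * h)
  structure(
    list(f_path = kde_density_fun(kp, support),
         f_benign = kde_density_fun(kb, support),
         bw_path = kp$bw, bw_benign = kb$bw,
         bw_method_path = kp$bw_method, bw_method_benign = kb$bw_method,
         n_path = kp$n, n_benign = kb$n,
         w = w, support = support, thresholds = thresholds),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("calibration_model:\n",
      "  pathogenic: n = ", x$n_path, ", bandwidth = ",
      signif(x$bw_path, 4), " (", x$bw_method_path, ")\n",
      "  benign:     n = ", x$n_benign, ", bandwidth = ",
      signif(x$bw_benign, 4), " (", x$bw_method_benign, ")\n",
      "  regularization weight w = ", x$w,
      ", support = [", signif(x$support[1], 4), ", ",
      signif(x$support[2], 4), "]\n", sep = "")
  invisible(x)
}

#' Log10 likelihood ratio of pathogenicity
#'
#' Each class density f is regularized toward the uniform density u on the
#' model support, `f~ = (n*f + w*u) / (n + w)` with n the class reference
#' count, avoiding extreme LLRs in score ranges containing few reference
#' variants. The returned value is `log10(f~_path / f~_benign)`. Scores
#' outside the support are evaluated at the nearest endpoint and flagged in
#' the `clamped` attribute.
#'
#' @param score Functional scores.
#' @param model A [fit_calibration()] model.
#' @return Numeric LLRs with a logical `clamped` attribute.
#' @export
llr <- function(score, model) {
  stopifnot(inherits(model, "calibration_model"))
  clamped <- score < model$support[1] | score > model$support[2]
  x <- pmin(pmax(score, model$support[1]), model$support[2])
  u <- 1 / diff(model$support)
  fp <- (model$n_path * model$f_path(x) + model$w * u) /
    (model$n_path + model$w)
  fb <- (model$n_benign * model$f_benign(x) + model$w * u) /
    (model$n_benign + model$w)
  structure(log10(fp / fb), clamped = clamped)
}

#' Map an LLR value to an ACMG evidence-strength category
#'
#' Pathogenic side: very strong above 2.5; strong in (1.3, 2.5]; moderate
#' in (0.64, 1.3]; supporting in (0.32, 0.64]. Benign side: supporting in
#' [-1.32, -0.32]; strong below -1.32. LLRs strictly between -0.32 and 0.32
#' carry no evidence.
#'
#' @param llr_value Numeric LLR values.
#' @param thresholds Named cutpoints as in [fit_calibration()].
#' @return Character vector of category labels.
#' @examples
#' acmg_category(c(2.6, 0.5, -1.5))
#' @export
acmg_category <- function(llr_value,
                          thresholds = c(very_strong_path = 2.5,
                                         strong_path = 1.3,
                                         moderate_path = 0.64,
                                         supporting_path = 0.32,
                                         supporting_benign = -0.32,
                                         strong_benign = -1.32)) {
  stopifnot(all(is.finite(llr_value)))
  t <- thresholds
  out <- rep("none", length(llr_value))
  out[llr_value > t[["very_strong_path"]]] <- "very_strong_path"
  out[llr_value > t[["strong_path"]] &
        llr_value <= t[["very_strong_path"]]] <- "strong_path"
  out[llr_value > t[["moderate_path"]] &
        llr_value <= t[["strong_path"]]] <- "moderate_path"
  out[llr_value > t[["supporting_path"]] &
        llr_value <= t[["moderate_path"]]] <- "supporting_path"
  out[llr_value <= t[["supporting_benign"]] &
        llr_value >= t[["strong_benign"]]] <- "supporting_benign"
  out[llr_value < t[["strong_benign"]]] <- "strong_benign"
  out
}

#' Tavtigian-style evidence-strength thresholds
#'
#' Starting from the odds of pathogenicity assigned to very strong evidence
#' and halving the exponent per evidence level, the LLR threshold for level
#' k (k = 0 very strong, 1 strong, 2 moderate, 3 supporting) is
#' `log10(odds^(1/2^k))`. With odds 350 this yields 2.544, 1.272, 0.636,
#' 0.318, which round to the conventional 2.5, 1.3, 0.64 and 0.32.
#'
#' @param odds_very_strong Odds of pathogenicity for very strong evidence
#'   (> 1).
#' @param levels Number of evidence levels.
#' @return Numeric thresholds, named very_strong/strong/moderate/supporting
#'   (extra levels unnamed).
#' @examples
#' round(tavtigian_thresholds(350), 3)
#' @export
tavtigian_thresholds <- function(odds_very_strong = 350, levels = 4L) {
  if (odds_very_strong <= 1) stop("odds_very_strong must exceed 1")
  if (levels < 1L) stop("levels must be at least 1")
  th <- log10(odds_very_strong) / 2^(seq_len(levels) - 1L)
  names(th) <- c("very_strong", "strong", "moderate",
                 "supporting")[seq_len(min(levels, 4L))]
  th
}

#' Balanced precision-recall curve, AUBPRC and R90BP
#'
#' Thresholds t sweep the observed scores (ties called together, with -Inf
#' and +Inf endpoints); a variant is called pathogenic when its score is at
#' most t (damaging variants score low). Recall is the fraction of
#' pathogenic reference variants called; the false-positive rate F is the
#' fraction of benign ones called; balanced precision `BP = R / (R + F)` is
#' the precision expected were the two reference sets equally sized. AUBPRC
#' is the trapezoidal area under BP versus recall, and R90BP the maximum
#' recall achieved with BP >= 0.90.
#'
#' @param scores Functional scores of reference variants.
#' @param labels Matching labels, `"pathogenic"` or `"benign"` (at least 2
#'   of each).
#' @return List with `curve` (threshold, recall, fpr, balanced_precision),
#'   `aubprc`, and `r90bp`.
#' @export
balanced_prc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- is.finite(scores) & labels %in% c("pathogenic", "benign")
  scores <- scores[ok]
  labels <- labels[ok]
  n_path <- sum(labels == "pathogenic")
  n_ben <- sum(labels == "benign")
  if (n_path < 2L || n_ben < 2L) {
    stop("balanced_prc needs at least 2 pathogenic and 2 benign variants")
  }
  thr <- c(-Inf, sort(unique(scores)), Inf)
  recall <- vapply(thr, function(t)
    sum(scores <= t & labels == "pathogenic") / n_path, 0)
  fpr <- vapply(thr, function(t)
    sum(scores <= t & labels == "benign") / n_ben, 0)
  bp <- ifelse(recall + fpr > 0, recall / (recall + fpr), 1)
  o <- order(recall)
  r <- recall[o]
  b <- bp[o]
  aubprc <- sum(diff(r) * (utils::head(b, -1) + utils::tail(b, -1)) / 2)
  r90 <- if (any(b >= 0.90)) max(r[b >= 0.90]) else 0
  list(curve = data.frame(threshold = thr, recall = recall, fpr = fpr,
                          balanced_precision = bp),
       aubprc = aubprc, r90bp = r90)
}

#' Calibrate a variant effect map against a clinical reference set
#'
#' Joins the reference set to the map, fits the kernel-density calibration
#' on the reference scores, computes the LLR and ACMG evidence category for
#' every scored map variant, and evaluates separation of the reference
#' classes with [balanced_prc()].
#'
#' @param map Map data.frame (columns `hgvs_pro`, `score`, `se`,
#'   `high_confidence` as from [merge_map()]).
#' @param reference Reference table accepted by [build_reference()].
#' @param high_confidence_only Restrict to high-confidence map scores
#'   (default TRUE, matching the use of post-filter scores for clinical
#'   calibration).
#' @param w Uniform-regularization weight.
#' @return List with `model`, `scores` (hgvs_pro, score, llr, evidence,
#'   clamped), `evaluation` (balanced PRC of the assayed reference
#'   variants), and `reference_used`.
#' @export
calibrate_map <- function(map, reference, high_confidence_only = TRUE,
                          w = 1) {
  ref <- build_reference(reference)
  m <- map
  if (high_confidence_only) {
    if (!"high_confidence" %in% names(m)) {
      stop("map lacks a high_confidence column; ",
           "set high_confidence_only = FALSE or merge with standard errors")
    }
    m <- m[!is.na(m$high_confidence) & m$high_confidence, ]
  }
  ref$score <- m$score[match(ref$hgvs_pro, m$hgvs_pro)]
  assayed <- ref[!is.na(ref$score), ]
  if (sum(assayed$label == "pathogenic") < 2L ||
      sum(assayed$label == "benign") < 2L) {
    stop("need at least 2 assayed pathogenic and 2 assayed benign ",
         "reference variants")
  }
  model <- fit_calibration(assayed$score[assayed$label == "pathogenic"],
                           assayed$score[assayed$label == "benign"], w = w)
  lv <- llr(m$score, model)
  scores <- data.frame(hgvs_pro = m$hgvs_pro, score = m$score,
                       llr = as.numeric(lv),
                       evidence = acmg_category(as.numeric(lv),
                                                model$thresholds),
                       clamped = attr(lv, "clamped"),
                       stringsAsFactors = FALSE)
  list(model = model, scores = scores,
       evaluation = balanced_prc(assayed$score, assayed$label),
       reference_used = assayed)
}
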