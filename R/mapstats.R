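# Descriptive analytics over a finished map: moving-window class medians,
# region/motif summaries, damaging/tolerated classification and coverage
# accounting.

#' Define a protein region or motif
#'
#' @param name Region name.
#' @param start,end Inclusive 1-based residue bounds.
#' @param positions Optional explicit position list (e.g. the conserved
#'   residues of a motif); all must lie within `[start, end]`.
#' @return A `region_spec` list.
#' @export
region_spec <- function(name, start, end, positions = NULL) {
  stopifnot(start >= 1L, start <= end)
  if (!is.null(positions)) {
    positions <- as.integer(positions)
    if (any(positions < start | positions > end)) {
      stop("explicit positions must lie within [start, end]")
    }
  }
  structure(list(name = name, start = as.integer(start),
                 end = as.integer(end), positions = positions),
            class = "region_spec")
}

region_positions <- function(region) {
  region$positions %||% seq(region$start, region$end)
}

#' Complement of one region within another
#'
#' Returns a region covering the positions of `within` that are not in
#' `region` (e.g. the kinase domain minus its motif positions).
#'
#' @param within,region `region_spec` objects.
#' @return A `region_spec` with explicit positions.
#' @export
region_minus <- function(within, region) {
  pos <- setdiff(region_positions(within), region_positions(region))
  if (length(pos) == 0L) {
    return(region_spec(paste0(within$name, "_minus_", region$name),
                       within$start, within$end, integer(0)))
  }
  region_spec(paste0(within$name, "_minus_", region$name),
              min(pos), max(pos), pos)
}

#' Moving-window class medians along the protein
#'
#' For each start position p the median score of class-`vclass` variants at
#' positions `[p, p + width - 1]` is reported (trailing windows keep their
#' actual, shorter span). Windows containing no variants yield NA.
#'
#' @param map Map data.frame with `position`, `vclass`, `score`.
#' @param vclass Variant class to summarize (default missense).
#' @param width Window width in residues (default 10).
#' @param protein_length Protein length; defaults to the largest map
#'   position.
#' @return Data.frame with `start`, `end`, `n`, `median`.
#' @export
moving_window_median <- function(map, vclass = "missense", width = 10L,
                                 protein_length = NULL) {
  stopifnot(width >= 1L)
  L <- protein_length %||% max(map$position)
  sub <- map[map$vclass == vclass & !is.na(map$score), ]
  out <- data.frame(start = seq_len(L))
  out$end <- pmin(out$start + width - 1L, L)
  stats_fn <- function(s, e) {
    x <- sub$score[sub$position >= s & sub$position <= e]
    c(n = length(x), median = if (length(x)) stats::median(x) else NA_real_)
  }
  m <- mapply(stats_fn, out$start, out$end)
  out$n <- as.integer(m["n", ])
  out$median <- m["median", ]
  out
}

#' Classify scores as damaging or tolerated
#'
#' Strictly below the threshold is damaging, strictly above is tolerated;
#' a score exactly at the threshold is unclassified.
#'
#' @param score Scores.
#' @param threshold Midpoint (default 0.5).
#' @return Character vector: damaging / tolerated / unclassified (NA in,
#'   NA out).
#' @export
classify_score <- function(score, threshold = 0.5) {
  out <- ifelse(score < threshold, "damaging",
                ifelse(score > threshold, "tolerated", "unclassified"))
  out[is.na(score)] <- NA_character_
  out
}

#' Summarize map scores over a region
#'
#' @param map Map data.frame with `position`, `vclass`, `score`.
#' @param region A [region_spec()].
#' @param vclass Optional class filter (e.g. "missense").
#' @param threshold Damaging/tolerated midpoint.
#' @return One-row data.frame: `region`, `n`, `median`, `fraction_damaging`,
#'   `fraction_tolerated`. For an empty selection n = 0 and the statistics
#'   are NA.
#' @export
region_summary <- function(map, region, vclass = NULL, threshold = 0.5) {
  stopifnot(inherits(region, "region_spec"))
  sel <- map$position %in% region_positions(region) & !is.na(map$score)
  if (!is.null(vclass)) sel <- sel & map$vclass %in% vclass
  x <- map$score[sel]
  if (length(x) == 0L) {
    return(data.frame(region = region$name, n = 0L, median = NA_real_,
                      fraction_damaging = NA_real_,
                      fraction_tolerated = NA_real_))
  }
  cls <- classify_score(x, threshold)
  data.frame(region = region$name, n = length(x),
             median = stats::median(x),
             fraction_damaging = mean(cls == "damaging"),
             fraction_tolerated = mean(cls == "tolerated"))
}

#' Rank-sum comparison of scores between two regions
#'
#' Wilcoxon rank-sum test of map scores at the positions of `region_a`
#' against those of `region_b`.
#'
#' @param map Map data.frame.
#' @param region_a,region_b [region_spec()] objects.
#' @param vclass Optional class filter.
#' @param alternative Passed to [stats::wilcox.test()]; `"less"` tests
#'   whether `region_a` scores are lower (the usual motif-versus-background
#'   direction).
#' @return The `htest` result.
#' @export
compare_regions <- function(map, region_a, region_b, vclass = NULL,
                            alternative = "two.sided") {
  sel <- function(region) {
    s <- map$position %in% region_positions(region) & !is.na(map$score)
    if (!is.null(vclass)) s <- s & map$vclass %in% vclass
    map$score[s]
  }
  a <- sel(region_a)
  b <- sel(region_b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("empty selection in region comparison")
  }
  stats::wilcox.test(a, b, alternative = alternative, exact = FALSE)
}

#' Coverage accounting against the substitution universe
#'
#' Counts scored variants by class and relates scored missense variants to
#' the possible-substitution universe (19 alternates at every position but
#' the initiator methionine) and to the subset reachable by single
#' nucleotide change from the supplied CDS.
#'
#' @param map Map data.frame with `hgvs_pro`, `position`, `alt_aa`,
#'   `vclass`, optionally `high_confidence`.
#' @param cds The [coding_sequence()] the map coordinates refer to.
#' @return Data.frame of labelled counts.
#' @export
coverage_report <- function(map, cds) {
  stopifnot(inherits(cds, "coding_sequence"))
  if (any(map$position > cds$protein_length)) {
    stop("map contains positions beyond the CDS protein length")
  }
  if (anyDuplicated(map$hgvs_pro)) {
    stop("duplicate hgvs_pro entries in map")
  }
  poss <- enumerate_possible_substitutions(cds)
  snv <- snv_reachable_set(cds)
  mis <- map[map$vclass == "missense", ]
  key <- function(df) paste(df$position, df$alt_aa)
  scored_in_possible <- sum(key(mis) %in% key(poss))
  scored_in_snv <- sum(key(mis) %in% key(snv$missense))
  hc <- if ("high_confidence" %in% names(map)) {
    sum(mis$high_confidence, na.rm = TRUE)
  } else NA_integer_
  data.frame(
    quantity = c("scored_missense", "scored_synonymous", "scored_nonsense",
                 "possible_substitutions", "scored_of_possible",
                 "snv_reachable_missense", "scored_of_snv_reachable",
                 "high_confidence_missense"),
    count = c(nrow(mis), sum(map$vclass == "synonymous"),
              sum(map$vclass == "nonsense"), nrow(poss),
              scored_in_possible, nrow(snv$missense), scored_in_snv, hc)
  )
}

#' Built-in STK11 region and motif presets
#'
#' Coordinates of the STK11 kinase domain, catalytic motifs and terminal
#' regions, read from the packaged region table. Motifs with conserved-
#' position ambiguity are provided as full spans; combine with
#' [region_minus()] for complements.
#'
#' @return Named list of [region_spec()] objects.
#' @export
stk11_regions <- function() {
  path <- system.file("extdata", "stk11_regions.csv", package = "dmsmap")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    pos <- if (nzchar(tab$positions[i])) {
      as.integer(strsplit(tab$positions[i], ";")[[1]])
    } else NULL
    region_spec(tab$name[i], tab$start[i], tab$end[i], pos)
  })
  names(out) <- tab$name
  out
}
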