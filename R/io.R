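# Readers/writers for the pipeline's delimited formats, the pipeline
# configuration object, and the end-to-end driver.

#' Read a per-tile variant count table
#'
#' Delimited text (comma or tab, auto-detected) with header columns `tile`,
#' `bio_rep`, `tech_rep`, `condition`, `count`, `depth` and the codon change
#' as `position`, `wt_codon`, `alt_codon`. Conditions must be one of
#' preselect, select, wtctrl_pre, wtctrl_sel.
#'
#' @param path Input file.
#' @return Validated count data.frame.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  counts <- utils::read.table(path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE)
  need <- c("tile", "bio_rep", "tech_rep", "condition", "position",
            "wt_codon", "alt_codon", "count", "depth")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0) {
    stop("count table missing columns: ", paste(miss, collapse = ", "))
  }
  if (any(counts$count < 0) || any(counts$depth <= 0)) {
    stop("counts must be non-negative and depths positive")
  }
  if (any(counts$count > counts$depth)) {
    stop("marginal count exceeds effective depth at line ",
         which(counts$count > counts$depth)[1] + 1L)
  }
  counts
}

#' Write a count table
#' @param counts Count data.frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_count_table <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a variant effect map CSV
#'
#' MaveDB-style schema: `hgvs_pro`, `score`, and optionally `se`,
#' `n_codons`, `n_bioreps`, `high_confidence`; extra columns are kept.
#' Duplicate `hgvs_pro` entries and non-numeric scores are errors (reported
#' with their line number). A file without `se` loads with
#' `high_confidence` undefined (NA).
#'
#' @param path Input CSV.
#' @return Map data.frame, annotated with `position`, `wt_aa`, `alt_aa`,
#'   `vclass` parsed from `hgvs_pro`.
#' @export
read_map_csv <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path)
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("hgvs_pro", "score") %in% names(map))) {
    stop("map CSV must have hgvs_pro and score columns")
  }
  dup <- duplicated(map$hgvs_pro)
  if (any(dup)) {
    stop("duplicate variant '", map$hgvs_pro[dup][1], "' at line ",
         which(dup)[1] + 1L)
  }
  sc <- suppressWarnings(as.numeric(map$score))
  bad <- is.na(sc) & !is.na(map$score) & map$score != "NA"
  if (any(bad)) {
    stop("malformed score '", map$score[bad][1], "' at line ",
         which(bad)[1] + 1L)
  }
  map$score <- sc
  parsed <- parse_hgvs_pro(map$hgvs_pro)
  map$position <- parsed$position
  map$wt_aa <- parsed$wt_aa
  map$alt_aa <- parsed$alt_aa
  map$vclass <- parsed$vclass
  if (!"se" %in% names(map)) {
    map$se <- NA_real_
  } else {
    map$se <- suppressWarnings(as.numeric(map$se))
  }
  if (!"high_confidence" %in% names(map)) {
    map$high_confidence <- ifelse(is.na(map$se), NA,
                                  high_confidence_filter(map$score, map$se))
  }
  map
}

#' Write a variant effect map CSV
#' @param map Map data.frame with at least `hgvs_pro` and `score`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(all(c("hgvs_pro", "score") %in% names(map)))
  utils::write.csv(map, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a clinical reference table
#'
#' CSV with `hgvs_pro` and either `label` (pathogenic/benign) or
#' `pathogenic_points` and `benign_points`.
#'
#' @param path Input CSV.
#' @return Data.frame as read (validated by [build_reference()]).
#' @export
read_reference_csv <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with defaults equal to the
#' published constants: frequency threshold 2e-5, divergence multiplier 3,
#' codon/replicate conflict delta 0.3, window width 10, classification
#' threshold 0.5, bootstrap B = 1000.
#'
#' @param cds_path Path to the CDS FASTA.
#' @param counts_path Path to a count table, or NULL to simulate.
#' @param reference_path Optional clinical reference CSV.
#' @param out_dir Output directory for artifacts.
#' @param seed Master seed for simulation and bootstrap.
#' @param simulate Optional [simulation_config()] used when `counts_path`
#'   is NULL.
#' @param n_alt_codons Library subset size for simulation (NULL = full).
#' @param freq_threshold,divergence_multiplier,alpha,boot Scoring
#'   parameters (see [score_replicates()]).
#' @param conflict_delta,squash Merging parameters (see [merge_map()]).
#' @param regularization_w,high_confidence_only Calibration parameters.
#' @param window_width,class_threshold Map-statistics parameters.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cds_path, counts_path = NULL,
                            reference_path = NULL, out_dir = tempdir(),
                            seed = 1L, simulate = NULL, n_alt_codons = NULL,
                            freq_threshold = 2e-5, divergence_multiplier = 3,
                            alpha = 0.05, boot = 1000L,
                            conflict_delta = 0.3, squash = TRUE,
                            regularization_w = 1,
                            high_confidence_only = TRUE,
                            window_width = 10L, class_threshold = 0.5) {
  structure(
    list(cds_path = cds_path, counts_path = counts_path,
         reference_path = reference_path, out_dir = out_dir,
         seed = as.integer(seed), simulate = simulate,
         n_alt_codons = n_alt_codons,
         freq_threshold = freq_threshold,
         divergence_multiplier = divergence_multiplier,
         alpha = alpha, boot = as.integer(boot),
         conflict_delta = conflict_delta, squash = squash,
         regularization_w = regularization_w,
         high_confidence_only = high_confidence_only,
         window_width = as.integer(window_width),
         class_threshold = class_threshold),
    class = "pipeline_config"
  )
}

#' Run the full pipeline
#'
#' (Optionally simulate) -> score -> merge -> (optionally calibrate) ->
#' map statistics, writing every intermediate as CSV into
#' `config$out_dir` together with a plain-text run log recording package
#' version, parameters and record counts at each filter stage. The whole
#' run is deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with `replicate_scores`, `map`, `audit`,
#'   `calibration` (or NULL), `coverage`, `window_medians`, and `log_lines`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    paste0("dmsmap version: ",
           as.character(utils::packageVersion("dmsmap"))),
    paste0("seed: ", config$seed),
    paste0("freq_threshold: ", config$freq_threshold),
    paste0("divergence_multiplier: ", config$divergence_multiplier),
    paste0("conflict_delta: ", config$conflict_delta),
    paste0("bootstrap_B: ", config$boot)
  )
  say <- function(...) log_lines <<- c(log_lines, paste0(...))

  cds <- read_cds(config$cds_path)
  say("cds: ", cds$name, " (", cds$protein_length, " aa)")

  if (is.null(config$counts_path)) {
    sim_cfg <- config$simulate %||%
      simulation_config(seed = config$seed,
                        n_positions = cds$protein_length)
    sim <- simulate_experiment(sim_cfg, cds,
                               n_alt_codons = config$n_alt_codons)
    counts <- sim$counts
    write_count_table(counts, file.path(config$out_dir, "counts.csv"))
    utils::write.csv(sim$truth,
                     file.path(config$out_dir, "true_scores.csv"),
                     row.names = FALSE, quote = FALSE)
    say("simulated counts: ", nrow(counts), " records, ",
        nrow(sim$codon_variants), " codon variants")
  } else {
    counts <- read_count_table(config$counts_path)
    say("read counts: ", nrow(counts), " records")
  }

  rs <- score_replicates(counts,
                         freq_threshold = config$freq_threshold,
                         divergence_multiplier = config$divergence_multiplier,
                         alpha = config$alpha, B = config$boot,
                         seed = config$seed)
  utils::write.csv(rs, file.path(config$out_dir, "replicate_scores.csv"),
                   row.names = FALSE, quote = FALSE)
  say("scored codon-replicate records: ", nrow(rs))
  say("  flagged low_frequency: ", sum(rs$flag_low_frequency))
  say("  flagged wt_indistinguishable: ", sum(rs$flag_wt_indistinguishable))
  say("  flagged replicate_divergent: ", sum(rs$flag_replicate_divergent))
  say("  well_measured: ", sum(rs$well_measured))

  merged <- merge_map(rs, conflict_delta = config$conflict_delta,
                      threshold = config$class_threshold,
                      squash = config$squash)
  map <- merged$map
  write_map_csv(map[c("hgvs_pro", "score", "se", "n_codons", "n_bioreps",
                      "high_confidence")],
                file.path(config$out_dir, "map.csv"))
  say("merged amino-acid variants: ", nrow(map))
  say("  codon conflicts dropped: ", nrow(merged$audit$codon_conflicts))
  say("  biorep conflicts dropped: ", nrow(merged$audit$biorep_conflicts))
  say("  single-replicate removals: ", nrow(merged$audit$singletons))
  say("  high_confidence: ", sum(map$high_confidence))

  calibration <- NULL
  if (!is.null(config$reference_path)) {
    reference <- read_reference_csv(config$reference_path)
    calibration <- calibrate_map(
      map, reference,
      high_confidence_only = config$high_confidence_only,
      w = config$regularization_w
    )
    utils::write.csv(calibration$scores,
                     file.path(config$out_dir, "llr.csv"),
                     row.names = FALSE, quote = FALSE)
    say("calibration: AUBPRC = ",
        signif(calibration$evaluation$aubprc, 4),
        ", R90BP = ", signif(calibration$evaluation$r90bp, 4))
  }

  coverage <- coverage_report(map, cds)
  utils::write.csv(coverage, file.path(config$out_dir, "coverage.csv"),
                   row.names = FALSE, quote = FALSE)
  windows <- moving_window_median(map, "missense", config$window_width,
                                  cds$protein_length)
  utils::write.csv(windows,
                   file.path(config$out_dir, "window_medians.csv"),
                   row.names = FALSE, quote = FALSE)

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(replicate_scores = rs, map = map, audit = merged$audit,
                 calibration = calibration, coverage = coverage,
                 window_medians = windows, log_lines = log_lines))
}
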