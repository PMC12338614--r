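# Synthetic experiment generator: emulates a tiled growth-selection deep
# mutational scan (HeLa-style, where loss-of-function variants gain fitness)
# with known ground-truth functional scores, shared per-variant sequencing
# error between the mutagenized and wild-type control libraries, log-normal
# clone abundances, and Poisson sequencing counts.

#' Configuration for the synthetic TileSeq experiment
#'
#' Defaults mirror the full-scale study design: a 433-codon ORF sequenced as
#' 12 tiles (~110 nt each) at 2 million reads per tile, three biological
#' replicates (independent transfections) each with two technical replicates
#' (separate lineages of the same transfection), and growth selection in
#' which null variants enrich about 8-fold over the selection period
#' (`selection_strength = log(8)`).
#'
#' @param seed Master seed; all randomness in the generator derives from it.
#' @param n_positions Number of codons (protein residues) in the target.
#' @param tiles Optional data.frame with columns `tile`, `start`, `end`
#'   (inclusive codon ranges) partitioning `1:n_positions`; by default
#'   `n_tiles` near-equal tiles are used.
#' @param n_tiles Number of tiles when `tiles` is NULL.
#' @param depth_per_tile Expected sequencing reads per tile per condition.
#' @param n_bio_replicates,n_tech_replicates Replicate structure.
#' @param selection_strength Dimensionless log-fitness span gamma*T: the
#'   expected pre-normalization log enrichment of a fully null variant.
#' @param error_rate_mean,error_rate_dispersion Mean and log-scale sd of the
#'   long-tailed (log-normal) per-variant sequencing-error frequency, shared
#'   exactly between mutagenized and wild-type control libraries.
#' @param mean_variant_frequency Mean pre-selection frequency of a codon
#'   variant in the library.
#' @param clone_sdlog Log-scale sd of per-clone abundance jitter.
#' @param damaging_fraction,tolerated_mean,tolerated_sd,damaging_mean,damaging_sd
#'   True-score mixture: missense variants are damaging with probability
#'   `damaging_fraction` (score ~ Normal(damaging_mean, damaging_sd)),
#'   otherwise tolerated (~ Normal(tolerated_mean, tolerated_sd)).
#' @param bio_noise_sd Per-biological-replicate log-fitness jitter sd.
#' @param core_range Inclusive residue range in which nonsense variants are
#'   null-like; outside it (terminal regions) they behave tolerated.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_positions = 433L,
                              tiles = NULL,
                              n_tiles = 12L,
                              depth_per_tile = 2e6,
                              n_bio_replicates = 3L,
                              n_tech_replicates = 2L,
                              selection_strength = log(8),
                              error_rate_mean = 2e-6,
                              error_rate_dispersion = 1,
                              mean_variant_frequency = 2e-4,
                              clone_sdlog = 0.5,
                              damaging_fraction = 0.2,
                              tolerated_mean = 1, tolerated_sd = 0.15,
                              damaging_mean = 0, damaging_sd = 0.15,
                              bio_noise_sd = 0.1,
                              core_range = c(22L, 311L)) {
  stopifnot(n_positions >= 2L, depth_per_tile > 0,
            n_bio_replicates >= 1L, n_tech_replicates >= 1L,
            error_rate_mean >= 0, mean_variant_frequency > 0,
            damaging_fraction >= 0, damaging_fraction <= 1,
            bio_noise_sd >= 0)
  if (is.null(tiles)) {
    n_tiles <- min(n_tiles, n_positions)
    cuts <- floor(seq(0L, n_positions, length.out = n_tiles + 1L))
    tiles <- data.frame(
      tile = sprintf("tile%02d", seq_len(n_tiles)),
      start = cuts[-length(cuts)] + 1L,
      end = cuts[-1L],
      stringsAsFactors = FALSE
    )
  }
  tiles <- tiles[order(tiles$start), , drop = FALSE]
  covered <- unlist(Map(seq, tiles$start, tiles$end))
  if (!identical(sort(as.integer(covered)), seq_len(n_positions))) {
    stop("tiles must partition positions 1..", n_positions)
  }
  if (core_range[1] > core_range[2]) stop("core_range must be increasing")
  structure(
    list(seed = as.integer(seed), n_positions = as.integer(n_positions),
         tiles = tiles, depth_per_tile = depth_per_tile,
         n_bio_replicates = as.integer(n_bio_replicates),
         n_tech_replicates = as.integer(n_tech_replicates),
         selection_strength = selection_strength,
         error_rate_mean = error_rate_mean,
         error_rate_dispersion = error_rate_dispersion,
         mean_variant_frequency = mean_variant_frequency,
         clone_sdlog = clone_sdlog,
         damaging_fraction = damaging_fraction,
         tolerated_mean = tolerated_mean, tolerated_sd = tolerated_sd,
         damaging_mean = damaging_mean, damaging_sd = damaging_sd,
         bio_noise_sd = bio_noise_sd,
         core_range = as.integer(core_range)),
    class = "simulation_config"
  )
}

#' Enumerate codon variants present in a mutagenized library
#'
#' POPCode-style NNN codon randomization can produce any of the 63 non-wild-
#' type codons at each position; optionally a random subset per position is
#' kept to model incomplete libraries (and to keep test problems small).
#'
#' @param cds A [coding_sequence()].
#' @param positions Codon positions to mutagenize (default all).
#' @param n_alt_codons If non-NULL, number of alternate codons sampled per
#'   position (deterministic given `seed`).
#' @param seed Seed for the per-position subset draw.
#' @return Data.frame of codon variants with protein-level annotation.
#' @export
enumerate_codon_variants <- function(cds, positions = NULL,
                                     n_alt_codons = NULL, seed = 1L) {
  stopifnot(inherits(cds, "coding_sequence"))
  positions <- positions %||% seq_len(cds$protein_length)
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  pick <- function(wt) {
    alts <- setdiff(all_codons, wt)
    if (!is.null(n_alt_codons) && n_alt_codons < length(alts)) {
      alts <- sample(alts, n_alt_codons)
    }
    alts
  }
  with_seed(seed, {
    alt_list <- lapply(cds$codons[positions], pick)
  })
  n_per <- lengths(alt_list)
  pos <- rep(positions, n_per)
  translate_codon_variant(cds, pos, cds$codons[pos],
                          unlist(alt_list, use.names = FALSE))
}

#' Assign ground-truth functional scores
#'
#' Scores are on the map scale: 1 is wild-type-like, 0 is null-like.
#' Synonymous variants draw from the tolerated component; nonsense variants
#' draw from the damaging component inside `core_range` and from the
#' tolerated component outside it (emulating tolerated terminal truncations);
#' missense variants are a Bernoulli mixture of the two components.
#' Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param variants Data.frame with `hgvs_pro`, `position`, `vclass`
#'   (amino-acid level; one score per distinct `hgvs_pro`).
#' @return The distinct amino-acid variant table with a `true_score` column.
#' @export
assign_true_scores <- function(config, variants) {
  stopifnot(inherits(config, "simulation_config"))
  if (nrow(variants) == 0L) stop("empty variant set")
  v <- variants[!duplicated(variants$hgvs_pro),
                c("hgvs_pro", "position", "vclass")]
  rownames(v) <- NULL
  n <- nrow(v)
  in_core <- v$position >= config$core_range[1] &
    v$position <= config$core_range[2]
  with_seed(config$seed + 1L, {
    tol <- stats::rnorm(n, config$tolerated_mean, config$tolerated_sd)
    dam <- stats::rnorm(n, config$damaging_mean, config$damaging_sd)
    is_dam <- stats::runif(n) < config$damaging_fraction
  })
  damaging <- (v$vclass == "nonsense" & in_core) |
    (v$vclass == "missense" & is_dam)
  v$true_score <- ifelse(damaging, dam, tol)
  v
}

#' Expected enrichment log-ratio under the selection model
#'
#' Selection is exponential growth over a fixed period with per-variant
#' fitness linear in the true score, so the expected pre-normalization log
#' enrichment of a variant with true score s is `gamma_T * (1 - s)`:
#' damaging variants (s near 0) enrich, wild-type-like variants (s near 1)
#' do not.
#'
#' @param s_true True score(s).
#' @param selection_strength gamma*T, the log-fitness span.
#' @return Expected log enrichment.
#' @examples
#' expected_logratio(c(1, 0.5, 0), 2) # 0, 1, 2
#' @export
expected_logratio <- function(s_true, selection_strength) {
  selection_strength * (1 - s_true)
}

#' Simulate a tiled count table
#'
#' Per biological replicate, clone abundances are log-normal around the mean
#' variant frequency; post-selection frequencies are proportional to
#' pre-selection frequency times `exp(gamma_T*(1-s) + bio jitter)`,
#' normalized by total population growth. Per technical replicate and
#' condition, counts are Poisson(depth * (true frequency + variant error
#' rate)); wild-type control counts are Poisson(depth * error rate) with the
#' same per-variant error rate, so wild-type subtraction is exactly the
#' right correction in expectation. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param codon_variants Codon-variant table from
#'   [enumerate_codon_variants()] (columns `position`, `wt_codon`,
#'   `alt_codon`, `hgvs_pro`).
#' @param truth Ground-truth table from [assign_true_scores()].
#' @return A long count table with columns `tile`, `bio_rep`, `tech_rep`,
#'   `condition` (preselect/select/wtctrl_pre/wtctrl_sel), codon identity,
#'   `hgvs_pro`, `count`, `depth`.
#' @export
simulate_counts <- function(config, codon_variants, truth) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$depth_per_tile <= 0) stop("depth_per_tile must be positive")
  cv <- codon_variants
  s <- truth$true_score[match(cv$hgvs_pro, truth$hgvs_pro)]
  if (anyNA(s)) stop("codon variant without a ground-truth score")
  tile_of <- function(pos) {
    idx <- findInterval(pos, config$tiles$start)
    if (any(idx < 1L) || any(pos > config$tiles$end[idx])) {
      stop("variant position outside all tiles")
    }
    config$tiles$tile[idx]
  }
  tiles <- tile_of(cv$position)
  nv <- nrow(cv)
  d <- config$depth_per_tile
  out <- vector("list",
                config$n_bio_replicates * config$n_tech_replicates * 4L)
  k <- 0L
  with_seed(config$seed + 2L, {
    err <- stats::rlnorm(
      nv,
      meanlog = log(config$error_rate_mean + 1e-300) -
        config$error_rate_dispersion^2 / 2,
      sdlog = config$error_rate_dispersion
    )
    if (config$error_rate_mean == 0) err[] <- 0
    for (b in seq_len(config$n_bio_replicates)) {
      abun <- stats::rlnorm(nv, 0, config$clone_sdlog)
      f_pre <- config$mean_variant_frequency * abun / mean(abun)
      jitter <- stats::rnorm(nv, 0, config$bio_noise_sd)
      growth <- exp(expected_logratio(s, config$selection_strength) + jitter)
      z <- 1 + sum(f_pre * (growth - 1))
      f_sel <- f_pre * growth / z
      for (t in seq_len(config$n_tech_replicates)) {
        lam <- list(
          preselect = f_pre + err, select = f_sel + err,
          wtctrl_pre = err, wtctrl_sel = err
        )
        for (cond in names(lam)) {
          k <- k + 1L
          out[[k]] <- data.frame(
            tile = tiles,
            bio_rep = sprintf("bio%d", b),
            tech_rep = sprintf("tech%d", t),
            condition = cond,
            position = cv$position,
            wt_codon = cv$wt_codon, alt_codon = cv$alt_codon,
            hgvs_pro = cv$hgvs_pro, vclass = cv$vclass,
            count = pmin(stats::rpois(nv, d * lam[[cond]]), d),
            depth = d,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full synthetic experiment
#'
#' Enumerates library codon variants from a CDS, assigns ground-truth
#' scores at the amino-acid level, and simulates the tiled count table.
#'
#' @param config A [simulation_config()]; `n_positions` must equal the CDS
#'   protein length.
#' @param cds A [coding_sequence()].
#' @param n_alt_codons Optional per-position library subset size (see
#'   [enumerate_codon_variants()]).
#' @return List with `counts`, `truth`, `codon_variants`, and the `config`.
#' @export
simulate_experiment <- function(config, cds, n_alt_codons = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(cds, "coding_sequence"))
  if (cds$protein_length != config$n_positions) {
    stop("config n_positions (", config$n_positions,
         ") does not match CDS protein length (", cds$protein_length, ")")
  }
  cv <- enumerate_codon_variants(cds, n_alt_codons = n_alt_codons,
                                 seed = config$seed + 3L)
  truth <- assign_true_scores(config, cv)
  counts <- simulate_counts(config, cv, truth)
  list(counts = counts, truth = truth, codon_variants = cv, config = config)
}
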