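# Shared fixtures: random coding sequences without internal stops, and a
# memoized scaled-down simulated experiment used by several test files
# (80 codons, 3 tiles at depth 2e5, 8 alternate codons per position,
# nonsense-sensitive core at residues 5-70; scoring with B = 200).

sense_codons <- function() {
  names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
}

make_test_cds <- function(n_codons, seed = 1L) {
  set.seed(seed)
  body <- sample(sense_codons(), n_codons - 1L, replace = TRUE)
  coding_sequence(paste0("ATG", paste(body, collapse = ""), "TAA"),
                  name = paste0("test", n_codons))
}

.fixture_cache <- new.env(parent = emptyenv())

# Default seeded simulation + scoring + merge, computed once per run.
default_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    cds <- make_test_cds(80, seed = 7)
    cfg <- simulation_config(seed = 11, n_positions = 80, n_tiles = 3,
                             depth_per_tile = 2e5, core_range = c(5, 70))
    sim <- simulate_experiment(cfg, cds, n_alt_codons = 8)
    rs <- score_replicates(sim$counts, B = 200, seed = 5)
    merged <- merge_map(rs)
    .fixture_cache$sim <- list(cds = cds, config = cfg, sim = sim,
                               rs = rs, merged = merged)
  }
  .fixture_cache$sim
}

# Truth joined onto the merged map.
default_map_vs_truth <- function() {
  fx <- default_sim()
  truth <- fx$sim$truth
  map <- fx$merged$map
  map$true_score <- truth$true_score[match(map$hgvs_pro, truth$hgvs_pro)]
  map
}
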