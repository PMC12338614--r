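toy_map <- function() {
  data.frame(
    hgvs_pro = c("p.A2V", "p.A2L", "p.K3R", "p.K3K", "p.W4*",
                 "p.S5T", "p.S5A", "p.S5R"),
    position = c(2L, 2L, 3L, 3L, 4L, 5L, 5L, 5L),
    alt_aa = c("V", "L", "R", "K", "*", "T", "A", "R"),
    vclass = c("missense", "missense", "missense", "synonymous",
               "nonsense", "missense", "missense", "missense"),
    score = c(0.1, 0.9, 1.3, 1.0, 0.0, 0.7, 0.8, 0.76),
    stringsAsFactors = FALSE
  )
}

test_that("moving-window medians honour window span and empty windows", {
  map <- toy_map()
  # constant scores give constant window medians
  const <- map
  const$score <- 1.0
  w <- moving_window_median(const, "missense", width = 3, protein_length = 6)
  expect_equal(w$median[1:4], rep(1.0, 4))
  # a window with no variants of the class is missing
  expect_true(is.na(w$median[6]))
  # hand-computed median over {0.1, 0.9, 1.3}
  w2 <- moving_window_median(map, "missense", width = 2, protein_length = 6)
  expect_equal(w2$median[2], 0.9)
  expect_equal(w2$n[2], 3L)
  # width 1 is the per-position median
  w1 <- moving_window_median(map, "missense", width = 1, protein_length = 6)
  expect_equal(w1$median[5], 0.76)
  expect_equal(w1$median[2], 0.5)
  expect_error(moving_window_median(map, "missense", width = 0), "width")
})

test_that("score classification is strict at the midpoint", {
  expect_equal(classify_score(c(0.49, 0.51, 0.5, NA)),
               c("damaging", "tolerated", "unclassified", NA))
})

test_that("region summaries cover selections and complements", {
  map <- toy_map()
  whole <- region_spec("all", 1, 6)
  s <- region_summary(map, whole, vclass = "missense")
  expect_equal(s$n, 6L)
  expect_equal(s$fraction_damaging, 1 / 6)
  # single position, hand-checked median
  s5 <- region_summary(map, region_spec("pos5", 5, 5))
  expect_equal(s5$median, 0.76)
  # empty selection: n = 0, no statistics
  s0 <- region_summary(map, region_spec("empty", 6, 6))
  expect_equal(s0$n, 0L)
  expect_true(is.na(s0$median))
  # complement of an empty motif is the region itself
  motif <- region_spec("motif", 3, 3, positions = integer(0))
  comp <- region_minus(whole, motif)
  expect_setequal(region_positions(comp), 1:6)
  # kinase-domain-minus-motif style complement
  comp2 <- region_minus(whole, region_spec("m", 2, 3))
  expect_setequal(region_positions(comp2), c(1, 4, 5, 6))
})

test_that("region comparisons use the rank-sum test with direction", {
  set.seed(4)
  map <- data.frame(
    hgvs_pro = sprintf("p.A%dV", 2:41), position = 2:41,
    alt_aa = "V", vclass = "missense",
    score = c(runif(20, 0, 0.2), runif(20, 0.8, 1.0))
  )
  low <- region_spec("low", 2, 21)
  high <- region_spec("high", 22, 41)
  # disjoint supports are overwhelmingly different
  expect_lt(compare_regions(map, low, high)$p.value, 1e-6)
  expect_lt(compare_regions(map, low, high,
                            alternative = "less")$p.value, 1e-6)
  # the opposite tail is non-significant, direction flips with the swap
  expect_gt(compare_regions(map, low, high,
                            alternative = "greater")$p.value, 0.99)
  expect_lt(compare_regions(map, high, low,
                            alternative = "greater")$p.value, 1e-6)
  # identical samples: two-sided p near 1
  expect_gt(compare_regions(map, low, low)$p.value, 0.99)
  expect_error(compare_regions(map, region_spec("none", 50, 60), low),
               "empty")
})

test_that("coverage accounting matches hand enumeration on a toy CDS", {
  cds <- make_test_cds(10, seed = 2)
  poss <- enumerate_possible_substitutions(cds)
  snv <- snv_reachable_set(cds)
  scored <- poss[c(1, 5, 20, 40, 100), ]
  scored$vclass <- "missense"
  scored$score <- 1
  scored$high_confidence <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  cov <- coverage_report(scored, cds)
  get <- function(q) cov$count[cov$quantity == q]
  expect_equal(get("possible_substitutions"), 19L * 9L)
  expect_equal(get("scored_missense"), 5L)
  expect_equal(get("scored_of_possible"), 5L)
  expect_equal(get("snv_reachable_missense"), nrow(snv$missense))
  expect_equal(get("scored_of_snv_reachable"),
               sum(paste(scored$position, scored$alt_aa) %in%
                     paste(snv$missense$position, snv$missense$alt_aa)))
  expect_equal(get("high_confidence_missense"), 3L)
  # duplicates are rejected, record order is irrelevant
  expect_error(coverage_report(rbind(scored, scored[1, ]), cds), "duplicate")
  cov2 <- coverage_report(scored[5:1, ], cds)
  expect_equal(cov2$count, cov$count)
  # empty map: zero coverage, denominators unchanged
  cov0 <- coverage_report(scored[0, ], cds)
  expect_equal(cov0$count[cov0$quantity == "scored_missense"], 0L)
  expect_equal(cov0$count[cov0$quantity == "possible_substitutions"],
               19L * 9L)
})

test_that("region summaries over a partition recombine to the global view", {
  map <- default_map_vs_truth()
  parts <- list(region_spec("a", 1, 30), region_spec("b", 31, 55),
                region_spec("c", 56, 80))
  sums <- do.call(rbind, lapply(parts, function(r)
    region_summary(map, r, vclass = "missense")))
  glob <- region_summary(map, region_spec("all", 1, 80),
                         vclass = "missense")
  expect_equal(sum(sums$n), glob$n)
  expect_gte(glob$median, min(sums$median))
  expect_lte(glob$median, max(sums$median))
})

test_that("bundled STK11 region presets load with published coordinates", {
  r <- stk11_regions()
  expect_equal(r$kinase_domain$start, 49L)
  expect_equal(r$kinase_domain$end, 309L)
  expect_equal(r$gxgxxg$start, 56L)
  expect_equal(r$dfg$start, 194L)
  expect_equal(region_positions(r$gxgxxg_glycines), c(56L, 58L, 61L))
  expect_equal(r$nonsense_core$start, 22L)
  expect_equal(r$nonsense_core$end, 311L)
})
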