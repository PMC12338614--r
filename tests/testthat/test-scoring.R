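test_that("frequencies are counts over effective depth", {
  expect_equal(variant_frequency(0, 1e6), 0)
  expect_equal(variant_frequency(200, 1e6), 2e-4)
  expect_equal(variant_frequency(1e6, 1e6), 1)
  expect_error(variant_frequency(1, 0), "positive")
  expect_error(variant_frequency(-1, 10), "non-negative")
  expect_error(variant_frequency(11, 10), "exceeds")
})

test_that("wild-type correction and flooring of the log-ratio", {
  r <- error_corrected_logratio(1e-4, 1e-3, 0, 0, depth_floor = 1e6)
  expect_equal(r$logratio, log(10))
  expect_false(r$floored)
  # symmetric correction cancels exactly
  r2 <- error_corrected_logratio(1.2e-4, 1.2e-4, 2e-5, 2e-5,
                                 depth_floor = 1e6)
  expect_equal(r2$logratio, 0)
  # post-selection frequency at or below the control floors at half a read
  r3 <- error_corrected_logratio(1e-4, 1e-5, 0, 2e-5, depth_floor = 1e6)
  expect_true(r3$floored)
  expect_equal(r3$logratio, log((0.5 / 1e6) / 1e-4))
})

test_that("rescaling anchors synonymous at 1 and nonsense at 0", {
  syn <- c(-0.1, 0, 0.1)
  non <- c(1.9, 2.0, 2.3)
  expect_equal(as.numeric(rescale_scores(2.0, syn, non)), 0)
  expect_equal(as.numeric(rescale_scores(0, syn, non)), 1)
  expect_equal(as.numeric(rescale_scores(1.0, syn, non)), 0.5)
  # medians map exactly, not approximately
  expect_equal(median(as.numeric(rescale_scores(syn, syn, non))), 1)
  expect_equal(median(as.numeric(rescale_scores(non, syn, non))), 0)
  expect_error(rescale_scores(1, c(1, 1), c(1, 1)), "degenerate")
})

test_that("rescaled scores are invariant to log base and affine shifts", {
  set.seed(8)
  lr <- rnorm(50, 1, 0.8)
  syn <- rnorm(21, 0, 0.1)
  non <- rnorm(21, 2, 0.1)
  base <- as.numeric(rescale_scores(lr, syn, non))
  shifted <- as.numeric(rescale_scores(lr + 3.7, syn + 3.7, non + 3.7))
  expect_equal(shifted, base)
  log10_scale <- as.numeric(rescale_scores(lr / log(10), syn / log(10),
                                           non / log(10)))
  expect_equal(log10_scale, base)
  scaled <- as.numeric(rescale_scores(lr * -2, syn * -2, non * -2))
  expect_equal(scaled, base)
})

test_that("frequencies, log-ratios and scores are depth-scale free", {
  m <- c(40, 400, 4000)
  d <- 1e5
  k <- 10
  expect_equal(variant_frequency(m, d), variant_frequency(m * k, d * k))
  lr1 <- error_corrected_logratio(m / d, (3 * m) / d, 1 / d, 1 / d, d)
  lr2 <- error_corrected_logratio(m / d, (3 * m) / d, 1 / d, 1 / d, d * k)
  expect_equal(lr1$logratio, lr2$logratio)
})

test_that("bootstrap se scales as 1/sqrt(counts) and matches delta method", {
  span <- 2 # syn median 0, non median -2
  se_small <- bootstrap_se(200, 1e6, 200, 1e6, 2, 1e6, 2, 1e6,
                           syn_median = 0, non_median = -2,
                           B = 1000, seed = 2)
  se_big <- bootstrap_se(20000, 1e8, 20000, 1e8, 200, 1e8, 200, 1e8,
                         syn_median = 0, non_median = -2,
                         B = 1000, seed = 2)
  expect_equal(se_small / se_big, 10, tolerance = 0.2)
  # high-count agreement with the delta-method sd within 25%
  delta <- delta_method_score_sd(20000, 20000, 0, -2)
  expect_equal(se_big, delta, tolerance = 0.25)
  # enormous counts drive the se to zero
  se_huge <- bootstrap_se(1e6, 1e9, 1e6, 1e9, 0, 1e9, 0, 1e9,
                          syn_median = 0, non_median = -2,
                          B = 200, seed = 2)
  expect_lt(se_huge, 0.01)
  expect_error(bootstrap_se(1, 10, 1, 10, 0, 10, 0, 10, 0, -2, B = 0),
               "at least 100")
  # determinism
  expect_identical(
    bootstrap_se(200, 1e6, 500, 1e6, 2, 1e6, 2, 1e6, 0, -2, 200, seed = 9),
    bootstrap_se(200, 1e6, 500, 1e6, 2, 1e6, 2, 1e6, 0, -2, 200, seed = 9)
  )
})

test_that("variance regularization pulls outliers toward the depth trend", {
  set.seed(6)
  m <- round(10^runif(200, 2, 4))
  true_var <- (1 / m + 1 / m) / 4
  var_boot <- true_var * exp(rnorm(200, 0, 0.4))
  var_boot[1] <- true_var[1] * 50 # one wild outlier
  reg <- regularize_variance(var_boot, m, m)
  expect_lt(reg[1], var_boot[1])
  expect_gt(reg[1], true_var[1])
  # typical values move only mildly
  expect_equal(median(reg / var_boot), 1, tolerance = 0.25)
})

test_that("well-measured filter applies the frequency and excess rules", {
  # frequency boundary: below 2e-5 flagged, exactly 2e-5 kept
  wm <- filter_well_measured(c(1e-5, 2e-5, 1e-4),
                             m_pre = c(10, 20, 100), d_pre = rep(1e6, 3),
                             m_wt_pre = c(0, 0, 0), d_wt_pre = rep(1e6, 3))
  expect_equal(wm$low_frequency, c(TRUE, FALSE, FALSE))
  # clear excess over the control is distinguishable
  wm2 <- filter_well_measured(5e-4, 500, 1e6, 2, 1e6)
  expect_false(wm2$wt_indistinguishable)
  # equal rates are not
  wm3 <- filter_well_measured(0, 50, 1e6, 50, 1e6)
  expect_true(wm3$wt_indistinguishable)
})

test_that("technical-replicate divergence uses a strict 3x Poisson rule", {
  # identical replicates always pass
  fd <- filter_replicate_divergence(0.8, 0.8, 0.05, 0.05)
  expect_false(fd$replicate_divergent)
  # exactly 3x the Poisson expectation is kept (strict inequality)
  gap <- 3 * sqrt(0.05^2 + 0.05^2)
  fd3 <- filter_replicate_divergence(0.5, 0.5 + gap, 0.05, 0.05)
  expect_false(fd3$replicate_divergent)
  fd10 <- filter_replicate_divergence(0.5, 0.5 + 10 * sqrt(2) * 0.05,
                                      0.05, 0.05)
  expect_true(fd10$replicate_divergent)
  # a missing replicate passes unpaired
  fdna <- filter_replicate_divergence(0.5, NA, 0.05, NA)
  expect_false(fdna$replicate_divergent)
  expect_true(fdna$unpaired)
})

test_that("per-replicate scoring anchors class medians exactly", {
  # single tile, zero sequencing error: well-measured synonymous median is
  # exactly 1 and nonsense exactly 0 by construction of the rescale
  cds <- make_test_cds(40, seed = 17)
  cfg <- simulation_config(seed = 51, n_positions = 40, n_tiles = 1,
                           depth_per_tile = 5e5, n_bio_replicates = 1,
                           error_rate_mean = 0, core_range = c(2, 40))
  sim <- simulate_experiment(cfg, cds, n_alt_codons = 12)
  rs <- score_replicates(sim$counts, B = 200, seed = 5)
  ok <- rs$well_measured
  expect_equal(median(rs$score[ok & rs$vclass == "synonymous"]), 1)
  expect_equal(median(rs$score[ok & rs$vclass == "nonsense"]), 0)
  # flags partition the record set: not well-measured iff some QC flag
  expect_equal(!rs$well_measured,
               rs$flag_low_frequency | rs$flag_wt_indistinguishable |
                 rs$flag_replicate_divergent)
  expect_true(all(rs$se[ok] > 0))
})

test_that("scoring output is deterministic given the seed", {
  fx <- default_sim()
  rs2 <- score_replicates(fx$sim$counts, B = 200, seed = 5)
  expect_identical(fx$rs, rs2)
})
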