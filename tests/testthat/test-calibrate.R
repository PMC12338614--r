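test_that("reference sets are built from classification points", {
  tab <- data.frame(
    hgvs_pro = c("p.K78I", "p.L286*", "p.I322L", "p.S404F", "p.A5V", "p.Q7R"),
    pathogenic_points = c(6, 8, 0, 0, 5, 0),
    benign_points = c(0, 0, 2, 4, 0, 1)
  )
  ref <- build_reference(tab)
  expect_equal(ref$label[ref$hgvs_pro == "p.K78I"], "pathogenic")
  expect_equal(ref$label[ref$hgvs_pro == "p.I322L"], "benign")
  # below both thresholds: excluded
  expect_false("p.A5V" %in% ref$hgvs_pro)
  expect_false("p.Q7R" %in% ref$hgvs_pro)
  tab$benign_points[1] <- 2
  expect_error(build_reference(tab), "both")
  # pre-resolved labels pass through
  ref2 <- build_reference(data.frame(hgvs_pro = "p.K78I",
                                     label = "pathogenic"))
  expect_equal(ref2$label, "pathogenic")
  expect_error(build_reference(data.frame(hgvs_pro = "x", label = "vus")),
               "unknown")
})

test_that("kernel densities are proper and near the truth at moderate n", {
  set.seed(12)
  x <- rnorm(500)
  model <- fit_calibration(x, x + 10)
  # density of N(0,1) at 0 is 0.3989
  expect_gt(model$f_path(0), 0.3)
  expect_lt(model$f_path(0), 0.5)
  # integrates to 1 over the support
  grid <- seq(model$support[1], model$support[2], length.out = 4001)
  integral <- sum(model$f_path(grid)) * diff(grid[1:2])
  expect_equal(integral, 1, tolerance = 1e-3)
  # degenerate class: identical points fall back without crashing
  k <- fit_kde(c(1, 1))
  expect_true(k$bw > 0)
  expect_true(k$bw_method %in% c("nrd0", "constant"))
  expect_error(fit_kde(1), "at least 2")
})

test_that("LLR is zero for identical references and antisymmetric on swap", {
  set.seed(3)
  x <- rnorm(40, 0.5, 0.3)
  m_same <- fit_calibration(x, x)
  at <- seq(-0.2, 1.2, by = 0.1)
  expect_equal(as.numeric(llr(at, m_same)), rep(0, length(at)))

  y <- rnorm(60, 0.9, 0.2)
  m_ab <- fit_calibration(x, y)
  m_ba <- fit_calibration(y, x)
  expect_equal(as.numeric(llr(at, m_ab)), -as.numeric(llr(at, m_ba)))
})

test_that("separated references give strong evidence, empty regions none", {
  set.seed(5)
  path <- rnorm(50, 0, 0.05)
  ben <- rnorm(50, 1, 0.05)
  m <- fit_calibration(path, ben)
  expect_gt(as.numeric(llr(0, m)), 1.3)
  expect_lt(as.numeric(llr(1, m)), -1.3)
  # midway between the clusters no reference mass remains and the
  # regularizers cancel (equal class sizes)
  expect_lt(abs(as.numeric(llr(0.5, m))), 0.05)
  # out-of-support scores clamp to the nearest endpoint, flagged
  v <- llr(c(-50, 0.5), m)
  expect_equal(attr(v, "clamped"), c(TRUE, FALSE))
  expect_equal(as.numeric(v)[1],
               as.numeric(llr(m$support[1], m)))
})

test_that("ACMG categories follow the published cutpoints", {
  expect_equal(acmg_category(c(2.6, 0.5, -1.5)),
               c("very_strong_path", "supporting_path", "strong_benign"))
  # boundary conventions: 'above 2.5' is very strong, 2.5 itself strong
  expect_equal(acmg_category(2.5), "strong_path")
  expect_equal(acmg_category(1.3), "moderate_path")
  expect_equal(acmg_category(0.64), "supporting_path")
  expect_equal(acmg_category(0.1), "none")
  expect_equal(acmg_category(-0.32), "supporting_benign")
  expect_equal(acmg_category(-1.32), "supporting_benign")
  expect_equal(acmg_category(-1.33), "strong_benign")
})

test_that("Tavtigian thresholds halve exponentially from the very-strong odds", {
  th <- tavtigian_thresholds(350)
  expect_equal(unname(th), log10(350) / c(1, 2, 4, 8))
  expect_equal(round(unname(th[4]), 3), 0.318)
  expect_equal(round(unname(th[1]), 3), 2.544)
  # two significant figures reproduce the conventional printed cutpoints
  expect_equal(unname(signif(th, 2)), c(2.5, 1.3, 0.64, 0.32))
  expect_equal(unname(tavtigian_thresholds(100)[2]), 1.0)
  expect_error(tavtigian_thresholds(1), "exceed 1")
})

test_that("balanced precision-recall handles separation, balance and noise", {
  # perfect separation: every threshold between the classes has BP = 1
  sc <- c(rnorm(20, 0, 0.05), rnorm(30, 1, 0.05))
  lab <- rep(c("pathogenic", "benign"), c(20, 30))
  res <- balanced_prc(sc, lab)
  expect_equal(res$aubprc, 1)
  expect_equal(res$r90bp, 1)
  # recall is monotone along the sweep
  expect_true(all(diff(res$curve$recall) >= 0))
  expect_true(all(res$curve$balanced_precision >= 0 &
                    res$curve$balanced_precision <= 1))

  # with equal class sizes balanced precision equals ordinary precision
  set.seed(9)
  sc2 <- runif(60)
  lab2 <- rep(c("pathogenic", "benign"), each = 30)
  res2 <- balanced_prc(sc2, lab2)
  for (i in seq_len(nrow(res2$curve))) {
    t <- res2$curve$threshold[i]
    tp <- sum(sc2 <= t & lab2 == "pathogenic")
    fp <- sum(sc2 <= t & lab2 == "benign")
    if (tp + fp > 0) {
      expect_equal(res2$curve$balanced_precision[i], tp / (tp + fp))
    }
  }

  # uninformative scores give an area near one half
  set.seed(10)
  sc3 <- runif(2000)
  lab3 <- sample(rep(c("pathogenic", "benign"), each = 1000))
  res3 <- balanced_prc(sc3, lab3)
  expect_gt(res3$aubprc, 0.45)
  expect_lt(res3$aubprc, 0.55)

  expect_error(balanced_prc(1:5, rep("pathogenic", 5)), "at least 2")
})

test_that("calibration round-trips on the synthetic map", {
  map <- default_map_vs_truth()
  mis <- map[map$vclass == "missense" & map$high_confidence, ]
  ref <- data.frame(hgvs_pro = mis$hgvs_pro,
                    label = ifelse(mis$true_score < 0.5,
                                   "pathogenic", "benign"))
  # hold out some variants so calibrated scores exist beyond the reference
  ref <- ref[seq(1, nrow(ref), by = 2), ]
  cal <- calibrate_map(map, ref, high_confidence_only = TRUE)
  expect_gt(cal$evaluation$aubprc, 0.95)
  joined <- merge(cal$scores, map[c("hgvs_pro", "true_score")],
                  by = "hgvs_pro")
  dam <- joined$true_score < 0.5 & joined$score < 0.5
  tol <- joined$true_score >= 0.5 & joined$score > 0.5
  expect_gt(median(joined$llr[dam]), 0)
  expect_lt(median(joined$llr[tol]), 0)
})
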