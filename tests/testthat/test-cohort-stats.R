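test_that("AUROC pair counting matches enumeration and its identities", {
  expect_equal(auroc_mann_whitney(c(1, 2, 3), c(4, 5, 6)), 1)
  expect_equal(auroc_mann_whitney(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(auroc_mann_whitney(c(1, 3), c(2, 4)), 0.75)
  expect_error(auroc_mann_whitney(numeric(), 1:3), "nonempty")

  set.seed(14)
  for (rep in 1:10) {
    x0 <- rnorm(20); x1 <- rnorm(25, 0.5)
    a01 <- auroc_mann_whitney(x0, x1)
    # complement identity, exactly
    expect_identical(a01 + auroc_mann_whitney(x1, x0), 1)
    # agreement with the rank-sum statistic: W = #(x0 > x1) pairs
    w <- mann_whitney_test(x0, x1)$statistic
    expect_equal(a01, 1 - w / (20 * 25), tolerance = 1e-12)
    # direct pair enumeration oracle
    expect_equal(a01, mean(outer(x0, x1, "<")) + 0.5 * mean(outer(x0, x1, "==")))
  }
})

test_that("simulated AUROC converges to the binormal closed form", {
  set.seed(15)
  x0 <- rnorm(50000, 276.5, 43.2)
  x1 <- rnorm(50000, 360.8, 44.5)
  expected <- pnorm((360.8 - 276.5) / sqrt(43.2^2 + 44.5^2))
  expect_equal(auroc_mann_whitney(x0, x1), expected, tolerance = 0.005)
})

test_that("signed-rank test handles exact, approximate and degenerate cases", {
  expect_equal(wilcoxon_signed_rank(1:5, 1:5)$p_value, 1)

  # n = 6 all-positive differences: exact two-sided p = 2/2^6
  res <- wilcoxon_signed_rank(c(2, 4, 6, 8, 10, 12), c(1, 2, 3, 4, 5, 6))
  expect_equal(res$p_value, 2 / 64)
  expect_equal(res$statistic, 21)

  # large paired shift is overwhelmingly significant
  set.seed(16)
  a <- rnorm(476, 400, 50)
  expect_lt(wilcoxon_signed_rank(a + rnorm(476, 92.2, 34.9), a)$p_value, 1e-10)
})

test_that("rank-sum test matches exact enumeration at small n", {
  x0 <- c(1.2, 3.4, 2.2); x1 <- c(4.1, 5.3, 2.9)
  expect_equal(mann_whitney_test(x0, x1)$p_value, mw_exact_p(x0, x1))
  # symmetric inputs are not significant
  expect_gt(mann_whitney_test(c(1, 2, 3), c(1.1, 2.1, 2.9))$p_value, 0.5)
})

test_that("Holm adjustment reproduces the hand-applied step-down rule", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.3), 0.3)
  expect_equal(holm_adjust(c(0.5, 0.6, 0.9)), c(1, 1, 1))
  expect_error(holm_adjust(c(0.2, 1.2)), "\\[0, 1\\]")

  set.seed(17)
  p <- runif(20)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))     # monotone in raw order
})

test_that("ICC(2,1) matches hand ANOVA and recovers variance components", {
  # duplicated identical ratings agree perfectly
  m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(icc_2_1(m)$icc, 1)

  # hand-computed ANOVA: MSR = 8, MSC = 1.5, MSE = 0 -> ICC = 8/9
  res <- icc_2_1(cbind(c(1, 3, 5), c(2, 4, 6)))
  expect_equal(res$icc, 8 / 9)
  expect_equal(res$msr, 8)
  expect_equal(res$msc, 1.5)
  expect_equal(res$mse, 0, tolerance = 1e-12)

  expect_error(icc_2_1(matrix(5, 4, 2)), "variance")
  expect_error(icc_2_1(cbind(1:2, 1:2)), "3 targets")

  # known variance components: ICC -> sb^2 / (sb^2 + se^2)
  set.seed(18)
  sb <- 50; se <- 10
  target_icc <- sb^2 / (sb^2 + se^2)
  est <- replicate(200, {
    truth <- rnorm(60, 300, sb)
    icc_2_1(cbind(truth + rnorm(60, 0, se), truth + rnorm(60, 0, se)))$icc
  })
  expect_lt(abs(mean(est) - target_icc), 3 * sd(est) / sqrt(200))
  # the F-based interval covers the estimate
  truth2 <- rnorm(60, 300, sb)
  one <- icc_2_1(cbind(truth2 + rnorm(60, 0, se), truth2 + rnorm(60, 0, se)))
  expect_true(one$ci_low <= one$icc && one$icc <= one$ci_high)
})

test_that("Pearson correlation handles the limiting and hand-computed cases", {
  x <- c(1, 2.5, 3, 4.2, 5)
  expect_equal(pearson_r(x, x)$estimate, 1)
  expect_equal(pearson_r(x, -x)$estimate, -1)
  y <- c(2.0, 2.2, 3.5, 3.9, 5.1)
  expect_equal(pearson_r(x, y)$estimate, cov(x, y) / (sd(x) * sd(y)))
})

test_that("stage-stratified VSS comparisons respect binning and eligibility", {
  # half-open bins anchored at zero: value 150 with width 75 is bin 2
  expect_equal(floor(150 / 75), 2)

  set.seed(19)
  n <- 600
  stage <- sample(1:3, n, replace = TRUE)
  min_nerv <- runif(n, 150, 450)
  tbl <- tibble::tibble(
    eye_id = sprintf("e%03d", 1:n),
    min_nerv = min_nerv, min_terv = NA_real_,
    stage = stage,
    vss = pmin(pmax(6 + 1.2 * stage - 0.012 * min_nerv + rnorm(n, 0, 0.8), 1), 9))
  res <- kruskal_wallis_by_bin(tbl, bin_width = 75)
  expect_true(all(res$side == "nasal"))
  expect_true(all(res$bin_lo == res$bin * 75))
  eligible <- res[res$eligible, ]
  expect_gt(nrow(eligible), 0)
  expect_true(all(eligible$adjusted_p >= eligible$p_value - 1e-15))

  # identical VSS across stages within a bin is non-significant
  tbl2 <- tibble::tibble(eye_id = sprintf("f%02d", 1:30),
                         min_nerv = rep(100, 30), min_terv = NA_real_,
                         stage = rep(1:3, each = 10), vss = rep(5, 30))
  res2 <- kruskal_wallis_by_bin(tbl2, bin_width = 75)
  expect_equal(res2$p_value[res2$eligible], 1)

  # stage-separated VSS in a single dense cohort: strong signal everywhere
  spec <- cohort_spec(n_eyes = 3000)
  sim <- simulate_cohort(spec, render = FALSE, seed = 20)
  tbl3 <- tibble::tibble(eye_id = sim$eyes$eye_id,
                         min_nerv = sim$eyes$true_min_nerv,
                         min_terv = sim$eyes$true_min_terv,
                         stage = sim$eyes$stage, vss = sim$eyes$vss)
  res3 <- kruskal_wallis_by_bin(tbl3, bin_width = 75)
  expect_true(all(res3$adjusted_p[res3$eligible] < 0.001))

  # nothing eligible -> warning
  expect_warning(kruskal_wallis_by_bin(tbl2[1:4, ], bin_width = 75), "no bin")
})

test_that("zone and asymmetry summaries report the cohort structure", {
  set.seed(23)
  n <- 300
  zone <- sample(c("I", "II"), n, TRUE)
  min_nerv <- ifelse(zone == "I", rnorm(n, 276.5, 43.2), rnorm(n, 360.8, 44.5))
  min_terv <- min_nerv + pmax(rnorm(n, 92.2, 34.9), 1)
  tbl <- tibble::tibble(
    eye_id = sprintf("z%03d", 1:n), zone = zone,
    min_nerv = min_nerv, min_terv = min_terv,
    mean_nerv = min_nerv + 25, mean_terv = min_terv + 25,
    abs_diff = min_terv - min_nerv,
    prop_diff = (min_terv - min_nerv) / min_terv)
  zs <- zone_summary(tbl)
  row <- zs[zs$metric == "min_nerv" & zs$zone == "I", ]
  expect_equal(row$mean, 276.5, tolerance = 3 * 43.2 / sqrt(sum(zone == "I")) + 1)
  expect_true(all(zs$auroc[zs$metric == "min_nerv"] > 0.8))
  expect_true(all(zs$p_value < 1e-6))

  asym <- asymmetry_summary(tbl)
  expect_equal(asym$n, n)
  expect_equal(asym$frac_nerv_lt_terv, 1)
  expect_equal(asym$mean_abs_diff, mean(tbl$abs_diff))
  expect_lt(asym$wilcoxon_p, 1e-10)

  # degenerate single-zone table: AUROC undefined and flagged
  zs1 <- zone_summary(tbl[tbl$zone == "I", ])
  expect_true(all(zs1$degenerate))
  expect_true(all(is.na(zs1$auroc)))
  expect_error(zone_summary(tbl[0, ]), "empty")
})
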