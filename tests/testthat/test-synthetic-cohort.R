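test_that("cohort spec validation names the offending field", {
  expect_error(cohort_spec(n_eyes = 0), "n_eyes")
  expect_error(cohort_spec(zone_mix = c(I = 0.6, II = 0.6)), "zone_mix")
  expect_error(cohort_spec(stage_mix = c(`1` = -0.1, `2` = 0.6, `3` = 0.5)),
               "stage_mix")
  expect_error(cohort_spec(notch_prob = 1.5), "notch_prob")
  expect_error(cohort_spec(paired_diff_params = c(mean = 90, sd = -1)),
               "paired_diff_params")
  expect_s3_class(cohort_spec(), "erv_cohort_spec")
})

test_that("zone presets carry the published minimum NERV/TERV parameters", {
  expect_equal(unname(ZONE_PRESETS$I$nerv), c(276.5, 43.2))
  expect_equal(unname(ZONE_PRESETS$II$nerv), c(360.8, 44.5))
  expect_equal(unname(ZONE_PRESETS$I$terv), c(345.0, 53.4))
  expect_equal(unname(ZONE_PRESETS$II$terv), c(452.6, 52.5))
})

test_that("degenerate-sd specs pin every latent minimum at the preset mean", {
  spec <- cohort_spec(
    n_eyes = 5, zone_mix = c(I = 1, II = 0), notch_prob = 0,
    nerv_params = list(I = c(mean = 276.5, sd = 0), II = c(mean = 360.8, sd = 0)),
    pairing_mode = "independent-by-zone",
    terv_params = list(I = c(mean = 345, sd = 0), II = c(mean = 452.6, sd = 0)))
  sim <- simulate_cohort(spec, render = FALSE, seed = 1)
  expect_equal(sim$eyes$true_min_nerv, rep(276.5, 5))
  expect_equal(sim$eyes$true_min_terv, rep(345, 5))
})

test_that("arc minima equal the drawn latent minima and notches behave", {
  set.seed(33)
  spec <- cohort_spec(n_eyes = 1, notch_prob = 1, deep_temporal_notch_prob = 0)
  grid <- function(arc) arc_radius(arc, seq(arc$center - arc$half_span,
                                            arc$center + arc$half_span,
                                            length.out = 4096))
  for (i in 1:20) {
    eye <- sample_eye(spec, "e")
    expect_equal(min(grid(eye$nasal_arc)), eye$true_min_nerv, tolerance = 0.5)
    expect_equal(min(grid(eye$temporal_arc)), eye$true_min_terv, tolerance = 0.5)
  }
  # notch-free arcs are unimodal smooth: single interior minimum
  spec0 <- cohort_spec(n_eyes = 1, notch_prob = 0)
  for (i in 1:10) {
    eye <- sample_eye(spec0, "e")
    g <- grid(eye$nasal_arc)
    d <- diff(g)
    expect_lte(sum(diff(sign(d[d != 0])) != 0), 1)   # at most one sign change
  }
})

test_that("latent sample means match generator parameters (law of large numbers)", {
  spec <- cohort_spec(n_eyes = 10000, zone_mix = c(I = 0, II = 1),
                      pairing_mode = "independent-by-zone", notch_prob = 0)
  sim <- simulate_cohort(spec, render = FALSE, seed = 7)
  se <- 44.5 / sqrt(10000)
  expect_lt(abs(mean(sim$eyes$true_min_nerv) - 360.8), 3 * se)
  # VSS trends: nondecreasing in stage, decreasing in NERV
  vss_by_stage <- tapply(sim$eyes$vss, sim$eyes$stage, mean)
  expect_true(all(diff(vss_by_stage) > 0))
  expect_lt(cor(sim$eyes$vss, sim$eyes$true_min_nerv), 0)
  expect_true(all(sim$eyes$vss >= 1 & sim$eyes$vss <= 9))
})

test_that("rendered clicks lie on the arc and shuffling is recoverable", {
  set.seed(2)
  spec <- cohort_spec(n_eyes = 1, notch_prob = 0)
  eye <- sample_eye(spec, "e")

  ann <- render_annotation(eye, "temporal", n_points = 50, click_jitter_sd = 0)
  r <- sqrt(rowSums(sweep(ann$points, 2, eye$disc_center)^2))
  th <- seq(eye$temporal_arc$center - eye$temporal_arc$half_span,
            eye$temporal_arc$center + eye$temporal_arc$half_span,
            length.out = 2048)
  expect_true(all(r >= min(arc_radius(eye$temporal_arc, th)) - 0.5))
  expect_true(all(r <= max(arc_radius(eye$temporal_arc, th)) + 0.5))

  # greedy reordering of the shuffled clicks recovers the angular sort
  ord <- order_points_greedy(ann$points)
  ang <- atan2(ord$points[, 2] - eye$disc_center[["y"]],
               ord$points[, 1] - eye$disc_center[["x"]])
  expect_true(all(diff(ang) > 0) || all(diff(ang) < 0))

  expect_error(render_annotation(eye, "nasal", n_points = 1), "n_points")
})

test_that("rendering on a circular arc preserves the radius under zero jitter", {
  set.seed(4)
  spec <- cohort_spec(
    n_eyes = 1, notch_prob = 0, pairing_mode = "independent-by-zone",
    nerv_params = list(I = c(mean = 300, sd = 0), II = c(mean = 300, sd = 0)))
  eye <- sample_eye(spec, "e")
  eye$nasal_arc$amp <- 0                      # degenerate modulation: a circle
  eye$nasal_arc$shift <- 300 - eye$nasal_arc$smooth_min
  ann <- render_annotation(eye, "nasal", n_points = 50, click_jitter_sd = 0)
  r <- sqrt(rowSums(sweep(ann$points, 2, eye$disc_center)^2))
  expect_true(all(abs(r - 300) < 0.5))
})

test_that("grader duplication is exact at zero noise and calibrated otherwise", {
  set.seed(6)
  spec <- cohort_spec(n_eyes = 1, notch_prob = 0)
  eye <- sample_eye(spec, "e")
  ann <- render_annotation(eye, "nasal")
  dup0 <- duplicate_with_grader_noise(ann, grader_noise_sd = 0)
  expect_equal(dup0$points, ann$points, tolerance = 1e-12)

  # closed-form variance-ratio calibration
  expect_equal(repro_noise_sd(62, 0.985), 62 * sqrt(0.015 / 0.985))
  # equal grader and between-image noise gives ICC ~ 0.5
  expect_equal(62^2 / (62^2 + repro_noise_sd(62, 0.5)^2), 0.5)

  # a radial offset moves every point along its disc ray
  set.seed(8)
  dup <- duplicate_with_grader_noise(ann, grader_noise_sd = 10)
  d0 <- sqrt(rowSums(sweep(ann$points, 2, ann$disc$centroid)^2))
  d1 <- sqrt(rowSums(sweep(dup$points, 2, ann$disc$centroid)^2))
  expect_equal(sd(d1 - d0), 0, tolerance = 1e-9)   # common offset per image
})

test_that("deep temporal notch eyes invert the nasal-temporal asymmetry", {
  set.seed(9)
  spec <- cohort_spec(n_eyes = 1, notch_prob = 1, deep_temporal_notch_prob = 1)
  found <- FALSE
  for (i in 1:40) {
    eye <- sample_eye(spec, "e")
    if (!is.null(eye$notch) && identical(eye$notch$type, "deep")) {
      found <- TRUE
      a_n <- render_annotation(eye, "nasal", click_jitter_sd = 0)
      a_t <- render_annotation(eye, "temporal", click_jitter_sd = 0)
      r_n <- min(sqrt(rowSums(sweep(a_n$points, 2, eye$disc_center)^2)))
      r_t <- min(sqrt(rowSums(sweep(a_t$points, 2, eye$disc_center)^2)))
      expect_lt(r_t, r_n)
      # the notch is flagged on the measured temporal profile
      m <- measure_annotation(a_t)
      expect_gte(sum(m$notches$type == "notch"), 1L)
      break
    }
  }
  expect_true(found)
})

test_that("cohort generation is reproducible from its seed", {
  spec <- cohort_spec(n_eyes = 8)
  a <- simulate_cohort(spec, seed = 123)
  b <- simulate_cohort(spec, seed = 123)
  expect_identical(a$eyes, b$eyes)
  expect_identical(lapply(a$annotations, `[[`, "points"),
                   lapply(b$annotations, `[[`, "points"))
})

test_that("the 476-eye asymmetry fixture is constructed exactly", {
  fx <- build_asymmetry_fixture(seed = 51)
  expect_equal(nrow(fx$eyes), 476L)
  expect_equal(sum(fx$eyes$inverted), 8L)
  expect_equal(length(fx$annotations), 2L * 476L)
  ok <- fx$eyes$true_min_nerv < fx$eyes$true_min_terv
  expect_equal(sum(ok), 468L)
  expect_true(all(which(!ok) == which(fx$eyes$inverted)))
})
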