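test_that("radial profile is plain Euclidean distance from the disc", {
  theta <- seq(0, pi, length.out = 50)
  prof <- radial_profile(circle_points(theta, r = 100, ctr = c(30, 40)),
                         disc_from_centroid(c(30, 40)))
  expect_equal(prof$distance, rep(100, 50), tolerance = 1e-9)

  expect_equal(radial_profile(cbind(3, 4), c(0, 0))$distance, 5)

  pts <- cbind(x = c(1, -2, 0, 7, 3), y = c(2, 5, -4, 1, 3))
  prof <- radial_profile(pts, c(1, 1))
  expect_equal(prof$distance, sqrt((pts[, 1] - 1)^2 + (pts[, 2] - 1)^2))
})

test_that("profile summary extracts min, mean, argmin and meridian angle", {
  const <- structure(list(distance = rep(300, 40),
                          vertices = cbind(x = 1:40, y = 0),
                          disc = c(x = 0, y = 0)), class = "erv_profile")
  s <- summarize_erv(const, side = "nasal")
  expect_equal(s$min_erv, 300, tolerance = 1e-9)
  expect_equal(s$mean_erv, 300, tolerance = 1e-9)
  expect_equal(unname(s$argmin), c(1, 0))  # first vertex on ties

  # hand-computed mixed profile
  prof <- structure(list(distance = c(310, 305, 280, 300),
                         vertices = cbind(x = 1:4, y = 1:4),
                         disc = c(x = 0, y = 0)), class = "erv_profile")
  s2 <- suppressWarnings(summarize_erv(prof, side = "temporal"))
  expect_equal(s2$min_erv, 280)
  expect_equal(s2$mean_erv, 298.75)
  expect_true(s2$min_erv <= s2$mean_erv)

  # right angle below the meridian: disc (0,0), fovea (100,0), argmin (0,50)
  prof3 <- structure(list(distance = 50, vertices = cbind(x = 0, y = 50),
                          disc = c(x = 0, y = 0)), class = "erv_profile")
  s3 <- suppressWarnings(summarize_erv(prof3, side = "temporal", fovea = c(100, 0)))
  expect_equal(s3$meridian_angle_deg, -90)
})

test_that("notch detection finds dips, reverse notches and double notches", {
  n <- 400
  base <- rep(350, n)
  expect_identical(nrow(detect_notches(base)), 0L)       # flat: nothing

  dip <- function(center, depth, sigma = 8) {
    depth * exp(-((seq_len(n) - center)^2) / (2 * sigma^2))
  }
  one <- detect_notches(base - dip(200, 40))
  expect_equal(one$type, "notch")
  expect_equal(one$index, 200, tolerance = 2)
  expect_equal(one$depth, 40, tolerance = 5)

  two <- detect_notches(base - dip(120, 30) - dip(300, 30))
  expect_equal(two$type, c("notch", "notch"))
  expect_equal(two$index, c(120, 300), tolerance = 2)

  rev_ <- detect_notches(base + dip(200, 40))
  expect_equal(rev_$type, "reverse")

  # below-threshold dip is ignored
  expect_identical(nrow(detect_notches(base - dip(200, 15))), 0L)

  # too-short profile warns and reports nothing
  expect_warning(short <- detect_notches(rep(300, 4)), "too short")
  expect_identical(nrow(short), 0L)
})

test_that("per-eye aggregation combines sides, images and asymmetry", {
  img <- tibble::tibble(
    image_id = c("a1", "a2", "a3"),
    eye_id = c("eyeA", "eyeA", "eyeA"),
    side = c("nasal", "nasal", "temporal"),
    min_erv = c(350, 340, 423),
    mean_erv = c(380, 370, 450),
    zone = "I", stage = 3L, vss = 7
  )
  eye <- aggregate_eyes(img)
  expect_equal(eye$min_nerv, 340)          # min across images
  expect_equal(eye$mean_nerv, 375)         # mean across images
  expect_equal(eye$abs_diff, 83)
  expect_equal(eye$prop_diff, (423 - 340) / 423)

  # published example: NERV 311, TERV 423 -> proportional difference ~0.265
  img2 <- tibble::tibble(image_id = c("b1", "b2"), eye_id = "eyeB",
                         side = c("nasal", "temporal"),
                         min_erv = c(311, 423), mean_erv = c(330, 440))
  eye2 <- aggregate_eyes(img2)
  expect_equal(eye2$prop_diff, 0.2648, tolerance = 1e-3)
  expect_true(sign(eye2$abs_diff) == sign(eye2$prop_diff))

  # nasal-only eye: temporal and asymmetry fields absent
  img3 <- img2[1, ]
  eye3 <- aggregate_eyes(img3)
  expect_true(is.na(eye3$min_terv) && is.na(eye3$abs_diff) && is.na(eye3$prop_diff))

  # conflicting metadata across one eye's images is an error
  img4 <- img2
  img4$zone <- c("I", "II")
  expect_error(aggregate_eyes(img4), "conflicting")
})

test_that("measured ERV scales exactly with the coordinates", {
  set.seed(5)
  spec <- cohort_spec(n_eyes = 1, notch_prob = 0)
  eye <- sample_eye(spec, "s")
  ann <- render_annotation(eye, "nasal", n_points = 30, click_jitter_sd = 0)
  m1 <- measure_annotation(ann)
  s <- 2.5
  ann2 <- ann
  ann2$points <- ann$points * s
  ann2$disc <- disc_from_centroid(ann$disc$centroid * s)
  ann2$fovea <- ann$fovea * s
  m2 <- measure_annotation(ann2)
  expect_equal(m2$min_erv, s * m1$min_erv, tolerance = 1e-6)
  expect_equal(m2$mean_erv, s * m1$mean_erv, tolerance = 1e-4)
})

test_that("pipeline recovers latent minima exactly for noise-free renders", {
  spec <- cohort_spec(n_eyes = 150, notch_prob = 0, click_jitter_sd = 0)
  sim <- simulate_cohort(spec, sides = "nasal", seed = 88)
  m <- measure_annotations(sim$annotations)
  err <- m$min_erv - sim$eyes$true_min_nerv
  expect_lt(max(abs(err)), 1)
  expect_true(all(m$min_erv <= m$mean_erv))
})
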