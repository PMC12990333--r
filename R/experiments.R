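#' Zone-discrimination AUROC experiment
#'
#' Draws large samples of minimum NERV values from the zone I and zone II
#' presets and computes the Mann--Whitney AUROC for predicting zone I
#' (lower values predict zone I), together with the binormal closed form
#' `pnorm(dmu / sqrt(sd1^2 + sd2^2))` as the analytic cross-check.
#'
#' @param n_per_zone draws per zone (default 50000).
#' @param seed integer seed.
#' @param presets zone presets (default [ZONE_PRESETS]).
#' @param metric `"nerv"` or `"terv"`.
#' @return list with `auroc`, `closed_form`, `n_per_zone`.
#' @export
experiment_zone_auroc <- function(n_per_zone = 50000, seed = 11,
                                  presets = ZONE_PRESETS, metric = "nerv") {
  set.seed(seed)
  p1 <- presets$I[[metric]]; p2 <- presets$II[[metric]]
  x1 <- stats::rnorm(n_per_zone, p1[["mean"]], p1[["sd"]])
  x2 <- stats::rnorm(n_per_zone, p2[["mean"]], p2[["sd"]])
  list(
    auroc = auroc_mann_whitney(x1, x2),
    closed_form = stats::pnorm((p2[["mean"]] - p1[["mean"]]) /
                                 sqrt(p1[["sd"]]^2 + p2[["sd"]]^2)),
    n_per_zone = n_per_zone
  )
}

#' Pipeline parameter-recovery experiment
#'
#' Generates a single-zone cohort with minima drawn from the zone preset,
#' renders one side's annotations (40 clicks, 2 px isotropic click jitter by
#' default), runs the full measurement pipeline (greedy ordering, spline
#' resampling, radial profile, minimum extraction), and reports the cohort
#' mean of the measured per-eye minimum. Cohorts are notch-free: the preset
#' describes the marginal distribution of the minimum, which a deep notch
#' deliberately violates (notch behaviour is validated by the asymmetry
#' fixture instead).
#'
#' @param zone `"I"` or `"II"`.
#' @param side `"nasal"` or `"temporal"`.
#' @param n_eyes cohort size (default 2000).
#' @param seed integer seed.
#' @return list with `measured_mean`, `latent_mean`, `preset_mean`, `n`.
#' @export
experiment_recovery <- function(zone = "I", side = "nasal", n_eyes = 2000,
                                seed = 21) {
  zm <- if (zone == "I") c(I = 1, II = 0) else c(I = 0, II = 1)
  spec <- cohort_spec(n_eyes = n_eyes, zone_mix = zm, notch_prob = 0,
                      pairing_mode = "independent-by-zone")
  sim <- simulate_cohort(spec, sides = side, seed = seed)
  m <- measure_annotations(sim$annotations)
  latent <- if (side == "nasal") sim$eyes$true_min_nerv else sim$eyes$true_min_terv
  list(measured_mean = mean(m$min_erv),
       latent_mean = mean(latent),
       preset_mean = ZONE_PRESETS[[zone]][[if (side == "nasal") "nerv" else "terv"]][["mean"]],
       n = n_eyes)
}

#' Paired nasal--temporal difference recovery experiment
#'
#' Generates a paired-difference cohort (TERV = NERV + d,
#' d ~ Normal(92.2, 34.9) by default), renders and measures both sides, and
#' reports the cohort mean of the measured per-eye `min TERV - min NERV`.
#'
#' @param n_eyes cohort size (default 2000).
#' @param seed integer seed.
#' @return list with `mean_diff`, `latent_mean_diff`, `n`.
#' @export
experiment_paired_difference <- function(n_eyes = 2000, seed = 31) {
  spec <- cohort_spec(n_eyes = n_eyes, notch_prob = 0,
                      pairing_mode = "paired-difference")
  sim <- simulate_cohort(spec, sides = c("nasal", "temporal"), seed = seed)
  eyes <- aggregate_eyes(measure_annotations(sim$annotations))
  list(mean_diff = mean(eyes$abs_diff),
       latent_mean_diff = mean(sim$eyes$true_min_terv - sim$eyes$true_min_nerv),
       n = n_eyes)
}

#' Two-grader reproducibility experiment
#'
#' Generates `n_images` single-side images whose latent minimum ERV varies
#' between images (see [repro_preset()]), produces one annotation per grader
#' with independent grader noise calibrated by [repro_noise_sd()], measures
#' the minimum ERV of every annotation through the full pipeline, and
#' estimates ICC(2,1) and the Pearson correlation between graders.
#'
#' @param n_images number of duplicated images (default 729).
#' @param seed integer seed.
#' @param preset see [repro_preset()].
#' @return list with `icc`, `ci_low`, `ci_high`, `pearson_r`, `n`,
#'   `grader_noise_sd`, and the n x 2 `ratings` matrix.
#' @export
experiment_reproducibility <- function(n_images = 729, seed = 41,
                                       preset = repro_preset(n_images)) {
  set.seed(seed)
  spec <- cohort_spec(
    n_eyes = n_images, zone_mix = c(I = 1, II = 0), notch_prob = 0,
    pairing_mode = "independent-by-zone",
    nerv_params = list(I = c(mean = preset$mu, sd = preset$sigma_b),
                       II = c(mean = preset$mu, sd = preset$sigma_b)))
  ratings <- matrix(NA_real_, n_images, 2L,
                    dimnames = list(NULL, c("graderA", "graderB")))
  for (i in seq_len(n_images)) {
    eye <- sample_eye(spec, sprintf("img%04d", i))
    base <- render_annotation(eye, "nasal", n_points = spec$n_points,
                              click_jitter_sd = spec$click_jitter_sd)
    for (g in 1:2) {
      ann <- duplicate_with_grader_noise(base, preset$grader_noise_sd,
                                         image_id = paste0(base$image_id, "_g", g))
      ratings[i, g] <- measure_annotation(ann)$min_erv
    }
  }
  icc <- icc_2_1(ratings)
  r <- pearson_r(ratings[, 1L], ratings[, 2L])
  list(icc = icc$icc, ci_low = icc$ci_low, ci_high = icc$ci_high,
       pearson_r = r$estimate, n = n_images,
       grader_noise_sd = preset$grader_noise_sd, ratings = ratings)
}

#' Asymmetry-fixture pipeline experiment
#'
#' Builds the deterministic 476-eye asymmetry fixture
#' ([build_asymmetry_fixture()]), runs the full measurement pipeline on all
#' rendered annotations, and summarises the nasal--temporal asymmetry of the
#' measured minima.
#'
#' @param seed fixture seed (default 51).
#' @return list with `n`, `n_nerv_lt_terv`, `frac_nerv_lt_terv`,
#'   `percent_nerv_lt_terv`, `mean_abs_diff` (over non-inverted eyes this
#'   tracks the paired-difference parameters), `eyes` (measured per-eye
#'   table joined with the latent inversion flag).
#' @export
experiment_asymmetry_fixture <- function(seed = 51) {
  fx <- build_asymmetry_fixture(seed = seed)
  eyes <- aggregate_eyes(measure_annotations(fx$annotations))
  eyes$inverted <- fx$eyes$inverted[match(eyes$eye_id, fx$eyes$eye_id)]
  s <- asymmetry_summary(eyes)
  list(n = s$n,
       n_nerv_lt_terv = s$n_nerv_lt_terv,
       frac_nerv_lt_terv = s$frac_nerv_lt_terv,
       percent_nerv_lt_terv = 100 * s$frac_nerv_lt_terv,
       mean_abs_diff = s$mean_abs_diff,
       eyes = eyes)
}
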