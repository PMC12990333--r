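#' Zone-conditional ERV population presets
#'
#' Published cohort parameters (mean, SD in pixels) of the minimum nasal and
#' temporal extent of retinal vascularization conditional on the clinical
#' zone diagnosis. These presets parameterise the synthetic generator when
#' zone discrimination is the quantity under study.
#'
#' @format a list with elements `I` and `II`, each a list with `nerv` and
#'   `terv`, each a named numeric vector `c(mean =, sd =)` in pixels.
#' @export
ZONE_PRESETS <- list(
  I  = list(nerv = c(mean = 276.5, sd = 43.2), terv = c(mean = 345.0, sd = 53.4)),
  II = list(nerv = c(mean = 360.8, sd = 44.5), terv = c(mean = 452.6, sd = 52.5))
)

#' Grader-noise calibration for a target intraclass correlation
#'
#' For a one-way decomposition of duplicated measurements into a
#' between-image component (SD `sigma_b`) and independent per-grader error
#' (SD `sigma_e`), the absolute-agreement ICC is
#' `sigma_b^2 / (sigma_b^2 + sigma_e^2)`. Inverting gives the grader error
#' SD that produces a desired ICC:
#' `sigma_e = sigma_b * sqrt((1 - icc) / icc)`.
#'
#' @param sigma_b between-image SD of the measured quantity, px.
#' @param icc target intraclass correlation in (0, 1).
#' @return grader error SD in pixels.
#' @examples
#' repro_noise_sd(62, 0.985)  # ~7.65 px
#' @export
repro_noise_sd <- function(sigma_b, icc = 0.985) {
  stopifnot(sigma_b > 0, icc > 0, icc < 1)
  sigma_b * sqrt((1 - icc) / icc)
}

#' Two-grader reproducibility preset
#'
#' Study conditions for the intergrader reproducibility experiment:
#' a cohort of images whose minimum ERV varies between images with SD
#' `sigma_b`, measured independently by two graders whose per-image
#' placement error is calibrated by [repro_noise_sd()] to a target ICC of
#' `icc_target`. The between-image SD of 62 px matches the spread of the
#' zone-conditional minima (`sqrt(43.2^2 + 44.5^2)` is approximately 62);
#' the mean is irrelevant to the ICC and is set to a mid-cohort 400 px.
#'
#' @param n_images number of duplicated images (default 729).
#' @param mu,sigma_b mean and SD (px) of the between-image minimum ERV.
#' @param icc_target target ICC(2,1) (default 0.985).
#' @return a list with the preset parameters and the calibrated
#'   `grader_noise_sd`.
#' @export
repro_preset <- function(n_images = 729, mu = 400, sigma_b = 62,
                         icc_target = 0.985) {
  list(n_images = n_images, mu = mu, sigma_b = sigma_b,
       icc_target = icc_target,
       grader_noise_sd = repro_noise_sd(sigma_b, icc_target))
}

#' Specify a synthetic ROP cohort
#'
#' Builds and validates the parameter set from which synthetic eyes are
#' drawn. Defaults are the study conditions: zone-conditional minimum
#' NERV/TERV distributions from [ZONE_PRESETS], a paired nasal--temporal
#' difference of 92.2 +/- 34.9 px, a stage mix matching the published
#' eye-level stage frequencies, notch prevalence matching the published
#' per-image notch frequency (229/1832), and a VSS covariate model
#' reproducing the published ordinal trends (VSS increases with stage and
#' with more posterior vascularization).
#'
#' @param n_eyes number of eyes to simulate.
#' @param zone_mix named proportions for zones `I` and `II` (sum to 1).
#' @param stage_mix named proportions for stages `1`, `2`, `3` (sum to 1).
#' @param nerv_params,terv_params per-zone `c(mean =, sd =)` of the minimum
#'   ERV in px; defaults from [ZONE_PRESETS].
#' @param pairing_mode `"paired-difference"` (TERV = NERV + d with
#'   d ~ Normal(`paired_diff_params`)) or `"independent-by-zone"` (both
#'   sides drawn from their zone marginals). The two printed parameter sets
#'   cannot be matched simultaneously by one simple generator; choose the
#'   mode matching the quantity under study.
#' @param paired_diff_params `c(mean =, sd =)` of TERV - NERV, px.
#' @param notch_prob probability an eye carries a notch.
#' @param deep_temporal_notch_prob conditional probability that a temporal
#'   notch is deep enough to invert the nasal--temporal asymmetry.
#' @param grader_noise_sd per-image grader placement error SD in px (see
#'   [duplicate_with_grader_noise()]); default calibrated to ICC 0.985.
#' @param vss_model named vector `c(intercept =, stage_coef =, erv_coef =,
#'   noise_sd =)`: VSS = clip(intercept + stage_coef * stage -
#'   erv_coef * min NERV + Normal(0, noise_sd), 1, 9).
#' @param image_size `c(width =, height =)` of the synthetic canvas, px.
#' @param n_points number of clicked points per rendered annotation.
#' @param click_jitter_sd isotropic SD of simulated click error, px.
#' @param seed optional integer seed used by [simulate_cohort()].
#' @return validated object of class `erv_cohort_spec`.
#' @export
cohort_spec <- function(n_eyes = 605,
                        zone_mix = c(I = 0.3, II = 0.7),
                        stage_mix = c(`1` = 0.276, `2` = 0.488, `3` = 0.236),
                        nerv_params = lapply(ZONE_PRESETS, `[[`, "nerv"),
                        terv_params = lapply(ZONE_PRESETS, `[[`, "terv"),
                        pairing_mode = c("paired-difference", "independent-by-zone"),
                        paired_diff_params = c(mean = 92.2, sd = 34.9),
                        notch_prob = 229 / 1832,
                        deep_temporal_notch_prob = 0.25,
                        grader_noise_sd = repro_noise_sd(62, 0.985),
                        vss_model = c(intercept = 6.0, stage_coef = 1.2,
                                      erv_coef = 0.012, noise_sd = 0.8),
                        image_size = c(width = 1600, height = 1200),
                        n_points = 40,
                        click_jitter_sd = 2,
                        seed = NULL) {
  spec <- list(
    n_eyes = n_eyes, zone_mix = zone_mix, stage_mix = stage_mix,
    nerv_params = nerv_params, terv_params = terv_params,
    pairing_mode = match.arg(pairing_mode),
    paired_diff_params = paired_diff_params,
    notch_prob = notch_prob,
    deep_temporal_notch_prob = deep_temporal_notch_prob,
    grader_noise_sd = grader_noise_sd,
    vss_model = vss_model, image_size = image_size,
    n_points = n_points, click_jitter_sd = click_jitter_sd, seed = seed
  )
  class(spec) <- "erv_cohort_spec"
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  fail <- function(field, msg)
    stop(sprintf("invalid cohort spec: field '%s' %s", field, msg), call. = FALSE)
  if (!is.numeric(spec$n_eyes) || spec$n_eyes < 1) fail("n_eyes", "must be >= 1")
  check_mix <- function(mix, field, labels) {
    if (!all(labels %in% names(mix))) fail(field, paste("needs names", paste(labels, collapse = ", ")))
    if (any(mix < 0) || any(mix > 1)) fail(field, "proportions must lie in [0, 1]")
    if (abs(sum(mix) - 1) > 1e-9) fail(field, "proportions must sum to 1")
  }
  check_mix(spec$zone_mix, "zone_mix", c("I", "II"))
  check_mix(spec$stage_mix, "stage_mix", c("1", "2", "3"))
  for (fld in c("nerv_params", "terv_params")) {
    pr <- spec[[fld]]
    if (!all(c("I", "II") %in% names(pr))) fail(fld, "needs zones I and II")
    for (z in c("I", "II")) {
      if (!all(c("mean", "sd") %in% names(pr[[z]]))) fail(fld, "entries need mean and sd")
      if (pr[[z]][["sd"]] < 0) fail(fld, "sd must be >= 0")
    }
  }
  if (!all(c("mean", "sd") %in% names(spec$paired_diff_params)) ||
      spec$paired_diff_params[["sd"]] < 0)
    fail("paired_diff_params", "needs mean and sd >= 0")
  for (fld in c("notch_prob", "deep_temporal_notch_prob")) {
    if (spec[[fld]] < 0 || spec[[fld]] > 1) fail(fld, "must lie in [0, 1]")
  }
  if (spec$grader_noise_sd < 0) fail("grader_noise_sd", "must be >= 0")
  if (!all(c("intercept", "stage_coef", "erv_coef", "noise_sd") %in% names(spec$vss_model)) ||
      spec$vss_model[["noise_sd"]] < 0)
    fail("vss_model", "needs intercept, stage_coef, erv_coef, noise_sd >= 0")
  if (!all(c("width", "height") %in% names(spec$image_size)) || any(spec$image_size <= 0))
    fail("image_size", "needs positive width and height")
  if (spec$n_points < 2) fail("n_points", "must be >= 2")
  if (spec$click_jitter_sd < 0) fail("click_jitter_sd", "must be >= 0")
  spec
}

#' @export
print.erv_cohort_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<erv_cohort_spec> %d eyes, zones I/II = %.2f/%.2f, pairing = %s\n",
    "  min NERV I: %.1f +/- %.1f px, II: %.1f +/- %.1f px\n",
    "  min TERV I: %.1f +/- %.1f px, II: %.1f +/- %.1f px\n",
    "  notch prob %.3f, grader noise %.2f px, %d clicks +/- %.1f px\n"),
    x$n_eyes, x$zone_mix[["I"]], x$zone_mix[["II"]], x$pairing_mode,
    x$nerv_params$I[["mean"]], x$nerv_params$I[["sd"]],
    x$nerv_params$II[["mean"]], x$nerv_params$II[["sd"]],
    x$terv_params$I[["mean"]], x$terv_params$I[["sd"]],
    x$terv_params$II[["mean"]], x$terv_params$II[["sd"]],
    x$notch_prob, x$grader_noise_sd, x$n_points, x$click_jitter_sd))
  invisible(x)
}
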