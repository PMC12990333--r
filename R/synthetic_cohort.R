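#' Sample one latent synthetic eye
#'
#' Draws a latent eye from a cohort specification: a clinical zone and stage,
#' true minimum NERV/TERV values from the zone-conditional (or
#' paired-difference) distributions, smooth radial ridge arcs on each side
#' whose minimum radius equals the drawn minimum, optional notch
#' perturbations, and a vascular severity score from the covariate model
#' `VSS = clip(intercept + stage_coef * stage - erv_coef * min NERV + noise,
#' 1, 9)`.
#'
#' Each side's arc is a radial function `r(theta)` spanning 120 degrees of
#' angle facing away from the disc (temporal arcs centred on the +x
#' direction, nasal on -x): a base radius plus a low-order cosine modulation
#' (amplitude at most 10% of the base) with, when the eye carries a notch, a
#' localized Gaussian radial dip (or bump, for a reverse notch)
#' superimposed. The arc is shifted so that its minimum radius equals the
#' drawn true minimum exactly (to grid resolution, well under 0.5 px).
#'
#' Uses the current RNG state; seed at the cohort level (see
#' [simulate_cohort()]).
#'
#' @param spec an `erv_cohort_spec`, see [cohort_spec()].
#' @param eye_id identifier for the eye.
#' @return an object of class `erv_latent_eye`: list with `eye_id`, `zone`,
#'   `stage`, `true_min_nerv`, `true_min_terv`, `disc_center`, `fovea`,
#'   `nasal_arc`, `temporal_arc`, `vss`, `notch` (NULL or a description of
#'   the carried notch).
#' @export
sample_eye <- function(spec, eye_id = "eye1") {
  stopifnot(inherits(spec, "erv_cohort_spec"))
  zone <- sample(c("I", "II"), 1L, prob = spec$zone_mix[c("I", "II")])
  stage <- sample(1:3, 1L, prob = spec$stage_mix[c("1", "2", "3")])

  np <- spec$nerv_params[[zone]]
  tp <- spec$terv_params[[zone]]
  nerv <- stats::rnorm(1L, np[["mean"]], np[["sd"]])
  terv <- if (spec$pairing_mode == "paired-difference") {
    nerv + stats::rnorm(1L, spec$paired_diff_params[["mean"]],
                        spec$paired_diff_params[["sd"]])
  } else {
    stats::rnorm(1L, tp[["mean"]], tp[["sd"]])
  }

  # notch phenotype assignment
  notch <- NULL
  if (stats::runif(1L) < spec$notch_prob) {
    side <- sample(c("nasal", "temporal"), 1L)
    deep <- side == "temporal" && stats::runif(1L) < spec$deep_temporal_notch_prob
    type <- if (deep) "deep" else sample(c("notch", "reverse", "double"), 1L,
                                         prob = c(0.7, 0.2, 0.1))
    notch <- list(side = side, type = type)
  }

  w <- spec$image_size[["width"]]; h <- spec$image_size[["height"]]
  disc <- c(x = w / 2 + stats::runif(1L, -20, 20),
            y = h / 2 + stats::runif(1L, -20, 20))
  fovea <- c(x = disc[["x"]] + 240, y = disc[["y"]] + stats::runif(1L, -15, 15))

  arc_for <- function(side, target_min) {
    notches <- list()
    smooth_min <- target_min
    if (!is.null(notch) && notch$side == side) {
      if (notch$type == "deep") {
        # handled by caller adjusting target; defensive fall-through
        notches <- list(gaussian_notch(side, sigma = deg2rad(6),
                                       depth = stats::runif(1L, 80, 140), sign = -1))
        smooth_min <- target_min + notches[[1L]]$depth
      } else if (notch$type == "reverse") {
        notches <- list(gaussian_notch(side, sigma = deg2rad(4),
                                       depth = stats::runif(1L, 30, 60), sign = 1))
      } else if (notch$type == "double") {
        notches <- list(
          gaussian_notch(side, sigma = deg2rad(4),
                         depth = stats::runif(1L, 30, 60), sign = -1, lobe = -1),
          gaussian_notch(side, sigma = deg2rad(4),
                         depth = stats::runif(1L, 30, 60), sign = -1, lobe = 1))
        smooth_min <- target_min + max(vapply(notches, `[[`, 0, "depth"))
      } else {
        notches <- list(gaussian_notch(side, sigma = deg2rad(4),
                                       depth = stats::runif(1L, 30, 60), sign = -1))
        smooth_min <- target_min + notches[[1L]]$depth
      }
    }
    make_arc(side, target_min = target_min, smooth_min = smooth_min,
             notches = notches)
  }

  # a deep temporal notch dips the temporal minimum below the nasal one
  true_terv <- terv
  if (!is.null(notch) && identical(notch$type, "deep"))
    true_terv <- nerv - stats::runif(1L, 25, 40)

  vm <- spec$vss_model
  vss <- vm[["intercept"]] + vm[["stage_coef"]] * stage -
    vm[["erv_coef"]] * nerv + stats::rnorm(1L, 0, vm[["noise_sd"]])
  vss <- min(max(vss, 1), 9)

  structure(list(
    eye_id = eye_id, zone = zone, stage = stage,
    true_min_nerv = nerv, true_min_terv = true_terv,
    disc_center = disc, fovea = fovea,
    nasal_arc = arc_for("nasal", nerv),
    temporal_arc = if (!is.null(notch) && identical(notch$type, "deep")) {
      make_deep_notch_arc(smooth_min = terv, target_min = true_terv)
    } else arc_for("temporal", true_terv),
    vss = vss, notch = notch,
    image_size = spec$image_size
  ), class = "erv_latent_eye")
}

deg2rad <- function(d) d * pi / 180

# angular placement for a notch: random position away from the arc edges
gaussian_notch <- function(side, sigma, depth, sign, lobe = 0) {
  center0 <- if (side == "temporal") 0 else pi
  half <- pi / 3
  lo <- center0 - (half - 4 * sigma)
  hi <- center0 + (half - 4 * sigma)
  pos <- if (lobe < 0) stats::runif(1L, lo, center0 - 2 * sigma)
         else if (lobe > 0) stats::runif(1L, center0 + 2 * sigma, hi)
         else stats::runif(1L, lo, hi)
  list(center = pos, sigma = sigma, depth = depth, sign = sign)
}

# Build a radial arc r(theta) over a 120-degree span with minimum radius
# exactly target_min. smooth_min is the trough of the smooth component
# before the vertical normalisation shift.
make_arc <- function(side, target_min, smooth_min = target_min,
                     notches = list(), amp_frac = NULL, theta0 = NULL,
                     sigma_deep = deg2rad(6)) {
  center <- if (side == "temporal") 0 else pi
  half <- pi / 3
  lo <- center - half; hi <- center + half
  if (is.null(theta0)) theta0 <- stats::runif(1L, center - half / 2, center + half / 2)
  if (is.null(amp_frac)) amp_frac <- stats::runif(1L, 0.02, 0.10)
  amp <- amp_frac * smooth_min
  omega <- pi / max(theta0 - lo, hi - theta0)
  arc <- list(side = side, center = center, half_span = half,
              smooth_min = smooth_min, amp = amp, theta0 = theta0,
              omega = omega, notches = notches, shift = 0)
  class(arc) <- "erv_arc"
  # vertical shift so the grid minimum equals target_min
  g <- arc_radius(arc, seq(lo, hi, length.out = 2048L))
  arc$shift <- target_min - min(g)
  arc$min_radius <- target_min
  arc
}

# Deep temporal notch: smooth part keeps the paired-difference minimum but a
# localized dip reaches target_min (below the nasal minimum).
make_deep_notch_arc <- function(smooth_min, target_min) {
  stopifnot(target_min < smooth_min)
  side <- "temporal"
  sigma <- deg2rad(6)
  base <- make_arc(side, target_min = smooth_min, smooth_min = smooth_min)
  n <- gaussian_notch(side, sigma = sigma, depth = 1, sign = -1)
  # depth so that the notch tip reaches target_min from the local base level
  base_at <- arc_radius(base, n$center)
  n$depth <- base_at - target_min
  base$notches <- list(n)
  lo <- base$center - base$half_span; hi <- base$center + base$half_span
  g <- arc_radius(base, seq(lo, hi, length.out = 2048L))
  base$shift <- base$shift + (target_min - min(g))
  base$min_radius <- target_min
  base
}

#' Evaluate a latent arc's radial function
#'
#' @param arc an `erv_arc` as stored in an `erv_latent_eye`.
#' @param theta angles (radians, image convention: y down, temporal arcs
#'   centred on 0, nasal on pi).
#' @return radii in pixels.
#' @export
arc_radius <- function(arc, theta) {
  r <- arc$smooth_min + arc$amp * (1 - cos(arc$omega * (theta - arc$theta0)))
  for (n in arc$notches) {
    d <- theta - n$center
    d <- ((d + pi) %% (2 * pi)) - pi      # nasal arcs wrap across pi
    r <- r + n$sign * n$depth * exp(-d^2 / (2 * n$sigma^2))
  }
  r + arc$shift
}

#' Render a clicked-point annotation from a latent eye
#'
#' Emulates a grader clicking points along the visible stage line in one
#' field of view: clicks are placed at even angular spacing over the side's
#' 120-degree arc (a careful grader spaces clicks to preserve the ridge
#' curvature), perturbed with isotropic Gaussian click jitter, and returned
#' in randomized order so that downstream point ordering is actually
#' exercised.
#'
#' @param eye an `erv_latent_eye` from [sample_eye()].
#' @param side `"nasal"` or `"temporal"`.
#' @param n_points number of clicks (>= 2).
#' @param click_jitter_sd isotropic click error SD, px.
#' @param image_id identifier (default derived from the eye and side).
#' @param disc_radius rendered disc radius in px (used when writing masks).
#' @return an object of class `erv_annotation`: list with `image_id`,
#'   `eye_id`, `fov_side`, `points` (shuffled n x 2 matrix), `disc` (an
#'   `erv_disc`), `disc_radius`, `fovea`, `zone`, `stage`, `vss`,
#'   `image_size`, and the latent `arc` (kept so duplicate grader
#'   annotations can be generated).
#' @export
render_annotation <- function(eye, side = c("nasal", "temporal"),
                              n_points = 40, click_jitter_sd = 2,
                              image_id = NULL, disc_radius = 60) {
  stopifnot(inherits(eye, "erv_latent_eye"))
  side <- match.arg(side)
  if (n_points < 2L) stop("render_annotation(): n_points must be >= 2")
  arc <- if (side == "nasal") eye$nasal_arc else eye$temporal_arc
  lo <- arc$center - arc$half_span
  span <- 2 * arc$half_span
  step <- span / n_points
  theta <- lo + (seq_len(n_points) - 0.5) * step
  r <- arc_radius(arc, theta)
  cx <- eye$disc_center[["x"]]; cy <- eye$disc_center[["y"]]
  pts <- cbind(x = cx + r * cos(theta), y = cy + r * sin(theta))
  if (click_jitter_sd > 0)
    pts <- pts + matrix(stats::rnorm(2L * n_points, 0, click_jitter_sd), ncol = 2L)
  ord <- sample.int(n_points)                 # randomized click order
  if (is.null(image_id)) image_id <- paste0(eye$eye_id, "_", side)
  structure(list(
    image_id = image_id, eye_id = eye$eye_id, fov_side = side,
    points = pts[ord, , drop = FALSE],
    disc = disc_from_centroid(eye$disc_center, area = pi * disc_radius^2),
    disc_radius = disc_radius,
    fovea = eye$fovea, zone = eye$zone, stage = eye$stage, vss = eye$vss,
    image_size = eye$image_size %||% c(width = 1600, height = 1200),
    arc = arc
  ), class = "erv_annotation")
}

#' @export
print.erv_annotation <- function(x, ...) {
  cat(sprintf("<erv_annotation> %s (%s, eye %s): %d points, disc (%.0f, %.0f)\n",
              x$image_id, x$fov_side, x$eye_id, nrow(x$points),
              x$disc$centroid[["x"]], x$disc$centroid[["y"]]))
  invisible(x)
}

#' Duplicate an annotation with independent grader noise
#'
#' Produces a second grader's annotation of the same latent ridge. Grader
#' disagreement is modelled as a per-image radial placement offset
#' `delta ~ Normal(0, grader_noise_sd)`: the second grader perceives the
#' vascular--avascular junction systematically `delta` pixels closer to or
#' farther from the disc across the whole image, which is the dominant
#' component of real intergrader disagreement and propagates to the
#' measured minimum ERV one-to-one. Independent per-click jitter can be
#' added on top via `click_jitter_sd`. With both noise terms zero the
#' duplicate is identical to the input.
#'
#' Applying this twice to one base annotation yields two graders with
#' independent errors, matching the one-way calibration in
#' [repro_noise_sd()].
#'
#' @param ann an `erv_annotation`.
#' @param grader_noise_sd SD (px) of the per-image radial offset.
#' @param click_jitter_sd SD (px) of additional independent per-point
#'   jitter (default 0).
#' @param image_id identifier of the duplicate (default `<id>_dup`).
#' @return an `erv_annotation` with the perturbed points.
#' @export
duplicate_with_grader_noise <- function(ann, grader_noise_sd,
                                        click_jitter_sd = 0,
                                        image_id = NULL) {
  stopifnot(inherits(ann, "erv_annotation"), grader_noise_sd >= 0)
  delta <- if (grader_noise_sd > 0) stats::rnorm(1L, 0, grader_noise_sd) else 0
  ctr <- ann$disc$centroid
  d <- ann$points - matrix(ctr, nrow(ann$points), 2L, byrow = TRUE)
  r <- sqrt(rowSums(d^2))
  scale <- (r + delta) / r
  pts <- matrix(ctr, nrow(ann$points), 2L, byrow = TRUE) + d * scale
  colnames(pts) <- c("x", "y")
  if (click_jitter_sd > 0)
    pts <- pts + matrix(stats::rnorm(2L * nrow(pts), 0, click_jitter_sd), ncol = 2L)
  out <- ann
  out$points <- pts
  out$image_id <- if (is.null(image_id)) paste0(ann$image_id, "_dup") else image_id
  out
}

#' Simulate a synthetic cohort
#'
#' Draws `spec$n_eyes` latent eyes and (optionally) renders clicked-point
#' annotations for the requested sides. All randomness flows from `seed`;
#' with the same seed the generated cohort is bit-reproducible.
#'
#' @param spec an `erv_cohort_spec`.
#' @param sides character vector of sides to render (subset of
#'   `c("nasal", "temporal")`); use `character()` with `render = FALSE` for
#'   latent-only simulation.
#' @param render if FALSE, only latent eyes are returned.
#' @param seed integer seed (default `spec$seed`).
#' @return list with `eyes` (tibble of latent per-eye values: eye_id, zone,
#'   stage, true_min_nerv, true_min_terv, vss, notch_side, notch_type),
#'   `latent` (list of `erv_latent_eye`) and `annotations` (list of
#'   `erv_annotation`, empty when `render = FALSE`).
#' @export
simulate_cohort <- function(spec, sides = c("nasal", "temporal"),
                            render = TRUE, seed = spec$seed) {
  stopifnot(inherits(spec, "erv_cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(spec$n_eyes)
  ids <- sprintf("eye%04d", seq_len(n))
  latent <- vector("list", n)
  annotations <- list()
  for (i in seq_len(n)) {
    eye <- sample_eye(spec, eye_id = ids[[i]])
    latent[[i]] <- eye
    if (render) {
      for (s in sides) {
        annotations[[length(annotations) + 1L]] <-
          render_annotation(eye, side = s, n_points = spec$n_points,
                            click_jitter_sd = spec$click_jitter_sd)
      }
    }
  }
  eyes <- tibble::tibble(
    eye_id = ids,
    zone = vapply(latent, `[[`, "", "zone"),
    stage = vapply(latent, `[[`, 0L, "stage"),
    true_min_nerv = vapply(latent, `[[`, 0, "true_min_nerv"),
    true_min_terv = vapply(latent, `[[`, 0, "true_min_terv"),
    vss = vapply(latent, `[[`, 0, "vss"),
    notch_side = vapply(latent, function(e) e$notch$side %||% NA_character_, ""),
    notch_type = vapply(latent, function(e) e$notch$type %||% NA_character_, "")
  )
  list(eyes = eyes, latent = latent, annotations = annotations)
}

#' Deterministic 476-eye nasal--temporal asymmetry fixture
#'
#' Constructs the asymmetry study conditions exactly: 476 eyes of which 468
#' have a temporal minimum exceeding the nasal minimum by
#' `d ~ Normal(92.2, 34.9)` truncated to be positive, and 8 carry a deep
#' temporal notch that forces the measured minimum TERV below the minimum
#' NERV. Annotations are rendered without click jitter so the pipeline's
#' classification of every eye is determined by construction.
#'
#' @param seed integer seed.
#' @param n_points clicks per annotation.
#' @return list with `eyes` (latent tibble including `inverted`),
#'   `annotations` (both sides for all 476 eyes).
#' @export
build_asymmetry_fixture <- function(seed = 51, n_points = 40) {
  set.seed(seed)
  n_total <- 476L
  n_inverted <- 8L
  spec <- cohort_spec(n_eyes = n_total, notch_prob = 0, click_jitter_sd = 0,
                      n_points = n_points)
  rtrunc_pos <- function(mean, sd) {
    repeat {
      x <- stats::rnorm(1L, mean, sd)
      if (x > 0) return(x)
    }
  }
  latent <- vector("list", n_total)
  annotations <- vector("list", 2L * n_total)
  inverted <- rep(FALSE, n_total)
  for (i in seq_len(n_total)) {
    id <- sprintf("eye%04d", i)
    nerv <- stats::rnorm(1L, 337.75, 52.15)
    d <- rtrunc_pos(92.2, 34.9)
    w <- spec$image_size[["width"]]; h <- spec$image_size[["height"]]
    disc <- c(x = w / 2 + stats::runif(1L, -20, 20),
              y = h / 2 + stats::runif(1L, -20, 20))
    fovea <- c(x = disc[["x"]] + 240, y = disc[["y"]] + stats::runif(1L, -15, 15))
    deep <- i > n_total - n_inverted
    inverted[i] <- deep
    true_terv <- if (deep) nerv - stats::runif(1L, 25, 40) else nerv + d
    eye <- structure(list(
      eye_id = id, zone = "II", stage = sample(1:3, 1L),
      true_min_nerv = nerv, true_min_terv = true_terv,
      disc_center = disc, fovea = fovea,
      nasal_arc = make_arc("nasal", target_min = nerv),
      temporal_arc = if (deep) {
        make_deep_notch_arc(smooth_min = nerv + d, target_min = true_terv)
      } else make_arc("temporal", target_min = nerv + d),
      vss = NA_real_, notch = if (deep) list(side = "temporal", type = "deep") else NULL,
      image_size = spec$image_size
    ), class = "erv_latent_eye")
    latent[[i]] <- eye
    annotations[[2L * i - 1L]] <- render_annotation(eye, "nasal",
                                                    n_points = n_points,
                                                    click_jitter_sd = 0)
    annotations[[2L * i]] <- render_annotation(eye, "temporal",
                                               n_points = n_points,
                                               click_jitter_sd = 0)
  }
  eyes <- tibble::tibble(
    eye_id = vapply(latent, `[[`, "", "eye_id"),
    true_min_nerv = vapply(latent, `[[`, 0, "true_min_nerv"),
    true_min_terv = vapply(latent, `[[`, 0, "true_min_terv"),
    inverted = inverted
  )
  list(eyes = eyes, annotations = annotations)
}

#' @export
print.erv_latent_eye <- function(x, ...) {
  cat(sprintf("<erv_latent_eye> %s zone %s stage %d: min NERV %.1f, min TERV %.1f px, VSS %.1f\n",
              x$eye_id, x$zone, x$stage, x$true_min_nerv, x$true_min_terv, x$vss))
  invisible(x)
}
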