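#' Radial ERV profile of a ridge path
#'
#' Computes the Euclidean distance in pixels from the optic-disc centroid to
#' every resampled vertex of the ridge path. This per-vertex distance is the
#' extent of retinal vascularization (ERV) along the ridge.
#'
#' @param path an `erv_ridge_path` (see [fit_smooth_path()]) or an n x 2
#'   matrix of vertices.
#' @param disc an `erv_disc` (see [disc_centroid()], [disc_from_centroid()])
#'   or a length-2 (x, y) coordinate.
#' @return an object of class `erv_profile`: list with `distance` (numeric
#'   vector, px), `vertices` (matrix) and `disc` (the centroid used).
#' @export
radial_profile <- function(path, disc) {
  v <- if (inherits(path, "erv_ridge_path")) path$vertices else as_xy_matrix(path, "path")
  if (nrow(v) == 0L) stop("radial_profile(): empty path")
  ctr <- disc_centre(disc)
  structure(list(
    distance = unname(sqrt((v[, 1L] - ctr[[1L]])^2 + (v[, 2L] - ctr[[2L]])^2)),
    vertices = v,
    disc = ctr
  ), class = "erv_profile")
}

disc_centre <- function(disc) {
  if (inherits(disc, "erv_disc")) disc$centroid
  else c(x = disc[[1L]], y = disc[[2L]])
}

#' Summarise a radial profile into a per-image ERV measurement
#'
#' Reduces the radial distance profile to the per-image quantities: the
#' minimum ERV (the most posterior point of the vascular--avascular
#' junction), the mean ERV over the resampled path (arc-length weighted by
#' construction of the resampling), the image location of the minimum, the
#' meridian angle of the minimum if the fovea is available, and notch
#' candidates along the profile.
#'
#' The meridian is the ray from the disc centre through the fovea; the
#' reported angle is the signed angle at the disc centre from that ray to
#' the disc-to-minimum ray, in degrees in (-180, 180], positive
#' counterclockwise in image coordinates (y pointing down).
#'
#' @param profile an `erv_profile` from [radial_profile()].
#' @param side `"nasal"` or `"temporal"`.
#' @param fovea optional (x, y) fovea coordinate.
#' @param image_id optional identifier carried into the result.
#' @param notch_depth_threshold,notch_window_frac notch detection
#'   parameters, see [detect_notches()].
#' @return an object of class `erv_measurement`: list with `image_id`,
#'   `side`, `min_erv`, `mean_erv`, `argmin` (x, y), `meridian_angle_deg`
#'   (NA when no fovea), `notches` (tibble from [detect_notches()]).
#' @export
summarize_erv <- function(profile, side = c("nasal", "temporal"), fovea = NULL,
                          image_id = NA_character_,
                          notch_depth_threshold = 20, notch_window_frac = 1 / 8) {
  stopifnot(inherits(profile, "erv_profile"))
  side <- match.arg(side)
  d <- profile$distance
  if (length(d) == 0L) stop("summarize_erv(): empty profile")
  i_min <- which.min(d)                       # first index on ties
  argmin <- profile$vertices[i_min, ]
  angle <- NA_real_
  if (!is.null(fovea) && all(is.finite(fovea))) {
    ctr <- profile$disc
    a_fov <- atan2(fovea[[2L]] - ctr[[2L]], fovea[[1L]] - ctr[[1L]])
    a_min <- atan2(argmin[[2L]] - ctr[[2L]], argmin[[1L]] - ctr[[1L]])
    # y points down, so increasing atan2 angle is clockwise on screen;
    # negate to make counterclockwise positive
    delta <- -(a_min - a_fov) * 180 / pi
    angle <- ((delta + 180) %% 360) - 180
    if (angle == -180) angle <- 180
  }
  structure(list(
    image_id = image_id,
    side = side,
    min_erv = d[i_min],
    mean_erv = mean(d),
    argmin = c(x = unname(argmin[[1L]]), y = unname(argmin[[2L]])),
    meridian_angle_deg = angle,
    notches = detect_notches(profile, depth_threshold = notch_depth_threshold,
                             window_frac = notch_window_frac)
  ), class = "erv_measurement")
}

#' @export
print.erv_measurement <- function(x, ...) {
  cat(sprintf("<erv_measurement> %s %s: min %.1f px, mean %.1f px, %d notch(es)\n",
              x$image_id, x$side, x$min_erv, x$mean_erv, nrow(x$notches)))
  invisible(x)
}

#' Detect notch phenotypes along a radial ERV profile
#'
#' A notch is a localized posterior incursion of the vascular--avascular
#' junction: a dip in the radial profile whose depth below the local
#' baseline exceeds a threshold. The baseline at each vertex is the median
#' of the profile over a window of `window_frac` of the path length on each
#' side. Local minima deeper than `depth_threshold` below their baseline are
#' reported as `"notch"`; symmetric local maxima rising more than the
#' threshold above baseline are reported as `"reverse"` (a notch protruding
#' peripherally). Two or more qualifying dips constitute a double notch;
#' each is reported. Candidates are non-maximum-suppressed within one
#' window so click noise cannot split one notch into several.
#'
#' @param profile an `erv_profile`, or a bare numeric distance vector.
#' @param depth_threshold minimum depth/height in pixels (default 20).
#' @param window_frac window half-width as a fraction of profile length
#'   (default 1/8).
#' @return a tibble with columns `type` ("notch"/"reverse"), `depth` (px),
#'   `x`, `y` (vertex location, NA when the profile has no coordinates),
#'   `index` (vertex index). Zero rows when nothing qualifies; a warning is
#'   issued (and zero rows returned) when the profile is shorter than two
#'   windows.
#' @export
detect_notches <- function(profile, depth_threshold = 20, window_frac = 1 / 8) {
  if (inherits(profile, "erv_profile")) {
    d <- profile$distance
    verts <- profile$vertices
  } else {
    d <- as.numeric(profile)
    verts <- NULL
  }
  empty <- tibble::tibble(type = character(), depth = numeric(),
                          x = numeric(), y = numeric(), index = integer())
  n <- length(d)
  w <- max(3L, as.integer(round(window_frac * n)))
  if (n < 2L * w) {
    warning("detect_notches(): profile too short for the requested window; no notches reported")
    return(empty)
  }
  baseline <- running_median(d, w)
  dev <- baseline - d                          # positive = dip below baseline

  cand <- function(excursion, type) {
    qual <- which(excursion > depth_threshold)
    if (!length(qual)) return(empty)
    # non-maximum suppression: keep the deepest vertex within each window
    qual <- qual[order(excursion[qual], decreasing = TRUE)]
    kept <- integer()
    for (i in qual) {
      if (!length(kept) || all(abs(kept - i) > w)) kept <- c(kept, i)
    }
    kept <- sort(kept)
    tibble::tibble(
      type = rep(type, length(kept)),
      depth = excursion[kept],
      x = if (is.null(verts)) rep(NA_real_, length(kept)) else verts[kept, 1L],
      y = if (is.null(verts)) rep(NA_real_, length(kept)) else verts[kept, 2L],
      index = kept
    )
  }
  out <- rbind(cand(dev, "notch"), cand(-dev, "reverse"))
  out[order(out$index), , drop = FALSE]
}

# centred running median with half-width w (edges use the truncated window)
running_median <- function(x, w) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1L, i - w):min(n, i + w)])
  }, numeric(1))
}

#' Run the full per-image measurement pipeline on one annotation
#'
#' Convenience composition of the geometry and measurement layers:
#' greedy ordering of the clicked points, interpolating spline path with
#' 1 px resampling, radial profile from the disc centroid, and profile
#' summary.
#'
#' @param ann an `erv_annotation` (see [render_annotation()] or
#'   [read_annotations()]).
#' @param notch_depth_threshold,notch_window_frac forwarded to
#'   [summarize_erv()].
#' @return an `erv_measurement`.
#' @export
measure_annotation <- function(ann, notch_depth_threshold = 20,
                               notch_window_frac = 1 / 8) {
  stopifnot(inherits(ann, "erv_annotation"))
  ord <- order_points_greedy(ann$points)
  path <- fit_smooth_path(ord$points, image_id = ann$image_id)
  prof <- radial_profile(path, ann$disc)
  summarize_erv(prof, side = ann$fov_side, fovea = ann$fovea,
                image_id = ann$image_id,
                notch_depth_threshold = notch_depth_threshold,
                notch_window_frac = notch_window_frac)
}

#' Per-image measurement table
#'
#' Applies [measure_annotation()] to a list of annotations and collects the
#' results, joined with each annotation's clinical metadata, into one row
#' per image.
#'
#' @param annotations list of `erv_annotation` objects.
#' @param ... forwarded to [measure_annotation()].
#' @return tibble with columns image_id, eye_id, side, min_erv, mean_erv,
#'   argmin_x, argmin_y, meridian_angle_deg, n_notches, zone, stage, vss.
#' @export
measure_annotations <- function(annotations, ...) {
  rows <- lapply(annotations, function(ann) {
    m <- measure_annotation(ann, ...)
    tibble::tibble(
      image_id = as.character(ann$image_id),
      eye_id = as.character(ann$eye_id),
      side = m$side,
      min_erv = m$min_erv,
      mean_erv = m$mean_erv,
      argmin_x = m$argmin[["x"]],
      argmin_y = m$argmin[["y"]],
      meridian_angle_deg = m$meridian_angle_deg,
      n_notches = sum(m$notches$type == "notch"),
      zone = ann$zone %||% NA_character_,
      stage = ann$stage %||% NA_integer_,
      vss = ann$vss %||% NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Aggregate per-image measurements into per-eye NERV/TERV records
#'
#' Within one eye (one examination), the eye-level minimum ERV on each side
#' is the minimum across that side's images of the per-image minima, and
#' the eye-level mean ERV is the mean across images of the per-image means.
#' When both sides are present the nasal--temporal asymmetry is quantified
#' as `abs_diff = min_terv - min_nerv` and
#' `prop_diff = (min_terv - min_nerv) / min_terv`.
#'
#' @param image_table tibble from [measure_annotations()] (needs columns
#'   eye_id, side, min_erv, mean_erv, and optionally zone, stage, vss).
#' @return a `CohortTable`: tibble with one row per eye and columns eye_id,
#'   min_nerv, mean_nerv, min_terv, mean_terv, abs_diff, prop_diff, zone,
#'   stage, vss. Sides not measured for an eye are NA, as are the asymmetry
#'   columns when either side is missing.
#' @export
aggregate_eyes <- function(image_table) {
  stopifnot(all(c("eye_id", "side", "min_erv", "mean_erv") %in% names(image_table)))
  meta_cols <- intersect(c("zone", "stage", "vss"), names(image_table))
  rows <- lapply(split(image_table, image_table$eye_id), function(g) {
    meta <- lapply(meta_cols, function(cl) {
      u <- unique(g[[cl]][!is.na(g[[cl]])])
      if (length(u) > 1L)
        stop(sprintf("aggregate_eyes(): conflicting %s metadata for eye %s",
                     cl, g$eye_id[[1L]]))
      if (length(u)) u else g[[cl]][NA_integer_][1L]
    })
    names(meta) <- meta_cols
    side_stat <- function(side, fun, col) {
      v <- g[[col]][g$side == side]
      if (length(v)) fun(v) else NA_real_
    }
    min_nerv <- side_stat("nasal", min, "min_erv")
    min_terv <- side_stat("temporal", min, "min_erv")
    both <- is.finite(min_nerv) && is.finite(min_terv)
    tibble::tibble(
      eye_id = g$eye_id[[1L]],
      min_nerv = min_nerv,
      mean_nerv = side_stat("nasal", mean, "mean_erv"),
      min_terv = min_terv,
      mean_terv = side_stat("temporal", mean, "mean_erv"),
      abs_diff = if (both) min_terv - min_nerv else NA_real_,
      prop_diff = if (both && min_terv > 0) (min_terv - min_nerv) / min_terv else NA_real_,
      zone = if ("zone" %in% meta_cols) as.character(meta$zone) else NA_character_,
      stage = if ("stage" %in% meta_cols) as.integer(meta$stage) else NA_integer_,
      vss = if ("vss" %in% meta_cols) as.numeric(meta$vss) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$eye_id), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
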