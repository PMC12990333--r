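#' Write an annotation set to disk
#'
#' Canonical on-disk layout: `points.csv` (image_id, x, y; one row per
#' click), `metadata.csv` (image_id, eye_id, laterality, fov_side, zone,
#' stage, vss), `fovea.csv` (image_id, x, y), and 8-bit grayscale PNG disc
#' masks `masks/<image_id>.png` (filled circle at the disc centroid; any
#' non-zero pixel is foreground).
#'
#' @param annotations list of `erv_annotation`.
#' @param dir output directory (created if absent).
#' @param write_masks write PNG disc masks (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_annotations <- function(annotations, dir, write_masks = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pts <- do.call(rbind, lapply(annotations, function(a) {
    data.frame(image_id = a$image_id, x = a$points[, 1L], y = a$points[, 2L])
  }))
  utils::write.csv(pts, file.path(dir, "points.csv"), row.names = FALSE)
  meta <- do.call(rbind, lapply(annotations, function(a) {
    data.frame(image_id = a$image_id, eye_id = a$eye_id,
               laterality = a$laterality %||% NA_character_,
               fov_side = a$fov_side,
               zone = a$zone %||% NA_character_,
               stage = a$stage %||% NA_integer_,
               vss = a$vss %||% NA_real_)
  }))
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  fov <- do.call(rbind, lapply(annotations, function(a) {
    if (is.null(a$fovea)) return(NULL)
    data.frame(image_id = a$image_id, x = a$fovea[[1L]], y = a$fovea[[2L]])
  }))
  if (!is.null(fov))
    utils::write.csv(fov, file.path(dir, "fovea.csv"), row.names = FALSE)
  if (write_masks) {
    mdir <- file.path(dir, "masks")
    dir.create(mdir, showWarnings = FALSE)
    for (a in annotations) {
      write_disc_mask(file.path(mdir, paste0(a$image_id, ".png")),
                      size = a$image_size %||% c(width = 1600, height = 1200),
                      center = a$disc$centroid,
                      radius = a$disc_radius %||% 60)
    }
  }
  invisible(dir)
}

write_disc_mask <- function(path, size, center, radius) {
  w <- as.integer(size[["width"]]); h <- as.integer(size[["height"]])
  x <- matrix(0:(w - 1L), h, w, byrow = TRUE)
  y <- matrix(0:(h - 1L), h, w)
  m <- ((x - center[[1L]])^2 + (y - center[[2L]])^2 <= radius^2) * 1
  png::writePNG(m, path)
  invisible(path)
}

#' Read an annotation set from disk
#'
#' Joins the points, metadata, optional fovea table and disc localizations
#' into validated `erv_annotation` objects. The disc may come either from
#' `disc_x`/`disc_y` columns in the metadata (source "provided") or from a
#' PNG mask in `masks_dir` (its centroid is computed). Images without any
#' disc localization are excluded with a logged reason, mirroring the
#' requirement that the optic disc be visible; the exclusions are reported
#' in the attached accounting.
#'
#' @param dir directory holding `points.csv`, `metadata.csv` and optionally
#'   `fovea.csv` and `masks/`; alternatively pass the individual paths.
#' @param points_csv,metadata_csv,fovea_csv,masks_dir explicit paths
#'   overriding the defaults under `dir`.
#' @return list of `erv_annotation`, with an attribute `exclusions`
#'   (tibble image_id, reason) and `counts` (images_in, images_used,
#'   images_excluded).
#' @export
read_annotations <- function(dir = NULL,
                             points_csv = file.path(dir, "points.csv"),
                             metadata_csv = file.path(dir, "metadata.csv"),
                             fovea_csv = file.path(dir, "fovea.csv"),
                             masks_dir = file.path(dir, "masks")) {
  pts <- utils::read.csv(points_csv, stringsAsFactors = FALSE)
  need <- c("image_id", "x", "y")
  if (!all(need %in% names(pts)))
    stop("read_annotations(): points CSV must have columns image_id, x, y")
  for (cc in c("x", "y")) {
    v <- suppressWarnings(as.numeric(pts[[cc]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L] + 1L       # +1: header line
      stop(sprintf("read_annotations(): non-numeric %s coordinate at %s line %d",
                   cc, points_csv, bad))
    }
    pts[[cc]] <- v
  }
  meta <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
  if (!all(c("image_id", "eye_id", "fov_side") %in% names(meta)))
    stop("read_annotations(): metadata CSV must have image_id, eye_id, fov_side")
  fov <- if (!is.null(fovea_csv) && file.exists(fovea_csv))
    utils::read.csv(fovea_csv, stringsAsFactors = FALSE) else NULL

  ids <- unique(pts$image_id)
  missing_meta <- setdiff(ids, meta$image_id)
  if (length(missing_meta))
    stop(sprintf("read_annotations(): no metadata for image(s) %s",
                 paste(utils::head(missing_meta, 5L), collapse = ", ")))

  anns <- list()
  excl <- list()
  for (id in ids) {
    m <- meta[meta$image_id == id, , drop = FALSE][1L, ]
    p <- as.matrix(pts[pts$image_id == id, c("x", "y")])
    disc <- NULL
    if (all(c("disc_x", "disc_y") %in% names(m)) &&
        is.finite(m$disc_x) && is.finite(m$disc_y)) {
      disc <- disc_from_centroid(c(m$disc_x, m$disc_y))
    } else if (!is.null(masks_dir)) {
      mask_path <- file.path(masks_dir, paste0(id, ".png"))
      if (file.exists(mask_path)) {
        img <- png::readPNG(mask_path)
        if (length(dim(img)) == 3L) img <- img[, , 1L]
        disc <- disc_centroid(img)
      }
    }
    if (is.null(disc)) {
      excl[[length(excl) + 1L]] <-
        tibble::tibble(image_id = id, reason = "no disc localization")
      message("read_annotations(): excluding ", id, " (no disc localization)")
      next
    }
    fv <- if (!is.null(fov) && id %in% fov$image_id) {
      r <- fov[fov$image_id == id, ][1L, ]
      c(x = r$x, y = r$y)
    } else NULL
    anns[[length(anns) + 1L]] <- structure(list(
      image_id = as.character(id), eye_id = as.character(m$eye_id),
      fov_side = match.arg(m$fov_side, c("nasal", "temporal")),
      points = as_xy_matrix(p),
      disc = disc,
      fovea = fv,
      zone = if ("zone" %in% names(m) && !is.na(m$zone)) as.character(m$zone) else NULL,
      stage = if ("stage" %in% names(m) && !is.na(m$stage)) as.integer(m$stage) else NULL,
      vss = if ("vss" %in% names(m) && !is.na(m$vss)) as.numeric(m$vss) else NULL,
      laterality = if ("laterality" %in% names(m) && !is.na(m$laterality))
        as.character(m$laterality) else NULL
    ), class = "erv_annotation")
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    tibble::tibble(image_id = character(), reason = character())
  attr(anns, "exclusions") <- exclusions
  attr(anns, "counts") <- c(images_in = length(ids),
                            images_used = length(anns),
                            images_excluded = nrow(exclusions))
  anns
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file with fields `input_dir` (or explicit paths),
#'   `out_dir`, and optional `notch_depth_threshold`, `notch_window_frac`,
#'   `bin_width`, `seed`.
#' @return a validated config list of class `erv_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

as_run_config <- function(cfg) {
  defaults <- list(notch_depth_threshold = 20, notch_window_frac = 1 / 8,
                   bin_width = 75, seed = 1L)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$input_dir) || is.null(cfg$out_dir))
    stop("run config needs input_dir and out_dir")
  if (cfg$bin_width <= 0) stop("run config: bin_width must be > 0")
  class(cfg) <- "erv_run_config"
  cfg
}

#' Run the full measurement and statistics pipeline from files
#'
#' Reads an annotation set, measures every image, aggregates per eye,
#' computes the cohort statistics (zone summary, asymmetry summary,
#' stage-stratified VSS comparisons), and writes `images.csv`, `eyes.csv`,
#' `stats.json` and a `manifest.json` with the parameter values and the
#' inclusion accounting (`images_in = images_used + images_excluded`). The
#' run is deterministic given the configuration.
#'
#' @param config an `erv_run_config` (see [read_run_config()]) or a list
#'   with the same fields.
#' @return list with `images` (per-image tibble), `eyes` (per-eye tibble),
#'   `stats` (list) and `manifest` (list), invisibly; all are also written
#'   under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "erv_run_config")) config else as_run_config(config)
  set.seed(cfg$seed)
  anns <- read_annotations(cfg$input_dir)
  counts <- attr(anns, "counts")
  images <- measure_annotations(anns,
                                notch_depth_threshold = cfg$notch_depth_threshold,
                                notch_window_frac = cfg$notch_window_frac)
  eyes <- aggregate_eyes(images)
  stats_out <- list()
  if (any(!is.na(eyes$zone)) && length(unique(stats::na.omit(eyes$zone))) > 1L)
    stats_out$zone <- zone_summary(eyes)
  if (any(is.finite(eyes$min_nerv) & is.finite(eyes$min_terv)))
    stats_out$asymmetry <- asymmetry_summary(eyes)
  if (any(!is.na(eyes$vss)) && any(!is.na(eyes$stage)))
    stats_out$vss_by_stage <- suppressWarnings(
      kruskal_wallis_by_bin(eyes, bin_width = cfg$bin_width))

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(images, file.path(cfg$out_dir, "images.csv"), row.names = FALSE)
  utils::write.csv(eyes, file.path(cfg$out_dir, "eyes.csv"), row.names = FALSE)
  jsonlite::write_json(stats_out, file.path(cfg$out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  manifest <- list(
    parameters = cfg[c("notch_depth_threshold", "notch_window_frac",
                       "bin_width", "seed")],
    counts = as.list(counts),
    n_eyes = nrow(eyes),
    exclusions = attr(anns, "exclusions")
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(list(images = images, eyes = eyes, stats = stats_out,
                 manifest = manifest))
}
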