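#' Order clicked ridge points by greedy nearest-neighbour traversal
#'
#' Graders click points along the visible stage line in any order; before a
#' path can be fit through them they must be put into along-the-ridge order.
#' The ordering rule is a greedy open tour: starting from a point, always
#' connect to the nearest unvisited point. The traversal is run from every
#' candidate start point and the ordering with the minimal total Euclidean
#' path length is returned, which removes the dependence on an arbitrary
#' starting click. Ties in total length are broken in favour of the lowest
#' starting index; ties in the nearest-neighbour step in favour of the
#' lowest point index.
#'
#' @param points numeric matrix (or data frame) with two columns, x and y,
#'   in pixel coordinates. Duplicate points are permitted (zero-length hops).
#' @return a list with
#'   \describe{
#'     \item{points}{the input points in traversal order (matrix),}
#'     \item{order}{the permutation such that `points[order, ]` is the
#'       returned ordering,}
#'     \item{length}{total Euclidean length of the open path.}
#'   }
#' @examples
#' pts <- cbind(x = c(0, 5, 2, 9), y = c(0, 0, 0, 0))
#' order_points_greedy(pts)$order  # 1 3 2 4
#' @export
order_points_greedy <- function(points) {
  points <- as_xy_matrix(points, "points")
  n <- nrow(points)
  if (n == 0L) stop("order_points_greedy(): no points supplied")
  if (anyNA(points) || any(!is.finite(points)))
    stop("order_points_greedy(): points contain NA or non-finite coordinates")
  if (n == 1L)
    return(list(points = points, order = 1L, length = 0))

  d <- as.matrix(stats::dist(points))
  best_order <- NULL
  best_len <- Inf
  for (start in seq_len(n)) {
    ord <- integer(n)
    ord[1L] <- start
    visited <- logical(n)
    visited[start] <- TRUE
    len <- 0
    cur <- start
    complete <- TRUE
    for (k in 2L:n) {
      row <- d[cur, ]
      row[visited] <- Inf
      nxt <- which.min(row)           # lowest index on ties
      len <- len + row[nxt]
      if (len >= best_len) {          # cannot beat the incumbent; ">=" keeps lowest start on ties
        complete <- FALSE
        break
      }
      ord[k] <- nxt
      visited[nxt] <- TRUE
      cur <- nxt
    }
    if (complete && len < best_len) {
      best_len <- len
      best_order <- ord
    }
  }
  list(points = points[best_order, , drop = FALSE],
       order = best_order,
       length = unname(best_len))
}

#' Fit a smooth interpolating spline path through ordered ridge points
#'
#' Fits a parametric cubic spline (chordal parameterisation, interpolating,
#' i.e. smoothing factor zero) through the ordered points and resamples it
#' at approximately 1-pixel arc-length spacing, so that the subsequent
#' radial distance profile is evaluated at every "pixel" of the ridge, not
#' only at the clicked points. With two points the path degrades to the
#' straight segment, with three to the natural-spline quadratic-like curve.
#'
#' @param ordered_points numeric matrix with columns x, y, already in
#'   along-ridge order (see [order_points_greedy()]).
#' @param image_id optional identifier used in error messages.
#' @return an object of class `erv_ridge_path`: a list with `vertices`
#'   (matrix, ~1 px spacing), `length` (total arc length, px), `order`
#'   (attached by callers), and `spline` (the chordal parameter values of
#'   the input points).
#' @examples
#' th <- seq(0, pi / 2, length.out = 20)
#' path <- fit_smooth_path(cbind(300 * cos(th), 300 * sin(th)))
#' range(sqrt(rowSums(path$vertices^2)))  # ~300
#' @export
fit_smooth_path <- function(ordered_points, image_id = NULL) {
  pts <- as_xy_matrix(ordered_points, "ordered_points")
  id <- if (is.null(image_id)) "" else paste0(" [image ", image_id, "]")
  if (nrow(pts) < 2L)
    stop("fit_smooth_path(): need at least 2 points", id)

  # drop zero-length hops (duplicate consecutive clicks)
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  keep <- c(TRUE, seg > .Machine$double.eps^0.5)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 2L)
    stop("fit_smooth_path(): points are all coincident", id)

  tt <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))  # chordal parameter
  n <- nrow(pts)
  if (n == 2L) {
    fx <- stats::approxfun(tt, pts[, 1L])
    fy <- stats::approxfun(tt, pts[, 2L])
  } else {
    fx <- stats::splinefun(tt, pts[, 1L], method = "natural")
    fy <- stats::splinefun(tt, pts[, 2L], method = "natural")
  }

  # dense evaluation, then arc-length reparameterisation at ~1 px spacing
  n_dense <- max(64L, 4L * ceiling(tt[n]))
  td <- seq(0, tt[n], length.out = n_dense)
  xd <- fx(td); yd <- fy(td)
  sd_ <- c(0, cumsum(sqrt(diff(xd)^2 + diff(yd)^2)))
  L <- sd_[n_dense]
  n_out <- max(2L, round(L) + 1L)
  s_tgt <- seq(0, L, length.out = n_out)
  t_tgt <- stats::approx(sd_, td, xout = s_tgt, ties = "ordered")$y
  vertices <- cbind(x = fx(t_tgt), y = fy(t_tgt))

  structure(list(vertices = vertices, length = L, knots = tt),
            class = "erv_ridge_path")
}

#' @export
print.erv_ridge_path <- function(x, ...) {
  cat(sprintf("<erv_ridge_path> %d vertices, arc length %.1f px\n",
              nrow(x$vertices), x$length))
  invisible(x)
}

#' Optic-disc centroid from a binary mask
#'
#' The optic-disc centre is defined as the centroid of the disc
#' segmentation: the arithmetic mean of the foreground pixel-centre
#' coordinates. If the mask contains several connected components the
#' largest one is used (4-connectivity).
#'
#' @param mask a matrix (rows = y, columns = x); any value greater than zero
#'   is foreground. Row/column indices are converted to 0-based pixel-centre
#'   coordinates (x = column, y = row).
#' @return an object of class `erv_disc`: list with `centroid` (named x, y),
#'   `area` (foreground pixel count of the used component) and `source`
#'   ("mask").
#' @examples
#' m <- matrix(0, 30, 50); m[11:21, 31:41] <- 1
#' disc_centroid(m)$centroid  # x = 35, y = 15
#' @export
disc_centroid <- function(mask) {
  if (!is.matrix(mask)) mask <- as.matrix(mask)
  fg <- mask > 0
  if (!any(fg)) stop("disc_centroid(): mask has no foreground pixels")
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  idx <- which(lab == keep, arr.ind = TRUE)
  # 0-based pixel-centre coordinates: x = column - 1, y = row - 1
  centroid <- c(x = mean(idx[, 2L]) - 1, y = mean(idx[, 1L]) - 1)
  structure(list(centroid = centroid, area = nrow(idx), source = "mask"),
            class = "erv_disc")
}

#' Wrap a known disc-centre coordinate as a disc localization
#'
#' @param centroid numeric length-2, (x, y) pixel coordinates.
#' @param area optional disc area in px^2 (NA if unknown).
#' @return an `erv_disc` object with `source = "provided"`.
#' @export
disc_from_centroid <- function(centroid, area = NA_real_) {
  stopifnot(length(centroid) == 2L, all(is.finite(centroid)))
  structure(list(centroid = c(x = centroid[[1L]], y = centroid[[2L]]),
                 area = area, source = "provided"),
            class = "erv_disc")
}

#' @export
print.erv_disc <- function(x, ...) {
  cat(sprintf("<erv_disc> centroid (%.1f, %.1f), area %s px^2 [%s]\n",
              x$centroid[["x"]], x$centroid[["y"]],
              format(x$area), x$source))
  invisible(x)
}

# 4-connected component labelling by iterative flood fill (masks are small)
label_components <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  todo <- which(fg & lab == 0L)
  while (length(todo)) {
    nxt <- nxt + 1L
    stack <- todo[1L]
    lab[stack] <- nxt
    while (length(stack)) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((i - 1L) %% nr) + 1L
      cc <- ((i - 1L) %/% nr) + 1L
      for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- r + off[1L]; c2 <- cc + off[2L]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc &&
            fg[r2, c2] && lab[r2, c2] == 0L) {
          j <- (c2 - 1L) * nr + r2
          lab[j] <- nxt
          stack <- c(stack, j)
        }
      }
    }
    todo <- which(fg & lab == 0L)
  }
  lab
}

# coerce (x, y) input to a 2-column numeric matrix
as_xy_matrix <- function(p, what = "points") {
  if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y")])
  if (is.null(dim(p)) && length(p) == 2L) p <- matrix(p, 1L, 2L)
  if (!is.matrix(p) || ncol(p) != 2L)
    stop(sprintf("%s must be an n x 2 matrix of (x, y) coordinates", what))
  storage.mode(p) <- "double"
  dimnames(p) <- list(NULL, c("x", "y"))
  p
}
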