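# ROI geometry and rasterization.
#
# Coordinate convention (used everywhere in the package): 0-based pixel
# coordinates, x = column, y = row, with y increasing downward.  The pixel
# stored at matrix element [i, j] (1-based R indexing) has its center at
# (x, y) = (j - 1, i - 1).  Anterior-view display convention: the patient's
# left side (the heart) appears on the image right.

#' Rectangular ROI
#'
#' Axis-aligned rectangle covering the half-open pixel index ranges
#' `[x0, x0 + w)` x `[y0, y0 + h)`.
#'
#' @param x0,y0 Top-left pixel indices (0-based integers).
#' @param w,h Width and height in pixels (positive integers).
#' @return An object of class `rect_roi`.
#' @export
rect_roi <- function(x0, y0, w, h) {
  stopifnot(
    is.numeric(x0), is.numeric(y0), length(x0) == 1L, length(y0) == 1L,
    x0 == floor(x0), y0 == floor(y0)
  )
  if (!is_count_scalar(w) || !is_count_scalar(h)) {
    stop_mibg("mibg_invalid_roi", "rect_roi: w and h must be positive integers")
  }
  structure(
    list(x0 = as.integer(x0), y0 = as.integer(y0),
         w = as.integer(w), h = as.integer(h)),
    class = c("rect_roi", "mibg_roi")
  )
}

#' Oval (elliptical) ROI
#'
#' @param cx,cy Center in pixel coordinates (may be fractional).
#' @param rx,ry Semi-axes in pixels (positive).
#' @return An object of class `oval_roi`.
#' @export
oval_roi <- function(cx, cy, rx, ry) {
  stopifnot(is.numeric(cx), is.numeric(cy), is.numeric(rx), is.numeric(ry))
  if (!(rx > 0 && ry > 0)) {
    stop_mibg("mibg_invalid_roi", "oval_roi: semi-axes must be positive")
  }
  structure(
    list(cx = as.numeric(cx), cy = as.numeric(cy),
         rx = as.numeric(rx), ry = as.numeric(ry)),
    class = c("oval_roi", "mibg_roi")
  )
}

#' Polygonal ROI
#'
#' A simple (non-self-intersecting) polygon given by its ordered vertices in
#' pixel coordinates.  Pixel membership uses the even-odd rule on pixel
#' centers; centers exactly on the boundary are included.
#'
#' @param x,y Numeric vectors of vertex coordinates (length >= 3).
#' @return An object of class `polygon_roi`.
#' @export
polygon_roi <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y) || length(x) < 3L) {
    stop_mibg("mibg_invalid_roi",
              "polygon_roi: need at least 3 vertices with matching x/y")
  }
  if (anyNA(x) || anyNA(y)) {
    stop_mibg("mibg_invalid_roi", "polygon_roi: vertices must be finite")
  }
  if (!polygon_is_simple(x, y)) {
    stop_mibg("mibg_invalid_roi", "polygon_roi: polygon is self-intersecting")
  }
  structure(
    list(x = as.numeric(x), y = as.numeric(y)),
    class = c("polygon_roi", "mibg_roi")
  )
}

#' Anatomical landmark square
#'
#' The bounding square used by the semi-automatic fixed-size ROI method:
#' top = lung apexes, bottom = upper cardiac border, left/right = medial
#' contours of the two lung fields (continuous pixel coordinates).
#'
#' @param top,bottom Row coordinates (top < bottom).
#' @param left,right Column coordinates (left < right).
#' @return An object of class `landmark_square`.
#' @export
landmark_square <- function(top, bottom, left, right) {
  stopifnot(is.numeric(top), is.numeric(bottom),
            is.numeric(left), is.numeric(right))
  if (!(top < bottom && left < right)) {
    stop_mibg("mibg_invalid_roi",
              "landmark_square: need top < bottom and left < right")
  }
  structure(
    list(top = as.numeric(top), bottom = as.numeric(bottom),
         left = as.numeric(left), right = as.numeric(right)),
    class = "landmark_square"
  )
}

# segment intersection test used by the simplicity check; proper crossings
# only (shared endpoints of adjacent edges are fine)
polygon_is_simple <- function(x, y) {
  n <- length(x)
  if (n == 3L) return(TRUE)
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (share a vertex)
      if (j == i + 1L || (i == 1L && j == n)) next
      d1 <- orient(x[i], y[i], x2[i], y2[i], x[j], y[j])
      d2 <- orient(x[i], y[i], x2[i], y2[i], x2[j], y2[j])
      d3 <- orient(x[j], y[j], x2[j], y2[j], x[i], y[i])
      d4 <- orient(x[j], y[j], x2[j], y2[j], x2[i], y2[i])
      if (d1 * d2 < 0 && d3 * d4 < 0) return(FALSE)
    }
  }
  TRUE
}

#' Rasterize an ROI to a pixel mask
#'
#' @param roi A `rect_roi`, `oval_roi` or `polygon_roi`.
#' @param dim Image dimensions `c(nrow, ncol)` (or a matrix, whose dimensions
#'   are used).
#' @param allow_empty If `TRUE`, return an all-`FALSE` mask instead of
#'   signalling an error when the ROI is entirely outside the image.
#' @return A logical matrix of the requested dimensions.
#' @details Rectangles cover half-open index ranges; ovals and polygons use
#'   pixel-center inclusion with boundary centers included.  Pixels falling
#'   outside the image are dropped; an ROI whose mask is empty after clipping
#'   raises an `mibg_empty_roi` error unless `allow_empty` is set.
#' @export
rasterize <- function(roi, dim, allow_empty = FALSE) {
  UseMethod("rasterize")
}

roi_dim <- function(dim) {
  if (is.matrix(dim)) dim <- base::dim(dim)
  if (inherits(dim, "planar_image")) dim <- base::dim(dim$counts)
  stopifnot(length(dim) == 2L, all(dim >= 1L))
  as.integer(dim)
}

finish_mask <- function(mask, allow_empty, what) {
  if (!any(mask) && !allow_empty) {
    stop_mibg("mibg_empty_roi", "%s rasterizes to an empty mask", what)
  }
  mask
}

#' @export
rasterize.rect_roi <- function(roi, dim, allow_empty = FALSE) {
  d <- roi_dim(dim)
  mask <- matrix(FALSE, d[1L], d[2L])
  rows <- intersect(seq_len(d[1L]), (roi$y0 + 1L):(roi$y0 + roi$h))
  cols <- intersect(seq_len(d[2L]), (roi$x0 + 1L):(roi$x0 + roi$w))
  if (length(rows) && length(cols)) mask[rows, cols] <- TRUE
  finish_mask(mask, allow_empty, "rect_roi")
}

#' @export
rasterize.oval_roi <- function(roi, dim, allow_empty = FALSE) {
  d <- roi_dim(dim)
  mask <- matrix(FALSE, d[1L], d[2L])
  rows <- seq_len(d[1L])
  cols <- seq_len(d[2L])
  rows <- rows[abs((rows - 1) - roi$cy) <= roi$ry + 1]
  cols <- cols[abs((cols - 1) - roi$cx) <= roi$rx + 1]
  if (length(rows) && length(cols)) {
    xs <- (cols - 1 - roi$cx) / roi$rx
    ys <- (rows - 1 - roi$cy) / roi$ry
    sub <- outer(ys^2, xs^2, `+`) <= 1 + 1e-12
    mask[rows, cols] <- sub
  }
  finish_mask(mask, allow_empty, "oval_roi")
}

#' @export
rasterize.polygon_roi <- function(roi, dim, allow_empty = FALSE) {
  d <- roi_dim(dim)
  mask <- matrix(FALSE, d[1L], d[2L])
  rows <- seq_len(d[1L])
  cols <- seq_len(d[2L])
  rows <- rows[(rows - 1) >= min(roi$y) - 1 & (rows - 1) <= max(roi$y) + 1]
  cols <- cols[(cols - 1) >= min(roi$x) - 1 & (cols - 1) <= max(roi$x) + 1]
  if (length(rows) && length(cols)) {
    sub <- polygon_scanline(roi$x, roi$y, rows - 1, cols - 1)
    if (is.null(sub)) { # degenerate row geometry: exact per-pixel fallback
      px <- rep(cols - 1, each = length(rows))
      py <- rep(rows - 1, times = length(cols))
      inside <- point_in_polygon(px, py, roi$x, roi$y)
      sub <- matrix(inside, length(rows), length(cols))
    }
    mask[rows, cols] <- sub
  }
  finish_mask(mask, allow_empty, "polygon_roi")
}

# even-odd scanline fill over pixel-center rows; boundary-inclusive for
# non-horizontal edges.  Returns NULL when a row has an odd crossing count
# or a pixel-center row coincides with a horizontal edge (the caller then
# falls back to the exact per-pixel test).
polygon_scanline <- function(vx, vy, ys, xs) {
  n <- length(vx)
  xj <- c(vx[n], vx[-n]); yj <- c(vy[n], vy[-n])
  if (any(vy == yj & (vy %in% ys))) return(NULL)
  ny <- length(ys); nx <- length(xs)
  out <- matrix(FALSE, ny, nx)
  YI <- matrix(vy, ny, n, byrow = TRUE)
  YJ <- matrix(yj, ny, n, byrow = TRUE)
  YS <- matrix(ys, ny, n)
  crosses <- (YI > YS) != (YJ > YS)
  XINT <- matrix(vx, ny, n, byrow = TRUE) +
    (YS - YI) * matrix(xj - vx, ny, n, byrow = TRUE) / (YJ - YI)
  x0 <- xs[1L]
  for (r in seq_len(ny)) {
    xi <- XINT[r, crosses[r, ]]
    if (!length(xi)) next
    if (length(xi) %% 2L) return(NULL)
    xi <- sort(xi)
    for (p in seq(1L, length(xi), by = 2L)) {
      a <- max(ceiling(xi[p] - x0) + 1L, 1L)
      b <- min(floor(xi[p + 1L] - x0) + 1L, nx)
      if (a <= b) out[r, a:b] <- TRUE
    }
  }
  out
}

# even-odd rule, boundary inclusive; vectorized over points x edges
point_in_polygon <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  np <- length(px)
  xi <- rep(vx, each = np); yi <- rep(vy, each = np)
  xj <- rep(c(vx[n], vx[-n]), each = np)
  yj <- rep(c(vy[n], vy[-n]), each = np)
  PX <- rep.int(px, n); PY <- rep.int(py, n)
  dx <- xj - xi; dy <- yj - yi

  crosses <- (yi > PY) != (yj > PY)
  xint <- xi + (PY - yi) * dx / (yj - yi) # NaN where dy == 0, never crossing
  flips <- crosses & (PX < xint)
  flips[is.na(flips)] <- FALSE
  inside <- (rowSums(matrix(flips, np, n)) %% 2L) == 1L

  # boundary test: point within eps of any edge
  len2 <- dx * dx + dy * dy
  tt <- ((PX - xi) * dx + (PY - yi) * dy) / ifelse(len2 > 0, len2, 1)
  tt <- pmin(1, pmax(0, tt))
  d2 <- (PX - (xi + tt * dx))^2 + (PY - (yi + tt * dy))^2
  onedge <- rowSums(matrix(d2 <= eps * eps, np, n)) > 0L

  inside | onedge
}

# cheap placement-validity check: bounding-box overlap first, full
# rasterization only when the ROI straddles the image border
roi_overlaps_image <- function(roi, dim) {
  d <- roi_dim(dim)
  bb <- if (inherits(roi, "rect_roi")) {
    c(roi$x0, roi$x0 + roi$w - 1, roi$y0, roi$y0 + roi$h - 1)
  } else if (inherits(roi, "oval_roi")) {
    c(roi$cx - roi$rx, roi$cx + roi$rx, roi$cy - roi$ry, roi$cy + roi$ry)
  } else {
    c(min(roi$x), max(roi$x), min(roi$y), max(roi$y))
  }
  if (bb[2] < 0 || bb[1] > d[2] - 1 || bb[4] < 0 || bb[3] > d[1] - 1) {
    return(FALSE)
  }
  fully_inside <- bb[1] >= 0 && bb[2] <= d[2] - 1 &&
    bb[3] >= 0 && bb[4] <= d[1] - 1
  if (fully_inside) return(TRUE)
  any(rasterize(roi, d, allow_empty = TRUE))
}

#' Mean counts per pixel inside an ROI
#'
#' @param image A `planar_image` or a numeric matrix.
#' @param roi An ROI object.
#' @return The arithmetic mean of the counts over the rasterized mask.
#' @export
mean_counts <- function(image, roi) {
  m <- if (inherits(image, "planar_image")) image$counts else image
  stopifnot(is.matrix(m))
  mask <- rasterize(roi, dim(m))
  mean(m[mask])
}

#' Place the fixed-size semi-automatic ROI pair from a landmark square
#'
#' Places a fixed-size rectangular mediastinal ROI at the midpoint of the
#' upper half of the anatomical landmark square and a fixed-size oval cardiac
#' ROI centered at the centroid of the lower-right quadrant (the oval may
#' extend beyond the square, over the myocardium and left-ventricular
#' cavity).
#'
#' @param square A [landmark_square()].
#' @param config List of options: `med_size` (width, height of the mediastinal
#'   rectangle; default `c(13, 20)`), `oval_size` (full axes of the cardiac
#'   oval bounding box; default `c(60, 70)`), `flip` (use the lower-left
#'   quadrant for the mirrored display convention; default `FALSE`).
#' @return List with elements `mediastinal` (a `rect_roi`) and `cardiac`
#'   (an `oval_roi`).
#' @export
place_semiautomatic_rois <- function(square, config = list()) {
  stopifnot(inherits(square, "landmark_square"))
  med_size <- config$med_size %||% c(13, 20)
  oval_size <- config$oval_size %||% c(60, 70)
  flip <- isTRUE(config$flip)
  w <- square$right - square$left
  h <- square$bottom - square$top
  if (w < med_size[1L] || h < med_size[2L]) {
    stop_mibg("mibg_placement",
              "landmark square (%.1f x %.1f) smaller than the mediastinal ROI (%d x %d)",
              w, h, med_size[1L], med_size[2L])
  }
  med_cx <- (square$left + square$right) / 2
  med_cy <- square$top + h / 4
  med <- rect_roi(
    x0 = floor(med_cx - med_size[1L] / 2 + 0.5),
    y0 = floor(med_cy - med_size[2L] / 2 + 0.5),
    w = med_size[1L], h = med_size[2L]
  )
  frac <- if (flip) 0.25 else 0.75
  card <- oval_roi(
    cx = square$left + frac * w,
    cy = square$top + 0.75 * h,
    rx = oval_size[1L] / 2, ry = oval_size[2L] / 2
  )
  list(mediastinal = med, cardiac = card,
       med_center = c(med_cx, med_cy),
       cardiac_center = c(card$cx, card$cy))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect the anatomical landmark square on a planar image
#'
#' Automates the operator's identification of the lung apexes, the medial
#' lung contours and the upper cardiac border.  The image is smoothed, lung
#' fields are segmented as the two largest lateral components below
#' `lung_fraction` times the image median, and the cardiac blob as the
#' largest component above `heart_fraction` times the smoothed maximum.
#'
#' @param image A `planar_image` or numeric matrix.
#' @param config List of options: `lung_fraction` (default 0.75),
#'   `heart_fraction` (default 0.75), `smooth` (box filter size, odd
#'   integer, default 3), `min_component` (minimum component size in pixels,
#'   default 30).
#' @return A [landmark_square()].
#' @export
detect_landmark_square <- function(image, config = list()) {
  m <- if (inherits(image, "planar_image")) image$counts else image
  stopifnot(is.matrix(m))
  lung_fraction <- config$lung_fraction %||% 0.75
  heart_fraction <- config$heart_fraction %||% 0.75
  k <- config$smooth %||% 3L
  min_comp <- config$min_component %||% 30L

  sm <- box_smooth(m, k)
  med <- stats::median(sm)
  lungmask <- sm < lung_fraction * med
  lab <- label_components(lungmask)
  sizes <- attr(lab, "sizes")
  keep <- which(sizes >= min_comp)
  if (length(keep) < 2L) {
    stop_mibg("mibg_landmark", "fewer than two candidate lung fields found")
  }
  nc <- ncol(m)
  ctr_x <- vapply(keep, function(l) {
    mean((which(lab == l, arr.ind = TRUE)[, 2L]) - 1)
  }, numeric(1))
  left_cands <- keep[ctr_x < (nc - 1) / 2]
  right_cands <- keep[ctr_x >= (nc - 1) / 2]
  if (!length(left_cands) || !length(right_cands)) {
    stop_mibg("mibg_landmark", "could not find one lung field on each side")
  }
  left_lab <- left_cands[which.max(sizes[left_cands])]
  right_lab <- right_cands[which.max(sizes[right_cands])]

  mx <- max(sm)
  heartmask <- sm > heart_fraction * mx
  hlab <- label_components(heartmask)
  if (!length(attr(hlab, "sizes")) || max(attr(hlab, "sizes")) < min_comp) {
    stop_mibg("mibg_landmark", "no cardiac blob found")
  }
  heart_px <- which(hlab == 1L, arr.ind = TRUE)
  bottom <- min(heart_px[, 1L]) - 1 # y of upper cardiac border

  lpx <- which(lab == left_lab, arr.ind = TRUE)
  rpx <- which(lab == right_lab, arr.ind = TRUE)
  top <- min(lpx[, 1L], rpx[, 1L]) - 1
  if (!(top < bottom)) {
    stop_mibg("mibg_landmark", "cardiac blob lies above the lung apexes")
  }
  # medial contours: innermost lung columns over the upper thorax rows
  thorax <- c(top, bottom) + 1 # back to 1-based row indices
  lsel <- lpx[lpx[, 1L] >= thorax[1L] & lpx[, 1L] <= thorax[2L], , drop = FALSE]
  rsel <- rpx[rpx[, 1L] >= thorax[1L] & rpx[, 1L] <= thorax[2L], , drop = FALSE]
  if (!nrow(lsel) || !nrow(rsel)) {
    stop_mibg("mibg_landmark", "lung fields do not span the upper thorax")
  }
  left <- max(lsel[, 2L]) - 1
  right <- min(rsel[, 2L]) - 1
  if (!(left < right)) {
    stop_mibg("mibg_landmark", "medial lung contours overlap")
  }
  landmark_square(top = top, bottom = bottom, left = left, right = right)
}
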