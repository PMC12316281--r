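# Exposure-area geometry.
#
# With no polygon-boolean engine available, an exposure area is represented as
# a union of "capsules": line segments buffered by a radius (a zero-length
# segment is a disc). Service areas, anchor buffers and route corridors are
# all naturally capsule unions, which makes point-in-area queries exact
# (point-to-segment distance) and keeps containment of the home buffer in the
# activity space structural.

#' Construct an exposure area
#'
#' An exposure area is a union of capsules (segments buffered by a radius),
#' the representation used for home network buffers, anchor-point buffers and
#' route corridors. Most users obtain these from [network_buffer()],
#' [route_corridor()] or [household_activity_space()] rather than directly.
#'
#' @param segments numeric matrix (or data frame) with columns
#'   `x1, y1, x2, y2, r` in meters; zero rows give an empty area.
#' @param kind `"home_buffer"` or `"activity_space"`.
#' @return An object of class `exposure_area`.
#' @export
exposure_area <- function(segments = NULL, kind = c("home_buffer", "activity_space")) {
  kind <- match.arg(kind)
  if (is.null(segments)) {
    segments <- matrix(numeric(0), ncol = 5)
  }
  segments <- as.matrix(segments)
  if (ncol(segments) != 5) {
    abort("`segments` must have 5 columns (x1, y1, x2, y2, r).",
      class = "foodscape_geometry_error"
    )
  }
  colnames(segments) <- c("x1", "y1", "x2", "y2", "r")
  if (nrow(segments) > 0 && any(segments[, "r"] <= 0)) {
    abort("capsule radii must be > 0", class = "foodscape_geometry_error")
  }
  structure(
    list(segments = segments, kind = kind),
    class = "exposure_area"
  )
}

#' @export
print.exposure_area <- function(x, ...) {
  cat(
    "<exposure_area:", x$kind, "> ", nrow(x$segments), " capsules, ",
    format(round(area_m2(x))), " m^2\n",
    sep = ""
  )
  invisible(x)
}

is_empty_area <- function(area) nrow(area$segments) == 0

# Distance from points (px, py) to the segment (x1,y1)-(x2,y2); vectorised
# over points.
dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  if (L2 < 1e-24) {
    return(sqrt((px - x1)^2 + (py - y1)^2))
  }
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Test points for inclusion in an exposure area
#'
#' Points on the boundary count as inside (closed-region convention), so an
#' outlet exactly on the buffer edge is part of the exposure.
#'
#' @param area an [exposure_area()].
#' @param x,y point coordinates in meters (vectors of equal length).
#' @return Logical vector.
#' @export
point_in_area <- function(area, x, y) {
  stopifnot(inherits(area, "exposure_area"), length(x) == length(y))
  inside <- rep(FALSE, length(x))
  segs <- area$segments
  if (nrow(segs) == 0 || length(x) == 0) {
    return(inside)
  }
  for (i in seq_len(nrow(segs))) {
    todo <- which(!inside)
    if (length(todo) == 0) break
    # cheap bbox rejection before the exact distance test
    xmin <- min(segs[i, 1], segs[i, 3]) - segs[i, 5]
    xmax <- max(segs[i, 1], segs[i, 3]) + segs[i, 5]
    ymin <- min(segs[i, 2], segs[i, 4]) - segs[i, 5]
    ymax <- max(segs[i, 2], segs[i, 4]) + segs[i, 5]
    cand <- todo[x[todo] >= xmin & x[todo] <= xmax &
      y[todo] >= ymin & y[todo] <= ymax]
    if (length(cand) == 0) next
    d <- dist_point_segment(
      x[cand], y[cand],
      segs[i, 1], segs[i, 2], segs[i, 3], segs[i, 4]
    )
    inside[cand[d <= segs[i, 5] + 1e-9]] <- TRUE
  }
  inside
}

area_bbox <- function(area) {
  segs <- area$segments
  if (nrow(segs) == 0) {
    return(c(0, 0, 0, 0))
  }
  c(
    min(segs[, 1] - segs[, 5], segs[, 3] - segs[, 5]),
    min(segs[, 2] - segs[, 5], segs[, 4] - segs[, 5]),
    max(segs[, 1] + segs[, 5], segs[, 3] + segs[, 5]),
    max(segs[, 2] + segs[, 5], segs[, 4] + segs[, 5])
  )
}

#' Area of an exposure area in square meters
#'
#' A single capsule has the closed-form area `2 r L + pi r^2`. Unions are
#' integrated on a regular grid whose cells are anchored at multiples of the
#' resolution, so areas are monotone under geometric containment at a fixed
#' resolution.
#'
#' @param area an [exposure_area()].
#' @param grid_res_m grid resolution in meters; `NULL` picks
#'   `min(radius)/6`, coarsened if the bounding box would exceed ~4e6 cells.
#' @return Area in m^2.
#' @export
area_m2 <- function(area, grid_res_m = NULL) {
  stopifnot(inherits(area, "exposure_area"))
  segs <- unique(area$segments)
  n <- nrow(segs)
  if (n == 0) {
    return(0)
  }
  if (n == 1) {
    L <- sqrt((segs[1, 3] - segs[1, 1])^2 + (segs[1, 4] - segs[1, 2])^2)
    return(unname(2 * segs[1, 5] * L + pi * segs[1, 5]^2))
  }
  bb <- area_bbox(area)
  if (is.null(grid_res_m)) {
    grid_res_m <- min(segs[, 5]) / 6
    max_cells <- 4e6
    need <- (bb[3] - bb[1]) * (bb[4] - bb[2]) / grid_res_m^2
    if (need > max_cells) {
      grid_res_m <- sqrt((bb[3] - bb[1]) * (bb[4] - bb[2]) / max_cells)
    }
  }
  res <- grid_res_m
  # global alignment: cell centers at (k + 0.5) * res
  ix0 <- floor(bb[1] / res)
  ix1 <- ceiling(bb[3] / res)
  iy0 <- floor(bb[2] / res)
  iy1 <- ceiling(bb[4] / res)
  nx <- ix1 - ix0
  ny <- iy1 - iy0
  inside <- matrix(FALSE, nrow = nx, ncol = ny)
  for (i in seq_len(n)) {
    r <- segs[i, 5]
    jx0 <- max(1, floor((min(segs[i, 1], segs[i, 3]) - r) / res) - ix0)
    jx1 <- min(nx, ceiling((max(segs[i, 1], segs[i, 3]) + r) / res) - ix0)
    jy0 <- max(1, floor((min(segs[i, 2], segs[i, 4]) - r) / res) - iy0)
    jy1 <- min(ny, ceiling((max(segs[i, 2], segs[i, 4]) + r) / res) - iy0)
    if (jx1 < jx0 || jy1 < jy0) next
    xs <- (ix0 + (jx0:jx1) - 0.5) * res
    ys <- (iy0 + (jy0:jy1) - 0.5) * res
    px <- rep(xs, times = length(ys))
    py <- rep(ys, each = length(xs))
    d <- dist_point_segment(px, py, segs[i, 1], segs[i, 2], segs[i, 3], segs[i, 4])
    hit <- matrix(d <= r, nrow = length(xs))
    inside[jx0:jx1, jy0:jy1] <- inside[jx0:jx1, jy0:jy1] | hit
  }
  sum(inside) * res^2
}

#' Area of an exposure area in square kilometers
#'
#' @inheritParams area_m2
#' @return Area in km^2 (>= 0; 0 for an empty area).
#' @export
area_km2 <- function(area, grid_res_m = NULL) {
  area_m2(area, grid_res_m = grid_res_m) / 1e6
}

# Union of exposure areas: concatenate capsules.
union_areas <- function(areas, kind) {
  segs <- do.call(rbind, lapply(areas, function(a) a$segments))
  exposure_area(segs, kind = kind)
}

# Drop interior vertices of a polyline that are collinear with their
# neighbours (within tol radians of deviation), so straight multi-edge routes
# collapse to single segments and get exact closed-form buffer areas.
merge_collinear <- function(coords, tol = 1e-9) {
  if (nrow(coords) <= 2) {
    return(coords)
  }
  keep <- rep(TRUE, nrow(coords))
  for (i in 2:(nrow(coords) - 1)) {
    a <- coords[i, ] - coords[i - 1, ]
    b <- coords[i + 1, ] - coords[i, ]
    cross <- a[1] * b[2] - a[2] * b[1]
    dot <- a[1] * b[1] + a[2] * b[2]
    if (abs(cross) <= tol * max(1, abs(dot)) && dot >= 0) keep[i] <- FALSE
  }
  # iterate until stable (successive removals can expose new collinearity)
  out <- coords[keep, , drop = FALSE]
  if (nrow(out) < nrow(coords)) merge_collinear(out, tol) else out
}

# Discretise one capsule into a polygon ring (counter-clockwise, closed).
capsule_polygon <- function(x1, y1, x2, y2, r, n_arc = 24) {
  dx <- x2 - x1
  dy <- y2 - y1
  L <- sqrt(dx^2 + dy^2)
  if (L < 1e-12) {
    th <- seq(0, 2 * pi, length.out = 4 * n_arc + 1)
    return(cbind(x1 + r * cos(th), y1 + r * sin(th)))
  }
  ang <- atan2(dy, dx)
  th1 <- seq(ang + pi / 2, ang + 3 * pi / 2, length.out = n_arc + 1)
  th2 <- seq(ang - pi / 2, ang + pi / 2, length.out = n_arc + 1)
  rbind(
    cbind(x2 + r * cos(th2), y2 + r * sin(th2)),
    cbind(x1 + r * cos(th1), y1 + r * sin(th1)),
    cbind(x2 + r * cos(th2[1]), y2 + r * sin(th2[1]))
  )
}

#' Monte Carlo area check helper
#'
#' Rejection-sampling estimate of an exposure area's size, used as an
#' independent numeric cross-check of the grid integrator.
#'
#' @inheritParams area_m2
#' @param n number of uniform samples over the bounding box.
#' @return Estimated area in m^2.
#' @export
area_m2_mc <- function(area, n = 1e5) {
  if (is_empty_area(area)) {
    return(0)
  }
  bb <- area_bbox(area)
  px <- runif(n, bb[1], bb[3])
  py <- runif(n, bb[2], bb[4])
  mean(point_in_area(area, px, py)) * (bb[3] - bb[1]) * (bb[4] - bb[2])
}
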