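# Radial normalisation of droplet positions against the irregular root edge:
# recentring, polar angle, ray-polygon edge radius, relative distance pp and
# the nine-class binning.

#' Slice geometry: marked center plus closed edge polygon
#'
#' @param center numeric c(x, y), the manually marked center, 0-based px.
#' @param edge two-column matrix of ordered edge vertices (closed polygon,
#'   first vertex not repeated), e.g. from [extract_edge_contour()].
#' @param scale micrometres per pixel (> 0).
#' @return list of class `slice_geometry`.
#' @export
slice_geometry <- function(center, edge, scale = 1) {
  edge <- as.matrix(edge)
  if (ncol(edge) != 2 || nrow(edge) < 16)
    stop_oildrops("edge must be a 2-column matrix with >= 16 vertices", "geometry_error")
  if (!is.finite(scale) || scale <= 0)
    stop_oildrops("scale must be finite and positive", "geometry_error")
  center <- as.numeric(center)
  if (length(center) != 2 || !all(is.finite(center)))
    stop_oildrops("center must be a finite (x, y) pair", "geometry_error")
  if (!point_in_polygon(center[1], center[2], edge))
    stop_oildrops("center is not strictly inside the edge polygon", "geometry_error")
  structure(list(center = c(x = center[1], y = center[2]), edge = edge, scale = scale),
            class = "slice_geometry")
}

#' @export
print.slice_geometry <- function(x, ...) {
  cat("Slice geometry: center (", x$center[1], ",", x$center[2], "),",
      nrow(x$edge), "edge vertices, scale", x$scale, "um/px\n")
  invisible(x)
}

# even-odd point-in-polygon for a single point
point_in_polygon <- function(px, py, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  crosses <- ((y > py) != (yn > py)) &
    (px < x + (py - y) * (xn - x) / (yn - y))
  sum(crosses, na.rm = TRUE) %% 2 == 1
}

#' Recentre coordinates on the marked slice center
#'
#' `x_mod = x_i - x_C`, `y_mod = y_i - y_C` (componentwise, exact).
#'
#' @param points two-column matrix or c(x, y) of droplet/edge coordinates.
#' @param center c(x, y) of the marked center.
#' @return same shape as `points`, recentred.
#' @export
recenter <- function(points, center) {
  if (is.null(dim(points))) return(c(points[1] - center[1], points[2] - center[2]))
  cbind(points[, 1] - center[1], points[, 2] - center[2])
}

#' Radius from recentred coordinates
#'
#' Euclidean norm `r = sqrt(x_mod^2 + y_mod^2)`.
#'
#' @param x_mod,y_mod recentred coordinates (vectorised).
#' @return non-negative radius, px.
#' @export
radius <- function(x_mod, y_mod) sqrt(x_mod^2 + y_mod^2)

#' Polar angle of recentred coordinates
#'
#' The image-analysis convention defines the angle through
#' `phi = arccos(x_mod / r)`, which covers the upper half-turn; the lower
#' half-plane (y_mod < 0) is mapped to `2*pi - arccos(x_mod / r)` so phi
#' spans \[0, 2*pi). The same convention is applied to droplets and edge
#' points, so the relative distance is independent of this choice. The pixel
#' frame has y growing downward; no flip is applied.
#'
#' @param x_mod,y_mod recentred coordinates (vectorised).
#' @return angle in \[0, 2*pi).
#' @export
polar_angle <- function(x_mod, y_mod) {
  r <- radius(x_mod, y_mod)
  if (any(r == 0))
    stop_oildrops("polar angle undefined for the zero vector", "undefined_angle")
  a <- acos(pmin(1, pmax(-1, x_mod / r)))
  phi <- ifelse(y_mod >= 0, a, 2 * pi - a)
  ifelse(phi >= 2 * pi, 0, phi)
}

#' Center-to-edge radius along a polar ray
#'
#' Casts the ray from the center at angle `phi`, intersects it with every
#' polygon segment, and returns the distance to the farthest intersection
#' (the outer boundary). For slices with coves a ray can cross the contour
#' more than twice; taking the farthest crossing keeps pp monotone along the
#' ray and bounded by 100.
#'
#' @param geometry [slice_geometry()].
#' @param phi angle(s) in radians.
#' @return list with `r_ce` (distance px) and `crossings` (number of valid
#'   ray-contour intersections), each the length of `phi`.
#' @export
edge_radius_at_angle <- function(geometry, phi) {
  p <- geometry$edge
  cx <- geometry$center[1]; cy <- geometry$center[2]
  x1 <- p[, 1] - cx; y1 <- p[, 2] - cy
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  ex <- x2 - x1; ey <- y2 - y1
  dx <- cos(phi); dy <- sin(phi)
  # center + t*d = P1 + s*e  =>  t = (x1*ey - y1*ex)/(dx*ey - dy*ex),
  #                              s = (x1*dy - y1*dx)/(dx*ey - dy*ex)
  denom <- outer(dx, ey) - outer(dy, ex)           # |phi| x |segments|
  tnum <- matrix(x1 * ey - y1 * ex, nrow = length(phi), ncol = length(ex), byrow = TRUE)
  snum <- outer(dy, x1) - outer(dx, y1)
  tt <- tnum / denom
  ss <- snum / denom
  # s-band shifted by 1e-9 so a ray through a shared vertex registers on
  # exactly one of the two adjacent segments despite rounding jitter
  ok <- is.finite(tt) & abs(denom) > 1e-12 & ss >= -1e-9 & ss < 1 - 1e-9 & tt > 1e-9
  tt[!ok] <- -Inf
  r_ce <- apply(tt, 1, max)
  crossings <- rowSums(ok)
  if (any(!is.finite(r_ce)))
    stop_oildrops("ray does not intersect the edge polygon", "geometry_error")
  list(r_ce = r_ce, crossings = crossings)
}

#' Relative distance of a droplet (percent of the center-to-edge radius)
#'
#' `pp = 100 * r_CD / r_CE`. Values marginally above 100 (segmentation halo
#' around the edge) are clamped: pp in (100, 105\] becomes 100 with a
#' warning; pp > 105 signals a wrong center/edge pairing and errors.
#'
#' @param r_cd center-to-droplet radius, px (vectorised).
#' @param r_ce center-to-edge radius at the droplet's angle, px.
#' @return pp in \[0, 100\].
#' @export
relative_distance <- function(r_cd, r_ce) {
  if (any(r_ce <= 0)) stop_oildrops("r_CE must be positive", "geometry_error")
  pp <- 100 * r_cd / r_ce
  high <- pp > 105
  if (any(high))
    stop_oildrops(paste0("relative distance ", format(max(pp)),
                         "% > 105%: droplet far outside edge"), "consistency_error")
  clamp <- pp > 100
  if (any(clamp)) {
    warning(sprintf("%d droplet(s) marginally outside the edge (pp <= 105%%) clamped to 100%%",
                    sum(clamp)))
    pp[clamp] <- 100
  }
  pp
}

#' Nine-class binning of relative distances
#'
#' Classes are the nine equal-width intervals of \[0, 100\]: class k covers
#' \[(k-1)*100/9, k*100/9), half-open, with class 9 closed at 100. Exact
#' multiples of 100/9 belong to the upper class.
#'
#' @param pp relative distance(s) in \[0, 100\].
#' @return integer class index 1..9.
#' @export
assign_class <- function(pp) {
  if (any(!is.finite(pp) | pp < 0 | pp > 100))
    stop_oildrops("pp must lie in [0, 100]", "domain_error")
  as.integer(pmin(floor(pp * 9 / 100), 8) + 1)
}

#' Map segmented droplets to radial records
#'
#' Applies the full radial normalisation to each droplet: recentring, radius,
#' polar angle, ray-cast edge radius, relative distance and class. A droplet
#' exactly at the center has undefined angle; it is recorded with pp = 0,
#' class 1.
#'
#' @param particles data.frame from [extract_particles()] (columns
#'   droplet_id, x, y, ...).
#' @param geometry [slice_geometry()].
#' @return data.frame: droplet_id, x, y, x_mod, y_mod, r_cd_px, phi_rad,
#'   r_ce_px, pp_percent, class_index, ray_crossings (crossings > 2 flag
#'   coved contours).
#' @export
map_droplets <- function(particles, geometry) {
  n <- nrow(particles)
  out <- data.frame(droplet_id = particles$droplet_id,
                    x = particles$x, y = particles$y,
                    x_mod = particles$x - geometry$center[1],
                    y_mod = particles$y - geometry$center[2])
  out$r_cd_px <- radius(out$x_mod, out$y_mod)
  out$phi_rad <- NA_real_; out$r_ce_px <- NA_real_
  out$pp_percent <- 0; out$class_index <- 1L; out$ray_crossings <- NA_integer_
  nonzero <- out$r_cd_px > 0
  if (any(nonzero)) {
    phi <- polar_angle(out$x_mod[nonzero], out$y_mod[nonzero])
    er <- edge_radius_at_angle(geometry, phi)
    out$phi_rad[nonzero] <- phi
    out$r_ce_px[nonzero] <- er$r_ce
    out$pp_percent[nonzero] <- relative_distance(out$r_cd_px[nonzero], er$r_ce)
    out$ray_crossings[nonzero] <- er$crossings
  }
  out$class_index <- assign_class(out$pp_percent)
  out
}

#' Per-pixel relative-distance map and class areas
#'
#' Computes pp for the center of every pixel inside the edge polygon and
#' tallies pixels per class. The edge radius is evaluated on a fine angular
#' grid (`n_grid` rays, linearly interpolated in angle), which is accurate
#' for the smooth contours of real slices. Class areas in mm^2 are pixel
#' counts times `(scale/1000)^2`; together the classes partition the polygon
#' interior exactly.
#'
#' @param geometry [slice_geometry()].
#' @param width,height image dimensions in px.
#' @param n_grid number of rays for the edge-radius lookup table.
#' @return list: `class_map` (integer matrix width x height, NA outside),
#'   `pp_map` (numeric matrix), `pixel_counts` (length 9),
#'   `areas_mm2` (length 9).
#' @export
relative_distance_map <- function(geometry, width, height, n_grid = 2048) {
  grid_phi <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  grid_r <- edge_radius_at_angle(geometry, grid_phi)$r_ce
  px <- rep(0:(width - 1), times = height)
  py <- rep(0:(height - 1), each = width)
  bnd <- rbind(geometry$edge, geometry$edge[1, ])
  inside <- mgcv::in.out(bnd, cbind(px, py))
  xm <- px[inside] - geometry$center[1]
  ym <- py[inside] - geometry$center[2]
  r <- sqrt(xm^2 + ym^2)
  pp <- numeric(length(r))
  nz <- r > 0
  a <- acos(pmin(1, pmax(-1, xm[nz] / r[nz])))
  phi <- ifelse(ym[nz] >= 0, a, 2 * pi - a)
  # circular linear interpolation on the ray grid
  pos <- phi / (2 * pi) * n_grid
  i0 <- floor(pos); frac <- pos - i0
  i0 <- (as.integer(i0) %% n_grid) + 1L
  i1 <- (i0 %% n_grid) + 1L
  r_ce <- grid_r[i0] * (1 - frac) + grid_r[i1] * frac
  pp[nz] <- pmin(100, 100 * r[nz] / r_ce)
  cls <- assign_class(pp)
  pixel_counts <- tabulate(cls, nbins = 9)
  pp_map <- matrix(NA_real_, width, height)
  class_map <- matrix(NA_integer_, width, height)
  idx <- cbind(px[inside] + 1L, py[inside] + 1L)
  pp_map[idx] <- pp
  class_map[idx] <- cls
  list(class_map = class_map, pp_map = pp_map, pixel_counts = pixel_counts,
       areas_mm2 = pixel_counts * (geometry$scale / 1000)^2)
}
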