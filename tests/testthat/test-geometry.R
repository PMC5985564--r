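# Radial normalisation: recentring, polar angles, ray-cast edge radii,
# relative distances, class binning and the per-pixel distance map.

circle_polygon <- function(r = 100, center = c(0, 0), n = 360) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# pp of points against a polygon via the package's ray casting
pp_of <- function(pts, center, poly) {
  geo <- slice_geometry(center, poly, scale = 1)
  rad <- map_droplets(data.frame(droplet_id = seq_len(nrow(pts)),
                                 x = pts[, 1], y = pts[, 2]), geo)
  rad$pp_percent
}

test_that("recenter and radius follow the coordinate formulas", {
  expect_equal(recenter(c(10, 5), c(3, 2)), c(7, 3))
  expect_equal(recenter(c(4, -1), c(4, -1)), c(0, 0))
  expect_equal(recenter(c(0, 0), c(4, -1)), c(-4, 1))
  expect_equal(radius(3, 4), 5)
  expect_equal(radius(0, 0), 0)
  expect_equal(radius(-5, 12), 13)
})

test_that("polar_angle extends arccos(x/r) to the full circle", {
  expect_equal(polar_angle(1, 0), 0)
  expect_equal(polar_angle(0, 1), pi / 2)
  expect_equal(polar_angle(0, -1), 3 * pi / 2)
  set.seed(3)
  x <- rnorm(200); y <- rnorm(200)
  expect_equal(polar_angle(x, y), atan2(y, x) %% (2 * pi), tolerance = 1e-12)
  expect_error(polar_angle(0, 0), class = "undefined_angle")
})

test_that("edge_radius_at_angle is exact on circles and squares", {
  geo <- slice_geometry(c(0, 0), circle_polygon(100), scale = 1)
  r <- edge_radius_at_angle(geo, seq(0, 2 * pi, length.out = 37)[-37])$r_ce
  expect_true(all(abs(r - 100) <= 0.5))

  sq <- rbind(cbind(seq(-50, 50, length.out = 11), -50),
              cbind(50, seq(-50, 50, length.out = 11)),
              cbind(seq(50, -50, length.out = 11), 50),
              cbind(-50, seq(50, -50, length.out = 11)))
  sq <- sq[!duplicated(sq), ]
  geo_sq <- slice_geometry(c(0, 0), sq, scale = 1)
  expect_equal(edge_radius_at_angle(geo_sq, 0)$r_ce, 50, tolerance = 1e-9)
  expect_equal(edge_radius_at_angle(geo_sq, pi / 4)$r_ce, 50 * sqrt(2), tolerance = 1e-9)
})

test_that("edge_radius_at_angle matches the dense-resampling oracle on star polygons", {
  phis <- seq(0, 2 * pi, length.out = 73)[-73]
  for (seed in 1:5) {
    poly <- star_polygon(seed)
    geo <- slice_geometry(c(0, 0), poly, scale = 1)
    oracle <- dense_radius_oracle(poly, c(0, 0))
    err <- abs(edge_radius_at_angle(geo, phis)$r_ce - oracle(phis))
    expect_lt(max(err), 1.5)
  }
})

test_that("farthest intersection is used for coved (non-star) contours", {
  # circle with a channel cut toward the center and a flap folded back into
  # it: the ray at phi = 0 crosses the boundary at x = 45, 70 and 85
  th <- seq(0.105, 2 * pi - 0.105, length.out = 320)
  arc <- cbind(100 * cos(th), 100 * sin(th))
  cove <- rbind(c(45, -10), c(45, 10), c(70, 10), c(70, -6),
                c(85, -6), c(85, 10))
  poly <- rbind(arc, c(99.5, -10), cove, c(99.5, 10))
  geo <- slice_geometry(c(0, 0), poly, scale = 1)
  res <- edge_radius_at_angle(geo, 0)
  expect_equal(res$crossings, 3)
  expect_equal(res$r_ce, 85)                 # outermost crossing, not the cove wall
  expect_equal(edge_radius_at_angle(geo, pi)$r_ce, 100, tolerance = 0.1)
})

test_that("relative_distance computes pp with clamp and consistency error", {
  expect_equal(relative_distance(50, 100), 50)
  expect_equal(relative_distance(100, 100), 100)
  expect_equal(relative_distance(0, 100), 0)
  expect_warning(pp <- relative_distance(103, 100), "clamped")
  expect_equal(pp, 100)
  expect_error(relative_distance(120, 100), class = "consistency_error")
  expect_error(relative_distance(50, 0), class = "geometry_error")
})

test_that("assign_class reproduces the nine printed interval limits", {
  expect_equal(assign_class(0), 1L)
  expect_equal(assign_class(100), 9L)
  expect_equal(assign_class(50), 5L)
  expect_equal(assign_class(11.10), 1L)
  expect_equal(assign_class(100 / 9), 2L)       # boundary goes to the upper class
  expect_equal(assign_class(800 / 9), 9L)
  expect_equal(assign_class(88.87), 8L)
  expect_equal(assign_class(c(5, 15, 95)), c(1L, 2L, 9L))
  expect_error(assign_class(-0.1), class = "domain_error")
  expect_error(assign_class(100.1), class = "domain_error")
})

test_that("pp is invariant under rigid motion and scaling of the whole slice", {
  poly <- star_polygon(11, base = 90, amp = 15, center = c(130, 120))
  center <- c(130, 120)
  set.seed(5)
  phi <- runif(40, 0, 2 * pi); f <- runif(40, 0.05, 0.98)
  oracle <- dense_radius_oracle(poly, center)
  pts <- cbind(center[1] + f * oracle(phi) * cos(phi),
               center[2] + f * oracle(phi) * sin(phi))
  pp0 <- pp_of(pts, center, poly)

  # translation
  d <- c(31, -17)
  expect_equal(pp_of(pts + rep(d, each = 40), center + d, poly + rep(d, each = nrow(poly))),
               pp0, tolerance = 1e-9)
  # 90 degree rotation about the center
  rot <- function(p) cbind(center[1] - (p[, 2] - center[2]), center[2] + (p[, 1] - center[1]))
  expect_equal(pp_of(rot(pts), center, rot(poly)), pp0, tolerance = 1e-9)
  # uniform scaling about the origin
  expect_equal(pp_of(pts * 2.5, center * 2.5, poly * 2.5), pp0, tolerance = 1e-9)
})

test_that("relative_distance_map matches analytic annuli and partitions the disk", {
  geo <- slice_geometry(c(320, 320), circle_polygon(300, c(320, 320), 720), scale = 10)
  m <- relative_distance_map(geo, 640, 640)
  frac <- m$pixel_counts / sum(m$pixel_counts)
  expect_true(all(abs(frac - (2 * (1:9) - 1) / 81) < 0.01))
  # partition: class pixels sum to polygon-interior pixels exactly
  expect_equal(sum(m$pixel_counts), sum(!is.na(m$class_map)))
  expect_equal(m$areas_mm2, m$pixel_counts * (10 / 1000)^2)
})

test_that("class areas are invariant to 90-degree rotation within 1%", {
  poly <- star_polygon(21, base = 90, amp = 18, center = c(128, 128))
  geo <- slice_geometry(c(128, 128), poly, scale = 1)
  m0 <- relative_distance_map(geo, 256, 256)
  rotp <- cbind(128 - (poly[, 2] - 128), 128 + (poly[, 1] - 128))
  geor <- slice_geometry(c(128, 128), rotp, scale = 1)
  m1 <- relative_distance_map(geor, 256, 256)
  rel <- abs(m1$pixel_counts - m0$pixel_counts) / pmax(1, m0$pixel_counts)
  expect_true(all(rel < 0.01))
})

test_that("map_droplets conserves droplet counts over classes", {
  poly <- star_polygon(31, base = 95, amp = 12, center = c(128, 128))
  geo <- slice_geometry(c(128, 128), poly, scale = 1)
  set.seed(9)
  pts <- data.frame(droplet_id = 1:30,
                    x = runif(30, 80, 176), y = runif(30, 80, 176))
  rad <- map_droplets(pts, geo)
  expect_equal(sum(tabulate(rad$class_index, 9)), 30)
  expect_true(all(rad$r_cd_px <= rad$r_ce_px + 1e-9, na.rm = TRUE))
  # droplet exactly at the center
  rad0 <- map_droplets(data.frame(droplet_id = 1, x = 128, y = 128), geo)
  expect_equal(rad0$pp_percent, 0)
  expect_equal(rad0$class_index, 1L)
})
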