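# Segmentation: grayscale conversion, Huang threshold, droplet binarisation,
# particle extraction and edge tracing.

test_that("to_grayscale8 handles 8-bit, 16-bit and RGB input", {
  rgb <- array(0, dim = c(4, 4, 3)); rgb[, , 2] <- 200; rgb[, , 1] <- 50
  expect_equal(as.vector(to_grayscale8(rgb)), rep(200L, 16))

  g8 <- matrix(sample.int(256, 64, replace = TRUE) - 1L, 8, 8)
  expect_identical(to_grayscale8(g8), g8)

  ramp <- matrix(as.numeric(0:65535), 256, 256)
  expect_equal(as.vector(to_grayscale8(ramp)), as.integer((0:65535) %/% 257))

  lum <- to_grayscale8(rgb, segmentation_params(channel = "luminance"))
  expect_equal(lum[1, 1], round(0.299 * 50 + 0.587 * 200))

  norm <- matrix(c(0, 0.5, 1, 0.25), 2, 2)   # [0,1] floats from file readers
  expect_equal(as.vector(to_grayscale8(norm)), c(0L, 128L, 255L, 64L))

  expect_error(to_grayscale8(matrix(numeric(0), 0, 0)), class = "invalid_input")
})

test_that("huang_threshold separates bimodal histograms", {
  # two point masses: any level in [10, 200) separates them under the
  # foreground = gray > t rule; entropy is flat there and the tie-break
  # takes the lowest level
  h <- numeric(256); h[10 + 1] <- 500; h[200 + 1] <- 500
  t <- huang_threshold(h)
  expect_gte(t, 10); expect_lt(t, 200)
  expect_identical(t, huang_oracle(h))

  # two-Gaussian histogram (modes 80 / 175): threshold lies between the
  # modes and equals the exhaustive scan (frozen oracle value 99)
  lev <- 0:255
  h2 <- round(1000 * (exp(-(lev - 80)^2 / 50) + exp(-(lev - 175)^2 / 50)))
  t2 <- huang_threshold(h2)
  expect_identical(t2, huang_oracle(h2))
  expect_identical(t2, 99L)
  expect_gt(t2, 80); expect_lt(t2, 175)

  h3 <- numeric(256); h3[100] <- 50
  expect_error(huang_threshold(h3), class = "degenerate_histogram")
})

test_that("huang_threshold equals the exhaustive fuzzy-entropy oracle", {
  set.seed(42)
  # two-Gaussian image, means 30/220 sd 10
  img <- matrix(round(c(rnorm(2000, 30, 10), rnorm(500, 220, 10))), 50, 50)
  img <- pmin(255, pmax(0, img))
  h <- gray_histogram(img)
  expect_identical(huang_threshold(h), huang_oracle(h))

  for (i in 1:10) {
    h <- round(runif(256) * rbinom(256, 1, 0.3) * 100)
    if (sum(h > 0) < 2) next
    expect_identical(huang_threshold(h), huang_oracle(h))
  }
})

test_that("binarize_droplets finds a bright disk and removes salt noise", {
  img <- matrix(10L, 64, 64)
  d <- disk_mask(64, 64, cbind(32, 32), 5)
  img[d] <- 255L
  mask <- binarize_droplets(img, segmentation_params(dilate_radius = 0))
  expect_equal(dim(mask), dim(img))
  parts <- extract_particles(mask, segmentation_params())
  expect_equal(nrow(parts), 1)

  # salt: isolated bright pixels, removed by the median step
  set.seed(1)
  salt <- img
  idx <- sample(which(!d & row(img) %% 3 == 0 & col(img) %% 3 == 0), 15)
  salt[idx] <- 255L
  p_nomed <- segmentation_params(median_radius = 0, dilate_radius = 0, min_area = 1)
  p_med <- segmentation_params(median_radius = 1, dilate_radius = 0, min_area = 1)
  n_without <- nrow(extract_particles(binarize_droplets(salt, p_nomed), p_nomed))
  n_with <- nrow(extract_particles(binarize_droplets(salt, p_med), p_med))
  expect_gt(n_without, 1)
  expect_equal(n_with, 1)

  expect_error(binarize_droplets(matrix(7L, 32, 32)), class = "degenerate_histogram")
})

test_that("extract_particles filters by circularity and is additive", {
  m <- disk_mask(100, 100, cbind(30, 30), 5)
  m[50:90, 70] <- TRUE                       # 1-px-wide 41-px line
  parts_all <- extract_particles(m, segmentation_params(min_circularity = 0, min_area = 1))
  expect_equal(nrow(parts_all), 2)
  circ <- parts_all$circularity[order(parts_all$area_px2, decreasing = TRUE)]
  expect_gt(circ[1], 0.8)                    # disk
  expect_lt(circ[2], 0.5)                    # line
  parts <- extract_particles(m, segmentation_params(min_circularity = 0.5))
  expect_equal(nrow(parts), 1)
  expect_equal(parts$x, 30, tolerance = 0.5)
  expect_equal(parts$y, 30, tolerance = 0.5)

  m2 <- disk_mask(100, 100, rbind(c(25, 25), c(70, 60)), c(5, 5))
  expect_equal(nrow(extract_particles(m2, segmentation_params())), 2)
})

test_that("particle centroids shift exactly with image translation", {
  m <- disk_mask(80, 80, rbind(c(20, 25), c(50, 40)), c(4, 6))
  p0 <- extract_particles(m, segmentation_params())
  shift <- c(7, 11)
  m2 <- matrix(FALSE, 80, 80)
  m2[(shift[1] + 1):80, (shift[2] + 1):80] <- m[1:(80 - shift[1]), 1:(80 - shift[2])]
  p1 <- extract_particles(m2, segmentation_params())
  expect_equal(nrow(p1), nrow(p0))
  expect_equal(p1$x, p0$x + shift[1])
  expect_equal(p1$y, p0$y + shift[2])
  expect_equal(p1$area_px2, p0$area_px2)
})

test_that("circularity of a rasterized disk rises with radius", {
  circ <- vapply(c(5, 10, 20, 40), function(r) {
    m <- disk_mask(2 * r + 20, 2 * r + 20, cbind(r + 10, r + 10), r)
    extract_particles(m, segmentation_params(min_circularity = 0))$circularity
  }, numeric(1))
  expect_true(all(diff(circ) >= -1e-9))
  expect_gt(circ[4], 0.95)
})

test_that("8-connectivity joins diagonally touching pixels", {
  m <- matrix(FALSE, 10, 10)
  m[2, 2] <- m[3, 3] <- m[4, 4] <- TRUE      # diagonal chain = one particle
  p <- extract_particles(m, segmentation_params(min_area = 1, min_circularity = 0))
  expect_equal(nrow(p), 1)
  expect_equal(p$area_px2, 3)
})

test_that("extract_edge_contour traces squares, circles, largest component", {
  sq <- matrix(FALSE, 140, 140); sq[21:120, 21:120] <- TRUE
  ct <- extract_edge_contour(sq)
  expect_gte(nrow(ct), 16)
  per <- sum(sqrt(rowSums((rbind(ct[-1, ], ct[1, ]) - ct)^2)))
  expect_lt(abs(per - 400) / 400, 0.05)

  circ <- disk_mask(240, 240, cbind(120, 120), 100)
  ct2 <- extract_edge_contour(circ)
  rad <- sqrt((ct2[, 1] - 120)^2 + (ct2[, 2] - 120)^2)
  expect_true(all(abs(rad - 100) <= 1.5))

  two <- disk_mask(240, 240, rbind(c(120, 120), c(20, 20)), c(60, 4))
  ct3 <- extract_edge_contour(two)
  rad3 <- sqrt((ct3[, 1] - 120)^2 + (ct3[, 2] - 120)^2)
  expect_true(all(rad3 < 70))               # contour of the large disk only

  expect_error(extract_edge_contour(matrix(FALSE, 10, 10)), class = "empty_mask")
})

test_that("read_center_annotation returns the annotation verbatim with bounds checks", {
  ann <- data.frame(slice_id = c("a", "b"), x = c(512, -3), y = c(480, 10))
  expect_equal(unname(read_center_annotation(ann, "a", 1024, 1024)), c(512, 480))
  expect_error(read_center_annotation(ann, "b", 1024, 1024), class = "annotation_error")
  expect_error(read_center_annotation(ann, "zzz", 1024, 1024),
               regexp = "zzz", class = "annotation_error")
})
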