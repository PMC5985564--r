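# Segmentation of composed root-slice fluorescence images: grayscale
# conversion, Huang fuzzy-entropy thresholding, particle extraction with
# size/circularity filters, and edge-contour tracing.
#
# Image convention: a slice image is a numeric matrix with dim = c(width,
# height) (EBImage layout: first index x rightward, second index y downward).
# All coordinates reported to the user are 0-based pixel indices with the
# origin at the top-left pixel center.

#' Default segmentation parameters
#'
#' @param median_radius median-filter radius in px (0 disables).
#' @param dilate_radius grayscale-dilation radius in px (square structuring
#'   element of side `2r + 1`; 0 disables).
#' @param min_area,max_area particle area band in px^2.
#' @param min_circularity,max_circularity circularity band; circularity is
#'   `4*pi*area/perimeter^2`, clipped to 1.
#' @param channel grayscale conversion for RGB input: `"green"` keeps the
#'   green channel only (droplets fluoresce green); `"luminance"` uses
#'   0.299 R + 0.587 G + 0.114 B.
#' @return a list of class `segmentation_params`.
#' @export
segmentation_params <- function(median_radius = 1, dilate_radius = 1,
                                min_area = 5, max_area = Inf,
                                min_circularity = 0.3, max_circularity = 1,
                                channel = c("green", "luminance")) {
  channel <- match.arg(channel)
  if (median_radius < 0 || dilate_radius < 0)
    stop_oildrops("filter radii must be >= 0", "invalid_params")
  if (min_area > max_area)
    stop_oildrops("min_area must be <= max_area", "invalid_params")
  if (min_circularity < 0 || max_circularity > 1 || min_circularity > max_circularity)
    stop_oildrops("circularity band must satisfy 0 <= min <= max <= 1", "invalid_params")
  structure(list(median_radius = median_radius, dilate_radius = dilate_radius,
                 min_area = min_area, max_area = max_area,
                 min_circularity = min_circularity,
                 max_circularity = max_circularity, channel = channel),
            class = "segmentation_params")
}

#' Read a slice image from TIFF or PNG
#'
#' @param path image file (8- or 16-bit, 1 or 3 channels).
#' @return numeric array, dim = c(width, height) or c(width, height, 3),
#'   values in \[0, 1\] (EBImage normalisation).
#' @export
read_slice_image <- function(path) {
  if (!file.exists(path))
    stop_oildrops(paste0("image file not found: ", path), "missing_file")
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3 && dim(a)[3] > 3) a <- a[, , 1:3]  # drop alpha
  a
}

#' Convert an image to an 8-bit grayscale matrix
#'
#' Single-channel input passes through (16-bit data are rescaled linearly to
#' 0–255, i.e. `floor(v/257)`; \[0, 1\] floats are scaled by 255). RGB input is
#' collapsed by the configured channel weighting, default green channel only.
#'
#' @param image numeric matrix (width x height) or array (width x height x 3).
#' @param params [segmentation_params()].
#' @return integer-valued matrix, range \[0, 255\].
#' @export
to_grayscale8 <- function(image, params = segmentation_params()) {
  if (length(image) == 0) stop_oildrops("empty image", "invalid_input")
  d <- dim(image)
  if (is.null(d) || length(d) < 2)
    stop_oildrops("image must be a 2-D matrix or 3-channel array", "invalid_input")
  if (length(d) == 3) {
    if (d[3] < 3) stop_oildrops("multi-channel image must have 3 channels", "invalid_input")
    image <- switch(params$channel,
      green = image[, , 2],
      luminance = 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
  }
  mx <- max(image)
  if (min(image) < 0) stop_oildrops("negative intensities", "invalid_input")
  if (mx <= 1) {                      # normalised floats (file readers)
    out <- round(image * 255)
  } else if (mx <= 255) {             # already 8-bit
    out <- round(image)
  } else if (mx <= 65535) {           # 16-bit counts
    out <- image %/% 257
  } else stop_oildrops("intensities exceed 16-bit range", "invalid_input")
  storage.mode(out) <- "integer"
  out
}

#' Huang fuzzy-entropy threshold
#'
#' Finds the gray level minimising the Huang–Wang fuzzy entropy. For a
#' candidate threshold t, pixels at or below t get membership based on the
#' distance to the mean gray value of the low side, pixels above t to the
#' mean of the high side: `u = 1 / (1 + |g - mu| / C)` with C the gray-level
#' range of the histogram. The Shannon entropy
#' `S(u) = -u log u - (1 - u) log(1 - u)` is summed over all pixels; the
#' returned level is the smallest t attaining the minimum (deterministic
#' tie-break). Foreground is conventionally `gray > t`.
#'
#' @param histogram numeric vector of 256 counts for levels 0..255.
#' @return integer threshold level in 0..255.
#' @export
huang_threshold <- function(histogram) {
  if (length(histogram) != 256 || any(histogram < 0))
    stop_oildrops("histogram must be 256 non-negative counts", "invalid_input")
  nz <- which(histogram > 0)
  if (length(nz) < 2)
    stop_oildrops("histogram has fewer than 2 nonzero bins", "degenerate_histogram")
  first <- nz[1]; last <- nz[length(nz)]       # 1-based bin indices
  g <- 0:255
  C <- (last - first)                           # gray-level range
  w <- cumsum(histogram * g)                    # weighted cumulative sums
  n <- cumsum(histogram)
  total_w <- w[256]; total_n <- n[256]
  cand <- first:(last - 1)                      # thresholds t = cand - 1
  ent <- vapply(cand, function(i) {
    mu0 <- w[i] / n[i]
    mu1 <- (total_w - w[i]) / (total_n - n[i])
    mu <- c(rep(mu0, i), rep(mu1, 256 - i))
    u <- 1 / (1 + abs(g - mu) / C)
    s <- ifelse(u <= 0 | u >= 1, 0, -u * log(u) - (1 - u) * log(1 - u))
    sum(histogram * s)
  }, numeric(1))
  as.integer(cand[which.min(ent)] - 1L)         # back to 0-based level
}

#' Histogram of an 8-bit image
#' @param gray integer matrix from [to_grayscale8()].
#' @return numeric vector of 256 counts.
#' @export
gray_histogram <- function(gray) {
  tabulate(as.integer(gray) + 1L, nbins = 256)
}

#' Binarise droplets: median filter, grayscale dilation, Huang threshold
#'
#' Pipeline order follows the segmentation protocol: median filter (despeckle)
#' then grayscale dilation, then Huang thresholding of the filtered image;
#' foreground = pixels above the threshold.
#'
#' A composed whole-slice image contains a third intensity mode — the black
#' area outside the slice — which would dominate the fuzzy-entropy objective.
#' Passing the slice-interior mask as `region` computes the threshold from
#' interior pixels only and restricts the droplet mask to the interior, which
#' is how the batch pipeline calls this.
#'
#' @param gray 8-bit grayscale matrix.
#' @param params [segmentation_params()].
#' @param region optional logical matrix; threshold from and mask within this
#'   region only.
#' @return logical matrix of the same dimensions (`TRUE` = droplet).
#' @export
binarize_droplets <- function(gray, params = segmentation_params(), region = NULL) {
  f <- filter_gray(gray, params)
  h <- if (is.null(region)) gray_histogram(f)
       else tabulate(as.integer(f[region]) + 1L, nbins = 256)
  t <- huang_threshold(h)
  mask <- f > t
  if (!is.null(region)) mask <- mask & region
  mask
}

# median + dilation on an 8-bit matrix, returning an 8-bit matrix
filter_gray <- function(gray, params) {
  f <- gray
  if (params$median_radius > 0) {
    x <- EBImage::medianFilter(f / 255, params$median_radius)
    f <- round(x * 255)
  }
  if (params$dilate_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(params$dilate_radius) + 1L, shape = "box")
    f <- EBImage::dilate(f, brush)
  }
  storage.mode(f) <- "integer"
  dim(f) <- dim(gray)
  f
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally (union-find over diagonal adjacencies).
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  nl <- max(lab)
  if (nl <= 1) return(lab)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  d <- dim(lab); w <- d[1]; h <- d[2]
  pairs <- rbind(
    cbind(as.vector(lab[-w, -h]), as.vector(lab[-1, -1])),   # down-right diagonal
    cbind(as.vector(lab[-1, -h]), as.vector(lab[-w, -1])))   # down-left diagonal
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) union2(pairs[k, 1], pairs[k, 2])
    roots <- vapply(seq_len(nl), find, integer(1))
    relab <- match(roots, sort(unique(roots)))
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  lab
}

# chain-code perimeter with the standard smooth-boundary correction:
# 0.95 * (straight steps + sqrt(2) * diagonal steps)
chain_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 2) return(0)
  nxt <- rbind(contour[-1, , drop = FALSE], contour[1, , drop = FALSE])
  step <- abs(nxt - contour)
  diagonal <- step[, 1] == 1 & step[, 2] == 1
  0.95 * (sum(!diagonal) + sqrt(2) * sum(diagonal))
}

#' Extract droplet particles from a binary mask
#'
#' Labels 8-connected components, computes area (px^2), centroid (0-based
#' pixel coordinates) and circularity `4*pi*area/perimeter^2` (chain-code
#' perimeter with anisotropy correction, clipped to 1; single-pixel objects
#' get circularity 1), then applies the configured size and circularity
#' filters. Result is sorted by centroid y then x.
#'
#' @param mask logical matrix from [binarize_droplets()].
#' @param params [segmentation_params()].
#' @return data.frame: droplet_id, x, y, area_px2, circularity.
#' @export
extract_particles <- function(mask, params = segmentation_params()) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  empty <- data.frame(droplet_id = integer(), x = numeric(), y = numeric(),
                      area_px2 = numeric(), circularity = numeric())
  if (!any(mask)) return(empty)
  lab <- label_components8(mask)
  nl <- max(lab)
  idx <- which(lab > 0)
  labs <- lab[idx]
  xi <- (idx - 1L) %% dim(lab)[1]           # 0-based x
  yi <- (idx - 1L) %/% dim(lab)[1]          # 0-based y
  area <- tabulate(labs, nbins = nl)
  cx <- tapply(xi, labs, mean)
  cy <- tapply(yi, labs, mean)
  contours <- EBImage::ocontour(lab)
  perim <- vapply(contours, chain_perimeter, numeric(1))
  circ <- ifelse(perim > 0, pmin(1, 4 * pi * area / perim^2), 1)
  keep <- area >= params$min_area & area <= params$max_area &
    circ >= params$min_circularity & circ <= params$max_circularity
  out <- data.frame(x = as.numeric(cx), y = as.numeric(cy),
                    area_px2 = as.numeric(area), circularity = as.numeric(circ))[keep, , drop = FALSE]
  out <- out[order(out$y, out$x), , drop = FALSE]
  out <- cbind(droplet_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Segment droplets in one grayscale slice image
#'
#' Convenience wrapper: [binarize_droplets()] then [extract_particles()].
#'
#' @inheritParams binarize_droplets
#' @return list with `mask` (logical matrix) and `particles` (data.frame).
#' @export
segment_droplets <- function(gray, params = segmentation_params(), region = NULL) {
  mask <- binarize_droplets(gray, params, region)
  list(mask = mask, particles = extract_particles(mask, params))
}

#' Segment the slice interior (tissue region)
#'
#' The composed image has the slice tissue on a black background. The
#' interior mask is obtained by median smoothing, Otsu thresholding (tissue
#' autofluorescence vs. black background; the rare bright droplets barely
#' move the between-class variance), hole filling, and keeping the largest
#' connected component.
#'
#' @param gray 8-bit grayscale matrix.
#' @param threshold optional fixed gray level overriding Otsu.
#' @param median_radius despeckle radius before thresholding.
#' @return logical matrix, `TRUE` = inside the slice.
#' @export
extract_slice_region <- function(gray, threshold = NULL, median_radius = 2) {
  f <- gray
  if (median_radius > 0) f <- round(EBImage::medianFilter(gray / 255, median_radius) * 255)
  if (is.null(threshold)) {
    img <- EBImage::Image(f / 255)
    threshold <- EBImage::otsu(img) * 255
  }
  mask <- f > threshold
  lab <- EBImage::bwlabel(EBImage::fillHull(mask))
  nl <- max(lab)
  if (nl == 0) stop_oildrops("no tissue region found", "empty_mask")
  sizes <- tabulate(lab[lab > 0], nbins = nl)
  lab == which.max(sizes)
}

#' Trace the outer edge contour of a region mask
#'
#' Keeps the largest connected component and returns its outer boundary as an
#' ordered closed polygon in 0-based pixel coordinates (first vertex not
#' repeated). Orientation is normalised so the shoelace signed area in the
#' image frame (y down) is positive.
#'
#' @param mask logical matrix (slice interior, or an edge-band mask).
#' @return two-column matrix (x, y) with >= 16 vertices, class
#'   `edge_contour`.
#' @export
extract_edge_contour <- function(mask) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (!any(mask)) stop_oildrops("mask has no foreground", "empty_mask")
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  biggest <- lab == which.max(sizes)
  ct <- EBImage::ocontour(EBImage::bwlabel(biggest))[[1]]   # 0-based (x, y)
  if (nrow(ct) >= 2 && all(ct[1, ] == ct[nrow(ct), ])) ct <- ct[-nrow(ct), , drop = FALSE]
  if (nrow(ct) < 16)
    stop_oildrops("edge contour has fewer than 16 vertices", "degenerate_contour")
  if (polygon_area_signed(ct) < 0) ct <- ct[rev(seq_len(nrow(ct))), , drop = FALSE]
  colnames(ct) <- c("x", "y")
  class(ct) <- c("edge_contour", class(ct))
  ct
}

# shoelace signed area (pixel frame, y down)
polygon_area_signed <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Read a manually marked slice center from an annotation table
#'
#' @param annotations data.frame with columns slice_id, x, y (0-based pixel
#'   coordinates), e.g. from `read.csv`.
#' @param slice_id slice to look up.
#' @param width,height image dimensions in px for the bounds check.
#' @return numeric c(x, y), the annotated point verbatim.
#' @export
read_center_annotation <- function(annotations, slice_id, width, height) {
  need <- c("slice_id", "x", "y")
  if (!all(need %in% names(annotations)))
    stop_oildrops("annotation table must have columns slice_id, x, y", "annotation_error")
  row <- annotations[annotations$slice_id == slice_id, , drop = FALSE]
  if (nrow(row) == 0)
    stop_oildrops(paste0("no center annotation for slice '", slice_id, "'"), "annotation_error")
  x <- as.numeric(row$x[1]); y <- as.numeric(row$y[1])
  if (!is.finite(x) || !is.finite(y) || x < 0 || y < 0 || x >= width || y >= height)
    stop_oildrops(paste0("center annotation out of bounds for slice '", slice_id, "'"),
                  "annotation_error")
  c(x = x, y = y)
}

#' Write a binary mask as an 8-bit PNG (foreground 255)
#' @param mask logical matrix.
#' @param path output file.
#' @export
write_mask_png <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(mask * 1), path, type = "png")
  invisible(path)
}
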