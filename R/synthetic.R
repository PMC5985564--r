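# Seeded synthetic root-slice generator with ground truth: an irregular
# star-shaped edge contour (Fourier-perturbed circle), a droplet-poor central
# cylinder, bright Gaussian-profile droplets at controlled relative radial
# positions, and additive noise. Every pipeline stage can be validated
# against the emitted truth tables without microscope data.

#' Specification of one synthetic slice
#'
#' Defaults emulate a typical composed valerian root-slice micrograph: a
#' roughly oval contour with mild coves, a nearly droplet-free central
#' cylinder (classes 1–2), a moderate parenchyma population and a
#' droplet-rich outermost class (about 43% of droplets in class 9).
#'
#' @param image_size c(width, height) px (or one number for square).
#' @param mean_radius mean edge radius R, px.
#' @param amplitudes Fourier amplitudes a_j (fractions of R) for harmonics
#'   j = 2..6; `sum(abs(a))` must stay < 0.35 so the contour remains
#'   star-shaped about the center.
#' @param center_offset c(dx, dy) of the true center from the image center.
#' @param lambda expected droplet count per class, length 9.
#' @param droplet_radius range c(min, max) of droplet radii, px.
#' @param peak_intensity droplet peak gray value.
#' @param background tissue background gray value (outside the slice is 0).
#' @param noise_sd additive Gaussian noise SD, gray levels.
#' @param salt_density fraction of pixels set to 255 (hot pixels).
#' @param scale micrometres per pixel.
#' @param seed integer; fixes all randomness of the slice.
#' @return list of class `synthetic_slice_spec`.
#' @export
synthetic_slice_spec <- function(image_size = 640, mean_radius = 260,
                                 amplitudes = c(0.08, 0.05, 0.04, 0.03, 0.02),
                                 center_offset = c(12, -9),
                                 lambda = c(0, 0.5, 4, 6, 8, 10, 13, 15, 43),
                                 droplet_radius = c(2, 4),
                                 peak_intensity = 220, background = 30,
                                 noise_sd = 8, salt_density = 5e-4,
                                 scale = 3.3, seed = 1) {
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  if (sum(abs(amplitudes)) >= 0.35)
    stop_oildrops("sum(|amplitudes|) must be < 0.35 (star-shaped contour)", "spec_error")
  if (length(lambda) != 9 || any(lambda < 0))
    stop_oildrops("lambda must be 9 non-negative rates", "spec_error")
  if (any(c(peak_intensity, background) < 0) || any(c(peak_intensity, background) > 255))
    stop_oildrops("intensities must lie in [0, 255]", "spec_error")
  structure(list(image_size = image_size, mean_radius = mean_radius,
                 amplitudes = amplitudes, center_offset = center_offset,
                 lambda = lambda, droplet_radius = droplet_radius,
                 peak_intensity = peak_intensity, background = background,
                 noise_sd = noise_sd, salt_density = salt_density,
                 scale = scale, seed = as.integer(seed)),
            class = "synthetic_slice_spec")
}

# analytic truth radius r(theta) of a spec's contour given the drawn phases
contour_radius_fn <- function(mean_radius, amplitudes, phases) {
  function(theta) {
    r <- rep(1, length(theta))
    for (j in seq_along(amplitudes))
      r <- r + amplitudes[j] * cos((j + 1) * theta + phases[j])
    mean_radius * r
  }
}

#' Generate the true edge contour of a synthetic slice
#'
#' `r(theta) = R * (1 + sum_j a_j cos(j*theta + phi_j))` for harmonics
#' j = 2..6, phases drawn from the seeded generator, sampled at `n_vertices`
#' angles. Star-shaped about the true center by the amplitude bound.
#'
#' @param spec [synthetic_slice_spec()].
#' @param n_vertices number of polygon vertices (>= 720 recommended).
#' @return two-column matrix (x, y), 0-based px, with attributes `center`
#'   (true center) and `radius_fn` (analytic radius function).
#' @export
generate_contour <- function(spec, n_vertices = 720) {
  phases <- with_seed(spec$seed + 1L, runif(length(spec$amplitudes), 0, 2 * pi))
  rf <- contour_radius_fn(spec$mean_radius, spec$amplitudes, phases)
  center <- spec$image_size / 2 + spec$center_offset
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  r <- rf(th)
  poly <- cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
  attr(poly, "center") <- c(x = center[1], y = center[2])
  attr(poly, "radius_fn") <- rf
  poly
}

#' Place ground-truth droplets at controlled relative distances
#'
#' Per class k the droplet count is Poisson(lambda\[k\]); each droplet draws
#' a uniform polar angle and a uniform relative distance within class k's
#' sub-interval, and is positioned at
#' `center + direction(phi) * (pp/100) * r_CE(phi)` using the analytic
#' contour radius. A minimum separation of twice the maximum droplet radius
#' is enforced by rejection (1000 retries per droplet).
#'
#' @param spec [synthetic_slice_spec()].
#' @param contour result of [generate_contour()].
#' @return data.frame: droplet_id, x, y, radius_px, true_pp, true_class.
#' @export
place_droplets <- function(spec, contour) {
  center <- attr(contour, "center")
  rf <- attr(contour, "radius_fn")
  min_sep <- 2 * max(spec$droplet_radius)
  with_seed(spec$seed + 2L, {
    counts <- rpois(9, spec$lambda)
    xs <- ys <- rads <- pps <- numeric(0)
    cls <- integer(0)
    for (k in 1:9) {
      for (i in seq_len(counts[k])) {
        placed <- FALSE
        for (try in seq_len(1000)) {
          phi <- runif(1, 0, 2 * pi)
          pp <- runif(1, (k - 1) * 100 / 9, k * 100 / 9)
          r <- pp / 100 * rf(phi)
          x <- center[1] + r * cos(phi); y <- center[2] + r * sin(phi)
          if (length(xs) == 0 || min((xs - x)^2 + (ys - y)^2) >= min_sep^2) {
            xs <- c(xs, x); ys <- c(ys, y)
            rads <- c(rads, runif(1, spec$droplet_radius[1], spec$droplet_radius[2]))
            pps <- c(pps, pp); cls <- c(cls, k)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop_oildrops("cannot satisfy droplet separation; lower lambda", "spec_error")
      }
    }
    data.frame(droplet_id = seq_along(xs), x = xs, y = ys, radius_px = rads,
               true_pp = pps, true_class = cls)
  })
}

#' Render a synthetic slice image with masks and ground truth
#'
#' Background gray value inside the contour, 0 outside; droplets are
#' Gaussian-profile disks (`sigma = radius/2`) added at peak intensity;
#' Gaussian read noise and salt (hot-pixel) noise are applied, and the image
#' is clipped to \[0, 255\]. Bit-identical for the same spec and seed.
#'
#' @param spec [synthetic_slice_spec()].
#' @param contour from [generate_contour()] (default: generated).
#' @param droplets from [place_droplets()] (default: generated).
#' @return list of class `synthetic_slice`: `image` (integer matrix
#'   width x height), `edge_mask`, `center` (true center), `droplets`
#'   (ground-truth table), `contour`, `spec`.
#' @export
render_slice <- function(spec, contour = generate_contour(spec),
                         droplets = place_droplets(spec, contour)) {
  w <- spec$image_size[1]; h <- spec$image_size[2]
  px <- rep(0:(w - 1), times = h)
  py <- rep(0:(h - 1), each = w)
  bnd <- rbind(contour, contour[1, ])
  inside <- mgcv::in.out(bnd, cbind(px, py))
  img <- matrix(0, w, h)
  img[cbind(px[inside] + 1L, py[inside] + 1L)] <- spec$background
  edge_mask <- matrix(FALSE, w, h)
  edge_mask[cbind(px[inside] + 1L, py[inside] + 1L)] <- TRUE
  amp <- spec$peak_intensity - spec$background
  for (i in seq_len(nrow(droplets))) {
    sigma <- droplets$radius_px[i] / 2
    halo <- ceiling(3 * sigma)
    x0 <- droplets$x[i]; y0 <- droplets$y[i]
    xr <- max(0, floor(x0 - halo)):min(w - 1, ceiling(x0 + halo))
    yr <- max(0, floor(y0 - halo)):min(h - 1, ceiling(y0 + halo))
    d2 <- outer((xr - x0)^2, (yr - y0)^2, "+")
    img[xr + 1, yr + 1] <- img[xr + 1, yr + 1] + amp * exp(-d2 / (2 * sigma^2))
  }
  img <- with_seed(spec$seed + 3L, {
    out <- img + rnorm(length(img), 0, spec$noise_sd)
    n_salt <- round(spec$salt_density * length(out))
    if (n_salt > 0) out[sample.int(length(out), n_salt)] <- 255
    out
  })
  img <- matrix(pmin(255, pmax(0, round(img))), w, h)
  storage.mode(img) <- "integer"
  structure(list(image = img, edge_mask = edge_mask,
                 center = attr(contour, "center"), droplets = droplets,
                 contour = contour, spec = spec),
            class = "synthetic_slice")
}

#' Write a rendered synthetic slice to disk
#'
#' Emits `<id>.png` (8-bit grayscale image), `<id>_edge.png` (true edge
#' mask), and rows for the center-annotation and ground-truth tables.
#'
#' @param slice [render_slice()] result.
#' @param dir output directory.
#' @param slice_id identifier used in filenames.
#' @return list with `image_path`, `center` row and `truth` table.
#' @export
write_synthetic_slice <- function(slice, dir, slice_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  image_path <- file.path(dir, paste0(slice_id, ".png"))
  EBImage::writeImage(EBImage::Image(slice$image / 255), image_path, type = "png")
  write_mask_png(slice$edge_mask, file.path(dir, paste0(slice_id, "_edge.png")))
  truth <- cbind(slice_id = slice_id, slice$droplets)
  list(image_path = image_path,
       center = data.frame(slice_id = slice_id,
                           x = slice$center[1], y = slice$center[2]),
       truth = truth)
}

#' Simulate a batch of synthetic slices with metadata
#'
#' Generates `n_slices` slices from a template spec (per-slice seeds derived
#' as `base seed + slice index`), writes images, true edge masks, a center
#' sidecar CSV, a ground-truth droplet CSV and a factor metadata CSV
#' (factor levels assigned round-robin unless given).
#'
#' @param dir output directory.
#' @param n_slices number of slices.
#' @param spec template [synthetic_slice_spec()]; its seed is the batch base
#'   seed.
#' @param clones,fractions,horizons level pools cycled over slices. RF4 is
#'   restricted to thick clones by the cycling order used.
#' @return invisibly, the metadata data.frame (also written to
#'   `metadata.csv`).
#' @export
simulate_batch <- function(dir, n_slices, spec = synthetic_slice_spec(),
                           clones = c("CE1", "CE2", "CE3", "CE4"),
                           fractions = c("RF1", "RF2", "RF3"),
                           horizons = c("HZ1", "HZ2", "HZ3")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  centers <- truths <- metas <- list()
  for (i in seq_len(n_slices)) {
    s <- spec
    s$seed <- spec$seed + 10L * i
    slice_id <- sprintf("S%03d", i)
    sl <- render_slice(s)
    out <- write_synthetic_slice(sl, dir, slice_id)
    centers[[i]] <- out$center
    truths[[i]] <- out$truth
    metas[[i]] <- data.frame(
      slice_id = slice_id, image_path = out$image_path,
      center_path = file.path(dir, "centers.csv"),
      clone = clones[(i - 1) %% length(clones) + 1],
      fraction = fractions[(i - 1) %% length(fractions) + 1],
      horizon = horizons[(i - 1) %% length(horizons) + 1],
      scale_um_per_px = s$scale)
  }
  write.csv(do.call(rbind, centers), file.path(dir, "centers.csv"), row.names = FALSE)
  write.csv(do.call(rbind, truths), file.path(dir, "ground_truth.csv"), row.names = FALSE)
  meta <- do.call(rbind, metas)
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}

#' Match detected droplets to ground truth by nearest neighbour
#'
#' Greedy matching: each truth droplet takes the closest unmatched detection
#' within `max_dist` px.
#'
#' @param truth data.frame with x, y, true_class.
#' @param detected data.frame with x, y (and optionally class_index).
#' @param max_dist maximum centroid distance, px.
#' @return data.frame: truth row index, detection index (NA = missed),
#'   distance, plus class columns when present.
#' @export
match_droplets <- function(truth, detected, max_dist = 3) {
  n_t <- nrow(truth); n_d <- nrow(detected)
  match_idx <- rep(NA_integer_, n_t); dist <- rep(NA_real_, n_t)
  if (n_d > 0 && n_t > 0) {
    dd <- outer(truth$x, detected$x, "-")^2 + outer(truth$y, detected$y, "-")^2
    used <- rep(FALSE, n_d)
    for (i in order(apply(dd, 1, min))) {
      j <- which.min(ifelse(used, Inf, dd[i, ]))
      if (length(j) && dd[i, j] <= max_dist^2 && !used[j]) {
        match_idx[i] <- j; dist[i] <- sqrt(dd[i, j]); used[j] <- TRUE
      }
    }
  }
  out <- data.frame(truth_idx = seq_len(n_t), det_idx = match_idx, dist_px = dist)
  if ("true_class" %in% names(truth)) out$true_class <- truth$true_class
  if (!is.null(detected$class_index))
    out$detected_class <- ifelse(is.na(match_idx), NA_integer_,
                                 detected$class_index[match_idx])
  out
}
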