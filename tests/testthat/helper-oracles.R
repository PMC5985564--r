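# Independent oracles and small fixture builders used across the suite.

# Naive Huang-Wang fuzzy-entropy scan: double loop, no cumulative-sum
# shortcuts. Returns the lowest minimising level.
huang_oracle <- function(h) {
  g <- 0:255
  nz <- which(h > 0)
  first <- nz[1]; last <- nz[length(nz)]
  C <- last - first
  best <- Inf; best_t <- NA
  for (i in first:(last - 1)) {
    lo <- 1:i; hi <- (i + 1):256
    mu0 <- sum(h[lo] * g[lo]) / sum(h[lo])
    mu1 <- sum(h[hi] * g[hi]) / sum(h[hi])
    ent <- 0
    for (j in which(h > 0)) {
      mu <- if (j <= i) mu0 else mu1
      u <- 1 / (1 + abs(g[j] - mu) / C)
      if (u > 0 && u < 1) ent <- ent + h[j] * (-u * log(u) - (1 - u) * log(1 - u))
    }
    if (ent < best - 1e-12) { best <- ent; best_t <- i - 1 }
  }
  as.integer(best_t)
}

# Binary mask (width x height matrix) with filled disks at 0-based centers.
disk_mask <- function(width, height, centers, radii) {
  m <- matrix(FALSE, width, height)
  px <- rep(0:(width - 1), times = height)
  py <- rep(0:(height - 1), each = width)
  for (i in seq_len(nrow(centers))) {
    hit <- (px - centers[i, 1])^2 + (py - centers[i, 2])^2 <= radii[i]^2
    m[cbind(px[hit] + 1L, py[hit] + 1L)] <- TRUE
  }
  m
}

# Smooth star-shaped test polygon: r(theta) = base + sum b_j cos(j theta + psi_j),
# amplitudes bounded so r stays within [base - amp, base + amp] and |r'| is
# small enough for the nearest-angle oracle.
star_polygon <- function(seed, base = 100, amp = 20, n_harmonics = 5,
                         center = c(0, 0), n_vertices = 720) {
  set.seed(seed)
  b <- runif(n_harmonics); b <- b / sum(b) * amp
  psi <- runif(n_harmonics, 0, 2 * pi)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  r <- base
  for (j in seq_len(n_harmonics)) r <- r + b[j] * cos(j * th + psi[j])
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

# Dense-resampling radius oracle: subdivide every polygon edge into steps of
# <= 0.2 px, record the polar angle and radius of each sample about `center`,
# and answer queries with the radius of the nearest-angle sample.
dense_radius_oracle <- function(poly, center) {
  p1 <- poly
  p2 <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  seg_len <- sqrt(rowSums((p2 - p1)^2))
  xs <- ys <- numeric(0)
  for (i in seq_len(nrow(poly))) {
    n <- max(2, ceiling(seg_len[i] / 0.2))
    t <- seq(0, 1, length.out = n + 1)[-(n + 1)]
    xs <- c(xs, p1[i, 1] + t * (p2[i, 1] - p1[i, 1]))
    ys <- c(ys, p1[i, 2] + t * (p2[i, 2] - p1[i, 2]))
  }
  dx <- xs - center[1]; dy <- ys - center[2]
  ang <- atan2(dy, dx) %% (2 * pi)
  rad <- sqrt(dx^2 + dy^2)
  o <- order(ang)
  ang <- ang[o]; rad <- rad[o]
  function(phi) {
    phi <- phi %% (2 * pi)
    i <- findInterval(phi, ang)
    cand <- cbind(ifelse(i == 0, length(ang), i), ifelse(i == length(ang), 1, i + 1))
    vapply(seq_along(phi), function(k) {
      d <- abs(ang[cand[k, ]] - phi[k])
      d <- pmin(d, 2 * pi - d)
      rad[cand[k, which.min(d)]]
    }, numeric(1))
  }
}

# Tiny noiseless synthetic spec for fast end-to-end tests.
small_spec <- function(seed = 1, ...) {
  args <- list(image_size = 256, mean_radius = 100, center_offset = c(5, -4),
               lambda = c(0, 0, 2, 2, 3, 3, 4, 4, 10),
               noise_sd = 0, salt_density = 0, seed = seed)
  do.call(synthetic_slice_spec, utils::modifyList(args, list(...)))
}
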