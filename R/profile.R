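# Per-slice class profiles (counts, areas, densities over the nine distance
# classes) and factor-level aggregation.

#' Slice metadata record
#'
#' Factor labels for one slice. Root classification (thin/thick) is derived
#' from the clone: CE1 and CE2 are thin-rooted, CE3 and CE4 thick-rooted.
#' The largest diameter fraction RF4 is only formed by thick-rooted clones;
#' a thin clone labelled RF4 draws a warning (not an error, since other
#' material may form it).
#'
#' @param slice_id identifier.
#' @param clone one of CE1..CE4.
#' @param fraction root diameter fraction, RF1..RF4.
#' @param horizon root horizon (depth segment), HZ1..HZ3.
#' @param scale micrometres per pixel.
#' @return list of class `slice_meta` with derived `classification`.
#' @export
slice_meta <- function(slice_id, clone, fraction, horizon, scale) {
  clones <- c("CE1", "CE2", "CE3", "CE4")
  fractions <- c("RF1", "RF2", "RF3", "RF4")
  horizons <- c("HZ1", "HZ2", "HZ3")
  bad <- c(if (!clone %in% clones) paste0("clone '", clone, "'"),
           if (!fraction %in% fractions) paste0("fraction '", fraction, "'"),
           if (!horizon %in% horizons) paste0("horizon '", horizon, "'"))
  if (length(bad))
    stop_oildrops(paste0("slice '", slice_id, "': unknown level(s): ",
                         paste(bad, collapse = ", ")), "validation_error")
  if (!is.finite(scale) || scale <= 0)
    stop_oildrops(paste0("slice '", slice_id, "': scale must be positive"), "validation_error")
  classification <- if (clone %in% c("CE1", "CE2")) "thin" else "thick"
  if (classification == "thin" && fraction == "RF4")
    warning(sprintf("slice '%s': thin-rooted clone %s labelled RF4 (normally not formed)",
                    slice_id, clone))
  structure(list(slice_id = slice_id, clone = clone, classification = classification,
                 fraction = fraction, horizon = horizon, scale = scale),
            class = "slice_meta")
}

#' Build the class profile of one slice
#'
#' Tallies droplet counts per distance class and divides by the class areas
#' to obtain densities in droplets/mm^2. Classes without droplets have
#' density 0; a class with droplets but no (zero) area is a data error.
#'
#' @param radial data.frame from [map_droplets()] (column class_index).
#' @param areas_mm2 numeric length-9 vector of class areas, mm^2 (e.g.
#'   `relative_distance_map(...)$areas_mm2`).
#' @param meta [slice_meta()] (optional, carried along).
#' @return list of class `class_profile`: counts, areas_mm2, densities,
#'   total_count, total_area_mm2, total_density, slice_id, meta.
#' @export
build_profile <- function(radial, areas_mm2, meta = NULL) {
  if (length(areas_mm2) != 9 || any(!is.finite(areas_mm2)) || any(areas_mm2 < 0))
    stop_oildrops("areas_mm2 must be 9 finite non-negative values", "data_error")
  counts <- tabulate(radial$class_index, nbins = 9)
  if (any(counts > 0 & areas_mm2 <= 0))
    stop_oildrops("droplets found in a class with zero area", "data_error")
  densities <- ifelse(counts > 0, counts / areas_mm2, 0)
  total_area <- sum(areas_mm2)
  structure(list(
    slice_id = meta$slice_id %||% NA_character_,
    counts = counts, areas_mm2 = areas_mm2, densities = densities,
    total_count = sum(counts), total_area_mm2 = total_area,
    total_density = if (total_area > 0) sum(counts) / total_area else 0,
    meta = meta), class = "class_profile")
}

#' @export
print.class_profile <- function(x, ...) {
  cat("Class profile", if (!is.na(x$slice_id)) paste0("(slice ", x$slice_id, ")"), "\n")
  m <- rbind(count = x$counts, area_mm2 = round(x$areas_mm2, 3),
             density = round(x$densities, 2))
  colnames(m) <- paste0("c", 1:9)
  print(m)
  cat("total:", x$total_count, "droplets over", round(x$total_area_mm2, 3),
      "mm^2 =", round(x$total_density, 2), "droplets/mm^2\n")
  invisible(x)
}

#' Long-format table of profiles
#' @param profiles list of [build_profile()] results.
#' @return data.frame: slice_id, class, count, area_mm2, density_per_mm2.
#' @export
profile_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) data.frame(
    slice_id = p$slice_id, class = 1:9, count = p$counts,
    area_mm2 = p$areas_mm2, density_per_mm2 = p$densities)))
}

meta_level <- function(meta, factor) {
  switch(factor, clone = meta$clone, classification = meta$classification,
         fraction = meta$fraction, horizon = meta$horizon,
         stop_oildrops(paste0("unknown factor '", factor, "'"), "usage_error"))
}

#' Summarise droplet counts and densities by an experimental factor
#'
#' For each level: number of slices, total droplets, mean and sample
#' (n-1) SD of per-slice droplet counts, mean and SD of per-slice total
#' densities. `mean_display` is the mean rounded half-up to an integer (the
#' conventional table display). Levels with a single slice report SD 0 and
#' are flagged.
#'
#' @param profiles list of [build_profile()] results (with meta).
#' @param factor one of "clone", "classification", "fraction", "horizon".
#' @return data.frame of class `factor_summary`.
#' @export
summarize_factor <- function(profiles, factor = c("clone", "classification",
                                                  "fraction", "horizon")) {
  factor <- match.arg(factor)
  levels <- vapply(profiles, function(p) meta_level(p$meta, factor), character(1))
  counts <- vapply(profiles, function(p) p$total_count, numeric(1))
  dens <- vapply(profiles, function(p) p$total_density, numeric(1))
  out <- do.call(rbind, lapply(sort(unique(levels)), function(lv) {
    i <- levels == lv
    n <- sum(i)
    data.frame(factor = factor, level = lv, n_slices = n,
               sum_droplets = sum(counts[i]),
               mean_per_slice = mean(counts[i]),
               mean_display = round_half_up(mean(counts[i])),
               sd_per_slice = if (n > 1) sd(counts[i]) else 0,
               mean_density = mean(dens[i]),
               sd_density = if (n > 1) sd(dens[i]) else 0,
               single_slice = n == 1)
  }))
  rownames(out) <- NULL
  class(out) <- c("factor_summary", class(out))
  out
}

#' Mean per-class counts or densities by factor level
#'
#' Entry (level, k) is the mean over the level's slices of the class-k count
#' (or density) — the columns of the class-distribution bar charts.
#'
#' @param profiles list of [build_profile()] results (with meta).
#' @param factor factor name (see [summarize_factor()]).
#' @param value "count" or "density".
#' @return levels x 9 numeric matrix.
#' @export
class_distribution_matrix <- function(profiles, factor = "clone",
                                      value = c("count", "density")) {
  value <- match.arg(value)
  levels <- vapply(profiles, function(p) meta_level(p$meta, factor), character(1))
  rows <- lapply(sort(unique(levels)), function(lv) {
    ps <- profiles[levels == lv]
    colMeans(do.call(rbind, lapply(ps, function(p)
      if (value == "count") p$counts else p$densities)))
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(sort(unique(levels)), paste0("class", 1:9))
  m
}

#' Plot a class-distribution profile
#'
#' Bar chart of mean per-class droplet counts with the mean per-class
#' densities overlaid as points (secondary axis), one group of bars per
#' factor level.
#'
#' @param profiles list of [build_profile()] results.
#' @param factor factor name.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the count matrix.
#' @export
plot_class_profile <- function(profiles, factor = "clone", ...) {
  cnt <- class_distribution_matrix(profiles, factor, "count")
  den <- class_distribution_matrix(profiles, factor, "density")
  mids <- barplot(cnt, beside = TRUE, names.arg = 1:9,
                  xlab = "distance class (center → edge)",
                  ylab = "mean droplets per slice",
                  legend.text = rownames(cnt), ...)
  if (max(den) > 0) {
    sc <- max(cnt) / max(den)
    points(mids, t(den) * sc, pch = 19, cex = 0.7)
    axis(4, at = pretty(c(0, max(den))) * sc, labels = pretty(c(0, max(den))))
  }
  invisible(cnt)
}
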