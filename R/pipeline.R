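# Batch pipeline: metadata validation, per-slice processing (segment -> map
# -> profile), factor summaries and statistics, with standard CSV/JSON file
# contracts and a manifest.

#' Pipeline configuration
#'
#' @param segmentation [segmentation_params()].
#' @param clamp_threshold pp clamp ceiling in percent (droplets between 100
#'   and this are snapped to the edge; beyond it is an error).
#' @param alpha significance level for all tests.
#' @param welch use Welch's t for two-level density comparisons.
#' @param interior_threshold fixed tissue threshold (NULL = Otsu).
#' @param n_grid rays in the edge-radius lookup of the pp map.
#' @param seed integer seed for any stochastic step.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(segmentation = segmentation_params(),
                            clamp_threshold = 105, alpha = 0.05,
                            welch = FALSE, interior_threshold = NULL,
                            n_grid = 2048, seed = 1) {
  structure(list(segmentation = segmentation, clamp_threshold = clamp_threshold,
                 alpha = alpha, welch = welch,
                 interior_threshold = interior_threshold,
                 n_grid = n_grid, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `segmentation` block mirrors [segmentation_params()]. Missing keys keep
#' their defaults.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  seg <- do.call(segmentation_params, y$segmentation %||% list())
  args <- y[setdiff(names(y), "segmentation")]
  do.call(pipeline_config, c(list(segmentation = seg), args))
}

#' Validate a slice metadata table
#'
#' Requires columns slice_id, image_path, center_path, clone, fraction,
#' horizon, scale_um_per_px. Unknown factor labels are an error (listing the
#' offenders); a thin-rooted clone labelled RF4 is a warning. Root
#' classification is derived from the clone.
#'
#' @param metadata data.frame or path to a CSV.
#' @return list of [slice_meta()] records plus the checked data.frame, as
#'   `list(metas, table)`.
#' @export
validate_metadata <- function(metadata) {
  if (is.character(metadata)) metadata <- read.csv(metadata, stringsAsFactors = FALSE)
  need <- c("slice_id", "image_path", "center_path", "clone", "fraction",
            "horizon", "scale_um_per_px")
  missing_cols <- setdiff(need, names(metadata))
  if (length(missing_cols))
    stop_oildrops(paste("metadata lacks column(s):", paste(missing_cols, collapse = ", ")),
                  "validation_error")
  if (nrow(metadata) == 0)
    stop_oildrops("metadata table is empty", "usage_error")
  if (anyDuplicated(metadata$slice_id))
    stop_oildrops("duplicate slice_id in metadata", "validation_error")
  metas <- lapply(seq_len(nrow(metadata)), function(i)
    slice_meta(metadata$slice_id[i], metadata$clone[i], metadata$fraction[i],
               metadata$horizon[i], metadata$scale_um_per_px[i]))
  list(metas = metas, table = metadata)
}

#' Process one slice: segment, trace the edge, map droplets, build profile
#'
#' @param image_path composed slice image (TIFF/PNG).
#' @param center c(x, y) annotated center (0-based px).
#' @param meta [slice_meta()].
#' @param config [pipeline_config()].
#' @param geometry optional [slice_geometry()] overriding the
#'   pipeline-extracted edge (e.g. synthetic truth).
#' @return list: particles, radial, geometry, profile, map.
#' @export
process_slice <- function(image_path, center, meta, config = pipeline_config(),
                          geometry = NULL) {
  raw <- read_slice_image(image_path)
  gray <- to_grayscale8(raw, config$segmentation)
  interior <- extract_slice_region(gray, threshold = config$interior_threshold)
  seg <- segment_droplets(gray, config$segmentation, region = interior)
  if (is.null(geometry)) {
    edge <- extract_edge_contour(interior)
    geometry <- slice_geometry(center, edge, meta$scale)
  }
  radial <- map_droplets(seg$particles, geometry)
  rmap <- relative_distance_map(geometry, nrow(gray), ncol(gray), config$n_grid)
  profile <- build_profile(radial, rmap$areas_mm2, meta)
  list(particles = seg$particles, radial = radial, geometry = geometry,
       profile = profile, map = rmap)
}

#' Run the full pipeline over a metadata table
#'
#' For every slice: read image and center annotation, segment droplets,
#' extract the edge, compute radial records and the class profile. Failures
#' are logged per slice and skipped. Factor summaries and the statistical
#' battery run on the successful slices. All tables are written as CSV, test
#' results as JSON, and a manifest records the configuration hash and
#' per-slice status.
#'
#' @param metadata data.frame or CSV path (see [validate_metadata()]).
#' @param out_dir output directory.
#' @param config [pipeline_config()].
#' @param factors factors to summarise and test.
#' @return invisibly, a list with `profiles`, `summaries`, `tests`,
#'   `status` (per-slice), and `exit_code` (0 ok, 1 partial failures).
#' @export
run_pipeline <- function(metadata, out_dir, config = pipeline_config(),
                         factors = c("clone", "classification", "fraction", "horizon")) {
  vm <- validate_metadata(metadata)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S "), sprintf(...), "\n",
                            sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  profiles <- list(); droplet_rows <- list(); radial_rows <- list(); area_rows <- list()
  status <- character(nrow(vm$table))
  for (i in seq_len(nrow(vm$table))) {
    row <- vm$table[i, ]; meta <- vm$metas[[i]]
    res <- tryCatch({
      ann <- read.csv(row$center_path, stringsAsFactors = FALSE)
      raw <- read_slice_image(row$image_path)
      d <- dim(raw)
      center <- read_center_annotation(ann, row$slice_id, d[1], d[2])
      process_slice(row$image_path, center, meta, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- conditionMessage(res)
      logf("FAIL %s: %s", row$slice_id, conditionMessage(res))
      next
    }
    status[i] <- "ok"
    logf("ok   %s: %d droplets", row$slice_id, res$profile$total_count)
    profiles[[row$slice_id]] <- res$profile
    droplet_rows[[i]] <- cbind(slice_id = row$slice_id, res$particles)
    radial_rows[[i]] <- cbind(slice_id = row$slice_id, res$radial)
    area_rows[[i]] <- data.frame(slice_id = row$slice_id, class_index = 1:9,
                                 area_mm2 = res$map$areas_mm2,
                                 pixel_count = res$map$pixel_counts)
  }
  if (!length(profiles))
    stop_oildrops("no slice processed successfully", "usage_error")
  write.csv(do.call(rbind, droplet_rows), file.path(out_dir, "droplets.csv"), row.names = FALSE)
  write.csv(do.call(rbind, radial_rows), file.path(out_dir, "radial.csv"), row.names = FALSE)
  write.csv(do.call(rbind, area_rows), file.path(out_dir, "class_areas.csv"), row.names = FALSE)
  write.csv(profile_table(profiles), file.path(out_dir, "profiles.csv"), row.names = FALSE)
  totals <- do.call(rbind, lapply(profiles, function(p) data.frame(
    slice_id = p$slice_id, total_count = p$total_count,
    total_area_mm2 = p$total_area_mm2, total_density = p$total_density)))
  write.csv(totals, file.path(out_dir, "totals.csv"), row.names = FALSE)
  summaries <- lapply(factors, function(f) summarize_factor(profiles, f))
  names(summaries) <- factors
  write.csv(do.call(rbind, summaries), file.path(out_dir, "summaries.csv"), row.names = FALSE)
  tests <- lapply(factors, function(f)
    tryCatch(compare_factor(profiles, f, alpha = config$alpha, welch = config$welch),
             error = function(e) list(error = conditionMessage(e))))
  names(tests) <- factors
  jsonlite::write_json(serialize_tests(tests), file.path(out_dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    config_hash = config_hash(config),
    n_slices = nrow(vm$table), n_ok = sum(status == "ok"),
    slices = stats::setNames(as.list(status), vm$table$slice_id))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("done: %d/%d slices ok", sum(status == "ok"), length(status))
  invisible(list(profiles = profiles, summaries = summaries, tests = tests,
                 status = stats::setNames(status, vm$table$slice_id),
                 exit_code = if (all(status == "ok")) 0L else 1L))
}

serialize_tests <- function(tests) {
  lapply(tests, function(batch) lapply(batch, function(t) {
    if (inherits(t, "oildrops_test"))
      list(test = t$test, statistic = t$statistic, p_value = t$p_value,
           groups = t$groups, letters = as.list(t$letters))
    else t
  }))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}
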