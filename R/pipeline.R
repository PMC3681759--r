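# Pipeline orchestration: configuration, per-scene processing
# (grid detection -> segmentation -> spatial inference), per-condition
# aggregation and a machine-readable run record.

#' Pipeline configuration
#'
#' @param pixel_size_um micrometres per pixel of the input images.
#' @param threshold_method threshold rule for all channels (`"otsu"` or
#'   `"fixed"`).
#' @param n_reps Monte Carlo replicates per image (>= 19; default 999).
#' @param seed integer master seed; per-image seeds are derived from it.
#' @param level envelope coverage in (0.5, 1).
#' @param statistic per-image summary statistic, `"d50"` or `"mean"`.
#' @param tie_epsilon_um dead zone for ON/OFF scoring.
#' @param max_neurite_width_um,min_soma_area_um2 soma-exclusion parameters.
#' @param out_dir optional output directory; when set, every stage's tables
#'   and a JSON run record are written there.
#' @return a `run_config` list.
#' @export
run_config <- function(pixel_size_um = 0.1,
                       threshold_method = c("otsu", "fixed"),
                       n_reps = 999L, seed = 1L, level = 0.95,
                       statistic = c("d50", "mean"), tie_epsilon_um = 0.1,
                       max_neurite_width_um = 3, min_soma_area_um2 = 20,
                       out_dir = NULL) {
  threshold_method <- match.arg(threshold_method)
  statistic <- match.arg(statistic)
  stopifnot(n_reps >= 19L, level > 0.5, level < 1, pixel_size_um > 0)
  structure(list(pixel_size_um = pixel_size_um,
                 threshold_method = threshold_method,
                 n_reps = as.integer(n_reps), seed = check_seed(seed),
                 level = level, statistic = statistic,
                 tie_epsilon_um = tie_epsilon_um,
                 max_neurite_width_um = max_neurite_width_um,
                 min_soma_area_um2 = min_soma_area_um2,
                 out_dir = out_dir),
            class = "run_config")
}

#' @keywords internal
process_scene_images <- function(reflectance, tubulin, patch, config,
                                 seed, label = "scene") {
  centers <- detect_pillars(reflectance, config$pixel_size_um,
                            config$threshold_method)
  if (nrow(centers) == 0L)
    stop("no pillar detected in the reflectance channel of ", label)
  lattice <- fit_lattice(centers, config$pixel_size_um)
  raw_mask <- segment_neurites(tubulin, config$threshold_method)
  mask <- exclude_somata(raw_mask, config$pixel_size_um,
                         config$max_neurite_width_um,
                         config$min_soma_area_um2)
  patches <- segment_patches(patch, config$pixel_size_um,
                             config$threshold_method)
  if (nrow(patches) == 0L)
    stop("no patch segmented in ", label)
  result <- analyze_image(patches, mask, lattice, n_reps = config$n_reps,
                          seed = seed, level = config$level,
                          statistic = config$statistic)
  list(lattice = lattice, mask = mask, patches = patches, result = result)
}

#' Run the full image pipeline on one or more scenes
#'
#' For every scene: detect the pillar grid on the reflectance channel, fit
#' the lattice, segment and soma-exclude the neurites, segment the patches,
#' and run the per-image patched-CSR inference; finally aggregate per-image
#' results (grouped by `conditions` when given) into condition verdicts.
#' With `config$out_dir` set, per-image grid and patch CSVs, a JSON result
#' per image, the aggregate JSON and a run record (config, seed, package
#' version) are written.
#'
#' @param scenes list of `scene_bundle` objects and/or paths to scene TIFFs.
#' @param config a [run_config()].
#' @param conditions optional character/factor of the same length as
#'   `scenes`, grouping images into spacing conditions.
#' @return list with `images` (per-scene lists: `lattice`, `mask`,
#'   `patches`, `result`) and `aggregates` (named list of
#'   `aggregate_result` per condition).
#' @export
run_pipeline <- function(scenes, config = run_config(), conditions = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(scenes, "scene_bundle") || is.character(scenes))
    scenes <- as.list(scenes)
  n <- length(scenes)
  if (n == 0L) stop("no scenes given")
  if (is.null(conditions)) conditions <- rep("all", n)
  stopifnot(length(conditions) == n)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  seeds <- config$seed + seq_len(n)  # derived, distinct, deterministic
  images <- vector("list", n)
  for (k in seq_len(n)) {
    sc <- scenes[[k]]
    label <- if (is.character(sc)) sc else sprintf("scene %d", k)
    if (is.character(sc)) sc <- read_scene(sc, config$pixel_size_um)
    images[[k]] <- process_scene_images(sc$reflectance, sc$tubulin, sc$patch,
                                        config, seeds[k], label)
    if (!is.null(out_dir)) {
      stem <- file.path(out_dir, sprintf("image%03d", k))
      utils::write.csv(images[[k]]$lattice$centers,
                       paste0(stem, "_grid.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(images[[k]]$patches),
                       paste0(stem, "_patches.csv"), row.names = FALSE)
      res <- images[[k]]$result
      jsonlite::write_json(
        res[c("observed_d50", "observed_mean", "lower_um", "upper_um",
              "p_attraction", "p_repulsion", "n_reps", "n_patches",
              "statistic", "level")],
        paste0(stem, "_result.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  aggregates <- lapply(split(seq_len(n), conditions), function(ks)
    aggregate_condition(lapply(images[ks], `[[`, "result")))
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      lapply(aggregates, function(a)
        a[c("mean_observed_um", "mean_lower_um", "mean_upper_um",
            "verdict", "n_images", "statistic")]),
      file.path(out_dir, "aggregates.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(config = unclass(config)[setdiff(names(config), "out_dir")],
           n_images = n,
           conditions = as.character(conditions),
           package_version = as.character(utils::packageVersion("pillarpatch"))),
      file.path(out_dir, "run_record.json"), auto_unbox = TRUE, digits = NA)
  }
  list(images = images, aggregates = aggregates)
}

#' Run the pipeline from a manifest of scene files
#'
#' @param manifest data.frame (or path to a CSV) with columns `image_path`,
#'   `condition` and optionally `spacing_um`, `width_um`.
#' @param config a [run_config()].
#' @return as [run_pipeline()].
#' @export
run_manifest <- function(manifest, config = run_config()) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  stopifnot(all(c("image_path", "condition") %in% names(manifest)))
  missing <- !file.exists(manifest$image_path)
  if (any(missing))
    stop("manifest refers to missing file(s): ",
         paste(manifest$image_path[missing], collapse = ", "))
  run_pipeline(as.list(manifest$image_path), config,
               conditions = manifest$condition)
}
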