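#' Pipeline configuration
#'
#' Central configuration for the command-style entry points. Defaults
#' mirror the experiment: a ~125 um cell with the probe edge 13 um from the
#' cell edge, classifier thresholds 0.10 (non-response) and 0.5 (global
#' fraction), and a 2 um strain grid.
#'
#' @param out_dir Output / bundle directory.
#' @param seed Integer master seed.
#' @param n_cells Number of cells to simulate.
#' @param probabilities Named numeric `(global, local, none)` class
#'   probabilities for simulation.
#' @param condition Condition label attached to simulated cells.
#' @param n_frames Frames per movie.
#' @param threshold_none,global_fraction Classifier thresholds.
#' @param window_s Post-stimulus window (s).
#' @param donor_floor Minimum donor counts for a defined ratio.
#' @param grid_spacing Strain grid spacing (um).
#' @param bead_density Beads per square um for the bead pair.
#' @param track_window,track_search,track_min_score Bead-tracking
#'   parameters (px, px, correlation).
#' @param dry_run Validate configuration without writing outputs.
#' @param ... Additional fields stored verbatim. Notably `class_counts`,
#'   a named vector `c(global=, local=, none=)` that fixes the cohort
#'   composition exactly instead of drawing it from `probabilities`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "mechfret-run", seed = 1,
                            n_cells = 30,
                            probabilities = c(global = 0.8, local = 0.2,
                                              none = 0),
                            condition = "control", n_frames = 45,
                            threshold_none = 0.10, global_fraction = 0.5,
                            window_s = 60, donor_floor = 1,
                            grid_spacing = 2, bead_density = 0.03,
                            track_window = 15, track_search = 31,
                            track_min_score = 0.5, dry_run = FALSE, ...) {
  if (threshold_none <= 0 || threshold_none >= 1 ||
      global_fraction <= 0 || global_fraction >= 1)
    stop_param("classifier thresholds must lie in (0, 1)")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_cells = n_cells, probabilities = probabilities,
                 condition = condition, n_frames = n_frames,
                 threshold_none = threshold_none,
                 global_fraction = global_fraction, window_s = window_s,
                 donor_floor = donor_floor, grid_spacing = grid_spacing,
                 bead_density = bead_density, track_window = track_window,
                 track_search = track_search,
                 track_min_score = track_min_score, dry_run = dry_run, ...),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields present in the file override the [pipeline_config()] defaults;
#' `overrides` (e.g. parsed command-line flags) take precedence over both.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Named list of final overrides.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_param("missing config file: %s", path)
    vals <- yaml::read_yaml(path)
    if (!is.null(vals$probabilities))
      vals$probabilities <- unlist(vals$probabilities)
  }
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

config_checksum <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(config, files, path) {
  jsonlite::write_json(
    list(config = unclass(config), config_md5 = config_checksum(config),
         package_version = as.character(utils::packageVersion("mechfret")),
         r_version = as.character(getRversion()),
         files = files),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate a complete fixture bundle on disk
#'
#' Writes everything the analysis consumes: the probe trace (CSV), a
#' fiducial-bead image pair under the default substrate field (TIFF, with
#' a ground-truth bead table), the shared cell mask, and one two-channel
#' movie per cell with a JSON ground-truth sidecar. A manifest lists every
#' file with the seed that produced it; the same seed reproduces the
#' bundle byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return The manifest path, invisibly.
#' @export
cmd_simulate <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$n_cells < 1) stop_param("'n_cells' must be >= 1")
  if (isTRUE(config$dry_run)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(config$out_dir))
    stop_param("cannot create output directory '%s'", config$out_dir)
  files <- list()

  trace <- generate_probe_trace(equipment_model())
  files$trace <- file.path(config$out_dir, "probe_trace.csv")
  write_trace_csv(trace, files$trace)

  # probe at the top edge of the bead field of view: the ring of peak
  # displacement (13 um beyond the probe edge) then lies well inside the
  # region where beads can be tracked
  field_model <- substrate_field_model(probe_position = c(80, 0))
  pair <- generate_bead_images(field_model,
                               bead_density = config$bead_density,
                               seed = config$seed)
  dir.create(file.path(config$out_dir, "beads"), showWarnings = FALSE)
  files$bead_reference <- file.path(config$out_dir, "beads", "reference.tif")
  files$bead_displaced <- file.path(config$out_dir, "beads", "displaced.tif")
  files$bead_truth <- file.path(config$out_dir, "beads", "truth.csv")
  write_count_tiff(pair$reference, files$bead_reference)
  write_count_tiff(pair$displaced, files$bead_displaced)
  write.csv(pair$beads, files$bead_truth, row.names = FALSE)
  jsonlite::write_json(
    list(pixel_size = pair$pixel_size, seed = config$seed,
         field = unclass(field_model)),
    file.path(config$out_dir, "beads", "meta.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cell <- cell_phantom()
  files$mask <- file.path(config$out_dir, "mask.tif")
  write_mask_tiff(cell$mask, files$mask)

  classes <- NULL
  if (!is.null(config$class_counts)) {
    cc <- config$class_counts
    classes <- rep(c("global", "local", "none"),
                   c(cc[["global"]], cc[["local"]], cc[["none"]]))
    if (length(classes) != config$n_cells)
      stop_param("class_counts sum (%d) must equal n_cells (%d)",
                 length(classes), config$n_cells)
  }
  cohort <- generate_cohort(config$probabilities, config$n_cells,
                            cell = cell, n_frames = config$n_frames,
                            seed = config$seed, classes = classes)
  dir.create(file.path(config$out_dir, "cells"), showWarnings = FALSE)
  cells <- lapply(seq_along(cohort), function(i) {
    prefix <- file.path(config$out_dir, "cells", sprintf("cell_%03d", i))
    write_channel_stack(cohort[[i]]$stack, prefix)
    list(prefix = prefix, seed = cohort[[i]]$seed,
         condition = config$condition,
         probe_position = cell$probe_position)
  })
  files$cells <- cells
  manifest <- file.path(config$out_dir, "manifest.json")
  write_manifest(config, files, manifest)
  message(sprintf("simulated %d cells into %s", config$n_cells,
                  config$out_dir))
  invisible(manifest)
}

#' Analyze a simulated (or compatible) fixture bundle
#'
#' Runs the full per-cell pipeline ([run_cell()]) on every movie listed in
#' the bundle manifest, writes the per-cell records (JSON) and the cohort
#' roll-up (CSV), and — when a control condition is present — the
#' proportion estimates and exact tests of [cohort_report()]. Per-cell
#' failures are collected; the run fails only if every cell fails.
#'
#' @param config A [pipeline_config()] whose `out_dir` holds a bundle from
#'   [cmd_simulate()].
#' @return Invisibly, a list with `records` (data frame) and `report`
#'   (a [cohort_report()] or `NULL`).
#' @export
cmd_analyze <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop_param("missing manifest: %s", manifest_path)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  if (isTRUE(config$dry_run)) return(invisible(NULL))
  mask <- read_mask_tiff(file.path(config$out_dir, "mask.tif"))
  cfg <- cell_config(donor_floor = config$donor_floor,
                     threshold_none = config$threshold_none,
                     global_fraction = config$global_fraction,
                     window_s = config$window_s)
  rows <- list(); failures <- list()
  for (ci in manifest$files$cells) {
    res <- tryCatch({
      stack <- read_channel_stack(ci$prefix)
      rec <- run_cell(stack, mask, unlist(ci$probe_position), cfg)
      gt <- attr(stack, "ground_truth")
      data.frame(cell_id = basename(ci$prefix),
                 condition = ci$condition %||% "control",
                 delta_closer = rec$deltas[["closer"]],
                 delta_middle = rec$deltas[["middle"]],
                 delta_farther = rec$deltas[["farther"]],
                 class = rec$cls,
                 true_class = if (!is.null(gt)) gt$true_class else NA)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[basename(ci$prefix)]] <- conditionMessage(res)
    } else rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows))
    stop_param("all %d cells failed; first error: %s", length(failures),
               failures[[1]])
  if (length(failures))
    warning(sprintf("%d cell(s) failed: %s", length(failures),
                    paste(names(failures), collapse = ", ")))
  records <- do.call(rbind, rows)
  write.csv(records, file.path(config$out_dir, "cohort.csv"),
            row.names = FALSE)
  jsonlite::write_json(records, file.path(config$out_dir, "records.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report <- NULL
  if ("control" %in% records$condition) {
    report <- cohort_report(records, control = "control")
    write_cohort_report(report, file.path(config$out_dir, "report"))
  }
  message(sprintf("analyzed %d cells (%d failed)", nrow(records),
                  length(failures)))
  invisible(list(records = records, report = report))
}

#' Displacement and strain maps from a bead image pair
#'
#' Tracks the beads ([track_beads()]), interpolates the scattered
#' displacements onto a regular grid ([interpolate_field()]), derives the
#' finite-difference strain field ([displacement_to_strain()]), and writes
#' the field CSV, the strain TIFF and a JSON summary (maximum displacement
#' and strain with their locations).
#'
#' @param config A [pipeline_config()] whose `out_dir` holds a `beads/`
#'   pair from [cmd_simulate()] (or externally supplied images at the same
#'   paths).
#' @return Invisibly, the summary list.
#' @export
cmd_strain <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  ref_path <- file.path(config$out_dir, "beads", "reference.tif")
  disp_path <- file.path(config$out_dir, "beads", "displaced.tif")
  for (p in c(ref_path, disp_path))
    if (!file.exists(p)) stop_param("missing bead image: %s", p)
  if (isTRUE(config$dry_run)) return(invisible(NULL))
  meta_path <- file.path(config$out_dir, "beads", "meta.json")
  pixel_size <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path)$pixel_size else 1
  ref <- read_count_tiff(ref_path)[[1]]
  disp <- read_count_tiff(disp_path)[[1]]
  beads <- track_beads(ref, disp, window = config$track_window,
                       search = config$track_search,
                       min_score = config$track_min_score,
                       pixel_size = pixel_size)
  rng_x <- range(beads$x_um); rng_y <- range(beads$y_um)
  grid <- grid_spec(rng_x, rng_y, config$grid_spacing)
  # displacement summaries come from the plain interpolated field;
  # differentiation amplifies tracking noise, so the strain map uses the
  # spline-regularized fit instead
  field <- interpolate_field(beads, grid)
  field_smooth <- interpolate_field(beads, grid, smoothing = "tps")
  strain <- displacement_to_strain(field_smooth)
  out <- file.path(config$out_dir, "strain")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_field_csv(field, file.path(out, "displacement_field.csv"))
  write_strain_tiff(strain, file.path(out, "strain_E.tif"))
  summary <- list(displacement = summarize_field(field),
                  strain = summarize_field(strain),
                  n_beads = nrow(beads),
                  mean_match_score = mean(beads$score))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
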