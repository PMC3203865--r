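# File formats: multi-page TIFF per channel (16-bit counts), 8-bit TIFF
# masks, CSV traces/bead tables, JSON sidecars and reports.

TIFF_MAX <- 65535

write_count_tiff <- function(img_or_list, path) {
  scale01 <- function(m) {
    if (max(m) > TIFF_MAX)
      stop_param("counts exceed 16-bit range in '%s'", path)
    m / TIFF_MAX
  }
  if (is.list(img_or_list)) {
    tiff::writeTIFF(lapply(img_or_list, scale01), path,
                    bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(scale01(img_or_list), path, bits.per.sample = 16L)
  }
  invisible(path)
}

read_count_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) round(p * TIFF_MAX))
}

#' Write / read a two-channel stack as multi-page TIFFs with a JSON sidecar
#'
#' `write_channel_stack()` writes `<prefix>_donor.tif`,
#' `<prefix>_acceptor.tif` (frame-major, 16-bit) and `<prefix>_meta.json`
#' (pixel size, frame interval, stimulus frame, plus any ground-truth
#' attribute). `read_channel_stack()` reconstructs the [channel_stack()].
#'
#' @param stack A [channel_stack()].
#' @param prefix Path prefix for the three files.
#' @return `write_channel_stack()` returns the sidecar path invisibly;
#'   `read_channel_stack()` returns a [channel_stack()].
#' @export
write_channel_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "channel_stack"))
  nt <- dim(stack$donor)[3]
  per_frame <- function(a) lapply(seq_len(nt), function(f) a[, , f])
  write_count_tiff(per_frame(stack$donor), paste0(prefix, "_donor.tif"))
  write_count_tiff(per_frame(stack$acceptor), paste0(prefix, "_acceptor.tif"))
  meta <- list(pixel_size = stack$pixel_size,
               frame_interval = stack$frame_interval,
               stimulus_frame = stack$stimulus_frame)
  gt <- attr(stack, "ground_truth")
  if (!is.null(gt)) meta$ground_truth <- gt
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paste0(prefix, "_meta.json"))
}

#' @rdname write_channel_stack
#' @export
read_channel_stack <- function(prefix) {
  meta_path <- paste0(prefix, "_meta.json")
  for (p in c(meta_path, paste0(prefix, "_donor.tif"),
              paste0(prefix, "_acceptor.tif")))
    if (!file.exists(p)) stop_param("missing stack file: %s", p)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  to_array <- function(pages) {
    a <- array(0, c(dim(pages[[1]]), length(pages)))
    for (f in seq_along(pages)) a[, , f] <- pages[[f]]
    a
  }
  stack <- channel_stack(
    to_array(read_count_tiff(paste0(prefix, "_donor.tif"))),
    to_array(read_count_tiff(paste0(prefix, "_acceptor.tif"))),
    meta$pixel_size, meta$frame_interval, meta$stimulus_frame)
  if (!is.null(meta$ground_truth))
    attr(stack, "ground_truth") <- meta$ground_truth
  stack
}

#' Write / read a binary mask as an 8-bit TIFF
#'
#' @param mask Logical matrix.
#' @param path File path.
#' @return `read_mask_tiff()` returns a logical matrix.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(ifelse(mask, 1, 0), path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  if (!file.exists(path)) stop_param("missing mask file: %s", path)
  tiff::readTIFF(path) > 0.5
}

#' Write a probe trace as CSV (time_s, displacement_um)
#'
#' @param trace Data frame from [generate_probe_trace()].
#' @param path File path.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(trace[, c("time_s", "displacement_um")], path,
            row.names = FALSE)
  invisible(path)
}

#' Write a gridded field as CSV (x_um, y_um, ux_um, uy_um)
#'
#' Long-format export of a `displacement_field`; undefined nodes are
#' omitted.
#'
#' @param field A `displacement_field`.
#' @param path File path.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  df <- expand.grid(y_um = field$grid_y, x_um = field$grid_x)
  df$ux_um <- as.vector(field$u_x)
  df$uy_um <- as.vector(field$u_y)
  df <- df[!is.na(df$ux_um), c("x_um", "y_um", "ux_um", "uy_um")]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a strain map as a 32-bit float TIFF
#'
#' @param strain A `strain_field`.
#' @param path File path.
#' @export
write_strain_tiff <- function(strain, path) {
  stopifnot(inherits(strain, "strain_field"))
  E <- strain$E
  E[is.na(E)] <- 0
  tiff::writeTIFF(E / max(E, 1), path, bits.per.sample = 32L,
                  reduce = FALSE)
  invisible(path)
}

#' Write a cohort report as JSON and CSV
#'
#' @param report A [cohort_report()].
#' @param dir Output directory.
#' @return The JSON path, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$estimates, file.path(dir, "proportions.csv"),
            row.names = FALSE)
  if (nrow(report$tests))
    write.csv(report$tests, file.path(dir, "tests.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(estimates = report$estimates, tests = report$tests,
         control = report$control),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(file.path(dir, "report.json"))
}
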