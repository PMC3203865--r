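#' Pre-stimulus baseline ratio per band
#'
#' Mean of each band's ratio over the pre-stimulus frames
#' `1:(stimulus_frame - 1)`. At least 3 pre-stimulus frames are required
#' for a stable baseline.
#'
#' @param tc Region time-course data frame (see
#'   [extract_region_timecourses()] / [region_mean_ratio()]).
#' @param stimulus_frame 1-based index of the first stimulated frame.
#' @return Named numeric `c(closer, middle, farther)`.
#' @export
compute_baseline <- function(tc, stimulus_frame) {
  pre <- seq_len(stimulus_frame - 1)
  if (length(pre) < 3)
    stop_param("need at least 3 pre-stimulus frames (got %d)", length(pre))
  if (stimulus_frame > nrow(tc))
    stop_param("'stimulus_frame' beyond the end of the time course")
  vapply(region_names,
         function(rn) mean(tc[[paste0("r_", rn)]][pre]), numeric(1))
}

#' Stimulated relative increase per band
#'
#' For each band, the stimulated increase is the baseline-normalized peak:
#' `delta = (max ratio within the post-stimulus window - baseline) /
#' baseline`. The window starts at `stimulus_frame` and spans `window_s`
#' seconds; the peak frame is recorded per band.
#'
#' @param tc Region time-course data frame.
#' @param baselines Named baselines from [compute_baseline()].
#' @param stimulus_frame 1-based index of the first stimulated frame.
#' @param window_s Post-stimulus window length in s (default 60).
#' @return A list with `deltas` (named numeric) and `peak_frames` (named
#'   integer).
#' @export
compute_stimulated_increase <- function(tc, baselines, stimulus_frame,
                                        window_s = 60) {
  t0 <- tc$time_s[stimulus_frame]
  idx <- which(tc$frame >= stimulus_frame & tc$time_s <= t0 + window_s)
  if (!length(idx)) stop_param("empty post-stimulus window")
  deltas <- numeric(0); peaks <- integer(0)
  for (rn in region_names) {
    r <- tc[[paste0("r_", rn)]][idx]
    i <- which.max(r)
    deltas[rn] <- (r[i] - baselines[rn]) / baselines[rn]
    peaks[rn] <- tc$frame[idx][i]
  }
  list(deltas = deltas, peak_frames = peaks)
}

#' Classify a calcium response as global, local or non-responsive
#'
#' Rule order: (1) if no band's stimulated increase exceeds
#' `threshold_none` (a ratio change within 10% of the basal level), the
#' cell is non-responsive; (2) otherwise the response is global if the
#' increase in the band farthest from the probe is at least
#' `global_fraction` (half) of that in the closest band — ties at exact
#' equality count as global; (3) otherwise it is local.
#'
#' @param deltas Numeric length-3 relative increases `(closer, middle,
#'   farther)`, named or positional.
#' @param threshold_none Non-response threshold on the maximum band
#'   increase (default 0.10).
#' @param global_fraction Minimum farther/closer increase ratio for a
#'   global call (default 0.5).
#' @return `"global"`, `"local"` or `"none"`.
#' @examples
#' classify_response(c(0.40, 0.30, 0.20))   # boundary case -> "global"
#' classify_response(c(0.40, 0.25, 0.19))   # -> "local"
#' classify_response(c(0.09, 0.05, 0.02))   # -> "none"
#' @export
classify_response <- function(deltas, threshold_none = 0.10,
                              global_fraction = 0.5) {
  if (length(deltas) != 3L || any(!is.finite(deltas)))
    stop_param("'deltas' must be 3 finite values (closer, middle, farther)")
  if (threshold_none <= 0 || threshold_none >= 1 ||
      global_fraction <= 0 || global_fraction >= 1)
    stop_param("thresholds must lie in (0, 1)")
  if (is.null(names(deltas))) names(deltas) <- region_names
  if (max(deltas) <= threshold_none) return("none")
  if (deltas[["farther"]] >= global_fraction * deltas[["closer"]])
    return("global")
  "local"
}

#' Analysis configuration for a single cell
#'
#' @param donor_floor Minimum donor counts for a defined ratio.
#' @param threshold_none,global_fraction Classifier thresholds (see
#'   [classify_response()]).
#' @param window_s Post-stimulus window in s.
#' @param background_roi Optional logical background mask; chosen
#'   automatically when `NULL` ([auto_background_roi()]).
#' @return A `cell_config` list.
#' @export
cell_config <- function(donor_floor = 1, threshold_none = 0.10,
                        global_fraction = 0.5, window_s = 60,
                        background_roi = NULL) {
  structure(list(donor_floor = donor_floor, threshold_none = threshold_none,
                 global_fraction = global_fraction, window_s = window_s,
                 background_roi = background_roi),
            class = "cell_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full per-cell response pipeline
#'
#' Background subtraction, band partition, ratio time courses (ratio of
#' band means), baseline, stimulated increases, and classification, in one
#' call. Errors are annotated with the stage that raised them.
#'
#' @param stack A [channel_stack()].
#' @param cell_mask Logical H x W cell mask.
#' @param probe_position Probe center `c(x, y)` in um.
#' @param config A [cell_config()].
#' @return An object of class `response_record`: baselines, deltas, class,
#'   per-band peak frames, and the band time courses.
#' @export
run_cell <- function(stack, cell_mask, probe_position,
                     config = cell_config()) {
  stopifnot(inherits(stack, "channel_stack"))
  roi <- config$background_roi %||%
    with_stage("background", auto_background_roi(cell_mask, probe_position,
                                                 stack$pixel_size))
  corrected <- with_stage("background",
                          subtract_background(stack, roi, cell_mask))
  part <- with_stage("partition",
                     partition_regions(cell_mask, probe_position,
                                       stack$pixel_size))
  tc <- with_stage("timecourse",
                   region_mean_ratio(corrected, part, config$donor_floor))
  base <- with_stage("baseline", compute_baseline(tc, stack$stimulus_frame))
  inc <- with_stage("increase",
                    compute_stimulated_increase(tc, base,
                                                stack$stimulus_frame,
                                                config$window_s))
  cls <- with_stage("classify",
                    classify_response(inc$deltas, config$threshold_none,
                                      config$global_fraction))
  structure(list(baseline = base, deltas = inc$deltas,
                 peak_frames = inc$peak_frames, cls = cls,
                 timecourses = tc, partition_axis = part$axis,
                 config = unclass(config)[c("donor_floor", "threshold_none",
                                            "global_fraction", "window_s")]),
            class = "response_record")
}

#' @export
print.response_record <- function(x, ...) {
  cat(sprintf("response_record: class = %s\n", x$cls))
  cat(sprintf("  baseline (closer/middle/farther): %.4g / %.4g / %.4g\n",
              x$baseline["closer"], x$baseline["middle"],
              x$baseline["farther"]))
  cat(sprintf("  delta    (closer/middle/farther): %.4g / %.4g / %.4g\n",
              x$deltas["closer"], x$deltas["middle"], x$deltas["farther"]))
  invisible(x)
}
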