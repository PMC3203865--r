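#' Two-channel FRET image stack
#'
#' Container for a time-lapse acquisition of the donor (ECFP) and acceptor
#' (YPet) emission channels. Frames are indexed 1..T; `stimulus_frame` is
#' the 1-based index of the first frame at or after stimulation, so frames
#' `1:(stimulus_frame - 1)` are the pre-stimulus baseline.
#'
#' @param donor,acceptor H x W x T arrays of non-negative intensities
#'   (counts), congruent in shape.
#' @param pixel_size Pixel size in um/pixel.
#' @param frame_interval Time between frames in s.
#' @param stimulus_frame 1-based index of the first stimulated frame
#'   (`2 <= stimulus_frame <= T`).
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(donor, acceptor, pixel_size, frame_interval,
                          stimulus_frame) {
  if (length(dim(donor)) != 3L || !all(dim(donor) == dim(acceptor)))
    stop_param("'donor' and 'acceptor' must be congruent H x W x T arrays")
  if (min(donor) < 0 || min(acceptor) < 0)
    stop_param("channel intensities must be non-negative")
  if (pixel_size <= 0 || frame_interval <= 0)
    stop_param("'pixel_size' and 'frame_interval' must be positive")
  nt <- dim(donor)[3]
  if (stimulus_frame < 2 || stimulus_frame > nt)
    stop_param("'stimulus_frame' must lie in [2, %d]", nt)
  structure(list(donor = donor, acceptor = acceptor,
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 stimulus_frame = as.integer(stimulus_frame)),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$donor)
  cat(sprintf(
    "channel_stack: %d x %d px, %d frames (%.3g um/px, %.3g s/frame, stim at frame %d)\n",
    d[1], d[2], d[3], x$pixel_size, x$frame_interval, x$stimulus_frame))
  invisible(x)
}

#' Subtract the background signal estimated from a cell-free region
#'
#' The mean intensity over a region not covered by the cell and away from
#' the probe tip is computed per frame and per channel and subtracted from
#' every pixel of that frame. Negative results are clipped at zero to keep
#' ratios stable at low counts.
#'
#' @param stack A [channel_stack()].
#' @param roi Logical H x W matrix marking the background region (nonempty).
#' @param cell_mask Optional logical H x W cell mask; if supplied, `roi`
#'   must be disjoint from it.
#' @return A new, background-corrected [channel_stack()].
#' @export
subtract_background <- function(stack, roi, cell_mask = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  dim_hw <- dim(stack$donor)[1:2]
  if (!is.logical(roi) || !all(dim(roi) == dim_hw))
    stop_param("'roi' must be a logical matrix congruent with the stack")
  if (!any(roi)) stop_param("background ROI is empty")
  if (!is.null(cell_mask) && any(roi & cell_mask))
    stop_param("background ROI overlaps the cell mask")
  out <- stack
  for (ch in c("donor", "acceptor")) {
    a <- stack[[ch]]
    for (f in seq_len(dim(a)[3])) {
      fr <- a[, , f]
      a[, , f] <- pmax(fr - mean(fr[roi]), 0)
    }
    out[[ch]] <- a
  }
  out
}

#' Pixel-wise YPet/ECFP ratio map
#'
#' Computes `acceptor / donor` at every pixel inside the cell mask where
#' the donor signal exceeds `donor_floor`; all other pixels are flagged
#' undefined (`NA`). Assumes the background has already been subtracted.
#'
#' @param stack A background-corrected [channel_stack()].
#' @param cell_mask Logical H x W cell mask.
#' @param donor_floor Minimum donor counts for a defined ratio (default 1).
#' @return An H x W x T array of ratios with `NA` at undefined pixels.
#' @export
compute_ratio_map <- function(stack, cell_mask, donor_floor = 1) {
  stopifnot(inherits(stack, "channel_stack"))
  dim_hw <- dim(stack$donor)[1:2]
  if (!is.logical(cell_mask) || !all(dim(cell_mask) == dim_hw))
    stop_param("'cell_mask' must be a logical matrix congruent with the stack")
  defined <- stack$donor > donor_floor &
    array(cell_mask, dim(stack$donor))
  if (!any(defined))
    stop_param("no defined ratio pixels: entire mask at or below donor_floor")
  ratio <- array(NA_real_, dim(stack$donor))
  ratio[defined] <- stack$acceptor[defined] / stack$donor[defined]
  ratio
}

#' Partition a cell mask into three bands along the probe axis
#'
#' The cell footprint is split into three bands of equal extent ordered by
#' distance from the probe: every mask pixel is projected onto the axis
#' from the probe toward the cell centroid, the projected extent is cut
#' into three equal intervals, and pixels are assigned by interval. Ties at
#' the cut boundaries go to the band nearer the probe. When the probe sits
#' directly below the cell this reduces to a vertical split into three
#' horizontal bands of equal height.
#'
#' @param cell_mask Logical H x W matrix (the cell footprint).
#' @param probe_position Probe center `c(x, y)` in um; must lie outside the
#'   mask.
#' @param pixel_size um per pixel.
#' @return An object of class `region_partition` with logical masks
#'   `closer`, `middle`, `farther` and the unit `axis` vector.
#' @export
partition_regions <- function(cell_mask, probe_position, pixel_size) {
  if (!is.logical(cell_mask) || length(dim(cell_mask)) != 2L)
    stop_param("'cell_mask' must be a logical matrix")
  if (!any(cell_mask)) stop_param("empty cell mask")
  co <- pixel_coords(dim(cell_mask), pixel_size)
  idx <- which(cell_mask)
  # probe must not fall on a mask pixel
  pr <- round(probe_position[2] / pixel_size) + 1
  pc <- round(probe_position[1] / pixel_size) + 1
  if (pr >= 1 && pr <= nrow(cell_mask) && pc >= 1 && pc <= ncol(cell_mask) &&
      cell_mask[pr, pc])
    stop_param("probe position lies inside the cell mask")
  centroid <- c(mean(co$x[idx]), mean(co$y[idx]))
  ax <- centroid - probe_position
  nrm <- sqrt(sum(ax^2))
  if (nrm == 0) stop_param("probe coincides with the cell centroid")
  ax <- ax / nrm
  t_all <- (co$x - probe_position[1]) * ax[1] +
    (co$y - probe_position[2]) * ax[2]
  t_mask <- t_all[idx]
  rng <- range(t_mask)
  if (diff(rng) < 2 * pixel_size)
    stop_param("degenerate mask: extent along the probe axis below 3 pixels")
  w <- diff(rng) / 3
  closer <- middle <- farther <- matrix(FALSE, nrow(cell_mask), ncol(cell_mask))
  closer[idx] <- t_mask <= rng[1] + w
  middle[idx] <- t_mask > rng[1] + w & t_mask <= rng[1] + 2 * w
  farther[idx] <- t_mask > rng[1] + 2 * w
  structure(list(closer = closer, middle = middle, farther = farther,
                 axis = ax),
            class = "region_partition")
}

region_names <- c("closer", "middle", "farther")

#' Per-band ratio time courses from a pixel-wise ratio map
#'
#' For each frame and band, the mean of the defined ratio pixels within the
#' band (mean-of-ratios). The number of contributing pixels is recorded per
#' frame. For the classifier the package uses the region-mean form
#' ([region_mean_ratio()]), which divides the average YPet intensity by the
#' average ECFP intensity over the band; this function summarizes the
#' display-oriented pixel-wise map.
#'
#' @param ratio_map H x W x T ratio array from [compute_ratio_map()].
#' @param part A [region_partition()] congruent with the map.
#' @param frame_interval Time between frames in s (for the `time_s` column).
#' @return A data frame with columns `frame`, `time_s`, `r_closer`,
#'   `r_middle`, `r_farther`, `n_closer`, `n_middle`, `n_farther`.
#' @export
extract_region_timecourses <- function(ratio_map, part, frame_interval = 1) {
  stopifnot(inherits(part, "region_partition"))
  if (!all(dim(ratio_map)[1:2] == dim(part$closer)))
    stop_param("partition is not congruent with the ratio map")
  nt <- dim(ratio_map)[3]
  out <- data.frame(frame = seq_len(nt),
                    time_s = (seq_len(nt) - 1) * frame_interval)
  for (rn in region_names) {
    m <- part[[rn]]
    vals <- apply(ratio_map, 3, function(fr) {
      v <- fr[m]
      v <- v[!is.na(v)]
      if (!length(v)) return(c(NA_real_, 0))
      c(mean(v), length(v))
    })
    bad <- which(vals[2, ] == 0)
    if (length(bad))
      stop_param("region '%s' has no defined ratio pixels in frame %d",
                 rn, bad[1])
    out[[paste0("r_", rn)]] <- vals[1, ]
    out[[paste0("n_", rn)]] <- as.integer(vals[2, ])
  }
  out
}

#' Per-band ratio time courses as ratio of region means
#'
#' The band ratio is computed per frame by dividing the average acceptor
#' (YPet) intensity over the band by the average donor (ECFP) intensity,
#' restricted to pixels where the donor exceeds `donor_floor`. This is the
#' form the response classifier consumes.
#'
#' @param stack A background-corrected [channel_stack()].
#' @param part A [region_partition()].
#' @param donor_floor Minimum donor counts for a pixel to contribute.
#' @return A data frame in the same layout as
#'   [extract_region_timecourses()].
#' @export
region_mean_ratio <- function(stack, part, donor_floor = 1) {
  stopifnot(inherits(stack, "channel_stack"),
            inherits(part, "region_partition"))
  if (!all(dim(stack$donor)[1:2] == dim(part$closer)))
    stop_param("partition is not congruent with the stack")
  nt <- dim(stack$donor)[3]
  out <- data.frame(frame = seq_len(nt),
                    time_s = (seq_len(nt) - 1) * stack$frame_interval)
  for (rn in region_names) {
    m <- part[[rn]]
    r <- numeric(nt); np <- integer(nt)
    for (f in seq_len(nt)) {
      don <- stack$donor[, , f][m]
      acc <- stack$acceptor[, , f][m]
      ok <- don > donor_floor
      if (!any(ok))
        stop_param("region '%s' has no defined ratio pixels in frame %d",
                   rn, f)
      r[f] <- mean(acc[ok]) / mean(don[ok])
      np[f] <- sum(ok)
    }
    out[[paste0("r_", rn)]] <- r
    out[[paste0("n_", rn)]] <- np
  }
  out
}

#' Pick a background ROI automatically
#'
#' Selects the corner block of the field of view that is free of the cell
#' mask and farthest from the probe tip, mirroring the manual choice of a
#' region not covered by the cells and away from the probe.
#'
#' @param cell_mask Logical H x W cell mask.
#' @param probe_position Probe center `c(x, y)` in um.
#' @param pixel_size um per pixel.
#' @param size_px Side of the square corner block in pixels.
#' @return A logical H x W matrix.
#' @export
auto_background_roi <- function(cell_mask, probe_position, pixel_size,
                                size_px = 6) {
  h <- nrow(cell_mask); w <- ncol(cell_mask)
  s <- min(size_px, h, w)
  corners <- list(c(1, 1), c(1, w - s + 1), c(h - s + 1, 1),
                  c(h - s + 1, w - s + 1))
  best <- NULL; best_d <- -Inf
  for (cn in corners) {
    rows <- cn[1]:(cn[1] + s - 1); cols <- cn[2]:(cn[2] + s - 1)
    if (any(cell_mask[rows, cols])) next
    ctr <- c((mean(cols) - 1) * pixel_size, (mean(rows) - 1) * pixel_size)
    d <- sqrt(sum((ctr - probe_position)^2))
    if (d > best_d) { best_d <- d; best <- list(rows = rows, cols = cols) }
  }
  if (is.null(best))
    stop_param("no cell-free corner block available for the background ROI")
  roi <- matrix(FALSE, h, w)
  roi[best$rows, best$cols] <- TRUE
  roi
}
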