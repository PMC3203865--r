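#' Circular cell phantom with a probe positioned at its edge
#'
#' Builds the footprint of a synthetic cell (a disc of the typical ~125 um
#' diameter) in an image, and places the probe center beyond the cell edge
#' along the downward image axis, separated from the edge by
#' `edge_to_probe_distance` (the 13 um working gap of the stimulation
#' device) plus the probe radius.
#'
#' @param image_shape `c(H, W)` in pixels.
#' @param pixel_size um per pixel.
#' @param diameter Cell diameter in um.
#' @param centroid Cell center `c(x, y)` in um; defaults to the image
#'   center.
#' @param edge_to_probe_distance Gap between cell edge and probe edge (um).
#' @param probe_radius Probe tip radius (um).
#' @return An object of class `cell_phantom` with fields `mask`, `centroid`,
#'   `diameter`, `pixel_size`, `probe_position`, `edge_to_probe_distance`,
#'   `probe_radius`.
#' @export
cell_phantom <- function(image_shape = c(56, 56), pixel_size = 2.5,
                         diameter = 125, centroid = NULL,
                         edge_to_probe_distance = 13, probe_radius = 25) {
  if (diameter <= 0) stop_param("'diameter' must be > 0")
  if (is.null(centroid))
    centroid <- (rev(image_shape) - 1) / 2 * pixel_size
  co <- pixel_coords(image_shape, pixel_size)
  mask <- (co$x - centroid[1])^2 + (co$y - centroid[2])^2 <= (diameter / 2)^2
  if (!any(mask)) stop_param("cell phantom falls outside the image")
  probe_position <- centroid +
    c(0, diameter / 2 + edge_to_probe_distance + probe_radius)
  structure(list(mask = mask, centroid = centroid, diameter = diameter,
                 pixel_size = pixel_size, probe_position = probe_position,
                 edge_to_probe_distance = edge_to_probe_distance,
                 probe_radius = probe_radius),
            class = "cell_phantom")
}

#' Ground-truth calcium response model for a phantom cell
#'
#' Describes the spatiotemporal calcium signal to imprint on a phantom:
#' an amplitude profile decaying with distance from the stimulation-proximal
#' cell edge (length scale `spatial_decay`; effectively infinite for a
#' global, cell-wide response) and a rise-then-exponential-recovery time
#' kernel. Class defaults: a global response rises by 0.4 cell-wide, a
#' local response rises by 0.4 at the proximal edge with a 25 um decay, and
#' a non-responsive cell stays below the 10% classification threshold.
#'
#' @param true_class One of `"global"`, `"local"`, `"none"`.
#' @param peak_relative_increase Fractional calcium-signal rise at the
#'   stimulation-proximal edge; must stay below 0.1 for `"none"`.
#' @param spatial_decay Decay length of the amplitude from the proximal
#'   edge, in um (`Inf` = uniform).
#' @param rise_time,recovery_time Kernel time constants in s
#'   (`rise_time < recovery_time`).
#' @param stimulus_frame 1-based index of the first stimulated frame.
#' @return An object of class `response_model`.
#' @export
response_model <- function(true_class = c("global", "local", "none"),
                           peak_relative_increase = NULL,
                           spatial_decay = NULL,
                           rise_time = 3, recovery_time = 20,
                           stimulus_frame = 10) {
  true_class <- match.arg(true_class)
  peak_relative_increase <- peak_relative_increase %||%
    switch(true_class, global = 0.4, local = 0.4, none = 0.03)
  spatial_decay <- spatial_decay %||%
    switch(true_class, global = Inf, local = 25, none = Inf)
  if (peak_relative_increase < 0)
    stop_param("'peak_relative_increase' must be >= 0")
  if (true_class == "none" && peak_relative_increase >= 0.1)
    stop_param("a 'none' phantom requires peak_relative_increase < 0.1")
  if (spatial_decay <= 0) stop_param("'spatial_decay' must be > 0")
  if (rise_time <= 0 || recovery_time <= 0 || rise_time >= recovery_time)
    stop_param("need 0 < rise_time < recovery_time")
  structure(list(true_class = true_class,
                 peak_relative_increase = peak_relative_increase,
                 spatial_decay = spatial_decay, rise_time = rise_time,
                 recovery_time = recovery_time,
                 stimulus_frame = as.integer(stimulus_frame)),
            class = "response_model")
}

#' Acquisition model for synthetic FRET movies
#'
#' Detector and optics parameters of the emulated time-lapse: frame timing,
#' pixel size, per-channel gains (counts at resting calcium), background
#' counts, resting YPet/ECFP ratio, and the noise model. At the default
#' gains the Poisson shot noise gives a per-pixel ratio coefficient of
#' variation of about 5%.
#'
#' @param frame_interval s between frames.
#' @param pixel_size um per pixel.
#' @param background_level Background counts added to every pixel.
#' @param donor_gain,acceptor_gain Resting-signal amplitude in counts.
#' @param baseline_ratio Resting YPet/ECFP ratio (dimensionless).
#' @param noise `"poisson"` for shot noise on counts, `"none"` to disable.
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(frame_interval = 2, pixel_size = 2.5,
                              background_level = 100, donor_gain = 800,
                              acceptor_gain = 800, baseline_ratio = 1.2,
                              noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  vals <- c(frame_interval, pixel_size, background_level, donor_gain,
            acceptor_gain, baseline_ratio)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_param("all acquisition parameters must be strictly positive")
  structure(list(frame_interval = frame_interval, pixel_size = pixel_size,
                 background_level = background_level, donor_gain = donor_gain,
                 acceptor_gain = acceptor_gain,
                 baseline_ratio = baseline_ratio, noise = noise),
            class = "acquisition_model")
}

# Rise-then-recovery kernel on post-stimulus time tau (s), normalized to a
# peak of 1: k(tau) = (1 - exp(-tau/a)) * exp(-tau/b) / k_max.
response_kernel <- function(tau, rise, recovery) {
  k <- (1 - exp(-tau / rise)) * exp(-tau / recovery)
  tau_star <- rise * log((rise + recovery) / rise)
  k_max <- (1 - exp(-tau_star / rise)) * exp(-tau_star / recovery)
  k / k_max
}

#' Generate a two-channel FRET movie of a phantom cell
#'
#' The per-pixel calcium signal is `c(x, t) = A(x) * k(t)`, with
#' `A(x) = peak_relative_increase * exp(-s(x) / spatial_decay)`, `s(x)` the
#' distance from the stimulation-proximal cell edge measured along the
#' probe-to-centroid axis, and `k(t)` a rise-then-exponential-recovery
#' kernel normalized to peak 1. The acceptor channel scales as `(1 + c)`
#' and the donor as `1 / (1 + c)`, so the YPet/ECFP ratio rises
#' monotonically with calcium (as `(1 + c)^2` times the resting ratio).
#' Background counts are added everywhere and pixels outside the mask carry
#' background only; Poisson shot noise is applied when the acquisition
#' model requests it.
#'
#' @param cell A [cell_phantom()].
#' @param resp A [response_model()].
#' @param acq An [acquisition_model()] (its `pixel_size` must match the
#'   phantom's).
#' @param n_frames Number of frames (must exceed `resp$stimulus_frame`).
#' @param seed Integer seed; fixed seeds give bit-identical movies.
#' @return A [channel_stack()] with attribute `ground_truth`: a list with
#'   `true_class`, the noise-free per-band realized ratio increases
#'   (`realized_increase`), and the generator parameters.
#' @export
generate_fret_movie <- function(cell, resp, acq = acquisition_model(),
                                n_frames = 45, seed = 1) {
  stopifnot(inherits(cell, "cell_phantom"), inherits(resp, "response_model"),
            inherits(acq, "acquisition_model"))
  if (resp$stimulus_frame >= n_frames)
    stop_param("'stimulus_frame' (%d) must be < n_frames (%d)",
               resp$stimulus_frame, n_frames)
  if (abs(acq$pixel_size - cell$pixel_size) > 1e-9)
    stop_param("acquisition and phantom pixel sizes differ")
  dim_hw <- dim(cell$mask)
  co <- pixel_coords(dim_hw, cell$pixel_size)
  ax <- cell$centroid - cell$probe_position
  ax <- ax / sqrt(sum(ax^2))
  proj <- (co$x - cell$probe_position[1]) * ax[1] +
    (co$y - cell$probe_position[2]) * ax[2]
  s <- proj - min(proj[cell$mask])           # distance from proximal edge
  A <- matrix(0, dim_hw[1], dim_hw[2])
  A[cell$mask] <- resp$peak_relative_increase *
    exp(-s[cell$mask] / resp$spatial_decay)
  tau <- pmax((seq_len(n_frames) - resp$stimulus_frame), 0) *
    acq$frame_interval
  k <- ifelse(tau > 0, response_kernel(tau, resp$rise_time,
                                       resp$recovery_time), 0)
  donor <- acceptor <- array(0, c(dim_hw, n_frames))
  for (f in seq_len(n_frames)) {
    cc <- A * k[f]
    don <- ifelse(cell$mask, acq$donor_gain / (1 + cc), 0)
    acc <- ifelse(cell$mask, acq$acceptor_gain * acq$baseline_ratio * (1 + cc),
                  0)
    donor[, , f] <- don + acq$background_level
    acceptor[, , f] <- acc + acq$background_level
  }
  # realized noise-free per-band ratio increases (ratio of band means after
  # background removal), the quantity the classifier will estimate
  part <- partition_regions(cell$mask, cell$probe_position, cell$pixel_size)
  realized <- sapply(region_names, function(rn) {
    m <- part[[rn]]
    r <- sapply(seq_len(n_frames), function(f) {
      cc <- A[m] * k[f]
      mean(acq$acceptor_gain * acq$baseline_ratio * (1 + cc)) /
        mean(acq$donor_gain / (1 + cc))
    })
    base <- mean(r[seq_len(resp$stimulus_frame - 1)])
    (max(r[resp$stimulus_frame:n_frames]) - base) / base
  })
  if (acq$noise == "poisson") {
    set.seed(as.integer(seed))
    donor <- array(rpois(length(donor), donor), dim(donor))
    acceptor <- array(rpois(length(acceptor), acceptor), dim(acceptor))
  }
  stack <- channel_stack(donor, acceptor, acq$pixel_size, acq$frame_interval,
                         resp$stimulus_frame)
  attr(stack, "ground_truth") <- list(
    true_class = resp$true_class,
    realized_increase = realized,
    response = unclass(resp), acquisition = unclass(acq), seed = seed)
  stack
}

#' Generate a cohort of phantom movies with multinomial class labels
#'
#' Draws a ground-truth response class for each cell from the multinomial
#' distribution `(p_global, p_local, p_none)` and generates one FRET movie
#' per cell with the per-class response template. Per-cell seeds are
#' derived deterministically from `seed` (seed + cell index), so the whole
#' cohort is bit-reproducible.
#'
#' @param p Numeric length-3 class probabilities `(global, local, none)`;
#'   must sum to 1 within 1e-9.
#' @param n_cells Number of cells (>= 1).
#' @param cell A [cell_phantom()] shared by all cells.
#' @param templates Named list of [response_model()]s for `global`, `local`,
#'   `none`.
#' @param acq An [acquisition_model()].
#' @param n_frames Frames per movie.
#' @param seed Integer seed.
#' @param classes Optional character vector of ground-truth classes, one
#'   per cell, bypassing the multinomial draw (for fixed-composition
#'   cohorts); its length overrides `n_cells`.
#' @return A list with one element per cell: `list(stack, true_class, seed)`.
#' @export
generate_cohort <- function(p, n_cells, cell = cell_phantom(),
                            templates = list(global = response_model("global"),
                                             local = response_model("local"),
                                             none = response_model("none")),
                            acq = acquisition_model(), n_frames = 45,
                            seed = 1, classes = NULL) {
  if (is.null(classes)) {
    if (length(p) != 3L || any(p < 0))
      stop_param("'p' must be 3 non-negative probabilities (global, local, none)")
    if (abs(sum(p) - 1) > 1e-9)
      stop_param("'p' must sum to 1 (got %g)", sum(p))
    if (n_cells < 1) stop_param("'n_cells' must be >= 1")
    set.seed(as.integer(seed))
    classes <- sample(c("global", "local", "none"), n_cells, replace = TRUE,
                      prob = p)
  } else {
    if (!all(classes %in% c("global", "local", "none")))
      stop_param("'classes' must be global/local/none labels")
    n_cells <- length(classes)
    if (n_cells < 1) stop_param("'n_cells' must be >= 1")
  }
  lapply(seq_len(n_cells), function(i) {
    cell_seed <- as.integer(seed) + i
    stack <- generate_fret_movie(cell, templates[[classes[i]]], acq,
                                 n_frames = n_frames, seed = cell_seed)
    list(stack = stack, true_class = classes[i], seed = cell_seed)
  })
}
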