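#' Phenomenological model of the substrate displacement field
#'
#' Describes the peak displacement pattern the vibrating probe imprints on
#' the gel surface: the displacement magnitude rises from the probe edge,
#' peaks (around 13-14 um) at a distance `peak_offset` (around 13 um) from
#' the edge, and decays exponentially beyond it, becoming negligible at the
#' far edge of a typical cell footprint. The direction of displacement is a
#' fixed unit vector (the probe is driven along one axis). This is a
#' descriptive fit to the measured maps, not a mechanical gel model; all
#' parameters are user-settable.
#'
#' @param probe_position Planar probe-center coordinates `c(x, y)` in um.
#' @param probe_radius Probe tip radius in um (tip diameter approximately
#'   50 um, so default 25).
#' @param peak_displacement Maximum substrate displacement in um.
#' @param peak_offset Distance from the probe edge at which the displacement
#'   peaks, in um.
#' @param decay_length Exponential decay scale beyond the peak, in um.
#' @param direction Unit vector of the dominant displacement (normalized
#'   internally).
#' @param edge_value Fraction of the peak displacement carried by the gel at
#'   the probe edge itself (the profile rises linearly from this value to 1
#'   at `peak_offset`).
#' @return An object of class `substrate_field_model`.
#' @export
substrate_field_model <- function(probe_position = c(0, 0), probe_radius = 25,
                                  peak_displacement = 13.5, peak_offset = 13,
                                  decay_length = 30, direction = c(1, 0),
                                  edge_value = 0.6) {
  if (peak_displacement < 0) stop_param("'peak_displacement' must be >= 0")
  if (decay_length <= 0) stop_param("'decay_length' must be > 0")
  if (peak_offset <= 0) stop_param("'peak_offset' must be > 0")
  if (probe_radius < 0) stop_param("'probe_radius' must be >= 0")
  if (edge_value < 0 || edge_value > 1)
    stop_param("'edge_value' must lie in [0, 1]")
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0)
    stop_param("'direction' must be a nonzero 2-vector")
  structure(
    list(probe_position = as.numeric(probe_position),
         probe_radius = probe_radius,
         peak_displacement = peak_displacement, peak_offset = peak_offset,
         decay_length = decay_length, direction = direction / nrm,
         edge_value = edge_value),
    class = "substrate_field_model"
  )
}

# Dimensionless radial profile g(d) and its derivative, d = distance from
# the probe edge (um). Rises linearly from edge_value at d = 0 to 1 at
# peak_offset, then decays as exp(-(d - peak_offset) / decay_length).
field_profile <- function(model, d) {
  off <- model$peak_offset; len <- model$decay_length; ev <- model$edge_value
  ifelse(d <= off,
         ev + (1 - ev) * d / off,
         exp(-(d - off) / len))
}

field_profile_deriv <- function(model, d) {
  off <- model$peak_offset; len <- model$decay_length; ev <- model$edge_value
  ifelse(d <= off,
         (1 - ev) / off,
         -exp(-(d - off) / len) / len)
}

#' Evaluate the analytic substrate displacement (and its gradient)
#'
#' Evaluates `u(r) = peak_displacement * g(d(r)) * direction` at arbitrary
#' points, where `d(r)` is the distance from the probe edge. With
#' `gradient = TRUE` the closed-form spatial derivatives of both components
#' are returned as well, which serves as the exact oracle for the
#' finite-difference strain computation.
#'
#' @param model A [substrate_field_model()].
#' @param x,y Point coordinates in um (recycled together).
#' @param gradient If `TRUE`, also return `dux_dx`, `dux_dy`, `duy_dx`,
#'   `duy_dy`.
#' @return A list with components `ux`, `uy` (um) and optionally the four
#'   gradient components (dimensionless).
#' @export
substrate_displacement <- function(model, x, y, gradient = FALSE) {
  stopifnot(inherits(model, "substrate_field_model"))
  dx <- x - model$probe_position[1]
  dy <- y - model$probe_position[2]
  r <- sqrt(dx^2 + dy^2)
  d <- pmax(r - model$probe_radius, 0)
  g <- field_profile(model, d)
  mag <- model$peak_displacement * g
  out <- list(ux = mag * model$direction[1], uy = mag * model$direction[2])
  if (gradient) {
    gp <- field_profile_deriv(model, d)
    # d(d)/dx = dx / r outside the probe, 0 at/inside the probe edge
    inv_r <- ifelse(r > model$probe_radius, 1 / r, 0)
    dmag_dx <- model$peak_displacement * gp * dx * inv_r
    dmag_dy <- model$peak_displacement * gp * dy * inv_r
    out$dux_dx <- dmag_dx * model$direction[1]
    out$dux_dy <- dmag_dy * model$direction[1]
    out$duy_dx <- dmag_dx * model$direction[2]
    out$duy_dy <- dmag_dy * model$direction[2]
  }
  out
}

#' Specify a regular sampling grid
#'
#' @param xlim,ylim Ranges in um, `c(min, max)`.
#' @param spacing Grid step h in um.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(xlim, ylim, spacing) {
  if (spacing <= 0) stop_param("'spacing' must be > 0")
  if (diff(xlim) <= 0 || diff(ylim) <= 0)
    stop_param("'xlim' and 'ylim' must be increasing ranges")
  structure(list(xlim = as.numeric(xlim), ylim = as.numeric(ylim),
                 spacing = spacing), class = "grid_spec")
}

# Construct a displacement_field container. u_x, u_y are matrices indexed
# [iy, ix] (image convention: rows follow grid_y).
displacement_field <- function(grid_x, grid_y, u_x, u_y, spacing,
                               analytic = NULL) {
  stopifnot(length(grid_y) == nrow(u_x), length(grid_x) == ncol(u_x),
            all(dim(u_x) == dim(u_y)))
  structure(list(grid_x = grid_x, grid_y = grid_y, u_x = u_x, u_y = u_y,
                 spacing = spacing, analytic = analytic),
            class = "displacement_field")
}

#' Sample the analytic substrate field on a grid
#'
#' Evaluates the model displacement on a regular grid and returns it
#' together with the closed-form gradient, so finite-difference strain
#' estimates can be checked against an exact oracle.
#'
#' @param model A [substrate_field_model()].
#' @param grid A [grid_spec()]. The grid must resolve the decay length:
#'   `spacing <= decay_length / 2`.
#' @return A `displacement_field` with fields `grid_x`, `grid_y` (um),
#'   `u_x`, `u_y` (um, matrices indexed `[iy, ix]`), `spacing`, and
#'   `analytic` (the exact gradient components on the same grid).
#' @export
generate_displacement_field <- function(model = substrate_field_model(),
                                        grid) {
  stopifnot(inherits(model, "substrate_field_model"),
            inherits(grid, "grid_spec"))
  if (grid$spacing > model$decay_length / 2)
    stop_param("grid spacing %g um too coarse for decay_length %g um (max %g)",
               grid$spacing, model$decay_length, model$decay_length / 2)
  gx <- seq(grid$xlim[1], grid$xlim[2], by = grid$spacing)
  gy <- seq(grid$ylim[1], grid$ylim[2], by = grid$spacing)
  X <- matrix(gx, length(gy), length(gx), byrow = TRUE)
  Y <- matrix(gy, length(gy), length(gx))
  u <- substrate_displacement(model, X, Y, gradient = TRUE)
  displacement_field(
    gx, gy,
    matrix(u$ux, length(gy), length(gx)),
    matrix(u$uy, length(gy), length(gx)),
    grid$spacing,
    analytic = list(dux_dx = matrix(u$dux_dx, length(gy), length(gx)),
                    dux_dy = matrix(u$dux_dy, length(gy), length(gx)),
                    duy_dx = matrix(u$duy_dx, length(gy), length(gx)),
                    duy_dy = matrix(u$duy_dy, length(gy), length(gx)))
  )
}

# Evaluate a displacement source at arbitrary (x, y) um. Accepts a
# substrate_field_model (analytic), a function(x, y) -> list(ux, uy), or a
# length-2 numeric (uniform translation in um).
eval_displacement <- function(field, x, y) {
  if (inherits(field, "substrate_field_model")) {
    substrate_displacement(field, x, y)
  } else if (is.function(field)) {
    field(x, y)
  } else if (is.numeric(field) && length(field) == 2L) {
    list(ux = rep(field[1], length(x)), uy = rep(field[2], length(x)))
  } else {
    stop_param("unsupported displacement source of class '%s'",
               paste(class(field), collapse = "/"))
  }
}

# Render Gaussian spots of sd psf_sigma (um) at continuous positions onto an
# H x W pixel grid; returns counts (before noise).
render_beads <- function(pos_x, pos_y, dim_hw, pixel_size, psf_sigma,
                         peak_counts, background) {
  img <- matrix(background, dim_hw[1], dim_hw[2])
  half <- ceiling(4 * psf_sigma / pixel_size)
  for (i in seq_along(pos_x)) {
    ci <- pos_x[i] / pixel_size + 1   # fractional col index
    ri <- pos_y[i] / pixel_size + 1
    cols <- max(1, floor(ci) - half):min(dim_hw[2], ceiling(ci) + half)
    rows <- max(1, floor(ri) - half):min(dim_hw[1], ceiling(ri) + half)
    if (!length(cols) || !length(rows)) next
    dxs <- ((cols - 1) * pixel_size - pos_x[i]) / psf_sigma
    dys <- ((rows - 1) * pixel_size - pos_y[i]) / psf_sigma
    spot <- peak_counts * outer(exp(-dys^2 / 2), exp(-dxs^2 / 2))
    img[rows, cols] <- img[rows, cols] + spot
  }
  img
}

#' Generate a fiducial-bead image pair under a displacement field
#'
#' Emulates the bead layer at the gel surface: beads are placed by a seeded
#' uniform point process, rendered as Gaussian spots, and the displaced
#' image moves each bead by the field evaluated at its reference position.
#' The per-bead ground-truth displacements are returned alongside the
#' images.
#'
#' @param field Displacement source: a [substrate_field_model()], a
#'   function `(x, y) -> list(ux, uy)`, or a length-2 numeric uniform
#'   translation (um).
#' @param bead_density Beads per square um (> 0).
#' @param psf_sigma Gaussian spot standard deviation in um.
#' @param image_spec List with `width_px`, `height_px`, `pixel_size` (um).
#' @param seed Integer seed; fixed seeds give bit-identical output.
#' @param peak_counts Peak bead intensity above background, in counts.
#' @param background Background level in counts.
#' @param noise Add Poisson shot noise to both images (`TRUE` by default).
#' @return A list with `reference` and `displaced` count images (H x W
#'   matrices), `beads` (data frame `x_um`, `y_um`, `ux_um`, `uy_um`), and
#'   `pixel_size`.
#' @export
generate_bead_images <- function(field, bead_density = 0.03, psf_sigma = 0.8,
                                 image_spec = list(width_px = 160,
                                                   height_px = 160,
                                                   pixel_size = 1),
                                 seed = 1, peak_counts = 2000,
                                 background = 100, noise = TRUE) {
  if (bead_density <= 0) stop_param("'bead_density' must be > 0")
  if (sqrt(1 / bead_density) < 4 * psf_sigma)
    warning("bead spots denser than resolvable (mean spacing < 4 * psf_sigma)")
  w_um <- (image_spec$width_px - 1) * image_spec$pixel_size
  h_um <- (image_spec$height_px - 1) * image_spec$pixel_size
  n <- max(1L, round(bead_density * w_um * h_um))
  set.seed(as.integer(seed))
  px <- runif(n, 0, w_um)
  py <- runif(n, 0, h_um)
  u <- eval_displacement(field, px, py)
  dim_hw <- c(image_spec$height_px, image_spec$width_px)
  ref <- render_beads(px, py, dim_hw, image_spec$pixel_size, psf_sigma,
                      peak_counts, background)
  disp <- render_beads(px + u$ux, py + u$uy, dim_hw, image_spec$pixel_size,
                       psf_sigma, peak_counts, background)
  if (isTRUE(noise)) {
    ref <- matrix(rpois(length(ref), ref), nrow(ref), ncol(ref))
    disp <- matrix(rpois(length(disp), disp), nrow(disp), ncol(disp))
  }
  list(reference = ref, displaced = disp,
       beads = data.frame(x_um = px, y_um = py, ux_um = u$ux, uy_um = u$uy),
       pixel_size = image_spec$pixel_size)
}
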