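#' Finite-difference derivative along a sampled axis
#'
#' Central (3-point) differences at interior nodes,
#' `(v[i+1] - v[i-1]) / (2h)`, and one-sided 2-point differences at the two
#' boundary nodes. Exact for linear data; interior accuracy O(h^2),
#' boundary O(h). `NA` values propagate through any stencil that touches
#' them.
#'
#' @param v Numeric vector of samples (length >= 3).
#' @param h Sample spacing.
#' @return Numeric vector of derivative estimates, same length as `v`.
#' @examples
#' finite_difference(c(0, 1, 2), 1)         # exact: 1 1 1
#' finite_difference(c(0, 1, 4), 1)         # x^2 on 0:2 -> 1 2 3
#' @export
finite_difference <- function(v, h) {
  n <- length(v)
  if (n < 3L) stop_param("finite differences need at least 3 samples")
  if (h <= 0) stop_param("'h' must be > 0")
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) / h
  d[n] <- (v[n] - v[n - 1]) / h
  i <- 2:(n - 1)
  d[i] <- (v[i + 1] - v[i - 1]) / (2 * h)
  d
}

# Row-wise derivative across columns (d/dx) and column-wise down rows (d/dy)
fd_along_x <- function(M, h) t(apply(M, 1, finite_difference, h = h))
fd_along_y <- function(M, h) apply(M, 2, finite_difference, h = h)

#' Strain field from a gridded displacement field
#'
#' Normal strain components `E_x = du_x/dx` and `E_y = du_y/dy` via the
#' 2-point boundary / 3-point interior finite-difference scheme, and the
#' total strain magnitude `E = sqrt(E_x^2 + E_y^2)`. Undefined displacement
#' nodes (`NA`) propagate to any strain node whose stencil touches them.
#'
#' @param field A `displacement_field` (see
#'   [generate_displacement_field()], [interpolate_field()]) on a grid of
#'   at least 3 x 3 nodes.
#' @return An object of class `strain_field` with matrices `E_x`, `E_y`,
#'   `E` and the grid coordinates.
#' @export
displacement_to_strain <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  if (nrow(field$u_x) < 3L || ncol(field$u_x) < 3L)
    stop_param("strain computation needs at least a 3 x 3 grid")
  E_x <- fd_along_x(field$u_x, field$spacing)
  E_y <- fd_along_y(field$u_y, field$spacing)
  structure(list(E_x = E_x, E_y = E_y, E = sqrt(E_x^2 + E_y^2),
                 grid_x = field$grid_x, grid_y = field$grid_y,
                 spacing = field$spacing),
            class = "strain_field")
}

# Local maxima above `threshold` (strictly greater than the 8 neighbors),
# excluding a border margin; returns a 2-column matrix (row, col).
detect_spots <- function(img, threshold, margin) {
  h <- nrow(img); w <- ncol(img)
  if (h < 2 * margin + 3 || w < 2 * margin + 3) return(cbind(integer(0), integer(0)))
  rows <- (margin + 1):(h - margin)
  cols <- (margin + 1):(w - margin)
  core <- img[rows, cols]
  is_max <- core > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & core > img[rows + dr, cols + dc]
  }
  idx <- which(is_max, arr.ind = TRUE)
  cbind(row = rows[idx[, 1]], col = cols[idx[, 2]])
}

# Gaussian-windowed normalized cross-correlation: pixels near the template
# center dominate, so neighboring beads inside the template bias the match
# far less than with a flat window.
ncc_score <- function(a, b, w) {
  ma <- sum(w * a); mb <- sum(w * b)
  va <- sum(w * a * a) - ma^2
  vb <- sum(w * b * b) - mb^2
  if (va <= 0 || vb <= 0) return(0)
  (sum(w * a * b) - ma * mb) / sqrt(va * vb)
}

gaussian_window <- function(half, sigma) {
  d <- (-half):half
  w <- outer(exp(-d^2 / (2 * sigma^2)), exp(-d^2 / (2 * sigma^2)))
  w / sum(w)
}

# Normalized-median test (universal outlier detection for PIV vector
# fields): per bead, the residual of each displacement component against
# the median over the k nearest neighbors, normalized by the median
# absolute neighbor residual plus a 0.1 px noise floor.
median_test_keep <- function(x, y, ux, uy, k = 8, tol = 2, eps = 0.1) {
  n <- length(x)
  k <- min(k, n - 1L)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  diag(d2) <- Inf
  keep <- logical(n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(k)]
    norm_res <- function(u) {
      med <- median(u[nb])
      r_nb <- median(abs(u[nb] - med))
      abs(u[i] - med) / (r_nb + eps)
    }
    keep[i] <- norm_res(ux) <= tol && norm_res(uy) <= tol
  }
  keep
}

# Parabolic sub-sample refinement from three scores around the maximum.
parabolic_offset <- function(sm, s0, sp) {
  den <- sm - 2 * s0 + sp
  if (den >= 0) return(0)  # not a proper peak
  off <- 0.5 * (sm - sp) / den
  max(min(off, 0.5), -0.5)
}

#' Track fiducial beads between a reference and a displaced frame
#'
#' Beads are detected in the reference image as local intensity maxima
#' above a threshold; each is matched in the displaced image by normalized
#' cross-correlation of a `window`-sized template over a `search`-sized
#' neighborhood, with parabolic sub-pixel refinement of the correlation
#' peak. Matches scoring below `min_score` are discarded.
#'
#' @param reference,displaced Congruent numeric image matrices.
#' @param window Odd template size in px (default 15).
#' @param search Odd search extent in px (default 31).
#' @param min_score Minimum normalized correlation for a valid match.
#' @param threshold Detection intensity threshold; default
#'   `median + 10 * mad` of the reference image.
#' @param pixel_size um per pixel (for the um-scaled output columns).
#' @param weight_sigma Standard deviation (px) of the Gaussian weighting
#'   applied to the correlation window, concentrating the match on the
#'   central bead; in a displacement field with strong spatial gradients a
#'   flat window would average neighboring beads into the estimate and
#'   bias displacement extrema toward their surroundings.
#' @param reject_outliers Apply the normalized-median outlier test
#'   (universal PIV outlier detection): a bead whose displacement deviates
#'   from the median of its `outlier_k` nearest neighbors by more than
#'   `outlier_tol` normalized residuals is discarded. This removes the
#'   occasional wrong-bead match when similar spot constellations fall
#'   inside the same search window.
#' @param outlier_k,outlier_tol Neighborhood size and threshold of the
#'   median test.
#' @return An object of class `bead_set`: a data frame with reference
#'   positions (`x_um`, `y_um` and pixel equivalents), displacements
#'   (`ux_um`, `uy_um`, `ux_px`, `uy_px`) and `score`.
#' @export
track_beads <- function(reference, displaced, window = 15, search = 31,
                        min_score = 0.5, threshold = NULL, pixel_size = 1,
                        weight_sigma = 2, reject_outliers = TRUE,
                        outlier_k = 8, outlier_tol = 2) {
  if (!all(dim(reference) == dim(displaced)))
    stop_param("reference and displaced images must be congruent")
  if (window %% 2 == 0 || search %% 2 == 0)
    stop_param("'window' and 'search' must be odd")
  threshold <- threshold %||% (median(reference) + 10 * mad(reference))
  hw <- (window - 1) %/% 2
  hs <- (search - 1) %/% 2
  spots <- detect_spots(reference, threshold, margin = hw + hs)
  if (nrow(spots) == 0L)
    stop_param("no beads detected in the reference image")
  res <- matrix(NA_real_, nrow(spots), 5)  # ux, uy (px), score, x, y (px)
  offs <- -hs:hs
  wgt <- gaussian_window(hw, sigma = weight_sigma)
  for (i in seq_len(nrow(spots))) {
    r0 <- spots[i, 1]; c0 <- spots[i, 2]
    tmpl <- reference[(r0 - hw):(r0 + hw), (c0 - hw):(c0 + hw)]
    scores <- matrix(-Inf, length(offs), length(offs))
    for (iy in seq_along(offs)) for (ix in seq_along(offs)) {
      rr <- r0 + offs[iy]; cc <- c0 + offs[ix]
      patch <- displaced[(rr - hw):(rr + hw), (cc - hw):(cc + hw)]
      scores[iy, ix] <- ncc_score(tmpl, patch, wgt)
    }
    best <- which(scores == max(scores), arr.ind = TRUE)[1, ]
    s0 <- scores[best[1], best[2]]
    if (s0 < min_score) next
    dy <- offs[best[1]]; dx <- offs[best[2]]
    refine <- s0 < 1 - 1e-9  # a perfect integer-offset match needs none
    if (refine && best[1] > 1 && best[1] < length(offs))
      dy <- dy + parabolic_offset(scores[best[1] - 1, best[2]], s0,
                                  scores[best[1] + 1, best[2]])
    if (refine && best[2] > 1 && best[2] < length(offs))
      dx <- dx + parabolic_offset(scores[best[1], best[2] - 1], s0,
                                  scores[best[1], best[2] + 1])
    res[i, ] <- c(dx, dy, s0, c0 - 1, r0 - 1)
  }
  keep <- !is.na(res[, 3])
  if (!any(keep))
    stop_param("no bead matched above min_score = %g", min_score)
  res <- res[keep, , drop = FALSE]
  if (isTRUE(reject_outliers) && nrow(res) > 4L) {
    ok <- median_test_keep(res[, 4], res[, 5], res[, 1], res[, 2],
                           k = outlier_k, tol = outlier_tol)
    if (any(ok)) res <- res[ok, , drop = FALSE]
  }
  structure(
    data.frame(x_px = res[, 4], y_px = res[, 5],
               x_um = res[, 4] * pixel_size, y_um = res[, 5] * pixel_size,
               ux_px = res[, 1], uy_px = res[, 2],
               ux_um = res[, 1] * pixel_size, uy_um = res[, 2] * pixel_size,
               score = res[, 3]),
    class = c("bead_set", "data.frame"))
}

#' Interpolate scattered bead displacements onto a regular grid
#'
#' Piecewise-linear (Delaunay barycentric) interpolation of the bead
#' displacement components onto the grid. Linear interpolation reproduces
#' affine fields exactly; nodes outside the convex hull of the beads are
#' flagged undefined (`NA`).
#'
#' With `smoothing = "tps"` each component is instead fit with a
#' penalized thin-plate regression spline (smoothness chosen by GCV) and
#' evaluated on the grid, with the same convex-hull flagging. The penalty
#' null space is affine, so affine fields are still reproduced, while the
#' sub-pixel tracking noise — which would otherwise be amplified into
#' spurious strain across short bead-to-bead baselines — is suppressed.
#' This regularized variant feeds the strain pipeline ([cmd_strain()]).
#'
#' @param beads A [track_beads()] result, or any data frame with columns
#'   `x_um`, `y_um`, `ux_um`, `uy_um`.
#' @param grid A [grid_spec()].
#' @param smoothing `"none"` (pure piecewise-linear interpolation) or
#'   `"tps"` (penalized thin-plate spline).
#' @return A `displacement_field`.
#' @export
interpolate_field <- function(beads, grid, smoothing = c("none", "tps")) {
  smoothing <- match.arg(smoothing)
  stopifnot(inherits(grid, "grid_spec"))
  need <- c("x_um", "y_um", "ux_um", "uy_um")
  if (!all(need %in% names(beads)))
    stop_param("'beads' must have columns %s", paste(need, collapse = ", "))
  if (nrow(beads) < 4L)
    stop_param("need at least 4 beads for interpolation (got %d)",
               nrow(beads))
  xy <- cbind(beads$x_um, beads$y_um)
  sv <- svd(scale(xy, center = TRUE, scale = FALSE))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop_param("degenerate bead geometry: positions are collinear")
  gx <- seq(grid$xlim[1], grid$xlim[2], by = grid$spacing)
  gy <- seq(grid$ylim[1], grid$ylim[2], by = grid$spacing)
  comp <- lapply(c("ux_um", "uy_um"), function(col) {
    z <- interp::interp(x = beads$x_um, y = beads$y_um, z = beads[[col]],
                        xo = gx, yo = gy, method = "linear",
                        duplicate = "mean", output = "grid")
    t(z$z)  # interp returns [x, y]; transpose to image convention [y, x]
  })
  if (smoothing == "tps") {
    hull_na <- is.na(comp[[1]])  # convex-hull flags from the linear pass
    df <- data.frame(x = beads$x_um, y = beads$y_um,
                     ux = beads$ux_um, uy = beads$uy_um)
    nodes <- expand.grid(y = gy, x = gx)
    kb <- min(60L, nrow(df) - 1L)
    comp <- lapply(c("ux", "uy"), function(col) {
      fit <- mgcv::gam(stats::reformulate(sprintf("s(x, y, k = %d)", kb),
                                          response = col), data = df)
      m <- matrix(mgcv::predict.gam(fit, newdata = nodes),
                  length(gy), length(gx))
      m[hull_na] <- NA_real_
      m
    })
  }
  displacement_field(gx, gy, comp[[1]], comp[[2]], grid$spacing)
}

#' Summaries of a displacement or strain field
#'
#' Maximum magnitude and its location over the defined grid nodes,
#' optionally restricted to a cell footprint. For a `displacement_field`
#' the summary reports `max_displacement_um`; for a `strain_field`,
#' `max_strain` (dimensionless).
#'
#' @param field A `displacement_field` or `strain_field`.
#' @param footprint Optional restriction: a logical matrix congruent with
#'   the grid, or a list `list(center = c(x, y), radius = r)` in um.
#' @return A list with the maximum, its grid location (`x_um`, `y_um`),
#'   and the number of defined nodes considered.
#' @export
summarize_field <- function(field, footprint = NULL) {
  if (inherits(field, "displacement_field")) {
    mag <- sqrt(field$u_x^2 + field$u_y^2)
    label <- "max_displacement_um"
  } else if (inherits(field, "strain_field")) {
    mag <- field$E
    label <- "max_strain"
  } else stop_param("unsupported field class")
  keep <- !is.na(mag)
  if (!is.null(footprint)) {
    if (is.list(footprint)) {
      X <- matrix(field$grid_x, length(field$grid_y), length(field$grid_x),
                  byrow = TRUE)
      Y <- matrix(field$grid_y, length(field$grid_y), length(field$grid_x))
      inside <- (X - footprint$center[1])^2 + (Y - footprint$center[2])^2 <=
        footprint$radius^2
    } else {
      if (!all(dim(footprint) == dim(mag)))
        stop_param("footprint mask not congruent with the field grid")
      inside <- footprint
    }
    keep <- keep & inside
  }
  if (!any(keep))
    stop_param("no defined grid nodes within the footprint")
  vals <- ifelse(keep, mag, -Inf)
  im <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  out <- list(x_um = field$grid_x[im[2]], y_um = field$grid_y[im[1]],
              n_nodes = sum(keep))
  out[[label]] <- mag[im[1], im[2]]
  out
}
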