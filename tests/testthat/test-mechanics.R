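# Finite differences, strain fields, bead tracking, interpolation.

test_that("finite differences use the 2-point/3-point stencils", {
  expect_equal(finite_difference(c(0, 1, 2), 1), c(1, 1, 1))
  # x^2 on 0:2 -> interior exact, boundaries carry the one-sided O(h) error
  expect_equal(finite_difference(c(0, 1, 4), 1), c(1, 2, 3))
  expect_equal(finite_difference(rep(3, 7), 0.5), rep(0, 7))
  expect_error(finite_difference(c(1, 2), 1), "3 samples")

  # linearity: D(a v + b w) = a D(v) + b D(w)
  set.seed(9)
  v <- stats::rnorm(12); w <- stats::rnorm(12)
  expect_equal(finite_difference(2 * v - 3 * w, 0.7),
               2 * finite_difference(v, 0.7) - 3 * finite_difference(w, 0.7))
})

test_that("strain fields follow the normal-strain formulas", {
  gx <- seq(0, 10, 1); gy <- seq(0, 8, 1)
  X <- matrix(gx, length(gy), length(gx), byrow = TRUE)
  Y <- matrix(gy, length(gy), length(gx))

  # u_x = 0.1 x, u_y = 0 -> E_x = 0.1, E_y = 0, E = 0.1 everywhere
  f1 <- mechfret:::displacement_field(gx, gy, 0.1 * X, 0 * X, 1)
  s1 <- displacement_to_strain(f1)
  expect_equal(s1$E_x, matrix(0.1, length(gy), length(gx)))
  expect_true(all(s1$E_y == 0))
  expect_equal(s1$E, matrix(0.1, length(gy), length(gx)))

  # u_x = 0.1 x, u_y = 0.1 y -> E = 0.1 sqrt(2)
  f2 <- mechfret:::displacement_field(gx, gy, 0.1 * X, 0.1 * Y, 1)
  expect_equal(displacement_to_strain(f2)$E,
               matrix(0.1 * sqrt(2), length(gy), length(gx)))

  # rigid translation leaves the strain unchanged
  f3 <- mechfret:::displacement_field(gx, gy, 0.1 * X + 5, 0.1 * Y - 2, 1)
  expect_equal(displacement_to_strain(f3)$E, displacement_to_strain(f2)$E)

  expect_error(displacement_to_strain(
    mechfret:::displacement_field(gx[1:2], gy, 0.1 * X[, 1:2],
                                  0 * X[, 1:2], 1)), "3 x 3")
})

test_that("finite-difference strain converges at O(h^2) to the analytic field", {
  m <- substrate_field_model(probe_position = c(80, 0))
  # a window strictly inside the exponential tail (d > peak_offset), where
  # the profile is smooth, so the interior stencil error scales as h^2
  err_at <- function(h) {
    f <- generate_displacement_field(m, grid_spec(c(60, 100), c(70, 110), h))
    s <- displacement_to_strain(f)
    interior_r <- 2:(length(f$grid_y) - 1)
    interior_c <- 2:(length(f$grid_x) - 1)
    max(abs((s$E_x - f$analytic$dux_dx)[interior_r, interior_c]))
  }
  e2 <- err_at(2); e1 <- err_at(1)
  expect_gt(e2 / e1, 3.5)
  expect_lt(e2 / e1, 4.5)

  # degree-1 fields are differentiated exactly (to float precision)
  gx <- seq(0, 20, 2); gy <- seq(0, 20, 2)
  X <- matrix(gx, length(gy), length(gx), byrow = TRUE)
  Y <- matrix(gy, length(gy), length(gx))
  fl <- mechfret:::displacement_field(gx, gy, 0.3 * X - 0.2 * Y + 1,
                                      0.1 * Y + 0.05 * X, 2)
  sl <- displacement_to_strain(fl)
  expect_equal(sl$E_x, matrix(0.3, length(gy), length(gx)),
               tolerance = 1e-12)
  expect_equal(sl$E_y, matrix(0.1, length(gy), length(gx)),
               tolerance = 1e-12)
})

test_that("identical images track to zero displacement", {
  pair <- generate_bead_images(c(0, 0), seed = 21)
  beads <- track_beads(pair$reference, pair$reference)
  expect_gt(nrow(beads), 20)
  expect_lt(max(abs(c(beads$ux_px, beads$uy_px))), 0.05)
  expect_true(all(beads$score > 0.99))
})

test_that("pure translation is recovered to sub-pixel accuracy", {
  pair <- generate_bead_images(c(3, 0), seed = 22)
  beads <- track_beads(pair$reference, pair$displaced)
  expect_equal(mean(beads$ux_px), 3, tolerance = 0.2 / 3)
  expect_lt(max(abs(beads$uy_px)), 0.3)
})

test_that("default-field bead displacements are accurate and complete", {
  m <- substrate_field_model(probe_position = c(80, 0))
  pair <- generate_bead_images(m, seed = 23)
  beads <- track_beads(pair$reference, pair$displaced)
  err <- bead_errors(beads, pair$beads)
  expect_lt(mean(err), 0.3)
  expect_error(track_beads(matrix(0, 64, 64), matrix(0, 64, 64)),
               "no beads")
})

test_that("interpolation reproduces uniform and linear fields exactly", {
  set.seed(5)
  n <- 40
  beads <- data.frame(x_um = runif(n, 0, 50), y_um = runif(n, 0, 50))
  g <- grid_spec(c(5, 45), c(5, 45), 5)

  # uniform displacement -> uniform grid field
  bu <- transform(beads, ux_um = 2, uy_um = -1)
  fu <- interpolate_field(bu, g)
  inside <- !is.na(fu$u_x)
  expect_true(all(abs(fu$u_x[inside] - 2) < 1e-9))
  expect_true(all(abs(fu$u_y[inside] + 1) < 1e-9))

  # linear field u_x = 0.1 x - 0.02 y: exact inside the hull
  bl <- transform(beads, ux_um = 0.1 * x_um - 0.02 * y_um,
                  uy_um = 0.03 * y_um)
  for (sm in c("none", "tps")) {
    fl <- interpolate_field(bl, g, smoothing = sm)
    ok <- !is.na(fl$u_x)
    X <- matrix(fl$grid_x, length(fl$grid_y), length(fl$grid_x),
                byrow = TRUE)
    Y <- matrix(fl$grid_y, length(fl$grid_y), length(fl$grid_x))
    expect_lt(max(abs((fl$u_x - (0.1 * X - 0.02 * Y))[ok])), 1e-6)
    expect_lt(max(abs((fl$u_y - 0.03 * Y)[ok])), 1e-6)
  }

  # collinear bead geometry is rejected
  bad <- data.frame(x_um = 1:3, y_um = 2 * (1:3) + 1,
                    ux_um = 0, uy_um = 0)
  expect_error(interpolate_field(bad, g), "4 beads")
  bad4 <- data.frame(x_um = 1:4, y_um = 2 * (1:4) + 1,
                     ux_um = 0, uy_um = 0)
  expect_error(interpolate_field(bad4, g), "collinear")
})

test_that("field summaries report maxima within a footprint", {
  m <- substrate_field_model(probe_position = c(80, 0))
  f <- generate_displacement_field(m, grid_spec(c(0, 160), c(0, 160), 2))
  s <- summarize_field(f)
  d <- sqrt((s$x_um - 80)^2 + s$y_um^2) - m$probe_radius
  expect_equal(s$max_displacement_um, 13.5, tolerance = 1e-6)
  expect_lt(abs(d - 13), f$spacing + 1e-9)

  f0 <- generate_displacement_field(
    substrate_field_model(peak_displacement = 0),
    grid_spec(c(0, 50), c(0, 50), 2))
  expect_equal(summarize_field(f0)$max_displacement_um, 0)

  # footprint with no defined nodes errors
  g <- grid_spec(c(0, 20), c(0, 20), 2)
  fna <- mechfret:::displacement_field(
    seq(0, 20, 2), seq(0, 20, 2),
    matrix(NA_real_, 11, 11), matrix(NA_real_, 11, 11), 2)
  expect_error(summarize_field(fna), "no defined")
})
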