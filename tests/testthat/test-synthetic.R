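# Generators: probe traces, displacement fields, bead pairs, FRET movies.

test_that("probe trace is a damped sinusoid with the configured spectrum", {
  tr <- generate_probe_trace(equipment_model(damping_time = Inf))
  expect_equal(dominant_frequency(tr), 140, tolerance = 2 / 140)
  expect_equal(peak_excursion(tr), 70, tolerance = 0.01)

  # zero amplitude -> identically zero trace
  tr0 <- generate_probe_trace(equipment_model(amplitude = 0))
  expect_true(all(tr0$displacement_um == 0))

  # 10 Hz undamped at 1 kHz: 10 zero-up-crossings per second
  tr10 <- generate_probe_trace(equipment_model(frequency = 10,
                                               sampling_rate = 1000,
                                               damping_time = Inf,
                                               duration = 1))
  v <- tr10$displacement_um
  ups <- sum(v[-1] > 0 & v[-length(v)] <= 0)
  expect_identical(ups, 10L)
})

test_that("probe trace energy decays across periods under damping", {
  md <- equipment_model(damping_time = 0.05, duration = 0.3)
  tr <- generate_probe_trace(md)
  per <- round(md$sampling_rate / md$frequency)
  n_per <- floor(nrow(tr) / per)
  energy <- vapply(seq_len(n_per), function(k) {
    sum(tr$displacement_um[((k - 1) * per + 1):(k * per)]^2)
  }, numeric(1))
  expect_true(all(diff(energy) < 0))
})

test_that("equipment model validates its parameters", {
  expect_error(equipment_model(frequency = -1), "frequency")
  expect_error(equipment_model(sampling_rate = 200), "Nyquist")
  expect_error(equipment_model(amplitude = -5), "amplitude")
})

test_that("displacement field peaks at the configured offset and decays", {
  m <- substrate_field_model(probe_position = c(80, 0))
  f <- generate_displacement_field(m, grid_spec(c(0, 160), c(0, 160), 1))
  s <- summarize_field(f)
  expect_equal(s$max_displacement_um, 13.5, tolerance = 0.01)
  d_peak <- sqrt((s$x_um - 80)^2 + s$y_um^2) - m$probe_radius
  expect_equal(d_peak, 13, tolerance = 1)  # within one grid step

  # negligible at the far edge of the cell footprint: exp(-125/30) < 2%
  far <- substrate_displacement(m, 80, m$probe_radius + 138)
  expect_lt(sqrt(far$ux^2 + far$uy^2), 0.02 * 13.5)

  # zero peak -> zero field and zero strain
  f0 <- generate_displacement_field(
    substrate_field_model(peak_displacement = 0),
    grid_spec(c(0, 100), c(0, 100), 2))
  expect_true(all(f0$u_x == 0) && all(f0$u_y == 0))
  expect_true(all(displacement_to_strain(f0)$E == 0))

  # too-coarse grid is rejected
  expect_error(generate_displacement_field(m, grid_spec(c(0, 100), c(0, 100),
                                                        20)),
               "too coarse")
})

test_that("analytic field gradient matches a central-difference check", {
  m <- substrate_field_model(probe_position = c(80, 0))
  f <- generate_displacement_field(m, grid_spec(c(20, 140), c(30, 140), 1))
  h <- f$spacing
  num <- t(apply(f$u_x, 1, finite_difference, h = h))
  interior <- 2:(ncol(num) - 1)
  # compare away from the profile kink at d = peak_offset
  X <- matrix(f$grid_x, length(f$grid_y), length(f$grid_x), byrow = TRUE)
  Y <- matrix(f$grid_y, length(f$grid_y), length(f$grid_x))
  d <- sqrt((X - 80)^2 + Y^2) - m$probe_radius
  smooth <- abs(d - m$peak_offset) > 3 * h & d > h
  err <- abs(num - f$analytic$dux_dx)[, interior]
  expect_lt(max(err[smooth[, interior]]), 5 * h^2)
})

test_that("bead image pairs carry exact ground truth and are reproducible", {
  spec <- list(width_px = 64, height_px = 64, pixel_size = 1)
  # zero field -> identical images
  p0 <- generate_bead_images(c(0, 0), bead_density = 0.01, image_spec = spec,
                             seed = 7, noise = FALSE)
  expect_identical(p0$reference, p0$displaced)

  # uniform translation -> every ground-truth displacement equal
  pt <- generate_bead_images(c(3, 0), bead_density = 0.01, image_spec = spec,
                             seed = 7, noise = FALSE)
  expect_true(all(pt$beads$ux_um == 3) && all(pt$beads$uy_um == 0))

  # determinism: same seed -> bit-identical images
  a <- generate_bead_images(c(1, 2), image_spec = spec, seed = 11)
  b <- generate_bead_images(c(1, 2), image_spec = spec, seed = 11)
  expect_identical(a, b)

  # unresolvable density warns
  expect_warning(generate_bead_images(c(0, 0), bead_density = 0.2,
                                      image_spec = spec, seed = 1),
                 "denser")
})

test_that("FRET movies realize the requested response pattern", {
  # non-responsive with zero amplitude, noise off: ratio constant in time
  ph <- make_phantom_movie("none", peak_relative_increase = 0)
  rmap <- compute_ratio_map(subtract_background(
    ph$stack, auto_background_roi(ph$cell$mask, ph$cell$probe_position,
                                  ph$cell$pixel_size)),
    ph$cell$mask)
  rng <- apply(rmap, c(1, 2), function(v) diff(range(v)))
  expect_lt(max(rng[ph$cell$mask]), 1e-12)

  # global phantom: identical relative increase in all three bands
  gl <- make_phantom_movie("global")
  inc <- attr(gl$stack, "ground_truth")$realized_increase
  expect_equal(unname(inc["farther"] / inc["closer"]), 1, tolerance = 1e-9)

  # local phantom: far-band increase well under half the close-band one
  lo <- make_phantom_movie("local")
  inc <- attr(lo$stack, "ground_truth")$realized_increase
  expect_lt(inc[["farther"]] / inc[["closer"]], 0.5)

  # determinism of the noisy movie
  m1 <- make_phantom_movie("global", noise = "poisson", seed = 3)$stack
  m2 <- make_phantom_movie("global", noise = "poisson", seed = 3)$stack
  expect_identical(m1, m2)
})

test_that("cohort sampling follows the multinomial class probabilities", {
  cell <- cell_phantom(image_shape = c(24, 24), pixel_size = 6,
                       diameter = 125)
  acq <- acquisition_model(pixel_size = 6)
  co <- generate_cohort(c(1, 0, 0), 5, cell = cell, acq = acq,
                        n_frames = 15, seed = 1)
  expect_identical(vapply(co, `[[`, "", "true_class"), rep("global", 5))

  # empirical fraction at n = 1000 within the binomial 99% band of 0.8
  tiny_cell <- cell_phantom(image_shape = c(16, 16), pixel_size = 9)
  big <- generate_cohort(c(0.8, 0.2, 0), 1000, cell = tiny_cell,
                         acq = acquisition_model(pixel_size = 9),
                         n_frames = 12, seed = 99)
  frac <- mean(vapply(big, `[[`, "", "true_class") == "global")
  expect_lt(abs(frac - 0.8), 0.04)

  expect_error(generate_cohort(c(0.5, 0.5, 0), 0), "n_cells")
  expect_error(generate_cohort(c(0.5, 0.6, 0), 5), "sum to 1")
  expect_error(generate_cohort(c(-0.1, 1.1, 0), 5), "non-negative")
})
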