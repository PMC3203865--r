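# Background subtraction, ratio maps, region partition, time courses.

test_that("background subtraction removes the ROI mean and clips at zero", {
  stack <- make_flat_stack(d = 100, a = 100)
  roi <- make_band_mask(c(20, 20), 1:3)
  out <- subtract_background(stack, roi)
  expect_true(all(out$donor == 0) && all(out$acceptor == 0))

  # cell pixel 500 over roi mean 100 -> 400
  stack2 <- make_flat_stack(d = 100, a = 100)
  stack2$donor[10, 10, ] <- 500
  out2 <- subtract_background(stack2, roi)
  expect_true(all(out2$donor[10, 10, ] == 400))

  # pixel 50 under roi mean 100 clips to 0 (not -50)
  stack3 <- make_flat_stack(d = 100, a = 100)
  stack3$donor[10, 10, ] <- 50
  out3 <- subtract_background(stack3, roi)
  expect_true(all(out3$donor[10, 10, ] == 0))

  # idempotent once the roi mean is zero
  expect_identical(subtract_background(out, roi), out)

  # roi overlapping the cell mask is rejected
  mask <- make_band_mask(c(20, 20), 2:12)
  expect_error(subtract_background(stack, roi, cell_mask = mask),
               "overlaps")
  expect_error(subtract_background(stack, matrix(FALSE, 20, 20)), "empty")
})

test_that("ratio maps guard the donor floor and flag undefined pixels", {
  stack <- make_flat_stack(d = 100, a = 200)
  mask <- make_band_mask(c(20, 20), 5:15)
  r <- compute_ratio_map(stack, mask)
  expect_true(all(r[, , 1][mask] == 2))
  expect_true(all(is.na(r[, , 1][!mask])))

  # donor 0 -> flagged undefined, no error
  stack$donor[6, 6, ] <- 0
  r2 <- compute_ratio_map(stack, mask)
  expect_true(all(is.na(r2[6, 6, ])))

  # everything below the floor is an empty result
  dead <- make_flat_stack(d = 0.5, a = 10)
  expect_error(compute_ratio_map(dead, mask), "donor_floor")
})

test_that("ratio of a noise-free non-responsive movie equals baseline_ratio", {
  ph <- make_phantom_movie("none", peak_relative_increase = 0)
  roi <- auto_background_roi(ph$cell$mask, ph$cell$probe_position,
                             ph$cell$pixel_size)
  r <- compute_ratio_map(subtract_background(ph$stack, roi), ph$cell$mask)
  expect_equal(max(abs(r[!is.na(r)] - ph$acq$baseline_ratio)), 0,
               tolerance = 1e-9)
})

test_that("partition splits a rectangle into three equal bands", {
  mask <- make_band_mask(c(100, 40), 6:95)  # 90 rows
  # probe below the mask (larger y), axis vertical
  part <- partition_regions(mask, probe_position = c(19.5, 120),
                            pixel_size = 1)
  expect_identical(sum(part$closer), 40L * 30L)
  expect_identical(sum(part$middle), 40L * 30L)
  expect_identical(sum(part$farther), 40L * 30L)
  # closer band is nearest the probe: its rows are the bottom ones
  expect_true(all(which(apply(part$closer, 1, any)) > 65))
  # partition property: disjoint union equals the mask
  expect_identical(part$closer | part$middle | part$farther, mask)
  expect_identical(sum(part$closer & part$middle), 0L)
})

test_that("partition of a disc matches closed-form circular segment areas", {
  cell <- cell_phantom(image_shape = c(300, 300), pixel_size = 0.5,
                       diameter = 125)
  part <- partition_regions(cell$mask, cell$probe_position, 0.5)
  R <- 125 / 2
  # area of { (x,y) in disc : x <= a } via the circular-segment formula
  seg <- function(a) R^2 * acos(-a / R) - (-a) * sqrt(R^2 - a^2)
  slab <- seg(-R / 3) / (pi * R^2)  # fraction in one outer slab
  areas <- c(sum(part$closer), sum(part$middle), sum(part$farther))
  fr <- areas / sum(areas)
  expect_equal(fr[1], slab, tolerance = 0.02)
  expect_equal(fr[3], slab, tolerance = 0.02)
  expect_equal(fr[2], 1 - 2 * slab, tolerance = 0.02)
})

test_that("partition is translation invariant and 90-degree equivariant", {
  mask <- matrix(FALSE, 60, 60)
  mask[15:40, 20:45] <- TRUE
  mask[15:20, 20:28] <- FALSE  # break symmetry
  probe <- c(32, 55)
  p0 <- partition_regions(mask, probe, 1)

  # rigid translation of mask + probe
  mask_t <- matrix(FALSE, 60, 60)
  mask_t[25:50, 25:50] <- TRUE
  mask_t[25:30, 25:33] <- FALSE
  p1 <- partition_regions(mask_t, probe + c(5, 10), 1)
  expect_identical(p1$closer[25:50, 25:50], p0$closer[15:40, 20:45])
  expect_identical(p1$farther[25:50, 25:50], p0$farther[15:40, 20:45])

  # 90-degree rotation (transpose + column flip rotates the image CW;
  # pixel (r, c) -> (c, H + 1 - r), i.e. (x, y) -> (H - 1 - y, x) in um)
  rot_img <- function(m) t(m)[, nrow(m):1]
  mask_r <- rot_img(mask)
  probe_r <- c(nrow(mask) - 1 - probe[2], probe[1])
  p2 <- partition_regions(mask_r, probe_r, 1)
  expect_identical(p2$closer, rot_img(p0$closer))
  expect_identical(p2$middle, rot_img(p0$middle))
  expect_identical(p2$farther, rot_img(p0$farther))
})

test_that("partition rejects degenerate geometry", {
  expect_error(partition_regions(make_band_mask(c(20, 20), 9:10),
                                 c(10, 19.5), 1), "degenerate")
  mask <- make_band_mask(c(20, 20), 5:15)
  expect_error(partition_regions(mask, c(10, 10), 1), "inside the cell")
})

test_that("region time courses summarize ratio maps per band", {
  stack <- make_flat_stack(d = 100, a = 200, dim_hw = c(30, 10))
  mask <- make_band_mask(c(30, 10), 2:28)
  part <- partition_regions(mask, c(4.5, 35), 1)
  r <- compute_ratio_map(stack, mask)
  tc <- extract_region_timecourses(r, part, frame_interval = 1)
  expect_true(all(abs(tc$r_closer - 2) < 1e-12))
  expect_true(all(abs(tc$r_farther - 2) < 1e-12))
  expect_identical(tc$n_closer + tc$n_middle + tc$n_farther,
                   rep(sum(mask), nrow(tc)))

  # a region losing all defined pixels raises a named error
  stack$donor[part$middle] <- 0  # kill frame-1 donor of the middle band
  r2 <- compute_ratio_map(stack, mask)
  expect_error(extract_region_timecourses(r2, part), "middle.*frame 1")
})

test_that("band ordering of rises matches the response geometry", {
  gl <- make_phantom_movie("global")
  part <- partition_regions(gl$cell$mask, gl$cell$probe_position,
                            gl$cell$pixel_size)
  roi <- auto_background_roi(gl$cell$mask, gl$cell$probe_position,
                             gl$cell$pixel_size)
  r <- compute_ratio_map(subtract_background(gl$stack, roi), gl$cell$mask)
  tc <- extract_region_timecourses(r, part, gl$stack$frame_interval)
  rise <- function(col) max(tc[[col]]) / tc[[col]][1] - 1
  expect_equal(rise("r_closer"), rise("r_farther"), tolerance = 1e-9)

  lo <- make_phantom_movie("local")
  r2 <- compute_ratio_map(subtract_background(lo$stack, roi), lo$cell$mask)
  tc2 <- extract_region_timecourses(r2, part, lo$stack$frame_interval)
  expect_gt(rise2 <- max(tc2$r_closer) / tc2$r_closer[1] - 1,
            max(tc2$r_middle) / tc2$r_middle[1] - 1)
  expect_gt(max(tc2$r_middle) / tc2$r_middle[1] - 1,
            max(tc2$r_farther) / tc2$r_farther[1] - 1)
})

test_that("mean-of-ratios equals ratio-of-means when the donor is constant", {
  ph <- make_phantom_movie("local")
  roi <- auto_background_roi(ph$cell$mask, ph$cell$probe_position,
                             ph$cell$pixel_size)
  corrected <- subtract_background(ph$stack, roi)
  # force a constant donor so the two region summaries must agree
  corrected$donor[] <- 500
  part <- partition_regions(ph$cell$mask, ph$cell$probe_position,
                            ph$cell$pixel_size)
  tc_mor <- extract_region_timecourses(
    compute_ratio_map(corrected, ph$cell$mask), part,
    corrected$frame_interval)
  tc_rom <- region_mean_ratio(corrected, part)
  expect_equal(tc_mor$r_closer, tc_rom$r_closer, tolerance = 1e-12)
  expect_equal(tc_mor$r_farther, tc_rom$r_farther, tolerance = 1e-12)
})
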