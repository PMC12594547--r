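# hand-built noise-free volume: constant slab between two axial pixels
slab_volume <- function(ny = 6, nz = 200, nx = 20, top = 40, bottom = 150,
                        n_repeats = 1, level_db = 0, floor_db = -60) {
  arr <- array(floor_db, c(n_repeats, ny, nz, nx))
  arr[, , top:bottom, ] <- level_db
  structure(list(stacks = arr,
                 geometry = scan_geometry(n_alines = nx, n_bscans = ny,
                                          n_repeats = n_repeats,
                                          n_depth = nz),
                 tissue_index = 1.376, seed = NA_integer_),
            class = "structural_volume")
}

test_that("average_repeats is the per-voxel mean and halves nothing else", {
  vol <- slab_volume(n_repeats = 3)
  avg <- average_repeats(vol)
  expect_equal(dim(avg$stacks), dim(vol$stacks)[-1])
  expect_equal(avg$stacks, vol$stacks[1, , , ])     # identical repeats
  # explicit two-repeat average
  v2 <- slab_volume(n_repeats = 2)
  v2$stacks[1, 1, 1, 1] <- 0; v2$stacks[2, 1, 1, 1] <- 2
  expect_equal(average_repeats(v2)$stacks[1, 1, 1], 1)
})

test_that("averaging independent exponential repeats shrinks the variance ~ 1/n", {
  set.seed(31)
  nrep <- 5; nvox <- 2e4
  stacks <- array(10 * log10(stats::rexp(nrep * nvox)),
                  c(nrep, 1, 200, 100))
  vol <- structure(list(stacks = stacks,
                        geometry = scan_geometry(n_alines = 100,
                                                 n_bscans = 1,
                                                 n_repeats = nrep,
                                                 n_depth = 200),
                        tissue_index = 1.376, seed = NA_integer_),
                   class = "structural_volume")
  # compare variances on the linear scale
  lin_avg <- colMeans(array(10^(stacks / 10), c(nrep, nvox)))
  v1 <- stats::var(as.vector(10^(stacks[1, , , ] / 10)))
  v5 <- stats::var(lin_avg)
  expect_within(v5 / v1, 1 / nrep, 0.05)
})

test_that("trim_stack removes the stated edges and only those", {
  vol <- slab_volume(ny = 20, nx = 30)
  trm <- trim_stack(vol, n_edge_frames = 4, n_edge_alines = 5)
  expect_equal(dim(trm$stacks), c(1, 12, 200, 20))  # repeat axis untouched
  expect_equal(dim(trim_stack(average_repeats(vol), 4, 5)$stacks),
               c(12, 200, 20))
  expect_equal(trim_stack(vol, 0, 0)$stacks, vol$stacks)  # identity
  expect_error(trim_stack(vol, 10, 0), "trim")
  # acquisition arithmetic at the instrument defaults
  expect_equal(alines_retained(scan_geometry()), 300L * 400L * 5L)
})

test_that("surfaces are found exactly on a noise-free slab", {
  vol <- slab_volume(top = 40, bottom = 150)
  surf <- detect_surfaces(average_repeats(vol))
  expect_true(all(surf$valid_mask))
  expect_true(all(surf$top_idx == 40))
  expect_true(all(surf$bottom_idx == 150))
  th <- thickness_from_surfaces(surf, vol$geometry, 1.376)
  expect_equal(th$mean_um, (150 - 40) * 5 / 1.376)
})

test_that("a uniform volume yields no valid surfaces", {
  vol <- slab_volume(level_db = -60)                # slab at the floor
  expect_warning(surf <- detect_surfaces(average_repeats(vol)),
                 "no detectable surface")
  expect_false(any(surf$valid_mask))
  expect_error(thickness_from_surfaces(surf, vol$geometry), "no valid")
})

test_that("surfaces on speckle phantoms track the truth within 2 px RMS", {
  spec <- small_structural_spec(seed = 21)
  out <- generate_structural_volume(spec)
  avg <- average_repeats(out$volume)
  surf <- detect_surfaces(avg)
  expect_gt(mean(surf$valid_mask), 0.99)
  truth_top <- out$truth$top_px[1, 1]
  truth_bot <- out$truth$bot_px[1, 1]
  rms_top <- sqrt(mean((surf$top_idx[surf$valid_mask] - truth_top)^2))
  rms_bot <- sqrt(mean((surf$bottom_idx[surf$valid_mask] - truth_bot)^2))
  expect_lt(rms_top, 2)
  expect_lt(rms_bot, 2)
})

test_that("pigmented patches are excluded with few false exclusions", {
  g <- small_structural_geometry()
  x_max <- (g$n_alines - 1) * g$lateral_pitch_x_um
  y_max <- (g$n_bscans - 1) * g$lateral_pitch_y_um
  # patch covering ~8% of the lateral field at 12 dB attenuation
  patch <- list(x0_um = 0.46 * x_max, x1_um = 0.54 * x_max,
                y0_um = 0, y1_um = y_max, attenuation = 10^(-1.2))
  spec <- phantom_spec(g, top_surface_um = 150, bottom_surface_um = 700,
                       pigment_patches = list(patch), seed = 13)
  out <- generate_structural_volume(spec)
  avg <- average_repeats(out$volume)
  surf <- detect_surfaces(avg)
  surf <- exclude_pigmented(avg, surf, percentile_cut = 0.10)
  pig <- t(matrix(out$truth$pigment_mask,
                  g$n_alines, g$n_bscans))           # frames x alines
  in_patch_excl <- mean(surf$pigment_excluded[pig])
  false_excl <- mean(surf$pigment_excluded[!pig])
  expect_gt(in_patch_excl, 0.90)
  expect_lt(false_excl, 0.02)
  # default phantom without patches stays under the 10% exclusion budget
  spec0 <- small_structural_spec(seed = 14)
  th0 <- measure_thickness(generate_structural_volume(spec0)$volume,
                           n_edge_frames = 4, n_edge_alines = 8)
  expect_lt(th0$excluded_fraction, 0.10)
})

test_that("a generous percentile cut excludes about that fraction", {
  spec <- small_structural_spec(seed = 15)
  avg <- average_repeats(generate_structural_volume(spec)$volume)
  surf <- detect_surfaces(avg)
  surf <- exclude_pigmented(avg, surf, percentile_cut = 0.20)
  expect_within(surf$excluded_fraction, 0.20, 0.02)
})

test_that("optical path converts to physical thickness via the tissue index", {
  surf <- structure(list(top_idx = matrix(1L, 2, 3),
                         bottom_idx = matrix(1L + round(550.4 / 5), 2, 3),
                         valid_mask = matrix(TRUE, 2, 3)),
                    class = "surface_pair")
  g <- scan_geometry(n_alines = 3, n_bscans = 2, n_depth = 200)
  th <- thickness_from_surfaces(surf, g, 1.376)
  expect_equal(th$mean_um, 550 / 1.376, tolerance = 0.01)
  # degenerate: coincident surfaces give zero thickness
  surf0 <- structure(list(top_idx = matrix(5L, 1, 2),
                          bottom_idx = matrix(5L, 1, 2),
                          valid_mask = matrix(TRUE, 1, 2)),
                     class = "surface_pair")
  expect_equal(thickness_from_surfaces(surf0, g, 1.376)$mean_um, 0)
})

test_that("thickness is invariant to global intensity scaling", {
  spec <- small_structural_spec(seed = 17)
  vol <- generate_structural_volume(spec)$volume
  th1 <- measure_thickness(vol, n_edge_frames = 4, n_edge_alines = 8)
  vol2 <- vol
  vol2$stacks <- vol2$stacks + 17            # dB offset = linear scaling
  th2 <- measure_thickness(vol2, n_edge_frames = 4, n_edge_alines = 8)
  expect_equal(th1$mean_um, th2$mean_um)
})

test_that("averaging and trimming commute", {
  spec <- small_structural_spec(seed = 19)
  vol <- generate_structural_volume(spec)$volume
  a <- trim_stack(average_repeats(vol), 4, 8)
  b <- average_repeats(trim_stack(vol, 4, 8))
  expect_equal(a$stacks, b$stacks)
})

test_that("more repeats do not worsen the mean thickness error", {
  errs <- sapply(c(1L, 5L), function(nrep) {
    mean(sapply(1:4, function(s) {
      g <- scan_geometry(n_alines = 64, n_bscans = 16, n_repeats = nrep,
                         n_depth = 220)
      spec <- phantom_spec(g, top_surface_um = 150, bottom_surface_um = 700,
                           intensity_noise = 0.3, seed = 100 + s)
      th <- measure_thickness(generate_structural_volume(spec)$volume,
                              n_edge_frames = 2, n_edge_alines = 4)
      abs(th$mean_um - 550)
    }))
  })
  expect_lte(errs[2], errs[1])
})
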