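test_that("structural phantom places interfaces and thickness by construction", {
  g <- scan_geometry(n_alines = 32, n_bscans = 8, n_repeats = 2,
                     n_depth = 250)
  spec <- phantom_spec(g, top_surface_um = 200, bottom_surface_um = 750,
                       intensity_noise = 0, seed = 3)
  out <- generate_structural_volume(spec)
  expect_true(all(out$truth$thickness_map_um == 550))
  expect_equal(dim(out$volume$stacks), c(2, 8, 250, 32))
  # interfaces in pixels follow the optical-path conversion
  expect_true(all(out$truth$top_px == 1 + round(200 * 1.376 / 5)))
  expect_true(all(out$truth$bot_px == 1 + round(750 * 1.376 / 5)))
})

test_that("phantom geometry validation rejects out-of-range interfaces", {
  g <- scan_geometry(n_alines = 16, n_bscans = 4, n_repeats = 1,
                     n_depth = 64)
  spec <- phantom_spec(g, top_surface_um = 100, bottom_surface_um = 700,
                       seed = 1)
  expect_error(generate_structural_volume(spec), "axial range")
  expect_error(phantom_spec(g, top_surface_um = 300,
                            bottom_surface_um = 200),
               "must exceed")
})

test_that("speckle is exponential with mean equal to the layer reflectivity", {
  g <- scan_geometry(n_alines = 64, n_bscans = 30, n_repeats = 1,
                     n_depth = 220)
  r <- 0.7
  spec <- phantom_spec(g, top_surface_um = 150, bottom_surface_um = 700,
                       layer_reflectivities = r, intensity_noise = 0,
                       phase_noise_rad = 0, seed = 11)
  out <- generate_structural_volume(spec)
  lin <- 10^(out$volume$stacks[1, , , ] / 10)
  # in-layer voxels, away from the quantized interfaces
  zr <- (out$truth$top_px[1, 1] + 2):(out$truth$bot_px[1, 1] - 2)
  vals <- as.vector(lin[, zr, ])
  expect_gt(length(vals), 1e5)
  expect_within(mean(vals), r, 0.01 * r)
  # exponential fit at the known rate (Kolmogorov-Smirnov)
  set.seed(42)
  ks <- stats::ks.test(sample(vals, 1e4), "pexp", 1 / r)
  expect_gt(ks$p.value, 0.01)
})

test_that("identical spec and seed give bit-identical synthetic data", {
  spec <- small_structural_spec(seed = 5)
  a <- generate_structural_volume(spec)
  b <- generate_structural_volume(spec)
  expect_identical(a$volume$stacks, b$volume$stacks)

  so <- small_oce_spec(seed = 7)
  expect_identical(generate_oce_dataset(so)$mb$phase,
                   generate_oce_dataset(so)$mb$phase)

  sa <- small_octa_spec(seed = 9)
  expect_identical(generate_octa_stack(sa)$stack$repeats,
                   generate_octa_stack(sa)$stack$repeats)

  d <- two_group_cohort_design()
  expect_identical(generate_cohort(d, seed = 3), generate_cohort(d, seed = 3))
})

test_that("the simulated wave is causal with the stated arrival times", {
  spec <- small_oce_spec(seed = 2, group_velocity_m_s = 2,
                         phase_noise_rad = 0)
  out <- generate_oce_dataset(spec)
  u <- out$truth$displacement_nm            # positions x time
  mb <- out$mb
  x <- mb$positions_um; t_s <- mb$times_s
  x0 <- mb$excitation_x_um
  tau <- abs(x - x0) * 1e-6 / 2             # arrival time at c = 2 m/s
  for (ip in seq(1, length(x), by = 13)) {
    before <- t_s < tau[ip] - 1e-12
    expect_true(all(u[ip, before] == 0))
  }
  # arrival-time difference between separated positions equals distance / c
  first_idx <- apply(u != 0, 1, function(z) which(z)[1])
  pitch <- diff(x)[1]
  sep <- round(400 / pitch)                 # ~0.4 mm in position samples
  i1 <- which(x > x0)[5]; i2 <- i1 + sep
  dt <- (first_idx[i2] - first_idx[i1]) / mb$geometry$aline_rate_hz
  true_dt <- (x[i2] - x[i1]) * 1e-6 / 2
  expect_within(dt, true_dt, 2 / mb$geometry$aline_rate_hz)
})

test_that("zero wave amplitude leaves the phase constant over time", {
  spec <- small_oce_spec(seed = 4, phase_noise_rad = 0)
  spec$wave$amplitude_nm <- 0
  mb <- generate_oce_dataset(spec)$mb
  expect_true(all(abs(mb$phase[, 2, ] - mb$phase[, 1, ]) < 1e-12))
})

test_that("stored phase is wrapped and unwrapping recovers the modulation", {
  # amplitude below the per-step wrap limit: recovery is near-exact
  spec <- small_oce_spec(seed = 6, phase_noise_rad = 0)
  out <- generate_oce_dataset(spec)
  expect_true(all(out$mb$phase > -pi & out$mb$phase <= pi))
  u <- displacement_from_phase(out$mb)
  zr <- out$mb$top_px[1] + 3                 # one in-tissue depth row
  rec <- u[, , zr]
  truth <- out$truth$displacement_nm
  rms_err <- sqrt(mean((rec - truth)^2)) / max(abs(truth))
  expect_lt(rms_err, 0.01)
})

test_that("vessel ground-truth mask matches the specified diameter", {
  spec <- small_octa_spec(seed = 1, diameters_um = 50, x_um = 600)
  out <- generate_octa_stack(spec)
  m <- out$truth$vessel_mask                 # [ny, nz, nx]
  g <- spec$geometry
  # lateral extent of the mask at mid-vessel depth
  widths <- apply(m, 1, function(sl) {
    cols <- which(apply(sl, 2, any))
    if (!length(cols)) 0 else diff(range(cols)) + 1
  })
  w_um <- mean(widths) * g$lateral_pitch_x_um
  expect_within(w_um, 50, g$lateral_pitch_x_um)
})

test_that("lumen voxels decorrelate between repeats and static ones do not", {
  # wide vessel so that whole 5x5 kernels fit inside the lumen
  spec <- small_octa_spec(seed = 8, diameters_um = 200, x_um = 600,
                          decorrelation = 1, intensity_noise = 0)
  out <- generate_octa_stack(spec)
  A <- out$stack$repeats[1, , , ]
  B <- out$stack$repeats[2, , , ]
  m <- out$truth$vessel_mask                 # [ny, nz, nx]
  expect_identical(A[!m], B[!m])             # zero noise: static is identical
  # kernel correlation for kernels fully inside the lumen averages near zero
  rs <- unlist(lapply(seq_len(dim(m)[1]), function(f) {
    msl <- m[f, , ]
    interior <- msl &
      dermoct:::boxsum(msl * 1, 5) == 25     # whole 5x5 window in-lumen
    if (!any(interior)) return(numeric(0))
    rm <- 1 - dermoct:::zncc_frames(A[f, , ], B[f, , ], 5)
    # zncc r = 1 - flow; recover r for the interior kernels
    (1 - rm)[interior]
  }))
  expect_gt(length(rs), 1e3)
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("zero decorrelation reproduces identical repeats up to noise", {
  spec <- small_octa_spec(seed = 10, decorrelation = 0, intensity_noise = 0)
  out <- generate_octa_stack(spec)
  expect_identical(out$stack$repeats[1, , , ], out$stack$repeats[3, , , ])
})

test_that("cohort generator honours the stated design", {
  # zero SD: every value equals its group mean
  d0 <- two_group_cohort_design(sd1 = 0, sd2 = 0)
  coh0 <- generate_cohort(d0, seed = 1)
  m28 <- coh0[coh0$group == "G2" & coh0$day == 28, "value"]
  expect_true(all(m28 == 1.6))
  # record count: n x groups x sites x days
  eff <- expand.grid(group = paste0("G", 1:4), day = c(0, 7, 28),
                     metric = "velocity_m_s", stringsAsFactors = FALSE)
  eff$mean <- 1.2; eff$sd <- 0.2
  coh <- generate_cohort(list(effects = eff, n_per_group = 15,
                              sites = c("top", "bottom")), seed = 2)
  expect_equal(nrow(coh), 15 * 4 * 2 * 3)
  # no duplicate cells
  expect_false(any(duplicated(coh[, c("animal_id", "site", "day", "metric")])))
})

test_that("sampled day-28 cohorts center on the pilot effect size", {
  d <- two_group_cohort_design(n_per_group = 6)
  # the bias-corrected sample g is (approximately) unbiased for the
  # population standardized difference (1.6 - 1.2) / pooled(0.3, 0.2)
  pop_delta <- 0.4 / pooled_sd(0.3, 6, 0.2, 6)
  gs <- vapply(1:1000, function(s) {
    coh <- generate_cohort(d, seed = s)
    d28 <- coh[coh$day == 28, ]
    v1 <- d28$value[d28$group == "G1"]; v2 <- d28$value[d28$group == "G2"]
    hedges_g(mean(v2), sd(v2), 6, mean(v1), sd(v1), 6)
  }, numeric(1))
  # MC standard error of the mean is ~0.02
  expect_within(mean(gs), pop_delta, 0.07)
  # and the pilot summaries themselves give the g = 1.45 anchor
  expect_equal(round(hedges_g(1.6, 0.3, 6, 1.2, 0.2, 6), 2), 1.45)
})
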