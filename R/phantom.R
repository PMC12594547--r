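#' Wave excitation parameters for an elastography phantom
#'
#' Describes the mechanical tone burst launched at the centre of the imaged
#' field by a non-contact acoustic radiation force source. The displacement
#' field realised by the phantom is a laterally propagating, exponentially
#' attenuated sine burst
#' \deqn{u(x,t) = A e^{-\alpha |x-x_0|} \sin(2\pi f (t - |x-x_0|/c))}
#' windowed to `n_pushes` cycles and identically zero before the arrival
#' time \eqn{|x - x_0|/c}.
#'
#' @param excitation_x_um lateral source position (um); `NULL` places the
#'   source at the field centre.
#' @param frequency_hz excitation frequency (Hz); typical protocol values
#'   are 1000, 5000 and 10000.
#' @param n_pushes number of burst cycles (1 = single push, 3 = push train).
#' @param group_velocity_m_s ground-truth propagation speed (m/s).
#' @param amplitude_nm peak axial displacement at the source (nm).
#' @param attenuation_per_mm exponential lateral amplitude decay (1/mm).
#' @return An object of class `wave_spec`.
#' @export
wave_spec <- function(excitation_x_um = NULL,
                      frequency_hz = 5000,
                      n_pushes = 1L,
                      group_velocity_m_s = 2.5,
                      amplitude_nm = 100,
                      attenuation_per_mm = 0.3) {
  if (group_velocity_m_s <= 0) stop("group_velocity_m_s must be > 0")
  if (frequency_hz <= 0) stop("frequency_hz must be > 0")
  if (!n_pushes %in% c(1L, 3L) && n_pushes < 1)
    stop("n_pushes must be a positive integer")
  if (amplitude_nm < 0) stop("amplitude_nm must be >= 0")
  structure(list(
    excitation_x_um = excitation_x_um,
    frequency_hz = frequency_hz,
    n_pushes = as.integer(n_pushes),
    group_velocity_m_s = group_velocity_m_s,
    amplitude_nm = amplitude_nm,
    attenuation_per_mm = attenuation_per_mm
  ), class = "wave_spec")
}

#' Vessel description for an angiography phantom
#'
#' A vessel is a tube of constant lumen diameter around a polyline
#' centerline given in physical volume coordinates (x = fast lateral,
#' y = slow lateral, z = depth below the tissue surface, all in um).
#' Voxels inside the lumen have a fraction `decorrelation` of their complex
#' scatterer amplitude independently resampled on every repeated B-scan,
#' emulating moving blood cells; `decorrelation = 1` is fully developed
#' flow, `0` is static tissue.
#'
#' @param centerline numeric matrix with columns x, y, z (um).
#' @param lumen_diameter_um ground-truth lumen diameter (um).
#' @param decorrelation fraction of signal resampled per repeat, in [0, 1].
#' @return An object of class `vessel_spec`.
#' @export
vessel_spec <- function(centerline, lumen_diameter_um, decorrelation = 1) {
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 3 || nrow(centerline) < 2)
    stop("centerline must be an n x 3 matrix (x, y, z in um) with n >= 2")
  if (lumen_diameter_um <= 0) stop("lumen_diameter_um must be > 0")
  if (decorrelation < 0 || decorrelation > 1)
    stop("decorrelation must be in [0, 1]")
  structure(list(centerline = centerline,
                 lumen_diameter_um = lumen_diameter_um,
                 decorrelation = decorrelation),
            class = "vessel_spec")
}

#' Straight vessel spanning the slow axis
#'
#' Convenience constructor for a vessel running parallel to the slow (y)
#' axis at a fixed lateral position and depth.
#'
#' @param x_um lateral position of the centerline (um).
#' @param z_um depth of the centerline below the top surface plane (um,
#'   physical depth from z = 0 of the volume).
#' @param geometry a [scan_geometry()] used to size the vessel extent.
#' @inheritParams vessel_spec
#' @return A `vessel_spec`.
#' @export
straight_vessel <- function(x_um, z_um, lumen_diameter_um, geometry,
                            decorrelation = 1) {
  y_max <- (geometry$n_bscans - 1) * geometry$lateral_pitch_y_um
  vessel_spec(rbind(c(x_um, 0, z_um), c(x_um, y_max, z_um)),
              lumen_diameter_um, decorrelation)
}

#' Full parameterisation of a synthetic OCT acquisition
#'
#' Bundles everything needed to simulate one acquisition: the scan geometry,
#' the two tissue interfaces (as constants or lateral maps, physical um),
#' the tissue group refractive index used for optical-path conversion,
#' per-layer backscatter levels, optional low-backscatter pigment patches,
#' the elastography wave, vessels, noise levels and the RNG seed. The same
#' spec and seed always produce bit-identical synthetic data.
#'
#' Speckle is modelled as fully developed: each voxel's complex scatterer
#' amplitude is circularly symmetric Gaussian with variance equal to the
#' local backscatter level, so the pre-log intensity is exponentially
#' distributed. Repeated scans share the scatterer realisation and differ
#' only by additive detection noise (and, for vessels, by resampled flow
#' voxels).
#'
#' @param geometry a [scan_geometry()].
#' @param top_surface_um,bottom_surface_um interface depths (um, physical):
#'   scalars or `n_alines x n_bscans` matrices. Bottom must exceed top
#'   everywhere.
#' @param tissue_index group refractive index of skin used to convert
#'   optical path to physical depth (dimensionless, default 1.376).
#' @param layer_reflectivities mean linear backscatter per sub-layer; the
#'   tissue slab between the interfaces is divided into equal bands, one
#'   per entry.
#' @param pigment_patches list of lateral rectangles, each a list with
#'   `x0_um`, `x1_um`, `y0_um`, `y1_um` and `attenuation` (linear factor
#'   < 1 multiplying backscatter).
#' @param wave a [wave_spec()].
#' @param vessels list of [vessel_spec()] objects.
#' @param phase_noise_rad SD of additive Gaussian phase noise (rad).
#' @param intensity_noise additive complex noise power (linear intensity
#'   units; also the backscatter level outside the tissue slab).
#' @param seed integer RNG seed recorded in all outputs.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(scan_geometry(n_alines = 64, n_bscans = 16,
#'                                    n_depth = 128))
#' @export
phantom_spec <- function(geometry = scan_geometry(),
                         top_surface_um = 150,
                         bottom_surface_um = 700,
                         tissue_index = 1.376,
                         layer_reflectivities = 1,
                         pigment_patches = list(),
                         wave = wave_spec(),
                         vessels = list(),
                         phase_noise_rad = 0.05,
                         intensity_noise = 0.01,
                         seed = 1L) {
  stopifnot(inherits(geometry, "scan_geometry"))
  if (tissue_index < 1) stop("tissue_index must be >= 1")
  if (phase_noise_rad < 0) stop("phase_noise_rad must be >= 0")
  if (intensity_noise < 0) stop("intensity_noise must be >= 0")
  if (any(layer_reflectivities <= 0))
    stop("layer_reflectivities must be > 0")
  top <- surface_map(top_surface_um, geometry, "top_surface_um")
  bot <- surface_map(bottom_surface_um, geometry, "bottom_surface_um")
  if (!all(bot > top))
    stop("bottom_surface_um must exceed top_surface_um everywhere")
  if (!is.null(wave)) stopifnot(inherits(wave, "wave_spec"))
  for (v in vessels) stopifnot(inherits(v, "vessel_spec"))
  structure(list(
    geometry = geometry,
    top_surface_um = top_surface_um,
    bottom_surface_um = bottom_surface_um,
    tissue_index = tissue_index,
    layer_reflectivities = layer_reflectivities,
    pigment_patches = pigment_patches,
    wave = wave,
    vessels = vessels,
    phase_noise_rad = phase_noise_rad,
    intensity_noise = intensity_noise,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# expand a scalar-or-matrix interface to an n_alines x n_bscans map
surface_map <- function(z, geometry, what) {
  if (is.matrix(z)) {
    if (!all(dim(z) == c(geometry$n_alines, geometry$n_bscans)))
      stop(what, " matrix must be n_alines x n_bscans")
    z
  } else {
    matrix(z, geometry$n_alines, geometry$n_bscans)
  }
}

wrap_phase <- function(phi) {
  # wrap to (-pi, pi]
  w <- phi - 2 * pi * floor((phi + pi) / (2 * pi))
  w[w <= -pi] <- pi
  w
}

# complex circular Gaussian field with per-element variance sigma2
cgauss <- function(n, sigma2) {
  complex(real = stats::rnorm(n, sd = sqrt(sigma2 / 2)),
          imaginary = stats::rnorm(n, sd = sqrt(sigma2 / 2)))
}

# backscatter volume [depth x alines x bscans] from interfaces, layers and
# pigment patches; floor = intensity_noise outside the tissue slab
reflectivity_volume <- function(spec) {
  g <- spec$geometry
  nz <- g$n_depth; nx <- g$n_alines; ny <- g$n_bscans
  top <- surface_map(spec$top_surface_um, g, "top_surface_um")
  bot <- surface_map(spec$bottom_surface_um, g, "bottom_surface_um")
  top_px <- matrix(depth_um_to_px(top, g, spec$tissue_index), nx, ny)
  bot_px <- matrix(depth_um_to_px(bot, g, spec$tissue_index), nx, ny)
  if (any(top_px < 1) || any(bot_px > nz))
    stop("interfaces outside axial range of the volume")
  atten <- pigment_attenuation_map(spec)
  nl <- length(spec$layer_reflectivities)
  r <- array(0, c(nz, nx, ny))
  z <- seq_len(nz)
  for (iy in seq_len(ny)) {
    tp <- top_px[, iy]; bp <- bot_px[, iy]
    # layer index of each (z, x): 0 outside slab, 1..nl inside
    zi <- outer(z, tp, ">=") & outer(z, bp, "<=")
    frac <- (outer(z, tp, "-")) / rep(pmax(bp - tp, 1L), each = nz)
    li <- pmin(nl, 1L + floor(frac * nl))
    vals <- matrix(0, nz, nx)
    vals[zi] <- spec$layer_reflectivities[li[zi]]
    r[, , iy] <- sweep(vals, 2, atten[, iy], `*`)
  }
  list(r = r, top_px = top_px, bot_px = bot_px,
       thickness_um = bot - top, pigment_mask = atten < 1)
}

pigment_attenuation_map <- function(spec) {
  g <- spec$geometry
  x_um <- (seq_len(g$n_alines) - 1) * g$lateral_pitch_x_um
  y_um <- (seq_len(g$n_bscans) - 1) * g$lateral_pitch_y_um
  atten <- matrix(1, g$n_alines, g$n_bscans)
  for (p in spec$pigment_patches) {
    ix <- x_um >= p$x0_um & x_um <= p$x1_um
    iy <- y_um >= p$y0_um & y_um <= p$y1_um
    atten[ix, iy] <- atten[ix, iy] * p$attenuation
  }
  atten
}

#' Simulate a repeated structural OCT volume
#'
#' Generates `n_repeats` log-scaled intensity stacks of a layered,
#' speckle-bearing tissue slab. The scatterer field is one complex circular
#' Gaussian realisation shared by all repeats (variance = local
#' backscatter), so pre-log intensity is exponential within a homogeneous
#' layer; repeats differ only by additive complex detection noise. The
#' interfaces, given in physical um, are placed at axial pixels via optical
#' path = physical depth x tissue refractive index. Pigment patches
#' multiply backscatter by their attenuation factor over their lateral
#' footprint.
#'
#' @param spec a [phantom_spec()].
#' @return A list with components `volume` (a `structural_volume`: field
#'   `stacks` is an `n_repeats x n_bscans x n_depth x n_alines` array of
#'   intensity in dB, plus `geometry`, `tissue_index`, `seed`) and `truth`
#'   (a `ground_truth` with `thickness_map_um`, `pigment_mask`, surface
#'   pixel maps).
#' @export
generate_structural_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$geometry
  set.seed(spec$seed)
  rv <- reflectivity_volume(spec)
  nz <- g$n_depth; nx <- g$n_alines; ny <- g$n_bscans; nr <- g$n_repeats
  field <- array(cgauss(nz * nx * ny, as.vector(rv$r)), c(nz, nx, ny))
  stacks <- array(NA_real_, c(nr, ny, nz, nx))
  for (k in seq_len(nr)) {
    noise <- if (spec$intensity_noise > 0)
      array(cgauss(nz * nx * ny, spec$intensity_noise), c(nz, nx, ny))
    else 0
    intens <- Mod(field + noise)^2
    stacks[k, , , ] <- aperm(intens, c(3, 1, 2))
  }
  stacks <- 10 * log10(stacks + 1e-12)
  volume <- structure(list(stacks = stacks, geometry = g,
                           tissue_index = spec$tissue_index,
                           seed = spec$seed),
                      class = "structural_volume")
  truth <- structure(list(thickness_map_um = rv$thickness_um,
                          top_px = rv$top_px, bot_px = rv$bot_px,
                          pigment_mask = rv$pigment_mask,
                          group_velocity_m_s = NA_real_,
                          vessel_mask = NULL,
                          lumen_diameters_um = numeric(0)),
                     class = "ground_truth")
  list(volume = volume, truth = truth)
}

# displacement field u(x, t) in nm for all positions (um) and times (s)
wave_displacement <- function(wave, x_um, t_s, x0_um) {
  dx_m <- abs(x_um - x0_um) * 1e-6
  tau <- dx_m / wave$group_velocity_m_s            # arrival time (s)
  amp <- wave$amplitude_nm *
    exp(-wave$attenuation_per_mm * abs(x_um - x0_um) / 1000)
  tt <- outer(-tau, t_s, `+`)                      # t - tau, pos x time
  burst <- sin(2 * pi * wave$frequency_hz * tt)
  dur <- wave$n_pushes / wave$frequency_hz
  burst[tt < 0 | tt > dur] <- 0
  amp * burst
}

#' Simulate a phase-sensitive M-B-mode elastography record
#'
#' At each of `n_bscans` lateral positions an M-mode series of `n_alines`
#' repeated A-lines is acquired at the A-line rate, capturing the transient
#' displacement wave launched at the excitation position (field centre by
#' default). The axial displacement modulates the interferometric phase by
#' \eqn{\Delta\phi = 4 \pi n u / \lambda}; the stored phase is the static
#' speckle phase plus this modulation plus Gaussian phase noise, wrapped to
#' \eqn{(-\pi, \pi]}. Depths above the top interface (air) carry no wave.
#'
#' @param spec a [phantom_spec()] with a non-null `wave`.
#' @return A list with `mb` (an `mb_series`: `phase` is a
#'   `positions x time x depth` array in rad, with `positions_um`,
#'   `times_s`, `excitation_x_um`, `top_px`, `geometry`, `tissue_index`,
#'   `wavelength_nm`, `seed`) and `truth` (a `ground_truth` whose
#'   `group_velocity_m_s` is the simulated speed).
#' @export
generate_oce_dataset <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(spec$wave)) stop("spec$wave must be specified")
  g <- spec$geometry
  w <- spec$wave
  if (w$frequency_hz > g$aline_rate_hz / 2)
    stop("excitation frequency above the Nyquist rate of the M-mode sampling")
  set.seed(spec$seed)
  np <- g$n_bscans          # M-mode images (lateral positions)
  nt <- g$n_alines          # A-lines per M-mode image (time samples)
  nz <- g$n_depth
  x_um <- (seq_len(np) - 1) * g$lateral_pitch_x_um
  t_s <- (seq_len(nt) - 1) / g$aline_rate_hz
  x0 <- if (is.null(w$excitation_x_um)) mean(range(x_um)) else w$excitation_x_um
  u <- wave_displacement(w, x_um, t_s, x0)         # np x nt, nm

  top <- surface_map(spec$top_surface_um, g, "top_surface_um")
  bot <- surface_map(spec$bottom_surface_um, g, "bottom_surface_um")
  iy <- max(1L, g$n_bscans %/% 2L)
  top_px <- depth_um_to_px(top[, iy], g, spec$tissue_index)[seq_len(min(np, nrow(top)))]
  if (length(top_px) < np) top_px <- rep_len(top_px, np)
  bot_px <- depth_um_to_px(bot[, iy], g, spec$tissue_index)[1]
  if (any(top_px < 1) || bot_px > nz)
    stop("interfaces outside axial range of the volume")

  lambda_nm <- g$center_wavelength_nm
  dphi <- 4 * pi * spec$tissue_index * u / lambda_nm   # np x nt, rad
  static <- matrix(stats::runif(np * nz, -pi, pi), np, nz)
  phase <- array(0, c(np, nt, nz))
  tissue <- outer(top_px, seq_len(nz), `<=`)           # np x nz logical
  for (it in seq_len(nt)) {
    ph <- static + dphi[, it] * tissue
    phase[, it, ] <- ph
  }
  if (spec$phase_noise_rad > 0)
    phase <- phase + array(stats::rnorm(length(phase),
                                        sd = spec$phase_noise_rad),
                           dim(phase))
  phase <- wrap_phase(phase)
  mb <- structure(list(phase = phase, positions_um = x_um, times_s = t_s,
                       excitation_x_um = x0, top_px = top_px,
                       geometry = g, tissue_index = spec$tissue_index,
                       wavelength_nm = lambda_nm, seed = spec$seed,
                       wave = w),
                  class = "mb_series")
  truth <- structure(list(group_velocity_m_s = w$group_velocity_m_s,
                          displacement_nm = u,
                          thickness_map_um = NULL, vessel_mask = NULL,
                          lumen_diameters_um = numeric(0),
                          pigment_mask = NULL),
                     class = "ground_truth")
  list(mb = mb, truth = truth)
}

# boolean vessel mask [n_bscans x n_depth x n_alines] in physical space;
# per_vessel = TRUE returns a list of masks, one per vessel
vessel_mask_volume <- function(spec, per_vessel = FALSE) {
  g <- spec$geometry
  nz <- g$n_depth; nx <- g$n_alines; ny <- g$n_bscans
  mask <- array(FALSE, c(ny, nz, nx))
  if (length(spec$vessels) == 0)
    return(if (per_vessel) list() else mask)
  masks <- vector("list", length(spec$vessels))
  x_um <- (seq_len(nx) - 1) * g$lateral_pitch_x_um
  y_um <- (seq_len(ny) - 1) * g$lateral_pitch_y_um
  z_um <- (seq_len(nz) - 1) * g$axial_pitch_um / spec$tissue_index
  # voxel coordinate arrays in [y, z, x] order
  Y <- array(rep(y_um, nz * nx), c(ny, nz, nx))
  Z <- array(rep(rep(z_um, each = ny), nx), c(ny, nz, nx))
  X <- array(rep(x_um, each = ny * nz), c(ny, nz, nx))
  for (vi in seq_along(spec$vessels)) {
    v <- spec$vessels[[vi]]
    cl <- v$centerline
    if (min(cl[, 1]) < min(x_um) - v$lumen_diameter_um ||
        max(cl[, 1]) > max(x_um) + v$lumen_diameter_um ||
        min(cl[, 3]) < 0 || max(cl[, 3]) > max(z_um))
      stop("vessel centerline outside the volume")
    d2 <- array(Inf, c(ny, nz, nx))
    for (s in seq_len(nrow(cl) - 1)) {
      p <- cl[s, ]; q <- cl[s + 1, ]
      vx <- q[1] - p[1]; vy <- q[2] - p[2]; vz <- q[3] - p[3]
      L2 <- vx^2 + vy^2 + vz^2
      tpar <- ((X - p[1]) * vx + (Y - p[2]) * vy + (Z - p[3]) * vz) / L2
      tpar[tpar < 0] <- 0; tpar[tpar > 1] <- 1
      dd <- (X - (p[1] + tpar * vx))^2 + (Y - (p[2] + tpar * vy))^2 +
        (Z - (p[3] + tpar * vz))^2
      d2 <- pmin(d2, dd)
    }
    masks[[vi]] <- d2 <= (v$lumen_diameter_um / 2)^2
    mask <- mask | masks[[vi]]
  }
  if (per_vessel) masks else mask
}

#' Simulate a repeated-B-scan angiography stack
#'
#' Static voxels keep one speckle realisation across all repeats (plus
#' detection noise); voxels inside a vessel lumen have a fraction
#' `decorrelation` of their complex amplitude independently resampled on
#' every repeat, so flowing blood decorrelates between repeated B-scans
#' while static tissue does not.
#'
#' @param spec a [phantom_spec()] with `geometry$n_repeats >= 2`.
#' @return A list with `stack` (an `angio_stack`: `repeats` is an
#'   `n_repeats x n_bscans x n_depth x n_alines` array of linear intensity)
#'   and `truth` (`ground_truth` with `vessel_mask`
#'   `[n_bscans x n_depth x n_alines]` and `lumen_diameters_um`).
#' @export
generate_octa_stack <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$geometry
  if (g$n_repeats < 2) stop("angiography requires >= 2 repeats")
  set.seed(spec$seed)
  rv <- reflectivity_volume(spec)
  nz <- g$n_depth; nx <- g$n_alines; ny <- g$n_bscans; nr <- g$n_repeats
  vmasks <- vessel_mask_volume(spec, per_vessel = TRUE)  # [ny, nz, nx] each
  mask_yzx <- array(FALSE, c(ny, nz, nx))
  for (m in vmasks) mask_yzx <- mask_yzx | m
  field <- array(cgauss(nz * nx * ny, as.vector(rv$r)), c(nz, nx, ny))
  # per-vessel voxel indices in [nz, nx, ny] order and decorrelation
  vidx <- lapply(vmasks, function(m) which(aperm(m, c(2, 3, 1))))
  vdec <- vapply(spec$vessels, function(v) v$decorrelation, numeric(1))
  repeats <- array(NA_real_, c(nr, ny, nz, nx))
  for (k in seq_len(nr)) {
    fk <- field
    for (vi in seq_along(vidx)) {
      idx <- vidx[[vi]]
      if (length(idx) && vdec[vi] > 0) {
        fresh <- cgauss(length(idx), rv$r[idx])
        fk[idx] <- sqrt(1 - vdec[vi]) * field[idx] +
          sqrt(vdec[vi]) * fresh
      }
    }
    noise <- if (spec$intensity_noise > 0)
      array(cgauss(nz * nx * ny, spec$intensity_noise), c(nz, nx, ny))
    else 0
    repeats[k, , , ] <- aperm(Mod(fk + noise)^2, c(3, 1, 2))
  }
  stack <- structure(list(repeats = repeats, geometry = g,
                          tissue_index = spec$tissue_index,
                          seed = spec$seed),
                     class = "angio_stack")
  truth <- structure(list(vessel_mask = mask_yzx,
                          lumen_diameters_um = vapply(
                            spec$vessels, `[[`, numeric(1),
                            "lumen_diameter_um"),
                          thickness_map_um = NULL,
                          group_velocity_m_s = NA_real_,
                          pigment_mask = NULL,
                          top_px = rv$top_px, bot_px = rv$bot_px),
                     class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Simulate a longitudinal cohort of per-animal measurements
#'
#' Draws long-format records (animal, group, site, day, metric, value) from
#' Gaussian distributions whose mean and SD are stated per
#' (group, day, metric) cell. The paired structure is preserved: each
#' animal carries a latent intercept shared across days and sites, scaled so
#' the stated SD is the marginal SD at every cell and `rho` is the
#' between-day correlation (when cell SDs are equal).
#'
#' @param design a list with `effects` (data.frame with columns `group`,
#'   `day`, `metric`, `mean`, `sd`), `n_per_group` (animals per group),
#'   `sites` (character vector, default `c("top", "bottom")`), and
#'   optionally `rho` (within-animal correlation, default 0.5).
#' @param seed integer RNG seed.
#' @return A data.frame of class `cohort_table` with columns `animal_id`,
#'   `group`, `site`, `day`, `metric`, `value`.
#' @examples
#' eff <- expand.grid(group = c("G1", "G2"), day = c(0, 28),
#'                    metric = "velocity_m_s", stringsAsFactors = FALSE)
#' eff$mean <- c(1.2, 1.2, 1.2, 1.6); eff$sd <- c(0.2, 0.2, 0.2, 0.3)
#' cohort <- generate_cohort(list(effects = eff, n_per_group = 6,
#'                                sites = "top"), seed = 1)
#' @export
generate_cohort <- function(design, seed) {
  eff <- design$effects
  stopifnot(is.data.frame(eff),
            all(c("group", "day", "metric", "mean", "sd") %in% names(eff)))
  n <- design$n_per_group
  if (is.null(n) || n < 1) stop("n_per_group must be >= 1")
  sites <- if (is.null(design$sites)) c("top", "bottom") else design$sites
  rho <- if (is.null(design$rho)) 0.5 else design$rho
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (any(eff$sd < 0)) stop("sd must be >= 0")
  set.seed(as.integer(seed))
  groups <- unique(eff$group)
  metrics <- unique(eff$metric)
  # latent per-animal standardised intercept, one per animal x metric
  out <- list(); i <- 0L
  for (gr in groups) {
    ids <- sprintf("%s_%02d", gr, seq_len(n))
    a <- matrix(stats::rnorm(n * length(metrics)), n, length(metrics),
                dimnames = list(ids, metrics))
    cells <- eff[eff$group == gr, , drop = FALSE]
    for (r in seq_len(nrow(cells))) {
      for (st in sites) {
        e <- stats::rnorm(n)
        val <- cells$mean[r] +
          sqrt(rho) * cells$sd[r] * a[, cells$metric[r]] +
          sqrt(1 - rho) * cells$sd[r] * e
        i <- i + 1L
        out[[i]] <- data.frame(animal_id = ids, group = gr, site = st,
                               day = cells$day[r], metric = cells$metric[r],
                               value = val, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cohort_table", "data.frame")
  attr(res, "seed") <- as.integer(seed)
  res
}

#' @export
print.phantom_spec <- function(x, ...) {
  g <- x$geometry
  cat("<phantom_spec>\n")
  cat(sprintf("  grid %d x %d x %d (x, y, z), %d repeats, seed %d\n",
              g$n_alines, g$n_bscans, g$n_depth, g$n_repeats, x$seed))
  cat(sprintf("  interfaces %s / %s um, n = %.3f\n",
              format(mean(surface_map(x$top_surface_um, g, "t"))),
              format(mean(surface_map(x$bottom_surface_um, g, "b"))),
              x$tissue_index))
  cat(sprintf("  %d vessel(s), %d pigment patch(es)\n",
              length(x$vessels), length(x$pigment_patches)))
  invisible(x)
}
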