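# Reduced-size phantom specs shared across the suite. Sizes are chosen so a
# full generate + analyse cycle stays around a second.

small_structural_geometry <- function(n_alines = 96L, n_bscans = 40L,
                                      n_repeats = 5L, n_depth = 220L) {
  scan_geometry(n_alines = n_alines, n_bscans = n_bscans,
                n_repeats = n_repeats, n_depth = n_depth)
}

small_structural_spec <- function(seed = 1L, ...) {
  phantom_spec(small_structural_geometry(),
               top_surface_um = 150, bottom_surface_um = 700,
               seed = seed, ...)
}

# M-B-mode phantom: n_alines = time samples, n_bscans = lateral positions
small_oce_spec <- function(seed = 1L, frequency_hz = 5000, n_pushes = 1L,
                           group_velocity_m_s = 2.5, phase_noise_rad = 0.05,
                           n_time = 160L, n_positions = 128L, ...) {
  g <- scan_geometry(n_alines = n_time, n_bscans = n_positions,
                     n_repeats = 1L, n_depth = 48L)
  phantom_spec(g, top_surface_um = 50, bottom_surface_um = 150,
               wave = wave_spec(frequency_hz = frequency_hz,
                                n_pushes = n_pushes,
                                group_velocity_m_s = group_velocity_m_s),
               phase_noise_rad = phase_noise_rad, seed = seed, ...)
}

small_octa_spec <- function(seed = 1L, diameters_um = c(40, 80),
                            decorrelation = 1,
                            x_um = c(400, 900), z_um = 200, ...) {
  g <- scan_geometry(n_alines = 128L, n_bscans = 64L, n_repeats = 5L,
                     n_depth = 96L)
  vessels <- mapply(function(d, x)
    straight_vessel(x_um = x, z_um = z_um, lumen_diameter_um = d, g,
                    decorrelation = decorrelation),
    diameters_um, x_um, SIMPLIFY = FALSE)
  phantom_spec(g, top_surface_um = 60, bottom_surface_um = 330,
               vessels = vessels, seed = seed, ...)
}

two_group_cohort_design <- function(mean1 = 1.2, sd1 = 0.2,
                                    mean2 = 1.6, sd2 = 0.3,
                                    n_per_group = 6, sites = "top") {
  eff <- expand.grid(group = c("G1", "G2"), day = c(0, 28),
                     metric = "velocity_m_s", stringsAsFactors = FALSE)
  eff$mean <- c(mean1, mean1, mean1, mean2)
  eff$sd <- c(sd1, sd1, sd1, sd2)
  list(effects = eff, n_per_group = n_per_group, sites = sites)
}

# -- independent oracles -----------------------------------------------------

# per-pixel loop implementation of the kernel ZNCC flow map for one frame
# pair; the production path uses box-filter sums instead
brute_flow_pair <- function(A, B, k) {
  h <- k %/% 2L
  nr <- nrow(A); nc <- ncol(A)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- max(1, i - h):min(nr, i + h)
      ci <- max(1, j - h):min(nc, j + h)
      a <- as.vector(A[ri, ci]); b <- as.vector(B[ri, ci])
      va <- stats::var(a) * (length(a) - 1)
      vb <- stats::var(b) * (length(b) - 1)
      if (va <= 1e-12 * max(sum(a^2), 1e-300) ||
          vb <= 1e-12 * max(sum(b^2), 1e-300)) {
        r <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      } else {
        r <- sum((a - mean(a)) * (b - mean(b))) / sqrt(va * vb)
      }
      out[i, j] <- min(max(1 - r, 0), 1)
    }
  }
  out
}

# exact two-sided signed-rank p by enumeration of all 2^n sign patterns
brute_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  Ws <- as.matrix(signs) %*% r
  lo <- mean(Ws <= W + 1e-9)
  hi <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(lo, hi))
}

# exact two-sided Mann-Whitney p by enumeration of all choose(n1+n2, n1)
# assignments of the combined ranks
brute_mwu_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  allr <- rank(seq_len(n1 + n2))
  Us <- apply(combs, 2, function(ix) sum(allr[ix])) - n1 * (n1 + 1) / 2
  lo <- mean(Us <= U + 1e-9)
  hi <- mean(Us >= U - 1e-9)
  min(1, 2 * min(lo, hi))
}

expect_within <- function(object, target, tol) {
  expect_true(abs(object - target) <= tol,
              label = sprintf("|%g - %g| <= %g", object, target, tol))
}
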