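#' Displacement from wrapped interferometric phase
#'
#' Temporal phase differences are wrapped to \eqn{(-\pi, \pi]} per voxel
#' (adding \eqn{\pm 2\pi} whenever a step exceeds \eqn{\pi} in magnitude),
#' cumulatively summed, and converted to axial displacement by
#' \deqn{u = \Delta\phi \, \lambda / (4 \pi n),}
#' with \eqn{\lambda} the centre wavelength and \eqn{n} the tissue group
#' refractive index. Unwrapping is temporal only; amplitudes are assumed to
#' stay below the per-sample wrap limit \eqn{\lambda / (4n)} per time step.
#'
#' @param mb an `mb_series` (phase `positions x time x depth`, rad).
#' @return A `positions x time x depth` array of displacement in nm
#'   (zero at the first time sample).
#' @export
displacement_from_phase <- function(mb) {
  stopifnot(inherits(mb, "mb_series"))
  ph <- mb$phase
  if (!all(is.finite(ph))) stop("phase contains non-finite values")
  np <- dim(ph)[1]; nt <- dim(ph)[2]; nz <- dim(ph)[3]
  if (nt < 2) stop("need at least two time samples")
  dphi <- ph[, -1, , drop = FALSE] - ph[, -nt, , drop = FALSE]
  dphi <- wrap_phase(dphi)
  u <- array(0, dim(ph))
  if (nt == 2) {
    u[, 2, ] <- dphi[, 1, ]
  } else {
    cs <- apply(dphi, c(1, 3), cumsum)       # (nt-1) x np x nz
    u[, -1, ] <- aperm(cs, c(2, 1, 3))
  }
  u * mb$wavelength_nm / (4 * pi * mb$tissue_index)
}

#' Depth-aggregated space-time displacement map
#'
#' Averages displacement over a sub-surface depth window to produce one
#' displacement trace per (lateral position, time). The default window is
#' 10 pixels starting at the tracked top surface of each position, where
#' the propagating wave energy is concentrated.
#'
#' @param displacement `positions x time x depth` array (nm), from
#'   [displacement_from_phase()].
#' @param mb the originating `mb_series` (provides positions, times and
#'   tracked surface indices).
#' @param depth_offset_px first window row relative to the top surface
#'   (default 0).
#' @param window_px number of depth pixels averaged (default 10).
#' @param top_px optional per-position surface indices overriding
#'   `mb$top_px`.
#' @return A `space_time_map`: `displacement` (`positions x time`, nm),
#'   `positions_um`, `times_s`, `excitation_x_um`.
#' @export
build_space_time <- function(displacement, mb, depth_offset_px = 0L,
                             window_px = 10L, top_px = NULL) {
  stopifnot(inherits(mb, "mb_series"))
  np <- dim(displacement)[1]; nz <- dim(displacement)[3]
  if (window_px < 1) stop("empty depth window")
  tp <- if (is.null(top_px)) mb$top_px else top_px
  tp <- rep_len(as.integer(tp), np)
  stm <- matrix(NA_real_, np, dim(displacement)[2])
  for (ip in seq_len(np)) {
    z0 <- tp[ip] + depth_offset_px
    zr <- z0:min(nz, z0 + window_px - 1L)
    zr <- zr[zr >= 1 & zr <= nz]
    if (!length(zr)) stop("depth window outside the volume")
    m <- displacement[ip, , zr, drop = FALSE]       # 1 x time x window
    stm[ip, ] <- rowMeans(matrix(m, dim(m)[2], dim(m)[3]))
  }
  structure(list(displacement = stm, positions_um = mb$positions_um,
                 times_s = mb$times_s, excitation_x_um = mb$excitation_x_um),
            class = "space_time_map")
}

# sub-sample delay (in samples) between two mean-removed time profiles via
# the peak of their normalized cross-correlation, refined parabolically;
# ties broken toward the smaller delay
xcorr_delay <- function(ref, sig) {
  ref <- ref - mean(ref); sig <- sig - mean(sig)
  if (all(ref == 0) || all(sig == 0)) return(NA_real_)
  n <- length(ref)
  cc <- stats::ccf(sig, ref, lag.max = n - 1, plot = FALSE,
                   demean = FALSE)
  acf <- as.vector(cc$acf); lags <- as.vector(cc$lag)
  k <- which(acf == max(acf))
  k <- k[which.min(abs(lags[k]))][1]          # tie -> smaller |delay|
  delay <- lags[k]
  if (k > 1 && k < length(acf)) {
    y1 <- acf[k - 1]; y2 <- acf[k]; y3 <- acf[k + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) delay <- delay + 0.5 * (y1 - y3) / den
  }
  delay
}

#' Group velocity on one side of the excitation
#'
#' Tracks the wave arrival on the chosen side of the excitation position:
#' each lateral position's time profile is cross-correlated against the
#' reference profile (the first usable position at least `min_offset_px`
#' lateral pixels from the excitation, excluding the near field); the
#' sub-sample peak delay is regressed on propagation distance and the speed
#' is the slope of the least-squares fit. The estimate is marked invalid
#' when the fit R-squared falls below `r2_threshold` or the slope is not
#' positive.
#'
#' @param stm a `space_time_map`.
#' @param side `"left"` or `"right"` of the excitation position.
#' @param min_offset_px near-field exclusion in lateral pixels (default 3).
#' @param r2_threshold minimum fit R-squared for a valid estimate
#'   (default 0.8).
#' @return A list: `speed_m_s`, `r2`, `valid`, `n_positions`, `side`.
#' @export
estimate_side_velocity <- function(stm, side = c("left", "right"),
                                   min_offset_px = 3L, r2_threshold = 0.8) {
  stopifnot(inherits(stm, "space_time_map"))
  side <- match.arg(side)
  x <- stm$positions_um
  x0 <- stm$excitation_x_um
  if (x0 < min(x) || x0 > max(x))
    stop("excitation position outside the lateral field")
  pitch <- if (length(x) > 1) stats::median(diff(x)) else 1
  off <- min_offset_px * pitch
  sel <- if (side == "left") which(x <= x0 - off) else which(x >= x0 + off)
  if (length(sel) < 5)
    stop("need at least 5 usable lateral positions on the ", side, " side")
  # reference: usable position closest to the excitation
  dist <- abs(x[sel] - x0)
  ord <- order(dist)
  sel <- sel[ord]; dist <- dist[ord]
  ref <- stm$displacement[sel[1], ]
  dt <- stats::median(diff(stm$times_s))
  delays <- vapply(sel, function(ip)
    xcorr_delay(ref, stm$displacement[ip, ]), numeric(1))
  ok <- is.finite(delays)
  invalid <- list(speed_m_s = NA_real_, r2 = NA_real_, valid = FALSE,
                  n_positions = sum(ok), side = side)
  if (sum(ok) < 5) return(invalid)
  d_um <- dist[ok] - dist[1]
  t_s <- delays[ok] * dt
  if (all(t_s == 0)) return(invalid)       # degenerate: no propagation seen
  fit <- stats::lm(t_s ~ d_um)
  slope <- stats::coef(fit)[["d_um"]]      # s per um
  r2 <- summary(fit)$r.squared
  if (!is.finite(slope) || slope <= 0 || r2 < r2_threshold) {
    invalid$r2 <- r2
    return(invalid)
  }
  list(speed_m_s = 1e-6 / slope, r2 = r2, valid = TRUE,
       n_positions = sum(ok), side = side)
}

#' Combine per-side and per-orientation velocity estimates
#'
#' Within one scan orientation the left and right side estimates are
#' averaged over the valid sides; when estimates from two perpendicular
#' scan orientations (longitudinal and transverse) are supplied, the
#' location value is the mean of the two orientation means.
#'
#' @param left,right per-side estimate lists from
#'   [estimate_side_velocity()] (either may be `NULL`).
#' @param transverse optional second-orientation `velocity_estimate` to
#'   combine with this one.
#' @return A `velocity_estimate`: `v_left_m_s`, `v_right_m_s`,
#'   `v_mean_m_s`, `fit_quality` (per-side R-squared), and when two
#'   orientations are combined, `v_location_m_s`.
#' @export
combine_velocities <- function(left = NULL, right = NULL,
                               transverse = NULL) {
  side_val <- function(s) if (!is.null(s) && isTRUE(s$valid)) s$speed_m_s else NA_real_
  vl <- side_val(left); vr <- side_val(right)
  vals <- c(vl, vr)
  if (all(is.na(vals)) && is.null(transverse))
    stop("no valid side estimate in either orientation")
  v_mean <- mean(vals, na.rm = TRUE)
  out <- structure(list(
    v_left_m_s = vl, v_right_m_s = vr,
    v_mean_m_s = v_mean,
    fit_quality = c(left = if (is.null(left)) NA_real_ else left$r2,
                    right = if (is.null(right)) NA_real_ else right$r2)
  ), class = "velocity_estimate")
  if (!is.null(transverse)) {
    stopifnot(inherits(transverse, "velocity_estimate"))
    o <- c(v_mean, transverse$v_mean_m_s)
    if (all(is.na(o))) stop("no valid side estimate in either orientation")
    out$v_location_m_s <- mean(o, na.rm = TRUE)
  }
  out
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat("<velocity_estimate>\n")
  cat(sprintf("  left %.3f m/s (R2 %.3f), right %.3f m/s (R2 %.3f)\n",
              x$v_left_m_s, x$fit_quality[["left"]],
              x$v_right_m_s, x$fit_quality[["right"]]))
  cat(sprintf("  mean %.3f m/s", x$v_mean_m_s))
  if (!is.null(x$v_location_m_s))
    cat(sprintf(", location (two orientations) %.3f m/s", x$v_location_m_s))
  cat("\n")
  invisible(x)
}

#' Group velocity from an M-B-mode record
#'
#' Convenience chain: phase to displacement, depth aggregation to a
#' space-time map, per-side time-of-flight estimation, and side averaging.
#'
#' @param mb an `mb_series`.
#' @inheritParams build_space_time
#' @inheritParams estimate_side_velocity
#' @return A `velocity_estimate`.
#' @export
estimate_group_velocity <- function(mb, depth_offset_px = 0L,
                                    window_px = 10L, r2_threshold = 0.8) {
  u <- displacement_from_phase(mb)
  stm <- build_space_time(u, mb, depth_offset_px, window_px)
  l <- estimate_side_velocity(stm, "left", r2_threshold = r2_threshold)
  r <- estimate_side_velocity(stm, "right", r2_threshold = r2_threshold)
  combine_velocities(l, r)
}
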