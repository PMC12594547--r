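#' Scan geometry of an OCT acquisition
#'
#' Describes the sampling grid of a volumetric OCT scan: the number of
#' A-lines per B-scan (fast lateral axis, x), the number of B-scans per
#' volume (slow lateral axis, y), the number of repeated B-scans acquired at
#' each slow-axis position, the axial pixel pitch expressed as optical path
#' length, the physical lateral pitches, the source centre wavelength and
#' the A-line rate.
#'
#' Defaults mirror a swept-source system scanning a 5.16 x 6.14 mm field
#' with 500 A-lines per B-scan, 500 B-scans, 5 repeats per position, a
#' 1300 nm centre wavelength and a 100 kHz A-line rate. The axial pitch
#' default of 5 um optical path per pixel is a configurable instrument
#' constant.
#'
#' @param n_alines A-lines per B-scan (fast axis).
#' @param n_bscans B-scans per volume (slow axis).
#' @param n_repeats repeated B-scans per slow-axis position.
#' @param n_depth axial pixels per A-line.
#' @param axial_pitch_um optical path length per axial pixel (um).
#' @param lateral_pitch_x_um,lateral_pitch_y_um physical pitch along the
#'   fast / slow axis (um).
#' @param center_wavelength_nm source centre wavelength (nm).
#' @param aline_rate_hz A-line acquisition rate (Hz).
#' @return An object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry()
#' g$n_alines
#' @export
scan_geometry <- function(n_alines = 500L,
                          n_bscans = 500L,
                          n_repeats = 5L,
                          n_depth = 256L,
                          axial_pitch_um = 5,
                          lateral_pitch_x_um = 5160 / 500,
                          lateral_pitch_y_um = 6140 / 500,
                          center_wavelength_nm = 1300,
                          aline_rate_hz = 1e5) {
  counts <- c(n_alines = n_alines, n_bscans = n_bscans,
              n_repeats = n_repeats, n_depth = n_depth)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts must be integers >= 1")
  pitches <- c(axial_pitch_um, lateral_pitch_x_um, lateral_pitch_y_um)
  if (any(pitches <= 0)) stop("all pitches must be > 0")
  if (aline_rate_hz <= 0) stop("aline_rate_hz must be > 0")
  if (center_wavelength_nm <= 0) stop("center_wavelength_nm must be > 0")
  structure(list(
    n_alines = as.integer(n_alines),
    n_bscans = as.integer(n_bscans),
    n_repeats = as.integer(n_repeats),
    n_depth = as.integer(n_depth),
    axial_pitch_um = axial_pitch_um,
    lateral_pitch_x_um = lateral_pitch_x_um,
    lateral_pitch_y_um = lateral_pitch_y_um,
    center_wavelength_nm = center_wavelength_nm,
    aline_rate_hz = aline_rate_hz
  ), class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat("<scan_geometry>\n")
  cat(sprintf("  %d A-lines x %d B-scans x %d repeats, %d depth px\n",
              x$n_alines, x$n_bscans, x$n_repeats, x$n_depth))
  cat(sprintf("  pitch: %.2f um (axial, optical) x %.2f x %.2f um (lateral)\n",
              x$axial_pitch_um, x$lateral_pitch_x_um, x$lateral_pitch_y_um))
  cat(sprintf("  %.0f nm source, %.0f kHz A-line rate\n",
              x$center_wavelength_nm, x$aline_rate_hz / 1e3))
  invisible(x)
}

# physical depth (um, in tissue) -> axial pixel index (1-based)
depth_um_to_px <- function(z_um, geometry, tissue_index) {
  1L + as.integer(round(z_um * tissue_index / geometry$axial_pitch_um))
}

# axial pixel difference -> physical distance in tissue (um)
px_to_um <- function(dpx, geometry, tissue_index) {
  dpx * geometry$axial_pitch_um / tissue_index
}
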