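#' Average repeated B-scans
#'
#' Arithmetic per-voxel mean over the repeat axis of a structural volume;
#' the repeat axis is removed. Averaging is done on the stored (log-scaled)
#' intensity values.
#'
#' @param vol a `structural_volume` (stacks
#'   `n_repeats x n_bscans x n_depth x n_alines`).
#' @return A `structural_volume` whose `stacks` field is a
#'   `n_bscans x n_depth x n_alines` array and `n_repeats` is 1.
#' @export
average_repeats <- function(vol) {
  stopifnot(inherits(vol, "structural_volume"))
  st <- vol$stacks
  if (length(dim(st)) != 4) stop("expected a 4-D repeats x frames x depth x alines array")
  if (dim(st)[1] < 1) stop("need at least one repeat")
  avg <- colMeans(st, dims = 1)          # drops the repeat axis
  out <- vol
  out$stacks <- avg
  out$geometry$n_repeats <- 1L
  out
}

#' Trim edge frames and edge A-lines
#'
#' Removes the outermost `n_edge_frames` B-scans from both ends of the slow
#' axis and `n_edge_alines` A-lines from both ends of every B-scan, to
#' suppress scan-edge artifacts. With the acquisition defaults
#' (500 frames, 500 A-lines, trims of 100 and 50) this retains
#' 300 x 400 A-lines per frame.
#'
#' @param vol a `structural_volume`, averaged (3-D stacks) or not (4-D).
#' @param n_edge_frames frames removed from each end of the slow axis.
#' @param n_edge_alines A-lines removed from each end of every B-scan.
#' @return The trimmed volume; depth is untouched.
#' @export
trim_stack <- function(vol, n_edge_frames = 100L, n_edge_alines = 50L) {
  stopifnot(inherits(vol, "structural_volume"))
  st <- vol$stacks
  nd <- length(dim(st))
  if (!nd %in% c(3, 4)) stop("expected a 3-D or 4-D stack")
  dims <- dim(st)
  ny <- dims[nd - 2]; nx <- dims[nd]
  if (ny <= 2 * n_edge_frames || nx <= 2 * n_edge_alines)
    stop("trim exceeds stack extent")
  fy <- seq.int(n_edge_frames + 1L, ny - n_edge_frames)
  fx <- seq.int(n_edge_alines + 1L, nx - n_edge_alines)
  out <- vol
  if (nd == 4) out$stacks <- st[, fy, , fx, drop = FALSE]
  else out$stacks <- st[fy, , fx, drop = FALSE]
  out$geometry$n_bscans <- length(fy)
  out$geometry$n_alines <- length(fx)
  out
}

#' A-lines retained per position after trimming
#'
#' The edge-trimming arithmetic of the thickness pipeline: with `n_frames`
#' B-scans, `n_alines` per B-scan and `n_repeats` repeats per position,
#' trimming `n_edge_frames` frames and `n_edge_alines` A-lines from each
#' end retains `(n_frames - 2 f) * (n_alines - 2 a) * n_repeats` A-lines.
#' At the acquisition defaults this is 300 x 400 x 5 = 600000.
#'
#' @param geometry a [scan_geometry()].
#' @param n_edge_frames,n_edge_alines trims applied at each end.
#' @return Integer count of retained A-lines per imaged position.
#' @export
alines_retained <- function(geometry, n_edge_frames = 100L,
                            n_edge_alines = 50L) {
  stopifnot(inherits(geometry, "scan_geometry"))
  ny <- geometry$n_bscans - 2L * n_edge_frames
  nx <- geometry$n_alines - 2L * n_edge_alines
  if (ny <= 0 || nx <= 0) stop("trim exceeds stack extent")
  as.integer(ny) * as.integer(nx) * geometry$n_repeats
}

#' Track the top and bottom tissue surfaces by intensity thresholding
#'
#' Per A-line, the detection threshold is `background mean +
#' threshold_k x background SD`, estimated in linear intensity from the
#' shallowest `n_background` rows (assumed to lie above the tissue). The
#' top surface is the first axial index, scanning downward, at which the
#' intensity exceeds the threshold for `min_run` consecutive pixels; the
#' bottom surface is the last such index scanning upward. Each surface is
#' then median-filtered laterally (window 5 A-lines) for continuity.
#' A-lines with no threshold crossing are marked invalid.
#'
#' @param vol an averaged (3-D) `structural_volume`, typically trimmed.
#' @param threshold_k background SD multiplier (default 4).
#' @param n_background number of shallow rows used to estimate the
#'   background level (default 15).
#' @param min_run consecutive supra-threshold pixels required to accept a
#'   crossing (default 2); suppresses single-speckle false crossings.
#' @return A `surface_pair`: `top_idx` and `bottom_idx` are
#'   `n_bscans x n_alines` matrices of axial pixel indices, `valid_mask`
#'   flags A-lines where both surfaces were found.
#' @export
detect_surfaces <- function(vol, threshold_k = 4, n_background = 15L,
                            min_run = 2L) {
  stopifnot(inherits(vol, "structural_volume"))
  st <- vol$stacks
  if (length(dim(st)) != 3)
    stop("detect_surfaces expects an averaged 3-D volume (frames x depth x alines)")
  ny <- dim(st)[1]; nz <- dim(st)[2]; nx <- dim(st)[3]
  if (n_background >= nz) stop("n_background exceeds depth")
  top <- matrix(NA_integer_, ny, nx)
  bot <- matrix(NA_integer_, ny, nx)
  valid <- matrix(FALSE, ny, nx)
  n_empty_frames <- 0L
  for (iy in seq_len(ny)) {
    lin <- 10^(st[iy, , ] / 10)                      # depth x alines, linear
    bg <- lin[seq_len(n_background), , drop = FALSE]
    thr <- colMeans(bg) + threshold_k * apply(bg, 2, stats::sd)
    above <- sweep(lin, 2, thr, `>`)
    # run-length criterion: all of i..i+min_run-1 above threshold
    run <- above
    if (min_run > 1) {
      for (m in seq_len(min_run - 1)) {
        shifted <- rbind(above[-seq_len(m), , drop = FALSE],
                         matrix(FALSE, m, nx))
        run <- run & shifted
      }
    }
    t_iy <- apply(run, 2, function(col) {
      w <- which(col); if (length(w)) w[1] else NA_integer_
    })
    b_iy <- apply(run, 2, function(col) {
      w <- which(col); if (length(w)) w[length(w)] + (min_run - 1L)
      else NA_integer_
    })
    ok <- !is.na(t_iy) & !is.na(b_iy)
    if (!any(ok)) {
      n_empty_frames <- n_empty_frames + 1L
      next
    }
    top[iy, ] <- lateral_median(t_iy, 5L)
    bot[iy, ] <- lateral_median(b_iy, 5L)
    valid[iy, ] <- ok & !is.na(top[iy, ]) & !is.na(bot[iy, ])
  }
  if (n_empty_frames > 0)
    warning(sprintf("%d frame(s) had no detectable surface and were excluded",
                    n_empty_frames))
  bad <- valid & (bot < top)
  valid[bad] <- FALSE
  structure(list(top_idx = top, bottom_idx = bot, valid_mask = valid,
                 threshold_k = threshold_k),
            class = "surface_pair")
}

# running median with given odd window, NA-tolerant, same length
lateral_median <- function(x, window = 5L) {
  n <- length(x)
  h <- window %/% 2L
  out <- integer(n)
  for (i in seq_len(n)) {
    w <- x[max(1L, i - h):min(n, i + h)]
    w <- w[!is.na(w)]
    out[i] <- if (length(w)) as.integer(round(stats::median(w))) else NA_integer_
  }
  out
}

#' Exclude pigmented A-lines by their in-tissue intensity
#'
#' Pigmented skin backscatters weakly; A-lines whose mean linear intensity
#' between the detected surfaces falls below the `percentile_cut` quantile
#' of the lateral intensity distribution (over all valid A-lines of all
#' frames) are marked invalid. The fraction excluded is recorded.
#'
#' @param vol the averaged 3-D `structural_volume` used for detection.
#' @param surfaces a `surface_pair` from [detect_surfaces()].
#' @param percentile_cut quantile of the in-tissue intensity distribution
#'   below which A-lines are excluded (default 0.05).
#' @return The `surface_pair` with the updated `valid_mask` and an
#'   `excluded_fraction` field (fraction of previously valid A-lines
#'   removed).
#' @export
exclude_pigmented <- function(vol, surfaces, percentile_cut = 0.05) {
  stopifnot(inherits(vol, "structural_volume"),
            inherits(surfaces, "surface_pair"))
  st <- vol$stacks
  ny <- dim(st)[1]; nx <- dim(st)[3]
  mean_int <- matrix(NA_real_, ny, nx)
  for (iy in seq_len(ny)) {
    lin <- 10^(st[iy, , ] / 10)
    for (ix in seq_len(nx)) {
      if (!surfaces$valid_mask[iy, ix]) next
      zr <- surfaces$top_idx[iy, ix]:surfaces$bottom_idx[iy, ix]
      mean_int[iy, ix] <- mean(lin[zr, ix])
    }
  }
  vals <- mean_int[surfaces$valid_mask]
  if (!length(vals)) stop("no valid A-lines to assess")
  cut <- stats::quantile(vals, percentile_cut, na.rm = TRUE, names = FALSE)
  out <- surfaces
  drop <- surfaces$valid_mask & !is.na(mean_int) & mean_int < cut
  out$valid_mask <- surfaces$valid_mask & !drop
  out$excluded_fraction <- sum(drop) / sum(surfaces$valid_mask)
  out$pigment_excluded <- drop
  out
}

#' Convert surface separations to physical skin thickness
#'
#' Per valid A-line the thickness is
#' `(bottom_idx - top_idx) * axial_pitch_um / tissue_index`, i.e. the
#' optical path between the surfaces divided by the tissue group refractive
#' index (default 1.376). The summary is the mean over all valid A-lines of
#' all retained frames.
#'
#' @param surfaces a `surface_pair`.
#' @param geometry the [scan_geometry()] of the measured volume.
#' @param tissue_index group refractive index (default 1.376).
#' @return A `thickness_result`: `thickness_map_um` (matrix, NA where
#'   invalid), `mean_um`, `median_um`, `n_alines_used`,
#'   `excluded_fraction`.
#' @export
thickness_from_surfaces <- function(surfaces, geometry,
                                    tissue_index = 1.376) {
  stopifnot(inherits(surfaces, "surface_pair"),
            inherits(geometry, "scan_geometry"))
  if (!any(surfaces$valid_mask)) stop("no valid A-lines")
  dpx <- surfaces$bottom_idx - surfaces$top_idx
  th <- px_to_um(dpx, geometry, tissue_index)
  th[!surfaces$valid_mask] <- NA_real_
  vals <- th[surfaces$valid_mask]
  structure(list(
    thickness_map_um = th,
    mean_um = mean(vals),
    median_um = stats::median(vals),
    n_alines_used = sum(surfaces$valid_mask),
    excluded_fraction = if (is.null(surfaces$excluded_fraction)) 0
    else surfaces$excluded_fraction,
    tissue_index = tissue_index
  ), class = "thickness_result")
}

#' @export
print.thickness_result <- function(x, ...) {
  cat("<thickness_result>\n")
  cat(sprintf("  mean %.1f um, median %.1f um over %d A-lines (n = %.3f)\n",
              x$mean_um, x$median_um, x$n_alines_used, x$tissue_index))
  cat(sprintf("  excluded fraction %.3f\n", x$excluded_fraction))
  invisible(x)
}

#' Full thickness pipeline on a repeated structural volume
#'
#' Runs the measurement chain in acquisition order: average the repeats,
#' trim edge frames and A-lines, detect the two surfaces, exclude weakly
#' backscattering (pigmented) A-lines, and convert pixel separations to
#' physical thickness.
#'
#' @param vol a 4-D `structural_volume`.
#' @param n_edge_frames,n_edge_alines trims (defaults 100 / 50; reduce for
#'   small volumes).
#' @param threshold_k surface-detection threshold multiplier.
#' @param percentile_cut pigment-exclusion percentile.
#' @param tissue_index group refractive index.
#' @return A `thickness_result`.
#' @export
measure_thickness <- function(vol, n_edge_frames = 100L, n_edge_alines = 50L,
                              threshold_k = 4, percentile_cut = 0.05,
                              tissue_index = vol$tissue_index) {
  avg <- average_repeats(vol)
  trm <- trim_stack(avg, n_edge_frames, n_edge_alines)
  surf <- detect_surfaces(trm, threshold_k = threshold_k)
  surf <- exclude_pigmented(trm, surf, percentile_cut = percentile_cut)
  thickness_from_surfaces(surf, trm$geometry, tissue_index)
}
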