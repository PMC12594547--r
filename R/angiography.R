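# sliding k x k window sums with zero padding; companion count map gives
# the number of in-image pixels under each window
boxsum <- function(m, k) {
  h <- k %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L * h, nc + 2L * h)
  p[(h + 1L):(h + nr), (h + 1L):(h + nc)] <- m
  S <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  S[-1L, -1L] <- t(apply(apply(p, 2, cumsum), 1, cumsum))
  k2 <- 2L * h + 1L
  S[(k2 + 1L):(nr + k2), (k2 + 1L):(nc + k2)] -
    S[1L:nr, (k2 + 1L):(nc + k2)] -
    S[(k2 + 1L):(nr + k2), 1L:nc] +
    S[1L:nr, 1L:nc]
}

# zero-normalized cross-correlation of two frames over k x k neighborhoods;
# degenerate (zero-variance) kernels: identical patches -> 1, else 0
zncc_frames <- function(A, B, k) {
  N <- boxsum(matrix(1, nrow(A), ncol(A)), k)
  SA <- boxsum(A, k); SB <- boxsum(B, k)
  SAA <- boxsum(A * A, k); SBB <- boxsum(B * B, k)
  SAB <- boxsum(A * B, k)
  covAB <- SAB - SA * SB / N
  varA <- pmax(SAA - SA^2 / N, 0)
  varB <- pmax(SBB - SB^2 / N, 0)
  tolA <- 1e-12 * pmax(SAA, 1e-300)
  tolB <- 1e-12 * pmax(SBB, 1e-300)
  r <- covAB / sqrt(pmax(varA * varB, 1e-300))
  degA <- varA <= tolA; degB <- varB <= tolB
  both <- degA & degB
  same <- abs(SA - SB) <= 1e-8 * pmax(abs(SA) + abs(SB), 1e-300)
  r[degA | degB] <- 0
  r[both & same] <- 1
  pmin(pmax(r, -1), 1)
}

#' Correlation-mapping angiography over repeated B-scans
#'
#' For each consecutive pair among the repeated B-scans at a slow-axis
#' position, the zero-normalized cross-correlation of the two frames is
#' computed over a `kernel_px x kernel_px` neighborhood (within the B-scan
#' plane, depth x lateral) around every pixel. The flow value is
#' `1 - mean pairwise correlation`, clipped to [0, 1]: static tissue keeps
#' one speckle realisation across repeats and correlates highly (flow near
#' 0), while moving scatterers decorrelate (flow near 1). Identical
#' zero-variance patches are assigned correlation 1.
#'
#' @param stack an `angio_stack` (repeats
#'   `n_repeats x n_bscans x n_depth x n_alines`, linear intensity).
#' @param kernel_px odd kernel size in pixels (default 5).
#' @return A `flow_map`: `flow` is a `n_depth x n_alines x n_bscans` array
#'   in [0, 1], with `kernel_px` and `geometry`.
#' @export
correlation_map <- function(stack, kernel_px = 5L) {
  stopifnot(inherits(stack, "angio_stack"))
  rep4 <- stack$repeats
  nr <- dim(rep4)[1]; ny <- dim(rep4)[2]
  nz <- dim(rep4)[3]; nx <- dim(rep4)[4]
  if (nr < 2) stop("correlation mapping requires >= 2 repeats")
  if (kernel_px %% 2 == 0) stop("kernel_px must be odd")
  if (kernel_px > nz || kernel_px > nx)
    stop("kernel_px larger than the frame")
  flow <- array(NA_real_, c(nz, nx, ny))
  for (iy in seq_len(ny)) {
    acc <- matrix(0, nz, nx)
    for (k in seq_len(nr - 1)) {
      A <- rep4[k, iy, , ]
      B <- rep4[k + 1, iy, , ]
      acc <- acc + zncc_frames(A, B, kernel_px)
    }
    flow[, , iy] <- pmin(pmax(1 - acc / (nr - 1), 0), 1)
  }
  structure(list(flow = flow, kernel_px = as.integer(kernel_px),
                 geometry = stack$geometry),
            class = "flow_map")
}

#' En-face projection of a flow volume
#'
#' Maximum-intensity projection of the flow volume over a depth band,
#' producing a lateral (fast x slow axis) flow image.
#'
#' @param fmap a `flow_map`.
#' @param depth_band integer vector `c(z0, z1)` of axial pixels (default:
#'   full depth).
#' @return An `n_alines x n_bscans` matrix of flow values in [0, 1].
#' @export
enface_flow <- function(fmap, depth_band = NULL) {
  stopifnot(inherits(fmap, "flow_map"))
  fl <- fmap$flow
  nz <- dim(fl)[1]
  zr <- if (is.null(depth_band)) seq_len(nz)
  else seq.int(max(1L, depth_band[1]), min(nz, depth_band[2]))
  apply(fl[zr, , , drop = FALSE], c(2, 3), max)
}

#' Depth band covered by tissue in an angiography stack
#'
#' Estimates the axial rows occupied by tissue from the repeat- and
#' frame-averaged intensity profile: rows whose mean intensity exceeds
#' `background mean + threshold_k x background SD` (background = the
#' shallowest `n_background` rows), shrunk by `margin_px` at both ends.
#' Restricting the en-face projection to this band keeps the decorrelating
#' air above the tissue out of the flow image.
#'
#' @param stack an `angio_stack`.
#' @param threshold_k background SD multiplier (default 4).
#' @param n_background shallow rows used as background (default 15).
#' @param margin_px rows trimmed from each end of the band (default 2).
#' @return `c(z0, z1)` axial pixel indices.
#' @export
tissue_depth_band <- function(stack, threshold_k = 4, n_background = 15L,
                              margin_px = 2L) {
  stopifnot(inherits(stack, "angio_stack"))
  prof <- apply(stack$repeats, 3, mean)            # mean intensity per depth
  bg <- prof[seq_len(min(n_background, length(prof)))]
  thr <- mean(bg) + threshold_k * stats::sd(bg)
  inside <- which(prof > thr)
  if (!length(inside)) stop("no tissue band found above the background")
  z0 <- min(inside) + margin_px
  z1 <- max(inside) - margin_px
  if (z0 > z1) stop("tissue band thinner than twice the margin")
  c(z0, z1)
}

shift_mat <- function(m, dr, dc) {
  # shift with edge replication
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

#' Multiscale Hessian vesselness of a 2-D flow image
#'
#' Tubular-structure enhancement from the eigenvalues of the
#' scale-normalized Hessian of the Gaussian-smoothed image. With
#' \eqn{|\lambda_1| \le |\lambda_2|}, the blobness ratio
#' \eqn{R_b = \lambda_1/\lambda_2} and structureness
#' \eqn{S = \sqrt{\lambda_1^2 + \lambda_2^2}} give the response
#' \deqn{v = \exp(-R_b^2 / 2\beta^2) (1 - \exp(-S^2 / 2 c^2))}
#' for \eqn{\lambda_2 < 0} (bright vessels on a dark background) and 0
#' otherwise, maximized over the scale set; `c` is half the maximum
#' structureness at each scale. The output is normalized to [0, 1].
#'
#' @param img 2-D numeric matrix (en-face flow projection).
#' @param scales Gaussian scales in pixels (default `c(1, 2, 4, 8)`).
#' @param beta blobness sensitivity (default 0.5).
#' @return Matrix of vesselness values in [0, 1].
#' @export
vesselness <- function(img, scales = c(1, 2, 4, 8), beta = 0.5) {
  if (!is.matrix(img)) stop("vesselness expects a 2-D matrix")
  best <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    sm <- EBImage::gblur(img, sigma = s)
    Dxx <- shift_mat(sm, 1L, 0L) - 2 * sm + shift_mat(sm, -1L, 0L)
    Dyy <- shift_mat(sm, 0L, 1L) - 2 * sm + shift_mat(sm, 0L, -1L)
    Dxy <- (shift_mat(sm, 1L, 1L) - shift_mat(sm, 1L, -1L) -
              shift_mat(sm, -1L, 1L) + shift_mat(sm, -1L, -1L)) / 4
    # scale normalization
    Dxx <- Dxx * s^2; Dyy <- Dyy * s^2; Dxy <- Dxy * s^2
    tmp <- sqrt((Dxx - Dyy)^2 + 4 * Dxy^2)
    l1 <- (Dxx + Dyy + tmp) / 2
    l2 <- (Dxx + Dyy - tmp) / 2
    swap <- abs(l1) > abs(l2)
    lo <- ifelse(swap, l2, l1)      # |lo| <= |hi|
    hi <- ifelse(swap, l1, l2)
    S2 <- lo^2 + hi^2
    cpar <- sqrt(max(S2)) / 2
    if (cpar <= 0) next
    Rb2 <- ifelse(hi != 0, (lo / hi)^2, 0)
    v <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * cpar^2)))
    v[hi >= 0] <- 0
    best <- pmax(best, v)
  }
  mx <- max(best)
  if (mx > 0) best <- best / mx
  best
}

# Zhang-Suen thinning of a logical matrix
skeletonize <- function(mask) {
  img <- mask * 1L
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P2 <- shift_mat(img, -1L, 0L); P3 <- shift_mat(img, -1L, 1L)
      P4 <- shift_mat(img, 0L, 1L);  P5 <- shift_mat(img, 1L, 1L)
      P6 <- shift_mat(img, 1L, 0L);  P7 <- shift_mat(img, 1L, -1L)
      P8 <- shift_mat(img, 0L, -1L); P9 <- shift_mat(img, -1L, -1L)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) +
        (P4 == 0 & P5 == 1) + (P5 == 0 & P6 == 1) +
        (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (step == 1)
        cond <- P2 * P4 * P6 == 0 & P4 * P6 * P8 == 0
      else
        cond <- P2 * P4 * P8 == 0 & P2 * P6 * P8 == 0
      del <- img == 1 & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        img[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img == 1L
}

# bilinear interpolation of matrix m at fractional (row, col) positions;
# returns NA outside the image
interp2 <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  r0 <- pmin(floor(r[ok]), nr - 1L); c0 <- pmin(floor(c[ok]), nc - 1L)
  fr <- r[ok] - r0; fc <- c[ok] - c0
  out[ok] <- m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
  out
}

#' Segment vessels and measure lumen widths
#'
#' Thresholds the vesselness map (Otsu by default), labels connected
#' components, skeletonizes the mask, samples centerline points at a fixed
#' spacing, extracts the flow profile perpendicular to the local centerline
#' direction, fits a Gaussian with offset, and reports the full width at
#' half maximum (2.3548 sigma) in physical um. Profiles with fit R-squared
#' below `r2_min` are discarded.
#'
#' @param vness vesselness matrix from [vesselness()]
#'   (`n_alines x n_bscans`).
#' @param flow_enface en-face flow matrix from [enface_flow()], measured
#'   along the profiles.
#' @param geometry the [scan_geometry()] giving the lateral pitches.
#' @param threshold vesselness threshold; `NULL` (default) uses Otsu's
#'   method.
#' @param sample_every_um centerline sampling interval (default 30 um).
#' @param profile_halfwidth_px half-length of the sampled profile in
#'   pixels (default 12).
#' @param r2_min minimum Gaussian-fit R-squared (default 0.7).
#' @param kernel_px correlation kernel size used to build the flow map;
#'   when given, the kernel's box response (SD `sqrt((k^2-1)/12)` pixels
#'   along the fast lateral axis) is removed from the fitted width in
#'   quadrature, since the correlation map blurs the lumen profile by its
#'   kernel.
#' @return A data.frame of class `lumen_measurements` with one row per
#'   retained profile: `vessel_id`, `x_um`, `y_um`, `width_um`, `r2`.
#'   Empty (zero rows) when the mask has no foreground.
#' @export
segment_and_measure <- function(vness, flow_enface, geometry,
                                threshold = NULL, sample_every_um = 30,
                                profile_halfwidth_px = 12, r2_min = 0.7,
                                kernel_px = NULL) {
  stopifnot(is.matrix(vness), is.matrix(flow_enface),
            inherits(geometry, "scan_geometry"))
  empty <- data.frame(vessel_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), width_um = numeric(0),
                      r2 = numeric(0))
  class(empty) <- c("lumen_measurements", "data.frame")
  if (is.null(threshold)) {
    rng <- range(vness)
    if (diff(rng) == 0) return(empty)
    threshold <- EBImage::otsu(EBImage::Image(vness), range = rng)
  }
  mask <- vness > threshold
  if (!any(mask)) return(empty)
  labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labels <- matrix(as.integer(EBImage::imageData(labels)),
                   nrow(mask), ncol(mask))
  skel <- skeletonize(mask)
  px <- geometry$lateral_pitch_x_um
  py <- geometry$lateral_pitch_y_um
  pts <- which(skel, arr.ind = TRUE)
  if (!nrow(pts)) return(empty)
  stride <- max(1L, round(sample_every_um / mean(c(px, py))))
  ord <- order(pts[, 2], pts[, 1])        # walk along columns (slow axis)
  pts <- pts[ord, , drop = FALSE]
  pts <- pts[seq(1, nrow(pts), by = stride), , drop = FALSE]
  rows <- list(); nres <- 0L
  for (i in seq_len(nrow(pts))) {
    r0 <- pts[i, 1]; c0 <- pts[i, 2]
    lab <- labels[r0, c0]
    # local direction from nearby skeleton pixels (physical coordinates)
    nb <- which(skel[max(1, r0 - 4):min(nrow(skel), r0 + 4),
                     max(1, c0 - 4):min(ncol(skel), c0 + 4), drop = FALSE],
                arr.ind = TRUE)
    nb[, 1] <- nb[, 1] + max(1, r0 - 4) - 1
    nb[, 2] <- nb[, 2] + max(1, c0 - 4) - 1
    if (nrow(nb) < 3) next
    xy <- cbind(nb[, 1] * px, nb[, 2] * py)
    ev <- eigen(stats::cov(xy), symmetric = TRUE)
    dirv <- ev$vectors[, 1]               # centerline direction (um)
    perp <- c(-dirv[2], dirv[1])
    perp <- perp / sqrt(sum(perp^2))
    # sample the flow profile along the perpendicular, in physical um
    s_um <- seq(-profile_halfwidth_px, profile_halfwidth_px,
                by = 0.5) * mean(c(px, py))
    rr <- r0 + s_um * perp[1] / px
    cc <- c0 + s_um * perp[2] / py
    prof <- interp2(flow_enface, rr, cc)
    ok <- !is.na(prof)
    if (sum(ok) < 7) next
    fit <- fit_gaussian_profile(s_um[ok], prof[ok])
    if (is.null(fit) || fit$r2 < r2_min || fit$sigma <= 0) next
    sigma_um <- fit$sigma
    if (!is.null(kernel_px) && kernel_px > 1) {
      # correlation-kernel box response along the profile (blur acts along
      # the fast lateral axis within the B-scan plane)
      sig_k <- sqrt((kernel_px^2 - 1) / 12) * px * abs(perp[1])
      sigma_um <- sqrt(max(sigma_um^2 - sig_k^2, (0.2 * px / 2.3548)^2))
    }
    nres <- nres + 1L
    rows[[nres]] <- data.frame(vessel_id = lab,
                               x_um = (r0 - 1) * px, y_um = (c0 - 1) * py,
                               width_um = 2.3548 * sigma_um, r2 = fit$r2)
  }
  if (!nres) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lumen_measurements", "data.frame")
  out
}

# Gaussian-with-offset least-squares fit; returns NULL on failure
fit_gaussian_profile <- function(s, y) {
  b0 <- stats::quantile(y, 0.1, names = FALSE)
  a0 <- max(y) - b0
  if (a0 <= 0) return(NULL)
  mu0 <- s[which.max(y)]
  above <- s[y > b0 + a0 / 2]
  sig0 <- max(diff(range(above)) / 2.3548, 1e-3)
  fit <- tryCatch(
    stats::nls(y ~ b + a * exp(-(s - mu)^2 / (2 * sig^2)),
               start = list(b = b0, a = a0, mu = mu0, sig = sig0),
               control = stats::nls.control(warnOnly = TRUE, maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  res <- y - stats::predict(fit)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(sigma = abs(cf[["sig"]]), mu = cf[["mu"]], amplitude = cf[["a"]],
       offset = cf[["b"]], r2 = r2)
}

#' Per-vessel summary of lumen measurements
#'
#' @param measurements a `lumen_measurements` data.frame.
#' @return A data.frame with one row per vessel_id: `n_profiles`,
#'   `mean_width_um`, `median_width_um`.
#' @export
summarize_lumens <- function(measurements) {
  if (!nrow(measurements))
    return(data.frame(vessel_id = integer(0), n_profiles = integer(0),
                      mean_width_um = numeric(0),
                      median_width_um = numeric(0)))
  sp <- split(measurements$width_um, measurements$vessel_id)
  data.frame(vessel_id = as.integer(names(sp)),
             n_profiles = vapply(sp, length, integer(1)),
             mean_width_um = vapply(sp, mean, numeric(1)),
             median_width_um = vapply(sp, stats::median, numeric(1)),
             row.names = NULL)
}
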