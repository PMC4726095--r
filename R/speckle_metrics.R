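#' Speckle contrast
#'
#' `C = sd(I) / mean(I)` over a region of interest (population standard
#' deviation). C is the standard quality metric for speckle patterns: higher
#' contrast means tracer speckles stand out better against the transmitted
#' baseline.
#'
#' @param roi numeric matrix (ROI of at least 16 x 16 px) with positive mean.
#' @return Speckle contrast, dimensionless.
#' @export
speckle_contrast <- function(roi) {
  if (!is.matrix(roi) || any(dim(roi) < 16))
    stopf("ROI must be a matrix of at least 16 x 16 px")
  mu <- mean(roi)
  if (mu <= 0) stopf("ROI mean intensity must be positive")
  sd_pop(roi) / mu
}

#' Ensemble-averaged normalized autocovariance map
#'
#' Per frame, the spatial autocovariance of the mean-subtracted ROI is
#' computed by the Wiener-Khinchin relation — the inverse Fourier transform
#' of `|FT(I - mean(I))|^2` — then averaged over the frame ensemble and
#' normalized so the zero-lag value is exactly 1. Mean subtraction is
#' per-frame, which removes frame-to-frame illumination drift before the
#' covariance is accumulated.
#'
#' @param stack an [image_stack()], list of frames, or single matrix.
#' @param roi optional `c(row0, col0, height, width)` region; default whole
#'   frame.
#' @return Normalized autocovariance matrix centered at zero lag (class
#'   `xpiv_covmap`), with attribute `center = c(row, col)` of the zero-lag
#'   bin and `n_frames`.
#' @export
autocovariance <- function(stack, roi = NULL) {
  frames <- if (inherits(stack, "xpiv_stack")) stack$frames
            else if (is.matrix(stack)) list(stack) else stack
  if (length(frames) < 1) stopf("need at least one frame")
  if (!is.null(roi)) {
    frames <- lapply(frames, function(f)
      f[roi[1]:(roi[1] + roi[3] - 1), roi[2]:(roi[2] + roi[4] - 1)])
  }
  acc <- 0
  for (f in frames) {
    f0 <- f - mean(f)
    acc <- acc + Re(stats::fft(Mod(stats::fft(f0))^2, inverse = TRUE))
  }
  if (max(abs(acc)) == 0)
    stopf("zero-variance ROI: autocovariance normalization undefined")
  cov <- fftshift2(acc / acc[1, 1])
  center <- c(floor(nrow(cov) / 2) + 1, floor(ncol(cov) / 2) + 1)
  structure(cov, class = c("xpiv_covmap", "matrix"),
            center = center, n_frames = length(frames))
}

# FWHM of a symmetric unit-peak profile sampled at integer lags: linear
# interpolation between the samples bracketing the half-maximum crossing on
# each side of the peak at index `i0`.
profile_fwhm <- function(p, i0) {
  half_width <- function(vals) {
    # vals: samples at lag distances 1, 2, ... from the unit peak
    below <- which(vals < 0.5)
    if (length(below) == 0) return(NA_real_)
    k <- below[1]
    v_prev <- if (k == 1) 1 else vals[k - 1]
    (k - 1) + (v_prev - 0.5) / (v_prev - vals[k])
  }
  right <- half_width(p[(i0 + 1):length(p)])
  left <- half_width(rev(p[1:(i0 - 1)]))
  if (is.na(left) || is.na(right)) return(NA_real_)
  left + right
}

#' Speckle size from an autocovariance map
#'
#' Full width at half maximum of the central lobe along each image axis,
#' with linear interpolation between the samples bracketing the
#' half-maximum crossing. The speckle size characterizes the spatial scale
#' of the speckle grains (for microbubble images, the projected bubble
#' image size).
#'
#' @param cov_map a normalized map from [autocovariance()].
#' @param pixel_pitch optional um/px; when given, sizes are also returned in
#'   um.
#' @return Named list: `size_y`, `size_x` (FWHM in px, rows/cols), and
#'   `size_y_um`, `size_x_um` if `pixel_pitch` was supplied.
#' @export
speckle_size <- function(cov_map, pixel_pitch = NULL) {
  ctr <- attr(cov_map, "center")
  if (is.null(ctr)) stopf("cov_map must come from autocovariance()")
  m <- unclass(cov_map)
  py <- m[, ctr[2]]
  px <- m[ctr[1], ]
  fy <- profile_fwhm(py, ctr[1])
  fx <- profile_fwhm(px, ctr[2])
  if (is.na(fy) || is.na(fx))
    stopf("speckle larger than ROI: autocovariance never falls below 0.5")
  out <- list(size_y = fy, size_x = fx)
  if (!is.null(pixel_pitch)) {
    out$size_y_um <- fy * pixel_pitch
    out$size_x_um <- fx * pixel_pitch
  }
  out
}

#' SR measurement-accuracy surrogate
#'
#' `SR = P_c * C`: the product of the relative correlation peak height and
#' the speckle contrast. SR summarizes how reliable a velocimetry
#' measurement is expected to be; image restoration should raise it.
#'
#' @param p_c relative peak height in `[0, 1]`.
#' @param contrast speckle contrast C (>= 0).
#' @return SR value.
#' @export
sr_value <- function(p_c, contrast) {
  if (any(p_c < 0 | p_c > 1, na.rm = TRUE)) stopf("p_c must lie in [0, 1]")
  if (any(contrast < 0, na.rm = TRUE)) stopf("contrast must be >= 0")
  p_c * contrast
}

#' Speckle quality report for an image stack
#'
#' Convenience wrapper computing contrast and speckle size over a common
#' ROI from an ensemble of frames (default: up to 100, mirroring typical
#' practice).
#'
#' @param stack an [image_stack()].
#' @param roi `c(row0, col0, height, width)`; default central half.
#' @param n_frames ensemble size (default 100, capped at stack length).
#' @return List of class `xpiv_speckle_report`: `contrast` (mean over the
#'   ensemble), `size_y`, `size_x` (px), sizes in um, `n_frames`, `roi`.
#' @export
speckle_report <- function(stack, roi = NULL, n_frames = 100L) {
  d <- dim(stack$frames[[1]])
  if (is.null(roi)) roi <- c(floor(d[1] / 4) + 1, floor(d[2] / 4) + 1,
                             floor(d[1] / 2), floor(d[2] / 2))
  n <- min(n_frames, length(stack$frames))
  frames <- stack$frames[seq_len(n)]
  cvals <- vapply(frames, function(f)
    speckle_contrast(f[roi[1]:(roi[1] + roi[3] - 1),
                       roi[2]:(roi[2] + roi[4] - 1)]), numeric(1))
  covmap <- autocovariance(frames, roi)
  sz <- speckle_size(covmap, stack$pixel_pitch)
  structure(
    list(contrast = mean(cvals), size_y = sz$size_y, size_x = sz$size_x,
         size_y_um = sz$size_y_um, size_x_um = sz$size_x_um,
         n_frames = n, roi = roi),
    class = "xpiv_speckle_report"
  )
}

#' @export
print.xpiv_speckle_report <- function(x, ...) {
  cat(sprintf(
    "<xpiv_speckle_report> C = %.4f, speckle size = %.2f x %.2f px (%.2f x %.2f um), n = %d frames\n",
    x$contrast, x$size_y, x$size_x, x$size_y_um, x$size_x_um, x$n_frames
  ))
  invisible(x)
}
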