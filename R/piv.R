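#' PIV engine configuration
#'
#' @param window_size interrogation window in px as `c(transverse, flow)` =
#'   `c(rows, cols)`; default 32 x 64 with the long axis along the flow.
#' @param overlap fractional window overlap in `[0, 1)`; default 0.5.
#' @param pc_threshold minimum relative peak height P_c for a vector to be
#'   considered reliable; default 0.5, the standard speckle-velocimetry
#'   criterion.
#' @param max_displacement largest correlation lag searched, px, as
#'   `c(rows, cols)`; default `floor(window_size / 4)` (quarter rule).
#' @param subpixel `"gaussian"` (3-point Gaussian, default) or
#'   `"parabolic"`.
#' @param nmt_threshold,nmt_eps normalized-median outlier test threshold
#'   (3 x 3 neighborhood) and noise floor in px; the test flags vectors
#'   inconsistent with their neighbors.
#' @param min_valid_fraction in ensemble averaging, grid points valid in
#'   fewer than this fraction of fields are dropped; default 0.25.
#' @return A list of class `xpiv_piv_config`.
#' @export
piv_config <- function(window_size = c(32L, 64L), overlap = 0.5,
                       pc_threshold = 0.5, max_displacement = NULL,
                       subpixel = c("gaussian", "parabolic"),
                       nmt_threshold = 2, nmt_eps = 0.1,
                       min_valid_fraction = 0.25) {
  window_size <- as.integer(window_size)
  if (length(window_size) != 2L || any(window_size < 8L))
    stopf("window_size must be two integers >= 8")
  if (overlap < 0 || overlap >= 1) stopf("overlap must be in [0, 1)")
  if (pc_threshold < 0 || pc_threshold > 1) stopf("pc_threshold must be in [0, 1]")
  if (is.null(max_displacement)) max_displacement <- pmax(window_size %/% 4L, 2L)
  max_displacement <- as.integer(rep(max_displacement, length.out = 2))
  structure(
    list(window_size = window_size, overlap = overlap,
         pc_threshold = pc_threshold, max_displacement = max_displacement,
         subpixel = match.arg(subpixel), nmt_threshold = nmt_threshold,
         nmt_eps = nmt_eps, min_valid_fraction = min_valid_fraction),
    class = "xpiv_piv_config"
  )
}

#' Zero-normalized cross-correlation of two interrogation windows
#'
#' Both windows are mean-subtracted; for each lag the product sum over the
#' overlap region is normalized by the overlap pixel count and the two
#' windows' (population) standard deviations, giving coefficients in
#' `[-1, 1]`. The peak coefficient is the relative peak height P_c. Ties in
#' the peak location are broken by smallest lag magnitude, then row-major
#' order, for determinism.
#'
#' @param win_a,win_b numeric matrices of identical shape.
#' @param max_displacement largest lag searched, `c(rows, cols)` px.
#' @param plan optional precomputed [zncc_plan()]; [compute_field()] builds
#'   one per run so repeated calls skip the per-window setup.
#' @return A list of class `xpiv_corrmap`: `map` (correlation matrix over
#'   lags), `dy`, `dx` (lag axes), `peak` (integer lag `c(dy, dx)`), `p_c`,
#'   `valid` (FALSE when either window has zero variance).
#' @export
correlate_windows <- function(win_a, win_b,
                              max_displacement = pmax(dim(win_a) %/% 4L, 2L),
                              plan = NULL) {
  if (!identical(dim(win_a), dim(win_b)))
    stopf("windows must share dimensions")
  if (is.null(plan)) plan <- zncc_plan(dim(win_a), max_displacement)
  h <- plan$h; w <- plan$w
  dy <- plan$dy; dx <- plan$dx
  a0 <- win_a - mean(win_a)
  b0 <- win_b - mean(win_b)
  sa <- sqrt(mean(a0^2)); sb <- sqrt(mean(b0^2))
  if (sa == 0 || sb == 0) {
    return(structure(list(map = matrix(NA_real_, length(dy), length(dx)),
                          dy = dy, dx = dx, peak = c(NA_integer_, NA_integer_),
                          p_c = NA_real_, valid = FALSE),
                     class = "xpiv_corrmap"))
  }
  # linear cross-correlation via zero-padded FFT: c(l) = sum a0(x) b0(x + l)
  plan$A[plan$win_rows, plan$win_cols] <- a0
  plan$B[plan$win_rows, plan$win_cols] <- b0
  cc <- Re(stats::fft(Conj(stats::fft(plan$A)) * stats::fft(plan$B),
                      inverse = TRUE)) / plan$np
  map <- cc[plan$row_idx, plan$col_idx, drop = FALSE] / (plan$n_overlap * sa * sb)
  pk <- max(map)
  cand <- which(map == pk, arr.ind = TRUE)
  if (nrow(cand) > 1) {
    mag <- dy[cand[, 1]]^2 + dx[cand[, 2]]^2
    cand <- cand[order(mag, cand[, 1], cand[, 2]), , drop = FALSE]
  }
  peak <- c(dy[cand[1, 1]], dx[cand[1, 2]])
  structure(list(map = map, dy = dy, dx = dx, peak = peak, p_c = pk,
                 valid = TRUE),
            class = "xpiv_corrmap")
}

#' Precomputed setup for repeated window correlations
#'
#' Fixes the zero-padded FFT size, lag index tables and overlap counts for
#' a given window shape and search range, so that [correlate_windows()] can
#' be called many times (one interrogation grid, many pairs) without
#' per-call setup.
#'
#' @param window_dim `c(rows, cols)` of the interrogation window, px.
#' @param max_displacement largest lag searched, `c(rows, cols)` px.
#' @return An environment consumed by [correlate_windows()].
#' @export
zncc_plan <- function(window_dim, max_displacement = pmax(window_dim %/% 4L, 2L)) {
  h <- as.integer(window_dim[1]); w <- as.integer(window_dim[2])
  md <- as.integer(rep(max_displacement, length.out = 2))
  md[1] <- min(md[1], h - 1L); md[2] <- min(md[2], w - 1L)
  pr <- stats::nextn(h + md[1], c(2, 3, 5))
  pc <- stats::nextn(w + md[2], c(2, 3, 5))
  dy <- -md[1]:md[1]; dx <- -md[2]:md[2]
  idx <- function(l, n) ifelse(l >= 0, l + 1L, n + l + 1L)
  plan <- new.env(parent = emptyenv())
  plan$h <- h; plan$w <- w; plan$md <- md
  plan$dy <- dy; plan$dx <- dx
  plan$np <- pr * pc
  plan$win_rows <- 1:h; plan$win_cols <- 1:w
  plan$row_idx <- idx(dy, pr); plan$col_idx <- idx(dx, pc)
  plan$n_overlap <- outer(h - abs(dy), w - abs(dx))
  plan$A <- matrix(0, pr, pc)  # padding stays zero; only the window region
  plan$B <- matrix(0, pr, pc)  # is overwritten on each call
  plan
}

# One-axis 3-point refinement around the peak. Gaussian fit needs positive
# ordinates; otherwise fall back to a parabolic fit.
refine_axis <- function(cm, c0, cp, method) {
  if (method == "gaussian" && cm > 0 && c0 > 0 && cp > 0) {
    denom <- log(cm) + log(cp) - 2 * log(c0)
    if (denom < 0) {
      d <- 0.5 * (log(cm) - log(cp)) / denom
      if (abs(d) < 1) return(list(offset = d, method = "gaussian"))
    }
  }
  denom <- cm + cp - 2 * c0
  d <- if (denom < 0) 0.5 * (cm - cp) / denom else 0
  list(offset = max(-0.999, min(0.999, d)), method = "parabolic")
}

#' Subpixel localization of a correlation peak
#'
#' Per-axis 3-point Gaussian fit through the peak and its two neighbors
#' (the standard PIV estimator for Gaussian-like particle-image peaks);
#' falls back to a parabolic fit when a neighbor is non-positive. The
#' refined offset lies in `(-1, 1)` px and is added to the integer lag.
#'
#' @param corr an `xpiv_corrmap` from [correlate_windows()].
#' @param method `"gaussian"` or `"parabolic"`.
#' @return List: `dy`, `dx` (total displacement of `win_b` relative to
#'   `win_a`, px), `p_c`, `on_border` (TRUE if the peak sat on the searched
#'   lag border: no refinement), `method` used per axis.
#' @export
subpixel_peak <- function(corr, method = c("gaussian", "parabolic")) {
  method <- match.arg(method)
  if (!isTRUE(corr$valid))
    return(list(dy = NA_real_, dx = NA_real_, p_c = NA_real_,
                on_border = NA, method = NA_character_))
  iy <- match(corr$peak[1], corr$dy)
  ix <- match(corr$peak[2], corr$dx)
  on_border <- iy == 1L || iy == length(corr$dy) ||
    ix == 1L || ix == length(corr$dx)
  if (on_border) {
    return(list(dy = as.numeric(corr$peak[1]), dx = as.numeric(corr$peak[2]),
                p_c = corr$p_c, on_border = TRUE, method = "none"))
  }
  ry <- refine_axis(corr$map[iy - 1, ix], corr$map[iy, ix],
                    corr$map[iy + 1, ix], method)
  rx <- refine_axis(corr$map[iy, ix - 1], corr$map[iy, ix],
                    corr$map[iy, ix + 1], method)
  list(dy = corr$peak[1] + ry$offset, dx = corr$peak[2] + rx$offset,
       p_c = corr$p_c, on_border = FALSE,
       method = c(y = ry$method, x = rx$method))
}

# Normalized median test (3x3 neighborhood) on the vector components;
# returns a logical "outlier" flag per grid point.
normalized_median_outliers <- function(u, v, threshold = 2, eps = 0.1) {
  ny <- nrow(u); nx <- ncol(u)
  out <- matrix(FALSE, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      if (!is.finite(u[i, j])) next
      ri <- max(1, i - 1):min(ny, i + 1)
      rj <- max(1, j - 1):min(nx, j + 1)
      res <- 0
      for (comp in list(u, v)) {
        nb <- comp[ri, rj]
        nb <- nb[is.finite(nb)]
        nb <- nb[-match(comp[i, j], nb)]          # drop self (one instance)
        if (length(nb) < 3) next
        med <- stats::median(nb)
        rm_ <- stats::median(abs(nb - med))
        res <- max(res, abs(comp[i, j] - med) / (rm_ + eps))
      }
      out[i, j] <- res > threshold
    }
  }
  out
}

#' Two-frame PIV velocity field
#'
#' Tiles the frame pair with interrogation windows at the configured
#' overlap; each window is correlated ([correlate_windows()]), the peak
#' refined to subpixel precision ([subpixel_peak()]), and the speckle
#' contrast of the window recorded so each vector carries its own SR value.
#' Vectors with `P_c` below the threshold, a border peak, or failing the
#' normalized-median outlier test are flagged invalid.
#'
#' @param frame_a,frame_b numeric matrices (consecutive frames).
#' @param config a [piv_config()].
#' @return A data.frame of class `xpiv_field` with columns `i`, `j` (grid
#'   indices), `y_px`, `x_px` (window centers), `v_px`, `u_px`
#'   (displacement in px/frame along rows/cols), `p_c`, `contrast`, `sr`,
#'   `valid`; attributes `grid_dim`, `units = "px/frame"`, `config`.
#' @export
compute_field <- function(frame_a, frame_b, config = piv_config()) {
  if (!identical(dim(frame_a), dim(frame_b)))
    stopf("frames must share dimensions")
  wr <- config$window_size[1]; wc <- config$window_size[2]
  if (wr > nrow(frame_a) || wc > ncol(frame_a))
    stopf("interrogation window (%d x %d) larger than frame (%d x %d)",
          wr, wc, nrow(frame_a), ncol(frame_a))
  sr_step <- max(1L, as.integer(round(wr * (1 - config$overlap))))
  sc_step <- max(1L, as.integer(round(wc * (1 - config$overlap))))
  y0 <- seq(1L, nrow(frame_a) - wr + 1L, by = sr_step)
  x0 <- seq(1L, ncol(frame_a) - wc + 1L, by = sc_step)
  ny <- length(y0); nx <- length(x0)
  u <- v <- pcm <- cm <- matrix(NA_real_, ny, nx)
  border <- matrix(FALSE, ny, nx)
  plan <- zncc_plan(config$window_size, config$max_displacement)
  for (i in seq_len(ny)) {
    rows <- y0[i]:(y0[i] + wr - 1L)
    for (j in seq_len(nx)) {
      cols <- x0[j]:(x0[j] + wc - 1L)
      wa <- frame_a[rows, cols]; wb <- frame_b[rows, cols]
      corr <- correlate_windows(wa, wb, plan = plan)
      sp <- subpixel_peak(corr, config$subpixel)
      u[i, j] <- sp$dx; v[i, j] <- sp$dy
      pcm[i, j] <- sp$p_c
      border[i, j] <- isTRUE(sp$on_border)
      mu <- mean(wa)
      cm[i, j] <- if (mu > 0) sd_pop(wa) / mu else NA_real_
    }
  }
  low_pc <- !is.finite(pcm) | pcm < config$pc_threshold
  u_chk <- u; v_chk <- v
  u_chk[low_pc | border] <- NA; v_chk[low_pc | border] <- NA
  nmt <- normalized_median_outliers(u_chk, v_chk, config$nmt_threshold,
                                    config$nmt_eps)
  valid <- !low_pc & !border & !nmt
  out <- data.frame(
    i = rep(seq_len(ny), times = nx), j = rep(seq_len(nx), each = ny),
    y_px = rep(y0 + (wr - 1) / 2, times = nx),
    x_px = rep(x0 + (wc - 1) / 2, each = ny),
    v_px = as.vector(v), u_px = as.vector(u),
    p_c = as.vector(pcm), contrast = as.vector(cm),
    sr = as.vector(sr_value(pmin(pmax(pcm, 0), 1), pmax(cm, 0))),
    valid = as.vector(valid)
  )
  structure(out, grid_dim = c(ny, nx), units = "px/frame", config = config,
            class = c("xpiv_field", "data.frame"))
}

#' Ensemble-average a list of instantaneous velocity fields
#'
#' Per-grid-point mean over the fields in which the vector is valid. Points
#' valid in fewer than `min_valid_fraction` of the fields (config of the
#' first field) are marked invalid.
#'
#' @param fields list of `xpiv_field` objects on identical grids.
#' @return An `xpiv_field` with columns as in [compute_field()] plus
#'   `n_pairs` (number of fields averaged per vector).
#' @export
ensemble_mean <- function(fields) {
  if (length(fields) == 0) stopf("no fields to average")
  g <- attr(fields[[1]], "grid_dim")
  for (f in fields) {
    if (!identical(attr(f, "grid_dim"), g)) stopf("velocity-field grids differ")
  }
  cfg <- attr(fields[[1]], "config")
  n <- length(fields)
  npt <- nrow(fields[[1]])
  get <- function(col)
    matrix(vapply(fields, function(f) f[[col]], numeric(npt)), nrow = npt)
  valid <- matrix(vapply(fields, function(f) f$valid & is.finite(f$u_px),
                         logical(npt)), nrow = npt)
  um <- get("u_px"); vm <- get("v_px"); pcm <- get("p_c"); cm <- get("contrast")
  um[!valid] <- NA; vm[!valid] <- NA
  n_valid <- rowSums(valid)
  mean_valid <- function(m) ifelse(n_valid > 0, rowMeans(m, na.rm = TRUE), NA_real_)
  out <- fields[[1]]
  out$u_px <- mean_valid(um)
  out$v_px <- mean_valid(vm)
  out$p_c <- rowMeans(pcm, na.rm = TRUE)
  out$contrast <- rowMeans(cm, na.rm = TRUE)
  out$sr <- ifelse(is.finite(out$p_c) & is.finite(out$contrast),
                   pmin(pmax(out$p_c, 0), 1) * pmax(out$contrast, 0), NA_real_)
  out$n_pairs <- n_valid
  out$valid <- n_valid >= cfg$min_valid_fraction * n
  out$u_px[!out$valid] <- NA
  out$v_px[!out$valid] <- NA
  attr(out, "ensemble_n") <- n
  out
}

#' Convert a velocity field from pixel to physical units
#'
#' `v[mm/s] = displacement[px/frame] * pixel_pitch[um/px] * frame_rate[1/s]
#' / 1000`. Pixel-unit columns are retained; physical positions are added
#' in um.
#'
#' @param field an `xpiv_field` in px/frame units.
#' @param pixel_pitch um/px.
#' @param frame_rate frames/s.
#' @return The field with added `u_mms`, `v_mms`, `x_um`, `y_um` columns
#'   and `units = "mm/s"`.
#' @export
to_physical <- function(field, pixel_pitch, frame_rate) {
  if (pixel_pitch <= 0 || frame_rate <= 0)
    stopf("pixel_pitch and frame_rate must be positive")
  s <- pixel_pitch * frame_rate / 1000
  field$u_mms <- field$u_px * s
  field$v_mms <- field$v_px * s
  field$x_um <- field$x_px * pixel_pitch
  field$y_um <- field$y_px * pixel_pitch
  attr(field, "units") <- "mm/s"
  attr(field, "pixel_pitch") <- pixel_pitch
  attr(field, "frame_rate") <- frame_rate
  field
}
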