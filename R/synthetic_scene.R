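#' Synthetic X-ray microbubble scene configuration
#'
#' Builds the ground-truth configuration for the synthetic phase-contrast
#' scene generator: a cylindrical vessel of radius `vessel_radius` carrying a
#' steady power-law ("bluntness") flow `u(r) = v_max * (1 - (r/R)^K)`, seeded
#' with microbubble tracers, imaged in orthographic projection onto the
#' detector behind a static tissue-like background with multiplicative
#' illumination nonuniformity and additive sensor noise.
#'
#' Defaults mirror a synchrotron imaging geometry: 1024 x 1024 px frames at
#' 1000 fps with a 1.8994 um/px pitch (1945 um field of view), 13.3 um mean
#' bubble diameter. `bubble_count` defaults to a dense-speckle seeding of
#' about 48 bubbles per 32 x 64 px interrogation window of projected lumen:
#' in the dense regime the window cross-correlation is a superposition of
#' per-tracer peaks and its maximum estimates the (speckle-width weighted)
#' chord-mean velocity — the amassed profile the inversion assumes — whereas
#' sparse seeding makes each vector a winner-takes-all draw from a few
#' bubbles (see the methods vignette).
#'
#' @param frame_shape integer c(rows, cols) of the detector frame, px.
#' @param pixel_pitch physical pixel size, um/px.
#' @param frame_rate acquisition rate, frames/s.
#' @param vessel_radius vessel lumen radius R, um.
#' @param vessel_center_row image row of the vessel axis, px.
#' @param v_max true maximum (centerline) velocity, mm/s.
#' @param bluntness bluntness index K (>= 1); 2 is parabolic Poiseuille flow,
#'   larger is blunter (shear-thinning blood).
#' @param bubble_mean_diameter mean tracer diameter, um.
#' @param bubble_diameter_cv coefficient of variation of the (lognormal)
#'   diameter distribution.
#' @param bubble_count number of bubbles in the rendered cylinder segment;
#'   `NULL` selects the default seeding density described above.
#' @param rim_amplitude,core_amplitude intensity amplitudes of the bright-rim
#'   and dark-core parts of the bubble template (fractions of full scale).
#' @param baseline mean transmitted intensity of the background, full scale
#'   in [0, 1].
#' @param background_amplitude standard deviation of the static tissue-like
#'   background structure (intensity units).
#' @param background_scale correlation length of the background structure, px.
#' @param illumination_gradient fractional peak-to-center amplitude of the
#'   smooth multiplicative illumination ramp.
#' @param noise_sigma standard deviation of additive Gaussian sensor noise.
#' @param seed integer RNG seed; a fixed seed makes generated sequences
#'   byte-identical.
#'
#' @return A list of class `xpiv_scene_config`.
#' @export
scene_config <- function(frame_shape = c(1024L, 1024L),
                         pixel_pitch = 1945 / 1024,
                         frame_rate = 1000,
                         vessel_radius = 500,
                         vessel_center_row = NULL,
                         v_max = 20,
                         bluntness = 3.31,
                         bubble_mean_diameter = 13.3,
                         bubble_diameter_cv = 0.15,
                         bubble_count = NULL,
                         rim_amplitude = 0.15,
                         core_amplitude = 0.25,
                         baseline = 0.5,
                         background_amplitude = 0.015,
                         background_scale = 24,
                         illumination_gradient = 0.1,
                         noise_sigma = 0.008,
                         seed = 1L) {
  frame_shape <- as.integer(frame_shape)
  if (length(frame_shape) != 2L || any(frame_shape <= 0L))
    stopf("frame_shape must be two positive integers")
  if (vessel_radius <= 0) stopf("vessel_radius must be positive")
  if (bluntness < 1) stopf("bluntness index K must be >= 1")
  if (frame_rate <= 0 || pixel_pitch <= 0) stopf("frame_rate and pixel_pitch must be positive")
  if (bubble_mean_diameter <= 0) stopf("bubble_mean_diameter must be positive")
  if (v_max < 0) stopf("v_max must be non-negative")
  if (noise_sigma < 0) stopf("noise_sigma must be non-negative")
  if (is.null(vessel_center_row)) vessel_center_row <- (frame_shape[1] + 1) / 2
  if (is.null(bubble_count)) {
    # ~48 bubbles per 32x64 px window of projected lumen (dense speckle)
    lumen_rows <- min(2 * vessel_radius / pixel_pitch, frame_shape[1])
    bubble_count <- round(48 * lumen_rows * frame_shape[2] / (32 * 64))
  }
  bubble_count <- as.integer(bubble_count)
  if (bubble_count < 0) stopf("bubble_count must be non-negative")
  structure(
    list(
      frame_shape = frame_shape, pixel_pitch = pixel_pitch,
      frame_rate = frame_rate, vessel_radius = vessel_radius,
      vessel_center_row = vessel_center_row, v_max = v_max,
      bluntness = bluntness, bubble_mean_diameter = bubble_mean_diameter,
      bubble_diameter_cv = bubble_diameter_cv, bubble_count = bubble_count,
      rim_amplitude = rim_amplitude, core_amplitude = core_amplitude,
      baseline = baseline, background_amplitude = background_amplitude,
      background_scale = background_scale,
      illumination_gradient = illumination_gradient,
      noise_sigma = noise_sigma, seed = as.integer(seed)
    ),
    class = "xpiv_scene_config"
  )
}

# Axial domain: bubble axial coordinate s maps to image column s / pitch.
# A margin of one template half-width on each side lets bubbles enter and
# leave the field of view smoothly; recycling wraps s around this domain.
scene_domain <- function(config) {
  margin <- 4 * config$bubble_mean_diameter          # um
  len_um <- config$frame_shape[2] * config$pixel_pitch
  c(lo = -margin, hi = len_um + margin)
}

#' Create a synthetic scene
#'
#' Samples bubble positions uniformly over the cylinder volume (uniform in
#' axial position and azimuth, uniform per unit cross-section area, i.e.
#' uniform in r^2) and freezes the static background and illumination fields
#' for the scene lifetime.
#'
#' @param config a [scene_config()].
#' @return A list of class `xpiv_scene` with fields `s`, `r`, `theta`
#'   (bubble cylinder coordinates, um), `diameter` (um), `background`
#'   (static background image including baseline), `illumination`
#'   (multiplicative field, mean 1).
#' @export
make_scene <- function(config) {
  if (!inherits(config, "xpiv_scene_config")) stopf("config must come from scene_config()")
  dom <- scene_domain(config)
  with_seed(config$seed, {
    n <- config$bubble_count
    s <- stats::runif(n, dom["lo"], dom["hi"])
    r <- config$vessel_radius * sqrt(stats::runif(n))
    theta <- stats::runif(n, 0, 2 * pi)
    cv <- config$bubble_diameter_cv
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      meanlog <- log(config$bubble_mean_diameter) - sdlog^2 / 2
      d <- stats::rlnorm(n, meanlog, sdlog)
    } else {
      d <- rep(config$bubble_mean_diameter, n)
    }
    nr <- config$frame_shape[1]; nc <- config$frame_shape[2]
    bg <- matrix(stats::rnorm(nr * nc), nr, nc)
    bg <- fft_gaussian_blur(bg, config$background_scale)
    bg <- bg - mean(bg)
    s_bg <- sd_pop(bg)
    bg <- if (s_bg > 0) bg / s_bg * config$background_amplitude else bg * 0
    background <- config$baseline + bg
    xx <- (seq_len(nc) - (nc + 1) / 2) / nc
    illumination <- matrix(1 + config$illumination_gradient * 2 * rep(xx, each = nr), nr, nc)
    structure(
      list(s = s, r = r, theta = theta, diameter = d,
           background = background, illumination = illumination),
      class = "xpiv_scene"
    )
  })
}

# Axial velocity law of the scene, mm/s at radial position r (um).
scene_velocity <- function(r, config) {
  config$v_max * (1 - (r / config$vessel_radius)^config$bluntness)
}

#' Advance the scene by one time step
#'
#' Each bubble's axial coordinate advances by `u(r) * dt` with
#' `u(r) = v_max * (1 - (r/R)^K)`; radial position and diameter are
#' unchanged while a bubble stays in view. Bubbles leaving the axial
#' domain downstream are recycled at the inflow edge with a fresh
#' transverse position drawn from the flux-weighted radial distribution
#' `p(r) dr` proportional to `r u(r) dr` (and a fresh azimuth): this is the
#' open-boundary condition of a continuously seeded pipe, and it is the
#' unique re-injection law under which the uniform-per-unit-volume tracer
#' concentration is exactly stationary (removal rate of a radial class is
#' proportional to its number times u(r); matching influx must be
#' flux-weighted). The draws use the current RNG stream
#' ([generate_sequence()] seeds it); the bubble count is conserved.
#'
#' @param scene an `xpiv_scene`.
#' @param dt time step, seconds.
#' @param config the [scene_config()] the scene was built from.
#' @return The advected scene.
#' @export
advect <- function(scene, dt, config) {
  if (dt <= 0) stopf("dt must be positive")
  u <- scene_velocity(scene$r, config)           # mm/s
  scene$s <- scene$s + u * 1000 * dt             # um
  dom <- scene_domain(config)
  len <- dom["hi"] - dom["lo"]
  wrapped <- which(scene$s > dom["hi"] | scene$s < dom["lo"])
  if (length(wrapped)) {
    scene$s[wrapped] <- ((scene$s[wrapped] - dom["lo"]) %% len) + dom["lo"]
    scene$r[wrapped] <- sample_flux_radius(length(wrapped), config)
    scene$theta[wrapped] <- stats::runif(length(wrapped), 0, 2 * pi)
  }
  names(scene$s) <- NULL
  scene
}

# Draw n radii from the flux-weighted distribution p(r) ~ r * u(r) by
# rejection: propose uniform-per-unit-area (r = R sqrt(U)), accept with
# probability u(r)/v_max. For v_max = 0 (no flow) no bubble ever wraps,
# but fall back to the area-uniform draw for safety.
sample_flux_radius <- function(n, config) {
  if (config$v_max <= 0)
    return(config$vessel_radius * sqrt(stats::runif(n)))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    prop <- config$vessel_radius * sqrt(stats::runif(length(need)))
    acc <- stats::runif(length(need)) <
      scene_velocity(prop, config) / config$v_max
    out[need[acc]] <- prop[acc]
    need <- need[!acc]
  }
  out
}

#' Render one projection frame of a scene
#'
#' Orthographic projection along the viewing axis: every bubble, regardless
#' of depth, is drawn equally sharp as a radially symmetric dark-core /
#' bright-rim template (difference of Gaussians, rim sigma = 0.35 d_px, core
#' sigma = 0.20 d_px) at its subpixel position; overlapping templates sum.
#' The static background is added, the multiplicative illumination applied,
#' Gaussian sensor noise of sd `noise_sigma` added, and the result clipped
#' to [0, 1].
#'
#' @param scene an `xpiv_scene`.
#' @param config the matching [scene_config()].
#' @param noise logical; draw additive sensor noise (uses the current RNG
#'   stream; [generate_sequence()] manages seeding).
#' @return A numeric matrix frame.
#' @export
render <- function(scene, config, noise = TRUE) {
  nr <- config$frame_shape[1]; nc <- config$frame_shape[2]
  canvas <- matrix(0, nr, nc)
  n <- length(scene$s)
  if (n > 0) {
    col_px <- scene$s / config$pixel_pitch + 0.5       # s = 0 -> left edge
    row_px <- config$vessel_center_row + scene$r * cos(scene$theta) / config$pixel_pitch
    d_px <- scene$diameter / config$pixel_pitch
    sr <- 0.35 * d_px; sc <- 0.20 * d_px
    # common stamp half-width so the per-bubble Gaussian factors can be
    # evaluated in bulk (4 exp calls); the stamps themselves are added in
    # a tight loop exploiting separability
    k <- max(3L, ceiling(3 * max(sr)))
    m <- 2L * k + 1L
    off <- -k:k
    r0 <- as.integer(floor(row_px)); c0 <- as.integer(floor(col_px))
    # m x n matrices: column b holds bubble b's row/col Gaussian factor
    dy <- outer(off, r0 - row_px, `+`)
    dx <- outer(off, c0 - col_px, `+`)
    gy_r <- exp(-sweep(dy^2, 2, 2 * sr^2, `/`))
    gx_r <- exp(-sweep(dx^2, 2, 2 * sr^2, `/`))
    gy_c <- exp(-sweep(dy^2, 2, 2 * sc^2, `/`))
    gx_c <- exp(-sweep(dx^2, 2, 2 * sc^2, `/`))
    rim <- config$rim_amplitude; core <- config$core_amplitude
    for (b in seq_len(n)) {
      rows <- (r0[b] - k):(r0[b] + k)
      cols <- (c0[b] - k):(c0[b] + k)
      if (r0[b] - k >= 1L && r0[b] + k <= nr &&
          c0[b] - k >= 1L && c0[b] + k <= nc) {
        canvas[rows, cols] <- canvas[rows, cols] +
          rim * (gy_r[, b] %o% gx_r[, b]) - core * (gy_c[, b] %o% gx_c[, b])
      } else {
        keep_r <- which(rows >= 1L & rows <= nr)
        keep_c <- which(cols >= 1L & cols <= nc)
        if (!length(keep_r) || !length(keep_c)) next
        canvas[rows[keep_r], cols[keep_c]] <- canvas[rows[keep_r], cols[keep_c]] +
          rim * (gy_r[keep_r, b] %o% gx_r[keep_c, b]) -
          core * (gy_c[keep_r, b] %o% gx_c[keep_c, b])
      }
    }
  }
  frame <- (scene$background + canvas) * scene$illumination
  if (noise && config$noise_sigma > 0)
    frame <- frame + matrix(stats::rnorm(nr * nc, 0, config$noise_sigma), nr, nc)
  pmin(pmax(frame, 0), 1)
}

#' Generate a seeded image sequence with ground truth
#'
#' Alternates [render()] and [advect()] with `dt = 1 / frame_rate`. The
#' entire sequence is driven by `config$seed`, so identical configurations
#' produce byte-identical stacks.
#'
#' @param config a [scene_config()].
#' @param n_frames number of frames (>= 2; velocimetry needs pairs).
#' @param keep_positions store per-frame bubble positions in the ground
#'   truth (memory permitting).
#' @return A list with `stack` (an [image_stack()]) and `truth`: the analytic
#'   amassed profile sampled across the lumen (`profile`: x_um, v_mms), the
#'   true `v_max`, `bluntness`, `vessel_radius`, `flow_rate_ml_min`, the
#'   expected centerline image displacement in px/frame, per-frame bubble
#'   positions (if kept), and the config echo.
#' @export
generate_sequence <- function(config, n_frames, keep_positions = FALSE) {
  if (n_frames < 2) stopf("n_frames must be >= 2: velocimetry needs image pairs")
  dt <- 1 / config$frame_rate
  scene0 <- make_scene(config)
  frames <- vector("list", n_frames)
  positions <- if (keep_positions) vector("list", n_frames) else NULL
  with_seed(config$seed + 1L, {
    scene <- scene0
    for (k in seq_len(n_frames)) {
      frames[[k]] <- render(scene, config)
      if (keep_positions)
        positions[[k]] <- data.frame(s = scene$s, r = scene$r,
                                     theta = scene$theta, d = scene$diameter)
      if (k < n_frames) scene <- advect(scene, dt, config)
    }
  })
  stack <- image_stack(frames, config$pixel_pitch, config$frame_rate)
  x_um <- seq(-config$vessel_radius, config$vessel_radius, length.out = 101)
  truth <- list(
    v_max = config$v_max,
    bluntness = config$bluntness,
    vessel_radius = config$vessel_radius,
    vessel_center_row = config$vessel_center_row,
    profile = data.frame(
      x_um = x_um,
      v_mms = amassed_profile(x_um, config$v_max, config$bluntness,
                              config$vessel_radius)
    ),
    flow_rate_ml_min = flow_rate(config$v_max, config$bluntness,
                                 config$vessel_radius),
    centerline_displacement_px =
      config$v_max * 1000 * dt / config$pixel_pitch,
    positions = positions,
    config = config
  )
  list(stack = stack, truth = truth)
}
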