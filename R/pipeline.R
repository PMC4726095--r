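#' Run configuration for the full measurement pipeline
#'
#' @param scene a [scene_config()] (simulate mode), or `NULL` when an input
#'   stack is supplied to [run_pipeline()].
#' @param restore a [restoration_config()].
#' @param piv a [piv_config()].
#' @param n_frames frames to simulate (simulate mode).
#' @param n_pairs maximum number of frame pairs (non-overlapping,
#'   1-2, 3-4, ...) entering the ensemble; default 200.
#' @param vessel_center_row,vessel_radius lumen geometry for profile
#'   extraction; default from the scene config.
#' @param stokes `NULL` to skip buoyancy correction, or a list of arguments
#'   for [stokes_terminal_velocity()] plus optional `gravity` (image
#'   components, default `c(1, 0)`).
#' @param seed integer seed recorded in every output; in simulate mode it
#'   overrides `scene$seed`.
#' @return A list of class `xpiv_run_config`.
#' @export
run_config <- function(scene = scene_config(), restore = restoration_config(),
                       piv = piv_config(), n_frames = 400L, n_pairs = 200L,
                       vessel_center_row = NULL, vessel_radius = NULL,
                       stokes = NULL, seed = NULL) {
  if (!is.null(seed) && !is.null(scene)) scene$seed <- as.integer(seed)
  structure(
    list(scene = scene, restore = restore, piv = piv,
         n_frames = as.integer(n_frames), n_pairs = as.integer(n_pairs),
         vessel_center_row = vessel_center_row %||% scene$vessel_center_row,
         vessel_radius = vessel_radius %||% scene$vessel_radius,
         stokes = stokes,
         seed = as.integer(seed %||% (if (!is.null(scene)) scene$seed else 0L))),
    class = "xpiv_run_config"
  )
}

# Ensemble PIV over non-overlapping frame pairs of a stack.
piv_ensemble <- function(stack, piv_cfg, n_pairs) {
  n <- length(stack$frames)
  starts <- seq(1L, n - 1L, by = 2L)
  if (length(starts) > n_pairs) starts <- starts[seq_len(n_pairs)]
  fields <- lapply(starts, function(k)
    compute_field(stack$frames[[k]], stack$frames[[k + 1L]], piv_cfg))
  ensemble_mean(fields)
}

#' Extract the transverse (amassed) velocity profile from a field
#'
#' Averages the along-flow velocity component over all valid vectors at
#' each transverse grid station and converts station positions to physical
#' offsets from the vessel axis.
#'
#' @param field an `xpiv_field` in physical units (see [to_physical()]).
#' @param vessel_center_row vessel axis image row, px.
#' @param pixel_pitch um/px.
#' @return data.frame with `x_um` (offset from the axis), `v_mms` (mean
#'   along-flow velocity), `n_vectors`, `p_c` (station means).
#' @export
extract_profile <- function(field, vessel_center_row, pixel_pitch) {
  if (!identical(attr(field, "units"), "mm/s"))
    stopf("field is not in physical units; run to_physical() first")
  sp <- split(field, field$i)
  rows <- lapply(sp, function(d) {
    ok <- d$valid & is.finite(d$u_mms)
    data.frame(
      x_um = (d$y_px[1] - vessel_center_row) * pixel_pitch,
      v_mms = if (any(ok)) mean(d$u_mms[ok]) else NA_real_,
      n_vectors = sum(ok),
      p_c = mean(d$p_c, na.rm = TRUE)
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$x_um), , drop = FALSE]
}

#' Run the full measurement pipeline
#'
#' Simulate (or take) an image stack, restore it, compute speckle metrics
#' before and after restoration, run ensemble two-frame PIV, convert to
#' physical units, optionally remove microbubble buoyancy, extract the
#' transverse profile and fit the amassed velocity-profile model.
#'
#' @param config an [run_config()].
#' @param stack optional pre-acquired [image_stack()]; when `NULL`, a stack
#'   is generated from `config$scene`.
#' @return A list of class `xpiv_run`: `fit` (an `xpiv_profile_fit`),
#'   `profile`, `field` (ensemble field, physical units), `metrics` (raw and
#'   restored speckle reports and mean SR), `restoration_log`, `truth`
#'   (simulate mode), and `provenance` (seed, config hash).
#' @export
run_pipeline <- function(config, stack = NULL) {
  truth <- NULL
  if (is.null(stack)) {
    if (is.null(config$scene)) stopf("no input stack and no scene config")
    sim <- generate_sequence(config$scene, config$n_frames)
    stack <- sim$stack
    truth <- sim$truth
  }
  restored <- restore(stack, config$restore)

  metrics_raw <- tryCatch(speckle_report(stack), error = function(e) NULL)
  metrics_restored <- tryCatch(speckle_report(restored), error = function(e) NULL)

  ens <- piv_ensemble(restored, config$piv, config$n_pairs)
  phys <- to_physical(ens, stack$pixel_pitch, stack$frame_rate)
  if (!is.null(config$stokes)) {
    st <- config$stokes
    gravity <- st$gravity %||% c(1, 0)
    st$gravity <- NULL
    v_t <- do.call(stokes_terminal_velocity, st)
    phys <- buoyancy_correct(phys, v_t, gravity)
  }
  prof <- extract_profile(phys, config$vessel_center_row, stack$pixel_pitch)
  hw_um <- config$piv$window_size[1] / 2 * stack$pixel_pitch
  # speckle-correlation width along the flow axis, in velocity units, for
  # the correlation-peak station model (FWHM -> sd of the Gaussian lobe)
  sigma_mms <- if (!is.null(metrics_restored)) {
    metrics_restored$size_x / (2 * sqrt(2 * log(2))) *
      stack$pixel_pitch * stack$frame_rate / 1000
  } else NULL
  fit <- tryCatch(
    fit_profile(prof$x_um, prof$v_mms, R = config$vessel_radius,
                smear_halfwidth_um = hw_um, peak_sigma_mms = sigma_mms),
    error = function(e) e
  )
  mean_pc <- mean(ens$p_c, na.rm = TRUE)
  structure(
    list(
      fit = if (inherits(fit, "error")) NULL else fit,
      fit_error = if (inherits(fit, "error")) conditionMessage(fit) else NULL,
      profile = prof, field = phys,
      metrics = list(
        raw = metrics_raw, restored = metrics_restored,
        sr_raw = if (!is.null(metrics_raw))
          sr_value(min(max(mean_pc, 0), 1), metrics_raw$contrast) else NA_real_,
        sr_restored = if (!is.null(metrics_restored))
          sr_value(min(max(mean_pc, 0), 1), metrics_restored$contrast) else NA_real_,
        mean_p_c = mean_pc,
        valid_fraction = mean(ens$valid)
      ),
      restoration_log = attr(restored, "restoration_log"),
      truth = truth,
      provenance = list(seed = config$seed, config_hash = config_hash(config))
    ),
    class = "xpiv_run"
  )
}

#' @export
print.xpiv_run <- function(x, ...) {
  cat("<xpiv_run>\n")
  if (!is.null(x$fit)) print(x$fit) else cat("  profile fit failed:", x$fit_error, "\n")
  cat(sprintf("  mean P_c = %.3f, valid vectors = %.0f%%, C raw -> restored: %.4f -> %.4f\n",
              x$metrics$mean_p_c, 100 * x$metrics$valid_fraction,
              x$metrics$raw$contrast %||% NA_real_,
              x$metrics$restored$contrast %||% NA_real_))
  invisible(x)
}

#' Measurability sweep over displacement settings
#'
#' Re-runs the simulate-restore-PIV chain over a ladder of centerline
#' displacement settings (px/frame, hardware-free parameterization) and
#' records the mean relative peak height P_c, speckle contrast C, SR, the
#' measured flow rate, and the valid-vector fraction at each setting. The
#' largest setting with mean `P_c >= 0.5` is reported as the maximum
#' measurable point.
#'
#' @param base_config an [run_config()] whose scene supplies geometry and
#'   imaging parameters.
#' @param displacements_px centerline displacements to test, px/frame
#'   (>= 3 settings).
#' @return A list of class `xpiv_sweep`: `table` (one row per setting) and
#'   `max_measurable_px` (NA when no setting passes the criterion).
#' @export
measurability_sweep <- function(base_config, displacements_px) {
  if (length(displacements_px) < 3) stopf("need at least 3 sweep settings")
  displacements_px <- sort(displacements_px)
  sc <- base_config$scene
  rows <- lapply(displacements_px, function(dpx) {
    cfg <- base_config
    cfg$scene$v_max <- dpx * sc$pixel_pitch * sc$frame_rate / 1000
    run <- run_pipeline(cfg)
    q <- if (!is.null(run$fit)) run$fit$flow_rate_ml_min else NA_real_
    data.frame(
      displacement_px = dpx,
      v_max_set_mms = cfg$scene$v_max,
      input_q_ml_min = flow_rate(cfg$scene$v_max, sc$bluntness, sc$vessel_radius),
      mean_p_c = run$metrics$mean_p_c,
      mean_contrast = run$metrics$restored$contrast,
      mean_sr = run$metrics$sr_restored,
      measured_q_ml_min = q,
      valid_fraction = run$metrics$valid_fraction
    )
  })
  tab <- do.call(rbind, rows)
  pass <- tab$displacement_px[is.finite(tab$mean_p_c) & tab$mean_p_c >= 0.5]
  structure(
    list(table = tab,
         max_measurable_px = if (length(pass)) max(pass) else NA_real_,
         seed = base_config$seed,
         config_hash = config_hash(base_config)),
    class = "xpiv_sweep"
  )
}

#' @export
print.xpiv_sweep <- function(x, ...) {
  cat("<xpiv_sweep>\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("  maximum measurable displacement (mean P_c >= 0.5): %s px/frame\n",
              format(x$max_measurable_px)))
  invisible(x)
}

#' Write a velocity field to CSV with provenance
#'
#' @param field an `xpiv_field`.
#' @param path output CSV path.
#' @param seed,config_hash provenance stamped into a header comment line.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path, seed = NA, config_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# xpiv velocity field; units=%s; seed=%s; config=%s",
                     attr(field, "units"), seed, config_hash), con)
  utils::write.csv(as.data.frame(field), con, row.names = FALSE)
  invisible(path)
}
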