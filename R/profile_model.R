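#' Line-of-sight correction factor alpha
#'
#' When an axisymmetric velocity profile `u(r) = v_max * (1 - (r/R)^K)` is
#' imaged in projection, every transverse station x averages the axial
#' velocity along the chord through the cylinder at normalized offset
#' `xi = |x|/R`. The "amassed" profile seen by projection velocimetry is
#' `v(x) = v_max * alpha(xi, K)` with
#'
#' `alpha(xi, K) = 1 - (1 / sqrt(1 - xi^2)) * Int_0^sqrt(1-xi^2) (xi^2 + eta^2)^(K/2) d eta`
#'
#' i.e. the chord average of `u(r)/v_max`. Closed forms: `alpha(0, K) =
#' K / (K + 1)` and `alpha(xi, 2) = (2/3) * (1 - xi^2)`.
#'
#' Evaluated by adaptive quadrature; `xi >= 1` returns 0 (wall limit, by
#' continuity).
#'
#' @param xi normalized transverse offset(s) in `[0, 1)`; vectorized.
#' @param K bluntness index, >= 1.
#' @return alpha values in `[0, 1]`.
#' @export
alpha_correction <- function(xi, K) {
  if (K < 1) stopf("bluntness index K must be >= 1")
  if (any(xi < 0)) stopf("xi must be non-negative")
  vapply(xi, function(x) {
    if (x >= 1) return(0)
    L <- sqrt(1 - x^2)
    val <- stats::integrate(function(eta) (x^2 + eta^2)^(K / 2), 0, L,
                            rel.tol = 1e-10, abs.tol = 1e-12)$value
    1 - val / L
  }, numeric(1))
}

#' Amassed (projection-averaged) velocity profile
#'
#' @param x transverse positions, um (same axis/origin as the image rows).
#' @param v_max maximum 3D velocity, mm/s.
#' @param K bluntness index (>= 1).
#' @param R vessel radius, um.
#' @param x0 transverse offset of the vessel center, um.
#' @return velocities in mm/s; zero outside the lumen.
#' @export
amassed_profile <- function(x, v_max, K, R, x0 = 0) {
  if (R <= 0) stopf("R must be positive")
  xi <- abs(x - x0) / R
  v <- numeric(length(x))
  inside <- xi < 1
  if (any(inside)) v[inside] <- v_max * alpha_correction(xi[inside], K)
  v
}

# Forward model of one measured station: quadrature over the window's
# transverse extent (5-point Gauss-Legendre, rows weighted by chord depth)
# and over depth along each chord (10-point GL, tracers uniform in depth).
# With `sigma` (mm/s) the prediction is the correlation-peak fixed point;
# without it, the plain weighted chord mean (the amassed profile smeared
# by the window).
station_model <- function(hw, sigma = NULL) {
  gl5_x <- c(-0.9061798459386640, -0.5384693101056831, 0,
             0.5384693101056831, 0.9061798459386640)
  gl5_w <- c(0.2369268850561891, 0.4786286704993665, 0.5688888888888889,
             0.4786286704993665, 0.2369268850561891) / 2
  # 10-point GL on [0, 1]
  g10 <- c(0.0130467357414141, 0.0674683166555077, 0.1602952158504878,
           0.2833023029353764, 0.4255628305091844, 0.5744371694908156,
           0.7166976970646236, 0.8397047841495122, 0.9325316833444923,
           0.9869532642585859)
  w10 <- c(0.0333356721543441, 0.0747256745752903, 0.1095431812579910,
           0.1346333596549982, 0.1477621123573764, 0.1477621123573764,
           0.1346333596549982, 0.1095431812579910, 0.0747256745752903,
           0.0333356721543441)
  if (hw > 0) {
    off <- hw * gl5_x; wr <- gl5_w
  } else {
    off <- 0; wr <- 1
  }
  function(x, vmax, K, R, xc) {
    n <- length(x)
    m <- length(off) * length(g10)
    U <- matrix(0, n, m)
    W0 <- matrix(0, n, m)
    col <- 1L
    for (k in seq_along(off)) {
      xk <- abs(x + off[k] - xc)
      L <- sqrt(pmax(R^2 - xk^2, 0))
      for (j in seq_along(g10)) {
        z <- L * g10[j]
        r <- sqrt(xk^2 + z^2)
        U[, col] <- vmax * pmax(1 - (r / R)^K, 0)
        W0[, col] <- wr[k] * L * w10[j]
        col <- col + 1L
      }
    }
    den0 <- rowSums(W0)
    ok <- den0 > 0
    D <- numeric(n)
    D[ok] <- rowSums(U * W0)[ok] / den0[ok]
    if (!is.null(sigma) && sigma > 0) {
      for (it in 1:12) {
        Wn <- W0 * exp(-(D - U)^2 / (2 * sigma^2))
        den <- rowSums(Wn)
        Dn <- ifelse(den > 0, rowSums(U * Wn) / den, 0)
        if (max(abs(Dn - D)) < 1e-10) { D <- Dn; break }
        D <- Dn
      }
      D[!ok] <- 0
    }
    D
  }
}

#' Fit the amassed profile model to a measured transverse profile
#'
#' Nonlinear least squares of `v(x) = v_max * alpha(|x - x0|/R, K)` over
#' `(v_max, K, x0)` and optionally `R`, with bounds `K` in `[1, 10]` and
#' multi-start from K = 2, 3, 5. Invalid samples (NA) are dropped. Requires
#' at least 8 valid samples spanning at least 60% of the lumen diameter.
#'
#' @param x transverse sample positions, um.
#' @param v measured amassed velocities, mm/s (NA = invalid vector).
#' @param R vessel radius in um; fixed unless `fit_radius = TRUE`.
#' @param fit_radius estimate R as a free parameter (started at `R`).
#' @param x0 starting value for the center offset, um.
#' @param smear_halfwidth_um transverse half-extent of the interrogation
#'   window, um. When positive, the forward model averages the amassed
#'   profile over `[x - hw, x + hw]` at each station (5-point
#'   Gauss-Legendre) with weights proportional to the projected tracer
#'   density, i.e. the chord depth `sqrt(R^2 - x'^2)`: tracers are uniform
#'   per unit volume, so station vectors sample window rows in proportion
#'   to the chord through the lumen. This accounts for both the blunting a
#'   finite window imposes on the measured profile and its bias toward the
#'   faster inner rows near the wall; 0 fits the point model.
#' @param peak_sigma_mms optional speckle-correlation width in velocity
#'   units, mm/s (the standard deviation of the speckle autocovariance
#'   lobe converted by pixel pitch and frame rate). When given, the
#'   forward model predicts the *correlation-peak* velocity of each
#'   station rather than the plain chord mean: the cross-correlation of a
#'   window containing tracers at many depths is a superposition of
#'   per-tracer peaks of width `sigma`, and its maximum sits at the
#'   self-consistent weighted mean `D = sum(u w) / sum(w)` with
#'   `w = exp(-(D - u)^2 / (2 sigma^2))` — slightly mode-ward of the chord
#'   mean. This models the measurement operator of projection
#'   velocimetry directly, the finite-speckle refinement of the
#'   projection correction factor.
#' @return A list of class `xpiv_profile_fit`: `v_max` (mm/s), `K`, `R` (um),
#'   `x0` (um), `residual_rms` (mm/s), `flow_rate_ml_min`, `n_used`, the
#'   fitted model object, and the data used.
#' @export
fit_profile <- function(x, v, R, fit_radius = FALSE, x0 = NULL,
                        smear_halfwidth_um = 0, peak_sigma_mms = NULL) {
  hw <- smear_halfwidth_um
  model <- if (hw > 0 || !is.null(peak_sigma_mms)) {
    station_model(hw, peak_sigma_mms)
  } else {
    amassed_profile
  }
  keep <- is.finite(x) & is.finite(v)
  x <- x[keep]; v <- v[keep]
  if (length(x) < 8) stopf("need >= 8 valid profile samples, got %d", length(x))
  if (R <= 0) stopf("R must be positive")
  span <- diff(range(x)) / (2 * R)
  if (span < 0.6)
    stopf("profile samples span only %.0f%% of the lumen (need >= 60%%)", 100 * span)
  if (is.null(x0)) x0 <- sum(x * pmax(v, 0)) / max(sum(pmax(v, 0)), .Machine$double.eps)

  dat <- data.frame(x = x, v = v)
  fits <- list()
  for (K0 in c(2, 3, 5)) {
    v0 <- max(v, na.rm = TRUE) * (K0 + 1) / K0
    fit <- if (fit_radius) {
      try(minpack.lm::nlsLM(
        v ~ model(x, vmax, K, Rfit, xc), data = dat,
        start = list(vmax = v0, K = K0, Rfit = R, xc = x0),
        lower = c(vmax = 0, K = 1, Rfit = 0.5 * R, xc = -R),
        upper = c(vmax = Inf, K = 10, Rfit = 2 * R, xc = R),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ), silent = TRUE)
    } else {
      try(minpack.lm::nlsLM(
        v ~ model(x, vmax, K, R, xc), data = dat,
        start = list(vmax = v0, K = K0, xc = x0),
        lower = c(vmax = 0, K = 1, xc = -R),
        upper = c(vmax = Inf, K = 10, xc = R),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ), silent = TRUE)
    }
    if (!inherits(fit, "try-error")) fits[[length(fits) + 1]] <- fit
  }
  if (length(fits) == 0)
    stopf("profile fit failed to converge from all starts (n = %d, span = %.2f)",
          length(x), span)
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  cf <- stats::coef(best)
  Rhat <- if (fit_radius) unname(cf["Rfit"]) else R
  out <- list(
    v_max = unname(cf["vmax"]), K = unname(cf["K"]), R = Rhat,
    x0 = unname(cf["xc"]),
    residual_rms = sqrt(mean(stats::residuals(best)^2)),
    flow_rate_ml_min = flow_rate(unname(cf["vmax"]), unname(cf["K"]), Rhat),
    n_used = length(x), fit = best, data = dat
  )
  class(out) <- "xpiv_profile_fit"
  out
}

#' @export
print.xpiv_profile_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<xpiv_profile_fit> v_max = %.3f mm/s, K = %.3f, R = %.1f um, ",
           "x0 = %.1f um\n  residual RMS = %.4f mm/s, Q = %.4f mL/min, ",
           "n = %d samples\n"),
    x$v_max, x$K, x$R, x$x0, x$residual_rms, x$flow_rate_ml_min, x$n_used
  ))
  invisible(x)
}

#' Stokes terminal velocity of a small spherical tracer
#'
#' `v_t = (rho_f - rho_p) * g * d^2 / (18 mu)`; positive values mean the
#' particle rises against gravity (buoyant gas bubble in liquid).
#'
#' @param d particle diameter, um.
#' @param rho_f fluid density, kg/m^3 (default: blood, 1060).
#' @param rho_p particle density, kg/m^3 (default: CO2 gas, 1.8).
#' @param mu dynamic viscosity, Pa s (default: blood plasma mixture, 2.4e-3).
#' @param g gravitational acceleration, m/s^2.
#' @return terminal velocity in mm/s.
#' @export
stokes_terminal_velocity <- function(d, rho_f = 1060, rho_p = 1.8,
                                     mu = 2.4e-3, g = 9.81) {
  if (mu <= 0) stopf("viscosity mu must be positive")
  if (d <= 0 || g <= 0) stopf("d and g must be positive")
  d_m <- d * 1e-6
  v_ms <- (rho_f - rho_p) * g * d_m^2 / (18 * mu)
  v_ms * 1000
}

#' Remove microbubble buoyancy from a velocity field
#'
#' Subtracts the Stokes rise velocity from the gravity-aligned component of
#' a physical-unit velocity field: `v_corrected = v_measured + v_t * g_hat`
#' (the buoyant rise contributes `-v_t * g_hat`, i.e. motion opposite to
#' gravity).
#'
#' @param field a velocity field from [to_physical()] (mm/s units).
#' @param v_t Stokes terminal velocity, mm/s (see
#'   [stokes_terminal_velocity()]).
#' @param gravity unit vector of gravity in image components `c(row, col)`;
#'   default `c(1, 0)` (gravity along increasing image rows).
#' @return The corrected field, with a `buoyancy_correction` provenance
#'   attribute.
#' @export
buoyancy_correct <- function(field, v_t, gravity = c(1, 0)) {
  if (!identical(attr(field, "units"), "mm/s"))
    stopf("field is not in physical units; run to_physical() first")
  g <- gravity / sqrt(sum(gravity^2))
  field$v_mms <- field$v_mms + v_t * g[1]
  field$u_mms <- field$u_mms + v_t * g[2]
  attr(field, "buoyancy_correction") <-
    list(v_t_mms = v_t, gravity = gravity)
  field
}

#' Volumetric flow rate from a fitted profile
#'
#' Area integral of `u(r) = v_max (1 - (r/R)^K)` over the lumen:
#' `Q = v_max * pi R^2 * K / (K + 2)`, converted to mL/min.
#'
#' @param v_max maximum velocity, mm/s.
#' @param K bluntness index.
#' @param R vessel radius, um.
#' @return flow rate in mL/min.
#' @export
flow_rate <- function(v_max, K, R) {
  if (R <= 0) stopf("R must be positive")
  q_m3s <- (v_max * 1e-3) * pi * (R * 1e-6)^2 * K / (K + 2)
  q_m3s * 1e6 * 60
}
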