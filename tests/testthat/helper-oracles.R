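# Independent brute-force oracles and small fixture builders shared by the
# test files. Everything here is deliberately naive (double loops, direct
# Monte-Carlo) so it cannot share a defect with the implementation.

# Direct O(N^2) zero-normalized cross-correlation over lags.
zncc_oracle <- function(a, b, md) {
  a0 <- a - mean(a); b0 <- b - mean(b)
  sa <- sqrt(mean(a0^2)); sb <- sqrt(mean(b0^2))
  dys <- -md[1]:md[1]; dxs <- -md[2]:md[2]
  m <- matrix(0, length(dys), length(dxs))
  for (ii in seq_along(dys)) {
    for (jj in seq_along(dxs)) {
      dy <- dys[ii]; dx <- dxs[jj]; s <- 0
      for (y in seq_len(nrow(a))) {
        for (x in seq_len(ncol(a))) {
          y2 <- y + dy; x2 <- x + dx
          if (y2 >= 1 && y2 <= nrow(a) && x2 >= 1 && x2 <= ncol(a))
            s <- s + a0[y, x] * b0[y2, x2]
        }
      }
      m[ii, jj] <- s / ((nrow(a) - abs(dy)) * (ncol(a) - abs(dx)) * sa * sb)
    }
  }
  m
}

# Direct circular autocovariance by shifted products (Wiener-Khinchin
# cross-check), normalized to unit zero lag, zero lag at the center.
autocov_oracle <- function(f) {
  f0 <- f - mean(f)
  nr <- nrow(f); nc <- ncol(f)
  out <- matrix(0, nr, nc)
  for (dy in 0:(nr - 1)) {
    for (dx in 0:(nc - 1)) {
      shifted <- f0[c((dy + 1):nr, seq_len(dy))[1:nr],
                    c((dx + 1):nc, seq_len(dx))[1:nc]]
      out[dy + 1, dx + 1] <- sum(f0 * shifted)
    }
  }
  out <- out / out[1, 1]
  sr <- floor(nr / 2); sc <- floor(nc / 2)
  out[c((sr + 1):nr, seq_len(sr)), c((sc + 1):nc, seq_len(sc))]
}

# Monte-Carlo chord average of u(r)/v_max through a unit cylinder at
# normalized transverse offset xi.
alpha_mc_oracle <- function(xi, K, n = 1e5) {
  L <- sqrt(1 - xi^2)
  z <- runif(n, 0, L)
  r <- sqrt(xi^2 + z^2)
  mean(1 - r^K)
}

# Periodic synthetic speckle field: white noise blurred by a Gaussian in
# the Fourier domain (circular), unit variance.
speckle_field <- function(n, sigma, seed = 1) {
  set.seed(seed)
  f <- matrix(rnorm(n * n), n, n)
  fr <- (function(k) { k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n; k / n })(0:(n - 1))
  gain <- outer(exp(-2 * pi^2 * sigma^2 * fr^2), exp(-2 * pi^2 * sigma^2 * fr^2))
  out <- Re(fft(fft(f) * gain, inverse = TRUE)) / length(f)
  out / sd(out)
}

# Subpixel circular shift by Fourier phase ramp (exact for periodic fields).
fourier_shift <- function(f, dy, dx) {
  n1 <- nrow(f); n2 <- ncol(f)
  k1 <- (function(k) { k[k >= ceiling(n1 / 2)] <- k[k >= ceiling(n1 / 2)] - n1; k })(0:(n1 - 1))
  k2 <- (function(k) { k[k >= ceiling(n2 / 2)] <- k[k >= ceiling(n2 / 2)] - n2; k })(0:(n2 - 1))
  ph <- outer(exp(-2i * pi * k1 * dy / n1), exp(-2i * pi * k2 * dx / n2))
  Re(fft(fft(f) * ph, inverse = TRUE)) / length(f)
}

# Small, fast scene for end-to-end smoke tests; named arguments override
# the defaults.
tiny_scene_config <- function(...) {
  defaults <- list(frame_shape = c(96, 96), vessel_radius = 80, v_max = 3,
                   bluntness = 2, bubble_count = 180, seed = 42)
  do.call(scene_config, utils::modifyList(defaults, list(...)))
}
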