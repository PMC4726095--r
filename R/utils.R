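# Internal numeric helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic package internals go through this so that a
# scene/config seed implies byte-identical output.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# DFT sample frequencies in cycles/px, numpy fftfreq layout.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / n
}

# Move the zero-lag/zero-frequency bin to the center of the matrix.
fftshift2 <- function(m) {
  sr <- floor(nrow(m) / 2)
  sc <- floor(ncol(m) / 2)
  m[c((sr + 1):nrow(m), seq_len(sr)), c((sc + 1):ncol(m), seq_len(sc)), drop = FALSE]
}

# Gaussian low-pass by multiplication in the frequency domain (circular
# boundary). `sigma` is the spatial standard deviation in px.
fft_gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  fy <- fft_freq(nrow(m))
  fx <- fft_freq(ncol(m))
  # transfer function of a unit-mass Gaussian kernel
  gy <- exp(-2 * pi^2 * sigma^2 * fy^2)
  gx <- exp(-2 * pi^2 * sigma^2 * fx^2)
  gain <- outer(gy, gx)
  Re(stats::fft(stats::fft(m) * gain, inverse = TRUE)) / length(m)
}

# Population standard deviation (n divisor); speckle statistics use the
# population convention so that a two-level half/half field has C = 1.
sd_pop <- function(x) {
  mu <- mean(x)
  sqrt(mean((x - mu)^2))
}

# Tiny polynomial rolling hash of a config object, used to stamp outputs
# for provenance (not cryptographic).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x, control = "all"), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 65599 + b) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483648))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
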