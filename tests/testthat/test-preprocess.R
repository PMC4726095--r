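test_that("flat-field correction inverts a known gain field", {
  set.seed(1)
  n <- 32
  S <- matrix(runif(n * n, 0.4, 0.6), n, n)          # true signal
  G <- outer(seq(0.7, 1.3, length.out = n), rep(1, n))  # smooth gain
  dark <- matrix(0.05, n, n)
  frame <- G * S + dark
  flat <- G * mean(S) + dark
  out <- flat_field_correct(frame, flat, dark)
  # output proportional to S pixelwise
  ratio <- out / S
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-10)

  # frame = flat, dark = 0 -> uniform output equal to mean(flat)
  out2 <- flat_field_correct(flat, flat)
  expect_equal(out2, matrix(mean(flat), n, n), tolerance = 1e-12)

  # uniform flat, dark = 0 -> identity
  out3 <- flat_field_correct(S, matrix(1, n, n))
  expect_equal(out3, S, tolerance = 1e-12)
})

test_that("flat-field correction validates shapes and clamps bad gain", {
  expect_error(flat_field_correct(matrix(1, 4, 4), matrix(1, 5, 5)), "dimensions")
  flat <- matrix(1, 8, 8); flat[1, 1] <- 0
  expect_warning(flat_field_correct(matrix(1, 8, 8), flat), "clamped")
})

test_that("background estimation is the pixelwise mean of the window", {
  f <- matrix(runif(64), 8, 8)
  stack <- replicate(10, f, simplify = FALSE)
  expect_equal(estimate_background(stack, 10), f)
  expect_error(estimate_background(stack, 100), "100")
  g <- matrix(2, 8, 8)
  expect_equal(estimate_background(c(stack[1:5], replicate(5, g, simplify = FALSE)), 10),
               (f + g) / 2)
})

test_that("background subtraction modes behave as documented", {
  set.seed(2)
  bg <- matrix(runif(256, 0.4, 0.6), 16, 16)
  # frame equal to the background collapses to a constant
  out <- subtract_background(bg, bg)
  expect_equal(sd(out), 0)
  frame <- bg + matrix(rnorm(256, 0, 0.01), 16, 16)
  out_m <- subtract_background(frame, bg, rebase = "mean")
  expect_equal(mean(out_m), mean(frame), tolerance = 1e-12)
  out_f <- subtract_background(frame, bg, rebase = "floor")
  expect_gte(min(out_f), 0)
  expect_error(subtract_background(frame, bg[1:8, ]), "dimensions")
})

test_that("background subtraction is idempotent on a static stack", {
  set.seed(3)
  f <- matrix(runif(256, 0.3, 0.7), 16, 16)
  stack <- replicate(5, f, simplify = FALSE)
  bg <- estimate_background(stack, 5)
  once <- subtract_background(f, bg, rebase = "mean")
  # second pass subtracts a background estimated from already-subtracted
  # frames: nothing further changes
  bg2 <- estimate_background(replicate(5, once, simplify = FALSE), 5)
  twice <- subtract_background(once, bg2, rebase = "mean")
  expect_equal(twice, once, tolerance = 1e-12)
})

test_that("band-pass keeps in-band waves and rejects impulses and DC", {
  n <- 128
  # constant frame unchanged (DC preserved)
  expect_equal(bandpass_filter(matrix(0.5, n, n), 4, 64),
               matrix(0.5, n, n), tolerance = 1e-12)
  # sinusoid with wavelength 16 px (inside [4, 64]) retained >= 90%
  wave <- matrix(sin(2 * pi * (1:n) / 16), n, n, byrow = TRUE)
  out <- bandpass_filter(wave + 0.5, 4, 64) - 0.5
  expect_gt(sd(out) / sd(wave), 0.90)
  # pixel-scale noise (wavelength ~2.1 px, beyond the 4 px edge)
  # attenuated >= 90%
  hf <- matrix(sin(2 * pi * (1:n) * 60 / n), n, n, byrow = TRUE)
  out2 <- bandpass_filter(hf + 0.5, 4, 64) - 0.5
  expect_lt(sd(out2) / sd(hf), 0.1)
  expect_error(bandpass_filter(hf, 64, 4), "low_wl")
})

test_that("FFC and band-pass are linear operators and preserve the mean", {
  set.seed(4)
  n <- 32
  X <- matrix(runif(n * n), n, n); Y <- matrix(runif(n * n), n, n)
  flat <- matrix(runif(n * n, 0.8, 1.2), n, n)
  a <- 1.7; b <- -0.4
  expect_equal(flat_field_correct(a * X + b * Y, flat),
               a * flat_field_correct(X, flat) + b * flat_field_correct(Y, flat),
               tolerance = 1e-10)
  expect_equal(bandpass_filter(a * X + b * Y, 4, 16),
               a * bandpass_filter(X, 4, 16) + b * bandpass_filter(Y, 4, 16),
               tolerance = 1e-10)
  # band-pass preserves the mean exactly (DC restored); FFC preserves it
  # up to the gain/frame sampling covariance, which is a few percent on
  # these uncorrelated random fields and vanishes for frames actually
  # imaged under the flat
  expect_equal(mean(bandpass_filter(X, 4, 16)), mean(X), tolerance = 1e-9)
  expect_equal(mean(flat_field_correct(X, flat)), mean(X), tolerance = 0.02)
  G <- flat / mean(flat)
  expect_equal(mean(flat_field_correct(G * X, flat)), mean(X), tolerance = 1e-10)
})

test_that("restore with all stages disabled is the identity", {
  g <- generate_sequence(tiny_scene_config(), 3)
  cfg <- restoration_config(ffc_enabled = FALSE, background_enabled = FALSE,
                            bandpass_low_wavelength = NULL,
                            bandpass_high_wavelength = NULL)
  out <- restore(g$stack, cfg)
  expect_identical(out$frames, g$stack$frames)
})

test_that("restore logs per-stage contrast and runs end to end", {
  g <- generate_sequence(tiny_scene_config(), 12)
  out <- suppressWarnings(restore(g$stack, restoration_config(background_window = 12)))
  log <- attr(out, "restoration_log")
  expect_true(all(c("raw", "ffc", "background", "bandpass") %in% log$stage))
  expect_true(all(is.finite(log$contrast)))
  expect_length(out$frames, 12)
})
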