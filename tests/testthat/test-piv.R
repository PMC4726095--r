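test_that("self-correlation peaks at zero lag with unit height", {
  set.seed(20)
  a <- matrix(rnorm(32 * 64), 32, 64)
  cc <- correlate_windows(a, a)
  expect_equal(cc$peak, c(0, 0))
  expect_equal(cc$p_c, 1, tolerance = 1e-12)
})

test_that("integer shifts of periodic content are recovered exactly", {
  set.seed(21)
  a <- matrix(rnorm(48 * 48), 48, 48)
  for (sh in list(c(2, 5), c(-3, 1), c(0, -6))) {
    b <- a[((seq_len(48) - 1 + sh[1]) %% 48) + 1, ((seq_len(48) - 1 + sh[2]) %% 48) + 1]
    # b(x) = a(x + sh): content moves by -sh
    cc <- correlate_windows(a, b, c(8, 8))
    expect_equal(cc$peak, -sh)
  }
})

test_that("ZNCC equals the direct double-loop oracle to 1e-10", {
  set.seed(22)
  for (rep in 1:3) {
    a <- matrix(runif(16 * 16), 16, 16)
    b <- matrix(runif(16 * 16), 16, 16)
    cc <- correlate_windows(a, b, c(4, 4))
    expect_equal(cc$map, zncc_oracle(a, b, c(4, 4)), tolerance = 1e-10)
  }
})

test_that("independent noise windows rarely reach the reliability threshold", {
  set.seed(23)
  pc <- replicate(1000, {
    a <- matrix(rnorm(64 * 64), 64, 64)
    b <- matrix(rnorm(64 * 64), 64, 64)
    correlate_windows(a, b, c(8, 8))$p_c
  })
  expect_gt(mean(pc < 0.3), 0.985)
  expect_lt(max(pc), 0.5)
})

test_that("zero-variance windows are flagged invalid without error", {
  cc <- correlate_windows(matrix(1, 16, 16), matrix(rnorm(256), 16, 16))
  expect_false(cc$valid)
  sp <- subpixel_peak(cc)
  expect_true(is.na(sp$dx))
})

test_that("subpixel refinement is exact on analytic Gaussian peaks", {
  dys <- -4:4
  for (off in c(-0.4, 0, 0.3)) {
    m <- exp(-outer((dys - off)^2, dys^2, `+`) / (2 * 1.5^2))
    corr <- structure(list(map = m, dy = dys, dx = dys,
                           peak = c(0, 0), p_c = max(m), valid = TRUE),
                      class = "xpiv_corrmap")
    sp <- subpixel_peak(corr)
    expect_equal(sp$dy, off, tolerance = 0.02)
    expect_equal(sp$dx, 0, tolerance = 1e-6)   # symmetric axis
  }
})

test_that("a Fourier-shifted speckle pair is measured to subpixel accuracy", {
  f <- speckle_field(64, 1.5, seed = 24)
  g <- fourier_shift(f, 0, 5.25)
  cc <- correlate_windows(f, g, c(4, 8))
  sp <- subpixel_peak(cc)
  expect_equal(sp$dx, 5.25, tolerance = 0.1)
  expect_equal(sp$dy, 0, tolerance = 0.1)
})

test_that("swapping the frame order negates the displacement", {
  f <- speckle_field(64, 1.5, seed = 25)
  g <- fourier_shift(f, 1.4, -2.6)
  ab <- subpixel_peak(correlate_windows(f, g, c(6, 6)))
  ba <- subpixel_peak(correlate_windows(g, f, c(6, 6)))
  expect_equal(ab$dx, -ba$dx, tolerance = 0.03)
  expect_equal(ab$dy, -ba$dy, tolerance = 0.03)
})

test_that("interrogation tiling produces the documented grid", {
  set.seed(26)
  a <- matrix(rnorm(1024 * 1024), 1024, 1024)
  cfg <- piv_config(window_size = c(32, 64), overlap = 0.5,
                    max_displacement = c(2, 2), pc_threshold = 1)
  fld <- compute_field(a, a, cfg)
  # (1024 - 32)/16 + 1 = 63 transverse stations,
  # (1024 - 64)/32 + 1 = 31 along the flow
  expect_equal(attr(fld, "grid_dim"), c(63, 31))
  expect_error(compute_field(a[1:16, 1:16], a[1:16, 1:16],
                             piv_config(window_size = c(32, 64))), "larger")
})

test_that("a uniform 3 px shift is recovered across the field", {
  f <- speckle_field(256, 1.5, seed = 27)
  g <- fourier_shift(f, 0, 3)
  cfg <- piv_config(window_size = c(32, 64), max_displacement = c(6, 6))
  fld <- compute_field(f, g, cfg)
  ok <- fld$valid
  expect_gt(mean(ok), 0.95)
  err <- sqrt((fld$u_px[ok] - 3)^2 + fld$v_px[ok]^2)
  expect_gt(mean(err < 0.1), 0.99)
})

test_that("field vectors agree with per-window correlation plus refinement", {
  g <- generate_sequence(tiny_scene_config(), 2)
  cfg <- piv_config(window_size = c(24, 32), max_displacement = c(4, 5),
                    pc_threshold = 0, nmt_threshold = Inf)
  fld <- compute_field(g$stack$frames[[1]], g$stack$frames[[2]], cfg)
  k <- which(!is.na(fld$u_px))[3]
  y0 <- fld$y_px[k] - (24 - 1) / 2; x0 <- fld$x_px[k] - (32 - 1) / 2
  wa <- g$stack$frames[[1]][y0:(y0 + 23), x0:(x0 + 31)]
  wb <- g$stack$frames[[2]][y0:(y0 + 23), x0:(x0 + 31)]
  sp <- subpixel_peak(correlate_windows(wa, wb, c(4, 5)))
  expect_equal(fld$u_px[k], sp$dx)
  expect_equal(fld$v_px[k], sp$dy)
  expect_equal(fld$p_c[k], sp$p_c)
})

test_that("ensemble averaging pools valid vectors and tracks counts", {
  g <- generate_sequence(tiny_scene_config(), 2)
  cfg <- piv_config(window_size = c(24, 32), max_displacement = c(4, 4))
  fld <- compute_field(g$stack$frames[[1]], g$stack$frames[[2]], cfg)
  ens <- ensemble_mean(replicate(10, fld, simplify = FALSE))
  ok <- fld$valid & is.finite(fld$u_px)
  expect_equal(ens$u_px[ok], fld$u_px[ok])
  expect_true(all(is.na(ens$u_px[!ok])))
  expect_equal(ens$n_pairs, ifelse(ok, 10, 0))
  bad <- fld; attr(bad, "grid_dim") <- c(1, 1)
  expect_error(ensemble_mean(list(fld, bad)), "grids differ")
})

test_that("ensemble noise shrinks as 1/sqrt(n)", {
  set.seed(28)
  base <- data.frame(i = 1, j = 1, y_px = 1, x_px = 1, v_px = 0, u_px = 0,
                     p_c = 1, contrast = 0.2, sr = 0.2, valid = TRUE)
  attr(base, "grid_dim") <- c(1, 1); attr(base, "units") <- "px/frame"
  attr(base, "config") <- piv_config()
  class(base) <- c("xpiv_field", "data.frame")
  spread <- function(n, reps = 200) {
    sd(replicate(reps, {
      fields <- lapply(seq_len(n), function(i) { f <- base; f$u_px <- rnorm(1); f })
      ensemble_mean(fields)$u_px
    }))
  }
  s50 <- spread(50); s200 <- spread(200)
  expect_equal(s50, 1 / sqrt(50), tolerance = 0.25)
  expect_equal(s200, 1 / sqrt(200), tolerance = 0.25)
  expect_gt(s50 / s200, sqrt(4) * 0.7)
})

test_that("unit conversion to physical velocities is exact", {
  f <- data.frame(i = 1, j = 1, y_px = 10, x_px = 20, v_px = 0, u_px = 1,
                  p_c = 1, contrast = 0.1, sr = 0.1, valid = TRUE)
  attr(f, "grid_dim") <- c(1, 1); attr(f, "units") <- "px/frame"
  class(f) <- c("xpiv_field", "data.frame")
  p <- to_physical(f, 1.8994, 1000)
  expect_equal(p$u_mms, 1.8994)
  f$u_px <- 10
  expect_equal(to_physical(f, 1.8994, 1000)$u_mms, 18.994)
  f$u_px <- 0
  expect_equal(to_physical(f, 1.8994, 1000)$u_mms, 0)
})

test_that("peak height falls as the within-window velocity spread grows", {
  # the per-lag overlap normalization makes the coefficient insensitive
  # to uniform translation; what destroys the peak at high speed is the
  # spread of displacements inside one window (image smearing in a
  # sheared flow), emulated here by shifting each row in proportion to
  # its position
  set.seed(29)
  pc_at <- function(dx) {
    mean(replicate(30, {
      wide <- speckle_field(128, 1.5, seed = sample.int(1e6, 1))
      a <- wide[1:64, 1:64] + matrix(rnorm(64 * 64, 0, 0.3), 64, 64)
      b <- matrix(0, 64, 64)
      for (r in 1:64) {
        s <- round(dx * (r - 1) / 63)
        b[r, ] <- wide[r, (1 + s):(64 + s)]
      }
      b <- b + matrix(rnorm(64 * 64, 0, 0.3), 64, 64)
      correlate_windows(a, b, c(4, 50))$p_c
    }))
  }
  pcs <- vapply(c(4, 24, 48), pc_at, numeric(1))
  expect_true(all(diff(pcs) < 0))
})
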