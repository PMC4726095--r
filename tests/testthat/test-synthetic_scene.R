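test_that("bubble positions are uniform per unit cross-section area", {
  cfg <- scene_config(frame_shape = c(64, 64), vessel_radius = 500,
                      bubble_count = 1e5, seed = 9)
  sc <- make_scene(cfg)
  expect_true(all(sc$r <= 500))
  # uniform-in-area implies P(r <= R/sqrt(2)) = 1/2
  frac <- mean(sc$r <= 500 / sqrt(2))
  expect_lt(abs(frac - 0.5), 0.005)
})

test_that("scene generation is deterministic and respects the empty case", {
  cfg <- tiny_scene_config()
  s1 <- make_scene(cfg); s2 <- make_scene(cfg)
  expect_identical(s1, s2)
  cfg0 <- tiny_scene_config(bubble_count = 0, noise_sigma = 0,
                            illumination_gradient = 0)
  s0 <- make_scene(cfg0)
  expect_length(s0$s, 0)
  expect_equal(render(s0, cfg0), s0$background)  # background only
})

test_that("configuration errors are caught", {
  expect_error(scene_config(vessel_radius = -1), "vessel_radius")
  expect_error(scene_config(bluntness = 0.5), "K")
  expect_error(scene_config(frame_shape = c(0, 10)), "frame_shape")
  expect_error(generate_sequence(tiny_scene_config(), 1), "pairs")
})

test_that("advection follows the bluntness velocity law", {
  cfg <- scene_config(frame_shape = c(64, 64), vessel_radius = 100,
                      v_max = 50, bluntness = 2, bubble_count = 3, seed = 1)
  sc <- make_scene(cfg)
  sc$r <- c(100, 0, 50)            # wall, centerline, half radius
  sc$s <- c(10, 10, 10)
  out <- advect(sc, dt = 1e-3, cfg)
  disp <- out$s - sc$s
  expect_equal(disp[1], 0)                       # no-slip at the wall
  expect_equal(disp[2], 50)                      # v_max * dt = 50 um
  expect_equal(disp[3], 0.75 * 50)               # 1 - (1/2)^2
})

test_that("recycling preserves the radial distribution and bubble count", {
  cfg <- scene_config(frame_shape = c(48, 48), vessel_radius = 200,
                      v_max = 40, bluntness = 2, bubble_count = 4000, seed = 5)
  sc <- make_scene(cfg)
  set.seed(11)
  for (i in 1:60) sc <- advect(sc, 1e-3, cfg)
  expect_length(sc$r, 4000)                      # conservation
  expect_true(all(sc$r <= 200))
  # area-uniformity survives many recycle events
  expect_lt(abs(mean(sc$r <= 200 / sqrt(2)) - 0.5), 0.03)
})

test_that("rendered bubbles have a dark core and bright rim", {
  cfg <- scene_config(frame_shape = c(64, 64), vessel_radius = 50,
                      bubble_count = 1, seed = 1, background_amplitude = 0,
                      illumination_gradient = 0, noise_sigma = 0)
  sc <- make_scene(cfg)
  sc$s <- 32 * cfg$pixel_pitch; sc$r <- 0; sc$theta <- 0; sc$diameter <- 13.3
  fr <- render(sc, cfg, noise = FALSE)
  i0 <- which(fr == min(fr), arr.ind = TRUE)[1, ]
  i1 <- which(fr == max(fr), arr.ind = TRUE)[1, ]
  expect_equal(unname(i0), c(32, 32), tolerance = 0)     # core at the center
  ring_r <- sqrt(sum((i1 - c(32, 32))^2))
  expect_gt(ring_r, 1); expect_lt(ring_r, 6)             # rim annulus
  expect_lt(min(fr), cfg$baseline)
  expect_gt(max(fr), cfg$baseline)
})

test_that("mean of many noise-only frames converges to the background", {
  cfg <- scene_config(frame_shape = c(32, 32), vessel_radius = 30,
                      bubble_count = 0, seed = 3, noise_sigma = 0.02,
                      illumination_gradient = 0)
  sc <- make_scene(cfg)
  set.seed(7)
  acc <- 0
  for (i in 1:100) acc <- acc + render(sc, cfg)
  acc <- acc / 100
  # CLT: per-pixel error ~ N(0, sigma/10); check a generous max bound and
  # the expected mean absolute deviation 0.798 * sigma/10
  expect_lt(max(abs(acc - sc$background)), 5 * 0.02 / sqrt(100))
  expect_lt(mean(abs(acc - sc$background)), 0.9 * 0.02 / sqrt(100))
})

test_that("generated sequences are byte-identical under a fixed seed", {
  cfg <- tiny_scene_config()
  g1 <- generate_sequence(cfg, 4)
  g2 <- generate_sequence(cfg, 4)
  expect_identical(g1$stack$frames, g2$stack$frames)
})

test_that("ground truth carries the acquisition arithmetic", {
  cfg <- scene_config(frame_shape = c(64, 64), pixel_pitch = 1.8994,
                      frame_rate = 1000, vessel_radius = 60, v_max = 19,
                      bluntness = 2, bubble_count = 10, seed = 2)
  g <- generate_sequence(cfg, 2)
  # 19 mm/s at 1000 fps and 1.8994 um/px -> 10.0 px/frame at the centerline
  expect_equal(g$truth$centerline_displacement_px, 10.0, tolerance = 0.01)
  expect_equal(g$truth$profile$v_mms[51], 19 * 2 / 3, tolerance = 1e-6)
  # 7000 frames at 1000 fps would be 7 s of data
  expect_equal(7000 / cfg$frame_rate, 7)
})

test_that("a zero-velocity sequence differs between frames only by noise", {
  cfg <- tiny_scene_config(v_max = 0, noise_sigma = 0.01)
  g <- generate_sequence(cfg, 2)
  d <- g$stack$frames[[1]] - g$stack$frames[[2]]
  expect_lt(sd(d), 3 * 0.01)   # two independent noise draws, no motion
  expect_gt(sd(d), 0)
})
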