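test_that("a temporally constant scene gives identical frames", {
  tm <- timing_config(rows = 16L, t_u_jitter_sd = 0)
  shape <- c(16L, 8L)
  # LEDs on for the whole recording: every row of every frame integrates the
  # same constant irradiance over the same exposure length
  tl <- manual_timeline(c(0, 10), c("LEDS_ON", "LEDS_OFF"))
  scene <- function(state, t) matrix(0.5, shape[1], shape[2])
  v <- capture(scene, tl, tm, n_frames = 20, shape = shape, gain = 40000)
  expect_equal(v$frames[, , 1], matrix(floor(0.5 * 40000 * 0.005), 16, 8))
  for (k in 2:20) expect_identical(v$frames[, , k], v$frames[, , 1])
})

test_that("rolling shutter splits a mid-readout switch at the predicted row", {
  tm <- timing_config(rows = 64L, t_u_jitter_sd = 0)
  shape <- c(64L, 4L)
  # switch mid-way through frame 0's readout, late enough that the top rows
  # finish their exposure fully dark and the bottom rows start fully lit
  t_sw <- 0.006
  tl <- manual_timeline(c(t_sw, 1), c("LEDS_ON", "LEDS_OFF"))
  bright <- 1.0
  scene <- function(state, t) {
    matrix(if (!is.null(state$led)) bright else 0, shape[1], shape[2])
  }
  v <- capture(scene, tl, tm, n_frames = 1, shape = shape, gain = 40000)

  # independent brute-force oracle: fine-grid integration per row
  s_fun <- function(t) ifelse(t >= t_sw & t < 1, bright, 0)
  dt <- 1e-6
  oracle <- vapply(0:(shape[1] - 1), function(r) {
    t0 <- r * tm$row_readout
    grid <- seq(t0, t0 + tm$exposure - dt, by = dt) + dt / 2
    min(floor(40000 * sum(s_fun(grid)) * dt), 255)
  }, numeric(1))
  expect_true(all(abs(v$frames[, 1, 1] - oracle) <= 1))

  # top rows (exposure entirely before the switch) dark, bottom rows lit;
  # the boundary is the switch time mapped through the row readout clock
  full_dark <- which(v$frames[, 1, 1] == 0)
  full_lit <- which(v$frames[, 1, 1] == 200)
  last_dark_row <- floor((t_sw - tm$exposure) / tm$row_readout)  # 0-based
  first_lit_row <- ceiling(t_sw / tm$row_readout)
  expect_equal(max(full_dark) - 1, last_dark_row)
  expect_equal(min(full_lit) - 1, first_lit_row)
})

test_that("free-run timestamps depend only on the frame rate", {
  tm <- timing_config(rows = 16L)
  shape <- c(16L, 4L)
  scene <- function(state, t) matrix(0, 16, 4)
  tl1 <- manual_timeline(c(0.001, 0.002), c("LEDS_ON", "LEDS_OFF"))
  tl2 <- manual_timeline(c(0.05, 0.9), c("EXT_ON", "EXT_OFF"))
  v1 <- capture(scene, tl1, tm, 10, shape)
  v2 <- capture(scene, tl2, tm, 10, shape)
  expect_identical(v1$timestamps, v2$timestamps)
  expect_equal(diff(v1$timestamps), rep(1 / 130, 9), tolerance = 1e-12)
  expect_error(capture(scene, tl1, tm, 0, shape), "positive")
})

test_that("capture is linear in scene irradiance before quantization", {
  tm <- timing_config(rows = 16L, t_u_jitter_sd = 0)
  shape <- c(16L, 6L)
  tl <- build_timeline(tm, pattern_sequence())
  m1 <- matrix(runif(16 * 6, 0, 0.3), 16, 6)
  m2 <- matrix(runif(16 * 6, 0, 0.3), 16, 6)
  mk <- function(m) function(state, t) if (is.null(state$led)) 0 * m else m
  v1 <- capture(mk(m1), tl, tm, 12, shape)
  v2 <- capture(mk(m2), tl, tm, 12, shape)
  v12 <- capture(mk(m1 + m2), tl, tm, 12, shape)
  expect_true(all(abs(v12$frames - v1$frames - v2$frames) <= 1))
})

test_that("stray light adds with clipping and zero offset is the identity", {
  v <- quick_sim(10, seed = 4)
  expect_identical(add_stray_light(v, 0)$frames, v$frames)
  v10 <- add_stray_light(v, 10)
  expect_equal(max(v10$frames), min(max(v$frames) + 10, 255))
  expect_true(all(v10$frames - v$frames <= 10))
  vbig <- add_stray_light(v, 255)
  expect_true(all(vbig$frames == 255))
  expect_error(add_stray_light(v, -1), ">= 0")
})

test_that("indicator sites saturate on full exposure and read partial otherwise", {
  shape <- tiny_shape
  layout <- default_detector_layout(shape)
  expect_true(all(render_indicator("000000000000", layout, shape) == 0))
  one <- render_indicator("100000000000", layout, shape)
  expect_equal(sum(one > 0), 1L)
  expect_error(render_indicator("1010", layout, shape), "12")

  tm <- timing_config(rows = shape[1], t_u_jitter_sd = 0)
  scene <- function(state, t) {
    if (is.null(state$seg)) matrix(0, shape[1], shape[2])
    else render_indicator(state$seg, layout, shape)
  }
  # SEG on well before frame 0 and off after it: full exposure -> 255 ADU
  tl_full <- manual_timeline(c(0, 0.5), c("SEG_ON", "SEG_OFF"),
                             code = "111111111111")
  vf <- capture(scene, tl_full, tm, 1, shape)
  expect_true(all(read_detectors(vf$frames[, , 1], layout) == 255))

  # SEG switched on partway through the detector rows' exposure:
  # intermediate ADU strictly between 0 and 255
  site1 <- layout$sites[1, ]
  t_mid <- site1$row * tm$row_readout + 0.6 * tm$exposure
  vp <- capture(scene, manual_timeline(c(t_mid, 0.5), c("SEG_ON", "SEG_OFF")),
                tm, 1, shape)
  lev <- read_detectors(vp$frames[, , 1], layout)[1]
  expect_gt(lev, 0)
  expect_lt(lev, 255)
  expect_equal(lev, floor(2.0 * 40000 * 0.4 * tm$exposure), tolerance = 2)
})

test_that("every cycle produces at least one frame carrying its indicator code", {
  v <- quick_sim(130, seed = 9)
  layout <- attr(v, "layout")
  cyc <- attr(attr(v, "timeline"), "cycles")
  n <- n_frames(v)
  frame_codes <- vapply(seq_len(n), function(k) {
    classify_frame(read_detectors(v$frames[, , k], layout))
  }, character(1))
  span <- n / v$frame_rate
  complete <- cyc[cyc$led_off < span - 1 / v$frame_rate, ]
  for (i in seq_len(nrow(complete))) {
    in_cycle <- v$timestamps > complete$led_on[i] - 0.013 &
      v$timestamps < complete$led_off[i]
    expect_true(complete$indicator[i] %in% frame_codes[in_cycle])
  }
})
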