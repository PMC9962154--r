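test_that("phantom generation is seed-deterministic and seed-sensitive", {
  p1 <- generate_phantom(1, tiny_shape)
  p1b <- generate_phantom(1, tiny_shape)
  expect_identical(p1$vein_depth_map, p1b$vein_depth_map)
  expect_identical(p1$texture_map, p1b$texture_map)
  expect_identical(p1$finger_mask, p1b$finger_mask)

  p2 <- generate_phantom(2, tiny_shape)
  in_mask <- p1$finger_mask & p2$finger_mask
  frac_diff <- mean(p1$vein_depth_map[in_mask] != p2$vein_depth_map[in_mask])
  expect_gt(frac_diff, 0.01)
})

test_that("phantom respects its structural invariants", {
  p <- generate_phantom(3, tiny_shape)
  expect_true(all(p$vein_depth_map[!p$finger_mask] == 0))
  expect_true(all(is.finite(p$vein_depth_map)) && all(p$vein_depth_map >= 0))
  expect_true(all(is.finite(p$tissue_depth_map)) && all(p$tissue_depth_map >= 0))
  expect_true(all(p$texture_map > 0 & p$texture_map <= 1))
  expect_true(sum(p$nail_mask) > 0)

  pv0 <- generate_phantom(3, tiny_shape, config = list(vein_density = 0))
  expect_true(all(pv0$vein_depth_map == 0))
  expect_gt(sum(pv0$finger_mask), 0)

  expect_error(generate_phantom(1, c(-4, 10)), "positive")
})

test_that("back-lit render matches the closed-form Beer-Lambert value", {
  ph <- pixel_phantom(tissue = 1, vein = 0, mu_tissue = 0.5)
  bank <- pixel_bank()
  img <- render_backlit(ph, bank, single_code(1), t = 0)
  expect_equal(img[1, 1], exp(-0.5), tolerance = 1e-12)

  expect_equal(render_backlit(ph, bank, "000000000000", 0)[1, 1], 0)

  ph0 <- pixel_phantom(tissue = 2, vein = 1.5, mu_tissue = 0, mu_blood = 0)
  expect_equal(render_backlit(ph0, pixel_bank(power = 3), single_code(2), 0)[1, 1], 3)

  bad_bank <- pixel_bank(wavelength = 555)
  expect_error(render_backlit(ph, bad_bank, single_code(1), 0), "wavelength")
})

test_that("zero-absorption render reduces to power times the falloff kernel", {
  shape <- c(21L, 21L)
  ph <- finger_phantom(
    finger_mask = matrix(TRUE, shape[1], shape[2]),
    vein_depth_map = matrix(0, shape[1], shape[2]),
    tissue_depth_map = matrix(1, shape[1], shape[2]),
    texture_map = matrix(1, shape[1], shape[2]),
    absorption = data.frame(wavelength_nm = 940, mu_tissue = 0, mu_blood = 0))
  bank <- diode_bank(
    data.frame(id = 1:12, row = 10, col = c(10, seq_len(11)),
               wavelength_nm = 940, power = 2),
    external = list(wavelength_nm = 830, power = 1, row = 10, col = 10,
                    sigma = 5),
    falloff_sigma = 4)
  img <- render_backlit(ph, bank, single_code(1), 0)
  rr <- (0:20 - 10)^2
  expected <- 2 * exp(-outer(rr, rr, `+`) / (2 * 4^2))
  expect_equal(img, expected, tolerance = 1e-12)
})

test_that("vein contrast is ordered by blood absorption across wavelengths", {
  ph <- generate_phantom(5, tiny_shape)
  # same source position, three wavelengths: geometry fixed, only mu varies
  vein_px <- which(ph$vein_depth_map == max(ph$vein_depth_map),
                   arr.ind = TRUE)[1, ]
  bg_cols <- which(ph$finger_mask[vein_px[1], ] &
                     ph$vein_depth_map[vein_px[1], ] == 0)
  bg_col <- bg_cols[which.min(abs(bg_cols - vein_px[2]))]
  contrast <- vapply(c(730, 875, 940), function(wl) {
    bank <- pixel_bank(wavelength = wl)
    bank$diodes$row <- vein_px[1] - 1; bank$diodes$col <- vein_px[2] - 1
    img <- render_backlit(ph, bank, single_code(1), 0)
    iv <- img[vein_px[1], vein_px[2]]; ib <- img[vein_px[1], bg_col]
    (ib - iv) / (ib + iv)
  }, numeric(1))
  mu <- default_absorption()
  mu_b <- mu$mu_blood[match(c(730, 875, 940), mu$wavelength_nm)]
  expect_identical(order(contrast), order(mu_b))
  expect_true(all(diff(contrast[order(mu_b)]) > 0))
})

test_that("cardiac modulation of a vein pixel tracks the configured amplitude", {
  amp <- 0.05
  ph <- pixel_phantom(tissue = 1, vein = 2, mu_tissue = 0.2, mu_blood = 0.25,
                      amplitude = amp, rate_bpm = 60)
  bank <- pixel_bank()
  ts <- seq(0, 1, by = 0.01)  # one cardiac period at 60 bpm
  series <- vapply(ts, function(t) render_backlit(ph, bank, single_code(1), t)[1, 1],
                   numeric(1))
  ptp_frac <- (max(series) - min(series)) / mean(series)
  # linearization: ptp ~= 2 * mu_blood * vein_depth * amplitude = 1.0 * amp
  expect_gt(ptp_frac, amp / 2)
  expect_lt(ptp_frac, 2 * amp)
  # render is deterministic in (phantom, pattern, t)
  expect_identical(render_backlit(ph, bank, single_code(1), 0.3),
                   render_backlit(ph, bank, single_code(1), 0.3))
})

test_that("cardiac waveform has zero mean and unit peak", {
  ts <- seq(0, 60 / 72, length.out = 10001)[-10001]
  w <- cardiac_waveform(ts, rate_bpm = 72)
  expect_lt(abs(mean(w)), 1e-6)
  expect_equal(max(abs(w)), 1, tolerance = 1e-6)
})

test_that("front-lit render shows texture but no veins", {
  shape <- c(32L, 48L)
  mask <- matrix(FALSE, shape[1], shape[2]); mask[5:28, 5:40] <- TRUE
  flat <- finger_phantom(
    finger_mask = mask,
    vein_depth_map = matrix(0, shape[1], shape[2]),
    tissue_depth_map = mask * 1,
    texture_map = matrix(1, shape[1], shape[2]))
  bank <- default_diode_bank(shape, finger_cols = 40)
  img <- render_frontlit(flat, bank)
  expect_true(all(img[!mask] == 0))
  # texture == 1: image is the pure falloff, smooth and positive inside
  expect_true(all(img[mask] > 0))

  # veins are sub-surface: the front-lit image is exactly invariant to them
  ph <- generate_phantom(7, tiny_shape)
  bank <- default_diode_bank(tiny_shape)
  no_veins <- ph; no_veins$vein_depth_map[] <- 0
  expect_identical(render_frontlit(ph, bank), render_frontlit(no_veins, bank))

  # and the surface texture is uncorrelated with the vein network; use a
  # phantom large enough for many independent texture patches, and factor
  # out the deterministic illumination profile shared by any two
  # center-weighted maps
  big <- c(128L, 192L)
  for (seed in c(7, 8)) {
    phb <- generate_phantom(seed, big)
    bankb <- default_diode_bank(big)
    fr <- render_frontlit(phb, bankb)
    flat <- phb; flat$texture_map[] <- 1
    prof <- render_frontlit(flat, bankb)
    sel <- phb$finger_mask
    r <- cor(fr[sel] / prof[sel], phb$vein_depth_map[sel])
    expect_lt(abs(r), 0.1)
  }
})
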