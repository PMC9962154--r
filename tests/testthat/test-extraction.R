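test_that("detector pixels are read in fixed diode order with bounds checks", {
  layout <- tiny_layout()
  frame <- matrix(0L, 8, 8)
  expect_equal(read_detectors(frame, layout), rep(0, 12))
  frame[layout$sites$row[3] + 1, layout$sites$col[3] + 1] <- 255L
  lev <- read_detectors(frame, layout)
  expect_equal(lev[3], 255)
  expect_equal(lev[-3], rep(0, 11))
  bad <- tiny_layout()
  bad$sites$row[1] <- 99L
  expect_error(read_detectors(frame, bad), "bounds")
})

test_that("frame classification applies the >= threshold rule per bit", {
  expect_equal(classify_frame(rep(0, 12)), "000000000000")
  expect_true(is_dark_code(classify_frame(rep(19, 12))))
  expect_equal(classify_frame(c(255, rep(0, 11))), "100000000000")
  # 19 is below the 20 ADU level, 20 at the level counts as lit
  expect_equal(classify_frame(c(19, 20, rep(0, 10))), "010000000000")
  expect_equal(classify_frame(c(30, rep(0, 11)), baseline = 15), "000000000000")
  expect_error(classify_frame(rep(0, 5)), "12")
})

test_that("degenerate videos are rejected with clear errors", {
  layout <- tiny_layout()
  dark <- matrix(0L, 8, 8)
  expect_error(extract(manual_video(list(dark, dark, dark)), layout),
               "no illumination patterns")
  lit <- dark; lit[layout$sites$row[1] + 1, layout$sites$col[1] + 1] <- 255L
  expect_error(extract(manual_video(list(lit, lit)), layout), "DARK")
})

test_that("extraction matches a brute-force oracle on a hand-built 9-frame video", {
  layout <- tiny_layout()
  set.seed(101)
  base <- function() {
    m <- matrix(as.integer(sample(0:200, 64, TRUE)), 8, 8)
    m[cbind(layout$sites$row + 1, layout$sites$col + 1)] <- 0L  # sites dark
    m
  }
  mark <- function(frame, j, level = 255L) {
    frame[layout$sites$row[j] + 1, layout$sites$col[j] + 1] <- level
    frame
  }
  bg1 <- matrix(3L, 8, 8)
  bg2 <- matrix(5L, 8, 8)
  bg3 <- matrix(2L, 8, 8)
  p1 <- lapply(1:3, function(i) mark(base(), 1))
  p2 <- lapply(1:2, function(i) mark(base(), 2))
  mixed <- mark(mark(base(), 2, 40L), 3, 40L)  # transition frame, low levels
  frames <- c(list(bg1), p1, list(bg2), p2, list(mixed), list(bg3))
  video <- manual_video(frames)
  res <- extract(video, layout)

  # oracle: index the clean frames manually, per-pixel max, subtract the
  # dark reference, clip at zero
  o1 <- pmax(pmax(pmax(p1[[1]], p1[[2]]), p1[[3]]) - bg1, 0L)
  o2 <- pmax(pmax(p2[[1]], p2[[2]]) - bg2, 0L)
  expect_equal(length(res$images), 2L)
  expect_identical(res$images[[1]], o1)
  expect_identical(res$images[[2]], o2)
  expect_equal(res$codes, c("100000000000", "010000000000"))
  expect_equal(res$times, video$timestamps[c(2, 6)])
  # the mixed transition frame was excluded from the maximum
  expect_equal(unname(attr(res, "dropped")["mixed_frames"]), 1L)
})

test_that("a simulated sweep yields P1-P12 then the external sentinel, in order", {
  v <- quick_sim(63, seed = 21)
  res <- extract(v)
  expected <- c(vapply(1:12, single_code, character(1)), "000011110000")
  expect_equal(res$codes[1:13], expected)
  expect_true(all(diff(res$times) > 0))
  # full agreement with the simulator's ground truth
  expect_equal(res$codes, true_code_at(v, res$times))
})

test_that("constant stray light leaves extraction invariant where unsaturated", {
  v <- quick_sim(130, seed = 22)
  res0 <- extract(v)
  for (off in c(10, 30)) {
    res1 <- extract(add_stray_light(v, off))
    expect_equal(res1$codes, res0$codes)
    expect_equal(res1$times, res0$times)
    for (i in seq_along(res0$images)) {
      unsat <- res0$images[[i]] < 255 - off
      expect_true(all(abs(res1$images[[i]][unsat] - res0$images[[i]][unsat]) <= 1))
    }
  }
})

test_that("raising the threshold never increases the number of pattern frames", {
  v <- quick_sim(130, seed = 23)
  counts <- vapply(c(20, 60, 120, 200, 254), function(th) {
    res <- try(extract(v, threshold = th), silent = TRUE)
    if (inherits(res, "try-error")) 0L else sum(!vapply(
      attr(res, "frame_codes"), is_dark_code, logical(1)))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("processed files follow the dataset naming and round-trip exactly", {
  img1 <- matrix(as.integer(sample(0:255, 48, TRUE)), 6, 8)
  img2 <- matrix(as.integer(sample(0:255, 48, TRUE)), 6, 8)
  res <- structure(list(images = list(img1, img2),
                        times = c(0.51, 0.39 + 0.6),
                        codes = c("100000000000", "000011110000")),
                   class = "extraction_result")
  out <- withr::local_tempdir()
  manifest <- write_processed(res, file.path(out, "finger01"))
  dir <- file.path(out, "finger01_processed")
  expect_true(dir.exists(dir))
  expect_setequal(manifest$filename, c("D01_0.51.png", "DEXT_0.99.png"))
  back <- read_processed(dir)
  expect_identical(back$images, res$images)
  expect_equal(back$times, res$times)
  expect_equal(back$codes, res$codes)

  # DEXT naming straight from the sentinel at a round time
  res$times <- c(0.51, 0.39)
  manifest2 <- write_processed(res, file.path(out, "finger02"))
  expect_true("DEXT_0.39.png" %in% manifest2$filename)
})

test_that("raw frames round-trip through the on-disk layout", {
  v <- quick_sim(13, seed = 24)
  dir <- withr::local_tempdir()
  idx <- write_frames(v, dir)
  expect_equal(nrow(idx), 13L)
  back <- read_frames(dir)
  expect_identical(back$frames, v$frames)
  expect_equal(back$timestamps, round(v$timestamps, 3), tolerance = 1e-9)
})
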