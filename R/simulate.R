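#' Simulate a full free-run acquisition
#'
#' Convenience wrapper tying the stages together: generate (or accept) a
#' phantom, place the diode bank and detector layout, build the jittered
#' illumination timeline with enough sweeps to cover the recording, and
#' capture the rolling-shutter video. The returned `frame_sequence` carries
#' the timeline (with per-cycle ground-truth codes) and the detector layout
#' as attributes, so extraction results can be scored against the truth.
#'
#' @param n_frames number of frames to record
#' @param seed integer seed driving phantom generation, timing jitter and
#'   read noise (the capture itself is deterministic given these)
#' @param shape `c(rows, cols)` of the frame (default `c(260, 336)`)
#' @param timing a [timing_config()]; its `rows` is overridden by `shape`
#' @param phantom optional [finger_phantom()] (generated from `seed` and
#'   `phantom_config` when NULL)
#' @param phantom_config parameter overrides for [generate_phantom()]
#' @param patterns a [pattern_sequence()] template; its `repeat_count` is
#'   raised to cover the recording duration
#' @param bank optional [diode_bank()]
#' @param layout optional [detector_layout()]
#' @param gain,read_noise_sd,seg_level camera model parameters, see
#'   [capture()] and [render_indicator()]
#' @return a `frame_sequence` (see [capture()]) with attributes `layout`,
#'   `phantom`, `bank` and `seed`
#' @export
simulate_acquisition <- function(n_frames, seed = 1L,
                                 shape = c(260L, 336L),
                                 timing = timing_config(),
                                 phantom = NULL,
                                 phantom_config = list(),
                                 patterns = pattern_sequence(),
                                 bank = NULL, layout = NULL,
                                 gain = 40000, read_noise_sd = 0,
                                 seg_level = 2.0) {
  timing$rows <- as.integer(shape[1])
  timing$row_readout <- 1 / timing$frame_rate / timing$rows
  if (is.null(phantom)) {
    phantom <- generate_phantom(seed, shape, phantom_config)
  }
  finger_cols <- attr(phantom, "finger_cols")
  if (is.null(finger_cols)) finger_cols <- round(0.82 * shape[2])
  if (is.null(bank)) bank <- default_diode_bank(shape, finger_cols)
  if (is.null(layout)) layout <- default_detector_layout(shape, finger_cols)
  duration <- n_frames / timing$frame_rate
  cycle <- timing$t_u + timing$t_delay + 2 * timing$seg_lag + timing$t_on
  sweeps_needed <- ceiling((duration + 5 * cycle) / (nrow(patterns) * cycle))
  sweeps <- max(attr(patterns, "repeat_count"), sweeps_needed)
  attr(patterns, "repeat_count") <- as.integer(sweeps)
  video <- with_local_seed(seed, {
    timeline <- build_timeline(timing, patterns)
    scene <- make_scene(phantom, bank, layout, seg_level,
                        strip_col0 = finger_cols)
    capture(scene, timeline, timing, n_frames, shape,
            gain = gain, read_noise_sd = read_noise_sd)
  })
  attr(video, "layout") <- layout
  attr(video, "phantom") <- phantom
  attr(video, "bank") <- bank
  attr(video, "seed") <- seed
  video
}

#' Ground-truth illumination code per cycle or frame time
#'
#' Looks up the simulator's timeline to find the illumination cycle a
#' frame starting at a given time belongs to (the cycle whose LED window
#' overlaps the frame's full rolling-shutter exposure the most), returning
#' the indicator code that was truly displayed -- the reference against
#' which extracted codes are scored.
#'
#' @param video a simulated `frame_sequence`
#' @param times vector of frame start times in seconds
#' @return character vector of 12-bit codes (`NA` for times overlapping no
#'   LED window)
#' @export
true_code_at <- function(video, times) {
  cyc <- attr(attr(video, "timeline"), "cycles")
  tm <- attr(video, "timing")
  if (is.null(cyc)) stop_invalid("video carries no ground-truth timeline")
  span <- if (is.null(tm)) 1 / video$frame_rate else {
    (tm$rows - 1) * tm$row_readout + tm$exposure
  }
  vapply(times, function(t) {
    ov <- pmin(cyc$led_off, t + span) - pmax(cyc$led_on, t)
    i <- which.max(ov)
    if (length(i) == 0L || ov[i] <= 0) NA_character_ else cyc$indicator[i]
  }, character(1))
}

#' Write raw frames as 8-bit grayscale PNGs
#'
#' Files are named by the second of measurement counting from the start of
#' recording (e.g. `0.508.png`), plus a sidecar `index.csv` (filename,
#' timestamp, ground-truth code where available) intended for testing only.
#'
#' @param video a `frame_sequence`
#' @param dir output directory (created if needed)
#' @return invisibly, the sidecar data.frame
#' @export
write_frames <- function(video, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_frames(video)
  fn <- sprintf("%.3f.png", video$timestamps)
  truth <- tryCatch(
    true_code_at(video, video$timestamps + 0.5 / video$frame_rate),
    error = function(e) rep(NA_character_, n))
  for (k in seq_len(n)) {
    png::writePNG(video$frames[, , k] / 255, file.path(dir, fn[k]))
  }
  idx <- data.frame(filename = fn, timestamp = video$timestamps,
                    code = truth, stringsAsFactors = FALSE)
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(idx)
}

#' Read a directory of raw frames
#'
#' Reads 8-bit grayscale PNGs whose names encode the capture second;
#' frames are sorted numerically (not lexically) by that time. The frame
#' rate is inferred from the median timestamp spacing.
#'
#' @param dir directory containing `<seconds>.png` files
#' @return a `frame_sequence`
#' @export
read_frames <- function(dir) {
  files <- list.files(dir, pattern = "^[0-9]+\\.?[0-9]*\\.png$")
  if (length(files) == 0L) stop_invalid("no raw PNG frames found in %s", dir)
  ts <- as.numeric(sub("\\.png$", "", files))
  ord <- order(ts)
  files <- files[ord]; ts <- ts[ord]
  first <- png::readPNG(file.path(dir, files[1]))
  if (length(dim(first)) == 3L) first <- first[, , 1]
  rows <- nrow(first); cols <- ncol(first)
  frames <- array(0L, dim = c(rows, cols, length(files)))
  for (k in seq_along(files)) {
    img <- png::readPNG(file.path(dir, files[k]))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    frames[, , k] <- as.integer(round(img * 255))
  }
  fr <- if (length(ts) > 1) 1 / stats::median(diff(ts)) else NA_real_
  structure(list(frames = frames, timestamps = ts, frame_rate = fr,
                 geometry = list(rows = rows, cols = cols)),
            class = "frame_sequence")
}
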