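#' Detector layout: indicator sites and detection thresholds
#'
#' Twelve calibration pixel positions inside the indicator strip, one per
#' back-light NIR diode (grouped 4 displays x 3 segments), together with
#' the detection threshold (20 ADU; chosen so a diode is detected even if
#' it was lit for only a small fraction of the exposure) and the saturation
#' level (255 ADU). Sites are calibration inputs: once selected they remain
#' unchanged for a device.
#'
#' @param sites data.frame with columns `id` (1..12), `row`, `col`
#'   (0-based pixel coordinates)
#' @param threshold detection level in ADU (default 20)
#' @param saturation saturation level in ADU (255 for 8-bit frames)
#' @return object of class `detector_layout`
#' @export
detector_layout <- function(sites, threshold = 20, saturation = 255) {
  stopifnot(is.data.frame(sites), all(c("id", "row", "col") %in% names(sites)))
  if (nrow(sites) != 12L) stop_invalid("a detector layout has exactly 12 sites")
  if (anyDuplicated(sites[, c("row", "col")])) {
    stop_invalid("detector sites must be distinct pixels")
  }
  if (threshold <= 0 || threshold >= saturation) {
    stop_invalid("detector threshold must satisfy 0 < threshold < saturation (%g)",
                 saturation)
  }
  structure(list(sites = sites[order(sites$id), ], threshold = threshold,
                 saturation = saturation),
            class = "detector_layout")
}

#' Default detector layout for a frame geometry
#'
#' Places the 4 displays (3 segments each) down the center column of the
#' indicator strip, which occupies the columns beyond the finger region.
#'
#' @param shape `c(rows, cols)` of the frame
#' @param finger_cols columns occupied by the finger region
#' @inheritParams detector_layout
#' @return a [detector_layout()]
#' @export
default_detector_layout <- function(shape, finger_cols = round(0.82 * shape[2]),
                                    threshold = 20, saturation = 255) {
  rows <- shape[1]; cols <- shape[2]
  if (finger_cols >= cols) stop_invalid("no columns left for the indicator strip")
  sc <- finger_cols + floor((cols - finger_cols) / 2)
  dr <- max(2L, round(0.04 * rows))
  base <- round(c(0.30, 0.42, 0.54, 0.66) * (rows - 1))
  sites <- data.frame(
    id = 1:12,
    row = as.integer(rep(base, each = 3) + rep(0:2, times = 4) * dr),
    col = as.integer(sc)
  )
  detector_layout(sites, threshold, saturation)
}

#' Render the indicator strip for a 12-bit code
#'
#' Lit segments render at `seg_level` irradiance, a level that maps to
#' saturation (255 ADU) over a full exposure under the default camera gain;
#' unlit segments render 0. Sites are modeled as single pixels, which is
#' all the extraction algorithm ever reads.
#'
#' @param pattern 12-bit indicator code
#' @param layout a [detector_layout()]
#' @param shape `c(rows, cols)` of the frame
#' @param seg_level irradiance of a lit segment (default 2.0)
#' @return numeric irradiance matrix
#' @export
render_indicator <- function(pattern, layout, shape, seg_level = 2.0) {
  bits <- parse_code(pattern)
  img <- matrix(0, shape[1], shape[2])
  st <- layout$sites
  if (any(st$row < 0 | st$row >= shape[1] | st$col < 0 | st$col >= shape[2])) {
    stop_invalid("detector sites out of frame bounds")
  }
  lit <- which(bits == 1L)
  if (length(lit)) {
    img[cbind(st$row[lit] + 1L, st$col[lit] + 1L)] <- seg_level
  }
  img
}

# ---------------------------------------------------------------------------
# Scene composition: irradiance as a function of illumination state and time.

#' Build a scene function for the simulator
#'
#' Returns `function(state, t)` giving the irradiance image for an
#' illumination state, where `state` is a list with `led` (12-bit NIR code
#' or NULL), `seg` (indicator code or NULL) and `ext` (logical, external
#' front LED). Static per-pattern components (Beer-Lambert attenuation,
#' falloff, front-lit image, indicator fragments) are cached; only the
#' cardiac modulation is recomputed per call.
#'
#' The indicator strip columns (from `strip_col0` on) belong to the display
#' module, which sits in its own opaque case: finger back- and front-light
#' do not reach them, only the 7-segment LEDs render there. Without this
#' shading, unattenuated light passing around the finger would flood the
#' detector pixels and break frame classification.
#'
#' @param phantom a [finger_phantom()]
#' @param bank a [diode_bank()]
#' @param layout a [detector_layout()]
#' @param seg_level irradiance of a lit indicator segment
#' @param strip_col0 0-based first column of the display module (`NULL`
#'   for no shading)
#' @return function(state, t) -> numeric irradiance matrix
#' @export
make_scene <- function(phantom, bank, layout, seg_level = 2.0,
                       strip_col0 = NULL) {
  shape <- dim(phantom$finger_mask)
  cache <- new.env(parent = emptyenv())
  frontlit <- NULL
  shade <- function(img) {
    if (!is.null(strip_col0) && strip_col0 < shape[2]) {
      img[, (strip_col0 + 1L):shape[2]] <- 0
    }
    img
  }
  function(state, t) {
    irr <- matrix(0, shape[1], shape[2])
    led <- state$led
    if (!is.null(led) && led != "000000000000") {
      key <- paste0("B", led)
      parts <- cache[[key]]
      if (is.null(parts)) {
        parts <- lapply(backlit_parts(phantom, bank, parse_code(led)),
                        function(p) { p$A <- shade(p$A); p })
        cache[[key]] <- parts
      }
      irr <- irr + combine_backlit_parts(parts, phantom, t)
    }
    if (isTRUE(state$ext)) {
      if (is.null(frontlit)) frontlit <<- shade(render_frontlit(phantom, bank))
      irr <- irr + frontlit
    }
    if (!is.null(state$seg)) {
      key <- paste0("S", state$seg)
      seg <- cache[[key]]
      if (is.null(seg)) {
        seg <- render_indicator(state$seg, layout, shape, seg_level)
        cache[[key]] <- seg
      }
      irr <- irr + seg
    }
    irr
  }
}

# Piecewise-constant illumination state over time, derived from a timeline.
state_intervals <- function(timeline, t_end) {
  times <- c(0, timeline$time, t_end)
  led <- NULL; seg <- NULL; ext <- FALSE
  out <- vector("list", length(times) - 1L)
  for (i in seq_len(nrow(timeline) + 1L)) {
    a <- times[i]; b <- times[i + 1L]
    out[[i]] <- list(start = a, end = b, led = led, seg = seg, ext = ext)
    if (i <= nrow(timeline)) {
      kind <- timeline$kind[i]; code <- timeline$code[i]
      if (kind == "LEDS_ON") led <- code
      else if (kind == "LEDS_OFF") led <- NULL
      else if (kind == "SEG_ON") seg <- code
      else if (kind == "SEG_OFF") seg <- NULL
      else if (kind == "EXT_ON") ext <- TRUE
      else if (kind == "EXT_OFF") ext <- FALSE
    }
  }
  out[vapply(out, function(s) s$end > s$start, logical(1))]
}

#' Capture a free-run rolling-shutter video of a scene
#'
#' Row `r` (0-based) of frame `k` integrates scene irradiance over
#' `[k/frame_rate + r*row_readout, k/frame_rate + r*row_readout + exposure]`
#' (ideal integrate-and-dump), is scaled by the gain constant, optionally
#' perturbed by Gaussian read noise, floored to integer ADU and clipped at
#' 255. Frames whose exposure straddles an LED switching event therefore
#' contain mixed rows -- the phenomenon the extraction algorithm must
#' reject. Timestamps depend only on the frame rate, never on the timeline
#' (free-run: no synchronization between camera and illuminator).
#'
#' @param scene function(state, t) -> irradiance matrix, e.g. from
#'   [make_scene()]; `state` has fields `led`, `seg`, `ext`.
#' @param timeline an `event_timeline` from [build_timeline()]
#' @param timing a [timing_config()]
#' @param n_frames number of frames to capture
#' @param shape `c(rows, cols)`; `rows` must match `timing$rows`
#' @param gain ADU per unit irradiance-second (default 40000: unit
#'   irradiance sustained over the full 5 ms exposure reads 200 ADU)
#' @param read_noise_sd Gaussian read noise sd in ADU (default 0); drawn
#'   from the current RNG stream.
#' @return object of class `frame_sequence`: list with `frames` (integer
#'   array rows x cols x n, ADU 0-255), `timestamps` (frame start, s),
#'   `frame_rate`, `geometry`; the timeline and its per-cycle ground truth
#'   are attached as attributes.
#' @export
capture <- function(scene, timeline, timing, n_frames, shape,
                    gain = 40000, read_noise_sd = 0) {
  if (!is_count(n_frames) || n_frames <= 0) {
    stop_invalid("n_frames must be a positive integer")
  }
  rows <- shape[1]; cols <- shape[2]
  if (rows != timing$rows) {
    stop_invalid("shape rows (%d) must match timing$rows (%d)", rows, timing$rows)
  }
  rho <- timing$row_readout; E <- timing$exposure
  T_f <- 1 / timing$frame_rate
  span <- (rows - 1) * rho + E
  ivs <- state_intervals(timeline, t_end = n_frames * T_f + span + 1)
  iv_start <- vapply(ivs, `[[`, numeric(1), "start")
  iv_end <- vapply(ivs, `[[`, numeric(1), "end")
  frames <- array(0L, dim = c(rows, cols, n_frames))
  timestamps <- (seq_len(n_frames) - 1L) * T_f
  row_off <- (seq_len(rows) - 1L) * rho
  img_cache_idx <- -1L; img_cache <- NULL
  render <- function(i) {
    s <- ivs[[i]]
    if (is.null(s$led) && is.null(s$seg) && !isTRUE(s$ext)) return(NULL) # dark
    if (i != img_cache_idx) {
      img_cache <<- scene(s, (s$start + s$end) / 2)
      img_cache_idx <<- i
    }
    img_cache
  }
  for (k in seq_len(n_frames)) {
    t0 <- timestamps[k]
    s_r <- t0 + row_off
    first <- findInterval(t0, iv_start)
    acc <- matrix(0, rows, cols)
    i <- max(first, 1L)
    while (i <= length(ivs) && iv_start[i] < t0 + span) {
      img <- render(i)
      if (!is.null(img)) {
        w <- pmin(iv_end[i], s_r + E) - pmax(iv_start[i], s_r)
        nz <- which(w > 0)
        if (length(nz)) {
          acc[nz, ] <- acc[nz, ] + img[nz, , drop = FALSE] * w[nz]
        }
      }
      i <- i + 1L
    }
    adu <- gain * acc
    if (read_noise_sd > 0) {
      adu <- adu + matrix(stats::rnorm(rows * cols, 0, read_noise_sd), rows)
    }
    frames[, , k] <- quantize_adu(adu)
  }
  structure(list(frames = frames, timestamps = timestamps,
                 frame_rate = timing$frame_rate,
                 geometry = list(rows = rows, cols = cols)),
            timeline = timeline,
            timing = timing,
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  n <- dim(x$frames)[3]
  cat(sprintf("frame_sequence: %d frames of %d x %d px, %.4g fps, %.3f s\n",
              n, x$geometry$rows, x$geometry$cols, x$frame_rate,
              n / x$frame_rate))
  invisible(x)
}

#' Number of frames in a frame sequence
#' @param video a `frame_sequence`
#' @return integer count
#' @export
n_frames <- function(video) dim(video$frames)[3]

#' Add stray light to a captured video
#'
#' Per-pixel addition of a constant (or slowly varying field) in ADU with
#' clipping at 255. Used to exercise the background-subtraction robustness
#' of the extraction stage against varying side illumination.
#'
#' @param video a `frame_sequence`
#' @param offset nonnegative scalar in ADU, or a rows x cols matrix
#' @return a new `frame_sequence`
#' @export
add_stray_light <- function(video, offset) {
  if (any(offset < 0)) stop_invalid("stray light offset must be >= 0")
  out <- video
  if (is.matrix(offset)) {
    offset <- array(offset, dim = dim(video$frames))
  }
  f <- video$frames + offset
  f[f > 255] <- 255L
  storage.mode(f) <- "integer"
  out$frames <- f
  out
}
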