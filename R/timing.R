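#' Illumination/camera timing configuration
#'
#' Houses the timing protocol constants: the register-update duration `t_u`
#' (hardware-determined; modeled as a mean plus optional per-cycle jitter),
#' the fixed delay `t_delay` (3 ms), the both-on window `t_on` (10 ms,
#' the period when NIR LEDs and the 7-segment indicator are lit together),
#' the camera exposure (5 ms) and frame rate (~130 frames/s). All NIR LEDs
#' are off for `t_off = t_u + t_delay` at the head of every cycle, which is
#' what guarantees a dark (reference) frame between illumination windows.
#'
#' The LED window brackets the indicator window by `seg_lag` on each side
#' (the indicator is switched after the LEDs and back off before them; the
#' switch goes through the I/O expander, a millisecond-scale latency). The
#' LED-on window is therefore `t_on + 2*seg_lag`; with the defaults that is
#' 13 ms, which exceeds `exposure + 1/frame_rate` (12.7 ms), so within
#' every cycle every image row receives at least one complete exposure
#' under full illumination -- the property the per-pixel maximum of the
#' extraction stage relies on.
#'
#' @param t_u seconds, register-update duration (default 0.014, which makes
#'   the per-pattern cycle `t_u + t_delay + 2*seg_lag + t_on = 30` ms and
#'   hence ~33 extracted frames/s at 13 patterns per sweep)
#' @param t_delay seconds (default 0.003)
#' @param t_on seconds the pattern and indicator stay lit together
#'   (default 0.010)
#' @param exposure seconds per-row exposure time (default 0.005)
#' @param frame_rate frames per second (default 130)
#' @param rows integer frame height in pixels (default 260, the post-binning
#'   slice height); row readout time is `1/frame_rate/rows`
#' @param seg_lag seconds between LEDS_ON and SEG_ON and again between
#'   SEG_OFF and LEDS_OFF (default 0.0015)
#' @param t_u_jitter_sd seconds, standard deviation of truncated-Gaussian
#'   per-cycle jitter on `t_u` (I2C transfer plus non-real-time OS
#'   scheduling make the real update time variable); 0 disables jitter.
#' @return object of class `timing_config`
#' @export
timing_config <- function(t_u = 0.014, t_delay = 0.003, t_on = 0.010,
                          exposure = 0.005, frame_rate = 130, rows = 260L,
                          seg_lag = 0.0015, t_u_jitter_sd = 0.0015) {
  if (any(c(t_u, t_delay, t_on, exposure, frame_rate) <= 0)) {
    stop_invalid("all timing durations must be positive")
  }
  if (t_on < exposure) {
    stop_invalid("t_on (%g s) must be at least the exposure time (%g s)",
                 t_on, exposure)
  }
  if (seg_lag < 0) stop_invalid("seg_lag must be >= 0")
  if (t_u_jitter_sd < 0) stop_invalid("t_u_jitter_sd must be >= 0")
  structure(list(
    t_u = t_u, t_delay = t_delay, t_off = t_u + t_delay, t_on = t_on,
    exposure = exposure, frame_rate = frame_rate, rows = as.integer(rows),
    row_readout = 1 / frame_rate / rows,
    seg_lag = seg_lag, t_u_jitter_sd = t_u_jitter_sd
  ), class = "timing_config")
}

#' @export
print.timing_config <- function(x, ...) {
  cat(sprintf(
    "timing_config: t_u=%g ms (jitter sd %g ms), t_delay=%g ms, t_on=%g ms\n",
    1e3 * x$t_u, 1e3 * x$t_u_jitter_sd, 1e3 * x$t_delay, 1e3 * x$t_on))
  cat(sprintf("  exposure=%g ms, %g fps, %d rows (row readout %.1f us)\n",
              1e3 * x$exposure, x$frame_rate, x$rows, 1e6 * x$row_readout))
  invisible(x)
}

#' External-illumination sentinel code
#'
#' The indicator code displayed together with the external (front) LED,
#' adopted verbatim as the sentinel that labels front-lit frames.
#' @return the string `"000011110000"`
#' @export
external_code <- function() "000011110000"

#' The 13-pattern illumination sequence
#'
#' Patterns P1-P12 are single-diode 12-bit codes in diode order (one
#' back-light NIR diode each); the last pattern P13 switches the external
#' front LED on and shows the sentinel [external_code()] on the indicator.
#'
#' @param patterns character vector of 12-bit codes for the NIR-only
#'   patterns (default: the 12 single-diode codes)
#' @param repeat_count number of full sweeps through the sequence
#' @return object of class `pattern_sequence`: data.frame with columns
#'   `index`, `code` (diode state), `indicator` (code shown on the 7-segment
#'   strip) and `external` (logical), plus a `repeat_count` attribute.
#' @export
pattern_sequence <- function(patterns = NULL, repeat_count = 1L) {
  if (is.null(patterns)) {
    patterns <- vapply(1:12, function(j) {
      bits <- integer(12); bits[j] <- 1L; format_code(bits)
    }, character(1))
  }
  if (length(patterns) != 12L) {
    stop_invalid("exactly 12 NIR-only patterns must precede the external pattern")
  }
  lapply(patterns, parse_code)  # validates
  if (!is_count(repeat_count) || repeat_count < 0) {
    stop_invalid("repeat_count must be a nonnegative integer")
  }
  seq_df <- data.frame(
    index = 1:13,
    code = c(patterns, "000000000000"),
    indicator = c(patterns, external_code()),
    external = c(rep(FALSE, 12), TRUE),
    stringsAsFactors = FALSE
  )
  structure(seq_df, repeat_count = as.integer(repeat_count),
            class = c("pattern_sequence", "data.frame"))
}

#' Build the event timeline for the illumination protocol
#'
#' One cycle per pattern: Registry update (`t_u`, with optional jitter) ->
#' delay (`t_delay`) -> LEDS_ON (or EXT_ON for the external pattern) ->
#' SEG_ON -> `t_on` elapses -> SEG_OFF -> LEDS_OFF/EXT_OFF. The indicator
#' window is nested strictly inside the LED window by `seg_lag` on both
#' sides, so SEG_ON never precedes LEDS_ON and SEG_OFF always precedes
#' LEDS_OFF. With zero jitter each cycle lasts exactly
#' `t_u + t_delay + 2*seg_lag + t_on` (exactly `t_u + t_delay + t_on` in
#' the zero-lag idealization).
#'
#' Jitter (when `t_u_jitter_sd > 0`) is drawn from the current RNG stream;
#' seed it (e.g. via [set.seed()] or [simulate_acquisition()]) for
#' reproducible timelines.
#'
#' @param timing a [timing_config()]
#' @param seq a [pattern_sequence()]
#' @return object of class `event_timeline`: data.frame with columns
#'   `time` (s), `kind` (LEDS_ON/LEDS_OFF/SEG_ON/SEG_OFF/EXT_ON/EXT_OFF),
#'   `code` (pattern payload), plus a `cycles` attribute with one row per
#'   cycle (sweep, pattern index, code, indicator, LED and SEG window
#'   bounds).
#' @export
build_timeline <- function(timing, seq) {
  stopifnot(inherits(timing, "timing_config"))
  if (!inherits(seq, "pattern_sequence") || nrow(seq) == 0L) {
    stop_invalid("seq must be a non-empty pattern_sequence")
  }
  sweeps <- attr(seq, "repeat_count")
  ev_time <- numeric(0); ev_kind <- character(0); ev_code <- character(0)
  cyc <- vector("list", sweeps * nrow(seq))
  t_cur <- 0
  ci <- 0L
  for (s in seq_len(sweeps)) {
    for (i in seq_len(nrow(seq))) {
      tu <- timing$t_u
      if (timing$t_u_jitter_sd > 0) {
        j <- stats::rnorm(1, 0, timing$t_u_jitter_sd)
        j <- max(min(j, 3 * timing$t_u_jitter_sd), -3 * timing$t_u_jitter_sd)
        tu <- max(tu + j, timing$t_u / 4)
      }
      led_on <- t_cur + tu + timing$t_delay
      seg_on <- led_on + timing$seg_lag
      seg_off <- seg_on + timing$t_on
      led_off <- seg_off + timing$seg_lag
      ext <- seq$external[i]
      on_kind <- if (ext) "EXT_ON" else "LEDS_ON"
      off_kind <- if (ext) "EXT_OFF" else "LEDS_OFF"
      ev_time <- c(ev_time, led_on, seg_on, seg_off, led_off)
      ev_kind <- c(ev_kind, on_kind, "SEG_ON", "SEG_OFF", off_kind)
      ev_code <- c(ev_code, seq$code[i], seq$indicator[i], seq$indicator[i],
                   seq$code[i])
      ci <- ci + 1L
      cyc[[ci]] <- data.frame(
        sweep = s, pattern = seq$index[i], code = seq$code[i],
        indicator = seq$indicator[i], external = ext,
        led_on = led_on, led_off = led_off,
        seg_on = seg_on, seg_off = seg_off,
        stringsAsFactors = FALSE)
      t_cur <- led_off
    }
  }
  tl <- data.frame(time = ev_time, kind = ev_kind, code = ev_code,
                   stringsAsFactors = FALSE)
  structure(tl,
            cycles = if (ci > 0L) do.call(rbind, cyc[seq_len(ci)]) else NULL,
            duration = t_cur,
            class = c("event_timeline", "data.frame"))
}

#' @export
print.event_timeline <- function(x, ...) {
  cyc <- attr(x, "cycles")
  cat(sprintf("event_timeline: %d events, %d cycles, %.3f s\n",
              nrow(x), if (is.null(cyc)) 0L else nrow(cyc),
              attr(x, "duration")))
  invisible(x)
}

#' Total duration of a timeline
#' @param timeline an `event_timeline`
#' @return seconds from t = 0 to the end of the last cycle
#' @export
timeline_duration <- function(timeline) attr(timeline, "duration")
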