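# Single YAML config drives all stages, so simulation ground truth and
# extraction settings cannot drift apart.

#' Documented default run configuration
#'
#' Defaults reproduce the device constants: 20 ADU detection threshold /
#' 255 saturation, t_on 10 ms, t_delay 3 ms, 5 ms exposure, 130 frames/s,
#' 260 px slice height, back-light wavelengths 730/875/940 nm.
#'
#' @return nested named list (see the shipped `inst/extdata/default.yaml`)
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_frames = 1000L,
    geometry = list(rows = 260L, cols = 336L, finger_col_frac = 0.82),
    phantom = default_phantom_config(),
    bank = list(falloff_sigma = NULL, ext_power = 0.7),
    timing = list(t_u = 0.014, t_delay = 0.003, t_on = 0.010,
                  exposure = 0.005, frame_rate = 130,
                  seg_lag = 0.0015, t_u_jitter_sd = 0.0015),
    camera = list(gain = 40000, read_noise_sd = 0, seg_level = 2.0),
    detector = list(threshold = 20, saturation = 255, sites = NULL),
    patterns = list(codes = NULL, repeat_count = 1L),
    roi = NULL  # filled from geometry by resolve_config()
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML key/value file, fills documented defaults for omitted keys
#' and cross-validates the result (thresholds within the 8-bit range,
#' detector sites and ROI inside the frame geometry, 12-bit pattern codes).
#' An empty or missing-key file yields exactly the documented defaults.
#'
#' @param path YAML file; `NULL` for pure defaults
#' @return validated config list of class `run_config`, with derived
#'   objects (`$objects$timing`, `$objects$patterns`, `$objects$layout`,
#'   `$objects$roi`) attached
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_invalid("config file not found: %s", path)
    user <- yaml::read_yaml(path)
    if (length(user)) cfg <- merge_config(cfg, user)
  }
  resolve_config(cfg)
}

#' Resolve and validate a configuration list
#'
#' @param cfg nested list in the shape of [default_config()]
#' @return config of class `run_config` (see [load_config()])
#' @export
resolve_config <- function(cfg) {
  g <- cfg$geometry
  if (!is_count(g$rows) || !is_count(g$cols) || g$rows <= 0 || g$cols <= 0) {
    stop_invalid("geometry$rows and geometry$cols must be positive integers")
  }
  shape <- c(as.integer(g$rows), as.integer(g$cols))
  finger_cols <- max(4L, round(g$finger_col_frac * g$cols))
  if (finger_cols >= g$cols) {
    stop_invalid("geometry$finger_col_frac leaves no indicator strip columns")
  }
  det <- cfg$detector
  if (!is.numeric(det$threshold) || det$threshold <= 0 ||
      det$threshold >= det$saturation) {
    stop_invalid(
      "detector$threshold must satisfy 0 < threshold < %g (saturation), got %s",
      det$saturation, format(det$threshold))
  }
  tm <- cfg$timing
  timing <- timing_config(t_u = tm$t_u, t_delay = tm$t_delay, t_on = tm$t_on,
                          exposure = tm$exposure, frame_rate = tm$frame_rate,
                          rows = shape[1], seg_lag = tm$seg_lag,
                          t_u_jitter_sd = tm$t_u_jitter_sd)
  patterns <- pattern_sequence(cfg$patterns$codes,
                               repeat_count = cfg$patterns$repeat_count)
  layout <- if (is.null(det$sites)) {
    default_detector_layout(shape, finger_cols, det$threshold, det$saturation)
  } else {
    detector_layout(as.data.frame(det$sites), det$threshold, det$saturation)
  }
  st <- layout$sites
  if (any(st$row < 0 | st$row >= shape[1] |
          st$col < 0 | st$col >= shape[2])) {
    stop_invalid("detector$sites fall outside the %d x %d frame",
                 shape[1], shape[2])
  }
  if (is.null(cfg$roi)) {
    cfg$roi <- list(row0 = round(0.25 * shape[1]),
                    col0 = round(0.25 * finger_cols),
                    height = round(0.50 * shape[1]),
                    width = round(0.37 * finger_cols))
  }
  r <- do.call(roi, cfg$roi[c("row0", "col0", "height", "width")])
  if (r$row0 + r$height > shape[1] || r$col0 + r$width > shape[2]) {
    stop_invalid("roi exceeds the %d x %d frame", shape[1], shape[2])
  }
  if (!is_count(cfg$n_frames) || cfg$n_frames <= 0) {
    stop_invalid("n_frames must be a positive integer")
  }
  if (cfg$camera$gain <= 0) stop_invalid("camera$gain must be positive")
  if (cfg$camera$read_noise_sd < 0) {
    stop_invalid("camera$read_noise_sd must be >= 0")
  }
  cfg$finger_cols <- finger_cols
  cfg$objects <- list(timing = timing, patterns = patterns, layout = layout,
                      roi = r, shape = shape)
  class(cfg) <- "run_config"
  cfg
}

#' Simulate an acquisition from a run configuration
#'
#' @param config a `run_config` from [load_config()]
#' @param n_frames override of `config$n_frames`
#' @param seed override of `config$seed`
#' @return a `frame_sequence` (see [simulate_acquisition()])
#' @export
simulate_from_config <- function(config, n_frames = config$n_frames,
                                 seed = config$seed) {
  stopifnot(inherits(config, "run_config"))
  ph_cfg <- config$phantom
  ph_cfg$finger_col_frac <- config$geometry$finger_col_frac
  bank <- default_diode_bank(
    config$objects$shape, config$finger_cols,
    falloff_sigma = if (is.null(config$bank$falloff_sigma)) {
      0.35 * config$objects$shape[1]
    } else {
      config$bank$falloff_sigma
    },
    ext_power = config$bank$ext_power)
  simulate_acquisition(
    n_frames = n_frames, seed = seed, shape = config$objects$shape,
    timing = config$objects$timing, phantom_config = ph_cfg,
    patterns = config$objects$patterns, bank = bank,
    layout = config$objects$layout,
    gain = config$camera$gain, read_noise_sd = config$camera$read_noise_sd,
    seg_level = config$camera$seg_level)
}
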