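# Blood-pulse recovery from the demultiplexed series: ROI averaging,
# per-diode mean-1 normalization (which is what permits combining diodes of
# different power and wavelength into one series), and a least-squares
# spectral fit over the physiological band for rate estimation / liveness.

#' Rectangular region of interest
#'
#' 0-based, half-open rectangle `[row0, row0+height) x [col0, col0+width)`
#' within the finger area over which image brightness is averaged.
#'
#' @param row0,col0 top-left corner (0-based)
#' @param height,width extent in pixels (both > 0)
#' @return object of class `roi`
#' @export
roi <- function(row0, col0, height, width) {
  if (height <= 0 || width <= 0) stop_invalid("roi area must be positive")
  if (row0 < 0 || col0 < 0) stop_invalid("roi origin must be nonnegative")
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi")
}

roi_slice <- function(r, img) {
  if (r$row0 + r$height > nrow(img) || r$col0 + r$width > ncol(img)) {
    stop_invalid("roi [%d+%d, %d+%d] exceeds image bounds (%d x %d)",
                 r$row0, r$height, r$col0, r$width, nrow(img), ncol(img))
  }
  img[(r$row0 + 1L):(r$row0 + r$height), (r$col0 + 1L):(r$col0 + r$width)]
}

#' ROI mean brightness per extracted image
#'
#' One sample per extracted image: the arithmetic mean of ADU over the ROI,
#' tagged with the source diode. External-illumination (front-lit) entries
#' carry no vein signal and are excluded by default.
#'
#' @param result an `extraction_result`
#' @param roi a [roi()]
#' @param include_external keep entries whose code is the external sentinel
#'   (default FALSE)
#' @return data.frame with columns `time`, `mean`, `diode` (1-based diode
#'   index for single-diode codes, `"EXT"` for the external sentinel, the
#'   code string otherwise)
#' @export
roi_mean_series <- function(result, roi, include_external = FALSE) {
  if (length(result$images) == 0L) stop_invalid("extraction result is empty")
  means <- vapply(result$images, function(img) mean(roi_slice(roi, img)),
                  numeric(1))
  idx <- code_diode(result$codes)
  diode <- ifelse(!is.na(idx), as.character(idx),
                  ifelse(result$codes == external_code(), "EXT", result$codes))
  out <- data.frame(time = result$times, mean = means, diode = diode,
                    stringsAsFactors = FALSE)
  if (!include_external) out <- out[out$diode != "EXT", ]
  if (nrow(out) == 0L) stop_invalid("no usable samples in the ROI series")
  out
}

#' Normalize per diode and combine into one pulse signal
#'
#' Each diode's brightness series is divided by its own arithmetic mean, so
#' every per-diode subset has mean exactly 1; the normalized samples are
#' then merged into a single time-ordered series. Scale differences between
#' diodes (power, wavelength, geometry) cancel exactly, which is why the
#' combined series can carry the cardiac modulation from all diodes at
#' once.
#'
#' @param series data.frame from [roi_mean_series()] (columns `time`,
#'   `mean`, `diode`)
#' @param detrend per-diode linear detrend before normalization (default
#'   FALSE)
#' @return object of class `pulse_signal`: list with `times`, `values`
#'   (unitless, per-diode mean 1) and `diode_ids`
#' @export
normalize_combine <- function(series, detrend = FALSE) {
  stopifnot(all(c("time", "mean", "diode") %in% names(series)))
  if (nrow(series) == 0L) stop_invalid("empty series")
  values <- series$mean
  for (d in unique(series$diode)) {
    i <- series$diode == d
    if (detrend && sum(i) > 2) {
      fit <- stats::lm.fit(cbind(1, series$time[i]), values[i])
      values[i] <- values[i] - fit$fitted.values + mean(values[i])
    }
    m <- mean(values[i])
    if (!is.finite(m) || m == 0) {
      stop_invalid("diode %s has zero mean brightness: degenerate signal", d)
    }
    values[i] <- values[i] / m
  }
  ord <- order(series$time)
  structure(list(times = series$time[ord], values = values[ord],
                 diode_ids = series$diode[ord]),
            class = "pulse_signal")
}

#' @export
print.pulse_signal <- function(x, ...) {
  cat(sprintf("pulse_signal: %d samples over %.2f s from %d diodes\n",
              length(x$times), diff(range(x$times)),
              length(unique(x$diode_ids))))
  invisible(x)
}

#' Minimum sampling rate to resolve the pulse on every diode
#'
#' With `n_diodes` multiplexed sources each needing to sample a cardiac
#' signal at `heart_rate` beats/min, the Nyquist criterion requires
#' `2 * (heart_rate / 60) * n_diodes` samples per second overall (e.g. 36
#' samples/s for 90 bpm and 12 diodes).
#'
#' @param heart_rate beats per minute (> 0)
#' @param n_diodes number of multiplexed sources (>= 1)
#' @return samples per second
#' @export
required_sampling_rate <- function(heart_rate, n_diodes) {
  if (!is.numeric(heart_rate) || heart_rate <= 0) {
    stop_invalid("heart_rate must be positive")
  }
  if (!is_count(n_diodes) || n_diodes < 1) {
    stop_invalid("n_diodes must be a positive integer")
  }
  2 * (heart_rate / 60) * n_diodes
}

# Least-squares amplitude of a sinusoid at frequency f fitted to (t, x).
ls_sin_amplitude <- function(t, x, f) {
  w <- 2 * pi * f
  s <- sin(w * t); c <- cos(w * t)
  X <- cbind(s, c)
  fit <- tryCatch(stats::lm.fit(X, x), error = function(e) NULL)
  if (is.null(fit)) return(0)
  sqrt(sum(fit$coefficients^2))
}

#' Estimate the pulse rate from an irregularly sampled signal
#'
#' Least-squares spectral fit (Lomb-Scargle-type periodogram for irregular
#' sampling): a single sinusoid is fitted at each frequency of a grid over
#' the physiological band, the dominant frequency is the grid peak refined
#' by golden-section search, and the amplitude is the fitted sinusoid
#' amplitude (half peak-to-peak) relative to the unit mean. A pulse is
#' declared detected only if that amplitude reaches `min_amplitude` and
#' stands `min_peak_ratio` times above the median spectral amplitude over
#' the band (the in-band noise floor); otherwise the result is flagged "no
#' pulse detected", the liveness safeguard against artificial-finger
#' presentations.
#'
#' @param signal a `pulse_signal` from [normalize_combine()]
#' @param band frequency search band in Hz (default 0.6-3.5, i.e. 36-210
#'   beats/min)
#' @param min_amplitude minimum fractional amplitude for a detection
#'   (default 0.001, calibrated about three-fold above the largest spectral
#'   amplitude a pulseless phantom produces under the default acquisition)
#' @param min_peak_ratio minimum peak-to-floor ratio for a detection
#'   (default 4)
#' @param oversample frequency grid oversampling relative to `1/span`
#'   (default 8)
#' @param trim_mad artifact rejection: samples further than `trim_mad`
#'   median absolute deviations from the median are dropped before the
#'   fit (windows that catch only a partial rolling-shutter exposure leave
#'   occasional gross brightness outliers, the image-series analogue of
#'   motion artifacts in photoplethysmography); `Inf` disables trimming.
#' @return object of class `pulse_estimate`: list with `detected`,
#'   `frequency_hz`, `rate_bpm`, `amplitude`, `peak_ratio`, `band`, `n`
#' @export
estimate_pulse_rate <- function(signal, band = c(0.6, 3.5),
                                min_amplitude = 0.001, min_peak_ratio = 4,
                                oversample = 8, trim_mad = 4) {
  t <- signal$times; x <- signal$values
  if (is.finite(trim_mad)) {
    s <- stats::mad(x)
    if (s > 0) {
      keep <- abs(x - stats::median(x)) <= trim_mad * s
      t <- t[keep]; x <- x[keep]
    }
  }
  x <- x - mean(x)
  span <- diff(range(t))
  if (span < 3 / band[1]) {
    stop_invalid(paste0("signal spans %.2f s but at least %.2f s (3 periods at ",
                        "the %.2f Hz band edge) are required"),
                 span, 3 / band[1], band[1])
  }
  df <- 1 / (oversample * span)
  grid <- seq(band[1], band[2], by = df)
  amps <- vapply(grid, function(f) ls_sin_amplitude(t, x, f), numeric(1))
  i <- which.max(amps)
  lo <- grid[max(1L, i - 2L)]; hi <- grid[min(length(grid), i + 2L)]
  opt <- stats::optimize(function(f) -ls_sin_amplitude(t, x, f),
                         lower = lo, upper = hi)
  f_hat <- opt$minimum
  a_hat <- -opt$objective
  floor_amp <- stats::median(amps)
  ratio <- if (floor_amp > 0) a_hat / floor_amp else Inf
  detected <- a_hat >= min_amplitude && ratio >= min_peak_ratio
  if (!detected) vs_log("no pulse detected (amplitude %.2g, ratio %.2g)",
                        a_hat, ratio)
  structure(list(detected = detected,
                 frequency_hz = if (detected) f_hat else NA_real_,
                 rate_bpm = if (detected) 60 * f_hat else NA_real_,
                 amplitude = a_hat, peak_ratio = ratio,
                 band = band, n = length(t)),
            class = "pulse_estimate")
}

#' @export
print.pulse_estimate <- function(x, ...) {
  if (x$detected) {
    cat(sprintf(
      "pulse_estimate: %.2f Hz (%.0f bpm), amplitude %.3f (peak ratio %.1f)\n",
      x$frequency_hz, x$rate_bpm, x$amplitude, x$peak_ratio))
  } else {
    cat(sprintf("pulse_estimate: no pulse detected (amplitude %.2g, ratio %.2g)\n",
                x$amplitude, x$peak_ratio))
  }
  invisible(x)
}

#' Write a pulse signal as CSV
#' @param signal a `pulse_signal`
#' @param path output file
#' @return invisibly, the data.frame written (`time_s`, `value`, `diode`)
#' @export
write_pulse_csv <- function(signal, path) {
  df <- data.frame(time_s = signal$times, value = signal$values,
                   diode = signal$diode_ids, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
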