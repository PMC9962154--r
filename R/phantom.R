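#' Construct a finger optical phantom
#'
#' A `finger_phantom` bundles the maps that drive trans-illuminated
#' (back-lit) and reflectance (front-lit) rendering of a finger: the finger
#' silhouette, per-pixel effective blood path length through veins, bulk
#' tissue path length, a multiplicative surface-reflectance texture, the
#' nail/lunula region (which attenuates less and shows up as the bright
#' patches within nails in extracted images), wavelength-dependent
#' absorption coefficients, and the cardiac pulse parameters.
#'
#' @param finger_mask logical/0-1 matrix, finger silhouette.
#' @param vein_depth_map nonnegative matrix, effective vein-blood path length
#'   per pixel (arbitrary length units); positive only inside `finger_mask`.
#' @param tissue_depth_map nonnegative matrix, bulk-tissue path length.
#' @param texture_map matrix in (0, 1], multiplicative surface reflectance
#'   used by front-lit rendering.
#' @param nail_mask logical/0-1 matrix of the nail/lunula region; tissue
#'   depth there is scaled by `nail_factor` at render time.
#' @param absorption data.frame with columns `wavelength_nm`, `mu_tissue`,
#'   `mu_blood` (absorption coefficients, inverse length units).
#' @param pulse list with `rate_bpm` (beats/min), `amplitude` (unitless
#'   fractional modulation of the vein path length, in \[0, 0.2\]; blood-pulse
#'   intensity modulation is a few percent), `phase` (radians).
#' @param nail_factor scalar in (0, 1\], tissue-depth multiplier under the
#'   nail (default 0.45).
#' @return object of class `finger_phantom`
#' @seealso [generate_phantom()], [render_backlit()], [render_frontlit()]
#' @export
finger_phantom <- function(finger_mask, vein_depth_map, tissue_depth_map,
                           texture_map, nail_mask = NULL,
                           absorption = default_absorption(),
                           pulse = list(rate_bpm = 90, amplitude = 0.03,
                                        phase = 0),
                           nail_factor = 0.45) {
  finger_mask <- matrix(as.logical(finger_mask), nrow(finger_mask))
  dm <- dim(finger_mask)
  if (is.null(nail_mask)) nail_mask <- matrix(FALSE, dm[1], dm[2])
  nail_mask <- matrix(as.logical(nail_mask), dm[1])
  for (nm in c("vein_depth_map", "tissue_depth_map", "texture_map")) {
    m <- get(nm)
    if (!is.matrix(m) || !all(dim(m) == dm)) {
      stop_invalid("%s must be a matrix with the same dimensions as finger_mask", nm)
    }
    if (!all(is.finite(m))) stop_invalid("%s must be finite", nm)
  }
  if (any(vein_depth_map < 0) || any(tissue_depth_map < 0)) {
    stop_invalid("depth maps must be nonnegative")
  }
  if (any(vein_depth_map[!finger_mask] > 0)) {
    stop_invalid("vein_depth_map must be positive only inside finger_mask")
  }
  if (any(texture_map <= 0) || any(texture_map > 1)) {
    stop_invalid("texture_map values must lie in (0, 1]")
  }
  if (!all(c("wavelength_nm", "mu_tissue", "mu_blood") %in% names(absorption))) {
    stop_invalid("absorption table needs columns wavelength_nm, mu_tissue, mu_blood")
  }
  if (!is.numeric(pulse$amplitude) || pulse$amplitude < 0 || pulse$amplitude > 0.2) {
    stop_invalid("pulse amplitude must lie in [0, 0.2]")
  }
  if (!is.numeric(pulse$rate_bpm) || pulse$rate_bpm <= 0) {
    stop_invalid("pulse rate_bpm must be positive")
  }
  if (is.null(pulse$phase)) pulse$phase <- 0
  structure(list(
    finger_mask = finger_mask,
    vein_depth_map = vein_depth_map,
    tissue_depth_map = tissue_depth_map,
    texture_map = texture_map,
    nail_mask = nail_mask,
    absorption = absorption,
    pulse = pulse,
    nail_factor = nail_factor
  ), class = "finger_phantom")
}

#' @export
print.finger_phantom <- function(x, ...) {
  dm <- dim(x$finger_mask)
  cat(sprintf("finger_phantom: %d x %d px, %d finger px, %d vein px\n",
              dm[1], dm[2], sum(x$finger_mask), sum(x$vein_depth_map > 0)))
  cat(sprintf("  pulse: %.0f bpm, amplitude %.3f\n",
              x$pulse$rate_bpm, x$pulse$amplitude))
  invisible(x)
}

#' Default absorption coefficients
#'
#' Illustrative per-unit-path absorption coefficients for bulk tissue and
#' venous blood at the three back-light wavelengths and the 830 nm external
#' illuminator. The absolute values are free parameters of the phantom (no
#' physiological claim); what matters downstream is the strict ordering of
#' `mu_blood` across wavelengths, which makes vein contrast strongest at
#' 940 nm and weakest at 730 nm in rendered images.
#'
#' @return data.frame with columns `wavelength_nm`, `mu_tissue`, `mu_blood`
#' @export
default_absorption <- function() {
  data.frame(
    wavelength_nm = c(730, 830, 875, 940),
    mu_tissue     = c(0.30, 0.26, 0.22, 0.18),
    mu_blood      = c(0.25, 0.32, 0.40, 0.55)
  )
}

#' Cardiac waveform
#'
#' Zero-mean periodic pulse waveform: a fundamental sinusoid plus one
#' second-harmonic component (relative weight `harmonic`) giving the
#' asymmetric rise/fall of a blood-pressure pulse, normalized so that
#' `max(|w|) == 1`.
#'
#' @param t time in seconds (vector ok)
#' @param rate_bpm heart rate in beats per minute
#' @param phase phase offset in radians
#' @param harmonic relative weight of the second harmonic (default 0.3)
#' @return numeric vector of waveform values in \[-1, 1\]
#' @export
cardiac_waveform <- function(t, rate_bpm, phase = 0, harmonic = 0.3) {
  theta <- 2 * pi * (rate_bpm / 60) * t + phase
  raw <- sin(theta) + harmonic * sin(2 * theta)
  # peak of sin(x) + h sin(2x): cos(x) + 2h cos(2x) = 0 => 4h c^2 + c - 2h = 0
  if (harmonic > 0) {
    cpk <- (-1 + sqrt(1 + 32 * harmonic^2)) / (8 * harmonic)
    spk <- sqrt(1 - cpk^2)
    peak <- spk + harmonic * 2 * spk * cpk
  } else {
    peak <- 1
  }
  raw / peak
}

#' Bank of back-light NIR diodes plus the external illuminator
#'
#' Twelve back-light sources arranged 3 wavelength rows x 4 columns along
#' the finger axis (940 nm / 875 nm / 730 nm rows with relative optical
#' powers 140 / 210 / 240 mW), plus one 830 nm front-side external LED.
#' Spatial falloff of each source on the sensor is a Gaussian kernel
#' (diffuse transmission through tissue blurs point sources).
#'
#' @param diodes data.frame with columns `id`, `row`, `col` (0-based pixel
#'   position of the source center), `wavelength_nm`, `power` (relative).
#' @param external list with `wavelength_nm`, `power`, `row`, `col`, `sigma`.
#' @param falloff_sigma Gaussian falloff width in pixels for back-light
#'   diodes (`Inf` for no falloff).
#' @return object of class `diode_bank`
#' @export
diode_bank <- function(diodes, external, falloff_sigma) {
  stopifnot(is.data.frame(diodes),
            all(c("id", "row", "col", "wavelength_nm", "power") %in% names(diodes)))
  if (nrow(diodes) != 12L) {
    stop_invalid("a diode bank has exactly 12 back-light sources, got %d",
                 nrow(diodes))
  }
  structure(list(diodes = diodes, external = external,
                 falloff_sigma = falloff_sigma),
            class = "diode_bank")
}

#' Default diode bank for a given frame geometry
#'
#' Places the 12 back-light diodes on a 3-row x 4-column grid over the
#' finger region and the external LED above the finger center.
#'
#' @param shape `c(rows, cols)` of the full frame
#' @param finger_cols number of columns occupied by the finger region
#'   (the indicator strip uses the remaining columns)
#' @param falloff_sigma Gaussian falloff width in pixels (default
#'   `0.35 * rows`)
#' @param ext_power relative optical power of the external LED
#' @return a [diode_bank()]
#' @export
default_diode_bank <- function(shape, finger_cols = round(0.82 * shape[2]),
                               falloff_sigma = 0.35 * shape[1],
                               ext_power = 0.7) {
  rows <- shape[1]
  row_fracs <- c(0.30, 0.50, 0.70)        # wavelength rows across the finger
  col_fracs <- c(0.15, 0.40, 0.64, 0.88)  # positions along the finger axis
  wl_by_row <- c(940, 875, 730)
  pw_by_row <- c(140, 210, 240) / 240
  diodes <- data.frame(
    id = 1:12,
    row = rep(round(row_fracs * (rows - 1)), each = 4),
    col = rep(round(col_fracs * (finger_cols - 1)), times = 3),
    wavelength_nm = rep(wl_by_row, each = 4),
    power = rep(pw_by_row, each = 4)
  )
  external <- list(wavelength_nm = 830, power = ext_power,
                   row = round(0.5 * (rows - 1)),
                   col = round(0.45 * (finger_cols - 1)),
                   sigma = 1.2 * rows)
  diode_bank(diodes, external, falloff_sigma)
}

#' @export
print.diode_bank <- function(x, ...) {
  cat(sprintf("diode_bank: 12 NIR diodes (%s nm), external %g nm\n",
              paste(unique(x$diodes$wavelength_nm), collapse = "/"),
              x$external$wavelength_nm))
  invisible(x)
}

gaussian_falloff <- function(shape, row0, col0, sigma) {
  if (!is.finite(sigma)) return(matrix(1, shape[1], shape[2]))
  dr2 <- (seq_len(shape[1]) - 1 - row0)^2
  dc2 <- (seq_len(shape[2]) - 1 - col0)^2
  exp(-outer(dr2, dc2, `+`) / (2 * sigma^2))
}

lookup_absorption <- function(absorption, wavelength_nm) {
  i <- match(wavelength_nm, absorption$wavelength_nm)
  if (is.na(i)) {
    stop_invalid("wavelength %g nm not present in the phantom absorption table",
                 wavelength_nm)
  }
  absorption[i, ]
}

# Static per-diode attenuation A = power * falloff * exp(-mu_t * T - mu_b * V)
# and pulsatile exponent M = mu_b * V, so that the time-dependent irradiance
# of one diode is A * exp(-M * amplitude * w(t)). Splitting the two lets the
# capture loop cache A and M per illumination pattern.
backlit_parts <- function(phantom, bank, bits) {
  shape <- dim(phantom$finger_mask)
  tissue <- phantom$tissue_depth_map *
    ifelse(phantom$nail_mask, phantom$nail_factor, 1)
  lapply(which(bits == 1L), function(j) {
    d <- bank$diodes[j, ]
    ab <- lookup_absorption(phantom$absorption, d$wavelength_nm)
    fall <- gaussian_falloff(shape, d$row, d$col, bank$falloff_sigma)
    A <- d$power * fall *
      exp(-ab$mu_tissue * tissue - ab$mu_blood * phantom$vein_depth_map)
    list(A = A, M = ab$mu_blood * phantom$vein_depth_map)
  })
}

combine_backlit_parts <- function(parts, phantom, t) {
  shape <- dim(phantom$finger_mask)
  irr <- matrix(0, shape[1], shape[2])
  if (length(parts) == 0L) return(irr)
  a <- phantom$pulse$amplitude
  w <- if (a > 0) {
    cardiac_waveform(t, phantom$pulse$rate_bpm, phantom$pulse$phase)
  } else {
    0
  }
  for (p in parts) {
    irr <- irr + if (a > 0) p$A * exp(-p$M * a * w) else p$A
  }
  irr
}

#' Render the trans-illuminated (back-lit) finger
#'
#' Beer-Lambert transmission with separable Gaussian source falloff: per
#' pixel, the irradiance is the sum over lit diodes of
#' `power * falloff * exp(-mu_tissue * tissue_depth - mu_blood *
#' vein_depth * (1 + amplitude * w(t)))`, where `w(t)` is the zero-mean
#' cardiac waveform. Nail pixels use reduced tissue depth (bright nail
#' regions in extracted images).
#'
#' @param phantom a [finger_phantom()]
#' @param bank a [diode_bank()]
#' @param pattern 12-bit diode state (string of 12 binary digits or 12-long
#'   0/1 vector)
#' @param t time in seconds (drives the cardiac modulation)
#' @return numeric irradiance matrix (arbitrary units)
#' @export
render_backlit <- function(phantom, bank, pattern, t = 0) {
  if (t < 0) stop_invalid("t must be >= 0")
  bits <- parse_code(pattern)
  combine_backlit_parts(backlit_parts(phantom, bank, bits), phantom, t)
}

#' Render the front-lit finger (external illuminator)
#'
#' Reflectance image: external LED power times its Gaussian falloff times
#' the surface texture map, inside the finger silhouette and zero outside.
#' Veins are sub-surface and do not appear under front lighting.
#'
#' @inheritParams render_backlit
#' @return numeric irradiance matrix
#' @export
render_frontlit <- function(phantom, bank) {
  shape <- dim(phantom$finger_mask)
  ext <- bank$external
  fall <- gaussian_falloff(shape, ext$row, ext$col, ext$sigma)
  ext$power * fall * phantom$texture_map * phantom$finger_mask
}
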