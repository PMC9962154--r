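# Shared fixtures, all built in code. Tests run on a reduced 64 x 96 frame:
# the rolling-shutter physics depend on the frame period and exposure, not
# on the pixel count, so the small geometry exercises the same timing
# phenomena at a fraction of the cost.

tiny_shape <- c(64L, 96L)

quick_sim <- function(n_frames, seed = 1L, shape = tiny_shape, ...) {
  simulate_acquisition(n_frames = n_frames, seed = seed, shape = shape, ...)
}

tiny_roi <- function() roi(row0 = 16, col0 = 20, height = 32, width = 30)

# Single-pixel phantom for closed-form Beer-Lambert checks.
pixel_phantom <- function(tissue = 1, vein = 0, mu_tissue = 0.5,
                          mu_blood = 0.3, wavelength = 940,
                          amplitude = 0, rate_bpm = 60) {
  finger_phantom(
    finger_mask = matrix(TRUE, 1, 1),
    vein_depth_map = matrix(vein, 1, 1),
    tissue_depth_map = matrix(tissue, 1, 1),
    texture_map = matrix(1, 1, 1),
    absorption = data.frame(wavelength_nm = wavelength,
                            mu_tissue = mu_tissue, mu_blood = mu_blood),
    pulse = list(rate_bpm = rate_bpm, amplitude = amplitude, phase = 0)
  )
}

pixel_bank <- function(wavelength = 940, power = 1) {
  diode_bank(
    diodes = data.frame(id = 1:12, row = 0, col = 0:11,
                        wavelength_nm = wavelength, power = power),
    external = list(wavelength_nm = 830, power = 1, row = 0, col = 0,
                    sigma = Inf),
    falloff_sigma = Inf
  )
}

single_code <- function(j) {
  bits <- integer(12); bits[j] <- 1L
  paste(bits, collapse = "")
}

# Hand-built event timeline (columns only; no cycle metadata needed).
manual_timeline <- function(time, kind, code = "100000000000") {
  structure(data.frame(time = time, kind = kind,
                       code = rep_len(code, length(time)),
                       stringsAsFactors = FALSE),
            duration = max(time),
            class = c("event_timeline", "data.frame"))
}

# Wrap a stack of integer matrices as a frame_sequence.
manual_video <- function(frame_list, frame_rate = 130) {
  rows <- nrow(frame_list[[1]]); cols <- ncol(frame_list[[1]])
  frames <- array(0L, dim = c(rows, cols, length(frame_list)))
  for (k in seq_along(frame_list)) frames[, , k] <- frame_list[[k]]
  structure(list(frames = frames,
                 timestamps = (seq_along(frame_list) - 1) / frame_rate,
                 frame_rate = frame_rate,
                 geometry = list(rows = rows, cols = cols)),
            class = "frame_sequence")
}

# 12 detector sites squeezed into an 8 x 8 frame (two strip columns).
tiny_layout <- function(threshold = 20) {
  detector_layout(
    data.frame(id = 1:12,
               row = c(0:5, 0:5),
               col = rep(c(6L, 7L), each = 6)),
    threshold = threshold)
}
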