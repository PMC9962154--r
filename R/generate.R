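# Procedural phantom generation: a capsule-shaped finger silhouette with a
# dome tissue-thickness profile, a nail/lunula patch near the tip, a branching
# curvilinear vein network grown by seeded random walks, and a smooth random
# surface texture. Everything is deterministic for a fixed seed.

#' Default phantom generator parameters
#'
#' @return named list of generator parameters (see [generate_phantom()])
#' @export
default_phantom_config <- function() {
  list(
    finger_col_frac = 0.82, # fraction of frame columns occupied by the finger
    half_width_frac = 0.34, # finger half-width as fraction of frame rows
    tissue_depth_max = 2.0, # dome peak bulk path length (arbitrary units)
    tissue_depth_min = 0.5, # path length at the silhouette edge
    vein_density = 1.0,     # scales trunk count and branching probability
    vein_depth_lo = 1.8,    # per-vessel blood path length range
    vein_depth_hi = 3.0,
    vein_radius_max = 4L,   # vessel radius 1..4 px (width 2..8 px)
    texture_lo = 0.6,       # texture map range (texture_lo, 1]
    texture_sigma = 3,      # smoothing of the texture random field, px
    nail_factor = 0.45,     # tissue-depth multiplier under the nail
    pulse = list(rate_bpm = 90, amplitude = 0.03, phase = 0)
  )
}

# Separable Gaussian blur with edge replication.
blur2d <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], half), v, rep(v[n], half))
    as.numeric(stats::convolve(vp, rev(k), type = "filter"))
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

finger_half_width <- function(cols_rel, half_width) {
  # taper along the finger then an elliptical tip cap
  s_tip <- 0.85
  hw <- half_width * (1 - 0.25 * cols_rel)
  cap <- cols_rel > s_tip
  hw[cap] <- half_width * (1 - 0.25 * s_tip) *
    sqrt(pmax(0, 1 - ((cols_rel[cap] - s_tip) / (1 - s_tip))^2))
  hw
}

stamp_disk <- function(map, r0, c0, radius, depth) {
  rows <- nrow(map); cols <- ncol(map)
  rr <- max(1L, r0 - radius):min(rows, r0 + radius)
  cc <- max(1L, c0 - radius):min(cols, c0 + radius)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
  # chord length through a cylindrical vessel
  prof <- depth * sqrt(pmax(0, 1 - d2 / (radius + 0.5)^2))
  map[rr, cc] <- pmax(map[rr, cc], prof)
  map
}

grow_vein_network <- function(shape, finger_cols, mask, config) {
  rows <- shape[1]
  vein <- matrix(0, rows, shape[2])
  density <- config$vein_density
  if (density <= 0) return(vein)
  rc <- (rows + 1) / 2
  x0 <- max(2L, round(0.04 * finger_cols))
  x1 <- round(0.93 * finger_cols)
  n_trunks <- max(1L, round(2 * density))
  # walkers: (row position, lateral drift, radius, depth, start col)
  walkers <- lapply(seq_len(n_trunks), function(i) {
    list(r = rc + runif(1, -0.4, 0.4) * 0.5 * rows * config$half_width_frac,
         drift = runif(1, -0.3, 0.3),
         radius = sample(seq_len(config$vein_radius_max), 1),
         depth = runif(1, config$vein_depth_lo, config$vein_depth_hi),
         from = x0)
  })
  branch_p <- 0.025 * density
  for (x in x0:x1) {
    spawned <- list()
    for (i in seq_along(walkers)) {
      wk <- walkers[[i]]
      if (x < wk$from) next
      hw <- finger_half_width((x - x0) / (finger_cols - x0), config$half_width_frac * rows)
      wk$drift <- wk$drift + rnorm(1, 0, 0.15)
      wk$drift <- max(min(wk$drift, 0.8), -0.8)
      wk$r <- wk$r + wk$drift + rnorm(1, 0, 0.4)
      lim <- max(1, hw - wk$radius - 1)
      wk$r <- max(min(wk$r, rc + lim), rc - lim)
      vein <- stamp_disk(vein, round(wk$r), x, wk$radius, wk$depth)
      if (runif(1) < branch_p && length(walkers) + length(spawned) < 8 * density) {
        spawned[[length(spawned) + 1L]] <- list(
          r = wk$r, drift = -wk$drift + rnorm(1, 0, 0.2),
          radius = max(1L, wk$radius - sample(0:1, 1)),
          depth = wk$depth * runif(1, 0.7, 1),
          from = x + 1L)
      }
      walkers[[i]] <- wk
    }
    walkers <- c(walkers, spawned)
  }
  vein[!mask] <- 0
  vein
}

#' Generate a finger optical phantom
#'
#' Deterministic for a fixed seed; different seeds yield visibly different
#' vein networks. The frame accommodates both the finger region (left
#' `finger_col_frac` fraction of columns) and the indicator strip placed as
#' a longitudinal extension of the finger (remaining columns; the strip
#' content itself is rendered by the acquisition stage).
#'
#' @param seed integer RNG seed
#' @param shape `c(rows, cols)` of the full frame in pixels
#' @param config generator parameters, see [default_phantom_config()];
#'   entries given here override the defaults.
#' @return a [finger_phantom()]
#' @export
generate_phantom <- function(seed, shape, config = list()) {
  if (length(shape) != 2L || any(shape <= 0) || any(shape != round(shape))) {
    stop_invalid("shape must be two positive integers (rows, cols)")
  }
  config <- utils::modifyList(default_phantom_config(), config)
  rows <- shape[1]; cols <- shape[2]
  finger_cols <- max(4L, round(config$finger_col_frac * cols))
  with_local_seed(seed, {
    rc <- (rows + 1) / 2
    x0 <- max(2L, round(0.04 * finger_cols))
    hw_px <- config$half_width_frac * rows
    mask <- matrix(FALSE, rows, cols)
    tissue <- matrix(0, rows, cols)
    for (x in x0:finger_cols) {
      hw <- finger_half_width((x - x0) / (finger_cols - x0), hw_px)
      if (hw < 0.5) next
      rr <- which(abs(seq_len(rows) - rc) <= hw)
      mask[rr, x] <- TRUE
      dome <- sqrt(pmax(0, 1 - ((rr - rc) / hw)^2))
      tissue[rr, x] <- config$tissue_depth_min +
        (config$tissue_depth_max - config$tissue_depth_min) * dome
    }
    # nail / lunula: elliptical patch straddling the tip region
    nail <- matrix(FALSE, rows, cols)
    nc <- x0 + 0.86 * (finger_cols - x0)
    a_r <- 0.38 * hw_px
    a_c <- 0.07 * finger_cols
    rr <- seq_len(rows); cc <- seq_len(cols)
    nail_d <- outer(((rr - rc) / a_r)^2, ((cc - nc) / a_c)^2, `+`)
    nail[nail_d <= 1] <- TRUE
    nail <- nail & mask

    vein <- grow_vein_network(shape, finger_cols, mask, config)

    texture <- matrix(runif(rows * cols), rows, cols)
    texture <- blur2d(texture, config$texture_sigma)
    rng <- range(texture)
    texture <- config$texture_lo +
      (1 - config$texture_lo) * (texture - rng[1]) / max(rng[2] - rng[1], 1e-12)
    texture[texture <= 0] <- 1e-6

    ph <- finger_phantom(mask, vein, tissue, texture, nail,
                         pulse = config$pulse, nail_factor = config$nail_factor)
    attr(ph, "seed") <- seed
    attr(ph, "finger_cols") <- finger_cols
    ph
  })
}
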