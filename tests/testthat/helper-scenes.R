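# Shared fixture builders. All fixtures are generated in code; scenes are
# kept small so the suite stays fast.

# One straight horizontal vessel spanning most of the field.
straight_scene <- function(d_um = 20, v_mm_s = 0.5, len_px = 280,
                           noise_sd = 0, jitter_amplitude_px = 0,
                           jitter_path = NULL, blink_frames = integer(0),
                           n_frames = 50, height = 140, margin = 20,
                           contrast = 0.5, background_texture = 0.05) {
  y <- height / 2
  vs <- vessel_spec(cbind(c(margin, margin + len_px), c(y, y)),
                    diameter_um = d_um, velocity_mm_s = v_mm_s,
                    contrast = contrast)
  scene_spec(margin * 2 + len_px, height, vessels = list(vs),
             n_frames = n_frames, noise_sd = noise_sd,
             jitter_amplitude_px = jitter_amplitude_px,
             jitter_path = jitter_path, blink_frames = blink_frames,
             background_texture = background_texture)
}

# The straight centerline of straight_scene as a vessel_segment, so
# velocimetry can be tested independently of segmentation.
straight_segment <- function(scene) {
  v <- scene$vessels[[1]]
  xs <- seq(v$points[1, 1], v$points[2, 1])
  structure(list(id = 1L, path = cbind(x = xs, y = rep(v$points[1, 2],
                                                       length(xs))),
                 length_um = (length(xs) - 1) * scene$pixel_size_um,
                 parent = 1L),
            class = "vessel_segment")
}

# A field of parallel vessels with distinct diameters/velocities, one row
# per vessel; used for pipeline-level tests.
parallel_scene <- function(n_vessels, seed, len_px = 240, spacing = 50,
                           noise_sd = 0.02, jitter_amplitude_px = 1,
                           d_range = c(9, 30), v_range = c(0.2, 1.5)) {
  set.seed(seed)
  vlist <- lapply(seq_len(n_vessels), function(i) {
    vessel_spec(
      cbind(c(20, 20 + len_px), rep(40 + (i - 1) * spacing, 2)),
      diameter_um = runif(1, d_range[1], d_range[2]),
      velocity_mm_s = runif(1, v_range[1], v_range[2]),
      type = sample(c("arteriole", "venule"), 1)
    )
  })
  scene_spec(40 + len_px, 40 + spacing * n_vessels, vessels = vlist,
             noise_sd = noise_sd, jitter_amplitude_px = jitter_amplitude_px)
}

# Brute-force oracle for the longest consecutive valid run.
brute_longest_run <- function(valid) {
  best <- NULL
  best_len <- 0
  for (i in seq_along(valid)) {
    for (j in i:length(valid)) {
      if (all(valid[i:j])) {
        if (j - i + 1 > best_len) {
          best <- c(i, j)
          best_len <- j - i + 1
        }
      } else {
        break
      }
    }
  }
  best
}

# Detrend a raw STI matrix the same way build_sti does.
detrend_sti <- function(m) {
  m <- m - rowMeans(m)
  sweep(m, 2, colMeans(m))
}

# Wrap a bare matrix as an sti object (for estimator-only tests).
as_sti <- function(m, arc_step_um = 1.25, frame_interval_s = 0.02) {
  structure(list(values = m, arc_step_um = arc_step_um,
                 frame_interval_s = frame_interval_s),
            class = "sti")
}

# Synthetic STI with an exact injected band slope (px/frame).
synthetic_sti <- function(slope, ns = 150, nt = 50, corr_px = 5,
                          noise_sd = 0, seed = 1) {
  set.seed(seed)
  grid <- seq(-abs(slope) * nt - 4 * corr_px - 2,
              ns + abs(slope) * nt + 4 * corr_px + 2, by = 0.5)
  raw <- rnorm(length(grid))
  kern <- dnorm(seq(-4, 4, by = 0.5 / corr_px))
  tex <- stats::filter(raw, kern / sum(kern), sides = 2)
  tex[is.na(tex)] <- 0
  look <- function(s) {
    pos <- (s - grid[1]) / 0.5 + 1
    i0 <- pmin(pmax(floor(pos), 1), length(tex) - 1)
    f <- pos - i0
    tex[i0] * (1 - f) + tex[i0 + 1] * f
  }
  m <- outer(seq_len(ns), seq_len(nt) - 1, function(s, t) look(s - slope * t))
  if (noise_sd > 0) m <- m + rnorm(length(m), 0, noise_sd)
  detrend_sti(m)
}
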