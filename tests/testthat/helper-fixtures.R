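# Shared fixtures built in code: small stacks, rendered shapes, and an
# independent brute-force Otsu used as an oracle.

make_stack <- function(vox, z_step = 1.5, pixel_size = 1,
                       channel_names = NULL, bit_depth = 16L) {
  image_stack(vox, z_step = z_step, pixel_size = pixel_size,
              channel_names = channel_names, bit_depth = bit_depth)
}

# disk/ellipse rendered into a matrix (background 0, foreground `value`)
render_ellipse <- function(side, a, b, value = 200, bg = 0) {
  ctr <- (side + 1) / 2
  m <- matrix(bg, side, side)
  for (y in seq_len(side)) for (x in seq_len(side))
    if (((y - ctr) / a)^2 + ((x - ctr) / b)^2 <= 1) m[y, x] <- value
  m
}

render_ball <- function(dim_zyx, center, radius, value = 1, z_aspect = 1) {
  v <- array(0, dim_zyx)
  for (z in seq_len(dim_zyx[1])) for (y in seq_len(dim_zyx[2]))
    for (x in seq_len(dim_zyx[3])) {
      if (((z - center[1]) * z_aspect)^2 + (y - center[2])^2 +
          (x - center[3])^2 <= radius^2)
        v[z, y, x] <- value
    }
  v
}

# Brute-force Otsu: exhaustive threshold sweep maximising between-class
# variance -- the independent oracle for automatic-threshold behaviour.
brute_otsu <- function(x) {
  vals <- sort(unique(as.numeric(x)))
  best <- -Inf
  best_t <- vals[1]
  for (t in vals[-length(vals)]) {
    lo <- x[x <= t]
    hi <- x[x > t]
    w <- length(lo) * length(hi) / length(x)^2
    v <- w * (mean(hi) - mean(lo))^2
    if (v > best) {
      best <- v
      best_t <- t
    }
  }
  best_t
}

small_sim <- function(seed = 2, ...) {
  cfg <- simulation_config(diameter = 120, n_nuclei = 60, rim_thickness = 20,
                           margin = 8, seed = seed,
                           zcomp_slope = zcomp_slope_for(150),
                           attenuation_length = 150, ...)
  generate_spheroid(cfg)
}

small_params <- function(...) segmentation_params(seed_range_px = c(5, 13), ...)
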