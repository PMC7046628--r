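#' Configuration for the synthetic spheroid simulator
#'
#' Describes a spheroid of densely packed spherical nuclei (~300 um sample
#' diameter by default), a proliferation-marker channel confined to the
#' spheroid rim, and a cytoplasmic tracker channel filling the whole
#' spheroid.  Optics are modelled as channel-wise exponential attenuation of
#' signal with depth, an optional per-slice excitation gain ramp
#' (z-compensation), Gaussian PSF blur, and additive Gaussian background
#' noise.
#'
#' @param diameter spheroid diameter before fixation/clearing, micrometres.
#' @param nucleus_radius nuclear radius, micrometres.
#' @param n_nuclei number of nuclei to place.
#' @param rim_fraction fraction of rim nuclei that are marker-positive.
#' @param rim_thickness thickness of the proliferative rim, micrometres
#'   (measured inward from the pre-fixation surface).
#' @param attenuation_length per-channel attenuation length L (um) of the
#'   exponential intensity decay `exp(-depth / L)`; a scalar is recycled to
#'   all channels; `Inf` disables attenuation.
#' @param shrink_factor isotropic post/pre size ratio applied by the
#'   clearing protocol (1 = none, < 1 = shrinkage).
#' @param zcomp_slope per-slice fractional gain increase; slice `k` is
#'   excited with gain `(1 + zcomp_slope)^k` (`"compound"` mode) or
#'   `1 + zcomp_slope * k` (`"linear"`).  0 disables z-compensation.
#' @param zcomp_mode `"compound"` (default) or `"linear"`; see Details.
#' @param background_offset,background_sd mean and standard deviation of the
#'   additive Gaussian background, intensity units.
#' @param amplitude per-channel peak signal amplitude at depth 0.
#' @param psf_sigma Gaussian PSF sigmas `(z, y, x)` in micrometres; zeros
#'   disable blurring.
#' @param overlap_tolerance nucleus centres are kept at least
#'   `2 * nucleus_radius * overlap_tolerance` apart when sampled.
#' @param z_step,pixel_size,bit_depth stack calibration, as in
#'   [image_stack()].
#' @param margin clear margin around the spheroid, micrometres.
#' @param shot_noise if `TRUE`, Poisson shot noise is applied to the signal
#'   before background noise is added.
#' @param seed RNG seed; identical seeds give bit-identical stacks.
#' @param channel_names names of the three generated channels (nuclear dye,
#'   proliferation marker, cytoplasmic tracker).
#'
#' @details With `zcomp_mode = "compound"` the laser gain is raised by the
#' same fraction at every step, so choosing
#' `zcomp_slope = exp(z_step / L) - 1` (see [zcomp_slope_for()]) cancels the
#' exponential attenuation exactly and the expected in-nucleus intensity
#' becomes depth-constant.  The `"linear"` mode ramps the gain as
#' `1 + slope * k` and can only compensate shallow stacks approximately.
#'
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(diameter = 300, nucleus_radius = 4,
                              n_nuclei = 200, rim_fraction = 0.8,
                              rim_thickness = 40,
                              attenuation_length = 150,
                              shrink_factor = 1, zcomp_slope = 0,
                              zcomp_mode = c("compound", "linear"),
                              background_offset = 10, background_sd = 5,
                              amplitude = c(nuclei = 200, marker = 200,
                                            tracker = 120),
                              psf_sigma = c(z = 1.5, y = 0.7, x = 0.7),
                              overlap_tolerance = 0.9,
                              z_step = 1.5, pixel_size = 1, bit_depth = 16L,
                              margin = 8, shot_noise = FALSE, seed = NULL,
                              channel_names = c("nuclei", "marker",
                                                "tracker")) {
  zcomp_mode <- match.arg(zcomp_mode)
  nc <- length(channel_names)
  if (length(attenuation_length) == 1L)
    attenuation_length <- rep(attenuation_length, nc)
  if (length(amplitude) == 1L) amplitude <- rep(amplitude, nc)
  attenuation_length <- setNames(as.numeric(attenuation_length), channel_names)
  amplitude <- setNames(as.numeric(amplitude), channel_names)
  stopifnot(diameter > 0, nucleus_radius > 0, n_nuclei >= 0,
            rim_fraction >= 0, rim_fraction <= 1, rim_thickness >= 0,
            all(attenuation_length > 0),
            shrink_factor > 0, shrink_factor <= 2,
            background_sd >= 0, all(amplitude >= 0),
            length(psf_sigma) == 3L, all(psf_sigma >= 0),
            overlap_tolerance > 0, z_step > 0, pixel_size > 0, margin >= 0)
  structure(list(diameter = diameter, nucleus_radius = nucleus_radius,
                 n_nuclei = as.integer(n_nuclei),
                 rim_fraction = rim_fraction, rim_thickness = rim_thickness,
                 attenuation_length = attenuation_length,
                 shrink_factor = shrink_factor, zcomp_slope = zcomp_slope,
                 zcomp_mode = zcomp_mode,
                 background_offset = background_offset,
                 background_sd = background_sd, amplitude = amplitude,
                 psf_sigma = as.numeric(psf_sigma),
                 overlap_tolerance = overlap_tolerance,
                 z_step = z_step, pixel_size = pixel_size,
                 bit_depth = as.integer(bit_depth), margin = margin,
                 shot_noise = shot_noise, seed = seed,
                 channel_names = channel_names),
            class = "simulation_config")
}

#' Z-compensation slope that cancels a given attenuation length
#'
#' @param attenuation_length attenuation length L, micrometres.
#' @param z_step slice spacing, micrometres.
#' @return the per-slice fractional gain increase `exp(z_step / L) - 1`.
#' @export
zcomp_slope_for <- function(attenuation_length, z_step = 1.5)
  exp(z_step / attenuation_length) - 1

# Per-slice excitation gain for 0-based slice indices k.
zcomp_gain <- function(k, slope, mode = "compound") {
  if (slope == 0) return(rep(1, length(k)))
  if (mode == "compound") (1 + slope)^k else 1 + slope * k
}

# Rejection-sample nucleus centres inside a sphere of radius rmax with a
# minimum pairwise separation.  Returns an n x 3 matrix (z, y, x) in um
# relative to the sphere centre.
sample_centers <- function(n, rmax, min_sep, max_tries = 200L) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  pts <- matrix(NA_real_, n, 3)
  placed <- 0L
  tries <- 0L
  sep2 <- min_sep^2
  while (placed < n) {
    if (tries > max_tries * n)
      stop("could not place ", n, " nuclei with separation ", min_sep,
           " um inside radius ", rmax, " um")
    p <- runif(3, -rmax, rmax)
    tries <- tries + 1L
    if (sum(p^2) > rmax^2) next
    if (placed > 0L) {
      d2 <- colSums((t(pts[seq_len(placed), , drop = FALSE]) - p)^2)
      if (any(d2 < sep2)) next
    }
    placed <- placed + 1L
    pts[placed, ] <- p
  }
  colnames(pts) <- c("z", "y", "x")
  pts
}

#' Generate a synthetic spheroid stack with ground truth
#'
#' Nucleus centres are rejection-sampled inside the pre-fixation sphere,
#' scaled by `shrink_factor`, and rasterised as spheres (overlaps resolved
#' by nearest centre) to produce a ground-truth label volume.  Channel
#' signal is blurred by the PSF, attenuated per voxel as
#' `exp(-depth / L) * gain(z)`, and additive Gaussian background noise is
#' applied.  The marker channel is nonzero only in marker-positive nuclei;
#' the tracker channel fills the whole (shrunken) sphere.
#'
#' @param config a [simulation_config()].
#' @return a list with elements `stack` (an [image_stack()]) and `truth`
#'   (class `simulation_truth`: `centers` in um, stack coordinates;
#'   `positive_flags`; `label_volume` (z, y, x); `config`).
#' @export
generate_spheroid <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  r_nuc <- config$nucleus_radius
  r_pre <- config$diameter / 2
  s <- config$shrink_factor
  r_eff <- r_pre * s
  centers <- sample_centers(config$n_nuclei, max(r_pre - r_nuc, 0),
                            2 * r_nuc * config$overlap_tolerance)
  dist_pre <- sqrt(rowSums(centers^2))
  rim <- which(dist_pre >= r_pre - config$rim_thickness - r_nuc)
  n_pos <- round(config$rim_fraction * length(rim))
  positive <- logical(config$n_nuclei)
  if (n_pos > 0)
    positive[sample(rim, n_pos)] <- TRUE
  centers <- centers * s  # protocol-induced isotropic shrinkage/swelling

  px <- config$pixel_size
  dz <- config$z_step
  ext <- 2 * r_eff + 2 * config$margin
  ny <- nx <- as.integer(ceiling(ext / px))
  nz <- as.integer(ceiling(ext / dz)) + 1L
  cy <- cx <- ext / 2
  cz <- config$margin + r_eff
  # voxel-centre coordinates in um
  zc <- (seq_len(nz) - 1) * dz
  yc <- (seq_len(ny) - 0.5) * px
  xc <- (seq_len(nx) - 0.5) * px

  labels <- array(0L, c(nz, ny, nx))
  bestd2 <- array(Inf, c(nz, ny, nx))
  abs_centers <- sweep(centers, 2, c(cz, cy, cx), "+")
  for (i in seq_len(nrow(abs_centers))) {
    ctr <- abs_centers[i, ]
    zi <- which(abs(zc - ctr[1]) <= r_nuc)
    yi <- which(abs(yc - ctr[2]) <= r_nuc)
    xi <- which(abs(xc - ctr[3]) <= r_nuc)
    if (!length(zi) || !length(yi) || !length(xi)) next
    d2 <- outer(outer((zc[zi] - ctr[1])^2, (yc[yi] - ctr[2])^2, "+"),
                (xc[xi] - ctr[3])^2, "+")
    inside <- d2 <= r_nuc^2 & d2 < bestd2[zi, yi, xi]
    sub <- labels[zi, yi, xi]
    sub[inside] <- i
    labels[zi, yi, xi] <- sub
    subd <- bestd2[zi, yi, xi]
    subd[inside] <- d2[inside]
    bestd2[zi, yi, xi] <- subd
  }
  rm(bestd2)

  sphere <- outer(outer((zc - cz)^2, (yc - cy)^2, "+"), (xc - cx)^2, "+") <=
    r_eff^2

  depth_factor <- function(ch) {
    L <- config$attenuation_length[[ch]]
    exp(-zc / L) * zcomp_gain(seq_len(nz) - 1, config$zcomp_slope,
                              config$zcomp_mode)
  }
  base_signal <- list(
    nuclei = (labels > 0) * config$amplitude[[1]],
    marker = array(0, dim(labels)),
    tracker = sphere * config$amplitude[[3]]
  )
  if (any(positive)) {
    pos_ids <- which(positive)
    base_signal$marker[labels %in% pos_ids] <- config$amplitude[[2]]
  }
  maxv <- 2^config$bit_depth - 1
  vox <- array(0, c(3L, nz, ny, nx))
  for (ci in 1:3) {
    sig <- base_signal[[ci]]
    if (any(config$psf_sigma > 0))
      sig <- sc_gauss_blur3d(sig, dim(sig),
                             config$psf_sigma[1] / dz,
                             config$psf_sigma[2] / px,
                             config$psf_sigma[3] / px)
    f <- depth_factor(ci)
    sig <- sig * f[slice.index(sig, 1)]
    if (config$shot_noise) sig <- array(rpois(length(sig), sig), dim(sig))
    sig <- sig + config$background_offset
    if (config$background_sd > 0)
      sig <- sig + rnorm(length(sig), 0, config$background_sd)
    vox[ci, , , ] <- pmin(pmax(round(sig), 0), maxv)
  }
  stack <- image_stack(vox, z_step = dz, pixel_size = px,
                       channel_names = config$channel_names,
                       bit_depth = config$bit_depth)
  truth <- structure(list(centers = abs_centers, positive_flags = positive,
                          label_volume = labels, config = config),
                     class = "simulation_truth")
  list(stack = stack, truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("<simulation_truth> %d nuclei (%d marker-positive)\n",
              nrow(x$centers), sum(x$positive_flags)))
  invisible(x)
}

#' Generate a uniformly stained attenuation phantom
#'
#' A homogeneous dye slab: every voxel of slice `k` has expected intensity
#' `amplitude * exp(-k * z_step / L) * gain(k) + background_offset`.  Used
#' to calibrate and test depth-profile metrics against the analytic
#' attenuation law without any geometry in the way.
#'
#' @param attenuation_length L in micrometres (`Inf` for none).
#' @param n_slices,side_px stack size.
#' @param amplitude,background_offset,background_sd intensity model.
#' @param zcomp_slope,zcomp_mode as in [simulation_config()].
#' @param z_step,pixel_size,bit_depth calibration.
#' @param seed RNG seed (only relevant when `background_sd > 0`).
#' @return an [image_stack()] with one channel `"phantom"`.
#' @export
generate_uniform_phantom <- function(attenuation_length = 150,
                                     n_slices = 200, side_px = 32,
                                     amplitude = 200, background_offset = 0,
                                     background_sd = 0, zcomp_slope = 0,
                                     zcomp_mode = "compound",
                                     z_step = 1.5, pixel_size = 1,
                                     bit_depth = 16L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  zc <- (seq_len(n_slices) - 1) * z_step
  f <- amplitude * exp(-zc / attenuation_length) *
    zcomp_gain(seq_len(n_slices) - 1, zcomp_slope, zcomp_mode) +
    background_offset
  vox <- array(rep(f, times = side_px * side_px),
               c(1L, n_slices, side_px, side_px))
  if (background_sd > 0)
    vox <- vox + array(rnorm(length(vox), 0, background_sd), dim(vox))
  vox <- pmin(pmax(vox, 0), 2^bit_depth - 1)
  image_stack(vox, z_step = z_step, pixel_size = pixel_size,
              channel_names = "phantom", bit_depth = bit_depth)
}

#' Simulate a panel of clearing protocols on shared geometry
#'
#' All protocols reuse the base configuration's seed, so the underlying
#' nucleus placement is identical and differences between arms are
#' attributable to the protocol optics (shrinkage, attenuation, amplitude).
#'
#' @param base a [simulation_config()].
#' @param protocols a list; each element is a list with fields `name`,
#'   and optionally `shrink_factor`, `attenuation_length`,
#'   `amplitude_scale` (default 1) and `zcomp_slope`.
#' @return a named list (one element per protocol, in input order) of lists
#'   with elements `name`, `stack`, `truth`.
#' @export
generate_protocol_panel <- function(base, protocols) {
  stopifnot(inherits(base, "simulation_config"), length(protocols) >= 1)
  nms <- vapply(protocols, function(p) p$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate protocol names")
  out <- vector("list", length(protocols))
  for (i in seq_along(protocols)) {
    p <- protocols[[i]]
    cfg <- base
    if (!is.null(p$shrink_factor)) cfg$shrink_factor <- p$shrink_factor
    if (!is.null(p$attenuation_length))
      cfg$attenuation_length[] <- rep(p$attenuation_length,
                                      length.out = length(cfg$attenuation_length))
    if (!is.null(p$amplitude_scale))
      cfg$amplitude <- cfg$amplitude * p$amplitude_scale
    if (!is.null(p$zcomp_slope)) cfg$zcomp_slope <- p$zcomp_slope
    sim <- generate_spheroid(cfg)
    out[[i]] <- list(name = p$name, stack = sim$stack, truth = sim$truth)
  }
  names(out) <- nms
  out
}
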