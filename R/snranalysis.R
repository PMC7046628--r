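#' Background statistics from shallow optical sections
#'
#' Estimates the mean and standard deviation of the imaging background from
#' designated slices (by default the shallowest 10% of the stack, where
#' scatter has not yet contaminated dark regions).  Background voxels are
#' those below an automatic (Otsu) threshold within the designated slices;
#' the returned standard deviation is a single scalar reused for all slices
#' of the SNR profile.
#'
#' @param stack an [image_stack()].
#' @param channel channel name or index.
#' @param background_slices optional integer vector of 1-based slice
#'   indices to use; default the first `max(1, floor(0.1 * nz))` slices.
#' @param exclude optional logical (y, x) matrix marking pixels (e.g. a
#'   signal ROI) to exclude from the background mask.
#' @return a list with `mean`, `sd`, `threshold` and `n` (number of
#'   background voxels used).
#' @export
background_stats <- function(stack, channel, background_slices = NULL,
                             exclude = NULL) {
  vol <- get_channel(stack, channel)
  nz <- dim(vol)[1]
  if (is.null(background_slices))
    background_slices <- seq_len(max(1L, floor(0.1 * nz)))
  if (any(background_slices < 1L | background_slices > nz))
    stop("background_slices out of range")
  sub <- vol[background_slices, , , drop = FALSE]
  if (!is.null(exclude)) {
    drop <- aperm(array(exclude, c(dim(sub)[2:3], dim(sub)[1])), c(3, 1, 2))
    sub <- sub[!drop]
  }
  rng <- range(sub)
  if (rng[2] <= rng[1]) stop("degenerate background: zero variance")
  thr <- rng[1] + EBImage::otsu(matrix((sub - rng[1]) / (rng[2] - rng[1]),
                                       nrow = 1),
                                range = c(0, 1)) * (rng[2] - rng[1])
  bg <- sub[sub < thr]
  if (length(bg) < 2) stop("empty background mask in designated slices")
  s <- sd(bg)
  if (s == 0) stop("degenerate background: zero variance")
  list(mean = mean(bg), sd = s, threshold = thr, n = length(bg))
}

#' Automatic per-section signal mask
#'
#' Median-filters the section (radius 1) and thresholds it with Otsu's
#' between-class-variance criterion; the mask is everything above
#' threshold.  Degenerate (near-constant) sections yield an empty or full
#' mask, which downstream code flags as undefined SNR.
#'
#' @param slice_image a 2-D numeric matrix.
#' @return a logical matrix.
#' @export
signal_mask <- function(slice_image) {
  rng <- range(slice_image)
  if (rng[2] <= rng[1])
    return(matrix(FALSE, nrow(slice_image), ncol(slice_image)))
  # normalise by the section's own range: Otsu is scale-invariant, and this
  # keeps the 256-level histogram informative for dim deep sections
  x01 <- (slice_image - rng[1]) / (rng[2] - rng[1])
  mf <- EBImage::medianFilter(x01, size = 1)
  thr <- EBImage::otsu(mf, range = c(0, 1))
  mf > thr
}

#' Depth-resolved signal-to-noise ratio profile
#'
#' For every optical section, the mean intensity inside the automatic
#' nuclear signal mask (restricted to the central circular ROI) is divided
#' by the scalar background standard deviation from [background_stats()]:
#' `SNR = mu_signal / sigma_background`.  Sections whose signal mask is
#' empty get `NA` (undefined), not zero.
#'
#' @inheritParams z_profile
#' @param background_slices passed to [background_stats()].
#' @param rose_threshold detectability threshold used later by
#'   [rose_cutoff()]; the Rose criterion value 5 by default.
#' @return an object of class `snr_profile` with fields `channel`,
#'   `depths_um`, `normalized_depths_um`, `mu_signal`, `sigma_background`
#'   (scalar), `snr`, `rose_threshold`, `roi_center`, `roi_diameter_um`.
#' @export
snr_profile <- function(stack, channel, size_ratio = 1, roi_center = NULL,
                        roi_diameter_um = 100, background_slices = NULL,
                        rose_threshold = 5) {
  ci <- channel_index(stack, channel)
  vol <- get_channel(stack, ci)
  if (is.null(roi_center)) roi_center <- default_roi_center(stack, ci)
  disk <- roi_disk(dim(vol)[2:3], roi_center, roi_diameter_um,
                   stack$pixel_size)
  bg <- background_stats(stack, ci, background_slices = background_slices)
  yr <- range(disk[, 1])
  xr <- range(disk[, 2])
  # disk indices relative to the cropped bounding box
  disk_local <- cbind(disk[, 1] - yr[1] + 1L, disk[, 2] - xr[1] + 1L)
  nz <- dim(vol)[1]
  mu <- rep(NA_real_, nz)
  for (k in seq_len(nz)) {
    crop <- vol[k, yr[1]:yr[2], xr[1]:xr[2]]
    mask <- signal_mask(crop)
    sel <- mask[disk_local]
    if (any(sel)) mu[k] <- mean(crop[disk_local[sel, , drop = FALSE]])
  }
  depths <- slice_depths(stack)
  structure(list(channel = stack$channel_names[ci], depths_um = depths,
                 normalized_depths_um = normalize_depth(depths, size_ratio),
                 mu_signal = mu, sigma_background = bg$sd,
                 mean_intensity = mu,  # allows decay_depths() on SNR data
                 snr = mu / bg$sd, rose_threshold = rose_threshold,
                 roi_center = roi_center, roi_diameter_um = roi_diameter_um),
            class = "snr_profile")
}

#' @export
print.snr_profile <- function(x, ...) {
  cat(sprintf("<snr_profile> channel %s, %d slices, max SNR %.1f, sigma_bg %.2f\n",
              x$channel, length(x$snr), max(x$snr, na.rm = TRUE),
              x$sigma_background))
  invisible(x)
}

#' Depth up to which the Rose criterion holds
#'
#' Returns the largest normalized depth `d*` such that every defined
#' section between the SNR maximum and `d*` has `SNR > rose_threshold`
#' (strictly; the Rose criterion is SNR > 5).  As for [decay_depths()], the
#' qualifying run starts at the profile maximum so that dim sections above
#' the sample surface cannot end it spuriously; below the maximum, a single
#' section dropping to or below the threshold -- or with undefined SNR --
#' ends the run.  When the criterion holds through the last section the
#' result is censored and should be reported as "> max depth".
#'
#' @param profile an [snr_profile()].
#' @param smooth optional odd moving-average window applied to the SNR
#'   trace before evaluation; 0 (default) disables it.
#' @return an object of class `rose_cutoff` with fields `cutoff_um` and
#'   `censored`.
#' @export
rose_cutoff <- function(profile, smooth = 0) {
  snr <- profile$snr
  nd <- profile$normalized_depths_um
  if (!length(snr)) stop("empty profile")
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    sm <- as.numeric(stats::filter(snr, k, sides = 2))
    snr <- ifelse(is.na(sm), snr, sm)
  }
  pass <- !is.na(snr) & snr > profile$rose_threshold
  k0 <- which.max(ifelse(is.na(snr), -Inf, snr))
  tail_pass <- pass[k0:length(pass)]
  if (all(tail_pass))
    return(structure(list(cutoff_um = nd[length(nd)], censored = TRUE),
                     class = "rose_cutoff"))
  first_fail <- k0 - 1L + which(!tail_pass)[1]
  cutoff <- if (first_fail <= k0) 0 else nd[first_fail - 1]
  structure(list(cutoff_um = cutoff, censored = FALSE),
            class = "rose_cutoff")
}

#' @export
print.rose_cutoff <- function(x, ...) {
  cat(sprintf("<rose_cutoff> %s%.1f um\n", if (x$censored) "> " else "",
              x$cutoff_um))
  invisible(x)
}
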