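# Circular ROI bookkeeping shared by the depth-profile and SNR modules.
# Returns the (y, x) index pair matrix of pixels whose centres fall inside
# a disk of the given diameter (um) around `center` (1-based pixel coords).
roi_disk <- function(dim_yx, center, roi_diameter_um, pixel_size) {
  r_px <- roi_diameter_um / 2 / pixel_size
  cy <- center[1]
  cx <- center[2]
  if (cy - r_px < 0.5 || cy + r_px > dim_yx[1] + 0.5 ||
      cx - r_px < 0.5 || cx + r_px > dim_yx[2] + 0.5)
    stop("ROI (diameter ", roi_diameter_um, " um) does not fit inside the image")
  yi <- which(abs(seq_len(dim_yx[1]) - cy) <= r_px)
  xi <- which(abs(seq_len(dim_yx[2]) - cx) <= r_px)
  g <- expand.grid(y = yi, x = xi)
  keep <- (g$y - cy)^2 + (g$x - cx)^2 <= r_px^2
  g <- g[keep, , drop = FALSE]
  if (!nrow(g)) {  # degenerate sub-pixel ROI: fall back to the centre pixel
    g <- data.frame(y = round(cy), x = round(cx))
  }
  as.matrix(g)
}

# Default ROI centre: centroid of the Otsu mask of the max projection,
# falling back to the image centre when segmentation finds nothing.
default_roi_center <- function(stack, channel) {
  proj <- max_projection(stack, channel)
  ctr <- tryCatch({
    mask <- projection_mask(proj)
    colMeans(which(mask, arr.ind = TRUE))
  }, error = function(e) {
    warning("no foreground for ROI centring; using image centre")
    (dim(proj) + 1) / 2
  })
  as.numeric(ctr)
}

#' Depth-resolved mean-intensity profile in a central ROI
#'
#' Places one circular ROI (default diameter 100 um) in the central region
#' of the spheroid and records the mean intensity of the chosen channel in
#' that fixed ROI for every optical section -- a z-axis profile.
#'
#' @param stack an [image_stack()].
#' @param channel channel name or index.
#' @param roi_center optional (y, x) centre in pixels; defaults to the
#'   centroid of the max-projection mask.
#' @param roi_diameter_um ROI diameter in micrometres.
#' @param size_ratio post/pre size ratio used to attach normalized depths
#'   (see [normalize_depth()]).
#' @return an object of class `z_profile` with fields `channel`,
#'   `depths_um`, `normalized_depths_um`, `mean_intensity`, `roi_center`,
#'   `roi_diameter_um`.
#' @export
z_profile <- function(stack, channel, roi_center = NULL,
                      roi_diameter_um = 100, size_ratio = 1) {
  ci <- channel_index(stack, channel)
  vol <- get_channel(stack, ci)
  if (is.null(roi_center)) roi_center <- default_roi_center(stack, ci)
  disk <- roi_disk(dim(vol)[2:3], roi_center, roi_diameter_um,
                   stack$pixel_size)
  nz <- dim(vol)[1]
  prof <- vapply(seq_len(nz), function(k) {
    mean(vol[k, , ][disk])
  }, numeric(1))
  depths <- slice_depths(stack)
  structure(list(channel = stack$channel_names[ci], depths_um = depths,
                 normalized_depths_um = normalize_depth(depths, size_ratio),
                 mean_intensity = prof, roi_center = roi_center,
                 roi_diameter_um = roi_diameter_um),
            class = "z_profile")
}

#' @export
print.z_profile <- function(x, ...) {
  cat(sprintf("<z_profile> channel %s, %d slices, depth 0-%.0f um (norm. 0-%.0f)\n",
              x$channel, length(x$depths_um), max(x$depths_um),
              max(x$normalized_depths_um)))
  cat(sprintf("  max intensity %.1f at %.1f um\n",
              max(x$mean_intensity),
              x$normalized_depths_um[which.max(x$mean_intensity)]))
  invisible(x)
}

#' Signal-decay depths from a z-profile
#'
#' Finds the normalized depths at which the profile first drops to 50% and
#' 10% of its maximum (i.e. 50% and 90% signal loss).  The search starts at
#' the profile maximum, so a dim entry slice cannot trigger a spurious
#' crossing, and sub-slice depths are obtained by linear interpolation
#' between the bracketing sections.  Crossings never reached within the
#' stack are flagged as censored.
#'
#' @param profile a [z_profile()] (or [snr_profile()]; any object with
#'   `normalized_depths_um` and `mean_intensity`).
#' @param smooth optional odd moving-average window (slices) applied before
#'   the search; 0 disables smoothing (default).
#' @return an object of class `decay_metrics` with fields `max_intensity`,
#'   `d50_um`, `d90_um`, `censored_50`, `censored_90`.
#' @export
decay_depths <- function(profile, smooth = 0) {
  v <- profile$mean_intensity
  nd <- profile$normalized_depths_um
  if (length(v) < 2) stop("profile must have at least 2 slices")
  if (all(v == 0)) stop("all-zero profile")
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    v <- as.numeric(stats::filter(v, k, sides = 2))
    half <- (smooth - 1) / 2
    v[seq_len(half)] <- v[half + 1]
    v[(length(v) - half + 1):length(v)] <- v[length(v) - half]
  }
  m <- max(v)
  k0 <- which.max(v)
  cross <- function(level) {
    idx <- which(v <= level & seq_along(v) >= k0)
    if (!length(idx)) return(list(d = NA_real_, censored = TRUE))
    i <- idx[1]
    if (i == 1) return(list(d = nd[1], censored = FALSE))
    d <- nd[i - 1] + (nd[i] - nd[i - 1]) * (v[i - 1] - level) /
      (v[i - 1] - v[i])
    list(d = d, censored = FALSE)
  }
  c50 <- cross(0.5 * m)
  c90 <- cross(0.1 * m)
  structure(list(max_intensity = m, d50_um = c50$d, d90_um = c90$d,
                 censored_50 = c50$censored, censored_90 = c90$censored),
            class = "decay_metrics")
}

#' @export
print.decay_metrics <- function(x, ...) {
  fmt <- function(d, cens) if (cens) "not reached" else sprintf("%.1f um", d)
  cat(sprintf("<decay_metrics> max %.1f; 50%% loss at %s; 90%% loss at %s\n",
              x$max_intensity, fmt(x$d50_um, x$censored_50),
              fmt(x$d90_um, x$censored_90)))
  invisible(x)
}
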