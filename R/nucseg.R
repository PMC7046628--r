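#' Parameters for 3D nuclei segmentation
#'
#' Defaults follow the published parameterisation of the seeded-watershed
#' pipeline: median filter range 3 px, local threshold range 10 px, hole
#' filling range 1 px, and Laplacian-of-Gaussian seed detection with a seed
#' (blob diameter) range of 9-25 px.  The seed range should be matched to
#' the apparent nuclear diameter in pixels, which depends on the
#' acquisition pixel size.
#'
#' @param median_radius_px radius of the per-section median filter.
#' @param local_threshold_range_px radius of the adaptive-threshold
#'   neighbourhood.
#' @param hole_fill_range_px holes up to this radius are filled.
#' @param seed_range_px numeric length-2, min and max blob diameter in
#'   pixels for LoG seed detection.
#' @param n_scales number of LoG scales sampled log-uniformly across the
#'   seed range.
#' @param log_threshold minimum scale-normalised LoG response (on the
#'   0-1 intensity scale) for a seed.
#' @param threshold_offset offset of the adaptive threshold above the local
#'   mean, on the 0-1 intensity scale.
#' @param min_object_voxels objects smaller than this are removed.
#' @param relief `"intensity"` (inverted smoothed intensity, default) or
#'   `"distance"` (inverted Euclidean distance transform) watershed relief.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(median_radius_px = 3,
                                local_threshold_range_px = 10,
                                hole_fill_range_px = 1,
                                seed_range_px = c(9, 25),
                                n_scales = 5,
                                log_threshold = 0.3,
                                threshold_offset = 0.04,
                                min_object_voxels = 30,
                                relief = c("intensity", "distance")) {
  relief <- match.arg(relief)
  stopifnot(median_radius_px > 0, local_threshold_range_px > 0,
            hole_fill_range_px > 0, length(seed_range_px) == 2,
            seed_range_px[1] > 0, seed_range_px[1] < seed_range_px[2],
            n_scales >= 1, min_object_voxels >= 0)
  structure(list(median_radius_px = median_radius_px,
                 local_threshold_range_px = local_threshold_range_px,
                 hole_fill_range_px = hole_fill_range_px,
                 seed_range_px = seed_range_px, n_scales = n_scales,
                 log_threshold = log_threshold,
                 threshold_offset = threshold_offset,
                 min_object_voxels = min_object_voxels, relief = relief),
            class = "segmentation_params")
}

# Fill background holes (closed regions not touching the section border)
# of area <= (2 * range + 1)^2 in a binary section.
fill_small_holes <- function(mask, range_px) {
  inv <- !mask
  storage.mode(inv) <- "numeric"
  lab <- EBImage::bwlabel(inv)
  if (max(lab) == 0) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  fill_ids <- setdiff(which(sizes <= (2 * range_px + 1)^2), border)
  if (length(fill_ids)) mask[lab %in% fill_ids] <- TRUE
  mask
}

#' Pre-process a channel for segmentation
#'
#' Converts the channel to 8-bit (min-max scaling over the stack), applies
#' a per-section median filter, and computes a foreground mask by local
#' adaptive thresholding (threshold = local mean over the configured
#' neighbourhood plus an offset), with small holes filled.  Local
#' thresholding keeps deep, dimmer nuclei segmentable where a global
#' threshold would drop them.
#'
#' @param stack an [image_stack()].
#' @param channel channel name or index.
#' @param params a [segmentation_params()].
#' @return a list with `filtered` (3-D (z, y, x) array, values in 0-1) and
#'   `mask` (logical 3-D array).
#' @export
preprocess <- function(stack, channel, params = segmentation_params()) {
  vol <- get_channel(stack, channel)
  rng <- range(vol)
  v01 <- if (rng[2] > rng[1]) (vol - rng[1]) / (rng[2] - rng[1]) else vol * 0
  v01 <- round(v01 * 255) / 255  # 8-bit quantisation
  nz <- dim(v01)[1]
  filtered <- v01
  mask <- array(FALSE, dim(v01))
  w <- params$local_threshold_range_px
  for (k in seq_len(nz)) {
    sl <- EBImage::medianFilter(matrix(v01[k, , ], dim(v01)[2], dim(v01)[3]),
                                size = params$median_radius_px)
    filtered[k, , ] <- sl
    fg <- EBImage::thresh(sl, w = w, h = w,
                          offset = params$threshold_offset) > 0
    mask[k, , ] <- fill_small_holes(fg, params$hole_fill_range_px)
  }
  list(filtered = filtered, mask = mask)
}

#' Detect nucleus seeds by multi-scale Laplacian of Gaussian
#'
#' Blob detection with diameters spanning `seed_range_px`: for each scale
#' the volume is Gaussian-smoothed (sigma = diameter / (2 sqrt(3)), the
#' LoG optimum for a solid sphere; the z sigma is divided by the voxel
#' aspect ratio), the scale-normalised negative Laplacian is evaluated, and
#' local maxima of the cross-scale maximum response above `log_threshold`
#' are kept.  Non-maximum suppression removes seeds lying within the
#' detected radius of a stronger seed.
#'
#' @param filtered 3-D (z, y, x) intensity array in 0-1, e.g. from
#'   [preprocess()].
#' @param params a [segmentation_params()].
#' @param z_aspect voxel aspect ratio `z_step / pixel_size`.
#' @param mask optional logical array; seeds outside it are discarded.
#' @return a data frame with columns `z`, `y`, `x` (1-based voxel indices),
#'   `diameter_px` and `response`, ordered by decreasing response.
#' @export
detect_seeds <- function(filtered, params = segmentation_params(),
                         z_aspect = 1, mask = NULL) {
  d <- dim(filtered)
  diams <- exp(seq(log(params$seed_range_px[1]), log(params$seed_range_px[2]),
                   length.out = params$n_scales))
  best <- array(-Inf, d)
  best_scale <- array(0, d)
  for (dm in diams) {
    s_xy <- dm / (2 * sqrt(3))
    s_z <- s_xy / z_aspect
    b <- sc_gauss_blur3d(filtered, d, s_z, s_xy, s_xy)
    resp <- -s_xy^2 * sc_laplacian3d(b, d, z_aspect)
    sel <- resp > best
    best[sel] <- resp[sel]
    best_scale[sel] <- dm
  }
  idx <- sc_local_maxima3d(best, d, params$log_threshold)
  if (!length(idx))
    return(data.frame(z = integer(0), y = integer(0), x = integer(0),
                      diameter_px = numeric(0), response = numeric(0)))
  co <- arrayInd(idx, d)
  seeds <- data.frame(z = co[, 1], y = co[, 2], x = co[, 3],
                      diameter_px = best_scale[idx], response = best[idx])
  if (!is.null(mask)) seeds <- seeds[mask[idx], , drop = FALSE]
  seeds <- seeds[order(-seeds$response, seeds$z, seeds$y, seeds$x), ,
                 drop = FALSE]
  # greedy NMS: drop a seed whose centre lies within the radius of an
  # already accepted, stronger seed (z distance in lateral-pixel units)
  keep <- logical(nrow(seeds))
  acc_z <- acc_y <- acc_x <- acc_r <- numeric(0)
  for (i in seq_len(nrow(seeds))) {
    r_i <- seeds$diameter_px[i] / 2
    if (length(acc_z)) {
      d2 <- ((seeds$z[i] - acc_z) * z_aspect)^2 + (seeds$y[i] - acc_y)^2 +
        (seeds$x[i] - acc_x)^2
      if (any(d2 < pmax(acc_r, r_i)^2)) next
    }
    keep[i] <- TRUE
    acc_z <- c(acc_z, seeds$z[i])
    acc_y <- c(acc_y, seeds$y[i])
    acc_x <- c(acc_x, seeds$x[i])
    acc_r <- c(acc_r, r_i)
  }
  seeds <- seeds[keep, , drop = FALSE]
  rownames(seeds) <- NULL
  seeds
}

#' Seeded 3D watershed segmentation
#'
#' Floods a relief (inverted smoothed intensity by default, or an inverted
#' distance transform) from the seed points, restricted to the foreground
#' mask, with 26-connectivity.  Every mask voxel connected to a seed is
#' assigned to exactly one catchment; objects smaller than
#' `min_object_voxels` are removed and the remaining labels renumbered
#' contiguously.
#'
#' @param filtered 3-D intensity array (0-1) used for the relief and for
#'   per-object mean intensities.
#' @param mask logical foreground array.
#' @param seeds data frame with `z`, `y`, `x` columns (1-based), e.g. from
#'   [detect_seeds()]; seeds outside the mask are dropped with a warning.
#' @param params a [segmentation_params()].
#' @param z_aspect voxel aspect ratio, used by the distance-transform
#'   relief.
#' @return an object of class `label_volume`: `labels` (3-D integer array,
#'   0 = background), `n_objects`, `per_object` (data frame with centroid,
#'   voxel volume and mean intensity), and `removed_voxels` (mask voxels
#'   dropped by small-object removal or unreachable from any seed).
#' @export
watershed_3d <- function(filtered, mask, seeds,
                         params = segmentation_params(), z_aspect = 1) {
  d <- dim(filtered)
  if (!nrow(seeds)) stop("no seeds supplied")
  flat <- seeds$z + d[1] * (seeds$y - 1 + d[2] * (seeds$x - 1))
  inside <- mask[flat]
  if (any(!inside))
    warning(sum(!inside), " seed(s) outside the foreground mask dropped")
  seeds <- seeds[inside, , drop = FALSE]
  if (!nrow(seeds)) stop("no seeds inside the foreground mask")
  relief <- switch(params$relief,
                   intensity = max(filtered) - filtered,
                   distance = {
                     edt <- sc_edt3d(mask, d, z_aspect)
                     max(edt) - edt
                   })
  labels <- sc_seeded_watershed(relief, mask, d,
                                as.matrix(seeds[, c("z", "y", "x")]))
  sizes <- tabulate(labels[labels > 0], nbins = nrow(seeds))
  small <- which(sizes > 0 & sizes < params$min_object_voxels)
  if (length(small)) labels[labels %in% small] <- 0L
  old <- sort(unique(labels[labels > 0]))
  remap <- integer(nrow(seeds))
  remap[old] <- seq_along(old)
  labels[labels > 0] <- remap[labels[labels > 0]]
  n_obj <- length(old)
  per_object <- label_statistics(labels, filtered, n_obj)
  structure(list(labels = labels, n_objects = n_obj,
                 per_object = per_object,
                 removed_voxels = sum(mask) - sum(labels > 0),
                 params = params),
            class = "label_volume")
}

# Per-object centroids, voxel volumes and mean intensities.
label_statistics <- function(labels, intensity, n_obj) {
  if (n_obj == 0)
    return(data.frame(label = integer(0), z = numeric(0), y = numeric(0),
                      x = numeric(0), volume_voxels = integer(0),
                      mean_intensity = numeric(0)))
  pos <- which(labels > 0)
  lab <- labels[pos]
  co <- arrayInd(pos, dim(labels))
  vol <- tabulate(lab, nbins = n_obj)
  data.frame(label = seq_len(n_obj),
             z = rowsum(co[, 1], lab)[, 1] / vol,
             y = rowsum(co[, 2], lab)[, 1] / vol,
             x = rowsum(co[, 3], lab)[, 1] / vol,
             volume_voxels = vol,
             mean_intensity = rowsum(intensity[pos], lab)[, 1] / vol)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %d objects, %d labelled voxels (%d removed)\n",
              x$n_objects, sum(x$labels > 0), x$removed_voxels))
  invisible(x)
}

#' Run the full segmentation pipeline on one channel
#'
#' Convenience wrapper: [preprocess()], [detect_seeds()] (restricted to the
#' foreground mask), then [watershed_3d()].
#'
#' @inheritParams preprocess
#' @return a `label_volume`.
#' @export
segment_channel <- function(stack, channel, params = segmentation_params()) {
  z_aspect <- stack$z_step / stack$pixel_size
  pp <- preprocess(stack, channel, params)
  seeds <- detect_seeds(pp$filtered, params, z_aspect = z_aspect,
                        mask = pp$mask)
  if (!nrow(seeds))
    return(structure(list(labels = array(0L, dim(pp$filtered)),
                          n_objects = 0L,
                          per_object = label_statistics(array(0L, c(1, 1, 1)),
                                                        array(0, c(1, 1, 1)), 0L),
                          removed_voxels = sum(pp$mask), params = params),
                     class = "label_volume"))
  watershed_3d(pp$filtered, pp$mask, seeds, params, z_aspect = z_aspect)
}

#' Count total and marker-positive nuclei
#'
#' Segments the nuclear and the marker channel independently with the full
#' pipeline and reports the total nucleus count, the marker-positive count
#' and their ratio.  With `marker_mode = "intensity"` the marker channel is
#' not segmented; instead nuclear objects are classified positive when
#' their mean marker intensity exceeds an automatic (Otsu) threshold over
#' the per-object means.
#'
#' @param stack an [image_stack()].
#' @param nuclear_channel,marker_channel channel names or indices.
#' @param params segmentation parameters for the nuclear channel.
#' @param marker_params segmentation parameters for the marker channel
#'   (defaults to `params`).
#' @param marker_mode `"segment"` (default, as in the published pipeline)
#'   or `"intensity"`.
#' @return an object of class `count_result` with `n_total`, `n_positive`,
#'   `positive_fraction` (`NA` when `n_total` is 0) and the underlying
#'   `nuclear` / `marker` label volumes.
#' @export
count_nuclei <- function(stack, nuclear_channel, marker_channel,
                         params = segmentation_params(),
                         marker_params = params,
                         marker_mode = c("segment", "intensity")) {
  marker_mode <- match.arg(marker_mode)
  seg_n <- segment_channel(stack, nuclear_channel, params)
  seg_m <- NULL
  if (marker_mode == "segment") {
    seg_m <- segment_channel(stack, marker_channel, marker_params)
    n_pos <- seg_m$n_objects
  } else {
    mvol <- get_channel(stack, marker_channel)
    mvol <- mvol / max(mvol, 1)
    means <- label_statistics(seg_n$labels, mvol, seg_n$n_objects)$mean_intensity
    if (length(means) > 1) {
      thr <- EBImage::otsu(matrix(means, nrow = 1), range = c(0, 1))
      n_pos <- sum(means > thr)
    } else n_pos <- 0L
  }
  n_tot <- seg_n$n_objects
  structure(list(n_total = n_tot, n_positive = n_pos,
                 positive_fraction = if (n_tot > 0) n_pos / n_tot else NA_real_,
                 nuclear = seg_n, marker = seg_m),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("<count_result> %d nuclei, %d marker-positive (fraction %s)\n",
              x$n_total, x$n_positive,
              if (is.na(x$positive_fraction)) "undefined"
              else sprintf("%.3f", x$positive_fraction)))
  invisible(x)
}

#' Object-level segmentation accuracy against ground truth
#'
#' Matches predicted and ground-truth objects one-to-one, greedily by
#' descending intersection-over-union, accepting pairs with IoU at or above
#' the threshold, and reports precision, recall and F-score
#' (`F = 2PR / (P + R)`).
#'
#' @param result a `label_volume` or a 3-D integer label array.
#' @param truth a `simulation_truth`, `label_volume` or 3-D integer array
#'   of the same shape.
#' @param match_iou IoU acceptance threshold (default 0.5).
#' @return a list with `precision`, `recall`, `f_score`, `n_matched`,
#'   `n_result`, `n_truth` and a `matches` data frame (result label, truth
#'   label, IoU).
#' @export
evaluate_segmentation <- function(result, truth, match_iou = 0.5) {
  rl <- if (inherits(result, "label_volume")) result$labels else result
  tl <- if (inherits(truth, "simulation_truth")) truth$label_volume
        else if (inherits(truth, "label_volume")) truth$labels else truth
  if (!identical(dim(rl), dim(tl)))
    stop("result and truth volumes have different shapes")
  pairs <- overlap_iou(rl, tl)
  n_r <- max(0L, max(rl))
  n_t <- max(0L, max(tl))
  matched_r <- logical(n_r)
  matched_t <- logical(n_t)
  matches <- pairs[pairs$iou >= match_iou, , drop = FALSE]
  matches <- matches[order(-matches$iou), , drop = FALSE]
  keep <- logical(nrow(matches))
  for (i in seq_len(nrow(matches))) {
    r <- matches$result[i]
    t <- matches$truth[i]
    if (!matched_r[r] && !matched_t[t]) {
      matched_r[r] <- matched_t[t] <- TRUE
      keep[i] <- TRUE
    }
  }
  matches <- matches[keep, , drop = FALSE]
  nm <- nrow(matches)
  p <- if (n_r > 0) nm / n_r else NA_real_
  r <- if (n_t > 0) nm / n_t else NA_real_
  f <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f_score = f, n_matched = nm,
       n_result = n_r, n_truth = n_t, matches = matches)
}

# Sparse pairwise IoU between two label volumes.
overlap_iou <- function(rl, tl) {
  n_t <- max(0L, max(tl))
  sel <- rl > 0 & tl > 0
  if (!any(sel))
    return(data.frame(result = integer(0), truth = integer(0),
                      iou = numeric(0)))
  key <- (as.numeric(rl[sel]) - 1) * n_t + as.numeric(tl[sel])
  cnt <- table(key)
  keys <- as.numeric(names(cnt))
  r_id <- as.integer((keys - 1) %/% n_t) + 1L
  t_id <- as.integer((keys - 1) %% n_t) + 1L
  inter <- as.integer(cnt)
  vol_r <- tabulate(rl[rl > 0], nbins = max(rl))
  vol_t <- tabulate(tl[tl > 0], nbins = n_t)
  data.frame(result = r_id, truth = t_id,
             iou = inter / (vol_r[r_id] + vol_t[t_id] - inter))
}

#' Segmentation recall stratified by depth
#'
#' Bins ground-truth objects by the depth of their centroid and reports the
#' recall (fraction matched at the IoU threshold) per bin -- the metric
#' behind the observation that z-compensation rescues segmentation in deep
#' spheroid layers.
#'
#' @inheritParams evaluate_segmentation
#' @param z_step slice spacing (um), for reporting bin depths.
#' @param n_bins number of equal-depth bins (default 3: shallow, middle,
#'   deep thirds).
#' @return a data frame with `bin`, `depth_min_um`, `depth_max_um`,
#'   `n_truth`, `n_matched`, `recall`.
#' @export
recall_by_depth <- function(result, truth, match_iou = 0.5, z_step = 1.5,
                            n_bins = 3) {
  tl <- if (inherits(truth, "simulation_truth")) truth$label_volume
        else if (inherits(truth, "label_volume")) truth$labels else truth
  ev <- evaluate_segmentation(result, truth, match_iou)
  n_t <- ev$n_truth
  stats_t <- label_statistics(tl, array(0, dim(tl)), n_t)
  depth <- (stats_t$z - 1) * z_step
  br <- seq(min(depth), max(depth), length.out = n_bins + 1)
  bin <- pmin(findInterval(depth, br, rightmost.closed = TRUE), n_bins)
  matched <- stats_t$label %in% ev$matches$truth
  out <- data.frame(bin = seq_len(n_bins),
                    depth_min_um = br[-length(br)], depth_max_um = br[-1])
  out$n_truth <- tabulate(bin, n_bins)
  out$n_matched <- vapply(seq_len(n_bins),
                          function(b) sum(matched[bin == b]), integer(1))
  out$recall <- ifelse(out$n_truth > 0, out$n_matched / out$n_truth, NA)
  out
}
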