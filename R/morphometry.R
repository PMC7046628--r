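#' Maximum intensity projection of one channel
#'
#' @param stack an [image_stack()].
#' @param channel channel name or index.
#' @return a (y, x) matrix, the per-pixel maximum over z, with the pixel
#'   size attached as attribute `pixel_size`.
#' @export
max_projection <- function(stack, channel) {
  vol <- get_channel(stack, channel)
  proj <- apply(vol, c(2, 3), max)
  attr(proj, "pixel_size") <- stack$pixel_size
  proj
}

# Otsu mask of a projection: automatic global threshold, largest connected
# component, holes filled.  Returns a logical matrix or errors when nothing
# is above threshold.
projection_mask <- function(projection) {
  rng <- range(projection)
  if (rng[2] <= rng[1]) stop("no foreground: projection is constant")
  x01 <- (projection - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(x01, range = c(0, 1))
  mask <- x01 > thr
  if (!any(mask)) stop("no foreground after thresholding")
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- lab == keep
  storage.mode(mask) <- "numeric"
  EBImage::fillHull(mask) > 0
}

#' Measure the spheroid diameter on a maximum projection
#'
#' The projection is segmented by automatic (Otsu) global thresholding,
#' reduced to its largest connected component with holes filled, and the
#' diameter is the mean of the mask's maximal extents along the two
#' principal (perpendicular) axes through its centroid -- the automated
#' analogue of measuring the sample twice at perpendicular angles with a
#' line tool.
#'
#' @param projection a (y, x) matrix, e.g. from [max_projection()].
#' @param pixel_size lateral pixel size in micrometres; defaults to the
#'   `pixel_size` attribute of `projection` when present.
#' @return diameter in micrometres.
#' @export
measure_diameter <- function(projection, pixel_size = NULL) {
  pixel_size <- pixel_size %||% attr(projection, "pixel_size")
  if (is.null(pixel_size)) stop("pixel_size is required")
  mask <- projection_mask(projection)
  pts <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  ev <- eigen(stats::cov(cen), symmetric = TRUE)$vectors
  ext <- vapply(1:2, function(i) {
    pr <- cen %*% ev[, i]
    diff(range(pr)) + 1  # + 1 px: extents count both boundary pixels
  }, numeric(1))
  mean(ext) * pixel_size
}

#' Relative spheroid size change between two states
#'
#' @param pre reference (e.g. pre-fixation) diameter, micrometres.
#' @param post measured diameter after treatment, micrometres.
#' @return an object of class `spheroid_measurement` with fields
#'   `diameter_um`, `pre_fixation_diameter_um`, `size_ratio` (post/pre) and
#'   `rel_change_pct` (`100 * (size_ratio - 1)`; negative means shrinkage).
#' @examples
#' relative_change(300, 165.6)  # -44.8 % shrinkage
#' @export
relative_change <- function(pre, post) {
  if (!is.numeric(pre) || pre <= 0) stop("reference diameter must be > 0")
  if (!is.numeric(post) || post <= 0) stop("measured diameter must be > 0")
  ratio <- post / pre
  structure(list(diameter_um = post, pre_fixation_diameter_um = pre,
                 size_ratio = ratio, rel_change_pct = 100 * (ratio - 1)),
            class = "spheroid_measurement")
}

#' @export
print.spheroid_measurement <- function(x, ...) {
  cat(sprintf("<spheroid_measurement> %.1f um (reference %.1f um): %+.1f%%\n",
              x$diameter_um, x$pre_fixation_diameter_um, x$rel_change_pct))
  invisible(x)
}

#' Map a measured imaging depth back to the pre-fixation scale
#'
#' Protocols that shrink or swell the sample change how much original
#' tissue a given physical depth corresponds to.  Dividing depth by the
#' post/pre size ratio expresses all depths on the common pre-fixation
#' scale, so a strongly shrunken sample's normalized depth range can exceed
#' its physical stack depth.
#'
#' @param depth physical depth(s), micrometres.
#' @param size_ratio post/pre diameter ratio (from [relative_change()]).
#' @return normalized depth(s), micrometres.
#' @export
normalize_depth <- function(depth, size_ratio) {
  if (!is.numeric(size_ratio) || size_ratio <= 0)
    stop("size_ratio must be > 0")
  depth / size_ratio
}
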