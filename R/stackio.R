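#' Calibrated multi-channel 3D image stack
#'
#' An `image_stack` holds a 4-D voxel array ordered (channel, z, y, x)
#' together with its physical calibration.  Depth is measured from the first
#' acquired optical section: slice `k` (0-based) lies at depth `k * z_step`
#' micrometres, so index 0 is the shallowest (brightest) plane of a
#' top-illuminated sample.
#'
#' @param voxels numeric array of intensities.  A 2-D matrix is promoted to
#'   a single-channel single-slice stack, a 3-D array `(z, y, x)` to a
#'   single-channel stack, and a 4-D array is taken as `(channel, z, y, x)`.
#' @param z_step axial distance between optical sections, micrometres.
#' @param pixel_size lateral pixel edge length, micrometres.
#' @param channel_names character vector naming the channels, e.g.
#'   `c("DAPI", "DRAQ5", "KI67")`.
#' @param bit_depth integer, 8 or 16.
#' @return an object of class `image_stack`.
#' @examples
#' s <- image_stack(array(0, c(1, 4, 16, 16)), z_step = 1.5, pixel_size = 0.6)
#' n_slices(s)
#' @export
image_stack <- function(voxels, z_step, pixel_size,
                        channel_names = NULL, bit_depth = 16L) {
  voxels <- promote_axes(voxels)
  nc <- dim(voxels)[1]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  stopifnot(is.numeric(z_step), length(z_step) == 1L, z_step > 0,
            is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (length(channel_names) != nc)
    stop("channel_names length (", length(channel_names),
         ") does not match channel dimension (", nc, ")")
  if (any(voxels < 0)) stop("intensities must be non-negative")
  if (max(voxels) > 2^bit_depth - 1)
    stop("intensities exceed the ", bit_depth, "-bit range")
  structure(list(voxels = voxels, z_step = z_step, pixel_size = pixel_size,
                 channel_names = channel_names, bit_depth = as.integer(bit_depth)),
            class = "image_stack")
}

# Promote 2-D/3-D arrays to the canonical (channel, z, y, x) order.
# Idempotent: a 4-D array is returned unchanged.
promote_axes <- function(voxels) {
  d <- dim(voxels)
  if (is.null(d)) stop("voxels must be an array")
  if (length(d) == 2L) dim(voxels) <- c(1L, 1L, d)
  else if (length(d) == 3L) dim(voxels) <- c(1L, d)
  else if (length(d) != 4L) stop("voxels must have 2 to 4 dimensions")
  voxels
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d channel(s) x %d slice(s) x %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  z_step %.3g um, pixel %.3g um, %d-bit\n",
              x$z_step, x$pixel_size, x$bit_depth))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname image_stack
#' @param stack an `image_stack`.
#' @export
n_channels <- function(stack) dim(stack$voxels)[1]

#' @rdname image_stack
#' @export
n_slices <- function(stack) dim(stack$voxels)[2]

#' Physical depth of every optical section
#'
#' @param stack an `image_stack`.
#' @return numeric vector, depth in micrometres of slices `0 .. nz-1`.
#' @export
slice_depths <- function(stack) (seq_len(n_slices(stack)) - 1) * stack$z_step

# Resolve a channel given by name or index; errors on unknown channels.
channel_index <- function(stack, channel) {
  if (is.numeric(channel)) {
    ci <- as.integer(channel)
    if (ci < 1L || ci > n_channels(stack)) stop("channel index out of range: ", channel)
    return(ci)
  }
  ci <- match(channel, stack$channel_names)
  if (is.na(ci))
    stop("unknown channel '", channel, "'; available: ",
         paste(stack$channel_names, collapse = ", "))
  ci
}

#' Extract one channel as a 3-D (z, y, x) array
#'
#' @param stack an `image_stack`.
#' @param channel channel name or index.
#' @export
get_channel <- function(stack, channel) {
  ci <- channel_index(stack, channel)
  d <- dim(stack$voxels)
  out <- stack$voxels[ci, , , , drop = FALSE]
  dim(out) <- d[2:4]
  out
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Write a calibrated stack as multi-page TIFF
#'
#' Pages are written channel-major (all z of channel 1, then channel 2, ...).
#' Because the TIFF writer available here cannot set the ImageDescription
#' tag, calibration and layout travel in a small YAML sidecar
#' (`<path>.meta.yaml`) that [read_stack()] picks up automatically.
#'
#' @param stack an `image_stack`.
#' @param path output file path; the parent directory must exist.
#' @return invisibly, `path`.
#' @export
write_stack <- function(stack, path) {
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  d <- dim(stack$voxels)
  maxv <- 2^stack$bit_depth - 1
  pages <- vector("list", d[1] * d[2])
  p <- 1L
  for (ci in seq_len(d[1])) for (zi in seq_len(d[2])) {
    pages[[p]] <- matrix(stack$voxels[ci, zi, , ] / maxv, d[3], d[4])
    p <- p + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "deflate")
  yaml::write_yaml(list(z_step = stack$z_step, pixel_size = stack$pixel_size,
                        channel_names = as.list(stack$channel_names),
                        bit_depth = stack$bit_depth,
                        n_channels = d[1], n_slices = d[2],
                        page_order = "CZ"),
                   sidecar_path(path))
  invisible(path)
}

# Parse calibration/layout from an OME-XML ImageDescription, if present.
parse_ome <- function(desc) {
  if (is.null(desc) || !grepl("<OME", desc, fixed = TRUE)) return(NULL)
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  px <- xml2::xml_find_first(doc, ".//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(NULL)
  at <- function(a) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) NULL else v
  }
  chn <- xml2::xml_find_all(doc, ".//*[local-name()='Channel']")
  nms <- xml2::xml_attr(chn, "Name")
  list(size_c = as.integer(at("SizeC") %||% 1L),
       size_z = as.integer(at("SizeZ") %||% 1L),
       dimension_order = at("DimensionOrder") %||% "XYZCT",
       pixel_size = as.numeric(at("PhysicalSizeX") %||% NA),
       z_step = as.numeric(at("PhysicalSizeZ") %||% NA),
       channel_names = if (length(nms) && !all(is.na(nms))) nms else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a TIFF / OME-TIFF stack
#'
#' Calibration and channel layout are taken, in order of precedence, from a
#' YAML sidecar written by [write_stack()], from OME-XML metadata embedded in
#' the file, and finally from the `z_step`/`pixel_size` arguments.  File
#' metadata always wins over arguments.  Plain multi-page TIFFs without
#' layout metadata are read as a single-channel z-stack (with a warning);
#' a single 2-D plane becomes a stack of shape (1, 1, y, x).
#'
#' @param path TIFF file.
#' @param z_step,pixel_size fallback calibration in micrometres, used only
#'   when the file carries none.
#' @param channel_names optional channel names overriding generic labels
#'   (never the sidecar/OME names).
#' @return an `image_stack`.
#' @export
read_stack <- function(path, z_step = NULL, pixel_size = NULL,
                       channel_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!length(pages)) stop("no image planes in ", path)
  bits <- attr(pages[[1]], "bits.per.sample") %||% 16L
  meta <- NULL
  order_cz <- TRUE  # channel-major pages
  nc <- 1L
  nz <- length(pages)
  nms <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- yaml::read_yaml(sidecar_path(path))
    nc <- meta$n_channels
    nz <- meta$n_slices
    nms <- unlist(meta$channel_names)
    order_cz <- identical(meta$page_order %||% "CZ", "CZ")
    z_step <- meta$z_step
    pixel_size <- meta$pixel_size
    bits <- meta$bit_depth %||% bits
  } else {
    ome <- parse_ome(attr(pages[[1]], "description"))
    if (!is.null(ome)) {
      nc <- ome$size_c
      nz <- ome$size_z
      nms <- ome$channel_names
      # OME DimensionOrder gives the fastest-varying plane axis first
      # (after XY): XYZCT => z fastest (channel-major pages), XYCZT =>
      # channel fastest.
      order_cz <- !startsWith(sub("^XY", "", ome$dimension_order), "C")
      if (!is.na(ome$z_step)) z_step <- ome$z_step
      if (!is.na(ome$pixel_size)) pixel_size <- ome$pixel_size
    } else if (length(pages) > 1L) {
      warning("no channel metadata in ", basename(path),
              "; reading ", length(pages), " pages as one-channel z-stack")
    }
  }
  if (is.null(z_step) || is.null(pixel_size) ||
      is.na(z_step) || is.na(pixel_size))
    stop("no calibration available for ", path,
         ": supply z_step and pixel_size")
  if (nc * nz != length(pages))
    stop("metadata claims ", nc, " x ", nz, " planes but file has ",
         length(pages))
  d_yx <- dim(pages[[1]])
  vox <- array(0, c(nc, nz, d_yx[1], d_yx[2]))
  for (p in seq_along(pages)) {
    if (order_cz) {  # page index p-1 = (c-1)*nz + (z-1)
      ci <- (p - 1L) %/% nz + 1L
      zi <- (p - 1L) %% nz + 1L
    } else {         # channel fastest
      ci <- (p - 1L) %% nc + 1L
      zi <- (p - 1L) %/% nc + 1L
    }
    vox[ci, zi, , ] <- pages[[p]]
  }
  image_stack(vox, z_step = z_step, pixel_size = pixel_size,
              channel_names = nms %||% channel_names,
              bit_depth = if (bits > 8) 16L else 8L)
}

metric_vocabulary <- c("diameter_um", "rel_change_pct", "d50_um", "d90_um",
                       "rose_cutoff_um", "n_nuclei", "n_positive",
                       "positive_fraction", "max_snr")

#' Tabular per-sample results
#'
#' A `result_table` is a data frame with one row per
#' (sample, channel, metric) combination.  `metric_name` is restricted to a
#' fixed vocabulary so that downstream aggregation cannot silently mix
#' incompatible quantities.
#'
#' @param sample_id,protocol,channel,metric_name,value,units vectors of
#'   equal length (recycled by `data.frame`).
#' @return a data frame of class `result_table`.
#' @export
result_table <- function(sample_id, protocol, channel, metric_name, value,
                         units) {
  df <- data.frame(sample_id = as.character(sample_id),
                   protocol = as.character(protocol),
                   channel = as.character(channel),
                   metric_name = as.character(metric_name),
                   value = as.numeric(value),
                   units = as.character(units),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$metric_name), metric_vocabulary)
  if (length(bad))
    stop("unknown metric_name(s): ", paste(bad, collapse = ", "))
  key <- paste(df$sample_id, df$channel, df$metric_name, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (sample_id, channel, metric_name) rows")
  class(df) <- c("result_table", "data.frame")
  df
}

#' Write / read a result table as CSV
#'
#' @param table a `result_table`.
#' @param path CSV file path.
#' @export
write_results <- function(table, path) {
  if (!nrow(table)) stop("result table is empty")
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  result_table(df$sample_id, df$protocol, df$channel, df$metric_name,
               df$value, df$units)
}
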