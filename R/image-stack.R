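#' Multi-channel 3D image stack
#'
#' Container for confocal-style image data: one or more channels stored as
#' numeric arrays in `(z, y, x)` order together with the physical voxel
#' dimensions. The default voxel sizes (0.07 um in xy, 0.25 um in z) match
#' high-resolution confocal acquisition of whole-mount fly brains.
#'
#' Physical coordinates are voxel-center based: the voxel with 1-based index
#' `i` along an axis with voxel size `v` spans `[(i-1)v, iv)` um and its
#' reported position is `(i - 0.5) v` um. Mapping a position back with
#' [um_to_voxel()] therefore recovers the source voxel exactly.
#'
#' @param channels named list of numeric arrays, all with identical
#'   `(z, y, x)` dimensions.
#' @param voxel_xy,voxel_z voxel edge lengths in micrometres.
#' @return An object of class `ImageStack` with elements `channels`,
#'   `voxel_xy`, `voxel_z` and `dim` (the common `(z, y, x)` array dimension).
#' @export
image_stack <- function(channels, voxel_xy = 0.07, voxel_z = 0.25) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)))
    stop_axonloc("'channels' must be a non-empty named list of arrays")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop_axonloc("every channel must be a 3D (z, y, x) array")
  if (length(unique(dims)) != 1L)
    stop_axonloc("all channels must share the same dimensions")
  check_number(voxel_xy, "voxel_xy", min = 0, strict_min = TRUE)
  check_number(voxel_z, "voxel_z", min = 0, strict_min = TRUE)
  structure(list(channels = channels, voxel_xy = voxel_xy, voxel_z = voxel_z,
                 dim = dims[[1L]]),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  cat(sprintf("ImageStack: %d x %d x %d voxels (z, y, x), %.3g x %.3g um\n",
              x$dim[1L], x$dim[2L], x$dim[3L], x$voxel_xy, x$voxel_z))
  cat("channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

get_channel <- function(stack, channel) {
  if (!inherits(stack, "ImageStack")) stop_axonloc("not an ImageStack")
  if (!channel %in% names(stack$channels))
    stop_axonloc(sprintf("channel '%s' not present (have: %s)", channel,
                         paste(names(stack$channels), collapse = ", ")))
  stack$channels[[channel]]
}

#' Convert physical positions to voxel indices
#'
#' @param pos_um numeric vector of positions along one axis, in micrometres.
#' @param voxel voxel size along that axis (um).
#' @param n number of voxels along that axis (positions are clamped inside).
#' @return 1-based integer voxel indices.
#' @export
um_to_voxel <- function(pos_um, voxel, n) {
  pmin(pmax(as.integer(floor(pos_um / voxel)) + 1L, 1L), as.integer(n))
}

#' @rdname um_to_voxel
#' @param idx 1-based voxel indices.
#' @return `voxel_to_um`: voxel-center positions in micrometres.
#' @export
voxel_to_um <- function(idx, voxel) (idx - 0.5) * voxel

#' Write and read image stacks as multi-page TIFF
#'
#' Each channel is written as its own multi-page 32-bit float TIFF (one page
#' per z slice) named `<prefix>_<channel>.tif`. TIFF float samples live in
#' `[0, 1]`, so intensities are min-max scaled on write and the original
#' channel ranges are recorded in a `<prefix>_scale.tsv` sidecar that
#' `read_stack_tiff` uses to restore physical intensities.
#'
#' @param stack an [image_stack()] object.
#' @param prefix path prefix for the output files.
#' @return `write_stack_tiff`: invisibly, the written TIFF paths.
#' @export
write_stack_tiff <- function(stack, prefix) {
  paths <- character(0)
  scales <- data.frame(channel = character(0), min = numeric(0), max = numeric(0))
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]]
    rng <- range(arr)
    scaled <- if (diff(rng) > 0) (arr - rng[1L]) / diff(rng) else arr * 0
    pages <- lapply(seq_len(dim(arr)[1L]), function(z) scaled[z, , ])
    path <- paste0(prefix, "_", ch, ".tif")
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    paths <- c(paths, path)
    scales <- rbind(scales, data.frame(channel = ch, min = rng[1L], max = rng[2L]))
  }
  utils::write.table(scales, paste0(prefix, "_scale.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' @rdname write_stack_tiff
#' @param prefix path prefix used when writing.
#' @param channels channel names to read (default: all listed in the
#'   sidecar).
#' @param voxel_xy,voxel_z voxel sizes in micrometres.
#' @return `read_stack_tiff`: an [image_stack()].
#' @export
read_stack_tiff <- function(prefix, channels = NULL, voxel_xy = 0.07,
                            voxel_z = 0.25) {
  scales <- utils::read.table(paste0(prefix, "_scale.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  if (is.null(channels)) channels <- scales$channel
  out <- lapply(channels, function(ch) {
    pages <- tiff::readTIFF(paste0(prefix, "_", ch, ".tif"), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(length(pages), dim(pages[[1L]])))
    for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
    rng <- unlist(scales[scales$channel == ch, c("min", "max")])
    arr * (rng[2L] - rng[1L]) + rng[1L]
  })
  names(out) <- channels
  image_stack(out, voxel_xy = voxel_xy, voxel_z = voxel_z)
}
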