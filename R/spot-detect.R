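#' Detection parameters for smFISH spots
#'
#' Defaults follow the quantification settings used for whole-mount brain
#' smFISH: spots with an estimated xy diameter of 0.4 um and a PSF elongation
#' along z of 0.8 um, a minimum connected-component size of 4 pixels for 2D
#' cell-body crops, a normalized detection threshold of 0.62 (probe-specific
#' alternatives in use were 0.42, 0.32 and 0.82), and contrast rescaling that
#' saturates 0.01% of pixels. Diameters are treated as full widths at half
#' maximum, so the filter sigma per axis is `diameter / (2 sqrt(2 log 2))`
#' (about `diameter / 2.355`), converted to voxels with the stack's voxel
#' sizes.
#'
#' @param xy_diameter,z_elongation spot extent in micrometres.
#' @param response_threshold detection threshold as a fraction of the
#'   maximum normalized filter response, in (0, 1).
#' @param min_component_px minimum connected-component size (2D detection).
#' @param saturation_fraction fraction of pixels saturated by
#'   [rescale_contrast()].
#' @return A `DetectionParams` list.
#' @export
detection_params <- function(xy_diameter = 0.4, z_elongation = 0.8,
                             response_threshold = 0.62, min_component_px = 4L,
                             saturation_fraction = 1e-4) {
  check_number(xy_diameter, "xy_diameter", min = 0, strict_min = TRUE)
  check_number(z_elongation, "z_elongation", min = 0, strict_min = TRUE)
  check_number(response_threshold, "response_threshold", min = 0, max = 1,
               strict_min = TRUE)
  if (response_threshold >= 1)
    stop_axonloc("'response_threshold' must be in (0, 1)")
  check_number(min_component_px, "min_component_px", min = 1)
  check_number(saturation_fraction, "saturation_fraction", min = 0, max = 1)
  structure(list(xy_diameter = xy_diameter, z_elongation = z_elongation,
                 response_threshold = response_threshold,
                 min_component_px = as.integer(min_component_px),
                 saturation_fraction = saturation_fraction),
            class = "DetectionParams")
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Rescale image contrast with a fixed saturated-pixel fraction
#'
#' Linearly maps intensities from `[min, q]` to `[0, 1]`, where `q` is the
#' `1 - saturation_fraction` quantile (type-1, i.e. an order statistic) of
#' the pixel values; values above `q` are clipped to 1. On an image whose
#' values are all distinct, the fraction of clipped (saturated) pixels
#' equals `saturation_fraction` to within one pixel.
#'
#' @param image numeric matrix or array of intensities.
#' @param saturation_fraction fraction of pixels to saturate (default
#'   1e-4, i.e. 0.01%).
#' @return The rescaled image, same shape, minimum 0 and maximum at most 1.
#'   A constant image is returned unchanged with a warning.
#' @export
rescale_contrast <- function(image, saturation_fraction = 1e-4) {
  check_number(saturation_fraction, "saturation_fraction", min = 0, max = 1)
  if (length(image) == 0L) stop_axonloc("empty image")
  lo <- min(image)
  q <- stats::quantile(image, 1 - saturation_fraction, type = 1L, names = FALSE)
  if (q == lo) {
    warning("constant image: contrast left unchanged")
    return(image)
  }
  out <- (pmin(image, q) - lo) / (q - lo)
  if (!is.null(dim(image))) dim(out) <- dim(image)
  out
}

#' Detect smFISH spots in a 2D crop
#'
#' Small-particle detection for single-z-slice cell-body crops: a
#' scale-normalized Laplacian-of-Gaussian band-pass response is computed at
#' the scale implied by `xy_diameter`, normalized by its maximum over the
#' image, and thresholded at `response_threshold`. Connected components
#' smaller than `min_component_px` pixels are discarded;
#' each surviving component yields one spot at its response-weighted
#' centroid.
#'
#' @param image numeric matrix (y, x) of pixel intensities.
#' @param params a [detection_params()].
#' @param pixel_size pixel edge length in micrometres.
#' @return A data frame with columns `x_um`, `y_um`, `response` (the
#'   component's maximum normalized response) and `n_px`.
#' @export
detect_spots_2d <- function(image, params = detection_params(),
                            pixel_size = 0.07) {
  if (length(image) == 0L || max(image) == min(image))
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      response = numeric(0), n_px = integer(0)))
  sigma <- fwhm_to_sigma(params$xy_diameter) / pixel_size
  resp <- log_response(image, c(sigma, sigma))
  resp[resp < 0] <- 0
  mx <- max(resp)
  if (mx == 0)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      response = numeric(0), n_px = integer(0)))
  resp <- resp / mx
  above <- resp >= params$response_threshold
  labels <- EBImage::bwlabel(EBImage::Image(above + 0))
  labels <- as.integer(labels)
  n <- max(labels)
  if (n == 0L)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      response = numeric(0), n_px = integer(0)))
  size <- tabulate(labels, n)
  rv <- as.vector(resp)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  ij <- arrayInd(idx, dim(image))
  wsum <- tapply(rv[idx], lab, sum)
  cy <- tapply(rv[idx] * ij[, 1L], lab, sum) / wsum
  cx <- tapply(rv[idx] * ij[, 2L], lab, sum) / wsum
  peak <- tapply(rv[idx], lab, max)
  keep <- size >= params$min_component_px
  data.frame(x_um = voxel_to_um(cx, pixel_size)[keep],
             y_um = voxel_to_um(cy, pixel_size)[keep],
             response = as.numeric(peak)[keep],
             n_px = size[keep], row.names = NULL)
}

#' Detect smFISH spots in a 3D stack
#'
#' Anisotropic scale-normalized Laplacian-of-Gaussian filtering with
#' per-axis sigmas derived from the xy diameter and z elongation (treated as
#' full widths at half maximum), followed by 26-neighbourhood local-maximum
#' detection on the max-normalized response. Maxima at or above
#' `response_threshold` are reported as spots at voxel-center positions in
#' micrometres. Plateau ties are resolved toward the lowest (z, y, x) index.
#'
#' @param stack an [image_stack()].
#' @param params a [detection_params()].
#' @param channel channel to analyze (default `"smfish"`).
#' @return A data frame with columns `x_um`, `y_um`, `z_um` and `response`
#'   (normalized response in `[0, 1]`), ordered by decreasing response.
#' @export
detect_spots_3d <- function(stack, params = detection_params(),
                            channel = "smfish") {
  arr <- get_channel(stack, channel)
  sz <- fwhm_to_sigma(params$z_elongation) / stack$voxel_z
  sxy <- fwhm_to_sigma(params$xy_diameter) / stack$voxel_xy
  min_depth <- as.integer(2 * ceiling(4 * sz) + 1L)
  if (dim(arr)[1L] < min_depth)
    stop_axonloc(sprintf(
      "stack too thin in z for the %g um filter: %d slices present, %d required",
      params$z_elongation, dim(arr)[1L], min_depth))
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      response = numeric(0))
  if (max(arr) == min(arr)) return(empty)
  resp <- log_response(arr, c(sz, sxy, sxy))
  resp[resp < 0] <- 0
  mx <- max(resp)
  if (mx == 0) return(empty)
  resp <- resp / mx
  cand <- resp >= params$response_threshold & local_maxima(resp)
  idx <- which(cand)
  if (!length(idx)) return(empty)
  zyx <- arrayInd(idx, dim(arr))
  out <- data.frame(x_um = voxel_to_um(zyx[, 3L], stack$voxel_xy),
                    y_um = voxel_to_um(zyx[, 2L], stack$voxel_xy),
                    z_um = voxel_to_um(zyx[, 1L], stack$voxel_z),
                    response = resp[idx])
  out[order(-out$response, out$z_um, out$y_um, out$x_um), , drop = FALSE]
}
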