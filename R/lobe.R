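#' Segment the axonal lobe and assign a proximal-to-distal axial coordinate
#'
#' Segments the lobe from the reference (membrane/GFP) channel: Gaussian
#' smoothing at `smoothing_scale` (default 0.146 um, the surface detail used
#' for lobe surface reconstruction), automatic Otsu thresholding, retention
#' of the largest 6-connected component, and 3D hole filling. Each mask
#' voxel then receives a normalized axial coordinate `s` in `[0, 1]`: voxel
#' positions are projected onto the mask's first principal axis, min-max
#' normalized, and oriented so that the supplied `proximal_anchor` maps near
#' 0 (so `s = 0` is proximal, `s = 1` distal).
#'
#' @param stack an [image_stack()].
#' @param channel reference channel name (default `"lobe"`).
#' @param smoothing_scale Gaussian smoothing scale in micrometres.
#' @param proximal_anchor length-3 numeric `(x, y, z)` position in
#'   micrometres marking the proximal end of the lobe.
#' @return A `LobeRegion` list: `mask` (logical `(z, y, x)` array), `s`
#'   (numeric array, `NA` outside the mask), `volume` (um^3), `voxel_xy`,
#'   `voxel_z`, `smoothing_scale`, `axis` (unit direction of increasing `s`
#'   as `(x, y, z)`).
#' @export
segment_lobe <- function(stack, channel = "lobe", smoothing_scale = 0.146,
                         proximal_anchor = c(0, 0, 0)) {
  check_number(smoothing_scale, "smoothing_scale", min = 0)
  arr <- get_channel(stack, channel)
  sig <- c(smoothing_scale / stack$voxel_z, smoothing_scale / stack$voxel_xy,
           smoothing_scale / stack$voxel_xy)
  sm <- gaussian_blur(arr, sig)
  th <- otsu_threshold(sm)
  mask <- sm > th
  if (!any(mask))
    stop_axonloc("segmentation failed: empty mask after automatic thresholding")
  mask <- fill_holes_3d(largest_component_3d(mask))

  idx <- which(mask)
  zyx <- arrayInd(idx, dim(mask))
  coords <- cbind(x = voxel_to_um(zyx[, 3L], stack$voxel_xy),
                  y = voxel_to_um(zyx[, 2L], stack$voxel_xy),
                  z = voxel_to_um(zyx[, 1L], stack$voxel_z))
  ctr <- colMeans(coords)
  pc1 <- stats::prcomp(coords, center = TRUE, scale. = FALSE)$rotation[, 1L]
  proj <- as.vector((coords - rep(ctr, each = nrow(coords))) %*% pc1)
  rng <- range(proj)
  s_vals <- if (diff(rng) > 0) (proj - rng[1L]) / diff(rng) else rep(0.5, length(proj))
  anchor_s <- (sum((proximal_anchor - ctr) * pc1) - rng[1L]) / max(diff(rng), .Machine$double.eps)
  if (anchor_s > 0.5) {
    s_vals <- 1 - s_vals
    pc1 <- -pc1
  }
  s <- array(NA_real_, dim(mask))
  s[idx] <- s_vals

  structure(list(mask = mask, s = s,
                 volume = sum(mask) * stack$voxel_xy^2 * stack$voxel_z,
                 voxel_xy = stack$voxel_xy, voxel_z = stack$voxel_z,
                 smoothing_scale = smoothing_scale,
                 axis = pc1 / sqrt(sum(pc1^2))),
            class = "LobeRegion")
}

#' @export
print.LobeRegion <- function(x, ...) {
  cat(sprintf("LobeRegion: %d voxels, %.1f um^3, axis (%.2f, %.2f, %.2f)\n",
              sum(x$mask), x$volume, x$axis[1L], x$axis[2L], x$axis[3L]))
  invisible(x)
}

spot_voxel_index <- function(spots, region) {
  d <- dim(region$mask)
  cbind(um_to_voxel(spots$z_um, region$voxel_z, d[1L]),
        um_to_voxel(spots$y_um, region$voxel_xy, d[2L]),
        um_to_voxel(spots$x_um, region$voxel_xy, d[3L]))
}

spot_axial_coord <- function(spots, region) region$s[spot_voxel_index(spots, region)]

#' Keep only spots inside the segmented lobe
#'
#' A spot is inside when the voxel containing its position belongs to the
#' region mask; the inside and outside subsets partition the input exactly.
#'
#' @param spots data frame with `x_um`, `y_um`, `z_um` columns.
#' @param region a [segment_lobe()] result.
#' @return The subset of `spots` inside the region, with an added `s`
#'   column (axial coordinate of the containing voxel).
#' @export
filter_spots_in_region <- function(spots, region) {
  stopifnot(inherits(region, "LobeRegion"))
  inside <- region$mask[spot_voxel_index(spots, region)]
  out <- spots[inside, , drop = FALSE]
  out$s <- spot_axial_coord(out, region)
  out
}

#' Count axonal spots in the distal two thirds of the lobe
#'
#' Counts in-region spots with axial coordinate `s >= 1/3` (the distal 2/3
#' of the lobe measured along the lobe axis). Samples with fewer than 10
#' axonal spots are flagged for exclusion.
#'
#' @param spots in-region spots (from [filter_spots_in_region()]); an `s`
#'   column is used if present, otherwise looked up from `region`.
#' @param region a [segment_lobe()] result.
#' @param min_spots exclusion threshold (default 10).
#' @return A list with `n_axonal` and `included` (`FALSE` when
#'   `n_axonal < min_spots`).
#' @export
count_axonal <- function(spots, region, min_spots = 10L) {
  s <- spots$s %||% spot_axial_coord(spots, region)
  n <- sum(s >= 1 / 3, na.rm = TRUE)
  list(n_axonal = n, included = n >= min_spots)
}

#' Distal gamma5 vs proximal gamma2-4 spot density ratio
#'
#' Splits the lobe at axial coordinate `s = 2/3`: the distal third is the
#' gamma5 compartment, the remaining proximal two thirds the gamma2-4
#' compartments. Spot densities (spots/um^3) are computed in each part and
#' their ratio (gamma5 / gamma2-4) is the compartment enrichment. The
#' inclusion flag follows the axonal-count rule of [count_axonal()].
#'
#' @inheritParams count_axonal
#' @return A `CompartmentQuant` list: counts (`n_gamma5`, `n_gamma24`,
#'   `n_axonal`), volumes and densities per compartment,
#'   `enrichment_ratio` (`NA` with `reason` when the proximal density is
#'   zero), and `included`.
#' @export
compartment_ratio <- function(spots, region, min_spots = 10L) {
  stopifnot(inherits(region, "LobeRegion"))
  s <- spots$s %||% spot_axial_coord(spots, region)
  if (anyNA(s)) stop_axonloc("spots must be filtered to the region first")
  voxvol <- region$voxel_xy^2 * region$voxel_z
  distal_vox <- sum(region$s >= 2 / 3, na.rm = TRUE)
  total_vox <- sum(region$mask)
  n5 <- sum(s >= 2 / 3)
  n24 <- length(s) - n5
  vol5 <- distal_vox * voxvol
  vol24 <- (total_vox - distal_vox) * voxvol
  d5 <- n5 / vol5
  d24 <- n24 / vol24
  ratio <- if (n24 == 0L) NA_real_ else d5 / d24
  ax <- count_axonal(data.frame(s = s), region, min_spots = min_spots)
  structure(list(n_gamma5 = n5, n_gamma24 = n24, n_axonal = ax$n_axonal,
                 vol_gamma5 = vol5, vol_gamma24 = vol24,
                 density_gamma5 = d5, density_gamma24 = d24,
                 enrichment_ratio = ratio,
                 reason = if (is.na(ratio)) "zero proximal spot count" else NA_character_,
                 included = ax$included),
            class = "CompartmentQuant")
}

#' @export
print.CompartmentQuant <- function(x, ...) {
  cat(sprintf(
    "CompartmentQuant: gamma5 %d spots / %.1f um^3, gamma2-4 %d / %.1f, ratio %.3g%s\n",
    x$n_gamma5, x$vol_gamma5, x$n_gamma24, x$vol_gamma24, x$enrichment_ratio,
    if (!x$included) " (excluded: <10 axonal spots)" else ""))
  invisible(x)
}

#' Normalize spot counts to the per-batch control mean
#'
#' Divides each sample's spot count by the mean count of the control-group
#' samples in the same replicate batch, making control means 1 per batch and
#' the result invariant to a common scale factor.
#'
#' @param counts numeric vector of per-sample spot counts.
#' @param group group label per sample.
#' @param batch replicate batch per sample (default: one batch).
#' @param control name of the control group (default `"control"`).
#' @return Numeric vector of normalized counts, same order as `counts`.
#' @export
normalize_counts <- function(counts, group, batch = rep(1L, length(counts)),
                             control = "control") {
  stopifnot(length(group) == length(counts), length(batch) == length(counts))
  out <- numeric(length(counts))
  for (b in unique(batch)) {
    in_b <- batch == b
    ctrl <- in_b & group == control
    if (!any(ctrl))
      stop_axonloc(sprintf("batch '%s' has no '%s' sample", b, control))
    m <- mean(counts[ctrl])
    if (m == 0)
      stop_axonloc(sprintf("batch '%s': control mean is zero", b))
    out[in_b] <- counts[in_b] / m
  }
  out
}
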