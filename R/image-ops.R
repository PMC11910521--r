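# Low-level grid operations on 2D/3D intensity arrays.
#
# Arrays follow the (z, y, x) layout used throughout the package; 2D images
# are (y, x). All filters use replicate (nearest-neighbour) padding so that
# object geometry near stack borders is not biased toward zero.

# Index-shift a dimension with edge clamping: out[i] = arr[clamp(i + off)].
shift_clamped <- function(arr, dim_k, off) {
  d <- dim(arr)
  idx <- pmin(pmax(seq_len(d[dim_k]) + off, 1L), d[dim_k])
  subs <- rep(list(quote(expr = )), length(d))
  subs[[dim_k]] <- idx
  do.call(`[`, c(list(arr), subs, list(drop = FALSE)))
}

# Shift with constant fill (used for local-maximum comparisons).
shift_filled <- function(arr, offsets, fill) {
  d <- dim(arr)
  out <- arr
  for (k in seq_along(offsets)) {
    off <- offsets[k]
    if (off == 0L) next
    idx <- seq_len(d[k]) + off
    bad <- idx < 1L | idx > d[k]
    idx[bad] <- 1L
    subs <- rep(list(quote(expr = )), length(d))
    subs[[k]] <- idx
    out <- do.call(`[`, c(list(out), subs, list(drop = FALSE)))
    if (any(bad)) {
      subs[[k]] <- which(bad)
      out <- do.call(`[<-`, c(list(out), subs, list(value = fill)))
    }
  }
  out
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w / sum(w)
}

# Separable convolution along one dimension via weighted shifted sums.
convolve_along <- function(arr, kernel, dim_k) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(arr)
  out <- array(0, dim(arr))
  for (j in seq_along(kernel))
    out <- out + kernel[j] * shift_clamped(arr, dim_k, j - r - 1L)
  out
}

# Anisotropic Gaussian smoothing; `sigma` in voxels, one entry per dimension.
gaussian_blur <- function(arr, sigma) {
  stopifnot(length(sigma) == length(dim(arr)))
  for (k in seq_along(sigma))
    if (sigma[k] > 0) arr <- convolve_along(arr, gaussian_kernel_1d(sigma[k]), k)
  arr
}

# Scale-normalized anisotropic Laplacian-of-Gaussian blob response.
# Smooths with per-axis sigma, applies the discrete Laplacian with per-axis
# sigma^2 normalization, and negates so that bright blobs give positive
# responses.
log_response <- function(arr, sigma) {
  sm <- gaussian_blur(arr, sigma)
  lap <- array(0, dim(arr))
  for (k in seq_along(sigma)) {
    if (dim(arr)[k] < 2L) next
    d2 <- shift_clamped(sm, k, 1L) + shift_clamped(sm, k, -1L) - 2 * sm
    lap <- lap + sigma[k]^2 * d2
  }
  -lap
}

# Strict local maxima over the full neighbourhood (8-connected in 2D,
# 26-connected in 3D). Plateau ties are broken in favour of the voxel with
# the lowest (z, y, x) index: equal-valued neighbours that come later in
# that order do not disqualify a voxel, earlier ones do.
local_maxima <- function(arr) {
  nd <- length(dim(arr))
  offs <- as.matrix(do.call(expand.grid, rep(list(-1L:1L), nd)))
  offs <- offs[rowSums(offs != 0L) > 0L, , drop = FALSE]
  ismax <- array(TRUE, dim(arr))
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    nb <- shift_filled(arr, -o, -Inf)  # value of the neighbour at +o
    first <- o[which(o != 0L)[1L]]
    ismax <- ismax & (if (first > 0L) arr >= nb else arr > nb)
  }
  ismax
}

# Otsu threshold of a numeric array, delegating the histogram criterion to
# EBImage on min-max normalized intensities.
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0)
    stop_axonloc("cannot threshold a constant image")
  norm <- (as.vector(x) - rng[1L]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(matrix(norm, nrow = 1L)), range = c(0, 1))
  rng[1L] + th * diff(rng)
}

# 6-connected flood fill over a 3D logical array from seed linear indices.
# Returns a logical array of reached voxels (restricted to `mask`).
flood_fill_3d <- function(mask, seeds) {
  d <- dim(mask)
  nz <- d[1L]; ny <- d[2L]; nx <- d[3L]
  reached <- array(FALSE, d)
  frontier <- seeds[mask[seeds] & !reached[seeds]]
  reached[frontier] <- TRUE
  nzy <- nz * ny
  while (length(frontier)) {
    i0 <- frontier - 1L
    z <- i0 %% nz
    y <- (i0 %/% nz) %% ny
    x <- i0 %/% nzy
    nbrs <- c(frontier[z > 0L] - 1L, frontier[z < nz - 1L] + 1L,
              frontier[y > 0L] - nz, frontier[y < ny - 1L] + nz,
              frontier[x > 0L] - nzy, frontier[x < nx - 1L] + nzy)
    nbrs <- unique(nbrs)
    nbrs <- nbrs[mask[nbrs] & !reached[nbrs]]
    reached[nbrs] <- TRUE
    frontier <- nbrs
  }
  reached
}

# Largest 6-connected component of a 3D logical mask.
largest_component_3d <- function(mask) {
  remaining <- mask
  best <- mask
  best_n <- 0L
  total <- sum(mask)
  if (total == 0L) return(mask)
  covered <- 0L
  while (covered < total) {
    seed <- which(remaining)[1L]
    comp <- flood_fill_3d(remaining, seed)
    n <- sum(comp)
    covered <- covered + n
    if (n > best_n) { best <- comp; best_n <- n }
    remaining <- remaining & !comp
    if (best_n >= total - covered) break  # no larger component possible
  }
  best
}

# Fill cavities of a 3D mask: background voxels not connected to the array
# border become foreground.
fill_holes_3d <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  idx <- array(seq_along(mask), d)
  border <- c(idx[c(1L, d[1L]), , ], idx[, c(1L, d[2L]), ], idx[, , c(1L, d[3L])])
  outside <- flood_fill_3d(bg, unique(border))
  mask | (bg & !outside)
}
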