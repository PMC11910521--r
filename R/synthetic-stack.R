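#' Configuration for the synthetic axon-lobe stack generator
#'
#' Describes a straight cylindrical "lobe" of given length and radius laid
#' along the x axis of a two-channel stack (a `lobe` reference channel and a
#' `smfish` spot channel), with diffraction-limited spots planted at
#' compartment-dependent Poisson densities. The proximal end of the lobe sits
#' at low x; the normalized axial coordinate `s = x / lobe_length` is 0 at
#' the proximal end and 1 at the distal tip, and spots with `s >= 2/3` are
#' labelled `distal`.
#'
#' @param seed integer seed; a fixed seed reproduces the output exactly.
#' @param lobe_length,lobe_radius cylinder geometry in micrometres.
#' @param voxel_xy,voxel_z voxel sizes in micrometres (defaults 0.07 and
#'   0.25 um, matching confocal acquisition of whole-mount brains).
#' @param density_proximal,density_distal planted spot densities
#'   (spots/um^3) for the proximal (`s < 2/3`) and distal (`s >= 2/3`)
#'   compartments.
#' @param psf_sigma_xy,psf_sigma_z Gaussian spot widths in micrometres
#'   (defaults from 0.4 um xy / 0.8 um z full widths at half maximum).
#' @param spot_amplitude peak intensity added by one spot.
#' @param background_mean constant background intensity.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param margin clear space (um) between the cylinder and the stack border.
#' @param min_spacing optional hard-core distance (um): planted positions
#'   closer than this to an earlier-kept position are thinned out. 0 leaves
#'   the plain Poisson process untouched.
#' @param shot_noise if `TRUE`, Poisson shot noise is applied to the noise
#'   free spot-channel signal before the additive Gaussian noise.
#' @param dim_zyx optional explicit stack dimension `(z, y, x)`; an error is
#'   raised when the lobe plus margins does not fit.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(seed = 1L, lobe_length = 15, lobe_radius = 2,
                              voxel_xy = 0.07, voxel_z = 0.25,
                              density_proximal = 0.5, density_distal = 0.5,
                              psf_sigma_xy = 0.4 / (2 * sqrt(2 * log(2))),
                              psf_sigma_z = 0.8 / (2 * sqrt(2 * log(2))),
                              spot_amplitude = 100, background_mean = 20,
                              noise_sd = 10, margin = 0.6, min_spacing = 0,
                              shot_noise = FALSE, dim_zyx = NULL) {
  check_number(lobe_length, "lobe_length", min = 0, strict_min = TRUE)
  check_number(lobe_radius, "lobe_radius", min = 0, strict_min = TRUE)
  check_number(voxel_xy, "voxel_xy", min = 0, strict_min = TRUE)
  check_number(voxel_z, "voxel_z", min = 0, strict_min = TRUE)
  check_number(density_proximal, "density_proximal", min = 0)
  check_number(density_distal, "density_distal", min = 0)
  check_number(psf_sigma_xy, "psf_sigma_xy", min = 0, strict_min = TRUE)
  check_number(psf_sigma_z, "psf_sigma_z", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(min_spacing, "min_spacing", min = 0)
  cfg <- list(seed = as.integer(seed), lobe_length = lobe_length,
              lobe_radius = lobe_radius, voxel_xy = voxel_xy, voxel_z = voxel_z,
              density_proximal = density_proximal,
              density_distal = density_distal, psf_sigma_xy = psf_sigma_xy,
              psf_sigma_z = psf_sigma_z, spot_amplitude = spot_amplitude,
              background_mean = background_mean, noise_sd = noise_sd,
              margin = margin, min_spacing = min_spacing,
              shot_noise = shot_noise, dim_zyx = dim_zyx)
  class(cfg) <- "SimulationConfig"
  cfg
}

stack_dims <- function(cfg) {
  span_x <- cfg$lobe_length + 2 * cfg$margin
  span_yz <- 2 * (cfg$lobe_radius + cfg$margin)
  auto <- c(z = as.integer(ceiling(span_yz / cfg$voxel_z)),
            y = as.integer(ceiling(span_yz / cfg$voxel_xy)),
            x = as.integer(ceiling(span_x / cfg$voxel_xy)))
  if (is.null(cfg$dim_zyx)) return(auto)
  d <- as.integer(cfg$dim_zyx)
  if (length(d) != 3L || any(d < auto))
    stop_axonloc(sprintf(
      "lobe does not fit the requested stack: need at least %d x %d x %d (z, y, x) voxels",
      auto[1L], auto[2L], auto[3L]))
  d
}

cylinder_mask <- function(cfg, d) {
  cx0 <- unname(cfg$margin)               # lobe proximal face (um, stack frame)
  cy <- unname(d[2L]) * cfg$voxel_xy / 2
  cz <- unname(d[1L]) * cfg$voxel_z / 2
  xs <- voxel_to_um(seq_len(d[3L]), cfg$voxel_xy)
  ys <- voxel_to_um(seq_len(d[2L]), cfg$voxel_xy)
  zs <- voxel_to_um(seq_len(d[1L]), cfg$voxel_z)
  r2 <- outer((zs - cz)^2, (ys - cy)^2, `+`)       # (z, y)
  in_disc <- r2 <= cfg$lobe_radius^2
  in_x <- xs >= cx0 & xs < cx0 + cfg$lobe_length
  mask <- array(FALSE, d)
  mask[, , in_x] <- in_disc
  list(mask = mask, origin = c(x = cx0, y = cy, z = cz))
}

sample_cylinder_positions <- function(n, cfg, x_range) {
  x <- runif(n, x_range[1L], x_range[2L])
  rad <- cfg$lobe_radius * sqrt(runif(n))
  ang <- runif(n, 0, 2 * pi)
  cbind(x = x, y = rad * cos(ang), z = rad * sin(ang))
}

#' Simulate a two-channel confocal-like stack with planted smFISH spots
#'
#' Builds the cylindrical lobe described by `config`, plants spot positions
#' from independent Poisson processes in the proximal (`s < 2/3`) and distal
#' (`s >= 2/3`) compartments, renders each spot as an anisotropic Gaussian
#' on the `smfish` channel, and renders the smoothed lobe mask on the `lobe`
#' reference channel. Both channels receive the configured background and
#' additive Gaussian noise.
#'
#' Planted positions are guaranteed to fall in voxels belonging to the lobe
#' mask (positions whose voxel center lands just outside the discretized
#' cylinder are redrawn within their compartment).
#'
#' @param config a [simulation_config()].
#' @param render if `FALSE`, skip image rendering and return empty channels;
#'   the ground truth (spot positions, labels, mask) is still complete. This
#'   keeps large-replicate distributional checks cheap.
#' @return A list with elements `stack` (an [image_stack()] with channels
#'   `lobe` and `smfish`) and `truth` (class `GroundTruth`: `spots` data
#'   frame with stack-frame um coordinates, axial coordinate `s` and
#'   `compartment` label; `region_mask`; `axial_orientation`; `origin`;
#'   `config`).
#' @export
simulate_stack <- function(config, render = TRUE) {
  stopifnot(inherits(config, "SimulationConfig"))
  d <- stack_dims(config)
  cyl <- cylinder_mask(config, d)
  L <- config$lobe_length

  spots <- with_substream(config$seed, "positions", {
    vol <- pi * config$lobe_radius^2 * L
    n_prox <- stats::rpois(1L, config$density_proximal * vol * 2 / 3)
    n_dist <- stats::rpois(1L, config$density_distal * vol / 3)
    x0 <- cyl$origin["x"]
    draw <- function(n, lo, hi) {
      if (n == 0L)
        return(matrix(numeric(0), ncol = 3L, dimnames = list(NULL, c("x", "y", "z"))))
      pos <- sample_cylinder_positions(n, config, x0 + c(lo, hi) * L)
      # redraw positions whose voxel falls outside the discretized mask
      repeat {
        iz <- um_to_voxel(pos[, "z"] + cyl$origin["z"], config$voxel_z, d[1L])
        iy <- um_to_voxel(pos[, "y"] + cyl$origin["y"], config$voxel_xy, d[2L])
        ix <- um_to_voxel(pos[, "x"], config$voxel_xy, d[3L])
        bad <- !cyl$mask[cbind(iz, iy, ix)]
        if (!any(bad)) break
        pos[bad, ] <- sample_cylinder_positions(sum(bad), config, x0 + c(lo, hi) * L)
      }
      pos
    }
    rbind(draw(n_prox, 0, 2 / 3), draw(n_dist, 2 / 3, 1))
  })

  if (config$min_spacing > 0 && nrow(spots) > 1L) {
    keep <- rep(TRUE, nrow(spots))
    for (i in 2:nrow(spots)) {
      prev <- spots[which(keep[seq_len(i - 1L)]), , drop = FALSE]
      dmin <- sqrt(min(colSums((t(prev) - spots[i, ])^2)))
      if (dmin < config$min_spacing) keep[i] <- FALSE
    }
    spots <- spots[keep, , drop = FALSE]
  }

  s_coord <- (spots[, "x"] - cyl$origin["x"]) / L
  truth_spots <- data.frame(
    x_um = spots[, "x"],
    y_um = spots[, "y"] + cyl$origin["y"],
    z_um = spots[, "z"] + cyl$origin["z"],
    s = s_coord,
    compartment = ifelse(s_coord >= 2 / 3, "distal", "proximal"),
    stringsAsFactors = FALSE)

  if (render) {
    sxy <- config$psf_sigma_xy / config$voxel_xy
    sz <- config$psf_sigma_z / config$voxel_z
    signal <- array(0, d)
    if (nrow(truth_spots)) {
      rz <- ceiling(4 * sz); rxy <- ceiling(4 * sxy)
      for (i in seq_len(nrow(truth_spots))) {
        cxv <- truth_spots$x_um[i] / config$voxel_xy + 0.5
        cyv <- truth_spots$y_um[i] / config$voxel_xy + 0.5
        czv <- truth_spots$z_um[i] / config$voxel_z + 0.5
        zi <- max(1L, floor(czv - rz)):min(d[1L], ceiling(czv + rz))
        yi <- max(1L, floor(cyv - rxy)):min(d[2L], ceiling(cyv + rxy))
        xi <- max(1L, floor(cxv - rxy)):min(d[3L], ceiling(cxv + rxy))
        ez <- exp(-(zi - czv)^2 / (2 * sz^2))
        ey <- exp(-(yi - cyv)^2 / (2 * sxy^2))
        ex <- exp(-(xi - cxv)^2 / (2 * sxy^2))
        signal[zi, yi, xi] <- signal[zi, yi, xi] +
          config$spot_amplitude * (ez %o% ey %o% ex)
      }
    }
    if (config$shot_noise)
      signal <- with_substream(config$seed, "shot", {
        array(stats::rpois(length(signal), signal), d)
      })
    smfish <- config$background_mean + signal +
      with_substream(config$seed, "noise", {
        array(stats::rnorm(prod(d), 0, config$noise_sd), d)
      })
    lobe <- config$spot_amplitude *
      gaussian_blur(cyl$mask + 0, c(sz, sxy, sxy)) +
      config$background_mean +
      with_substream(config$seed, "refnoise", {
        array(stats::rnorm(prod(d), 0, config$noise_sd), d)
      })
    channels <- list(lobe = lobe, smfish = smfish)
  } else {
    channels <- list(lobe = array(0, d), smfish = array(0, d))
  }

  truth <- structure(list(spots = truth_spots, region_mask = cyl$mask,
                          axial_orientation = c(x = 1, y = 0, z = 0),
                          origin = cyl$origin, config = config),
                     class = "GroundTruth")
  list(stack = image_stack(channels, config$voxel_xy, config$voxel_z),
       truth = truth)
}
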