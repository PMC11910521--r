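test_that("contrast rescaling saturates the configured pixel fraction", {
  # permutation of 0..10^6-1 at fraction 1e-4 -> exactly 100 clipped pixels
  set.seed(11)
  img <- matrix(sample(0:(1e6 - 1)), 1000, 1000)
  out <- rescale_contrast(img, 1e-4)
  q <- stats::quantile(img, 1 - 1e-4, type = 1)
  expect_identical(sum(img > q), 100L)          # exactly 100 clipped pixels
  expect_identical(sum(out == 1), 101L)         # clipped + the quantile pixel
  expect_identical(min(out), 0)
  expect_identical(max(out), 1)

  expect_warning(same <- rescale_contrast(matrix(3, 5, 5)), "constant")
  expect_identical(same, matrix(3, 5, 5))
})

test_that("2D detection finds a planted spot and obeys the size/threshold rules", {
  blank <- matrix(10, 80, 80)
  expect_identical(nrow(detect_spots_2d(blank)), 0L)

  img <- planted_crop_2d(cy = 60.3, cx = 40.7)   # SNR 10
  det <- detect_spots_2d(img)
  expect_identical(nrow(det), 1L)
  expect_lt(abs(det$x_um - (40.7 - 0.5) * 0.07), 0.07)  # within 1 px
  expect_lt(abs(det$y_um - (60.3 - 0.5) * 0.07), 0.07)

  # raising the threshold never increases the count
  counts <- vapply(c(0.2, 0.4, 0.62, 0.8, 0.95), function(th)
    nrow(detect_spots_2d(img, detection_params(response_threshold = th))), 1L)
  expect_true(all(diff(counts) <= 0))

  # the component-size cutoff is a non-strict minimum
  npx <- det$n_px
  expect_identical(nrow(detect_spots_2d(img, detection_params(min_component_px = npx))), 1L)
  expect_identical(nrow(detect_spots_2d(img, detection_params(min_component_px = npx + 1L))), 0L)
})

test_that("3D detection recovers planted spots and resolves close pairs", {
  sim <- small_sim()
  det <- detect_spots_3d(sim$stack)
  sc <- match_spots(det, sim$truth$spots)
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$precision, 0.95)

  # blank stack -> no spots; thin stack -> informative error
  d <- c(24L, 40L, 40L)
  blank <- image_stack(list(smfish = array(10, d)))
  expect_identical(nrow(detect_spots_3d(blank)), 0L)
  thin <- image_stack(list(smfish = array(runif(5 * 40 * 40), c(5L, 40L, 40L))))
  expect_error(detect_spots_3d(thin), "slices")

  # two spots separated by 3x the xy diameter are both found
  arr <- array(0, d)
  s_xy <- (0.4 / 2.355) / 0.07; s_z <- (0.8 / 2.355) / 0.25
  for (cx in c(14, 14 + 3 * 0.4 / 0.07)) {
    zi <- 1:24; yi <- 1:40; xi <- 1:40
    arr <- arr + 100 * (exp(-(zi - 12)^2 / (2 * s_z^2)) %o%
                          exp(-(yi - 20)^2 / (2 * s_xy^2)) %o%
                          exp(-(xi - cx)^2 / (2 * s_xy^2)))
  }
  pair <- detect_spots_3d(image_stack(list(smfish = arr + 10)))
  expect_identical(nrow(pair), 2L)

  # monotone in threshold
  counts <- vapply(c(0.3, 0.62, 0.9), function(th)
    nrow(detect_spots_3d(sim$stack, detection_params(response_threshold = th))), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("lobe segmentation recovers geometry and axial orientation", {
  sim <- small_sim()
  cfg <- sim$config
  reg <- segment_lobe(sim$stack,
                      proximal_anchor = c(0, sim$truth$origin["y"],
                                          sim$truth$origin["z"]))
  # volume within 10% of pi r^2 L
  expect_lt(abs(reg$volume - pi * cfg$lobe_radius^2 * cfg$lobe_length) /
              (pi * cfg$lobe_radius^2 * cfg$lobe_length), 0.1)

  # s increases monotonically with x along the cylinder
  idx <- which(reg$mask)
  zyx <- arrayInd(idx, dim(reg$mask))
  expect_gt(cor(reg$s[idx], zyx[, 3], method = "spearman"), 0.99)

  # anchoring at the far end reverses the coordinate
  far <- segment_lobe(sim$stack,
                      proximal_anchor = c(cfg$lobe_length + 2 * cfg$margin,
                                          sim$truth$origin["y"],
                                          sim$truth$origin["z"]))
  expect_equal(far$s[idx], 1 - reg$s[idx], tolerance = 1e-12)

  # constant reference channel cannot be segmented
  flat <- image_stack(list(lobe = array(1, c(10L, 20L, 20L))))
  expect_error(segment_lobe(flat), "constant")
})

test_that("in-region filtering partitions spots and feeds the compartment counts", {
  sim <- small_sim()
  reg <- segment_lobe(sim$stack,
                      proximal_anchor = c(0, sim$truth$origin["y"],
                                          sim$truth$origin["z"]))
  truth <- sim$truth$spots
  inside <- filter_spots_in_region(truth, reg)
  # planted spots were generated inside the lobe; segmentation may shave
  # only boundary voxels
  expect_gte(nrow(inside), 0.9 * nrow(truth))

  # partition: inside + outside = input, disjointly
  vox_in <- reg$mask[axonloc:::spot_voxel_index(truth, reg)]
  expect_identical(nrow(inside) + sum(!vox_in), nrow(truth))

  # an off-lobe spot is removed
  corner <- data.frame(x_um = 0.01, y_um = 0.01, z_um = 0.01)
  expect_identical(nrow(filter_spots_in_region(corner, reg)), 0L)

  cq <- compartment_ratio(inside, reg)
  expect_identical(cq$n_gamma5 + cq$n_gamma24, nrow(inside))
  expect_equal(cq$vol_gamma5 + cq$vol_gamma24, reg$volume, tolerance = 1e-12)
  expect_equal(cq$density_gamma5, cq$n_gamma5 / cq$vol_gamma5)
})

test_that("axonal counting keeps the distal 2/3 and applies the 10-spot rule", {
  sim <- small_sim()
  reg <- segment_lobe(sim$stack,
                      proximal_anchor = c(0, sim$truth$origin["y"],
                                          sim$truth$origin["z"]))
  # uniform spots along the axis: ~2/3 retained
  set.seed(42)
  n <- 3000
  unif <- data.frame(s = runif(n))
  frac <- count_axonal(unif, reg)$n_axonal / n
  expect_lt(abs(frac - 2 / 3), 0.03)

  expect_false(count_axonal(data.frame(s = rep(0.9, 9)), reg)$included)
  expect_true(count_axonal(data.frame(s = rep(0.9, 10)), reg)$included)

  # all-distal spots leave the proximal density zero -> undefined ratio
  distal <- data.frame(s = runif(20, 0.7, 1))
  cq <- compartment_ratio(distal, reg)
  expect_true(is.na(cq$enrichment_ratio))
  expect_match(cq$reason, "proximal")
})

test_that("spot positions re-bin to their source voxel", {
  sim <- small_sim()
  det <- detect_spots_3d(sim$stack)
  d <- sim$stack$dim
  iz <- um_to_voxel(det$z_um, sim$stack$voxel_z, d[1])
  expect_identical(voxel_to_um(iz, sim$stack$voxel_z), det$z_um)
  ix <- um_to_voxel(det$x_um, sim$stack$voxel_xy, d[3])
  expect_identical(voxel_to_um(ix, sim$stack$voxel_xy), det$x_um)
})

test_that("count normalization uses the per-batch control mean", {
  counts <- c(20, 30, 10)
  grp <- c("control", "control", "mutant")
  norm <- normalize_counts(counts, grp)
  expect_equal(norm, c(0.8, 1.2, 0.4))
  expect_equal(mean(norm[grp == "control"]), 1)
  expect_equal(normalize_counts(counts * 2, grp), norm)

  two <- normalize_counts(c(20, 30, 10, 5, 5, 20), rep(c("control", "control", "mutant"), 2),
                          batch = rep(1:2, each = 3))
  expect_equal(two[6], 4)
  expect_error(normalize_counts(c(0, 0, 1), grp), "zero")
  expect_error(normalize_counts(1:3, c("a", "a", "mutant")), "no 'control'")
})
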