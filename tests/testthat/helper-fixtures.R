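# Shared fixtures, built in code at test time.

# Toy coding transcript: single exon, 5'UTR 200 nt / CDS 600 nt / 3'UTR 400 nt.
toy_transcript <- function(strand = "+") {
  transcript_model("gToy", "tToy", "2L", strand,
                   data.frame(start = 1000L, end = 2200L),
                   cds_start = 1200L, cds_end = 1800L)
}

# Two-exon transcript on a chosen strand with an intron, CDS spanning the
# junction: exon1 [100, 400), exon2 [900, 1700); L = 1100.
# Transcript-space partition: 5'UTR 150 / CDS 600 / 3'UTR 350.
junction_transcript <- function(strand = "+") {
  exons <- data.frame(start = c(100L, 900L), end = c(400L, 1700L))
  if (strand == "+") {
    # t=150 -> g=250; t=749 -> g=900 + (749-300) = 1349
    transcript_model("gJx", "tJx", "3R", strand, exons,
                     cds_start = 250L, cds_end = 1350L)
  } else {
    # on the minus strand t=0 is g=1699; t=150 -> g=1549; t=749 -> g=950
    transcript_model("gJx", "tJx", "3R", strand, exons,
                     cds_start = 950L, cds_end = 1550L)
  }
}

# Small rendered stack shared by several detection/segmentation tests.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = 101L, lobe_length = 12, lobe_radius = 1.5,
                               density_proximal = 0.6, density_distal = 0.6,
                               min_spacing = 1, noise_sd = 8)
      cache <<- c(simulate_stack(cfg), list(config = cfg))
    }
    cache
  }
})

# 2D crop with one planted Gaussian spot (fwhm 0.4 um at 0.07 um pixels).
planted_crop_2d <- function(cy = 60.3, cx = 40.7, amplitude = 100,
                            noise_sd = 10, n = 120, seed = 7) {
  s <- (0.4 / (2 * sqrt(2 * log(2)))) / 0.07
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  img <- 10 + amplitude * exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * s^2))
  set.seed(seed)
  img + matrix(rnorm(n * n, 0, noise_sd), n, n)
}

# Greedy matching-free detection scores at a given radius (um).
match_spots <- function(detected, truth, radius = 0.3) {
  if (!nrow(detected) || !nrow(truth))
    return(list(recall = 0, precision = 0))
  d2 <- outer(detected$x_um, truth$x_um, `-`)^2 +
    outer(detected$y_um, truth$y_um, `-`)^2 +
    outer(detected$z_um, truth$z_um, `-`)^2
  list(recall = mean(apply(d2, 2L, min) < radius^2),
       precision = mean(apply(d2, 1L, min) < radius^2))
}
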