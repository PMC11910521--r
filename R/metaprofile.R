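#' Metatranscript profile of crosslink peak positions
#'
#' Pools significant crosslink peaks from transcripts carrying at least
#' `min_peaks` mapped significant peaks, converts their genomic positions to
#' spliced transcript coordinates, rescales them onto the 0-100 virtual
#' transcript (5'UTR 0-19, CDS 20-69, 3'UTR 70-100; see
#' [rescale_position()]), and estimates the density of the pooled
#' meta-coordinates with a Gaussian kernel reflected at both boundaries.
#' The density is evaluated on a fixed grid over `[0, 100]` with step 0.5
#' and integrates to 1 (trapezoidal rule) up to the reflection
#' approximation.
#'
#' Peaks are single-nucleotide anchors and are weighted equally by default;
#' the bandwidth defaults to Scott's rule (`sd * n^(-1/5)`) on the pooled
#' rescaled positions.
#'
#' @param models list of [transcript_model()] objects (e.g. from
#'   [build_reference()]).
#' @param peaks data frame with columns `transcript_id` (or `gene_id`
#'   matching the models), `position` (0-based genomic), and optionally
#'   `significant` (logical, default all `TRUE`) and `count`.
#' @param min_peaks minimum number of mapped significant peaks for a
#'   transcript to contribute (default 20).
#' @param bandwidth KDE bandwidth in meta-coordinate units; `NULL` for
#'   Scott's rule.
#' @param weight_by_count if `TRUE`, peaks are weighted by their `count`
#'   column instead of equally.
#' @param step grid step over `[0, 100]`.
#' @return A `MetaProfile` list: `grid`, `density`, `n_transcripts`,
#'   `n_peaks`, `bandwidth`, `positions` (the pooled meta-coordinates).
#' @export
metaprofile <- function(models, peaks, min_peaks = 20L, bandwidth = NULL,
                        weight_by_count = FALSE, step = 0.5) {
  if (!length(models)) stop_axonloc("no transcript models supplied")
  if (is.null(peaks$significant)) peaks$significant <- TRUE
  key <- if ("transcript_id" %in% names(peaks)) "transcript_id" else "gene_id"
  if (!key %in% names(peaks))
    stop_axonloc("peaks need a 'transcript_id' or 'gene_id' column")
  model_key <- vapply(models, `[[`, "", key)

  pos <- numeric(0)
  wts <- numeric(0)
  n_tx <- 0L
  for (i in seq_along(models)) {
    m <- models[[i]]
    p <- peaks[peaks[[key]] == model_key[i] & peaks$significant, , drop = FALSE]
    if (!nrow(p)) next
    tp <- genomic_to_transcript(m, p$position)
    keep <- !is.na(tp)
    if (sum(keep) < min_peaks) next
    n_tx <- n_tx + 1L
    pos <- c(pos, rescale_position(m, tp[keep]))
    wts <- c(wts, if (weight_by_count && !is.null(p$count)) p$count[keep]
             else rep(1, sum(keep)))
  }
  if (n_tx == 0L)
    stop_axonloc(sprintf(
      "no transcript carries >= %d mapped significant peaks", min_peaks))

  wts <- wts / sum(wts)
  if (is.null(bandwidth)) {
    sdw <- sqrt(sum(wts * (pos - sum(wts * pos))^2))
    bandwidth <- max(sdw * length(pos)^(-1 / 5), step / 2)
  }
  grid <- seq(0, 100, by = step)
  dens <- rep(0, length(grid))
  # Gaussian kernel with reflection at 0 and 100
  for (reflected in list(pos, -pos, 200 - pos)) {
    d <- outer(grid, reflected, function(g, x) stats::dnorm(g - x, sd = bandwidth))
    dens <- dens + as.vector(d %*% wts)
  }
  structure(list(grid = grid, density = dens, n_transcripts = n_tx,
                 n_peaks = length(pos), bandwidth = bandwidth,
                 positions = pos),
            class = "MetaProfile")
}

#' @export
print.MetaProfile <- function(x, ...) {
  cat(sprintf("MetaProfile: %d peaks on %d transcripts, bandwidth %.3g\n",
              x$n_peaks, x$n_transcripts, x$bandwidth))
  invisible(x)
}

#' Gate iCLIP targets by significant peak support
#'
#' A gene is an iCLIP target when it carries at least one significant peak
#' supported by at least `min_support` uniquely mapped cDNAs.
#'
#' @param peaks data frame with columns `gene_id`, `count` (supporting
#'   cDNAs) and optionally `significant` (default all `TRUE`).
#' @param min_support minimum cDNA support (default 5).
#' @return Character vector of gene identifiers (sorted, unique).
#' @export
gate_iclip_targets <- function(peaks, min_support = 5L) {
  if (!nrow(peaks)) return(character(0))
  if (is.null(peaks$significant)) peaks$significant <- TRUE
  sort(unique(peaks$gene_id[peaks$significant & peaks$count >= min_support]))
}

#' Median-of-ratios size factors for a count matrix
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes with a nonzero geometric mean across samples) of the ratio between
#' the sample's count and the gene's geometric mean.
#'
#' @param mat numeric matrix, genes x samples.
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors <- function(mat) {
  if (ncol(mat) < 2L) stop_axonloc("size factors need >= 2 samples")
  if (any(colSums(mat) == 0))
    stop_axonloc("sample with all-zero counts: ",
                 paste(colnames(mat)[colSums(mat) == 0], collapse = ", "))
  logs <- log(mat)
  geo <- rowMeans(logs)
  use <- is.finite(geo)
  if (!any(use)) stop_axonloc("no gene has nonzero counts in every sample")
  sf <- apply(logs[use, , drop = FALSE], 2L, function(lc) exp(stats::median(lc - geo[use])))
  sf
}

#' Quantify 3'UTR crosslink signal per gene with size-factor normalization
#'
#' For each gene's transcript model, sums the cDNA counts of crosslink sites
#' whose spliced transcript position falls in the 3'UTR (crosslinks in the
#' 5'UTR, CDS, introns or on the wrong strand contribute nothing), then
#' normalizes the per-sample totals with median-of-ratios [size_factors()]
#' computed across all samples jointly.
#'
#' @param models list of [transcript_model()] objects.
#' @param crosslinks named list (one element per sample) of data frames
#'   with columns `chromosome`, `position` (0-based genomic), `strand` and
#'   `count`.
#' @return A `UTRCountTable` list: `raw` (genes x samples matrix),
#'   `size_factors`, `normalized` (`raw` scaled by `1 / size_factor`).
#' @export
quantify_3utr <- function(models, crosslinks) {
  if (length(crosslinks) < 2L)
    stop_axonloc("normalization needs >= 2 samples")
  if (is.null(names(crosslinks)))
    names(crosslinks) <- paste0("sample", seq_along(crosslinks))
  genes <- vapply(models, `[[`, "", "gene_id")
  raw <- matrix(0, nrow = length(models), ncol = length(crosslinks),
                dimnames = list(genes, names(crosslinks)))
  for (j in seq_along(crosslinks)) {
    cl <- crosslinks[[j]]
    for (i in seq_along(models)) {
      m <- models[[i]]
      sel <- normalize_chromosome(cl$chromosome) == m$chromosome &
        cl$strand == m$strand
      if (!any(sel)) next
      tp <- genomic_to_transcript(m, cl$position[sel])
      ok <- !is.na(tp)
      if (!any(ok)) next
      reg <- assign_region(m, tp[ok])
      raw[i, j] <- sum(cl$count[sel][ok][reg == "3UTR"])
    }
  }
  sf <- size_factors(raw)
  structure(list(raw = raw, size_factors = sf,
                 normalized = sweep(raw, 2L, sf, `/`)),
            class = "UTRCountTable")
}

#' @export
print.UTRCountTable <- function(x, ...) {
  cat(sprintf("UTRCountTable: %d genes x %d samples; size factors: %s\n",
              nrow(x$raw), ncol(x$raw),
              paste(sprintf("%.3g", x$size_factors), collapse = ", ")))
  invisible(x)
}
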