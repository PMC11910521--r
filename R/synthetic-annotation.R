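#' Simulate multi-exon transcript annotations with region-biased peaks
#'
#' Generates one multi-exon coding transcript per gene on random strands of
#' the seven reference chromosomes (X, Y, MT, 2L, 2R, 3L, 3R), together
#' with crosslink peaks placed uniformly within a transcript region drawn
#' from `region_bias` (probabilities for 5'UTR, CDS, 3'UTR). The default
#' bias reflects the strongly 3'UTR-skewed binding of an Imp-like protein.
#' Every peak is guaranteed to fall inside an exon of its transcript, on
#' either strand.
#'
#' @param n_genes number of genes (>= 1).
#' @param region_bias probability triple `(p5, pCDS, p3)` summing to 1
#'   (tolerance 1e-9).
#' @param min_peaks_per_transcript minimum number of peaks per transcript
#'   (default 25, so transcripts qualify for [metaprofile()]'s >= 20
#'   significant-peak rule even after significance thinning).
#' @param seed integer seed.
#' @param prob_significant probability that a peak is flagged significant.
#' @return A `SyntheticAnnotationSet` list: `annotation` (GTF-convention
#'   exon/CDS data frame), `models` (ground-truth [transcript_model()]
#'   list), `peaks` (data frame with `gene_id`, `transcript_id`,
#'   `chromosome`, `position` 0-based genomic, `strand`, `count`,
#'   `significant`, and the ground-truth `region`), `region_bias`.
#' @export
simulate_annotation <- function(n_genes, region_bias = c(0.05, 0.15, 0.80),
                                min_peaks_per_transcript = 25L, seed = 1L,
                                prob_significant = 0.9) {
  check_number(n_genes, "n_genes", min = 1)
  if (length(region_bias) != 3L || any(region_bias < 0))
    stop_axonloc("region_bias must be three non-negative probabilities")
  if (abs(sum(region_bias) - 1) > 1e-9)
    stop_axonloc(sprintf("region_bias must sum to 1 (got %.12g)", sum(region_bias)))

  with_substream(seed, "annotation", {
    models <- vector("list", n_genes)
    anno <- vector("list", n_genes)
    peaks <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      gene_id <- sprintf("gene%04d", g)
      tx_id <- sprintf("tx%04d.1", g)
      chrom <- sample(reference_chromosomes, 1L)
      strand <- sample(c("+", "-"), 1L)
      L5 <- sample(50:300, 1L)
      Lcds <- 3L * sample(100:500, 1L)
      L3 <- sample(100:800, 1L)
      L <- L5 + Lcds + L3
      n_ex <- sample(2:6, 1L)
      widths <- 20L + as.integer(stats::rmultinom(1L, L - 20L * n_ex,
                                                  stats::runif(n_ex)))
      introns <- sample(50:2000, n_ex - 1L, replace = TRUE)
      gstart <- sample.int(1e7L, 1L)
      starts <- gstart + cumsum(c(0L, widths[-n_ex] + introns))
      exons <- data.frame(start = starts, end = starts + widths)

      # transcript -> genomic map on the plus-strand layout
      before <- cumsum(c(0L, widths))
      t2g <- function(t) {
        pp <- if (strand == "-") L - 1L - t else t
        bin <- findInterval(pp, before)
        as.integer(exons$start[bin] + (pp - before[bin]))
      }
      cds_t <- c(L5, L5 + Lcds - 1L)
      cds_g <- range(t2g(cds_t))
      m <- transcript_model(gene_id, tx_id, chrom, strand, exons,
                            cds_start = cds_g[1L], cds_end = cds_g[2L] + 1L)
      stopifnot(m$L5 == L5, m$Lcds == Lcds, m$L3 == L3)
      models[[g]] <- m

      n_pk <- min_peaks_per_transcript + stats::rpois(1L, 5)
      region <- sample(c("5UTR", "CDS", "3UTR"), n_pk, replace = TRUE,
                       prob = region_bias)
      roff <- c(`5UTR` = 0L, CDS = L5, `3UTR` = L5 + Lcds)
      rlen <- c(`5UTR` = L5, CDS = Lcds, `3UTR` = L3)
      tpos <- roff[region] +
        floor(stats::runif(n_pk) * rlen[region])
      peaks[[g]] <- data.frame(
        gene_id = gene_id, transcript_id = tx_id, chromosome = chrom,
        position = t2g(as.integer(tpos)), strand = strand,
        count = 1L + stats::rpois(n_pk, 12),
        significant = stats::runif(n_pk) < prob_significant,
        region = region, row.names = NULL, stringsAsFactors = FALSE)

      # CDS rows are per-exon pieces of the CDS genomic span (GTF style)
      cds_lo <- pmax(exons$start, cds_g[1L])
      cds_hi <- pmin(exons$end, cds_g[2L] + 1L)
      has_cds <- cds_lo < cds_hi
      anno[[g]] <- data.frame(
        seqnames = chrom,
        type = c(rep("exon", n_ex), rep("CDS", sum(has_cds))),
        start = c(exons$start + 1L, cds_lo[has_cds] + 1L),
        end = c(exons$end, cds_hi[has_cds]),
        strand = strand, gene_id = gene_id, transcript_id = tx_id,
        transcript_biotype = "protein_coding", status = "validated",
        row.names = NULL, stringsAsFactors = FALSE)
    }
    names(models) <- vapply(models, `[[`, "", "gene_id")
    structure(list(annotation = do.call(rbind, anno), models = models,
                   peaks = do.call(rbind, peaks), region_bias = region_bias),
              class = "SyntheticAnnotationSet")
  })
}
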