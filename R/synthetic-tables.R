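#' Simulate per-gene assay tables with a planted target set
#'
#' Builds the three gene-level tables consumed by the target-gating stage
#' with a planted set of true targets: planted targets pass all three gates
#' (synaptosome `log2FC > 0`, RIP `log2FC > 1` in every comparison, and at
#' least one significant iCLIP peak supported by >= 5 cDNAs) by
#' construction, while every non-target is forced to fail at least one
#' randomly chosen gate. The triple overlap of the gated sets therefore
#' recovers exactly the planted targets.
#'
#' @param n_genes number of genes.
#' @param n_targets number of planted targets (`<= n_genes`).
#' @param seed integer seed.
#' @param n_comparisons number of RIP bound-vs-control comparisons
#'   (default 4: two bound replicates against two controls).
#' @return A `SyntheticAssayTables` list: `synaptosome_stats` (`gene_id`,
#'   `log2FC`, `padj`, `mean_rpm`), `rip_stats` (`gene_id` plus one log2FC
#'   column per comparison), `iclip_peak_support` (peak-level `gene_id`,
#'   `count`, `significant`), `planted_target_set`.
#' @export
simulate_assay_tables <- function(n_genes, n_targets, seed = 1L,
                                  n_comparisons = 4L) {
  check_number(n_genes, "n_genes", min = 1)
  check_number(n_targets, "n_targets", min = 0, max = n_genes)
  with_substream(seed, "tables", {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    targets <- sort(sample(genes, n_targets))
    is_t <- genes %in% targets
    fail_gate <- sample(1:3, n_genes, replace = TRUE)  # used for non-targets

    syn_lfc <- stats::runif(n_genes, -2, 3)
    syn_lfc[is_t] <- stats::runif(sum(is_t), 0.9, 3)
    force1 <- !is_t & fail_gate == 1L
    syn_lfc[force1] <- stats::runif(sum(force1), -2, 0)
    syn <- data.frame(gene_id = genes, log2FC = syn_lfc,
                      padj = ifelse(is_t, stats::runif(n_genes, 0, 0.049),
                                    stats::runif(n_genes)),
                      mean_rpm = stats::rlnorm(n_genes, 3, 1.2),
                      stringsAsFactors = FALSE)

    rip <- matrix(stats::runif(n_genes * n_comparisons, -1, 3),
                  nrow = n_genes,
                  dimnames = list(genes, paste0("comparison", seq_len(n_comparisons))))
    rip[is_t, ] <- stats::runif(sum(is_t) * n_comparisons, 1.05, 3)
    for (i in which(!is_t & fail_gate == 2L))
      rip[i, sample.int(n_comparisons, 1L)] <- stats::runif(1L, -1, 0.99)
    rip_stats <- data.frame(gene_id = genes, rip, row.names = NULL,
                            stringsAsFactors = FALSE)

    iclip <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
      n_pk <- sample(1:3, 1L)
      if (is_t[i]) {
        count <- c(sample(5:40, 1L), sample(1:40, n_pk - 1L, replace = TRUE))
        signif <- c(TRUE, stats::runif(n_pk - 1L) < 0.8)
      } else if (fail_gate[i] == 3L) {
        # every peak fails: low support, or unsupported significance
        low <- stats::runif(n_pk) < 0.5
        count <- ifelse(low, sample(1:4, n_pk, replace = TRUE),
                        sample(5:40, n_pk, replace = TRUE))
        signif <- low & stats::runif(n_pk) < 0.5
      } else {
        count <- sample(1:40, n_pk, replace = TRUE)
        signif <- stats::runif(n_pk) < 0.8
      }
      data.frame(gene_id = genes[i], count = as.integer(count),
                 significant = signif, stringsAsFactors = FALSE)
    }))

    structure(list(synaptosome_stats = syn, rip_stats = rip_stats,
                   iclip_peak_support = iclip, planted_target_set = targets),
              class = "SyntheticAssayTables")
  })
}

#' Simulate courtship indices for naive and trained flies
#'
#' Naive courtship indices are drawn around `naive_mean` and trained
#' indices around `naive_mean * (1 - suppression)`, both with Gaussian
#' noise and clipped to `[0, 1]`. Complete suppression (`suppression = 1`)
#' yields trained indices of exactly 0. The expected memory index of a
#' trained fly is therefore approximately `suppression`.
#'
#' @param n_naive,n_trained group sizes (defaults 30, matching typical
#'   courtship-conditioning cohorts of 20-40 males).
#' @param naive_mean mean naive courtship index, in `(0, 1]`.
#' @param suppression planted suppression effect (`<= 1`);
#'   `1 - E[CI_trained] / E[CI_naive]` before clipping.
#' @param noise_sd standard deviation of the per-fly noise.
#' @param seed integer seed.
#' @return A `CourtshipDataset` list: `naive_cis`, `trained_cis`,
#'   `suppression`, `naive_mean`.
#' @export
simulate_courtship <- function(n_naive = 30L, n_trained = 30L,
                               naive_mean = 0.6, suppression = 0.4,
                               noise_sd = 0.15, seed = 1L) {
  check_number(naive_mean, "naive_mean", min = 0, max = 1, strict_min = TRUE)
  check_number(suppression, "suppression", max = 1)
  check_number(noise_sd, "noise_sd", min = 0)
  with_substream(seed, "courtship", {
    clip01 <- function(x) pmin(pmax(x, 0), 1)
    naive <- clip01(stats::rnorm(n_naive, naive_mean, noise_sd))
    trained <- if (suppression == 1) rep(0, n_trained) else
      clip01(stats::rnorm(n_trained, naive_mean * (1 - suppression), noise_sd))
    structure(list(naive_cis = naive, trained_cis = trained,
                   suppression = suppression, naive_mean = naive_mean),
              class = "CourtshipDataset")
  })
}
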