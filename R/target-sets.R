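#' Expression pre-filter on a count matrix
#'
#' Removes genes that have no count in any sample or do not reach a CPM
#' (counts per million) above 0.5 in at least 3 samples.
#'
#' @param counts numeric matrix, genes x samples (>= 3 samples), with gene
#'   identifiers as row names.
#' @param cpm_threshold CPM cutoff (strict; default 0.5).
#' @param min_samples minimum number of samples above the cutoff (default 3).
#' @return Character vector of retained gene identifiers.
#' @export
cpm_filter <- function(counts, cpm_threshold = 0.5, min_samples = 3L) {
  if (ncol(counts) < min_samples)
    stop_axonloc(sprintf("need >= %d samples", min_samples))
  totals <- colSums(counts)
  if (any(totals == 0))
    stop_axonloc("sample with zero total count: ",
                 paste(colnames(counts)[totals == 0], collapse = ", "))
  cpm <- sweep(counts, 2L, totals, `/`) * 1e6
  keep <- rowSums(cpm > cpm_threshold) >= min_samples & rowSums(counts) > 0
  rownames(counts)[keep]
}

#' Classify genes as synaptically enriched or depleted
#'
#' A gene is `enriched` when `log2FC >= 0.85` and `padj < 0.05`, `depleted`
#' when `log2FC <= -0.85` and `padj < 0.05`, and `neither` otherwise. Genes
#' with a missing adjusted p-value are labelled `neither` with a warning.
#'
#' @param stats data frame with columns `gene_id`, `log2FC`, `padj`.
#' @param lfc_threshold absolute log2 fold-change cutoff (non-strict;
#'   default 0.85).
#' @param padj_threshold adjusted p-value cutoff (strict; default 0.05).
#' @return Character vector of labels (`enriched` / `depleted` / `neither`)
#'   named by `gene_id`; the three labels partition the input.
#' @export
classify_synaptic <- function(stats, lfc_threshold = 0.85,
                              padj_threshold = 0.05) {
  if (anyNA(stats$padj))
    warning(sprintf("%d gene(s) with missing padj labelled 'neither'",
                    sum(is.na(stats$padj))))
  sig <- !is.na(stats$padj) & stats$padj < padj_threshold
  lab <- rep("neither", nrow(stats))
  lab[sig & stats$log2FC >= lfc_threshold] <- "enriched"
  lab[sig & stats$log2FC <= -lfc_threshold] <- "depleted"
  stats::setNames(lab, stats$gene_id)
}

#' Select RIP targets robust across all comparisons
#'
#' Keeps genes whose log2 fold change exceeds 1 (strictly) in every
#' bound-vs-control comparison.
#'
#' @param lfc data frame or matrix of per-comparison log2 fold changes
#'   (genes x comparisons) with gene identifiers as row names, or a data
#'   frame with a `gene_id` column and one column per comparison.
#' @param threshold strict log2FC cutoff (default 1).
#' @return Character vector of gene identifiers.
#' @export
rip_gate <- function(lfc, threshold = 1) {
  if (is.data.frame(lfc) && "gene_id" %in% names(lfc)) {
    rownames(lfc) <- lfc$gene_id
    lfc <- lfc[, setdiff(names(lfc), "gene_id"), drop = FALSE]
  }
  lfc <- as.matrix(lfc)
  if (ncol(lfc) < 1L) stop_axonloc("need >= 1 comparison column")
  rownames(lfc)[rowSums(lfc > threshold) == ncol(lfc)]
}

#' Three-way overlap of synaptosome, RIP and iCLIP target sets
#'
#' The synaptosome arm contributes genes with `log2FC > 0` (strict); the
#' triple intersection with the RIP and iCLIP sets identifies candidate
#' Imp-dependent axonally localized mRNAs.
#'
#' @param synaptosome_stats data frame with `gene_id` and `log2FC`.
#' @param rip_set,iclip_set character vectors of gene identifiers (e.g.
#'   from [rip_gate()] and [gate_iclip_targets()]).
#' @return An `OverlapResult` list: `synaptosome`, `rip`, `iclip` (the
#'   input sets) and `intersection`.
#' @export
triple_overlap <- function(synaptosome_stats, rip_set, iclip_set) {
  syn <- sort(unique(synaptosome_stats$gene_id[synaptosome_stats$log2FC > 0]))
  rip <- sort(unique(as.character(rip_set)))
  icl <- sort(unique(as.character(iclip_set)))
  if (length(intersect(syn, union(rip, icl))) == 0L &&
      length(syn) && (length(rip) || length(icl)))
    warning("synaptosome gene identifiers share no names with the other sets")
  structure(list(synaptosome = syn, rip = rip, iclip = icl,
                 intersection = intersect(intersect(syn, rip), icl)),
            class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf("OverlapResult: synaptosome %d, RIP %d, iCLIP %d; triple overlap %d\n",
              length(x$synaptosome), length(x$rip), length(x$iclip),
              length(x$intersection)))
  invisible(x)
}

#' Jaccard distance between two gene sets
#'
#' `d(A, B) = 1 - |A n B| / |A u B|`, the dissimilarity used to detect
#' redundant GO terms that share most of their genes.
#'
#' @param a,b vectors of gene identifiers (duplicates ignored).
#' @return Distance in `[0, 1]`; an error if both sets are empty.
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) stop_axonloc("Jaccard distance undefined for two empty sets")
  1 - length(intersect(a, b)) / u
}

#' Cluster GO terms by shared genes
#'
#' Computes the pairwise [jaccard_distance()] matrix between the terms'
#' gene sets, clusters it with average-linkage hierarchical clustering, and
#' cuts the tree at `cut_height`. Each cluster reports a representative
#' term: the member with the smallest summed distance to the other members
#' (ties to the first in input order).
#'
#' @param annotations named list of gene-identifier vectors (one per term),
#'   or a data frame with columns `term_id` and `gene_id` in long format.
#' @param cut_height tree cut height on the Jaccard distance scale
#'   (default 0.5).
#' @return A data frame with columns `term_id`, `cluster` and
#'   `representative` (logical).
#' @export
cluster_terms <- function(annotations, cut_height = 0.5) {
  if (is.data.frame(annotations))
    annotations <- split(annotations$gene_id, annotations$term_id)
  if (length(annotations) < 2L) stop_axonloc("need >= 2 terms to cluster")
  if (any(lengths(annotations) == 0L)) stop_axonloc("empty term gene set")
  n <- length(annotations)
  dm <- matrix(0, n, n, dimnames = list(names(annotations), names(annotations)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    dm[i, j] <- dm[j, i] <- jaccard_distance(annotations[[i]], annotations[[j]])
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  rep_flag <- logical(n)
  for (k in unique(cl)) {
    members <- which(cl == k)
    sums <- rowSums(dm[members, members, drop = FALSE])
    rep_flag[members[which.min(sums)]] <- TRUE
  }
  data.frame(term_id = names(annotations), cluster = unname(cl),
             representative = rep_flag, row.names = NULL,
             stringsAsFactors = FALSE)
}
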