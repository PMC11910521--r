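#' Spliced transcript model with UTR/CDS partition
#'
#' Internal coordinates are 0-based and half-open; transcript position 0 is
#' the transcript's 5' end on either strand. Exons are genomic intervals
#' sorted by genomic start; the CDS is a genomic span whose first and last
#' bases must fall inside exons. Region lengths satisfy
#' `L5 + Lcds + L3 = L` (the summed exon length) by construction.
#'
#' @param gene_id,transcript_id identifiers.
#' @param chromosome chromosome name (expected `X`, `Y`, `MT`, `2L`, `2R`,
#'   `3L` or `3R` after normalization).
#' @param strand `"+"` or `"-"`.
#' @param exons data frame / matrix with columns `start`, `end` (0-based,
#'   half-open genomic intervals; may be unsorted but must not overlap).
#' @param cds_start,cds_end genomic 0-based half-open span of the coding
#'   sequence.
#' @return A `TranscriptModel` list with the fields above plus `L5`,
#'   `Lcds`, `L3` and `L` (nucleotides).
#' @export
transcript_model <- function(gene_id, transcript_id, chromosome, strand,
                             exons, cds_start, cds_end) {
  if (!strand %in% c("+", "-")) stop_axonloc("strand must be '+' or '-'")
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$end <= exons$start))
    stop_axonloc(sprintf("%s: empty or inverted exon", transcript_id))
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop_axonloc(sprintf("%s: overlapping exons", transcript_id))
  if (cds_end <= cds_start)
    stop_axonloc(sprintf("%s: empty CDS", transcript_id))
  m <- structure(list(gene_id = gene_id, transcript_id = transcript_id,
                      chromosome = chromosome, strand = strand, exons = exons,
                      cds_start = cds_start, cds_end = cds_end),
                 class = "TranscriptModel")
  L <- sum(exons$end - exons$start)
  t1 <- genomic_to_transcript(m, if (strand == "+") cds_start else cds_end - 1L)
  t2 <- genomic_to_transcript(m, if (strand == "+") cds_end - 1L else cds_start)
  if (is.na(t1) || is.na(t2))
    stop_axonloc(sprintf("%s: CDS boundary outside exons", transcript_id))
  m$L <- L
  m$L5 <- t1
  m$Lcds <- t2 - t1 + 1L
  m$L3 <- L - t2 - 1L
  m
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (%s) %s%s: %d exons, L=%d (5'UTR %d / CDS %d / 3'UTR %d)\n",
              x$transcript_id, x$gene_id, x$chromosome, x$strand,
              nrow(x$exons), x$L, x$L5, x$Lcds, x$L3))
  invisible(x)
}

#' Map genomic positions to spliced transcript coordinates
#'
#' Strand-aware: transcript position 0 is the transcript's 5' end, so on the
#' minus strand the highest genomic exon base maps to 0. Positions outside
#' the model's exons (intronic or flanking) return `NA` ("not in exon").
#'
#' @param model a [transcript_model()].
#' @param genomic_position integer vector of 0-based genomic positions.
#' @param chromosome optional chromosome of the queried positions; an error
#'   is raised when it does not match the model.
#' @return Integer vector of 0-based transcript positions (`NA` when not in
#'   an exon).
#' @export
genomic_to_transcript <- function(model, genomic_position, chromosome = NULL) {
  if (!is.null(chromosome) && any(chromosome != model$chromosome))
    stop_axonloc(sprintf("chromosome mismatch: query on %s, model %s on %s",
                         paste(unique(chromosome), collapse = ","),
                         model$transcript_id, model$chromosome))
  ex <- model$exons
  widths <- ex$end - ex$start
  before <- cumsum(c(0L, widths))[seq_len(nrow(ex))]
  out <- rep(NA_integer_, length(genomic_position))
  for (i in seq_len(nrow(ex))) {
    hit <- genomic_position >= ex$start[i] & genomic_position < ex$end[i]
    out[hit] <- before[i] + (genomic_position[hit] - ex$start[i])
  }
  if (model$strand == "-") out <- sum(widths) - 1L - out
  as.integer(out)
}

#' @rdname genomic_to_transcript
#' @param transcript_position integer vector of 0-based transcript
#'   positions in `[0, L)`.
#' @return `transcript_to_genomic`: integer vector of 0-based genomic
#'   positions; the two maps are mutual inverses on exonic positions.
#' @export
transcript_to_genomic <- function(model, transcript_position) {
  if (any(transcript_position < 0L | transcript_position >= model$L))
    stop_axonloc(sprintf("transcript position out of range [0, %d)", model$L))
  ex <- model$exons
  widths <- ex$end - ex$start
  plus_pos <- if (model$strand == "-") model$L - 1L - transcript_position else transcript_position
  before <- cumsum(c(0L, widths))
  bin <- findInterval(plus_pos, before, rightmost.closed = FALSE)
  as.integer(ex$start[bin] + (plus_pos - before[bin]))
}

#' Assign a transcript position to the 5'UTR, CDS or 3'UTR
#'
#' The 5'UTR runs from the mRNA start to the CDS start and the 3'UTR from
#' the CDS end to the mRNA end; boundaries are half-open, so the position
#' exactly at the CDS start is CDS and the position exactly at the CDS end
#' is 3'UTR.
#'
#' @param model a [transcript_model()].
#' @param transcript_position integer vector of 0-based positions in
#'   `[0, L)`.
#' @return Character vector with values `"5UTR"`, `"CDS"`, `"3UTR"`.
#' @export
assign_region <- function(model, transcript_position) {
  if (any(transcript_position < 0L | transcript_position >= model$L))
    stop_axonloc(sprintf("transcript position out of range [0, %d)", model$L))
  ifelse(transcript_position < model$L5, "5UTR",
         ifelse(transcript_position < model$L5 + model$Lcds, "CDS", "3UTR"))
}

#' Rescale a transcript position onto the 0-100 metatranscript
#'
#' Positions in the 5'UTR, CDS and 3'UTR are linearly rescaled onto the
#' intervals 0-19, 20-69 and 70-100 of a virtual common transcript: within
#' a region of length `Lr` with 0-based region offset `p`, the
#' meta-coordinate is `lo + p / (Lr - 1) * (hi - lo)` (and `lo` when
#' `Lr = 1`), so a region's first base maps to its interval's lower bound
#' and its last base to the upper bound. The transcript's last base maps to
#' 100.
#'
#' @inheritParams assign_region
#' @return Numeric vector of meta-coordinates in `[0, 100]`.
#' @export
rescale_position <- function(model, transcript_position) {
  region <- assign_region(model, transcript_position)
  bounds <- list(`5UTR` = c(0, 19), CDS = c(20, 69), `3UTR` = c(70, 100))
  starts <- c(`5UTR` = 0L, CDS = model$L5, `3UTR` = model$L5 + model$Lcds)
  lens <- c(`5UTR` = model$L5, CDS = model$Lcds, `3UTR` = model$L3)
  out <- numeric(length(transcript_position))
  for (r in names(bounds)) {
    hit <- region == r
    if (!any(hit)) next
    p <- transcript_position[hit] - starts[[r]]
    Lr <- lens[[r]]
    b <- bounds[[r]]
    out[hit] <- if (Lr > 1L) b[1L] + p / (Lr - 1L) * (b[2L] - b[1L]) else b[1L]
  }
  out
}

normalize_chromosome <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom))
  chrom[chrom %in% c("M", "mitochondrion_genome", "dmel_mitochondrion_genome")] <- "MT"
  chrom
}

reference_chromosomes <- c("X", "Y", "MT", "2L", "2R", "3L", "3R")

#' Build the standardized transcript reference
#'
#' Constructs one [transcript_model()] per gene from an exon/CDS annotation
#' table: transcripts not assigned to the X, Y, MT, 2L, 2R, 3L or 3R
#' chromosomes are removed first, then non-coding transcripts (no CDS
#' record, or a non-coding `transcript_biotype`) and transcripts flagged
#' with ambiguous annotation status (`incomplete`, `unknown`), and finally
#' only the longest transcript of each gene (by summed exon length; ties go
#' to the lexicographically smallest transcript identifier) is retained.
#' Transcripts whose CDS falls outside their exons are rejected with a
#' warning naming the record.
#'
#' @param annotation data frame in GTF convention (1-based, closed
#'   intervals) with columns `seqnames`, `type` (`"exon"` / `"CDS"` rows
#'   are used), `start`, `end`, `strand`, `gene_id`, `transcript_id`, and
#'   optionally `transcript_biotype` and `status`. Typically produced by
#'   [read_gtf()] or [simulate_annotation()].
#' @return Named list of `TranscriptModel` objects (one per gene, named by
#'   `gene_id`).
#' @export
build_reference <- function(annotation) {
  a <- as.data.frame(annotation)
  need <- c("seqnames", "type", "start", "end", "strand", "gene_id", "transcript_id")
  if (!all(need %in% names(a)))
    stop_axonloc("annotation must have columns: ", paste(need, collapse = ", "))
  a$seqnames <- normalize_chromosome(a$seqnames)
  a <- a[a$seqnames %in% reference_chromosomes, , drop = FALSE]
  if ("transcript_biotype" %in% names(a)) {
    coding_tx <- unique(a$transcript_id[a$transcript_biotype %in% "protein_coding"])
    a <- a[a$transcript_id %in% coding_tx, , drop = FALSE]
  }
  if ("status" %in% names(a)) {
    bad <- unique(a$transcript_id[a$status %in% c("incomplete", "unknown")])
    a <- a[!a$transcript_id %in% bad, , drop = FALSE]
  }
  ex <- a[a$type == "exon", , drop = FALSE]
  cds <- a[a$type == "CDS", , drop = FALSE]
  coding <- intersect(unique(ex$transcript_id), unique(cds$transcript_id))
  ex <- ex[ex$transcript_id %in% coding, , drop = FALSE]
  if (!nrow(ex)) return(structure(list(), names = character(0)))

  tx_len <- tapply(ex$end - ex$start + 1L, ex$transcript_id, sum)
  tx_gene <- tapply(ex$gene_id, ex$transcript_id, `[`, 1L)
  tx <- data.frame(transcript_id = names(tx_len), gene_id = as.character(tx_gene),
                   len = as.integer(tx_len), stringsAsFactors = FALSE)
  tx <- tx[order(tx$gene_id, -tx$len, tx$transcript_id), , drop = FALSE]
  chosen <- tx[!duplicated(tx$gene_id), , drop = FALSE]

  models <- list()
  for (i in seq_len(nrow(chosen))) {
    tid <- chosen$transcript_id[i]
    exi <- ex[ex$transcript_id == tid, , drop = FALSE]
    cdi <- cds[cds$transcript_id == tid, , drop = FALSE]
    m <- tryCatch(
      transcript_model(gene_id = chosen$gene_id[i], transcript_id = tid,
                       chromosome = exi$seqnames[1L], strand = exi$strand[1L],
                       exons = data.frame(start = exi$start - 1L, end = exi$end),
                       cds_start = min(cdi$start) - 1L, cds_end = max(cdi$end)),
      error = function(e) {
        warning(sprintf("transcript %s rejected: %s", tid, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (!is.null(m)) models[[m$gene_id]] <- m
  }
  models
}
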