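# File format boundaries. Internally everything is 0-based half-open;
# GTF (1-based, closed) and BED (0-based, half-open) conventions are
# converted here and nowhere else.

#' Read and write transcript annotations as GTF
#'
#' @param path file path.
#' @return `read_gtf`: a data frame in the convention expected by
#'   [build_reference()] (1-based closed `start`/`end`, plus `seqnames`,
#'   `type`, `strand`, `gene_id`, `transcript_id` and any further GTF
#'   attributes present).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  df
}

#' @rdname read_gtf
#' @param annotation data frame with columns `seqnames`, `type`, `start`,
#'   `end` (1-based closed), `strand`, `gene_id`, `transcript_id` and
#'   optional extra attribute columns.
#' @export
write_gtf <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$seqnames,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    strand = annotation$strand)
  extra <- setdiff(names(annotation), c("seqnames", "start", "end", "strand",
                                        "width"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(annotation[, extra, drop = FALSE])
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read and write single-nucleotide crosslink peaks as BED6
#'
#' The BED score column carries the supporting cDNA count; each record is a
#' one-base interval anchored at the crosslink site.
#'
#' @param path file path.
#' @return `read_bed_peaks`: data frame with `chromosome`, `position`
#'   (0-based), `name`, `count`, `strand`.
#' @export
read_bed_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chromosome = as.character(GenomicRanges::seqnames(gr)),
             position = GenomicRanges::start(gr) - 1L,
             name = if (is.null(gr$name)) NA_character_ else gr$name,
             count = if (is.null(gr$score)) NA_integer_ else as.integer(gr$score),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname read_bed_peaks
#' @param peaks data frame with columns `chromosome`, `position` (0-based
#'   single-nucleotide anchor), `strand`, `count`, and optionally `name`.
#' @export
write_bed_peaks <- function(peaks, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chromosome,
    ranges = IRanges::IRanges(start = peaks$position + 1L, width = 1L),
    strand = peaks$strand,
    name = peaks$name %||% paste0("peak", seq_len(nrow(peaks))),
    score = peaks$count)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write detected spots or ground truth to TSV
#'
#' @param spots data frame of spots (um coordinates plus any extra
#'   columns).
#' @param path output path.
#' @export
write_spots_tsv <- function(spots, path) {
  utils::write.table(spots, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spots_tsv
#' @export
read_spots_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
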