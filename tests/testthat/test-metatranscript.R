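test_that("reference building applies chromosome, biotype, status and longest rules", {
  mk <- function(tx, gene, chrom, len, type = "exon", biotype = "protein_coding",
                 status = "validated", start = 1000L) {
    data.frame(seqnames = chrom, type = type, start = start,
               end = start + len - 1L, strand = "+", gene_id = gene,
               transcript_id = tx, transcript_biotype = biotype,
               status = status, stringsAsFactors = FALSE)
  }
  cds <- function(tx, gene, chrom, start, end, ...)
    mk(tx, gene, chrom, end - start + 1L, type = "CDS", start = start, ...)
  anno <- rbind(
    mk("t1a", "g1", "2L", 1500L), cds("t1a", "g1", "2L", 1200L, 1800L),
    mk("t1b", "g1", "2L", 2000L), cds("t1b", "g1", "2L", 1200L, 1800L),
    mk("t2", "g2", "4", 1000L), cds("t2", "g2", "4", 1200L, 1500L),
    mk("t3", "g3", "3R", 900L, biotype = "lncRNA"),
    mk("t4", "g4", "X", 800L, status = "incomplete"),
    cds("t4", "g4", "X", 1100L, 1300L),
    mk("t5", "g5", "chr2R", 600L), cds("t5", "g5", "chr2R", 1100L, 1300L))
  ref <- build_reference(anno)
  expect_setequal(names(ref), c("g1", "g5"))          # g2: chrom 4; g3: non-coding; g4: incomplete
  expect_identical(ref$g1$transcript_id, "t1b")       # longest kept
  expect_identical(ref$g5$chromosome, "2R")           # chr prefix normalized

  # equal lengths: lexicographically smallest transcript id wins
  tie <- rbind(mk("tB", "g6", "3L", 1000L), cds("tB", "g6", "3L", 1200L, 1500L),
               mk("tA", "g6", "3L", 1000L), cds("tA", "g6", "3L", 1200L, 1500L))
  expect_identical(build_reference(tie)$g6$transcript_id, "tA")

  # CDS outside the exons is rejected with the record identifier
  bad <- rbind(mk("tbad", "g7", "2L", 500L), cds("tbad", "g7", "2L", 5000L, 5300L))
  expect_warning(ref_bad <- build_reference(bad), "tbad")
  expect_length(ref_bad, 0L)
})

test_that("region lengths partition every model exactly", {
  ann <- simulate_annotation(25, seed = 6L)
  for (m in ann$models) {
    expect_identical(m$L5 + m$Lcds + m$L3, m$L)
    expect_identical(m$L, as.integer(sum(m$exons$end - m$exons$start)))
    expect_gt(m$Lcds, 0L)
  }
})

test_that("genomic/transcript mapping is strand-aware and self-inverse", {
  for (strand in c("+", "-")) {
    m <- junction_transcript(strand)
    # origin: first transcript base is the 5'-most exon base of that strand
    origin_g <- if (strand == "+") 100L else 1699L
    expect_identical(genomic_to_transcript(m, origin_g), 0L)
    # intronic and flanking positions are not in any exon
    expect_true(is.na(genomic_to_transcript(m, 500L)))
    expect_true(is.na(genomic_to_transcript(m, 50L)))
    # round trip on 1000 random positions
    set.seed(13)
    tp <- sample(0:(m$L - 1L), 1000L, replace = TRUE)
    expect_identical(genomic_to_transcript(m, transcript_to_genomic(m, tp)), tp)
  }
  expect_error(genomic_to_transcript(junction_transcript("+"), 150L,
                                     chromosome = "2L"), "mismatch")
})

test_that("mirroring a gene to the minus strand leaves the mapping unchanged", {
  plus <- junction_transcript("+")
  C <- 2000L  # mirror genome coordinate: g -> C - 1 - g
  minus <- transcript_model("gJx", "tJx", "3R", "-",
                            data.frame(start = C - plus$exons$end,
                                       end = C - plus$exons$start),
                            cds_start = C - plus$cds_end,
                            cds_end = C - plus$cds_start)
  expect_identical(minus$L5, plus$L5)
  expect_identical(minus$L3, plus$L3)
  set.seed(21)
  g <- transcript_to_genomic(plus, sample(0:(plus$L - 1L), 300L, replace = TRUE))
  expect_identical(genomic_to_transcript(minus, C - 1L - g),
                   genomic_to_transcript(plus, g))
})

test_that("region assignment and rescaling hit the printed boundaries", {
  m <- toy_transcript()
  expect_identical(assign_region(m, m$L5), "CDS")              # CDS start
  expect_identical(assign_region(m, m$L5 + m$Lcds), "3UTR")    # CDS end
  expect_identical(assign_region(m, 0L), "5UTR")
  expect_error(assign_region(m, m$L), "range")

  expect_equal(rescale_position(m, 0L), 0)
  expect_equal(rescale_position(m, m$L5 - 1L), 19)
  expect_equal(rescale_position(m, m$L5), 20)
  expect_equal(rescale_position(m, m$L5 + m$Lcds - 1L), 69)
  expect_equal(rescale_position(m, m$L5 + m$Lcds), 70)
  expect_equal(rescale_position(m, m$L - 1L), 100)

  # a transcript without a 5'UTR starts in the CDS at meta 20
  no5 <- transcript_model("g", "t", "X", "+", data.frame(start = 0L, end = 900L),
                          cds_start = 0L, cds_end = 600L)
  expect_identical(assign_region(no5, 0L), "CDS")
  expect_equal(rescale_position(no5, 0L), 20)

  # monotone within regions, never outside [0, 100]
  meta <- rescale_position(m, 0:(m$L - 1L))
  expect_true(all(meta >= 0 & meta <= 100))
  expect_true(all(diff(meta) > 0))
})

test_that("metaprofile pools qualifying transcripts and integrates to 1", {
  trapz <- function(p) sum((p$density[-1] + p$density[-length(p$density)]) / 2 *
                             diff(p$grid))
  utr3 <- simulate_annotation(20, region_bias = c(0, 0, 1), seed = 7L)
  prof <- metaprofile(utr3$models, utr3$peaks)
  expect_lt(abs(trapz(prof) - 1), 0.01)
  mass3 <- sum(prof$density[prof$grid >= 70]) / sum(prof$density)
  expect_gte(mass3, 0.95)

  unif <- simulate_annotation(60, region_bias = c(1, 1, 1) / 3,
                              min_peaks_per_transcript = 40L, seed = 8L,
                              prob_significant = 1)
  pu <- metaprofile(unif$models, unif$peaks)
  expect_lt(abs(trapz(pu) - 1), 0.01)
  mid <- pu$grid >= 10 & pu$grid <= 90    # away from reflection boundaries
  expect_true(all(abs(pu$density[mid] - 0.01) < 0.2 * 0.01 + 3 * sd(pu$density[mid])))

  # the >= 20 significant-peak rule is a strict gate per transcript
  m <- toy_transcript()
  mk_peaks <- function(n) data.frame(
    transcript_id = "tToy",
    position = transcript_to_genomic(
      m, as.integer(seq(m$L5 + m$Lcds, m$L - 1L, length.out = n))),
    significant = TRUE)
  expect_error(metaprofile(list(m), mk_peaks(19)), "20")
  p20 <- metaprofile(list(m), mk_peaks(20))
  expect_identical(p20$n_transcripts, 1L)
  expect_identical(p20$n_peaks, 20L)
})

test_that("iCLIP target gating requires a significant peak with 5 cDNAs", {
  pk <- data.frame(gene_id = c("a", "a", "b", "c", "d"),
                   count = c(4L, 3L, 5L, 50L, 5L),
                   significant = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_setequal(gate_iclip_targets(pk), c("b", "d"))
  expect_identical(gate_iclip_targets(pk[0, ]), character(0))
})

test_that("3'UTR quantification restricts to the 3'UTR and normalizes by median of ratios", {
  ann <- simulate_annotation(8, seed = 10L)
  models <- ann$models
  set.seed(31)
  make_sample <- function(scale = 1) do.call(rbind, lapply(models, function(m) {
    tp <- sort(sample(0:(m$L - 1L), 40L))
    data.frame(chromosome = m$chromosome,
               position = transcript_to_genomic(m, tp), strand = m$strand,
               count = 1L + rpois(40L, 5 * scale), row.names = NULL)
  }))
  a <- make_sample()
  # identical samples: size factors 1, normalized = raw
  same <- quantify_3utr(models, list(s1 = a, s2 = a))
  expect_equal(unname(same$size_factors), c(1, 1))
  expect_equal(same$normalized, same$raw)

  # doubling all counts doubles the size factor, normalized counts agree
  b <- a; b$count <- a$count * 2L
  dbl <- quantify_3utr(models, list(s1 = a, s2 = b))
  expect_equal(unname(dbl$size_factors[2] / dbl$size_factors[1]), 2)
  expect_equal(dbl$normalized[, 1], dbl$normalized[, 2])

  # a CDS-only crosslink contributes nothing
  m <- toy_transcript()
  in_cds <- data.frame(chromosome = "2L",
                       position = transcript_to_genomic(m, m$L5 + 5L),
                       strand = "+", count = 100L)
  in_utr <- data.frame(chromosome = "2L",
                       position = transcript_to_genomic(m, m$L5 + m$Lcds + 5L),
                       strand = "+", count = 7L)
  q <- quantify_3utr(list(m), list(s1 = rbind(in_cds, in_utr),
                                   s2 = in_utr))
  expect_identical(unname(q$raw[1, ]), c(7, 7))

  expect_error(quantify_3utr(models, list(s1 = a)), ">= 2 samples")
  zero <- a; zero$count <- 0L
  expect_error(quantify_3utr(models, list(s1 = a, s2 = zero)), "all-zero")
})

test_that("size factors agree with the established median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(5)
  mat <- matrix(rpois(300, 50) * rep(c(1, 2, 0.5), each = 100), ncol = 3,
                dimnames = list(paste0("g", 1:100), paste0("s", 1:3)))
  expect_equal(unname(size_factors(mat)),
               unname(DESeq2::estimateSizeFactorsForMatrix(mat)),
               tolerance = 1e-10)
})
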