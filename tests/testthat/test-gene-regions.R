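make_models <- function() {
  tx1 <- list(transcript_id = "tx1", gene_id = "g1",
              biotype = "protein_coding", strand = "+", seqid = "chr1",
              exons = rbind(c(100L, 200L), c(300L, 450L)),
              cds = rbind(c(150L, 200L), c(300L, 400L)),
              utr5 = rbind(c(100L, 150L)),
              utr3 = rbind(c(400L, 450L)),
              introns = intron_intervals(rbind(c(100L, 200L),
                                               c(300L, 450L))))
  tx2 <- list(transcript_id = "tx2", gene_id = "g2",
              biotype = "nonsense_mediated_decay", strand = "-",
              seqid = "chr1",
              exons = rbind(c(600L, 900L)),
              cds = rbind(c(700L, 850L)),
              utr5 = rbind(c(850L, 900L)),   # 5'UTR at high coords on -
              utr3 = rbind(c(600L, 700L)),
              introns = matrix(integer(0), ncol = 2))
  list(g1 = list(gene_id = "g1", seqid = "chr1", strand = "+",
                 start = 100L, end = 450L,
                 transcripts = list(tx1 = tx1)),
       g2 = list(gene_id = "g2", seqid = "chr1", strand = "-",
                 start = 600L, end = 900L,
                 transcripts = list(tx2 = tx2)))
}

test_that("GFF3 writing and reading round-trips gene models", {
  models <- make_models()
  path <- tempfile(fileext = ".gff3")
  write_gff3(models, path)
  back <- read_gff3(path)
  expect_named(back, c("g1", "g2"))
  tx1 <- back$g1$transcripts$tx1
  expect_equal(unname(tx1$exons), rbind(c(100L, 200L), c(300L, 450L)))
  # inter-exon gap becomes the intron
  expect_equal(unname(tx1$introns), rbind(c(200L, 300L)))
  tx2 <- back$g2$transcripts$tx2
  expect_identical(nrow(tx2$introns), 0L)   # single exon: zero introns
  expect_identical(tx2$biotype, "nonsense_mediated_decay")
  # minus strand: 3'UTR sits at lower genomic coordinates than the CDS
  expect_lt(max(tx2$utr3[, 2]), min(tx2$cds[, 1]) + 1L)
})

test_that("orphan features are reported by id", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t1\t500\t.\t+\t.\tID=gA",
               "chr1\t.\tmRNA\t1\t500\t.\t+\t.\tID=txA;Parent=missing_gene"),
             path)
  expect_error(read_gff3(path), "txA")
})

test_that("region extraction splices and orients by transcript strand", {
  models <- make_models()
  genome <- c(chr1 = generate_background(1000, 0.5, seed = 77))
  regions <- extract_region_sequences(models, genome)

  # + strand single-interval 3'UTR: verbatim substring
  expect_identical(regions$utr3[["tx1"]], substr(genome[["chr1"]], 401, 450))
  # - strand: reverse complement of the genomic substring
  expect_identical(regions$utr3[["tx2"]],
                   revcomp(substr(genome[["chr1"]], 601, 700)))
  # two-interval CDS: concatenation in transcript order
  expect_identical(regions$cds[["tx1"]],
                   paste0(substr(genome[["chr1"]], 151, 200),
                          substr(genome[["chr1"]], 301, 400)))
  # partition sanity: |cds| + |utr5| + |utr3| = sum of exon lengths
  tx1 <- models$g1$transcripts$tx1
  expect_identical(nchar(regions$cds[["tx1"]]) +
                     nchar(regions$utr5[["tx1"]]) +
                     nchar(regions$utr3[["tx1"]]),
                   sum(tx1$exons[, 2] - tx1$exons[, 1]))
  # genes category: whole gene span, one entry per gene
  expect_identical(nchar(regions$genes[["g1"]]), 350L)
  expect_error(extract_region_sequences(models, c(chr1 = "ACGT")),
               "out of bounds")
})

test_that("gc_content counts G+C over non-N bases only", {
  expect_identical(gc_content("ATAT"), 0)
  expect_identical(gc_content("GCGC"), 1)
  expect_identical(gc_content("ATGC"), 0.5)
  expect_identical(gc_content("ATGCNNNN"), 0.5)
  expect_error(gc_content(""), "undefined")
  expect_error(gc_content("NNN"), "undefined")
  # strand invariance
  s <- generate_background(3000, 0.37, seed = 9)
  expect_equal(gc_content(revcomp(s)), gc_content(s))
})

test_that("point positions map onto hits with half-open semantics", {
  h <- repeat_hits(query_id = "q1", start = 100L, end = 400L,
                   strand = "+", family = "AluY")
  pos <- data.frame(query_id = c("q1", "q1", "q1", "q2"),
                    position = c(150L, 400L, 99L, 150L))
  ann <- annotate_positions(h, pos)
  expect_identical(ann$in_repeat, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(ann$family[1], "AluY")

  none <- annotate_positions(repeat_hits(), pos)
  expect_false(any(none$in_repeat))

  # brute-force interval scan oracle on random hits/positions
  set.seed(12)
  hits <- repeat_hits(query_id = "q", start = st <- sample(0:900, 10),
                      end = st + sample(20:80, 10, replace = TRUE),
                      strand = "+", family = "AluY")
  pos <- data.frame(query_id = "q", position = sample(0:1000, 50))
  ann <- annotate_positions(hits, pos)
  brute <- vapply(pos$position, function(p)
    any(hits$start <= p & p < hits$end), logical(1))
  expect_identical(ann$in_repeat, brute)
})

test_that("scanning extracted UTRs matches projecting genomic hits", {
  lib <- small_library()
  utr <- generate_iralu_utr(alu_subfamily_library(seed = 3), gap = 50,
                            divergence = 0, seed = 5,
                            family_first = "AluSz")
  # embed the UTR as the single-exon 3'UTR of a plus-strand transcript
  flank <- generate_background(300, 0.5, seed = 6)
  genome <- c(chrU = paste0(flank, utr$sequence))
  off <- nchar(flank)
  tx <- list(transcript_id = "txU", gene_id = "gU",
             biotype = "protein_coding", strand = "+", seqid = "chrU",
             exons = rbind(c(0L, off + nchar(utr$sequence))),
             cds = rbind(c(0L, off)),
             utr5 = matrix(integer(0), ncol = 2),
             utr3 = rbind(c(off, off + nchar(utr$sequence))),
             introns = matrix(integer(0), ncol = 2))
  models <- list(gU = list(gene_id = "gU", seqid = "chrU", strand = "+",
                           start = 0L, end = off + nchar(utr$sequence),
                           transcripts = list(txU = tx)))
  regions <- extract_region_sequences(models, genome)
  sub_lib <- alu_subfamily_library(seed = 3)
  h_utr <- scan_repeats(regions$utr3, sub_lib)
  h_gen <- scan_repeats(c(chrU = genome[["chrU"]]), sub_lib)
  # project genomic hits into UTR coordinates
  h_gen$start <- h_gen$start - off
  h_gen$end <- h_gen$end - off
  expect_identical(h_utr$start, h_gen$start)
  expect_identical(h_utr$end, h_gen$end)
  expect_identical(h_utr$strand, h_gen$strand)
})
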