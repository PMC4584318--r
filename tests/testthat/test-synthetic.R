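test_that("background generation controls length, composition and seed", {
  expect_identical(generate_background(0, 0.5, seed = 1), "")
  expect_error(generate_background(-1, 0.5, seed = 1), ">= 0")

  only_gc <- generate_background(1000, 1.0, seed = 7)
  expect_true(grepl("^[GC]+$", only_gc))
  only_at <- generate_background(500, 0.0, seed = 7)
  expect_true(grepl("^[AT]+$", only_at))

  # binomial sampling oracle: observed GC within 3 * sqrt(p(1-p)/n)
  s <- generate_background(100000, 0.5, seed = 42)
  expect_lt(abs(gc_content(s) - 0.5), 3 * sqrt(0.25 / 100000))

  expect_identical(generate_background(2000, 0.41, seed = 11),
                   generate_background(2000, 0.41, seed = 11))
  expect_false(generate_background(2000, 0.41, seed = 11) ==
                 generate_background(2000, 0.41, seed = 12))
})

test_that("consensus library respects spec, rejects duplicates, is seeded", {
  lib <- generate_consensus_library(c(FLAM = 120L, AluY = 300L), seed = 1)
  expect_named(lib, c("FLAM", "AluY"))
  expect_identical(nchar(lib), c(FLAM = 120L, AluY = 300L))
  expect_error(generate_consensus_library(c(AluY = 300, AluY = 310)),
               "duplicate")
  expect_error(generate_consensus_library(c(X = 10)), ">= 30")
  expect_identical(lib, generate_consensus_library(
    c(FLAM = 120L, AluY = 300L), seed = 1))
})

test_that("subfamily library members are related but distinct", {
  lib <- alu_subfamily_library(seed = 5)
  expect_identical(nchar(lib[["AluSz"]]), 311L)
  expect_identical(nchar(lib[["AluSg"]]), 307L)
  # relatedness: mismatch fraction over the shared prefix well below random
  a <- strsplit(substr(lib[["AluSz"]], 1, 307), "")[[1]]
  b <- strsplit(lib[["AluSg"]], "")[[1]]
  expect_lt(mean(a != b), 0.25)
  expect_gt(mean(a != b), 0)
})

test_that("mutate_copy is substitution-only with binomial realized rate", {
  lib <- small_library()
  expect_identical(mutate_copy(lib[["AluY"]], 0, seed = 1)$sequence,
                   lib[["AluY"]])
  expect_identical(mutate_copy("", 0.5, seed = 1)$sequence, "")

  m <- mutate_copy(lib[["AluY"]], 0.1, seed = 2)
  expect_identical(nchar(m$sequence), 300L)
  cons <- strsplit(lib[["AluY"]], "")[[1]]
  mut <- strsplit(m$sequence, "")[[1]]
  expect_equal(mean(cons != mut), m$realized_divergence)

  # mean realized divergence across seeds within 3 s.e. of the target
  real <- vapply(1:500, function(s)
    mutate_copy(lib[["AluY"]], 0.10, seed = s)$realized_divergence,
    numeric(1))
  se <- sqrt(0.1 * 0.9 / 300 / 500)
  expect_lt(abs(mean(real) - 0.10), 3 * se)
})

test_that("plant_copies substitutes non-overlapping, strand-aware copies", {
  lib <- small_library()
  bg <- generate_background(6000, 0.41, seed = 4)

  none <- plant_copies(bg, lib, synthetic_config(n_copies = 0, seed = 1))
  expect_identical(none$sequence, bg)
  expect_identical(nrow(none$truth), 0L)

  cfg <- synthetic_config(background_length = 6000, n_copies = 1,
                          divergence = 0, strand_prob_sense = 1, seed = 3)
  one <- plant_copies(bg, setNames(lib["AluY"], "AluY"), cfg)
  tr <- one$truth
  expect_identical(nrow(tr), 1L)
  # string-compare oracle: host substring equals the (unmutated) copy
  expect_identical(substr(one$sequence, tr$start + 1, tr$end), lib[["AluY"]])
  expect_identical(nchar(one$sequence), nchar(bg))

  cfg20 <- synthetic_config(background_length = 20000, n_copies = 20,
                            divergence = 0.05, seed = 8)
  big <- plant_copies(generate_background(20000, 0.41, seed = 5), lib, cfg20)
  expect_identical(nrow(big$truth), 20L)
  expect_false(any_overlap(big$truth))
  expect_true(all(big$truth$start >= 0 & big$truth$end <= 20000))
  expect_false(is.unsorted(big$truth$start))

  # antisense copies are reverse-complemented into the host
  cfg_anti <- synthetic_config(background_length = 6000, n_copies = 1,
                               divergence = 0, strand_prob_sense = 0,
                               seed = 3)
  anti <- plant_copies(bg, lib["AluY"], cfg_anti)
  tr <- anti$truth
  expect_identical(substr(anti$sequence, tr$start + 1, tr$end),
                   revcomp(lib[["AluY"]]))

  # impossible placement errors out
  expect_error(plant_copies(generate_background(350, 0.5, seed = 1), lib,
                            synthetic_config(n_copies = 40, seed = 1)),
               "overlap|length")
})

test_that("IRAlu UTR construction plants an inverted or control pair", {
  lib <- alu_subfamily_library(seed = 2)
  u <- generate_iralu_utr(lib, gap = 0, divergence = 0, seed = 1,
                          family_first = "AluSz", family_second = "AluSg")
  expect_true(u$is_iralu)
  expect_identical(u$truth$strand, c("+", "-"))
  expect_identical(u$truth$end - u$truth$start, c(311L, 307L))
  expect_identical(u$truth$start[2], u$truth$end[1])  # gap 0: adjacent
  expect_identical(substr(u$sequence, u$truth$start[1] + 1, u$truth$end[1]),
                   lib[["AluSz"]])
  expect_identical(substr(u$sequence, u$truth$start[2] + 1, u$truth$end[2]),
                   revcomp(lib[["AluSg"]]))

  ctrl <- generate_iralu_utr(lib, gap = 10, divergence = 0, seed = 1,
                             family_first = "AluSz",
                             family_second = "AluSg", orientation = "same")
  expect_false(ctrl$is_iralu)
  expect_identical(ctrl$truth$strand, c("+", "+"))
})

test_that("annotation table plants a detectable enriched term", {
  expect_error(generate_annotation_table(10, 2, fold_effect = 0.5),
               "fold_effect")

  single <- generate_annotation_table(50, 1, enriched_term = 1,
                                      fold_effect = 1, seed = 1)
  expect_identical(unique(single$table$term_id), "T0001")

  # simulation oracle: with fold 10, the planted term has the smallest
  # median Fisher p across replicates
  n_genes <- 500L; n_terms <- 8L; subset <- 50L
  pmat <- matrix(NA_real_, 100, n_terms)
  for (r in 1:100) {
    g <- generate_annotation_table(n_genes, n_terms, enriched_term = 2,
                                   fold_effect = 10, seed = 1000 + r,
                                   subset_size = subset)
    genes <- g$subset
    for (t in seq_len(n_terms)) {
      term <- sprintf("T%04d", t)
      members <- unique(g$table$gene_id[g$table$term_id == term])
      pmat[r, t] <- fisher_right_tail(length(intersect(members, genes)),
                                      length(members), subset, n_genes)
    }
  }
  med <- apply(pmat, 2, median)
  expect_identical(which.min(med), 2L)
})

test_that("truth tables round-trip through BED", {
  lib <- small_library()
  cfg <- synthetic_config(background_length = 8000, n_copies = 5,
                          divergence = 0.02, seed = 6)
  pl <- plant_copies(generate_background(8000, 0.41, seed = 2), lib, cfg)
  path <- tempfile(fileext = ".bed")
  write_truth_bed(pl$truth, "host1", path)
  bed <- read.table(path, sep = "\t")
  expect_identical(bed$V2, pl$truth$start)
  expect_identical(bed$V3, pl$truth$end)
  expect_identical(bed$V6, pl$truth$strand)
})
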