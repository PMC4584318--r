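test_that("scan recovers planted copies exactly and stays quiet on background", {
  lib <- small_library()
  # negative control: no planted copies
  bg <- generate_background(5000, 0.41, seed = 21)
  expect_identical(nrow(scan_repeats(c(neg = bg), lib)), 0L)

  # exact sense copy: one hit, exact interval, divergence 0
  cfg <- synthetic_config(background_length = 5000, n_copies = 1,
                          divergence = 0, strand_prob_sense = 1, seed = 2)
  pl <- plant_copies(bg, lib["AluY"], cfg)
  h <- scan_repeats(c(q = pl$sequence), lib["AluY"])
  expect_identical(nrow(h), 1L)
  expect_identical(h$start, pl$truth$start)
  expect_identical(h$end, pl$truth$end)
  expect_identical(h$strand, "+")
  expect_identical(h$divergence_pct, 0)
  expect_identical(h$score, 600L)  # 300 matches x 2

  # reverse-complemented query: mirror hit with flipped strand
  hrc <- scan_repeats(c(q = revcomp(pl$sequence)), lib["AluY"])
  expect_identical(nrow(hrc), 1L)
  expect_identical(hrc$strand, "-")
  expect_identical(hrc$start, 5000L - pl$truth$end)
  expect_identical(hrc$end, 5000L - pl$truth$start)

  expect_error(scan_repeats(c(q = bg), character(0)), "library")
  expect_identical(nrow(scan_repeats(c(q = strrep("N", 500)), lib)), 0L)
})

test_that("reported scores equal an independent local-alignment oracle", {
  lib <- small_library()
  cfg <- synthetic_config(background_length = 20000, n_copies = 12,
                          divergence = 0.08, seed = 31)
  pl <- plant_copies(generate_background(20000, 0.41, seed = 30), lib, cfg)
  h <- scan_repeats(c(q = pl$sequence), lib)
  expect_gte(nrow(h), 10L)
  for (i in seq_len(nrow(h))) {
    frag <- substr(pl$sequence, h$start[i] + 1, h$end[i])
    cons <- lib[[h$family[i]]]
    if (h$strand[i] == "-") cons <- revcomp(cons)
    expect_equal(h$score[i], biostrings_local_score(frag, cons))
  }
})

test_that("strand calls match truth at zero divergence", {
  lib <- small_library()
  cfg <- synthetic_config(background_length = 30000, n_copies = 15,
                          divergence = 0, strand_prob_sense = 0.5, seed = 44)
  pl <- plant_copies(generate_background(30000, 0.41, seed = 40), lib, cfg)
  h <- scan_repeats(c(q = pl$sequence), lib)
  expect_identical(nrow(h), nrow(pl$truth))
  expect_identical(h$start, pl$truth$start)
  expect_identical(h$strand, pl$truth$strand)
})

test_that("overlap resolution keeps the best-scoring non-redundant set", {
  two <- repeat_hits(query_id = "q", start = c(0, 500), end = c(300, 800),
                     strand = "+", family = c("AluY", "AluSx"),
                     score = c(400, 300))
  expect_identical(nrow(resolve_overlaps(two)), 2L)

  # 90% overlap: only the higher score survives
  ov <- repeat_hits(query_id = "q", start = c(0, 30), end = c(300, 330),
                    strand = "+", family = c("AluY", "AluSx"),
                    score = c(500, 300))
  kept <- resolve_overlaps(ov)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$score, 500L)

  # tie on score and start: alphabetical family wins
  tie <- repeat_hits(query_id = "q", start = c(0, 0), end = c(300, 300),
                     strand = c("+", "-"), family = c("AluY", "AluJb"),
                     score = 400)
  expect_identical(resolve_overlaps(tie)$family, "AluJb")

  # greedy contract on random hit sets: the kept set is conflict-free
  # and every dropped hit conflicts with a kept hit of at least its score
  set.seed(7)
  conflicts <- function(hits, i, j) {
    ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
    shorter <- min(hits$end[i] - hits$start[i], hits$end[j] - hits$start[j])
    ov > 0.5 * shorter
  }
  for (rep in 1:20) {
    n <- 5L
    st <- sample(0:400, n)
    hits <- repeat_hits(query_id = "q", start = st, end = st + 150,
                        strand = "+", family = sprintf("F%02d", 1:n),
                        score = sample(200:600, n))
    kept <- resolve_overlaps(hits, max_overlap_frac = 0.5)
    if (nrow(kept) > 1)
      for (i in 1:(nrow(kept) - 1)) for (j in (i + 1):nrow(kept))
        expect_false(conflicts(kept, i, j))
    dropped <- hits[!paste(hits$start, hits$family) %in%
                      paste(kept$start, kept$family), , drop = FALSE]
    for (d in seq_len(nrow(dropped))) {
      both <- rbind(dropped[d, ], kept)
      clash <- vapply(2:nrow(both), function(j) conflicts(both, 1, j) &&
                        both$score[j] >= both$score[1], logical(1))
      expect_true(any(clash))
    }
  }
})

test_that("RepeatMasker .out files parse, convert and round-trip", {
  header <- c("   SW  perc perc perc  query ...", "score div ...", "")
  path <- tempfile(fileext = ".out")
  writeLines(header, path)
  expect_identical(nrow(read_repeatmasker_out(path)), 0L)

  writeLines(c(header,
               " 1234 12.3 0.1 0.2 chr1 101 400 (5000) C AluSx SINE/Alu 1 300 (0) 1",
               "  800  5.0 0.0 0.0 chr1 900 1100 (4300) + L1PA3 LINE/L1 1 201 (0) 2"),
             path)
  h <- read_repeatmasker_out(path)
  expect_identical(h$start, c(100L, 899L))
  expect_identical(h$end, c(400L, 1100L))
  expect_identical(h$strand, c("-", "+"))
  expect_identical(h$family, c("AluSx", "L1PA3"))
  expect_identical(h$repeat_class, c("SINE/Alu", "LINE/L1"))

  # round trip through the writer
  rt <- tempfile(fileext = ".out")
  write_repeatmasker_out(h, rt)
  h2 <- read_repeatmasker_out(rt)
  expect_identical(h2$start, h$start)
  expect_identical(h2$end, h$end)
  expect_identical(h2$strand, h$strand)
  expect_identical(h2$family, h$family)
  expect_identical(h2$score, h$score)

  writeLines(c(header, "only three fields"), path)
  expect_error(read_repeatmasker_out(path), "line 4")
})

test_that("Alu classification covers dimers, monomers and fragments", {
  h <- repeat_hits(query_id = "q", start = c(0, 400, 800, 1200),
                   end = c(300, 700, 1100, 1500), strand = "+",
                   family = c("FLAM_C", "L1PA3", "Alu", "AluSx"))
  expect_identical(is_alu(h), c(TRUE, FALSE, TRUE, TRUE))
  expect_identical(repeat_class_of(c("FRAM", "FAM", "MIRb", "MER5A")),
                   c("SINE/Alu", "SINE/Alu", "SINE/other", "DNA"))
})
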