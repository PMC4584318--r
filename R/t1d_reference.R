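#' Published summary tables for the T1D candidate-gene set
#'
#' Loads the packaged reference tables for the 941 Type-1-diabetes
#' candidate genes: per-region sequence characteristics (counts, total
#' lengths, GC levels), the Alu/repeat distribution (element counts,
#' harbouring fractions, densities, coverage), Alu orientation counts in
#' UTRs for the T1D and background sets, and the 3'UTR IRAlu transcript
#' inventory. These printed aggregates are the inputs for the
#' re-derivation of densities, percentages and IRAlu gene counts; the
#' underlying raw sequence data are not redistributable.
#'
#' @return list of data.frames: `regions`, `alu`, `orientation`,
#'   `iralu` (the latter an `iralu_report`).
#' @export
t1d_reference <- function() {
  path <- function(f) system.file("extdata", f, package = "alulandscape",
                                  mustWork = TRUE)
  rd <- function(f) read.table(path(f), sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE, quote = "")
  list(regions = rd("t1d_region_summary.tsv"),
       alu = rd("t1d_alu_distribution.tsv"),
       orientation = rd("t1d_alu_orientation.tsv"),
       iralu = read_iralu_table(path("t1d_iralu_3utr.tsv")))
}

#' Chi-square bound for Alu-base enrichment against the genome
#'
#' Builds the 2x2 base-count table (Alu bases vs non-Alu bases, gene set
#' vs genome background) from coverage percentages and total lengths,
#' and returns the chi-square test. With gene-set coverage ~15% over
#' ~20 Mb against ~11% genome background, the p-value is far below the
#' 2.2e-16 display floor for any human-scale genome length.
#'
#' @param set_length gene-set total length in nt.
#' @param set_pct_covered percent of the gene set covered by Alus.
#' @param genome_length genome size in nt.
#' @param genome_pct_covered percent of the genome covered by Alus.
#' @param yates continuity correction flag.
#' @return a [chi_square_2x2()] result.
#' @export
alu_enrichment_test <- function(set_length, set_pct_covered,
                                genome_length, genome_pct_covered = 11,
                                yates = TRUE) {
  a <- round(set_length * set_pct_covered / 100)
  b <- set_length - a
  c <- round(genome_length * genome_pct_covered / 100)
  d <- genome_length - c
  chi_square_2x2(a, b, c, d, yates = yates)
}
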