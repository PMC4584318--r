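#' Percentage with explicit truncation or rounding
#'
#' Published repeat-landscape tables truncate percentages at the printed
#' precision (51.61 prints as 51.6) but round the integer percentages
#' quoted in prose (58.87 prints as 59); both conventions are explicit
#' modes here, with truncation the default.
#'
#' @param numerator,denominator counts; `denominator > 0`.
#' @param decimals decimal places to keep.
#' @param mode `"truncate"` (default) or `"round"`.
#' @return numeric percentage.
#' @export
#' @examples
#' percent(112, 217, 1)            # 51.6
#' percent(554, 941, 0, "round")   # 59
percent <- function(numerator, denominator, decimals = 2L,
                    mode = c("truncate", "round")) {
  mode <- match.arg(mode)
  if (any(denominator <= 0)) stop("denominator must be > 0", call. = FALSE)
  x <- 100 * numerator / denominator
  f <- 10^decimals
  if (mode == "truncate") floor(x * f + 1e-9) / f else round(x * f) / f
}

#' Repeat density: nt of sequence per Alu element
#'
#' Truncated (floored) integer, the convention of "one Alu element
#' occurrence per N nt" table rows.
#'
#' @param total_length total sequence length in nt.
#' @param n_alus number of Alu elements (>= 1).
#' @return integer-valued nt per Alu.
#' @export
#' @examples
#' alu_density(20074601, 11335)  # 1771
alu_density <- function(total_length, n_alus) {
  if (any(n_alus == 0))
    stop("density undefined when there are no Alu elements", call. = FALSE)
  floor(total_length / n_alus)
}

# union length of hit intervals per sequence, overlaps counted once
.covered_bases <- function(hits) {
  if (nrow(hits) == 0L) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(hits$start + 1L, hits$end))
  sum(IRanges::width(ir))
}

#' Summarise the repeat landscape of one region category
#'
#' Aggregates hits over a sequence set: counts of repeats and Alus,
#' fraction of sequences harbouring them, Alu-covered bases (interval
#' union, overlaps not double-counted), coverage percentage, density and
#' orientation tallies.
#'
#' @param hits a `repeat_hits` data.frame whose `query_id`s refer to
#'   `sequences`.
#' @param sequences named character vector of the category's sequences
#'   (or named integer vector of their lengths).
#' @param category label, e.g. "genes", "cds", "introns", "utr5", "utr3".
#' @param decimals decimal places for the percentage columns.
#' @return one-row data.frame of class `repeat_summary`.
#' @export
summarize_repeats <- function(hits, sequences, category = "genes",
                              decimals = 2L) {
  lens <- if (is.numeric(sequences)) sequences else
    setNames(nchar(sequences), names(sequences))
  if (!all(hits$query_id %in% names(lens)))
    stop("hits refer to sequences not in `sequences`", call. = FALSE)
  total_length <- sum(as.numeric(lens))
  alu <- hits[is_alu(hits), , drop = FALSE]
  n_alus <- nrow(alu)
  covered <- 0L
  for (qid in unique(alu$query_id))
    covered <- covered + .covered_bases(alu[alu$query_id == qid, , drop = FALSE])
  out <- data.frame(
    category = category,
    n_sequences = length(lens),
    total_length = total_length,
    n_repeats = nrow(hits),
    n_alus = n_alus,
    pct_seq_with_repeats = if (total_length > 0)
      percent(length(unique(hits$query_id)), length(lens), decimals) else NA,
    pct_seq_with_alus = if (total_length > 0)
      percent(length(unique(alu$query_id)), length(lens), decimals) else NA,
    alu_covered_bases = covered,
    pct_covered_by_alus = if (total_length > 0)
      percent(covered, total_length, decimals) else NA,
    density_nt_per_alu = if (n_alus > 0) alu_density(total_length, n_alus)
      else NA_real_,
    n_sense_alus = sum(alu$strand == "+"),
    n_antisense_alus = sum(alu$strand == "-"))
  class(out) <- c("repeat_summary", "data.frame")
  out
}

#' Orientation tally of Alu elements
#'
#' @param hits a `repeat_hits` data.frame; only Alu-class rows are
#'   counted. Must contain at least one Alu.
#' @param decimals decimal places for the percentages.
#' @param mode percentage mode, `"round"` for integer prose figures
#'   (default) or `"truncate"` for table-precision figures.
#' @return list with `n_sense`, `n_antisense`, `pct_sense`,
#'   `pct_antisense`.
#' @export
orientation_tally <- function(hits, decimals = 0L, mode = "round") {
  alu <- hits[is_alu(hits), , drop = FALSE]
  n_sense <- sum(alu$strand == "+")
  n_anti <- sum(alu$strand == "-")
  n <- n_sense + n_anti
  if (n == 0L) stop("no Alu elements to tally", call. = FALSE)
  list(n_sense = n_sense, n_antisense = n_anti,
       pct_sense = percent(n_sense, n, decimals, mode),
       pct_antisense = percent(n_anti, n, decimals, mode))
}

#' Rank genes by total repeat content
#'
#' @param hits a `repeat_hits` data.frame.
#' @param query_to_gene named character vector mapping `query_id` to gene
#'   name; defaults to the identity (query ids are gene names).
#' @param top_n number of rows to return.
#' @return data.frame (gene, n_repeats, n_sines, n_alus) in descending
#'   repeat order; ties broken by Alu count, then gene name.
#' @export
rank_genes <- function(hits, query_to_gene = NULL, top_n = 20L) {
  if (nrow(hits) == 0L)
    return(data.frame(gene = character(0), n_repeats = integer(0),
                      n_sines = integer(0), n_alus = integer(0)))
  gene <- if (is.null(query_to_gene)) hits$query_id
    else unname(query_to_gene[hits$query_id])
  sine <- startsWith(hits$repeat_class, "SINE")
  alu <- is_alu(hits)
  tab <- data.frame(gene = gene, one = 1L, sine = as.integer(sine),
                    alu = as.integer(alu))
  agg <- aggregate(cbind(one, sine, alu) ~ gene, data = tab, FUN = sum)
  names(agg) <- c("gene", "n_repeats", "n_sines", "n_alus")
  agg <- agg[order(-agg$n_repeats, -agg$n_alus, agg$gene), , drop = FALSE]
  rownames(agg) <- NULL
  head(agg, top_n)
}

#' Contribution of UTRs and CDS to mRNA length
#'
#' @param utr5_len,cds_len,utr3_len region lengths in nt (total > 0).
#' @return named numeric vector of percentages (`pct_utr5`, `pct_cds`,
#'   `pct_utr3`) summing to 100.
#' @export
length_contributions <- function(utr5_len, cds_len, utr3_len) {
  stopifnot(utr5_len >= 0, cds_len >= 0, utr3_len >= 0)
  total <- utr5_len + cds_len + utr3_len
  if (total == 0) stop("total mRNA length is zero", call. = FALSE)
  c(pct_utr5 = 100 * utr5_len / total,
    pct_cds = 100 * cds_len / total,
    pct_utr3 = 100 * utr3_len / total)
}
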