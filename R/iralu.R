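#' Find inverted Alu pairs in one 3'UTR
#'
#' A transcript's 3'UTR harbours an IRAlu when at least one sense and one
#' antisense Alu element co-occur in it (fragments of any length count
#' towards the inventory). All (sense, antisense) pairs whose members
#' both reach `min_alu_length` are additionally enumerated for duplex
#' folding; the primary pair maximises the combined alignment score, with
#' ties broken by smaller gap and then leftmost position.
#'
#' @param hits a `repeat_hits` data.frame restricted to one transcript's
#'   3'UTR, in transcript-oriented coordinates.
#' @param min_alu_length minimum element length for pair membership (the
#'   inventory and the IRAlu flag are not length-filtered).
#' @return list with `is_iralu` (logical), `pairs` (data.frame of
#'   sense/antisense member coordinates, `gap` between inner boundaries
#'   and `combined_score`) and `primary` (one-row data.frame or NULL).
#' @export
find_iralus <- function(hits, min_alu_length = 100L) {
  alu <- hits[is_alu(hits), , drop = FALSE]
  sense <- alu[alu$strand == "+", , drop = FALSE]
  anti <- alu[alu$strand == "-", , drop = FALSE]
  is_iralu <- nrow(sense) > 0L && nrow(anti) > 0L
  long <- function(h) h[(h$end - h$start) >= min_alu_length, , drop = FALSE]
  s <- long(sense); a <- long(anti)
  pairs <- NULL
  if (nrow(s) > 0L && nrow(a) > 0L) {
    idx <- expand.grid(si = seq_len(nrow(s)), ai = seq_len(nrow(a)))
    pairs <- data.frame(
      sense_family = s$family[idx$si], sense_start = s$start[idx$si],
      sense_end = s$end[idx$si], sense_score = s$score[idx$si],
      antisense_family = a$family[idx$ai],
      antisense_start = a$start[idx$ai], antisense_end = a$end[idx$ai],
      antisense_score = a$score[idx$ai])
    pairs$gap <- pmax(0L, pmax(pairs$sense_start, pairs$antisense_start) -
                        pmin(pairs$sense_end, pairs$antisense_end))
    pairs$combined_score <- pairs$sense_score + pairs$antisense_score
    ord <- order(-pairs$combined_score, pairs$gap,
                 pmin(pairs$sense_start, pairs$antisense_start))
    pairs <- pairs[ord, , drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(sense_family = character(0),
                        sense_start = integer(0), sense_end = integer(0),
                        sense_score = integer(0),
                        antisense_family = character(0),
                        antisense_start = integer(0),
                        antisense_end = integer(0),
                        antisense_score = integer(0), gap = integer(0),
                        combined_score = integer(0))
  }
  list(is_iralu = is_iralu, pairs = pairs,
       primary = if (nrow(pairs) > 0L) pairs[1L, , drop = FALSE] else NULL)
}

#' Build an IRAlu report over per-transcript 3'UTR hits
#'
#' One row per transcript: gene, transcript, total Alu count, ";"-joined
#' subfamilies, lengths and directions ("s"/"a"), biotype and the IRAlu
#' flag.
#'
#' @param utr_hits named list of `repeat_hits` data.frames, one per
#'   transcript (names = transcript ids), transcript-oriented.
#' @param transcript_gene named character vector transcript id -> gene.
#' @param transcript_biotype named character vector transcript id ->
#'   biotype label (normalised with [normalize_biotype()]).
#' @param min_alu_length passed to [find_iralus()].
#' @return data.frame of class `iralu_report`.
#' @export
iralu_report <- function(utr_hits, transcript_gene, transcript_biotype,
                         min_alu_length = 100L) {
  rows <- list()
  for (tid in names(utr_hits)) {
    h <- utr_hits[[tid]]
    alu <- h[is_alu(h), , drop = FALSE]
    if (nrow(alu) == 0L) next
    alu <- alu[order(alu$start), , drop = FALSE]
    res <- find_iralus(alu, min_alu_length)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = unname(transcript_gene[tid]),
      transcript_id = tid,
      total_alus = nrow(alu),
      subfamilies = paste(alu$family, collapse = ";"),
      lengths = paste(alu$end - alu$start, collapse = ";"),
      directions = paste(ifelse(alu$strand == "+", "s", "a"),
                         collapse = ";"),
      biotype = normalize_biotype(unname(transcript_biotype[tid])),
      is_iralu = res$is_iralu)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), transcript_id = character(0),
               total_alus = integer(0), subfamilies = character(0),
               lengths = character(0), directions = character(0),
               biotype = character(0), is_iralu = logical(0))
  rownames(out) <- NULL
  class(out) <- c("iralu_report", "data.frame")
  out
}

#' Count genes with IRAlu-positive transcripts
#'
#' @param report an `iralu_report` data.frame (or anything with `gene`,
#'   `is_iralu` and `biotype` columns).
#' @return list with `n_genes` (distinct genes having at least one
#'   IRAlu-positive transcript) and `n_protein_coding_genes` (distinct
#'   genes having at least one IRAlu-positive protein-coding transcript).
#' @export
tabulate_iralu_genes <- function(report) {
  pos <- report[report$is_iralu, , drop = FALSE]
  pc <- pos[pos$biotype == "protein_coding", , drop = FALSE]
  list(n_genes = length(unique(pos$gene)),
       n_protein_coding_genes = length(unique(pc$gene)))
}

#' Read a published-style IRAlu annotation table
#'
#' Reads a TSV with columns gene, transcript_id, total_alus,
#' subfamilies, lengths, directions (";"-joined, "s"/"a") and biotype,
#' and recomputes the IRAlu flag from the directions column.
#'
#' @param path TSV file; the packaged T1D candidate-gene 3'UTR inventory
#'   ships at `system.file("extdata", "t1d_iralu_3utr.tsv", package =
#'   "alulandscape")`.
#' @return an `iralu_report` data.frame.
#' @export
read_iralu_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "")
  dirs <- strsplit(gsub("[[:space:]]", "", tab$directions), ";")
  tab$biotype <- normalize_biotype(tab$biotype)
  tab$is_iralu <- vapply(dirs, function(d) any(d == "s") && any(d == "a"),
                         logical(1))
  class(tab) <- c("iralu_report", "data.frame")
  tab
}

#' Compare detected IRAlu flags against synthetic truth
#'
#' @param truth named logical vector (transcript id -> truly an IRAlu).
#' @param predicted named logical vector from the detector, same names.
#' @return list of confusion counts (`tp`, `fp`, `tn`, `fn`) plus
#'   `sensitivity` and `specificity` (NA when undefined).
#' @export
iralu_confusion <- function(truth, predicted) {
  stopifnot(setequal(names(truth), names(predicted)))
  predicted <- predicted[names(truth)]
  tp <- sum(truth & predicted); fn <- sum(truth & !predicted)
  fp <- sum(!truth & predicted); tn <- sum(!truth & !predicted)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}
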