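#' Alignment parameters for the repeat detector
#'
#' BLAST-like defaults: match +2, mismatch -3, affine gaps of length L
#' costing `gap_open + (L - 1) * gap_extend`, exact 12-mer seeds, and a
#' minimum reported score of 200 over at least 50 aligned nt. The x-drop
#' value bounds how far an extension is pursued past the current optimum
#' via the realignment band width.
#'
#' @param match,mismatch substitution scores (`match > 0 > mismatch`).
#' @param gap_open,gap_extend gap scores (negative).
#' @param seed_k exact-match seed length.
#' @param xdrop score drop-off used to size the realignment band.
#' @param min_score minimum alignment score to report a hit.
#' @param min_length minimum hit length in nt (>= `seed_k`).
#' @param band diagonal band half-width for realignment windows.
#' @param max_overlap_frac overlap fraction (of the shorter hit) above
#'   which [resolve_overlaps()] drops the lower-scoring hit.
#' @return an object of class `alignment_params`.
#' @export
alignment_params <- function(match = 2L, mismatch = -3L, gap_open = -5L,
                             gap_extend = -2L, seed_k = 12L, xdrop = 30L,
                             min_score = 200L, min_length = 50L,
                             band = 25L, max_overlap_frac = 0.5) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0,
            seed_k >= 4, min_length >= seed_k, band >= 1,
            max_overlap_frac >= 0, max_overlap_frac <= 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 seed_k = as.integer(seed_k), xdrop = as.integer(xdrop),
                 min_score = as.integer(min_score),
                 min_length = as.integer(min_length),
                 band = as.integer(band),
                 max_overlap_frac = max_overlap_frac),
            class = "alignment_params")
}

#' Scan sequences for repeat-library matches on both strands
#'
#' Seed-and-extend detector: exact k-mer seeds against each consensus
#' (forward and reverse complement) are clustered by diagonal and
#' realigned by local Smith-Waterman inside a banded window, so every
#' reported score is the true local-alignment optimum for its interval.
#' Overlapping calls from different consensi are reduced to a
#' non-redundant annotation with [resolve_overlaps()].
#'
#' @param query named character vector (or `DNAStringSet`) of query
#'   sequences over A/C/G/T/N.
#' @param library named character vector of consensus sequences.
#' @param params an [alignment_params()].
#' @return a `repeat_hits` data.frame sorted by query then start.
#' @export
scan_repeats <- function(query, library, params = alignment_params()) {
  if (length(library) == 0L)
    stop("`library` must contain at least one consensus", call. = FALSE)
  if (inherits(query, "DNAStringSet")) query <- as.character(query)
  if (inherits(library, "DNAStringSet")) library <- as.character(library)
  if (is.null(names(query)))
    names(query) <- paste0("query", seq_along(query))
  query <- vapply(query, .check_dna, character(1), what = "query")
  library <- vapply(library, .check_dna, character(1), allow_n = FALSE,
                    what = "library")
  out <- list()
  for (qid in names(query)) {
    qseq <- query[[qid]]
    hits_q <- list()
    for (fam in names(library)) {
      for (strand in c("+", "-")) {
        cons <- if (strand == "+") library[[fam]] else revcomp(library[[fam]])
        raw <- .cpp_seed_scan(qseq, cons, params$match, params$mismatch,
                              params$gap_open, params$gap_extend,
                              params$seed_k, params$band,
                              params$min_score, params$min_length)
        if (nrow(raw) == 0L) next
        hits_q[[length(hits_q) + 1L]] <- repeat_hits(
          query_id = qid, start = raw$qstart, end = raw$qend,
          strand = strand, family = fam,
          score = raw$score,
          divergence_pct = ifelse(raw$aligned_cols > 0,
                                  100 * raw$mismatches / raw$aligned_cols, 0))
      }
    }
    if (length(hits_q)) {
      h <- do.call(rbind, hits_q)
      class(h) <- c("repeat_hits", "data.frame")
      out[[length(out) + 1L]] <- resolve_overlaps(h, params$max_overlap_frac)
    }
  }
  if (length(out) == 0L) return(repeat_hits())
  h <- do.call(rbind, out)
  h <- h[order(h$query_id, h$start, h$end), , drop = FALSE]
  rownames(h) <- NULL
  class(h) <- c("repeat_hits", "data.frame")
  h
}

#' Reduce overlapping hits to a non-redundant annotation
#'
#' Greedy selection by descending score: a hit overlapping an
#' already-kept hit by more than `max_overlap_frac` of the shorter hit is
#' dropped. Ties are broken by earlier start, then lexicographic family.
#'
#' @param hits a `repeat_hits` data.frame (any number of queries).
#' @param max_overlap_frac tolerated overlap fraction of the shorter hit.
#' @return the kept hits, sorted by query then interval start.
#' @export
resolve_overlaps <- function(hits, max_overlap_frac = 0.5) {
  if (nrow(hits) == 0L) return(hits)
  keep_all <- list()
  for (qid in unique(hits$query_id)) {
    h <- hits[hits$query_id == qid, , drop = FALSE]
    ord <- order(-h$score, h$start, h$family)
    h <- h[ord, , drop = FALSE]
    kept <- logical(nrow(h))
    for (i in seq_len(nrow(h))) {
      ok <- TRUE
      for (j in which(kept)) {
        ov <- min(h$end[i], h$end[j]) - max(h$start[i], h$start[j])
        if (ov <= 0) next
        shorter <- min(h$end[i] - h$start[i], h$end[j] - h$start[j])
        if (ov > max_overlap_frac * shorter) { ok <- FALSE; break }
      }
      kept[i] <- ok
    }
    keep_all[[length(keep_all) + 1L]] <- h[kept, , drop = FALSE]
  }
  h <- do.call(rbind, keep_all)
  h <- h[order(h$query_id, h$start, h$end), , drop = FALSE]
  rownames(h) <- NULL
  class(h) <- c("repeat_hits", "data.frame")
  h
}

#' Local Smith-Waterman alignment of two sequences
#'
#' Exposes the detector's affine-gap local aligner directly; useful for
#' re-scoring a hit interval against its consensus.
#'
#' @param a,b DNA strings.
#' @param params an [alignment_params()] (only the substitution and gap
#'   scores are used).
#' @return list with `score`, 0-based half-open extents on both
#'   sequences, `mismatches` and `aligned_cols` (gap columns excluded).
#' @export
smith_waterman <- function(a, b, params = alignment_params()) {
  a <- .check_dna(a, what = "a")
  b <- .check_dna(b, what = "b")
  .cpp_smith_waterman(a, b, params$match, params$mismatch,
                      params$gap_open, params$gap_extend)
}
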