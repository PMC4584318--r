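#' Folding parameters
#'
#' Weighted base-pair maximisation: GC pairs score 3, AU 2 and GU
#' wobble 1, with a minimum hairpin loop of 3 unpaired nt — a
#' qualitative stand-in for free-energy folding that preserves the
#' stability ordering GC > AU > GU. The cofold linker is a run of
#' non-pairing sentinel positions joining the two strands.
#'
#' @param min_hairpin minimum unpaired loop length (>= 0).
#' @param pair_scores named numeric vector with positive `GC`, `AU`,
#'   `GU` scores.
#' @param linker_length cofold linker length in nt.
#' @return an object of class `fold_params`.
#' @export
fold_params <- function(min_hairpin = 3L,
                        pair_scores = c(GC = 3L, AU = 2L, GU = 1L),
                        linker_length = 10L) {
  stopifnot(min_hairpin >= 0, linker_length >= 1,
            all(c("GC", "AU", "GU") %in% names(pair_scores)),
            all(pair_scores[c("GC", "AU", "GU")] > 0))
  structure(list(min_hairpin = as.integer(min_hairpin),
                 pair_scores = pair_scores,
                 linker_length = as.integer(linker_length)),
            class = "fold_params")
}

.to_rna <- function(x) {
  x <- toupper(x)
  x <- chartr("T", "U", x)
  if (!grepl("^[ACGU]*$", x))
    stop("sequence contains characters outside the RNA/DNA alphabet",
         call. = FALSE)
  x
}

.fold_result <- function(structure, pairs, score, cut_point = NA_integer_,
                         intermolecular_fraction = NA_real_) {
  structure(list(structure = structure, n_pairs = nrow(pairs),
                 score = score, pairs = pairs, cut_point = cut_point,
                 intermolecular_fraction = intermolecular_fraction),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$structure, "\n", sep = "")
  cat("pairs:", x$n_pairs, " score:", x$score)
  if (!is.na(x$cut_point))
    cat("  cut:", x$cut_point,
        " intermolecular:", round(x$intermolecular_fraction, 3))
  cat("\n")
  invisible(x)
}

#' Fold a single RNA (or DNA) sequence by base-pair maximisation
#'
#' Nussinov-style dynamic program maximising the summed pair score
#' subject to nesting and the minimum hairpin loop. The traceback is
#' deterministic: position i pairs with the smallest admissible partner
#' achieving the optimum, else stays unpaired.
#'
#' @param sequence string over A/C/G/U (T accepted and treated as U).
#' @param params a [fold_params()].
#' @return a `fold_result`: dot-bracket `structure`, `n_pairs`, `score`
#'   and the 1-based `pairs` table.
#' @export
#' @examples
#' nussinov_fold("GGGAAAACCC")
nussinov_fold <- function(sequence, params = fold_params()) {
  seq <- .to_rna(sequence)
  ps <- params$pair_scores
  r <- .cpp_nussinov(seq, params$min_hairpin,
                     as.integer(ps[["GC"]]), as.integer(ps[["AU"]]),
                     as.integer(ps[["GU"]]), -1L, -1L)
  pairs <- data.frame(i = r$pair_i + 1L, j = r$pair_j + 1L,
                      score = r$pair_score)
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  rownames(pairs) <- NULL
  .fold_result(r$structure, pairs, r$score)
}

#' Cofold two sequences through a non-pairing linker
#'
#' Concatenates `seq_a`, a sentinel linker that can never pair, and
#' `seq_b`, then folds; pairs spanning the cut are exempt from the
#' hairpin-loop constraint, so the linker emulates the strand break of a
#' two-molecule duplex. The returned structure covers the two strands
#' only (linker removed) and reports the fraction of pairs that are
#' intermolecular.
#'
#' @param seq_a,seq_b non-empty sequences.
#' @param params a [fold_params()].
#' @return a `fold_result` with `cut_point = nchar(seq_a)` and
#'   `intermolecular_fraction`.
#' @export
cofold <- function(seq_a, seq_b, params = fold_params()) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("both sequences must be non-empty", call. = FALSE)
  a <- .to_rna(seq_a); b <- .to_rna(seq_b)
  na <- nchar(a); L <- params$linker_length
  seq <- paste0(a, strrep("X", L), b)
  ps <- params$pair_scores
  r <- .cpp_nussinov(seq, params$min_hairpin,
                     as.integer(ps[["GC"]]), as.integer(ps[["AU"]]),
                     as.integer(ps[["GU"]]), na, na + L)
  struct <- paste0(substr(r$structure, 1L, na),
                   substr(r$structure, na + L + 1L, nchar(seq)))
  i <- r$pair_i + 1L; j <- r$pair_j + 1L
  i <- ifelse(i > na + L, i - L, i)
  j <- ifelse(j > na + L, j - L, j)
  pairs <- data.frame(i = i, j = j, score = r$pair_score)
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  rownames(pairs) <- NULL
  inter <- if (nrow(pairs) > 0)
    mean(pairs$i <= na & pairs$j > na) else 0
  .fold_result(struct, pairs, r$score, cut_point = na,
               intermolecular_fraction = inter)
}

#' Duplex verdict for an IRAlu pair
#'
#' Extracts the two Alu subsequences from the 3'UTR exactly as they
#' occur in the transcript (no reverse complementing: the antisense
#' element already carries the complementary sequence), cofolds them and
#' calls a duplex when the intermolecular pairing fraction reaches
#' `min_inter_frac` and the pair count reaches `min_pairs_frac` of the
#' shorter element's length.
#'
#' @param pair one-row pair data.frame from [find_iralus()] (columns
#'   `sense_start`, `sense_end`, `antisense_start`, `antisense_end`).
#' @param utr_sequence the transcript-oriented 3'UTR sequence.
#' @param params a [fold_params()].
#' @param min_inter_frac intermolecular-fraction threshold.
#' @param min_pairs_frac pair-count threshold as a fraction of the
#'   shorter element length.
#' @return list with `fold` (a `fold_result`), `verdict` ("duplex" or
#'   "no-duplex") and the two thresholds applied.
#' @export
duplex_report <- function(pair, utr_sequence, params = fold_params(),
                          min_inter_frac = 0.5, min_pairs_frac = 0.3) {
  n <- nchar(utr_sequence)
  if (pair$sense_end > n || pair$antisense_end > n ||
      pair$sense_start < 0 || pair$antisense_start < 0)
    stop("pair coordinates outside the UTR", call. = FALSE)
  s_seq <- substr(utr_sequence, pair$sense_start + 1L, pair$sense_end)
  a_seq <- substr(utr_sequence, pair$antisense_start + 1L,
                  pair$antisense_end)
  fr <- cofold(s_seq, a_seq, params)
  shorter <- min(nchar(s_seq), nchar(a_seq))
  duplex <- fr$intermolecular_fraction >= min_inter_frac &&
    fr$n_pairs >= min_pairs_frac * shorter
  list(fold = fr, verdict = if (duplex) "duplex" else "no-duplex",
       min_inter_frac = min_inter_frac, min_pairs_frac = min_pairs_frac)
}
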