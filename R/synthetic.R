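#' Synthetic sequence data with planted repeats
#'
#' The synthetic-data module emulates the inputs of a repeat-landscape
#' study without any downloads: GC-controlled i.i.d. background sequence,
#' a consensus repeat library, point-mutated strand-randomised planted
#' copies with exact interval ground truth, 3'UTR-like sequences carrying
#' inverted (or same-orientation control) Alu pairs, and a gene-to-term
#' annotation table with one planted enriched term.
#'
#' @name synthetic
NULL

#' Configuration for planting repeat copies
#'
#' @param background_length background length in nt (>= 0).
#' @param gc_fraction GC proportion of the background, in \[0, 1\].
#' @param n_copies number of repeat copies to plant.
#' @param divergence per-base substitution probability in \[0, 1).
#' @param strand_prob_sense probability a planted copy is on the sense
#'   strand of the host sequence.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(background_length = 100000L, gc_fraction = 0.41,
                             n_copies = 20L, divergence = 0.05,
                             strand_prob_sense = 0.5, seed = 1L) {
  stopifnot(background_length >= 0, gc_fraction >= 0, gc_fraction <= 1,
            n_copies >= 0, divergence >= 0, divergence < 1,
            strand_prob_sense >= 0, strand_prob_sense <= 1)
  structure(list(background_length = as.integer(background_length),
                 gc_fraction = gc_fraction, n_copies = as.integer(n_copies),
                 divergence = divergence,
                 strand_prob_sense = strand_prob_sense,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate i.i.d. background sequence with a target GC fraction
#'
#' Bases are drawn independently with P(G) = P(C) = `gc_fraction`/2 and
#' P(A) = P(T) = (1 - `gc_fraction`)/2.
#'
#' @param length sequence length in nt (>= 0).
#' @param gc_fraction target GC proportion in \[0, 1\].
#' @param seed integer seed.
#' @return a single DNA string.
#' @export
#' @examples
#' generate_background(50, 0.41, seed = 1)
generate_background <- function(length, gc_fraction = 0.41, seed = 1L) {
  if (length < 0) stop("`length` must be >= 0", call. = FALSE)
  stopifnot(gc_fraction >= 0, gc_fraction <= 1)
  if (length == 0L) return("")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  with_seed(seed, paste(sample(names(p), length, replace = TRUE, prob = p),
                        collapse = ""))
}

#' Generate a random consensus repeat library
#'
#' Stand-in for a curated repeat-family consensus library: one random
#' sequence per family, fixed by seed. Family consensi are independent;
#' see [alu_subfamily_library()] for related subfamilies.
#'
#' @param library_spec named integer vector of consensus lengths, e.g.
#'   `c(AluY = 300, FLAM_C = 120)`. Lengths must be >= 30.
#' @param seed integer seed.
#' @param gc_fraction GC proportion of the consensi.
#' @return named character vector of consensus sequences.
#' @export
generate_consensus_library <- function(library_spec, seed = 1L,
                                       gc_fraction = 0.55) {
  nm <- names(library_spec)
  if (is.null(nm) || any(nm == ""))
    stop("`library_spec` must be a named vector of lengths", call. = FALSE)
  if (anyDuplicated(nm))
    stop("duplicate family name in `library_spec`: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  if (any(library_spec < 30))
    stop("consensus lengths must be >= 30 nt", call. = FALSE)
  with_seed(seed, {
    out <- vapply(as.integer(library_spec), function(len) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                   prob = c((1 - gc_fraction) / 2, gc_fraction / 2,
                            gc_fraction / 2, (1 - gc_fraction) / 2)),
            collapse = "")
    }, character(1))
    names(out) <- nm
    out
  })
}

#' Generate a library of related Alu-like subfamily consensi
#'
#' Real Alu subfamilies share high sequence identity because they descend
#' from a common ancestor. This generator mutates a single random
#' ancestor per subfamily (default 5% substitutions) and trims each to
#' the requested length, so sense/antisense copies of *different*
#' subfamilies can still base-pair into a duplex, as real IRAlus do.
#'
#' @param library_spec named integer vector of subfamily lengths; the
#'   defaults use typical full-length Alu and free-monomer sizes.
#' @param seed integer seed.
#' @param subfamily_divergence substitution proportion of each subfamily
#'   from the shared ancestor.
#' @return named character vector of consensus sequences.
#' @export
alu_subfamily_library <- function(library_spec = c(AluSz = 311, AluSg = 307,
                                                   AluSx = 300, AluY = 311,
                                                   AluJb = 315, FLAM_C = 120,
                                                   FRAM = 160, FAM = 156),
                                  seed = 1L, subfamily_divergence = 0.05) {
  stopifnot(all(library_spec >= 30))
  if (anyDuplicated(names(library_spec)))
    stop("duplicate family name", call. = FALSE)
  anc_len <- max(library_spec)
  ancestor <- generate_background(anc_len, 0.55, seed = seed)
  out <- character(length(library_spec))
  for (i in seq_along(library_spec)) {
    mut <- mutate_copy(ancestor, subfamily_divergence, seed = seed + i)
    out[i] <- substr(mut$sequence, 1L, library_spec[[i]])
  }
  names(out) <- names(library_spec)
  out
}

#' Apply point substitutions to a sequence
#'
#' Each position is mutated independently with probability `divergence`
#' to one of the three other bases; length is always preserved.
#'
#' @param consensus DNA string.
#' @param divergence substitution probability in \[0, 1).
#' @param seed integer seed.
#' @return list with `sequence` and `realized_divergence` (Hamming
#'   distance divided by length).
#' @export
mutate_copy <- function(consensus, divergence, seed = 1L) {
  stopifnot(divergence >= 0, divergence < 1)
  consensus <- .check_dna(consensus, allow_n = FALSE, what = "consensus")
  n <- nchar(consensus)
  if (n == 0L) return(list(sequence = "", realized_divergence = 0))
  if (divergence == 0)
    return(list(sequence = consensus, realized_divergence = 0))
  with_seed(seed, {
    bases <- strsplit(consensus, "")[[1]]
    hit <- which(runif(n) < divergence)
    for (i in hit) {
      alt <- setdiff(c("A", "C", "G", "T"), bases[i])
      bases[i] <- alt[sample.int(3L, 1L)]
    }
    list(sequence = paste(bases, collapse = ""),
         realized_divergence = length(hit) / n)
  })
}

#' Plant mutated repeat copies into a background sequence
#'
#' Copies are substituted (not inserted) into the host at random
#' non-overlapping intervals, so truth coordinates match the emitted
#' sequence exactly; antisense copies are reverse-complemented.
#'
#' @param background host DNA string.
#' @param library named character vector of consensus sequences.
#' @param config a [synthetic_config()].
#' @param max_retries placement attempts per copy before giving up.
#' @return list with `sequence` (same length as `background`) and
#'   `truth`, a data.frame (family, start, end, strand,
#'   realized_divergence) sorted by start; coordinates 0-based half-open.
#' @export
plant_copies <- function(background, library, config, max_retries = 1000L) {
  stopifnot(inherits(config, "synthetic_config"))
  background <- .check_dna(background, what = "background")
  bg_len <- nchar(background)
  truth <- data.frame(family = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      realized_divergence = numeric(0))
  if (config$n_copies == 0L)
    return(list(sequence = background, truth = truth))
  with_seed(config$seed, {
    fams <- sample(names(library), config$n_copies, replace = TRUE)
    if (sum(nchar(library[fams])) > bg_len)
      stop("total planted length exceeds background length", call. = FALSE)
    occupied <- matrix(integer(0), ncol = 2)
    rows <- vector("list", config$n_copies)
    host <- background
    for (i in seq_len(config$n_copies)) {
      mut <- mutate_copy(library[[fams[i]]], config$divergence,
                         seed = sample.int(2^30, 1L))
      len <- nchar(mut$sequence)
      if (len > bg_len)
        stop("copy longer than background", call. = FALSE)
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        s <- sample.int(bg_len - len + 1L, 1L) - 1L
        e <- s + len
        if (nrow(occupied) == 0L ||
            all(e <= occupied[, 1] | s >= occupied[, 2])) {
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place copy ", i, " without overlap after ",
             max_retries, " retries", call. = FALSE)
      occupied <- rbind(occupied, c(s, e))
      strand <- if (runif(1) < config$strand_prob_sense) "+" else "-"
      seq_in <- if (strand == "+") mut$sequence else revcomp(mut$sequence)
      substr(host, s + 1L, e) <- seq_in
      rows[[i]] <- data.frame(family = fams[i], start = s, end = e,
                              strand = strand,
                              realized_divergence = mut$realized_divergence)
    }
    truth <- do.call(rbind, rows)
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    list(sequence = host, truth = truth)
  })
}

#' Generate a 3'UTR-like sequence carrying an Alu pair
#'
#' Builds flank + first copy + gap + second copy + flank. With
#' `orientation = "inverted"` the second copy is antisense (an IRAlu);
#' with `"same"` both copies are sense, a negative control that must not
#' be called an IRAlu downstream.
#'
#' @param library named character vector of consensi (use
#'   [alu_subfamily_library()] for realistic relatedness).
#' @param gap background nt between the two copies (>= 0).
#' @param divergence substitution probability applied to each copy.
#' @param seed integer seed.
#' @param family_first,family_second family names of the two copies.
#' @param orientation `"inverted"` or `"same"`.
#' @param flank background nt on each side.
#' @param gc_fraction background GC.
#' @return list with `sequence`, `truth` (two-row hit-style data.frame,
#'   0-based half-open, strand relative to the UTR), and `is_iralu`.
#' @export
generate_iralu_utr <- function(library, gap = 30L, divergence = 0,
                               seed = 1L, family_first = names(library)[1],
                               family_second = family_first,
                               orientation = c("inverted", "same"),
                               flank = 150L, gc_fraction = 0.48) {
  orientation <- match.arg(orientation)
  stopifnot(gap >= 0, flank >= 0)
  gap <- as.integer(gap); flank <- as.integer(flank)
  c1 <- mutate_copy(library[[family_first]], divergence, seed = seed + 11L)
  c2 <- mutate_copy(library[[family_second]], divergence, seed = seed + 23L)
  left  <- generate_background(flank, gc_fraction, seed = seed + 31L)
  mid   <- generate_background(gap, gc_fraction, seed = seed + 41L)
  right <- generate_background(flank, gc_fraction, seed = seed + 53L)
  seq2 <- if (orientation == "inverted") revcomp(c2$sequence) else c2$sequence
  utr <- paste0(left, c1$sequence, mid, seq2, right)
  s1 <- flank
  e1 <- s1 + nchar(c1$sequence)
  s2 <- e1 + gap
  e2 <- s2 + nchar(c2$sequence)
  truth <- data.frame(
    family = c(family_first, family_second),
    start = c(s1, s2), end = c(e1, e2),
    strand = c("+", if (orientation == "inverted") "-" else "+"),
    realized_divergence = c(c1$realized_divergence, c2$realized_divergence))
  list(sequence = utr, truth = truth,
       is_iralu = orientation == "inverted")
}

#' Generate a gene-to-term annotation table with one planted enriched term
#'
#' Background membership of every gene in every term is Bernoulli with
#' `base_prob`; for the designated gene subset, membership in
#' `enriched_term` has probability `min(1, base_prob * fold_effect)`.
#'
#' @param n_genes,n_terms table dimensions (>= 1).
#' @param enriched_term index (1..n_terms) of the planted term.
#' @param fold_effect membership-probability multiplier (>= 1); 1 is the
#'   null table.
#' @param seed integer seed.
#' @param subset_size number of genes in the enriched subset.
#' @param base_prob background membership probability.
#' @return list with `table` (data.frame gene_id, term_id), `subset`
#'   (the enriched gene ids) and `enriched_term` (term id).
#' @export
generate_annotation_table <- function(n_genes, n_terms, enriched_term = 1L,
                                      fold_effect = 1, seed = 1L,
                                      subset_size = max(1L, n_genes %/% 10L),
                                      base_prob = 0.05) {
  stopifnot(n_genes >= 1, n_terms >= 1,
            enriched_term >= 1, enriched_term <= n_terms)
  if (fold_effect < 1)
    stop("`fold_effect` must be >= 1", call. = FALSE)
  genes <- sprintf("g%05d", seq_len(n_genes))
  terms <- sprintf("T%04d", seq_len(n_terms))
  subset <- genes[seq_len(min(subset_size, n_genes))]
  with_seed(seed, {
    rows <- vector("list", n_terms)
    for (t in seq_len(n_terms)) {
      p <- rep(base_prob, n_genes)
      if (t == enriched_term)
        p[seq_along(subset)] <- min(1, base_prob * fold_effect)
      member <- runif(n_genes) < p
      if (any(member))
        rows[[t]] <- data.frame(gene_id = genes[member], term_id = terms[t])
    }
    tab <- do.call(rbind, rows)
    if (is.null(tab))
      tab <- data.frame(gene_id = character(0), term_id = character(0))
    rownames(tab) <- NULL
    list(table = tab, subset = subset, enriched_term = terms[enriched_term])
  })
}

#' Write a truth table as BED6
#'
#' Columns: host id, start, end, family, score (0), strand; coordinates
#' stay 0-based half-open as BED requires.
#' @param truth data.frame with family/start/end/strand columns.
#' @param query_id host sequence name.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_truth_bed <- function(truth, query_id, path) {
  bed <- data.frame(chrom = query_id, start = truth$start, end = truth$end,
                    name = truth$family, score = 0L, strand = truth$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
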