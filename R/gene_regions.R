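#' Gene and transcript models
#'
#' Transcript structures (exons, CDS, UTRs) are stored with 0-based
#' half-open genomic intervals; GFF3 readers and writers do the 1-based
#' inclusive conversion at the boundary. Introns are derived as the gaps
#' between consecutive exons.
#'
#' @name gene_regions
NULL

# interval matrix helpers: m is an n x 2 matrix of (start, end), 0-based
# half-open, kept sorted by start
.iv_sort <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(matrix(integer(0), ncol = 2))
  m[order(m[, 1]), , drop = FALSE]
}
.iv_len <- function(m) if (is.null(m) || nrow(m) == 0L) 0L else
  sum(m[, 2] - m[, 1])

#' Derive introns from an exon interval list
#'
#' @param exons n x 2 matrix of sorted, non-overlapping exon intervals
#'   (0-based half-open).
#' @return matrix of intron intervals (possibly zero rows).
#' @export
intron_intervals <- function(exons) {
  exons <- .iv_sort(exons)
  if (nrow(exons) < 2L) return(matrix(integer(0), ncol = 2))
  m <- cbind(exons[-nrow(exons), 2], exons[-1, 1])
  m[m[, 1] < m[, 2], , drop = FALSE]
}

#' Read gene models from GFF3
#'
#' Accepts GFF3 with gene / mRNA (or transcript) / exon / CDS /
#' five_prime_UTR / three_prime_UTR features linked by Parent
#' attributes. Coordinates are converted to 0-based half-open. Features
#' whose Parent cannot be resolved raise an error naming the offenders.
#'
#' @param path GFF3 file.
#' @return a named list of gene models; each gene is a list with
#'   `gene_id` and `transcripts` (each with `transcript_id`, `biotype`,
#'   `strand`, `seqid` and interval matrices `exons`, `cds`, `utr5`,
#'   `utr3`, `introns`).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ids <- as.character(meta$ID)
  parents <- lapply(seq_along(gr), function(i) {
    p <- meta$Parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p)[1]
  })
  parents <- unlist(parents)
  starts <- GenomicRanges::start(gr) - 1L   # to 0-based half-open
  ends <- GenomicRanges::end(gr)
  strands <- as.character(GenomicRanges::strand(gr))
  seqids <- as.character(GenomicRanges::seqnames(gr))

  gene_rows <- which(type == "gene")
  tx_rows <- which(type %in% c("mRNA", "transcript"))
  feat_rows <- which(type %in% c("exon", "CDS", "five_prime_UTR",
                                 "three_prime_UTR"))

  gene_ids <- ids[gene_rows]
  tx_parent <- parents[tx_rows]
  orphan_tx <- which(!(tx_parent %in% gene_ids))
  tx_ids <- ids[tx_rows]
  feat_parent <- parents[feat_rows]
  orphan_feat <- which(!(feat_parent %in% tx_ids))
  if (length(orphan_tx) || length(orphan_feat)) {
    bad <- c(tx_ids[orphan_tx],
             ifelse(is.na(ids[feat_rows][orphan_feat]),
                    paste0("<", type[feat_rows][orphan_feat], ">"),
                    ids[feat_rows][orphan_feat]))
    stop("orphan features with unresolved Parent: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  biotype <- if ("biotype" %in% colnames(meta))
    as.character(meta$biotype) else rep(NA_character_, length(gr))

  models <- list()
  for (gi in gene_rows) {
    gid <- ids[gi]
    txs <- list()
    for (ti in tx_rows[tx_parent == gid]) {
      tid <- ids[ti]
      rows <- feat_rows[feat_parent == tid]
      pick <- function(what) {
        r <- rows[type[rows] == what]
        .iv_sort(cbind(starts[r], ends[r]))
      }
      exons <- pick("exon")
      bt <- biotype[ti]
      if (is.na(bt)) bt <- "protein_coding"
      txs[[tid]] <- list(transcript_id = tid, gene_id = gid,
                         biotype = normalize_biotype(bt),
                         strand = strands[ti], seqid = seqids[ti],
                         exons = exons, cds = pick("CDS"),
                         utr5 = pick("five_prime_UTR"),
                         utr3 = pick("three_prime_UTR"),
                         introns = intron_intervals(exons))
    }
    models[[gid]] <- list(gene_id = gid, seqid = seqids[gi],
                          strand = strands[gi],
                          start = starts[gi], end = ends[gi],
                          transcripts = txs)
  }
  models
}

#' Normalise a transcript biotype label
#'
#' Maps free-text biotype labels (e.g. "Protein coding (Major isoform)",
#' "Nonsense-mediated decay") onto `protein_coding`,
#' `nonsense_mediated_decay`, or `other`.
#' @param x character vector of biotype labels.
#' @return character vector of normalised labels.
#' @export
normalize_biotype <- function(x) {
  y <- tolower(gsub("[ -]+", "_", trimws(x)))
  out <- rep("other", length(x))
  out[grepl("^protein_coding", y)] <- "protein_coding"
  out[grepl("^nonsense_mediated_decay", y)] <- "nonsense_mediated_decay"
  out
}

#' Write gene models as GFF3
#'
#' @param models gene-model list as returned by [read_gff3()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  fmt <- function(seqid, type, s, e, strand, attrs)
    sprintf("%s\t.\t%s\t%d\t%d\t.\t%s\t.\t%s",
            seqid, type, s + 1L, e, strand, attrs)
  for (g in models) {
    lines <- c(lines, fmt(g$seqid, "gene", g$start, g$end, g$strand,
                          paste0("ID=", g$gene_id)))
    for (tx in g$transcripts) {
      lines <- c(lines, fmt(tx$seqid, "mRNA",
                            min(tx$exons[, 1]), max(tx$exons[, 2]),
                            tx$strand,
                            paste0("ID=", tx$transcript_id, ";Parent=",
                                   g$gene_id, ";biotype=", tx$biotype)))
      emit <- function(m, what) {
        if (is.null(m) || nrow(m) == 0L) return(character(0))
        sprintf("%s\t.\t%s\t%d\t%d\t.\t%s\t.\tParent=%s",
                tx$seqid, what, m[, 1] + 1L, m[, 2], tx$strand,
                tx$transcript_id)
      }
      lines <- c(lines, emit(tx$exons, "exon"), emit(tx$cds, "CDS"),
                 emit(tx$utr5, "five_prime_UTR"),
                 emit(tx$utr3, "three_prime_UTR"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# splice one interval list out of a genome, transcript-oriented
.splice <- function(genome_seq, ivs, strand) {
  if (is.null(ivs) || nrow(ivs) == 0L) return("")
  parts <- substring(genome_seq, ivs[, 1] + 1L, ivs[, 2])
  s <- paste(parts, collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' Extract region sequences for every isoform
#'
#' Splices each transcript's CDS, intron, 5'UTR and 3'UTR intervals in
#' transcript order and reverse-complements minus-strand transcripts, so
#' "sense" downstream always means transcript orientation. The `genes`
#' category is the full genomic span of each gene (one entry per gene);
#' the other categories have one entry per isoform.
#'
#' @param models gene-model list from [read_gff3()].
#' @param genome named character vector or `DNAStringSet` of contigs.
#' @return list of named character vectors: `genes`, `cds`, `introns`,
#'   `utr5`, `utr3`. Empty regions are dropped.
#' @export
extract_region_sequences <- function(models, genome) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  cats <- list(genes = character(0), cds = character(0),
               introns = character(0), utr5 = character(0),
               utr3 = character(0))
  for (g in models) {
    gseq <- genome[[g$seqid]]
    if (is.null(gseq)) stop("contig not in genome: ", g$seqid, call. = FALSE)
    if (g$end > nchar(gseq))
      stop("interval out of bounds on ", g$seqid, call. = FALSE)
    cats$genes[[g$gene_id]] <-
      .splice(gseq, cbind(g$start, g$end), g$strand)
    for (tx in g$transcripts) {
      if (nrow(tx$exons) && max(tx$exons[, 2]) > nchar(gseq))
        stop("interval out of bounds on ", g$seqid, call. = FALSE)
      for (cat in c("cds", "introns", "utr5", "utr3")) {
        s <- .splice(gseq, tx[[cat]], tx$strand)
        if (nzchar(s)) cats[[cat]][[tx$transcript_id]] <- s
      }
    }
  }
  cats
}

#' GC content of a sequence
#'
#' (#G + #C) / (#A + #C + #G + #T); N bases are excluded from both
#' numerator and denominator. Errors on empty or all-N input.
#'
#' @param sequence DNA string(s).
#' @return numeric proportion(s) in \[0, 1\].
#' @export
#' @examples
#' gc_content("ATGC")
gc_content <- function(sequence) {
  sequence <- vapply(sequence, .check_dna, character(1),
                     what = "sequence", USE.NAMES = FALSE)
  counts <- Biostrings::letterFrequency(Biostrings::DNAStringSet(sequence),
                                        c("A", "C", "G", "T"))
  denom <- rowSums(counts)
  if (any(denom == 0))
    stop("gc_content undefined for empty or all-N sequence", call. = FALSE)
  unname((counts[, "G"] + counts[, "C"]) / denom)
}

#' Overlay point positions onto repeat hits
#'
#' A position overlaps a hit iff `start <= position < end` on the same
#' query (0-based, half-open).
#'
#' @param hits a `repeat_hits` data.frame.
#' @param positions data.frame with columns `query_id` and `position`.
#' @return `positions` with added columns `in_repeat` (logical) and
#'   `family` (of the overlapping hit, or NA).
#' @export
annotate_positions <- function(hits, positions) {
  out <- positions
  out$in_repeat <- FALSE
  out$family <- NA_character_
  if (nrow(hits) == 0L || nrow(positions) == 0L) return(out)
  hr <- GenomicRanges::GRanges(hits$query_id,
                               IRanges::IRanges(hits$start + 1L, hits$end))
  pr <- GenomicRanges::GRanges(positions$query_id,
                               IRanges::IRanges(positions$position + 1L,
                                                positions$position + 1L))
  ov <- GenomicRanges::findOverlaps(pr, hr, select = "first")
  hitrow <- !is.na(ov)
  out$in_repeat[hitrow] <- TRUE
  out$family[hitrow] <- hits$family[ov[hitrow]]
  out
}
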