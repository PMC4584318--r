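#' Pipeline configuration
#'
#' Bundles the file paths, detector and folding parameters for an
#' end-to-end run. Stages communicate through files in standard formats
#' (FASTA/GFF3/BED/TSV/JSON) so each stage is independently runnable.
#'
#' @param genome_fasta FASTA of contigs.
#' @param gff3 gene models (GFF3).
#' @param library_fasta consensus repeat library (FASTA).
#' @param annotation_tsv optional gene-to-term TSV (gene_id TAB term_id,
#'   no header) for the enrichment stage.
#' @param rm_out optional pre-computed RepeatMasker `.out` annotation for
#'   the gene sequences; when given, the gene category is not re-scanned.
#' @param out_dir output directory (created if missing).
#' @param aln an [alignment_params()].
#' @param fold a [fold_params()].
#' @param min_alu_length IRAlu pair-membership length.
#' @param min_count,alpha enrichment-stage filters.
#' @param seed integer seed recorded in the manifest.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_fasta, gff3, library_fasta,
                            annotation_tsv = NULL, rm_out = NULL,
                            out_dir = "alulandscape_out",
                            aln = alignment_params(), fold = fold_params(),
                            min_alu_length = 100L, min_count = 10L,
                            alpha = 1, seed = 1L) {
  structure(list(genome_fasta = genome_fasta, gff3 = gff3,
                 library_fasta = library_fasta,
                 annotation_tsv = annotation_tsv, rm_out = rm_out,
                 out_dir = out_dir, aln = aln, fold = fold,
                 min_alu_length = as.integer(min_alu_length),
                 min_count = as.integer(min_count), alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.need_file <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop(what, " file not found: ",
         if (is.null(path)) "<unset>" else path, call. = FALSE)
  path
}

#' Run the full repeat-landscape pipeline
#'
#' Executes regions -> scan (or `.out` parsing) -> stats -> enrichment ->
#' IRAlu -> fold, writing a summary table, gene ranking, IRAlu report,
#' enrichment table, fold verdicts and a JSON run manifest into
#' `out_dir`. Any stage error aborts with the stage name. Re-running
#' with identical inputs and config reproduces the analytic outputs
#' byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(f) file.path(config$out_dir, f)
  wtsv <- function(x, f) {
    write.table(x, outfile(f), sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }

  res <- list()
  res$regions <- .stage("regions", {
    genome <- Biostrings::readDNAStringSet(
      .need_file(config$genome_fasta, "genome FASTA"))
    names(genome) <- sub("\\s.*$", "", names(genome))
    models <- read_gff3(.need_file(config$gff3, "GFF3"))
    regions <- extract_region_sequences(models, genome)
    for (cat in names(regions)) {
      if (length(regions[[cat]]) == 0L) next
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(regions[[cat]]),
        outfile(paste0("regions_", cat, ".fa")))
    }
    list(models = models, regions = regions)
  })

  res$scan <- .stage("scan", {
    library <- Biostrings::readDNAStringSet(
      .need_file(config$library_fasta, "repeat library FASTA"))
    names(library) <- sub("\\s.*$", "", names(library))
    hits <- list()
    for (cat in names(res$regions$regions)) {
      seqs <- res$regions$regions[[cat]]
      if (length(seqs) == 0L) { hits[[cat]] <- repeat_hits(); next }
      if (cat == "genes" && !is.null(config$rm_out)) {
        hits[[cat]] <- read_repeatmasker_out(
          .need_file(config$rm_out, ".out annotation"))
      } else {
        hits[[cat]] <- scan_repeats(seqs, library, config$aln)
      }
      write_hits_bed(hits[[cat]], outfile(paste0("hits_", cat, ".bed")))
    }
    hits
  })

  res$stats <- .stage("stats", {
    summaries <- do.call(rbind, lapply(names(res$scan), function(cat)
      summarize_repeats(res$scan[[cat]], res$regions$regions[[cat]], cat)))
    wtsv(summaries, "summary.tsv")
    ranking <- rank_genes(res$scan$genes, top_n = 20L)
    wtsv(ranking, "ranking.tsv")
    list(summaries = summaries, ranking = ranking)
  })

  res$enrich <- .stage("enrich", {
    if (is.null(config$annotation_tsv)) NULL else {
      ann <- read.table(.need_file(config$annotation_tsv, "annotation TSV"),
                        sep = "\t", header = FALSE,
                        col.names = c("gene_id", "term_id"),
                        stringsAsFactors = FALSE)
      ghits <- res$scan$genes
      gene_list <- unique(ghits$query_id[is_alu(ghits)])
      enr <- enrich_terms(gene_list, ann, min_count = config$min_count,
                          alpha = config$alpha)
      wtsv(enr, "enrichment.tsv")
      enr
    }
  })

  res$iralu <- .stage("iralu", {
    models <- res$regions$models
    tx_gene <- character(0); tx_bio <- character(0)
    for (g in models) for (tx in g$transcripts) {
      tx_gene[tx$transcript_id] <- g$gene_id
      tx_bio[tx$transcript_id] <- tx$biotype
    }
    utr3_hits <- res$scan$utr3
    by_tx <- split(seq_len(nrow(utr3_hits)), utr3_hits$query_id)
    hit_list <- lapply(by_tx, function(i) {
      h <- utr3_hits[i, , drop = FALSE]
      class(h) <- c("repeat_hits", "data.frame")
      h
    })
    rep <- iralu_report(hit_list, tx_gene, tx_bio, config$min_alu_length)
    wtsv(rep, "iralu.tsv")
    list(report = rep, counts = tabulate_iralu_genes(rep),
         hits = hit_list)
  })

  res$fold <- .stage("fold", {
    rows <- list()
    for (tid in names(res$iralu$hits)) {
      fi <- find_iralus(res$iralu$hits[[tid]], config$min_alu_length)
      if (is.null(fi$primary)) next
      utr_seq <- res$regions$regions$utr3[[tid]]
      dr <- duplex_report(fi$primary, utr_seq, config$fold)
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tid,
        sense_family = fi$primary$sense_family,
        antisense_family = fi$primary$antisense_family,
        n_pairs = dr$fold$n_pairs, score = dr$fold$score,
        intermolecular_fraction = round(dr$fold$intermolecular_fraction, 4),
        verdict = dr$verdict)
    }
    verdicts <- if (length(rows)) do.call(rbind, rows) else
      data.frame(transcript_id = character(0), sense_family = character(0),
                 antisense_family = character(0), n_pairs = integer(0),
                 score = integer(0), intermolecular_fraction = numeric(0),
                 verdict = character(0))
    wtsv(verdicts, "fold.tsv")
    verdicts
  })

  manifest <- .stage("manifest", {
    inputs <- Filter(Negate(is.null),
                     list(genome_fasta = config$genome_fasta,
                          gff3 = config$gff3,
                          library_fasta = config$library_fasta,
                          annotation_tsv = config$annotation_tsv,
                          rm_out = config$rm_out))
    m <- list(
      tool = "alulandscape",
      version = as.character(utils::packageVersion("alulandscape")),
      timestamp = format(Sys.time(), tz = "UTC"),
      seed = config$seed,
      params = list(alignment = unclass(config$aln),
                    fold = list(min_hairpin = config$fold$min_hairpin,
                                pair_scores = as.list(config$fold$pair_scores),
                                linker_length = config$fold$linker_length),
                    min_alu_length = config$min_alu_length),
      input_md5 = as.list(tools::md5sum(unlist(inputs))),
      rows = list(summary = nrow(res$stats$summaries),
                  ranking = nrow(res$stats$ranking),
                  iralu = nrow(res$iralu$report),
                  enrichment = if (is.null(res$enrich)) 0L
                    else nrow(res$enrich),
                  fold = nrow(res$fold)),
      iralu_gene_counts = res$iralu$counts)
    jsonlite::write_json(m, outfile("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    m
  })

  invisible(c(res, list(manifest = manifest)))
}

#' Write a complete synthetic input bundle
#'
#' Generates a small self-contained study: one contig per gene, each with
#' a two-exon transcript (5'UTR, CDS, 3'UTR); Alu copies planted into
#' introns/flanks with exact truth; a designated subset of genes carrying
#' an inverted Alu pair in the 3'UTR (and one same-orientation control);
#' a subfamily consensus library; and a gene-to-term annotation table
#' whose planted term is enriched in the Alu-carrying genes. All outputs
#' are plain text (FASTA/GFF3/BED/TSV).
#'
#' @param out_dir directory to write into (created if missing).
#' @param n_genes number of synthetic genes.
#' @param n_iralu how many genes get an inverted pair in the 3'UTR.
#' @param divergence substitution proportion of planted copies.
#' @param seed integer seed; outputs are byte-identical per seed.
#' @return invisibly, a list with the file paths and the truth tables.
#' @export
simulate_bundle <- function(out_dir, n_genes = 8L, n_iralu = 2L,
                            divergence = 0.05, seed = 1L) {
  stopifnot(n_iralu + 1L <= n_genes)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  library <- alu_subfamily_library(seed = seed)
  lib_path <- file.path(out_dir, "library.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(library), lib_path)

  genome <- character(0)
  models <- list()
  truth_rows <- list()
  iralu_truth <- logical(0)
  for (i in seq_len(n_genes)) {
    gid <- sprintf("gene%02d", i)
    tid <- sprintf("tx%02d", i)
    contig <- sprintf("chr_%s", gid)
    gseed <- seed + 100L * i
    utr5 <- generate_background(200L, 0.55, seed = gseed + 1L)
    cds1 <- generate_background(400L, 0.5, seed = gseed + 2L)
    cds2 <- generate_background(350L, 0.5, seed = gseed + 3L)
    intron_res <- plant_copies(
      generate_background(2000L, 0.43, seed = gseed + 4L), library,
      synthetic_config(background_length = 2000L, n_copies = 2L,
                       divergence = divergence, seed = gseed + 5L))
    if (i <= n_iralu) {
      u <- generate_iralu_utr(library, gap = 40L, divergence = divergence,
                              seed = gseed + 6L, family_first = "AluSz",
                              family_second = "AluSg",
                              orientation = "inverted")
    } else if (i == n_iralu + 1L) {
      u <- generate_iralu_utr(library, gap = 40L, divergence = divergence,
                              seed = gseed + 6L, family_first = "AluSz",
                              family_second = "AluSg",
                              orientation = "same")
    } else {
      u <- list(sequence = generate_background(700L, 0.48,
                                               seed = gseed + 6L),
                truth = NULL, is_iralu = FALSE)
    }
    iralu_truth[tid] <- u$is_iralu
    seqs <- c(utr5, cds1, intron_res$sequence, cds2, u$sequence)
    lens <- nchar(seqs)
    offs <- cumsum(c(0L, lens))
    contig_seq <- paste(seqs, collapse = "")
    genome[[contig]] <- contig_seq
    exon1 <- c(0L, offs[3])                 # 5'UTR + CDS part 1
    exon2 <- c(offs[4], offs[6])            # CDS part 2 + 3'UTR
    tx <- list(transcript_id = tid, gene_id = gid,
               biotype = "protein_coding", strand = "+", seqid = contig,
               exons = rbind(exon1, exon2),
               cds = rbind(c(offs[2], offs[3]), c(offs[4], offs[5])),
               utr5 = rbind(c(0L, offs[2])),
               utr3 = rbind(c(offs[5], offs[6])),
               introns = rbind(c(offs[3], offs[4])))
    models[[gid]] <- list(gene_id = gid, seqid = contig, strand = "+",
                          start = 0L, end = offs[6],
                          transcripts = setNames(list(tx), tid))
    tr <- intron_res$truth
    tr$start <- tr$start + offs[3]
    tr$end <- tr$end + offs[3]
    tr$query_id <- contig
    if (!is.null(u$truth)) {
      ut <- u$truth
      ut$start <- ut$start + offs[5]
      ut$end <- ut$end + offs[5]
      ut$query_id <- contig
      tr <- rbind(tr, ut)
    }
    truth_rows[[gid]] <- tr
  }
  genome_path <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), genome_path)
  gff_path <- file.path(out_dir, "genes.gff3")
  write_gff3(models, gff_path)
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  truth_path <- file.path(out_dir, "truth.bed")
  bed <- data.frame(truth$query_id, truth$start, truth$end, truth$family,
                    0L, truth$strand)
  write.table(bed, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  # annotation table: term T0001 planted on the bundle's (Alu-carrying)
  # genes against a filler background universe
  gene_ids <- sprintf("gene%02d", seq_len(n_genes))
  filler <- sprintf("fill%03d", seq_len(60L))
  all_genes <- c(gene_ids, filler)
  ann_tab <- with_seed(seed + 7L, {
    rows <- list(data.frame(gene_id = c(gene_ids, sample(filler, 5L)),
                            term_id = "T0001"))
    for (t in 2:6) {
      member <- all_genes[runif(length(all_genes)) < 0.2]
      if (length(member))
        rows[[t]] <- data.frame(gene_id = member,
                                term_id = sprintf("T%04d", t))
    }
    do.call(rbind, rows)
  })
  ann_path <- file.path(out_dir, "annotations.tsv")
  write.table(ann_tab, ann_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  invisible(list(genome_fasta = genome_path, gff3 = gff_path,
                 library_fasta = lib_path, annotation_tsv = ann_path,
                 truth_bed = truth_path, truth = truth,
                 iralu_truth = iralu_truth))
}
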