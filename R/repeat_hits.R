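#' Construct a table of repeat hits
#'
#' The central data model for annotated repeat occurrences: one row per
#' element, 0-based half-open coordinates on the query, strand relative
#' to the query, subfamily name, repeat class, alignment score and
#' percent divergence from the consensus.
#'
#' @param query_id,start,end,strand,family,repeat_class,score,divergence_pct
#'   equal-length vectors (recycled scalars allowed).
#' @return a data.frame of class `repeat_hits`.
#' @export
repeat_hits <- function(query_id = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        family = character(0), repeat_class = NULL,
                        score = 0L, divergence_pct = 0) {
  n <- max(length(query_id), length(start))
  if (is.null(repeat_class)) repeat_class <- repeat_class_of(family)
  h <- data.frame(query_id = rep_len(as.character(query_id), n),
                  start = rep_len(as.integer(start), n),
                  end = rep_len(as.integer(end), n),
                  strand = rep_len(as.character(strand), n),
                  family = rep_len(as.character(family), n),
                  repeat_class = rep_len(as.character(repeat_class), n),
                  score = rep_len(as.integer(score), n),
                  divergence_pct = rep_len(as.numeric(divergence_pct), n))
  validate_hits(h)
  class(h) <- c("repeat_hits", "data.frame")
  h
}

validate_hits <- function(h) {
  if (nrow(h) == 0L) return(invisible(h))
  if (any(h$start >= h$end))
    stop("hit intervals must satisfy start < end", call. = FALSE)
  if (any(h$divergence_pct < 0 | h$divergence_pct > 100))
    stop("divergence_pct must lie in [0, 100]", call. = FALSE)
  if (!all(h$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  invisible(h)
}

#' Infer a repeat class from a subfamily name
#'
#' Maps subfamily names to the major interspersed-repeat classes; Alu
#' dimers and the free monomers FLAM/FRAM/FAM all map to "SINE/Alu".
#'
#' @param family character vector of subfamily names.
#' @return character vector of classes: SINE/Alu, SINE/other, LINE, LTR,
#'   DNA or other.
#' @export
repeat_class_of <- function(family) {
  out <- rep("other", length(family))
  out[grepl("^Alu($|[A-Za-z0-9_])", family)] <- "SINE/Alu"
  out[grepl("^(FLAM|FRAM|FAM)($|[A-Za-z0-9_])", family)] <- "SINE/Alu"
  out[grepl("^MIR", family)] <- "SINE/other"
  out[grepl("^(L1|L2|L3|LINE|CR1)", family)] <- "LINE"
  out[grepl("^(LTR|ERV|MLT|MST|THE)", family)] <- "LTR"
  out[grepl("^(DNA|MER|Charlie|Tigger|hAT)", family)] <- "DNA"
  out
}

#' Is a hit an Alu element?
#'
#' TRUE iff the repeat class is SINE/Alu; this includes the monomeric
#' FLAM/FRAM/FAM subfamilies and unresolved "Alu" fragments, which count
#' as Alus in the element inventories.
#'
#' @param hits a `repeat_hits` data.frame (or anything with
#'   `repeat_class`/`family` columns).
#' @return logical vector, one per hit.
#' @export
is_alu <- function(hits) {
  cls <- hits$repeat_class
  if (is.null(cls)) cls <- repeat_class_of(hits$family)
  cls == "SINE/Alu"
}

#' Write hits as BED6
#'
#' Columns chrom/start/end/name/score/strand with the family as the
#' feature name; coordinates already 0-based half-open.
#' @param hits a `repeat_hits` data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(hits$query_id, hits$start, hits$end, hits$family,
                    hits$score, hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a RepeatMasker-style `.out` annotation file
#'
#' Parses the classic whitespace-delimited `.out` dialect (3 header
#' lines; columns: SW score, %div, %del, %ins, query, begin, end, (left),
#' strand, repeat name, class/family, ...). Coordinates are converted
#' from 1-based inclusive to 0-based half-open and strand "C" to "-".
#'
#' @param path file in `.out` dialect.
#' @return a `repeat_hits` data.frame.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 0L) lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(repeat_hits())
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 11L)
  if (length(bad))
    stop("malformed .out line ", bad[1] + 3L, ": expected >= 11 columns, got ",
         nf[bad[1]], call. = FALSE)
  f <- function(i) vapply(fields, `[[`, character(1), i)
  strand_raw <- f(9)
  if (!all(strand_raw %in% c("+", "C")))
    stop("unrecognised strand symbol in .out file: ",
         paste(setdiff(strand_raw, c("+", "C")), collapse = ", "),
         call. = FALSE)
  repeat_hits(query_id = f(5),
              start = as.integer(f(6)) - 1L,
              end = as.integer(f(7)),
              strand = ifelse(strand_raw == "C", "-", "+"),
              family = f(10),
              repeat_class = f(11),
              score = as.integer(f(1)),
              divergence_pct = as.numeric(f(2)))
}

#' Write hits in the RepeatMasker `.out` dialect
#'
#' Inverse of [read_repeatmasker_out()]: emits 3 header lines and one row
#' per hit with 1-based inclusive coordinates and "C" for antisense.
#'
#' @param hits a `repeat_hits` data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_repeatmasker_out <- function(hits, path) {
  header <- c(
    "   SW  perc perc perc  query     position in query    matching repeat",
    "score  div. del. ins.  sequence  begin end   (left)   repeat    class/family  begin end (left) ID",
    "")
  rows <- sprintf("%5d %5.1f  0.0  0.0  %s %d %d (0) %s %s %s 1 %d (0) %d",
                  hits$score, hits$divergence_pct, hits$query_id,
                  hits$start + 1L, hits$end,
                  ifelse(hits$strand == "-", "C", "+"),
                  hits$family, hits$repeat_class,
                  hits$end - hits$start, seq_len(nrow(hits)))
  writeLines(c(header, rows), path)
  invisible(path)
}
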