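#' 2x2 chi-square test of enrichment
#'
#' Pearson chi-square with one degree of freedom, Yates continuity
#' correction on by default (matching the usual R default for 2x2
#' tables). The p-value is computed in log space so it stays meaningful
#' far below double precision; [format_p()] applies the conventional
#' display floor of 2.2e-16.
#'
#' @param a,b,c,d cell counts: rows = target vs background, columns =
#'   hit vs non-hit (e.g. Alu bases vs non-Alu bases).
#' @param yates apply the continuity correction.
#' @return list with `statistic`, `df` (1), `p_value` and `log10_p`.
#' @export
chi_square_2x2 <- function(a, b, c, d, yates = TRUE) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be >= 0", call. = FALSE)
  n <- a + b + c + d
  if (n <= 0) stop("empty table", call. = FALSE)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0))
    stop("zero marginal total", call. = FALSE)
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - n / 2)
  stat <- n * num^2 / (r1 * r2 * c1 * c2)
  logp <- pchisq(stat, df = 1, lower.tail = FALSE, log.p = TRUE)
  list(statistic = stat, df = 1,
       p_value = exp(logp), log10_p = logp / log(10))
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value.
#'
#' @param xs,ys numeric vectors, each of length >= 2.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(xs, ys) {
  nx <- length(xs); ny <- length(ys)
  if (nx < 2 || ny < 2) stop("each group needs n >= 2", call. = FALSE)
  vx <- stats::var(xs); vy <- stats::var(ys)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (mean(xs) == mean(ys))
      return(list(statistic = 0, df = nx + ny - 2, p_value = 1))
    stop("zero variance in both groups with unequal means", call. = FALSE)
  }
  t <- (mean(xs) - mean(ys)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = t, df = df,
       p_value = 2 * pt(abs(t), df, lower.tail = FALSE))
}

# log of sum of exponentials, stable
.logsumexp <- function(lx) {
  m <- max(lx)
  m + log(sum(exp(lx - m)))
}

# log hypergeometric pmf: P(X = i) drawing n from N with K successes
.lhyper <- function(i, K, n, N)
  lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)

#' Right-tail Fisher exact probability
#'
#' P(X >= k) under Hypergeometric(N, K, n): the probability of seeing at
#' least `k` category genes in a list of `n` drawn from a universe of `N`
#' containing `K` category genes. Computed by exact term summation in
#' log space.
#'
#' @param k observed overlap; `0 <= k <= min(K, n)`.
#' @param K category total in the universe.
#' @param n list size.
#' @param N universe size.
#' @return probability.
#' @export
fisher_right_tail <- function(k, K, n, N) {
  if (K > N || n > N || k > min(K, n) || k < 0 || any(c(K, n, N) < 0))
    stop("inconsistent margins for hypergeometric tail", call. = FALSE)
  if (k == 0) return(1)
  i <- k:min(K, n)
  exp(.logsumexp(.lhyper(i, K, n, N)))
}

#' EASE score: the jackknifed Fisher exact probability
#'
#' The right-tail hypergeometric probability computed after removing one
#' overlapping gene from the list (`k - 1` instead of `k`), giving a
#' conservative upper bound on the Fisher exact p that penalises
#' categories supported by few genes.
#'
#' @inheritParams fisher_right_tail
#' @return probability; always >= [fisher_right_tail()] on the same
#'   margins.
#' @export
ease_score <- function(k, K, n, N) {
  if (k < 1) stop("EASE score needs k >= 1 (one gene to remove)",
                  call. = FALSE)
  fisher_right_tail(k - 1, K, n, N)
}

#' Bonferroni correction
#'
#' @param p p-value(s).
#' @param m number of tests (>= 1).
#' @return `min(1, p * m)`, vectorised.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, p * m)
}

#' Group enrichment score
#'
#' Minus log10 of the geometric mean of a cluster's EASE scores, i.e.
#' `-mean(log10(scores))`. A cluster whose terms all sit at p = 0.05
#' scores 1.30103; 1.3 is the usual reporting threshold.
#'
#' @param ease_scores probabilities in (0, 1\].
#' @return the minus-log10 group score.
#' @export
#' @examples
#' group_enrichment_score(rep(0.05, 4))  # 1.30103
group_enrichment_score <- function(ease_scores) {
  if (length(ease_scores) == 0L) stop("empty score list", call. = FALSE)
  if (any(ease_scores <= 0 | ease_scores > 1))
    stop("EASE scores must lie in (0, 1]", call. = FALSE)
  -mean(log10(ease_scores))
}

#' Term enrichment of a gene list by EASE score
#'
#' For every annotation term meeting the minimum gene count, computes the
#' EASE score of the list/term overlap against the annotation universe
#' and the Bonferroni-corrected value over all tested terms. Genes absent
#' from the annotation table are dropped from the list (unmapped ids).
#'
#' @param genes character vector of gene ids.
#' @param annotation data.frame with columns `gene_id` and `term_id`.
#' @param universe universe gene ids; default all genes in `annotation`.
#' @param min_count minimum list genes in a term for the term to be
#'   tested.
#' @param alpha optional EASE-score cutoff applied to the output rows.
#' @return data.frame (term, count, percent, p_value, bonferroni) sorted
#'   by ascending p.
#' @export
enrich_terms <- function(genes, annotation, universe = NULL,
                         min_count = 10L, alpha = 1) {
  if (is.null(universe)) universe <- unique(annotation$gene_id)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (!all(genes %in% universe))
    genes <- intersect(genes, universe)   # drop unmapped ids
  genes <- unique(genes)
  N <- length(universe)
  n <- length(genes)
  terms <- unique(annotation$term_id)
  rows <- list()
  for (term in terms) {
    members <- unique(annotation$gene_id[annotation$term_id == term])
    members <- intersect(members, universe)
    K <- length(members)
    k <- length(intersect(members, genes))
    if (k < min_count) next
    p <- ease_score(k, K, n, N)
    rows[[length(rows) + 1L]] <- data.frame(
      term = term, count = k,
      percent = if (n > 0) percent(k, n, 2L) else NA,
      p_value = p)
  }
  if (length(rows) == 0L)
    return(data.frame(term = character(0), count = integer(0),
                      percent = numeric(0), p_value = numeric(0),
                      bonferroni = numeric(0)))
  out <- do.call(rbind, rows)
  out$bonferroni <- bonferroni(out$p_value, nrow(out))
  out <- out[out$p_value <= alpha, , drop = FALSE]
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Display a p-value with the conventional floor
#'
#' Values below 2.2e-16 (the double-precision display floor) print as
#' "< 2.2e-16", mirroring standard R console output.
#'
#' @param p probabilities.
#' @param floor display floor.
#' @return character vector.
#' @export
format_p <- function(p, floor = 2.2e-16) {
  ifelse(p < floor, paste("<", format(floor)), format(p, digits = 3))
}
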