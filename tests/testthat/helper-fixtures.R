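# shared fixtures: tiny libraries and a brute-force structure enumerator

small_library <- function(seed = 3L) {
  generate_consensus_library(c(AluY = 300L, FLAM_C = 120L), seed = seed)
}

# brute-force interval overlap check
any_overlap <- function(truth) {
  n <- nrow(truth)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (max(truth$start[i], truth$start[j]) <
        min(truth$end[i], truth$end[j])) return(TRUE)
  FALSE
}

# exhaustive maximum over all valid nested structures (independent of the
# DP): recursive enumeration of "j pairs with k or stays unpaired"
brute_fold_score <- function(seq, min_hairpin = 3L,
                             scores = c(GC = 3L, AU = 2L, GU = 1L)) {
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  ps <- function(a, b) {
    key <- paste0(sort(c(a, b)), collapse = "")
    switch(key, "CG" = scores[["GC"]], "AU" = scores[["AU"]],
           "GU" = scores[["GU"]], -1L)
  }
  rec <- function(i, j) {
    if (j - i < min_hairpin + 1L) return(0L)
    best <- rec(i, j - 1L)                       # j unpaired
    for (k in i:(j - min_hairpin - 1L)) {
      w <- ps(s[k], s[j])
      if (w < 0) next
      left <- if (k > i) rec(i, k - 1L) else 0L
      inner <- rec(k + 1L, j - 1L)
      best <- max(best, w + left + inner)
    }
    best
  }
  n <- length(s)
  if (n < 2) return(0L)
  rec(1L, n)
}

# hypergeometric right tail by explicit outcome enumeration (small N)
brute_hyper_tail <- function(k, K, n, N) {
  sum(vapply(k:min(K, n), function(i)
    choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
}

# Biostrings local alignment with the detector's scoring scheme: gap of
# length L costs 5 + 2*(L-1) = 3 + 2*L
biostrings_local_score <- function(a, b, match = 2, mismatch = -3) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  Biostrings::pairwiseAlignment(a, b, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = 3, gapExtension = 2,
                                scoreOnly = TRUE)
}
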