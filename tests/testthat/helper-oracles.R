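# Independent oracles used to verify the package's implementations.

# Semi-global edit distance (full pattern vs any substring of text) by
# straight dynamic programming, row-vectorised with the cummin trick for
# the within-row (insertion) dependency. Non-ACGT symbols never match.
oracle_semiglobal <- function(pattern, text) {
  pc <- strsplit(pattern, "")[[1]]
  tc <- strsplit(text, "")[[1]]
  m <- length(pc)
  n <- length(tc)
  if (m == 0) return(0L)
  if (n == 0) return(m)
  acgt <- c("A", "C", "G", "T")
  prev <- rep(0L, n + 1)
  idx <- 0:n
  for (i in seq_len(m)) {
    sub_cost <- ifelse(pc[i] == tc & pc[i] %in% acgt, 0L, 1L)
    tmp <- c(i, pmin(prev[1:n] + sub_cost, prev[2:(n + 1)] + 1L))
    prev <- cummin(tmp - idx) + idx
  }
  min(prev)
}

# Best local-alignment (Smith-Waterman) score with match +1, mismatch -1,
# gap -2. An alignment with span >= 20 and identity >= 0.8 implies a score
# of at least 0.8*20 - 2*0.2*20 = 8, so a best score below 8 certifies that
# no such alignment exists.
oracle_sw_score <- function(a, b) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  m <- length(ac)
  n <- length(bc)
  prev <- rep(0L, n + 1)
  best <- 0L
  for (i in seq_len(m)) {
    cur <- integer(n + 1)
    for (j in seq_len(n)) {
      d <- prev[j] + if (ac[i] == bc[j]) 1L else -1L
      cur[j + 1] <- max(0L, d, prev[j + 1] - 2L, cur[j] - 2L)
    }
    best <- max(best, max(cur))
    prev <- cur
  }
  best
}

# Codon-table translation independent of the package's translation path;
# stops at the first stop codon.
oracle_translate <- function(dna) {
  code <- Biostrings::GENETIC_CODE
  n <- (nchar(dna) %/% 3) * 3
  if (n == 0) return("")
  codons <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0) aa <- aa[seq_len(stop_at[1] - 1)]
  paste(aa, collapse = "")
}

non_stop_codons <- function() {
  b <- c("A", "C", "G", "T")
  setdiff(as.vector(outer(outer(b, b, paste0), b, paste0)),
          c("TAA", "TAG", "TGA"))
}

random_dna_str <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
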