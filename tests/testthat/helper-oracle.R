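# Independent alignment oracles, deliberately sharing no code with the
# package's alignment path (which delegates to Biostrings' C implementation).

# Plain-R quadratic-time affine-gap local aligner (Gotoh recurrences).
oracle_local_score <- function(q, s, mat, open = 11, ext = 1) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  m <- length(qc)
  n <- length(sc)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[qc[i - 1], sc[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Exhaustive enumeration of every local alignment path (first column always a
# residue pair; gaps charged open + g*ext). Exponential: tiny inputs only.
# Validates the Gotoh oracle itself.
enum_local_score <- function(q, s, mat, open = 11, ext = 1) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  m <- length(qc)
  n <- length(sc)
  best <- 0
  rec <- function(i, j, score, last) {
    if (score > best) best <<- score
    if (i <= m && j <= n) rec(i + 1, j + 1, score + mat[qc[i], sc[j]], "d")
    if (i <= m) rec(i + 1, j, score - ext - if (last == "u") 0 else open, "u")
    if (j <= n) rec(i, j + 1, score - ext - if (last == "l") 0 else open, "l")
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      rec(i + 1, j + 1, mat[qc[i], sc[j]], "d")
    }
  }
  best
}

random_peptide <- function(len, alphabet = c("A", "C", "G", "W")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# diagonal self-score of a sequence under a substitution matrix
diag_self_score <- function(seq, mat) {
  chars <- strsplit(seq, "")[[1]]
  sum(mat[cbind(chars, chars)])
}
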