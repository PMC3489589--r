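# Brute-force folding oracle: enumerate every non-crossing structure with a
# minimum hairpin loop of 3 and score it with the same stacking-weighted
# scheme as the built-in folder (GC = 3, AU = 2, GU = 1, +1 per stacked
# pair).  Exponential, usable up to ~12 nt.

oracle_pair_score <- function(a, b) {
  key <- paste0(a, b)
  switch(key, GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1, NA_integer_)
}

# all structures of chars[i..j] as lists of pair matrices (2 columns, i < j)
oracle_structures <- function(chars, i, j) {
  if (j - i < 4) return(list(matrix(integer(0), ncol = 2)))
  out <- list()
  # i unpaired
  for (s in oracle_structures(chars, i + 1, j)) out[[length(out) + 1]] <- s
  # i paired with k (loop >= 3)
  for (k in (i + 4):j) {
    if (is.na(oracle_pair_score(chars[i], chars[k]))) next
    inner <- oracle_structures(chars, i + 1, k - 1)
    rest <- oracle_structures(chars, k + 1, j)
    for (a in inner) for (b in rest) {
      out[[length(out) + 1]] <- rbind(c(i, k), a, b)
    }
  }
  out
}

oracle_score <- function(chars, pairs) {
  if (nrow(pairs) == 0) return(0)
  s <- sum(vapply(seq_len(nrow(pairs)),
                  function(r) oracle_pair_score(chars[pairs[r, 1]], chars[pairs[r, 2]]),
                  1.0))
  has <- paste(pairs[, 1], pairs[, 2])
  stacked <- sum(paste(pairs[, 1] + 1, pairs[, 2] - 1) %in% has)
  s + stacked
}

# maximum achievable structure score, by exhaustive enumeration
oracle_best_score <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  max(vapply(oracle_structures(chars, 1, length(chars)), oracle_score,
             1, chars = chars))
}

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, "")
}

# dot-bracket reconstruction from a 0-based partner table
dotbracket_from_pairs <- function(partner) {
  out <- rep(".", length(partner))
  for (i in seq_along(partner)) {
    if (!is.na(partner[i])) out[i] <- if (partner[i] + 1 > i) "(" else ")"
  }
  paste(out, collapse = "")
}

# n distinct 9-mers, deterministically (index -> base-4 expansion)
.fake_9mers <- function(n) ligbias:::.index_to_seq(seq_len(n) - 1, 9)
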