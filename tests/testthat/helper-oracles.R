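# Independent oracles used across the suite. Each is deliberately
# written as the most direct (brute-force) computation, independent of
# the package's implementation path.

# Pearson chi-square via an explicit expected-matrix loop
oracle_chisq <- function(counts) {
  n <- sum(counts)
  chi2 <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      e <- sum(counts[i, ]) * sum(counts[, j]) / n
      chi2 <- chi2 + (counts[i, j] - e)^2 / e
    }
  }
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(chi2 = chi2, df = df,
       p = pchisq(chi2, df, lower.tail = FALSE),
       v = sqrt(chi2 / (n * (min(dim(counts)) - 1))))
}

# two-sided exact Wilcoxon rank-sum p-value by full enumeration of all
# choose(n_a + n_b, n_a) group assignments of the pooled values
oracle_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  combos <- combn(n, length(a))
  w_all <- apply(combos, 2, function(idx) {
    sum(ranks[idx]) - length(a) * (length(a) + 1) / 2
  })
  mu <- length(a) * length(b) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# standard genetic code written out independently of Biostrings
oracle_codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aa <- paste0(
    "FFLLSSSSYY**CC*W",  # TTT..TGG
    "LLLLPPPPHHQQRRRR",  # CTT..CGG
    "IIIMTTTTNNKKSSRR",  # ATT..AGG
    "VVVVAAAADDEEGGGG")  # GTT..GGG
  codons <- character(64)
  k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1
    codons[k] <- paste0(b1, b2, b3)
  }
  setNames(strsplit(aa, "")[[1]], codons)
})

# random valid chiasma records
random_chiasma_records <- function(n, sample_id = "S1") {
  data.frame(sample_id = sample_id,
             cell_id = sprintf("c%d", sample.int(5, n, replace = TRUE)),
             bivalent_id = sprintf("b%d", sample.int(20, n, replace = TRUE)),
             arm_id = sample(c(1L, 2L), n, replace = TRUE),
             rel_pos = runif(n),
             stringsAsFactors = FALSE)
}

# random contingency table with positive marginals
random_table <- function(max_dim = 4, max_count = 30) {
  repeat {
    r <- sample(2:max_dim, 1)
    c <- sample(2:max_dim, 1)
    m <- matrix(sample(0:max_count, r * c, replace = TRUE), r, c)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}
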