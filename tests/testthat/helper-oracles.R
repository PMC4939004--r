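# Brute-force statistical oracles, independent of the package kernels.

# two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, probabilities from factorials
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  lp <- function(x) lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)
  xs <- max(0, r1 - (n - c1)):min(r1, c1)
  probs <- exp(vapply(xs, lp, numeric(1)))
  obs <- exp(lp(a))
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exact two-sided Wilcoxon p by enumeration of all assignments of pooled
# ranks to the first sample (deviation-from-mean tail definition)
wilcoxon_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  E <- n * (n + m + 1) / 2
  combs <- combn(n + m, n)
  sums <- colSums(matrix(r[combs], nrow = n))
  mean(abs(sums - E) >= abs(W - E) - 1e-9)
}

# mappability match count by full quadratic scan (R-level, both strands)
mappability_oracle <- function(genome, k, d) {
  lapply(names(genome), function(chr) {
    L <- nchar(genome[[chr]])
    vapply(seq_len(L - k + 1L) - 1L, function(pos)
      kmer_match_count(genome, chr, pos, k, d), numeric(1))
  })
}

random_genome <- function(n, seed, gc = 0.5) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
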