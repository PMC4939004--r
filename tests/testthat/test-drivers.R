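toy_sm <- function(normalized, strains, starts = NULL) {
  n <- nrow(normalized)
  sites <- data.frame(site_id = rownames(normalized), chrom = "chr1",
                      start = starts %||% (seq_len(n) * 1000L),
                      end = (starts %||% (seq_len(n) * 1000L)) + 400L)
  meta <- data.frame(library = colnames(normalized), strain = strains,
                     replicate = ave(seq_along(strains), strains,
                                     FUN = seq_along))
  sm <- site_matrix(sites, matrix(0L, n, length(strains),
                                  dimnames = dimnames(normalized)), meta)
  sm$normalized <- normalized
  sm
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("SNP association recovers a perfect genotype fit", {
  strains <- paste0("S", 1:7)
  y <- c(10, 10, 10, 20, 20, 20, 20)
  norm <- matrix(rep(y, each = 1), nrow = 1,
                 dimnames = list("s1", strains))
  sm <- toy_sm(norm, strains, starts = 1000L)
  df <- data.frame(chrom = "chr1", pos = 1200L, ref = "A", alt = "G")
  g <- c(0, 0, 0, 1, 1, 1, 1)
  for (i in seq_along(strains)) df[[strains[i]]] <- g[i]
  snps <- snp_table(df, strains)
  res <- snp_association("s1", sm, snps)
  expect_equal(res$r_squared, 1)
  expect_equal(res$beta, 10)
  expect_equal(res$p, 0)
  # constant genotype: NA with a reason, not an error
  df2 <- df; for (s in strains) df2[[s]] <- 1L
  df2$pos <- 1100L
  res2 <- snp_association("s1", sm, snp_table(df2, strains))
  expect_true(is.na(res2$p))
  expect_equal(res2$reason, "constant_genotype")
})

test_that("association p-values are uniform under the null", {
  set.seed(1101)
  strains <- paste0("S", 1:7)
  ps <- replicate(800, {
    y <- rnorm(7)
    g <- sample(c(0, 1), 7, replace = TRUE)
    if (var(g) == 0) return(NA_real_)
    n <- 7
    beta <- cov(g, y) / var(g)
    r2 <- 1 - sum((y - mean(y) - beta * (g - mean(g)))^2) /
      sum((y - mean(y))^2)
    pf(r2 / (1 - r2) * (n - 2), 1, n - 2, lower.tail = FALSE)
  })
  ps <- ps[!is.na(ps)]
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("fraction of SNP-explained variable sites tracks the planted rate", {
  set.seed(1102)
  strains <- paste0("S", 1:7)
  n <- 200
  driven <- seq_len(60)                     # 30% of 200
  g_list <- lapply(seq_len(n), function(i)
    sample(rep(c(0L, 1L), c(4, 3))))
  norm <- t(vapply(seq_len(n), function(i) {
    base <- rnorm(7, 100, 17)
    if (i %in% driven) base <- base + 75 * g_list[[i]]
    rep(base, each = 2) + rnorm(14, 0, 5)
  }, numeric(14)))
  rownames(norm) <- sprintf("s%03d", seq_len(n))
  colnames(norm) <- paste0(rep(strains, each = 2), "_", rep(1:2, 7))
  sm <- toy_sm(norm, rep(strains, each = 2))
  df <- data.frame(chrom = "chr1", pos = seq_len(n) * 1000L + 100L,
                   ref = "A", alt = "G")
  gmat <- do.call(rbind, g_list)
  for (i in seq_along(strains)) df[[strains[i]]] <- gmat[, i]
  snps <- snp_table(df, strains)
  out <- fraction_snp_explained(sm$sites$site_id, sm, snps)
  expect_lt(abs(out$fraction - 0.30), 0.05)
  # all driven with a strong effect: fraction >= 0.95 among driven sites
  out2 <- fraction_snp_explained(sm$sites$site_id[driven], sm, snps)
  expect_gte(out2$fraction, 0.95)
  # no SNPs at all
  empty <- snp_table(df[0, ], strains)
  expect_message(out3 <- fraction_snp_explained(sm$sites$site_id, sm, empty),
                 "no variable site")
  expect_equal(out3$fraction, 0)
})

test_that("DM calling applies strict thresholds to variance and range", {
  strains <- paste0("S", 1:7)
  mk <- function(vals) {
    df <- data.frame(chrom = "chr1", pos = 100L)
    for (i in seq_along(strains)) df[[strains[i]]] <- vals[i]
    cpg_table(df, strains)
  }
  flat <- call_dm_cpgs(mk(rep(0.5, 7)))
  expect_false(flat$dm)
  expect_equal(flat$variance, 0)
  # (0,0,0,1,1,1,1): sample variance 2/7, range 1 -> DM
  bi <- call_dm_cpgs(mk(c(0, 0, 0, 1, 1, 1, 1)))
  expect_equal(bi$variance, 2 / 7)
  expect_equal(bi$range, 1)
  expect_true(bi$dm)
  # 25 strains, 23 at 0.5 plus 0.1 and 0.9: variance 0.32/24 -> not DM
  s25 <- paste0("S", 1:25)
  df <- data.frame(chrom = "chr1", pos = 100L)
  vals <- c(rep(0.5, 23), 0.1, 0.9)
  for (i in seq_along(s25)) df[[s25[i]]] <- vals[i]
  near <- call_dm_cpgs(cpg_table(df, s25))
  expect_equal(near$variance, 0.32 / 24)
  expect_equal(near$range, 0.8)
  expect_false(near$dm)
})

test_that("threshold boundaries are strict inequalities", {
  # variance exactly 0.05 with range 0.894: fails the strict variance test
  s9 <- paste0("S", 1:9)
  a <- sqrt(0.2)
  df <- data.frame(chrom = "chr1", pos = 1L)
  vals <- c(0.5 - a, 0.5 + a, rep(0.5, 7))
  for (i in seq_along(s9)) df[[s9[i]]] <- vals[i]
  out <- call_dm_cpgs(cpg_table(df, s9))
  expect_equal(out$variance, 0.05)
  expect_gt(out$range, 0.75)
  expect_false(out$dm)
  # range exactly 0.75 with variance 0.28: fails the strict range test
  df2 <- data.frame(chrom = "chr1", pos = 1L, a = 0.125, b = 0.875)
  out2 <- call_dm_cpgs(cpg_table(df2, c("a", "b")))
  expect_equal(out2$range, 0.75)
  expect_gt(out2$variance, 0.05)
  expect_false(out2$dm)
})

test_that("polymorphic CpGs are excluded before DM calling", {
  strains <- paste0("S", 1:7)
  df <- data.frame(chrom = "chr1", pos = c(100L, 200L))
  for (s in strains) df[[s]] <- c(0.5, 0.5)
  df[strains] <- rbind(c(0, 0, 0, 1, 1, 1, 1), rep(0.5, 7))
  cp <- cpg_table(df, strains)
  sdf <- data.frame(chrom = "chr1", pos = 100L, ref = "C", alt = "T")
  for (s in strains) sdf[[s]] <- 0L
  sdf$S1 <- 1L
  expect_message(out <- call_dm_cpgs(cp, snps = snp_table(sdf, strains)),
                 "polymorphic")
  expect_equal(nrow(out), 1L)
  expect_equal(out$pos, 200L)
})

test_that("methylation variance grouping separates TE from unique sites", {
  set.seed(1103)
  strains <- paste0("S", 1:7)
  sites <- data.frame(site_id = sprintf("s%03d", 1:40), chrom = "chr1",
                      start = seq_len(40) * 1000L,
                      end = seq_len(40) * 1000L + 400L)
  tes <- te_table(chrom = "chr1", start = sites$start[1:20] + 50L,
                  end = sites$start[1:20] + 150L, class = "LINE",
                  subfamily = "L1")
  hits <- overlap_tes(sites, tes)
  df <- data.frame(chrom = "chr1", pos = sites$start + 200L)
  vals <- rbind(
    t(replicate(20, pmin(pmax(rnorm(7, 0.5, 0.15), 0), 1))),   # TE sites
    t(replicate(20, pmin(pmax(rnorm(7, 0.5, 0.02), 0), 1))))   # unique
  for (i in seq_along(strains)) df[[strains[i]]] <- vals[, i]
  cp <- cpg_table(df, strains)
  out <- methylation_variance_by_group(cp, sites, hits)
  expect_gt(out$medians[["te"]], out$medians[["unique"]])
  expect_lt(out$p_te_vs_unique, 0.001)
  # all-identical methylation: variance 0 everywhere, p = 1
  df0 <- df; for (s in strains) df0[[s]] <- 0.5
  out0 <- methylation_variance_by_group(cpg_table(df0, strains), sites, hits)
  expect_equal(out0$p_te_vs_unique, 1)
})

test_that("DM enrichment in TEs is a two-sided Fisher test", {
  strains <- c("a", "b", "c")
  n <- 200
  df <- data.frame(chrom = "chr1", pos = seq_len(n) * 100L)
  dm_flag <- rep(c(TRUE, FALSE), c(10, 190))
  for (s in strains) df[[s]] <- 0.5
  cp <- cpg_table(df, strains)
  cp$variance <- 0; cp$range <- 0; cp$dm <- dm_flag
  # TEs covering exactly the DM CpGs
  tes <- te_table(chrom = "chr1", start = df$pos[1:10] - 5L,
                  end = df$pos[1:10] + 5L, subfamily = "A")
  out <- dm_te_enrichment(cp, tes)
  expect_equal(out$table["dm", "in_te"], 10L)
  expect_equal(out$p, fisher_oracle(10, 0, 0, 190), tolerance = 1e-12)
  # equal DM fraction inside and outside: p = 1
  tes2 <- te_table(chrom = "chr1", start = df$pos[c(1:5, 11:105)] - 5L,
                   end = df$pos[c(1:5, 11:105)] + 5L, subfamily = "A")
  out2 <- dm_te_enrichment(cp, tes2)
  expect_equal(out2$p, 1, tolerance = 1e-9)
})
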