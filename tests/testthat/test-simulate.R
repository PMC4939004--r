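interval_overlaps_test <- function(tes) {
  n <- 0L
  for (chr in unique(tes$chrom)) {
    t <- tes[tes$chrom == chr, ]
    t <- t[order(t$start), ]
    if (nrow(t) > 1L) n <- n + sum(t$start[-1] < t$end[-nrow(t)])
  }
  n
}

test_that("simulated TE instances carry the planted divergence", {
  spec <- data.frame(subfamily = c("youngL1", "oldL1"),
                     class = "LINE", family = "L1",
                     length = c(6000L, 6000L), copies = c(10L, 10L),
                     age = c(0, 1e7), motif = "", motif_offset = 0L,
                     stringsAsFactors = FALSE)
  sim <- simulate_genome(n_chroms = 1L, chrom_length = 3e5L, te_spec = spec,
                         seed = 901)
  expect_equal(nrow(sim$tes), 20L)
  # age 0: identical to consensus
  young <- sim$tes[sim$tes$subfamily == "youngL1", ]
  expect_true(all(young$divergence == 0))
  for (i in seq_len(nrow(young))) {
    ins <- substr(sim$genome[[young$chrom[i]]], young$start[i] + 1L,
                  young$end[i])
    if (young$strand[i] == "-") ins <- revcomp(ins)
    expect_equal(ins, sim$consensus$youngL1)
  }
  # age 1e7 at rate 4.5e-9: expected divergence 0.045, binomial 3 SD bound
  old <- sim$tes[sim$tes$subfamily == "oldL1", ]
  p <- 0.045
  bound <- 3 * sqrt(p * (1 - p) / 6000)
  expect_true(all(abs(old$divergence - p) < bound))
  # placements never overlap
  ov <- interval_overlaps_test(sim$tes)
  expect_equal(ov, 0L)
})

test_that("genome simulation rejects impossible specifications", {
  spec <- default_te_spec()
  spec$age[1] <- 1e9   # divergence 4.5 > 0.75
  expect_error(simulate_genome(te_spec = spec, seed = 1), "0.75")
  spec2 <- default_te_spec()
  spec2$copies <- spec2$copies * 100L
  expect_error(simulate_genome(n_chroms = 1L, chrom_length = 1e5L,
                               te_spec = spec2, seed = 1), "capacity")
})

test_that("strain simulation places SNPs at the requested rate", {
  ref <- c(chr1 = random_genome(5e5, 902), chr2 = random_genome(5e5, 903))
  sim <- simulate_strains(ref, n_strains = 7L, snp_rate = 2e-3, seed = 904)
  n <- nrow(sim$snps)
  expect_lt(abs(n - 2000), 3 * sqrt(2000))
  # alleles: nonempty proper subsets
  gmat <- as.matrix(as.data.frame(sim$snps)[, attr(sim$snps, "strains")])
  expect_true(all(rowSums(gmat) >= 1 & rowSums(gmat) <= 6))
  # ref alleles match the genome
  i <- sample(n, 50)
  expect_equal(substring(ref["chr1"], sim$snps$pos[i][sim$snps$chrom[i] == "chr1"] + 1,
                         sim$snps$pos[i][sim$snps$chrom[i] == "chr1"] + 1),
               sim$snps$ref[i][sim$snps$chrom[i] == "chr1"],
               ignore_attr = TRUE)
  expect_equal(nrow(simulate_strains(ref, 7L, 0, seed = 905)$snps), 0L)
  expect_equal(nrow(simulate_strains(ref, 7L, 1e-4, 0, seed = 906)$carriers), 0L)
  expect_error(simulate_strains(ref, 0L, 1e-3), "strain")
  expect_error(simulate_strains(ref, 7L, -1), ">= 0")
})

test_that("polymorphic TE carriers are a controlled fraction", {
  ref <- c(chr1 = random_genome(2e5, 907))
  spec <- default_te_spec()
  spec$copies <- c(4L, 4L, 4L, 10L, 4L, 5L, 5L)
  sim <- simulate_genome(1L, 2e5L, spec, seed = 908)
  st <- simulate_strains(sim$genome, 7L, 1e-4,
                         polymorphic_te_fraction = 0.25, tes = sim$tes,
                         seed = 909)
  expect_equal(nrow(st$carriers), floor(0.25 * nrow(sim$tes)))
  expect_true(all(st$carriers$te_id %in% sim$tes$te_id))
})

test_that("count simulation validates parameters and plants means", {
  sites <- data.frame(site_id = sprintf("s%03d", 1:1000), chrom = "chr1",
                      start = 1:1000 * 500L, end = 1:1000 * 500L + 400L)
  s <- rep(paste0("S", 1:7), each = 2)
  meta <- data.frame(library = paste0(s, "_", rep(1:2, 7)), strain = s,
                     replicate = rep(1:2, 7))
  expect_error(simulate_counts(sites, meta, params = list(alpha = 0),
                               seed = 1), "Poisson limit")
  # no plan: no planted labels
  cs0 <- simulate_counts(sites[1:10, ], meta, seed = 910)
  expect_length(cs0$truth$variable_site_ids, 0L)
  # fold 4 in 3 strains at 50 sites: affected means near 400
  plan <- data.frame(site_id = sites$site_id[1:50], role = "variable",
                     mechanism = "fold", fold = 4, affected = "S1,S2,S3",
                     strain_folds = NA)
  cs <- simulate_counts(sites, meta, plan = plan, seed = 911)
  aff_cols <- meta$strain %in% c("S1", "S2", "S3")
  m <- mean(cs$sm$counts[1:50, aff_cols])
  expect_lt(abs(m - 400) / 400, 0.05)
  expect_equal(mean(cs$sm$counts[51:1000, ]), 100, tolerance = 0.05)
  expect_setequal(cs$truth$variable_site_ids, sites$site_id[1:50])
})

test_that("fragment simulation respects the mixture weights and length model", {
  g <- c(chr1 = random_genome(1e5, 912))
  expect_equal(nrow(simulate_fragments(g, NULL, 0, seed = 1)), 0L)
  plan <- data.frame(chrom = "chr1", start = 5e4L, end = 52e3L,
                     enrichment = 10)
  fr <- simulate_fragments(g, plan, 20000L, seed = 913)
  mids <- (fr$start + fr$end) %/% 2
  inside <- mean(mids >= 5e4 & mids < 52e3)
  w <- (10 - 1) * 2000 + 2000        # peak mass + its uniform share
  expected <- w / (1e5 + (10 - 1) * 2000)
  expect_lt(abs(inside - expected), 3 * sqrt(expected * (1 - expected) / 20000))
  # length model: mean 170 +/- 3, SE of the mean over 10k draws
  fr2 <- simulate_fragments(g, NULL, 10000L, seed = 914)
  expect_lt(abs(mean(fr2$end - fr2$start) - 170), 0.1)
  expect_error(simulate_fragments(g, transform(plan, enrichment = 0.5),
                                  100L, seed = 1), ">= 1")
  expect_error(simulate_fragments(g, transform(plan, end = 2e5L), 100L,
                                  seed = 1), "outside")
})

test_that("planted DM CpGs satisfy the DM definition exactly, non-DM never do", {
  strains <- paste0("S", 1:25)
  pos <- data.frame(chrom = "chr1", pos = seq_len(200) * 50L)
  plan <- data.frame(chrom = pos$chrom, pos = pos$pos,
                     dm = rep(c(TRUE, FALSE), c(20, 180)),
                     spread = 0.05)
  cp <- simulate_methylation(pos, strains, plan, seed = 915)
  called <- call_dm_cpgs(cp)
  expect_equal(which(called$dm), which(plan$dm))
  vals <- as.matrix(as.data.frame(cp)[, strains])
  v <- apply(vals, 1, var); rg <- apply(vals, 1, function(r) diff(range(r)))
  expect_true(all(v[plan$dm] > 0.05 & rg[plan$dm] > 0.75))
  expect_true(all(v[!plan$dm] <= 0.05 | rg[!plan$dm] <= 0.75))
  expect_error(simulate_methylation(pos, strains,
                                    data.frame(chrom = "chrX", pos = 1L,
                                               dm = TRUE), seed = 1),
               "unknown CpG")
})

test_that("generators are deterministic given a seed", {
  spec <- data.frame(subfamily = "A", class = "LINE", family = "L1",
                     length = 1000L, copies = 8L, age = 2e7,
                     motif = "", motif_offset = 0L)
  g1 <- simulate_genome(1L, 5e4L, spec, seed = 916)
  g2 <- simulate_genome(1L, 5e4L, spec, seed = 916)
  expect_identical(g1, g2)
  f1 <- simulate_fragments(g1$genome, NULL, 500L, seed = 917)
  f2 <- simulate_fragments(g1$genome, NULL, 500L, seed = 917)
  expect_identical(f1, f2)
})
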