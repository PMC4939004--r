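strain_design <- function(n_strains = 7L, reps = 2L)
  rep(paste0("S", seq_len(n_strains)), each = reps)

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "b"]), c(2.5, 3.5, 4.5))
  # identical columns are a fixed point
  m2 <- cbind(x = c(5, 1, 7), y = c(5, 1, 7))
  expect_equal(quantile_normalize(m2), m2)
  # single row: every entry becomes the row mean
  m3 <- cbind(3, 9)
  expect_equal(unname(quantile_normalize(m3)), cbind(6, 6))
  expect_error(quantile_normalize(matrix(1, 3, 1)), ">= 2")
  # invariant: identical sorted value vectors across tie-free columns
  set.seed(810)
  r <- matrix(rnorm(600, 100, 20), ncol = 6)
  qr <- quantile_normalize(r)
  for (j in 2:6) expect_equal(sort(qr[, j]), sort(qr[, 1]))
  # rank order within columns is preserved
  for (j in 1:6) expect_equal(order(qr[, j]), order(r[, j]))
  # with ties (integer counts) the tie-mean rule preserves column sums
  rt <- matrix(rpois(600, 30), ncol = 6)
  qt <- quantile_normalize(rt)
  expect_equal(unname(colSums(qt)), rep(mean(colSums(rt)), 6),
               tolerance = 1e-9)
  # independent cross-check: agrees with limma on tie-free data
  expect_equal(unname(qr), unname(limma::normalizeQuantiles(r)),
               tolerance = 1e-9)
})

test_that("identical counts across libraries give LRT 0 and p 1", {
  x <- matrix(50, nrow = 3, ncol = 14)
  res <- nb_variability_test(x, strain_design())
  expect_equal(res$lrt, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
  # all-zero sites are flagged untested with adjusted p 1
  x[2, ] <- 0
  res0 <- nb_variability_test(x, strain_design())
  expect_false(res0$tested[2])
  expect_true(is.na(res0$p[2]))
  expect_equal(res0$adjusted_p[2], 1)
})

test_that("the NB test needs replicated strains", {
  x <- matrix(rpois(30, 50), nrow = 3)
  expect_error(nb_variability_test(x, c(rep("A", 2), rep("B", 2),
                                        rep("C", 2), rep("D", 3), "E")),
               "replicates")
})

test_that("NB test is invariant to library order within strains", {
  set.seed(811)
  x <- matrix(rnbinom(40 * 14, size = 20, mu = 100), 40, 14)
  s <- strain_design()
  res <- nb_variability_test(x, s)
  perm <- c(2, 1, 3, 4, 6, 5, 8, 7, 9, 10, 12, 11, 14, 13)
  res_p <- nb_variability_test(x[, perm], s[perm])
  expect_equal(res_p$p, res$p, tolerance = 1e-10)
  expect_equal(res_p$alpha, res$alpha, tolerance = 1e-10)
})

test_that("planted strain effects are detected with high power", {
  set.seed(812)
  n <- 600
  x <- matrix(rnbinom(n * 14, size = 20, mu = 100), n, 14)
  s <- strain_design()
  aff <- s %in% c("S1", "S2", "S3")
  x[1:60, aff] <- rnbinom(60 * sum(aff), size = 20, mu = 400)
  res <- nb_variability_test(x, s)
  expect_gte(mean(res$adjusted_p[1:60] < 1e-4), 0.95)
  # null sites stay mostly quiet after adjustment
  expect_lte(mean(res$adjusted_p[61:n] < 0.05), 0.05)
})

test_that("classification takes exact top and bottom fractions with stable ties", {
  res <- data.frame(site_id = sprintf("s%02d", 1:10),
                    p = rep(0.5, 10), adjusted_p = rep(0.5, 10),
                    chrom = "chr1", start = 10:1 * 100L)
  lab <- classify_sites(res, 0.2)
  expect_equal(sum(lab$label == "variable"), 2L)
  expect_equal(sum(lab$label == "common"), 2L)
  # coordinate tie-break: smallest starts rank first
  expect_equal(lab$site_id[lab$label == "variable"], c("s09", "s10"))
  expect_equal(lab$site_id[lab$label == "common"], c("s01", "s02"))
  # rerunning with permuted rows gives identical labels per site
  perm <- sample(10)
  lab2 <- classify_sites(res[perm, ], 0.2)
  expect_equal(lab2$label[order(lab2$site_id)], lab$label[order(lab$site_id)])
  expect_error(classify_sites(res, 0.5), "< 0.5")
})

test_that("classification counts use half-away-from-zero rounding", {
  res <- data.frame(site_id = as.character(1:1000), p = runif(1000),
                    adjusted_p = runif(1000), chrom = "chr1",
                    start = seq_len(1000))
  lab <- classify_sites(res, 0.05)
  expect_equal(sum(lab$label == "variable"), 50L)
  expect_equal(sum(lab$label == "common"), 50L)
  # 0.05 * 50775 = 2538.75 rounds to 2539
  res2 <- data.frame(site_id = as.character(1:50775), p = runif(50775),
                     adjusted_p = runif(50775), chrom = "chr1",
                     start = seq_len(50775))
  lab2 <- classify_sites(res2, 0.05)
  expect_equal(sum(lab2$label == "variable"), 2539L)
})

test_that("end-to-end label recovery on a planted matrix", {
  set.seed(813)
  n <- 500
  s <- strain_design()
  sites <- data.frame(site_id = sprintf("site_%03d", 1:n), chrom = "chr1",
                      start = seq_len(n) * 1000L,
                      end = seq_len(n) * 1000L + 400L)
  meta <- data.frame(library = paste0(s, "_", rep(1:2, 7)), strain = s,
                     replicate = rep(1:2, 7))
  # variable sites get per-strain fold profiles with a guaranteed strong
  # up/down contrast pair, as in the default scenario
  folds <- vapply(1:25, function(i) {
    f <- 2^rnorm(7, 0, 1)
    hl <- sample.int(7, 2)
    f[hl[1]] <- f[hl[1]] * 4; f[hl[2]] <- f[hl[2]] * 0.25
    paste(signif(f, 6), collapse = ",")
  }, character(1))
  plan <- data.frame(
    site_id = sites$site_id[1:50],
    role = rep(c("variable", "common"), each = 25),
    mechanism = c(rep("fold", 25), rep("none", 25)),
    fold = NA, affected = NA,
    strain_folds = c(folds, rep(NA, 25)))
  cs <- simulate_counts(sites, meta, params = list(mu = 100, alpha = 0.05,
                                                   mu_common = 5000,
                                                   alpha_common = 1e-8),
                        plan = plan, seed = 814)
  qn <- quantile_normalize(cs$sm$counts)
  res <- nb_variability_test(qn, meta$strain)
  res$chrom <- sites$chrom; res$start <- sites$start
  lab <- classify_sites(res, 0.05)
  vrec <- mean(cs$truth$variable_site_ids %in%
                 lab$site_id[lab$label == "variable"])
  crec <- mean(cs$truth$common_site_ids %in%
                 lab$site_id[lab$label == "common"])
  expect_gte(vrec, 0.9)
  expect_gte(crec, 0.9)
})
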