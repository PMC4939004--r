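toy_sites <- function(starts, width = 100L, chrom = "chr1")
  data.frame(site_id = sprintf("s%03d", seq_along(starts)), chrom = chrom,
             start = starts, end = starts + width)

test_that("TE age is the exact quotient of divergence and rate", {
  expect_equal(te_age(0), 0)
  expect_equal(te_age(0.045, 4.5e-9), 1.0e7)
  expect_equal(te_age(0.18, 4.5e-9), 4.0e7)   # the young/old cutoff
  expect_error(te_age(0.1, 0), "> 0")
  expect_error(te_age(1.5), "\\[0, 1\\]")
  # strictly monotone in divergence at fixed rate
  d <- sort(runif(20))
  expect_true(all(diff(te_age(d)) > 0))
})

test_that("site-TE overlap uses >= 1 bp half-open semantics", {
  sites <- toy_sites(c(100L))
  tes <- te_table(chrom = rep("chr1", 2), start = c(199L, 200L),
                  end = c(300L, 320L), subfamily = c("A", "B"))
  h <- overlap_tes(sites, tes)
  expect_equal(nrow(h), 1L)
  expect_equal(h$subfamily, "A")
  # a site spanning two LINEs: one class flag, two subfamily tallies
  tes2 <- te_table(chrom = rep("chr1", 2), start = c(100L, 160L),
                   end = c(140L, 220L), class = "LINE",
                   subfamily = c("L1a", "L1b"))
  h2 <- overlap_tes(sites, tes2)
  expect_equal(nrow(h2), 2L)
  expect_equal(length(unique(h2$site_id)), 1L)
})

test_that("class enrichment reduces to Fisher's test on site-level flags", {
  sites <- toy_sites(seq(0L, 990000L, by = 10000L)[1:20])
  tes <- te_table(chrom = "chr1", start = sites$start[1:10] + 10L,
                  end = sites$start[1:10] + 50L, class = "LINE",
                  subfamily = "L1")
  h <- overlap_tes(sites, tes)
  # variable = sites 1..10 (all hit), common = 11..20 (none hit)
  ce <- class_enrichment(h, sites$site_id[1:10], sites$site_id[11:20], "LINE")
  expect_equal(ce$prop_variable, 1)
  expect_equal(ce$prop_common, 0)
  expect_equal(ce$p, 2 / choose(20, 10), tolerance = 1e-12)
  # identical proportions: p = 1
  ce2 <- class_enrichment(h, sites$site_id[c(1:5, 11:15)],
                          sites$site_id[c(6:10, 16:20)], "LINE")
  expect_equal(ce2$p, 1)
  # degenerate margin: no site hits the class anywhere
  ce3 <- class_enrichment(h, sites$site_id[1:10], sites$site_id[11:20], "LTR")
  expect_equal(ce3$p, 1)
})

test_that("subfamily enrichment filters rare subfamilies and adjusts p", {
  sites <- toy_sites(seq(0L, 990000L, by = 2000L)[1:60])
  tes <- te_table(
    chrom = "chr1",
    start = c(sites$start[1:20] + 10L, sites$start[31:34] + 10L),
    end = c(sites$start[1:20] + 50L, sites$start[31:34] + 50L),
    class = "LINE",
    subfamily = rep(c("L1Md_T", "rare"), c(20, 4)))
  h <- overlap_tes(sites, tes)
  res <- subfamily_enrichment(h, sites$site_id[1:30], sites$site_id[31:60])
  expect_false("rare" %in% res$subfamily)   # 4 hits < 5
  expect_equal(res$subfamily[1], "L1Md_T")
  expect_equal(res$n_variable[1], 20L)
  expect_equal(res$n_common[1], 0L)
  expect_lt(res$adjusted_p[1], 1e-5)
  # symmetric tallies: adjusted p 1
  res2 <- subfamily_enrichment(h, sites$site_id[c(1:10, 31:32)],
                               sites$site_id[c(11:20, 33:34)])
  expect_equal(res2$adjusted_p[res2$subfamily == "L1Md_T"], 1)
})

test_that("age distributions are compared by the exact rank-sum test", {
  out <- age_distribution_compare(c(1, 2, 3) * 1e6, c(4, 5, 6) * 1e6)
  expect_equal(out$p, 0.1)
  same <- age_distribution_compare(c(1e6, 2e6), c(1e6, 2e6))
  expect_equal(same$p, 1)
  # strongly separated young vs old ages
  set.seed(1001)
  young <- runif(30, 4e6, 1.5e7)
  old <- runif(25, 6e7, 9e7)
  expect_lt(age_distribution_compare(young, old)$p, 1e-6)
})

test_that("subfamily accessibility matrix z-scores strain means", {
  sites <- toy_sites(c(1000L, 5000L, 9000L))
  tes <- te_table(chrom = "chr1", start = sites$start + 10L,
                  end = sites$start + 60L, class = "LINE",
                  subfamily = c("A", "A", "B"))
  h <- overlap_tes(sites, tes)
  s <- rep(c("S1", "S2", "S3"), each = 2)
  meta <- data.frame(library = paste0(s, "_", rep(1:2, 3)), strain = s,
                     replicate = rep(1:2, 3))
  counts <- matrix(10, 3, 6, dimnames = list(sites$site_id, meta$library))
  sm <- site_matrix(sites, counts, meta)
  sm$normalized <- sm$counts
  z0 <- subfamily_accessibility_matrix(sm, h)
  expect_true(all(z0 == 0))   # identical strain columns
  # one strain elevated 2x everywhere has the row-max z in every row
  sm$normalized[, meta$strain == "S2"] <- 20
  z <- subfamily_accessibility_matrix(sm, h)
  expect_true(all(apply(z, 1, which.max) == 2))
})

test_that("polymorphic TE fractions count hit instances once", {
  sites <- toy_sites(c(1000L, 5000L, 9000L))
  tes <- te_table(chrom = "chr1", start = sites$start + 10L,
                  end = sites$start + 60L, subfamily = "A")
  h <- overlap_tes(sites, tes)
  none <- polymorphic_fraction(h, sites$site_id,
                               data.frame(te_id = integer(),
                                          carriers = character()))
  expect_equal(none$fraction, 0)
  all_p <- polymorphic_fraction(h, sites$site_id,
                                data.frame(te_id = tes$te_id,
                                           carriers = "S1"))
  expect_equal(all_p$fraction, 1)
  some <- polymorphic_fraction(h, sites$site_id[1:2],
                               data.frame(te_id = tes$te_id[1],
                                          carriers = "S1"))
  expect_equal(some$fraction, 0.5)
})

test_that("boundary profiles aggregate coverage around TE ends", {
  tes <- te_table(chrom = "chr1", start = c(4000L, 12000L),
                  end = c(6000L, 14000L), strand = c("+", "-"),
                  subfamily = "A", divergence = c(0.01, 0.3))
  L <- 20000L
  # uniform coverage: every bin equals the constant
  cov_u <- list(chr1 = rep(2, L))
  bp <- boundary_profile(cov_u, tes, flank = 1000L, bin = 50L)
  expect_true(all(bp$five_prime == 2))
  expect_true(all(bp$three_prime == 2))
  expect_equal(bp$ages, sort(tes$age))
  # zero coverage: zero matrices
  bp0 <- boundary_profile(list(chr1 = rep(0, L)), tes, flank = 1000L)
  expect_true(all(bp0$five_prime == 0))
  # elevated coverage inside the young element only
  cov_y <- rep(1, L); cov_y[4001:6000] <- 5
  bp2 <- boundary_profile(list(chr1 = cov_y), tes, flank = 1000L, bin = 50L)
  inside <- 21:40   # bins past the boundary, inside the element
  young_row <- 1    # rows ordered by age ascending
  expect_equal(mean(bp2$five_prime[young_row, inside]), 5)
  expect_equal(mean(bp2$five_prime[2, inside]), 1)
  # short elements are excluded with a message
  tes_short <- rbind(tes, te_table(chrom = "chr1", start = 8000L,
                                   end = 8060L, subfamily = "tiny"))
  expect_message(bp3 <- boundary_profile(list(chr1 = cov_u$chr1), tes_short,
                                         flank = 1000L, bin = 50L),
                 "excluding 1")
  expect_equal(nrow(bp3$five_prime), 2L)
})
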