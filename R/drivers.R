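# Attribution of chromatin variability to SNP genotype (per-site linear
# regression) and to differential DNA methylation.

# per-strain replicate-averaged normalized counts for one site
strain_response <- function(sm, site_id) {
  stopifnot(!is.null(sm$normalized))
  strains <- unique(sm$meta$strain)
  v <- vapply(strains, function(s)
    mean(sm$normalized[site_id, sm$meta$strain == s]), numeric(1))
  setNames(v, strains)
}

#' SNP-genotype association at one site
#'
#' For every SNP overlapping the site, the per-strain response (mean of
#' replicate normalized counts) is regressed on the 0/1 genotype vector by
#' ordinary least squares; slope, R-squared and the F-test p-value
#' (1 and n_strains - 2 df) are returned.  Constant genotype vectors give an
#' NA result with a reason code rather than an error.
#'
#' @param site_id a site id present in `sm`.
#' @param sm a `site_matrix` with normalized counts.
#' @param snps a `snp_table`.
#' @return data.frame with one row per overlapping SNP: `site_id`, `chrom`,
#'   `pos`, `beta`, `r_squared`, `p`, `reason` (NA when testable).
#' @export
snp_association <- function(site_id, sm, snps) {
  site <- sm$sites[sm$sites$site_id == site_id, , drop = FALSE]
  if (!nrow(site)) stop("unknown site: ", site_id)
  strains <- unique(sm$meta$strain)
  if (length(strains) < 3L) stop("need >= 3 strains for regression")
  sel <- snps$chrom == site$chrom & snps$pos >= site$start & snps$pos < site$end
  hits <- snps[sel, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(site_id = character(), chrom = character(),
                      pos = integer(), beta = numeric(),
                      r_squared = numeric(), p = numeric(),
                      reason = character()))
  y <- strain_response(sm, site_id)
  out <- lapply(seq_len(nrow(hits)), function(i) {
    g <- as.numeric(hits[i, strains])
    row <- data.frame(site_id = site_id, chrom = hits$chrom[i],
                      pos = hits$pos[i], beta = NA_real_,
                      r_squared = NA_real_, p = NA_real_,
                      reason = NA_character_, stringsAsFactors = FALSE)
    if (var(g) == 0) { row$reason <- "constant_genotype"; return(row) }
    n <- length(g)
    beta <- stats::cov(g, y) / var(g)
    yhat <- mean(y) + beta * (g - mean(g))
    sst <- sum((y - mean(y))^2)
    ssr <- sum((y - yhat)^2)
    r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
    if (is.na(r2)) { row$reason <- "constant_response"; return(row) }
    row$beta <- beta
    row$r_squared <- r2
    if (r2 >= 1) row$p <- 0
    else row$p <- pf(r2 / (1 - r2) * (n - 2), 1, n - 2, lower.tail = FALSE)
    row
  })
  do.call(rbind, out)
}

#' Fraction of variable sites explained by SNPs
#'
#' Runs [snp_association()] for every variable site, Benjamini-Hochberg
#' adjusts across all site-SNP tests, and reports the fraction of variable
#' sites with at least one SNP whose adjusted p-value is below `alpha`.
#'
#' @param variable_ids variable site ids.
#' @param sm a `site_matrix` with normalized counts.
#' @param snps a `snp_table`.
#' @param alpha significance level on the adjusted p-values (default 0.05).
#' @return list: `fraction`, `n_explained`, `n_variable`, `tests`
#'   (the full association table).
#' @export
fraction_snp_explained <- function(variable_ids, sm, snps, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  tests <- do.call(rbind, lapply(variable_ids, snp_association, sm = sm,
                                 snps = snps))
  if (is.null(tests) || !nrow(tests) || all(is.na(tests$p))) {
    message("fraction_snp_explained: no variable site overlaps a testable SNP")
    return(list(fraction = 0, n_explained = 0L,
                n_variable = length(variable_ids), tests = tests))
  }
  tests$adjusted_p <- bh_adjust(tests$p)
  expl <- unique(tests$site_id[!is.na(tests$adjusted_p) &
                               tests$adjusted_p < alpha])
  list(fraction = length(expl) / length(variable_ids),
       n_explained = length(expl), n_variable = length(variable_ids),
       tests = tests)
}

#' Call differentially methylated CpGs
#'
#' A CpG is differentially methylated (DM) iff its cross-strain sample
#' variance (n - 1 denominator) strictly exceeds `variance_threshold` AND
#' its range (max - min) strictly exceeds `range_threshold`.  CpGs with
#' fewer than two non-missing strain values are untestable (`dm = NA`).
#' CpGs whose position coincides with a SNP are excluded beforehand when
#' `snps` is given (polymorphic CpGs).
#'
#' @param cpgs a `cpg_table`.
#' @param variance_threshold variance cutoff (default 0.05).
#' @param range_threshold range cutoff (default 0.75).
#' @param snps optional `snp_table` used to drop polymorphic CpGs.
#' @return the table with added `variance`, `range`, `dm` columns (rows for
#'   polymorphic CpGs removed), plus a `dm_counts` attribute.
#' @export
call_dm_cpgs <- function(cpgs, variance_threshold = 0.05,
                         range_threshold = 0.75, snps = NULL) {
  strains <- attr(cpgs, "strains")
  df <- as.data.frame(cpgs)
  if (!is.null(snps) && nrow(snps)) {
    key <- paste(df$chrom, df$pos)
    poly <- key %in% paste(snps$chrom, snps$pos)
    if (any(poly))
      message(sprintf("call_dm_cpgs: excluding %d polymorphic CpG(s)", sum(poly)))
    df <- df[!poly, , drop = FALSE]
  }
  vals <- as.matrix(df[, strains, drop = FALSE])
  n_ok <- rowSums(!is.na(vals))
  v <- apply(vals, 1L, function(r) if (sum(!is.na(r)) >= 2L) var(r, na.rm = TRUE) else NA_real_)
  rg <- apply(vals, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) >= 2L) max(r) - min(r) else NA_real_
  })
  df$variance <- v
  df$range <- rg
  df$dm <- ifelse(n_ok < 2L, NA,
                  v > variance_threshold & rg > range_threshold)
  out <- cpg_table(df, strains)
  attr(out, "dm_counts") <- c(dm = sum(df$dm, na.rm = TRUE),
                              not_dm = sum(!df$dm, na.rm = TRUE),
                              untestable = sum(is.na(df$dm)))
  out
}

# assign each CpG inside a variable site to a group by the site's annotation
# (TE > other-repeat > unique precedence)
assign_cpg_groups <- function(cpgs, sites, hits) {
  te_classes_proper <- c("LINE", "SINE", "LTR", "DNA")
  site_group <- setNames(rep("unique", nrow(sites)), sites$site_id)
  other_sites <- unique(hits$site_id[hits$class == "Other"])
  te_sites <- unique(hits$site_id[hits$class %in% te_classes_proper])
  site_group[names(site_group) %in% other_sites] <- "other_repeat"
  site_group[names(site_group) %in% te_sites] <- "te"
  df <- as.data.frame(cpgs)
  grp <- rep(NA_character_, nrow(df))
  for (chr in unique(df$chrom)) {
    ci <- which(df$chrom == chr)
    si <- which(sites$chrom == chr)
    if (!length(si)) next
    pos <- findInterval(df$pos[ci], sites$start[si])
    ok <- pos >= 1L & df$pos[ci] < sites$end[si][pmax(pos, 1L)]
    grp[ci[ok]] <- site_group[sites$site_id[si][pos[ok]]]
  }
  grp
}

#' Cross-strain methylation variance by site annotation group
#'
#' CpGs falling inside the given sites are grouped by the site's annotation
#' (TE, other repeat, or unique sequence; TE > other-repeat > unique
#' precedence for sites with mixed annotation), and the distributions of
#' per-CpG cross-strain variances are compared (TE vs unique, Wilcoxon
#' rank-sum).
#'
#' @param cpgs a `cpg_table` (with `variance` column, else computed).
#' @param sites site data.frame (typically the variable sites).
#' @param hits a `te_hits` table for those sites.
#' @return list: `variances` (named list per group), `medians`,
#'   `p_te_vs_unique`.
#' @export
methylation_variance_by_group <- function(cpgs, sites, hits) {
  strains <- attr(cpgs, "strains")
  df <- as.data.frame(cpgs)
  if (!"variance" %in% names(df)) {
    vals <- as.matrix(df[, strains, drop = FALSE])
    df$variance <- apply(vals, 1L, var, na.rm = TRUE)
  }
  grp <- assign_cpg_groups(cpgs, sites, hits)
  keep <- !is.na(grp) & !is.na(df$variance)
  groups <- split(df$variance[keep], grp[keep])
  for (g in setdiff(c("te", "other_repeat", "unique"), names(groups)))
    message("methylation_variance_by_group: empty group omitted: ", g)
  p <- if (all(c("te", "unique") %in% names(groups)))
    wilcoxon_rank_sum(groups$te, groups$unique) else NA_real_
  list(variances = groups,
       medians = vapply(groups, stats::median, numeric(1)),
       p_te_vs_unique = p)
}

#' DM-CpG enrichment in TE sequence
#'
#' Two-sided Fisher's exact test on (DM / not DM) x (CpG inside a TE / not).
#'
#' @param cpgs a `cpg_table` with a `dm` column (see [call_dm_cpgs()]).
#' @param tes a `te_table` used to annotate CpG positions.
#' @return list: `table` (2x2), `prop_dm_in_te`, `prop_other_in_te`, `p`.
#' @export
dm_te_enrichment <- function(cpgs, tes) {
  df <- as.data.frame(cpgs)
  stopifnot("dm" %in% names(df))
  df <- df[!is.na(df$dm), , drop = FALSE]
  cp <- data.frame(chrom = df$chrom, start = df$pos, end = df$pos + 1L)
  ov <- interval_overlaps(cp, tes)
  in_te <- seq_len(nrow(df)) %in% ov$q
  a <- sum(df$dm & in_te); b <- sum(df$dm & !in_te)
  cc <- sum(!df$dm & in_te); d <- sum(!df$dm & !in_te)
  tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE,
                dimnames = list(c("dm", "not_dm"), c("in_te", "not_in_te")))
  p <- if ((a + cc) == 0 || (b + d) == 0 || (a + b) == 0 || (cc + d) == 0) 1
       else fisher_exact_two_sided(tab)
  list(table = tab,
       prop_dm_in_te = if (a + b > 0) a / (a + b) else NA_real_,
       prop_other_in_te = if (cc + d > 0) cc / (cc + d) else NA_real_,
       p = p)
}
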