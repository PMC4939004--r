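# TE overlap, age derivation, class/subfamily/age enrichment and boundary
# aggregate profiles.

#' TE age from divergence
#'
#' `age = divergence / substitution_rate` (years); divergence is the
#' fraction of bases differing from the subfamily consensus.
#'
#' @param divergence fraction in `[0, 1]`.
#' @param substitution_rate substitutions/site/year (> 0); default 4.5e-9,
#'   the mouse neutral rate.
#' @return age in years.
#' @export
te_age <- function(divergence, substitution_rate = 4.5e-9) {
  if (any(substitution_rate <= 0)) stop("substitution_rate must be > 0")
  if (any(divergence < 0 | divergence > 1)) stop("divergence must lie in [0, 1]")
  divergence / substitution_rate
}

#' Overlap sites with TE annotations
#'
#' A site hits a TE iff the intervals share >= 1 bp (half-open semantics).
#' All hits are recorded: a site overlapping two TEs of one class counts
#' once for class proportions, but each TE instance contributes its own row
#' for subfamily tallies.
#'
#' @param sites site data.frame (`site_id`, `chrom`, `start`, `end`).
#' @param tes a `te_table`.
#' @return a `te_hits` data.frame with one row per (site, TE) pair:
#'   `site_id`, `te_id`, `class`, `family`, `subfamily`, `divergence`,
#'   `age`, `te_length`, `te_strand`.
#' @export
overlap_tes <- function(sites, tes) {
  ov <- interval_overlaps(sites, tes)
  out <- data.frame(
    site_id = sites$site_id[ov$q],
    te_id = tes$te_id[ov$s],
    class = as.character(tes$class)[ov$s],
    family = tes$family[ov$s],
    subfamily = tes$subfamily[ov$s],
    divergence = tes$divergence[ov$s],
    age = tes$age[ov$s],
    te_length = tes$length[ov$s],
    te_strand = tes$strand[ov$s],
    stringsAsFactors = FALSE)
  class(out) <- c("te_hits", "data.frame")
  out
}

#' TE class enrichment between variable and common sites
#'
#' Two-sided Fisher's exact test on the 2x2 table of
#' (variable/common) x (site overlaps the class / does not).
#'
#' @param hits a `te_hits` table from [overlap_tes()].
#' @param variable_ids,common_ids site ids of the two groups (nonempty).
#' @param te_class one of `"LINE"`, `"SINE"`, `"LTR"`, `"DNA"`, `"Other"`.
#' @return list: `prop_variable`, `prop_common`, `table` (2x2), `p`.
#' @export
class_enrichment <- function(hits, variable_ids, common_ids, te_class) {
  stopifnot(length(variable_ids) > 0, length(common_ids) > 0)
  hit_sites <- unique(hits$site_id[hits$class == te_class])
  a <- sum(variable_ids %in% hit_sites)
  b <- length(variable_ids) - a
  cc <- sum(common_ids %in% hit_sites)
  d <- length(common_ids) - cc
  tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE,
                dimnames = list(c("variable", "common"), c("hit", "no_hit")))
  p <- if ((a + cc) == 0 || (b + d) == 0) 1 else fisher_exact_two_sided(tab)
  list(class = te_class, prop_variable = a / length(variable_ids),
       prop_common = cc / length(common_ids), table = tab, p = p)
}

#' Per-subfamily enrichment between variable and common sites
#'
#' One 2x2 Fisher test per subfamily (sites hitting the subfamily vs not,
#' by variable/common), Benjamini-Hochberg corrected across subfamilies.
#' Subfamilies with fewer than `min_hits` total site hits are excluded.
#'
#' @inheritParams class_enrichment
#' @param min_hits minimum total site hits for a subfamily to be tested.
#' @return data.frame: `subfamily`, `n_variable`, `n_common`, `p`,
#'   `adjusted_p`, ordered by `p`.
#' @export
subfamily_enrichment <- function(hits, variable_ids, common_ids, min_hits = 5L) {
  nv <- length(variable_ids); ncm <- length(common_ids)
  subs <- unique(hits$subfamily)
  rows <- lapply(subs, function(sf) {
    hs <- unique(hits$site_id[hits$subfamily == sf])
    a <- sum(variable_ids %in% hs)
    cc <- sum(common_ids %in% hs)
    data.frame(subfamily = sf, n_variable = a, n_common = cc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(subfamily = character(),
                                      n_variable = integer(),
                                      n_common = integer(),
                                      p = numeric(), adjusted_p = numeric()))
  out <- out[out$n_variable + out$n_common >= min_hits, , drop = FALSE]
  if (!nrow(out)) { out$p <- numeric(0); out$adjusted_p <- numeric(0); return(out) }
  out$p <- vapply(seq_len(nrow(out)), function(i)
    fisher_exact_two_sided(matrix(c(out$n_variable[i], nv - out$n_variable[i],
                                    out$n_common[i], ncm - out$n_common[i]),
                                  2, byrow = TRUE)), numeric(1))
  out$adjusted_p <- bh_adjust(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare TE age distributions between two site groups
#'
#' Two-sided Wilcoxon rank-sum test on per-instance TE ages (exact
#' enumeration for small samples, normal approximation with tie and
#' continuity corrections otherwise).
#'
#' @param ages_variable,ages_common numeric vectors of TE ages (years).
#' @return list: `p`, `median_variable`, `median_common`.
#' @export
age_distribution_compare <- function(ages_variable, ages_common) {
  stopifnot(length(ages_variable) > 0, length(ages_common) > 0)
  list(p = wilcoxon_rank_sum(ages_variable, ages_common),
       median_variable = stats::median(ages_variable),
       median_common = stats::median(ages_common))
}

#' Subfamily-by-strain accessibility matrix
#'
#' Entry (subfamily, strain) = mean over the subfamily's hit sites of the
#' strain's replicate-averaged normalized count, z-scored within each
#' subfamily across strains.  Subfamilies with no hit sites are omitted.
#'
#' @param sm a `site_matrix` with a `normalized` slot.
#' @param hits a `te_hits` table.
#' @return numeric matrix, subfamilies x strains (z-scores).
#' @export
subfamily_accessibility_matrix <- function(sm, hits) {
  stopifnot(!is.null(sm$normalized))
  strains <- unique(sm$meta$strain)
  strain_means <- vapply(strains, function(s)
    rowMeans(sm$normalized[, sm$meta$strain == s, drop = FALSE]),
    numeric(nrow(sm$normalized)))
  rownames(strain_means) <- sm$sites$site_id
  subs <- unique(hits$subfamily)
  rows <- lapply(subs, function(sf) {
    sid <- unique(hits$site_id[hits$subfamily == sf])
    sid <- intersect(sid, rownames(strain_means))
    if (!length(sid)) return(NULL)
    colMeans(strain_means[sid, , drop = FALSE])
  })
  keep <- !vapply(rows, is.null, logical(1))
  m <- do.call(rbind, rows[keep])
  rownames(m) <- subs[keep]
  t(apply(m, 1L, function(r) {
    s <- sd(r)
    if (s == 0) r * 0 else (r - mean(r)) / s
  }))
}

#' Polymorphic fraction of TEs at variable sites
#'
#' Fraction of distinct TE instances hit by variable sites that are flagged
#' polymorphic, plus a per-site concordance flag set when the accessible
#' strains (top half by replicate-averaged normalized count) equal the
#' polymorphic TE's carrier set.
#'
#' @param hits a `te_hits` table.
#' @param variable_ids variable site ids.
#' @param carriers data.frame `te_id`, `carriers` (comma-separated strain
#'   names); TEs absent from it are non-polymorphic.
#' @param sm optional `site_matrix` (needed for concordance flags).
#' @return list: `fraction`, `n_polymorphic`, `n_hit_tes`, `concordance`
#'   (data.frame or NULL).
#' @export
polymorphic_fraction <- function(hits, variable_ids, carriers, sm = NULL) {
  vh <- hits[hits$site_id %in% variable_ids, , drop = FALSE]
  te_ids <- unique(vh$te_id)
  n_hit <- length(te_ids)
  poly_ids <- intersect(te_ids, carriers$te_id)
  frac <- if (n_hit) length(poly_ids) / n_hit else 0
  conc <- NULL
  if (!is.null(sm) && !is.null(sm$normalized) && length(poly_ids)) {
    strains <- unique(sm$meta$strain)
    strain_means <- vapply(strains, function(s)
      rowMeans(sm$normalized[, sm$meta$strain == s, drop = FALSE]),
      numeric(nrow(sm$normalized)))
    rownames(strain_means) <- sm$sites$site_id
    ph <- vh[vh$te_id %in% poly_ids, , drop = FALSE]
    conc <- do.call(rbind, lapply(seq_len(nrow(ph)), function(i) {
      sid <- ph$site_id[i]
      if (!sid %in% rownames(strain_means)) return(NULL)
      v <- strain_means[sid, ]
      acc <- names(sort(v, decreasing = TRUE))[seq_len(length(v) %/% 2L)]
      carr <- strsplit(carriers$carriers[carriers$te_id == ph$te_id[i]][1], ",")[[1]]
      data.frame(site_id = sid, te_id = ph$te_id[i],
                 concordant = setequal(acc, carr), stringsAsFactors = FALSE)
    }))
  }
  list(fraction = frac, n_polymorphic = length(poly_ids), n_hit_tes = n_hit,
       concordance = conc)
}

#' Coverage profiles around TE boundaries
#'
#' Per-TE coverage in `[boundary - flank, boundary + flank)` at `bin`-bp
#' bins around the 5' and 3' ends (strand-aware; rows are reversed for
#' minus-strand elements and the 3' matrix is flipped, so both matrices
#' read left-to-right from outside the element into its body).  Rows are
#' ordered by age ascending.  Aggregate curves rescale each element body to
#' `body_bins` bins with fixed-width flanks and average within length
#' strata.  Elements shorter than two bins are excluded.
#'
#' @param coverage named list of per-bp coverage vectors (see
#'   [fragment_coverage()]).
#' @param tes a `te_table`.
#' @param flank flank in bp (default 2500).
#' @param bin bin width in bp (default 50).
#' @param length_strata breaks in bp for the aggregate length strata.
#' @param body_bins bins for the rescaled element body.
#' @return list: `five_prime`, `three_prime` (TE x bin matrices, rownames =
#'   te_id ordered by age), `ages`, `aggregate` (per-stratum mean curves),
#'   `excluded` (te_ids too short).
#' @export
boundary_profile <- function(coverage, tes, flank = 2500L, bin = 50L,
                             length_strata = c(0, 1000, 3000, 6000, Inf),
                             body_bins = 50L) {
  short <- tes$length < 2L * bin
  if (any(short))
    message(sprintf("boundary_profile: excluding %d element(s) shorter than 2 bins",
                    sum(short)))
  tt <- tes[!short, , drop = FALSE]
  tt <- tt[order(tt$age), , drop = FALSE]
  nb <- as.integer(2L * flank / bin)
  grab <- function(chr, from) {
    # mean coverage in nb bins of width bin starting at `from` (0-based)
    v <- coverage[[chr]]
    idx <- from + seq_len(nb * bin)            # 1-based into v
    vals <- ifelse(idx >= 1L & idx <= length(v), v[pmax(pmin(idx, length(v)), 1L)], 0)
    colMeans(matrix(vals, nrow = bin))
  }
  five <- matrix(0, nrow(tt), nb)
  three <- matrix(0, nrow(tt), nb)
  for (i in seq_len(nrow(tt))) {
    plus <- tt$strand[i] != "-"
    b5 <- if (plus) tt$start[i] else tt$end[i]
    b3 <- if (plus) tt$end[i] else tt$start[i]
    w5 <- grab(tt$chrom[i], b5 - flank)
    w3 <- grab(tt$chrom[i], b3 - flank)
    if (!plus) { w5 <- rev(w5); w3 <- rev(w3) }
    five[i, ] <- w5
    three[i, ] <- rev(w3)   # flip: outside -> inside, like the 5' matrix
  }
  rownames(five) <- rownames(three) <- tt$te_id
  # aggregate: rescaled body + fixed flanks, per length stratum
  fl_bins <- as.integer(flank / bin)
  agg <- list()
  strat <- cut(tt$length, breaks = length_strata, right = FALSE)
  for (lv in levels(strat)) {
    idx <- which(strat == lv)
    if (!length(idx)) next
    curves <- t(vapply(idx, function(i) {
      plus <- tt$strand[i] != "-"
      chr <- tt$chrom[i]
      up <- grab(chr, (if (plus) tt$start[i] else tt$end[i]) - flank)[seq_len(fl_bins)]
      dn_raw <- grab(chr, (if (plus) tt$end[i] else tt$start[i]) - flank)
      dn <- dn_raw[fl_bins + seq_len(fl_bins)]
      if (!plus) { up <- rev(grab(chr, tt$end[i] - flank))[seq_len(fl_bins)]
                   dn <- rev(grab(chr, tt$start[i] - flank))[fl_bins + seq_len(fl_bins)] }
      v <- coverage[[chr]]
      bi <- (tt$start[i] + 1L):tt$end[i]
      body <- v[pmax(pmin(bi, length(v)), 1L)]
      if (!plus) body <- rev(body)
      body_r <- stats::approx(seq_along(body), body,
                              xout = seq(1, length(body), length.out = body_bins))$y
      c(up, body_r, dn)
    }, numeric(2L * fl_bins + body_bins)))
    agg[[lv]] <- colMeans(curves)
  }
  list(five_prime = five, three_prime = three, ages = tt$age,
       aggregate = agg, bin = bin, flank = flank,
       excluded = tes$te_id[short])
}
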