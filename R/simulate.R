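# Synthetic-data generators with known ground truth: genomes with planted
# TE copies of controlled age, strain SNP tables, NB count matrices with
# planted variable/common strata, FAIRE-like fragment libraries, and
# methylation tables with planted DM CpGs.

#' Default TE subfamily specification
#'
#' Seven subfamilies spanning ages 5-90 Myr.  The two young LINE
#' subfamilies carry a GAS-like STAT motif in their consensus so that motif
#' enrichment at young LINEs is recoverable downstream.
#'
#' @param motif motif string planted into young-LINE consensus sequences.
#' @return data.frame: `subfamily`, `class`, `family`, `length`, `copies`,
#'   `age`, `motif`, `motif_offset`.
#' @export
default_te_spec <- function(motif = "TTCCCGGAA") {
  data.frame(
    subfamily = c("L1Md_T", "L1Md_A", "L1_Mus3", "B1_Mus", "IAPEz",
                  "RLTR10", "MER20"),
    class = c("LINE", "LINE", "LINE", "SINE", "LTR", "LTR", "DNA"),
    family = c("L1", "L1", "L1", "Alu", "ERVK", "ERVK", "hAT-Charlie"),
    length = c(6000L, 6000L, 5000L, 150L, 2000L, 500L, 200L),
    copies = c(22L, 22L, 30L, 80L, 30L, 40L, 40L),
    age = c(5e6, 8e6, 6.5e7, 6e7, 1e7, 7e7, 9e7),
    motif = c(motif, motif, "", "", "", "", ""),
    # centered in the consensus: downstream sites sit at TE midpoints
    motif_offset = c(2995L, 2995L, 0L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
}

random_dna <- function(n, gc = 0.42) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_sequence <- function(seq, p_sub) {
  s <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(s)) < p_sub)
  if (length(hit)) {
    alt <- vapply(s[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    s[hit] <- alt
  }
  list(seq = paste(s, collapse = ""), divergence = length(hit) / length(s))
}

#' Simulate a genome with planted TE copies of controlled age
#'
#' Background sequence is i.i.d. at the given GC fraction.  Each TE
#' instance is its subfamily consensus mutated at a per-site substitution
#' probability of `age x substitution_rate` (capped at 0.75); the realized
#' divergence (fraction of mutated sites) is recorded and defines the
#' instance's derived age.  Instances are placed uniformly without overlap.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param te_spec data.frame as from [default_te_spec()] (an optional
#'   `consensus` column overrides the generated consensus).
#' @param seed integer seed.
#' @param gc background GC fraction.
#' @param substitution_rate substitutions/site/year.
#' @param min_gap minimum gap between placed TEs (bp).
#' @return list: `genome` (named character vector), `tes` (a `te_table`),
#'   `consensus` (named list of subfamily consensus sequences).
#' @export
simulate_genome <- function(n_chroms = 2L, chrom_length = 1e6L,
                            te_spec = default_te_spec(), seed = 1L,
                            gc = 0.42, substitution_rate = 4.5e-9,
                            min_gap = 200L) {
  set.seed(seed)
  p_sub <- te_spec$age * substitution_rate
  if (any(p_sub > 0.75))
    stop("target divergence exceeds 0.75 for subfamily ",
         te_spec$subfamily[p_sub > 0.75][1])
  total_te <- sum((te_spec$length + min_gap) * te_spec$copies)
  if (total_te > 0.6 * n_chroms * chrom_length)
    stop("TE copies exceed genome capacity")
  chroms <- paste0("chr", seq_len(n_chroms))
  genome <- setNames(vapply(chroms, function(x) random_dna(chrom_length, gc),
                            character(1)), chroms)
  consensus <- list()
  for (i in seq_len(nrow(te_spec))) {
    sf <- te_spec$subfamily[i]
    consensus[[sf]] <- if (!is.null(te_spec$consensus))
      te_spec$consensus[i] else random_dna(te_spec$length[i], gc)
    if (nzchar(te_spec$motif[i] %||% "")) {
      m <- te_spec$motif[i]
      off <- te_spec$motif_offset[i]
      substr(consensus[[sf]], off + 1L, off + nchar(m)) <- m
    }
  }
  # uniform non-overlapping placement, largest elements first
  placed <- data.frame(chrom = character(), start = integer(), end = integer())
  rows <- list()
  spec_order <- order(-te_spec$length)
  for (i in spec_order) {
    len <- te_spec$length[i]
    for (cp in seq_len(te_spec$copies[i])) {
      ok <- FALSE
      for (try in seq_len(2000L)) {
        chr <- sample(chroms, 1L)
        st <- sample.int(chrom_length - len - min_gap, 1L) - 1L
        prev <- placed[placed$chrom == chr, , drop = FALSE]
        if (!nrow(prev) ||
            all(st + len + min_gap <= prev$start | st >= prev$end + min_gap)) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("TE copies exceed genome capacity (placement failed)")
      placed <- rbind(placed, data.frame(chrom = chr, start = st,
                                         end = st + len))
      mut <- mutate_sequence(consensus[[te_spec$subfamily[i]]],
                             min(te_spec$age[i] * substitution_rate, 0.75))
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "-") revcomp(mut$seq) else mut$seq
      substr(genome[[chr]], st + 1L, st + len) <- ins
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = chr, start = st, end = st + len, strand = strand,
                   class = te_spec$class[i], family = te_spec$family[i],
                   subfamily = te_spec$subfamily[i],
                   divergence = mut$divergence, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  tes <- te_table(df$chrom, df$start, df$end, strand = df$strand,
                  class = df$class, family = df$family,
                  subfamily = df$subfamily, divergence = df$divergence,
                  substitution_rate = substitution_rate)
  list(genome = genome, tes = tes, consensus = consensus)
}

#' Simulate strain SNPs and polymorphic TE carriers
#'
#' SNPs are placed uniformly at `snp_rate` per bp; each alt allele is
#' carried by a random nonempty proper subset of strains.  A fraction of
#' TE instances is marked polymorphic with a random carrier subset.
#'
#' @param reference named character vector of chromosome sequences.
#' @param n_strains number of strains (>= 2 for proper subsets).
#' @param snp_rate SNPs per bp, in `[0, 0.01]`.
#' @param polymorphic_te_fraction fraction of TEs marked polymorphic.
#' @param tes optional `te_table` (required if the fraction is > 0).
#' @param seed integer seed.
#' @param strain_names optional strain names (default `S1..Sn`).
#' @return list: `snps` (a `snp_table`), `carriers` (data.frame `te_id`,
#'   `carriers` comma-joined).
#' @export
simulate_strains <- function(reference, n_strains = 7L, snp_rate = 1e-3,
                             polymorphic_te_fraction = 0, tes = NULL,
                             seed = 1L, strain_names = NULL) {
  if (n_strains < 1L) stop("need at least one strain")
  if (snp_rate < 0) stop("snp_rate must be >= 0")
  if (snp_rate > 0.01) stop("snp_rate above 0.01 per bp is not supported")
  set.seed(seed)
  strains <- strain_names %||% paste0("S", seq_len(n_strains))
  rows <- list()
  for (chr in names(reference)) {
    L <- nchar(reference[[chr]])
    n <- rbinom(1L, L, snp_rate)
    if (!n) next
    pos <- sort(sample.int(L, n)) - 1L
    ref <- substring(reference[[chr]], pos + 1L, pos + 1L)
    keep <- ref %in% c("A", "C", "G", "T")
    pos <- pos[keep]; ref <- ref[keep]
    alt <- vapply(ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    rows[[chr]] <- data.frame(chrom = chr, pos = pos, ref = ref, alt = alt,
                              stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows)
  else data.frame(chrom = character(), pos = integer(),
                  ref = character(), alt = character())
  if (nrow(df)) {
    gmat <- t(vapply(seq_len(nrow(df)), function(i) {
      k <- sample.int(max(n_strains - 1L, 1L), 1L)  # nonempty proper subset
      g <- integer(n_strains)
      g[sample.int(n_strains, k)] <- 1L
      g
    }, integer(n_strains)))
    for (j in seq_len(n_strains)) df[[strains[j]]] <- gmat[, j]
  } else for (s in strains) df[[s]] <- integer()
  rownames(df) <- NULL
  snps <- snp_table(df, strains)
  carriers <- data.frame(te_id = integer(), carriers = character())
  if (polymorphic_te_fraction > 0) {
    if (is.null(tes)) stop("tes required when polymorphic_te_fraction > 0")
    n_poly <- floor(polymorphic_te_fraction * nrow(tes))
    if (n_poly > 0) {
      ids <- sort(sample(tes$te_id, n_poly))
      carriers <- data.frame(
        te_id = ids,
        carriers = vapply(ids, function(i) {
          k <- sample.int(max(n_strains - 1L, 1L), 1L)
          paste(sort(sample(strains, k)), collapse = ",")
        }, character(1)),
        stringsAsFactors = FALSE)
    }
  }
  list(snps = snps, carriers = carriers)
}

#' Simulate an NB count matrix with planted truth
#'
#' Counts are drawn per library from a negative binomial
#' (variance = mu + alpha mu^2).  The plan assigns roles: `variable` sites
#' receive strain-specific mean fold-changes (explicit per-strain folds, a
#' fold applied to an affected strain subset, or — mechanism `snp` — the
#' fold applied per genotype as `mu * fold^g`); mechanism `meth` scales the
#' strain mean with `1 + (fold - 1) * (1 - methylation)` at a linked CpG.
#' `common` sites get a high mean and near-zero dispersion so their
#' cross-strain stability is detectable.  All labels land in the returned
#' `sim_truth`.
#'
#' @param sites union site data.frame (`site_id`, ...).
#' @param meta library metadata (`library`, `strain`, `replicate`).
#' @param params list: `mu`, `alpha`, `mu_common`, `alpha_common`,
#'   `snp_fold`, `meth_fold` (defaults 100, 0.05, 1500, 1e-8, 4, 8).
#' @param plan data.frame with columns `site_id`, `role` (variable/common),
#'   `mechanism` (fold/snp/meth), `fold`, `affected` (comma-joined strains)
#'   and optional `strain_folds` (comma-joined per-strain multipliers in
#'   strain order).  Sites absent from the plan are background.
#' @param meth_link named list: site_id -> per-strain methylation fractions
#'   (for mechanism `meth`).
#' @param seed integer seed.
#' @return list: `sm` (a `site_matrix` with raw counts), `truth`
#'   (a `sim_truth` list).
#' @export
simulate_counts <- function(sites, meta, params = list(), plan = NULL,
                            meth_link = NULL, seed = 1L) {
  p <- utils::modifyList(list(mu = 100, alpha = 0.05, mu_common = 1500,
                              alpha_common = 1e-8, snp_fold = 4,
                              meth_fold = 8), params)
  if (p$mu <= 0) stop("mu must be > 0")
  if (p$alpha <= 0 || p$alpha_common <= 0)
    stop("alpha must be > 0; for the Poisson limit use alpha = 1e-8")
  set.seed(seed)
  strains <- unique(meta$strain)
  ns <- nrow(sites)
  mu_mat <- matrix(p$mu, ns, length(strains),
                   dimnames = list(sites$site_id, strains))
  alpha_site <- rep(p$alpha, ns)
  names(alpha_site) <- sites$site_id
  truth <- list(variable_site_ids = character(),
                common_site_ids = character(),
                snp_driven_site_ids = character(),
                methylation_driven_site_ids = character(),
                plan = plan, seed = seed)
  if (!is.null(plan) && nrow(plan)) {
    unknown <- setdiff(plan$site_id, sites$site_id)
    if (length(unknown)) stop("plan references unknown site(s): ",
                              paste(head(unknown, 3), collapse = ", "))
    for (i in seq_len(nrow(plan))) {
      sid <- plan$site_id[i]
      if (plan$role[i] == "common") {
        mu_mat[sid, ] <- p$mu_common
        alpha_site[sid] <- p$alpha_common
        truth$common_site_ids <- c(truth$common_site_ids, sid)
        next
      }
      truth$variable_site_ids <- c(truth$variable_site_ids, sid)
      mech <- plan$mechanism[i]
      sf <- plan$strain_folds[i] %||% NA_character_
      if (!is.na(sf) && nzchar(sf)) {
        folds <- as.numeric(strsplit(sf, ",")[[1]])
        stopifnot(length(folds) == length(strains))
        mu_mat[sid, ] <- p$mu * folds
      } else if (mech == "snp") {
        aff <- strsplit(plan$affected[i], ",")[[1]]
        g <- as.integer(strains %in% aff)
        mu_mat[sid, ] <- p$mu * plan$fold[i]^g
        truth$snp_driven_site_ids <- c(truth$snp_driven_site_ids, sid)
      } else if (mech == "meth") {
        m <- meth_link[[sid]]
        if (is.null(m)) stop("no methylation link for site ", sid)
        mu_mat[sid, ] <- p$mu * (1 + (plan$fold[i] - 1) * (1 - m[strains]))
        truth$methylation_driven_site_ids <-
          c(truth$methylation_driven_site_ids, sid)
      } else {
        aff <- strsplit(plan$affected[i], ",")[[1]]
        mu_mat[sid, strains %in% aff] <- p$mu * plan$fold[i]
      }
    }
  }
  counts <- matrix(0L, ns, nrow(meta),
                   dimnames = list(sites$site_id, meta$library))
  for (j in seq_len(nrow(meta))) {
    mu_j <- mu_mat[, meta$strain[j]]
    counts[, j] <- rnbinom(ns, size = 1 / alpha_site, mu = mu_j)
  }
  truth$meth_link <- meth_link
  class(truth) <- "sim_truth"
  list(sm = site_matrix(sites, counts, meta), truth = truth)
}

#' Simulate a fragment library
#'
#' Fragment midpoints are drawn from a mixture of a uniform background over
#' the genome and peak-centered components with mass proportional to
#' `(enrichment - 1) x width`, so the expected midpoint density inside a
#' peak is `enrichment` times background.  Peak components are Gaussian
#' around the peak center (sd = width/6), clamped inside the peak.
#' Fragment lengths are `round(Normal(mean, sd))`, floored at 20 bp.
#'
#' @param genome named character vector of sequences (only lengths used).
#' @param peak_plan data.frame `chrom`, `start`, `end`, `enrichment` (>= 1).
#' @param n_fragments total fragments to draw.
#' @param fragment_length_mean,fragment_length_sd length model (170 +/- 3).
#' @param seed integer seed.
#' @return data.frame of fragments: `chrom`, `start`, `end`.
#' @export
simulate_fragments <- function(genome, peak_plan, n_fragments,
                               fragment_length_mean = 170,
                               fragment_length_sd = 3, seed = 1L) {
  set.seed(seed)
  if (n_fragments == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  lens <- setNames(nchar(genome), names(genome))
  if (!is.null(peak_plan) && nrow(peak_plan)) {
    if (any(peak_plan$enrichment < 1)) stop("enrichment must be >= 1")
    bad <- peak_plan$start < 0 | peak_plan$end > lens[peak_plan$chrom]
    if (any(bad)) stop("peak outside genome: row ", which(bad)[1])
    w_peaks <- (peak_plan$enrichment - 1) * (peak_plan$end - peak_plan$start)
  } else w_peaks <- numeric(0)
  w_bg <- sum(lens)
  comp <- sample.int(length(w_peaks) + 1L, n_fragments, replace = TRUE,
                     prob = c(w_bg, w_peaks))
  chrom <- character(n_fragments)
  mid <- integer(n_fragments)
  bg <- comp == 1L
  if (any(bg)) {
    gpos <- sample.int(w_bg, sum(bg), replace = TRUE) - 1L
    cum <- cumsum(as.numeric(lens))
    ci <- findInterval(gpos, c(0, cum), rightmost.closed = FALSE)
    chrom[bg] <- names(lens)[ci]
    mid[bg] <- gpos - c(0, cum)[ci]
  }
  if (any(!bg)) {
    pi <- comp[!bg] - 1L
    ctr <- (peak_plan$start[pi] + peak_plan$end[pi]) / 2
    wd <- peak_plan$end[pi] - peak_plan$start[pi]
    m <- round(rnorm(length(pi), ctr, wd / 6))
    m <- pmin(pmax(m, peak_plan$start[pi]), peak_plan$end[pi] - 1L)
    chrom[!bg] <- peak_plan$chrom[pi]
    mid[!bg] <- as.integer(m)
  }
  len <- pmax(20L, as.integer(round(rnorm(n_fragments, fragment_length_mean,
                                          fragment_length_sd))))
  start <- mid - len %/% 2L
  start <- pmax(0L, pmin(start, lens[chrom] - len))
  out <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(start + len), stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Simulate a cross-strain methylation table
#'
#' Planted DM CpGs are bimodal by construction — about half the strains
#' drawn in `[0, 0.08]`, the rest in `[0.92, 1]` — so they always satisfy
#' the DM definition (variance > 0.05 and range > 0.75).  Non-DM CpGs are
#' drawn around a per-CpG center (restricted to `[0.2, 0.8]`) with the
#' requested spread and clamped to center +/- 0.2, so they always fail it.
#'
#' @param cpg_positions data.frame `chrom`, `pos`.
#' @param strains strain names.
#' @param dm_plan data.frame aligned with `cpg_positions` rows by
#'   (`chrom`, `pos`): columns `dm` (logical) and optional `spread`
#'   (sd for non-DM values, default 0.03) and `center`.
#' @param seed integer seed.
#' @return a `cpg_table` with per-strain methylation fractions.
#' @export
simulate_methylation <- function(cpg_positions, strains, dm_plan, seed = 1L) {
  set.seed(seed)
  key <- paste(cpg_positions$chrom, cpg_positions$pos)
  pkey <- paste(dm_plan$chrom, dm_plan$pos)
  if (any(!pkey %in% key)) stop("dm_plan references unknown CpG")
  idx <- match(key, pkey)
  dm <- ifelse(is.na(idx), FALSE, dm_plan$dm[idx])
  spread <- if ("spread" %in% names(dm_plan))
    ifelse(is.na(idx), 0.03, dm_plan$spread[idx]) else rep(0.03, length(key))
  center <- if ("center" %in% names(dm_plan) && !all(is.na(dm_plan$center)))
    ifelse(is.na(idx) | is.na(dm_plan$center[idx]),
           runif(length(key), 0.2, 0.8), dm_plan$center[idx])
  else runif(length(key), 0.2, 0.8)
  n <- length(strains)
  vals <- matrix(0, length(key), n, dimnames = list(NULL, strains))
  for (i in seq_along(key)) {
    if (dm[i]) {
      lo <- sample.int(n, ceiling(n / 2))
      v <- numeric(n)
      v[lo] <- runif(length(lo), 0, 0.08)
      v[-lo] <- runif(n - length(lo), 0.92, 1)
      vals[i, ] <- v
    } else {
      ctr <- min(max(center[i], 0.2), 0.8)
      v <- rnorm(n, ctr, spread[i])
      vals[i, ] <- pmin(pmax(v, ctr - 0.2), ctr + 0.2)
    }
  }
  df <- data.frame(chrom = cpg_positions$chrom, pos = cpg_positions$pos,
                   stringsAsFactors = FALSE)
  for (j in seq_len(n)) df[[strains[j]]] <- vals[, j]
  cpg_table(df, strains)
}
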