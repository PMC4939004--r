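# End-to-end orchestration on the default synthetic scenario: genome ->
# strains -> planted sites -> methylation -> fragments -> peaks -> union ->
# counts -> variability -> TE / driver / motif analyses -> report.

default_scenario <- function() {
  list(n_chroms = 2L, chrom_length = 1e6L, n_strains = 7L, reps = 2L,
       site_width = 400L, slot_width = 1200L,
       n_background_sites = 850L,
       n_var_young_free = 17L, n_var_young_snp = 8L, n_var_young_meth = 10L,
       n_var_unique_free = 8L, n_var_unique_snp = 7L,
       n_common_old_line = 12L, n_common_sine = 13L, n_common_unique = 25L,
       enrichment_range = c(10, 40), frags_per_library = 60000L,
       snp_rate = 1e-3, polymorphic_te_fraction = 0.10,
       mu = 100, alpha = 0.05, mu_common = 5000, alpha_common = 1e-8,
       snp_fold = 4, meth_fold = 8, free_fold_sd = 1,
       te_cpg_spread = 0.12, unique_cpg_spread = 0.03,
       motif = "TTCCCGGAA")
}

# choose n hosts from a TE subset, enforcing a minimum center distance
pick_hosts <- function(tes, n, min_dist = 2000L) {
  if (!nrow(tes)) stop("no candidate host TEs")
  ord <- sample.int(nrow(tes))
  centers <- (tes$start + tes$end) %/% 2L
  chosen <- integer(0)
  for (i in ord) {
    prev <- chosen[tes$chrom[chosen] == tes$chrom[i]]
    if (!length(prev) || all(abs(centers[prev] - centers[i]) >= min_dist))
      chosen <- c(chosen, i)
    if (length(chosen) == n) break
  }
  if (length(chosen) < n)
    stop("could not place ", n, " sites on candidate TEs")
  tes[chosen, , drop = FALSE]
}

# free 1500-bp slots outside TEs (with margin) on one chromosome
free_slots <- function(chrom, chrom_length, tes, slot_width, margin = 300L) {
  tt <- tes[tes$chrom == chrom, , drop = FALSE]
  occ <- IRanges::IRanges(pmax(tt$start - margin, 0L) + 1L, tt$end + margin)
  free <- IRanges::setdiff(IRanges::IRanges(1L, chrom_length),
                           IRanges::reduce(occ))
  free <- free[IRanges::width(free) >= slot_width]
  starts <- unlist(lapply(seq_along(free), function(i) {
    s <- IRanges::start(free)[i] - 1L
    w <- IRanges::width(free)[i]
    s + slot_width * (seq_len(w %/% slot_width) - 1L)
  }))
  data.frame(chrom = chrom, slot_start = starts)
}

# Build the planted-site plan for the default scenario: intervals, roles,
# mechanisms, causal SNPs and the CpG/DM plan.  Deterministic given seed.
build_site_plan <- function(genome, tes, strains, sc, seed) {
  set.seed(seed)
  width <- sc$site_width
  half <- width %/% 2L
  young_lines <- tes[tes$class == "LINE" & tes$age < 4e7, , drop = FALSE]
  old_lines <- tes[tes$class == "LINE" & tes$age >= 4e7, , drop = FALSE]
  sines <- tes[tes$class == "SINE", , drop = FALSE]

  n_young <- sc$n_var_young_free + sc$n_var_young_snp + sc$n_var_young_meth
  hy <- pick_hosts(young_lines, n_young)
  ho <- pick_hosts(old_lines, sc$n_common_old_line)
  hs <- pick_hosts(sines, sc$n_common_sine)

  te_site <- function(host, role, mech) {
    ctr <- (host$start + host$end) %/% 2L
    data.frame(chrom = host$chrom, start = ctr - half, end = ctr + half,
               role = role, mechanism = mech, host_te = host$te_id,
               stringsAsFactors = FALSE)
  }
  young_roles <- sample(rep(c("free", "snp", "meth"),
                            c(sc$n_var_young_free, sc$n_var_young_snp,
                              sc$n_var_young_meth)))
  planted <- rbind(
    do.call(rbind, lapply(seq_len(nrow(hy)), function(i)
      te_site(hy[i, ], "variable", young_roles[i]))),
    do.call(rbind, lapply(seq_len(nrow(ho)), function(i)
      te_site(ho[i, ], "common", "none"))),
    do.call(rbind, lapply(seq_len(nrow(hs)), function(i)
      te_site(hs[i, ], "common", "none"))))

  # unique-sequence slots, far from TEs and from each other
  slots <- do.call(rbind, lapply(names(genome), function(chr)
    free_slots(chr, nchar(genome[[chr]]), tes, sc$slot_width)))
  n_unique <- sc$n_var_unique_free + sc$n_var_unique_snp +
    sc$n_common_unique + sc$n_background_sites
  if (nrow(slots) < n_unique)
    stop("not enough TE-free slots for ", n_unique, " sites")
  slots <- slots[sample.int(nrow(slots), n_unique), , drop = FALSE]
  ctr <- slots$slot_start + sc$slot_width %/% 2L
  uroles <- c(rep(c("free", "snp"), c(sc$n_var_unique_free, sc$n_var_unique_snp)),
              rep("common", sc$n_common_unique),
              rep("background", sc$n_background_sites))
  planted <- rbind(planted, data.frame(
    chrom = slots$chrom, start = ctr - half, end = ctr + half,
    role = ifelse(uroles == "background", "background",
                  ifelse(uroles == "common", "common", "variable")),
    mechanism = ifelse(uroles %in% c("free", "snp"), uroles, "none"),
    host_te = NA_integer_, stringsAsFactors = FALSE))
  planted <- planted[order(planted$chrom, planted$start), , drop = FALSE]
  planted$planted_id <- sprintf("planted_%04d", seq_len(nrow(planted)))
  rownames(planted) <- NULL

  n_strains <- length(strains)
  planted$fold <- NA_real_
  planted$affected <- NA_character_
  planted$strain_folds <- NA_character_
  planted$snp_pos <- NA_integer_
  for (i in which(planted$mechanism == "snp")) {
    k <- sample(2:(n_strains - 2L), 1L)
    planted$affected[i] <- paste(sort(sample(strains, k)), collapse = ",")
    planted$fold[i] <- sc$snp_fold
    planted$snp_pos[i] <- (planted$start[i] + planted$end[i]) %/% 2L + 5L
  }
  for (i in which(planted$mechanism == "free")) {
    f <- 2^rnorm(n_strains, 0, sc$free_fold_sd)
    hi_lo <- sample.int(n_strains, 2L)
    f[hi_lo[1]] <- f[hi_lo[1]] * 4
    f[hi_lo[2]] <- f[hi_lo[2]] * 0.25
    planted$strain_folds[i] <- paste(signif(f, 6), collapse = ",")
  }
  planted$fold[planted$mechanism == "meth"] <- sc$meth_fold

  # heterogeneous (site-fixed, library-shared) fragment enrichment so that
  # replicate peak scores are rank-correlated, as in real peak strength
  planted$enrichment <- exp(runif(nrow(planted), log(sc$enrichment_range[1]),
                                  log(sc$enrichment_range[2])))

  # CpG plan: one CpG 30 bp left of each planted-site center (DM at
  # methylation-driven sites); TE-hosted variable sites get a second,
  # wider-spread CpG 30 bp right of center
  ctr_all <- (planted$start + planted$end) %/% 2L
  cpgs <- data.frame(chrom = planted$chrom, pos = ctr_all - 30L,
                     planted_id = planted$planted_id,
                     dm = planted$mechanism == "meth",
                     spread = ifelse(planted$role == "variable" &
                                       !is.na(planted$host_te),
                                     sc$te_cpg_spread, sc$unique_cpg_spread),
                     stringsAsFactors = FALSE)
  extra_i <- which(planted$role == "variable" & !is.na(planted$host_te) &
                     planted$mechanism != "meth")
  if (length(extra_i))
    cpgs <- rbind(cpgs, data.frame(chrom = planted$chrom[extra_i],
                                   pos = ctr_all[extra_i] + 30L,
                                   planted_id = planted$planted_id[extra_i],
                                   dm = FALSE, spread = sc$te_cpg_spread,
                                   stringsAsFactors = FALSE))
  cpgs <- cpgs[order(cpgs$chrom, cpgs$pos), , drop = FALSE]
  rownames(cpgs) <- NULL
  planted
  list(planted = planted, cpgs = cpgs)
}

# add the plan's causal SNPs to the simulated SNP table
add_causal_snps <- function(snps, plan, genome) {
  strains <- attr(snps, "strains")
  rows <- plan[!is.na(plan$snp_pos), , drop = FALSE]
  if (!nrow(rows)) return(snps)
  df <- as.data.frame(snps)
  add <- lapply(seq_len(nrow(rows)), function(i) {
    chr <- rows$chrom[i]; pos <- rows$snp_pos[i]
    ref <- substring(genome[[chr]], pos + 1L, pos + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    g <- as.integer(strains %in% strsplit(rows$affected[i], ",")[[1]])
    out <- data.frame(chrom = chr, pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
    for (j in seq_along(strains)) out[[strains[j]]] <- g[j]
    out
  })
  add <- do.call(rbind, add)
  df <- df[!(paste(df$chrom, df$pos) %in% paste(add$chrom, add$pos)), ,
           drop = FALSE]
  df <- rbind(df, add)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  snp_table(df, strains)
}

# map planted intervals to the union sites containing their centers
map_planted_to_union <- function(plan, union_df) {
  ctr <- (plan$start + plan$end) %/% 2L
  out <- rep(NA_character_, nrow(plan))
  for (chr in unique(plan$chrom)) {
    pi <- which(plan$chrom == chr)
    si <- which(union_df$chrom == chr)
    if (!length(si)) next
    pos <- findInterval(ctr[pi], union_df$start[si])
    ok <- pos >= 1L & ctr[pi] < union_df$end[si][pmax(pos, 1L)]
    out[pi[ok]] <- union_df$site_id[si][pos[ok]]
  }
  out
}

default_pwm_set <- function(motif) {
  cons_pwm <- function(name, cons) {
    L <- nchar(cons)
    counts <- matrix(1, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    b <- strsplit(cons, "")[[1]]
    counts[cbind(match(b, c("A", "C", "G", "T")), seq_len(L))] <- 12
    make_pwm(name, counts)
  }
  list(GAS = cons_pwm("GAS", motif),
       HNF4_like = cons_pwm("HNF4_like", "CAAAGTCCAGG"),
       CTCF_like = cons_pwm("CTCF_like", "CCGCGAGGTGGC"))
}

#' Run the full pipeline on the default synthetic scenario
#'
#' Simulates a genome with planted TEs, strain SNPs, planted accessible
#' sites, methylation and fragment libraries; calls peaks per library,
#' filters for replicate reproducibility, forms the union site set; draws
#' the planted count matrix at the union sites, normalizes, tests and
#' classifies; and runs the TE-enrichment, SNP-association, methylation and
#' motif analyses.  All stage outputs are persisted under `run_dir`
#' (`inputs/`, `peaks/`, `matrix/`, `results/`, `report.json`) and a
#' machine-readable report with recovery metrics against the simulation
#' truth is returned.  Deterministic given the config seed (per-stage seeds
#' are derived from it by a fixed hash).
#'
#' @param config an [analysis_config()]; scenario sizes can be overridden
#'   via a `scenario` list entry.
#' @param run_dir output directory (created).
#' @return the report, invisibly (also written to `run_dir/report.json`).
#' @export
run_all <- function(config = analysis_config(),
                    run_dir = tempfile("accessTE_run_")) {
  validate_config(config)
  sc <- utils::modifyList(default_scenario(), config$scenario %||% list())
  seed <- config$rng_seed
  for (d in c("", "inputs", "inputs/fragments", "inputs/pseudogenomes",
              "peaks", "matrix", "results"))
    dir.create(file.path(run_dir, d), recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  n_records <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s (partial outputs in %s)",
                   name, conditionMessage(e), run_dir), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  gsim <- t_stage("genome", {
    g <- simulate_genome(sc$n_chroms, sc$chrom_length,
                         default_te_spec(sc$motif),
                         seed = stage_seed(seed, "genome"),
                         substitution_rate = config$substitution_rate)
    write_fasta(g$genome, file.path(run_dir, "inputs", "genome.fa"))
    write_repeatmasker_out(g$tes, file.path(run_dir, "inputs", "tes.out"))
    g
  })
  genome <- gsim$genome; tes <- gsim$tes
  n_records$tes <- nrow(tes)

  strains <- paste0("S", seq_len(sc$n_strains))
  ssim <- t_stage("strains", {
    simulate_strains(genome, sc$n_strains, sc$snp_rate,
                     sc$polymorphic_te_fraction, tes,
                     seed = stage_seed(seed, "strains"),
                     strain_names = strains)
  })

  planset <- t_stage("site_plan", {
    ps <- build_site_plan(genome, tes, strains, sc,
                          stage_seed(seed, "site_plan"))
    snps <- add_causal_snps(ssim$snps, ps$planted, genome)
    # keep planted CpGs off SNP positions
    clash <- paste(ps$cpgs$chrom, ps$cpgs$pos) %in% paste(snps$chrom, snps$pos)
    ps$cpgs$pos[clash] <- ps$cpgs$pos[clash] + 1L
    write_snv_vcf(snps, file.path(run_dir, "inputs", "snps.vcf"))
    data.table::fwrite(ps$planted, file.path(run_dir, "inputs", "planted_sites.tsv"),
                       sep = "\t", quote = FALSE)
    data.table::fwrite(ssim$carriers, file.path(run_dir, "inputs", "polymorphic_tes.tsv"),
                       sep = "\t", quote = FALSE)
    c(ps, list(snps = snps))
  })
  planted <- planset$planted
  snps <- planset$snps
  n_records$snps <- nrow(snps)
  n_records$planted_sites <- nrow(planted)

  meth <- t_stage("methylation", {
    m <- simulate_methylation(planset$cpgs[, c("chrom", "pos")], strains,
                              planset$cpgs,
                              seed = stage_seed(seed, "methylation"))
    write_cpg_table(m, file.path(run_dir, "inputs", "methylation.tsv"))
    m
  })

  t_stage("pseudogenomes", {
    for (s in strains)
      write_fasta(build_pseudo_genome(genome, snps, s),
                  file.path(run_dir, "inputs", "pseudogenomes",
                            paste0(s, ".fa")))
    NULL
  })

  meta <- data.frame(
    library = paste0(rep(strains, each = sc$reps), "_r", seq_len(sc$reps)),
    strain = rep(strains, each = sc$reps),
    replicate = rep(seq_len(sc$reps), sc$n_strains),
    stringsAsFactors = FALSE)

  frags <- t_stage("fragments", {
    peak_plan <- data.frame(chrom = planted$chrom, start = planted$start,
                            end = planted$end, enrichment = planted$enrichment)
    fr <- lapply(meta$library, function(lib)
      simulate_fragments(genome, peak_plan, sc$frags_per_library,
                         seed = stage_seed(seed, paste0("fragments_", lib))))
    names(fr) <- meta$library
    for (lib in meta$library)
      write_bed(fr[[lib]], file.path(run_dir, "inputs", "fragments",
                                     paste0(lib, ".bed")))
    fr
  })

  chrom_lengths <- setNames(nchar(genome), names(genome))
  peaks <- t_stage("peaks", {
    pk <- lapply(frags, call_peaks, chrom_lengths = chrom_lengths,
                 feature_length = config$feature_length,
                 threshold_sd = config$threshold_sd %||% 4)
    for (lib in names(pk))
      write_bed(pk[[lib]][, c("chrom", "start", "end")],
                file.path(run_dir, "peaks", paste0(lib, "_peaks.bed")))
    rep_pk <- lapply(strains, function(s) {
      libs <- meta$library[meta$strain == s]
      reproducible_peaks(pk[[libs[1]]], pk[[libs[2]]],
                         window = config$idr_window %||% 20L,
                         cutoff = config$idr_cutoff %||% 0.5)
    })
    names(rep_pk) <- strains
    for (s in strains)
      write_bed(rep_pk[[s]][, c("chrom", "start", "end")],
                file.path(run_dir, "peaks", paste0(s, "_reproducible.bed")))
    rep_pk
  })
  n_records$reproducible_peaks <- vapply(peaks, nrow, integer(1))

  union_df <- t_stage("union", {
    u <- union_sites(peaks)
    write_bed(cbind(u[, c("chrom", "start", "end")], name = u$site_id),
              file.path(run_dir, "peaks", "union.bed"))
    u
  })
  n_records$union_sites <- nrow(union_df)

  csim <- t_stage("counts", {
    mapped <- map_planted_to_union(planted, union_df)
    plan <- data.frame(site_id = mapped,
                       role = ifelse(planted$role == "background", NA,
                                     planted$role),
                       mechanism = planted$mechanism,
                       fold = planted$fold,
                       affected = planted$affected,
                       strain_folds = planted$strain_folds,
                       stringsAsFactors = FALSE)
    plan <- plan[!is.na(plan$site_id) & !is.na(plan$role), , drop = FALSE]
    plan <- plan[!duplicated(plan$site_id), , drop = FALSE]
    meth_link <- NULL
    mi <- which(planted$mechanism == "meth" & !is.na(mapped))
    if (length(mi)) {
      meth_link <- lapply(mi, function(i) {
        row <- which(planset$cpgs$planted_id == planted$planted_id[i] &
                       planset$cpgs$dm)[1]
        key <- paste(planset$cpgs$chrom[row], planset$cpgs$pos[row])
        mrow <- match(key, paste(meth$chrom, meth$pos))
        unlist(as.data.frame(meth)[mrow, strains])
      })
      names(meth_link) <- mapped[mi]
    }
    out <- simulate_counts(union_df, meta,
                           params = sc[c("mu", "alpha", "mu_common",
                                         "alpha_common", "snp_fold",
                                         "meth_fold")],
                           plan = plan, meth_link = meth_link,
                           seed = stage_seed(seed, "counts"))
    out$mapped <- mapped
    data.table::fwrite(data.table::as.data.table(out$sm$counts,
                                                 keep.rownames = "site_id"),
                       file.path(run_dir, "matrix", "counts.tsv"),
                       sep = "\t", quote = FALSE)
    data.table::fwrite(meta, file.path(run_dir, "matrix", "meta.tsv"),
                       sep = "\t", quote = FALSE)
    out
  })
  sm <- csim$sm
  truth <- csim$truth

  sm <- t_stage("variability", {
    sm$normalized <- quantile_normalize(sm$counts)
    res <- nb_variability_test(sm$normalized, sm$meta$strain)
    res$chrom <- sm$sites$chrom
    res$start <- sm$sites$start
    res <- classify_sites(res, config$variable_fraction)
    sm$results <- res
    data.table::fwrite(res, file.path(run_dir, "results", "variability.tsv"),
                       sep = "\t", quote = FALSE)
    sm
  })
  variable_ids <- sm$results$site_id[sm$results$label == "variable"]
  common_ids <- sm$results$site_id[sm$results$label == "common"]

  te_res <- t_stage("te_analysis", {
    hits <- overlap_tes(union_df, tes)
    cls <- lapply(c("LINE", "LTR", "SINE", "DNA"), function(k)
      class_enrichment(hits, variable_ids, common_ids, k))
    names(cls) <- c("LINE", "LTR", "SINE", "DNA")
    subfam <- subfamily_enrichment(hits, variable_ids, common_ids)
    av <- hits$age[hits$site_id %in% variable_ids]
    ac <- hits$age[hits$site_id %in% common_ids]
    ages <- if (length(av) && length(ac)) age_distribution_compare(av, ac)
    else list(p = NA_real_)
    sam <- subfamily_accessibility_matrix(sm, hits)
    poly <- polymorphic_fraction(hits, variable_ids, ssim$carriers, sm)
    data.table::fwrite(subfam, file.path(run_dir, "results",
                                         "subfamily_enrichment.tsv"),
                       sep = "\t", quote = FALSE)
    list(hits = hits, class_enrichment = cls, subfamily = subfam,
         ages = ages, accessibility_matrix = sam, polymorphic = poly)
  })

  drv <- t_stage("drivers", {
    fse <- fraction_snp_explained(variable_ids, sm, snps, alpha = 0.05)
    dm <- call_dm_cpgs(meth, config$dm_variance_threshold,
                       config$dm_range_threshold, snps = snps)
    planted_dm_keys <- paste(planset$cpgs$chrom, planset$cpgs$pos)[planset$cpgs$dm]
    called_dm_keys <- paste(dm$chrom, dm$pos)[!is.na(dm$dm) & dm$dm]
    var_sites <- sm$sites[sm$sites$site_id %in% variable_ids, , drop = FALSE]
    mvg <- methylation_variance_by_group(dm, var_sites, te_res$hits)
    dte <- dm_te_enrichment(dm, tes)
    data.table::fwrite(as.data.frame(dm),
                       file.path(run_dir, "results", "dm_cpgs.tsv"),
                       sep = "\t", quote = FALSE)
    list(snp = fse, dm = dm,
         dm_exact = setequal(planted_dm_keys, called_dm_keys),
         n_dm_planted = length(planted_dm_keys),
         n_dm_called = length(called_dm_keys),
         meth_groups = mvg, dm_te = dte)
  })

  mot <- t_stage("motifs", {
    pwms <- default_pwm_set(sc$motif)
    write_pwm(pwms, file.path(run_dir, "inputs", "pwms.txt"))
    hits <- te_res$hits
    young_line <- unique(hits$site_id[hits$class == "LINE" &
                                        hits$age < config$age_cutoff])
    old_line <- unique(hits$site_id[hits$class == "LINE" &
                                      hits$age >= config$age_cutoff])
    young_ids <- intersect(variable_ids, young_line)
    old_ids <- old_line
    neither_ids <- sm$results$site_id[sm$results$label == "neither"]
    pool_ids <- setdiff(neither_ids, unique(hits$site_id))
    seqs <- site_sequences(union_df, genome)
    tgt_y <- seqs[young_ids]; tgt_o <- seqs[old_ids]
    pool <- seqs[pool_ids]
    bg_y <- gc_matched_background(tgt_y, pool, ratio = 2L,
                                  seed = stage_seed(seed, "background_young"))
    enr_y <- motif_enrichment(tgt_y, bg_y, pwms,
                              config$motif_p_threshold,
                              config$motif_occurrence_fraction)
    enr_o <- if (length(tgt_o)) {
      bg_o <- gc_matched_background(tgt_o, pool, ratio = 2L,
                                    seed = stage_seed(seed, "background_old"))
      motif_enrichment(tgt_o, bg_o, pwms, config$motif_p_threshold,
                       config$motif_occurrence_fraction)
    } else NULL
    gw <- scan_genome(genome, pwms["GAS"])
    pred <- predicted_binding_sites(gw, union_df)
    pred_te <- interval_overlaps(pred[, c("chrom", "start", "end")], tes)
    line_idx <- which(tes$class == "LINE")
    motif_lines <- intersect(unique(pred_te$s), line_idx)
    age_p <- if (length(motif_lines) && length(line_idx) > length(motif_lines))
      wilcoxon_rank_sum(tes$age[motif_lines], tes$age[line_idx]) else NA_real_
    data.table::fwrite(enr_y, file.path(run_dir, "results",
                                        "motif_enrichment_young.tsv"),
                       sep = "\t", quote = FALSE)
    if (!is.null(enr_o))
      data.table::fwrite(enr_o, file.path(run_dir, "results",
                                          "motif_enrichment_old.tsv"),
                         sep = "\t", quote = FALSE)
    list(young = enr_y, old = enr_o, n_predicted = nrow(pred),
         motif_line_age_p = age_p)
  })

  prof <- t_stage("profile", {
    lib1 <- meta$library[1:2]
    cov <- fragment_coverage(do.call(rbind, frags[lib1]), chrom_lengths)
    bp <- boundary_profile(cov, tes[tes$class == "LINE", , drop = FALSE],
                           flank = config$flank)
    young <- bp$ages < config$age_cutoff
    list(mean_body_young = mean(bp$five_prime[young, ]),
         mean_body_old = mean(bp$five_prime[!young, ]))
  })

  report <- t_stage("report", {
    mapped <- csim$mapped
    truth_var <- mapped[planted$role == "variable"]
    truth_com <- mapped[planted$role == "common"]
    truth_var <- truth_var[!is.na(truth_var)]
    truth_com <- truth_com[!is.na(truth_com)]
    rep <- list(
      seed = seed,
      config = unclass(config)[setdiff(names(config), "scenario")],
      scenario = sc,
      n_records = n_records,
      stage_timings = timings,
      recovery = list(
        n_planted_variable = sum(planted$role == "variable"),
        n_planted_common = sum(planted$role == "common"),
        variable_recall = length(intersect(variable_ids, truth_var)) /
          sum(planted$role == "variable"),
        variable_precision = if (length(variable_ids))
          length(intersect(variable_ids, truth_var)) / length(variable_ids)
        else NA,
        common_recall = length(intersect(common_ids, truth_com)) /
          sum(planted$role == "common"),
        common_precision = if (length(common_ids))
          length(intersect(common_ids, truth_com)) / length(common_ids)
        else NA,
        fraction_snp_explained = drv$snp$fraction,
        dm_recovered_exactly = drv$dm_exact,
        n_dm_planted = drv$n_dm_planted,
        n_dm_called = drv$n_dm_called),
      enrichment = list(
        line_p = NA, ltr_p = NA, sine_p = NA, dna_p = NA,
        age_wilcoxon_p = NA, polymorphic_fraction = NA,
        meth_te_vs_unique_p = drv$meth_groups$p_te_vs_unique,
        dm_te_p = drv$dm_te$p),
      motifs = list(
        young_selected = NA, old_selected = NA,
        motif_line_age_p = mot$motif_line_age_p),
      profile = prof)
    rep
  })
  # fill enrichment/motif fields computed above
  report$enrichment$line_p <- te_res$class_enrichment$LINE$p
  report$enrichment$ltr_p <- te_res$class_enrichment$LTR$p
  report$enrichment$sine_p <- te_res$class_enrichment$SINE$p
  report$enrichment$dna_p <- te_res$class_enrichment$DNA$p
  report$enrichment$age_wilcoxon_p <- te_res$ages$p
  report$enrichment$polymorphic_fraction <- te_res$polymorphic$fraction
  ry <- mot$young[mot$young$motif == "GAS", , drop = FALSE]
  ro <- if (!is.null(mot$old)) mot$old[mot$old$motif == "GAS", , drop = FALSE]
  report$motifs$young_selected <- isTRUE(nrow(ry) == 1 && ry$selected)
  report$motifs$young_p <- if (nrow(ry)) ry$p else NA
  report$motifs$young_fraction <- if (nrow(ry)) ry$target_fraction else NA
  report$motifs$old_selected <- isTRUE(!is.null(ro) && nrow(ro) == 1 && ro$selected)
  report$stage_timings <- timings
  jsonlite::write_json(report, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  report$run_dir <- run_dir
  report$site_matrix <- sm
  report$te <- te_res
  report$drivers <- drv
  report$truth <- truth
  invisible(report)
}
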