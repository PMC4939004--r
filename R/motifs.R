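# PWM scanning, GC-matched backgrounds and known-motif enrichment.

#' Construct a position weight matrix object
#'
#' @param name motif name.
#' @param counts 4 x L base-count matrix with rownames A, C, G, T (column
#'   sums > 0).
#' @param background base frequencies (A, C, G, T) summing to 1.
#' @param pseudocount smoothing pseudocount (> 0), distributed by background.
#' @param score_threshold hit threshold as a fraction of the maximal
#'   log-odds score (default 0.8).
#' @return an object of class `pwm`, with precomputed base-2 log-odds.
#' @export
make_pwm <- function(name, counts, background = rep(0.25, 4),
                     pseudocount = 1, score_threshold = 0.8) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4L, !is.null(rownames(counts)),
            all(rownames(counts) == c("A", "C", "G", "T")),
            all(colSums(counts) > 0), pseudocount > 0,
            length(background) == 4L, abs(sum(background) - 1) < 1e-6)
  probs <- sweep(counts + pseudocount * background, 2L,
                 colSums(counts) + pseudocount, "/")
  logodds <- log2(sweep(probs, 1L, background, "/"))
  structure(list(name = name, counts = counts, background = background,
                 pseudocount = pseudocount, score_threshold = score_threshold,
                 logodds = logodds, max_score = sum(apply(logodds, 2L, max))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': length %d, max log-odds %.2f bits, threshold %.0f%%\n",
              x$name, ncol(x$counts), x$max_score, 100 * x$score_threshold))
  invisible(x)
}

#' Reverse-complement a DNA string
#'
#' @param seq character vector of A/C/G/T/N strings.
#' @return reverse complements.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# score every window start of an encoded sequence (integer codes 1..4,
# NA for N) against a log-odds matrix; windows with N score -Inf
score_windows <- function(codes, logodds) {
  L <- ncol(logodds)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  nas <- logical(n)
  for (j in seq_len(L)) {
    cj <- codes[j:(j + n - 1L)]
    bad <- is.na(cj)
    nas <- nas | bad
    cj[bad] <- 1L
    sc <- sc + logodds[cbind(cj, j)]
  }
  sc[nas] <- -Inf
  sc
}

encode_dna <- function(seq) {
  x <- utf8ToInt(seq)
  code <- rep(NA_integer_, 128)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[x]
}

#' Scan a sequence with a PWM
#'
#' Base-2 log-odds scores (pseudocount-smoothed) at every window on both
#' strands; hits are windows scoring at least `score_threshold * max_score`.
#' Reverse-strand hits are reported in forward coordinates.  Windows
#' containing N are skipped.
#'
#' @param seq a single DNA string.
#' @param pwm a `pwm` object.
#' @return data.frame: `start` (0-based), `end`, `strand`, `score`.
#' @export
scan_pwm <- function(seq, pwm) {
  L <- ncol(pwm$logodds)
  if (nchar(seq) < L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), score = numeric()))
  thr <- pwm$score_threshold * pwm$max_score
  fwd <- score_windows(encode_dna(seq), pwm$logodds)
  rc <- score_windows(encode_dna(revcomp(seq)), pwm$logodds)
  n <- nchar(seq)
  hf <- which(fwd >= thr)
  hr <- which(rc >= thr)
  out <- data.frame(
    start = c(hf - 1L, n - (hr - 1L) - L),
    strand = rep(c("+", "-"), c(length(hf), length(hr))),
    score = c(fwd[hf], rc[hr]))
  out$end <- out$start + L
  out <- out[order(out$start, out$strand), c("start", "end", "strand", "score")]
  rownames(out) <- NULL
  out
}

#' Scan a genome with a set of PWMs
#'
#' @param genome named character vector of sequences.
#' @param pwms list of `pwm` objects.
#' @return data.frame: `motif`, `chrom`, `start`, `end`, `strand`, `score`.
#' @export
scan_genome <- function(genome, pwms) {
  out <- list()
  for (p in pwms) for (chr in names(genome)) {
    h <- scan_pwm(genome[[chr]], p)
    if (nrow(h))
      out[[length(out) + 1L]] <- cbind(motif = p$name, chrom = chr, h,
                                       stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(motif = character(), chrom = character(), start = integer(),
                  end = integer(), strand = character(), score = numeric())
  rownames(res) <- NULL
  res
}

gc_fraction <- function(seqs) {
  gc <- vapply(strsplit(seqs, ""), function(s)
    sum(s %in% c("G", "C")) / max(sum(s %in% c("A", "C", "G", "T")), 1L),
    numeric(1))
  gc
}

#' Sample a GC-matched background sequence set
#'
#' Pool sequences are binned by GC fraction (5-percentage-point bins) and
#' sampled without replacement to match the target bin histogram at `ratio`
#' backgrounds per target.  When a bin cannot be filled from the pool, the
#' deficit is taken from the nearest non-empty adjacent bins (logged).
#' Deterministic given `seed`.
#'
#' @param targets character vector of target sequences.
#' @param pool character vector of candidate background sequences
#'   (recommended >= 5x the targets).
#' @param ratio backgrounds per target (default 2).
#' @param seed integer seed.
#' @param bin_width GC bin width (default 0.05).
#' @return character vector of background sequences (a subset of `pool`).
#' @export
gc_matched_background <- function(targets, pool, ratio = 2L, seed = 1L,
                                  bin_width = 0.05) {
  stopifnot(length(targets) > 0, length(pool) > 0)
  set.seed(seed)
  breaks <- seq(0, 1, by = bin_width)
  tb <- cut(gc_fraction(targets), breaks, include.lowest = TRUE)
  pb <- cut(gc_fraction(pool), breaks, include.lowest = TRUE)
  want <- table(tb) * ratio
  avail <- split(seq_along(pool), pb)
  chosen <- integer(0)
  lv <- levels(tb)
  for (i in seq_along(lv)) {
    need <- want[[lv[i]]]
    if (need == 0) next
    cand <- setdiff(avail[[lv[i]]], chosen)
    take <- if (length(cand) <= need) cand
            else sample(cand, need)
    deficit <- need - length(take)
    if (deficit > 0) {
      message(sprintf("gc_matched_background: GC bin %s short by %d; relaxing to adjacent bins",
                      lv[i], deficit))
      off <- 1L
      while (deficit > 0 && off < length(lv)) {
        for (j in c(i - off, i + off)) {
          if (deficit <= 0 || j < 1L || j > length(lv)) next
          cand2 <- setdiff(avail[[lv[j]]], c(chosen, take))
          extra <- if (length(cand2) <= deficit) cand2 else sample(cand2, deficit)
          take <- c(take, extra)
          deficit <- deficit - length(extra)
        }
        off <- off + 1L
      }
      if (deficit > 0) stop("background pool exhausted; supply a larger pool")
    }
    chosen <- c(chosen, take)
  }
  pool[sort(chosen)]
}

#' Known-motif enrichment in target vs background sequences
#'
#' Occurrence is sequence-level (a sequence either contains >= 1 hit or
#' not).  Over-representation in targets relative to the combined
#' target+background universe is tested with a one-sided hypergeometric
#' p-value; a motif is selected iff `p < p_threshold` and the target
#' occurrence fraction exceeds `occurrence_fraction`.
#'
#' @param targets,background character vectors of sequences.
#' @param pwms list of `pwm` objects.
#' @param p_threshold selection p cutoff (default 0.01).
#' @param occurrence_fraction minimum target occurrence fraction (default 0.10).
#' @return data.frame (one row per motif, ranked by `p`): `motif`,
#'   `target_fraction`, `background_fraction`, `p`, `selected`.
#' @export
motif_enrichment <- function(targets, background, pwms,
                             p_threshold = 0.01, occurrence_fraction = 0.10) {
  if (!length(targets)) stop("empty target set")
  occurs <- function(seqs, p) vapply(seqs, function(s) nrow(scan_pwm(s, p)) > 0,
                                     logical(1), USE.NAMES = FALSE)
  rows <- lapply(pwms, function(p) {
    qt <- sum(occurs(targets, p))
    qb <- sum(occurs(background, p))
    nt <- length(targets); nb <- length(background)
    pv <- hypergeom_enrichment_p(qt, qt + qb, nt + nb, nt)
    data.frame(motif = p$name, target_fraction = qt / nt,
               background_fraction = if (nb) qb / nb else NA_real_,
               p = pv,
               selected = pv < p_threshold & (qt / nt) > occurrence_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif-occurrence binding prediction within accessible sites
#'
#' Genome-wide motif hits are retained iff fully contained in an accessible
#' site, yielding predicted binding intervals joinable with TE overlap
#' tables for age summaries.
#'
#' @param hits genome-wide hit table from [scan_genome()].
#' @param sites accessible site data.frame (`site_id`, `chrom`, `start`, `end`).
#' @return the retained hits with an added `site_id` column.
#' @export
predicted_binding_sites <- function(hits, sites) {
  if (!nrow(hits)) return(cbind(hits, site_id = character(0)))
  ov <- interval_overlaps(hits[, c("chrom", "start", "end")], sites)
  contained <- ov[hits$start[ov$q] >= sites$start[ov$s] &
                  hits$end[ov$q] <= sites$end[ov$s], , drop = FALSE]
  out <- hits[contained$q, , drop = FALSE]
  out$site_id <- sites$site_id[contained$s]
  rownames(out) <- NULL
  out
}

#' Extract site sequences from a genome
#'
#' @param sites site data.frame (`chrom`, `start`, `end`).
#' @param genome named character vector of sequences.
#' @return character vector of site sequences (named by `site_id` if present).
#' @export
site_sequences <- function(sites, genome) {
  out <- vapply(seq_len(nrow(sites)), function(i)
    substr(genome[[sites$chrom[i]]], sites$start[i] + 1L, sites$end[i]),
    character(1))
  if (!is.null(sites$site_id)) names(out) <- sites$site_id
  out
}
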