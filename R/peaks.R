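# Accessible-chromatin peak calling from fragment intervals.
#
# Density model: a Gaussian kernel (sigma = feature_length / 6) over fragment
# midpoints, evaluated per bp and scaled to fragments-per-bp.  The calling
# threshold is the closed-form mean + 4 SD of the density under uniform
# placement of the same number of fragments on the same chromosome.

# centered FFT convolution of per-bp counts with a symmetric kernel
kernel_density_bp <- function(counts, kern) {
  L <- length(counts)
  w <- (length(kern) - 1L) %/% 2L
  N <- stats::nextn(L + 2L * w + 1L, factors = 2L)
  xp <- c(counts, numeric(N - L))
  kp <- numeric(N)
  kp[1:(w + 1L)] <- kern[(w + 1L):(2L * w + 1L)]
  kp[(N - w + 1L):N] <- kern[1:w]
  dens <- Re(fft(fft(xp) * fft(kp), inverse = TRUE)) / N
  dens[seq_len(L)]
}

#' Call accessible-chromatin peaks from fragment intervals
#'
#' Gaussian kernel density of fragment midpoints (`sigma = feature_length/6`)
#' evaluated at every bp, in units of fragments per bp.  Contiguous runs
#' above the background threshold (closed-form mean + `threshold_sd` SD under
#' uniform fragment placement) become peaks; the summit is the density
#' argmax and the score the summit density.
#'
#' @param fragments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open fragment intervals).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param feature_length kernel feature length in bp (default 400).
#' @param threshold_sd threshold multiplier over background SD (default 4).
#' @return data.frame of peaks: `chrom`, `start`, `end`, `score`, `summit`.
#' @export
call_peaks <- function(fragments, chrom_lengths, feature_length = 400L,
                       threshold_sd = 4) {
  if (feature_length < 50) stop("feature_length must be >= 50")
  if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chrom_lengths must be a named vector of positive lengths")
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      score = numeric(), summit = integer())
  if (is.null(fragments) || !nrow(fragments)) return(empty)
  sigma <- feature_length / 6
  w <- as.integer(ceiling(5 * sigma))
  kern <- dnorm(seq(-w, w), 0, sigma)
  out <- list()
  for (chr in names(chrom_lengths)) {
    L <- as.integer(chrom_lengths[[chr]])
    fr <- fragments[fragments$chrom == chr, , drop = FALSE]
    if (!nrow(fr)) next
    mids <- pmin(pmax(as.integer((fr$start + fr$end) %/% 2L), 0L), L - 1L)
    counts <- tabulate(mids + 1L, nbins = L)
    dens <- kernel_density_bp(counts, kern)
    n <- nrow(fr)
    ksum <- sum(kern); ksq <- sum(kern^2)
    mu_bg <- n * ksum / L
    var_bg <- n * (ksq / L - (ksum / L)^2)
    thr <- mu_bg + threshold_sd * sqrt(max(var_bg, 0))
    above <- dens > thr
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    pk <- lapply(keep, function(i) {
      s <- starts[i]; e <- ends[i]
      sm <- s + which.max(dens[s:e]) - 1L
      data.frame(chrom = chr, start = s - 1L, end = e,
                 score = dens[sm], summit = sm - 1L)
    })
    out[[chr]] <- do.call(rbind, pk)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start), , drop = FALSE]
}

# IRanges overlap of two interval data.frames; returns query/subject index pairs
interval_overlaps <- function(a, b) {
  if (!nrow(a) || !nrow(b))
    return(data.frame(q = integer(), s = integer(), width = integer()))
  gr_a <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start + 1L, a$end))
  gr_b <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start + 1L, b$end))
  hits <- GenomicRanges::findOverlaps(gr_a, gr_b, minoverlap = 1L)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_a)[S4Vectors::queryHits(hits)],
    IRanges::ranges(gr_b)[S4Vectors::subjectHits(hits)]))
  data.frame(q = S4Vectors::queryHits(hits), s = S4Vectors::subjectHits(hits),
             width = ov)
}

#' Filter peaks for replicate reproducibility
#'
#' A rank-concordance surrogate for the irreproducible discovery rate:
#' candidates are replicate-1 peaks overlapping (>= 1 bp) a replicate-2
#' peak; ranked by replicate-1 score, the retained prefix ends where the
#' rolling mean (window `window`) absolute normalized rank discordance
#' between replicate scores first exceeds `cutoff`.  Retained peaks carry
#' merged coordinates (union of the matched pair) and the replicate-1 score.
#'
#' @param peaks_rep1,peaks_rep2 peak data.frames from [call_peaks()] (scores
#'   required).
#' @param window rolling window for the discordance statistic.
#' @param cutoff discordance cutoff in `[0, 1]`.
#' @return data.frame of reproducible peaks (`chrom`, `start`, `end`,
#'   `score`, `summit`).
#' @export
reproducible_peaks <- function(peaks_rep1, peaks_rep2, window = 20L,
                               cutoff = 0.5) {
  for (p in list(peaks_rep1, peaks_rep2))
    if (nrow(p) && (is.null(p$score) || any(is.na(p$score))))
      stop("peaks must carry scores")
  ov <- interval_overlaps(peaks_rep1, peaks_rep2)
  if (!nrow(ov)) return(peaks_rep1[0, , drop = FALSE])
  # best rep2 match per candidate: largest overlap, then higher score
  ord <- order(ov$q, -ov$width, -peaks_rep2$score[ov$s])
  ov <- ov[ord, , drop = FALSE]
  ov <- ov[!duplicated(ov$q), , drop = FALSE]
  cand <- ov$q
  s1 <- peaks_rep1$score[cand]
  s2 <- peaks_rep2$score[ov$s]
  o <- order(-s1)
  cand <- cand[o]; match2 <- ov$s[o]
  n <- length(cand)
  r1 <- seq_len(n)
  r2 <- rank(-s2[o], ties.method = "average")
  disc <- abs(r1 - r2) / n
  roll <- vapply(seq_len(n), function(i)
    mean(disc[max(1L, i - window + 1L):i]), numeric(1))
  # the stop rule needs a full window: partial windows at the head of the
  # ranking are dominated by single-peak rank noise
  stop_at <- which(roll > cutoff & seq_len(n) >= window)
  keep <- if (length(stop_at)) seq_len(stop_at[1] - 1L) else seq_len(n)
  if (!length(keep)) return(peaks_rep1[0, , drop = FALSE])
  i1 <- cand[keep]; i2 <- match2[keep]
  res <- data.frame(
    chrom = peaks_rep1$chrom[i1],
    start = pmin(peaks_rep1$start[i1], peaks_rep2$start[i2]),
    end = pmax(peaks_rep1$end[i1], peaks_rep2$end[i2]),
    score = peaks_rep1$score[i1],
    summit = peaks_rep1$summit[i1])
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge per-strain peak lists into a union site set
#'
#' Intervals overlapping by >= 1 bp across any inputs are merged into
#' maximal runs (book-ended intervals are kept separate), sorted by
#' (chrom, start).
#'
#' @param peak_lists a list of peak/interval data.frames (`chrom`, `start`,
#'   `end`).
#' @return data.frame of union sites: `site_id`, `chrom`, `start`, `end`.
#' @export
union_sites <- function(peak_lists) {
  if (!is.data.frame(peak_lists) && is.list(peak_lists))
    all_pk <- do.call(rbind, lapply(peak_lists, function(p)
      p[, c("chrom", "start", "end"), drop = FALSE]))
  else all_pk <- peak_lists[, c("chrom", "start", "end"), drop = FALSE]
  if (is.null(all_pk) || !nrow(all_pk))
    return(data.frame(site_id = character(), chrom = character(),
                      start = integer(), end = integer()))
  gr <- GenomicRanges::GRanges(all_pk$chrom,
                               IRanges::IRanges(all_pk$start + 1L, all_pk$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  red <- GenomicRanges::sort(red)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1L,
                    end = GenomicRanges::end(red))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(site_id = sprintf("site_%05d", seq_len(nrow(out))), out)
  out$site_id <- as.character(out$site_id)
  rownames(out) <- NULL
  out
}

#' Count fragments per union site
#'
#' A fragment is assigned to a site iff its midpoint lies within the site
#' (half-open), so each fragment is counted at most once.
#'
#' @param fragment_sets named list of per-library fragment data.frames.
#' @param sites union site data.frame (sorted, non-overlapping).
#' @return integer matrix, sites x libraries.
#' @export
count_fragments <- function(fragment_sets, sites) {
  if (is.data.frame(fragment_sets)) fragment_sets <- list(fragment_sets)
  ns <- nrow(sites)
  if (ns) {
    o <- order(sites$chrom, sites$start)
    if (any(o != seq_len(ns))) stop("sites must be sorted by (chrom, start)")
    by_chr <- split(seq_len(ns), sites$chrom)
    for (idx in by_chr)
      if (length(idx) > 1L &&
          any(sites$start[idx][-1L] < sites$end[idx][-length(idx)]))
        stop("sites must be non-overlapping")
  }
  mat <- matrix(0L, nrow = ns, ncol = length(fragment_sets),
                dimnames = list(sites$site_id, names(fragment_sets)))
  if (!ns) return(mat)
  for (j in seq_along(fragment_sets)) {
    fr <- fragment_sets[[j]]
    if (is.null(fr) || !nrow(fr)) next
    for (chr in unique(fr$chrom)) {
      si <- which(sites$chrom == chr)
      if (!length(si)) next
      frc <- fr[fr$chrom == chr, , drop = FALSE]
      mids <- as.integer((frc$start + frc$end) %/% 2L)
      pos <- findInterval(mids, sites$start[si])
      ok <- pos >= 1L & mids < sites$end[si][pmax(pos, 1L)]
      tab <- tabulate(pos[ok], nbins = length(si))
      mat[si, j] <- mat[si, j] + tab
    }
  }
  mat
}

#' Per-bp fragment coverage
#'
#' @param fragments fragment data.frame (`chrom`, `start`, `end`).
#' @param chrom_lengths named vector of chromosome lengths.
#' @return named list of per-bp integer coverage vectors.
#' @export
fragment_coverage <- function(fragments, chrom_lengths) {
  out <- lapply(names(chrom_lengths), function(chr) {
    L <- as.integer(chrom_lengths[[chr]])
    fr <- fragments[fragments$chrom == chr, , drop = FALSE]
    if (!nrow(fr)) return(numeric(L))
    s <- pmax(fr$start, 0L) + 1L
    e <- pmin(fr$end, L) + 1L
    d <- tabulate(s, nbins = L + 1L) - tabulate(e, nbins = L + 1L)
    cumsum(d)[seq_len(L)]
  })
  names(out) <- names(chrom_lengths)
  out
}
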