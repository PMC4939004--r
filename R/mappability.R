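#' Compute a k-mer mappability track
#'
#' For each genome position carrying a full k-mer, the mappability score is
#' `M = 1 / n_matches`, where `n_matches` counts the genome positions (either
#' strand, self included) whose k-mer lies within `max_mismatches` of the
#' position's forward k-mer.  `M = 1` marks a unique match, 0.5 two matches,
#' and so on.  The engine is exact (pigeonhole seeding plus Hamming
#' verification) and intended for desk-scale genomes; a hard size cap guards
#' against accidental whole-genome runs.  Windows containing N are `NA`.
#'
#' @param genome named character vector of chromosome sequences.
#' @param kmer_length k-mer length in bp (default 170, the mean fragment
#'   length of the study design).
#' @param max_mismatches mismatch budget (default 2).
#' @param max_genome_size refuse genomes larger than this many bp.
#' @return object of class `mappability_track`: a list with per-chromosome
#'   numeric vectors `score` (length `L - k + 1`, values in `(0, 1]` or NA),
#'   plus `kmer_length` and `max_mismatches`.
#' @export
mappability_track <- function(genome, kmer_length = 170L, max_mismatches = 2L,
                              max_genome_size = 5e6) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  if (sum(nchar(genome)) > max_genome_size)
    stop("genome exceeds the exact-engine size cap (", max_genome_size, " bp)")
  if (any(nchar(genome) < kmer_length))
    stop("kmer_length exceeds the length of chromosome ",
         names(genome)[nchar(genome) < kmer_length][1])
  counts <- .mappability_counts(unname(genome), as.integer(kmer_length),
                                as.integer(max_mismatches))
  names(counts) <- names(genome)
  score <- lapply(counts, function(x) 1 / x)
  structure(list(score = score, kmer_length = as.integer(kmer_length),
                 max_mismatches = as.integer(max_mismatches)),
            class = "mappability_track")
}

#' @export
print.mappability_track <- function(x, ...) {
  cat(sprintf("mappability track: %d-mers, <=%d mismatches, %d chromosome(s)\n",
              x$kmer_length, x$max_mismatches, length(x$score)))
  for (nm in names(x$score))
    cat(sprintf("  %s: %d positions, mean M = %.4f\n", nm, length(x$score[[nm]]),
                mean(x$score[[nm]], na.rm = TRUE)))
  invisible(x)
}

#' Convert a mappability track to a bedGraph-ready data.frame
#'
#' @param track a `mappability_track`.
#' @return data.frame with `chrom`, `start`, `end`, `value` rows per position
#'   (run-merging happens in [write_bedgraph()]).
#' @export
mappability_to_track <- function(track) {
  out <- lapply(names(track$score), function(chr) {
    v <- track$score[[chr]]
    keep <- !is.na(v)
    pos <- which(keep) - 1L
    data.frame(chrom = rep(chr, sum(keep)), start = pos, end = pos + 1L,
               value = v[keep], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Brute-force k-mer match count (oracle)
#'
#' Counts, by direct Hamming comparison against every genome window on both
#' strands, the positions matching the forward k-mer at (`chrom`, `pos`).
#' Independent of the seeded engine in [mappability_track()]; quadratic, so
#' only for small genomes or single-position verification.
#'
#' @param genome named character vector of sequences.
#' @param chrom,pos 0-based query position.
#' @param kmer_length,max_mismatches as in [mappability_track()].
#' @return integer match count (self included).
#' @export
kmer_match_count <- function(genome, chrom, pos, kmer_length = 170L,
                             max_mismatches = 2L) {
  k <- kmer_length
  q <- utf8ToInt(substr(genome[[chrom]], pos + 1L, pos + k))
  if (length(q) < k) stop("no full k-mer at the query position")
  nmatch <- 0L
  for (chr in names(genome)) {
    s <- utf8ToInt(genome[[chr]])
    comp <- s
    comp[s == utf8ToInt("A")] <- utf8ToInt("T")
    comp[s == utf8ToInt("T")] <- utf8ToInt("A")
    comp[s == utf8ToInt("C")] <- utf8ToInt("G")
    comp[s == utf8ToInt("G")] <- utf8ToInt("C")
    comp[s == utf8ToInt("N")] <- -1L       # N never matches
    rc <- rev(comp)
    sN <- s
    sN[s == utf8ToInt("N")] <- -2L
    L <- length(s)
    nw <- L - k + 1L
    if (nw < 1L) next
    mm_f <- integer(nw)
    mm_r <- integer(nw)
    for (j in seq_len(k)) {
      wf <- sN[j:(j + nw - 1L)]
      wr <- rc[j:(j + nw - 1L)]
      mm_f <- mm_f + (wf != q[j])
      mm_r <- mm_r + (wr != q[j])
    }
    # rc window i (1-based on rc sequence) is genome position L - i - k + 2
    hit_f <- mm_f <= max_mismatches
    hit_r_rcidx <- which(mm_r <= max_mismatches)
    hit_pos <- unique(c(which(hit_f), L - hit_r_rcidx - k + 2L))
    nmatch <- nmatch + length(hit_pos)
  }
  nmatch
}
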