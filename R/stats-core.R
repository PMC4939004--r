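#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the two-sided p-value by probability-mass summation: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the observed table's probability (a relative tolerance
#' of 1e-7 guards the comparison against rounding, as in mainstream tools).
#'
#' @param tab a 2x2 matrix of non-negative counts, or a length-4 vector
#'   `c(a, b, c, d)` filled row-wise.
#' @return the two-sided p-value.  Degenerate margins (an all-zero row or
#'   column) return 1 by convention.
#' @examples
#' fisher_exact_two_sided(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
#' @export
fisher_exact_two_sided <- function(tab) {
  if (is.matrix(tab)) {
    stopifnot(all(dim(tab) == c(2L, 2L)))
    a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  } else {
    stopifnot(length(tab) == 4L)
    a <- tab[1]; b <- tab[2]; cc <- tab[3]; d <- tab[4]
  }
  v <- c(a, b, cc, d)
  if (any(v < 0) || any(v != round(v))) stop("table entries must be non-negative integers")
  if (sum(v) == 0) stop("table total must be > 0")
  m <- a + cc          # first-column margin
  n <- b + d           # second-column margin
  k <- a + b           # first-row margin
  if (m == 0 || n == 0 || k == 0 || (cc + d) == 0) return(1)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, n, k)
  obs <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= obs * (1 + 1e-7)])
  min(1, p)
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact null enumeration over all assignments of the pooled ranks when
#' `min(n, m) <= 8` and the number of arrangements is at most
#' `choose(20, 10)`; ties are handled exactly via midranks.  Larger samples
#' use the normal approximation with tie and continuity corrections.  The
#' two-sided exact p-value is the null probability of a rank sum at least as
#' far from its expectation as observed.
#'
#' @param x,y numeric samples.
#' @return the two-sided p-value.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # 0.1
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) return(1)
  r <- rank(pooled)
  W <- sum(r[seq_len(n)])
  N <- n + m
  EW <- n * (N + 1) / 2
  small <- min(n, m)
  if (small <= 8L && choose(N, small) <= choose(20, 10)) {
    # enumerate which pooled positions belong to the smaller sample
    ksel <- if (n <= m) n else m
    combs <- utils::combn(N, ksel)
    sums <- colSums(matrix(r[combs], nrow = ksel))
    if (n <= m) {
      Eref <- EW; Wref <- W
    } else {                          # enumerate the y-sample instead
      Eref <- m * (N + 1) / 2; Wref <- sum(r) - W
    }
    dev <- abs(Wref - Eref)
    p <- mean(abs(sums - Eref) >= dev - 1e-9)
    return(min(1, p))
  }
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab)
  VW <- n * m / 12 * ((N + 1) - tie_corr / (N * (N - 1)))
  if (VW <= 0) return(1)
  z <- W - EW
  z <- (z - sign(z) * 0.5) / sqrt(VW)   # continuity correction
  min(1, 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1 (delegates to [stats::p.adjust()]).  `NA` p-values propagate.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' One-sided hypergeometric enrichment p-value
#'
#' Probability of drawing at least `q` marked items when `draw` items are
#' taken from a universe of `total` items of which `marked` are marked.
#'
#' @param q observed marked draws.
#' @param marked number of marked items in the universe.
#' @param total universe size.
#' @param draw number of draws.
#' @return upper-tail p-value `P(X >= q)`.
#' @export
hypergeom_enrichment_p <- function(q, marked, total, draw) {
  stopifnot(total >= marked, draw <= total, q >= 0)
  phyper(q - 1, marked, total - marked, draw, lower.tail = FALSE)
}
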