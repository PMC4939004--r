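# Quantile normalization and the negative-binomial cross-strain
# variability test that splits union sites into variable / common sets.

#' Site-by-library count container
#'
#' Lightweight list container (in the style of limma's EList) bundling the
#' union sites, the raw count matrix, library metadata and, once computed,
#' the normalized matrix, per-site test results and labels.
#'
#' @param sites data.frame of union sites (`site_id`, `chrom`, `start`, `end`).
#' @param counts sites x libraries non-negative count matrix.
#' @param meta data.frame with one row per library: `library`, `strain`,
#'   `replicate`.
#' @return an object of class `site_matrix`.
#' @export
site_matrix <- function(sites, counts, meta) {
  stopifnot(nrow(counts) == nrow(sites), ncol(counts) == nrow(meta),
            all(c("library", "strain", "replicate") %in% names(meta)),
            all(counts >= 0))
  rownames(counts) <- sites$site_id
  colnames(counts) <- meta$library
  structure(list(sites = sites, counts = counts, normalized = NULL,
                 meta = meta, results = NULL),
            class = "site_matrix")
}

#' @export
print.site_matrix <- function(x, ...) {
  cat(sprintf("site_matrix: %d sites x %d libraries (%d strains)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$meta$strain))))
  if (!is.null(x$results) && "label" %in% names(x$results))
    cat(sprintf("  labels: %d variable, %d common\n",
                sum(x$results$label == "variable"),
                sum(x$results$label == "common")))
  invisible(x)
}

#' Quantile-normalize a count matrix
#'
#' Each column's values are replaced, in rank order, by the across-column
#' mean of order statistics; ties within a column receive the mean of the
#' target values they span.  Tie-free columns end up with the identical
#' multiset of values; tied (integer-count) columns share the target
#' distribution up to tie averaging, with exactly equal column sums.
#'
#' @param counts numeric matrix (sites x libraries), >= 2 columns.
#' @return normalized numeric matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (!nrow(counts) || !ncol(counts)) stop("empty matrix")
  if (ncol(counts) < 2L) stop("quantile normalization needs >= 2 libraries")
  if (nrow(counts) == 1L) {
    out <- matrix(mean(counts), 1L, ncol(counts))
    dimnames(out) <- dimnames(counts)
    return(out)
  }
  target <- rowMeans(apply(counts, 2L, sort))
  out <- counts
  for (j in seq_len(ncol(counts))) {
    ord <- order(counts[, j])
    xo <- counts[ord, j]
    grp <- cumsum(!duplicated(xo))           # runs of tied values
    out[ord, j] <- stats::ave(target, grp)   # mean of spanned targets
  }
  dimnames(out) <- dimnames(counts)
  out
}

# log-likelihood term of an NB with fixed size r at mean mu (continuous x
# relaxation; x-independent lgamma terms cancel in the LRT and are omitted)
.nb_ll_term <- function(x, mu, r) {
  out <- r * log(r / (r + mu))
  pos <- x > 0
  out[pos] <- out[pos] + x[pos] * log(mu[pos] / (r[pos] + mu[pos]))
  out
}

#' Negative-binomial cross-strain variability test
#'
#' Per site: the dispersion `alpha` (variance = mu + alpha mu^2) is estimated
#' by method-of-moments pooled over within-strain replicates, floored at
#' 1e-8 and shrunk 50/50 toward a mean-dispersion trend fitted across sites
#' (`alpha ~ a0 + a1/mu`); a likelihood-ratio test then compares the NB
#' model with free strain means against a common mean at the fixed
#' dispersion, with p-values from a chi-squared with `n_strains - 1` df and
#' Benjamini-Hochberg adjustment across all tested sites.  All-zero sites
#' are reported untested (`p = NA`, `adjusted_p = 1`, `tested = FALSE`).
#'
#' @param normalized sites x libraries numeric matrix (quantile-normalized
#'   counts; non-integer values enter the NB likelihood as-is).
#' @param strains character/factor of length `ncol(normalized)` assigning
#'   each library to a strain; every strain needs >= 2 replicates.
#' @param dispersion_floor minimum dispersion.
#' @return data.frame with one row per site: `site_id` (rownames of the
#'   input), per-strain fitted means `mean_<strain>`, `alpha`, `lrt`, `df`,
#'   `p`, `adjusted_p`, `tested`.
#' @export
nb_variability_test <- function(normalized, strains, dispersion_floor = 1e-8) {
  x <- as.matrix(normalized)
  strains <- as.character(strains)
  stopifnot(length(strains) == ncol(x))
  tab <- table(strains)
  if (any(tab < 2L))
    stop("every strain needs >= 2 replicates for dispersion estimation: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  if (length(tab) < 2L) stop("need >= 2 strains")
  sn <- names(tab)
  S <- length(sn)
  n_sites <- nrow(x)
  strain_cols <- lapply(sn, function(s) which(strains == s))
  m_mat <- matrix(0, n_sites, S, dimnames = list(NULL, sn))
  num <- numeric(n_sites)   # sum_s (v_s - m_s)
  den <- numeric(n_sites)   # sum_s m_s^2
  for (j in seq_len(S)) {
    cols <- strain_cols[[j]]
    xs <- x[, cols, drop = FALSE]
    m <- rowMeans(xs)
    v <- rowSums((xs - m)^2) / (length(cols) - 1L)
    m_mat[, j] <- m
    num <- num + (v - m)
    den <- den + m^2
  }
  mu_all <- rowMeans(x)
  tested <- mu_all > 0
  alpha_raw <- ifelse(den > 0, num / den, NA_real_)
  alpha_floor <- pmax(alpha_raw, dispersion_floor)
  # mean-dispersion trend: alpha = a0 + a1 / mu, fitted across tested sites
  fit_idx <- which(tested & is.finite(alpha_floor))
  if (length(fit_idx) >= 10L) {
    fit <- tryCatch(lm(alpha_floor[fit_idx] ~ I(1 / mu_all[fit_idx])),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- coef(fit)
      alpha_trend <- pmax(cf[1] + cf[2] / mu_all, dispersion_floor)
    } else alpha_trend <- rep(stats::median(alpha_floor[fit_idx]), n_sites)
  } else {
    mid <- if (length(fit_idx)) stats::median(alpha_floor[fit_idx]) else dispersion_floor
    alpha_trend <- rep(mid, n_sites)
  }
  alpha_hat <- pmax(0.5 * alpha_floor + 0.5 * alpha_trend, dispersion_floor)
  alpha_hat[!tested] <- NA_real_
  r <- 1 / alpha_hat
  lrt <- numeric(n_sites)
  for (j in seq_len(S)) {
    cols <- strain_cols[[j]]
    for (cc in cols) {
      lrt <- lrt + .nb_ll_term(x[, cc], m_mat[, j], r) -
        .nb_ll_term(x[, cc], mu_all, r)
    }
  }
  lrt <- pmax(2 * lrt, 0)
  p <- rep(NA_real_, n_sites)
  p[tested] <- pchisq(lrt[tested], df = S - 1L, lower.tail = FALSE)
  adj <- rep(1, n_sites)
  adj[tested] <- bh_adjust(p[tested])
  res <- data.frame(site_id = rownames(x) %||% as.character(seq_len(n_sites)),
                    stringsAsFactors = FALSE)
  for (j in seq_len(S)) res[[paste0("mean_", sn[j])]] <- m_mat[, j]
  res$alpha <- alpha_hat
  res$lrt <- ifelse(tested, lrt, NA_real_)
  res$df <- S - 1L
  res$p <- p
  res$adjusted_p <- adj
  res$tested <- tested
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# half-away-from-zero rounding (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' Classify sites into variable / common sets
#'
#' Sites are ranked by adjusted p ascending (ties broken by raw p, then by
#' chromosome and start).  The first `round(variable_fraction * n)` sites
#' (half-away-from-zero rounding) are labelled `variable`, the last
#' `round(variable_fraction * n)` are labelled `common`, the rest `neither`.
#'
#' @param results data.frame with columns `adjusted_p` and `p` and,
#'   for deterministic tie-breaks, `chrom` and `start` (site coordinates).
#' @param variable_fraction fraction per class (default 0.05; must be < 0.5).
#' @return `results` with added `rank` and `label` columns, in input order.
#' @export
classify_sites <- function(results, variable_fraction = 0.05) {
  if (variable_fraction >= 0.5) stop("variable_fraction must be < 0.5")
  n <- nrow(results)
  chrom <- results$chrom %||% rep("", n)
  start <- results$start %||% rep(0L, n)
  ord <- order(results$adjusted_p, results$p, chrom, start, na.last = TRUE)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  k <- round_half_up(variable_fraction * n)
  label <- rep("neither", n)
  label[rank <= k] <- "variable"
  label[rank > n - k] <- "common"
  results$rank <- rank
  results$label <- label
  results
}
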