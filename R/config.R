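#' Analysis configuration
#'
#' Bundles the tunable parameters shared across the pipeline.  Defaults are
#' the study constants: 170-mer mappability with up to 2 mismatches (the mean
#' mapped fragment length), a 400 bp peak-calling feature length, top/bottom
#' 5 % variable/common classification, a neutral substitution rate of
#' 4.5e-9 per site per year with a 40 Myr young/old TE age cutoff,
#' differential-methylation thresholds (cross-strain variance > 0.05 and
#' range > 0.75), motif selection cutoffs (enrichment p < 0.01 and occurrence
#' in > 10 % of targets) and a 2500 bp flank for TE boundary profiles.
#'
#' @param kmer_length mappability k-mer length in bp.
#' @param max_mismatches mismatch budget for a k-mer match.
#' @param feature_length peak-calling kernel feature length in bp.
#' @param variable_fraction fraction of sites labelled variable (and common).
#' @param substitution_rate neutral substitution rate, substitutions/site/year.
#' @param age_cutoff young/old TE age boundary in years.
#' @param dm_variance_threshold cross-strain methylation variance threshold.
#' @param dm_range_threshold cross-strain methylation range threshold.
#' @param motif_p_threshold enrichment p-value cutoff for motif selection.
#' @param motif_occurrence_fraction minimum fraction of target sequences with
#'   a motif occurrence for selection.
#' @param flank flank in bp for TE boundary profiles.
#' @param rng_seed integer seed driving all simulation randomness.
#' @param ... further named options stored as-is (e.g. peak-calling
#'   `threshold_sd`, IDR-surrogate `idr_window`/`idr_cutoff`, simulation
#'   scenario overrides).
#' @return An object of class `access_config` (a named list).
#' @export
analysis_config <- function(kmer_length = 170L,
                            max_mismatches = 2L,
                            feature_length = 400L,
                            variable_fraction = 0.05,
                            substitution_rate = 4.5e-9,
                            age_cutoff = 4.0e7,
                            dm_variance_threshold = 0.05,
                            dm_range_threshold = 0.75,
                            motif_p_threshold = 0.01,
                            motif_occurrence_fraction = 0.10,
                            flank = 2500L,
                            rng_seed = 1L,
                            ...) {
  cfg <- list(
    kmer_length = as.integer(kmer_length),
    max_mismatches = as.integer(max_mismatches),
    feature_length = as.integer(feature_length),
    variable_fraction = variable_fraction,
    substitution_rate = substitution_rate,
    age_cutoff = age_cutoff,
    dm_variance_threshold = dm_variance_threshold,
    dm_range_threshold = dm_range_threshold,
    motif_p_threshold = motif_p_threshold,
    motif_occurrence_fraction = motif_occurrence_fraction,
    flank = as.integer(flank),
    rng_seed = as.integer(rng_seed)
  )
  extra <- list(...)
  if (length(extra)) {
    if (is.null(names(extra)) || any(names(extra) == ""))
      stop("extra config options must be named")
    cfg[names(extra)] <- extra
  }
  class(cfg) <- "access_config"
  validate_config(cfg)
  cfg
}

#' Validate an analysis configuration
#'
#' @param cfg an `access_config` object.
#' @return `cfg`, invisibly, after checking invariants.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "access_config"))
  pos_int <- function(x) length(x) == 1L && is.finite(x) && x > 0 && x == as.integer(x)
  for (f in c("kmer_length", "feature_length", "flank"))
    if (!pos_int(cfg[[f]])) stop(sprintf("config field '%s' must be a positive integer", f))
  if (!(length(cfg$max_mismatches) == 1L && cfg$max_mismatches >= 0 &&
        cfg$max_mismatches == as.integer(cfg$max_mismatches)))
    stop("max_mismatches must be a non-negative integer")
  prop <- function(x) length(x) == 1L && is.finite(x) && x > 0 && x < 1
  for (f in c("variable_fraction", "motif_p_threshold", "motif_occurrence_fraction"))
    if (!prop(cfg[[f]])) stop(sprintf("config field '%s' must lie in (0, 1)", f))
  if (cfg$variable_fraction >= 0.5)
    stop("variable_fraction must be < 0.5 (variable and common sets must not overlap)")
  if (!(cfg$substitution_rate > 0)) stop("substitution_rate must be > 0")
  if (!(cfg$age_cutoff > 0)) stop("age_cutoff must be > 0")
  for (f in c("dm_variance_threshold", "dm_range_threshold"))
    if (!(cfg[[f]] > 0)) stop(sprintf("config field '%s' must be > 0", f))
  invisible(cfg)
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @return `read_config` returns an `access_config`; `write_config` returns
#'   `path` invisibly.
#' @rdname config_io
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

#' @param cfg an `access_config`.
#' @rdname config_io
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.access_config <- function(x, ...) {
  cat("accessTE analysis configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.atomic(v) && length(v) <= 4)
      cat(sprintf("  %-26s %s\n", nm, paste(format(v), collapse = ", ")))
    else cat(sprintf("  %-26s <%s>\n", nm, class(v)[1]))
  }
  invisible(x)
}

# Deterministic per-stage seed derived from the global seed and a stage name.
# Polynomial string hash mod (2^31 - 1) keeps the result a valid 32-bit seed.
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
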