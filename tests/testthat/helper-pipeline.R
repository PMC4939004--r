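# Shared cache for the full-scenario pipeline run used by several
# acceptance checks: run once, reuse across test blocks.
.pipeline_cache <- new.env(parent = emptyenv())

cached_pipeline_run <- function() {
  if (is.null(.pipeline_cache$report)) {
    dir <- file.path(tempdir(), "accessTE_accept_run")
    .pipeline_cache$report <- run_all(analysis_config(rng_seed = 1L), dir)
    .pipeline_cache$dir <- dir
  }
  .pipeline_cache
}

# md5 digests of all stage output files under a run directory (report.json
# carries wall-clock timings and is excluded by design)
stage_output_md5 <- function(run_dir) {
  files <- sort(list.files(run_dir, recursive = TRUE, full.names = FALSE))
  files <- files[files != "report.json"]
  md5 <- tools::md5sum(file.path(run_dir, files))
  names(md5) <- files
  md5
}
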