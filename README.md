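# accessTE

Strain-to-strain variation in chromatin accessibility, and how much of it
traces back to transposable elements (TEs), SNPs and DNA methylation.

`accessTE` is an R package for panels of inbred mouse strains profiled for
open chromatin (FAIRE-seq-like fragment data) with replicates.  It covers
the full analysis path:

1. **Strain pseudo-genomes** — substitute each strain's homozygous SNVs
   into the reference, coordinates preserved.
2. **Exact k-mer mappability** — `M(p) = 1/n(p)`, where `n(p)` counts
   genome positions on either strand whose k-mer lies within a mismatch
   budget (defaults: 170-mers, 2 mismatches) of position `p`'s k-mer;
   `M = 1` means a unique match, `0.5` two matches.  Exact
   pigeonhole-seeded engine with a brute-force oracle for verification.
3. **Peak calling** — Gaussian kernel density of fragment midpoints
   (`sigma = feature_length/6`, 400 bp default) against a closed-form
   uniform-background threshold, a rank-concordance replicate-
   reproducibility filter, union of per-strain peaks, midpoint counting.
4. **Variable vs common sites** — quantile normalization, then a per-site
   negative-binomial likelihood-ratio test across strains
   (`var = mu + alpha mu^2`, method-of-moments dispersion shrunk toward a
   mean-dispersion trend, chi-squared with `n_strains - 1` df,
   Benjamini–Hochberg).  The top and bottom `round(0.05 n)` sites by
   adjusted p are the *variable* and *common* classes.
5. **TE analysis** — RepeatMasker `.out` ingestion; per-instance age
   `= divergence / 4.5e-9` years; class and subfamily enrichment at
   variable vs common sites (exact two-sided Fisher), age-distribution
   comparison (exact/corrected Wilcoxon rank-sum), subfamily-by-strain
   accessibility z-scores, polymorphic-TE overlap, TE boundary coverage
   profiles.
6. **Drivers** — per-SNP genotype regression of strain-mean accessibility
   with an F-test (fraction of variable sites SNP-explained at BH 0.05);
   differentially methylated CpGs (cross-strain variance > 0.05 AND range
   > 0.75, strict), methylation-variance contrasts by site annotation,
   DM-in-TE enrichment.
7. **Motifs** — PWM log-odds scanning on both strands, GC-matched
   background sampling, hypergeometric enrichment at young (< 40 Myr) vs
   old LINE sites with the selection rule p < 0.01 and > 10% target
   occurrence, and motif-occurrence binding prediction within accessible
   sites.

A first-class synthetic-data module (`simulate_genome()`,
`simulate_strains()`, `simulate_counts()`, `simulate_fragments()`,
`simulate_methylation()`) generates every input with known ground truth,
and `run_all()` chains the whole pipeline on that scenario, writing all
stage outputs plus a recovery report.

## Worked example

```r
library(accessTE)

report <- run_all(analysis_config(rng_seed = 1L), "my_run")
#> (stages: genome, strains, site_plan, methylation, pseudogenomes,
#>  fragments, peaks, union, counts, variability, te_analysis, drivers,
#>  motifs, profile, report — outputs under my_run/)

report$n_records$union_sites        # 950 union accessible sites
report$recovery$variable_recall     # 0.96  (48/50 planted variable sites in the top-5% class)
report$recovery$common_recall       # 0.96  (planted common sites in the bottom-5% class)
report$recovery$fraction_snp_explained  # 0.3125 (planted: 0.30)
report$recovery$dm_recovered_exactly    # TRUE  (all 10 planted DM CpGs, no extras)
report$enrichment$line_p            # 4.6e-06  LINE enrichment at variable sites (Fisher)
report$enrichment$age_wilcoxon_p    # 1.2e-10  TEs at variable sites are younger
report$motifs$young_selected        # TRUE  planted GAS/STAT motif selected at young-LINE sites
report$motifs$young_fraction        # 0.74  fraction of young-LINE site sequences with a hit
report$motifs$old_selected          # FALSE (not selected at old-LINE sites)
```

Reading those numbers: of the 950 union sites, the 48-site variable class
recovers 96% of the planted variable stratum and the common class 96% of
the planted stable stratum; 31% of variable sites have an associated SNP
(15/48 were planted SNP-driven, i.e. 30%); LINEs are strongly enriched at
variable sites and those LINEs are significantly younger; and the motif
planted in young-LINE consensus sequences is recovered by the enrichment
rule at young-LINE sites only.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/scripts/run_pipeline.R --seed 1 --out my_run
```

Individual stages are exported and run on real data files too:
`read_fasta()`, `read_snv_vcf()`, `read_repeatmasker_out()`,
`read_cpg_table()`, `read_pwm()` ingest the standard formats;
`call_peaks()` onward make no assumption that the data are simulated.

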