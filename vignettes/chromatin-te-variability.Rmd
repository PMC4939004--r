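---
title: "Methods: cross-strain chromatin accessibility variation at transposable elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-strain chromatin accessibility variation at transposable elements}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Inbred mouse strains differ heritably in which regulatory regions of the
liver genome are in open (nucleosome-depleted) chromatin.  A natural
experimental design profiles accessibility — e.g. by FAIRE-seq — in several
strains with replicates, identifies a union set of accessible sites, and
asks which sites vary across strains and why.  Two genomic features turn out
to carry much of the signal: underlying sequence variants (SNPs), and
transposable elements (TEs), whose evolutionary age stratifies their
regulatory behaviour.  `accessTE` implements this analysis end to end as a
reusable, fully testable pipeline, together with a synthetic-data module
that generates every input with known ground truth.

# Pipeline stages and their models

## Strain pseudo-genomes and mappability

Reads from non-reference strains align poorly to a reference genome at
variant positions.  The standard mitigation substitutes each strain's
homozygous SNP alleles into the reference (`build_pseudo_genome()`),
preserving coordinates.  Only SNVs are used; inbred strains are assumed
homozygous, and heterozygous VCF records are rejected at parse time.

To diagnose residual alignment bias — important at young, low-divergence
TEs, which contain little unique sequence — `mappability_track()` computes
an exact k-mer mappability score.  For a position `p`, `M(p) = 1 / n(p)`
where `n(p)` counts genome positions (either strand, self included) whose
k-mer lies within a Hamming mismatch budget of `p`'s forward k-mer:
`M = 1` is a unique match, `0.5` two matches, and so on.  Defaults are
`k = 170` (the mean fragment length of the motivating design) and 2
mismatches.  The engine is exact: the k-mer is split into
`max_mismatches + 1` contiguous parts, so any match within budget must
match one part exactly (pigeonhole); exact-part hash lookups enumerate a
complete candidate set, verified by direct Hamming comparison.  This is
quadratic in the worst case and guarded by a genome-size cap (5 Mb by
default) — the intended scale is synthetic genomes and spot checks, not
whole mammalian genomes.  Windows containing N receive `NA`, and N never
matches any base, including itself.  A pure-R brute-force oracle
(`kmer_match_count()`) ships with the package and the test suite asserts
exact equality on random genomes.

## Peak calling and replicate reproducibility

`call_peaks()` estimates a per-bp fragment-midpoint density with a Gaussian
kernel of `sigma = feature_length / 6` (feature length 400 bp by default,
mirroring the kernel-density caller commonly used for FAIRE data), scaled
to fragments per bp.  The calling threshold is the closed-form mean plus
`threshold_sd` (default 4) standard deviations of the density under uniform
placement of the same number of fragments on the same chromosome.  A
caveat the tests document explicitly: this Gaussian background
approximation is well calibrated at realistic fragment depths but
underestimates the Poisson upper tail when libraries are very sparse
(hundreds of fragments per megabase), where isolated fragment pairs can
exceed 4 SD.  Such noise calls are random in position and are removed by
the replicate-reproducibility filter; the threshold multiplier is
config-exposed for users who want a stricter single-library caller.

`reproducible_peaks()` is a deliberately explicit rank-based surrogate for
the irreproducible discovery rate idea: candidates are replicate-1 peaks
overlapping a replicate-2 peak by at least 1 bp; ranked by replicate-1
score, the retained prefix ends where the rolling mean (window 20) of the
absolute normalized rank discordance between replicate scores first
exceeds 0.5.  The stop rule is only armed once the window is full —
partial windows at the head of the ranking carry single-peak rank noise.
Two consequences worth knowing: perfectly concordant lists are retained in
full, and a library whose peak scores are pure noise (no strength
heterogeneity) has expected discordance near 0.5 at the head of the list
and is heavily truncated.  Real peak strengths are heterogeneous, which is
why the synthetic scenario draws per-site enrichments from a log-uniform
range rather than a constant.

Union sites (`union_sites()`) merge per-strain reproducible peaks that
share at least 1 bp; book-ended intervals stay separate.  Fragment
counting at union sites is by fragment midpoint, so every fragment is
counted at most once and column sums are bounded by library sizes.

## Quantile normalization and the variability test

Counts are quantile-normalized before testing (`quantile_normalize()`):
each column's values are replaced, in rank order, by the across-column
mean of order statistics, ties receiving the mean of the target values
they span.  The implementation is the package's own short exact routine;
it agrees with `limma::normalizeQuantiles()` on tie-free data (asserted in
the tests) but enforces the tie-span-mean rule exactly, which preserves
column sums even with heavy integer ties.

`nb_variability_test()` asks, per site, whether strain means differ, under
a negative binomial model with variance `mu + alpha mu^2`:

* dispersion `alpha` is estimated per site by method of moments pooled
  over within-strain replicates (`sum(v_s - m_s) / sum(m_s^2)`), floored
  at 1e-8, then shrunk 50/50 toward a mean-dispersion trend
  `alpha ~ a0 + a1/mu` fitted across sites — a deliberately explicit,
  fully determined stand-in for the empirical-Bayes machinery of NB
  differential-analysis packages;
* the test statistic is a likelihood-ratio of free strain means versus a
  common mean at the fixed dispersion (strain sample means are the NB MLE
  at fixed size), referred to a chi-squared with `n_strains - 1` df;
  normalized non-integer values enter the NB likelihood as a continuous
  relaxation;
* p-values are Benjamini–Hochberg adjusted; all-zero sites are reported
  untested with adjusted p 1.

With two replicates per strain the per-site dispersion estimate is noisy
and the raw test mildly anti-conservative; the BH-adjusted null rejection
rate stays well under 5% in the packaged simulations.  `classify_sites()`
ranks by adjusted p (ties: raw p, then coordinates) and labels the top and
bottom `round(variable_fraction * n)` sites *variable* and *common*,
with half-away-from-zero rounding — the convention that reproduces a
2539-site variable class from 50,775 sites at 5%.

## TE ages, enrichment, drivers, motifs

TE age is `divergence / substitution_rate`, with divergence the fraction
of bases differing from the subfamily consensus (RepeatMasker's percent
divergence divided by 100 at parse time) and a default neutral rate of
4.5e-9 substitutions/site/year for mouse; 40 Myr separates "young" from
"old" wherever the distinction is used.  Enrichment of TE classes and
subfamilies at variable versus common sites uses the package's exact
statistics kernels: a probability-mass-summation two-sided Fisher test and
a Wilcoxon rank-sum test that enumerates the exact null (handling ties via
midranks) when `min(n, m) <= 8` and otherwise uses the normal
approximation with tie and continuity corrections.  Both have brute-force
enumeration oracle twins in the test suite, with agreement asserted to
1e-12.  Subfamily tests exclude subfamilies with fewer than five total
site hits and are BH-corrected.

SNP attribution regresses, per SNP overlapping a site, the per-strain
replicate-averaged normalized count on the 0/1 genotype vector (replicates
are averaged because genotype only varies at strain level); significance
is the OLS F-test, BH-adjusted over all site-SNP tests, and a variable
site counts as "SNP-explained" if any overlapping SNP passes adjusted
p < 0.05.  Differential methylation uses the strict conjunction
variance > 0.05 AND range > 0.75 on per-CpG cross-strain methylation
fractions (sample variance, n-1), after removing CpGs that coincide with
SNP positions.  Methylation variance is compared between CpGs in
TE-overlapping, other-repeat, and unique variable sites (TE >
other-repeat > unique precedence for mixed sites).

Motif analysis scans base-2 log-odds PWMs (pseudocount-smoothed, both
strands, hit threshold 0.8 of the maximal score — the threshold is a
package default, config-exposed, since scanning tools differ here) over
site sequences; enrichment is sequence-level occurrence tested by a
one-sided hypergeometric against a GC-matched background (5-percentage-
point GC bins, two backgrounds per target, nearest-bin relaxation when a
bin is unmatchable), and a motif is *selected* iff p < 0.01 and it occurs
in more than 10% of targets.  Predicted binding sites are genome-wide
hits fully contained in accessible sites.

# The synthetic scenario: what it emulates and what it does not

The generator defaults define one desk-scale study: 2 chromosomes of 1 Mb,
7 strains with 2 replicates each, about 950 planted accessible sites, and
roughly 260 TE copies from 7 subfamilies (three LINE, one SINE, two LTR,
one DNA) spanning target ages 5–90 Myr.  Key choices, made once:

* TE instances are subfamily consensus sequences mutated at per-site
  probability `age x rate`; realized divergence is recorded per instance,
  so derived ages scatter around the target, as real instances do.
  A GAS-like STAT motif (`TTCCCGGAA`) is planted mid-consensus in the two
  young LINE subfamilies only, which is what makes young-LINE motif
  enrichment recoverable.
* 50 variable sites: 35 centered on young LINEs, 15 on unique sequence.
  Fifteen are SNP-driven (a causal SNP at the site center; carriers get a
  4-fold mean increase), ten methylation-driven (strain mean scales as
  `1 + (fold - 1)(1 - methylation)` with a planted bimodal DM CpG,
  fold 8), and twenty-five carry free per-strain fold profiles
  (`2^Normal(0,1)` with one forced 4x and one forced 0.25x strain) —
  continuous profiles keep chance alignment with bystander SNP genotypes
  rare, which is what keeps the SNP-explained fraction near its planted
  30%.
* 50 common sites (12 old LINEs, 13 SINEs, 25 unique) are drawn at a high
  mean (5000) with near-Poisson dispersion, making them genuinely the
  least variable stratum rather than merely average — the bottom-5% class
  is otherwise not identifiable against the uniform null p background.
* 850 background sites at mean 100, dispersion 0.05 (the NB
  gamma-Poisson parameterization `var = mu + alpha mu^2` throughout).
* fragment libraries: 60,000 fragments per library, lengths
  `Normal(170, 3)`, per-site enrichment log-uniform on 10–40 (shared
  across libraries, so replicate peak scores are rank-correlated);
  SNPs at 1e-3 per bp with alt alleles on random nonempty proper strain
  subsets; 10% of TEs flagged polymorphic.

Counts at union sites are drawn from the planted NB model rather than by
counting the simulated fragments, so that every downstream recovery metric
has exact ground truth; `count_fragments()` is exercised separately.  The
generator does not emulate read-level sequencing error, alignment,
GC-dependent coverage bias, fragment-length/site-width interactions, or
LD structure among SNPs — so passing recovery tests demonstrates the
pipeline's statistical machinery, not robustness to alignment artifacts
in real data.

# Numerical and policy details

* Coordinates are 0-based half-open internally; VCF and RepeatMasker
  `.out` convert at the parser boundary.  Overlap means >= 1 shared bp.
* Dispersion floor 1e-8 (the documented Poisson limit; requesting
  `alpha = 0` is an error that points there).
* Fisher's two-sided p sums hypergeometric masses `<= observed x (1 +
  1e-7)`; degenerate margins give p 1.
* Classification ties break by raw p then (chrom, start), making labels
  deterministic under permutation of input rows.
* The per-stage RNG seeds derive from the global seed by a fixed string
  hash (`stage_seed()`), so any stage can be re-run in isolation,
  reproducibly; rerunning `run_all()` with one seed gives byte-identical
  stage outputs (`report.json` is excluded from that contract because it
  records wall-clock stage timings).
* Problem sizes in the packaged tests — e.g. 1 kb oracle genomes for
  mappability equality, 2,000-site null and 1,000-site power simulations
  for the NB test, one full default-scenario run — were chosen as the
  smallest sizes at which the corresponding statistical claims are stable.

# Known limitations

* The reproducibility filter is a rank-concordance heuristic, not a
  copula-mixture IDR estimator; its window and cutoff are config-exposed.
* The analytic peak threshold is permissive on very sparse libraries (see
  above).
* The exact mappability engine is for desk-scale genomes; parts of the
  k-mer must fit in 64 bases, so `max_mismatches = 0` is limited to
  `k <= 64` (the default budget of 2 supports `k <= 192`).
* `snp_association()` treats strains as exchangeable observations; kinship
  or population structure among strains is out of scope.
* Subfamily consensus sequences are generated, not real repeat library
  entries; motif content of real TE subfamilies is richer than the single
  planted motif.
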