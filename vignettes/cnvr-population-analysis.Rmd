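---
title: "Methods: CNVR construction, Vst scans, and the simulated-truth design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNVR construction, Vst scans, and the simulated-truth design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvrscan)
```

This vignette documents the models, conventions and design decisions
behind the package: what each stage computes, which parameters matter,
what the cohort simulator does and does not emulate, and where genuinely
open choices were resolved.

## The pipeline model

The package operates on the output of a read-depth CNV caller of the
CNVnator family: one tab-separated file per sample with a call type,
`chrom:start-end` coordinates, call size, normalized read depth (RD,
diploid = 1.0), four significance columns and q0, the fraction of reads
with mapping quality zero. Five stages follow:

1. **Filter.** Retain calls with p-value < 0.01, size > 1 kb and
   q0 < 0.5. All three are strict inequalities, exactly as this filter is
   conventionally stated; a call at p = 0.01 or size = 1000 bp is
   removed. The caller emits q0 = −1 when no reads inform the statistic;
   we treat that as missing and retain the call, since discarding would
   silently drop real calls in unmappable-but-called regions. The first
   significance column is used as the filter p-value (the caller's t-test
   column); the remaining three are carried opaquely. Both choices are
   configurable in `filter_spec()` / `read_cnv_calls()` consumers.
2. **Merge.** CNVRs are connected components of the pairwise-overlap
   relation (≥ 1 shared base) among filtered calls per chromosome, closed
   transitively, each spanning the envelope of its member calls.
   Adjacency is not overlap: book-ended calls stay separate. No
   reciprocal-overlap fraction is required by default
   (`min_overlap_frac = 0`); setting it > 0 demands that fraction of both
   calls and is useful as a sensitivity check. A region with at least one
   deletion and one duplication call is typed `both` — this is why the
   type exists at all in cohort tables.
3. **Genotype.** CN per CNVR per sample is the overlap-length-weighted
   mean of RD over the sample's calls intersecting the region, with
   uncovered bases contributing the diploid baseline 1.0 and "no call at
   all" giving exactly 1.0. With binned depth tracks, CN is mean bin
   depth over the region divided by the sample's genome-wide mean bin
   depth. The Redon classification deleted (< 0.4) / conserved
   ([0.4, 1.6]) / duplicated (> 1.6) partitions the CN axis exhaustively;
   it only makes sense on this normalized scale, which is why the whole
   package works in diploid-equals-1 units and never absolute copy
   counts.
4. **Vst scan.** `Vst = (V_T − V_S)/V_T` with `V_T` the variance of CN
   over all individuals and `V_S = Σ n_i Var_i / Σ n_i`. We use
   population variances (denominator n) and size weights `n_i`,
   the standard construction of this statistic; because the formula's
   variance convention is often left unstated in applications, a
   `var_type = "sample"` switch allows n − 1 denominators for sensitivity
   analysis. `V_T = 0` (all individuals identical) defines Vst = 0.
   Negative values — within-group variance exceeding total — are reported
   as computed, never clamped: clamping would distort the selection
   quantile. Candidate regions are the top 1% by the nearest-rank rule:
   with n regions the threshold is the k-th largest Vst,
   `k = max(1, floor(0.01 n))`, and ties at the threshold are included,
   which makes "top 1%" well defined for small n and tied scans. Which
   groups form the two sides of a contrast (e.g. high- versus
   low-altitude populations) is user input, not hard-coded.
5. **Annotate.** Each CNVR gets exactly one genomic-context class with
   precedence exonic > intronic > upstream > downstream > intergenic.
   Flanks default to 1.9 kb on either side, strand-aware (upstream of a
   `+` gene is below its start; of a `−` gene above its end). 1 kb is the
   more common annotation default, but 1.9 kb is the convention of the
   analyses this package reproduces; the parameter is exposed as
   `flank_bp`. A region upstream of one gene and downstream of another
   resolves to upstream by the precedence order. Genes without annotated
   exons are treated as one exon spanning the gene body — the
   conservative reading, since any overlap then counts as exonic.
   Classes are per-CNVR (one label each), not per-base proportions.

## Coordinates

The API is 1-based inclusive throughout — the GFF/GRanges convention, and
the natural one for an implementation standing on IRanges — with lengths
`end − start + 1`. BED output is 0-based half-open, and every written
table states its convention in a `#` header line. Size bins for the CNVR
summary are left-closed/right-open on the boundaries 10 kb, 50 kb,
100 kb, 500 kb, 1 Mb, so a region of exactly 10,000 bp falls in the
second bin.

## The cohort simulator

`simulation_config()` describes a cohort as chromosomes, groups with
sample counts, and loci; each locus carries, per group, a categorical
distribution over CN states (e.g. `{0.5: 0.7, 1: 0.3}`).
`generate_truth()` draws every (sample, locus) CN independently from the
sample's group distribution; `emit_callset()` writes caller-dialect files
(one record per non-diploid truth entry, RD = CN plus truncated Gaussian
jitter, p and q0 drawn to pass the filter) plus a truth sidecar;
`emit_depth()` writes per-bin depths drawn Poisson with mean
`mean_coverage × CN`; `emit_genes()` writes a GFF3 realizing one planted
genomic-context class per locus; `expected_vst()` gives the analytic Vst
implied by the distributions, the value an empirical scan converges to.

Default conditions mirror a multi-breed whole-genome study: seven groups
of four samples (28 individuals), 100-bp bins, `mean_coverage = 20`
(mid-range of typical 17–23× cohort coverage), `rd_noise_sd = 0.05` (a
modest jitter consistent with read-depth estimates at 1–4 kb scale),
`junk_call_rate = 0.05`. Junk calls are engineered to fail exactly one
filter criterion each (p ≥ 0.01, size ≤ 1 kb, or q0 ≥ 0.5) and are
flagged in the sidecar, so filter tests can attribute every removal; at
the default cohort size (about five real calls per sample) the 5% rate
rounds to zero junk per sample, and tests that exercise junk handling
raise the rate explicitly. One global seed governs everything; each
sample draws from its own deterministically derived sub-stream, so output
files are byte-identical across runs and insensitive to sample order.

The planted gene layout cycles the five region classes over loci in
coordinate order: an exon across the locus; a two-exon gene whose intron
contains it; a gene placed 100 bp beyond it so the locus sits in the
upstream (or downstream) flank; or no gene. With loci spaced ≥ 20 kb as
in the default configuration, the planted class is recovered exactly for
any flank between 200 bp and 5 kb, which is the range the tests sweep.

What the simulator does **not** emulate: read-level artifacts
(mappability, GC bias), overdispersed depth noise, breakpoint
uncertainty (emitted calls have exact locus coordinates), linkage between
loci, and within-group relatedness — individuals are independent draws,
which matches the variance assumptions behind Vst but not the structure
of real breeds. Passing tests therefore demonstrate the correctness of
the filtering/merging/genotyping/scan arithmetic on caller-shaped input,
not robustness to caller artifacts on real genomes.

## Numerical choices and degenerate inputs

- Percentages in report tables are rounded half away from zero to two
  decimals, the convention of published cohort tables.
- A cohort's mean calls per sample is reported as the exact quotient
  (count / sample count), not re-rounded to match any external table.
- Empty inputs: filtering and merging of zero calls yield empty frames;
  the report layer renders an empty CNVR set without percentages rather
  than erroring; a region distribution over zero CNVRs is undefined and
  raises an error.
- Calls whose stated size disagrees with their coordinates are corrected
  to the coordinate-derived size with a warning, coordinates being the
  more trustworthy field.
- Merging is order-independent by construction (union–find over overlap
  pairs, output sorted by position), and genotyping defaults any
  evidence-free cell to CN 1.0 so the matrix is always complete.
- Per-group CNVR tables re-run the merge within each group's samples: a
  single global merge cannot produce group-wise region counts, since a
  global region's boundaries depend on other groups' calls.

## Problem sizes used in validation

The validation suite runs, at fixed seeds: 1000-case random-input
agreement between the Vst implementation and a brute-force two-pass
variance oracle (tolerance 1e-12); analytic-Vst recovery on cohorts of
100 samples per group over 20 replicate loci (mean absolute error below
0.05, degenerate scenarios exact); a 1000-locus scan with 28 samples in
seven groups and ten planted fully-differentiated loci, all of which must
fall in the top 1%; 500 fuzzed filter/merge property cases; and a flank
sweep over 500–5000 bp for the planted region-class layout. These sizes
keep each check well under a minute while leaving the statistical
margins (3 standard errors for moment checks) comfortably wide.

## Known limitations

- Vst significance is not assessed (no permutation p-values); the top-1%
  rule is a rank cutoff, as in the scan literature this follows.
- Call-mode genotyping assumes a sample's own calls do not overlap each
  other, which holds for per-sample read-depth callers.
- Region classification reports one class per CNVR; long CNVRs spanning
  several contexts are labelled by the highest-precedence contact.
- GO/KEGG enrichment of CNVR genes is out of scope: gene lists per CNVR
  are produced, enrichment depends on external databases.
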