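---
title: "Bin-based methylome analysis and transgenerational DMR tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-based methylome analysis and transgenerational DMR tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methgrid)
library(dplyr)
```

`methgrid` analyses whole-genome bisulfite sequencing (WGBS) data on a fixed
200-bp grid, with particular attention to *ectopic* CG methylation: CG-only
gains laid on top of a plant-like methylome and tracked across generations
after the methylation trigger is gone. This vignette explains the models and
procedures, the parameters that matter, what the bundled simulator does and
does not emulate, and the numerical choices made where the design was open.

## Methylation levels and the conversion filter

Bisulfite sequencing reads unmethylated cytosine as thymine, so the
methylation level of a cytosine is the fraction of reads carrying C:
level = #C / (#C + #T). Region-level summaries pool counts
(Σ#C / Σ(#C + #T)) rather than averaging per-cytosine levels, so deeply
covered cytosines carry proportionally more weight and the region level
retains the #C/(#C+#T) semantics; the unweighted mean is available via
`weighted = FALSE` where a sensitivity check is wanted.

Failed bisulfite conversion leaves every cytosine of the affected molecule
reading as methylated. Because genuine CHH methylation is sparse outside
heterochromatin, a run of **more than three consecutive methylated CHH
calls** on one read is treated as the signature of conversion failure and
the whole read is dropped (`filter_nonconverted_reads()`). Two readings of
"consecutive" are possible: consecutive *among the read's CHH calls* (an
intervening CG or CHG call does not interrupt the run) or strictly adjacent
in the full call sequence. The default is the former — conversion failure is
a property of the molecule, so a diagnostic CHH run should not be rescued by
an interleaved CG call — and `within = "all_calls"` switches to the stricter
reading. A read with exactly three consecutive methylated CHH calls always
survives.

Coverage thresholds: deep amplicon-style analysis (`region_methylation()`)
excludes cytosines under 20 reads; everywhere else (bins, gene bodies,
genome-wide differences) the threshold is 4×, harmonised with the DMR rule.

## The 200-bp bin grid and DMR calling

`bin_methylome()` tiles each chromosome from position 0 into fixed 200-bp
bins and pools, per context, the counts of cytosines covered ≥ 4×, keeping
the tally of contributing cytosines. The grid origin and the coverage rule
used for ranking are not externally constrained; both are package choices
(origin 0; pooled counts over ≥ 4× cytosines) applied uniformly so every
sample shares one grid.

A bin is a **hyper DMR** (`call_dmrs()`) iff, jointly:

1. ≥ 4 covered cytosines in *both* samples (`min_cytosines`),
2. pooled level difference (test − reference) > 0.10 (`min_diff`, strict),
3. two-sided Fisher exact p < 0.05 on the pooled 2×2 count table.

Hypo DMRs mirror the rule with difference < −0.10; hyper DMRs of A vs B are
exactly the hypo DMRs of B vs A with identical p-values. The p-values are
used **raw**: the procedure is a per-bin screen whose specificity comes
mainly from the effect-size filter (on null bins at the reference
conditions, 6 cytosines × 20×, the full hyper rule fires on ≈ 2% of bins),
and an FDR-adjusted variant is available via `correct = "BH"`. The test
itself (`bin_fisher_test()`) is an exact hypergeometric tail sum, vectorised
by grouping bins that share margins; it agrees with exhaustive enumeration
to < 1e−9 over all tables with margins ≤ 30 and with `stats::fisher.test()`
on random larger tables. A pooled-proportion score test (`method = "score"`)
is provided for sensitivity analysis only.

DMR identity across samples is **bin identity** (same grid cell), not
interval overlap: every set lives on the same grid, so interval logic would
add ambiguity without adding information. Merging adjacent DMR bins into
larger regions is deliberately out of scope — the analysis operates at bin
granularity throughout.

## Rank percentiles, clusters and matched controls

To relate ectopic gain to pre-existing methylation, bins with no CG
methylation in *any* sample are removed (`filter_unmethylated_bins()`,
evaluated after coverage filtering: an uncovered bin counts as
unmethylated), and the rest are ranked by the reference sample's CG level in
**descending** order — percentile 1 is the most methylated, heterochromatic
end. The sort direction matters and is stated explicitly because only one
direction makes the "top" percentiles the high-methylation cluster. Ties are
broken by genomic order so the ranking is reproducible. Percentile sizes
differ by at most one bin.

`assign_clusters()` groups percentiles into four clusters with default
boundaries 13/25/43: cluster 1 (1–13) is saturated heterochromatin, 2
(14–25) mixed-context methylation, 3 (26–43) CG-only methylation, 4 (44–100)
essentially unmethylated. These boundaries are dataset-derived defaults
promoted to parameters — on another genome they should be re-examined, not
reused blindly.

For enrichment questions a background matched on pre-existing methylation is
essential. `sample_mcg_equivalent()` draws, for each percentile holding k
hyper-DMR bins, exactly k non-DMR bins of the same percentile, uniformly
without replacement (with replacement would permit duplicate "regions",
which is meaningless for genomic intervals). The eligible pool excludes hypo
DMRs of the same comparison as well — a control should be non-differential
in either direction. The control histogram over percentiles equals the DMR
histogram exactly for every seed; exhausted percentiles are an error unless
`allow_shortfall` is set, in which case the deficit is reported.

## Heritability chains

Reproducibility and inheritance are measured by set algebra on bin ids.
Within a generation, the DMR sets of independent transgenic lines are
intersected; across generations the per-generation sets are unioned
(`combine_line_generation()`), so a site must replicate across lines but is
kept if established in either early generation. Inheritance after transgene
segregation is a chained intersection (`heritability_chain()`): for example
heritable(T4−) = T4− ∩ T3+ ∩ T2+, and heritable(T5−) = T5− ∩ heritable(T4−).
A plan entry's references resolve first to earlier heritable sets, so chains
compose naturally.

The "percent heritable" denominator is genuinely ambiguous, so both are
reported: `pct_reference` = |heritable| / |chained reference| (the primary
readout — of the previously established DMRs, how many persist) and
`pct_target` = |heritable| / |target|. On simulated data with region-level
retention probability r = 0.8, `pct_reference` per transition recovers
≈ 80% within binomial error.

## Gene-body methylation and feature annotation

Gene-body CG methylation (`gene_body_methylation()`) pools over the full
annotated gene span. Whether the original analyses used spans or exonic
cytosines is not recoverable; the span is the default because it is
annotation-robust, and `exons_only = TRUE` provides the alternative.
Classification is a pure strict-inequality threshold function:
*de novo gbM* = reference < 3% and gain > 10 points; *enhanced gbM* =
reference > 3% and gain > 10 points; a reference of exactly 3% falls in
neither class (documented edge, tested at ±ε). Epiallele-style status uses
40%/1%: *lost* = wild type > 40% and mutant < 1%, *maintained* = both > 40%,
*no-gbM* = both < 1%, else *other*. Control genes for expression-style
contrasts are drawn from the same reference-gbM percentile band
(± `tolerance` percentiles) among genes whose spans overlap no hyper DMR.

`annotate_features()` assigns each region by its **midpoint** with
precedence promoter > TTS > exon > intron > TE > intergenic. The promoter is
TSS − 1000 bp to TSS + 100 bp, strand-aware; the TTS window mirrors it
(3′ end − 100 bp to + 1000 bp) because no external definition of the TTS
extent is available. Midpoint assignment (rather than maximal overlap) is
deterministic and appropriate for 200-bp bins, and the explicit precedence
replaces reliance on an external annotator's defaults. Enrichment is
observed/expected category frequency against the mCG-equivalent controls
(or any supplied background); a category absent from the background has an
undefined ratio and is reported as `NA`, never as infinity.

## Profiles and signal comparisons

`metaplot()` rescales each region body to `n_body_bins` relative slices
(default 20) with absolute flanks (default 2 kb in 10 slices), flips
minus-strand regions so profiles read 5′→3′, and averages
overlap-width-weighted signal per slice across regions (mean ± SE). Regions
shorter than one position per body slice are skipped with a message; a
region missing data in a slice is skipped for that slice only. The plotting
parameters are conventional defaults, not constrained values.

`compare_signal()` computes per-region means over the full region or its
strand-aware 3′ half ("last 50%" in transcriptional orientation — the half
where gbM-associated signal changes concentrate), averages replicate tracks
within each genotype first, and runs an unpaired Welch two-sample t-test
across regions. Averaging-then-testing (rather than pooling replicates) is
the package's choice where the upstream convention is unstated; the Welch
test is unpaired, matching its standard two-sample form. A zero-variance
degenerate input reports statistic 0 and p = 1 with a warning rather than
failing.

## The simulator: what it emulates, and what it does not

The generator exists to give every pipeline stage a ground truth. It
emulates, deliberately at toy scale:

- a genome with gene-dense arms and a TE-dense centred pericentromere
  (uniform base composition at 36% GC);
- gbM genes (default 30% of genes) with CG-only body methylation following
  a smooth dome `60·x³(1−x)²` over relative position x in transcriptional
  orientation — unit mean (so the body average equals `gbm_body_cg_level`,
  default 0.35) and peak at 60% of gene length, inside the expected
  mid-body 40–80% window;
- TEs methylated at `te_levels` (defaults CG 0.9, CHG 0.7, CHH 0.1);
  background elsewhere defaults to 0 in all contexts;
- ectopic CG-only gains on 200-bp grid-aligned regions, sampled with weight
  `exp(-accessibility_bias × accessibility) × (1 + genebody_bias × in_gene)`
  so gains prefer less accessible chromatin and gene bodies. The strength
  of the accessibility coupling is a free parameter (default 2) — no
  quantitative external constraint exists for it. Accessibility itself is a
  covariate on the bin grid (high on arms, low over the pericentromere and
  a random ~30% of gene bodies), not a model of any chromatin assay;
- region-level inheritance: each established region survives a generation
  with probability `retention_rate_r` (default 0.8) independently, and a
  lost region reverts its CG sites to baseline together. Retention is
  region-wise, not per-cytosine, because inheritance is tracked at DMR
  level; a region once lost never returns;
- reads as runs of `read_length_cytosines` consecutive cytosines on one
  strand with Poisson starts (per-cytosine depth ≈ Poisson(coverage)),
  Bernoulli calls, and a configurable fraction of fully unconverted reads
  — modelled as all-methylated reads, the canonical signature the
  conversion filter targets.

Three establishment modes cover the analyses' needs: a per-bin rate, an
exact region count (weighted sampling without replacement), and a
genome-wide mean-gain target. The target mode uses weighted *quota*
sampling: regions are taken in weighted random order until their accumulated
gain mass (accounting for capping at probability 1 and for saturated sites)
reaches the target, so the realised genome-wide mean CG gain matches the
configuration to within one region's mass rather than only in expectation.
Eligibility additionally requires that a region can express a pooled gain
above `min_region_gain` (default half the site-level gain): CG sites at or
above `saturation_level` (0.9) never gain, and a region dominated by such
sites cannot show a region-level difference — consistent with saturated
heterochromatin showing no hyper-methylation, and with ground-truth regions
mapping one-to-one onto analysis bins so recovery is exact.

Two read-outs exist: `sample_reads()` (full per-read calls, needed for the
conversion filter) and `sample_cytosine_counts()` (direct Poisson/binomial
per-cytosine counts, equivalent to sampling reads with no unconverted
fraction and aggregating). Genome-scale validations use the count sampler;
read-level properties are always exercised with the read sampler.

Not emulated, hence not demonstrated by passing tests: sequence-composition
biases of real genomes (CpG islands, isochores), correlated methylation
between neighbouring cytosines beyond region structure, sequencing error
and mapping artefacts, partial conversion failure within a read,
re-establishment of lost regions, and any real chromatin assay. Results on
simulated data show the pipeline's correctness and calibration under its
stated model, not performance on real libraries.

## Numerical choices and degenerate inputs

- Symmetric CG dyads are **not** merged across strands: accounting is
  per-cytosine and strand-specific, matching per-cytosine callers.
- Percentile assignment uses `floor((rank−1)·100/n)+1`, giving contiguous
  groups whose sizes differ by ≤ 1; all tie-breaks are genomic order.
- The Fisher tail sum uses the conventional `1 + 1e−7` relative guard when
  comparing table probabilities, the same convention as R's exact test, and
  p-values are clamped to 1.
- A region or gene with no surviving cytosine yields a defined "no data"
  result (`NA` level) and is excluded from classification, never an error;
  a bin grid mismatch, an unknown gene id, a cytosine beyond the chromosome
  end, or a DMR bin missing from the percentile map are errors.
- Cytosines whose trinucleotide context would extend past a chromosome end
  are skipped with a message during context enumeration.
- Simulation problem sizes used in the test-suite validations (chosen as
  comfortable desk-scale conditions): 2 chromosomes × 0.5–1 Mb, 1,000 gain
  regions for heritability recovery at 20× coverage, 10,000 constructed
  bins for DMR calibration, and a 2 × 500 kb two-line, three-generation
  end-to-end run.

## Known limitations

Bins are fixed-width and grid-aligned; variable-width or sliding windows
are out of scope, as are smoothing/HMM segmentation, merging DMR bins,
isoform-resolved gene bodies, and ChIP-style normalisation. Cluster
boundaries and all thresholds are exposed as parameters but their defaults
encode one study design; on other data they are starting points. The raw
(uncorrected) DMR p-value is a faithful screen definition, not a
multiple-testing-safe inference; use `correct = "BH"` when false-discovery
control matters.
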