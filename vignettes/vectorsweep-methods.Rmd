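---
title: "Methods: statistics and design choices in vectorsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics and design choices in vectorsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

vectorsweep implements the analysis chain used in whole-genome studies of
insecticide resistance in *Anopheles* mosquitoes: phenotype the mosquitoes
with WHO tube tests, sequence resistant and susceptible individuals, and
look for resistance-associated variation at three scales — individual
candidate SNPs, genomic windows of differentiation and selection, and
structural (copy-number) alleles. This vignette explains each statistic,
the tunable parameters and their defaults, the numerical conventions, and
what the synthetic-data generator does and does not emulate.

## Bioassay summarisation

WHO tube tests expose replicate tubes of mosquitoes to an insecticide at a
discriminating concentration (and optionally at 5× intensity), alongside
oil-exposed controls. Replicates are pooled; mortality is deaths at 24 h
over exposed, with knocked-down mosquitoes counted as dead. Abbott's
formula

$$ \mathrm{corrected} = 100 \cdot \frac{T - C}{100 - C} $$

adjusts treatment mortality $T$ for control mortality $C$. Following WHO
practice, the correction is applied when $C \ge 5\%$, skipped below, and
the test is invalid when $C > 20\%$. Classification at the discriminating
dose: mortality $< 90\%$ confirms resistance, $[90, 98)\%$ is suspected
resistance (the 97–98% gap is placed in the suspected band), $\ge 98\%$ is
susceptible. At 5× intensity, $\ge 98\%$ indicates low-intensity and
$< 98\%$ moderate-to-high-intensity resistance.

One deliberate rounding convention: `summarise_bioassay()` rounds the
pooled treatment and control mortalities to two decimals *before* applying
Abbott's formula. Published tube-test tables are built this way — their
corrected values back-calculate exactly from the printed two-decimal
mortalities, not from the raw ratios (which can differ in the second
decimal). `abbott_correct()` itself is exact on whatever inputs it is
given, so callers who prefer full precision can use it directly.

## Variant QC

Site filters follow the GATK hard-filter recommendations with strict
inequalities: `QD > 5.0`, `QUAL > 30.0`, `SOR < 3.0`, `FS < 60.0`,
`MQ > 40.0`, `MQRankSum > −12.5`, `ReadPosRankSum > −8.0`. A site at
exactly a threshold fails. An absent INFO annotation passes its rule — the
GATK convention, since rank-sum annotations are undefined for sites
without heterozygotes — with a `strict_missing_info` switch for the
conservative reading. Genotypes are masked (set missing) unless `DP > 5`
and `GQ > 20`; the depth/quality rule is read as GATK's genotype-level DP
and GQ. Sites with more than 20% missing genotypes after masking are
dropped, so the missingness filter must run after the genotype mask
(`apply_variant_qc()` enforces the order; site filter and genotype mask
themselves commute). Sample retention by coverage — keep a sample if at
least 40% of the genome has more than 10× coverage, inclusive at 0.40 —
consumes a per-sample fraction table computed upstream from alignments;
the alignment stage itself is out of scope. Only biallelic SNPs are
handled; multiallelic records are rejected with a count and should be
split upstream.

## Candidate-SNP screen

Frequencies are allele counts over alleles actually called: missing
genotypes leave the denominator, which matters in small panels. Odds
ratios are computed on allele counts (2 × 2: alternate/reference ×
resistant/susceptible) rather than carrier counts, matching how allele
frequencies are tabulated; controls are excluded because their resistance
phenotype is unknown (they were the bioassay survival controls). With any
zero cell, 0.5 is added to every cell (Haldane–Anscombe) and the result is
flagged. The 95% CI is Woolf's,
$\exp(\ln \mathrm{OR} \pm 1.96\sqrt{\sum 1/\text{cell}})$. The "common
SNP" highlight is strict: pooled frequency over 5%, so exactly 5.0% is not
flagged. Display rounds percentages to one decimal; internals keep full
precision. Amino-acid effect labels are consumed from the candidate table,
not predicted.

## Rogers–Huff linkage disequilibrium

The composite LD correlation is computed directly from alternate-allele
dosages, so it needs no phasing:
$r = \mathrm{cov}(x, y) / \sqrt{\mathrm{var}(x)\,\mathrm{var}(y)}$ with
population-moment (biased, $1/n$) denominators, the convention of the
common implementations. Since the $1/n$ factors cancel between numerator
and denominator, $r$ equals the sample Pearson correlation — which the
test suite exploits as an independent oracle. Missing dosages are handled
by pairwise-complete deletion. A site that is monomorphic among the
complete pairs has undefined $r$: it is reported as `NA`, never coerced to
0, because small panels (tens of mosquitoes) genuinely produce such sites.
By default all phenotype groups are pooled for LD, configurable through
the `samples` argument.

## Windowed FST with permutation significance

Differentiation between resistant and susceptible groups uses Hudson's
two-population estimator. Per site, with sample frequencies $p_1, p_2$
from $n_1, n_2$ called alleles:

$$ N = (p_1 - p_2)^2 - \frac{p_1(1-p_1)}{n_1 - 1} -
       \frac{p_2(1-p_2)}{n_2 - 1}, \qquad
   D = p_1(1 - p_2) + p_2(1 - p_1) $$

and a window's FST is $\sum N / \sum D$ over its sites (ratio-of-sums —
the stable windowed form; a one-site window reduces to the per-site
estimator). Windows are non-overlapping 1 kb spans; windows without
variants are omitted; negative values (sampling noise around zero) are
retained rather than clipped.

An FST peak can reflect locally correlated SNPs (e.g. extended haplotype
homozygosity under a sweep) rather than phenotype, so significance comes
from a phenotype-permutation null: in each of `n_perm = 200` iterations
the resistant/susceptible labels are permuted once genome-wide, preserving
group sizes, and all windows are recomputed. Permuting once per iteration
(not per window) keeps the iteration a coherent genome-wide null, which a
single noise floor requires. A window is flagged only if (a) its observed
FST exceeds the 99th centile of its own permuted values and (b) it exceeds
`noise_multiplier = 3` times a noise floor. The source description of the
noise rule ("three times the minimum distribution") admits two readings;
the default takes the floor as the genome-wide 99th centile of all
permuted window values, with `noise_mode = "per_window"` for the
per-window reading. Neither is asserted as the original authors' — both
are available and the choice is logged in the output columns. Below 100
permutations the 99th centile is unstable and the function warns.

## Garud's H12 scan

For a window of phased haplotypes with sorted class frequencies
$p_1 \ge p_2 \ge \dots$: $H_1 = \sum p_i^2$,
$H_{12} = (p_1 + p_2)^2 + \sum_{i \ge 3} p_i^2$,
$H_{123} = (p_1+p_2+p_3)^2 + \sum_{i \ge 4} p_i^2$, and
$H_2/H_1 = (H_1 - p_1^2)/H_1$. Pooling the top two classes makes $H_{12}$
sensitive to soft sweeps, where the swept haplotype exists on more than
one background. Windows are 1000 consecutive SNPs; a terminal window with
fewer SNPs is dropped, not padded, because a shorter window has an
inflated homozygosity baseline. Haplotypes containing missing alleles in a
window are dropped before counting.

The resistant and susceptible groups differ in haplotype count (46 vs 20
in a 23/10 panel), and $H_{12}$ is biased by sample size, so the scan
equalises: each window's value is the mean of `n_iter = 200` evaluations
on random subsamples of `subsample_size` haplotypes drawn without
replacement (default: the smallest scanned group's haplotype count). The
degenerate setting — one iteration with the full group — reproduces the
direct statistic exactly. Runs of windows with mean $H_{12} > 0.2$ are
reported as sweep regions; 0.2 is the conventional empirical cutoff below
which scans of these panels show only background. Genes are intersected
with the bp span of above-threshold windows (half-open; a gene that only
abuts a window end does not overlap).

## Haplotype clustering

In windows of interest (FST peaks, sweep regions), haplotypes are
clustered by single linkage on normalised Hamming distance, cut at
`max_distance = 0.001` — i.e. haplotypes differing at no more than 0.1% of
sites count as "highly similar"; distance 0 recovers exact duplicates.
Reported clusters need `min_cluster = 20` members (inclusive — where
descriptions oscillate between "≥ 20" and "> 20", the inclusive reading is
taken). Each cluster is tested for phenotype association with a two-sided
Fisher exact test on the membership × phenotype 2 × 2 table, controls
excluded, with Benjamini–Hochberg correction across all clusters tested
(the multiplicity rule is this package's addition; the source is silent).

## CNV screen from soft-clipped reads

Whole-genome amplification distorts read depth, so coverage-based CNV
calling is deliberately excluded; instead known CNV alleles are screened
by clip evidence at their published breakpoints. For a breakpoint, the
denominator is every read with MQ ≥ 10 whose alignment covers or abuts it;
the numerator is the subset whose soft-clip boundary (first aligned base
for leading `S`, one past the last aligned base for trailing `S`) lies
within `tolerance_bp = 0` of the breakpoint on the expected side — left
clips at the CNV start, right clips at the end. Only CIGAR `S` operations
count; hard clips are read trimming, not breakpoint evidence. An allele is
called present when the proportion reaches the threshold at either
breakpoint; the comparison is inclusive (≥ 19.5%), since the source states
the cutoff without a comparator. `calibrate_threshold()` reproduces the
cutoff from a labelled verification set: the midpoint between the highest
non-carrier and lowest carrier proportion when the classes separate,
otherwise the Youden-optimal cutpoint from an exhaustive sweep. The screen
is presence/absence only — not copy-number quantification — and uses the
proportion alone, with no minimum absolute read count. A non-zero
`tolerance_bp` is available because WGA chimeras can shift clip boundaries
by a few bases.

## The synthetic-data generator

`generate_panel()` emulates the study design the pipeline targets: 23
resistant, 10 susceptible and 9 control diploid females with phased
genotypes. Background sites are *unlinked* — every haplotype allele is an
independent Bernoulli draw from the site's background frequency, drawn
uniformly from [0.05, 0.5] by default (polymorphic everywhere, skewed
toward the low-frequency end as folded site-frequency spectra are).
Linkage exists only where planted: a sweep feature stores one core
haplotype over its interval and copies it onto a Bernoulli(`core_freq`)
subset of haplotypes; candidate SNPs and differentiated windows redraw
genotypes at group-specific frequencies, optionally as exact counts
(`exact = TRUE`) for deterministic truth. Realised counts, sweep core
membership and CNV carriers are recorded as ground truth. VCFs carry the
INFO/FORMAT fields the QC filters consume, with per-site overrides for
planting filter violations; SAM fixtures place soft-clip boundaries
exactly at CNV breakpoints. Positions are 1-based as in VCF; all intervals
are half-open [start, end); everything is byte-identical under a fixed
seed.

What it does not emulate — and hence what passing tests do not show about
real data: coalescent genealogies and LD decay (background LD is exactly
zero, so the permutation null is cleaner than in real genomes, where
linked windows are correlated), recombination within sweeps, read errors,
alignment artefacts, or population structure. The generator validates the
machinery against known truth; it does not validate biological inference
on real panels.

## Numerical and design conventions

- Windows and intervals half-open, 1-based on input; TSV outputs carry a
  header comment naming the convention.
- Undefined statistics (monomorphic LD, zero-denominator FST windows,
  no-coverage breakpoints) propagate as `NA`/explicit markers, never as 0.
- All stochastic stages consume seeds derived from one base seed, salted
  by stage name (`stage_seed()`), so toggling one stage never shifts
  another's stream and every derived seed stays within 32-bit range.
- Quantile for the permutation centile is R's default (type 7).
- Ties in Youden calibration resolve to the smallest optimal threshold.

## Problem sizes

The test suite and acceptance script run on panels sized to exercise the
statistics meaningfully while keeping a full run in tens of seconds: the
study-shaped 23/10/9 panel; 500 one-kb FST windows (~2500 unlinked sites)
with 200 permutations for the null calibration; six 1000-SNP windows
(6000 sites, 46 haplotypes, 200 subsample iterations) for sweep detection;
depth 50–200 for clip-proportion recovery. These sizes were chosen as the
smallest at which the binomial/permutation error bands in the property
tests are tight enough to be informative.

## Known limitations

- Biallelic SNPs only; indels and multiallelics must be handled upstream.
- Sample-coverage fractions are an input, not computed from BAMs.
- The FST noise-floor rule is one of two defensible readings (both
  implemented, see above).
- Odds ratios use allele counts; carrier-based ORs would need the
  genotype-count table directly.
- With tens of samples, association tests are underpowered; the package
  reports per-SNP and per-cluster intervals and p-values without claiming
  genome-wide calibration.
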