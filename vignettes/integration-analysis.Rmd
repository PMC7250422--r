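---
title: "Quantifying and characterizing nuclease-free targeted integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and characterizing nuclease-free targeted integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(intequant)
```

`intequant` characterizes AAV-mediated, nuclease-free targeted gene
integration at one genomic locus from four kinds of raw data: short
paired-end amplicon reads, ddPCR droplet counts, deep arm-resequencing
reads, and long reads spanning the integration junction. This vignette is
the package's methodological account: the models behind each pipeline,
the defaults and why they were chosen, what the simulators do and do not
emulate, and the numerical corner cases.

## The locus model

Everything is defined relative to a `locus_model`: two homology arms
flanking a payload, the wild-type insert the payload replaces, genomic
flanks outside the arms, the terminal "d region" of the viral ITR, and an
annotation of inherited heterozygous SNPs. All internal coordinates are
0-based half-open; SNP positions are expressed as *distance to the first
payload base* (`offset >= 1`), the natural axis for crossover analysis,
and converted internally.

Four junction k-mers (default k = 12, six bases each side of the
arm/genotype boundary) discriminate WT from integrated alleles.
Validation enforces that each k-mer is pairwise distinct and occurs
exactly once, in its own amplicon, on either strand — the single property
the counting estimator relies on. k is configurable; 12 is the default
because 6+6 is long enough to be locus-unique and short enough to sit
comfortably inside a 75 nt read.

The packaged example locus (`example_locus_model()`,
`inst/extdata/example_locus/`) is a synthetic stand-in: random sequences
with the canonical dimensions (960/911 bp arms, 140 bp replaced insert, a
20 nt AAV2 d-region) and a donor carrying 7 left-arm + 2 right-arm het
SNPs, six of the seven left-arm SNPs on one haplotype and one on the
other — the haplotype structure that makes allele-specificity testable.
Real primer and arm sequences are locus-specific and live in the user's
config; nothing in the package depends on a reference genome download.
The replaced insert is modelled at 140 nt; its exact boundaries are a
free parameter of the config.

## Junction counting and the standard curve

A fragment (read pair) is *edited* if either mate contains the edited
junction 12-mer on either strand, *WT* for the WT 12-mer, and
uninformative otherwise; a fragment matching both k-mers is counted
uninformative and tallied separately. Matching is exact: at Q30 the
per-12-mer loss from residual sequencing error is under 2% and — crucially
— symmetric between genotypes, so it cancels in the ratio. The denominator
of `observed % = 100 n_e / (n_e + n_w)` is restricted to informative
fragments because non-spanning fragments are unassignable and their count
depends only on fragmentation geometry.

PCR amplifies the two amplicons with unequal efficiency. With relative
efficiency $\rho$ per cycle over $C$ cycles a true mixing fraction $f$ is
observed as $f\rho^C / (f\rho^C + 1 - f)$ — nearly linear over 0–10%.
The dilution-panel regression (observed on expected, OLS) absorbs this;
`apply_correction()` inverts the fitted line and flags corrected values
below zero as below the assay noise floor rather than clamping them, so a
negative control stays visible as such. The correction assumes sample and
standards share the amplification bias; if cycle numbers differ between
them, that assumption is the user's to check.

## ddPCR linkage

Three independent Poisson species per droplet (free payload $\lambda_P$,
free genomic $\lambda_G$, linked $\lambda_L$) give closed-form class
fractions; the inversion in `estimate_linkage()` is exact on those
fractions, and `linkage_percent` uses total genomic species
($\lambda_G + \lambda_L$) as denominator because that is the biological
quantity "fraction of target alleles integrated". Negative raw
$\lambda_L$ (double positives below independence) is clipped to zero and
flagged. A saturated assay (no double-negative droplets) is an error, not
a number. Uncertainty comes from a nonparametric bootstrap over droplets
(default 1,000 resamples) since droplet counts are the only observable.
Shearing is modelled in the simulator as acting *before* partitioning — a
sheared integrated molecule becomes one free payload plus one free
genomic fragment that partition independently — which is what physically
degrades linkage signal.

## Variant calling and the de novo criteria

The internal caller is a frequency caller over a Q30 pileup with the
filter triplet minimum variant frequency 0.05%, minimum base quality 30,
minimum depth 200. Alignment is seed-and-extend: an exact 15-mer seed
fixes the diagonal, a gapless comparison places substitution-only reads,
and reads that look indel-bearing fall back to banded affine-gap dynamic
programming (match +2, mismatch −4, gap open −4, extend −2). Pairs that
do not place properly (both mates, opposite strands) are discarded and
tallied. Indels are reported VCF-style with their anchor position; the
12 nt at each amplicon end are masked against alignment edge artifacts
(configurable).

Calling and *reporting* are deliberately separate knobs: the pileup emits
down to 0.05% so the LoD panel regression has dynamic range, while the de
novo criteria operate at the 0.5% reporting threshold — (a) above
threshold and passing filters, (b) reproduced in both technical
replicates, (c) "not observed" in WT alleles, operationalized as WT
frequency below the same threshold. Replicate frequencies are reported
separately and a de novo call carries their mean. The LoD panel
evaluation computes sensitivity and precision at the reporting threshold
and the log–log OLS of observed on expected frequency over nonzero
levels.

## Crossover localization

For a het SNP at distance $d$ from the payload, integration on its
haplotype retains the donor allele only when the crossover fell closer
than $d$; under crossover-distance CDF $F$ and equal haplotype usage the
integrated-allele frequency is $\tfrac12 F(d)$ and the correction
frequency $1 - \mathrm{vaf_{int}}/\mathrm{vaf_{wt}}$ estimates $1 -
F(d)$. Normalizing by the *measured* WT frequency (rather than assuming
50%) cancels donor allele-balance noise. SNPs with WT frequency below 10%
are excluded as not credibly heterozygous. The trend is summarized as an
OLS line (slope $-1/L$ under uniform crossovers); no changepoint or
hotspot estimator is fitted by default because the methodology is
designed to *test* for abruptness, not assume it — `hotspot_test()` is an
optional diagnostic comparing the largest adjacent jump against a
bootstrap null around the linear trend. Allele specificity is the mean
ratio of observed to expected retention at the minority haplotype's
offsets, with expected retention interpolated from the majority
haplotype's line and a parametric (binomial) bootstrap CI; a CI containing
1 is reported as no detectable specificity.

## Long-read ITR scan

Reads are filtered on mean per-base accuracy ("quality > 90" is
interpreted as 90% accuracy derived from Phred scores, configurable,
since the raw phrasing is ambiguous) and on the 1000–2000 nt window after
a first 400 nt trim. Each read is aligned semi-globally (band 10% of read
length around a seeded diagonal) to the ITR, seamless and WT amplicons;
highest score wins and *ties are left unassigned* — deliberately
conservative, so an ITR call never rests on an ambiguous alignment. The
ITR reference models only the d-region, the terminal ITR segment
documented to survive integration; full hairpin structure is out of
scope. The three ITR criteria (full-length arm coverage with payload
anchor; ≥5 consecutive matched d-region bases at the junction; genomic
sequence beyond the junction) are evaluated from the winning alignment.
Reads covering payload and arm but no genomic flank are flagged as
mispriming products, mirroring the dominant artifact class in this assay.
Sample-unique marker subsequences, when declared, remove library
cross-contamination.

## The simulators: what they emulate, and what they do not

The simulators generate data with exactly the statistical structure the
estimators assume: binomial genotype mixing, uniform fragment placement
(with a configurable junction-spanning fraction), residual substitution
error after quality filtering (default 0.1% short-read; 2%/2%/1%
sub/ins/del for long reads, i.e. 5% total), crossover positions from a
configurable distribution (uniform by default, matching the observed
linear correction trend), categorical ITR trimming over documented trim
offsets (default: full d-region), and three-Poisson droplet loading with
pre-partition shearing. Residual error rates are set post-filter because
published filter cutoffs (Q30, quality > 90) do not pin down the residual
spectrum; the values are configurable parameters, not claims.

They do **not** emulate PCR chimeras, polymerase-specific error spectra,
position-dependent quality decay, flow-cell artifacts, or index hopping.
Consequently, green tests demonstrate that the estimators are correct
*under their stated models* and at the published problem sizes — they are
necessary, not sufficient, evidence about behavior on real libraries,
where the k-mer counting and tie-breaking conservatism matter precisely
because those artifacts exist.

## Numerical choices and problem sizes

* Junction matching is exact (no mismatch tolerance): deterministic and
  oracle-checkable; the symmetric loss cancels in the ratio.
* The banded aligner scores tie-free integer arithmetic; band half-width
  is 12 for 75 nt reads and 5% of read length for long reads.
* Bootstrap defaults: 1,000 resamples (droplets, allele specificity).
* Degenerate inputs error loudly: empty read sets, saturated droplet
  tables, panels with fewer than three levels, single-haplotype
  specificity tests, correction models with non-positive slope.
* Validation suites run at the published scales: the 5-step curve at
  20,000 informative pairs per level, arm resequencing at 10,000x, the
  8-step LoD panel (0, 0.1, 0.5, 1, 2, 5, 10, 100%) at 50,000x, the ITR
  specificity run at 5,000 long reads — sizes chosen to reproduce the
  validation conditions of the assays themselves. (One published listing
  of the LoD panel includes a ninth 50% level; the panel function takes
  `levels` as input and does not hard-code either reading.)

## Known limitations

* Amplicon-based: structural variants, large rearrangements and
  off-target integrations are invisible by design.
* The correction model is linear over 0–10%; far outside the panel range
  extrapolation is unchecked.
* The ddPCR model assumes ideal partitioning (no volume variation, no
  rain) — input is post-gating counts.
* Crossover inference assumes gene conversion tracts resolve as a single
  crossover point per molecule; complex tracts would blur, not bias, the
  trend.
* The internal variant caller is characterized against its own LoD panel,
  not against external callers; its filter defaults mirror the printed
  values used in the assay it reproduces.
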