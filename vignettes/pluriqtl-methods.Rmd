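---
title: "Methods: integrating SNP and copy-number variation with multi-level expression"
author: "pluriqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating SNP and copy-number variation with multi-level expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pluriqtl)
```

## The problem

Pluripotent stem cell lines — embryonic (hESC) and reprogrammed (hiPSC) —
differ genetically: in single-nucleotide genotypes, and in copy-number
changes that arise in culture or survive reprogramming. Both kinds of
variation can change expression, at the whole-gene level and, through
alternative splicing, at the transcript and exon level. `pluriqtl`
provides a tested implementation of an integrative workflow that (i)
quality-controls array-style probe intensities and genotype calls, (ii)
tests each copy-number-altered gene for a dosage effect on its expression,
(iii) scans cis-linked SNP-feature pairs for genotype-expression
associations at four interval definitions, and (iv) asks whether
associated SNPs plausibly alter transcription-factor binding.

## Probe quality control

Probes are filtered before any association testing, in a fixed order:

1. **Background.** Antigenomic control probes (no genomic target) estimate
   the intensity a probe attains by GC-dependent non-specific
   hybridisation. Within each GC bin the limit is the mean plus two
   standard deviations (n−1 denominator; a single observation has SD 0)
   of the pooled antigenomic intensities, on the linear scale. A genomic
   probe survives iff its **maximum** intensity across samples strictly
   exceeds its bin's limit: probes at or below the limit are treated as
   background. The strict inequality is deliberate — a probe that never
   rises above the background bound carries no usable signal. A GC bin
   that occurs among genomic probes but has no antigenomic observations
   is an error rather than a silent pass.
2. **Flags.** Probes annotated as cross-hybridising or as overlapping a
   known SNP are removed. The flags are consumed as precomputed
   annotation: recomputing them from probe sequence is out of scope.
3. **Small probesets.** Probesets left with fewer than three probes are
   masked entirely; one or two probes give unreliable summaries.

Surviving probesets are summarised as the per-sample mean of log2
intensities. This is a deliberate stand-in for a full multi-array
normalisation: the QC decisions are the substance here, and a mean of
logs keeps the summary transparent and exactly testable. Consequences:
no between-array normalisation is applied, which is acceptable for the
simulated data (no array effects are generated) and stated as a
limitation for real data.

## Genotype quality control

Genotype calls are coded 1 (homozygous reference), 2 (heterozygous), 3
(homozygous alternate), each with a calling confidence in (0, 1].

* **Variation.** A SNP is kept iff its genetic variation within the
  analysed group is at least 0.25; the boundary is kept because only
  SNPs with *less than* 25 % variation are removed. The default metric is
  the minor-allele frequency of the coded calls
  (`MAF = min(f, 1−f)`, `f = Σ(call−1)/(2n)`); the phrase "25 % of
  genetic variation" could also mean the fraction of samples carrying a
  non-modal genotype, so that reading is available as
  `variation_metric = "genotype_fraction"`. MAF is the default because it
  is the standard population-genetic measure and gives the 1/2/3 coding a
  direct allele-dosage meaning.
* **Cascade rule.** The scan runs in three groups (hESC, hiPSC, all).
  Variation is re-computed per group, but a SNP removed from the
  whole-sample analysis is removed from the subgroups as well.
* **Confidence.** A SNP is removed if any analysed sample's call
  confidence is strictly below 0.9 (exactly 0.9 survives).
* **Regions.** SNPs inside any sample's reported copy-number region, or on
  a mosaic-gained chromosome, are excluded so that genotype-expression
  associations are not confounded by dosage. Interval membership is
  closed (boundaries excluded SNPs).

All three filters are per-SNP predicates and commute; the pipeline fixes
the order above for reporting.

## Copy-number / expression integration

Segments with fewer than 5 markers or shorter than the profile's minimum
length (10 kb for hiPSC-style calls, 50 kb for the more conservative
hESC-style calls) are discarded. A gene is labelled `gain` or `loss` in a
sample when its span overlaps a surviving segment of that state by at
least one base; conflicting states give `ambiguous`, which is excluded
from testing.

For each (gene, direction) the weight statistic is

$$w = \frac{m_{G1} - m_{G0}}{sd_{G1} + sd_{G0}}$$

with group 1 the altered-state samples and group 0 the normal samples.
The loss direction is oriented `(m_G0 − m_loss)/(sd_loss + sd_G0)` so a
positive weight always means "expression moved the way dosage predicts".
The statistic is location- and positive-scale-invariant; a zero
denominator with a non-zero numerator is ranked as most extreme (±Inf),
and 0/0 is 0. Singleton altered groups are allowed (their SD is 0) —
single-sample CNVs are common in small panels and are reported as such.

Significance comes from a permutation null: altered/normal labels are
reassigned uniformly at random with group sizes preserved, 10 000 times,
and the one-sided Monte-Carlo p-value uses the add-one plug-in
`(1 + #{w* ≥ w}) / (1 + N)` so p is never exactly zero. When
`choose(n, k) ≤ N` and exhaustive mode is on, all assignments are
enumerated and the plain proportion is returned (the plug-in is a
finite-sampling correction and is not needed under enumeration). The test
is one-sided in the dosage-predicted direction because the question is
directional (gain→high, loss→low); genes shifting against dosage are
reported with a flag but no significance claim. Permutation index
matrices are cached per (group size, sample count) pattern and reused
across genes — the null draws are exchangeable across genes, and reuse
only affects which Monte-Carlo noise is shared, not the marginal
distribution. Benjamini–Hochberg correction is applied within each
direction family.

## cis-eQTL scans

QC-passed SNPs are linked to features at four interval definitions, all
unstranded with inclusive boundaries and 1-based inclusive coordinates:

| level | window |
|---|---|
| gene | gene span ± 5000 bp |
| transcript | transcript span |
| exon, short | exon plus immediately adjacent intron(s), union over parent transcripts |
| exon, long | whole parent gene span |

The short set is a subset of the long set on every input (a tested
invariant). For each linked pair, ordinary least squares regresses log2
expression on the genotype code; since 1/2/3 is an affine transform of
allele dosage, the slope is log2 expression per alternate allele. The
two-sided p-value uses the t distribution with n−2 degrees of freedom;
perfect fits return p = 0 with a flag; monomorphic or below-variation
SNPs within the analysed group are skipped with a recorded reason
(requiring at least two genotype classes *within* the group, not merely
in the full panel, keeps each family's tests well-defined). BH families
are (level × group), matching the separately-run analyses; pooling all
levels into one family is possible but non-default. Summaries count
significant pairs, unique features and genes per family, SNPs inside vs
outside the feature span, the gene-resolution Venn across the four
levels, and the genes significant in both the SNP and the CNV scan
(where the expression difference may reflect dosage, not genotype).

## Allele-differential TF binding

TRANSFAC-style count matrices become log-odds PWMs by normalising each
column to frequencies, adding a pseudocount of 0.005 and renormalising
(dividing by 1.02), then taking log2 against a uniform background of
0.25. The binding score of a sequence is the maximum summed log-odds over
all windows of both strands (strand scanning is on by default; the
source analysis is silent on strand, and binding is physically
strand-symmetric). The relative score rescales between the motif's
attainable minimum and maximum (`(s − min)/(max − min)`), which reads
"fraction of the maximum possible binding score" as standard min–max
practice; the raw ratio `s/max` is available as a config option. An
allele pair is kept when either allele reaches 80 % of the maximum, and
the reported effect is the absolute difference of the two relative
scores. TFs are ranked by their best pair's difference; the "large
difference" cutoff is not specified by the source analysis, so the
default is 0.2 on the relative-score scale, configurable and echoed in
every output. Degenerate motifs (max = min) are excluded with a log
entry; windows containing non-ACGT bases are skipped with a warning.

## The synthetic study

The generator is first-class, tested code: it defines the conditions
under which the pipeline's statistical behaviour is validated.

* **Design.** 20 samples (9 hESC, 8 hiPSC, 3 fibroblast), two synthetic
  10 Mb chromosomes, 60 non-overlapping genes (1–2 transcripts each, 2–4
  exons per transcript), 150 SNPs placed inside genes, in the 5 kb
  flanks, and far away. Coordinates carry no reference-genome meaning.
* **Genotypes.** Hardy–Weinberg sampling at a uniform allele frequency in
  [0.05, 0.5]; confidences in [0.9, 1] except a 5 % fraction of SNPs
  given one sub-0.9 call to exercise the confidence filter.
* **Planted effects.** 20 causal SNPs (effect 1.0 log2 per allele dose)
  targeting genes, transcripts and exons in rotation, and 10
  dosage-affected genes at ±0.6 log2, applied to all of the gene's
  features in the carrier samples. Causal SNPs are placed inside their
  target feature and generated to pass QC (sample MAF ≥ 0.25,
  confidences ≥ 0.9, outside CNV regions): recovery measures association
  power, not QC attrition. Every planted pair is checked to be linkable
  at generation time. CNV segments pass the marker/length thresholds by
  construction; three decoy segments violate them, and one event
  reproduces the fibroblast→hiPSC inheritance pattern.
* **Expression.** Probe log2 intensity = feature baseline (U[6, 10]) +
  probe affinity (N(0, 0.3)) + planted effects + N(0, 0.5) noise, probes
  emitted on the linear scale. Noise is per-probe; the four-probe
  summary therefore has residual SD ≈ 0.25. Antigenomic probes cover
  every GC bin in 6–18 with a GC-increasing background; decoy probes
  (flagged, or background-level) and 1–2-probe probesets exercise each QC
  step.
* **Motifs.** Count matrices with 3 high-information columns (counts
  18/1/0/0) among weakly constrained ones — the mixed-information profile
  of real TF motifs — plus one uniform (degenerate) motif. Planted hits
  put the consensus on the reference allele with the SNP at a
  high-information column, so the alternate allele genuinely disrupts the
  site. SNP flanks default to 9 bp per side (one base short of the
  longest motif): long enough for every motif to cover the SNP at any
  offset, short enough that spurious alternative windows are rare.
  ChIP-style binding regions are placed away from all SNPs.

What the generator does **not** emulate: array physics and raw probe-level
normalisation artefacts, linkage disequilibrium between SNPs, sample-level
batch effects, partial-overlap dosage (a CNV shifts all of a gene's
features equally), and genotype-calling error. Passing recovery tests
therefore demonstrates the statistical machinery under clean additive
conditions, not robustness to those real-data complications.

## Numerical choices

* SDs use the n−1 denominator throughout; single observations have SD 0.
* Weight sentinels: ±Inf for zero denominator with non-zero numerator
  (sorted most extreme by the permutation comparison), 0 for 0/0.
* Monte-Carlo p-values use the add-one plug-in; exhaustive enumeration
  drops it.
* Perfect regression fits (residual SS ≤ 1e−12 × total SS) return p = 0
  and are flagged; constant expression returns slope 0, p = 1. Zero
  p-values from perfect fits stay zero through the BH step.
* Intervals are 1-based inclusive in all inputs and outputs; membership
  tests include boundaries.
* All randomness derives from one integer seed; generator stages use
  fixed offsets of it, so each fixture is individually reproducible and
  the end-to-end run is byte-identical under a fixed seed.

## Problem sizes used in validation

The packaged checks run the weight-statistic oracle on 1000 random group
fixtures, the permutation calibration on 2000 null genes (20 samples, 5
altered, 10 000 permutations), the regression oracle on 1000 random
fixtures plus a 2000-test null uniformity check, the linking oracles on
100 randomised annotations, and the recovery study on 50 independent
replicates of the default synthetic design. These sizes give the Monte
Carlo estimates standard errors well inside the asserted bands while
keeping a full run of the suite within a few minutes on one CPU.

## Known limitations

* The mean-of-log2 summary is not RMA; with real CEL-derived intensities
  an upstream normalisation should replace it.
* No covariate adjustment or population-structure correction in the eQTL
  scan (the design is a small, related panel; the source analysis used
  none either).
* The permutation and BH machinery treats genes and pairs as independent;
  correlated expression inflates the variance of the empirical FDR.
* PWM scores are not calibrated to p-values; the 80 % gate and the 0.2
  difference threshold are score-scale conventions, not error rates.
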