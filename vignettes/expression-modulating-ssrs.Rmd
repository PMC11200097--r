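---
title: "Mining transcriptome SSRs and detecting expression-modulating motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining transcriptome SSRs and detecting expression-modulating motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrexp)
```

## The problem

Simple sequence repeats (SSRs) — tandem repeats of 1–6 bp units — are
abundant in transcribed regions and can act as rheostats of gene
expression: the motif, the transcribed region it sits in, and the amount of
repeat DNA a gene carries are all candidate regulators. Given only a
transcriptome (FASTA), CDS coordinates with lncRNA flags, and an
organ-level TPM matrix, `ssrexp` asks: *which motif × region combinations
show statistically supported association with a gene's expression capacity
or tissue specificity?* Such combinations are called expression-modulating
motifs, **expMotifs**, and individual supporting loci eSSRs.

This vignette documents the model and its assumptions, the tunable
parameters, the synthetic-data generator used for calibration, and the
numerical and design choices a user should know about.

## SSR detection model

A perfect SSR is a maximal uninterrupted run of a *primitive* motif (one
that is not itself a repetition of a shorter unit). Detection follows the
MISA conventions:

* minimum repeat units of 15, 8, 5, 4, 3, 3 for motif sizes 1–6
  (`miner_criteria()`), making 15 bp the shortest reportable tract;
* a run is reported once, at the smallest primitive unit meeting its
  minimum — a poly-A tract is never double-counted as AA or AAA, and an
  AT run is only a dinucleotide SSR;
* trailing partial repeats are truncated, so
  `tract_length == motif_size × repeat_count` exactly;
* runs are broken at `N`; coordinates are 1-based inclusive on the
  transcript, matching the `+ 1` in the relative-position formula below;
* two or more SSRs with no intervening bases form a compound SSR
  (`max_interruption_bp = 0`; MISA's conventional 100 is available for
  interoperability). Compound membership is an annotation, not a merge,
  so dataset totals count every perfect SSR. Because a homopolymer run
  can legitimately extend one base into a downstream tract of another
  motif, the pipeline chains such minimally overlapping records instead
  of failing; `find_compound_ssrs()` errors on overlap by default.

The test suite holds the miner to *exact* equivalence with a brute-force
oracle that checks every (start, motif size, primitive motif) triple for a
left-maximal qualifying run, on repeat-rich 2 kb sequences.

Motifs are recorded two ways. The *actual* motif is the unit as read on the
transcript strand (GA, CT, TC are distinct — effects can be
strand-specific). The *standardized* motif is the class representative
under rotation + reverse-complement equivalence, computed as the
lexicographically smallest rotation of the motif or its reverse complement;
exhaustive enumeration gives 2, 4, 10, … classes for sizes 1, 2, 3, …
(`count_canonical_classes()`).

## Region model

An SSR wholly 5' of the CDS is 5'-UTR, wholly inside it CDS, wholly 3' of
it 3'-UTR; an SSR overlapping a junction is a boundary record, and boundary
records — like SSRs on transcripts lacking both CDS and lncRNA status — are
excluded from region-level statistics as lacking solid localization.
LncRNA SSRs use the whole transcript as their region. The relative position
of an SSR in its region is

$$\mathrm{rel} = \frac{\mathrm{ssr\_start} - \mathrm{region\_start} + 1}
{\mathrm{region\_length}} \in (0, 1].$$

"Position of the SSR" is read as its start coordinate: this is the only
reading that keeps the value in (0, 1] for every tract length. Background
GC for an SSR is the GC of its host region with the tract excised, which is
what the SSR's own GC is compared against.

## Expression model

Per transcript, `TPM_max` (maximum across organs) measures expression
capacity and `TPM_CV` — the *sample* (n−1) coefficient of variation —
measures tissue specificity. The sample convention matters: for an n-organ
profile expressed in exactly one organ the CV is exactly √n, hence the
level-1 TPM_CV threshold 3.4641 = √12 in a 12-organ design, which isolates
strictly one-organ genes. Both variables are binned into five levels
(level 1 highest) with cuts 1/10/100/1000 for TPM_max and
0.5/1/1.5/3.4641 for TPM_CV; each level interval is closed at its lower
cut so a CV of exactly √12 lands in level 1. Interval closure for the
inner levels is a convention the data do not pin down; it is configurable
via `assign_level()`'s cuts. Transcripts with zero TPM everywhere get no
levels (their log expression is undefined), and the UTR/CDS
differential-expression contrast is restricted to genes with TPM strictly
above 0.01 in *every* organ.

## The expMotif cascade

Stage 1 (primary filter): per motif × region × response, a Mann–Whitney
test compares carriers against all other profiled transcripts; a motif
occupying ≥ 3 regions additionally gets a Kruskal–Wallis across regions
with Dunn's post hoc. Candidates pass at raw p < 0.05 — the screening
convention of the field; an optional BH mode across all combinations is
available but off by default, since stage 2 provides the error control.
Carrier groups under 3 are skipped with a warning.

Stage 2 (regression suite): for each candidate group with more than
`min_carriers = 10` usable carriers, ln TPM_max (or ln TPM_CV) is
regressed on each SSR characteristic — abundance (SSRs per transcript),
density (SSRs per Mb of transcript) and summed tract length — with
polynomial degrees 1–3, plus the three additive bivariate linear pairs.
Bivariate fits with VIF above 10 (the common convention; configurable)
are discarded. The optimal model is the minimum-BIC significant fit
(overall F-test p < 0.05).

Manual exclusion of overfit models is replaced by a reproducible guard: a
degree-k polynomial is excluded when its top-order coefficient is not
significant or when its BIC does not improve on degree k−1 by at least 2 —
the usual "positive evidence" threshold on BIC differences.

A call requires *both* stages: primary p < 0.05 **and** a surviving
significant optimal model. Under the null these two checks are
approximately independent, so the false-call rate is far below α — the
acceptance suite verifies it never exceeds the single-test envelope.
Standardized mode is run first; actual mode is conventionally restricted to
actual motifs of candidate standardized classes, with the strict
`> 10`-carriers rule. Which of Mann–Whitney versus Kruskal–Wallis applies
to a given motif depends only on how many regions it occupies; both are
recorded whenever both run.

## Relative-position density

Called motifs are profiled by kernel density estimates of their relative
positions per expression level. Positions live on (0, 1], so a plain KDE
leaks mass off both ends; the estimate therefore reflects the sample at 0
and 1 and evaluates on [0, 1], restoring mass conservation (curves
integrate to 1 ± 0.02 in the acceptance checks). Bandwidth is Silverman's
rule of thumb on the level's own positions, with a floor of 1e−3 for
degenerate (all-equal) inputs. Levels with fewer than 5 positions are
skipped with a warning.

## The synthetic-data generator

`synthetic_config()` defines the study conditions the simulations emulate:

* transcripts with 5'-UTR/CDS/3'-UTR partitions plus a lncRNA fraction,
  lengths drawn log-normally around configurable means, and per-region
  background GC;
* backgrounds rejection-sampled to be SSR-free against the miner, so the
  planted truth table is unambiguous and recall assertions can be exact;
* planted perfect SSRs per (motif, region, carrier probability,
  repeat-count range), with flanks adjusted so a tract cannot extend into
  a longer run, and every planted transcript re-mined and required to
  reproduce exactly its truth rows (re-drawn otherwise). Copies that do
  not fit a crowded region are skipped; a tract longer than its region is
  an error;
* expression: baseline ln TPM_max ~ Normal(μ0 = 1, σ0 = 1.5), plus
  Σ β × characteristic for planted effects; organ shares from a Dirichlet
  whose concentration (5 by default; 0.15 for transcripts flagged
  tissue-specific) controls TPM_CV — as concentration → ∞ profiles
  flatten and CV → 0; finally each organ column is normalized to a common
  total, mimicking TPM's compositional constraint. The 12-organ default
  matches the design the thresholds (√12) assume.

What the generator does *not* emulate: isoform structure, read-level
noise, mapping ambiguity, assembly redundancy, phylogenetic correlation
among transcripts, and realistic genome-scale motif composition. Passing
the planted-recovery and calibration tests therefore demonstrates that the
*procedure* is correct and calibrated under its assumptions, not that any
particular biological dataset will yield stable expMotif calls.

## Calibration results computed by the test suite

The acceptance tests (`tests/testthat/test-acceptance.R`) recompute, at
problem sizes chosen to finish in minutes on one core: exact miner/oracle
agreement on one hundred 2 kb sequences; recovery of one planted expMotif
(β = 1.5 per SSR on ln TPM_max, ~25–35 carriers among 300 transcripts)
among 50 null motifs in ≥ 90 of 100 seeded runs with false calls inside
the binomial envelope of α; ≥ 90% CI coverage for planted linear density
effects β ∈ {0.5, 1, 2} at n = 500 over 200 replicates; a primary-filter
null rejection rate inside the 95% binomial envelope of α = 0.05 over
1000 null groups; and mass conservation plus ±0.05 cluster localization
for the position densities.

## Degenerate inputs and numerical choices

* Constant characteristics are skipped in regression (singular designs);
  rank-deficient bivariate fits are dropped; perfect collinearity is
  treated as infinite VIF.
* A zero-mean TPM vector has undefined CV: flagged NA with a warning and
  excluded from level analyses.
* All-identical values across Kruskal–Wallis groups take the p = 1 path
  (zero tie-corrected variance) rather than erroring.
* Kendall τ on a constant vector is NA with a warning.
* Ties use mid-ranks throughout; Dunn's z uses the standard
  Σ(t³−t)/(12(N−1)) tie correction, with BH adjustment across pairs, and
  a one-sided mode (direction from the observed rank-mean ordering) where
  directional letters are wanted.
* Chi-squared residuals are *adjusted standardized* residuals,
  (O−E)/√(E(1−r/N)(1−c/N)), approximately standard normal under
  independence.

## Known limitations

Imperfect (interrupted) repeats, units above 6 bp, and genome-scale
scanning are out of scope. Density denominators are summed bp of the
relevant scope, not per-sequence averages, so per-region densities
recombine exactly into whole-dataset figures. The detector reports
evidence for *association*; calling a motif an expMotif is a statistical
statement about its carriers in this dataset, not a demonstration of
mechanism.
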