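# ssrexp

Simple sequence repeats (SSRs, microsatellites) are tandem repeats of 1–6 bp
units that are increasingly recognized as "tuning knobs" of gene expression:
the motif, its location within a transcript, and the size of the repeat
tract can all modulate how strongly and how tissue-specifically a gene is
expressed. `ssrexp` is an R package for researchers who want to mine SSRs
from a transcriptome, characterize their distribution across transcribed
regions, and screen them for statistically supported expression-modulating
motifs (**expMotifs**) — all from three plain inputs: transcript sequences
(FASTA), CDS coordinates with lncRNA flags (TSV), and a TPM expression
matrix over organs (TSV).

## What it computes

**Mining.** Perfect SSRs are detected MISA-style: maximal uninterrupted
runs of a primitive 1–6 bp motif with at least 15, 8, 5, 4, 3 and 3 repeat
units for mono- through hexanucleotides (minimum reportable tract: 15 bp).
Adjacent SSRs with no intervening bases form compound SSRs. Each motif is
kept both as read on the transcript strand (*actual*) and folded into its
*standardized* class — the lexicographic minimum over all rotations of the
motif and of its reverse complement, so GA, AG, CT and TC all belong to the
class AG/CT.

**Region mapping.** Each SSR is assigned by full containment to the 5'-UTR,
CDS or 3'-UTR (or to a UTR/CDS boundary, a lncRNA, or an unannotated
transcript), with its relative position

    rel_pos = (ssr_start − region_start + 1) / region_length  ∈ (0, 1]

and the GC content of the tract and of its host region (tract excised).

**Expression profiling.** Per transcript, TPM_max (expression capacity) and
TPM_CV — the sample coefficient of variation across organs (tissue
specificity, bounded by √n_organs; √12 ≈ 3.4641 identifies one-organ genes
in a 12-organ design) — each binned into five levels.

**Association statistics.** SSR abundance (per sequence), density (per Mb),
frequency, GC and tract length per grouping; chi-squared tests with
adjusted standardized residuals to localize motif × region enrichment;
Kruskal–Wallis + Dunn (BH-adjusted) comparisons; Kendall τ-b; and the
four-group (5'-UTR-only / CDS-only / 3'-UTR-only / SSR-free)
differential-expression contrast on everywhere-expressed genes.

**expMotif detection.** A two-stage cascade per motif × region × response:
(1) a Mann–Whitney primary filter of carriers versus non-carriers (raw
p < 0.05), with Kruskal–Wallis across regions where applicable; (2) a
regression suite — linear/quadratic/cubic in each SSR characteristic
(abundance, density, tract length) plus additive bivariate pairs — on
ln TPM_max or ln TPM_CV, VIF-screened for collinearity, with BIC model
selection and an overfit guard. A motif is called an expMotif only when
both stages are significant. Relative-position probability-density curves
(boundary-reflected KDE) profile called motifs by expression level.

**Synthetic data.** `synthetic_config()` / `simulate_dataset()` generate
transcriptomes with SSR-free backgrounds (rejection-sampled against the
miner), planted SSRs with exact truth tables, and 12-organ TPM matrices
with planted effects of SSR characteristics on ln TPM_max and on tissue
specificity — so the whole pipeline is testable with no downloads.

## Worked example

```r
library(ssrexp)

plan <- data.frame(motif = c("AG", "AAT"), region = c("FIVE_UTR", "THREE_UTR"),
                   prob = 0.3, min_reps = c(8, 5), max_reps = c(12, 8),
                   mean_extra_copies = 0.8)
cfg <- synthetic_config(n_transcripts = 150, seed = 11, ssr_plan = plan,
  expression = list(effects = data.frame(motif = "AG", region = "FIVE_UTR",
                                         characteristic = "abundance",
                                         beta = 1.5)))
sim <- simulate_dataset(cfg)
ssrs <- mine_ssrs(sim$sequences)
am   <- map_regions(ssrs, sim$annotations, sim$sequences)
pr   <- profile_expression(sim$tpm)
det  <- detect_expmotifs(am, pr, sim$annotations)
subset(det$calls, called)
#>   motif   region response n_carriers    primary_p best_form best_predictors r_squared      bic called
#> 3    AG FIVE_UTR  tpm_max         46 3.156184e-10    linear       abundance 0.4732173 164.6881   TRUE
```

The planted AG repeat in the 5'-UTR — whose abundance was given a +1.5
effect per SSR on ln TPM_max — is the only call: its carriers differ from
non-carriers by Mann–Whitney (p ≈ 3e−10) and a linear model in abundance is
the BIC-optimal significant fit (R² ≈ 0.47). The null AAT motif in the
3'-UTR is not called.

`run_pipeline(config, out_dir)` executes the same stages over input files
(or a simulation config) and writes every stage table, dataset/region
summaries, a warnings sidecar and a run manifest;
`inst/scripts/ssrexp.R` is a thin Rscript wrapper around it.

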