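# peakcalibre

Expression-guided calibration and annotation of transcription-factor
ChIP-seq peaks.

## The problem

A ChIP-seq experiment for a transcription factor returns thousands of
peak calls spanning a wide range of fold enrichments, and only part of
that range reflects binding strong enough to regulate transcription.
`peakcalibre` implements the downstream analysis developed around the
genome-wide binding map of the ETV6 repressor in t(12;21)-positive pre-B
leukemia cells, where the question is sharpened by biology: direct ETV6
binding happens at ETS motifs (GGAA/T core), while the ETV6-AML1 fusion
protein of the t(12;21) background recruits the factor to RUNX motifs,
and IRF partners to a composite ETS-IRF element. The package is aimed at
computational biologists who have narrowPeak calls, a differential
expression gene list, and reference annotations, and want a reproducible
path from raw peak calls to a calibrated, annotated, motif-classified
peak set.

Stages (each usable on its own, all orchestrated by `run_all()`):

1. **QC filtering** — drop peaks overlapping blacklisted regions (≥ 1 bp),
   with fold enrichment above 50, or q-value above 0.1.
2. **Closest-TSS association** — each peak's effective summit to the
   nearest gene TSS, with deterministic tie-breaking.
3. **Threshold calibration** — for each fold-enrichment cutoff
   *t* ∈ {3.0, 3.1, …, 7.0}, test whether genes with a peak at FE ≥ *t*
   are enriched among the modulated genes, via the one-sided Fisher exact
   test on the 2×2 table (*k*, |M|−*k*; |G(t)|−*k*, N−|M|−|G(t)|+*k*),
   computed as the hypergeometric tail P(X ≥ *k*); select the *t*
   minimizing *p*.
4. **Genomic annotation** — EXON/INTRON/PROXIMAL (≤ 2 kb upstream)/
   DISTAL (2–10 kb)/5d (10–100 kb)/OTHER categories and a ±10 kb TSS
   profile.
5. **Cross-cell-line comparison** — per-reference-set overlap counts
   ("count(X→Y)" = X regions touching ≥ 1 Y region) and a chromatin-state
   assignment (max-bp-overlap against a 15-state coreMarks segmentation)
   for all / shared / specific peaks.
6. **Motif-class decomposition** — PWM log-odds scanning of peak
   sequences (both strands, fraction-of-maximum threshold), four-way
   ETS/RUNX classification, summit-centering profiles, class composition
   versus threshold, pooled-*t* group fold-enrichment tests, and the
   ETS-IRF compound search among motif-free peaks.

A fully seeded synthetic-data generator (`generate_workspace()`) plants
ground truth for every stage — motif classes with class-dependent fold
enrichments, an expression coupling that switches at FE = 4.5,
cross-set overlap fractions, chromatin-state bias — so the complete
pipeline runs and is testable with no downloads.

## Worked example

The `analysis/` directory is a numbered workflow over the package. On
the default synthetic workspace (`analysis/01_simulate.R`, seed 1,
2,000 peaks, 3,000 genes):

```
$ Rscript analysis/01_simulate.R
workspace written to results/workspace
  2000 peaks on 3 chromosomes; planted classes: ETS_ONLY=643 ETS_RUNX=305 NEITHER=712 RUNX_ONLY=340
  457 modulated genes (183 up, 274 down) of 3000 in the universe

$ Rscript analysis/03_calibrate.R     # after 02_filter_associate.R
selected threshold: FE >= 4.5
  1037 peaks -> 870 genes; 93.0% of modulated genes vs 29.00% of all genes (ratio 3.2)
  Fisher p = 8.49e-224
```

The sweep lands exactly on the planted change-point of 4.5: genes whose
best peak reaches FE ≥ 4.5 were modulated at rate 0.5 against a baseline
of 0.01, and the Fisher minimum identifies that boundary. The remaining
drivers print the comparison and motif results:

```
$ Rscript analysis/04_compare_states.R
venn (A = 1037 selected peaks): A&B 191 (18.42%), A&C 39 (3.76%), A&B&C 26 (2.51%)
top chromatin states, shared peaks:   Enh 45% / TssAFlnk 44%
top chromatin states, specific peaks: Quies 79% / BivFlnk 3%

$ Rscript analysis/05_motifs.R
motif classes among selected peaks:
 ETS_ONLY  ETS_RUNX   NEITHER RUNX_ONLY
     43.7      20.3      23.9      12.1
ETS-containing fraction: 0.64 at FE >= 3.0 -> 0.75 at FE >= 7.0
pooled t-test ETS-containing vs NEITHER: t = 6.02, p = 2.52e-09
```

The recovered overlap fractions (18.4% / 3.8% / 2.5%) sit on the planted
0.19 / 0.05 / 0.035; shared peaks land on the planted TssAFlnk/Enh
states while specific peaks stay quiescent; ETS-containing peaks are
significantly stronger and their share grows with the threshold —
the planted fold-enrichment structure. `analysis/06_report.R` runs the
same analysis through `run_all()`, which re-derives every summary count
from the stage TSVs before writing `summary.json`.

## Layout

```
R/                  package code (intervals & I/O, peak processing,
                    calibration, motifs, comparison, synthetic data,
                    pipeline orchestration)
analysis/           numbered workflow drivers (simulate .. report)
scripts/acceptance.R  headline-quantity reproduction (see above)
tests/testthat/     unit, property and end-to-end tests with
                    brute-force oracles
vignettes/          methods vignette: models, conventions, parameter
                    choices, generator design, limitations
```
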