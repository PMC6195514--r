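---
title: "Methods: expression-guided peak threshold calibration and motif-class decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-guided peak threshold calibration and motif-class decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakcalibre)
```

# The problem

A transcription-factor ChIP-seq experiment yields thousands of peak calls
whose fold enrichments span more than an order of magnitude. Only a
fraction of those peaks reflect binding events strong enough to matter for
transcription. `peakcalibre` implements the downstream analysis built
around one way of drawing that line: if binding is functional, genes near
strong peaks should be over-represented among the genes that actually
change expression when the factor is perturbed. The package was written
for the analysis of ETV6 binding in t(12;21)-positive pre-B leukemia
cells — a repressor whose direct sites carry ETS motifs, and whose
indirect recruitment (through the ETV6-AML1 fusion protein, or through IRF
partners) shows up as RUNX- or IRF-containing peaks — but every stage is
generic over narrowPeak/BED/FASTA inputs.

# The calibration model

Let $N$ be the size of the gene universe, $M$ the set of modulated
(differentially expressed) genes, and for a fold-enrichment threshold $t$
let $G(t)$ be the set of distinct genes having at least one associated
peak with $\mathrm{FE} \ge t$. The calibration sweep computes, per $t$:

* $\mathrm{pct}_{\mathrm{mod}}(t) = 100\,|G(t) \cap M| / |M|$ — the
  percentage of modulated genes with a peak;
* $\mathrm{pct}_{\mathrm{all}}(t) = 100\,|G(t)| / N$ — the same
  percentage over the whole universe;
* their ratio (the enrichment ratio); and
* a one-sided Fisher exact test of the $2 \times 2$ table
  $[\,k,\ |M|-k;\ |G(t)|-k,\ N-|M|-(|G(t)|-k)\,]$ with
  $k = |G(t) \cap M|$, computed as the hypergeometric upper tail
  $P(X \ge k)$ via `stats::phyper` in log space (universes of
  $6 \times 10^4$ genes and $p$-values near $10^{-35}$ are routine).

The selected threshold $t^\*$ minimizes the Fisher $p$ over the grid,
with exact ties resolved toward the more stringent threshold. Two choices
here were genuinely open:

* **Table construction.** Modulated genes are kept inside the universe
  margin (the standard Fisher table). The alternative — excluding $M$
  from the background — changes the count in the fourth cell by $|M|$,
  which is negligible when $|M| \ll N$ but is a different test; we expose
  only the standard construction because it is the one the test's margins
  actually satisfy.
* **Sidedness.** The question is enrichment, so the default is one-sided
  "greater"; a two-sided variant (through `stats::fisher.test`) is
  available via the `alternative` argument but is not the default.

The grid is generated by integer index ($t = t_{\min} + i \cdot s$), not
by repeated addition, so the 0.1 steps cannot drift; the default grid is
3.0–7.0 in 0.1 steps, endpoints inclusive (41 values), and threshold
comparison is inclusive ($\mathrm{FE} \ge t$). No multiple-testing
correction is applied across the grid: the sweep selects a minimum, it
does not report the 41 $p$-values as discoveries.

# Peak processing conventions

Coordinates are 0-based half-open everywhere (BED convention), and
*overlap* always means at least one shared base pair, with no
reciprocal-fraction requirement — matching the default behaviour of the
standard interval-intersection tools. Other conventions that needed a
decision:

* **Effective summit.** The caller-reported summit offset when present;
  the interval midpoint $\lfloor(start+end)/2\rfloor$ otherwise.
* **QC filter.** Peaks with fold enrichment *strictly above* 50 are
  discarded ("above" is strict, so FE = 50 is retained), as are peaks
  with $q > 0.1$ and peaks touching a blacklist interval. Each rejection
  is logged with one reason, assessed in that order.
* **Closest TSS.** Unstranded absolute distance from the effective summit
  to the TSS. Upstream tools in this space disagree (some measure from
  peak centers, some from edges); we standardize on the summit. Ties go
  to the lexicographically smallest gene id, which makes the result
  independent of input order. The minus-strand TSS is the last covered
  base of the span ($end - 1$).
* **Genomic categories.** Genic placement (EXON, then INTRON) takes
  precedence over the upstream bins, because the categories are reported
  as disjoint slices of one composition; intergenic summits upstream of
  their closest TSS fall into PROXIMAL ($\le$ 2 kb), DISTAL (2–10 kb) or
  FIVE_D (10–100 kb); everything else — including summits downstream of
  the gene body — is OTHER.

# Motif scanning and classification

Known-motif scanning replaces de-novo discovery: a PWM library with
family labels (ETS, RUNX, IRF, ETS-IRF compound, other) is scanned over
peak sequences on both strands. Scoring is log-odds against a uniform
0.25 background with a pseudocount of 0.01 applied to the probabilities
at parse time; an N base contributes 0. A window is a hit when its score
reaches a fraction (default 0.8) of the matrix's maximal achievable
score — discovery tools use per-motif calibrated cutoffs they do not
print, so a fraction-of-maximum rule is the transparent, swappable
substitute. No GC correction is applied to the background; the bundled
matrices are sharp consensus-built PWMs (GGAA-core ETS, TGTGGT-core RUNX,
GAAA-repeat IRF, and an EICE-style GGAA+IRF compound) for which the 0.8
rule effectively demands a consensus match.

Peaks are then classified four ways by ETS/RUNX content (ETS_ONLY,
RUNX_ONLY, ETS_RUNX, NEITHER — a partition), with the ETS-IRF compound
flagged separately because its interest lies inside the NEITHER class.
The compound element is modelled as a single PWM; the alternative (two
half-site PWMs plus a spacing constraint) would add a geometry parameter
the analysis has no data to calibrate.

Group fold-enrichment comparisons use the classical pooled-variance
Student's t (Welch behind a flag), reporting medians and 5th/95th
percentiles for whisker plots; two degenerate equal groups give
$t = 0, p = 1$. The shuffle-based enrichment report (hit frequency
against mononucleotide shuffles, empirical $p$ with a +1 correction)
stands in for a discovery tool's ranking statistic; it defaults to 100
shuffles when called directly and is off in `run_all()` because the
classification pipeline does not consume it.

# Cross-set comparison and chromatin states

Overlap counts between peak sets are *per reference set*:
`count(X→Y)` is the number of X regions touching at least one Y region,
and is not symmetric — two abutting fragments in Y count once from X's
side, and region counts from each set's perspective genuinely differ.
The shared/specific partition for state analysis is defined against one
named reference set (shared = at least one overlap with it).

Chromatin-state assignment gives each peak the state with maximal
base-pair overlap across a 15-label segmentation; exact ties go to the
state covering the effective summit, and peaks touching no segment fall
back to Quies with a warning counter (segmentations tile the genome, so
the fallback should fire only on contig mismatches — which a
chromosome-name validation warning surfaces separately). Fractions are
reported per subset; no enrichment test is attached to the state
composition.

# The synthetic-data generator

Every pipeline input can be generated with planted ground truth, so the
whole analysis runs and is testable without downloads. The generator's
defaults are the study conditions the package targets:

* **Class priors** (0.30, 0.17, 0.15, 0.38 for ETS_ONLY, RUNX_ONLY,
  ETS_RUNX, NEITHER): the NEITHER share of 0.38 is anchored to the
  motif-free fraction reported in the source analysis; the remaining
  mass is split to keep ETS-containing peaks the plurality, as observed.
* **Fold enrichments** are lognormal per class, meanlog 1.7 for
  ETS-containing classes vs 1.35 for the others, sdlog 0.45 — medians
  near 5.5 vs 3.9, placing plenty of density around the decision region
  of the 3–7 grid while keeping essentially all mass below the QC cap of
  50. The gap plants the "ETS peaks are stronger" structure.
* **Expression coupling**: a gene whose best associated peak has
  FE $\ge t_0 = 4.5$ is modulated with probability 0.5, otherwise 0.01;
  modulated genes split up/down at 59:88. This is the change-point the
  calibration sweep is asked to recover.
* **Companion overlap fractions** 0.19 / 0.05 with 0.035 triple, the
  magnitudes of the cross-cell-line overlaps the comparison stage
  reports; companion private peaks are placed away from the primary set
  so the planted fractions are the ground truth.
* **Chromatin-state bias**: shared peaks' neighbourhoods relabeled
  TssAFlnk/Enh with probability 0.9; specific peaks stay on the Quies
  background with probability 0.8.
* **Motif planting** at exact consensus, Gaussian($0, 40$ bp) around the
  summit (a mutation-rate knob exists to stress the scanner); 15% of
  NEITHER peaks receive the ETS-IRF compound and 10% a lone IRF site, so
  the compound report has planted content to recover.

The synthetic genome is far more gene-dense than a mammalian genome
(3,000 genes of 2–20 kb on 6 Mb), which keeps the calibration universe
meaningful at desk scale but skews the genomic-category composition
heavily genic; the category logic is therefore exercised against sparse,
hand-built gene fixtures in the tests rather than against the generator's
default genome. Peaks are placed non-overlapping within chromosomes —
another deliberate departure from real data, where peak calls can abut or overlap — because
overlapping placements would let one peak's planted motif leak into a
neighbour and blur the truth table. One master seed fans out to fixed
per-stage child seeds, so any stage regenerates independently and every
file is byte-identical across runs.

What passing tests on this generator do **not** show: robustness to
degenerate motif instances (real binding sites diverge from consensus),
GC- or mappability-structured backgrounds, fragment-size artifacts,
overlapping gene annotations on real genomes, or calibration behaviour
when the expression coupling is weaker or graded rather than a clean
change-point. The generator emulates the shape of the inputs and the
planted relationships between them, not read-level noise.

# Problem sizes and numerical tolerances

The test suite exercises the oracle comparisons on random fixtures up to
2,000 intervals, the hypergeometric tail against direct pmf summation on
universes up to 200 (relative tolerance $10^{-10}$), threshold recovery
on 20 independent 2,000-peak simulations (success = selected threshold
within $\pm 0.3$ of the planted 4.5), and motif-class recovery on one
2,000-peak genome of three 2-Mb chromosomes. These sizes make the full
suite comfortably reproducible on a laptop while keeping the binomial
confidence intervals of the planted-fraction checks tight enough to be
meaningful. Where a fraction's sampling noise matters (class priors,
overlap fractions), tests assert within four binomial standard errors of
the planted value.

# Known limitations

* Exact peak-level reproduction of the source study's genome-wide counts
  is out of reach by construction: it requires the deposited raw data and
  external reference files, and the study did not state whether its TSS
  distances were summit- or edge-based nor how ties were broken. The
  package reproduces the *procedures* and verifies them on printed
  worked examples and planted synthetic truth.
* The Fisher table behind the study's printed $p$-value cannot be
  reconstructed unambiguously (background inclusion, sidedness); the
  package's table gives the same order of magnitude, and that is the
  level at which it is checked.
* Printed percentages in the source mix truncation and rounding; the
  package stores full precision and leaves display rounding to
  formatting.
* The scanner's fraction-of-maximum threshold is not a calibrated
  false-positive rate; for permissive matrices it admits more degenerate
  matches than a per-motif calibrated cutoff would.
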