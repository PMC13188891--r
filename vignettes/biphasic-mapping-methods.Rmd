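---
title: "Methods: biphasic backcross mapping, dominance and expression screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biphasic backcross mapping, dominance and expression screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biphasr)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, and the design decisions taken where the
methodology leaves room.

## The genetic model

All simulations run over a `genome_map`: chromosomes with a physical
length (bp), a genetic length (cM) and markers at regular spacing.
Individuals carry two phased haplotypes whose alleles record strain of
origin — `R` for the resistant strain, `S` for the susceptible or
knockout strain — plus a separately tracked ABCC2 background genotype
(`R1R1`/`R1S1`) and the identity of the causal marker of the secondary
resistance locus (R2).

Meiosis is sex-dependent, which is the whole point of the biphasic
design in Lepidoptera:

* **Females are achiasmatic.** Each gamete chromosome is an intact copy
  of one of the two parental homologs, chosen by a fair coin,
  independently across chromosomes. A female-informative backcross
  (`BC1_female_informative`: F1 female × knockout male) therefore
  segregates whole chromosomes, and a selected trait shows up as a
  chromosome-wide allele-frequency shift.
* **Males recombine.** Crossover counts per chromosome are Poisson with
  mean `genetic_length / 100` Morgans, positions uniform in genetic
  coordinates, no interference (the Haldane model). A male-informative
  backcross (`BC2_male_informative`) therefore produces the
  within-chromosome recombination gradient that fine mapping needs.

Backcross genotype expectations follow directly: at the causal marker
both mapping designs give S2S2 : S2R2 at 1:1, so the resistant allele
sits at frequency 0.25 in an unselected pool; complete selection against
S2S2 doubles it to 0.5 on the causal chromosome and leaves unlinked
chromosomes at 0.25. Those two numbers (0.25 and 0.5) are the
calibration points the test suite and the acceptance script verify.

**Genetic map defaults.** No genetic map is available for this system,
so every chromosome defaults to 50 cM — one expected crossover per
bivalent, a standard order-of-magnitude default — with uniform cM/bp
within a chromosome. Both are configurable; the 50 cM placeholder is a
deliberate, visible assumption, not an estimate. One visible
consequence: with 50 cM spread over a ~12 Mb chromosome, complete
selection leaves even distal markers strongly co-selected, so simulated
fine-map intervals are much wider than intervals obtained on real data
with sharper local recombination. The fine-mapping tests therefore check
*coverage* (the interval contains the causal site) and *gradient* (ΔAF
decays with distance), not a reproduction of any particular interval
width.

## Sequencing models

`simulate_pool_counts()` models pooled whole-genome sequencing: per
marker, site depth is Poisson(`mean_depth`), and the resistant-allele
depth is Binomial with success probability
`f(1 − e) + (1 − f)e`, where `f` is the true pool frequency and `e` a
symmetric per-read allele-flip error (default 0.001, a typical Illumina
substitution scale; at that size the AF bias is second-order). Pool
sizes default to the study design this package mirrors: 160 selected /
86 control larvae for the chromosome scan and 253 / 257 for fine
mapping.

`simulate_amplicon_counts()` models targeted deep sequencing: lognormal
read totals around `mean_reads` (default 38,000, the scale of a pooled
amplicon run on a desktop sequencer), and — with probability
`nonspecific_prob` — contamination by an off-target template fixed for
one allele at a Uniform(0.3, 0.9) fraction of reads. That contamination
mechanism is exactly what the control-pool AF filter in QC is designed
to catch: an unselected backcross pool should sit near AF 0.25, so a
control AF below 0.125 or above 0.5 marks the amplicon as nonspecific.

`simulate_expression_counts()` draws negative-binomial counts
(`size = 1/dispersion`) with strain-specific means
`base_mean × fold_change`. Dispersion 0.05 is a typical within-strain
biological variability for bulk RNA-seq of an inbred line.

**What the generator does not emulate.** Read alignment, variant-calling
artifacts, mapping bias, linked-marker LD decay from historical
recombination, GC/coverage waviness, batch effects in RNA-seq, and
larval ecology (development time, density) are all out of scope. Passing
tests therefore demonstrate that the analysis correctly inverts the
generative model stated above — not that it is robust to every artifact
of real pipelines upstream of the allele-depth tables it consumes.

## The BSA-seq scan

Per pool and chromosome, SNP allele frequencies are summarized by a
Gaussian-kernel density on the fixed grid [0, 1], step 0.005, with
Silverman's rule (`bw.nrd0`) as the default bandwidth — the defaults of
the common KDE plotting stacks, and overridable. Numerical choices:

* **AF filter boundaries.** "below 0.05 or above 0.95" are *removed*, so
  the boundaries themselves are retained (strict inequalities). The
  filter is idempotent and order-preserving, and both properties are
  tested.
* **Peak and ties.** The profile peak is the grid argmax; ties break
  toward the lower AF so the statistic is deterministic.
* **Degenerate input.** Zero-variance AF vectors make Silverman's
  bandwidth collapse; the default is to raise an error, with an opt-in
  jitter fallback (`jitter_if_degenerate = TRUE`, sd 1e-6) for
  point-mass inputs.
* **Shift statistic.** The linkage call uses the absolute difference of
  peak locations between selected and control profiles (threshold 0.1),
  mirroring the verbal peak-shift argument of chromosome-level BSA; a
  KS-style distance between the grid-integrated distributions is
  reported alongside as a diagnostic but does not drive the call. The
  call is invariant to chromosome order and robust to halving the
  marker set (tested).

A noise floor worth knowing: with a pool of `N` larvae, every marker on
an unlinked chromosome shares the same true frequency
`K / (2N)` with `K ~ Binomial(N, 1/2)`, so per-chromosome peaks scatter
around 0.25 with a standard deviation of about `0.25 / sqrt(N)`
(~0.02 at N = 160) *regardless of sequencing depth or marker count*.
Bands used in tests (peaks within [0.20, 0.30] on unlinked chromosomes)
are read against that pool-level sampling noise.

## Amplicon fine mapping

QC keeps amplicons with at least 500 reads in *both* pools and a
control AF inside [0.125, 0.5] (inclusive). The per-marker test for
selection-increased AF is a deliberate design decision — the
methodology this package implements names no specific statistic — and
is documented as such:

* one-sided two-proportion z-test with pooled variance (alternative:
  selected AF greater than control AF). At amplicon depths in the tens
  of thousands the normal approximation is excellent; the test suite
  pins it against an exact two-binomial enumeration oracle to within
  10% relative error for p in roughly [1e-4, 0.5] at totals ≥ 500;
* Benjamini–Hochberg adjustment across retained amplicons, alpha 0.01;
* an effect-size floor ΔAF ≥ 0.1, which prevents depth alone from
  making biologically negligible shifts significant.

The candidate interval spans the outermost significant SNP positions
(1-based inclusive internally; BED export converts to 0-based
half-open). Width is displayed as `round(width_bp / 1000)` kb. No
gap-bridging heuristic is applied: all significant markers on the
called chromosome define one spanning interval, and significant markers
with no significant neighbor are echoed in a warnings list rather than
silently dropped or silently included.

## Dominance estimation

Genotypes are called from diagnostic PCR fragment sizes (ABCC2:
102 bp resistant / 120 bp susceptible; APN1: 327 / 234). Segregation
against 1:1 uses the plain Pearson goodness-of-fit chi-square, df 1,
**without** Yates continuity correction: the uncorrected statistic
reproduces all four published two-decimal p-values (1.00, 0.43, 0.78,
0.01) from their count tables, while the corrected one does not — that
is the deciding evidence for the choice. The test suite also maps where
the uncorrected chi-square and the exact binomial test disagree at
alpha 0.05 (only where both p-values sit in the boundary band around
the threshold).

The dominance coefficient is `h = (w_RS − w_SS) / (w_RR − w_SS)`. The
count simplification `h = n_het / n_homR` is valid only when no
susceptible homozygote survives (`w_SS = 0`) and the two surviving
classes start at equal frequency; `estimate_h_counts()` documents that
precondition and the algebraic identity between the two estimators is
tested on a grid. Sampling noise can push the raw ratio past 1, so h is
clamped to [0, 1] with a warning, the raw value is retained, and
display rounding is two decimals, round-half-even. Background-dependent
dominance is a *parameter* of the simulator (heterozygote survival
differs by background); the package does not attempt to infer modifier
architecture.

## Expression screen

RPKM is `1e9 × count / (length × total_mapped)`. For locus-restricted
toy tables the per-sample total defaults to the column sum — a
documented divergence from genome-wide totals, which are simply not
derivable from a 37-gene table; an explicit `totals` argument overrides
it, and the demo fixes totals at 1e7 reads/sample so the detection
cutoff operates on a realistic scale. Detection is inclusive at mean
RPKM ≥ 0.5 in at least one strain. The strain comparison is a Welch
t-test on per-replicate RPKM values (safer than Student's under unequal
variance; the source methodology states only "t-test"), and candidates
must differ by at least 3-fold with per-gene p ≤ 0.01 — mirrored per
gene, without multiplicity correction, as in the original rule; a BH
column is appended for reference only.

## Problem sizes used by the test suite

Simulation scales were chosen once, as desk-scale analogues of the
study design: chromosome scans at 32 chromosomes × ~200 markers with
320 BC1 offspring (pools 160/86, depth 1000); fine mapping at the
48-amplicon panel geometry with 506 BC2 offspring (pools 253/257),
100 seeded repetitions for interval coverage; dominance consistency at
n = 2000 backcross offspring × 120 seeds per heterozygote-survival
level; expression calibration on 150 null tables of 20 genes. Million-
SNP genome scans and the observed (data-specific) quantities of real
experiments — e.g. a particular selected-pool peak location or an
observed interval width — are structural targets, not reproduction
targets, and are covered by the parameter-recovery analogues above.

## Known limitations

* The 50 cM uniform genetic map is a placeholder; real recombination
  landscapes will change fine-map interval widths (not coverage).
* The achiasmy model is absolute; rare female recombination would
  slightly blur chromosome-level peaks.
* The z-test assumes independent reads within a pool; PCR duplicates
  would overdisperse counts and make p-values anti-conservative. With
  the default QC depth floor and the ΔAF effect floor this mainly
  affects borderline markers.
* Expression screening inherits every caveat of RPKM-plus-t-test on
  n = 6: it is the original study's rule, not a recommendation over
  count-based differential-expression models.
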