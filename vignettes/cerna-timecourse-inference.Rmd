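---
title: "Methods: time-course ceRNA network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-course ceRNA network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAti)
```

ceRNAti infers a lncRNA–miRNA–mRNA competing-endogenous-RNA network
from a short patient time course sampled around a reperfusion event.
This vignette is the package's own account of the method: the model at
each stage, its assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical and design choices that were
genuinely open.

## Study design and data model

The pipeline expects one sample per (patient, time) pair, time in hours
with 0 the pre-reperfusion baseline (default design: 2 patients ×
{0, 2, 12, 24, 72} h), and non-negative FPKM-like abundances whose
units are treated as opaque. All correlation computations — sample QC,
co-expression adjacency, profile assignment, pair retention — operate
on `log(x + 1)`, a variance-stabilising transform that is defined at
zero and close to `log` for well-expressed genes. The coefficient of
variation alone is computed on the raw scale, where it is scale-free;
on log values it would not be.

Reperfusion exposure enters as a per-sample numeric trait. The default
encoding is binary (0 pre-intervention, 1 after), with `"hours"` and
`"log_hours"` selectable: with so few time points a monotone dose
interpretation is hard to defend, and the binary indicator makes
"correlated with injury exposure" mean "systematically different after
reperfusion", which is the interpretable claim at this design size.

## Stage 1 — variability screen

Per patient, `CV = s/x̄` with the sample (n−1) standard deviation over
that patient's time-ordered values. The retention rule is strict,
`CV > 0.6`; a gene sitting exactly at the threshold is dropped. Genes
with zero mean in a patient have no defined CV and are removed from
that patient's candidate list with a logged count. Retained genes are
split by biotype into DELs (lncRNAs) and DEMs (mRNAs) and intersected
across all patients; the screen is deliberately not a
differential-expression model — no distributional assumptions are made
beyond "interesting genes vary over the time course in every patient".

As QC, squared Pearson correlations between all sample pairs on the
log scale are reported; grossly discordant samples show up as low-R²
rows.

## Stage 2 — co-expression modules

The shared DEL+DEM set enters an unsigned weighted co-expression
analysis:

* adjacency `a_ij = |cor(x_i, x_j)|^β` (Pearson, log scale). The
  network is unsigned because both positively and negatively
  injury-correlated genes belong in one analysis; the direction is
  recovered later at the node level.
* β is scanned over 1..20 and the smallest value reaching a scale-free
  topology fit of R² ≥ 0.9 is selected. The fit index bins the
  connectivities `k_i = Σ_j a_ij` into 10 equal-width bins and
  correlates `log10(mean k)` with `log10(bin frequency)`. If no power
  reaches the target the maximiser is used and the scan is flagged —
  preferable to failing, since on heavily structured input (one
  dominant planted module) scale-freeness is genuinely absent.
* topological overlap
  `TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i, k_j) + 1 − a_ij)`,
  `TOM_ii = 1`, smooths the adjacency by shared neighbourhood.
* modules are branches of an average-linkage tree on `1 − TOM`, cut
  statically at height 0.95, keeping branches of ≥ 20 genes. This is a
  simplification of the dynamic-hybrid tree cut: the adaptive
  branch-splitting and PAM-like reassignment stages are deliberately
  not implemented, a documented limitation. On well-separated signal
  the static cut finds the same modules; on marginal structure it is
  more conservative.
* each module is summarised by its eigengene, the first right singular
  vector of the per-gene standardized member submatrix (unit norm).
  The sign is fixed by non-negative correlation with the mean member
  profile, falling back to the first member when that mean is
  numerically zero (two perfectly anti-correlated members) — without
  the convention, the sign of the module–trait correlation would be
  platform-dependent.
* module–trait association is the Pearson correlation of eigengene and
  trait with a two-sided p from the t distribution on n − 2 df.
  P-values are reported raw by default (single-module significance is
  what is interpreted downstream); a Benjamini–Hochberg option exists
  for users testing many modules.

## Stage 3 — time profiles

Integer model profiles of length T anchored at 0 with successive
differences bounded by c form the candidate family,
`(2c+1)^(T−1) − 1` of them after excluding the flat profile (80 for
T = 5, c = 1). Defaults c = 1 and m = 50 representatives follow common
short-time-series practice: with 5 time points, finer step resolution
is not identifiable. Representatives are chosen greedily to maximise
the minimum pairwise distance `1 − cor`, with lexicographic tie-breaks
— fully deterministic.

Each gene's series is its mean over patients of log abundance at each
time point, anchored by subtracting the 0 h value so profiles describe
change relative to the pre-reperfusion baseline. Genes go to the
best-correlated representative (ties to the lowest profile id;
zero-variance series excluded). Significance: each gene's time-point
order is permuted independently, series re-anchored and re-assigned;
a profile's p is `(#{null count ≥ observed} + 1)/(B + 1)` over B
permutations (default 1000). The add-one smoothing keeps p in (0, 1];
the permutation unit is the time axis, not gene labels, so the null
preserves each gene's value distribution while destroying temporal
order — exactly the structure the profiles claim to detect.

## Stage 4 — ceRNA assembly

Candidate lncRNA–mRNA pairs are an input file; the pipeline does not
attempt target prediction or cis-window computation. Among
trait-associated RNAs (below), a candidate pair is retained when its
Pearson `|r| ≥ 0.9` across all samples, both signs admitted with the
direction recorded. The default cutoff is deliberately strict: with 10
samples, the null tail `P(|r| ≥ 0.9)` is ~4·10⁻⁴, so retained pairs
are sparse and the candidate-to-retained reduction is drastic by
construction. The cutoff is a configuration knob, not an estimate.

A triplet (L, mi, M) exists when (L, M) is retained, (L, mi) is a
lncRNA–miRNA pair and (mi, M) a miRNA–mRNA pair; the network is the
union of the three typed edge sets restricted to triplet members.
miRNA expression is never required — targeting edges come from
databases, and the assembly is pure set intersection (tested against a
literal triple-loop oracle). Gene-centred submodules are induced by
all triplets containing a focus mRNA, and per-node summaries report
each measured node's mean time course, its trait-correlation sign and
its peak time point.

**Which RNAs are "trait-associated"?** Members of any module with
trait p < 0.05, united by default with genes assigned to a significant
time profile. The union is the default because the two stages detect
complementary signatures (covariation with exposure vs. coherent
temporal shape) and either is evidence of injury association; an
intersection flag exists for stricter runs, and the choice is recorded
in the run manifest.

## Stage 5 — enrichment

A plain offline hypergeometric upper tail per term,
`p = P(X ≥ k)`, X ~ Hypergeometric(N, K, n), against a user-supplied
GMT-like annotation map; BH q-values are always reported, but the
significance call uses raw p < 0.05, mirroring the single-threshold
convention of the online tools this replaces. The default universe is
the annotation's gene set (or the expression matrix's genes when
supplied); no ontology-graph propagation or EASE-style score
modification is attempted. Note the discreteness: with small networks
the test is conservative, and achievable p-values are a finite set.

## The synthetic-data generator

`generate_dataset(sim_config())` emulates the study design the
pipeline targets, and its defaults are the package's declared test
conditions: 2 patients × {0, 2, 12, 24, 72} h; 300 mRNAs, 100 lncRNAs,
50 miRNAs; one planted 30-gene module at trait correlation 0.8; 40
planted profile genes; 5 planted triplets; log-scale noise σ = 0.4;
baseline log-abundance N(2, 1); 200 random decoy pairs per edge type.

Construction is on the `log(1 + x)` scale — each gene's latent series
is baseline + planted signal + Gaussian noise, floored at 0 and mapped
through `expm1`. Because the pipeline correlates on `log(1 + x)`, the
latent scale and the analysis scale coincide wherever abundances are
positive, which keeps the noise-free calibration properties exact:

* the planted module's latent trajectory is
  `ρ·z(trait) + √(1−ρ²)·u` with `u` orthogonalised against the trait,
  so its sample correlation with the trait is exactly ρ, per dataset,
  not merely in expectation;
* planted profile genes follow integer templates scaled per gene, so
  with σ = 0 their anchored series correlate 1 with their template and
  nothing else;
* a planted triplet's lncRNA and mRNA share one identical latent
  series (trajectory and temporal noise), the idealised ceRNA
  signature. Planted-signal genes also sit 4 log-units above the
  background baseline so their latent series stays above the
  non-negativity floor.

What the generator does **not** emulate — and hence what passing tests
do not establish about real cohorts: library-size and composition
effects, count-level sampling noise, gene–gene correlation beyond the
planted structures, patient-level batch differences, miRNA expression
dynamics, sequence-level target plausibility, and realistic database
error rates in the pair files. The generator validates the machinery
(recovery, calibration, determinism), not the biology.

Triplet endpoints are planted inside the trait-correlated module, so
they are simultaneously co-expressed and trait-associated — the
configuration in which end-to-end recovery is well defined. Recovery is
always assessed conditionally on surviving the CV screen, which remains
a genuine stochastic attrition step (a triplet gene whose per-patient
trajectory happens to be flat is honestly lost).

## Numerical choices and degenerate inputs

* Constant genes are removed before any correlation (with a warning);
  zero-variance anchored series are excluded from profile assignment;
  zero-mean genes have undefined CV and are dropped per patient.
* The TOM computation symmetrises its output to remove floating-point
  drift; validation rejects asymmetric or out-of-range adjacencies.
* All tie-breaks are deterministic: lexicographic profile ids in
  representative selection and assignment, first-maximum in peak
  detection, first-member fallback in eigengene orientation.
* The permutation stream is governed by a single seed; two runs with
  identical configuration and seed produce byte-identical output
  directories (the manifest stores parameters, seed and input
  checksums, and no timestamps).
* Fewer than 10 shared genes skips the co-expression stage; an empty
  candidate set yields an empty network and a clean run, not an error.

## Validation problem sizes

The shipped tests and the acceptance script run at desk scale, chosen
to exercise every code path while keeping the suite fast: brute-force
TOM equivalence on 20 random 50-gene adjacencies; assembly equivalence
on 20 random typed pair sets; exhaustive hypergeometric enumeration for
all universes up to N = 12; exact permutation enumeration at T = 3 and
a 100-dataset flat-signal null at B = 200; a 10 000-replicate type-I
check of the module–trait test; and 20-seed recovery runs of the
default simulated design. Real studies are larger in genes but not in
samples; the n = 10 sample count, which dominates the statistics, is
the authentic design size.

## Known limitations

* The static tree cut can merge adjacent weak modules that the
  dynamic-hybrid algorithm would split.
* With two patients the cross-patient intersection is a weak
  replication filter; with one patient it degenerates to that
  patient's screen.
* Profile significance at T = 5 rests on 119 distinguishable time
  orderings per gene; p-values below ~1/120 per gene are unreachable,
  which the add-one smoothing makes explicit.
* The co-expression cutoff and the CV threshold are thresholds on
  noisy statistics; genes and pairs near either boundary flicker
  between runs of different cohorts, and no uncertainty is propagated
  across stages.
* Enrichment inherits every bias of the supplied annotation map.
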