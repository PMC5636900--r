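---
title: "Methods: linking PT neuron structure and function to subcortical targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking PT neuron structure and function to subcortical targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptarget)
```

## The scientific problem

Pyramidal tract neurons (PTs) are the thick-tufted pyramidal cells of
cortical layer 5B that carry the output of a cortical area to subcortical
stations. In rat vibrissal somatosensory cortex (vS1) the four major
targets are the posterior medial thalamus (POm), the superior colliculus
(SC), the pontine nuclei (Pons) and the spinal trigeminal subnucleus
caudalis (Sp5C). Individual PTs project largely to one of these, and
several cellular properties co-vary with the target: soma depth within
L5, the laminar distribution of dendrites, ongoing firing rate, and the
temporal profile of whisker-evoked responses.

`ptarget` implements the quantitative chain from raw measurements to
target prediction:

1. **Spike-train metrics** (ongoing rate, burst fractions, onset and
   sustained responses) and PSTHs from per-trial spike times.
2. **PSTH similarity indices** comparing each cell's normalized evoked
   PSTH with the four target-group templates.
3. **Laminar morphometry** from SWC reconstructions: per-layer path
   length, branch points, complexity and a 21-dimensional feature space.
4. **Soma-density profiling** of retrogradely labeled populations and
   per-column abundance estimates.
5. **A Mahalanobis-distance classifier** with chi-squared assignment
   confidences over configurable structure-function feature spaces.
6. **A synthetic-cohort generator**, calibrated to the published group
   statistics, that drives every stage so the whole pipeline runs and is
   tested without access to the original recordings.

## Spike-train metrics

Spike times are in milliseconds relative to stimulus onset; the standard
recording window is \[-200, 1100\] ms around a 700 ms air-puff whisker
deflection, with 20-30 stimulation trials per cell. All intervals are
half-open \[t, t + dt), so a spike at exactly 0 is evoked, not ongoing.

- *Ongoing rate*: trial-pooled rate in \[-200, 0) ms.
- *Burst fractions*: an ongoing spike is in a burst if it participates in
  an inter-spike interval at or below 10 ms (100 Hz) or 5 ms (200 Hz)
  within the same trial; reported as % of ongoing spikes. Bursts never
  span trials.
- *Onset response*: pooled rate in \[0, 100) ms minus the ongoing rate
  (elevation; negative values are reported as-is), and the fraction of
  trials with at least one onset-window spike. The 100 ms onset window is
  a configurable convention chosen to match the onset-response
  definition.
- *Sustained response*: pooled rate in \[100, 700) ms minus the ongoing
  rate. Reporting sustained activity as an elevation is what makes a
  "flat at baseline" group read as approximately 0 Hz.
- *PSTH*: counts pooled over trials in 5 ms bins (260 bins over the
  standard window), converted to Hz.

## PSTH similarity and the two indices

For each cell and each group-average PSTH: (1) the ongoing rate is
subtracted from every 5 ms bin and negative bins are set to zero; (2) the
result is divided by its maximal bin; (3) the bin-wise absolute
difference to the other normalized PSTH is (4) summed over the entire
recording period. This sum is the dissimilarity ("similarity value"):
zero for identical normalized PSTHs, and an L1 metric on the normalized
space (the tests assert the metric axioms on random triples).

The four per-cell values are combined into two indices,

$$\mathrm{SI1} = \frac{S_{\mathrm{Pons}} - S_{\mathrm{SC}}}{S_{\mathrm{SC}} + S_{\mathrm{Pons}}},
\qquad
\mathrm{SI2} = \frac{S_{\mathrm{Sp5C}} - S_{\mathrm{POm}}}{S_{\mathrm{POm}} + S_{\mathrm{Sp5C}}},$$

both in \[-1, 1\]. A 0/0 ratio is defined as 0 (neutral). Group templates
are built by averaging the raw PSTHs of all cells with the same label and
then normalizing (rather than averaging normalized per-cell PSTHs); when
a labeled cell is scored against its own group it is not excluded from
the template, matching the straightforward reading of the procedure — a
leave-one-out variant is easy to construct from the exported pieces but
is not the default.

## Laminar morphometry

Morphologies are rooted trees of typed nodes (soma, basal, apical) read
from standard 7-column SWC. One coordinate axis (default `y`) increases
with cortical depth, pia at 0; full 3D registration to a standardized
reference frame is out of scope — the depth-axis convention stands in
for it. The default layer scheme puts boundaries at 100, 600, 900, 1050,
1400 and 1850 um; only the L5A/L5B border at 1050 um is
study-specific, and every boundary is overridable.

Per layer, each edge's Euclidean length is apportioned by clipping its
linearly interpolated depth interval at the layer boundaries (validated
against a 0.1 um dense-sampling oracle); a branch point is any
non-soma node with at least two children (a trifurcation counts once),
assigned to the layer containing its depth; *complexity* is path length
times branch points, so it is zero in any layer without a bifurcation.

The feature space has 21 dimensions: soma depth; total/basal/apical path
length and branch points; per-layer (L1, L2/3, L4, L5A, L5B) path length
and branch points; maximal horizontal tuft extent; apical trunk length to
the main bifurcation; number of primary basal stems; maximal branch
order. The exact published feature list is not available, so this
registry is a documented stand-in and is pluggable (`features` argument
of `feature_vector()`). PCA of the z-scored feature matrix (constant
columns dropped; component signs fixed by making the largest-magnitude
loading positive) separates thick-tufted from slender-tufted
morphologies along PC1.

## Soma-density profiling

Somata marked per channel in serial 50 um slices are converted to 1D
depth profiles by counting in 50 um bins. Slices are aligned by the L4
peak of their all-neuron (NeuN) profile — integer-bin shifts to the
median peak bin, ties resolved toward the shallowest bin; a slice whose
NeuN maximum is not in L4 is excluded with a warning. The aligned
average NeuN profile is scaled to a reference profile in
neurons-per-average-column units by least squares,
$s = \sum p\,\mathrm{ref} / \sum p^2$, searched over integer shifts
(shift and scale are optimized jointly and both reported, since the
profile grids need not start at the same depth). Labeled-channel
profiles are scaled by the same factor; their scaled sum estimates
labeled cells per average barrel column. The packaged reference profile
is a synthetic construction (smooth layered density with an L4 peak,
~21,400 neurons per column) used for self-contained runs and recovery
tests; real-data users supply their own reference.

## Target classification

Cells are grouped into three clusters — POm, Sp5C, and merged SC+Pons
(SC- and Pons-projecting cells share depth, rate and similarity
characteristics) — and each cluster is summarized by its sample mean and
sample covariance. The distance of a cell to each cluster is the
Mahalanobis distance $d_i = \sqrt{(x-\mu_i)^\top C_i^{-1} (x-\mu_i)}$,
i.e. distance in units of the cluster's standard deviation. The cell is
assigned to the nearest cluster and the confidence is

$$P(k) = \frac{p_k}{\sum_i p_i}, \qquad p_i = 1 - F(d_i^2, \mathrm{DOF}),$$

with $F$ the chi-squared CDF and DOF the (shared) feature dimension:
$p_i$ is the probability of finding a cell at distance $d_i$ or farther
from cluster $i$ under its Gaussian model. The implementation is
verified against an independent incomplete-gamma oracle to 1e-8.

Numerical choices:

- *Ridge*: small clusters (3-5 cells) give singular covariances. We add
  1e-6 of each feature's own variance to its diagonal entry. A ridge
  proportional to the per-axis variance (rather than to the trace) keeps
  the Mahalanobis distance exactly invariant under affine rescaling of
  individual features, which the test suite asserts; axes with zero
  variance fall back to the mean positive variance.
- *Conditioning*: feature spaces mix micrometres, Hertz and
  dimensionless indices, so covariances can be numerically
  ill-conditioned while mathematically positive definite. Inversion is
  performed on the correlation scale
  ($C^{-1} = D^{-1/2} R^{-1} D^{-1/2}$).
- *Ties* resolve to the first cluster and are flagged; if every $p_i$
  underflows to zero the assigned cluster receives confidence 1, with a
  flag.
- *Standardization* before clustering is available behind a flag but off
  by default: with per-cluster Mahalanobis distances, global rescaling
  of a feature is immaterial.
- Dual-labeled cells never enter the cluster fit; they are classified as
  held-out queries and counted correct if assigned to either of their
  targets' clusters.

The scalar "dendritic property" axis of the combined 3D space is the
first principal component of the per-layer complexity 5-vector across
the cohort; the full 5-vector space is also available
(`dendrite_laminar`), with DOF adjusting accordingly.

A caveat worth stating: with leave-one-out evaluation on clusters of
3-4 cells, held-out cells are often far (in Mahalanobis units) from
*every* cluster; the normalized confidence $P(k)$ can then be high even
for a misassigned cell. Assignment confidence and assignment accuracy
are therefore reported separately by `evaluate_cohort()`.

## The synthetic-cohort generator

The generator emulates the statistical structure the analysis assumes,
calibrated to the published group statistics of identified PTs:

| group | depth (um) | ongoing (Hz) | onset (Hz) | onset prob | sustained (Hz) | envelope |
|-------|-----------|--------------|------------|------------|----------------|----------|
| POm   | 1042 ± 105 | 7.2 | 5.1 | 0.66 | 0.8 | flat at baseline |
| SC    | 1055 ± 97  | 1.3 | 1.7 | 0.23 | 2.3 | constant elevated |
| Pons  | 1131 ± 110 | 1.8 | 4.5 | 0.38 | 3.3 | decaying |
| Sp5C  | 1154 ± 98  | 4.3 | 6.9 | 0.64 | 3.3 | late ramp |

Functional group statistics are published as mean ± SE of groups of
five cells, so per-cell SDs are taken as SE x sqrt(5); depth SDs are
published directly. Design choices, and what they imply:

- **Truncation.** Depths and ongoing rates are Gaussian resampled until
  positive. Onset and sustained *elevations* are left Gaussian: they are
  differences, negative values occur in real cells, and truncating a
  distribution like N(0.8, 3.1) at zero would inflate the POm sustained
  mean to ~2.8 Hz and destroy the calibration. The instantaneous
  intensity is floored at zero instead. Onset probabilities are clipped
  to \[0, 1\].
- **Intensity model.** Spikes are an inhomogeneous Poisson process:
  ongoing rate before 0 and after 800 ms; ongoing + onset elevation on
  \[0, 100); ongoing + a shaped sustained envelope on \[100, 700); a
  linear return to baseline on \[700, 800), reflecting the observed
  ~100 ms decay after stimulus offset.
- **Envelope shapes** preserve the group's mean sustained elevation:
  flat-at-baseline and constant-elevated are constant at the mean (the
  POm mean is simply near zero); decaying falls linearly from 2x to 0;
  the late ramp is 0 before 500 ms and 3.0x the mean after (elevated for
  200 of the 600 ms, so the factor 3 is what preserves the mean).
- **Onset-probability calibration.** Under a pure Poisson model the
  per-trial onset probability is tied to the onset-window rate,
  $p_{\exp} = 1 - e^{-0.1 r}$. The published probabilities sit slightly
  below the Poisson expectation of the published rates, and per-cell
  rate dispersion pushes the expected probability further down (the link
  is concave). The generator therefore calibrates from both sides: when
  $p_{\exp}$ exceeds the cell's target probability, a trial's
  onset-window spikes are deleted with probability
  $1 - p/p_{\exp}$; when it falls short, a single uniformly timed onset
  spike is injected into spikeless trials with probability
  $(p - p_{\exp})/(1 - p_{\exp})$. Either way the realized per-trial
  probability equals the per-cell target in expectation, and the rate
  distortions of the two branches largely cancel at the cohort level.
- **Bursts.** Each ongoing-period spike is followed, with probability
  $q = b/(2-b)$ (so that the fraction of spikes in doublets matches the
  target burst fraction $b$), by a doublet spike at 1-5 ms (200 Hz
  bursts, with conditional probability $b_{200}/b_{100}$) or 5-10 ms;
  the base ongoing intensity is divided by $1+q$ so the total ongoing
  rate is preserved. Per-cell burst fractions are drawn with 50%
  relative SD, since only group-mean SEs are published.
- **Morphologies** are built to per-layer length/branch-point targets:
  a vertical apical trunk ascends to L1 (contributing its span to each
  layer), bifurcation nodes on the trunk carry horizontal side branches
  that absorb each layer's length remainder, layers with zero branch
  points absorb it in an unbranched out-and-back detour, basal stems
  spread the soma layer's share around the soma, and a descending basal
  cable serves layers below the soma. Lengths are met essentially
  exactly (well within the 5% tolerance the tests assert) and
  branch-point counts exactly. Per-cell variability multiplies both
  targets by a common size factor (Gaussian, mean 1, group-specific SD
  taken from the published total-length dispersions, floored at 0.45 —
  below that the jittered targets would fall under the trunk span a
  layer traversal geometrically requires). The shared factor reproduces
  the strong observed correlation between path length and branch
  counts. The per-layer targets themselves encode the qualitative
  laminar fingerprints: POm cells sparse in L5A, SC cells dense in L5A
  but sparse in L5B, Pons cells with the most extensive L1 tufts, Sp5C
  cells sparse in L4 — with group totals matching the published total
  lengths and branch-point counts.
- **Dual-labeled cells** are appended as extra cells (default 3 on top
  of the 5/5/5/4 single-labeled layout, mirroring the recorded sample).
  They inherit all generative parameters from their primary group — the
  second label is annotation — and POm/Sp5C pairings are excluded, as
  that overlap is essentially absent in the real population.
- **Soma fields** draw all-neuron somata from the reference depth
  profile and labeled somata from the group depth Gaussians, per slice,
  with a per-slice volume factor (mean 0.5, +-15%) and an integer-bin
  vertical jitter of up to +-2 bins (100 um); the configured per-column
  abundances (256/174/421/284 for POm/SC/Pons/Sp5C) are recorded as
  ground truth for recovery tests.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: non-Poisson spiking beyond injected doublets
(no refractoriness, no slow rate fluctuations or up/down states),
correlations between a cell's rate parameters, tortuous dendrite
geometry (straight segments and right-angle detours; realistic lengths
and branch counts but not realistic shapes), L6 dendrites, axons,
registration error along the depth axis, and tracer-efficiency or
double-labeling artefacts in the soma fields. Recovery of the
calibration by the pipeline validates the analysis code, not the
biology.

## Problem sizes and reproducibility

Every generator function takes a seed and is bit-reproducible; the
pipeline report bundle contains no timestamps, so reruns are
byte-identical (asserted by checksum in the tests). The test and
acceptance workloads use cohorts of 200 cells for single-group rate
recovery, 43 cells (11/11/11/10) for evoked-rate recovery over 50
replicates, and 100 replicate cohorts of 5/5/5/4 cells for the
leave-one-out classification surrogate — sizes chosen to put sampling
error well inside the tolerances being asserted while keeping a full run
in the low minutes on one core.

## Known limitations

- The 21-feature registry is a stand-in for the unavailable published
  list; swapping in the true list is a one-argument change.
- The depth-axis convention replaces full curvilinear registration;
  depths are only as meaningful as the user's registration.
- The classifier's confidence is a within-model quantity; with very
  small clusters it should be read together with accuracy (see caveat
  above).
- Statistical hypothesis tests reported alongside the original analyses
  (t-tests, ANOVA, correlations) are standard and left to base R on the
  exported tables rather than re-implemented.
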