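---
title: "Methods behind nicheshift: models, parameters and the synthetic tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind nicheshift: models, parameters and the synthetic tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicheshift)
```

nicheshift analyzes imaging-based single-cell spatial transcriptomics of
the CosMx kind: rectangular fields of view (FOVs, 985 × 657 µm, ≈ 0.65
mm²) containing segmented cells with polygon boundaries, a ~1000-plex
count matrix at roughly 100 transcripts per cell, and negative-control
probes. The motivating application is bone-marrow biopsies from acute
myeloid leukemia patients before and after immune-checkpoint-inhibitor
therapy, where the question is how the composition and signaling of the
leukemia-cell neighborhood changes with treatment and clinical response.
This vignette documents the statistical models, every consequential
parameter choice, and the limits of the synthetic tissue generator used
for validation.

## Edge-to-edge distance geometry

All distances are minimum distances between cell *boundaries*, not
centroids. Marrow cells are tightly packed and vary in size, so centroid
distance systematically overstates separation for large cells; the
centroid distance is always at least the edge distance. The kernel is an
exact segment-to-segment minimum over the two polygon boundaries (with
overlap/containment detected and reported as distance 0), with
bounding-box pruning and a distance cutoff — we never need distances
beyond 45 µm, the largest ring radius, which keeps the all-pairs pass per
FOV near-linear in practice.

## Ring-neighborhood counts and the Poisson GLMM

Around every index (leukemia) cell we count neighbors of each type in
five half-open distance rings [0, 5), [5, 15), [15, 25), [25, 35),
[35, 45) µm. 5 µm is roughly half a cell diameter (touching neighbors);
45 µm ≈ 3 cell diameters is where local niche structure dissipates.
Boundary values go to the upper ring, and distances ≥ 45 µm are dropped;
each neighbor is counted in exactly one ring.

For one neighbor type the count in ring $r$ of index cell $i$ in FOV $f$
is modeled as

$$
y_{ifr} \sim \mathrm{Pois}(\mu_{ifr}), \quad
\log \mu_{ifr} = \log N_{ifr} + x_{ifr}^\top\beta + u_f, \quad
u_f \sim N(0, \sigma^2),
$$

where $N_{ifr}$ is the ring total (all neighbors in the ring, the offset:
we model neighborhood *composition*, not density), and the fixed effects
are the full three-way interaction response × timepoint × ring with
treatment coding (reference: nonresponder, timepoint A, ring 0). The FOV
random intercept absorbs section- and FOV-level abundance differences;
FOVs are the replicates. Rings with $N_{ifr} = 0$ are dropped (the
conditional likelihood is empty).

Two contrasts are reported as rate ratios with Wald confidence intervals:
post- vs pre-treatment within responders
($\mathtt{timepointB} + \mathtt{responder{:}timepointB}$, plus the ring
interactions for rings > 0) and responder vs nonresponder at baseline.
Bonferroni multiplicity uses $m$ = number of cell types × number of
contrast types.

Numerical choices: `lme4::glmer` with `nAGQ = 0` (penalized quasi-
likelihood-style joint optimization). Across seeds the median recovered
rate ratio is identical to the Laplace fit while ~16× faster; the package
exposes `nAGQ` for users who want the slower fit. Derivative-based
convergence checks are disabled (`calc.derivs = FALSE`) for speed;
convergence is still reported and non-converged fits refuse to emit
contrasts.

A calibration caveat measured during validation: with few FOVs the Wald
tests are anti-conservative in the far tail (with only 3 FOVs per
response × timepoint group, the family-wise error of a Bonferroni-guarded
28-test family was ~0.39 instead of ≤ 0.05; with 20 FOVs per group it is
~0.07). This is the usual few-clusters behavior of Wald inference with an
estimated random-effect variance. Plan for tens of FOVs per group, and
treat borderline adjusted p-values with few FOVs skeptically. A useful
computational identity: index cells within a FOV share all covariates, so
summing counts and ring totals over index cells within FOV × ring leaves
the likelihood unchanged and fits much faster.

## Density-shift test

For a query cell type and one patient, pool over each timepoint's FOVs
the minimum edge distance from every query cell to its nearest leukemia
cell. Each sample's distribution is estimated with a Gaussian kernel
density (rule-of-thumb `nrd0` bandwidth) on a fixed grid of 512 points
over [0, 45] µm, and the observed shift is the difference of the two
curves, $S = \hat f_A - \hat f_B$. The null distribution is built by
drawing, per FOV and per permutation (J = 100), the same number of
pseudo-query cells from that FOV's non-leukemia cells (without
replacement) at *both* timepoints — this removes the query labels while
preserving each FOV's geometry and sample sizes. Grid points where
$|S - \bar S_{\mathrm{perm}}| > \mathrm{SD}_{\mathrm{perm}}$ are flagged.

A 1-SD band is deliberately permissive (≈ 32% pointwise under a normal
null, and KDE curves are strongly autocorrelated across the grid), so the
flag pattern is read as a *descriptive* localization of where the two
distance distributions differ, not as a familywise-calibrated test; on
null synthetic tissue the flag rate is typically 15–50%. The package's
positive control plants the effect directly: the closest (or furthest)
non-leukemia neighbor of each leukemia cell is relabeled to the query
type at one timepoint, which produces a flagged, correctly signed deficit
below 5 µm essentially always.

## Proximity-stratified ligand-receptor analysis

Within one patient-timepoint sample, non-leukemia cells are "close"
(≤ 5 µm, touching range) or "far" (≥ 30 µm, beyond direct-contact
signaling) from the nearest leukemia cell; both thresholds inclusive,
the in-between excluded. Anchor genes must be leukemia-high — per-FOV,
the leukemia per-type median exceeds the mean of the other types'
medians by > 2 SD of those medians — in at least half of the sample's
FOVs (persistence guards against single-FOV artifacts). For each
anchor's partner gene and each non-leukemia cell type, per-FOV
pseudo-bulk means (plain averages of raw counts, which stabilize
~0.1–2-count genes) are compared close vs far with the exact
Mann-Whitney U test, FOVs as replicates; at least 2 FOVs per group are
required, and Benjamini-Hochberg adjustment is applied within sample ×
direction. The shipped 25-pair table includes the TNFSF12→TNFRSF12A
(TWEAK) axis used throughout the examples.

## Cell typing

Reference cells are cells whose counts hit marker genes of exactly one
type; per-type reference profiles are the mean count vectors over all
genes; background $b$ is the mean negative-probe count. A cell's
likelihood under type $t$ scales the profile to the cell's depth
($s = \text{total}/\sum_g \lambda_{gt}$) and uses independent Poissons
with rate $s\lambda_{gt} + b$; the posterior over types (uniform prior)
is normalized by log-sum-exp, and zero-count cells are flagged and left
uniform. Round 2 reruns the identical machinery on round-1 T/B
lymphocytes with subtype markers (CD4/CD8/naive/cytotoxic, B subsets);
non-lymphocytes are never relabeled. An external size check reports the
fraction of cells above 648 µm² (20,000 pixels at 0.18 µm/px) labeled
megakaryocyte, the one anomalously large marrow type.

## Segmentation mask evaluation and merging

Instance masks are integer label matrices (0 = background). Matching is
greedy one-to-one by descending IOU (ties broken by lower label), and a
match counts as TP at IOU ≥ 0.7; F1 = TP/(TP + (FP + FN)/2). The
nuclear/membrane merge adopts a membrane cell for each nucleus whose
majority (> 50%) of pixels it contains; nuclei without a membrane are
dilated by a Euclidean radius (default 3 µm) with nearest-nucleus-wins
clipping, and membranes containing multiple nuclei are reported.

## The synthetic tissue generator, and its limits

Cells are grown from a jittered hexagonal grid; polygons are the Voronoi
cells (computed by half-plane clipping) trimmed to a 16-gon of radius
0.9 × spacing, giving a confluent, marrow-like packing in which the
median cell touches ≥ 3 neighbors. Types are assigned from a
configurable mixture (default: 25% leukemia blasts, erythroid and
myeloid compartments, T/B/DC minorities). Planted structure:

- *Proximity enrichment* places an exact near/far allocation of the
  target type so that the realized near-vs-far rate ratio equals the
  requested multiplier (weighted sampling saturates in confluent tissue
  and undershoots).
- *LR signal* multiplies a gene's Poisson mean by a fold in cells of a
  type within 5 µm of leukemia.
- *Density-shift control* relabels each leukemia cell's closest/furthest
  neighbor.

Expression is independent Poisson per gene with per-type profiles
(markers ≈ 6, background genes ≈ 2, cross-type leak 0.05, giving ~100
median counts/cell); negative probes are Poisson(0.05). Known realism
limits: no overdispersion or gene-gene correlation, no segmentation
error or transcript spillover between touching cells, no cell-size
variation by type (so megakaryocyte-style size validation needs
dedicated fixtures), uniform cell density, and types placed
independently except for the planted structure. These omissions are
intentional — every validation has an analytically known truth.

Typical validated problem sizes on one CPU: 1000-cell FOV generated in
~0.5 s; all-pairs ring distances for a 500-cell FOV in ~0.04 s; a
12,000-row GLMM fit in ~2 s (nAGQ = 0); a full two-patient,
two-timepoint pipeline with J = 100 permutations in well under a minute.

## Worked example

```{r example, eval = FALSE}
cfg <- tissue_config(n_patients = 2, timepoints = c("A", "B"),
                     fovs_per_sample = 3, n_cells_per_fov = 500, seed = 1)
tissue <- simulate_tissue(cfg)
res <- run_pipeline(tissue, out_dir = "out",
                    density_query = "T_CD8", lr_pairs = read_lr_pairs(),
                    J = 100, seed = 1)
print(res)
head(res$enrichment)
```
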