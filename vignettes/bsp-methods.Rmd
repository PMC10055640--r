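---
title: "The big-small patch statistic: model, simulators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The big-small patch statistic: model, simulators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bspsvg)
```

## The problem

Spatially resolved transcriptomics (SRT) measures expression of N genes
at M spots — barcoded capture locations or segmented cells — whose 2D or
3D coordinates are known. A spatially variable gene (SVG) is one whose
expression varies systematically with position rather than randomly
across spots. Kernel-regression detectors (SpatialDE, SPARK) fit a
spatial covariance model per gene; `bspsvg` instead implements the
big-small patch (BSP) statistic, a non-parametric test that needs no
model of the spatial covariance and works identically in 2D and 3D.

## The statistic

The intuition: average a gene over small neighborhoods and over large
neighborhoods. For a gene with no spatial structure, averaging over more
spots shrinks the variance of the local averages roughly like 1/n, so
the coarse-grained variance collapses relative to the fine-grained one.
For a gene with a coherent spatial pattern wider than the small
neighborhood, coarse averaging preserves the pattern and the variance
ratio stays large.

Concretely, after normalization (below), for each spot $i$ and radius
$D$ the patch $S_i$ collects the spots within Euclidean distance $D$,
and the local mean of gene $j$ is

$$\hat X_i(j) = \frac{1}{|S_i|}\sum_{l \in S_i} X_l(j).$$

With $\sigma_D(j) = \mathrm{var}_i\,\hat X_i(j)$ the variance of local
means over all M spots, the BSP score of gene $j$ is

$$r(j) = w_j\,\frac{\sigma_{D_2}(j)}{\sigma_{D_1}(j)},
\qquad w_j = \frac{\sigma_j^2}{\max_k \sigma_k^2},$$

where $D_1 < D_2$ are the small and big radii and $\sigma_j^2$ is the
variance of the gene's normalized expression over spots. The weight
$w_j$ damps genes whose variance ratio is large only because they barely
vary at all.

### Normalizations

* **Expression** is min-max scaled to $[0,1]$ per gene, so all genes
  contribute on one scale. A constant gene maps to all zeros; it gets
  weight 0, score 0, $p = 1$.
* **Coordinates** are multiplied by $(M/\Delta X \Delta Y)^{1/2}$ in 2D
  or $(M/\Delta X \Delta Y \Delta Z)^{1/3}$ in 3D, where the $\Delta$'s
  are the axis-aligned bounding-box ranges. This puts the typical
  spot-to-spot spacing near 1 unit regardless of the input scale, so a
  single pair of default radii works for any platform. The
  transformation is equivariant: feeding coordinates in micrometers or
  millimeters gives identical normalized geometry. If one dimension has
  zero range (a single section passed as 3D) it is dropped from the
  density estimate with a warning, since the volume would be zero.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `d1` | 1 | normalized spacing | small radius; captures nearest neighbors |
| `d2` | 3 | normalized spacing | big radius; sets the pattern scale probed |
| `alpha` | 0.05 | — | significance level for SVG calls |
| `null_augmentation_threshold` | 1000 | genes | below this, fit the null on permuted genes |
| `null_pool_size` | 10000 | genes | permuted-null pool size when augmenting |
| `include_center` | `TRUE` | — | patch convention (see below) |

Raising `d2` probes broader structures; it should stay well below the
sample diameter, since a radius covering the whole sample makes every
patch identical and all $\sigma_{D_2}$ exactly zero.

### The patch convention

Whether a spot belongs to its own patch is a genuine design choice. The
package defaults to including it (`include_center = TRUE`, the behavior
of a KD-tree ball query), because the statistic's analytic anchor — a
radius covering the whole sample gives every gene $\sigma_D = 0$
*exactly*, since all patches then contain all spots and share one mean —
holds only under that convention. Excluding the center turns
full-coverage patches into leave-one-out means with a small positive
variance of order $\sigma_j^2/(M-1)^2$. The strict neighbor-only variant
remains available via the flag; under it, a spot with no neighbor inside
the radius keeps its own value as its local mean, the limit of a patch
shrinking onto its center.

### Null model and p-values

Scores across genes are treated as draws from a common null
distribution. They are nonnegative and unbounded, so they are mapped
into $(0,1)$ by dividing by $\max_j r(j) \cdot (1 + 10^{-9})$ — the
inflation keeps the top score strictly inside the support, so its
p-value is finite — and a two-parameter beta is fitted by maximum
likelihood (`fitdistrplus::fitdist`), with a method-of-moments start.
The p-value of a gene is the upper-tail probability of the fitted beta
at its rescaled score, hence non-increasing in the score. Zero scores
are excluded from the fit and assigned $p = 1$ directly.

With enough genes (≥ `null_augmentation_threshold`, default 1000) the
fit uses the observed scores themselves: true SVGs are assumed a small
minority, and on a pure-null panel of 10,000 genes the empirical rate of
$p < 0.05$ lands at $0.05 \pm 0.02$ (checked in the test suite). For
small targeted panels (tens of genes, e.g. image-based platforms) the
observed score distribution is neither null-dominated nor large enough
for a stable tail fit, so permuted null genes — each a random
permutation of a real gene's values across spots — are generated until
`null_pool_size` null scores exist, and the beta is fitted on those
alone. Real scores beyond the null pool's range are clamped to the top
of the support and reported as $p = 0$: they exceed everything the null
can produce. Raw p-values drive the default SVG calls; Benjamini-
Hochberg adjusted values are always reported in `p_adjusted` and can
drive the calls via `use_adjusted = TRUE`.

### Moran's I baseline

`morans_i()` provides the classical autocorrelation baseline
$$I = \frac{M}{S_0}\,\frac{\sum_{il} w_{il}(x_i-\bar x)(x_l-\bar x)}
{\sum_i (x_i-\bar x)^2},$$
with binary radius, k-nearest-neighbor, or inverse-distance weights.
P-values come from random permutations of values over spots (999 by
default, one-sided for positive autocorrelation), with the analytic
normal approximation under the randomization assumption behind a flag.
The benchmark helper uses k-nearest weights (k = 6) rather than radius
weights: under a Poisson point pattern some spots have no neighbor
within the small radius, which the radius scheme treats as an error.

## The simulators

Both simulators produce a labeled `simulated_replicate` so power can be
measured against known truth.

**2D** (`simulate_replicate_2d`): 260 spots uniform in the unit square;
a pattern region (one hotspot, two hotspots, or a band) sized to mark
20% of spots; 1000 SVGs with log-intensity
$\log(\mathrm{base}) + \log(FC)\cdot\mathbf{1}[\text{marked}] + \varepsilon$,
$\varepsilon \sim N(0, \tau^2)$, observed as Poisson counts of the
exponentiated intensity; and 9000 nulls, 9 spot-permutations of each
SVG. Defaults $FC = 4$, $\tau = 0.5$ are the benchmark's moderate
signal/noise point ($FC \in \{3,4,5\}$, $\tau \in \{0.2,0.5,0.8\}$ span
the grid). The generative law is a standard log-normal-intensity
Poisson emulation of count data; `base_intensity = 10` gives realistic
spot-level counts. The original benchmark drew its region geometry from
curated olfactory-bulb patterns on real spot positions; the parametric
regions here match the marked fraction but not the exact shapes, and
real coordinates plus masks can be supplied through the same functions.

**3D** (`simulate_replicate_3d`): 10 stacked sections of 225 cells
each, uniform in a 15 × 15 window with the section index as z. The
window side of 15 makes the cell density 1 per unit volume, so the raw
simulation units are already ≈ normalized units and the sphere radii
$r \in \{1.5, 2, 2.5\}$ are measured in typical cell spacings. The
pattern is the union of spheres around a random walk with exact step
length 2; sign constraints on the step directions give a curved stick
(monotone in x and z), a thin plate (monotone in z), or an irregular
lump (unconstrained). Marked cells draw their expression from the upper
$q$-quantile tail of a reference pool, unmarked cells from the full
pool; $q \in \{0.66, 0.80, 0.88\}$ corresponds to fold changes
$\{2, 2.5, 3\}$ for the original empirical pool, and `fc = ...` solves
the truncated-mean equation for whatever pool is configured. Each SVG
spawns 9 spot-permuted nulls from the noiseless values; Gaussian noise
with SD $\sigma_{\text{mult}}$ times the mean per-gene SD is added to
the whole matrix last, so SVGs and nulls carry identical noise.

Unstated details settled here (exposed in `sim3d_config`): walk length
10 steps (at $r = 2$ the pattern marks ~10% of the 2250 cells, a clear
minority); unconstrained axes start at the window center and redraw
out-of-window steps, monotone axes start at their lower bound and run
free so sticks and plates traverse the sample; one walk per replicate
shared by all SVGs, as one tissue structure drives many genes (per-gene
walks behind `shared_pattern = FALSE`); the default pool is
log-normal(0, 1) standing in for an empirical single-cell expression
distribution — any numeric vector of real measurements can replace it.

What the simulations do *not* emulate: real platform count depth and
dropout, the curated region shapes, section-registration artifacts, and
correlated gene modules. Passing benchmarks here shows the statistic
separates patterned from permuted genes under these generative laws,
not that it handles every artifact of real tissue.

## Power evaluation

`power_at_fdr()` ranks genes by p-value and, for each FDR budget,
reports the best true-positive rate over ranking prefixes whose
*realized* FDR (from ground truth) stays within budget — the standard
benchmark construction; an estimated-FDR analysis on real data can use
`p_adjusted` instead. Tied p-values enter the ranking as one block so
curves do not depend on storage order. `compare_power_3d()` wraps
simulation, both methods and curve averaging; at the moderate 3D
setting (pattern I, r = 2, FC = 2.5, noise 1) BSP's averaged power at
FDR ≤ 0.05 exceeds the Moran baseline's, reproducing the qualitative
ordering the statistic was designed for.

## Numerical choices

* $\sigma_D$ and $\sigma_j^2$ use the population variance (divide by
  M). The ratio in the score is invariant to the divisor; fixing it
  only pins the reported intermediate values.
* Patch membership uses strict inequality $\mathrm{dist} < D$; ties at
  exactly $D$ are excluded.
* Weights are computed on the min-max-normalized expression, so
  weights and local-mean variances live on the same $[0,1]^2$ scale.
* $\sigma_{D_1} = 0$ (constant gene, or geometry where even small
  patches cover everything) scores 0 with $p = 1$ rather than dividing
  by zero: such genes cannot be spatially variable.
* Distances are computed blockwise from the squared-norm expansion;
  results match a naive all-pairs scan to machine precision, verified
  against a brute-force oracle at M ≤ 200.
* Every stochastic step (simulators, permutation nulls, Moran
  permutations) takes an explicit integer seed and restores the
  caller's RNG state; fixed seeds give byte-identical replicates.

The test suite runs its heavy checks at deliberately modest sizes —
calibration on 10,000 permuted genes over 260 spots, power comparison
on 5 replicates of 100 SVGs + 900 nulls with 499 Moran permutations —
chosen so the full suite completes in about two minutes while keeping
Monte-Carlo error well inside the asserted tolerances.

## Limitations

* The beta fit on observed scores assumes SVGs are a minority; panels
  dominated by true spatial structure inflate the null and cost power
  (the permuted-null path avoids this at extra compute).
* BSP detects patterns at scales between `d1` and roughly `d2`;
  structure much finer than the spot spacing, or global gradients
  aligned with density variation, may be missed or diluted.
* P-values of 0 can occur when real scores exceed the permuted-null
  pool's range; downstream consumers should treat them as "below
  resolution", not as exact zeros.
* No count-depth normalization, batch correction, or covariate
  adjustment is performed; apply platform-appropriate preprocessing
  before `run_bsp()` if library sizes vary strongly across spots.
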