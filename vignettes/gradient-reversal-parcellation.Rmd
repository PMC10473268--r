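---
title: "Parcellation by gradient reversals: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parcellation by gradient reversals: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
assumptions it leans on, and where the design was genuinely open — and
why we decided each open point the way we did.

## The model

The data are a directed, nonnegative voxel-to-voxel connection-strength
matrix `C` and a many-to-one projection of voxels onto a 2D pixel grid
(the *flat view*). The working hypothesis is topographic: connectivity
varies along smooth spatial gradients within a region, and a region
border is a *reversal* — a fold — of such a gradient, not a jump in
connectivity values. Two voxels with nearly identical embedding
coordinates can therefore belong to different regions if a reversal
separates them; this is what distinguishes the approach from similarity
clustering, which assumes within-region homogeneity.

Diffusion embedding turns `C` into coordinates: profiles (the
concatenation of each voxel's outgoing row and incoming column) are
sum-normalized, their Gram matrix is symmetrically normalized by its
row sums (the Fokker–Planck / anisotropy-0.5 convention), and the
eigenvectors of the resulting operator — scaled by their eigenvalues,
stationary vector dropped, signs fixed by making each component's
largest-magnitude entry positive — are the components. Because the
operator is a symmetric positive semidefinite Gram-derived matrix, a
dense symmetric eigendecomposition is exact and deterministic; we do not
use iterative sparse solvers at the problem sizes treated here.

Assumptions worth stating explicitly:

* the flat view loses little: the spread of component values across the
  voxels of one pixel should be small against the spread across a
  region (`withinPixelSpreadRatio()` measures exactly this);
* gradients are context-dependent: a trend spanning the whole volume may
  vanish when a subregion is embedded alone, and new local trends
  appear. The recursion therefore re-embeds every region in isolation
  (within-region connectivity only), and all quality metrics are
  evaluated in that isolated context;
* borders thinner than roughly three pixels cannot be resolved, because
  both the border-detection kernel and the finite-difference stencil
  integrate over that scale.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 20 | components retained per embedding |
| `t`, `alpha` | 1, 0.5 | diffusion time; anisotropy normalization |
| `kernelWidth` | 5 px | FWHM of the border-map Gaussian (and of field pre-smoothing) |
| `threshold` | 0.97 | convolved-length border criterion (strict `<`) |
| `kMin`, `kMax` | 2, 10 | Ward cluster-count search range |
| `minClusterSize` | max(10, 1% of pixels) | HDBSCAN floor, suppresses speckle |
| `minSize` | 10 px | smallest surviving region (post-merge) |
| `minVoxels` | `3 * k` | smallest region still embedded |
| `gdThreshold`, `riThreshold` | 30°, 0.4 | diagnostic acceptance flags on leaves |

The acceptance thresholds deserve a comment: they *flag* leaves in the
hierarchy (`accepted` column) but do not stop the recursion. We tried
threshold-based stopping and removed it: a region whose two strongest
gradients are clean can still contain a genuine connectivity-block
border that only weaker components reveal (the node-distance toy model
below is the canonical example), so stopping on the two-component
criterion forfeits recoverable structure. Recursion stops when a
splitter proposes nothing, when a proposal fails the improvement rule,
or when the region falls under the size floors.

`minVoxels = 3 * k` is a numerical precondition, not a tuning knob: an
embedding of a region with barely more voxels than requested components
is spectrally degenerate, and its harmonic-dominated components
manufacture spurious reversals.

## Numerical choices

**Gradient pre-smoothing.** Flattened components are convolved with the
same width-5 Gaussian before central differences are taken. Normalized
gradients divide by the local gradient magnitude, so wherever a field is
shallow, per-pixel noise rotates the unit vectors freely; without
smoothing the convolved-length criterion saturates (every pixel looks
like a border) at any nonzero noise level, and the pair-counting metrics
sit at their random baselines (`ri ≈ 1`, `gd ≈ 45°`) for every region,
which would make failure undetectable. Smoothing at the border kernel's
own width restores the intended contrast without introducing a second
scale. The masked convolution renormalizes kernel mass over valid
pixels, so region edges do not artificially shorten vectors; the same
masking keeps pixels outside the current region out of every stencil.

**Border map and distances.** Kernel truncated at 3σ; border flags are
strict (`length < 0.97`); the pixel graph uses 8-neighborhood edges of
weight 1 if either endpoint is border, 0 otherwise; all-pairs distances
by Dijkstra (zero-weight edges are legal), infinite distances from
disconnected parts are replaced by a large finite surrogate before Ward
linkage. Ward is `hclust(method = "ward.D2")` on the precomputed
distances; the silhouette score is computed on the same distances, and
ties in both the silhouette and the component selection resolve to the
smaller cluster count / lower component index.

**Component selection and the improvement rule.** Each component's
candidate split is post-processed first and then scored by the mean
per-subregion reversal index of that component's own gradient;
reversal-free components (no border anywhere) propose nothing and are
not eligible — scored literally, such a component's zero would always
win and no region would ever split. The winning split must also
*improve*: its score must fall below the whole-region reversal index of
the same component (for the cosine splitter, the strength-weighted index
over all components). A region in which no component's reversals can be
reduced by cutting is atomic.

**HDBSCAN.** Implemented in-package on the precomputed distance matrix
(core distances → mutual reachability → single-linkage tree → condensed
tree); cluster extraction defaults to the *leaf* rule (finest stable
granularity). The excess-of-mass rule is available but returns the
coarsest level of a nested hierarchy, which discards exactly the
granularity a single application is expected to deliver; with the leaf
rule a nested model is recovered in one pass and the recursion's job is
only to confirm. Points the tree rejects keep label 0 and are
reassigned by the SVM extrapolation step.

**Degenerate inputs.** Disconnected voxels (zero profile rows) are
removed with a warning before embedding; all-zero distance matrices and
all-border or borderless regions return "no split"; a region whose
bounding box is smaller than the kernel in both directions warns and
reports no border; zero-length gradients are undefined entries, never
division errors; merging never eliminates a region with no neighbor.

## The toy models

The generators build connectomes in a voxelized unit cube whose first
grid axis (depth) is projected out by the flat map; they are the
package's ground-truth test surface, not biology.

* `reversingHierarchyModel()` — `levels` counts hierarchy levels
  including the root, so the default 3 gives two orthogonal binary
  splits: four quadrant leaves. Per split generation, the target value
  `alpha` is a triangle wave along the split axis (continuous, spanning
  [0, 1], reversing slope at every internal border) and `beta` the
  orthogonal flat coordinate; strengths are
  `exp(-S² / (2σ²))` of the Euclidean target distance with
  `σ = 0.1 · max(S)`, and the per-generation matrices multiply
  elementwise. The squared-exponent (Gaussian) kernel is a deliberate
  choice: the linear-exponent alternative yields an essentially flat
  eigenvalue spectrum (a near-disconnected similarity graph), which
  nullifies the strength weights of the cosine splitter; the Gaussian
  kernel reproduces the expected decay (20th component at a few percent
  of the first).
* `nodeDistanceModel()` — only the deepest generation's matrix is
  built (noise included), and each entry is then divided by the
  hierarchy-tree path distance between its two regions (within-region
  pairs divide by 1, a literal 0 being undefined). The division applies
  to signal and noise alike. This model's upper split is a connectivity
  *block* border with no gradient reversal in the two strongest
  components — the stress test for the stopping discussion above.
* `randomSplitModel()` — recursive splits of the flat view at random
  lines (first angle uniform on [0, 2π), later angles within ±0.5 rad
  of the previous split's angle plus 90°, placement between 40/60 and
  60/40 by area). Each line mirrors its region: a source point connects
  to targets near its mirror image with strength
  `Π(L)·exp(-d/ρ(L)) + 1`, `Π = 1/max(4-L, 1)`, `ρ = 25·e^{-L/3}`, `L`
  the 1-based split level; contributions over the source's ancestor
  lines are summed and the matrix symmetrized.

**Noise.** `addNoise()` adds i.i.d. uniform `(-φ, φ)` noise per entry
and clamps at zero; since the noise-free hierarchy-model signal has
maximum 1, `φ` reads as an amplitude relative to the signal. Noise
enters where each model's strength matrix is defined — before the
node-distance division and per level before the reversing-hierarchy
multiplication — so it is shaped by the same operations as the signal.

What the models do *not* emulate: realistic network topology, laminar
structure, distance-dependent connection probability, measurement-point
spread, or any anatomical prior. Passing these tests shows that the
machinery detects the reversals it was built to detect and resists the
stated noise; it does not certify performance on real connectomes.

## Study conditions used by the tests and the acceptance script

Chosen once, as the package's study conditions:

* node-distance experiments: `levels = 3`, grid 16×16 with depth 4
  (1024 voxels), `φ ∈ {0.1, 5}`;
* reversing-hierarchy experiments: grid 32×32 with depth 2. At 16
  pixels the deepest-level bands would be 4 px wide — at or below the
  ~3-pixel resolution limit once a 5-px kernel is applied — so the
  flat extent is doubled instead;
* random-split experiments: grid 24×24 with depth 2, at most 8 regions
  of at least 50 pixels, `φ = 0.5`, three instances, schedule
  "reversal detection until convergence, then cosine clustering".

## Known limitations

* **Harmonics.** In isolated regions whose second connectivity trend is
  weaker than the first harmonic of the strongest trend, the second
  component is that harmonic: its gradient is parallel to the first
  (`gd` near 90°) and reverses mid-region (`ri ≈ 0.5`) even for a
  perfectly recovered region. The quality metrics therefore flag such
  regions as non-atomic although no finer ground truth exists; the
  worked example in the README shows the effect on recovered quadrants.
* **Partial granularity per application.** The component-selection rule
  prefers the cleanest split, which for nested structure is often a
  correct but coarse cut; full granularity arrives over successive
  applications rather than in one.
* **Border placement accuracy.** Pre-smoothing, the border-band width,
  and SVM reassignment each displace borders by a pixel or two; on the
  random-split model the recovered partitions also over-fragment
  relative to the planted one (correct borders plus extra cuts), which
  inflates the mean gradient deviation of the leaves.
* **Scale.** Dense eigendecompositions bound practical problem sizes to
  a few thousand voxels per embedding; applying the pipeline to a
  full-cortex connectome would require an iterative eigensolver behind
  `diffusionEmbed()`.
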