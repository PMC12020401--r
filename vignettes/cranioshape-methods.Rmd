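---
title: "Methods: region-disentangled latent shape analysis and the regional outcome metric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-disentangled latent shape analysis and the regional outcome metric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Objective assessment of craniofacial surgery asks two questions: *how much*
did an operation change the shape of each anatomic subunit (orbits, nose,
upper lip, midface, ...), and *was that change in the right direction* —
toward the shape statistics of a healthy reference population? cranioshape
answers both on triangle head meshes in dense point correspondence with a
shared template: every mesh has the same vertex count and triangulation, so
vertex *i* means the same anatomical point on every head. Correspondence is
assumed to be established upstream (by nonrigid registration tooling); this
package validates it topologically and never computes it.

The pipeline is: synthesize (or load) corresponded mesh populations →
augment by spectral interpolation → encode each mesh into a
region-disentangled latent vector → fit per-class Gaussians in latent space
→ classify (QDA) and visualize (LDA) → score each pre/post-operative pair
with the regional outcome metric.

## The latent representation

Each mesh is encoded into a 75-dimensional latent vector partitioned into
R = 15 subsets of width d = 5, one per anatomic region, so that subset
`z_r` controls region *r* and little else ("disentanglement"). The
reference architecture for this idea is a swap-disentangled variational
mesh autoencoder trained at scale; re-implementing it faithfully is neither
possible from the information available nor needed for the contracts this
package tests. Instead the package trains a *structurally* disentangled
model at toy scale:

* per-region **linear** encoder/decoder pairs act on their region's
  centered vertex block; the R codes concatenate into the latent;
* the posterior is a diagonal Gaussian whose **mean** is used at inference,
  so encoding is deterministic;
* training minimizes reconstruction error plus a small unit-Gaussian prior
  divergence (weight `beta = 1e-3`, entering the code update as a ridge)
  by exact alternating least squares — one exact code update and one exact
  decoder update per epoch — so the loss is non-increasing by construction
  and training is CPU-trivial and exactly reproducible from its seed;
* the swap-consistency idea survives as a *monitored* penalty: each epoch
  the latents of mesh hybrids built by `region_swap()` are compared with
  the composite of their parents' latents. With per-region maps this
  penalty is near zero by construction (the architecture enforces what the
  original model learns), which is exactly the simplification the package
  is designed around. It is reported in the training log, with weight
  `gamma = 1` in the logged total, but not optimized.

Because regions tile the vertex set, decoding is exactly local: perturbing
subset `z_r` moves only region-*r* vertices. Encoding of region-swapped
hybrids leaks a little across subsets through the 2-ring boundary blend;
the tested contract is that off-subset leakage stays below 20% of the total
difference for same-class pairs.

## Distances, classification, visualization

Per class *c* and per region *r* the package fits Gaussian models
(mean `mu_c^r`, covariance `Sigma_c^r`) with ridge regularization
`Sigma + eps * tr(Sigma)/p * I` (default `eps = 1e-6`, escalated tenfold
and recorded whenever the result is not positive definite; the trace scale
falls back to 1 for zero-variance degenerate classes).

The working distance is the Mahalanobis distance under the **healthy**
covariance,

    dM(z1, z2) = sqrt( (z1 - z2)' inv(Sigma_H^r) (z1 - z2) ),

which is calibrated in standard deviations of the healthy distribution:
`dM = 1` means one healthy SD apart. (The source formula's typography shows
the covariance without inverse or square root; only the standard form above
is consistent with that calibration, so it is what the package implements.)

Diagnosis uses quadratic discriminant analysis on the fitted class
Gaussians with uniform priors by default — augmented class sizes reflect
augmentation policy, not prevalence. Ties in the arg-max are broken by
class-name order. Manifold visualization uses linear discriminant analysis
to project the 75-dimensional latents (or a 5-wide regional subset) to 2D:
exactly 2 axes for 3 or more classes, one axis padded with a declared zero
second axis for 2 classes. LDA is *only* for visualization; the outcome
metric is never computed in the projected space. Pre/post-operative points
are projected with the frozen transform, never refit.

## The regional outcome metric

For a patient with preoperative and postoperative regional latents
`z_pre^r`, `z_post^r`, the metric is

    m_r = [ dM(z_pre^r, z_post^r) / max(dM(z_post^r, mu_H^r), eps) ]
          * <s_hat_r, v_hat_H^r>

with `s_hat_r` the unit direction (versor) of the surgical movement and
`v_hat_H^r` the versor from the preoperative point toward the healthy mean.
Three interpretation choices are deliberate and recorded:

* **Ratio, not product.** The typography of the source expression is
  ambiguous; the ratio is the only reading under which large values mean a
  large movement *ending close to* the healthy center. The product form
  remains available (`form = "product"`) for comparison.
* **Whitened geometry.** Versors and the inner product are computed in the
  healthy-whitened regional space (`w = Sigma^-1/2 (z - mu)`), so
  directions and distances share one geometry and every ingredient of
  `m_r` is invariant under a common invertible linear reparametrization of
  latents and covariances (a tested property).
* **Degeneracies are flagged, not fatal.** Zero movement gives `m_r = 0`
  with a `no_movement` flag; a postoperative point at the healthy mean
  floors the denominator at `eps = 1e-6` SD with a `denominator_floored`
  flag; a preoperative point already at the healthy mean flags the null
  healthy versor.

On a noise-free simulated surgery that moves a region along the ideal ray
with completeness `alpha`, the metric is exactly
`alpha / (1 - alpha)`: zero at no change, 1 when the distance to the
healthy mean is halved, unbounded as the region lands on the mean, negative
for adverse movements. This closed form is what the acceptance tests check
end to end through the autoencoder.

## The synthetic world

No mesh cohort is distributed with the package; the generator *is* the
stated world, and its defaults are fixed:

* **Template** — an icosphere subdivided 4 times (2562 vertices; tests use
  2–3 subdivisions, i.e. 162/642 vertices, to stay fast), scaled
  anisotropically to head proportions (half-axes 75 x 95 x 88 mm) with an
  18 mm smooth face-side protrusion, partitioned into 15 contiguous regions
  by geodesic growing from fixed anchor directions.
* **Classes** — healthy (zero offset by convention) plus two syndromic
  classes with fixed smooth offset fields of 10 mm RMS confined to their
  designated regions (midface-dominant for synA, fronto-orbital for synB),
  against 1 mm of smooth individual variation. The 10:1 effect size is a
  deliberately strong, clearly separable signature.
* **Smooth fields** — linear combinations of 16 low-order polynomial
  harmonics of the template directions. Class signatures use the full
  basis; *individual* variation uses only the degree-<= 1 sub-basis
  (12 degrees of freedom). That choice is structural: within-class
  covariances must be estimable from cohorts of ~30 subjects, so the
  within-class intrinsic dimension is kept below the smallest class size.
  Real craniofacial variation is far richer; consequences below.
* **Region confinement** — offsets and surgical moves are masked by a
  2-ring boundary blend with per-ring decay 1/5, which keeps >= 90% of a
  class signature's squared norm inside its designated regions (a tested
  generator contract) while avoiding tearing at region borders.
* **Surgery** — on the target regions, vertices move by `alpha` times the
  difference to the healthy mean (toward mode), its negation (away mode),
  or a random smooth field of matched norm, plus optional smooth noise;
  `alpha > 1` models deliberate overcorrection. The ground truth is
  recorded on the subject.
* **Augmentation** — same-class pairs are blended in the truncated
  eigenbasis of the template's uniform (combinatorial) graph Laplacian,
  `k = 128` by default, `lambda ~ Uniform(0.2, 0.8)`. The combinatorial
  Laplacian is used (rather than cotangent or degree-normalized variants)
  so the null space is the constant vector on any connected mesh. The
  out-of-basis residual is blended with the same weight, preserving the
  endpoint identities at any `k` — which also makes the interpolation
  algebraically a vertex-wise convex combination; it is implemented through
  the spectral path so the basis, truncation and band-energy behavior are
  exercised and testable.

**What a green test establishes — and what it does not.** The synthetic
world validates the machinery: the metric's calibration and closed form,
disentanglement locality, classification of cohorts whose class signatures
dwarf individual variation. It does not emulate age structure, sex,
growth, registration error, or high-rank individual variation. One visible
artifact: syndromic offsets lie partly in directions where the healthy
class has almost no variance, so *global* Mahalanobis distances of
syndromic subjects are enormous (thousands of SD) under the ridge-floored
healthy covariance. Regional distances, which drive `m_r`, are
well-conditioned; global distances should be read only comparatively
(pre vs post).

## Numerical choices

* Covariance ridge `eps = 1e-6` (relative to `tr/p`), auto-escalated;
  whitening via symmetric eigendecomposition square root with eigenvalues
  clamped at 1e-12.
* Denominator floor of `m_r`: 1e-6 SD.
* Mesh I/O: ASCII PLY and OBJ, coordinates at 9 significant digits
  (lossless round trip at 1e-6 mm); the region partition travels as a
  sidecar CSV (`vertex_index, region_id, region_name`), 0-based vertex
  indices, 1-based region ids.
* Eigenvector and discriminant-axis signs are fixed (largest-magnitude
  entry positive) for bitwise reproducibility; every generator is a pure
  function of its spec including the seed.
* Displacement heatmaps clip at 10 mm for color; raw values are always
  retained.

## Interface notes

The package is an analysis library: the module that would be a shell tool
in a service deployment is fulfilled by `run_pipeline()` plus the plotting
functions, with a thin wrapper at `inst/scripts/run_pipeline.R` for
command-line use. All stage outputs (latents, confusion, outcomes,
summaries, arrows) are plain CSV/JSON, and every figure is regenerable from
those exports alone.

## Known limitations

* The autoencoder is linear; it cannot represent curvature of the shape
  manifold, and its reconstruction floor is the per-region rank-5
  approximation error of the individual-variation fields (about 10% of
  population shape deviation under the defaults).
* Whether the original work computed versors in raw or whitened latent
  coordinates is not determinable; the whitened choice is the package's
  own, made for geometric consistency.
* Healthy-class augmentation is supported but off by default; whether the
  healthy covariance should be fitted on originals only is likewise a
  config choice (`classes` argument of `augment_population()`), defaulting
  to originals only.
* Geodesic (curved) latent trajectories between the preoperative point and
  the healthy mean are out of scope; the metric is defined on straight
  whitened-space rays.
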