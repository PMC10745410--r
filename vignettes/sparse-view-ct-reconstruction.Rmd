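---
title: "Sparse-view CT reconstruction with adaptive four-direction TV"
author: "fdtvct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-view CT reconstruction with adaptive four-direction TV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdtvct)
```

## The problem

X-ray computed tomography reconstructs a 2-D attenuation map $F \in
\mathbb{R}^N$ from line-integral measurements $P \in \mathbb{R}^M$ through
the discrete imaging model $P = WF$, where $W = \{w_{ij}\}$ holds the
intersection length of ray $i$ with pixel $j$.  In *sparse-view* CT the
number of view angles is reduced far below the classical sampling
requirement (here: 30--90 views over 180° instead of several hundred), so
$M \ll N$ and the system is severely ill-posed: unregularized algebraic
reconstruction produces streak artifacts and noise.

The package implements a projection-onto-convex-sets (POCS) plus
total-variation (TV) minimization scheme for this regime,

$$F^* = \arg\min \|F\|_{TV} \quad \text{s.t.} \quad P = WF,\; F \ge 0,$$

solved by alternating a data-fidelity stage (SART sweeps followed by a
non-negativity projection) with steepest-descent minimization of the TV
term.  Its two distinctive ingredients are a **four-direction TV
functional** and **data-driven control of both iteration parameters**
(the SART relaxation and the TV step size).

## The projector

`buildSystemMatrix()` assembles $W$ by incremental Siddon-style grid
traversal of zero-width rays:

* **Geometry.** Parallel beam; view angles $k \cdot
  \mathrm{span}/n_\mathrm{views}$, $k = 0, \dots, n_\mathrm{views}-1$.  The
  image grid is centred on the rotation centre; angle 0 sends rays along the
  $+x$ (column) direction, and $y$ runs along rows.
* **Detector.** A linear array perpendicular to the rays, centred on the
  rotation centre.  By default its bins span the image *diagonal*
  ($\sqrt2\,n_\mathrm{cols}$ pixels), so every pixel is intersected at every
  angle; the spacing is configurable for sensitivity studies.  Edge bins can
  miss the square grid at near-axis-aligned angles; such all-zero rows are
  flagged (`zeroRays()`) and skipped by the solvers.
* **Weights.** Exact intersection lengths in physical units; a ray passing
  exactly through a pixel corner contributes nothing (segments shorter than
  $10^{-12}$ are dropped).  Each row of $W$ therefore sums to the chord
  length of the ray through the grid, and no entry exceeds
  $\sqrt2 \times$ pixel size -- both are enforced by the class validity
  check and verified against closed-form line--box clipping in the tests.

$W$ is stored once as the sparse transpose (`Matrix::dgCMatrix` of
$W^\top$): its compressed-column slots are exactly the compressed-row
layout of $W$ that the C++ SART kernel consumes, and `Matrix` handles the
forward/back projections (`forwardProject()`, `backProject()`), which are
adjoint to $10^{-10}$ relative precision by construction.

## The four-direction TV functional

For pixel $(i,j)$ with backward differences $d_v = f_{i,j}-f_{i-1,j}$,
$d_h = f_{i,j}-f_{i,j-1}$ and the two backward diagonal differences
$d_{d1} = f_{i,j}-f_{i-1,j-1}$, $d_{d2} = f_{i,j}-f_{i-1,j+1}$,

$$\mu_{i,j} = \sqrt{\frac{d_v^2 + d_h^2 + d_{d1}^2 + d_{d2}^2}{2\Delta^2}
  + \varepsilon^2}, \qquad \|F\|_{TV} = \sum_{i,j} \mu_{i,j}.$$

Out-of-range neighbour differences are zero (the common replicate-boundary
convention, applied identically in value and gradient).  $\Delta$ is the
sampling interval (default 1 pixel) and $\varepsilon = 10^{-8}$ keeps the
steepest-descent denominators finite; the functional is bounded below by
$nm\varepsilon$ and is exactly invariant under constant shifts.

Two gradient forms are provided:

* `form = "analytic"` (default): the exact gradient of the functional
  above, including the diagonal terms -- every $\mu$ in which a pixel
  participates contributes.  This is the form the descent method needs:
  the package verifies it against central finite differences of the
  functional to $10^{-5}$ relative error, so the TV stage provably descends
  the stated objective.
* `form = "printed"`: a literal five-point horizontal/vertical stencil
  divided by the four-direction magnitudes, kept for comparison because
  variants of this shorthand circulate in the literature.  It is *not* the
  gradient of the functional (it omits the diagonal coupling), which is why
  it is not the default.

The conventional two-direction TV (`tv2Value()`/`tv2Gradient()`, used by
the SART-TV baseline) keeps only $d_v, d_h$ under the same
$1/(2\Delta^2)$ normalisation, so the four-direction functional dominates
it by construction.  The global scale of either functional is irrelevant to
reconstruction because descent steps use the normalised gradient
$G/\|G\|_2$.  Note one asymmetry worth knowing: both diagonal differences
look toward row $i{-}1$, so the stencil is not symmetric under image
transposition -- a vertical and a horizontal edge of equal strength do not
give identical TV values.

## The solver

`reconstruct()` runs, from $F^{(0)} = 0$, up to $K_\mathrm{iter}$ outer
iterations (default 200) of:

1. **POCS stage.** One SART sweep over all views in ascending angle order.
   For view $\phi$ with relaxation $\lambda_\phi$, all pixels are updated
   simultaneously from the rays of that view:
   $$f_j \leftarrow f_j + \lambda_\phi\,
     \frac{\sum_{p_i \in P_\phi} \frac{p_i - \sum_n w_{in} f_n}
     {\sum_n w_{in}}\, w_{ij}}{\sum_{p_i \in P_\phi} w_{ij}}.$$
   Zero-sum rays are skipped; pixels unseen by a view are untouched.  After
   the full sweep, negative pixels are set to zero (the non-negativity
   projection; a per-view variant is available via `nonneg = "view"`, the
   difference is negligible and per-sweep is the default).
2. **TV stage.** $N_{TV}$ (default 20) steepest-descent steps
   $F \leftarrow F - \eta\, G/\|G\|_2$ on the chosen TV functional.  The
   gradient is normalised once by its global L2 norm; steps with
   $\|G\| < 10^{-15}$ are skipped.
3. **Stopping.** $res = \frac1N \|F^{(k)} - F^{(k-1)}\|_2 <
   \varepsilon_0 = 10^{-12}$ ends the loop early.

Because the TV stage runs after the in-loop positivity step, the final
iterate can carry $\mathcal{O}(10^{-3})$ negative excursions; the returned
image receives one last projection onto the non-negative set, while the
iterates themselves follow the pseudo-code exactly.

### Adaptive parameter control

* **Per-view relaxation** (`adaptiveRelaxation()`):
  $\lambda_\phi = \exp(-\sum_{p_i \in P_\phi} p_i / \sum_i p_i) \in (0,1]$.
  Each view's relaxation shrinks with the share of the total projection
  mass it carries, so sparser samplings (larger per-view share) get smaller
  steps -- the damping that sparse-view reconstruction needs.  The ratio of
  *sums* is used; with equal ray counts per view a ratio of means would
  exceed one and break the $(0,1]$ range.  The vector depends only on the
  sinogram and is computed once per run.  (For an all-zero sinogram the
  ratio is undefined; `adaptiveRelaxation()` raises an error, and
  `reconstruct()` substitutes $\lambda = 1$, under which the zero image is
  already the fixed point.)
* **Adaptive TV step** (`adaptiveStep()`): with $\Delta d(k) =
  \|F_{SART}^{(k)} - F^{(k-1)}\|_2$ the image change produced by the POCS
  stage,
  $$\eta_k = \Delta d(1)\, \frac{\Delta d(k)}{\sum_{j=1}^{k} \Delta d(j)}.$$
  The cumulative sum runs over iterations $1..k$: this gives
  $\eta_1 = \Delta d(1)$, $\eta_k \le \Delta d(1)$ always, and $\eta_k \to
  0$ as the POCS updates stabilise -- exactly the "start large, decay"
  schedule steepest-descent TV needs, with no user parameter.

The five algorithm presets (`reconConfig()`) combine these pieces: plain
`SART` ($\lambda$ fixed, no TV), `SART_TV` and `SART_FDTV` (fixed $\lambda
= 0.5$, fixed $\eta = 0.3$, two- resp. four-direction TV), the adaptive
method `ADAPTIVE_FDTV` (both controls adaptive, four-direction TV), and the
classical `ASD_POCS` baseline, which instead shrinks its TV step by a
multiplicative factor whenever the TV-induced change exceeds a fraction of
the POCS-induced change (controls `beta = 1`, `betaRed = 0.995`, `ng = 20`,
`alpha = 0.2`, `alphaRed = 0.95`, `rMax = 0.95`, the values published with
that method).  Everything is deterministic: no RNG exists anywhere in the
solver path, and identical inputs reproduce results bit-for-bit.

## Quality metrics

* `psnr()`: $10\log_{10}(\mathrm{peak}^2/\mathrm{MSE})$ in dB.  The peak is
  taken from the *reference* image by default (standard practice); a
  `peak = "test"` variant mirrors formulations that use the reconstruction
  maximum.  Identical images return `Inf`.
* `ssim()`: default is the standard windowed index (11×11 Gaussian window,
  $\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$, dynamic range from the
  reference), averaging the local map over the full image as MATLAB does;
  `crop = TRUE` instead drops the 5-pixel filter border, which reproduces
  scikit-image's implementation exactly and is used as the oracle in the
  tests.  A `mode = "global"` variant evaluates a single whole-image index
  from means and standard deviations only; it omits the cross-covariance,
  cannot detect sign-flipped structure (the tests demonstrate this on
  anti-correlated checkerboards), and exists for literal comparisons.
* `rmse()`: plain root-mean-square error; `qualityReport()` bundles all
  three.

## Simulating the benchmark data

`runExperiment()` reproduces the digital-phantom protocol: 256×256 modified
Shepp--Logan ground truth, 512 detectors, 30/60/90 equispaced views over
180°, all five algorithms, $K_\mathrm{iter} = 200$, $N_{TV} = 20$,
$\lambda = 0.5$ / $\eta = 0.3$ for the fixed-parameter baselines (the
shipped `table1.yaml`).

The one genuinely consequential design choice is **how the sinogram is
simulated**.  Multiplying the rasterized phantom by the same $W$ used for
reconstruction (an "inverse crime") makes the data exactly consistent with
the discrete model: TV reconstructions then become nearly perfect
(&gt; 40 dB at 30 views) and plain SART *improves* monotonically with more
views -- behaviour that published sparse-view benchmarks on this phantom do
not show.  The package therefore simulates phantom data **analytically**
(`phantomSinogram()`): the line integral of each ellipse has the closed
form $2ab\sqrt{\alpha^2 - s^2}/\alpha^2$ with $\alpha^2 = a^2\sin^2\gamma +
b^2\cos^2\gamma$, and the sinogram is their sum.  The small residual
inconsistency between exact integrals and the pixel-grid projector (about
2% relative at 256²) then plays the role measurement imperfections play in
real scans: SART exhibits its characteristic semiconvergence (error decays,
then artifacts build up as more views force a tighter fit to inconsistent
data), and the TV methods settle at a discretization-limited plateau.  The
matrix-based simulator remains available (`sinogram: matrix` in configs)
and is what the solver property tests use, because on consistent data exact
statements hold (monotone residual decrease, RMSE convergence).

What the generator does **not** emulate: photon (Poisson) noise, detector
aperture/blur, scatter, polychromatic physics, fan/cone geometry.  Passing
benchmarks on these data therefore demonstrates correct algorithm
behaviour under sparse sampling and model mismatch, not clinical
performance.  Absolute quality indices on this benchmark depend strongly on
the simulator's mismatch level (and on the SSIM variant); relative
comparisons between algorithms under identical data are the meaningful
output.

## Numerical choices, in one place

| Quantity | Value | Where |
|---|---|---|
| TV guard $\varepsilon$ | $10^{-8}$ | `tvConfig()` |
| Sampling interval $\Delta$ | 1 pixel | `tvConfig()` |
| Stopping tolerance $\varepsilon_0$ | $10^{-12}$ (per-pixel L2) | `reconConfig()` |
| Gradient-norm skip threshold | $10^{-15}$ | `tvDescent()` |
| Dropped traversal segments | $< 10^{-12}$ (corner grazing) | projector |
| Outer / inner iterations | 200 / 20 | `reconConfig()` |
| Fixed $\lambda$, fixed $\eta$ | 0.5, 0.3 | baselines |
| SSIM window | 11×11 Gaussian, $\sigma=1.5$ | `ssim()` |

The test suite exercises grids from 16² to 64² for solver properties and
the full 256² protocol for the benchmark checks; the 64²/128-detector
preset (`table1_small.yaml`) runs the whole pipeline in seconds and is the
recommended starting point.

## Known limitations

* 2-D parallel beam only; no fan/cone geometries and no noise model.
* The per-view relaxation depends only on projection mass, so for equal-mass
  views it is a single number $\exp(-1/n_\mathrm{views})$ close to 1; its
  damping effect is mild at moderate view counts.
* The adaptive step schedule decays like $1/k$ once the POCS changes
  plateau; with strongly inconsistent data the late TV stages are weak, and
  residual streaks from the last SART sweep can survive in the final image.
* The printed-form TV gradient is provided for comparison but does not
  descend the four-direction functional; do not combine it with convergence
  arguments.
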