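# fdtvct

Sparse-view X-ray CT reconstruction in R: SART/POCS iterative
reconstruction regularized by an **adaptive four-direction total-variation
(FDTV)** scheme, with a sparse parallel-beam projector, analytic
Shepp–Logan phantoms, PSNR/SSIM/RMSE evaluation and a config-driven
benchmark runner.

## The problem and who this is for

Reducing the number of CT view angles lowers radiation dose and scan time,
but makes the reconstruction problem `P = W F` severely ill-posed
(`M ≪ N`): algebraic methods like SART produce streaks and noise.
Total-variation regularization recovers piecewise-constant images from few
views, but conventional TV differentiates only horizontally and
vertically, blurring edges as views get scarce, and its iteration
parameters (SART relaxation λ, TV step η) traditionally need manual
tuning.  This package is for researchers and students of iterative
tomographic reconstruction who want a complete, deterministic,
desk-scale implementation of the adaptive scheme and its baselines.

## The method

The constrained problem `min ‖F‖_TV s.t. P = WF, F ≥ 0` is solved by
alternating:

1. **POCS stage** — one SART sweep per outer iteration (simultaneous
   per-view pixel updates weighted by ray–pixel intersection lengths),
   followed by a non-negativity projection.  The per-view relaxation is set
   from the data: `λ_φ = exp(−Σ_{i∈P_φ} p_i / Σ_i p_i) ∈ (0, 1]`, so each
   view is damped according to its share of the projection mass.
2. **TV stage** — `N_TV = 20` steepest-descent steps `F ← F − η G/‖G‖₂` on
   the four-direction TV functional with per-pixel magnitude
   `μ_ij = sqrt[(d_v² + d_h² + d_d1² + d_d2²)/(2Δ²) + ε²]`
   (vertical, horizontal and both diagonal backward differences).  The step
   is tied to the image change `Δd(k) = ‖F_SART^(k) − F^(k−1)‖₂` produced
   by the POCS stage: `η_k = Δd(1) · Δd(k) / Σ_{j≤k} Δd(j)`, which starts
   at `Δd(1)` and decays to zero with no user parameter.

Iterations stop when `res = ‖F^(k) − F^(k−1)‖₂ / N < 10⁻¹²` or after
`K_iter = 200` outer iterations.  Baselines: plain SART, SART-TV and
SART-FDTV with fixed λ = 0.5 / η = 0.3, and classical ASD-POCS.

## Worked example

```r
library(fdtvct)
phantom <- sheppLogan(64)
geom <- makeParallelGeometry(30, 128)          # 30 views over 180 deg
A <- buildSystemMatrix(geom, phantom)
sino <- phantomSinogram(geom, 64)              # exact ellipse line integrals

sart     <- reconstruct(sino, A, reconConfig("SART", kIter = 50))
adaptive <- reconstruct(sino, A, reconConfig("ADAPTIVE_FDTV", kIter = 50))

cat(sprintf("SART:          PSNR %.2f dB, SSIM %.4f\n",
            psnr(phantom, reconImage(sart)), ssim(phantom, reconImage(sart))))
cat(sprintf("ADAPTIVE_FDTV: PSNR %.2f dB, SSIM %.4f\n",
            psnr(phantom, reconImage(adaptive)),
            ssim(phantom, reconImage(adaptive))))
head(iterationTrace(adaptive), 3)
```

prints

```
SART:          PSNR 20.46 dB, SSIM 0.5581
ADAPTIVE_FDTV: PSNR 23.28 dB, SSIM 0.7159
  k   delta_d       eta          res
1 1 16.990099 16.990099 0.0036143658
2 2 10.653497  6.547772 0.0016011668
3 3  9.762674  4.434251 0.0006596063
```

At this deliberately small scale (64×64, 30 views, 50 iterations) the
adaptive FDTV method already gains ~3 dB PSNR and +0.16 SSIM over plain
SART on the same data: TV suppresses the streak artifacts that SART fits
into the inconsistent sparse-view measurements.  The trace shows the
adaptive step `eta` starting at `Δd(1)` and decaying as the POCS updates
shrink.

Full benchmarks are one call (or one CLI line) away:

```r
runExperiment(system.file("extdata", "table1_small.yaml", package = "fdtvct"))
# full 256x256 protocol (~15 min):
runExperiment(system.file("extdata", "table1.yaml", package = "fdtvct"))
```

Each run writes reconstructions (NPY + PNG), per-iteration traces,
profile CSVs and a `summary.csv` of PSNR/SSIM/RMSE per algorithm × view
count.  A thin command-line front end with verbs `phantom`, `project`,
`reconstruct`, `evaluate` and `run` lives in `exec/fdtvct`.

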