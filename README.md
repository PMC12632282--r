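# bayespose

Bayesian orientation estimation for cryo-EM and cryo-ET, in R.

Each observation in single-particle cryo-electron microscopy (cryo-EM) or
cryo-electron tomography (cryo-ET) is a noisy view of a reference structure
*V* in an unknown orientation *g* ∈ SO(3):

    y = Π(g ∘ V) + ε,   (g ∘ V)(x) = V(g⁻¹x),   ε ~ N(0, σ²I),

where Π is the identity (cryo-ET subtomogram alignment), a tomographic
projection (cryo-EM), or a cyclic shift on a polar raster (in-plane 2D
matching). The standard estimate of *g* — the grid rotation maximizing
cross-correlation with the reference — is the maximum-likelihood estimator
(MLE), and it degrades badly at low signal-to-noise ratio.

`bayespose` implements the Bayes estimator under squared chordal loss
d²_F(g₁,g₂) = ‖g₁ − g₂‖²_F, the **MMSE orientation estimator**:

    ĝ_relax = Σ_ℓ p(ℓ) g⁽ℓ⁾         (posterior mean over a rotation grid)
    ĝ_MMSE  = argmin_{Ω ∈ SO(3)} ‖Ω − ĝ_relax‖_F   (orthogonal Procrustes)

with posterior weights p(ℓ) ∝ w_ℓ Λ(g⁽ℓ⁾) exp(−‖y − x_ℓ‖²/2σ²) over
templates x_ℓ = Π(g⁽ℓ⁾ ∘ V), computed stably in the log domain. Alongside
it: the MLE and MAP grid estimators, Haar-uniform and isotropic-Gaussian
IG-SO(3)(η) rotation priors (density and sampler), quadrature grids on
SO(3), the soft-assignment EM reconstruction whose M-step is exactly the
MMSE-operator alignment average (with its hard-assignment counterpart),
MRC/STAR/CSV I/O, synthetic phantoms, and a Monte Carlo benchmark harness.
The MMSE estimator matches the MLE at high SNR, dominates it in mean
squared chordal error at low SNR, benefits further from an informative
prior, and — used as the soft-assignment step of iterative refinement — is
markedly less prone to the "Einstein from Noise" template-bias artifact.

## Worked example

```r
library(bayespose)

V    <- make_phantom(16, "band_limited", seed = 3)   # unit-power reference
grid <- so3_grid(3000)                               # rotation grid (L = 2996)
bank <- build_templates(V, grid, "no_projection_3d")

sigma <- sigma_for_snr(V, 0.1)                       # SNR = 0.1
obs   <- simulate_batch(V, prior_haar(), sigma, "no_projection_3d",
                        n = 1000, seed = 11)

fit <- estimate_batch(obs, bank, methods = c("mle", "mmse"))
fit |>
  dplyr::group_by(method) |>
  dplyr::summarize(mean_sq_chordal = mean(d_F^2),
                   mean_geodesic   = mean(d_G))
```

```
# A tibble: 2 × 3
  method mean_sq_chordal mean_geodesic
  <chr>            <dbl>         <dbl>
1 mle             0.0515         0.152
2 mmse            0.0485         0.148
```

At SNR 0.1 on this reference the MMSE estimator's mean squared chordal
error (0.0485) is below the MLE's (0.0515) — a 6% reduction, about nine
standard errors of the paired per-trial difference; the mean geodesic
errors (radians) tell the same story. At high SNR the two curves merge, and
the error floor is set by the grid: refining L by a decade shrinks the
geodesic error as L^(−1/3).

Benchmark drivers wrap such studies with seeds, per-cell standard errors
and `autoplot()` methods: `run_error_vs_snr()`, `run_grid_scaling()`,
`run_prior_mismatch()` (IG-SO(3) truth, matched/mismatched priors), and
`run_einstein_from_noise()` (soft vs hard refinement from a biased template
down to pure noise). `run_refinement()` / `run_refinement_polar()` expose
the EM loops directly, with broom-style `tidy()`/`glance()` on the fitted
trajectories. A thin CLI over these functions is installed at
`inst/cli/bayespose` (subcommands `simulate`, `estimate`, `reconstruct`,
`benchmark`).

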