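---
title: "Bayesian orientation estimation: models, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian orientation estimation: models, estimators, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayespose)
```

## The problem

In single-particle cryo-electron microscopy (cryo-EM) and cryo-electron
tomography (cryo-ET), each observation is a noisy view of a known (or
provisionally reconstructed) reference structure $V$ in an unknown
orientation $g \in SO(3)$:

$$ y = \Pi(g \circ V) + \varepsilon, \qquad
   (g \circ V)(x) = V(g^{-1}x), \qquad
   \varepsilon \sim \mathcal N(0, \sigma^2 I). $$

Three instances of $\Pi$ are implemented:

* **no projection** (cryo-ET subtomogram alignment): $y$ is a noisy rotated
  3D volume;
* **tomographic projection** (cryo-EM): $y$ is a noisy 2D projection of the
  rotated volume, the line integral along the beam axis;
* **polar 2D** (in-plane template matching): $y$ is a noisy cyclic shift of
  a polar-raster image, the $SO(2)$ case.

The standard practice is projection matching: scan a grid
$\{g^{(\ell)}\}_{\ell=0}^{L-1}$ of candidate rotations and keep the best
cross-correlation. That is the maximum-likelihood estimator (MLE), and it is
statistically sub-optimal at low signal-to-noise ratio. This package
implements the Bayes alternative under the squared chordal loss
$d_F^2(g_1,g_2) = \lVert g_1 - g_2\rVert_F^2$: the minimum-mean-square-error
(MMSE) estimator, along with the MLE and MAP baselines, non-uniform rotation
priors, and the soft-assignment EM reconstruction the MMSE operator induces.

## The estimators

All three share one computation: per-node log-likelihoods
$-\lVert y - x_\ell \rVert^2 / 2\sigma^2$ against the template bank
$x_\ell = \Pi(g^{(\ell)} \circ V)$, evaluated through the inner-product
expansion with precomputed template norms so a whole batch of observations
is one BLAS matrix product.

* **MLE** — the argmin node of $\lVert y - x_\ell\rVert^2$. Noise level and
  prior do not enter.
* **MAP** — the argmax node of
  $w_\ell \, \Lambda(g^{(\ell)}) \exp(-\lVert y - x_\ell\rVert^2/2\sigma^2)$,
  where $w_\ell$ are quadrature weights and $\Lambda$ the prior density
  relative to Haar measure. With a uniform prior it coincides with the MLE
  node. (Whether the discrete argmax should include $\log w_\ell$ is not
  determined by the continuous formulation; the weight-inclusive form is the
  default and the pure prior-times-likelihood form is available via
  `use_quadrature_weights = FALSE`. On the equal-weight grids this package
  builds, the two are identical.)
* **MMSE** — the Bayes estimator under squared chordal loss. The relaxed
  minimizer over all $3\times 3$ matrices is the posterior mean
  $\hat g_{\text{relax}} = \sum_\ell p(\ell)\, g^{(\ell)}$, computed
  entrywise; the constrained minimizer is its orthogonal Procrustes
  projection back onto $SO(3)$ (SVD with a determinant sign correction).
  The Procrustes gap $\lVert \hat g_{\text{relax}} - \hat g_{\text{MMSE}}
  \rVert_F$ is returned as a diagnostic: it is near $2\sqrt2 \cdot$
  (posterior spread) and approaches zero as the posterior concentrates.

Posterior weights are always assembled in the log domain with
max-subtraction before exponentiation. At cryo-EM-like noise levels the
linear-domain weights underflow double precision catastrophically; the
log-domain path is stable for $\sigma$ down to $10^{-6}$ on unit-power
signals (tested).

In the $SO(2)$ (polar) case the posterior mean of the $2\times 2$ rotation
matrices is a point inside the unit disc; its projection onto $SO(2)$ is
the angle of the mean resultant vector, which is the exact two-dimensional
analogue of the Procrustes step. The resultant length doubles as the
degeneracy diagnostic.

Two structural facts connect the estimators and are enforced by tests: with
a strictly positive prior the MMSE and MAP estimators converge to the MLE as
$\sigma \to 0$ (at high SNR the three disagree by at most the grid spacing),
and under a correctly specified prior the MMSE estimator attains the
smallest posterior expected squared chordal loss of any rotation — the test
suite checks it beats $10^5$ Haar-sampled candidates on random posteriors.

## Discretizing SO(3)

`so3_grid(L)` builds a product quadrature: approximately $L^{2/3}$ viewing
directions from a Fibonacci sphere lattice (deterministic, near-equal-area)
times approximately $L^{1/3}$ equispaced in-plane angles, with equal weights
summing to one. Equal-weight near-uniform coverings reproduce every Haar
moment this package relies on (the mean rotation matrix over the
`so3_grid(2976)` nodes vanishes to $10^{-2}$ elementwise, and smooth test
functions integrate to their $10^5$-sample Monte Carlo values within 2%);
exact Gauss-type quadrature on $SO(3)$ is a non-goal.

The realized $L$ is the nearest product $n_1 n_2$ to the request, and is
reported in the grid object. At high SNR the estimation error is pure
discretization: each of the three rotational degrees of freedom refines as
$L^{1/3}$, so the mean geodesic error scales as $L^{-1/3}$. The benchmark
`run_grid_scaling()` fits this exponent and recovers $|{\text{slope}}| =
1/3$ within confidence intervals.

### Concentrated priors and Monte Carlo grids

For a sharply concentrated prior (isotropic Gaussian with small $\eta$) a
uniform quadrature is the wrong discretization: nearly all nodes fall where
the prior mass is negligible (for $\eta = 0.1$, a fraction $\sim 10^{-3}$ of
Haar mass lies within the prior's bulk, i.e. a handful of nodes at
$L \approx 3000$). `so3_grid_from_prior()` instead samples $L$ i.i.d. nodes
from the prior with equal weights. Posterior expectations over such a grid
are importance-sampling approximations of the prior-weighted integrals, so
the prior density must not be applied a second time at the nodes — the
estimator is called with a uniform working prior. The density-weighting
route (`prior_log_density_at_nodes()`) remains available for tabulated or
mild priors on uniform grids; prior-mismatch benchmarks use the Monte Carlo
route for the IG-SO(3) priors and the uniform grid for the uniform prior
and the MLE.

## The isotropic Gaussian on SO(3)

`prior_igso3(eta)` uses the heat-kernel construction standard in the
machine-learning literature on rotation diffusion: density relative to Haar
measure, as a function of the rotation angle $\omega$,

$$ f_\eta(\omega) \;\propto\; \sum_{l \ge 0} (2l+1)\,
   e^{-l(l+1)\eta^2/2}\, \frac{\sin((l+\tfrac12)\omega)}{\sin(\omega/2)}, $$

truncated when the coefficient falls below $10^{-12}$, multiplied by the
Haar angle factor $(1-\cos\omega)/\pi$ for the angle marginal and normalized
numerically. Whether the time parameter should be $\eta^2$ or $\eta^2/2$ in
the exponent is a convention, not a theorem; this package fixes
$e^{-l(l+1)\eta^2/2}$, isolates it in one internal function
(`.igso3_haar_density`) so it can be swapped, and pins the two contracts
that matter instead: as $\eta \to \infty$ the angle density converges to the
Haar marginal (sup gap $< 10^{-3}$ at $\eta = 50$), and as $\eta \to 0$ the
mass concentrates at the identity ($P(\omega < 0.5) > 0.99$ at
$\eta = 0.05$).

Sampling is axis-angle: axes uniform on the sphere, angles by inverse-CDF
lookup on a 4096-point tabulation cached per $\eta$. The sampler passes a
Kolmogorov–Smirnov test against its own density at $n = 10^4$.

Density evaluation underflows for $\eta \lesssim 0.05$ at angles far from
zero (the density is clamped at $10^{-300}$ before the log). Grids for such
priors should come from `so3_grid_from_prior()`, which never evaluates the
density; MAP under an extremely concentrated prior on a uniform grid is
outside the reliable range and is documented as such rather than patched
with asymptotics.

## Reconstruction by soft and hard assignment

For the no-projection model with $M$ observations and unknown i.i.d.
uniform rotations, the EM algorithm alternates:

* **E-step** — posterior weights $p_i(\ell) \propto w_\ell
  \exp(-\lVert y_i - g^{(\ell)}\circ \hat V\rVert^2/2\sigma^2)$, one matrix
  product for the whole batch;
* **M-step (soft)** — $\hat V \leftarrow \frac1M \sum_i \sum_\ell
  p_i(\ell)\, (g^{(\ell)})^{-1} \circ y_i$: every observation back-rotated
  to every node, posterior-weighted, averaged. This is exactly the average
  of the observations aligned by their MMSE rotation *operators* (the
  posterior mean acting on the data), and the test suite verifies the
  identity against the naive double loop to $10^{-8}$.
* **M-step (hard)** — each observation aligned only by the inverse of its
  MLE node.

Two quantities are tracked per iteration. The complete-data weighted loss
$\sum_i \sum_\ell p_i(\ell) \lVert y_i - g^{(\ell)}\circ\hat V\rVert^2$ is
the M-step objective, but it is *not* the functional EM guarantees monotone
— the marginal negative log-likelihood is. Both are recorded in the
trajectory (`objective`, `nll`), and the monotonicity tests assert the NLL,
on polar instances where the group action is an exact permutation and the
guarantee is not blurred by interpolation error. Iteration stops when the
relative $L_2$ change of the estimate falls below `tol` ($10^{-3}$ by
default) or after `max_iter` (100) iterations; the relative-change norm is
$L_2$ on the raw grid, matching the squared-loss objective.

In 3D, back-rotation uses the same tricubic resampling as the forward
model, and the M-step accumulates one observation at a time, so memory
stays at one volume plus one observation regardless of $M$ and $L$. A
consequence of interpolation: starting refinement at the truth with clean
on-grid observations converges in two iterations, not one — the first
M-step pays a single resampling pass, after which the update is a fixed
point. On the polar grid the action is exact and convergence from truth is
immediate.

### Template bias

With pure-noise observations, iterative refinement still returns an image
correlated with its initialization — the "Einstein from Noise" artifact.
The mechanism is the alignment step: picking the best-correlated rotation
of the template for each noise image biases the average toward the
template. Hard assignment commits to the argmax and maximizes this bias;
soft assignment spreads each observation over rotations in proportion to
the evidence, and with no evidence the back-rotated average largely cancels.
`run_einstein_from_noise()` quantifies the gap: at $d = 300 \times 30$ and
$M = 2000$ pure-noise observations, the hard reconstruction's correlation
with the template is higher than the soft one's by many standard errors,
while at high SNR the two reconstructions are indistinguishable (mutual
Pearson correlation $> 0.99$), as the high-SNR equivalence of the MLE and
MMSE estimators predicts. Reconstruction correlations on the polar grid are
always maximized over the global cyclic shift, a gauge freedom the model
cannot fix.

## Synthetic references

No external data is required; the generators produce every study input.

* `make_phantom(kind = "band_limited")` — a band-limited Gaussian random
  field (Gaussian annulus around 0.10 cycles/voxel) under a soft spherical
  mask. This is the reference for the orientation benchmarks because its
  rotational self-correlation decays quickly and monotonically with angle
  and has no distant secondary maxima — the property that makes a ribosome
  a good alignment target. Smooth blob clusters at $16^3$, by contrast,
  routinely carry accidental near-two-fold self-correlations above 0.8,
  which a coarse grid confuses with the true pose; that failure mode is a
  property of toy blob references, not of the estimators.
* `"gaussian_blobs"` / `"asymmetric_blobs"` — smooth blob clusters, the
  latter regenerated until no rotational self-correlation exceeds 0.95
  (checked over random rotations plus a scan of two-fold axes).
* `"spherical_shell"` — rotation-invariant by construction; the symmetry
  oracle for operator tests.
* `make_phantom_polar()` — periodic Gaussian bumps or angular-harmonic
  patterns on the polar raster, for the $SO(2)$ experiments.

Phantoms keep a 25% empty margin so rotation loses negligible mass to the
zero fill, and are unit-power normalized so that the SNR convention
(mean squared signal value over the grid divided by $\sigma^2$ — the
package's own definition; benchmark tables always report raw $\sigma$
alongside) is comparable across references.

What passing tests on these phantoms do **not** show: robustness to
contrast transfer functions, in-plane translations, non-white noise,
structured backgrounds, or model mismatch between reference and particles —
none of which the forward model contains (CTF and shifts are out of scope
by design).

## Numerical choices

* Coordinates: voxel centers, origin at the geometric center
  $((N-1)/2$ per axis$)$, right-handed axes, projection along $+z$;
  active rotations throughout.
* Rotation resampling: tricubic Catmull–Rom, zero fill outside the grid;
  sampling at integer coordinates is exact, so the identity rotation is
  bit-exact. Double resampling costs 2–6% relative $L_2$ on $16^3$
  references, which is why interpolation-sensitive contracts are tested on
  smoother or larger phantoms.
* Projection: real-space $z$-sum, which conserves mass exactly; the
  Fourier central-slice route is a non-goal.
* Procrustes: SVD with determinant correction on the smallest singular
  direction; when the correction is active and the two smallest singular
  values agree within $10^{-8}$ the minimizer is non-unique (symmetric
  bimodal posteriors genuinely produce this) and the result carries a flag.
* `arccos` arguments are clamped to $[-1, 1]$; ties break to the lowest
  node index, flagged; absolute comparison tolerance is $10^{-10}$ unless a
  contract states otherwise.
* All randomness flows through explicit integer seeds; batch drivers derive
  per-cell sub-seeds from one master seed, drawing trial seeds before any
  auxiliary seeds so that adding estimators to a study never changes the
  simulated data.

## Problem sizes

The benchmark defaults shrink the original study settings to desk scale
while preserving every qualitative contract: $16^3$ references (the 3D
refinement experiments support $32^3$), grids $L \in \{300, 1000, 3000\}$
(one decade, enough to fit the scaling exponent), 300–1000 Monte Carlo
trials per cell against 3000 in the full-scale studies, and the polar
template-bias study at $d = 300 \times 30$ with $M = 2000$ observations and
20 replicates against $M = 5\times10^4$. Standard errors accompany every
reported mean, and all dominance statements are tested as paired
differences against twice their standard error, never as point
comparisons.

## Limitations

* The cryo-EM forward model is simplified: no CTF, no translations, white
  noise only ($\Sigma = \sigma^2 I$); the general-covariance formulas are
  straightforward but not implemented.
* No gradient-based or multiresolution pose refinement off the grid; the
  error floor is the grid spacing.
* The projection-model (Fourier-slice) 3D reconstruction pipeline is out of
  scope: the EM module covers the no-projection model (3D) and the polar
  model (2D). Estimated poses export to quaternion CSV and RELION-style
  STAR (ZYZ Euler angles in degrees — a convention chosen for
  interoperability, not dictated by the model) for downstream tools.
* The IG-SO(3) parameterization convention is pinned by its limits, not by
  an external normalization; results quoted in terms of $\eta$ are
  comparable within this package.
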