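---
title: "Methods: self-supervised INR estimation of the Standard Model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-supervised INR estimation of the Standard Model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
signal model, the estimator, the synthetic test bench, the numerical
choices, and what the shipped checks do and do not demonstrate.

## The Standard Model and its two forward paths

White matter diffusion MRI signal is modeled as the spherical convolution
of an axially symmetric two-compartment kernel with a fiber orientation
distribution (FOD): an intra-axonal stick (signal fraction $f_i$, axial
diffusivity $D_i$, zero perpendicular diffusivity) and an extra-axonal
zeppelin ($D_e^\parallel$, $D_e^\perp$), both exposed to a b-tensor
encoding described per measurement by $(b, b_\Delta, \mathbf u)$. With the
FOD expanded in even-order real spherical harmonics (SH; Descoteaux-style
orthonormal convention, coefficients ordered by degree $l$ then phase $m$),
the convolution is diagonal per degree: each $p_l^m$ is scaled by the
kernel's Legendre projection

$$r_l(a) = 2\pi \int_{-1}^{1} P_l(t)\, e^{-a t^2}\, dt,$$

with $a = b\,b_\Delta D_i$ (intra) or $a = b\,b_\Delta (D_e^\parallel -
D_e^\perp)$ (extra), multiplied by the isotropic exponential prefactors.
This *analytic path* is valid for $b_\Delta \ge 0$ and $D_e^\parallel >
D_e^\perp$. A *numeric path* evaluates the two spherical integrals by
quadrature and has no sign restrictions.

Numerical choices:

* $r_l(a)$ uses a fixed 64-node Gauss–Legendre rule on $[0,1]$ (even
  symmetry doubles the domain). The rule is exact for the polynomial factor
  at every supported degree, smooth and differentiable in $a$, and needs no
  per-degree closed forms; the $l=0$ closed form
  $4\pi\sqrt{\pi/4a}\,\mathrm{erf}\sqrt a$ is kept as a test oracle. At
  $a=0$ it reproduces $r_l(0) = 4\pi\delta_{l0}$ to machine precision, so
  the $b=0$ identity $S = S_0\sqrt{4\pi}\,p_0^0$ is exact.
* The numeric path uses a composite-Simpson product grid in
  $(\theta,\phi)$ with the $\sin\theta$ Jacobian, default $65 \times 97$
  nodes. The size was set by measurement: the integrand
  $e^{-a(\mathbf n\cdot\mathbf u)^2}P(\mathbf n)$ is not band-limited, and
  at the largest attenuation the optimized protocol reaches
  ($a = 8 \times 4 = 32$) a $33\times65$ grid errs at the percent level
  while $65\times97$ stays below $3\cdot10^{-4}$ relative — comfortably
  inside the $10^{-3}$ cross-path agreement the tests enforce.
  Measurements with $b\,b_\Delta = 0$ are integrated exactly
  ($\int P = \sqrt{4\pi}p_0^0$ by orthonormality). A Gauss–Legendre-in-
  $\cos\theta$ grid (`sphere_grid(type = "gauss")`) integrates band-limited
  integrands to machine precision and backs the orthonormality tests.
* Rotations are never applied through Wigner machinery; tests realize them
  by dense resampling of the FOD and orthonormal re-projection.

## The estimator

`fit_sm_inr()` trains a coordinate network $\mathbf x \mapsto
(f_i, D_i, D_e^\parallel, D_e^\perp, S_0, p_l^m)$:

1. **Coordinate scaling.** Voxel-center coordinates are scaled so the
   longest physical axis spans $[-1,1]$, other axes by the same factor
   (aspect preserved), centered on the volume.
2. **Fourier-feature encoding.** $\gamma(\mathbf x) = [\cos(2\pi A\mathbf
   x), \sin(2\pi A\mathbf x)]$ with $A$ an $n_p\times 3$ matrix drawn once
   from $N(0, \sigma^2)$ and frozen. $\sigma^2$ is the single knob that
   trades spatial detail against regularization: frequencies of magnitude
   $|a|$ produce structure at wavelength $\sim 1/|a|$ in scaled units.
3. **MLP.** Four fully connected ReLU layers of width $n_h$; the latent
   vector is therefore non-negative. Hidden layers use uniform fan-in
   initialization.
4. **Heads.** One affine map per output: sigmoids scaled to the
   physiological boxes $f_i\in[0,1]$, $D_i, D_e^\parallel \in [0,4]$,
   $D_e^\perp\in[0,1.5]$ µm²/ms (the architecture enforces the bounds — no
   clamping anywhere), a scaled softplus for $S_0$, identity for the SH
   coefficients. Head weights start at zero: kernel outputs begin
   mid-range, $S_0$ begins at the mean $b=0$ signal (the softplus scale is
   set from the data), and the FOD begins as the unit-integral isotropic
   distribution ($p_0^0 = 1/\sqrt{4\pi}$ bias). This starts optimization
   at a physiological, non-saturated point.
5. **Objective.** Per voxel, the data loss is summed over all measurements
   — squared error, or the $\nu$-dependent part of the Rician negative
   log-likelihood $\nu^2/2\sigma^2 - \log I_0(S\nu/\sigma^2)$ with a
   numerically stable $\log I_0$ (scaled Bessel below $5\cdot10^4$,
   asymptotic series above) — plus the FOD non-negativity penalty
   $\Lambda$: the mean over 300 fixed electrostatic-repulsion directions
   of $\max(0, -P(\mathbf n))$, weight 1. Averaging (rather than summing)
   over directions makes $\Lambda$ scale-comparable to the data term; the
   weight and the direction count are this package's choices (300
   oversamples the $l_{max}=8$ band limit roughly six-fold). The batch
   mean of per-voxel losses is minimized by Adam ($\beta_1=0.9$,
   $\beta_2=0.999$, $\epsilon=10^{-8}$, no weight decay, learning rate
   $10^{-4}$, batch 500, 150 epochs by default, shuffled coordinates each
   epoch, no learning-rate schedule and no early stopping). The full
   dataset is used without a train/test split: the network's task is to
   *represent* this dataset.
6. **Rician noise level.** $\sigma(\mathbf x)$ is an input map — known
   exactly in simulation, externally estimated in practice; the package
   deliberately contains no internal noise estimator.
7. **Gradient non-uniformity.** Given a per-voxel gradient-coil tensor
   $L$, the nominal B-tensor $B = (b/3)[(1-b_\Delta)I + 3 b_\Delta
   \mathbf u\mathbf u^T]$ is mapped to $LBL^T$ and summarized by the
   closest axially symmetric description ($b_{eff} = \mathrm{tr}$,
   principal axis, $b_{\Delta,eff}$ from the eigenvalue split). This
   axial-symmetry reading is an approximation that degrades for non-linear
   encodings under strong non-uniformity. Exact-identity tensors collapse
   onto the uncorrected code path, so a null correction is bit-identical
   to no correction. The numeric path is selected automatically whenever
   any (effective) $b_\Delta$ is negative.
8. **Degeneracy.** $S_0$ and the FOD scale are jointly free, so only the
   product $S_0\,p_l^m$ is identified; kernel parameters are unaffected.
   The default mirrors that joint freedom; pinning $p_0^0$ is possible by
   fixing the corresponding head bias but is not the default.

Both the training loop and all gradients — through the heads, the MLP, and
the analytic or quadrature forward model — are hand-derived reverse-mode
implementations on BLAS matrix operations, verified against finite
differences in the test suite.

## The synthetic test bench

`generate_phantom()` builds ground truth with the statistical structure the
estimator assumes in white matter:

* **Kernel fields** are white noise on the voxel lattice convolved with a
  Gaussian kernel (default width 6 mm ≈ 3 voxels) and squashed by a `tanh`
  map into physiological sub-ranges ($f_i\in(0.3,0.8)$, $D_i\in(1.5,3.0)$,
  $D_e^\parallel\in(1.0,2.5)$, $D_e^\perp = r\,D_e^\parallel$ with smooth
  $r\in(0.2,0.6)$, so $D_e^\parallel > D_e^\perp$ holds everywhere by
  construction). Because the smoothing kernel is evaluated continuously,
  the truth is an analytic function of position — the upsampling study
  evaluates it between voxels. Gaussian smoothing of lattice noise stands
  in for anisotropic diffusion filtering of real parameter maps: simpler
  and seedable, at the cost of isotropic, stationary smoothness.
* **FODs** are mixtures of one or two Watson densities
  $\propto e^{\kappa(\boldsymbol\mu\cdot\mathbf n)^2}$ with smoothly
  varying orientations (`single`, `crossing`, `fanning`), projected onto
  even SH by the same Legendre-projection machinery and normalized to unit
  integral. Watson mixtures replace data-derived FODs, which would require
  external datasets and tools. The concentration default is
  $l_{max}$-dependent ($\kappa = 2, 4, 4, 6$ for $l_{max} = 2,4,6,8$):
  these are the sharpest values whose band-limited truncation remains
  non-negative, giving single-fiber $p_2$ around 0.3–0.55 — mild but
  physiological. Sharper FODs at low band limits would go negative purely
  through truncation.
* **Protocol.** The published optimized six-shell b-tensor protocol:
  $b = (0, 1000, 2000, 8000, 5000, 2000)$ s/mm², directions
  $(4, 20, 40, 40, 35, 15)$, $b_\Delta = (1, 1, 1, 1, 0.8, 0)$; shell
  directions by electrostatic repulsion on a hemisphere (1000 projected-
  gradient iterations on the antipodal Coulomb energy) with half flipped.
  All $b_\Delta \ge 0$, so simulation uses the analytic path.
* **Noise.** Per-voxel $\sigma = $ mean $b=0$ signal / SNR; Gaussian adds
  one draw per measurement, Rician takes the magnitude of two Gaussian
  channels. $S_0 \equiv 1$ and four $b=0$ volumes by default.

What the phantom does **not** emulate: anatomy (no tissue boundaries, no
partial volume), anisotropic or non-stationary smoothness, relaxation and
free-water contributions, spatially correlated or non-central-chi noise,
and FODs beyond two fiber populations. Passing the shipped checks
demonstrates correct inference under the model's own assumptions at
phantom scale — not performance on real brains.

## Study conditions in the shipped checks

The test suite and `scripts/acceptance.R` run three studies sized for a
single CPU (a few minutes each):

* **Recovery** (core claim, scaled down): $12^3$ phantom, optimized
  protocol, $l_{max}=2$, Gaussian SNR 20, reduced network $n_p=512$,
  $n_h=256$, 150 epochs, batch 500. The INR's per-parameter Pearson $\rho$
  against truth must strictly exceed voxel-wise NLLS for all four kernel
  parameters.
* **Rician bias**: same phantom with Rician SNR-20 noise, fitted with MSE
  and with the Rician likelihood; the signed mean $D_i$ bias must shrink
  in magnitude under the likelihood. A pure-loss check (10⁵ Rician draws,
  amplitude 1, $\sigma=0.25$) verifies the estimator-level property.
* **Upsampling**: $10^3$ phantom, Gaussian SNR 50, factor-8 continuous
  maps vs trilinear interpolation of the NLLS $f_i$ map, RMSE against the
  analytic truth; 400 epochs here, because at 1000 voxels an epoch is only
  two optimizer steps and the recovery schedule would stop short of
  convergence (no criterion fixes the schedule for this study).

**Choice of $\sigma^2 = 0.3$ for these studies.** The brain-scale defaults
($\sigma^2 = 3.5$, or 2.5 at high noise) assume brain-like structure:
features at a small fraction of the field of view. These phantoms have a
correlation length of ~3 voxels on 10–12-voxel grids — a quarter of the
FOV — so the matched encoding scale is an order of magnitude coarser.
Two observations make the scaling concrete: with $\sigma^2=2.5$ the
reduced network is still descending at epoch 150 (underfit within the
fixed schedule), and interpolation of a voxel-wise map implicitly
*averages* white estimation noise, so the upsampling comparison is won by
whichever method has the smaller smooth error component — which requires
the encoding bandwidth to match the field, not exceed it. $\sigma^2=0.3$
does both; it is the package's documented default for phantom-scale work,
while `fit_sm_inr()` keeps 3.5 as its function default.

## Degenerate inputs, ties, tolerances

* Zero-norm b-vectors are only legal on $b=0$ rows (replaced by a fixed
  axis and flagged). Protocols reject $b<0$ and $b_\Delta\notin[-0.5,1]$.
* The analytic path refuses $b_\Delta<0$ or $D_e^\parallel \le
  D_e^\perp$ by name, pointing at the numeric path. During INR training
  the bounded heads keep parameters inside the boxes, and transiently
  $D_e^\parallel < D_e^\perp$ is tolerated: the Legendre quadrature is
  mathematically exact for negative arguments too.
* NLLS enforces bounds by smooth reparameterization (sigmoids;
  $D_e^\perp$ as a fraction of $\min(D_e^\parallel, 1.5)$) because plain
  Levenberg–Marquardt is unconstrained; the best of a data-driven and a
  seeded random initialization is kept, ties broken by residual norm. FOD
  non-negativity is deliberately *not* enforced in NLLS — only the INR
  carries the constraint.
* The effective-B eigenvector sign is fixed to a non-negative first
  component; antipodal symmetry makes the choice inert. The distinct
  eigenvalue (prolate or oblate) is chosen by the larger eigenvalue gap.
* Pure-$b=0$ voxels return $S_0$ with an explicit unidentifiability flag.

## Known limitations

* Fitting times in plain R are minutes at phantom scale; full-size brains
  at $n_p=5000$, $n_h=2048$ are better served by an accelerator, which
  this implementation intentionally does not require.
* The axially-symmetric effective-protocol approximation and the absence
  of relaxation/free-water terms are inherited model limitations.
* The per-voxel effective-protocol training path (non-trivial gradient
  coil tensors) is supported but markedly slower than the grouped nominal
  path; the shipped checks exercise its null-consistency, not its speed.
* The $S_0$–FOD scale degeneracy means absolute FOD amplitudes should not
  be compared across fits without a normalization convention.
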