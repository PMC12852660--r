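# sminr

Self-supervised estimation of the **Standard Model (SM) of white matter**
from b-tensor-encoded diffusion MRI, using an **implicit neural
representation (INR)**: a coordinate network that maps a continuous spatial
position to the SM kernel parameters and the fiber orientation distribution
(FOD), trained directly against the measured signal through the SM forward
model. No labeled training data, no voxel-wise optimization — the network's
sinusoidal spatial encoding provides inherent spatial regularization, which
is what makes the estimates robust at low SNR.

Intended users: diffusion-MRI methods researchers who want noise-robust,
spatially coherent SM parameter maps (and FODs up to spherical-harmonic
order 8) from multi-shell / b-tensor acquisitions, plus a fully synthetic
test bench to validate estimators without any external data.

## The model

The signal of a voxel is the spherical convolution of a two-compartment
axially symmetric kernel with the FOD `P(n)`:

    S(b, bΔ, u) = S0 ∫_{S²} K(b, bΔ, n·u) P(n) dn

with the kernel a mixture of an intra-axonal *stick* (fraction `f_i`, axial
diffusivity `D_i`, zero perpendicular diffusivity) and an extra-axonal
*zeppelin* (axial `De∥`, perpendicular `De⊥`):

    K_zep(b, bΔ, t) = exp[ ⅓ b bΔ (D∥ − D⊥) − ⅓ b (D∥ + 2 D⊥) − b bΔ t² (D∥ − D⊥) ]

`b` is the b-value (stored internally in ms/µm² so `b·D` is dimensionless),
`bΔ` the b-tensor shape (1 linear, 0 spherical, −0.5 planar), `u` the
principal encoding axis. With `P(n)` expanded in even-order real spherical
harmonics `p_l^m`, the convolution reduces per degree to a product with the
kernel's Legendre projection `r_l(a) = 2π ∫ P_l(t) e^{−a t²} dt`
(Funk–Hecke), which is the fast *analytic* forward path (valid for `bΔ ≥ 0`
and `De∥ > De⊥`); a spherical Simpson quadrature path handles negative
`bΔ`.

The estimator `fit_sm_inr()` trains a Fourier-feature encoding
(`γ(x) = [cos 2πAx, sin 2πAx]`, `A ~ N(0, σ²)`), a four-layer ReLU MLP and
bounded output heads (scaled sigmoids for `f_i ∈ [0,1]`,
`D_i, De∥ ∈ [0,4]`, `De⊥ ∈ [0,1.5]` µm²/ms; softplus for `S0`; identity
for `p_l^m`) with Adam against the per-voxel signal loss (MSE or Rician
negative log-likelihood) plus an FOD non-negativity penalty. Everything —
network, optimizer, and the gradients through the forward model — is
implemented in R on BLAS matrix operations.

## Worked example

```r
library(sminr)

proto <- optimized_protocol()            # 154-measurement b-tensor protocol
ph    <- generate_phantom(shape = c(12, 12, 12), lmax = 2, seed = 1)
noisy <- add_noise(simulate_signals(ph, proto), proto,
                   noise_spec("gaussian", snr = 20, seed = 2))

fit <- fit_sm_inr(noisy$signals, proto, lmax = 2,
                  n_p = 512, n_h = 256, sigma2 = 0.3,
                  epochs = 150, seed = 1)
print(fit)
#> Standard Model INR fit
#>   1728 masked voxels on a 12 x 12 x 12 grid, 154 measurements
#>   lmax = 2, loss = mse, integration = analytic
#>   150 epochs; mean loss 0.89747 -> 0.37555

nlls <- fit_sm_nlls(noisy$signals, proto, lmax = 2, seed = 1)
est  <- coef(fit)
compare_methods(
  metric_report(est,        ph$theta, label = "INR"),
  metric_report(nlls$theta, ph$theta, label = "NLLS"))
#>   method parameter       rho       rmse n_voxels
#> 2    INR       D_i 0.8537964 0.17702284     1728
#> 3    INR    De_par 0.7098281 0.27787181     1728
#> 4    INR   De_perp 0.9037011 0.10533776     1728
#> 1    INR       f_i 0.9790160 0.02198664     1728
#> 6   NLLS       D_i 0.6550841 0.34761034     1728
#> 7   NLLS    De_par 0.3706656 0.77361681     1728
#> 8   NLLS   De_perp 0.7107612 0.21288394     1728
#> 5   NLLS       f_i 0.7855296 0.07643869     1728
```

The loss trace falls to the noise floor (`154·σ² ≈ 0.385` for SNR 20 with
`S0 = 1`), and the INR's correlation with the ground truth exceeds the
voxel-wise nonlinear-least-squares baseline on every kernel parameter —
the spatial regularization is doing real work at this noise level. Because
the representation is continuous in space, maps at any resolution come from
the same fit:

```r
maps8 <- upsample(fit, 8)      # 96^3 parameter volumes, 0.25 mm voxels
```

A thin command-line wrapper with `simulate`, `fit`, `predict`, `nlls` and
`evaluate` subcommands is installed at `inst/cli/sminr.R`
(`Rscript $(Rscript -e 'cat(system.file("cli/sminr.R", package="sminr"))') fit --help-style flags ...`).
On-disk formats: NIfTI-1 volumes, FSL `bval`/`bvec` (b in s/mm²), a
plain-text `bdelta` file (one value per volume), gradient-coil tensor
fields as 9-component 4-D NIfTI in row-major order (L11, L12, L13, L21, …),
SH coefficient volumes ordered by degree `l` then phase `m = −l..l`.

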