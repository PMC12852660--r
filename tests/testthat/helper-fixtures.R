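# Shared fixtures, built lazily and cached for the whole test session.
# Heavy objects (trained fits) are only constructed when a test first asks
# for them, so unit-test files stay fast.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_protocol <- function() fx_get("protocol", function() optimized_protocol())

# random rotation matrix
fx_rotation <- function() {
  q <- matrix(stats::rnorm(9), 3)
  s <- svd(q)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# rotate an FOD by dense resampling + orthonormal re-projection
fx_rotate_fod <- function(coeffs, R) {
  lmax <- sminr:::lmax_from_ncoef(length(coeffs))
  key <- paste0("rotgrid", lmax)
  gb <- fx_get(key, function() {
    g <- sphere_grid(64, 97, type = "gauss")
    list(g = g, B = real_sh_basis(lmax, g$dirs))
  })
  amp <- fod_amplitude(coeffs, gb$g$dirs %*% R)
  drop(t(gb$B) %*% (gb$g$weights * amp))
}

# random Watson-mixture FOD with unit integral
fx_random_fod <- function(lmax, kappa = default_kappa_for(lmax)) {
  mu <- stats::rnorm(3)
  mu <- mu / sqrt(sum(mu^2))
  sminr:::watson_sh(mu, kappa, lmax)
}

default_kappa_for <- function(lmax) c(`2` = 2, `4` = 4, `6` = 4, `8` = 6)[[as.character(lmax)]]

# random kernel parameters inside the phantom sub-ranges
fx_random_theta <- function() {
  De_par <- stats::runif(1, 1.0, 2.5)
  c(f_i = stats::runif(1, 0.3, 0.8), D_i = stats::runif(1, 1.5, 3.0),
    De_par = De_par, De_perp = De_par * stats::runif(1, 0.2, 0.6), S0 = 1)
}

# ---- study fixtures (acceptance scale) ----

# 12^3 phantom, published protocol, Gaussian SNR 20 (recovery study)
fx_recovery <- function() fx_get("recovery", function() {
  ph <- generate_phantom(shape = c(12, 12, 12), lmax = 2, seed = 1)
  proto <- fx_protocol()
  nz <- add_noise(simulate_signals(ph, proto), proto,
                  noise_spec("gaussian", 20, seed = 2))
  list(phantom = ph, protocol = proto, noisy = nz)
})

fx_recovery_inr <- function() fx_get("recovery_inr", function() {
  fx <- fx_recovery()
  fit_sm_inr(fx$noisy$signals, fx$protocol, lmax = 2, n_p = 512, n_h = 256,
             sigma2 = 0.3, epochs = 150, batch_size = 500, seed = 1)
})

fx_recovery_nlls <- function() fx_get("recovery_nlls", function() {
  fx <- fx_recovery()
  fit_sm_nlls(fx$noisy$signals, fx$protocol, lmax = 2, seed = 1)
})

# 12^3 phantom with Rician SNR-20 noise (bias study)
fx_rician_study <- function() fx_get("rician_study", function() {
  fx <- fx_recovery()
  nz <- add_noise(simulate_signals(fx$phantom, fx$protocol), fx$protocol,
                  noise_spec("rician", 20, seed = 3))
  list(phantom = fx$phantom, protocol = fx$protocol, noisy = nz)
})

# 10^3 SNR-50 phantom (upsampling study)
fx_upsample_study <- function() fx_get("upsample_study", function() {
  proto <- fx_protocol()
  ph <- generate_phantom(shape = c(10, 10, 10), lmax = 2, seed = 1)
  nz <- add_noise(simulate_signals(ph, proto), proto,
                  noise_spec("gaussian", 50, seed = 5))
  list(phantom = ph, protocol = proto, noisy = nz)
})

# small 6^3 SNR-30 dataset for fast fitting tests
fx_small <- function() fx_get("small", function() {
  proto <- fx_protocol()
  ph <- generate_phantom(shape = c(6, 6, 6), lmax = 2, seed = 3)
  nz <- add_noise(simulate_signals(ph, proto), proto,
                  noise_spec("gaussian", 30, seed = 4))
  list(phantom = ph, protocol = proto, noisy = nz)
})
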