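test_that("MSE loss is the plain mean of squared differences", {
  expect_equal(mse_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse_loss(c(1, 1), c(0, 2)), 1)
  expect_false(mse_loss(c(1, 2), c(2, 1)) == mse_loss(c(1, 2), c(1, 2)))
  expect_error(mse_loss(1:3, 1:2), "mismatch")
})

test_that("Rician loss is consistent where least squares is biased", {
  set.seed(5)
  n <- 1e5
  sg <- 0.25
  draws <- sqrt((1 + rnorm(n) * sg)^2 + (rnorm(n) * sg)^2)
  nu_ric <- optimize(function(nu) rician_nll_loss(draws, rep(nu, n), sg),
                     c(0.2, 2))$minimum
  nu_mse <- optimize(function(nu) mse_loss(draws, rep(nu, n)),
                     c(0.2, 2))$minimum
  expect_lt(abs(nu_ric - 1), 0.01)      # likelihood recovers the amplitude
  expect_gt(nu_mse, 1.02)               # least squares chases the Rician mean
  # log I0 overflow guard: finite at huge argument
  expect_true(is.finite(rician_nll_loss(1, 1, 1e-3)))
  # asymptotic branch continuous with the Bessel branch
  x <- 5e4
  direct <- x + log(besselI(x, 0, expon.scaled = TRUE))
  expect_equal(sminr:::log_bessel_i0(x + 1), direct + 1 - 1 / (2 * x),
               tolerance = 1e-4)
  expect_error(rician_nll_loss(1, 1, 0), "sigma")
})

test_that("FOD non-negativity penalty has its closed-form values", {
  dirs <- hemisphere_directions(300)
  expect_equal(fod_nonneg_penalty(c(1 / sqrt(4 * pi), rep(0, 5)), dirs), 0)
  expect_equal(fod_nonneg_penalty(c(-1, rep(0, 5)), dirs), 1 / sqrt(4 * pi),
               tolerance = 1e-12)
  set.seed(6)
  p <- rnorm(15)
  expect_equal(fod_nonneg_penalty(3 * p, dirs), 3 * fod_nonneg_penalty(p, dirs),
               tolerance = 1e-12)
})

test_that("training reduces the loss and reproduces exactly under a seed", {
  fx <- fx_small()
  f1 <- fit_sm_inr(fx$noisy$signals, fx$protocol, lmax = 2, n_p = 64,
                   n_h = 48, sigma2 = 0.3, epochs = 8, seed = 5)
  expect_lt(f1$trace[length(f1$trace)], f1$trace[1])
  f2 <- fit_sm_inr(fx$noisy$signals, fx$protocol, lmax = 2, n_p = 64,
                   n_h = 48, sigma2 = 0.3, epochs = 8, seed = 5)
  expect_identical(coef(f1), coef(f2))
  expect_error(fit_sm_inr(fx$noisy$signals, fx$protocol, loss = "rician"),
               "sigma_map")
})

test_that("a noiseless phantom is fitted to below 1% signal error", {
  proto <- fx_protocol()
  ph <- generate_phantom(shape = c(8, 8, 8), lmax = 2, seed = 4)
  sig <- simulate_signals(ph, proto)
  fit <- fit_sm_inr(sig, proto, lmax = 2, n_p = 256, n_h = 256,
                    sigma2 = 0.3, epochs = 150, seed = 1)
  res <- residuals(fit)
  expect_lt(sqrt(mean(res^2)), 0.01)    # mean b0 signal is 1
})

test_that("constant-parameter phantoms yield near-constant maps", {
  proto <- fx_protocol()
  ph <- generate_phantom(shape = c(8, 8, 8), lmax = 2, seed = 9,
                         smoothness_mm = Inf)
  expect_lt(max(apply(ph$theta, 2, sd)), 1e-12)
  nz <- add_noise(simulate_signals(ph, proto), proto,
                  noise_spec("gaussian", 50, seed = 10))
  fit <- fit_sm_inr(nz$signals, proto, lmax = 2, n_p = 128, n_h = 64,
                    sigma2 = 0.3, epochs = 100, seed = 1)
  est <- coef(fit)
  cov <- apply(est[, 1:4], 2, function(v) sd(v) / mean(v))
  expect_true(all(cov < 0.02))
})

test_that("numeric-integration training runs and reduces the loss", {
  # planar-encoded protocol forces the quadrature path
  set.seed(11)
  u <- matrix(rnorm(30), 10, 3)
  u <- u / sqrt(rowSums(u^2))
  proto <- sm_protocol(c(0, 0, rep(2, 4), rep(1, 4)),
                       c(1, 1, rep(-0.5, 4), rep(1, 4)), u)
  ph <- generate_phantom(shape = c(4, 4, 4), lmax = 2, seed = 12)
  S <- matrix(0, 64, proto$n)
  nq <- sminr:::compile_numeric(proto, 2)
  S <- sminr:::sm_numeric_forward(ph$theta, ph$fod, nq)$S
  dwi <- volume_grid(array(S, c(4, 4, 4, proto$n)))
  fit <- fit_sm_inr(dwi, proto, lmax = 2, n_p = 32, n_h = 24, sigma2 = 0.3,
                    epochs = 4, batch_size = 64, seed = 2)
  expect_equal(fit$config$integration, "numeric")
  expect_lt(fit$trace[length(fit$trace)], fit$trace[1])
})

test_that("save/load/resume reproduces an uninterrupted training run", {
  fx <- fx_small()
  full <- fit_sm_inr(fx$noisy$signals, fx$protocol, lmax = 2, n_p = 64,
                     n_h = 48, sigma2 = 0.3, epochs = 4, seed = 9)
  half <- fit_sm_inr(fx$noisy$signals, fx$protocol, lmax = 2, n_p = 64,
                     n_h = 48, sigma2 = 0.3, epochs = 2, seed = 9)
  f <- withr::local_tempfile()
  save_model(half, f)
  resumed <- fit_sm_inr(fx$noisy$signals, fx$protocol, lmax = 2,
                        epochs = 2, seed = 9, model = load_model(f)$model)
  expect_equal(resumed$model$trace, full$trace, tolerance = 1e-12)
  expect_identical(coef(resumed), coef(full))
})

test_that("upsampling at factor 1 reproduces the training grid", {
  fx <- fx_small()
  fit <- fit_sm_inr(fx$noisy$signals, fx$protocol, lmax = 2, n_p = 64,
                    n_h = 48, sigma2 = 0.3, epochs = 2, seed = 5)
  maps <- upsample(fit, 1)
  est <- coef(fit)
  expect_equal(matrix(maps$data, ncol = ncol(est)), est,
               ignore_attr = TRUE, tolerance = 1e-12)
  up <- upsample(fit, 3)
  expect_equal(dim(up$data), c(18L, 18L, 18L, 11L))
  expect_true(all(is.finite(up$data)))
  expect_equal(up$voxel_size, fx$noisy$signals$voxel_size / 3)
})
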