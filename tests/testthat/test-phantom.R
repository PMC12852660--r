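test_that("phantom fields respect bounds, validity and unit FOD integral", {
  ph <- generate_phantom(shape = c(8, 8, 8), lmax = 2, seed = 1)
  th <- ph$theta
  expect_true(all(th[, "f_i"] >= 0.3 & th[, "f_i"] <= 0.8))
  expect_true(all(th[, "D_i"] >= 1.5 & th[, "D_i"] <= 3.0))
  expect_true(all(th[, "De_par"] >= 1.0 & th[, "De_par"] <= 2.5))
  expect_true(all(th[, "De_perp"] < th[, "De_par"]))
  expect_true(all(th[, "De_perp"] <= 1.5))
  expect_equal(ph$fod[, 1], rep(1 / sqrt(4 * pi), nrow(ph$fod)))
  # non-negative FOD amplitudes on a 300-direction test set (tiny
  # band-limit truncation dips below 1e-3 of peak are tolerated)
  dirs <- hemisphere_directions(300)
  amp <- fod_amplitude(ph$fod, dirs)
  expect_gt(min(amp), -1e-3 * max(amp))
  expect_error(generate_phantom(shape = c(3, 8, 8)), ">= 4")
})

test_that("smoothness controls the spatial autocorrelation of the fields", {
  ph <- generate_phantom(shape = c(10, 10, 10), voxel_size = c(2, 2, 2),
                         lmax = 2, seed = 2, smoothness_mm = 6)  # 3 voxels
  f <- array(ph$theta[, "f_i"], c(10, 10, 10))
  lag1 <- cor(c(f[-10, , ]), c(f[-1, , ]))
  expect_gt(lag1, 0.9)
  # a barely-smoothed phantom decorrelates much faster
  ph0 <- generate_phantom(shape = c(10, 10, 10), lmax = 2, seed = 2,
                          smoothness_mm = 1)
  f0 <- array(ph0$theta[, "f_i"], c(10, 10, 10))
  expect_lt(cor(c(f0[-10, , ]), c(f0[-1, , ])), lag1)
})

test_that("crossing phantoms place two peak pairs at the configured angle", {
  ph <- generate_phantom(shape = c(6, 6, 6), lmax = 6, seed = 7,
                         fiber_config = "crossing", crossing_angle = 90)
  pp <- phantom_params_at(ph, matrix(c(3.5, 3.5, 3.5), 1))
  g <- sphere_grid(121, 241, type = "gauss")
  amp <- fod_amplitude(drop(pp$fod), g$dirs)
  top <- g$dirs[order(-amp)[1:200], ]
  d1 <- top[1, ]
  second <- top[abs(top %*% d1) < 0.7, , drop = FALSE]
  expect_gt(nrow(second), 0)
  ang <- acos(min(1, abs(sum(d1 * second[1, ])))) * 180 / pi
  expect_lt(abs(ang - 90), 5)
})

test_that("simulated signals follow the forward model's structure", {
  fx <- fx_small()
  proto <- fx$protocol
  sig <- simulate_signals(fx$phantom, proto)
  b0 <- which(proto$b == 0)
  for (i in b0)
    expect_equal(c(sig$data[, , , i]), rep(1, 216), tolerance = 1e-12)
  # shell-mean signal decreases with b across linear-encoding shells
  lte <- proto$b_delta > 0.9
  shell_b <- sort(unique(proto$b[lte]))
  means <- sapply(shell_b, function(b)
    mean(sig$data[, , , proto$b == b & lte]))
  expect_true(all(diff(means) < 0))
  sig2 <- simulate_signals(fx$phantom, proto)
  expect_identical(sig$data, sig2$data)
})

test_that("noise generation matches the stated sigma rule and distributions", {
  fx <- fx_small()
  sig <- simulate_signals(fx$phantom, fx$protocol)
  # kind none is the identity with a zero sigma map
  id <- add_noise(sig, fx$protocol, noise_spec("none"))
  expect_identical(id$signals$data, sig$data)
  expect_true(all(id$sigma$data == 0))
  # S0 = 1, SNR = 20 -> sigma = 0.05 everywhere in the mask
  nz <- add_noise(sig, fx$protocol, noise_spec("gaussian", 20, seed = 1))
  expect_equal(c(nz$sigma$data), rep(0.05, 216), tolerance = 1e-12)
  expect_identical(add_noise(sig, fx$protocol,
                             noise_spec("gaussian", 20, seed = 1))$signals$data,
                   nz$signals$data)
  # empirical SNR on the b0 volumes recovers the target within 10%
  nz2 <- add_noise(sig, fx$protocol, noise_spec("gaussian", 25, seed = 2))
  b0 <- which(fx$protocol$b == 0)
  b0s <- matrix(nz2$signals$data[, , , b0], ncol = length(b0))
  snr_hat <- mean(b0s) / sd(b0s - rowMeans(b0s)) / sqrt(length(b0) /
                                                          (length(b0) - 1))
  expect_lt(abs(snr_hat - 25) / 25, 0.1)
  # Rician draws are positive; Rayleigh mean at S = 0 is sigma sqrt(pi/2)
  ric <- add_noise(sig, fx$protocol, noise_spec("rician", 20, seed = 3))
  expect_true(all(ric$signals$data > 0))
  sg <- 0.25
  draws <- sminr:::with_seed(8, sqrt((rnorm(1e5) * sg)^2 + (rnorm(1e5) * sg)^2))
  expect_lt(abs(mean(draws) - sg * sqrt(pi / 2)) / (sg * sqrt(pi / 2)), 0.01)
  expect_error(noise_spec("gaussian", -2), "positive")
})

test_that("continuous ground truth agrees between evaluation paths", {
  ph <- generate_phantom(shape = c(6, 6, 6), lmax = 4, seed = 5,
                         fiber_config = "fanning")
  t1 <- phantom_truth_maps(ph, 1)
  expect_equal(t1$theta, ph$theta, tolerance = 1e-12)
  expect_equal(t1$fod, ph$fod, tolerance = 1e-12)
  co <- sminr:::refined_voxel_centers(c(6, 6, 6), 2)
  pick <- c(1, 100, 863)
  direct <- phantom_params_at(ph, co[pick, ])
  t2 <- phantom_truth_maps(ph, 2)
  expect_equal(t2$theta[pick, ], direct$theta, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(t2$fod[pick, ], direct$fod, tolerance = 1e-10)
})
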