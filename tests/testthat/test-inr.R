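test_that("initialization is deterministic and matches the declared law", {
  m1 <- init_inr(5000, 16, sigma2 = 3.5, lmax = 2, seed = 11)
  m2 <- init_inr(5000, 16, sigma2 = 3.5, lmax = 2, seed = 11)
  X <- matrix(runif(30, -1, 1), 10, 3)
  expect_identical(sminr:::inr_forward(m1, X), sminr:::inr_forward(m2, X))
  # sample variance of the 5000 x 3 encoding entries within 5% of sigma2
  expect_lt(abs(var(as.numeric(m1$A)) - 3.5) / 3.5, 0.05)
  m8 <- init_inr(32, 16, lmax = 8, seed = 1)
  expect_equal(m8$n_out, 5L + 45L)
  expect_error(init_inr(32, 16, lmax = 3), "even")
})

test_that("coordinate scaling preserves aspect ratio and centers", {
  g <- list(shape = c(5L, 5L, 5L), voxel_size = c(2, 2, 2))
  sc <- coordinate_scaler(g)
  corners <- rbind(c(1, 1, 1), c(5, 5, 5))
  expect_equal(scale_coordinates(corners, sc),
               rbind(c(-1, -1, -1), c(1, 1, 1)), ignore_attr = TRUE)
  expect_equal(scale_coordinates(rbind(c(3, 3, 3)), sc),
               rbind(c(0, 0, 0)), ignore_attr = TRUE)
  # 100 x 50 x 50 mm extents: x spans [-1, 1], y and z span [-0.5, 0.5]
  g2 <- list(shape = c(11L, 6L, 6L), voxel_size = c(10, 10, 10))
  sc2 <- coordinate_scaler(g2)
  expect_equal(scale_coordinates(rbind(c(1, 1, 1), c(11, 6, 6)), sc2),
               rbind(c(-1, -0.5, -0.5), c(1, 0.5, 0.5)), ignore_attr = TRUE)
  expect_error(coordinate_scaler(list(shape = c(1L, 1L, 1L),
                                      voxel_size = c(1, 1, 1))), "degenerate")
})

test_that("Fourier encoding obeys its defining identities", {
  m <- init_inr(8, 4, seed = 2)
  m$A <- matrix(0, 8, 3)
  g <- fourier_encode(rbind(c(0.3, -0.2, 0.9)), m)
  expect_equal(drop(g), c(rep(1, 8), rep(0, 8)))
  m$A <- matrix(rnorm(24), 8, 3)
  X <- matrix(runif(60, -1, 1), 20, 3)
  G <- fourier_encode(X, m)
  expect_true(all(G >= -1 & G <= 1))
  expect_equal(dim(G), c(20L, 16L))
  # a row with A x = 1/4 lands on (cos, sin)(pi/2) = (0, 1)
  m$A[1, ] <- c(0.25, 0, 0)
  g <- fourier_encode(rbind(c(1, 0, 0)), m)
  expect_equal(g[1, 1], 0, tolerance = 1e-12)
  expect_equal(g[1, 9], 1, tolerance = 1e-12)
})

test_that("head architecture enforces bounds at every input", {
  m <- init_inr(64, 32, lmax = 4, seed = 3)
  # random nonzero heads so outputs explore the activation ranges
  m$Wh <- matrix(rnorm(32 * m$n_out, sd = 2), 32, m$n_out)
  set.seed(4)
  est <- predict(m, matrix(runif(3000, -1, 1), 1000, 3), scaled = TRUE)
  expect_true(all(est[, "f_i"] >= 0 & est[, "f_i"] <= 1))
  expect_true(all(est[, "D_i"] >= 0 & est[, "D_i"] <= 4))
  expect_true(all(est[, "De_par"] >= 0 & est[, "De_par"] <= 4))
  expect_true(all(est[, "De_perp"] >= 0 & est[, "De_perp"] <= 1.5))
  expect_true(all(est[, "S0"] >= 0))
  expect_equal(ncol(est), 5 + 15)
  # saturation reaches the bound endpoints
  mbig <- m
  mbig$bh <- c(rep(1e4, 4), 0, rep(0, m$n_c))
  est_hi <- predict(mbig, rbind(c(0, 0, 0)), scaled = TRUE)
  expect_equal(unname(est_hi[1, 1:4]), c(1, 4, 4, 1.5), tolerance = 1e-6)
  mbig$bh <- c(rep(-1e4, 4), 0, rep(0, m$n_c))
  est_lo <- predict(mbig, rbind(c(0, 0, 0)), scaled = TRUE)
  expect_equal(unname(est_lo[1, 1:4]), c(0, 0, 0, 0), tolerance = 1e-6)
  # continuity: vanishing input perturbation, vanishing output change
  x0 <- rbind(c(0.1, 0.2, -0.3))
  d1 <- max(abs(predict(m, x0 + 1e-4, scaled = TRUE) -
                  predict(m, x0, scaled = TRUE)))
  d2 <- max(abs(predict(m, x0 + 1e-6, scaled = TRUE) -
                  predict(m, x0, scaled = TRUE)))
  expect_lt(d2, d1)
  expect_lt(d2, 1e-3)
  expect_warning(predict(m, rbind(c(2, 0, 0)), scaled = TRUE),
                 "extrapolat")
})

test_that("encoding + MLP can regress a smooth scalar field to < 5% NRMSE", {
  m <- init_inr(128, 128, sigma2 = 0.5, lmax = 2, seed = 2, s0_scale = 1)
  co <- sminr:::refined_voxel_centers(c(12, 12, 12), 1)
  sc <- coordinate_scaler(list(shape = c(12L, 12L, 12L),
                               voxel_size = c(1, 1, 1)))
  X <- scale_coordinates(co, sc)
  y <- 1 + 0.4 * sin(pi * X[, 1]) * cos(pi * X[, 2]) + 0.3 * sin(pi * X[, 3] / 2)
  tens <- sminr:::model_tensors(m)
  st <- sminr:::adam_init()
  for (it in 1:400) {
    mm <- sminr:::set_model_tensors(m, tens)
    fw <- sminr:::inr_forward(mm, X, want_cache = TRUE)
    dtheta <- matrix(0, length(y), 5)
    dtheta[, 5] <- 2 * (fw$theta[, 5] - y) / length(y)
    g <- sminr:::inr_backward(mm, fw$cache, dtheta,
                              matrix(0, length(y), m$n_c))
    o <- sminr:::adam_step(st, tens, g, 1e-3)
    st <- o$state
    tens <- o$params
  }
  pred <- sminr:::inr_forward(sminr:::set_model_tensors(m, tens), X)$theta[, 5]
  expect_lt(sqrt(mean((pred - y)^2)) / sd(y), 0.05)
})
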