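test_that("zeppelin kernel collapses to its algebraic limits", {
  expect_equal(zeppelin_kernel(0, 1, 0.3, 2, 1), 1)
  expect_equal(zeppelin_kernel(2, 0.7, 0.3, 1.5, 1.5), exp(-2 * 1.5),
               tolerance = 1e-12)                 # isotropic: mean-D decay
  expect_equal(zeppelin_kernel(2, 0.4, 0.3, 1.5, 1.5),
               zeppelin_kernel(2, 0.9, -0.2, 1.5, 1.5), tolerance = 1e-12)
  expect_equal(zeppelin_kernel(3, 1, 1, 2.5, 0.8), exp(-3 * 2.5),
               tolerance = 1e-12)                 # bD=1, t=1: axial decay
  # stick limit equals the intra-axonal factor of the forward equation
  b <- 2; t <- 0.6; Di <- 2.2
  expect_equal(zeppelin_kernel(b, 1, t, Di, 0),
               exp(-b * t^2 * Di) * exp(b * Di / 3 - b * Di / 3),
               tolerance = 1e-12)
  expect_error(zeppelin_kernel(-1, 1, 0, 1, 1), "non-negative")
})

test_that("analytic signal satisfies its closed-form limits", {
  proto <- fx_protocol()
  set.seed(4)
  p <- c(1 / sqrt(4 * pi), rnorm(5) * 0.1)
  th <- kernel_params(0.6, 2.5, 1.8, 0.6, S0 = 1.3)
  S <- sm_signal_analytic(th, p, proto)
  b0 <- proto$b == 0
  expect_equal(S[b0], rep(1.3 * sqrt(4 * pi) * p[1], sum(b0)),
               tolerance = 1e-14)
  # spherical encoding: orientation-independent biexponential
  iso <- proto$b_delta == 0 & proto$b > 0
  b <- proto$b[iso][1]
  pred <- 1.3 * sqrt(4 * pi) * p[1] *
    (0.6 * exp(-b * 2.5 / 3) + 0.4 * exp(-b * (1.8 + 2 * 0.6) / 3))
  expect_equal(S[iso], rep(pred, sum(iso)), tolerance = 1e-12)
  # higher-degree coefficients are inert on the spherical shell
  p_mod <- p + c(0, rnorm(5))
  expect_equal(sm_signal_analytic(th, p_mod, proto)[iso], S[iso],
               tolerance = 1e-12)
})

test_that("orientation-averaged stick matches the 1-D quadrature oracle", {
  # f_i = 1, bD = 1, b D_i = 3 -> S/S0 = int_0^1 exp(-3 t^2) dt
  pr <- sm_protocol(1.5, 1, matrix(c(0, 0, 1), 1))
  S <- sm_signal_analytic(c(1, 2, 1.8, 0.6, 1), c(1 / sqrt(4 * pi), rep(0, 5)),
                          pr)
  oracle <- stats::integrate(function(t) exp(-3 * t^2), 0, 1,
                             rel.tol = 1e-12)$value
  expect_equal(S, oracle, tolerance = 1e-6)
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  expect_equal(S, sqrt(pi / (4 * 3)) * erf(sqrt(3)), tolerance = 1e-6)
})

test_that("analytic path rejects out-of-domain inputs by name", {
  pr <- sm_protocol(1, -0.5, matrix(c(0, 0, 1), 1))
  p <- c(1 / sqrt(4 * pi), rep(0, 5))
  expect_error(sm_signal_analytic(c(0.5, 2, 1.8, 0.6, 1), p, pr),
               "sm_signal_numeric")
  expect_error(sm_signal_analytic(c(0.5, 2, 0.6, 1.2, 1), p, fx_protocol()),
               "De_par > De_perp")
  expect_silent(sm_signal_numeric(c(0.5, 2, 0.6, 1.2, 1), p, pr))
})

test_that("signal decreases monotonically with b for a non-negative FOD", {
  u <- matrix(rep(c(0.48, -0.6, 0.64), 8), ncol = 3, byrow = TRUE)
  pr <- sm_protocol(seq(0.5, 8, length.out = 8), rep(1, 8), u)
  set.seed(5)
  for (i in 1:5) {
    th <- fx_random_theta()
    S <- sm_signal_analytic(th, fx_random_fod(4), pr)
    expect_true(all(diff(S) < 0))
  }
})

test_that("numeric quadrature path agrees with the analytic path", {
  proto <- fx_protocol()
  set.seed(6)
  for (lmax in c(2, 6)) {
    th <- fx_random_theta()
    p <- fx_random_fod(lmax)
    Sa <- sm_signal_analytic(th, p, proto)
    Sn <- sm_signal_numeric(th, p, proto)
    expect_lt(max(abs(Sa - Sn) / abs(Sa)), 1e-3)
  }
  expect_error(sm_signal_numeric(fx_random_theta(), fx_random_fod(8), proto,
                                 quadrature = sphere_grid(9, 9)), "coarse")
})

test_that("planar-shape orientation average matches a Monte-Carlo oracle", {
  # bD = -0.5, f_i = 0, isotropic FOD: compare the spherical integral of the
  # extra-axonal kernel against dense Monte-Carlo integration
  pr <- sm_protocol(3, -0.5, matrix(c(0, 0, 1), 1))
  th <- c(0, 2, 1.1, 0.5, 1)
  p <- c(1 / sqrt(4 * pi), rep(0, 5))
  S <- sm_signal_numeric(th, p, pr)
  set.seed(7)
  n <- 1e6
  z <- rnorm(n); y <- rnorm(n); x <- rnorm(n)
  t2 <- z^2 / (x^2 + y^2 + z^2)
  bbd <- 3 * -0.5
  dd <- 1.1 - 0.5
  pref <- exp(bbd * dd / 3 - 3 * (1.1 + 2 * 0.5) / 3)
  draws <- pref * exp(-bbd * t2 * dd)
  se <- sd(draws) / sqrt(n)
  expect_lt(abs(S - mean(draws)), 3 * se + 1e-6)
})

test_that("batched analytic gradients match finite differences", {
  proto <- fx_protocol()
  cp <- sminr:::compile_protocol(proto, 4)
  set.seed(8)
  V <- 2
  theta <- rbind(fx_random_theta(), fx_random_theta())
  p <- rbind(fx_random_fod(4), fx_random_fod(4))
  tgt <- matrix(rnorm(V * proto$n), V)
  fw <- sminr:::sm_batch_forward(theta, p, cp, want_grad = TRUE)
  bk <- sminr:::sm_batch_backward(tgt, theta, p, cp, fw$cache)
  lossf <- function(th, pp) sum(tgt * sminr:::sm_batch_forward(th, pp, cp)$S)
  eps <- 1e-6
  for (j in 1:5) {
    th1 <- theta; th1[1, j] <- th1[1, j] + eps
    th2 <- theta; th2[1, j] <- th2[1, j] - eps
    expect_equal(bk$dtheta[1, j], (lossf(th1, p) - lossf(th2, p)) / (2 * eps),
                 tolerance = 1e-5)
  }
  for (j in c(1, 4, 11)) {
    p1 <- p; p1[2, j] <- p1[2, j] + eps
    p2 <- p; p2[2, j] <- p2[2, j] - eps
    expect_equal(bk$dp[2, j], (lossf(theta, p1) - lossf(theta, p2)) / (2 * eps),
                 tolerance = 1e-5)
  }
  # single-voxel Jacobian agrees with the batch forward
  sj <- sminr:::sm_signal_jac(theta[1, ], p[1, ], cp)
  expect_equal(sj$S, drop(sminr:::sm_batch_forward(theta[1, , drop = FALSE],
                                                   p[1, , drop = FALSE],
                                                   cp)$S), tolerance = 1e-12)
})
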