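#' Axially symmetric (zeppelin) diffusion kernel
#'
#' Signal of a zeppelin compartment under b-tensor encoding:
#' \deqn{K(b, b_\Delta, t) = \exp[\tfrac13 b b_\Delta (D^\parallel -
#' D^\perp) - \tfrac13 b (D^\parallel + 2 D^\perp) - b b_\Delta t^2
#' (D^\parallel - D^\perp)]}
#' with \eqn{t = n \cdot u}. The stick kernel is the \eqn{D^\perp = 0} case.
#'
#' @param b b-value in ms/um^2 (>= 0).
#' @param b_delta b-tensor shape in [-0.5, 1].
#' @param t cosine between fiber and encoding axis, in [-1, 1].
#' @param D_par,D_perp axial/perpendicular diffusivity in um^2/ms (>= 0).
#' @return kernel value in (0, 1]; arguments recycle as usual.
#' @export
zeppelin_kernel <- function(b, b_delta, t, D_par, D_perp) {
  if (any(b < 0)) stop("b must be non-negative")
  if (any(abs(t) > 1 + 1e-12)) stop("t must lie in [-1, 1]")
  if (any(D_par < 0) || any(D_perp < 0)) stop("diffusivities must be >= 0")
  dd <- D_par - D_perp
  exp(b * b_delta * dd / 3 - b * (D_par + 2 * D_perp) / 3 -
        b * b_delta * t^2 * dd)
}

#' Kernel parameter set of the Standard Model
#'
#' Validating constructor for the five kernel parameters. The physiological
#' bounds enforced by the estimator heads are \code{f_i} in [0, 1],
#' \code{D_i} and \code{De_par} in [0, 4] um^2/ms, \code{De_perp} in
#' [0, 1.5] um^2/ms and \code{S0 >= 0}.
#'
#' @param f_i intra-axonal signal fraction.
#' @param D_i intra-axonal axial diffusivity (um^2/ms).
#' @param De_par,De_perp extra-axonal axial/perpendicular diffusivity.
#' @param S0 non-weighted signal.
#' @return named numeric vector of class \code{kernel_params}.
#' @export
kernel_params <- function(f_i, D_i, De_par, De_perp, S0 = 1) {
  p <- c(f_i = f_i, D_i = D_i, De_par = De_par, De_perp = De_perp, S0 = S0)
  if (any(!is.finite(p))) stop("kernel parameters must be finite")
  if (f_i < 0 || f_i > 1) stop("f_i outside [0, 1]")
  if (D_i < 0 || D_i > 4) stop("D_i outside [0, 4]")
  if (De_par < 0 || De_par > 4) stop("De_par outside [0, 4]")
  if (De_perp < 0 || De_perp > 1.5) stop("De_perp outside [0, 1.5]")
  if (S0 < 0) stop("S0 must be >= 0")
  structure(p, class = "kernel_params")
}

kernel_bounds <- function() {
  list(lo = c(f_i = 0, D_i = 0, De_par = 0, De_perp = 0),
       hi = c(f_i = 1, D_i = 4, De_par = 4, De_perp = 1.5))
}

# Precompute everything about a protocol that the batched forward model
# reuses: measurements grouped by unique (b, b_delta), the SH basis at the
# encoding directions, and the Legendre-projection quadrature tables.
compile_protocol <- function(protocol, lmax) {
  stopifnot(inherits(protocol, "sm_protocol"))
  check_lmax(lmax)
  key <- paste(signif(protocol$b, 12), signif(protocol$b_delta, 12))
  tab <- sh_index_table(lmax)
  groups <- lapply(unique(key), function(k) {
    idx <- which(key == k)
    list(idx = idx, b = protocol$b[idx[1]], bd = protocol$b_delta[idx[1]],
         Y = real_sh_basis(lmax, protocol$u[idx, , drop = FALSE]))
  })
  list(groups = groups, lmax = lmax, n_c = nrow(tab), n_m = protocol$n,
       lcol = tab$l / 2 + 1, protocol = protocol)
}

as_theta_matrix <- function(params) {
  if (inherits(params, "kernel_params")) params <- unclass(params)
  if (is.list(params)) params <- unlist(params)
  if (!is.matrix(params)) params <- matrix(params, nrow = 1)
  if (ncol(params) != 5) stop("expected 5 kernel parameters per voxel")
  colnames(params) <- c("f_i", "D_i", "De_par", "De_perp", "S0")
  params
}

# Batched analytic forward model over V voxels.  theta: V x 5 (f_i, D_i,
# De_par, De_perp, S0); p: V x n_c SH coefficients.  Returns the V x N_m
# signal matrix and, when want_grad, a cache consumed by sm_batch_backward.
sm_batch_forward <- function(theta, p, cp, want_grad = FALSE) {
  V <- nrow(theta)
  f <- theta[, 1]; Di <- theta[, 2]; Dpar <- theta[, 3]
  Dperp <- theta[, 4]; S0 <- theta[, 5]
  S <- matrix(0, V, cp$n_m)
  cache <- if (want_grad) vector("list", length(cp$groups)) else NULL
  for (gi in seq_along(cp$groups)) {
    g <- cp$groups[[gi]]
    bbd <- g$b * g$bd
    aI <- bbd * Di
    aE <- bbd * (Dpar - Dperp)
    RI <- legendre_proj_mat(aI, cp$lmax, deriv = want_grad)
    RE <- legendre_proj_mat(aE, cp$lmax, deriv = want_grad)
    if (want_grad) { dRI <- RI$dr; RI <- RI$r; dRE <- RE$dr; RE <- RE$r }
    RIc <- RI[, cp$lcol, drop = FALSE]
    REc <- RE[, cp$lcol, drop = FALSE]
    prefI <- exp((bbd - g$b) / 3 * Di)
    prefE <- exp(bbd * (Dpar - Dperp) / 3 - g$b * (Dpar + 2 * Dperp) / 3)
    uI <- (f * prefI) * RIc
    uE <- ((1 - f) * prefE) * REc
    W <- S0 * (uI + uE)
    S[, g$idx] <- (W * p) %*% t(g$Y)
    if (want_grad)
      cache[[gi]] <- list(RIc = RIc, REc = REc,
                          dRIc = dRI[, cp$lcol, drop = FALSE],
                          dREc = dRE[, cp$lcol, drop = FALSE],
                          prefI = prefI, prefE = prefE, uI = uI, uE = uE,
                          W = W)
  }
  list(S = S, cache = cache)
}

# Reverse-mode gradients of the batched analytic model: given dL/dS (V x
# N_m), returns dL/dtheta (V x 5) and dL/dp (V x n_c).
sm_batch_backward <- function(dS, theta, p, cp, cache) {
  V <- nrow(theta)
  f <- theta[, 1]; Di <- theta[, 2]; Dpar <- theta[, 3]
  Dperp <- theta[, 4]; S0 <- theta[, 5]
  dtheta <- matrix(0, V, 5)
  dp <- matrix(0, V, cp$n_c)
  for (gi in seq_along(cp$groups)) {
    g <- cp$groups[[gi]]
    cc <- cache[[gi]]
    bbd <- g$b * g$bd
    Tm <- dS[, g$idx, drop = FALSE] %*% g$Y      # V x n_c
    dp <- dp + cc$W * Tm
    M1 <- p * Tm                                  # dL/dW
    dtheta[, 5] <- dtheta[, 5] + rowSums((cc$uI + cc$uE) * M1)
    dtheta[, 1] <- dtheta[, 1] +
      rowSums((S0 * (cc$prefI * cc$RIc - cc$prefE * cc$REc)) * M1)
    dtheta[, 2] <- dtheta[, 2] + rowSums(
      (S0 * f * cc$prefI) *
        (((bbd - g$b) / 3) * cc$RIc + bbd * cc$dRIc) * M1)
    dtheta[, 3] <- dtheta[, 3] + rowSums(
      (S0 * (1 - f) * cc$prefE) *
        (((bbd - g$b) / 3) * cc$REc + bbd * cc$dREc) * M1)
    dtheta[, 4] <- dtheta[, 4] + rowSums(
      (S0 * (1 - f) * cc$prefE) *
        (((-bbd - 2 * g$b) / 3) * cc$REc - bbd * cc$dREc) * M1)
  }
  list(dtheta = dtheta, dp = dp)
}

# Signal and Jacobian for a single voxel (NLLS).  Returns S (N_m) and
# J (N_m x (5 + n_c)) with columns (f_i, D_i, De_par, De_perp, S0, p...).
sm_signal_jac <- function(theta, p, cp) {
  theta <- as_theta_matrix(theta)
  p <- as.numeric(p)
  f <- theta[1]; Di <- theta[2]; Dpar <- theta[3]
  Dperp <- theta[4]; S0 <- theta[5]
  S <- numeric(cp$n_m)
  J <- matrix(0, cp$n_m, 5 + cp$n_c)
  for (g in cp$groups) {
    bbd <- g$b * g$bd
    RI <- legendre_proj_mat(bbd * Di, cp$lmax, deriv = TRUE)
    RE <- legendre_proj_mat(bbd * (Dpar - Dperp), cp$lmax, deriv = TRUE)
    RIc <- RI$r[1, cp$lcol]; dRIc <- RI$dr[1, cp$lcol]
    REc <- RE$r[1, cp$lcol]; dREc <- RE$dr[1, cp$lcol]
    prefI <- exp((bbd - g$b) / 3 * Di)
    prefE <- exp(bbd * (Dpar - Dperp) / 3 - g$b * (Dpar + 2 * Dperp) / 3)
    uI <- f * prefI * RIc
    uE <- (1 - f) * prefE * REc
    W <- S0 * (uI + uE)
    S[g$idx] <- g$Y %*% (W * p)
    J[g$idx, 6:(5 + cp$n_c)] <- sweep(g$Y, 2, W, `*`)
    wf <- S0 * (prefI * RIc - prefE * REc)
    wDi <- S0 * f * prefI * (((bbd - g$b) / 3) * RIc + bbd * dRIc)
    wDpar <- S0 * (1 - f) * prefE * (((bbd - g$b) / 3) * REc + bbd * dREc)
    wDperp <- S0 * (1 - f) * prefE *
      (((-bbd - 2 * g$b) / 3) * REc - bbd * dREc)
    wS0 <- uI + uE
    J[g$idx, 1] <- g$Y %*% (wf * p)
    J[g$idx, 2] <- g$Y %*% (wDi * p)
    J[g$idx, 3] <- g$Y %*% (wDpar * p)
    J[g$idx, 4] <- g$Y %*% (wDperp * p)
    J[g$idx, 5] <- g$Y %*% (wS0 * p)
  }
  list(S = S, J = J)
}

#' Standard Model signal, analytic (Funk-Hecke) path
#'
#' Predicts the signal \eqn{S(b, b_\Delta, u)} of the two-compartment
#' stick-plus-zeppelin model convolved with an SH-parameterized FOD. Each SH
#' degree is scaled by the kernel's Legendre projection
#' ([legendre_projection()]): per measurement the intra-axonal term uses
#' \eqn{a_i = b b_\Delta D_i} with prefactor
#' \eqn{\exp(\tfrac13 b b_\Delta D_i - \tfrac13 b D_i)} and the extra-axonal
#' term uses \eqn{a_e = b b_\Delta (D_e^\parallel - D_e^\perp)} with
#' prefactor \eqn{\exp(\tfrac13 b b_\Delta (D_e^\parallel - D_e^\perp) -
#' \tfrac13 b (D_e^\parallel + 2 D_e^\perp))}, combined with weights
#' \eqn{f_i} and \eqn{1 - f_i}. Valid only for \eqn{b_\Delta \ge 0} and
#' \eqn{D_e^\parallel > D_e^\perp}; otherwise use [sm_signal_numeric()].
#'
#' @param params a [kernel_params()] (or named vector/list of the five
#'   parameters).
#' @param fod SH coefficient vector (even orders, see [sh_index_table()]).
#' @param protocol an [sm_protocol()].
#' @return predicted signal vector of length \code{protocol$n}.
#' @export
sm_signal_analytic <- function(params, fod, protocol) {
  theta <- as_theta_matrix(params)
  if (any(protocol$b_delta < 0))
    stop("analytic path requires b_delta >= 0 for every measurement; ",
         "use sm_signal_numeric()", call. = FALSE)
  if (theta[3] <= theta[4])
    stop("analytic path requires De_par > De_perp; use sm_signal_numeric()",
         call. = FALSE)
  lmax <- lmax_from_ncoef(length(fod))
  cp <- compile_protocol(protocol, lmax)
  drop(sm_batch_forward(theta, matrix(fod, 1), cp)$S)
}

#' Standard Model signal, numeric spherical-quadrature path
#'
#' Evaluates the two spherical convolution integrals of the forward model by
#' quadrature over the sphere (composite Simpson product grid by default).
#' Slower than [sm_signal_analytic()] but valid for negative b-tensor shapes
#' and any diffusivity ordering.
#'
#' @inheritParams sm_signal_analytic
#' @param quadrature a [sphere_grid()]; the default 65 x 97 Simpson grid
#'   resolves band limits up to lmax = 8 and attenuations up to
#'   \eqn{b b_\Delta D \approx 32} to better than 1e-3 relative.
#' @return predicted signal vector of length \code{protocol$n}.
#' @export
sm_signal_numeric <- function(params, fod, protocol, quadrature = sphere_grid()) {
  theta <- as_theta_matrix(params)
  lmax <- lmax_from_ncoef(length(fod))
  if (length(quadrature$weights) < 4 * (lmax + 1)^2)
    stop("quadrature grid too coarse for lmax = ", lmax)
  nq <- compile_numeric(protocol, lmax, quadrature)
  drop(sm_numeric_forward(theta, matrix(fod, 1), nq)$S)
}

compile_numeric <- function(protocol, lmax, quadrature = sphere_grid()) {
  B <- real_sh_basis(lmax, quadrature$dirs)
  t2 <- (quadrature$dirs %*% t(protocol$u))^2   # Q x N_m
  list(B = B, w = quadrature$weights, t2 = t2, protocol = protocol,
       lmax = lmax, n_c = ncol(B), n_m = protocol$n)
}

sm_numeric_forward <- function(theta, p, nq, want_grad = FALSE) {
  V <- nrow(theta)
  f <- theta[, 1]; Di <- theta[, 2]; Dpar <- theta[, 3]
  Dperp <- theta[, 4]; S0 <- theta[, 5]
  Pn <- p %*% t(nq$B)                            # V x Q amplitudes
  pr <- nq$protocol
  S <- matrix(0, V, nq$n_m)
  for (m in seq_len(nq$n_m)) {
    b <- pr$b[m]; bbd <- b * pr$b_delta[m]
    if (bbd == 0) {
      # constant kernel on the sphere: the integral is exactly
      # sqrt(4 pi) p00 by orthonormality
      II <- IE <- sqrt(4 * pi) * p[, 1]
    } else {
      t2 <- nq$t2[, m]
      KI <- exp(-outer(Di * bbd, t2))            # V x Q
      KE <- exp(-outer((Dpar - Dperp) * bbd, t2))
      II <- (KI * Pn) %*% nq$w
      IE <- (KE * Pn) %*% nq$w
    }
    prefI <- exp((bbd - b) / 3 * Di)
    prefE <- exp(bbd * (Dpar - Dperp) / 3 - b * (Dpar + 2 * Dperp) / 3)
    S[, m] <- S0 * (f * prefI * II + (1 - f) * prefE * IE)
  }
  list(S = S)
}

# Gradients for the numeric path (used when fitting with
# integration = "numeric").  Recomputes the per-measurement kernels; memory
# stays at V x Q.
sm_numeric_backward <- function(dS, theta, p, nq) {
  V <- nrow(theta)
  f <- theta[, 1]; Di <- theta[, 2]; Dpar <- theta[, 3]
  Dperp <- theta[, 4]; S0 <- theta[, 5]
  Pn <- p %*% t(nq$B)
  pr <- nq$protocol
  dtheta <- matrix(0, V, 5)
  dp <- matrix(0, V, ncol(p))
  wB <- nq$w * nq$B                              # Q x n_c
  for (m in seq_len(nq$n_m)) {
    b <- pr$b[m]; bbd <- b * pr$b_delta[m]
    t2 <- nq$t2[, m]
    if (bbd == 0) {
      II <- IE <- sqrt(4 * pi) * p[, 1]
      JI <- JE <- 0
      KI <- KE <- NULL
    } else {
      KI <- exp(-outer(Di * bbd, t2))
      KE <- exp(-outer((Dpar - Dperp) * bbd, t2))
      II <- (KI * Pn) %*% nq$w
      IE <- (KE * Pn) %*% nq$w
      JI <- (KI * Pn) %*% (nq$w * t2)            # d(II)/da with a = bbd*D
      JE <- (KE * Pn) %*% (nq$w * t2)
    }
    prefI <- exp((bbd - b) / 3 * Di)
    prefE <- exp(bbd * (Dpar - Dperp) / 3 - b * (Dpar + 2 * Dperp) / 3)
    G <- dS[, m]
    dtheta[, 5] <- dtheta[, 5] + G * (f * prefI * II + (1 - f) * prefE * IE)
    dtheta[, 1] <- dtheta[, 1] + G * S0 * (prefI * II - prefE * IE)
    dtheta[, 2] <- dtheta[, 2] + G * S0 * f * prefI *
      (((bbd - b) / 3) * II - bbd * JI)
    dtheta[, 3] <- dtheta[, 3] + G * S0 * (1 - f) * prefE *
      (((bbd - b) / 3) * IE - bbd * JE)
    dtheta[, 4] <- dtheta[, 4] + G * S0 * (1 - f) * prefE *
      (((-bbd - 2 * b) / 3) * IE + bbd * JE)
    CI <- G * S0 * f * prefI
    CE <- G * S0 * (1 - f) * prefE
    if (bbd == 0) {
      dp[, 1] <- dp[, 1] + (CI + CE) * sqrt(4 * pi)
    } else {
      dp <- dp + (CI * KI + CE * KE) %*% wB
    }
  }
  list(dtheta = dtheta, dp = dp)
}
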