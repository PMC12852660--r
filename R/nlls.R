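# Smooth reparameterization that enforces the physiological bounds and the
# analytic-path validity De_perp < De_par:
#   f_i    = sigmoid(x1)
#   D_i    = 4 sigmoid(x2)
#   De_par = 4 sigmoid(x3)
#   De_perp= sigmoid(x4) * min(De_par, 1.5)
#   S0     = exp(x5)
#   p_lm   = x6...
nlls_unpack <- function(x, n_c) {
  f <- sigmoid(x[1])
  Di <- 4 * sigmoid(x[2])
  Dpar <- 4 * sigmoid(x[3])
  cap <- min(Dpar, 1.5)
  Dperp <- sigmoid(x[4]) * cap
  S0 <- exp(x[5])
  list(theta = cbind(f_i = f, D_i = Di, De_par = Dpar, De_perp = Dperp,
                     S0 = S0),
       p = matrix(x[6:(5 + n_c)], 1))
}

# chain rule d(model params)/d(x) as a (5 + n_c) x (5 + n_c) sparse-ish
# Jacobian applied to the forward-model Jacobian
nlls_chain <- function(x, J, n_c) {
  s1 <- sigmoid(x[1]); s2 <- sigmoid(x[2]); s3 <- sigmoid(x[3])
  s4 <- sigmoid(x[4])
  Dpar <- 4 * s3
  cap <- min(Dpar, 1.5)
  Jx <- J
  Jx[, 1] <- J[, 1] * s1 * (1 - s1)
  Jx[, 2] <- J[, 2] * 4 * s2 * (1 - s2)
  dDpar_dx3 <- 4 * s3 * (1 - s3)
  dcap_dx3 <- if (Dpar < 1.5) dDpar_dx3 else 0
  Jx[, 3] <- J[, 3] * dDpar_dx3 + J[, 4] * s4 * dcap_dx3
  Jx[, 4] <- J[, 4] * cap * s4 * (1 - s4)
  Jx[, 5] <- J[, 5] * exp(x[5])
  Jx
}

nlls_pack_init <- function(theta, p) {
  clamp <- function(z) pmin(1 - 1e-6, pmax(1e-6, z))
  logit <- function(z) log(z / (1 - z))
  Dpar <- theta[3]
  cap <- min(Dpar, 1.5)
  c(logit(clamp(theta[1])), logit(clamp(theta[2] / 4)),
    logit(clamp(Dpar / 4)), logit(clamp(theta[4] / cap)),
    log(max(theta[5], 1e-6)), p)
}

#' Voxel-wise nonlinear least-squares Standard Model fit
#'
#' Minimizes the sum of squared signal residuals over the kernel parameters
#' and SH coefficients jointly, using Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]) with an analytic Jacobian. Bounds and analytic
#' validity (\code{De_par > De_perp}) are enforced by a smooth
#' reparameterization. Several initializations are fitted — one data-driven
#' (log-signal diffusivity heuristics, isotropic FOD) and the rest random
#' within bounds — and the solution with the smallest residual norm is
#' returned. No FOD non-negativity constraint is applied.
#'
#' @param signal measured signal vector (length \code{protocol$n}).
#' @param protocol an [sm_protocol()] with non-negative b-tensor shapes.
#' @param lmax even SH band limit.
#' @param n_init number of initializations (>= 1).
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @param seed seed for the random initializations.
#' @param cp optional precompiled protocol (internal reuse).
#' @return list of class \code{sm_nlls_voxel}: \code{theta}, \code{fod},
#'   \code{residual_norm}, \code{converged}, \code{init_index},
#'   \code{identifiable}.
#' @export
nlls_fit_voxel <- function(signal, protocol, lmax = 2, n_init = 2,
                           max_iter = 1000, seed = 1, cp = NULL) {
  if (length(signal) != protocol$n) stop("signal length != protocol$n")
  if (is.null(cp)) cp <- compile_protocol(protocol, lmax)
  n_c <- cp$n_c
  b0 <- protocol$b < 1e-9
  if (all(b0)) {
    return(structure(list(
      theta = cbind(f_i = NA_real_, D_i = NA_real_, De_par = NA_real_,
                    De_perp = NA_real_, S0 = mean(signal)),
      fod = matrix(c(1 / sqrt(4 * pi), rep(0, n_c - 1)), 1),
      residual_norm = stats::sd(signal) * sqrt(max(length(signal) - 1, 0)),
      converged = FALSE, init_index = NA_integer_, identifiable = FALSE),
      class = "sm_nlls_voxel"))
  }

  S0_init <- if (any(b0)) mean(signal[b0]) else max(signal)
  S0_init <- max(S0_init, 1e-6)
  # mean apparent diffusivity from the lowest LTE shell as a starting point
  lte <- which(!b0 & protocol$b_delta > 0.9)
  md <- if (length(lte)) {
    bref <- min(protocol$b[lte])
    srat <- mean(signal[lte][protocol$b[lte] == bref]) / S0_init
    max(min(-log(max(srat, 1e-3)) / bref, 3), 0.3)
  } else 1
  p_iso <- c(1 / sqrt(4 * pi), rep(0, n_c - 1))
  inits <- list(nlls_pack_init(c(0.5, min(3 * md, 3.5), min(2 * md, 3.5),
                                 min(0.8 * md, 1.4), S0_init), p_iso))
  if (n_init > 1) {
    rand <- with_seed(seed, lapply(seq_len(n_init - 1), function(i) {
      th <- c(stats::runif(1, 0.1, 0.9), stats::runif(1, 0.5, 3.5),
              stats::runif(1, 0.5, 3.5), stats::runif(1, 0.1, 1.2),
              S0_init * stats::runif(1, 0.8, 1.2))
      th[4] <- min(th[4], 0.9 * th[3])
      nlls_pack_init(th, p_iso * stats::runif(1, 0.5, 1.5))
    }))
    inits <- c(inits, rand)
  }

  resid_fn <- function(x) {
    u <- nlls_unpack(x, n_c)
    drop(sm_batch_forward(u$theta, u$p, cp)$S) - signal
  }
  jac_fn <- function(x) {
    u <- nlls_unpack(x, n_c)
    J <- sm_signal_jac(u$theta, u$p, cp)$J
    nlls_chain(x, J, n_c)
  }

  best <- NULL
  for (i in seq_along(inits)) {
    fit <- try(suppressWarnings(minpack.lm::nls.lm(
      par = inits[[i]], fn = resid_fn, jac = jac_fn,
      control = minpack.lm::nls.lm.control(maxiter = min(max_iter, 1024)))),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn)
      best <- list(fit = fit, rn = rn, idx = i)
  }
  if (is.null(best)) {
    return(structure(list(theta = matrix(NA_real_, 1, 5), fod =
                            matrix(NA_real_, 1, n_c),
                          residual_norm = NA_real_, converged = FALSE,
                          init_index = NA_integer_, identifiable = TRUE),
                     class = "sm_nlls_voxel"))
  }
  u <- nlls_unpack(best$fit$par, n_c)
  structure(list(theta = u$theta, fod = u$p, residual_norm = best$rn,
                 converged = best$fit$info %in% 1:4, init_index = best$idx,
                 identifiable = TRUE),
            class = "sm_nlls_voxel")
}

#' Voxel-wise NLLS fit of a volume
#'
#' Independent [nlls_fit_voxel()] fits at every masked voxel, optionally
#' with per-voxel effective protocols from a gradient-coil tensor field.
#'
#' @param dwi 4-D [volume_grid()] (or array) of signals.
#' @param protocol an [sm_protocol()].
#' @param mask 3-D logical mask.
#' @param lmax even SH band limit.
#' @param grad_tensor optional 9-component gradient-coil tensor field (see
#'   [fit_sm_inr()]).
#' @param n_init,max_iter,seed per-voxel settings (see [nlls_fit_voxel()]).
#' @param verbose log progress every 500 voxels.
#' @return object of class \code{sm_nlls_fit} with per-voxel parameter and
#'   coefficient matrices, residual norms and convergence flags.
#' @export
fit_sm_nlls <- function(dwi, protocol, mask = NULL, lmax = 2,
                        grad_tensor = NULL, n_init = 2, max_iter = 1000,
                        seed = 1, verbose = FALSE) {
  if (!inherits(dwi, "volume_grid")) dwi <- volume_grid(dwi)
  if (length(dim(dwi$data)) != 4 || dim(dwi$data)[4] != protocol$n)
    stop("dwi must be 4-D with one volume per protocol measurement")
  mask <- as_mask_array(mask, dwi$shape)
  if (!any(mask)) stop("empty mask")
  vox <- which(mask)
  nvox <- length(vox)
  S <- matrix(dwi$data, prod(dwi$shape), protocol$n)[vox, , drop = FALSE]

  Lmat <- NULL
  if (!is.null(grad_tensor)) {
    gt <- if (inherits(grad_tensor, "volume_grid")) grad_tensor$data
          else grad_tensor
    if (length(dim(gt)) != 4 || dim(gt)[4] != 9)
      stop("grad_tensor must have 9 components")
    Lmat <- matrix(gt, prod(dwi$shape), 9)[vox, , drop = FALSE]
    if (all(Lmat == rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = nvox)))
      Lmat <- NULL
  }

  cp <- compile_protocol(protocol, lmax)
  n_c <- cp$n_c
  theta <- matrix(NA_real_, nvox, 5,
                  dimnames = list(NULL, c("f_i", "D_i", "De_par", "De_perp",
                                          "S0")))
  fod <- matrix(NA_real_, nvox, n_c)
  rn <- rep(NA_real_, nvox)
  conv <- logical(nvox)
  for (v in seq_len(nvox)) {
    cpv <- cp
    prv <- protocol
    if (!is.null(Lmat)) {
      prv <- effective_protocol(protocol, matrix(Lmat[v, ], 3, 3,
                                                 byrow = TRUE))
      cpv <- compile_protocol(prv, lmax)
    }
    r <- nlls_fit_voxel(S[v, ], prv, lmax = lmax, n_init = n_init,
                        max_iter = max_iter, seed = seed + v, cp = cpv)
    theta[v, ] <- r$theta
    fod[v, ] <- r$fod
    rn[v] <- r$residual_norm
    conv[v] <- r$converged
    if (verbose && v %% 500 == 0)
      message("NLLS voxel ", v, " / ", nvox)
  }
  structure(list(theta = theta, fod = fod, residual_norm = rn,
                 converged = conv, mask = mask, voxels = vox,
                 grid = list(shape = dwi$shape,
                             voxel_size = dwi$voxel_size,
                             affine = dwi$affine),
                 lmax = as.integer(lmax), protocol = protocol),
            class = "sm_nlls_fit")
}

#' @export
print.sm_nlls_fit <- function(x, ...) {
  cat("Voxel-wise NLLS Standard Model fit\n")
  cat(sprintf("  %d voxels, lmax = %d; converged: %d (%.1f%%)\n",
              length(x$voxels), x$lmax, sum(x$converged),
              100 * mean(x$converged)))
  cat(sprintf("  median residual norm %.4g\n",
              stats::median(x$residual_norm, na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.sm_nlls_fit <- function(object, ...) {
  cbind(object$theta, object$fod)
}
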