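#' Mean squared error between signal vectors
#'
#' @param S_meas,S_pred equal-length signal vectors.
#' @return mean of squared differences.
#' @export
mse_loss <- function(S_meas, S_pred) {
  if (length(S_meas) != length(S_pred)) stop("signal length mismatch")
  mean((S_meas - S_pred)^2)
}

# log I0(x), numerically stable for all x >= 0: exponentially scaled Bessel
# function for moderate x, asymptotic series
# log I0(x) ~ x - log(2 pi x)/2 + log(1 + 1/(8x) + 9/(128 x^2)) beyond the
# range where the scaled Bessel underflows.
log_bessel_i0 <- function(x) {
  x <- abs(x)                    # I0 is even
  out <- x
  lo <- x < 5e4
  if (any(lo))
    out[lo] <- x[lo] + log(besselI(x[lo], 0, expon.scaled = TRUE))
  if (any(!lo)) {
    xl <- x[!lo]
    out[!lo] <- xl - 0.5 * log(2 * pi * xl) +
      log1p(1 / (8 * xl) + 9 / (128 * xl^2))
  }
  out
}

bessel_i1_i0_ratio <- function(x) {
  sgn <- sign(x)                 # I1/I0 is odd
  x <- abs(x)
  out <- x
  lo <- x < 5e4
  if (any(lo))
    out[lo] <- besselI(x[lo], 1, expon.scaled = TRUE) /
      besselI(x[lo], 0, expon.scaled = TRUE)
  if (any(!lo)) {
    xl <- x[!lo]
    out[!lo] <- 1 - 1 / (2 * xl) - 1 / (8 * xl^2)
  }
  sgn * out
}

#' Rician negative log-likelihood loss
#'
#' Mean over measurements of \eqn{\nu^2/(2\sigma^2) - \log I_0(S \nu /
#' \sigma^2)} with \eqn{\nu} the noise-free signal prediction: the
#' \eqn{\nu}-dependent part of the Rician negative log-likelihood. Fitting
#' this loss removes the positive magnitude bias that a least-squares fit
#' inherits from Rician noise. Differentiable in \eqn{\nu}.
#'
#' @param S_meas measured magnitudes (>= 0).
#' @param S_pred predicted noise-free signal \eqn{\nu}.
#' @param sigma noise standard deviation, scalar or per measurement (> 0).
#' @return scalar loss.
#' @export
rician_nll_loss <- function(S_meas, S_pred, sigma) {
  if (length(S_meas) != length(S_pred)) stop("signal length mismatch")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  s2 <- sigma^2
  mean(S_pred^2 / (2 * s2) - log_bessel_i0(S_meas * S_pred / s2))
}

#' FOD non-negativity penalty
#'
#' Samples the FOD on a fixed spherical direction set and averages the
#' magnitudes of negative amplitudes:
#' \eqn{\Lambda = \mathrm{mean}_n \max(0, -P(n))}. Zero exactly when the FOD
#' is non-negative on the sample set; positively homogeneous of degree one
#' in the coefficients.
#'
#' @param coeffs SH coefficient vector or matrix (voxels in rows).
#' @param constraint_dirs direction set (default 300 electrostatic-repulsion
#'   directions).
#' @return scalar penalty (or vector, one per voxel row).
#' @export
fod_nonneg_penalty <- function(coeffs,
                               constraint_dirs = hemisphere_directions(300)) {
  amp <- fod_amplitude(coeffs, constraint_dirs)
  if (is.matrix(amp)) rowMeans(pmax(0, -amp)) else mean(pmax(0, -amp))
}

adam_init <- function() list(t = 0L, m = list(), v = list())

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    if (is.null(state$m[[k]])) {
      state$m[[k]] <- g * 0
      state$v[[k]] <- g * 0
    }
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(state = state, params = params)
}

model_tensors <- function(model) {
  list(Wh = model$Wh, bh = model$bh,
       W1 = model$layers[[1]]$W, b1 = model$layers[[1]]$b,
       W2 = model$layers[[2]]$W, b2 = model$layers[[2]]$b,
       W3 = model$layers[[3]]$W, b3 = model$layers[[3]]$b,
       W4 = model$layers[[4]]$W, b4 = model$layers[[4]]$b)
}

set_model_tensors <- function(model, tensors) {
  model$Wh <- tensors$Wh
  model$bh <- tensors$bh
  for (i in 1:4) {
    model$layers[[i]]$W <- tensors[[paste0("W", i)]]
    model$layers[[i]]$b <- tensors[[paste0("b", i)]]
  }
  model
}

#' Fit the Standard Model to a dMRI dataset with an implicit neural
#' representation
#'
#' Self-supervised fit: the network ([init_inr()]) maps masked voxel-center
#' coordinates to SM kernel parameters and FOD coefficients, the forward
#' model predicts the signal for every measurement, and the weights are
#' trained with Adam to minimize, per voxel, the summed per-measurement data
#' loss (MSE or Rician negative log-likelihood) plus the FOD non-negativity
#' penalty, averaged over the batch. The full dataset is used every epoch in
#' shuffled batches; there is no train/test split because the goal is to
#' represent this dataset, not to generalize beyond it.
#'
#' @param dwi 4-D [volume_grid()] (or array) of diffusion-weighted signals;
#'   4th dimension matches the protocol.
#' @param protocol an [sm_protocol()].
#' @param mask 3-D logical mask ([volume_grid()] or array); only masked
#'   voxels contribute to the loss.
#' @param lmax even SH band limit of the estimated FOD.
#' @param loss \code{"mse"} or \code{"rician"} (the latter requires
#'   \code{sigma_map}).
#' @param sigma_map per-voxel noise standard deviation for the Rician loss.
#' @param grad_tensor optional per-voxel 3 x 3 gradient-coil tensor field
#'   (4-D array/volume with 9 components in row-major order); when given,
#'   the per-voxel effective protocols replace the nominal one.
#' @param n_p,n_h,sigma2 architecture hyperparameters (see [init_inr()]).
#' @param lr,epochs,batch_size Adam learning rate, epochs, batch size.
#' @param integration \code{"auto"} picks the analytic Funk-Hecke path when
#'   all b-tensor shapes are non-negative, otherwise spherical quadrature.
#' @param nonneg_weight weight of the FOD non-negativity penalty (averaged
#'   over directions, so it is scale-comparable to the data term).
#' @param nonneg_dirs number of constraint directions.
#' @param seed seed controlling initialization and batch shuffling; fits are
#'   bit-reproducible given the seed.
#' @param model optional warm-start [init_inr()] model (e.g. from
#'   [load_model()]) whose training is resumed.
#' @param verbose print the epoch loss every few epochs.
#' @return object of class \code{sm_inr_fit} with the trained model, the
#'   per-epoch mean loss trace, and the fit context; see
#'   [predict.sm_inr_fit()], [coef.sm_inr_fit()], [residuals.sm_inr_fit()],
#'   [upsample()].
#' @export
fit_sm_inr <- function(dwi, protocol, mask = NULL, lmax = 2,
                       loss = c("mse", "rician"), sigma_map = NULL,
                       grad_tensor = NULL, n_p = 5000, n_h = 2048,
                       sigma2 = 3.5, lr = 1e-4, epochs = 150,
                       batch_size = 500, integration = c("auto", "analytic",
                                                         "numeric"),
                       nonneg_weight = 1, nonneg_dirs = 300, seed = 1,
                       model = NULL, verbose = FALSE) {
  loss <- match.arg(loss)
  integration <- match.arg(integration)
  if (!inherits(dwi, "volume_grid")) dwi <- volume_grid(dwi)
  if (length(dim(dwi$data)) != 4 || dim(dwi$data)[4] != protocol$n)
    stop("dwi must be 4-D with one volume per protocol measurement")
  mask <- as_mask_array(mask, dwi$shape)
  if (!any(mask)) stop("empty mask")
  if (loss == "rician" && is.null(sigma_map))
    stop("the Rician loss requires a sigma_map")

  vox <- which(mask)
  ijk <- arrayInd(vox, dwi$shape)
  nvox <- length(vox)
  signals <- matrix(dwi$data, prod(dwi$shape), protocol$n)[vox, , drop = FALSE]
  sigma <- NULL
  if (!is.null(sigma_map)) {
    sm <- if (inherits(sigma_map, "volume_grid")) sigma_map$data else sigma_map
    sigma <- as.numeric(sm)[vox]
    if (any(sigma <= 0)) stop("sigma must be > 0 inside the mask")
  }

  scaler <- coordinate_scaler(dwi)
  X <- scale_coordinates(ijk, scaler)

  b0 <- protocol$b < 1e-9
  mean_b0 <- mean(signals[, b0, drop = FALSE])
  if (!is.finite(mean_b0) || mean_b0 <= 0) mean_b0 <- mean(abs(signals))

  if (is.null(model)) {
    model <- init_inr(n_p, n_h, sigma2 = sigma2, lmax = lmax, seed = seed,
                      s0_scale = mean_b0 / log(2))
    model$scaler <- scaler
  } else {
    stopifnot(inherits(model, "sm_inr"))
    if (model$lmax != lmax) stop("warm-start model has lmax ", model$lmax,
                                 ", requested ", lmax)
    if (is.null(model$scaler)) model$scaler <- scaler
  }

  # per-voxel effective protocols for gradient non-uniformity correction;
  # an identity tensor field collapses exactly onto the nominal path
  eff <- NULL
  if (!is.null(grad_tensor)) {
    gt <- if (inherits(grad_tensor, "volume_grid")) grad_tensor$data
          else grad_tensor
    if (length(dim(gt)) != 4 || dim(gt)[4] != 9)
      stop("grad_tensor must have 9 components (row-major 3 x 3 per voxel)")
    Lmat <- matrix(gt, prod(dwi$shape), 9)[vox, , drop = FALSE]
    if (!all(Lmat == rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1),
                         each = nvox))) {
      eff <- lapply(seq_len(nvox), function(v) {
        L <- matrix(Lmat[v, ], 3, 3, byrow = TRUE)
        effective_protocol(protocol, L)
      })
    }
  }

  if (integration == "auto")
    integration <- if (any(protocol$b_delta < 0) ||
                       (!is.null(eff) &&
                        any(vapply(eff, function(p) any(p$b_delta < 0),
                                   logical(1)))))
      "numeric" else "analytic"

  cdirs <- hemisphere_directions(nonneg_dirs, seed = 1)
  Yc <- real_sh_basis(lmax, cdirs)

  cp <- if (is.null(eff)) {
    if (integration == "analytic") compile_protocol(protocol, lmax)
    else compile_numeric(protocol, lmax)
  } else NULL

  if (is.null(model$adam)) model$adam <- adam_init()
  tensors <- model_tensors(model)
  state <- model$adam

  if (!is.null(model$rng)) {
    assign(".Random.seed", model$rng, envir = globalenv())
  } else {
    set.seed(seed + 1L)
  }

  trace <- model$trace
  for (ep in seq_len(epochs)) {
    perm <- sample.int(nvox)
    ep_loss <- 0
    for (start in seq(1, nvox, by = batch_size)) {
      bi <- perm[start:min(nvox, start + batch_size - 1)]
      res <- inr_train_step(model, tensors, X[bi, , drop = FALSE],
                            signals[bi, , drop = FALSE],
                            if (is.null(sigma)) NULL else sigma[bi],
                            loss, cp, integration,
                            if (is.null(eff)) NULL else eff[bi],
                            protocol, lmax, Yc, nonneg_weight)
      out <- adam_step(state, tensors, res$grads, lr)
      state <- out$state
      tensors <- out$params
      model <- set_model_tensors(model, tensors)
      ep_loss <- ep_loss + res$loss * length(bi)
    }
    trace <- c(trace, ep_loss / nvox)
    if (verbose && (ep %% 10 == 0 || ep == 1))
      message(sprintf("epoch %4d  mean loss %.6g", length(trace),
                      trace[length(trace)]))
  }

  model$adam <- state
  model$epoch <- model$epoch + as.integer(epochs)
  model$rng <- get(".Random.seed", envir = globalenv())
  model$trace <- trace

  structure(list(model = model, trace = trace, protocol = protocol,
                 grid = list(shape = dwi$shape, voxel_size = dwi$voxel_size,
                             affine = dwi$affine),
                 mask = mask, voxels = vox, ijk = ijk, signals = signals,
                 config = list(lmax = lmax, loss = loss,
                               integration = integration, n_p = model$n_p,
                               n_h = model$n_h, sigma2 = model$sigma2,
                               lr = lr, epochs = epochs,
                               batch_size = batch_size,
                               nonneg_weight = nonneg_weight,
                               nonneg_dirs = nonneg_dirs, seed = seed),
                 call = match.call()),
            class = "sm_inr_fit")
}

# One forward/backward pass over a batch; returns the mean per-voxel loss
# and gradients for every trainable tensor.
inr_train_step <- function(model, tensors, Xb, Sb, sigmab, loss, cp,
                           integration, effb, protocol, lmax, Yc,
                           nonneg_weight) {
  model <- set_model_tensors(model, tensors)
  V <- nrow(Xb)
  fw <- inr_forward(model, Xb, want_cache = TRUE)
  theta <- fw$theta
  p <- fw$p

  if (is.null(effb)) {
    if (integration == "analytic") {
      sf <- sm_batch_forward(theta, p, cp, want_grad = TRUE)
      Sp <- sf$S
    } else {
      Sp <- sm_numeric_forward(theta, p, cp)$S
    }
  } else {
    Sp <- matrix(0, V, protocol$n)
    cps <- lapply(effb, function(pr) compile_protocol(pr, lmax))
    sfs <- vector("list", V)
    for (v in seq_len(V)) {
      sfs[[v]] <- sm_batch_forward(theta[v, , drop = FALSE],
                                   p[v, , drop = FALSE], cps[[v]],
                                   want_grad = TRUE)
      Sp[v, ] <- sfs[[v]]$S
    }
  }

  # per-voxel data term summed over measurements, averaged over the batch
  if (loss == "mse") {
    diff <- Sp - Sb
    data_loss <- sum(diff^2) / V
    dS <- 2 * diff / V
  } else {
    s2 <- sigmab^2
    x <- Sb * Sp / s2
    data_loss <- sum(Sp^2 / (2 * s2) - log_bessel_i0(x)) / V
    dS <- (Sp / s2 - bessel_i1_i0_ratio(x) * Sb / s2) / V
  }

  amp <- p %*% t(Yc)
  neg <- amp < 0
  pen <- nonneg_weight * sum(-amp[neg]) / ncol(Yc) / V
  dp_pen <- -(nonneg_weight / ncol(Yc) / V) * (neg %*% Yc)

  if (is.null(effb)) {
    if (integration == "analytic") {
      bk <- sm_batch_backward(dS, theta, p, cp, sf$cache)
    } else {
      bk <- sm_numeric_backward(dS, theta, p, cp)
    }
  } else {
    dtheta <- matrix(0, V, 5)
    dpm <- matrix(0, V, ncol(p))
    for (v in seq_len(V)) {
      b1 <- sm_batch_backward(dS[v, , drop = FALSE],
                              theta[v, , drop = FALSE],
                              p[v, , drop = FALSE], cps[[v]],
                              sfs[[v]]$cache)
      dtheta[v, ] <- b1$dtheta
      dpm[v, ] <- b1$dp
    }
    bk <- list(dtheta = dtheta, dp = dpm)
  }

  grads <- inr_backward(model, fw$cache, bk$dtheta, bk$dp + dp_pen)
  list(loss = data_loss + pen, grads = grads)
}

#' @export
print.sm_inr_fit <- function(x, ...) {
  cat("Standard Model INR fit\n")
  cat(sprintf("  %d masked voxels on a %s grid, %d measurements\n",
              length(x$voxels), paste(x$grid$shape, collapse = " x "),
              x$protocol$n))
  cat(sprintf("  lmax = %d, loss = %s, integration = %s\n", x$config$lmax,
              x$config$loss, x$config$integration))
  cat(sprintf("  %d epochs; mean loss %.5g -> %.5g\n", length(x$trace),
              x$trace[1], x$trace[length(x$trace)]))
  invisible(x)
}

#' @export
summary.sm_inr_fit <- function(object, ...) {
  est <- coef(object)
  cat("Standard Model INR fit -- parameter summary over masked voxels\n")
  print(apply(est[, 1:5, drop = FALSE], 2, function(v)
    c(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v))))
  invisible(est)
}

#' Per-voxel parameter estimates at the masked training voxels
#'
#' @param object an [fit_sm_inr()] result.
#' @param ... unused.
#' @return matrix, one row per masked voxel (kernel parameters then SH
#'   coefficients).
#' @export
coef.sm_inr_fit <- function(object, ...) {
  predict(object$model, object$ijk)
}

#' Predict parameter maps from a fitted INR
#'
#' @param object an [fit_sm_inr()] result.
#' @param coords optional \code{V x 3} fractional voxel coordinates; when
#'   omitted, maps on the (optionally refined) training grid are returned.
#' @param factor integer grid refinement factor (1 reproduces the training
#'   grid exactly).
#' @param ... passed to [predict.sm_inr()].
#' @return with \code{coords}: a parameter matrix; otherwise a
#'   [volume_grid()] whose 4-D data holds one volume per output parameter
#'   (named via \code{dimnames}).
#' @export
predict.sm_inr_fit <- function(object, coords = NULL, factor = 1, ...) {
  if (!is.null(coords)) return(predict(object$model, coords, ...))
  stopifnot(factor >= 1, factor == round(factor))
  centers <- refined_voxel_centers(object$grid$shape, factor)
  # refined border centers sit half an original voxel outside the
  # voxel-center hull but inside the field of view: not extrapolation
  est <- predict(object$model, centers, warn = FALSE, ...)
  geom <- refined_grid_geometry(object$grid, factor)
  arr <- array(est, c(geom$shape, ncol(est)))
  dimnames(arr) <- c(rep(list(NULL), 3), list(colnames(est)))
  volume_grid(arr, voxel_size = geom$voxel_size, affine = geom$affine)
}

#' Continuously upsample fitted parameter maps
#'
#' Evaluates the fitted representation at voxel centers of a grid refined by
#' an integer factor in every dimension; at factor 1 this reproduces the
#' training-grid predictions exactly.
#'
#' @param fit an [fit_sm_inr()] result.
#' @param factor integer refinement factor (e.g. 8).
#' @param ... passed to [predict.sm_inr_fit()].
#' @return a 4-D [volume_grid()] of parameter maps.
#' @export
upsample <- function(fit, factor, ...) {
  stopifnot(inherits(fit, "sm_inr_fit"))
  predict(fit, factor = factor, ...)
}

#' Signal-domain residuals at the masked voxels
#'
#' @param object an [fit_sm_inr()] result (must still carry its training
#'   signals; reloaded models need \code{newdata}).
#' @param newdata optional V x N_m signal matrix replacing the stored one.
#' @param ... unused.
#' @return V x N_m matrix of measured minus predicted signals.
#' @export
residuals.sm_inr_fit <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$signals else newdata
  if (is.null(S)) stop("no stored signals; supply newdata")
  est <- coef(object)
  cp <- compile_protocol(object$protocol, object$config$lmax)
  pred <- sm_batch_forward(est[, 1:5, drop = FALSE],
                           est[, -(1:5), drop = FALSE], cp)$S
  S - pred
}

#' Loss trace plot
#'
#' @param x an [fit_sm_inr()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sm_inr_fit <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "l",
                 xlab = "epoch", ylab = "mean loss", ...)
  invisible(x)
}
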