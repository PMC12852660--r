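#' Initialize an implicit neural representation of SM parameter maps
#'
#' The network maps a scaled 3-D coordinate through a random Fourier-feature
#' encoding \eqn{\gamma(x) = [\cos(2\pi A x), \sin(2\pi A x)]} (A is
#' \code{n_p x 3} with N(0, sigma2) entries, fixed after initialization),
#' four fully connected ReLU layers of width \code{n_h}, and one affine head
#' per output: scaled sigmoids for the four kernel parameters (so the
#' physiological bounds are enforced by the architecture, not by clamping),
#' a scaled softplus for \code{S0}, and identity maps for the SH
#' coefficients. Hidden weights use uniform fan-in initialization; head
#' weights start at zero so kernel outputs begin mid-range and the FOD
#' begins as the unit-integral isotropic distribution
#' (\eqn{p_0^0 = 1/\sqrt{4\pi}}).
#'
#' @param n_p number of Fourier encodings (frequency rows of A).
#' @param n_h hidden-layer width.
#' @param sigma2 variance of the encoding frequencies; larger values admit
#'   finer spatial detail (weaker spatial regularization).
#' @param lmax even SH band limit of the FOD head block.
#' @param seed integer seed; initialization is fully reproducible from it.
#' @param s0_scale multiplier of the softplus S0 head, normally set from the
#'   mean b = 0 signal by [fit_sm_inr()] so training starts at a
#'   physiological signal scale.
#' @return object of class \code{sm_inr}.
#' @export
init_inr <- function(n_p, n_h, sigma2 = 3.5, lmax = 2, seed = 1,
                     s0_scale = 1 / log(2)) {
  check_lmax(lmax)
  stopifnot(n_p >= 1, n_h >= 1, sigma2 > 0)
  n_c <- n_sh_coeffs(lmax)
  n_out <- 5L + n_c
  model <- with_seed(seed, {
    A <- matrix(stats::rnorm(n_p * 3, sd = sqrt(sigma2)), n_p, 3)
    lin <- function(fan_in, fan_out) {
      bound <- 1 / sqrt(fan_in)
      list(W = matrix(stats::runif(fan_in * fan_out, -bound, bound),
                      fan_in, fan_out),
           b = stats::runif(fan_out, -bound, bound))
    }
    L <- list(lin(2 * n_p, n_h), lin(n_h, n_h), lin(n_h, n_h), lin(n_h, n_h))
    bh <- numeric(n_out)
    bh[6] <- 1 / sqrt(4 * pi)          # isotropic unit-integral FOD
    list(A = A, layers = L, Wh = matrix(0, n_h, n_out), bh = bh)
  })
  structure(list(A = model$A, layers = model$layers, Wh = model$Wh,
                 bh = model$bh, n_p = as.integer(n_p), n_h = as.integer(n_h),
                 sigma2 = sigma2, lmax = as.integer(lmax), n_c = n_c,
                 n_out = n_out, bounds = kernel_bounds(),
                 s0_scale = s0_scale, scaler = NULL, seed = as.integer(seed),
                 epoch = 0L, adam = NULL, rng = NULL),
            class = "sm_inr")
}

#' @export
print.sm_inr <- function(x, ...) {
  cat("SM implicit neural representation\n")
  cat(sprintf("  encoding: n_p = %d, sigma2 = %g; MLP: 4 x %d (ReLU)\n",
              x$n_p, x$sigma2, x$n_h))
  cat(sprintf("  outputs: 5 kernel parameters + %d SH coefficients (lmax %d)\n",
              x$n_c, x$lmax))
  cat(sprintf("  trained epochs: %d\n", x$epoch))
  invisible(x)
}

#' Coordinate scaler of a volume grid
#'
#' Maps fractional 1-based voxel indices to the cube \code{[-1, 1]^3},
#' preserving aspect ratio: the longest physical axis (voxel-center to
#' voxel-center) spans [-1, 1] and the others are scaled by the same factor,
#' centered on the volume center.
#'
#' @param grid a [volume_grid()] (or a list with \code{shape} and
#'   \code{voxel_size}).
#' @return list with \code{center}, \code{voxel_size} and \code{factor}.
#' @export
coordinate_scaler <- function(grid) {
  shape <- grid$shape
  vs <- grid$voxel_size
  span <- (shape - 1) * vs
  if (max(span) <= 0) stop("degenerate grid: zero physical extent")
  list(center = (shape + 1) / 2, voxel_size = vs, factor = 2 / max(span))
}

#' Scale voxel coordinates into the encoding cube
#'
#' @param coords \code{V x 3} fractional 1-based voxel indices (voxel
#'   centers are integers).
#' @param grid a [volume_grid()] or a scaler from [coordinate_scaler()].
#' @return \code{V x 3} matrix of scaled coordinates.
#' @export
scale_coordinates <- function(coords, grid) {
  sc <- if (!is.null(grid$factor)) grid else coordinate_scaler(grid)
  coords <- matrix(as.numeric(as.matrix(coords)), ncol = 3)
  sweep(coords, 2, sc$center) %*% diag(sc$voxel_size * sc$factor, 3)
}

#' Fourier-feature encoding of scaled coordinates
#'
#' \eqn{\gamma(x) = [\cos(2\pi A x), \sin(2\pi A x)]}, cosine block first.
#'
#' @param x_scaled \code{V x 3} scaled coordinates in \code{[-1, 1]^3}.
#' @param model an [init_inr()] model (or a list with element \code{A}).
#' @return \code{V x 2 n_p} matrix with entries in [-1, 1].
#' @export
fourier_encode <- function(x_scaled, model) {
  x_scaled <- matrix(as.numeric(as.matrix(x_scaled)), ncol = 3)
  Z <- 2 * pi * (x_scaled %*% t(model$A))
  cbind(cos(Z), sin(Z))
}

relu <- function(x) (x > 0) * x

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

sigmoid <- function(x) 1 / (1 + exp(-x))

# Full forward pass from scaled coordinates to (theta, p).  Returns the
# activations needed for backprop when want_cache.
inr_forward <- function(model, x_scaled, want_cache = FALSE) {
  G <- fourier_encode(x_scaled, model)
  H <- G
  Hs <- if (want_cache) vector("list", 4) else NULL
  for (i in 1:4) {
    H <- relu(H %*% model$layers[[i]]$W +
                rep(model$layers[[i]]$b, each = nrow(H)))
    if (want_cache) Hs[[i]] <- H
  }
  O <- H %*% model$Wh + rep(model$bh, each = nrow(H))
  lo <- model$bounds$lo
  hi <- model$bounds$hi
  sig <- sigmoid(O[, 1:4, drop = FALSE])
  theta <- cbind(sweep(sweep(sig, 2, hi - lo, `*`), 2, lo, `+`),
                 model$s0_scale * softplus(O[, 5]))
  colnames(theta) <- c("f_i", "D_i", "De_par", "De_perp", "S0")
  p <- O[, 6:model$n_out, drop = FALSE]
  out <- list(theta = theta, p = p)
  if (want_cache) {
    out$cache <- list(G = G, Hs = Hs, sig = sig, o5 = O[, 5])
  }
  out
}

# Backprop dL/dtheta, dL/dp through heads and MLP; returns gradients for
# every trainable tensor (encoding A is fixed).
inr_backward <- function(model, cache, dtheta, dp) {
  lo <- model$bounds$lo
  hi <- model$bounds$hi
  dO <- cbind(dtheta[, 1:4, drop = FALSE] *
                sweep(cache$sig * (1 - cache$sig), 2, hi - lo, `*`),
              dtheta[, 5] * model$s0_scale * sigmoid(cache$o5),
              dp)
  H4 <- cache$Hs[[4]]
  g <- list(Wh = crossprod(H4, dO), bh = colSums(dO))
  dH <- dO %*% t(model$Wh)
  for (i in 4:1) {
    dH <- dH * (cache$Hs[[i]] > 0)
    Hin <- if (i == 1) cache$G else cache$Hs[[i - 1]]
    g[[paste0("W", i)]] <- crossprod(Hin, dH)
    g[[paste0("b", i)]] <- colSums(dH)
    if (i > 1) dH <- dH %*% t(model$layers[[i]]$W)
  }
  g
}

#' Predict SM parameters and FOD coefficients at coordinates
#'
#' Evaluates the network at arbitrary continuous voxel coordinates. Kernel
#' outputs respect the physiological bounds at every input by construction.
#' Coordinates outside the training cube produce a warning (extrapolation)
#' but are evaluated.
#'
#' @param object an [init_inr()] model (standalone use requires a scaler; a
#'   fitted model carries one).
#' @param coords \code{V x 3} fractional 1-based voxel indices, or already
#'   scaled coordinates if \code{scaled = TRUE}.
#' @param scaled interpret \code{coords} as already lying in [-1, 1]^3.
#' @param chunk evaluate at most this many coordinates at a time.
#' @param warn warn when coordinates leave the training cube.
#' @param ... unused.
#' @return matrix \code{V x (5 + n_coeffs)} with named columns: kernel
#'   parameters then SH coefficients in [sh_index_table()] order.
#' @export
predict.sm_inr <- function(object, coords, scaled = FALSE, chunk = 20000L,
                           warn = TRUE, ...) {
  coords <- matrix(as.numeric(as.matrix(coords)), ncol = 3)
  if (!scaled) {
    if (is.null(object$scaler))
      stop("model has no coordinate scaler; fit it or pass scaled coords")
    coords <- scale_coordinates(coords, object$scaler)
  }
  if (warn && any(abs(coords) > 1 + 1e-9))
    warning("coordinates outside [-1, 1]^3: extrapolating the representation")
  V <- nrow(coords)
  out <- matrix(0, V, object$n_out)
  tab <- sh_index_table(object$lmax)
  colnames(out) <- c("f_i", "D_i", "De_par", "De_perp", "S0",
                     sprintf("p_%d_%d", tab$l, tab$m))
  for (start in seq(1, V, by = chunk)) {
    i <- start:min(V, start + chunk - 1)
    fw <- inr_forward(object, coords[i, , drop = FALSE])
    out[i, ] <- cbind(fw$theta, fw$p)
  }
  out
}
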