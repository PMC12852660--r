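#' Noise specification for simulated signals
#'
#' @param kind \code{"none"}, \code{"gaussian"} or \code{"rician"}.
#' @param snr target signal-to-noise ratio on the b = 0 images (> 0;
#'   ignored for \code{"none"}).
#' @param seed integer seed for the noise draw.
#' @return list of class \code{noise_spec}.
#' @export
noise_spec <- function(kind = c("none", "gaussian", "rician"), snr = Inf,
                       seed = 1) {
  kind <- match.arg(kind)
  if (kind != "none" && (!is.finite(snr) || snr <= 0))
    stop("snr must be a positive finite number for noisy simulations")
  structure(list(kind = kind, snr = snr, seed = as.integer(seed)),
            class = "noise_spec")
}

# A smooth random scalar field: white noise on the voxel lattice convolved
# with a Gaussian kernel of width s (voxels), evaluable at arbitrary
# continuous coordinates.  On-grid samples are exactly Gaussian-smoothed
# white noise; off-grid evaluation interpolates the same analytic function,
# which is what the upsampling comparison needs as ground truth.
smooth_field_def <- function(shape, smooth_vox, seed) {
  eps <- with_seed(seed, array(stats::rnorm(prod(shape)), shape))
  list(eps = eps, s = smooth_vox, shape = shape)
}

# Evaluate the normalized Gaussian-weighted lattice sum at fractional
# 1-based voxel coordinates (V x 3).  The kernel is truncated at 3 s.
smooth_field_eval <- function(def, coords) {
  s <- def$s
  if (!is.finite(s)) return(rep(0, nrow(coords)))
  r <- max(1L, ceiling(3 * s))
  V <- nrow(coords)
  num <- numeric(V)
  den <- numeric(V)
  i0 <- floor(coords)
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    ii <- i0[, 1] + dx
    jj <- i0[, 2] + dy
    kk <- i0[, 3] + dz
    ok <- ii >= 1 & ii <= def$shape[1] & jj >= 1 & jj <= def$shape[2] &
      kk >= 1 & kk <= def$shape[3]
    if (!any(ok)) next
    d2 <- (coords[ok, 1] - ii[ok])^2 + (coords[ok, 2] - jj[ok])^2 +
      (coords[ok, 3] - kk[ok])^2
    w <- exp(-d2 / (2 * s^2))
    idx <- cbind(ii[ok], jj[ok], kk[ok])
    num[ok] <- num[ok] + w * def$eps[idx]
    den[ok] <- den[ok] + w
  }
  num / pmax(den, 1e-300)
}

# Map a roughly standard-normal smooth field into the open interval
# (lo, hi) via tanh; smooth everywhere, no clipping.
squash_field <- function(v, lo, hi, center, scale) {
  mid <- (lo + hi) / 2
  mid + 0.5 * (hi - lo) * tanh((v - center) / (2 * scale))
}

# Even-order SH coefficients of a unit-integral Watson density exp(k (mu.n)^2)
# about axis mu: p_lm = (lambda_l / lambda_0) Y_lm(mu) by Funk-Hecke.
watson_sh <- function(mu, kappa, lmax) {
  lam <- legendre_proj_mat(-kappa, lmax)   # row vector over degrees
  ratio <- lam[1, ] / lam[1, 1]
  tab <- sh_index_table(lmax)
  Y <- real_sh_basis(lmax, matrix(mu / sqrt(sum(mu^2)), 1))
  drop(Y) * ratio[tab$l / 2 + 1]
}

default_kappa <- function(lmax) {
  # sharpest concentration whose lmax-truncated expansion stays >= 0
  c(`2` = 2, `4` = 4, `6` = 4, `8` = 6)[[as.character(lmax)]]
}

#' Generate a smooth Standard Model phantom
#'
#' Ground-truth kernel parameter fields are spatially smooth random fields
#' (Gaussian-kernel-smoothed lattice white noise squashed into physiological
#' sub-ranges): \code{f_i} in (0.3, 0.8), \code{D_i} in (1.5, 3.0),
#' \code{De_par} in (1.0, 2.5) um^2/ms and \code{De_perp = r * De_par} with
#' smooth \code{r} in (0.2, 0.6), which guarantees
#' \code{De_par > De_perp} everywhere. FODs are mixtures of one or two
#' Watson densities with smoothly varying orientations, projected onto even
#' SH and normalized to unit integral (\eqn{p_0^0 = 1/\sqrt{4\pi}}). All
#' fields are defined as continuous functions, so the ground truth can be
#' evaluated at arbitrary coordinates ([phantom_params_at()]).
#'
#' @param shape grid dimensions (>= 4 per axis).
#' @param voxel_size voxel edge lengths in mm.
#' @param lmax even SH band limit of the stored FOD coefficients.
#' @param seed integer seed; phantoms are reproducible.
#' @param smoothness_mm Gaussian smoothing kernel width (standard deviation,
#'   mm); \code{Inf} yields spatially constant fields.
#' @param fiber_config \code{"single"}, \code{"crossing"} or
#'   \code{"fanning"}.
#' @param crossing_angle separation of the two fiber populations in degrees
#'   (crossing configuration).
#' @param kappa Watson concentration; default depends on \code{lmax} so the
#'   truncated FOD stays non-negative.
#' @param S0 non-weighted signal level inside the mask.
#' @return object of class \code{sm_phantom}: grid geometry, boolean
#'   \code{mask}, per-voxel \code{theta} (V x 5) and \code{fod} (V x n_c)
#'   ground truth, and the continuous field definitions.
#' @export
generate_phantom <- function(shape = c(12, 12, 12), voxel_size = c(2, 2, 2),
                             lmax = 2, seed = 1, smoothness_mm = 6,
                             fiber_config = c("single", "crossing",
                                              "fanning"),
                             crossing_angle = 90,
                             kappa = default_kappa(lmax), S0 = 1) {
  fiber_config <- match.arg(fiber_config)
  shape <- as.integer(shape)
  if (any(shape < 4)) stop("shape must be >= 4 voxels per axis")
  check_lmax(lmax)
  s_vox <- smoothness_mm / mean(voxel_size)

  defs <- lapply(1:7, function(i) smooth_field_def(shape, s_vox, seed + i))
  grid_centers <- refined_voxel_centers(shape, 1)
  raw <- vapply(defs, smooth_field_eval, numeric(nrow(grid_centers)),
                coords = grid_centers)
  centers <- colMeans(raw)
  scales <- pmax(apply(raw, 2, stats::sd), 1e-8)

  ranges <- list(f_i = c(0.3, 0.8), D_i = c(1.5, 3.0), De_par = c(1.0, 2.5),
                 r_perp = c(0.2, 0.6))
  cfg <- list(shape = shape, voxel_size = voxel_size, lmax = lmax,
              seed = seed, smoothness_mm = smoothness_mm,
              fiber_config = fiber_config, crossing_angle = crossing_angle,
              kappa = kappa, S0 = S0, defs = defs, centers = centers,
              scales = scales, ranges = ranges)

  out <- phantom_eval(cfg, grid_centers)
  structure(list(grid = list(shape = shape, voxel_size = voxel_size,
                             affine = diag(c(voxel_size, 1))),
                 mask = array(TRUE, shape), theta = out$theta,
                 fod = out$p, lmax = as.integer(lmax), seed = seed,
                 config = cfg),
            class = "sm_phantom")
}

# Evaluate the ground-truth fields at fractional voxel coordinates.
# 'fields' may carry precomputed standardized smooth fields (V x 7).
phantom_eval <- function(cfg, coords, fields = NULL) {
  V <- nrow(coords)
  if (is.null(fields))
    fields <- vapply(seq_along(cfg$defs), function(i) {
      v <- smooth_field_eval(cfg$defs[[i]], coords)
      (v - cfg$centers[i]) / cfg$scales[i]
    }, numeric(V))
  fields <- matrix(fields, nrow = V)
  rg <- cfg$ranges
  f_i <- squash_field(fields[, 1], rg$f_i[1], rg$f_i[2], 0, 1)
  D_i <- squash_field(fields[, 2], rg$D_i[1], rg$D_i[2], 0, 1)
  De_par <- squash_field(fields[, 3], rg$De_par[1], rg$De_par[2], 0, 1)
  r_perp <- squash_field(fields[, 4], rg$r_perp[1], rg$r_perp[2], 0, 1)
  theta <- cbind(f_i = f_i, D_i = D_i, De_par = De_par,
                 De_perp = r_perp * De_par, S0 = rep(cfg$S0, V))

  # smoothly varying primary orientation, bounded away from degeneracy
  t1 <- tanh(fields[, 5] / 2)
  t2 <- tanh(fields[, 6] / 2)
  t3 <- tanh(fields[, 7] / 2)
  mu <- cbind(t1, t2, 1.2 + 0.4 * t3)
  mu <- mu / sqrt(rowSums(mu^2))

  lcol <- sh_index_table(cfg$lmax)$l / 2 + 1
  lam <- legendre_proj_mat(-cfg$kappa, cfg$lmax)
  ratio <- (lam[1, ] / lam[1, 1])[lcol]
  if (cfg$fiber_config == "single") {
    p <- real_sh_basis(cfg$lmax, mu) * rep(ratio, each = V)
  } else if (cfg$fiber_config == "crossing") {
    ang <- cfg$crossing_angle * pi / 180
    mu2 <- t(vapply(seq_len(V), function(v)
      rotate_about(mu[v, ], crossing_axis(mu[v, ]), ang), numeric(3)))
    p <- 0.5 * (real_sh_basis(cfg$lmax, mu) +
                  real_sh_basis(cfg$lmax, mu2)) * rep(ratio, each = V)
  } else {                              # fanning: dispersion varies along x
    xk <- (coords[, 1] - 1) / max(cfg$shape[1] - 1, 1)
    kap <- cfg$kappa * (0.35 + 0.65 * xk)
    lamv <- legendre_proj_mat(-kap, cfg$lmax)
    p <- real_sh_basis(cfg$lmax, mu) * (lamv / lamv[, 1])[, lcol]
  }
  p[, 1] <- 1 / sqrt(4 * pi)            # exact unit integral
  list(theta = theta, p = p)
}

crossing_axis <- function(mu) {
  e <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ax <- c(mu[2] * e[3] - mu[3] * e[2], mu[3] * e[1] - mu[1] * e[3],
          mu[1] * e[2] - mu[2] * e[1])
  ax / sqrt(sum(ax^2))
}

rotate_about <- function(v, axis, angle) {
  # Rodrigues rotation
  k <- axis / sqrt(sum(axis^2))
  v * cos(angle) + c(k[2] * v[3] - k[3] * v[2],
                     k[3] * v[1] - k[1] * v[3],
                     k[1] * v[2] - k[2] * v[1]) * sin(angle) +
    k * sum(k * v) * (1 - cos(angle))
}

# Separable evaluation of the lattice-Gaussian field on a tensor-product
# coordinate grid: the kernel factorizes per axis, so the normalized sum is
# a sequence of three mode products plus an outer-product denominator.
smooth_field_eval_axes <- function(def, ax1, ax2, ax3) {
  s <- def$s
  sh <- def$shape
  if (!is.finite(s))
    return(array(0, c(length(ax1), length(ax2), length(ax3))))
  Wm <- function(ax, n) exp(-outer(ax, seq_len(n), `-`)^2 / (2 * s^2))
  W1 <- Wm(ax1, sh[1]); W2 <- Wm(ax2, sh[2]); W3 <- Wm(ax3, sh[3])
  T1 <- W1 %*% matrix(def$eps, sh[1], sh[2] * sh[3])
  T1 <- array(T1, c(length(ax1), sh[2], sh[3]))
  T2 <- apply(T1, c(1, 3), function(v) W2 %*% v)      # n2f x n1f x n3
  T2 <- aperm(T2, c(2, 1, 3))
  T3 <- apply(T2, c(1, 2), function(v) W3 %*% v)      # n3f x n1f x n2f
  num <- aperm(T3, c(2, 3, 1))
  den <- outer(outer(rowSums(W1), rowSums(W2)), rowSums(W3))
  num / pmax(den, 1e-300)
}

#' Ground-truth maps on a refined grid
#'
#' Evaluates the phantom's continuous parameter fields at the voxel centers
#' of the grid refined by an integer factor (the same centers
#' [upsample()] predicts at), using a fast separable evaluation. At factor 1
#' this reproduces the stored phantom fields.
#'
#' @param phantom an [generate_phantom()] result.
#' @param factor integer refinement factor.
#' @return list with \code{theta} (V x 5) and \code{fod} (V x n_c), rows in
#'   array order of the refined grid.
#' @export
phantom_truth_maps <- function(phantom, factor = 1) {
  stopifnot(inherits(phantom, "sm_phantom"), factor >= 1,
            factor == round(factor))
  cfg <- phantom$config
  axes <- lapply(cfg$shape, function(n)
    (seq_len(n * factor) - 0.5) / factor + 0.5)
  fields <- vapply(seq_along(cfg$defs), function(i) {
    a <- smooth_field_eval_axes(cfg$defs[[i]], axes[[1]], axes[[2]],
                                axes[[3]])
    (as.numeric(a) - cfg$centers[i]) / cfg$scales[i]
  }, numeric(prod(cfg$shape) * factor^3))
  coords <- refined_voxel_centers(cfg$shape, factor)
  out <- phantom_eval(cfg, coords, fields = fields)
  list(theta = out$theta, fod = out$p)
}

#' Ground-truth parameters at arbitrary continuous coordinates
#'
#' @param phantom an [generate_phantom()] result.
#' @param coords \code{V x 3} fractional 1-based voxel coordinates.
#' @return list with \code{theta} (V x 5) and \code{fod} (V x n_c).
#' @export
phantom_params_at <- function(phantom, coords) {
  stopifnot(inherits(phantom, "sm_phantom"))
  coords <- matrix(as.numeric(as.matrix(coords)), ncol = 3)
  out <- phantom_eval(phantom$config, coords)
  list(theta = out$theta, fod = out$p)
}

#' Simulate noiseless Standard Model signals for a phantom
#'
#' Evaluates the analytic forward model at every masked voxel for every
#' protocol measurement; voxels outside the mask are zero.
#'
#' @param phantom an [generate_phantom()] result.
#' @param protocol an [sm_protocol()] with non-negative b-tensor shapes
#'   (e.g. [optimized_protocol()]).
#' @return 4-D [volume_grid()] of signals.
#' @export
simulate_signals <- function(phantom, protocol) {
  stopifnot(inherits(phantom, "sm_phantom"))
  cp <- compile_protocol(protocol, phantom$lmax)
  vox <- which(phantom$mask)
  S <- matrix(0, prod(phantom$grid$shape), protocol$n)
  chunk <- 2000L
  for (start in seq(1, length(vox), by = chunk)) {
    i <- start:min(length(vox), start + chunk - 1)
    S[vox[i], ] <- sm_batch_forward(phantom$theta[i, , drop = FALSE],
                                    phantom$fod[i, , drop = FALSE], cp)$S
  }
  volume_grid(array(S, c(phantom$grid$shape, protocol$n)),
              voxel_size = phantom$grid$voxel_size,
              affine = phantom$grid$affine)
}

#' Add noise with spatially varying sigma set by the b = 0 signal
#'
#' The per-voxel noise standard deviation is the voxel's mean b = 0 signal
#' divided by the target SNR. Gaussian noise adds one N(0, sigma^2) draw per
#' measurement; Rician noise takes the magnitude
#' \eqn{\sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}} of two independent Gaussian
#' channels.
#'
#' @param signals 4-D [volume_grid()] of noiseless signals.
#' @param protocol the matching [sm_protocol()] (identifies b = 0 volumes).
#' @param noise a [noise_spec()].
#' @return list with \code{signals} (noisy 4-D [volume_grid()]) and
#'   \code{sigma} (3-D [volume_grid()] noise map).
#' @export
add_noise <- function(signals, protocol, noise = noise_spec("none")) {
  stopifnot(inherits(signals, "volume_grid"), inherits(noise, "noise_spec"))
  d <- signals$data
  shape <- dim(d)[1:3]
  b0 <- protocol$b < 1e-9
  S <- matrix(d, prod(shape), dim(d)[4])
  sigma <- rowMeans(S[, b0, drop = FALSE]) / noise$snr
  if (noise$kind == "none") sigma <- rep(0, nrow(S))
  out <- S
  if (noise$kind != "none") {
    out <- with_seed(noise$seed, {
      e1 <- matrix(stats::rnorm(length(S)), nrow(S)) * sigma
      if (noise$kind == "gaussian") {
        S + e1
      } else {
        e2 <- matrix(stats::rnorm(length(S)), nrow(S)) * sigma
        sqrt((S + e1)^2 + e2^2)
      }
    })
  }
  list(signals = volume_grid(array(out, dim(d)),
                             voxel_size = signals$voxel_size,
                             affine = signals$affine),
       sigma = volume_grid(array(sigma, shape),
                           voxel_size = signals$voxel_size,
                           affine = signals$affine))
}
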