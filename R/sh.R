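#' Index table of even-order real spherical harmonics
#'
#' Coefficients are ordered lexicographically in \code{(l, m)}: degree
#' \code{l = 0, 2, ..., lmax}, and within each degree \code{m = -l, ..., l}.
#' This ordering is used everywhere in the package, including 4-D NIfTI
#' coefficient volumes.
#'
#' @param lmax even spherical-harmonic band limit (one of 2, 4, 6, 8; 0 is
#'   also accepted for degenerate cases).
#' @return data frame with columns \code{l} and \code{m}, one row per basis
#'   function; \code{(lmax+1)(lmax+2)/2} rows.
#' @export
sh_index_table <- function(lmax) {
  check_lmax(lmax, allow_zero = TRUE)
  l <- unlist(lapply(seq(0, lmax, by = 2), function(li) rep(li, 2 * li + 1)))
  m <- unlist(lapply(seq(0, lmax, by = 2), function(li) seq(-li, li)))
  data.frame(l = as.integer(l), m = as.integer(m))
}

check_lmax <- function(lmax, allow_zero = FALSE) {
  ok <- length(lmax) == 1 && is.finite(lmax) && lmax == round(lmax) &&
    lmax %% 2 == 0 && (lmax > 0 || allow_zero) && lmax <= 8 && lmax >= 0
  if (!ok)
    stop("'lmax' must be an even integer in {2, 4, 6, 8}", call. = FALSE)
  invisible(as.integer(lmax))
}

n_sh_coeffs <- function(lmax) (lmax + 1L) * (lmax + 2L) / 2L

as_direction_matrix <- function(directions) {
  if (is.list(directions) && !is.null(directions$dirs))
    directions <- directions$dirs
  d <- as.matrix(directions)
  if (ncol(d) != 3 && nrow(d) == 3) d <- t(d)
  if (ncol(d) != 3) stop("directions must be n x 3 unit vectors")
  if (nrow(d) == 0) stop("empty direction set")
  storage.mode(d) <- "double"
  d
}

#' Evaluate the orthonormal real spherical-harmonic basis
#'
#' Real, even-order basis in the Descoteaux convention: for \code{m < 0} the
#' function is \eqn{\sqrt{2}\,\mathrm{Im}(Y_l^{|m|})}, for \code{m = 0} it is
#' \eqn{Y_l^0}, and for \code{m > 0} it is \eqn{\sqrt{2}\,\mathrm{Re}(Y_l^m)}.
#' The basis is orthonormal on the unit sphere: on a dense quadrature grid
#' with weights \code{w}, \code{t(B) \%*\% (w * B)} is the identity.
#'
#' @param lmax even band limit.
#' @param directions unit vectors: an \code{n x 3} matrix or a sphere
#'   direction set from [sphere_grid()] / [hemisphere_directions()].
#' @return \code{n_dirs x n_coeffs} basis matrix, columns ordered as in
#'   [sh_index_table()].
#' @export
real_sh_basis <- function(lmax, directions) {
  check_lmax(lmax, allow_zero = TRUE)
  d <- as_direction_matrix(directions)
  nrm <- sqrt(rowSums(d^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("directions must be unit-norm")
  ct <- pmin(1, pmax(-1, d[, 3]))
  phi <- atan2(d[, 2], d[, 1])
  tab <- sh_index_table(lmax)
  B <- matrix(0, nrow(d), nrow(tab))
  for (l in seq(0, lmax, by = 2)) {
    # associated Legendre P_l^m(cos theta), m = 0..l, Condon-Shortley phase
    P <- pracma::legendre(l, ct)
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    for (m in seq(-l, l)) {
      am <- abs(m)
      nc <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - am) / factorial(l + am))
      v <- nc * P[am + 1, ]
      if (m > 0) v <- sqrt(2) * v * cos(m * phi)
      if (m < 0) v <- sqrt(2) * v * sin(am * phi)
      B[, which(tab$l == l & tab$m == m)] <- v
    }
  }
  B
}

#' Evaluate an FOD's amplitude on the sphere
#'
#' @param coeffs real SH coefficient vector (length \code{(lmax+1)(lmax+2)/2})
#'   or a matrix with one row per voxel.
#' @param directions unit vectors (see [real_sh_basis()]).
#' @return numeric vector of amplitudes (or matrix, voxels x directions).
#' @export
fod_amplitude <- function(coeffs, directions) {
  if (is.matrix(coeffs)) {
    lmax <- lmax_from_ncoef(ncol(coeffs))
    B <- real_sh_basis(lmax, directions)
    return(coeffs %*% t(B))
  }
  lmax <- lmax_from_ncoef(length(coeffs))
  B <- real_sh_basis(lmax, directions)
  drop(B %*% coeffs)
}

lmax_from_ncoef <- function(nc) {
  lmax <- (sqrt(8 * nc + 1) - 3) / 2
  if (abs(lmax - round(lmax)) > 1e-9 || round(lmax) %% 2 != 0)
    stop("coefficient count ", nc, " does not match any even lmax")
  as.integer(round(lmax))
}

# 64-node Gauss-Legendre rule on [0, 1]; exact for polynomial integrands up
# to degree 127, so the l <= 8 Legendre projections below are limited only by
# the smooth exponential factor.
gl_rule <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pracma::gaussLegendre(64, 0, 1)
    cache
  }
})

# Legendre polynomial values P_l(t) for all even degrees 0..lmax, as a
# length(t) x (lmax/2 + 1) matrix, by the three-term recurrence.
legendre_poly_even <- function(t, lmax) {
  Pprev <- rep(1, length(t))    # P_0
  out <- matrix(Pprev, ncol = 1)
  if (lmax == 0) return(out)
  Pcur <- t                     # P_1
  for (l in 2:lmax) {
    Pnext <- ((2 * l - 1) * t * Pcur - (l - 1) * Pprev) / l
    Pprev <- Pcur
    Pcur <- Pnext
    if (l %% 2 == 0) out <- cbind(out, Pcur, deparse.level = 0)
  }
  out
}

# r_l(a) = 2*pi * int_{-1}^{1} P_l(t) exp(-a t^2) dt for all even l up to
# lmax, vectorized over a (rows).  With deriv = TRUE also returns d r_l / d a.
# 'a' may be negative here; the public wrapper restricts the sign.
legendre_proj_mat <- function(a, lmax, deriv = FALSE) {
  gl <- gl_rule()
  P <- legendre_poly_even(gl$x, lmax)          # 64 x L
  E <- exp(-outer(as.numeric(a), gl$x^2))      # n x 64
  R <- 4 * pi * (E %*% (gl$w * P))
  if (!deriv) return(R)
  dR <- -4 * pi * (E %*% (gl$w * gl$x^2 * P))
  list(r = R, dr = dR)
}

#' Legendre projection of a Gaussian orientation kernel
#'
#' Computes \eqn{r_l(a) = 2\pi \int_{-1}^{1} P_l(t)\, e^{-a t^2}\, dt}, the
#' Funk-Hecke coefficient by which degree-\code{l} SH coefficients are scaled
#' when convolving an axially symmetric kernel \eqn{e^{-a t^2}} with a
#' spherical function. Evaluated by a fixed 64-node Gauss-Legendre rule on
#' \code{[0, 1]} (even symmetry doubles the domain), which is smooth and
#' differentiable in \code{a}; the closed form
#' \eqn{r_0(a) = 4\pi\sqrt{\pi/(4a)}\,\mathrm{erf}(\sqrt a)} is used as an
#' independent oracle in the tests.
#'
#' @param l even degree (0, 2, 4, 6 or 8).
#' @param a non-negative attenuation argument (vectorized). Negative \code{a}
#'   arises only for planar b-tensor shapes, which require the numeric
#'   integration path ([sm_signal_numeric()]).
#' @return \code{r_l(a)}, same length as \code{a}.
#' @export
legendre_projection <- function(l, a) {
  check_lmax(l, allow_zero = TRUE)
  if (any(a < 0))
    stop("legendre_projection requires a >= 0; use sm_signal_numeric() ",
         "for negative b-tensor shapes", call. = FALSE)
  R <- legendre_proj_mat(a, l)
  R[, ncol(R)]
}

#' Degree-2 rotational invariant of an FOD
#'
#' \eqn{p_2 = \sqrt{4\pi/5}\,\sqrt{\sum_m |p_{2m}|^2}}: a rotation-invariant
#' scalar summary of the FOD's degree-2 energy (orientation coherence).
#'
#' @param coeffs SH coefficient vector (lmax >= 2) or matrix (voxels in rows).
#' @return non-negative scalar (or vector, one per row).
#' @export
p2_invariant <- function(coeffs) {
  if (!is.matrix(coeffs)) coeffs <- matrix(coeffs, nrow = 1)
  lmax <- lmax_from_ncoef(ncol(coeffs))
  if (lmax < 2) stop("p2 requires lmax >= 2")
  tab <- sh_index_table(lmax)
  i2 <- which(tab$l == 2)
  drop(sqrt(4 * pi / 5) * sqrt(rowSums(coeffs[, i2, drop = FALSE]^2)))
}

#' Quadrature grid on the unit sphere
#'
#' Product grid in spherical coordinates. \code{type = "simpson"} uses
#' composite Simpson weights in both angles with the \eqn{\sin\theta}
#' Jacobian (differentiable, used by the numeric forward path);
#' \code{type = "gauss"} uses Gauss-Legendre nodes in \eqn{\cos\theta} and a
#' uniform periodic rule in \eqn{\phi}, which integrates band-limited
#' spherical polynomials to machine precision.
#'
#' @param n_theta nodes in the polar angle (odd for Simpson).
#' @param n_phi nodes in azimuth (odd for Simpson).
#' @param type \code{"simpson"} or \code{"gauss"}.
#' @return list with \code{dirs} (\code{n x 3} unit vectors) and quadrature
#'   \code{weights} summing to \eqn{4\pi}.
#' @export
sphere_grid <- function(n_theta = 65, n_phi = 97, type = c("simpson", "gauss")) {
  type <- match.arg(type)
  if (type == "simpson") {
    if (n_theta %% 2 == 0 || n_phi %% 2 == 0)
      stop("Simpson rule needs odd node counts")
    th <- seq(0, pi, length.out = n_theta)
    ph <- seq(0, 2 * pi, length.out = n_phi)
    wt <- simpson_weights(n_theta) * (pi / (n_theta - 1))
    wp <- simpson_weights(n_phi) * (2 * pi / (n_phi - 1))
    st <- sin(th)
    dirs <- cbind(c(outer(st, cos(ph))), c(outer(st, sin(ph))),
                  rep(cos(th), n_phi))
    w <- c(outer(st * wt, wp))
  } else {
    gl <- pracma::gaussLegendre(n_theta, -1, 1)
    ph <- 2 * pi * (seq_len(n_phi) - 0.5) / n_phi
    st <- sqrt(pmax(0, 1 - gl$x^2))
    dirs <- cbind(c(outer(st, cos(ph))), c(outer(st, sin(ph))),
                  rep(gl$x, n_phi))
    w <- c(outer(gl$w, rep(2 * pi / n_phi, n_phi)))
  }
  list(dirs = dirs, weights = w)
}

simpson_weights <- function(n) {
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1
  w[n] <- 1
  w / 3
}

#' Evenly spread directions by electrostatic repulsion
#'
#' Places \code{n} unit vectors by minimizing the Coulomb energy of antipodal
#' charge pairs (each point interacts with every other point and its
#' antipode), the standard criterion for diffusion gradient schemes.
#' Projected gradient descent with a decaying step, 1000 iterations,
#' deterministic given \code{seed}.
#'
#' @param n number of directions (>= 1).
#' @param seed integer seed for the random initialization.
#' @param iterations descent iterations.
#' @return list with \code{dirs} (\code{n x 3}) and \code{weights = NULL}.
#' @export
hemisphere_directions <- function(n, seed = 1, iterations = 1000) {
  if (n < 1) stop("n must be >= 1")
  x <- with_seed(seed, {
    m <- matrix(stats::rnorm(3 * n), n, 3)
    m[m[, 3] < 0, ] <- -m[m[, 3] < 0, , drop = FALSE]
    m / sqrt(rowSums(m^2))
  })
  if (n == 1) return(list(dirs = x, weights = NULL))
  key <- sprintf("hemi_%d_%d_%d", n, seed, iterations)
  cached <- get0(key, envir = .sminr_cache)
  if (!is.null(cached)) return(cached)
  for (it in seq_len(iterations)) {
    step <- 0.05 / (1 + it / 100)
    C <- x %*% t(x)
    C[C > 1] <- 1
    C[C < -1] <- -1
    r1 <- sqrt(pmax(2 - 2 * C, 1e-12))   # |x_i - x_j|
    r2 <- sqrt(pmax(2 + 2 * C, 1e-12))   # |x_i + x_j|
    A1 <- 1 / r1^3
    A2 <- 1 / r2^3
    diag(A1) <- 0
    diag(A2) <- 0
    # F_i = sum_j (x_i - x_j)/r1^3 + (x_i + x_j)/r2^3
    F <- x * rowSums(A1 + A2) - (A1 - A2) %*% x
    F <- F - x * rowSums(F * x)          # tangential component
    nf <- sqrt(rowSums(F^2))
    F <- F / pmax(max(nf), 1e-12)
    x <- x + step * F
    x <- x / sqrt(rowSums(x^2))
  }
  out <- list(dirs = x, weights = NULL)
  assign(key, out, envir = .sminr_cache)
  out
}

.sminr_cache <- new.env(parent = emptyenv())

min_pairwise_angle <- function(dirs) {
  d <- as_direction_matrix(dirs)
  G <- abs(d %*% t(d))         # antipodally symmetric
  diag(G) <- 0
  acos(pmin(1, max(G))) * 180 / pi
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
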