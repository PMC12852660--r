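#' Acquisition protocol container
#'
#' Per-measurement b-value (stored in ms/um^2), b-tensor shape and principal
#' encoding direction. Inputs in the field-standard s/mm^2 convention are
#' divided by 1000 on read so that b * D is dimensionless with diffusivities
#' in um^2/ms.
#'
#' @param b b-values in ms/um^2 (use [read_protocol()] for s/mm^2 files).
#' @param b_delta b-tensor shapes in [-0.5, 1] (1 linear, 0 spherical,
#'   -0.5 planar).
#' @param u n x 3 matrix of unit encoding directions (arbitrary on b = 0
#'   rows, replaced by (1, 0, 0)).
#' @return object of class \code{sm_protocol} with fields \code{b},
#'   \code{b_delta}, \code{u} and \code{n}.
#' @export
sm_protocol <- function(b, b_delta, u) {
  b <- as.numeric(b)
  b_delta <- as.numeric(b_delta)
  u <- unname(as.matrix(u))
  if (ncol(u) != 3 && nrow(u) == 3) u <- t(u)
  n <- length(b)
  if (length(b_delta) != n || nrow(u) != n)
    stop("b, b_delta and u must describe the same number of measurements")
  if (any(b < 0)) stop("negative b-value")
  if (any(b_delta < -0.5 - 1e-9 | b_delta > 1 + 1e-9))
    stop("b_delta outside [-0.5, 1]")
  nrm <- sqrt(rowSums(u^2))
  zero <- nrm < 1e-12
  if (any(zero & b > 1e-12))
    stop("zero-norm direction on a diffusion-weighted measurement")
  u[zero, ] <- matrix(rep(c(1, 0, 0), sum(zero)), ncol = 3, byrow = TRUE)
  names(zero) <- NULL
  nrm[zero] <- 1
  if (any(b > 1e-12 & abs(nrm - 1) > 1e-6))
    stop("encoding directions must be unit-norm")
  u <- u / nrm
  structure(list(b = b, b_delta = b_delta, u = u, n = n,
                 b0_replaced = which(zero)),
            class = "sm_protocol")
}

#' @export
print.sm_protocol <- function(x, ...) {
  key <- paste(signif(x$b, 6), signif(x$b_delta, 6))
  shells <- unique(key)
  cat("Acquisition protocol:", x$n, "measurements,", length(shells),
      "unique (b, b_delta) shells\n")
  for (k in shells) {
    i <- which(key == k)[1]
    cat(sprintf("  b = %6.3f ms/um^2  b_delta = %5.2f  n = %d\n",
                x$b[i], x$b_delta[i], sum(key == k)))
  }
  invisible(x)
}

#' Read an acquisition protocol from FSL-style files
#'
#' \code{bval}/\code{bvec} follow the FSL convention (whitespace-delimited,
#' b-vectors as three rows or three columns); the b-tensor shape file is
#' plain text with one value per volume in the same order. b-values are
#' converted from s/mm^2 to ms/um^2 (divided by 1000). Zero-norm b-vectors on
#' b = 0 volumes are replaced by (1, 0, 0) and recorded in
#' \code{$b0_replaced}.
#'
#' @param bval_path,bvec_path,bdelta_path file paths.
#' @return an [sm_protocol()] object.
#' @export
read_protocol <- function(bval_path, bvec_path, bdelta_path) {
  bval <- scan(bval_path, quiet = TRUE)
  bvec <- as.matrix(utils::read.table(bvec_path))
  bdelta <- scan(bdelta_path, quiet = TRUE)
  if (nrow(bvec) == 3 && ncol(bvec) != 3) bvec <- t(bvec)
  if (length(bval) != nrow(bvec) || length(bval) != length(bdelta))
    stop("bval, bvec and bdelta describe different numbers of volumes")
  sm_protocol(b = bval / 1000, b_delta = bdelta, u = bvec)
}

#' Write an acquisition protocol to FSL-style files
#'
#' Inverse of [read_protocol()]: b-values are written in s/mm^2, b-vectors as
#' three rows.
#'
#' @param protocol an [sm_protocol()].
#' @param bval_path,bvec_path,bdelta_path output paths.
#' @export
write_protocol <- function(protocol, bval_path, bvec_path, bdelta_path) {
  stopifnot(inherits(protocol, "sm_protocol"))
  writeLines(paste(format(protocol$b * 1000, scientific = FALSE,
                          trim = TRUE), collapse = " "), bval_path)
  utils::write.table(t(protocol$u), bvec_path, row.names = FALSE,
                     col.names = FALSE)
  writeLines(paste(format(protocol$b_delta, trim = TRUE), collapse = " "),
             bdelta_path)
  invisible(protocol)
}

#' The optimized multi-shell b-tensor protocol used for simulation
#'
#' Six shells with b = (0, 1000, 2000, 8000, 5000, 2000) s/mm^2,
#' (4, 20, 40, 40, 35, 15) directions and b-tensor shapes
#' (1, 1, 1, 1, 0.8, 0); 154 measurements in total. Directions per shell are
#' spread by electrostatic repulsion on the hemisphere after which half are
#' flipped to the opposite hemisphere.
#'
#' @param seed seed for the per-shell direction optimization.
#' @return an [sm_protocol()] (b in ms/um^2).
#' @export
optimized_protocol <- function(seed = 20) {
  b_shell <- c(0, 1000, 2000, 8000, 5000, 2000) / 1000
  n_shell <- c(4, 20, 40, 40, 35, 15)
  bd_shell <- c(1, 1, 1, 1, 0.8, 0)
  b <- rep(b_shell, n_shell)
  bd <- rep(bd_shell, n_shell)
  u <- matrix(0, sum(n_shell), 3)
  row <- 1
  for (s in seq_along(b_shell)) {
    if (b_shell[s] == 0) {
      d <- matrix(rep(c(1, 0, 0), n_shell[s]), ncol = 3, byrow = TRUE)
    } else {
      d <- hemisphere_directions(n_shell[s], seed = seed + s)$dirs
      flip <- seq_len(n_shell[s]) %% 2 == 0
      d[flip, ] <- -d[flip, , drop = FALSE]
    }
    u[row:(row + n_shell[s] - 1), ] <- d
    row <- row + n_shell[s]
  }
  sm_protocol(b = b, b_delta = bd, u = u)
}

#' Per-voxel effective protocol under a gradient-coil tensor
#'
#' Builds the nominal axially symmetric B-tensor
#' \eqn{B = (b/3)[(1 - b_\Delta) I + 3 b_\Delta u u^T]} (so that
#' \eqn{\mathrm{tr}(B) = b}), applies the dimensionless gradient-coil tensor
#' \code{L} as \eqn{B_{eff} = L B L^T}, and returns the closest axially
#' symmetric description: \eqn{b_{eff} = \mathrm{tr}(B_{eff})}, \code{u_eff}
#' the principal eigenvector, and
#' \eqn{b_{\Delta,eff} = (\lambda_1 - (\lambda_2 + \lambda_3)/2)/b_{eff}}.
#' An exact identity \code{L} returns the input protocol unchanged. The
#' axially-symmetric reading is an approximation: gradient non-uniformity
#' generally breaks B-tensor axial symmetry for non-linear encodings.
#'
#' @param protocol nominal [sm_protocol()].
#' @param L 3 x 3 gradient-coil tensor.
#' @return effective [sm_protocol()] for the voxel.
#' @export
effective_protocol <- function(protocol, L) {
  stopifnot(inherits(protocol, "sm_protocol"))
  L <- as.matrix(L)
  if (!all(dim(L) == c(3, 3)) || any(!is.finite(L)))
    stop("L must be a finite 3 x 3 matrix")
  if (all(L == diag(3))) return(protocol)
  n <- protocol$n
  b_eff <- numeric(n)
  bd_eff <- numeric(n)
  u_eff <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    b <- protocol$b[i]
    if (b == 0) {
      b_eff[i] <- 0
      bd_eff[i] <- protocol$b_delta[i]
      u_eff[i, ] <- protocol$u[i, ]
      next
    }
    bd <- protocol$b_delta[i]
    u <- protocol$u[i, ]
    B <- (b / 3) * ((1 - bd) * diag(3) + 3 * bd * tcrossprod(u))
    Be <- L %*% B %*% t(L)
    Be <- (Be + t(Be)) / 2
    eg <- eigen(Be, symmetric = TRUE)   # eigenvalues descending
    b_eff[i] <- sum(diag(Be))
    if (b_eff[i] <= 0) stop("degenerate gradient tensor: effective b <= 0")
    ev <- eg$values
    # the axis is the most distinct eigenvalue (prolate: largest;
    # oblate/planar: smallest)
    k <- if (ev[1] - ev[2] >= ev[2] - ev[3]) 1 else 3
    lam1 <- ev[k]
    rest <- ev[-k]
    bd_eff[i] <- (lam1 - mean(rest)) / b_eff[i]
    v <- eg$vectors[, k]
    nz <- which(abs(v) > 1e-12)[1]
    if (v[nz] < 0) v <- -v          # antipodally inert sign convention
    u_eff[i, ] <- v
  }
  sm_protocol(b = b_eff, b_delta = pmin(1, pmax(-0.5, bd_eff)), u = u_eff)
}

protocol_fingerprint <- function(protocol) {
  v <- c(protocol$b, protocol$b_delta, as.numeric(protocol$u))
  sprintf("%.8e", sum(v * seq_along(v)) + sum(v^2))
}
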