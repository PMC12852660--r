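#' Pearson correlation between estimate and truth over a mask
#'
#' Non-finite estimates are dropped (their count is available through
#' [metric_report()]). Undefined correlations (zero variance, fewer than 3
#' voxels) return \code{NA}.
#'
#' @param est,truth numeric arrays/vectors of equal length.
#' @param mask optional logical array/vector selecting voxels.
#' @return Pearson's rho, or \code{NA} when undefined.
#' @export
pearson_rho <- function(est, truth, mask = NULL) {
  v <- select_pairs(est, truth, mask)
  if (length(v$e) < 3) return(NA_real_)
  if (stats::sd(v$e) == 0 || stats::sd(v$t) == 0) return(NA_real_)
  stats::cor(v$e, v$t)
}

#' Root mean squared error over a mask
#'
#' @inheritParams pearson_rho
#' @return RMSE in the parameter's units.
#' @export
rmse <- function(est, truth, mask = NULL) {
  v <- select_pairs(est, truth, mask)
  if (length(v$e) == 0) stop("no finite voxels selected")
  sqrt(mean((v$e - v$t)^2))
}

select_pairs <- function(est, truth, mask) {
  e <- as.numeric(est)
  t <- as.numeric(truth)
  if (length(e) != length(t)) stop("est and truth differ in length")
  keep <- if (is.null(mask)) rep(TRUE, length(e)) else as.logical(mask)
  keep <- keep & is.finite(e) & is.finite(t)
  list(e = e[keep], t = t[keep])
}

#' Separable interpolation of a 3-D map onto a refined grid
#'
#' Upsamples by an integer factor with either trilinear interpolation or
#' separable cubic convolution (Keys kernel, a = -1/2). Edges are padded by
#' linear extrapolation so linear ramps are reproduced exactly everywhere.
#'
#' @param map 3-D array or [volume_grid()].
#' @param factor integer refinement factor (>= 1; 1 is the identity).
#' @param method \code{"linear"} or \code{"cubic"}.
#' @return array of dimension \code{dim(map) * factor}.
#' @export
interpolate_map <- function(map, factor, method = c("linear", "cubic")) {
  method <- match.arg(method)
  if (inherits(map, "volume_grid")) map <- map$data
  if (length(dim(map)) != 3) stop("map must be 3-D")
  stopifnot(factor >= 1, factor == round(factor))
  if (factor == 1) return(map)
  a <- map
  for (ax in 1:3) a <- interp_axis(a, ax, factor, method)
  a
}

# 1-D kernel interpolation along axis ax of a 3-D array, vectorized over
# the other two axes by permuting the axis to the front.
interp_axis <- function(arr, ax, factor, method) {
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  d <- dim(a)
  n <- d[1]
  m <- matrix(a, n, prod(d[-1]))
  # pad by linear extrapolation (preserves ramps through the border)
  pad <- 2
  top <- m[rep(1, pad), , drop = FALSE] +
    (m[rep(1, pad), , drop = FALSE] - m[rep(2, pad), , drop = FALSE]) *
    rev(seq_len(pad))
  bot <- m[rep(n, pad), , drop = FALSE] +
    (m[rep(n, pad), , drop = FALSE] - m[rep(n - 1, pad), , drop = FALSE]) *
    seq_len(pad)
  mp <- rbind(top, m, bot)
  xi <- (seq_len(n * factor) - 0.5) / factor + 0.5   # in source index units
  i0 <- floor(xi)
  fr <- xi - i0
  out <- matrix(0, n * factor, ncol(m))
  if (method == "linear") {
    w <- cbind(1 - fr, fr)
    offs <- 0:1
  } else {
    w <- cbind(keys_kernel(fr + 1), keys_kernel(fr), keys_kernel(1 - fr),
               keys_kernel(2 - fr))
    offs <- -1:2
  }
  for (k in seq_along(offs)) {
    rows <- i0 + offs[k] + pad
    out <- out + w[, k] * mp[rows, , drop = FALSE]
  }
  dim(out) <- c(n * factor, d[-1])
  aperm(out, order(perm))
}

keys_kernel <- function(x) {
  x <- abs(x)
  ifelse(x <= 1, 1.5 * x^3 - 2.5 * x^2 + 1,
         ifelse(x < 2, -0.5 * x^3 + 2.5 * x^2 - 4 * x + 2, 0))
}

#' Accuracy report of estimated parameter maps against ground truth
#'
#' Computes Pearson's rho and RMSE per kernel parameter (and the p2
#' rotational invariant when FOD coefficients are supplied) over the masked
#' voxels, dropping non-finite estimates and counting them.
#'
#' @param est matrix of estimates (voxels x parameters) with columns
#'   \code{f_i}, \code{D_i}, \code{De_par}, \code{De_perp} (and optionally
#'   more); typically \code{coef()} of a fit restricted to the mask voxels.
#' @param truth matching matrix of ground-truth values.
#' @param est_fod,truth_fod optional SH coefficient matrices for the p2
#'   invariant.
#' @param label method label stored in the report.
#' @return object of class \code{sm_metric_report} with named \code{rho} and
#'   \code{rmse} vectors, voxel counts and the label.
#' @export
metric_report <- function(est, truth, est_fod = NULL, truth_fod = NULL,
                          label = "method") {
  params <- intersect(colnames(truth), c("f_i", "D_i", "De_par", "De_perp"))
  if (length(params) == 0) params <- colnames(truth)
  rho <- vapply(params, function(pn) pearson_rho(est[, pn], truth[, pn]),
                numeric(1))
  rms <- vapply(params, function(pn) rmse(est[, pn], truth[, pn]),
                numeric(1))
  dropped <- sum(!stats::complete.cases(est[, params, drop = FALSE]))
  if (!is.null(est_fod) && !is.null(truth_fod)) {
    ok <- stats::complete.cases(est_fod)
    rho <- c(rho, p2 = pearson_rho(p2_invariant(est_fod[ok, , drop = FALSE]),
                                   p2_invariant(truth_fod[ok, , drop = FALSE])))
    rms <- c(rms, p2 = rmse(p2_invariant(est_fod[ok, , drop = FALSE]),
                            p2_invariant(truth_fod[ok, , drop = FALSE])))
  }
  structure(list(rho = rho, rmse = rms, n_voxels = nrow(est),
                 n_dropped = dropped, label = label),
            class = "sm_metric_report")
}

#' @export
print.sm_metric_report <- function(x, ...) {
  cat(sprintf("Metric report [%s]: %d voxels (%d dropped)\n", x$label,
              x$n_voxels, x$n_dropped))
  tab <- rbind(rho = x$rho, RMSE = x$rmse)
  print(round(tab, 4))
  invisible(x)
}

#' Tabulate and rank metric reports of several methods
#'
#' @param ... [metric_report()] objects sharing the same mask/truth.
#' @return data frame with one row per (method, parameter) pair, ordered by
#'   method label then parameter; also printable as a wide comparison.
#' @export
compare_methods <- function(...) {
  reports <- list(...)
  if (length(reports) == 1 && is.list(reports[[1]]) &&
      !inherits(reports[[1]], "sm_metric_report"))
    reports <- reports[[1]]
  stopifnot(all(vapply(reports, inherits, logical(1), "sm_metric_report")))
  nv <- vapply(reports, function(r) r$n_voxels, numeric(1))
  if (length(unique(nv)) > 1)
    stop("reports cover different voxel sets")
  rows <- do.call(rbind, lapply(reports, function(r)
    data.frame(method = r$label, parameter = names(r$rho),
               rho = unname(r$rho), rmse = unname(r$rmse),
               n_voxels = r$n_voxels, row.names = NULL)))
  rows[order(rows$method, rows$parameter), , drop = FALSE]
}
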