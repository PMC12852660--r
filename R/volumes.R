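#' Gridded volume container
#'
#' Thin wrapper around a 3-D or 4-D array plus voxel geometry: voxel size in
#' mm and the 4 x 4 voxel-to-world affine (NIfTI convention, 0-based voxel
#' indices).
#'
#' @param data 3-D or 4-D numeric/logical array.
#' @param voxel_size length-3 positive voxel edge lengths (mm).
#' @param affine 4 x 4 voxel-to-world transform; default is a diagonal
#'   scaling by \code{voxel_size}.
#' @return object of class \code{volume_grid}.
#' @export
volume_grid <- function(data, voxel_size = c(1, 1, 1), affine = NULL) {
  nd <- length(dim(data))
  if (is.null(dim(data)) || nd < 3 || nd > 4)
    stop("data must be a 3-D or 4-D array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive lengths")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4 x 4 matrix")
  structure(list(data = data, shape = dim(data)[1:3],
                 voxel_size = voxel_size, affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("volume_grid:", paste(dim(x$data), collapse = " x "),
      "voxels of", paste(signif(x$voxel_size, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI-1 file (.nii or .nii.gz), 3-D or 4-D.
#' @param mask logical; threshold the data at 0.5 into a boolean field.
#' @return a [volume_grid()].
#' @export
read_volume <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 4) stop("only 3-D and 4-D volumes are supported")
  if (length(d) < 3) stop("volume must be at least 3-D")
  data <- array(as.vector(img), d)        # plain array, no image attributes
  if (mask) data <- data > 0.5
  vs <- as.numeric(attr(img, "pixdim"))[1:3]
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  volume_grid(data, voxel_size = vs, affine = aff)
}

#' Write a NIfTI volume
#'
#' The grid's affine is stored as the sform; no resampling is performed.
#' Data are stored as float32 by default (uint8 for logical masks).
#'
#' @param grid a [volume_grid()] (or bare array, written with unit voxels).
#' @param path output path (.nii or .nii.gz).
#' @param datatype NIfTI storage type passed to [RNifti::writeNifti()].
#' @export
write_volume <- function(grid, path, datatype = NULL) {
  if (!inherits(grid, "volume_grid")) grid <- volume_grid(grid)
  data <- grid$data
  if (is.null(datatype)) datatype <- if (is.logical(data)) "uint8" else "float"
  if (is.logical(data)) data <- array(as.integer(data), dim(data))
  img <- RNifti::asNifti(data)
  pd <- rep(1, length(dim(data)))
  pd[1:3] <- grid$voxel_size
  RNifti::pixdim(img) <- pd
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

as_mask_array <- function(mask, shape) {
  if (inherits(mask, "volume_grid")) mask <- mask$data
  if (is.null(mask)) mask <- array(TRUE, shape)
  m <- mask > 0.5
  if (!all(dim(m)[1:3] == shape)) stop("mask does not match the data grid")
  array(m, shape)
}

# Fractional 1-based voxel indices of voxel centers; factor > 1 refines the
# grid in every dimension while covering the same field of view.
refined_voxel_centers <- function(shape, factor = 1) {
  ax <- lapply(shape, function(n) (seq_len(n * factor) - 0.5) / factor + 0.5)
  as.matrix(expand.grid(i = ax[[1]], j = ax[[2]], k = ax[[3]]))
}

refined_grid_geometry <- function(grid, factor) {
  s <- 1 / factor
  Tm <- diag(c(s, s, s, 1))
  Tm[1:3, 4] <- 0.5 * s - 0.5      # 0-based index mapping new -> old
  list(shape = grid$shape * factor,
       voxel_size = grid$voxel_size / factor,
       affine = grid$affine %*% Tm)
}
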