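# Single-file model container: a magic line, a JSON metadata header, then
# raw little-endian float64 blobs for every weight array in manifest order.
# Inspectable (the header is plain JSON) and language-portable.

MODEL_MAGIC <- "SMINR01"

model_blob_list <- function(model) {
  blobs <- list(A = model$A)
  for (i in 1:4) {
    blobs[[paste0("W", i)]] <- model$layers[[i]]$W
    blobs[[paste0("b", i)]] <- model$layers[[i]]$b
  }
  blobs$Wh <- model$Wh
  blobs$bh <- model$bh
  if (!is.null(model$adam) && length(model$adam$m)) {
    for (k in names(model$adam$m)) {
      blobs[[paste0("adam_m_", k)]] <- model$adam$m[[k]]
      blobs[[paste0("adam_v_", k)]] <- model$adam$v[[k]]
    }
  }
  if (!is.null(model$rng)) blobs$rng <- as.numeric(model$rng)
  # float-critical scalars carried in binary so loading is bit-exact
  blobs$scalars <- c(model$s0_scale, model$sigma2,
                     if (is.null(model$scaler)) rep(NA_real_, 7)
                     else c(model$scaler$center, model$scaler$voxel_size,
                            model$scaler$factor))
  blobs
}

#' Save a fitted (or initialized) INR model to a single file
#'
#' Stores the encoding matrix, all network weights, the optimizer and RNG
#' state (so training can be resumed exactly), the coordinate scaler, SH
#' band limit, parameter bounds, seed and a protocol fingerprint. Loading
#' reproduces predictions bit-identically.
#'
#' @param fit an [fit_sm_inr()] result or a bare [init_inr()] model.
#' @param path output file.
#' @export
save_model <- function(fit, path) {
  if (inherits(fit, "sm_inr_fit")) {
    model <- fit$model
    extra <- list(trace = fit$trace, config = fit$config, grid = fit$grid,
                  fingerprint = protocol_fingerprint(fit$protocol),
                  protocol = list(b = fit$protocol$b,
                                  b_delta = fit$protocol$b_delta,
                                  u = as.numeric(fit$protocol$u)))
  } else if (inherits(fit, "sm_inr")) {
    model <- fit
    extra <- list(trace = model$trace)
  } else stop("expected an sm_inr_fit or sm_inr object")

  blobs <- model_blob_list(model)
  manifest <- lapply(blobs, function(b)
    if (is.matrix(b)) dim(b) else length(b))
  meta <- list(magic = MODEL_MAGIC, version = 1L,
               n_p = model$n_p, n_h = model$n_h, sigma2 = model$sigma2,
               lmax = model$lmax, s0_scale = model$s0_scale,
               seed = model$seed, epoch = model$epoch,
               bounds = model$bounds, scaler = model$scaler,
               adam_t = if (is.null(model$adam)) 0L else model$adam$t,
               has_rng = !is.null(model$rng),
               rng_int = if (is.null(model$rng)) NULL
                         else is.integer(model$rng),
               manifest = manifest, extra = extra)
  hdr <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                          null = "null")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(MODEL_MAGIC, con)
  writeBin(as.numeric(nchar(hdr, type = "bytes")), con, size = 8,
           endian = "little")
  writeChar(as.character(hdr), con, eos = NULL)
  for (b in blobs) writeBin(as.numeric(b), con, size = 8, endian = "little")
  invisible(path)
}

#' Load an INR model saved by [save_model()]
#'
#' @param path model file.
#' @param lmax optional expected SH band limit; a mismatch is an error.
#' @param protocol optional protocol; a fingerprint mismatch warns.
#' @return an [fit_sm_inr()]-style object when fit context was stored
#'   (without training signals), otherwise a bare \code{sm_inr} model.
#' @export
load_model <- function(path, lmax = NULL, protocol = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, MODEL_MAGIC))
    stop("not a model container (bad magic)")
  nhdr <- readBin(con, "numeric", size = 8, endian = "little")
  if (length(nhdr) != 1 || is.na(nhdr) || nhdr <= 0 ||
      nhdr != round(nhdr))
    stop("corrupt model file: bad header length")
  hdr <- readChar(con, nhdr, useBytes = TRUE)
  meta <- jsonlite::fromJSON(hdr, simplifyVector = TRUE)
  if (!identical(meta$magic, MODEL_MAGIC)) stop("corrupt model header")
  if (!is.null(lmax) && meta$lmax != lmax)
    stop("model has lmax ", meta$lmax, ", expected ", lmax)

  blobs <- list()
  for (k in names(meta$manifest)) {
    d <- meta$manifest[[k]]
    n <- prod(d)
    v <- readBin(con, "numeric", n = n, size = 8, endian = "little")
    if (length(v) != n) stop("corrupt model file: truncated blob ", k)
    blobs[[k]] <- if (length(d) == 2) matrix(v, d[1], d[2]) else v
  }

  sc <- blobs$scalars
  model <- init_inr(meta$n_p, meta$n_h, sigma2 = sc[2],
                    lmax = meta$lmax, seed = meta$seed, s0_scale = sc[1])
  model$A <- blobs$A
  for (i in 1:4) {
    model$layers[[i]]$W <- blobs[[paste0("W", i)]]
    model$layers[[i]]$b <- blobs[[paste0("b", i)]]
  }
  model$Wh <- blobs$Wh
  model$bh <- blobs$bh
  model$epoch <- meta$epoch
  if (!anyNA(sc[3:9]))
    model$scaler <- list(center = sc[3:5], voxel_size = sc[6:8],
                         factor = sc[9])
  if (meta$adam_t > 0) {
    st <- adam_init()
    st$t <- as.integer(meta$adam_t)
    for (k in grep("^adam_m_", names(blobs), value = TRUE)) {
      nm <- sub("^adam_m_", "", k)
      st$m[[nm]] <- blobs[[k]]
      st$v[[nm]] <- blobs[[paste0("adam_v_", nm)]]
    }
    model$adam <- st
  }
  if (isTRUE(meta$has_rng)) {
    rng <- blobs$rng
    model$rng <- if (isTRUE(meta$rng_int)) as.integer(rng) else rng
  }
  if (!is.null(meta$extra$trace)) model$trace <- meta$extra$trace

  if (is.null(meta$extra$config)) return(model)

  proto <- sm_protocol(meta$extra$protocol$b, meta$extra$protocol$b_delta,
                       matrix(meta$extra$protocol$u, ncol = 3))
  if (!is.null(protocol) &&
      !identical(protocol_fingerprint(protocol), meta$extra$fingerprint))
    warning("protocol fingerprint differs from the one the model was ",
            "fitted with")
  grid <- meta$extra$grid
  grid$shape <- as.integer(grid$shape)
  grid$affine <- matrix(as.numeric(grid$affine), 4, 4)
  mask <- NULL
  structure(list(model = model, trace = meta$extra$trace, protocol = proto,
                 grid = grid, mask = mask, voxels = NULL, ijk = NULL,
                 signals = NULL, config = meta$extra$config,
                 call = NULL),
            class = "sm_inr_fit")
}
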