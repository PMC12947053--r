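# Local 3D refinement and sigmoid-weighted fusion.
#
# Selected kernels are cropped from the MP-MRI volume (no resampling), sent
# through the local 3D predictor, and the per-voxel local probabilities are
# averaged into a composite map with an integer coverage count. Fusion:
# voxels with zero coverage keep the global 2D probability unchanged;
# covered voxels get sigmoid(w2d * P2D + w3d * P3Dcomposite + b).

#' Fusion weights
#'
#' @param w2d,w3d non-negative weighting coefficients of the global 2D and
#'   composite 3D probabilities.
#' @param b bias; `"centered"` (the default policy) sets
#'   `b = -(w2d + w3d) / 2` so that two 0.5 inputs fuse to 0.5.
#' @return An object of class `fusion_weights`.
#' @export
fusion_weights <- function(w2d, w3d, b = "centered") {
  if (w2d < 0 || w3d < 0)
    stop("fusion_weights: w2d and w3d must be non-negative")
  if (identical(b, "centered")) b <- -(w2d + w3d) / 2
  stopifnot(is.finite(b))
  structure(list(w2d = w2d, w3d = w3d, b = b), class = "fusion_weights")
}

#' Extract a 4-channel kernel subvolume
#'
#' Exact crop, no resampling. The returned tensor carries the kernel as an
#' attribute so location-aware predictors (e.g., the ground-truth oracle)
#' can use it.
#'
#' @param volume an [mpmri_volume()].
#' @param kernel a [kernel_region()].
#' @return `4 x d x d x d` array with attribute `kernel`.
#' @export
extract_subvolume <- function(volume, kernel) {
  d <- kernel$d; co <- kernel$corner
  dims <- dim(volume$data)[-1]
  if (any(co < 0L) || any(co + d > dims))
    stop("extract_subvolume: kernel exceeds the volume bounds")
  sub <- volume$data[, co[1] + seq_len(d), co[2] + seq_len(d),
                     co[3] + seq_len(d), drop = FALSE]
  attr(sub, "kernel") <- kernel
  sub
}

#' Average local predictions into a composite map with coverage counts
#'
#' @param locals list of local predictions, each a list with elements
#'   `kernel` ([kernel_region()]) and `probs` (`d x d x d` array in `[0, 1]`).
#' @param grid_size full-volume dimensions, length 3.
#' @return list with `probs` (composite probability array; 0 and ignored
#'   where uncovered) and `coverage` (integer array of contributing-kernel
#'   counts per voxel). Order-invariant in `locals`.
#' @export
build_composite <- function(locals, grid_size) {
  grid_size <- as.integer(grid_size)
  acc <- array(0, grid_size)
  cov <- array(0L, grid_size)
  seen <- character(0)
  for (lp in locals) {
    k <- lp$kernel; d <- k$d
    if (!identical(dim(lp$probs), rep(as.integer(d), 3L)))
      stop("build_composite: local prediction shape does not match its kernel")
    if (anyNA(lp$probs) || any(lp$probs < 0 | lp$probs > 1))
      stop("build_composite: local probabilities outside [0, 1]")
    key <- paste(k$corner, collapse = ",")
    if (key %in% seen)
      warning("build_composite: duplicate kernel at corner (", key,
              ") counted twice")
    seen <- c(seen, key)
    ii <- k$corner[1] + seq_len(d); jj <- k$corner[2] + seq_len(d)
    kk <- k$corner[3] + seq_len(d)
    acc[ii, jj, kk] <- acc[ii, jj, kk] + lp$probs
    cov[ii, jj, kk] <- cov[ii, jj, kk] + 1L
  }
  probs <- ifelse(cov > 0L, acc / pmax(cov, 1L), 0)
  list(probs = array(probs, grid_size), coverage = cov)
}

#' Fuse global 2D and composite 3D probabilities
#'
#' @param p2d [probability_volume()] or 3D array: the global 2D probability.
#' @param composite list from [build_composite()].
#' @param weights a [fusion_weights()].
#' @return 3D array: `p2d` unchanged where coverage is 0 (no sigmoid
#'   applied), `sigmoid(w2d*p2d + w3d*composite + b)` where coverage >= 1.
#' @export
fuse <- function(p2d, composite, weights) {
  stopifnot(inherits(weights, "fusion_weights"))
  if (inherits(p2d, "probability_volume")) p2d <- p2d$data
  if (!identical(dim(p2d), dim(composite$probs)))
    stop("fuse: grids do not match")
  out <- p2d
  covered <- composite$coverage >= 1L
  if (any(covered)) {
    z <- weights$w2d * p2d[covered] + weights$w3d * composite$probs[covered] +
      weights$b
    out[covered] <- logistic(z)
  }
  out
}

#' Run the localized 3D refinement and fusion stage
#'
#' Pipeline: select kernels on the uncertainty map, crop the MP-MRI
#' subvolumes, predict each with the 3D backend, average into the composite
#' map, fuse with the global 2D probability, binarize (strictly > 0.5).
#' An empty selection is a graceful no-op: the fused map equals `p2d`.
#'
#' @param volume an [mpmri_volume()].
#' @param u2d 3D uncertainty array from [run_uncertainty_stage()].
#' @param p2d the global 2D [probability_volume()] (or array).
#' @param predictor3d a volume predictor.
#' @param config a [selection_config()].
#' @param weights a [fusion_weights()].
#' @return list with `pfused` ([probability_volume()]), `mask`
#'   ([label_volume()]), `kernels`, `composite`.
#' @export
run_refinement_stage <- function(volume, u2d, p2d, predictor3d,
                                 config = selection_config(),
                                 weights = fusion_weights(1, 1)) {
  if (inherits(p2d, "probability_volume")) {
    spacing <- p2d$spacing
    p2d <- p2d$data
  } else spacing <- volume$spacing
  kernels <- select_kernels(unclass(u2d), config)
  if (length(kernels) == 0L) {
    return(list(pfused = probability_volume(p2d, spacing = spacing),
                mask = label_volume(binarize(p2d), spacing = spacing),
                kernels = kernels,
                composite = list(probs = array(0, dim(p2d)),
                                 coverage = array(0L, dim(p2d)))))
  }
  locals <- lapply(kernels, function(k) {
    sub <- extract_subvolume(volume, k)
    list(kernel = k, probs = predictor3d(sub))
  })
  composite <- build_composite(locals, dim(p2d))
  pf <- fuse(p2d, composite, weights)
  list(pfused = probability_volume(pf, spacing = spacing),
       mask = label_volume(binarize(pf), spacing = spacing),
       kernels = kernels, composite = composite)
}
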