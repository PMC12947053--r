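# Sliding-window localization of high-cumulative-uncertainty subvolumes.
#
# Every cubic d x d x d window fully inside the volume is scored by the sum
# of the voxel-wise uncertainty it encloses (exact, via a 3D summed-area
# table). Windows are then accepted greedily by descending score, rejecting
# any candidate whose volumetric overlap with an already-accepted kernel
# exceeds the constraint (default 40% of the kernel volume), until the best
# remaining score falls below a stop fraction of the top score.

#' Cubic kernel region
#'
#' @param corner 0-based voxel index of the minimum corner, length 3.
#' @param d edge length in voxels (>= 1).
#' @param score cumulative uncertainty inside the kernel (>= 0).
#' @param rank selection order (1 = highest score accepted first).
#' @return An object of class `kernel_region`.
#' @export
kernel_region <- function(corner, d, score = NA_real_, rank = NA_integer_) {
  corner <- as.integer(corner)
  stopifnot(length(corner) == 3L, d >= 1L, all(corner >= 0L))
  structure(list(corner = corner, d = as.integer(d), score = score,
                 rank = rank),
            class = "kernel_region")
}

#' Kernel selection configuration
#'
#' @param d kernel edge in voxels. The headline choices are 32 for ET/TC and
#'   64 for WT (power-of-two round-down of the cohort's median tumor extents).
#' @param max_overlap maximum allowed pairwise volumetric overlap as a
#'   fraction of the kernel volume, in `[0, 1)`; default 0.4.
#' @param stop_fraction selection halts once the best remaining score drops
#'   below `stop_fraction` times the first accepted score, in `(0, 1]`;
#'   default 0.1. Set `stop_abs` instead for an absolute score threshold.
#' @param stride voxels between candidate corners (>= 1, default 1: densest).
#' @param stop_abs optional absolute score threshold overriding the relative
#'   rule.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(d = 32L, max_overlap = 0.4, stop_fraction = 0.1,
                             stride = 1L, stop_abs = NULL) {
  stopifnot(d >= 1L, max_overlap >= 0, max_overlap < 1,
            stop_fraction > 0, stop_fraction <= 1, stride >= 1L)
  structure(list(d = as.integer(d), max_overlap = max_overlap,
                 stop_fraction = stop_fraction, stride = as.integer(stride),
                 stop_abs = stop_abs),
            class = "selection_config")
}

# cumulative sum of a 3D array along one axis, axes restored
cumsum_axis <- function(A, axis) {
  others <- setdiff(1:3, axis)
  out <- apply(A, others, cumsum)        # dims become c(axis, others)
  aperm(out, match(1:3, c(axis, others)))
}

#' Exact window sums over all candidate corners
#'
#' Computes, via a 3D summed-area table, the sum of `U` over the d-cube at
#' every candidate corner in `[0, dim - d]` at the given stride.
#'
#' @param U 3D uncertainty array.
#' @param d window edge (voxels); must not exceed any dimension.
#' @param stride candidate spacing (voxels).
#' @return list with `scores` (3D array over candidate corners) and
#'   `corners` (list of the 0-based corner coordinates per axis).
#' @export
window_sums <- function(U, d, stride = 1L) {
  U <- unclass(U)
  dims <- dim(U)
  stopifnot(length(dims) == 3L)
  if (any(d > dims)) stop("window_sums: window edge exceeds a volume dimension")
  # summed-area table padded with a zero face on each leading side
  S <- array(0, dims + 1L)
  S[-1, -1, -1] <- U
  for (axis in 1:3) S <- cumsum_axis(S, axis)
  ax <- lapply(dims, function(n) seq.int(0L, n - d, by = stride))
  lo <- lapply(ax, function(a) a + 1L)        # 1-based index into S of corner
  hi <- lapply(ax, function(a) a + d + 1L)
  blk <- function(i, j, k) S[i, j, k, drop = FALSE]
  scores <- blk(hi[[1]], hi[[2]], hi[[3]]) -
    blk(lo[[1]], hi[[2]], hi[[3]]) - blk(hi[[1]], lo[[2]], hi[[3]]) -
    blk(hi[[1]], hi[[2]], lo[[3]]) +
    blk(lo[[1]], lo[[2]], hi[[3]]) + blk(lo[[1]], hi[[2]], lo[[3]]) +
    blk(hi[[1]], lo[[2]], lo[[3]]) -
    blk(lo[[1]], lo[[2]], lo[[3]])
  list(scores = array(scores, vapply(ax, length, integer(1))), corners = ax)
}

#' Volumetric overlap fraction of two equal-sized kernels
#'
#' @param a,b [kernel_region()] objects with equal `d`.
#' @return `|intersection| / d^3`, in `[0, 1]`; symmetric.
#' @export
overlap_fraction <- function(a, b) {
  if (a$d != b$d) stop("overlap_fraction: kernels must share one edge length")
  ov <- pmax(0, a$d - abs(a$corner - b$corner))
  prod(ov) / a$d^3
}

#' Greedy overlap-constrained kernel selection
#'
#' Candidates (all in-bounds corners at the configured stride) are visited by
#' descending window score, ties broken by lexicographic corner order. A
#' candidate is accepted iff its overlap fraction with every previously
#' accepted kernel is at most `max_overlap`. Selection halts when the best
#' remaining score falls below `stop_fraction` times the first accepted
#' score (or below `stop_abs` when set), or when candidates are exhausted.
#' An all-zero uncertainty map yields an empty selection.
#'
#' @param U 3D uncertainty array.
#' @param config a [selection_config()].
#' @return list of [kernel_region()] in selection order, each with its score
#'   and rank.
#' @export
select_kernels <- function(U, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  ws <- window_sums(U, config$d, config$stride)
  sc <- as.vector(ws$scores)
  if (all(sc <= 0)) return(list())
  nd <- dim(ws$scores)
  ij <- arrayInd(seq_along(sc), nd)
  corners <- cbind(ws$corners[[1]][ij[, 1]], ws$corners[[2]][ij[, 2]],
                   ws$corners[[3]][ij[, 3]])
  ord <- order(-sc, corners[, 1], corners[, 2], corners[, 3])
  accepted <- list()
  top <- NULL
  for (idx in ord) {
    s <- sc[idx]
    thresh <- if (!is.null(config$stop_abs)) config$stop_abs
      else if (is.null(top)) -Inf else config$stop_fraction * top
    if (s < thresh || s <= 0) break
    cand <- kernel_region(corners[idx, ], config$d, score = s)
    ok <- all(vapply(accepted, function(a)
      overlap_fraction(a, cand) <= config$max_overlap, logical(1)))
    if (ok) {
      cand$rank <- length(accepted) + 1L
      accepted[[cand$rank]] <- cand
      if (is.null(top)) top <- s
    }
  }
  accepted
}

#' Kernel edge from a median anatomical extent
#'
#' Rounds the extent down to the nearest power of two: median extents of
#' ~42-53 mm (enhancing tumor / tumor core) give d = 32 and ~83 mm (whole
#' tumor) gives d = 64 on a 1 mm isotropic grid.
#'
#' @param median_extent positive extent in mm (>= 1).
#' @return the largest power of two `<= median_extent`, in voxels.
#' @export
choose_kernel_size <- function(median_extent) {
  if (median_extent < 1) stop("choose_kernel_size: extent must be >= 1")
  2^floor(log2(median_extent))
}

#' Export kernels as plain records
#'
#' @param kernels list of [kernel_region()].
#' @return data.frame with corner columns, edge, score and rank.
#' @export
kernels_as_table <- function(kernels) {
  if (length(kernels) == 0L)
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      d = integer(), score = numeric(), rank = integer()))
  do.call(rbind, lapply(kernels, function(x)
    data.frame(i = x$corner[1], j = x$corner[2], k = x$corner[3],
               d = x$d, score = x$score, rank = x$rank)))
}
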