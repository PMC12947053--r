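# Ensemble aggregation: mean probability, binarized mask, and the Shannon
# entropy uncertainty map. Per pixel, the ensemble's continuous predictions
# in [0,1] are linearly discretized into B bins (default 100, last bin
# right-closed so 1.0 is counted) and the entropy -sum f(t) ln f(t) is taken
# over the nonzero-bin empirical frequencies, in nats: 0 at unanimity,
# ln(k) when k bins are equally filled, at most ln(B).

#' Stack of back-projected ensemble predictions for one slice
#'
#' @param probs `n_origins x H x W` array of probabilities in `[0, 1]`.
#' @param valid logical array of the same shape marking in-domain pull-backs;
#'   defaults to all valid.
#' @return An object of class `prediction_stack`.
#' @export
prediction_stack <- function(probs, valid = NULL) {
  probs <- as.array(probs)
  if (length(dim(probs)) != 3L)
    stop("prediction_stack: probs must be n_origins x H x W")
  if (is.null(valid)) valid <- array(TRUE, dim(probs))
  if (anyNA(probs[valid]) || any(probs[valid] < 0 | probs[valid] > 1))
    stop("prediction_stack: probabilities outside [0, 1]")
  if (dim(probs)[1] < 2L)
    warning("prediction_stack: fewer than 2 ensemble members; entropy is trivially 0")
  structure(list(probs = probs, valid = valid), class = "prediction_stack")
}

# bin index in 1..bins for p in [0,1]; last bin right-closed
bin_index <- function(p, bins) pmin(floor(p * bins), bins - 1L) + 1L

#' Shannon-entropy uncertainty map of a prediction stack
#'
#' @param stack a [prediction_stack()].
#' @param bins number of uniform discretization bins on `[0, 1]` (default 100).
#' @return `H x W` entropy matrix (nats) with attributes `bins` and
#'   `no_valid` (logical matrix flagging pixels with zero valid predictions,
#'   whose entropy is reported as 0).
#' @export
entropy_map <- function(stack, bins = 100L) {
  stopifnot(inherits(stack, "prediction_stack"), bins >= 2L)
  bins <- as.integer(bins)
  d <- dim(stack$probs)
  n <- d[1]; P <- d[2] * d[3]
  pm <- matrix(stack$probs, n, P)
  vm <- matrix(stack$valid, n, P)
  pix <- matrix(rep(seq_len(P), each = n), n, P)
  idx <- bin_index(pm[vm], bins) + (pix[vm] - 1L) * bins
  cnt <- matrix(tabulate(idx, nbins = as.double(bins) * P), bins, P)
  nv <- colSums(vm)
  f <- cnt / rep(pmax(nv, 1L), each = bins)
  term <- f * log(f)
  term[cnt == 0L] <- 0
  ent <- matrix(-colSums(term), d[2], d[3])
  ent[ent <= 0] <- 0  # guard against -0 and rounding
  structure(ent, bins = bins, no_valid = matrix(nv == 0L, d[2], d[3]))
}

#' Mean probability of a prediction stack
#'
#' Per-pixel arithmetic mean over valid ensemble members; pixels with no
#' valid member get 0.
#'
#' @param stack a [prediction_stack()].
#' @return `H x W` matrix in `[0, 1]`.
#' @export
mean_probability <- function(stack) {
  stopifnot(inherits(stack, "prediction_stack"))
  d <- dim(stack$probs)
  p <- stack$probs
  p[!stack$valid] <- 0
  s <- colSums(p)                      # sums over the ensemble axis
  nv <- colSums(stack$valid)
  out <- ifelse(nv > 0, s / pmax(nv, 1L), 0)
  matrix(out, d[2], d[3])
}

#' Binarize a probability map
#'
#' Strictly-greater comparison: probability must exceed the threshold, so a
#' value of exactly 0.5 maps to 0 at the default.
#'
#' @param p probability array (any dimension) or [probability_volume()].
#' @param threshold scalar in (0, 1); default 0.5.
#' @return integer array of 0/1 with the same shape.
#' @export
binarize <- function(p, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  if (inherits(p, "probability_volume")) p <- p$data
  array(as.integer(p > threshold), dim(p))
}

#' Run the 2D ensemble uncertainty stage over a volume
#'
#' Processes the volume slice-by-slice along the third axis: for each axial
#' slice, generate projection origins (optionally restricted to the brain
#' ROI), deform the 4-channel slice about each origin, apply the 2D
#' predictor, pull each prediction back to the original grid, then reduce
#' the stack to the mean probability, the binarized mask and the entropy
#' uncertainty map.
#'
#' @param volume an [mpmri_volume()].
#' @param predictor a slice predictor (see [mock_threshold_predictor()]).
#' @param interval origin-grid pixel interval (8 reproduces the full
#'   1024-origin setting on 256 x 256 slices; 16 gives 16 origins per
#'   64 x 64 slice, the desk-scale default).
#' @param params a [projection_params()].
#' @param roi optional [brain_roi()]; slices with no in-ROI origin fall back
#'   to the full grid with a warning.
#' @param bins entropy discretization bins.
#' @return list with `p2d` ([probability_volume()]), `mask2d`
#'   ([label_volume()]), `u2d` (entropy array with class
#'   `uncertainty_volume`), and `meta` (interval, radius, bins, n_origins).
#' @export
run_uncertainty_stage <- function(volume, predictor, interval = 16L,
                                  params = projection_params(), roi = NULL,
                                  bins = 100L) {
  stopifnot(inherits(volume, "mpmri_volume"))
  d <- dim(volume$data)
  H <- d[2]; W <- d[3]; Z <- d[4]
  p2d <- array(0, c(H, W, Z))
  u2d <- array(0, c(H, W, Z))
  n_origins <- integer(Z)
  for (k in seq_len(Z)) {
    roi_slice <- if (!is.null(roi)) roi$data[, , k] else NULL
    origins <- tryCatch(
      generate_origin_grid(H, W, interval, roi = roi_slice),
      error = function(e) {
        warning(sprintf("slice %d: no origins inside ROI; falling back to the full grid", k))
        generate_origin_grid(H, W, interval)
      })
    n <- nrow(origins)
    n_origins[k] <- n
    slice <- volume$data[, , , k]
    probs <- array(0, c(n, H, W))
    valid <- array(TRUE, c(n, H, W))
    for (i in seq_len(n)) {
      deformed <- project_slice(slice, origins[i, ], params)
      pred <- predictor(deformed)
      bp <- back_project(pred, origins[i, ], params, original_size = c(H, W))
      probs[i, , ] <- bp$values
      valid[i, , ] <- bp$valid
    }
    stack <- prediction_stack(probs, valid)
    p2d[, , k] <- mean_probability(stack)
    u2d[, , k] <- entropy_map(stack, bins)
  }
  list(
    p2d = probability_volume(p2d, spacing = volume$spacing),
    mask2d = label_volume(binarize(p2d), spacing = volume$spacing),
    u2d = structure(u2d, bins = as.integer(bins), class = "uncertainty_volume"),
    meta = list(interval = interval, radius = params$radius, bins = bins,
                n_origins = n_origins))
}
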