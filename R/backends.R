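# Pluggable segmenter backends.
#
# A slice predictor maps a 4 x H x W array to an H x W probability matrix in
# [0,1]; a volume predictor maps 4 x d x d x d to d x d x d. Deep backbones
# (e.g., a self-configuring U-Net) plug in behind the same contract; the
# deterministic predictors below make the whole framework runnable and
# testable at desk scale.

new_predictor <- function(fn, name, kind = c("slice", "volume"),
                          target = NA_character_) {
  kind <- match.arg(kind)
  structure(fn, name = name, kind = kind, target = target,
            class = c(paste0(kind, "_predictor"), "predictor", "function"))
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Deterministic threshold (logistic) predictor
#'
#' Emits `logistic((x[channel] - center) / softness)` per pixel/voxel: a
#' smooth intensity-threshold segmenter. Fully deterministic, yet the
#' spherical deformation and back-projection interpolation induce genuine
#' inter-projection variability near tissue boundaries, which is what the
#' entropy stage measures.
#'
#' @param channel 1-based channel index (1 FLAIR, 2 T1, 3 T1ce, 4 T2).
#' @param center intensity at which the output probability is 0.5.
#' @param softness intensity scale of the transition (> 0).
#' @param kind `"slice"` (2D) or `"volume"` (3D).
#' @return A predictor callable.
#' @export
mock_threshold_predictor <- function(channel, center, softness = 0.05,
                                     kind = c("slice", "volume")) {
  kind <- match.arg(kind)
  if (softness <= 0) stop("mock_threshold_predictor: softness must be > 0")
  channel <- as.integer(channel)
  if (channel < 1L || channel > 4L)
    stop("mock_threshold_predictor: channel index out of range (1..4)")
  fn <- function(x) {
    nd <- length(dim(x))
    if (nd == 3L) logistic((x[channel, , ] - center) / softness)
    else logistic((x[channel, , , ] - center) / softness)
  }
  new_predictor(fn, sprintf("mock_threshold(ch=%d,center=%g)", channel, center),
                kind)
}

#' Constant-output predictor
#'
#' @param value constant probability in `[0, 1]`.
#' @param kind `"slice"` or `"volume"`.
#' @return A predictor emitting `value` everywhere.
#' @export
constant_predictor <- function(value, kind = c("slice", "volume")) {
  kind <- match.arg(kind)
  if (value < 0 || value > 1) stop("constant_predictor: value must be in [0, 1]")
  fn <- function(x) {
    d <- dim(x)[-1]
    array(value, d)
  }
  new_predictor(fn, sprintf("constant(%g)", value), kind)
}

#' Ground-truth oracle volume predictor
#'
#' Returns the reference label crop for any requested kernel; the crop
#' location is communicated via the `kernel` attribute set by the refinement
#' stage. Used to bound what a perfect local 3D segmenter could contribute.
#'
#' @param reference a [label_volume()] on the full grid.
#' @return A volume predictor.
#' @export
oracle_volume_predictor <- function(reference) {
  stopifnot(inherits(reference, "label_volume"))
  ref <- reference$data
  fn <- function(x) {
    k <- attr(x, "kernel")
    if (is.null(k)) stop("oracle_volume_predictor: input carries no kernel attribute")
    d <- k$d
    ref[k$corner[1] + seq_len(d), k$corner[2] + seq_len(d),
        k$corner[3] + seq_len(d)] + 0
  }
  new_predictor(fn, "oracle(ground-truth)", "volume")
}

#' Check a predictor against the backend contract
#'
#' Verifies output shape, `[0, 1]` range and determinism on a given input.
#'
#' @param predictor a predictor callable.
#' @param input a conforming input array.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
check_predictor_contract <- function(predictor, input) {
  out1 <- predictor(input)
  out2 <- predictor(input)
  if (!identical(dim(out1), dim(input)[-1]))
    stop("contract: output shape must equal the input spatial shape")
  if (anyNA(out1) || any(out1 < 0 | out1 > 1))
    stop("contract: outputs must lie in [0, 1]")
  if (!identical(out1, out2))
    stop("contract: predictor must be deterministic")
  invisible(TRUE)
}
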