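# Channel order is fixed package-wide: FLAIR, T1, T1ce, T2.
MODALITIES <- c("flair", "t1", "t1ce", "t2")
TARGETS <- c("ET", "TC", "WT")

#' Multi-parametric MRI volume
#'
#' Construct a 4-channel volumetric image (channel order FLAIR, T1, T1ce, T2)
#' with spacing metadata. All four channels share one voxel grid; spacing is
#' in mm per voxel per axis.
#'
#' @param data numeric array of dimension `c(4, X, Y, Z)`, finite values.
#' @param spacing positive numeric length-3 vector, mm per voxel.
#' @param origin,direction optional spatial metadata, carried unchanged.
#' @return An object of class `mpmri_volume`.
#' @export
mpmri_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3)) {
  data <- as.array(data)
  if (length(dim(data)) != 4L || dim(data)[1] != 4L)
    stop("mpmri_volume: `data` must be a 4 x X x Y x Z array (FLAIR, T1, T1ce, T2)")
  if (!all(is.finite(data)))
    stop("mpmri_volume: all intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("mpmri_volume: spacing must be 3 positive values (mm/voxel)")
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction),
            class = "mpmri_volume")
}

#' Binary label volume
#'
#' @param data integer-valued X x Y x Z array with values in \{0, 1\}.
#' @param target one of `"ET"`, `"TC"`, `"WT"` (or `NA` when unassigned).
#' @param spacing mm per voxel per axis.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, target = NA_character_, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("label_volume: `data` must be a 3D array")
  if (!all(data %in% c(0, 1)))
    stop("label_volume: values must be 0 or 1")
  if (!is.na(target)) target <- match.arg(target, TARGETS)
  structure(list(data = array(as.integer(data), dim(data)), target = target,
                 spacing = as.numeric(spacing)),
            class = "label_volume")
}

#' Per-voxel probability volume
#'
#' @param data X x Y x Z array with values in `[0, 1]`; `NaN` forbidden.
#' @param target optional target tag.
#' @param spacing mm per voxel per axis.
#' @return An object of class `probability_volume`.
#' @export
probability_volume <- function(data, target = NA_character_,
                               spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("probability_volume: `data` must be a 3D array")
  if (anyNA(data) || any(data < 0 | data > 1))
    stop("probability_volume: values must lie in [0, 1] and not be NaN")
  structure(list(data = data, target = target, spacing = as.numeric(spacing)),
            class = "probability_volume")
}

#' Intracranial (brain) region of interest
#'
#' @param data binary X x Y x Z array; must be nonempty when used to
#'   restrict projection origins.
#' @return An object of class `brain_roi`.
#' @export
brain_roi <- function(data) {
  data <- as.array(data)
  if (length(dim(data)) != 3L || !all(data %in% c(0, 1)))
    stop("brain_roi: `data` must be a binary 3D array")
  structure(list(data = array(as.integer(data), dim(data))),
            class = "brain_roi")
}

# drop RNifti pointer/header attributes, keep a plain array
strip_nifti <- function(img) {
  a <- as.array(img)
  array(as.vector(a), dim(a))
}

grid_dim <- function(x) {
  if (inherits(x, "mpmri_volume")) dim(x$data)[-1] else dim(x$data)
}

#' Read a NIfTI volume
#'
#' Loads a single NIfTI file. A 4D file with 4 volumes is returned as an
#' [mpmri_volume()] (the caller asserts the channel order is FLAIR, T1,
#' T1ce, T2 — it is never guessed from file names). A 3D file is returned
#' as a [label_volume()] when `as = "label"` (values must be 0/1) or as a
#' plain [probability_volume()]/intensity array otherwise.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param as one of `"auto"`, `"mpmri"`, `"label"`, `"probability"`.
#' @param target target tag to attach to label/probability output.
#' @return An `mpmri_volume`, `label_volume` or `probability_volume`.
#' @export
read_volume <- function(path, as = c("auto", "mpmri", "label", "probability"),
                        target = NA_character_) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("read_volume: no such file: ", path)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)
  arr <- strip_nifti(img)
  nd <- length(dim(arr))
  spacing <- spacing[seq_len(min(3L, length(spacing)))]
  if (length(spacing) < 3L) spacing <- c(spacing, rep(1, 3L - length(spacing)))
  if (length(unique(round(spacing, 6))) > 1L)
    warning("read_volume: non-isotropic spacing ", paste(spacing, collapse = "x"),
            " mm; the kernel search treats mm and voxels as equal at 1 mm isotropic")
  if (as == "auto") as <- if (nd == 4L) "mpmri" else
    if (all(arr %in% c(0, 1))) "label" else "probability"
  switch(as,
    mpmri = {
      if (nd != 4L) stop("read_volume: expected a 4D multi-channel file")
      # NIfTI stores channels on the 4th axis; internal layout is channel-first
      mpmri_volume(aperm(arr, c(4, 1, 2, 3)), spacing = spacing)
    },
    label = label_volume(arr, target = target, spacing = spacing),
    probability = probability_volume(arr, target = target, spacing = spacing))
}

#' Read one multi-file MP-MRI case
#'
#' @param paths character vector of 4 NIfTI paths in the order FLAIR, T1,
#'   T1ce, T2 (explicit by position, never inferred from names).
#' @return An [mpmri_volume()].
#' @export
read_mpmri <- function(paths) {
  if (length(paths) != 4L)
    stop("read_mpmri: exactly 4 paths required (FLAIR, T1, T1ce, T2)")
  chans <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("read_mpmri: no such file: ", p)
    strip_nifti(RNifti::readNifti(p))
  })
  d <- dim(chans[[1]])
  if (!all(vapply(chans, function(a) identical(dim(a), d), logical(1))))
    stop("read_mpmri: channels do not share one grid")
  spacing <- RNifti::pixdim(RNifti::readNifti(paths[1]))[1:3]
  data <- array(0, c(4L, d))
  for (c in 1:4) data[c, , , ] <- chans[[c]]
  mpmri_volume(data, spacing = spacing)
}

#' Write a volume to NIfTI
#'
#' @param x an `mpmri_volume`, `label_volume`, `probability_volume`,
#'   `brain_roi` or bare 3D array.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "mpmri_volume")) {
    arr <- aperm(x$data, c(2, 3, 4, 1))
    spacing <- x$spacing
  } else if (is.array(x)) {
    arr <- x; spacing <- c(1, 1, 1)
  } else {
    arr <- x$data
    spacing <- if (!is.null(x$spacing)) x$spacing else c(1, 1, 1)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing[1:3]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Save a probability volume as float NIfTI
#'
#' Values outside `[0, 1]` are rejected; the round trip through
#' [read_volume()] is lossless to float precision.
#'
#' @param volume a [probability_volume()] (or 3D array in `[0, 1]`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_probability <- function(volume, path) {
  if (is.array(volume)) volume <- probability_volume(volume)
  if (!inherits(volume, "probability_volume"))
    stop("save_probability: expected a probability_volume")
  write_volume(volume, path)
}

#' @export
print.mpmri_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mpmri_volume> 4 channels (FLAIR,T1,T1ce,T2), grid %s, spacing %s mm\n",
              paste(d[-1], collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> target %s, grid %s, %d foreground voxels\n",
              x$target, paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}
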