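# Synthetic nested-ellipsoid tumor phantom.
#
# Tissue classes (integer codes): 0 background, 1 normal brain, 2 peritumoral
# edema (ED), 3 necrotic / non-enhancing core (NCR/NET), 4 enhancing tumor
# (ET). Composite targets follow the BraTS convention: ET = {4},
# TC = {3, 4}, WT = {2, 3, 4}, so ET subset TC subset WT by construction.

TISSUE_CLASSES <- c("background", "normal", "ED", "NCRNET", "ET")

#' Default per-channel contrast table
#'
#' Mean intensity per tissue class (rows) per channel (columns, order FLAIR,
#' T1, T1ce, T2), on an arbitrary normalized intensity scale. The values are
#' conventions chosen so that ET is hyperintense on T1ce and edema is
#' hyperintense on FLAIR/T2, the qualitative contrasts the framework relies
#' on; they are not a claim about real scanner intensity distributions.
#'
#' @return 5 x 4 numeric matrix with dimnames.
#' @export
default_contrast_table <- function() {
  m <- rbind(
    background = c(0.00, 0.00, 0.00, 0.00),
    normal     = c(0.30, 0.40, 0.40, 0.30),
    ED         = c(0.80, 0.35, 0.35, 0.75),
    NCRNET     = c(0.50, 0.25, 0.20, 0.50),
    ET         = c(0.55, 0.45, 0.90, 0.45))
  colnames(m) <- MODALITIES
  m
}

#' Phantom specification
#'
#' Defines a synthetic MP-MRI case: nested ellipsoidal tumor subregions
#' (ET inside NCR/NET inside ED) inside an ellipsoidal brain, a per-channel
#' contrast table, additive Gaussian noise, and a seed. Semi-axes are in mm;
#' on the default 1 mm isotropic grid, mm and voxels coincide.
#'
#' @param grid_size integer length-3, voxel grid (default 64 x 64 x 48).
#' @param center ellipsoid center in 0-based voxel coordinates; default the
#'   grid center.
#' @param semi_axes_et,semi_axes_ncr,semi_axes_ed,semi_axes_brain length-3
#'   semi-axes (mm) of the ET, NCR/NET (= TC extent), ED (= WT extent) and
#'   brain ellipsoids; must be elementwise non-decreasing in that order.
#' @param contrast 5 x 4 contrast table as from [default_contrast_table()].
#' @param noise_sd additive Gaussian noise standard deviation (>= 0).
#' @param spacing mm per voxel.
#' @param seed RNG seed for the noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = c(64, 64, 48),
                         center = (grid_size - 1) / 2,
                         semi_axes_et = c(5, 5, 4),
                         semi_axes_ncr = c(9, 9, 7),
                         semi_axes_ed = c(14, 14, 11),
                         semi_axes_brain = c(26, 26, 20),
                         contrast = default_contrast_table(),
                         noise_sd = 0.05,
                         spacing = c(1, 1, 1),
                         seed = 1L) {
  grid_size <- as.integer(grid_size)
  stopifnot(length(grid_size) == 3L, all(grid_size >= 8L))
  if (noise_sd < 0) stop("phantom_spec: noise_sd must be >= 0")
  if (!all(semi_axes_et <= semi_axes_ncr) ||
      !all(semi_axes_ncr <= semi_axes_ed) ||
      !all(semi_axes_ed <= semi_axes_brain))
    stop("phantom_spec: ellipsoids not nested (need ET <= NCR/NET <= ED <= brain semi-axes)")
  if (!identical(dim(contrast), c(5L, 4L)))
    stop("phantom_spec: contrast table must be 5 classes x 4 channels")
  structure(list(grid_size = grid_size, center = as.numeric(center),
                 semi_axes = list(ET = semi_axes_et, NCRNET = semi_axes_ncr,
                                  ED = semi_axes_ed, brain = semi_axes_brain),
                 contrast = contrast, noise_sd = noise_sd,
                 spacing = as.numeric(spacing), seed = as.integer(seed)),
            class = "phantom_spec")
}

# 0/1 array: voxel centers (0-based index * spacing) inside the ellipsoid
ellipsoid_mask <- function(grid_size, center, semi_axes, spacing = c(1, 1, 1)) {
  x <- ((seq_len(grid_size[1]) - 1) * spacing[1] - center[1] * spacing[1]) / semi_axes[1]
  y <- ((seq_len(grid_size[2]) - 1) * spacing[2] - center[2] * spacing[2]) / semi_axes[2]
  z <- ((seq_len(grid_size[3]) - 1) * spacing[3] - center[3] * spacing[3]) / semi_axes[3]
  q <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  array(as.integer(q <= 1), grid_size)
}

#' Generate a synthetic MP-MRI phantom case
#'
#' Builds the tissue-class map from the nested ellipsoids, fills each channel
#' with the class means from the contrast table, adds Gaussian noise, and
#' derives the three composite label volumes plus the brain ROI. Deterministic
#' for a fixed `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` ([mpmri_volume()]), `labels` (named
#'   list of [label_volume()] for ET, TC, WT), `roi` ([brain_roi()]) and
#'   `classes` (the integer tissue-class array).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_size
  inner <- lapply(spec$semi_axes, function(sa)
    ellipsoid_mask(gs, spec$center, sa, spec$spacing))
  # class priority: ET > NCR/NET > ED > normal brain > background
  classes <- array(0L, gs)
  classes[inner$brain == 1L] <- 1L
  classes[inner$ED == 1L] <- 2L
  classes[inner$NCRNET == 1L] <- 3L
  classes[inner$ET == 1L] <- 4L

  data <- array(0, c(4L, gs))
  for (ch in 1:4) {
    plane <- spec$contrast[classes + 1L, ch]
    data[ch, , , ] <- array(plane, gs)
  }
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(spec$seed)
    data <- data + array(stats::rnorm(length(data), sd = spec$noise_sd), dim(data))
  }
  volume <- mpmri_volume(data, spacing = spec$spacing)
  labels <- list(
    ET = label_volume(classes == 4L, target = "ET", spacing = spec$spacing),
    TC = label_volume(classes >= 3L, target = "TC", spacing = spec$spacing),
    WT = label_volume(classes >= 2L, target = "WT", spacing = spec$spacing))
  roi <- brain_roi(classes >= 1L)
  list(volume = volume, labels = labels, roi = roi, classes = classes)
}
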