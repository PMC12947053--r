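# Spherical (gnomonic) slice deformation.
#
# A slice is draped onto a sphere of radius R tangent at a chosen projection
# origin and unrolled equidistantly: an output pixel at radial distance rho
# from the origin samples the source at radius s(rho) = R * tan(rho / R)
# along the same direction (undefined at rho >= pi*R/2, filled), so the
# neighborhood of the origin is relatively magnified while the full field of
# view is retained. The inverse pull-back is rho(s) = R * atan(s / R).

#' Projection parameters
#'
#' @param radius sphere radius R in pixels (> 0). Default 64, which for a
#'   256 x 256 slice puts the `pi*R/2` horizon (~100.5 px) near the slice
#'   half-width: peripheral compression is visible but nondegenerate.
#' @param interpolation 0 = nearest neighbor, 1 = bilinear.
#' @param fill value for out-of-domain samples (default 0, the MR background
#'   after skull stripping).
#' @param output_size optional `c(height, width)`; defaults to the input size.
#' @return An object of class `projection_params`.
#' @export
projection_params <- function(radius = 64, interpolation = 1L, fill = 0,
                              output_size = NULL) {
  if (radius <= 0) stop("projection_params: radius must be > 0")
  if (!interpolation %in% c(0L, 1L))
    stop("projection_params: interpolation must be 0 (nearest) or 1 (bilinear)")
  structure(list(radius = radius, interpolation = as.integer(interpolation),
                 fill = fill, output_size = output_size),
            class = "projection_params")
}

#' Uniform grid of projection origins
#'
#' Origins are placed at offset `floor(interval/2)` then every `interval`
#' pixels in each dimension (row-major order), optionally restricted to a
#' brain-ROI slice. A 256 x 256 slice at the default 8-pixel interval yields
#' exactly 1024 origins.
#'
#' @param height,width slice size in pixels.
#' @param interval pixel spacing between origins (>= 1, <= min(height, width)).
#' @param roi optional binary `height x width` matrix; origins falling outside
#'   it are dropped.
#' @return data.frame with 0-based integer columns `row`, `col`.
#' @export
generate_origin_grid <- function(height, width, interval = 8L, roi = NULL) {
  interval <- as.integer(interval)
  if (interval < 1L) stop("generate_origin_grid: interval must be >= 1")
  if (interval > min(height, width))
    stop("generate_origin_grid: interval exceeds the slice size")
  off <- interval %/% 2L
  rows <- seq.int(off, height - 1L, by = interval)
  cols <- seq.int(off, width - 1L, by = interval)
  g <- expand.grid(col = cols, row = rows)[, c("row", "col")]  # row-major
  if (!is.null(roi)) {
    roi <- as.matrix(roi)
    keep <- roi[cbind(g$row + 1L, g$col + 1L)] > 0
    g <- g[keep, , drop = FALSE]
    if (nrow(g) == 0L)
      stop("generate_origin_grid: no origins inside the ROI; use a denser interval")
  }
  rownames(g) <- NULL
  g
}

# Vectorized sampling of a matrix at fractional (0-based) coordinates.
# order 1 = bilinear, 0 = nearest; out-of-bounds -> fill.
sample_image <- function(img, r, c, order = 1L, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  out <- rep(fill, length(r))
  if (order == 0L) {
    ri <- round(r); ci <- round(c)
    ok <- ri >= 0 & ri <= H - 1 & ci >= 0 & ci <= W - 1
    out[ok] <- img[cbind(ri[ok] + 1, ci[ok] + 1)]
  } else {
    ok <- r >= 0 & r <= H - 1 & c >= 0 & c <= W - 1
    r0 <- floor(pmin(r[ok], H - 2)); c0 <- floor(pmin(c[ok], W - 2))
    fr <- r[ok] - r0; fc <- c[ok] - c0
    i00 <- c0 * H + r0 + 1                 # linear index of the (r0, c0) cell
    v <- img[i00] * (1 - fr) * (1 - fc) +
      img[i00 + 1] * fr * (1 - fc) +
      img[i00 + H] * (1 - fr) * fc +
      img[i00 + H + 1] * fr * fc
    out[ok] <- v
  }
  out
}

# Source-sampling coordinates for the forward deformation about an origin.
# Returns 0-based fractional (row, col) per output pixel; NA where the
# mapping is undefined (rho >= pi*R/2).
forward_map <- function(height, width, origin, R) {
  dr <- matrix(seq_len(height) - 1 - origin$row, height, width)
  dc <- matrix(rep(seq_len(width) - 1 - origin$col, each = height), height, width)
  rho <- sqrt(dr^2 + dc^2)
  defined <- rho < (pi * R / 2)
  s <- ifelse(defined, R * tan(rho / R), NA_real_)
  scale <- ifelse(rho > 0, s / rho, 1)
  list(r = origin$row + dr * scale, c = origin$col + dc * scale,
       defined = defined)
}

#' Deform a slice about a projection origin
#'
#' @param slice a `height x width` matrix or a `channels x height x width`
#'   array; channels are remapped identically.
#' @param origin a single-row data.frame (or list) with 0-based `row`, `col`.
#' @param params a [projection_params()].
#' @return Same shape as `slice` (or `params$output_size`), deformed.
#' @export
project_slice <- function(slice, origin, params = projection_params()) {
  R <- params$radius
  multi <- length(dim(slice)) == 3L
  H <- if (multi) dim(slice)[2] else nrow(slice)
  W <- if (multi) dim(slice)[3] else ncol(slice)
  if (pi * R / 2 < 1)
    stop("project_slice: radius so small the whole image collapses (pi*R/2 < 1 px)")
  if (origin$row < 0 || origin$row > H - 1 || origin$col < 0 || origin$col > W - 1)
    stop("project_slice: origin outside image bounds")
  os <- if (is.null(params$output_size)) c(H, W) else params$output_size
  m <- forward_map(os[1], os[2], origin, R)
  rr <- ifelse(m$defined, m$r, -1e9)  # forced out-of-bounds -> fill
  cc <- ifelse(m$defined, m$c, -1e9)
  remap1 <- function(ch) matrix(
    sample_image(ch, as.vector(rr), as.vector(cc),
                 order = params$interpolation, fill = params$fill),
    os[1], os[2])
  if (!multi) return(remap1(slice))
  out <- array(params$fill, c(dim(slice)[1], os))
  for (ch in seq_len(dim(slice)[1])) out[ch, , ] <- remap1(slice[ch, , ])
  out
}

#' Pull a prediction on the deformed grid back to the original grid
#'
#' Inverse of [project_slice()]: an original-grid pixel at source radius `s`
#' from the origin samples the deformed grid at `rho(s) = R * atan(s / R)`.
#' Values are clamped to `[0, 1]` after interpolation.
#'
#' @param prediction matrix on the deformed grid.
#' @param origin,params as for [project_slice()].
#' @param original_size `c(height, width)` of the original grid; defaults to
#'   the prediction's size.
#' @return list with `values` (matrix on the original grid) and `valid`
#'   (logical matrix: pull-back landed in-domain).
#' @export
back_project <- function(prediction, origin, params = projection_params(),
                         original_size = dim(prediction)) {
  R <- params$radius
  H <- original_size[1]; W <- original_size[2]
  dr <- matrix(seq_len(H) - 1 - origin$row, H, W)
  dc <- matrix(rep(seq_len(W) - 1 - origin$col, each = H), H, W)
  s <- sqrt(dr^2 + dc^2)
  rho <- R * atan(s / R)
  scale <- ifelse(s > 0, rho / s, 1)
  r <- origin$row + dr * scale
  c <- origin$col + dc * scale
  valid <- r >= 0 & r <= nrow(prediction) - 1 &
    c >= 0 & c <= ncol(prediction) - 1
  vals <- matrix(sample_image(prediction, as.vector(r), as.vector(c),
                              order = params$interpolation, fill = params$fill),
                 H, W)
  if (params$interpolation == 1L) vals <- pmin(pmax(vals, 0), 1)
  list(values = vals, valid = valid)
}

#' Deform a multi-channel slice about every origin
#'
#' @param slice `channels x height x width` array.
#' @param origins data.frame from [generate_origin_grid()].
#' @param params a [projection_params()].
#' @return list of deformed arrays, one per origin, in origin order.
#' @export
project_ensemble <- function(slice, origins, params = projection_params()) {
  if (nrow(origins) == 0L) stop("project_ensemble: empty origin list")
  lapply(seq_len(nrow(origins)), function(i)
    project_slice(slice, origins[i, ], params))
}
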