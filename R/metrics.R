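# Segmentation metrics and the paired statistical comparison protocol.

as_mask <- function(x) {
  if (inherits(x, "label_volume")) x$data else {
    if (!all(x %in% c(0, 1))) stop("expected a binary mask")
    array(as.integer(x), if (is.null(dim(x))) length(x) else dim(x))
  }
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks are not on the same grid")
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`. When both masks are empty the conventional
#' value 1 is returned with attribute `both_empty = TRUE`.
#'
#' @param pred,ref binary masks ([label_volume()] or 0/1 arrays) on one grid.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(pred, ref) {
  a <- as_mask(pred); b <- as_mask(ref)
  check_same_grid(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(structure(1, both_empty = TRUE))
  2 * sum(a & b) / (sa + sb)
}

# surface voxels: mask voxels with a 6-neighbor outside the mask (the volume
# border counts as outside)
surface_voxels <- function(mask) {
  d <- dim(mask)
  pad <- array(0L, d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- mask
  core <- function(di, dj, dk)
    pad[1 + di + seq_len(d[1]), 1 + dj + seq_len(d[2]), 1 + dk + seq_len(d[3])]
  nb_min <- pmin(core(1, 0, 0), core(-1, 0, 0), core(0, 1, 0),
                 core(0, -1, 0), core(0, 0, 1), core(0, 0, -1))
  which(mask == 1L & nb_min == 0L, arr.ind = TRUE)
}

# directed nearest-surface distances (mm): for each row of A (voxel indices),
# min Euclidean distance to any row of B, spacing-aware; chunked to bound
# memory.
directed_surface_distances <- function(A, B, spacing) {
  Amm <- sweep(A - 1, 2, spacing, `*`)
  Bmm <- sweep(B - 1, 2, spacing, `*`)
  nb <- nrow(Bmm)
  bb <- rowSums(Bmm^2)
  out <- numeric(nrow(Amm))
  chunk <- max(1L, floor(2e6 / nb))
  for (s in seq(1, nrow(Amm), by = chunk)) {
    ii <- s:min(s + chunk - 1, nrow(Amm))
    G <- Amm[ii, , drop = FALSE] %*% t(Bmm)
    d2 <- outer(rowSums(Amm[ii, , drop = FALSE]^2), bb, `+`) - 2 * G
    out[ii] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' Surfaces are 6-connectivity boundary voxels; for each direction the 95th
#' percentile of nearest-surface distances is taken and the maximum of the
#' two directed percentiles is reported. Either mask empty gives `NA` with
#' attribute `undefined = TRUE` (excluded from aggregates by callers).
#'
#' @param pred,ref binary masks on one grid.
#' @param spacing mm per voxel per axis.
#' @return HD95 in mm, or `NA` when undefined.
#' @export
hd95 <- function(pred, ref, spacing = c(1, 1, 1)) {
  a <- as_mask(pred); b <- as_mask(ref)
  check_same_grid(a, b)
  if (sum(a) == 0 || sum(b) == 0)
    return(structure(NA_real_, undefined = TRUE))
  SA <- surface_voxels(a); SB <- surface_voxels(b)
  dab <- directed_surface_distances(SA, SB, spacing)
  dba <- directed_surface_distances(SB, SA, spacing)
  max(stats::quantile(dab, 0.95, names = FALSE),
      stats::quantile(dba, 0.95, names = FALSE))
}

#' Voxel-wise sensitivity, specificity and accuracy
#'
#' @param pred,ref binary masks on one grid.
#' @return named list with `sensitivity` TP/(TP+FN), `specificity`
#'   TN/(TN+FP), `accuracy` (TP+TN)/total, and the raw `counts`.
#'   Zero-denominator entries are `NA` with attribute `undefined`.
#' @export
confusion_metrics <- function(pred, ref) {
  a <- as_mask(pred); b <- as_mask(ref)
  check_same_grid(a, b)
  tp <- sum(a == 1L & b == 1L); fn <- sum(a == 0L & b == 1L)
  tn <- sum(a == 0L & b == 0L); fp <- sum(a == 1L & b == 0L)
  safe <- function(num, den)
    if (den == 0) structure(NA_real_, undefined = TRUE) else num / den
  list(sensitivity = safe(tp, tp + fn),
       specificity = safe(tn, tn + fp),
       accuracy = (tp + tn) / length(a),
       counts = c(tp = tp, fp = fp, tn = tn, fn = fn))
}

#' Score one prediction against a reference on every metric
#'
#' @param pred,ref binary masks on one grid.
#' @param spacing mm per voxel.
#' @return one-row data.frame: dsc, hd95, sensitivity, specificity, accuracy.
#' @export
segmentation_metrics <- function(pred, ref, spacing = c(1, 1, 1)) {
  cm <- confusion_metrics(pred, ref)
  data.frame(dsc = as.numeric(dice(pred, ref)),
             hd95 = as.numeric(hd95(pred, ref, spacing)),
             sensitivity = as.numeric(cm$sensitivity),
             specificity = as.numeric(cm$specificity),
             accuracy = as.numeric(cm$accuracy))
}

#' Paired Wilcoxon signed-rank comparison with Bonferroni correction
#'
#' For each metric column, compares the proposed method against each
#' baseline over paired per-case values using the two-sided Wilcoxon
#' signed-rank test (zero differences excluded; exact distribution for
#' n <= 25 untied pairs, normal approximation with continuity correction
#' otherwise). Significance is flagged at `alpha / comparisons`.
#'
#' @param reports data.frame with columns `case`, `method`, `metric`,
#'   `value` (long format; `target` column optional and carried through).
#' @param method name of the proposed method in `reports$method`.
#' @param baselines character vector of baseline method names.
#' @param alpha family significance level (default 0.05).
#' @param comparisons Bonferroni divisor; defaults to `length(baselines)`.
#' @return data.frame: target, metric, baseline, n, p_value, threshold,
#'   significant.
#' @export
compare_methods <- function(reports, method, baselines, alpha = 0.05,
                            comparisons = length(baselines)) {
  stopifnot(comparisons >= 1)
  if (!"target" %in% names(reports)) reports$target <- "all"
  threshold <- alpha / comparisons
  grid <- expand.grid(target = unique(reports$target),
                      metric = unique(reports$metric),
                      baseline = baselines, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    g <- grid[r, ]
    sub <- reports[reports$target == g$target & reports$metric == g$metric, ]
    x <- sub$value[match(paste(unique(sub$case), method),
                         paste(sub$case, sub$method))]
    y <- sub$value[match(paste(unique(sub$case), g$baseline),
                         paste(sub$case, sub$method))]
    keep <- is.finite(x) & is.finite(y)
    p <- wilcoxon_signed_rank(x[keep], y[keep])
    data.frame(target = g$target, metric = g$metric, baseline = g$baseline,
               n = sum(keep), p_value = p, threshold = threshold,
               significant = is.finite(p) && p < threshold)
  })
  do.call(rbind, rows)
}

#' Two-sided Wilcoxon signed-rank p-value for paired samples
#'
#' Zero differences are dropped (zero-exclusion convention). The exact null
#' distribution is used for n <= 25 when the absolute differences are
#' untied; otherwise the normal approximation with continuity correction.
#' Fewer than 5 informative pairs triggers an underpowered-test warning but
#' the p-value is still computed; zero informative pairs give p = 1.
#'
#' @param x,y equal-length paired numeric vectors.
#' @return two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  if (n < 5L) warning("wilcoxon_signed_rank: fewer than 5 nonzero pairs; test underpowered")
  exact <- n <= 25L && !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
}
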