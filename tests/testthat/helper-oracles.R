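# Independent oracles and shared fixtures. Oracles are deliberately naive
# (triple loops, all-pairs scans) and never call the implementation paths
# they check.

# naive triple-loop window sums
naive_window_sums <- function(U, d, stride = 1L) {
  dims <- dim(U)
  ax <- lapply(dims, function(n) seq.int(0L, n - d, by = stride))
  out <- array(0, vapply(ax, length, integer(1)))
  for (a in seq_along(ax[[1]]))
    for (b in seq_along(ax[[2]]))
      for (c2 in seq_along(ax[[3]]))
        out[a, b, c2] <- sum(U[ax[[1]][a] + 1:d, ax[[2]][b] + 1:d,
                               ax[[3]][c2] + 1:d])
  out
}

# naive greedy overlap-constrained selection (reference implementation)
naive_select <- function(U, d, max_overlap, stop_fraction, stride = 1L) {
  sc <- naive_window_sums(U, d, stride)
  ax <- lapply(dim(U), function(n) seq.int(0L, n - d, by = stride))
  idx <- which(array(TRUE, dim(sc)), arr.ind = TRUE)
  corners <- cbind(ax[[1]][idx[, 1]], ax[[2]][idx[, 2]], ax[[3]][idx[, 3]])
  vals <- as.vector(sc)
  ord <- order(-vals, corners[, 1], corners[, 2], corners[, 3])
  acc <- list()
  top <- NULL
  for (i in ord) {
    if (vals[i] <= 0) break
    if (!is.null(top) && vals[i] < stop_fraction * top) break
    ok <- TRUE
    for (a in acc) {
      ov <- prod(pmax(0, d - abs(a$corner - corners[i, ]))) / d^3
      if (ov > max_overlap) { ok <- FALSE; break }
    }
    if (ok) {
      acc[[length(acc) + 1L]] <- list(corner = corners[i, ], score = vals[i])
      if (is.null(top)) top <- vals[i]
    }
  }
  acc
}

# all-pairs directed surface distance oracle for HD95
naive_hd95 <- function(a, b, spacing = c(1, 1, 1)) {
  surf <- function(m) {
    d <- dim(m)
    out <- NULL
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (m[i, j, k] != 1) next
      nb <- c(
        if (i > 1) m[i - 1, j, k] else 0, if (i < d[1]) m[i + 1, j, k] else 0,
        if (j > 1) m[i, j - 1, k] else 0, if (j < d[2]) m[i, j + 1, k] else 0,
        if (k > 1) m[i, j, k - 1] else 0, if (k < d[3]) m[i, j, k + 1] else 0)
      if (any(nb == 0)) out <- rbind(out, c(i, j, k))
    }
    out
  }
  SA <- surf(a); SB <- surf(b)
  dir_d <- function(P, Q) {
    apply(P, 1, function(p) {
      min(apply(Q, 1, function(q) sqrt(sum(((p - q) * spacing)^2))))
    })
  }
  max(quantile(dir_d(SA, SB), 0.95, names = FALSE),
      quantile(dir_d(SB, SA), 0.95, names = FALSE))
}

# smooth 2D test field in [0, 1]
smooth_field <- function(H, W) {
  r <- matrix(seq_len(H), H, W) / H
  c <- matrix(rep(seq_len(W), each = H), H, W) / W
  0.5 + 0.25 * sin(2 * pi * r) * cos(2 * pi * c) + 0.2 * r * (1 - c)
}

# small, fast phantom for pipeline-level tests
small_phantom_spec <- function(seed = 1L, noise_sd = 0.05)
  phantom_spec(grid_size = c(32, 32, 24), semi_axes_et = c(3, 3, 2.5),
               semi_axes_ncr = c(5, 5, 4), semi_axes_ed = c(8, 8, 6),
               semi_axes_brain = c(13, 13, 10), noise_sd = noise_sd,
               seed = seed)

# one cached desk-scale uncertainty run shared by several suites
phantom_run_cache <- new.env(parent = emptyenv())
cached_phantom_run <- function() {
  if (is.null(phantom_run_cache$run)) {
    ph <- generate_phantom(phantom_spec(seed = 11L))
    st <- suppressWarnings(
      run_uncertainty_stage(ph$volume, mock_threshold_predictor(3, 0.65),
                            interval = 16L, roi = ph$roi))
    phantom_run_cache$run <- list(ph = ph, st = st)
  }
  phantom_run_cache$run
}
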