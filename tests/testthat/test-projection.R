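test_that("origin grid matches direct enumeration and drops non-ROI origins", {
  g <- generate_origin_grid(256, 256, 8)
  expect_equal(nrow(g), 1024L)
  expect_equal(nrow(generate_origin_grid(8, 8, 8)), 1L)
  g4 <- generate_origin_grid(16, 16, 8)
  # direct enumeration: offset 4, step 8 -> rows/cols {4, 12}, row-major
  expect_equal(g4$row, c(4, 4, 12, 12))
  expect_equal(g4$col, c(4, 12, 4, 12))

  roi <- matrix(0L, 16, 16); roi[1:8, ] <- 1L  # keep only rows 0..7
  gr <- generate_origin_grid(16, 16, 8, roi = roi)
  expect_equal(nrow(gr), 2L)
  expect_true(all(gr$row == 4))
  expect_error(generate_origin_grid(16, 16, 8, roi = matrix(0L, 16, 16)),
               "denser interval")
  expect_error(generate_origin_grid(16, 16, 0), "interval")
})

test_that("constant slices stay constant and the origin pixel is a fixed point", {
  params <- projection_params(radius = 20)
  img <- matrix(0.6, 32, 32)
  out <- project_slice(img, list(row = 15, col = 15), params)
  # in-domain region: wherever the source sample landed inside the image
  expect_true(all(abs(out - 0.6) < 1e-12 | out == params$fill))
  expect_equal(out[16, 16], 0.6)

  set.seed(4)
  img2 <- matrix(runif(32 * 32), 32, 32)
  out2 <- project_slice(img2, list(row = 10, col = 20), params)
  expect_equal(out2[11, 21], img2[11, 21])  # integer-aligned origin maps to itself
})

test_that("deformation approaches identity as the radius grows", {
  # analytic displacement bound: max |s(rho) - rho| < 0.01 px at R = 1e6
  H <- 256
  rho_max <- sqrt(2) * (H - 1)
  R <- 1e6
  expect_lt(abs(R * tan(rho_max / R) - rho_max), 0.01)
  set.seed(5)
  img <- matrix(runif(64 * 64), 64, 64)
  near_id <- project_slice(img, list(row = 31, col = 31),
                           projection_params(radius = 1e6))
  # interior: the remap pushes the extreme border rows a hair out of domain
  expect_lt(max(abs(near_id - img)[2:63, 2:63]), 1e-6)
  # displacement is monotonically decreasing in R
  disp <- function(R) max(abs(R * tan(80 / R) - 80))
  expect_true(all(diff(sapply(c(60, 120, 240, 480, 1e4), disp)) < 0))
})

test_that("local radial scale is 1 at the origin and grows outward", {
  # finite-difference ds/drho of the implemented map vs sec^2(rho/R)
  R <- 64
  rho <- seq(0, 90, by = 0.5)
  s <- R * tan(rho / R)
  fd <- diff(s) / diff(rho)
  closed <- 1 / cos(((rho[-1] + rho[-length(rho)]) / 2) / R)^2
  expect_equal(fd, closed, tolerance = 1e-3)
  expect_true(all(diff(fd) > 0))
  expect_equal(fd[1], 1, tolerance = 1e-4)
})

test_that("forward-then-inverse remap reproduces a smooth field", {
  img <- smooth_field(64, 64)
  params <- projection_params(radius = 64)
  origin <- list(row = 31, col = 31)
  fwd <- project_slice(img, origin, params)
  bp <- back_project(fwd, origin, params)
  interior <- bp$valid
  interior[c(1, 64), ] <- FALSE; interior[, c(1, 64)] <- FALSE
  expect_lt(mean(abs(bp$values[interior] - img[interior])), 0.02)
})

test_that("back-projection keeps constants, clamps, and preserves binaries under nearest", {
  params <- projection_params(radius = 32)
  origin <- list(row = 15, col = 15)
  bp <- back_project(matrix(0.7, 32, 32), origin, params)
  expect_true(all(abs(bp$values[bp$valid] - 0.7) < 1e-12))
  nn <- projection_params(radius = 32, interpolation = 0L)
  binpred <- matrix(rbinom(32 * 32, 1, 0.5), 32, 32)
  bpn <- back_project(binpred, origin, nn)
  expect_true(all(bpn$values %in% c(0, 1)))
  expect_error(back_project(matrix(0.5, 8, 8), origin, params,
                            original_size = c(32, 32)), NA)
})

test_that("ensembles equal independent per-origin projection, channels independent", {
  set.seed(6)
  slice <- array(runif(4 * 24 * 24), c(4, 24, 24))
  origins <- generate_origin_grid(24, 24, 12)
  params <- projection_params(radius = 24)
  ens <- project_ensemble(slice, origins, params)
  expect_length(ens, nrow(origins))
  for (i in seq_along(ens))
    expect_identical(ens[[i]], project_slice(slice, origins[i, ], params))
  # channel equivariance
  one <- project_slice(slice, origins[1, ], params)
  for (ch in 1:4)
    expect_identical(one[ch, , ], project_slice(slice[ch, , ], origins[1, ], params))
  expect_error(project_ensemble(slice, origins[0, ], params), "empty")
  expect_error(project_slice(slice, list(row = 50, col = 0), params), "bounds")
  expect_error(project_slice(slice, origins[1, ], projection_params(radius = 0.5)),
               "collapses")
})
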