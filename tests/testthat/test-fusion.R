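test_that("subvolume extraction is an exact crop", {
  set.seed(31)
  vol <- mpmri_volume(array(runif(4 * 12 * 12 * 12), c(4, 12, 12, 12)))
  k0 <- kernel_region(c(0, 0, 0), 4)
  expect_equal(extract_subvolume(vol, k0),
               vol$data[, 1:4, 1:4, 1:4, drop = FALSE], ignore_attr = TRUE)
  k <- kernel_region(c(3, 5, 7), 4)
  expect_equal(extract_subvolume(vol, k),
               vol$data[, 4:7, 6:9, 8:11, drop = FALSE], ignore_attr = TRUE)
  # overlapping kernels share identical intensities on shared voxels
  k2 <- kernel_region(c(5, 5, 7), 4)
  a <- extract_subvolume(vol, k); b <- extract_subvolume(vol, k2)
  expect_equal(a[, 3:4, , ], b[, 1:2, , ], ignore_attr = TRUE)
  expect_error(extract_subvolume(vol, kernel_region(c(10, 0, 0), 4)), "bounds")
})

test_that("composite map averages local predictions with coverage counts", {
  gs <- c(8, 8, 8)
  k1 <- kernel_region(c(0, 0, 0), 4)
  k2 <- kernel_region(c(2, 0, 0), 4)
  one <- build_composite(list(list(kernel = k1, probs = array(0.6, c(4, 4, 4)))), gs)
  expect_true(all(one$probs[1:4, 1:4, 1:4] == 0.6))
  expect_true(all(one$coverage[1:4, 1:4, 1:4] == 1L))
  expect_true(all(one$coverage[5:8, , ] == 0L))

  two <- build_composite(list(
    list(kernel = k1, probs = array(0.2, c(4, 4, 4))),
    list(kernel = k2, probs = array(0.8, c(4, 4, 4)))), gs)
  expect_true(all(two$probs[3:4, 1:4, 1:4] == 0.5))
  expect_true(all(two$coverage[3:4, 1:4, 1:4] == 2L))

  # random overlapping set vs accumulate-and-divide oracle; order-invariant
  set.seed(32)
  locals <- lapply(1:5, function(i)
    list(kernel = kernel_region(sample(0:4, 3, replace = TRUE), 4),
         probs = array(runif(64), c(4, 4, 4))))
  got <- build_composite(locals, gs)
  acc <- array(0, gs); cov <- array(0L, gs)
  for (lp in locals) {
    co <- lp$kernel$corner
    ii <- co[1] + 1:4; jj <- co[2] + 1:4; kk <- co[3] + 1:4
    acc[ii, jj, kk] <- acc[ii, jj, kk] + lp$probs
    cov[ii, jj, kk] <- cov[ii, jj, kk] + 1L
  }
  expect_equal(got$coverage, cov)
  expect_equal(got$probs[cov > 0], (acc / pmax(cov, 1))[cov > 0], tolerance = 1e-12)
  expect_equal(build_composite(rev(locals), gs)$probs, got$probs)
  expect_true(all(got$probs >= 0 & got$probs <= 1))
  expect_warning(build_composite(list(locals[[1]], locals[[1]]), gs), "duplicate")
})

test_that("fusion keeps uncovered voxels bit-identical and is monotone when covered", {
  set.seed(33)
  gs <- c(6, 6, 6)
  p2d <- array(runif(prod(gs)), gs)
  comp <- list(probs = array(runif(prod(gs)), gs),
               coverage = array(rbinom(prod(gs), 1, 0.5), gs))
  w <- fusion_weights(1, 1, b = -1)
  out <- fuse(p2d, comp, w)
  cov0 <- comp$coverage == 0L
  expect_identical(out[cov0], p2d[cov0])
  expect_true(all(out >= 0 & out <= 1))
  # symmetric midpoint: sigma(0) = 0.5
  mid <- fuse(array(0.5, gs), list(probs = array(0.5, gs),
                                   coverage = array(1L, gs)), w)
  expect_true(all(abs(mid - 0.5) < 1e-12))
  # monotone in each input on covered voxels
  grid <- seq(0, 1, by = 0.1)
  f2 <- vapply(grid, function(p)
    fuse(array(p, c(1, 1, 1)),
         list(probs = array(0.3, c(1, 1, 1)), coverage = array(1L, c(1, 1, 1))),
         fusion_weights(1.3, 0.7))[1], numeric(1))
  f3 <- vapply(grid, function(p)
    fuse(array(0.3, c(1, 1, 1)),
         list(probs = array(p, c(1, 1, 1)), coverage = array(1L, c(1, 1, 1))),
         fusion_weights(1.3, 0.7))[1], numeric(1))
  expect_true(all(diff(f2) > 0))
  expect_true(all(diff(f3) > 0))
  # w3d = 0: output depends only on p2d
  fA <- fuse(p2d, comp, fusion_weights(2, 0))
  comp2 <- comp; comp2$probs <- array(runif(prod(gs)), gs)
  expect_identical(fA, fuse(p2d, comp2, fusion_weights(2, 0)))
  expect_error(fusion_weights(-0.1, 1), "non-negative")
})

test_that("refinement stage is a graceful no-op on empty selections", {
  set.seed(34)
  vol <- mpmri_volume(array(runif(4 * 10 * 10 * 10), c(4, 10, 10, 10)))
  p2d <- probability_volume(array(runif(1000), c(10, 10, 10)))
  u0 <- array(0, c(10, 10, 10))
  r <- run_refinement_stage(vol, u0, p2d, constant_predictor(1, "volume"),
                            selection_config(d = 4L))
  expect_identical(r$pfused$data, p2d$data)
  expect_identical(r$mask$data, binarize(p2d$data))
  expect_length(r$kernels, 0L)
})

test_that("oracle-refined fusion never hurts inside covered regions on the phantom", {
  run <- cached_phantom_run()
  ph <- run$ph; st <- run$st
  sel <- selection_config(d = 32L)
  r <- run_refinement_stage(ph$volume, st$u2d, st$p2d,
                            oracle_volume_predictor(ph$labels$ET),
                            sel, fusion_weights(0.5, 6))
  covered <- r$composite$coverage >= 1L
  ref_cov <- ph$labels$ET$data[covered]
  dsc_fused <- dice(r$mask$data[covered], ref_cov)
  dsc_2d <- dice(st$mask2d$data[covered], ref_cov)
  expect_gte(dsc_fused, dsc_2d)
  # rerun reproduces identical outputs
  r2 <- run_refinement_stage(ph$volume, st$u2d, st$p2d,
                             oracle_volume_predictor(ph$labels$ET),
                             sel, fusion_weights(0.5, 6))
  expect_identical(r$pfused$data, r2$pfused$data)
})
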