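test_that("NIfTI round trips preserve data and spacing", {
  set.seed(3)
  vol <- mpmri_volume(array(runif(4 * 16 * 16 * 8), c(4, 16, 16, 8)),
                      spacing = c(1, 1, 1))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f, as = "mpmri")
  expect_equal(back$data, vol$data, tolerance = 1e-7)
  expect_equal(back$spacing, vol$spacing)

  mask <- array(rbinom(16 * 16 * 8, 1, 0.3), c(16, 16, 8))
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(label_volume(mask), f2)
  lv <- read_volume(f2, as = "label", target = "ET")
  expect_s3_class(lv, "label_volume")
  expect_equal(lv$data, array(as.integer(mask), dim(mask)))

  p <- probability_volume(array(runif(6^3), c(6, 6, 6)))
  f3 <- withr::local_tempfile(fileext = ".nii.gz")
  save_probability(p, f3)
  expect_equal(read_volume(f3, as = "probability")$data, p$data,
               tolerance = 1e-6)
  zeros <- probability_volume(array(0, c(6, 6, 6)))
  f4 <- withr::local_tempfile(fileext = ".nii.gz")
  save_probability(zeros, f4)
  expect_true(all(read_volume(f4, as = "probability")$data == 0))
})

test_that("invalid volumes are rejected at construction and load", {
  expect_error(label_volume(array(c(0, 2), c(2, 1, 1))), "0 or 1")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(array(c(0, 2), c(2, 2, 2)), f)
  expect_error(read_volume(f, as = "label"), "0 or 1")
  expect_error(read_volume(file.path(tempdir(), "nope.nii.gz")), "no such file")
  expect_error(probability_volume(array(1.2, c(2, 2, 2))), "\\[0, 1\\]")
  expect_error(mpmri_volume(array(1, c(3, 4, 4, 4))), "4 x X x Y x Z")
  expect_error(mpmri_volume(array(NA_real_, c(4, 2, 2, 2))), "finite")
})

test_that("non-isotropic spacing warns but loads", {
  img <- RNifti::asNifti(array(runif(4^3), c(4, 4, 4)))
  RNifti::pixdim(img) <- c(1, 1, 2)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  expect_warning(read_volume(f, as = "probability"), "non-isotropic")
})

test_that("noiseless phantom intensities equal the contrast table exactly", {
  spec <- small_phantom_spec(noise_sd = 0)
  ph <- generate_phantom(spec)
  ct <- spec$contrast
  for (ch in 1:4) {
    chan <- ph$volume$data[ch, , , ]
    for (cls in 0:4)
      if (any(ph$classes == cls))
        expect_true(all(chan[ph$classes == cls] == ct[cls + 1, ch]),
                    label = sprintf("class %d channel %d", cls, ch))
  }
})

test_that("phantom labels are nested and contrasts ordered as designed", {
  ph <- generate_phantom(small_phantom_spec())
  et <- ph$labels$ET$data; tc <- ph$labels$TC$data; wt <- ph$labels$WT$data
  expect_true(all(tc[et == 1L] == 1L))
  expect_true(all(wt[tc == 1L] == 1L))
  expect_true(all(ph$roi$data[wt == 1L] == 1L))
  # ET hyperintense on T1ce; ED hyperintense on FLAIR among non-core tissue
  t1ce <- ph$volume$data[3, , , ]
  flair <- ph$volume$data[1, , , ]
  expect_gt(mean(t1ce[et == 1L]), max(mean(t1ce[ph$classes == 3L]),
                                      mean(t1ce[ph$classes == 1L])))
  expect_gt(mean(flair[ph$classes == 2L]), mean(flair[ph$classes == 1L]))
})

test_that("phantom generation is deterministic and rejects non-nested ellipsoids", {
  a <- generate_phantom(small_phantom_spec(seed = 9L))
  b <- generate_phantom(small_phantom_spec(seed = 9L))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labels$WT$data, b$labels$WT$data)
  expect_error(phantom_spec(semi_axes_et = c(10, 10, 10),
                            semi_axes_ncr = c(5, 5, 5)), "not nested")
})

test_that("ET voxel count matches voxel-center-in-ellipsoid enumeration", {
  spec <- phantom_spec(grid_size = c(24, 24, 24), center = c(11.5, 11.5, 11.5),
                       semi_axes_et = c(4, 4, 4), semi_axes_ncr = c(6, 6, 6),
                       semi_axes_ed = c(8, 8, 8), semi_axes_brain = c(11, 11, 11),
                       noise_sd = 0)
  ph <- generate_phantom(spec)
  # brute-force enumeration over every voxel center
  count <- 0L
  for (i in 0:23) for (j in 0:23) for (k in 0:23)
    if (((i - 11.5) / 4)^2 + ((j - 11.5) / 4)^2 + ((k - 11.5) / 4)^2 <= 1)
      count <- count + 1L
  expect_identical(sum(ph$labels$ET$data), count)
})
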