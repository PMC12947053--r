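test_that("Dice matches hand counts and conventions", {
  m <- array(0L, c(4, 4, 4)); m[1:2, 1, 1] <- 1L
  expect_equal(dice(m, m), 1)
  n <- array(0L, c(4, 4, 4)); n[3:4, 4, 4] <- 1L
  expect_equal(dice(m, n), 0)
  a <- array(0L, c(4, 4, 4)); a[1:4, 1, 1] <- 1L
  b <- array(0L, c(4, 4, 4)); b[3:4, 1, 1] <- 1L; b[1:2, 2, 1] <- 1L
  expect_equal(dice(a, b), 0.5)                    # 2*2 / (4+4)
  expect_equal(dice(a, b), dice(b, a))
  e <- array(0L, c(4, 4, 4))
  expect_equal(as.numeric(dice(e, e)), 1)
  expect_true(attr(dice(e, e), "both_empty"))
  expect_error(dice(m, array(0L, c(3, 3, 3))), "same grid")
})

test_that("HD95 matches direct distances and the all-pairs oracle", {
  m <- array(0L, c(16, 4, 4)); m[2, 2, 2] <- 1L
  n <- array(0L, c(16, 4, 4)); n[12, 2, 2] <- 1L
  expect_equal(hd95(m, n), 10)
  expect_equal(hd95(m, n, spacing = c(2, 1, 1)), 20)
  expect_equal(hd95(m, m), 0)

  set.seed(51)
  a <- array(0L, c(10, 10, 10)); a[3:6, 3:7, 4:6] <- 1L
  b <- array(0L, c(10, 10, 10)); b[4:8, 2:6, 3:7] <- 1L
  b[sample(which(b == 1L), 10)] <- 0L
  expect_equal(hd95(a, b), naive_hd95(a, b), tolerance = 1e-9)
  expect_equal(hd95(b, a), hd95(a, b))
  empty <- array(0L, c(10, 10, 10))
  expect_true(is.na(hd95(a, empty)))
  expect_true(attr(hd95(a, empty), "undefined"))
})

test_that("confusion metrics match a voxel-loop oracle", {
  set.seed(52)
  pred <- array(rbinom(5^3, 1, 0.4), c(5, 5, 5))
  ref <- array(rbinom(5^3, 1, 0.4), c(5, 5, 5))
  cm <- confusion_metrics(pred, ref)
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && ref[i] == 1) tp <- tp + 1L
    if (pred[i] == 1 && ref[i] == 0) fp <- fp + 1L
    if (pred[i] == 0 && ref[i] == 0) tn <- tn + 1L
    if (pred[i] == 0 && ref[i] == 1) fn <- fn + 1L
  }
  expect_equal(cm$counts, c(tp = tp, fp = fp, tn = tn, fn = fn))
  expect_equal(sum(cm$counts), length(pred))
  expect_equal(cm$sensitivity, tp / (tp + fn))
  expect_equal(cm$specificity, tn / (tn + fp))
  expect_equal(cm$accuracy, (tp + tn) / length(pred))

  perfect <- confusion_metrics(ref, ref)
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$accuracy),
               c(1, 1, 1))
  allpos <- confusion_metrics(array(1L, dim(ref)), ref)
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
})

test_that("signed-rank p-values match the closed-form tail for one-sided shifts", {
  # all n differences positive and untied: two-sided exact p = 2 / 2^n
  for (n in c(6, 8, 10)) {
    y <- seq_len(n)
    x <- y + seq_len(n)          # differences 1..n, untied, all positive
    expect_equal(wilcoxon_signed_rank(x, y), 2 / 2^n, tolerance = 1e-12)
  }
  expect_equal(wilcoxon_signed_rank(1:8, 1:8), 1)  # all zero differences
  expect_warning(wilcoxon_signed_rank(c(1, 2, 3), c(0, 1, 2)), "underpowered")
})

test_that("method comparison applies the Bonferroni threshold", {
  set.seed(53)
  cases <- sprintf("c%02d", 1:12)
  val_f <- runif(12, 0.8, 0.95)
  reports <- rbind(
    data.frame(case = cases, method = "fused", metric = "dsc", value = val_f),
    data.frame(case = cases, method = "m2d", metric = "dsc",
               value = val_f - runif(12, 0.05, 0.15)),
    data.frame(case = cases, method = "m3d", metric = "dsc",
               value = val_f + rnorm(12, 0, 0.005)))
  tab <- compare_methods(reports, "fused", c("m2d", "m3d"), alpha = 0.05)
  expect_equal(unique(tab$threshold), 0.025)       # 0.05 / 2
  row2d <- tab[tab$baseline == "m2d", ]
  expect_true(row2d$significant)                   # uniformly better
  expect_lt(row2d$p_value, 0.025)
  # identical methods: no signal
  rep_same <- rbind(
    data.frame(case = cases, method = "fused", metric = "dsc", value = val_f),
    data.frame(case = cases, method = "same", metric = "dsc", value = val_f))
  tab2 <- compare_methods(rep_same, "fused", "same")
  expect_false(tab2$significant)
  expect_equal(tab2$threshold, 0.05)
})
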