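test_that("confusion counts tally voxels exactly", {
  a <- array(FALSE, c(10, 10, 10)); a[1:10, 1, 1] <- TRUE
  m <- BinaryMask(a)
  cc <- confusionCounts(m, m)
  expect_equal(c(cc@TP, cc@FP, cc@FN, cc@TN), c(10, 0, 0, 990))

  p <- mask_from_voxels(c(10, 10, 1), cbind(1:4, 1, 1))
  t <- mask_from_voxels(c(10, 10, 1), cbind(1:6, 2, 1))
  cc <- confusionCounts(p, t)  # disjoint; pred positives are FP
  expect_equal(c(cc@TP, cc@FP, cc@FN), c(0, 4, 6))
  expect_equal(cc@TP + cc@FP + cc@FN + cc@TN, 100)

  set.seed(8)
  for (rep in 1:20) {
    pm <- random_mask(c(8, 8, 8), runif(1, 0.05, 0.5))
    tm <- random_mask(c(8, 8, 8), runif(1, 0.05, 0.5))
    cc <- confusionCounts(pm, tm)
    # exhaustive per-voxel tally
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_len(512)) {
      pv <- maskArray(pm)[i]; tv <- maskArray(tm)[i]
      if (pv && tv) tp <- tp + 1L else if (pv) fp <- fp + 1L
      else if (tv) fn <- fn + 1L else tn <- tn + 1L
    }
    expect_equal(c(cc@TP, cc@FP, cc@FN, cc@TN), c(tp, fp, fn, tn))
  }
})

test_that("overlap metrics match their formulas and degenerate conventions", {
  m <- overlapMetrics(new("ConfusionCounts", TP = 3, FP = 3, FN = 1, TN = 93))
  expect_equal(m[["dsc"]], 0.6)
  expect_equal(m[["ji"]], 3 / 7)
  expect_equal(m[["precision"]], 0.5)
  expect_equal(m[["recall"]], 0.75)

  expect_equal(unname(overlapMetrics(new("ConfusionCounts", TP = 5, FP = 0, FN = 0, TN = 3))),
               rep(1, 4))
  expect_equal(unname(overlapMetrics(new("ConfusionCounts", TP = 0, FP = 0, FN = 0, TN = 8))),
               rep(1, 4))  # both empty
  empty_pred <- overlapMetrics(new("ConfusionCounts", TP = 0, FP = 0, FN = 4, TN = 4))
  expect_equal(unname(empty_pred), c(0, 0, 0, 0))
})

test_that("JI and DSC obey their algebraic identity on random masks", {
  set.seed(9)
  for (rep in 1:50) {
    m <- overlapMetrics(confusionCounts(random_mask(c(6, 6, 6), 0.3),
                                        random_mask(c(6, 6, 6), 0.3)))
    expect_equal(m[["ji"]], m[["dsc"]] / (2 - m[["dsc"]]), tolerance = 1e-12)
    expect_gte(m[["dsc"]], m[["ji"]])
  }
})

test_that("HD95 handles worked cases, spacing, and symmetry", {
  a <- array(FALSE, c(12, 12, 12)); a[4:8, 4:8, 4:8] <- TRUE
  m <- BinaryMask(a)
  expect_equal(hd95(m, m), 0)

  p1 <- mask_from_voxels(c(12, 12, 12), rbind(c(2, 6, 6)))
  p2 <- mask_from_voxels(c(12, 12, 12), rbind(c(7, 6, 6)))
  expect_equal(hd95(p1, p2), 5)  # pooled set {5, 5}

  # anisotropic spacing: one slice apart at 3 mm slice thickness
  s1 <- mask_from_voxels(c(8, 8, 4), rbind(c(4, 4, 2)), spacing = c(0.5, 0.5, 3))
  s2 <- mask_from_voxels(c(8, 8, 4), rbind(c(4, 4, 3)), spacing = c(0.5, 0.5, 3))
  expect_equal(hd95(s1, s2), 3)

  none <- BinaryMask(array(FALSE, c(12, 12, 12)))
  expect_true(is.na(hd95(none, m)))
  expect_true(is.na(hd95(m, none)))

  set.seed(10)
  for (rep in 1:5) {
    x <- random_mask(c(8, 8, 8), 0.1)
    y <- random_mask(c(8, 8, 8), 0.1)
    expect_equal(hd95(x, y), hd95(y, x))
  }
})

test_that("HD95 equals the exhaustive all-pairs surface-distance oracle", {
  set.seed(11)
  for (rep in 1:30) {
    d <- c(sample(5:16, 1), sample(5:16, 1), sample(5:16, 1))
    sp <- c(runif(1, 0.5, 1.5), runif(1, 0.5, 1.5), runif(1, 0.5, 3))
    x <- random_mask(d, runif(1, 0.05, 0.4), spacing = sp)
    y <- random_mask(d, runif(1, 0.05, 0.4), spacing = sp)
    if (!any(maskArray(x)) || !any(maskArray(y))) next
    expect_equal(hd95(x, y),
                 brute_hd(maskArray(x), maskArray(y), sp), tolerance = 1e-9)
  }
})

test_that("tumor volume converts voxel counts to milliliters", {
  expect_equal(tumorVolume(BinaryMask(array(FALSE, c(4, 4, 4)))),
               list(voxels = 0, ml = 0))
  a <- array(TRUE, c(10, 10, 10))
  expect_equal(tumorVolume(BinaryMask(a)), list(voxels = 1000, ml = 1))
  b <- array(FALSE, c(10, 10, 2)); b[1:10, 1:10, 1] <- TRUE
  expect_equal(tumorVolume(BinaryMask(b, VoxelGrid(c(10, 10, 2), c(0.5, 0.5, 2)))),
               list(voxels = 100, ml = 0.05))
})

test_that("tertile stratification splits ranked volumes with remainder to lower groups", {
  g6 <- stratifyTertiles(c(a = 1, b = 2, c = 3, d = 4, e = 5, f = 6))
  expect_equal(as.vector(table(g6$group)), c(2, 2, 2))
  expect_equal(unname(g6$group[c("a", "c", "f")]),
               factor(c("Small", "Medium", "Large"),
                      levels = c("Small", "Medium", "Large")))
  expect_equal(g6$boundaries, c(small_max = 2, medium_max = 4))

  g7 <- stratifyTertiles(setNames(7:1, letters[1:7]))
  expect_equal(as.vector(table(g7$group)), c(3, 2, 2))

  g63 <- stratifyTertiles(setNames(rnorm(63, 10000, 3000), sprintf("c%02d", 1:63)))
  expect_equal(as.vector(table(g63$group)), c(21, 21, 21))

  expect_error(stratifyTertiles(c(1, 2)), "at least 3")
})

test_that("solidity is 1 for convex slices and matches the hull oracle otherwise", {
  rect <- array(FALSE, c(10, 10, 3)); rect[3:8, 2:7, 2] <- TRUE
  expect_equal(solidity(BinaryMask(rect)), 1)

  one <- mask_from_voxels(c(5, 5, 5), rbind(c(3, 3, 3)))
  expect_equal(solidity(one), 1)

  expect_true(is.na(solidity(BinaryMask(array(FALSE, c(4, 4, 4))))))

  # plus-sign of two 1x5 bars: 9 fg pixels, rasterized hull is the
  # 13-pixel diamond |x-3| + |y-3| <= 2
  cross <- array(FALSE, c(5, 5, 1))
  cross[3, 1:5, 1] <- TRUE
  cross[1:5, 3, 1] <- TRUE
  expect_equal(solidity(BinaryMask(cross)), 9 / 13, tolerance = 1e-12)

  # random shapes against the chull-augmentation inclusion oracle
  set.seed(12)
  for (rep in 1:10) {
    sl <- matrix(runif(15 * 15) < 0.25, 15, 15)
    if (sum(sl) < 3) next
    m <- BinaryMask(array(sl, c(15, 15, 1)))
    pts <- which(sl, arr.ind = TRUE)
    box <- expand.grid(x = min(pts[, 1]):max(pts[, 1]),
                       y = min(pts[, 2]):max(pts[, 2]))
    hull_n <- sum(vapply(seq_len(nrow(box)), function(i)
      hull_contains(pts, c(box$x[i], box$y[i])), logical(1)))
    expect_equal(solidity(m), nrow(pts) / max(nrow(pts), hull_n),
                 tolerance = 1e-12)
  }
})

test_that("metric reports carry the fixed column order and flag undefined HD95", {
  truth <- mask_from_voxels(c(8, 8, 8), as.matrix(expand.grid(3:6, 3:6, 3:6)))
  r <- metricReport(truth, truth, caseId = "k1")
  expect_identical(names(r), c("case_id", "class_id", "dsc", "ji", "hd95_mm",
                               "precision", "recall", "volume_voxels",
                               "volume_ml", "solidity"))
  expect_equal(r$dsc, 1)
  expect_equal(r$hd95_mm, 0)
  expect_equal(r$volume_voxels, 64)

  empty <- BinaryMask(array(FALSE, c(8, 8, 8)))
  r2 <- metricReport(empty, truth, caseId = "k2")
  expect_true(is.na(r2$hd95_mm))
  expect_equal(r2$dsc, 0)

  lab <- array(0L, c(8, 8, 8)); lab[3:6, 3:6, 3:6] <- 1L; lab[4:5, 4:5, 4] <- 2L
  v <- LabelVolume(lab, nClasses = 3L)
  multi <- evaluateLabels(v, v, caseId = "k3")
  expect_equal(nrow(multi), 2)
  expect_equal(multi$dsc, c(1, 1))
  expect_equal(multi$class_id, c(1L, 2L))
})
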