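# one voxel per vote pattern: build K rater masks realizing given counts
raters_with_counts <- function(K, counts, dim3 = c(length(counts), 1, 1)) {
  masks <- lapply(seq_len(K), function(j) {
    a <- array(FALSE, dim3)
    a[seq_along(counts), 1, 1] <- j <= counts
    BinaryMask(a)
  })
  RaterSet(masks)
}

test_that("majority voting is strict: ties with even K go to background", {
  rs5 <- raters_with_counts(5L, c(3L, 2L, 5L, 0L))
  mv <- maskArray(majorityVote(rs5))[, 1, 1]
  expect_identical(mv, c(TRUE, FALSE, TRUE, FALSE))

  rs4 <- raters_with_counts(4L, c(2L, 3L))
  mv4 <- maskArray(majorityVote(rs4))[, 1, 1]
  expect_identical(mv4, c(FALSE, TRUE))
})

test_that("soft voting averages probabilities and preserves sum-to-1", {
  p <- array(runif(2 * 2 * 2), c(2, 2, 2))
  f <- prob_field2(p)
  expect_equal(probArray(softVote(list(f, f, f))), probArray(f))

  f1 <- prob_field2(array(0.8, c(1, 1, 1)))
  f2 <- prob_field2(array(0.4, c(1, 1, 1)))
  avg <- softVote(list(f1, f2))
  expect_equal(probArray(avg)[1, 1, 1, 2], 0.6)
  expect_equal(sum(probArray(avg)[1, 1, 1, ]), 1)

  expect_error(softVote(list()), "at least one")
})

test_that("averaging probabilities can overturn the per-voxel argmax consensus", {
  # 3 classes at one voxel: raters argmax to classes 0 and 2, but the
  # averaged distribution peaks at the middle class
  mk <- function(p) ProbabilityField(array(p, c(1, 1, 1, 3)), VoxelGrid(c(1, 1, 1)))
  a <- mk(c(0.6, 0.4, 0.0))
  b <- mk(c(0.0, 0.4, 0.6))
  avg <- softVote(list(a, b))
  expect_equal(as.vector(probArray(avg)), c(0.3, 0.4, 0.3))
  expect_identical(labelArray(argmaxLabels(avg))[1, 1, 1], 1L)
})

test_that("argmax labelling breaks exact ties toward the lower class", {
  oh <- onehot_from_labels(array(c(0L, 1L, 2L, 0L), c(2, 2, 1)), 3L)
  pf <- ProbabilityField(array(as.numeric(oneHotArray(oh)), c(2, 2, 1, 3)),
                         voxelGrid(oh))
  expect_identical(labelArray(argmaxLabels(pf)),
                   array(c(0L, 1L, 2L, 0L), c(2, 2, 1)))

  tie <- prob_field2(array(0.5, c(1, 1, 1)))
  expect_identical(labelArray(argmaxLabels(tie))[1, 1, 1], 0L)

  set.seed(3)
  for (rep in 1:20) {
    raw <- array(runif(4 * 4 * 2 * 3), c(4, 4, 2, 3))
    raw <- raw / array(rep(apply(raw, 1:3, sum), 3), dim(raw))
    pf <- ProbabilityField(raw)
    lab <- labelArray(argmaxLabels(pf))
    pm <- matrix(raw, ncol = 3)
    picked <- pm[cbind(seq_len(nrow(pm)), as.vector(lab) + 1L)]
    expect_true(all(picked >= apply(pm, 1, max) - 1e-12))
  }
})

test_that("STAPLE reproduces unanimous raters at any threshold", {
  a <- array(FALSE, c(10, 10, 10)); a[3:7, 4:8, 2:6] <- TRUE
  rs <- RaterSet(lapply(1:4, function(i) BinaryMask(a)))
  res <- stapleEM(rs)
  expect_true(res@converged)
  for (t in c(0.02, 0.2, 0.5, 0.8, 0.98)) {
    expect_identical(maskArray(thresholdWeights(res, t)), a)
  }
  expect_true(all(sensitivities(res) >= 0.99))
  expect_true(all(specificities(res) >= 0.99))
})

test_that("single-rater STAPLE returns the rater's own mask", {
  set.seed(5)
  m <- random_mask(c(8, 8, 8), 0.1)
  res <- stapleEM(RaterSet(list(m)))
  expect_identical(maskArray(thresholdWeights(res, 0.5)), maskArray(m))
})

test_that("STAPLE rejects an all-empty rater set", {
  rs <- RaterSet(list(BinaryMask(array(FALSE, c(4, 4, 4)))))
  expect_error(stapleEM(rs), "degenerate")
})

test_that("STAPLE is invariant to rater ordering", {
  set.seed(11)
  truth <- mask_from_voxels(c(16, 16, 16), as.matrix(expand.grid(5:11, 5:11, 5:11)))
  masks <- lapply(c(0.95, 0.8, 0.65), function(s)
    corruptRater(truth, s, 0.99, seed = round(s * 100)))
  rs <- RaterSet(masks, c("a", "b", "c"))
  perm <- c(3L, 1L, 2L)
  rsp <- RaterSet(masks[perm], c("a", "b", "c")[perm])
  r1 <- stapleEM(rs)
  r2 <- stapleEM(rsp)
  expect_lt(max(abs(stapleWeights(r1) - stapleWeights(r2))), 1e-10)
  expect_equal(unname(sensitivities(r2)), unname(sensitivities(r1))[perm])
  expect_equal(unname(specificities(r2)), unname(specificities(r1))[perm])
})

test_that("STAPLE weights are monotone in rater agreement", {
  set.seed(13)
  truth <- mask_from_voxels(c(16, 16, 16), as.matrix(expand.grid(5:11, 5:11, 5:11)))
  masks <- lapply(c(0.9, 0.8, 0.7, 0.6), function(s)
    corruptRater(truth, s, 0.98, seed = round(s * 1000)))
  rs <- RaterSet(masks)
  res <- stapleEM(rs, StapleParams(roiMode = "union_dilated", roiMargin = 2L))
  D <- vapply(masks, function(m) as.vector(maskArray(m)), logical(16^3))
  W <- as.vector(stapleWeights(res))
  pattern <- apply(D, 1, function(r) paste(as.integer(r), collapse = ""))
  w_by_pat <- tapply(W, pattern, max)  # weights are constant per pattern
  pats <- do.call(rbind, lapply(strsplit(names(w_by_pat), ""), as.integer))
  for (i in seq_len(nrow(pats))) {
    for (j in seq_len(nrow(pats))) {
      if (i != j && all(pats[i, ] >= pats[j, ]) && any(pats[i, ] > pats[j, ])) {
        expect_gte(w_by_pat[i], w_by_pat[j] - 1e-12)
      }
    }
  }
})

test_that("threshold masks follow the weight field and nest monotonically", {
  w <- array(c(0.1, 0.2, 0.9, rep(0, 5)), c(2, 2, 2))
  r <- staple_result_from_weights(w)
  expect_identical(as.vector(maskArray(thresholdWeights(r, 0.2)))[1:3],
                   c(FALSE, TRUE, TRUE))
  expect_identical(as.vector(maskArray(thresholdWeights(r, 0.95)))[1:3],
                   rep(FALSE, 3))
  expect_error(thresholdWeights(r, 0), "0, 1")
  expect_error(thresholdWeights(r, 1), "0, 1")

  set.seed(17)
  wr <- staple_result_from_weights(array(runif(64), c(4, 4, 4)))
  ts <- sort(runif(6, 0.05, 0.95))
  for (k in seq_along(ts)[-1]) {
    lo <- maskArray(thresholdWeights(wr, ts[k - 1]))
    hi <- maskArray(thresholdWeights(wr, ts[k]))
    expect_true(all(lo | !hi))  # hi subset of lo
  }
})

test_that("threshold grid search maximizes mean DSC with balanced tie-break", {
  expect_equal(gridSearchThreshold(
    list(staple_result_from_weights(array(0.5, c(2, 2, 1)))),
    list(mask_from_voxels(c(2, 2, 1), rbind(c(1, 1, 1)))),
    grid = 0.4), 0.4)

  # truth = {W >= 0.3} exactly; DSC is 1 only at t = 0.3 on the default grid
  w <- array(0, c(4, 4, 1))
  w[1:2, 1, 1] <- c(0.3, 0.55)
  w[3:4, 1, 1] <- c(0.9, 0.25)
  w[1:2, 2, 1] <- c(0.1, 0.05)
  truth <- BinaryMask(w >= 0.3)
  got <- gridSearchThreshold(list(staple_result_from_weights(w)), list(truth))
  expect_equal(got, 0.30)

  # equal mean DSC at t=0.3 and t=0.7; the balanced operating point wins
  # even though the smaller-threshold rule alone would pick 0.3:
  #   t=0.3: TP=3 FP=3 FN=0 -> DSC 2/3, |prec-rec| = 1/2
  #   t=0.7: TP=2 FP=1 FN=1 -> DSC 2/3, |prec-rec| = 0
  w2 <- array(0, c(6, 1, 1))
  w2[, 1, 1] <- c(0.9, 0.9, 0.5, 0.9, 0.5, 0.5)
  truth2 <- mask_from_voxels(c(6, 1, 1), rbind(c(1, 1, 1), c(2, 1, 1), c(3, 1, 1)))
  cc <- function(t) overlapMetrics(confusionCounts(
    thresholdWeights(staple_result_from_weights(w2), t), truth2))
  expect_equal(cc(0.3)[["dsc"]], cc(0.7)[["dsc"]])
  expect_gt(abs(cc(0.3)[["precision"]] - cc(0.3)[["recall"]]),
            abs(cc(0.7)[["precision"]] - cc(0.7)[["recall"]]))
  got2 <- gridSearchThreshold(list(staple_result_from_weights(w2)), list(truth2),
                              grid = c(0.3, 0.7))
  expect_equal(got2, 0.7)

  expect_error(gridSearchThreshold(list(), list()), "non-empty")
})

test_that("multi-class fusion composes per-class results with tumor precedence", {
  lab <- array(0L, c(8, 8, 4))
  lab[2:6, 2:6, 2:3] <- 1L
  lab[3:5, 3:5, 2] <- 2L
  v <- LabelVolume(lab, nClasses = 3L)
  expect_identical(labelArray(fuseMulticlass(list(v, v, v), "majority")), lab)
  expect_identical(labelArray(fuseMulticlass(list(v, v, v), "staple")), lab)

  # organ and tumor both fused TRUE at one voxel -> labelled tumor
  organ <- array(0L, c(4, 4, 1)); organ[2, 2, 1] <- 1L
  tum <- array(0L, c(4, 4, 1)); tum[2, 2, 1] <- 2L
  both <- list(LabelVolume(organ, nClasses = 3L), LabelVolume(organ, nClasses = 3L),
               LabelVolume(tum, nClasses = 3L), LabelVolume(tum, nClasses = 3L),
               LabelVolume(tum, nClasses = 3L))
  # class1 majority: 2/5 -> no; class2 majority: 3/5 -> yes -> tumor
  expect_identical(labelArray(fuseMulticlass(both, "majority"))[2, 2, 1], 2L)

  # majority method equals composing per-class majorityVote calls
  set.seed(23)
  vols <- lapply(1:5, function(i) random_label_volume(c(6, 6, 3), 3L))
  fused <- fuseMulticlass(vols, "majority")
  expected <- array(0L, c(6, 6, 3))
  for (cls in 1:2) {
    mv <- majorityVote(RaterSet(lapply(vols, extractClassMask, classId = cls)))
    expected[maskArray(mv)] <- cls
  }
  expect_identical(labelArray(fused), expected)
})

test_that("perfect raters are reproduced exactly by every fusion method", {
  v <- makePhantom(VoxelGrid(c(24, 24, 24)), "lobulated", radii = c(6, 7, 5),
                   irregularity = 0.15, seed = 2)
  truth <- extractClassMask(v, 1)
  rs <- RaterSet(lapply(1:5, function(i) truth))
  expect_identical(maskArray(majorityVote(rs)), maskArray(truth))
  expect_identical(maskArray(thresholdWeights(stapleEM(rs), 0.5)), maskArray(truth))
  maps <- lapply(1:5, function(i) makeProbabilityMap(truth, sharpness = 10))
  soft <- extractClassMask(argmaxLabels(softVote(maps)), 1L)
  expect_identical(maskArray(soft), maskArray(truth))
})
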