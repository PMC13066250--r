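# Evaluation metrics: voxelwise confusion counts, overlap metrics
# (DSC/JI/precision/recall), the 95th-percentile Hausdorff distance in mm,
# tumor volume, tertile stratification, and 2D solidity.

#' ConfusionCounts: voxelwise 2x2 confusion table
#'
#' TP/FP/FN/TN counts from a pixel-by-pixel comparison of a prediction
#' against the ground truth; conserved: the four counts sum to the voxel
#' total. Orientation: prediction positives not in the truth are FP.
#'
#' @slot TP,FP,FN,TN non-negative counts.
#' @export
setClass("ConfusionCounts",
         representation(TP = "numeric", FP = "numeric", FN = "numeric", TN = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@TP, object@FP, object@FN, object@TN)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    return("counts must be non-negative integers")
  TRUE
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d FN=%d TN=%d\n",
              object@TP, object@FP, object@FN, object@TN))
})

#' Confusion counts between prediction and truth
#'
#' @param pred,truth [BinaryMask-class] objects on one grid; `pred` is the
#'   candidate segmentation, `truth` the reference.
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(pred, truth) {
  stopifnot(is(pred, "BinaryMask"), is(truth, "BinaryMask"))
  checkSameGrid(pred, truth)
  p <- pred@values
  t <- truth@values
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  new("ConfusionCounts", TP = tp, FP = fp, FN = fn,
      TN = length(p) - tp - fp - fn)
}

#' Overlap metrics from confusion counts
#'
#' \itemize{
#'   \item `DSC = 2 TP / ((TP+FN) + (TP+FP))` — Dice similarity coefficient
#'   \item `JI  = TP / (TP+FP+FN)` — Jaccard index
#'   \item `precision = TP / (TP+FP)`, `recall = TP / (TP+FN)`
#' }
#' Degenerate conventions: if truth and prediction are both empty all four
#' metrics are 1; otherwise any ratio with a zero denominator is 0. The
#' algebraic identity `JI = DSC / (2 - DSC)` holds for every output.
#'
#' @param counts a [ConfusionCounts-class].
#' @return named numeric vector `c(dsc, ji, precision, recall)`.
#' @export
overlapMetrics <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  TP <- counts@TP; FP <- counts@FP; FN <- counts@FN
  if (TP + FP + FN == 0) {
    return(c(dsc = 1, ji = 1, precision = 1, recall = 1))
  }
  rat <- function(num, den) if (den == 0) 0 else num / den
  c(dsc = rat(2 * TP, (TP + FN) + (TP + FP)),
    ji = rat(TP, TP + FP + FN),
    precision = rat(TP, TP + FP),
    recall = rat(TP, TP + FN))
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' Robust boundary-distance metric. Surface voxels are foreground voxels with
#' at least one face-adjacent background voxel (the volume border counts as
#' background). Distances are Euclidean mm between voxel centers, using the
#' grid spacing, so anisotropic slices are handled correctly. Both directed
#' nearest-surface distance sets (prediction to truth and truth to
#' prediction) are pooled and the 95th percentile of the pooled set (linear
#' interpolation between order statistics, `quantile` type 7) is returned;
#' `method = "max"` instead takes the larger of the two directed 95th
#' percentiles. `NA` when either mask is empty — the metric is only defined
#' when both masks mark a tumor.
#'
#' @param pred,truth [BinaryMask-class] objects on one grid.
#' @param percentile percentile of the distance set (default 95).
#' @param method `"pooled"` (default) or `"max"` (max of directed percentiles).
#' @return distance in mm, or `NA_real_` if either mask is empty.
#' @export
hd95 <- function(pred, truth, percentile = 95, method = c("pooled", "max")) {
  method <- match.arg(method)
  stopifnot(is(pred, "BinaryMask"), is(truth, "BinaryMask"))
  checkSameGrid(pred, truth)
  if (!any(pred@values) || !any(truth@values)) return(NA_real_)
  spacing <- gridSpacing(pred)
  A <- .coordsMM(.surface(pred@values), spacing)
  B <- .coordsMM(.surface(truth@values), spacing)
  dAB <- .nearestDist(A, B)
  dBA <- .nearestDist(B, A)
  q <- percentile / 100
  if (method == "pooled") {
    unname(stats::quantile(c(dAB, dBA), q, type = 7))
  } else {
    max(stats::quantile(dAB, q, type = 7), stats::quantile(dBA, q, type = 7))
  }
}

#' Tumor volume in voxels and milliliters
#'
#' @param mask a [BinaryMask-class].
#' @return list with `voxels` (count) and `ml` (count x voxel volume in mm^3,
#'   divided by 1000).
#' @export
tumorVolume <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  n <- sum(mask@values)
  list(voxels = n, ml = n * prod(gridSpacing(mask)) / 1000)
}

#' Stratify cases into tertiles by tumor volume
#'
#' Ranks cases ascending by ground-truth tumor volume (ties broken by case
#' id) and splits them into three contiguous groups as equal as possible,
#' remainder going to the lower groups; e.g. 7 cases split 3/2/2 and 63 cases
#' split 21/21/21. Size-stratified evaluation is how volume-dependent
#' performance differences between fusion methods are exposed.
#'
#' @param volumes named numeric vector, case id to tumor volume (voxels).
#' @return list with `group` (factor `Small`/`Medium`/`Large` named by case)
#'   and `boundaries` (max volume of Small and of Medium).
#' @export
stratifyTertiles <- function(volumes) {
  n <- length(volumes)
  if (n < 3L) stop("stratifyTertiles: need at least 3 cases")
  if (is.null(names(volumes))) names(volumes) <- as.character(seq_len(n))
  ord <- order(volumes, names(volumes))
  q <- n %/% 3L
  r <- n %% 3L
  sizes <- c(q + (r >= 1L), q + (r >= 2L), q)
  grp <- factor(rep(c("Small", "Medium", "Large"), times = sizes),
                levels = c("Small", "Medium", "Large"))
  group <- grp[order(ord)]  # back to input order
  names(group) <- names(volumes)
  sorted <- volumes[ord]
  list(group = group,
       boundaries = c(small_max = unname(sorted[sizes[1]]),
                      medium_max = unname(sorted[sizes[1] + sizes[2]])))
}

# pixel centers inside-or-on the convex hull of 2D integer points;
# half-plane tests against the chull polygon, boundary pixels included
.hullRasterCount <- function(pts) {
  if (nrow(pts) == 1L) return(1L)
  pts <- unique(pts)
  if (nrow(pts) == 1L) return(1L)
  # collinear set: lattice points on the extreme segment
  cx <- pts[, 1] - pts[1, 1]
  cy <- pts[, 2] - pts[1, 2]
  cross_all <- cx * cy[which.max(cx^2 + cy^2)] - cy * cx[which.max(cx^2 + cy^2)]
  if (all(abs(cross_all) < 1e-9)) {
    d2 <- outer(pts[, 1], pts[, 1], `-`)^2 + outer(pts[, 2], pts[, 2], `-`)^2
    ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
    a <- pts[ij[1], ]; b <- pts[ij[2], ]
    g <- function(x, y) if (y == 0) abs(x) else if (x == 0) abs(y) else g(y, x %% y)
    return(g(abs(b[1] - a[1]), abs(b[2] - a[2])) + 1L)
  }
  h <- grDevices::chull(pts[, 1], pts[, 2])  # clockwise vertex indices
  poly <- pts[h, , drop = FALSE]
  nv <- nrow(poly)
  xr <- range(pts[, 1]); yr <- range(pts[, 2])
  cand <- expand.grid(x = xr[1]:xr[2], y = yr[1]:yr[2])
  inside <- rep(TRUE, nrow(cand))
  for (e in seq_len(nv)) {
    a <- poly[e, ]
    b <- poly[if (e == nv) 1L else e + 1L, ]
    cr <- (b[1] - a[1]) * (cand$y - a[2]) - (b[2] - a[2]) * (cand$x - a[1])
    inside <- inside & cr <= 1e-9  # chull is clockwise
  }
  sum(inside)
}

#' Solidity of a mask
#'
#' Ratio of foreground area to the area of its convex hull; 1 for convex
#' shapes, small for spiky or lobulated ones. Computed in 2D on the axial
#' slice (third axis) of maximal foreground area: solidity = foreground
#' pixel count / pixel count of the rasterized convex hull of the foreground
#' pixel centers (centers on the hull boundary count as inside). Ties between
#' slices break to the lowest slice index.
#'
#' @param mask a [BinaryMask-class].
#' @return solidity in (0, 1], or `NA_real_` for an empty mask.
#' @export
solidity <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  if (!any(mask@values)) return(NA_real_)
  areas <- apply(mask@values, 3L, sum)
  z <- which.max(areas)
  slice <- mask@values[, , z]
  pts <- which(slice, arr.ind = TRUE)
  nfg <- nrow(pts)
  hull <- .hullRasterCount(pts)
  nfg / max(nfg, hull)
}

#' Per-case metric report
#'
#' One evaluation row for a prediction/truth mask pair: overlap metrics,
#' HD95, and the ground-truth case descriptors (tumor volume and solidity)
#' used for stratified and morphology analyses. Column order is fixed for
#' CSV interchange: `case_id, class_id, dsc, ji, hd95_mm, precision, recall,
#' volume_voxels, volume_ml, solidity`.
#'
#' @param pred,truth [BinaryMask-class] objects on one grid.
#' @param caseId case identifier string.
#' @param classId class index the masks represent (default 1).
#' @param hd95Method passed to [hd95()].
#' @return one-row `data.frame` with the columns above; `hd95_mm` is `NA`
#'   when either mask is empty, `solidity`/`volume` describe the truth mask.
#' @export
metricReport <- function(pred, truth, caseId = "case", classId = 1L,
                         hd95Method = "pooled") {
  m <- overlapMetrics(confusionCounts(pred, truth))
  vol <- tumorVolume(truth)
  data.frame(case_id = as.character(caseId), class_id = as.integer(classId),
             dsc = m[["dsc"]], ji = m[["ji"]],
             hd95_mm = hd95(pred, truth, method = hd95Method),
             precision = m[["precision"]], recall = m[["recall"]],
             volume_voxels = vol$voxels, volume_ml = vol$ml,
             solidity = solidity(truth),
             stringsAsFactors = FALSE)
}

#' Evaluate all foreground classes of a label volume
#'
#' Convenience wrapper producing one [metricReport()] row per foreground
#' class of a multi-class prediction against a multi-class truth.
#'
#' @param pred,truth [LabelVolume-class] objects on one grid with equal C.
#' @param caseId case identifier string.
#' @param hd95Method passed to [hd95()].
#' @return `data.frame` with `C - 1` rows.
#' @export
evaluateLabels <- function(pred, truth, caseId = "case", hd95Method = "pooled") {
  stopifnot(is(pred, "LabelVolume"), is(truth, "LabelVolume"))
  checkSameGrid(pred, truth)
  if (nClasses(pred) != nClasses(truth)) stop("class-count mismatch")
  rows <- lapply(seq_len(nClasses(truth) - 1L), function(cls) {
    metricReport(extractClassMask(pred, cls), extractClassMask(truth, cls),
                 caseId = caseId, classId = cls, hd95Method = hd95Method)
  })
  do.call(rbind, rows)
}
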