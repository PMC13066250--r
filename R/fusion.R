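# Ensemble fusion strategies: strict-majority voting over binary masks,
# soft voting over probability fields, and STAPLE expectation-maximization.

#' Strict-majority vote over rater masks
#'
#' A voxel is foreground iff strictly more than K/2 raters mark it. With even
#' K a tie therefore goes to background. Majority voting discards prediction
#' confidence entirely, which is exactly why it serves as the simplest
#' reference fusion method.
#'
#' @param raters a [RaterSet-class].
#' @return a [BinaryMask-class] on the raters' grid.
#' @export
majorityVote <- function(raters) {
  stopifnot(is(raters, "RaterSet"))
  K <- nRaters(raters)
  counts <- Reduce(`+`, lapply(raters@masks, function(m) m@values))
  new("BinaryMask", grid = voxelGrid(raters), values = counts > K / 2)
}

#' Soft vote: average per-class probability maps
#'
#' Unweighted arithmetic mean of the per-class probabilities across models —
#' the default ensemble of self-configuring segmentation frameworks. The
#' average of sum-to-1 fields is again sum-to-1.
#'
#' @param maps list of [ProbabilityField-class] objects on one grid with a
#'   common class count.
#' @return the averaged [ProbabilityField-class].
#' @export
softVote <- function(maps) {
  if (length(maps) < 1L) stop("softVote: need at least one probability map")
  stopifnot(all(vapply(maps, is, logical(1), "ProbabilityField")))
  checkSameGrid(maps)
  C <- vapply(maps, nClasses, integer(1))
  if (length(unique(C)) != 1L)
    stop(sprintf("softVote: class-count mismatch (%s)", paste(C, collapse = ", ")))
  mean_vals <- Reduce(`+`, lapply(maps, function(m) m@values)) / length(maps)
  new("ProbabilityField", grid = voxelGrid(maps[[1]]), values = mean_vals)
}

#' Hard labels from a probability field
#'
#' Per-voxel argmax over classes; exact ties break toward the lower class
#' index (so a 0.5/0.5 two-class tie is background).
#'
#' @param map a [ProbabilityField-class].
#' @return a [LabelVolume-class] with the same class count.
#' @export
argmaxLabels <- function(map) {
  stopifnot(is(map, "ProbabilityField"))
  d <- dim(map@values)
  m <- matrix(map@values, ncol = d[4])
  lab <- max.col(m, ties.method = "first") - 1L
  new("LabelVolume", grid = map@grid,
      labels = array(as.integer(lab), d[1:3]), nClasses = d[4])
}

#' STAPLE: simultaneous truth and performance level estimation
#'
#' Binary STAPLE EM over the rater decision matrix D_ij (rater j's call at
#' voxel i). The algorithm alternates between estimating the latent consensus
#' weight field W_i (E-step) and each rater's sensitivity p_j and specificity
#' q_j (M-step), so that reliable raters earn larger weight in the consensus
#' than unreliable ones:
#'
#' \itemize{
#'   \item E-step: `W_i = a_i / (a_i + b_i)` with
#'     `a_i = gamma * prod_j p_j^D_ij (1-p_j)^(1-D_ij)` and
#'     `b_i = (1-gamma) * prod_j (1-q_j)^D_ij q_j^(1-D_ij)`,
#'     evaluated in the log domain.
#'   \item M-step: `p_j = sum_i W_i D_ij / sum_i W_i`,
#'     `q_j = sum_i (1-W_i)(1-D_ij) / sum_i (1-W_i)`.
#' }
#'
#' The foreground prior gamma is fixed at the mean rater foreground fraction
#' within the ROI (default) or at a user value; it is not re-estimated, which
#' guards against prior collapse on tiny foregrounds. p_j and q_j are clamped
#' to `[1e-6, 1-1e-6]` before the log-domain E-step (the 0.9999
#' initialization and perfect-agreement inputs otherwise hit log(0)).
#' Iteration stops when the largest absolute change over all p_j and q_j
#' falls below `tolerance`, or at `maxIterations` with `converged = FALSE`.
#' The algorithm is deterministic.
#'
#' With `roiMode = "full_volume"` the EM sums run over every voxel; since a
#' whole CT volume is overwhelmingly background, the estimated specificities
#' are then near 1 for any rater. `roiMode = "union_dilated"` restricts the
#' sums to the union of rater masks dilated by `roiMargin` voxels, which makes
#' specificity an informative, recoverable quantity. Weights outside the ROI
#' are 0.
#'
#' @param raters a [RaterSet-class]; at least one rater must have at least
#'   one foreground voxel.
#' @param params a [StapleParams-class].
#' @return a [StapleResult-class].
#' @references Warfield, Zou and Wells (2004) IEEE TMI 23(7):903-921.
#' @export
#' @examples
#' truth <- array(FALSE, c(8, 8, 8)); truth[3:6, 3:6, 3:6] <- TRUE
#' rs <- RaterSet(list(BinaryMask(truth), BinaryMask(truth), BinaryMask(truth)))
#' res <- stapleEM(rs)
#' sensitivities(res)
stapleEM <- function(raters, params = StapleParams()) {
  stopifnot(is(raters, "RaterSet"), is(params, "StapleParams"))
  K <- nRaters(raters)
  grid <- voxelGrid(raters)
  union_fg <- Reduce(`|`, lapply(raters@masks, function(m) m@values))
  if (!any(union_fg))
    stop("stapleEM: degenerate input, no rater marks any foreground voxel")

  roi <- if (params@roiMode == "union_dilated") {
    .dilate(union_fg, params@roiMargin)
  } else {
    array(TRUE, grid@shape)
  }
  roi_idx <- which(roi)
  D <- vapply(raters@masks, function(m) as.numeric(m@values[roi_idx]),
              numeric(length(roi_idx)))
  D <- matrix(D, ncol = K)

  gamma <- if (params@priorMode == "fixed") params@gamma else mean(colMeans(D))
  gamma <- min(max(gamma, 1e-6), 1 - 1e-6)

  p <- rep(params@initSensitivity, K)
  q <- rep(params@initSpecificity, K)
  clamp <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  W <- NULL
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(params@maxIterations)) {
    pc <- clamp(p); qc <- clamp(q)
    # log a_i - log b_i, vectorized over the ROI
    la <- log(gamma) + D %*% log(pc) + (1 - D) %*% log(1 - pc)
    lb <- log(1 - gamma) + D %*% log(1 - qc) + (1 - D) %*% log(qc)
    W <- as.vector(1 / (1 + exp(lb - la)))

    sw <- sum(W)
    swc <- sum(1 - W)
    p_new <- as.vector(crossprod(D, W)) / sw
    q_new <- as.vector(crossprod(1 - D, 1 - W)) / swc
    delta <- max(abs(p_new - p), abs(q_new - q))
    p <- p_new
    q <- q_new
    if (delta < params@tolerance) {
      converged <- TRUE
      break
    }
  }
  # final E-step so the weights reflect the converged parameters
  pc <- clamp(p); qc <- clamp(q)
  la <- log(gamma) + D %*% log(pc) + (1 - D) %*% log(1 - pc)
  lb <- log(1 - gamma) + D %*% log(1 - qc) + (1 - D) %*% log(qc)
  W <- as.vector(1 / (1 + exp(lb - la)))

  weights <- array(0, grid@shape)
  weights[roi_idx] <- W
  names(p) <- names(q) <- raters@raterNames
  new("StapleResult", grid = grid, weights = weights,
      sens = pmin(pmax(p, 0), 1), spec = pmin(pmax(q, 0), 1),
      prior = gamma, iterations = iter, converged = converged)
}

#' Threshold a STAPLE weight field
#'
#' The EM consensus is a probabilistic map; the final binary segmentation is
#' `W_i >= t`. Lower thresholds favour recall, higher thresholds precision;
#' masks are nested: `mask(t1)` contains `mask(t2)` whenever `t1 <= t2`.
#'
#' @param r a [StapleResult-class].
#' @param t threshold in (0, 1).
#' @return a [BinaryMask-class].
#' @export
thresholdWeights <- function(r, t) {
  stopifnot(is(r, "StapleResult"))
  if (!is.numeric(t) || length(t) != 1L || t <= 0 || t >= 1)
    stop("threshold t must lie in (0, 1)")
  new("BinaryMask", grid = r@grid, values = r@weights >= t)
}

#' Grid search for the STAPLE threshold
#'
#' Selects, from a grid of candidate thresholds, the one maximizing mean DSC
#' against reference masks over validation cases. Ties (within 1e-12) break
#' first by minimal mean |precision - recall| (a balanced operating point),
#' then by the smaller threshold.
#'
#' @param results list of [StapleResult-class] objects (validation cases).
#' @param truths list of reference [BinaryMask-class] objects, same length.
#' @param grid numeric vector of candidate thresholds in (0, 1); default
#'   `seq(0.05, 0.95, by = 0.05)`.
#' @return the selected threshold (scalar).
#' @export
gridSearchThreshold <- function(results, truths, grid = seq(0.05, 0.95, by = 0.05)) {
  if (length(results) == 0L || length(results) != length(truths))
    stop("gridSearchThreshold: need equal-length non-empty result/truth lists")
  if (length(grid) == 0L || any(grid <= 0 | grid >= 1))
    stop("gridSearchThreshold: grid values must lie in (0, 1)")
  score <- vapply(grid, function(t) {
    per_case <- vapply(seq_along(results), function(i) {
      m <- overlapMetrics(confusionCounts(thresholdWeights(results[[i]], t), truths[[i]]))
      c(m[["dsc"]], abs(m[["precision"]] - m[["recall"]]))
    }, numeric(2))
    c(mean(per_case[1, ]), mean(per_case[2, ]))
  }, numeric(2))
  best_dsc <- max(score[1, ])
  cand <- which(score[1, ] >= best_dsc - 1e-12)
  cand <- cand[order(score[2, cand], grid[cand])]
  grid[cand[1]]
}

#' Fuse multi-class label volumes per class
#'
#' Decomposes each rater's label volume into per-class binary masks, fuses
#' each foreground class independently with the chosen method, and composes
#' the fused masks back into labels with precedence to the higher class index
#' on overlap (tumor over organ); background elsewhere.
#'
#' @param volumes list of [LabelVolume-class] objects on one grid with a
#'   common class count.
#' @param method `"majority"` or `"staple"`. Soft voting operates on
#'   probability fields, not hard labels: use [softVote()] followed by
#'   [argmaxLabels()].
#' @param params [StapleParams-class] for `method = "staple"`.
#' @param threshold STAPLE weight threshold for `method = "staple"`.
#' @return the fused [LabelVolume-class].
#' @export
fuseMulticlass <- function(volumes, method = c("majority", "staple"),
                           params = StapleParams(), threshold = 0.5) {
  method <- match.arg(method)
  stopifnot(length(volumes) >= 1L,
            all(vapply(volumes, is, logical(1), "LabelVolume")))
  checkSameGrid(volumes)
  C <- vapply(volumes, nClasses, integer(1))
  if (length(unique(C)) != 1L)
    stop("fuseMulticlass: class-count mismatch")
  C <- C[1]
  grid <- voxelGrid(volumes[[1]])
  labels <- array(0L, grid@shape)
  for (cls in seq_len(C - 1L)) {
    rs <- RaterSet(lapply(volumes, extractClassMask, classId = cls))
    fused <- switch(method,
      majority = majorityVote(rs),
      staple = {
        if (!any(vapply(rs@masks, function(m) any(m@values), logical(1)))) {
          new("BinaryMask", grid = grid, values = array(FALSE, grid@shape))
        } else {
          thresholdWeights(stapleEM(rs, params), threshold)
        }
      })
    labels[fused@values] <- cls  # ascending loop => higher class wins overlap
  }
  new("LabelVolume", grid = grid, labels = labels, nClasses = C)
}
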