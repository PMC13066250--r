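# Forward values of the segmentation losses used to diversify model
# ensembles: cross-entropy, Top-K, Dice, generalized Dice, and their hybrid
# sums. No gradients: these characterize predictions, they do not train.

# common unpacking/validation: prediction s_ic vs one-hot truth g_ic,
# flattened to N x C matrices
.lossArrays <- function(pred, truth) {
  stopifnot(is(pred, "ProbabilityField"), is(truth, "OneHotField"))
  checkSameGrid(pred, truth)
  C <- nClasses(pred)
  if (C != nClasses(truth))
    stop(sprintf("class-count mismatch: prediction C=%d, truth C=%d",
                 C, nClasses(truth)))
  list(s = matrix(pred@values, ncol = C),
       g = matrix(as.numeric(truth@values), ncol = C),
       N = prod(gridShape(pred)), C = C)
}

#' Cross-entropy loss
#'
#' `-(1/N) sum_c sum_i g_ic log s_ic`, the standard distribution-based
#' segmentation loss: it compares predicted class probabilities against the
#' one-hot truth pixel by pixel. Predicted probabilities are clamped to
#' `[1e-12, 1]` so confident errors yield a large finite value rather than
#' infinity.
#'
#' @param pred a [ProbabilityField-class] (s_ic).
#' @param truth a [OneHotField-class] (g_ic) on the same grid.
#' @return non-negative scalar; 0 iff the true class has probability 1 at
#'   every pixel.
#' @export
lossCE <- function(pred, truth) {
  a <- .lossArrays(pred, truth)
  s <- pmin(pmax(a$s, 1e-12), 1)
  -sum(a$g * log(s)) / a$N
}

#' Top-K cross-entropy loss
#'
#' Mean per-pixel cross-entropy over the hardest `kPercent`% of pixels: each
#' pixel's contribution `l_i = -sum_c g_ic log s_ic` is ranked descending and
#' the top `ceiling(kPercent * N / 100)` pixels are averaged (ties at the
#' selection boundary include all tied pixels). At `kPercent = 100` this is
#' exactly [lossCE()]. Concentrating on hard pixels is how the Top-K variant
#' counteracts easy-background domination during training.
#'
#' @inheritParams lossCE
#' @param kPercent percentage of pixels to keep, in (0, 100].
#' @return non-negative scalar, non-increasing in `kPercent`.
#' @export
lossTopK <- function(pred, truth, kPercent = 10) {
  if (!is.numeric(kPercent) || length(kPercent) != 1L ||
      kPercent <= 0 || kPercent > 100)
    stop("kPercent must lie in (0, 100]")
  a <- .lossArrays(pred, truth)
  s <- pmin(pmax(a$s, 1e-12), 1)
  li <- -rowSums(a$g * log(s))
  m <- ceiling(kPercent * a$N / 100)
  cut <- sort(li, decreasing = TRUE)[m]
  mean(li[li >= cut])
}

#' Dice loss
#'
#' `1 - 2 (sum_c sum_i g_ic s_ic + eps) / (sum_c sum_i g_ic + sum_c sum_i
#' s_ic + eps)` with `eps = 1e-5` smoothing the empty-class case. The
#' region-based counterpart of cross-entropy: it directly targets the overlap
#' the DSC metric measures.
#'
#' @inheritParams lossCE
#' @param classes optional integer vector of class indices (0-based) over
#'   which the sums run; default all classes. Restricting to foreground
#'   classes is the common convention when background dominates.
#' @return scalar in `[0, 1]` (up to the eps smoothing).
#' @export
lossDice <- function(pred, truth, classes = NULL) {
  a <- .lossArrays(pred, truth)
  sel <- if (is.null(classes)) seq_len(a$C) else as.integer(classes) + 1L
  if (any(sel < 1L | sel > a$C)) stop("classes out of range")
  eps <- 1e-5
  g <- a$g[, sel, drop = FALSE]
  s <- a$s[, sel, drop = FALSE]
  1 - (2 * sum(g * s) + eps) / (sum(g) + sum(s) + eps)
}

#' Generalized Dice loss
#'
#' Dice loss with per-class weights `w_c`, by default inversely proportional
#' to the squared class volume (`w_c = 1 / (sum_i g_ic + eps)^2`), so rare
#' classes are not drowned out by abundant ones:
#' `1 - (2 sum_c w_c sum_i g_ic s_ic + eps) / (sum_c w_c sum_i (g_ic + s_ic)
#' + eps)`. With uniform weights this reduces exactly to [lossDice()].
#'
#' @inheritParams lossDice
#' @param weights optional numeric vector of per-class weights (recycled over
#'   `classes`); default inverse squared class frequency. At least one weight
#'   must be positive.
#' @param exponent inverse-frequency exponent for the default weights: 2
#'   (squared-volume convention, default) or 1.
#' @return scalar, ~0 for a perfect prediction.
#' @export
lossGDice <- function(pred, truth, classes = NULL, weights = NULL, exponent = 2) {
  a <- .lossArrays(pred, truth)
  sel <- if (is.null(classes)) seq_len(a$C) else as.integer(classes) + 1L
  if (any(sel < 1L | sel > a$C)) stop("classes out of range")
  eps <- 1e-5
  g <- a$g[, sel, drop = FALSE]
  s <- a$s[, sel, drop = FALSE]
  if (is.null(weights)) {
    weights <- 1 / (colSums(g) + eps)^exponent
  } else {
    weights <- rep_len(as.numeric(weights), length(sel))
    if (any(weights < 0) || all(weights == 0))
      stop("weights must be non-negative with at least one positive entry")
  }
  num <- sum(weights * colSums(g * s))
  den <- sum(weights * (colSums(g) + colSums(s)))
  1 - (2 * num + eps) / (den + eps)
}

#' Hybrid losses
#'
#' Plain sums of a distribution-based and a region-based term, the loss
#' combinations used to induce ensemble diversity: `CE+Dice`, `TopK+Dice`
#' and `CE+GDice`.
#'
#' @inheritParams lossCE
#' @param name one of `"CE+Dice"`, `"TopK+Dice"`, `"CE+GDice"`.
#' @param kPercent Top-K percentage for `"TopK+Dice"` (default 10).
#' @param classes,weights,exponent passed to the region term; see
#'   [lossDice()] and [lossGDice()].
#' @return non-negative scalar.
#' @export
lossHybrid <- function(pred, truth, name = c("CE+Dice", "TopK+Dice", "CE+GDice"),
                       kPercent = 10, classes = NULL, weights = NULL, exponent = 2) {
  name <- match.arg(name)
  switch(name,
    "CE+Dice" = lossCE(pred, truth) + lossDice(pred, truth, classes),
    "TopK+Dice" = lossTopK(pred, truth, kPercent) + lossDice(pred, truth, classes),
    "CE+GDice" = lossCE(pred, truth) +
      lossGDice(pred, truth, classes, weights, exponent))
}
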