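#' @include AllGenerics.R
NULL

# Central S4 containers. Axis convention, used everywhere in the package:
# arrays are indexed [i, j, k] with k (the third axis) the axial/slice axis;
# spacing is mm per voxel along the same axes. Grids are never resampled --
# mismatched grids are an error, not a silent fix.

#' VoxelGrid: discrete geometry of a volume
#'
#' Shape (voxels per axis) and spacing (mm per voxel) of a 3D voxel grid.
#' All volumes, masks and probability fields in a fusion run must live on one
#' grid; [checkSameGrid()] enforces this. Axis 3 is the axial (slice) axis.
#'
#' @slot shape integer(3), voxels per axis, all >= 1.
#' @slot spacing numeric(3), mm per voxel, all > 0. Anisotropic spacing is
#'   common in CT (slice thickness often exceeds in-plane resolution) and is
#'   honoured by all physical-distance computations.
#' @export
setClass("VoxelGrid", representation(shape = "integer", spacing = "numeric"))

setValidity("VoxelGrid", function(object) {
  if (length(object@shape) != 3L || any(is.na(object@shape)) || any(object@shape < 1L))
    return("shape must be 3 positive integers")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) || any(object@spacing <= 0))
    return("spacing must be 3 positive reals (mm)")
  TRUE
})

#' @param shape integer(3) voxels per axis.
#' @param spacing numeric(3) mm per voxel (default 1 mm isotropic).
#' @rdname VoxelGrid-class
#' @export
VoxelGrid <- function(shape, spacing = c(1, 1, 1)) {
  new("VoxelGrid", shape = as.integer(shape), spacing = as.numeric(spacing))
}

# virtual parent for anything that lives on a grid
setClass("VoxelData", representation(grid = "VoxelGrid", "VIRTUAL"))

#' LabelVolume: integer class labels on a voxel grid
#'
#' Multi-class segmentation with class 0 = background; e.g. background /
#' organ / tumor is C = 3. Labels must lie in `[0, C-1]`.
#'
#' @slot grid the [VoxelGrid-class].
#' @slot labels 3D integer array, dim equal to the grid shape.
#' @slot nClasses integer C >= 2.
#' @export
setClass("LabelVolume", contains = "VoxelData",
         representation(labels = "array", nClasses = "integer"))

setValidity("LabelVolume", function(object) {
  if (!identical(dim(object@labels), object@grid@shape))
    return("label array dim must equal grid shape")
  if (object@nClasses < 2L) return("nClasses must be >= 2")
  rng <- range(object@labels)
  if (rng[1] < 0L || rng[2] >= object@nClasses)
    return(sprintf("labels must lie in [0, %d]", object@nClasses - 1L))
  TRUE
})

#' @param labels integer array (or numeric with integral values).
#' @param grid a [VoxelGrid-class]; defaults to 1 mm isotropic over `dim(labels)`.
#' @param nClasses number of classes C; defaults to `max(labels) + 1`, at least 2.
#' @rdname LabelVolume-class
#' @export
LabelVolume <- function(labels, grid = NULL, nClasses = NULL) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (is.null(grid)) grid <- VoxelGrid(dim(labels))
  if (is.null(nClasses)) nClasses <- max(2L, max(labels) + 1L)
  new("LabelVolume", grid = grid, labels = labels, nClasses = as.integer(nClasses))
}

#' BinaryMask: one-class foreground indicator
#'
#' Boolean field on a grid; `TRUE` marks foreground for a single class. This
#' is the rater decision object the fusion algorithms consume.
#'
#' @slot grid the [VoxelGrid-class].
#' @slot values 3D logical array.
#' @export
setClass("BinaryMask", contains = "VoxelData", representation(values = "array"))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@values)) return("mask values must be logical")
  if (!identical(dim(object@values), object@grid@shape))
    return("mask dim must equal grid shape")
  if (anyNA(object@values)) return("mask must not contain NA")
  TRUE
})

#' @param values logical 3D array (numeric is coerced with `!= 0`).
#' @param grid a [VoxelGrid-class]; defaults to 1 mm isotropic.
#' @rdname BinaryMask-class
#' @export
BinaryMask <- function(values, grid = NULL) {
  values <- as.array(values)
  if (!is.logical(values)) {
    values <- values != 0
  }
  if (is.null(grid)) grid <- VoxelGrid(dim(values))
  new("BinaryMask", grid = grid, values = values)
}

#' ProbabilityField: per-class soft predictions
#'
#' C probability fields (softmax-style outputs) stored as a 4D array
#' `[i, j, k, class]`; every voxel's class probabilities sum to 1 within 1e-6.
#'
#' @slot grid the [VoxelGrid-class].
#' @slot values 4D numeric array, last dimension = class, values in `[0, 1]`.
#' @export
setClass("ProbabilityField", contains = "VoxelData", representation(values = "array"))

setValidity("ProbabilityField", function(object) {
  d <- dim(object@values)
  if (length(d) != 4L || !identical(d[1:3], object@grid@shape))
    return("values must be a 4D array [grid shape x classes]")
  if (d[4] < 2L) return("need at least 2 classes")
  v <- object@values
  if (anyNA(v) || min(v) < -1e-9 || max(v) > 1 + 1e-9)
    return("probabilities must lie in [0, 1]")
  m <- matrix(v, ncol = d[4])
  if (max(abs(rowSums(m) - 1)) > 1e-6)
    return("per-voxel class probabilities must sum to 1 within 1e-6")
  TRUE
})

#' @param values 4D numeric array `[i, j, k, class]`.
#' @param grid a [VoxelGrid-class]; defaults to 1 mm isotropic.
#' @rdname ProbabilityField-class
#' @export
ProbabilityField <- function(values, grid = NULL) {
  values <- as.array(values)
  if (is.null(grid)) grid <- VoxelGrid(dim(values)[1:3])
  new("ProbabilityField", grid = grid, values = values)
}

#' OneHotField: indicator encoding of a LabelVolume
#'
#' C boolean indicator fields with exactly one class `TRUE` at every voxel;
#' the ground-truth representation the loss functions consume. Built with
#' [oneHotEncode()].
#'
#' @slot grid the [VoxelGrid-class].
#' @slot values 4D logical array, last dimension = class.
#' @export
setClass("OneHotField", contains = "VoxelData", representation(values = "array"))

setValidity("OneHotField", function(object) {
  d <- dim(object@values)
  if (length(d) != 4L || !identical(d[1:3], object@grid@shape))
    return("values must be a 4D logical array [grid shape x classes]")
  if (!is.logical(object@values)) return("indicators must be logical")
  m <- matrix(object@values, ncol = d[4])
  if (any(rowSums(m) != 1L)) return("exactly one class must be TRUE at every voxel")
  TRUE
})

#' RaterSet: ordered binary masks from K raters
#'
#' The raters (trained models, human readers, ...) whose decisions are fused.
#' All masks must share one grid; raters are treated symmetrically by every
#' fusion method.
#'
#' @slot masks list of K [BinaryMask-class] objects on one grid.
#' @slot raterNames character(K).
#' @export
setClass("RaterSet", representation(masks = "list", raterNames = "character"))

setValidity("RaterSet", function(object) {
  if (length(object@masks) < 1L) return("need at least one rater")
  if (!all(vapply(object@masks, is, logical(1), "BinaryMask")))
    return("all elements must be BinaryMask objects")
  if (length(object@raterNames) != length(object@masks))
    return("one name per rater required")
  g <- object@masks[[1]]@grid
  for (m in object@masks[-1]) {
    if (!identical(m@grid@shape, g@shape) ||
        max(abs(m@grid@spacing - g@spacing)) > 1e-4)
      return("all rater masks must share one grid")
  }
  TRUE
})

#' @param masks list of [BinaryMask-class] objects.
#' @param raterNames optional character names; defaults to `rater1..raterK`.
#' @rdname RaterSet-class
#' @export
RaterSet <- function(masks, raterNames = NULL) {
  if (is.null(raterNames)) raterNames <- paste0("rater", seq_along(masks))
  new("RaterSet", masks = masks, raterNames = as.character(raterNames))
}

#' StapleParams: configuration of the STAPLE EM algorithm
#'
#' Defaults follow common practice for model-ensemble fusion: initial
#' sensitivity and specificity 0.9999 for every rater, convergence tolerance
#' 1e-4 on the maximum parameter change, at most 100 iterations.
#'
#' @slot initSensitivity,initSpecificity initial p_j, q_j in (0, 1).
#' @slot tolerance EM stops when every |delta p_j| and |delta q_j| < tolerance.
#' @slot maxIterations iteration cap; `converged = FALSE` if hit.
#' @slot priorMode `"mean_rater_fraction"` (gamma = mean rater foreground
#'   fraction within the ROI, held fixed) or `"fixed"` (use slot `gamma`).
#' @slot gamma foreground prior used when `priorMode = "fixed"`.
#' @slot roiMode `"full_volume"` (sums over every voxel) or `"union_dilated"`
#'   (sums restricted to the union of rater masks dilated by `roiMargin`
#'   face-connected steps; makes specificity informative when the background
#'   dwarfs the foreground).
#' @slot roiMargin dilation margin in voxels for `"union_dilated"`.
#' @export
setClass("StapleParams", representation(
  initSensitivity = "numeric", initSpecificity = "numeric",
  tolerance = "numeric", maxIterations = "integer",
  priorMode = "character", gamma = "numeric",
  roiMode = "character", roiMargin = "integer"))

setValidity("StapleParams", function(object) {
  inOpen <- function(x) length(x) == 1L && is.finite(x) && x > 0 && x < 1
  if (!inOpen(object@initSensitivity) || !inOpen(object@initSpecificity))
    return("initial sensitivity/specificity must lie in (0, 1)")
  if (object@tolerance <= 0) return("tolerance must be positive")
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  if (!object@priorMode %in% c("mean_rater_fraction", "fixed"))
    return("priorMode must be 'mean_rater_fraction' or 'fixed'")
  if (object@priorMode == "fixed" && !inOpen(object@gamma))
    return("fixed prior gamma must lie in (0, 1)")
  if (!object@roiMode %in% c("full_volume", "union_dilated"))
    return("roiMode must be 'full_volume' or 'union_dilated'")
  if (object@roiMode == "union_dilated" && object@roiMargin < 1L)
    return("roiMargin must be >= 1 for union_dilated")
  TRUE
})

#' @param initSensitivity,initSpecificity,tolerance,maxIterations,priorMode,gamma,roiMode,roiMargin
#'   see the slot documentation.
#' @rdname StapleParams-class
#' @export
StapleParams <- function(initSensitivity = 0.9999, initSpecificity = 0.9999,
                         tolerance = 1e-4, maxIterations = 100L,
                         priorMode = c("mean_rater_fraction", "fixed"),
                         gamma = 0.5,
                         roiMode = c("full_volume", "union_dilated"),
                         roiMargin = 3L) {
  new("StapleParams",
      initSensitivity = initSensitivity, initSpecificity = initSpecificity,
      tolerance = tolerance, maxIterations = as.integer(maxIterations),
      priorMode = match.arg(priorMode), gamma = gamma,
      roiMode = match.arg(roiMode), roiMargin = as.integer(roiMargin))
}

#' StapleResult: output of the STAPLE EM fusion
#'
#' Voxelwise consensus weight field W (posterior probability of foreground)
#' together with the estimated per-rater sensitivities p_j and specificities
#' q_j, the foreground prior gamma, and the convergence record. Weights
#' outside the EM ROI are 0. Threshold with [thresholdWeights()].
#'
#' @slot grid the [VoxelGrid-class] of the input raters.
#' @slot weights 3D numeric array of W in `[0, 1]`.
#' @slot sens,spec numeric(K), named by rater.
#' @slot prior foreground prior gamma used in the E-step.
#' @slot iterations EM iterations performed.
#' @slot converged logical; `FALSE` if the iteration cap was hit first.
#' @export
setClass("StapleResult", representation(
  grid = "VoxelGrid", weights = "array",
  sens = "numeric", spec = "numeric", prior = "numeric",
  iterations = "integer", converged = "logical"))

setValidity("StapleResult", function(object) {
  if (!identical(dim(object@weights), object@grid@shape))
    return("weight array dim must equal grid shape")
  w <- range(object@weights)
  if (w[1] < -1e-12 || w[2] > 1 + 1e-12) return("weights must lie in [0, 1]")
  if (any(object@sens < 0 | object@sens > 1) || any(object@spec < 0 | object@spec > 1))
    return("sensitivities/specificities must lie in [0, 1]")
  if (length(object@sens) != length(object@spec))
    return("one sensitivity and one specificity per rater")
  TRUE
})

# ---- accessors -------------------------------------------------------------

#' @rdname grid-accessors
#' @export
setMethod("voxelGrid", "VoxelData", function(x) x@grid)
#' @rdname grid-accessors
#' @export
setMethod("voxelGrid", "StapleResult", function(x) x@grid)
#' @rdname grid-accessors
#' @export
setMethod("voxelGrid", "RaterSet", function(x) x@masks[[1]]@grid)

#' @rdname grid-accessors
#' @export
setMethod("gridShape", "VoxelGrid", function(x) x@shape)
#' @rdname grid-accessors
#' @export
setMethod("gridShape", "ANY", function(x) voxelGrid(x)@shape)
#' @rdname grid-accessors
#' @export
setMethod("gridSpacing", "VoxelGrid", function(x) x@spacing)
#' @rdname grid-accessors
#' @export
setMethod("gridSpacing", "ANY", function(x) voxelGrid(x)@spacing)

#' @rdname grid-accessors
#' @export
setMethod("nClasses", "LabelVolume", function(x) x@nClasses)
#' @rdname grid-accessors
#' @export
setMethod("nClasses", "ProbabilityField", function(x) dim(x@values)[4])
#' @rdname grid-accessors
#' @export
setMethod("nClasses", "OneHotField", function(x) dim(x@values)[4])

#' @rdname LabelVolume-class
#' @export
setMethod("labelArray", "LabelVolume", function(x) x@labels)
#' @rdname BinaryMask-class
#' @export
setMethod("maskArray", "BinaryMask", function(x) x@values)
#' @rdname ProbabilityField-class
#' @export
setMethod("probArray", "ProbabilityField", function(x) x@values)
#' @rdname OneHotField-class
#' @export
setMethod("oneHotArray", "OneHotField", function(x) x@values)

#' @rdname RaterSet-class
#' @export
setMethod("raterMasks", "RaterSet", function(x) x@masks)
#' @rdname RaterSet-class
#' @export
setMethod("raterNames", "RaterSet", function(x) x@raterNames)
#' @rdname RaterSet-class
#' @export
setMethod("nRaters", "RaterSet", function(x) length(x@masks))

#' @rdname StapleResult-class
#' @export
setMethod("stapleWeights", "StapleResult", function(x) x@weights)
#' @rdname StapleResult-class
#' @export
setMethod("sensitivities", "StapleResult", function(x) x@sens)
#' @rdname StapleResult-class
#' @export
setMethod("specificities", "StapleResult", function(x) x@spec)

# ---- show ------------------------------------------------------------------

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid %s voxels @ %s mm\n",
              paste(object@shape, collapse = "x"),
              paste(format(object@spacing, trim = TRUE), collapse = "x")))
})

setMethod("show", "LabelVolume", function(object) {
  tab <- tabulate(as.vector(object@labels) + 1L, nbins = object@nClasses)
  cat(sprintf("LabelVolume %s voxels @ %s mm, C=%d\n",
              paste(object@grid@shape, collapse = "x"),
              paste(format(object@grid@spacing, trim = TRUE), collapse = "x"),
              object@nClasses))
  cat("  class counts:", paste(sprintf("%d=%d", seq_along(tab) - 1L, tab),
                               collapse = ", "), "\n")
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask %s voxels @ %s mm, %d foreground (%.2f%%)\n",
              paste(object@grid@shape, collapse = "x"),
              paste(format(object@grid@spacing, trim = TRUE), collapse = "x"),
              sum(object@values), 100 * mean(object@values)))
})

setMethod("show", "ProbabilityField", function(object) {
  cat(sprintf("ProbabilityField %s voxels @ %s mm, C=%d\n",
              paste(object@grid@shape, collapse = "x"),
              paste(format(object@grid@spacing, trim = TRUE), collapse = "x"),
              dim(object@values)[4]))
})

setMethod("show", "RaterSet", function(object) {
  cat(sprintf("RaterSet of %d raters on %s grid\n", length(object@masks),
              paste(object@masks[[1]]@grid@shape, collapse = "x")))
  fg <- vapply(object@masks, function(m) sum(m@values), numeric(1))
  cat(" ", paste(sprintf("%s: %d fg", object@raterNames, fg), collapse = "; "), "\n")
})

setMethod("show", "StapleResult", function(object) {
  cat(sprintf("StapleResult: %d raters, %d iterations (%s), prior %.4f\n",
              length(object@sens), object@iterations,
              if (object@converged) "converged" else "NOT converged",
              object@prior))
  cat("  sensitivity:", paste(sprintf("%s=%.3f", names(object@sens), object@sens),
                              collapse = ", "), "\n")
  cat("  specificity:", paste(sprintf("%s=%.3f", names(object@spec), object@spec),
                              collapse = ", "), "\n")
})
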