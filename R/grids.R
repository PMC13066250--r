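#' Check that objects share one voxel grid
#'
#' Verifies that all supplied grid-bearing objects (volumes, masks,
#' probability fields, rater sets, STAPLE results, or bare [VoxelGrid-class]
#' objects) have identical shapes and spacings agreeing within 1e-4 mm per
#' axis. Fusion and evaluation never resample: a mismatch is always an error
#' naming the first offending pair.
#'
#' @param ... grid-bearing objects, or a single list of them.
#' @return invisibly `TRUE`; otherwise an error.
#' @export
#' @examples
#' a <- BinaryMask(array(FALSE, c(4, 4, 4)))
#' b <- BinaryMask(array(TRUE, c(4, 4, 4)))
#' checkSameGrid(a, b)
checkSameGrid <- function(...) {
  items <- list(...)
  if (length(items) == 1L && is.list(items[[1]]) && !isVirtualClass(class(items[[1]])))
    items <- items[[1]]
  if (length(items) == 0L) stop("checkSameGrid: empty collection")
  grids <- lapply(items, function(x) if (is(x, "VoxelGrid")) x else voxelGrid(x))
  ref <- grids[[1]]
  for (i in seq_along(grids)[-1]) {
    g <- grids[[i]]
    if (!identical(g@shape, ref@shape))
      stop(sprintf("grid mismatch between items 1 and %d: shape %s vs %s",
                   i, paste(ref@shape, collapse = "x"), paste(g@shape, collapse = "x")))
    if (max(abs(g@spacing - ref@spacing)) > 1e-4)
      stop(sprintf("grid mismatch between items 1 and %d: spacing (%s) vs (%s) mm",
                   i, paste(format(ref@spacing), collapse = ", "),
                   paste(format(g@spacing), collapse = ", ")))
  }
  invisible(TRUE)
}

#' One-hot encode a label volume
#'
#' Expands integer labels into C boolean indicator fields g_ic, the
#' ground-truth representation the loss functions consume. Exactly one class
#' is `TRUE` at every voxel; `argmax` of the result recovers the input.
#'
#' @param v a [LabelVolume-class].
#' @return a [OneHotField-class] with `nClasses(v)` indicator fields.
#' @export
oneHotEncode <- function(v) {
  stopifnot(is(v, "LabelVolume"))
  C <- v@nClasses
  d <- v@grid@shape
  out <- array(FALSE, c(d, C))
  lab <- as.vector(v@labels)
  n <- length(lab)
  out[seq_len(n) + n * as.numeric(lab)] <- TRUE
  new("OneHotField", grid = v@grid, values = out)
}

#' Extract one class as a binary mask
#'
#' Per-class binarization before fusion: `TRUE` exactly where
#' `labels == classId`. Over all classes the extracted masks partition the
#' volume.
#'
#' @param v a [LabelVolume-class].
#' @param classId class index in `[0, C-1]` (0 = background).
#' @return a [BinaryMask-class].
#' @export
extractClassMask <- function(v, classId) {
  stopifnot(is(v, "LabelVolume"))
  classId <- as.integer(classId)
  if (classId < 0L || classId >= v@nClasses)
    stop(sprintf("classId %d out of range [0, %d]", classId, v@nClasses - 1L))
  new("BinaryMask", grid = v@grid, values = v@labels == classId)
}
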