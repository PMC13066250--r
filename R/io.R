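# NIfTI readers and writers (RNifti). Label volumes are stored with integer
# datatypes, probability fields as floating 4D volumes (one sub-volume per
# class). Voxel spacing comes from the header pixdim; orientation codes are
# recorded on read and must agree across the volumes of one run -- nothing
# is ever silently reoriented or resampled.

#' Read a label volume from NIfTI
#'
#' Rejects non-integer-valued data (a probability map passed where labels are
#' expected is a configuration error, not something to round over). The
#' header orientation code is recorded in the `"orientation"` attribute so
#' callers can verify consistency across the files of a run (see
#' [readRaterSet()]).
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param nClasses declared class count; defaults to `max(label) + 1` (at
#'   least 2). Labels above `nClasses - 1` are an error.
#' @return a [LabelVolume-class] with attribute `orientation`.
#' @export
readLabelVolume <- function(path, nClasses = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim(img))  # plain array, no image class
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) {
    arr <- array(arr, d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop(sprintf("'%s': expected a 3D label volume, got %dD", path, length(d)))
  if (anyNA(arr) || any(arr != round(arr)))
    stop(sprintf("'%s': non-integer voxel values; not a label volume", path))
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(spacing <= 0)) stop(sprintf("'%s': non-positive pixdim", path))
  storage.mode(arr) <- "integer"
  if (is.null(nClasses)) nClasses <- max(2L, max(arr) + 1L)
  if (max(arr) >= nClasses)
    stop(sprintf("'%s': label %d exceeds declared class count %d",
                 path, max(arr), nClasses))
  v <- new("LabelVolume", grid = VoxelGrid(d, spacing), labels = arr,
           nClasses = as.integer(nClasses))
  attr(v, "orientation") <- RNifti::orientation(img)
  v
}

#' Read a binary mask from NIfTI
#'
#' A label volume restricted to values 0/1.
#'
#' @param path NIfTI file.
#' @return a [BinaryMask-class] with attribute `orientation`.
#' @export
readBinaryMask <- function(path) {
  v <- readLabelVolume(path, nClasses = 2L)
  m <- new("BinaryMask", grid = v@grid, values = v@labels == 1L)
  attr(m, "orientation") <- attr(v, "orientation")
  m
}

#' Write a label volume (or mask) to NIfTI
#'
#' Integer datatype (`int16`), spacing written to the header pixdim;
#' round-trip safe with [readLabelVolume()].
#'
#' @param v a [LabelVolume-class] or [BinaryMask-class].
#' @param path output file (`.nii` / `.nii.gz`).
#' @return invisibly `path`.
#' @export
writeLabelVolume <- function(v, path) {
  arr <- if (is(v, "BinaryMask")) {
    a <- array(0L, gridShape(v)); a[v@values] <- 1L; a
  } else if (is(v, "LabelVolume")) {
    v@labels
  } else stop("writeLabelVolume: need a LabelVolume or BinaryMask")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- gridSpacing(v)
  # give the header a coded scanner-anatomical sform so orientation is defined
  RNifti::sform(img) <- structure(diag(c(gridSpacing(v), 1)), code = 1L)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read a set of rater masks, enforcing header consistency
#'
#' Reads K mask files and errors if any pair disagrees in grid shape,
#' spacing, or orientation code — mixed orientations in one run would make
#' voxelwise fusion silently wrong, so they are refused rather than fixed.
#'
#' @param paths character vector of NIfTI files.
#' @param raterNames optional rater names (default: file base names).
#' @return a [RaterSet-class].
#' @export
readRaterSet <- function(paths, raterNames = NULL) {
  if (length(paths) < 1L) stop("readRaterSet: need at least one file")
  masks <- lapply(paths, readBinaryMask)
  orients <- vapply(masks, function(m) attr(m, "orientation"), character(1))
  if (length(unique(orients)) > 1L) {
    bad <- which(orients != orients[1])[1]
    stop(sprintf("orientation mismatch: '%s' is %s but '%s' is %s; reorient inputs explicitly before fusing",
                 paths[1], orients[1], paths[bad], orients[bad]))
  }
  checkSameGrid(masks)
  if (is.null(raterNames))
    raterNames <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  RaterSet(masks, raterNames)
}

#' Read a probability field from NIfTI
#'
#' Accepts either one 4D floating volume (classes along the 4th dimension)
#' or several 3D per-class volumes.
#'
#' @param paths one 4D file, or a vector of per-class 3D files.
#' @return a [ProbabilityField-class].
#' @export
readProbabilityField <- function(paths) {
  if (length(paths) == 1L) {
    img <- RNifti::readNifti(paths)
    arr <- array(as.vector(img), dim(img))
    if (length(dim(arr)) != 4L)
      stop(sprintf("'%s': expected a 4D probability volume", paths))
    spacing <- RNifti::pixdim(img)[1:3]
  } else {
    vols <- lapply(paths, function(p) {
      img <- RNifti::readNifti(p)
      list(arr = array(as.vector(img), dim(img)),
           spacing = RNifti::pixdim(img)[1:3])
    })
    d <- dim(vols[[1]]$arr)
    arr <- array(0, c(d, length(vols)))
    for (k in seq_along(vols)) {
      if (!identical(dim(vols[[k]]$arr), d))
        stop("per-class volumes disagree in shape")
      arr[, , , k] <- vols[[k]]$arr
    }
    spacing <- vols[[1]]$spacing
  }
  ProbabilityField(arr, VoxelGrid(dim(arr)[1:3], spacing))
}

#' Write a probability field to a 4D floating NIfTI
#'
#' @param pf a [ProbabilityField-class].
#' @param path output file.
#' @return invisibly `path`.
#' @export
writeProbabilityField <- function(pf, path) {
  stopifnot(is(pf, "ProbabilityField"))
  img <- RNifti::asNifti(pf@values)
  RNifti::pixdim(img) <- c(gridSpacing(pf), 1)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write a STAPLE weight field to a floating NIfTI
#'
#' @param r a [StapleResult-class].
#' @param path output file.
#' @return invisibly `path`.
#' @export
writeWeightVolume <- function(r, path) {
  stopifnot(is(r, "StapleResult"))
  img <- RNifti::asNifti(r@weights)
  RNifti::pixdim(img) <- gridSpacing(r)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}
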