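#' Accessors for voxel-grid data objects
#'
#' Every spatial object in the package carries a [VoxelGrid-class] describing
#' its discrete geometry. These generics expose the grid, its shape (voxels per
#' axis) and spacing (mm per voxel), and the underlying payload arrays.
#'
#' @param x an object carrying a voxel grid.
#' @return `voxelGrid` returns a [VoxelGrid-class]; `gridShape` an integer
#'   vector of length 3; `gridSpacing` a numeric vector of length 3 (mm).
#' @name grid-accessors
#' @aliases voxelGrid gridShape gridSpacing
#' @examples
#' g <- VoxelGrid(c(8, 8, 4), c(1, 1, 3))
#' gridShape(g)
#' gridSpacing(g)
NULL

#' @rdname grid-accessors
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))

#' @rdname grid-accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname grid-accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname grid-accessors
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' @param x a [LabelVolume-class].
#' @rdname LabelVolume-class
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))

#' @param x a [BinaryMask-class].
#' @rdname BinaryMask-class
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @param x a [ProbabilityField-class].
#' @rdname ProbabilityField-class
#' @export
setGeneric("probArray", function(x) standardGeneric("probArray"))

#' @param x a [OneHotField-class].
#' @rdname OneHotField-class
#' @export
setGeneric("oneHotArray", function(x) standardGeneric("oneHotArray"))

#' @param x a [RaterSet-class].
#' @rdname RaterSet-class
#' @export
setGeneric("raterMasks", function(x) standardGeneric("raterMasks"))

#' @rdname RaterSet-class
#' @export
setGeneric("raterNames", function(x) standardGeneric("raterNames"))

#' @rdname RaterSet-class
#' @export
setGeneric("nRaters", function(x) standardGeneric("nRaters"))

#' @param x a [StapleResult-class].
#' @rdname StapleResult-class
#' @export
setGeneric("stapleWeights", function(x) standardGeneric("stapleWeights"))

#' @rdname StapleResult-class
#' @export
setGeneric("sensitivities", function(x) standardGeneric("sensitivities"))

#' @rdname StapleResult-class
#' @export
setGeneric("specificities", function(x) standardGeneric("specificities"))
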