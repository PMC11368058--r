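#' Pixel matrix of an image or mask object
#' @param x a GraySlice or LesionMask
#' @return numeric matrix
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "GraySlice", function(x) x@pixels)

#' @rdname pixels
#' @export
setMethod("pixels", "LesionMask", function(x) x@pixels)

#' Pixel spacing in millimetres
#' @param x a GraySlice or LesionMask
#' @return numeric(1), mm per pixel
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname spacing
#' @export
setMethod("spacing", "GraySlice", function(x) x@spacing)

#' @rdname spacing
#' @export
setMethod("spacing", "LesionMask", function(x) x@spacing)

#' Mirror an image or mask about its vertical midline
#'
#' Left-right (horizontal) flip, i.e. column reversal. This is an
#' involution: \code{horizontalFlip(horizontalFlip(x))} returns \code{x}
#' unchanged. On axial brain slices it maps each hemisphere onto the other,
#' which is the symmetry the refinement generator exploits.
#'
#' @param x a GraySlice, LesionMask, matrix or 3-D array (H x W x C)
#' @return an object of the same class with columns reversed
#' @export
setGeneric("horizontalFlip", function(x) standardGeneric("horizontalFlip"))

#' Number of outside (context) patches in a PatchSet
#' @param x a PatchSet
#' @return integer count of patches labelled outside the mask
#' @export
setGeneric("nOutside", function(x) standardGeneric("nOutside"))

#' @rdname nOutside
#' @export
setMethod("nOutside", "PatchSet", function(x) sum(!x@inside))
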