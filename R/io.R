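#' Read a 2-D grayscale PNG as a GraySlice
#'
#' PNG values (stored in [0, 1]) are linearly rescaled to the package's
#' [-1, 1] intensity convention. Multi-channel files are collapsed to
#' grayscale by channel averaging.
#'
#' @param path PNG file path
#' @param spacing mm per pixel to attach, default 1
#' @return a \linkS4class{GraySlice}
#' @export
readSlicePNG <- function(path, spacing = 1) {
  if (!file.exists(path)) stop("readSlicePNG: file not found: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3L, dim(a)[3L]), drop = FALSE],
                                       c(1, 2), mean)
  GraySlice(a * 2 - 1, spacing)
}

#' Write a GraySlice as a grayscale PNG
#'
#' Intensities are mapped from [-1, 1] back to [0, 1] storage.
#'
#' @param img a \linkS4class{GraySlice}
#' @param path output PNG path
#' @return the path, invisibly
#' @export
writeSlicePNG <- function(img, path) {
  stopifnot(is(img, "GraySlice"))
  png::writePNG((img@pixels + 1) / 2, target = path)
  invisible(path)
}

#' Read a PNG as a binary LesionMask
#'
#' Any nonzero pixel collapses to 1.
#'
#' @param path PNG file path
#' @param spacing mm per pixel, default 1
#' @return a \linkS4class{LesionMask}
#' @export
readMaskPNG <- function(path, spacing = 1) {
  if (!file.exists(path)) stop("readMaskPNG: file not found: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  LesionMask(a > 1e-6, spacing)
}

#' Write a LesionMask as a PNG
#' @param mask a \linkS4class{LesionMask}
#' @param path output PNG path
#' @return the path, invisibly
#' @export
writeMaskPNG <- function(mask, path) {
  stopifnot(is(mask, "LesionMask"))
  png::writePNG(mask@pixels, target = path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path .nii or .nii.gz file
#' @return list with \code{data} (3-D array) and \code{spacing} (mm per
#'   pixel in-plane, from the header pixdim)
#' @export
readNiftiVolume <- function(path) {
  if (!file.exists(path)) stop("readNiftiVolume: file not found: ", path)
  v <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(v)
  sp <- if (length(pd) >= 1 && is.finite(pd[1]) && pd[1] > 0) pd[1] else 1
  list(data = unclass(v)[, , , drop = FALSE], spacing = sp)
}

#' Extract axial GraySlice stacks from a NIfTI volume
#'
#' Each axial plane is normalized independently to [-1, 1].
#'
#' @param path NIfTI file path
#' @return list of \linkS4class{GraySlice} objects, one per axial plane
#' @export
readNiftiSlices <- function(path) {
  v <- readNiftiVolume(path)
  lapply(seq_len(dim(v$data)[3L]), function(k)
    normalizeIntensity(v$data[, , k], spacing = v$spacing))
}

#' Extract axial LesionMask stacks from a NIfTI label volume
#'
#' Any nonzero label (e.g. all tumour subregion labels) collapses to 1.
#'
#' @param path NIfTI label volume path
#' @return list of \linkS4class{LesionMask} objects, one per axial plane
#' @export
readNiftiMaskSlices <- function(path) {
  v <- readNiftiVolume(path)
  lapply(seq_len(dim(v$data)[3L]), function(k)
    LesionMask(v$data[, , k] != 0, spacing = v$spacing))
}
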