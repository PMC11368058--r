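#' @import methods
NULL

#' GraySlice: a 2-D grayscale image slice
#'
#' Container for a single 2-D grayscale slice with isotropic pixel spacing.
#' Pixel values are stored in the normalized intensity range \eqn{[-1, 1]};
#' the darkest value (-1) is the background convention for skull-stripped
#' data. Rows index the vertical (anterior-posterior on axial brain slices)
#' and columns the horizontal (left-right) axis; horizontal flips mirror
#' about the vertical midline.
#'
#' @slot pixels numeric matrix, values in [-1, 1].
#' @slot spacing numeric(1), millimetres per pixel (isotropic).
#' @export
setClass("GraySlice",
  representation(pixels = "matrix", spacing = "numeric"),
  prototype(pixels = matrix(-1, 1, 1), spacing = 1))

setValidity("GraySlice", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (nrow(p) < 1L || ncol(p) < 1L) return("height and width must be positive")
  if (any(!is.finite(p))) return("pixels must be finite")
  if (min(p) < -1 - 1e-9 || max(p) > 1 + 1e-9)
    return("pixel values must lie in [-1, 1]; use normalizeIntensity()")
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0)
    return("spacing must be a single positive number (mm per pixel)")
  TRUE
})

#' LesionMask: a binary 2-D lesion/missing-region mask
#'
#' Binary mask paired with a \linkS4class{GraySlice}. Value 1 marks lesion
#' (or missing/to-be-filled) pixels, 0 marks background/healthy pixels.
#'
#' @slot pixels numeric matrix with values in {0, 1}.
#' @slot spacing numeric(1), millimetres per pixel.
#' @export
setClass("LesionMask",
  representation(pixels = "matrix", spacing = "numeric"),
  prototype(pixels = matrix(0, 1, 1), spacing = 1))

setValidity("LesionMask", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (nrow(p) < 1L || ncol(p) < 1L) return("height and width must be positive")
  if (!all(p %in% c(0, 1))) return("mask values must be 0 or 1")
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0)
    return("spacing must be a single positive number (mm per pixel)")
  TRUE
})

#' PatchSet: a non-overlapping tiling of a feature map into square patches
#'
#' Patches are taken in raster order (left to right, then top to bottom) and
#' stored as flattened columns of a matrix. Each patch is labelled inside if
#' at least one of its pixels is masked, otherwise outside; only outside
#' patches serve as attention context.
#'
#' @slot patches numeric matrix, one flattened patch per column
#'   (length patchSize^2 * channels).
#' @slot patchSize integer(1), patch side length in pixels.
#' @slot inside logical vector, one flag per patch (TRUE = inside mask).
#' @slot gridDim integer(2), patch-grid rows and columns.
#' @slot featDim integer(3), height, width, channels of the tiled map.
#' @export
setClass("PatchSet",
  representation(patches = "matrix", patchSize = "integer",
                 inside = "logical", gridDim = "integer",
                 featDim = "integer"))

setValidity("PatchSet", function(object) {
  np <- prod(object@gridDim)
  if (ncol(object@patches) != np) return("patch count must equal grid size")
  if (length(object@inside) != np) return("one inside label per patch")
  if (nrow(object@patches) !=
      object@patchSize^2 * object@featDim[3L])
    return("patch rows must equal patchSize^2 * channels")
  TRUE
})

#' AttentionMatrix: all-pairs patch affinities and attention scores
#'
#' Stores the raw cosine affinities between every pair of patches and the
#' squared-and-normalized attention scores. Scores are column-stochastic
#' over the outside (context) patches: rows are source (outside) patches,
#' columns are target patches; rows corresponding to inside patches are
#' zero so that no lesion pixel ever serves as context.
#'
#' @slot affinity numeric matrix (n x n), cosine similarities.
#' @slot scores numeric matrix (n x n), squared-normalized scores.
#' @slot inside logical vector, patch labels the scores were built from.
#' @slot orientation character(1), "PIAS" (forward path) or "FIAS"
#'   (flipped path).
#' @export
setClass("AttentionMatrix",
  representation(affinity = "matrix", scores = "matrix",
                 inside = "logical", orientation = "character"))

setValidity("AttentionMatrix", function(object) {
  n <- length(object@inside)
  if (!all(dim(object@affinity) == c(n, n))) return("affinity must be n x n")
  if (!all(dim(object@scores) == c(n, n))) return("scores must be n x n")
  if (min(object@scores) < 0) return("scores must be nonnegative")
  if (!object@orientation %in% c("PIAS", "FIAS"))
    return("orientation must be PIAS or FIAS")
  TRUE
})

#' MetricReport: evaluation summary for a synthesis run
#'
#' @slot healthiness numeric(1), 1 minus the ratio of pathological pixel
#'   counts found in outputs vs inputs (1 = no residual pathology).
#' @slot mpsnr numeric(1), masked PSNR in dB outside the lesion mask.
#' @slot mssim numeric(1), masked SSIM outside the lesion mask.
#' @slot sh numeric(1), structure healthiness in [0, 1] (NA if not computed).
#' @slot nImages integer(1), number of evaluated images.
#' @slot nLargeLesion integer(1), number of large-lesion images behind sh.
#' @export
setClass("MetricReport",
  representation(healthiness = "numeric", mpsnr = "numeric",
                 mssim = "numeric", sh = "numeric",
                 nImages = "integer", nLargeLesion = "integer"),
  prototype(healthiness = NA_real_, mpsnr = NA_real_, mssim = NA_real_,
            sh = NA_real_, nImages = 0L, nLargeLesion = 0L))

setValidity("MetricReport", function(object) {
  if (!is.na(object@sh) && (object@sh < 0 || object@sh > 1))
    return("sh must lie in [0, 1]")
  if (!is.na(object@mssim) && object@mssim > 1 + 1e-9)
    return("mssim cannot exceed 1")
  TRUE
})

# ---- model containers ------------------------------------------------------

#' Virtual parent of all trainable conv-net models in the package
#'
#' @slot params named list of numeric arrays (weights and biases).
#' @slot config named list of architecture hyperparameters.
#' @export
setClass("ConvNetModel",
  representation("VIRTUAL", params = "list", config = "list"))

#' SegmentorModel: a U-Net lesion segmentor
#'
#' Encoder-decoder U-Net with skip connections producing a sigmoid
#' probability map, thresholded to a binary lesion mask.
#'
#' @slot threshold numeric(1), decision threshold in (0, 1).
#' @export
setClass("SegmentorModel", contains = "ConvNetModel",
  representation(threshold = "numeric"),
  prototype(threshold = 0.5))

setValidity("SegmentorModel", function(object) {
  if (object@threshold <= 0 || object@threshold >= 1)
    return("threshold must lie in (0, 1)")
  TRUE
})

#' VagueFillerModel: stage-2 coarse inpainting network
#'
#' Straight-line residual chain of gated convolutions operating at H/4
#' resolution, without skip connections; trained with L1 loss only.
#' @export
setClass("VagueFillerModel", contains = "ConvNetModel")

#' GeneratorModel: stage-3 flip-symmetric refinement generator
#'
#' Dual-path encoder (shared weights on the image and its horizontal flip),
#' contextual attention (ACM/ATM) at the deepest feature level, channel
#' fusion, decoder, and full-resolution contextual residual aggregation.
#' Ablation switches useCra/useFlip select the plain, +CRA and +CRA+FLIP
#' configurations.
#' @export
setClass("GeneratorModel", contains = "ConvNetModel")

setValidity("GeneratorModel", function(object) {
  cfg <- object@config
  if (isTRUE(cfg$useFlip) && !isTRUE(cfg$useCra))
    return("useFlip requires useCra (the flip path feeds the attention fusion)")
  TRUE
})

#' DiscriminatorModel: spectral-normalized hinge discriminator
#'
#' Strided convolutional score map, mean-reduced to a scalar score.
#' @export
setClass("DiscriminatorModel", contains = "ConvNetModel")

#' FeatureExtractor: fixed feature extractor for the perceptual loss
#'
#' Parameters are frozen; the default backbone is a deterministic
#' randomly-initialized conv net ("random-fixed") so the package is
#' self-contained. A pretrained VGG16 can be plugged in through the same
#' interface when its weights are available.
#' @export
setClass("FeatureExtractor", contains = "ConvNetModel")

#' EdgeClassifier: binary deformation classifier on Canny edge maps
#'
#' Small VGG-style conv net whose sigmoid output is the probability that an
#' edge map is free of deformations.
#' @export
setClass("EdgeClassifier", contains = "ConvNetModel")

# ---- show methods ----------------------------------------------------------

setMethod("show", "GraySlice", function(object) {
  cat(sprintf("GraySlice %dx%d, spacing %.3g mm, range [%.3f, %.3f]\n",
              nrow(object@pixels), ncol(object@pixels), object@spacing,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "LesionMask", function(object) {
  cat(sprintf("LesionMask %dx%d, spacing %.3g mm, %d masked px (%.1f%%)\n",
              nrow(object@pixels), ncol(object@pixels), object@spacing,
              sum(object@pixels), 100 * mean(object@pixels)))
})

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet: %d patches of %dx%d (%d channels), %d outside / %d inside\n",
              ncol(object@patches), object@patchSize, object@patchSize,
              object@featDim[3L], sum(!object@inside), sum(object@inside)))
})

setMethod("show", "AttentionMatrix", function(object) {
  cat(sprintf("AttentionMatrix (%s): %d x %d, %d context patches\n",
              object@orientation, nrow(object@scores), ncol(object@scores),
              sum(!object@inside)))
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport\n")
  cat(sprintf("  healthiness (H): %s\n", format(object@healthiness)))
  cat(sprintf("  masked PSNR (MP): %s dB\n", format(object@mpsnr)))
  cat(sprintf("  masked SSIM (MS): %s\n", format(object@mssim)))
  cat(sprintf("  structure healthiness (SH): %s  [n large-lesion = %d]\n",
              format(object@sh), object@nLargeLesion))
  cat(sprintf("  images evaluated: %d\n", object@nImages))
})

setMethod("show", "ConvNetModel", function(object) {
  npar <- sum(vapply(object@params, length, 1L))
  cat(sprintf("%s: %d parameter arrays, %d parameters\n",
              class(object), length(object@params), npar))
})
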