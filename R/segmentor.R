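# Stage 1: lesion localization. A U-Net trained with pixel-wise binary
# cross-entropy, or manual annotations loaded from file; plus the
# 5 mm-margin mask preparation used by the later stages.

.sliceBatch <- function(slices, idx) {
  .stackBatch(lapply(idx, function(i)
    if (is(slices[[i]], "GraySlice") || is(slices[[i]], "LesionMask"))
      slices[[i]]@pixels else slices[[i]]))
}

#' Train a U-Net lesion segmentor
#'
#' Standard encoder-decoder U-Net with skip connections, trained with
#' pixel-wise binary cross-entropy and Adam. The model with the best
#' validation Dice seen during training is returned. Deterministic under a
#' fixed seed.
#'
#' @param images list of \linkS4class{GraySlice}
#' @param masks list of \linkS4class{LesionMask}, paired with images
#' @param config list of options: \code{epochs} (default 20), \code{batch}
#'   (4), \code{lr} (1e-3), \code{lrHalveEvery} (5 epochs),
#'   \code{baseWidth} (32), \code{depth} (4), \code{seed} (1),
#'   \code{valFraction} (0.2), \code{threshold} (0.5), \code{evalEvery}
#'   (evaluate validation Dice every this many steps; default 25)
#' @return a trained \linkS4class{SegmentorModel}
#' @export
trainUnet <- function(images, masks, config = list()) {
  if (length(images) != length(masks))
    stop("trainUnet: images and masks must be paired lists of equal length")
  if (length(images) < 1L) stop("trainUnet: need at least one pair")
  if (all(vapply(masks, function(m) sum(m@pixels), 1) == 0))
    stop("trainUnet: all masks are empty; nothing to learn")
  cfg <- modifyList(list(epochs = 20L, batch = 4L, lr = 1e-3,
                         lrHalveEvery = 5L, baseWidth = 32L, depth = 4L,
                         seed = 1L, valFraction = 0.2, threshold = 0.5,
                         evalEvery = 25L), config)
  n <- length(images)
  model <- buildUnet(cfg$baseWidth, cfg$depth, 1L, seed = cfg$seed)
  params <- model@params
  mcfg <- model@config
  nval <- if (n >= 5L) max(1L, floor(cfg$valFraction * n)) else 0L
  ord <- .withSeed(cfg$seed + 1L, sample.int(n))
  valIdx <- if (nval > 0L) ord[seq_len(nval)] else integer(0)
  trIdx <- setdiff(ord, valIdx)
  if (length(trIdx) == 0L) { trIdx <- ord; valIdx <- integer(0) }
  batch <- min(cfg$batch, length(trIdx))
  stepsPerEpoch <- max(1L, ceiling(length(trIdx) / batch))
  nsteps <- cfg$epochs * stepsPerEpoch
  st <- .adamInit(params)
  best <- list(params = params, dice = -Inf)
  valDice <- function(p) {
    if (length(valIdx) == 0L) return(NA_real_)
    ds <- vapply(valIdx, function(i) {
      z <- .unetForward(p, mcfg, .sliceBatch(images, i), needCache = FALSE)$logits
      pr <- .sigmoidF(z[, , 1L, 1L]) >= cfg$threshold
      diceScore(pr * 1, masks[[i]]@pixels)
    }, 1)
    mean(ds)
  }
  .withSeed(cfg$seed + 2L, {
    for (step in seq_len(nsteps)) {
      epoch <- (step - 1L) %/% stepsPerEpoch
      lr <- lrSchedule(cfg$lr, epoch, cfg$lrHalveEvery)
      bi <- trIdx[sample.int(length(trIdx), batch,
                             replace = batch > length(trIdx))]
      x <- .sliceBatch(images, bi)
      y <- .sliceBatch(masks, bi)
      fw <- .unetForward(params, mcfg, x)
      l <- .bceWithLogits(fw$logits, y)
      gr <- .unetBackward(l$grad, fw$cache)
      upd <- .adamStep(params, gr, st, lr)
      params <- upd$params; st <- upd$state
      if (length(valIdx) > 0L &&
          (step %% cfg$evalEvery == 0L || step == nsteps)) {
        d <- valDice(params)
        if (d > best$dice) best <- list(params = params, dice = d)
      }
    }
  })
  if (length(valIdx) == 0L) best <- list(params = params, dice = NA_real_)
  new("SegmentorModel", params = best$params,
      config = c(mcfg[setdiff(names(mcfg), "trained")],
                 list(trained = TRUE, valDice = best$dice)),
      threshold = cfg$threshold)
}

#' Predict a binary lesion mask for a slice
#'
#' The sigmoid probability map is thresholded at the model's decision
#' threshold. Inputs whose dims do not divide by 2^depth are bilinearly
#' resized up for the forward pass and the mask is resized back with
#' nearest-neighbour interpolation, so the output shape always equals the
#' input shape.
#'
#' @param model a \linkS4class{SegmentorModel}
#' @param img a \linkS4class{GraySlice}
#' @return a \linkS4class{LesionMask}
#' @export
predictLesionMask <- function(model, img) {
  stopifnot(is(model, "SegmentorModel"), is(img, "GraySlice"))
  p <- img@pixels
  mult <- 2L^model@config$depth
  h <- nrow(p); w <- ncol(p)
  h2 <- as.integer(ceiling(h / mult) * mult)
  w2 <- as.integer(ceiling(w / mult) * mult)
  pr <- if (h2 != h || w2 != w) .resizeBilinear(p, h2, w2) else p
  z <- .unetForward(model@params, model@config,
                    array(pr, c(h2, w2, 1L, 1L)), needCache = FALSE)$logits
  prob <- .sigmoidF(z[, , 1L, 1L])
  m <- (prob >= model@threshold) * 1
  if (h2 != h || w2 != w) m <- .resizeNearest(m, h, w)
  LesionMask(m, img@spacing)
}

#' Prepare the inference mask: add the 5 mm safety margin
#'
#' Dilates the predicted (or manually annotated) lesion mask by
#' \code{margin_mm}; the dilated mask drives the coarse filler, the
#' refinement generator and the final compositing, so the lesion and its
#' adjacent margin are replaced while everything else is preserved.
#'
#' @param mask a \linkS4class{LesionMask}
#' @param margin_mm margin in millimetres, default 5
#' @return a \linkS4class{LesionMask} containing the input mask
#' @export
prepareInferenceMask <- function(mask, margin_mm = 5) {
  dilateMask(mask, margin_mm)
}

#' Load a manual pixel-level annotation as a LesionMask
#'
#' Accepts PNG or NIfTI (a single plane or a volume plus \code{slice}).
#' Nonzero labels collapse to 1; if \code{targetShape} differs from the
#' stored shape the mask is resized with nearest-neighbour interpolation
#' (set \code{resize = FALSE} to make a shape mismatch an error).
#'
#' @param path annotation file (.png, .nii, .nii.gz)
#' @param targetShape integer(2) required (rows, cols), or NULL to keep
#' @param slice axial plane to take from a NIfTI volume (default 1)
#' @param resize allow nearest-neighbour resizing, default TRUE
#' @param spacing mm per pixel for the returned mask
#' @return a \linkS4class{LesionMask}
#' @export
loadManualAnnotation <- function(path, targetShape = NULL, slice = 1L,
                                 resize = TRUE, spacing = 1) {
  if (!file.exists(path)) stop("loadManualAnnotation: file not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    m <- (a > 1e-6) * 1
  } else {
    v <- readNiftiVolume(path)
    if (slice > dim(v$data)[3L]) stop("loadManualAnnotation: slice out of range")
    m <- (v$data[, , slice] != 0) * 1
    spacing <- v$spacing
  }
  if (any(!is.finite(m))) stop("loadManualAnnotation: annotation contains NaN")
  if (!is.null(targetShape) && !all(dim(m) == targetShape)) {
    if (!resize)
      stop("loadManualAnnotation: shape ", paste(dim(m), collapse = "x"),
           " does not match target ", paste(targetShape, collapse = "x"))
    m <- .resizeNearest(m, targetShape[1L], targetShape[2L])
  }
  LesionMask(m, spacing)
}

#' Save a model checkpoint
#'
#' Single-file archive holding the class, architecture config, parameters
#' and threshold.
#'
#' @param model any \linkS4class{ConvNetModel}
#' @param path output file
#' @return the path, invisibly
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "ConvNetModel"))
  obj <- list(class = class(model)[1L], params = model@params,
              config = model@config,
              threshold = if (.hasSlot(model, "threshold"))
                model@threshold else NULL)
  saveRDS(obj, path)
  invisible(path)
}

.hasSlot <- function(x, nm) nm %in% slotNames(class(x))

#' Load a model checkpoint written by \code{\link{saveCheckpoint}}
#' @param path checkpoint file
#' @return the restored model object
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("loadCheckpoint: file not found: ", path)
  obj <- readRDS(path)
  if (obj$class == "SegmentorModel")
    new(obj$class, params = obj$params, config = obj$config,
        threshold = obj$threshold)
  else
    new(obj$class, params = obj$params, config = obj$config)
}
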