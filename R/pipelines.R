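# Training (healthy images + random masks) and inference (pathological
# images) pipelines, plus the dataset slicing rules.

#' Learning rate at a given epoch
#'
#' All trainable stages share the same schedule: the initial rate is
#' halved every \code{halveEvery} epochs (0.001, 0.0005 from epoch 5,
#' 0.00025 from epoch 10, ...).
#'
#' @param lr0 initial learning rate, default 0.001
#' @param epoch zero-based epoch index
#' @param halveEvery epochs between halvings, default 5
#' @return numeric(1)
#' @export
lrSchedule <- function(lr0 = 0.001, epoch = 0L, halveEvery = 5L) {
  lr0 * 0.5^(epoch %/% halveEvery)
}

#' Default batch size for a slice geometry
#'
#' 16 for slices up to 256 px (the 240 x 240 brain geometry), 4 for larger
#' slices (the 512 x 512 CT geometry).
#'
#' @param dims integer(2) slice dims
#' @return integer batch size
#' @export
defaultBatchSize <- function(dims) {
  if (max(dims) >= 512L) 4L else 16L
}

#' Train the full synthesis model on healthy slices
#'
#' Two-phase schedule. Phase A trains the coarse filler alone with L1 loss
#' on freshly masked healthy slices. Phase B freezes the filler and trains
#' the refinement generator adversarially against a spectral-normalized
#' hinge discriminator, with the perceptual term (weight \code{lambda})
#' anchoring the output to the original healthy slice. Masks are sampled
#' per step covering 30-60\% of each slice's foreground; intensities are
#' in [-1, 1]; mask value 1 marks the missing region. Adam with initial
#' learning rate 0.001 halved every 5 epochs.
#'
#' Training uses healthy images only: if ground-truth lesion masks are
#' supplied alongside the slices and any is nonempty, the loader refuses
#' the data.
#'
#' @param healthy list of healthy \linkS4class{GraySlice}s
#' @param config list: \code{stepsV}/\code{stepsG} (step counts; if absent,
#'   \code{epochsV}/\code{epochsG} with defaults 10/10 are used),
#'   \code{batch} (defaultBatchSize of the slice dims), \code{lr} (1e-3),
#'   \code{lrHalveEvery} (5), \code{ratioRange} (c(0.30, 0.60)),
#'   \code{lambda} (64), \code{fillerWidths}, \code{genWidth},
#'   \code{discWidth}, \code{patchSize} (16), \code{useCra}/\code{useFlip}
#'   (TRUE), \code{seed} (1), \code{pretrainedV} (optional trained
#'   \linkS4class{VagueFillerModel}: phase A is skipped, e.g. to hold
#'   stage 2 fixed across ablation arms)
#' @param gtMasks optional list of ground-truth \linkS4class{LesionMask}s
#'   accompanying the slices; any nonempty mask raises an error
#' @return list with \code{V}, \code{G}, \code{D} (trained models) and
#'   \code{history} (data.frame: step, phase, l1, d_loss, g_adv,
#'   perceptual, total)
#' @export
trainPseudoHealthy <- function(healthy, config = list(), gtMasks = NULL) {
  if (length(healthy) < 1L) stop("trainPseudoHealthy: no training slices")
  if (!is.null(gtMasks) &&
      any(vapply(gtMasks, function(m) sum(m@pixels) > 0, TRUE)))
    stop("trainPseudoHealthy: training expects healthy images only; ",
         "a nonempty ground-truth lesion mask was supplied")
  dims <- dim(healthy[[1L]]@pixels)
  cfg <- modifyList(list(stepsV = NULL, stepsG = NULL, epochsV = 10L,
                         epochsG = 10L, batch = defaultBatchSize(dims),
                         lr = 1e-3, lrHalveEvery = 5L,
                         ratioRange = c(0.30, 0.60), lambda = 64,
                         fillerWidths = c(32L, 64L, 128L), genWidth = 32L,
                         discWidth = 32L, patchSize = 16L, useCra = TRUE,
                         useFlip = TRUE, seed = 1L), config)
  n <- length(healthy)
  batch <- min(cfg$batch, n)
  stepsPerEpoch <- max(1L, ceiling(n / batch))
  stepsV <- if (!is.null(cfg$stepsV)) cfg$stepsV else
    cfg$epochsV * stepsPerEpoch
  stepsG <- if (!is.null(cfg$stepsG)) cfg$stepsG else
    cfg$epochsG * stepsPerEpoch

  # Phase A: coarse filler, L1 only (skipped when a pretrained filler is
  # supplied, e.g. to hold stage 2 fixed across ablation arms)
  if (!is.null(cfg$pretrainedV)) {
    V <- cfg$pretrainedV
    va <- list(model = V, history = numeric(0))
    stepsV <- 0L
  } else {
    V <- buildVagueFiller(cfg$fillerWidths, seed = cfg$seed)
    va <- trainVagueFiller(V, healthy,
                           list(steps = stepsV, batch = batch, lr = cfg$lr,
                                lrHalveEvery = cfg$lrHalveEvery,
                                ratioRange = cfg$ratioRange,
                                seed = cfg$seed))
    V <- va$model
  }

  # Phase B: generator + discriminator, filler frozen
  G <- buildGenerator(cfg$genWidth, cfg$patchSize, cfg$useCra, cfg$useFlip,
                      seed = cfg$seed + 1L)
  D <- buildDiscriminator(cfg$discWidth, seed = cfg$seed + 2L)
  gp <- G@params; dp <- D@params
  ucur <- D@config$u
  fx <- buildFeatureExtractor(seed = cfg$seed + 3L)
  stG <- .adamInit(gp); stD <- .adamInit(dp)
  hist <- data.frame(step = integer(0), phase = character(0),
                     l1 = numeric(0), d_loss = numeric(0),
                     g_adv = numeric(0), perceptual = numeric(0),
                     total = numeric(0))
  if (length(va$history) > 0L)
    hist <- rbind(hist, data.frame(step = seq_along(va$history), phase = "V",
                                   l1 = va$history, d_loss = NA, g_adv = NA,
                                   perceptual = NA, total = va$history))
  gcfg <- G@config
  .withSeed(cfg$seed + 4L, {
    for (step in seq_len(stepsG)) {
      epoch <- (step - 1L) %/% stepsPerEpoch
      lr <- lrSchedule(cfg$lr, epoch, cfg$lrHalveEvery)
      bi <- sample.int(n, batch, replace = batch > n)
      imgs <- healthy[bi]
      mseeds <- sample.int(.Machine$integer.max - 1L, batch)
      msk <- lapply(seq_len(batch), function(j) {
        fg <- imgs[[j]]@pixels > -1 + 1e-9
        sampleTrainingMask(dim(fg), fg, cfg$ratioRange, seed = mseeds[j],
                           spacing = imgs[[j]]@spacing)
      })
      xV <- .fillerInput(imgs, msk)
      vag <- .fillerForward(V@params, V@config, xV, needCache = FALSE)$out
      vlist <- lapply(seq_len(batch), function(j) vag[, , 1L, j])
      mlist <- lapply(msk, pixels)
      gfw <- .genForward(gp, gcfg, vlist, mlist)
      # composite with the original healthy slice outside the mask
      fake <- gfw$out
      for (j in seq_len(batch))
        fake[, , 1L, j] <- mlist[[j]] * gfw$out[, , 1L, j] +
          (1 - mlist[[j]]) * imgs[[j]]@pixels
      real <- .stackBatch(lapply(imgs, pixels))
      # --- discriminator step ---
      fr <- .discForward(dp, ucur, real)
      ucur <- fr$u
      ff <- .discForward(dp, ucur, fake)
      ucur <- ff$u
      dl <- hingeDLoss(fr$scores, ff$scores)
      dsr <- -(fr$scores < 1) / length(fr$scores)
      dsf <- (ff$scores > -1) / length(ff$scores)
      gD <- .gradAdd(.discBackward(dsr, fr$cache)$grads,
                     .discBackward(dsf, ff$cache)$grads)
      upd <- .adamStep(dp, gD, stD, lr)
      dp <- upd$params; stD <- upd$state
      # --- generator step ---
      ff2 <- .discForward(dp, ucur, fake)
      ucur <- ff2$u
      gadv <- hingeGLoss(ff2$scores)
      dscore <- rep(-1 / length(ff2$scores), length(ff2$scores))
      dfakeAdv <- .discBackward(dscore, ff2$cache, needDx = TRUE)$dx
      pg <- .perceptualLossGrad(fx, real, fake, cfg$lambda)
      dfake <- dfakeAdv + pg$grad
      gG <- .genBackward(dfake, gfw$cache)
      upd <- .adamStep(gp, gG, stG, lr)
      gp <- upd$params; stG <- upd$state
      l1m <- mean(abs(fake - real))
      hist <- rbind(hist, data.frame(step = stepsV + step, phase = "G",
                                     l1 = l1m, d_loss = dl, g_adv = gadv,
                                     perceptual = pg$loss,
                                     total = generatorTotalLoss(gadv,
                                                                pg$loss)))
    }
  })
  Gout <- new("GeneratorModel", params = gp,
              config = c(gcfg[setdiff(names(gcfg), "trained")],
                         list(trained = TRUE)))
  Dcfg <- D@config; Dcfg$u <- ucur
  Dout <- new("DiscriminatorModel", params = dp, config = Dcfg)
  list(V = V, G = Gout, D = Dout, history = hist)
}

#' Synthesize a pseudo-healthy slice from a pathological slice
#'
#' Stage 1 localizes the lesion (a trained segmentor, or a provided
#' manual-annotation mask), stage 2 coarse-fills the lesion plus its 5 mm
#' margin, stage 3 refines the fill with contextual residual attention,
#' and the result is composited with the input so that every pixel outside
#' the dilated mask is preserved bit-exactly.
#'
#' @param p a pathological \linkS4class{GraySlice} (normalized)
#' @param segmentor a trained \linkS4class{SegmentorModel}, or a
#'   \linkS4class{LesionMask} holding a manual annotation
#' @param V a trained \linkS4class{VagueFillerModel}
#' @param G a trained \linkS4class{GeneratorModel}
#' @param margin_mm safety margin around the detected lesion, default 5
#' @return list with \code{image} (the pseudo-healthy
#'   \linkS4class{GraySlice}) and \code{mask} (the dilated
#'   \linkS4class{LesionMask} actually replaced)
#' @export
synthesizePseudoHealthy <- function(p, segmentor, V, G, margin_mm = 5) {
  stopifnot(is(p, "GraySlice"), is(V, "VagueFillerModel"),
            is(G, "GeneratorModel"))
  if (!isTRUE(V@config$trained) || !isTRUE(G@config$trained))
    stop("synthesizePseudoHealthy: V and G must be trained models")
  rawMask <- if (is(segmentor, "LesionMask")) segmentor
             else if (is(segmentor, "SegmentorModel"))
               predictLesionMask(segmentor, p)
             else stop("synthesizePseudoHealthy: segmentor must be a ",
                       "SegmentorModel or a LesionMask")
  mask <- prepareInferenceMask(rawMask, margin_mm)
  if (sum(mask@pixels) == 0)
    return(list(image = p, mask = mask))
  vague <- vagueFill(V, p, mask)
  refined <- refineSlice(G, vague, mask)
  final <- compositeSlice(p, refined, mask)
  list(image = final, mask = mask)
}

#' Extract every k-th axial slice from a volume
#'
#' Slices are taken at indices 0, k, 2k, ... (0-based) in acquisition
#' order and kept when \code{keep} returns TRUE. The default predicate
#' keeps slices whose foreground (pixels above the background floor)
#' exceeds 1\% of the image; pass \code{keep = NULL} to keep everything.
#'
#' @param volume 3-D array (H x W x S), or a list of
#'   \linkS4class{GraySlice}s in order
#' @param every_k stride (>= 1)
#' @param keep predicate \code{function(GraySlice) -> logical}, NULL for
#'   none, or missing for the foreground default
#' @param spacing mm per pixel when \code{volume} is an array
#' @return list of \linkS4class{GraySlice}s
#' @export
extractSlices <- function(volume, every_k = 1L,
                          keep = foregroundPredicate(0.01), spacing = 1) {
  if (every_k < 1L) stop("extractSlices: every_k must be >= 1")
  slices <- if (is.list(volume)) volume
  else {
    if (length(dim(volume)) != 3L || dim(volume)[3L] < 1L)
      stop("extractSlices: empty volume")
    lapply(seq_len(dim(volume)[3L]), function(k)
      normalizeIntensity(volume[, , k], spacing))
  }
  if (length(slices) == 0L) stop("extractSlices: empty volume")
  idx <- seq(1L, length(slices), by = every_k)
  out <- slices[idx]
  if (!is.null(keep)) out <- out[vapply(out, keep, TRUE)]
  out
}

#' Foreground-fraction keep predicate for extractSlices
#'
#' @param minFraction minimum fraction of above-background pixels
#' @return a predicate function on \linkS4class{GraySlice}s
#' @export
foregroundPredicate <- function(minFraction = 0.01) {
  function(s) mean(s@pixels > -1 + 1e-9) > minFraction
}

#' Select images whose lesion exceeds a fraction of the brain area
#'
#' Keeps index i iff \code{lesion_pixels / brain_pixels > threshold}
#' (strict): at the default 0.20 a lesion of exactly 20\% of the brain is
#' excluded. Used to gate the structure-healthiness evaluation to
#' large-lesion cases.
#'
#' @param masks list of \linkS4class{LesionMask}s
#' @param foregrounds list of binary matrices or
#'   \linkS4class{LesionMask}-likes marking the brain area
#' @param threshold fraction of the brain area, default 0.20
#' @return integer vector of kept indices
#' @export
largeLesionFilter <- function(masks, foregrounds, threshold = 0.20) {
  if (length(masks) != length(foregrounds))
    stop("largeLesionFilter: masks and foregrounds must be paired")
  keep <- vapply(seq_along(masks), function(i) {
    fg <- foregrounds[[i]]
    fg <- if (is(fg, "LesionMask")) fg@pixels else as.matrix(fg)
    nb <- sum(fg != 0)
    if (nb == 0) stop("largeLesionFilter: zero brain area at index ", i)
    sum(masks[[i]]@pixels) / nb > threshold
  }, TRUE)
  which(keep)
}
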