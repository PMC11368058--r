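# Binary deformation classifier on Canny edge maps: a small VGG-style
# conv net (conv-ReLU-maxpool stages, global average pooling, sigmoid
# head). Output is the probability that an edge map is deformation-free.

.clsForward <- function(params, x, needCache = TRUE) {
  cc <- list()
  h <- x
  nStages <- sum(grepl("^c[0-9]+\\.W$", names(params)))
  for (i in seq_len(nStages)) {
    cv <- .convForward(h, params[[paste0("c", i, ".W")]],
                       params[[paste0("c", i, ".b")]], pad = 1L,
                       needCache = needCache)
    a <- .reluF(cv$out)
    mp <- .maxPool2Forward(a)
    cc[[i]] <- list(cv = cv$cache, z = cv$out, mp = mp$cache)
    h <- mp$out
  }
  d <- dim(h)
  # flatten the coarse spatial map: deformation is a layout property, so
  # the head keeps the spatial arrangement rather than pooling it away
  flat <- matrix(h, prod(d[1:3]), d[4L])
  z <- as.vector(crossprod(flat, params[["fc.W"]])) + params[["fc.b"]]
  prob <- .sigmoidF(z)
  list(prob = prob, z = z,
       cache = if (needCache) list(cc = cc, flat = flat, hd = d,
                                   nStages = nStages))
}

.clsBackward <- function(dz, cache, params) {
  g <- list()
  g[["fc.W"]] <- cache$flat %*% matrix(dz, ncol = 1L)
  g[["fc.b"]] <- sum(dz)
  dh <- array(params[["fc.W"]] %*% matrix(dz, nrow = 1L), cache$hd)
  for (i in cache$nStages:1) {
    dmp <- .maxPool2Backward(dh, cache$cc[[i]]$mp)
    dzc <- .reluB(dmp, cache$cc[[i]]$z)
    bi <- .convBackward(dzc, cache$cc[[i]]$cv, needDx = i > 1L)
    g[[paste0("c", i, ".W")]] <- bi$dW
    g[[paste0("c", i, ".b")]] <- bi$db
    if (i > 1L) dh <- bi$dx
  }
  g
}

#' Build an untrained edge-map deformation classifier
#'
#' Conv-ReLU-maxpool stages followed by a linear head over the flattened
#' coarse feature map (the spatial layout carries the deformation signal).
#'
#' @param widths channels of the conv stages, default c(8, 16, 32, 32)
#' @param inputSize square input side the head is built for, default 64
#' @param seed RNG seed
#' @return an \linkS4class{EdgeClassifier}
#' @export
buildEdgeClassifier <- function(widths = c(8L, 16L, 32L, 32L),
                                inputSize = 64L, seed = 1L) {
  w <- as.integer(widths)
  ns <- length(w)
  final <- as.integer(inputSize) %/% 2L^ns
  if (final < 1L) stop("buildEdgeClassifier: too many stages for inputSize")
  nf <- final^2 * w[ns]
  params <- list()
  .withSeed(seed, {
    cin <- 1L
    for (i in seq_len(ns)) {
      params[[paste0("c", i, ".W")]] <- .heInit(3, 3, cin, w[i])
      params[[paste0("c", i, ".b")]] <- .zeros(w[i])
      cin <- w[i]
    }
    params[["fc.W"]] <- matrix(stats::rnorm(nf, sd = 1 / sqrt(nf)), nf, 1L)
    params[["fc.b"]] <- 0
  })
  new("EdgeClassifier", params = params,
      config = list(widths = w, inputSize = as.integer(inputSize),
                    trained = FALSE))
}

# Edge maps must match the head's input size; nearest resize otherwise.
.clsInput <- function(maps, inputSize) {
  .stackBatch(lapply(maps, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == inputSize)) m <- .resizeNearest(m, inputSize,
                                                       inputSize)
    m
  }))
}

#' Train the deformation classifier on edge maps
#'
#' Binary cross-entropy training: label 1 for deformation-free (healthy)
#' edge maps, 0 for deformed ones. The returned classifier reports its
#' held-out accuracy in \code{config$valAccuracy}.
#'
#' @param healthyEdges list of binary edge-map matrices (class 1)
#' @param deformedEdges list of binary edge-map matrices (class 0)
#' @param config list: \code{epochs} (15), \code{batch} (8), \code{lr}
#'   (1e-3), \code{lrHalveEvery} (5), \code{valFraction} (0.2),
#'   \code{widths}, \code{seed} (1)
#' @return a trained \linkS4class{EdgeClassifier}
#' @export
trainDeformationClassifier <- function(healthyEdges, deformedEdges,
                                       config = list()) {
  if (length(healthyEdges) == 0L || length(deformedEdges) == 0L)
    stop("trainDeformationClassifier: both classes must be nonempty")
  cfg <- modifyList(list(epochs = 20L, batch = 8L, lr = 1e-3,
                         lrHalveEvery = 5L, valFraction = 0.2,
                         widths = c(8L, 16L, 32L, 32L), inputSize = 64L,
                         seed = 1L), config)
  toM <- function(x) if (is(x, "GraySlice")) x@pixels else as.matrix(x)
  xs <- c(lapply(healthyEdges, toM), lapply(deformedEdges, toM))
  ys <- c(rep(1, length(healthyEdges)), rep(0, length(deformedEdges)))
  n <- length(xs)
  model <- buildEdgeClassifier(cfg$widths, cfg$inputSize, seed = cfg$seed)
  params <- model@params
  ord <- .withSeed(cfg$seed + 1L, sample.int(n))
  nval <- if (n >= 10L) max(2L, floor(cfg$valFraction * n)) else 0L
  valIdx <- if (nval > 0L) ord[seq_len(nval)] else integer(0)
  trIdx <- setdiff(ord, valIdx)
  batch <- min(cfg$batch, length(trIdx))
  stepsPerEpoch <- max(1L, ceiling(length(trIdx) / batch))
  nsteps <- cfg$epochs * stepsPerEpoch
  st <- .adamInit(params)
  .withSeed(cfg$seed + 2L, {
    for (step in seq_len(nsteps)) {
      epoch <- (step - 1L) %/% stepsPerEpoch
      lr <- lrSchedule(cfg$lr, epoch, cfg$lrHalveEvery)
      bi <- trIdx[sample.int(length(trIdx), batch,
                             replace = batch > length(trIdx))]
      x <- .clsInput(xs[bi], cfg$inputSize)
      y <- ys[bi]
      fw <- .clsForward(params, x)
      dz <- (fw$prob - y) / length(y)
      gr <- .clsBackward(dz, fw$cache, params)
      upd <- .adamStep(params, gr, st, lr)
      params <- upd$params; st <- upd$state
    }
  })
  acc <- NA_real_
  if (length(valIdx) > 0L) {
    pv <- .clsForward(params, .clsInput(xs[valIdx], cfg$inputSize),
                      needCache = FALSE)$prob
    acc <- mean((pv >= 0.5) == (ys[valIdx] == 1))
  }
  new("EdgeClassifier", params = params,
      config = list(widths = cfg$widths, inputSize = cfg$inputSize,
                    trained = TRUE, valAccuracy = acc))
}

#' Probability that an edge map is deformation-free
#'
#' @param classifier a trained \linkS4class{EdgeClassifier}
#' @param edgeMap binary matrix from \code{\link{cannyEdges}}, or a list
#'   of them
#' @return numeric vector of probabilities in [0, 1]
#' @export
predictDeformationFree <- function(classifier, edgeMap) {
  stopifnot(is(classifier, "EdgeClassifier"))
  maps <- if (is.list(edgeMap)) edgeMap else list(edgeMap)
  x <- .clsInput(maps, classifier@config$inputSize %||% 64L)
  .clsForward(classifier@params, x, needCache = FALSE)$prob
}
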