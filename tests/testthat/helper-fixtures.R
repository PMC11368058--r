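# Shared fixtures, built in code and memoized for the test session. The
# desk-scale study conditions are fixed here: 64 x 64 phantoms with three
# mirrored structure pairs, smooth noise sd 0.03, mass-effect lesions of
# amplitude 1-3 px, and narrow network widths suited to CPU training.

.fx <- new.env(parent = emptyenv())

.memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# 200 training phantoms + 50 held-out, the smoke-test study conditions.
fixtureTrainSet <- function() {
  .memo("train200", makePairedDataset(200, phantomSpec(size = 64),
                                      seed = 101))
}

fixtureHoldout <- function() {
  .memo("hold50", makePairedDataset(50, phantomSpec(size = 64), seed = 202))
}

# Small dataset for cheap unit tests.
fixtureSmallSet <- function() {
  .memo("small12", makePairedDataset(12, phantomSpec(size = 64), seed = 77))
}

deskFillerWidths <- c(8L, 16L, 16L)

# Segmentor trained on the 200 pathological phantoms.
fixtureSegmentor <- function() {
  .memo("segmentor", {
    ds <- fixtureTrainSet()
    trainUnet(ds$pathological, ds$mask,
              list(epochs = 8L, batch = 4L, baseWidth = 8L, depth = 3L,
                   seed = 1L, evalEvery = 80L))
  })
}

# Full pipeline: coarse filler 200 steps, generator 500 adversarial steps.
fixtureTrainedPipeline <- function() {
  .memo("pipeline", {
    ds <- fixtureTrainSet()
    trainPseudoHealthy(ds$healthy,
                       list(stepsV = 200L, stepsG = 500L, batch = 4L,
                            fillerWidths = deskFillerWidths, genWidth = 8L,
                            discWidth = 8L, patchSize = 8L, seed = 1L))
  })
}

# Edge-map deformation classifier on healthy vs mass-effect phantoms.
fixtureEdgeClassifier <- function() {
  .memo("edgecls", {
    ds <- fixtureTrainSet()
    trainDeformationClassifier(lapply(ds$healthy, cannyEdges),
                               lapply(ds$pathological, cannyEdges),
                               list(epochs = 10L, seed = 1L))
  })
}

# Ablation runs under equal stage-3 budgets (500 steps each, matching the
# canonical refinement budget), with stage 2 held fixed across the arms.
fixtureAblation <- function() {
  .memo("ablation", {
    ds <- fixtureTrainSet()
    V <- buildVagueFiller(deskFillerWidths, seed = 1L)
    V <- trainVagueFiller(V, ds$healthy,
                          list(steps = 150L, batch = 2L, lr = 1e-3,
                               lrHalveEvery = 5L,
                               ratioRange = c(0.30, 0.60),
                               seed = 1L))$model
    cfgs <- list(gan = c(FALSE, FALSE), cra = c(TRUE, FALSE),
                 craflip = c(TRUE, TRUE))
    lapply(cfgs, function(sw)
      trainPseudoHealthy(ds$healthy,
                         list(stepsG = 500L, batch = 2L,
                              fillerWidths = deskFillerWidths,
                              genWidth = 8L, discWidth = 8L,
                              patchSize = 8L, seed = 1L,
                              useCra = sw[1L], useFlip = sw[2L],
                              pretrainedV = V)))
  })
}

# Mean masked-region L1 of refined outputs against the healthy ground
# truth over the first n held-out phantoms.
heldoutMaskedL1 <- function(V, G, n = 30L) {
  hold <- fixtureHoldout()
  vals <- vapply(seq_len(n), function(i) {
    p <- hold$pathological[[i]]; h <- hold$healthy[[i]]
    m <- prepareInferenceMask(hold$mask[[i]], 5)
    vg <- vagueFill(V, p, m)
    rf <- refineSlice(G, vg, m)
    sel <- pixels(m) == 1
    c(vague = mean(abs(pixels(vg)[sel] - pixels(h)[sel])),
      refined = mean(abs(pixels(rf)[sel] - pixels(h)[sel])))
  }, c(vague = 1, refined = 1))
  rowMeans(vals)
}

# Mark an untrained model as usable in pipelines that require trained
# models (for identity-preservation checks, which must hold regardless of
# training state).
asTrained <- function(model) {
  cfg <- model@config
  cfg$trained <- TRUE
  model@config <- cfg
  model
}

# Random GraySlice for property tests.
randomSlice <- function(h, w = h, seed = 1L, spacing = 1) {
  set.seed(seed)
  GraySlice(matrix(runif(h * w, -1, 1), h, w), spacing)
}
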