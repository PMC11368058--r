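# Contextual attention: affinity scores between context (outside-mask) and
# hole (inside-mask) patches, attention transfer, and full-resolution
# residual aggregation. These are the refinement generator's non-learned
# core; the vectorized forms here are cross-checked against brute-force
# nested-loop references in the test suite.

#' Attention Calculation Module: squared-normalized cosine patch affinities
#'
#' For every outside (context) patch \eqn{b_i} and every patch \eqn{b_j},
#' the raw affinity is the cosine similarity
#' \eqn{c_{i,j} = \langle b_i/\|b_i\|,\; b_j/\|b_j\| \rangle}. Affinities
#' are squared and normalized over the outside patches,
#' \eqn{s_{i,j} = c_{i,j}^2 / \sum_{i'} c_{i',j}^2}, so that every score
#' column is a convex-weight vector over the context patches. Rows
#' belonging to inside patches are zeroed: masked content never serves as
#' context. Zero-norm patches are handled with an epsilon-guarded norm, and
#' a column whose affinities are all zero falls back to uniform weights
#' over the outside patches, so degenerate masks cannot produce NaNs.
#'
#' @param patches a \linkS4class{PatchSet} (needs at least one outside patch)
#' @param orientation "PIAS" (forward path) or "FIAS" (flipped path)
#' @param eps norm guard, default 1e-8
#' @return an \linkS4class{AttentionMatrix}
#' @export
attentionScores <- function(patches, orientation = "PIAS", eps = 1e-8) {
  stopifnot(is(patches, "PatchSet"))
  inside <- patches@inside
  if (all(inside))
    stop("attentionScores: no outside patches to attend to")
  P <- patches@patches
  nrms <- sqrt(colSums(P * P))
  Pn <- sweep(P, 2L, pmax(nrms, eps), "/")
  aff <- crossprod(Pn) # n x n cosine similarities
  w <- aff * aff
  w[inside, ] <- 0 # only outside patches are sources
  cs <- colSums(w)
  s <- sweep(w, 2L, pmax(cs, .Machine$double.xmin), "/")
  if (any(cs <= 0)) { # uniform fallback over context patches
    nOut <- sum(!inside)
    s[, cs <= 0] <- 0
    s[!inside, cs <= 0] <- 1 / nOut
  }
  new("AttentionMatrix", affinity = aff, scores = s, inside = inside,
      orientation = orientation)
}

#' Attention Transfer Module: fill hole patches with weighted context
#'
#' Each inside patch is replaced by the score-weighted combination of the
#' outside patches, \eqn{b_j = \sum_i s_{i,j} b_i}; outside patches are
#' left untouched. Because each score column is a convex weight vector,
#' every filled pixel lies within the per-position min/max envelope of the
#' context patches.
#'
#' @param patches a \linkS4class{PatchSet}
#' @param scores an \linkS4class{AttentionMatrix} built from a patch set of
#'   the same grid
#' @return a \linkS4class{PatchSet} with inside patches filled
#' @export
attentionTransfer <- function(patches, scores) {
  stopifnot(is(patches, "PatchSet"), is(scores, "AttentionMatrix"))
  n <- ncol(patches@patches)
  if (ncol(scores@scores) != n)
    stop("attentionTransfer: score dimensions do not match patch count")
  inside <- scores@inside
  if (!any(inside)) return(patches)
  out <- patches
  # rows of 'scores' belonging to inside patches are zero, so the full
  # product only mixes context patches
  out@patches[, inside] <- patches@patches %*% scores@scores[, inside]
  out
}

#' High-frequency residual of a slice
#'
#' The residual is the slice minus its own blur, \code{x - up(down(x))},
#' with factor-k block-average downsampling and bilinear upsampling. It
#' carries the high-pass content only: downsampling the residual is close
#' to zero at the low resolution (within interpolation tolerance).
#'
#' @param img a \linkS4class{GraySlice} or numeric matrix
#' @param factor integer downsampling factor, default 4
#' @return numeric matrix of the same shape (not range-restricted)
#' @export
residualImage <- function(img, factor = 4L) {
  m <- if (is(img, "GraySlice")) img@pixels else as.matrix(img)
  lo <- .downsampleAvg(m, factor)
  m - .upsampleFactor(lo, factor)
}

#' Contextual residual aggregation
#'
#' Transplants full-resolution high-frequency texture into the hole: the
#' lesion-area residual patches are rebuilt as score-weighted combinations
#' of the context residual patches, \eqn{R_j = \sum_i s_{i,j} R_i}, using
#' the same attention scores computed at the feature level (the forward
#' path's scores: residuals live in the unflipped frame). Outside residual
#' patches are unchanged. The patch grid (image size / patchSize) must
#' match the grid the scores were computed on.
#'
#' @param residual numeric matrix from \code{\link{residualImage}}
#' @param scores an \linkS4class{AttentionMatrix}
#' @param mask a \linkS4class{LesionMask} or binary matrix, full resolution
#' @param patchSize image-level patch side, default 16
#' @return numeric matrix: the aggregated residual
#' @export
aggregateResiduals <- function(residual, scores, mask, patchSize = 16L) {
  residual <- as.matrix(residual)
  ps <- extractPatches(residual, patchSize, mask)
  if (ncol(ps@patches) != ncol(scores@scores))
    stop("aggregateResiduals: patch grid does not match score dimensions")
  filled <- attentionTransfer(ps, scores)
  scatterPatches(filled)
}
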