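# Evaluation suite: healthiness H, structure healthiness SH, and the
# assembled MetricReport (masked PSNR/SSIM live in ssim.R).

#' Healthiness of synthesized outputs
#'
#' \eqn{H = 1 - E[N(f_p(output))] / E[N(f_p(input))]} where \eqn{N} counts
#' pixels the evaluation segmentor \code{f_p} flags as pathological. The
#' denominator uses the segmentor's own prediction on the inputs, not the
#' ground-truth masks, so segmentor bias cancels between numerator and
#' denominator. The ratio is of means (matching the nested expectations),
#' not a mean of per-image ratios. H = 1 when no output shows pathology;
#' H = 0 when outputs carry as much detected pathology as inputs.
#'
#' @param outputs list of synthesized \linkS4class{GraySlice}s
#' @param inputs list of pathological \linkS4class{GraySlice}s, paired
#' @param f_p a trained \linkS4class{SegmentorModel} (the evaluation
#'   segmentor, trained/refined on a split disjoint from generator
#'   training), or a function \code{GraySlice -> LesionMask} for custom
#'   evaluators
#' @return numeric(1), at most 1
#' @export
healthiness <- function(outputs, inputs, f_p) {
  if (length(outputs) != length(inputs))
    stop("healthiness: outputs and inputs must be paired")
  if (length(outputs) == 0L) stop("healthiness: empty input")
  predict <- if (is.function(f_p)) f_p
  else {
    stopifnot(is(f_p, "SegmentorModel"))
    function(s) predictLesionMask(f_p, s)
  }
  cntOut <- vapply(outputs, function(s) sum(predict(s)@pixels), 1)
  cntIn <- vapply(inputs, function(s) sum(predict(s)@pixels), 1)
  if (mean(cntIn) <= 0)
    stop("healthiness: the segmentor finds no pathology in the inputs")
  1 - mean(cntOut) / mean(cntIn)
}

#' Structure healthiness of large-lesion outputs
#'
#' Mean probability, under the edge-map deformation classifier, that the
#' Canny edge maps of the outputs are deformation-free. Evaluated only on
#' outputs synthesized from large-lesion inputs (select them with
#' \code{\link{largeLesionFilter}} first).
#'
#' @param outputs list of synthesized \linkS4class{GraySlice}s from
#'   large-lesion inputs
#' @param classifier a trained \linkS4class{EdgeClassifier}, or a function
#'   mapping a list of edge maps to probabilities
#' @return numeric(1) in [0, 1]
#' @export
structureHealthiness <- function(outputs, classifier) {
  if (length(outputs) == 0L)
    stop("structureHealthiness: empty output set")
  edges <- lapply(outputs, cannyEdges)
  probs <- if (is.function(classifier)) classifier(edges)
  else {
    stopifnot(is(classifier, "EdgeClassifier"))
    predictDeformationFree(classifier, edges)
  }
  mean(probs)
}

#' Assemble a full metric report for a synthesis run
#'
#' Computes healthiness over all pairs, masked PSNR/SSIM averaged over
#' pairs (each restricted to the complement of its mask), and structure
#' healthiness over the outputs whose input lesion exceeds 20\% of the
#' brain area (NA when there are none or no classifier is given).
#'
#' @param outputs,inputs paired lists of \linkS4class{GraySlice}s
#' @param masks list of \linkS4class{LesionMask}s used at synthesis
#' @param f_p evaluation \linkS4class{SegmentorModel} for H (NULL skips H)
#' @param classifier \linkS4class{EdgeClassifier} for SH (NULL skips SH)
#' @param foregrounds brain-area matrices for the large-lesion filter;
#'   default: above-background pixels of each input
#' @return a \linkS4class{MetricReport}
#' @export
evaluateSynthesis <- function(outputs, inputs, masks, f_p = NULL,
                              classifier = NULL, foregrounds = NULL) {
  n <- length(outputs)
  stopifnot(n == length(inputs), n == length(masks))
  if (is.null(foregrounds))
    foregrounds <- lapply(inputs, function(s) (s@pixels > -1 + 1e-9) * 1)
  H <- if (!is.null(f_p)) healthiness(outputs, inputs, f_p) else NA_real_
  mp <- mean(vapply(seq_len(n), function(i)
    maskedPSNR(outputs[[i]], inputs[[i]], masks[[i]]), 1))
  ms <- mean(vapply(seq_len(n), function(i)
    maskedSSIM(outputs[[i]], inputs[[i]], masks[[i]]), 1))
  big <- largeLesionFilter(masks, foregrounds)
  sh <- if (!is.null(classifier) && length(big) > 0L)
    structureHealthiness(outputs[big], classifier) else NA_real_
  new("MetricReport", healthiness = H, mpsnr = mp, mssim = ms, sh = sh,
      nImages = as.integer(n), nLargeLesion = length(big))
}
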