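#' Run the per-sample somatic pipeline
#'
#' End-to-end convenience wrapper: calls variants for every cell and the
#' consensus, applies coverage QC (cells failing are dropped), applies the
#' low-complexity masks, checks cell/consensus homology (failing cells
#' dropped), and identifies somatic variants.
#'
#' @param cells Named list of per-cell [AlleleCountTable-class]s.
#' @param consensus Consensus [AlleleCountTable-class].
#' @param reference An [MtReference-class].
#' @param masks A [MaskSet-class].
#' @param minLevel,minSiteDepth,errorRate Passed to [callVariants()].
#' @param qcFraction,qcDepth Passed to [coverageQC()].
#' @param sampleName Sample identifier.
#' @return List with `somatic` ([SomaticVariantSet-class]), `qc`
#'   (per-cell coverage report), `homology` (per-cell similarity report),
#'   `cellCalls` (post-mask calls of passing cells) and `consensusCalls`.
#' @export
runSample <- function(cells, consensus, reference = mtReference(),
                      masks = maskSet(), minLevel = 0.02,
                      minSiteDepth = 100L, errorRate = 0.001,
                      qcFraction = 0.99, qcDepth = 1500L,
                      sampleName = "sample") {
  qc <- do.call(rbind, lapply(cells, coverageQC,
                              minFraction = qcFraction, minDepth = qcDepth))
  rownames(qc) <- NULL
  passing <- names(cells)[qc$pass]
  consensusCalls <- applyMasks(
    callVariants(consensus, reference, minLevel = minLevel,
                 minSiteDepth = minSiteDepth, errorRate = errorRate),
    masks)
  cellCalls <- lapply(cells[passing], function(ct) {
    cl <- applyMasks(callVariants(ct, reference, minLevel = minLevel,
                                  minSiteDepth = minSiteDepth,
                                  errorRate = errorRate), masks)
    attr(cl, "sample") <- ct@sample
    cl
  })
  homology <- do.call(rbind, lapply(cellCalls, homologyCheck,
                                    consensusCalls = consensusCalls))
  if (is.null(homology))
    homology <- data.frame(cell = character(), sharedFraction = numeric(),
                           pass = logical())
  rownames(homology) <- NULL
  # pass = NA means the check could not be assessed; such cells are kept
  keep <- homology$cell[is.na(homology$pass) | homology$pass]
  cellCalls <- cellCalls[names(cellCalls) %in% keep]
  somatic <- identifySomatic(cellCalls, consensusCalls,
                             analysisFloor = minLevel, sample = sampleName)
  list(somatic = somatic, qc = qc, homology = homology,
       cellCalls = cellCalls, consensusCalls = consensusCalls)
}

#' Recovery of simulated somatic truth
#'
#' Compares a [SomaticVariantSet-class] against simulator ground truth.
#' Recall is measured over truth variants flagged `expectedSomatic` (private
#' somatic variants inside the analysis window whose diluted consensus
#' fraction is below the detection floor) with true HF at or above
#' `minTrueHF`. Precision counts a somatic call as a true positive when the
#' same (cell, position, alt) is a private somatic variant in truth,
#' whatever its fraction.
#'
#' @param somatic A [SomaticVariantSet-class].
#' @param truth Truth `data.frame` from [simulateSample()].
#' @param minTrueHF Recall restricted to truth variants at/above this HF.
#' @return `data.frame` with `nExpected`, `nRecovered`, `recall`, `nCalls`,
#'   `nTruePositive`, `precision`.
#' @export
evaluateRecovery <- function(somatic, truth, minTrueHF = 0.05) {
  calls <- somaticCalls(somatic)
  callKey <- paste(calls$cell, calls$pos, calls$alt)
  somTruth <- truth[truth$type == "somatic", , drop = FALSE]
  expected <- somTruth[somTruth$expectedSomatic &
                         somTruth$hf >= minTrueHF, , drop = FALSE]
  expKey <- paste(expected$cell, expected$pos, expected$alt)
  truthKey <- paste(somTruth$cell, somTruth$pos, somTruth$alt)
  nRec <- sum(expKey %in% callKey)
  nTP <- sum(callKey %in% truthKey)
  data.frame(nExpected = nrow(expected), nRecovered = nRec,
             recall = if (nrow(expected)) nRec / nrow(expected) else NA_real_,
             nCalls = nrow(calls), nTruePositive = nTP,
             precision = if (nrow(calls)) nTP / nrow(calls) else NA_real_)
}
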