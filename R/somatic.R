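#' Remove calls at masked positions
#'
#' @param calls Call `data.frame` from [callVariants()].
#' @param masks A [MaskSet-class].
#' @return The calls with masked positions removed, order preserved.
#' @export
applyMasks <- function(calls, masks) {
  if (!nrow(calls)) return(calls)
  out <- calls[!inMask(calls$pos, masks), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.homKeys <- function(calls) {
  # a homoplasmy must carry the majority of all reads at the site: with the
  # alt/(alt+ref) HF definition a lone error read can reach HF ~ 1 at a
  # site whose reference depth is itself error-level
  keep <- calls$zygosity == "homoplasmic" & !calls$lowConfidence &
    calls$altDepth > 0.5 * calls$depth
  with(calls[keep, , drop = FALSE], paste(pos, alt))
}

#' Cell/consensus homology check by homoplasmic variant sharing
#'
#' Confirms that a single cell carries the consensus sample's germline
#' haplotype: the fraction of the consensus homoplasmic variant set also
#' homoplasmic in the cell must exceed 0.99. Failing cells are candidates
#' for contamination and should be excluded from somatic analysis.
#'
#' @param cellCalls,consensusCalls Call `data.frame`s from [callVariants()]
#'   against the same reference.
#' @param minSimilarity Pass threshold (default 0.99, strict).
#' @return `data.frame` with `cell`, `sharedFraction`, `pass`. When the
#'   consensus has no homoplasmies the check cannot be assessed: both are
#'   `NA` with a warning.
#' @export
homologyCheck <- function(cellCalls, consensusCalls, minSimilarity = 0.99) {
  cell <- attr(cellCalls, "sample")
  if (is.null(cell)) cell <- NA_character_
  consHom <- .homKeys(consensusCalls)
  if (!length(consHom)) {
    warning("consensus has no homoplasmic variants; homology check skipped")
    return(data.frame(cell = cell, sharedFraction = NA_real_, pass = NA,
                      stringsAsFactors = FALSE))
  }
  shared <- length(intersect(.homKeys(cellCalls), consHom)) / length(consHom)
  data.frame(cell = cell, sharedFraction = shared,
             pass = shared > minSimilarity, stringsAsFactors = FALSE)
}

#' Identify somatic variants across the cells of one sample
#'
#' A variant (position, alt) in cell c is somatic iff it is heteroplasmic
#' with `analysisFloor < HF < upper` in c, is absent from the consensus, and
#' is absent from every other cell of the sample. "Absent" means below the
#' detection floor (default 0.02) in the comparator - exact zero-read
#' absence is unattainable under sequencing error. Low-confidence calls
#' never enter somatic sets and cannot veto a variant. With fewer than two
#' cells the privacy criterion degenerates and only the consensus criterion
#' applies (with a warning).
#'
#' Masks are expected to have been applied already (see [applyMasks()]);
#' supply `masks` to have them applied here. The returned object also
#' retains the pre-floor variant list (HF > 0 and < `upper`, same consensus
#' and privacy criteria) for HF histograms of the full sub-threshold tail.
#'
#' @param perCellCalls Named list (cell id -> call `data.frame`) of post-QC,
#'   post-homology cells.
#' @param consensusCalls Consensus call `data.frame`.
#' @param analysisFloor Somatic HF floor (default 0.02, strict).
#' @param detectionFloor HF at/above which a variant counts as "present" in
#'   a comparator (default 0.02).
#' @param upper Somatic HF ceiling (default 0.98, strict).
#' @param errorAlpha Significance level on the caller's binomial error
#'   p-value required of a somatic call (default 1e-3); calls whose alt
#'   depth is consistent with sequencing error are never somatic. `NA`
#'   p-values (e.g. calls read from VCF) pass.
#' @param masks Optional [MaskSet-class] to apply first.
#' @param sample Sample identifier.
#' @return A [SomaticVariantSet-class].
#' @export
identifySomatic <- function(perCellCalls, consensusCalls,
                            analysisFloor = 0.02, detectionFloor = 0.02,
                            upper = 0.98, errorAlpha = 1e-3, masks = NULL,
                            sample = "sample") {
  stopifnot(is.list(perCellCalls), !is.null(names(perCellCalls)))
  if (!is.null(masks)) {
    perCellCalls <- lapply(perCellCalls, applyMasks, masks = masks)
    consensusCalls <- applyMasks(consensusCalls, masks)
  }
  cells <- names(perCellCalls)
  if (length(cells) < 2L)
    warning("fewer than 2 cells: privacy criterion degenerates; ",
            "applying heteroplasmy and consensus-absence criteria only")
  consPresent <- with(consensusCalls[consensusCalls$hf >= detectionFloor &
                                       !consensusCalls$lowConfidence, ,
                                     drop = FALSE], paste(pos, alt))
  presence <- lapply(perCellCalls, function(cl)
    with(cl[cl$hf >= detectionFloor & !cl$lowConfidence, , drop = FALSE],
         paste(pos, alt)))
  presenceCount <- table(unlist(presence, use.names = FALSE))

  pick <- function(cl, cellName, floorStrict) {
    if (!nrow(cl)) return(NULL)
    key <- paste(cl$pos, cl$alt)
    cand <- cl$hf > floorStrict & cl$hf < upper & !cl$lowConfidence
    if (floorStrict > 0 && "pError" %in% names(cl))
      cand <- cand & (is.na(cl$pError) | cl$pError <= errorAlpha)
    consensusAbsent <- !(key %in% consPresent)
    if (length(cells) >= 2L) {
      nPresent <- as.integer(presenceCount[key])
      nPresent[is.na(nPresent)] <- 0L
      selfPresent <- key %in% presence[[cellName]]
      othersPresent <- nPresent - as.integer(selfPresent) > 0L
      private <- !othersPresent
    } else private <- TRUE
    out <- cl[cand & consensusAbsent & private, , drop = FALSE]
    if (!nrow(out)) return(NULL)
    out$cell <- cellName
    out$maskPassed <- TRUE
    out$privacyPassed <- TRUE
    out$consensusAbsent <- TRUE
    rownames(out) <- NULL
    out
  }

  somatic <- do.call(rbind, lapply(cells, function(cn)
    pick(perCellCalls[[cn]], cn, analysisFloor)))
  preFloor <- do.call(rbind, lapply(cells, function(cn)
    pick(perCellCalls[[cn]], cn, 0)))
  empty <- data.frame(pos = integer(), ref = character(), alt = character(),
                      altDepth = integer(), refDepth = integer(),
                      depth = integer(), hf = numeric(),
                      zygosity = character(), pError = numeric(),
                      lowConfidence = logical(), cell = character(),
                      maskPassed = logical(), privacyPassed = logical(),
                      consensusAbsent = logical(), stringsAsFactors = FALSE)
  if (is.null(somatic)) somatic <- empty
  if (is.null(preFloor)) preFloor <- empty
  new("SomaticVariantSet", sample = sample, calls = somatic,
      preFloor = preFloor, cells = cells)
}

#' @describeIn identifySomatic Accessor: somatic call `data.frame` of a
#'   [SomaticVariantSet-class].
#' @param x A [SomaticVariantSet-class].
#' @export
somaticCalls <- function(x) {
  stopifnot(is(x, "SomaticVariantSet"))
  x@calls
}

#' @describeIn identifySomatic Accessor: pre-floor (HF > 0) call list.
#' @export
preFloorCalls <- function(x) {
  stopifnot(is(x, "SomaticVariantSet"))
  x@preFloor
}

#' @describeIn identifySomatic Accessor: post-QC cell universe.
#' @export
sampleCells <- function(x) {
  stopifnot(is(x, "SomaticVariantSet"))
  x@cells
}
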