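#' @import methods
#' @importFrom stats aov rbinom rnbinom rbeta runif rpois pbinom pbeta
#'   pf shapiro.test wilcox.test sd var setNames complete.cases
#' @importFrom utils read.table write.table head
NULL

# genome length of the revised Cambridge Reference Sequence (NC_012920.1)
MT_GENOME_LENGTH <- 16569L

MT_BASES <- c("A", "C", "G", "T")

LOCUS_CLASSES <- c("D-loop", "rRNA", "tRNA", "protein-coding")

# locus-class lengths as printed alongside the normalized-burden analysis;
# used verbatim for normalization (computed lengths differ slightly, see
# computedLocusLengths())
MT_NORMALIZATION_LENGTHS <- c(
  "D-loop" = 1124, "rRNA" = 2511, "tRNA" = 1486, "protein-coding" = 11382
)

#' MtReference: the circular mitochondrial reference genome
#'
#' Holds the 16,569 bp human mitochondrial reference sequence. Coordinates
#' are 1-based inclusive and position arithmetic is modular: position
#' 16,569 + 1 wraps to position 1.
#'
#' @slot sequence A [Biostrings::DNAString] of length 16,569.
#' @slot name Sequence identifier, default `"NC_012920.1"`.
#' @export
setClass("MtReference",
  representation(sequence = "DNAString", name = "character")
)

setValidity("MtReference", function(object) {
  if (length(object@sequence) != MT_GENOME_LENGTH)
    return(sprintf("reference must be exactly %d bp, got %d",
                   MT_GENOME_LENGTH, length(object@sequence)))
  if (length(object@name) != 1L) return("name must be a single string")
  letters <- Biostrings::uniqueLetters(object@sequence)
  if (!all(letters %in% c(MT_BASES, "N")))
    return("reference may only contain A, C, G, T, N")
  TRUE
})

#' LocusMap: circular locus annotation of the mitochondrial genome
#'
#' Maps every genomic position to a locus class (D-loop, rRNA, tRNA,
#' protein-coding, or intergenic) and gene name. The D-loop interval wraps
#' the circular origin (m.16024-576). Overlapping features (e.g.
#' MT-ATP8/MT-ATP6) are resolved for burden counting by first-in-genome-order
#' precedence; consequence annotation inspects all overlapping genes.
#'
#' @slot intervals `data.frame` with columns `name`, `start`, `end`,
#'   `strand` (`"heavy"`/`"light"`), `class`.
#' @slot normLengths Named numeric, locus-class lengths used for burden
#'   normalization (the printed constants, not recomputed).
#' @slot classByPos,nameByPos Character vectors of length 16,569 giving the
#'   precedence-resolved class/name per position (`"intergenic"` where
#'   unannotated).
#' @export
setClass("LocusMap",
  representation(intervals = "data.frame", normLengths = "numeric",
                 classByPos = "character", nameByPos = "character")
)

setValidity("LocusMap", function(object) {
  iv <- object@intervals
  need <- c("name", "start", "end", "strand", "class")
  if (!all(need %in% names(iv)))
    return(paste("intervals must have columns:", paste(need, collapse = ", ")))
  if (any(iv$start < 1L | iv$start > MT_GENOME_LENGTH |
          iv$end < 1L | iv$end > MT_GENOME_LENGTH))
    return("interval coordinates must lie in [1, 16569]")
  wraps <- iv$end < iv$start
  if (any(wraps & iv$class != "D-loop"))
    return("only the D-loop interval may wrap the origin")
  if (!all(iv$class %in% LOCUS_CLASSES))
    return(paste("unknown locus class; allowed:",
                 paste(LOCUS_CLASSES, collapse = ", ")))
  if (!all(iv$strand %in% c("heavy", "light")))
    return("strand must be 'heavy' or 'light'")
  if (length(object@classByPos) != MT_GENOME_LENGTH ||
      length(object@nameByPos) != MT_GENOME_LENGTH)
    return("position lookup vectors must cover all 16,569 positions")
  if (!all(names(object@normLengths) %in% LOCUS_CLASSES))
    return("normLengths must be named by locus class")
  TRUE
})

#' MaskSet: low-complexity exclusion regions
#'
#' Positions falling in any mask interval (1-based, inclusive ends) are
#' excluded from comparative analysis. The rCRS placeholder positions
#' 3,106-3,107 are always masked, regardless of the supplied regions.
#'
#' @slot ranges An [IRanges::IRanges] of masked intervals.
#' @export
setClass("MaskSet", representation(ranges = "IRanges"))

setValidity("MaskSet", function(object) {
  if (length(object@ranges) > 0 &&
      (min(IRanges::start(object@ranges)) < 1L ||
       max(IRanges::end(object@ranges)) > MT_GENOME_LENGTH))
    return("mask regions must lie within [1, 16569]")
  TRUE
})

#' AlleleCountTable: per-position base counts for one cell or consensus
#'
#' The pipeline's entry point: a 16,569 x 4 matrix of A/C/G/T counts plus
#' total depth for a single cell or consensus (bulk) sample. Uncovered
#' positions carry zero counts.
#'
#' @slot counts Integer matrix, 16,569 rows, columns `A`, `C`, `G`, `T`.
#' @slot depth Integer vector of per-position total depth; must equal
#'   `rowSums(counts)`.
#' @slot sample Sample identifier.
#' @slot isConsensus `TRUE` for a consensus (bulk) sample.
#' @export
setClass("AlleleCountTable",
  representation(counts = "matrix", depth = "integer",
                 sample = "character", isConsensus = "logical")
)

setValidity("AlleleCountTable", function(object) {
  if (!is.integer(object@counts)) return("counts must be an integer matrix")
  if (nrow(object@counts) != MT_GENOME_LENGTH)
    return("counts must have one row per genomic position (16,569)")
  if (!identical(colnames(object@counts), MT_BASES))
    return("counts columns must be A, C, G, T in order")
  if (any(object@counts < 0L)) return("counts must be non-negative")
  if (length(object@depth) != MT_GENOME_LENGTH)
    return("depth must have length 16,569")
  if (!identical(as.integer(rowSums(object@counts)), object@depth))
    return("base counts must sum to depth at every position")
  if (length(object@sample) != 1L || length(object@isConsensus) != 1L)
    return("sample and isConsensus must be scalars")
  TRUE
})

#' SomaticVariantSet: per-cell somatic variants of one sample
#'
#' Variants surviving the somatic filter: heteroplasmic within the analysis
#' window, absent from the consensus, private to one cell, and outside mask
#' regions. Also retains the pre-floor variant list (HF > 0 and < 0.98)
#' needed for heteroplasmy-fraction histograms.
#'
#' @slot sample Sample identifier.
#' @slot calls `data.frame` of somatic calls (one row per cell/pos/alt) with
#'   HF, depth, zygosity and provenance flags `maskPassed`, `privacyPassed`,
#'   `consensusAbsent`.
#' @slot preFloor `data.frame` of the pre-floor (HF > 0) variant list.
#' @slot cells Character vector of the post-QC cell universe (cells with
#'   zero somatic variants included).
#' @export
setClass("SomaticVariantSet",
  representation(sample = "character", calls = "data.frame",
                 preFloor = "data.frame", cells = "character")
)

setValidity("SomaticVariantSet", function(object) {
  cl <- object@calls
  need <- c("cell", "pos", "ref", "alt", "hf", "depth")
  if (!all(need %in% names(cl)))
    return(paste("calls must have columns:", paste(need, collapse = ", ")))
  if (nrow(cl) > 0) {
    if (any(!cl$cell %in% object@cells))
      return("calls reference cells outside the cell universe")
    key <- paste(cl$pos, cl$alt)
    if (anyDuplicated(key))
      return("a (position, alt) pair occurs in more than one cell")
  }
  TRUE
})

#' SimSampleConfig: parameters of the single-sample simulator
#'
#' Defaults emulate deep single-cell mtDNA sequencing of bone-marrow
#' mesenchymal stem cells: ~800 mtDNA copies per cell, a shared homoplasmic
#' germline haplotype, 1-7 sample-level heteroplasmies with fractions in
#' [0.02, 0.94], private somatic variants subjected to Wright-Fisher drift,
#' negative-binomial depth around 3000x and symmetric base error.
#'
#' @slot nCells Cells per sample.
#' @slot copyNumber mtDNA copies per cell (Wright-Fisher population size).
#' @slot nGermline Homoplasmic germline variants per sample.
#' @slot nSharedHet Sample-level heteroplasmies; `NA` draws uniformly 1-7.
#' @slot sharedHetRange HF range for sample-level heteroplasmies.
#' @slot somaticRate Expected private somatic variants per cell (Poisson).
#' @slot driftGenerations Divisions over which Wright-Fisher resampling acts.
#' @slot depthMean,depthSize Negative-binomial depth model (mean, size);
#'   `depthSize = Inf` gives fixed depth.
#' @slot errorRate Per-base miscall probability (split evenly across the
#'   three non-reference bases).
#' @slot dloopEnrichment Sampling-weight multiplier for D-loop positions
#'   when placing somatic variants.
#' @slot nLowCoverageCells Number of cells given a low-coverage window so
#'   they fail coverage QC.
#' @slot seed Root seed; all randomness flows from it.
#' @export
setClass("SimSampleConfig",
  representation(nCells = "integer", copyNumber = "integer",
                 nGermline = "integer", nSharedHet = "integer",
                 sharedHetRange = "numeric", somaticRate = "numeric",
                 driftGenerations = "integer", depthMean = "numeric",
                 depthSize = "numeric", errorRate = "numeric",
                 dloopEnrichment = "numeric", nLowCoverageCells = "integer",
                 seed = "integer")
)

setValidity("SimSampleConfig", function(object) {
  if (object@nCells < 1L) return("nCells must be >= 1")
  if (object@copyNumber < 2L) return("copyNumber must be >= 2")
  if (object@nGermline < 0L) return("nGermline must be >= 0")
  if (!is.na(object@nSharedHet) && object@nSharedHet < 0L)
    return("nSharedHet must be >= 0 (or NA to draw)")
  if (length(object@sharedHetRange) != 2L ||
      any(object@sharedHetRange <= 0) || any(object@sharedHetRange >= 1) ||
      diff(object@sharedHetRange) < 0)
    return("sharedHetRange must be an increasing pair in (0, 1)")
  if (object@somaticRate < 0) return("somaticRate must be >= 0")
  if (object@driftGenerations < 0L) return("driftGenerations must be >= 0")
  if (object@depthMean < 0) return("depthMean must be >= 0")
  if (object@errorRate < 0 || object@errorRate >= 0.25)
    return("errorRate must lie in [0, 0.25)")
  if (object@dloopEnrichment <= 0) return("dloopEnrichment must be > 0")
  if (is.na(object@seed)) return("seed is mandatory")
  TRUE
})

setMethod("show", "MtReference", function(object) {
  cat("MtReference", object@name, "-", length(object@sequence), "bp circular\n")
})

setMethod("show", "LocusMap", function(object) {
  cat("LocusMap:", nrow(object@intervals), "intervals;",
      "classes:", paste(names(object@normLengths), collapse = ", "), "\n")
})

setMethod("show", "MaskSet", function(object) {
  cat("MaskSet:", length(object@ranges), "regions,",
      sum(IRanges::width(object@ranges)), "bp masked\n")
})

setMethod("show", "AlleleCountTable", function(object) {
  cat("AlleleCountTable:", object@sample,
      if (object@isConsensus) "(consensus)" else "(single cell)",
      "- median depth", stats::median(object@depth), "\n")
})

setMethod("show", "SomaticVariantSet", function(object) {
  cat("SomaticVariantSet:", object@sample, "-", nrow(object@calls),
      "somatic variants across", length(object@cells), "cells;",
      nrow(object@preFloor), "pre-floor variants\n")
})
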