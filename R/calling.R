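#' Construct an allele-count table
#'
#' @param counts Integer matrix with 16,569 rows and columns `A`, `C`, `G`,
#'   `T` (uncovered positions zero-filled).
#' @param sample Sample identifier.
#' @param isConsensus `TRUE` for a consensus (bulk) sample.
#' @return An [AlleleCountTable-class].
#' @export
alleleCountTable <- function(counts, sample, isConsensus = FALSE) {
  storage.mode(counts) <- "integer"
  new("AlleleCountTable", counts = counts,
      depth = as.integer(rowSums(counts)),
      sample = as.character(sample), isConsensus = isConsensus)
}

#' Heteroplasmic fraction
#'
#' HF is the proportion of variant allele depth relative to reference allele
#' depth: `alt / (alt + ref)`. Other-allele and N reads do not enter the
#' denominator.
#'
#' @param altDepth,refDepth Non-negative integer vectors.
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' computeHF(50, 150)  # 0.25
#' @export
computeHF <- function(altDepth, refDepth) {
  if (any(altDepth < 0) || any(refDepth < 0))
    stop("allele depths must be non-negative")
  total <- altDepth + refDepth
  if (any(total == 0))
    stop("undefined HF: alt + ref depth is zero")
  altDepth / total
}

#' Classify zygosity from a heteroplasmic fraction
#'
#' Homoplasmic: HF > 0.98 (strict). Heteroplasmic: 0.02 < HF <= 0.98.
#' Sub-threshold: HF <= 0.02. The boundaries follow the strict printed
#' definitions, so HF = 0.98 is heteroplasmic and HF = 0.02 is
#' sub-threshold.
#'
#' @param hf Numeric vector in \[0, 1\].
#' @param lower,upper Zygosity thresholds.
#' @return Character vector over
#'   `{"homoplasmic", "heteroplasmic", "sub-threshold"}`.
#' @export
classifyZygosity <- function(hf, lower = 0.02, upper = 0.98) {
  if (any(is.na(hf)) || any(hf < 0 | hf > 1))
    stop("hf must lie in [0, 1]")
  ifelse(hf > upper, "homoplasmic",
         ifelse(hf > lower, "heteroplasmic", "sub-threshold"))
}

#' Call substitutions from an allele-count table
#'
#' Emits one call per (position, non-reference base) with at least one
#' supporting read, so the full sub-threshold tail needed for HF histograms
#' is retained; calls at or below `minLevel` are flagged by their
#' `"sub-threshold"` zygosity rather than dropped. Each call carries a
#' binomial error p-value (probability of at least the observed alt count
#' under `Binomial(depth, errorRate)`). Calls at sites below `minSiteDepth`
#' are flagged low-confidence and excluded from downstream somatic sets.
#' Multi-allelic sites emit one call per alt base.
#'
#' @param x An [AlleleCountTable-class].
#' @param reference An [MtReference-class].
#' @param minLevel Minimum heteroplasmy level for the analysis floor
#'   (default 0.02).
#' @param minSiteDepth Minimum site depth for a confident call.
#' @param errorRate Assumed per-base miscall probability for the error
#'   p-value.
#' @param denominator `"altref"` (default; HF = alt/(alt+ref)) or
#'   `"total"` (HF = alt/depth).
#' @return `data.frame` with columns `pos`, `ref`, `alt`, `altDepth`,
#'   `refDepth`, `depth`, `hf`, `zygosity`, `pError`, `lowConfidence`.
#' @export
callVariants <- function(x, reference, minLevel = 0.02, minSiteDepth = 100L,
                         errorRate = 0.001,
                         denominator = c("altref", "total")) {
  stopifnot(is(x, "AlleleCountTable"), is(reference, "MtReference"))
  denominator <- match.arg(denominator)
  if (minLevel <= 0 || minLevel >= 0.5)
    stop("minLevel must lie in (0, 0.5)")
  ref <- refBase(reference, seq_len(MT_GENOME_LENGTH))
  refIdx <- match(ref, MT_BASES)
  refCount <- x@counts[cbind(seq_len(MT_GENOME_LENGTH), refIdx)]
  out <- vector("list", 4L)
  for (b in seq_along(MT_BASES)) {
    alt <- MT_BASES[b]
    cnt <- x@counts[, b]
    hit <- which(cnt > 0L & refIdx != b & !is.na(refIdx))
    if (!length(hit)) next
    hf <- if (denominator == "altref")
      cnt[hit] / (cnt[hit] + refCount[hit]) else cnt[hit] / x@depth[hit]
    out[[b]] <- data.frame(
      pos = hit, ref = ref[hit], alt = alt, altDepth = cnt[hit],
      refDepth = refCount[hit], depth = x@depth[hit], hf = hf,
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, out)
  if (is.null(calls))
    calls <- data.frame(pos = integer(), ref = character(),
                        alt = character(), altDepth = integer(),
                        refDepth = integer(), depth = integer(),
                        hf = numeric(), stringsAsFactors = FALSE)
  calls <- calls[order(calls$pos, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  calls$zygosity <- if (nrow(calls)) classifyZygosity(calls$hf, lower = minLevel)
                    else character(0)
  calls$pError <- pbinom(calls$altDepth - 1L, calls$depth, errorRate,
                         lower.tail = FALSE)
  calls$lowConfidence <- calls$depth < minSiteDepth
  attr(calls, "sample") <- x@sample
  calls
}

#' Coverage quality control
#'
#' A sample passes QC when the fraction of the 16,569 genomic positions at
#' depth >= `minDepth` is at least `minFraction` (default: 99% of the
#' genome at >= 1500x).
#'
#' @param x An [AlleleCountTable-class].
#' @param minFraction Required covered fraction (default 0.99).
#' @param minDepth Depth threshold (default 1500).
#' @param map Optional [LocusMap-class] for a per-locus-class coverage
#'   summary.
#' @return `data.frame` (one row) with `sample`, `coveredFraction`, `pass`,
#'   and, when a map is given, a `byClass` attribute with per-class covered
#'   fractions.
#' @export
coverageQC <- function(x, minFraction = 0.99, minDepth = 1500L, map = NULL) {
  stopifnot(is(x, "AlleleCountTable"))
  covered <- x@depth >= minDepth
  frac <- mean(covered)
  rep <- data.frame(sample = x@sample, coveredFraction = frac,
                    pass = frac >= minFraction, stringsAsFactors = FALSE)
  if (!is.null(map))
    attr(rep, "byClass") <- tapply(covered, map@classByPos, mean)
  rep
}

#' Summarize an HF distribution around the detection floor
#'
#' Splits heteroplasmic fractions at the detection floor: values at or below
#' the floor (the sub-threshold class) versus values above it (retained for
#' analysis), with percentages.
#'
#' @param hf Numeric vector of heteroplasmic fractions.
#' @param floor Detection floor (default 0.02).
#' @return `data.frame` with `n`, `nBelow`, `nRetained`, `pctBelow`,
#'   `pctRetained`.
#' @export
hfFloorSummary <- function(hf, floor = 0.02) {
  n <- length(hf)
  nBelow <- sum(hf <= floor)
  data.frame(n = n, nBelow = nBelow, nRetained = n - nBelow,
             pctBelow = 100 * nBelow / n,
             pctRetained = 100 * (n - nBelow) / n)
}
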