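#' Simulator configuration
#'
#' Defaults emulate deep single-cell mtDNA sequencing of bone-marrow
#' mesenchymal stem cells: 8 cells per sample, ~800 mtDNA copies per cell,
#' 25 homoplasmic germline variants, 1-7 sample-level heteroplasmies with
#' fractions drawn uniformly in \[0.02, 0.94\], ~40 private somatic variants
#' per cell whose initial fractions follow a low-HF mixture (97%
#' Beta(1, 30), 3% Uniform(0.3, 0.9)) and then drift for 20 Wright-Fisher
#' generations, negative-binomial depth (mean 3000, size 150) and symmetric
#' per-base error 0.001.
#'
#' @param nCells,copyNumber,nGermline,nSharedHet,sharedHetRange,somaticRate
#'   See [SimSampleConfig-class].
#' @param driftGenerations,depthMean,depthSize,errorRate,dloopEnrichment
#'   See [SimSampleConfig-class].
#' @param nLowCoverageCells,seed See [SimSampleConfig-class].
#' @return A [SimSampleConfig-class].
#' @export
simSampleConfig <- function(nCells = 8L, copyNumber = 800L, nGermline = 25L,
                            nSharedHet = NA_integer_,
                            sharedHetRange = c(0.02, 0.94),
                            somaticRate = 40, driftGenerations = 20L,
                            depthMean = 3000, depthSize = 150,
                            errorRate = 0.001, dloopEnrichment = 6,
                            nLowCoverageCells = 0L, seed) {
  new("SimSampleConfig", nCells = as.integer(nCells),
      copyNumber = as.integer(copyNumber), nGermline = as.integer(nGermline),
      nSharedHet = as.integer(nSharedHet),
      sharedHetRange = as.numeric(sharedHetRange),
      somaticRate = as.numeric(somaticRate),
      driftGenerations = as.integer(driftGenerations),
      depthMean = as.numeric(depthMean), depthSize = as.numeric(depthSize),
      errorRate = as.numeric(errorRate),
      dloopEnrichment = as.numeric(dloopEnrichment),
      nLowCoverageCells = as.integer(nLowCoverageCells),
      seed = as.integer(seed))
}

#' Wright-Fisher drift of a heteroplasmic fraction
#'
#' Each generation resamples the variant copy count as
#' `Binomial(copyNumber, current fraction)`; the fraction is the count over
#' `copyNumber`. States 0 and 1 are absorbing. With zero generations the
#' input is returned unchanged. The closed-form variance after t
#' generations is `hf0 (1 - hf0) (1 - (1 - 1/N)^t)`.
#'
#' @param hf0 Initial fraction in \[0, 1\] (scalar).
#' @param copyNumber Population size N (mtDNA copies per cell).
#' @param generations Number of resampling generations.
#' @param n Number of independent replicate trajectories.
#' @return Numeric vector of `n` final fractions.
#' @examples
#' set.seed(1); mean(driftHF(0.1, 800, 20, n = 1000))
#' @export
driftHF <- function(hf0, copyNumber, generations, n = 1L) {
  stopifnot(hf0 >= 0, hf0 <= 1, copyNumber >= 1, generations >= 0)
  f <- rep(hf0, n)
  for (g in seq_len(generations))
    f <- rbinom(n, copyNumber, f) / copyNumber
  f
}

.drawDepth <- function(n, mean, size) {
  if (is.finite(size)) rnbinom(n, mu = mean, size = size)
  else rep(as.integer(round(mean)), n)
}

#' Generate an allele-count table from true variant fractions
#'
#' Per position, depth is drawn from a negative-binomial model (or fixed)
#' and reads are distributed multinomially: at a variant position the alt
#' base has probability `hf (1 - e) + (1 - hf) e/3`, the two other
#' non-reference bases `e/3` each, and the reference the remainder;
#' non-variant positions carry error-only alt reads (`e/3` per non-reference
#' base). Counts always sum to depth.
#'
#' @param trueVariants `data.frame` with columns `pos`, `alt`, `hf` (empty
#'   for a variant-free sample). At most one alt per position.
#' @param depthMean,depthSize Depth model; `depthSize = Inf` fixes depth at
#'   `depthMean`.
#' @param errorRate Per-base miscall probability in \[0, 0.25).
#' @param reference An [MtReference-class].
#' @param sample Sample identifier for the table.
#' @param isConsensus Consensus flag for the table.
#' @param depth Optional pre-drawn integer depth vector (overrides the
#'   model; used for low-coverage windows).
#' @return An [AlleleCountTable-class].
#' @export
generateCounts <- function(trueVariants, depthMean, depthSize = Inf,
                           errorRate = 0, reference,
                           sample = "sim", isConsensus = FALSE,
                           depth = NULL) {
  stopifnot(errorRate >= 0, errorRate < 0.25)
  L <- MT_GENOME_LENGTH
  ref <- refBase(reference, seq_len(L))
  refIdx <- match(ref, MT_BASES)
  if (nrow(trueVariants)) {
    if (anyDuplicated(trueVariants$pos))
      stop("at most one alt base per position is supported")
    if (any(trueVariants$alt == ref[trueVariants$pos]))
      stop("variant alt base equals the reference base")
    if (any(trueVariants$hf < 0 | trueVariants$hf > 1))
      stop("true HF must lie in [0, 1]")
  }
  if (is.null(depth)) depth <- .drawDepth(L, depthMean, depthSize)
  depth <- as.integer(depth)

  e3 <- errorRate / 3
  prob <- matrix(e3, nrow = L, ncol = 4L, dimnames = list(NULL, MT_BASES))
  prob[cbind(seq_len(L), refIdx)] <- 1 - errorRate
  if (nrow(trueVariants)) {
    vpos <- trueVariants$pos
    valt <- match(trueVariants$alt, MT_BASES)
    vref <- refIdx[vpos]
    pAlt <- trueVariants$hf * (1 - errorRate) + (1 - trueVariants$hf) * e3
    prob[cbind(vpos, valt)] <- pAlt
    prob[cbind(vpos, vref)] <- 1 - pAlt - 2 * e3
  }
  # sequential binomial decomposition of the per-position multinomial
  counts <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, MT_BASES))
  remaining <- depth
  pLeft <- rep(1, L)
  for (b in 1:3) {
    p <- ifelse(pLeft > 0, prob[, b] / pLeft, 0)
    p <- pmin(pmax(p, 0), 1)
    counts[, b] <- rbinom(L, remaining, p)
    remaining <- remaining - counts[, b]
    pLeft <- pLeft - prob[, b]
  }
  counts[, 4L] <- remaining
  alleleCountTable(counts, sample = sample, isConsensus = isConsensus)
}

.drawAlt <- function(ref, transitionProb = 0.85) {
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  vapply(ref, function(r) {
    others <- setdiff(MT_BASES, r)
    w <- ifelse(others == transition[[r]], transitionProb,
                (1 - transitionProb) / 2)
    sample(others, 1L, prob = w)
  }, character(1L), USE.NAMES = FALSE)
}

.drawSomaticHF <- function(n, highFraction = 0.03) {
  high <- runif(n) < highFraction
  hf <- rbeta(n, 1, 30)
  hf[high] <- runif(sum(high), 0.3, 0.9)
  hf
}

#' Simulate one sample: per-cell and consensus allele counts with truth
#'
#' Generates a shared homoplasmic germline haplotype, sample-level
#' heteroplasmies (fractions drifting independently per cell), and private
#' somatic variants per cell (positions drawn without replacement across
#' the sample's cells from unmasked positions, D-loop positions upweighted
#' by `dloopEnrichment`; initial fractions from the low-HF mixture, then
#' Wright-Fisher drift). The consensus table is generated from the pooled
#' true fractions: germline at 1.0, shared heteroplasmies at their sample
#' fraction, private somatic variants diluted to `hf / nCells`. The first
#' `nLowCoverageCells` cells receive a low-coverage window spanning 5% of
#' the genome so they fail coverage QC.
#'
#' Ground truth records, per cell, every variant with its true fraction and
#' type, the expected consensus fraction, and an `expectedSomatic` flag:
#' private somatic variants whose cell fraction lies strictly inside
#' (0.02, 0.98) and whose diluted consensus fraction is below the 0.02
#' detection floor - exactly the variants the somatic definition can
#' recover.
#'
#' @param config A [SimSampleConfig-class]; its seed drives all randomness.
#' @param reference An [MtReference-class] (default: packaged).
#' @param masks A [MaskSet-class] (default: packaged).
#' @param map A [LocusMap-class] (default: packaged).
#' @param sampleName Sample identifier.
#' @return List with `cells` (named list of [AlleleCountTable-class]),
#'   `consensus` ([AlleleCountTable-class]), `truth` (`data.frame`:
#'   `cell`, `pos`, `ref`, `alt`, `hf`, `type`, `consensusFraction`,
#'   `expectedSomatic`), `sampleTruth` (germline + shared variants), and
#'   `config`.
#' @export
simulateSample <- function(config, reference = mtReference(),
                           masks = maskSet(), map = locusMap(),
                           sampleName = "S1") {
  set.seed(config@seed)
  L <- MT_GENOME_LENGTH
  ref <- refBase(reference, seq_len(L))
  pool <- setdiff(seq_len(L), maskedPositions(masks))
  pool <- pool[ref[pool] != "N"]

  nShared <- if (is.na(config@nSharedHet)) sample.int(7L, 1L)
             else config@nSharedHet
  nBackground <- config@nGermline + nShared
  bgPos <- sort(sample(pool, nBackground))
  germPos <- bgPos[seq_len(config@nGermline)]
  sharedPos <- setdiff(bgPos, germPos)
  sharedHF <- runif(nShared, config@sharedHetRange[1L],
                    config@sharedHetRange[2L])
  sampleTruth <- data.frame(
    pos = c(germPos, sharedPos),
    ref = ref[c(germPos, sharedPos)],
    alt = .drawAlt(ref[c(germPos, sharedPos)]),
    hf = c(rep(1, config@nGermline), sharedHF),
    type = c(rep("germline", config@nGermline), rep("shared", nShared)),
    stringsAsFactors = FALSE)

  # private somatic positions: sampled without replacement across all cells
  cellNames <- sprintf("%s_c%02d", sampleName, seq_len(config@nCells))
  nSomatic <- rpois(config@nCells, config@somaticRate)
  somPool <- setdiff(pool, bgPos)
  somPool <- somPool[map@classByPos[somPool] != "intergenic"]
  w <- ifelse(map@classByPos[somPool] == "D-loop", config@dloopEnrichment, 1)
  somPos <- sample(somPool, sum(nSomatic), prob = w)
  somCell <- rep(cellNames, nSomatic)
  hf0 <- .drawSomaticHF(sum(nSomatic))
  somHF <- vapply(hf0, function(h)
    driftHF(h, config@copyNumber, config@driftGenerations), numeric(1L))

  somatic <- data.frame(cell = somCell, pos = somPos, ref = ref[somPos],
                        alt = .drawAlt(ref[somPos]), hf = somHF,
                        type = rep("somatic", length(somPos)),
                        stringsAsFactors = FALSE)
  somatic <- somatic[somatic$hf > 0, , drop = FALSE]  # drift losses

  cellTruthList <- vector("list", config@nCells)
  cells <- vector("list", config@nCells)
  names(cells) <- cellNames
  lowWindow <- as.integer(round(0.05 * L))
  for (i in seq_len(config@nCells)) {
    cn <- cellNames[i]
    # shared heteroplasmies drift independently in each cell
    cellShared <- vapply(sharedHF, function(h)
      driftHF(h, config@copyNumber, config@driftGenerations), numeric(1L))
    mine <- somatic[somatic$cell == cn, , drop = FALSE]
    truth <- rbind(
      data.frame(cell = rep(cn, length(germPos)), pos = germPos,
                 ref = ref[germPos],
                 alt = sampleTruth$alt[seq_len(config@nGermline)],
                 hf = rep(1, length(germPos)),
                 type = rep("germline", length(germPos)),
                 stringsAsFactors = FALSE),
      data.frame(cell = rep(cn, length(sharedPos)), pos = sharedPos,
                 ref = ref[sharedPos],
                 alt = sampleTruth$alt[config@nGermline + seq_len(nShared)],
                 hf = cellShared, type = rep("shared", length(sharedPos)),
                 stringsAsFactors = FALSE),
      mine[, c("cell", "pos", "ref", "alt", "hf", "type")])
    truth <- truth[truth$hf > 0, , drop = FALSE]
    depth <- .drawDepth(L, config@depthMean, config@depthSize)
    if (i <= config@nLowCoverageCells) {
      s <- sample.int(L - lowWindow, 1L)
      depth[s:(s + lowWindow - 1L)] <- rpois(lowWindow, 20)
    }
    cells[[i]] <- generateCounts(truth[, c("pos", "alt", "hf")],
                                 depthMean = config@depthMean,
                                 depthSize = config@depthSize,
                                 errorRate = config@errorRate,
                                 reference = reference, sample = cn,
                                 depth = depth)
    cellTruthList[[i]] <- truth
  }
  truth <- do.call(rbind, cellTruthList)
  rownames(truth) <- NULL

  # consensus: cell-weighted pooled fractions; private somatics diluted
  consFrac <- setNames(rep(0, nrow(truth)), NULL)
  key <- paste(truth$pos, truth$alt)
  dilution <- ifelse(truth$type == "somatic", truth$hf / config@nCells,
                     NA_real_)
  consTab <- rbind(
    data.frame(pos = sampleTruth$pos, alt = sampleTruth$alt,
               hf = sampleTruth$hf, stringsAsFactors = FALSE),
    data.frame(pos = truth$pos[truth$type == "somatic"],
               alt = truth$alt[truth$type == "somatic"],
               hf = truth$hf[truth$type == "somatic"] / config@nCells,
               stringsAsFactors = FALSE))
  consensus <- generateCounts(consTab, depthMean = config@depthMean,
                              depthSize = config@depthSize,
                              errorRate = config@errorRate,
                              reference = reference,
                              sample = paste0(sampleName, "_consensus"),
                              isConsensus = TRUE)
  consKey <- paste(consTab$pos, consTab$alt)
  truth$consensusFraction <- consTab$hf[match(key, consKey)]
  truth$expectedSomatic <- truth$type == "somatic" &
    truth$hf > 0.02 & truth$hf < 0.98 & truth$consensusFraction < 0.02

  list(cells = cells, consensus = consensus, truth = truth,
       sampleTruth = sampleTruth, config = config)
}

#' Simulate a multi-sample study
#'
#' Runs [simulateSample()] for `nSamples` samples, deriving one sub-seed per
#' sample from the root seed. The default emulates a 13-sample cohort.
#'
#' @param nSamples Number of samples (default 13).
#' @param seed Root seed.
#' @param configFn Function `(sampleIndex, seed) -> SimSampleConfig`;
#'   the default applies `...` to [simSampleConfig()].
#' @param reference,masks,map Shared genome resources (defaults: packaged).
#' @param ... Passed to [simSampleConfig()] by the default `configFn`.
#' @return Named list of [simulateSample()] results (`S1` ... `Sn`).
#' @export
simulateStudy <- function(nSamples = 13L, seed, configFn = NULL,
                          reference = mtReference(), masks = maskSet(),
                          map = locusMap(), ...) {
  set.seed(seed)
  subSeeds <- sample.int(.Machine$integer.max - 1L, nSamples)
  if (is.null(configFn))
    configFn <- function(i, s) simSampleConfig(seed = s, ...)
  out <- lapply(seq_len(nSamples), function(i)
    simulateSample(configFn(i, subSeeds[i]), reference = reference,
                   masks = masks, map = map, sampleName = paste0("S", i)))
  names(out) <- paste0("S", seq_len(nSamples))
  out
}

#' Fabricate pathogenicity score tables for simulated variants
#'
#' Emulates predictor score distributions skewed toward pathogenicity with
#' Beta mixtures: MutPred-like scores from 0.8 Beta(6, 2) + 0.2 Beta(2, 6)
#' and more conservative APOGEE2-like scores from 0.5 Beta(5, 3) +
#' 0.5 Beta(1.5, 5). Only protein-coding substitutions receive scores.
#'
#' @param variants `data.frame` with columns `pos`, `ref`, `alt`.
#' @param seed Seed for the score draws.
#' @param coverage Fraction of variants present in each table (the rest
#'   stay unscored).
#' @return List of two [scoreTable()]s: `mutpred`, `apogee2`.
#' @export
simulateScoreTables <- function(variants, seed, coverage = 0.95) {
  set.seed(seed)
  u <- unique(variants[, c("pos", "ref", "alt")])
  n <- nrow(u)
  drawMix <- function(n, w, a1, b1, a2, b2) {
    pick <- runif(n) < w
    ifelse(pick, rbeta(n, a1, b1), rbeta(n, a2, b2))
  }
  keep1 <- runif(n) < coverage
  keep2 <- runif(n) < coverage
  mut <- cbind(u[keep1, , drop = FALSE],
               score = drawMix(sum(keep1), 0.8, 6, 2, 2, 6))
  apo <- cbind(u[keep2, , drop = FALSE],
               score = drawMix(sum(keep2), 0.5, 5, 3, 1.5, 5))
  list(mutpred = scoreTable(mut, tool = "MutPred"),
       apogee2 = scoreTable(apo, tool = "APOGEE2"))
}
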