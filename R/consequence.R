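#' Validate a pathogenicity score table
#'
#' Score tables map (position, ref, alt) substitutions to predictor scores
#' in \[0, 1\]. Lookups outside the table are "unscored" (`NA`), never a
#' default value.
#'
#' @param x `data.frame` with columns `pos`, `ref`, `alt`, `score` (and
#'   optionally `tool`), or a path to such a TSV.
#' @param tool Provenance label, e.g. `"MutPred"` or `"APOGEE2"`.
#' @return Validated `data.frame` with a `tool` attribute.
#' @export
scoreTable <- function(x, tool = "score") {
  if (is.character(x))
    x <- read.table(x, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("pos", "ref", "alt", "score")
  if (!all(need %in% names(x)))
    stop("score table needs columns: ", paste(need, collapse = ", "))
  if (any(is.na(x$score)) || any(x$score < 0 | x$score > 1))
    stop("scores must lie in [0, 1]")
  if (anyDuplicated(paste(x$pos, x$ref, x$alt)))
    stop("duplicated (pos, ref, alt) entries in score table")
  attr(x, "tool") <- tool
  x
}

.mutateCodon <- function(codon, offset, base) {
  substr(codon, offset + 1L, offset + 1L) <- base
  codon
}

#' Annotate variants with locus class and protein-level consequence
#'
#' For protein-coding positions the reference codon is obtained strand-aware
#' via [codonContext()], the alternate base substituted (reverse-complemented
#' for light-strand genes such as MT-ND6), and both codons translated under
#' the vertebrate mitochondrial genetic code. Identical residues are
#' synonymous; differing residues non-synonymous, with `stop_gain` /
#' `stop_loss` sub-flags. When a position lies in overlapping genes all are
#' evaluated and the most severe consequence (non-synonymous over
#' synonymous, ties broken by genome order) is reported. Non-protein
#' positions are `non-coding`.
#'
#' @param calls Call `data.frame` with columns `pos`, `ref`, `alt` (e.g.
#'   [somaticCalls()] output).
#' @param map A [LocusMap-class].
#' @param reference The [MtReference-class] the calls were made against; a
#'   mismatch between a call's `ref` and the reference sequence is an error.
#' @return The input with added columns `locusClass`, `gene`, `consequence`
#'   (`synonymous`/`non-synonymous`/`non-coding`), `subType` (`stop_gain`,
#'   `stop_loss` or `NA`), `refAA`, `altAA`, `incompleteStopCaveat`.
#' @export
annotateConsequence <- function(calls, map, reference) {
  n <- nrow(calls)
  loc <- if (n) locusOf(calls$pos, map) else
    data.frame(class = character(), name = character())
  calls$locusClass <- loc$class
  calls$gene <- loc$name
  calls$consequence <- rep("non-coding", n)
  calls$subType <- rep(NA_character_, n)
  calls$refAA <- rep(NA_character_, n)
  calls$altAA <- rep(NA_character_, n)
  calls$incompleteStopCaveat <- rep(FALSE, n)
  if (!n) return(calls)

  seqRef <- refBase(reference, calls$pos)
  bad <- calls$ref != seqRef
  if (any(bad))
    stop("reference base mismatch at position(s) ",
         paste(head(calls$pos[bad]), collapse = ", "),
         ": calls were made against a different reference")

  pc <- map@intervals[map@intervals$class == "protein-coding", , drop = FALSE]
  for (i in seq_len(n)) {
    p <- calls$pos[i]
    genes <- pc[pc$start <= p & pc$end >= p, , drop = FALSE]
    if (!nrow(genes)) next
    best <- NULL
    for (g in seq_len(nrow(genes))) {
      gene <- genes[g, ]
      ctx <- codonContext(p, gene, map, reference)
      altBase <- if (gene$strand == "light")
        .COMPLEMENT[[calls$alt[i]]] else calls$alt[i]
      altCodon <- .mutateCodon(ctx$codon, ctx$offset, altBase)
      refAA <- translateCodons(ctx$codon)
      altAA <- translateCodons(altCodon)
      cons <- if (identical(refAA, altAA)) "synonymous" else "non-synonymous"
      sub <- if (cons == "non-synonymous" && altAA == "*") "stop_gain"
             else if (cons == "non-synonymous" && refAA == "*") "stop_loss"
             else NA_character_
      cand <- list(gene = gene$name, consequence = cons, subType = sub,
                   refAA = refAA, altAA = altAA,
                   caveat = ctx$incompleteStop)
      if (is.null(best) ||
          (best$consequence == "synonymous" && cons == "non-synonymous"))
        best <- cand
    }
    calls$gene[i] <- best$gene
    calls$consequence[i] <- best$consequence
    calls$subType[i] <- best$subType
    calls$refAA[i] <- best$refAA
    calls$altAA[i] <- best$altAA
    calls$incompleteStopCaveat[i] <- best$caveat
  }
  calls
}

#' Classify pathogenicity from score tables
#'
#' Applies the predictor thresholds independently and strictly: a MutPred
#' score > 0.50 or an APOGEE 2 score > 0.38 flags a variant as predicted
#' pathogenic. Only protein-coding variants are scored; unscored variants
#' carry `NA` flags and are excluded from pathogenic-fraction denominators.
#'
#' @param annotated Output of [annotateConsequence()].
#' @param mutpred,apogee2 Optional [scoreTable()]s.
#' @param mutpredThreshold,apogee2Threshold Strict thresholds (defaults 0.50
#'   and 0.38).
#' @return The input with added columns `mutpredScore`, `apogee2Score`,
#'   `pathogenicMutpred`, `pathogenicApogee2`.
#' @export
classifyPathogenicity <- function(annotated, mutpred = NULL, apogee2 = NULL,
                                  mutpredThreshold = 0.50,
                                  apogee2Threshold = 0.38) {
  lookup <- function(tab) {
    s <- rep(NA_real_, nrow(annotated))
    if (is.null(tab)) return(s)
    tab <- scoreTable(tab, tool = attr(tab, "tool"))
    coding <- annotated$consequence %in% c("synonymous", "non-synonymous")
    idx <- match(paste(annotated$pos, annotated$ref, annotated$alt),
                 paste(tab$pos, tab$ref, tab$alt))
    s[coding] <- tab$score[idx[coding]]
    s
  }
  annotated$mutpredScore <- lookup(mutpred)
  annotated$apogee2Score <- lookup(apogee2)
  annotated$pathogenicMutpred <- annotated$mutpredScore > mutpredThreshold
  annotated$pathogenicApogee2 <- annotated$apogee2Score > apogee2Threshold
  annotated
}
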