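#' Per-cell, per-locus somatic burden
#'
#' Counts somatic variants per cell and locus class and normalizes by the
#' fixed locus-class lengths carried by the map (D-loop 1124, rRNA 2511,
#' tRNA 1486, protein-coding 11,382). Cells with no variants contribute
#' all-zero rows; intergenic variants (none under the packaged annotation's
#' burden precedence) are dropped with a warning.
#'
#' @param x A [SomaticVariantSet-class] or a list of them (multi-sample).
#' @param map A [LocusMap-class].
#' @return `data.frame` with columns `sample`, `cell`, `locusClass`,
#'   `count`, `normCount`, plus a per-cell `total` repeated across the
#'   cell's rows.
#' @export
burdenByLocus <- function(x, map) {
  if (is(x, "SomaticVariantSet")) x <- list(x)
  rows <- lapply(x, function(svs) {
    calls <- somaticCalls(svs)
    cls <- if (nrow(calls)) locusOf(calls$pos, map)$class else character(0)
    if (any(cls == "intergenic")) {
      warning("dropping variants in intergenic positions from burden")
      calls <- calls[cls != "intergenic", , drop = FALSE]
      cls <- cls[cls != "intergenic"]
    }
    grid <- expand.grid(cell = sampleCells(svs), locusClass = LOCUS_CLASSES,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tab <- table(factor(calls$cell, levels = sampleCells(svs)),
                 factor(cls, levels = LOCUS_CLASSES))
    grid$count <- as.integer(tab[cbind(grid$cell, grid$locusClass)])
    grid$normCount <- grid$count / as.numeric(map@normLengths[grid$locusClass])
    grid$sample <- svs@sample
    tot <- tapply(grid$count, grid$cell, sum)
    grid$total <- as.integer(tot[grid$cell])
    grid[, c("sample", "cell", "locusClass", "count", "normCount", "total")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

SUBSTITUTION_CLASSES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                          "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

#' Substitution spectrum of somatic variants
#'
#' Tabulates the 12 reference-strand substitution classes (T>C and A>G are
#' reported separately, not pyrimidine-collapsed) with counts and
#' percentages over all variants pooled across cells and samples.
#'
#' @param x A [SomaticVariantSet-class], a list of them, or a call
#'   `data.frame` with `ref` and `alt` columns.
#' @return `data.frame` with columns `class`, `count`, `percent`.
#' @export
substitutionSpectrum <- function(x) {
  if (is(x, "SomaticVariantSet")) x <- list(x)
  calls <- if (is.data.frame(x)) x
           else do.call(rbind, lapply(x, somaticCalls))
  lab <- if (nrow(calls)) paste0(calls$ref, ">", calls$alt) else character(0)
  cnt <- table(factor(lab, levels = SUBSTITUTION_CLASSES))
  n <- sum(cnt)
  data.frame(class = SUBSTITUTION_CLASSES, count = as.integer(cnt),
             percent = if (n) 100 * as.integer(cnt) / n else rep(0, 12L),
             stringsAsFactors = FALSE)
}

#' Dunnett's many-to-one comparisons
#'
#' Single-step Dunnett test of each group mean against a designated
#' reference group, via the multivariate-t distribution: statistics are the
#' usual two-sample t-statistics on the pooled within-group error, and each
#' two-sided adjusted p-value is one minus the probability that all
#' comparison statistics fall inside the observed bound, evaluated with the
#' Genz-Bretz algorithm (absolute tolerance `abseps`, default 1e-6).
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (coerced to factor).
#' @param reference The reference group level.
#' @param abseps Absolute tolerance of the multivariate-t integration.
#' @return `data.frame` with one row per comparison: `comparison`,
#'   `estimate`, `statistic`, `df`, `p`, `reference`.
#' @export
dunnettTest <- function(values, groups, reference, abseps = 1e-6) {
  groups <- factor(groups)
  if (!reference %in% levels(groups))
    stop("reference group not present: ", reference)
  groups <- stats::relevel(groups, ref = reference)
  ni <- table(groups)
  if (any(ni < 2L)) {
    warning("dropping group(s) with < 2 observations: ",
            paste(names(ni)[ni < 2L], collapse = ", "))
    keep <- groups %in% names(ni)[ni >= 2L]
    values <- values[keep]
    groups <- droplevels(groups[keep])
    ni <- table(groups)
  }
  k <- nlevels(groups) - 1L
  if (k < 1L) stop("need at least one non-reference group")
  N <- length(values)
  means <- tapply(values, groups, mean)
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) /
    (N - (k + 1L))
  n0 <- ni[[1L]]
  others <- levels(groups)[-1L]
  est <- means[others] - means[[1L]]
  se <- sqrt(mse * (1 / ni[others] + 1 / n0))
  tstat <- est / se
  lambda <- sqrt(ni[others] / (ni[others] + n0))
  corr <- outer(lambda, lambda)
  diag(corr) <- 1
  df <- N - (k + 1L)
  p <- vapply(abs(tstat), function(b) {
    if (!is.finite(b)) return(0)
    1 - mvtnorm::pmvt(lower = rep(-b, k), upper = rep(b, k), df = df,
                      corr = corr,
                      algorithm = mvtnorm::GenzBretz(abseps = abseps,
                                                     maxpts = 250000L))[1L]
  }, numeric(1L))
  data.frame(comparison = paste(others, "-", levels(groups)[1L]),
             estimate = as.numeric(est), statistic = as.numeric(tstat),
             df = df, p = pmax(pmin(p, 1), 0),
             reference = levels(groups)[1L],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-way ANOVA plus Dunnett many-to-one comparisons
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector.
#' @param reference Reference group for Dunnett's comparisons.
#' @param abseps Multivariate-t integration tolerance.
#' @return `data.frame` of test results: an `anova` row (F statistic,
#'   unadjusted p) followed by one `dunnett` row per comparison (t
#'   statistic, single-step adjusted p). P-values are reported unadjusted
#'   for multiplicity across tests.
#' @export
anovaDunnett <- function(values, groups, reference, abseps = 1e-6) {
  groups <- factor(groups)
  ni <- table(groups)
  if (any(ni < 2L)) {
    warning("excluding group(s) with < 2 observations: ",
            paste(names(ni)[ni < 2L], collapse = ", "))
    keep <- groups %in% names(ni)[ni >= 2L]
    values <- values[keep]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  fit <- aov(values ~ groups)
  an <- summary(fit)[[1L]]
  anRow <- data.frame(test = "anova", comparison = "all groups",
                      statistic = an[["F value"]][1L], p = an[["Pr(>F)"]][1L],
                      reference = NA_character_, stringsAsFactors = FALSE)
  dn <- dunnettTest(values, groups, reference, abseps = abseps)
  dnRows <- data.frame(test = "dunnett", comparison = dn$comparison,
                       statistic = dn$statistic, p = dn$p,
                       reference = dn$reference, stringsAsFactors = FALSE)
  rbind(anRow, dnRows)
}

#' Compare somatic burdens across samples or locus classes
#'
#' `grouping = "sample"` compares per-cell total somatic counts between
#' samples (reference: the designated sample, conventionally the first).
#' `grouping = "locusClass"` compares per-cell length-normalized counts
#' between locus classes (reference: conventionally the D-loop). Counts are
#' treated as continuous in the ANOVA; `method = "kruskal"` substitutes a
#' Kruskal-Wallis test for the ANOVA row.
#'
#' @param burdens Output of [burdenByLocus()].
#' @param grouping `"sample"` or `"locusClass"`.
#' @param reference Reference group for Dunnett's test.
#' @param method `"anova"` (default) or `"kruskal"`.
#' @return `data.frame` of test results (see [anovaDunnett()]).
#' @export
compareBurdens <- function(burdens, grouping = c("sample", "locusClass"),
                           reference = NULL, method = c("anova", "kruskal")) {
  grouping <- match.arg(grouping)
  method <- match.arg(method)
  if (grouping == "sample") {
    percell <- unique(burdens[, c("sample", "cell", "total")])
    values <- percell$total
    groups <- percell$sample
    if (is.null(reference)) reference <- sort(unique(groups))[1L]
  } else {
    values <- burdens$normCount
    groups <- burdens$locusClass
    if (is.null(reference)) reference <- "D-loop"
  }
  res <- anovaDunnett(values, groups, reference)
  if (method == "kruskal") {
    kw <- stats::kruskal.test(values, factor(groups))
    res[res$test == "anova", c("test", "statistic", "p")] <-
      list("kruskal", unname(kw$statistic), kw$p.value)
  }
  res
}

#' Compare heteroplasmic-fraction distributions between groups
#'
#' With more than two groups: one-way ANOVA on the HF values plus Dunnett
#' many-to-one comparisons against the reference group (variants are the
#' units; cells without variants contribute no values). With exactly two
#' groups (e.g. non-synonymous versus synonymous): two-sided Mann-Whitney U
#' test with normal approximation and continuity correction.
#'
#' @param hf Numeric vector of heteroplasmic fractions (one per variant).
#' @param groups Grouping vector parallel to `hf`.
#' @param reference Reference group (multi-group case); defaults to the
#'   first sorted level.
#' @return `data.frame` of test results.
#' @export
compareHFDistributions <- function(hf, groups, reference = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) == 2L) {
    lev <- levels(groups)
    wt <- wilcox.test(hf[groups == lev[1L]], hf[groups == lev[2L]],
                      alternative = "two.sided", exact = FALSE,
                      correct = TRUE)
    return(data.frame(test = "mann-whitney",
                      comparison = paste(lev[1L], "vs", lev[2L]),
                      statistic = unname(wt$statistic), p = wt$p.value,
                      reference = NA_character_, stringsAsFactors = FALSE))
  }
  if (is.null(reference)) reference <- sort(levels(groups))[1L]
  anovaDunnett(hf, groups, reference)
}

#' Shape statistics of a pathogenicity score distribution
#'
#' Reports kurtosis in both conventions - `kurtosisExcess` (normal = 0) and
#' `kurtosisPearson` (normal = 3; Pearson = excess + 3) - a Shapiro-Wilk
#' normality p-value, and the count and fraction of scores strictly above
#' the pathogenicity threshold. Shape statistics require at least 8 scores
#' and non-degenerate variance; otherwise they are `NA` while the counts
#' are still returned. The fraction's denominator is the number of scored
#' variants.
#'
#' @param scores Numeric vector of predictor scores (NAs dropped).
#' @param threshold Strict pathogenicity threshold.
#' @return `data.frame` with `n`, `kurtosisExcess`, `kurtosisPearson`,
#'   `shapiroP`, `pathogenicCount`, `pathogenicFraction`.
#' @export
scoreShape <- function(scores, threshold) {
  scores <- scores[!is.na(scores)]
  n <- length(scores)
  cnt <- sum(scores > threshold)
  kE <- kP <- shp <- NA_real_
  if (n >= 8L && sd(scores) > 0) {
    kE <- e1071::kurtosis(scores, type = 1)
    kP <- kE + 3
    shp <- tryCatch(shapiro.test(if (n > 5000) scores[seq_len(5000)]
                                 else scores)$p.value,
                    error = function(e) NA_real_)
  }
  data.frame(n = n, kurtosisExcess = kE, kurtosisPearson = kP,
             shapiroP = shp, pathogenicCount = cnt,
             pathogenicFraction = if (n) cnt / n else NA_real_)
}
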