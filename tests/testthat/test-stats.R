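fakeSVS <- function(df, cells, sample = "S") {
  need <- c("altDepth", "refDepth", "depth", "zygosity", "pError",
            "lowConfidence", "maskPassed", "privacyPassed",
            "consensusAbsent")
  for (nm in need) if (!nm %in% names(df))
    df[[nm]] <- if (nm %in% c("altDepth", "refDepth", "depth")) 2000L
                else if (nm == "zygosity") "heteroplasmic"
                else if (nm == "pError") 0 else TRUE
  df$lowConfidence <- FALSE
  new("SomaticVariantSet", sample = sample, calls = df,
      preFloor = df, cells = cells)
}

test_that("burden normalization divides by the printed locus lengths and
           zero-variant cells keep all-zero rows", {
  pool <- setdiff(seq_len(GENOME_LEN), maskedPositions(MASKS))
  dpos <- pool[locusOf(pool, MAP)$class == "D-loop"][1:2]
  df <- data.frame(cell = "c1", pos = dpos, ref = refBase(REF, dpos),
                   alt = "A", hf = 0.1, stringsAsFactors = FALSE)
  df$alt <- vapply(df$ref, function(r)
    setdiff(c("A", "C", "G", "T"), r)[1], character(1))
  svs <- fakeSVS(df, cells = c("c1", "c2"))
  b <- burdenByLocus(svs, MAP)
  expect_equal(b$normCount[b$cell == "c1" & b$locusClass == "D-loop"],
               2 / 1124)
  expect_true(all(b$count[b$cell == "c2"] == 0))
  expect_identical(unique(b$total[b$cell == "c1"]), 2L)
  # linearity: doubling the variant list doubles normalized counts
  df2 <- df; df2$pos <- pool[locusOf(pool, MAP)$class == "D-loop"][3:4]
  df2$ref <- refBase(REF, df2$pos)
  df2$alt <- vapply(df2$ref, function(r)
    setdiff(c("A", "C", "G", "T"), r)[1], character(1))
  svs2 <- fakeSVS(rbind(df, df2), cells = c("c1", "c2"))
  b2 <- burdenByLocus(svs2, MAP)
  expect_equal(b2$normCount[b2$cell == "c1" & b2$locusClass == "D-loop"],
               2 * b$normCount[b$cell == "c1" & b$locusClass == "D-loop"])
})

test_that("substitution spectrum reports literal reference-strand classes
           summing to 100 percent", {
  df <- data.frame(ref = c("T", "T", "A"), alt = c("C", "C", "G"))
  sp <- substitutionSpectrum(df)
  expect_equal(sp$percent[sp$class == "T>C"], 200 / 3)
  expect_equal(sp$percent[sp$class == "A>G"], 100 / 3)
  expect_equal(sum(sp$percent), 100, tolerance = 0.0005)
  empty <- substitutionSpectrum(df[0, ])
  expect_true(all(empty$count == 0) && all(empty$percent == 0))
  # error-free simulated truth away from the decision boundaries is
  # reproduced exactly
  sim <- simulateSample(simSampleConfig(nCells = 3L, errorRate = 0,
                                        seed = 404L), REF, MASKS, MAP)
  res <- runSample(sim$cells, sim$consensus, REF, MASKS, errorRate = 1e-4)
  band <- sim$truth[sim$truth$expectedSomatic & sim$truth$hf >= 0.05 &
                      sim$truth$hf <= 0.9 &
                      sim$truth$consensusFraction < 0.015, ]
  calls <- somaticCalls(res$somatic)
  key <- function(d) paste(d$cell, d$pos, d$alt)
  expect_true(all(key(band) %in% key(calls)))
  spTruth <- substitutionSpectrum(band)
  spCalls <- substitutionSpectrum(calls[key(calls) %in% key(band), ])
  expect_equal(spCalls$count, spTruth$count)
})

test_that("identical groups give a null ANOVA and flat Mann-Whitney", {
  g <- rep(c("a", "b"), each = 20)
  v <- rep(seq_len(20), 2)
  res <- compareHFDistributions(v / 40, g)
  expect_identical(res$test, "mann-whitney")
  expect_gt(res$p, 0.95)
  res3 <- anovaDunnett(c(v, seq_len(20)) / 40,
                       c(g, rep("c", 20)), reference = "a")
  expect_equal(res3$statistic[res3$test == "anova"], 0, tolerance = 1e-12)
  expect_equal(res3$p[res3$test == "anova"], 1)
  expect_true(all(res3$p[res3$test == "dunnett"] > 0.999))
})

test_that("Dunnett statistics match an independent implementation", {
  skip_if_not_installed("multcomp")
  set.seed(77)
  df <- data.frame(
    y = c(rnorm(12, 10, 2), rnorm(10, 12, 2), rnorm(14, 9.5, 2)),
    g = factor(rep(c("ctrl", "t1", "t2"), c(12, 10, 14))))
  mine <- dunnettTest(df$y, df$g, reference = "ctrl")
  fit <- stats::aov(y ~ g, data = df)
  set.seed(1)
  gl <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
  expect_equal(mine$statistic, unname(gl$test$tstat), tolerance = 1e-8)
  # the reference integrates the multivariate t by quasi-Monte-Carlo at
  # absolute tolerance 1e-3; agreement is bounded by that
  expect_equal(mine$p, as.numeric(gl$test$pvalues), tolerance = 2e-3,
               ignore_attr = TRUE)
})

test_that("a shifted group is detected by Dunnett and Mann-Whitney", {
  set.seed(88)
  ns <- rbeta(200, 3, 6) * 0.5 + 0.25
  s <- rbeta(200, 2, 8) * 0.5
  res <- compareHFDistributions(c(ns, s),
                                rep(c("NS", "S"), each = 200))
  expect_lt(res$p, 0.05)
  b <- data.frame(v = c(rnorm(30, 5), rnorm(30, 5), rnorm(30, 8)),
                  g = rep(c("ref", "g1", "g2"), each = 30))
  dn <- dunnettTest(b$v, b$g, reference = "ref")
  expect_lt(dn$p[dn$comparison == "g2 - ref"], 0.05)
  expect_gt(dn$p[dn$comparison == "g1 - ref"], 0.05)
})

test_that("a D-loop-enriched simulation yields a significant D-loop excess", {
  sims <- simulateStudy(nSamples = 3L, seed = 515L, nCells = 6L,
                        dloopEnrichment = 8)
  svsList <- lapply(names(sims), function(nm)
    runSample(sims[[nm]]$cells, sims[[nm]]$consensus, REF, MASKS,
              sampleName = nm)$somatic)
  b <- burdenByLocus(svsList, MAP)
  res <- compareBurdens(b, grouping = "locusClass", reference = "D-loop")
  expect_lt(res$p[res$test == "anova"], 0.05)
  expect_true(all(res$p[res$test == "dunnett"] < 0.05))
  # groups with too few observations are excluded with a warning
  expect_warning(anovaDunnett(c(1, 2, 3, 4, 5), c("a", "a", "b", "b", "c"),
                              reference = "a"), "< 2 observations")
})

test_that("score shape reports both kurtosis conventions and strict
           pathogenic counts", {
  s <- scoreShape(c(0.6, 0.7, 0.2), threshold = 0.5)
  expect_identical(s$pathogenicCount, 2L)
  expect_equal(s$pathogenicFraction, 2 / 3)
  expect_true(is.na(s$kurtosisExcess))  # below the n >= 8 minimum

  deg <- scoreShape(rep(0.4, 20), threshold = 0.5)
  expect_true(is.na(deg$kurtosisExcess))
  expect_identical(deg$pathogenicCount, 0L)

  set.seed(99)
  x <- rnorm(5000)
  sh <- scoreShape(pmin(pmax((x + 4) / 8, 0), 1), threshold = 0.5)
  expect_equal(sh$kurtosisPearson, sh$kurtosisExcess + 3)
  expect_lt(abs(sh$kurtosisExcess), 0.3)
  expect_identical(sh$n, 5000L)
})

test_that("kruskal option replaces the omnibus row", {
  b <- data.frame(sample = rep(c("S1", "S2"), each = 8),
                  cell = paste0("c", 1:16),
                  locusClass = "D-loop",
                  count = 1L, normCount = 1 / 1124,
                  total = c(rep(3L, 8), rep(9L, 8)))
  res <- compareBurdens(b, grouping = "sample", method = "kruskal")
  expect_identical(res$test[1], "kruskal")
  expect_lt(res$p[1], 0.05)
})
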