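test_that("per-gene prediction falls back to observed counts when degenerate", {
  hl <- CUHistogramList(list(
    a = CUHistogram(c(`1` = 100), gene = "a"),           # one copy level
    b = CUHistogram(c(`1` = 5, `2` = 4), gene = "b")))   # N < 20
  pred <- predictGeneCounts(hl, method = "ztnb", t = 9)
  expect_false(any(pred$applied))
  expect_equal(pred$cG, pred$N)

  # t = 0 is a fixed point for every estimator
  hl <- randomHistList(15, seed = 17)
  for (m in c("ztnb", "ds", "gt")) {
    pred <- predictGeneCounts(hl, method = m, t = 0)
    expect_equal(pred$cG, pred$N, info = m)
  }
  expect_error(predictGeneCounts(hl, method = "bogus", t = 0))
})

test_that("predicted counts track simulated truth for well-sampled genes", {
  set.seed(23)
  nG <- 60
  truthN <- rep(3000L, nG)
  mus <- exp(runif(nG, log(0.8), log(8)))
  hl <- CUHistogramList(lapply(seq_len(nG), function(k) {
    histFromCounts(rbinom(truthN[k], rnbinom(truthN[k], mu = mus[k], size = 1), 0.5),
                   gene = sprintf("g%02d", k))
  }))
  # extrapolate back to full depth (reads x2) and compare with the molecules
  # present at full amplification depth
  full <- vapply(seq_len(nG), function(k) {
    set.seed(1000 + k)
    sum(rnbinom(truthN[k], mu = mus[k], size = 1) > 0)
  }, numeric(1))
  pred <- predictGeneCounts(hl, method = "ztnb", t = 1)
  mare <- mean(abs(pred$cG - full) / full)
  expect_lt(mare, 0.10)
})

test_that("matrix correction conserves the observed grand total", {
  # hand example: T = 100, P = 200, c_g = 10 -> m_g = 5
  m <- Matrix::sparseMatrix(i = 1:2, j = c(1, 1), x = c(10, 90),
                            dimnames = list(c("a", "b"), "c1"))
  out <- applyCorrection(m, c(a = 10, b = 190))
  expect_equal(out$result@perGene$mG[1], 5)
  expect_equal(sum(out$matrix), 100)

  # identity when every prediction equals the observation
  big <- randomCountMatrix(40, 20, seed = 19)
  rs <- Matrix::rowSums(big)
  out <- applyCorrection(big, setNames(rs, rownames(big)))
  expect_equal(as.matrix(out$matrix), as.matrix(big))

  # random predictions: sum of m_g = T and grand total preserved to 1e-9
  set.seed(20)
  preds <- setNames(rs * runif(40, 1, 4), rownames(big))
  out <- applyCorrection(big, preds)
  T <- sum(big)
  expect_lt(abs(sum(out$result@perGene$mG) - T) / T, 1e-9)
  expect_lt(abs(sum(out$matrix) - T) / T, 1e-9)

  expect_error(applyCorrection(big, preds[-1]), "no prediction")
  expect_warning(applyCorrection(big, setNames(rs * 0.5, rownames(big))),
                 "below observed")
})

test_that("quantile normalization maps source ranks onto target quantiles", {
  src <- c(0.2, 0.4)
  expect_equal(quantileNormalize(src, c(0.6, 0.8)), c(0.6, 0.8))
  expect_equal(quantileNormalize(src, src), src)

  set.seed(25)
  a <- runif(100); b <- rbeta(100, 2, 5)
  out <- quantileNormalize(a, b)
  expect_equal(sort(out), sort(b))            # order statistics transferred
  expect_equal(order(out), order(a))          # rank order preserved
  expect_equal(quantileNormalize(out, b), out)  # idempotent vs same target
})

test_that("pooled 3-bin histograms are UMI-weighted means of saturation metrics", {
  target <- data.frame(gene = c("g1", "g2"), fscm = c(0.6, 0.5),
                       fdcm = c(0.3, 0.2), nUMIs = c(100, 50))
  # single source identical to the target leaves the metrics unchanged
  pooled <- poolHistograms(target, list(target), normalize = FALSE)
  expect_equal(molecules(pooled[["g1"]]), c(60, 30, 10))

  # weighted mean: fscm 0.6 (n 100) + 0.8 (n 300) -> 0.75
  src <- data.frame(gene = "g1", fscm = 0.8, fdcm = 0.1, nUMIs = 300)
  pooled <- poolHistograms(target[1, ], list(src), normalize = FALSE)
  m <- saturationMetrics(pooled[["g1"]])
  expect_equal(unname(m["fscm"]), 0.75)
  expect_equal(unname(m["nUMIs"]), 100)  # scaled to the target's UMIs

  # fmcm is the complement: fscm .6, fdcm .3 -> fmcm .1
  pooled <- poolHistograms(target, list(), normalize = FALSE)
  expect_equal(unname(saturationMetrics(pooled[["g1"]])["fmcm"]), 0.1)

  # a gene absent from every source keeps its own metrics
  srcOther <- data.frame(gene = "g2", fscm = 0.9, fdcm = 0.05, nUMIs = 10)
  pooled <- poolHistograms(target, list(srcOther), normalize = FALSE)
  expect_equal(unname(saturationMetrics(pooled[["g1"]])["fscm"]), 0.6)

  # pooled histograms are valid DS input
  expect_s4_class(dsPredict(pooled[["g1"]], 9, mt = 2), "PredictionResult")
})

test_that("binomial downsampling matches the binomial pmf and conserves reads", {
  out <- binomialDownsampleHist(CUHistogram(c(`1` = 100)), 0.5)
  expect_equal(out$n, 50)

  out <- binomialDownsampleHist(CUHistogram(c(`2` = 10)), 0.5)
  expect_equal(copies(out$histogram), c(1L, 2L))
  expect_equal(molecules(out$histogram), c(5, 2.5))
  expect_equal(out$n, 7.5)
  expect_equal(out$lost, 2.5)

  h <- randomHistList(1, seed = 27)[[1]]
  idn <- binomialDownsampleHist(h, 1)
  expect_equal(copies(idn$histogram), copies(h))
  expect_equal(molecules(idn$histogram), molecules(h))
  expect_equal(idn$n, nMolecules(h))

  # read conservation at arbitrary x
  for (x in c(0.17, 0.5, 0.83)) {
    d <- binomialDownsampleHist(h, x)
    expect_equal(nReads(d$histogram), x * nReads(h))
  }
  # thinning composes: x1 then x2 equals x1 * x2
  d1 <- binomialDownsampleHist(h, 0.6)
  d2 <- binomialDownsampleHist(d1$histogram, 0.5)
  d12 <- binomialDownsampleHist(h, 0.3)
  expect_equal(d2$n, d12$n, tolerance = 1e-12)
  expect_equal(molecules(d2$histogram), molecules(d12$histogram),
               tolerance = 1e-10)

  expect_error(binomialDownsampleHist(h, 0), "in \\(0, 1\\]")
  expect_error(binomialDownsampleHist(h, 1.2), "in \\(0, 1\\]")
})

test_that("analytic downsampling equals the mean of Monte-Carlo read thinning", {
  set.seed(29)
  x <- rnbinom(1e5, mu = 3, size = 1)
  x <- x[x > 0]
  h <- histFromCounts(x)
  ana <- binomialDownsampleHist(h, 0.3)$n
  reps <- 50
  mc <- replicate(reps, sum(rbinom(length(x), x, 0.3) > 0))
  expect_lt(abs(ana - mean(mc)), 3 * sd(mc) / sqrt(reps))
})

test_that("batch correction leaves data untouched at x = 1 and improves concordance", {
  genes <- data.frame(gene = sprintf("g%03d", 1:200),
                      nMolecules = 600L, nbSize = 1,
                      nbMean = exp(seq(log(0.5), log(16), length.out = 200)))
  deep <- simulateDataset(simSpec(genes, nCells = 30, readFraction = 1,
                                  seed = 33))
  shal <- simulateDataset(simSpec(genes, nCells = 30, readFraction = 0.5,
                                  seed = 34))
  bd <- buildCUHistograms(deep$table)
  bs <- buildCUHistograms(shal$table)

  out1 <- batchCorrect(bd$matrix, bd$histograms, bs$matrix, x = 1)
  expect_equal(as.matrix(out1$matrix), as.matrix(bd$matrix))
  expect_true(all(out1$correction@perGene$fG == 1))

  auto <- batchCorrect(bd$matrix, bd$histograms, bs$matrix, x = "auto")
  expect_lt(abs(auto$correction@x - 0.5), 0.1)
  shared <- intersect(rownames(bd$matrix), rownames(bs$matrix))
  prof <- function(m) log2(meanExpression(m)[shared] + 1)
  expect_gt(ccc(prof(auto$matrix), prof(bs$matrix)),
            ccc(prof(bd$matrix), prof(bs$matrix)))

  expect_error(batchCorrect(bd$matrix, bd$histograms,
                            bs$matrix[character(0), ], x = "auto"),
               "at least 2 shared genes")
  expect_error(batchCorrect(bd$matrix, bd$histograms, bs$matrix, x = 2),
               "in \\(0, 1\\]")
})
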