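test_that("Good-Toulmin alternating sum matches hand-computed values", {
  expect_equal(goodToulmin(CUHistogram(c(`1` = 10)), 1)@newMolecules, 10)
  expect_equal(goodToulmin(CUHistogram(c(`1` = 5, `2` = 3)), 1)@newMolecules,
               2)
  # t = 0 returns the observed count for any histogram
  for (h in as.list(randomHistList(10, seed = 2))) {
    p <- goodToulmin(h, 0)
    expect_equal(p@newMolecules, 0)
    expect_equal(p@distinct, nMolecules(h))
  }
  # domain and range guards
  h <- CUHistogram(c(`1` = 5, `2` = 3))
  expect_error(goodToulmin(h, -0.1), ">= 0")
  expect_error(goodToulmin(h, 1.5), "unstable")
  expect_s4_class(goodToulmin(h, 1.5, allowExtrapolation = TRUE),
                  "PredictionResult")
  # at t <= 1 the sum N + U = sum h(i) (1 - (-t)^i) can never go negative;
  # clamping only arises under explicit extrapolation beyond t = 1
  p <- goodToulmin(CUHistogram(c(`2` = 5)), 1)
  expect_equal(p@distinct, 0)
  expect_false(p@clamped)
  p <- goodToulmin(CUHistogram(c(`2` = 5)), 2, allowExtrapolation = TRUE)
  expect_equal(p@distinct, 0)
  expect_true(p@clamped)
})

test_that("Good-Toulmin at t = 1 agrees with the simulator's doubled depth", {
  # compare U against the molecules actually gained when reads double,
  # within 3 Monte-Carlo standard errors of the gain
  set.seed(21)
  reps <- 15
  diffs <- replicate(reps, {
    full <- rnbinom(20000, mu = 1, size = 1)
    half <- rbinom(20000, full, 0.5)
    gt <- goodToulmin(histFromCounts(half), 1)
    gt@newMolecules - (sum(full > 0) - sum(half > 0))
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(reps))
})

test_that("ZTNB EM recovers negative binomial parameters from truncated data", {
  cases <- list(c(mu = 2, size = 1, seed = 42),
                c(mu = 5, size = 0.5, seed = 3))
  for (cs in cases) {
    set.seed(cs[["seed"]])
    x <- rnbinom(50000, mu = cs[["mu"]], size = cs[["size"]])
    fit <- ztnbFit(histFromCounts(x))
    expect_true(fit@converged)
    expect_lt(abs(fit@mu - cs[["mu"]]) / cs[["mu"]], 0.05)
    expect_lt(abs(fit@size - cs[["size"]]) / cs[["size"]], 0.10)
    expect_lt(abs(fit@L - 50000) / 50000, 0.02)
    # invariants: L = N / (1 - pdf(0)) and z = L - N
    p0 <- (fit@size / (fit@size + fit@mu))^fit@size
    expect_equal(fit@L, fit@N / (1 - p0))
    expect_equal(fit@z, fit@L - fit@N, tolerance = 1e-8)
  }
})

test_that("ZTNB library-size bias shrinks as molecule counts grow", {
  bias <- vapply(c(1e3, 1e4, 1e5), function(n) {
    set.seed(n)
    fit <- ztnbFit(histFromCounts(rnbinom(n, mu = 2, size = 1)))
    abs(fit@L - n) / n
  }, numeric(1))
  expect_lt(bias[3], bias[1])
  expect_lt(bias[3], 0.02)
})

test_that("degenerate histograms are refused with a typed error", {
  expect_error(ztnbFit(CUHistogram(c(`1` = 100))),
               class = "umisat_degenerate_histogram")
  expect_error(ztnbFit(CUHistogram(c(`1` = 5, `2` = 4))),
               class = "umisat_degenerate_histogram")  # N < 20
})

test_that("ZTNB prediction hits its algebraic fixed points and saturates at L", {
  set.seed(8)
  fit <- ztnbFit(histFromCounts(rnbinom(30000, mu = 2, size = 1)))
  expect_equal(ztnbPredict(fit, 0)@distinct, fit@N)
  expect_lt(abs(ztnbPredict(fit, 1e20)@distinct - fit@L) / fit@L, 1e-6)
  expect_error(ztnbPredict(fit, -1), ">= 0")
  # monotone nondecreasing in t
  grid <- c(0, 0.25, 0.5, 1, 2, 5, 9, 100, 1e4, 1e20)
  d <- vapply(grid, function(t) ztnbPredict(fit, t)@distinct, numeric(1))
  expect_true(all(diff(d) >= 0))
})

test_that("DS rational approximant reproduces the symbolic Pade oracle", {
  # series h1*t - h2*t^2 under the [0/1] Pade of g = h1/(1 + (h2/h1) t):
  # t -> Inf limit is h1^2 / h2, so distinct -> N + h1^2/h2 = 150 + 200
  h <- CUHistogram(c(`1` = 100, `2` = 50))
  expect_equal(dsPredict(h, 1e20, mt = 2)@distinct, 350, tolerance = 1e-9)
  expect_equal(dsPredict(h, 0)@distinct, 150)
  # finite-t value of the oracle rational function 100 t / (1 + 0.5 t)
  expect_equal(dsPredict(h, 3)@distinct, 150 + 100 * 3 / (1 + 0.5 * 3),
               tolerance = 1e-12)
  expect_error(dsPredict(h, -1), ">= 0")
  expect_error(dsPredict(CUHistogram(c(`1` = 100)), 9),
               class = "umisat_estimator_unstable")
  # monotone on an NB-generated histogram
  set.seed(14)
  hh <- histFromCounts(rnbinom(20000, mu = 1, size = 1))
  grid <- c(0, 0.5, 1, 2, 5, 9, 100, 1e4, 1e20)
  d <- vapply(grid, function(t) dsPredict(hh, t)@distinct, numeric(1))
  expect_true(all(diff(d) >= 0))
})

test_that("ZTNB and DS agree on extrapolation from NB-generated histograms", {
  # single-draw extrapolation error has MC sd ~2-4% at this problem size,
  # so agreement is measured as the mean over replicates (the bias)
  set.seed(31)
  reps <- 4
  res <- replicate(reps, {
    full <- rnbinom(100000, mu = 2, size = 1)
    thin <- rbinom(100000, full, 0.1)
    hThin <- histFromCounts(thin)
    stopifnot(nMolecules(hThin) >= 1e4)
    truth <- sum(full > 0)
    z <- ztnbPredict(ztnbFit(hThin), 9)@distinct
    d <- dsPredict(hThin, 9, mt = 2)@distinct
    c(zerr = (z - truth) / truth, derr = (d - truth) / truth,
      gap = (z - d) / d)
  })
  expect_lt(abs(mean(res["zerr", ])), 0.05)
  expect_lt(abs(mean(res["derr", ])), 0.05)
  expect_lt(abs(mean(res["gap", ])), 0.05)
})
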