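test_that("composite intensity P blends and clamps as defined", {
  expect_equal(compositeP(6, 3), 4)          # (6 + 2*3)/3
  expect_equal(compositeP(-3, 3), 2)         # negative Fo^2 clamped
  expect_equal(compositeP(5, 99, f = 1), 5)  # pure-Fo^2 limit
  expect_equal(compositeP(5, 99, f = 0), 99) # pure-Fc^2 limit
  expect_error(compositeP(1, 1, f = 1.5),
               class = "weightopt_validation_error")
})

test_that("P stays between the clamped Fo^2 and Fc^2 for any f", {
  set.seed(7)
  for (rep in 1:20) {
    fo <- rnorm(1, 5, 10); fc <- rexp(1, 1 / 5); f <- runif(1)
    P <- compositeP(fo, fc, f)
    expect_gte(P, min(max(fo, 0), fc) - 1e-12)
    expect_lte(P, max(max(fo, 0), fc) + 1e-12)
  }
})

test_that("q factor switches on the sign of c", {
  expect_equal(qFactor(0, c(0, 0.3, 1)), c(1, 1, 1))
  expect_equal(qFactor(2, 0.5), exp(0.5))
  expect_equal(qFactor(-2, 0.5), 1 - exp(-0.5))
  expect_error(qFactor(-2, 0), class = "weightopt_validation_error")
})

test_that("weights reproduce hand-evaluated denominators", {
  # statistical limit
  rs <- makeRs(fobsSq = 4, fcalcSq = 4, sigma = 0.5)
  expect_equal(reflectionWeights(rs, weightingScheme(a = 0, b = 0)), 4)

  # (aP)^2 term: P = 10 (Fo^2 = Fc^2 = 10), a = 0.1
  rs <- makeRs(fobsSq = 10, fcalcSq = 10, sigma = 1)
  expect_equal(reflectionWeights(rs, weightingScheme(a = 0.1, b = 0)), 0.5)

  # the optimized multipole scheme a = 0.0114, b = 0.0082 at P = 2,
  # sigma^2 = 0.04; oracle: independent denominator evaluation
  rs <- makeRs(fobsSq = 2, fcalcSq = 2, sigma = 0.2)
  wOracle <- 1 / (0.2^2 + (0.0114 * 2)^2 + 0.0082 * 2)
  expect_equal(reflectionWeights(rs, weightingScheme(a = 0.0114, b = 0.0082)),
               wOracle)
  expect_equal(wOracle, 17.5686, tolerance = 1e-5)

  # negative d can push the denominator non-positive
  err <- expect_error(
    reflectionWeights(makeRs(1, 1, sigma = 0.1), weightingScheme(d = -1)),
    class = "weightopt_validation_error")
  expect_match(conditionMessage(err), "\\(1 0 1\\)")
})

test_that("weights decrease strictly as a or b grows (P > 0)", {
  rs <- makeRs(fobsSq = c(5, 50), fcalcSq = c(6, 45), sigma = c(1, 2))
  for (aVal in c(0, 0.05, 0.2)) {
    w1 <- reflectionWeights(rs, weightingScheme(a = aVal, b = 0.1))
    w2 <- reflectionWeights(rs, weightingScheme(a = aVal + 0.01, b = 0.1))
    w3 <- reflectionWeights(rs, weightingScheme(a = aVal, b = 0.3))
    expect_true(all(w2 < w1))
    expect_true(all(w3 < w1))
  }
})

test_that("cut-offs keep exactly the reflections passing every criterion", {
  rs5 <- makeRs(fobsSq = 1:5, fcalcSq = rep(1, 5), sigma = rep(1, 5))
  expect_equal(applyFilters(rs5, filterSpec()), rs5)   # no cuts: identity
  kept <- applyFilters(rs5, filterSpec(minIOverSigma = 3))
  expect_equal(nReflections(kept), 3L)

  rs <- generateReflections(100, seed = 5, aTrue = 0.05, bTrue = 0.5)
  spec <- filterSpec(minIOverSigma = 2, maxSinThetaOverLambda = 0.6)
  res <- applyFilters(rs, spec, counts = TRUE)
  # brute-force row-by-row oracle
  d <- reflections(rs)
  s <- sinThetaOverLambda(cellOf(rs), d$h, d$k, d$l)
  keepOracle <- (d$fobsSq / d$sigmaFobsSq >= 2) & (s <= 0.6)
  expect_equal(nReflections(res$set), sum(keepOracle))
  expect_equal(reflections(res$set), reflections(rs)[keepOracle, ],
               ignore_attr = TRUE)
  expect_equal(unname(res$removed["iOverSigma"]),
               sum(d$fobsSq / d$sigmaFobsSq < 2))
  expect_equal(unname(res$removed["resolution"]), sum(s > 0.6))

  err <- expect_error(applyFilters(rs5, filterSpec(minIntensity = 100)),
                      class = "weightopt_validation_error")
  expect_match(conditionMessage(err), "intensity: 5")
})

test_that("wGooF matches hand sums and scales as sqrt(k) in the weights", {
  perfect <- makeRs(fobsSq = c(1, 2, 3), fcalcSq = c(1, 2, 3))
  expect_equal(wGoof(perfect, rep(1, 3), p = 1), 0)

  rs <- makeRs(fobsSq = c(2, 1, 5), fcalcSq = c(1, 2, 3))  # Delta = 1,-1,2
  expect_equal(wGoof(rs, rep(1, 3), p = 1), sqrt(6 / 2))
  k <- 3.7
  expect_equal(wGoof(rs, rep(k, 3), p = 1), sqrt(k) * sqrt(3))

  expect_error(wGoof(rs, rep(1, 3), p = 3),
               class = "weightopt_validation_error")
  expect_error(wGoof(rs, c(1, -1, 1), p = 1),
               class = "weightopt_validation_error")
})

test_that("statistical limit: w = 1/sigma^2 and wGooF equals GooF exactly", {
  rs <- generateReflections(200, seed = 9, aTrue = 0.05, bTrue = 0.5)
  statw <- weightingScheme(a = 0, b = 0, c = 0, d = 0, e = 0)
  w <- reflectionWeights(rs, statw)
  expect_identical(w, 1 / reflections(rs)$sigmaFobsSq^2)
  st <- refinementStats(rs, statw, p = 20)
  expect_identical(st@wgoof, st@goof)
})

test_that("refinement statistics match a spreadsheet-style recomputation", {
  fo2 <- c(4.1, 0.9, 2.6, 9.2)
  fc2 <- c(4.0, 1.0, 2.5, 9.0)
  sig <- c(0.2, 0.1, 0.15, 0.3)
  rs <- makeRs(fo2, fc2, sig)
  sch <- weightingScheme(a = 0.05, b = 0.1)

  # independent element-by-element oracle
  P <- (pmax(fo2, 0) + 2 * fc2) / 3
  w <- 1 / (sig^2 + (0.05 * P)^2 + 0.1 * P)
  d2 <- (fo2 - fc2)^2
  r1O <- sum(abs(sqrt(pmax(fo2, 0)) - sqrt(fc2))) / sum(sqrt(pmax(fo2, 0)))
  wr2O <- sqrt(sum(w * d2) / sum(w * fo2^2))
  goofO <- sqrt(sum(d2 / sig^2) / (4 - 1))
  wgoofO <- sqrt(sum(w * d2) / (4 - 1))

  st <- refinementStats(rs, sch, p = 1)
  expect_equal(st@r1, r1O)
  expect_equal(st@wr2, wr2O)
  expect_equal(st@goof, goofO)
  expect_equal(st@wgoof, wgoofO)

  # perfect fit: everything zero
  stPerfect <- refinementStats(makeRs(fc2, fc2, sig), sch, p = 1)
  expect_equal(c(stPerfect@r1, stPerfect@wr2, stPerfect@goof,
                 stPerfect@wgoof), rep(0, 4))
})

test_that("statistics are invariant under reflection order permutation", {
  rs <- generateReflections(100, seed = 2, aTrue = 0.03, bTrue = 0.2)
  sch <- weightingScheme(a = 0.03, b = 0.2)
  set.seed(1)
  perm <- sample(100)
  rsPerm <- rs[perm]
  a <- refinementStats(rs, sch, p = 10)
  b <- refinementStats(rsPerm, sch, p = 10)
  expect_equal(a@r1, b@r1)
  expect_equal(a@wr2, b@wr2)
  expect_equal(a@wgoof, b@wgoof)
})
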