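test_that("Fc-ordered binning partitions with the stated remainder rule", {
  rs <- generateReflections(1000, seed = 1)
  bin <- binByFc(rs, 10)
  expect_equal(unname(tabulate(bin)), rep(100L, 10))

  # bins are contiguous in Fc^2
  fc2 <- reflections(rs)$fcalcSq
  for (b in 1:9) expect_lte(max(fc2[bin == b]), min(fc2[bin == b + 1]))

  expect_equal(sort(unique(binByFc(makeRs(1:10, 1:10), 10))), 1:10)
  expect_equal(unname(tabulate(binByFc(rnorm(1005), 10))),
               c(rep(101L, 5), rep(100L, 5)))
  expect_error(binByFc(makeRs(1:5, 1:5), 10),
               class = "weightopt_validation_error")
})

test_that("binned objective is zero iff every bin statistic is 1", {
  # w*Delta^2 = (n-p)/n constant => every t_k = 1 => objective 0
  n <- 20; p <- 10
  delta <- sqrt((n - p) / n)
  rs <- makeRs(fobsSq = (1:n) + delta, fcalcSq = 1:n, sigma = rep(1, n))
  expect_equal(binnedVarianceObjective(rs, weightingScheme(a = 0, b = 0),
                                       p = p, nBins = 5),
               0, tolerance = 1e-14)

  # two-bin toy with bin statistics (1, 2): hand oracle mean((t-1)^2)
  rs2 <- makeRs(fobsSq = c(1, 2, 3, 4) + c(1, 1, 2, 2),
                fcalcSq = c(1, 2, 3, 4), sigma = rep(1, 4))
  # t = sqrt((4/4) * c(mean(1,1), mean(4,4))) = c(1, 2)
  expect_equal(binnedVarianceObjective(rs2, weightingScheme(a = 0, b = 0),
                                       p = 0, nBins = 2),
               ((1 - 1)^2 + (2 - 1)^2) / 2)
})

test_that("objective at the generating truth beats the statistical scheme", {
  rs <- generateReflections(2000, seed = 4, aTrue = 0.05, bTrue = 0.5)
  objTruth <- binnedVarianceObjective(rs, weightingScheme(a = 0.05, b = 0.5),
                                      p = 50)
  obj0 <- binnedVarianceObjective(rs, weightingScheme(a = 0, b = 0), p = 50)
  expect_lt(objTruth, obj0)
})

test_that("per-bin degrees of freedom variant guards against p-rich models", {
  rs <- generateReflections(100, seed = 6, aTrue = 0.05)
  v1 <- binnedVarianceObjective(rs, weightingScheme(a = 0, b = 0), p = 5,
                                nBins = 10, binDof = "perbin")
  expect_gte(v1, 0)
  expect_error(
    binnedVarianceObjective(rs, weightingScheme(a = 0, b = 0), p = 150,
                            nBins = 10, binDof = "perbin"),
    class = "weightopt_validation_error")
})

test_that("SHELXL-style start lands near the inflation scale", {
  # no inflation: the floor value
  rs0 <- generateReflections(2000, seed = 8)
  expect_equal(unname(shelxlStyleStart(rs0)["aStart"]), 0.01)

  # strong (aP)^2 inflation: within a factor of 3 of the truth
  rs <- generateReflections(2000, seed = 8, aTrue = 0.1, bTrue = 0)
  a0 <- unname(shelxlStyleStart(rs)["aStart"])
  expect_gt(a0, 0.1 / 3)
  expect_lt(a0, 0.1 * 3)
  expect_equal(unname(shelxlStyleStart(rs)["bStart"]), 0)

  # perfect fit: fallback
  expect_equal(shelxlStyleStart(makeRs(1:20, 1:20)),
               c(aStart = 0.1, bStart = 0))
})

test_that("grid search recovers a convex analytic objective to grid resolution", {
  obj <- function(a, b) (a - 0.3)^2 + (b - 0.7)^2
  cfg <- gridSearchConfig(aStart = 0.05, bStart = 0.1,
                          aStop = 1e-4, bStop = 5e-3)
  res <- gridSearch(cfg = cfg, objective = obj)
  expect_true(res@converged)
  expect_lt(abs(res@aOpt - 0.3), 1e-4)
  expect_lt(abs(res@bOpt - 0.7), 5e-3)

  # dense brute-force oracle at half the stopping resolution
  aGrid <- seq(0, 0.6, by = 5e-5)
  bGrid <- seq(0, 1.4, by = 2.5e-3)
  dense <- outer(aGrid, bGrid, function(a, b) (a - 0.3)^2 + (b - 0.7)^2)
  expect_lte(res@objective, min(dense) + 1e-10)
})

test_that("a flat objective converges in place without moving", {
  res <- gridSearch(cfg = gridSearchConfig(aStart = 0.2, bStart = 0.4,
                                           aStop = 1e-3, bStop = 1e-3),
                    objective = function(a, b) 1.23)
  expect_true(res@converged)
  expect_equal(res@aOpt, 0.2)
  expect_equal(res@bOpt, 0.4)
  expect_equal(res@objective, 1.23)
})

test_that("search is deterministic, clipped at zero, and monotone in best-so-far", {
  rs <- generateReflections(800, seed = 12, aTrue = 0.05, bTrue = 0.5)
  cfg <- gridSearchConfig(aStop = 1e-4, bStop = 5e-3)
  r1 <- gridSearch(rs, p = 40, cfg = cfg)
  r2 <- gridSearch(rs, p = 40, cfg = cfg)
  expect_identical(r1@aOpt, r2@aOpt)
  expect_identical(r1@bOpt, r2@bOpt)
  expect_identical(r1@trace, r2@trace)

  expect_true(all(r1@evaluations$a >= 0))
  expect_true(all(r1@evaluations$b >= 0))
  expect_true(all(diff(cummin(r1@trace$objective)) <= 0))
  best <- cummin(r1@trace$objective)
  expect_true(all(r1@trace$objective >= best - 1e-15))
  # returned optimum never worse than the starting point
  expect_lte(r1@objective, r1@evaluations$objective[1])
})

test_that("stopping-point guard: tiny computed starts abort under reference stops", {
  rs <- guardInstance()
  # strict mode, reference stops: computed aStart ~ 1e-5 gives a step
  # below aStop = 1e-4
  err <- expect_error(
    gridSearch(rs, p = 5,
               cfg = gridSearchConfig(aStop = 1e-4, bStop = 5e-3,
                                      strict = TRUE)),
    class = "weightopt_config_error")
  expect_match(conditionMessage(err), "stopping")

  # the documented workaround stops let the same instance run
  res <- gridSearch(rs, p = 5,
                    cfg = gridSearchConfig(aStop = 1e-7, bStop = 1e-6,
                                           strict = TRUE))
  expect_true(res@converged)

  # default (non-strict) mode floors the steps and runs even with
  # reference stops
  res2 <- gridSearch(rs, p = 5,
                     cfg = gridSearchConfig(aStop = 1e-4, bStop = 5e-3))
  expect_true(res2@converged)
})

test_that("configuration validation rejects malformed searches", {
  expect_error(gridSearchConfig(gridSide = 8), "odd")
  expect_error(gridSearchConfig(aStop = 0), "aStop")
  expect_error(gridSearchConfig(shrinkFactor = 1), "shrinkFactor")
  expect_error(gridSearchConfig(nBins = 1), "nBins")
  expect_error(gridSearch(cfg = gridSearchConfig(),
                          objective = function(a, b) a + b),
               class = "weightopt_config_error")  # no starts, no data
})

test_that("trace export writes one tab-separated row per iteration", {
  res <- gridSearch(cfg = gridSearchConfig(aStart = 0.1, bStart = 0.1,
                                           aStop = 1e-3, bStop = 1e-3),
                    objective = function(a, b) (a - 0.05)^2 + (b - 0.02)^2)
  path <- tempfile(fileext = ".tsv")
  writeTrace(res, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), res@nIterations)
  expect_named(tab, c("iteration", "a", "b", "stepA", "stepB", "objective"))
})
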