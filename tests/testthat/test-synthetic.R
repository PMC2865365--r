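test_that("chain traces honor the geometric constraints deterministically", {
  a <- makeChain(15, seed = 1)
  b <- makeChain(15, seed = 1)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a, makeChain(15, seed = 2))))
  # consecutive spacing 3.8 A, non-consecutive separation >= 4.0 A
  for (seed in 1:25) {
    ch <- makeChain(12, seed = seed)
    steps <- sqrt(rowSums(diff(ch)^2))
    expect_equal(steps, rep(3.8, 11), tolerance = 1e-9)
    D <- as.matrix(dist(ch))
    nonconsec <- abs(row(D) - col(D)) > 1
    expect_gte(min(D[nonconsec]), 4.0)
  }
  expect_error(makeChain(3, seed = 1), "nRes")
})

test_that("cell content is conserved when symmetry is hidden in a subgroup", {
  # 6 chains in the P4 ASU: 24 chains in P1, 12 in the monoclinic subgroup
  fx24 <- makeUnderassignedStructure("P4", chainsPerAsu = 6, nRes = 6,
                                     subgroup = "P1", seed = 3)
  expect_equal(nChains(fx24$model), 24)
  fx12 <- makeUnderassignedStructure("P4", chainsPerAsu = 6, nRes = 6,
                                     subgroup = "P112", seed = 3)
  expect_equal(nChains(fx12$model), 12)
  # conservation: chains in presented cell x |presented group| is constant
  expect_equal(nChains(fx24$model) * length(operators(fx24$model@group)),
               nChains(fx12$model) * length(operators(fx12$model@group)))
  expect_error(makeUnderassignedStructure("P4", subgroup = "P2", seed = 1),
               "not a subgroup")
})

test_that("simulated observations have the stated limiting behaviour", {
  fx <- fixP4()
  model <- fx$model
  # noise-free, complete: expanded obs reproduce calculated intensities, so
  # R_symop agrees exactly for any operator
  obs <- simulateObservedIntensities(model, dmin = 4, fracNoise = 0,
                                     completeness = 1, seed = 1)
  obsP1 <- expandObsToP1(obs)
  calcP1 <- calcStructureFactors(scatOf(model), dmin = 4)
  op <- symOp("-y,x,z")
  expect_equal(rSymop(obsP1, op)$value, rSymop(calcP1, op)$value,
               tolerance = 1e-12)
  # multiplicative noise: R_symop of a true operator matches a direct
  # Monte-Carlo estimate of the same statistic within 20%
  cv <- 0.05
  got <- mean(vapply(1:5, function(s) {
    o <- simulateObservedIntensities(model, dmin = 4, fracNoise = cv, seed = s)
    rSymop(expandObsToP1(o), op)$value
  }, numeric(1)))
  set.seed(99)
  mc <- mean(vapply(1:2000, function(i) {
    I0 <- calcP1@I[sample.int(length(calcP1@I), 2)]
    Ia <- I0[1] * (1 + rnorm(1, 0, cv)); Ib <- I0[1] * (1 + rnorm(1, 0, cv))
    abs(Ia - Ib) / (Ia + Ib)
  }, numeric(1)))
  expect_equal(got, mc, tolerance = 0.2)
  # half completeness roughly quarters the scorable pair count
  full <- simulateObservedIntensities(model, dmin = 4, fracNoise = 0, seed = 2)
  nFull <- rSymop(expandObsToP1(full), op)$nPairs
  ratios <- vapply(1:4, function(s) {
    half <- simulateObservedIntensities(model, dmin = 4, fracNoise = 0,
                                        completeness = 0.5, seed = s)
    rSymop(expandObsToP1(half), op)$nPairs / nFull
  }, numeric(1))
  expect_equal(mean(ratios), 0.25, tolerance = 0.35)
})
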