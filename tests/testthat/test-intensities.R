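test_that("structure factors match first principles and the brute-force oracle", {
  cell <- unitCell(18, 15, 13, 90, 95, 90)
  # single scatterer at the origin: phase 0, |F| = weight, for every H
  one <- new("Scatterers", xyz = matrix(0, 1, 3), occ = 1, B = 0, weight = 2.5,
             cell = cell)
  sf <- calcStructureFactors(one, dmin = 4)
  expect_lt(max(abs(sf@phi)), 1e-12)
  expect_equal(sf@F, rep(2.5, nReflections(sf)), tolerance = 1e-12)
  # centrosymmetric pair: all phases 0 or pi
  pair <- new("Scatterers", xyz = rbind(c(0.13, 0.22, 0.31), -c(0.13, 0.22, 0.31)),
              occ = c(1, 1), B = c(5, 5), weight = c(1, 1), cell = cell)
  sfp <- calcStructureFactors(pair, dmin = 4)
  expect_lt(max(abs(sin(sfp@phi))), 1e-9)
  # random 50-site model with occupancies and B factors vs independent oracle
  set.seed(11)
  sc <- new("Scatterers", xyz = matrix(runif(150), 50, 3),
            occ = runif(50, 0.4, 1), B = runif(50, 2, 40),
            weight = runif(50, 1, 8), cell = cell)
  sff <- calcStructureFactors(sc, dmin = 4)
  oracle <- sfOracle(sc@xyz, sc@occ, sc@B, sc@weight, cell, sff@hkl)
  expect_lt(max(Mod(oracle - complex(modulus = sff@F, argument = sff@phi))) /
              max(Mod(oracle)), 1e-8)
  expect_error(calcStructureFactors(new("Scatterers",
    xyz = matrix(numeric(0), 0, 3), occ = numeric(0), B = numeric(0),
    weight = numeric(0), cell = cell)), "empty")
})

test_that("observed-data expansion to P1 is orbit-exact and idempotent", {
  cell <- unitCell(20, 24, 30)
  hkl <- millerIndices(cell, 6)
  set.seed(3)
  I <- runif(nrow(hkl), 1, 10)
  # P1 input: expansion only completes Friedel mates (a no-op in the
  # hemisphere representation)
  p1in <- reflectionSet(cell, spaceGroup("P1"), hkl, I = I)
  ex <- expandObsToP1(p1in)
  expect_equal(nReflections(ex), nrow(hkl))
  # P2-merged data: each orbit populates its full multiplicity
  p2 <- spaceGroup("P2")
  merged <- mergeUnderGroup(p1in, p2)
  ex2 <- expandObsToP1(merged)
  W <- rotationPart(operators(p2)[[2]])
  for (r in sample(nReflections(merged), 20)) {
    H <- merged@hkl[r, ]
    mates <- xtalsym:::.friedelCanon(rbind(H, as.numeric(H %*% W)))$hkl
    j <- match(xtalsym:::.hklKey(mates), xtalsym:::.hklKey(ex2@hkl))
    expect_false(any(is.na(j)))
    expect_equal(ex2@I[j], rep(merged@I[r], nrow(mates)), tolerance = 1e-12)
  }
  # round trip: expand then re-merge gives the merged values back exactly
  rem <- mergeUnderGroup(ex2, p2)
  j <- match(xtalsym:::.hklKey(rem@hkl), xtalsym:::.hklKey(merged@hkl))
  ordI <- merged@I[j[!is.na(j)]]
  expect_equal(rem@I[!is.na(j)], ordI, tolerance = 1e-12)
  # negative intensities are clipped with a warning
  bad <- reflectionSet(cell, spaceGroup("P1"), hkl[1:5, ], I = c(-1, 1, 2, 3, 4))
  expect_warning(exb <- expandObsToP1(bad), "clipped")
  expect_equal(attr(exb, "nClipped"), 1)
})

test_that("R_symop has its exact limits and matches a direct oracle", {
  fx <- fixP4()
  sf <- calcStructureFactors(scatOf(fx$model), dmin = 3.5)
  # operator of the (true) symmetry: exactly zero
  expect_lt(rSymop(sf, symOp("-y,x,z"))$value, 1e-12)
  # operator not in the symmetry: far from zero
  expect_gt(rSymop(sf, symOp("x,-y,-z"))$value, 0.2)
  # uniform random intensities: matches the two-line oracle, value near 1/3
  cell <- unitCell(20, 20, 26)
  hkl <- millerIndices(cell, 5)
  set.seed(21)
  I <- runif(nrow(hkl))
  rs <- reflectionSet(cell, spaceGroup("P1"), hkl, I = I)
  op <- symOp("-x,-y,z")
  got <- rSymop(rs, op)
  W <- rotationPart(op)
  keys <- xtalsym:::.hklKey(hkl)
  num <- 0; den <- 0; np <- 0
  for (i in seq_len(nrow(hkl))) {
    hw <- xtalsym:::.friedelCanon(matrix(as.numeric(hkl[i, ] %*% W), 1))$hkl
    k <- xtalsym:::.hklKey(hw)
    if (k == keys[i]) next
    j <- match(k, keys)
    if (is.na(j)) next
    num <- num + abs(I[i] - I[j]); den <- den + I[i] + I[j]; np <- np + 1
  }
  expect_equal(got$value, num / den, tolerance = 1e-12)
  expect_equal(got$nPairs, np)
  expect_equal(got$value, 1 / 3, tolerance = 0.15)  # i.i.d.-uniform expectation
  # scale invariance
  rs2 <- rs; rs2@I <- rs@I * 1234.5
  expect_equal(rSymop(rs2, op)$value, got$value, tolerance = 1e-12)
  # r(W) = r(W^-1) exactly (identical pair set)
  op4 <- symOp("-y,x,z")
  expect_identical(rSymop(rs, op4)$value, rSymop(rs, solve(op4))$value)
  # no scorable pairs is an explicit signal
  tiny <- reflectionSet(cell, spaceGroup("P1"), matrix(c(0, 0, 2), 1), I = 1)
  expect_error(rSymop(tiny, symOp("-y,x,z")), "no pairs|no scorable")
})

test_that("R_symop grows monotonically with coordinate noise", {
  sigmas <- c(0, 0.05, 0.2, 0.5)
  means <- vapply(sigmas, function(s) {
    vals <- vapply(1:3, function(seed) {
      fx <- makeUnderassignedStructure("P4", chainsPerAsu = 1, nRes = 10,
                                       noiseSigma = s, subgroup = "P1",
                                       seed = 100 + seed)
      sf <- calcStructureFactors(scatOf(fx$model), dmin = 4)
      rSymop(sf, symOp("-y,x,z"))$value
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("setting scores reproduce the expected plausibility pattern", {
  fx <- fixP4()
  model <- fx$model
  sf <- calcStructureFactors(scatOf(model), dmin = 3.5)
  st <- enumeratePattersonSettings(model@cell,
                                   findLatticeTwofolds(model@cell),
                                   nChains(model))
  st <- scorePattersonSettings(st, sf)
  tab <- settingsTable(st)
  # the cell is metrically tetragonal but only the fourfold is real:
  # P4/m plausible, P4/mmm and every setting with an in-plane twofold not
  plaus <- tab$setting[tab$plausible]
  expect_true("P4/m" %in% plaus)
  expect_true("P-1" %in% plaus)
  expect_false("P4/mmm" %in% plaus)
  expect_false("Pmmm" %in% plaus)
  expect_equal(tab$max_rsymop_calc[tab$setting == "P-1"], 0)
  # threshold limit: r_max = 1 makes everything plausible
  st2 <- scorePattersonSettings(st, sf, rMax = 1.0)
  expect_true(all(vapply(st2, function(s) s@plausible, logical(1))))
  # a random triclinic arrangement in the same cell leaves only P-1
  set.seed(9)
  rnd <- crystalModel(model@cell, spaceGroup("P1"),
                      list(list(id = "A", seq = rep("GLY", 40),
                                xyz = matrix(runif(120), 40, 3))))
  sfr <- calcStructureFactors(scatOf(rnd), dmin = 3.5)
  str_ <- scorePattersonSettings(st, sfr)
  plr <- settingsTable(str_)
  expect_equal(plr$setting[plr$plausible], "P-1")
})
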