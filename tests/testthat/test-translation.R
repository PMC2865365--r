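test_that("the correlation map peaks at the true origin for a symmetric model", {
  fx <- fixP4()
  sc <- scatOf(fx$model)
  mp <- correlationMap(sc, spaceGroup("P4"), dmin = 3.5)
  expect_gt(mp@rMax, 0.999)
  expect_equal(mp@xMax, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(max(mp@values), 1 + 1e-9)
  # polar direction: the map is constant along the fourfold
  zvar <- apply(mp@values, c(1, 2), function(v) diff(range(v)))
  expect_lt(max(zvar), 1e-6)
})

test_that("grid values agree with a brute-force shifted-ensemble oracle", {
  # 3-chain toy, few hundred reflections, 6^3 grid
  set.seed(14)
  cell <- unitCell(17, 17, 14)
  chains <- lapply(1:3, function(i)
    list(id = LETTERS[i], seq = rep("ALA", 6),
         xyz = matrix(runif(18, 0.05, 0.9), 6, 3)))
  model <- crystalModel(cell, spaceGroup("P1"), chains)
  sc <- scatOf(model)
  G <- spaceGroup("P4")
  mp <- correlationMap(sc, G, dmin = 3.5, gridDivisions = c(6L, 6L, 6L))
  expect_lte(nReflections(calcStructureFactors(sc, 3.5)), 500)
  # oracle: explicitly build the shifted ensemble coordinates and recompute
  # structure factors by direct summation at every grid point
  hkl <- millerIndices(cell, 3.5)
  Imerge <- {
    F0 <- sfOracle(sc@xyz, sc@occ, sc@B, sc@weight, cell, hkl)
    acc <- numeric(nrow(hkl))
    for (op in operators(G)) {
      HW <- round(hkl %*% rotationPart(op))
      Fw <- sfOracle(sc@xyz, sc@occ, sc@B, sc@weight, cell, HW)
      acc <- acc + Mod(Fw)^2
    }
    acc / length(operators(G))
  }
  for (pt in list(c(0, 0, 0), c(1, 2, 0), c(3, 5, 2), c(2, 0, 4))) {
    x <- pt / 6
    ens <- do.call(rbind, lapply(operators(G), function(op)
      applyOp(sweep(sc@xyz, 2, x, "+"), op)))
    Fe <- sfOracle(ens, rep(1, nrow(ens)), rep(20, nrow(ens)),
                   rep(1, nrow(ens)), cell, hkl)
    rOracle <- stats::cor(Imerge, Mod(Fe)^2)
    expect_equal(mp@values[pt[1] + 1, pt[2] + 1, pt[3] + 1], rOracle,
                 tolerance = 1e-6)
  }
})

test_that("the map is invariant under the allowed-origin shifts of the group", {
  fx <- fixP4()
  sc <- scatOf(fx$model)
  G <- spaceGroup("P4")
  sh <- allowedOriginShifts(G)
  # discrete allowed origins of P4 (polar z removed): (0,0,0) and (1/2,1/2,0)
  expect_equal(nrow(sh), 2)
  expect_true(any(apply(sh, 1, function(s) isTRUE(all.equal(s, c(0.5, 0.5, 0))))))
  mp <- correlationMap(sc, G, dmin = 4.5, gridDivisions = c(8L, 8L, 4L))
  v <- mp@values
  # r(x) = r(x + (1/2,1/2,0)): roll the grid by half along x and y
  rolled <- v[c(5:8, 1:4), c(5:8, 1:4), , drop = FALSE]
  expect_equal(as.numeric(v), as.numeric(rolled), tolerance = 1e-6)
})

test_that("phase agreement is zero for true operators and large for screws", {
  fx <- fixP4()
  sc <- scatOf(fx$model)
  expect_equal(phaseAgreement(sc, identityOp()), 0, tolerance = 1e-12)
  expect_lt(phaseAgreement(sc, symOp("-y,x,z")), 1e-10)
  expect_gt(phaseAgreement(sc, symOp("-y,x,z+1/2")), 0.3)
  # a half-cell-shifted second copy mimics the duplicated-ASU situation:
  # the screw scores low and the pure rotation high
  dup <- sc
  dup@xyz <- rbind(sc@xyz, sweep(sc@xyz, 2, c(0, 0, 1 / 2), "+"))
  dup@occ <- rep(1, nrow(dup@xyz)); dup@B <- rep(20, nrow(dup@xyz))
  dup@weight <- rep(1, nrow(dup@xyz))
  expect_lt(phaseAgreement(dup, symOp("-y,x,z+1/2")), 0.01)
  expect_lt(phaseAgreement(dup, symOp("-y,x,z")), 0.01)
})

test_that("space-group ranking puts the true group first", {
  fx <- fixP4()
  sc <- scatOf(fx$model)
  rk <- rankSpaceGroups(sc, "P4/m", spaceGroup("P1"), dmin = 3.5)
  expect_equal(symbol(rk[[1]]$group), "P4")
  expect_lt(rk[[1]]$maxPhi, 0.2)           # grid-limited, still far below screws
  expect_gt(rk[[1]]$rMax, 0.99)
  expect_true(all(vapply(rk[-1], function(r) r$maxPhi, numeric(1)) > 0.3))
  # screw example: P2_1 crystal presented as P1; the screw wins over P2
  fx2 <- makeUnderassignedStructure("P21", chainsPerAsu = 2, nRes = 10,
                                    subgroup = "P1", seed = 33)
  m <- fx2$model
  # move into the conventional monoclinic frame via the pipeline chain
  out <- checkSymmetry(m)
  expect_equal(out$report@targetGroup, "P21")
  expect_lt(out$report@maxPhi, 1e-6)
})
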