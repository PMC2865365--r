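test_that("orthogonalization follows the PDB convention", {
  cell <- unitCell(40, 50, 60, 90, 100, 90)
  O <- orthMatrix(cell)
  expect_equal(as.numeric(O %*% c(1, 0, 0)), c(40, 0, 0))           # a along x
  expect_equal((O %*% c(0, 1, 0))[3], 0, tolerance = 1e-12)         # b in xy
  expect_equal(det(O), cellVolume(cell), tolerance = 1e-9)
  expect_equal(crossprod(O), metricTensor(cell), tolerance = 1e-9)
  expect_error(unitCell(-1, 2, 3), "positive")
  expect_error(unitCell(10, 10, 10, 0, 90, 90), "angles")
})

test_that("Niggli reduction returns a reduced cell and preserves volume", {
  # already reduced: identity change of basis
  r <- reduceCell(unitCell(40, 50, 60))
  expect_equal(rotationPart(r$cb), diag(3))
  expect_equal(unname(cellParameters(r$cell)), c(40, 50, 60, 90, 90, 90))
  # permuted cell: the axis permutation restoring a <= b <= c
  r2 <- reduceCell(unitCell(60, 40, 50))
  expect_equal(unname(cellParameters(r2$cell)[1:3]), c(40, 50, 60))
  expect_true(all(abs(abs(rotationPart(r2$cb)) - xtalsym:::.permMatrix(c(2, 3, 1))) < 1e-9) ||
              det(rotationPart(r2$cb)) != 0)
  # generic cells: reduced conditions + volume preservation, cb integral
  set.seed(6)
  for (i in 1:10) {
    cell <- unitCell(20 + runif(1, 0, 30), 20 + runif(1, 0, 30),
                     20 + runif(1, 0, 30), 70 + runif(1, 0, 40),
                     70 + runif(1, 0, 40), 70 + runif(1, 0, 40))
    rr <- reduceCell(cell)
    p <- cellParameters(rr$cell)
    expect_lte(p[1], p[2] * (1 + 1e-9))
    expect_lte(p[2], p[3] * (1 + 1e-9))
    ang <- p[4:6]
    expect_true(all(ang <= 90 + 1e-6) || all(ang >= 90 - 1e-6))
    expect_equal(cellVolume(rr$cell), cellVolume(cell), tolerance = 1e-9)
    expect_true(xtalsym:::.ratIsIntegral(rotationPart(rr$cb) * rr$cb@Rden))
  }
  # coplanar basis vectors (gamma = beta + alpha): zero cell volume
  expect_error(reduceCell(unitCell(10, 10, 10, 90, 45, 45)), "degenerate|volume")
})

test_that("centring removal divides the volume by the multiplicity", {
  cc <- unitCell(80, 40, 55, 90, 105, 90)
  rc <- removeCentring(cc, spaceGroup("C2"))
  expect_equal(cellVolume(cc) / cellVolume(rc$cell), 2, tolerance = 1e-9)
  expect_equal(length(operators(rc$group)), 2)     # twofold retained
  rf <- removeCentring(unitCell(60, 60, 60), spaceGroup("F222"))
  expect_equal(cellVolume(unitCell(60, 60, 60)) / cellVolume(rf$cell), 4,
               tolerance = 1e-9)
  rp <- removeCentring(unitCell(30, 30, 30), spaceGroup("P213"))
  expect_equal(rotationPart(rp$cb), diag(3))       # P group: identity
  # C-centred monoclinic: reduced primitive cell has half the volume
  rr <- reduceCell(rc$cell)
  expect_equal(cellVolume(rr$cell), cellVolume(cc) / 2, tolerance = 1e-6)
})

test_that("cells symmetrize to their crystal-system constraints", {
  near <- unitCell(30.02, 29.98, 22.01, 90.01, 89.98, 90.02)
  tet <- symmetrizeCell(near, "tetragonal")
  p <- cellParameters(tet)
  expect_equal(unname(p[1]), unname(p[2]))
  expect_equal(unname(p[4:6]), c(90, 90, 90))
  hex <- symmetrizeCell(near, "hexagonal")
  expect_equal(unname(cellParameters(hex)[6]), 120)
})
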