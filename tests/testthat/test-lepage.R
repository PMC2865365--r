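test_that("exact metrics yield the full expected twofold sets at delta = 0", {
  tw <- findLatticeTwofolds(unitCell(30, 30, 22))
  expect_length(tw, 5)              # z, x, y, xy, x-y
  expect_true(all(vapply(tw, function(x) x$delta, numeric(1)) < 1e-9))
  axes <- vapply(tw, function(x) paste(x$uvw, collapse = ","), character(1))
  expect_setequal(axes, c("0,0,1", "1,0,0", "0,1,0", "1,1,0", "1,-1,0"))
  expect_length(findLatticeTwofolds(unitCell(28, 28, 28)), 9)       # cubic
  expect_length(findLatticeTwofolds(unitCell(30, 30, 22, 90, 90, 120)), 7)
  # every returned operator is an exact lattice twofold
  for (x in tw) {
    W <- rotationPart(x$op)
    expect_true(xtalsym:::.ratIsIntegral(W))
    expect_equal(W %*% W, diag(3))
  }
})

test_that("a generic triclinic metric admits no twofold within tolerance", {
  cell <- unitCell(31, 42, 53, 95, 100, 105)
  expect_length(findLatticeTwofolds(cell, 1.4), 0)
  # brute-force check: even with a huge tolerance the best delta is > 1.4 deg
  all_ <- findLatticeTwofolds(cell, 5)
  if (length(all_)) expect_gt(min(vapply(all_, function(x) x$delta, numeric(1))), 1.4)
})

test_that("near-symmetric cells give small deltas and a sorted list", {
  tw <- findLatticeTwofolds(unitCell(30.01, 29.99, 22, 90.02, 89.97, 90.03))
  expect_length(tw, 5)
  d <- vapply(tw, function(x) x$delta, numeric(1))
  expect_true(all(diff(d) >= 0))
  expect_true(all(d > 0 & d < 0.1))   # order 0.01-0.05 degrees
})

test_that("delta is invariant under a change of basis of the cell", {
  cell <- unitCell(30.01, 29.99, 22, 90.02, 89.97, 90.03)
  d0 <- sort(vapply(findLatticeTwofolds(cell), function(x) x$delta, numeric(1)))
  for (seed in c(4, 9)) {
    cb <- randomUnimodularBasis(seed)
    cell2 <- changeBasis(cell, cb)
    # reduce back so the +/-2 search bound applies, then compare deltas
    red <- reduceCell(cell2)
    d1 <- sort(vapply(findLatticeTwofolds(red$cell), function(x) x$delta,
                      numeric(1)))
    expect_equal(d1, d0, tolerance = 1e-8)
  }
})

test_that("opDelta generalizes Le Page delta to higher-order lattice rotations", {
  cell <- unitCell(30, 30, 22)
  expect_equal(opDelta(symOp("-y,x,z"), cell), 0, tolerance = 1e-9)
  expect_equal(opDelta(identityOp(), cell), 0)
  # a != b misaligns the diagonal twofolds, and through them any derived
  # fourfold of a Patterson setting inherits a nonzero worst-case delta
  near <- unitCell(30.05, 29.95, 22)
  expect_gt(opDelta(symOp("y,x,-z"), near), 0.05)
  st <- enumeratePattersonSettings(near, findLatticeTwofolds(near), 8)
  p4m <- Filter(function(s) symbol(s) == "P4/m", st)
  expect_length(p4m, 1)
  expect_gt(p4m[[1]]@maxDelta, 0.05)
  expect_lt(p4m[[1]]@maxDelta, 0.2)
})
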