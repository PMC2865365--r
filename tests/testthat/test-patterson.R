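test_that("a tetragonal metric enumerates the full setting hierarchy", {
  cell <- unitCell(30, 30, 22)
  st <- enumeratePattersonSettings(cell, findLatticeTwofolds(cell), 24)
  tab <- table(vapply(st, symbol, character(1)))
  expect_equal(unname(tab["P4/mmm"]), 1)
  expect_equal(unname(tab["P4/m"]), 1)
  expect_equal(unname(tab["Cmmm"]), 1)
  expect_equal(unname(tab["Pmmm"]), 1)
  expect_equal(unname(tab["C12/m1"]), 2)   # orientational variants kept
  expect_equal(unname(tab["P12/m1"]), 3)
  expect_equal(unname(tab["P-1"]), 1)
  # chain bookkeeping: n_chains_in_asu x |rotation group| = chains in P1
  for (s in st) expect_equal(s@nChainsAsu * length(s@ops), 24)
  chains <- vapply(st, function(s) s@nChainsAsu, numeric(1))
  names(chains) <- vapply(st, symbol, character(1))
  expect_equal(unname(chains["P4/mmm"]), 3)
  expect_equal(unname(chains["P4/m"]), 6)
  # exact metric: every setting has max_delta 0
  expect_true(all(vapply(st, function(s) s@maxDelta, numeric(1)) < 1e-9))
  # settings are sorted by decreasing rotation order
  ords <- vapply(st, function(s) length(s@ops), numeric(1))
  expect_true(all(diff(ords) <= 0))
})

test_that("triclinic metric yields only the P-1 setting", {
  cell <- unitCell(31, 42, 53, 95, 100, 105)
  st <- enumeratePattersonSettings(cell, findLatticeTwofolds(cell), 5)
  expect_length(st, 1)
  expect_equal(symbol(st[[1]]), "P-1")
  expect_equal(st[[1]]@nChainsAsu, 5)
  expect_equal(st[[1]]@maxDelta, 0)
})

test_that("cubic settings are exactly the rotation subgroups of the holohedry", {
  cell <- unitCell(28, 28, 28)
  st <- enumeratePattersonSettings(cell, findLatticeTwofolds(cell), 24)
  # independent oracle: exhaustive closure of all <= 3-element generator
  # subsets of the 24 proper cubic rotations, implemented with raw matrices
  gens <- list(diag(3))
  perms <- list(diag(3)[, c(2, 3, 1)], diag(3)[, c(3, 1, 2)], diag(3))
  signs <- list()
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1))
    signs <- c(signs, list(diag(c(s1, s2, s3))))
  rots <- list()
  for (p in list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(1, 3, 2), c(3, 2, 1), c(2, 1, 3)))
    for (sg in signs) {
      M <- sg %*% diag(3)[p, ]
      if (abs(det(M) - 1) < 1e-9) rots <- c(rots, list(M))
    }
  expect_length(rots, 24)
  keyM <- function(M) paste(round(M), collapse = ",")
  closeSet <- function(gens) {
    ops <- list(diag(3)); keys <- keyM(diag(3))
    queue <- gens
    while (length(queue)) {
      M <- queue[[1]]; queue <- queue[-1]
      if (keyM(M) %in% keys) next
      ops <- c(ops, list(M)); keys <- c(keys, keyM(M))
      for (o in ops) {
        queue <- c(queue, list(M %*% o), list(o %*% M))
      }
    }
    sort(keys)
  }
  subKeys <- character(0)
  n <- length(rots)
  for (i in 1:n) for (j in i:n) {
    ck <- closeSet(list(rots[[i]], rots[[j]]))
    subKeys <- c(subKeys, paste(ck, collapse = ";"))
  }
  # identity is among the 24 rotations, so the trivial subgroup arises from
  # the (identity, identity) pair; no correction needed
  nOracle <- length(unique(subKeys))
  # oracle counts distinct subgroups generated by <= 2 elements; the
  # enumerated settings must match exactly
  expect_equal(length(st), nOracle)
  expect_equal(symbol(st[[1]]), "Pm-3m")
  expect_true("Pm-3" %in% vapply(st, symbol, character(1)))
})
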