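test_that("group closure reproduces hand-derived small groups", {
  expect_equal(length(operators(groupClosure(list()))), 1)     # P1
  p4 <- groupClosure(list(symOp("-y,x,z")))
  expect_equal(length(operators(p4)), 4)
  expect_setequal(vapply(operators(p4), opXyz, character(1)),
                  c("x,y,z", "-y,x,z", "-x,-y,z", "y,-x,z"))
  # P4_2: fourfolds carry w_z = 1/2, the twofold has no translation
  p42 <- groupClosure(list(symOp("-y,x,z+1/2")))
  xyzs <- vapply(operators(p42), opXyz, character(1))
  expect_setequal(xyzs, c("x,y,z", "-y,x,z+1/2", "-x,-y,z", "y,-x,z+1/2"))
  expect_error(groupClosure(list(symOp("x+1/16,y,z"), symOp("x,y+1/16,z"))),
               "192")
})

test_that("the 65-group catalogue satisfies the group axioms by exhaustion", {
  cat_ <- sohnckeGroups()
  expect_length(cat_, 65)
  expected_pointorder <- c("1" = 1, "2" = 2, "222" = 4, "4" = 4, "422" = 8,
                           "3" = 3, "312" = 6, "321" = 6, "32" = 6,
                           "6" = 6, "622" = 12, "23" = 12, "432" = 24)
  centringMult <- c(P = 1, A = 2, B = 2, C = 2, I = 2, F = 4, R = 3)
  for (g in cat_) {
    keys <- vapply(operators(g), xtalsym:::.opKey, character(1))
    expect_false(anyDuplicated(keys) > 0)
    pg <- attr(g, "pointGroup")
    expect_equal(length(keys),
                 unname(expected_pointorder[pg] * centringMult[g@centring]),
                 info = g@symbol)
    # closure and inverses, exhaustively
    for (a in operators(g)) {
      expect_true(xtalsym:::.opKey(solve(a)) %in% keys, info = g@symbol)
      for (b in operators(g))
        expect_true(xtalsym:::.opKey(a %*% b) %in% keys, info = g@symbol)
    }
    expect_true(g@sohncke)
  }
})

test_that("symbol lookup handles short, full and permuted settings", {
  expect_equal(spaceGroup("P 21 21 21")@symbol, "P212121")
  expect_equal(length(operators(spaceGroup("C2"))), 4)
  expect_error(spaceGroup("P-1"), "non-Sohncke|unknown")
  expect_error(spaceGroup("Pm-3m"), "non-Sohncke|unknown")
  # c-unique monoclinic variants
  expect_setequal(vapply(operators(spaceGroup("P112")), opXyz, character(1)),
                  c("x,y,z", "-x,-y,z"))
  expect_setequal(vapply(operators(spaceGroup("P1121")), opXyz, character(1)),
                  c("x,y,z", "-x,-y,z+1/2"))
  # permuted orthorhombic: screw along a
  g <- spaceGroup("P2122")
  ords <- sort(vapply(operators(g), function(o) sum(abs(translationPart(o))), numeric(1)))
  expect_equal(length(operators(g)), 4)
  expect_true(any(vapply(operators(g), function(o)
    isTRUE(all.equal(translationPart(o), c(1 / 2, 0, 0))), logical(1))))
})

test_that("standardizeSetting maps permuted settings onto the catalogue", {
  s <- standardizeSetting(spaceGroup("P2122"))
  expect_equal(s$group@symbol, "P2221")
  # already-conventional group: identity permutation works
  s2 <- standardizeSetting(spaceGroup("P4"))
  expect_equal(s2$group@symbol, "P4")
  expect_equal(rotationPart(s2$cb), diag(3))
  # both unique-axis monoclinic variants map to the b-unique entry
  expect_equal(standardizeSetting(spaceGroup("P1121"))$group@symbol, "P21")
  expect_equal(standardizeSetting(spaceGroup("P21"))$group@symbol, "P21")
  expect_error(standardizeSetting(groupClosure(list(symOp("-y,x,z+1/3") %*% symOp("-x,-y,z")))),
               "no catalogued setting|order")
})

test_that("left coset decomposition partitions G and is deterministic", {
  G <- spaceGroup("P4")
  cd1 <- leftCosets(G, spaceGroup("P1"))
  expect_equal(cd1@nCosets, 4)
  expect_length(cd1@representatives, 3)
  cd2 <- leftCosets(G, spaceGroup("P112"))
  expect_equal(cd2@nCosets, 2)
  expect_length(cd2@representatives, 1)
  expect_equal(opOrder(cd2@representatives[[1]])$order, 4)  # a fourfold
  # G = H: single coset, no representatives
  cd3 <- leftCosets(G, G)
  expect_equal(cd3@nCosets, 1)
  expect_length(cd3@representatives, 0)
  # not a subgroup: clear error naming the operator
  expect_error(leftCosets(G, spaceGroup("P2")), "not a subgroup.*-x,y,-z")
  # partition property, exhaustively, for a larger pair
  G2 <- spaceGroup("P422"); H2 <- spaceGroup("P112")
  cd <- leftCosets(G2, H2)
  expect_equal(cd@nCosets, 4)
  seen <- character(0)
  for (rep_ in c(list(identityOp()), cd@representatives)) {
    coset <- vapply(operators(H2), function(h) xtalsym:::.opKey(rep_ %*% h),
                    character(1))
    expect_length(intersect(coset, seen), 0)
    seen <- c(seen, coset)
  }
  expect_setequal(seen, vapply(operators(G2), xtalsym:::.opKey, character(1)))
})

test_that("candidate space groups are filtered by Patterson symmetry", {
  expect_equal(vapply(candidateSpaceGroups("P4/m"), symbol, character(1)),
               c("P4", "P41", "P42", "P43"))
  expect_equal(vapply(candidateSpaceGroups("P-1"), symbol, character(1)), "P1")
  p4mmm <- vapply(candidateSpaceGroups("P4/mmm"), symbol, character(1))
  expect_length(p4mmm, 8)
  expect_true(all(grepl("^P4", p4mmm)))
  # enantiomorphic pairs are both present
  expect_true(all(c("P41", "P43") %in% p4mmm == c(FALSE, FALSE)))
  expect_true(all(c("P4122", "P4322") %in% p4mmm))
  expect_error(candidateSpaceGroups("X2/m"), "unknown")
})
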