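test_that("Kearsley superposition is exact and matches an SVD oracle", {
  set.seed(17)
  A <- matrix(rnorm(150), 50, 3)
  expect_equal(kearsleySuperpose(A, A)$rmsd, 0, tolerance = 1e-12)
  expect_equal(kearsleySuperpose(A, A)$rotation, diag(3), tolerance = 1e-9)
  # known rotation + translation is recovered
  th <- 0.8
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  B <- sweep(A %*% t(Rz), 2, c(4, -2, 7), "+")
  k <- kearsleySuperpose(A, B)
  expect_lt(k$rmsd, 1e-9)
  expect_equal(k$rotation %*% Rz, diag(3), tolerance = 1e-9)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  # noisy clouds: rmsd agrees with an independent SVD (Kabsch) oracle
  for (seed in 1:5) {
    set.seed(seed)
    B2 <- B + matrix(rnorm(150, 0, 0.4), 50, 3)
    k2 <- kearsleySuperpose(A, B2)
    cA <- colMeans(A); cB <- colMeans(B2)
    X <- sweep(A, 2, cA); Y <- sweep(B2, 2, cB)
    s <- svd(t(Y) %*% X)
    R <- s$v %*% diag(c(1, 1, sign(det(s$v %*% t(s$u))))) %*% t(s$u)
    rms <- sqrt(sum((Y %*% t(R) - X)^2) / 50)
    expect_equal(k2$rmsd, rms, tolerance = 1e-8)
  }
  expect_error(kearsleySuperpose(A, A[1:10, ]), "length")
  expect_error(kearsleySuperpose(A[1:2, ], A[1:2, ]), "3 points")
})

test_that("chain matching is a complete bijection on a perfect fixture", {
  fx <- fixP4()
  model <- fx$model
  H <- model@group
  G <- spaceGroup("P4")
  cosets <- leftCosets(G, H)
  mm <- matchChains(model, H, cosets, tol = 2)
  expect_length(mm$unmatched, 0)
  expect_length(mm$matches, (cosets@nCosets - 1) * nChains(model))
  expect_true(all(vapply(mm$matches, function(m) m$rmsd, numeric(1)) < 1e-9))
  # per coset, the X -> Y map is a bijection
  for (ci in seq_along(cosets@representatives)) {
    ys <- vapply(Filter(function(m) m$coset == ci, mm$matches),
                 function(m) m$Y, numeric(1))
    expect_setequal(ys, seq_len(nChains(model)))
  }
  # displacing one chain by 10 A breaks its matches
  broken <- model
  broken@chains[[1]]$xyz <- broken@chains[[1]]$xyz +
    rep(solve(orthMatrix(model@cell)) %*% c(10, 0, 0), each = nrow(broken@chains[[1]]$xyz))
  mm2 <- matchChains(broken, H, cosets, tol = 2)
  expect_gt(length(mm2$unmatched), 0)
  expect_true(any(vapply(mm2$unmatched, function(u) u$X == 1, logical(1))))
})

test_that("origin refinement recovers the exact shift and the Eq-8 identity holds", {
  fx <- fixP4()
  model <- fx$model
  H <- model@group
  G <- spaceGroup("P4")
  cosets <- leftCosets(G, H)
  # shift the model off-origin and match at a slightly wrong starting shift
  shift <- c(0.11, 0.07, 0)
  shifted <- shiftModel(model, shift)
  approx <- shiftModel(shifted, c(-0.10, -0.08, 0))   # x0 off by ~0.01
  mm <- matchChains(approx, H, cosets, tol = 2)
  expect_length(mm$unmatched, 0)
  # refinement runs on the unshifted model; the exact minimizer undoes `shift`
  ref <- refineOrigin(shifted, H, cosets, mm)
  expect_lt(shiftError(ref$xRefined, -shift, G), 1e-10)
  expect_lt(ref$deltaRSym, 1e-10)
  expect_equal(ref$deltaRSym^2 * ref$totalMatches, ref$fMin, tolerance = 1e-12)
  expect_error(refineOrigin(shifted, H, cosets, list(matches = list())), "no chain matches")
})

test_that("Delta r_sym scales as sqrt(6) sigma under per-coordinate noise", {
  sigma <- 0.05
  vals <- vapply(1:20, function(seed) {
    fx <- makeUnderassignedStructure("P4", chainsPerAsu = 1, nRes = 12,
                                     noiseSigma = sigma, subgroup = "P1",
                                     seed = 500 + seed)
    model <- fx$model
    H <- model@group
    G <- spaceGroup("P4")
    cosets <- leftCosets(G, H)
    mm <- matchChains(model, H, cosets, tol = 2)
    refineOrigin(model, H, cosets, mm)$deltaRSym
  }, numeric(1))
  expect_equal(mean(vals), sqrt(6) * sigma, tolerance = 0.15)
})

test_that("ASU models are built per coset and the deviation split behaves", {
  fx <- fixP4()
  model <- fx$model
  H <- model@group
  G <- spaceGroup("P4")
  cosets <- leftCosets(G, H)
  mm <- matchChains(model, H, cosets, tol = 2)
  asu <- buildAsuModels(model, H, cosets, mm, c(0, 0, 0))
  expect_length(asu$models, cosets@nCosets)
  P <- nChains(model)
  for (m in asu$models) expect_equal(nChains(m), P / cosets@nCosets)
  # perfect fixture: all models identical to <= 1e-9 A
  O <- orthMatrix(model@cell)
  ref <- do.call(rbind, lapply(asu$models[[1]]@chains, function(ch) t(O %*% t(ch$xyz))))
  for (m in asu$models[-1]) {
    other <- do.call(rbind, lapply(m@chains, function(ch) t(O %*% t(ch$xyz))))
    expect_lt(max(abs(other - ref)), 1e-9)
  }
  rd <- residualDeviations(asu)
  expect_lt(rd$deltaRAsu, 1e-9)
  expect_lt(rd$deltaRChain, 1e-9)
  # models differing only by a rigid shift of the whole ASU:
  # Delta r_ASU collapses to ~0 while the raw deviation does not
  asu2 <- asu
  m2 <- asu2$models[[2]]
  m2@chains <- lapply(m2@chains, function(ch) { ch$xyz <- ch$xyz + 0.02; ch })
  asu2$models[[2]] <- m2
  rd2 <- residualDeviations(asu2)
  expect_lt(rd2$deltaRAsu, 1e-9)
  # noisy fixture: Delta r_ASU ~ Delta r_chain ~ Delta r_sym within 10%
  fxn <- makeUnderassignedStructure("P4", chainsPerAsu = 1, nRes = 25,
                                    noiseSigma = 0.05, subgroup = "P1",
                                    seed = 77)
  mn <- fxn$model
  cosetsN <- leftCosets(G, mn@group)
  mmn <- matchChains(mn, mn@group, cosetsN, tol = 2)
  refn <- refineOrigin(mn, mn@group, cosetsN, mmn)
  asun <- buildAsuModels(mn, mn@group, cosetsN, mmn, refn$xRefined)
  rdn <- residualDeviations(asun)
  expect_equal(rdn$deltaRAsu, refn$deltaRSym, tolerance = 0.10)
  expect_equal(rdn$deltaRChain, refn$deltaRSym, tolerance = 0.10)
  expect_lte(rdn$deltaRAsu, refn$deltaRSym + 1e-9)
  expect_lte(rdn$deltaRChain, rdn$deltaRAsu + 1e-6)
})
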