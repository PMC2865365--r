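# Shared fixtures and independent oracles for the test suite.
# Fixtures are generated in code (seeded) and cached per test run.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- builder()
  .fixtureCache[[key]]
}

# perfect P4 crystal presented as P1 (2 chains x 12 residues per true ASU)
fixP4 <- function() cached("p4", function()
  makeUnderassignedStructure("P4", chainsPerAsu = 2, nRes = 12, noiseSigma = 0,
                             subgroup = "P1", seed = 42))

# P1 scatterers of a model (full cell contents)
scatOf <- function(model) asScatterers(expandToP1(model))

# independent direct-summation structure-factor oracle (explicit double loop,
# no vectorized shortcuts shared with the implementation)
sfOracle <- function(xyz, occ, B, w, cell, hkl) {
  Gstar <- solve(metricTensor(cell))
  out <- complex(nrow(hkl))
  for (r in seq_len(nrow(hkl))) {
    H <- hkl[r, ]
    s2 <- as.numeric(H %*% Gstar %*% H)
    acc <- 0 + 0i
    for (j in seq_len(nrow(xyz))) {
      acc <- acc + w[j] * occ[j] * exp(-B[j] * s2 / 4) *
        exp(2i * pi * sum(H * xyz[j, ]))
    }
    out[r] <- acc
  }
  out
}

# minimal distance between the refined shift and an expected shift, taken
# modulo the allowed-origin translations of `group` and ignoring polar
# directions
shiftError <- function(xRefined, xExpected, group) {
  N <- xtalsym:::.polarBasis(group)
  proj <- function(v) {
    if (!ncol(N)) return(v)
    as.numeric(v - N %*% solve(crossprod(N), crossprod(N, v)))
  }
  sh <- allowedOriginShifts(group)
  best <- Inf
  for (i in seq_len(nrow(sh))) {
    d <- proj(xRefined - xExpected - sh[i, ])
    d <- d - round(d)
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# build a tiny monoclinic (c-unique) model whose assigned group contains the
# twofold along z; used for the crystallographic-operator limit checks
fixMonoclinicZ <- function(nSites = 50, seed = 4) {
  cell <- unitCell(28, 24, 20, 90, 90, 105)
  set.seed(seed)
  asu <- cbind(runif(nSites, 0.03, 0.45), runif(nSites, 0.03, 0.45),
               runif(nSites))
  crystalModel(cell, spaceGroup("P112"),
               list(list(id = "A", seq = rep("ALA", nSites), xyz = asu)))
}
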