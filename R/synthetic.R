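#' @include model.R structurefactors.R spacegroup.R
NULL

# run expr with a private RNG stream (Mersenne-Twister seeded by `seed`),
# restoring the caller's stream afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Generate a compact self-avoiding C-alpha trace
#'
#' Random walk with 3.8 Angstrom steps (consecutive C-alpha spacing), a
#' minimum non-consecutive separation of 4.0 Angstrom, confined to a sphere
#' whose radius grows with chain length so the trace stays protein-like in
#' compactness.  Deterministic for a given seed.
#'
#' @param nRes number of residues (>= 5).
#' @param seed integer seed.
#' @return nRes x 3 cartesian coordinate matrix centred at the origin.
#' @export
makeChain <- function(nRes, seed) {
  stopifnot(nRes >= 5)
  radius <- 3.2 * nRes^(1 / 3) + 3.5
  .withSeed(seed, {
    for (attempt in 1:200) {
      pts <- matrix(0, nRes, 3)
      k <- 1; tries <- 0
      while (k < nRes && tries < 500 * nRes) {
        tries <- tries + 1
        d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
        p <- pts[k, ] + 3.8 * d
        if (sqrt(sum(p^2)) > radius) next
        if (k >= 2) {
          dd <- sqrt(rowSums(sweep(pts[1:(k - 1), , drop = FALSE], 2, p)^2))
          if (min(dd) < 4.0) next
        }
        k <- k + 1
        pts[k, ] <- p
      }
      if (k == nRes) return(sweep(pts, 2, colMeans(pts)))
    }
    stop("chain placement failed after bounded retries")
  })
}

# default cell for a crystal system, scaled so that `natoms` C-alpha sites
# fit at loose protein-like packing
.defaultCell <- function(system, natoms) {
  vtarget <- max(6000, natoms * 170)
  shape <- switch(system,
    triclinic = c(1, 1.15, 1.3), monoclinic = c(1, 0.85, 1.25),
    orthorhombic = c(1, 1.2, 1.45), tetragonal = c(1, 1, 0.72),
    trigonal = c(1, 1, 0.85), hexagonal = c(1, 1, 0.85),
    cubic = c(1, 1, 1))
  angles <- switch(system,
    triclinic = c(95, 100, 105), monoclinic = c(90, 105, 90),
    trigonal = c(90, 90, 120), hexagonal = c(90, 90, 120),
    c(90, 90, 90))
  sinf <- prod(sin(angles * pi / 180))
  s <- (vtarget / (prod(shape) * sinf))^(1 / 3)
  unitCell(s * shape[1], s * shape[2], s * shape[3],
           angles[1], angles[2], angles[3])
}

# minimum-image clash test of cartesian-new vs existing fractional sites
.clashes <- function(fracNew, fracOld, O, minDist = 3.0) {
  if (!nrow(fracOld)) return(FALSE)
  for (i in seq_len(nrow(fracNew))) {
    d <- sweep(fracOld, 2, fracNew[i, ])
    d <- d - round(d)
    dc <- t(O %*% t(d))
    if (min(sqrt(rowSums(dc^2))) < minDist) return(TRUE)
  }
  FALSE
}

#' Build a synthetic crystal with intentionally underassigned symmetry
#'
#' Chains are generated in the asymmetric unit of `trueGroup`, expanded by
#' the left-coset representatives into the asymmetric unit of `subgroup`
#' (so the cell content is exactly preserved), independently perturbed with
#' isotropic Gaussian coordinate noise, origin-shifted, and optionally put
#' through a random unimodular change of basis.  The returned model is
#' labelled with `subgroup` only; the ground truth records what was hidden.
#'
#' @param trueGroup Hermann-Mauguin symbol of the true symmetry.
#' @param chainsPerAsu chains in the true asymmetric unit (default 2).
#' @param nRes residues per chain (default 20).
#' @param noiseSigma Gaussian sigma per cartesian coordinate (Angstrom).
#' @param originShift fractional triple applied to the presented model.
#' @param subgroup symbol of the assigned (presented) symmetry; must be a
#'   subgroup of `trueGroup` in the same frame.
#' @param cbScramble logical: apply a random unimodular change of basis.
#' @param rigidSigma optional list(rotDeg=, transA=) adding a per-chain
#'   rigid-body perturbation (random rotation about the chain centroid up to
#'   rotDeg degrees, translation up to transA Angstrom): this creates true
#'   pseudosymmetry, where the deviation is *not* explained by atomic noise.
#' @param seed integer seed controlling every random choice.
#' @return list with `model` (a [CrystalModel-class] presented in
#'   `subgroup`) and `truth` (list: trueGroup, presentedGroup, appliedCb,
#'   appliedOriginShift, noiseSigma, seed).
#' @export
makeUnderassignedStructure <- function(trueGroup, chainsPerAsu = 2, nRes = 20,
                                       noiseSigma = 0, originShift = c(0, 0, 0),
                                       subgroup = "P1", cbScramble = FALSE,
                                       rigidSigma = NULL, seed = 1) {
  G <- spaceGroup(trueGroup)
  H <- spaceGroup(subgroup)
  bad <- isSubgroup(G, H)
  if (!isTRUE(bad))
    stop("'", subgroup, "' is not a subgroup of '", trueGroup,
         "' in the reference setting (operator ", bad, ")")
  catEntry <- .buildCatalogue()[[G@symbol]]
  if (is.null(catEntry))
    stop("trueGroup must be a reference-setting catalogue symbol, got '",
         trueGroup, "'")
  sys <- catEntry@crystalSystem
  natoms <- chainsPerAsu * length(G@ops) * nRes
  cell <- .defaultCell(sys, natoms)
  ops <- operators(G)
  .withSeed(seed + 7L, {
    for (growth in 1:6) {
      O <- orthMatrix(cell)
      Oinv <- solve(O)
      placed <- matrix(numeric(0), 0, 3)
      chains <- list()
      ok <- TRUE
      for (i in seq_len(chainsPerAsu)) {
        trace <- makeChain(nRes, seed + 131L * i)
        success <- FALSE
        for (try_ in 1:60) {
          # random orientation + random position
          q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
          R <- matrix(c(
            1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
            2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
            2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
          centre <- stats::runif(3)
          frac <- t(Oinv %*% t(trace %*% t(R))) + rep(centre, each = nRes)
          # all symmetry images of the candidate chain
          imgs <- lapply(ops, function(op) applyOp(frac, op))
          allimg <- do.call(rbind, imgs)
          # self-image clash (between distinct images) and clash vs placed
          selfbad <- FALSE
          for (a in seq_along(imgs)) {
            for (b in seq_along(imgs)) {
              if (b <= a) next
              if (.clashes(imgs[[a]], imgs[[b]], O)) { selfbad <- TRUE; break }
            }
            if (selfbad) break
          }
          if (selfbad || .clashes(allimg, placed, O)) next
          placed <- rbind(placed, allimg)
          chains[[i]] <- list(id = LETTERS[i],
                              seq = sample(.aa3, nRes, replace = TRUE),
                              xyz = frac)
          success <- TRUE
          break
        }
        if (!success) { ok <- FALSE; break }
      }
      if (ok) break
      cell <- do.call(unitCell, as.list(c(cell@abc * 1.15, cell@angles)))
    }
    if (!ok) stop("impossible geometry: cell too small for the requested contents")

    # expand the true-group ASU into the subgroup ASU via coset representatives
    cosets <- leftCosets(G, H)
    reps <- c(list(identityOp()), cosets@representatives)
    presented <- list()
    idx <- 0
    for (r in reps) {
      for (ch in chains) {
        idx <- idx + 1
        nc <- ch
        nc$xyz <- applyOp(ch$xyz, r)
        nc$id <- LETTERS[(idx - 1) %% 26 + 1]
        if (idx > 26) nc$id <- paste0(nc$id, (idx - 1) %/% 26)
        presented <- c(presented, list(nc))
      }
    }
    O <- orthMatrix(cell)
    Oinv <- solve(O)
    presented <- lapply(presented, function(ch) {
      xyz <- ch$xyz
      if (!is.null(rigidSigma)) {
        th <- stats::runif(1, 0, rigidSigma$rotDeg) * pi / 180
        ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
        K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
        R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
        tr <- stats::runif(3, -1, 1); tr <- tr / sqrt(sum(tr^2)) * stats::runif(1, 0, rigidSigma$transA)
        cart <- t(O %*% t(xyz))
        cen <- colMeans(cart)
        cart <- sweep(sweep(cart, 2, cen) %*% t(R), 2, cen + tr, "+")
        xyz <- t(Oinv %*% t(cart))
      }
      if (noiseSigma > 0) {
        cart <- t(O %*% t(xyz)) + matrix(stats::rnorm(length(xyz), 0, noiseSigma),
                                         ncol = 3)
        xyz <- t(Oinv %*% t(cart))
      }
      ch$xyz <- sweep(xyz, 2, originShift, "+")
      ch
    })
    model <- crystalModel(cell, H, presented,
                          provenance = sprintf("synthetic %s-in-%s seed %d",
                                               trueGroup, subgroup, seed))
    cb <- NULL
    if (cbScramble) {
      cb <- randomUnimodularBasis(seed + 97L)
      model <- changeBasis(model, cb)
      model@group@symbol <- H@symbol
    }
    list(model = model,
         truth = list(trueGroup = trueGroup, presentedGroup = subgroup,
                      appliedCb = cb, appliedOriginShift = originShift,
                      noiseSigma = noiseSigma, seed = seed))
  })
}

#' Simulate observed reflection intensities for a model
#'
#' Calculated intensities with multiplicative Gaussian noise (coefficient of
#' variation `fracNoise`), randomly thinned to the requested completeness
#' and merged in the model's assigned group.
#'
#' @param model a [CrystalModel-class].
#' @param dmin resolution limit (default 3.5 Angstrom).
#' @param fracNoise CV of the multiplicative noise (default 0.05).
#' @param completeness fraction of the unique reflections retained.
#' @param seed integer seed.
#' @return a [ReflectionSet-class] merged in the model's group.
#' @export
simulateObservedIntensities <- function(model, dmin = 3.5, fracNoise = 0.05,
                                        completeness = 1.0, seed = 1) {
  stopifnot(completeness > 0, completeness <= 1)
  p1 <- expandToP1(model)
  sf <- calcStructureFactors(asScatterers(p1), dmin)
  merged <- mergeUnderGroup(sf, model@group)
  .withSeed(seed + 23L, {
    I <- merged@I * (1 + stats::rnorm(length(merged@I), 0, fracNoise))
    I[I < 0] <- 0
    keep <- seq_along(I)
    if (completeness < 1)
      keep <- sort(sample(keep, round(length(keep) * completeness)))
    reflectionSet(merged@cell, merged@group, merged@hkl[keep, , drop = FALSE],
                  I = I[keep], sigI = fracNoise * pmax(I[keep], 1e-6))
  })
}
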