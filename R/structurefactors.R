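#' @include AllClasses.R cell.R model.R
NULL

#' Friedel-unique Miller indices to a resolution limit
#'
#' One index per Friedel pair (hemisphere convention: l > 0, or l = 0 and
#' h > 0, or h = l = 0 and k > 0), excluding (0,0,0), at d >= dmin.
#'
#' @param cell a [UnitCell-class].
#' @param dmin resolution limit in Angstrom.
#' @return n x 3 integer matrix.
#' @export
millerIndices <- function(cell, dmin) {
  stopifnot(dmin > 0)
  p <- cell@abc
  lim <- ceiling(p / dmin) + 1L
  g <- expand.grid(h = -lim[1]:lim[1], k = -lim[2]:lim[2], l = 0:lim[3])
  hkl <- as.matrix(g)
  keep <- hkl[, 3] > 0 | (hkl[, 3] == 0 & (hkl[, 1] > 0 | (hkl[, 1] == 0 & hkl[, 2] > 0)))
  hkl <- hkl[keep, , drop = FALSE]
  d <- dSpacing(cell, hkl)
  hkl <- hkl[d >= dmin, , drop = FALSE]
  if (!nrow(hkl)) stop("no reflections: dmin larger than the cell allows")
  dimnames(hkl) <- NULL
  hkl
}

# canonicalize indices into the Friedel hemisphere; returns list(hkl, conj)
.friedelCanon <- function(hkl) {
  inhemi <- hkl[, 3] > 0 | (hkl[, 3] == 0 & (hkl[, 1] > 0 | (hkl[, 1] == 0 & hkl[, 2] > 0)))
  flip <- !inhemi
  hkl[flip, ] <- -hkl[flip, , drop = FALSE]
  list(hkl = hkl, conj = flip)
}

.hklKey <- function(hkl) paste(hkl[, 1], hkl[, 2], hkl[, 3], sep = ",")

#' Construct a reflection set
#'
#' @param cell a [UnitCell-class].
#' @param group merging symmetry, a [SpaceGroup-class].
#' @param hkl n x 3 integer Miller indices.
#' @param I intensities; computed as F^2 when only `F` is given.
#' @param sigI,F,phi optional columns.
#' @return a [ReflectionSet-class].
#' @export
reflectionSet <- function(cell, group, hkl, I = NULL, sigI = NULL, F = NULL,
                          phi = NULL) {
  n <- nrow(hkl)
  if (is.null(I)) {
    stopifnot(!is.null(F))
    I <- F^2
  }
  new("ReflectionSet", cell = cell, group = group, hkl = hkl, I = as.numeric(I),
      sigI = if (is.null(sigI)) rep(NA_real_, n) else as.numeric(sigI),
      F = if (is.null(F)) rep(NA_real_, n) else as.numeric(F),
      phi = if (is.null(phi)) rep(NA_real_, n) else as.numeric(phi))
}

#' Number of reflections
#' @param x a [ReflectionSet-class].
#' @export
nReflections <- function(x) nrow(x@hkl)

setMethod("show", "ReflectionSet", function(object) {
  cat(sprintf("ReflectionSet: %d reflections, merging symmetry %s\n",
              nrow(object@hkl),
              if (nzchar(object@group@symbol)) object@group@symbol else "<anonymous>"))
})

# complex structure factors by direct summation over point scatterers
.complexSF <- function(scat, hkl) {
  Gstar <- solve(metricTensor(scat@cell))
  s2 <- rowSums((hkl %*% Gstar) * hkl)
  damp <- exp(-outer(s2 / 4, scat@B))   # nrefl x natom
  wocc <- scat@occ * scat@weight
  ph <- 2 * pi * (hkl %*% t(scat@xyz))
  Fc <- (cos(ph) * damp) %*% wocc + 1i * ((sin(ph) * damp) %*% wocc)
  as.complex(Fc)
}

#' Calculate structure factors from a point-scatterer model
#'
#' Direct summation F(H) = sum_j w_j occ_j exp(-B_j s^2/4) exp(2 pi i H x_j)
#' over the full P1 cell contents, for all Friedel-unique indices with
#' d >= dmin.  Phases are stored; the returned set's merging symmetry is P1.
#'
#' @param scat a [Scatterers-class] holding the *P1-expanded* model.
#' @param dmin resolution limit in Angstrom (default 3.5).
#' @return a [ReflectionSet-class] with I, F and phi populated.
#' @export
calcStructureFactors <- function(scat, dmin = 3.5) {
  if (!nrow(scat@xyz)) stop("empty scatterer model")
  hkl <- millerIndices(scat@cell, dmin)
  Fc <- .complexSF(scat, hkl)
  reflectionSet(scat@cell, spaceGroup("P1"), hkl, I = Mod(Fc)^2,
                F = Mod(Fc), phi = Arg(Fc))
}

#' Expand merged observations to P1 intensities
#'
#' Every symmetry-equivalent index under the set's merging group (Friedel
#' mates included) is populated with the merged value; amplitudes are
#' squared into intensities when intensities are absent.  Negative
#' intensities are clipped to zero (their count is attached as the
#' `nClipped` attribute).
#'
#' @param obs a [ReflectionSet-class] with its merging group set.
#' @return a [ReflectionSet-class] in P1.
#' @export
expandObsToP1 <- function(obs) {
  if (!length(obs@group@ops)) stop("observations carry no merging symmetry")
  I <- obs@I
  nclip <- sum(I < 0)
  if (nclip) {
    warning(nclip, " negative intensities clipped to 0")
    I[I < 0] <- 0
  }
  allh <- list(); allI <- list()
  for (op in operators(obs@group)) {
    Hg <- obs@hkl %*% rotationPart(op)
    stopifnot(.ratIsIntegral(Hg))
    cc <- .friedelCanon(round(Hg))
    allh <- c(allh, list(cc$hkl)); allI <- c(allI, list(I))
  }
  hkl <- do.call(rbind, allh)
  Iv <- unlist(allI)
  keys <- .hklKey(hkl)
  keep <- !duplicated(keys)
  out <- reflectionSet(obs@cell, spaceGroup("P1"), hkl[keep, , drop = FALSE],
                       I = Iv[keep])
  attr(out, "nClipped") <- nclip
  out
}

#' Merge a P1 reflection set under a space group
#'
#' Orbit-averages intensities over the rotation parts of the group (with
#' Friedel equivalence) and returns one record per orbit representative
#' (the lexicographically smallest canonical index of the orbit).
#'
#' @param p1 a [ReflectionSet-class] in P1.
#' @param group a [SpaceGroup-class].
#' @return a [ReflectionSet-class] with merging symmetry `group`.
#' @export
mergeUnderGroup <- function(p1, group) {
  n <- nrow(p1@hkl)
  repkey <- rep(NA_character_, n)
  for (op in operators(group)) {
    Hg <- round(p1@hkl %*% rotationPart(op))
    cc <- .friedelCanon(Hg)
    kk <- .hklKey(cc$hkl)
    newrep <- is.na(repkey) | kk < repkey
    repkey[newrep] <- kk[newrep]
  }
  grp <- match(repkey, unique(repkey))
  Im <- tapply(p1@I, grp, mean)
  hklrep <- do.call(rbind, lapply(strsplit(unique(repkey), ","), as.numeric))
  reflectionSet(p1@cell, group, hklrep, I = as.numeric(Im[as.character(seq_along(unique(repkey)))]))
}

#' @describeIn changeBasis transform a reflection set: indices go
#'   contravariantly (h' = h R^-1, which must land on integers), the cell
#'   and merging group move along.
#' @export
setMethod("changeBasis", signature("ReflectionSet", "ChangeOfBasis"), function(x, cb, ...) {
  Rinv <- .ratAsNumeric(.ratInv(.cbR(cb)))
  hkl <- x@hkl %*% Rinv
  if (!.ratIsIntegral(hkl))
    stop("change of basis maps Miller indices off the lattice")
  cc <- .friedelCanon(round(hkl))
  x@hkl <- cc$hkl
  x@cell <- changeBasis(x@cell, cb)
  x@group <- changeBasis(x@group, cb)
  x@phi <- rep(NA_real_, nrow(cc$hkl))  # phases are frame-dependent; drop
  x
})
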