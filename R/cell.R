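#' @include AllClasses.R AllGenerics.R changebasis.R
NULL

#' Construct a unit cell
#'
#' @param a,b,c cell lengths in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees.
#' @return a [UnitCell-class].
#' @examples
#' unitCell(151.0, 151.0, 76.2, 90, 90, 90)
#' @export
unitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  new("UnitCell", abc = c(a, b, c), angles = c(alpha, beta, gamma))
}

#' @rdname cellParameters
#' @export
setMethod("cellParameters", "UnitCell", function(x) {
  stats::setNames(c(x@abc, x@angles), c("a", "b", "c", "alpha", "beta", "gamma"))
})

#' Metric tensor of a cell (Angstrom^2)
#' @param cell a [UnitCell-class].
#' @export
metricTensor <- function(cell) {
  p <- cell@abc; ang <- cell@angles * pi / 180
  ca <- cos(ang[1]); cb <- cos(ang[2]); cg <- cos(ang[3])
  G <- matrix(c(p[1]^2, p[1] * p[2] * cg, p[1] * p[3] * cb,
                p[1] * p[2] * cg, p[2]^2, p[2] * p[3] * ca,
                p[1] * p[3] * cb, p[2] * p[3] * ca, p[3]^2), 3, 3)
  G
}

#' Orthogonalization matrix (cartesian = O %*% fractional)
#'
#' PDB convention: a along x, b in the xy plane.
#' @param cell a [UnitCell-class].
#' @export
orthMatrix <- function(cell) {
  p <- cell@abc; ang <- cell@angles * pi / 180
  ca <- cos(ang[1]); cb <- cos(ang[2]); cg <- cos(ang[3]); sg <- sin(ang[3])
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(p[1], p[2] * cg, p[3] * cb,
           0,    p[2] * sg, p[3] * (ca - cb * cg) / sg,
           0,    0,         p[3] * v / sg), 3, 3, byrow = TRUE)
}

#' Cell volume in Angstrom^3
#' @param cell a [UnitCell-class].
#' @export
cellVolume <- function(cell) {
  ang <- cell@angles * pi / 180
  ca <- cos(ang[1]); cb <- cos(ang[2]); cg <- cos(ang[3])
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0) return(0)
  prod(cell@abc) * sqrt(arg)
}

#' Resolution of reflections (Angstrom)
#' @param cell a [UnitCell-class].
#' @param hkl n x 3 integer matrix of Miller indices.
#' @export
dSpacing <- function(cell, hkl) {
  Gstar <- solve(metricTensor(cell))
  s2 <- rowSums((hkl %*% Gstar) * hkl)
  1 / sqrt(s2)
}

.cellFromMetric <- function(G) {
  a <- sqrt(G[1, 1]); b <- sqrt(G[2, 2]); c <- sqrt(G[3, 3])
  al <- acos(G[2, 3] / (b * c)) * 180 / pi
  be <- acos(G[1, 3] / (a * c)) * 180 / pi
  ga <- acos(G[1, 2] / (a * b)) * 180 / pi
  unitCell(a, b, c, al, be, ga)
}

#' @describeIn changeBasis transform a unit cell: with coordinate action
#'   x' = R x, the new basis (columns) is A' = A R^-1 and the metric tensor
#'   becomes (R^-1)' G R^-1.
#' @export
setMethod("changeBasis", signature("UnitCell", "ChangeOfBasis"), function(x, cb, ...) {
  Rinv <- .ratAsNumeric(.ratInv(.cbR(cb)))
  G <- metricTensor(x)
  .cellFromMetric(t(Rinv) %*% G %*% Rinv)
})

#' Idealize a cell to the constraints of a crystal system
#'
#' Averages the parameters that a crystal system constrains to be equal and
#' snaps constrained angles to exactly 90 or 120 degrees, leaving free
#' parameters untouched.  Used when a near-symmetric reduced cell is taken
#' into a candidate higher-symmetry frame, so that candidate operators map
#' the idealized lattice exactly.
#'
#' @param cell a [UnitCell-class].
#' @param system one of "triclinic", "monoclinic", "orthorhombic",
#'   "tetragonal", "trigonal", "hexagonal", "rhombohedral", "cubic".
#' @return a [UnitCell-class].
#' @export
symmetrizeCell <- function(cell, system) {
  p <- cell@abc; ang <- cell@angles
  switch(system,
    triclinic = cell,
    monoclinic = unitCell(p[1], p[2], p[3], 90, ang[2], 90),
    orthorhombic = unitCell(p[1], p[2], p[3], 90, 90, 90),
    tetragonal = {
      ab <- mean(p[1:2]); unitCell(ab, ab, p[3], 90, 90, 90)
    },
    trigonal = ,
    hexagonal = {
      ab <- mean(p[1:2]); unitCell(ab, ab, p[3], 90, 90, 120)
    },
    rhombohedral = {
      ab <- mean(p[1:2]); unitCell(ab, ab, p[3], 90, 90, 120)
    },
    cubic = {
      m <- mean(p); unitCell(m, m, m, 90, 90, 90)
    },
    stop("unknown crystal system: ", system))
}

setMethod("show", "UnitCell", function(object) {
  p <- cellParameters(object)
  cat(sprintf("UnitCell: a=%.3f b=%.3f c=%.3f  alpha=%.3f beta=%.3f gamma=%.3f\n",
              p[1], p[2], p[3], p[4], p[5], p[6]))
})
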