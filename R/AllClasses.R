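#' @import methods
NULL

#' Exact crystallographic symmetry operation
#'
#' A symmetry operation acts on fractional coordinates as
#' \eqn{x' = W x + w} with a rational rotation part \eqn{W} and a rational
#' translation part \eqn{w} reduced modulo 1 into \eqn{[0,1)}.  All algebra
#' (composition, inversion, change of basis) is exact: parts are stored as
#' integer numerator arrays over a single positive denominator.
#'
#' @slot Wnum integer-valued 3x3 numerator matrix of the rotation part.
#' @slot Wden positive scalar denominator of the rotation part.
#' @slot wnum integer-valued length-3 numerator of the translation part.
#' @slot wden positive scalar denominator of the translation part.
#' @seealso [symOp()], [opXyz()], [rotationPart()], [translationPart()]
#' @export
setClass("SymOp",
  representation(Wnum = "matrix", Wden = "numeric",
                 wnum = "numeric", wden = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (!all(dim(object@Wnum) == c(3, 3))) msg <- c(msg, "W must be 3x3")
    if (object@Wden <= 0 || object@wden <= 0) msg <- c(msg, "denominators must be positive")
    if (!.ratIsIntegral(object@Wnum) || !.ratIsIntegral(object@wnum))
      msg <- c(msg, "numerators must be integral")
    d <- det(object@Wnum) / object@Wden^3
    if (abs(abs(d) - 1) > 1e-9) msg <- c(msg, "det(W) must be +1 or -1")
    if (length(msg)) msg else TRUE
  })

#' Rational change-of-basis operator
#'
#' Re-expresses a structure in a new reference frame: fractional coordinates
#' transform covariantly as \eqn{x' = R x + T}, Miller indices contravariantly
#' as \eqn{h' = h R^{-1}}, and symmetry operations by conjugation
#' \eqn{g' = (R,T)\, g\, (R,T)^{-1}}.  \eqn{R} and \eqn{T} are exact rationals
#' and the operator is always invertible.
#'
#' @slot Rnum,Rden numerator matrix / denominator of the rotation part.
#' @slot Tnum,Tden numerator vector / denominator of the translation part.
#' @seealso [changeOfBasis()], [changeBasis()]
#' @export
setClass("ChangeOfBasis",
  representation(Rnum = "matrix", Rden = "numeric",
                 Tnum = "numeric", Tden = "numeric"),
  validity = function(object) {
    if (abs(det(object@Rnum)) < 0.5) return("R must be invertible")
    if (object@Rden <= 0 || object@Tden <= 0) return("denominators must be positive")
    TRUE
  })

#' Space group as an explicit finite operator set
#'
#' Holds the complete list of symmetry operations of one cell (point
#' operations composed with centring translations included), closed under
#' composition and inversion.  Catalogue instances carry their
#' Hermann-Mauguin symbol, crystal system and Patterson symmetry; groups
#' produced by [groupClosure()] or a change of basis may be anonymous.
#'
#' @slot symbol short Hermann-Mauguin symbol ("" if anonymous).
#' @slot ops list of [SymOp-class] objects (first element is the identity).
#' @slot sohncke logical; TRUE when all rotation parts are proper.
#' @slot pattersonSymbol Patterson symmetry symbol ("" if unknown).
#' @slot crystalSystem one of "triclinic", "monoclinic", ... ("" if unknown).
#' @slot centring centring letter ("P", "C", "I", "F", "R" or "").
#' @slot number space-group number (NA for anonymous groups).
#' @export
setClass("SpaceGroup",
  representation(symbol = "character", ops = "list", sohncke = "logical",
                 pattersonSymbol = "character", crystalSystem = "character",
                 centring = "character", number = "numeric"),
  prototype(symbol = "", sohncke = NA, pattersonSymbol = "",
            crystalSystem = "", centring = "", number = NA_real_))

#' Left coset decomposition of a space group over a subgroup
#'
#' Partition of a target group G into cosets of a subgroup H.  The first
#' coset is H itself (identity representative, omitted); the stored
#' representatives g_2..g_n are the trial operators that must be evaluated
#' when G is tested as a higher-symmetry candidate for a structure currently
#' described in H.
#'
#' @slot group the target group G.
#' @slot subgroup the subgroup H (expressed in G's frame).
#' @slot representatives list of [SymOp-class], one per non-identity coset.
#' @slot nCosets integer, |G| / |H|.
#' @export
setClass("CosetDecomposition",
  representation(group = "SpaceGroup", subgroup = "SpaceGroup",
                 representatives = "list", nCosets = "integer"))

#' Crystallographic unit cell
#'
#' Cell lengths in Angstrom, angles in degrees, with the derived
#' orthogonalization matrix O (PDB convention: a along x, b in the xy plane)
#' such that cartesian = O %*% fractional.
#'
#' @slot abc lengths (Angstrom).
#' @slot angles alpha, beta, gamma (degrees).
#' @export
setClass("UnitCell",
  representation(abc = "numeric", angles = "numeric"),
  validity = function(object) {
    if (any(object@abc <= 0)) return("cell lengths must be positive")
    if (any(object@angles <= 0) || any(object@angles >= 180))
      return("cell angles must lie in (0, 180)")
    if (cellVolume(object) <= 0) return("cell volume must be positive")
    TRUE
  })

#' Coordinate model of a crystal structure
#'
#' Chains of C-alpha sites in fractional coordinates, tied to a unit cell and
#' a space group.  Chain order preserves input-file order (the first-in-file
#' rule is used when reduced asymmetric-unit models are built).
#'
#' @slot cell a [UnitCell-class].
#' @slot group a [SpaceGroup-class].
#' @slot chains named list; each element is a list with elements `id`
#'   (character), `seq` (character vector of residue codes) and `xyz`
#'   (n x 3 matrix of fractional coordinates).
#' @slot provenance character; source path and parse notes.
#' @export
setClass("CrystalModel",
  representation(cell = "UnitCell", group = "SpaceGroup", chains = "list",
                 provenance = "character"),
  prototype(provenance = character(0)),
  validity = function(object) {
    for (ch in object@chains) {
      if (!is.matrix(ch$xyz) || ncol(ch$xyz) != 3) return("chain xyz must be n x 3")
      if (!all(is.finite(ch$xyz))) return("fractional coordinates must be finite")
    }
    TRUE
  })

#' Set of Bragg reflections
#'
#' Miller indices with intensities (optionally amplitudes and phases) tied to
#' a cell and a merging symmetry.  Friedel mates are treated as equivalent
#' throughout: indices are canonicalized to one hemisphere.
#'
#' @slot cell a [UnitCell-class].
#' @slot group merging symmetry, a [SpaceGroup-class].
#' @slot hkl n x 3 integer matrix of Miller indices.
#' @slot I numeric intensities (arbitrary scale).
#' @slot sigI numeric, optional (NA when absent).
#' @slot F numeric amplitudes, optional.
#' @slot phi numeric phases in radians, optional.
#' @export
setClass("ReflectionSet",
  representation(cell = "UnitCell", group = "SpaceGroup", hkl = "matrix",
                 I = "numeric", sigI = "numeric", F = "numeric",
                 phi = "numeric"),
  validity = function(object) {
    n <- nrow(object@hkl)
    if (length(object@I) != n) return("I must match hkl rows")
    if (!.ratIsIntegral(object@hkl)) return("Miller indices must be integers")
    TRUE
  })

#' Point-scatterer model for structure-factor synthesis
#'
#' Unit point scatterers at fractional positions with occupancies, isotropic
#' B factors (Angstrom^2) and scattering weights.  Every statistic in this
#' package (R_symop, the correlation map, the phase score) is invariant to
#' the per-atom form factor, so point scatterers suffice.
#'
#' @slot xyz n x 3 fractional coordinates.
#' @slot occ occupancies in (0, 1].
#' @slot B isotropic B factors (>= 0).
#' @slot weight scattering weights (> 0).
#' @slot cell a [UnitCell-class].
#' @export
setClass("Scatterers",
  representation(xyz = "matrix", occ = "numeric", B = "numeric",
                 weight = "numeric", cell = "UnitCell"),
  validity = function(object) {
    if (ncol(object@xyz) != 3) return("xyz must be n x 3")
    if (any(object@occ <= 0) || any(object@occ > 1)) return("occupancies must lie in (0,1]")
    if (any(object@B < 0)) return("B factors must be >= 0")
    TRUE
  })

#' Candidate Patterson setting
#'
#' One metrically allowed Patterson symmetry of a reduced cell: its rotation
#' operators (exact integer matrices in the reduced frame), the change of
#' basis to the conventional frame, the worst Le Page delta over its
#' operators and -- once scored -- the worst-case R_symop over its
#' non-identity operators.
#'
#' @slot pattersonSymbol conventional Patterson symbol (e.g. "P4/m").
#' @slot cbToConventional [ChangeOfBasis-class] reduced -> conventional frame.
#' @slot ops list of [SymOp-class]: the rotation group in the reduced frame.
#' @slot maxDelta worst Le Page delta (degrees) over the operators.
#' @slot nChainsAsu expected chains per asymmetric unit.
#' @slot maxRsymopCalc worst-case R_symop from calculated intensities (NA before scoring).
#' @slot maxRsymopObs same from observed intensities (NA when absent).
#' @slot plausible logical (NA before scoring).
#' @export
setClass("PattersonSetting",
  representation(pattersonSymbol = "character", cbToConventional = "ChangeOfBasis",
                 ops = "list", maxDelta = "numeric", nChainsAsu = "numeric",
                 maxRsymopCalc = "numeric", maxRsymopObs = "numeric",
                 plausible = "logical"),
  prototype(maxRsymopCalc = NA_real_, maxRsymopObs = NA_real_, plausible = NA))

#' Translation-search correlation map
#'
#' The Pearson correlation r(x, G) between merged model intensities and
#' intensities of the symmetry-superposed ensemble, evaluated on a fractional
#' grid over the unit cell.  Components of the peak position along polar
#' directions of G are canonicalized to zero.
#'
#' @slot group candidate [SpaceGroup-class].
#' @slot gridDivisions integer triple.
#' @slot values numeric array (gridDivisions) of correlation values.
#' @slot xMax fractional triple of the highest peak.
#' @slot rMax correlation at the peak.
#' @export
setClass("CorrelationMap",
  representation(group = "SpaceGroup", gridDivisions = "integer",
                 values = "array", xMax = "numeric", rMax = "numeric"))

#' Verdict of a symmetry check against one target group
#'
#' All quantities needed to judge whether the input structure should be
#' re-assigned: coset count, refined origin shift, phase scores, RMS C-alpha
#' deviations (total / after whole-ASU alignment / after per-chain
#' alignment), worst-case R_symop for calculated and observed intensities,
#' and the resulting plausibility flag.
#'
#' @slot inputGroup,targetGroup Hermann-Mauguin symbols.
#' @slot nCosets integer.
#' @slot xRefined refined fractional origin shift.
#' @slot maxPhi worst phase-agreement score over coset representatives.
#' @slot deltaRSym,deltaRAsu,deltaRChain RMS C-alpha deviations (Angstrom).
#' @slot rsymopCalcMax,rsymopObsMax worst-case R_symop fractions.
#' @slot candidate logical verdict.
#' @slot details list of free-form stage diagnostics.
#' @export
setClass("SymmetryReport",
  representation(inputGroup = "character", targetGroup = "character",
                 nCosets = "integer", xRefined = "numeric", maxPhi = "numeric",
                 deltaRSym = "numeric", deltaRAsu = "numeric",
                 deltaRChain = "numeric", rsymopCalcMax = "numeric",
                 rsymopObsMax = "numeric", candidate = "logical",
                 details = "list"),
  prototype(rsymopObsMax = NA_real_, deltaRAsu = NA_real_,
            deltaRChain = NA_real_, details = list()))
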