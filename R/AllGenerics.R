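#' @include AllClasses.R
NULL

#' Rotation part of a symmetry operation
#' @param x a [SymOp-class] or [ChangeOfBasis-class].
#' @return numeric 3x3 matrix.
#' @export
setGeneric("rotationPart", function(x) standardGeneric("rotationPart"))

#' Translation part of a symmetry operation
#' @param x a [SymOp-class] or [ChangeOfBasis-class].
#' @return numeric length-3 vector.
#' @export
setGeneric("translationPart", function(x) standardGeneric("translationPart"))

#' Hermann-Mauguin (or Patterson) symbol of an object
#' @param x a [SpaceGroup-class] or [PattersonSetting-class].
#' @export
setGeneric("symbol", function(x) standardGeneric("symbol"))

#' Operator list of a space group
#' @param x a [SpaceGroup-class].
#' @return list of [SymOp-class].
#' @export
setGeneric("operators", function(x) standardGeneric("operators"))

#' Re-express an object in a new reference frame
#'
#' Applies a rational change-of-basis operator to an object: fractional
#' coordinates transform as x' = R x + T, Miller indices as h' = h R^-1,
#' symmetry operations by conjugation.  The entire object moves as a rigid
#' body, so its symmetry properties are invariant.
#'
#' @param x a [SymOp-class], [SpaceGroup-class], [UnitCell-class],
#'   [CrystalModel-class], [ReflectionSet-class] or coordinate matrix.
#' @param cb a [ChangeOfBasis-class].
#' @param ... further arguments for methods.
#' @return an object of the same kind as `x`.
#' @export
setGeneric("changeBasis", function(x, cb, ...) standardGeneric("changeBasis"))

#' Number of chains in a model
#' @param x a [CrystalModel-class].
#' @export
setGeneric("nChains", function(x) standardGeneric("nChains"))

#' Cell parameters (a, b, c, alpha, beta, gamma)
#' @param x a [UnitCell-class] or object carrying one.
#' @export
setGeneric("cellParameters", function(x) standardGeneric("cellParameters"))
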