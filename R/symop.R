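#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a symmetry operation
#'
#' Builds a [SymOp-class] either from an xyz triplet string in the dialect of
#' PDB REMARK 290 / mmCIF `_symmetry_equiv_pos_as_xyz` (e.g.
#' `"-y,x,z+1/2"`), or from an explicit rotation matrix and translation
#' vector whose entries are ratios of small integers.  The translation is
#' reduced modulo 1 into `[0,1)` and all components are stored exactly.
#'
#' @param xyz xyz triplet string, or NULL when `W`/`w` are given.
#' @param W 3x3 rational rotation part (numeric, entries p/q with q <= 48).
#' @param w length-3 rational translation part.
#' @return a [SymOp-class].
#' @examples
#' symOp("-y,x,z")            # fourfold about z
#' symOp(W = diag(3), w = c(1/2, 1/2, 0))  # centring translation
#' @export
symOp <- function(xyz = NULL, W = NULL, w = c(0, 0, 0)) {
  if (!is.null(xyz)) {
    p <- .parseXyz(xyz)
    return(.symOpFromRat(p$W, p$w))
  }
  stopifnot(!is.null(W))
  .symOpFromRat(.approxRat(W), .approxRat(w))
}

# convert a numeric matrix/vector with small-denominator rational entries
.approxRat <- function(x, maxden = 48) {
  for (d in 1:maxden) {
    if (.ratIsIntegral(x * d, tol = 1e-6)) return(.ratNew(round(x * d), d))
  }
  stop("entries are not small-denominator rationals")
}

.symOpFromRat <- function(W, w) {
  w <- .ratMod1(w)
  new("SymOp", Wnum = W$num, Wden = W$den, wnum = w$num, wden = w$den)
}

.opW <- function(op) list(num = op@Wnum, den = op@Wden)
.opw <- function(op) list(num = op@wnum, den = op@wden)

#' @describeIn symOp identity operation
#' @export
identityOp <- function() symOp("x,y,z")

#' @rdname rotationPart
#' @export
setMethod("rotationPart", "SymOp", function(x) x@Wnum / x@Wden)

#' @rdname translationPart
#' @export
setMethod("translationPart", "SymOp", function(x) x@wnum / x@wden)

#' Compose two symmetry operations
#'
#' `a %*% b` applies `b` first, then `a`; the result is exact and its
#' translation is reduced modulo 1.
#' @param x,y [SymOp-class] objects.
#' @export
setMethod("%*%", signature("SymOp", "SymOp"), function(x, y) {
  W <- .ratMul(.opW(x), .opW(y))
  w <- .ratAdd(.ratMul(.opW(x), .opw(y)), .opw(x))
  .symOpFromRat(W, list(num = as.numeric(w$num), den = w$den))
})

#' Invert a symmetry operation (exact)
#' @param a a [SymOp-class].
#' @param b ignored.
#' @export
setMethod("solve", "SymOp", function(a, b, ...) {
  Winv <- .ratInv(.opW(a))
  wneg <- .ratMul(Winv, .ratNeg(.opw(a)))
  .symOpFromRat(Winv, list(num = as.numeric(wneg$num), den = wneg$den))
})

# canonical string key for hashing/equality
.opKey <- function(op) {
  paste(c(op@Wnum, op@Wden, op@wnum, op@wden), collapse = "/")
}

.opEq <- function(a, b) .opKey(a) == .opKey(b)

.isIdentityOp <- function(op) {
  all(op@Wnum == diag(3) * op@Wden) && all(op@wnum == 0)
}

#' xyz triplet string of an operation
#' @param op a [SymOp-class].
#' @return character, e.g. `"-y,x,z+1/2"`.
#' @export
opXyz <- function(op) .formatXyz(.opW(op), .opw(op))

#' Rotation order and axis of an operation
#'
#' The order is the smallest k with W^k = I; the axis is the primitive
#' integer direct-lattice direction invariant under W (for the identity the
#' axis is undefined).
#' @param op a [SymOp-class].
#' @return list with elements `order`, `axis` (integer triple or NULL),
#'   `proper` (logical).
#' @export
opOrder <- function(op) {
  W <- .opW(op)
  proper <- round(det(W$num)) / W$den^3 > 0
  acc <- W
  k <- 1
  while (!(acc$den == 1 && all(acc$num == diag(3))) && k <= 6) {
    acc <- .ratMul(acc, W)
    k <- k + 1
  }
  if (k > 6) stop("rotation part has order > 6: not crystallographic")
  axis <- NULL
  if (k > 1 && proper) {
    # sum of powers of W projects onto the invariant axis
    P <- W; S <- .ratAdd(.ratNew(diag(3)), W)
    for (i in 2:(k - 1)) { P <- .ratMul(P, W); S <- .ratAdd(S, P) }
    cols <- S$num
    j <- which(colSums(abs(cols)) > 0)[1]
    v <- cols[, j]
    v <- v / .gcdAll(v)
    # deterministic sign: first nonzero component positive
    if (v[which(v != 0)[1]] < 0) v <- -v
    axis <- round(v)
  }
  list(order = k, axis = axis, proper = proper)
}

# short operator notation such as "2_z", "4+_z", "3-_111", used in reports
.opShorthand <- function(op) {
  info <- opOrder(op)
  if (info$order == 1) return("1")
  if (!info$proper) return(paste0("-", info$order))
  ax <- info$axis
  axname <- {
    nm <- c("x", "y", "z")
    if (sum(ax != 0) == 1) nm[which(ax != 0)]
    else paste0(ifelse(ax < 0, "-", ""), abs(ax), collapse = "")
  }
  ord <- if (info$order == 2) "2" else {
    # sense of rotation: sign of the off-axis antisymmetric part
    W <- rotationPart(op)
    tr <- sum(diag(W))
    ssum <- (W[3, 2] - W[2, 3]) * ax[1] + (W[1, 3] - W[3, 1]) * ax[2] +
      (W[2, 1] - W[1, 2]) * ax[3]
    paste0(info$order, if (ssum >= 0) "+" else "-")
  }
  paste0(ord, "_", axname)
}

setMethod("show", "SymOp", function(object) {
  cat("SymOp:", opXyz(object), "\n")
})
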