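#' @include AllClasses.R AllGenerics.R symop.R
NULL

#' Construct a change-of-basis operator
#'
#' @param R 3x3 rational matrix: the coordinate action, x' = R x + T.
#' @param T length-3 rational translation.
#' @param xyz alternatively, an xyz triplet string.
#' @return a [ChangeOfBasis-class].
#' @examples
#' changeOfBasis(xyz = "-y,-x,-z")   # the axis swap a',b',c' = -b,-a,-c
#' @export
changeOfBasis <- function(R = diag(3), T = c(0, 0, 0), xyz = NULL) {
  if (!is.null(xyz)) {
    p <- .parseXyz(xyz)
    return(new("ChangeOfBasis", Rnum = p$W$num, Rden = p$W$den,
               Tnum = p$w$num, Tden = p$w$den))
  }
  Rr <- .approxRat(R); Tr <- .approxRat(T)
  new("ChangeOfBasis", Rnum = Rr$num, Rden = Rr$den, Tnum = Tr$num, Tden = Tr$den)
}

#' @describeIn changeOfBasis identity change of basis
#' @export
identityBasis <- function() changeOfBasis()

.cbR <- function(cb) list(num = cb@Rnum, den = cb@Rden)
.cbT <- function(cb) list(num = cb@Tnum, den = cb@Tden)

#' @rdname rotationPart
#' @export
setMethod("rotationPart", "ChangeOfBasis", function(x) x@Rnum / x@Rden)

#' @rdname translationPart
#' @export
setMethod("translationPart", "ChangeOfBasis", function(x) x@Tnum / x@Tden)

#' Compose change-of-basis operators (right one applies first)
#' @param x,y [ChangeOfBasis-class] objects.
#' @export
setMethod("%*%", signature("ChangeOfBasis", "ChangeOfBasis"), function(x, y) {
  R <- .ratMul(.cbR(x), .cbR(y))
  T_ <- .ratAdd(.ratMul(.cbR(x), .cbT(y)), .cbT(x))
  new("ChangeOfBasis", Rnum = R$num, Rden = R$den,
      Tnum = as.numeric(T_$num), Tden = T_$den)
})

#' Exact inverse of a change-of-basis operator
#' @param a a [ChangeOfBasis-class].
#' @param b ignored.
#' @export
setMethod("solve", "ChangeOfBasis", function(a, b, ...) {
  Rinv <- .ratInv(.cbR(a))
  Tn <- .ratMul(Rinv, .ratNeg(.cbT(a)))
  new("ChangeOfBasis", Rnum = Rinv$num, Rden = Rinv$den,
      Tnum = as.numeric(Tn$num), Tden = Tn$den)
})

setMethod("show", "ChangeOfBasis", function(object) {
  cat("ChangeOfBasis:", .formatXyz(.cbR(object), .cbT(object)), "\n")
})

#' @describeIn changeBasis conjugate a symmetry operation: g' = cb g cb^-1
#' @export
setMethod("changeBasis", signature("SymOp", "ChangeOfBasis"), function(x, cb, ...) {
  R <- .cbR(cb); T_ <- .cbT(cb)
  Rinv <- .ratInv(R)
  W <- .ratMul(.ratMul(R, .opW(x)), Rinv)
  # w' = R w + T - W' T
  w1 <- .ratAdd(.ratMul(R, .opw(x)), T_)
  w2 <- .ratMul(W, .ratNeg(T_))
  w <- .ratAdd(w1, list(num = as.numeric(w2$num), den = w2$den))
  .symOpFromRat(W, list(num = as.numeric(w$num), den = w$den))
})

#' @describeIn changeBasis transform a whole group; when the new cell is
#'   larger than the old one (|det R| < 1) the centring translations induced
#'   by the old lattice are added, and when it is smaller, duplicate
#'   operators are merged, so the result is again a space group of the new
#'   cell.
#' @export
setMethod("changeBasis", signature("SpaceGroup", "ChangeOfBasis"), function(x, cb, ...) {
  ops <- lapply(x@ops, changeBasis, cb = cb)
  # induced centring translations: images of old lattice vectors that land
  # at fractional positions of the new cell
  R <- .cbR(cb)
  d <- R$den
  extra <- list()
  if (abs(round(det(R$num)) / d^3) < 1 - 1e-12 || d > 1) {
    rng <- 0:(max(2, d * 2) - 1)
    seen <- character(0)
    for (i in rng) for (j in rng) for (k in rng) {
      v <- .ratMod1(.ratMul(R, .ratNew(c(i, j, k))))
      if (all(v$num == 0)) next
      key <- paste(v$num, v$den, collapse = "/")
      if (key %in% seen) next
      seen <- c(seen, key)
      extra <- c(extra, list(.symOpFromRat(.ratNew(diag(3)),
                                           list(num = as.numeric(v$num),
                                                den = v$den))))
    }
  }
  allops <- c(ops, unlist(lapply(extra, function(t_) {
    lapply(ops, function(o) t_ %*% o)
  }), recursive = FALSE))
  keys <- vapply(allops, .opKey, character(1))
  allops <- allops[!duplicated(keys)]
  g <- new("SpaceGroup", symbol = x@symbol, ops = .sortOps(allops),
           sohncke = x@sohncke, pattersonSymbol = x@pattersonSymbol,
           crystalSystem = x@crystalSystem, centring = "",
           number = x@number)
  g
})

#' @describeIn changeBasis transform fractional coordinates (rows of a matrix)
#' @export
setMethod("changeBasis", signature("matrix", "ChangeOfBasis"), function(x, cb, ...) {
  R <- rotationPart(cb); T_ <- translationPart(cb)
  t(R %*% t(x) + T_)
})

#' Random unimodular change of basis
#'
#' Product of a random proper signed axis permutation and random integer
#' shears; determinant +1, entries bounded.  Used for metamorphic testing
#' and by the synthetic-crystal generator.
#'
#' @param seed integer seed.
#' @param nshear number of elementary shears (default 2).
#' @return a [ChangeOfBasis-class].
#' @export
randomUnimodularBasis <- function(seed, nshear = 2) {
  rs <- .seededRNG(seed)
  M <- .permMatrix(.axisPerms[[1 + rs$int(6)]])
  if (det(M) < 0) M[, 3] <- -M[, 3]
  for (s in seq_len(nshear)) {
    i <- 1 + rs$int(3)
    j <- 1 + ((i - 1 + 1 + rs$int(2)) %% 3)  # j != i
    E <- diag(3)
    E[i, j] <- rs$int(3) - 1  # shear in {-1,0,1}
    M <- M %*% E
  }
  changeOfBasis(R = M, T = c(0, 0, 0))
}

# minimal deterministic RNG helper: isolates sampling from the global stream
.seededRNG <- function(seed) {
  env <- new.env()
  env$state <- as.integer(seed)
  list(
    int = function(n) {
      # linear congruential step, returns value in 0..n-1
      env$state <- as.integer((1103515245 * (env$state %% 65536) + 12345) %% 2147483647)
      env$state %% n
    }
  )
}
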