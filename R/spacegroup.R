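#' @include AllClasses.R AllGenerics.R symop.R
NULL

# cache for the Sohncke catalogue and parsed groups
.xtalsymCache <- new.env(parent = emptyenv())

# The 65 Sohncke space groups: number, short Hermann-Mauguin symbol, full
# ITA symbol, crystal system, point group, Patterson symmetry, generator
# xyz triplets (identity omitted) and centring translation triplets.
# Generators follow the standard ITA reference settings (b-unique monoclinic,
# hexagonal-axes rhombohedral).
.sohnckeData <- list(
  list(1,  "P1",  "P 1", "triclinic", "1", "P-1", character(0), character(0)),
  list(3,  "P2",  "P 1 2 1", "monoclinic", "2", "P12/m1", "-x,y,-z", character(0)),
  list(4,  "P21", "P 1 21 1", "monoclinic", "2", "P12/m1", "-x,y+1/2,-z", character(0)),
  list(5,  "C2",  "C 1 2 1", "monoclinic", "2", "C12/m1", "-x,y,-z", "x+1/2,y+1/2,z"),
  list(16, "P222",    "P 2 2 2", "orthorhombic", "222", "Pmmm", c("-x,-y,z", "x,-y,-z"), character(0)),
  list(17, "P2221",   "P 2 2 21", "orthorhombic", "222", "Pmmm", c("-x,-y,z+1/2", "x,-y,-z"), character(0)),
  list(18, "P21212",  "P 21 21 2", "orthorhombic", "222", "Pmmm", c("-x,-y,z", "x+1/2,-y+1/2,-z"), character(0)),
  list(19, "P212121", "P 21 21 21", "orthorhombic", "222", "Pmmm", c("-x+1/2,-y,z+1/2", "x+1/2,-y+1/2,-z"), character(0)),
  list(20, "C2221",   "C 2 2 21", "orthorhombic", "222", "Cmmm", c("-x,-y,z+1/2", "x,-y,-z"), "x+1/2,y+1/2,z"),
  list(21, "C222",    "C 2 2 2", "orthorhombic", "222", "Cmmm", c("-x,-y,z", "x,-y,-z"), "x+1/2,y+1/2,z"),
  list(22, "F222",    "F 2 2 2", "orthorhombic", "222", "Fmmm", c("-x,-y,z", "x,-y,-z"),
       c("x,y+1/2,z+1/2", "x+1/2,y,z+1/2", "x+1/2,y+1/2,z")),
  list(23, "I222",    "I 2 2 2", "orthorhombic", "222", "Immm", c("-x,-y,z", "x,-y,-z"), "x+1/2,y+1/2,z+1/2"),
  list(24, "I212121", "I 21 21 21", "orthorhombic", "222", "Immm", c("-x,-y+1/2,z", "x,-y,-z+1/2"), "x+1/2,y+1/2,z+1/2"),
  list(75, "P4",  "P 4", "tetragonal", "4", "P4/m", "-y,x,z", character(0)),
  list(76, "P41", "P 41", "tetragonal", "4", "P4/m", "-y,x,z+1/4", character(0)),
  list(77, "P42", "P 42", "tetragonal", "4", "P4/m", "-y,x,z+1/2", character(0)),
  list(78, "P43", "P 43", "tetragonal", "4", "P4/m", "-y,x,z+3/4", character(0)),
  list(79, "I4",  "I 4", "tetragonal", "4", "I4/m", "-y,x,z", "x+1/2,y+1/2,z+1/2"),
  list(80, "I41", "I 41", "tetragonal", "4", "I4/m", "-y,x+1/2,z+1/4", "x+1/2,y+1/2,z+1/2"),
  list(89, "P422",   "P 4 2 2", "tetragonal", "422", "P4/mmm", c("-y,x,z", "x,-y,-z"), character(0)),
  list(90, "P4212",  "P 4 21 2", "tetragonal", "422", "P4/mmm", c("-y+1/2,x+1/2,z", "x+1/2,-y+1/2,-z"), character(0)),
  list(91, "P4122",  "P 41 2 2", "tetragonal", "422", "P4/mmm", c("-y,x,z+1/4", "x,-y,-z+1/2"), character(0)),
  list(92, "P41212", "P 41 21 2", "tetragonal", "422", "P4/mmm", c("-y+1/2,x+1/2,z+1/4", "x+1/2,-y+1/2,-z+3/4"), character(0)),
  list(93, "P4222",  "P 42 2 2", "tetragonal", "422", "P4/mmm", c("-y,x,z+1/2", "x,-y,-z"), character(0)),
  list(94, "P42212", "P 42 21 2", "tetragonal", "422", "P4/mmm", c("-y+1/2,x+1/2,z+1/2", "x+1/2,-y+1/2,-z+1/2"), character(0)),
  list(95, "P4322",  "P 43 2 2", "tetragonal", "422", "P4/mmm", c("-y,x,z+3/4", "x,-y,-z+1/2"), character(0)),
  list(96, "P43212", "P 43 21 2", "tetragonal", "422", "P4/mmm", c("-y+1/2,x+1/2,z+3/4", "x+1/2,-y+1/2,-z+1/4"), character(0)),
  list(97, "I422",  "I 4 2 2", "tetragonal", "422", "I4/mmm", c("-y,x,z", "x,-y,-z"), "x+1/2,y+1/2,z+1/2"),
  list(98, "I4122", "I 41 2 2", "tetragonal", "422", "I4/mmm", c("-y,x+1/2,z+1/4", "x,-y+1/2,-z+1/4"), "x+1/2,y+1/2,z+1/2"),
  list(143, "P3",  "P 3", "trigonal", "3", "P-3", "-y,x-y,z", character(0)),
  list(144, "P31", "P 31", "trigonal", "3", "P-3", "-y,x-y,z+1/3", character(0)),
  list(145, "P32", "P 32", "trigonal", "3", "P-3", "-y,x-y,z+2/3", character(0)),
  list(146, "R3",  "R 3", "trigonal", "3", "R-3", "-y,x-y,z", c("x+2/3,y+1/3,z+1/3", "x+1/3,y+2/3,z+2/3")),
  list(149, "P312",  "P 3 1 2", "trigonal", "312", "P-31m", c("-y,x-y,z", "-y,-x,-z"), character(0)),
  list(150, "P321",  "P 3 2 1", "trigonal", "321", "P-3m1", c("-y,x-y,z", "y,x,-z"), character(0)),
  list(151, "P3112", "P 31 1 2", "trigonal", "312", "P-31m", c("-y,x-y,z+1/3", "-y,-x,-z+2/3"), character(0)),
  list(152, "P3121", "P 31 2 1", "trigonal", "321", "P-3m1", c("-y,x-y,z+1/3", "y,x,-z"), character(0)),
  list(153, "P3212", "P 32 1 2", "trigonal", "312", "P-31m", c("-y,x-y,z+2/3", "-y,-x,-z+1/3"), character(0)),
  list(154, "P3221", "P 32 2 1", "trigonal", "321", "P-3m1", c("-y,x-y,z+2/3", "y,x,-z"), character(0)),
  list(155, "R32",   "R 3 2", "trigonal", "32", "R-3m", c("-y,x-y,z", "y,x,-z"), c("x+2/3,y+1/3,z+1/3", "x+1/3,y+2/3,z+2/3")),
  list(168, "P6",  "P 6", "hexagonal", "6", "P6/m", "x-y,x,z", character(0)),
  list(169, "P61", "P 61", "hexagonal", "6", "P6/m", "x-y,x,z+1/6", character(0)),
  list(170, "P65", "P 65", "hexagonal", "6", "P6/m", "x-y,x,z+5/6", character(0)),
  list(171, "P62", "P 62", "hexagonal", "6", "P6/m", "x-y,x,z+1/3", character(0)),
  list(172, "P64", "P 64", "hexagonal", "6", "P6/m", "x-y,x,z+2/3", character(0)),
  list(173, "P63", "P 63", "hexagonal", "6", "P6/m", "x-y,x,z+1/2", character(0)),
  list(177, "P622",  "P 6 2 2", "hexagonal", "622", "P6/mmm", c("x-y,x,z", "-y,-x,-z"), character(0)),
  list(178, "P6122", "P 61 2 2", "hexagonal", "622", "P6/mmm", c("x-y,x,z+1/6", "-y,-x,-z+5/6"), character(0)),
  list(179, "P6522", "P 65 2 2", "hexagonal", "622", "P6/mmm", c("x-y,x,z+5/6", "-y,-x,-z+1/6"), character(0)),
  list(180, "P6222", "P 62 2 2", "hexagonal", "622", "P6/mmm", c("x-y,x,z+1/3", "-y,-x,-z+2/3"), character(0)),
  list(181, "P6422", "P 64 2 2", "hexagonal", "622", "P6/mmm", c("x-y,x,z+2/3", "-y,-x,-z+1/3"), character(0)),
  list(182, "P6322", "P 63 2 2", "hexagonal", "622", "P6/mmm", c("x-y,x,z+1/2", "-y,-x,-z+1/2"), character(0)),
  list(195, "P23", "P 2 3", "cubic", "23", "Pm-3", c("-x,-y,z", "z,x,y"), character(0)),
  list(196, "F23", "F 2 3", "cubic", "23", "Fm-3", c("-x,-y,z", "z,x,y"),
       c("x,y+1/2,z+1/2", "x+1/2,y,z+1/2", "x+1/2,y+1/2,z")),
  list(197, "I23", "I 2 3", "cubic", "23", "Im-3", c("-x,-y,z", "z,x,y"), "x+1/2,y+1/2,z+1/2"),
  list(198, "P213", "P 21 3", "cubic", "23", "Pm-3", c("-x+1/2,-y,z+1/2", "z,x,y"), character(0)),
  list(199, "I213", "I 21 3", "cubic", "23", "Im-3", c("-x,-y+1/2,z", "z,x,y"), "x+1/2,y+1/2,z+1/2"),
  list(207, "P432",  "P 4 3 2", "cubic", "432", "Pm-3m", c("-y,x,z", "z,x,y"), character(0)),
  list(208, "P4232", "P 42 3 2", "cubic", "432", "Pm-3m", c("-y+1/2,x+1/2,z+1/2", "z,x,y"), character(0)),
  list(209, "F432",  "F 4 3 2", "cubic", "432", "Fm-3m", c("-y,x,z", "z,x,y"),
       c("x,y+1/2,z+1/2", "x+1/2,y,z+1/2", "x+1/2,y+1/2,z")),
  list(210, "F4132", "F 41 3 2", "cubic", "432", "Fm-3m", c("-y+1/4,x+1/4,z+1/4", "z,x,y"),
       c("x,y+1/2,z+1/2", "x+1/2,y,z+1/2", "x+1/2,y+1/2,z")),
  list(211, "I432",  "I 4 3 2", "cubic", "432", "Im-3m", c("-y,x,z", "z,x,y"), "x+1/2,y+1/2,z+1/2"),
  list(212, "P4332", "P 43 3 2", "cubic", "432", "Pm-3m", c("-y+3/4,x+1/4,z+3/4", "z,x,y"), character(0)),
  list(213, "P4132", "P 41 3 2", "cubic", "432", "Pm-3m", c("-y+1/4,x+3/4,z+1/4", "z,x,y"), character(0)),
  list(214, "I4132", "I 41 3 2", "cubic", "432", "Im-3m", c("-y+1/4,x+3/4,z+1/4", "z,x,y"), "x+1/2,y+1/2,z+1/2")
)

#' Close a set of generators into a space group
#'
#' Repeated exact composition until no new operation appears.  Centring
#' translations are supplied as separate pure-translation generators.  The
#' closure is refused beyond 192 elements (a runaway input: no
#' crystallographic space group needs more operators per cell).
#'
#' @param generators list of [SymOp-class] (or xyz triplet strings).
#' @param centrings optional list of centring translation vectors (each a
#'   length-3 rational vector) or xyz strings.
#' @param symbol,number optional metadata for the resulting group.
#' @return a [SpaceGroup-class] whose operator list is closed under
#'   composition and inversion, identity first.
#' @examples
#' groupClosure(list(symOp("-y,x,z")))   # the four operators of P4
#' @export
groupClosure <- function(generators, centrings = list(), symbol = "",
                         number = NA_real_) {
  gens <- lapply(generators, function(g) if (is.character(g)) symOp(g) else g)
  cen <- lapply(centrings, function(v) {
    if (is.character(v)) symOp(v) else symOp(W = diag(3), w = v)
  })
  ops <- list(identityOp())
  keys <- .opKey(ops[[1]])
  queue <- ops
  gens <- c(gens, cen)
  while (length(queue)) {
    a <- queue[[1]]; queue <- queue[-1]
    for (g in gens) {
      p <- a %*% g
      k <- .opKey(p)
      if (!(k %in% keys)) {
        ops <- c(ops, list(p)); keys <- c(keys, k); queue <- c(queue, list(p))
        if (length(ops) > 192) stop("group closure exceeds 192 elements")
      }
    }
  }
  sohncke <- all(vapply(ops, function(o) round(det(o@Wnum)) / o@Wden^3 > 0, logical(1)))
  new("SpaceGroup", symbol = symbol, ops = .sortOps(ops), sohncke = sohncke,
      number = number)
}

# deterministic operator order: identity first, then lexicographic on
# (flattened W, then w)
.opLexKey <- function(op) c(t(op@Wnum / op@Wden), op@wnum / op@wden)

.sortOps <- function(ops) {
  keym <- t(vapply(ops, .opLexKey, numeric(12)))
  ord <- do.call(order, as.data.frame(keym))
  ops <- ops[ord]
  idn <- which(vapply(ops, .isIdentityOp, logical(1)))
  if (length(idn)) c(ops[idn], ops[-idn]) else ops
}

.buildCatalogue <- function() {
  if (!is.null(.xtalsymCache$catalogue)) return(.xtalsymCache$catalogue)
  cat_ <- lapply(.sohnckeData, function(e) {
    g <- groupClosure(as.list(e[[7]]), as.list(e[[8]]), symbol = e[[2]],
                      number = e[[1]])
    g@crystalSystem <- e[[4]]
    g@pattersonSymbol <- e[[6]]
    g@centring <- substr(e[[2]], 1, 1)
    attr(g, "pointGroup") <- e[[5]]
    attr(g, "fullSymbol") <- e[[3]]
    g
  })
  names(cat_) <- vapply(.sohnckeData, function(e) e[[2]], character(1))
  .xtalsymCache$catalogue <- cat_
  cat_
}

#' The Sohncke space-group catalogue
#'
#' @return named list of the 65 Sohncke [SpaceGroup-class] objects in
#'   space-group-number order.
#' @export
sohnckeGroups <- function() .buildCatalogue()

.normalizeSymbol <- function(symbol) {
  s <- gsub("[ _()]", "", symbol)
  s <- sub(":H$", "", s, ignore.case = TRUE)
  toupper(s)
}

# axis-permutation variants (monoclinic/orthorhombic) for symbol lookup and
# standardizeSetting; perms act as new_i = old_perm[i]
.axisPerms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2),
                   c(1, 3, 2), c(3, 2, 1), c(2, 1, 3))

.permMatrix <- function(p) {
  M <- matrix(0, 3, 3)
  for (i in 1:3) M[i, p[i]] <- 1
  M
}

.centringLetterFromVec <- function(v) {
  key <- paste(round(v * 2), collapse = "")
  switch(key, "011" = "A", "101" = "B", "110" = "C", "111" = "I", "?")
}

# symbol parts along a,b,c for monoclinic/orthorhombic full symbols
.symbolParts <- function(full) {
  parts <- strsplit(full, " ")[[1]]
  list(letter = parts[1], parts = parts[-1])
}

.lookupSymbol <- function(symbol) {
  key <- .normalizeSymbol(symbol)
  cat_ <- .buildCatalogue()
  hit <- .xtalsymCache$symbolIndex
  if (is.null(hit)) {
    idx <- new.env(parent = emptyenv())
    for (nm in names(cat_)) {
      g <- cat_[[nm]]
      assign(.normalizeSymbol(nm), list(group = g, cb = NULL), idx)
      assign(.normalizeSymbol(attr(g, "fullSymbol")), list(group = g, cb = NULL), idx)
      # permuted settings for monoclinic and orthorhombic groups
      if (g@crystalSystem %in% c("monoclinic", "orthorhombic")) {
        sp <- .symbolParts(attr(g, "fullSymbol"))
        for (p in .axisPerms) {
          M <- .permMatrix(p)
          if (det(M) < 0) M[, 3] <- -M[, 3]  # keep handedness
          # coordinate action of the permutation: x'_i = x_{p(i)}
          cb <- changeOfBasis(R = .permMatrix(p), T = c(0, 0, 0))
          newparts <- sp$parts[order(p)]
          letter <- sp$letter
          if (letter %in% c("A", "B", "C")) {
            v <- c(A = 1, B = 2, C = 3)[letter]
            letter <- c("A", "B", "C")[which(order(p) == v)]
          }
          psym <- .normalizeSymbol(paste0(letter, paste(newparts, collapse = "")))
          if (!exists(psym, idx)) assign(psym, list(group = g, cb = cb), idx)
          # short monoclinic form (unique-axis-b only): P2 etc. already indexed
        }
      }
    }
    .xtalsymCache$symbolIndex <- idx
    hit <- idx
  }
  if (!exists(key, hit)) return(NULL)
  get(key, hit)
}

#' Look up a space group by Hermann-Mauguin symbol
#'
#' Accepts short symbols ("P21", "C2", "P43212"), full ITA symbols with
#' spaces ("P 21 21 21", "P 1 2 1"), and permuted-axis monoclinic or
#' orthorhombic settings ("P 21 2 2", "P 1 1 21"); the latter are returned in
#' the permuted setting (their operators conjugated accordingly).  Only the
#' 65 Sohncke groups are accepted: protein crystals cannot adopt the
#' remaining 165 space groups.
#'
#' @param symbol Hermann-Mauguin symbol.
#' @return a [SpaceGroup-class].
#' @examples
#' spaceGroup("P43212")
#' spaceGroup("P 1 21 1")
#' @export
spaceGroup <- function(symbol) {
  hit <- .lookupSymbol(symbol)
  if (is.null(hit))
    stop("unknown or non-Sohncke space-group symbol: '", symbol, "'")
  g <- hit$group
  if (!is.null(hit$cb)) {
    g <- changeBasis(g, solve(hit$cb))
    g@symbol <- .normalizeSymbol(symbol)
  }
  g
}

#' @rdname symbol
#' @export
setMethod("symbol", "SpaceGroup", function(x) x@symbol)

#' @rdname operators
#' @export
setMethod("operators", "SpaceGroup", function(x) x@ops)

#' Number of operators per cell
#' @param x a [SpaceGroup-class].
#' @export
groupOrder <- function(x) length(x@ops)

setMethod("show", "SpaceGroup", function(object) {
  cat("SpaceGroup", if (nzchar(object@symbol)) object@symbol else "<anonymous>",
      sprintf("(%d operators%s)\n", length(object@ops),
              if (nzchar(object@pattersonSymbol))
                paste0(", Patterson ", object@pattersonSymbol) else ""))
  for (op in object@ops[seq_len(min(8, length(object@ops)))])
    cat("  ", opXyz(op), "\n")
  if (length(object@ops) > 8) cat("  ...\n")
})

.groupKeys <- function(g) vapply(g@ops, .opKey, character(1))

#' Test whether H is a subgroup of G
#' @param G,H [SpaceGroup-class] objects in the same frame.
#' @return TRUE, or the first offending operator's xyz string.
#' @export
isSubgroup <- function(G, H) {
  gk <- .groupKeys(G)
  for (op in H@ops) if (!(.opKey(op) %in% gk)) return(opXyz(op))
  TRUE
}

#' Left coset decomposition of G with respect to H
#'
#' Breaks the target group G into |G|/|H| left cosets g_i H.  The coset
#' containing the identity is H itself and is omitted from the
#' representative list; within each remaining coset the representative is
#' the operator with lexicographically smallest (flattened rotation part,
#' then translation) so the decomposition is deterministic.  The
#' representatives are the trial operators that must hold for the structure
#' if G is its true symmetry.
#'
#' @param G target group.
#' @param H subgroup (in G's frame, or transformed into it via `cb`).
#' @param cb optional [ChangeOfBasis-class] taking H's frame to G's frame.
#' @return a [CosetDecomposition-class].
#' @examples
#' leftCosets(spaceGroup("P4"), spaceGroup("P1"))   # 4 cosets
#' @export
leftCosets <- function(G, H, cb = NULL) {
  if (!is.null(cb)) H <- changeBasis(H, cb)
  bad <- isSubgroup(G, H)
  if (!isTRUE(bad))
    stop("H is not a subgroup of G after transformation; offending operator: ", bad)
  hkeys <- .groupKeys(H)
  assigned <- character(0)
  reps <- list()
  for (g in G@ops) {
    k <- .opKey(g)
    if (k %in% assigned) next
    coset <- lapply(H@ops, function(h) g %*% h)
    ckeys <- vapply(coset, .opKey, character(1))
    assigned <- c(assigned, ckeys)
    if (.opKey(identityOp()) %in% ckeys) next  # the H coset itself
    reps <- c(reps, list(.sortOps(coset)[[1]]))
    if (.isIdentityOp(reps[[length(reps)]]))
      reps[[length(reps)]] <- .sortOps(coset)[[2]]
  }
  # deterministic representative order
  if (length(reps) > 1) {
    keym <- t(vapply(reps, .opLexKey, numeric(12)))
    reps <- reps[do.call(order, as.data.frame(keym))]
  }
  n <- length(G@ops) / length(H@ops)
  stopifnot(n == round(n), length(reps) == n - 1)
  new("CosetDecomposition", group = G, subgroup = H, representatives = reps,
      nCosets = as.integer(n))
}

setMethod("show", "CosetDecomposition", function(object) {
  cat(sprintf("CosetDecomposition: %d cosets (|G|=%d, |H|=%d)\n",
              object@nCosets, length(object@group@ops),
              length(object@subgroup@ops)))
  for (r in object@representatives)
    cat("  g_i =", opXyz(r), sprintf("[%s]\n", .opShorthand(r)))
})

#' Sohncke space groups sharing a Patterson symmetry
#'
#' Returns, in catalogue order, every Sohncke group whose diffraction
#' (Patterson) symmetry equals the given symbol; enantiomorphic pairs are
#' both present.  These are the candidate space groups that must be
#' discriminated by phases once a Patterson setting is accepted.
#'
#' @param pattersonSymbol e.g. "P4/m", "P-1", "C12/m1".
#' @return list of [SpaceGroup-class].
#' @examples
#' names(sapply(candidateSpaceGroups("P4/m"), symbol))
#' @export
candidateSpaceGroups <- function(pattersonSymbol) {
  cat_ <- .buildCatalogue()
  key <- .normalizeSymbol(pattersonSymbol)
  known <- unique(vapply(cat_, function(g) g@pattersonSymbol, character(1)))
  if (!(key %in% .normalizeSymbol(known)))
    stop("unknown Patterson symmetry symbol: '", pattersonSymbol, "'")
  out <- Filter(function(g) .normalizeSymbol(g@pattersonSymbol) == key, cat_)
  unname(out)
}

#' Convert a nonstandard (axis-permuted) setting to the catalogue setting
#'
#' Searches the proper axis permutations for one that maps the operator set
#' of the input group onto a catalogued Sohncke group (e.g. P2122 to P2221).
#'
#' @param G a [SpaceGroup-class] in a permuted-axis setting.
#' @return list with elements `group` (the catalogue [SpaceGroup-class]) and
#'   `cb` (the [ChangeOfBasis-class] taking the nonstandard frame to the
#'   conventional one).
#' @export
standardizeSetting <- function(G) {
  cat_ <- .buildCatalogue()
  catkeys <- lapply(cat_, function(g) sort(.groupKeys(g)))
  for (p in .axisPerms) {
    M <- .permMatrix(p)
    cb <- changeOfBasis(R = M, T = c(0, 0, 0))
    Gp <- changeBasis(G, cb)
    gk <- sort(.groupKeys(Gp))
    for (nm in names(cat_)) {
      if (length(gk) != length(catkeys[[nm]])) next
      if (all(gk == catkeys[[nm]])) {
        return(list(group = cat_[[nm]], cb = cb))
      }
    }
  }
  stop("no catalogued setting matches this group under axis permutation")
}
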