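#' @include AllClasses.R AllGenerics.R cell.R spacegroup.R
NULL

#' Construct a coordinate model
#'
#' @param cell a [UnitCell-class].
#' @param group a [SpaceGroup-class] (the *assigned* symmetry of the model).
#' @param chains list of chains; each chain is a list with `id`, `seq`
#'   (character vector of one-letter or three-letter residue codes) and
#'   `xyz` (n x 3 fractional coordinates).  File order is preserved.
#' @param provenance optional character notes.
#' @return a [CrystalModel-class].
#' @export
crystalModel <- function(cell, group, chains, provenance = character(0)) {
  new("CrystalModel", cell = cell, group = group, chains = chains,
      provenance = provenance)
}

#' @rdname nChains
#' @export
setMethod("nChains", "CrystalModel", function(x) length(x@chains))

#' Chain identifiers of a model
#' @param x a [CrystalModel-class].
#' @export
chainIds <- function(x) vapply(x@chains, function(ch) ch$id, character(1))

#' @rdname cellParameters
#' @export
setMethod("cellParameters", "CrystalModel", function(x) cellParameters(x@cell))

setMethod("show", "CrystalModel", function(object) {
  p <- cellParameters(object)
  cat(sprintf("CrystalModel: %d chains, %d C-alpha sites, group %s\n",
              nChains(object),
              sum(vapply(object@chains, function(ch) nrow(ch$xyz), numeric(1))),
              if (nzchar(object@group@symbol)) object@group@symbol else "<anonymous>"))
  show(object@cell)
})

#' @describeIn changeBasis transform a model (cell, coordinates and group)
#' @export
setMethod("changeBasis", signature("CrystalModel", "ChangeOfBasis"), function(x, cb, ...) {
  x@cell <- changeBasis(x@cell, cb)
  x@chains <- lapply(x@chains, function(ch) {
    ch$xyz <- changeBasis(ch$xyz, cb)
    ch
  })
  x@group <- changeBasis(x@group, cb)
  x
})

#' Apply a fractional origin shift to all chains
#' @param model a [CrystalModel-class].
#' @param x fractional triple.
#' @export
shiftModel <- function(model, x) {
  model@chains <- lapply(model@chains, function(ch) {
    ch$xyz <- sweep(ch$xyz, 2, x, "+")
    ch
  })
  model
}

#' Apply a symmetry operation to a coordinate matrix
#' @param xyz n x 3 fractional coordinates.
#' @param op a [SymOp-class].
#' @export
applyOp <- function(xyz, op) {
  t(rotationPart(op) %*% t(xyz) + translationPart(op))
}

#' Expand a model to P1
#'
#' Applies every operator of the model's space group to every chain,
#' producing the full cell contents with the assigned symmetry made
#' explicit.  Chain ids gain an operator suffix; the resulting group is P1
#' with the same cell.
#'
#' @param model a [CrystalModel-class].
#' @return a [CrystalModel-class] whose group is P1.
#' @export
expandToP1 <- function(model) {
  ops <- operators(model@group)
  chains <- list()
  for (i in seq_along(ops)) {
    for (ch in model@chains) {
      nc <- ch
      nc$xyz <- applyOp(ch$xyz, ops[[i]])
      nc$id <- if (i == 1) ch$id else paste0(ch$id, ".", i)
      chains <- c(chains, list(nc))
    }
  }
  p1 <- spaceGroup("P1")
  crystalModel(model@cell, p1, chains, model@provenance)
}

#' Collect the C-alpha sites of a model as point scatterers
#'
#' @param model a [CrystalModel-class].
#' @param B isotropic B factor applied to all sites (default 20).
#' @return a [Scatterers-class].
#' @export
asScatterers <- function(model, B = 20) {
  xyz <- do.call(rbind, lapply(model@chains, function(ch) ch$xyz))
  n <- nrow(xyz)
  new("Scatterers", xyz = xyz, occ = rep(1, n), B = rep(B, n),
      weight = rep(1, n), cell = model@cell)
}

#' All C-alpha sites of a model as one fractional matrix
#' @param model a [CrystalModel-class].
#' @export
modelSites <- function(model) {
  do.call(rbind, lapply(model@chains, function(ch) ch$xyz))
}
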