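#' @include cell.R
NULL

#' Reduce a unit cell to the Niggli setting
#'
#' Krivy-Gruber iteration on the metric tensor, tracking the integer change
#' of basis.  The reduced cell satisfies a <= b <= c with a standardized
#' angle type (all angles acute or all non-acute), volume is preserved, and
#' all downstream scores are invariant to which stable reduced setting is
#' chosen.
#'
#' @param cell a [UnitCell-class].
#' @param eps relative tolerance of the metric comparisons (default 1e-5).
#' @return list with elements `cell` (reduced [UnitCell-class]) and `cb`
#'   (the [ChangeOfBasis-class] taking input fractional coordinates to
#'   reduced ones).
#' @export
reduceCell <- function(cell, eps = 1e-5) {
  if (cellVolume(cell) < 1e-6) stop("degenerate cell: volume is ~0")
  G <- metricTensor(cell)
  scale <- mean(diag(G))
  e <- eps * scale
  M <- diag(3)  # accumulated basis transform: new basis columns in old frame
  upd <- function(T_) { M <<- M %*% T_; G <<- t(T_) %*% G %*% T_ }
  for (iter in 1:200) {
    A <- G[1, 1]; B <- G[2, 2]; C <- G[3, 3]
    xi <- 2 * G[2, 3]; eta <- 2 * G[1, 3]; zeta <- 2 * G[1, 2]
    if (A > B + e || (abs(A - B) <= e && abs(xi) > abs(eta) + e)) {
      upd(matrix(c(0, -1, 0, -1, 0, 0, 0, 0, -1), 3, 3)); next
    }
    if (B > C + e || (abs(B - C) <= e && abs(eta) > abs(zeta) + e)) {
      upd(matrix(c(-1, 0, 0, 0, 0, -1, 0, -1, 0), 3, 3)); next
    }
    if (xi * eta * zeta > e^3) {
      s <- function(v) if (v < 0) -1 else 1
      upd(diag(c(s(xi), s(eta), s(zeta))))
    } else {
      f <- c(1, 1, 1); z <- -1
      if (xi > e) f[1] <- -1 else if (!(xi < -e)) z <- 1
      if (eta > e) f[2] <- -1 else if (!(eta < -e)) z <- 2
      if (zeta > e) f[3] <- -1 else if (!(zeta < -e)) z <- 3
      if (prod(f) < 0) {
        if (z < 0) stop("Niggli reduction: inconsistent signs")
        f[z] <- -f[z]
      }
      upd(diag(f))
    }
    A <- G[1, 1]; B <- G[2, 2]; C <- G[3, 3]
    xi <- 2 * G[2, 3]; eta <- 2 * G[1, 3]; zeta <- 2 * G[1, 2]
    if (abs(xi) > B + e || (abs(xi - B) <= e && 2 * eta < zeta - e) ||
        (abs(xi + B) <= e && zeta < -e)) {
      sg <- if (xi > 0) 1 else -1
      upd(matrix(c(1, 0, 0, 0, 1, 0, 0, -sg, 1), 3, 3)); next
    }
    if (abs(eta) > A + e || (abs(eta - A) <= e && 2 * xi < zeta - e) ||
        (abs(eta + A) <= e && zeta < -e)) {
      sg <- if (eta > 0) 1 else -1
      upd(matrix(c(1, 0, 0, 0, 1, 0, -sg, 0, 1), 3, 3)); next
    }
    if (abs(zeta) > A + e || (abs(zeta - A) <= e && 2 * xi < eta - e) ||
        (abs(zeta + A) <= e && eta < -e)) {
      sg <- if (zeta > 0) 1 else -1
      upd(matrix(c(1, 0, 0, -sg, 1, 0, 0, 0, 1), 3, 3)); next
    }
    if (xi + eta + zeta + A + B < -e ||
        (abs(xi + eta + zeta + A + B) <= e && 2 * (A + eta) + zeta > e)) {
      upd(matrix(c(1, 0, 0, 0, 1, 0, 1, 1, 1), 3, 3)); next
    }
    break
  }
  # coordinate action is the inverse of the basis-column transform
  cb <- changeOfBasis(R = solve(M), T = c(0, 0, 0))
  list(cell = .cellFromMetric(G), cb = cb)
}

# primitive-basis columns (in the centred frame) per centring letter
.centringBasis <- list(
  P = diag(3),
  A = matrix(c(1, 0, 0, 0, 1 / 2, 1 / 2, 0, -1 / 2, 1 / 2), 3, 3),
  B = matrix(c(1 / 2, 0, 1 / 2, 0, 1, 0, -1 / 2, 0, 1 / 2), 3, 3),
  C = matrix(c(1 / 2, 1 / 2, 0, -1 / 2, 1 / 2, 0, 0, 0, 1), 3, 3),
  I = matrix(c(-1 / 2, 1 / 2, 1 / 2, 1 / 2, -1 / 2, 1 / 2, 1 / 2, 1 / 2, -1 / 2), 3, 3),
  F = matrix(c(0, 1 / 2, 1 / 2, 1 / 2, 0, 1 / 2, 1 / 2, 1 / 2, 0), 3, 3),
  R = matrix(c(2 / 3, 1 / 3, 1 / 3, -1 / 3, 1 / 3, 1 / 3, -1 / 3, -2 / 3, 1 / 3), 3, 3)
)

# detect the centring letter of a group from its pure-translation operators
.detectCentring <- function(group) {
  cvs <- list()
  for (op in group@ops) {
    if (all(op@Wnum == diag(3) * op@Wden) && any(op@wnum != 0))
      cvs <- c(cvs, list(op@wnum / op@wden))
  }
  if (!length(cvs)) return("P")
  keys <- sort(vapply(cvs, function(v) paste(round(v * 6), collapse = ","), character(1)))
  kk <- paste(keys, collapse = ";")
  if (kk == "0,3,3") return("A")
  if (kk == "3,0,3") return("B")
  if (kk == "3,3,0") return("C")
  if (kk == "3,3,3") return("I")
  if (kk == "0,3,3;3,0,3;3,3,0") return("F")
  if (kk == "2,4,4;4,2,2" || kk == "4,2,2;2,4,4") return("R")
  stop("unrecognized centring translations: ", kk)
}

#' Remove lattice centring from a model or cell/group pair
#'
#' Changes basis to a primitive cell: the cell volume divides by the
#' centring multiplicity, the group loses its centring translations, and a
#' model's chains are carried along unchanged (the asymmetric-unit content
#' is not affected by the choice of cell).
#'
#' @param x a [CrystalModel-class] or [UnitCell-class].
#' @param group a [SpaceGroup-class]; taken from the model when `x` is one.
#' @return list with `model` (or `cell`), `group` and `cb`.
#' @export
removeCentring <- function(x, group = NULL) {
  if (is(x, "CrystalModel")) group <- x@group
  letter <- .detectCentring(group)
  Mb <- .centringBasis[[letter]]
  cb <- changeOfBasis(R = solve(Mb), T = c(0, 0, 0))
  gp <- changeBasis(group, cb)
  gp@centring <- "P"
  if (is(x, "CrystalModel")) {
    m <- changeBasis(x, cb)
    m@group <- gp
    list(model = m, group = gp, cb = cb)
  } else {
    list(cell = changeBasis(x, cb), group = gp, cb = cb)
  }
}
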