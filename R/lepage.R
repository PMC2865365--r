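#' @include cell.R symop.R
NULL

# coprime integer triples with components in [-bound, bound], one
# representative per +/- pair (first nonzero component positive)
.coprimeTriples <- function(bound = 2) {
  out <- list()
  for (u in -bound:bound) for (v in -bound:bound) for (w in -bound:bound) {
    if (u == 0 && v == 0 && w == 0) next
    first <- c(u, v, w)[which(c(u, v, w) != 0)[1]]
    if (first < 0) next
    if (.gcdAll(c(u, v, w)) != 1) next
    out <- c(out, list(c(u, v, w)))
  }
  out
}

#' Search the lattice metric for twofold axes (Le Page method)
#'
#' A candidate twofold is a pair of a direct-lattice axis t = u a + v b + w c
#' and a reciprocal-lattice axis tau = h a* + k b* + l c* with u h + v k +
#' w l = 2, for which the corresponding rotation W = t tau' - I is an exact
#' integer matrix on the lattice.  The Le Page delta is the angle between t
#' and tau in cartesian space; it is zero for an exact metric symmetry axis
#' and the default acceptance tolerance of 1.4 degrees reflects the
#' deviations routinely seen in rotation-photography experiments.
#'
#' @param cell a reduced [UnitCell-class].
#' @param deltaTol tolerance in degrees (0 to 5, default 1.4).
#' @param bound search bound on the integer components (default 2).
#' @return data-frame-like list of twofolds sorted by delta ascending; each
#'   element has `uvw`, `hkl`, `delta` (degrees) and `op` (a [SymOp-class]).
#' @export
findLatticeTwofolds <- function(cell, deltaTol = 1.4, bound = 2) {
  stopifnot(deltaTol >= 0, deltaTol <= 5)
  O <- orthMatrix(cell)
  Ostar <- t(solve(O))   # columns are a*, b*, c* in cartesian
  trips <- .coprimeTriples(bound)
  out <- list()
  seen <- character(0)
  for (t_ in trips) {
    tc <- as.numeric(O %*% t_)
    for (m in trips) {
      for (sgn in c(1, -1)) {
        mm <- m * sgn
        dot <- sum(t_ * mm)
        if (!(dot %in% c(1, 2))) next
        W <- (2 / dot) * outer(t_, mm) - diag(3)
        if (!.ratIsIntegral(W)) next
        key <- paste(W, collapse = ",")
        if (key %in% seen) next
        mc <- as.numeric(Ostar %*% mm)
        cosd <- sum(tc * mc) / sqrt(sum(tc^2) * sum(mc^2))
        delta <- acos(min(1, max(-1, cosd))) * 180 / pi
        if (delta <= deltaTol) {
          seen <- c(seen, key)
          out <- c(out, list(list(uvw = t_, hkl = mm, delta = delta,
                                  op = symOp(W = W))))
        }
      }
    }
  }
  out[order(vapply(out, function(x) x$delta, numeric(1)))]
}

# primitive integer axis of a rotation: right kernel of (W - I) for the
# direct axis, left kernel for the reciprocal axis
.intAxis <- function(M, bound = 4) {
  best <- NULL
  for (u in -bound:bound) for (v in -bound:bound) for (w in -bound:bound) {
    vv <- c(u, v, w)
    if (all(vv == 0)) next
    first <- vv[which(vv != 0)[1]]
    if (first < 0) next
    if (.gcdAll(vv) != 1) next
    if (all(abs(M %*% vv) < 1e-9)) {
      if (is.null(best) || sum(vv^2) < sum(best^2)) best <- vv
    }
  }
  best
}

#' Le Page delta of an arbitrary lattice rotation
#'
#' Angle between the direct-space and reciprocal-space invariant axes of an
#' integer rotation matrix, in the given cell.  Zero for the identity.
#'
#' @param op a [SymOp-class] with integer rotation part.
#' @param cell a [UnitCell-class].
#' @return delta in degrees.
#' @export
opDelta <- function(op, cell) {
  W <- rotationPart(op)
  if (all(W == diag(3))) return(0)
  u <- .intAxis(W - diag(3))
  m <- .intAxis(t(W) - diag(3))
  if (is.null(u) || is.null(m)) return(NA_real_)
  O <- orthMatrix(cell)
  tc <- as.numeric(O %*% u)
  mc <- as.numeric(t(solve(O)) %*% m)
  ips <- abs(sum(tc * mc)) / sqrt(sum(tc^2) * sum(mc^2))
  acos(min(1, ips)) * 180 / pi
}
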