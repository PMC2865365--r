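#' @include lepage.R spacegroup.R changebasis.R
NULL

# close a set of integer rotations under composition (no translations)
.closeRotations <- function(ops, cap = 24) {
  allops <- list(identityOp())
  keys <- .opKey(allops[[1]])
  queue <- allops
  gens <- ops
  while (length(queue)) {
    a <- queue[[1]]; queue <- queue[-1]
    for (g in gens) {
      p <- a %*% g
      k <- .opKey(p)
      if (!(k %in% keys)) {
        allops <- c(allops, list(p)); keys <- c(keys, k); queue <- c(queue, list(p))
        if (length(allops) > cap) return(NULL)
      }
    }
  }
  .sortOps(allops)
}

# all distinct subgroups of a small rotation group: closures of all
# one- and two-element generator subsets (sufficient for point groups of
# order <= 24, which are all 2-generated)
.rotationSubgroups <- function(L) {
  n <- length(L)
  subs <- list(list(identityOp()))
  keys <- list(.opKey(identityOp()))
  add <- function(ops) {
    kk <- paste(sort(vapply(ops, .opKey, character(1))), collapse = ";")
    if (!(kk %in% unlist(keys))) {
      subs[[length(subs) + 1]] <<- ops
      keys[[length(keys) + 1]] <<- kk
    }
  }
  keys <- list(paste(.opKey(identityOp())))
  for (i in seq_len(n)) {
    ci <- .closeRotations(L[i])
    if (!is.null(ci)) add(ci)
    for (j in seq_len(n)) {
      if (j <= i) next
      cij <- .closeRotations(L[c(i, j)])
      if (!is.null(cij)) add(cij)
    }
  }
  subs
}

# classify a proper rotation point group by its element orders
.classifyRotGroup <- function(ops) {
  ords <- vapply(ops, function(o) opOrder(o)$order, numeric(1))
  n <- length(ops)
  tab <- tabulate(ords, nbins = 6)
  if (n == 1) return("1")
  if (n == 2) return("2")
  if (n == 3) return("3")
  if (n == 4 && tab[4] == 2) return("4")
  if (n == 4 && tab[2] == 3) return("222")
  if (n == 6 && tab[6] == 2) return("6")
  if (n == 6 && tab[3] == 2 && tab[2] == 3) return("32")
  if (n == 8 && tab[4] == 2) return("422")
  if (n == 12 && tab[6] == 2) return("622")
  if (n == 12 && tab[3] == 8) return("23")
  if (n == 24 && tab[4] == 6) return("432")
  stop("unrecognized rotation point group of order ", n)
}

# lattice vectors (|component| <= bound) in the plane Sum_k W^k v = 0
.planeVectors <- function(W, k, bound = 3) {
  S <- diag(3)
  P <- diag(3)
  for (i in seq_len(k - 1)) { P <- P %*% W; S <- S + P }
  out <- list()
  for (u in -bound:bound) for (v in -bound:bound) for (w in -bound:bound) {
    vv <- c(u, v, w)
    if (all(vv == 0)) next
    if (all(abs(S %*% vv) < 1e-9)) out <- c(out, list(vv))
  }
  out
}

# choose a primitive basis (p1, p2) of a rank-2 sublattice from candidate
# vectors: shortest p1, then p2 minimizing |det(p1, axis, p2)|, then length
.planeBasis <- function(cands, axis, Gmetric) {
  len <- vapply(cands, function(v) sqrt(sum(v * (Gmetric %*% v))), numeric(1))
  ord <- order(len)
  p1 <- cands[[ord[1]]]
  best <- NULL; bestkey <- c(Inf, Inf)
  for (i in ord[-1]) {
    p2 <- cands[[i]]
    d <- abs(det(cbind(p1, axis, p2)))
    if (d < 1e-9) next
    key <- c(d, len[i])
    if (key[1] < bestkey[1] - 1e-9 ||
        (abs(key[1] - bestkey[1]) < 1e-9 && key[2] < bestkey[2] - 1e-9)) {
      best <- p2; bestkey <- key
    }
  }
  list(p1 = p1, p2 = best)
}

# centring letter of the conventional basis M (columns, integer) w.r.t. the
# primitive lattice; returns list(letter, index)
.centringOfBasis <- function(M) {
  idx <- round(abs(det(M)))
  if (idx == 1) return(list(letter = "P", index = 1))
  Rinv <- solve(M)
  vs <- list()
  seen <- character(0)
  for (u in 0:3) for (v in 0:3) for (w in 0:3) {
    x <- Rinv %*% c(u, v, w)
    x <- x - floor(x + 1e-9)
    x[abs(x) < 1e-9] <- 0
    if (all(x == 0)) next
    key <- paste(round(x * 12), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key); vs <- c(vs, list(as.numeric(x)))
  }
  if (idx == 4) return(list(letter = "F", index = 4))
  if (idx == 3) return(list(letter = "R", index = 3))
  v <- vs[[1]]
  two <- round(v * 2)
  letter <- switch(paste(two, collapse = ""),
                   "011" = "A", "101" = "B", "110" = "C", "111" = "I", "?")
  list(letter = letter, index = idx, vec = v)
}

# conventional-frame basis and Patterson symbol for a rotation subgroup of
# the reduced lattice; returns list(symbol, M)
.conventionalFrame <- function(ops, cell) {
  type <- .classifyRotGroup(ops)
  Gm <- metricTensor(cell)
  info <- lapply(ops, function(o) c(list(op = o), opOrder(o)))
  axes <- function(k) Filter(function(x) x$order == k, info)
  if (type == "1") return(list(symbol = "P-1", M = diag(3), type = type))
  if (type == "2") {
    tw <- axes(2)[[1]]
    W <- rotationPart(tw$op)
    pb <- .planeBasis(.planeVectors(W, 2), tw$axis, Gm)
    M <- cbind(pb$p1, tw$axis, pb$p2)
    if (det(M) < 0) M[, 3] <- -M[, 3]
    for (adj in 1:3) {
      cen <- .centringOfBasis(M)
      if (cen$letter %in% c("P", "C")) break
      if (cen$letter == "A") { M <- cbind(M[, 3], M[, 2], -M[, 1]) }
      else if (cen$letter == "I") { M[, 3] <- M[, 1] + M[, 3] }
      else if (cen$letter == "B") { M[, 1] <- (M[, 1] + M[, 3]) / 2 }
      else break
    }
    cen <- .centringOfBasis(M)
    return(list(symbol = paste0(cen$letter, "12/m1"), M = M, type = type))
  }
  if (type %in% c("222", "23", "432")) {
    ax <- if (type == "432") axes(4) else axes(2)
    uax <- lapply(ax, function(x) x$axis)
    uax <- uax[!duplicated(vapply(uax, paste, collapse = ",", character(1)))]
    M <- do.call(cbind, uax[1:3])
    if (det(M) < 0) M[, 3] <- -M[, 3]
    cen <- .centringOfBasis(M)
    letter <- cen$letter
    if (type == "222" && letter %in% c("A", "B")) {
      # cycle axes so the centred pair becomes a, b
      perm <- if (letter == "A") c(2, 3, 1) else c(3, 1, 2)
      M <- M[, perm]
      if (det(M) < 0) M[, 3] <- -M[, 3]
      cen <- .centringOfBasis(M)
      letter <- cen$letter
    }
    base <- switch(type, "222" = "mmm", "23" = "m-3", "432" = "m-3m")
    return(list(symbol = paste0(letter, base), M = M, type = type))
  }
  # principal-axis groups: 4, 422, 3, 32, 6, 622
  k <- if (type %in% c("4", "422")) 4 else if (type %in% c("3", "32")) 3 else 6
  pr <- axes(k)[[1]]
  Wk <- rotationPart(pr$op)
  Wrot <- if (k == 6) Wk %*% Wk else Wk   # use the 3-fold for hexagonal b axis
  if (type %in% c("4", "422")) Wrot <- Wk
  pv <- .planeVectors(Wk, k)
  len <- vapply(pv, function(v) sqrt(sum(v * (Gm %*% v))), numeric(1))
  a1 <- pv[[order(len)[1]]]
  b1 <- as.numeric(Wrot %*% a1)
  M <- cbind(a1, b1, pr$axis)
  if (det(M) < 0) M[, 3] <- -M[, 3]
  cen <- .centringOfBasis(M)
  if (type %in% c("4", "422") && cen$letter == "C") {
    # C-centred tetragonal is a smaller P cell
    M[, 1] <- (a1 + b1) / 2; M[, 2] <- as.numeric(Wrot %*% M[, 1])
    cen <- .centringOfBasis(M)
  }
  sym <- switch(type,
    "4" = paste0(if (cen$letter == "I") "I" else "P", "4/m"),
    "422" = paste0(if (cen$letter == "I") "I" else "P", "4/mmm"),
    "3" = if (cen$letter == "R") "R-3" else "P-3",
    "6" = "P6/m",
    "622" = "P6/mmm",
    "32" = {
      if (cen$letter == "R") "R-3m" else {
        # orientation of the in-plane twofolds relative to (a1, b1)
        tw <- axes(2)
        Minv <- solve(M)
        u2 <- as.numeric(Minv %*% tw[[1]]$axis)
        u2 <- u2 / max(abs(u2))
        u2 <- round(u2 * 2) / 2
        along <- function(v, targets) any(vapply(targets, function(t_) {
          cr <- v[1] * t_[2] - v[2] * t_[1]
          abs(cr) < 1e-6
        }, logical(1)))
        if (along(u2, list(c(1, 0), c(0, 1), c(1, 1)))) "P-3m1" else "P-31m"
      }
    })
  list(symbol = sym, M = M, type = type)
}

#' Enumerate candidate Patterson settings of a reduced cell
#'
#' Builds the lattice rotation group generated by the accepted twofold axes,
#' enumerates all of its distinct rotation subgroups (orientational variants
#' kept as separate settings), and assigns each a conventional frame and
#' Patterson symbol.  The triclinic setting is always present with delta 0.
#'
#' @param cell reduced primitive [UnitCell-class].
#' @param twofolds output of [findLatticeTwofolds()].
#' @param nChainsP1 number of chains in the primitive P1 cell.
#' @return list of [PattersonSetting-class], sorted by decreasing rotation
#'   order, then increasing worst delta.
#' @export
enumeratePattersonSettings <- function(cell, twofolds, nChainsP1) {
  gens <- lapply(twofolds, function(t_) t_$op)
  L <- .closeRotations(gens)
  while (is.null(L) && length(gens) > 1) {
    # runaway closure from marginal axes: drop the worst-delta generator
    gens <- gens[-length(gens)]
    L <- .closeRotations(gens)
  }
  if (is.null(L)) L <- list(identityOp())
  subs <- .rotationSubgroups(L)
  # delta of a higher-order axis: its own direct/reciprocal misalignment is
  # not the whole story -- a 4- or 6-fold also requires the in-plane metric
  # to fit, which is what the deltas of the perpendicular twofolds measure.
  # Each operator therefore inherits the worst delta of the accepted
  # twofolds perpendicular to its axis.
  twAxes <- lapply(twofolds, function(t_) t_$uvw)
  twDelta <- vapply(twofolds, function(t_) t_$delta, numeric(1))
  opDeltaFull <- function(op) {
    d0 <- opDelta(op, cell)
    info <- opOrder(op)
    if (info$order <= 2 || is.null(info$axis)) return(d0)
    m <- .intAxis(t(rotationPart(op)) - diag(3))   # reciprocal axis
    if (is.null(m)) return(d0)
    perp <- vapply(twAxes, function(v) sum(v * m) == 0, logical(1))
    max(d0, twDelta[perp], 0)
  }
  settings <- lapply(subs, function(ops) {
    conv <- .conventionalFrame(ops, cell)
    deltas <- vapply(ops, opDeltaFull, numeric(1))
    cb <- changeOfBasis(R = solve(conv$M), T = c(0, 0, 0))
    new("PattersonSetting",
        pattersonSymbol = conv$symbol,
        cbToConventional = cb,
        ops = ops,
        maxDelta = max(0, deltas, na.rm = TRUE),
        nChainsAsu = nChainsP1 / length(ops))
  })
  ord <- order(-vapply(settings, function(s) length(s@ops), numeric(1)),
               vapply(settings, function(s) s@maxDelta, numeric(1)),
               vapply(settings, function(s) s@pattersonSymbol, character(1)))
  settings[ord]
}

#' @rdname symbol
#' @export
setMethod("symbol", "PattersonSetting", function(x) x@pattersonSymbol)

setMethod("show", "PattersonSetting", function(object) {
  cat(sprintf("PattersonSetting %s {%s}: %g chains/ASU, max delta %.3f deg",
              object@pattersonSymbol,
              paste(vapply(object@ops, .opShorthand, character(1)), collapse = ", "),
              object@nChainsAsu, object@maxDelta))
  if (!is.na(object@maxRsymopCalc))
    cat(sprintf(", max R_symop(calc) %.3f", object@maxRsymopCalc))
  if (!is.na(object@maxRsymopObs))
    cat(sprintf(", max R_symop(obs) %.3f", object@maxRsymopObs))
  if (!is.na(object@plausible))
    cat(sprintf(", plausible: %s", if (object@plausible) "yes" else "no"))
  cat("\n")
})

#' Patterson settings as a data frame (Table-style report)
#'
#' @param settings list of [PattersonSetting-class].
#' @return data.frame with one row per setting.
#' @export
settingsTable <- function(settings) {
  data.frame(
    setting = vapply(settings, function(s) s@pattersonSymbol, character(1)),
    operators = vapply(settings, function(s)
      paste(vapply(s@ops, .opShorthand, character(1)), collapse = " "), character(1)),
    n_chains = vapply(settings, function(s) s@nChainsAsu, numeric(1)),
    delta = vapply(settings, function(s) s@maxDelta, numeric(1)),
    max_rsymop_calc = vapply(settings, function(s) s@maxRsymopCalc, numeric(1)),
    max_rsymop_obs = vapply(settings, function(s) s@maxRsymopObs, numeric(1)),
    plausible = vapply(settings, function(s) s@plausible, logical(1)),
    stringsAsFactors = FALSE
  )
}
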