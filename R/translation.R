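#' @include structurefactors.R spacegroup.R
NULL

# polar (continuous allowed-origin) directions of a group: null space of the
# stacked (W_g - I); returns 3 x k basis matrix (possibly 0 columns)
.polarBasis <- function(group) {
  Ws <- lapply(operators(group), rotationPart)
  Astack <- do.call(rbind, lapply(Ws, function(W) W - diag(3)))
  sv <- svd(Astack, nu = 0, nv = 3)
  null <- sv$v[, sv$d < 1e-9, drop = FALSE]
  null
}

# project out polar components of a fractional shift
.canonicalizeShift <- function(x, group) {
  N <- .polarBasis(group)
  if (!ncol(N)) return(x)
  as.numeric(x - N %*% solve(crossprod(N), crossprod(N, x)))
}

#' Discrete allowed-origin shifts of a group
#'
#' Translations s with (W_g - I) s integral for every operator: shifting the
#' whole model by s moves the symmetry-element arrangement onto itself, so
#' the correlation map and all scores are invariant.  Components along polar
#' (continuous) directions are excluded; the discrete shifts are enumerated
#' on a 1/12 grid, which covers every crystallographic case.
#'
#' @param group a [SpaceGroup-class].
#' @return matrix with one allowed shift per row (the zero shift included).
#' @export
allowedOriginShifts <- function(group) {
  Ws <- lapply(operators(group), rotationPart)
  N <- .polarBasis(group)
  cand <- as.matrix(expand.grid(0:11, 0:11, 0:11)) / 12
  ok <- apply(cand, 1, function(s) {
    all(vapply(Ws, function(W) .ratIsIntegral((W - diag(3)) %*% s), logical(1)))
  })
  sh <- cand[ok, , drop = FALSE]
  # remove polar components and deduplicate
  if (ncol(N)) {
    sh <- t(apply(sh, 1, function(s)
      as.numeric(s - N %*% solve(crossprod(N), crossprod(N, s)))))
    sh <- round(sh * 12) / 12
    sh <- sh %% 1
  }
  sh[!duplicated(.hklKey(round(sh * 12))), , drop = FALSE]
}

# shared machinery: given P1 scatterers and a list of groups with identical
# rotation-part multisets, evaluate the correlation map of each group on a
# common grid.  Returns list of CorrelationMap.
.correlationMaps <- function(scat, groups, dmin, gridDivisions = NULL,
                             blockSize = 2048) {
  cell <- scat@cell
  hkl <- millerIndices(cell, dmin)
  if (nrow(hkl) < 10) stop("fewer than 10 usable reflections")
  # collect per-operator index images over the union of all groups' ops
  allops <- unique(unlist(lapply(groups, function(g)
    lapply(operators(g), identity)), recursive = FALSE))
  Hgs <- lapply(allops, function(op) round(hkl %*% rotationPart(op)))
  union_ <- unique(do.call(rbind, lapply(Hgs, function(H) .friedelCanon(H)$hkl)))
  Fc <- .complexSF(scat, union_)
  ukeys <- .hklKey(union_)
  lookupF <- function(H) {
    cc <- .friedelCanon(H)
    Fv <- Fc[match(.hklKey(cc$hkl), ukeys)]
    Fv[cc$conj] <- Conj(Fv[cc$conj])
    Fv
  }
  if (is.null(gridDivisions)) {
    gridDivisions <- pmax(4L, as.integer(ceiling(cell@abc / (dmin / 2))))
  }
  gd <- gridDivisions
  gx <- (0:(gd[1] - 1)) / gd[1]; gy <- (0:(gd[2] - 1)) / gd[2]
  gz <- (0:(gd[3] - 1)) / gd[3]
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  ng <- nrow(grid)
  out <- vector("list", length(groups))
  # per group: operator images, phase constants, merged intensities
  ginfo <- lapply(groups, function(g) {
    ops <- operators(g)
    Hg <- lapply(ops, function(op) round(hkl %*% rotationPart(op)))
    cg <- lapply(ops, function(op) exp(2i * pi * as.numeric(hkl %*% translationPart(op))))
    Fg <- lapply(Hg, lookupF)
    Imerge <- Reduce(`+`, lapply(Fg, function(f) Mod(f)^2)) / length(ops)
    list(ops = ops, Hg = Hg, cg = cg, Fg = Fg, Imerge = Imerge)
  })
  vals <- lapply(groups, function(g) numeric(ng))
  for (start in seq(1, ng, by = blockSize)) {
    idx <- start:min(start + blockSize - 1, ng)
    Xb <- t(grid[idx, , drop = FALSE])      # 3 x nb
    for (gi in seq_along(groups)) {
      info <- ginfo[[gi]]
      Fe <- matrix(0 + 0i, nrow(hkl), length(idx))
      for (oi in seq_along(info$ops)) {
        ph <- exp(2i * pi * (info$Hg[[oi]] %*% Xb))
        Fe <- Fe + (info$cg[[oi]] * info$Fg[[oi]]) * ph
      }
      Ie <- Mod(Fe)^2
      vals[[gi]][idx] <- suppressWarnings(as.numeric(stats::cor(info$Imerge, Ie)))
    }
  }
  for (gi in seq_along(groups)) {
    v <- vals[[gi]]
    v[is.na(v)] <- -1
    arr <- array(v, dim = gd)
    best <- max(v)
    # ties: lexicographically smallest (ix, iy, iz)
    cand <- which(v >= best - 1e-9)
    ci <- arrayInd(cand, gd)
    ord <- order(ci[, 1], ci[, 2], ci[, 3])
    pick <- ci[ord[1], ]
    xmax <- (pick - 1) / gd
    xmax <- .canonicalizeShift(xmax, groups[[gi]])
    xmax[abs(xmax) < 1e-12] <- 0
    out[[gi]] <- new("CorrelationMap", group = groups[[gi]],
                     gridDivisions = as.integer(gd), values = arr,
                     xMax = as.numeric(xmax), rMax = best)
  }
  out
}

#' Intensity-correlation translation map r(x, G)
#'
#' For every fractional grid point x, the Pearson correlation between (a)
#' the model's P1 intensities merged under G and (b) intensities of the
#' hypothetical ensemble obtained by shifting the model by x and
#' superposing one copy per operator of G.  Peaks approaching 1 mark
#' candidate origin shifts; the map is constant along polar directions of G
#' and invariant under G's discrete allowed-origin shifts.  The grid step is
#' about half the resolution limit along each axis.
#'
#' @param scat P1 [Scatterers-class] in G's frame.
#' @param group candidate [SpaceGroup-class].
#' @param dmin resolution limit (Angstrom).
#' @param gridDivisions optional integer triple overriding the default grid.
#' @return a [CorrelationMap-class].
#' @export
correlationMap <- function(scat, group, dmin = 3.5, gridDivisions = NULL) {
  .correlationMaps(scat, list(group), dmin, gridDivisions)[[1]]
}

setMethod("show", "CorrelationMap", function(object) {
  cat(sprintf("CorrelationMap for %s: grid %s, r_max %.4f at (%.4f, %.4f, %.4f)\n",
              object@group@symbol, paste(object@gridDivisions, collapse = "x"),
              object@rMax, object@xMax[1], object@xMax[2], object@xMax[3]))
})

#' Amplitude-weighted phase-agreement score
#'
#' For a symmetry operation g = (W, w), a model invariant under g has
#' phi_H = phi_HW + 2 pi H.w for every reflection, so the weighted mean
#' absolute wrapped phase mismatch
#' \deqn{\Phi(g) = \frac{\sum_H |F_H|^2\,|wrap(\phi_H - \phi_{HW} - 2\pi H\cdot w)|}{(\pi/n)\sum_H |F_H|^2}}
#' is zero; it approaches 1 for random phase relationships.  Weights are
#' squared amplitudes and the wrap order is n = 1 (full 2-pi wrapping),
#' which normalizes the score into [0, 1].  This is the statistic that
#' separates a rotation from its screw counterpart when intensities alone
#' cannot.
#'
#' @param scat P1 [Scatterers-class], already shifted to the candidate
#'   origin.
#' @param op a [SymOp-class] of the candidate group.
#' @param dmin resolution limit (Angstrom).
#' @param n wrap order (default 1).
#' @return score in [0, 1].
#' @export
phaseAgreement <- function(scat, op, dmin = 3.5, n = 1) {
  hkl <- millerIndices(scat@cell, dmin)
  if (!nrow(hkl)) stop("empty reflection list")
  HW <- round(hkl %*% rotationPart(op))
  cc <- .friedelCanon(HW)
  both <- rbind(hkl, cc$hkl)
  Fb <- .complexSF(scat, both)
  nr <- nrow(hkl)
  FH <- Fb[seq_len(nr)]
  FHW <- Fb[nr + seq_len(nr)]
  FHW[cc$conj] <- Conj(FHW[cc$conj])
  dphi <- Arg(FH) - Arg(FHW) - 2 * pi * as.numeric(hkl %*% translationPart(op))
  wrap <- dphi - (2 * pi / n) * round(dphi / (2 * pi / n))
  wI <- Mod(FH)^2
  sum(wI * abs(wrap)) / ((pi / n) * sum(wI))
}

#' Rank candidate space groups for a Patterson setting
#'
#' Evaluates every Sohncke group sharing the setting's Patterson symmetry:
#' the correlation map supplies the origin shift x_max and peak height
#' r_max; the phase score Phi, evaluated at x_max for every left-coset
#' representative of the candidate over the input group, separates rotation
#' from screw alternatives.  Candidates whose frame does not contain the
#' input group as a subgroup are excluded with a reason; candidates with
#' r_max below `rCorrMin` are retained in the table but flagged ineligible.
#' The ranking is by maximum Phi ascending, then r_max descending.
#'
#' @param scat P1 [Scatterers-class] in the setting's conventional frame.
#' @param pattersonSymbol the setting's Patterson symbol.
#' @param inputGroup the input symmetry expressed in the same frame.
#' @param dmin resolution limit (Angstrom).
#' @param rCorrMin eligibility threshold on r_max (default 0.8).
#' @param gridDivisions optional grid override.
#' @return list of rankings; each element has `group`, `xMax`, `rMax`,
#'   `maxPhi`, `nCosets`, `eligible` and `reason`.  Sorted best first.
#' @export
rankSpaceGroups <- function(scat, pattersonSymbol, inputGroup, dmin = 3.5,
                            rCorrMin = 0.8, gridDivisions = NULL) {
  cands <- candidateSpaceGroups(pattersonSymbol)
  keep <- list(); dropped <- list()
  for (g in cands) {
    if (isTRUE(isSubgroup(g, inputGroup))) keep <- c(keep, list(g))
    else dropped <- c(dropped, list(list(group = g, xMax = rep(NA_real_, 3),
                                         rMax = NA_real_, maxPhi = NA_real_,
                                         nCosets = NA_integer_, eligible = FALSE,
                                         reason = "input symmetry is not a subgroup")))
  }
  if (!length(keep)) return(dropped)
  maps <- .correlationMaps(scat, keep, dmin, gridDivisions)
  out <- list()
  for (i in seq_along(keep)) {
    g <- keep[[i]]
    map <- maps[[i]]
    shifted <- scat
    shifted@xyz <- sweep(scat@xyz, 2, map@xMax, "+")
    cd <- leftCosets(g, inputGroup)
    phis <- vapply(cd@representatives, function(rep_)
      phaseAgreement(shifted, rep_, dmin), numeric(1))
    maxphi <- if (length(phis)) max(phis) else 0
    eligible <- map@rMax >= rCorrMin
    out <- c(out, list(list(group = g, xMax = map@xMax, rMax = map@rMax,
                            maxPhi = maxphi, nCosets = cd@nCosets,
                            eligible = eligible,
                            reason = if (eligible) "" else
                              sprintf("r_max %.3f below threshold %.2f", map@rMax, rCorrMin))))
  }
  ord <- order(!vapply(out, function(x) x$eligible, logical(1)),
               vapply(out, function(x) x$maxPhi, numeric(1)),
               -vapply(out, function(x) x$rMax, numeric(1)))
  c(out[ord], dropped)
}

#' Export a correlation map as plain text
#'
#' One line per grid point: fractional x, y, z and the correlation value,
#' preceded by comment lines with the group and grid, for inspection or
#' plotting.
#'
#' @param map a [CorrelationMap-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
exportMap <- function(map, path) {
  gd <- map@gridDivisions
  grid <- as.matrix(expand.grid((0:(gd[1] - 1)) / gd[1],
                                (0:(gd[2] - 1)) / gd[2],
                                (0:(gd[3] - 1)) / gd[3]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# correlation map, group %s", map@group@symbol),
               sprintf("# grid %d %d %d", gd[1], gd[2], gd[3]),
               sprintf("# r_max %.6f at %.6f %.6f %.6f", map@rMax,
                       map@xMax[1], map@xMax[2], map@xMax[3])), con)
  writeLines(sprintf("%.6f %.6f %.6f %.8f", grid[, 1], grid[, 2], grid[, 3],
                     as.numeric(map@values)), con)
  invisible(path)
}
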