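#' @include kearsley.R model.R spacegroup.R translation.R
NULL

# sequence-similarity gate: equal length and >= minIdentity identity
.seqComparable <- function(sa, sb, minIdentity = 0.95) {
  length(sa) == length(sb) && mean(sa == sb) >= minIdentity
}

#' Match symmetry-equivalent chains under the coset representatives
#'
#' For each left-coset representative g_i and each chain X of the asymmetric
#' unit, finds the chain Y, operator h of the input group H and integer
#' lattice translation t such that g_i applied to X superimposes (without
#' refit) on h(Y) + t, with a mean C-alpha deviation below `tol`.  Y is only
#' considered when X and Y have similar sequences, and within each coset the
#' X -> Y assignment must be a bijection.
#'
#' @param model [CrystalModel-class], origin-shifted into the optimized
#'   setting (its chains are the H-asymmetric unit).
#' @param H input-symmetry [SpaceGroup-class] in the same frame.
#' @param cosets [CosetDecomposition-class] of the target group over H.
#' @param tol acceptance tolerance on the mean C-alpha deviation (Angstrom,
#'   default 2).
#' @return list with `matches` (list of match records: `coset`, `X`, `Y`,
#'   `h` index into H's operators, `t`, `nCalpha`, `rmsd`) and `unmatched`
#'   (list of failing (coset, X) pairs).
#' @export
matchChains <- function(model, H, cosets, tol = 2.0) {
  O <- orthMatrix(model@cell)
  chains <- model@chains
  P <- length(chains)
  Hops <- operators(H)
  matches <- list(); unmatched <- list()
  for (ci in seq_along(cosets@representatives)) {
    gi <- cosets@representatives[[ci]]
    taken <- integer(0)
    for (xi in seq_len(P)) {
      gx <- applyOp(chains[[xi]]$xyz, gi)
      best <- NULL
      for (yi in seq_len(P)) {
        if (!.seqComparable(chains[[xi]]$seq, chains[[yi]]$seq)) next
        for (hi in seq_along(Hops)) {
          hy <- applyOp(chains[[yi]]$xyz, Hops[[hi]])
          d <- gx - hy
          t0 <- round(colMeans(d))
          # centroid rounding almost always gives t; scan the +/-1 shell
          # only when it fails (chains straddling cell boundaries)
          tries <- list(t0)
          evalT <- function(t_) {
            dev <- t(O %*% t(sweep(d, 2, t_)))
            mean(sqrt(rowSums(dev^2)))
          }
          if (evalT(t0) > tol) {
            tries <- lapply(seq_len(27), function(q) {
              t0 + c((q - 1) %% 3 - 1, ((q - 1) %/% 3) %% 3 - 1, (q - 1) %/% 9 - 1)
            })
          }
          for (t_ in tries) {
            dev <- t(O %*% t(sweep(d, 2, t_)))
            md <- mean(sqrt(rowSums(dev^2)))
            if (md <= tol && (is.null(best) || md < best$meanDev)) {
              best <- list(coset = ci, X = xi, Y = yi, h = hi, t = t_,
                           nCalpha = nrow(d),
                           rmsd = sqrt(mean(rowSums(dev^2))),
                           meanDev = md)
            }
          }
        }
      }
      if (is.null(best)) {
        unmatched <- c(unmatched, list(list(coset = ci, X = xi)))
      } else {
        if (best$Y %in% taken)
          stop("ambiguous chain matching: chain ", chains[[best$Y]]$id,
               " assigned twice within coset ", ci,
               " (symmetry mapping must be a bijection)")
        taken <- c(taken, best$Y)
        matches <- c(matches, list(best))
      }
    }
  }
  list(matches = matches, unmatched = unmatched)
}

#' Refine the origin shift by exact least squares
#'
#' Minimizes the cartesian square difference between chain-matched C-alpha
#' positions,
#' \deqn{f(x) = \sum_{cosets}\sum_{chains}\sum_{C\alpha}
#'   \| O [ g_i(X + x) - ( h(Y + x) + t ) ] \|^2,}
#' which is exactly quadratic in the fractional shift x, so the minimum is
#' found from the normal equations in closed form.  Directions along which f
#' is flat (polar directions of the coset structure) are pinned to zero via
#' the pseudo-inverse.  The deviation from perfect symmetry is
#' \eqn{\Delta r_{sym} = (f_{min} / \Sigma N)^{1/2}} over the
#' \eqn{\Sigma N} matched C-alpha pairs.
#'
#' @param model [CrystalModel-class] in the candidate-group setting,
#'   *without* the origin shift applied.
#' @param H input group in the same frame.
#' @param cosets [CosetDecomposition-class].
#' @param matching output of [matchChains()] (matches found at the
#'   approximate shift).
#' @return list with `xRefined`, `fMin` (Angstrom^2), `totalMatches` and
#'   `deltaRSym` (Angstrom).
#' @export
refineOrigin <- function(model, H, cosets, matching) {
  if (!length(matching$matches)) stop("no chain matches to refine against")
  O <- orthMatrix(model@cell)
  M <- crossprod(O)   # metric: |O v|^2 = v' M v
  Hops <- operators(H)
  N <- matrix(0, 3, 3); rhs <- numeric(3)
  terms <- list()
  totN <- 0
  for (mt in matching$matches) {
    gi <- cosets@representatives[[mt$coset]]
    h <- Hops[[mt$h]]
    Wg <- rotationPart(gi); wg <- translationPart(gi)
    Wh <- rotationPart(h); wh <- translationPart(h)
    X <- model@chains[[mt$X]]$xyz
    Y <- model@chains[[mt$Y]]$xyz
    A <- Wg - Wh
    C <- t(Wg %*% t(X)) + rep(wg, each = nrow(X)) -
         (t(Wh %*% t(Y)) + rep(wh + mt$t, each = nrow(Y)))
    n <- nrow(X)
    N <- N + n * t(A) %*% M %*% A
    rhs <- rhs - as.numeric(t(A) %*% M %*% colSums(C))
    terms <- c(terms, list(list(A = A, C = C)))
    totN <- totN + n
  }
  eg <- eigen(N, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-9
  if (!any(keep)) {
    x <- c(0, 0, 0)
  } else {
    Ninv <- eg$vectors[, keep, drop = FALSE] %*%
      diag(1 / eg$values[keep], sum(keep)) %*% t(eg$vectors[, keep, drop = FALSE])
    x <- as.numeric(Ninv %*% rhs)
  }
  f <- 0
  for (tm in terms) {
    res <- sweep(tm$C, 2, as.numeric(tm$A %*% x), "+")
    resc <- t(O %*% t(res))
    f <- f + sum(resc^2)
  }
  list(xRefined = x, fMin = f, totalMatches = totN,
       deltaRSym = sqrt(f / totN))
}

# union of mutual-match groups: orbits of chain indices under all coset maps
.matchGroups <- function(matches, P) {
  parent <- seq_len(P)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (mt in matches) {
    a <- find(mt$X); b <- find(mt$Y)
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(P), find, integer(1))
  split(seq_len(P), roots)
}

#' Build the n superposed asymmetric-unit models
#'
#' Chains are grouped into mutual-match groups; the first-in-file chain of
#' each group forms the primary model.  For each non-identity coset i an
#' additional model is generated by transforming the matched chain Y of each
#' primary chain X back through \eqn{g_i^{-1}(h(Y + x) + t) - x}, placing it
#' in approximate alignment with X.  A perfectly symmetric structure yields
#' n identical models; differences among the models express the NCS
#' variability of the input.
#'
#' @param model [CrystalModel-class] in the candidate setting, *without* the
#'   shift applied.
#' @param H input group in the same frame.
#' @param cosets [CosetDecomposition-class].
#' @param matching output of [matchChains()].
#' @param xRefined refined fractional origin shift.
#' @return list with `models` (list of n [CrystalModel-class], each with
#'   P/n chains, primary first) and `groups` (the mutual-match chain-index
#'   groups).
#' @export
buildAsuModels <- function(model, H, cosets, matching, xRefined) {
  P <- nChains(model)
  n <- cosets@nCosets
  groups <- .matchGroups(matching$matches, P)
  sizes <- lengths(groups)
  if (length(unique(sizes)) != 1)
    stop("inconsistent chain matching: mutual-match groups of unequal size (",
         paste(sizes, collapse = ","), ")")
  shifted <- shiftModel(model, xRefined)
  primaryIdx <- sort(vapply(groups, min, integer(1)))
  primary <- shifted
  primary@chains <- shifted@chains[primaryIdx]
  models <- list(primary)
  Hops <- operators(H)
  for (ci in seq_along(cosets@representatives)) {
    gi <- cosets@representatives[[ci]]
    giInv <- solve(gi)
    chains <- list()
    for (xi in primaryIdx) {
      mt <- NULL
      for (m in matching$matches)
        if (m$coset == ci && m$X == xi) { mt <- m; break }
      if (is.null(mt))
        stop("incomplete matching: no match for chain ", model@chains[[xi]]$id,
             " under coset ", ci)
      h <- Hops[[mt$h]]
      ych <- shifted@chains[[mt$Y]]
      hy <- sweep(applyOp(ych$xyz, h), 2, mt$t, "+")
      ych$xyz <- applyOp(hy, giInv)
      ych$id <- paste0(ych$id, "~", ci)
      chains <- c(chains, list(ych))
    }
    mi <- shifted
    mi@chains <- chains
    models <- c(models, list(mi))
  }
  stopifnot(length(models) == n)
  list(models = models, groups = groups)
}

#' Rigid-body / residual split of the symmetry deviation
#'
#' Delta r_ASU: RMS deviation between pairs of ASU models after one
#' whole-ASU Kearsley alignment per pair (rigid-body differences absorbed).
#' Delta r_chain: the same with the alignment done chain by chain.  Both are
#' N-weighted over all model pairs; with per-atom noise they approach
#' Delta r_sym, while rigid-body NCS differences push them far below it.
#'
#' @param asu output of [buildAsuModels()] (or a list with `models`).
#' @return list with `deltaRAsu` and `deltaRChain` (Angstrom).
#' @export
residualDeviations <- function(asu) {
  models <- asu$models
  n <- length(models)
  if (n < 2) return(list(deltaRAsu = NA_real_, deltaRChain = NA_real_))
  O <- orthMatrix(models[[1]]@cell)
  cart <- function(m) lapply(m@chains, function(ch) t(O %*% t(ch$xyz)))
  carts <- lapply(models, cart)
  sum2Asu <- 0; nAsu <- 0
  sum2Ch <- 0; nCh <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    Ai <- do.call(rbind, carts[[i]])
    Aj <- do.call(rbind, carts[[j]])
    k <- kearsleySuperpose(Ai, Aj)
    Nij <- nrow(Ai)
    sum2Asu <- sum2Asu + Nij * k$rmsd^2
    nAsu <- nAsu + Nij
    for (ci in seq_along(carts[[i]])) {
      kc <- kearsleySuperpose(carts[[i]][[ci]], carts[[j]][[ci]])
      nc <- nrow(carts[[i]][[ci]])
      sum2Ch <- sum2Ch + nc * kc$rmsd^2
      nCh <- nCh + nc
    }
  }
  list(deltaRAsu = sqrt(sum2Asu / nAsu), deltaRChain = sqrt(sum2Ch / nCh))
}
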