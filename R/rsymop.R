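#' @include structurefactors.R patterson.R
NULL

#' Symmetry-operator reliability R_symop
#'
#' The average fractional difference between pairs of intensities related by
#' a candidate rotation operator:
#' \deqn{R = \sum_{pairs} |I_H - I_{HW}| \; / \; \sum_{pairs} (I_H + I_{HW})}
#' over all index pairs (H, HW) present in the P1 set.  Indices invariant
#' under W (self-pairs, including Friedel-degenerate ones) carry no
#' information and are excluded; pairs whose partner is absent are skipped
#' and counted.  The statistic is ideally zero for a valid operator and
#' values up to ~0.25 must be tolerated for measured data.
#'
#' @param p1 a [ReflectionSet-class] in P1 (calculated or expanded observed
#'   intensities).
#' @param op a [SymOp-class] whose rotation part is an integer matrix in
#'   this basis (it must map the lattice to itself).
#' @return list with `value` (fraction in `[0,1]`), `nPairs` (directed pair
#'   count) and `nMissing` (indices whose partner was absent).
#' @export
rSymop <- function(p1, op) {
  W <- rotationPart(op)
  if (!.ratIsIntegral(W))
    stop("operator is not an integer matrix in this basis")
  HW <- round(p1@hkl %*% W)
  cc <- .friedelCanon(HW)
  keys <- .hklKey(p1@hkl)
  pk <- .hklKey(cc$hkl)
  j <- match(pk, keys)
  self <- pk == keys
  ok <- !is.na(j) & !self
  nmiss <- sum(is.na(j) & !self)
  if (!any(ok)) stop("no scorable pairs for operator ", opXyz(op))
  Ii <- p1@I[ok]; Ij <- p1@I[j[ok]]
  denom <- sum(Ii + Ij)
  val <- if (denom > 0) sum(abs(Ii - Ij)) / denom else 0
  list(value = val, nPairs = sum(ok), nMissing = nmiss)
}

#' Score Patterson settings by worst-case R_symop
#'
#' For each candidate setting the worst R_symop over its non-identity
#' rotation operators is recorded (calculated intensities always; observed
#' ones when given), and the setting is flagged plausible when the worst
#' case stays below `rMax`.  The triclinic setting scores zero by
#' construction and is always plausible.
#'
#' @param settings list of [PattersonSetting-class] (operators in the same
#'   frame as the intensity sets).
#' @param calcP1 [ReflectionSet-class] of calculated intensities in P1.
#' @param obsP1 optional [ReflectionSet-class] of observed intensities in P1.
#' @param rMax plausibility threshold (default 0.25).
#' @return the settings list with score slots filled.
#' @export
scorePattersonSettings <- function(settings, calcP1, obsP1 = NULL, rMax = 0.25) {
  lapply(settings, function(s) {
    nontriv <- Filter(function(o) !.isIdentityOp(o), s@ops)
    if (!length(nontriv)) {
      s@maxRsymopCalc <- 0
      s@maxRsymopObs <- if (is.null(obsP1)) NA_real_ else 0
      s@plausible <- TRUE
      return(s)
    }
    s@maxRsymopCalc <- max(vapply(nontriv, function(o) rSymop(calcP1, o)$value,
                                  numeric(1)))
    if (!is.null(obsP1))
      s@maxRsymopObs <- max(vapply(nontriv, function(o) rSymop(obsP1, o)$value,
                                   numeric(1)))
    s@plausible <- s@maxRsymopCalc <= rMax &&
      (is.null(obsP1) || is.na(s@maxRsymopObs) || s@maxRsymopObs <= rMax)
    s
  })
}
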