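#' @include reduce.R rsymop.R translation.R matching.R io.R
NULL

#' Pipeline configuration
#'
#' Default tolerances of the symmetry check: statistics are computed to a
#' limiting resolution of 3.5 Angstrom; lattice axes are accepted up to a
#' Le Page delta of 1.4 degrees; a setting or operator is plausible while
#' R_symop stays below 0.25; a target group is a reassignment candidate when
#' the RMS C-alpha displacement needed to impose it stays below 0.325
#' Angstrom (an intentionally conservative figure of the order of typical
#' coordinate uncertainty); candidate groups need a correlation peak of at
#' least 0.8; chains match when their mean C-alpha deviation under the trial
#' operator is below 2 Angstrom.
#'
#' @param dMin resolution limit (Angstrom).
#' @param deltaTol Le Page delta tolerance (degrees).
#' @param rsymopMax R_symop plausibility threshold (fraction).
#' @param drSymMax Delta r_sym candidate cutoff (Angstrom).
#' @param rCorrMin correlation-peak eligibility threshold.
#' @param matchTol chain-match tolerance (Angstrom).
#' @param seed integer seed (reserved for stochastic extensions; the check
#'   itself is deterministic).
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(dMin = 3.5, deltaTol = 1.4, rsymopMax = 0.25,
                           drSymMax = 0.325, rCorrMin = 0.8, matchTol = 2.0,
                           seed = 1L) {
  stopifnot(dMin > 0, deltaTol >= 0, rsymopMax > 0, drSymMax > 0,
            rCorrMin > 0, matchTol > 0)
  structure(list(dMin = dMin, deltaTol = deltaTol, rsymopMax = rsymopMax,
                 drSymMax = drSymMax, rCorrMin = rCorrMin,
                 matchTol = matchTol, seed = as.integer(seed)),
            class = "PipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

# crystal system implied by a Patterson symbol
.pattersonSystem <- function(sym) {
  if (sym == "P-1") return("triclinic")
  if (grepl("12/m1", sym)) return("monoclinic")
  if (grepl("mmm$", sym) && !grepl("4|6", sym)) return("orthorhombic")
  if (grepl("4/m", sym)) return("tetragonal")
  if (sym %in% c("P-3", "P-3m1", "P-31m")) return("trigonal")
  if (sym %in% c("R-3", "R-3m")) return("rhombohedral")
  if (grepl("6/m", sym)) return("hexagonal")
  if (grepl("m-3", sym)) return("cubic")
  stop("cannot infer crystal system of ", sym)
}

#' Check a model (and optional data) for underassigned symmetry
#'
#' Runs the full reference-frame chain: centring removal, cell reduction,
#' P1 expansion, lattice twofold search, Patterson-setting enumeration and
#' intensity scoring (calculated and, when given, observed), then for each
#' plausible non-trivial setting the space-group ranking (translation search
#' plus phase scores), coset decomposition, chain matching, origin
#' refinement, ASU-model generation and the deviation split.  The verdict is
#' positive when the displacement and intensity thresholds of `config` are
#' all met; absence of observed data never blocks the coordinate-based
#' verdict.
#'
#' @param model a [CrystalModel-class].
#' @param obs optional [ReflectionSet-class] merged in the model's group.
#' @param config a [pipelineConfig()].
#' @return list with `report` (a [SymmetryReport-class]), `asuModels`
#'   (when a target was evaluated), `settings` (scored
#'   [PattersonSetting-class] list), `ranking` (per-setting space-group
#'   rankings) and `frames` (the composed change-of-basis operators).
#' @export
checkSymmetry <- function(model, obs = NULL, config = pipelineConfig()) {
  inputSymbol <- model@group@symbol
  # 1. centring removal
  rc <- .stage("remove_centring", removeCentring(model))
  modelP <- rc$model
  # 2. cell reduction
  red <- .stage("reduce_cell", reduceCell(modelP@cell))
  modelR <- .stage("reduce_cell", changeBasis(modelP, red$cb))
  cbTot <- red$cb %*% rc$cb
  nChainsP1 <- nChains(model) * length(modelR@group@ops)
  # 3. P1 expansion + calculated intensities in the reduced frame
  calcP1 <- .stage("calc_intensities", {
    p1 <- expandToP1(modelR)
    calcStructureFactors(asScatterers(p1), config$dMin)
  })
  obsP1 <- NULL
  if (!is.null(obs)) {
    obsP1 <- .stage("expand_obs", {
      obsR <- changeBasis(obs, cbTot)
      expandObsToP1(obsR)
    })
  }
  # 4. lattice symmetry and Patterson settings
  twofolds <- .stage("lattice_twofolds",
                     findLatticeTwofolds(modelR@cell, config$deltaTol))
  settings <- .stage("patterson_settings",
                     enumeratePattersonSettings(modelR@cell, twofolds, nChainsP1))
  settings <- .stage("score_settings",
                     scorePattersonSettings(settings, calcP1, obsP1,
                                            rMax = config$rsymopMax))
  plausible <- Filter(function(s) isTRUE(s@plausible) && length(s@ops) > 1,
                      settings)
  rankings <- list()
  attempts <- list()
  for (s in plausible) {
    res <- tryCatch(
      .evaluateSetting(modelR, s, calcP1, obsP1, config, inputSymbol),
      error = function(e) list(failed = conditionMessage(e)))
    if (!is.null(res$failed)) {
      attempts <- c(attempts, list(list(setting = s@pattersonSymbol,
                                        reason = res$failed)))
      next
    }
    rankings <- c(rankings, list(res$ranking))
    attempts <- c(attempts, list(list(setting = s@pattersonSymbol,
                                      report = res$report)))
    if (isTRUE(res$report@candidate)) {
      return(list(report = res$report, asuModels = res$asuModels,
                  settings = settings, ranking = res$ranking,
                  attempts = attempts,
                  frames = list(toReduced = cbTot,
                                toConventional = res$cbConv)))
    }
  }
  # no candidate: report the best evaluated attempt, or a negative verdict
  evaluated <- Filter(function(a) !is.null(a$report), attempts)
  if (length(evaluated)) {
    best <- evaluated[[which.min(vapply(evaluated, function(a)
      a$report@deltaRSym, numeric(1)))]]
    return(list(report = best$report, asuModels = NULL, settings = settings,
                ranking = rankings, attempts = attempts,
                frames = list(toReduced = cbTot)))
  }
  report <- new("SymmetryReport", inputGroup = inputSymbol,
                targetGroup = inputSymbol, nCosets = 1L,
                xRefined = c(0, 0, 0), maxPhi = NA_real_,
                deltaRSym = NA_real_, rsymopCalcMax = NA_real_,
                candidate = FALSE,
                details = list(reason = "no plausible higher-symmetry setting",
                               attempts = attempts))
  list(report = report, asuModels = NULL, settings = settings,
       ranking = rankings, attempts = attempts,
       frames = list(toReduced = cbTot))
}

# evaluate one plausible Patterson setting end to end
.evaluateSetting <- function(modelR, setting, calcP1, obsP1, config,
                             inputSymbol) {
  cbConv <- setting@cbToConventional
  modelC <- changeBasis(modelR, cbConv)
  modelC@cell <- symmetrizeCell(modelC@cell,
                                .pattersonSystem(setting@pattersonSymbol))
  Hc <- modelC@group
  scatC <- asScatterers(expandToP1(modelC))
  ranking <- rankSpaceGroups(scatC, setting@pattersonSymbol, Hc,
                             dmin = config$dMin, rCorrMin = config$rCorrMin)
  pick <- NULL
  for (r in ranking) {
    if (!is.na(r$nCosets) && r$nCosets >= 2 && isTRUE(r$eligible)) { pick <- r; break }
  }
  if (is.null(pick))
    stop("no eligible candidate group (all ruled out by subgroup or ",
         "correlation checks)")
  G <- pick$group
  cosets <- leftCosets(G, Hc)
  shifted <- shiftModel(modelC, pick$xMax)
  mm <- matchChains(shifted, Hc, cosets, tol = config$matchTol)
  if (length(mm$unmatched))
    stop(sprintf("chain matching failed for %d (coset, chain) pairs under %s",
                 length(mm$unmatched), G@symbol))
  ref <- refineOrigin(modelC, Hc, cosets, mm)
  asu <- buildAsuModels(modelC, Hc, cosets, mm, ref$xRefined)
  resid <- residualDeviations(asu)
  # phase score at the *refined* origin (the grid peak is granularity-limited)
  scatRef <- asScatterers(expandToP1(shiftModel(modelC, ref$xRefined)))
  maxPhi <- max(c(0, vapply(cosets@representatives, function(rep_)
    phaseAgreement(scatRef, rep_, config$dMin), numeric(1))))
  # worst-case R_symop over the coset representatives, in the reduced frame
  backCb <- solve(cbConv)
  repsR <- lapply(cosets@representatives, changeBasis, cb = backCb)
  rcal <- max(vapply(repsR, function(o) rSymop(calcP1, o)$value, numeric(1)))
  robs <- if (is.null(obsP1)) NA_real_ else
    max(vapply(repsR, function(o) rSymop(obsP1, o)$value, numeric(1)))
  cand <- ref$deltaRSym < config$drSymMax && rcal < config$rsymopMax &&
    (is.na(robs) || robs < config$rsymopMax)
  report <- new("SymmetryReport",
                inputGroup = inputSymbol, targetGroup = G@symbol,
                nCosets = cosets@nCosets,
                xRefined = ref$xRefined, maxPhi = maxPhi,
                deltaRSym = ref$deltaRSym, deltaRAsu = resid$deltaRAsu,
                deltaRChain = resid$deltaRChain,
                rsymopCalcMax = rcal, rsymopObsMax = robs,
                candidate = cand,
                details = list(
                  patterson_setting = setting@pattersonSymbol,
                  x_max_grid = pick$xMax, r_max = pick$rMax,
                  total_matches = ref$totalMatches, f_min = ref$fMin))
  list(report = report, asuModels = asu, ranking = ranking, cbConv = cbConv)
}

setMethod("show", "SymmetryReport", function(object) {
  writeLines(formatReport(object))
})

#' Batch survey of PDB files
#'
#' Runs [checkSymmetry()] on every file, isolating per-file failures, and
#' returns the results ranked by increasing Delta r_sym together with a
#' coset-count histogram and an input-point-group tabulation of the
#' candidates.
#'
#' @param paths character vector of PDB files.
#' @param config a [pipelineConfig()].
#' @return list with `table` (data.frame sorted by Delta r_sym), `errors`
#'   (named list), `cosetHistogram` and `pointGroupTable`.
#' @export
batchSurvey <- function(paths, config = pipelineConfig()) {
  rows <- list(); errors <- list()
  for (p in paths) {
    res <- tryCatch({
      m <- readModel(p)
      out <- checkSymmetry(m, config = config)
      r <- out$report
      data.frame(path = p, input_group = r@inputGroup,
                 target_group = r@targetGroup, n_cosets = r@nCosets,
                 delta_r_sym = r@deltaRSym, delta_r_asu = r@deltaRAsu,
                 rsymop_calc_max = r@rsymopCalcMax,
                 candidate = isTRUE(r@candidate), stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) errors[[p]] <- conditionMessage(res)
    else rows <- c(rows, list(res))
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(0), input_group = character(0),
               target_group = character(0), n_cosets = integer(0),
               delta_r_sym = numeric(0), delta_r_asu = numeric(0),
               rsymop_calc_max = numeric(0), candidate = logical(0))
  tab <- tab[order(tab$delta_r_sym, na.last = TRUE), , drop = FALSE]
  cand <- tab[tab$candidate %in% TRUE, , drop = FALSE]
  cosetHist <- if (nrow(cand)) table(cand$n_cosets) else table(integer(0))
  pgOf <- function(sym) {
    hit <- .lookupSymbol(sym)
    if (is.null(hit)) NA_character_ else attr(hit$group, "pointGroup")
  }
  pgTab <- if (nrow(cand))
    table(vapply(cand$input_group, pgOf, character(1))) else table(character(0))
  list(table = tab, errors = errors, cosetHistogram = cosetHist,
       pointGroupTable = pgTab)
}
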