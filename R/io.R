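#' @include model.R structurefactors.R
NULL

#' Read a protein coordinate model from a PDB file
#'
#' Parses the CRYST1 cell and space-group symbol (leniently with respect to
#' spacing, but never silently falling back to P1) and collects the C-alpha
#' atoms of the protein chains via the bio3d parser.  Waters, HETATM
#' records and alternate locations other than '' or 'A' are dropped with
#' counts recorded in the provenance.  Cartesian coordinates are converted
#' to fractional with the cell's orthogonalization matrix.
#'
#' @param path PDB file path.
#' @return a [CrystalModel-class].
#' @export
readModel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) stop("missing CRYST1 record in ", path)
  cl <- cl[1]
  nums <- suppressWarnings(as.numeric(c(
    substr(cl, 7, 15), substr(cl, 16, 24), substr(cl, 25, 33),
    substr(cl, 34, 40), substr(cl, 41, 47), substr(cl, 48, 54))))
  if (any(is.na(nums))) stop("unparseable CRYST1 record: ", cl)
  cell <- unitCell(nums[1], nums[2], nums[3], nums[4], nums[5], nums[6])
  symtxt <- trimws(substr(cl, 56, 66))
  group <- spaceGroup(symtxt)   # errors for unknown / non-Sohncke symbols
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  nHet <- sum(at$type != "ATOM")
  at <- at[at$type == "ATOM", , drop = FALSE]
  alt <- ifelse(is.na(at$alt), "", at$alt)
  nAlt <- sum(!(alt %in% c("", "A")))
  at <- at[alt %in% c("", "A"), , drop = FALSE]
  at <- at[at$elety == "CA" & !(at$resid %in% c("HOH", "WAT")), , drop = FALSE]
  if (!nrow(at)) stop("no protein C-alpha atoms in ", path)
  Oinv <- solve(orthMatrix(cell))
  chains <- list()
  for (chid in unique(at$chain)) {
    sub <- at[at$chain == chid, , drop = FALSE]
    frac <- t(Oinv %*% t(as.matrix(sub[, c("x", "y", "z")])))
    chains <- c(chains, list(list(id = as.character(chid),
                                  seq = as.character(sub$resid),
                                  xyz = unname(frac))))
  }
  crystalModel(cell, group, chains,
               provenance = c(path,
                              sprintf("dropped: %d HETATM, %d altloc", nHet, nAlt)))
}

.aa1to3 <- NULL  # residue names kept as read; synthetic models use 3-letter codes

#' Write a model as a PDB file
#'
#' CRYST1 with the model's cell and space-group symbol, one CA ATOM record
#' per site (fractional coordinates converted to cartesian and canonicalized
#' into the cell only here, chain by chain so chains are not torn), TER
#' between chains.
#'
#' @param model a [CrystalModel-class].
#' @param path output file path.
#' @param wrap move each chain's centroid into `[0,1)` (default TRUE).
#' @return invisibly, `path`.
#' @export
writeModel <- function(model, path, wrap = TRUE) {
  p <- cellParameters(model)
  sym <- model@group@symbol
  symout <- if (nzchar(sym)) {
    hit <- .lookupSymbol(sym)
    if (!is.null(hit)) attr(hit$group, "fullSymbol") else sym
  } else "P 1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                     p[1], p[2], p[3], p[4], p[5], p[6], symout,
                     length(model@group@ops)), con)
  O <- orthMatrix(model@cell)
  serial <- 0
  for (ch in model@chains) {
    xyz <- ch$xyz
    if (wrap) {
      cen <- colMeans(xyz)
      xyz <- sweep(xyz, 2, floor(cen))
    }
    cart <- t(O %*% t(xyz))
    chid <- substr(ch$id, 1, 1)
    for (i in seq_len(nrow(cart))) {
      serial <- serial + 1
      res <- ch$seq[i]
      if (is.na(res) || !nzchar(res)) res <- "ALA"
      writeLines(sprintf("ATOM  %5d  CA  %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
                         serial %% 100000, substr(res, 1, 3), chid, i %% 10000,
                         cart[i, 1], cart[i, 2], cart[i, 3], 1.0, 20.0), con)
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read merged reflection data
#'
#' Accepts either an mmCIF `_refln` loop (columns `index_h/k/l` with
#' `intensity_meas` or `F_meas_au`; intensities preferred when both are
#' present) or whitespace-separated `h k l I [sigI]` text.  Amplitudes are
#' squared into intensities.  If the file carries a cell it must agree with
#' `cell` within 1 percent; duplicate symmetry-equivalent indices under
#' `group` are rejected with the offending lines named.
#'
#' @param path reflection file.
#' @param cell the model's [UnitCell-class].
#' @param group merging symmetry, a [SpaceGroup-class].
#' @return a [ReflectionSet-class].
#' @export
readReflections <- function(path, cell, group) {
  lines <- readLines(path, warn = FALSE)
  isCif <- any(grepl("^\\s*loop_", lines)) && any(grepl("_refln", lines))
  if (isCif) {
    out <- .readReflnCif(lines, cell, group)
  } else {
    out <- .readReflnText(lines, cell, group)
  }
  # duplicate check under the merging group (Friedel included)
  hkl <- out@hkl
  repkey <- rep(NA_character_, nrow(hkl))
  for (op in operators(group)) {
    Hg <- round(hkl %*% rotationPart(op))
    cc <- .friedelCanon(Hg)
    kk <- .hklKey(cc$hkl)
    newrep <- is.na(repkey) | kk < repkey
    repkey[newrep] <- kk[newrep]
  }
  if (anyDuplicated(repkey)) {
    d <- which(repkey == repkey[anyDuplicated(repkey)])[1:2]
    stop("duplicate symmetry-equivalent reflections: records ", d[1], " and ",
         d[2], " (", .hklKey(hkl[d[1], , drop = FALSE]), " vs ",
         .hklKey(hkl[d[2], , drop = FALSE]), ") are equivalent under ",
         group@symbol)
  }
  out
}

.readReflnText <- function(lines, cell, group) {
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf < 4)
  if (length(bad)) stop("unparseable reflection lines: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  m <- t(vapply(fields, function(f) as.numeric(f[1:min(5, length(f))])[1:5],
                numeric(5)))
  hkl <- m[, 1:3, drop = FALSE]
  if (!.ratIsIntegral(hkl)) stop("non-integer Miller indices in reflection text")
  reflectionSet(cell, group, round(hkl), I = m[, 4], sigI = m[, 5])
}

.readReflnCif <- function(lines, cell, group) {
  # minimal mmCIF _refln loop reader
  cellTags <- c(a = "_cell.length_a", b = "_cell.length_b", c = "_cell.length_c")
  for (tag in cellTags) {
    ln <- grep(paste0("^\\s*", tag, "\\b"), lines, value = TRUE)
    if (length(ln)) {
      val <- suppressWarnings(as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]][2]))
      idx <- which(cellTags == tag)
      if (!is.na(val) && abs(val - cell@abc[idx]) / cell@abc[idx] > 0.01)
        stop("reflection-file cell disagrees with model cell (", tag, " = ",
             val, " vs ", round(cell@abc[idx], 3), ")")
    }
  }
  li <- grep("^\\s*loop_\\s*$", lines)
  for (start in li) {
    tags <- character(0)
    i <- start + 1
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1
    }
    if (!any(grepl("^_refln", tags))) next
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (!nzchar(ln) || grepl("^(loop_|_|#)", ln)) break
      rows <- c(rows, list(strsplit(ln, "\\s+")[[1]]))
      i <- i + 1
    }
    tab <- do.call(rbind, rows)
    colid <- function(nm) {
      j <- match(nm, tags)
      if (is.na(j)) NA_integer_ else j
    }
    jh <- colid("_refln.index_h"); jk <- colid("_refln.index_k"); jl <- colid("_refln.index_l")
    if (is.na(jh)) stop("mmCIF _refln loop lacks index columns")
    hkl <- cbind(as.numeric(tab[, jh]), as.numeric(tab[, jk]), as.numeric(tab[, jl]))
    jI <- colid("_refln.intensity_meas"); jsig <- colid("_refln.intensity_sigma")
    jF <- colid("_refln.F_meas_au"); jFs <- colid("_refln.F_meas_sigma_au")
    if (!is.na(jI)) {
      I <- as.numeric(tab[, jI])
      sig <- if (!is.na(jsig)) as.numeric(tab[, jsig]) else NULL
      return(reflectionSet(cell, group, round(hkl), I = I, sigI = sig))
    }
    if (!is.na(jF)) {
      F_ <- as.numeric(tab[, jF])
      return(reflectionSet(cell, group, round(hkl), F = F_))
    }
    stop("mmCIF _refln loop has neither intensity nor amplitude columns")
  }
  stop("no _refln loop found in mmCIF file")
}

#' Write the report, tables and ASU models of a symmetry check
#'
#' Produces `report.json` (full precision), `report.txt` (human-readable
#' operator/setting/verdict tables) and `model_coset_<i>.pdb` for each
#' superposed asymmetric-unit model.
#'
#' @param report a [SymmetryReport-class].
#' @param asuModels optional output of [buildAsuModels()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeOutputs <- function(report, asuModels = NULL, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  js <- file.path(dir, "report.json")
  jsonlite::write_json(reportAsList(report), js, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, js)
  tx <- file.path(dir, "report.txt")
  writeLines(formatReport(report), tx)
  files <- c(files, tx)
  if (!is.null(asuModels)) {
    for (i in seq_along(asuModels$models)) {
      f <- file.path(dir, sprintf("model_coset_%d.pdb", i))
      writeModel(asuModels$models[[i]], f)
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Plain-list form of a report (JSON-ready)
#' @param report a [SymmetryReport-class].
#' @export
reportAsList <- function(report) {
  list(input_group = report@inputGroup,
       target_group = report@targetGroup,
       n_cosets = report@nCosets,
       x_refined = report@xRefined,
       max_phi = report@maxPhi,
       delta_r_sym = report@deltaRSym,
       delta_r_asu = report@deltaRAsu,
       delta_r_chain = report@deltaRChain,
       rsymop_calc_max = report@rsymopCalcMax,
       rsymop_obs_max = report@rsymopObsMax,
       candidate = report@candidate,
       details = report@details)
}

#' Human-readable report text
#' @param report a [SymmetryReport-class].
#' @export
formatReport <- function(report) {
  c(sprintf("Input symmetry      %s", report@inputGroup),
    sprintf("Target symmetry     %s", report@targetGroup),
    sprintf("No. of cosets       %d", report@nCosets),
    sprintf("Origin shift        (%.5f, %.5f, %.5f)",
            report@xRefined[1], report@xRefined[2], report@xRefined[3]),
    sprintf("Maximum Phi(g_i)    %.4f", report@maxPhi),
    sprintf("Delta r_sym   (A)   %.3f", report@deltaRSym),
    sprintf("Delta r_ASU   (A)   %.3f", report@deltaRAsu),
    sprintf("Delta r_chain (A)   %.3f", report@deltaRChain),
    sprintf("R_symop calc (%%)    %.1f", 100 * report@rsymopCalcMax),
    if (!is.na(report@rsymopObsMax))
      sprintf("R_symop obs  (%%)    %.1f", 100 * report@rsymopObsMax),
    sprintf("Candidate           %s", if (isTRUE(report@candidate)) "YES" else "no"))
}
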