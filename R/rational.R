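# Exact rational arithmetic on small matrices/vectors.
#
# A rational matrix (or vector) is stored as a list(num=, den=) where `num`
# holds integer-valued doubles and `den` is a single positive integer-valued
# double.  All entries share the one denominator.  Every operation reduces by
# the collective gcd, so equality is plain componentwise comparison.  Doubles
# are exact for the integer magnitudes that arise here (denominators stay far
# below 2^53).

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }
  a
}

.gcdAll <- function(v) {
  g <- 0
  for (x in v) {
    g <- .gcd2(g, x)
    if (g == 1) break
  }
  g
}

.ratNew <- function(num, den = 1) {
  if (den < 0) { num <- -num; den <- -den }
  stopifnot(den > 0)
  g <- .gcdAll(c(den, as.numeric(num)))
  if (g > 1) { num <- num / g; den <- den / g }
  list(num = num, den = den)
}

.ratIsIntegral <- function(x, tol = 1e-9) all(abs(x - round(x)) < tol)

# rational matrix %*% rational matrix (or matrix %*% vector)
.ratMul <- function(a, b) .ratNew(a$num %*% b$num, a$den * b$den)

.ratAdd <- function(a, b) .ratNew(a$num * b$den + b$num * a$den, a$den * b$den)

.ratNeg <- function(a) list(num = -a$num, den = a$den)

# inverse of a 3x3 rational matrix via the adjugate (exact)
.ratInv <- function(a) {
  n <- a$num
  d <- det(n)
  if (abs(d) < 0.5) stop("rational matrix is singular")
  d <- round(d)
  adj <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    m <- n[-j, -i, drop = FALSE]
    adj[i, j] <- (-1)^(i + j) * round(det(m))
  }
  .ratNew(adj * a$den, d)
}

# reduce a rational vector modulo 1 into [0,1)
.ratMod1 <- function(a) {
  num <- ((round(a$num) %% a$den) + a$den) %% a$den
  .ratNew(num, a$den)
}

.ratEq <- function(a, b) a$den == b$den && all(a$num == b$num)

.ratAsNumeric <- function(a) a$num / a$den

# ---- xyz triplet parsing ("-y,x,z+1/2" dialect) -----------------------------

.parseXyzTerm <- function(s) {
  # one coordinate expression -> list(row = length-3, t = list(num, den))
  s <- gsub(" ", "", s)
  row <- c(0, 0, 0); tn <- 0; td <- 1
  # tokenize signed terms
  toks <- regmatches(s, gregexpr("[+-]?[^+-]+", s))[[1]]
  for (tk in toks) {
    sgn <- if (substr(tk, 1, 1) == "-") -1 else 1
    body <- sub("^[+-]", "", tk)
    if (grepl("[xyz]", body)) {
      coef <- sub("[xyz].*$", "", body)
      coef <- sub("\\*$", "", coef)
      cnum <- if (coef == "") 1 else as.numeric(coef)
      ax <- regmatches(body, regexpr("[xyz]", body))
      idx <- match(ax, c("x", "y", "z"))
      row[idx] <- row[idx] + sgn * cnum
    } else if (grepl("/", body)) {
      pq <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1]])
      tn <- tn * pq[2] + sgn * pq[1] * td
      td <- td * pq[2]
    } else {
      tn <- tn + sgn * as.numeric(body) * td
    }
  }
  list(row = row, t = .ratNew(tn, td))
}

.parseXyz <- function(xyz) {
  parts <- strsplit(xyz, ",", fixed = TRUE)[[1]]
  if (length(parts) != 3L) stop("xyz triplet must have three components: ", xyz)
  W <- matrix(0, 3, 3)
  ts <- vector("list", 3)
  for (i in 1:3) {
    tm <- .parseXyzTerm(parts[i])
    W[i, ] <- tm$row
    ts[[i]] <- tm$t
  }
  den <- ts[[1]]$den * ts[[2]]$den * ts[[3]]$den
  num <- vapply(1:3, function(i) ts[[i]]$num * den / ts[[i]]$den, numeric(1))
  list(W = .ratNew(W, 1), w = .ratNew(num, den))
}

.fmtFrac <- function(num, den) {
  if (num == 0) return("")
  g <- .gcd2(num, den); num <- num / g; den <- den / g
  if (den == 1) sprintf("%+d", num) else sprintf("%+d/%d", num, den)
}

.formatXyz <- function(W, w) {
  # W, w rational lists; returns "x,y,z"-style triplet
  ax <- c("x", "y", "z")
  out <- character(3)
  Wn <- W$num; Wd <- W$den
  for (i in 1:3) {
    terms <- ""
    for (j in 1:3) {
      c_ <- Wn[i, j] / Wd
      if (c_ == 0) next
      co <- if (c_ == 1) "+" else if (c_ == -1) "-" else sprintf("%+g*", c_)
      terms <- paste0(terms, co, ax[j])
    }
    terms <- paste0(terms, .fmtFrac(w$num[i], w$den))
    terms <- sub("^\\+", "", terms)
    out[i] <- if (terms == "") "0" else terms
  }
  paste(out, collapse = ",")
}
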