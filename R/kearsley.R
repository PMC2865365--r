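#' @include AllClasses.R
NULL

#' Least-squares rigid superposition (Kearsley quaternion method)
#'
#' Finds the proper rotation and translation minimizing the RMS deviation
#' between two equal-length cartesian point sets, via the eigenvector of the
#' 4x4 quaternion matrix belonging to its smallest eigenvalue.  The
#' minimized residual is available in closed form from that eigenvalue.
#'
#' @param A,B n x 3 cartesian coordinate matrices (Angstrom); B is rotated
#'   onto A.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3; the
#'   superposed B is `B %*% t(rotation) + translation`), and `rmsd`
#'   (Angstrom).
#' @export
kearsleySuperpose <- function(A, B) {
  if (!is.matrix(A) || !is.matrix(B) || ncol(A) != 3 || ncol(B) != 3)
    stop("A and B must be n x 3 matrices")
  if (nrow(A) != nrow(B)) stop("point sets differ in length")
  n <- nrow(A)
  if (n < 3) stop("at least 3 points are required")
  cA <- colMeans(A); cB <- colMeans(B)
  X <- sweep(A, 2, cA); Y <- sweep(B, 2, cB)
  # Kearsley sum/difference coordinates
  xm <- Y[, 1] - X[, 1]; ym <- Y[, 2] - X[, 2]; zm <- Y[, 3] - X[, 3]
  xp <- Y[, 1] + X[, 1]; yp <- Y[, 2] + X[, 2]; zp <- Y[, 3] + X[, 3]
  Q <- matrix(0, 4, 4)
  Q[1, 1] <- sum(xm^2 + ym^2 + zm^2)
  Q[2, 2] <- sum(xm^2 + yp^2 + zp^2)
  Q[3, 3] <- sum(xp^2 + ym^2 + zp^2)
  Q[4, 4] <- sum(xp^2 + yp^2 + zm^2)
  Q[1, 2] <- Q[2, 1] <- sum(yp * zm - ym * zp)
  Q[1, 3] <- Q[3, 1] <- sum(xm * zp - xp * zm)
  Q[1, 4] <- Q[4, 1] <- sum(xp * ym - xm * yp)
  Q[2, 3] <- Q[3, 2] <- sum(xm * ym - xp * yp)
  Q[2, 4] <- Q[4, 2] <- sum(xm * zm - xp * zp)
  Q[3, 4] <- Q[4, 3] <- sum(ym * zm - yp * zp)
  eig <- eigen(Q, symmetric = TRUE)
  q <- eig$vectors[, 4]   # eigenvector of the smallest eigenvalue
  q1 <- q[1]; q2 <- q[2]; q3 <- q[3]; q4 <- q[4]
  R <- matrix(c(
    q1^2 + q2^2 - q3^2 - q4^2, 2 * (q2 * q3 + q1 * q4),   2 * (q2 * q4 - q1 * q3),
    2 * (q2 * q3 - q1 * q4),   q1^2 + q3^2 - q2^2 - q4^2, 2 * (q3 * q4 + q1 * q2),
    2 * (q2 * q4 + q1 * q3),   2 * (q3 * q4 - q1 * q2),   q1^2 + q4^2 - q2^2 - q3^2
  ), 3, 3, byrow = TRUE)
  R <- t(R)   # orientation: rotate B onto A
  translation <- cA - as.numeric(R %*% cB)
  # evaluate the residual of the minimizing rotation directly: numerically
  # sharper than sqrt(lambda_min/n) when the fit is near-exact
  res <- Y %*% t(R) - X
  rmsd <- sqrt(sum(res^2) / n)
  list(rotation = R, translation = translation, rmsd = rmsd)
}
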