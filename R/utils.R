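# Numeric helpers shared across modules.

.rad <- function(deg) deg * pi / 180
.deg <- function(rad) rad * 180 / pi

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, as used for reported
#' occupancy percentages. A small epsilon guards against binary
#' representation of decimal fractions (e.g. 71.35 stored just below 71.35).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

## Angle between two 3-vectors, degrees in [0, 180].
vecAngle <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    stop("cannot measure the angle of a zero-length vector")
  .deg(acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))))
}

## Rodrigues rotation matrix about a (not necessarily unit) axis.
rotationMatrix <- function(axis, angleDeg) {
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("rotation axis must be non-zero")
  u <- axis / n
  th <- .rad(angleDeg)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## Squared cross-distance matrix between row-wise coordinate matrices.
crossDist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

## One frame's coordinates for a set of atom indices, always a matrix.
.frameCoords <- function(coords, idx, f) {
  matrix(coords[idx, , f], ncol = 3L)
}

## Per-frame Euclidean distance between two atoms of a coordinate array
## (atoms x 3 x frames).
.pairDistSeries <- function(coords, i, j) {
  d <- coords[i, , , drop = FALSE] - coords[j, , , drop = FALSE]
  sqrt(colSums(matrix(d, nrow = 3L)^2))
}

## Per-frame angle at `h` of the d-h-a triple, degrees. All args are
## 3 x frames coordinate matrices.
.tripleAngleSeries <- function(d, h, a) {
  v1 <- d - h
  v2 <- a - h
  n1 <- sqrt(colSums(v1^2))
  n2 <- sqrt(colSums(v2^2))
  cosang <- colSums(v1 * v2) / (n1 * n2)
  .deg(acos(pmax(-1, pmin(1, cosang))))
}
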