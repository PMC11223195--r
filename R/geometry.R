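# Helix kink-angle analysis.
#
# The kink metric is the angle between two four-residue C-alpha
# displacement vectors flanking the hinge (defaults: residues 20->24 and
# 32->36 of the receptor chain). Parallel vectors give 0 degrees; note that
# on an ideal helix each four-residue vector is tilted off the helix axis,
# so even a perfectly straight helix reads a nonzero baseline angle.

.kinkCaIndices <- function(atoms, spec) {
  vapply(c(spec@vec1Start, spec@vec1End, spec@vec2Start, spec@vec2End),
         function(r) .atomIndex(atoms, spec@chain, r, "CA"), integer(1))
}

#' Kink angle of one frame
#'
#' Arccos of the normalized dot product of v1 = CA(vec1End) - CA(vec1Start)
#' and v2 = CA(vec2End) - CA(vec2Start), in degrees in [0, 180].
#'
#' @param x an \linkS4class{Assembly}, \linkS4class{TrajectoryWindow} or
#'   nAtoms x 3 coordinate matrix.
#' @param spec a \linkS4class{KinkVectorSpec}.
#' @param frame frame index when `x` is a trajectory.
#' @param atoms atom table, required when `x` is a bare matrix.
#' @return angle in degrees.
#' @export
kinkAngle <- function(x, spec = kinkVectorSpec(), frame = 1L, atoms = NULL) {
  if (is(x, "TrajectoryWindow")) {
    atoms <- x@topology@atoms
    xyz <- x@coords[, , frame]
  } else if (is(x, "Assembly")) {
    atoms <- x@atoms
    xyz <- x@xyz
  } else {
    if (is.null(atoms)) stop("atoms table required for matrix input")
    xyz <- x
  }
  idx <- .kinkCaIndices(atoms, spec)
  vecAngle(xyz[idx[2], ] - xyz[idx[1], ], xyz[idx[4], ] - xyz[idx[3], ])
}

## lower-edge-anchored histogram mode; ties broken toward the lower bin
.binnedMode <- function(angles, binWidth) {
  bins <- floor(angles / binWidth)
  counts <- table(bins)
  best <- as.integer(names(counts)[which.max(counts)])  # first max = lowest
  (best + 0.5) * binWidth
}

#' Per-frame kink-angle series with summary statistics
#'
#' Computes the kink angle of every frame, the arithmetic mean, the
#' standard error of the mean (sd over frames / sqrt(nFrames)) and the
#' center of the most populated histogram bin (bins `[k, k+1) * binWidth`
#' anchored at zero; ties go to the lower bin).
#'
#' @param traj a \linkS4class{TrajectoryWindow} with at least one frame.
#' @param spec a \linkS4class{KinkVectorSpec}.
#' @param binWidth histogram bin width, degrees (default 1).
#' @return a \linkS4class{KinkSeries}.
#' @export
kinkSeries <- function(traj, spec = kinkVectorSpec(), binWidth = 1.0) {
  stopifnot(is(traj, "TrajectoryWindow"))
  nf <- nFrames(traj)
  if (nf < 1L) stop("input error: empty trajectory")
  idx <- .kinkCaIndices(traj@topology@atoms, spec)
  v1 <- matrix(traj@coords[idx[2], , ] - traj@coords[idx[1], , ], nrow = 3L)
  v2 <- matrix(traj@coords[idx[4], , ] - traj@coords[idx[3], , ], nrow = 3L)
  cosang <- colSums(v1 * v2) /
    (sqrt(colSums(v1^2)) * sqrt(colSums(v2^2)))
  ang <- .deg(acos(pmax(-1, pmin(1, cosang))))
  sem <- if (nf > 1L) stats::sd(ang) / sqrt(nf) else 0
  new("KinkSeries", angles = ang, times = traj@times, mean = mean(ang),
      sem = sem, mode = .binnedMode(ang, binWidth), binWidth = binWidth)
}
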