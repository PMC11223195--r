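# Synthetic trajectory generation with scheduled hydrogen-bond ground truth.

#' Frame mask for an occupancy schedule
#'
#' Quota mode selects exactly `round(target * nFrames)` frames, evenly
#' spread with a phase offset, so the realized occupancy equals the target
#' to within 1/nFrames and is independent of the seed. Bernoulli mode draws
#' each frame independently with probability `target` from the seeded RNG
#' stream.
#'
#' @param schedule an \linkS4class{OccupancySchedule}.
#' @param nFrames number of frames.
#' @return logical vector of length `nFrames`.
#' @export
scheduleMask <- function(schedule, nFrames) {
  stopifnot(nFrames >= 1L)
  if (schedule@mode == "quota") {
    k <- round(nFrames * schedule@target)
    mask <- rep(FALSE, nFrames)
    if (k > 0) {
      idx <- floor((seq_len(k) - 1 + schedule@phase) * nFrames / k) + 1L
      mask[pmin(idx, nFrames)] <- TRUE
    }
    mask
  } else {
    stats::runif(nFrames) < schedule@target
  }
}

.scheduleKey <- function(s)
  paste(s@donorResno, s@donorAtom, s@hydrogen, s@acceptorChain,
        s@acceptorResno, s@acceptorAtom, sep = ":")

.checkSchedules <- function(schedules) {
  if (!length(schedules)) return(invisible(NULL))
  keys <- vapply(schedules, .scheduleKey, character(1))
  if (anyDuplicated(keys))
    stop("schedule error: duplicate schedule for ",
         keys[duplicated(keys)][1])
  acc <- vapply(schedules, function(s)
    paste(s@acceptorChain, s@acceptorResno, s@acceptorAtom, sep = ":"),
    character(1))
  if (anyDuplicated(acc))
    stop("schedule error: acceptor atom ", acc[duplicated(acc)][1],
         " is claimed by two schedules")
  invisible(NULL)
}

#' Generate a synthetic trajectory with known ground truth
#'
#' Produces `nFrames` frames from a base assembly: isotropic Gaussian
#' noise (sd `noiseSigma` per coordinate) is added to every atom, then each
#' occupancy schedule is enforced exactly by repositioning its acceptor
#' atom along its hydrogen's direction from the (noisy) donor -- at
#' `bondedDistance` on mask-TRUE frames (collinear donor-hydrogen-acceptor,
#' angle 180 degrees) and `unbondedDistance` on mask-FALSE frames. Scheduled
#' hydrogens are pinned 1 A from the donor along the same direction, so
#' scheduled geometry is exact regardless of noise, and the donor-acceptor
#' and hydrogen-acceptor distance conventions agree on every frame.
#'
#' @param assembly base \linkS4class{Assembly} (or the list returned by
#'   [trimerAssembly()]).
#' @param nFrames number of frames (>= 1).
#' @param noiseSigma per-coordinate thermal noise sd, Angstrom (>= 0).
#' @param schedules list of \linkS4class{OccupancySchedule}; two schedules
#'   naming the same acceptor atom (or duplicated outright) are a schedule
#'   error.
#' @param seed integer seed; the result is reproducible given the seed.
#' @param dt frame spacing, ns.
#' @param chainRoles chain role map for the topology.
#' @param bondedDistance,unbondedDistance enforced donor-acceptor distances
#'   on satisfied / unsatisfied frames.
#' @return a \linkS4class{TrajectoryWindow} whose `groundTruth` records the
#'   seed, noise, kink (if the assembly came from [trimerAssembly()]) and
#'   per-schedule frame masks.
#' @export
generateTrajectory <- function(assembly, nFrames, noiseSigma = 0.15,
                               schedules = list(), seed = 1L, dt = 0.15,
                               chainRoles = c(C = "receptor", A = "adaptorA",
                                              B = "adaptorB"),
                               bondedDistance = 2.8, unbondedDistance = 4.2) {
  kink <- NULL
  if (is.list(assembly) && !is.null(assembly$assembly)) {
    kink <- assembly$kink
    assembly <- assembly$assembly
  }
  stopifnot(is(assembly, "Assembly"), nFrames >= 1, noiseSigma >= 0)
  .checkSchedules(schedules)
  atoms <- assembly@atoms
  nAtoms <- nrow(atoms)

  set.seed(as.integer(seed))
  masks <- lapply(schedules, scheduleMask, nFrames = nFrames)

  coords <- array(rep(t(assembly@xyz), nFrames),
                  dim = c(3L, nAtoms, nFrames))
  if (noiseSigma > 0)
    coords <- coords + array(stats::rnorm(3 * nAtoms * nFrames,
                                          sd = noiseSigma),
                             dim = dim(coords))
  coords <- aperm(coords, c(2L, 1L, 3L))

  for (si in seq_along(schedules)) {
    s <- schedules[[si]]
    receptorChain <- names(chainRoles)[chainRoles == "receptor"]
    di <- .atomIndex(atoms, receptorChain, s@donorResno, s@donorAtom)
    hi <- .atomIndex(atoms, receptorChain, s@donorResno, s@hydrogen)
    ai <- .atomIndex(atoms, s@acceptorChain, s@acceptorResno, s@acceptorAtom)
    u <- assembly@xyz[hi, ] - assembly@xyz[di, ]
    u <- u / sqrt(sum(u^2))
    r <- ifelse(masks[[si]], bondedDistance, unbondedDistance)
    donor <- coords[di, , ]                      # 3 x frames
    coords[hi, , ] <- donor + u                  # 1 A along u
    coords[ai, , ] <- donor + matrix(u, 3, nFrames) *
      matrix(r, 3, nFrames, byrow = TRUE)
  }

  gt <- list(seed = as.integer(seed), noiseSigma = noiseSigma, dt = dt,
             kinkAngle = if (!is.null(kink)) kink@kinkAngle else NULL,
             kinkHinge = if (!is.null(kink)) kink@hingeResidue else NULL,
             schedules = lapply(seq_along(schedules), function(i) {
               s <- schedules[[i]]
               list(label = s@label, pair = s@pair,
                    chain = s@acceptorChain, target = s@target,
                    mode = s@mode, mask = masks[[i]])
             }))
  new("TrajectoryWindow", topology = complexTopology(atoms, chainRoles),
      coords = coords, times = (seq_len(nFrames) - 1) * dt,
      groundTruth = gt)
}

#' Restrict a trajectory to a time window
#'
#' Keeps frames with time at or after `start` and at or before `end`
#' (both inclusive; the first retained frame is the nearest frame at or
#' after the start time).
#'
#' @param traj a \linkS4class{TrajectoryWindow}.
#' @param start,end window bounds, ns.
#' @return the windowed \linkS4class{TrajectoryWindow}.
#' @export
windowFrames <- function(traj, start, end) {
  keep <- which(traj@times >= start & traj@times <= end)
  if (!length(keep))
    stop(sprintf("input error: no frames in window [%g, %g] ns", start, end))
  new("TrajectoryWindow", topology = traj@topology,
      coords = traj@coords[, , keep, drop = FALSE],
      times = traj@times[keep], groundTruth = traj@groundTruth)
}
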