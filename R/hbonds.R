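# Geometric hydrogen-bond and salt-bridge analysis.

## satisfaction series for one donor/hydrogens/acceptor entry.
## dPos: 3 x frames donor, hPos: list of 3 x frames hydrogens, aPos acceptor.
.hbondSeries <- function(dPos, hPos, aPos, criteria) {
  nf <- ncol(dPos)
  anyOk <- rep(FALSE, nf)
  for (h in hPos) {
    ang <- .tripleAngleSeries(dPos, h, aPos)
    dist <- if (criteria@distanceDefinition == "donor_acceptor")
      sqrt(colSums((dPos - aPos)^2)) else sqrt(colSums((h - aPos)^2))
    anyOk <- anyOk | (dist <= criteria@distanceCutoff &
                        ang >= criteria@angleCutoff)
  }
  anyOk
}

.coordSeries <- function(traj, idx) {
  matrix(traj@coords[idx, , ], nrow = 3L)
}

#' Test the hydrogen-bond criteria on one frame
#'
#' TRUE iff the relevant distance (donor-acceptor or hydrogen-acceptor,
#' per the criteria's convention) is at or below the distance cutoff and
#' the donor-hydrogen-acceptor angle is at or above the angle cutoff.
#'
#' @param donor,hydrogen,acceptor coordinate 3-vectors.
#' @param criteria an \linkS4class{HBondCriteria}.
#' @return logical.
#' @export
detectHBond <- function(donor, hydrogen, acceptor,
                        criteria = hBondCriteria()) {
  .hbondSeries(matrix(donor, 3, 1), list(matrix(hydrogen, 3, 1)),
               matrix(acceptor, 3, 1), criteria)
}

.registryEntries <- function(traj, registry) {
  atoms <- traj@topology@atoms
  roles <- traj@topology@chainRoles
  receptorChain <- names(roles)[roles == "receptor"]
  lapply(seq_len(nrow(registry)), function(k) {
    r <- registry[k, ]
    hyd <- strsplit(r$hydrogens, ",")[[1]]
    list(pair = r$pair, label = r$label, chain = r$acceptorChain,
         d = .coordSeries(traj, .atomIndex(atoms, receptorChain,
                                           r$donorResno, r$donorAtom)),
         h = lapply(hyd, function(hh)
           .coordSeries(traj, .atomIndex(atoms, receptorChain,
                                         r$donorResno, hh))),
         a = .coordSeries(traj, .atomIndex(atoms, r$acceptorChain,
                                           r$acceptorResno, r$acceptorAtom)))
  })
}

#' Hydrogen-bond occupancy table for a trajectory
#'
#' For every registry entry, the percentage of frames on which any of the
#' donor's hydrogens satisfies the geometric criteria with the acceptor
#' (hydrogens of one donor atom are interchangeable for occupancy
#' bookkeeping). Also records, per residue pair and chain, the union
#' occupancy -- the percentage of frames with at least one of the pair's
#' bonds present, which corrects the plain per-label sum for co-occurrence.
#'
#' @param traj a \linkS4class{TrajectoryWindow}.
#' @param registry donor/acceptor registry (see [defaultRegistry()]).
#' @param criteria an \linkS4class{HBondCriteria}.
#' @param system system label recorded in the table.
#' @return an \linkS4class{OccupancyTable}.
#' @export
occupancyTable <- function(traj, registry = defaultRegistry(),
                           criteria = hBondCriteria(), system = "system") {
  if (nrow(registry) == 0L) stop("input error: empty registry")
  if (nFrames(traj) < 1L) stop("input error: empty trajectory")
  entries <- .registryEntries(traj, registry)
  sat <- lapply(entries, function(e) .hbondSeries(e$d, e$h, e$a, criteria))
  tab <- data.frame(
    system = system,
    pair = vapply(entries, `[[`, character(1), "pair"),
    label = vapply(entries, `[[`, character(1), "label"),
    chain = vapply(entries, `[[`, character(1), "chain"),
    occupancy = vapply(sat, function(s) 100 * mean(s), numeric(1)),
    stringsAsFactors = FALSE)
  key <- paste(tab$pair, tab$chain)
  uni <- lapply(split(seq_along(sat), key), function(ix)
    Reduce(`|`, sat[ix]))
  pairUnion <- data.frame(
    system = system,
    pair = sub(" .*$", "", names(uni)),
    chain = sub("^.* ", "", names(uni)),
    occupancy = vapply(uni, function(s) 100 * mean(s), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(pairUnion) <- NULL
  new("OccupancyTable", table = tab, pairUnion = pairUnion,
      nFrames = nFrames(traj), criteria = criteria)
}

#' Aggregate occupancy of a residue pair on one chain
#'
#' The plain sum of the pair's per-label occupancies (the reporting
#' convention for aggregate hydrogen-bond probabilities; it can double
#' count frames where bonds co-occur). The co-occurrence-corrected union
#' occupancy is returned alongside when the table was measured from a
#' trajectory, and the result is flagged whenever the raw sum exceeds
#' 100 percent.
#'
#' @param table an \linkS4class{OccupancyTable}.
#' @param pair residue-pair label, e.g. "K26/D16".
#' @param chain adaptor chain id.
#' @param system optional system label to restrict to.
#' @return list with elements `reported` (sum rounded half-up to one
#'   decimal), `raw` (unrounded sum), `union` (co-occurrence-corrected,
#'   NA for reference tables) and `overcounted` (raw > 100).
#' @export
aggregateOccupancy <- function(table, pair, chain, system = NULL) {
  tab <- occupancy(table)
  sel <- tab$pair == pair & tab$chain == chain
  if (!is.null(system)) sel <- sel & tab$system == system
  if (!any(sel))
    stop(sprintf("key error: no occupancy rows for pair %s chain %s%s",
                 pair, chain,
                 if (is.null(system)) "" else paste0(" in system ", system)))
  raw <- sum(tab$occupancy[sel])
  uni <- pairUnionOccupancy(table)
  u <- NA_real_
  if (nrow(uni)) {
    us <- uni$pair == pair & uni$chain == chain
    if (!is.null(system)) us <- us & uni$system == system
    if (any(us)) u <- sum(uni$occupancy[us])
  }
  list(reported = roundHalfUp(raw, 1), raw = raw, union = u,
       overcounted = raw > 100)
}

#' Per-frame distance between two atoms
#'
#' @param traj a \linkS4class{TrajectoryWindow}.
#' @param atomA,atomB lists with elements chain, resno, elety.
#' @return numeric vector of distances (Angstrom), one per frame.
#' @export
distanceTrace <- function(traj, atomA, atomB) {
  atoms <- traj@topology@atoms
  .pairDistSeries(traj@coords,
                  .atomIndex(atoms, atomA$chain, atomA$resno, atomA$elety),
                  .atomIndex(atoms, atomB$chain, atomB$resno, atomB$elety))
}

#' Per-frame hydrogen-bond counts
#'
#' Number of simultaneously satisfied registry entries per frame, plus the
#' per-label satisfaction matrix.
#'
#' @inheritParams occupancyTable
#' @return list with `total` (integer per frame) and `perLabel` (logical
#'   frames x entries matrix, columns named "pair label chain").
#' @export
hbondCountSeries <- function(traj, registry = defaultRegistry(),
                             criteria = hBondCriteria()) {
  if (nFrames(traj) < 1L) stop("input error: empty trajectory")
  entries <- .registryEntries(traj, registry)
  sat <- vapply(entries, function(e) .hbondSeries(e$d, e$h, e$a, criteria),
                logical(nFrames(traj)))
  sat <- matrix(sat, nrow = nFrames(traj))
  colnames(sat) <- vapply(entries, function(e)
    paste(e$pair, e$label, e$chain), character(1))
  list(total = as.integer(rowSums(sat)), perLabel = sat)
}

#' Salt-bridge occupancy between two charged atom groups
#'
#' Percentage of frames on which the minimum distance between the basic
#' and acidic heavy-atom groups is at or below the cutoff (default 4 A,
#' the standard literature criterion for side-chain salt bridges).
#'
#' @param traj a \linkS4class{TrajectoryWindow}.
#' @param basicGroup,acidicGroup data.frames with columns chain, resno,
#'   elety naming the charged-group heavy atoms.
#' @param cutoff distance cutoff, Angstrom.
#' @return occupancy percent in [0, 100].
#' @export
saltBridgeOccupancy <- function(traj, basicGroup, acidicGroup, cutoff = 4.0) {
  atoms <- traj@topology@atoms
  gIdx <- function(g) {
    if (is.null(g) || nrow(g) == 0L)
      stop("selection error: empty charged-atom group")
    vapply(seq_len(nrow(g)), function(k)
      .atomIndex(atoms, g$chain[k], g$resno[k], g$elety[k]), integer(1))
  }
  bi <- gIdx(basicGroup)
  ai <- gIdx(acidicGroup)
  nf <- nFrames(traj)
  hit <- vapply(seq_len(nf), function(f) {
    d2 <- crossDist2(.frameCoords(traj@coords, bi, f),
                     .frameCoords(traj@coords, ai, f))
    min(d2) <= cutoff^2
  }, logical(1))
  100 * mean(hit)
}
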