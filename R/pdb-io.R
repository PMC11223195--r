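# PDB input/output. Single-model structures go through bio3d; the
# multi-model trajectory writer formats standard ATOM/MODEL records itself
# (vectorized), since bio3d writes single models only. Reading always goes
# through bio3d::read.pdb, so everything written here round-trips through an
# independent parser.

## PDB atom-name field: names of 1-3 characters start in column 14.
.pdbAtomName <- function(elety) {
  ifelse(nchar(elety) < 4L, sprintf(" %-3s", elety), sprintf("%-4s", elety))
}

.atomRecords <- function(atoms, xyz) {
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          atoms$eleno, .pdbAtomName(atoms$elety), atoms$resid, atoms$chain,
          atoms$resno, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0)
}

#' Write a single-model PDB file
#'
#' @param x an \linkS4class{Assembly} (or list from [trimerAssembly()]).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeAssemblyPDB <- function(x, file) {
  if (is.list(x) && !is.null(x$assembly)) x <- x$assembly
  writeLines(c(.atomRecords(x@atoms, x@xyz), "END"), file)
  invisible(file)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame; coordinates at the format's 3-decimal
#' precision. Output is byte-deterministic for identical input.
#'
#' @param traj a \linkS4class{TrajectoryWindow}.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeTrajectoryPDB <- function(traj, file) {
  atoms <- traj@topology@atoms
  nf <- nFrames(traj)
  blocks <- vapply(seq_len(nf), function(f) {
    paste(c(sprintf("MODEL     %4d", f),
            .atomRecords(atoms, traj@coords[, , f]),
            "ENDMDL"), collapse = "\n")
  }, character(1))
  writeLines(c(blocks, "END"), file)
  invisible(file)
}

#' Write the generator's ground truth as a JSON sidecar
#'
#' Records seed, noise, frame spacing, programmed kink and the per-schedule
#' frame masks of a synthetic trajectory.
#'
#' @param traj a synthetic \linkS4class{TrajectoryWindow}.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeGroundTruthJSON <- function(traj, file) {
  jsonlite::write_json(traj@groundTruth, file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(file)
}

.bio3dToAtoms <- function(pdb) {
  data.frame(eleno = as.integer(pdb$atom$eleno),
             elety = pdb$atom$elety,
             resid = pdb$atom$resid,
             chain = pdb$atom$chain,
             resno = as.integer(pdb$atom$resno),
             stringsAsFactors = FALSE)
}

#' Read a (possibly multi-model) PDB trajectory
#'
#' @param file multi-model PDB path.
#' @param dt frame spacing, ns (ignored if a sidecar provides it).
#' @param sidecar optional ground-truth JSON written by
#'   [writeGroundTruthJSON()]; restores frame spacing and ground truth.
#' @param chainRoles chain role map.
#' @return a \linkS4class{TrajectoryWindow}.
#' @export
readTrajectoryPDB <- function(file, dt = 1, sidecar = NULL,
                              chainRoles = c(C = "receptor", A = "adaptorA",
                                             B = "adaptorB")) {
  pdb <- bio3d::read.pdb(file, multi = TRUE)
  atoms <- .bio3dToAtoms(pdb)
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  coords <- array(0, dim = c(nrow(atoms), 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  gt <- list()
  if (!is.null(sidecar)) {
    gt <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(gt$dt)) dt <- gt$dt
    if (is.data.frame(gt$schedules)) {
      df <- gt$schedules
      gt$schedules <- lapply(seq_len(nrow(df)), function(i) {
        s <- lapply(df, function(col) col[[i]])
        s$mask <- as.logical(unlist(s$mask))
        s
      })
    }
  }
  new("TrajectoryWindow",
      topology = complexTopology(atoms, chainRoles),
      coords = coords, times = (seq_len(nf) - 1) * dt, groundTruth = gt)
}

#' Read a topology + trajectory pair, optionally windowed
#'
#' The topology file defines the atom table; the trajectory must carry the
#' same number of atoms (a mismatch is a parse error). When a time window
#' is given, frames are restricted to times in [start, end], both ends
#' inclusive, starting at the nearest frame at or after the start time.
#'
#' @param topology single-model PDB path.
#' @param trajectory multi-model PDB path.
#' @param window optional c(start, end) in ns.
#' @param dt frame spacing, ns.
#' @param sidecar optional ground-truth JSON path.
#' @param chainRoles chain role map.
#' @return a \linkS4class{TrajectoryWindow}.
#' @export
readSystem <- function(topology, trajectory, window = NULL, dt = 1,
                       sidecar = NULL,
                       chainRoles = c(C = "receptor", A = "adaptorA",
                                      B = "adaptorB")) {
  topo <- bio3d::read.pdb(topology)
  topoAtoms <- .bio3dToAtoms(topo)
  traj <- readTrajectoryPDB(trajectory, dt = dt, sidecar = sidecar,
                            chainRoles = chainRoles)
  if (nrow(topoAtoms) != nrow(traj@topology@atoms))
    stop(sprintf(
      "parse error: topology has %d atoms but trajectory frames have %d",
      nrow(topoAtoms), nrow(traj@topology@atoms)))
  if (!identical(topoAtoms$elety, traj@topology@atoms$elety))
    stop("parse error: topology and trajectory atom records disagree")
  if (!is.null(window)) traj <- windowFrames(traj, window[1], window[2])
  traj
}
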