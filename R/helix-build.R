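# Synthetic helix and trimer construction.
#
# Coordinates are built in a canonical frame: the helix axis is z, residue i
# (0-based) has its C-alpha at (r cos(i tau), r sin(i tau), i d). Backbone
# N, C and O ride on coaxial helices with fixed cylindrical offsets; their
# exact geometry is idealized (bond lengths approximate) because only the
# C-alpha trace and the named side-chain probe atoms carry analysis-relevant
# geometry.

## cylindrical offsets (radius, delta-phase deg, delta-z) per backbone atom
.backboneOffsets <- list(
  N  = c(1.50, -28, -0.95),
  CA = c(NA, 0, 0),            # radius comes from the HelixSpec
  C  = c(1.70, 24, 0.60),
  O  = c(2.10, 30, 1.55))

## which residue types carry which synthetic side-chain probe atoms
.probeAtoms <- list(
  LYS = c("NZ", "HZ1", "HZ2", "HZ3"),
  ASP = c("OD1", "OD2"),
  THR = c("OG1"),
  TRP = c("NE1", "HE1"))

.probeOwner <- c(NZ = "LYS", HZ1 = "LYS", HZ2 = "LYS", HZ3 = "LYS",
                 OD1 = "ASP", OD2 = "ASP", OG1 = "THR",
                 NE1 = "TRP", HE1 = "TRP")

#' Build an ideal alpha-helix backbone
#'
#' Places C-alpha atoms on a parametric helix (axis = z) and adds backbone
#' N, C and O atoms at idealized cylindrical offsets.
#'
#' @param spec a \linkS4class{HelixSpec}.
#' @param chain chain id for the atom table.
#' @param startResno residue number of the first residue.
#' @return an \linkS4class{Assembly}.
#' @examples
#' helix <- buildIdealHelix(helixSpec(12), chain = "A")
#' @export
buildIdealHelix <- function(spec, chain = "A", startResno = 1L) {
  stopifnot(is(spec, "HelixSpec"))
  validObject(spec)
  n <- spec@nResidues
  tau <- .rad(spec@twist)
  resno <- startResno + seq_len(n) - 1L
  resid <- bio3d::aa123(spec@sequence)

  atoms <- list()
  xyz <- list()
  for (i in seq_len(n)) {
    phase <- (i - 1L) * tau
    z0 <- (i - 1L) * spec@rise
    for (atom in names(.backboneOffsets)) {
      off <- .backboneOffsets[[atom]]
      r <- if (is.na(off[1])) spec@radius else off[1]
      ph <- phase + .rad(off[2])
      atoms[[length(atoms) + 1L]] <-
        data.frame(elety = atom, resid = resid[i], chain = chain,
                   resno = resno[i], stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1L]] <- c(r * cos(ph), r * sin(ph), z0 + off[3])
    }
  }
  atoms <- do.call(rbind, atoms)
  atoms$eleno <- seq_len(nrow(atoms))
  atoms <- atoms[, .atomCols]
  .assembly(atoms, do.call(rbind, xyz))
}

## local frame of a residue in the canonical helix: radial, tangential and
## axial unit vectors at its C-alpha.
.residueFrame <- function(ca) {
  er <- c(ca[1], ca[2], 0)
  if (sqrt(sum(er^2)) < 1e-9) er <- c(1, 0, 0) else er <- er / sqrt(sum(er^2))
  ez <- c(0, 0, 1)
  et <- c(ez[2] * er[3] - ez[3] * er[2],
          ez[3] * er[1] - ez[1] * er[3],
          ez[1] * er[2] - ez[2] * er[1]) # z x er
  list(er = er, et = et, ez = ez)
}

## probe positions for one residue, given its C-alpha and local frame
.probePositions <- function(resid, ca) {
  f <- .residueFrame(ca)
  tet <- sqrt(8) / 3  # tetrahedral: cos(109.47 deg) pairwise
  hz <- function(phi) (1 / 3) * f$er + tet * (cos(.rad(phi)) * f$et +
                                                sin(.rad(phi)) * f$ez)
  switch(resid,
    LYS = {
      nz <- ca + 3.4 * f$er
      list(NZ = nz, HZ1 = nz + hz(0), HZ2 = nz + hz(120), HZ3 = nz + hz(240))
    },
    ASP = {
      d1 <- cos(.rad(25)) * f$er + sin(.rad(25)) * f$et
      d2 <- cos(.rad(25)) * f$er - sin(.rad(25)) * f$et
      list(OD1 = ca + 2.5 * d1, OD2 = ca + 2.5 * d2)
    },
    THR = list(OG1 = ca + 1.9 * f$er),
    TRP = {
      ne1 <- ca + 2.9 * f$er
      list(NE1 = ne1, HE1 = ne1 + 1.0 * f$er)
    },
    stop(sprintf("topology error: no probe atoms defined for residue type %s",
                 resid)))
}

#' Add named side-chain probe atoms to a canonical helix
#'
#' Adds the side-chain donor/acceptor atoms used by the occupancy analysis
#' (NZ/HZ1-3 on lysine, OD1/OD2 on aspartate, OG1 on threonine, NE1/HE1 on
#' tryptophan) at idealized offsets from their parent C-alpha, pointing
#' radially out of the helix. Must be applied before [applyKink()] so probes
#' follow their residue through the bend.
#'
#' @param assembly an \linkS4class{Assembly} in the canonical frame.
#' @param requests optional data.frame with columns chain, resno, elety
#'   naming specific probe atoms; requesting an atom on the wrong residue
#'   type is a topology error. Default (NULL) places all probes supported
#'   by the sequence.
#' @return the augmented \linkS4class{Assembly}, probe atoms appended in
#'   residue order.
#' @export
placeSidechainProbes <- function(assembly, requests = NULL) {
  atoms <- assembly@atoms
  xyz <- assembly@xyz
  resKey <- unique(atoms[, c("chain", "resno", "resid")])

  if (is.null(requests)) {
    want <- do.call(rbind, lapply(seq_len(nrow(resKey)), function(k) {
      probes <- .probeAtoms[[resKey$resid[k]]]
      if (is.null(probes)) return(NULL)
      data.frame(chain = resKey$chain[k], resno = resKey$resno[k],
                 elety = probes, stringsAsFactors = FALSE)
    }))
    if (is.null(want)) return(assembly)
  } else {
    want <- requests
    for (k in seq_len(nrow(want))) {
      owner <- .probeOwner[[want$elety[k]]]
      if (is.null(owner))
        stop(sprintf("topology error: unknown probe atom '%s'", want$elety[k]))
      here <- resKey$resid[resKey$chain == want$chain[k] &
                             resKey$resno == want$resno[k]]
      if (length(here) != 1L)
        stop(sprintf("topology error: residue %s on chain %s not found",
                     want$resno[k], want$chain[k]))
      if (here != owner)
        stop(sprintf(
          "topology error: atom %s belongs to %s but residue %s on chain %s is %s",
          want$elety[k], owner, want$resno[k], want$chain[k], here))
    }
  }

  newAtoms <- list(); newXyz <- list()
  for (k in seq_len(nrow(resKey))) {
    sel <- want$chain == resKey$chain[k] & want$resno == resKey$resno[k]
    if (!any(sel)) next
    ca <- xyz[.atomIndex(atoms, resKey$chain[k], resKey$resno[k], "CA"), ]
    pos <- .probePositions(resKey$resid[k], ca)
    for (atom in want$elety[sel]) {
      if (is.null(pos[[atom]]))
        stop(sprintf("topology error: atom %s not available on %s",
                     atom, resKey$resid[k]))
      newAtoms[[length(newAtoms) + 1L]] <-
        data.frame(elety = atom, resid = resKey$resid[k],
                   chain = resKey$chain[k], resno = resKey$resno[k],
                   stringsAsFactors = FALSE)
      newXyz[[length(newXyz) + 1L]] <- pos[[atom]]
    }
  }
  atoms2 <- rbind(atoms[, c("elety", "resid", "chain", "resno")],
                  do.call(rbind, newAtoms))
  xyz2 <- rbind(xyz, do.call(rbind, newXyz))
  ## keep atoms grouped by chain/residue, backbone before side chain
  ord <- order(atoms2$chain, atoms2$resno,
               seq_len(nrow(atoms2)))
  atoms2 <- atoms2[ord, ]
  xyz2 <- xyz2[ord, , drop = FALSE]
  atoms2$eleno <- seq_len(nrow(atoms2))
  .assembly(atoms2[, .atomCols], xyz2)
}

#' Bend a canonical helix at a hinge residue
#'
#' Rotates every atom of every residue beyond the hinge rigidly by the kink
#' angle about an axis through the hinge C-alpha, perpendicular to the
#' canonical helix axis (z) at the given azimuth. Residues at and before
#' the hinge are untouched; intra-segment distances are preserved exactly.
#'
#' @param assembly an \linkS4class{Assembly} in the canonical frame.
#' @param kink a \linkS4class{KinkSpec}; the hinge must not lie within the
#'   first or last four residues of the chain.
#' @param chain chain to bend; defaults to the assembly's only chain.
#' @return the bent \linkS4class{Assembly}.
#' @export
applyKink <- function(assembly, kink, chain = NULL) {
  stopifnot(is(kink, "KinkSpec"))
  validObject(kink)
  atoms <- assembly@atoms
  if (is.null(chain)) {
    chain <- unique(atoms$chain)
    if (length(chain) != 1L)
      stop("assembly has several chains; name the one to bend")
  }
  resnos <- sort(unique(atoms$resno[atoms$chain == chain]))
  pos <- match(kink@hingeResidue, resnos)
  if (is.na(pos))
    stop(sprintf("parameter error: hinge residue %d not on chain %s",
                 kink@hingeResidue, chain))
  if (pos <= 4L || pos > length(resnos) - 4L)
    stop(sprintf(
      "parameter error: hinge residue %d lies within four residues of a helix end",
      kink@hingeResidue))
  if (kink@kinkAngle == 0) return(assembly)

  centre <- assembly@xyz[.atomIndex(atoms, chain, kink@hingeResidue, "CA"), ]
  axis <- c(cos(.rad(kink@azimuth)), sin(.rad(kink@azimuth)), 0)
  R <- rotationMatrix(axis, kink@kinkAngle)
  move <- atoms$chain == chain & atoms$resno > kink@hingeResidue
  xyz <- assembly@xyz
  shifted <- sweep(xyz[move, , drop = FALSE], 2, centre)
  xyz[move, ] <- shifted %*% t(R) + matrix(centre, sum(move), 3, byrow = TRUE)
  .assembly(atoms, xyz)
}

#' Set the distance between two atoms
#'
#' Translates atom `b` along the a-to-b line so the pair distance equals
#' `distance`; used to orient a donor/acceptor pair at a stated separation.
#'
#' @param assembly an \linkS4class{Assembly}.
#' @param a,b lists with elements chain, resno, elety.
#' @param distance target distance, Angstrom.
#' @return the modified \linkS4class{Assembly}.
#' @export
setAtomPairDistance <- function(assembly, a, b, distance) {
  ia <- .atomIndex(assembly@atoms, a$chain, a$resno, a$elety)
  ib <- .atomIndex(assembly@atoms, b$chain, b$resno, b$elety)
  u <- assembly@xyz[ib, ] - assembly@xyz[ia, ]
  n <- sqrt(sum(u^2))
  if (n < 1e-9) stop("atoms coincide; direction undefined")
  xyz <- assembly@xyz
  xyz[ib, ] <- xyz[ia, ] + (distance / n) * u
  .assembly(assembly@atoms, xyz)
}

## translate all atoms of a chain
.translateChain <- function(assembly, chain, shift) {
  sel <- assembly@atoms$chain == chain
  xyz <- assembly@xyz
  xyz[sel, ] <- sweep(xyz[sel, , drop = FALSE], 2, -shift)
  .assembly(assembly@atoms, xyz)
}

.combineAssemblies <- function(...) {
  parts <- list(...)
  atoms <- do.call(rbind, lapply(parts, function(p) p@atoms))
  xyz <- do.call(rbind, lapply(parts, function(p) p@xyz))
  ord <- order(atoms$chain, atoms$resno, seq_len(nrow(atoms)))
  atoms <- atoms[ord, ]
  xyz <- xyz[ord, , drop = FALSE]
  atoms$eleno <- seq_len(nrow(atoms))
  .assembly(atoms, xyz)
}

#' Default receptor (TREM2-like) helix specification
#'
#' Thirty residues numbered 14-43: poly-alanine with the interface residues
#' L19, L24, K26 and W34 substituted (A20, A32 and A36 are alanine already).
#'
#' @return a \linkS4class{HelixSpec}.
#' @export
receptorHelixSpec <- function() {
  seq1 <- rep("A", 30)
  names(seq1) <- 14:43
  seq1[c("19", "24")] <- "L"
  seq1["26"] <- "K"
  seq1["34"] <- "W"
  helixSpec(30, sequence = unname(seq1))
}

#' Default adaptor (DAP12-like) helix specification
#'
#' Twenty-eight residues numbered 6-33: poly-alanine with the DxxxT-motif
#' and interface residues I12, D16, T20 and I23 substituted.
#'
#' @return a \linkS4class{HelixSpec}.
#' @export
adaptorHelixSpec <- function() {
  seq1 <- rep("A", 28)
  names(seq1) <- 6:33
  seq1[c("12", "23")] <- "I"
  seq1["16"] <- "D"
  seq1["20"] <- "T"
  helixSpec(28, sequence = unname(seq1))
}

## Programmed bend of the kinked reference system. The four-point kink
## reading of an ideal helix differs from the segment-axis bend by a
## geometric offset (the four-residue C-alpha vectors are tilted off the
## local axis); at bend azimuth 135 this segment-axis bend gives a
## four-point reading of 101 degrees, the kinked system's modal value.
.kinkedSystemBend <- 100.87
.kinkedSystemAzimuth <- 135

#' Build a three-chain receptor/adaptor helix bundle
#'
#' Assembles one receptor helix (chain C, at the origin) and two adaptor
#' helices (chain A at +x, chain B at -x) with side-chain probe atoms
#' placed, optionally bending the receptor at K26. In the kinked
#' configuration the bundle packs the receptor against adaptor A only
#' (adaptor B sits beyond contact range), emulating the one-sided interface
#' of a kinked receptor; unkinked bundles are symmetric.
#'
#' @param kink a \linkS4class{KinkSpec} for the receptor, NULL for a
#'   straight receptor, or TRUE for the default kinked configuration
#'   (hinge K26, segment bend 100.87 degrees at azimuth 135 -- the bend
#'   whose four-point reading is ~101 degrees, tilting the upper segment
#'   partly toward adaptor A and away from adaptor B).
#' @param separationA,separationB axis-to-axis distances (Angstrom) from
#'   the receptor to adaptors A and B. Defaults: 9.5/9.5 for straight
#'   bundles, 9.5/20 when a kink is given.
#' @param receptorSpec,adaptorSpec helix specifications.
#' @return a list with elements `assembly` (\linkS4class{Assembly}),
#'   `topology` (\linkS4class{ComplexTopology}) and `kink` (the
#'   \linkS4class{KinkSpec} used, or NULL).
#' @export
trimerAssembly <- function(kink = NULL, separationA = 9.5,
                           separationB = if (is.null(kink)) 9.5 else 20,
                           receptorSpec = receptorHelixSpec(),
                           adaptorSpec = adaptorHelixSpec()) {
  if (isTRUE(kink)) kink <- kinkSpec(26, .kinkedSystemBend,
                                     azimuth = .kinkedSystemAzimuth)
  receptor <- placeSidechainProbes(
    buildIdealHelix(receptorSpec, chain = "C", startResno = 14L))
  if (!is.null(kink)) receptor <- applyKink(receptor, kink, chain = "C")
  adA <- placeSidechainProbes(
    buildIdealHelix(adaptorSpec, chain = "A", startResno = 6L))
  adB <- placeSidechainProbes(
    buildIdealHelix(adaptorSpec, chain = "B", startResno = 6L))
  adA <- .translateChain(adA, "A", c(separationA, 0, 0))
  adB <- .translateChain(adB, "B", c(-separationB, 0, 0))
  assembly <- .combineAssemblies(receptor, adA, adB)
  list(assembly = assembly, topology = complexTopology(assembly),
       kink = kink)
}
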