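#' @import methods
NULL

.atomCols <- c("eleno", "elety", "resid", "chain", "resno")

.checkAtomTable <- function(atoms) {
  if (!is.data.frame(atoms)) return("atoms must be a data.frame")
  miss <- setdiff(.atomCols, names(atoms))
  if (length(miss))
    return(paste0("atoms is missing column(s): ", paste(miss, collapse = ", ")))
  NULL
}

# ---------------------------------------------------------------------------
# Synthetic-generator parameter classes
# ---------------------------------------------------------------------------

#' Ideal helix parameterization
#'
#' Geometry of an ideal alpha-helix: C-alpha atoms lie on a circular helix
#' of given radius, axial rise and twist per residue. Defaults are textbook
#' alpha-helix values (1.5 A rise, 2.3 A C-alpha radius, 100 degrees per
#' residue).
#'
#' @slot nResidues number of residues (>= 5; a four-residue kink vector
#'   needs room on either side of a hinge).
#' @slot rise axial rise per residue, Angstrom.
#' @slot radius C-alpha helix radius, Angstrom.
#' @slot twist twist per residue, degrees in (0, 360).
#' @slot sequence one-letter residue codes, one per residue.
#' @exportClass HelixSpec
setClass("HelixSpec",
  representation(nResidues = "integer", rise = "numeric", radius = "numeric",
                 twist = "numeric", sequence = "character"),
  validity = function(object) {
    errs <- character()
    if (object@nResidues < 5L)
      errs <- c(errs, "nResidues must be >= 5")
    if (object@rise <= 0) errs <- c(errs, "rise must be > 0")
    if (object@radius < 0) errs <- c(errs, "radius must be >= 0")
    if (object@twist <= 0 || object@twist >= 360)
      errs <- c(errs, "twist must lie strictly between 0 and 360 degrees")
    if (length(object@sequence) != object@nResidues)
      errs <- c(errs, "sequence length must equal nResidues")
    if (length(errs)) errs else TRUE
  })

#' @param nResidues,rise,radius,twist,sequence see slots of
#'   \linkS4class{HelixSpec}. `sequence` may be a single string or a
#'   character vector of one-letter codes; default is poly-alanine.
#' @return a `HelixSpec`.
#' @rdname HelixSpec-class
#' @export
helixSpec <- function(nResidues, rise = 1.5, radius = 2.3, twist = 100,
                      sequence = NULL) {
  if (is.null(sequence)) sequence <- rep("A", nResidues)
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  new("HelixSpec", nResidues = as.integer(nResidues), rise = rise,
      radius = radius, twist = twist, sequence = sequence)
}

#' Programmed helix kink
#'
#' A rigid bend applied to an ideal helix: all residues beyond the hinge are
#' rotated by `kinkAngle` about an axis through the hinge C-alpha,
#' perpendicular to the helix axis, at the given azimuth around it.
#'
#' @slot hingeResidue residue number (in the helix's own numbering) of the
#'   hinge; must not be within the first or last four residues.
#' @slot kinkAngle bend angle, degrees in [0, 180].
#' @slot azimuth orientation of the bend plane, degrees. Azimuth 90 bends
#'   the canonical (z-axis) helix toward +x.
#' @exportClass KinkSpec
setClass("KinkSpec",
  representation(hingeResidue = "integer", kinkAngle = "numeric",
                 azimuth = "numeric"),
  validity = function(object) {
    if (object@kinkAngle < 0 || object@kinkAngle > 180)
      "kinkAngle must lie in [0, 180] degrees" else TRUE
  })

#' @param hingeResidue,kinkAngle,azimuth see slots.
#' @return a `KinkSpec`.
#' @rdname KinkSpec-class
#' @export
kinkSpec <- function(hingeResidue, kinkAngle, azimuth = 90) {
  new("KinkSpec", hingeResidue = as.integer(hingeResidue),
      kinkAngle = kinkAngle, azimuth = azimuth)
}

#' Per-frame hydrogen-bond occupancy schedule
#'
#' Ground-truth schedule for one donor-hydrogen-acceptor triple in a
#' synthetic trajectory. On frames where the mask is TRUE the trajectory
#' generator enforces donor-acceptor distance 2.8 A with a collinear
#' hydrogen (D-H-A = 180 degrees); on FALSE frames the acceptor sits at
#' 4.2 A, violating both the donor-acceptor and hydrogen-acceptor distance
#' conventions.
#'
#' @slot label short label, e.g. "NZ-OD1".
#' @slot pair residue-pair label, e.g. "K26/D16".
#' @slot donorResno,donorAtom donor residue number and heavy-atom name on
#'   the receptor chain.
#' @slot hydrogen name of the donor hydrogen this schedule owns.
#' @slot acceptorChain,acceptorResno,acceptorAtom acceptor atom address.
#' @slot target target occupancy fraction in [0, 1].
#' @slot mode "quota" (deterministic count round(target * nFrames), evenly
#'   spread) or "bernoulli" (independent per-frame draws).
#' @slot phase quota placement phase in [0, 1); staggering phases of
#'   schedules sharing a residue pair keeps their masks nearly disjoint,
#'   mimicking a bond that alternates between acceptor atoms.
#' @exportClass OccupancySchedule
setClass("OccupancySchedule",
  representation(label = "character", pair = "character",
                 donorResno = "integer", donorAtom = "character",
                 hydrogen = "character", acceptorChain = "character",
                 acceptorResno = "integer", acceptorAtom = "character",
                 target = "numeric", mode = "character", phase = "numeric"),
  validity = function(object) {
    errs <- character()
    if (object@target < 0 || object@target > 1)
      errs <- c(errs, "target occupancy must lie in [0, 1]")
    if (!object@mode %in% c("quota", "bernoulli"))
      errs <- c(errs, "mode must be 'quota' or 'bernoulli'")
    if (object@phase < 0 || object@phase >= 1)
      errs <- c(errs, "phase must lie in [0, 1)")
    if (length(errs)) errs else TRUE
  })

#' @param label,pair,donorResno,donorAtom,hydrogen,acceptorChain,acceptorResno,acceptorAtom,target,mode,phase
#'   see slots.
#' @return an `OccupancySchedule`.
#' @rdname OccupancySchedule-class
#' @export
occupancySchedule <- function(label, pair, donorResno, donorAtom, hydrogen,
                              acceptorChain, acceptorResno, acceptorAtom,
                              target, mode = "quota", phase = 0) {
  new("OccupancySchedule", label = label, pair = pair,
      donorResno = as.integer(donorResno), donorAtom = donorAtom,
      hydrogen = hydrogen, acceptorChain = acceptorChain,
      acceptorResno = as.integer(acceptorResno), acceptorAtom = acceptorAtom,
      target = target, mode = mode, phase = phase)
}

# ---------------------------------------------------------------------------
# Structural containers
# ---------------------------------------------------------------------------

#' Single-model structure (atom table + coordinates)
#'
#' @slot atoms data.frame with columns eleno, elety, resid (3-letter
#'   residue name), chain, resno.
#' @slot xyz numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @exportClass Assembly
setClass("Assembly",
  representation(atoms = "data.frame", xyz = "matrix"),
  validity = function(object) {
    err <- .checkAtomTable(object@atoms)
    if (!is.null(err)) return(err)
    if (nrow(object@xyz) != nrow(object@atoms) || ncol(object@xyz) != 3L)
      return("xyz must be an nAtoms x 3 matrix")
    TRUE
  })

.assembly <- function(atoms, xyz) {
  rownames(xyz) <- NULL
  rownames(atoms) <- NULL
  new("Assembly", atoms = atoms, xyz = xyz)
}

#' Chain/residue role assignments for a receptor-adaptor trimer
#'
#' Atom table plus the mapping of PDB chain ids onto biological roles:
#' exactly one receptor (TREM2-like) chain and two adaptor (DAP12-like)
#' chains.
#'
#' @slot atoms atom table (see \linkS4class{Assembly}).
#' @slot chainRoles named character; names are chain ids, values are
#'   "receptor", "adaptorA" or "adaptorB".
#' @exportClass ComplexTopology
setClass("ComplexTopology",
  representation(atoms = "data.frame", chainRoles = "character"),
  validity = function(object) {
    err <- .checkAtomTable(object@atoms)
    if (!is.null(err)) return(err)
    roles <- object@chainRoles
    if (sum(roles == "receptor") != 1L)
      return("chainRoles must assign exactly one receptor chain")
    if (sum(roles %in% c("adaptorA", "adaptorB")) != 2L ||
        !all(c("adaptorA", "adaptorB") %in% roles))
      return("chainRoles must assign exactly two adaptor chains (adaptorA, adaptorB)")
    if (!all(names(roles) %in% unique(object@atoms$chain)))
      return("chainRoles names must be chain ids present in the atom table")
    TRUE
  })

#' @param x an \linkS4class{Assembly} or atom data.frame.
#' @param chainRoles named character mapping chain ids to roles; default
#'   assigns chain C as receptor and chains A/B as adaptors.
#' @return a `ComplexTopology`.
#' @rdname ComplexTopology-class
#' @export
complexTopology <- function(x, chainRoles = c(C = "receptor", A = "adaptorA",
                                              B = "adaptorB")) {
  atoms <- if (is(x, "Assembly")) x@atoms else x
  new("ComplexTopology", atoms = atoms, chainRoles = chainRoles)
}

#' An ordered set of trajectory frames over a topology
#'
#' @slot topology a \linkS4class{ComplexTopology}.
#' @slot coords numeric array, nAtoms x 3 x nFrames.
#' @slot times frame times, ns.
#' @slot groundTruth list recording generator ground truth (kink angle,
#'   schedule masks, seed) when the trajectory is synthetic; empty for
#'   trajectories read from files without a sidecar.
#' @exportClass TrajectoryWindow
setClass("TrajectoryWindow",
  representation(topology = "ComplexTopology", coords = "array",
                 times = "numeric", groundTruth = "list"),
  validity = function(object) {
    d <- dim(object@coords)
    if (length(d) != 3L || d[2] != 3L)
      return("coords must be an nAtoms x 3 x nFrames array")
    if (d[1] != nrow(object@topology@atoms))
      return("coords atom dimension disagrees with the topology atom table")
    if (d[3] < 1L) return("a trajectory needs at least one frame")
    if (length(object@times) != d[3])
      return("times must have one entry per frame")
    TRUE
  })

# ---------------------------------------------------------------------------
# Analysis result containers
# ---------------------------------------------------------------------------

#' Kink-vector residue selection
#'
#' The two four-residue C-alpha displacement vectors whose angle defines
#' the helix kink. Defaults are the receptor-helix residues A20-L24 (first
#' vector) and A32-A36 (second vector).
#'
#' @slot chain chain id carrying the vectors.
#' @slot vec1Start,vec1End,vec2Start,vec2End residue numbers.
#' @exportClass KinkVectorSpec
setClass("KinkVectorSpec",
  representation(chain = "character", vec1Start = "integer",
                 vec1End = "integer", vec2Start = "integer",
                 vec2End = "integer"),
  validity = function(object) {
    if (object@vec1Start == object@vec1End ||
        object@vec2Start == object@vec2End)
      "each kink vector needs two distinct residues" else TRUE
  })

#' @param chain,vec1Start,vec1End,vec2Start,vec2End see slots.
#' @return a `KinkVectorSpec`.
#' @rdname KinkVectorSpec-class
#' @export
kinkVectorSpec <- function(chain = "C", vec1Start = 20, vec1End = 24,
                           vec2Start = 32, vec2End = 36) {
  new("KinkVectorSpec", chain = chain, vec1Start = as.integer(vec1Start),
      vec1End = as.integer(vec1End), vec2Start = as.integer(vec2Start),
      vec2End = as.integer(vec2End))
}

#' Per-frame kink angle series with summary statistics
#'
#' @slot angles per-frame kink angle, degrees in [0, 180].
#' @slot times frame times, ns.
#' @slot mean arithmetic mean of the angles.
#' @slot sem standard error of the mean (sd / sqrt(nFrames)).
#' @slot mode center of the most populated histogram bin (ties broken
#'   toward the lower bin).
#' @slot binWidth histogram bin width, degrees.
#' @exportClass KinkSeries
setClass("KinkSeries",
  representation(angles = "numeric", times = "numeric", mean = "numeric",
                 sem = "numeric", mode = "numeric", binWidth = "numeric"),
  validity = function(object) {
    if (any(object@angles < 0 | object@angles > 180))
      return("kink angles must lie in [0, 180] degrees")
    if (abs(object@mean - mean(object@angles)) > 1e-9)
      return("mean slot disagrees with the angle series")
    TRUE
  })

#' Residue-pair contact persistence between two chains
#'
#' @slot persistence matrix of contact persistence fractions in [0, 1];
#'   rows are residues of the first chain, columns of the second, dimnames
#'   carry residue numbers.
#' @slot chainPair the two chain ids.
#' @slot level "c_alpha" or "all_atom".
#' @slot cutoff contact distance cutoff, Angstrom.
#' @slot window first and last frame index used (inclusive).
#' @slot nFrames number of frames in the window.
#' @exportClass ContactMap
setClass("ContactMap",
  representation(persistence = "matrix", chainPair = "character",
                 level = "character", cutoff = "numeric",
                 window = "integer", nFrames = "integer"),
  validity = function(object) {
    if (any(object@persistence < 0 | object@persistence > 1))
      return("persistence values must lie in [0, 1]")
    if (!object@level %in% c("c_alpha", "all_atom"))
      return("level must be 'c_alpha' or 'all_atom'")
    if (object@cutoff <= 0) return("cutoff must be > 0")
    TRUE
  })

#' Consensus contacts across several persistent maps
#'
#' Per residue pair, the number of contact maps (out of the six
#' system-by-adaptor-chain maps in the full design) in which the pair
#' survived the persistence filter, and the retained flag (count >=
#' threshold).
#'
#' @slot counts integer matrix of presence counts.
#' @slot retained logical matrix, counts >= threshold.
#' @slot threshold retention threshold (default 3 of 6).
#' @slot nMaps number of maps merged.
#' @slot mapKeys labels of the merged maps.
#' @exportClass ConsensusContactSet
setClass("ConsensusContactSet",
  representation(counts = "matrix", retained = "matrix",
                 threshold = "integer", nMaps = "integer",
                 mapKeys = "character"),
  validity = function(object) {
    if (any(object@counts < 0 | object@counts > object@nMaps))
      return("counts must lie in 0..nMaps")
    if (!identical(dim(object@counts), dim(object@retained)))
      return("counts and retained must have identical dimensions")
    if (!all(object@retained == (object@counts >= object@threshold)))
      return("retained must equal counts >= threshold")
    TRUE
  })

#' Geometric hydrogen-bond criteria
#'
#' @slot distanceCutoff distance cutoff, Angstrom (default 3.0).
#' @slot angleCutoff donor-hydrogen-acceptor angle cutoff, degrees
#'   (default 150).
#' @slot distanceDefinition which distance the cutoff applies to:
#'   "donor_acceptor" (default) or "hydrogen_acceptor".
#' @exportClass HBondCriteria
setClass("HBondCriteria",
  representation(distanceCutoff = "numeric", angleCutoff = "numeric",
                 distanceDefinition = "character"),
  validity = function(object) {
    errs <- character()
    if (object@distanceCutoff <= 0)
      errs <- c(errs, "distanceCutoff must be > 0")
    if (object@angleCutoff <= 0 || object@angleCutoff > 180)
      errs <- c(errs, "angleCutoff must lie in (0, 180]")
    if (!object@distanceDefinition %in% c("donor_acceptor", "hydrogen_acceptor"))
      errs <- c(errs, "distanceDefinition must be 'donor_acceptor' or 'hydrogen_acceptor'")
    if (length(errs)) errs else TRUE
  })

#' @param distanceCutoff,angleCutoff,distanceDefinition see slots.
#' @return an `HBondCriteria`.
#' @rdname HBondCriteria-class
#' @export
hBondCriteria <- function(distanceCutoff = 3.0, angleCutoff = 150,
                          distanceDefinition = "donor_acceptor") {
  new("HBondCriteria", distanceCutoff = distanceCutoff,
      angleCutoff = angleCutoff, distanceDefinition = distanceDefinition)
}

#' Hydrogen-bond occupancy table
#'
#' One row per (system, residue pair, donor-acceptor label, chain), giving
#' the percentage of frames on which the bond satisfied the geometric
#' criteria.
#'
#' @slot table data.frame with columns system, pair, label, chain,
#'   occupancy (percent in [0, 100]).
#' @slot pairUnion data.frame with columns system, pair, chain, occupancy:
#'   the co-occurrence-corrected union occupancy (percent of frames with at
#'   least one of the pair's bonds present). Empty when the table was built
#'   from published values rather than a trajectory.
#' @slot nFrames frames analysed (NA for reference tables).
#' @slot criteria the \linkS4class{HBondCriteria} used (or defaults for
#'   reference tables).
#' @exportClass OccupancyTable
setClass("OccupancyTable",
  representation(table = "data.frame", pairUnion = "data.frame",
                 nFrames = "integer", criteria = "HBondCriteria"),
  validity = function(object) {
    need <- c("system", "pair", "label", "chain", "occupancy")
    if (!all(need %in% names(object@table)))
      return("table must have columns system, pair, label, chain, occupancy")
    occ <- object@table$occupancy
    if (any(occ < 0 | occ > 100))
      return("occupancies must lie in [0, 100] percent")
    TRUE
  })

# ---------------------------------------------------------------------------
# Pipeline containers
# ---------------------------------------------------------------------------

#' Full analysis configuration
#'
#' Systems (topology/trajectory files and time windows) plus every analysis
#' parameter. All defaults are the standard values of the analysis: 11 A
#' C-alpha cutoff, 3 A all-atom and hydrogen-bond cutoff, 150 degree angle
#' cutoff, 0.5 persistence threshold, consensus threshold 3.
#'
#' @slot systems list of lists with elements name, topology, trajectory,
#'   dt (ns per frame), and optional window (c(start, end), ns) applied to
#'   the C-alpha maps.
#' @slot chainRoles chain role map (see \linkS4class{ComplexTopology}).
#' @slot kinkVectors a \linkS4class{KinkVectorSpec}.
#' @slot caCutoff,aaCutoff contact cutoffs, Angstrom.
#' @slot persistenceThreshold strict persistence threshold in [0, 1).
#' @slot consensusThreshold minimum presence count for consensus retention.
#' @slot criteria \linkS4class{HBondCriteria}.
#' @slot registry donor/acceptor registry data.frame (see
#'   [defaultRegistry()]).
#' @slot binWidth kink histogram bin width, degrees.
#' @slot outDir output directory ("" to skip writing files).
#' @slot seed integer seed recorded in provenance.
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
  representation(systems = "list", chainRoles = "character",
                 kinkVectors = "KinkVectorSpec", caCutoff = "numeric",
                 aaCutoff = "numeric", persistenceThreshold = "numeric",
                 consensusThreshold = "integer", criteria = "HBondCriteria",
                 registry = "data.frame", binWidth = "numeric",
                 outDir = "character", seed = "integer"),
  validity = function(object) {
    errs <- character()
    if (length(object@systems) < 1L)
      errs <- c(errs, "at least one system is required")
    bad <- vapply(object@systems, function(s)
      !all(c("name", "topology", "trajectory") %in% names(s)), logical(1))
    if (any(bad))
      errs <- c(errs, "each system needs name, topology and trajectory entries")
    if (object@persistenceThreshold < 0 || object@persistenceThreshold >= 1)
      errs <- c(errs, "persistenceThreshold must lie in [0, 1)")
    if (object@caCutoff <= 0 || object@aaCutoff <= 0)
      errs <- c(errs, "contact cutoffs must be > 0")
    if (length(errs)) errs else TRUE
  })

#' Results of a full pipeline run
#'
#' @slot kink named list of \linkS4class{KinkSeries}, one per system.
#' @slot caMaps,aaMaps named lists of \linkS4class{ContactMap} (keys
#'   "system|chain").
#' @slot filteredMaps persistence-filtered all-atom maps (same keys).
#' @slot consensus a \linkS4class{ConsensusContactSet} or NULL if fewer
#'   than three systems were configured.
#' @slot classification data.frame of interaction classes for retained
#'   consensus pairs.
#' @slot occupancy an \linkS4class{OccupancyTable} pooling all systems.
#' @slot hbondCounts named list of per-frame hydrogen-bond count series.
#' @slot files character vector of files written.
#' @slot provenance list: config hash, seed, package version, timestampless
#'   run parameters sufficient to reproduce the run.
#' @exportClass RunReport
setClass("RunReport",
  representation(kink = "list", caMaps = "list", aaMaps = "list",
                 filteredMaps = "list", consensus = "ANY",
                 classification = "data.frame", occupancy = "OccupancyTable",
                 hbondCounts = "list", files = "character",
                 provenance = "list"))
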