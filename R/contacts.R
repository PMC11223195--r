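# Residue-residue contact maps, persistence filtering, consensus merging
# and interaction-type classification.

.hydrophobicSet <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")
.basicSet <- c("LYS", "ARG", "HIS")
.acidicSet <- c("ASP", "GLU")

## indicator matrix residues x atoms for grouping atom-level contacts
.residueIndicator <- function(resno, levels) {
  m <- matrix(0, length(levels), length(resno))
  m[cbind(match(resno, levels), seq_along(resno))] <- 1
  m
}

#' Residue-pair contact map between two chains
#'
#' A residue pair is in contact in a frame iff the minimum distance between
#' the selected atom sets is at or below the cutoff (inclusive);
#' persistence is the fraction of frames in contact. At level "c_alpha"
#' the selected atoms are the C-alphas (default cutoff 11 A); at
#' "all_atom" every atom of the residue, hydrogens included unless
#' `heavyOnly` (default cutoff 3 A).
#'
#' @param traj a \linkS4class{TrajectoryWindow}.
#' @param chainPair the two chain ids, first is the map's rows.
#' @param level "c_alpha" or "all_atom".
#' @param cutoff contact cutoff, Angstrom; default 11 (c_alpha) or 3
#'   (all_atom).
#' @param window optional c(first, last) frame indices (inclusive).
#' @param heavyOnly drop hydrogens at all_atom level.
#' @return a \linkS4class{ContactMap}.
#' @export
contactMap <- function(traj, chainPair = c("C", "A"),
                       level = c("c_alpha", "all_atom"), cutoff = NULL,
                       window = NULL, heavyOnly = FALSE) {
  level <- match.arg(level)
  if (is.null(cutoff)) cutoff <- if (level == "c_alpha") 11 else 3
  stopifnot(cutoff > 0)
  if (chainPair[1] == chainPair[2])
    stop("chains of a contact map must be disjoint")
  atoms <- traj@topology@atoms
  pick <- function(ch) {
    idx <- .selectAtoms(atoms, chain = ch,
                        elety = if (level == "c_alpha") "CA" else NULL)
    if (heavyOnly && level == "all_atom")
      idx <- idx[!grepl("^H", atoms$elety[idx])]
    if (!length(idx))
      stop(sprintf("selection error: no atoms selected on chain %s", ch))
    idx
  }
  i1 <- pick(chainPair[1])
  i2 <- pick(chainPair[2])
  res1 <- sort(unique(atoms$resno[i1]))
  res2 <- sort(unique(atoms$resno[i2]))
  g1 <- .residueIndicator(atoms$resno[i1], res1)
  g2 <- .residueIndicator(atoms$resno[i2], res2)

  frames <- if (is.null(window)) seq_len(nFrames(traj))
            else seq.int(window[1], window[2])
  acc <- matrix(0, length(res1), length(res2))
  cut2 <- cutoff^2
  for (f in frames) {
    d2 <- crossDist2(.frameCoords(traj@coords, i1, f),
                     .frameCoords(traj@coords, i2, f))
    hit <- (g1 %*% (d2 <= cut2) %*% t(g2)) > 0
    acc <- acc + hit
  }
  pers <- acc / length(frames)
  dimnames(pers) <- list(res1, res2)
  new("ContactMap", persistence = pers, chainPair = chainPair,
      level = level, cutoff = cutoff,
      window = as.integer(c(min(frames), max(frames))),
      nFrames = length(frames))
}

#' Zero out non-persistent contacts
#'
#' Retains residue pairs whose persistence is strictly greater than the
#' threshold (">50% of the simulation time" at the default 0.5); all other
#' pairs are zeroed.
#'
#' @param map a \linkS4class{ContactMap}.
#' @param threshold persistence threshold in [0, 1).
#' @return the filtered \linkS4class{ContactMap}.
#' @export
persistenceFilter <- function(map, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold < 1)
  pers <- map@persistence
  pers[pers <= threshold] <- 0
  new("ContactMap", persistence = pers, chainPair = map@chainPair,
      level = map@level, cutoff = map@cutoff, window = map@window,
      nFrames = map@nFrames)
}

#' Merge persistent contact maps into a consensus set
#'
#' Counts, per residue pair, in how many of the given persistence-filtered
#' maps the pair survives (persistence > 0 after filtering); pairs with
#' count >= threshold are retained. In the full design the input is the six
#' (system x adaptor chain) all-atom maps and the threshold is 3.
#'
#' @param maps named list of filtered \linkS4class{ContactMap}s; all must
#'   share residue numbering on both axes.
#' @param threshold minimum presence count.
#' @return a \linkS4class{ConsensusContactSet}.
#' @export
consensusMerge <- function(maps, threshold = 3L) {
  stopifnot(length(maps) >= 1L)
  dn <- dimnames(maps[[1]]@persistence)
  for (m in maps)
    if (!identical(dimnames(m@persistence), dn))
      stop("alignment error: contact maps have mismatched residue ranges")
  counts <- Reduce(`+`, lapply(maps, function(m) (m@persistence > 0) * 1L))
  keys <- names(maps)
  if (is.null(keys)) keys <- paste0("map", seq_along(maps))
  new("ConsensusContactSet", counts = counts,
      retained = counts >= threshold, threshold = as.integer(threshold),
      nMaps = length(maps), mapKeys = keys)
}

#' Classify retained interface pairs by interaction type
#'
#' Each retained consensus pair is assigned every class whose rule it
#' satisfies (classes are not exclusive): `salt_bridge` for oppositely
#' charged residue types, `hydrogen_bond` when the registry lists a
#' donor/acceptor entry for the pair with nonzero measured occupancy on at
#' least one chain, `hydrophobic` when both residues belong to the
#' hydrophobic set (A, V, L, I, M, F, W, P -- tryptophan included, glycine
#' excluded). Pairs matching no rule are flagged unclassified.
#'
#' @param consensus a \linkS4class{ConsensusContactSet} (receptor residues
#'   on rows, adaptor residues on columns).
#' @param topology a \linkS4class{ComplexTopology}.
#' @param occupancies an \linkS4class{OccupancyTable} covering the
#'   registered donor/acceptor pairs.
#' @param registry donor/acceptor registry (see [defaultRegistry()]).
#' @param hydrophobicSet 3-letter residue names treated as hydrophobic.
#' @return data.frame with columns receptorResno, receptorResid,
#'   adaptorResno, adaptorResid, pair, hydrophobic, hydrogenBond,
#'   saltBridge, unclassified.
#' @export
classifyInteractions <- function(consensus, topology, occupancies,
                                 registry = defaultRegistry(),
                                 hydrophobicSet = .hydrophobicSet) {
  pairs <- retainedPairs(consensus)
  if (nrow(pairs) == 0L)
    stop("input error: consensus set is empty")
  atoms <- topology@atoms
  roles <- topology@chainRoles
  receptorChain <- names(roles)[roles == "receptor"]
  adaptorChains <- names(roles)[roles != "receptor"]
  resName <- function(chain, resno) {
    nm <- unique(atoms$resid[atoms$chain %in% chain & atoms$resno == resno])
    if (length(nm) != 1L)
      stop(sprintf("topology error: residue %s on chain(s) %s unknown",
                   resno, paste(chain, collapse = "/")))
    nm
  }
  occ <- occupancy(occupancies)
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    rr <- pairs$receptorResno[k]
    ar <- pairs$adaptorResno[k]
    rn <- resName(receptorChain, rr)
    an <- resName(adaptorChains, ar)
    pairLabel <- paste0(bio3d::aa321(rn), rr, "/", bio3d::aa321(an), ar)
    hydro <- rn %in% hydrophobicSet && an %in% hydrophobicSet
    salt <- (rn %in% .basicSet && an %in% .acidicSet) ||
      (rn %in% .acidicSet && an %in% .basicSet)
    regHit <- registry$donorResno == rr & registry$acceptorResno == ar
    hb <- FALSE
    if (any(regHit)) {
      rows <- occ$pair == pairLabel & occ$occupancy > 0
      hb <- any(rows)
    }
    data.frame(receptorResno = rr, receptorResid = rn, adaptorResno = ar,
               adaptorResid = an, pair = pairLabel, hydrophobic = hydro,
               hydrogenBond = hb, saltBridge = salt,
               unclassified = !(hydro || hb || salt),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Atom-level contact persistence for one residue pair
#'
#' Persistence matrix over (atoms of residue 1) x (atoms of residue 2) at
#' the given cutoff, for drilling into which atoms carry a residue-level
#' contact.
#'
#' @param traj a \linkS4class{TrajectoryWindow}.
#' @param res1,res2 lists with elements chain, resno.
#' @param cutoff contact cutoff, Angstrom (default 3).
#' @param window optional c(first, last) frame indices.
#' @return numeric matrix of persistences with atom-name dimnames.
#' @export
atomisticPairMap <- function(traj, res1, res2, cutoff = 3, window = NULL) {
  atoms <- traj@topology@atoms
  i1 <- .selectAtoms(atoms, chain = res1$chain, resno = res1$resno)
  i2 <- .selectAtoms(atoms, chain = res2$chain, resno = res2$resno)
  if (!length(i1) || !length(i2))
    stop("selection error: residue has no atoms")
  frames <- if (is.null(window)) seq_len(nFrames(traj))
            else seq.int(window[1], window[2])
  acc <- matrix(0, length(i1), length(i2))
  cut2 <- cutoff^2
  for (f in frames) {
    d2 <- crossDist2(.frameCoords(traj@coords, i1, f),
                     .frameCoords(traj@coords, i2, f))
    acc <- acc + (d2 <= cut2)
  }
  pers <- acc / length(frames)
  dimnames(pers) <- list(atoms$elety[i1], atoms$elety[i2])
  pers
}

#' Per-frame count of residue pairs in contact
#'
#' The number of residue pairs between the two chains whose minimum
#' atom-set distance is at or below the cutoff, per frame. (Residue-pair
#' counting, rather than atom-pair counting, is an assumption of this
#' implementation.)
#'
#' @inheritParams contactMap
#' @return integer vector, one count per frame.
#' @export
contactCountSeries <- function(traj, chainPair = c("C", "A"),
                               level = c("c_alpha", "all_atom"),
                               cutoff = NULL) {
  level <- match.arg(level)
  if (is.null(cutoff)) cutoff <- if (level == "c_alpha") 11 else 3
  atoms <- traj@topology@atoms
  sel <- function(ch) .selectAtoms(atoms, chain = ch,
                                   elety = if (level == "c_alpha") "CA" else NULL)
  i1 <- sel(chainPair[1]); i2 <- sel(chainPair[2])
  res1 <- sort(unique(atoms$resno[i1]))
  res2 <- sort(unique(atoms$resno[i2]))
  g1 <- .residueIndicator(atoms$resno[i1], res1)
  g2 <- .residueIndicator(atoms$resno[i2], res2)
  cut2 <- cutoff^2
  as.integer(vapply(seq_len(nFrames(traj)), function(f) {
    d2 <- crossDist2(.frameCoords(traj@coords, i1, f),
                     .frameCoords(traj@coords, i2, f))
    sum((g1 %*% (d2 <= cut2) %*% t(g2)) > 0)
  }, numeric(1)))
}

#' Summed middle-region persistence of a contact map
#'
#' Sums persistence over the transmembrane middle region (defaults:
#' receptor residues 14-41, adaptor residues 6-32), the region over which
#' the kinked bundle engages one adaptor chain only.
#'
#' @param map a \linkS4class{ContactMap} with the receptor on rows.
#' @param receptorRange,adaptorRange residue-number ranges (inclusive).
#' @return the summed persistence.
#' @export
middleRegionPersistence <- function(map, receptorRange = c(14, 41),
                                    adaptorRange = c(6, 32)) {
  r <- as.integer(rownames(map@persistence))
  a <- as.integer(colnames(map@persistence))
  sum(map@persistence[r >= receptorRange[1] & r <= receptorRange[2],
                      a >= adaptorRange[1] & a <= adaptorRange[2]])
}
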