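# Donor/acceptor registry, published reference occupancies, and the
# default synthetic study systems built from them.

#' Default donor/acceptor registry
#'
#' The hydrogen-bonding partners tracked across the receptor/adaptor
#' interface: K26 NZ (hydrogens HZ1-3) to D16 OD1, D16 OD2 and T20 OG1,
#' and W34 NE1 (hydrogen HE1) to T20 OG1 and T20 backbone O -- each
#' against both adaptor chains.
#'
#' @return data.frame with columns pair, label, donorResno, donorAtom,
#'   hydrogens (comma-separated), acceptorResno, acceptorAtom,
#'   acceptorChain.
#' @export
defaultRegistry <- function() {
  base <- data.frame(
    pair = c("K26/D16", "K26/D16", "K26/T20", "W34/T20", "W34/T20"),
    label = c("NZ-OD1", "NZ-OD2", "NZ-OG1", "NE1-OG1", "NE1-O"),
    donorResno = c(26L, 26L, 26L, 34L, 34L),
    donorAtom = c("NZ", "NZ", "NZ", "NE1", "NE1"),
    hydrogens = c("HZ1,HZ2,HZ3", "HZ1,HZ2,HZ3", "HZ1,HZ2,HZ3", "HE1", "HE1"),
    acceptorResno = c(16L, 16L, 20L, 20L, 20L),
    acceptorAtom = c("OD1", "OD2", "OG1", "OG1", "O"),
    stringsAsFactors = FALSE)
  out <- rbind(cbind(base, acceptorChain = "A"),
               cbind(base, acceptorChain = "B"))
  rownames(out) <- NULL
  out
}

#' Published hydrogen-bond probabilities of the three reference systems
#'
#' The published per-label occupancy percentages of the kinked (6z0g_TD)
#' and unkinked (6z0i_TD, AF_TD) receptor/adaptor systems, shipped with
#' the package. These values serve two roles: worked-example input for
#' [aggregateOccupancy()], and the default occupancy-schedule targets of
#' the synthetic study systems.
#'
#' @return an \linkS4class{OccupancyTable} (nFrames is NA; no union
#'   occupancies are available for published values).
#' @export
referenceOccupancyTable <- function() {
  path <- system.file("extdata", "hbond_probabilities.csv",
                      package = "tmtriad", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  new("OccupancyTable", table = tab,
      pairUnion = data.frame(system = character(), pair = character(),
                             chain = character(), occupancy = numeric(),
                             stringsAsFactors = FALSE),
      nFrames = NA_integer_, criteria = hBondCriteria())
}

## hydrogen owned by each schedule label, and quota phases staggered so
## bonds sharing a residue pair alternate rather than co-occur
.scheduleHydrogen <- c("NZ-OD1" = "HZ1", "NZ-OD2" = "HZ2",
                       "NZ-OG1" = "HZ3", "NE1-OG1" = "HE1", "NE1-O" = "HE1")
.schedulePhase <- c("NZ-OD1" = 0, "NZ-OD2" = 0.5, "NZ-OG1" = 0.25,
                    "NE1-OG1" = 0.75, "NE1-O" = 0.4)

#' Occupancy schedules reproducing a reference system's probabilities
#'
#' Builds the occupancy schedules whose targets are the published
#' occupancies of the named system (entries with zero occupancy get no
#' schedule; their atoms stay at nominal positions, far from the donors).
#'
#' @param system one of "6z0g_TD", "6z0i_TD", "AF_TD".
#' @param mode "quota" (exact realized occupancies) or "bernoulli".
#' @param reference an \linkS4class{OccupancyTable} of targets; defaults
#'   to [referenceOccupancyTable()].
#' @return list of \linkS4class{OccupancySchedule}.
#' @export
defaultSchedules <- function(system, mode = "quota",
                             reference = referenceOccupancyTable()) {
  tab <- occupancy(reference)
  tab <- tab[tab$system == system, ]
  if (nrow(tab) == 0L)
    stop(sprintf("unknown reference system '%s'", system))
  reg <- defaultRegistry()
  out <- list()
  for (k in seq_len(nrow(tab))) {
    if (tab$occupancy[k] == 0) next
    r <- reg[reg$label == tab$label[k] & reg$acceptorChain == tab$chain[k], ]
    out[[length(out) + 1L]] <- occupancySchedule(
      label = tab$label[k], pair = tab$pair[k],
      donorResno = r$donorResno, donorAtom = r$donorAtom,
      hydrogen = .scheduleHydrogen[[tab$label[k]]],
      acceptorChain = tab$chain[k], acceptorResno = r$acceptorResno,
      acceptorAtom = r$acceptorAtom, target = tab$occupancy[k] / 100,
      mode = mode, phase = .schedulePhase[[tab$label[k]]])
  }
  out
}

#' Generate and write the three synthetic study systems
#'
#' Builds the default study conditions: a kinked bundle ("6z0g_TD"-like,
#' receptor bent at K26 and packed against adaptor A only) and two
#' straight bundles ("6z0i_TD"- and "AF_TD"-like, symmetric interfaces),
#' each with occupancy schedules targeting the published hydrogen-bond
#' probabilities of the corresponding reference system. Writes, per
#' system, a single-model topology PDB, a multi-model trajectory PDB and
#' a ground-truth JSON sidecar.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; system seeds are derived deterministically.
#' @param nFrames frames per trajectory (default 2000, emulating a 300 ns
#'   production window at 0.15 ns spacing).
#' @param noiseSigma thermal noise, Angstrom.
#' @param dt frame spacing, ns.
#' @param mode schedule mode, "quota" or "bernoulli".
#' @return an \linkS4class{AnalysisConfig} pointing at the written files.
#' @export
writeSyntheticSystems <- function(dir, seed = 1L, nFrames = 2000L,
                                  noiseSigma = 0.15, dt = 0.15,
                                  mode = "quota") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  names <- c("6z0g_TD", "6z0i_TD", "AF_TD")
  ## contact-map window: 175-225 ns of a 300 ns trajectory, scaled
  ## proportionally when a shorter trajectory is generated
  tmax <- (nFrames - 1) * dt
  window <- c(175, 225) / 300 * min(tmax, 300)
  systems <- list()
  for (i in seq_along(names)) {
    nm <- names[i]
    asm <- if (nm == "6z0g_TD") trimerAssembly(kink = TRUE)
           else trimerAssembly()
    traj <- generateTrajectory(asm, nFrames = nFrames,
                               noiseSigma = noiseSigma,
                               schedules = defaultSchedules(nm, mode = mode),
                               seed = as.integer(seed) + 1000L * i, dt = dt)
    prefix <- file.path(dir, gsub("[^A-Za-z0-9_]", "_", nm))
    writeAssemblyPDB(asm$assembly, paste0(prefix, "_topo.pdb"))
    writeTrajectoryPDB(traj, paste0(prefix, "_traj.pdb"))
    writeGroundTruthJSON(traj, paste0(prefix, "_groundtruth.json"))
    systems[[i]] <- list(name = nm, topology = paste0(prefix, "_topo.pdb"),
                         trajectory = paste0(prefix, "_traj.pdb"),
                         sidecar = paste0(prefix, "_groundtruth.json"),
                         dt = dt, window = window)
  }
  analysisConfig(systems = systems, seed = as.integer(seed))
}
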