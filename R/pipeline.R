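# End-to-end orchestration: read systems, run kink / contact / hydrogen-bond
# analyses, merge consensus, classify, write tables.

#' @rdname AnalysisConfig-class
#' @param systems,chainRoles,kinkVectors,caCutoff,aaCutoff,persistenceThreshold,consensusThreshold,criteria,registry,binWidth,outDir,seed
#'   see slots of \linkS4class{AnalysisConfig}.
#' @return an `AnalysisConfig`.
#' @export
analysisConfig <- function(systems,
                           chainRoles = c(C = "receptor", A = "adaptorA",
                                          B = "adaptorB"),
                           kinkVectors = kinkVectorSpec(),
                           caCutoff = 11, aaCutoff = 3,
                           persistenceThreshold = 0.5,
                           consensusThreshold = 3L,
                           criteria = hBondCriteria(),
                           registry = defaultRegistry(),
                           binWidth = 1.0, outDir = "", seed = 1L) {
  new("AnalysisConfig", systems = systems, chainRoles = chainRoles,
      kinkVectors = kinkVectors, caCutoff = caCutoff, aaCutoff = aaCutoff,
      persistenceThreshold = persistenceThreshold,
      consensusThreshold = as.integer(consensusThreshold),
      criteria = criteria, registry = registry, binWidth = binWidth,
      outDir = outDir, seed = as.integer(seed))
}

#' Read an analysis configuration from YAML
#'
#' Minimal configurations name only the systems (name/topology/trajectory,
#' optional dt, window, sidecar); every analysis parameter defaults to the
#' standard values. Recognized top-level keys: systems, chain_roles,
#' kink_vectors (chain, vec1, vec2), ca_cutoff, aa_cutoff,
#' persistence_threshold, consensus_threshold, hbond (distance, angle,
#' distance_definition), bin_width, out_dir, seed.
#'
#' @param file YAML path.
#' @return an \linkS4class{AnalysisConfig}.
#' @export
readAnalysisConfig <- function(file) {
  y <- yaml::read_yaml(file)
  if (is.null(y$systems)) stop("config error: no systems defined")
  systems <- lapply(y$systems, function(s) {
    s$dt <- if (is.null(s$dt)) 1 else s$dt
    if (!is.null(s$window)) s$window <- as.numeric(unlist(s$window))
    s
  })
  args <- list(systems = systems)
  if (!is.null(y$chain_roles)) args$chainRoles <- unlist(y$chain_roles)
  if (!is.null(y$kink_vectors))
    args$kinkVectors <- kinkVectorSpec(
      chain = y$kink_vectors$chain,
      vec1Start = y$kink_vectors$vec1[1], vec1End = y$kink_vectors$vec1[2],
      vec2Start = y$kink_vectors$vec2[1], vec2End = y$kink_vectors$vec2[2])
  if (!is.null(y$ca_cutoff)) args$caCutoff <- y$ca_cutoff
  if (!is.null(y$aa_cutoff)) args$aaCutoff <- y$aa_cutoff
  if (!is.null(y$persistence_threshold))
    args$persistenceThreshold <- y$persistence_threshold
  if (!is.null(y$consensus_threshold))
    args$consensusThreshold <- y$consensus_threshold
  if (!is.null(y$hbond))
    args$criteria <- hBondCriteria(
      distanceCutoff = if (is.null(y$hbond$distance)) 3 else y$hbond$distance,
      angleCutoff = if (is.null(y$hbond$angle)) 150 else y$hbond$angle,
      distanceDefinition = if (is.null(y$hbond$distance_definition))
        "donor_acceptor" else y$hbond$distance_definition)
  if (!is.null(y$bin_width)) args$binWidth <- y$bin_width
  if (!is.null(y$out_dir)) args$outDir <- y$out_dir
  if (!is.null(y$seed)) args$seed <- y$seed
  do.call(analysisConfig, args)
}

.writeCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

.mapToCsv <- function(map, path) {
  df <- as.data.frame(map@persistence)
  df <- cbind(resno = rownames(map@persistence), df)
  .writeCsv(df, path)
}

#' Run the full analysis over all configured systems
#'
#' Per system: kink-angle series of the receptor helix, windowed C-alpha
#' contact maps and full-window all-atom contact maps against each adaptor
#' chain, persistence filtering, hydrogen-bond occupancy table and
#' per-frame bond counts. With three systems configured the six filtered
#' all-atom maps are merged into a consensus set and retained pairs are
#' classified; with fewer systems the consensus step is skipped with a
#' notice. When the config names an output directory, every table is
#' written as CSV/JSON with a provenance header-free deterministic format.
#'
#' @param config an \linkS4class{AnalysisConfig}.
#' @param verbose print per-stage progress.
#' @return a \linkS4class{RunReport}.
#' @export
runAll <- function(config, verbose = FALSE) {
  stopifnot(is(config, "AnalysisConfig"))
  validObject(config)
  roles <- config@chainRoles
  receptorChain <- names(roles)[roles == "receptor"]
  adaptorChains <- names(roles)[roles %in% c("adaptorA", "adaptorB")]
  adaptorChains <- adaptorChains[order(roles[adaptorChains])]
  if (length(receptorChain) != 1L || length(adaptorChains) != 2L)
    stop("config error: chainRoles must name exactly one receptor and two adaptor chains")
  note <- function(...) if (verbose) message(sprintf(...))

  kink <- list(); caMaps <- list(); aaMaps <- list(); filteredMaps <- list()
  occTabs <- list(); unionTabs <- list(); hbCounts <- list()
  nFramesSeen <- NA_integer_
  topoRef <- NULL

  for (s in config@systems) {
    for (f in c(s$topology, s$trajectory))
      if (!file.exists(f)) stop("I/O error: cannot read ", f)
    note("reading system %s", s$name)
    traj <- readSystem(s$topology, s$trajectory, window = NULL,
                       dt = if (is.null(s$dt)) 1 else s$dt,
                       sidecar = s$sidecar, chainRoles = roles)
    topoRef <- traj@topology
    nFramesSeen <- nFrames(traj)

    note("  kink series")
    kink[[s$name]] <- kinkSeries(traj, config@kinkVectors, config@binWidth)

    wtraj <- if (!is.null(s$window))
      windowFrames(traj, s$window[1], s$window[2]) else traj
    for (ch in adaptorChains) {
      key <- paste(s$name, ch, sep = "|")
      note("  contact maps vs chain %s", ch)
      caMaps[[key]] <- contactMap(wtraj, c(receptorChain, ch),
                                  level = "c_alpha",
                                  cutoff = config@caCutoff)
      aaMaps[[key]] <- contactMap(traj, c(receptorChain, ch),
                                  level = "all_atom",
                                  cutoff = config@aaCutoff)
      filteredMaps[[key]] <- persistenceFilter(aaMaps[[key]],
                                               config@persistenceThreshold)
    }

    note("  hydrogen bonds")
    occ <- occupancyTable(traj, config@registry, config@criteria,
                          system = s$name)
    occTabs[[s$name]] <- occupancy(occ)
    unionTabs[[s$name]] <- pairUnionOccupancy(occ)
    hbCounts[[s$name]] <- hbondCountSeries(traj, config@registry,
                                           config@criteria)$total
  }

  occAll <- new("OccupancyTable",
                table = do.call(rbind, c(occTabs, list(make.row.names = FALSE))),
                pairUnion = do.call(rbind, c(unionTabs,
                                             list(make.row.names = FALSE))),
                nFrames = nFramesSeen, criteria = config@criteria)

  consensus <- NULL
  classification <- data.frame()
  if (length(config@systems) >= 3L) {
    note("consensus merge over %d maps", length(filteredMaps))
    consensus <- consensusMerge(filteredMaps, config@consensusThreshold)
    if (sum(consensus@retained) > 0)
      classification <- classifyInteractions(consensus, topoRef, occAll,
                                             config@registry)
  } else {
    message("fewer than three systems configured; skipping consensus merge")
  }

  files <- character()
  if (nzchar(config@outDir)) {
    dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(...) file.path(config@outDir, sprintf(...))
    for (nm in names(kink)) {
      ks <- kink[[nm]]
      files <- c(files, .writeCsv(
        data.frame(frame = seq_along(ks@angles), time = ks@times,
                   angle_deg = sprintf("%.6f", ks@angles)),
        out("kink_%s.csv", nm)))
    }
    kinkSummary <- lapply(kink, function(ks)
      list(mean = ks@mean, sem = ks@sem, mode = ks@mode,
           bin_width = ks@binWidth))
    jsonlite::write_json(kinkSummary, out("kink_summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    files <- c(files, out("kink_summary.json"))
    for (key in names(caMaps)) {
      safe <- gsub("[^A-Za-z0-9_]", "_", key)
      files <- c(files, .mapToCsv(caMaps[[key]], out("ca_map_%s.csv", safe)),
                 .mapToCsv(filteredMaps[[key]],
                           out("aa_map_persistent_%s.csv", safe)))
    }
    files <- c(files, .writeCsv(occAll@table, out("occupancy.csv")))
    counts <- data.frame(frame = seq_len(nFramesSeen))
    for (nm in names(hbCounts)) counts[[nm]] <- hbCounts[[nm]]
    files <- c(files, .writeCsv(counts, out("hbond_counts.csv")))
    if (!is.null(consensus)) {
      jsonlite::write_json(
        list(threshold = consensus@threshold, nMaps = consensus@nMaps,
             retained = retainedPairs(consensus),
             classification = classification),
        out("consensus.json"), auto_unbox = TRUE, digits = 10,
        pretty = TRUE)
      files <- c(files, out("consensus.json"))
    }
  }

  provenance <- list(
    seed = config@seed,
    package = as.character(utils::packageVersion("tmtriad")),
    parameters = list(ca_cutoff = config@caCutoff,
                      aa_cutoff = config@aaCutoff,
                      persistence_threshold = config@persistenceThreshold,
                      consensus_threshold = config@consensusThreshold,
                      hbond_distance = config@criteria@distanceCutoff,
                      hbond_angle = config@criteria@angleCutoff,
                      distance_definition = config@criteria@distanceDefinition,
                      bin_width = config@binWidth),
    systems = lapply(config@systems, function(s)
      s[intersect(names(s), c("name", "topology", "trajectory", "dt",
                              "window"))]))
  provenance$configHash <- sum(utf8ToInt(jsonlite::toJSON(
    provenance$parameters, auto_unbox = TRUE)))

  new("RunReport", kink = kink, caMaps = caMaps, aaMaps = aaMaps,
      filteredMaps = filteredMaps, consensus = consensus,
      classification = classification, occupancy = occAll,
      hbondCounts = hbCounts, files = files, provenance = provenance)
}
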