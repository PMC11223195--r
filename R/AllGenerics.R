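# Generics and accessors. Slot access from user code should go through
# these rather than @.

#' @rdname ComplexTopology-class
#' @param object an object.
#' @export
setGeneric("atomTable", function(object) standardGeneric("atomTable"))

#' @rdname ComplexTopology-class
#' @export
setGeneric("chainRoles", function(object) standardGeneric("chainRoles"))

#' @rdname TrajectoryWindow-class
#' @param object an object.
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' @rdname TrajectoryWindow-class
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname TrajectoryWindow-class
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname TrajectoryWindow-class
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname KinkSeries-class
#' @param object an object.
#' @export
setGeneric("angles", function(object) standardGeneric("angles"))

#' @rdname KinkSeries-class
#' @export
setGeneric("kinkMean", function(object) standardGeneric("kinkMean"))

#' @rdname KinkSeries-class
#' @export
setGeneric("kinkSem", function(object) standardGeneric("kinkSem"))

#' @rdname KinkSeries-class
#' @export
setGeneric("kinkMode", function(object) standardGeneric("kinkMode"))

#' @rdname ContactMap-class
#' @param object an object.
#' @export
setGeneric("persistence", function(object) standardGeneric("persistence"))

#' @rdname ConsensusContactSet-class
#' @param object an object.
#' @export
setGeneric("presenceCounts", function(object) standardGeneric("presenceCounts"))

#' @rdname ConsensusContactSet-class
#' @export
setGeneric("retainedPairs", function(object) standardGeneric("retainedPairs"))

#' @rdname OccupancyTable-class
#' @param object an object.
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))

#' @rdname OccupancyTable-class
#' @export
setGeneric("pairUnionOccupancy",
           function(object) standardGeneric("pairUnionOccupancy"))

# --- methods ---------------------------------------------------------------

#' @rdname ComplexTopology-class
setMethod("atomTable", "ComplexTopology", function(object) object@atoms)
#' @rdname ComplexTopology-class
setMethod("atomTable", "Assembly", function(object) object@atoms)
#' @rdname TrajectoryWindow-class
setMethod("atomTable", "TrajectoryWindow",
          function(object) object@topology@atoms)
#' @rdname ComplexTopology-class
setMethod("chainRoles", "ComplexTopology", function(object) object@chainRoles)
#' @rdname TrajectoryWindow-class
setMethod("chainRoles", "TrajectoryWindow",
          function(object) object@topology@chainRoles)

#' @rdname TrajectoryWindow-class
setMethod("coords", "TrajectoryWindow", function(object) object@coords)
#' @rdname ComplexTopology-class
setMethod("coords", "Assembly", function(object) object@xyz)
#' @rdname TrajectoryWindow-class
setMethod("nFrames", "TrajectoryWindow",
          function(object) dim(object@coords)[3])
#' @rdname TrajectoryWindow-class
setMethod("frameTimes", "TrajectoryWindow", function(object) object@times)
#' @rdname TrajectoryWindow-class
setMethod("groundTruth", "TrajectoryWindow", function(object) object@groundTruth)

#' @rdname KinkSeries-class
setMethod("angles", "KinkSeries", function(object) object@angles)
#' @rdname KinkSeries-class
setMethod("kinkMean", "KinkSeries", function(object) object@mean)
#' @rdname KinkSeries-class
setMethod("kinkSem", "KinkSeries", function(object) object@sem)
#' @rdname KinkSeries-class
setMethod("kinkMode", "KinkSeries", function(object) object@mode)

#' @rdname ContactMap-class
setMethod("persistence", "ContactMap", function(object) object@persistence)

#' @rdname ConsensusContactSet-class
setMethod("presenceCounts", "ConsensusContactSet",
          function(object) object@counts)

#' @rdname ConsensusContactSet-class
setMethod("retainedPairs", "ConsensusContactSet", function(object) {
  idx <- which(object@retained, arr.ind = TRUE)
  data.frame(
    receptorResno = as.integer(rownames(object@retained))[idx[, 1]],
    adaptorResno = as.integer(colnames(object@retained))[idx[, 2]],
    count = object@counts[idx])
})

#' @rdname OccupancyTable-class
setMethod("occupancy", "OccupancyTable", function(object) object@table)
#' @rdname OccupancyTable-class
setMethod("pairUnionOccupancy", "OccupancyTable",
          function(object) object@pairUnion)

# --- show ------------------------------------------------------------------

setMethod("show", "ComplexTopology", function(object) {
  roles <- object@chainRoles
  cat("ComplexTopology:", nrow(object@atoms), "atoms,",
      length(unique(paste(object@atoms$chain, object@atoms$resno))),
      "residues\n")
  for (ch in names(roles)) {
    sel <- object@atoms$chain == ch
    cat(sprintf("  chain %s (%s): residues %d-%d, %d atoms\n", ch, roles[ch],
                min(object@atoms$resno[sel]), max(object@atoms$resno[sel]),
                sum(sel)))
  }
})

setMethod("show", "TrajectoryWindow", function(object) {
  d <- dim(object@coords)
  cat(sprintf("TrajectoryWindow: %d atoms x %d frames, t = %.4g..%.4g ns\n",
              d[1], d[3], min(object@times), max(object@times)))
  if (length(object@groundTruth))
    cat("  synthetic ground truth attached:",
        paste(names(object@groundTruth), collapse = ", "), "\n")
})

setMethod("show", "KinkSeries", function(object) {
  cat(sprintf(
    "KinkSeries: %d frames; mean %.2f +/- %.2f deg; mode %.1f deg (%g deg bins)\n",
    length(object@angles), object@mean, object@sem, object@mode,
    object@binWidth))
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf(
    "ContactMap %s-%s (%s, cutoff %.1f A): %d x %d residues, %d frames, %d pairs with persistence > 0\n",
    object@chainPair[1], object@chainPair[2], object@level, object@cutoff,
    nrow(object@persistence), ncol(object@persistence), object@nFrames,
    sum(object@persistence > 0)))
})

setMethod("show", "ConsensusContactSet", function(object) {
  cat(sprintf(
    "ConsensusContactSet: %d maps, threshold %d; %d retained pair(s)\n",
    object@nMaps, object@threshold, sum(object@retained)))
})

setMethod("show", "OccupancyTable", function(object) {
  cat(sprintf("OccupancyTable: %d rows", nrow(object@table)))
  if (!is.na(object@nFrames)) cat(sprintf(" over %d frames", object@nFrames))
  cat("\n")
  print(utils::head(object@table, 10))
  if (nrow(object@table) > 10) cat("  ...\n")
})

setMethod("show", "RunReport", function(object) {
  cat("RunReport:", length(object@kink), "system(s)\n")
  for (nm in names(object@kink)) {
    ks <- object@kink[[nm]]
    cat(sprintf("  %s: kink mean %.2f deg, mode %.1f deg\n", nm,
                ks@mean, ks@mode))
  }
  if (!is.null(object@consensus))
    cat("  consensus retained pairs:", sum(object@consensus@retained), "\n")
  if (length(object@files))
    cat("  files written:", length(object@files), "\n")
})
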