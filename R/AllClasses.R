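#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' GelImage: a grayscale gel photograph
#'
#' Holds the 2-D intensity matrix of a (real or simulated) DGGE gel.
#' Rows are the migration axis with row 1 at the well (top of the gel);
#' columns are the lateral axis. The normalized migration position of row
#' \eqn{r} is \eqn{p = (r-1)/(H-1)} for an image of height \eqn{H}.
#'
#' @slot intensity numeric matrix of nonnegative intensities.
#' @slot bitDepth integer, 8 or 16; intensities live in [0, 2^bitDepth - 1].
#' @slot laneSpans data.frame with columns \code{lane}, \code{from},
#'   \code{to} (column indices), possibly empty when lane layout is unknown.
#' @export
setClass("GelImage", slots = c(
  intensity = "matrix",
  bitDepth  = "integer",
  laneSpans = "data.frame"
))

setValidity("GelImage", function(object) {
  msg <- character()
  if (!is.numeric(object@intensity))
    msg <- c(msg, "intensity must be a numeric matrix")
  if (nrow(object@intensity) < 64)
    msg <- c(msg, "gel image must have at least 64 rows")
  if (any(object@intensity < 0))
    msg <- c(msg, "intensities must be nonnegative")
  if (!(object@bitDepth %in% c(8L, 16L)))
    msg <- c(msg, "bitDepth must be 8 or 16")
  if (nrow(object@laneSpans) > 0 &&
      !all(c("lane", "from", "to") %in% names(object@laneSpans)))
    msg <- c(msg, "laneSpans needs columns lane, from, to")
  if (length(msg)) msg else TRUE
})

#' LaneProfile: one lane's densitometric curve
#'
#' Intensity as a function of normalized migration position for a single
#' lane, the 1-D signal from which bands are called and Pearson
#' similarities computed.
#'
#' @slot laneId character scalar identifying the lane (sample).
#' @slot values nonnegative numeric vector of intensities.
#' @slot positions numeric vector of normalized positions in [0, 1],
#'   nondecreasing, same length as \code{values}.
#' @export
setClass("LaneProfile", slots = c(
  laneId    = "character",
  values    = "numeric",
  positions = "numeric"
))

setValidity("LaneProfile", function(object) {
  msg <- character()
  if (length(object@laneId) != 1L)
    msg <- c(msg, "laneId must be a single string")
  if (length(object@values) != length(object@positions))
    msg <- c(msg, "values and positions must have equal length")
  if (length(object@positions) &&
      (min(object@positions) < 0 || max(object@positions) > 1))
    msg <- c(msg, "positions must lie in [0, 1]")
  if (is.unsorted(object@positions))
    msg <- c(msg, "positions must be nondecreasing")
  if (length(msg)) msg else TRUE
})

#' ProfileSet: a set of aligned lane profiles
#'
#' A \linkS4class{SummarizedExperiment} whose single \code{"intensity"}
#' assay holds one column per lane and one row per resampled migration
#' position; \code{rowData(x)$position} carries the common [0, 1] grid and
#' \code{colData(x)} the lane metadata (\code{temperature}, \code{reactor},
#' \code{day}, ... when known).
#'
#' @export
setClass("ProfileSet", contains = "SummarizedExperiment")

setValidity("ProfileSet", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "ProfileSet needs an 'intensity' assay")
  rd <- rowData(object)
  if (!"position" %in% colnames(rd)) {
    msg <- c(msg, "rowData must carry a 'position' column")
  } else {
    p <- rd$position
    if (length(p) && (min(p) < 0 || max(p) > 1 || is.unsorted(p)))
      msg <- c(msg, "positions must be nondecreasing within [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' BandClassTable: global band classes across lanes
#'
#' Cluster centers of band positions pooled over all lanes; bands of
#' different lanes assigned to the same class are treated as the same
#' DNA fragment for presence/absence comparison.
#'
#' @slot centers strictly increasing positions in [0, 1] (mean member
#'   position per class).
#' @slot lower,upper the position extent of each class's members; because
#'   classes are built by single-linkage chaining, a member may be farther
#'   than one tolerance from its class center but never from its extent.
#' @slot tolerance the single-linkage gap (fraction of gel length) used to
#'   build the classes and to match bands to them.
#' @export
setClass("BandClassTable", slots = c(
  centers   = "numeric",
  lower     = "numeric",
  upper     = "numeric",
  tolerance = "numeric"
))

setValidity("BandClassTable", function(object) {
  msg <- character()
  if (length(object@tolerance) != 1L || object@tolerance <= 0)
    msg <- c(msg, "tolerance must be a single positive number")
  ctr <- object@centers
  if (length(object@lower) != length(ctr) ||
      length(object@upper) != length(ctr))
    msg <- c(msg, "lower/upper must match centers in length")
  if (length(ctr)) {
    if (min(ctr) < 0 || max(ctr) > 1)
      msg <- c(msg, "centers must lie in [0, 1]")
    if (any(object@lower > ctr) || any(object@upper < ctr))
      msg <- c(msg, "each center must lie within its class extent")
    if (length(ctr) > 1 && any(diff(ctr) <= object@tolerance))
      msg <- c(msg, "adjacent centers must be separated by more than tolerance")
    if (length(ctr) > 1 &&
        any(object@lower[-1] - object@upper[-length(ctr)] <=
              object@tolerance))
      msg <- c(msg, "adjacent class extents must be separated by more than tolerance")
  }
  if (length(msg)) msg else TRUE
})

#' FingerprintSet: lane fingerprints over global band classes
#'
#' @slot presence lanes x classes 0/1 matrix of band presence.
#' @slot intensity lanes x classes matrix of band areas (0 where absent).
#' @slot classes the \linkS4class{BandClassTable} the columns refer to.
#' @slot bands data.frame of the underlying called bands
#'   (lane_id, position, height, prominence, area, class_index).
#' @export
setClass("FingerprintSet", slots = c(
  presence  = "matrix",
  intensity = "matrix",
  classes   = "BandClassTable",
  bands     = "data.frame"
))

setValidity("FingerprintSet", function(object) {
  msg <- character()
  if (!identical(dim(object@presence), dim(object@intensity)))
    msg <- c(msg, "presence and intensity matrices must have equal dims")
  if (ncol(object@presence) != length(object@classes@centers))
    msg <- c(msg, "matrix columns must match number of band classes")
  if (!all(object@presence %in% c(0, 1)))
    msg <- c(msg, "presence must be binary")
  if (any((object@intensity > 0) != (object@presence == 1)))
    msg <- c(msg, "presence must be 1 exactly where intensity > 0")
  if (length(msg)) msg else TRUE
})

#' SimilarityMatrix: pairwise lane similarities in percent
#'
#' @slot values symmetric matrix of percent similarities in [0, 100] with
#'   100 on the diagonal; dimnames carry the lane ids.
#' @slot method "jaccard" (binary band classes) or "pearson"
#'   (densitometric curves).
#' @export
setClass("SimilarityMatrix", slots = c(
  values = "matrix",
  method = "character"
))

setValidity("SimilarityMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v) || !isTRUE(all.equal(v, t(v), tolerance = 1e-8)))
    msg <- c(msg, "values must be a symmetric square matrix")
  if (any(v < 0) || any(v > 100))
    msg <- c(msg, "similarities must lie in [0, 100]")
  if (nrow(v) && max(abs(diag(v) - 100)) > 1e-8)
    msg <- c(msg, "diagonal must equal 100")
  if (is.null(rownames(v)))
    msg <- c(msg, "values must carry lane ids as dimnames")
  if (!object@method %in% c("jaccard", "pearson"))
    msg <- c(msg, "method must be 'jaccard' or 'pearson'")
  if (length(msg)) msg else TRUE
})

#' GelDendrogram: UPGMA tree over lanes
#'
#' Stored hclust-style: \code{merge} has one row per internal node with
#' negative entries for leaves and positive entries for earlier merges;
#' \code{height} holds the merge dissimilarity d = 100 - similarity.
#' Heights are non-decreasing (UPGMA trees are ultrametric).
#'
#' @slot merge integer matrix (n-1 x 2) of merge steps.
#' @slot height numeric vector of merge dissimilarities.
#' @slot labels leaf (lane) ids, in input order.
#' @slot order leaf permutation for crossing-free plotting.
#' @export
setClass("GelDendrogram", slots = c(
  merge  = "matrix",
  height = "numeric",
  labels = "character",
  order  = "integer"
))

setValidity("GelDendrogram", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (nrow(object@merge) != n - 1L)
    msg <- c(msg, "merge must have n-1 rows")
  if (length(object@height) != n - 1L)
    msg <- c(msg, "height must have n-1 entries")
  if (is.unsorted(object@height + 1e-9))
    msg <- c(msg, "merge heights must be non-decreasing (ultrametricity)")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "leaf labels must be unique")
  if (length(msg)) msg else TRUE
})

#' CommunityTrajectory: simulator ground truth
#'
#' Per-lane (reactor, day) relative-abundance vectors over a species pool.
#' Each column is a probability vector; species absent from a lane carry 0.
#'
#' @slot abundance species x lanes matrix; columns sum to 1.
#' @slot laneInfo data.frame with one row per lane: \code{lane},
#'   \code{temperature}, \code{reactor}, \code{day}.
#' @slot pool the species pool data.frame (species_id, melting_position,
#'   amplification_factor).
#' @export
setClass("CommunityTrajectory", slots = c(
  abundance = "matrix",
  laneInfo  = "data.frame",
  pool      = "data.frame"
))

setValidity("CommunityTrajectory", function(object) {
  msg <- character()
  if (ncol(object@abundance) != nrow(object@laneInfo))
    msg <- c(msg, "one laneInfo row per abundance column required")
  if (nrow(object@abundance) != nrow(object@pool))
    msg <- c(msg, "one pool row per abundance row required")
  if (any(object@abundance < 0))
    msg <- c(msg, "abundances must be nonnegative")
  s <- colSums(object@abundance)
  if (length(s) && max(abs(s - 1)) > 1e-9)
    msg <- c(msg, "abundance columns must sum to 1 (within 1e-9)")
  need <- c("lane", "temperature", "reactor", "day")
  if (!all(need %in% names(object@laneInfo)))
    msg <- c(msg, "laneInfo needs columns lane, temperature, reactor, day")
  if (length(msg)) msg else TRUE
})

#' MovingWindowSeries: moving-window percent change per temperature
#'
#' @slot values per-reactor data.frame: temperature, interval_start,
#'   interval_end, reactor, pct_change.
#' @slot means per-interval data.frame: temperature, interval_start,
#'   interval_end, mean_pct_change, n.
#' @export
setClass("MovingWindowSeries", slots = c(
  values = "data.frame",
  means  = "data.frame"
))

setValidity("MovingWindowSeries", function(object) {
  msg <- character()
  if (!all(c("temperature", "interval_start", "interval_end", "reactor",
             "pct_change") %in% names(object@values)))
    msg <- c(msg, "values is missing required columns")
  if (!all(c("temperature", "interval_start", "interval_end",
             "mean_pct_change", "n") %in% names(object@means)))
    msg <- c(msg, "means is missing required columns")
  pc <- c(object@values$pct_change, object@means$mean_pct_change)
  if (length(pc) && (min(pc) < -1e-9 || max(pc) > 100 + 1e-9))
    msg <- c(msg, "percent change must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})
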