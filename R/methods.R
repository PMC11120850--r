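#' @include AllGenerics.R
NULL

#' Construct a GelImage
#'
#' @param intensity numeric matrix (rows = migration, row 1 = well).
#' @param bitDepth 8 or 16.
#' @param laneSpans optional data.frame (lane, from, to) of known lane
#'   column spans.
#' @return a \linkS4class{GelImage}.
#' @export
GelImage <- function(intensity, bitDepth = 16L, laneSpans = NULL) {
  if (is.null(laneSpans))
    laneSpans <- data.frame(lane = integer(), from = integer(),
                            to = integer())
  new("GelImage", intensity = unname(as.matrix(intensity)),
      bitDepth = as.integer(bitDepth), laneSpans = laneSpans)
}

#' Construct a LaneProfile
#'
#' @param laneId lane identifier.
#' @param values intensity vector.
#' @param positions normalized migration positions; defaults to a uniform
#'   [0, 1] grid of the same length as \code{values}.
#' @return a \linkS4class{LaneProfile}.
#' @export
LaneProfile <- function(laneId, values, positions = NULL) {
  if (is.null(positions))
    positions <- seq(0, 1, length.out = length(values))
  new("LaneProfile", laneId = as.character(laneId),
      values = as.numeric(values), positions = as.numeric(positions))
}

#' Construct a ProfileSet from a value matrix and lane metadata
#'
#' @param values positions x lanes matrix of profile intensities.
#' @param positions normalized [0, 1] grid (one per row of \code{values}).
#' @param laneData data.frame of per-lane metadata; must contain a
#'   \code{lane} column used for the column names.
#' @return a \linkS4class{ProfileSet}.
#' @export
ProfileSet <- function(values, positions = NULL, laneData = NULL) {
  values <- as.matrix(values)
  if (is.null(positions))
    positions <- seq(0, 1, length.out = nrow(values))
  if (is.null(laneData))
    laneData <- data.frame(lane = colnames(values) %||%
                             paste0("lane", seq_len(ncol(values))))
  colnames(values) <- as.character(laneData$lane)
  se <- SummarizedExperiment(
    assays = SimpleList(intensity = values),
    rowData = DataFrame(position = as.numeric(positions)),
    colData = DataFrame(laneData, row.names = as.character(laneData$lane)))
  new("ProfileSet", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- accessors -----------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("gelIntensity", "GelImage", function(x) x@intensity)
#' @rdname accessors
#' @export
setMethod("bitDepth", "GelImage", function(x) x@bitDepth)
#' @rdname accessors
#' @export
setMethod("laneSpans", "GelImage", function(x) x@laneSpans)

#' @rdname accessors
#' @export
setMethod("profileValues", "LaneProfile", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("profilePositions", "LaneProfile", function(x) x@positions)
#' @rdname accessors
#' @export
setMethod("laneIds", "LaneProfile", function(x) x@laneId)

#' @rdname accessors
#' @export
setMethod("profileValues", "ProfileSet",
          function(x) assay(x, "intensity"))
#' @rdname accessors
#' @export
setMethod("profilePositions", "ProfileSet",
          function(x) rowData(x)$position)
#' @rdname accessors
#' @export
setMethod("laneIds", "ProfileSet", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("presenceMatrix", "FingerprintSet", function(x) x@presence)
#' @rdname accessors
#' @export
setMethod("intensityMatrix", "FingerprintSet", function(x) x@intensity)
#' @rdname accessors
#' @export
setMethod("bandTable", "FingerprintSet", function(x) x@bands)
#' @rdname accessors
#' @export
setMethod("bandClasses", "FingerprintSet", function(x) x@classes)
#' @rdname accessors
#' @export
setMethod("laneIds", "FingerprintSet", function(x) rownames(x@presence))

#' @rdname accessors
#' @export
setMethod("classCenters", "BandClassTable", function(x) x@centers)
#' @rdname accessors
#' @export
setMethod("classTolerance", "BandClassTable", function(x) x@tolerance)

#' @rdname accessors
#' @export
setMethod("similarityValues", "SimilarityMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("similarityMethod", "SimilarityMatrix", function(x) x@method)
#' @rdname accessors
#' @export
setMethod("laneIds", "SimilarityMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("mergeHeights", "GelDendrogram", function(x) x@height)
#' @rdname accessors
#' @export
setMethod("leafLabels", "GelDendrogram", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("abundanceMatrix", "CommunityTrajectory", function(x) x@abundance)
#' @rdname accessors
#' @export
setMethod("laneInfo", "CommunityTrajectory", function(x) x@laneInfo)
#' @rdname accessors
#' @export
setMethod("speciesPool", "CommunityTrajectory", function(x) x@pool)
#' @rdname accessors
#' @export
setMethod("laneIds", "CommunityTrajectory", function(x) x@laneInfo$lane)

#' @rdname accessors
#' @export
setMethod("windowValues", "MovingWindowSeries", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("windowMeans", "MovingWindowSeries", function(x) x@means)

## ---- show methods --------------------------------------------------------

setMethod("show", "GelImage", function(object) {
  d <- dim(object@intensity)
  cat("GelImage:", d[1], "x", d[2], "px,", object@bitDepth, "bit\n")
  if (nrow(object@laneSpans))
    cat("  known lanes:", nrow(object@laneSpans), "\n")
})

setMethod("show", "LaneProfile", function(object) {
  cat("LaneProfile", sQuote(object@laneId), "with",
      length(object@values), "points\n")
})

setMethod("show", "BandClassTable", function(object) {
  cat("BandClassTable:", length(object@centers),
      "classes (tolerance", object@tolerance, ")\n")
})

setMethod("show", "FingerprintSet", function(object) {
  cat("FingerprintSet:", nrow(object@presence), "lanes x",
      ncol(object@presence), "band classes;",
      nrow(object@bands), "called bands\n")
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat("SimilarityMatrix (", object@method, "): ",
      nrow(object@values), " lanes\n", sep = "")
})

setMethod("show", "GelDendrogram", function(object) {
  cat("GelDendrogram (UPGMA):", length(object@labels), "leaves, root at d =",
      round(max(object@height), 2), "\n")
})

setMethod("show", "CommunityTrajectory", function(object) {
  cat("CommunityTrajectory:", nrow(object@abundance), "species x",
      ncol(object@abundance), "lanes (",
      length(unique(object@laneInfo$temperature)), "temperatures,",
      length(unique(object@laneInfo$day)), "days )\n")
})

setMethod("show", "MovingWindowSeries", function(object) {
  cat("MovingWindowSeries:", nrow(object@means), "intervals over",
      length(unique(object@means$temperature)), "temperatures\n")
})

## ---- coercions -----------------------------------------------------------

#' Convert a GelDendrogram to a stats::hclust object
#'
#' Heights are kept in dissimilarity units (d = 100 - similarity), so the
#' standard \code{plot()}/\code{cophenetic()} machinery applies.
#'
#' @param tree a \linkS4class{GelDendrogram}.
#' @return an object of class \code{hclust}.
#' @export
asHclust <- function(tree) {
  stopifnot(is(tree, "GelDendrogram"))
  structure(list(merge = tree@merge, height = tree@height,
                 order = tree@order, labels = tree@labels,
                 method = "average", call = match.call(),
                 dist.method = "percent dissimilarity"),
            class = "hclust")
}
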