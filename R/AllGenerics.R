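#' @include AllClasses.R
NULL

#' Accessors for DGGEtools classes
#'
#' Small accessor generics so user code never reaches into slots:
#' \code{gelIntensity} and \code{laneSpans} for \linkS4class{GelImage};
#' \code{profileValues}, \code{profilePositions} and \code{laneIds} for
#' profiles; \code{presenceMatrix}, \code{intensityMatrix} and
#' \code{bandTable} for \linkS4class{FingerprintSet}; \code{classCenters}
#' and \code{classTolerance} for \linkS4class{BandClassTable};
#' \code{similarityValues} and \code{similarityMethod} for
#' \linkS4class{SimilarityMatrix}; \code{mergeHeights} and
#' \code{leafLabels} for \linkS4class{GelDendrogram};
#' \code{abundanceMatrix}, \code{laneInfo} and \code{speciesPool} for
#' \linkS4class{CommunityTrajectory}; \code{windowValues} and
#' \code{windowMeans} for \linkS4class{MovingWindowSeries}.
#'
#' @param x an object of the respective class.
#' @return The slot contents (matrix, vector or data.frame as documented
#'   in the class).
#' @name accessors
#' @aliases gelIntensity laneSpans bitDepth profileValues profilePositions
#'   laneIds presenceMatrix intensityMatrix bandTable bandClasses
#'   classCenters classTolerance similarityValues similarityMethod
#'   mergeHeights leafLabels abundanceMatrix laneInfo speciesPool
#'   windowValues windowMeans
NULL

#' @rdname accessors
#' @export
setGeneric("gelIntensity", function(x) standardGeneric("gelIntensity"))
#' @rdname accessors
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))
#' @rdname accessors
#' @export
setGeneric("laneSpans", function(x) standardGeneric("laneSpans"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("profilePositions", function(x) standardGeneric("profilePositions"))
#' @rdname accessors
#' @export
setGeneric("laneIds", function(x) standardGeneric("laneIds"))
#' @rdname accessors
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))
#' @rdname accessors
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))
#' @rdname accessors
#' @export
setGeneric("bandTable", function(x) standardGeneric("bandTable"))
#' @rdname accessors
#' @export
setGeneric("bandClasses", function(x) standardGeneric("bandClasses"))
#' @rdname accessors
#' @export
setGeneric("classCenters", function(x) standardGeneric("classCenters"))
#' @rdname accessors
#' @export
setGeneric("classTolerance", function(x) standardGeneric("classTolerance"))
#' @rdname accessors
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))
#' @rdname accessors
#' @export
setGeneric("similarityMethod", function(x) standardGeneric("similarityMethod"))
#' @rdname accessors
#' @export
setGeneric("mergeHeights", function(x) standardGeneric("mergeHeights"))
#' @rdname accessors
#' @export
setGeneric("leafLabels", function(x) standardGeneric("leafLabels"))
#' @rdname accessors
#' @export
setGeneric("abundanceMatrix", function(x) standardGeneric("abundanceMatrix"))
#' @rdname accessors
#' @export
setGeneric("laneInfo", function(x) standardGeneric("laneInfo"))
#' @rdname accessors
#' @export
setGeneric("speciesPool", function(x) standardGeneric("speciesPool"))
#' @rdname accessors
#' @export
setGeneric("windowValues", function(x) standardGeneric("windowValues"))
#' @rdname accessors
#' @export
setGeneric("windowMeans", function(x) standardGeneric("windowMeans"))

#' Compute ecology indices
#'
#' @param x a \linkS4class{FingerprintSet} (or binary vector for
#'   \code{richness}).
#' @param ... method-specific arguments.
#' @name ecology-generics
NULL

#' @rdname ecology-generics
#' @export
setGeneric("richness", function(x, ...) standardGeneric("richness"))

#' UPGMA clustering of a similarity matrix
#'
#' @param x a \linkS4class{SimilarityMatrix}.
#' @param ... unused.
#' @export
setGeneric("upgma", function(x, ...) standardGeneric("upgma"))

#' Newick serialization of a dendrogram
#'
#' @param x a \linkS4class{GelDendrogram}.
#' @param ... unused.
#' @export
setGeneric("toNewick", function(x, ...) standardGeneric("toNewick"))

#' Cophenetic similarity between two leaves
#'
#' @param x a \linkS4class{GelDendrogram}.
#' @param ... leaf labels.
#' @export
setGeneric("copheneticSimilarity",
           function(x, ...) standardGeneric("copheneticSimilarity"))
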