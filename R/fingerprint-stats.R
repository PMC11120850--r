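#' @include band-calling.R
NULL

#' Jaccard similarity of two binary fingerprints (percent)
#'
#' \eqn{100 |A \cap B| / |A \cup B|} over band classes present in either
#' lane. Two empty fingerprints are identical by convention and return
#' 100 with a warning.
#'
#' @param a,b equal-length 0/1 vectors over the same band classes.
#' @return percent similarity in [0, 100].
#' @export
jaccardSimilarity <- function(a, b) {
  if (length(a) != length(b))
    stop("fingerprint vectors differ in length (", length(a), " vs ",
         length(b), ")")
  a <- a != 0; b <- b != 0
  un <- sum(a | b)
  if (un == 0) {
    warning("both fingerprints are empty; identical by convention (100%)")
    return(100)
  }
  100 * sum(a & b) / un
}

#' Pearson similarity of two densitometric curves (percent)
#'
#' Product-moment correlation of the two profile value vectors, with
#' negative correlations clipped to zero before conversion to percent so
#' that the derived percent change (100 - similarity) stays in [0, 100].
#'
#' @param p,q \linkS4class{LaneProfile}s (or bare numeric vectors) of
#'   equal resampled length; neither may be constant.
#' @return percent similarity in [0, 100].
#' @export
pearsonSimilarity <- function(p, q) {
  pv <- if (is(p, "LaneProfile")) p@values else as.numeric(p)
  qv <- if (is(q, "LaneProfile")) q@values else as.numeric(q)
  if (length(pv) != length(qv))
    stop("profiles differ in length (", length(pv), " vs ", length(qv), ")")
  if (stats::sd(pv) == 0 || stats::sd(qv) == 0)
    stop("Pearson similarity is undefined for a constant profile")
  100 * max(0, stats::cor(pv, qv))
}

#' Pairwise similarity matrix over lanes
#'
#' Assembles all pairwise similarities of a set of lanes, computed once
#' per pair so the result is symmetric by construction.
#'
#' @param items a \linkS4class{FingerprintSet} (method \code{"jaccard"})
#'   or a \linkS4class{ProfileSet} (method \code{"pearson"}).
#' @param method similarity measure; defaults to the one matching the
#'   input type.
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
similarityMatrix <- function(items, method = NULL) {
  if (is(items, "FingerprintSet")) {
    if (is.null(method)) method <- "jaccard"
    if (method != "jaccard")
      stop("a FingerprintSet supports method 'jaccard' only; ",
           "pass a ProfileSet for 'pearson'")
    m <- presenceMatrix(items)
    ids <- rownames(m)
    getter <- function(i) m[i, ]
    fun <- jaccardSimilarity
  } else if (is(items, "ProfileSet")) {
    if (is.null(method)) method <- "pearson"
    if (method != "pearson")
      stop("a ProfileSet supports method 'pearson' only; ",
           "pass a FingerprintSet for 'jaccard'")
    m <- profileValues(items)
    ids <- colnames(m)
    getter <- function(i) m[, i]
    fun <- pearsonSimilarity
  } else {
    stop("items must be a FingerprintSet or a ProfileSet")
  }
  n <- length(ids)
  if (n < 2) stop("need at least 2 lanes")
  S <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      S[i, j] <- S[j, i] <- fun(getter(i), getter(j))
    }
  }
  new("SimilarityMatrix", values = S, method = method)
}
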