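#' @include fingerprint-stats.R
NULL

#' UPGMA clustering of a similarity matrix
#'
#' Classic unweighted pair group method with arithmetic mean, run on the
#' dissimilarity d = 100 - similarity. At each step the closest pair of
#' clusters is merged and distances to the new cluster are the
#' size-weighted means \eqn{d_{(ij)k} = (n_i d_{ik} + n_j d_{jk}) /
#' (n_i + n_j)}, which keeps cluster-to-cluster distances equal to the
#' mean pairwise leaf dissimilarity. Exact ties are broken toward the
#' smallest (row, column) index pair in the current cluster ordering, so
#' trees are reproducible (input-order dependent when ties exist).
#'
#' @param x a \linkS4class{SimilarityMatrix} with at least 2 lanes.
#' @param ... unused.
#' @return a \linkS4class{GelDendrogram}; merge heights are
#'   dissimilarities, so a merge at height 60 joins clusters of 40%
#'   mean similarity.
#' @export
setMethod("upgma", "SimilarityMatrix", function(x, ...) {
  S <- similarityValues(x)
  n <- nrow(S)
  if (n < 2) stop("need at least 2 lanes to cluster")
  D <- 100 - S
  labels <- rownames(S)
  active <- seq_len(n)            # positions into bookkeeping vectors
  code <- -seq_len(n)             # hclust codes: -leaf or +merge row
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(active)
    best <- c(NA_integer_, NA_integer_); bestD <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        dij <- D[active[i], active[j]]
        if (dij < bestD) { bestD <- dij; best <- c(i, j) }
      }
    }
    ai <- active[best[1]]; aj <- active[best[2]]
    ci <- code[ai]; cj <- code[aj]
    merge[step, ] <- if (ci < cj) c(ci, cj) else c(cj, ci)
    height[step] <- bestD
    ## size-weighted distance update (stored on ai's row/column)
    for (k in active) {
      if (k == ai || k == aj) next
      dk <- (size[ai] * D[ai, k] + size[aj] * D[aj, k]) /
        (size[ai] + size[aj])
      D[ai, k] <- D[k, ai] <- dk
    }
    size[ai] <- size[ai] + size[aj]
    code[ai] <- step
    active <- active[-best[2]]
  }
  ord <- .leafOrder(merge, n)
  new("GelDendrogram", merge = merge, height = height, labels = labels,
      order = ord)
})

## Leaf ordering for crossing-free plotting (standard hclust traversal).
.leafOrder <- function(merge, n) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  as.integer(rec(nrow(merge)))
}

## Leaves (1-based indices) under each merge row.
.mergeLeafSets <- function(tree) {
  m <- tree@merge
  sets <- vector("list", nrow(m))
  for (r in seq_len(nrow(m))) {
    kids <- m[r, ]
    sets[[r]] <- unlist(lapply(kids, function(k)
      if (k < 0) -k else sets[[k]]))
  }
  sets
}

#' @describeIn toNewick Serialize the dendrogram as a Newick string.
#'   Each node sits at depth (merge height)/2 as in standard dendrogram
#'   plots, so a branch's length is (parent height - child height)/2 and
#'   the tree-path distance between two leaves equals the dissimilarity
#'   at which they merge. The string round-trips through standard Newick
#'   parsers.
#' @param digits number of significant digits for branch lengths.
#' @export
setMethod("toNewick", "GelDendrogram", function(x, digits = 10, ...) {
  if (anyDuplicated(x@labels))
    stop("duplicate leaf ids cannot be serialized unambiguously")
  fmt <- function(v) sprintf("%.*g", digits, v)
  rec <- function(node, parentH) {
    if (node < 0) {
      lab <- x@labels[-node]
      return(paste0(lab, ":", fmt(parentH / 2)))
    }
    h <- x@height[node]
    paste0("(", rec(x@merge[node, 1], h), ",",
           rec(x@merge[node, 2], h), "):", fmt((parentH - h) / 2))
  }
  root <- nrow(x@merge)
  h <- x@height[root]
  paste0("(", rec(x@merge[root, 1], h), ",",
         rec(x@merge[root, 2], h), ");")
})

#' @describeIn copheneticSimilarity Percent similarity at which two lanes
#'   first join one cluster: 100 minus the merge height of their lowest
#'   common ancestor.
#' @param laneA,laneB leaf labels.
#' @export
setMethod("copheneticSimilarity", "GelDendrogram",
          function(x, laneA, laneB, ...) {
  ia <- match(laneA, x@labels)
  ib <- match(laneB, x@labels)
  if (is.na(ia)) stop("unknown leaf: ", laneA)
  if (is.na(ib)) stop("unknown leaf: ", laneB)
  if (ia == ib) return(100)
  sets <- .mergeLeafSets(x)
  for (r in seq_along(sets)) {            # rows are height-ordered
    if (ia %in% sets[[r]] && ib %in% sets[[r]])
      return(100 - x@height[r])
  }
  stop("tree has no common ancestor for the two leaves (invalid tree)")
})

#' Full cophenetic similarity matrix of a dendrogram
#'
#' @param tree a \linkS4class{GelDendrogram}.
#' @return a \linkS4class{SimilarityMatrix}-shaped base matrix of
#'   cophenetic percent similarities (the original method tag is not
#'   retained).
#' @export
copheneticMatrix <- function(tree) {
  stopifnot(is(tree, "GelDendrogram"))
  n <- length(tree@labels)
  M <- matrix(100, n, n, dimnames = list(tree@labels, tree@labels))
  sets <- .mergeLeafSets(tree)
  for (r in seq_along(sets)) {
    kids <- tree@merge[r, ]
    left <- if (kids[1] < 0) -kids[1] else sets[[kids[1]]]
    right <- if (kids[2] < 0) -kids[2] else sets[[kids[2]]]
    M[left, right] <- M[right, left] <- 100 - tree@height[r]
  }
  M
}
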