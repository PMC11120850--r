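# Independent oracles shared by the unit and acceptance tests.

# Naive UPGMA: at every step recompute each cluster pair's mean pairwise
# leaf dissimilarity from the ORIGINAL matrix (O(n^3) overall), merging
# the first minimal pair in cluster order.
naiveUpgma <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- NULL; bestD <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < bestD) { bestD <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestD)
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
    partitions[[length(partitions) + 1]] <- lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# Leaf sets under each merge row of a GelDendrogram, for topology checks.
leafSets <- function(tree) {
  m <- tree@merge
  sets <- vector("list", nrow(m))
  for (r in seq_len(nrow(m))) {
    sets[[r]] <- sort(unlist(lapply(m[r, ], function(k)
      if (k < 0) -k else sets[[k]])))
  }
  sets
}

randomSimilarity <- function(n, seed) {
  set.seed(seed)
  S <- matrix(runif(n * n, 0, 100), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 100
  dimnames(S) <- list(LETTERS[1:n], LETTERS[1:n])
  new("SimilarityMatrix", values = S, method = "pearson")
}

# Cache for the end-to-end default-condition simulations shared by the
# dynamics-related acceptance checks (each seed simulated once).
.accCache <- new.env(parent = emptyenv())
acceptanceRun <- function(seed) {
  key <- as.character(seed)
  if (is.null(.accCache[[key]]))
    .accCache[[key]] <- simulateAndProfile(seed)
  .accCache[[key]]
}
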