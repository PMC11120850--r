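#' @include image-processing.R
NULL

## Interior local maxima of a numeric vector (strict on at least one side,
## first point of any flat-top plateau).
.localMaxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  ## keep a flat-top plateau only if it eventually falls off to the right
  idx[vapply(idx, function(i) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    j < n && x[j + 1L] < x[i]
  }, logical(1))]
}

## Topographic prominence of peak i: height above the higher of the two
## key saddles, where each saddle is the minimum between the peak and the
## nearest higher ground (or the signal end) on that side.
.prominence <- function(x, i) {
  n <- length(x)
  h <- x[i]
  leftBase <- h
  j <- i - 1L
  lo <- h
  while (j >= 1L && x[j] <= h) { lo <- min(lo, x[j]); j <- j - 1L }
  leftBase <- lo
  j <- i + 1L
  lo <- h
  while (j <= n && x[j] <= h) { lo <- min(lo, x[j]); j <- j + 1L }
  rightBase <- lo
  h - max(leftBase, rightBase)
}

#' Call bands from a densitometric profile
#'
#' Bands are local maxima of the profile whose topographic prominence
#' reaches \code{minProminence} times the profile maximum (only bands of
#' appreciable intensity are profiled) and which are at least
#' \code{minSeparation} apart; when two candidate peaks are closer, the
#' taller one wins. Each band's area is integrated (trapezoid rule)
#' between the flanking minima separating it from its neighboring kept
#' bands.
#'
#' @param profile a \linkS4class{LaneProfile}.
#' @param minProminence required prominence as a fraction of the profile
#'   maximum, in (0, 1].
#' @param minSeparation minimum peak separation as a fraction of gel
#'   length.
#' @return data.frame sorted by position with columns \code{lane_id},
#'   \code{position}, \code{height}, \code{prominence}, \code{area}.
#'   An all-zero profile yields zero rows.
#' @export
callBands <- function(profile, minProminence = 0.05,
                      minSeparation = 0.01) {
  stopifnot(is(profile, "LaneProfile"),
            minProminence > 0, minProminence <= 1, minSeparation >= 0)
  x <- profile@values
  pos <- profile@positions
  empty <- data.frame(lane_id = character(), position = numeric(),
                      height = numeric(), prominence = numeric(),
                      area = numeric())
  if (all(x == 0)) return(empty)
  cand <- .localMaxima(x)
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(i) .prominence(x, i), numeric(1))
  keep <- prom >= minProminence * max(x)
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)
  ## enforce separation greedily, tallest peaks first
  ord <- order(x[cand], decreasing = TRUE)
  sel <- logical(length(cand))
  for (k in ord) {
    if (!any(sel & abs(pos[cand] - pos[cand[k]]) < minSeparation))
      sel[k] <- TRUE
  }
  cand <- cand[sel]; prom <- prom[sel]
  o <- order(cand)
  cand <- cand[o]; prom <- prom[o]
  ## support boundaries: minimum between consecutive kept peaks
  n <- length(x)
  bounds <- integer(length(cand) + 1L)
  bounds[1] <- 1L
  bounds[length(bounds)] <- n
  if (length(cand) > 1) {
    for (k in seq_len(length(cand) - 1L)) {
      seg <- cand[k]:cand[k + 1L]
      bounds[k + 1L] <- seg[which.min(x[seg])]
    }
  }
  area <- vapply(seq_along(cand), function(k) {
    i <- bounds[k]:bounds[k + 1L]
    sum(diff(pos[i]) * (x[i][-1] + x[i][-length(i)]) / 2)
  }, numeric(1))
  data.frame(lane_id = profile@laneId, position = pos[cand],
             height = x[cand], prominence = prom, area = area)
}

#' Build global band classes across lanes
#'
#' Single-linkage clustering of all called band positions in one
#' dimension: sorted positions are chained into one class while
#' consecutive gaps stay within \code{tolerance}; each class center is
#' the mean of its member positions. This mirrors how gel-analysis
#' software aligns bands across lanes so that presence/absence vectors
#' share a common feature space. Deterministic: positions are processed
#' in sorted order.
#'
#' @param bands data.frame with a \code{position} column (pooled over all
#'   lanes), or a bare numeric vector of positions.
#' @param tolerance maximum linking gap as a fraction of gel length.
#' @return a \linkS4class{BandClassTable}.
#' @export
buildBandClasses <- function(bands, tolerance = 0.01) {
  stopifnot(tolerance > 0)
  pos <- if (is.data.frame(bands)) bands$position else as.numeric(bands)
  if (!length(pos))
    return(new("BandClassTable", centers = numeric(), lower = numeric(),
               upper = numeric(), tolerance = tolerance))
  pos <- sort(pos)
  grp <- cumsum(c(1L, as.integer(diff(pos) > tolerance)))
  new("BandClassTable",
      centers = as.numeric(tapply(pos, grp, mean)),
      lower = as.numeric(tapply(pos, grp, min)),
      upper = as.numeric(tapply(pos, grp, max)),
      tolerance = tolerance)
}

#' Fingerprint one lane against a band-class table
#'
#' Assigns each called band to the nearest class center; a band farther
#' than the table's tolerance from every class's position extent signals
#' that the classes were not built from this lane's bands and raises an
#' error. Two bands of one
#' lane mapping to one class have their areas summed.
#'
#' @param bands data.frame from \code{\link{callBands}} for one lane.
#' @param classes a \linkS4class{BandClassTable}.
#' @return list with \code{binary} (0/1 over classes), \code{intensity}
#'   (summed band area per class) and \code{class_index} (per input
#'   band).
#' @export
fingerprintLane <- function(bands, classes) {
  stopifnot(is(classes, "BandClassTable"))
  ctr <- classes@centers
  nC <- length(ctr)
  binary <- numeric(nC)
  intensity <- numeric(nC)
  if (nrow(bands) == 0)
    return(list(binary = binary, intensity = intensity,
                class_index = integer()))
  if (nC == 0)
    stop("band-class table is empty but the lane has bands")
  idx <- vapply(bands$position, function(p) which.min(abs(ctr - p)),
                integer(1))
  ## a chained class can span more than one tolerance around its center,
  ## so membership is judged against the class extent, not the center
  off <- pmax(0, classes@lower[idx] - bands$position,
              bands$position - classes@upper[idx])
  if (any(off > classes@tolerance))
    stop("band at position ", bands$position[which.max(off)],
         " is farther than the tolerance (", classes@tolerance,
         ") from every band class; classes and bands do not match")
  for (k in seq_along(idx)) intensity[idx[k]] <- intensity[idx[k]] +
      bands$area[k]
  binary[intensity > 0] <- 1
  list(binary = binary, intensity = intensity, class_index = idx)
}

#' Fingerprint all lanes of a ProfileSet
#'
#' Calls bands on every lane, builds the global band-class table from the
#' pooled positions, and assembles the lanes x classes presence and
#' intensity (band-area) matrices.
#'
#' @param profiles a \linkS4class{ProfileSet}.
#' @param minProminence,minSeparation see \code{\link{callBands}}.
#' @param tolerance band-class matching tolerance, see
#'   \code{\link{buildBandClasses}}.
#' @return a \linkS4class{FingerprintSet}.
#' @export
fingerprintGel <- function(profiles, minProminence = 0.05,
                           minSeparation = 0.01, tolerance = 0.01) {
  stopifnot(is(profiles, "ProfileSet"))
  ids <- laneIds(profiles)
  vals <- profileValues(profiles)
  pos <- profilePositions(profiles)
  bandList <- lapply(seq_along(ids), function(j)
    callBands(LaneProfile(ids[j], vals[, j], pos),
              minProminence, minSeparation))
  allBands <- do.call(rbind, bandList)
  classes <- buildBandClasses(allBands, tolerance)
  nC <- length(classes@centers)
  presence <- matrix(0, length(ids), nC,
                     dimnames = list(ids, NULL))
  intensity <- presence
  tagged <- list()
  for (j in seq_along(ids)) {
    fp <- fingerprintLane(bandList[[j]], classes)
    presence[j, ] <- fp$binary
    intensity[j, ] <- fp$intensity
    b <- bandList[[j]]
    if (nrow(b)) b$class_index <- fp$class_index
    tagged[[j]] <- b
  }
  bands <- do.call(rbind, tagged)
  if (is.null(bands))
    bands <- data.frame(lane_id = character(), position = numeric(),
                        height = numeric(), prominence = numeric(),
                        area = numeric(), class_index = integer())
  rownames(bands) <- NULL
  new("FingerprintSet", presence = presence, intensity = intensity,
      classes = classes, bands = bands)
}
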