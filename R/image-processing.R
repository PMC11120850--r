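#' @include methods.R
NULL

## Centered running minimum / maximum with window w (odd effective width),
## truncated at the signal ends. w is small relative to length, so the
## direct scan is plenty fast for profile-sized vectors.
.runningExtreme <- function(x, w, fun) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i)
    fun(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}

## 1-D grayscale morphological opening: erosion (running min) followed by
## dilation (running max) with the same flat structuring element.
.opening <- function(x, w) {
  .runningExtreme(.runningExtreme(x, w, min), w, max)
}

#' Detect lane column spans in a gel image
#'
#' Lanes are located as the strongest peaks of the smoothed column-sum
#' intensity projection. When fewer than \code{expectedLanes} projection
#' peaks exist (e.g. a blank image), the width is partitioned uniformly
#' and a warning is emitted.
#'
#' @param image a \linkS4class{GelImage}.
#' @param expectedLanes number of lanes to find (>= 1).
#' @param smoothWindow smoothing window for the projection, as a fraction
#'   of image width.
#' @return data.frame with columns \code{lane}, \code{from}, \code{to}:
#'   non-overlapping column spans ordered left to right.
#' @export
detectLanes <- function(image, expectedLanes, smoothWindow = 0.02) {
  stopifnot(is(image, "GelImage"), expectedLanes >= 1)
  W <- ncol(image@intensity)
  if (W < expectedLanes)
    stop("image has ", W, " columns, fewer than ", expectedLanes, " lanes")
  if (expectedLanes == 1L)
    return(data.frame(lane = 1L, from = 1L, to = W))
  proj <- colSums(image@intensity)
  w <- max(3L, round(smoothWindow * W))
  if (w %% 2 == 0) w <- w + 1L
  kern <- rep(1 / w, w)
  sm <- as.numeric(stats::filter(proj, kern, sides = 2))
  h <- (w - 1L) %/% 2L
  ## fill the filter's edge NAs with truncated-window means
  for (i in seq_len(h)) {
    sm[i] <- mean(proj[1:(i + h)])
    sm[W - i + 1L] <- mean(proj[(W - i + 1L - h):W])
  }
  locmax <- which(diff(sign(diff(sm))) < 0) + 1L
  locmax <- locmax[sm[locmax] > min(sm) + 1e-12]
  ## plateau tops yield adjacent candidates; keep the strongest peaks
  ## subject to a minimum spacing of half a nominal lane pitch
  minSep <- max(2L, floor(W / (2L * expectedLanes)))
  keep <- integer()
  for (i in locmax[order(sm[locmax], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= minSep))
      keep <- c(keep, i)
  }
  locmax <- keep[seq_len(min(length(keep), expectedLanes))]
  if (length(locmax) < expectedLanes) {
    warning("found ", length(locmax), " projection peaks for ",
            expectedLanes, " expected lanes; falling back to a uniform ",
            "partition")
    edges <- round(seq(0, W, length.out = expectedLanes + 1L))
    return(data.frame(lane = seq_len(expectedLanes),
                      from = edges[-length(edges)] + 1L,
                      to = edges[-1]))
  }
  centers <- sort(locmax)
  ## span edges: midpoints between adjacent centers; outer edges extend by
  ## half the median lane pitch, clipped to the image
  mid <- floor((centers[-1] + centers[-length(centers)]) / 2)
  half <- round(stats::median(diff(centers)) / 2)
  from <- c(max(1L, centers[1] - half), mid + 1L)
  to <- c(mid, min(W, centers[length(centers)] + half))
  data.frame(lane = seq_len(expectedLanes), from = as.integer(from),
             to = as.integer(to))
}

#' Extract a lane's densitometric profile
#'
#' The profile value at each migration row is the mean intensity across
#' the span's columns, making the curve invariant to lane width.
#'
#' @param image a \linkS4class{GelImage}.
#' @param span a one-row data.frame (or list) with \code{from}/\code{to}
#'   column indices.
#' @param laneId label for the resulting profile.
#' @return a \linkS4class{LaneProfile} of length \code{nrow(image)}.
#' @export
extractProfile <- function(image, span, laneId = "lane") {
  stopifnot(is(image, "GelImage"))
  from <- as.integer(span$from %||% span[[1]])
  to <- as.integer(span$to %||% span[[2]])
  W <- ncol(image@intensity)
  if (is.na(from) || is.na(to) || from > to)
    stop("empty lane span")
  if (from < 1 || to > W)
    stop("span [", from, ", ", to, "] outside image width ", W)
  vals <- rowMeans(image@intensity[, from:to, drop = FALSE])
  LaneProfile(laneId, vals)
}

#' Subtract the slowly varying background from a profile
#'
#' The background estimate is the 1-D grayscale morphological opening of
#' the profile (running minimum then running maximum over a window wider
#' than any band), which passes broad baseline trends but not the narrow
#' band peaks. The result is the profile minus this baseline, floored at
#' zero.
#'
#' @param profile a \linkS4class{LaneProfile}.
#' @param window structuring-element width as a fraction of profile
#'   length, in (0, 1); must round to at least 3 samples.
#' @return a background-corrected \linkS4class{LaneProfile}.
#' @export
subtractBackground <- function(profile, window = 0.1) {
  stopifnot(is(profile, "LaneProfile"), window > 0, window < 1)
  n <- length(profile@values)
  w <- round(window * n)
  if (w < 3)
    stop("background window rounds to ", w,
         " samples (< 3) at profile length ", n)
  bg <- .opening(profile@values, w)
  LaneProfile(profile@laneId, pmax(profile@values - bg, 0),
              profile@positions)
}

#' Resample and normalize a profile
#'
#' Linearly interpolates the profile onto a uniform [0, 1] grid of
#' \code{resolution} points, then normalizes by total area
#' (\code{mode = "total"}, so Pearson comparisons are not dominated by
#' exposure differences) or by the maximum (\code{mode = "max"}). An
#' all-zero profile is resampled but passed through unnormalized with a
#' warning.
#'
#' @param profile a \linkS4class{LaneProfile}.
#' @param resolution number of resampled points (>= 32; default 500).
#' @param mode \code{"total"} or \code{"max"}.
#' @return a normalized \linkS4class{LaneProfile} of length
#'   \code{resolution}.
#' @export
normalizeProfile <- function(profile, resolution = 500L,
                             mode = c("total", "max")) {
  stopifnot(is(profile, "LaneProfile"), resolution >= 32)
  mode <- match.arg(mode)
  grid <- seq(0, 1, length.out = resolution)
  v <- stats::approx(profile@positions, profile@values, xout = grid,
                     rule = 2)$y
  if (all(v == 0)) {
    warning("all-zero profile passed through unnormalized")
    return(LaneProfile(profile@laneId, v, grid))
  }
  v <- switch(mode, total = v / sum(v), max = v / max(v))
  LaneProfile(profile@laneId, v, grid)
}

#' Process a gel image into a ProfileSet
#'
#' Convenience wrapper chaining \code{\link{detectLanes}} (or the image's
#' known spans), \code{\link{extractProfile}},
#' \code{\link{subtractBackground}} and \code{\link{normalizeProfile}}
#' over all lanes of one image.
#'
#' @param image a \linkS4class{GelImage}.
#' @param laneData per-lane metadata data.frame with a \code{lane} column
#'   (ids, temperature, day, ...); its row count sets the expected lane
#'   count.
#' @param backgroundWindow,resolution,mode processing parameters, see the
#'   individual steps.
#' @param useKnownSpans use \code{laneSpans(image)} when present instead
#'   of re-detecting.
#' @return a \linkS4class{ProfileSet} with one column per lane.
#' @export
processGel <- function(image, laneData, backgroundWindow = 0.1,
                       resolution = 500L, mode = "total",
                       useKnownSpans = FALSE) {
  stopifnot(is(image, "GelImage"), "lane" %in% names(laneData))
  nL <- nrow(laneData)
  spans <- if (useKnownSpans && nrow(image@laneSpans) >= nL)
    image@laneSpans[seq_len(nL), ] else detectLanes(image, nL)
  mat <- matrix(0, resolution, nL)
  for (j in seq_len(nL)) {
    p <- extractProfile(image, spans[j, ], laneId = laneData$lane[j])
    p <- subtractBackground(p, backgroundWindow)
    p <- normalizeProfile(p, resolution, mode)
    mat[, j] <- profileValues(p)
  }
  ProfileSet(mat, seq(0, 1, length.out = resolution), laneData)
}
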