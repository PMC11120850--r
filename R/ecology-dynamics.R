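#' @include clustering.R
NULL

#' @describeIn richness Band-count richness of each lane: the number of
#'   band classes present (the number of 1s in the binary fingerprint),
#'   used as a proxy for the carrying capacity of the community.
#' @export
setMethod("richness", "FingerprintSet", function(x, ...) {
  rowSums(presenceMatrix(x))
})

#' @describeIn richness Richness of a bare binary vector.
#' @export
setMethod("richness", "numeric", function(x, ...) sum(x != 0))

#' Community organization (Gini percent) of one lane's band intensities
#'
#' The Gini coefficient of the band areas, expressed as a percentage:
#' \eqn{Co = 100 \, G}, \eqn{G = \sum_i (2i - n - 1) x_i / (n^2 \mu)}
#' with the intensities sorted ascending and \eqn{\mu} their mean. Equal
#' band intensities (perfect evenness) give 0; a single overwhelmingly
#' dominant band pushes Co toward 100. Zero-intensity classes are
#' absences, not bands, and are rejected.
#'
#' @param intensities positive band areas of one lane (n >= 1).
#' @return Co in [0, 100].
#' @export
communityOrganization <- function(intensities) {
  x <- as.numeric(intensities)
  if (length(x) < 1) stop("need at least one band intensity")
  if (any(x <= 0))
    stop("band intensities must be positive; drop absent classes first")
  n <- length(x)
  x <- sort(x)
  g <- sum((2 * seq_len(n) - n - 1) * x) / (n^2 * mean(x))
  100 * g
}

#' Pareto-Lorenz curve of band intensities
#'
#' Points (k/n, cumulative intensity share of the k smallest bands) for
#' k = 0..n: the Lorenz curve underlying the Gini-based community
#' organization. Starts at (0, 0), ends at (1, 1), and is convex; the
#' further it bows below the diagonal, the more uneven the community.
#'
#' @param intensities positive band areas of one lane.
#' @return data.frame with columns \code{fraction_bands},
#'   \code{fraction_intensity}.
#' @export
lorenzCurve <- function(intensities) {
  x <- as.numeric(intensities)
  if (length(x) < 1) stop("need at least one band intensity")
  if (any(x <= 0))
    stop("band intensities must be positive; drop absent classes first")
  x <- sort(x)
  n <- length(x)
  data.frame(fraction_bands = (0:n) / n,
             fraction_intensity = c(0, cumsum(x)) / sum(x))
}

#' Percent change from percent similarity
#'
#' The moving-window statistic: \code{100 - similarity}.
#'
#' @param similarity percent similarity in [0, 100].
#' @return percent change in [0, 100].
#' @export
percentChange <- function(similarity) {
  if (any(similarity < 0 | similarity > 100))
    stop("similarity must lie in [0, 100]")
  100 - similarity
}

#' Moving-window analysis of community dynamics
#'
#' For every reactor and every pair of consecutive sampling days, the
#' percent change is 100 minus the Pearson similarity of the two
#' densitometric curves; per temperature, the mean across replicate
#' reactors summarizes each interval. Plotted against the interval's end
#' day this is the moving-window curve; higher values mean faster
#' community turnover. The first interval (day 0 to the first sampled
#' day) is computed and flagged via \code{is_first_interval} so
#' presentations that start at the second interval can drop it without
#' losing information.
#'
#' @param profiles a \linkS4class{ProfileSet} whose \code{colData}
#'   carries \code{temperature}, \code{reactor} and \code{day} for every
#'   lane.
#' @param design the \code{\link{experimentDesign}}; every (temperature,
#'   reactor, day) combination must have exactly one profile.
#' @return a \linkS4class{MovingWindowSeries}.
#' @export
movingWindow <- function(profiles, design) {
  stopifnot(is(profiles, "ProfileSet"), inherits(design, "ExperimentDesign"))
  cd <- as.data.frame(colData(profiles))
  need <- c("temperature", "reactor", "day")
  if (!all(need %in% names(cd)))
    stop("profile colData must carry temperature, reactor and day")
  vals <- profileValues(profiles)
  days <- design$samplingDays
  out <- list()
  for (temp in design$temperatures) {
    for (r in seq_len(design$reactorsPerTemperature)) {
      idx <- vapply(days, function(d) {
        w <- which(cd$temperature == temp & cd$reactor == r & cd$day == d)
        if (length(w) != 1)
          stop("need exactly one profile for temperature ", temp,
               ", reactor ", r, ", day ", d, " (found ", length(w), ")")
        w
      }, integer(1))
      for (k in seq_len(length(days) - 1L)) {
        pc <- percentChange(
          pearsonSimilarity(vals[, idx[k]], vals[, idx[k + 1L]]))
        out[[length(out) + 1L]] <- data.frame(
          temperature = temp, interval_start = days[k],
          interval_end = days[k + 1L], reactor = r, pct_change = pc,
          is_first_interval = k == 1L)
      }
    }
  }
  values <- do.call(rbind, out)
  agg <- stats::aggregate(
    pct_change ~ temperature + interval_start + interval_end, values, mean)
  cnt <- stats::aggregate(
    pct_change ~ temperature + interval_start + interval_end, values, length)
  means <- data.frame(agg[c("temperature", "interval_start", "interval_end")],
                      mean_pct_change = agg$pct_change, n = cnt$pct_change)
  means <- means[order(means$temperature, means$interval_end), ]
  rownames(means) <- NULL
  new("MovingWindowSeries", values = values, means = means)
}

#' Rate of change per temperature
#'
#' Averages the per-interval mean percent change of each temperature's
#' moving-window series into a single turnover-speed summary. With equal
#' replicate counts per interval this equals the flat mean over all
#' per-reactor values.
#'
#' @param series a \linkS4class{MovingWindowSeries}.
#' @param dropFirstInterval drop the interval starting at the first
#'   sampling day before averaging (default FALSE).
#' @return named numeric vector of percent rates, one per temperature.
#' @export
rateOfChange <- function(series, dropFirstInterval = FALSE) {
  stopifnot(is(series, "MovingWindowSeries"))
  m <- windowMeans(series)
  if (dropFirstInterval) {
    first <- min(m$interval_start)
    m <- m[m$interval_start != first, , drop = FALSE]
  }
  if (!nrow(m)) stop("no intervals left to average")
  out <- tapply(m$mean_pct_change, m$temperature, mean)
  stats::setNames(as.numeric(out), names(out))
}
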