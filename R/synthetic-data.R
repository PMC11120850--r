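#' @include methods.R
NULL

## Deterministic named-stream seeding: every stochastic stage draws from a
## seed derived from (global seed, stream name), so stages can be re-run
## independently and re-runs are reproducible. Kept below 2^31 - 1.
.streamSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(as.numeric(seed)) %% 1e6) * 1013 + h * 97) %% 2147483587L
}

#' Build a random species pool
#'
#' Each species is a distinct 16S fragment with a fixed melting position
#' along the denaturant gradient (fraction of gel length, 0 = well) and a
#' per-species amplification factor modelling PCR/staining bias. DGGE
#' separates same-length fragments by melting behaviour, so position
#' encodes sequence, not size.
#'
#' Positions are drawn uniformly on \code{positionRange} but constrained
#' to distinct cells of the profile-resolution grid, so no two species can
#' co-migrate at the resolution downstream profiles are sampled at.
#'
#' @param nSpecies number of species (>= 1).
#' @param seed integer seed; same (nSpecies, seed) gives the same pool.
#' @param resolution profile grid resolution used for the collision check
#'   (default 500).
#' @param positionRange admissible melting positions (default
#'   \code{c(0.05, 0.95)}, keeping bands off the gel edges).
#' @param amplificationSdLog log-sd of the lognormal amplification factors.
#' @return data.frame with columns \code{species_id},
#'   \code{melting_position}, \code{amplification_factor}.
#' @export
buildSpeciesPool <- function(nSpecies, seed, resolution = 500L,
                             positionRange = c(0.05, 0.95),
                             amplificationSdLog = 0.25) {
  stopifnot(nSpecies >= 1, resolution >= 32)
  lo <- ceiling(positionRange[1] * (resolution - 1))
  hi <- floor(positionRange[2] * (resolution - 1))
  cells <- lo:hi
  if (nSpecies > length(cells))
    stop("cannot place ", nSpecies, " species without collision at ",
         "profile resolution ", resolution, " (", length(cells),
         " distinct positions available)")
  set.seed(.streamSeed(seed, "species-pool"))
  pos <- sort(sample(cells, nSpecies)) / (resolution - 1)
  amp <- stats::rlnorm(nSpecies, meanlog = 0, sdlog = amplificationSdLog)
  data.frame(species_id = seq_len(nSpecies),
             melting_position = pos,
             amplification_factor = amp)
}

#' Experiment design: temperatures x reactors x sampling days
#'
#' Defaults reproduce a 4-temperature anaerobic-digestion layout:
#' 28/36/44/52 deg C, 3 replicate reactors per temperature, sampled at
#' days 0, 7, 14, 30 and 60 (12 reactors, 60 lanes in total).
#'
#' @param temperatures numeric temperatures (deg C).
#' @param reactorsPerTemperature replicate reactors per temperature.
#' @param samplingDays strictly increasing integer days.
#' @return a list of class \code{"ExperimentDesign"}.
#' @export
experimentDesign <- function(temperatures = c(28, 36, 44, 52),
                             reactorsPerTemperature = 3L,
                             samplingDays = c(0L, 7L, 14L, 30L, 60L)) {
  samplingDays <- as.integer(samplingDays)
  if (length(samplingDays) < 1 || is.unsorted(samplingDays, strictly = TRUE))
    stop("samplingDays must be strictly increasing")
  stopifnot(reactorsPerTemperature >= 1, length(temperatures) >= 1,
            !anyDuplicated(temperatures))
  structure(list(temperatures = temperatures,
                 reactorsPerTemperature = as.integer(reactorsPerTemperature),
                 samplingDays = samplingDays),
            class = "ExperimentDesign")
}

#' Community shift model
#'
#' Parametrizes how each temperature's community turns over between
#' sampling days. Per interval a fraction
#' \eqn{f_k = 1 - (1 - rate)^{w_k K}} of abundance mass (K = number of
#' intervals, \eqn{w_k} the interval weights summing to 1) moves from the
#' currently dominant species to species previously at or below the
#' detection limit (band appearance/disappearance, the phenomenon DGGE
#' tracks). With uniform weights \eqn{f_k = rate} in every interval, so
#' the rate reads as the fraction of the community replaced per sampling
#' interval; concentrated weights shift that turnover early
#' (thermophilic-like) or late (mesophilic-like) while keeping
#' \eqn{f_k < 1}. The richness trajectory sets the expected number of
#' detectable species per sampling day.
#'
#' Defaults: turnover rates 0.25/0.40/0.55/0.70 for 28/36/44/52 deg C
#' (turnover increases with temperature, spaced so the Pearson percent
#' change neither saturates at the thermophilic end nor collapses into
#' noise at 28 deg C), weights peaking at the interval ending day 30 for
#' mesophilic and day 14 for thermophilic temperatures, richness
#' 4/6/5/5/9 over days 0/7/14/30/60, between-reactor jitter 0.15.
#'
#' @param temperatures temperatures the model covers.
#' @param turnoverRate per-temperature total turnover fraction in [0, 1].
#' @param intervalWeights list (one numeric vector per temperature) of
#'   nonnegative weights over the inter-day intervals, each summing to 1.
#' @param richnessTrajectory list (one integer vector per temperature) of
#'   expected detectable-species counts, one per sampling day.
#' @param replicateJitter lognormal sd of per-reactor abundance jitter.
#' @param detectionLimit relative abundance below which a species counts
#'   as absent (default 0.01).
#' @return a list of class \code{"ShiftModel"}.
#' @export
shiftModel <- function(temperatures = c(28, 36, 44, 52),
                       turnoverRate = c(0.25, 0.40, 0.55, 0.70),
                       intervalWeights = NULL,
                       richnessTrajectory = NULL,
                       replicateJitter = 0.15,
                       detectionLimit = 0.01) {
  nT <- length(temperatures)
  if (length(turnoverRate) == 1L) turnoverRate <- rep(turnoverRate, nT)
  stopifnot(length(turnoverRate) == nT,
            all(turnoverRate >= 0), all(turnoverRate <= 1),
            replicateJitter >= 0, detectionLimit >= 0, detectionLimit < 1)
  if (is.null(intervalWeights)) {
    mesoW   <- c(0.15, 0.25, 0.40, 0.20)  # peak on the day-14 -> 30 interval
    thermoW <- c(0.20, 0.45, 0.20, 0.15)  # peak on the day-7 -> 14 interval
    intervalWeights <- lapply(temperatures,
                              function(t) if (t >= 40) thermoW else mesoW)
  }
  if (is.numeric(intervalWeights))
    intervalWeights <- rep(list(intervalWeights), nT)
  if (is.null(richnessTrajectory))
    richnessTrajectory <- rep(list(c(4L, 6L, 5L, 5L, 9L)), nT)
  if (is.numeric(richnessTrajectory))
    richnessTrajectory <- rep(list(as.integer(richnessTrajectory)), nT)
  stopifnot(length(intervalWeights) == nT, length(richnessTrajectory) == nT)
  for (w in intervalWeights) {
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
      stop("interval weights must be nonnegative and sum to 1 ",
           "for every temperature")
  }
  names(intervalWeights) <- names(richnessTrajectory) <-
    names(turnoverRate) <- as.character(temperatures)
  structure(list(temperatures = temperatures,
                 turnoverRate = turnoverRate,
                 intervalWeights = intervalWeights,
                 richnessTrajectory = richnessTrajectory,
                 replicateJitter = replicateJitter,
                 detectionLimit = detectionLimit),
            class = "ShiftModel")
}

## Remove total mass f from the most abundant species by water-filling:
## the largest abundances are lowered to a common cap chosen so exactly f
## is removed. Dominants lose mass first; minor species are untouched.
.removeFromDominants <- function(a, f) {
  if (f <= 0) return(a)
  if (f >= sum(a)) stop("cannot remove more mass than present")
  s <- sort(a[a > 0], decreasing = TRUE)
  cum <- cumsum(s)
  cap <- (cum[length(s)] - f) / length(s)
  for (k in seq_along(s)) {
    ck <- (cum[k] - f) / k
    if (k == length(s) || ck >= s[k + 1]) { cap <- ck; break }
  }
  pmin(a, cap)
}

## One temperature's shared (pre-jitter) trajectory: species x days matrix.
.simulateBaseTrajectory <- function(days, rate, weights, richness, pool,
                                    detectionLimit, seed) {
  nS <- nrow(pool)
  nInt <- length(days) - 1L
  if (length(weights) != nInt)
    stop("need one interval weight per consecutive day pair (", nInt, ")")
  if (length(richness) != length(days))
    stop("need one richness value per sampling day")
  if (max(richness) > nS)
    stop("richness trajectory requests ", max(richness),
         " species but the pool has only ", nS)
  set.seed(seed)
  traj <- matrix(0, nS, length(days))
  ## Day 0: the initial feedstock community sits near the top of the gel
  ## (low melting positions), with one clearly dominant member.
  init <- order(pool$melting_position)[seq_len(richness[1])]
  w0 <- 0.55^(seq_along(init) - 1)
  a <- numeric(nS)
  a[init] <- w0 / sum(w0)
  traj[, 1] <- a
  for (k in seq_len(nInt)) {
    ## rate = fraction of mass replaced per interval at uniform timing;
    ## the weights reshape timing while keeping f in [0, 1): with
    ## exponent w * nInt the uniform-weight case gives f = rate exactly
    f <- 1 - (1 - rate)^(weights[k] * nInt)
    f <- min(f, 0.995)
    if (f > 0) {
      rNext <- richness[k + 1L]
      absent <- which(a == 0)
      ## the moved mass comes half proportionally from everyone and half
      ## from the most dominant species (water-filling), so a strongly
      ## dominant initial band fades over time while the decline in
      ## profile similarity stays graded in f
      a <- a * (1 - f / 2)
      a <- .removeFromDominants(a, sum(a) - (1 - f))
      ## replacement breadth scales with the moved fraction: at least the
      ## richness shortfall, at least one new band whenever mass moves
      surv <- sum(a >= detectionLimit)
      m <- max(rNext - surv, round(f * rNext), 1L)
      m <- min(m, length(absent), rNext)
      recruits <- sample(absent, m)
      share <- stats::rexp(m)
      share <- 0.5 * share / sum(share) + 0.5 / m
      a[recruits] <- f * share
      det <- which(a >= detectionLimit)
      if (length(det) > rNext) {
        drop <- det[order(a[det])][seq_len(length(det) - rNext)]
        a[drop] <- 0
      }
      a <- a / sum(a)
    }
    traj[, k + 1L] <- a
  }
  traj
}

#' Simulate ground-truth community trajectories
#'
#' Runs the \code{\link{shiftModel}} over the \code{\link{experimentDesign}}:
#' each temperature gets a shared turnover trajectory (same recruitment
#' events in all its reactors), and each reactor applies a fixed lognormal
#' abundance jitter, so replicates are similar but not identical and all
#' Day-0 communities agree up to jitter.
#'
#' @param design an \code{\link{experimentDesign}}.
#' @param shift a \code{\link{shiftModel}} covering every design temperature.
#' @param pool a species pool from \code{\link{buildSpeciesPool}}.
#' @param seed integer seed.
#' @return a \linkS4class{CommunityTrajectory}; lanes are ordered by day,
#'   then temperature, then reactor.
#' @export
simulateTrajectories <- function(design, shift, pool, seed) {
  stopifnot(inherits(design, "ExperimentDesign"),
            inherits(shift, "ShiftModel"))
  if (!all(design$temperatures %in% shift$temperatures))
    stop("shift model must define parameters for every design temperature")
  days <- design$samplingDays
  nS <- nrow(pool)
  cols <- list()
  info <- list()
  for (temp in design$temperatures) {
    key <- as.character(temp)
    base <- .simulateBaseTrajectory(
      days, shift$turnoverRate[[key]], shift$intervalWeights[[key]],
      shift$richnessTrajectory[[key]], pool, shift$detectionLimit,
      .streamSeed(seed, paste0("trajectory-", key)))
    for (r in seq_len(design$reactorsPerTemperature)) {
      set.seed(.streamSeed(seed, paste0("jitter-", key, "-", r)))
      jit <- exp(stats::rnorm(nS, 0, shift$replicateJitter))
      for (k in seq_along(days)) {
        v <- base[, k] * jit
        v <- v / sum(v)
        lane <- sprintf("T%g_R%d_D%02d", temp, r, days[k])
        cols[[lane]] <- v
        info[[lane]] <- data.frame(lane = lane, temperature = temp,
                                   reactor = r, day = days[k])
      }
    }
  }
  laneInfo <- do.call(rbind, info)
  ord <- order(laneInfo$day, laneInfo$temperature, laneInfo$reactor)
  laneInfo <- laneInfo[ord, , drop = FALSE]
  rownames(laneInfo) <- NULL
  ab <- do.call(cbind, cols)[, laneInfo$lane, drop = FALSE]
  new("CommunityTrajectory", abundance = ab, laneInfo = laneInfo,
      pool = pool)
}

#' Gel rendering configuration
#'
#' Geometry and noise model for turning abundance vectors into a synthetic
#' gel photograph. Species render as 2-D Gaussian bands; the background is
#' a vertical linear ramp plus additive Gaussian noise, mimicking uneven
#' staining and camera noise.
#'
#' @param nLanes lanes per image.
#' @param height image height in pixels (migration axis).
#' @param laneWidth,laneGap lane width and inter-lane gap in pixels; image
#'   width is \code{nLanes * (laneWidth + laneGap) + laneGap}.
#' @param bandSigma band sd along the migration axis (px).
#' @param lateralSigma band sd across the lane (px).
#' @param peakAmplitude intensity of a hypothetical band with relative
#'   abundance 1 and amplification factor 1.
#' @param background,backgroundGradient baseline intensity at the well and
#'   its increase toward the gel bottom.
#' @param noiseSigma sd of additive Gaussian noise (intensity units).
#' @param detectionLimit relative abundance below which a species renders
#'   no band (default 0.01).
#' @param bitDepth 8 or 16.
#' @return a list of class \code{"GelRenderConfig"}.
#' @export
gelRenderConfig <- function(nLanes = 12L, height = 400L, laneWidth = 28L,
                            laneGap = 8L, bandSigma = 3, lateralSigma = 7,
                            peakAmplitude = 30000, background = 1000,
                            backgroundGradient = 500, noiseSigma = 15,
                            detectionLimit = 0.01, bitDepth = 16L) {
  stopifnot(bandSigma > 0, lateralSigma > 0, detectionLimit >= 0,
            detectionLimit < 1, bitDepth %in% c(8L, 16L), nLanes >= 1,
            height >= 64, laneWidth >= 3, laneGap >= 0, noiseSigma >= 0)
  if (bitDepth == 8L && peakAmplitude == 30000) peakAmplitude <- 180
  cfg <- list(nLanes = as.integer(nLanes), height = as.integer(height),
              laneWidth = as.integer(laneWidth), laneGap = as.integer(laneGap),
              bandSigma = bandSigma, lateralSigma = lateralSigma,
              peakAmplitude = peakAmplitude, background = background,
              backgroundGradient = backgroundGradient,
              noiseSigma = noiseSigma, detectionLimit = detectionLimit,
              bitDepth = as.integer(bitDepth))
  cfg$width <- cfg$nLanes * (cfg$laneWidth + cfg$laneGap) + cfg$laneGap
  structure(cfg, class = "GelRenderConfig")
}

## Lane center columns (1-based) for a render config.
.laneCenters <- function(cfg) {
  pitch <- cfg$laneWidth + cfg$laneGap
  cfg$laneGap + (seq_len(cfg$nLanes) - 1L) * pitch + (cfg$laneWidth + 1) / 2
}

#' Render abundance vectors to a synthetic gel image
#'
#' Every species whose relative abundance reaches the detection limit
#' contributes a 2-D Gaussian band centred at (melting position x gel
#' height, lane centre) with peak amplitude proportional to abundance x
#' amplification factor. Background ramp and additive noise are applied
#' and intensities clipped (never wrapped) to the configured bit depth;
#' clipping emits a warning.
#'
#' @param lanes species x lanes abundance matrix (columns sum to 1), or a
#'   list of abundance vectors.
#' @param pool species pool matching the rows of \code{lanes}.
#' @param cfg a \code{\link{gelRenderConfig}}; must provide at least as
#'   many lanes as supplied.
#' @param seed integer seed (noise only).
#' @param laneIds optional lane labels.
#' @return list with \code{image} (a \linkS4class{GelImage} with known
#'   lane spans) and \code{truth}, the ground-truth band table
#'   (lane, lane_id, species_id, position_fraction, amplitude).
#' @export
renderGel <- function(lanes, pool, cfg = gelRenderConfig(), seed = 1L,
                      laneIds = NULL) {
  if (is.list(lanes) && !is.matrix(lanes)) lanes <- do.call(cbind, lanes)
  lanes <- as.matrix(lanes)
  stopifnot(inherits(cfg, "GelRenderConfig"), nrow(lanes) == nrow(pool))
  nL <- ncol(lanes)
  if (nL > cfg$nLanes)
    stop("config provides ", cfg$nLanes, " lanes but ", nL, " supplied")
  if (is.null(laneIds)) laneIds <- colnames(lanes) %||%
      paste0("lane", seq_len(nL))
  H <- cfg$height; W <- cfg$width
  img <- matrix(0, H, W)
  centers <- .laneCenters(cfg)
  truth <- list()
  rows <- seq_len(H)
  for (j in seq_len(nL)) {
    a <- lanes[, j]
    keep <- which(a >= cfg$detectionLimit)
    cc <- centers[j]
    colIdx <- max(1L, floor(cc - 4 * cfg$lateralSigma)):
      min(W, ceiling(cc + 4 * cfg$lateralSigma))
    latK <- exp(-((colIdx - cc)^2) / (2 * cfg$lateralSigma^2))
    for (i in keep) {
      amp <- a[i] * pool$amplification_factor[i] * cfg$peakAmplitude
      r0 <- pool$melting_position[i] * (H - 1) + 1
      rowIdx <- max(1L, floor(r0 - 4 * cfg$bandSigma)):
        min(H, ceiling(r0 + 4 * cfg$bandSigma))
      migK <- exp(-((rowIdx - r0)^2) / (2 * cfg$bandSigma^2))
      img[rowIdx, colIdx] <- img[rowIdx, colIdx] + amp * (migK %o% latK)
      truth[[length(truth) + 1L]] <- data.frame(
        lane = j, lane_id = laneIds[j], species_id = pool$species_id[i],
        position_fraction = pool$melting_position[i], amplitude = amp)
    }
  }
  bg <- cfg$background + cfg$backgroundGradient * (rows - 1) / (H - 1)
  img <- img + bg
  if (cfg$noiseSigma > 0) {
    set.seed(.streamSeed(seed, "render-noise"))
    img <- img + matrix(stats::rnorm(H * W, 0, cfg$noiseSigma), H, W)
  }
  top <- 2^cfg$bitDepth - 1
  nClip <- sum(img > top)
  if (nClip > 0)
    warning(nClip, " pixel(s) exceeded the ", cfg$bitDepth,
            "-bit range and were clipped")
  img <- pmin(pmax(img, 0), top)
  spans <- data.frame(lane = seq_len(nL),
                      from = pmax(1L, round(centers[seq_len(nL)] -
                                              cfg$laneWidth / 2)),
                      to = pmin(W, round(centers[seq_len(nL)] +
                                           cfg$laneWidth / 2)))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(lane = integer(), lane_id = character(),
               species_id = integer(), position_fraction = numeric(),
               amplitude = numeric())
  list(image = GelImage(img, cfg$bitDepth, spans), truth = truth)
}

#' Write a complete synthetic fixture to disk
#'
#' Renders one gel image per sampling day (all reactors of all
#' temperatures side by side, as on a physical gel) and writes: per-day
#' TIFFs, the pooled ground-truth band table (CSV), the design, shift
#' model and render config (YAML), and a manifest recording the seed and
#' per-file MD5 checksums. Re-running with the same inputs and seed
#' reproduces byte-identical files.
#'
#' @param trajectory a \linkS4class{CommunityTrajectory}.
#' @param cfg a \code{\link{gelRenderConfig}}.
#' @param outDir output directory; refuses to write into a non-empty
#'   directory unless \code{overwrite = TRUE}.
#' @param seed integer seed for rendering noise.
#' @param design,shift optional design/shift model echoed into the YAML.
#' @param overwrite allow writing into a non-empty directory.
#' @return invisibly, the manifest list.
#' @export
writeFixture <- function(trajectory, cfg = gelRenderConfig(), outDir,
                         seed = 1L, design = NULL, shift = NULL,
                         overwrite = FALSE) {
  stopifnot(is(trajectory, "CommunityTrajectory"))
  if (dir.exists(outDir) && length(dir(outDir)) > 0 && !overwrite)
    stop("output directory ", outDir,
         " is not empty; use overwrite = TRUE to replace it")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  li <- laneInfo(trajectory)
  ab <- abundanceMatrix(trajectory)
  days <- sort(unique(li$day))
  files <- character()
  truthAll <- list()
  for (d in days) {
    sel <- which(li$day == d)
    sel <- sel[order(li$temperature[sel], li$reactor[sel])]
    res <- renderGel(ab[, sel, drop = FALSE], speciesPool(trajectory), cfg,
                     seed = .streamSeed(seed, paste0("render-day-", d)),
                     laneIds = li$lane[sel])
    fn <- sprintf("gel_day%02d.tiff", d)
    writeGelImage(res$image, file.path(outDir, fn))
    files <- c(files, fn)
    if (nrow(res$truth)) res$truth$image <- fn
    truthAll[[as.character(d)]] <- res$truth
  }
  truth <- do.call(rbind, truthAll)
  rownames(truth) <- NULL
  utils::write.csv(truth, file.path(outDir, "ground_truth_bands.csv"),
                   row.names = FALSE)
  utils::write.csv(li, file.path(outDir, "lane_table.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(design = design, shift = shift,
                        render = unclass(cfg)),
                   file.path(outDir, "fixture_config.yaml"))
  allFiles <- c(files, "ground_truth_bands.csv", "lane_table.csv",
                "fixture_config.yaml")
  manifest <- list(seed = as.integer(seed),
                   n_images = length(files),
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(file.path(outDir, allFiles))),
                     allFiles)))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(manifest)
}

#' Read and write gel images
#'
#' Grayscale TIFF (any bit depth r-tiff supports) and PNG round-tripping
#' for \linkS4class{GelImage}. Intensities are stored normalized to the
#' image bit depth on disk.
#'
#' @param image a \linkS4class{GelImage}.
#' @param path file path; format chosen by extension (.tif/.tiff/.png).
#' @return \code{writeGelImage} returns the path invisibly;
#'   \code{readGelImage} returns a \linkS4class{GelImage}.
#' @export
writeGelImage <- function(image, path) {
  stopifnot(is(image, "GelImage"))
  top <- 2^image@bitDepth - 1
  norm <- image@intensity / top
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = image@bitDepth,
                    compression = "none")
  } else if (ext == "png") {
    png::writePNG(norm, path)
  } else stop("unsupported image extension: ", ext)
  invisible(path)
}

#' @rdname writeGelImage
#' @param bitDepth bit depth to restore intensities to on read.
#' @export
readGelImage <- function(path, bitDepth = 16L) {
  ext <- tolower(tools::file_ext(path))
  norm <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
          else if (ext == "png") png::readPNG(path)
          else stop("unsupported image extension: ", ext)
  if (length(dim(norm)) == 3L) norm <- norm[, , 1]
  GelImage(norm * (2^bitDepth - 1), bitDepth = bitDepth)
}
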