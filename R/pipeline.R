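#' @include ecology-dynamics.R
NULL

.defaultConfig <- function() {
  list(
    mode = "full",
    seed = 1L,
    nSpecies = 40L,
    design = list(temperatures = c(28, 36, 44, 52),
                  reactorsPerTemperature = 3L,
                  samplingDays = c(0L, 7L, 14L, 30L, 60L)),
    shift = list(turnoverRate = c(0.25, 0.40, 0.55, 0.70),
                 replicateJitter = 0.15,
                 detectionLimit = 0.01),
    render = list(nLanes = 12L, height = 400L, laneWidth = 28L,
                  laneGap = 8L, bandSigma = 3, lateralSigma = 7,
                  peakAmplitude = 30000, background = 1000,
                  backgroundGradient = 500, noiseSigma = 15,
                  detectionLimit = 0.01, bitDepth = 16L),
    processing = list(backgroundWindow = 0.1, resolution = 500L,
                      normalization = "total"),
    bands = list(minProminence = 0.05, minSeparation = 0.01,
                 tolerance = 0.01),
    similarity = list(methods = c("jaccard", "pearson")),
    paths = list(fixtureDir = NULL)
  )
}

.checkRange <- function(value, name, lo, hi, loOpen = FALSE,
                        hiOpen = FALSE) {
  bad <- value < lo | value > hi |
    (loOpen & value == lo) | (hiOpen & value == hi)
  if (any(bad))
    stop("config field ", name, " = ", paste(value[bad], collapse = ", "),
         " outside its range ", if (loOpen) "(" else "[", lo, ", ", hi,
         if (hiOpen) ")" else "]",
         " (fractions of gel length / profile maximum are unitless)")
}

#' Validate and complete a pipeline configuration
#'
#' Fills defaults for missing fields, rejects unknown keys (no silent
#' ignoring), and range-checks every threshold. The returned object
#' serializes to YAML and parses back to an equal configuration.
#'
#' @param raw a (possibly empty or partial) named list, e.g. parsed from
#'   a YAML file.
#' @return a completed list of class \code{"RunConfig"}.
#' @export
validateConfig <- function(raw = list()) {
  def <- .defaultConfig()
  if (is.null(raw)) raw <- list()
  stopifnot(is.list(raw))
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- def
  for (nm in names(raw)) {
    if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
      sub <- setdiff(names(raw[[nm]]), names(def[[nm]]))
      if (length(sub))
        stop("unknown config keys in ", nm, ": ",
             paste(sub, collapse = ", "))
      for (s in names(raw[[nm]])) cfg[[nm]][s] <- list(raw[[nm]][[s]])
    } else {
      cfg[nm] <- list(raw[[nm]])
    }
  }
  if (!cfg$mode %in% c("simulate", "analyze", "full"))
    stop("mode must be one of simulate, analyze, full")
  .checkRange(cfg$bands$minProminence, "bands$minProminence", 0, 1,
              loOpen = TRUE)
  .checkRange(cfg$bands$minSeparation, "bands$minSeparation", 0, 1)
  .checkRange(cfg$bands$tolerance, "bands$tolerance", 0, 1, loOpen = TRUE)
  .checkRange(cfg$processing$backgroundWindow, "processing$backgroundWindow",
              0, 1, loOpen = TRUE, hiOpen = TRUE)
  if (cfg$processing$resolution < 32)
    stop("processing$resolution must be at least 32 grid points")
  if (!cfg$processing$normalization %in% c("total", "max"))
    stop("processing$normalization must be 'total' or 'max'")
  .checkRange(cfg$shift$turnoverRate, "shift$turnoverRate", 0, 1)
  .checkRange(cfg$shift$detectionLimit, "shift$detectionLimit", 0, 1,
              hiOpen = TRUE)
  .checkRange(cfg$render$detectionLimit, "render$detectionLimit", 0, 1,
              hiOpen = TRUE)
  if (!all(cfg$similarity$methods %in% c("jaccard", "pearson")))
    stop("similarity$methods may contain only 'jaccard' and 'pearson'")
  if (cfg$nSpecies < 1) stop("nSpecies must be at least 1")
  structure(cfg, class = "RunConfig")
}

## MD5 of the YAML serialization of the analysis-relevant config sections
## (mode and paths excluded, so a full run and an analyze re-run of its
## fixture stamp identical checksums into their outputs).
.configChecksum <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  keep <- c("seed", "nSpecies", "design", "shift", "render",
            "processing", "bands", "similarity")
  yaml::write_yaml(unclass(cfg)[keep], tf)
  unname(tools::md5sum(tf))
}

## CSV with a provenance header comment; read back with
## read.csv(..., comment.char = "#").
.writeTable <- function(df, path, stage, cfgSum) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# stage: ", stage, "; config_md5: ", cfgSum), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Run the full fingerprint pipeline
#'
#' Depending on \code{config$mode}: \code{"simulate"} writes a synthetic
#' fixture (gel TIFFs + ground truth); \code{"analyze"} analyzes an
#' existing fixture directory (\code{config$paths$fixtureDir}, needing
#' gel images plus a \code{lane_table.csv} with lane/temperature/
#' reactor/day); \code{"full"} does both. Analysis produces per-lane
#' profiles, band tables, per-day binary matrices, Jaccard and/or
#' Pearson similarity matrices and UPGMA Newick trees, ecology indices
#' (richness, community organization) and the moving-window series, plus
#' a manifest with the config checksum and per-file MD5 sums. Identical
#' config and seed reproduce byte-identical outputs.
#'
#' @param config a \code{\link{validateConfig}} result (or raw list).
#' @param outDir output directory.
#' @param overwrite allow writing into a non-empty directory.
#' @return invisibly, a list with the analysis objects (profiles,
#'   fingerprints per day, similarity matrices, trees, indices,
#'   moving-window series, manifest).
#' @export
runPipeline <- function(config = validateConfig(), outDir,
                        overwrite = FALSE) {
  if (!inherits(config, "RunConfig")) config <- validateConfig(config)
  if (dir.exists(outDir) && length(dir(outDir)) > 0 && !overwrite)
    stop("output directory ", outDir,
         " is not empty; use overwrite = TRUE to replace it")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cfgSum <- .configChecksum(config)
  logFile <- file.path(outDir, "run.log")
  logLines <- c(paste0("config_md5: ", cfgSum),
                paste0("mode: ", config$mode),
                paste0("seed: ", config$seed))
  design <- do.call(experimentDesign, config$design)
  rcfg <- do.call(gelRenderConfig, config$render)
  fixtureDir <- config$paths$fixtureDir
  result <- list(config = config)

  if (config$mode %in% c("simulate", "full")) {
    pool <- buildSpeciesPool(config$nSpecies, config$seed,
                             resolution = config$processing$resolution)
    shift <- shiftModel(temperatures = design$temperatures,
                        turnoverRate = config$shift$turnoverRate,
                        replicateJitter = config$shift$replicateJitter,
                        detectionLimit = config$shift$detectionLimit)
    traj <- simulateTrajectories(design, shift, pool, config$seed)
    fixtureDir <- file.path(outDir, "fixture")
    writeFixture(traj, rcfg, fixtureDir, seed = config$seed,
                 design = unclass(design), overwrite = overwrite)
    logLines <- c(logLines, paste0("fixture: ", length(
      dir(fixtureDir, pattern = "\\.tiff$")), " gel images written"))
    result$trajectory <- traj
  }

  if (config$mode %in% c("analyze", "full")) {
    if (is.null(fixtureDir) || !dir.exists(fixtureDir))
      stop("analyze mode needs an existing fixture directory ",
           "(config$paths$fixtureDir)")
    laneTab <- utils::read.csv(file.path(fixtureDir, "lane_table.csv"),
                               comment.char = "#")
    days <- sort(unique(laneTab$day))
    imgFiles <- sprintf("gel_day%02d.tiff", days)
    profMats <- list(); laneMeta <- list()
    fps <- list(); sims <- list(); trees <- list()
    for (di in seq_along(days)) {
      d <- days[di]
      li <- laneTab[laneTab$day == d, , drop = FALSE]
      li <- li[order(li$temperature, li$reactor), , drop = FALSE]
      img <- readGelImage(file.path(fixtureDir, imgFiles[di]),
                          bitDepth = rcfg$bitDepth)
      prof <- processGel(img, li,
                         backgroundWindow = config$processing$backgroundWindow,
                         resolution = config$processing$resolution,
                         mode = config$processing$normalization)
      profMats[[di]] <- profileValues(prof)
      laneMeta[[di]] <- li
      fp <- fingerprintGel(prof,
                           minProminence = config$bands$minProminence,
                           minSeparation = config$bands$minSeparation,
                           tolerance = config$bands$tolerance)
      fps[[as.character(d)]] <- fp
      bm <- presenceMatrix(fp)
      .writeTable(data.frame(lane_id = rownames(bm), bm,
                             check.names = FALSE),
                  file.path(outDir, sprintf("binary_day%02d.csv", d)),
                  "band_calling", cfgSum)
      for (method in config$similarity$methods) {
        sm <- if (method == "jaccard") similarityMatrix(fp, "jaccard")
              else similarityMatrix(prof, "pearson")
        sims[[paste(method, d, sep = "_")]] <- sm
        .writeTable(data.frame(lane_id = rownames(similarityValues(sm)),
                               similarityValues(sm), check.names = FALSE),
                    file.path(outDir, sprintf("similarity_%s_day%02d.csv",
                                              method, d)),
                    "fingerprint_stats", cfgSum)
        tree <- upgma(sm)
        trees[[paste(method, d, sep = "_")]] <- tree
        writeLines(toNewick(tree),
                   file.path(outDir, sprintf("tree_%s_day%02d.nwk",
                                             method, d)))
      }
    }
    ## pooled profile set over all days for the moving-window analysis
    allMeta <- do.call(rbind, laneMeta)
    allProf <- ProfileSet(do.call(cbind, profMats),
                          seq(0, 1,
                              length.out = config$processing$resolution),
                          allMeta)
    profLong <- do.call(rbind, lapply(seq_along(allMeta$lane), function(j)
      data.frame(lane_id = allMeta$lane[j],
                 position = profilePositions(allProf),
                 value = profileValues(allProf)[, j])))
    .writeTable(profLong, file.path(outDir, "profiles.csv"),
                "image_processing", cfgSum)
    bands <- do.call(rbind, lapply(names(fps), function(d) {
      b <- bandTable(fps[[d]])
      if (nrow(b)) b$image <- sprintf("gel_day%02d.tiff", as.integer(d))
      b
    }))
    .writeTable(bands, file.path(outDir, "bands.csv"), "band_calling",
                cfgSum)
    indices <- do.call(rbind, lapply(names(fps), function(d) {
      fp <- fps[[d]]
      rich <- richness(fp)
      co <- vapply(seq_along(rich), function(i) {
        x <- intensityMatrix(fp)[i, ]
        if (all(x == 0)) NA_real_ else communityOrganization(x[x > 0])
      }, numeric(1))
      data.frame(lane_id = laneIds(fp), day = as.integer(d),
                 richness = as.integer(rich), community_organization = co)
    }))
    .writeTable(indices, file.path(outDir, "indices.csv"),
                "ecology_dynamics", cfgSum)
    mw <- movingWindow(allProf, design)
    .writeTable(merge(windowValues(mw), windowMeans(mw),
                      by = c("temperature", "interval_start",
                             "interval_end"), sort = TRUE),
                file.path(outDir, "moving_window.csv"),
                "ecology_dynamics", cfgSum)
    roc <- rateOfChange(mw)
    .writeTable(data.frame(temperature = names(roc),
                           rate_of_change = as.numeric(roc)),
                file.path(outDir, "rate_of_change.csv"),
                "ecology_dynamics", cfgSum)
    logLines <- c(logLines,
                  paste0("analyzed ", length(days), " gel images, ",
                         nrow(allMeta), " lanes"),
                  paste0("rate of change (%): ",
                         paste(names(roc), round(roc, 1), sep = "=",
                               collapse = ", ")))
    result <- c(result, list(profiles = allProf, fingerprints = fps,
                             similarities = sims, trees = trees,
                             indices = indices, movingWindow = mw,
                             rateOfChange = roc))
  }

  outFiles <- sort(dir(outDir, recursive = TRUE))
  outFiles <- setdiff(outFiles, "run.log")
  manifest <- list(seed = as.integer(config$seed), mode = config$mode,
                   config_md5 = as.character(cfgSum),
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(file.path(outDir, outFiles))),
                     outFiles)))
  outFiles <- setdiff(outFiles, "manifest.yaml")
  manifest$files <- manifest$files[outFiles]
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  writeLines(logLines, logFile)
  result$manifest <- manifest
  invisible(result)
}
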