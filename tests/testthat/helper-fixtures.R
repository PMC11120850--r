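# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk except what the tests themselves write.

# Species pool with guaranteed pairwise position separation (for band
# recovery checks where bands must not co-migrate).
separatedPool <- function(n, seed, minSep = 0.03, range = c(0.06, 0.94),
                          ampSdLog = 0.2) {
  set.seed(seed)
  grid <- seq(range[1], range[2], by = minSep)
  stopifnot(n <= length(grid))
  data.frame(species_id = seq_len(n),
             melting_position = sort(sample(grid, n)),
             amplification_factor = stats::rlnorm(n, 0, ampSdLog))
}

# Small noiseless render config used where pixel-exact behavior matters.
cleanRenderConfig <- function(nLanes = 1L, height = 200L, ...) {
  gelRenderConfig(nLanes = nLanes, height = height, background = 0,
                  backgroundGradient = 0, noiseSigma = 0, ...)
}

# Random abundance matrix: n lanes over the pool, each lane `k` detectable
# species with Dirichlet-ish weights, all >= minAbund.
randomLanes <- function(pool, nLanes, k, seed, minAbund = 0.05) {
  set.seed(seed)
  ab <- matrix(0, nrow(pool), nLanes)
  for (j in seq_len(nLanes)) {
    sp <- sample(nrow(pool), k)
    w <- stats::rexp(k) + minAbund * k
    ab[sp, j] <- w / sum(w)
  }
  ab
}

# Simulate the default design, render all days, and return the pooled
# ProfileSet plus the trajectory (the standard end-to-end fixture).
simulateAndProfile <- function(seed, rates = NULL, nSpecies = 40,
                               cfg = gelRenderConfig()) {
  pool <- buildSpeciesPool(nSpecies, seed)
  design <- experimentDesign()
  shift <- if (is.null(rates)) shiftModel() else
    shiftModel(turnoverRate = rates)
  traj <- simulateTrajectories(design, shift, pool, seed)
  ab <- abundanceMatrix(traj)
  li <- laneInfo(traj)
  mats <- list(); metas <- list()
  for (d in design$samplingDays) {
    s <- which(li$day == d)
    s <- s[order(li$temperature[s], li$reactor[s])]
    r <- renderGel(ab[, s, drop = FALSE], pool, cfg,
                   seed = seed * 100 + d, laneIds = li$lane[s])
    p <- processGel(r$image, li[s, ])
    mats[[as.character(d)]] <- profileValues(p)
    metas[[as.character(d)]] <- li[s, ]
  }
  list(profiles = ProfileSet(do.call(cbind, mats),
                             laneData = do.call(rbind, metas)),
       trajectory = traj, design = design, pool = pool)
}
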