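test_that("species pools are deterministic, bounded and collision-free", {
  p1 <- buildSpeciesPool(1, 7)
  expect_equal(nrow(p1), 1)
  expect_gte(p1$melting_position, 0.05)
  expect_lte(p1$melting_position, 0.95)

  expect_identical(buildSpeciesPool(20, 3), buildSpeciesPool(20, 3))

  p50 <- buildSpeciesPool(50, 1)
  cells <- round(p50$melting_position * 499)
  for (i in 1:49) for (j in (i + 1):50)
    expect_true(cells[i] != cells[j])
  expect_true(all(p50$amplification_factor > 0))

  expect_error(buildSpeciesPool(50, 1, resolution = 40), "resolution 40")
})

test_that("zero turnover freezes every reactor's community", {
  pool <- buildSpeciesPool(30, 2)
  design <- experimentDesign()
  shift <- shiftModel(turnoverRate = 0)
  traj <- simulateTrajectories(design, shift, pool, 2)
  ab <- abundanceMatrix(traj)
  li <- laneInfo(traj)
  for (temp in design$temperatures) {
    for (r in 1:3) {
      lanes <- li$lane[li$temperature == temp & li$reactor == r]
      ref <- ab[, lanes[1]]
      for (l in lanes[-1]) expect_equal(ab[, l], ref)
    }
  }
})

test_that("abundance columns are probability vectors and day 0 is shared", {
  pool <- buildSpeciesPool(40, 5)
  traj <- simulateTrajectories(experimentDesign(), shiftModel(), pool, 5)
  ab <- abundanceMatrix(traj)
  li <- laneInfo(traj)
  expect_equal(ncol(ab), 60)  # 12 reactors x 5 days
  expect_true(max(abs(colSums(ab) - 1)) < 1e-9)
  expect_true(all(ab >= 0))
  # without jitter, day-0 lanes agree exactly across reactors and temps
  shift0 <- shiftModel(replicateJitter = 0)
  traj0 <- simulateTrajectories(experimentDesign(), shift0, pool, 5)
  ab0 <- abundanceMatrix(traj0)
  li0 <- laneInfo(traj0)
  d0 <- li0$lane[li0$day == 0]
  for (l in d0[-1]) expect_equal(ab0[, l], ab0[, d0[1]])
})

test_that("turnover timing concentrates change on the weighted interval", {
  pool <- buildSpeciesPool(40, 11)
  design <- experimentDesign()
  w <- c(0.05, 0.85, 0.05, 0.05)  # nearly all turnover in days 7 -> 14
  shift <- shiftModel(turnoverRate = 0.5, intervalWeights = w,
                      replicateJitter = 0)
  traj <- simulateTrajectories(design, shift, pool, 11)
  ab <- abundanceMatrix(traj)
  li <- laneInfo(traj)
  for (temp in design$temperatures) {
    lanes <- li[li$temperature == temp & li$reactor == 1, ]
    lanes <- lanes[order(lanes$day), ]
    l1 <- vapply(seq_len(nrow(lanes) - 1), function(k)
      sum(abs(ab[, lanes$lane[k + 1]] - ab[, lanes$lane[k]])), numeric(1))
    expect_equal(which.max(l1), 2L)
  }
})

test_that("interval turnover distance is monotone in the turnover rate", {
  pool <- buildSpeciesPool(40, 4)
  design <- experimentDesign(temperatures = 36,
                             reactorsPerTemperature = 1L)
  rates <- seq(0.1, 0.9, by = 0.2)
  l1ByRate <- sapply(rates, function(r) {
    shift <- shiftModel(temperatures = 36, turnoverRate = r,
                        intervalWeights = rep(0.25, 4),
                        replicateJitter = 0)
    traj <- simulateTrajectories(design, shift, pool, 4)
    ab <- abundanceMatrix(traj)
    li <- laneInfo(traj)
    li <- li[order(li$day), ]
    vapply(seq_len(nrow(li) - 1), function(k)
      sum(abs(ab[, li$lane[k + 1]] - ab[, li$lane[k]])), numeric(1))
  })
  for (interval in 1:4)
    expect_true(all(diff(l1ByRate[interval, ]) >= -1e-9))
})

test_that("richness requests beyond the pool are rejected", {
  pool <- buildSpeciesPool(5, 1)
  expect_error(
    simulateTrajectories(experimentDesign(), shiftModel(), pool, 1),
    "pool has only 5")
})

test_that("rendered bands sit where the melting positions say", {
  pool <- data.frame(species_id = 1L, melting_position = 0.3,
                     amplification_factor = 1)
  cfg <- cleanRenderConfig()
  res <- renderGel(matrix(1), pool, cfg, seed = 1)
  img <- gelIntensity(res$image)
  prof <- rowMeans(img[, laneSpans(res$image)$from:laneSpans(res$image)$to])
  locmax <- which(diff(sign(diff(prof))) < 0) + 1L
  expect_length(locmax, 1)
  expect_equal(locmax, round(0.3 * (cfg$height - 1)) + 1L)
})

test_that("the detection limit gates the ground-truth band table", {
  pool <- data.frame(species_id = 1:2,
                     melting_position = c(0.2, 0.6),
                     amplification_factor = c(1, 1))
  cfg <- cleanRenderConfig(detectionLimit = 0.01)
  ab <- matrix(c(0.995, 0.005), ncol = 1)  # second species at 0.5 x limit
  res <- renderGel(ab, pool, cfg, seed = 1)
  expect_equal(res$truth$species_id, 1L)

  # a lane with 9 detectable species yields 9 ground-truth bands
  pool9 <- separatedPool(9, 1)
  ab9 <- matrix(rep(1 / 9, 9), ncol = 1)
  res9 <- renderGel(ab9, pool9, cleanRenderConfig(), seed = 1)
  expect_equal(nrow(res9$truth), 9)
})

test_that("rendering is deterministic and clips rather than wraps", {
  pool <- separatedPool(5, 3)
  ab <- randomLanes(pool, 2, 3, 3)
  cfg <- gelRenderConfig(nLanes = 2, height = 120)
  r1 <- renderGel(ab, pool, cfg, seed = 9)
  r2 <- renderGel(ab, pool, cfg, seed = 9)
  expect_identical(gelIntensity(r1$image), gelIntensity(r2$image))

  hot <- gelRenderConfig(nLanes = 1, height = 120, peakAmplitude = 1e6)
  expect_warning(
    rh <- renderGel(ab[, 1, drop = FALSE], pool, hot, seed = 1),
    "clipped")
  expect_lte(max(gelIntensity(rh$image)), 2^16 - 1)
  expect_gte(min(gelIntensity(rh$image)), 0)
})

test_that("fixtures regenerate byte-identically and refuse overwrites", {
  pool <- buildSpeciesPool(30, 6)
  design <- experimentDesign()
  traj <- simulateTrajectories(design, shiftModel(), pool, 6)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  unlink(c(d1, d2), recursive = TRUE)
  cfg <- gelRenderConfig(height = 200)
  m1 <- writeFixture(traj, cfg, d1, seed = 6)
  m2 <- writeFixture(traj, cfg, d2, seed = 6)
  expect_equal(m1$files, m2$files)
  expect_equal(m1$n_images, 5)  # one gel per sampling day
  expect_error(writeFixture(traj, cfg, d1, seed = 6), "not empty")

  # truth CSV rows = detectable (lane, species) pairs of the trajectory
  truth <- read.csv(file.path(d1, "ground_truth_bands.csv"))
  expected <- sum(abundanceMatrix(traj) >= cfg$detectionLimit)
  expect_equal(nrow(truth), expected)
  unlink(c(d1, d2), recursive = TRUE)
})
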