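gaussProfile <- function(centers, heights, n = 500, sigma = 0.01) {
  pos <- seq(0, 1, length.out = n)
  v <- rep(0, n)
  for (k in seq_along(centers))
    v <- v + heights[k] * exp(-((pos - centers[k])^2) / (2 * sigma^2))
  LaneProfile("lane", v, pos)
}

test_that("band calling finds isolated Gaussian peaks", {
  step <- 1 / 499  # positions are quantized to the profile grid
  b1 <- callBands(gaussProfile(0.4, 1), minProminence = 0.1)
  expect_equal(nrow(b1), 1)
  expect_true(abs(b1$position - 0.4) <= step)
  expect_equal(b1$height, 1, tolerance = 5e-3)

  b2 <- callBands(gaussProfile(c(0.3, 0.7), c(1, 1)), minProminence = 0.1)
  expect_equal(nrow(b2), 2)
  expect_true(all(abs(b2$position - c(0.3, 0.7)) <= step))
  expect_true(all(diff(b2$position) > 0))  # sorted by position

  expect_equal(nrow(callBands(LaneProfile("z", rep(0, 100)))), 0)
})

test_that("prominence and separation thresholds prune peaks", {
  # a 3% shoulder next to a full peak is below a 5% prominence cut
  p <- gaussProfile(c(0.3, 0.6), c(1, 0.03))
  expect_equal(nrow(callBands(p, minProminence = 0.05)), 1)
  expect_equal(nrow(callBands(p, minProminence = 0.01)), 2)

  # two peaks closer than minSeparation collapse to the taller one
  cl <- gaussProfile(c(0.50, 0.52), c(1, 0.8), sigma = 0.004)
  got <- callBands(cl, minProminence = 0.05, minSeparation = 0.05)
  expect_equal(nrow(got), 1)
  expect_true(abs(got$position - 0.50) <= 1 / 499)
})

test_that("band area integrates the peak support", {
  p <- gaussProfile(0.5, 1, sigma = 0.01)
  b <- callBands(p, minProminence = 0.1)
  # Gaussian integral = h * sigma * sqrt(2*pi); support spans the profile
  expect_equal(b$area, sqrt(2 * pi) * 0.01, tolerance = 0.01)
  expect_gte(b$area, b$height * (1 / 499))
})

test_that("band classes reproduce single-linkage gap structure", {
  t1 <- buildBandClasses(c(0.10, 0.105, 0.50), tolerance = 0.01)
  expect_length(classCenters(t1), 2)
  expect_equal(classCenters(t1), c(0.1025, 0.50))

  expect_length(classCenters(buildBandClasses(numeric(), 0.01)), 0)

  # chaining: consecutive gaps of 0.009 link into one class
  t2 <- buildBandClasses(c(0.10, 0.109, 0.118), tolerance = 0.01)
  expect_length(classCenters(t2), 1)
  expect_equal(classCenters(t2), mean(c(0.10, 0.109, 0.118)))
})

test_that("band classes match an hclust single-linkage oracle", {
  set.seed(31)
  for (rep in 1:25) {
    pos <- runif(sample(3:40, 1))
    tol <- runif(1, 0.01, 0.1)
    got <- classCenters(buildBandClasses(pos, tol))
    cl <- cutree(hclust(dist(pos), method = "single"), h = tol + 1e-12)
    oracle <- sort(as.numeric(tapply(pos, cl, mean)))
    expect_equal(got, oracle)
  }
})

test_that("class tables are permutation-invariant in lane order", {
  set.seed(5)
  bandsA <- data.frame(position = runif(30))
  bandsB <- bandsA[sample(30), , drop = FALSE]
  expect_equal(classCenters(buildBandClasses(bandsA, 0.03)),
               classCenters(buildBandClasses(bandsB, 0.03)))
})

test_that("lane fingerprints map bands onto classes correctly", {
  classes <- buildBandClasses(seq(0.1, 0.9, by = 0.1), tolerance = 0.01)
  bands9 <- data.frame(position = seq(0.1, 0.9, by = 0.1) + 0.002,
                       area = rep(1, 9))
  fp <- fingerprintLane(bands9, classes)
  expect_equal(sum(fp$binary), 9)

  fp0 <- fingerprintLane(data.frame(position = numeric(),
                                    area = numeric()), classes)
  expect_equal(fp0$binary, rep(0, 9))

  # two bands of one lane in the same class: one presence, summed area
  twob <- data.frame(position = c(0.101, 0.099), area = c(2, 3))
  fp2 <- fingerprintLane(twob, classes)
  expect_equal(sum(fp2$binary), 1)
  expect_equal(fp2$intensity[1], 5)

  off <- data.frame(position = 0.35, area = 1)
  expect_error(fingerprintLane(off, classes), "tolerance")
})

test_that("fingerprintGel recovers bands from clean rendered gels", {
  pool <- separatedPool(8, 17, minSep = 0.05)
  ab <- randomLanes(pool, 4, 5, 17, minAbund = 0.08)
  cfg <- cleanRenderConfig(nLanes = 4)
  res <- renderGel(ab, pool, cfg, seed = 17)
  prof <- processGel(res$image, data.frame(lane = paste0("L", 1:4)))
  fp <- fingerprintGel(prof)
  # each lane's called band count equals its detectable species count
  expect_equal(unname(richness(fp)), colSums(ab >= cfg$detectionLimit))
  # binary vector has a 1 exactly where intensity > 0 (validity holds)
  expect_true(validObject(fp))
})
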