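test_that("richness counts present band classes", {
  pres <- matrix(0, 2, 9, dimnames = list(c("d60", "empty"), NULL))
  pres[1, ] <- 1
  fp <- new("FingerprintSet", presence = pres, intensity = pres,
            classes = buildBandClasses(seq(0.1, 0.9, 0.1), 0.01),
            bands = data.frame())
  expect_equal(unname(richness(fp)), c(9, 0))
  expect_equal(richness(c(1, 0, 1, 1)), 3)
  expect_equal(richness(pres[1, ]), sum(pres[1, ]))
})

test_that("community organization equals the Gini percentage", {
  expect_equal(communityOrganization(rep(3, 5)), 0)
  expect_equal(communityOrganization(c(10, 10, 10, 70)), 45)
  expect_equal(communityOrganization(42), 0)  # single band
  expect_error(communityOrganization(c(1, 0, 2)), "positive")
  expect_error(communityOrganization(numeric()), "at least one")
})

test_that("Gini matches a Lorenz-curve trapezoid oracle on random lanes", {
  lorenzGini <- function(x) {
    x <- sort(x); n <- length(x)
    cx <- c(0, cumsum(x)) / sum(x)
    area <- sum((cx[-1] + cx[-(n + 1)]) / 2) / n
    100 * (1 - 2 * area)
  }
  set.seed(21)
  for (rep in 1:200) {
    x <- rexp(sample(2:15, 1)) + 0.01
    expect_equal(communityOrganization(x), lorenzGini(x),
                 tolerance = 1e-12)
  }
})

test_that("Co is scale-invariant and rises with concentration", {
  set.seed(3)
  for (rep in 1:20) {
    x <- rexp(6) + 0.1
    expect_equal(communityOrganization(x * runif(1, 0.1, 50)),
                 communityOrganization(x))
  }
  # moving a fixed total from equal shares into one dominant band
  for (n in 2:10) {
    even <- rep(10, n)
    skew <- c(rep(5, n - 1), 10 * n - 5 * (n - 1))
    expect_gt(communityOrganization(skew), communityOrganization(even))
  }
})

test_that("Lorenz curves are anchored, convex and consistent with Co", {
  eq <- lorenzCurve(rep(2, 4))
  expect_equal(eq$fraction_intensity, eq$fraction_bands)

  lc <- lorenzCurve(c(10, 10, 10, 70))
  expect_equal(lc$fraction_intensity[lc$fraction_bands == 0.75], 0.30)
  expect_equal(lc$fraction_intensity[c(1, 5)], c(0, 1))
  expect_true(all(diff(diff(lc$fraction_intensity)) >= -1e-12))  # convex

  # Gini from the curve area equals communityOrganization
  area <- sum((lc$fraction_intensity[-1] + lc$fraction_intensity[-5]) / 2) / 4
  expect_equal(100 * (1 - 2 * area), communityOrganization(c(10, 10, 10, 70)))
})

test_that("percent change mirrors similarity exactly", {
  expect_equal(percentChange(100), 0)
  expect_equal(percentChange(0), 100)
  expect_equal(percentChange(9), 91)
  expect_error(percentChange(101), "0, 100")
  expect_error(percentChange(-2), "0, 100")
})

test_that("moving windows are zero for static communities", {
  design <- experimentDesign(temperatures = c(28, 36),
                             reactorsPerTemperature = 2L,
                             samplingDays = c(0L, 7L, 14L))
  pos <- seq(0, 1, length.out = 50)
  base <- exp(-((pos - 0.4)^2) / 0.005)
  lanes <- expand.grid(reactor = 1:2, temperature = c(28, 36),
                       day = c(0, 7, 14))
  lanes$lane <- sprintf("T%d_R%d_D%d", lanes$temperature, lanes$reactor,
                        lanes$day)
  ps <- ProfileSet(matrix(base, 50, nrow(lanes)), pos, lanes)
  mw <- movingWindow(ps, design)
  expect_true(all(windowValues(mw)$pct_change == 0))
  expect_equal(windowMeans(mw)$interval_end,
               rep(c(7, 14), 2))
  expect_true(all(windowValues(mw)$is_first_interval ==
                    (windowValues(mw)$interval_start == 0)))

  # a missing lane is reported, not silently skipped
  expect_error(movingWindow(ps[, -1], design), "exactly one profile")
})

test_that("interval endpoints follow the default sampling design", {
  fx <- simulateAndProfile(23, cfg = gelRenderConfig(height = 200))
  mw <- movingWindow(fx$profiles, fx$design)
  m <- windowMeans(mw)
  expect_equal(sort(unique(m$interval_start)), c(0, 7, 14, 30))
  expect_equal(sort(unique(m$interval_end)), c(7, 14, 30, 60))
  expect_true(all(m$n == 3))
  expect_true(all(m$mean_pct_change >= 0 & m$mean_pct_change <= 100))
})

test_that("rate of change averages interval means", {
  mk <- function(df) {
    vals <- df[rep(seq_len(nrow(df)), each = 2), ]
    vals$reactor <- rep(1:2, nrow(df))
    vals$pct_change <- vals$mean_pct_change
    new("MovingWindowSeries", values = vals, means = df)
  }
  one <- mk(data.frame(temperature = 28, interval_start = 0,
                       interval_end = 7, mean_pct_change = 40, n = 2))
  expect_equal(rateOfChange(one), c(`28` = 40))

  two <- mk(data.frame(temperature = 28, interval_start = c(0, 7),
                       interval_end = c(7, 14),
                       mean_pct_change = c(0, 100), n = 2))
  expect_equal(rateOfChange(two), c(`28` = 50))
  expect_equal(rateOfChange(two, dropFirstInterval = TRUE), c(`28` = 100))

  # with equal replicate counts, mean of means = pooled mean
  fx <- simulateAndProfile(29, cfg = gelRenderConfig(height = 200))
  mw <- movingWindow(fx$profiles, fx$design)
  roc <- rateOfChange(mw)
  v <- windowValues(mw)
  pooled <- tapply(v$pct_change, v$temperature, mean)
  expect_equal(roc, c(pooled)[names(roc)], tolerance = 1e-12)
})
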