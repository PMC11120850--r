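test_that("lane detection finds rendered lane centers within 2 px", {
  pool <- separatedPool(12, 8)
  ab <- randomLanes(pool, 12, 4, 8)
  cfg <- gelRenderConfig()
  res <- renderGel(ab, pool, cfg, seed = 8)
  spans <- detectLanes(res$image, 12)
  expect_equal(nrow(spans), 12)
  expect_true(all(spans$from[-1] > spans$to[-12]))  # non-overlapping
  found <- (spans$from + spans$to) / 2
  truth <- DGGEtools:::.laneCenters(cfg)
  expect_true(all(abs(found - truth) <= 2))
})

test_that("degenerate lane layouts fall back sensibly", {
  img <- GelImage(matrix(5, 100, 80))
  expect_equal(detectLanes(img, 1),
               data.frame(lane = 1L, from = 1L, to = 80L))
  blank <- GelImage(matrix(0, 100, 80))
  expect_warning(spans <- detectLanes(blank, 4), "uniform")
  expect_equal(spans$from, c(1L, 21L, 41L, 61L))
  expect_equal(spans$to, c(20L, 40L, 60L, 80L))
  expect_error(detectLanes(GelImage(matrix(0, 100, 3)), 5), "fewer")
})

test_that("profile extraction averages the span and ignores lane width", {
  img <- GelImage(matrix(7, 100, 40))
  p <- extractProfile(img, list(from = 5, to = 20))
  expect_equal(profileValues(p), rep(7, 100))

  # same band energy split over two half-intensity columns vs one column
  m1 <- matrix(0, 100, 10); m2 <- matrix(0, 100, 10)
  band <- exp(-((1:100 - 40)^2) / 18)
  m1[, 5] <- band * 2
  m2[, 5] <- band; m2[, 6] <- band
  p1 <- extractProfile(GelImage(m1), list(from = 5, to = 5))
  p2 <- extractProfile(GelImage(m2), list(from = 5, to = 6))
  expect_equal(profileValues(p1) / 2, profileValues(p2))

  expect_error(extractProfile(img, list(from = 10, to = 5)), "empty")
  expect_error(extractProfile(img, list(from = 30, to = 45)), "outside")
})

test_that("morphological opening removes baselines but keeps peaks", {
  flat <- LaneProfile("f", rep(4, 200))
  expect_equal(profileValues(subtractBackground(flat, 0.1)), rep(0, 200))

  # narrow Gaussian on a constant offset: offset goes, peak height stays
  x <- seq_len(500)
  prof <- LaneProfile("g", 50 + 100 * exp(-((x - 250)^2) / (2 * 4^2)))
  out <- profileValues(subtractBackground(prof, 0.1))
  expect_lt(abs(max(out) - 100) / 100, 0.05)
  expect_equal(out[1:100], rep(0, 100))

  # monotone ramp: residual bounded by range x window
  ramp <- LaneProfile("r", seq(0, 100, length.out = 300))
  res <- profileValues(subtractBackground(ramp, 0.1))
  expect_true(all(res < 100 * 0.1 + 1e-9))

  expect_error(subtractBackground(LaneProfile("s", rep(1, 10)), 0.1),
               "< 3")
})

test_that("opening matches a brute-force erosion/dilation oracle", {
  bruteOpening <- function(x, w) {
    n <- length(x); h <- (w - 1) %/% 2
    ero <- sapply(1:n, function(i) min(x[max(1, i - h):min(n, i + h)]))
    sapply(1:n, function(i) max(ero[max(1, i - h):min(n, i + h)]))
  }
  set.seed(42)
  for (rep in 1:20) {
    x <- abs(rnorm(60)) * 10
    w <- sample(c(3, 5, 9, 15), 1)
    got <- profileValues(subtractBackground(LaneProfile("x", x), w / 60))
    expect_equal(got, pmax(x - bruteOpening(x, w), 0))
  }
})

test_that("profile normalization hits its identities exactly", {
  x <- seq_len(128)
  p <- LaneProfile("p", 3 + 2 * sin(x / 9)^2)
  expect_equal(max(profileValues(normalizeProfile(p, 200, "max"))), 1)
  expect_equal(sum(profileValues(normalizeProfile(p, 200, "total"))), 1)

  # linear interpolation reproduces affine profiles exactly
  lin <- LaneProfile("l", 2 + 3 * seq(0, 1, length.out = 100))
  out <- normalizeProfile(lin, 73, "max")
  grid <- profilePositions(out)
  expect_equal(profileValues(out), (2 + 3 * grid) / 5)

  expect_warning(z <- normalizeProfile(LaneProfile("z", rep(0, 64)), 40),
                 "all-zero")
  expect_equal(profileValues(z), rep(0, 40))
})

test_that("processed zero-noise gels put argmaxima on true band rows", {
  pool <- separatedPool(6, 13, minSep = 0.08)
  ab <- matrix(0, 6, 3)
  ab[1:2, 1] <- c(0.6, 0.4)
  ab[3:4, 2] <- c(0.5, 0.5)
  ab[5:6, 3] <- c(0.7, 0.3)
  cfg <- cleanRenderConfig(nLanes = 3, height = 400)
  res <- renderGel(ab, pool, cfg, seed = 1)
  prof <- processGel(res$image,
                     data.frame(lane = c("a", "b", "c")),
                     resolution = 500)
  step <- 1 / 499
  v <- profileValues(prof)
  pos <- profilePositions(prof)
  for (j in 1:3) {
    truePos <- pool$melting_position[ab[, j] > 0]
    locmax <- which(diff(sign(diff(v[, j]))) < 0) + 1L
    # strongest local maxima must match true band positions on the grid
    top <- locmax[order(v[locmax, j], decreasing = TRUE)][1:2]
    expect_true(all(abs(sort(pos[top]) - sort(truePos)) <= step + 1e-9))
  }
})

test_that("gel images survive a TIFF round trip", {
  pool <- separatedPool(4, 2)
  ab <- randomLanes(pool, 2, 2, 2)
  res <- renderGel(ab, pool, gelRenderConfig(nLanes = 2, height = 100),
                   seed = 2)
  tf <- tempfile(fileext = ".tiff")
  writeGelImage(res$image, tf)
  back <- readGelImage(tf, bitDepth = 16L)
  # 16-bit storage quantizes intensities to whole grey levels
  expect_lte(max(abs(gelIntensity(back) - gelIntensity(res$image))), 1)
  unlink(tf)
})
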