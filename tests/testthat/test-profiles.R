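test_that("density maps conserve track-point mass", {
  g <- unitGeometry()
  # single stationary cell: its bin holds 1/bin_area, others 0
  tr <- stationaryTrack(-325, 125, n = 40)
  dm <- densityMap(tr, g, cellSize = 50)
  expect_equal(sum(dm$counts), 40)
  expect_equal(max(dm$density), 1 / 50^2)
  expect_equal(sum(dm$density > 0), 1L)

  # uniform points: total mass equals the number of points
  set.seed(31)
  tr2 <- pointsAsTracks(cbind(runif(4000, -600, -100), runif(4000, -250, 250)))
  nF <- diff(range(tr2$frame)) + 1
  dm2 <- densityMap(tr2, g, cellSize = 50)
  expect_equal(sum(dm2$counts), 4000)
  expect_equal(sum(dm2$density) * 50^2 * nF, 4000)
  expect_error(densityMap(tr2[0, ], g), "empty")
})

test_that("axial profiles bin and normalise correctly", {
  g <- unitGeometry()
  tr <- pointsAsTracks(cbind(rep(10, 50), runif(50, -90, 90)))
  pr <- axialProfile(tr, g, binWidth = 20, depth = 100, nFrames = 1)
  expect_equal(pr@counts, c(50, 0, 0, 0, 0))
  expect_equal(pr@density[1], 50 / (20 * 200 * 1))
  expect_error(axialProfile(tr, g, binWidth = 0), "> 0")

  # sampling oracle: multinomial draw from the model density
  set.seed(32)
  p <- sampleExponentialPositions(100, 100, 5, 5000, insideRect(600), g)
  pr2 <- axialProfile(pointsAsTracks(p), g, binWidth = 20, depth = 600,
                      nFrames = 1)
  expect_equal(sum(pr2@counts), 5000)
  f <- function(x) 100 * exp(-x / 100) + 5
  mids <- binCenters(pr2)
  w <- vapply(seq_along(mids), function(j)
    integrate(f, (j - 1) * 20, j * 20)$value, numeric(1))
  expected <- 5000 * w / sum(w)
  chisq <- sum((pr2@counts - expected)^2 / expected)
  expect_gt(pchisq(chisq, df = length(expected) - 1, lower.tail = FALSE),
            1e-3)
})

test_that("radial profiles are area-normalised semi-annuli", {
  g <- unitGeometry()
  # uniform points in the front semicircle: flat density
  set.seed(33)
  n <- 30000
  r <- 400 * sqrt(runif(n)); th <- runif(n, pi / 2, 3 * pi / 2)
  tr <- pointsAsTracks(cbind(r * cos(th), r * sin(th)))
  pr <- radialProfile(tr, g, binWidth = 50, maxRadius = 400, nFrames = 1)
  expect_lt(diff(range(pr@density)) / mean(pr@density), 0.15)

  # spike at r = 55
  tr2 <- pointsAsTracks(cbind(-55 * cos(seq(0, 1, length.out = 30)),
                              -55 * sin(seq(0, 1, length.out = 30))))
  pr2 <- radialProfile(tr2, g, binWidth = 10, maxRadius = 100, nFrames = 1)
  expect_equal(which(pr2@counts > 0), 6L)  # bin (50, 60]

  # Monte-Carlo area oracle: density equals counts / MC-estimated bin area
  set.seed(34)
  mc <- cbind(runif(4e5, -400, 400), runif(4e5, -400, 400))
  keep <- mc[, 1] < 0 & sqrt(rowSums(mc^2)) <= 400
  rmc <- sqrt(rowSums(mc[keep, , drop = FALSE]^2))
  areaMC <- tabulate(findInterval(rmc, seq(0, 400, 50),
                                  rightmost.closed = TRUE), 8) /
    sum(keep) * (pi * 400^2 / 2)
  withMC <- pr@counts / areaMC
  expect_equal(withMC, pr@density, tolerance = 0.05)
})

test_that("noiseless exponential profiles are recovered exactly", {
  x <- seq(10, 790, by = 20)
  y <- 100 * exp(-x / 150) + 5
  fit <- fitExponential(list(x = x, y = y))
  expect_equal(decayLength(fit), 150, tolerance = 1e-6)
  expect_equal(amplitude(fit), 100, tolerance = 1e-6)
  expect_equal(baseline(fit), 5, tolerance = 1e-6)

  # constant profile: degeneracy flag, no lambda
  fit0 <- fitExponential(list(x = x, y = rep(3, length(x))))
  expect_true(fit0@degenerate)
  expect_true(is.na(decayLength(fit0)))
})

test_that("noisy exponential fits agree with a dense grid-search oracle", {
  g <- unitGeometry()
  set.seed(35)
  p <- sampleExponentialPositions(100, 80, 4, 5000, insideRect(600), g)
  pr <- axialProfile(pointsAsTracks(p), g, binWidth = 20, depth = 600,
                     nFrames = 1)
  fit <- fitExponential(pr)
  # oracle: profile lambda over a dense grid, (a, b) by linear LS given
  # lambda
  x <- binCenters(pr); y <- pr@density
  rssAt <- function(lam) {
    X <- cbind(exp(-x / lam), 1)
    sum(lm.fit(X, y)$residuals^2)
  }
  grid <- seq(40, 300, by = 0.25)
  lamGrid <- grid[which.min(vapply(grid, rssAt, numeric(1)))]
  expect_lt(abs(decayLength(fit) - lamGrid), 1)
  expect_lt(abs(decayLength(fit) - 100) / 100, 0.15)
})

test_that("plateau-exponential fits recover noiseless parameters", {
  x <- seq(25, 2975, by = 50)
  L0 <- 500; lam <- 700; a <- 40; b <- 2
  y <- ifelse(x <= L0, a + b, a * exp(-(x - L0) / lam) + b)
  fit <- fitPlateauExponential(list(x = x, y = y))
  expect_equal(plateauLength(fit), 500, tolerance = 1e-4)
  expect_equal(decayLength(fit), 700, tolerance = 1e-5)
  expect_equal(amplitude(fit), 40, tolerance = 1e-5)

  # L0 = 0 data reduce to the plain exponential fit
  y2 <- a * exp(-x / lam) + b
  f2 <- fitPlateauExponential(list(x = x, y = y2))
  fe <- fitExponential(list(x = x, y = y2))
  expect_lt(plateauLength(f2), 50)
  expect_equal(decayLength(f2), decayLength(fe), tolerance = 1e-3)
})

test_that("profiled breakpoint equals the exhaustive edge search", {
  set.seed(36)
  edges <- seq(0, 3000, by = 100)
  x <- edges[-1] - 50
  y <- ifelse(x <= 700, 42, 40 * exp(-(x - 700) / 600) + 2) +
    rnorm(length(x), 0, 1)
  y <- pmax(y, 0)
  prof <- new("ConcentrationProfile", region = "inside", binEdges = edges,
              density = y, counts = round(y * 10), nFrames = 1)
  fit <- fitPlateauExponential(prof, refine = FALSE)
  # oracle: exhaustive search over candidate bin edges
  rssAt <- function(L0) {
    X <- cbind(ifelse(x <= L0, 1, exp(-(x - L0) / decayLength(fit))), 1)
    sum(lm.fit(X, y)$residuals^2)
  }
  cand <- edges[edges <= sort(x, decreasing = TRUE)[4]]
  best <- cand[which.min(vapply(cand, rssAt, numeric(1)))]
  expect_equal(plateauLength(fit), best)
})

test_that("model selection prefers the true generating model", {
  x <- seq(25, 1975, by = 50)
  yExp <- 60 * exp(-x / 300) + 3
  selE <- selectProfileModel(list(x = x, y = yExp + rnorm(length(x), 0, 0.3)))
  expect_equal(selE$model, "exponential")

  yPw <- ifelse(x <= 800, 63, 60 * exp(-(x - 800) / 300) + 3)
  selP <- selectProfileModel(list(x = x, y = yPw + rnorm(length(x), 0, 0.3)))
  expect_equal(selP$model, "piecewise")
  expect_gt(selP$deltaAIC, 2)
})

test_that("replicate decay lengths average arithmetically", {
  g <- unitGeometry()
  fits <- lapply(1:3, function(s) {
    p <- sampleExponentialPositions(120, 80, 4, 3000, insideRect(700), g,
                                    seed = 40 + s)
    fitExponential(axialProfile(pointsAsTracks(p), g, binWidth = 20,
                                depth = 700, nFrames = 1))
  })
  avg <- averageDecayLength(fits)
  expect_equal(avg$mean, mean(vapply(fits, decayLength, numeric(1))))
  expect_equal(avg$n, 3L)
})

test_that("profile fits export to CSV and JSON", {
  g <- unitGeometry()
  p <- sampleExponentialPositions(100, 80, 4, 2000, insideRect(600), g,
                                  seed = 44)
  pr <- axialProfile(pointsAsTracks(p), g, binWidth = 20, depth = 600,
                     nFrames = 1)
  fit <- fitExponential(pr)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  out <- exportProfileFit(pr, fit, csv, js)
  tab <- read.csv(csv)
  expect_equal(tab$density, pr@density)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$lam, decayLength(fit), tolerance = 1e-12)
})
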