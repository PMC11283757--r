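test_that("instantaneous speeds match finite differences", {
  # straight motion, 5 um per frame at 30 fps
  tr <- trackFromPositions(cbind(5 * (0:29), 0))
  sp <- instantaneousSpeed(cbind(tr$x_um, tr$y_um), tr$t_s)
  expect_equal(sp, rep(150, 29))
  # stationary cell
  sp0 <- instantaneousSpeed(cbind(rep(1, 10), rep(2, 10)), (0:9) / 30)
  expect_equal(sp0, rep(0, 9))
  expect_error(instantaneousSpeed(cbind(0:3, 0), rep(0, 4)), "time step")

  # sinusoidal path: oracle = finite differences of smoothed positions
  t <- (0:99) / 30
  pos <- cbind(100 * t, 20 * sin(2 * pi * t))
  sp2 <- instantaneousSpeed(pos, t, smoothingWindow = 3)
  sm <- function(v) {
    n <- length(v)
    out <- v
    for (i in 2:(n - 1)) out[i] <- mean(v[(i - 1):(i + 1)])
    out
  }
  smoothed <- cbind(sm(pos[, 1]), sm(pos[, 2]))
  oracle <- sqrt(diff(smoothed[, 1])^2 + diff(smoothed[, 2])^2) / diff(t)
  expect_equal(sp2, oracle)
})

test_that("straightness follows its analytic values", {
  expect_equal(straightness(cbind(seq(0, 98, 2), 0)), 1)
  # closed loop back to the start
  th <- seq(0, 2 * pi, length.out = 200)
  expect_lt(straightness(cbind(cos(th), sin(th))), 0.01)
  # semicircular arc: S = 2 / pi
  th2 <- seq(0, pi, length.out = 2000)
  expect_equal(straightness(cbind(cos(th2), sin(th2))), 2 / pi,
               tolerance = 1e-5)
  expect_error(straightness(matrix(c(1, 2), 1, 2)), "at least 2")
  expect_error(straightness(cbind(c(1, 1), c(2, 2))), "zero path")
})

test_that("straightness is bounded and invariant under similarity maps", {
  set.seed(71)
  for (i in 1:50) {
    p <- randomWalk(sample(5:60, 1), step = runif(1, 1, 10), seed = i)
    S <- straightness(p)
    expect_gte(S, 0); expect_lte(S, 1)
    # rotation + translation + uniform scaling leave S unchanged
    th <- runif(1, 0, 2 * pi); sc <- runif(1, 0.1, 10)
    R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    q <- sc * t(R %*% t(p)) + matrix(runif(2, -50, 50), nrow(p), 2,
                                     byrow = TRUE)
    expect_equal(straightness(q), S, tolerance = 1e-9)
  }
  # S = 1 iff points are collinear and monotonically ordered
  expect_equal(straightness(cbind(c(0, 1, 2, 5), c(0, 2, 4, 10))), 1)
  expect_lt(straightness(cbind(c(0, 2, 1), c(0, 0, 0))), 1)
})

test_that("radial tracks are classified ingoing and outgoing", {
  g <- unitGeometry()
  n <- 120
  # radially inbound track crossing the corona after t > 60 s
  rIn <- seq(500, 10, length.out = n)
  tIn <- trackFromPositions(cbind(-rIn / sqrt(2), -rIn / sqrt(2)),
                            frameRate = 1)
  tIn$t_s <- tIn$t_s + 100; tIn$frame <- tIn$frame + 100
  segs <- classifySegments(tIn, g)
  expect_equal(unique(vapply(segs, `[[`, character(1), "label")), "ingoing")

  tOut <- tIn
  tOut$x_um <- rev(tIn$x_um); tOut$y_um <- rev(tIn$y_um)
  segsO <- classifySegments(tOut, g)
  expect_equal(unique(vapply(segsO, `[[`, character(1), "label")),
               "outgoing")
  expect_error(classifySegments(tIn, g, corona = coronaRegion(60, 300),
                                patchRadius = 200), "beyond the patch")
})

test_that("segment classification matches a point-by-point oracle", {
  g <- unitGeometry()
  m <- gradientModel(20)
  tr <- simulateAssay(swimmerConfig(nCells = 40, duration = 120,
                                    dt = 1 / 60, seed = 72), m, g)
  corona <- makeCorona(130)
  segs <- classifySegments(tr, g, corona = corona)
  # oracle: independent rle-free scan applying the same predicates
  oracle <- list()
  for (id in unique(tr$track_id)) {
    d <- tr[tr$track_id == id, ]
    d <- d[order(d$frame), ]
    r <- sqrt(d$x_um^2 + d$y_um^2)
    inCor <- d$t_s > 60 & r <= 200 & r >= corona@coronaInner &
      r <= corona@coronaOuter
    i <- 1
    while (i <= nrow(d)) {
      if (!inCor[i]) { i <- i + 1; next }
      j <- i
      while (j < nrow(d) && inCor[j + 1]) j <- j + 1
      lo <- max(i - 1, 1); hi <- min(j + 1, nrow(d))
      if (hi - lo + 1 >= 3) {
        dr <- r[hi] - r[lo]
        if (abs(dr) >= 0.8 * (corona@coronaOuter - corona@coronaInner))
          oracle[[length(oracle) + 1]] <-
            list(id = id, lab = if (dr < 0) "ingoing" else "outgoing",
                 n = hi - lo + 1)
      }
      i <- j + 1
    }
  }
  dirSegs <- Filter(function(s) s$label != "neutral", segs)
  expect_equal(length(dirSegs), length(oracle))
  expect_equal(vapply(dirSegs, `[[`, character(1), "label"),
               vapply(oracle, `[[`, character(1), "lab"))
  expect_equal(vapply(dirSegs, function(s) nrow(s$positions), numeric(1)),
               vapply(oracle, `[[`, numeric(1), "n"))
})

test_that("arc-length truncation is exact at the full length", {
  p <- randomWalk(40, step = 4, seed = 73)
  L <- sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
  tp <- truncateToArcLength(p, L - 1e-9)
  expect_equal(straightness(tp), straightness(p), tolerance = 1e-6)
  expect_null(truncateToArcLength(p, L + 1))
  # interpolated endpoint sits exactly at the requested arc length
  tp2 <- truncateToArcLength(p, 37.5)
  steps <- sqrt(diff(tp2[, 1])^2 + diff(tp2[, 2])^2)
  expect_equal(sum(steps), 37.5)
})

test_that("straightness robustness separates ballistic from diffusive", {
  # ballistic segments: median S about 1 at all lengths
  segsB <- lapply(1:30, function(i) {
    th <- runif(1, 0, 2 * pi)
    list(positions = cbind(cos(th) * seq(0, 300, 5),
                           sin(th) * seq(0, 300, 5)))
  })
  rb <- straightnessRobustness(segsB, minSegments = 20)
  expect_true(all(rb$median_S > 0.999))
  expect_false(any(rb$flagged))

  # pure random walks: median S decreases with truncation length
  segsR <- lapply(1:400, function(i) list(positions = randomWalk(200, 5, i)))
  rr <- straightnessRobustness(segsR, minSegments = 50)
  expect_true(all(diff(rr$median_S) < 0))
  expect_warning(straightnessRobustness(segsR[1:3]), "insufficient")
})

test_that("group straightness comparisons use rank tests with Holm", {
  set.seed(74)
  same <- list(a = runif(30, 0.4, 0.6), b = runif(30, 0.4, 0.6),
               c = runif(30, 0.4, 0.6))
  resSame <- compareStraightness(same)
  expect_true(all(resSame$pAdj > 0.01))
  sep <- list(lo = runif(20, 0.1, 0.2), hi = runif(20, 0.9, 1.0))
  expect_lt(compareStraightness(sep)$p, 0.01)
  expect_error(compareStraightness(list(a = 1:2, b = 1:5)), "at least 3")

  # small-n p-values approximate the exact rank permutation law
  a <- c(0.2, 0.5, 0.9, 0.4); b <- c(0.6, 0.8, 0.95, 0.7)
  p <- compareStraightness(list(a = a, b = b))$p
  pw <- wilcox.test(a, b, exact = TRUE)$p.value
  expect_lt(abs(p - pw), 0.1)
})

test_that("speed-distance histograms are column-normalised", {
  g <- unitGeometry()
  m0 <- gradientModel(reservoirConc = 0, Q = 0)
  tr <- simulateAssay(swimmerConfig(nCells = 30, duration = 60,
                                    dt = 1 / 60, chi = 0, kappa = 0,
                                    turnGain = 0, giveUpTime = 0,
                                    seed = 75), m0, g)
  svd <- speedVsDistance(tr, g)
  cs <- colSums(svd$frequency)
  expect_true(all(abs(cs[cs > 0] - 1) < 1e-9))
  # uniform-speed simulation: near/far ratio 1
  expect_equal(svd$ratio, 1, tolerance = 0.02)
})

test_that("chemokinesis closure recovers the generator speed-up", {
  g <- unitGeometry()
  m <- gradientModel(reservoirConc = 20, D = 300)
  tr <- simulateAssay(swimmerConfig(nCells = 50, duration = 150,
                                    dt = 1 / 60, chi = 0, turnGain = 0,
                                    giveUpTime = 0, kappa = 0.5,
                                    seed = 76), m, g)
  svd <- speedVsDistance(tr, g)
  # generator oracle: predicted ratio from the concentration field at the
  # recorded positions
  sp <- trackSpeeds(tr)
  r <- sqrt(sp$x_mid^2 + sp$y_mid^2)
  C <- concentrationAt(cbind(sp$x_mid, sp$y_mid), t = 75, m, g)
  vModel <- 1 + 0.5 * C / (C + 1)
  predicted <- median(vModel[r <= 200]) / median(vModel[r > 200])
  expect_equal(svd$ratio, predicted, tolerance = 0.08)
  expect_gt(svd$ratio, 1.15)
  expect_lt(svd$p, 0.01)
})
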