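test_that("background estimation is the per-pixel temporal median", {
  f <- matrix(runif(400), 20, 20)
  stack <- array(rep(f, 5), dim = c(20, 20, 5))
  expect_equal(estimateBackground(stack), f)

  # a bright blob visiting any pixel in <= 5 of 11 frames leaves no trace
  stack <- array(0.2, dim = c(30, 30, 11))
  for (k in 1:11) stack[10 + k, 15, k] <- 1   # moves one row per frame
  bg <- estimateBackground(stack)
  expect_equal(bg, matrix(0.2, 30, 30))

  # random stack: equals brute-force sort-and-pick median
  set.seed(8)
  stack <- array(runif(16 * 16 * 9), dim = c(16, 16, 9))
  oracle <- apply(stack, c(1, 2), function(v) sort(v)[5])
  expect_equal(estimateBackground(stack), oracle)
  expect_error(estimateBackground(array(0, dim = c(4, 4, 1))), "2 frames")
})

test_that("cell detection recovers sub-pixel centroids", {
  bg <- matrix(0.1, 80, 100)
  expect_equal(nrow(detectCells(bg, bg, threshold = 0.05)), 0L)
  expect_error(detectCells(bg, bg, threshold = 0), "> 0")

  # one Gaussian spot at (x = 40.0, y = 60.0): centroid within 0.5 px
  xs <- matrix(rep(0:99, each = 80), 80, 100)
  ys <- matrix(rep(0:79, 100), 80, 100)
  img <- bg + exp(-((xs - 40)^2 + (ys - 60)^2) / (2 * 1.5^2))
  det <- detectCells(img, bg, threshold = 0.05, minArea = 3)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x - 40), 0.5)
  expect_lt(abs(det$y - 60), 0.5)
})

test_that("detection matches the renderer ground truth for 25 cells", {
  g <- unitGeometry()
  set.seed(21)
  # 25 cells on a jittered grid, one frame; canvas 200x200 px
  gx <- rep(seq(30, 170, length.out = 5), 5) + runif(25, -3, 3)
  gy <- rep(seq(30, 170, length.out = 5), each = 5) + runif(25, -3, 3)
  pos <- toAssayFrame(cbind(gx, gy), g)
  tracks <- data.frame(track_id = 1:25, frame = 0, x_um = pos[, 1],
                       y_um = pos[, 2], t_s = 0)
  stack <- renderFrames(tracks, g, dims = c(200, 200), noiseSd = 0.005,
                        seed = 3)
  det <- detectCells(stack[, , 1], matrix(0.1, 200, 200), threshold = 0.1)
  expect_equal(nrow(det), 25L)
  d <- sqrt(outer(det$x, gx, "-")^2 + outer(det$y, gy, "-")^2)
  expect_lt(max(apply(d, 2, min)), 1)
})

test_that("linking follows single and well-separated blobs", {
  det <- data.frame(frame = 0:29, x = 2 * (0:29), y = 0)
  tr <- linkDetections(det, maxDisplacement = 5)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(nrow(tr), 30L)

  two <- rbind(data.frame(frame = 0:19, x = 0:19, y = 0),
               data.frame(frame = 0:19, x = 0:19, y = 100))
  tr2 <- linkDetections(two, maxDisplacement = 5)
  expect_equal(length(unique(tr2$track_id)), 2L)
  # no identity swap: each track keeps a constant y
  ys <- tapply(tr2$y, tr2$track_id, function(v) length(unique(v)))
  expect_true(all(ys == 1))
  expect_error(linkDetections(two, maxDisplacement = -1), ">= 0")
})

test_that("greedy linking matches exhaustive matching when unambiguous", {
  # oracle: minimum-cost bipartite assignment by permutation enumeration
  optCost <- function(p1, p2) {
    perms <- function(v) if (length(v) == 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(r) c(v[i], r))))
    min(vapply(perms(seq_len(nrow(p2))), function(pr)
      sum(sqrt(rowSums((p1 - p2[pr, , drop = FALSE])^2))), numeric(1)))
  }
  set.seed(13)
  for (rep in 1:10) {
    # 3 well-separated parents moving < 4 um; next frame close to parents
    p1 <- cbind(runif(3, 0, 100), runif(3, 0, 100))
    while (min(dist(p1)) < 30)
      p1 <- cbind(runif(3, 0, 100), runif(3, 0, 100))
    p2 <- p1 + matrix(runif(6, -4, 4), 3, 2)
    det <- rbind(data.frame(frame = 0, x = p1[, 1], y = p1[, 2]),
                 data.frame(frame = 1, x = p2[, 1], y = p2[, 2]))
    tr <- linkDetections(det, maxDisplacement = 15)
    expect_equal(length(unique(tr$track_id)), 3L)
    cost <- sum(vapply(split(tr, tr$track_id), function(d)
      sqrt(diff(d$x)^2 + diff(d$y)^2), numeric(1)))
    expect_equal(cost, optCost(p1, p2), tolerance = 1e-12)
  }
})

test_that("linking is invariant to detection order within a frame", {
  set.seed(17)
  det <- do.call(rbind, lapply(0:9, function(f)
    data.frame(frame = f, x = runif(6, 0, 200), y = runif(6, 0, 200))))
  tr1 <- linkDetections(det, maxDisplacement = 60)
  sh <- det[sample(nrow(det)), ]
  tr2 <- linkDetections(sh, maxDisplacement = 60)
  key <- function(tr) {
    tr <- tr[order(tr$frame, tr$x, tr$y), ]
    # compare the partition of points into tracks, not the id labels
    unname(split(paste(tr$frame, round(tr$x, 9), round(tr$y, 9)),
                 tr$track_id)[order(vapply(
                   split(seq_len(nrow(tr)), tr$track_id), min, integer(1)))])
  }
  expect_setequal(vapply(key(tr1), paste, character(1), collapse = "|"),
                  vapply(key(tr2), paste, character(1), collapse = "|"))
})

test_that("gap closing bridges short disappearances", {
  det <- data.frame(frame = c(0, 1, 2, 5, 6), x = c(0, 2, 4, 10, 12), y = 0)
  tr <- linkDetections(det, maxDisplacement = 8, memory = 2)
  expect_equal(length(unique(tr$track_id)), 1L)
  trNoMem <- linkDetections(det, maxDisplacement = 8, memory = 0)
  expect_equal(length(unique(trNoMem$track_id)), 2L)
})

test_that("track tables round-trip through CSV", {
  g <- unitGeometry()
  set.seed(23)
  tracks <- do.call(rbind, lapply(1:100, function(id)
    trackFromPositions(randomWalk(20, seed = id), id = id)))
  path <- tempfile(fileext = ".csv")
  writeTracks(tracks, path)
  back <- readTracks(path)
  expect_equal(back$x_um, tracks$x_um, tolerance = 1e-9)
  expect_equal(back$track_id, tracks$track_id)

  # shuffled rows come back sorted by track and frame
  shuffled <- tracks[sample(nrow(tracks)), ]
  writeTracks(shuffled, path)
  back2 <- readTracks(path)
  expect_equal(back2$frame, back$frame)
  expect_equal(back2$x_um, back$x_um, tolerance = 1e-9)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("a,b,c", "1,2,3"), bad)
  expect_error(readTracks(bad), "must have columns")

  # pixel tables need a geometry and convert on read
  px <- data.frame(track_id = 1, frame = 0:4, x_px = 0:4, y_px = 0)
  write.csv(px, path, row.names = FALSE)
  expect_error(readTracks(path), "geometry")
  conv <- readTracks(path, g)
  expect_equal(conv$x_um, 0:4)
})

test_that("short tracks are filtered for analysis", {
  tracks <- rbind(trackFromPositions(randomWalk(30), id = 1),
                  trackFromPositions(randomWalk(5), id = 2))
  kept <- filterTracks(tracks, minFrames = 15)
  expect_equal(unique(kept$track_id), 1)
})

test_that("rendered stacks are deterministic and trackable end-to-end", {
  # free disk (capillary shrunk out of the arena) so cells stay on canvas;
  # cell density matches the assay (order 1e-5 cells per um^2)
  g <- assayGeometry(c(0, 0), capillaryWidth = 1, capillaryLength = 1,
                     wallThickness = 0.5)
  m <- gradientModel(reservoirConc = 0, Q = 0)
  sw <- swimmerConfig(nCells = 5, chi = 0, kappa = 0, turnGain = 0,
                      giveUpTime = 0, duration = 3, dt = 1 / 60,
                      arenaRadius = 350, seed = 5)
  tr <- simulateAssay(sw, m, g)
  # shift into a 400x400 px canvas (2 um per px) centred on the arena
  gr <- assayGeometry(c(200, 200), axisDeg = 0, pixelScale = 2,
                      frameRate = 30)
  s1 <- renderFrames(tr, gr, dims = c(400, 400), seed = 9)
  s2 <- renderFrames(tr, gr, dims = c(400, 400), seed = 9)
  expect_identical(s1, s2)

  det <- detectStack(s1, background = matrix(0.1, 400, 400),
                     threshold = 0.12, minArea = 3)
  linked <- linkDetections(det, maxDisplacement = 6, memory = 2)
  # recovery: >= 95% of ground-truth points matched within 1 px
  pxTruth <- fromAssayFrame(cbind(tr$x_um, tr$y_um), gr)
  nHit <- 0
  for (f in unique(tr$frame)) {
    tp <- pxTruth[tr$frame == f, , drop = FALSE]
    dp <- linked[linked$frame == f, c("x", "y")]
    if (!nrow(dp)) next
    d <- sqrt(outer(tp[, 1], dp$x, "-")^2 + outer(tp[, 2], dp$y, "-")^2)
    nHit <- nHit + sum(apply(d, 1, min) < 1)
  }
  expect_gte(nHit / nrow(tr), 0.95)
})
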