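# Shared fixtures: a unit-scale geometry at the origin and small track
# builders used across the module tests.

unitGeometry <- function(frameRate = 30)
  assayGeometry(c(0, 0), axisDeg = 0, pixelScale = 1, frameRate = frameRate)

# geometry with a control capillary on the opposite side of the dish
pairedGeometry <- function(frameRate = 30)
  assayGeometry(c(300, 400), axisDeg = 0, pixelScale = 2,
                frameRate = frameRate,
                controlOriginPx = c(300, 100), controlAxisDeg = 0)

# one track from a position matrix
trackFromPositions <- function(pos, frameRate = 30, id = 1L) {
  n <- nrow(pos)
  data.frame(track_id = id, frame = seq_len(n) - 1L,
             x_um = pos[, 1], y_um = pos[, 2],
             t_s = (seq_len(n) - 1L) / frameRate)
}

# stationary point observed over n frames
stationaryTrack <- function(x, y, n, frameRate = 30, id = 1L)
  trackFromPositions(cbind(rep(x, n), rep(y, n)), frameRate, id)

# points (n x 2 matrix) to a one-frame-per-point pseudo track table
pointsAsTracks <- function(p)
  data.frame(track_id = 1L, frame = seq_len(nrow(p)) - 1L,
             x_um = p[, 1], y_um = p[, 2],
             t_s = (seq_len(nrow(p)) - 1L) / 30)

# 2D random-walk positions with given step length
randomWalk <- function(nSteps, step = 5, seed = 1) {
  set.seed(seed)
  th <- runif(nSteps, 0, 2 * pi)
  cbind(cumsum(c(0, step * cos(th))), cumsum(c(0, step * sin(th))))
}

# small-n exact permutation p-value for the two-group Kruskal-Wallis H
kwPermutationP <- function(a, b) {
  H_of <- function(x, y) capitax::kruskalWallisTwo(x, y)$H
  obs <- H_of(a, b)
  v <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(v), n)
  Hs <- apply(idx, 2, function(i) H_of(v[i], v[-i]))
  mean(Hs >= obs - 1e-12)
}
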