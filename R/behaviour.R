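# centred moving average; endpoints without a full window keep their raw
# values (avoids edge bias on directed motion)
.movavg <- function(v, w) {
  if (w <= 1L) return(v)
  n <- length(v)
  half <- (w - 1L) %/% 2L
  if (n < w) return(v)
  cs <- cumsum(c(0, v))
  out <- v
  i <- (half + 1L):(n - half)
  out[i] <- (cs[i + half + 1L] - cs[i - half]) / (2L * half + 1L)
  out
}

#' Instantaneous swimming speed along a trajectory
#'
#' Centred moving-average smoothing of the positions (default 3 frames, to
#' suppress centroid jitter at video frame rates) followed by
#' finite-difference speeds `|dposition| / dt` per step.
#'
#' @param positions n x 2 matrix, micrometres.
#' @param times length-n vector, seconds, strictly increasing.
#' @param smoothingWindow odd window length in frames (1 disables
#'   smoothing; default 3).
#' @return numeric vector of n - 1 step speeds, um s^-1.
#' @export
instantaneousSpeed <- function(positions, times, smoothingWindow = 3) {
  p <- .as_points(positions)
  if (nrow(p) < 2L) stop("need at least 2 points")
  if (any(diff(times) <= 0)) stop("zero or negative time step")
  xs <- .movavg(p[, 1L], smoothingWindow)
  ys <- .movavg(p[, 2L], smoothingWindow)
  sqrt(diff(xs)^2 + diff(ys)^2) / diff(times)
}

#' Per-step speeds for a whole track table
#'
#' @param tracks assay-frame track table (see [track-tables]).
#' @param smoothingWindow passed to [instantaneousSpeed()].
#' @return `data.frame` with `track_id`, `t_mid`, `x_mid`, `y_mid`,
#'   `speed` (one row per step).
#' @export
trackSpeeds <- function(tracks, smoothingWindow = 3) {
  out <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (nrow(tr) < 2L) return(NULL)
    sp <- instantaneousSpeed(cbind(tr$x_um, tr$y_um), tr$t_s, smoothingWindow)
    data.frame(track_id = tr$track_id[1L],
               t_mid = (tr$t_s[-1L] + tr$t_s[-nrow(tr)]) / 2,
               x_mid = (tr$x_um[-1L] + tr$x_um[-nrow(tr)]) / 2,
               y_mid = (tr$y_um[-1L] + tr$y_um[-nrow(tr)]) / 2,
               speed = sp)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Trajectory straightness index
#'
#' `S = D / L`: net start-to-end displacement over the summed step lengths.
#' `S = 1` for a perfectly straight ordered path, and `S` is much smaller
#' than 1 for convoluted searching paths. Invariant under rotation,
#' translation and uniform scaling.
#'
#' @param segment n x 2 position matrix (n >= 2), or a segment list from
#'   [classifySegments()] (its `positions` element is used).
#' @return S in `[0, 1]`.
#' @examples
#' straightness(cbind(0:9, 0))                    # 1
#' th <- seq(0, pi, length.out = 400)
#' straightness(cbind(cos(th), sin(th)))          # 2 / pi for a semicircle
#' @export
straightness <- function(segment) {
  p <- if (is.list(segment) && !is.null(segment$positions))
    segment$positions else segment
  p <- .as_points(p)
  if (nrow(p) < 2L) stop("a segment needs at least 2 points")
  steps <- sqrt(diff(p[, 1L])^2 + diff(p[, 2L])^2)
  L <- sum(steps)
  if (L <= 0) stop("zero path length")
  D <- sqrt((p[nrow(p), 1L] - p[1L, 1L])^2 + (p[nrow(p), 2L] - p[1L, 2L])^2)
  min(D / L, 1)
}

#' Classify trajectory segments as ingoing, outgoing or neutral
#'
#' Ingoing/outgoing segments are the maximal runs of a trajectory inside
#' the analysis corona, recorded after `tMin` seconds (once the cue patch
#' has developed) and within the patch radius; the label follows the sign of
#' the net radial displacement across the run (toward the source = ingoing).
#' Neutral segments are runs recorded during the first `tMin` seconds at
#' radial distances beyond `neutralRadius`, i.e. before and beyond any cue
#' influence.
#'
#' @param tracks assay-frame track table.
#' @param geometry an [AssayGeometry-class].
#' @param corona a corona [RegionSpec-class] (default [makeCorona()] at
#'   130 um: radii 60-200 um).
#' @param patchRadius developed-patch radius, micrometres (default 200).
#' @param tMin patch development time, seconds (default 60).
#' @param neutralRadius minimum radius for neutral segments, micrometres
#'   (default 400).
#' @param minPoints minimum points per segment (default 3).
#' @param minNetFraction minimum net radial displacement of a directional
#'   segment, as a fraction of the corona width (default 0.8): segments
#'   must genuinely traverse the corona, which excludes radial jitter at
#'   the corona boundaries from both directional classes.
#' @return list of segments, each a list with `track_id`, `label`
#'   (`"ingoing"`, `"outgoing"`, `"neutral"`), `positions`, `times`.
#' @export
classifySegments <- function(tracks, geometry,
                             corona = makeCorona(130),
                             patchRadius = 200, tMin = 60,
                             neutralRadius = 400, minPoints = 3,
                             minNetFraction = 0.8) {
  if (corona@coronaOuter > patchRadius)
    stop("corona extends beyond the patch radius")
  segs <- list()
  runs_of <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts, ends)[r$values, , drop = FALSE]
  }
  for (tr in split(tracks, tracks$track_id)) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    r <- sqrt(tr$x_um^2 + tr$y_um^2)
    # directional segments: in the corona, after patch development
    mask <- tr$t_s > tMin & r <= patchRadius &
      r >= corona@coronaInner & r <= corona@coronaOuter
    for (k in seq_len(nrow(rn <- runs_of(mask)))) {
      # include the crossing steps into/out of the corona so a straight
      # radial crossing retains its full arc length
      i <- max(rn[k, 1L] - 1L, 1L):min(rn[k, 2L] + 1L, nrow(tr))
      if (length(i) < minPoints) next
      dr <- r[i[length(i)]] - r[i[1L]]
      width <- corona@coronaOuter - corona@coronaInner
      if (abs(dr) < minNetFraction * width) next
      segs[[length(segs) + 1L]] <- list(
        track_id = tr$track_id[1L],
        label = if (dr < 0) "ingoing" else "outgoing",
        positions = cbind(tr$x_um[i], tr$y_um[i]), times = tr$t_s[i])
    }
    # neutral segments: early recording, far from the source
    mask <- tr$t_s < tMin & r > neutralRadius
    for (k in seq_len(nrow(rn <- runs_of(mask)))) {
      i <- rn[k, 1L]:rn[k, 2L]
      if (length(i) < minPoints) next
      segs[[length(segs) + 1L]] <- list(
        track_id = tr$track_id[1L], label = "neutral",
        positions = cbind(tr$x_um[i], tr$y_um[i]), times = tr$t_s[i])
    }
  }
  segs
}

#' Summarise segments into a straightness table
#'
#' Because the straightness index depends on trajectory length, segments
#' are truncated to a common arc length (default 7 body lengths of 20 um =
#' 140 um) before computing S; segments shorter than that are dropped. Set
#' `arcLength = NULL` to use full segments.
#'
#' @param segments list from [classifySegments()].
#' @param arcLength standardised arc length, micrometres (default 140;
#'   NULL disables truncation).
#' @return `data.frame` with `track_id`, `label`, `n_points`, `D`, `L`,
#'   `S` (D and L refer to the truncated path).
#' @export
segmentTable <- function(segments, arcLength = 140) {
  empty <- data.frame(track_id = integer(), label = character(),
                      n_points = integer(), D = numeric(), L = numeric(),
                      S = numeric())
  if (!length(segments)) return(empty)
  rows <- lapply(segments, function(s) {
    p <- s$positions
    if (!is.null(arcLength)) {
      p <- truncateToArcLength(p, arcLength)
      if (is.null(p)) return(NULL)
    }
    steps <- sqrt(diff(p[, 1L])^2 + diff(p[, 2L])^2)
    L <- sum(steps)
    D <- sqrt(sum((p[nrow(p), ] - p[1L, ])^2))
    data.frame(track_id = s$track_id, label = s$label, n_points = nrow(p),
               D = D, L = L, S = if (L > 0) min(D / L, 1) else NA_real_)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Truncate a path to a prescribed arc length
#'
#' Walks along the path from its first point and cuts it at cumulative step
#' length `arcLength`, interpolating the final point on the cut step.
#'
#' @param positions n x 2 matrix.
#' @param arcLength target arc length (same units as positions).
#' @return truncated position matrix, or NULL when the path is shorter than
#'   `arcLength`.
#' @export
truncateToArcLength <- function(positions, arcLength) {
  p <- .as_points(positions)
  steps <- sqrt(diff(p[, 1L])^2 + diff(p[, 2L])^2)
  cs <- cumsum(steps)
  if (!length(cs) || cs[length(cs)] < arcLength) return(NULL)
  k <- which(cs >= arcLength)[1L]
  excess <- cs[k] - arcLength
  frac <- if (steps[k] > 0) 1 - excess / steps[k] else 1
  end <- p[k, ] + frac * (p[k + 1L, ] - p[k, ])
  rbind(p[seq_len(k), , drop = FALSE], end)
}

#' Robustness of the straightness index to segment length
#'
#' The straightness index depends on trajectory length, so medians are
#' compared across arc-length standardised truncations of the segments,
#' spanning 3 to 10 body lengths by default. Lengths whose median deviates
#' by more than 10% from the reference length's median are flagged.
#'
#' @param segments list from [classifySegments()] (or any list with
#'   `positions`).
#' @param lengthsBL numeric vector of truncation lengths in body lengths
#'   (default `3:10`).
#' @param bodyLength body length, micrometres (default 20).
#' @param referenceBL reference truncation for the stability flag
#'   (default 7).
#' @param minSegments minimum usable segments per length (default 20);
#'   lengths with fewer are reported NA with a warning.
#' @return `data.frame` with `length_bl`, `length_um`, `n`, `median_S`,
#'   `flagged`.
#' @export
straightnessRobustness <- function(segments, lengthsBL = 3:10,
                                   bodyLength = 20, referenceBL = 7,
                                   minSegments = 20) {
  res <- lapply(lengthsBL, function(bl) {
    lum <- bl * bodyLength
    Ss <- vapply(segments, function(s) {
      tp <- truncateToArcLength(s$positions, lum)
      if (is.null(tp)) NA_real_ else straightness(tp)
    }, numeric(1L))
    Ss <- Ss[is.finite(Ss)]
    data.frame(length_bl = bl, length_um = lum, n = length(Ss),
               median_S = if (length(Ss) >= minSegments) median(Ss)
                          else NA_real_)
  })
  out <- do.call(rbind, res)
  if (any(is.na(out$median_S)))
    warning("insufficient segments (< ", minSegments, ") at ",
            sum(is.na(out$median_S)), " length(s)")
  ref <- out$median_S[which.min(abs(out$length_bl - referenceBL))]
  out$flagged <- is.finite(out$median_S) & is.finite(ref) &
    abs(out$median_S - ref) > 0.1 * abs(ref)
  out
}

#' Pairwise comparison of straightness distributions
#'
#' Two-sided Mann-Whitney rank-sum tests between every pair of groups, with
#' Holm correction for the number of pairs.
#'
#' @param groups named list of numeric S samples (>= 3 values each).
#' @return `data.frame` with `group1`, `group2`, `p`, `pAdj`.
#' @export
compareStraightness <- function(groups) {
  if (any(vapply(groups, length, integer(1L)) < 3L))
    stop("each group needs at least 3 values")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2L)
  p <- apply(pairs, 2L, function(ij)
    suppressWarnings(wilcox.test(groups[[ij[1L]]], groups[[ij[2L]]],
                                 exact = FALSE)$p.value))
  data.frame(group1 = nm[pairs[1L, ]], group2 = nm[pairs[2L, ]],
             p = p, pAdj = p.adjust(p, "holm"))
}

#' Speed versus radial distance and chemokinesis test
#'
#' Two-dimensional relative-frequency histogram of instantaneous speeds
#' against radial distance from the cue source (frequencies sum to 1 within
#' each radial bin), plus a chemokinesis statistic: the ratio of the median
#' speed within `cueRadius` of the source to the median speed in the
#' remaining area (also excluding the surroundings of the control capillary
#' entrance when the geometry defines one), with a two-sided rank-sum
#' p-value.
#'
#' @param tracks assay-frame track table.
#' @param geometry an [AssayGeometry-class].
#' @param speedBins,radialBins bin edges (defaults: speeds 0-400 by
#'   25 um s^-1; radii 0-1000 by 100 um).
#' @param cueRadius near-source radius, micrometres (default 200).
#' @param smoothingWindow passed to [trackSpeeds()].
#' @return list with `speedBins`, `radialBins`, `frequency` matrix
#'   (speed x radius), `ratio`, `p`, `medianNear`, `medianFar`, `nNear`,
#'   `nFar`.
#' @export
speedVsDistance <- function(tracks, geometry,
                            speedBins = seq(0, 400, by = 25),
                            radialBins = seq(0, 1000, by = 100),
                            cueRadius = 200, smoothingWindow = 3) {
  sp <- trackSpeeds(tracks, smoothingWindow)
  if (is.null(sp) || !nrow(sp)) stop("no speeds computable")
  r <- sqrt(sp$x_mid^2 + sp$y_mid^2)
  si <- findInterval(pmin(sp$speed, max(speedBins)), speedBins,
                     rightmost.closed = TRUE)
  ri <- findInterval(r, radialBins, rightmost.closed = TRUE)
  ok <- si >= 1 & si <= length(speedBins) - 1L &
    ri >= 1 & ri <= length(radialBins) - 1L
  freq <- matrix(0, length(speedBins) - 1L, length(radialBins) - 1L)
  tab <- table(factor(si[ok], levels = seq_len(nrow(freq))),
               factor(ri[ok], levels = seq_len(ncol(freq))))
  freq[] <- as.numeric(tab)
  colSums_ <- colSums(freq)
  nzc <- colSums_ > 0
  freq[, nzc] <- sweep(freq[, nzc, drop = FALSE], 2L, colSums_[nzc], "/")
  near <- r <= cueRadius
  far <- !near
  if (all(is.finite(geometry@controlOrigin))) {
    cg <- controlGeometry(geometry)
    pxy <- fromAssayFrame(cbind(sp$x_mid, sp$y_mid), geometry)
    um <- toAssayFrame(pxy, cg)
    far <- far & sqrt(um[, 1L]^2 + um[, 2L]^2) > cueRadius
  }
  vNear <- sp$speed[near]; vFar <- sp$speed[far]
  if (!length(vNear) || !length(vFar))
    stop("no steps in the near or far zone")
  p <- suppressWarnings(wilcox.test(vNear, vFar, exact = FALSE)$p.value)
  list(speedBins = speedBins, radialBins = radialBins, frequency = freq,
       ratio = median(vNear) / median(vFar), p = p,
       medianNear = median(vNear), medianFar = median(vFar),
       nNear = length(vNear), nFar = length(vFar))
}
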