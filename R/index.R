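#' Per-frame cell counts inside a region
#'
#' Counts track points falling in a region at every frame of the recording
#' (frames with no detections count zero).
#'
#' @param tracks assay-frame track table (see [track-tables]).
#' @param region a [RegionSpec-class].
#' @param geometry an [AssayGeometry-class].
#' @param frameRange optional `c(first, last)` frame indices; defaults to
#'   the observed span.
#' @return a [CountSeries-class].
#' @export
countInRegion <- function(tracks, region, geometry, frameRange = NULL) {
  if (!nrow(tracks)) stop("empty track table")
  if (is.null(frameRange)) frameRange <- range(tracks$frame)
  frames <- seq(frameRange[1L], frameRange[2L])
  inside <- regionMembership(cbind(tracks$x_um, tracks$y_um), region, geometry)
  counts <- tabulate(
    factor(tracks$frame[inside], levels = frames), nbins = length(frames))
  new("CountSeries", times = frames / geometry@frameRate,
      counts = as.numeric(counts), region = region)
}

#' Contiguous window with the maximum mean count
#'
#' Slides a window of `windowS` seconds over the series and returns the
#' earliest window maximising the mean count.
#'
#' @param series a [CountSeries-class] (uniformly sampled).
#' @param windowS window length, seconds (default 120, the 2-minute
#'   accumulation window).
#' @return list with `window` = `c(start, end)` seconds, `mean`, and the
#'   0-based `startIndex`.
#' @export
maxMeanWindow <- function(series, windowS = 120) {
  dt <- diff(series@times)
  if (max(abs(dt - dt[1L])) > 1e-6 * dt[1L])
    stop("series must be uniformly sampled")
  n <- length(series@counts)
  nw <- round(windowS / dt[1L]) + 1L
  if (nw > n) stop("series shorter than the requested window")
  cs <- cumsum(c(0, series@counts))
  means <- (cs[(nw + 1L):(n + 1L)] - cs[1L:(n - nw + 1L)]) / nw
  i <- which.max(means)  # which.max returns the first maximum: earliest tie
  list(window = c(series@times[i], series@times[i + nw - 1L]),
       mean = means[i], startIndex = i - 1L)
}

#' Two-group Kruskal-Wallis rank test
#'
#' Thin wrapper around [stats::kruskal.test()] for the two-group case,
#' returning the tie-corrected H statistic and its chi-square p-value with
#' one degree of freedom. When every value in both groups is identical the
#' statistic is 0 and p = 1.
#'
#' @param a,b numeric count vectors (each of length >= 2).
#' @return list with `H` and `p`.
#' @export
kruskalWallisTwo <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (diff(range(c(a, b))) == 0) return(list(H = 0, p = 1))
  kt <- kruskal.test(list(a, b))
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

# Integrated autocorrelation time of a count series, in samples:
# tau = 1 + 2 * sum(rho_k) over the initial positive sequence of
# autocorrelations (stopping at the first non-positive lag).
.acf_thin_step <- function(x) {
  n <- length(x)
  if (n < 3L || sd(x) == 0) return(1L)
  maxLag <- min(n - 2L, max(10L, n %/% 4L))
  rho <- stats::acf(x, lag.max = maxLag, plot = FALSE)$acf[-1L]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1L] - 1L)]
  tau <- 1 + 2 * sum(rho)
  max(1L, as.integer(ceiling(tau)))
}

#' Autocorrelation-corrected two-group rank test on count series
#'
#' Per-frame region counts are strongly autocorrelated (a cell stays in a
#' region for many consecutive frames), which makes the nominal per-frame
#' Kruskal-Wallis p-value anti-conservative. This variant subsamples both
#' series to 1 Hz and then thins by the integrated autocorrelation time
#' (initial-positive-sequence estimator) so the retained counts are
#' approximately independent, before applying the rank test. The thinning
#' step is capped so that at least about 10 samples per group survive.
#'
#' @param a,b per-frame count vectors.
#' @param frameRate frames per second of the series.
#' @return list with `H`, `p`, and `nEff` (retained samples per group).
#' @export
kruskalWallisCorrected <- function(a, b, frameRate = 30) {
  step1 <- max(1L, as.integer(round(frameRate)))   # to 1 Hz
  a1 <- a[seq(1L, length(a), by = step1)]
  b1 <- b[seq(1L, length(b), by = step1)]
  step2 <- max(.acf_thin_step(a1), .acf_thin_step(b1))
  # keep at least ~10 retained samples per group so the rank test retains
  # power on strongly trending (high-ACT) series
  step2 <- min(step2, max(1L, min(length(a1), length(b1)) %/% 10L))
  a2 <- a1[seq(1L, length(a1), by = step2)]
  b2 <- b1[seq(1L, length(b1), by = step2)]
  if (length(a2) < 2L || length(b2) < 2L) { a2 <- a1; b2 <- b1 }
  kw <- kruskalWallisTwo(a2, b2)
  c(kw, list(nEff = c(length(a2), length(b2))))
}

#' Gated chemotactic index for one region pair
#'
#' Ratio of the mean cue-region count over its best accumulation window of
#' `windowS` seconds to the mean count in the congruent control region over
#' the entire assay. The index is gated to 1 (neutral) when the cue/control
#' count difference is not significant at `alpha`; by default the gate uses
#' the autocorrelation-corrected rank-test p-value
#' ([kruskalWallisCorrected()]), and the nominal per-frame p-value is
#' reported alongside. A zero control mean yields `Inf` with
#' `undefined = TRUE`.
#'
#' @param cue,control [CountSeries-class] objects on congruent regions.
#' @param alpha gate significance level (default 0.01).
#' @param windowS accumulation window, seconds (default 120).
#' @param frameRate frames per second (for the corrected test; default
#'   inferred from the series spacing).
#' @param gateOn `"corrected"` (default) or `"raw"`: which p-value drives
#'   the gate.
#' @return list with `ic`, `gated`, `pRaw`, `pCorr`, `window`, `cueMean`,
#'   `controlMean`, `undefined`.
#' @export
chemotacticIndex <- function(cue, control, alpha = 0.01, windowS = 120,
                             frameRate = NULL,
                             gateOn = c("corrected", "raw")) {
  gateOn <- match.arg(gateOn)
  if (!length(cue@counts) || !length(control@counts))
    stop("empty count series")
  if (is.null(frameRate)) frameRate <- 1 / median(diff(cue@times))
  win <- maxMeanWindow(cue, windowS)
  controlMean <- mean(control@counts)
  pRaw <- kruskalWallisTwo(cue@counts, control@counts)$p
  pCorr <- kruskalWallisCorrected(cue@counts, control@counts, frameRate)$p
  pGate <- if (gateOn == "corrected") pCorr else pRaw
  gated <- pGate > alpha
  undefined <- FALSE
  if (gated) {
    ic <- 1
  } else if (controlMean == 0) {
    ic <- Inf
    undefined <- TRUE
  } else {
    ic <- win$mean / controlMean
  }
  list(ic = ic, gated = gated, pRaw = pRaw, pCorr = pCorr,
       window = win$window, cueMean = win$mean, controlMean = controlMean,
       undefined = undefined)
}

#' Inside and outside chemotactic indices of an assay
#'
#' Convenience wrapper computing the gated maximum chemotactic index inside
#' the capillary (rectangular region of depth `lambdaIn`) and in the outside
#' patch (semicircle of radius `lambdaOut`), using the cue capillary's own
#' fitted decay lengths for both the cue and the congruent control regions.
#'
#' @param tracks assay-frame track table (cue capillary at the origin).
#' @param geometry an [AssayGeometry-class] with a control capillary.
#' @param lambdaIn,lambdaOut region extents, micrometres (typically the
#'   fitted decay lengths).
#' @param controlTracks optional track table already expressed in the
#'   control capillary's frame; when NULL the same `tracks` are re-expressed
#'   via [controlGeometry()] (requires pixel-frame information) — for
#'   simulated assays pass the control-side tracks explicitly.
#' @inheritParams chemotacticIndex
#' @return a [ChemotaxisIndex-class].
#' @export
chemotaxisIndices <- function(tracks, geometry, lambdaIn, lambdaOut,
                              controlTracks = NULL, alpha = 0.01,
                              windowS = 120,
                              gateOn = c("corrected", "raw")) {
  gateOn <- match.arg(gateOn)
  if (is.null(controlTracks)) {
    cg <- controlGeometry(geometry)
    px <- fromAssayFrame(cbind(tracks$x_um, tracks$y_um), geometry)
    um <- toAssayFrame(px, cg)
    controlTracks <- tracks
    controlTracks$x_um <- um[, 1L]
    controlTracks$y_um <- um[, 2L]
  }
  fr <- range(c(tracks$frame, controlTracks$frame))
  res <- list()
  for (side in c("inside", "outside")) {
    reg <- if (side == "inside") insideRect(lambdaIn)
           else outsideSemicircle(lambdaOut)
    cue <- countInRegion(tracks, reg, geometry, frameRange = fr)
    ctl <- countInRegion(controlTracks, reg, geometry, frameRange = fr)
    res[[side]] <- chemotacticIndex(cue, ctl, alpha = alpha,
                                    windowS = windowS,
                                    frameRate = geometry@frameRate,
                                    gateOn = gateOn)
  }
  new("ChemotaxisIndex",
      icInside = res$inside$ic, icOutside = res$outside$ic,
      pInside = res$inside$pRaw, pOutside = res$outside$pRaw,
      pInsideCorr = res$inside$pCorr, pOutsideCorr = res$outside$pCorr,
      windowInside = res$inside$window, windowOutside = res$outside$window,
      gatedInside = res$inside$gated, gatedOutside = res$outside$gated,
      alpha = alpha)
}

#' Long-term accumulation rate
#'
#' Ordinary least-squares slope of the per-frame counts against time over
#' the full assay, in cells per second.
#'
#' @param series a [CountSeries-class] with at least 10 frames.
#' @return list with `slope`, `se`, `intercept`.
#' @export
accumulationRate <- function(series) {
  if (length(series@counts) < 10L) stop("need at least 10 frames")
  if (diff(range(series@times)) == 0) stop("degenerate time axis")
  fit <- lm(series@counts ~ series@times)
  cf <- summary(fit)$coefficients
  list(slope = unname(cf[2L, 1L]), se = unname(cf[2L, 2L]),
       intercept = unname(cf[1L, 1L]))
}
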