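#' Time-averaged cell density map
#'
#' Bins every track point on a square grid and divides by bin area and the
#' number of frames, giving mean cells per unit area per frame.
#'
#' @param tracks track table in the assay frame (see [track-tables]).
#' @param geometry an [AssayGeometry-class] (currently unused beyond
#'   validation; kept for interface symmetry).
#' @param cellSize grid cell edge, micrometres (default 50).
#' @param nFrames number of frames averaged over; default spans the
#'   observed frame range.
#' @return list with `xEdges`, `yEdges`, `counts` and `density` matrices
#'   (rows = x bins, columns = y bins).
#' @export
densityMap <- function(tracks, geometry, cellSize = 50, nFrames = NULL) {
  if (!nrow(tracks)) stop("empty track table")
  if (is.null(nFrames)) nFrames <- diff(range(tracks$frame)) + 1
  x <- tracks$x_um; y <- tracks$y_um
  xe <- seq(floor(min(x) / cellSize) * cellSize,
            ceiling(max(x) / cellSize) * cellSize + cellSize, by = cellSize)
  ye <- seq(floor(min(y) / cellSize) * cellSize,
            ceiling(max(y) / cellSize) * cellSize + cellSize, by = cellSize)
  xi <- findInterval(x, xe, rightmost.closed = TRUE)
  yi <- findInterval(y, ye, rightmost.closed = TRUE)
  counts <- matrix(0, length(xe) - 1L, length(ye) - 1L)
  tab <- table(factor(xi, levels = seq_len(nrow(counts))),
               factor(yi, levels = seq_len(ncol(counts))))
  counts[] <- as.numeric(tab)
  list(xEdges = xe, yEdges = ye, counts = counts,
       density = counts / (cellSize^2 * nFrames))
}

.profile_frames <- function(tracks, nFrames) {
  if (is.null(nFrames)) diff(range(tracks$frame)) + 1 else nFrames
}

#' Axial concentration profile inside the capillary
#'
#' Density of track points versus axial distance `d` from the entrance,
#' restricted to the capillary interior. Each bin's count is divided by the
#' bin area (`binWidth` times the capillary inner width) and the number of
#' frames.
#'
#' @param tracks assay-frame track table.
#' @param geometry an [AssayGeometry-class].
#' @param binWidth bin width, micrometres (default 20).
#' @param depth profile extent along the axis; defaults to the deepest
#'   observed point (rounded up to a bin).
#' @param nFrames frames averaged over (default: observed frame span).
#' @return a [ConcentrationProfile-class] with `region = "inside"`.
#' @export
axialProfile <- function(tracks, geometry, binWidth = 20, depth = NULL,
                         nFrames = NULL) {
  if (binWidth <= 0) stop("'binWidth' must be > 0")
  nF <- .profile_frames(tracks, nFrames)
  w <- geometry@capillaryWidth
  inside <- tracks$x_um >= 0 & tracks$x_um <= geometry@capillaryLength &
    abs(tracks$y_um) <= w / 2
  d <- tracks$x_um[inside]
  if (is.null(depth))
    depth <- if (length(d)) ceiling(max(d) / binWidth) * binWidth else binWidth
  edges <- seq(0, depth, by = binWidth)
  if (length(edges) < 2L) stop("profile extent shorter than one bin")
  counts <- tabulate(findInterval(d[d >= 0 & d <= depth], edges,
                                  rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  new("ConcentrationProfile", region = "inside", binEdges = edges,
      density = counts / (binWidth * w * nF), counts = as.numeric(counts),
      nFrames = nF)
}

#' Radial concentration profile outside the capillary
#'
#' Density of track points versus radial distance `r` from the entrance in
#' the outside half-plane (`axial < 0`). Bin counts are divided by the
#' semi-annulus area `pi (r2^2 - r1^2) / 2` and the number of frames;
#' set `normalizeArea = FALSE` to get raw counts per frame instead.
#'
#' @inheritParams axialProfile
#' @param binWidth bin width, micrometres (default 10).
#' @param maxRadius profile extent; defaults to the farthest outside point
#'   (rounded up to a bin).
#' @param normalizeArea divide by semi-annulus area (default TRUE).
#' @return a [ConcentrationProfile-class] with `region = "outside"`.
#' @export
radialProfile <- function(tracks, geometry, binWidth = 10, maxRadius = NULL,
                          nFrames = NULL, normalizeArea = TRUE) {
  if (binWidth <= 0) stop("'binWidth' must be > 0")
  nF <- .profile_frames(tracks, nFrames)
  outside <- tracks$x_um < 0
  r <- sqrt(tracks$x_um[outside]^2 + tracks$y_um[outside]^2)
  if (is.null(maxRadius))
    maxRadius <- if (length(r)) ceiling(max(r) / binWidth) * binWidth else
      binWidth
  edges <- seq(0, maxRadius, by = binWidth)
  if (length(edges) < 2L) stop("profile extent shorter than one bin")
  counts <- tabulate(findInterval(r[r <= maxRadius], edges,
                                  rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  area <- if (normalizeArea)
    pi * (tail(edges, -1L)^2 - head(edges, -1L)^2) / 2
  else rep(1, length(counts))
  new("ConcentrationProfile", region = "outside", binEdges = edges,
      density = counts / (area * nF), counts = as.numeric(counts),
      nFrames = nF)
}

.fit_starts <- function(x, y) {
  extent <- diff(range(x))
  ntail <- max(2L, ceiling(length(y) * 0.2))
  b0 <- max(mean(tail(y, ntail)), 0)
  a0 <- max(mean(head(y, ntail)) - b0, max(y) - b0, .Machine$double.eps)
  lams <- extent * c(0.25, 0.5, 1)
  lapply(lams, function(l0) list(a = a0, b = b0, lam = l0))
}

.is_degenerate <- function(y) {
  s <- diff(range(y))
  s <= 0 || s < 1e-10 * max(abs(y), 1e-300)
}

#' Fit a decaying exponential to a concentration profile
#'
#' Unweighted least-squares fit of `C(x) = a * exp(-x / lambda) + b` to the
#' binned density, with multi-start initialisation (`lambda0` at 1/4, 1/2
#' and 1 times the profile extent; baseline from the tail mean) to avoid the
#' local minima typical of exponential regression. Lambda is constrained to
#' at most 10 times the profile extent; a fit pinned at that bound is
#' flagged non-decaying. A near-constant profile returns a degenerate fit
#' with no lambda.
#'
#' @param profile a [ConcentrationProfile-class] (or list with `x`, `y`).
#' @param weights optional per-bin weights for weighted least squares
#'   (e.g. Poisson `1/max(count,1)` variances); default unweighted.
#' @return an [ExpFit-class].
#' @examples
#' x <- seq(10, 390, by = 20)
#' y <- 100 * exp(-x / 150) + 5
#' f <- fitExponential(list(x = x, y = y))
#' decayLength(f)  # 150
#' @export
fitExponential <- function(profile, weights = NULL) {
  xy <- .profile_xy(profile)
  x <- xy$x; y <- xy$y
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 finite profile bins")
  if (.is_degenerate(y))
    return(new("ExpFit", a = 0, b = mean(y), lam = NA_real_, rss = 0,
               degenerate = TRUE))
  extent <- diff(range(x))
  lamMax <- 10 * extent
  w <- if (is.null(weights)) rep(1, length(y)) else weights[ok]
  best <- NULL
  for (st in .fit_starts(x, y)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-x / lam) + b,
        start = st, weights = w,
        lower = c(a = 0, b = 0, lam = extent * 1e-4),
        upper = c(a = Inf, b = Inf, lam = lamMax),
        control = minpack.lm::nls.lm.control(
          maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("exponential fit failed to converge from any start")
  cf <- coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients["lam", "Std. Error"],
                 error = function(e) NA_real_)
  new("ExpFit", a = unname(cf["a"]), b = unname(cf["b"]),
      lam = unname(cf["lam"]), rss = best$rss, seLam = se,
      nonDecaying = unname(cf["lam"]) >= lamMax * (1 - 1e-6))
}

.profile_xy <- function(profile) {
  if (is(profile, "ConcentrationProfile"))
    list(x = binCenters(profile), y = profile@density)
  else if (is.list(profile) && all(c("x", "y") %in% names(profile)))
    list(x = as.numeric(profile$x), y = as.numeric(profile$y))
  else stop("'profile' must be a ConcentrationProfile or list(x, y)")
}

.pw_model <- function(x, a, b, lam, L0) {
  ifelse(x <= L0, a + b, a * exp(-(x - L0) / lam) + b)
}

.pw_fit_given_L0 <- function(x, y, w, L0, st, lamMax) {
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ ifelse(x <= L0, a + b, a * exp(-(x - L0) / lam) + b),
      start = st, weights = w,
      lower = c(a = 0, b = 0, lam = diff(range(x)) * 1e-4),
      upper = c(a = Inf, b = Inf, lam = lamMax),
      control = minpack.lm::nls.lm.control(
        maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(coef = coef(fit), rss = sum(w * residuals(fit)^2), fit = fit)
}

#' Fit a plateau-exponential (piecewise) profile
#'
#' Models a constant plateau `a + b` up to breakpoint `L0` followed by an
#' exponential decay `a * exp(-(x - L0)/lambda) + b`, continuous at `L0`.
#' The breakpoint is profiled over the bin edges (exhaustively) and, when
#' `refine = TRUE`, polished by a one-dimensional continuous search within
#' the bracketing bins.
#'
#' @inheritParams fitExponential
#' @param refine continuously refine `L0` between bin edges (default TRUE).
#' @return a [PiecewiseFit-class].
#' @export
fitPlateauExponential <- function(profile, weights = NULL, refine = TRUE) {
  xy <- .profile_xy(profile)
  x <- xy$x; y <- xy$y
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 6L) stop("need at least 6 finite profile bins")
  if (.is_degenerate(y))
    return(new("PiecewiseFit", a = 0, b = mean(y), lam = NA_real_, rss = 0,
               degenerate = TRUE, plateauLen = NA_real_))
  extent <- diff(range(x))
  lamMax <- 10 * extent
  w <- if (is.null(weights)) rep(1, length(y)) else weights[ok]
  edges <- if (is(profile, "ConcentrationProfile"))
    profile@binEdges else c(0, x + diff(c(0, x))[1] / 2)
  # candidate breakpoints: bin edges leaving >= 4 bins of decay
  cands <- unique(c(0, edges[edges <= sort(x, decreasing = TRUE)[4L]]))
  starts <- .fit_starts(x, y)
  best <- NULL
  for (L0 in cands) {
    for (st in starts) {
      r <- .pw_fit_given_L0(x, y, w, L0, st, lamMax)
      if (!is.null(r) && (is.null(best) || r$rss < best$rss)) {
        best <- r; best$L0 <- L0
      }
    }
  }
  if (is.null(best)) stop("piecewise fit failed to converge from any start")
  if (refine) {
    span <- max(diff(sort(cands)))
    lo <- max(min(cands), best$L0 - span)
    hi <- min(max(cands), best$L0 + span)
    if (hi > lo) {
      st <- as.list(best$coef)
      obj <- function(L0) {
        r <- .pw_fit_given_L0(x, y, w, L0, st, lamMax)
        if (is.null(r)) Inf else r$rss
      }
      op <- optimize(obj, c(lo, hi), tol = 1e-8 * max(extent, 1))
      if (op$objective < best$rss) {
        r <- .pw_fit_given_L0(x, y, w, op$minimum, st, lamMax)
        if (!is.null(r)) { best <- r; best$L0 <- op$minimum }
      }
    }
  }
  cf <- best$coef
  se <- tryCatch(summary(best$fit)$coefficients["lam", "Std. Error"],
                 error = function(e) NA_real_)
  new("PiecewiseFit", a = unname(cf["a"]), b = unname(cf["b"]),
      lam = unname(cf["lam"]), rss = best$rss, seLam = se,
      plateauLen = best$L0,
      nonDecaying = unname(cf["lam"]) >= lamMax * (1 - 1e-6))
}

#' Choose between exponential and plateau-exponential profile models
#'
#' Compares the two fits by small-sample corrected AIC; the piecewise model
#' (one extra parameter) is selected only when it improves AICc by more
#' than 2.
#'
#' @inheritParams fitExponential
#' @return list with `model` (`"exponential"` or `"piecewise"`), `fit`
#'   (the chosen fit object), `deltaAIC` (AICc exponential minus AICc
#'   piecewise) and both candidate fits.
#' @export
selectProfileModel <- function(profile, weights = NULL) {
  fe <- fitExponential(profile, weights)
  fp <- fitPlateauExponential(profile, weights)
  n <- length(.profile_xy(profile)$x)
  aicc <- function(rss, k) {
    k <- k + 1  # + residual variance
    n * log(max(rss, 1e-300) / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
  }
  dA <- aicc(fe@rss, 3) - aicc(fp@rss, 4)
  pick <- !fe@degenerate && !fp@degenerate && dA > 2
  list(model = if (pick) "piecewise" else "exponential",
       fit = if (pick) fp else fe, deltaAIC = dA,
       exponential = fe, piecewise = fp)
}

#' Average decay lengths across replicate fits
#'
#' Replicate assays are summarised by the arithmetic mean of their fitted
#' lambdas (degenerate/non-decaying fits excluded with a warning).
#'
#' @param fits list of [ExpFit-class] objects.
#' @return list with `mean`, `sd`, `n`.
#' @export
averageDecayLength <- function(fits) {
  lam <- vapply(fits, decayLength, numeric(1L))
  bad <- !is.finite(lam)
  if (any(bad)) {
    warning(sum(bad), " degenerate/non-finite fit(s) excluded from average")
    lam <- lam[!bad]
  }
  list(mean = mean(lam), sd = sd(lam), n = length(lam))
}

#' Export a profile and its fit
#'
#' Writes the binned profile as CSV (`bin_center,density,count`) and the fit
#' parameters as JSON.
#'
#' @param profile a [ConcentrationProfile-class].
#' @param fit an [ExpFit-class] or [PiecewiseFit-class].
#' @param csvPath,jsonPath output paths (either may be NULL to skip).
#' @return invisibly, the JSON-able fit summary list.
#' @export
exportProfileFit <- function(profile, fit, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    write.csv(data.frame(bin_center = binCenters(profile),
                         density = profile@density,
                         count = profile@counts),
              csvPath, row.names = FALSE, quote = FALSE)
  out <- list(a = fit@a, b = fit@b, lam = fit@lam, rss = fit@rss,
              se_lam = fit@seLam, degenerate = fit@degenerate,
              non_decaying = fit@nonDecaying)
  if (is(fit, "PiecewiseFit")) out$plateau_len <- fit@plateauLen
  if (!is.null(jsonPath))
    jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = NA,
                         na = "null")
  invisible(out)
}
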