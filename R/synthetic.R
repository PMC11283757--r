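#' Build a point-source gradient model
#'
#' By default the source strength `Q` is chosen so that the steady-state
#' concentration at the mouth radius equals the reservoir concentration of
#' the cue solution filling the capillary, tying the outside field to the
#' capillary contents.
#'
#' @param reservoirConc cue concentration in the capillary, uM (default 20).
#' @param D diffusivity, um^2 s^-1 (default 1000, a small organic solute in
#'   water).
#' @param C0 background concentration, uM (default 0).
#' @param mouthRadius effective source radius, micrometres (default 100,
#'   half the capillary width).
#' @param Q source strength, fmol s^-1; derived from `reservoirConc` when
#'   NULL.
#' @param source assay-frame source position (default the entrance centre).
#' @param decayingSource deplete the reservoir exponentially (default
#'   FALSE, frozen source).
#' @param sourceTau depletion time scale, seconds (default 600).
#' @return a [GradientModel-class].
#' @export
gradientModel <- function(reservoirConc = 20, D = 1000, C0 = 0,
                          mouthRadius = 100, Q = NULL, source = c(0, 0),
                          decayingSource = FALSE, sourceTau = 600) {
  if (is.null(Q))
    Q <- reservoirConc * 1e-6 * 2 * pi * D * mouthRadius
  new("GradientModel", Q = Q, D = D, C0 = C0, source = as.numeric(source),
      reservoirConc = reservoirConc, mouthRadius = mouthRadius,
      decayingSource = decayingSource, sourceTau = sourceTau)
}

.model_as_list <- function(model) {
  list(Q = model@Q, D = model@D, C0 = model@C0, source = model@source,
       reservoirConc = model@reservoirConc, mouthRadius = model@mouthRadius,
       decayingSource = model@decayingSource, sourceTau = model@sourceTau)
}

#' Evaluate the cue concentration field
#'
#' Outside the capillary, the half-space continuous point-source solution
#' `C(r, t) = C0 + Q / (2 pi D r) * erfc(r / sqrt(4 D t))` (capped at the
#' mouth concentration below the mouth radius); inside, a one-dimensional
#' erf profile from the mouth concentration to the reservoir concentration,
#' continuous at the entrance.
#'
#' @param points n x 2 assay-frame points, micrometres.
#' @param t time since capillary immersion, seconds (>= 0).
#' @param model a [GradientModel-class].
#' @param geometry an [AssayGeometry-class] (for the capillary interior
#'   extent); a default 200 um x 50 mm capillary is assumed when NULL.
#' @return concentrations, uM.
#' @examples
#' m <- gradientModel(reservoirConc = 20)
#' concentrationAt(cbind(-100, 0), t = 60, m)
#' @export
concentrationAt <- function(points, t, model, geometry = NULL) {
  if (t < 0) stop("'t' must be >= 0")
  p <- .as_points(points)
  capW <- if (is.null(geometry)) 200 else geometry@capillaryWidth
  capL <- if (is.null(geometry)) 50000 else geometry@capillaryLength
  .concField(p[, 1L], p[, 2L], t, .model_as_list(model), capW, capL)
}

#' Configure the swimmer simulation
#'
#' Defaults emulate the assay conditions: 10-minute recordings of cells
#' swimming at around 150 um s^-1 (typical observed speeds are below
#' 200 um s^-1, rising to 300 um s^-1 under chemokinesis near the source),
#' 20 um body length, and of order a hundred cells in the recorded region.
#'
#' @param nCells number of swimmers (default 100).
#' @param v0 base speed, um s^-1 (default 150).
#' @param rotDiffusion rotational diffusivity, rad^2 s^-1 (default 0.5).
#' @param chi klinotaxis gain, dimensionless (default 1; 0 disables
#'   gradient steering).
#' @param kappa chemokinesis gain (default 0.5: speed rises 50% at
#'   saturating concentration; 0 disables).
#' @param turnGain searching-regime gain: relative increase of the
#'   rotational diffusivity at saturating concentration (default 10;
#'   0 disables), emulating area-restricted search inside the patch.
#' @param giveUpTime mean patch residence before a searcher switches to a
#'   ballistic leaving state, seconds (default 15; 0 disables), emulating
#'   the reversion to straight swimming when abandoning the patch.
#' @param kHalf half-saturation concentration, uM (default 1).
#' @param bodyLength micrometres (default 20).
#' @param dt integration step, seconds (default 1/300; output is decimated
#'   to the geometry frame rate).
#' @param duration assay duration, seconds (default 600).
#' @param seed RNG seed (default 1).
#' @param arenaRadius radius of the simulated recorded region, micrometres
#'   (default 1500).
#' @return a [SwimmerConfig-class].
#' @export
swimmerConfig <- function(nCells = 100, v0 = 150, rotDiffusion = 0.5,
                          chi = 1, kappa = 0.5, turnGain = 10,
                          giveUpTime = 15, kHalf = 1,
                          bodyLength = 20, dt = 1 / 300, duration = 600,
                          seed = 1, arenaRadius = 1500) {
  new("SwimmerConfig", nCells = nCells, v0 = v0,
      rotDiffusion = rotDiffusion, chi = chi, kappa = kappa,
      turnGain = turnGain, giveUpTime = giveUpTime, kHalf = kHalf,
      bodyLength = bodyLength, dt = dt, duration = duration, seed = seed,
      arenaRadius = arenaRadius)
}

#' Simulate a microcapillary assay
#'
#' Agent-based swimmers in the diffusing point-source field: headings
#' evolve by rotational diffusion plus a deterministic klinotactic turn
#' toward the local gradient at angular rate
#' `chi * v * |grad C| / (C + eps) * sin(phi_grad - heading)`
#' (logarithmic sensing), speed is modulated as
#' `v = v0 * (1 + kappa * C / (C + kHalf))`, and moves into the capillary
#' glass, past the closed capillary end, or beyond the arena reflect the
#' heading. Cells may enter the capillary through the open mouth. Positions
#' are recorded at the geometry frame rate.
#'
#' @param swim a [SwimmerConfig-class].
#' @param grad a [GradientModel-class].
#' @param geometry an [AssayGeometry-class]; defaults to a unit-scale
#'   geometry at 30 fps.
#' @return assay-frame track table (see [track-tables]) with one track per
#'   cell spanning the full recording.
#' @export
simulateAssay <- function(swim, grad, geometry = assayGeometry(c(0, 0))) {
  validObject(swim); validObject(grad)
  outEvery <- max(1L, as.integer(round(1 / (geometry@frameRate * swim@dt))))
  set.seed(as.integer(swim@seed))
  res <- .simulateSwimmers(
    as.integer(swim@nCells), swim@v0, swim@rotDiffusion, swim@chi,
    swim@kappa, swim@turnGain, swim@giveUpTime, swim@kHalf, swim@dt,
    swim@duration, swim@arenaRadius,
    .model_as_list(grad), geometry@capillaryWidth, geometry@capillaryLength,
    geometry@wallThickness, outEvery)
  nout <- ncol(res$x)
  n <- nrow(res$x)
  frames <- rep(seq_len(nout) - 1L, each = n)
  data.frame(track_id = rep(seq_len(n), nout),
             frame = frames,
             x_um = as.numeric(res$x),
             y_um = as.numeric(res$y),
             t_s = frames * outEvery * swim@dt)
}

#' Sample positions from an exponential accumulation density
#'
#' Direct sampler for profile-fit tests: draws points whose areal density
#' follows `a * exp(-x / lam) + b` restricted to a region. Inside the
#' capillary, `x` is the axial distance (transverse position uniform across
#' the width); outside, `x` is the radial distance within the front
#' semicircle (rejection sampling against the annulus-weighted density).
#'
#' @param lam decay length, micrometres (> 0).
#' @param a,b amplitude and baseline (arbitrary density units, >= 0).
#' @param n number of points (> 0).
#' @param region an `inside_rect` or `outside_semicircle`
#'   [RegionSpec-class].
#' @param geometry an [AssayGeometry-class].
#' @param seed optional RNG seed.
#' @return n x 2 matrix of assay-frame positions.
#' @export
sampleExponentialPositions <- function(lam, a, b, n, region,
                                       geometry = assayGeometry(c(0, 0)),
                                       seed = NULL) {
  if (lam <= 0) stop("'lam' must be > 0")
  if (n <= 0) stop("'n' must be > 0")
  if (a < 0 || b < 0) stop("'a' and 'b' must be >= 0")
  if (a == 0 && b == 0) stop("'a' and 'b' cannot both be 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  f <- function(x) a * exp(-x / lam) + b
  if (region@kind == "inside_rect") {
    depth <- region@depthOrRadius
    M <- f(0)
    xs <- numeric(0)
    while (length(xs) < n) {
      m <- max(2L * (n - length(xs)), 100L)
      prop <- runif(m, 0, depth)
      keep <- runif(m) < f(prop) / M
      xs <- c(xs, prop[keep])
    }
    xs <- xs[seq_len(n)]
    ys <- runif(n, -geometry@capillaryWidth / 2, geometry@capillaryWidth / 2)
    cbind(xs, ys)
  } else if (region@kind == "outside_semicircle") {
    R <- region@depthOrRadius
    M <- f(0)                       # bound for areal density
    rs <- numeric(0)
    while (length(rs) < n) {
      m <- max(2L * (n - length(rs)), 100L)
      prop <- R * sqrt(runif(m))    # uniform over the disc area
      keep <- runif(m) < f(prop) / M
      rs <- c(rs, prop[keep])
    }
    rs <- rs[seq_len(n)]
    th <- runif(n, pi / 2, 3 * pi / 2)  # front half-plane (axial < 0)
    cbind(rs * cos(th), rs * sin(th))
  } else {
    stop("sampling supports inside_rect and outside_semicircle regions")
  }
}

#' Render synthetic video frames from tracks
#'
#' Draws each cell as a Gaussian intensity spot on a constant background
#' with additive Gaussian pixel noise; deterministic for a given seed.
#' Intended as ground-truth input for end-to-end tracking tests.
#'
#' @param tracks assay-frame track table.
#' @param geometry an [AssayGeometry-class] mapping micrometres to pixels.
#' @param dims `c(ny, nx)` frame dimensions in pixels.
#' @param cellSigmaPx Gaussian spot sigma, pixels (default 1.5).
#' @param amplitude spot peak intensity (default 1).
#' @param backgroundLevel constant background intensity (default 0.1).
#' @param noiseSd additive noise sd (default 0.01).
#' @param seed RNG seed (default 1).
#' @return 3D array `[ny, nx, nframes]`.
#' @export
renderFrames <- function(tracks, geometry, dims = c(200, 200),
                         cellSigmaPx = 1.5, amplitude = 1,
                         backgroundLevel = 0.1, noiseSd = 0.01, seed = 1) {
  set.seed(as.integer(seed))
  frames <- sort(unique(tracks$frame))
  px <- fromAssayFrame(cbind(tracks$x_um, tracks$y_um), geometry)
  ny <- dims[1L]; nx <- dims[2L]
  out <- array(0, dim = c(ny, nx, length(frames)))
  half <- ceiling(4 * cellSigmaPx)
  off <- seq(-half, half)
  clipped <- 0L
  for (k in seq_along(frames)) {
    img <- matrix(backgroundLevel, ny, nx)
    sel <- which(tracks$frame == frames[k])
    for (i in sel) {
      cx <- px[i, 1L]; cy <- px[i, 2L]
      if (cx < 0 || cx > nx - 1 || cy < 0 || cy > ny - 1) {
        clipped <- clipped + 1L
        next
      }
      xi <- round(cx) + off; yi <- round(cy) + off
      okx <- xi >= 0 & xi <= nx - 1
      oky <- yi >= 0 & yi <= ny - 1
      gx <- exp(-(xi[okx] - cx)^2 / (2 * cellSigmaPx^2))
      gy <- exp(-(yi[oky] - cy)^2 / (2 * cellSigmaPx^2))
      img[yi[oky] + 1L, xi[okx] + 1L] <-
        img[yi[oky] + 1L, xi[okx] + 1L] + amplitude * outer(gy, gx)
    }
    img <- img + matrix(rnorm(ny * nx, 0, noiseSd), ny, nx)
    out[, , k] <- img
  }
  if (clipped > 0L)
    warning(clipped, " track point(s) outside the canvas were clipped")
  out
}
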