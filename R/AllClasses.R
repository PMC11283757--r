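#' @import methods
#' @importFrom stats median coef lm optimize p.adjust rnorm runif sd
#'   wilcox.test kruskal.test cor residuals t.test
#' @importFrom utils head read.csv tail write.csv combn
#' @useDynLib capitax, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Assay-frame geometry of a two-capillary chemotaxis assay
#'
#' An `AssayGeometry` fixes the coordinate system used by every spatial
#' statistic in the package. The origin sits at the centre of the cue
#' capillary entrance; the axis unit vector points from the entrance into
#' the capillary, so the first (axial) assay-frame coordinate is positive
#' inside the capillary and negative in the open dish in front of it.
#'
#' @slot origin numeric(2), pixel coordinates of the cue-capillary entrance
#'   centre (image convention: x right, y down, origin top-left).
#' @slot axis numeric(2), unit vector of the capillary axis in the assay
#'   frame (after the image y-flip), pointing into the capillary.
#' @slot pixelScale micrometres per pixel, > 0.
#' @slot frameRate frames per second, > 0.
#' @slot capillaryWidth inner width of the square capillary, micrometres.
#' @slot capillaryLength length of the capillary, micrometres.
#' @slot wallThickness glass wall thickness, micrometres; points inside the
#'   glass belong to no region.
#' @slot controlOrigin,controlAxis same as `origin`/`axis` for the control
#'   capillary.
#'
#' @seealso [assayGeometry()], [toAssayFrame()], [regionMembership()]
#' @export
setClass("AssayGeometry",
  representation(
    origin = "numeric",
    axis = "numeric",
    pixelScale = "numeric",
    frameRate = "numeric",
    capillaryWidth = "numeric",
    capillaryLength = "numeric",
    wallThickness = "numeric",
    controlOrigin = "numeric",
    controlAxis = "numeric"
  )
)

setValidity("AssayGeometry", function(object) {
  msg <- character()
  if (length(object@origin) != 2L || !all(is.finite(object@origin)))
    msg <- c(msg, "'origin' must be a finite length-2 numeric")
  if (length(object@axis) != 2L ||
      abs(sqrt(sum(object@axis^2)) - 1) > 1e-8)
    msg <- c(msg, "'axis' must be a unit-norm length-2 vector")
  if (length(object@controlAxis) == 2L && all(is.finite(object@controlAxis)) &&
      abs(sqrt(sum(object@controlAxis^2)) - 1) > 1e-8)
    msg <- c(msg, "'controlAxis' must be a unit-norm length-2 vector")
  if (object@pixelScale <= 0) msg <- c(msg, "'pixelScale' must be > 0")
  if (object@frameRate <= 0) msg <- c(msg, "'frameRate' must be > 0")
  if (object@capillaryWidth <= 0)
    msg <- c(msg, "'capillaryWidth' must be > 0")
  if (object@capillaryLength <= 0)
    msg <- c(msg, "'capillaryLength' must be > 0")
  if (object@wallThickness < 0)
    msg <- c(msg, "'wallThickness' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Spatial region of interest in the assay frame
#'
#' Regions are defined relative to the capillary entrance (the assay-frame
#' origin): `inside_rect` is the rectangular strip reaching `depth` into the
#' capillary; `outside_semicircle` is the half-disc of given radius in front
#' of the entrance; `corona` is the annulus between two radii; `neutral` is
#' everything farther than `depth_or_radius` from the origin.
#'
#' @slot kind one of `"inside_rect"`, `"outside_semicircle"`, `"corona"`,
#'   `"neutral"`.
#' @slot depthOrRadius depth (inside) or radius (outside/neutral), micrometres.
#' @slot coronaInner,coronaOuter corona radii, micrometres (corona only).
#'
#' @seealso [insideRect()], [outsideSemicircle()], [coronaRegion()],
#'   [neutralZone()], [makeCorona()]
#' @export
setClass("RegionSpec",
  representation(
    kind = "character",
    depthOrRadius = "numeric",
    coronaInner = "numeric",
    coronaOuter = "numeric"
  ),
  prototype(depthOrRadius = NA_real_, coronaInner = NA_real_,
            coronaOuter = NA_real_)
)

setValidity("RegionSpec", function(object) {
  kinds <- c("inside_rect", "outside_semicircle", "corona", "neutral")
  msg <- character()
  if (!object@kind %in% kinds)
    msg <- c(msg, paste0("unknown region kind '", object@kind, "'"))
  if (object@kind == "corona") {
    if (!is.finite(object@coronaInner) || !is.finite(object@coronaOuter) ||
        object@coronaInner < 0 || object@coronaOuter <= object@coronaInner)
      msg <- c(msg, "corona requires 0 <= coronaInner < coronaOuter")
  } else {
    if (!is.finite(object@depthOrRadius) || object@depthOrRadius <= 0)
      msg <- c(msg, "'depthOrRadius' must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Binned cell-concentration profile
#'
#' Time-averaged cell density versus distance from the capillary entrance:
#' axial distance `d` inside the capillary, radial distance `r` outside.
#' Densities are cells per square micrometre per frame; dividing raw bin
#' counts by bin area and number of frames makes profiles comparable across
#' assays of different durations.
#'
#' @slot region `"inside"` or `"outside"`.
#' @slot binEdges strictly increasing bin edges, micrometres.
#' @slot density cells um^-2 frame^-1 per bin.
#' @slot counts raw number of track points per bin.
#' @slot nFrames number of frames averaged over.
#'
#' @seealso [axialProfile()], [radialProfile()], [fitExponential()]
#' @export
setClass("ConcentrationProfile",
  representation(
    region = "character",
    binEdges = "numeric",
    density = "numeric",
    counts = "numeric",
    nFrames = "numeric"
  )
)

setValidity("ConcentrationProfile", function(object) {
  msg <- character()
  if (!object@region %in% c("inside", "outside"))
    msg <- c(msg, "'region' must be 'inside' or 'outside'")
  if (any(diff(object@binEdges) <= 0))
    msg <- c(msg, "'binEdges' must be strictly increasing")
  if (length(object@density) != length(object@binEdges) - 1L)
    msg <- c(msg, "'density' must have one value per bin")
  if (any(object@density < 0, na.rm = TRUE))
    msg <- c(msg, "'density' must be non-negative")
  if (object@nFrames <= 0) msg <- c(msg, "'nFrames' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Exponential fit of an accumulation profile
#'
#' Least-squares fit of `C(x) = a * exp(-x / lambda) + b` to a binned
#' concentration profile. `lambda` is the accumulation length scale: the
#' depth of exploration inside the capillary or the size of the cell patch
#' outside of it.
#'
#' @slot a density amplitude (same units as the profile density).
#' @slot b density baseline.
#' @slot lam decay length lambda, micrometres.
#' @slot rss residual sum of squares.
#' @slot seLam standard error of lambda, micrometres (NA if unavailable).
#' @slot degenerate TRUE when the profile carries no decay signal
#'   (near-constant); `lam` is NA then.
#' @slot nonDecaying TRUE when the fitted lambda exceeds 10x the profile
#'   extent, i.e. the profile is effectively flat on the observed range.
#'
#' @seealso [fitExponential()], [decayLength()]
#' @export
setClass("ExpFit",
  representation(
    a = "numeric",
    b = "numeric",
    lam = "numeric",
    rss = "numeric",
    seLam = "numeric",
    degenerate = "logical",
    nonDecaying = "logical"
  ),
  prototype(seLam = NA_real_, degenerate = FALSE, nonDecaying = FALSE)
)

setValidity("ExpFit", function(object) {
  msg <- character()
  if (!object@degenerate && !is.na(object@lam) && object@lam <= 0)
    msg <- c(msg, "'lam' must be > 0")
  if (!is.na(object@a) && object@a < -sqrt(.Machine$double.eps))
    msg <- c(msg, "'a' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Plateau-exponential (piecewise) fit of an accumulation profile
#'
#' Models a constant plateau of length `plateauLen` preceding the
#' exponential decay: `C(x) = a + b` for `x <= L0` and
#' `a * exp(-(x - L0)/lambda) + b` beyond, continuous at the breakpoint.
#' Used where cells fill the first stretch of the capillary uniformly
#' before the accumulation decays.
#'
#' @slot plateauLen plateau length L0, micrometres (>= 0).
#'
#' @seealso [fitPlateauExponential()], [selectProfileModel()]
#' @export
setClass("PiecewiseFit",
  contains = "ExpFit",
  representation(plateauLen = "numeric"),
  prototype(plateauLen = 0)
)

setValidity("PiecewiseFit", function(object) {
  if (!is.na(object@plateauLen) && object@plateauLen < 0)
    "'plateauLen' must be >= 0" else TRUE
})

#' Per-frame cell counts in a region
#'
#' @slot times seconds, strictly increasing.
#' @slot counts non-negative integer counts per frame.
#' @slot region the [RegionSpec-class] counted over.
#'
#' @seealso [countInRegion()], [maxMeanWindow()], [chemotacticIndex()]
#' @export
setClass("CountSeries",
  representation(
    times = "numeric",
    counts = "numeric",
    region = "RegionSpec"
  )
)

setValidity("CountSeries", function(object) {
  msg <- character()
  if (length(object@times) != length(object@counts))
    msg <- c(msg, "'times' and 'counts' must have equal length")
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "'times' must be strictly increasing")
  if (any(object@counts < 0) ||
      any(abs(object@counts - round(object@counts)) > 1e-9))
    msg <- c(msg, "'counts' must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' Gated maximum chemotactic index
#'
#' The maximum chemotactic index is the mean cell count near the cue over
#' the best 2-minute window divided by the mean control count over the whole
#' assay, computed separately inside the capillary and in the outside patch.
#' Indices whose cue/control count difference is not significant at `alpha`
#' are gated to 1 (neutral).
#'
#' @slot icInside,icOutside dimensionless index values (gated indices are 1).
#' @slot pInside,pOutside Kruskal-Wallis p-values on per-frame counts.
#' @slot pInsideCorr,pOutsideCorr autocorrelation-corrected p-values
#'   (1 Hz subsampling plus thinning by the estimated correlation time);
#'   these drive the gate.
#' @slot windowInside,windowOutside numeric(2), the maximising window in
#'   seconds.
#' @slot gatedInside,gatedOutside TRUE when the index was set to 1.
#' @slot alpha gate significance level.
#'
#' @seealso [chemotaxisIndices()], [chemotacticIndex()]
#' @export
setClass("ChemotaxisIndex",
  representation(
    icInside = "numeric",
    icOutside = "numeric",
    pInside = "numeric",
    pOutside = "numeric",
    pInsideCorr = "numeric",
    pOutsideCorr = "numeric",
    windowInside = "numeric",
    windowOutside = "numeric",
    gatedInside = "logical",
    gatedOutside = "logical",
    alpha = "numeric"
  )
)

setValidity("ChemotaxisIndex", function(object) {
  msg <- character()
  for (s in c("icInside", "icOutside")) {
    v <- slot(object, s)
    if (is.finite(v) && v < 0) msg <- c(msg, paste0("'", s, "' must be >= 0"))
  }
  if (isTRUE(object@gatedInside) && is.finite(object@icInside) &&
      object@icInside != 1)
    msg <- c(msg, "gated inside index must equal 1")
  if (isTRUE(object@gatedOutside) && is.finite(object@icOutside) &&
      object@icOutside != 1)
    msg <- c(msg, "gated outside index must equal 1")
  if (length(msg)) msg else TRUE
})

#' Diffusing point-source concentration field
#'
#' Continuous release of a cue at the capillary mouth into the half-space in
#' front of the entrance: `C(r, t) = C0 + Q/(2 pi D r) * erfc(r / sqrt(4 D t))`
#' for radii beyond the mouth radius, capped at the mouth concentration
#' closer in. Inside the capillary a one-dimensional erf profile
#' interpolates between the mouth concentration and the reservoir
#' concentration deep inside, continuous at the entrance.
#'
#' @slot Q source strength, fmol s^-1.
#' @slot D diffusivity, um^2 s^-1.
#' @slot C0 background concentration, uM.
#' @slot source assay-frame position of the source (the entrance centre).
#' @slot reservoirConc concentration of the cue solution filling the
#'   capillary, uM.
#' @slot mouthRadius effective source radius, micrometres.
#' @slot decayingSource TRUE to let the reservoir deplete exponentially
#'   (time scale `sourceTau`); FALSE freezes the source strength.
#' @slot sourceTau reservoir depletion time scale, seconds.
#'
#' @seealso [gradientModel()], [concentrationAt()]
#' @export
setClass("GradientModel",
  representation(
    Q = "numeric",
    D = "numeric",
    C0 = "numeric",
    source = "numeric",
    reservoirConc = "numeric",
    mouthRadius = "numeric",
    decayingSource = "logical",
    sourceTau = "numeric"
  ),
  prototype(decayingSource = FALSE, sourceTau = 600)
)

setValidity("GradientModel", function(object) {
  msg <- character()
  if (object@Q < 0) msg <- c(msg, "'Q' must be >= 0")
  if (object@D <= 0) msg <- c(msg, "'D' must be > 0")
  if (object@C0 < 0) msg <- c(msg, "'C0' must be >= 0")
  if (object@mouthRadius <= 0) msg <- c(msg, "'mouthRadius' must be > 0")
  if (length(object@source) != 2L) msg <- c(msg, "'source' must be length 2")
  if (length(msg)) msg else TRUE
})

#' Configuration of the agent-based swimmer simulation
#'
#' Swimmers move at speed `v0` modulated by chemokinesis gain `kappa`
#' (relative speed increase at saturating concentration), with headings
#' subject to rotational diffusion and a deterministic klinotactic turn
#' toward the local concentration gradient with gain `chi` (logarithmic
#' sensing).
#'
#' @slot nCells number of swimmers.
#' @slot v0 base swimming speed, um s^-1.
#' @slot rotDiffusion rotational diffusivity, rad^2 s^-1.
#' @slot chi klinotaxis gain (dimensionless turn-bias gain).
#' @slot kappa chemokinesis gain (relative speed increase at saturating
#'   concentration).
#' @slot turnGain searching-regime gain: relative increase of the
#'   rotational diffusivity at saturating concentration (area-restricted
#'   search inside the patch).
#' @slot giveUpTime mean time, seconds, a searching cell spends inside the
#'   cue patch before giving up and leaving ballistically (no steering,
#'   baseline turning) until the concentration falls back toward
#'   background; 0 disables the give-up switch.
#' @slot kHalf half-saturation concentration of the kinesis/sensing
#'   response, uM.
#' @slot bodyLength cell body length, micrometres.
#' @slot dt integration time step, seconds.
#' @slot duration simulated assay duration, seconds.
#' @slot seed RNG seed.
#' @slot arenaRadius radius of the simulated (recorded) dish region,
#'   micrometres, centred on the capillary entrance.
#'
#' @seealso [swimmerConfig()], [simulateAssay()]
#' @export
setClass("SwimmerConfig",
  representation(
    nCells = "numeric",
    v0 = "numeric",
    rotDiffusion = "numeric",
    chi = "numeric",
    kappa = "numeric",
    turnGain = "numeric",
    giveUpTime = "numeric",
    kHalf = "numeric",
    bodyLength = "numeric",
    dt = "numeric",
    duration = "numeric",
    seed = "numeric",
    arenaRadius = "numeric"
  )
)

setValidity("SwimmerConfig", function(object) {
  msg <- character()
  if (object@nCells < 1) msg <- c(msg, "'nCells' must be >= 1")
  if (object@v0 <= 0) msg <- c(msg, "'v0' must be > 0")
  if (object@rotDiffusion < 0) msg <- c(msg, "'rotDiffusion' must be >= 0")
  if (object@chi < 0 || object@kappa < 0 || object@turnGain < 0 ||
      object@giveUpTime < 0)
    msg <- c(msg, "gains 'chi', 'kappa', 'turnGain' and 'giveUpTime' must be >= 0")
  if (object@dt <= 0) msg <- c(msg, "'dt' must be > 0")
  if (object@duration <= 0) msg <- c(msg, "'duration' must be > 0")
  if (object@bodyLength <= 0) msg <- c(msg, "'bodyLength' must be > 0")
  if (object@v0 * object@dt > object@bodyLength)
    msg <- c(msg, "'dt' too large: one step exceeds a body length")
  if (object@arenaRadius <= 0) msg <- c(msg, "'arenaRadius' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Radiotracer uptake time series
#'
#' @slot times incubation times, hours, non-negative increasing.
#' @slot activity dpm ml^-1 in the cell fraction.
#' @slot blankActivity dpm ml^-1 in the killed blank (scalar or one value
#'   per time point).
#' @slot cellDensity cells ml^-1 (scalar or per time point).
#' @slot meanCellVolume um^3 (scalar or per time point).
#'
#' @seealso [uptakeSeries()], [normalizeUptake()], [fitUptake()]
#' @export
setClass("UptakeSeries",
  representation(
    times = "numeric",
    activity = "numeric",
    blankActivity = "numeric",
    cellDensity = "numeric",
    meanCellVolume = "numeric"
  )
)

setValidity("UptakeSeries", function(object) {
  msg <- character()
  n <- length(object@times)
  if (any(object@times < 0) || any(diff(object@times) <= 0))
    msg <- c(msg, "'times' must be non-negative and increasing")
  if (length(object@activity) != n)
    msg <- c(msg, "'activity' must match 'times' in length")
  if (any(object@activity < 0) || any(object@blankActivity < 0))
    msg <- c(msg, "activities must be >= 0")
  for (s in c("blankActivity", "cellDensity", "meanCellVolume"))
    if (!length(slot(object, s)) %in% c(1L, n))
      msg <- c(msg, paste0("'", s, "' must be scalar or per time point"))
  if (length(msg)) msg else TRUE
})

#' Saturating uptake-kinetics fit
#'
#' Least-squares fit of `U(t) = Usat * (1 - exp(-t / tau))` to a
#' biovolume-normalised uptake series, plus a linear initial-phase rate on
#' the points at `t <=` 5 h (reported separately, as uptake rates are
#' conventionally quoted over the initial incubation hours).
#'
#' @slot initialRate model initial rate Usat / tau, dpm um^-3 h^-1.
#' @slot satiation plateau Usat, dpm um^-3.
#' @slot tau saturation time scale, hours.
#' @slot rss residual sum of squares.
#' @slot linearRate OLS slope on early points, dpm um^-3 h^-1.
#' @slot linearSe standard error of `linearRate`.
#'
#' @seealso [fitUptake()]
#' @export
setClass("UptakeFit",
  representation(
    initialRate = "numeric",
    satiation = "numeric",
    tau = "numeric",
    rss = "numeric",
    linearRate = "numeric",
    linearSe = "numeric"
  ),
  prototype(linearRate = NA_real_, linearSe = NA_real_)
)

setValidity("UptakeFit", function(object) {
  msg <- character()
  if (is.finite(object@satiation) && object@satiation < 0)
    msg <- c(msg, "'satiation' must be >= 0")
  if (is.finite(object@tau) && object@tau <= 0)
    msg <- c(msg, "'tau' must be > 0")
  if (length(msg)) msg else TRUE
})
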