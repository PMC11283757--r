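#' Run the full assay analysis pipeline
#'
#' Orchestrates the stages on one assay: load (or simulate) cue- and
#' control-side tracks, compute axial/radial accumulation profiles and
#' their exponential fits, derive the gated chemotactic indices with the
#' fitted decay lengths as region extents, the long-term accumulation
#' rates, and the swimming-behaviour statistics (straightness by segment
#' class, speed versus distance). Deterministic given the config and seed.
#'
#' The config is a named list (or a YAML file path) with optional blocks:
#' \describe{
#'   \item{tracks / control_tracks}{CSV paths of cue/control track tables;
#'     when absent and `simulate` is present, tracks are simulated.}
#'   \item{simulate}{list of [swimmerConfig()] and [gradientModel()]
#'     overrides (`n_cells`, `v0`, `chi`, `kappa`, `duration`, `seed`,
#'     `reservoir_uM`, ...); a paired null (chi = kappa = 0) simulation
#'     provides the control side.}
#'   \item{geometry}{[readGeometryConfig()] keys; defaults to a unit-scale
#'     30 fps geometry at the origin.}
#'   \item{analysis}{`bin_width_in` (20), `bin_width_out` (10), `alpha`
#'     (0.01), `window_s` (120), `patch_radius` (200), `neutral_radius`
#'     (400), `corona_center` (130), `min_track_frames` (15).}
#' }
#'
#' @param config named list or YAML file path.
#' @param outDir optional directory; when given, profiles, fits, indices
#'   and behaviour tables are written as CSV/JSON.
#' @return report list with elements `tracks`, `profiles`, `fits`,
#'   `index`, `rates`, `behaviour`, `config`.
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  geo <- config$geometry
  geometry <- if (is.null(geo)) assayGeometry(c(0, 0)) else
    assayGeometry(as.numeric(geo$origin_px %||% c(0, 0)),
                  axisDeg = geo$axis_deg %||% 0,
                  pixelScale = geo$pixel_scale_um %||% 1,
                  frameRate = geo$frame_rate_fps %||% 30,
                  capillaryWidth = geo$capillary_width_um %||% 200,
                  capillaryLength = geo$capillary_length_um %||% 50000,
                  wallThickness = geo$wall_thickness_um %||% 100)
  an <- config$analysis %||% list()
  alpha <- an$alpha %||% 0.01
  windowS <- an$window_s %||% 120
  binIn <- an$bin_width_in %||% 20
  binOut <- an$bin_width_out %||% 10
  minFrames <- an$min_track_frames %||% 15

  if (!is.null(config$tracks)) {
    cue <- readTracks(config$tracks, geometry)
    ctl <- if (!is.null(config$control_tracks))
      readTracks(config$control_tracks, geometry) else NULL
  } else {
    sim <- config$simulate %||% list()
    grad <- gradientModel(
      reservoirConc = sim$reservoir_uM %||% 20,
      D = sim$diffusivity %||% 1000,
      decayingSource = isTRUE(sim$decaying_source))
    mk <- function(chi, kappa, turnGain, giveUp, seed)
      swimmerConfig(nCells = sim$n_cells %||% 100,
                    v0 = sim$v0 %||% 150,
                    rotDiffusion = sim$rot_diffusion %||% 0.5,
                    chi = chi, kappa = kappa, turnGain = turnGain,
                    giveUpTime = giveUp,
                    duration = sim$duration %||% 600,
                    dt = sim$dt %||% (1 / 300),
                    seed = seed)
    seed <- sim$seed %||% 1
    cue <- simulateAssay(mk(sim$chi %||% 1, sim$kappa %||% 0.5,
                            sim$turn_gain %||% 10, sim$give_up_time %||% 15,
                            seed),
                         grad, geometry)
    # control capillary holds plain medium: no field, insensitive swimmers
    ctlGrad <- gradientModel(reservoirConc = 0, Q = 0,
                             D = sim$diffusivity %||% 1000)
    ctl <- simulateAssay(mk(0, 0, 0, 0, seed + 1), ctlGrad, geometry)
  }
  cue <- filterTracks(cue, minFrames)
  if (!is.null(ctl)) ctl <- filterTracks(ctl, minFrames)

  profIn <- axialProfile(cue, geometry, binWidth = binIn)
  profOut <- radialProfile(cue, geometry, binWidth = binOut)
  selIn <- selectProfileModel(profIn)
  fitOut <- fitExponential(profOut)
  lamIn <- decayLength(selIn$fit)
  lamOut <- decayLength(fitOut)
  if (!is.finite(lamIn)) lamIn <- an$fallback_lambda_in %||% 500
  if (!is.finite(lamOut)) lamOut <- an$fallback_lambda_out %||% 150

  idx <- chemotaxisIndices(cue, geometry, lambdaIn = lamIn,
                           lambdaOut = lamOut, controlTracks = ctl,
                           alpha = alpha, windowS = windowS)

  insideSeries <- countInRegion(cue, insideRect(lamIn), geometry)
  rates <- accumulationRate(insideSeries)

  segs <- classifySegments(
    cue, geometry,
    corona = makeCorona(an$corona_center %||% 130),
    patchRadius = an$patch_radius %||% 200,
    tMin = an$t_min %||% 60,
    neutralRadius = an$neutral_radius %||% 400)
  st <- segmentTable(segs)
  sMed <- if (nrow(st))
    vapply(split(st$S, st$label), median, numeric(1L)) else numeric(0)
  svd <- tryCatch(speedVsDistance(cue, geometry),
                  error = function(e) NULL)

  report <- list(
    tracks = list(cue = cue, control = ctl),
    profiles = list(inside = profIn, outside = profOut),
    fits = list(inside = selIn$fit, insideModel = selIn$model,
                outside = fitOut),
    index = idx,
    rates = rates,
    behaviour = list(segments = st, medianS = sMed, speed = svd),
    config = config)

  if (!is.null(outDir)) writeReport(report, outDir)
  report
}

#' Write a pipeline report bundle to disk
#'
#' Emits `profile_inside.csv`, `profile_outside.csv`, `fits.json`,
#' `index.json`, `segments.csv` and `tracks_cue.csv` under `outDir`.
#'
#' @param report list from [runPipeline()].
#' @param outDir output directory (created if needed).
#' @return invisibly, `outDir`.
#' @export
writeReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  exportProfileFit(report$profiles$inside, report$fits$inside,
                   csvPath = file.path(outDir, "profile_inside.csv"))
  exportProfileFit(report$profiles$outside, report$fits$outside,
                   csvPath = file.path(outDir, "profile_outside.csv"))
  fits <- list(
    inside = c(exportProfileFit(report$profiles$inside,
                                report$fits$inside),
               list(model = report$fits$insideModel)),
    outside = exportProfileFit(report$profiles$outside,
                               report$fits$outside))
  jsonlite::write_json(fits, file.path(outDir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  idx <- report$index
  jsonlite::write_json(
    list(ic_inside = idx@icInside, ic_outside = idx@icOutside,
         p_inside = idx@pInside, p_outside = idx@pOutside,
         p_inside_corr = idx@pInsideCorr, p_outside_corr = idx@pOutsideCorr,
         gated_inside = idx@gatedInside, gated_outside = idx@gatedOutside,
         window_inside = idx@windowInside, window_outside = idx@windowOutside,
         alpha = idx@alpha,
         accumulation_slope = report$rates$slope,
         accumulation_slope_se = report$rates$se),
    file.path(outDir, "index.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  if (nrow(report$behaviour$segments))
    write.csv(report$behaviour$segments,
              file.path(outDir, "segments.csv"), row.names = FALSE,
              quote = FALSE)
  writeTracks(report$tracks$cue, file.path(outDir, "tracks_cue.csv"))
  invisible(outDir)
}
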