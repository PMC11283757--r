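#' Decay length of an accumulation-profile fit
#'
#' @param object an [ExpFit-class] or [PiecewiseFit-class].
#' @return lambda in micrometres (NA for degenerate fits).
#' @export
setGeneric("decayLength", function(object) standardGeneric("decayLength"))

#' @rdname decayLength
#' @export
setMethod("decayLength", "ExpFit", function(object) object@lam)

#' Plateau length of a piecewise profile fit
#'
#' @param object a [PiecewiseFit-class].
#' @return plateau length L0 in micrometres.
#' @export
setGeneric("plateauLength", function(object) standardGeneric("plateauLength"))

#' @rdname plateauLength
#' @export
setMethod("plateauLength", "PiecewiseFit", function(object) object@plateauLen)

#' Amplitude and baseline of a profile fit
#'
#' @param object an [ExpFit-class].
#' @return amplitude `a` resp. baseline `b` on the density scale.
#' @export
setGeneric("amplitude", function(object) standardGeneric("amplitude"))

#' @rdname amplitude
#' @export
setMethod("amplitude", "ExpFit", function(object) object@a)

#' @rdname amplitude
#' @export
setGeneric("baseline", function(object) standardGeneric("baseline"))

#' @rdname amplitude
#' @export
setMethod("baseline", "ExpFit", function(object) object@b)

#' Bin centres of a concentration profile
#'
#' @param object a [ConcentrationProfile-class].
#' @return numeric vector of bin mid-points, micrometres.
#' @export
setGeneric("binCenters", function(object) standardGeneric("binCenters"))

#' @rdname binCenters
#' @export
setMethod("binCenters", "ConcentrationProfile", function(object) {
  e <- object@binEdges
  (head(e, -1L) + tail(e, -1L)) / 2
})

#' Profile density values
#'
#' @param object a [ConcentrationProfile-class].
#' @return cells um^-2 frame^-1 per bin.
#' @export
setGeneric("profileDensity", function(object) standardGeneric("profileDensity"))

#' @rdname profileDensity
#' @export
setMethod("profileDensity", "ConcentrationProfile",
          function(object) object@density)

#' Chemotactic index accessors
#'
#' @param object a [ChemotaxisIndex-class].
#' @return the inside resp. outside maximum chemotactic index.
#' @export
setGeneric("icInside", function(object) standardGeneric("icInside"))

#' @rdname icInside
#' @export
setMethod("icInside", "ChemotaxisIndex", function(object) object@icInside)

#' @rdname icInside
#' @export
setGeneric("icOutside", function(object) standardGeneric("icOutside"))

#' @rdname icInside
#' @export
setMethod("icOutside", "ChemotaxisIndex", function(object) object@icOutside)

setMethod("show", "AssayGeometry", function(object) {
  cat("AssayGeometry\n")
  cat(sprintf("  origin (px): (%.2f, %.2f); axis: (%.4f, %.4f)\n",
              object@origin[1], object@origin[2],
              object@axis[1], object@axis[2]))
  cat(sprintf("  pixel scale: %g um/px; frame rate: %g fps\n",
              object@pixelScale, object@frameRate))
  cat(sprintf("  capillary: %g um wide x %g um long, wall %g um\n",
              object@capillaryWidth, object@capillaryLength,
              object@wallThickness))
  if (all(is.finite(object@controlOrigin)))
    cat(sprintf("  control origin (px): (%.2f, %.2f)\n",
                object@controlOrigin[1], object@controlOrigin[2]))
})

setMethod("show", "RegionSpec", function(object) {
  if (object@kind == "corona")
    cat(sprintf("RegionSpec corona [%g, %g] um\n",
                object@coronaInner, object@coronaOuter))
  else
    cat(sprintf("RegionSpec %s, %g um\n", object@kind, object@depthOrRadius))
})

setMethod("show", "ConcentrationProfile", function(object) {
  cat(sprintf("ConcentrationProfile (%s): %d bins over [%g, %g] um, %d points\n",
              object@region, length(object@density),
              min(object@binEdges), max(object@binEdges),
              sum(object@counts)))
})

setMethod("show", "ExpFit", function(object) {
  if (object@degenerate) {
    cat("ExpFit: degenerate (no decay signal)\n")
  } else {
    cat(sprintf("ExpFit: a = %.4g, b = %.4g, lambda = %.4g um (se %.3g), rss = %.4g%s\n",
                object@a, object@b, object@lam, object@seLam, object@rss,
                if (object@nonDecaying) " [non-decaying]" else ""))
  }
})

setMethod("show", "PiecewiseFit", function(object) {
  if (object@degenerate) {
    cat("PiecewiseFit: degenerate (no decay signal)\n")
  } else {
    cat(sprintf(
      "PiecewiseFit: plateau L0 = %.4g um, a = %.4g, b = %.4g, lambda = %.4g um, rss = %.4g\n",
      object@plateauLen, object@a, object@b, object@lam, object@rss))
  }
})

setMethod("show", "CountSeries", function(object) {
  cat(sprintf("CountSeries: %d frames over %.1f s, mean count %.2f (%s)\n",
              length(object@counts), diff(range(object@times)),
              mean(object@counts), object@region@kind))
})

setMethod("show", "ChemotaxisIndex", function(object) {
  g <- function(x) if (isTRUE(x)) " [gated]" else ""
  cat("ChemotaxisIndex (max, 2-min window)\n")
  cat(sprintf("  inside : Ic = %.3g%s (p = %.3g, corrected %.3g)\n",
              object@icInside, g(object@gatedInside),
              object@pInside, object@pInsideCorr))
  cat(sprintf("  outside: Ic = %.3g%s (p = %.3g, corrected %.3g)\n",
              object@icOutside, g(object@gatedOutside),
              object@pOutside, object@pOutsideCorr))
})

setMethod("show", "GradientModel", function(object) {
  cat(sprintf(
    "GradientModel: Q = %.4g fmol/s, D = %g um^2/s, C0 = %g uM, reservoir %g uM%s\n",
    object@Q, object@D, object@C0, object@reservoirConc,
    if (object@decayingSource)
      sprintf(", depleting (tau = %g s)", object@sourceTau) else ""))
})

setMethod("show", "SwimmerConfig", function(object) {
  cat(sprintf(
    "SwimmerConfig: %d cells, v0 = %g um/s, Dr = %g rad^2/s, chi = %g, kappa = %g\n",
    object@nCells, object@v0, object@rotDiffusion, object@chi, object@kappa))
  cat(sprintf("  dt = %g s, duration = %g s, arena radius = %g um, seed = %d\n",
              object@dt, object@duration, object@arenaRadius,
              as.integer(object@seed)))
})

setMethod("show", "UptakeFit", function(object) {
  cat(sprintf(
    "UptakeFit: satiation = %.4g dpm/um^3, tau = %.3g h, initial rate = %.4g dpm um^-3 h^-1\n",
    object@satiation, object@tau, object@initialRate))
  if (is.finite(object@linearRate))
    cat(sprintf("  linear 0-5 h rate = %.4g (se %.3g) dpm um^-3 h^-1\n",
                object@linearRate, object@linearSe))
})
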