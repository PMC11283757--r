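#' Construct the assay geometry
#'
#' Defines the mapping between image pixels and the assay frame: origin at
#' the centre of the cue-capillary entrance, axial coordinate along the
#' capillary axis (positive inward), transverse coordinate across it.
#' `axisDeg` is the direction of the capillary axis measured
#' counter-clockwise from the +x direction after the image y-flip (image y
#' grows downward; the assay frame is right-handed with y up).
#'
#' @param originPx numeric(2), entrance centre in pixels.
#' @param axisDeg capillary-axis direction, degrees.
#' @param pixelScale micrometres per pixel.
#' @param frameRate frames per second (default 30).
#' @param capillaryWidth inner capillary width, micrometres (default 200).
#' @param capillaryLength capillary length, micrometres (default 50000).
#' @param wallThickness glass wall thickness, micrometres (default 100).
#' @param controlOriginPx,controlAxisDeg same for the control capillary
#'   (optional).
#' @return an [AssayGeometry-class].
#' @examples
#' g <- assayGeometry(c(512, 384), axisDeg = 0, pixelScale = 2)
#' toAssayFrame(cbind(522, 384), g)  # 10 px along the axis -> 20 um inside
#' @export
assayGeometry <- function(originPx, axisDeg = 0, pixelScale = 1,
                          frameRate = 30, capillaryWidth = 200,
                          capillaryLength = 50000, wallThickness = 100,
                          controlOriginPx = c(NA_real_, NA_real_),
                          controlAxisDeg = NA_real_) {
  th <- axisDeg * pi / 180
  axis <- c(cos(th), sin(th))
  cax <- if (is.na(controlAxisDeg)) c(NA_real_, NA_real_) else
    c(cos(controlAxisDeg * pi / 180), sin(controlAxisDeg * pi / 180))
  new("AssayGeometry",
      origin = as.numeric(originPx), axis = axis,
      pixelScale = pixelScale, frameRate = frameRate,
      capillaryWidth = capillaryWidth, capillaryLength = capillaryLength,
      wallThickness = wallThickness,
      controlOrigin = as.numeric(controlOriginPx), controlAxis = cax)
}

#' Read an assay geometry from a YAML config file
#'
#' Recognised keys: `origin_px` (length 2), `axis_deg`, `pixel_scale_um`,
#' `frame_rate_fps`, `capillary_width_um`, `capillary_length_um`,
#' `wall_thickness_um`, `control_origin_px`, `control_axis_deg`.
#'
#' @param path path to a YAML file.
#' @return an [AssayGeometry-class].
#' @export
readGeometryConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  req <- c("origin_px", "axis_deg", "pixel_scale_um")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stop("geometry config is missing keys: ", paste(miss, collapse = ", "))
  assayGeometry(
    originPx = as.numeric(cfg$origin_px),
    axisDeg = cfg$axis_deg,
    pixelScale = cfg$pixel_scale_um,
    frameRate = cfg$frame_rate_fps %||% 30,
    capillaryWidth = cfg$capillary_width_um %||% 200,
    capillaryLength = cfg$capillary_length_um %||% 50000,
    wallThickness = cfg$wall_thickness_um %||% 100,
    controlOriginPx = as.numeric(cfg$control_origin_px %||%
                                   c(NA_real_, NA_real_)),
    controlAxisDeg = cfg$control_axis_deg %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Swap a geometry to its control capillary
#'
#' Returns the same geometry with origin and axis replaced by the control
#' capillary's, so that all region constructors and statistics can be reused
#' verbatim on the control side.
#'
#' @param geometry an [AssayGeometry-class] with control origin/axis set.
#' @return an [AssayGeometry-class].
#' @export
controlGeometry <- function(geometry) {
  if (!all(is.finite(geometry@controlOrigin)) ||
      !all(is.finite(geometry@controlAxis)))
    stop("geometry has no control capillary defined")
  g <- geometry
  g@origin <- geometry@controlOrigin
  g@axis <- geometry@controlAxis
  g@controlOrigin <- geometry@origin
  g@controlAxis <- geometry@axis
  validObject(g)
  g
}

.as_points <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 2L) stop("points must be length-2 or an n x 2 matrix")
    p <- matrix(p, ncol = 2L)
  }
  p <- as.matrix(p)
  if (ncol(p) != 2L) stop("points must be an n x 2 matrix")
  storage.mode(p) <- "double"
  p
}

#' Map pixel coordinates into the assay frame
#'
#' Affine, invertible map: translate to the entrance origin, flip the image
#' y-axis, scale to micrometres, and rotate so the first coordinate runs
#' along the capillary axis (positive inside the capillary).
#'
#' @param pointsPx n x 2 matrix (or length-2 vector) of pixel coordinates.
#' @param geometry an [AssayGeometry-class].
#' @return n x 2 matrix of assay-frame coordinates, micrometres; columns
#'   `axial`, `transverse`.
#' @seealso [fromAssayFrame()]
#' @export
toAssayFrame <- function(pointsPx, geometry) {
  p <- .as_points(pointsPx)
  if (any(!is.finite(p))) stop("non-finite input coordinates")
  dx <- p[, 1L] - geometry@origin[1L]
  dy <- -(p[, 2L] - geometry@origin[2L])   # image y grows downward
  vx <- dx * geometry@pixelScale
  vy <- dy * geometry@pixelScale
  a <- geometry@axis
  out <- cbind(axial = vx * a[1L] + vy * a[2L],
               transverse = -vx * a[2L] + vy * a[1L])
  out
}

#' Map assay-frame coordinates back to pixels
#'
#' Exact inverse of [toAssayFrame()].
#'
#' @param pointsUm n x 2 matrix of assay-frame coordinates, micrometres.
#' @param geometry an [AssayGeometry-class].
#' @return n x 2 matrix of pixel coordinates.
#' @export
fromAssayFrame <- function(pointsUm, geometry) {
  p <- .as_points(pointsUm)
  if (any(!is.finite(p))) stop("non-finite input coordinates")
  a <- geometry@axis
  vx <- p[, 1L] * a[1L] - p[, 2L] * a[2L]
  vy <- p[, 1L] * a[2L] + p[, 2L] * a[1L]
  cbind(x = vx / geometry@pixelScale + geometry@origin[1L],
        y = -vy / geometry@pixelScale + geometry@origin[2L])
}

#' Region constructors
#'
#' `insideRect(depth)` is the rectangular area within axial distance `depth`
#' from the entrance, spanning the capillary inner width.
#' `outsideSemicircle(radius)` is the half-disc of that radius in front of
#' the entrance (the other half is blocked by the capillary).
#' `coronaRegion(inner, outer)` is the annulus between the two radii.
#' `neutralZone(radius)` is everything farther than `radius` from the
#' entrance.
#'
#' @param depth,radius,inner,outer lengths in micrometres.
#' @return a [RegionSpec-class].
#' @export
insideRect <- function(depth)
  new("RegionSpec", kind = "inside_rect", depthOrRadius = depth)

#' @rdname insideRect
#' @export
outsideSemicircle <- function(radius)
  new("RegionSpec", kind = "outside_semicircle", depthOrRadius = radius)

#' @rdname insideRect
#' @export
coronaRegion <- function(inner, outer)
  new("RegionSpec", kind = "corona", coronaInner = inner, coronaOuter = outer)

#' @rdname insideRect
#' @export
neutralZone <- function(radius)
  new("RegionSpec", kind = "neutral", depthOrRadius = radius)

#' Build a corona scaled to the cell body length
#'
#' The corona width is `multiplier` body lengths (default: 7 body lengths of
#' 20 um = 140 um), centred on `rCenter`.
#'
#' @param rCenter corona centre radius, micrometres.
#' @param bodyLength cell body length, micrometres (default 20).
#' @param multiplier number of body lengths spanned by the corona width
#'   (default 7).
#' @return a [RegionSpec-class] of kind `corona`.
#' @examples
#' makeCorona(130)          # width 140 um: radii [60, 200]
#' @export
makeCorona <- function(rCenter, bodyLength = 20, multiplier = 7) {
  if (bodyLength <= 0 || multiplier < 1 || rCenter <= 0)
    stop("'rCenter' and 'bodyLength' must be > 0 and 'multiplier' >= 1")
  w <- bodyLength * multiplier
  inner <- rCenter - w / 2
  if (inner < 0) stop("corona inner radius would be negative")
  coronaRegion(inner, rCenter + w / 2)
}

#' Test whether points fall in the capillary glass wall
#'
#' @param pointsUm n x 2 assay-frame points.
#' @param geometry an [AssayGeometry-class].
#' @return logical vector.
#' @keywords internal
inGlassWall <- function(pointsUm, geometry) {
  p <- .as_points(pointsUm)
  w2 <- geometry@capillaryWidth / 2
  p[, 1L] >= 0 & p[, 1L] <= geometry@capillaryLength &
    abs(p[, 2L]) > w2 &
    abs(p[, 2L]) <= w2 + geometry@wallThickness
}

#' Region membership of assay-frame points
#'
#' Vectorised point-in-region predicate. Points lying inside the capillary
#' glass wall belong to no region. For `inside_rect` membership requires
#' `0 <= axial <= depth` and `|transverse| <= width/2`; for
#' `outside_semicircle`, `axial < 0` and distance to the origin at most the
#' radius; for `corona`, distance between the two radii (in front of or at
#' the entrance plane); for `neutral`, distance beyond the radius.
#'
#' @param pointsUm n x 2 matrix (or length-2 vector) of assay-frame points,
#'   micrometres.
#' @param spec a [RegionSpec-class].
#' @param geometry an [AssayGeometry-class].
#' @param excludeGlass classify points inside the wall glass as
#'   non-members (default TRUE).
#' @return logical vector of length n.
#' @examples
#' g <- assayGeometry(c(0, 0), pixelScale = 1)
#' regionMembership(c(50, 0), insideRect(100), g)        # TRUE
#' regionMembership(c(-150, 0), outsideSemicircle(100), g) # FALSE
#' @export
regionMembership <- function(pointsUm, spec, geometry, excludeGlass = TRUE) {
  p <- .as_points(pointsUm)
  x <- p[, 1L]; y <- p[, 2L]
  r <- sqrt(x^2 + y^2)
  res <- switch(spec@kind,
    inside_rect = x >= 0 & x <= spec@depthOrRadius &
      abs(y) <= geometry@capillaryWidth / 2,
    outside_semicircle = x < 0 & r <= spec@depthOrRadius,
    corona = r >= spec@coronaInner & r <= spec@coronaOuter,
    neutral = r > spec@depthOrRadius,
    stop("unknown region kind '", spec@kind, "'")
  )
  if (excludeGlass) res <- res & !inGlassWall(p, geometry)
  res
}
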