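#' Track tables
#'
#' Throughout the package a set of trajectories is a plain `data.frame`
#' with one row per (track, frame) observation and columns
#' `track_id`, `frame` (0-based), `x_um`, `y_um` (assay frame, micrometres)
#' and `t_s` (seconds). [linkDetections()] produces the same layout in
#' pixel units (`x_px`, `y_px`); [tracksToAssayFrame()] converts.
#'
#' @name track-tables
NULL

.check_stack <- function(frames) {
  if (is.list(frames)) {
    if (!length(frames)) stop("empty image stack")
    d <- dim(frames[[1L]])
    if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1L))))
      stop("frames must share dimensions")
    frames <- array(unlist(frames), dim = c(d, length(frames)))
  }
  if (length(dim(frames)) != 3L) stop("expected a 3D array or list of matrices")
  frames
}

#' Estimate a static background image
#'
#' Per-pixel temporal median of the stack. Moving cells visit any one pixel
#' for only a few frames, so the median recovers the static scene.
#'
#' @param frames 3D array `[ny, nx, nframes]` or list of matrices.
#' @return background matrix `[ny, nx]`.
#' @export
estimateBackground <- function(frames) {
  frames <- .check_stack(frames)
  if (dim(frames)[3L] < 2L) stop("need at least 2 frames")
  d <- dim(frames)
  m <- matrix(aperm(frames, c(3L, 1L, 2L)), nrow = d[3L])
  bg <- apply(m, 2L, median)
  matrix(bg, d[1L], d[2L])
}

#' Detect cells in a background-subtracted frame
#'
#' Thresholds `|frame - background|`, labels connected components
#' (via \pkg{EBImage}), discards components smaller than `minArea`, and
#' returns intensity-weighted centroids. Pixel coordinates are 0-based with
#' origin at the top-left pixel centre, `x` along columns, `y` along rows.
#'
#' @param frame,background matrices of equal dimensions.
#' @param threshold absolute-difference threshold, > 0.
#' @param minArea minimum component area in pixels (default 3).
#' @return `data.frame` with columns `x`, `y`, `area`.
#' @export
detectCells <- function(frame, background, threshold, minArea = 3) {
  if (!identical(dim(frame), dim(background)))
    stop("'frame' and 'background' must have identical dimensions")
  if (threshold <= 0) stop("'threshold' must be > 0")
  d <- abs(frame - background)
  mask <- d > threshold
  if (!any(mask))
    return(data.frame(x = numeric(), y = numeric(), area = numeric()))
  lab <- EBImage::bwlabel(mask)
  idx <- which(lab > 0)
  labv <- lab[idx]
  w <- d[idx]
  rows <- (idx - 1L) %% nrow(d)      # 0-based row -> y
  cols <- (idx - 1L) %/% nrow(d)     # 0-based col -> x
  area <- tabulate(labv)
  sw <- vapply(split(w, labv), sum, numeric(1L))
  sx <- vapply(split(w * cols, labv), sum, numeric(1L))
  sy <- vapply(split(w * rows, labv), sum, numeric(1L))
  keep <- area >= minArea
  data.frame(x = (sx / sw)[keep], y = (sy / sw)[keep], area = area[keep],
             row.names = NULL)
}

#' Detect cells across a stack
#'
#' @param frames 3D array or list of matrices.
#' @param background optional background matrix; estimated with
#'   [estimateBackground()] when NULL.
#' @inheritParams detectCells
#' @return `data.frame` with columns `frame` (0-based), `x`, `y`, `area`.
#' @export
detectStack <- function(frames, background = NULL, threshold, minArea = 3) {
  frames <- .check_stack(frames)
  if (is.null(background)) background <- estimateBackground(frames)
  nf <- dim(frames)[3L]
  out <- vector("list", nf)
  for (i in seq_len(nf)) {
    det <- detectCells(frames[, , i], background, threshold, minArea)
    if (nrow(det)) det$frame <- i - 1L
    out[[i]] <- det
  }
  res <- do.call(rbind, out[vapply(out, nrow, integer(1L)) > 0])
  if (is.null(res))
    return(data.frame(frame = integer(), x = numeric(), y = numeric(),
                      area = numeric()))
  res[c("frame", "x", "y", "area")]
}

#' Link detections into trajectories
#'
#' Greedy nearest-neighbour frame-to-frame linking with gap closing: at each
#' frame, candidate (track, detection) pairs within `maxDisplacement` are
#' assigned in order of increasing distance (ties broken by lower detection
#' index), so every realised link is a mutual nearest neighbour among the
#' still-unassigned candidates. A track may skip up to `memory` frames
#' before being closed. Deterministic given the input; invariant to the
#' ordering of detections within a frame up to exact distance ties.
#'
#' @param detections `data.frame` with columns `frame`, `x`, `y` (any
#'   consistent length unit; `maxDisplacement` must match it).
#' @param maxDisplacement maximum link length per frame step.
#' @param memory maximum number of skipped frames bridged by a link
#'   (default 2).
#' @return track table with columns `track_id`, `frame`, `x`, `y`
#'   (units of the input).
#' @export
linkDetections <- function(detections, maxDisplacement, memory = 2) {
  if (maxDisplacement < 0) stop("'maxDisplacement' must be >= 0")
  need <- c("frame", "x", "y")
  if (!all(need %in% names(detections)))
    stop("detections need columns: ", paste(need, collapse = ", "))
  det <- detections[order(detections$frame), , drop = FALSE]
  if (!nrow(det))
    return(data.frame(track_id = integer(), frame = integer(),
                      x = numeric(), y = numeric()))
  frames <- sort(unique(det$frame))
  # active track state
  t_id <- integer(); t_x <- numeric(); t_y <- numeric(); t_f <- integer()
  next_id <- 1L
  rows <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    di <- which(det$frame == f)
    dx <- det$x[di]; dy <- det$y[di]
    assigned <- rep(NA_integer_, length(di))   # index into track state
    alive <- which(t_f >= f - memory - 1L & t_f < f)
    if (length(alive) && length(di)) {
      dmat <- sqrt(outer(dx, t_x[alive], "-")^2 +
                   outer(dy, t_y[alive], "-")^2)
      cand <- which(dmat <= maxDisplacement, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dmat[cand], cand[, 1L])
        usedD <- logical(length(di)); usedT <- logical(length(alive))
        for (ci in ord) {
          i <- cand[ci, 1L]; j <- cand[ci, 2L]
          if (!usedD[i] && !usedT[j]) {
            usedD[i] <- TRUE; usedT[j] <- TRUE
            assigned[i] <- alive[j]
          }
        }
      }
    }
    for (i in seq_along(di)) {
      if (is.na(assigned[i])) {           # start a new track
        t_id <- c(t_id, next_id); t_x <- c(t_x, dx[i]); t_y <- c(t_y, dy[i])
        t_f <- c(t_f, f)
        assigned[i] <- length(t_id)
        next_id <- next_id + 1L
      } else {
        j <- assigned[i]
        t_x[j] <- dx[i]; t_y[j] <- dy[i]; t_f[j] <- f
      }
    }
    rows[[k]] <- data.frame(track_id = t_id[assigned], frame = f,
                            x = dx, y = dy)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert a pixel track table to the assay frame
#'
#' @param tracks track table with `x`/`y` or `x_px`/`y_px` pixel columns.
#' @param geometry an [AssayGeometry-class].
#' @return track table with `track_id`, `frame`, `x_um`, `y_um`, `t_s`.
#' @export
tracksToAssayFrame <- function(tracks, geometry) {
  xc <- if ("x_px" %in% names(tracks)) "x_px" else "x"
  yc <- if ("y_px" %in% names(tracks)) "y_px" else "y"
  p <- toAssayFrame(cbind(tracks[[xc]], tracks[[yc]]), geometry)
  data.frame(track_id = tracks$track_id, frame = tracks$frame,
             x_um = p[, 1L], y_um = p[, 2L],
             t_s = tracks$frame / geometry@frameRate)
}

#' Read and write track tables
#'
#' CSV with header `track_id,frame,x_um,y_um` (optional `t_s`), or
#' `track_id,frame,x_px,y_px` with a geometry supplied, in which case
#' positions are converted to the assay frame on read. Rows are sorted by
#' track and frame; duplicated frames within a track are an error.
#'
#' @param path CSV file path.
#' @param geometry optional [AssayGeometry-class] for pixel input or to
#'   (re)compute `t_s`.
#' @return track table (see [track-tables]).
#' @export
readTracks <- function(path, geometry = NULL) {
  tab <- read.csv(path)
  if (!all(c("track_id", "frame") %in% names(tab)))
    stop("track file must have columns 'track_id' and 'frame'")
  if (all(c("x_px", "y_px") %in% names(tab))) {
    if (is.null(geometry))
      stop("pixel-coordinate track file requires a geometry")
    tab <- tracksToAssayFrame(tab, geometry)
  } else if (!all(c("x_um", "y_um") %in% names(tab))) {
    stop("track file must have columns 'x_um','y_um' or 'x_px','y_px'")
  }
  tab <- tab[order(tab$track_id, tab$frame), , drop = FALSE]
  dup <- unlist(lapply(split(tab$frame, tab$track_id),
                       function(f) any(duplicated(f))))
  if (any(dup))
    stop("non-monotone frames: duplicated frame index within track(s) ",
         paste(names(dup)[dup], collapse = ", "))
  if (!"t_s" %in% names(tab)) {
    if (is.null(geometry))
      stop("track file lacks 't_s'; supply a geometry with a frame rate")
    tab$t_s <- tab$frame / geometry@frameRate
  }
  rownames(tab) <- NULL
  tab[c("track_id", "frame", "x_um", "y_um", "t_s")]
}

#' @rdname readTracks
#' @param tracks track table to write.
#' @export
writeTracks <- function(tracks, path) {
  need <- c("track_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(tracks)))
    stop("track table needs columns: ", paste(need, collapse = ", "))
  cols <- c(need, intersect("t_s", names(tracks)))
  write.csv(tracks[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop tracks shorter than a minimum number of frames
#'
#' Centroid statistics on very short tracks are jitter-dominated; the
#' default keeps tracks of at least 15 frames (0.5 s at 30 fps).
#'
#' @param tracks track table.
#' @param minFrames minimum number of observations per track (default 15).
#' @return filtered track table.
#' @export
filterTracks <- function(tracks, minFrames = 15) {
  n <- table(tracks$track_id)
  keep <- names(n)[n >= minFrames]
  out <- tracks[as.character(tracks$track_id) %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
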