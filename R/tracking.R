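## Deterministic FACT streamline propagation: seeds on an isotropic
## lattice across a mask, nearest-voxel (non-interpolated) peak
## directions, amplitude floor, turn-angle threshold and GM-WM interface
## termination.

#' Tracking parameters
#'
#' Defaults follow the low-SNR intraoperative protocol: 1-mm seed grid,
#' 1-mm steps, termination when the peak amplitude falls below 0.01 or
#' the turn angle between successive steps exceeds 60 degrees, plus
#' termination at the gray-white matter interface. A minimum length of
#' two steps drops degenerate seeds.
#'
#' @param stepMm propagation step (mm).
#' @param seedSpacingMm seed lattice spacing (mm).
#' @param ampFloor peak-amplitude termination threshold.
#' @param maxTurnDeg maximal turn angle between successive steps, in
#'   (0, 90].
#' @param minLengthMm minimum streamline length kept (default 2 steps).
#' @param maxSteps per-direction step cap.
#' @return list of class "TrackingParams".
#' @export
trackingParams <- function(stepMm = 1, seedSpacingMm = 1, ampFloor = 0.01,
                           maxTurnDeg = 60, minLengthMm = 2 * stepMm,
                           maxSteps = 1000L) {
  stopifnot(stepMm > 0, seedSpacingMm > 0, ampFloor > 0,
            maxTurnDeg > 0, maxTurnDeg <= 90, minLengthMm > 0,
            maxSteps > 0)
  structure(list(stepMm = stepMm, seedSpacingMm = seedSpacingMm,
                 ampFloor = ampFloor, maxTurnDeg = maxTurnDeg,
                 minLengthMm = minLengthMm, maxSteps = as.integer(maxSteps)),
            class = "TrackingParams")
}

#' Seed points on an isotropic lattice across a mask
#'
#' Lattice points at `spacingMm`, origin at the minimum corner of the
#' mask's voxel bounding box, kept when their containing voxel is
#' in-mask. Order is deterministic: x varies fastest, then y, then z.
#'
#' @param mask logical array.
#' @param voxelSize voxel edge (mm).
#' @param spacingMm lattice spacing (mm).
#' @return n x 3 matrix of mm coordinates (0 rows for an empty mask).
#' @export
seedGrid <- function(mask, voxelSize, spacingMm = 1) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(matrix(numeric(), 0, 3))
  lo <- (apply(idx, 2, min) - 1L) * voxelSize        # bbox corner (mm)
  hi <- apply(idx, 2, max) * voxelSize
  cpp_seed_grid(as.integer(c(mask)), dim(mask), voxelSize, spacingMm,
                lo, hi)
}

#' Deterministic FACT fiber tracking
#'
#' From each seed, propagates bidirectionally using the peak of the
#' current voxel maximally aligned with the incoming direction
#' (sign-resolved to the incoming hemisphere; FACT keeps the direction
#' constant within a voxel). Propagation terminates when the chosen
#' peak's amplitude drops below `ampFloor`, the turn angle between
#' successive steps exceeds `maxTurnDeg`, the position leaves the
#' white-matter mask (the exiting vertex is retained), or `maxSteps` is
#' reached. The two half-tracks are joined; tracks shorter than
#' `minLengthMm` are dropped. The first step at a seed follows the
#' voxel's largest-amplitude peak in both signs.
#'
#' @param peaks a [PeakVolume-class].
#' @param wmMask logical array (white matter), same grid as `peaks`.
#' @param seeds n x 3 matrix of seed points (mm); default: lattice over
#'   `wmMask` at `params$seedSpacingMm`.
#' @param params a [trackingParams()].
#' @param metadata named list stored on the result (subject, timepoint,
#'   ...).
#' @return a [StreamlineSet-class]; counters `skippedSeeds` (seeds
#'   outside the mask) and `droppedShort` are in its metadata.
#' @export
trackFibers <- function(peaks, wmMask, seeds = NULL,
                        params = trackingParams(), metadata = list()) {
  stopifnot(is(peaks, "PeakVolume"))
  if (!identical(dim(wmMask)[1:3], as.integer(peaks@dim)))
    stop("peaks and wmMask must share the grid")
  if (is.null(seeds))
    seeds <- seedGrid(wmMask, peaks@voxelSize, params$seedSpacingMm)
  res <- cpp_track(as.numeric(peaks@directions),
                   as.numeric(peaks@amplitudes), peaks@dim,
                   peaks@voxelSize, as.integer(c(wmMask)),
                   seeds, params$stepMm, params$ampFloor,
                   params$maxTurnDeg, params$minLengthMm,
                   params$maxSteps)
  lines <- res$streamlines
  ## steps have constant length, so arc length is (nVertices - 1) * step
  lens <- (vapply(lines, nrow, 0L) - 1L) * params$stepMm
  info <- data.frame(length = as.numeric(lens))
  metadata$skippedSeeds <- res$skippedSeeds
  metadata$droppedShort <- res$droppedShort
  metadata$params <- params
  metadata$cache <- new.env(parent = emptyenv())  # lazy vertex stack
  new("StreamlineSet", streamlines = lines, voxelSize = peaks@voxelSize,
      dim = peaks@dim, info = info, metadata = metadata)
}

## linear 1-based voxel index of each vertex of a polyline (NA outside)
vertexVoxels <- function(m, dims, vs) {
  v <- floor(m / vs)
  inside <- v[, 1] >= 0 & v[, 2] >= 0 & v[, 3] >= 0 &
            v[, 1] < dims[1] & v[, 2] < dims[2] & v[, 3] < dims[3]
  out <- rep(NA_integer_, nrow(m))
  out[inside] <- 1L + v[inside, 1] + dims[1] * (v[inside, 2] +
                                                dims[2] * v[inside, 3])
  out
}

subsetStreamlines <- function(x, keep) {
  md <- x@metadata
  md$cache <- NULL              # stack cache is tied to the full set
  ## hot path: slot assignment without re-running validity
  out <- x
  slot(out, "streamlines", check = FALSE) <- x@streamlines[keep]
  slot(out, "info", check = FALSE) <- x@info[keep, , drop = FALSE]
  slot(out, "metadata", check = FALSE) <- md
  out
}

## memoized voxel/id stack of a streamline set (cache lives in an
## environment so it is shared across copies of the same full set)
getStackInfo <- function(sset) {
  env <- sset@metadata$cache
  if (is.null(env))
    return(cpp_stack_info(sset@streamlines, sset@dim, sset@voxelSize))
  if (is.null(env$stack))
    env$stack <- cpp_stack_info(sset@streamlines, sset@dim,
                                sset@voxelSize)
  env$stack
}

## stack all vertices of a set into one matrix with streamline ids
stackVertices <- function(sset) {
  nv <- vapply(sset@streamlines, nrow, 0L)
  list(verts = do.call(rbind, sset@streamlines),
       id = rep.int(seq_along(nv), nv), nPerLine = nv)
}
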