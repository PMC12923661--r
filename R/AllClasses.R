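## Central S4 containers. World coordinates are millimetres on a regular
## isotropic grid; voxel indices are 0-based internally with the
## voxel-center convention world = (index + 0.5) * voxelSize, axis order
## (x, y, z), z = feet-head.

#' Diffusion acquisition scheme
#'
#' b-values and unit gradient directions of a diffusion acquisition,
#' together with the grid geometry they are simulated/fit on. The default
#' scheme mirrors a two-shell intraoperative protocol: six b=0 volumes,
#' 20 directions at b=1000 s/mm^2 and 32 at b=2000 s/mm^2, 2.55 mm
#' isotropic voxels.
#'
#' @slot bvals numeric vector of b-values in s/mm^2.
#' @slot bvecs 3 x n matrix of gradient directions; unit-norm columns for
#'   b > 0, zero columns for b = 0.
#' @slot voxelSize isotropic voxel edge in mm.
#' @slot gridDim integer(3), grid dimensions.
#' @export
setClass("AcquisitionScheme",
  representation(bvals = "numeric", bvecs = "matrix",
                 voxelSize = "numeric", gridDim = "integer"))

setValidity("AcquisitionScheme", function(object) {
  msg <- character()
  if (!is.numeric(object@bvecs) || nrow(object@bvecs) != 3L ||
      ncol(object@bvecs) != length(object@bvals))
    msg <- c(msg, "bvecs must be a 3 x length(bvals) matrix")
  else {
    nz <- object@bvals > 0
    nrm <- sqrt(colSums(object@bvecs[, nz, drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "gradient directions for b > 0 must be unit-norm")
  }
  if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
    msg <- c(msg, "voxelSize must be a positive scalar")
  if (length(object@gridDim) != 3L || any(object@gridDim < 1L))
    msg <- c(msg, "gridDim must be three positive integers")
  if (length(msg)) msg else TRUE
})

#' Discrete fiber-peak field
#'
#' Per-voxel fiber peaks: up to K unit directions with non-negative
#' amplitudes per voxel. Directions are sign-ambiguous (d and -d denote
#' the same peak). This is the substrate FACT tracking propagates on; the
#' amplitude carries the termination threshold (background voxels have
#' amplitude 0).
#'
#' @slot directions numeric array of dim c(dim, K, 3).
#' @slot amplitudes numeric array of dim c(dim, K).
#' @slot voxelSize isotropic voxel edge in mm.
#' @slot dim integer(3) grid dimensions.
#' @export
setClass("PeakVolume",
  representation(directions = "array", amplitudes = "array",
                 voxelSize = "numeric", dim = "integer"))

setValidity("PeakVolume", function(object) {
  d <- object@dim
  K <- nPeaks(object)
  if (!identical(dim(object@amplitudes)[1:3], as.integer(d)))
    return("amplitudes must have dim c(dim, K)")
  if (!identical(dim(object@directions), c(as.integer(d), K, 3L)))
    return("directions must have dim c(dim, K, 3)")
  if (any(object@amplitudes < 0)) return("amplitudes must be >= 0")
  TRUE
})

#' Set of streamlines
#'
#' Ordered 3D polylines in mm world coordinates, with per-streamline
#' provenance. Produced by [trackFibers()] and filtered by the gating
#' operations.
#'
#' @slot streamlines list of n x 3 numeric matrices.
#' @slot voxelSize isotropic voxel edge of the originating grid (mm).
#' @slot dim integer(3) grid dimensions.
#' @slot info data.frame with one row per streamline (at least `length`,
#'   the polyline arc length in mm).
#' @slot metadata named list (subject, timepoint, tract, side, counters).
#' @export
setClass("StreamlineSet",
  representation(streamlines = "list", voxelSize = "numeric",
                 dim = "integer", info = "data.frame", metadata = "list"))

setValidity("StreamlineSet", function(object) {
  if (nrow(object@info) != length(object@streamlines))
    return("info must have one row per streamline")
  TRUE
})

#' Voxelwise diffusion tensor map
#'
#' Per-voxel symmetric diffusion tensors (mm^2/s) stored as the six unique
#' elements, with the fitted S0 and a validity mask. Voxels with any
#' non-positive signal are invalid, never imputed.
#'
#' @slot tensors nvox x 6 matrix, columns Dxx, Dyy, Dzz, Dxy, Dxz, Dyz.
#' @slot s0 numeric vector of fitted S0 (length nvox).
#' @slot valid logical vector (length nvox).
#' @slot dim integer(3); @slot voxelSize mm.
#' @export
setClass("TensorMap",
  representation(tensors = "matrix", s0 = "numeric", valid = "logical",
                 dim = "integer", voxelSize = "numeric"))

setValidity("TensorMap", function(object) {
  nv <- prod(object@dim)
  if (nrow(object@tensors) != nv || ncol(object@tensors) != 6L)
    return("tensors must be nvox x 6")
  if (length(object@valid) != nv) return("valid must have length nvox")
  TRUE
})

#' Per-tract metric profile
#'
#' Macro- and microstructural record of one reconstructed tract at one
#' timepoint: voxel-count volume (absolute and as % of supratentorial WM),
#' mean streamline length, cylinder-equivalent diameter, whole-tract FA/MD
#' (across-streamline averages) and the along-tract FA/MD profiles over
#' equal-arc-length centerline segments (55 by default). Empty segments
#' are NA-flagged, never zero-filled.
#'
#' @slot tract,side,timepoint,subject character identifiers.
#' @slot volumeMm3,volumeNorm,lengthMm,diameterMm,faMean,mdMean numeric.
#' @slot faProfile,mdProfile numeric vectors (one value per segment).
#' @slot segmentCounts integer vector of vertices assigned per segment.
#' @slot nStreamlines integer.
#' @export
setClass("TractProfile",
  representation(tract = "character", side = "character",
                 timepoint = "character", subject = "character",
                 volumeMm3 = "numeric", volumeNorm = "numeric",
                 lengthMm = "numeric", diameterMm = "numeric",
                 faMean = "numeric", mdMean = "numeric",
                 faProfile = "numeric", mdProfile = "numeric",
                 segmentCounts = "integer", nStreamlines = "integer"))

setValidity("TractProfile", function(object) {
  if (length(object@faProfile) != length(object@mdProfile) ||
      length(object@faProfile) != length(object@segmentCounts))
    return("faProfile, mdProfile and segmentCounts must share length")
  TRUE
})

#' Paired pre/intraoperative synthetic subject
#'
#' One synthetic patient: the preoperative and intraoperative dataset
#' (masks, peaks, tensors, simulated DWI) on a shared grid and scheme,
#' the ground-truth injected surgical effect, demographics, and the
#' speech-disturbance label.
#'
#' @slot subjectId character; @slot age numeric years; @slot sex character.
#' @slot pre,intra named lists (masks, peaks, tensors, s0, dwi, scheme).
#' @slot truth named list: the effect parameters exactly as applied.
#' @slot speechIncrease logical.
#' @export
setClass("SubjectPair",
  representation(subjectId = "character", age = "numeric", sex = "character",
                 pre = "list", intra = "list", truth = "list",
                 speechIncrease = "logical"))

## ---- generics -------------------------------------------------------

#' Number of peaks per voxel
#' @param x a PeakVolume
#' @return integer
#' @export
setGeneric("nPeaks", function(x) standardGeneric("nPeaks"))

#' @rdname nPeaks
#' @export
setMethod("nPeaks", "PeakVolume", function(x) {
  da <- dim(x@amplitudes)
  if (length(da) == 3L) 1L else da[4L]
})

#' Number of streamlines
#' @param x a StreamlineSet
#' @return integer
#' @export
setGeneric("nStreamlines", function(x) standardGeneric("nStreamlines"))

#' @rdname nStreamlines
#' @export
setMethod("nStreamlines", "StreamlineSet",
          function(x) length(x@streamlines))

#' Streamline polylines
#' @param x a StreamlineSet
#' @return list of n x 3 matrices (mm)
#' @export
setGeneric("streamlines", function(x) standardGeneric("streamlines"))

#' @rdname streamlines
#' @export
setMethod("streamlines", "StreamlineSet", function(x) x@streamlines)

#' Streamline lengths in mm
#' @param x a StreamlineSet
#' @return numeric vector
#' @export
setGeneric("streamlineLengths",
           function(x) standardGeneric("streamlineLengths"))

#' @rdname streamlineLengths
#' @export
setMethod("streamlineLengths", "StreamlineSet", function(x) x@info$length)

#' @export
setMethod("length", "StreamlineSet", function(x) length(x@streamlines))

#' Voxel size accessor
#' @param x an object with a voxelSize slot
#' @return numeric, mm
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "AcquisitionScheme", function(x) x@voxelSize)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "PeakVolume", function(x) x@voxelSize)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "StreamlineSet", function(x) x@voxelSize)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "TensorMap", function(x) x@voxelSize)

#' b-values and gradient directions
#' @param x an AcquisitionScheme
#' @return numeric vector / 3 x n matrix
#' @export
setGeneric("bvals", function(x) standardGeneric("bvals"))
#' @rdname bvals
#' @export
setMethod("bvals", "AcquisitionScheme", function(x) x@bvals)
#' @rdname bvals
#' @export
setGeneric("bvecs", function(x) standardGeneric("bvecs"))
#' @rdname bvals
#' @export
setMethod("bvecs", "AcquisitionScheme", function(x) x@bvecs)

## ---- show methods ---------------------------------------------------

setMethod("show", "AcquisitionScheme", function(object) {
  tab <- table(object@bvals)
  cat("AcquisitionScheme:",
      paste(sprintf("%s x b=%s", tab, names(tab)), collapse = ", "),
      sprintf("| voxel %.3g mm | grid %s\n", object@voxelSize,
              paste(object@gridDim, collapse = "x")))
})

setMethod("show", "PeakVolume", function(object) {
  cat(sprintf("PeakVolume: grid %s, %d peak(s)/voxel, voxel %.3g mm, %d voxels with amplitude > 0\n",
              paste(object@dim, collapse = "x"), nPeaks(object),
              object@voxelSize,
              sum(apply(object@amplitudes, seq_len(3), max) > 0)))
})

setMethod("show", "StreamlineSet", function(object) {
  n <- nStreamlines(object)
  cat(sprintf("StreamlineSet: %d streamlines", n))
  if (n) cat(sprintf(", length %.1f-%.1f mm (mean %.1f)",
                     min(object@info$length), max(object@info$length),
                     mean(object@info$length)))
  md <- object@metadata
  keep <- intersect(c("subject", "timepoint", "tract", "side"), names(md))
  if (length(keep))
    cat(" [", paste(sprintf("%s=%s", keep, unlist(md[keep])),
                    collapse = ", "), "]", sep = "")
  cat("\n")
})

setMethod("show", "TensorMap", function(object) {
  cat(sprintf("TensorMap: grid %s, %d valid voxels\n",
              paste(object@dim, collapse = "x"), sum(object@valid)))
})

setMethod("show", "TractProfile", function(object) {
  cat(sprintf("TractProfile: %s %s (%s, subject %s)\n", object@tract,
              object@side, object@timepoint, object@subject))
  cat(sprintf("  volume %.0f mm^3 (%.3f%% of WM), length %.1f mm, diameter %.2f mm\n",
              object@volumeMm3, object@volumeNorm, object@lengthMm,
              object@diameterMm))
  cat(sprintf("  FA %.3f, MD %.3g mm^2/s; %d segments (%d empty), %d streamlines\n",
              object@faMean, object@mdMean, length(object@faProfile),
              sum(is.na(object@faProfile)), object@nStreamlines))
})

setMethod("show", "SubjectPair", function(object) {
  cat(sprintf("SubjectPair %s: age %.1f y, sex %s, speechIncrease %s\n",
              object@subjectId, object@age, object@sex,
              object@speechIncrease))
  cat(sprintf("  truth: volumeScale %.3g, mdDelta %.3g mm^2/s in [%.2f, %.2f], snrScale %.3g\n",
              object@truth$volumeScale, object@truth$mdDelta,
              object@truth$mdWindow[1], object@truth$mdWindow[2],
              object@truth$snrScale))
})

#' Tidy one-row data frame of a tract profile
#'
#' @param x a TractProfile
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with scalar metrics; along-tract values are in
#'   [profileTable()].
#' @export
as.data.frame.TractProfile <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  data.frame(subject = x@subject, timepoint = x@timepoint, tract = x@tract,
             side = x@side, nStreamlines = x@nStreamlines,
             volumeMm3 = x@volumeMm3, volumeNorm = x@volumeNorm,
             lengthMm = x@lengthMm, diameterMm = x@diameterMm,
             faMean = x@faMean, mdMean = x@mdMean,
             stringsAsFactors = FALSE)
}

#' Tidy long table of along-tract profiles
#'
#' One row per (metric, segment) of each profile: the substrate for
#' along-tract figures and the per-segment statistics.
#'
#' @param profiles a TractProfile or list of TractProfile objects.
#' @return data.frame with columns subject, timepoint, tract, side,
#'   metric, segment, value, count.
#' @export
profileTable <- function(profiles) {
  if (is(profiles, "TractProfile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    ns <- length(p@faProfile)
    data.frame(subject = p@subject, timepoint = p@timepoint,
               tract = p@tract, side = p@side,
               metric = rep(c("FA", "MD"), each = ns),
               segment = rep(seq_len(ns), 2L),
               value = c(p@faProfile, p@mdProfile),
               count = rep(p@segmentCounts, 2L),
               stringsAsFactors = FALSE)
  }))
}
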