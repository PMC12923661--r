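## Tractometry: macrostructural metrics (voxel-count volume, normalized
## volume, cylinder-equivalent diameter) and microstructural metrics
## (whole-tract FA/MD across streamlines, along-tract profiles over
## equal-arc-length centerline segments).

#' Tract volume from visited voxels
#'
#' Volume = (number of voxels containing at least one streamline vertex)
#' x voxel volume; normalized volume = 100 x volume / supratentorial
#' white-matter volume.
#'
#' @param sset a [StreamlineSet-class] (non-empty).
#' @param wmMask supratentorial white-matter mask (logical array).
#' @return list: `volumeMm3`, `volumeNorm` (percent), `nVoxels`.
#' @export
tractVolume <- function(sset, wmMask) {
  if (!nStreamlines(sset)) stop("empty streamline set")
  nWm <- sum(wmMask)
  if (!nWm) stop("empty white-matter mask")
  vox <- cpp_stack_info(sset@streamlines, sset@dim, sset@voxelSize)$vox
  nv <- cpp_visited_count(vox, prod(sset@dim))
  vs <- sset@voxelSize
  vv <- vs^3
  list(volumeMm3 = nv * vv, volumeNorm = 100 * nv / nWm, nVoxels = nv)
}

#' Cylinder-equivalent tract diameter
#'
#' diameter = 2 * sqrt(volume / (pi * length)), with length the mean
#' streamline length of the tract.
#'
#' @param volumeMm3 tract volume (mm^3), > 0.
#' @param lengthMm mean streamline length (mm), > 0.
#' @return diameter in mm.
#' @export
tractDiameter <- function(volumeMm3, lengthMm) {
  if (volumeMm3 <= 0) stop("volume must be positive")
  if (lengthMm <= 0) stop("length must be positive")
  2 * sqrt(volumeMm3 / (pi * lengthMm))
}

#' Whole-tract scalar statistic across streamlines
#'
#' Samples the scalar map at each vertex (nearest voxel), averages per
#' streamline, then takes the unweighted mean across streamlines, so
#' every streamline contributes equally regardless of vertex count.
#' Streamlines entirely outside the map's validity are excluded and
#' counted.
#'
#' @param sset a [StreamlineSet-class].
#' @param map numeric array (NA outside validity).
#' @return list: `mean`, `perStreamline`, `nExcluded`.
#' @export
wholeTractStat <- function(sset, map) {
  n <- nStreamlines(sset)
  sv <- cpp_stack_info(sset@streamlines, sset@dim, sset@voxelSize)
  v <- sv$vox
  vals <- rep(NA_real_, length(v))
  vals[!is.na(v)] <- map[v[!is.na(v)]]
  ok <- !is.na(vals)
  per <- rep(NA_real_, n)
  if (any(ok)) {
    sums <- rowsum(vals[ok], group = sv$id[ok])
    cnts <- tabulate(sv$id[ok], nbins = n)
    ids <- as.integer(rownames(sums))
    per[ids] <- sums[, 1] / cnts[ids]
  }
  list(mean = mean(per, na.rm = TRUE), perStreamline = per,
       nExcluded = sum(is.na(per)))
}

#' Segment-count rule for along-tract profiling
#'
#' ceiling(mean streamline length / voxel size): e.g. a 138-mm mean
#' length on 2.55-mm voxels gives 55 segments.
#'
#' @param meanLengthMm mean streamline length (mm).
#' @param voxelSize voxel edge (mm).
#' @return integer segment count.
#' @export
nSegmentsRule <- function(meanLengthMm, voxelSize) {
  as.integer(ceiling(meanLengthMm / voxelSize))
}

#' Average tract centerline
#'
#' Each streamline is resampled to `nSegments + 1` points equidistant in
#' arc length; the centerline is the pointwise mean. Streamlines must
#' already share a consistent orientation (from gating), so point 1 sits
#' at the dentate (or Wernicke) end.
#'
#' @param sset a non-empty, consistently oriented [StreamlineSet-class].
#' @param nSegments number of segments (default 55).
#' @return (nSegments + 1) x 3 matrix of mm points.
#' @export
tractCenterline <- function(sset, nSegments = 55L) {
  if (!nStreamlines(sset)) stop("empty streamline set")
  rs <- cpp_resample(sset@streamlines, nSegments + 1L)
  n <- dim(rs)[3]
  matrix(rowMeans(matrix(rs, ncol = n)), ncol = 3)
}

#' Along-tract profile by nearest-segment projection
#'
#' Each streamline vertex is assigned to the nearest centerline segment
#' (Euclidean distance to segment midpoints, ties toward the lower
#' index); the profile is the per-segment mean of the scalar map sampled
#' at the assigned vertices (nearest voxel). Segment 1 is at the dentate
#' (or Wernicke) end. Empty segments are NA-flagged.
#'
#' @param sset a [StreamlineSet-class].
#' @param map numeric array (NA outside validity).
#' @param centerline matrix from [tractCenterline()].
#' @return list: `profile` (per-segment means), `counts` (vertices per
#'   segment), `nSegments`.
#' @export
alongTractProfile <- function(sset, map, centerline) {
  ns <- nrow(centerline) - 1L
  mids <- (centerline[-1, , drop = FALSE] +
           centerline[-nrow(centerline), , drop = FALSE]) / 2
  verts <- do.call(rbind, sset@streamlines)
  seg <- cpp_assign_nearest(verts, mids)
  v <- vertexVoxels(verts, sset@dim, sset@voxelSize)
  vals <- rep(NA_real_, length(v))
  vals[!is.na(v)] <- map[v[!is.na(v)]]
  counts <- tabulate(seg[!is.na(vals)], nbins = ns)
  sums <- rep(0, ns)
  ok <- !is.na(vals)
  if (any(ok)) {
    agg <- rowsum(vals[ok], group = seg[ok])
    sums[as.integer(rownames(agg))] <- agg[, 1]
  }
  prof <- ifelse(counts > 0, sums / counts, NA_real_)
  list(profile = prof, counts = as.integer(counts), nSegments = ns)
}

#' Full tractometry record for one tract at one timepoint
#'
#' Combines [tractVolume()], [tractDiameter()], [wholeTractStat()],
#' [tractCenterline()] and [alongTractProfile()] into a
#' [TractProfile-class]. Returns NULL for an empty streamline set (a
#' failed reconstruction).
#'
#' @param sset gated, oriented [StreamlineSet-class].
#' @param faMap,mdMap scalar maps from [scalarMaps()].
#' @param wmMask supratentorial white-matter mask.
#' @param nSegments along-tract segment count (default 55).
#' @param tract,side,timepoint,subject identifiers (defaults from the
#'   set's metadata).
#' @return a [TractProfile-class] or NULL.
#' @export
tractProfile <- function(sset, faMap, mdMap, wmMask, nSegments = 55L,
                         tract = NULL, side = NULL, timepoint = NULL,
                         subject = NULL, geom = NULL) {
  n <- nStreamlines(sset)
  if (!n) return(NULL)
  md <- sset@metadata
  if (is.null(geom)) geom <- profileGeometry(sset, nSegments)
  sv <- geom$sv; seg <- geom$seg
  nWm <- sum(wmMask)
  if (!nWm) stop("empty white-matter mask")
  ps <- cpp_profile_stats(sv$vox, sv$id, seg, as.numeric(faMap),
                          as.numeric(mdMap), nSegments, n)
  volumeMm3 <- ps$nVisited * sset@voxelSize^3
  volumeNorm <- 100 * ps$nVisited / nWm
  lenMm <- mean(streamlineLengths(sset))
  summarize <- function(segSum, segCnt, lineSum, lineCnt) {
    perLine <- ifelse(lineCnt > 0, lineSum / lineCnt, NA_real_)
    list(profile = ifelse(segCnt > 0, segSum / segCnt, NA_real_),
         counts = as.integer(segCnt),
         mean = mean(perLine, na.rm = TRUE))
  }
  fa <- summarize(ps$segSum1, ps$segCnt1, ps$lineSum1, ps$lineCnt1)
  mdp <- summarize(ps$segSum2, ps$segCnt2, ps$lineSum2, ps$lineCnt2)
  new("TractProfile",
      tract = tract %||% (md$tract %||% "tract"),
      side = side %||% (md$side %||% "unknown"),
      timepoint = timepoint %||% (md$timepoint %||% "unknown"),
      subject = subject %||% (md$subject %||% "unknown"),
      volumeMm3 = volumeMm3, volumeNorm = volumeNorm,
      lengthMm = lenMm,
      diameterMm = tractDiameter(volumeMm3, lenMm),
      faMean = fa$mean, mdMean = mdp$mean,
      faProfile = fa$profile, mdProfile = mdp$profile,
      segmentCounts = fa$counts,
      nStreamlines = n)
}

## geometry shared by all scalar maps of one tract at one timepoint:
## vertex stack + voxel ids, nearest-segment assignment, centerline.
## Depends only on the streamlines, so it can be reused across
## timepoints whose gated streamlines are identical.
profileGeometry <- function(sset, nSegments) {
  sv <- cpp_stack_info(sset@streamlines, sset@dim, sset@voxelSize)
  cl <- tractCenterline(sset, nSegments)
  mids <- (cl[-1, , drop = FALSE] + cl[-nrow(cl), , drop = FALSE]) / 2
  list(sv = sv, seg = cpp_assign_segments(sset@streamlines, mids),
       centerline = cl)
}
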