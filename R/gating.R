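## ROI waypoint gating: AND/NOT mask logic on whole-brain streamlines,
## decussating/non-decussating DRTT classification, and the cohort-level
## normalized-median-length filter for the arcuate fasciculus.

#' Specify a tract gate
#'
#' @param include named list of inclusion (AND) masks; a streamline must
#'   intersect every one.
#' @param exclude named list of exclusion (NOT) masks; touching any
#'   removes the streamline.
#' @param endpointRois optional character(2): names of the two masks in
#'   `include` that anchor the tract ends; kept streamlines are oriented
#'   so vertex 1 is nearest the first one.
#' @return list of class "GateSpec".
#' @export
gateSpec <- function(include, exclude = list(), endpointRois = NULL) {
  if (!length(include)) stop("include must name at least one ROI")
  if (length(intersect(names(include), names(exclude))))
    stop("include and exclude must be disjoint by name")
  structure(list(include = include, exclude = exclude,
                 endpointRois = endpointRois), class = "GateSpec")
}

## a streamline "intersects" an ROI when any vertex's containing voxel
## is in-mask (vertex test; adequate for 1-mm steps on 2.55-mm voxels)
touchesMask <- function(voxelIdx, mask) {
  ok <- !is.na(voxelIdx)
  any(mask[voxelIdx[ok]])
}

#' Apply inclusion/exclusion ROI gates to a streamline set
#'
#' Keeps streamlines whose vertices visit every inclusion mask and no
#' exclusion mask. If `endpointRois` is set, kept streamlines are
#' reversed as needed so that vertex 1 is nearest (to the mask centroid
#' of) the first endpoint ROI. An empty result is returned empty with a
#' `reconstructionFailed` flag in the metadata, mirroring failed tract
#' reconstructions.
#'
#' @param sset a [StreamlineSet-class].
#' @param gate a [gateSpec()].
#' @return the gated [StreamlineSet-class].
#' @export
applyGates <- function(sset, gate) {
  dims <- sset@dim; vs <- sset@voxelSize
  n <- nStreamlines(sset)
  keep <- rep(TRUE, n)
  if (n) {
    sv <- getStackInfo(sset)
    keep <- cpp_gate_keep(sv$vox, sv$id, n,
                          lapply(unname(gate$include), as.logical),
                          lapply(unname(gate$exclude), as.logical))
  }
  out <- subsetStreamlines(sset, keep)
  if (!is.null(gate$endpointRois) && nStreamlines(out)) {
    anchor <- gate$include[[gate$endpointRois[1]]]
    ctr <- maskCentroid(anchor, vs)
    slot(out, "streamlines", check = FALSE) <-
      cpp_orient_toward(out@streamlines, ctr)
  }
  out@metadata$reconstructionFailed <- nStreamlines(out) == 0L
  out
}

maskCentroid <- function(mask, vs) {
  ijk <- which(mask, arr.ind = TRUE)
  (colMeans(ijk) - 0.5) * vs
}

#' Classify DRTT streamlines as decussating or non-decussating
#'
#' The decussating DRTT (d-DRTT) crosses the midline in the brainstem
#' and connects the dentate nucleus with the contralateral motor cortex;
#' the non-decussating DRTT (nd-DRTT) connects to the ipsilateral motor
#' cortex. Streamlines must already be dentate- and motor-gated and
#' oriented dentate-first; the classification looks at the motor-end
#' (last) vertex. The side label is the hemisphere of the dentate
#' nucleus.
#'
#' @param sset dentate-oriented [StreamlineSet-class].
#' @param dentateSide "left" or "right".
#' @param motorMasks named list with elements `left` and `right` (motor
#'   cortex masks).
#' @return list of StreamlineSets: `d_DRTT`, `nd_DRTT`, `unclassified`.
#' @export
classifyDRTT <- function(sset, dentateSide, motorMasks) {
  dentateSide <- match.arg(dentateSide, c("left", "right"))
  contra <- setdiff(c("left", "right"), dentateSide)
  ends <- cpp_end_voxels(sset@streamlines, sset@dim, sset@voxelSize)
  lab <- rep("unclassified", nStreamlines(sset))
  ok <- !is.na(ends)
  lab[ok][motorMasks[[dentateSide]][ends[ok]]] <- "nd_DRTT"
  lab[ok][motorMasks[[contra]][ends[ok]]] <- "d_DRTT"
  out <- lapply(c(d_DRTT = "d_DRTT", nd_DRTT = "nd_DRTT",
                  unclassified = "unclassified"), function(cl) {
    s <- subsetStreamlines(sset, lab == cl)
    s@metadata$tract <- cl
    s@metadata$side <- dentateSide
    s
  })
  out
}

#' Cohort-level length filter for the arcuate fasciculus
#'
#' For each subject the median AF streamline length is normalized by the
#' subject's brain height (feet-head extent of the brain mask). The
#' cohort threshold is the first percentile of these normalized medians
#' (linear interpolation between order statistics); within each subject,
#' streamlines whose own normalized length falls below the threshold are
#' removed — the mechanism that strips short spurious streamlines.
#'
#' @param afSets list of per-subject [StreamlineSet-class] objects.
#' @param brainHeightsMm numeric vector of per-subject brain heights
#'   (mm); see [brainHeight()].
#' @param percentile threshold percentile of the normalized-median
#'   distribution (default 1).
#' @return list: `sets` (filtered sets), `threshold`, `normalizedMedians`,
#'   `nRemoved` per subject.
#' @export
filterAF <- function(afSets, brainHeightsMm, percentile = 1) {
  stopifnot(length(afSets) == length(brainHeightsMm))
  if (any(brainHeightsMm <= 0)) stop("brain height must be positive")
  med <- vapply(seq_along(afSets), function(i) {
    len <- streamlineLengths(afSets[[i]])
    if (!length(len)) NA_real_ else median(len) / brainHeightsMm[i]
  }, numeric(1))
  if (sum(!is.na(med)) < 2L) {
    warning("fewer than 2 subjects with AF streamlines; filter skipped")
    return(list(sets = afSets, threshold = NA_real_,
                normalizedMedians = med,
                nRemoved = integer(length(afSets))))
  }
  thr <- unname(quantile(med, percentile / 100, na.rm = TRUE, type = 7))
  nRemoved <- integer(length(afSets))
  sets <- lapply(seq_along(afSets), function(i) {
    s <- afSets[[i]]
    keep <- streamlineLengths(s) / brainHeightsMm[i] >= thr
    nRemoved[i] <<- sum(!keep)
    subsetStreamlines(s, keep)
  })
  list(sets = sets, threshold = thr, normalizedMedians = med,
       nRemoved = nRemoved)
}

#' Brain height in the feet-head direction
#'
#' Extent of the brain mask along z in mm (a proxy of brain size used to
#' normalize streamline lengths).
#'
#' @param brainMask logical array.
#' @param voxelSize voxel edge (mm).
#' @return numeric (mm).
#' @export
brainHeight <- function(brainMask, voxelSize) {
  k <- which(apply(brainMask, 3, any))
  if (!length(k)) stop("empty brain mask")
  (max(k) - min(k) + 1L) * voxelSize
}
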