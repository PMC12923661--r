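## Simulation studies over synthetic cohorts: power of the paired
## volume-change detection under injected compression, localization of
## the injected MD elevation in the along-tract profile, and type-I
## calibration of the per-segment battery under the null.

#' Tracking parameters used by the simulation studies
#'
#' Identical to [trackingParams()] except for a 15-mm minimum streamline
#' length. Every gated tract in the phantom must span both of its
#' endpoint ROIs and is therefore at least ~25 mm long, so pruning
#' below 15 mm cannot change any tract metric; it only discards the
#' short fragments produced by seeds near the field-support wall, which
#' dominate the computational cost of large replicate studies.
#'
#' @return a [trackingParams()] object.
#' @export
studyTrackingParams <- function() trackingParams(minLengthMm = 15)

#' Phantom configuration with the injected surgical effect
#'
#' The "alteration" condition: bundle-radius scale 0.7 on the left
#' d-DRTT, a localized MD elevation (mean 0.3e-3, SD 0.2e-3 mm^2/s
#' across subjects) over the first quarter of arc length from the
#' dentate end, and an SNR scale of 0.906. The "null" condition injects
#' nothing (pre and intra differ only by noise realization).
#'
#' @param condition "alteration" or "null".
#' @param bundles bundles to generate (default left d-DRTT plus the
#'   left AF control tract).
#' @param ... further arguments to [phantomConfig()].
#' @return a [phantomConfig()].
#' @export
studyConfig <- function(condition = c("alteration", "null"),
                        bundles = c("d_DRTT_left", "AF_left"), ...) {
  condition <- match.arg(condition)
  eff <- if (condition == "alteration")
    list(volumeScale = 0.7, mdDeltaMean = 0.3e-3, mdDeltaSd = 0.2e-3,
         mdWindow = c(0, 0.25), snrScale = 0.906,
         appliesTo = "d_DRTT_left")
  else
    list(volumeScale = 1, mdDeltaMean = 0, mdDeltaSd = 0,
         mdWindow = c(0, 0.25), snrScale = 1, appliesTo = "d_DRTT_left")
  phantomConfig(bundles = bundles, effect = eff, ...)
}

#' Detection rate of an injected paired volume decrease
#'
#' Repeatedly simulates cohorts with the injected compression and runs
#' the paired analysis of normalized tract volume on the affected tract;
#' a replicate counts as detected when the mixed-model timepoint effect
#' is negative with p < 0.05.
#'
#' @param nReplicates number of cohort replicates.
#' @param nSubjects subjects per cohort.
#' @param seed master seed.
#' @param cfg phantom configuration (default: the alteration condition,
#'   affected tract only).
#' @param tract,side tract evaluated.
#' @return list: `rate` (fraction detected), `pLmm`, `pWilcoxon`,
#'   `meanPercentChange` per replicate.
#' @export
volumeDetectionStudy <- function(nReplicates = 100L, nSubjects = 30L,
                                 seed = 1L,
                                 cfg = studyConfig("alteration",
                                                   bundles = "d_DRTT_left"),
                                 tract = "d_DRTT", side = "left") {
  pL <- pW <- pc <- numeric(nReplicates)
  params <- studyTrackingParams()
  for (r in seq_len(nReplicates)) {
    co <- simulateCohort(cfg, nSubjects, seed + 7919L * r,
                         params = params, micro = FALSE)
    bat <- runStatsBattery(co, parts = "paired", metrics = "volumeNorm")
    row <- bat$paired[bat$paired$tract == tract &
                      bat$paired$side == side &
                      bat$paired$metric == "volumeNorm", ]
    pL[r] <- row$pLmm; pW[r] <- row$pWilcoxon; pc[r] <- row$percentChange
    detected <- row$estimate < 0 & row$pLmm < 0.05
    if (r == 1L && !isTRUE(detected))
      message("replicate 1 not detected (p = ", signif(row$pLmm, 3), ")")
  }
  est <- pL < 0.05 & pc < 0
  list(rate = mean(est), pLmm = pL, pWilcoxon = pW,
       meanPercentChange = mean(pc))
}

#' Localization of the injected MD elevation along the tract
#'
#' On a simulated cohort with the MD elevation injected in a known
#' arc-length window at the dentate end, computes the across-subject
#' variance of the paired MD change per along-tract segment and
#' compares the injected window (+/- 1 segment) with the remaining
#' segments.
#'
#' @param cohort a [simulateCohort()] result under the alteration
#'   condition (micro = TRUE).
#' @param mdWindow arc-length fraction window that was injected.
#' @param tract,side affected tract.
#' @param pad segments of slack around the window (default 1).
#' @return list: `ratio` (mean in-window variance / mean out-of-window
#'   variance), `windowSegments`, `variance` per segment,
#'   `outsideElevated` (segments outside window+pad whose variance
#'   exceeds the in-window mean).
#' @export
mdWindowVarianceRatio <- function(cohort, mdWindow = c(0, 0.25),
                                  tract = "d_DRTT", side = "left",
                                  pad = 1L) {
  dm <- deltaProfileMatrix(cohort$profiles, tract, side, "MD")
  v <- apply(dm, 2, var, na.rm = TRUE)
  ns <- length(v)
  centers <- (seq_len(ns) - 0.5) / ns
  win <- which(centers >= mdWindow[1] & centers <= mdWindow[2])
  winPad <- seq.int(max(1L, min(win) - pad), min(ns, max(win) + pad))
  rest <- setdiff(seq_len(ns), winPad)
  ratio <- mean(v[win], na.rm = TRUE) / mean(v[rest], na.rm = TRUE)
  list(ratio = ratio, windowSegments = win, variance = v,
       outsideElevated = sum(v[rest] > mean(v[win], na.rm = TRUE),
                             na.rm = TRUE))
}

#' Type-I calibration of the per-segment battery under the null
#'
#' Simulates cohorts with no injected effect and counts, per tract and
#' metric panel, replicates in which any segment is BH-significant at
#' 0.05. Under the null this any-significant rate should not exceed
#' 0.05 (plus Monte-Carlo error).
#'
#' @param nReplicates cohort replicates.
#' @param nSubjects subjects per cohort.
#' @param seed master seed.
#' @param cfg phantom configuration (default: null condition, affected
#'   tract only — the calibration property is per panel, and the
#'   distant-control contrast belongs to the alteration study).
#' @param alpha significance level.
#' @return list: `rate` (fraction of panels with any BH-significant
#'   segment), `nPanels`, `mcSE` (binomial Monte-Carlo SE at `alpha`),
#'   `perPanel` data.frame.
#' @export
nullCalibrationStudy <- function(nReplicates = 200L, nSubjects = 20L,
                                 seed = 1L,
                                 cfg = studyConfig("null",
                                                   bundles = "d_DRTT_left",
                                                   simulateRegion =
                                                     "tracts"),
                                 alpha = 0.05) {
  rows <- list()
  params <- studyTrackingParams()
  for (r in seq_len(nReplicates)) {
    co <- simulateCohort(cfg, nSubjects, seed + 104729L * r,
                         params = params, micro = TRUE)
    bat <- runStatsBattery(co, parts = "segments")
    seg <- bat$segments
    for (tr in unique(seg$tract)) for (sd_ in unique(seg$side))
      for (m in unique(seg$metric)) {
        s <- seg[seg$tract == tr & seg$side == sd_ & seg$metric == m, ]
        if (!nrow(s)) next
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, tract = tr, side = sd_, metric = m,
          anySignificant = any(s$pFdr < alpha, na.rm = TRUE))
      }
  }
  per <- do.call(rbind, rows)
  nP <- nrow(per)
  list(rate = mean(per$anySignificant), nPanels = nP,
       mcSE = sqrt(alpha * (1 - alpha) / nP), perPanel = per)
}

#' Geometry recovery checks for the tracker and diameter metric
#'
#' Builds a straight cylindrical bundle and a 40-mm-radius
#' quarter-circle bundle, tracks them with the default FACT parameters,
#' and compares (a) the cylinder-equivalent diameter against the true
#' tube diameter and (b) the mean streamline arc length against the
#' analytic quarter-circle length pi * r / 2.
#'
#' @param radiusMm tube radius for the cylinder check; about two voxel
#'   edges, so that the voxelized cross-section is a fair sample of the
#'   disc (much thinner tubes degenerate to a single voxel column).
#' @param arcRadiusMm quarter-circle radius.
#' @param voxelSize voxel edge (mm).
#' @return list: `diameterErrorPct`, `arcLengthErrorPct`, plus the
#'   measured values.
#' @export
geometryRecoveryStudy <- function(radiusMm = 5, arcRadiusMm = 40,
                                  voxelSize = 2.55) {
  params <- trackingParams()
  ## straight cylinder along z
  dims <- c(16L, 16L, 40L)
  ext <- dims * voxelSize
  cp <- cbind(ext[1] / 2, ext[2] / 2,
              seq(3 * voxelSize, ext[3] - 3 * voxelSize, length.out = 5))
  spec <- bundleSpec("nd_DRTT", "left", cp, radiusMm,
                     endpointRois = c("a", "b"))
  scheme <- acquisitionScheme(dims, voxelSize)
  f <- makeBundleField(spec, scheme)
  wm <- array(TRUE, dims)
  seeds <- seedGrid(f$mask, voxelSize, params$seedSpacingMm)
  ss <- trackFibers(f$peaks, wm, seeds, params)
  vol <- tractVolume(ss, f$mask)
  dia <- tractDiameter(vol$volumeMm3, mean(streamlineLengths(ss)))
  diaErr <- 100 * (dia - 2 * radiusMm) / (2 * radiusMm)
  ## quarter circle of radius arcRadiusMm in the x-z plane
  dims2 <- as.integer(ceiling(c(arcRadiusMm + 10 * voxelSize,
                                8 * voxelSize,
                                arcRadiusMm + 10 * voxelSize) /
                              voxelSize))
  ext2 <- dims2 * voxelSize
  th <- seq(0, pi / 2, length.out = 9)
  ctr <- c(4 * voxelSize, ext2[2] / 2, 4 * voxelSize)
  cp2 <- cbind(ctr[1] + arcRadiusMm * cos(th), ctr[2],
               ctr[3] + arcRadiusMm * sin(th))
  spec2 <- bundleSpec("nd_DRTT", "left", cp2, radiusMm = 2.5,
                      endpointRois = c("a", "b"))
  scheme2 <- acquisitionScheme(dims2, voxelSize)
  f2 <- makeBundleField(spec2, scheme2)
  wm2 <- array(TRUE, dims2)
  ## seed on the spine at the arc midpoint so the track covers the arc
  mid <- cp2[5, , drop = FALSE]
  ss2 <- trackFibers(f2$peaks, wm2, mid, params)
  if (!nStreamlines(ss2)) stop("quarter-circle bundle not traversed")
  ## traversed arc = streamline portion between the vertices closest to
  ## the two arc endpoints (clips the overshoot into the tube end caps)
  m <- streamlines(ss2)[[1]]
  j1 <- which.min(rowSums(sweep(m, 2, cp2[1, ])^2))
  j2 <- which.min(rowSums(sweep(m, 2, cp2[nrow(cp2), ])^2))
  arcLen <- abs(j2 - j1) * params$stepMm
  arcTrue <- pi * arcRadiusMm / 2
  arcErr <- 100 * (arcLen - arcTrue) / arcTrue
  list(diameterErrorPct = diaErr, measuredDiameterMm = dia,
       arcLengthErrorPct = arcErr, measuredArcLengthMm = arcLen,
       analyticArcLengthMm = arcTrue)
}
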