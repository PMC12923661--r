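## Pipeline driver: phantom -> tracking -> gating -> tractometry ->
## statistics, plus cohort-level assembly used by the simulation studies.

maskOr <- function(masks, names, dims) {
  present <- intersect(names, names(masks))
  if (!length(present)) return(array(FALSE, dims))
  Reduce(`|`, masks[present])
}

## Track and gate one timepoint of one subject; returns named
## StreamlineSets for the tracts implied by cfg$bundles, plus maps/SNR.
processTimepoint <- function(ds, cfg, params, subject, timepoint,
                             micro = TRUE, reuse = NULL,
                             reuseGating = FALSE) {
  dims <- cfg$gridDim
  masks <- ds$masks
  maps <- list(fa = NULL, md = NULL)
  snr <- NULL
  if (micro && !is.null(ds$dwi)) {
    tmap <- fitTensor(ds$dwi, ds$scheme)
    maps <- scalarMaps(tmap)
    snr <- wmSNR(ds$dwi, masks$white_matter)$snr
  }
  ## seeding: voxels whose peak amplitude clears the FACT floor, within
  ## WM — equivalent to whole-brain seeding here because background
  ## amplitude is exactly 0 (every outside seed is dropped at length 0)
  if (!is.null(reuse)) {
    ## tracking depends only on the peak field and the WM mask; when
    ## those are bit-identical to a previous timepoint, its whole-brain
    ## streamlines are reused verbatim (gating is still rerun)
    wb <- reuse$wholeBrain
    wb@metadata$subject <- subject
    wb@metadata$timepoint <- timepoint
  } else {
    K <- nPeaks(ds$peaks)
    ampArr <- matrix(ds$peaks@amplitudes, prod(dims))
    ampMax <- ampArr[, 1]
    if (K > 1L) for (k in 2L:K) ampMax <- pmax(ampMax, ampArr[, k])
    ampMax <- array(ampMax, dims)
    seedMask <- masks$white_matter & (ampMax >= params$ampFloor)
    seeds <- seedGrid(seedMask, cfg$voxelSize, params$seedSpacingMm)
    wb <- trackFibers(ds$peaks, masks$white_matter, seeds, params,
                      metadata = list(subject = subject,
                                      timepoint = timepoint))
  }
  if (reuseGating && !is.null(reuse)) {
    ## gate masks are identical and the pre tumor touched no streamline,
    ## so the gated tracts are identical too; only relabel them
    out <- lapply(reuse$tracts, function(s) {
      s@metadata$subject <- subject
      s@metadata$timepoint <- timepoint
      s
    })
    return(list(tracts = out, maps = maps, snr = snr,
                brainHeight = brainHeight(masks$brain, cfg$voxelSize),
                wholeBrainCount = nStreamlines(wb), wholeBrain = wb,
                tumorTouched = 0L))
  }
  sv <- getStackInfo(wb)
  tumorTouched <- cpp_mask_touch_count(sv$vox, sv$id, nStreamlines(wb),
                                       as.logical(masks$tumor))
  out <- list()
  sides <- c(left = "l", right = "r")
  for (side in names(sides)) {
    s1 <- sides[[side]]
    drttHere <- intersect(paste0(c("d_DRTT_", "nd_DRTT_"), side),
                          cfg$bundles)
    if (length(drttHere)) {
      dent <- paste0("dentate_", s1)
      inc <- list(masks[[dent]],
                  maskOr(masks, c("thalamus_l", "thalamus_r"), dims),
                  maskOr(masks, c("motor_cortex_l", "motor_cortex_r"),
                         dims))
      names(inc) <- c(dent, "thalamus", "motor_cortex")
      gate <- gateSpec(inc,
                       exclude = list(corpus_callosum =
                                        masks$corpus_callosum,
                                      tumor = masks$tumor),
                       endpointRois = c(dent, "motor_cortex"))
      gated <- applyGates(wb, gate)
      cls <- classifyDRTT(gated, side,
                          list(left = maskOr(masks, "motor_cortex_l",
                                             dims),
                               right = maskOr(masks, "motor_cortex_r",
                                              dims)))
      for (tr in c("d_DRTT", "nd_DRTT"))
        if (paste0(tr, "_", side) %in% cfg$bundles) {
          s <- cls[[tr]]
          s@metadata$subject <- subject
          s@metadata$timepoint <- timepoint
          out[[paste0(tr, "_", side)]] <- s
        }
    }
    if (paste0("AF_", side) %in% cfg$bundles) {
      wer <- paste0("wernicke_", s1); bro <- paste0("broca_", s1)
      inc <- setNames(list(masks[[wer]], masks[[bro]]), c(wer, bro))
      gate <- gateSpec(inc,
                       exclude = list(corpus_callosum =
                                        masks$corpus_callosum,
                                      tumor = masks$tumor),
                       endpointRois = c(wer, bro))
      s <- applyGates(wb, gate)
      s@metadata$tract <- "AF"; s@metadata$side <- side
      s@metadata$subject <- subject
      s@metadata$timepoint <- timepoint
      out[[paste0("AF_", side)]] <- s
    }
  }
  list(tracts = out, maps = maps, snr = snr,
       brainHeight = brainHeight(masks$brain, cfg$voxelSize),
       wholeBrainCount = nStreamlines(wb), wholeBrain = wb,
       tumorTouched = tumorTouched)
}

sameTrackingInputs <- function(a, b) {
  identical(a$peaks@directions, b$peaks@directions) &&
    identical(a$peaks@amplitudes, b$peaks@amplitudes) &&
    identical(a$masks$white_matter, b$masks$white_matter)
}

## gated tracts carry over from pre to intra when, additionally, every
## gate mask other than the (resected) tumor is identical and the pre
## tumor intersected no whole-brain streamline
sameGatingInputs <- function(a, b, resPre) {
  nm <- setdiff(names(a$masks), c("tumor", "brain"))
  identical(a$masks[nm], b$masks[nm]) &&
    !any(b$masks$tumor) && identical(resPre$tumorTouched, 0L)
}

emptyMap <- function(dims) array(NA_real_, dims)

## TractProfile allowing macro-only mode (no scalar maps)
buildProfile <- function(sset, maps, wmMask, nSegments, micro,
                         geom = NULL) {
  if (!nStreamlines(sset)) return(NULL)
  if (micro)
    return(tractProfile(sset, maps$fa, maps$md, wmMask,
                        nSegments = nSegments, geom = geom))
  vol <- tractVolume(sset, wmMask)
  lenMm <- mean(streamlineLengths(sset))
  md <- sset@metadata
  new("TractProfile", tract = md$tract %||% "tract",
      side = md$side %||% "unknown",
      timepoint = md$timepoint %||% "unknown",
      subject = md$subject %||% "unknown",
      volumeMm3 = vol$volumeMm3, volumeNorm = vol$volumeNorm,
      lengthMm = lenMm,
      diameterMm = tractDiameter(vol$volumeMm3, lenMm),
      faMean = NA_real_, mdMean = NA_real_,
      faProfile = rep(NA_real_, nSegments),
      mdProfile = rep(NA_real_, nSegments),
      segmentCounts = integer(nSegments),
      nStreamlines = nStreamlines(sset))
}

#' Simulate and analyze a synthetic cohort
#'
#' Generates `n` paired subjects from the phantom configuration and runs
#' the full tractometry pipeline on each: tracking, gating (including
#' the cohort-level AF length filter), tensor fitting, and per-tract
#' macro/micro metrics.
#'
#' @param cfg a [phantomConfig()].
#' @param n number of subjects.
#' @param seed integer master seed; per-subject seeds are derived by a
#'   fixed modular mixing so they stay within R's integer range.
#' @param params a [trackingParams()].
#' @param nSegments along-tract segment count (default 55).
#' @param micro logical; FALSE skips DWI simulation/fitting and yields
#'   macrostructural metrics only (much faster).
#' @return list: `metrics` (tidy per-subject scalar metrics), `profiles`
#'   (long along-tract table), `subjects` (demographics, SNR, structural
#'   volumes, labels, ground truth), `status` (per subject/timepoint/
#'   tract reconstruction record), `afFilter` (threshold record).
#' @export
simulateCohort <- function(cfg, n, seed, params = trackingParams(),
                           nSegments = 55L, micro = TRUE) {
  subjRows <- list(); profRows <- list(); metricRows <- list()
  statusRows <- list()
  afStore <- list(pre = list(), intra = list())
  afAux <- list(pre = list(), intra = list())
  heights <- list(pre = numeric(n), intra = numeric(n))
  for (i in seq_len(n)) {
    subjSeed <- as.integer((as.numeric(seed) * 1000003 + i) %% 2147483629)
    pair <- makeSubjectPair(cfg, subjSeed, simulate = micro)
    sid <- pair@subjectId
    vols <- list()
    resPre <- NULL
    geomCache <- list()
    for (tp in c("pre", "intra")) {
      ds <- slot(pair, tp)
      reuse <- if (tp == "intra" &&
                   sameTrackingInputs(pair@pre, pair@intra))
        resPre else NULL
      res <- processTimepoint(ds, cfg, params, sid, tp, micro = micro,
                              reuse = reuse,
                              reuseGating = !is.null(reuse) &&
                                sameGatingInputs(pair@pre, pair@intra,
                                                 resPre))
      if (tp == "pre") resPre <- res
      heights[[tp]][i] <- res$brainHeight
      for (key in names(res$tracts)) {
        statusRows[[length(statusRows) + 1L]] <- data.frame(
          subject = sid, timepoint = tp, tract = key,
          nStreamlines = nStreamlines(res$tracts[[key]]),
          reconstructed = nStreamlines(res$tracts[[key]]) > 0L,
          stringsAsFactors = FALSE)
        if (grepl("^AF_", key)) {
          afStore[[tp]][[sid]] <- res$tracts[[key]]
          afAux[[tp]][[sid]] <- list(maps = res$maps,
                                     wm = ds$masks$white_matter)
          next  # AF metrics computed after the cohort length filter
        }
        sset <- res$tracts[[key]]
        g <- NULL
        if (micro && nStreamlines(sset)) {
          if (tp == "pre") {
            g <- profileGeometry(sset, nSegments)
            geomCache[[key]] <- list(streams = sset@streamlines,
                                     geom = g)
          } else if (!is.null(geomCache[[key]]) &&
                     identical(geomCache[[key]]$streams,
                               sset@streamlines)) {
            g <- geomCache[[key]]$geom
          }
        }
        p <- buildProfile(sset, res$maps, ds$masks$white_matter,
                          nSegments, micro, geom = g)
        if (!is.null(p)) {
          metricRows[[length(metricRows) + 1L]] <- as.data.frame(p)
          if (micro) profRows[[length(profRows) + 1L]] <- profileTable(p)
        }
      }
      vols[[tp]] <- list(
        snr = res$snr,
        ventricle = sum(ds$masks$ventricles) /
          sum(ds$masks$white_matter | ds$masks$gray_matter |
              ds$masks$ventricles) * 100,
        tumor = sum(ds$masks$tumor) * cfg$voxelSize^3)
    }
    subjRows[[i]] <- data.frame(
      subject = sid, age = pair@age, sex = pair@sex,
      speechIncrease = pair@speechIncrease,
      snrPre = vols$pre$snr %||% NA_real_,
      snrIntra = vols$intra$snr %||% NA_real_,
      ventriclePre = vols$pre$ventricle,
      ventricleIntra = vols$intra$ventricle,
      tumorPreMm3 = vols$pre$tumor,
      truthVolumeScale = pair@truth$volumeScale,
      truthMdDelta = pair@truth$mdDelta,
      truthSnrScale = pair@truth$snrScale,
      stringsAsFactors = FALSE)
  }
  ## cohort-level AF length filter, then AF metrics
  afFilter <- NULL
  afGeom <- list()
  for (tp in c("pre", "intra")) {
    sets <- afStore[[tp]]
    if (!length(sets)) next
    flt <- filterAF(unname(sets), heights[[tp]][seq_along(sets)])
    if (tp == "pre") afFilter <- flt[c("threshold", "normalizedMedians")]
    for (j in seq_along(sets)) {
      sid <- names(sets)[j]
      aux <- afAux[[tp]][[sid]]
      s <- flt$sets[[j]]
      g <- NULL
      if (micro && nStreamlines(s)) {
        if (tp == "pre") {
          g <- profileGeometry(s, nSegments)
          afGeom[[sid]] <- list(streams = s@streamlines, geom = g)
        } else if (!is.null(afGeom[[sid]]) &&
                   identical(afGeom[[sid]]$streams, s@streamlines)) {
          g <- afGeom[[sid]]$geom
        }
      }
      p <- buildProfile(s, aux$maps, aux$wm, nSegments, micro,
                        geom = g)
      if (!is.null(p)) {
        metricRows[[length(metricRows) + 1L]] <- as.data.frame(p)
        if (micro) profRows[[length(profRows) + 1L]] <- profileTable(p)
      }
    }
  }
  list(metrics = do.call(rbind, metricRows),
       profiles = if (length(profRows)) do.call(rbind, profRows) else
         NULL,
       subjects = do.call(rbind, subjRows),
       status = do.call(rbind, statusRows),
       afFilter = afFilter)
}

#' Paired change matrix of an along-tract metric
#'
#' @param profiles long profile table from [simulateCohort()].
#' @param tract,side,metric selectors.
#' @return subjects x segments matrix of intra - pre values.
#' @export
deltaProfileMatrix <- function(profiles, tract, side, metric) {
  sel <- profiles$tract == tract & profiles$side == side &
    profiles$metric == metric
  p <- profiles[sel, , drop = FALSE]
  subj <- sort(unique(p$subject))
  ns <- max(p$segment)
  get <- function(tp) {
    m <- matrix(NA_real_, length(subj), ns,
                dimnames = list(subj, NULL))
    q <- p[p$timepoint == tp, ]
    m[cbind(match(q$subject, subj), q$segment)] <- q$value
    m
  }
  get("intra") - get("pre")
}

#' Run the full statistical battery on a simulated cohort
#'
#' Per tract and side: paired Wilcoxon, linear mixed-effects timepoint
#' p (unadjusted and adjusted for age and for SNR), Cohen's d and
#' percent change for volume, diameter and whole-tract FA/MD; segment
#' z-tests (BH-corrected within each metric x tract x side family);
#' rank-sum group contrasts of changes by speech label; logistic
#' regression of the label on age and sex; Pearson correlation of
#' volume change against ventricular volume.
#'
#' @param cohort result of [simulateCohort()].
#' @param parts which analyses to run (default all): any of "paired",
#'   "segments", "groups", "logistic", "correlations".
#' @return list of data.frames: `paired`, `segments`, `groups`,
#'   `logistic`, `correlations`.
#' @export
runStatsBattery <- function(cohort,
                            parts = c("paired", "segments", "groups",
                                      "logistic", "correlations"),
                            metrics = c("volumeNorm", "diameterMm",
                                        "faMean", "mdMean")) {
  parts <- match.arg(parts, several.ok = TRUE)
  metrics <- match.arg(metrics, several.ok = TRUE)
  met <- cohort$metrics; sub <- cohort$subjects
  combos <- unique(met[, c("tract", "side")])
  pairedRows <- list(); segRows <- list(); groupRows <- list()
  corRows <- list()
  for (r in seq_len(nrow(combos))) {
    tr <- combos$tract[r]; sd_ <- combos$side[r]
    m <- met[met$tract == tr & met$side == sd_, ]
    wide <- merge(m[m$timepoint == "pre", ],
                  m[m$timepoint == "intra", ],
                  by = "subject", suffixes = c(".pre", ".intra"))
    wide <- merge(wide, sub, by = "subject")
    metricsNeeded <- if (any(c("paired", "groups", "correlations") %in%
                              parts)) metrics else character()
    for (metric in metricsNeeded) {
      pre <- wide[[paste0(metric, ".pre")]]
      intra <- wide[[paste0(metric, ".intra")]]
      if (all(is.na(pre)) || sum(!is.na(pre - intra)) < 3) next
      ok <- !is.na(pre) & !is.na(intra)
      lab <- wide$speechIncrease[ok]
      dvals <- intra[ok] - pre[ok]
      if ("paired" %in% parts) {
        long <- data.frame(y = c(pre[ok], intra[ok]),
                           tp = rep(c("pre", "intra"), each = sum(ok)),
                           subj = rep(wide$subject[ok], 2),
                           age = rep(wide$age[ok], 2),
                           snr = c(wide$snrPre[ok], wide$snrIntra[ok]))
        lmm <- pairedLMM(long$y, long$tp, long$subj)
        lmmAge <- pairedLMM(long$y, long$tp, long$subj, long$age)
        lmmSnr <- if (all(is.na(long$snr))) list(p = NA_real_) else
          pairedLMM(long$y, long$tp, long$subj, long$snr)
        wsr <- if (all(intra[ok] == pre[ok])) list(p = NA_real_) else
          wilcoxonSignedRank(pre[ok], intra[ok])
        cd <- cohensD(pre[ok], intra[ok])
        pairedRows[[length(pairedRows) + 1L]] <- data.frame(
          tract = tr, side = sd_, metric = metric, n = sum(ok),
          percentChange = percentChange(mean(pre[ok]), mean(intra[ok])),
          pWilcoxon = wsr$p, pLmm = lmm$p, pLmmAge = lmmAge$p,
          pLmmSnr = lmmSnr$p, estimate = lmm$estimate, d = cd$d,
          band = cd$band, stringsAsFactors = FALSE)
      }
      ## group contrast of paired change by speech label
      if ("groups" %in% parts && metric %in% c("faMean", "mdMean") &&
          length(unique(lab[!is.na(lab)])) == 2L) {
        rs <- wilcoxonRankSum(dvals[lab %in% TRUE], dvals[lab %in% FALSE])
        groupRows[[length(groupRows) + 1L]] <- data.frame(
          tract = tr, side = sd_, metric = metric,
          nIncrease = sum(lab %in% TRUE), nStable = sum(lab %in% FALSE),
          p = rs$p, stringsAsFactors = FALSE)
      }
      if ("correlations" %in% parts &&
          metric %in% c("volumeNorm", "diameterMm") &&
          sum(ok) >= 5 && sd(dvals) > 0) {
        ct <- changeCorrelation(dvals, wide$ventriclePre[ok])
        corRows[[length(corRows) + 1L]] <- data.frame(
          tract = tr, side = sd_, metric = metric, against = "ventricle",
          r = ct$r, p = ct$p, n = ct$n, stringsAsFactors = FALSE)
      }
    }
    if ("segments" %in% parts && !is.null(cohort$profiles)) {
      for (metric in c("FA", "MD")) {
        dm <- deltaProfileMatrix(cohort$profiles, tr, sd_, metric)
        if (is.null(dm) || !nrow(dm)) next
        zt <- segmentZTest(dm)
        zt$tract <- tr; zt$side <- sd_; zt$metric <- metric
        segRows[[length(segRows) + 1L]] <- zt
      }
    }
  }
  logistic <- if ("logistic" %in% parts) tryCatch(
    logisticOutcome(sub$age, sub$sex, sub$speechIncrease),
    error = function(e) NULL) else NULL
  list(paired = do.call(rbind, pairedRows),
       segments = if (length(segRows)) do.call(rbind, segRows) else NULL,
       groups = if (length(groupRows)) do.call(rbind, groupRows) else
         NULL,
       logistic = logistic,
       correlations = if (length(corRows)) do.call(rbind, corRows) else
         NULL)
}

#' Run the end-to-end pipeline and write an artifact tree
#'
#' Generates a cohort, runs tracking/gating/tractometry/statistics, and
#' writes `phantom/` (NIfTI masks, FA/MD maps, bval/bvec, truth files),
#' `tracts/` (TCK per tract), `metrics.csv`, `profiles.csv` and `stats/`
#' under `outDir`. Reruns with the same config and seed produce
#' identical tables.
#'
#' @param cfg a [phantomConfig()].
#' @param n number of subjects.
#' @param seed master seed.
#' @param outDir output directory.
#' @param params a [trackingParams()].
#' @param nSegments along-tract segments.
#' @return invisible list with the cohort and battery results.
#' @export
runPipeline <- function(cfg, n, seed, outDir, params = trackingParams(),
                        nSegments = 55L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "phantom"), showWarnings = FALSE)
  dir.create(file.path(outDir, "tracts"), showWarnings = FALSE)
  dir.create(file.path(outDir, "stats"), showWarnings = FALSE)
  cohort <- simulateCohort(cfg, n, seed, params, nSegments)
  write.csv(cohort$metrics, file.path(outDir, "metrics.csv"),
            row.names = FALSE)
  write.csv(cohort$profiles, file.path(outDir, "profiles.csv"),
            row.names = FALSE)
  write.csv(cohort$subjects, file.path(outDir, "subjects.csv"),
            row.names = FALSE)
  write.csv(cohort$status,
            file.path(outDir, "reconstruction_status.csv"),
            row.names = FALSE)
  ## representative imaging artifacts for the first subject
  pair <- makeSubjectPair(cfg, as.integer((as.numeric(seed) * 1000003 + 1)
                                          %% 2147483629))
  pdir <- file.path(outDir, "phantom", pair@subjectId)
  dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
  vs <- cfg$voxelSize
  for (tp in c("pre", "intra")) {
    ds <- slot(pair, tp)
    writeVolume(ds$masks$white_matter, file.path(pdir,
      sprintf("%s_wm.nii.gz", tp)), vs)
    writeVolume(ds$masks$brain, file.path(pdir,
      sprintf("%s_brain.nii.gz", tp)), vs)
    tmap <- fitTensor(ds$dwi, ds$scheme)
    maps <- scalarMaps(tmap)
    writeVolume(replace(maps$fa, is.na(maps$fa), 0),
                file.path(pdir, sprintf("%s_fa.nii.gz", tp)), vs)
    writeVolume(replace(maps$md, is.na(maps$md), 0),
                file.path(pdir, sprintf("%s_md.nii.gz", tp)), vs)
    res <- processTimepoint(ds, cfg, params, pair@subjectId, tp)
    for (key in names(res$tracts))
      if (nStreamlines(res$tracts[[key]]))
        writeTck(res$tracts[[key]], file.path(outDir, "tracts",
          sprintf("%s_%s_%s.tck", pair@subjectId, tp, key)))
  }
  writeBvalBvec(pair@pre$scheme, file.path(pdir, "dwi.bval"),
                file.path(pdir, "dwi.bvec"))
  writeTruth(pair, file.path(pdir, "truth.yaml"))
  battery <- runStatsBattery(cohort)
  for (nm in names(battery))
    if (is.data.frame(battery[[nm]]))
      write.csv(battery[[nm]],
                file.path(outDir, "stats", paste0(nm, ".csv")),
                row.names = FALSE)
  ## run-level structured summary
  seg <- battery$segments
  yaml::write_yaml(list(
    nSubjects = n, seed = seed,
    nSegments = nSegments,
    failedReconstructions = sum(!cohort$status$reconstructed),
    afFilterThreshold = cohort$afFilter$threshold,
    significantPaired = if (!is.null(battery$paired))
      sum(battery$paired$pLmm < 0.05, na.rm = TRUE) else 0L,
    significantSegments = if (!is.null(seg))
      sum(seg$pFdr < 0.05, na.rm = TRUE) else 0L),
    file.path(outDir, "stats", "summary.yaml"))
  invisible(list(cohort = cohort, battery = battery))
}
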