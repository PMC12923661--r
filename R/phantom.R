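## Synthetic fiber phantom: paired pre/intraoperative datasets with known
## injected effects (bundle compression, localized MD elevation near the
## dentate end, SNR reduction) on a small isotropic grid.

#' Construct a diffusion acquisition scheme
#'
#' The default reproduces a two-shell intraoperative protocol: six b=0
#' volumes, 20 directions at b=1000 s/mm^2, 32 at b=2000 s/mm^2, with
#' 2.55 mm isotropic voxels. Directions are spread deterministically on
#' the sphere (spherical Fibonacci lattice per shell).
#'
#' @param gridDim integer(3) grid dimensions.
#' @param voxelSize isotropic voxel size in mm (default 2.55).
#' @param nB0 number of b=0 volumes (default 6).
#' @param shells b-values of the diffusion shells (s/mm^2).
#' @param nDirs number of directions per shell.
#' @return an [AcquisitionScheme-class] object.
#' @examples
#' acquisitionScheme(c(20L, 20L, 20L))
#' @export
acquisitionScheme <- function(gridDim, voxelSize = 2.55, nB0 = 6L,
                              shells = c(1000, 2000), nDirs = c(20L, 32L)) {
  stopifnot(length(shells) == length(nDirs))
  bvals <- c(rep(0, nB0), rep(shells, nDirs))
  dirs <- do.call(cbind, c(list(matrix(0, 3, nB0)),
                           lapply(seq_along(shells), function(i)
                             fibonacciSphere(nDirs[i], offset = i))))
  new("AcquisitionScheme", bvals = bvals, bvecs = dirs,
      voxelSize = voxelSize, gridDim = as.integer(gridDim))
}

#' Deterministic unit directions on the sphere
#'
#' Spherical Fibonacci lattice; `offset` decorrelates successive shells.
#'
#' @param n number of directions.
#' @param offset integer lattice phase.
#' @return 3 x n matrix of unit columns.
#' @export
fibonacciSphere <- function(n, offset = 0L) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * (i + offset / 3)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  rbind(r * cos(phi), r * sin(phi), z)
}

#' Specify a synthetic fiber bundle
#'
#' A bundle is a tube of constant radius around a smooth spine through
#' the given control points. `endpointRois` name the ROIs at the first
#' and last control point (e.g. dentate -> motor cortex).
#'
#' @param name one of "d_DRTT", "nd_DRTT", "AF".
#' @param side "left" or "right" (hemisphere of the dentate or Wernicke
#'   ROI).
#' @param controlPoints n x 3 matrix of mm points (>= 4 rows).
#' @param radiusMm tube radius in mm.
#' @param decussates logical; must be TRUE iff name == "d_DRTT".
#' @param endpointRois character(2), ordered ROI names.
#' @return a list of class "BundleSpec".
#' @export
bundleSpec <- function(name, side, controlPoints, radiusMm,
                       decussates = identical(name, "d_DRTT"),
                       endpointRois) {
  name <- match.arg(name, c("d_DRTT", "nd_DRTT", "AF"))
  side <- match.arg(side, c("left", "right"))
  controlPoints <- as.matrix(controlPoints)
  if (nrow(controlPoints) < 4L)
    stop("a bundle spine needs at least 4 control points")
  if (radiusMm <= 0) stop("radiusMm must be positive")
  if (decussates != identical(name, "d_DRTT"))
    stop("decussates must be TRUE exactly for the d_DRTT")
  structure(list(name = name, side = side, controlPoints = controlPoints,
                 radiusMm = radiusMm, decussates = decussates,
                 endpointRois = endpointRois),
            class = "BundleSpec")
}

## dense spine samples + unit tangents + arc-length fractions
sampleSpine <- function(controlPoints, sampleStep = 1) {
  cp <- as.matrix(controlPoints)
  d <- sqrt(rowSums(diff(cp)^2))
  t0 <- c(0, cumsum(d))
  tt <- seq(0, t0[length(t0)], by = sampleStep)
  ## fmm end conditions: a natural spline forces zero end curvature,
  ## which biases the end tangents of curved spines by O(h) * curvature
  fns <- lapply(1:3, function(j)
    splinefun(t0, cp[, j], method = "fmm"))
  pts <- sapply(fns, function(f) f(tt))
  tan <- sapply(fns, function(f) f(tt, deriv = 1))  # analytic tangents
  tan <- tan / sqrt(rowSums(tan^2))
  len <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(len))
  n <- nrow(pts)
  list(points = pts, tangents = tan, arcFrac = cum / cum[n],
       length = cum[n])
}

## voxel centers of the grid restricted to a bounding box (0-based ijk)
gridCenters <- function(dim, vs, lo = c(0, 0, 0), hi = dim) {
  lo <- pmax(0L, floor(lo)); hi <- pmin(dim, ceiling(hi))
  ii <- seq.int(lo[1], hi[1] - 1L); jj <- seq.int(lo[2], hi[2] - 1L)
  kk <- seq.int(lo[3], hi[3] - 1L)
  g <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  list(ijk = g, xyz = (g + 0.5) * vs)
}

## voxels within radius of the spine; returns linear 1-based indices,
## nearest arc-length fraction and tangent per voxel
tubeVoxels <- function(spine, radiusMm, dim, vs, flatEnds = FALSE) {
  tv <- cpp_tube_voxels(spine$points, radiusMm, as.integer(dim), vs,
                        flatEnds)
  list(index = tv$index, arcFrac = spine$arcFrac[tv$nearest],
       tangent = spine$tangents[tv$nearest, , drop = FALSE])
}

#' Rasterize one bundle into a peak field, tensor field and mask
#'
#' Voxels within the tube radius of the bundle spine carry a single peak
#' tangent to the spine (amplitude `peakAmp`) and an axially symmetric
#' tensor with eigenvalues (`lambdaPar`, `lambdaPerp`, `lambdaPerp`);
#' all other voxels have zero amplitude and a zero tensor (the caller
#' overlays isotropic background tissue).
#'
#' @param spec a [bundleSpec()].
#' @param scheme an [AcquisitionScheme-class] (grid geometry).
#' @param peakAmp peak amplitude inside the bundle (>= the configured
#'   floor; default 1).
#' @param lambdaPar,lambdaPerp axial/radial diffusivities in mm^2/s
#'   (defaults 1.7e-3, 0.3e-3).
#' @param mdDelta additive MD change (mm^2/s) applied inside `mdWindow`.
#' @param mdWindow arc-length fraction interval c(a, b) measured from the
#'   first control point (the dentate/Wernicke end).
#' @param supportMarginMm extra radius (mm) over which the peak/tensor
#'   field extends beyond the bundle mask. FACT follows the direction of
#'   the voxel a position falls in, so a streamline offset from the
#'   bundle axis weaves across voxels whose centers can sit up to a
#'   voxel half-diagonal farther out than the streamline itself; with a
#'   hard field edge at the mask radius, seeds near the wall of an
#'   oblique or curved tube are lost mid-course. A support shell of
#'   about two voxels lets every in-mask seed traverse the bundle. 0
#'   (the default) rasterizes a hard-edged tube.
#' @return list with elements `peaks` ([PeakVolume-class]), `tensors`
#'   (nvox x 6 matrix), `mask` (logical array; the bundle at
#'   `radiusMm`), `support` (logical array; mask plus the field shell),
#'   `tube` (per-voxel detail of the support), `spine`.
#' @export
makeBundleField <- function(spec, scheme, peakAmp = 1,
                            lambdaPar = 1.7e-3, lambdaPerp = 0.3e-3,
                            mdDelta = 0, mdWindow = c(0, 0),
                            supportMarginMm = 0) {
  dims <- scheme@gridDim; vs <- scheme@voxelSize
  spine <- sampleSpine(spec$controlPoints)
  margin <- 2 * vs
  if (any(spine$points < margin) ||
      any(sweep(spine$points, 2, dims * vs - margin) > 0))
    stop("bundle spine exits the grid interior (needs a 2-voxel margin)")
  tube <- tubeVoxels(spine, spec$radiusMm + supportMarginMm, dims, vs,
                     flatEnds = supportMarginMm > 0)
  nvox <- prod(dims)
  amp <- array(0, c(dims, 1L))
  dirs <- array(0, c(dims, 1L, 3L))
  amp[tube$index] <- peakAmp
  for (c3 in 1:3) dirs[tube$index + (c3 - 1L) * nvox] <- tube$tangent[, c3]
  tens <- matrix(0, nvox, 6)
  t3 <- tube$tangent
  dl <- lambdaPar - lambdaPerp
  tens[tube$index, 1] <- lambdaPerp + dl * t3[, 1]^2
  tens[tube$index, 2] <- lambdaPerp + dl * t3[, 2]^2
  tens[tube$index, 3] <- lambdaPerp + dl * t3[, 3]^2
  tens[tube$index, 4] <- dl * t3[, 1] * t3[, 2]
  tens[tube$index, 5] <- dl * t3[, 1] * t3[, 3]
  tens[tube$index, 6] <- dl * t3[, 2] * t3[, 3]
  if (mdDelta != 0) {
    inwin <- tube$arcFrac >= mdWindow[1] & tube$arcFrac <= mdWindow[2]
    for (j in 1:3) tens[tube$index[inwin], j] <-
      tens[tube$index[inwin], j] + mdDelta
  }
  support <- array(FALSE, dims)
  support[tube$index] <- TRUE
  mask <- support
  if (supportMarginMm > 0) {
    core <- tubeVoxels(spine, spec$radiusMm, dims, vs, flatEnds = TRUE)
    mask <- array(FALSE, dims)
    mask[core$index] <- TRUE
  }
  peaks <- new("PeakVolume", directions = dirs, amplitudes = amp,
               voxelSize = vs, dim = as.integer(dims))
  list(peaks = peaks, tensors = tens, mask = mask, support = support,
       tube = tube, spine = spine)
}

#' Default phantom configuration
#'
#' Grid, acquisition, anatomy fractions and effect defaults for the
#' synthetic cohort. The defaults are the study conditions the phantom
#' emulates: 2.55-mm voxels, 6/20/32 two-shell scheme, preoperative WM
#' SNR ~24.4 with an intraoperative SNR scale of 0.906 (a ~9.4% drop),
#' bundle compression via a radius scale of 0.7, and a localized MD
#' elevation (mean 0.3e-3, SD 0.2e-3 mm^2/s across subjects) confined to
#' the first quarter of arc length from the dentate end of the left
#' d-DRTT.
#'
#' @param gridDim integer(3); default c(26, 30, 34) — a 66 x 77 x 87 mm
#'   field of view, scaled to a young child's brain.
#' @param voxelSize mm; default 2.55.
#' @param bundles character subset of c("d_DRTT_left", "d_DRTT_right",
#'   "nd_DRTT_left", "nd_DRTT_right", "AF_left", "AF_right").
#' @param radiusMm bundle (mask) tube radius (mm).
#' @param supportMarginMm field-support shell beyond the mask radius
#'   (mm); see [makeBundleField()].
#' @param roiRadiusMm endpoint/waypoint ROI sphere radius (mm).
#' @param snr preoperative white-matter SNR.
#' @param effect list(volumeScale, mdDeltaMean, mdDeltaSd, mdWindow,
#'   snrScale, appliesTo) — the injected intraoperative effect.
#' @param speechThreshold MD-elevation threshold (mm^2/s) above which a
#'   left-sided affected bundle yields speechIncrease = TRUE.
#' @param speechNoiseProb probability of a spontaneous TRUE label.
#' @param jitterMm SD of the per-subject control-point jitter (mm).
#' @param simulateRegion "brain" simulates the DWI signal over the whole
#'   brain mask; "tracts" restricts the simulation to the bundle tubes
#'   and their gray-matter end caps — the only voxels the tract metrics
#'   ever sample — which is much faster for large simulation studies.
#' @return a list of class "PhantomConfig".
#' @export
phantomConfig <- function(gridDim = c(26L, 30L, 34L), voxelSize = 2.55,
                          bundles = c("d_DRTT_left", "AF_left"),
                          radiusMm = 2, supportMarginMm = 3.5,
                          roiRadiusMm = 6, snr = 24.36,
                          effect = list(volumeScale = 1, mdDeltaMean = 0,
                                        mdDeltaSd = 0,
                                        mdWindow = c(0, 0.25),
                                        snrScale = 1,
                                        appliesTo = "d_DRTT_left"),
                          speechThreshold = 0.3e-3,
                          speechNoiseProb = 0, jitterMm = 1.2,
                          simulateRegion = c("brain", "tracts")) {
  simulateRegion <- match.arg(simulateRegion)
  structure(list(gridDim = as.integer(gridDim), voxelSize = voxelSize,
                 bundles = bundles, radiusMm = radiusMm,
                 supportMarginMm = supportMarginMm,
                 roiRadiusMm = roiRadiusMm, snr = snr, effect = effect,
                 speechThreshold = speechThreshold,
                 speechNoiseProb = speechNoiseProb, jitterMm = jitterMm,
                 simulateRegion = simulateRegion),
            class = "PhantomConfig")
}

## anatomy as fractions of the grid extent; x: left->right, z: feet->head
bundleFractions <- list(
  d_DRTT_left = rbind(c(0.40, 0.45, 0.10), c(0.46, 0.47, 0.20),
                      c(0.55, 0.50, 0.32), c(0.58, 0.50, 0.55),
                      c(0.60, 0.47, 0.72), c(0.62, 0.45, 0.88)),
  nd_DRTT_left = rbind(c(0.33, 0.45, 0.10), c(0.36, 0.47, 0.20),
                       c(0.34, 0.50, 0.32), c(0.35, 0.50, 0.55),
                       c(0.33, 0.47, 0.72), c(0.32, 0.45, 0.88)),
  AF_left = rbind(c(0.14, 0.30, 0.52), c(0.12, 0.42, 0.66),
                  c(0.13, 0.58, 0.70), c(0.17, 0.72, 0.58)))

mirrorX <- function(fr) { fr[, 1] <- 1 - fr[, 1]; fr }

#' Default bundle geometry
#'
#' Stylized spines: the d-DRTT rises from the dentate end, crosses the
#' midsagittal plane in the brainstem segment, and ascends through the
#' contralateral thalamus to the motor cortex; the nd-DRTT stays
#' ipsilateral; the AF arcs between the Wernicke and Broca regions. Left
#' and right are mirror images; per-subject jitter is added by
#' [makeSubjectPair()].
#'
#' @param which bundle name, e.g. "d_DRTT_left".
#' @param cfg a [phantomConfig()].
#' @param jitter optional n x 3 mm offsets added to the control points.
#' @param radiusMm tube radius override (mm).
#' @return a [bundleSpec()].
#' @export
defaultBundle <- function(which, cfg, jitter = NULL, radiusMm = NULL) {
  side <- if (grepl("right$", which)) "right" else "left"
  base <- sub("_(left|right)$", "", which)
  fr <- bundleFractions[[paste0(base, "_left")]]
  if (side == "right") fr <- mirrorX(fr)
  ext <- cfg$gridDim * cfg$voxelSize
  cp <- sweep(fr, 2, ext, "*")
  if (!is.null(jitter)) {
    cp <- cp + jitter
    ## keep jittered control points well inside the grid so the spline
    ## spine (which may overshoot slightly between points) stays within
    ## the 2-voxel interior margin
    margin <- 2 * cfg$voxelSize + 1.5
    cp <- pmax(cp, margin)
    cp <- pmin(cp, rep(ext - margin, each = nrow(cp)))
  }
  rois <- if (base == "AF") {
    paste0(c("wernicke_", "broca_"), substr(side, 1, 1))
  } else {
    motorSide <- if (base == "d_DRTT") setdiff(c("left", "right"), side)
                 else side
    c(paste0("dentate_", substr(side, 1, 1)),
      paste0("motor_cortex_", substr(motorSide, 1, 1)))
  }
  bundleSpec(base, side, cp, radiusMm %||% cfg$radiusMm,
             endpointRois = rois)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sphereMask <- function(center, radius, dims, vs) {
  gc <- gridCenters(dims, vs, center / vs - radius / vs - 1,
                    center / vs + radius / vs + 1)
  keep <- rowSums(sweep(gc$xyz, 2, center)^2) <= radius^2
  m <- array(FALSE, dims)
  ijk <- gc$ijk[keep, , drop = FALSE]
  m[1L + ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3])] <- TRUE
  m
}

boxMask <- function(loFrac, hiFrac, dims, vs) {
  ext <- dims * vs
  ## voxel centers (i + 0.5) * vs inside [loFrac, hiFrac] * ext, per axis
  rng <- lapply(1:3, function(j) {
    i0 <- max(0L, as.integer(ceiling(loFrac[j] * ext[j] / vs - 0.5)))
    i1 <- min(dims[j] - 1L, as.integer(floor(hiFrac[j] * ext[j] / vs - 0.5)))
    if (i0 > i1) integer() else seq.int(i0, i1) + 1L
  })
  m <- array(FALSE, dims)
  m[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
  m
}

## Build one complete dataset (masks, peaks, tensors, S0) for one
## timepoint of one subject. `specs` are jittered bundleSpecs; effect is
## NULL (pre) or the applied SurgicalEffect list (intra).
buildDataset <- function(cfg, specs, effect = NULL,
                         ventricleScale = 1, tumorRadius = 5) {
  dims <- cfg$gridDim; vs <- cfg$voxelSize; ext <- dims * vs
  nvox <- prod(dims)
  scheme <- acquisitionScheme(dims, vs)
  intra <- !is.null(effect)

  fields <- lapply(specs, function(sp) {
    key <- paste(sp$name, sp$side, sep = "_")
    rad <- sp$radiusMm
    mdD <- 0; mdW <- c(0, 0)
    if (intra && key %in% effect$appliesTo) {
      rad <- rad * effect$volumeScale
      mdD <- effect$mdDelta
      mdW <- effect$mdWindow
    }
    sp$radiusMm <- rad
    makeBundleField(sp, scheme, mdDelta = mdD, mdWindow = mdW,
                    supportMarginMm = cfg$supportMarginMm %||% 0)
  })
  names(fields) <- vapply(specs, function(sp)
    paste(sp$name, sp$side, sep = "_"), "")

  ## compose peaks/tensors: first bundle claiming a voxel wins
  amp <- array(0, c(dims, 1L)); dirs <- array(0, c(dims, 1L, 3L))
  tens <- matrix(0, nvox, 6)
  claimed <- logical(nvox)
  for (f in fields) {
    idx <- f$tube$index[!claimed[f$tube$index]]
    sel <- !claimed[f$tube$index]
    amp[idx] <- f$peaks@amplitudes[idx]
    for (c3 in 1:3) dirs[idx + (c3 - 1L) * nvox] <-
      f$peaks@directions[idx + (c3 - 1L) * nvox]
    tens[idx, ] <- f$tensors[idx, ]
    claimed[idx] <- TRUE
  }
  supportMask <- array(claimed, dims)

  ## ROI masks at spine endpoints / waypoints
  masks <- list()
  roiR <- cfg$roiRadiusMm
  for (i in seq_along(specs)) {
    sp <- specs[[i]]; f <- fields[[i]]
    pts <- f$spine$points
    ends <- list(pts[1, ], pts[nrow(pts), ])
    for (j in 1:2) {
      nm <- sp$endpointRois[j]
      m <- sphereMask(ends[[j]], roiR, dims, vs)
      masks[[nm]] <- if (is.null(masks[[nm]])) m else masks[[nm]] | m
    }
    if (sp$name %in% c("d_DRTT", "nd_DRTT")) {
      thal <- pts[which.min(abs(f$spine$arcFrac - 0.55)), ]
      tside <- if (sp$name == "d_DRTT")
        setdiff(c("left", "right"), sp$side) else sp$side
      nm <- paste0("thalamus_", substr(tside, 1, 1))
      m <- sphereMask(thal, roiR + 1, dims, vs)
      masks[[nm]] <- if (is.null(masks[[nm]])) m else masks[[nm]] | m
    }
  }

  masks$corpus_callosum <- boxMask(c(0.46, 0.30, 0.62), c(0.54, 0.70, 0.72),
                                   dims, vs)
  masks$ventricles <- sphereMask(c(0.50, 0.72, 0.30) * ext,
                                 6 * ventricleScale^(1 / 3), dims, vs)
  masks$tumor <- if (intra) array(FALSE, dims) else
    sphereMask(c(0.52, 0.62, 0.08) * ext, tumorRadius, dims, vs)

  ## tissue partition: WM = bundle tubes + deep background box; GM =
  ## endpoint gray structures (dentate, cortex regions) outside the
  ## tubes, so every bundle voxel is white matter and streamlines
  ## terminate at the gray-white interface just past the tube ends;
  ## CSF = ventricles. Pairwise disjoint by construction.
  gmNames <- unique(unlist(lapply(specs, `[[`, "endpointRois")))
  csf <- masks$ventricles
  wmBg <- boxMask(c(0.30, 0.30, 0.35), c(0.70, 0.70, 0.78), dims, vs)
  wm <- (supportMask | wmBg) & !csf & !masks$tumor
  gm <- Reduce(`|`, masks[gmNames]) & !wm & !csf & !masks$tumor
  masks$white_matter <- wm
  masks$gray_matter <- gm
  masks$csf <- csf
  masks$brain <- wm | gm | csf | masks$tumor

  ## background tissue tensors (isotropic): WM 0.7e-3, GM 0.9e-3,
  ## CSF 3.0e-3, tumor 1.2e-3 mm^2/s
  iso <- function(sel, md) { for (j in 1:3) tens[sel & !claimed, j] <<- md }
  iso(c(wm), 0.7e-3); iso(c(gm), 0.9e-3); iso(c(csf), 3.0e-3)
  iso(c(masks$tumor), 1.2e-3)
  ## bundle voxels inside GM caps keep their anisotropic tensor & peak

  s0 <- numeric(nvox)
  s0[c(masks$brain)] <- 1

  peaks <- new("PeakVolume", directions = dirs, amplitudes = amp,
               voxelSize = vs, dim = as.integer(dims))
  list(scheme = scheme, peaks = peaks, tensors = tens, s0 = s0,
       masks = masks, bundleMasks = lapply(fields, `[[`, "mask"),
       bundleSupports = lapply(fields, `[[`, "support"),
       bundleTubes = lapply(fields, `[[`, "tube"), specs = specs)
}

#' Simulate a diffusion-weighted series with Rician noise
#'
#' Mono-exponential single-tensor signal S = S0 exp(-b g' D g), corrupted
#' by Rician noise: the magnitude of (S + N(0, sigma), N(0, sigma)) with
#' sigma = S0ref / snr. Only voxels in `mask` are simulated; the rest of
#' the grid is zero.
#'
#' @param tensors nvox x 6 tensor matrix (mm^2/s).
#' @param s0 numeric vector of noiseless S0 per voxel.
#' @param mask logical array/vector of voxels to simulate.
#' @param scheme an [AcquisitionScheme-class].
#' @param snr signal-to-noise ratio (S0ref / sigma); `Inf` for noiseless.
#' @param seed integer RNG seed (reproducible draws).
#' @param s0ref reference signal for the noise level (default 1).
#' @return list: `signal` (nMaskVox x nVolumes matrix), `voxels` (linear
#'   1-based indices), `dim`, `scheme`, `snr`.
#' @export
simulateDWI <- function(tensors, s0, mask, scheme, snr, seed = NULL,
                        s0ref = 1) {
  if (snr <= 0) stop("snr must be positive")
  idx <- which(c(mask))
  b <- scheme@bvals; g <- scheme@bvecs
  ## b * g' D g for all volumes at once: design on the 6 tensor columns
  q <- rbind(g[1, ]^2, g[2, ]^2, g[3, ]^2,
             2 * g[1, ] * g[2, ], 2 * g[1, ] * g[3, ], 2 * g[2, ] * g[3, ])
  expo <- tensors[idx, , drop = FALSE] %*% q    # nvox x nvol, g'Dg
  evals <- tensorEigenvalues(tensors[idx, , drop = FALSE])
  if (any(evals < -1e-12))
    stop("non-positive-definite tensor in the simulation mask")
  S <- s0[idx] * exp(-sweep(expo, 2, b, "*"))
  if (is.finite(snr)) {
    if (!is.null(seed)) set.seed(seed)
    sigma <- s0ref / snr
    n <- length(S)
    S <- sqrt((S + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  }
  list(signal = S, voxels = idx, dim = scheme@gridDim, scheme = scheme,
       snr = snr)
}

#' Generate one paired pre/intraoperative synthetic subject
#'
#' Draws subject-level anatomy (control-point jitter, bundle radius
#' variation, ventricle and tumor size), builds the preoperative dataset,
#' regenerates the intraoperative dataset with the injected effect
#' (radius x volumeScale on the affected bundles, MD + mdDelta inside the
#' arc-length window measured from the dentate end, SNR x snrScale), and
#' assigns the speech-disturbance label: TRUE iff the applied mdDelta
#' exceeds `speechThreshold` on a left-sided affected bundle, or with
#' probability `speechNoiseProb` otherwise.
#'
#' @param cfg a [phantomConfig()].
#' @param seed integer seed; the pair is fully reproducible from
#'   config + seed.
#' @param subjectId identifier string.
#' @param simulate logical; if FALSE, skip the DWI simulation (geometry,
#'   peaks, tensors and masks only — sufficient for macrostructural
#'   analyses).
#' @return a [SubjectPair-class].
#' @export
makeSubjectPair <- function(cfg, seed, subjectId = sprintf("S%03d", seed),
                            simulate = TRUE) {
  set.seed(seed)
  age <- runif(1, 2, 17)
  sex <- sample(c("F", "M"), 1)
  nCp <- vapply(cfg$bundles, function(b)
    nrow(bundleFractions[[sub("_right$", "_left", b)]]), 0L)
  jit <- lapply(nCp, function(n)
    matrix(rnorm(3L * n, 0, cfg$jitterMm), ncol = 3))
  radius <- cfg$radiusMm * runif(1, 0.9, 1.1)
  ventricleScale <- runif(1, 0.6, 1.6)
  tumorRadius <- runif(1, 3.5, 5)
  eff <- cfg$effect
  mdDelta <- if (eff$mdDeltaSd > 0)
    max(0, rnorm(1, eff$mdDeltaMean, eff$mdDeltaSd)) else eff$mdDeltaMean
  specs <- lapply(seq_along(cfg$bundles), function(i)
    defaultBundle(cfg$bundles[i], cfg, jitter = jit[[i]],
                  radiusMm = radius))
  applied <- list(volumeScale = eff$volumeScale, mdDelta = mdDelta,
                  mdWindow = eff$mdWindow, snrScale = eff$snrScale,
                  appliesTo = eff$appliesTo)
  leftAffected <- any(grepl("left$", applied$appliesTo))
  speech <- (mdDelta >= cfg$speechThreshold && leftAffected) ||
    (runif(1) < cfg$speechNoiseProb)

  pre <- buildDataset(cfg, specs, effect = NULL,
                      ventricleScale = ventricleScale,
                      tumorRadius = tumorRadius)
  ## a no-op effect leaves everything but the resected tumor unchanged,
  ## so the intra dataset can be derived from the preoperative one
  ## (valid only while the tumor is disjoint from the other tissue)
  noEffect <- applied$volumeScale == 1 && applied$mdDelta == 0
  tissue <- pre$masks$white_matter | pre$masks$gray_matter |
    pre$masks$csf
  intra <- if (noEffect && !any(pre$masks$tumor & tissue)) {
    ds <- pre
    ds$s0[c(pre$masks$tumor)] <- 0
    ds$masks$tumor <- array(FALSE, cfg$gridDim)
    ds$masks$brain <- tissue
    ds
  } else buildDataset(cfg, specs, effect = applied,
                      ventricleScale = ventricleScale,
                      tumorRadius = tumorRadius)
  if (simulate) {
    region <- function(ds) {
      if (identical(cfg$simulateRegion, "tracts"))
        Reduce(`|`, ds$bundleSupports) | ds$masks$gray_matter
      else ds$masks$brain
    }
    pre$dwi <- simulateDWI(pre$tensors, pre$s0, region(pre),
                           pre$scheme, cfg$snr,
                           seed = (seed %% 1000000L) + 70000000L)
    intra$dwi <- simulateDWI(intra$tensors, intra$s0, region(intra),
                             intra$scheme, cfg$snr * applied$snrScale,
                             seed = (seed %% 1000000L) + 80000000L)
  }
  new("SubjectPair", subjectId = subjectId, age = age, sex = sex,
      pre = pre, intra = intra, truth = applied,
      speechIncrease = as.logical(speech))
}
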