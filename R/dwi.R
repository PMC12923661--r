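## Diffusion tensor model: ordinary log-linear least-squares fit,
## closed-form eigenvalues of the symmetric 3x3 tensor, FA/MD scalar
## maps and the white-matter SNR statistic.

#' Fit diffusion tensors by ordinary least squares on log-signal
#'
#' Unweighted log-linear fit of the mono-exponential tensor model
#' ln S = ln S0 - b g' D g, using all b-values (both shells). Voxels
#' inside the mask with any non-positive signal are marked invalid, not
#' imputed.
#'
#' @param dwi either the compact list returned by [simulateDWI()] or a
#'   4D array with dim c(grid, nVolumes).
#' @param scheme an [AcquisitionScheme-class].
#' @param mask logical array of voxels to fit (default: all simulated
#'   voxels).
#' @param shells optional numeric vector of b-values to use (always
#'   keep 0 in it), e.g. `c(0, 1000)` for a single-shell fit; the
#'   default uses every acquired volume.
#' @return a [TensorMap-class].
#' @export
fitTensor <- function(dwi, scheme, mask = NULL, shells = NULL) {
  if (is.array(dwi) && length(dim(dwi)) == 4L) {
    dims <- dim(dwi)[1:3]
    nv <- prod(dims)
    sig <- matrix(dwi, nv, dim(dwi)[4])
    vox <- seq_len(nv)
  } else {
    dims <- dwi$dim
    sig <- dwi$signal
    vox <- dwi$voxels
  }
  b <- scheme@bvals; g <- scheme@bvecs
  if (!is.null(shells)) {
    sel <- b %in% shells
    b <- b[sel]; g <- g[, sel, drop = FALSE]
    sig <- sig[, sel, drop = FALSE]
  }
  if (length(b) < 7L || !any(b == 0))
    stop("tensor fit needs >= 7 volumes including >= 1 b0")
  if (!is.null(mask)) {
    keep <- which(c(mask)[vox])
    sig <- sig[keep, , drop = FALSE]
    vox <- vox[keep]
  }
  X <- cbind(1, -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
             -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
             -2 * b * g[2, ] * g[3, ])
  qrX <- qr(X)
  if (qrX$rank < 7L) stop("degenerate design matrix (gradient scheme)")
  ok <- rowSums(sig <= 0) == 0L
  beta <- matrix(NA_real_, 7L, length(vox))
  if (any(ok))
    beta[, ok] <- qr.coef(qrX, t(log(sig[ok, , drop = FALSE])))
  nvox <- prod(dims)
  tens <- matrix(0, nvox, 6)
  s0 <- numeric(nvox)
  valid <- logical(nvox)
  tens[vox[ok], ] <- t(beta[2:7, ok, drop = FALSE])
  s0[vox[ok]] <- exp(beta[1L, ok])
  valid[vox[ok]] <- TRUE
  new("TensorMap", tensors = tens, s0 = s0, valid = valid,
      dim = as.integer(dims), voxelSize = scheme@voxelSize)
}

#' Eigenvalues of symmetric 3x3 tensors, vectorized
#'
#' Closed-form (trigonometric/Cardano) eigenvalues, descending order.
#'
#' @param tens n x 6 matrix, columns Dxx, Dyy, Dzz, Dxy, Dxz, Dyz.
#' @return n x 3 matrix of eigenvalues, largest first.
#' @export
tensorEigenvalues <- function(tens) {
  tens <- rbind(tens)[, 1:6, drop = FALSE]
  dxx <- tens[, 1]; dyy <- tens[, 2]; dzz <- tens[, 3]
  dxy <- tens[, 4]; dxz <- tens[, 5]; dyz <- tens[, 6]
  q <- (dxx + dyy + dzz) / 3
  p1 <- dxy^2 + dxz^2 + dyz^2
  p2 <- (dxx - q)^2 + (dyy - q)^2 + (dzz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  out <- cbind(q, q, q)
  nz <- p > 0
  if (any(nz)) {
    pn <- p[nz]
    bxx <- (dxx[nz] - q[nz]) / pn; byy <- (dyy[nz] - q[nz]) / pn
    bzz <- (dzz[nz] - q[nz]) / pn
    bxy <- dxy[nz] / pn; bxz <- dxz[nz] / pn; byz <- dyz[nz] / pn
    detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
            bxz * (bxy * byz - byy * bxz)
    phi <- acos(pmin(1, pmax(-1, detB / 2))) / 3
    e1 <- q[nz] + 2 * pn * cos(phi)
    e3 <- q[nz] + 2 * pn * cos(phi + 2 * pi / 3)
    out[nz, ] <- cbind(e1, 3 * q[nz] - e1 - e3, e3)
  }
  out
}

#' Fractional anisotropy and mean diffusivity from eigenvalues
#'
#' MD = trace/3; FA = sqrt(3/2) * ||lambda - MD|| / ||lambda||. Negative
#' eigenvalues are clamped to 0 first (the clamp count is reported by
#' [scalarMaps()]). An all-zero tensor has FA defined as 0.
#'
#' @param evals n x 3 eigenvalue matrix (or length-3 vector).
#' @return numeric vector.
#' @export
faFromEigenvalues <- function(evals) {
  evals <- pmax(rbind(evals)[, 1:3, drop = FALSE], 0)
  md <- rowMeans(evals)
  num <- rowSums((evals - md)^2)
  den <- rowSums(evals^2)
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  pmin(1, fa)
}

#' @rdname faFromEigenvalues
#' @export
mdFromEigenvalues <- function(evals) {
  rowMeans(pmax(rbind(evals)[, 1:3, drop = FALSE], 0))
}

#' FA of a single tensor
#' @param tensor length-6 vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) or 3x3
#'   symmetric matrix.
#' @return scalar in [0, 1] ([tensorFA()]) or mm^2/s ([tensorMD()]).
#' @export
tensorFA <- function(tensor) {
  faFromEigenvalues(tensorEigenvalues(asTensor6(tensor)))
}

#' @rdname tensorFA
#' @export
tensorMD <- function(tensor) {
  mdFromEigenvalues(tensorEigenvalues(asTensor6(tensor)))
}

asTensor6 <- function(tensor) {
  if (is.matrix(tensor) && all(dim(tensor) == c(3, 3)))
    tensor <- c(tensor[1, 1], tensor[2, 2], tensor[3, 3],
                tensor[1, 2], tensor[1, 3], tensor[2, 3])
  matrix(tensor, ncol = 6)
}

#' FA and MD maps from a fitted tensor map
#'
#' @param tmap a [TensorMap-class].
#' @return list: `fa`, `md` (numeric arrays, NA outside the validity
#'   mask), `nClamped` (count of voxels with negative eigenvalues
#'   clamped to 0).
#' @export
scalarMaps <- function(tmap) {
  dims <- tmap@dim
  fa <- array(NA_real_, dims); md <- array(NA_real_, dims)
  idx <- which(tmap@valid)
  if (length(idx)) {
    ev <- tensorEigenvalues(tmap@tensors[idx, , drop = FALSE])
    nClamped <- sum(rowSums(ev < 0) > 0L)
    fa[idx] <- faFromEigenvalues(ev)
    md[idx] <- mdFromEigenvalues(ev)
  } else nClamped <- 0L
  list(fa = fa, md = md, nClamped = nClamped)
}

#' White-matter SNR from repeated b0 volumes
#'
#' Per voxel, the temporal mean of the b0 signal divided by its temporal
#' standard deviation (sample SD, n-1 denominator); the statistic is the
#' mean of that ratio over white-matter voxels. Voxels with zero SD are
#' excluded and counted.
#'
#' @param b0 either an nvox x nB0 matrix, a 4D array, or the compact
#'   [simulateDWI()] list (its b=0 volumes are extracted).
#' @param wmMask logical array of white-matter voxels.
#' @return list: `snr`, `nVoxels` used, `nZeroSd` excluded.
#' @export
wmSNR <- function(b0, wmMask) {
  if (is.list(b0) && !is.null(b0$signal)) {
    sel <- b0$scheme@bvals == 0
    m <- b0$signal[, sel, drop = FALSE]
    vox <- b0$voxels
  } else if (is.array(b0) && length(dim(b0)) == 4L) {
    m <- matrix(b0, prod(dim(b0)[1:3]), dim(b0)[4])
    vox <- seq_len(nrow(m))
  } else {
    m <- as.matrix(b0)
    vox <- seq_len(nrow(m))
  }
  if (ncol(m) < 2L) stop("need >= 2 b0 volumes")
  inWm <- which(c(wmMask)[vox])
  if (!length(inWm)) stop("empty white-matter mask")
  m <- m[inWm, , drop = FALSE]
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
  ok <- sdv > 0
  if (!any(ok)) stop("all white-matter voxels have zero temporal SD")
  list(snr = mean(mu[ok] / sdv[ok]), nVoxels = sum(ok),
       nZeroSd = sum(!ok))
}

#' Relative change between two printed summary values
#'
#' `100 * (post - pre) / pre`; e.g. white-matter SNR means 24.36 to
#' 22.07 give -9.4 (a 9.4% decrease).
#'
#' @param pre,post numeric.
#' @return percent change.
#' @export
percentChange <- function(pre, post) 100 * (post - pre) / pre
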