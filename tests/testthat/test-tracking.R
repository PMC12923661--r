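test_that("seed grid matches brute-force lattice enumeration", {
  set.seed(1)
  vs <- 2.55
  for (i in 1:5) {
    dims <- c(4L, 4L, 4L)
    mask <- array(runif(prod(dims)) < 0.4, dims)
    if (!any(mask)) mask[2, 2, 2] <- TRUE
    expect_equal(seedGrid(mask, vs, 1), oracleSeedGrid(mask, vs, 1),
                 ignore_attr = TRUE)
  }
  ## a single in-mask voxel holds 2-3 lattice points per axis
  m1 <- array(FALSE, c(4L, 4L, 4L)); m1[2, 2, 2] <- TRUE
  s <- seedGrid(m1, vs, 1)
  expect_equal(nrow(s), nrow(oracleSeedGrid(m1, vs, 1)))
  perAxis <- apply(s, 2, function(x) length(unique(x)))
  expect_true(all(perAxis >= 2 & perAxis <= 3))
  ## empty mask; spacing equal to the bbox extent leaves <= 8 corners
  expect_equal(nrow(seedGrid(array(FALSE, c(3L, 3L, 3L)), vs)), 0)
  big <- array(TRUE, c(4L, 4L, 4L))
  expect_lte(nrow(seedGrid(big, vs, 4 * vs)), 8)
})

test_that("FACT tracks a uniform slab straight through", {
  dims <- c(9L, 9L, 9L); vs <- 2.55
  peaks <- uniformZField(dims, vs)
  wm <- array(FALSE, dims)
  wm[, , 3:7] <- TRUE                       # slab in z
  seed <- matrix((dims * vs) / 2, 1)
  ss <- trackFibers(peaks, wm, seed, trackingParams())
  expect_equal(nStreamlines(ss), 1)
  m <- streamlines(ss)[[1]]
  ## straight line: x and y constant, spans the slab plus the two
  ## retained exit vertices
  expect_equal(max(abs(sweep(m[, 1:2], 2, seed[1:2]))), 0)
  slabExtent <- 5 * vs
  expect_lt(abs(streamlineLengths(ss) - slabExtent), 2 * 1 + vs)
})

test_that("propagation stops at a 90-degree peak boundary", {
  dims <- c(9L, 9L, 9L); vs <- 2.55
  nv <- prod(dims)
  dirs <- array(0, c(dims, 1L, 3L))
  half <- array(rep(seq_len(dims[3]) > 4, each = prod(dims[1:2])), dims)
  dirs[which(!half) + 2L * nv] <- 1         # z peaks below
  dirs[which(half) + 0L * nv] <- 1          # x peaks above
  peaks <- new("PeakVolume", directions = dirs,
               amplitudes = array(1, c(dims, 1L)), voxelSize = vs,
               dim = dims)
  wm <- array(TRUE, dims)
  seed <- matrix(c(dims[1:2] * vs / 2, 1.5 * vs), 1)
  ss <- trackFibers(peaks, wm, seed, trackingParams())
  m <- streamlines(ss)[[1]]
  ## all vertices stay on the seed's x/y column: the 90-degree turn at
  ## the boundary exceeds the 60-degree limit
  expect_equal(max(abs(sweep(m[, 1:2], 2, seed[1:2]))), 0)
  expect_lt(max(m[, 3]), 5 * vs + 1 + 1e-9)
})

test_that("tracking is deterministic and mirror-symmetric", {
  dims <- c(9L, 9L, 12L); vs <- 2.55; ext <- dims * vs
  sch <- acquisitionScheme(dims, vs)
  cp <- cbind(seq(3 * vs, ext[1] - 3 * vs, length.out = 5),
              ext[2] / 2,
              seq(3 * vs, ext[3] - 3 * vs, length.out = 5))
  f <- makeBundleField(bundleSpec("nd_DRTT", "left", cp, 4,
                                  endpointRois = c("a", "b")), sch)
  wm <- array(TRUE, dims)
  ## seeds in general position (inside voxels, off lattice boundaries)
  ijk <- which(f$mask, arr.ind = TRUE)
  seeds <- sweep((ijk - 1) * vs, 2, c(0.93, 1.21, 1.48), "+")
  s1 <- trackFibers(f$peaks, wm, seeds, trackingParams())
  s2 <- trackFibers(f$peaks, wm, seeds, trackingParams())
  expect_identical(streamlines(s1), streamlines(s2))
  ## mirror the field in x and the streamline SET mirrors exactly
  ## (orientation of each polyline and seed order are not meaningful)
  mirror <- function(a) {
    d <- dim(a)
    do.call(`[`, c(list(a), list(rev(seq_len(d[1]))),
                   lapply(d[-1], seq_len), list(drop = FALSE)))
  }
  dirsM <- mirror(f$peaks@directions)
  dirsM[, , , , 1] <- -dirsM[, , , , 1]
  peaksM <- new("PeakVolume", directions = dirsM,
                amplitudes = mirror(f$peaks@amplitudes),
                voxelSize = vs, dim = dims)
  seedsM <- seeds; seedsM[, 1] <- ext[1] - seeds[, 1]
  sM <- trackFibers(peaksM, wm, seedsM, trackingParams())
  expect_equal(nStreamlines(sM), nStreamlines(s1))
  canon <- function(m) {
    a <- round(m, 6)
    if (nrow(a) > 1 &&
        paste(a[nrow(a), ], collapse = ",") < paste(a[1, ], collapse = ","))
      a <- a[rev(seq_len(nrow(a))), , drop = FALSE]
    paste(t(a), collapse = ",")
  }
  keys1 <- sort(vapply(streamlines(s1), canon, ""))
  keysM <- sort(vapply(streamlines(sM), function(m) {
    m[, 1] <- ext[1] - m[, 1]; canon(m)
  }, ""))
  expect_identical(keysM, keys1)
})

test_that("no interior vertex sits in a sub-threshold voxel", {
  cfg <- phantomConfig(bundles = c("d_DRTT_left", "AF_left"))
  pair <- makeSubjectPair(cfg, 21, simulate = FALSE)
  ds <- pair@pre
  params <- trackingParams()
  seeds <- seedGrid(Reduce(`|`, ds$bundleMasks), cfg$voxelSize, 2)
  ss <- trackFibers(ds$peaks, ds$masks$white_matter, seeds, params)
  nv <- prod(cfg$gridDim)
  amp <- ds$peaks@amplitudes
  bad <- vapply(streamlines(ss), function(m) {
    v <- floor(m / cfg$voxelSize)
    ok <- v[, 1] >= 0 & v[, 2] >= 0 & v[, 3] >= 0 &
      v[, 1] < cfg$gridDim[1] & v[, 2] < cfg$gridDim[2] &
      v[, 3] < cfg$gridDim[3]
    a <- rep(1, nrow(m))
    a[ok] <- amp[1 + v[ok, 1] + cfg$gridDim[1] *
                   (v[ok, 2] + cfg$gridDim[2] * v[ok, 3])]
    any(a[-c(1, length(a))] < params$ampFloor)
  }, TRUE)
  expect_false(any(bad))
})

test_that("bundle seeds reach both endpoint regions", {
  cfg <- phantomConfig(bundles = "d_DRTT_left")
  pair <- makeSubjectPair(cfg, 31, simulate = FALSE)
  ds <- pair@pre
  seeds <- seedGrid(ds$bundleMasks$d_DRTT_left, cfg$voxelSize, 1.5)
  ss <- trackFibers(ds$peaks, ds$masks$white_matter, seeds,
                    trackingParams())
  ## dilate each ROI by one voxel (6-neighborhood)
  dilate <- function(m) {
    d <- dim(m); out <- m
    out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
    out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
    out[, , -1] <- out[, , -1] | m[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
    out
  }
  roiA <- dilate(ds$masks$dentate_l)
  roiB <- dilate(ds$masks$motor_cortex_r)
  inMask <- function(p, m) {
    v <- floor(p / cfg$voxelSize)
    all(v >= 0) && all(v < cfg$gridDim) &&
      m[1 + v[1] + cfg$gridDim[1] * (v[2] + cfg$gridDim[2] * v[3])]
  }
  okEnds <- vapply(streamlines(ss), function(mtx) {
    a <- mtx[1, ]; b <- mtx[nrow(mtx), ]
    (inMask(a, roiA) && inMask(b, roiB)) ||
      (inMask(a, roiB) && inMask(b, roiA))
  }, TRUE)
  expect_gte(mean(okEnds), 0.9)
})
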