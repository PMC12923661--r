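test_that("acquisition scheme matches the two-shell protocol", {
  sch <- acquisitionScheme(c(20L, 20L, 20L))
  expect_equal(sum(bvals(sch) == 0), 6)
  expect_equal(sum(bvals(sch) == 1000), 20)
  expect_equal(sum(bvals(sch) == 2000), 32)
  nz <- bvals(sch) > 0
  expect_equal(colSums(bvecs(sch)[, nz]^2), rep(1, sum(nz)),
               tolerance = 1e-10)
  expect_equal(voxelSize(sch), 2.55)
})

test_that("bundle peaks are tangent to the spine", {
  dims <- c(12L, 12L, 24L); vs <- 2.55
  ext <- dims * vs
  sch <- acquisitionScheme(dims, vs)
  ## straight z-axis spine: every in-bundle peak is (0, 0, 1)
  cp <- cbind(ext[1] / 2, ext[2] / 2,
              seq(3 * vs, ext[3] - 3 * vs, length.out = 5))
  f <- makeBundleField(bundleSpec("nd_DRTT", "left", cp, 2 * vs,
                                  endpointRois = c("a", "b")), sch)
  idx <- which(f$mask)
  nv <- prod(dims)
  dz <- f$peaks@directions[idx + 2L * nv]
  expect_true(all(abs(abs(dz) - 1) < 1e-9))
  expect_true(all(f$peaks@amplitudes[idx] >= 0.5))
  ## semicircular spine: tangent at arc midpoint orthogonal to the ends
  dims2 <- c(30L, 12L, 30L); ext2 <- dims2 * vs
  th <- seq(0, pi, length.out = 17)
  r <- 25
  cp2 <- cbind(ext2[1] / 2 + r * cos(th), ext2[2] / 2,
               3 * vs + 3 + r * sin(th))
  f2 <- makeBundleField(bundleSpec("nd_DRTT", "left", cp2, 3,
                                   endpointRois = c("a", "b")),
                        acquisitionScheme(dims2, vs))
  tanAt <- function(frac) {
    i <- which.min(abs(f2$spine$arcFrac - frac))
    f2$spine$tangents[i, ]
  }
  expect_lt(abs(sum(tanAt(0.5) * tanAt(0))), 0.05)
  expect_lt(abs(sum(tanAt(0.5) * tanAt(1))), 0.05)
})

test_that("bundle tensors have the configured diffusivities", {
  dims <- c(12L, 12L, 24L); vs <- 2.55; ext <- dims * vs
  cp <- cbind(ext[1] / 2, ext[2] / 2,
              seq(3 * vs, ext[3] - 3 * vs, length.out = 5))
  f <- makeBundleField(bundleSpec("nd_DRTT", "left", cp, 5,
                                  endpointRois = c("a", "b")),
                       acquisitionScheme(dims, vs))
  idx <- which(f$mask)
  md <- tensorMD(f$tensors[idx[1], ])
  expect_equal(md, (1.7e-3 + 0.3e-3 + 0.3e-3) / 3, tolerance = 1e-12)
  expect_equal(tensorFA(f$tensors[idx[1], ]),
               tensorFA(c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0)),
               tolerance = 1e-12)
})

test_that("a spine leaving the grid interior is rejected", {
  dims <- c(10L, 10L, 10L); vs <- 2.55; ext <- dims * vs
  cp <- cbind(ext[1] / 2, ext[2] / 2,
              seq(0.5, ext[3] - 0.5, length.out = 5))  # touches faces
  expect_error(
    makeBundleField(bundleSpec("nd_DRTT", "left", cp, 3,
                               endpointRois = c("a", "b")),
                    acquisitionScheme(dims, vs)),
    "interior")
})

test_that("noiseless DWI follows the mono-exponential tensor signal", {
  dims <- c(4L, 4L, 4L); vs <- 2.55
  sch <- acquisitionScheme(dims, vs)
  nv <- prod(dims)
  tens <- matrix(0, nv, 6)
  mdTrue <- 0.7e-3
  tens[, 1:3] <- mdTrue                 # isotropic
  s0 <- rep(2, nv)
  mask <- array(TRUE, dims)
  dwi <- simulateDWI(tens, s0, mask, sch, snr = Inf)
  b <- bvals(sch)
  expect_equal(unname(dwi$signal[1, b == 0]), rep(2, 6))
  expect_equal(unname(dwi$signal[1, b == 1000]),
               rep(2 * exp(-1000 * mdTrue), 20), tolerance = 1e-12)
  ## reproducibility and the non-positive-definite guard
  d1 <- simulateDWI(tens, s0, mask, sch, snr = 20, seed = 9)
  d2 <- simulateDWI(tens, s0, mask, sch, snr = 20, seed = 9)
  expect_identical(d1$signal, d2$signal)
  bad <- tens; bad[1, 1] <- -1e-3
  expect_error(simulateDWI(bad, s0, mask, sch, snr = Inf),
               "positive-definite")
})

test_that("subject pairs honor the injected effect and ground truth", {
  cfgNull <- studyConfig("null")
  p0 <- makeSubjectPair(cfgNull, 11, simulate = TRUE)
  ## null effect: identical geometry/tensors, different noise only
  expect_identical(p0@pre$tensors, p0@intra$tensors)
  expect_identical(p0@pre$peaks@directions, p0@intra$peaks@directions)
  expect_false(identical(p0@pre$dwi$signal, p0@intra$dwi$signal))
  ## compression shrinks the intra bundle mask
  cfgA <- studyConfig("alteration")
  pA <- makeSubjectPair(cfgA, 11, simulate = FALSE)
  expect_lt(sum(pA@intra$bundleMasks$d_DRTT_left),
            sum(pA@pre$bundleMasks$d_DRTT_left))
  expect_equal(pA@truth$volumeScale, 0.7)
  ## determinism: config + seed fully reproduce the pair
  pB <- makeSubjectPair(cfgA, 11, simulate = FALSE)
  expect_identical(pA@pre$tensors, pB@pre$tensors)
  expect_identical(pA@truth, pB@truth)
})

test_that("phantom masks are consistent", {
  cfg <- phantomConfig(bundles = c("d_DRTT_left", "AF_left"))
  pair <- makeSubjectPair(cfg, 3, simulate = FALSE)
  m <- pair@pre$masks
  ## bundles are white matter; tissue classes are pairwise disjoint
  bundle <- Reduce(`|`, pair@pre$bundleMasks)
  expect_true(all(m$white_matter[bundle]))
  expect_false(any(m$white_matter & m$gray_matter))
  expect_false(any(m$white_matter & m$csf))
  expect_false(any(m$gray_matter & m$csf))
  expect_true(all(m$white_matter[m$brain] | m$gray_matter[m$brain] |
                  m$csf[m$brain] | m$tumor[m$brain]))
  ## endpoint ROIs intersect the first/last 10% of bundle arc length
  tube <- pair@pre$bundleTubes$d_DRTT_left
  lowEnd <- tube$index[tube$arcFrac <= 0.1]
  highEnd <- tube$index[tube$arcFrac >= 0.9]
  expect_true(any(m$dentate_l[lowEnd]))
  expect_true(any(m$motor_cortex_r[highEnd]))
  ## tumor present preoperatively, resected intraoperatively
  expect_gt(sum(m$tumor), 0)
  expect_equal(sum(pair@intra$masks$tumor), 0)
})

test_that("speech label follows the MD-elevation rule", {
  cfg <- studyConfig("alteration")
  cfg$effect$mdDeltaMean <- 0.6e-3; cfg$effect$mdDeltaSd <- 0
  hi <- makeSubjectPair(cfg, 5, simulate = FALSE)
  expect_true(hi@speechIncrease)
  cfg$effect$mdDeltaMean <- 0.05e-3
  lo <- makeSubjectPair(cfg, 5, simulate = FALSE)
  expect_false(lo@speechIncrease)
})
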