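## small two-ROI world shared by several gating tests
gateWorld <- function() {
  dims <- c(10L, 10L, 10L); vs <- 2.55
  roiA <- array(FALSE, dims); roiA[, , 1:2] <- TRUE
  roiB <- array(FALSE, dims); roiB[, , 9:10] <- TRUE
  cc <- array(FALSE, dims); cc[5:6, , 5:6] <- TRUE
  list(dims = dims, vs = vs, roiA = roiA, roiB = roiB, cc = cc)
}

test_that("AND/NOT waypoint logic keeps and removes correctly", {
  w <- gateWorld()
  through <- cbind(2.5, 2.5, seq(1, 25, by = 1))          # A to B
  blocked <- cbind(13, 13, seq(1, 25, by = 1))            # hits cc
  short <- cbind(2.5, 2.5, seq(1, 8, by = 1))             # misses B
  ss <- makeSSet(list(through, blocked, short), w$vs, w$dims)
  gate <- gateSpec(include = list(A = w$roiA, B = w$roiB),
                   exclude = list(cc = w$cc))
  kept <- applyGates(ss, gate)
  expect_equal(nStreamlines(kept), 1)
  expect_equal(streamlines(kept)[[1]], through)
  ## empty result flags a failed reconstruction
  none <- applyGates(makeSSet(list(short), w$vs, w$dims), gate)
  expect_equal(nStreamlines(none), 0)
  expect_true(none@metadata$reconstructionFailed)
})

test_that("gating matches the brute-force set-logic oracle", {
  set.seed(11)
  w <- gateWorld()
  lines <- replicate(100, randomLine(w$dims, w$vs, 20),
                     simplify = FALSE)
  ss <- makeSSet(lines, w$vs, w$dims)
  gate <- gateSpec(include = list(A = w$roiA, B = w$roiB),
                   exclude = list(cc = w$cc))
  kept <- applyGates(ss, gate)
  oracle <- oracleGate(lines, list(w$roiA, w$roiB), list(w$cc),
                       w$dims, w$vs)
  expect_identical(streamlines(kept), lines[oracle])
})

test_that("gating is idempotent and orients streamlines", {
  w <- gateWorld()
  up <- cbind(2.5, 2.5, seq(1, 25, by = 1))
  down <- up[rev(seq_len(nrow(up))), ]
  gate <- gateSpec(include = list(A = w$roiA, B = w$roiB),
                   endpointRois = c("A", "B"))
  ss <- makeSSet(list(up, down), w$vs, w$dims)
  g1 <- applyGates(ss, gate)
  ## both streamlines now start at the A end
  expect_true(all(vapply(streamlines(g1), function(m)
    m[1, 3] < m[nrow(m), 3], TRUE)))
  g2 <- applyGates(g1, gate)
  expect_identical(streamlines(g2), streamlines(g1))
})

test_that("d/nd classification follows the contralateral rule", {
  cfg <- phantomConfig(bundles = c("d_DRTT_left", "nd_DRTT_left"))
  pair <- makeSubjectPair(cfg, 17, simulate = FALSE)
  ds <- pair@pre
  seeds <- seedGrid(Reduce(`|`, ds$bundleMasks), cfg$voxelSize, 1.5)
  wb <- trackFibers(ds$peaks, ds$masks$white_matter, seeds,
                    trackingParams())
  gate <- gateSpec(include = list(dentate_l = ds$masks$dentate_l,
                                  thalamus = ds$masks$thalamus_l |
                                    ds$masks$thalamus_r,
                                  motor = ds$masks$motor_cortex_l |
                                    ds$masks$motor_cortex_r),
                   endpointRois = c("dentate_l", "motor"))
  gated <- applyGates(wb, gate)
  cls <- classifyDRTT(gated, "left",
                      list(left = ds$masks$motor_cortex_l,
                           right = ds$masks$motor_cortex_r))
  ## partition property
  nTot <- nStreamlines(gated)
  expect_equal(nStreamlines(cls$d_DRTT) + nStreamlines(cls$nd_DRTT) +
                 nStreamlines(cls$unclassified), nTot)
  expect_gt(nStreamlines(cls$d_DRTT), 0)
  expect_gt(nStreamlines(cls$nd_DRTT), 0)
  ## construction truth: a decussating streamline ends right of the
  ## midline, a non-decussating one left of it
  ext <- cfg$gridDim * cfg$voxelSize
  endX <- function(s) vapply(streamlines(s), function(m)
    m[nrow(m), 1], numeric(1))
  expect_true(all(endX(cls$d_DRTT) > ext[1] / 2))
  expect_true(all(endX(cls$nd_DRTT) < ext[1] / 2))
})

test_that("pure bundles classify entirely to their own class", {
  for (b in c("d_DRTT_left", "nd_DRTT_left")) {
    cfg <- phantomConfig(bundles = b)
    pair <- makeSubjectPair(cfg, 23, simulate = FALSE)
    ds <- pair@pre
    res <- tractshift:::processTimepoint(ds, cfg, trackingParams(),
                                         "s", "pre", micro = FALSE)
    expect_gt(nStreamlines(res$tracts[[b]]), 0)
  }
})

test_that("AF length filter follows the percentile definition", {
  ## cohort of 101 normalized medians 1.00..2.00: the first percentile
  ## under linear interpolation is 1.01
  lens <- seq(1, 2, by = 0.01)
  sets <- lapply(lens, function(L)
    makeSSet(list(cbind(0.5, 0.5, c(0, L))), vs = 1, dims = c(5L, 5L, 5L)))
  flt <- filterAF(sets, brainHeightsMm = rep(1, 101))
  expect_equal(flt$threshold, 1.01, tolerance = 1e-12)
  ## degenerate cohort: identical subjects, nothing removed
  same <- lapply(1:5, function(i)
    makeSSet(list(cbind(0.5, 0.5, c(0, 1.5))), vs = 1,
             dims = c(5L, 5L, 5L)))
  f2 <- filterAF(same, rep(1, 5))
  expect_equal(sum(f2$nRemoved), 0)
})

test_that("AF filter removes spurious short streamlines", {
  set.seed(3)
  ## genuine streamlines span the full bundle (tight length cluster);
  ## 10% spurious fragments at ~0.2x the normal length
  mkSubject <- function() {
    genuine <- replicate(90, {
      L <- 100 + rnorm(1, 0, 0.5)
      cbind(10 + rnorm(1), 10 + rnorm(1), seq(0, L, length.out = 50))
    }, simplify = FALSE)
    spurious <- replicate(10, {
      L <- runif(1, 18, 22)
      cbind(10 + rnorm(1), 10 + rnorm(1), seq(0, L, length.out = 12))
    }, simplify = FALSE)
    makeSSet(c(genuine, spurious), vs = 2.55, dims = c(20L, 20L, 60L))
  }
  sets <- replicate(12, mkSubject(), simplify = FALSE)
  heights <- rep(140, 12)
  flt <- filterAF(sets, heights)
  ## truth-label oracle: the filter must remove exactly the streamlines
  ## whose normalized length falls below the cohort threshold — all
  ## spurious fragments (far below any median) and nothing else than
  ## what the threshold dictates
  for (i in seq_along(sets)) {
    lensAll <- streamlineLengths(sets[[i]])
    kept <- streamlineLengths(flt$sets[[i]])
    expectKept <- lensAll[lensAll / heights[i] >= flt$threshold]
    expect_equal(sort(kept), sort(expectKept))
    expect_equal(sum(kept < 50), 0)          # every spurious removed
  }
  ## monotone in the percentile
  f5 <- filterAF(sets, heights, percentile = 5)
  expect_gte(sum(f5$nRemoved), sum(flt$nRemoved))
})
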