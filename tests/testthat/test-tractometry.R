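test_that("tract volume counts visited voxels", {
  vs <- 2.55; dims <- c(10L, 10L, 10L)
  wm <- array(TRUE, dims)
  ## one streamline crossing 5 distinct voxels along z
  m <- cbind(1, 1, (0:4) * vs + vs / 2)
  ss <- makeSSet(list(m), vs, dims)
  v <- tractVolume(ss, wm)
  expect_equal(v$volumeMm3, 5 * vs^3)
  expect_equal(v$volumeNorm, 100 * 5 / sum(wm))
  ## duplication changes nothing (union of voxels)
  v2 <- tractVolume(makeSSet(list(m, m), vs, dims), wm)
  expect_equal(v2$volumeMm3, v$volumeMm3)
  ## random set against the brute-force oracle
  set.seed(5)
  lines <- replicate(30, randomLine(dims, vs), simplify = FALSE)
  v3 <- tractVolume(makeSSet(lines, vs, dims), wm)
  expect_equal(v3$volumeMm3, oracleVolume(lines, dims, vs))
  expect_error(tractVolume(makeSSet(list(), vs, dims), wm), "empty")
})

test_that("diameter follows the cylinder-equivalent formula", {
  expect_equal(tractDiameter(pi, 1), 2)
  expect_equal(tractDiameter(4 * pi, 1), 4)   # 4x volume, 2x diameter
  expect_error(tractDiameter(10, 0), "length")
})

test_that("whole-tract stat averages across streamlines, not vertices", {
  vs <- 1; dims <- c(10L, 10L, 10L)
  map <- array(0.2, dims)
  map[, , 6:10] <- 0.4
  ## streamline 1: 4 vertices all in the 0.2 region; streamline 2: 20
  ## vertices all in the 0.4 region -> unweighted mean is 0.3
  m1 <- cbind(1.5, 1.5, seq(0.5, 3.5, by = 1))
  m2 <- cbind(2.5, 2.5, seq(5.5, 9.5, length.out = 20))
  ss <- makeSSet(list(m1, m2), vs, dims)
  expect_equal(wholeTractStat(ss, map)$mean, 0.3)
  expect_equal(wholeTractStat(ss, array(7, dims))$mean, 7)
  ## random case against the naive two-stage oracle
  set.seed(6)
  mapR <- array(runif(prod(dims)), dims)
  lines <- replicate(20, randomLine(dims, vs, 8), simplify = FALSE)
  oracle <- mean(vapply(lines, function(m) {
    v <- floor(m)
    mean(mapR[1 + v[, 1] + dims[1] * (v[, 2] + dims[2] * v[, 3])])
  }, numeric(1)))
  expect_equal(wholeTractStat(makeSSet(lines, vs, dims), mapR)$mean,
               oracle, tolerance = 1e-12)
})

test_that("segment-count rule reproduces 55 segments", {
  expect_identical(nSegmentsRule(138, 2.55), 55L)
  expect_identical(nSegmentsRule(10, 2.55), 4L)
})

test_that("centerline is the pointwise mean of resampled streamlines", {
  vs <- 1; dims <- c(20L, 20L, 20L)
  ## single streamline: centerline equals its own resampling
  m <- cbind(5, 5, seq(1, 15, by = 0.5))
  cl <- tractCenterline(makeSSet(list(m), vs, dims), nSegments = 7)
  expect_equal(nrow(cl), 8)
  expect_equal(cl[, 3], seq(1, 15, length.out = 8), tolerance = 1e-9)
  ## two parallel offset lines: centerline is the midline
  m1 <- cbind(4, 5, seq(1, 15, by = 1))
  m2 <- cbind(6, 5, seq(1, 15, by = 1))
  cl2 <- tractCenterline(makeSSet(list(m1, m2), vs, dims), 7)
  expect_equal(cl2[, 1], rep(5, 8), tolerance = 1e-9)
})

test_that("along-tract profile projects vertices to nearest segments", {
  vs <- 1; dims <- c(12L, 12L, 64L)
  n <- 55L
  ## straight bundle along z with a step map at arc fraction 0.30
  L <- 55
  lines <- lapply(seq(-1, 1, length.out = 9), function(off)
    cbind(6 + off, 6, seq(2, 2 + L, by = 0.5)))
  ss <- makeSSet(lines, vs, dims)
  map <- array(1, dims)
  map[, , seq_len(floor(2 + 0.30 * L))] <- 0   # low before 30% arc
  cl <- tractCenterline(ss, n)
  prof <- alongTractProfile(ss, map, cl)
  expect_equal(length(prof$profile), 55)
  ## constant map -> flat profile
  flat <- alongTractProfile(ss, array(3, dims), cl)
  expect_true(all(abs(flat$profile - 3) < 1e-12))
  ## the step lands between segments 16 and 17 (0.30 * 55 = 16.5)
  expect_lt(mean(prof$profile[1:14]), 0.2)
  expect_gt(mean(prof$profile[19:55]), 0.8)
  step <- which(diff(prof$profile > 0.5) == 1)
  expect_true(step %in% 15:18)
  ## vertex assignment equals the brute-force nearest-segment oracle
  mids <- (cl[-1, ] + cl[-nrow(cl), ]) / 2
  verts <- do.call(rbind, lines)
  expect_equal(as.integer(tractshift:::cpp_assign_nearest(verts, mids)),
               as.integer(oracleNearest(verts, mids)))
})

test_that("per-streamline means bound the whole-tract mean", {
  set.seed(8)
  vs <- 1; dims <- c(10L, 10L, 10L)
  map <- array(runif(prod(dims)), dims)
  lines <- replicate(15, randomLine(dims, vs, 10), simplify = FALSE)
  st <- wholeTractStat(makeSSet(lines, vs, dims), map)
  expect_gte(st$mean, min(st$perStreamline))
  expect_lte(st$mean, max(st$perStreamline))
})

test_that("normalized volume is invariant under joint translation", {
  set.seed(9)
  vs <- 2.55; dims <- c(12L, 12L, 12L)
  wm <- array(FALSE, dims); wm[3:8, 3:8, 3:8] <- TRUE
  lines <- replicate(10, sweep(randomLine(c(6L, 6L, 6L), vs), 2,
                               2 * vs, "+"), simplify = FALSE)
  v0 <- tractVolume(makeSSet(lines, vs, dims), wm)
  ## translate streamlines and mask together by whole voxels
  shift <- c(1L, 2L, 1L) * vs
  linesT <- lapply(lines, function(m) sweep(m, 2, shift, "+"))
  wmT <- array(FALSE, dims)
  wmT[3:8 + 1L, 3:8 + 2L, 3:8 + 1L] <- TRUE
  vT <- tractVolume(makeSSet(linesT, vs, dims), wmT)
  expect_equal(vT$volumeMm3, v0$volumeMm3)
  expect_equal(vT$volumeNorm, v0$volumeNorm)
})

test_that("the injected MD window appears in the right segments", {
  ## one noiseless subject with a localized MD elevation near the
  ## dentate end: the profile is elevated over the injected window
  ## (+/- 1 segment) and flat elsewhere
  cfg <- studyConfig("alteration")
  cfg$effect$mdDeltaMean <- 0.4e-3; cfg$effect$mdDeltaSd <- 0
  pair <- makeSubjectPair(cfg, 41, simulate = FALSE)
  for (tp in c("pre", "intra")) {
    ds <- slot(pair, tp)
    res <- tractshift:::processTimepoint(ds, cfg, trackingParams(),
                                         "s", tp, micro = FALSE)
    md <- array(NA_real_, cfg$gridDim)
    md[] <- tensorMD(ds$tensors)
    md[!ds$masks$brain] <- NA
    p <- tractProfile(res$tracts$d_DRTT_left, md, md,
                      ds$masks$white_matter)
    assign(paste0("prof_", tp), p@mdProfile)
  }
  delta <- prof_intra - prof_pre
  ns <- length(delta)
  centers <- (seq_len(ns) - 0.5) / ns
  win <- which(centers >= 0 & centers <= 0.25)
  pad <- seq_len(min(max(win) + 1L, ns))
  expect_gt(mean(delta[win], na.rm = TRUE), 0.25e-3)
  outside <- setdiff(seq_len(ns), pad)
  expect_lt(max(abs(delta[outside]), na.rm = TRUE), 0.1e-3)
})
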