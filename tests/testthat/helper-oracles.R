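## Independent brute-force oracles and tiny fixture builders. The
## oracles deliberately use the most naive formulation available so they
## stay independent of the implementation paths they check.

## exhaustive two-sided signed-rank p over all 2^n sign assignments
oracleSignedRankP <- function(pre, intra) {
  d <- intra - pre
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  vObs <- sum(r[d > 0])
  ev <- n * (n + 1) / 4
  stats <- apply(expand.grid(rep(list(c(0, 1)), n)), 1,
                 function(s) sum(r[s == 1]))
  mean(abs(stats - ev) >= abs(vObs - ev) - 1e-9)
}

## exhaustive rank-sum p over all group assignments
oracleRankSumP <- function(x, y) {
  all <- c(x, y)
  r <- rank(all)
  nx <- length(x)
  wObs <- sum(r[seq_len(nx)])
  ev <- nx * (length(all) + 1) / 2
  combs <- utils::combn(length(all), nx)
  stats <- apply(combs, 2, function(i) sum(r[i]))
  mean(abs(stats - ev) >= abs(wObs - ev) - 1e-9)
}

## Benjamini-Hochberg step-up written straight from its definition
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) adj[o[i]] <- p[o[i]] * m / i
  ## monotonicity from the largest rank downwards
  for (i in rev(seq_len(m - 1)))
    adj[o[i]] <- min(adj[o[i]], adj[o[i + 1]])
  pmin(adj, 1)
}

## naive gate logic: loop every streamline and mask
oracleGate <- function(lines, include, exclude, dims, vs) {
  inVoxel <- function(m, mask) {
    v <- floor(m / vs)
    ok <- v[, 1] >= 0 & v[, 2] >= 0 & v[, 3] >= 0 &
      v[, 1] < dims[1] & v[, 2] < dims[2] & v[, 3] < dims[3]
    any(mask[1 + v[ok, 1] + dims[1] * (v[ok, 2] + dims[2] * v[ok, 3])])
  }
  vapply(lines, function(m) {
    all(vapply(include, function(msk) inVoxel(m, msk), TRUE)) &&
      !any(vapply(exclude, function(msk) inVoxel(m, msk), TRUE))
  }, TRUE)
}

## naive visited-voxel volume
oracleVolume <- function(lines, dims, vs) {
  keys <- unlist(lapply(lines, function(m) {
    v <- floor(m / vs)
    ok <- v[, 1] >= 0 & v[, 2] >= 0 & v[, 3] >= 0 &
      v[, 1] < dims[1] & v[, 2] < dims[2] & v[, 3] < dims[3]
    paste(v[ok, 1], v[ok, 2], v[ok, 3])
  }))
  length(unique(keys)) * vs^3
}

## naive nearest-midpoint assignment (ties toward lower index)
oracleNearest <- function(points, mids) {
  apply(points, 1, function(p) {
    d <- colSums((t(mids) - p)^2)
    which(d == min(d))[1]
  })
}

## naive lattice enumeration for the seed grid
oracleSeedGrid <- function(mask, vs, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  lo <- (apply(idx, 2, min) - 1L) * vs
  hi <- apply(idx, 2, max) * vs
  pts <- expand.grid(x = seq(lo[1], hi[1] + 1e-9, by = spacing),
                     y = seq(lo[2], hi[2] + 1e-9, by = spacing),
                     z = seq(lo[3], hi[3] + 1e-9, by = spacing))
  keep <- apply(pts, 1, function(p) {
    v <- floor(p / vs)
    all(v >= 0) && all(v < dim(mask)) &&
      mask[1 + v[1] + dim(mask)[1] * (v[2] + dim(mask)[2] * v[3])]
  })
  as.matrix(pts[keep, , drop = FALSE])
}

## StreamlineSet from a plain list of polylines
makeSSet <- function(lines, vs = 2.55, dims = c(10L, 10L, 10L),
                     metadata = list()) {
  lens <- vapply(lines, function(m)
    sum(sqrt(rowSums(diff(m)^2))), numeric(1))
  new("StreamlineSet", streamlines = lines, voxelSize = vs,
      dim = as.integer(dims), info = data.frame(length = lens),
      metadata = metadata)
}

## random gentle polyline inside a grid
randomLine <- function(dims, vs, nv = 12) {
  start <- runif(3, 2, dims * vs - 2)
  step <- rnorm(3); step <- step / sqrt(sum(step^2))
  t(vapply(seq_len(nv), function(i)
    pmin(pmax(start + (i - 1) * step + rnorm(3, 0, 0.2), 0.1),
         dims * vs - 0.1), numeric(3)))
}

## uniform single-peak field pointing along z
uniformZField <- function(dims, vs = 2.55, amp = 1) {
  nv <- prod(dims)
  dirs <- array(0, c(dims, 1L, 3L))
  dirs[seq_len(nv) + 2L * nv] <- 1      # z component
  new("PeakVolume", directions = dirs,
      amplitudes = array(amp, c(dims, 1L)),
      voxelSize = vs, dim = as.integer(dims))
}
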