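// Deterministic FACT streamline propagation and along-tract helpers.
//
// Conventions (shared with the R layer):
//  * voxel indices are 0-based here; world = (index + 0.5) * voxelSize
//    (voxel-center convention), so the voxel containing a point p is
//    floor(p / voxelSize)
//  * peak directions are sign-ambiguous (d and -d are the same peak)
//  * dirs is an R array of dim c(X, Y, Z, K, 3); amps c(X, Y, Z, K)

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz, K;
  double vs;
  R_xlen_t nvox;
  const double* dirs;
  const double* amps;
  const int* wm;

  // linear 0-based voxel index of world point p, or -1 if outside grid
  inline R_xlen_t voxel(const double* p) const {
    int ix = (int)std::floor(p[0] / vs);
    int iy = (int)std::floor(p[1] / vs);
    int iz = (int)std::floor(p[2] / vs);
    if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz)
      return -1;
    return (R_xlen_t)ix + (R_xlen_t)nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz);
  }
  inline double amp(R_xlen_t v, int k) const { return amps[v + nvox * k]; }
  inline double dir(R_xlen_t v, int k, int c) const {
    return dirs[v + nvox * ((R_xlen_t)k + (R_xlen_t)K * c)];
  }
};

// one half-track from seed along initial direction d0; appends vertices
// (excluding the seed itself) to out
void halfTrack(const Grid& g, const double* seed, const double* d0,
               double step, double ampFloor, double cosMaxTurn,
               int maxSteps, std::vector<double>& out) {
  double pos[3] = { seed[0], seed[1], seed[2] };
  double dir[3] = { d0[0], d0[1], d0[2] };
  for (int i = 0; i < maxSteps; ++i) {
    double np[3] = { pos[0] + step * dir[0],
                     pos[1] + step * dir[1],
                     pos[2] + step * dir[2] };
    R_xlen_t v = g.voxel(np);
    out.push_back(np[0]); out.push_back(np[1]); out.push_back(np[2]);
    if (v < 0) break;              // left the grid: retain vertex, stop
    if (!g.wm[v]) break;           // GM-WM interface: retain vertex, stop
    // FACT: peak of the current voxel maximally aligned with incoming
    // direction (sign-resolved); ties broken toward the lower peak index
    int best = -1; double bestAbs = -1.0, bestDot = 0.0;
    for (int k = 0; k < g.K; ++k) {
      double d = dir[0] * g.dir(v, k, 0) + dir[1] * g.dir(v, k, 1) +
                 dir[2] * g.dir(v, k, 2);
      double a = std::fabs(d);
      if (a > bestAbs) { bestAbs = a; bestDot = d; best = k; }
    }
    if (best < 0 || g.amp(v, best) < ampFloor) break;  // amplitude floor
    if (bestAbs < cosMaxTurn) break;                   // turn angle rule
    double s = (bestDot >= 0.0) ? 1.0 : -1.0;
    dir[0] = s * g.dir(v, best, 0);
    dir[1] = s * g.dir(v, best, 1);
    dir[2] = s * g.dir(v, best, 2);
    pos[0] = np[0]; pos[1] = np[1]; pos[2] = np[2];
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_track(NumericVector dirs, NumericVector amps, IntegerVector dim,
               double voxelSize, IntegerVector wm, NumericMatrix seeds,
               double step, double ampFloor, double maxTurnDeg,
               double minLengthMm, int maxSteps) {
  Grid g;
  g.nx = dim[0]; g.ny = dim[1]; g.nz = dim[2];
  g.vs = voxelSize;
  g.nvox = (R_xlen_t)g.nx * g.ny * g.nz;
  g.K = (int)(amps.size() / g.nvox);
  g.dirs = dirs.begin(); g.amps = amps.begin(); g.wm = wm.begin();
  const double cosMaxTurn = std::cos(maxTurnDeg * M_PI / 180.0);

  int skippedSeeds = 0, droppedShort = 0;
  const int nSeed = seeds.nrow();
  List pool(nSeed);   // preallocated; kept entries compacted at the end
  int nKept = 0;
  std::vector<double> fwd, bwd;
  for (int s = 0; s < nSeed; ++s) {
    double seed[3] = { seeds(s, 0), seeds(s, 1), seeds(s, 2) };
    R_xlen_t v = g.voxel(seed);
    if (v < 0 || !g.wm[v]) { ++skippedSeeds; continue; }
    // first-step direction: the voxel's largest-amplitude peak
    int k0 = 0;
    for (int k = 1; k < g.K; ++k) if (g.amp(v, k) > g.amp(v, k0)) k0 = k;
    if (g.amp(v, k0) < ampFloor) { ++droppedShort; continue; }
    double d0[3] = { g.dir(v, k0, 0), g.dir(v, k0, 1), g.dir(v, k0, 2) };
    double d0m[3] = { -d0[0], -d0[1], -d0[2] };
    fwd.clear(); bwd.clear();
    halfTrack(g, seed, d0, step, ampFloor, cosMaxTurn, maxSteps, fwd);
    halfTrack(g, seed, d0m, step, ampFloor, cosMaxTurn, maxSteps, bwd);
    const int nb = (int)(bwd.size() / 3), nf = (int)(fwd.size() / 3);
    const int n = nb + 1 + nf;
    if ((double)(n - 1) * step < minLengthMm) { ++droppedShort; continue; }
    NumericMatrix m(n, 3);
    for (int i = 0; i < nb; ++i) {           // backward half, reversed
      int r = nb - 1 - i;
      m(i, 0) = bwd[3 * r]; m(i, 1) = bwd[3 * r + 1]; m(i, 2) = bwd[3 * r + 2];
    }
    m(nb, 0) = seed[0]; m(nb, 1) = seed[1]; m(nb, 2) = seed[2];
    for (int i = 0; i < nf; ++i) {
      m(nb + 1 + i, 0) = fwd[3 * i];
      m(nb + 1 + i, 1) = fwd[3 * i + 1];
      m(nb + 1 + i, 2) = fwd[3 * i + 2];
    }
    pool[nKept++] = m;
  }
  List lines(nKept);
  for (int i = 0; i < nKept; ++i) lines[i] = pool[i];
  return List::create(_["streamlines"] = lines,
                      _["skippedSeeds"] = skippedSeeds,
                      _["droppedShort"] = droppedShort);
}

// Lattice seed points at `spacing` over the bounding box [lo, hi] (mm),
// kept when the containing voxel is in-mask. Order: x fastest, then y,
// then z (matching expand.grid).
// [[Rcpp::export]]
NumericMatrix cpp_seed_grid(IntegerVector mask, IntegerVector dim,
                            double vs, double spacing,
                            NumericVector lo, NumericVector hi) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> keep;
  for (double z = lo[2]; z <= hi[2] + 1e-9; z += spacing)
    for (double y = lo[1]; y <= hi[1] + 1e-9; y += spacing)
      for (double x = lo[0]; x <= hi[0] + 1e-9; x += spacing) {
        int ix = (int)std::floor(x / vs), iy = (int)std::floor(y / vs),
            iz = (int)std::floor(z / vs);
        if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny ||
            iz >= nz) continue;
        if (mask[(R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz)]) {
          keep.push_back(x); keep.push_back(y); keep.push_back(z);
        }
      }
  const int n = (int)(keep.size() / 3);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = keep[3 * i]; out(i, 1) = keep[3 * i + 1];
    out(i, 2) = keep[3 * i + 2];
  }
  return out;
}

// For voxel centers in the spine bounding box (+radius), the nearest
// spine sample and its distance; returns only voxels within radius.
// flatEnds drops voxels whose nearest sample is a spine endpoint
// (truncating the spherical end caps).
// [[Rcpp::export]]
List cpp_tube_voxels(NumericMatrix spine, double radius,
                     IntegerVector dim, double vs,
                     bool flatEnds = false) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], ns = spine.nrow();
  double mn[3] = {R_PosInf, R_PosInf, R_PosInf},
         mx[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < ns; ++i)
    for (int c = 0; c < 3; ++c) {
      if (spine(i, c) < mn[c]) mn[c] = spine(i, c);
      if (spine(i, c) > mx[c]) mx[c] = spine(i, c);
    }
  int lo[3], hi[3], dims[3] = {nx, ny, nz};
  for (int c = 0; c < 3; ++c) {
    lo[c] = std::max(0, (int)std::floor((mn[c] - radius) / vs) - 1);
    hi[c] = std::min(dims[c] - 1, (int)std::ceil((mx[c] + radius) / vs) + 1);
  }
  std::vector<int> idx, nearest;
  const double r2 = radius * radius;
  for (int k = lo[2]; k <= hi[2]; ++k)
    for (int j = lo[1]; j <= hi[1]; ++j)
      for (int i = lo[0]; i <= hi[0]; ++i) {
        double cx = (i + 0.5) * vs, cy = (j + 0.5) * vs,
               cz = (k + 0.5) * vs;
        double bestD = R_PosInf; int best = -1;
        for (int s = 0; s < ns; ++s) {
          double dx = cx - spine(s, 0), dy = cy - spine(s, 1),
                 dz = cz - spine(s, 2);
          double d = dx * dx + dy * dy + dz * dz;
          if (d < bestD) { bestD = d; best = s; }
        }
        if (bestD <= r2 && !(flatEnds && (best == 0 || best == ns - 1))) {
          idx.push_back(1 + i + nx * (j + ny * k));
          nearest.push_back(best + 1);
        }
      }
  return List::create(_["index"] = wrap(idx), _["nearest"] = wrap(nearest));
}

// Voxel index (1-based, NA outside the grid) and streamline id of every
// vertex of a list of polylines, concatenated in order.
// [[Rcpp::export]]
List cpp_stack_info(List streamlines, IntegerVector dim, double vs) {
  const int S = streamlines.size();
  R_xlen_t total = 0;
  for (int s = 0; s < S; ++s)
    total += as<NumericMatrix>(streamlines[s]).nrow();
  IntegerVector vox(total), id(total);
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t pos = 0;
  for (int s = 0; s < S; ++s) {
    NumericMatrix m = streamlines[s];
    const int n = m.nrow();
    for (int i = 0; i < n; ++i, ++pos) {
      id[pos] = s + 1;
      int ix = (int)std::floor(m(i, 0) / vs);
      int iy = (int)std::floor(m(i, 1) / vs);
      int iz = (int)std::floor(m(i, 2) / vs);
      if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz)
        vox[pos] = NA_INTEGER;
      else
        vox[pos] = 1 + ix + nx * (iy + ny * iz);
    }
  }
  return List::create(_["vox"] = vox, _["id"] = id);
}

// One-pass accumulation of tract profile statistics: per-segment sums
// and counts for two scalar maps, per-streamline sums/counts for the
// across-streamline means, and the visited-voxel count.
// [[Rcpp::export]]
List cpp_profile_stats(IntegerVector vox, IntegerVector id,
                       IntegerVector seg, NumericVector map1,
                       NumericVector map2, int nSeg, int nStream) {
  NumericVector segSum1(nSeg), segSum2(nSeg);
  IntegerVector segCnt1(nSeg), segCnt2(nSeg);
  NumericVector lineSum1(nStream), lineSum2(nStream);
  IntegerVector lineCnt1(nStream), lineCnt2(nStream);
  std::vector<char> seen(map1.size(), 0);
  int nVisited = 0;
  const R_xlen_t n = vox.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (vox[i] == NA_INTEGER) continue;
    const int v = vox[i] - 1;
    if (!seen[v]) { seen[v] = 1; ++nVisited; }
    const int s = seg[i] - 1, l = id[i] - 1;
    const double m1 = map1[v], m2 = map2[v];
    if (!ISNAN(m1)) {
      segSum1[s] += m1; ++segCnt1[s];
      lineSum1[l] += m1; ++lineCnt1[l];
    }
    if (!ISNAN(m2)) {
      segSum2[s] += m2; ++segCnt2[s];
      lineSum2[l] += m2; ++lineCnt2[l];
    }
  }
  return List::create(_["segSum1"] = segSum1, _["segCnt1"] = segCnt1,
                      _["segSum2"] = segSum2, _["segCnt2"] = segCnt2,
                      _["lineSum1"] = lineSum1, _["lineCnt1"] = lineCnt1,
                      _["lineSum2"] = lineSum2, _["lineCnt2"] = lineCnt2,
                      _["nVisited"] = nVisited);
}

// Streamline-level AND/NOT gate evaluation in one pass: a streamline is
// kept when it touches every include mask and no exclude mask. Masks
// are logical vectors over the (1-based) voxel index space.
// [[Rcpp::export]]
LogicalVector cpp_gate_keep(IntegerVector vox, IntegerVector id,
                            int nStream, List include, List exclude) {
  const int nInc = include.size(), nExc = exclude.size();
  std::vector<const int*> inc(nInc), exc(nExc);
  for (int k = 0; k < nInc; ++k)
    inc[k] = LOGICAL(as<LogicalVector>(include[k]));
  for (int k = 0; k < nExc; ++k)
    exc[k] = LOGICAL(as<LogicalVector>(exclude[k]));
  // bit flags per streamline: include hits in low bits, exclude above
  std::vector<unsigned int> flags(nStream, 0);
  const R_xlen_t n = vox.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (vox[i] == NA_INTEGER) continue;
    const int v = vox[i] - 1, l = id[i] - 1;
    unsigned int f = flags[l];
    for (int k = 0; k < nInc; ++k)
      if (inc[k][v] == TRUE) f |= (1u << k);
    for (int k = 0; k < nExc; ++k)
      if (exc[k][v] == TRUE) f |= (1u << (nInc + k));
    flags[l] = f;
  }
  const unsigned int needed = (nInc >= 32) ? ~0u : ((1u << nInc) - 1u);
  LogicalVector keep(nStream);
  for (int l = 0; l < nStream; ++l)
    keep[l] = ((flags[l] & needed) == needed) &&
              ((flags[l] >> nInc) == 0u);
  return keep;
}

// Orient polylines so vertex 1 is nearest the anchor point: returns the
// input list with reversed copies where the last vertex was closer.
// [[Rcpp::export]]
List cpp_orient_toward(List streamlines, NumericVector anchor) {
  const int S = streamlines.size();
  List out(S);
  for (int s = 0; s < S; ++s) {
    NumericMatrix m = streamlines[s];
    const int n = m.nrow();
    double dF = 0, dL = 0;
    for (int c = 0; c < 3; ++c) {
      double a = m(0, c) - anchor[c], b = m(n - 1, c) - anchor[c];
      dF += a * a; dL += b * b;
    }
    if (dL < dF) {
      NumericMatrix r(n, 3);
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c) r(i, c) = m(n - 1 - i, c);
      out[s] = r;
    } else out[s] = m;
  }
  return out;
}

// Number of distinct streamlines with at least one vertex in the mask.
// [[Rcpp::export]]
int cpp_mask_touch_count(IntegerVector vox, IntegerVector id,
                         int nStream, LogicalVector mask) {
  std::vector<char> touched(nStream, 0);
  const int* m = LOGICAL(mask);
  int n = 0;
  for (R_xlen_t i = 0; i < vox.size(); ++i) {
    if (vox[i] == NA_INTEGER) continue;
    if (m[vox[i] - 1] == TRUE && !touched[id[i] - 1]) {
      touched[id[i] - 1] = 1; ++n;
    }
  }
  return n;
}

// Number of distinct (1-based) voxel indices, ignoring NAs.
// [[Rcpp::export]]
int cpp_visited_count(IntegerVector vox, int nvox) {
  std::vector<char> seen(nvox, 0);
  int n = 0;
  for (R_xlen_t i = 0; i < vox.size(); ++i) {
    if (vox[i] == NA_INTEGER) continue;
    if (!seen[vox[i] - 1]) { seen[vox[i] - 1] = 1; ++n; }
  }
  return n;
}

// Voxel index (1-based, NA outside) of the LAST vertex of each polyline.
// [[Rcpp::export]]
IntegerVector cpp_end_voxels(List streamlines, IntegerVector dim,
                             double vs) {
  const int S = streamlines.size();
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out(S);
  for (int s = 0; s < S; ++s) {
    NumericMatrix m = streamlines[s];
    const int i = m.nrow() - 1;
    int ix = (int)std::floor(m(i, 0) / vs);
    int iy = (int)std::floor(m(i, 1) / vs);
    int iz = (int)std::floor(m(i, 2) / vs);
    if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz)
      out[s] = NA_INTEGER;
    else
      out[s] = 1 + ix + nx * (iy + ny * iz);
  }
  return out;
}

// Nearest segment-midpoint assignment for every vertex of a list of
// polylines (1-based segment ids, concatenated; ties toward lower index).
// [[Rcpp::export]]
IntegerVector cpp_assign_segments(List streamlines, NumericMatrix mids) {
  const int S = streamlines.size(), nm = mids.nrow();
  R_xlen_t total = 0;
  for (int s = 0; s < S; ++s)
    total += as<NumericMatrix>(streamlines[s]).nrow();
  IntegerVector out(total);
  R_xlen_t pos = 0;
  for (int s = 0; s < S; ++s) {
    NumericMatrix m = streamlines[s];
    const int n = m.nrow();
    for (int i = 0; i < n; ++i, ++pos) {
      double px = m(i, 0), py = m(i, 1), pz = m(i, 2);
      int best = 0; double bestD = R_PosInf;
      for (int j = 0; j < nm; ++j) {
        double dx = px - mids(j, 0), dy = py - mids(j, 1),
               dz = pz - mids(j, 2);
        double d = dx * dx + dy * dy + dz * dz;
        if (d < bestD) { bestD = d; best = j; }
      }
      out[pos] = best + 1;
    }
  }
  return out;
}

// Nearest segment-midpoint assignment (1-based); ties toward lower index.
// [[Rcpp::export]]
IntegerVector cpp_assign_nearest(NumericMatrix points, NumericMatrix mids) {
  const int n = points.nrow(), m = mids.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double px = points(i, 0), py = points(i, 1), pz = points(i, 2);
    int best = 0; double bestD = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double dx = px - mids(j, 0), dy = py - mids(j, 1), dz = pz - mids(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < bestD) { bestD = d; best = j; }
    }
    out[i] = best + 1;
  }
  return out;
}

// Resample each polyline to nPoints equidistant-in-arc-length points.
// Returns an array of dim c(nPoints, 3, nStreamlines).
// [[Rcpp::export]]
NumericVector cpp_resample(List streamlines, int nPoints) {
  const int S = streamlines.size();
  NumericVector out((R_xlen_t)nPoints * 3 * S);
  std::vector<double> cum;
  for (int s = 0; s < S; ++s) {
    NumericMatrix m = streamlines[s];
    const int n = m.nrow();
    cum.assign(n, 0.0);
    for (int i = 1; i < n; ++i) {
      double dx = m(i, 0) - m(i - 1, 0), dy = m(i, 1) - m(i - 1, 1),
             dz = m(i, 2) - m(i - 1, 2);
      cum[i] = cum[i - 1] + std::sqrt(dx * dx + dy * dy + dz * dz);
    }
    const double L = cum[n - 1];
    int seg = 0;
    for (int j = 0; j < nPoints; ++j) {
      double t = (nPoints == 1) ? 0.0 : L * j / (nPoints - 1);
      double x, y, z;
      if (n == 1 || L <= 0.0) {
        x = m(0, 0); y = m(0, 1); z = m(0, 2);
      } else {
        while (seg < n - 2 && cum[seg + 1] < t) ++seg;
        double denom = cum[seg + 1] - cum[seg];
        double w = (denom > 0.0) ? (t - cum[seg]) / denom : 0.0;
        if (w < 0.0) w = 0.0;
        if (w > 1.0) w = 1.0;
        x = m(seg, 0) + w * (m(seg + 1, 0) - m(seg, 0));
        y = m(seg, 1) + w * (m(seg + 1, 1) - m(seg, 1));
        z = m(seg, 2) + w * (m(seg + 1, 2) - m(seg, 2));
      }
      out[(R_xlen_t)j + (R_xlen_t)nPoints * (0 + 3 * (R_xlen_t)s)] = x;
      out[(R_xlen_t)j + (R_xlen_t)nPoints * (1 + 3 * (R_xlen_t)s)] = y;
      out[(R_xlen_t)j + (R_xlen_t)nPoints * (2 + 3 * (R_xlen_t)s)] = z;
    }
  }
  out.attr("dim") = IntegerVector::create(nPoints, 3, S);
  return out;
}
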