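#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact voxel-intersection (Siddon-style) line integral of an attenuation
// map along the segment from `S` to `P`, both in world mm.  `mu` is a 3D
// array in units of 1/mm; voxel (i,j,k) (0-based here) occupies the cell
// centred at org + i*sp with half-width sp/2.  Returns the dimensionless
// integral of mu * dl over the part of the segment inside the grid.
static double ray_integral(const double *mu, const int *d, const double *sp,
                           const double *org, const double *S, const double *P) {
  double dir[3];
  double len2 = 0.0;
  for (int a = 0; a < 3; ++a) {
    dir[a] = P[a] - S[a];
    len2 += dir[a] * dir[a];
  }
  double len = std::sqrt(len2);
  if (len == 0.0) return 0.0;

  // Clip the parametric interval [0,1] against the grid bounding box.
  double amin = 0.0, amax = 1.0;
  for (int a = 0; a < 3; ++a) {
    double lo = org[a] - 0.5 * sp[a];
    double hi = org[a] + (d[a] - 0.5) * sp[a];
    if (std::fabs(dir[a]) < 1e-12) {
      if (S[a] < lo || S[a] > hi) return 0.0;
    } else {
      double t1 = (lo - S[a]) / dir[a];
      double t2 = (hi - S[a]) / dir[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > amin) amin = t1;
      if (t2 < amax) amax = t2;
    }
  }
  if (amin >= amax) return 0.0;

  // Entry voxel, step direction and the parametric increment per voxel.
  const double eps = 1e-9 * (amax - amin);
  int idx[3], step[3];
  double anext[3], dalpha[3];
  for (int a = 0; a < 3; ++a) {
    double pos = S[a] + (amin + eps) * dir[a];
    int i = (int)std::floor((pos - (org[a] - 0.5 * sp[a])) / sp[a]);
    if (i < 0) i = 0;
    if (i >= d[a]) i = d[a] - 1;
    idx[a] = i;
    if (dir[a] > 1e-12) {
      step[a] = 1;
      double plane = org[a] - 0.5 * sp[a] + (i + 1) * sp[a];
      anext[a] = (plane - S[a]) / dir[a];
      dalpha[a] = sp[a] / dir[a];
    } else if (dir[a] < -1e-12) {
      step[a] = -1;
      double plane = org[a] - 0.5 * sp[a] + i * sp[a];
      anext[a] = (plane - S[a]) / dir[a];
      dalpha[a] = -sp[a] / dir[a];
    } else {
      step[a] = 0;
      anext[a] = R_PosInf;
      dalpha[a] = R_PosInf;
    }
  }

  double total = 0.0;
  double acur = amin;
  const long nx = d[0], nxy = (long)d[0] * d[1];
  while (acur < amax - 1e-15) {
    double aexit = anext[0];
    if (anext[1] < aexit) aexit = anext[1];
    if (anext[2] < aexit) aexit = anext[2];
    if (aexit > amax) aexit = amax;
    double seg = (aexit - acur) * len;
    if (seg > 0.0) {
      long lin = idx[0] + nx * idx[1] + nxy * idx[2];
      total += mu[lin] * seg;
    }
    if (aexit >= amax) break;
    for (int a = 0; a < 3; ++a) {
      if (anext[a] <= aexit + 1e-15) {
        idx[a] += step[a];
        anext[a] += dalpha[a];
        if (idx[a] < 0 || idx[a] >= d[a]) return total;
      }
    }
    acur = aexit;
  }
  return total;
}

// [[Rcpp::export]]
NumericVector radiological_paths_cpp(NumericVector mu, IntegerVector dims,
                                     NumericVector spacing, NumericVector origin,
                                     NumericVector source, NumericMatrix points) {
  const int n = points.nrow();
  NumericVector out(n);
  int d[3] = {dims[0], dims[1], dims[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  double S[3] = {source[0], source[1], source[2]};
  const double *pm = mu.begin();
  for (int i = 0; i < n; ++i) {
    double P[3] = {points(i, 0), points(i, 1), points(i, 2)};
    out[i] = ray_integral(pm, d, sp, org, S, P);
  }
  return out;
}

// 6-connected component labelling of a 3D binary mask (flood fill).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz, nxy = (long)nx * ny;
  IntegerVector lab(n, 0);
  std::vector<long> stack;
  int cur = 0;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    stack.clear();
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      long v = stack.back();
      stack.pop_back();
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / nxy);
      const long nb[6] = {v - 1, v + 1, v - nx, v + nx, v - nxy, v + nxy};
      const bool ok[6] = {i > 0, i < nx - 1, j > 0, j < ny - 1, k > 0, k < nz - 1};
      for (int t = 0; t < 6; ++t) {
        if (ok[t] && mask[nb[t]] && lab[nb[t]] == 0) {
          lab[nb[t]] = cur;
          stack.push_back(nb[t]);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
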