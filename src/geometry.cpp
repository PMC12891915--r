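#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Moller-Trumbore ray/triangle intersection. Returns t (>0) or -1 if no hit.
static inline double ray_tri(const double *o, const double *d,
                             const double *a, const double *b, const double *c) {
  const double eps = 1e-12;
  double e1[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double e2[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double p[3] = {d[1] * e2[2] - d[2] * e2[1],
                 d[2] * e2[0] - d[0] * e2[2],
                 d[0] * e2[1] - d[1] * e2[0]};
  double det = e1[0] * p[0] + e1[1] * p[1] + e1[2] * p[2];
  if (std::fabs(det) < eps) return -1.0;
  double inv = 1.0 / det;
  double s[3] = {o[0] - a[0], o[1] - a[1], o[2] - a[2]};
  double u = (s[0] * p[0] + s[1] * p[1] + s[2] * p[2]) * inv;
  if (u < -1e-9 || u > 1.0 + 1e-9) return -1.0;
  double q[3] = {s[1] * e1[2] - s[2] * e1[1],
                 s[2] * e1[0] - s[0] * e1[2],
                 s[0] * e1[1] - s[1] * e1[0]};
  double v = (d[0] * q[0] + d[1] * q[1] + d[2] * q[2]) * inv;
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return -1.0;
  double t = (e2[0] * q[0] + e2[1] * q[1] + e2[2] * q[2]) * inv;
  return (t > eps) ? t : -1.0;
}

// For each ray (one origin, many directions): number of hits, nearest and
// farthest positive intersection distance. Columns: nhits, tmin, tmax.
// [[Rcpp::export]]
NumericMatrix cpp_ray_mesh(NumericVector origin, NumericMatrix dirs,
                           NumericMatrix V, IntegerMatrix F) {
  int nd = dirs.nrow(), nf = F.nrow();
  NumericMatrix out(nd, 3);
  std::vector<double> ta(nf * 9);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) {
      int iv = F(f, k);
      ta[9*f + 3*k]     = V(iv, 0);
      ta[9*f + 3*k + 1] = V(iv, 1);
      ta[9*f + 3*k + 2] = V(iv, 2);
    }
  double o[3] = {origin[0], origin[1], origin[2]};
  for (int r = 0; r < nd; ++r) {
    double d[3] = {dirs(r, 0), dirs(r, 1), dirs(r, 2)};
    int nh = 0; double tmin = R_PosInf, tmax = -1.0;
    for (int f = 0; f < nf; ++f) {
      double t = ray_tri(o, d, &ta[9*f], &ta[9*f+3], &ta[9*f+6]);
      if (t > 0) {
        ++nh;
        if (t < tmin) tmin = t;
        if (t > tmax) tmax = t;
      }
    }
    out(r, 0) = nh;
    out(r, 1) = (nh > 0) ? tmin : NA_REAL;
    out(r, 2) = (nh > 0) ? tmax : NA_REAL;
  }
  return out;
}

// Exact point -> triangle squared distance (Eberly's region decomposition).
static double pt_tri_sq(const double *p, const double *a,
                        const double *b, const double *c) {
  double ab[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double ac[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double ap[3] = {p[0]-a[0], p[1]-a[1], p[2]-a[2]};
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  double px = a[0], py = a[1], pz = a[2];
  if (d1 <= 0 && d2 <= 0) { /* vertex a */ }
  else {
    double bp[3] = {p[0]-b[0], p[1]-b[1], p[2]-b[2]};
    double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    if (d3 >= 0 && d4 <= d3) { px=b[0]; py=b[1]; pz=b[2]; }
    else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double v = d1 / (d1 - d3);
        px = a[0] + v*ab[0]; py = a[1] + v*ab[1]; pz = a[2] + v*ab[2];
      } else {
        double cp[3] = {p[0]-c[0], p[1]-c[1], p[2]-c[2]};
        double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
        double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
        if (d6 >= 0 && d5 <= d6) { px=c[0]; py=c[1]; pz=c[2]; }
        else {
          double vb = d5*d2 - d1*d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) {
            double w = d2 / (d2 - d6);
            px = a[0] + w*ac[0]; py = a[1] + w*ac[1]; pz = a[2] + w*ac[2];
          } else {
            double va = d3*d6 - d5*d4;
            if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              px = b[0] + w*(c[0]-b[0]); py = b[1] + w*(c[1]-b[1]); pz = b[2] + w*(c[2]-b[2]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              px = a[0] + v*ab[0] + w*ac[0];
              py = a[1] + v*ab[1] + w*ac[1];
              pz = a[2] + v*ab[2] + w*ac[2];
            }
          }
        }
      }
    }
  }
  double dx = p[0]-px, dy = p[1]-py, dz = p[2]-pz;
  return dx*dx + dy*dy + dz*dz;
}

// Min distance from each query point to a triangle soup.
// [[Rcpp::export]]
NumericVector cpp_points_mesh_dist(NumericMatrix P, NumericMatrix V,
                                   IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  NumericVector out(np);
  // per-face centroid + circumradius bound for early reject
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  for (int f = 0; f < nf; ++f) {
    int i0=F(f,0), i1=F(f,1), i2=F(f,2);
    cx[f] = (V(i0,0)+V(i1,0)+V(i2,0))/3.0;
    cy[f] = (V(i0,1)+V(i1,1)+V(i2,1))/3.0;
    cz[f] = (V(i0,2)+V(i1,2)+V(i2,2))/3.0;
    double r2 = 0;
    for (int k = 0; k < 3; ++k) {
      int iv = F(f,k);
      double dx=V(iv,0)-cx[f], dy=V(iv,1)-cy[f], dz=V(iv,2)-cz[f];
      double d2 = dx*dx+dy*dy+dz*dz;
      if (d2 > r2) r2 = d2;
    }
    rad[f] = std::sqrt(r2);
  }
  std::vector<double> ta(nf * 9);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) {
      int iv = F(f, k);
      ta[9*f + 3*k]     = V(iv, 0);
      ta[9*f + 3*k + 1] = V(iv, 1);
      ta[9*f + 3*k + 2] = V(iv, 2);
    }
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i,0), P(i,1), P(i,2)};
    double best = R_PosInf, bestd = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double dx=p[0]-cx[f], dy=p[1]-cy[f], dz=p[2]-cz[f];
      double dc = std::sqrt(dx*dx+dy*dy+dz*dz) - rad[f];
      if (dc > bestd) continue;
      double d2 = pt_tri_sq(p, &ta[9*f], &ta[9*f+3], &ta[9*f+6]);
      if (d2 < best) { best = d2; bestd = std::sqrt(best); }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Parity voxelization: voxel (i,j,k) center is inside iff a +x ray from the
// column start crosses the surface an odd number of times before it.
// Returns integer array nx*ny*nz (column-major, dim set in R).
// [[Rcpp::export]]
IntegerVector cpp_voxelize(NumericMatrix V, IntegerMatrix F,
                           NumericVector origin, double pitch,
                           int nx, int ny, int nz) {
  IntegerVector out(nx * ny * nz);
  int nf = F.nrow();
  double d[3] = {1.0, 1e-7, 2e-7};  // jittered axis avoids edge-on hits
  double nrm = std::sqrt(d[0]*d[0]+d[1]*d[1]+d[2]*d[2]);
  d[0]/=nrm; d[1]/=nrm; d[2]/=nrm;
  // flat per-face vertex coordinates + y/z bounds for column rejection
  std::vector<double> ta(nf * 9), ylo(nf), yhi(nf), zlo(nf), zhi(nf);
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      int iv = F(f, k);
      ta[9*f + 3*k]     = V(iv, 0);
      ta[9*f + 3*k + 1] = V(iv, 1);
      ta[9*f + 3*k + 2] = V(iv, 2);
    }
    ylo[f] = std::min({ta[9*f+1], ta[9*f+4], ta[9*f+7]}) - pitch;
    yhi[f] = std::max({ta[9*f+1], ta[9*f+4], ta[9*f+7]}) + pitch;
    zlo[f] = std::min({ta[9*f+2], ta[9*f+5], ta[9*f+8]}) - pitch;
    zhi[f] = std::max({ta[9*f+2], ta[9*f+5], ta[9*f+8]}) + pitch;
  }
  std::vector<double> ts;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      double o[3] = {origin[0] - pitch, origin[1] + (j + 0.5) * pitch,
                     origin[2] + (k + 0.5) * pitch};
      ts.clear();
      for (int f = 0; f < nf; ++f) {
        if (o[1] < ylo[f] || o[1] > yhi[f] ||
            o[2] < zlo[f] || o[2] > zhi[f]) continue;
        double t = ray_tri(o, d, &ta[9*f], &ta[9*f+3], &ta[9*f+6]);
        if (t > 0) ts.push_back(t);
      }
      if (ts.empty()) continue;
      std::sort(ts.begin(), ts.end());
      for (int i = 0; i < nx; ++i) {
        double tx = pitch + (i + 0.5) * pitch;  // distance along ray to voxel center
        int crossings = std::upper_bound(ts.begin(), ts.end(), tx) - ts.begin();
        if (crossings % 2 == 1)
          out[i + nx * (j + ny * (long)k)] = 1;
      }
    }
  }
  return out;
}

// Two-pass 26-neighbour chamfer distance transform (weights 3,4,5 ~ 1,sqrt2,sqrt3).
// Input: 0/1 occupancy; output: chamfer distance to background, 0 outside.
// [[Rcpp::export]]
NumericVector cpp_chamfer_dt(IntegerVector vox, int nx, int ny, int nz) {
  const double BIG = 1e18;
  std::vector<double> d(vox.size());
  for (R_xlen_t i = 0; i < vox.size(); ++i) d[i] = vox[i] ? BIG : 0.0;
  auto idx = [&](int i, int j, int k) { return i + nx * (j + ny * (long)k); };
  auto w = [](int di, int dj, int dk) {
    int s = std::abs(di) + std::abs(dj) + std::abs(dk);
    return (s == 1) ? 3.0 : (s == 2 ? 4.0 : 5.0);
  };
  // forward pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double &v = d[idx(i,j,k)];
        if (v == 0) continue;
        for (int dk = -1; dk <= 0; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (dk == 0 && (dj > 0 || (dj == 0 && di >= 0))) continue;
              int ii=i+di, jj=j+dj, kk=k+dk;
              double nb = (ii<0||jj<0||kk<0||ii>=nx||jj>=ny||kk>=nz)
                          ? 0.0 : d[idx(ii,jj,kk)];
              double cand = nb + w(di,dj,dk);
              if (cand < v) v = cand;
            }
      }
  // backward pass
  for (int k = nz - 1; k >= 0; --k)
    for (int j = ny - 1; j >= 0; --j)
      for (int i = nx - 1; i >= 0; --i) {
        double &v = d[idx(i,j,k)];
        if (v == 0) continue;
        for (int dk = 0; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (dk == 0 && (dj < 0 || (dj == 0 && di <= 0))) continue;
              int ii=i+di, jj=j+dj, kk=k+dk;
              double nb = (ii<0||jj<0||kk<0||ii>=nx||jj>=ny||kk>=nz)
                          ? 0.0 : d[idx(ii,jj,kk)];
              double cand = nb + w(di,dj,dk);
              if (cand < v) v = cand;
            }
      }
  return NumericVector(d.begin(), d.end());
}

// Fill projected triangles into a px-by-px binary raster. P2 holds 2D vertex
// coordinates already in pixel units (0..px).
// [[Rcpp::export]]
IntegerMatrix cpp_rasterize_tris(NumericMatrix P2, IntegerMatrix F, int px) {
  IntegerMatrix img(px, px);
  int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    int i0=F(f,0), i1=F(f,1), i2=F(f,2);
    double x0=P2(i0,0), y0=P2(i0,1);
    double x1=P2(i1,0), y1=P2(i1,1);
    double x2=P2(i2,0), y2=P2(i2,1);
    int xmin = std::max(0, (int)std::floor(std::min({x0,x1,x2})));
    int xmax = std::min(px - 1, (int)std::ceil(std::max({x0,x1,x2})));
    int ymin = std::max(0, (int)std::floor(std::min({y0,y1,y2})));
    int ymax = std::min(px - 1, (int)std::ceil(std::max({y0,y1,y2})));
    double det = (x1-x0)*(y2-y0) - (x2-x0)*(y1-y0);
    if (std::fabs(det) < 1e-14) continue;
    for (int yi = ymin; yi <= ymax; ++yi) {
      double py = yi + 0.5;
      for (int xi = xmin; xi <= xmax; ++xi) {
        double pxc = xi + 0.5;
        double l1 = ((x1-x0)*(py-y0) - (pxc-x0)*(y1-y0)) / det;
        double l2 = ((pxc-x0)*(y2-y0) - (x2-x0)*(py-y0)) / det;
        double l0 = 1.0 - l1 - l2;
        if (l0 >= -1e-9 && l1 >= -1e-9 && l2 >= -1e-9)
          img(yi, xi) = 1;
      }
    }
  }
  return img;
}
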