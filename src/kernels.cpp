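#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

// Mie prefactors chosen so that epsilon is the literal well depth:
// 9-6 form:  (27/4) eps [ (s/r)^9 - (s/r)^6 ],   minimum -eps at r = (3/2)^(1/3) s
// 12-4 form: (3*sqrt(3)/2) eps [ (s/r)^12 - (s/r)^4 ], minimum -eps at r = 3^(1/8) s
static const double C96  = 27.0 / 4.0;
static const double C124 = 3.0 * 1.7320508075688772935 / 2.0;
// Coulomb conversion factor, kJ mol^-1 nm e^-2
static const double FCOUL = 138.935485;

static inline double mie_u(double r, double eps, double sig, int form) {
  double sr = sig / r;
  if (form == 0) {
    double sr3 = sr * sr * sr;
    double sr6 = sr3 * sr3;
    return C96 * eps * (sr6 * sr3 - sr6);
  } else {
    double sr2 = sr * sr;
    double sr4 = sr2 * sr2;
    return C124 * eps * (sr4 * sr4 * sr4 - sr4);
  }
}

// dU/dr
static inline double mie_dudr(double r, double eps, double sig, int form) {
  double sr = sig / r;
  if (form == 0) {
    double sr3 = sr * sr * sr;
    double sr6 = sr3 * sr3;
    double sr9 = sr6 * sr3;
    return C96 * eps * (-9.0 * sr9 + 6.0 * sr6) / r;
  } else {
    double sr2 = sr * sr;
    double sr4 = sr2 * sr2;
    double sr12 = sr4 * sr4 * sr4;
    return C124 * eps * (-12.0 * sr12 + 4.0 * sr4) / r;
  }
}

static inline double mimg(double d, double L) {
  // minimum image for one component
  return d - L * std::round(d / L);
}

// Nonbonded energy, forces, and diagonal virial under minimum image.
// Potential (Mie + screened Coulomb) shifted to zero at the cutoff.
// pos: N x 3, type: 0-based type index per bead, eps/sig/form: ntype x ntype,
// excl: 2-column 0-based bead index pairs excluded from nonbonded sums.
// [[Rcpp::export]]
List nb_energy_forces_cpp(NumericMatrix pos, NumericVector box,
                          IntegerVector type,
                          NumericMatrix eps, NumericMatrix sig,
                          IntegerMatrix form,
                          NumericVector charge, double dielectric,
                          double cutoff, IntegerMatrix excl,
                          bool periodic) {
  int n = pos.nrow();
  double Lx = box[0], Ly = box[1], Lz = box[2];
  double rc2 = cutoff * cutoff;

  std::unordered_set<long long> exset;
  for (int k = 0; k < excl.nrow(); ++k) {
    long long i = excl(k, 0), j = excl(k, 1);
    if (i > j) std::swap(i, j);
    exset.insert(i * (long long)n + j);
  }

  NumericMatrix f(n, 3);
  double e = 0.0;
  double vxx = 0.0, vyy = 0.0, vzz = 0.0;

  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (!exset.empty() &&
          exset.count((long long)i * n + j)) continue;
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      if (periodic) {
        dx = mimg(dx, Lx); dy = mimg(dy, Ly); dz = mimg(dz, Lz);
      }
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      double r = std::sqrt(r2);
      if (r <= 0) stop("coincident beads (r = 0) in nonbonded sum");
      int ti = type[i], tj = type[j];
      double ep = eps(ti, tj), sg = sig(ti, tj);
      int fo = form(ti, tj);
      double u = 0.0, dudr = 0.0;
      if (ep > 0.0) {
        u += mie_u(r, ep, sg, fo) - mie_u(cutoff, ep, sg, fo);
        dudr += mie_dudr(r, ep, sg, fo);
      }
      double qq = charge[i] * charge[j];
      if (qq != 0.0) {
        double pref = FCOUL * qq / dielectric;
        u += pref / r - pref / cutoff;
        dudr += -pref / r2;
      }
      e += u;
      double fr = -dudr / r; // force magnitude / r
      double fx = fr * dx, fy = fr * dy, fz = fr * dz;
      f(i, 0) += fx; f(i, 1) += fy; f(i, 2) += fz;
      f(j, 0) -= fx; f(j, 1) -= fy; f(j, 2) -= fz;
      vxx += fx * dx; vyy += fy * dy; vzz += fz * dz;
    }
  }
  return List::create(_["energy"] = e, _["forces"] = f,
                      _["virial"] = NumericVector::create(vxx, vyy, vzz));
}

// Harmonic bonds and angles. bonds: 2-col 0-based; angles: 3-col (i-j-k, j apex).
// [[Rcpp::export]]
List bonded_energy_forces_cpp(NumericMatrix pos, NumericVector box,
                              IntegerMatrix bonds, NumericVector b0,
                              NumericVector kb,
                              IntegerMatrix angles, NumericVector th0,
                              NumericVector kth, bool periodic) {
  int n = pos.nrow();
  double Lx = box[0], Ly = box[1], Lz = box[2];
  NumericMatrix f(n, 3);
  double e = 0.0;
  double vxx = 0.0, vyy = 0.0, vzz = 0.0;

  for (int k = 0; k < bonds.nrow(); ++k) {
    int i = bonds(k, 0), j = bonds(k, 1);
    double dx = pos(i, 0) - pos(j, 0);
    double dy = pos(i, 1) - pos(j, 1);
    double dz = pos(i, 2) - pos(j, 2);
    if (periodic) { dx = mimg(dx, Lx); dy = mimg(dy, Ly); dz = mimg(dz, Lz); }
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - b0[k];
    e += 0.5 * kb[k] * dr * dr;
    double fr = -kb[k] * dr / r;
    double fx = fr * dx, fy = fr * dy, fz = fr * dz;
    f(i, 0) += fx; f(i, 1) += fy; f(i, 2) += fz;
    f(j, 0) -= fx; f(j, 1) -= fy; f(j, 2) -= fz;
    vxx += fx * dx; vyy += fy * dy; vzz += fz * dz;
  }

  for (int k = 0; k < angles.nrow(); ++k) {
    int i = angles(k, 0), j = angles(k, 1), m = angles(k, 2);
    double ax = pos(i, 0) - pos(j, 0), ay = pos(i, 1) - pos(j, 1),
           az = pos(i, 2) - pos(j, 2);
    double bx = pos(m, 0) - pos(j, 0), by = pos(m, 1) - pos(j, 1),
           bz = pos(m, 2) - pos(j, 2);
    if (periodic) {
      ax = mimg(ax, Lx); ay = mimg(ay, Ly); az = mimg(az, Lz);
      bx = mimg(bx, Lx); by = mimg(by, Ly); bz = mimg(bz, Lz);
    }
    double ra = std::sqrt(ax * ax + ay * ay + az * az);
    double rb = std::sqrt(bx * bx + by * by + bz * bz);
    double cs = (ax * bx + ay * by + az * bz) / (ra * rb);
    if (cs > 1.0) cs = 1.0;
    if (cs < -1.0) cs = -1.0;
    double th = std::acos(cs);
    double dth = th - th0[k];
    e += 0.5 * kth[k] * dth * dth;
    double sn = std::sqrt(1.0 - cs * cs);
    if (sn < 1e-8) sn = 1e-8; // near-linear: regularized gradient
    double c = -kth[k] * dth / sn;
    // dcos/dri and dcos/drm
    double fix = c * (bx / (ra * rb) - cs * ax / (ra * ra));
    double fiy = c * (by / (ra * rb) - cs * ay / (ra * ra));
    double fiz = c * (bz / (ra * rb) - cs * az / (ra * ra));
    double fmx = c * (ax / (ra * rb) - cs * bx / (rb * rb));
    double fmy = c * (ay / (ra * rb) - cs * by / (rb * rb));
    double fmz = c * (az / (ra * rb) - cs * bz / (rb * rb));
    // F = -dU/dr; chain rule dU/dcos * dcos/dr, with dU/dth = kth*dth and
    // dth/dcos = -1/sin -> dU/dcos = -kth*dth/sin = c
    f(i, 0) -= fix; f(i, 1) -= fiy; f(i, 2) -= fiz;
    f(m, 0) -= fmx; f(m, 1) -= fmy; f(m, 2) -= fmz;
    f(j, 0) += fix + fmx; f(j, 1) += fiy + fmy; f(j, 2) += fiz + fmz;
    vxx += -fix * ax - fmx * bx;
    vyy += -fiy * ay - fmy * by;
    vzz += -fiz * az - fmz * bz;
  }
  return List::create(_["energy"] = e, _["forces"] = f,
                      _["virial"] = NumericVector::create(vxx, vyy, vzz));
}

// Cell-list neighbor search under minimum image; falls back to an O(N^2)
// scan when the box admits fewer than 3 cells along any edge.
// Returns 2-column 1-based pair index matrix for all pairs with r < rlist.
// [[Rcpp::export]]
IntegerMatrix neighbor_pairs_cpp(NumericMatrix pos, NumericVector box,
                                 double rlist, bool periodic) {
  int n = pos.nrow();
  double Lx = box[0], Ly = box[1], Lz = box[2];
  double rl2 = rlist * rlist;
  std::vector<int> pi, pj;

  int ncx = periodic ? (int)std::floor(Lx / rlist) : 0;
  int ncy = periodic ? (int)std::floor(Ly / rlist) : 0;
  int ncz = periodic ? (int)std::floor(Lz / rlist) : 0;

  if (ncx >= 3 && ncy >= 3 && ncz >= 3) {
    int ncell = ncx * ncy * ncz;
    std::vector<std::vector<int> > cells(ncell);
    std::vector<int> cx(n), cy(n), cz(n);
    for (int i = 0; i < n; ++i) {
      double x = pos(i, 0) - Lx * std::floor(pos(i, 0) / Lx);
      double y = pos(i, 1) - Ly * std::floor(pos(i, 1) / Ly);
      double z = pos(i, 2) - Lz * std::floor(pos(i, 2) / Lz);
      int ix = std::min((int)(x / Lx * ncx), ncx - 1);
      int iy = std::min((int)(y / Ly * ncy), ncy - 1);
      int iz = std::min((int)(z / Lz * ncz), ncz - 1);
      cx[i] = ix; cy[i] = iy; cz[i] = iz;
      cells[(ix * ncy + iy) * ncz + iz].push_back(i);
    }
    for (int i = 0; i < n; ++i) {
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int ix = (cx[i] + dx + ncx) % ncx;
            int iy = (cy[i] + dy + ncy) % ncy;
            int iz = (cz[i] + dz + ncz) % ncz;
            const std::vector<int> &cell = cells[(ix * ncy + iy) * ncz + iz];
            for (size_t k = 0; k < cell.size(); ++k) {
              int j = cell[k];
              if (j <= i) continue;
              double ddx = mimg(pos(i, 0) - pos(j, 0), Lx);
              double ddy = mimg(pos(i, 1) - pos(j, 1), Ly);
              double ddz = mimg(pos(i, 2) - pos(j, 2), Lz);
              if (ddx * ddx + ddy * ddy + ddz * ddz < rl2) {
                pi.push_back(i + 1); pj.push_back(j + 1);
              }
            }
          }
    }
    // cell neighborhoods can revisit a pair when ncx==3 etc.; dedupe
    std::unordered_set<long long> seen;
    std::vector<int> ui, uj;
    for (size_t k = 0; k < pi.size(); ++k) {
      long long key = (long long)pi[k] * (n + 1) + pj[k];
      if (seen.insert(key).second) { ui.push_back(pi[k]); uj.push_back(pj[k]); }
    }
    pi.swap(ui); pj.swap(uj);
  } else {
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        double ddx = pos(i, 0) - pos(j, 0);
        double ddy = pos(i, 1) - pos(j, 1);
        double ddz = pos(i, 2) - pos(j, 2);
        if (periodic) {
          ddx = mimg(ddx, Lx); ddy = mimg(ddy, Ly); ddz = mimg(ddz, Lz);
        }
        if (ddx * ddx + ddy * ddy + ddz * ddz < rl2) {
          pi.push_back(i + 1); pj.push_back(j + 1);
        }
      }
  }
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) { out(k, 0) = pi[k]; out(k, 1) = pj[k]; }
  return out;
}
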