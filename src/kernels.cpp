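// Numerical kernels for pairwise particle registration.
//
// All geometry is in nm. A rigid transform maps particle b into the frame of
// particle a: r' = R %*% r + t. The similarity score is the uncertainty-
// normalized Bhattacharyya overlap of the two localization clouds; the
// registration objective is the overlap integral of two Gaussian mixtures in
// which every component has the same width ("scale"), uncertainties ignored.
//
// Exponential terms with argument below -60 are skipped: relative to the
// leading terms they are < 1e-26, far below double rounding, so exported
// values are still exact to machine precision.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <functional>

using namespace Rcpp;

static const double EXP_CUT = 60.0;   // exported values: exact to double rounding
static const double OPT_CUT = 12.0;   // optimizer objective: relative error ~1e-5

// ---------------------------------------------------------------------------
// Bhattacharyya similarity
// ---------------------------------------------------------------------------

// 2D: term = exp(-0.5 r^2 / (sa^2+sb^2)) / (sa^2+sb^2)
static double bhat2d(const double* ax, const double* ay, const double* sa, int na,
                     const double* bx, const double* by, const double* sb, int nb) {
  double acc = 0.0;
  for (int i = 0; i < na; ++i) {
    const double xi = ax[i], yi = ay[i], sa2 = sa[i] * sa[i];
    for (int j = 0; j < nb; ++j) {
      const double s2 = sa2 + sb[j] * sb[j];
      const double dx = xi - bx[j], dy = yi - by[j];
      const double q = 0.5 * (dx * dx + dy * dy) / s2;
      if (q < EXP_CUT) acc += std::exp(-q) / s2;
    }
  }
  return acc / ((double)na * (double)nb);
}

// 3D with optional anisotropic (lateral/axial) uncertainties. Per-axis
// variance sums enter the exponent; the prefactor uses the geometric mean of
// the three per-axis variance sums (reduces to 1/s2 in the isotropic case).
static double bhat3d(const double* ax, const double* ay, const double* az,
                     const double* sa, const double* saz, int na,
                     const double* bx, const double* by, const double* bz,
                     const double* sb, const double* sbz, int nb) {
  const bool aniso = (saz != nullptr && sbz != nullptr);
  double acc = 0.0;
  for (int i = 0; i < na; ++i) {
    const double xi = ax[i], yi = ay[i], zi = az[i];
    const double sa2 = sa[i] * sa[i];
    const double saz2 = aniso ? saz[i] * saz[i] : sa2;
    for (int j = 0; j < nb; ++j) {
      const double sxy = sa2 + sb[j] * sb[j];
      const double sz = aniso ? saz2 + sbz[j] * sbz[j] : sxy;
      const double dx = xi - bx[j], dy = yi - by[j], dz = zi - bz[j];
      const double q = 0.5 * ((dx * dx + dy * dy) / sxy + dz * dz / sz);
      if (q < EXP_CUT) acc += std::exp(-q) / std::cbrt(sxy * sxy * sz);
    }
  }
  return acc / ((double)na * (double)nb);
}

static void applyTransform(const NumericMatrix& B, const NumericMatrix& R,
                           const NumericVector& t, std::vector<double>& bx,
                           std::vector<double>& by, std::vector<double>& bz) {
  const int nb = B.nrow(), d = B.ncol();
  bx.resize(nb); by.resize(nb);
  if (d == 2) {
    for (int j = 0; j < nb; ++j) {
      bx[j] = R(0, 0) * B(j, 0) + R(0, 1) * B(j, 1) + t[0];
      by[j] = R(1, 0) * B(j, 0) + R(1, 1) * B(j, 1) + t[1];
    }
  } else {
    bz.resize(nb);
    for (int j = 0; j < nb; ++j) {
      bx[j] = R(0, 0) * B(j, 0) + R(0, 1) * B(j, 1) + R(0, 2) * B(j, 2) + t[0];
      by[j] = R(1, 0) * B(j, 0) + R(1, 1) * B(j, 1) + R(1, 2) * B(j, 2) + t[1];
      bz[j] = R(2, 0) * B(j, 0) + R(2, 1) * B(j, 1) + R(2, 2) * B(j, 2) + t[2];
    }
  }
}

// [[Rcpp::export]]
double cppBhatScore(NumericMatrix A, NumericVector sa, NumericVector saz,
                    NumericMatrix B, NumericVector sb, NumericVector sbz,
                    NumericMatrix R, NumericVector t) {
  const int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  std::vector<double> bx, by, bz;
  applyTransform(B, R, t, bx, by, bz);
  if (d == 2)
    return bhat2d(REAL(A), REAL(A) + na, REAL(sa), na,
                  bx.data(), by.data(), REAL(sb), nb);
  const bool aniso = (saz.size() == na && sbz.size() == nb);
  return bhat3d(REAL(A), REAL(A) + na, REAL(A) + 2 * na, REAL(sa),
                aniso ? REAL(saz) : nullptr, na, bx.data(), by.data(),
                bz.data(), REAL(sb), aniso ? REAL(sbz) : nullptr, nb);
}

// ---------------------------------------------------------------------------
// GMM overlap (registration objective)
// ---------------------------------------------------------------------------

// Exact overlap integral of two GMMs with equal component weights and uniform
// width `scale`: (1/(Ka*Kb)) sum_ij N(r_ai - r_bj; 0, 2*scale^2 * I).
static double gmmKernelSum(const double* ax, const double* ay, const double* az,
                           int na, const double* bx, const double* by,
                           const double* bz, int nb, double inv4s2,
                           double qcut = EXP_CUT) {
  double acc = 0.0;
  if (az == nullptr) {
    for (int i = 0; i < na; ++i) {
      const double xi = ax[i], yi = ay[i];
      double sub = 0.0;
      for (int j = 0; j < nb; ++j) {
        const double dx = xi - bx[j], dy = yi - by[j];
        const double q = (dx * dx + dy * dy) * inv4s2;
        if (q < qcut) sub += std::exp(-q);
      }
      acc += sub;
    }
  } else {
    for (int i = 0; i < na; ++i) {
      const double xi = ax[i], yi = ay[i], zi = az[i];
      double sub = 0.0;
      for (int j = 0; j < nb; ++j) {
        const double dx = xi - bx[j], dy = yi - by[j], dz = zi - bz[j];
        const double q = (dx * dx + dy * dy + dz * dz) * inv4s2;
        if (q < qcut) sub += std::exp(-q);
      }
      acc += sub;
    }
  }
  return acc;
}

// [[Rcpp::export]]
double cppGmmOverlap(NumericMatrix A, NumericMatrix B, double scale,
                     NumericMatrix R, NumericVector t) {
  const int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  std::vector<double> bx, by, bz;
  applyTransform(B, R, t, bx, by, bz);
  const double inv4s2 = 1.0 / (4.0 * scale * scale);
  const double ksum = (d == 2)
    ? gmmKernelSum(REAL(A), REAL(A) + na, nullptr, na, bx.data(), by.data(),
                   nullptr, nb, inv4s2)
    : gmmKernelSum(REAL(A), REAL(A) + na, REAL(A) + 2 * na, na, bx.data(),
                   by.data(), bz.data(), nb, inv4s2);
  const double twoS2 = 2.0 * scale * scale;
  const double norm = (d == 2) ? (2.0 * M_PI * twoS2)
                               : std::pow(2.0 * M_PI * twoS2, 1.5);
  return ksum / ((double)na * (double)nb * norm);
}

// ---------------------------------------------------------------------------
// Nelder-Mead (derivative-free simplex), minimization
// ---------------------------------------------------------------------------

struct NMOut { double f; int nev; bool conv; };

static NMOut nelderMead(std::vector<double>& x, const std::vector<double>& step,
                        const std::function<double(const double*)>& f,
                        int maxEval, double ftol) {
  const int n = (int)x.size();
  const int m = n + 1;
  std::vector<std::vector<double>> sim(m, x);
  std::vector<double> fv(m);
  int nev = 0;
  for (int v = 0; v < m; ++v) {
    if (v > 0) sim[v][v - 1] += step[v - 1];
    fv[v] = f(sim[v].data()); ++nev;
  }
  bool conv = false;
  std::vector<double> cen(n), xr(n), xe(n), xc(n);
  while (nev < maxEval) {
    int lo = 0, hi = 0;
    for (int v = 1; v < m; ++v) {
      if (fv[v] < fv[lo]) lo = v;
      if (fv[v] > fv[hi]) hi = v;
    }
    int nh = (hi == 0) ? 1 : 0;
    for (int v = 0; v < m; ++v)
      if (v != hi && fv[v] > fv[nh]) nh = v;
    if (std::fabs(fv[hi] - fv[lo]) <= ftol * (std::fabs(fv[lo]) + 1e-300)) {
      conv = true; break;
    }
    for (int d = 0; d < n; ++d) {
      double s = 0.0;
      for (int v = 0; v < m; ++v) if (v != hi) s += sim[v][d];
      cen[d] = s / n;
    }
    for (int d = 0; d < n; ++d) xr[d] = cen[d] + (cen[d] - sim[hi][d]);
    const double fr = f(xr.data()); ++nev;
    if (fr < fv[lo]) {
      for (int d = 0; d < n; ++d) xe[d] = cen[d] + 2.0 * (cen[d] - sim[hi][d]);
      const double fe = f(xe.data()); ++nev;
      if (fe < fr) { sim[hi] = xe; fv[hi] = fe; }
      else { sim[hi] = xr; fv[hi] = fr; }
    } else if (fr < fv[nh]) {
      sim[hi] = xr; fv[hi] = fr;
    } else {
      for (int d = 0; d < n; ++d) xc[d] = cen[d] + 0.5 * (sim[hi][d] - cen[d]);
      const double fc = f(xc.data()); ++nev;
      if (fc < fv[hi]) { sim[hi] = xc; fv[hi] = fc; }
      else {
        for (int v = 0; v < m; ++v) {
          if (v == lo) continue;
          for (int d = 0; d < n; ++d)
            sim[v][d] = sim[lo][d] + 0.5 * (sim[v][d] - sim[lo][d]);
          fv[v] = f(sim[v].data()); ++nev;
        }
      }
    }
  }
  int lo = 0;
  for (int v = 1; v < m; ++v) if (fv[v] < fv[lo]) lo = v;
  x = sim[lo];
  return {fv[lo], nev, conv};
}

// ---------------------------------------------------------------------------
// 2D pair registration
// ---------------------------------------------------------------------------

// Evenly spaced subsample of row indices (deterministic).
static std::vector<int> subsampleIdx(int n, int m) {
  std::vector<int> idx;
  if (m >= n) { idx.resize(n); for (int i = 0; i < n; ++i) idx[i] = i; return idx; }
  idx.resize(m);
  for (int k = 0; k < m; ++k) idx[k] = (int)(((double)k + 0.5) * n / m);
  return idx;
}

struct Cloud2 {
  std::vector<double> x, y, s;
  double cx = 0.0, cy = 0.0;
};

static Cloud2 makeCloud2(const NumericMatrix& M, const NumericVector& sig,
                         const std::vector<int>& idx) {
  Cloud2 c;
  const int n = (int)idx.size(), nr = M.nrow();
  const double* mx = REAL(M); const double* my = REAL(M) + nr;
  c.x.resize(n); c.y.resize(n); c.s.resize(n);
  for (int k = 0; k < n; ++k) {
    c.x[k] = mx[idx[k]]; c.y[k] = my[idx[k]]; c.s[k] = sig[idx[k]];
  }
  return c;
}

// objective: negative GMM kernel sum (constants dropped) of a vs transformed b
struct Obj2D {
  const Cloud2* a; const Cloud2* b;
  double inv4s2;
  mutable std::vector<double> bx, by;
  mutable long nev = 0;
  double operator()(const double* p) const {
    const double c = std::cos(p[0]), s = std::sin(p[0]);
    const int nb = (int)b->x.size();
    bx.resize(nb); by.resize(nb);
    for (int j = 0; j < nb; ++j) {
      bx[j] = c * b->x[j] - s * b->y[j] + p[1];
      by[j] = s * b->x[j] + c * b->y[j] + p[2];
    }
    ++nev;
    return -gmmKernelSum(a->x.data(), a->y.data(), nullptr, (int)a->x.size(),
                         bx.data(), by.data(), nullptr, nb, inv4s2, OPT_CUT);
  }
};

static double bhatAt2D(const Cloud2& a, const Cloud2& b, const double* p) {
  const double c = std::cos(p[0]), s = std::sin(p[0]);
  const int nb = (int)b.x.size();
  std::vector<double> bx(nb), by(nb);
  for (int j = 0; j < nb; ++j) {
    bx[j] = c * b.x[j] - s * b.y[j] + p[1];
    by[j] = s * b.x[j] + c * b.y[j] + p[2];
  }
  return bhat2d(a.x.data(), a.y.data(), a.s.data(), (int)a.x.size(),
                bx.data(), by.data(), b.s.data(), nb);
}

struct Reg2Out {
  double theta, tx, ty, S, gmm;
  int nConv, nev;
  std::vector<double> perStart;  // nstart rows x 4 (theta, tx, ty, S)
};

static Reg2Out registerPair2Core(const NumericMatrix& A, const NumericVector& sa,
                                 const NumericMatrix& B, const NumericVector& sb,
                                 double scale, const std::vector<double>& angles,
                                 int maxEvalCoarse, int maxEvalRefine,
                                 double ftol, int maxLocsOptim, bool doOptim) {
  const int na = A.nrow(), nb = B.nrow();
  std::vector<int> all_a = subsampleIdx(na, na), all_b = subsampleIdx(nb, nb);
  Cloud2 fa = makeCloud2(A, sa, all_a), fb = makeCloud2(B, sb, all_b);
  for (int i = 0; i < na; ++i) { fa.cx += fa.x[i]; fa.cy += fa.y[i]; }
  fa.cx /= na; fa.cy /= na;
  for (int j = 0; j < nb; ++j) { fb.cx += fb.x[j]; fb.cy += fb.y[j]; }
  fb.cx /= nb; fb.cy /= nb;

  Reg2Out out; out.nConv = 0; out.nev = 0;
  if (!doOptim) {
    double p0[3] = {0.0, 0.0, 0.0};
    out.theta = 0.0; out.tx = 0.0; out.ty = 0.0;
    out.S = bhatAt2D(fa, fb, p0);
    out.gmm = NA_REAL;
    return out;
  }

  Cloud2 ca = makeCloud2(A, sa, subsampleIdx(na, maxLocsOptim));
  Cloud2 cb = makeCloud2(B, sb, subsampleIdx(nb, maxLocsOptim));
  Obj2D objCoarse{&ca, &cb, 1.0 / (4.0 * scale * scale)};
  Obj2D objFull{&fa, &fb, 1.0 / (4.0 * scale * scale)};

  const int nstart = (int)angles.size();
  out.perStart.resize((size_t)nstart * 4);
  double bestS = -1.0;
  std::vector<double> bestP(3, 0.0);
  for (int k = 0; k < nstart; ++k) {
    const double th = angles[k];
    const double c = std::cos(th), s = std::sin(th);
    std::vector<double> p = {th, fa.cx - (c * fb.cx - s * fb.cy),
                             fa.cy - (s * fb.cx + c * fb.cy)};
    std::vector<double> step = {0.15, scale, scale};
    NMOut nm = nelderMead(p, step, std::cref(objCoarse), maxEvalCoarse, ftol);
    if (nm.conv) ++out.nConv;
    const double S = bhatAt2D(fa, fb, p.data());
    out.perStart[k] = p[0]; out.perStart[nstart + k] = p[1];
    out.perStart[2 * nstart + k] = p[2]; out.perStart[3 * nstart + k] = S;
    if (S > bestS) { bestS = S; bestP = p; }
  }
  // one refinement pass of the winning start on the full clouds
  if (maxEvalRefine > 0) {
    std::vector<double> p = bestP;
    std::vector<double> step = {0.05, 0.5 * scale, 0.5 * scale};
    nelderMead(p, step, std::cref(objFull), maxEvalRefine, ftol);
    const double S = bhatAt2D(fa, fb, p.data());
    if (S > bestS) { bestS = S; bestP = p; }
  }
  out.nev = (int)(objCoarse.nev + objFull.nev);
  out.theta = std::remainder(bestP[0], 2.0 * M_PI);
  out.tx = bestP[1]; out.ty = bestP[2];
  out.S = bestS;
  double pFin[3] = {out.theta, out.tx, out.ty};
  out.gmm = -objFull(pFin);
  return out;
}

// [[Rcpp::export]]
List cppRegisterPair2D(NumericMatrix A, NumericVector sa, NumericMatrix B,
                       NumericVector sb, double scale, NumericVector angles,
                       int maxEvalCoarse, int maxEvalRefine, double ftol,
                       int maxLocsOptim, bool doOptim) {
  std::vector<double> ang(angles.begin(), angles.end());
  Reg2Out r = registerPair2Core(A, sa, B, sb, scale, ang, maxEvalCoarse,
                                maxEvalRefine, ftol, maxLocsOptim, doOptim);
  const int nstart = (int)ang.size();
  NumericMatrix per(doOptim ? nstart : 0, 4);
  if (doOptim)
    for (int k = 0; k < nstart; ++k)
      for (int c = 0; c < 4; ++c) per(k, c) = r.perStart[(size_t)c * nstart + k];
  colnames(per) = CharacterVector::create("theta", "tx", "ty", "S");
  return List::create(_["theta"] = r.theta, _["tx"] = r.tx, _["ty"] = r.ty,
                      _["S"] = r.S, _["gmm"] = r.gmm,
                      _["nStartsConverged"] = r.nConv, _["nEval"] = r.nev,
                      _["perStart"] = per);
}

// [[Rcpp::export]]
List cppAllPairs2D(List coords, List sigmas, double scale, int nAngles,
                   int maxEvalCoarse, int maxEvalRefine, double ftol,
                   int maxLocsOptim, int minLocsOptim) {
  const int N = coords.size();
  NumericMatrix S(N, N);
  const R_xlen_t npair = (R_xlen_t)N * (N - 1) / 2;
  NumericMatrix params(npair, 3);
  IntegerVector nConv(npair);
  std::vector<double> ang(nAngles);
  for (int k = 0; k < nAngles; ++k) ang[k] = 2.0 * M_PI * k / nAngles;

  // cache matrices to avoid repeated list extraction
  std::vector<NumericMatrix> Cs(N);
  std::vector<NumericVector> Ss(N);
  for (int i = 0; i < N; ++i) { Cs[i] = as<NumericMatrix>(coords[i]); Ss[i] = as<NumericVector>(sigmas[i]); }

  // diagonal: self-similarity at identity (diagnostic only)
  NumericMatrix I2 = NumericMatrix::diag(2, 1.0);
  NumericVector t0 = NumericVector::create(0.0, 0.0);
  for (int i = 0; i < N; ++i) {
    NumericVector dummy(0);
    S(i, i) = cppBhatScore(Cs[i], Ss[i], dummy, Cs[i], Ss[i], dummy, I2, t0);
  }

  R_xlen_t k = 0;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j, ++k) {
      const bool doOpt = (Cs[i].nrow() >= minLocsOptim && Cs[j].nrow() >= minLocsOptim);
      Reg2Out r = registerPair2Core(Cs[i], Ss[i], Cs[j], Ss[j], scale, ang,
                                    maxEvalCoarse, maxEvalRefine, ftol,
                                    maxLocsOptim, doOpt);
      S(i, j) = r.S; S(j, i) = r.S;
      params(k, 0) = r.theta; params(k, 1) = r.tx; params(k, 2) = r.ty;
      nConv[k] = r.nConv;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["S"] = S, _["params"] = params,
                      _["nStartsConverged"] = nConv);
}

// ---------------------------------------------------------------------------
// 3D pair registration (rotation-vector increments around initial rotations)
// ---------------------------------------------------------------------------

static void rodrigues(const double* w, double R[9]) {
  const double th2 = w[0] * w[0] + w[1] * w[1] + w[2] * w[2];
  const double th = std::sqrt(th2);
  double A, Bc;
  if (th < 1e-8) { A = 1.0 - th2 / 6.0; Bc = 0.5 - th2 / 24.0; }
  else { A = std::sin(th) / th; Bc = (1.0 - std::cos(th)) / th2; }
  const double wx = w[0], wy = w[1], wz = w[2];
  R[0] = 1.0 + Bc * (-wz * wz - wy * wy);
  R[1] = Bc * wx * wy + A * wz;
  R[2] = Bc * wx * wz - A * wy;
  R[3] = Bc * wx * wy - A * wz;
  R[4] = 1.0 + Bc * (-wx * wx - wz * wz);
  R[5] = Bc * wy * wz + A * wx;
  R[6] = Bc * wx * wz + A * wy;
  R[7] = Bc * wy * wz - A * wx;
  R[8] = 1.0 + Bc * (-wx * wx - wy * wy);
}
// R above is column-major 3x3: R[col*3 + row]

struct Cloud3 {
  std::vector<double> x, y, z, s, sz;
  double cx = 0, cy = 0, cz = 0;
};

static Cloud3 makeCloud3(const NumericMatrix& M, const NumericVector& sig,
                         const NumericVector& sigz, const std::vector<int>& idx) {
  Cloud3 c;
  const int n = (int)idx.size(), nr = M.nrow();
  const double* mx = REAL(M); const double* my = mx + nr; const double* mz = my + nr;
  c.x.resize(n); c.y.resize(n); c.z.resize(n); c.s.resize(n);
  const bool aniso = sigz.size() == nr;
  if (aniso) c.sz.resize(n);
  for (int k = 0; k < n; ++k) {
    c.x[k] = mx[idx[k]]; c.y[k] = my[idx[k]]; c.z[k] = mz[idx[k]];
    c.s[k] = sig[idx[k]];
    if (aniso) c.sz[k] = sigz[idx[k]];
  }
  return c;
}

static void transform3(const Cloud3& b, const double Rm[9], const double* t,
                       std::vector<double>& bx, std::vector<double>& by,
                       std::vector<double>& bz) {
  const int nb = (int)b.x.size();
  bx.resize(nb); by.resize(nb); bz.resize(nb);
  for (int j = 0; j < nb; ++j) {
    bx[j] = Rm[0] * b.x[j] + Rm[3] * b.y[j] + Rm[6] * b.z[j] + t[0];
    by[j] = Rm[1] * b.x[j] + Rm[4] * b.y[j] + Rm[7] * b.z[j] + t[1];
    bz[j] = Rm[2] * b.x[j] + Rm[5] * b.y[j] + Rm[8] * b.z[j] + t[2];
  }
}

static void composeRot(const double A[9], const double B[9], double C[9]) {
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r)
      C[c * 3 + r] = A[r] * B[c * 3] + A[3 + r] * B[c * 3 + 1] + A[6 + r] * B[c * 3 + 2];
}

struct Reg3Out {
  double R[9]; double t[3]; double S, gmm; int nConv;
};

static Reg3Out registerPair3Core(const NumericMatrix& A, const NumericVector& sa,
                                 const NumericVector& saz, const NumericMatrix& B,
                                 const NumericVector& sb, const NumericVector& sbz,
                                 double scale, const List& initRots,
                                 int maxEvalCoarse, int maxEvalRefine,
                                 double ftol, int maxLocsOptim, bool doOptim) {
  const int na = A.nrow(), nb = B.nrow();
  Cloud3 fa = makeCloud3(A, sa, saz, subsampleIdx(na, na));
  Cloud3 fb = makeCloud3(B, sb, sbz, subsampleIdx(nb, nb));
  for (int i = 0; i < na; ++i) { fa.cx += fa.x[i]; fa.cy += fa.y[i]; fa.cz += fa.z[i]; }
  fa.cx /= na; fa.cy /= na; fa.cz /= na;
  for (int j = 0; j < nb; ++j) { fb.cx += fb.x[j]; fb.cy += fb.y[j]; fb.cz += fb.z[j]; }
  fb.cx /= nb; fb.cy /= nb; fb.cz /= nb;

  Reg3Out out; out.nConv = 0;
  const double inv4s2 = 1.0 / (4.0 * scale * scale);
  std::vector<double> bx, by, bz;

  auto bhatFull = [&](const double Rm[9], const double* t) {
    transform3(fb, Rm, t, bx, by, bz);
    return bhat3d(fa.x.data(), fa.y.data(), fa.z.data(), fa.s.data(),
                  fa.sz.empty() ? nullptr : fa.sz.data(), na, bx.data(),
                  by.data(), bz.data(), fb.s.data(),
                  fb.sz.empty() ? nullptr : fb.sz.data(), nb);
  };

  if (!doOptim) {
    for (int q = 0; q < 9; ++q) out.R[q] = (q % 4 == 0) ? 1.0 : 0.0;
    out.t[0] = out.t[1] = out.t[2] = 0.0;
    out.S = bhatFull(out.R, out.t);
    out.gmm = NA_REAL;
    return out;
  }

  Cloud3 ca = makeCloud3(A, sa, saz, subsampleIdx(na, maxLocsOptim));
  Cloud3 cb = makeCloud3(B, sb, sbz, subsampleIdx(nb, maxLocsOptim));

  double bestS = -1.0;
  double bestR[9]; double bestT[3];
  const int nstart = initRots.size();
  for (int k = 0; k < nstart; ++k) {
    NumericMatrix R0m = initRots[k];
    double R0[9];
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r) R0[c * 3 + r] = R0m(r, c);
    // params: rotation-vector increment (3) + translation (3)
    auto obj = [&](const double* p) {
      double dR[9], Rm[9];
      rodrigues(p, dR);
      composeRot(R0, dR, Rm);
      transform3(cb, Rm, p + 3, bx, by, bz);
      return -gmmKernelSum(ca.x.data(), ca.y.data(), ca.z.data(),
                           (int)ca.x.size(), bx.data(), by.data(), bz.data(),
                           (int)bx.size(), inv4s2, OPT_CUT);
    };
    std::vector<double> p(6, 0.0);
    p[3] = fa.cx - (R0[0] * fb.cx + R0[3] * fb.cy + R0[6] * fb.cz);
    p[4] = fa.cy - (R0[1] * fb.cx + R0[4] * fb.cy + R0[7] * fb.cz);
    p[5] = fa.cz - (R0[2] * fb.cx + R0[5] * fb.cy + R0[8] * fb.cz);
    std::vector<double> step = {0.15, 0.15, 0.15, scale, scale, scale};
    NMOut nm = nelderMead(p, step, obj, maxEvalCoarse, ftol);
    if (nm.conv) ++out.nConv;
    double dR[9], Rm[9];
    rodrigues(p.data(), dR);
    composeRot(R0, dR, Rm);
    const double S = bhatFull(Rm, p.data() + 3);
    if (S > bestS) {
      bestS = S;
      for (int q = 0; q < 9; ++q) bestR[q] = Rm[q];
      for (int q = 0; q < 3; ++q) bestT[q] = p[3 + q];
    }
  }
  // refinement on full clouds around the winner
  if (maxEvalRefine > 0) {
    auto obj = [&](const double* p) {
      double dR[9], Rm[9];
      rodrigues(p, dR);
      composeRot(bestR, dR, Rm);
      transform3(fb, Rm, p + 3, bx, by, bz);
      return -gmmKernelSum(fa.x.data(), fa.y.data(), fa.z.data(), na, bx.data(),
                           by.data(), bz.data(), nb, inv4s2, OPT_CUT);
    };
    std::vector<double> p(6, 0.0);
    p[3] = bestT[0]; p[4] = bestT[1]; p[5] = bestT[2];
    std::vector<double> step = {0.05, 0.05, 0.05, 0.5 * scale, 0.5 * scale, 0.5 * scale};
    nelderMead(p, step, obj, maxEvalRefine, ftol);
    double dR[9], Rm[9];
    rodrigues(p.data(), dR);
    composeRot(bestR, dR, Rm);
    const double S = bhatFull(Rm, p.data() + 3);
    if (S > bestS) {
      bestS = S;
      for (int q = 0; q < 9; ++q) bestR[q] = Rm[q];
      for (int q = 0; q < 3; ++q) bestT[q] = p[3 + q];
    }
  }
  for (int q = 0; q < 9; ++q) out.R[q] = bestR[q];
  for (int q = 0; q < 3; ++q) out.t[q] = bestT[q];
  out.S = bestS;
  transform3(fb, bestR, bestT, bx, by, bz);
  out.gmm = gmmKernelSum(fa.x.data(), fa.y.data(), fa.z.data(), na, bx.data(),
                         by.data(), bz.data(), nb, inv4s2);
  return out;
}

static NumericMatrix rotToMat(const double R[9]) {
  NumericMatrix M(3, 3);
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) M(r, c) = R[c * 3 + r];
  return M;
}

// [[Rcpp::export]]
List cppRegisterPair3D(NumericMatrix A, NumericVector sa, NumericVector saz,
                       NumericMatrix B, NumericVector sb, NumericVector sbz,
                       double scale, List initRots, int maxEvalCoarse,
                       int maxEvalRefine, double ftol, int maxLocsOptim,
                       bool doOptim) {
  Reg3Out r = registerPair3Core(A, sa, saz, B, sb, sbz, scale, initRots,
                                maxEvalCoarse, maxEvalRefine, ftol,
                                maxLocsOptim, doOptim);
  return List::create(_["R"] = rotToMat(r.R),
                      _["t"] = NumericVector::create(r.t[0], r.t[1], r.t[2]),
                      _["S"] = r.S, _["gmm"] = r.gmm,
                      _["nStartsConverged"] = r.nConv);
}

// [[Rcpp::export]]
List cppAllPairs3D(List coords, List sigmas, List sigmasZ, double scale,
                   List initRots, int maxEvalCoarse, int maxEvalRefine,
                   double ftol, int maxLocsOptim, int minLocsOptim) {
  const int N = coords.size();
  NumericMatrix S(N, N);
  const R_xlen_t npair = (R_xlen_t)N * (N - 1) / 2;
  NumericMatrix params(npair, 12);  // 9 rotation (column-major) + 3 translation
  IntegerVector nConv(npair);

  std::vector<NumericMatrix> Cs(N);
  std::vector<NumericVector> Sg(N), SgZ(N);
  for (int i = 0; i < N; ++i) {
    Cs[i] = as<NumericMatrix>(coords[i]);
    Sg[i] = as<NumericVector>(sigmas[i]);
    SgZ[i] = as<NumericVector>(sigmasZ[i]);
  }
  NumericMatrix I3 = NumericMatrix::diag(3, 1.0);
  NumericVector t0 = NumericVector::create(0.0, 0.0, 0.0);
  for (int i = 0; i < N; ++i)
    S(i, i) = cppBhatScore(Cs[i], Sg[i], SgZ[i], Cs[i], Sg[i], SgZ[i], I3, t0);

  R_xlen_t k = 0;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j, ++k) {
      const bool doOpt = (Cs[i].nrow() >= minLocsOptim && Cs[j].nrow() >= minLocsOptim);
      Reg3Out r = registerPair3Core(Cs[i], Sg[i], SgZ[i], Cs[j], Sg[j], SgZ[j],
                                    scale, initRots, maxEvalCoarse,
                                    maxEvalRefine, ftol, maxLocsOptim, doOpt);
      S(i, j) = r.S; S(j, i) = r.S;
      for (int q = 0; q < 9; ++q) params(k, q) = r.R[q];
      for (int q = 0; q < 3; ++q) params(k, 9 + q) = r.t[q];
      nConv[k] = r.nConv;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["S"] = S, _["params"] = params,
                      _["nStartsConverged"] = nConv);
}
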