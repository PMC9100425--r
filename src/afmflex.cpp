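// Compute core: pseudo-AFM renderers, structure-based potential, stage wall,
// harmonic restraints, cosine-similarity AFM bias (analytic gradient) and the
// BAOAB Langevin integrator. All lengths in nm, energies in reduced units
// (kcal/mol scale), k_B = 0.0019872041 per K, uniform bead mass in reduced
// units (set where the integrator defines it).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <string>
#include <vector>
#include <unordered_set>
using namespace Rcpp;

static const double KBOLTZ = 0.0019872041; // energy / K

// ---------------------------------------------------------------------------
// RNG: mt19937_64 (standard-specified sequence) + Box-Muller, one stream per
// (seed, stream) pair so replicas are independent and reproducible.
// ---------------------------------------------------------------------------
namespace {

inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct GaussRNG {
  std::mt19937_64 eng;
  bool has_spare;
  double spare;
  GaussRNG(uint64_t seed, uint64_t stream) : has_spare(false), spare(0.0) {
    uint64_t s = seed;
    uint64_t a = splitmix64(s);
    for (uint64_t i = 0; i <= stream; ++i) a = splitmix64(s);
    eng.seed(a);
  }
  // uniform in (0, 1]
  double unif_oc() {
    return ((eng() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  double gauss() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif_oc(), u2 = unif_oc();
    double r = std::sqrt(-2.0 * std::log(u1));
    double t = 2.0 * M_PI * u2;
    spare = r * std::sin(t);
    has_spare = true;
    return r * std::cos(t);
  }
};

// ---------------------------------------------------------------------------
// Grid geometry helper (pixel (i,j) 0-based -> center x0 + i*dx, y0 + j*dy)
// ---------------------------------------------------------------------------
struct Grid {
  int nx, ny;
  double dx, dy, x0, y0;
};

struct MaskBox { int ix0, ix1, iy0, iy1; }; // 0-based inclusive

// ---------------------------------------------------------------------------
// Smoothed renderer: H_p = gamma * log(1 + sum_i exp(a_ip)),
// a_ip = (z_i + r_i)/gamma - (x_i - x_p)^2/(2 sx^2) - (y_i - y_p)^2/(2 sy^2).
// Per-bead truncated lateral support; stable log-sum-exp (baseline term 0).
// ---------------------------------------------------------------------------
struct SmoothWorkspace {
  std::vector<double> M, D, H;      // per masked pixel
  std::vector<double> ebuf;         // per bead-window-pixel exp(a - M)
  std::vector<int> win;             // per bead: ix0, ix1, iy0, iy1
  std::vector<size_t> eoff;         // offset of each bead's block in ebuf
};

inline int clampi(int v, int lo, int hi) { return v < lo ? lo : (v > hi ? hi : v); }

// Computes H over mask pixels; fills workspace for gradient pass.
static void smooth_forward(const NumericMatrix &coords, const NumericVector &radius,
                           const Grid &g, const MaskBox &m,
                           double sx, double sy, double gamma,
                           SmoothWorkspace &ws) {
  const int n = coords.nrow();
  const int mw = m.ix1 - m.ix0 + 1, mh = m.iy1 - m.iy0 + 1;
  ws.M.assign((size_t)mw * mh, 0.0);
  ws.D.assign((size_t)mw * mh, 0.0);
  ws.H.assign((size_t)mw * mh, 0.0);
  ws.win.assign((size_t)4 * n, 0);
  ws.eoff.assign((size_t)n + 1, 0);

  const double inv2sx2 = 1.0 / (2.0 * sx * sx);
  const double inv2sy2 = 1.0 / (2.0 * sy * sy);

  // Per-bead lateral support: pixels where the term's exponent could come
  // within 20 of the stage baseline, d_cut = sigma sqrt(2((z+r)/gamma+20)).
  // Dropped terms satisfy exp(a - M) <= e^-20, so the truncation error is
  // below gamma * n * e^-20 < 1e-6 nm.
  size_t tot = 0;
  for (int b = 0; b < n; ++b) {
    double expo = std::max(0.0, (coords(b, 2) + radius[b]) / gamma) + 20.0;
    double dcut = std::sqrt(2.0 * expo);
    int wx = (int)std::ceil((sx * dcut) / g.dx + 0.5);
    int wy = (int)std::ceil((sy * dcut) / g.dy + 0.5);
    int ci = (int)std::lround((coords(b, 0) - g.x0) / g.dx);
    int cj = (int)std::lround((coords(b, 1) - g.y0) / g.dy);
    int ix0 = clampi(ci - wx, m.ix0, m.ix1 + 1); // may collapse to empty
    int ix1 = clampi(ci + wx, m.ix0 - 1, m.ix1);
    int iy0 = clampi(cj - wy, m.iy0, m.iy1 + 1);
    int iy1 = clampi(cj + wy, m.iy0 - 1, m.iy1);
    if (ix1 < ix0 || iy1 < iy0) { ix0 = 1; ix1 = 0; iy0 = 1; iy1 = 0; }
    ws.win[4 * b] = ix0; ws.win[4 * b + 1] = ix1;
    ws.win[4 * b + 2] = iy0; ws.win[4 * b + 3] = iy1;
    ws.eoff[b] = tot;
    if (ix1 >= ix0 && iy1 >= iy0)
      tot += (size_t)(ix1 - ix0 + 1) * (iy1 - iy0 + 1);
  }
  ws.eoff[n] = tot;
  ws.ebuf.assign(tot, 0.0);

  // pass 1: per-pixel max exponent (baseline 0 from the "+1" term)
  for (int b = 0; b < n; ++b) {
    int ix0 = ws.win[4 * b], ix1 = ws.win[4 * b + 1];
    int iy0 = ws.win[4 * b + 2], iy1 = ws.win[4 * b + 3];
    if (ix1 < ix0) continue;
    const double xb = coords(b, 0), yb = coords(b, 1);
    const double ztop = (coords(b, 2) + radius[b]) / gamma;
    for (int j = iy0; j <= iy1; ++j) {
      double yp = g.y0 + j * g.dy, dy2 = (yb - yp) * (yb - yp) * inv2sy2;
      for (int i = ix0; i <= ix1; ++i) {
        double xp = g.x0 + i * g.dx;
        double a = ztop - (xb - xp) * (xb - xp) * inv2sx2 - dy2;
        size_t p = (size_t)(j - m.iy0) * mw + (i - m.ix0);
        if (a > ws.M[p]) ws.M[p] = a;
      }
    }
  }
  // pass 2: stable sums (store exp(a - M) per bead-pixel for the gradient)
  for (size_t p = 0; p < ws.D.size(); ++p) ws.D[p] = std::exp(-ws.M[p]);
  for (int b = 0; b < n; ++b) {
    int ix0 = ws.win[4 * b], ix1 = ws.win[4 * b + 1];
    int iy0 = ws.win[4 * b + 2], iy1 = ws.win[4 * b + 3];
    if (ix1 < ix0) continue;
    const double xb = coords(b, 0), yb = coords(b, 1);
    const double ztop = (coords(b, 2) + radius[b]) / gamma;
    size_t off = ws.eoff[b];
    for (int j = iy0; j <= iy1; ++j) {
      double yp = g.y0 + j * g.dy, dy2 = (yb - yp) * (yb - yp) * inv2sy2;
      for (int i = ix0; i <= ix1; ++i, ++off) {
        double xp = g.x0 + i * g.dx;
        double a = ztop - (xb - xp) * (xb - xp) * inv2sx2 - dy2;
        size_t p = (size_t)(j - m.iy0) * mw + (i - m.ix0);
        double da = a - ws.M[p];
        // terms more than 20 below the pixel's max exponent cannot move
        // H_p (or its gradient) by more than ~gamma n e^-20: skip the exp
        if (da < -20.0) { ws.ebuf[off] = 0.0; continue; }
        double e = std::exp(da);
        ws.ebuf[off] = e;
        ws.D[p] += e;
      }
    }
  }
  for (size_t p = 0; p < ws.H.size(); ++p)
    ws.H[p] = gamma * (ws.M[p] + std::log(ws.D[p]));
}

// Accumulates -dV/dr into forces given dV/dH per masked pixel.
static void smooth_backward(const NumericMatrix &coords, const Grid &g,
                            const MaskBox &m, double sx, double sy, double gamma,
                            const SmoothWorkspace &ws,
                            const std::vector<double> &dVdH,
                            NumericMatrix &forces) {
  const int n = coords.nrow();
  const int mw = m.ix1 - m.ix0 + 1;
  const double invsx2 = 1.0 / (sx * sx), invsy2 = 1.0 / (sy * sy);
  for (int b = 0; b < n; ++b) {
    int ix0 = ws.win[4 * b], ix1 = ws.win[4 * b + 1];
    int iy0 = ws.win[4 * b + 2], iy1 = ws.win[4 * b + 3];
    if (ix1 < ix0) continue;
    const double xb = coords(b, 0), yb = coords(b, 1);
    size_t off = ws.eoff[b];
    double fx = 0.0, fy = 0.0, fz = 0.0;
    for (int j = iy0; j <= iy1; ++j) {
      double yp = g.y0 + j * g.dy;
      for (int i = ix0; i <= ix1; ++i, ++off) {
        size_t p = (size_t)(j - m.iy0) * mw + (i - m.ix0);
        double w = ws.ebuf[off] / ws.D[p];     // dH_p/dz_b / 1
        double gdv = dVdH[p];
        if (w == 0.0 || gdv == 0.0) continue;
        double xp = g.x0 + i * g.dx;
        // dH/dx = -gamma * w * (xb - xp)/sx^2 ; dH/dz = w
        fx -= gdv * (-gamma * w * (xb - xp) * invsx2);
        fy -= gdv * (-gamma * w * (yb - yp) * invsy2);
        fz -= gdv * w;
      }
    }
    forces(b, 0) += fx; forces(b, 1) += fy; forces(b, 2) += fz;
  }
}

// cosine similarity over masked pixels + dV/dH for V = k(1 - cs).
// Returns cs; fills dVdH. ss_out gets sum H^2 (0 => undefined similarity).
static double bias_dVdH(const std::vector<double> &H, const NumericMatrix &href,
                        const MaskBox &m, double k,
                        std::vector<double> &dVdH, double &ss_out) {
  const int mw = m.ix1 - m.ix0 + 1, mh = m.iy1 - m.iy0 + 1;
  double num = 0.0, ss = 0.0, rr = 0.0;
  for (int j = 0; j < mh; ++j)
    for (int i = 0; i < mw; ++i) {
      double h = H[(size_t)j * mw + i];
      double r = href(m.iy0 + j, m.ix0 + i);
      num += h * r; ss += h * h; rr += r * r;
    }
  ss_out = ss;
  if (ss <= 0.0 || rr <= 0.0) return NA_REAL;
  double ns = std::sqrt(ss), nr = std::sqrt(rr);
  double cs = num / (ns * nr);
  dVdH.assign((size_t)mw * mh, 0.0);
  for (int j = 0; j < mh; ++j)
    for (int i = 0; i < mw; ++i) {
      size_t p = (size_t)j * mw + i;
      double h = H[p];
      double r = href(m.iy0 + j, m.ix0 + i);
      double dcs = r / (ns * nr) - cs * h / ss;
      dVdH[p] = -k * dcs;
    }
  return cs;
}

inline MaskBox whole_mask(const Grid &g) { return MaskBox{0, g.nx - 1, 0, g.ny - 1}; }

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_render_smooth(NumericMatrix coords, NumericVector radius,
                                int nx, int ny, double dx, double dy,
                                double x0, double y0,
                                double sx, double sy, double gamma) {
  Grid g{nx, ny, dx, dy, x0, y0};
  MaskBox m = whole_mask(g);
  SmoothWorkspace ws;
  smooth_forward(coords, radius, g, m, sx, sy, gamma, ws);
  NumericMatrix H(ny, nx);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      H(j, i) = ws.H[(size_t)j * nx + i];
  return H;
}

// [[Rcpp::export]]
NumericMatrix cpp_render_collision(NumericMatrix coords, NumericVector radius,
                                   int nx, int ny, double dx, double dy,
                                   double x0, double y0, double tip_radius) {
  const int n = coords.nrow();
  NumericMatrix H(ny, nx); // zero-initialized (stage floor)
  for (int b = 0; b < n; ++b) {
    double reach = radius[b] + tip_radius;
    double xb = coords(b, 0), yb = coords(b, 1), zb = coords(b, 2);
    int ix0 = clampi((int)std::floor((xb - reach - x0) / dx), 0, nx - 1);
    int ix1 = clampi((int)std::ceil((xb + reach - x0) / dx), 0, nx - 1);
    int iy0 = clampi((int)std::floor((yb - reach - y0) / dy), 0, ny - 1);
    int iy1 = clampi((int)std::ceil((yb + reach - y0) / dy), 0, ny - 1);
    for (int j = iy0; j <= iy1; ++j) {
      double yp = y0 + j * dy;
      for (int i = ix0; i <= ix1; ++i) {
        double xp = x0 + i * dx;
        double d2 = (xb - xp) * (xb - xp) + (yb - yp) * (yb - yp);
        if (d2 >= reach * reach) continue;
        // tip apex height when a sphere tip (radius R) on pixel p's vertical
        // line touches bead b: h = z_b - R + sqrt((R + r_b)^2 - d^2)
        double h = zb - tip_radius + std::sqrt(reach * reach - d2);
        if (h > H(j, i)) H(j, i) = h;
      }
    }
  }
  return H;
}

// [[Rcpp::export]]
List cpp_bias_energy_forces(NumericMatrix coords, NumericVector radius,
                            NumericMatrix href,
                            double dx, double dy, double x0, double y0,
                            int mx0, int mx1, int my0, int my1, // 0-based incl.
                            double k, double sx, double sy, double gamma) {
  Grid g{href.ncol(), href.nrow(), dx, dy, x0, y0};
  MaskBox m{mx0, mx1, my0, my1};
  SmoothWorkspace ws;
  smooth_forward(coords, radius, g, m, sx, sy, gamma, ws);
  std::vector<double> dVdH;
  double ss = 0.0;
  double cs = bias_dVdH(ws.H, href, m, k, dVdH, ss);
  NumericMatrix forces(coords.nrow(), 3);
  if (!NumericVector::is_na(cs))
    smooth_backward(coords, g, m, sx, sy, gamma, ws, dVdH, forces);
  return List::create(_["cs"] = cs, _["energy"] = NumericVector::is_na(cs)
                        ? NA_REAL : k * (1.0 - cs),
                      _["forces"] = forces, _["sum_sq_sim"] = ss);
}

// ---------------------------------------------------------------------------
// Structure-based protein potential:
//   bonds     V = kb (d - d0)^2
//   angles    V = ka (th - th0)^2
//   contacts  V = -eps exp(-(d - d0)^2 / (2 w^2))
//   excl.vol. V = e [(s/d)^12 - 2 (s/d)^6 + 1], d < s = r_i + r_j (WCA-like)
// ---------------------------------------------------------------------------
namespace {

struct Topo {
  IntegerMatrix bonds;   NumericVector bond_r0, bond_k;
  IntegerMatrix angles;  NumericVector ang_th0, ang_k;
  IntegerMatrix contacts; NumericVector con_r0, con_eps, con_w;
  double ev_eps;
  std::unordered_set<uint64_t> excl;
};

inline uint64_t pairkey(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (uint64_t)i * (uint64_t)n + (uint64_t)j;
}

static Topo unpack_topo(const List &tl, int n) {
  Topo t;
  t.bonds = as<IntegerMatrix>(tl["bonds_ij"]);
  t.bond_r0 = as<NumericVector>(tl["bonds_r0"]);
  t.bond_k = as<NumericVector>(tl["bonds_k"]);
  t.angles = as<IntegerMatrix>(tl["angles_ijk"]);
  t.ang_th0 = as<NumericVector>(tl["angles_th0"]);
  t.ang_k = as<NumericVector>(tl["angles_k"]);
  t.contacts = as<IntegerMatrix>(tl["contacts_ij"]);
  t.con_r0 = as<NumericVector>(tl["contacts_r0"]);
  t.con_eps = as<NumericVector>(tl["contacts_eps"]);
  t.con_w = as<NumericVector>(tl["contacts_w"]);
  t.ev_eps = as<double>(tl["ev_eps"]);
  for (int b = 0; b < t.bonds.nrow(); ++b)
    t.excl.insert(pairkey(t.bonds(b, 0), t.bonds(b, 1), n));
  for (int a = 0; a < t.angles.nrow(); ++a) {
    t.excl.insert(pairkey(t.angles(a, 0), t.angles(a, 1), n));
    t.excl.insert(pairkey(t.angles(a, 1), t.angles(a, 2), n));
    t.excl.insert(pairkey(t.angles(a, 0), t.angles(a, 2), n));
  }
  for (int c = 0; c < t.contacts.nrow(); ++c)
    t.excl.insert(pairkey(t.contacts(c, 0), t.contacts(c, 1), n));
  return t;
}

static double protein_ef(const NumericMatrix &coords, const NumericVector &radius,
                         const Topo &t, NumericMatrix &forces) {
  const int n = coords.nrow();
  double E = 0.0;
  // bonds
  for (int b = 0; b < t.bonds.nrow(); ++b) {
    int i = t.bonds(b, 0), j = t.bonds(b, 1);
    double ux = coords(i,0)-coords(j,0), uy = coords(i,1)-coords(j,1), uz = coords(i,2)-coords(j,2);
    double d = std::sqrt(ux*ux + uy*uy + uz*uz);
    double dd = d - t.bond_r0[b];
    E += t.bond_k[b] * dd * dd;
    if (d > 1e-12) {
      double f = -2.0 * t.bond_k[b] * dd / d;
      forces(i,0) += f*ux; forces(i,1) += f*uy; forces(i,2) += f*uz;
      forces(j,0) -= f*ux; forces(j,1) -= f*uy; forces(j,2) -= f*uz;
    }
  }
  // angles
  for (int a = 0; a < t.angles.nrow(); ++a) {
    int i = t.angles(a,0), j = t.angles(a,1), k = t.angles(a,2);
    double ux = coords(i,0)-coords(j,0), uy = coords(i,1)-coords(j,1), uz = coords(i,2)-coords(j,2);
    double vx = coords(k,0)-coords(j,0), vy = coords(k,1)-coords(j,1), vz = coords(k,2)-coords(j,2);
    double nu = std::sqrt(ux*ux+uy*uy+uz*uz), nv = std::sqrt(vx*vx+vy*vy+vz*vz);
    if (nu < 1e-12 || nv < 1e-12) continue;
    double ct = (ux*vx+uy*vy+uz*vz)/(nu*nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double dth = th - t.ang_th0[a];
    E += t.ang_k[a] * dth * dth;
    double st = std::sqrt(1.0 - ct*ct);
    if (st < 1e-8) continue;
    double dVdth = 2.0 * t.ang_k[a] * dth;
    double cu = 1.0/(nu*st), cv = 1.0/(nv*st);
    // dth/du = (ct*u_hat - v_hat)/(nu*st)
    double gix = cu*(ct*ux/nu - vx/nv), giy = cu*(ct*uy/nu - vy/nv), giz = cu*(ct*uz/nu - vz/nv);
    double gkx = cv*(ct*vx/nv - ux/nu), gky = cv*(ct*vy/nv - uy/nu), gkz = cv*(ct*vz/nv - uz/nu);
    forces(i,0) -= dVdth*gix; forces(i,1) -= dVdth*giy; forces(i,2) -= dVdth*giz;
    forces(k,0) -= dVdth*gkx; forces(k,1) -= dVdth*gky; forces(k,2) -= dVdth*gkz;
    forces(j,0) += dVdth*(gix+gkx); forces(j,1) += dVdth*(giy+gky); forces(j,2) += dVdth*(giz+gkz);
  }
  // native contacts (Gaussian wells)
  for (int c = 0; c < t.contacts.nrow(); ++c) {
    int i = t.contacts(c,0), j = t.contacts(c,1);
    double ux = coords(i,0)-coords(j,0), uy = coords(i,1)-coords(j,1), uz = coords(i,2)-coords(j,2);
    double d = std::sqrt(ux*ux+uy*uy+uz*uz);
    double w2 = t.con_w[c]*t.con_w[c];
    double dd = d - t.con_r0[c];
    double g = std::exp(-dd*dd/(2.0*w2));
    E += -t.con_eps[c]*g;
    if (d > 1e-12) {
      double f = -t.con_eps[c]*g*dd/(w2*d); // -dV/dd * 1/d
      forces(i,0) += f*ux; forces(i,1) += f*uy; forces(i,2) += f*uz;
      forces(j,0) -= f*ux; forces(j,1) -= f*uy; forces(j,2) -= f*uz;
    }
  }
  // soft-core excluded volume over non-excluded pairs
  if (t.ev_eps > 0.0) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double s = radius[i] + radius[j];
        double ux = coords(i,0)-coords(j,0), uy = coords(i,1)-coords(j,1), uz = coords(i,2)-coords(j,2);
        double d2 = ux*ux+uy*uy+uz*uz;
        if (d2 >= s*s) continue;
        if (t.excl.count(pairkey(i, j, n))) continue;
        double d = std::sqrt(d2);
        if (d < 1e-9) continue;
        // soft core: linear continuation below 0.7 s keeps forces bounded
        // when configurations far from this topology's reference overlap
        double dc = 0.7 * s, de = d < dc ? dc : d;
        double sr6 = std::pow(s/de, 6.0), sr12 = sr6*sr6;
        double V = t.ev_eps*(sr12 - 2.0*sr6 + 1.0);
        double dVdd = -t.ev_eps*12.0*(sr12 - sr6)/de;
        if (d < dc) V += dVdd * (d - dc);
        E += V;
        double f = -dVdd/d;
        forces(i,0) += f*ux; forces(i,1) += f*uy; forces(i,2) += f*uz;
        forces(j,0) -= f*ux; forces(j,1) -= f*uy; forces(j,2) -= f*uz;
      }
  }
  return E;
}

// 12-6 wall in z with minimum -eps at z = sigma; linear continuation below
// 0.7 sigma keeps forces finite if a bead ever penetrates the stage.
static double stage_ef(const NumericMatrix &coords, const NumericVector &sigma,
                       double eps, NumericMatrix &forces, int &ncapped) {
  const int n = coords.nrow();
  double E = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = sigma[i];
    double z = coords(i, 2), zc = 0.7 * s;
    bool capped = z < zc;
    double ze = capped ? zc : z;
    double sr6 = std::pow(s / ze, 6.0), sr12 = sr6 * sr6;
    double V = eps * (sr12 - 2.0 * sr6);
    double dVdz = eps * (-12.0 * sr12 + 12.0 * sr6) / ze;
    if (capped) { V += dVdz * (z - zc); ++ncapped; }
    E += V;
    forces(i, 2) -= dVdz;
  }
  return E;
}

// anchors: (idx -> fixed point, k, d0); pairs: (i, j, k, d0); all x multiplier
static double restraint_ef(const NumericMatrix &coords,
                           const IntegerVector &an_idx, const NumericMatrix &an_xyz,
                           const NumericVector &an_k, const NumericVector &an_d0,
                           const IntegerMatrix &pr_ij, const NumericVector &pr_k,
                           const NumericVector &pr_d0,
                           double mult, NumericMatrix &forces) {
  double E = 0.0;
  if (mult == 0.0) return 0.0;
  for (int r = 0; r < an_idx.size(); ++r) {
    int i = an_idx[r];
    double ux = coords(i,0)-an_xyz(r,0), uy = coords(i,1)-an_xyz(r,1), uz = coords(i,2)-an_xyz(r,2);
    double d = std::sqrt(ux*ux+uy*uy+uz*uz);
    double dd = d - an_d0[r];
    double keff = mult * an_k[r];
    E += 0.5 * keff * dd * dd;
    if (d > 1e-12) {
      double f = -keff * dd / d;
      forces(i,0) += f*ux; forces(i,1) += f*uy; forces(i,2) += f*uz;
    }
  }
  for (int r = 0; r < pr_ij.nrow(); ++r) {
    int i = pr_ij(r,0), j = pr_ij(r,1);
    double ux = coords(i,0)-coords(j,0), uy = coords(i,1)-coords(j,1), uz = coords(i,2)-coords(j,2);
    double d = std::sqrt(ux*ux+uy*uy+uz*uz);
    double dd = d - pr_d0[r];
    double keff = mult * pr_k[r];
    E += 0.5 * keff * dd * dd;
    if (d > 1e-12) {
      double f = -keff * dd / d;
      forces(i,0) += f*ux; forces(i,1) += f*uy; forces(i,2) += f*uz;
      forces(j,0) -= f*ux; forces(j,1) -= f*uy; forces(j,2) -= f*uz;
    }
  }
  return E;
}

} // namespace

// [[Rcpp::export]]
List cpp_protein_energy_forces(NumericMatrix coords, NumericVector radius, List topo) {
  Topo t = unpack_topo(topo, coords.nrow());
  NumericMatrix forces(coords.nrow(), 3);
  double E = protein_ef(coords, radius, t, forces);
  return List::create(_["energy"] = E, _["forces"] = forces);
}

// [[Rcpp::export]]
List cpp_stage_energy_forces(NumericMatrix coords, NumericVector sigma, double eps) {
  NumericMatrix forces(coords.nrow(), 3);
  int ncap = 0;
  double E = stage_ef(coords, sigma, eps, forces, ncap);
  return List::create(_["energy"] = E, _["forces"] = forces, _["n_capped"] = ncap);
}

// [[Rcpp::export]]
List cpp_restraint_energy_forces(NumericMatrix coords,
                                 IntegerVector an_idx, NumericMatrix an_xyz,
                                 NumericVector an_k, NumericVector an_d0,
                                 IntegerMatrix pr_ij, NumericVector pr_k,
                                 NumericVector pr_d0, double mult) {
  NumericMatrix forces(coords.nrow(), 3);
  double E = restraint_ef(coords, an_idx, an_xyz, an_k, an_d0,
                          pr_ij, pr_k, pr_d0, mult, forces);
  return List::create(_["energy"] = E, _["forces"] = forces);
}

// ---------------------------------------------------------------------------
// BAOAB Langevin integrator over V_protein + V_stage + V_restraint + V_AFM.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix coords0, NumericVector radius, List topo,
                      NumericVector stage_sigma, double stage_eps,
                      List restraints, double restraint_mult,
                      bool bias_on, NumericMatrix href,
                      double dx, double dy, double x0, double y0,
                      int mx0, int mx1, int my0, int my1,
                      double k_bias, double sx, double sy, double gamma_afm,
                      double temperature, double friction, double dt,
                      int n_steps, int record_interval,
                      int seed, int stream) {
  const int n = coords0.nrow();
  Topo t = unpack_topo(topo, n);
  IntegerVector an_idx = as<IntegerVector>(restraints["an_idx"]);
  NumericMatrix an_xyz = as<NumericMatrix>(restraints["an_xyz"]);
  NumericVector an_k = as<NumericVector>(restraints["an_k"]);
  NumericVector an_d0 = as<NumericVector>(restraints["an_d0"]);
  IntegerMatrix pr_ij = as<IntegerMatrix>(restraints["pr_ij"]);
  NumericVector pr_k = as<NumericVector>(restraints["pr_k"]);
  NumericVector pr_d0 = as<NumericVector>(restraints["pr_d0"]);

  Grid g{href.ncol(), href.nrow(), dx, dy, x0, y0};
  MaskBox m{mx0, mx1, my0, my1};

  GaussRNG rng((uint64_t)(uint32_t)seed, (uint64_t)(uint32_t)stream);
  // Uniform bead mass in reduced units; heavy enough that the stiffest
  // modes of the structure-based model satisfy omega*dt < 1 at dt = 0.3.
  const double kT = KBOLTZ * temperature;
  const double mass = 40.0;
  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(std::max(0.0, kT * (1.0 - c1 * c1) / mass));

  NumericMatrix x = clone(coords0);
  NumericMatrix v(n, 3);
  double vs = std::sqrt(kT / mass);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) v(i, d) = vs * rng.gauss();

  NumericMatrix f(n, 3);
  SmoothWorkspace ws;
  std::vector<double> dVdH;

  double e_prot = 0.0, e_stage = 0.0, e_rest = 0.0, e_bias = 0.0, cs = NA_REAL;
  int ncap = 0;
  bool undefined_sim = false;
  auto eval_forces = [&]() {
    std::fill(f.begin(), f.end(), 0.0);
    e_prot = protein_ef(x, radius, t, f);
    e_stage = stage_ef(x, stage_sigma, stage_eps, f, ncap);
    e_rest = restraint_ef(x, an_idx, an_xyz, an_k, an_d0, pr_ij, pr_k, pr_d0,
                          restraint_mult, f);
    e_bias = 0.0; cs = NA_REAL;
    if (bias_on) {
      smooth_forward(x, radius, g, m, sx, sy, gamma_afm, ws);
      double ss = 0.0;
      cs = bias_dVdH(ws.H, href, m, k_bias, dVdH, ss);
      if (NumericVector::is_na(cs)) { undefined_sim = true; return; }
      e_bias = k_bias * (1.0 - cs);
      smooth_backward(x, g, m, sx, sy, gamma_afm, ws, dVdH, f);
    }
  };

  eval_forces();

  int n_rec = n_steps / record_interval;
  IntegerVector rec_step(n_rec);
  NumericVector rec_cs(n_rec), rec_eprot(n_rec), rec_estage(n_rec),
      rec_ebias(n_rec), rec_erest(n_rec), rec_kin(n_rec);
  NumericVector snaps((size_t)n * 3 * n_rec);
  snaps.attr("dim") = IntegerVector::create(n, 3, n_rec);

  bool aborted = false;
  std::string abort_msg = "";
  int irec = 0;
  const double hdt = 0.5 * dt;

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        v(i, d) += hdt * f(i, d) / mass;
        x(i, d) += hdt * v(i, d);
      }
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        v(i, d) = c1 * v(i, d) + c2 * rng.gauss();
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        x(i, d) += hdt * v(i, d);
    eval_forces();
    if (undefined_sim) {
      aborted = true;
      abort_msg = "similarity undefined: simulated image all-zero on the mask";
    }
    for (int i = 0; i < n && !aborted; ++i)
      for (int d = 0; d < 3; ++d)
        v(i, d) += hdt * f(i, d) / mass;

    double etot = e_prot + e_stage + e_rest + e_bias;
    if (!aborted && !std::isfinite(etot)) {
      aborted = true;
      abort_msg = "non-finite potential energy at step " + std::to_string(step);
    }
    if (aborted) break;

    if (step % record_interval == 0 && irec < n_rec) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) ke += 0.5 * mass * v(i, d) * v(i, d);
      rec_step[irec] = step;
      rec_cs[irec] = cs;
      rec_eprot[irec] = e_prot; rec_estage[irec] = e_stage;
      rec_ebias[irec] = e_bias; rec_erest[irec] = e_rest;
      rec_kin[irec] = ke;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          snaps[(size_t)irec * n * 3 + (size_t)d * n + i] = x(i, d);
      ++irec;
    }
  }

  return List::create(
      _["steps"] = rec_step, _["cs"] = rec_cs,
      _["e_protein"] = rec_eprot, _["e_stage"] = rec_estage,
      _["e_bias"] = rec_ebias, _["e_restraint"] = rec_erest,
      _["kinetic"] = rec_kin, _["snapshots"] = snaps,
      _["n_recorded"] = irec,
      _["final_coords"] = x, _["final_velocities"] = v,
      _["aborted"] = aborted, _["abort_message"] = abort_msg,
      _["n_stage_capped"] = ncap);
}
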