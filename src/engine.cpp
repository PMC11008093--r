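// Core molecular-dynamics engine for the coarse-grained membrane-wrapping
// model: Langevin velocity-Verlet integration, cell/Verlet neighbour lists,
// rigid-body nanoparticle dynamics, a Berendsen-style zero-tension lateral
// barostat, and per-step dynamic ligand-receptor bond updates.
//
// Reduced Lennard-Jones units throughout (epsilon, sigma, tau, m = 1).
// Species codes (0-based here, 1-based in R):
//   0 head, 1 tail, 2 receptor_head, 3 np_surface, 4 ligand.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static const int NSP = 5;
static const int SP_TAIL = 1, SP_RECEPTOR = 2, SP_LIGAND = 4;

// ---------------------------------------------------------------------------
// Deterministic RNG (xoshiro256**, seeded via splitmix64) so trajectories are
// bitwise reproducible for a given seed, independent of R's RNG state.
struct RNG {
  uint64_t s[4];
  explicit RNG(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t r = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  bool has_g = false;
  double g2 = 0.0;
  double gauss() {
    if (has_g) { has_g = false; return g2; }
    double u1, u2;
    do { u1 = unif(); } while (u1 <= 0.0);
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    g2 = r * std::sin(2.0 * M_PI * u2);
    has_g = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
  int randint(int n) { return (int)(next() % (uint64_t)n); }
};

// ---------------------------------------------------------------------------
struct PairTables {
  double b[NSP][NSP];        // WCA length scale per species pair
  double wca_eps[NSP][NSP];
  double cos_eps[NSP][NSP];  // 0 = no cosine attraction for this pair
  double cos_rc[NSP][NSP];
  double cos_wc[NSP][NSP];
  double cut2[NSP][NSP];     // squared interaction cutoff
  double wcut2[NSP][NSP];    // squared WCA cutoff (2^(1/6) b)^2
  double lcut2[NSP][NSP];    // squared Verlet-list cutoff (incl. skin and,
                             // in bond mode, the formation radius)
  PairTables() {
    for (int a = 0; a < NSP; a++)
      for (int b2 = 0; b2 < NSP; b2++) {
        b[a][b2] = 1.0; wca_eps[a][b2] = 0.0;
        cos_eps[a][b2] = 0.0; cos_rc[a][b2] = 0.0; cos_wc[a][b2] = 1.0;
        cut2[a][b2] = 0.0; wcut2[a][b2] = 0.0; lcut2[a][b2] = 1e30;
      }
  }
};

struct FeneType { double K, R0, b, eps; };

struct LRB {                  // dynamic-bond scheme parameters
  bool enabled = false;
  double eps = 0, rc = 0, wc = 0, r_form = 0, p_form = 0, r_break = 0;
  double cap = 1;             // may be R_PosInf
};

struct BondEvent { double time; int lig, rec; int type; double r; }; // 1 formed, 0 broken

struct Sim {
  int N = 0;
  std::vector<double> x, y, z, vx, vy, vz, fx, fy, fz, mass;
  std::vector<int> species;
  double Lx = 0, Ly = 0, Lz = 0;
  double time = 0;

  std::vector<std::array<int, 2>> bonds;
  std::vector<int> bond_type;
  std::vector<std::array<int, 3>> angles;
  std::vector<FeneType> fene;
  double angK = 10, angTheta0 = M_PI;

  PairTables pt;
  LRB lrb;

  // dynamic ligand-receptor bonds
  std::vector<std::array<int, 2>> lr_bonds;       // (ligand, receptor)
  std::vector<int> lr_count;                       // live bonds per bead
  std::vector<std::vector<int>> lr_partners;       // partners per bead
  std::vector<BondEvent> events;

  // rigid body (the nanoparticle)
  bool has_body = false;
  std::vector<int> body_idx;
  std::vector<int> body_of;                        // -1 for free beads
  double bodyM = 0;
  std::array<double, 3> com{}, vcom{}, Lang{};
  double quat[4] = {1, 0, 0, 0};
  std::vector<std::array<double, 3>> rbody;
  double Ibinv[3][3] = {{0}};

  // exclusions: direct FENE partners
  std::vector<std::vector<int>> bonded_to;

  // neighbour list (flat pair arrays, buffers reused across rebuilds)
  double verlet_cut = 0, skin = 0.4;
  std::vector<int> pli, plj;
  std::vector<double> x0, y0, z0;                  // positions at last build
  long n_builds = 0;

  // accumulators from the last force evaluation
  double pe_pair = 0, pe_bond = 0, pe_angle = 0, pe_lr_pair = 0,
         pe_lr_bond = 0;
  double Wxx = 0, Wyy = 0;

  // Positions are re-wrapped into [0, L) at every neighbour-list rebuild
  // (rigid bodies as a unit), so inter-rebuild drift keeps |d| < 1.5 L and a
  // single fold suffices — much cheaper than nearbyint on this hot path.
  static inline double fold(double d, double L) {
    if (d > 0.5 * L) d -= L;
    else if (d < -0.5 * L) d += L;
    return d;
  }
  double min_image_x(double d) const { return fold(d, Lx); }
  double min_image_y(double d) const { return fold(d, Ly); }
  double min_image_z(double d) const { return fold(d, Lz); }

  void wrap_positions() {
    for (int i = 0; i < N; i++) {
      if (body_of[i] >= 0) continue;
      x[i] -= Lx * std::floor(x[i] / Lx);
      y[i] -= Ly * std::floor(y[i] / Ly);
      z[i] -= Lz * std::floor(z[i] / Lz);
    }
    if (has_body) {
      double sx = Lx * std::floor(com[0] / Lx);
      double sy = Ly * std::floor(com[1] / Ly);
      double sz = Lz * std::floor(com[2] / Lz);
      if (sx != 0 || sy != 0 || sz != 0) {
        com[0] -= sx; com[1] -= sy; com[2] -= sz;
        for (int i : body_idx) { x[i] -= sx; y[i] -= sy; z[i] -= sz; }
      }
    }
  }

  bool excluded(int i, int j) const {
    if (body_of[i] >= 0 && body_of[i] == body_of[j]) return true;
    const std::vector<int> &bi = bonded_to[i];
    return std::find(bi.begin(), bi.end(), j) != bi.end();
  }

  // ---- neighbour list ----
  void build_neighbors() {
    n_builds++;
    wrap_positions();
    const double rc = verlet_cut + skin, rc2 = rc * rc;
    pli.clear(); plj.clear();
    int ncx = std::max(1, (int)std::floor(Lx / rc));
    int ncy = std::max(1, (int)std::floor(Ly / rc));
    int ncz = std::max(1, (int)std::floor(Lz / rc));
    if (ncx < 3 || ncy < 3 || ncz < 3) {
      for (int i = 0; i < N; i++)
        for (int j = i + 1; j < N; j++) {
          double dx = min_image_x(x[i] - x[j]);
          double dy = min_image_y(y[i] - y[j]);
          double dz = min_image_z(z[i] - z[j]);
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < rc2 && d2 < pt.lcut2[species[i]][species[j]] &&
              !excluded(i, j)) {
            pli.push_back(i); plj.push_back(j);
          }
        }
    } else {
      int ncell = ncx * ncy * ncz;
      std::vector<int> head(ncell, -1), nxt(N, -1);
      for (int i = 0; i < N; i++) {
        double xi = x[i] - Lx * std::floor(x[i] / Lx);
        double yi = y[i] - Ly * std::floor(y[i] / Ly);
        double zi = z[i] - Lz * std::floor(z[i] / Lz);
        int cx = std::min(ncx - 1, (int)(xi / Lx * ncx));
        int cy = std::min(ncy - 1, (int)(yi / Ly * ncy));
        int cz = std::min(ncz - 1, (int)(zi / Lz * ncz));
        int c = (cz * ncy + cy) * ncx + cx;
        nxt[i] = head[c]; head[c] = i;
      }
      for (int cz = 0; cz < ncz; cz++)
        for (int cy = 0; cy < ncy; cy++)
          for (int cx = 0; cx < ncx; cx++) {
            int c = (cz * ncy + cy) * ncx + cx;
            for (int dz = -1; dz <= 1; dz++)
              for (int dy = -1; dy <= 1; dy++)
                for (int dx = -1; dx <= 1; dx++) {
                  int c2x = (cx + dx + ncx) % ncx;
                  int c2y = (cy + dy + ncy) % ncy;
                  int c2z = (cz + dz + ncz) % ncz;
                  int c2 = (c2z * ncy + c2y) * ncx + c2x;
                  if (c2 < c) continue;
                  for (int i = head[c]; i >= 0; i = nxt[i])
                    for (int j = head[c2]; j >= 0; j = nxt[j]) {
                      if (c2 == c && j >= i) continue;
                      double ddx = min_image_x(x[i] - x[j]);
                      double ddy = min_image_y(y[i] - y[j]);
                      double ddz = min_image_z(z[i] - z[j]);
                      double dd2 = ddx * ddx + ddy * ddy + ddz * ddz;
                      if (dd2 < rc2 &&
                          dd2 < pt.lcut2[species[i]][species[j]] &&
                          !excluded(i, j)) {
                        pli.push_back(std::min(i, j));
                        plj.push_back(std::max(i, j));
                      }
                    }
                }
          }
    }
    x0 = x; y0 = y; z0 = z;
  }

  bool need_rebuild() const {
    const double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < N; i++) {
      double dx = x[i] - x0[i], dy = y[i] - y0[i], dz = z[i] - z0[i];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }

  // ---- forces ----
  void compute_forces() {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    pe_pair = pe_bond = pe_angle = pe_lr_pair = pe_lr_bond = 0;
    Wxx = Wyy = 0;

    // non-bonded pairs
    const size_t npairs = pli.size();
    for (size_t k = 0; k < npairs; k++) {
      {
        const int i = pli[k], j = plj[k];
        const int si = species[i], sj = species[j];
        double dx = min_image_x(x[i] - x[j]);
        double dy = min_image_y(y[i] - y[j]);
        double dz = min_image_z(z[i] - z[j]);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= pt.cut2[si][sj]) continue;
        double fpr = 0.0;  // force / r
        const double b = pt.b[si][sj], weps = pt.wca_eps[si][sj];
        if (r2 < pt.wcut2[si][sj]) {
          double sr2 = b * b / r2, sr6 = sr2 * sr2 * sr2;
          fpr += 4.0 * weps * (12.0 * sr6 * sr6 - 6.0 * sr6) / r2;
          pe_pair += 4.0 * weps * (sr6 * sr6 - sr6) + weps;
        }
        const double ceps = pt.cos_eps[si][sj];
        if (ceps > 0.0) {
          double r = std::sqrt(r2);
          double crc = pt.cos_rc[si][sj], cwc = pt.cos_wc[si][sj];
          double u = 0.0;
          if (r <= crc) {
            u = -ceps;
          } else if (r <= crc + cwc) {
            double xx = M_PI * (r - crc) / (2.0 * cwc);
            double c = std::cos(xx);
            u = -ceps * c * c;
            fpr += -ceps * M_PI / (2.0 * cwc) * std::sin(2.0 * xx) / r;
          }
          if (si == SP_TAIL && sj == SP_TAIL) pe_pair += u;
          else pe_lr_pair += u;
        }
        fx[i] += fpr * dx; fy[i] += fpr * dy; fz[i] += fpr * dz;
        fx[j] -= fpr * dx; fy[j] -= fpr * dy; fz[j] -= fpr * dz;
        Wxx += fpr * dx * dx; Wyy += fpr * dy * dy;
      }
    }

    // FENE bonds
    for (size_t k = 0; k < bonds.size(); k++) {
      int i = bonds[k][0], j = bonds[k][1];
      const FeneType &ft = fene[bond_type[k]];
      double dx = min_image_x(x[i] - x[j]);
      double dy = min_image_y(y[i] - y[j]);
      double dz = min_image_z(z[i] - z[j]);
      double r2 = dx * dx + dy * dy + dz * dz;
      double rlog = 1.0 - r2 / (ft.R0 * ft.R0);
      if (rlog <= 0.0)
        stop("overstretched FENE bond (r >= %g sigma) between beads %d and %d at t = %g tau",
             ft.R0, i + 1, j + 1, time);
      double fbond = -ft.K / rlog;
      pe_bond += -0.5 * ft.K * ft.R0 * ft.R0 * std::log(rlog);
      const double wcut2 = std::cbrt(2.0) * ft.b * ft.b;  // per bond, cold
      if (r2 < wcut2) {
        double sr2 = ft.b * ft.b / r2, sr6 = sr2 * sr2 * sr2;
        fbond += 4.0 * ft.eps * (12.0 * sr6 * sr6 - 6.0 * sr6) / r2;
        pe_bond += 4.0 * ft.eps * (sr6 * sr6 - sr6) + ft.eps;
      }
      fx[i] += fbond * dx; fy[i] += fbond * dy; fz[i] += fbond * dz;
      fx[j] -= fbond * dx; fy[j] -= fbond * dy; fz[j] -= fbond * dz;
      Wxx += fbond * dx * dx; Wyy += fbond * dy * dy;
    }

    // harmonic angles, E = K (theta - theta0)^2
    for (size_t k = 0; k < angles.size(); k++) {
      int i1 = angles[k][0], i2 = angles[k][1], i3 = angles[k][2];
      double d1x = min_image_x(x[i1] - x[i2]);
      double d1y = min_image_y(y[i1] - y[i2]);
      double d1z = min_image_z(z[i1] - z[i2]);
      double d2x = min_image_x(x[i3] - x[i2]);
      double d2y = min_image_y(y[i3] - y[i2]);
      double d2z = min_image_z(z[i3] - z[i2]);
      double rsq1 = d1x * d1x + d1y * d1y + d1z * d1z;
      double rsq2 = d2x * d2x + d2y * d2y + d2z * d2z;
      double r1 = std::sqrt(rsq1), r2 = std::sqrt(rsq2);
      double dot = d1x * d2x + d1y * d2y + d1z * d2z;
      double c = dot / (r1 * r2);
      c = std::max(-1.0, std::min(1.0, c));
      // sin(theta) from the cross product: well-conditioned near theta = pi,
      // where acos/sqrt(1 - c^2) lose precision (lipids sit near 180 deg)
      double cxv = d1y * d2z - d1z * d2y;
      double cyv = d1z * d2x - d1x * d2z;
      double czv = d1x * d2y - d1y * d2x;
      double cr = std::sqrt(cxv * cxv + cyv * cyv + czv * czv);
      double s = cr / (r1 * r2);
      if (s < 1e-12) s = 1e-12;
      double dtheta = std::atan2(cr, dot) - angTheta0;
      pe_angle += angK * dtheta * dtheta;
      double a = -2.0 * angK * dtheta / s;
      double a11 = a * c / rsq1, a12 = -a / (r1 * r2), a22 = a * c / rsq2;
      double f1x = a11 * d1x + a12 * d2x;
      double f1y = a11 * d1y + a12 * d2y;
      double f1z = a11 * d1z + a12 * d2z;
      double f3x = a22 * d2x + a12 * d1x;
      double f3y = a22 * d2y + a12 * d1y;
      double f3z = a22 * d2z + a12 * d1z;
      fx[i1] += f1x; fy[i1] += f1y; fz[i1] += f1z;
      fx[i3] += f3x; fy[i3] += f3y; fz[i3] += f3z;
      fx[i2] -= f1x + f3x; fy[i2] -= f1y + f3y; fz[i2] -= f1z + f3z;
      Wxx += d1x * f1x + d2x * f3x;
      Wyy += d1y * f1y + d2y * f3y;
    }

    // dynamic ligand-receptor bonds: same cosine well as the pair scheme;
    // zero force beyond its support (a freshly formed long bond is slack).
    if (lrb.enabled) {
      for (size_t k = 0; k < lr_bonds.size(); k++) {
        int i = lr_bonds[k][0], j = lr_bonds[k][1];
        double dx = min_image_x(x[i] - x[j]);
        double dy = min_image_y(y[i] - y[j]);
        double dz = min_image_z(z[i] - z[j]);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        double fpr = 0.0;
        if (r <= lrb.rc) {
          pe_lr_bond += -lrb.eps;
        } else if (r <= lrb.rc + lrb.wc) {
          double xx = M_PI * (r - lrb.rc) / (2.0 * lrb.wc);
          double c = std::cos(xx);
          pe_lr_bond += -lrb.eps * c * c;
          fpr = -lrb.eps * M_PI / (2.0 * lrb.wc) * std::sin(2.0 * xx) / r;
        }
        fx[i] += fpr * dx; fy[i] += fpr * dy; fz[i] += fpr * dz;
        fx[j] -= fpr * dx; fy[j] -= fpr * dy; fz[j] -= fpr * dz;
        Wxx += fpr * dx * dx; Wyy += fpr * dy * dy;
      }
    }
  }

  double potential_energy() const {
    return pe_pair + pe_bond + pe_angle + pe_lr_pair + pe_lr_bond;
  }

  // ---- rigid body ----
  void init_body() {
    if (!has_body) return;
    bodyM = 0;
    com = {0, 0, 0};
    // accumulate relative to the first bead with minimum-image displacements
    // so a body straddling a periodic boundary is handled correctly
    int ref = body_idx[0];
    for (int i : body_idx) {
      bodyM += mass[i];
      com[0] += mass[i] * min_image_x(x[i] - x[ref]);
      com[1] += mass[i] * min_image_y(y[i] - y[ref]);
      com[2] += mass[i] * min_image_z(z[i] - z[ref]);
    }
    com[0] = x[ref] + com[0] / bodyM;
    com[1] = y[ref] + com[1] / bodyM;
    com[2] = z[ref] + com[2] / bodyM;
    for (int i : body_idx) {  // rebuild contiguous bead positions
      x[i] = com[0] + min_image_x(x[i] - com[0]);
      y[i] = com[1] + min_image_y(y[i] - com[1]);
      z[i] = com[2] + min_image_z(z[i] - com[2]);
    }
    vcom = {0, 0, 0}; Lang = {0, 0, 0};
    quat[0] = 1; quat[1] = quat[2] = quat[3] = 0;
    rbody.clear();
    double I[3][3] = {{0}};
    for (int i : body_idx) {
      std::array<double, 3> r = {x[i] - com[0], y[i] - com[1], z[i] - com[2]};
      rbody.push_back(r);
      double m = mass[i];
      double r2 = r[0] * r[0] + r[1] * r[1] + r[2] * r[2];
      for (int a = 0; a < 3; a++)
        for (int bI = 0; bI < 3; bI++)
          I[a][bI] += m * ((a == bI ? r2 : 0.0) - r[a] * r[bI]);
    }
    // invert the (symmetric, well-conditioned) inertia tensor
    double det = I[0][0] * (I[1][1] * I[2][2] - I[1][2] * I[2][1])
               - I[0][1] * (I[1][0] * I[2][2] - I[1][2] * I[2][0])
               + I[0][2] * (I[1][0] * I[2][1] - I[1][1] * I[2][0]);
    if (std::abs(det) < 1e-12) stop("singular rigid-body inertia tensor");
    double inv[3][3] = {
      {(I[1][1] * I[2][2] - I[1][2] * I[2][1]) / det,
       (I[0][2] * I[2][1] - I[0][1] * I[2][2]) / det,
       (I[0][1] * I[1][2] - I[0][2] * I[1][1]) / det},
      {(I[1][2] * I[2][0] - I[1][0] * I[2][2]) / det,
       (I[0][0] * I[2][2] - I[0][2] * I[2][0]) / det,
       (I[0][2] * I[1][0] - I[0][0] * I[1][2]) / det},
      {(I[1][0] * I[2][1] - I[1][1] * I[2][0]) / det,
       (I[0][1] * I[2][0] - I[0][0] * I[2][1]) / det,
       (I[0][0] * I[1][1] - I[0][1] * I[1][0]) / det}};
    for (int a = 0; a < 3; a++)
      for (int bI = 0; bI < 3; bI++) Ibinv[a][bI] = inv[a][bI];
  }

  void quat_to_rot(double R[3][3]) const {
    double w = quat[0], qx = quat[1], qy = quat[2], qz = quat[3];
    R[0][0] = 1 - 2 * (qy * qy + qz * qz);
    R[0][1] = 2 * (qx * qy - w * qz);
    R[0][2] = 2 * (qx * qz + w * qy);
    R[1][0] = 2 * (qx * qy + w * qz);
    R[1][1] = 1 - 2 * (qx * qx + qz * qz);
    R[1][2] = 2 * (qy * qz - w * qx);
    R[2][0] = 2 * (qx * qz - w * qy);
    R[2][1] = 2 * (qy * qz + w * qx);
    R[2][2] = 1 - 2 * (qx * qx + qy * qy);
  }

  std::array<double, 3> omega_world() const {
    double R[3][3];
    quat_to_rot(R);
    // omega = R Ibinv R^T L
    double Lb[3], wb[3];
    for (int a = 0; a < 3; a++)
      Lb[a] = R[0][a] * Lang[0] + R[1][a] * Lang[1] + R[2][a] * Lang[2];
    for (int a = 0; a < 3; a++)
      wb[a] = Ibinv[a][0] * Lb[0] + Ibinv[a][1] * Lb[1] + Ibinv[a][2] * Lb[2];
    std::array<double, 3> w;
    for (int a = 0; a < 3; a++)
      w[a] = R[a][0] * wb[0] + R[a][1] * wb[1] + R[a][2] * wb[2];
    return w;
  }

  void body_set_beads() {
    double R[3][3];
    quat_to_rot(R);
    std::array<double, 3> w = omega_world();
    for (size_t k = 0; k < body_idx.size(); k++) {
      int i = body_idx[k];
      const std::array<double, 3> &rb = rbody[k];
      double rx = R[0][0] * rb[0] + R[0][1] * rb[1] + R[0][2] * rb[2];
      double ry = R[1][0] * rb[0] + R[1][1] * rb[1] + R[1][2] * rb[2];
      double rz = R[2][0] * rb[0] + R[2][1] * rb[1] + R[2][2] * rb[2];
      x[i] = com[0] + rx; y[i] = com[1] + ry; z[i] = com[2] + rz;
      vx[i] = vcom[0] + w[1] * rz - w[2] * ry;
      vy[i] = vcom[1] + w[2] * rx - w[0] * rz;
      vz[i] = vcom[2] + w[0] * ry - w[1] * rx;
    }
  }

  void body_force_torque(double F[3], double T[3]) const {
    F[0] = F[1] = F[2] = 0; T[0] = T[1] = T[2] = 0;
    for (int i : body_idx) {
      F[0] += fx[i]; F[1] += fy[i]; F[2] += fz[i];
      double rx = x[i] - com[0], ry = y[i] - com[1], rz = z[i] - com[2];
      T[0] += ry * fz[i] - rz * fy[i];
      T[1] += rz * fx[i] - rx * fz[i];
      T[2] += rx * fy[i] - ry * fx[i];
    }
  }

  void body_advance_orientation(double dt) {
    std::array<double, 3> w = omega_world();
    // qdot = 0.5 * (0, w) * q ; single-step update + renormalisation
    double qw = quat[0], qx = quat[1], qy = quat[2], qz = quat[3];
    double dw = 0.5 * (-w[0] * qx - w[1] * qy - w[2] * qz);
    double dx = 0.5 * (w[0] * qw + w[1] * qz - w[2] * qy);
    double dy = 0.5 * (w[1] * qw + w[2] * qx - w[0] * qz);
    double dz = 0.5 * (w[2] * qw + w[0] * qy - w[1] * qx);
    quat[0] += dt * dw; quat[1] += dt * dx;
    quat[2] += dt * dy; quat[3] += dt * dz;
    double nrm = std::sqrt(quat[0] * quat[0] + quat[1] * quat[1] +
                           quat[2] * quat[2] + quat[3] * quat[3]);
    for (int a = 0; a < 4; a++) quat[a] /= nrm;
  }

  // ---- dynamic bonds ----
  void add_lr_bond(int lig, int rec) {
    lr_bonds.push_back({lig, rec});
    lr_count[lig]++; lr_count[rec]++;
    lr_partners[lig].push_back(rec);
    lr_partners[rec].push_back(lig);
  }

  void remove_lr_bond(size_t k) {
    int lig = lr_bonds[k][0], rec = lr_bonds[k][1];
    lr_count[lig]--; lr_count[rec]--;
    auto &pl = lr_partners[lig];
    pl.erase(std::find(pl.begin(), pl.end(), rec));
    auto &pr = lr_partners[rec];
    pr.erase(std::find(pr.begin(), pr.end(), lig));
    lr_bonds[k] = lr_bonds.back();
    lr_bonds.pop_back();
  }

  double pair_dist(int i, int j) const {
    double dx = min_image_x(x[i] - x[j]);
    double dy = min_image_y(y[i] - y[j]);
    double dz = min_image_z(z[i] - z[j]);
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  }

  // Rupture first, then stochastic formation over a seeded random shuffle of
  // the candidate pairs, respecting the valence cap on both partners.
  void update_bonds(RNG &rng, bool log_events) {
    if (!lrb.enabled) return;
    for (size_t k = 0; k < lr_bonds.size();) {
      double r = pair_dist(lr_bonds[k][0], lr_bonds[k][1]);
      if (r > lrb.r_break) {
        if (log_events)
          events.push_back({time, lr_bonds[k][0], lr_bonds[k][1], 0, r});
        remove_lr_bond(k);
      } else {
        k++;
      }
    }
    // candidates from the Verlet list (its cutoff covers r_form + skin)
    std::vector<std::array<int, 2>> cand;
    for (size_t k = 0; k < pli.size(); k++) {
      int i = pli[k], j = plj[k];
      int si = species[i], sj = species[j];
      int lig, rec;
      if (si == SP_LIGAND && sj == SP_RECEPTOR) { lig = i; rec = j; }
      else if (si == SP_RECEPTOR && sj == SP_LIGAND) { lig = j; rec = i; }
      else continue;
      if (lr_count[lig] >= lrb.cap || lr_count[rec] >= lrb.cap) continue;
      const std::vector<int> &pl = lr_partners[lig];
      if (std::find(pl.begin(), pl.end(), rec) != pl.end()) continue;
      if (pair_dist(lig, rec) < lrb.r_form) cand.push_back({lig, rec});
    }
    for (int k = (int)cand.size() - 1; k > 0; k--)  // Fisher-Yates shuffle
      std::swap(cand[k], cand[rng.randint(k + 1)]);
    for (auto &c : cand) {
      if (lr_count[c[0]] >= lrb.cap || lr_count[c[1]] >= lrb.cap) continue;
      if (rng.unif() < lrb.p_form) {
        add_lr_bond(c[0], c[1]);
        if (log_events)
          events.push_back({time, c[0], c[1], 1, pair_dist(c[0], c[1])});
      }
    }
  }

  // ---- binding graph / valency ----
  // Pair mode counts every ligand/receptor pair within the interaction
  // support; bond mode reads the live bond set.
  void valency_sample(bool pair_mode, double support,
                      double &mean_val, double &bound_frac, int &n_edges) {
    int NL = 0;
    for (int i = 0; i < N; i++) if (species[i] == SP_LIGAND) NL++;
    std::vector<int> cnt(N, 0);
    n_edges = 0;
    if (pair_mode) {
      double sup2 = support * support;
      for (size_t k = 0; k < pli.size(); k++) {
        int i = pli[k], j = plj[k];
        int si = species[i], sj = species[j];
        if (!((si == SP_LIGAND && sj == SP_RECEPTOR) ||
              (si == SP_RECEPTOR && sj == SP_LIGAND))) continue;
        double dx = min_image_x(x[i] - x[j]);
        double dy = min_image_y(y[i] - y[j]);
        double dz = min_image_z(z[i] - z[j]);
        if (dx * dx + dy * dy + dz * dz < sup2) {
          cnt[i]++; cnt[j]++; n_edges++;
        }
      }
    } else {
      for (auto &bd : lr_bonds) { cnt[bd[0]]++; cnt[bd[1]]++; }
      n_edges = (int)lr_bonds.size();
    }
    int bound = 0;
    for (int i = 0; i < N; i++)
      if (species[i] == SP_LIGAND && cnt[i] > 0) bound++;
    mean_val = NL > 0 ? (double)n_edges / NL : 0.0;
    bound_frac = NL > 0 ? (double)bound / NL : 0.0;
  }
};

// ---------------------------------------------------------------------------
// Construction from the R-side state / force field lists

static Sim make_sim(const List &state, const List &ff) {
  Sim s;
  NumericMatrix pos = state["pos"], vel = state["vel"];
  IntegerVector species = state["species"];
  NumericVector mass = state["mass"], box = state["box"];
  s.N = pos.nrow();
  s.x.resize(s.N); s.y.resize(s.N); s.z.resize(s.N);
  s.vx.resize(s.N); s.vy.resize(s.N); s.vz.resize(s.N);
  s.fx.assign(s.N, 0); s.fy.assign(s.N, 0); s.fz.assign(s.N, 0);
  s.mass.resize(s.N); s.species.resize(s.N);
  for (int i = 0; i < s.N; i++) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
    s.vx[i] = vel(i, 0); s.vy[i] = vel(i, 1); s.vz[i] = vel(i, 2);
    s.mass[i] = mass[i];
    s.species[i] = species[i] - 1;
    if (s.species[i] < 0 || s.species[i] >= NSP) stop("invalid species code");
  }
  s.Lx = box[0]; s.Ly = box[1]; s.Lz = box[2];
  s.time = as<double>(state["time"]);

  IntegerMatrix bonds = state["bonds"];
  IntegerVector btype = state["bond_type"];
  s.bonded_to.assign(s.N, {});
  for (int k = 0; k < bonds.nrow(); k++) {
    int i = bonds(k, 0) - 1, j = bonds(k, 1) - 1;
    s.bonds.push_back({i, j});
    s.bond_type.push_back(btype[k] - 1);
    s.bonded_to[i].push_back(j);
    s.bonded_to[j].push_back(i);
  }
  IntegerMatrix angles = state["angles"];
  for (int k = 0; k < angles.nrow(); k++)
    s.angles.push_back({angles(k, 0) - 1, angles(k, 1) - 1, angles(k, 2) - 1});

  s.body_of.assign(s.N, -1);
  List rb = state["rigid_bodies"];
  if (rb.size() > 1) stop("at most one rigid body is supported");
  if (rb.size() == 1) {
    IntegerVector idx = rb[0];
    s.has_body = true;
    for (int k = 0; k < idx.size(); k++) {
      s.body_idx.push_back(idx[k] - 1);
      s.body_of[idx[k] - 1] = 0;
    }
  }

  // force field tables
  NumericMatrix bmat = ff["b"];
  List tc = ff["tail_cos"];
  double tce = as<double>(tc["epsilon"]), tcr = as<double>(tc["r_c"]),
         tcw = as<double>(tc["w_c"]);
  for (int a = 0; a < NSP; a++)
    for (int b2 = 0; b2 < NSP; b2++) {
      s.pt.b[a][b2] = bmat(a, b2);
      s.pt.wca_eps[a][b2] = 1.0;
      s.pt.cos_eps[a][b2] = 0.0;
      s.pt.cos_rc[a][b2] = 0.0;
      s.pt.cos_wc[a][b2] = 1.0;
    }
  s.pt.cos_eps[SP_TAIL][SP_TAIL] = tce;
  s.pt.cos_rc[SP_TAIL][SP_TAIL] = tcr;
  s.pt.cos_wc[SP_TAIL][SP_TAIL] = tcw;

  if (!Rf_isNull(ff["lr"])) {
    List lr = ff["lr"];
    std::string mode = as<std::string>(lr["mode"]);
    double eps = as<double>(lr["epsilon"]);
    double rc = as<double>(lr["r_c"]), wc = as<double>(lr["w_c"]);
    if (mode == "pair") {
      s.pt.cos_eps[SP_RECEPTOR][SP_LIGAND] = eps;
      s.pt.cos_eps[SP_LIGAND][SP_RECEPTOR] = eps;
      s.pt.cos_rc[SP_RECEPTOR][SP_LIGAND] = rc;
      s.pt.cos_rc[SP_LIGAND][SP_RECEPTOR] = rc;
      s.pt.cos_wc[SP_RECEPTOR][SP_LIGAND] = wc;
      s.pt.cos_wc[SP_LIGAND][SP_RECEPTOR] = wc;
    } else {
      s.lrb.enabled = true;
      s.lrb.eps = eps; s.lrb.rc = rc; s.lrb.wc = wc;
      s.lrb.r_form = as<double>(lr["r_form"]);
      s.lrb.p_form = as<double>(lr["p_form"]);
      s.lrb.r_break = as<double>(lr["r_break"]);
      s.lrb.cap = as<double>(lr["valence_cap"]);
    }
  }

  for (int a = 0; a < NSP; a++)
    for (int b2 = 0; b2 < NSP; b2++) {
      double wcut = std::pow(2.0, 1.0 / 6.0) * s.pt.b[a][b2];
      s.pt.wcut2[a][b2] = wcut * wcut;
      double cut = wcut;
      if (s.pt.cos_eps[a][b2] > 0.0)
        cut = std::max(cut, s.pt.cos_rc[a][b2] + s.pt.cos_wc[a][b2]);
      s.pt.cut2[a][b2] = cut * cut;
      double lcut = cut;
      if (s.lrb.enabled &&
          ((a == SP_LIGAND && b2 == SP_RECEPTOR) ||
           (a == SP_RECEPTOR && b2 == SP_LIGAND)))
        lcut = std::max(lcut, s.lrb.r_form);
      lcut += s.skin;
      s.pt.lcut2[a][b2] = lcut * lcut;
    }

  List fene = ff["fene"];
  for (int k = 0; k < fene.size(); k++) {
    List fk = fene[k];
    List wca = fk["wca"];
    s.fene.push_back({as<double>(fk["K"]), as<double>(fk["R0"]),
                      as<double>(wca["b"]), as<double>(wca["epsilon"])});
  }
  List ang = ff["angle"];
  s.angK = as<double>(ang["K"]);
  s.angTheta0 = as<double>(ang["theta0"]);

  // live dynamic bonds
  s.lr_count.assign(s.N, 0);
  s.lr_partners.assign(s.N, {});
  IntegerMatrix lrb0 = state["lr_bonds"];
  for (int k = 0; k < lrb0.nrow(); k++)
    s.add_lr_bond(lrb0(k, 0) - 1, lrb0(k, 1) - 1);

  double maxcut = 0;
  for (int a = 0; a < NSP; a++)
    for (int b2 = 0; b2 < NSP; b2++)
      maxcut = std::max(maxcut, std::sqrt(s.pt.cut2[a][b2]));
  if (s.lrb.enabled) maxcut = std::max(maxcut, s.lrb.r_form);
  s.verlet_cut = maxcut;

  if (s.has_body) s.init_body();
  return s;
}

static List export_state(const Sim &s, const List &state_in) {
  NumericMatrix pos(s.N, 3), vel(s.N, 3);
  // rigid-body beads are shifted as a unit (by the wrap of the body centre)
  // so the body stays contiguous in the exported state
  double bshift[3] = {0, 0, 0};
  if (s.has_body) {
    bshift[0] = s.Lx * std::floor(s.com[0] / s.Lx);
    bshift[1] = s.Ly * std::floor(s.com[1] / s.Ly);
    bshift[2] = s.Lz * std::floor(s.com[2] / s.Lz);
  }
  for (int i = 0; i < s.N; i++) {
    if (s.body_of[i] >= 0) {
      pos(i, 0) = s.x[i] - bshift[0];
      pos(i, 1) = s.y[i] - bshift[1];
      pos(i, 2) = s.z[i] - bshift[2];
    } else {
      pos(i, 0) = s.x[i] - s.Lx * std::floor(s.x[i] / s.Lx);
      pos(i, 1) = s.y[i] - s.Ly * std::floor(s.y[i] / s.Ly);
      pos(i, 2) = s.z[i] - s.Lz * std::floor(s.z[i] / s.Lz);
    }
    vel(i, 0) = s.vx[i]; vel(i, 1) = s.vy[i]; vel(i, 2) = s.vz[i];
  }
  IntegerMatrix lrb((int)s.lr_bonds.size(), 2);
  for (size_t k = 0; k < s.lr_bonds.size(); k++) {
    lrb(k, 0) = s.lr_bonds[k][0] + 1;
    lrb(k, 1) = s.lr_bonds[k][1] + 1;
  }
  List out = clone(state_in);
  out["pos"] = pos;
  out["vel"] = vel;
  out["box"] = NumericVector::create(s.Lx, s.Ly, s.Lz);
  out["lr_bonds"] = lrb;
  out["time"] = s.time;
  out.attr("class") = "system_state";
  return out;
}

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run(List state, List ff, List ip, int n_steps, List opts) {
  Sim s = make_sim(state, ff);
  const double dt = as<double>(ip["dt"]);
  const double kT = as<double>(ip["kT"]);
  const double damp = as<double>(ip["damp"]);
  const double pdamp = as<double>(ip["pdamp"]);
  const double P0 = as<double>(ip["P_lateral"]);
  const bool thermostat = as<bool>(ip["thermostat"]);
  const bool barostat = as<bool>(ip["barostat"]);
  RNG rng((uint64_t)as<double>(ip["seed"]));

  const int stride_thermo = as<int>(opts["stride_thermo"]);
  const int stride_traj = as<int>(opts["stride_traj"]);
  const int stride_val = as<int>(opts["stride_valency"]);
  const bool keep_traj = as<bool>(opts["keep_trajectory"]);
  const bool log_events = as<bool>(opts["log_events"]);
  const double lr_support = as<double>(opts["lr_support"]);
  const bool pair_mode = !s.lrb.enabled;
  const bool measure_valency = as<bool>(opts["measure_valency"]);

  const double noise_pref = std::sqrt(2.0 * kT / (damp * dt));

  // degrees of freedom for the kinetic temperature
  int n_free = 0;
  for (int i = 0; i < s.N; i++) if (s.body_of[i] < 0) n_free++;
  double ndof = 3.0 * n_free + (s.has_body ? 6.0 : 0.0);
  if (ndof <= 0) stop("no degrees of freedom");

  const double min_cut = s.verlet_cut;
  std::vector<double> th_t, th_T, th_pe, th_ke, th_P, th_Lx, th_Ly;
  std::vector<int> th_nb;
  std::vector<double> val_t, val_mean, val_bound;
  std::vector<NumericMatrix> frames;
  std::vector<double> frame_t, frame_Lx, frame_Ly;

  s.build_neighbors();
  s.compute_forces();

  auto kinetic = [&](void) {
    double ke = 0;
    for (int i = 0; i < s.N; i++)
      if (s.body_of[i] < 0)
        ke += 0.5 * s.mass[i] * (s.vx[i] * s.vx[i] + s.vy[i] * s.vy[i] +
                                 s.vz[i] * s.vz[i]);
    if (s.has_body) {
      ke += 0.5 * s.bodyM * (s.vcom[0] * s.vcom[0] + s.vcom[1] * s.vcom[1] +
                             s.vcom[2] * s.vcom[2]);
      std::array<double, 3> w = s.omega_world();
      ke += 0.5 * (w[0] * s.Lang[0] + w[1] * s.Lang[1] + w[2] * s.Lang[2]);
    }
    return ke;
  };

  auto add_langevin = [&](void) {
    for (int i = 0; i < s.N; i++) {
      double gm = s.mass[i] / damp;
      double pref = noise_pref * std::sqrt(s.mass[i]);
      s.fx[i] += -gm * s.vx[i] + pref * rng.gauss();
      s.fy[i] += -gm * s.vy[i] + pref * rng.gauss();
      s.fz[i] += -gm * s.vz[i] + pref * rng.gauss();
    }
  };
  if (thermostat) add_langevin();

  double Fb[3], Tb[3];
  if (s.has_body) s.body_force_torque(Fb, Tb);

  for (int istep = 0; istep < n_steps; istep++) {
    // first half kick + drift
    for (int i = 0; i < s.N; i++) {
      if (s.body_of[i] >= 0) continue;
      double h = 0.5 * dt / s.mass[i];
      s.vx[i] += h * s.fx[i]; s.vy[i] += h * s.fy[i]; s.vz[i] += h * s.fz[i];
      s.x[i] += dt * s.vx[i]; s.y[i] += dt * s.vy[i]; s.z[i] += dt * s.vz[i];
    }
    if (s.has_body) {
      for (int d = 0; d < 3; d++) {
        s.vcom[d] += 0.5 * dt * Fb[d] / s.bodyM;
        s.com[d] += dt * s.vcom[d];
        s.Lang[d] += 0.5 * dt * Tb[d];
      }
      s.body_advance_orientation(dt);
      s.body_set_beads();
    }
    s.time += dt;

    // dynamic-bond hook (once per step, before the force evaluation)
    if (s.lrb.enabled) {
      if (s.need_rebuild()) s.build_neighbors();
      s.update_bonds(rng, log_events);
    }

    if (s.need_rebuild()) s.build_neighbors();
    s.compute_forces();
    if (thermostat) add_langevin();
    if (s.has_body) s.body_force_torque(Fb, Tb);

    // second half kick
    for (int i = 0; i < s.N; i++) {
      if (s.body_of[i] >= 0) continue;
      double h = 0.5 * dt / s.mass[i];
      s.vx[i] += h * s.fx[i]; s.vy[i] += h * s.fy[i]; s.vz[i] += h * s.fz[i];
    }
    if (s.has_body) {
      for (int d = 0; d < 3; d++) {
        s.vcom[d] += 0.5 * dt * Fb[d] / s.bodyM;
        s.Lang[d] += 0.5 * dt * Tb[d];
      }
      s.body_set_beads();
    }

    // lateral Berendsen barostat toward zero tension
    double Plat = 0;
    if (barostat || (stride_thermo > 0 && (istep + 1) % stride_thermo == 0)) {
      double kxx = 0, kyy = 0;
      for (int i = 0; i < s.N; i++) {
        if (s.body_of[i] >= 0) continue;
        kxx += s.mass[i] * s.vx[i] * s.vx[i];
        kyy += s.mass[i] * s.vy[i] * s.vy[i];
      }
      if (s.has_body) {
        kxx += s.bodyM * s.vcom[0] * s.vcom[0];
        kyy += s.bodyM * s.vcom[1] * s.vcom[1];
      }
      double V = s.Lx * s.Ly * s.Lz;
      Plat = 0.5 * ((kxx + s.Wxx) + (kyy + s.Wyy)) / V;
    }
    if (barostat) {
      // couple to the areal tension Plat * Lz so the relaxation rate does
      // not depend on how much empty height the box carries
      double mu = 1.0 + dt / (3.0 * pdamp) * (Plat - P0) * s.Lz;
      s.Lx *= mu; s.Ly *= mu;
      for (int i = 0; i < s.N; i++) {
        if (s.body_of[i] >= 0) continue;
        s.x[i] *= mu; s.y[i] *= mu;
      }
      if (s.has_body) {
        s.com[0] *= mu; s.com[1] *= mu;
        s.body_set_beads();
      }
      if (s.Lx < 2.0 * min_cut || s.Ly < 2.0 * min_cut)
        stop("barostat shrank the box below twice the interaction cutoff");
    }

    if (!std::isfinite(s.x[0]) || !std::isfinite(s.fx[0]))
      stop("non-finite coordinate or force at t = %g tau", s.time);

    if (stride_thermo > 0 && (istep + 1) % stride_thermo == 0) {
      double ke = kinetic();
      th_t.push_back(s.time);
      th_T.push_back(2.0 * ke / ndof);
      th_pe.push_back(s.potential_energy());
      th_ke.push_back(ke);
      th_P.push_back(Plat);
      th_Lx.push_back(s.Lx);
      th_Ly.push_back(s.Ly);
      th_nb.push_back((int)s.lr_bonds.size());
    }
    if (measure_valency && stride_val > 0 && (istep + 1) % stride_val == 0) {
      double mv, bf; int ne;
      s.valency_sample(pair_mode, lr_support, mv, bf, ne);
      val_t.push_back(s.time);
      val_mean.push_back(mv);
      val_bound.push_back(bf);
    }
    if (keep_traj && stride_traj > 0 && (istep + 1) % stride_traj == 0) {
      NumericMatrix fr(s.N, 3);
      for (int i = 0; i < s.N; i++) {
        fr(i, 0) = s.x[i] - s.Lx * std::floor(s.x[i] / s.Lx);
        fr(i, 1) = s.y[i] - s.Ly * std::floor(s.y[i] / s.Ly);
        fr(i, 2) = s.z[i] - s.Lz * std::floor(s.z[i] / s.Lz);
      }
      frames.push_back(fr);
      frame_t.push_back(s.time);
      frame_Lx.push_back(s.Lx);
      frame_Ly.push_back(s.Ly);
    }
    if (istep % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  List thermo = List::create(
      _["time"] = th_t, _["temperature"] = th_T, _["pe"] = th_pe,
      _["ke"] = th_ke, _["p_lateral"] = th_P, _["Lx"] = th_Lx,
      _["Ly"] = th_Ly, _["n_lr_bonds"] = th_nb);
  List valency = List::create(_["time"] = val_t, _["mean_valency"] = val_mean,
                              _["bound_fraction"] = val_bound);
  int nev = (int)s.events.size();
  NumericVector ev_t(nev), ev_r(nev);
  IntegerVector ev_l(nev), ev_rcp(nev);
  CharacterVector ev_type(nev);
  for (int k = 0; k < nev; k++) {
    ev_t[k] = s.events[k].time;
    ev_l[k] = s.events[k].lig + 1;
    ev_rcp[k] = s.events[k].rec + 1;
    ev_type[k] = s.events[k].type == 1 ? "formed" : "broken";
    ev_r[k] = s.events[k].r;
  }
  List events = List::create(_["time"] = ev_t, _["ligand"] = ev_l,
                             _["receptor"] = ev_rcp, _["event"] = ev_type,
                             _["r"] = ev_r);
  List traj = List::create(_["time"] = frame_t, _["Lx"] = frame_Lx,
                           _["Ly"] = frame_Ly, _["frames"] = wrap(frames));
  return List::create(_["state"] = export_state(s, state),
                      _["thermo"] = thermo, _["valency"] = valency,
                      _["events"] = events, _["trajectory"] = traj,
                      _["n_neighbor_builds"] = (double)s.n_builds);
}

// [[Rcpp::export]]
List cpp_potential_energy(List state, List ff) {
  Sim s = make_sim(state, ff);
  s.build_neighbors();
  s.compute_forces();
  return List::create(
      _["total"] = s.potential_energy(), _["pair"] = s.pe_pair,
      _["bond"] = s.pe_bond, _["angle"] = s.pe_angle,
      _["lr_pair"] = s.pe_lr_pair, _["lr_bond"] = s.pe_lr_bond);
}

// Instantaneous lateral (xy) pressure from the kinetic term plus the pair,
// bond and angle virials.
// [[Rcpp::export]]
double cpp_lateral_pressure(List state, List ff) {
  Sim s = make_sim(state, ff);
  s.build_neighbors();
  s.compute_forces();
  double kxx = 0, kyy = 0;
  for (int i = 0; i < s.N; i++) {
    if (s.body_of[i] >= 0) continue;
    kxx += s.mass[i] * s.vx[i] * s.vx[i];
    kyy += s.mass[i] * s.vy[i] * s.vy[i];
  }
  if (s.has_body) {
    kxx += s.bodyM * s.vcom[0] * s.vcom[0];
    kyy += s.bodyM * s.vcom[1] * s.vcom[1];
  }
  double V = s.Lx * s.Ly * s.Lz;
  return 0.5 * ((kxx + s.Wxx) + (kyy + s.Wyy)) / V;
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, NumericVector box,
                                 double cutoff) {
  int N = pos.nrow();
  if (cutoff > std::min({box[0], box[1], box[2]}) / 2.0)
    stop("cutoff exceeds half the smallest box length (minimum image violated)");
  Sim s;
  s.N = N;
  s.x.resize(N); s.y.resize(N); s.z.resize(N);
  for (int i = 0; i < N; i++) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
  }
  s.Lx = box[0]; s.Ly = box[1]; s.Lz = box[2];
  s.species.assign(N, 0);
  s.body_of.assign(N, -1);
  s.bonded_to.assign(N, {});
  s.verlet_cut = cutoff;
  s.skin = 0.0;
  s.build_neighbors();
  std::vector<std::array<int, 2>> out;
  double c2 = cutoff * cutoff;
  for (size_t k = 0; k < s.pli.size(); k++) {
    int i = s.pli[k], j = s.plj[k];
    double dx = s.min_image_x(s.x[i] - s.x[j]);
    double dy = s.min_image_y(s.y[i] - s.y[j]);
    double dz = s.min_image_z(s.z[i] - s.z[j]);
    if (dx * dx + dy * dy + dz * dz < c2)
      out.push_back({std::min(i, j) + 1, std::max(i, j) + 1});
  }
  IntegerMatrix m((int)out.size(), 2);
  for (size_t k = 0; k < out.size(); k++) {
    m(k, 0) = out[k][0]; m(k, 1) = out[k][1];
  }
  return m;
}

// One dynamic-bond update on a static configuration (the per-step hook,
// exposed for direct testing).
// [[Rcpp::export]]
List cpp_update_bonds(List state, List lr, double seed) {
  List ff_min = List::create(
      _["b"] = NumericMatrix(NSP, NSP),
      _["tail_cos"] = List::create(_["epsilon"] = 0.0, _["r_c"] = 1.0,
                                   _["w_c"] = 1.0),
      _["fene"] = List::create(),
      _["angle"] = List::create(_["K"] = 10.0, _["theta0"] = M_PI),
      _["lr"] = lr);
  NumericMatrix bm = ff_min["b"];
  std::fill(bm.begin(), bm.end(), 0.95);
  Sim s = make_sim(state, ff_min);
  if (!s.lrb.enabled) stop("cpp_update_bonds requires mode = \"bond\"");
  RNG rng((uint64_t)seed);
  s.build_neighbors();
  s.update_bonds(rng, true);
  List res = export_state(s, state);
  int nev = (int)s.events.size();
  NumericVector ev_t(nev), ev_r(nev);
  IntegerVector ev_l(nev), ev_rcp(nev);
  CharacterVector ev_type(nev);
  for (int k = 0; k < nev; k++) {
    ev_t[k] = s.events[k].time;
    ev_l[k] = s.events[k].lig + 1;
    ev_rcp[k] = s.events[k].rec + 1;
    ev_type[k] = s.events[k].type == 1 ? "formed" : "broken";
    ev_r[k] = s.events[k].r;
  }
  return List::create(_["state"] = res,
                      _["events"] = List::create(
                          _["time"] = ev_t, _["ligand"] = ev_l,
                          _["receptor"] = ev_rcp, _["event"] = ev_type,
                          _["r"] = ev_r));
}
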