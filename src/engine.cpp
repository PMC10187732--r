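// Compiled core: Ashbaugh-Hatch pair interactions, cell/Verlet neighbor
// lists, and a BAOAB-discretized Langevin integrator for bead-spring chains
// in orthorhombic periodic boxes.
//
// Units throughout: length nm, energy kcal/mol, time fs, mass g/mol.
// FCON converts kcal/mol to g nm^2 / (mol fs^2).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <set>
#include <utility>
#include <vector>

using namespace Rcpp;

static const double FCON = 4.184e-6; // (g nm^2/fs^2) per (kcal/mol)

// ---------------------------------------------------------------------------
// deterministic RNG (engine-owned; independent of R's RNG stream)
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s;
  bool have_spare;
  double spare;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL),
                                have_spare(false), spare(0.0) {
    for (int i = 0; i < 8; ++i) next();
  }
  uint64_t next() { // xorshift64*
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { // (0, 1)
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double gauss() { // Box-Muller with caching
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

// ---------------------------------------------------------------------------
// pair potential: U(r) = U_LJ + (1-lambda) eps for r <= 2^(1/6) sigma,
//                 lambda U_LJ for r <= r_cut, 0 beyond (unshifted truncation)
// ---------------------------------------------------------------------------
struct PairParams {
  double eps, sigma2, rmin2, rcut2;
  double lam[4]; // lam[ti*2+tj], types 0 = H, 1 = P
};

static inline void ah_pair(double r2, double lambda, const PairParams& pp,
                           double& u, double& fdivr) {
  double sr2 = pp.sigma2 / r2;
  double sr6 = sr2 * sr2 * sr2;
  double sr12 = sr6 * sr6;
  double ulj = 4.0 * pp.eps * (sr12 - sr6);
  double fr = 24.0 * pp.eps * (2.0 * sr12 - sr6) / r2; // F/r for full LJ
  if (r2 <= pp.rmin2) {
    u = ulj + (1.0 - lambda) * pp.eps;
    fdivr = fr;
  } else {
    u = lambda * ulj;
    fdivr = lambda * fr;
  }
}

static inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// ---------------------------------------------------------------------------
// neighbor pairs within cutoff (+skin) under minimum image; cell list when
// the box supports >= 3 cells per dimension, brute force otherwise
// ---------------------------------------------------------------------------
static void build_pairs(const std::vector<double>& x,
                        const std::vector<double>& y,
                        const std::vector<double>& z,
                        const double box[3], double rc,
                        std::vector<int>& pi, std::vector<int>& pj) {
  int n = static_cast<int>(x.size());
  pi.clear(); pj.clear();
  double rc2 = rc * rc;
  // prefer cells of edge ~rc/2 (scan +/-2): ~8x fewer distance checks than
  // rc-sized cells in dense systems
  int nc[3], reach;
  bool use_cells;
  {
    int nc_half[3], nc_full[3];
    for (int d = 0; d < 3; ++d) {
      nc_half[d] = static_cast<int>(std::floor(2.0 * box[d] / rc));
      nc_full[d] = static_cast<int>(std::floor(box[d] / rc));
    }
    if (nc_half[0] >= 5 && nc_half[1] >= 5 && nc_half[2] >= 5 && n > 32) {
      for (int d = 0; d < 3; ++d) nc[d] = nc_half[d];
      reach = 2; use_cells = true;
    } else if (nc_full[0] >= 3 && nc_full[1] >= 3 && nc_full[2] >= 3 && n > 32) {
      for (int d = 0; d < 3; ++d) nc[d] = nc_full[d];
      reach = 1; use_cells = true;
    } else {
      reach = 0; use_cells = false;
    }
  }
  if (!use_cells) {
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = min_image(x[i] - x[j], box[0]);
        double dy = min_image(y[i] - y[j], box[1]);
        double dz = min_image(z[i] - z[j], box[2]);
        if (dx * dx + dy * dy + dz * dz <= rc2) { pi.push_back(i); pj.push_back(j); }
      }
    return;
  }
  int ncell = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncell, -1), nxt(n, -1), cellof(n);
  for (int i = 0; i < n; ++i) {
    int cx = static_cast<int>(std::floor((x[i] / box[0] - std::floor(x[i] / box[0])) * nc[0])) % nc[0];
    int cy = static_cast<int>(std::floor((y[i] / box[1] - std::floor(y[i] / box[1])) * nc[1])) % nc[1];
    int cz = static_cast<int>(std::floor((z[i] / box[2] - std::floor(z[i] / box[2])) * nc[2])) % nc[2];
    int c = (cx * nc[1] + cy) * nc[2] + cz;
    cellof[i] = c;
    nxt[i] = head[c];
    head[c] = i;
  }
  for (int cx = 0; cx < nc[0]; ++cx)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cz = 0; cz < nc[2]; ++cz) {
        int c = (cx * nc[1] + cy) * nc[2] + cz;
        for (int ox = -reach; ox <= reach; ++ox)
          for (int oy = -reach; oy <= reach; ++oy)
            for (int oz = -reach; oz <= reach; ++oz) {
              int dx_ = (cx + ox + nc[0]) % nc[0];
              int dy_ = (cy + oy + nc[1]) % nc[1];
              int dz_ = (cz + oz + nc[2]) % nc[2];
              int c2 = (dx_ * nc[1] + dy_) * nc[2] + dz_;
              if (c2 < c) continue;
              for (int i = head[c]; i >= 0; i = nxt[i])
                for (int j = (c2 == c ? nxt[i] : head[c2]); j >= 0; j = nxt[j]) {
                  double ddx = min_image(x[i] - x[j], box[0]);
                  double ddy = min_image(y[i] - y[j], box[1]);
                  double ddz = min_image(z[i] - z[j], box[2]);
                  if (ddx * ddx + ddy * ddy + ddz * ddz <= rc2) {
                    if (i < j) { pi.push_back(i); pj.push_back(j); }
                    else       { pi.push_back(j); pj.push_back(i); }
                  }
                }
            }
      }
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, NumericVector box, double cutoff) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  double b[3] = { box[0], box[1], box[2] };
  std::vector<int> pi, pj;
  build_pairs(x, y, z, b, cutoff, pi, pj);
  IntegerMatrix out(static_cast<int>(pi.size()), 2);
  for (size_t k = 0; k < pi.size(); ++k) { out(k, 0) = pi[k] + 1; out(k, 1) = pj[k] + 1; }
  return out;
}

// ---------------------------------------------------------------------------
// system nonbonded energy (1-2 bonded pairs excluded)
// ---------------------------------------------------------------------------
static double nb_energy(const std::vector<double>& x, const std::vector<double>& y,
                        const std::vector<double>& z, const IntegerVector& type,
                        const IntegerVector& chain, const double box[3],
                        const PairParams& pp, double rcut) {
  std::vector<int> pi, pj;
  build_pairs(x, y, z, box, rcut, pi, pj);
  double u = 0.0;
  for (size_t k = 0; k < pi.size(); ++k) {
    int i = pi[k], j = pj[k];
    if (chain[i] == chain[j] && std::abs(i - j) == 1) continue;
    double dx = min_image(x[i] - x[j], box[0]);
    double dy = min_image(y[i] - y[j], box[1]);
    double dz = min_image(z[i] - z[j], box[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > pp.rcut2) continue;
    if (r2 < 1e-12) stop("overlapping particles (r < 1e-6 nm) in nonbonded energy");
    double uu, ff;
    ah_pair(r2, pp.lam[type[i] * 2 + type[j]], pp, uu, ff);
    u += uu;
  }
  return u;
}

static PairParams make_pp(double eps, double sigma, double rcut, NumericMatrix lambda) {
  PairParams pp;
  pp.eps = eps;
  pp.sigma2 = sigma * sigma;
  pp.rmin2 = std::pow(2.0, 1.0 / 3.0) * pp.sigma2; // (2^(1/6) sigma)^2
  pp.rcut2 = rcut * rcut;
  pp.lam[0] = lambda(0, 0); pp.lam[1] = lambda(0, 1);
  pp.lam[2] = lambda(1, 0); pp.lam[3] = lambda(1, 1);
  return pp;
}

// [[Rcpp::export]]
double cpp_nonbonded_energy(NumericMatrix pos, IntegerVector type, IntegerVector chain,
                            NumericVector box, double eps, double sigma, double rcut,
                            NumericMatrix lambda) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  double b[3] = { box[0], box[1], box[2] };
  PairParams pp = make_pp(eps, sigma, rcut, lambda);
  return nb_energy(x, y, z, type, chain, b, pp, rcut);
}

// interaction energy between two rigid bead sets, no periodic images
// [[Rcpp::export]]
double cpp_inter_energy(NumericMatrix posA, NumericMatrix posB,
                        IntegerVector typeA, IntegerVector typeB,
                        double eps, double sigma, double rcut, NumericMatrix lambda) {
  PairParams pp = make_pp(eps, sigma, rcut, lambda);
  double u = 0.0;
  for (int i = 0; i < posA.nrow(); ++i)
    for (int j = 0; j < posB.nrow(); ++j) {
      double dx = posA(i, 0) - posB(j, 0);
      double dy = posA(i, 1) - posB(j, 1);
      double dz = posA(i, 2) - posB(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > pp.rcut2) continue;
      double uu, ff;
      ah_pair(r2, pp.lam[typeA[i] * 2 + typeB[j]], pp, uu, ff);
      u += uu;
    }
  return u;
}

// chain-chain contact edges: chains sharing any monomer pair within cutoff
// [[Rcpp::export]]
IntegerMatrix cpp_contact_edges(NumericMatrix pos, IntegerVector chain,
                                NumericVector box, double cutoff) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  double b[3] = { box[0], box[1], box[2] };
  std::vector<int> pi, pj;
  build_pairs(x, y, z, b, cutoff, pi, pj);
  std::set<std::pair<int, int> > edges;
  for (size_t k = 0; k < pi.size(); ++k) {
    int ci = chain[pi[k]], cj = chain[pj[k]];
    if (ci == cj) continue;
    edges.insert(std::make_pair(std::min(ci, cj), std::max(ci, cj)));
  }
  IntegerMatrix out(static_cast<int>(edges.size()), 2);
  int k = 0;
  for (std::set<std::pair<int, int> >::iterator it = edges.begin(); it != edges.end(); ++it, ++k) {
    out(k, 0) = it->first;
    out(k, 1) = it->second;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Langevin dynamics (BAOAB splitting) with optional harmonic bias on the
// centre-of-mass distance between chain 1 and chain 2 (umbrella windows)
// ---------------------------------------------------------------------------
struct Forces {
  std::vector<double> fx, fy, fz;
  double u_nb, u_bond, u_bias;
};

// compact interaction list entry: pair indices, hydropathy, and the periodic
// image shift frozen at rebuild time (valid while displacements stay within
// the skin, since pair separations are far below half the box)
struct NbPair { int i, j; double lam, sx, sy, sz; };

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos0, NumericMatrix vel0, IntegerVector type,
                      IntegerVector chain, NumericVector box,
                      double eps, double sigma, double rcut, NumericMatrix lambda,
                      double kb, double r0,
                      int n_steps, double dt, double gamma, double kT, double mass,
                      int sample_every, double seed,
                      double bias_k, double bias_r0, int rcom_every,
                      double skin) {
  int n = pos0.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  std::vector<int> ty(n), ch(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
    vx[i] = vel0(i, 0); vy[i] = vel0(i, 1); vz[i] = vel0(i, 2);
    ty[i] = type[i]; ch[i] = chain[i];
  }
  double b[3] = { box[0], box[1], box[2] };
  PairParams pp = make_pp(eps, sigma, rcut, lambda);

  std::vector<int> bi, bj;
  for (int i = 0; i < n - 1; ++i)
    if (ch[i] == ch[i + 1]) { bi.push_back(i); bj.push_back(i + 1); }

  std::vector<int> gA, gB;
  if (bias_k > 0) {
    for (int i = 0; i < n; ++i) {
      if (ch[i] == 1) gA.push_back(i);
      else if (ch[i] == 2) gB.push_back(i);
    }
    if (gA.empty() || gB.empty()) stop("umbrella bias requires chains labelled 1 and 2");
  }

  Rng rng(static_cast<uint64_t>(seed));

  double rlist = rcut + skin;
  std::vector<int> rpi, rpj;
  std::vector<NbPair> nblist;
  std::vector<double> x0(n), y0(n), z0(n);
  double half_skin2 = 0.25 * skin * skin;

  Forces F;
  F.fx.assign(n, 0.0); F.fy.assign(n, 0.0); F.fz.assign(n, 0.0);

  // rebuild: raw pair list -> compact list with exclusions resolved and
  // per-pair hydropathy attached
  #define REBUILD() do {                                                     \
    build_pairs(x, y, z, b, rlist, rpi, rpj);                                \
    nblist.clear();                                                          \
    nblist.reserve(rpi.size());                                              \
    for (size_t k_ = 0; k_ < rpi.size(); ++k_) {                             \
      int i_ = rpi[k_], j_ = rpj[k_];                                        \
      if (ch[i_] == ch[j_] && (j_ - i_ == 1 || i_ - j_ == 1)) continue;      \
      NbPair p_; p_.i = i_; p_.j = j_; p_.lam = pp.lam[ty[i_] * 2 + ty[j_]]; \
      p_.sx = b[0] * std::nearbyint((x[i_] - x[j_]) / b[0]);                 \
      p_.sy = b[1] * std::nearbyint((y[i_] - y[j_]) / b[1]);                 \
      p_.sz = b[2] * std::nearbyint((z[i_] - z[j_]) / b[2]);                 \
      nblist.push_back(p_);                                                  \
    }                                                                        \
    for (int i_ = 0; i_ < n; ++i_) { x0[i_] = x[i_]; y0[i_] = y[i_]; z0[i_] = z[i_]; } \
  } while (0)

  REBUILD();

  double rcom = 0.0;

  struct Eval {
    static void forces(const std::vector<double>& x, const std::vector<double>& y,
                       const std::vector<double>& z, const double b[3],
                       const PairParams& pp, const std::vector<NbPair>& nblist,
                       const std::vector<int>& bi, const std::vector<int>& bj,
                       double kb, double r0,
                       const std::vector<int>& gA, const std::vector<int>& gB,
                       double bias_k, double bias_r0,
                       Forces& F, double& rcom_out) {
      std::fill(F.fx.begin(), F.fx.end(), 0.0);
      std::fill(F.fy.begin(), F.fy.end(), 0.0);
      std::fill(F.fz.begin(), F.fz.end(), 0.0);
      F.u_nb = 0.0; F.u_bond = 0.0; F.u_bias = 0.0;
      const double Lx = b[0], Ly = b[1], Lz = b[2];
      const double inv_sigma2 = 1.0 / pp.sigma2;
      const size_t np = nblist.size();
      const NbPair* pl = nblist.empty() ? 0 : &nblist[0];
      for (size_t k = 0; k < np; ++k) {
        const NbPair& p = pl[k];
        double dx = x[p.i] - x[p.j] - p.sx;
        double dy = y[p.i] - y[p.j] - p.sy;
        double dz = z[p.i] - z[p.j] - p.sz;
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 > pp.rcut2) continue;
        double sr2 = pp.sigma2 / r2;
        double sr6 = sr2 * sr2 * sr2;
        double sr12 = sr6 * sr6;
        double ulj = 4.0 * pp.eps * (sr12 - sr6);
        double fr = 24.0 * pp.eps * (2.0 * sr12 - sr6) * sr2 * inv_sigma2;
        if (r2 <= pp.rmin2) {
          F.u_nb += ulj + (1.0 - p.lam) * pp.eps;
        } else {
          F.u_nb += p.lam * ulj;
          fr *= p.lam;
        }
        F.fx[p.i] += fr * dx; F.fy[p.i] += fr * dy; F.fz[p.i] += fr * dz;
        F.fx[p.j] -= fr * dx; F.fy[p.j] -= fr * dy; F.fz[p.j] -= fr * dz;
      }
      for (size_t k = 0; k < bi.size(); ++k) {
        int i = bi[k], j = bj[k];
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        dx -= Lx * std::nearbyint(dx / Lx);
        dy -= Ly * std::nearbyint(dy / Ly);
        dz -= Lz * std::nearbyint(dz / Lz);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        double du = r - r0;
        F.u_bond += kb * du * du;          // U = k_b (r - r0)^2
        double fmag = -2.0 * kb * du / r;
        F.fx[i] += fmag * dx; F.fy[i] += fmag * dy; F.fz[i] += fmag * dz;
        F.fx[j] -= fmag * dx; F.fy[j] -= fmag * dy; F.fz[j] -= fmag * dz;
      }
      rcom_out = NA_REAL;
      if (bias_k > 0 && !gA.empty()) {
        double ax = 0, ay = 0, az = 0, bx = 0, by = 0, bz = 0;
        for (size_t k = 0; k < gA.size(); ++k) { ax += x[gA[k]]; ay += y[gA[k]]; az += z[gA[k]]; }
        for (size_t k = 0; k < gB.size(); ++k) { bx += x[gB[k]]; by += y[gB[k]]; bz += z[gB[k]]; }
        ax /= gA.size(); ay /= gA.size(); az /= gA.size();
        bx /= gB.size(); by /= gB.size(); bz /= gB.size();
        double dx = min_image(bx - ax, Lx);
        double dy = min_image(by - ay, Ly);
        double dz = min_image(bz - az, Lz);
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        rcom_out = d;
        double du = d - bias_r0;
        F.u_bias = 0.5 * bias_k * du * du;
        double fmagA = bias_k * du / d;    // pulls A toward B when d > r0
        for (size_t k = 0; k < gA.size(); ++k) {
          F.fx[gA[k]] += fmagA * dx / gA.size();
          F.fy[gA[k]] += fmagA * dy / gA.size();
          F.fz[gA[k]] += fmagA * dz / gA.size();
        }
        for (size_t k = 0; k < gB.size(); ++k) {
          F.fx[gB[k]] -= fmagA * dx / gB.size();
          F.fy[gB[k]] -= fmagA * dy / gB.size();
          F.fz[gB[k]] -= fmagA * dz / gB.size();
        }
      }
    }
  };

  Eval::forces(x, y, z, b, pp, nblist, bi, bj, kb, r0,
               gA, gB, bias_k, bias_r0, F, rcom);

  double c1 = (gamma > 0) ? std::exp(-gamma * dt / mass) : 1.0;
  double sig_v = (gamma > 0) ? std::sqrt(kT * FCON / mass * (1.0 - c1 * c1)) : 0.0;
  double acc = dt * 0.5 * FCON / mass;

  int n_frames = n_steps / sample_every;
  NumericVector frames(static_cast<R_xlen_t>(n_frames) * n * 3);
  NumericVector u_nb_s(n_frames), u_bond_s(n_frames), ke_s(n_frames), t_s(n_frames);
  int n_rcom = (bias_k > 0 && rcom_every > 0) ? n_steps / rcom_every : 0;
  NumericVector rcom_s(n_rcom);

  int fr = 0, rk = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      vx[i] += acc * F.fx[i]; vy[i] += acc * F.fy[i]; vz[i] += acc * F.fz[i];
      x[i] += 0.5 * dt * vx[i]; y[i] += 0.5 * dt * vy[i]; z[i] += 0.5 * dt * vz[i];
    }
    if (gamma > 0) {
      for (int i = 0; i < n; ++i) {
        vx[i] = c1 * vx[i] + sig_v * rng.gauss();
        vy[i] = c1 * vy[i] + sig_v * rng.gauss();
        vz[i] = c1 * vz[i] + sig_v * rng.gauss();
      }
    }
    double maxd2 = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += 0.5 * dt * vx[i]; y[i] += 0.5 * dt * vy[i]; z[i] += 0.5 * dt * vz[i];
      double ddx = x[i] - x0[i], ddy = y[i] - y0[i], ddz = z[i] - z0[i];
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 > maxd2) maxd2 = d2;
    }
    if (maxd2 > half_skin2) {
      if (!std::isfinite(maxd2))
        stop("integration blow-up (non-finite coordinates) at step %d", step);
      REBUILD();
    }
    Eval::forces(x, y, z, b, pp, nblist, bi, bj, kb, r0,
                 gA, gB, bias_k, bias_r0, F, rcom);
    for (int i = 0; i < n; ++i) {
      vx[i] += acc * F.fx[i]; vy[i] += acc * F.fy[i]; vz[i] += acc * F.fz[i];
    }

    if (n_rcom > 0 && step % rcom_every == 0 && rk < n_rcom) rcom_s[rk++] = rcom;

    if (step % sample_every == 0 && fr < n_frames) {
      if (!std::isfinite(x[0]))
        stop("integration blow-up (non-finite coordinates) at step %d", step);
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        ke += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
      ke *= 0.5 * mass / FCON;
      R_xlen_t off = static_cast<R_xlen_t>(fr) * n * 3;
      for (int i = 0; i < n; ++i) {
        frames[off + i] = x[i];
        frames[off + n + i] = y[i];
        frames[off + 2 * n + i] = z[i];
      }
      u_nb_s[fr] = F.u_nb;
      u_bond_s[fr] = F.u_bond;
      ke_s[fr] = ke;
      t_s[fr] = static_cast<double>(step) * dt;
      ++fr;
    }
    if (step % 200000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  for (int i = 0; i < n; ++i) {
    pos_out(i, 0) = x[i]; pos_out(i, 1) = y[i]; pos_out(i, 2) = z[i];
    vel_out(i, 0) = vx[i]; vel_out(i, 1) = vy[i]; vel_out(i, 2) = vz[i];
  }
  frames.attr("dim") = IntegerVector::create(n, 3, n_frames);
  return List::create(_["frames"] = frames, _["time"] = t_s,
                      _["u_nb"] = u_nb_s, _["u_bond"] = u_bond_s, _["ke"] = ke_s,
                      _["rcom"] = rcom_s,
                      _["pos"] = pos_out, _["vel"] = vel_out);
}
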