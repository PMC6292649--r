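#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic RNG (splitmix64 + Box-Muller), independent of R's RNG so that
// trajectories are bit-reproducible from the integer seed alone.
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t state;
  bool has_spare;
  double spare;
  explicit Rng(uint64_t seed) : state(seed), has_spare(false), spare(0.0) {
    // warm up
    for (int i = 0; i < 8; ++i) next_u64();
  }
  uint64_t next_u64() {
    uint64_t z = (state += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { // (0,1)
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 2.0 * M_PI * u2;
    spare = r * std::sin(th);
    has_spare = true;
    return r * std::cos(th);
  }
};

// contact indicator f(r) = (1 + tanh(mu*(rc - r)))/2 = 1/(1 + e^{-2 mu (rc - r)})
// (logistic form: one exp per evaluation); df/dr = -2 mu f (1 - f)
static inline double fcontact(double r, double mu, double rc) {
  return 1.0 / (1.0 + std::exp(-2.0 * mu * (rc - r)));
}

struct PairModel {
  int N;
  std::vector<int> lab;          // 0-based type codes
  std::vector<double> tm;        // 6x6 type matrix, column-major
  std::unordered_set<int64_t> loops;
  double loop_eps;
  std::vector<double> gamma;     // gamma[d], d = 0..d_max (0,1 unused)
  int d_max;
  double mu, rc;
  double sigma, ev_k;            // excluded volume (nonbonded, |i-j|>=2)
  double bond_k, bond_r0;
  double Rs, wall_k;             // wall_k <= 0 disables confinement
  double r_cut;                  // f-term cutoff (f < 1e-4 beyond)

  double type_e(int i, int j) const { return tm[lab[i] + 6 * lab[j]]; }
  bool is_loop(int i, int j) const {
    if (i > j) std::swap(i, j);
    return loops.count((int64_t)i * N + j) > 0;
  }
  double contact_coeff(int i, int j, double &type_part, double &loop_part,
                       double &ideal_part) const {
    type_part = type_e(i, j);
    loop_part = is_loop(i, j) ? loop_eps : 0.0;
    int d = std::abs(i - j);
    ideal_part = (d >= 2 && d <= d_max) ? gamma[d] : 0.0;
    return type_part + loop_part + ideal_part;
  }
};

static PairModel build_model(int N, IntegerVector labels, NumericMatrix type_matrix,
                             IntegerVector loop_i, IntegerVector loop_j,
                             double loop_eps, NumericVector gamma_tab, int d_max,
                             double mu, double rc, double sigma, double ev_k,
                             double bond_k, double bond_r0,
                             double Rs, double wall_k) {
  PairModel m;
  m.N = N;
  m.lab.assign(labels.begin(), labels.end());
  m.tm.assign(type_matrix.begin(), type_matrix.end());
  for (int k = 0; k < loop_i.size(); ++k) {
    int a = loop_i[k], b = loop_j[k];
    if (a > b) std::swap(a, b);
    m.loops.insert((int64_t)a * N + b);
  }
  m.loop_eps = loop_eps;
  m.gamma.assign(gamma_tab.begin(), gamma_tab.end());
  m.d_max = std::min<int>(d_max, (int)m.gamma.size() - 1);
  m.mu = mu; m.rc = rc; m.sigma = sigma; m.ev_k = ev_k;
  m.bond_k = bond_k; m.bond_r0 = bond_r0;
  m.Rs = Rs; m.wall_k = wall_k;
  // f < 1e-4  <=>  tanh(mu(rc-r)) < -(1 - 2e-4)
  m.r_cut = rc + std::atanh(1.0 - 2e-4) / mu;
  return m;
}

// ---------------------------------------------------------------------------
// Exact O(N^2) decomposed energy (analysis-grade; no cutoff truncation).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_energy_terms(NumericMatrix coords, IntegerVector labels,
                               NumericMatrix type_matrix,
                               IntegerVector loop_i, IntegerVector loop_j,
                               double loop_eps, NumericVector gamma_tab, int d_max,
                               double mu, double rc, double sigma, double ev_k,
                               double bond_k, double bond_r0,
                               double Rs, double wall_k) {
  int N = coords.nrow();
  PairModel m = build_model(N, labels, type_matrix, loop_i, loop_j, loop_eps,
                            gamma_tab, d_max, mu, rc, sigma, ev_k,
                            bond_k, bond_r0, Rs, wall_k);
  double e_bond = 0, e_ev = 0, e_type = 0, e_loop = 0, e_ideal = 0, e_conf = 0;
  for (int i = 0; i < N - 1; ++i) {
    double dx = coords(i + 1, 0) - coords(i, 0);
    double dy = coords(i + 1, 1) - coords(i, 1);
    double dz = coords(i + 1, 2) - coords(i, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - m.bond_r0;
    e_bond += 0.5 * m.bond_k * dr * dr;
  }
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double dx = coords(j, 0) - coords(i, 0);
      double dy = coords(j, 1) - coords(i, 1);
      double dz = coords(j, 2) - coords(i, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double f = fcontact(r, m.mu, m.rc);
      double tp, lp, ip;
      m.contact_coeff(i, j, tp, lp, ip);
      e_type += tp * f;
      e_loop += lp * f;
      e_ideal += ip * f;
      if (j - i >= 2 && r < m.sigma) {
        double o = m.sigma - r;
        e_ev += 0.5 * m.ev_k * o * o;
      }
    }
  }
  if (m.wall_k > 0) {
    for (int i = 0; i < N; ++i) {
      double rr = std::sqrt(coords(i, 0) * coords(i, 0) +
                            coords(i, 1) * coords(i, 1) +
                            coords(i, 2) * coords(i, 2));
      if (rr > m.Rs) {
        double o = rr - m.Rs;
        e_conf += m.wall_k * o * o;
      }
    }
  }
  return NumericVector::create(_["bonded"] = e_bond, _["excluded"] = e_ev,
                               _["type"] = e_type, _["loop"] = e_loop,
                               _["ideal"] = e_ideal, _["confinement"] = e_conf);
}

static void add_pair_force(const PairModel &m, const double *x, double *F,
                           int i, int j, bool use_cutoff) {
  double dx = x[3 * j] - x[3 * i];
  double dy = x[3 * j + 1] - x[3 * i + 1];
  double dz = x[3 * j + 2] - x[3 * i + 2];
  double r2 = dx * dx + dy * dy + dz * dz;
  double rmax = use_cutoff ? m.r_cut : 1e30;
  if (r2 > rmax * rmax) return;
  double r = std::sqrt(r2);
  if (r < 1e-12) return; // coincident beads: no defined direction
  double fr = 0.0;       // dE/dr
  double tp, lp, ip;
  double e = m.contact_coeff(i, j, tp, lp, ip);
  if (e != 0.0) {
    double f = fcontact(r, m.mu, m.rc);
    fr += e * (-2.0 * m.mu * f * (1.0 - f)); // e * df/dr
  }
  if (j - i >= 2 && r < m.sigma) fr += -m.ev_k * (m.sigma - r);
  if (fr != 0.0) {
    double c = -fr / r; // force on j along +rhat
    F[3 * j] += c * dx; F[3 * j + 1] += c * dy; F[3 * j + 2] += c * dz;
    F[3 * i] -= c * dx; F[3 * i + 1] -= c * dy; F[3 * i + 2] -= c * dz;
  }
}

static void compute_forces_exact(const PairModel &m, const double *x, double *F) {
  int N = m.N;
  std::fill(F, F + 3 * N, 0.0);
  for (int i = 0; i < N - 1; ++i) {
    double dx = x[3 * (i + 1)] - x[3 * i];
    double dy = x[3 * (i + 1) + 1] - x[3 * i + 1];
    double dz = x[3 * (i + 1) + 2] - x[3 * i + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r > 1e-12) {
      double c = -m.bond_k * (r - m.bond_r0) / r;
      F[3 * (i + 1)] += c * dx; F[3 * (i + 1) + 1] += c * dy; F[3 * (i + 1) + 2] += c * dz;
      F[3 * i] -= c * dx; F[3 * i + 1] -= c * dy; F[3 * i + 2] -= c * dz;
    }
  }
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j)
      add_pair_force(m, x, F, i, j, false);
  if (m.wall_k > 0) {
    for (int i = 0; i < N; ++i) {
      double rr = std::sqrt(x[3 * i] * x[3 * i] + x[3 * i + 1] * x[3 * i + 1] +
                            x[3 * i + 2] * x[3 * i + 2]);
      if (rr > m.Rs) {
        double c = -2.0 * m.wall_k * (rr - m.Rs) / rr;
        F[3 * i] += c * x[3 * i];
        F[3 * i + 1] += c * x[3 * i + 1];
        F[3 * i + 2] += c * x[3 * i + 2];
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_total_force(NumericMatrix coords, IntegerVector labels,
                              NumericMatrix type_matrix,
                              IntegerVector loop_i, IntegerVector loop_j,
                              double loop_eps, NumericVector gamma_tab, int d_max,
                              double mu, double rc, double sigma, double ev_k,
                              double bond_k, double bond_r0,
                              double Rs, double wall_k) {
  int N = coords.nrow();
  PairModel m = build_model(N, labels, type_matrix, loop_i, loop_j, loop_eps,
                            gamma_tab, d_max, mu, rc, sigma, ev_k,
                            bond_k, bond_r0, Rs, wall_k);
  std::vector<double> x(3 * N), F(3 * N);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = coords(i, c);
  compute_forces_exact(m, x.data(), F.data());
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = F[3 * i + c];
  return out;
}

// ---------------------------------------------------------------------------
// Verlet neighbour list with skin; rebuilt every `every` steps.  The pair
// cutoff is r_cut (f < 1e-4 beyond), which also covers the excluded-volume
// range sigma < r_cut.  The combined contact coefficient e_ij (type + loop +
// condensation) is cached per pair at build time.
// ---------------------------------------------------------------------------
struct NeighbourList {
  std::vector<int> pi, pj;
  std::vector<double> e;    // combined contact coefficient
  std::vector<char> ev;     // excluded volume applies (|i-j| >= 2)
  std::vector<int> head, nxt, cell_of; // cell-list scratch

  void add_pair(const PairModel &m, int i, int j) {
    if (i > j) std::swap(i, j);
    double tp, lp, ip;
    pi.push_back(i); pj.push_back(j);
    e.push_back(m.contact_coeff(i, j, tp, lp, ip));
    ev.push_back(j - i >= 2);
  }

  void build(const PairModel &m, const double *x, double cutoff) {
    int N = m.N;
    pi.clear(); pj.clear(); e.clear(); ev.clear();
    double cutoff2 = cutoff * cutoff;
    // bounding box
    double lo[3] = {x[0], x[1], x[2]}, hi[3] = {x[0], x[1], x[2]};
    for (int i = 1; i < N; ++i)
      for (int c = 0; c < 3; ++c) {
        lo[c] = std::min(lo[c], x[3 * i + c]);
        hi[c] = std::max(hi[c], x[3 * i + c]);
      }
    int nc[3];
    long tot = 1;
    for (int c = 0; c < 3; ++c) {
      nc[c] = std::max(1, (int)((hi[c] - lo[c]) / cutoff));
      tot *= nc[c];
    }
    if (tot > 27L * N || N < 32) {
      // sparse occupancy or tiny system: plain O(N^2) scan
      for (int i = 0; i < N; ++i)
        for (int j = i + 1; j < N; ++j) {
          double dx = x[3 * j] - x[3 * i];
          double dy = x[3 * j + 1] - x[3 * i + 1];
          double dz = x[3 * j + 2] - x[3 * i + 2];
          if (dx * dx + dy * dy + dz * dz < cutoff2) add_pair(m, i, j);
        }
      return;
    }
    head.assign(tot, -1);
    nxt.assign(N, -1);
    cell_of.assign(N, 0);
    auto cidx = [&](int i, int c) {
      int k = (int)((x[3 * i + c] - lo[c]) / cutoff);
      return std::min(std::max(k, 0), nc[c] - 1);
    };
    for (int i = 0; i < N; ++i) {
      int cx = cidx(i, 0), cy = cidx(i, 1), cz = cidx(i, 2);
      int cell = (cz * nc[1] + cy) * nc[0] + cx;
      cell_of[i] = cell;
      nxt[i] = head[cell];
      head[cell] = i;
    }
    for (int i = 0; i < N; ++i) {
      int cx = cell_of[i] % nc[0];
      int cy = (cell_of[i] / nc[0]) % nc[1];
      int cz = cell_of[i] / (nc[0] * nc[1]);
      for (int dz = -1; dz <= 1; ++dz) {
        int z = cz + dz; if (z < 0 || z >= nc[2]) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int y = cy + dy; if (y < 0 || y >= nc[1]) continue;
          for (int dxc = -1; dxc <= 1; ++dxc) {
            int xx = cx + dxc; if (xx < 0 || xx >= nc[0]) continue;
            int cell = (z * nc[1] + y) * nc[0] + xx;
            for (int j = head[cell]; j >= 0; j = nxt[j]) {
              if (j <= i) continue;
              double ddx = x[3 * j] - x[3 * i];
              double ddy = x[3 * j + 1] - x[3 * i + 1];
              double ddz = x[3 * j + 2] - x[3 * i + 2];
              if (ddx * ddx + ddy * ddy + ddz * ddz < cutoff2)
                add_pair(m, i, j);
            }
          }
        }
      }
    }
  }
};

static void compute_forces_nl(const PairModel &m, const double *x, double *F,
                              const NeighbourList &nl) {
  int N = m.N;
  std::fill(F, F + 3 * N, 0.0);
  for (int i = 0; i < N - 1; ++i) {
    double dx = x[3 * (i + 1)] - x[3 * i];
    double dy = x[3 * (i + 1) + 1] - x[3 * i + 1];
    double dz = x[3 * (i + 1) + 2] - x[3 * i + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r > 1e-12) {
      double c = -m.bond_k * (r - m.bond_r0) / r;
      F[3 * (i + 1)] += c * dx; F[3 * (i + 1) + 1] += c * dy; F[3 * (i + 1) + 2] += c * dz;
      F[3 * i] -= c * dx; F[3 * i + 1] -= c * dy; F[3 * i + 2] -= c * dz;
    }
  }
  const double rcut2 = m.r_cut * m.r_cut;
  for (size_t k = 0; k < nl.pi.size(); ++k) {
    int i = nl.pi[k], j = nl.pj[k];
    double dx = x[3 * j] - x[3 * i];
    double dy = x[3 * j + 1] - x[3 * i + 1];
    double dz = x[3 * j + 2] - x[3 * i + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > rcut2) continue;
    double r = std::sqrt(r2);
    if (r < 1e-12) continue;
    double fr = 0.0;
    if (nl.e[k] != 0.0) {
      double f = fcontact(r, m.mu, m.rc);
      fr += nl.e[k] * (-2.0 * m.mu * f * (1.0 - f));
    }
    if (nl.ev[k] && r < m.sigma) fr += -m.ev_k * (m.sigma - r);
    if (fr != 0.0) {
      double c = -fr / r;
      F[3 * j] += c * dx; F[3 * j + 1] += c * dy; F[3 * j + 2] += c * dz;
      F[3 * i] -= c * dx; F[3 * i + 1] -= c * dy; F[3 * i + 2] -= c * dz;
    }
  }
  if (m.wall_k > 0) {
    for (int i = 0; i < N; ++i) {
      double rr = std::sqrt(x[3 * i] * x[3 * i] + x[3 * i + 1] * x[3 * i + 1] +
                            x[3 * i + 2] * x[3 * i + 2]);
      if (rr > m.Rs) {
        double c = -2.0 * m.wall_k * (rr - m.Rs) / rr;
        F[3 * i] += c * x[3 * i];
        F[3 * i + 1] += c * x[3 * i + 1];
        F[3 * i + 2] += c * x[3 * i + 2];
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Overdamped (Brownian / Euler-Maruyama) integrator.
//   r += F * dt + sqrt(2 * mult_i * dt) * xi   (D0 = 1, kT = 1)
// The deterministic drift per bead is capped at cap_drift (non-crossing guard);
// steps whose total per-bead displacement would exceed cap_reject are redrawn.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_brownian_run(NumericMatrix coords0, IntegerVector labels,
                      NumericMatrix type_matrix,
                      IntegerVector loop_i, IntegerVector loop_j,
                      double loop_eps, NumericVector gamma_tab, int d_max,
                      double mu, double rc, double sigma, double ev_k,
                      double bond_k, double bond_r0,
                      double Rs, double wall_k,
                      NumericVector mult, int n_steps, double dt, int stride,
                      double seed, double cap_drift, double cap_reject,
                      int nl_every, double nl_skin) {
  int N = coords0.nrow();
  PairModel m = build_model(N, labels, type_matrix, loop_i, loop_j, loop_eps,
                            gamma_tab, d_max, mu, rc, sigma, ev_k,
                            bond_k, bond_r0, Rs, wall_k);
  Rng rng((uint64_t)seed);
  std::vector<double> x(3 * N), F(3 * N), disp(3 * N), sd(N);
  for (int i = 0; i < N; ++i) {
    sd[i] = std::sqrt(2.0 * mult[i] * dt);
    for (int c = 0; c < 3; ++c) x[3 * i + c] = coords0(i, c);
  }
  int T = n_steps / stride + 1;
  NumericVector frames((R_xlen_t)T * N * 3);
  // frame layout [t, i, c] with dims (T, N, 3)
  auto store = [&](int t) {
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < 3; ++c)
        frames[t + (R_xlen_t)T * (i + (R_xlen_t)N * c)] = x[3 * i + c];
  };
  store(0);
  NeighbourList nl;
  double cutoff = m.r_cut + nl_skin;
  long n_flagged = 0, n_rejected = 0;
  int frame = 1;
  for (int step = 0; step < n_steps; ++step) {
    if (step % nl_every == 0) nl.build(m, x.data(), cutoff);
    compute_forces_nl(m, x.data(), F.data(), nl);
    // capped drift
    for (int i = 0; i < N; ++i) {
      double gx = F[3 * i] * dt, gy = F[3 * i + 1] * dt, gz = F[3 * i + 2] * dt;
      double g = std::sqrt(gx * gx + gy * gy + gz * gz);
      if (g > cap_drift) {
        double s = cap_drift / g;
        gx *= s; gy *= s; gz *= s;
        ++n_flagged;
      }
      disp[3 * i] = gx; disp[3 * i + 1] = gy; disp[3 * i + 2] = gz;
    }
    // noise, with rejection of extreme total displacements
    for (int i = 0; i < N; ++i) {
      double tx, ty, tz, d2;
      int tries = 0;
      do {
        tx = disp[3 * i] + sd[i] * rng.norm();
        ty = disp[3 * i + 1] + sd[i] * rng.norm();
        tz = disp[3 * i + 2] + sd[i] * rng.norm();
        d2 = tx * tx + ty * ty + tz * tz;
        if (d2 <= cap_reject * cap_reject) break;
        ++n_rejected;
      } while (++tries < 100);
      if (tries >= 100)
        stop("brownian_run: displacement cap could not be satisfied at step %d", step + 1);
      x[3 * i] += tx; x[3 * i + 1] += ty; x[3 * i + 2] += tz;
      if (!std::isfinite(x[3 * i]) || !std::isfinite(x[3 * i + 1]) ||
          !std::isfinite(x[3 * i + 2]))
        stop("brownian_run: non-finite coordinate at step %d", step + 1);
    }
    if ((step + 1) % stride == 0) store(frame++);
  }
  frames.attr("dim") = IntegerVector::create(T, N, 3);
  return List::create(_["frames"] = frames, _["n_flagged"] = n_flagged,
                      _["n_rejected"] = n_rejected);
}

// ---------------------------------------------------------------------------
// Low-friction Langevin sampler (BAOAB, m = 1, kT = 1).  Per-bead force norms
// are clamped at f_clamp, which regularises the initial collapse of extended
// chains and is inert at equilibrium.  Returns sampled conformations.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_langevin_sample(NumericMatrix coords0, IntegerVector labels,
                         NumericMatrix type_matrix,
                         IntegerVector loop_i, IntegerVector loop_j,
                         double loop_eps, NumericVector gamma_tab, int d_max,
                         double mu, double rc, double sigma, double ev_k,
                         double bond_k, double bond_r0,
                         double Rs, double wall_k,
                         int n_samples, int spacing_steps, int burnin_steps,
                         double dt, double friction, double seed,
                         double f_clamp, double v_clamp,
                         int nl_every, double nl_skin,
                         bool return_velocities) {
  int N = coords0.nrow();
  PairModel m = build_model(N, labels, type_matrix, loop_i, loop_j, loop_eps,
                            gamma_tab, d_max, mu, rc, sigma, ev_k,
                            bond_k, bond_r0, Rs, wall_k);
  Rng rng((uint64_t)seed);
  std::vector<double> x(3 * N), v(3 * N), F(3 * N);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) {
      x[3 * i + c] = coords0(i, c);
      v[3 * i + c] = rng.norm(); // Maxwell-Boltzmann, kT = m = 1
    }
  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);
  NeighbourList nl;
  double cutoff = m.r_cut + nl_skin;
  auto clamp_forces = [&]() {
    for (int i = 0; i < N; ++i) {
      double g = std::sqrt(F[3 * i] * F[3 * i] + F[3 * i + 1] * F[3 * i + 1] +
                           F[3 * i + 2] * F[3 * i + 2]);
      if (g > f_clamp) {
        double s = f_clamp / g;
        F[3 * i] *= s; F[3 * i + 1] *= s; F[3 * i + 2] *= s;
      }
    }
  };
  // collapse-phase regularisation: bounds per-step displacement so the
  // neighbour list stays fresh; inert at equilibrium (thermal |v| ~ 1.7)
  auto clamp_velocities = [&]() {
    if (v_clamp <= 0) return;
    for (int i = 0; i < N; ++i) {
      double g = std::sqrt(v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                           v[3 * i + 2] * v[3 * i + 2]);
      if (g > v_clamp) {
        double s = v_clamp / g;
        v[3 * i] *= s; v[3 * i + 1] *= s; v[3 * i + 2] *= s;
      }
    }
  };
  nl.build(m, x.data(), cutoff);
  compute_forces_nl(m, x.data(), F.data(), nl);
  clamp_forces();
  List samples(n_samples);
  List vels(return_velocities ? n_samples : 0);
  long total_steps = (long)burnin_steps + (long)n_samples * spacing_steps;
  int got = 0;
  for (long step = 0; step < total_steps; ++step) {
    // B
    for (int k = 0; k < 3 * N; ++k) v[k] += 0.5 * dt * F[k];
    // A
    for (int k = 0; k < 3 * N; ++k) x[k] += 0.5 * dt * v[k];
    // O
    for (int k = 0; k < 3 * N; ++k) v[k] = c1 * v[k] + c2 * rng.norm();
    // A
    for (int k = 0; k < 3 * N; ++k) x[k] += 0.5 * dt * v[k];
    if ((step + 1) % nl_every == 0) nl.build(m, x.data(), cutoff);
    compute_forces_nl(m, x.data(), F.data(), nl);
    clamp_forces();
    // B
    for (int k = 0; k < 3 * N; ++k) v[k] += 0.5 * dt * F[k];
    clamp_velocities();
    for (int k = 0; k < 3 * N; ++k)
      if (!std::isfinite(x[k]))
        stop("langevin_sample: non-finite coordinate at step %ld", step + 1);
    if (step >= burnin_steps && (step + 1 - burnin_steps) % spacing_steps == 0 &&
        got < n_samples) {
      NumericMatrix s(N, 3);
      for (int i = 0; i < N; ++i)
        for (int c = 0; c < 3; ++c) s(i, c) = x[3 * i + c];
      samples[got] = s;
      if (return_velocities) {
        NumericMatrix vv(N, 3);
        for (int i = 0; i < N; ++i)
          for (int c = 0; c < 3; ++c) vv(i, c) = v[3 * i + c];
        vels[got] = vv;
      }
      ++got;
    }
  }
  if (return_velocities)
    return List::create(_["samples"] = samples, _["velocities"] = vels);
  return List::create(_["samples"] = samples);
}

// ---------------------------------------------------------------------------
// Ensemble-averaged contact map c_ij = <f(r_ij)> and direct P(s) accumulation.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_contact_map(List ensemble, double mu, double rc) {
  int M = ensemble.size();
  NumericMatrix first = ensemble[0];
  int N = first.nrow();
  NumericMatrix acc(N, N);
  for (int s = 0; s < M; ++s) {
    NumericMatrix cf = ensemble[s];
    for (int i = 0; i < N; ++i) {
      acc(i, i) += fcontact(0.0, mu, rc);
      for (int j = i + 1; j < N; ++j) {
        double dx = cf(j, 0) - cf(i, 0);
        double dy = cf(j, 1) - cf(i, 1);
        double dz = cf(j, 2) - cf(i, 2);
        double f = fcontact(std::sqrt(dx * dx + dy * dy + dz * dz), mu, rc);
        acc(i, j) += f;
        acc(j, i) += f;
      }
    }
  }
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) acc(i, j) /= M;
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_pscurve(List ensemble, IntegerVector svals, double mu, double rc) {
  int M = ensemble.size();
  NumericMatrix first = ensemble[0];
  int N = first.nrow();
  NumericVector out(svals.size());
  for (int k = 0; k < svals.size(); ++k) {
    int s = svals[k];
    double acc = 0.0;
    for (int e = 0; e < M; ++e) {
      NumericMatrix cf = ensemble[e];
      for (int i = 0; i + s < N; ++i) {
        double dx = cf(i + s, 0) - cf(i, 0);
        double dy = cf(i + s, 1) - cf(i, 1);
        double dz = cf(i + s, 2) - cf(i, 2);
        acc += fcontact(std::sqrt(dx * dx + dy * dy + dz * dz), mu, rc);
      }
    }
    out[k] = acc / ((double)M * (N - s));
  }
  return out;
}
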