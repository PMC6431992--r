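// Metropolis kernel for the bead-spring translocation model.
//
// The chain has n = n_bonds + 1 monomers. Energies: FENE bonds, Morse
// excluded volume between non-bonded pairs, kappa*(1 + cos theta) bending
// (theta = interior angle, collinear bonds => theta = pi => zero energy),
// truncated-shifted Morse wall repulsion as a function of the distance to
// the confining solid, and a uniform electric field acting along -z inside
// the pore column. All energies in units of kbt; lmax is the unit of length.
//
// Randomness comes from R's RNG (unif_rand), so set.seed() on the R side
// makes every kernel entry point bit-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Pars {
  int nb;                     // number of bonds N
  double kappa, E, R, L, D;
  double q, k, l0, lmin, lmax, r0;
  double am, rmin, eps, woff;
  double step, kbt, rcut, rcut2;
};

Pars as_pars(const List& p) {
  Pars P;
  P.nb   = as<int>(p["n_bonds"]);
  P.kappa = as<double>(p["kappa"]);
  P.E    = as<double>(p["e_field"]);
  P.R    = as<double>(p["r_sep"]);
  P.L    = as<double>(p["l_pore"]);
  P.D    = as<double>(p["d_pore"]);
  P.q    = as<double>(p["q_charge"]);
  P.k    = as<double>(p["k_spring"]);
  P.l0   = as<double>(p["l0"]);
  P.lmin = as<double>(p["lmin"]);
  P.lmax = as<double>(p["lmax"]);
  P.r0   = as<double>(p["r0"]);
  P.am   = as<double>(p["alpha_morse"]);
  P.rmin = as<double>(p["rmin_morse"]);
  P.eps  = as<double>(p["eps_morse"]);
  P.woff = as<double>(p["wall_offset"]);
  P.step = as<double>(p["step_max"]);
  P.kbt  = as<double>(p["kbt"]);
  P.rcut = as<double>(p["cutoff"]);
  P.rcut2 = P.rcut * P.rcut;
  return P;
}

inline double fene_e(double l, const Pars& P) {
  if (l <= P.lmin || l >= P.lmax) return R_PosInf;
  double x = (l - P.l0) / P.r0;
  return -0.5 * P.k * P.r0 * P.r0 * std::log(1.0 - x * x);
}

inline double morse_e(double r, const Pars& P) {
  if (r >= P.rcut) return 0.0;
  double e1 = std::exp(-P.am * (r - P.rmin));
  return P.eps * (e1 * e1 - 2.0 * e1);
}

// Wall repulsion: Morse shifted by +eps for gap <= rmin, zero beyond.
inline double wall_e(double gap, const Pars& P) {
  if (gap > P.rmin) return 0.0;
  double e1 = std::exp(-P.am * (gap - P.rmin));
  return P.eps * (e1 * e1 - 2.0 * e1) + P.eps;
}

inline double elec_e(double z, const Pars& P) {
  if (z >= 0.0) return 0.0;
  if (z >= -P.L) return P.q * P.E * z;
  return -P.q * P.E * P.L;
}

// Distance from a point to the nearest confining solid.
// Open geometry: left membrane is the slab -L <= z <= 0 minus the pore
// cylinder rho < D/2; right membrane is the half-space z <= -(L + R).
// Returns -1 when the point lies strictly inside membrane material.
inline double gap_open(double x, double y, double z, const Pars& P) {
  double half = 0.5 * P.D;
  double rho = std::sqrt(x * x + y * y);
  double dz = 0.0;
  if (z > 0.0) dz = z;
  else if (z < -P.L) dz = -P.L - z;
  double dr = (rho < half) ? (half - rho) : 0.0;
  double dleft;
  if (dz == 0.0 && dr == 0.0) {
    // z in [-L, 0] and rho >= D/2: inside (or on the surface of) the slab
    if (z > -P.L && z < 0.0 && rho > half) return -1.0;
    dleft = 0.0;
  } else {
    dleft = std::sqrt(dz * dz + dr * dr);
  }
  double dright = z + P.L + P.R;
  if (dright < 0.0) return -1.0;
  return dleft < dright ? dleft : dright;
}

struct Engine {
  Pars P;
  int n;                       // monomers
  std::vector<double> x, y, z;
  bool closed;                 // relaxation: pore shut, full wall at z = 0
  bool fixed0;                 // monomer 0 frozen (relaxation)
  bool freespace;              // dilute chain: no walls, no field
  long long trials, accepts;
  double U;                    // incrementally tracked total energy
  // cached Morse pair energies: pm[i*n+j] for |i-j| > 1, psum[i] = row sum
  std::vector<double> pm, psum, scratch;
  // cached single-site terms: per-bond FENE, per-vertex bend, per-monomer
  // wall and field energies; kept bitwise equal to fresh evaluation so the
  // cached old-site energy reproduces site_nonpair() exactly
  std::vector<double> be, ve, we_, ee;

  Engine(const NumericMatrix& pos, const Pars& pars,
         bool closed_, bool fixed0_, bool freespace_)
      : P(pars), n(pos.nrow()), x(n), y(n), z(n),
        closed(closed_), fixed0(fixed0_), freespace(freespace_),
        trials(0), accepts(0), U(0.0),
        pm((size_t)n * n, 0.0), psum(n, 0.0), scratch(n, 0.0),
        be(n > 1 ? n - 1 : 0, 0.0), ve(n, 0.0), we_(n, 0.0), ee(n, 0.0) {
    for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
    rebuild_pairs();
    rebuild_sites();
  }

  void rebuild_sites() {
    for (int b = 0; b < n - 1; ++b) be[b] = fene_e(std::sqrt(dist2(b, b + 1)), P);
    for (int t = 1; t <= n - 2; ++t) ve[t] = bend_at(t);
    for (int i = 0; i < n; ++i) refresh_external(i);
  }

  inline void refresh_external(int i) {
    if (!freespace && !(closed && i == 0)) {
      double g = gap_of(i);
      we_[i] = (g < 0.0) ? R_PosInf : wall_e(g + P.woff, P);
      ee[i] = elec_e(z[i], P);
    } else {
      we_[i] = 0.0; ee[i] = 0.0;
    }
  }

  void rebuild_pairs() {
    std::fill(pm.begin(), pm.end(), 0.0);
    std::fill(psum.begin(), psum.end(), 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = i + 2; j < n; ++j) {
        double r2 = dist2(i, j);
        if (r2 < P.rcut2) {
          double v = morse_e(std::sqrt(r2), P);
          pm[(size_t)i * n + j] = pm[(size_t)j * n + i] = v;
          psum[i] += v; psum[j] += v;
        }
      }
  }

  inline double dist2(int i, int j) const {
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    return dx * dx + dy * dy + dz * dz;
  }

  inline double bend_at(int t) const {   // vertex t, needs 1 <= t <= n-2
    double b1x = x[t] - x[t - 1], b1y = y[t] - y[t - 1], b1z = z[t] - z[t - 1];
    double b2x = x[t + 1] - x[t], b2y = y[t + 1] - y[t], b2z = z[t + 1] - z[t];
    double dot = b1x * b2x + b1y * b2y + b1z * b2z;
    double nrm = std::sqrt((b1x * b1x + b1y * b1y + b1z * b1z) *
                           (b2x * b2x + b2y * b2y + b2z * b2z));
    double cos_int = -dot / nrm;          // +1 at full backfold, -1 straight
    return P.kappa * (1.0 + cos_int);
  }

  inline double gap_of(int i) const {
    if (closed) return z[i];              // pore shut: plain wall at z = 0
    return gap_open(x[i], y[i], z[i], P);
  }

  // Bond, bend, wall and field terms involving monomer i (pair terms are
  // handled through the cached sums).
  double site_nonpair(int i) const {
    double u = 0.0;
    if (i > 0) {
      double f = fene_e(std::sqrt(dist2(i - 1, i)), P);
      if (!R_FINITE(f)) return R_PosInf;
      u += f;
    }
    if (i < n - 1) {
      double f = fene_e(std::sqrt(dist2(i, i + 1)), P);
      if (!R_FINITE(f)) return R_PosInf;
      u += f;
    }
    for (int t = i - 1; t <= i + 1; ++t)
      if (t >= 1 && t <= n - 2) u += bend_at(t);
    if (!freespace && !(closed && i == 0)) {
      // monomer 0 is held by the relaxation constraint inside the shut
      // pore, outside the closed-wall geometry: skip its wall/field terms
      double g = gap_of(i);
      if (g < 0.0) return R_PosInf;
      // wall-particle centres sit woff behind the material surface
      u += wall_e(g + P.woff, P);
      u += elec_e(z[i], P);
    }
    return u;
  }

  // Morse pair energy of monomer i at its current coordinates, recomputed
  // into `scratch`; returns the row sum.
  double pair_row(int i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      int d = j > i ? j - i : i - j;
      if (d <= 1) { scratch[j] = 0.0; continue; }
      double r2 = dist2(i, j);
      double v = (r2 < P.rcut2) ? morse_e(std::sqrt(r2), P) : 0.0;
      scratch[j] = v;
      s += v;
    }
    return s;
  }

  void full_energy(double out[6]) const {
    double uf = 0, um = 0, ub = 0, uw = 0, ue = 0;
    for (int i = 0; i < n - 1; ++i) uf += fene_e(std::sqrt(dist2(i, i + 1)), P);
    for (int i = 0; i < n; ++i)
      for (int j = i + 2; j < n; ++j) {
        double r2 = dist2(i, j);
        if (r2 < P.rcut2) um += morse_e(std::sqrt(r2), P);
      }
    for (int t = 1; t <= n - 2; ++t) ub += bend_at(t);
    if (!freespace)
      for (int i = 0; i < n; ++i) {
        if (closed && i == 0) continue;
        double g = gap_of(i);
        uw += (g < 0.0) ? R_PosInf : wall_e(g + P.woff, P);
        ue += elec_e(z[i], P);
      }
    out[0] = uf; out[1] = um; out[2] = ub; out[3] = uw; out[4] = ue;
    out[5] = uf + um + ub + uw + ue;
  }

  // One Monte Carlo step = n trial moves.
  void mcs() {
    int lo = fixed0 ? 1 : 0;
    int m = n - lo;
    for (int k = 0; k < n; ++k) {
      ++trials;
      int i = lo + (int)(unif_rand() * m);
      if (i >= n) i = n - 1;
      double dx = (2.0 * unif_rand() - 1.0) * P.step;
      double dy = (2.0 * unif_rand() - 1.0) * P.step;
      double dz = (2.0 * unif_rand() - 1.0) * P.step;
      double nx = x[i] + dx, ny = y[i] + dy, nz = z[i] + dz;
      if (closed && nz < 0.0) continue;   // reflecting shut pore
      // cached old-site energy, summed in the same order as site_nonpair()
      double e_old = 0.0;
      if (i > 0) e_old += be[i - 1];
      if (i < n - 1) e_old += be[i];
      for (int t = i - 1; t <= i + 1; ++t)
        if (t >= 1 && t <= n - 2) e_old += ve[t];
      if (!freespace && !(closed && i == 0)) { e_old += we_[i]; e_old += ee[i]; }
      e_old += psum[i];
      double ox = x[i], oy = y[i], oz = z[i];
      x[i] = nx; y[i] = ny; z[i] = nz;
      double e_new = site_nonpair(i);
      if (!R_FINITE(e_new)) { x[i] = ox; y[i] = oy; z[i] = oz; continue; }
      e_new += pair_row(i);
      double du = e_new - e_old;
      if (du <= 0.0 || unif_rand() < std::exp(-du / P.kbt)) {
        ++accepts;
        U += du;
        double s = 0.0;
        for (int j = 0; j < n; ++j) {
          double v = scratch[j];
          double old = pm[(size_t)i * n + j];
          if (v != old) {
            psum[j] += v - old;
            pm[(size_t)i * n + j] = pm[(size_t)j * n + i] = v;
          }
          s += v;
        }
        psum[i] = s;
        if (i > 0) be[i - 1] = fene_e(std::sqrt(dist2(i - 1, i)), P);
        if (i < n - 1) be[i] = fene_e(std::sqrt(dist2(i, i + 1)), P);
        for (int t = i - 1; t <= i + 1; ++t)
          if (t >= 1 && t <= n - 2) ve[t] = bend_at(t);
        refresh_external(i);
      } else {
        x[i] = ox; y[i] = oy; z[i] = oz;
      }
    }
  }

  NumericMatrix positions() const {
    NumericMatrix out(n, 3);
    for (int i = 0; i < n; ++i) { out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i]; }
    return out;
  }

  // Region codes: 0 cis, 1 pore, 2 trans, 3 membrane
  inline int region(int i) const {
    if (z[i] >= 0.0) return 0;
    if (z[i] <= -P.L) return 2;
    double half = 0.5 * P.D;
    return (x[i] * x[i] + y[i] * y[i] < half * half) ? 1 : 3;
  }
};

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_total_energy(NumericMatrix pos, List params,
                               bool closed_pore = false, bool free_space = false) {
  Engine eng(pos, as_pars(params), closed_pore, false, free_space);
  double out[6];
  eng.full_energy(out);
  NumericVector res = NumericVector::create(
      _["u_fene"] = out[0], _["u_morse"] = out[1], _["u_bend"] = out[2],
      _["u_wall"] = out[3], _["u_elec"] = out[4], _["u_total"] = out[5]);
  return res;
}

// Generic stepper. Optionally records bond lengths and interior-angle
// cosines every `record_every` MCS (after an initial `burn`), which is how
// the dilute-chain equilibrium samplers used for validation are built.
// [[Rcpp::export]]
List cpp_evolve(NumericMatrix pos, List params, int n_mcs,
                bool closed_pore = false, bool fix_first = false,
                bool free_space = false, int record_every = 0, int burn = 0) {
  Engine eng(pos, as_pars(params), closed_pore, fix_first, free_space);
  double e0[6];
  eng.full_energy(e0);
  eng.U = e0[5];

  int nrec = 0;
  if (record_every > 0) nrec = (n_mcs - burn) / record_every;
  int nb = eng.n - 1, na = eng.n - 2;
  NumericMatrix bonds(nrec > 0 ? nrec : 0, nb > 0 ? nb : 0);
  NumericMatrix cosang(nrec > 0 ? nrec : 0, na > 0 ? na : 0);
  int irec = 0;

  for (int t = 1; t <= n_mcs; ++t) {
    eng.mcs();
    if (record_every > 0 && t > burn && (t - burn) % record_every == 0 && irec < nrec) {
      for (int b = 0; b < nb; ++b) bonds(irec, b) = std::sqrt(eng.dist2(b, b + 1));
      for (int a = 0; a < na; ++a) {
        int tverts = a + 1;
        double u = eng.bend_at(tverts);
        // recover cos(theta_interior) from the energy expression
        cosang(irec, a) = (eng.P.kappa != 0.0) ? (u / eng.P.kappa - 1.0)
                                               : NA_REAL;
      }
      ++irec;
    }
  }
  double e1[6];
  eng.full_energy(e1);
  return List::create(
      _["positions"] = eng.positions(),
      _["u_init"] = e0[5], _["u_incr"] = eng.U, _["u_final"] = e1[5],
      _["trials"] = (double)eng.trials, _["accepts"] = (double)eng.accepts,
      _["bonds"] = bonds, _["cos_angles"] = cosang);
}

// Cis-side equilibration with the pore shut and monomer 0 frozen.
// Stops when consecutive windows of `window` MCS have mean total energies
// within rel. tol, after at least min_mcs and at most max_mcs.
// [[Rcpp::export]]
List cpp_relax(NumericMatrix pos, List params, int min_mcs, int window,
               double tol, int max_mcs) {
  Engine eng(pos, as_pars(params), true, true, false);
  double e0[6];
  eng.full_energy(e0);
  eng.U = e0[5];

  std::vector<double> wmeans;
  double acc = 0.0;
  int in_win = 0, t = 0;
  bool converged = false;
  double prev_mean = NA_REAL;

  while (t < max_mcs) {
    eng.mcs();
    ++t;
    acc += eng.U;
    if (++in_win == window) {
      double m = acc / window;
      wmeans.push_back(m);
      if (!ISNA(prev_mean) && t >= min_mcs) {
        double denom = std::fabs(prev_mean) > 1.0 ? std::fabs(prev_mean) : 1.0;
        if (std::fabs(m - prev_mean) / denom < tol) { converged = true; break; }
      }
      prev_mean = m;
      acc = 0.0; in_win = 0;
    }
  }
  double e1[6];
  eng.full_energy(e1);
  return List::create(
      _["positions"] = eng.positions(), _["mcs"] = t,
      _["converged"] = converged, _["window_means"] = wrap(wmeans),
      _["u_init"] = e0[5], _["u_incr"] = eng.U, _["u_final"] = e1[5],
      _["trials"] = (double)eng.trials, _["accepts"] = (double)eng.accepts);
}

// Full translocation protocol from an equilibrated cis conformation.
// Clock starts at release (t = 0). Withdrawal (chain fully back on cis with
// an empty pore, after having engaged the pore) restores the stored
// conformation and resets the clock. Completion: last monomer's z < -L.
// Waiting times are pore-residence counts at one-MCS granularity.
// [[Rcpp::export]]
List cpp_translocate(NumericMatrix pos_eq, List params, double max_mcs,
                     bool record_events = false, int snapshot_every = 0) {
  Pars P = as_pars(params);
  Engine eng(pos_eq, P, false, false, false);
  double e0[6];
  eng.full_energy(e0);
  eng.U = e0[5];

  int n = eng.n;
  std::vector<double> waiting(n, 0.0);
  std::vector<double> last_seen(n, -1.0);
  std::vector<int> prev_region(n);
  for (int i = 0; i < n; ++i) prev_region[i] = eng.region(i);

  std::vector<double> ev_mcs;
  std::vector<int> ev_mono, ev_code;   // 1 enter, 2 exit->trans, 3 exit->cis, 4 withdrawal, 5 done
  List snapshots;

  int attempts = 1;
  bool engaged = false, done = false, failed = false;
  double t = 0.0, total_t = 0.0;
  long long tr0 = 0, ac0 = 0;          // counters at start of current attempt

  while (!done) {
    if (total_t >= max_mcs) { failed = true; break; }
    eng.mcs();
    t += 1.0; total_t += 1.0;

    bool any_neg = false;
    for (int i = 0; i < n; ++i) {
      int r = eng.region(i);
      if (r == 1) { waiting[i] += 1.0; last_seen[i] = t; }
      if (eng.z[i] < 0.0) any_neg = true;
      if (record_events && r != prev_region[i]) {
        int code = 0;
        if (r == 1) code = 1;
        else if (prev_region[i] == 1 && r == 2) code = 2;
        else if (prev_region[i] == 1 && r == 0) code = 3;
        if (code) { ev_mcs.push_back(t); ev_mono.push_back(i); ev_code.push_back(code); }
      }
      prev_region[i] = r;
    }
    if (any_neg) engaged = true;

    if (snapshot_every > 0 && ((long long)t) % snapshot_every == 0)
      snapshots.push_back(eng.positions());

    if (eng.z[n - 1] < -P.L) {          // last monomer reached trans: finished
      done = true;
      if (record_events) { ev_mcs.push_back(t); ev_mono.push_back(-1); ev_code.push_back(5); }
      break;
    }

    if (engaged && !any_neg) {          // chain fully back on cis: restart
      if (record_events) { ev_mcs.push_back(t); ev_mono.push_back(-1); ev_code.push_back(4); }
      for (int i = 0; i < n; ++i) {
        eng.x[i] = pos_eq(i, 0); eng.y[i] = pos_eq(i, 1); eng.z[i] = pos_eq(i, 2);
        waiting[i] = 0.0; last_seen[i] = -1.0;
      }
      eng.rebuild_pairs();
      eng.rebuild_sites();
      double er[6];
      eng.full_energy(er);
      eng.U = er[5];
      for (int i = 0; i < n; ++i) prev_region[i] = eng.region(i);
      engaged = false;
      t = 0.0;
      ++attempts;
      tr0 = eng.trials; ac0 = eng.accepts;
      if (snapshot_every > 0) snapshots = List();
    }
  }

  if (snapshot_every > 0) snapshots.push_back(eng.positions());

  double e1[6];
  eng.full_energy(e1);
  List events = R_NilValue;
  if (record_events) {
    int ne = ev_mcs.size();
    NumericMatrix em(ne, 3);
    for (int i = 0; i < ne; ++i) { em(i, 0) = ev_mcs[i]; em(i, 1) = ev_mono[i]; em(i, 2) = ev_code[i]; }
    events = List::create(em);
  }
  return List::create(
      _["tau"] = t, _["failed"] = failed, _["attempts"] = attempts,
      _["waiting"] = wrap(waiting), _["last_seen"] = wrap(last_seen),
      _["positions"] = eng.positions(),
      _["trials_attempt"] = (double)(eng.trials - tr0),
      _["accepts_attempt"] = (double)(eng.accepts - ac0),
      _["trials_total"] = (double)eng.trials,
      _["accepts_total"] = (double)eng.accepts,
      _["u_incr"] = eng.U, _["u_final"] = e1[5],
      _["events"] = events, _["snapshots"] = snapshots);
}
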