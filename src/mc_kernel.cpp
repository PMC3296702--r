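// Lattice Monte Carlo kernel for single DNA replication cycles.
//
// Replicated DNA is kept as a sorted list of disjoint "islands" [a, b];
// the left edge of an island is a left-moving fork, the right edge a
// right-moving fork.  Initiations open new islands on unreplicated sites,
// edges advance by v*dt per step (stalling at Poisson-placed defects with
// exponential repair), and overlapping islands merge, which is a fork
// coalescence.  Per-site replication times and the replicating direction
// (-1 left fork, 0 origin, +1 right fork) are recorded; within a step the
// earlier sub-step arrival claims a site.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Edge {
  double pos;        // current position (unwrapped in PBC mode)
  double old_pos;    // position at the start of the current step
  bool stalled;
  double resume_t;   // absolute time at which a stalled edge resumes
  bool dead;         // reached a non-periodic domain end
};

struct Island {
  Edge left;   // left-moving fork (position decreases)
  Edge right;  // right-moving fork (position increases)
};

struct Defect {
  double pos;
  bool consumed;
};

struct Sim {
  const NumericVector& site_x;
  int n;
  double x_lo, x_hi, L, dx;
  bool pbc;
  std::vector<double> t_rep;
  std::vector<int> dir;
  int n_claimed;

  Sim(const NumericVector& sx, double lo, double hi, double dx_, bool pbc_)
    : site_x(sx), n(sx.size()), x_lo(lo), x_hi(hi), L(hi - lo), dx(dx_),
      pbc(pbc_), t_rep(sx.size(), NA_REAL), dir(sx.size(), NA_INTEGER),
      n_claimed(0) {}

  void claim(int i, double t, int d) {
    if (i < 0 || i >= n) return;
    if (ISNA(t_rep[i])) {
      t_rep[i] = t; dir[i] = d; ++n_claimed;
    } else if (t < t_rep[i]) {
      t_rep[i] = t; dir[i] = d;
    }
  }

  int wrap_index(long i) const {
    if (pbc) {
      long m = i % n; if (m < 0) m += n; return (int)m;
    }
    return (i < 0 || i >= n) ? -1 : (int)i;
  }

  bool site_replicated(int i) const { return !ISNA(t_rep[i]); }

  // sites with center in (p0, p1], replicated by a right-moving fork
  void sweep_right(double p0, double p1, double t0, double speed) {
    long i0 = (long)std::floor((p0 - x_lo) / dx - 0.5 + 1e-9) + 1;
    long i1 = (long)std::floor((p1 - x_lo) / dx - 0.5 + 1e-9);
    for (long i = i0; i <= i1; ++i) {
      int j = wrap_index(i);
      if (j < 0) continue;
      double c = x_lo + (i + 0.5) * dx;
      double t_arr = speed > 0 ? t0 + (c - p0) / speed : t0;
      claim(j, t_arr, +1);
    }
  }

  // sites with center in [p1, p0), replicated by a left-moving fork
  void sweep_left(double p0, double p1, double t0, double speed) {
    long i1 = (long)std::floor((p0 - x_lo) / dx - 0.5 - 1e-9);
    long i0 = (long)std::ceil((p1 - x_lo) / dx - 0.5 - 1e-9);
    for (long i = i0; i <= i1; ++i) {
      int j = wrap_index(i);
      if (j < 0) continue;
      double c = x_lo + (i + 0.5) * dx;
      double t_arr = speed > 0 ? t0 + (p0 - c) / speed : t0;
      claim(j, t_arr, -1);
    }
  }
};

double velocity_at(const NumericVector& v, const Sim& sim, double pos) {
  long i = (long)std::floor((pos - sim.x_lo) / sim.dx);
  int j = sim.pbc ? sim.wrap_index(i) : std::min(std::max((int)i, 0), sim.n - 1);
  return v[j];
}

// first unconsumed defect strictly inside (lo, hi]; -1 if none
int find_defect(std::vector<Defect>& defs, const Sim& sim,
                double lo, double hi) {
  for (size_t k = 0; k < defs.size(); ++k) {
    if (defs[k].consumed) continue;
    double p = defs[k].pos;
    if (sim.pbc) {
      // compare in unwrapped frame: shift defect into (lo, lo + L]
      double sh = p + sim.L * std::ceil((lo - p) / sim.L + 1e-12);
      if (sh > lo && sh <= hi) { defs[k].pos = sh; return (int)k; }
    } else if (p > lo && p <= hi) {
      return (int)k;
    }
  }
  return -1;
}

// advance the right-moving edge of an island over one time step
void advance_right(Edge& e, Sim& sim, std::vector<Defect>& defs,
                   const NumericVector& v_p, double t, double dt,
                   double tau) {
  e.old_pos = e.pos;
  if (e.dead) return;
  double t0 = t, rem = dt;
  if (e.stalled) {
    if (e.resume_t >= t + dt) return;
    rem = t + dt - e.resume_t;
    t0 = e.resume_t;
    e.stalled = false;
  }
  double sp = velocity_at(v_p, sim, e.pos);
  double target = e.pos + sp * rem;
  int dk = find_defect(defs, sim, e.pos, target);
  if (dk >= 0) {
    double q = defs[dk].pos;
    double t_hit = t0 + (q - e.pos) / sp;
    sim.sweep_right(e.pos, q, t0, sp);
    e.pos = q;
    defs[dk].consumed = true;
    double rep = std::isfinite(tau) ? R::rexp(tau) : R_PosInf;
    e.stalled = true;
    e.resume_t = t_hit + rep;
  } else {
    if (!sim.pbc && target >= sim.x_hi) {
      sim.sweep_right(e.pos, sim.x_hi, t0, sp);
      e.pos = sim.x_hi;
      e.dead = true;
    } else {
      sim.sweep_right(e.pos, target, t0, sp);
      e.pos = target;
    }
  }
}

void advance_left(Edge& e, Sim& sim, std::vector<Defect>& defs,
                  const NumericVector& v_m, double t, double dt,
                  double tau) {
  e.old_pos = e.pos;
  if (e.dead) return;
  double t0 = t, rem = dt;
  if (e.stalled) {
    if (e.resume_t >= t + dt) return;
    rem = t + dt - e.resume_t;
    t0 = e.resume_t;
    e.stalled = false;
  }
  double sp = velocity_at(v_m, sim, e.pos);
  double target = e.pos - sp * rem;
  // mirrored defect search: defects in [target, pos)
  int dk = -1;
  {
    for (size_t k = 0; k < defs.size(); ++k) {
      if (defs[k].consumed) continue;
      double p = defs[k].pos;
      if (sim.pbc) {
        double sh = p - sim.L * std::ceil((p - e.pos) / sim.L + 1e-12);
        if (sh < e.pos && sh >= target) {
          defs[k].pos = sh; dk = (int)k; break;
        }
      } else if (p < e.pos && p >= target) { dk = (int)k; break; }
    }
  }
  if (dk >= 0) {
    double q = defs[dk].pos;
    double t_hit = t0 + (e.pos - q) / sp;
    sim.sweep_left(e.pos, q, t0, sp);
    e.pos = q;
    defs[dk].consumed = true;
    double rep = std::isfinite(tau) ? R::rexp(tau) : R_PosInf;
    e.stalled = true;
    e.resume_t = t_hit + rep;
  } else {
    if (!sim.pbc && target <= sim.x_lo) {
      sim.sweep_left(e.pos, sim.x_lo, t0, sp);
      e.pos = sim.x_lo;
      e.dead = true;
    } else {
      sim.sweep_left(e.pos, target, t0, sp);
      e.pos = target;
    }
  }
}

} // namespace

// [[Rcpp::export]]
List mc_cycle_kernel(NumericVector site_x, NumericVector bg_site,
                     NumericMatrix shapes, NumericVector amps,
                     NumericVector gate_on, NumericVector gate_off,
                     NumericVector v_p, NumericVector v_m,
                     double dx, double dt, int n_steps,
                     bool pbc, double x_lo, double x_hi,
                     double defect_d, double defect_tau) {
  const int n = site_x.size();
  const int nz = amps.size();
  Sim sim(site_x, x_lo, x_hi, dx, pbc);
  std::vector<Island> isl;
  std::vector<Defect> defs;
  std::vector<double> init_x, init_t, coal_x, coal_t;

  if (R_finite(defect_d) && defect_d > 0) {
    double p = x_lo + R::rexp(defect_d);
    while (p < x_hi) {
      defs.push_back({p, false});
      p += R::rexp(defect_d);
    }
  }

  double max_bg = 0;
  for (int i = 0; i < n; ++i) max_bg = std::max(max_bg, bg_site[i]);

  bool closed = false;  // PBC: circle fully replicated
  for (int step = 0; step < n_steps && !closed; ++step) {
    double t = step * dt;

    // --- initiations (binomial thinning under the peak rate bound) ---
    double amp_act = 0;
    std::vector<double> act(nz);
    for (int z = 0; z < nz; ++z) {
      act[z] = (t >= gate_on[z] && t <= gate_off[z]) ? amps[z] : 0.0;
      amp_act += act[z];
    }
    double p_ub = (max_bg + amp_act) * dx * dt;
    if (p_ub > 0.1)
      stop("MC resolution error: I*dx*dt = %g exceeds 0.1; refine the lattice",
           p_ub);
    if (p_ub > 0) {
      int n_prop = (int)R::rbinom((double)n, p_ub);
      for (int k = 0; k < n_prop; ++k) {
        int i = (int)std::floor(R::unif_rand() * n);
        if (i >= n) i = n - 1;
        if (sim.site_replicated(i)) continue;
        double Ii = bg_site[i];
        for (int z = 0; z < nz; ++z)
          if (act[z] > 0) Ii += act[z] * shapes(i, z);
        if (R::unif_rand() * p_ub > Ii * dx * dt) continue;
        // fire at site i at start of the step
        double xi = site_x[i];
        sim.claim(i, t, 0);
        init_x.push_back(xi); init_t.push_back(t);
        Island nw;
        nw.left = {xi, xi, false, 0.0, false};
        nw.right = {xi, xi, false, 0.0, false};
        // insert sorted by left position
        size_t at = 0;
        while (at < isl.size() && isl[at].left.pos < xi) ++at;
        isl.insert(isl.begin() + at, nw);
      }
    }

    // --- fork movement ---
    for (size_t k = 0; k < isl.size(); ++k) {
      advance_left(isl[k].left, sim, defs, v_m, t, dt, defect_tau);
      advance_right(isl[k].right, sim, defs, v_p, t, dt, defect_tau);
    }

    // --- coalescences: merge overlapping neighbours (cascading) ---
    bool merged = true;
    while (merged && isl.size() > 0) {
      merged = false;
      size_t m = isl.size();
      for (size_t k = 0; k < m; ++k) {
        size_t nx = (k + 1) % m;
        if (!pbc && nx == 0 && m > 1) continue;
        if (m == 1 && !pbc) break;
        double b = isl[k].right.pos;
        double a = isl[nx].left.pos;
        double b_old = isl[k].right.old_pos;
        double a_old = isl[nx].left.old_pos;
        double shift = 0;
        if (pbc && nx <= k) shift = sim.L;  // wrap-around neighbour
        a += shift; a_old += shift;
        if (b < a) continue;
        if (isl[k].right.dead || isl[nx].left.dead) continue;
        // crossing point from effective speeds over this step
        double sb = (b - b_old) / dt;
        double sa = (a_old - a) / dt;
        double tc, xc;
        if (sb + sa > 0) {
          double dtau = (a_old - b_old) / (sb + sa);
          dtau = std::min(std::max(dtau, 0.0), dt);
          tc = t + dtau;
          xc = b_old + sb * dtau;
        } else {
          tc = t + dt; xc = 0.5 * (a + b);
        }
        if (pbc) {
          double w = xc;
          while (w >= sim.x_hi) w -= sim.L;
          while (w < sim.x_lo) w += sim.L;
          coal_x.push_back(w);
        } else {
          coal_x.push_back(xc);
        }
        coal_t.push_back(tc);
        if (m == 1) {  // the circle closed on itself
          closed = true;
          merged = false;
          break;
        }
        // keep outer edges: left of k, right of nx (shifted frame)
        Island keep;
        keep.left = isl[k].left;
        keep.right = isl[nx].right;
        if (shift > 0) keep.right.pos += shift, keep.right.old_pos += shift;
        if (nx > k) {
          isl[k] = keep;
          isl.erase(isl.begin() + nx);
        } else {  // nx == 0 wrapped
          isl[k] = keep;
          isl.erase(isl.begin());
        }
        merged = true;
        break;
      }
    }

    if (!pbc && sim.n_claimed == n) break;
    if (pbc && isl.size() == 1 &&
        isl[0].right.pos - isl[0].left.pos >= sim.L)
      closed = true;
  }

  return List::create(
    _["t_rep"] = NumericVector(sim.t_rep.begin(), sim.t_rep.end()),
    _["dir"] = IntegerVector(sim.dir.begin(), sim.dir.end()),
    _["init_x"] = NumericVector(init_x.begin(), init_x.end()),
    _["init_t"] = NumericVector(init_t.begin(), init_t.end()),
    _["coal_x"] = NumericVector(coal_x.begin(), coal_x.end()),
    _["coal_t"] = NumericVector(coal_t.begin(), coal_t.end()),
    _["complete"] = (sim.n_claimed == n)
  );
}
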