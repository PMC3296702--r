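// Inner time loop of the mean-field rate-equation solver.
//
// Explicit first-order upwind advection (direction-aware, flux form) with a
// forward-Euler source/sink update; the stall/repair exchange uses an
// implicit repair step so small repair times are not stiffness-limited.
// Mirrors solve_replication()'s documented scheme; all validation and
// set-up stays on the R side.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List solver_kernel(int n, double dx, double dt, int n_t,
                   NumericMatrix shapes, NumericVector amps,
                   NumericVector gate_on, NumericVector gate_off,
                   double bg,
                   NumericVector v_p, NumericVector v_m,
                   int bc_mode,  // 0 periodic, 1 isolated, 2 injection
                   double I_left, double I_right, double v_out,
                   bool has_stall, double d_def, double tau,
                   bool early_stop) {
  const double eps = 1e-12;
  const int nz = amps.size();

  NumericMatrix f(n, n_t), rp(n, n_t), rm(n, n_t), fp(n, n_t), fm(n, n_t);
  NumericMatrix sp(has_stall ? n : 1, has_stall ? n_t : 1);
  NumericMatrix sm(has_stall ? n : 1, has_stall ? n_t : 1);

  std::vector<double> f_k(n, 0), fp_k(n, 0), fm_k(n, 0);
  std::vector<double> rp_k(n, 0), rm_k(n, 0), sp_k(n, 0), sm_k(n, 0);
  std::vector<double> Fp(n), Fm(n), adv_p(n), adv_m(n), S(n), I_row(n);

  double N_init = 0, N_coal = 0;
  int k_last = n_t;
  bool bad_f = false;
  int bad_cell = -1;
  double bad_t = 0;

  for (int k = 0; k < n_t - 1 && !bad_f; ++k) {
    double t_k = k * dt;

    // I(x, t): background + gated zone shapes
    for (int i = 0; i < n; ++i) I_row[i] = bg;
    for (int z = 0; z < nz; ++z) {
      if (t_k >= gate_on[z] && t_k <= gate_off[z]) {
        double a = amps[z];
        if (a > 0)
          for (int i = 0; i < n; ++i) I_row[i] += a * shapes(i, z);
      }
    }

    // upwind fluxes and inflow
    for (int i = 0; i < n; ++i) { Fp[i] = v_p[i] * rp_k[i]; Fm[i] = v_m[i] * rm_k[i]; }
    double Fp_in = 0, Fm_in = 0;
    if (bc_mode == 0) { Fp_in = Fp[n - 1]; Fm_in = Fm[0]; }
    else if (bc_mode == 2) {
      Fp_in = v_out * I_left * t_k * std::exp(-I_left * v_out * t_k * t_k / 2.0);
      Fm_in = v_out * I_right * t_k * std::exp(-I_right * v_out * t_k * t_k / 2.0);
    }
    for (int i = 0; i < n; ++i) {
      double up = (i == 0) ? Fp_in : Fp[i - 1];
      adv_p[i] = rp_k[i] - (dt / dx) * (Fp[i] - up);
      double dn = (i == n - 1) ? Fm_in : Fm[i + 1];
      adv_m[i] = rm_k[i] - (dt / dx) * (Fm[i] - dn);
    }

    double sum_S = 0;
    for (int i = 0; i < n; ++i) {
      double one_mf = std::max(1.0 - f_k[i], 0.0);
      double inv_mf = 1.0 / std::max(one_mf, eps);
      double Si = I_row[i] * one_mf;
      S[i] = Si;
      sum_S += Si;

      double C_mm = (v_p[i] + v_m[i]) * rp_k[i] * rm_k[i] * inv_mf;
      double C_ps = 0, C_ms = 0, stall_p = 0, stall_m = 0;
      double rep_p = 0, rep_m = 0, sp_new = 0, sm_new = 0;
      if (has_stall) {
        C_ps = v_p[i] * rp_k[i] * sm_k[i] * inv_mf;
        C_ms = v_m[i] * rm_k[i] * sp_k[i] * inv_mf;
        stall_p = v_p[i] * rp_k[i] / d_def;
        stall_m = v_m[i] * rm_k[i] / d_def;
        double sp_tmp = sp_k[i] + dt * (stall_p - C_ms);
        double sm_tmp = sm_k[i] + dt * (stall_m - C_ps);
        if (std::isfinite(tau)) {
          sp_new = std::max(sp_tmp / (1.0 + dt / tau), 0.0);
          sm_new = std::max(sm_tmp / (1.0 + dt / tau), 0.0);
          rep_p = sp_new / tau;
          rep_m = sm_new / tau;
        } else {
          sp_new = std::max(sp_tmp, 0.0);
          sm_new = std::max(sm_tmp, 0.0);
        }
      }
      double avail_p = adv_p[i] / dt + Si - stall_p + rep_p - C_ps;
      double avail_m = adv_m[i] / dt + Si - stall_m + rep_m - C_ms;
      C_mm = std::min(C_mm, std::max(avail_p, 0.0));
      C_mm = std::min(C_mm, std::max(avail_m, 0.0));

      double rp_new = std::max(adv_p[i] + dt * (Si - C_mm - C_ps - stall_p + rep_p), 0.0);
      double rm_new = std::max(adv_m[i] + dt * (Si - C_mm - C_ms - stall_m + rep_m), 0.0);

      // replication fraction: moving forks only; proportional clamp at 1
      double inc_p = dt * v_p[i] * rp_k[i];
      double inc_m = dt * v_m[i] * rm_k[i];
      double tot = inc_p + inc_m;
      if (f_k[i] + tot > 1.0 && tot > 0) {
        double sc = std::max(1.0 - f_k[i], 0.0) / tot;
        inc_p *= sc; inc_m *= sc;
      }
      fp_k[i] += inc_p;
      fm_k[i] += inc_m;
      f_k[i] = fp_k[i] + fm_k[i];
      if (f_k[i] > 1.0 + 1e-6 && !bad_f) {
        bad_f = true; bad_cell = i + 1; bad_t = t_k + dt;
      }

      N_coal += (C_mm + C_ps + C_ms) * dx * dt;
      rp_k[i] = rp_new; rm_k[i] = rm_new;
      if (has_stall) { sp_k[i] = sp_new; sm_k[i] = sm_new; }
    }
    N_init += sum_S * dx * dt;

    for (int i = 0; i < n; ++i) {
      f(i, k + 1) = f_k[i];
      rp(i, k + 1) = rp_k[i];
      rm(i, k + 1) = rm_k[i];
      fp(i, k + 1) = fp_k[i];
      fm(i, k + 1) = fm_k[i];
      if (has_stall) { sp(i, k + 1) = sp_k[i]; sm(i, k + 1) = sm_k[i]; }
    }

    if (early_stop && (k + 1) % 25 == 0) {
      double mass = 0, max_unrep = 0;
      for (int i = 0; i < n; ++i) {
        mass += rp_k[i] + rm_k[i] + sp_k[i] + sm_k[i];
        max_unrep = std::max(max_unrep, 1.0 - f_k[i]);
      }
      // a vanishing fork population (well below one fork per ensemble, so
      // the end probability is already > 0.999) with replication essentially
      // complete or sources exhausted ends the run
      if (mass * dx < 3e-4 && (sum_S * dx < 1e-10 || max_unrep < 1e-2)) {
        k_last = k + 2;
        break;
      }
    }
  }

  return List::create(
    _["f"] = f, _["rho_plus"] = rp, _["rho_minus"] = rm,
    _["f_plus"] = fp, _["f_minus"] = fm,
    _["rho_stall_plus"] = sp, _["rho_stall_minus"] = sm,
    _["N_init"] = N_init, _["N_coal"] = N_coal,
    _["k_last"] = k_last,
    _["bad_f"] = bad_f, _["bad_cell"] = bad_cell, _["bad_t"] = bad_t
  );
}
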