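#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One explicit diffusion step, reflecting (no-flux) boundaries, applied to
// every row of `field` (rows = variables, columns = grid points).
// lambda = D * dt / dz^2 must satisfy lambda <= 0.5 (checked in R).
static void diffuse_rows(NumericMatrix field, double lambda) {
  const int nv = field.nrow(), nz = field.ncol();
  if (nz < 2 || lambda == 0.0) return;
  std::vector<double> buf(nz);
  for (int i = 0; i < nv; ++i) {
    for (int z = 0; z < nz; ++z) buf[z] = field(i, z);
    field(i, 0) = buf[0] + lambda * (buf[1] - buf[0]);
    for (int z = 1; z < nz - 1; ++z)
      field(i, z) = buf[z] + lambda * (buf[z - 1] - 2.0 * buf[z] + buf[z + 1]);
    field(i, nz - 1) = buf[nz - 1] + lambda * (buf[nz - 2] - buf[nz - 1]);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_diffuse(NumericMatrix field, double lambda, int n_steps) {
  NumericMatrix out = clone(field);
  for (int s = 0; s < n_steps; ++s) diffuse_rows(out, lambda);
  return out;
}

// Asynchronous integrator for the mediator-explicit community model.
//
// Growth/uptake fires every dtau; mediator diffusion every dt_med; cell
// dispersal every dc_cell (both counted from the start of the call, with
// coincident events ordered growth -> mediator diffusion -> cell dispersal).
// Well-mixed dynamics are this same kernel with one grid point and
// dt_med = dc_cell = Inf.
//
// S: n_species x n_z (cells/ml), C: n_mediators x n_z (fmol/ml)
// rho: n_species x n_mediators signed influence (1/hr at saturation)
// beta, alpha: n_mediators x n_species production / consumption rates
// Stops at t_max, or as soon as the spatially averaged total density
// reaches dilth (hit_dilth = TRUE), or falls below ext_total (all_dead).
// [[Rcpp::export]]
List cpp_advance(NumericMatrix S0, NumericMatrix C0,
                 NumericMatrix rho, NumericMatrix beta, NumericMatrix alpha,
                 NumericVector r0,
                 double kY, double ksat, double dtau,
                 double dt_med, double lam_med,
                 double dc_cell, double lam_cell,
                 double t0, double t_max,
                 double dilth, double ext_total,
                 bool infinite_dispersal, bool consumption_saturating,
                 int record_every) {
  NumericMatrix S = clone(S0), C = clone(C0);
  const int nc = S.nrow(), nz = S.ncol(), nm = C.nrow();
  const bool cap = R_finite(kY);
  const long n_growth = (long)std::ceil((t_max - t0) / dtau - 1e-9);
  long done_med = 0, done_cell = 0, g = 0;
  bool hit_dilth = false, all_dead = false;

  std::vector<double> s_old(nc), rate(nc);
  std::vector<NumericMatrix> snapS, snapC;
  std::vector<double> snap_t;

  for (g = 1; g <= n_growth; ++g) {
    double tot_all = 0.0;
    for (int z = 0; z < nz; ++z) {
      double tot = 0.0;
      for (int i = 0; i < nc; ++i) { s_old[i] = S(i, z); tot += s_old[i]; }
      const double crowd = cap ? (1.0 - tot / kY) : 1.0;
      for (int i = 0; i < nc; ++i) {
        double gr = r0[i];
        for (int j = 0; j < nm; ++j) {
          const double rij = rho(i, j);
          if (rij == 0.0) continue;
          const double c = C(j, z);
          gr += (rij > 0.0) ? rij * c / (c + ksat) : rij * c / ksat;
        }
        rate[i] = crowd * gr;
      }
      // mediator production/consumption from pre-update densities
      for (int j = 0; j < nm; ++j) {
        double dc = 0.0;
        const double c = C(j, z);
        const double upt = consumption_saturating ? c / (c + ksat) : 1.0;
        for (int i = 0; i < nc; ++i)
          dc += (beta(j, i) - alpha(j, i) * upt) * s_old[i];
        const double cn = c + dc * dtau;
        C(j, z) = cn > 0.0 ? cn : 0.0;
      }
      for (int i = 0; i < nc; ++i) {
        const double sn = s_old[i] * std::exp(rate[i] * dtau);
        S(i, z) = sn;
        tot_all += sn;
      }
    }
    if (!std::isfinite(tot_all))
      stop("non-finite species density at t = %f hr (growth step %d)",
           t0 + g * dtau, (int)g);

    if (infinite_dispersal) {
      for (int i = 0; i < nc; ++i) {
        double m = 0.0;
        for (int z = 0; z < nz; ++z) m += S(i, z);
        m /= nz;
        for (int z = 0; z < nz; ++z) S(i, z) = m;
      }
    }

    // diffusion events due by the end of this growth step
    if (R_finite(dt_med)) {
      const long due = (long)std::floor(g * dtau / dt_med + 1e-9);
      for (; done_med < due; ++done_med) diffuse_rows(C, lam_med);
    }
    if (!infinite_dispersal && R_finite(dc_cell)) {
      const long due = (long)std::floor(g * dtau / dc_cell + 1e-9);
      for (; done_cell < due; ++done_cell) diffuse_rows(S, lam_cell);
    }

    if (record_every > 0 && g % record_every == 0) {
      snapS.push_back(clone(S));
      snapC.push_back(clone(C));
      snap_t.push_back(t0 + g * dtau);
    }

    const double mean_tot = tot_all / nz;
    if (mean_tot >= dilth) { hit_dilth = true; break; }
    if (mean_tot < ext_total) { all_dead = true; break; }
  }
  if (g > n_growth) g = n_growth;

  List snaps = List::create(_["times"] = wrap(snap_t),
                            _["S"] = wrap(snapS), _["C"] = wrap(snapC));
  return List::create(_["S"] = S, _["C"] = C,
                      _["t"] = t0 + g * dtau,
                      _["n_steps"] = (double)g,
                      _["hit_dilth"] = hit_dilth,
                      _["all_dead"] = all_dead,
                      _["snapshots"] = snaps);
}
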