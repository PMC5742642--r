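#include <Rcpp.h>
using namespace Rcpp;

// Spatial-frequency-domain diffusion reflectance for a semi-infinite medium.
// mutr = mua + musp ; a' = musp/mutr ; mueff' = sqrt(3*mua*mutr + (2*pi*fx)^2)
// Rd = 3*A*a' / ((mueff'/mutr + 1) * (mueff'/mutr + 3*A))
// A is the internal-reflection parameter (computed once in R from n).
static inline double rd_diffusion_scalar(double mua, double musp, double fx,
                                         double A) {
  const double mutr = mua + musp;
  const double ap = musp / mutr;
  const double k = 2.0 * M_PI * fx;
  const double mueff = std::sqrt(3.0 * mua * mutr + k * k);
  const double q = mueff / mutr;
  return 3.0 * A * ap / ((q + 1.0) * (q + 3.0 * A));
}

// [[Rcpp::export]]
NumericVector rd_diffusion_cpp(NumericVector mua, NumericVector musp,
                               NumericVector fx, double A) {
  const R_xlen_t n = std::max(std::max(mua.size(), musp.size()), fx.size());
  NumericVector out(n);
  const R_xlen_t na = mua.size(), ns = musp.size(), nf = fx.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = rd_diffusion_scalar(mua[i % na], musp[i % ns], fx[i % nf], A);
  }
  return out;
}

// White Monte Carlo in a semi-infinite half-space z > 0 with a refractive-
// index mismatched boundary (unpolarized Fresnel reflection). Henyey-
// Greenstein scattering with anisotropy g at rate mus = musp / (1 - g) in the
// near-surface zone (z < z_deep), where the reflectance is sensitive to the
// phase function; below z_deep the walk is diffusive and phase-function
// independent, so the photon switches to isotropic steps at the transport
// rate musp (optical depth is rescaled properly at the zone interface).
// No absorption during transport; each escaped photon reports its exit radius
// rho and total pathlength L so that absorption is applied afterwards by
// reweighting with exp(-mua * L).
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
List white_mc_cpp(double musp, double g, double n_rel, int n_photons,
                  double max_path, double z_deep) {
  std::vector<double> rho_out, path_out;
  rho_out.reserve(n_photons);
  path_out.reserve(n_photons);

  const double mus_fine = musp / (1.0 - g);
  const double cos_crit =
      (n_rel > 1.0) ? std::sqrt(1.0 - 1.0 / (n_rel * n_rel)) : 0.0;
  long n_killed = 0;

  for (int ip = 0; ip < n_photons; ++ip) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;  // launched inward, normal incidence
    double L = 0.0;
    bool alive = true;
    while (alive) {
      double tau = -std::log(unif_rand());  // optical depth to next scatter
      bool scattered_deep = false;
      // propagate, handling boundary and zone crossings within the step
      while (tau > 0.0) {
        const bool deep = z >= z_deep;
        const double mus = deep ? musp : mus_fine;
        double s = tau / mus;
        // distance to the z_deep plane along the current direction
        double s_zone = INFINITY;
        if (!deep && uz > 0.0) s_zone = (z_deep - z) / uz;
        if (deep && uz < 0.0) s_zone = (z_deep - z) / uz;  // uz<0: positive
        if (uz < 0.0) {
          const double s_surf = -z / uz;
          if (s_surf <= s && s_surf <= s_zone) {  // reaches the surface
            x += s_surf * ux;
            y += s_surf * uy;
            L += s_surf;
            z = 0.0;
            tau -= s_surf * mus;
            const double ci = -uz;  // cos(theta_i), incidence from inside
            double R;
            if (ci <= cos_crit) {
              R = 1.0;  // total internal reflection
            } else {
              const double si = std::sqrt(1.0 - ci * ci);
              const double st = n_rel * si;  // Snell, n_in/n_out = n_rel
              const double ct = std::sqrt(1.0 - st * st);
              const double rs = (n_rel * ci - ct) / (n_rel * ci + ct);
              const double rp = (n_rel * ct - ci) / (n_rel * ct + ci);
              R = 0.5 * (rs * rs + rp * rp);
            }
            if (unif_rand() > R) {  // transmitted: escapes
              rho_out.push_back(std::sqrt(x * x + y * y));
              path_out.push_back(L);
              alive = false;
              break;
            }
            uz = -uz;  // reflected back in
            continue;
          }
        }
        if (s_zone < s) {  // crosses the zone interface before scattering
          x += s_zone * ux;
          y += s_zone * uy;
          z += s_zone * uz;
          L += s_zone;
          tau -= s_zone * mus;  // remaining optical depth, re-scaled next pass
          // nudge across the plane so the zone test flips
          z = deep ? z_deep * (1.0 - 1e-12) : z_deep * (1.0 + 1e-12);
          continue;
        }
        x += s * ux;
        y += s * uy;
        z += s * uz;
        L += s;
        tau = 0.0;
        scattered_deep = deep;
      }
      if (!alive) break;
      if (L > max_path) {  // truncation guard; bias ~ exp(-mua*max_path)
        ++n_killed;
        break;
      }
      // scatter: isotropic in the deep zone, Henyey-Greenstein near surface
      double ct;
      if (scattered_deep || g == 0.0) {
        ct = 2.0 * unif_rand() - 1.0;
      } else {
        const double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif_rand());
        ct = (1.0 + g * g - f * f) / (2.0 * g);
      }
      const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      const double phi = 2.0 * M_PI * unif_rand();
      const double cp = std::cos(phi), sp = std::sin(phi);
      if (scattered_deep || std::fabs(uz) > 0.99999) {
        // isotropic result is direction-free; also handles near-vertical
        if (scattered_deep) {
          uz = ct;
          ux = st * cp;
          uy = st * sp;
        } else {
          ux = st * cp;
          uy = st * sp;
          uz = ct * (uz > 0.0 ? 1.0 : -1.0);
        }
      } else {
        const double den = std::sqrt(1.0 - uz * uz);
        const double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        const double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        const double nuz = -st * cp * den + uz * ct;
        ux = nux;
        uy = nuy;
        uz = nuz;
      }
    }
  }
  return List::create(_["rho"] = wrap(rho_out), _["path"] = wrap(path_out),
                      _["n_killed"] = n_killed, _["n_photons"] = n_photons);
}

// Nearest coarse-grid LUT node under the squared-relative-error objective;
// initialization for the Newton refinement.
// [[Rcpp::export]]
List lut_nearest_cpp(NumericVector rd_dc, NumericVector rd_ac,
                     NumericVector tdc, NumericVector tac,
                     NumericVector node_mua, NumericVector node_musp) {
  const R_xlen_t n = rd_dc.size(), m = tdc.size();
  NumericVector mua0(n), musp0(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double best = R_PosInf;
    R_xlen_t bj = 0;
    const double a = rd_dc[i], b = rd_ac[i];
    for (R_xlen_t j = 0; j < m; ++j) {
      const double d1 = (a - tdc[j]) / a, d2 = (b - tac[j]) / b;
      const double d = d1 * d1 + d2 * d2;
      if (d < best) {
        best = d;
        bj = j;
      }
    }
    mua0[i] = node_mua[bj];
    musp0[i] = node_musp[bj];
  }
  return List::create(_["mua"] = mua0, _["musp"] = musp0);
}

// Vectorized damped Newton solve of
//   Rd(0;   mua, musp) = rd_dc
//   Rd(fx;  mua, musp) = rd_ac
// in log-parameter space (positivity-preserving). Starting points come from a
// lookup-table nearest/bilinear search done in R. Non-converged entries are
// returned as NaN so callers can flag them invalid rather than clamp.
// [[Rcpp::export]]
List invert_rd_cpp(NumericVector rd_dc, NumericVector rd_ac, double fx,
                   double A, NumericVector mua0, NumericVector musp0,
                   int max_iter, double tol) {
  const R_xlen_t n = rd_dc.size();
  NumericVector mua_out(n), musp_out(n);
  IntegerVector iters(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double la = std::log(mua0[i]), ls = std::log(musp0[i]);
    bool ok = false;
    int it = 0;
    for (; it < max_iter; ++it) {
      const double mua = std::exp(la), musp = std::exp(ls);
      const double f1 = rd_diffusion_scalar(mua, musp, 0.0, A) - rd_dc[i];
      const double f2 = rd_diffusion_scalar(mua, musp, fx, A) - rd_ac[i];
      if (std::fabs(f1) < tol * rd_dc[i] && std::fabs(f2) < tol * rd_ac[i]) {
        ok = true;
        break;
      }
      const double h = 1e-6;
      const double J11 =
          (rd_diffusion_scalar(mua * std::exp(h), musp, 0.0, A) -
           rd_diffusion_scalar(mua * std::exp(-h), musp, 0.0, A)) /
          (2.0 * h);
      const double J12 =
          (rd_diffusion_scalar(mua, musp * std::exp(h), 0.0, A) -
           rd_diffusion_scalar(mua, musp * std::exp(-h), 0.0, A)) /
          (2.0 * h);
      const double J21 =
          (rd_diffusion_scalar(mua * std::exp(h), musp, fx, A) -
           rd_diffusion_scalar(mua * std::exp(-h), musp, fx, A)) /
          (2.0 * h);
      const double J22 =
          (rd_diffusion_scalar(mua, musp * std::exp(h), fx, A) -
           rd_diffusion_scalar(mua, musp * std::exp(-h), fx, A)) /
          (2.0 * h);
      const double det = J11 * J22 - J12 * J21;
      if (!std::isfinite(det) || std::fabs(det) < 1e-300) break;
      double da = -(J22 * f1 - J12 * f2) / det;
      double ds = -(-J21 * f1 + J11 * f2) / det;
      // damp: cap log-steps to keep iterates in a sane region
      const double cap = 1.0;
      if (da > cap) da = cap; else if (da < -cap) da = -cap;
      if (ds > cap) ds = cap; else if (ds < -cap) ds = -cap;
      la += da;
      ls += ds;
    }
    if (ok) {
      mua_out[i] = std::exp(la);
      musp_out[i] = std::exp(ls);
    } else {
      mua_out[i] = NA_REAL;
      musp_out[i] = NA_REAL;
    }
    iters[i] = it;
  }
  return List::create(_["mua"] = mua_out, _["musp"] = musp_out,
                      _["iterations"] = iters);
}

// Harmonic resummation renderer core: given per-pixel optical properties and a
// set of harmonic spatial frequencies with column-wise carrier values, build
//   image[r, c] = power * ( a0 * Rd(0)[px] + sum_h amp_h * Rd(fx_h)[px] * carrier_h[c] )
// carriers is (n_harmonics x ncol), amplitudes length n_harmonics.
// [[Rcpp::export]]
NumericMatrix render_harmonics_cpp(NumericVector mua, NumericVector musp,
                                   int nrow, int ncol, double A, double power,
                                   double a0, NumericVector fx_h,
                                   NumericVector amp_h, NumericMatrix carriers) {
  NumericMatrix img(nrow, ncol);
  const int nh = fx_h.size();
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      const R_xlen_t px = (R_xlen_t)c * nrow + r;  // column-major like R
      const double ma = mua[px], ms = musp[px];
      double v = a0 * rd_diffusion_scalar(ma, ms, 0.0, A);
      for (int h = 0; h < nh; ++h) {
        v += amp_h[h] * rd_diffusion_scalar(ma, ms, fx_h[h], A) * carriers(h, c);
      }
      img(r, c) = power * v;
    }
  }
  return img;
}
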