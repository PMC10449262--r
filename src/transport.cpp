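// Weighted-photon Monte Carlo transport through horizontal layered media
// (MCML-style): exponential step sampling, Henyey-Greenstein scattering,
// fractional absorption, Fresnel reflection/refraction at layer
// boundaries, Russian roulette.  Detection gates photons leaving the top
// surface on exit radius and on the acceptance cone of the numerical
// aperture, recording the cumulative optical path and residual weight of
// each detected photon.  Uses R's RNG so runs are reproducible under
// set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double hg_cost(double g, double xi) {
  if (std::fabs(g) < 1e-12) return 2.0 * xi - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * xi);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// Unpolarized Fresnel reflectance for incidence cosine ci (>=0), indices
// ni -> nt; also returns the transmitted cosine via *ct.
static double fresnel(double ni, double nt, double ci, double *ct) {
  if (ci > 1.0) ci = 1.0;
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = ni * si / nt;
  if (st >= 1.0) { *ct = 0.0; return 1.0; }       // total internal reflection
  double c_t = std::sqrt(std::max(0.0, 1.0 - st * st));
  *ct = c_t;
  if (si < 1e-12) {                                // normal incidence
    double r = (ni - nt) / (ni + nt);
    return r * r;
  }
  double rs = (ni * ci - nt * c_t) / (ni * ci + nt * c_t);
  double rp = (nt * ci - ni * c_t) / (nt * ci + ni * c_t);
  return 0.5 * (rs * rs + rp * rp);
}

static inline double hg_pdf(double g, double cost) {
  // phase function per steradian, normalized over the sphere
  double d = 1.0 + g * g - 2.0 * g * cost;
  return (1.0 - g * g) / (4.0 * M_PI * d * std::sqrt(d));
}

// [[Rcpp::export]]
List mc_transport_cpp(NumericVector thickness, NumericVector n_idx,
                      NumericVector mua, NumericVector mus,
                      NumericVector g_hg, int n_photons,
                      double det_radius, double det_na,
                      double roulette_thresh, double roulette_surv,
                      bool local_est, double opl_bin, double opl_max) {
  const int nl = thickness.size();
  std::vector<double> zb(nl + 1);
  zb[0] = 0.0;
  for (int i = 0; i < nl; ++i) zb[i + 1] = zb[i] + thickness[i];
  const double n_air = 1.0;
  const double cos_acc = std::sqrt(std::max(0.0, 1.0 - det_na * det_na));
  const long max_steps = 10000000L;

  // local-estimator bookkeeping: acceptance solid angle inside the top
  // layer (Snell-mapped from the NA cone in air) and the normal-incidence
  // escape transmission through each interface above a given layer
  std::vector<double> esc_att(nl), esc_opl(nl), esc_T(nl);
  {
    double rsp_top = (n_idx[0] - n_air) / (n_idx[0] + n_air);
    double T = 1.0 - rsp_top * rsp_top;
    double att = 0.0, opl = 0.0;
    for (int l = 0; l < nl; ++l) {
      if (l > 0) {
        double r = (n_idx[l] - n_idx[l - 1]) / (n_idx[l] + n_idx[l - 1]);
        T *= 1.0 - r * r;
        att += (mua[l - 1] + mus[l - 1]) * thickness[l - 1];
        opl += n_idx[l - 1] * thickness[l - 1];
      }
      esc_att[l] = att;   // attenuation accumulated above layer l's top
      esc_opl[l] = opl;   // optical path accumulated above layer l's top
      esc_T[l] = T;
    }
  }
  int nbin = 0;
  if (local_est) nbin = (int)std::ceil(opl_max / opl_bin) + 1;
  std::vector<double> bin_w(nbin, 0.0);

  std::vector<double> det_opl, det_w;
  double specular = 0.0, reflected = 0.0, transmitted = 0.0, absorbed = 0.0;

  RNGScope scope;
  for (int ph = 0; ph < n_photons; ++ph) {
    // launch: pencil beam, normal incidence; specular loss at entry
    double rsp = (n_air - n_idx[0]) / (n_air + n_idx[0]);
    rsp *= rsp;
    double w = 1.0 - rsp;
    specular += rsp;
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    int lay = 0;
    double opl = 0.0;
    double s_dimless = 0.0;                        // leftover dimensionless step
    bool alive = true;
    long steps = 0;

    while (alive) {
      if (++steps > max_steps) { absorbed += w; break; }
      double mut = mua[lay] + mus[lay];
      if (s_dimless <= 0.0)
        s_dimless = -std::log(std::max(unif_rand(), 1e-300));
      double s = (mut > 0.0) ? s_dimless / mut : 1e12;

      // distance to the layer boundary along uz
      double db = 1e12;
      int to = 0;                                  // -1 up, +1 down
      if (uz > 1e-12)      { db = (zb[lay + 1] - z) / uz; to = 1; }
      else if (uz < -1e-12) { db = (zb[lay] - z) / uz;     to = -1; }

      if (db <= s) {
        // move to the boundary
        x += ux * db; y += uy * db; z += uz * db;
        opl += n_idx[lay] * db;
        s_dimless -= db * mut;
        if (s_dimless < 0.0) s_dimless = 0.0;
        double ci = std::fabs(uz);
        double nt = (to < 0) ? (lay == 0 ? n_air : n_idx[lay - 1])
                             : (lay == nl - 1 ? n_air : n_idx[lay + 1]);
        double ct;
        double rf = fresnel(n_idx[lay], nt, ci, &ct);
        if (unif_rand() < rf) {
          uz = -uz;                                // internal reflection
          z = (to < 0) ? zb[lay] : zb[lay + 1];
        } else {
          // refract
          double scale = (ci > 1e-12) ? n_idx[lay] / nt : 1.0;
          ux *= scale; uy *= scale;
          uz = (to < 0) ? -ct : ct;
          // renormalize against rounding
          double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
          ux /= nrm; uy /= nrm; uz /= nrm;
          if (to < 0 && lay == 0) {
            reflected += w;                        // escaped through the top
            double r = std::sqrt(x * x + y * y);
            if (!local_est && r <= det_radius && std::fabs(uz) >= cos_acc) {
              det_opl.push_back(opl);
              det_w.push_back(w);
            }
            alive = false;
          } else if (to > 0 && lay == nl - 1) {
            transmitted += w;                      // escaped through the bottom
            alive = false;
          } else {
            lay += to;
            z = (to < 0) ? zb[lay + 1] : zb[lay];
          }
        }
        continue;
      }

      // full step inside the layer
      x += ux * s; y += uy * s; z += uz * s;
      opl += n_idx[lay] * s;
      s_dimless = 0.0;
      if (mut > 0.0) {
        double da = w * mua[lay] / mut;
        absorbed += da;
        w -= da;
      }
      // local (point-detector) estimate: expected weight scattered from
      // this event straight up into the acceptance cone and ballistically
      // out of the sample.  Only down-going photons are tallied -- the
      // single-backscatter return that forms the coherence-gated signal;
      // the up-going forward-scatter channel (multiple-scattering
      // background) has phase-function values orders of magnitude larger
      // and would swamp the path-resolved estimate with rare spikes.
      // Virtual contribution -- the analog weight ledger is untouched.
      if (local_est && mus[lay] > 0.0 && uz > 0.0) {
        double r2 = x * x + y * y;
        if (r2 <= det_radius * det_radius) {
          double sin_l = det_na / n_idx[lay];
          if (sin_l < 1.0) {
            double dOmega =
              2.0 * M_PI * (1.0 - std::sqrt(1.0 - sin_l * sin_l));
            double zin = z - zb[lay];
            double att = esc_att[lay] + (mua[lay] + mus[lay]) * zin;
            double c = w * hg_pdf(g_hg[lay], -uz) * dOmega *
                       std::exp(-att) * esc_T[lay];
            double dzt = opl + esc_opl[lay] + n_idx[lay] * zin;
            int bi = (int)std::floor(dzt / opl_bin);
            if (bi >= 0 && bi < nbin) bin_w[bi] += c;
          }
        }
      }
      // scatter (Henyey-Greenstein)
      double cost = hg_cost(g_hg[lay], unif_rand());
      double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
      double phi = 2.0 * M_PI * unif_rand();
      double cosp = std::cos(phi), sinp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = sint * cosp;
        uy = sint * sinp;
        uz = (uz >= 0.0) ? cost : -cost;
      } else {
        double tmp = std::sqrt(1.0 - uz * uz);
        double nux = sint * (ux * uz * cosp - uy * sinp) / tmp + ux * cost;
        double nuy = sint * (uy * uz * cosp + ux * sinp) / tmp + uy * cost;
        double nuz = -sint * cosp * tmp + uz * cost;
        ux = nux; uy = nuy; uz = nuz;
      }
      // Russian roulette
      if (w < roulette_thresh) {
        if (unif_rand() < roulette_surv) {
          absorbed -= w * (1.0 - roulette_surv) / roulette_surv;
          w /= roulette_surv;
        } else {
          absorbed += w;
          alive = false;
        }
      }
    }
  }

  if (local_est) {
    for (int b = 0; b < nbin; ++b) {
      if (bin_w[b] > 0.0) {
        det_opl.push_back((b + 0.5) * opl_bin);
        det_w.push_back(bin_w[b]);
      }
    }
  }

  return List::create(
    _["delta_z"] = NumericVector(det_opl.begin(), det_opl.end()),
    _["weight"] = NumericVector(det_w.begin(), det_w.end()),
    _["specular"] = specular,
    _["reflected"] = reflected,
    _["transmitted"] = transmitted,
    _["absorbed"] = absorbed);
}

// Sum Gaussian coherence envelopes of detected photons onto a grid given
// in the same (optical-path) units as delta_z.
// [[Rcpp::export]]
NumericVector synth_envelope_cpp(NumericVector delta_z, NumericVector weight,
                                 NumericVector z_opt, double l_coh,
                                 double i0) {
  const int n = z_opt.size();
  NumericVector out(n);
  if (delta_z.size() == 0 || n == 0) return out;
  const double dz = (n > 1) ? (z_opt[1] - z_opt[0]) : l_coh;
  const double z0 = z_opt[0];
  const int halo = (int)std::ceil(6.0 * l_coh / std::fabs(dz)) + 1;
  for (int i = 0; i < delta_z.size(); ++i) {
    int c = (int)std::floor((delta_z[i] - z0) / dz);
    int lo = std::max(0, c - halo), hi = std::min(n - 1, c + halo);
    for (int j = lo; j <= hi; ++j) {
      double u = (z_opt[j] - delta_z[i]) / l_coh;
      out[j] += i0 * weight[i] * std::exp(-u * u);
    }
  }
  return out;
}
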