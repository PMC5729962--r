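// Monte Carlo photon-packet transport in a semi-infinite homogeneous medium,
// MCML-style: exponential step sampling, weighted absorption with Russian
// roulette, Henyey-Greenstein scattering, Fresnel reflection/refraction at
// the z = 0 boundary. Units: cm and cm^-1 throughout. z grows into the
// tissue. The RNG is std::mt19937_64 seeded directly from the caller so runs
// are bit-reproducible and independent of R's RNG state.
#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

namespace {

constexpr double ROULETTE_THRESHOLD = 1e-4;
constexpr double ROULETTE_SURVIVAL = 0.1;

struct Rng {
  std::mt19937_64 eng;
  explicit Rng(uint64_t seed) : eng(seed) {}
  // uniform in (0, 1]: safe for -log()
  double open() { return (eng() >> 11) * (1.0 / 9007199254740992.0) + 5.421010862427522e-20; }
  // uniform in [0, 1)
  double unit() { return (eng() >> 11) * (1.0 / 9007199254740992.0); }
};

double sample_hg_cos(Rng& rng, double g) {
  if (std::fabs(g) < 1e-6) return 2.0 * rng.unit() - 1.0;
  double frac = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.unit());
  double ct = (1.0 + g * g - frac * frac) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

void scatter(Rng& rng, double g, double& ux, double& uy, double& uz) {
  double ct = sample_hg_cos(rng, g);
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double psi = 2.0 * M_PI * rng.unit();
  double cp = std::cos(psi), sp = std::sin(psi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double denom = std::sqrt(1.0 - uz * uz);
    double nux = st * (ux * uz * cp - uy * sp) / denom + ux * ct;
    double nuy = st * (uy * uz * cp + ux * sp) / denom + uy * ct;
    double nuz = -st * cp * denom + uz * ct;
    ux = nux; uy = nuy; uz = nuz;
  }
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

// unpolarized Fresnel reflectance for a photon hitting z = 0 from inside
// (n1 = tissue) toward the coupling medium (n2). cosi > 0.
double fresnel_r(double n1, double n2, double cosi, double& cost_out) {
  double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
  double sint = n1 / n2 * sini;
  if (sint >= 1.0) { cost_out = 0.0; return 1.0; } // total internal reflection
  double cost = std::sqrt(1.0 - sint * sint);
  cost_out = cost;
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

// fraction of the circle of radius d centred at the launch point that falls
// inside the detector disc (radius det_r, at in-plane distance L from the
// launch point). Exact in expectation by azimuthal symmetry of transport
// about the launch axis; the standard ring-detector variance reduction.
double arc_fraction(double d, double L, double det_r) {
  if (L < 1e-12) return d <= det_r ? 1.0 : 0.0;
  if (d + L <= det_r) return 1.0;
  if (d >= L + det_r || L >= d + det_r) return 0.0;
  double arg = (d * d + L * L - det_r * det_r) / (2.0 * d * L);
  if (arg > 1.0) arg = 1.0;
  if (arg < -1.0) arg = -1.0;
  return std::acos(arg) / M_PI;
}

struct Tallies {
  double specular = 0, absorbed = 0, escaped = 0, killed = 0, lost = 0;
  double collected = 0, collected_sq = 0;
};

} // namespace

// Fiber-probe reflectance: launch inside the source fiber footprint within
// its NA acceptance cone; score photons escaping through the surface by the
// arc-fraction overlap with the detector fiber footprint, gated on the NA
// acceptance condition n_tissue * sin(theta_exit_in_tissue) <= NA.
// [[Rcpp::export]]
List cpp_mc_probe(double mua, double mus, double g, double n_tissue,
                  double n_above, double src_r, double det_r, double sep,
                  double na, int n_photons, double seed,
                  int max_steps = 200000) {
  if (mus <= 0.0) stop("mus must be positive (musp = 0 cells are handled by the caller)");
  Rng rng(static_cast<uint64_t>(seed));
  Tallies t;
  const double mut = mua + mus;
  const double albedo_absorb = mua / mut;
  double rsp = (n_above - n_tissue) / (n_above + n_tissue);
  rsp = rsp * rsp;
  double sin_max = na / n_tissue;
  if (sin_max > 1.0) sin_max = 1.0;
  const double cos_min = std::sqrt(1.0 - sin_max * sin_max);

  for (int i = 0; i < n_photons; ++i) {
    // launch position uniform on the source fiber disc (centred at origin)
    double rr = src_r * std::sqrt(rng.unit());
    double phi = 2.0 * M_PI * rng.unit();
    double x0 = rr * std::cos(phi), y0 = rr * std::sin(phi);
    double x = x0, y = y0, z = 0.0;
    // direction uniform over solid angle within the acceptance cone
    double ct = 1.0 - rng.unit() * (1.0 - cos_min);
    double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
    double psi = 2.0 * M_PI * rng.unit();
    double ux = st * std::cos(psi), uy = st * std::sin(psi), uz = ct;
    double w = 1.0 - rsp;
    t.specular += rsp;

    bool alive = true;
    int steps = 0;
    while (alive) {
      if (++steps > max_steps) { t.lost += w; break; }
      double s = -std::log(rng.open()) / mut;
      // propagate, handling (at most one) boundary encounter per step
      while (s > 0.0) {
        if (uz < 0.0 && z + uz * s < 0.0) {
          double s1 = -z / uz;
          x += ux * s1; y += uy * s1; z = 0.0;
          s -= s1;
          double cosi = -uz, cost;
          double R = fresnel_r(n_tissue, n_above, cosi, cost);
          if (rng.unit() < R) {
            uz = -uz; // internal reflection, finish the step going down
          } else {
            // escapes through the surface
            t.escaped += w;
            double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
            if (n_tissue * sini <= na) {
              double d = std::hypot(x - x0, y - y0);
              double L = std::hypot(sep - x0, y0);
              double f = arc_fraction(d, L, det_r);
              if (f > 0.0) {
                t.collected += w * f;
                t.collected_sq += (w * f) * (w * f);
              }
            }
            alive = false;
            s = 0.0;
          }
        } else {
          x += ux * s; y += uy * s; z += uz * s;
          s = 0.0;
        }
      }
      if (!alive) break;
      double dw = w * albedo_absorb;
      t.absorbed += dw;
      w -= dw;
      if (w < ROULETTE_THRESHOLD) {
        if (rng.unit() < ROULETTE_SURVIVAL) {
          w /= ROULETTE_SURVIVAL;
        } else {
          t.killed += w;
          break;
        }
      }
      scatter(rng, g, ux, uy, uz);
    }
  }

  return List::create(
    _["collected"] = t.collected, _["collected_sq"] = t.collected_sq,
    _["escaped"] = t.escaped, _["absorbed"] = t.absorbed,
    _["specular"] = t.specular, _["killed"] = t.killed, _["lost"] = t.lost,
    _["n_photons"] = n_photons);
}

// Radially resolved diffuse reflectance Rd(r) for a normally incident pencil
// beam (the configuration the diffusion-approximation oracle describes).
// ring_weight[i] collects the weight escaping with exit radius in
// [r_edges[i], r_edges[i+1]).
// [[Rcpp::export]]
List cpp_mc_radial(double mua, double mus, double g, double n_tissue,
                   double n_above, int n_photons, double seed,
                   NumericVector r_edges, int max_steps = 200000) {
  if (mus <= 0.0) stop("mus must be positive");
  Rng rng(static_cast<uint64_t>(seed));
  const double mut = mua + mus;
  const double albedo_absorb = mua / mut;
  double rsp = (n_above - n_tissue) / (n_above + n_tissue);
  rsp = rsp * rsp;
  int nr = r_edges.size() - 1;
  NumericVector ring(nr);
  Tallies t;

  for (int i = 0; i < n_photons; ++i) {
    double x = 0, y = 0, z = 0;
    double ux = 0, uy = 0, uz = 1.0;
    double w = 1.0 - rsp;
    t.specular += rsp;
    bool alive = true;
    int steps = 0;
    while (alive) {
      if (++steps > max_steps) { t.lost += w; break; }
      double s = -std::log(rng.open()) / mut;
      while (s > 0.0) {
        if (uz < 0.0 && z + uz * s < 0.0) {
          double s1 = -z / uz;
          x += ux * s1; y += uy * s1; z = 0.0;
          s -= s1;
          double cosi = -uz, cost;
          double R = fresnel_r(n_tissue, n_above, cosi, cost);
          double we = w * (1.0 - R);
          if (we > 0.0) {
            t.escaped += we;
            double r = std::hypot(x, y);
            for (int k = 0; k < nr; ++k) {
              if (r >= r_edges[k] && r < r_edges[k + 1]) { ring[k] += we; break; }
            }
          }
          w *= R;
          uz = -uz;
          if (w <= 0.0) { alive = false; s = 0.0; }
        } else {
          x += ux * s; y += uy * s; z += uz * s;
          s = 0.0;
        }
      }
      if (!alive) break;
      double dw = w * albedo_absorb;
      t.absorbed += dw;
      w -= dw;
      if (w < ROULETTE_THRESHOLD) {
        if (rng.unit() < ROULETTE_SURVIVAL) {
          w /= ROULETTE_SURVIVAL;
        } else {
          t.killed += w;
          break;
        }
      }
      scatter(rng, g, ux, uy, uz);
    }
  }

  return List::create(
    _["ring_weight"] = ring, _["escaped"] = t.escaped,
    _["absorbed"] = t.absorbed, _["specular"] = t.specular,
    _["killed"] = t.killed, _["lost"] = t.lost,
    _["n_photons"] = n_photons);
}

// Raw Henyey-Greenstein deflection cosines (for distributional checks).
// [[Rcpp::export]]
NumericVector cpp_hg_sample(int n, double g, double seed) {
  Rng rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_hg_cos(rng, g);
  return out;
}
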