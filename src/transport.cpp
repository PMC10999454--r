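// Weighted-photon Monte Carlo transport through a layered slab stack with an
// embedded cylinder (bone), in transmittance or reflectance PPG geometry.
// Scheme: MCML-style hop-drop-spin with implicit capture, Henyey-Greenstein
// scattering, unpolarised Fresnel boundaries at the outer surfaces (interior
// interfaces are index-matched) and Russian roulette termination.
//
// Every photon owns a counter-based RNG stream seeded from (seed, photon
// index), so photon i's history is reproducible independent of batch size.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

constexpr double kEps = 1e-9;        // boundary nudge, mm
constexpr double kTwoPi = 6.283185307179586476925286766559;

// ---- RNG: xoshiro256++ with splitmix64 seeding --------------------------

inline uint64_t splitmix64(uint64_t& s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s[4];

  void seed(uint64_t base, uint64_t stream) {
    uint64_t sm = base ^ (0x9E3779B97F4A7C15ULL * (stream + 1));
    s[0] = splitmix64(sm);
    s[1] = splitmix64(sm);
    s[2] = splitmix64(sm);
    s[3] = splitmix64(sm);
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on [0, 1)
  inline double u_co() { return (next() >> 11) * 0x1.0p-53; }
  // uniform on (0, 1] (safe for log())
  inline double u_oc() { return ((next() >> 11) + 1) * 0x1.0p-53; }
};

// ---- elementary transport rules -----------------------------------------

inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

double fresnel_unpolarised(double n1, double n2, double cos_i) {
  cos_i = clampd(cos_i, 0.0, 1.0);
  if (n1 == n2) return 0.0;
  double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  double sin_t = n1 / n2 * sin_i;
  if (sin_t >= 1.0) return 1.0;  // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t * sin_t);
  double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
  double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

double hg_cos(double g, double xi) {
  if (std::fabs(g) < 1e-6) return 2.0 * xi - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * xi);
  double ct = (1.0 + g * g - f * f) / (2.0 * g);
  return clampd(ct, -1.0, 1.0);
}

// Rotate a unit direction by polar angle acos(ct) and azimuth phi.
void spin(double& ux, double& uy, double& uz, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  double nx, ny, nz;
  if (std::fabs(uz) > 0.99999) {
    nx = st * cp;
    ny = st * sp;
    nz = (uz >= 0.0 ? ct : -ct);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    nz = -st * cp * den + uz * ct;
  }
  double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
  ux = nx / norm;
  uy = ny / norm;
  uz = nz / norm;
}

// Positive distance to the bone cylinder surface (axis along y at x = 0,
// z = zc) along the current direction; +Inf if never hit. Valid whether the
// photon is inside or outside the cylinder.
double cylinder_distance(double x, double z, double ux, double uz,
                         double zc, double r) {
  double a = ux * ux + uz * uz;
  if (a < 1e-20) return R_PosInf;
  double px = x, pz = z - zc;
  double b = px * ux + pz * uz;
  double c = px * px + pz * pz - r * r;
  double disc = b * b - a * c;
  if (disc <= 0.0) return R_PosInf;
  double sq = std::sqrt(disc);
  double t1 = (-b - sq) / a;
  if (t1 > kEps) return t1;
  double t2 = (-b + sq) / a;
  if (t2 > kEps) return t2;
  return R_PosInf;
}

}  // namespace

// ---- exported elementary operations (unit-test surface; the engine calls
// ---- the same internals) -------------------------------------------------

//' @rdname transport-kernels
//' @export
// [[Rcpp::export]]
NumericVector sample_step(NumericVector xi, double mu_t) {
  if (!(mu_t > 0)) stop("`mu_t` must be positive (invalid medium)");
  NumericVector out(xi.size());
  for (R_xlen_t i = 0; i < xi.size(); ++i) {
    if (!(xi[i] > 0.0 && xi[i] <= 1.0))
      stop("`xi` must lie in (0, 1]");
    out[i] = -std::log(xi[i]) / mu_t;
  }
  return out;
}

//' @rdname transport-kernels
//' @export
// [[Rcpp::export]]
NumericVector hg_cos_theta(double g, NumericVector xi) {
  if (g < -1.0 || g > 1.0) stop("`g` must lie in [-1, 1]");
  NumericVector out(xi.size());
  for (R_xlen_t i = 0; i < xi.size(); ++i) out[i] = hg_cos(g, xi[i]);
  return out;
}

//' @rdname transport-kernels
//' @export
// [[Rcpp::export]]
NumericVector update_direction(NumericVector u, double cos_theta, double phi) {
  if (u.size() != 3) stop("`u` must be a direction-cosine vector of length 3");
  double ux = u[0], uy = u[1], uz = u[2];
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  if (std::fabs(norm - 1.0) > 1e-6) stop("`u` must be a unit vector");
  ux /= norm; uy /= norm; uz /= norm;
  spin(ux, uy, uz, clampd(cos_theta, -1.0, 1.0), phi);
  return NumericVector::create(ux, uy, uz);
}

//' @rdname transport-kernels
//' @export
// [[Rcpp::export]]
NumericVector fresnel_reflectance(double n1, double n2, NumericVector cos_i) {
  if (n1 < 1.0 || n2 < 1.0) stop("refractive indices must be >= 1");
  NumericVector out(cos_i.size());
  for (R_xlen_t i = 0; i < cos_i.size(); ++i) {
    if (cos_i[i] < 0.0 || cos_i[i] > 1.0)
      stop("`cos_i` must lie in [0, 1]");
    out[i] = fresnel_unpolarised(n1, n2, cos_i[i]);
  }
  return out;
}

//' @rdname transport-kernels
//' @export
// [[Rcpp::export]]
NumericVector roulette_weight(NumericVector w, NumericVector xi,
                              double threshold, double survival_factor) {
  if (survival_factor <= 1.0) stop("`survival_factor` must exceed 1");
  if (w.size() != xi.size()) stop("`w` and `xi` must have equal length");
  NumericVector out(w.size());
  for (R_xlen_t i = 0; i < w.size(); ++i) {
    if (w[i] >= threshold) {
      out[i] = w[i];
    } else if (xi[i] < 1.0 / survival_factor) {
      out[i] = w[i] * survival_factor;
    } else {
      out[i] = 0.0;
    }
  }
  return out;
}

//' @rdname transport-kernels
//' @export
// [[Rcpp::export]]
DataFrame launch_positions(int n, double seed, double beam_sigma) {
  // the exact launch draw the engine performs for photons 0..n-1
  NumericVector x(n), y(n), z(n), uz(n);
  Rng rng;
  const uint64_t base = (uint64_t)(int64_t)seed;
  for (int i = 0; i < n; ++i) {
    rng.seed(base, (uint64_t)i);
    double amp = beam_sigma * std::sqrt(-2.0 * std::log(rng.u_oc()));
    double ang = kTwoPi * rng.u_co();
    x[i] = amp * std::cos(ang);
    y[i] = amp * std::sin(ang);
    z[i] = 0.0;
    uz[i] = 1.0;
  }
  return DataFrame::create(_["x"] = x, _["y"] = y, _["z"] = z, _["uz"] = uz);
}

// ---- full engine ---------------------------------------------------------

// [[Rcpp::export]]
List rt_run(int n_photons, double seed,
            NumericVector z_edges, IntegerVector slab_region,
            int muscle_slab, int bone_region, double bone_zc,
            double bone_radius,
            NumericVector mua, NumericVector mus, NumericVector g,
            double n_tissue, double n_ambient,
            int mode,  // 0 = transmittance, 1 = reflectance
            double sds, double det_radius, double beam_sigma,
            double lateral_max, double roulette_threshold,
            double roulette_m, bool record_paths, int max_paths) {
  const int nslab = slab_region.size();
  const int nreg = mua.size();
  if (z_edges.size() != nslab + 1) stop("z_edges/slab_region length mismatch");
  for (int k = 0; k < nreg; ++k) {
    if (mua[k] < 0 || mus[k] < 0 || mua[k] + mus[k] <= 0)
      stop("every region needs mua >= 0, mus >= 0, mua + mus > 0");
  }
  const double z_top = z_edges[0], z_bot = z_edges[nslab];
  const double lat2 = lateral_max * lateral_max;
  const double det2 = det_radius * det_radius;
  const uint64_t base_seed = (uint64_t)(int64_t)seed;

  // specular reflection at orthogonal incidence, deducted at launch
  const double r_spec = fresnel_unpolarised(n_ambient, n_tissue, 1.0);
  const double w0 = 1.0 - r_spec;

  std::vector<double> absorbed(nreg, 0.0), det_absorbed(nreg, 0.0);
  std::vector<double> dep(nreg);
  double w_detected = 0.0, escaped = 0.0, lateral = 0.0, roulette_net = 0.0;
  long n_detected = 0;

  std::vector<double> rec_x, rec_y, rec_ux, rec_uy, rec_uz, rec_w, rec_L,
      rec_zmax;
  List paths;
  int n_paths = 0;
  if (record_paths) paths = List(std::min(n_photons, max_paths));

  Rng rng;
  std::vector<double> verts;  // interleaved (x, z) interaction vertices

  for (int i = 0; i < n_photons; ++i) {
    if ((i & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    rng.seed(base_seed, (uint64_t)i);

    // launch: 2-D Gaussian beam, orthogonal incidence
    double amp = beam_sigma * std::sqrt(-2.0 * std::log(rng.u_oc()));
    double ang = kTwoPi * rng.u_co();
    double x = amp * std::cos(ang), y = amp * std::sin(ang), z = z_top;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = w0, L = 0.0, zmax = z_top;
    std::fill(dep.begin(), dep.end(), 0.0);
    if (record_paths) verts.clear();

    int slab = 0;
    bool alive = true;
    int fate = -1;             // 0 detected, 1 escaped, 2 lateral, 3 roulette
    double exit_x = 0, exit_y = 0, exit_ux = 0, exit_uy = 0, exit_uz = 0;
    bool exit_top = false;

    while (alive) {
      // ---- hop: propagate one sampled optical depth through the geometry
      double tau = -std::log(rng.u_oc());
      while (alive && tau > 0.0) {
        int reg = slab_region[slab];
        if (slab == muscle_slab) {
          double dx = x, dz = z - bone_zc;
          if (dx * dx + dz * dz < bone_radius * bone_radius)
            reg = bone_region;
        }
        double mut = mua[reg] + mus[reg];
        double s_geo = tau / mut;

        double d_plane = R_PosInf;
        if (uz > 0.0)
          d_plane = (z_edges[slab + 1] - z) / uz;
        else if (uz < 0.0)
          d_plane = (z_edges[slab] - z) / uz;
        double d_b = d_plane;
        int hit = 1;
        if (slab == muscle_slab) {
          double d_cyl = cylinder_distance(x, z, ux, uz, bone_zc, bone_radius);
          if (d_cyl < d_b) { d_b = d_cyl; hit = 2; }
        }

        if (s_geo < d_b) {
          x += s_geo * ux; y += s_geo * uy; z += s_geo * uz;
          L += s_geo;
          tau = 0.0;
        } else {
          x += d_b * ux; y += d_b * uy; z += d_b * uz;
          L += d_b;
          tau -= d_b * mut;
          bool at_top = (hit == 1 && slab == 0 && uz < 0.0);
          bool at_bot = (hit == 1 && slab == nslab - 1 && uz > 0.0);
          if (at_top || at_bot) {
            z = at_top ? z_top : z_bot;
            double ci = std::fabs(uz);
            if (rng.u_co() < fresnel_unpolarised(n_tissue, n_ambient, ci)) {
              uz = -uz;  // internally reflected, keep the remaining depth
            } else {
              // refract out (Snell); all exit angles are accepted downstream
              double scale = n_tissue / n_ambient;
              double sx = ux * scale, sy = uy * scale;
              double s2 = sx * sx + sy * sy;
              double cz = std::sqrt(std::max(0.0, 1.0 - s2));
              exit_x = x; exit_y = y;
              exit_ux = sx; exit_uy = sy;
              exit_uz = (uz > 0.0 ? cz : -cz);
              exit_top = at_top;
              alive = false;
              fate = 1;  // provisionally escaped; detection resolved below
            }
          } else {
            // interior boundary (index-matched): nudge across, re-locate
            x += kEps * ux; y += kEps * uy; z += kEps * uz;
            while (slab < nslab - 1 && z >= z_edges[slab + 1]) ++slab;
            while (slab > 0 && z < z_edges[slab]) --slab;
          }
        }
        if (z > zmax) zmax = z;
        if (alive && x * x + y * y > lat2) {
          lateral += w;
          alive = false;
          fate = 2;
        }
      }
      if (!alive) break;

      // ---- drop: implicit capture
      int reg = slab_region[slab];
      if (slab == muscle_slab) {
        double dx = x, dz = z - bone_zc;
        if (dx * dx + dz * dz < bone_radius * bone_radius) reg = bone_region;
      }
      double mut = mua[reg] + mus[reg];
      double dw = w * mua[reg] / mut;
      absorbed[reg] += dw;
      dep[reg] += dw;
      w -= dw;
      if (record_paths) { verts.push_back(x); verts.push_back(z); }
      if (w <= 0.0) { fate = 3; break; }  // pure absorber: packet exhausted

      // ---- spin
      double ct = hg_cos(g[reg], rng.u_co());
      double phi = kTwoPi * rng.u_co();
      spin(ux, uy, uz, ct, phi);

      // ---- roulette
      if (w < roulette_threshold) {
        if (rng.u_co() < 1.0 / roulette_m) {
          roulette_net -= w * (roulette_m - 1.0);
          w *= roulette_m;
        } else {
          roulette_net += w;
          fate = 3;
          break;
        }
      }
    }

    if (fate == 1) {
      // exited through an outer surface: detected or escaped-undetected?
      bool detected = false;
      if (mode == 0 && !exit_top) {
        detected = (exit_x * exit_x + exit_y * exit_y) <= det2;
      } else if (mode == 1 && exit_top) {
        double dx = exit_x - sds;
        detected = (dx * dx + exit_y * exit_y) <= det2;
      }
      if (detected) {
        ++n_detected;
        w_detected += w;
        for (int k = 0; k < nreg; ++k) det_absorbed[k] += dep[k];
        rec_x.push_back(exit_x);
        rec_y.push_back(exit_y);
        rec_ux.push_back(exit_ux);
        rec_uy.push_back(exit_uy);
        rec_uz.push_back(exit_uz);
        rec_w.push_back(w);
        rec_L.push_back(L);
        rec_zmax.push_back(zmax);
        if (record_paths && n_paths < max_paths) {
          int nv = (int)(verts.size() / 2);
          NumericMatrix m(nv, 2);
          for (int v = 0; v < nv; ++v) {
            m(v, 0) = verts[2 * v];
            m(v, 1) = verts[2 * v + 1];
          }
          paths[n_paths++] = m;
        }
      } else {
        escaped += w;
      }
    }
  }

  List records = List::create(
      _["x"] = wrap(rec_x), _["y"] = wrap(rec_y), _["ux"] = wrap(rec_ux),
      _["uy"] = wrap(rec_uy), _["uz"] = wrap(rec_uz), _["w"] = wrap(rec_w),
      _["pathlength"] = wrap(rec_L), _["z_max"] = wrap(rec_zmax));

  List out = List::create(
      _["n_launched"] = (double)n_photons,
      _["n_detected"] = (double)n_detected,
      _["w_detected"] = w_detected,
      _["specular"] = r_spec * (double)n_photons,
      _["absorbed"] = wrap(absorbed),
      _["detected_absorbed"] = wrap(det_absorbed),
      _["escaped"] = escaped,
      _["lateral"] = lateral,
      _["roulette_net"] = roulette_net,
      _["records"] = records,
      _["n_paths"] = n_paths);
  if (record_paths) {
    if (n_paths < (int)paths.size() && n_paths >= 0) {
      List trimmed(n_paths);
      for (int k = 0; k < n_paths; ++k) trimmed[k] = paths[k];
      out["paths"] = trimmed;
    } else {
      out["paths"] = paths;
    }
  }
  return out;
}
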