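// Voxel Monte Carlo photon transport kernel.
//
// Hop-drop-spin transport of weighted photon packets through an x-z
// labeled cross-section extruded along y.  The dimensionless step is
// carried across voxels of differing total attenuation, absorption is
// deposited by implicit capture, scattering follows Henyey-Greenstein,
// refractive-index mismatches at voxel faces and at the air-tissue
// boundary are handled with unpolarized Fresnel reflection/Snell
// refraction, and low-weight packets undergo Russian roulette.  Weight
// bookkeeping is exact: roulette boosts/losses are balanced against the
// absorbed tally, so launched = reflected + transmitted + absorbed +
// lateral holds to floating-point accuracy for every run.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

// splitmix64, used to seed per-photon xoshiro256+ streams so results are
// reproducible for a given seed and independent of scheduling
static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s[4];
  void seed(uint64_t stream) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(stream);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  inline double unif() {
    return (next() >> 11) * 0x1.0p-53;
  }
  // uniform in (0, 1]
  inline double unif_oc() {
    return 1.0 - unif();
  }
};

static inline double hg_cos(double g, double xi) {
  double ct;
  if (g == 0.0) {
    ct = 1.0 - 2.0 * xi;
  } else {
    double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * xi);
    ct = (1.0 + g * g - f * f) / (2.0 * g);
  }
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

static inline void spin(double &ux, double &uy, double &uz,
                        double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.999999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nuz = -den * st * cp + uz * ct;
    ux = nux; uy = nuy; uz = nuz;
  }
  // renormalize against slow drift
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

// unpolarized Fresnel reflectance for |cos_i|, with cos_t output
static inline double fresnel_R(double n1, double n2, double cos_i,
                               double &cos_t) {
  if (n1 == n2) { cos_t = cos_i; return 0.0; }
  double sin_i2 = 1.0 - cos_i * cos_i;
  double sin_t2 = (n1 / n2) * (n1 / n2) * sin_i2;
  if (sin_t2 >= 1.0) { cos_t = 0.0; return 1.0; }
  cos_t = std::sqrt(1.0 - sin_t2);
  double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
  double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

} // namespace

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(IntegerMatrix label, int ny, double pitch,
                NumericMatrix props,   // columns: mu_a, mu_s, g, n (row = label)
                double src_x, double src_y,
                IntegerVector det_face,     // 0 entry face, 1 exit face
                NumericVector det_cx, NumericVector det_cy,
                NumericVector det_half,
                int n_photons, double seed,
                double roulette_threshold, double roulette_survive,
                double max_events, bool tally_fluence,
                double n_outside) {
  const int nx = label.nrow(), nz = label.ncol();
  const int ndet = det_face.size();

  double tot_refl = 0, tot_trans = 0, tot_abs = 0, tot_lat = 0;
  double refl_sq = 0, trans_sq = 0;
  std::vector<double> det_w(ndet, 0.0), det_w2(ndet, 0.0);
  NumericMatrix fluence(tally_fluence ? nx : 1, tally_fluence ? nz : 1);
  double max_cons_err = 0.0;
  int n_capped = 0;
  double total_events = 0.0;

  const uint64_t seed_base = (uint64_t)(int64_t)seed;

  for (int ip = 0; ip < n_photons; ++ip) {
    Rng rng;
    uint64_t stream = seed_base * 0x9E3779B97F4A7C15ULL +
      (uint64_t)(ip + 1) * 0xD1B54A32D192ED03ULL;
    rng.seed(stream);

    double x = src_x, y = src_y, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    int ix = (int)(x / pitch); if (ix >= nx) ix = nx - 1;
    int iy = (int)(y / pitch); if (iy >= ny) iy = ny - 1;
    int iz = 0;
    double w = 1.0;

    double p_refl = 0, p_trans = 0, p_abs = 0, p_lat = 0;

    // specular reflection at launch (external medium n_outside)
    {
      double n_in = props(label(ix, iz) - 1, 3);
      double rsp = (n_in - n_outside) / (n_in + n_outside);
      rsp *= rsp;
      p_refl += rsp;
      w -= rsp;
    }

    double s = -std::log(rng.unif_oc());
    bool alive = true;
    double events = 0.0;

    while (alive) {
      if (events++ > max_events) {
        p_abs += w; ++n_capped; alive = false; break;
      }
      int lab = label(ix, iz) - 1;
      double mu_a = props(lab, 0), mu_s = props(lab, 1);
      double mu_t = mu_a + mu_s;

      // distance to the nearest voxel face along the direction
      double tb = 1e30; int axis = -1; int dir = 0;
      if (ux > 0) { double t = ((ix + 1) * pitch - x) / ux; if (t < tb) { tb = t; axis = 0; dir = 1; } }
      else if (ux < 0) { double t = (ix * pitch - x) / ux; if (t < tb) { tb = t; axis = 0; dir = -1; } }
      if (uy > 0) { double t = ((iy + 1) * pitch - y) / uy; if (t < tb) { tb = t; axis = 1; dir = 1; } }
      else if (uy < 0) { double t = (iy * pitch - y) / uy; if (t < tb) { tb = t; axis = 1; dir = -1; } }
      if (uz > 0) { double t = ((iz + 1) * pitch - z) / uz; if (t < tb) { tb = t; axis = 2; dir = 1; } }
      else if (uz < 0) { double t = (iz * pitch - z) / uz; if (t < tb) { tb = t; axis = 2; dir = -1; } }
      if (tb < 0) tb = 0;

      if (mu_t * tb < s) {
        // hop to the face and handle the crossing
        if (tally_fluence) fluence(ix, iz) += w * tb;
        x += ux * tb; y += uy * tb; z += uz * tb;
        s -= mu_t * tb;
        int jx = ix, jy = iy, jz = iz;
        if (axis == 0) jx += dir; else if (axis == 1) jy += dir; else jz += dir;

        if (jz < 0 || jz >= nz) {
          // axial boundary: Fresnel against the outside medium
          double n1 = props(lab, 3);
          double cos_i = std::fabs(uz);
          double cos_t;
          double R = fresnel_R(n1, n_outside, cos_i, cos_t);
          if (rng.unif() < R) {
            uz = -uz;
            iz = iz; // stay
          } else {
            // exits: tally and detector binning
            if (jz < 0) { p_refl += w; } else { p_trans += w; }
            int face = (jz < 0) ? 0 : 1;
            for (int k = 0; k < ndet; ++k) {
              if (det_face[k] == face &&
                  std::fabs(x - det_cx[k]) <= det_half[k] &&
                  std::fabs(y - det_cy[k]) <= det_half[k]) {
                det_w[k] += w; det_w2[k] += w * w;
              }
            }
            alive = false;
          }
        } else if (jx < 0 || jx >= nx || jy < 0 || jy >= ny) {
          // lateral faces: matched-index escape (finite finger width)
          p_lat += w;
          alive = false;
        } else {
          int lab2 = label(jx, jz) - 1;
          double n1 = props(lab, 3), n2 = props(lab2, 3);
          if (n1 == n2) {
            ix = jx; iy = jy; iz = jz;
          } else {
            double cos_i = (axis == 0) ? std::fabs(ux)
                          : (axis == 1) ? std::fabs(uy) : std::fabs(uz);
            double cos_t;
            double R = fresnel_R(n1, n2, cos_i, cos_t);
            if (rng.unif() < R) {
              if (axis == 0) ux = -ux; else if (axis == 1) uy = -uy; else uz = -uz;
            } else {
              double scale = n1 / n2;
              if (axis == 0) {
                uy *= scale; uz *= scale; ux = (ux >= 0 ? cos_t : -cos_t);
              } else if (axis == 1) {
                ux *= scale; uz *= scale; uy = (uy >= 0 ? cos_t : -cos_t);
              } else {
                ux *= scale; uy *= scale; uz = (uz >= 0 ? cos_t : -cos_t);
              }
              double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
              ux /= norm; uy /= norm; uz /= norm;
              ix = jx; iy = jy; iz = jz;
            }
          }
        }
      } else {
        // interaction inside the voxel
        double step = s / mu_t;
        if (tally_fluence) fluence(ix, iz) += w * step;
        x += ux * step; y += uy * step; z += uz * step;
        double dw = w * mu_a / mu_t;
        w -= dw;
        p_abs += dw;

        if (w < roulette_threshold) {
          if (rng.unif() < roulette_survive) {
            // boost is balanced against the absorbed tally
            p_abs -= w * (1.0 / roulette_survive - 1.0);
            w /= roulette_survive;
          } else {
            p_abs += w;
            alive = false;
          }
        }
        if (alive) {
          double g = props(lab, 2);
          double ct = hg_cos(g, rng.unif());
          double phi = 2.0 * M_PI * rng.unif();
          spin(ux, uy, uz, ct, phi);
          s = -std::log(rng.unif_oc());
        }
      }
    }

    double cons = std::fabs(p_refl + p_trans + p_abs + p_lat - 1.0);
    if (cons > max_cons_err) max_cons_err = cons;
    tot_refl += p_refl; tot_trans += p_trans;
    tot_abs += p_abs; tot_lat += p_lat;
    refl_sq += p_refl * p_refl; trans_sq += p_trans * p_trans;
    total_events += events;
  }

  return List::create(
    _["reflected"] = tot_refl,
    _["transmitted"] = tot_trans,
    _["absorbed"] = tot_abs,
    _["lateral"] = tot_lat,
    _["reflected_sq"] = refl_sq,
    _["transmitted_sq"] = trans_sq,
    _["detected"] = NumericVector(det_w.begin(), det_w.end()),
    _["detected_sq"] = NumericVector(det_w2.begin(), det_w2.end()),
    _["fluence"] = fluence,
    _["n_capped"] = n_capped,
    _["max_conservation_error"] = max_cons_err,
    _["mean_events"] = total_events / n_photons
  );
}
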