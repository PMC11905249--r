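// Voxel Monte Carlo photon transport with Woodcock (delta) tracking.
//
// Physics model (kilovoltage range, <= 150 keV):
//  * photoelectric absorption with optional single-line K-alpha
//    fluorescence for high-Z absorbers (Z >= 20), probability = K
//    fluorescence yield;
//  * incoherent scattering from free electrons (Klein-Nishina), sampled by
//    composition-rejection; the Compton electron deposits locally;
//  * coherent scattering with the Thomson angular law (no form factors);
//  * electrons are not transported (collision-kerma approximation; CSDA
//    range < 0.2 mm below 120 keV);
//  * photons falling below the cutoff are terminated and their residual
//    energy booked in a separate "discarded" audit bucket.
//
// Cross sections arrive as per-material lookup tables on a uniform energy
// grid (nearest-bin lookup). Deterministic for a fixed seed; single
// threaded.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

constexpr double MEC2 = 511.0;  // electron rest energy, keV

// PCG32 (O'Neill's minimal generator): small, fast, reproducible
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xs = static_cast<uint32_t>(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = static_cast<uint32_t>(old >> 59u);
    return (xs >> rot) | (xs << ((32u - rot) & 31u));
  }
  double u() { return (next() + 0.5) * (1.0 / 4294967296.0); }
};

struct Vec3 {
  double x, y, z;
};

inline void rotate_direction(Vec3& d, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cf = std::cos(phi), sf = std::sin(phi);
  double sz2 = 1.0 - d.z * d.z;
  if (sz2 > 1e-20) {
    double sz = std::sqrt(sz2);
    double nx = d.x * ct + st * (d.x * d.z * cf - d.y * sf) / sz;
    double ny = d.y * ct + st * (d.y * d.z * cf + d.x * sf) / sz;
    double nz = d.z * ct - st * sz * cf;
    d.x = nx; d.y = ny; d.z = nz;
  } else {
    d.x = st * cf;
    d.y = st * sf;
    d.z = (d.z > 0 ? ct : -ct);
  }
}

// Klein-Nishina sampling of eps = E'/E by composition-rejection
inline double sample_kn_eps(double energy, Pcg32& rng) {
  double alpha = energy / MEC2;
  double eps0 = 1.0 / (1.0 + 2.0 * alpha);
  double w1 = -std::log(eps0);          // integral of 1/eps
  double w2 = 0.5 * (1.0 - eps0 * eps0); // integral of eps
  for (;;) {
    double eps;
    if (rng.u() * (w1 + w2) < w1) {
      eps = eps0 * std::exp(rng.u() * w1);
    } else {
      eps = std::sqrt(eps0 * eps0 + rng.u() * (1.0 - eps0 * eps0));
    }
    double t = (1.0 - eps) / (alpha * eps);
    double sin2 = t * (2.0 - t);
    double h = 1.0 - eps * sin2 / (1.0 + eps * eps);
    if (rng.u() <= h) return eps;
  }
}

inline double sample_thomson_ct(Pcg32& rng) {
  for (;;) {
    double mu = 2.0 * rng.u() - 1.0;
    if (rng.u() <= 0.5 * (1.0 + mu * mu)) return mu;
  }
}

struct Beam {
  Vec3 focal;           // focal spot (parallel: any point on the axis)
  Vec3 axis;            // unit beam axis
  Vec3 uax, vax;        // aperture plane unit vectors
  Vec3 iso;             // isocenter (aperture centre)
  double half_u, half_v;
  bool parallel;
  int n_cdf;            // angular sub-bins along u
  NumericMatrix cdf;    // nspec x n_cdf cumulative spectra
  NumericVector spec_edges; // nspec + 1 energy bin edges
};

struct Grid {
  int nx, ny, nz;
  double dx, dy, dz;
  double ox, oy, oz;
  const int* mat;
  const double* rho;
  double x1, y1, z1; // far corner
  inline bool inside(const Vec3& p) const {
    return p.x > ox && p.x < x1 && p.y > oy && p.y < y1 &&
           p.z > oz && p.z < z1;
  }
  inline int voxel(const Vec3& p) const {
    int ix = static_cast<int>((p.x - ox) / dx);
    int iy = static_cast<int>((p.y - oy) / dy);
    int iz = static_cast<int>((p.z - oz) / dz);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
      return -1;
    return ix + nx * (iy + ny * iz);
  }
};

// advance a photon outside the box to its entry point; false if it misses
inline bool clip_to_grid(const Grid& g, Vec3& p, const Vec3& d) {
  double t0 = 0.0, t1 = 1e30;
  const double lo[3] = {g.ox, g.oy, g.oz};
  const double hi[3] = {g.x1, g.y1, g.z1};
  const double pp[3] = {p.x, p.y, p.z};
  const double dd[3] = {d.x, d.y, d.z};
  for (int k = 0; k < 3; ++k) {
    if (std::fabs(dd[k]) < 1e-12) {
      if (pp[k] <= lo[k] || pp[k] >= hi[k]) return false;
    } else {
      double ta = (lo[k] - pp[k]) / dd[k];
      double tb = (hi[k] - pp[k]) / dd[k];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    }
  }
  if (t0 >= t1) return false;
  double eps = 1e-6 * (g.dx + g.dy + g.dz);
  p.x += (t0 + eps) * d.x;
  p.y += (t0 + eps) * d.y;
  p.z += (t0 + eps) * d.z;
  return true;
}

} // namespace

// [[Rcpp::export]]
List mc_transport(IntegerVector shape, NumericVector voxel_cm,
                  NumericVector origin_cm, IntegerVector material_index,
                  NumericVector density, NumericVector egrid,
                  NumericMatrix mu_mass, NumericMatrix p_pe,
                  NumericMatrix p_incoh, NumericMatrix fl_frac,
                  NumericVector fl_omega, NumericVector fl_eka,
                  NumericVector fl_edge, NumericVector mu_majorant,
                  List beams_in, double cutoff_keV, double n_histories,
                  int n_batches, double seed, bool primary_only,
                  bool fluorescence, NumericVector exit_weight) {
  Grid g;
  g.nx = shape[0]; g.ny = shape[1]; g.nz = shape[2];
  g.dx = voxel_cm[0]; g.dy = voxel_cm[1]; g.dz = voxel_cm[2];
  g.ox = origin_cm[0]; g.oy = origin_cm[1]; g.oz = origin_cm[2];
  g.x1 = g.ox + g.nx * g.dx;
  g.y1 = g.oy + g.ny * g.dy;
  g.z1 = g.oz + g.nz * g.dz;
  g.mat = INTEGER(material_index);
  g.rho = REAL(density);

  const int n_e = egrid.size();
  const double e0 = egrid[0];
  const double de = egrid[1] - egrid[0];
  const double* maj = REAL(mu_majorant);
  const bool do_exit_tally = exit_weight.size() == n_e;

  const int n_beams = beams_in.size();
  std::vector<Beam> beams(n_beams);
  for (int b = 0; b < n_beams; ++b) {
    List bl = beams_in[b];
    NumericVector f = bl["focal"], ax = bl["axis"], ua = bl["uax"],
                  va = bl["vax"], is = bl["iso"];
    Beam& bm = beams[b];
    bm.focal = {f[0], f[1], f[2]};
    bm.axis = {ax[0], ax[1], ax[2]};
    bm.uax = {ua[0], ua[1], ua[2]};
    bm.vax = {va[0], va[1], va[2]};
    bm.iso = {is[0], is[1], is[2]};
    bm.half_u = as<double>(bl["half_u"]);
    bm.half_v = as<double>(bl["half_v"]);
    bm.parallel = as<bool>(bl["parallel"]);
    bm.cdf = as<NumericMatrix>(bl["cdf"]);
    bm.n_cdf = bm.cdf.ncol();
    bm.spec_edges = as<NumericVector>(bl["spec_edges"]);
  }

  const R_xlen_t n_vox = material_index.size();
  std::vector<double> edep_sum(n_vox, 0.0), edep_sumsq(n_vox, 0.0);
  std::vector<double> batch(n_vox, 0.0);
  NumericMatrix audit(n_batches, 4); // emitted, deposited, escaped, discarded
  NumericVector exit_tally(n_batches);

  const double hist_total = n_histories;
  const long long per_batch =
      static_cast<long long>(std::ceil(hist_total / n_batches));

  struct StackPhoton { Vec3 p, d; double E; int n_int; };

  for (int ib = 0; ib < n_batches; ++ib) {
    std::fill(batch.begin(), batch.end(), 0.0);
    Pcg32 rng(static_cast<uint64_t>(seed) + 0x9E3779B9ULL * (ib + 1),
              0xDA3E39CB94B95BDBULL ^ static_cast<uint64_t>(ib));
    double em = 0, dep = 0, esc = 0, disc = 0, exitw = 0;

    for (long long h = 0; h < per_batch; ++h) {
      const Beam& bm = beams[h % n_beams];
      // sample aperture point
      double uu = (2.0 * rng.u() - 1.0) * bm.half_u;
      double vv = (2.0 * rng.u() - 1.0) * bm.half_v;
      Vec3 ap = {bm.iso.x + uu * bm.uax.x + vv * bm.vax.x,
                 bm.iso.y + uu * bm.uax.y + vv * bm.vax.y,
                 bm.iso.z + uu * bm.uax.z + vv * bm.vax.z};
      Vec3 pos, dir;
      double fan_u;
      if (bm.parallel) {
        dir = bm.axis;
        // start well upstream of the grid along the axis
        double back = (g.x1 - g.ox) + (g.y1 - g.oy) + (g.z1 - g.oz);
        pos = {ap.x - back * dir.x, ap.y - back * dir.y, ap.z - back * dir.z};
        fan_u = 0.0;
      } else {
        pos = bm.focal;
        double ddx = ap.x - pos.x, ddy = ap.y - pos.y, ddz = ap.z - pos.z;
        double nrm = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
        dir = {ddx / nrm, ddy / nrm, ddz / nrm};
        fan_u = std::fabs(uu) / (bm.half_u + 1e-12);
      }
      // energy: pick angular sub-bin by |u| fraction, then inverse CDF
      int kbin = std::min(static_cast<int>(fan_u * bm.n_cdf), bm.n_cdf - 1);
      double r = rng.u();
      int ns = bm.cdf.nrow();
      int loidx = 0, hiidx = ns - 1;
      // binary search for first cdf >= r
      while (loidx < hiidx) {
        int mid = (loidx + hiidx) / 2;
        if (bm.cdf(mid, kbin) < r) loidx = mid + 1; else hiidx = mid;
      }
      double el = bm.spec_edges[loidx], eh = bm.spec_edges[loidx + 1];
      double E = el + rng.u() * (eh - el);
      em += E;

      StackPhoton stack[8];
      int ntrack = 0;
      stack[ntrack++] = {pos, dir, E, 0};

      while (ntrack > 0) {
        StackPhoton ph = stack[--ntrack];
        if (ph.E < cutoff_keV) { disc += ph.E; continue; }
        if (!g.inside(ph.p)) {
          if (!clip_to_grid(g, ph.p, ph.d)) {
            if (do_exit_tally && ph.n_int == 0) {
              int ei = static_cast<int>((ph.E - e0) / de + 0.5);
              ei = std::min(std::max(ei, 0), n_e - 1);
              exitw += exit_weight[ei] * ph.E;
            }
            esc += ph.E;
            continue;
          }
        }
        bool alive = true;
        while (alive) {
          int ei = static_cast<int>((ph.E - e0) / de + 0.5);
          ei = std::min(std::max(ei, 0), n_e - 1);
          double mu_max = maj[ei];
          double step = -std::log(rng.u()) / mu_max;
          ph.p.x += step * ph.d.x;
          ph.p.y += step * ph.d.y;
          ph.p.z += step * ph.d.z;
          int vox = g.voxel(ph.p);
          if (vox < 0) {
            if (do_exit_tally && ph.n_int == 0) {
              exitw += exit_weight[ei] * ph.E;
            }
            esc += ph.E;
            alive = false;
            break;
          }
          int m = g.mat[vox];
          double mu_loc = mu_mass(ei, m) * g.rho[vox];
          if (rng.u() * mu_max > mu_loc) continue; // fictitious
          ph.n_int++;
          double r2 = rng.u();
          double ppe = p_pe(ei, m), pin = p_incoh(ei, m);
          if (r2 < ppe) {
            // photoelectric
            double edep = ph.E;
            if (!primary_only && fluorescence && fl_omega[m] > 0 &&
                ph.E > fl_edge[m] && rng.u() < fl_frac(ei, m) &&
                rng.u() < fl_omega[m]) {
              double eka = fl_eka[m];
              if (eka < ph.E) {
                edep = ph.E - eka;
                if (ntrack < 8) {
                  double ct = 2.0 * rng.u() - 1.0;
                  double phi = 2.0 * M_PI * rng.u();
                  double st = std::sqrt(1.0 - ct * ct);
                  Vec3 fd = {st * std::cos(phi), st * std::sin(phi), ct};
                  stack[ntrack++] = {ph.p, fd, eka, ph.n_int};
                } else {
                  edep = ph.E; // stack full: deposit everything
                }
              }
            }
            batch[vox] += edep;
            dep += edep;
            alive = false;
          } else if (r2 < ppe + pin) {
            // incoherent
            double eps = sample_kn_eps(ph.E, rng);
            double t = (1.0 - eps) / ((ph.E / MEC2) * eps);
            double ct = 1.0 - t;
            double edep = ph.E * (1.0 - eps);
            batch[vox] += edep;
            dep += edep;
            double enew = ph.E * eps;
            if (primary_only) {
              esc += enew;
              alive = false;
            } else {
              ph.E = enew;
              rotate_direction(ph.d, ct, 2.0 * M_PI * rng.u());
              if (ph.E < cutoff_keV) { disc += ph.E; alive = false; }
            }
          } else {
            // coherent: redirect only
            if (primary_only) {
              esc += ph.E;
              alive = false;
            } else {
              rotate_direction(ph.d, sample_thomson_ct(rng),
                               2.0 * M_PI * rng.u());
            }
          }
        }
      }
    }
    for (R_xlen_t v = 0; v < n_vox; ++v) {
      edep_sum[v] += batch[v];
      edep_sumsq[v] += batch[v] * batch[v];
    }
    audit(ib, 0) = em; audit(ib, 1) = dep;
    audit(ib, 2) = esc; audit(ib, 3) = disc;
    exit_tally[ib] = exitw;
    Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["edep_sum"] = NumericVector(edep_sum.begin(), edep_sum.end()),
      _["edep_sumsq"] = NumericVector(edep_sumsq.begin(), edep_sumsq.end()),
      _["audit"] = audit,
      _["exit_tally"] = exit_tally,
      _["histories_per_batch"] = static_cast<double>(per_batch),
      _["n_batches"] = n_batches);
}

// [[Rcpp::export]]
NumericMatrix mc_sample_compton(int n, double energy_keV, double seed) {
  Pcg32 rng(static_cast<uint64_t>(seed), 0x853C49E6748FEA9BULL);
  NumericMatrix out(n, 2); // scattered energy, cos(theta)
  double alpha = energy_keV / MEC2;
  for (int i = 0; i < n; ++i) {
    double eps = sample_kn_eps(energy_keV, rng);
    out(i, 0) = energy_keV * eps;
    out(i, 1) = 1.0 - (1.0 - eps) / (alpha * eps);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector mc_sample_thomson(int n, double seed) {
  Pcg32 rng(static_cast<uint64_t>(seed), 0x853C49E6748FEA9BULL);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_thomson_ct(rng);
  return out;
}
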