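#include <Rcpp.h>
using namespace Rcpp;

// minimum-image displacement component in a cubic box of edge L
static inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

static double potential(const double *pos, const NumericMatrix &sites,
                        const NumericVector &depth, const NumericVector &width,
                        double L) {
  double U = 0.0;
  for (int k = 0; k < sites.nrow(); ++k) {
    double dx = min_image(pos[0] - sites(k, 0), L);
    double dy = min_image(pos[1] - sites(k, 1), L);
    double dz = min_image(pos[2] - sites(k, 2), L);
    double d2 = dx * dx + dy * dy + dz * dz;
    double w = width[k];
    U -= std::fabs(depth[k]) * std::exp(-d2 / (2.0 * w * w));
  }
  return U;
}

// Metropolis Monte Carlo of a single ion among fixed Gaussian-well sites.
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".mc_ion_run")]]
List mc_ion_run(NumericMatrix sites, NumericVector depth, NumericVector width,
                double box_edge, double temperature, NumericVector start,
                int n_sweeps, int sample_every, double step_size) {
  const double RT = 8.31446e-3 * temperature; // kJ/mol
  double pos[3] = {start[0], start[1], start[2]};
  double U = potential(pos, sites, depth, width, box_edge);
  int n_frames = n_sweeps / sample_every;
  NumericMatrix frames(n_frames, 3);
  long accepted = 0;
  int fi = 0;
  for (int s = 1; s <= n_sweeps; ++s) {
    double trial[3];
    for (int j = 0; j < 3; ++j) {
      trial[j] = pos[j] + step_size * (unif_rand() - 0.5);
      // wrap into [0, L)
      trial[j] -= box_edge * std::floor(trial[j] / box_edge);
    }
    double Ut = potential(trial, sites, depth, width, box_edge);
    if (Ut <= U || unif_rand() < std::exp(-(Ut - U) / RT)) {
      pos[0] = trial[0]; pos[1] = trial[1]; pos[2] = trial[2];
      U = Ut;
      ++accepted;
    }
    if (s % sample_every == 0 && fi < n_frames) {
      frames(fi, 0) = pos[0];
      frames(fi, 1) = pos[1];
      frames(fi, 2) = pos[2];
      ++fi;
    }
  }
  return List::create(_["frames"] = frames,
                      _["acceptance"] = (double)accepted / n_sweeps);
}

// Pooled minimum-image ion-site distances, one column per site.
// [[Rcpp::export(name = ".min_image_dists")]]
NumericMatrix min_image_dists(NumericMatrix frames, NumericMatrix sites,
                              double box_edge, bool periodic) {
  int n = frames.nrow(), m = sites.nrow();
  NumericMatrix out(n, m);
  for (int k = 0; k < m; ++k) {
    double sx = sites(k, 0), sy = sites(k, 1), sz = sites(k, 2);
    for (int i = 0; i < n; ++i) {
      double dx = frames(i, 0) - sx;
      double dy = frames(i, 1) - sy;
      double dz = frames(i, 2) - sz;
      if (periodic) {
        dx = min_image(dx, box_edge);
        dy = min_image(dy, box_edge);
        dz = min_image(dz, box_edge);
      }
      out(i, k) = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  }
  return out;
}
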