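#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Energy-minimisation point-pattern reconstruction.
//
// Candidate locations are admissible voxel centers (x, y jittered uniformly
// within the voxel; the axial coordinate is pre-snapped to the nearest z-disc
// plane). The energy is the squared discrepancy between the current and the
// target nearest-neighbour and radial (distance-to-myofibril) histograms,
// both expressed as proportions on fixed bins. One uniformly chosen point is
// relocated to one uniformly chosen admissible voxel per proposal; moves are
// accepted greedily (temperature 0) or by a Metropolis rule under a geometric
// annealing schedule. Nearest-neighbour bookkeeping is incremental between
// accepted moves and fully refreshed on acceptance; an audit compares the
// bookkept energy with a from-scratch recomputation every 1000 accepts.

static const double INF = std::numeric_limits<double>::infinity();

static inline double dist3(const std::vector<double>& x,
                           const std::vector<double>& y,
                           const std::vector<double>& z, int i, int j) {
  double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static void nn_full(const std::vector<double>& x, const std::vector<double>& y,
                    const std::vector<double>& z, int n,
                    std::vector<double>& nnd, std::vector<int>& nni) {
  for (int i = 0; i < n; ++i) {
    double m = INF;
    int mi = -1;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d = dist3(x, y, z, i, j);
      if (d < m) { m = d; mi = j; }
    }
    nnd[i] = m;
    nni[i] = mi;
  }
}

static inline int binof(double d, double dr, int nb) {
  int b = (int)(d / dr);
  return b >= nb ? nb - 1 : b;
}

static double energy_from(const std::vector<double>& nnd, int n, double g_dr,
                          int g_nb, const double* g_t,
                          const std::vector<int>& rcnt, int r_nb,
                          const double* r_t, double w_g, double w_rad) {
  double e = 0.0;
  std::vector<int> gc(g_nb, 0);
  for (int i = 0; i < n; ++i) gc[binof(nnd[i], g_dr, g_nb)]++;
  for (int b = 0; b < g_nb; ++b) {
    double d = gc[b] / (double)n - g_t[b];
    e += w_g * d * d;
  }
  if (w_rad > 0.0) {
    for (int b = 0; b < r_nb; ++b) {
      double d = rcnt[b] / (double)n - r_t[b];
      e += w_rad * d * d;
    }
  }
  return e;
}

// [[Rcpp::export]]
List reconstruct_cpp(NumericVector adm_x, NumericVector adm_y,
                     NumericVector adm_z, NumericVector adm_rad,
                     NumericVector jitter, int n_points, double g_dr,
                     NumericVector g_target, double r_dr,
                     NumericVector r_target, double w_g, double w_rad,
                     double min_spacing, int max_iter, double tol,
                     double temp0, double cool, int max_consec_rej) {
  RNGScope scope;
  int N = adm_x.size();
  int n = n_points;
  int g_nb = g_target.size();
  int r_nb = r_target.size();

  std::vector<double> px(n), py(n), pz(n), rad(n);
  int status = 0;

  // CSR initialisation inside the admissible set, respecting min_spacing
  {
    int placed = 0, consec = 0;
    while (placed < n) {
      int v = (int)(unif_rand() * N);
      if (v >= N) v = N - 1;
      double cx = adm_x[v] + (unif_rand() - 0.5) * jitter[0];
      double cy = adm_y[v] + (unif_rand() - 0.5) * jitter[1];
      double cz = adm_z[v];
      bool ok = true;
      for (int j = 0; j < placed; ++j) {
        double dx = px[j] - cx, dy = py[j] - cy, dz = pz[j] - cz;
        if (dx * dx + dy * dy + dz * dz < min_spacing * min_spacing) {
          ok = false;
          break;
        }
      }
      if (ok) {
        px[placed] = cx; py[placed] = cy; pz[placed] = cz;
        rad[placed] = adm_rad[v];
        ++placed;
        consec = 0;
      } else if (++consec > max_consec_rej) {
        status = 1;
        break;
      }
    }
  }
  if (status != 0)
    return List::create(_["status"] = status);

  std::vector<double> nnd(n);
  std::vector<int> nni(n);
  nn_full(px, py, pz, n, nnd, nni);

  std::vector<int> rcnt(r_nb, 0);
  for (int i = 0; i < n; ++i) rcnt[binof(rad[i], r_dr, r_nb)]++;

  double E = energy_from(nnd, n, g_dr, g_nb, g_target.begin(), rcnt, r_nb,
                         r_target.begin(), w_g, w_rad);
  std::vector<double> trace;
  trace.push_back(E);

  std::vector<double> tmp(n), dnew(n);
  long accepted = 0;
  int consec = 0, iter = 0;
  double audit_max = 0.0;

  for (iter = 0; iter < max_iter && E > tol; ++iter) {
    int i = (int)(unif_rand() * n);
    if (i >= n) i = n - 1;
    int v = (int)(unif_rand() * N);
    if (v >= N) v = N - 1;
    double cx = adm_x[v] + (unif_rand() - 0.5) * jitter[0];
    double cy = adm_y[v] + (unif_rand() - 0.5) * jitter[1];
    double cz = adm_z[v];

    bool ok = true;
    double mn = INF;
    for (int j = 0; j < n; ++j) {
      if (j == i) { dnew[j] = INF; continue; }
      double dx = px[j] - cx, dy = py[j] - cy, dz = pz[j] - cz;
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      dnew[j] = d;
      if (d < min_spacing) { ok = false; break; }
      if (d < mn) mn = d;
    }
    if (!ok) {
      if (++consec > max_consec_rej) { status = 2; break; }
      continue;
    }
    consec = 0;

    // candidate nearest-neighbour distances
    double ox = px[i], oy = py[i], oz = pz[i];
    px[i] = cx; py[i] = cy; pz[i] = cz;  // temporarily move for rescans
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (nni[j] == i) {
        double m2 = dnew[j];
        for (int k = 0; k < n; ++k) {
          if (k == j || k == i) continue;
          double d = dist3(px, py, pz, j, k);
          if (d < m2) m2 = d;
        }
        tmp[j] = m2;
      } else {
        tmp[j] = nnd[j] < dnew[j] ? nnd[j] : dnew[j];
      }
    }
    tmp[i] = mn;

    int rb_old = binof(rad[i], r_dr, r_nb);
    int rb_new = binof(adm_rad[v], r_dr, r_nb);
    rcnt[rb_old]--; rcnt[rb_new]++;

    double Enew = energy_from(tmp, n, g_dr, g_nb, g_target.begin(), rcnt,
                              r_nb, r_target.begin(), w_g, w_rad);
    double dE = Enew - E;
    double T = temp0 > 0.0 ? temp0 * std::pow(cool, (double)iter) : 0.0;
    bool accept = dE < 0.0 || (T > 0.0 && unif_rand() < std::exp(-dE / T));

    if (accept) {
      rad[i] = adm_rad[v];
      nnd = tmp;
      nn_full(px, py, pz, n, nnd, nni);  // refresh indices exactly
      E = Enew;
      trace.push_back(E);
      ++accepted;
      if (accepted % 1000 == 0) {
        std::vector<int> rc2(r_nb, 0);
        for (int q = 0; q < n; ++q) rc2[binof(rad[q], r_dr, r_nb)]++;
        double Echk = energy_from(nnd, n, g_dr, g_nb, g_target.begin(), rc2,
                                  r_nb, r_target.begin(), w_g, w_rad);
        double diff = std::fabs(Echk - E);
        if (diff > audit_max) audit_max = diff;
      }
    } else {
      // roll back
      px[i] = ox; py[i] = oy; pz[i] = oz;
      rcnt[rb_old]++; rcnt[rb_new]--;
    }
  }

  NumericMatrix pts(n, 3);
  for (int i = 0; i < n; ++i) {
    pts(i, 0) = px[i]; pts(i, 1) = py[i]; pts(i, 2) = pz[i];
  }
  return List::create(_["points"] = pts, _["radial"] = NumericVector(rad.begin(), rad.end()),
                      _["energy"] = E, _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["iterations"] = iter, _["accepted"] = (double)accepted,
                      _["audit_max"] = audit_max, _["status"] = status,
                      _["converged"] = E <= tol);
}
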