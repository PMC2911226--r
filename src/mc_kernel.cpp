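// Metropolis Monte-Carlo kernel for tethered tetrapeptide docking.
// Mirrors the R reference scorer (R/energy.R); the two are cross-checked
// in the test suite.  Moves are torsion perturbations of the peptide
// (P2/P3 sidechain and backbone) and of flexible receptor (gatekeeper)
// sidechains.  Incremental energies: a move only re-evaluates pair terms
// involving moved atoms.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// splitmix64: tiny deterministic PRNG, independent of R's RNG so that
// per-peptide runs are bit-reproducible from their own seeds.
struct Prng {
  uint64_t state;
  explicit Prng(uint64_t seed) : state(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

struct Params {
  double cutoff, cutoff2, coulomb_k, diel, hb_r0, hb_eps, hb_rmin, hb_rmax,
      hb_cos_max, k_tor, k_tether, clash_dist, clash_energy, kT, max_step;
};

struct Atoms {
  std::vector<double> x, y, z, rmin_half, eps, q;
  std::vector<int> don_base, is_acc;
  int n;
};

Atoms unpack(const NumericMatrix &xyz, const List &ann) {
  Atoms a;
  a.n = xyz.nrow();
  a.x.resize(a.n); a.y.resize(a.n); a.z.resize(a.n);
  for (int i = 0; i < a.n; ++i) {
    a.x[i] = xyz(i, 0); a.y[i] = xyz(i, 1); a.z[i] = xyz(i, 2);
  }
  a.rmin_half = as<std::vector<double>>(ann["rmin_half"]);
  a.eps = as<std::vector<double>>(ann["eps"]);
  a.q = as<std::vector<double>>(ann["q"]);
  a.don_base = as<std::vector<int>>(ann["don_base"]);
  a.is_acc = as<std::vector<int>>(ann["is_acc"]);
  return a;
}

inline double dist2(const Atoms &A, int i, const Atoms &B, int j) {
  double dx = A.x[i] - B.x[j], dy = A.y[i] - B.y[j], dz = A.z[i] - B.z[j];
  return dx * dx + dy * dy + dz * dz;
}

inline double lj_pair(const Atoms &A, int i, const Atoms &B, int j,
                      double r, const Params &p, bool *clash) {
  if (r < p.clash_dist) { if (clash) *clash = true; return p.clash_energy; }
  double rmin = A.rmin_half[i] + B.rmin_half[j];
  double eps = std::sqrt(A.eps[i] * B.eps[j]);
  double sr2 = (rmin / r) * (rmin / r);
  double sr6 = sr2 * sr2 * sr2;
  double e = eps * (sr6 * sr6 - 2.0 * sr6);
  return e > p.clash_energy ? p.clash_energy : e;
}

// H-bond term, donor i in A vs acceptor j in B.  Returns energy; if
// `count` is non-null it is incremented when the geometric window is met.
inline double hb_dir(const Atoms &A, int i, const Atoms &B, int j, double r,
                     const Params &p, int *count) {
  if (A.don_base[i] < 0 || !B.is_acc[j]) return 0.0;
  if (r < p.hb_rmin || r > p.hb_rmax) return 0.0;
  int b = A.don_base[i];
  double v1x = A.x[b] - A.x[i], v1y = A.y[b] - A.y[i], v1z = A.z[b] - A.z[i];
  double v2x = B.x[j] - A.x[i], v2y = B.y[j] - A.y[i], v2z = B.z[j] - A.z[i];
  double n1 = std::sqrt(v1x * v1x + v1y * v1y + v1z * v1z);
  double n2 = std::sqrt(v2x * v2x + v2y * v2y + v2z * v2z);
  double ct = (v1x * v2x + v1y * v2y + v1z * v2z) / (n1 * n2);
  if (ct > p.hb_cos_max) return 0.0;  // angle below the minimum
  if (count) ++(*count);
  double x2 = (p.hb_r0 / r) * (p.hb_r0 / r);
  double x10 = x2 * x2 * x2 * x2 * x2;
  return p.hb_eps * (5.0 * x10 * x2 - 6.0 * x10) * ct * ct;
}

// Full peptide<->receptor pair energy for one peptide atom.
inline double inter_atom(const Atoms &P, int i, const Atoms &R,
                         const Params &p, int *n_within, bool *clash,
                         int *hb_count) {
  double e = 0.0;
  for (int j = 0; j < R.n; ++j) {
    double r2 = dist2(P, i, R, j);
    if (r2 >= p.cutoff2) continue;
    double r = std::sqrt(r2);
    if (n_within) ++(*n_within);
    e += lj_pair(P, i, R, j, r, p, clash);
    if (r >= p.clash_dist) {
      double qq = P.q[i] * R.q[j];
      if (qq != 0.0) e += p.coulomb_k * qq / (p.diel * r * r);
      e += hb_dir(P, i, R, j, r, p, hb_count);
      e += hb_dir(R, j, P, i, r, p, hb_count);
    }
  }
  return e;
}

struct Tors {
  int which;                 // 0 peptide, 1 receptor
  int ai, aj;                // axis atoms
  std::vector<int> moving;
  double chi0, chi;
  double weight;
};

void rotate(Atoms &A, const std::vector<int> &idx, int ai, int aj,
            double angle_deg) {
  double th = angle_deg * M_PI / 180.0;
  double ux = A.x[aj] - A.x[ai], uy = A.y[aj] - A.y[ai],
         uz = A.z[aj] - A.z[ai];
  double n = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= n; uy /= n; uz /= n;
  double c = std::cos(th), s = std::sin(th), t = 1.0 - c;
  double m[3][3] = {
    {c + ux * ux * t, ux * uy * t - uz * s, ux * uz * t + uy * s},
    {ux * uy * t + uz * s, c + uy * uy * t, uy * uz * t - ux * s},
    {ux * uz * t - uy * s, uy * uz * t + ux * s, c + uz * uz * t}};
  for (int k : idx) {
    double px = A.x[k] - A.x[ai], py = A.y[k] - A.y[ai],
           pz = A.z[k] - A.z[ai];
    A.x[k] = A.x[ai] + m[0][0] * px + m[0][1] * py + m[0][2] * pz;
    A.y[k] = A.y[ai] + m[1][0] * px + m[1][1] * py + m[1][2] * pz;
    A.z[k] = A.z[ai] + m[2][0] * px + m[2][1] * py + m[2][2] * pz;
  }
}

typedef std::vector<std::vector<char>> BoolMat;

BoolMat excl_matrix(const IntegerMatrix &pairs, int n1, int n2) {
  BoolMat m(n1, std::vector<char>(n2, 0));
  for (int k = 0; k < pairs.nrow(); ++k) {
    int i = pairs(k, 0), j = pairs(k, 1);
    if (i >= 0 && i < n1 && j >= 0 && j < n2) m[i][j] = 1;
  }
  return m;
}

}  // namespace

// [[Rcpp::export(name = ".mc_kernel")]]
List mc_kernel(NumericMatrix pep_xyz, List pep_ann, IntegerMatrix pep_excl,
               NumericMatrix rec_xyz, List rec_ann,
               IntegerVector rec_flex, IntegerMatrix rec_excl,
               List torsions, IntegerVector anchor_idx,
               NumericMatrix anchor_ref, List par) {
  Params p;
  p.cutoff = par["cutoff"]; p.coulomb_k = par["coulomb_k"];
  p.diel = par["dielectric_factor"]; p.hb_r0 = par["hb_r0"];
  p.hb_eps = par["hb_eps"]; p.hb_rmin = par["hb_rmin"];
  p.hb_rmax = par["hb_rmax"];
  double amin = par["hb_angle_min"];
  p.hb_cos_max = std::cos(amin * M_PI / 180.0);
  p.k_tor = par["k_tor"]; p.k_tether = par["k_tether"];
  p.clash_dist = par["clash_dist"]; p.clash_energy = par["clash_energy"];
  p.kT = par["kT"]; p.max_step = par["max_step"];
  p.cutoff2 = p.cutoff * p.cutoff;
  int iterations = par["iterations"];
  int trace_interval = par["trace_interval"];
  uint64_t seed = (uint64_t)(double)par["seed"];

  Atoms P = unpack(pep_xyz, pep_ann);
  Atoms R = unpack(rec_xyz, rec_ann);
  BoolMat pexcl = excl_matrix(pep_excl, P.n, P.n);
  // symmetrise
  for (int i = 0; i < P.n; ++i)
    for (int j = 0; j < P.n; ++j) if (pexcl[i][j]) pexcl[j][i] = 1;
  std::vector<char> is_flex(R.n, 0);
  for (int k = 0; k < rec_flex.size(); ++k) is_flex[rec_flex[k]] = 1;
  BoolMat rexcl = excl_matrix(rec_excl, R.n, R.n);
  for (int i = 0; i < R.n; ++i)
    for (int j = 0; j < R.n; ++j) if (rexcl[i][j]) rexcl[j][i] = 1;

  int nt = torsions.size();
  std::vector<Tors> tors(nt);
  double wsum = 0.0;
  for (int k = 0; k < nt; ++k) {
    List t = torsions[k];
    tors[k].which = t["which"];
    tors[k].ai = t["ai"]; tors[k].aj = t["aj"];
    tors[k].moving = as<std::vector<int>>(t["moving"]);
    tors[k].chi0 = t["chi0"];
    tors[k].chi = t.containsElementNamed("chi_start")
                      ? (double)t["chi_start"] : tors[k].chi0;
    tors[k].weight = t["weight"];
    wsum += tors[k].weight;
  }
  if (nt > 0 && wsum <= 0.0) stop("move set has zero total weight");

  // ---- energy pieces -------------------------------------------------
  // Self-sterics are repulsive-only (WCA-shifted LJ, >= 0): internal
  // relaxation can never look like binding energy.
  auto wca_pair = [&](const Atoms &A, int i, const Atoms &B, int j) {
    double rmin = A.rmin_half[i] + B.rmin_half[j];
    double r2 = dist2(A, i, B, j);
    if (r2 >= rmin * rmin) return 0.0;
    double r = std::sqrt(r2);
    if (r < p.clash_dist) return p.clash_energy;
    double eps = std::sqrt(A.eps[i] * B.eps[j]);
    double sr2 = (rmin / r) * (rmin / r);
    double sr6 = sr2 * sr2 * sr2;
    double e = eps * (sr6 * sr6 - 2.0 * sr6) + eps;
    return e > p.clash_energy ? p.clash_energy : e;
  };
  auto intra_atom = [&](int i) {  // peptide atom i vs all other pep atoms
    double e = 0.0;
    for (int j = 0; j < P.n; ++j) {
      if (j == i || pexcl[i][j]) continue;
      e += wca_pair(P, i, P, j);
    }
    return 0.5 * e;  // pairs are visited twice when summed over all i
  };
  auto intra_total = [&]() {
    double e = 0.0;
    for (int i = 0; i < P.n; ++i) e += intra_atom(i);
    return e;
  };
  // receptor flexible-sidechain vs rest-of-receptor (repulsive only)
  auto recrec_atom = [&](int i) {
    double e = 0.0;
    for (int j = 0; j < R.n; ++j) {
      if (j == i || rexcl[i][j]) continue;
      if (is_flex[j] && j < i) continue;  // avoid double count among flex
      e += wca_pair(R, i, R, j);
    }
    return e;
  };
  auto recrec_total = [&]() {
    double e = 0.0;
    for (int k = 0; k < rec_flex.size(); ++k) e += recrec_atom(rec_flex[k]);
    return e;
  };
  auto inter_total = [&](int *n_within, bool *clash, int *hb) {
    double e = 0.0;
    for (int i = 0; i < P.n; ++i)
      e += inter_atom(P, i, R, p, n_within, clash, hb);
    return e;
  };
  auto tether_total = [&]() {
    double e = 0.0;
    for (int k = 0; k < anchor_idx.size(); ++k) {
      int i = anchor_idx[k];
      double dx = P.x[i] - anchor_ref(k, 0), dy = P.y[i] - anchor_ref(k, 1),
             dz = P.z[i] - anchor_ref(k, 2);
      e += dx * dx + dy * dy + dz * dz;
    }
    return p.k_tether * e;
  };
  auto torsion_strain = [&]() {
    double e = 0.0;
    for (int k = 0; k < nt; ++k)
      e += p.k_tor * (1.0 - std::cos((tors[k].chi - tors[k].chi0) *
                                     M_PI / 180.0));
    return e;
  };

  // receptor self-sterics are reported relative to the initial rotamers
  // (an unmoved receptor contributes zero strain); annealing stages pass
  // the first stage's reference through `recrec_ref` so all stages share
  // one energy frame
  double e_recrec0 = par.containsElementNamed("recrec_ref") &&
                             R_finite((double)par["recrec_ref"])
                         ? (double)par["recrec_ref"]
                         : recrec_total();
  double e_inter = inter_total(nullptr, nullptr, nullptr);
  double total = e_inter + intra_total() + torsion_strain() +
                 tether_total();

  double best_total = total;
  Atoms bestP = P, bestR = R;
  std::vector<double> best_chis(nt), cur_deltas;
  for (int k = 0; k < nt; ++k) best_chis[k] = tors[k].chi;

  Prng rng(seed);
  int accepted = 0, uphill = 0;
  std::vector<double> trace_it, trace_e;
  trace_it.push_back(0.0); trace_e.push_back(best_total);

  std::vector<double> sx, sy, sz;  // saved coords of moving atoms
  for (int it = 1; it <= iterations; ++it) {
    if (nt == 0) break;
    // pick torsion by weight
    double u = rng.unif() * wsum, acc = 0.0;
    int k = nt - 1;
    for (int m = 0; m < nt; ++m) {
      acc += tors[m].weight;
      if (u < acc) { k = m; break; }
    }
    Tors &t = tors[k];
    Atoms &A = (t.which == 0) ? P : R;
    double delta = (2.0 * rng.unif() - 1.0) * p.max_step;

    // old energy contributions of the moved atoms
    double e_old = 0.0;
    if (t.which == 0) {
      for (int i : t.moving) {
        e_old += inter_atom(P, i, R, p, nullptr, nullptr, nullptr);
        for (int j = 0; j < P.n; ++j) {  // intra vs non-moving only
          if (j == i || pexcl[i][j]) continue;
          bool j_moves = false;
          for (int mm : t.moving) if (mm == j) { j_moves = true; break; }
          if (j_moves) continue;
          e_old += wca_pair(P, i, P, j);
        }
        for (int a = 0; a < anchor_idx.size(); ++a)
          if (anchor_idx[a] == i) {
            double dx = P.x[i] - anchor_ref(a, 0),
                   dy = P.y[i] - anchor_ref(a, 1),
                   dz = P.z[i] - anchor_ref(a, 2);
            e_old += p.k_tether * (dx * dx + dy * dy + dz * dz);
          }
      }
    } else {
      for (int i : t.moving) {
        e_old += inter_atom(R, i, P, p, nullptr, nullptr, nullptr);
        for (int j = 0; j < R.n; ++j) {
          if (j == i || rexcl[i][j]) continue;
          bool j_moves = false;
          for (int mm : t.moving) if (mm == j) { j_moves = true; break; }
          if (j_moves) continue;
          e_old += wca_pair(R, i, R, j);
        }
      }
    }
    double chi_old = t.chi;
    e_old += p.k_tor * (1.0 - std::cos((chi_old - t.chi0) * M_PI / 180.0));

    // save and move
    size_t nm = t.moving.size();
    sx.resize(nm); sy.resize(nm); sz.resize(nm);
    for (size_t m = 0; m < nm; ++m) {
      sx[m] = A.x[t.moving[m]]; sy[m] = A.y[t.moving[m]];
      sz[m] = A.z[t.moving[m]];
    }
    rotate(A, t.moving, t.ai, t.aj, delta);
    double chi_new = chi_old + delta;
    if (chi_new > 180.0) chi_new -= 360.0;
    if (chi_new <= -180.0) chi_new += 360.0;

    // new energy contributions
    double e_new = 0.0;
    if (t.which == 0) {
      for (int i : t.moving) {
        e_new += inter_atom(P, i, R, p, nullptr, nullptr, nullptr);
        for (int j = 0; j < P.n; ++j) {
          if (j == i || pexcl[i][j]) continue;
          bool j_moves = false;
          for (int mm : t.moving) if (mm == j) { j_moves = true; break; }
          if (j_moves) continue;
          e_new += wca_pair(P, i, P, j);
        }
        for (int a = 0; a < anchor_idx.size(); ++a)
          if (anchor_idx[a] == i) {
            double dx = P.x[i] - anchor_ref(a, 0),
                   dy = P.y[i] - anchor_ref(a, 1),
                   dz = P.z[i] - anchor_ref(a, 2);
            e_new += p.k_tether * (dx * dx + dy * dy + dz * dz);
          }
      }
    } else {
      for (int i : t.moving) {
        e_new += inter_atom(R, i, P, p, nullptr, nullptr, nullptr);
        for (int j = 0; j < R.n; ++j) {
          if (j == i || rexcl[i][j]) continue;
          bool j_moves = false;
          for (int mm : t.moving) if (mm == j) { j_moves = true; break; }
          if (j_moves) continue;
          e_new += wca_pair(R, i, R, j);
        }
      }
    }
    e_new += p.k_tor * (1.0 - std::cos((chi_new - t.chi0) * M_PI / 180.0));

    double dE = e_new - e_old;
    bool accept = dE <= 0.0 ||
                  (p.kT > 0.0 && rng.unif() < std::exp(-dE / p.kT));
    if (accept) {
      ++accepted;
      if (dE > 1e-12) ++uphill;
      t.chi = chi_new;
      total += dE;
      if (total < best_total) {
        best_total = total;
        bestP = P; bestR = R;
        for (int m = 0; m < nt; ++m) best_chis[m] = tors[m].chi;
      }
    } else {
      for (size_t m = 0; m < nm; ++m) {
        A.x[t.moving[m]] = sx[m]; A.y[t.moving[m]] = sy[m];
        A.z[t.moving[m]] = sz[m];
      }
    }
    if (trace_interval > 0 && it % trace_interval == 0) {
      trace_it.push_back((double)it);
      trace_e.push_back(best_total);
    }
  }

  // exact decomposition at the best pose (avoids incremental drift)
  P = bestP; R = bestR;
  for (int k = 0; k < nt; ++k) tors[k].chi = best_chis[k];
  int n_within = 0, hb_count = 0;
  bool clash = false;
  double b_inter = inter_total(&n_within, &clash, &hb_count);
  double b_intra = intra_total();
  double b_recrec = recrec_total() - e_recrec0;
  double b_tor = torsion_strain();
  double b_teth = tether_total();
  double strain = b_tor + b_intra + b_recrec;
  double e_bind = (n_within == 0) ? 0.0 : (b_inter + strain);

  NumericMatrix outP(P.n, 3), outR(R.n, 3);
  for (int i = 0; i < P.n; ++i) {
    outP(i, 0) = P.x[i]; outP(i, 1) = P.y[i]; outP(i, 2) = P.z[i];
  }
  for (int i = 0; i < R.n; ++i) {
    outR(i, 0) = R.x[i]; outR(i, 1) = R.y[i]; outR(i, 2) = R.z[i];
  }
  NumericMatrix trace(trace_it.size(), 2);
  for (size_t i = 0; i < trace_it.size(); ++i) {
    trace(i, 0) = trace_it[i]; trace(i, 1) = trace_e[i];
  }

  return List::create(
      _["pep_xyz"] = outP, _["rec_xyz"] = outR,
      _["E_bind"] = e_bind, _["E_total"] = b_inter + strain + b_teth,
      _["inter"] = b_inter, _["strain"] = strain, _["tether"] = b_teth,
      _["n_hb"] = hb_count, _["clash"] = clash, _["separated"] = n_within == 0,
      _["accepted"] = accepted, _["uphill_accepted"] = uphill,
      _["recrec0"] = e_recrec0,
      _["chis"] = NumericVector(best_chis.begin(), best_chis.end()),
      _["trace"] = trace);
}
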