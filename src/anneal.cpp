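#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Deterministic xorshift64* generator so annealing trajectories are a pure
// function of the integer seed, independent of R's RNG state.
struct XorShift {
  uint64_t s;
  explicit XorShift(int seed) {
    s = static_cast<uint64_t>(seed) * 2685821657736338717ULL + 1442695040888963407ULL;
    for (int i = 0; i < 8; ++i) next();
  }
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 2685821657736338717ULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

static inline double dist3(const double* x, int i, int j, int n) {
  double dx = x[i] - x[j], dy = x[i + n] - x[j + n], dz = x[i + 2 * n] - x[j + 2 * n];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static inline double dist3sq(const double* x, int i, int j, int n) {
  double dx = x[i] - x[j], dy = x[i + n] - x[j + n], dz = x[i + 2 * n] - x[j + 2 * n];
  return dx * dx + dy * dy + dz * dz;
}

struct Terms {
  int n;
  std::vector<int> bi, bj; std::vector<double> bt;       // chain bonds
  std::vector<int> ri, rj; std::vector<double> rlo, rup; // NOE bounds
  std::vector<int> si, sj; double ss_target;             // disulfide bonds
  double w_noe, w_chain, w_rep, w_ss, rep_dist;
  std::vector<char> excl;                                // n*n repulsion exclusion
  // per-particle adjacency into the term vectors
  std::vector<std::vector<int>> badj, radj, sadj;

  Terms(int n_, IntegerMatrix bonds, NumericVector bond_t,
        IntegerMatrix rest, NumericVector lo, NumericVector up,
        IntegerMatrix ss, double ss_t, NumericVector w, double repd)
      : n(n_), ss_target(ss_t), rep_dist(repd) {
    w_noe = w[0]; w_chain = w[1]; w_rep = w[2]; w_ss = w[3];
    excl.assign((size_t)n * n, 0);
    badj.resize(n); radj.resize(n); sadj.resize(n);
    for (int k = 0; k < bonds.nrow(); ++k) {
      int i = bonds(k, 0), j = bonds(k, 1);
      bi.push_back(i); bj.push_back(j); bt.push_back(bond_t[k]);
      badj[i].push_back(k); badj[j].push_back(k);
      excl[(size_t)i * n + j] = excl[(size_t)j * n + i] = 1;
    }
    for (int k = 0; k < rest.nrow(); ++k) {
      int i = rest(k, 0), j = rest(k, 1);
      ri.push_back(i); rj.push_back(j); rlo.push_back(lo[k]); rup.push_back(up[k]);
      radj[i].push_back(k); radj[j].push_back(k);
    }
    for (int k = 0; k < ss.nrow(); ++k) {
      int i = ss(k, 0), j = ss(k, 1);
      si.push_back(i); sj.push_back(j);
      sadj[i].push_back(k); sadj[j].push_back(k);
      excl[(size_t)i * n + j] = excl[(size_t)j * n + i] = 1;
    }
  }

  // energy of all terms touching particle p; squared-distance short-circuits
  // avoid sqrt for the (common) satisfied restraints and non-clashing pairs
  double local(const double* x, int p) const {
    double e = 0.0;
    double rep2 = rep_dist * rep_dist;
    for (int k : badj[p]) {
      double d = dist3(x, bi[k], bj[k], n) - bt[k];
      e += w_chain * d * d;
    }
    for (int k : radj[p]) {
      double d2 = dist3sq(x, ri[k], rj[k], n);
      if (d2 > rup[k] * rup[k]) {
        double v = std::sqrt(d2) - rup[k]; e += w_noe * v * v;
      } else if (d2 < rlo[k] * rlo[k]) {
        double v = rlo[k] - std::sqrt(d2); e += w_noe * v * v;
      }
    }
    for (int k : sadj[p]) {
      double d = dist3(x, si[k], sj[k], n) - ss_target;
      e += w_ss * d * d;
    }
    const char* ex = &excl[(size_t)p * n];
    for (int q = 0; q < n; ++q) {
      if (q == p || ex[q]) continue;
      double d2 = dist3sq(x, p, q, n);
      if (d2 < rep2) { double v = rep_dist - std::sqrt(d2); e += w_rep * v * v; }
    }
    return e;
  }

  double total(const double* x) const {
    double e = 0.0;
    for (size_t k = 0; k < bi.size(); ++k) {
      double d = dist3(x, bi[k], bj[k], n) - bt[k];
      e += w_chain * d * d;
    }
    for (size_t k = 0; k < ri.size(); ++k) {
      double d = dist3(x, ri[k], rj[k], n);
      if (d > rup[k]) { double v = d - rup[k]; e += w_noe * v * v; }
      else if (d < rlo[k]) { double v = rlo[k] - d; e += w_noe * v * v; }
    }
    for (size_t k = 0; k < si.size(); ++k) {
      double d = dist3(x, si[k], sj[k], n) - ss_target;
      e += w_ss * d * d;
    }
    for (int p = 0; p < n; ++p)
      for (int q = p + 1; q < n; ++q) {
        if (excl[(size_t)p * n + q]) continue;
        double d = dist3(x, p, q, n);
        if (d < rep_dist) { double v = rep_dist - d; e += w_rep * v * v; }
      }
    return e;
  }
};

// [[Rcpp::export(name = ".cg_energy")]]
double cg_energy(NumericMatrix coords, IntegerMatrix bonds, NumericVector bond_t,
                 IntegerMatrix rest, NumericVector rlo, NumericVector rup,
                 IntegerMatrix ss, double ss_target, NumericVector weights,
                 double rep_dist) {
  Terms t(coords.nrow(), bonds, bond_t, rest, rlo, rup, ss, ss_target, weights, rep_dist);
  return t.total(REAL(coords));
}

// Metropolis single-particle annealing with geometric cooling; returns the
// best-seen configuration.
// [[Rcpp::export(name = ".cg_anneal")]]
List cg_anneal(NumericMatrix coords, IntegerMatrix bonds, NumericVector bond_t,
               IntegerMatrix rest, NumericVector rlo, NumericVector rup,
               IntegerMatrix ss, double ss_target, NumericVector weights,
               double rep_dist, double t_start, double t_end, int n_steps,
               double move_max, double move_min, int seed) {
  int n = coords.nrow();
  Terms terms(n, bonds, bond_t, rest, rlo, rup, ss, ss_target, weights, rep_dist);
  XorShift rng(seed);

  NumericMatrix cur = clone(coords);
  double* x = REAL(cur);
  double e_cur = terms.total(x);
  NumericMatrix best = clone(cur);
  double e_best = e_cur;

  double cool = (n_steps > 1) ? std::pow(t_end / t_start, 1.0 / (n_steps - 1)) : 1.0;
  double temp = t_start;
  double lt0 = std::log(t_start), lt1 = std::log(t_end);

  for (int step = 0; step < n_steps; ++step) {
    // move amplitude follows the cooling schedule on a log scale
    double f = (lt0 == lt1) ? 0.0 : (std::log(temp) - lt1) / (lt0 - lt1);
    double amp = move_min + (move_max - move_min) * f;
    for (int p = 0; p < n; ++p) {
      double old0 = x[p], old1 = x[p + n], old2 = x[p + 2 * n];
      double e0 = terms.local(x, p);
      x[p] += amp * (2.0 * rng.unif() - 1.0);
      x[p + n] += amp * (2.0 * rng.unif() - 1.0);
      x[p + 2 * n] += amp * (2.0 * rng.unif() - 1.0);
      double de = terms.local(x, p) - e0;
      bool accept = de <= 0.0 || rng.unif() < std::exp(-de / temp);
      if (accept) {
        e_cur += de;
        if (e_cur < e_best) {
          e_best = e_cur;
          std::copy(x, x + 3 * n, REAL(best));
        }
      } else {
        x[p] = old0; x[p + n] = old1; x[p + 2 * n] = old2;
      }
    }
    temp *= cool;
  }
  // guard against drift of the incrementally updated energy
  double e_best_exact = terms.total(REAL(best));
  return List::create(_["coords"] = best, _["energy"] = e_best_exact,
                      _["final_energy"] = terms.total(x));
}
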