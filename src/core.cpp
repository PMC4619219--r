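#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>
using namespace Rcpp;

// Coordinates are held point-major (x,y,z per locus) in a flat vector for
// cache locality; freq is the full symmetric n x n matrix, flattened
// column-major (symmetry makes the order irrelevant).

namespace {

struct Thresholds {
  double contact_d2;  // squared contact distance threshold (um^2)
  double max_d2;      // squared maximum adjacent-distance restraint
  double min_d2;      // squared minimum adjacent-distance restraint
};

struct Weights {
  double cs, ns, fi, ms;
};

struct Counts {
  long c1, c2, c3, c4;   // contact sat / unsat, non-contact sat / unsat
  double if_sat, if_tot; // frequency-weighted contact satisfaction
  long ms_sat;           // adjacent pairs within [min_d2, max_d2]
  int n;
};

inline double sqdist(const std::vector<double>& X, int i, int j) {
  double dx = X[3 * i]     - X[3 * j];
  double dy = X[3 * i + 1] - X[3 * j + 1];
  double dz = X[3 * i + 2] - X[3 * j + 2];
  return dx * dx + dy * dy + dz * dz;
}

// All unordered off-diagonal pairs are scored; contact satisfied when
// d^2 <= contact_d2 (closed), non-contact satisfied when d^2 > contact_d2.
Counts count_all(const std::vector<double>& X, int n,
                 const std::vector<double>& F, const Thresholds& t) {
  Counts c = {0, 0, 0, 0, 0.0, 0.0, 0, n};
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d2 = sqdist(X, i, j);
      double f = F[(size_t)i * n + j];
      if (f > 0) {
        c.if_tot += f;
        if (d2 <= t.contact_d2) { ++c.c1; c.if_sat += f; } else ++c.c2;
      } else {
        if (d2 > t.contact_d2) ++c.c3; else ++c.c4;
      }
    }
    double b2 = sqdist(X, i, i + 1);
    if (b2 >= t.min_d2 && b2 <= t.max_d2) ++c.ms_sat;
  }
  return c;
}

// Weighted average of the defined sub-scores; undefined ones (no contact
// pairs, no non-contacts, zero total IF, n < 2) drop out with their weight.
double total_from_counts(const Counts& c, const Weights& w) {
  double num = 0.0, den = 0.0;
  if (c.c1 + c.c2 > 0) { num += w.cs * 100.0 * c.c1 / (c.c1 + c.c2); den += w.cs; }
  if (c.c3 + c.c4 > 0) { num += w.ns * 100.0 * c.c3 / (c.c3 + c.c4); den += w.ns; }
  if (c.if_tot > 0)    { num += w.fi * 100.0 * c.if_sat / c.if_tot;  den += w.fi; }
  if (c.n >= 2)        { num += w.ms * 100.0 * c.ms_sat / c.n;       den += w.ms; }
  if (den <= 0) stop("all sub-scores are undefined for this instance");
  return num / den;
}

double total_score(const std::vector<double>& X, int n,
                   const std::vector<double>& F, const Thresholds& t,
                   const Weights& w) {
  Counts c = count_all(X, n, F, t);
  return total_from_counts(c, w);
}

// Isotropic direction (normalized standard-normal triple) scaled by a
// uniform length on [0, 1) um -- the move law shared by growth,
// adaptation and mutation.
inline void random_vector(double v[3]) {
  double x, y, z, nrm;
  do {
    x = norm_rand(); y = norm_rand(); z = norm_rand();
    nrm = std::sqrt(x * x + y * y + z * z);
  } while (nrm < 1e-12);
  double len = unif_rand();
  v[0] = x / nrm * len; v[1] = y / nrm * len; v[2] = z / nrm * len;
}

inline void translate_suffix(std::vector<double>& X, int n, int from,
                             const double v[3], double sign) {
  for (int k = from; k < n; ++k) {
    X[3 * k]     += sign * v[0];
    X[3 * k + 1] += sign * v[1];
    X[3 * k + 2] += sign * v[2];
  }
}

std::vector<double> as_flat_coords(const NumericMatrix& coords) {
  int n = coords.nrow();
  std::vector<double> X((size_t)3 * n);
  for (int i = 0; i < n; ++i) {
    X[3 * i] = coords(i, 0); X[3 * i + 1] = coords(i, 1); X[3 * i + 2] = coords(i, 2);
  }
  return X;
}

std::vector<double> as_flat_freq(const NumericMatrix& freq) {
  return std::vector<double>(freq.begin(), freq.end());
}

NumericMatrix to_matrix(const std::vector<double>& X, int n) {
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = X[3 * i]; out(i, 1) = X[3 * i + 1]; out(i, 2) = X[3 * i + 2];
  }
  return out;
}

// One adaptation move at locus i: `trials` candidate suffix translations,
// keep the best only when it strictly improves the current total score
// (greedy) or unconditionally (SA proposal construction).
bool move_at(std::vector<double>& X, int n, const std::vector<double>& F,
             const Thresholds& t, const Weights& w, int i, int trials,
             bool greedy, double& cur_score) {
  double best[3] = {0, 0, 0};
  double best_score = R_NegInf;
  double v[3];
  // exact restore of the suffix between trials (adding then subtracting
  // the trial vector would leave rounding residue on rejected moves)
  std::vector<double> saved(X.begin() + 3 * i, X.end());
  for (int k = 0; k < trials; ++k) {
    random_vector(v);
    translate_suffix(X, n, i, v, +1.0);
    double s = total_score(X, n, F, t, w);
    std::copy(saved.begin(), saved.end(), X.begin() + 3 * i);
    if (s > best_score) {
      best_score = s; best[0] = v[0]; best[1] = v[1]; best[2] = v[2];
    }
  }
  if (greedy && !(best_score > cur_score)) return false;
  translate_suffix(X, n, i, best, +1.0);
  cur_score = best_score;
  return true;
}

// One iteration: attempt a move at every locus, loci visited in random order.
double pass_over(std::vector<double>& X, int n, const std::vector<double>& F,
                 const Thresholds& t, const Weights& w, int trials,
                 bool greedy, double cur_score) {
  IntegerVector order = Rcpp::sample(n, n, false);  // 1-based, uses R RNG
  for (int k = 0; k < n; ++k)
    move_at(X, n, F, t, w, order[k] - 1, trials, greedy, cur_score);
  return cur_score;
}

Thresholds as_thresholds(double contact_d2, double max_d2, double min_d2) {
  Thresholds t = {contact_d2, max_d2, min_d2};
  return t;
}

Weights as_weights(const NumericVector& w) {
  Weights out = {w[0], w[1], w[2], w[3]};
  return out;
}

} // namespace

// [[Rcpp::export]]
List cpp_score_counts(NumericMatrix coords, NumericMatrix freq,
                      double contact_d2, double max_d2, double min_d2) {
  int n = coords.nrow();
  std::vector<double> X = as_flat_coords(coords), F = as_flat_freq(freq);
  Thresholds t = as_thresholds(contact_d2, max_d2, min_d2);
  Counts c = count_all(X, n, F, t);
  return List::create(_["c1"] = (double)c.c1, _["c2"] = (double)c.c2,
                      _["c3"] = (double)c.c3, _["c4"] = (double)c.c4,
                      _["if_sat"] = c.if_sat, _["if_tot"] = c.if_tot,
                      _["ms_sat"] = (double)c.ms_sat, _["n"] = n);
}

// [[Rcpp::export]]
double cpp_total_score(NumericMatrix coords, NumericMatrix freq,
                       double contact_d2, double max_d2, double min_d2,
                       NumericVector weights) {
  std::vector<double> X = as_flat_coords(coords), F = as_flat_freq(freq);
  Thresholds t = as_thresholds(contact_d2, max_d2, min_d2);
  return total_score(X, coords.nrow(), F, t, as_weights(weights));
}

// [[Rcpp::export]]
List cpp_pair_labels(NumericMatrix coords, NumericMatrix freq,
                     double contact_d2) {
  int n = coords.nrow();
  std::vector<double> X = as_flat_coords(coords);
  IntegerMatrix labels(n, n);
  NumericMatrix d2m(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d2 = sqdist(X, i, j);
      int lab;
      if (freq(i, j) > 0) lab = (d2 <= contact_d2) ? 1 : 2;
      else                lab = (d2 >  contact_d2) ? 3 : 4;
      labels(i, j) = labels(j, i) = lab;
      d2m(i, j) = d2m(j, i) = d2;
    }
  }
  return List::create(_["labels"] = labels, _["d2"] = d2m);
}

// [[Rcpp::export]]
List cpp_adaptation_move(NumericMatrix coords, NumericMatrix freq,
                         double contact_d2, double max_d2, double min_d2,
                         NumericVector weights, int i, int trials) {
  int n = coords.nrow();
  if (i < 0 || i >= n) stop("locus index out of range");
  std::vector<double> X = as_flat_coords(coords), F = as_flat_freq(freq);
  Thresholds t = as_thresholds(contact_d2, max_d2, min_d2);
  Weights w = as_weights(weights);
  double cur = total_score(X, n, F, t, w);
  bool acc = move_at(X, n, F, t, w, i, trials, true, cur);
  return List::create(_["coords"] = to_matrix(X, n), _["accepted"] = acc,
                      _["score"] = cur);
}

// [[Rcpp::export]]
List cpp_adaptation_pass(NumericMatrix coords, NumericMatrix freq,
                         double contact_d2, double max_d2, double min_d2,
                         NumericVector weights, int trials, bool greedy) {
  int n = coords.nrow();
  std::vector<double> X = as_flat_coords(coords), F = as_flat_freq(freq);
  Thresholds t = as_thresholds(contact_d2, max_d2, min_d2);
  Weights w = as_weights(weights);
  double cur = total_score(X, n, F, t, w);
  cur = pass_over(X, n, F, t, w, trials, greedy, cur);
  return List::create(_["coords"] = to_matrix(X, n), _["score"] = cur);
}

// Full adaptation stage: `iters` greedy iterations; a snapshot is taken
// after every score-improving iteration, the ensemble keeping the
// `ensemble_max` most recent (equivalently highest-scoring, since the
// greedy score is non-decreasing).
// [[Rcpp::export]]
List cpp_adaptation_run(NumericMatrix coords, NumericMatrix freq,
                        double contact_d2, double max_d2, double min_d2,
                        NumericVector weights, int iters, int trials,
                        int ensemble_max) {
  int n = coords.nrow();
  std::vector<double> X = as_flat_coords(coords), F = as_flat_freq(freq);
  Thresholds t = as_thresholds(contact_d2, max_d2, min_d2);
  Weights w = as_weights(weights);
  double cur = total_score(X, n, F, t, w);

  std::deque<std::vector<double> > snaps;
  std::deque<double> snap_scores;
  NumericVector trace(iters);

  for (int it = 0; it < iters; ++it) {
    double before = cur;
    cur = pass_over(X, n, F, t, w, trials, true, cur);
    if (cur > before) {
      snaps.push_back(X);
      snap_scores.push_back(cur);
      if ((int)snaps.size() > ensemble_max) {
        snaps.pop_front();
        snap_scores.pop_front();
      }
    }
    trace[it] = cur;
  }
  if (snaps.empty()) {  // no improving iteration: ensemble is the input
    snaps.push_back(X);
    snap_scores.push_back(cur);
  }

  List members(snaps.size());
  NumericVector scores(snaps.size());
  for (size_t k = 0; k < snaps.size(); ++k) {
    members[k] = to_matrix(snaps[k], n);
    scores[k] = snap_scores[k];
  }
  return List::create(_["members"] = members, _["scores"] = scores,
                      _["coords"] = to_matrix(X, n), _["score"] = cur,
                      _["trace"] = trace);
}

// Score-gated single-point mutations: each displacement moves one locus
// only (no suffix propagation) and is kept iff the total score strictly
// increases.
// [[Rcpp::export]]
List cpp_ga_mutate(NumericMatrix coords, NumericMatrix freq,
                   double contact_d2, double max_d2, double min_d2,
                   NumericVector weights, int n_mut) {
  int n = coords.nrow();
  std::vector<double> X = as_flat_coords(coords), F = as_flat_freq(freq);
  Thresholds t = as_thresholds(contact_d2, max_d2, min_d2);
  Weights w = as_weights(weights);
  double cur = total_score(X, n, F, t, w);
  double v[3];
  for (int k = 0; k < n_mut; ++k) {
    int i = (int)(unif_rand() * n);
    if (i >= n) i = n - 1;
    random_vector(v);
    X[3 * i] += v[0]; X[3 * i + 1] += v[1]; X[3 * i + 2] += v[2];
    double s = total_score(X, n, F, t, w);
    if (s > cur) {
      cur = s;
    } else {
      X[3 * i] -= v[0]; X[3 * i + 1] -= v[1]; X[3 * i + 2] -= v[2];
    }
  }
  return List::create(_["coords"] = to_matrix(X, n), _["score"] = cur);
}

// Growth initialization: R_0 at the origin, R_i = R_{i-1} + r with r a
// random vector of length in [0, 1) um.
// [[Rcpp::export]]
NumericMatrix cpp_growth_init(int n) {
  std::vector<double> X((size_t)3 * n, 0.0);
  double v[3];
  for (int i = 1; i < n; ++i) {
    random_vector(v);
    X[3 * i]     = X[3 * (i - 1)]     + v[0];
    X[3 * i + 1] = X[3 * (i - 1) + 1] + v[1];
    X[3 * i + 2] = X[3 * (i - 1) + 2] + v[2];
  }
  return to_matrix(X, n);
}
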