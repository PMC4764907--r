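#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise square-root Jensen-Shannon distance between rows of a
// probability matrix (rows already zero-replaced and renormalized in R).
// KLD uses the natural log, so entries are bounded by sqrt(ln 2).
// [[Rcpp::export(name = ".jsd_matrix_cpp")]]
NumericMatrix jsd_matrix_cpp(NumericMatrix p) {
  int n = p.nrow(), d = p.ncol();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double jsd = 0.0;
      for (int t = 0; t < d; ++t) {
        double pi = p(i, t), pj = p(j, t);
        double m = 0.5 * (pi + pj);
        if (pi > 0.0) jsd += 0.5 * pi * std::log(pi / m);
        if (pj > 0.0) jsd += 0.5 * pj * std::log(pj / m);
      }
      if (jsd < 0.0) jsd = 0.0; // guard against rounding
      double dist = std::sqrt(jsd);
      out(i, j) = dist;
      out(j, i) = dist;
    }
  }
  return out;
}

// Deterministic PAM (k-medoids): greedy BUILD followed by steepest-descent
// SWAP. Ties are broken toward the lowest index, so the result is a pure
// function of the distance matrix. Returns 1-based medoid indices, 1-based
// per-point cluster labels (index into the medoid vector) and the total
// deviation sum_i d(i, medoid(i)).
// [[Rcpp::export(name = ".pam_cpp")]]
List pam_cpp(NumericMatrix d, int k) {
  int n = d.nrow();
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n");
  std::vector<int> medoids;
  std::vector<bool> is_medoid(n, false);
  std::vector<double> nearest(n, R_PosInf);

  // BUILD: first medoid minimizes total distance; each further medoid
  // maximally reduces the total deviation.
  for (int step = 0; step < k; ++step) {
    int best = -1;
    double best_total = R_PosInf;
    for (int c = 0; c < n; ++c) {
      if (is_medoid[c]) continue;
      double total = 0.0;
      for (int i = 0; i < n; ++i)
        total += std::min(nearest[i], d(i, c));
      // ascending scan + strict improvement = lowest-index tie-break
      if (total < best_total - 1e-12) {
        best_total = total;
        best = c;
      }
    }
    is_medoid[best] = true;
    medoids.push_back(best);
    for (int i = 0; i < n; ++i)
      nearest[i] = std::min(nearest[i], d(i, best));
  }

  // SWAP: repeatedly apply the single best (medoid, non-medoid) exchange
  // while it strictly decreases the total deviation. Each candidate swap's
  // deviation change is computed in O(n) from per-point nearest and
  // second-nearest medoid distances.
  std::vector<double> d1(n), d2(n);
  std::vector<int> near1(n);
  bool improved = true;
  while (improved) {
    improved = false;
    for (int i = 0; i < n; ++i) {
      double b1 = R_PosInf, b2 = R_PosInf;
      int m1 = -1;
      for (size_t j = 0; j < medoids.size(); ++j) {
        double v = d(i, medoids[j]);
        if (v < b1) {
          b2 = b1;
          b1 = v;
          m1 = (int)j;
        } else if (v < b2) {
          b2 = v;
        }
      }
      d1[i] = b1;
      d2[i] = b2;
      near1[i] = m1;
    }
    int best_m = -1, best_h = -1;
    double best_delta = -1e-12;
    for (size_t mi = 0; mi < medoids.size(); ++mi) {
      for (int h = 0; h < n; ++h) {
        if (is_medoid[h]) continue;
        double delta = 0.0;
        for (int i = 0; i < n; ++i) {
          double dih = d(i, h);
          if (near1[i] == (int)mi) {
            delta += std::min(d2[i], dih) - d1[i];
          } else if (dih < d1[i]) {
            delta += dih - d1[i];
          }
        }
        if (delta < best_delta) {
          best_delta = delta;
          best_m = (int)mi;
          best_h = h;
        }
      }
    }
    if (best_m >= 0) {
      is_medoid[medoids[best_m]] = false;
      medoids[best_m] = best_h;
      is_medoid[best_h] = true;
      improved = true;
    }
  }

  std::sort(medoids.begin(), medoids.end());
  IntegerVector med_out(k);
  for (int j = 0; j < k; ++j) med_out[j] = medoids[j] + 1;
  IntegerVector labels(n);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    int best_j = 0;
    double mn = d(i, medoids[0]);
    for (int j = 1; j < k; ++j) {
      double v = d(i, medoids[j]);
      if (v < mn) { // strict: ties go to the lowest medoid index
        mn = v;
        best_j = j;
      }
    }
    labels[i] = best_j + 1;
    total += mn;
  }
  return List::create(
    _["medoids"] = med_out,
    _["labels"] = labels,
    _["total_deviation"] = total
  );
}
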