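#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Seeded watershed (priority flood) on an energy image.
//
// labels0: 0 = unlabelled (growable), -1 = outside the growth mask,
//          >0 = seed labels. Flooding uses the morphological watershed
//          semantics: the priority of a pixel is the maximum energy along
//          its growth path (the flood level), so a region must cross its
//          own membrane crest before it can descend into a neighbouring
//          valley. Equal flood levels (plateaus) are resolved by the
//          Euclidean distance from the pixel to the seed of the claiming
//          region, so a plateau contested by several regions splits along
//          the exact midline between their seeds; remaining ties fall to
//          arrival order (FIFO), then lexicographic linear index; fully
//          deterministic. 4-connected. seed_y/seed_x hold the (fractional,
//          1-based) seed coordinates indexed by label.
// ---------------------------------------------------------------------------

struct WsNode {
  double energy;  // flood level: max energy along the growth path
  double tie;     // distance from the pixel to the claiming region's seed
  long seq;       // insertion order, FIFO
  int idx;        // linear index, final tie-break
  int label;
};

struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.energy != b.energy) return a.energy > b.energy; // min-heap
    if (a.tie != b.tie) return a.tie > b.tie;
    if (a.seq != b.seq) return a.seq > b.seq;
    return a.idx > b.idx;
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix energy, NumericVector seed_y,
                            NumericVector seed_x, IntegerMatrix labels0) {
  int nr = energy.nrow(), nc = energy.ncol();
  if (labels0.nrow() != nr || labels0.ncol() != nc)
    stop("energy and label images must have identical dimensions");
  IntegerMatrix lab(clone(labels0));
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;

  auto seed_dist = [&](int r, int c, int label) {
    double dy = (r + 1) - seed_y[label - 1];
    double dx = (c + 1) - seed_x[label - 1];
    return std::sqrt(dy * dy + dx * dx);
  };

  // neighbours of seed pixels enter the queue first
  int dr[4] = {-1, 1, 0, 0};
  int dc[4] = {0, 0, -1, 1};
  long seq = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (lab(r, c) > 0) {
        for (int k = 0; k < 4; ++k) {
          int r2 = r + dr[k], c2 = c + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (lab(r2, c2) == 0)
            pq.push({energy(r2, c2), seed_dist(r2, c2, lab(r, c)), seq++,
                     r2 + nr * c2, lab(r, c)});
        }
      }
    }
  }
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    int r = nd.idx % nr, c = nd.idx / nr;
    if (lab(r, c) != 0) continue; // already claimed
    lab(r, c) = nd.label;
    for (int k = 0; k < 4; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (lab(r2, c2) == 0)
        pq.push({std::max(nd.energy, energy(r2, c2)),
                 seed_dist(r2, c2, nd.label), seq++,
                 r2 + nr * c2, nd.label});
    }
  }
  for (int i = 0; i < nr * nc; ++i)
    if (lab[i] == -1) lab[i] = 0;
  return lab;
}

// ---------------------------------------------------------------------------
// Two-group log-rank statistic with the hypergeometric tie correction.
// Returns (chisq, observed1, expected1, variance). grp is 0/1.
// ---------------------------------------------------------------------------

static void logrank_core(const std::vector<double>& time,
                         const std::vector<int>& event,
                         const std::vector<int>& grp,
                         double out[4]) {
  int n = (int)time.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return time[a] < time[b];
  });
  double O1 = 0.0, E1 = 0.0, V = 0.0;
  double atrisk = n;
  double atrisk1 = 0;
  for (int i = 0; i < n; ++i) atrisk1 += grp[i];
  int i = 0;
  while (i < n) {
    double t = time[ord[i]];
    int j = i;
    double d = 0, d1 = 0, nties = 0, nties1 = 0;
    while (j < n && time[ord[j]] == t) {
      d += event[ord[j]];
      d1 += event[ord[j]] * grp[ord[j]];
      nties += 1;
      nties1 += grp[ord[j]];
      ++j;
    }
    if (d > 0) {
      double p1 = atrisk1 / atrisk;
      O1 += d1;
      E1 += d * p1;
      if (atrisk > 1)
        V += d * p1 * (1.0 - p1) * (atrisk - d) / (atrisk - 1.0);
    }
    atrisk -= nties;
    atrisk1 -= nties1;
    i = j;
  }
  double chisq = (V > 0) ? (O1 - E1) * (O1 - E1) / V : 0.0;
  out[0] = chisq; out[1] = O1; out[2] = E1; out[3] = V;
}

// [[Rcpp::export]]
NumericVector cpp_logrank(NumericVector time, IntegerVector event,
                          IntegerVector grp) {
  int n = time.size();
  std::vector<double> t(n);
  std::vector<int> e(n), g(n);
  for (int i = 0; i < n; ++i) { t[i] = time[i]; e[i] = event[i]; g[i] = grp[i]; }
  double out[4];
  logrank_core(t, e, g, out);
  return NumericVector::create(_["chisq"] = out[0], _["observed1"] = out[1],
                               _["expected1"] = out[2], _["variance"] = out[3]);
}

// ---------------------------------------------------------------------------
// Cut-point scan: every observed readout value is a candidate cut; patients
// with value >= cut form the positive group. Admissible cuts keep both group
// prevalences >= minprev. target 0 = maximise ORR in the positive group,
// target 1 = maximise the log-rank chi-square. Ties keep the smallest cut
// (candidates are scanned in ascending order with strict improvement).
// Returns (best_cut, best_stat, n_admissible); best_cut = NA if none.
// ---------------------------------------------------------------------------

static void scan_core(const std::vector<double>& values,
                      const std::vector<double>& time,
                      const std::vector<int>& event,
                      const std::vector<int>& resp,
                      int target, double minprev, double out[3]) {
  int n = (int)values.size();
  // candidates: sorted unique observed values; ascending scan with strict
  // improvement keeps the smallest cut on ties
  std::vector<int> vord(n);
  for (int i = 0; i < n; ++i) vord[i] = i;
  std::sort(vord.begin(), vord.end(), [&](int a, int b) {
    return values[a] < values[b];
  });
  // suffix responder counts in value order (for the ORR target)
  std::vector<int> resp_suffix(n + 1, 0);
  for (int i = n - 1; i >= 0; --i)
    resp_suffix[i] = resp_suffix[i + 1] + resp[vord[i]];
  // presort by time once (for the log-rank target)
  std::vector<int> tord(n);
  for (int i = 0; i < n; ++i) tord[i] = i;
  if (target != 0)
    std::sort(tord.begin(), tord.end(), [&](int a, int b) {
      return time[a] < time[b];
    });
  double best_cut = NA_REAL, best_stat = R_NegInf;
  int n_adm = 0;
  for (int ci = 0; ci < n; ++ci) {
    if (ci > 0 && values[vord[ci]] == values[vord[ci - 1]]) continue;
    double cut = values[vord[ci]];
    int npos = n - ci;
    double fpos = (double)npos / n, fneg = (double)(n - npos) / n;
    if (fpos < minprev || fneg < minprev) continue;
    ++n_adm;
    double stat;
    if (target == 0) {
      stat = 100.0 * resp_suffix[ci] / npos;
    } else {
      double O1 = 0.0, E1 = 0.0, V = 0.0;
      double atrisk = n, atrisk1 = npos;
      int i = 0;
      while (i < n) {
        double tcur = time[tord[i]];
        int j = i;
        double d = 0, d1 = 0, nties = 0, nties1 = 0;
        while (j < n && time[tord[j]] == tcur) {
          int g = values[tord[j]] >= cut ? 1 : 0;
          d += event[tord[j]];
          d1 += event[tord[j]] * g;
          nties += 1;
          nties1 += g;
          ++j;
        }
        if (d > 0) {
          double p1 = atrisk1 / atrisk;
          O1 += d1;
          E1 += d * p1;
          if (atrisk > 1)
            V += d * p1 * (1.0 - p1) * (atrisk - d) / (atrisk - 1.0);
        }
        atrisk -= nties;
        atrisk1 -= nties1;
        i = j;
      }
      stat = (V > 0) ? (O1 - E1) * (O1 - E1) / V : 0.0;
    }
    if (stat > best_stat) { best_stat = stat; best_cut = cut; }
  }
  out[0] = best_cut; out[1] = best_stat; out[2] = n_adm;
}

// [[Rcpp::export]]
NumericVector cpp_scan_cutpoints(NumericVector values, NumericVector time,
                                 IntegerVector event, IntegerVector resp,
                                 int target, double minprev) {
  int n = values.size();
  std::vector<double> v(n), t(n);
  std::vector<int> e(n), r(n);
  for (int i = 0; i < n; ++i) {
    v[i] = values[i]; t[i] = time[i]; e[i] = event[i]; r[i] = resp[i];
  }
  double out[3];
  scan_core(v, t, e, r, target, minprev, out);
  return NumericVector::create(_["cut"] = out[0], _["stat"] = out[1],
                               _["n_admissible"] = out[2]);
}

// One cross-validation training fold: draw B bootstrap resamples internally
// from R's RNG stream, optimise the cut on each, and return the modal cut
// (smallest on modal ties); NA if every resample lacks an admissible cut.
// [[Rcpp::export]]
double cpp_fold_modal_cut(NumericVector values, NumericVector time,
                          IntegerVector event, IntegerVector resp,
                          int target, double minprev, int B) {
  int n = values.size();
  std::vector<double> v(n), t(n);
  std::vector<int> e(n), r(n);
  std::vector<double> cuts;
  cuts.reserve(B);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) {
      int j = (int)(R::unif_rand() * n);
      if (j == n) j = n - 1;
      v[i] = values[j]; t[i] = time[j]; e[i] = event[j]; r[i] = resp[j];
    }
    double out[3];
    scan_core(v, t, e, r, target, minprev, out);
    if (!ISNAN(out[0])) cuts.push_back(out[0]);
  }
  if (cuts.empty()) return NA_REAL;
  std::sort(cuts.begin(), cuts.end());
  double best = cuts[0];
  size_t best_count = 0, i = 0;
  while (i < cuts.size()) {
    size_t j = i;
    while (j < cuts.size() && cuts[j] == cuts[i]) ++j;
    if (j - i > best_count) { best_count = j - i; best = cuts[i]; }
    i = j;
  }
  return best;
}

// Bootstrap wrapper: idx is an n x B matrix of 1-based resample indices
// drawn in R (so all randomness stays under R's RNG). Returns the optimal
// cut of each bootstrap sample (NA where no admissible cut exists).
// [[Rcpp::export]]
NumericVector cpp_bootstrap_cuts(NumericVector values, NumericVector time,
                                 IntegerVector event, IntegerVector resp,
                                 int target, double minprev,
                                 IntegerMatrix idx) {
  int n = idx.nrow(), B = idx.ncol();
  NumericVector cuts(B);
  std::vector<double> v(n), t(n);
  std::vector<int> e(n), r(n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) {
      int j = idx(i, b) - 1;
      v[i] = values[j]; t[i] = time[j]; e[i] = event[j]; r[i] = resp[j];
    }
    double out[3];
    scan_core(v, t, e, r, target, minprev, out);
    cuts[b] = out[0];
  }
  return cuts;
}
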