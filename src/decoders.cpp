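#include <Rcpp.h>
using namespace Rcpp;

// Viterbi decoding over k hidden copy-number states with a distance-dependent
// self-transition: stay(d) = 1 - (1 - p_stay) * (1 - exp(-d / D)); the
// remaining mass is split equally over the other k-1 states.
// emis: n x k matrix of log emission densities; dist: n-1 inter-marker gaps.
// log_init: k initial log probabilities. Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector viterbi_decode(NumericMatrix emis, NumericVector dist,
                             NumericVector log_init, double p_stay, double D) {
  const int n = emis.nrow(), k = emis.ncol();
  if (n == 0) return IntegerVector(0);
  NumericMatrix score(n, k);
  IntegerMatrix back(n, k);
  for (int s = 0; s < k; ++s) score(0, s) = log_init[s] + emis(0, s);
  for (int i = 1; i < n; ++i) {
    double stay = 1.0 - (1.0 - p_stay) * (1.0 - std::exp(-dist[i - 1] / D));
    if (stay >= 1.0) stay = 1.0 - 1e-12;
    double lstay = std::log(stay);
    double lmove = std::log((1.0 - stay) / (k - 1));
    for (int s = 0; s < k; ++s) {
      double best = score(i - 1, s) + lstay;
      int arg = s;
      for (int t = 0; t < k; ++t) {
        if (t == s) continue;
        double cand = score(i - 1, t) + lmove;
        if (cand > best) { best = cand; arg = t; }
      }
      score(i, s) = best + emis(i, s);
      back(i, s) = arg;
    }
  }
  IntegerVector path(n);
  int cur = 0;
  for (int s = 1; s < k; ++s) if (score(n - 1, s) > score(n - 1, cur)) cur = s;
  path[n - 1] = cur + 1;
  for (int i = n - 1; i > 0; --i) {
    cur = back(i, cur);
    path[i - 1] = cur + 1;
  }
  return path;
}

// All maximal scoring subsequences of x (Ruzzo & Tompa's linear-time
// algorithm). Returns a 3-column matrix: 1-based start, end, score.
// [[Rcpp::export]]
NumericMatrix maximal_scoring_segments(NumericVector x) {
  const int n = x.size();
  std::vector<int> L, R;
  std::vector<double> Ls, Rs; // cumulative score before L, at R
  double cum = 0.0;
  for (int i = 0; i < n; ++i) {
    if (x[i] <= 0) { cum += x[i]; continue; }
    int l = i, r = i + 1;
    double ls = cum, rs = cum + x[i];
    cum = rs;
    // integrate the new subsequence per Ruzzo-Tompa step 1-4
    for (;;) {
      int j = -1;
      for (int t = (int)L.size() - 1; t >= 0; --t) {
        if (Ls[t] < ls) { j = t; break; }
      }
      if (j < 0) {
        // no such subsequence: all list entries with Ls >= ls are maximal-dead
        L.push_back(l); R.push_back(r); Ls.push_back(ls); Rs.push_back(rs);
        break;
      }
      if (Rs[j] >= rs) {
        L.push_back(l); R.push_back(r); Ls.push_back(ls); Rs.push_back(rs);
        break;
      }
      // extend subsequence j to cover through r, drop j..end, retry
      l = L[j]; ls = Ls[j];
      L.resize(j); R.resize(j); Ls.resize(j); Rs.resize(j);
    }
  }
  NumericMatrix out(L.size(), 3);
  for (size_t t = 0; t < L.size(); ++t) {
    out(t, 0) = L[t] + 1;
    out(t, 1) = R[t];
    out(t, 2) = Rs[t] - Ls[t];
  }
  return out;
}
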