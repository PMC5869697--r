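// Permutation kernel for the two-set weighted Kolmogorov-Smirnov
// connectivity score: redraws gene positions (disjoint up/down sets,
// weights kept) with R's RNG and recomputes the combined score.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// enrichment score of one weighted hit set given (unsorted) 1-based
// positions in a ranking of length N; hits[i] carries weight w[i]
static double es_one(std::vector<std::pair<int, double> > &hits, int N) {
  int m = hits.size();
  if (m == 0) return 0.0;
  if (m == N) return 1.0;
  std::sort(hits.begin(), hits.end());
  double W = 0.0;
  for (int j = 0; j < m; ++j) W += hits[j].second;
  double missdec = 1.0 / (N - m);
  double cw = 0.0, maxH = R_NegInf, minL = 0.0;
  for (int j = 0; j < m; ++j) {
    double miss = (hits[j].first - (j + 1)) * missdec;
    double L = cw / W - miss;
    cw += hits[j].second;
    double H = cw / W - miss;
    if (H > maxH) maxH = H;
    if (L < minL) minL = L;
  }
  return (maxH >= -minL - 1e-12) ? maxH : minL;
}

// [[Rcpp::export(name = ".score_perm_cpp")]]
NumericVector score_perm_cpp(int N, NumericVector w_up,
                             NumericVector w_dn, int n_perm) {
  int mu = w_up.size(), md = w_dn.size(), m = mu + md;
  if (m > N) stop("more query genes than ranked genes");
  NumericVector out(n_perm);
  std::vector<int> pool(N);
  std::vector<std::pair<int, double> > hu(mu), hd(md);
  for (int b = 0; b < n_perm; ++b) {
    for (int i = 0; i < N; ++i) pool[i] = i + 1;
    // partial Fisher-Yates draw of m positions without replacement
    for (int j = 0; j < m; ++j) {
      int k = j + (int)(unif_rand() * (N - j));
      if (k >= N) k = N - 1;
      std::swap(pool[j], pool[k]);
    }
    for (int j = 0; j < mu; ++j)
      hu[j] = std::make_pair(pool[j], (double)w_up[j]);
    for (int j = 0; j < md; ++j)
      hd[j] = std::make_pair(pool[mu + j], (double)w_dn[j]);
    double eu = es_one(hu, N), ed = es_one(hd, N);
    bool same = (eu != 0.0) && (ed != 0.0) && ((eu > 0) == (ed > 0));
    out[b] = same ? 0.0 : (eu - ed) / 2.0;
  }
  return out;
}
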