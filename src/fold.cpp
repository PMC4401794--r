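#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Weighted Nussinov folding: maximize the total pair weight (GC=3, AU=2,
// GU=1) over all nested secondary structures with a minimum hairpin loop
// of `min_loop` unpaired bases. Deterministic traceback: at each interval
// the last base is left unpaired unless pairing it strictly improves the
// score; among equal-scoring pairing partners the smallest index wins.

static inline int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
  return 0;
}

static void traceback(const std::vector<std::vector<int> > &M,
                      const std::string &s, int min_loop,
                      int i, int j, std::string &db) {
  while (i < j) {
    if (M[i][j] == M[i][j - 1]) {  // j unpaired
      --j;
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      int w = pair_weight(s[k], s[j]);
      if (w == 0) continue;
      int left = (k > i) ? M[i][k - 1] : 0;
      int in = (k + 1 <= j - 1) ? M[k + 1][j - 1] : 0;
      if (M[i][j] == left + in + w) {
        db[k] = '(';
        db[j] = ')';
        if (k > i) traceback(M, s, min_loop, i, k - 1, db);
        i = k + 1;
        --j;
        break;
      }
    }
  }
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_loop = 3) {
  int n = (int)seq.size();
  for (int i = 0; i < n; ++i) {
    char &c = seq[i];
    if (c == 'T') c = 'U';
    if (c != 'A' && c != 'C' && c != 'G' && c != 'U' && c != 'N')
      stop("invalid character in sequence: '%s'", std::string(1, c).c_str());
  }
  std::string db(n, '.');
  if (n == 0)
    return List::create(_["structure"] = db, _["score"] = 0);

  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        int w = pair_weight(seq[k], seq[j]);
        if (w == 0) continue;
        int left = (k > i) ? M[i][k - 1] : 0;
        int in = (k + 1 <= j - 1) ? M[k + 1][j - 1] : 0;
        if (left + in + w > best) best = left + in + w;
      }
      M[i][j] = best;
    }
  }
  traceback(M, seq, min_loop, 0, n - 1, db);
  return List::create(_["structure"] = db, _["score"] = M[0][n - 1]);
}
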