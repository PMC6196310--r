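#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Smoothed partial tree kernel.
//
// Delta(n1, n2) follows the standard recursion: for two leaves
// mu * lambda * sigma; otherwise
//   mu * sigma * ( lambda^2 + sum over equal-length child subsequences
//                  lambda^{d(I1)+d(I2)} * prod Delta(children) )
// with d(I) = i_last - i_first + 1.  The subsequence sum is computed by the
// usual dynamic program: with C_l(x,y) the sum over subsequence pairs of
// length l ending exactly at child positions (x, y) of
// lambda^{(x - first1) + (y - first2)} * prod Delta, the total is
// lambda^2 * sum_l sum_{x,y} C_l(x,y), and
//   C_1(x,y)     = Delta(a[x], b[y])
//   C_{l+1}(x,y) = Delta(a[x], b[y]) * lambda^2 * T_l(x-1, y-1)
//   T_l(x,y)     = C_l(x,y) + lambda T_l(x-1,y) + lambda T_l(x,y-1)
//                  - lambda^2 T_l(x-1,y-1).

struct FlatTree {
  std::vector<int> labels;                 // 0-based label ids
  std::vector<std::vector<int>> children;  // 0-based node ids
};

static FlatTree as_flat(const List& t) {
  FlatTree ft;
  IntegerVector lab = t["labels"];
  List ch = t["children"];
  int n = lab.size();
  ft.labels.assign(lab.begin(), lab.end());
  ft.children.resize(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector ci = ch[i];
    ft.children[i].assign(ci.begin(), ci.end());
  }
  return ft;
}

class SptkPair {
public:
  SptkPair(const FlatTree& a, const FlatTree& b, const NumericMatrix& S,
           double mu, double lambda)
    : a_(a), b_(b), S_(S), mu_(mu), la_(lambda),
      memo_(a.labels.size() * b.labels.size(), -1.0) {}

  double delta(int i, int j) {
    size_t key = (size_t)i * b_.labels.size() + j;
    double& m = memo_[key];
    if (m >= 0.0) return m;
    double sigma = S_(a_.labels[i], b_.labels[j]);
    if (sigma == 0.0) return m = 0.0;
    const std::vector<int>& ca = a_.children[i];
    const std::vector<int>& cb = b_.children[j];
    if (ca.empty() && cb.empty()) return m = mu_ * la_ * sigma;
    int p = ca.size(), q = cb.size();
    double total = 0.0;
    if (p > 0 && q > 0) {
      int lmax = p < q ? p : q;
      std::vector<double> D((size_t)p * q);
      for (int x = 0; x < p; ++x)
        for (int y = 0; y < q; ++y)
          D[(size_t)x * q + y] = delta(ca[x], cb[y]);
      std::vector<double> C((size_t)p * q), T((size_t)p * q), Cn((size_t)p * q);
      // l = 1
      for (int x = 0; x < p; ++x)
        for (int y = 0; y < q; ++y) {
          C[(size_t)x * q + y] = D[(size_t)x * q + y];
          total += C[(size_t)x * q + y];
        }
      double la2 = la_ * la_;
      for (int l = 2; l <= lmax; ++l) {
        // T from C
        for (int x = 0; x < p; ++x)
          for (int y = 0; y < q; ++y) {
            double t = C[(size_t)x * q + y];
            if (x > 0) t += la_ * T[(size_t)(x - 1) * q + y];
            if (y > 0) t += la_ * T[(size_t)x * q + y - 1];
            if (x > 0 && y > 0) t -= la2 * T[(size_t)(x - 1) * q + y - 1];
            T[(size_t)x * q + y] = t;
          }
        double level = 0.0;
        for (int x = 0; x < p; ++x)
          for (int y = 0; y < q; ++y) {
            double v = 0.0;
            if (x > 0 && y > 0)
              v = D[(size_t)x * q + y] * la2 * T[(size_t)(x - 1) * q + y - 1];
            Cn[(size_t)x * q + y] = v;
            level += v;
          }
        std::swap(C, Cn);
        total += level;
        if (level == 0.0) break;
      }
    }
    return m = mu_ * sigma * la_ * la_ * (1.0 + total);
  }

  double kernel() {
    double k = 0.0;
    for (size_t i = 0; i < a_.labels.size(); ++i)
      for (size_t j = 0; j < b_.labels.size(); ++j)
        k += delta((int)i, (int)j);
    return k;
  }

private:
  const FlatTree& a_;
  const FlatTree& b_;
  const NumericMatrix& S_;
  double mu_, la_;
  std::vector<double> memo_;
};

// [[Rcpp::export]]
double cpp_sptk_pair(List t1, List t2, NumericMatrix S, double mu,
                     double lambda) {
  FlatTree a = as_flat(t1), b = as_flat(t2);
  SptkPair k(a, b, S, mu, lambda);
  return k.kernel();
}

// [[Rcpp::export]]
NumericMatrix cpp_sptk_gram(List rows, List cols, NumericMatrix S, double mu,
                            double lambda, bool symmetric) {
  int nr = rows.size();
  int nc = symmetric ? nr : cols.size();
  std::vector<FlatTree> fr(nr), fc;
  for (int i = 0; i < nr; ++i) fr[i] = as_flat(rows[i]);
  NumericMatrix G(nr, nc);
  if (symmetric) {
    for (int i = 0; i < nr; ++i)
      for (int j = i; j < nr; ++j) {
        SptkPair k(fr[i], fr[j], S, mu, lambda);
        double v = k.kernel();
        G(i, j) = v;
        G(j, i) = v;
      }
  } else {
    fc.resize(nc);
    for (int j = 0; j < nc; ++j) fc[j] = as_flat(cols[j]);
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < nc; ++j) {
        SptkPair k(fr[i], fc[j], S, mu, lambda);
        G(i, j) = k.kernel();
      }
  }
  return G;
}
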