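#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Symmetric reflection of an index into [0, n)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

// Moving-window gray-level co-occurrence features.
//
// q: quantized image (values 0..levels-1), NA not allowed.
// For every pixel, a window x window neighborhood (symmetric reflection
// at borders) is scanned; for each cell the four standard direction
// offsets at the given distance d -- 0deg (0,+d), 45deg (-d,+d),
// 90deg (-d,0), 135deg (-d,-d) -- contribute one symmetrized pair
// (both (a,b) and (b,a) are counted). Features of the normalized
// matrix P: CON = sum (i-j)^2 P_ij; ASM = sum P_ij^2;
// ENT = -sum P_ij ln P_ij; VAR = sum (i - mu)^2 P_ij with mu the mean
// of i under P; COR = sum (i-mu_i)(j-mu_j) P_ij / (sd_i sd_j), NaN when
// a marginal sd is zero.
// [[Rcpp::export]]
List glcm_features_cpp(IntegerMatrix q, int levels, int window, int dist) {
  const int nr = q.nrow(), nc = q.ncol();
  const int h = window / 2;
  const int L = levels;
  NumericMatrix VAR(nr, nc), ENT(nr, nc), COR(nr, nc), CON(nr, nc),
      ASM(nr, nc);
  const int off_r[4] = {0, -dist, -dist, -dist};
  const int off_c[4] = {dist, dist, 0, -dist};
  std::vector<double> P(L * L);
  std::vector<double> pi(L), pj(L);

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      std::fill(P.begin(), P.end(), 0.0);
      double total = 0.0;
      for (int wc = c - h; wc <= c + h; ++wc) {
        for (int wr = r - h; wr <= r + h; ++wr) {
          int a = q(reflect_idx(wr, nr), reflect_idx(wc, nc));
          for (int d = 0; d < 4; ++d) {
            int b = q(reflect_idx(wr + off_r[d], nr),
                      reflect_idx(wc + off_c[d], nc));
            P[a * L + b] += 1.0;
            P[b * L + a] += 1.0;
            total += 2.0;
          }
        }
      }
      double con = 0.0, asm_ = 0.0, ent = 0.0;
      std::fill(pi.begin(), pi.end(), 0.0);
      std::fill(pj.begin(), pj.end(), 0.0);
      for (int i = 0; i < L; ++i) {
        for (int j = 0; j < L; ++j) {
          double p = P[i * L + j] / total;
          if (p > 0.0) {
            con += (double)(i - j) * (i - j) * p;
            asm_ += p * p;
            ent -= p * std::log(p);
            pi[i] += p;
            pj[j] += p;
          }
        }
      }
      double mu_i = 0.0, mu_j = 0.0;
      for (int i = 0; i < L; ++i) {
        mu_i += i * pi[i];
        mu_j += i * pj[i];
      }
      double var_i = 0.0, var_j = 0.0;
      for (int i = 0; i < L; ++i) {
        var_i += (i - mu_i) * (i - mu_i) * pi[i];
        var_j += (i - mu_j) * (i - mu_j) * pj[i];
      }
      double cov = 0.0;
      for (int i = 0; i < L; ++i) {
        if (pi[i] == 0.0) continue;
        for (int j = 0; j < L; ++j) {
          double p = P[i * L + j] / total;
          if (p > 0.0) cov += (i - mu_i) * (j - mu_j) * p;
        }
      }
      CON(r, c) = con;
      ASM(r, c) = asm_;
      ENT(r, c) = ent;
      VAR(r, c) = var_i;
      COR(r, c) = (var_i > 0.0 && var_j > 0.0)
                      ? cov / std::sqrt(var_i * var_j)
                      : NA_REAL;
    }
  }
  return List::create(_["VAR"] = VAR, _["ENT"] = ENT, _["COR"] = COR,
                      _["CON"] = CON, _["ASM"] = ASM);
}
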