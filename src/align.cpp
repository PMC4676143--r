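#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh three-state DP).
// Gap of length L costs gapOpen + L * gapExt.
// States: 0 = M (residue-residue), 1 = X (residue of `a` over a gap in `b`),
// 2 = Y (gap in `a` under a residue of `b`).
// Tie-breaking is fixed: on equal score prefer M, then X, then Y, both when
// choosing the predecessor state and when choosing the final state, so the
// traceback is fully deterministic.

static const double NEG_INF = -1e30;

static inline int pick3(double m, double x, double y) {
  // index of max with preference M > X > Y on ties
  if (m >= x && m >= y) return 0;
  if (x >= y) return 1;
  return 2;
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b, NumericMatrix submat,
                  std::string alphabet, double gapOpen, double gapExt) {
  const int n = a.size(), m = b.size();
  // residue -> row index of submat
  std::vector<int> code(256, -1);
  for (size_t k = 0; k < alphabet.size(); ++k)
    code[(unsigned char)alphabet[k]] = (int)k;
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = code[(unsigned char)a[i]];
    if (ai[i] < 0) stop("residue '%s' not in scoring alphabet",
                        std::string(1, a[i]).c_str());
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = code[(unsigned char)b[j]];
    if (bi[j] < 0) stop("residue '%s' not in scoring alphabet",
                        std::string(1, b[j]).c_str());
  }

  const double go = gapOpen + gapExt;  // cost of the first gapped position
  const size_t W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  std::vector<unsigned char> tbM((n + 1) * W), tbX((n + 1) * W),
      tbY((n + 1) * W);

  M[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    Y[j] = -(gapOpen + gapExt * j);
    tbY[j] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -(gapOpen + gapExt * i);
    tbX[i * W] = 1;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                   u = (i - 1) * W + j, l = i * W + (j - 1);
      const double s = submat(ai[i - 1], bi[j - 1]);
      int p = pick3(M[d], X[d], Y[d]);
      M[c] = (p == 0 ? M[d] : p == 1 ? X[d] : Y[d]) + s;
      tbM[c] = (unsigned char)p;

      p = pick3(M[u] - go, X[u] - gapExt, Y[u] - go);
      X[c] = (p == 0 ? M[u] - go : p == 1 ? X[u] - gapExt : Y[u] - go);
      tbX[c] = (unsigned char)p;

      p = pick3(M[l] - go, X[l] - go, Y[l] - gapExt);
      Y[c] = (p == 0 ? M[l] - go : p == 1 ? X[l] - go : Y[l] - gapExt);
      tbY[c] = (unsigned char)p;
    }
  }

  const size_t e = n * W + m;
  int st = pick3(M[e], X[e], Y[e]);
  const double score = (st == 0 ? M[e] : st == 1 ? X[e] : Y[e]);

  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t c = i * W + j;
    if (st == 0) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      st = tbM[c];
      --i; --j;
    } else if (st == 1) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      st = tbX[c];
      --i;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      st = tbY[c];
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score, _["a"] = ra, _["b"] = rb);
}

// Profile-profile alignment with the same three-state DP. Profiles are
// (nSymbols x L) relative-frequency matrices over the residue alphabet
// (gaps excluded from the frequencies but included in the normalisation, so
// gappy columns carry proportionally less score). Column-column score is
// fA' S fB. Returns, for each profile, a logical vector over the merged
// columns that is TRUE where that profile receives a new gap column.
// [[Rcpp::export(name = ".nw_profile_cpp")]]
List nw_profile_cpp(NumericMatrix pa, NumericMatrix pb, NumericMatrix submat,
                    double gapOpen, double gapExt) {
  const int n = pa.ncol(), m = pb.ncol(), K = submat.nrow();
  if (pa.nrow() != K || pb.nrow() != K)
    stop("profile rows must match the scoring alphabet");

  // Precompute S * fB columns for speed
  NumericMatrix sb(K, m);
  for (int j = 0; j < m; ++j)
    for (int r = 0; r < K; ++r) {
      double acc = 0.0;
      for (int s = 0; s < K; ++s) acc += submat(r, s) * pb(s, j);
      sb(r, j) = acc;
    }

  const double go = gapOpen + gapExt;
  const size_t W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  std::vector<unsigned char> tbM((n + 1) * W), tbX((n + 1) * W),
      tbY((n + 1) * W);
  M[0] = 0.0;
  for (int j = 1; j <= m; ++j) { Y[j] = -(gapOpen + gapExt * j); tbY[j] = 2; }
  for (int i = 1; i <= n; ++i) { X[i * W] = -(gapOpen + gapExt * i); tbX[i * W] = 1; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                   u = (i - 1) * W + j, l = i * W + (j - 1);
      double s = 0.0;
      for (int r = 0; r < K; ++r) s += pa(r, i - 1) * sb(r, j - 1);
      int p = pick3(M[d], X[d], Y[d]);
      M[c] = (p == 0 ? M[d] : p == 1 ? X[d] : Y[d]) + s;
      tbM[c] = (unsigned char)p;
      p = pick3(M[u] - go, X[u] - gapExt, Y[u] - go);
      X[c] = (p == 0 ? M[u] - go : p == 1 ? X[u] - gapExt : Y[u] - go);
      tbX[c] = (unsigned char)p;
      p = pick3(M[l] - go, X[l] - go, Y[l] - gapExt);
      Y[c] = (p == 0 ? M[l] - go : p == 1 ? X[l] - go : Y[l] - gapExt);
      tbY[c] = (unsigned char)p;
    }
  }

  const size_t e = n * W + m;
  int st = pick3(M[e], X[e], Y[e]);
  const double score = (st == 0 ? M[e] : st == 1 ? X[e] : Y[e]);

  std::vector<int> gapA, gapB;  // 1 = gap inserted into that profile
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t c = i * W + j;
    if (st == 0) { gapA.push_back(0); gapB.push_back(0); st = tbM[c]; --i; --j; }
    else if (st == 1) { gapA.push_back(0); gapB.push_back(1); st = tbX[c]; --i; }
    else { gapA.push_back(1); gapB.push_back(0); st = tbY[c]; --j; }
  }
  std::reverse(gapA.begin(), gapA.end());
  std::reverse(gapB.begin(), gapB.end());
  return List::create(_["score"] = score,
                      _["gapA"] = LogicalVector(gapA.begin(), gapA.end()),
                      _["gapB"] = LogicalVector(gapB.begin(), gapB.end()));
}
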