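#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// IUPAC nucleotide bit codes: A=1, C=2, G=4, T=8; ambiguity = union.
static int iupac_bits(char c) {
  switch (c) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;  case 'T': return 8;
    case 'R': return 1|4; case 'Y': return 2|8; case 'S': return 2|4; case 'W': return 1|8;
    case 'K': return 4|8; case 'M': return 1|2;
    case 'B': return 2|4|8; case 'D': return 1|4|8; case 'H': return 1|2|8; case 'V': return 1|2|4;
    case 'N': return 15;
    default: return 0;
  }
}

// Global alignment with affine gaps (Gotoh). A gap of length L costs
// gap_open + L * gap_extend (both penalties are negative numbers here).
// Bases "match" when their IUPAC sets intersect.
//
// Deterministic tie-breaking, applied both when taking cell maxima and during
// traceback: state M (diagonal) is preferred over X (gap in b, i.e. a base of
// `a` over '-'), which is preferred over Y (gap in a).
// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b,
                 double match, double mismatch,
                 double gap_open, double gap_extend) {
  const int n = (int) a.size(), m = (int) b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  const double NEG = -1e30;
  const size_t W = (size_t) m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  // traceback: which predecessor state fed each cell (0=M, 1=X, 2=Y)
  std::vector<unsigned char> tbM((n + 1) * W), tbX((n + 1) * W), tbY((n + 1) * W);

  std::vector<int> abits(n), bbits(m);
  for (int i = 0; i < n; ++i) {
    abits[i] = iupac_bits(a[i]);
    if (!abits[i]) stop("invalid character '%s' in sequence a at position %d",
                        std::string(1, a[i]), i + 1);
  }
  for (int j = 0; j < m; ++j) {
    bbits[j] = iupac_bits(b[j]);
    if (!bbits[j]) stop("invalid character '%s' in sequence b at position %d",
                        std::string(1, b[j]), j + 1);
  }

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) { X[i * W] = gap_open + gap_extend * i; tbX[i * W] = 1; }
  tbX[W] = 0;  // first gap opens from M
  for (int j = 1; j <= m; ++j) { Y[j] = gap_open + gap_extend * j; tbY[j] = 2; }
  tbY[1] = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                   u = (i - 1) * W + j, l = i * W + (j - 1);
      const double s = (abits[i - 1] & bbits[j - 1]) ? match : mismatch;
      // M: prefer M > X > Y on ties
      double best = M[d]; unsigned char who = 0;
      if (X[d] > best) { best = X[d]; who = 1; }
      if (Y[d] > best) { best = Y[d]; who = 2; }
      M[c] = best + s; tbM[c] = who;
      // X: gap in b (consume a[i-1])
      best = M[u] + gap_open + gap_extend; who = 0;
      if (X[u] + gap_extend > best) { best = X[u] + gap_extend; who = 1; }
      if (Y[u] + gap_open + gap_extend > best) { best = Y[u] + gap_open + gap_extend; who = 2; }
      X[c] = best; tbX[c] = who;
      // Y: gap in a (consume b[j-1])
      best = M[l] + gap_open + gap_extend; who = 0;
      if (X[l] + gap_open + gap_extend > best) { best = X[l] + gap_open + gap_extend; who = 1; }
      if (Y[l] + gap_extend > best) { best = Y[l] + gap_extend; who = 2; }
      Y[c] = best; tbY[c] = who;
    }
  }

  const size_t e = (size_t) n * W + m;
  int state = 0; double score = M[e];
  if (X[e] > score) { score = X[e]; state = 1; }
  if (Y[e] > score) { score = Y[e]; state = 2; }

  std::string ga, gb;
  ga.reserve(n + m); gb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t c = (size_t) i * W + j;
    if (state == 0) {
      int prev = tbM[c];
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tbX[c];
      ga.push_back(a[i - 1]); gb.push_back('-');
      --i; state = prev;
    } else {
      int prev = tbY[c];
      ga.push_back('-'); gb.push_back(b[j - 1]);
      --j; state = prev;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());

  return List::create(_["a_gapped"] = ga, _["b_gapped"] = gb, _["score"] = score);
}
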