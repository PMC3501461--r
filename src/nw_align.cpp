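#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty.
// Traceback ties are broken deterministically: diagonal, then up
// (gap in b), then left (gap in a), evaluated from the bottom-right
// corner. Rows index sequence a, columns sequence b.

// [[Rcpp::export(name = ".nwAlignCpp")]]
List nwAlignCpp(std::string a, std::string b,
                NumericMatrix submat, double gap) {
  int n = a.size(), m = b.size();
  CharacterVector rn = rownames(submat);
  // residue -> matrix index lookup (ASCII table)
  std::vector<int> lut(256, -1);
  for (int k = 0; k < rn.size(); ++k) {
    std::string s = as<std::string>(rn[k]);
    if (s.size() == 1) lut[(unsigned char)s[0]] = k;
  }
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = lut[(unsigned char)a[i]];
    if (ai[i] < 0) stop("character '%s' not in substitution matrix",
                        std::string(1, a[i]).c_str());
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = lut[(unsigned char)b[j]];
    if (bi[j] < 0) stop("character '%s' not in substitution matrix",
                        std::string(1, b[j]).c_str());
  }

  NumericMatrix F(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) F(i, 0) = -gap * i;
  for (int j = 1; j <= m; ++j) F(0, j) = -gap * j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = F(i - 1, j - 1) + submat(ai[i - 1], bi[j - 1]);
      double u = F(i - 1, j) - gap;
      double l = F(i, j - 1) - gap;
      F(i, j) = std::max(d, std::max(u, l));
    }
  }

  std::string oa, ob;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        F(i, j) == F(i - 1, j - 1) + submat(ai[i - 1], bi[j - 1])) {
      oa.push_back(a[i - 1]); ob.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && F(i, j) == F(i - 1, j) - gap) {
      oa.push_back(a[i - 1]); ob.push_back('-'); --i;
    } else {
      oa.push_back('-'); ob.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(oa.begin(), oa.end());
  std::reverse(ob.begin(), ob.end());

  return List::create(_["score"] = F(n, m),
                      _["aligned_a"] = oa,
                      _["aligned_b"] = ob);
}
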