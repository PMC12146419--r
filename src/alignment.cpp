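#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh).
// Convention: a gap of length L costs -(gap_open + (L-1) * gap_extend),
// i.e. gap_open is charged on the first gapped position, gap_extend on each
// subsequent one. gap_open/gap_extend are supplied as non-positive scores.
static double sw_pair(const std::vector<int>& a, const std::vector<int>& b,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Eprev(m + 1, NEG), Ecur(m + 1, NEG); // gap in a (horizontal over b? see below)
  std::vector<double> F(m + 1, NEG);                        // gap opened along columns
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0;
    Ecur[0] = NEG;
    double Erow = NEG; // E: gap in sequence b (consuming a along the row? standard Gotoh row gap)
    for (int j = 1; j <= m; ++j) {
      // E: alignment ends with gap in b-direction (move along j)
      Erow = std::max(Hcur[j - 1] + gap_open, Erow + gap_extend);
      // F: gap along i
      F[j] = std::max(Hprev[j] + gap_open, F[j] + gap_extend);
      double diag = Hprev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double h = std::max(0.0, std::max(diag, std::max(Erow, F[j])));
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}

static std::vector<int> encode_seq(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int)(unsigned char)s[i];
  return v;
}

// [[Rcpp::export(name = ".sw_score_cpp")]]
double sw_score_cpp(std::string a, std::string b, double match, double mismatch,
                    double gap_open, double gap_extend) {
  std::vector<int> ea = encode_seq(a), eb = encode_seq(b);
  return sw_pair(ea, eb, match, mismatch, gap_open, gap_extend);
}

// All-pairs raw local alignment scores sp(i, j) for a set of sequences.
// [[Rcpp::export(name = ".sw_score_matrix_cpp")]]
NumericMatrix sw_score_matrix_cpp(CharacterVector seqs, double match,
                                  double mismatch, double gap_open,
                                  double gap_extend) {
  const int n = seqs.size();
  std::vector<std::vector<int> > enc(n);
  for (int i = 0; i < n; ++i) enc[i] = encode_seq(as<std::string>(seqs[i]));
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double s = sw_pair(enc[i], enc[j], match, mismatch, gap_open, gap_extend);
      out(i, j) = s;
      out(j, i) = s;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
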