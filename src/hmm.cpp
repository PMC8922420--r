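// Viterbi and forward DP for the profile HMM scorer, log2 space,
// global in model / local in sequence (free background flanks).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double ls2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log2(std::exp2(a - m) + std::exp2(b - m));
}

// [[Rcpp::export]]
List cpp_hmm_score(IntegerVector aa_row, NumericMatrix em,
                   NumericMatrix lt) {
  // aa_row: 1-based row of each residue in em, NA -> 0 log-odds
  // em: 20 x L match log-odds; lt: L x 7 log transitions
  // (mm mi md im ii dm dd), row j: into position j (im: I_{j-1}->M_j),
  // except mi/ii which leave M_j/I_j at row j.
  int n = aa_row.size(), L = em.ncol();
  const double NEG = R_NegInf;
  std::vector<double> Mv(L, NEG), Iv(L, NEG), Dv(L, NEG);
  std::vector<double> Mf(L, NEG), If(L, NEG), Df(L, NEG);
  std::vector<double> Mpv(L), Ipv(L), Dpv(L), Mpf(L), Ipf(L), Dpf(L);
  double Cv = NEG, Cf = NEG; // N flank is 0 throughout
  // pure-delete prefix reachable before any residue is consumed
  Dv[0] = lt(0, 2);
  Df[0] = lt(0, 2);
  for (int j = 1; j < L; j++) {
    Dv[j] = Dv[j - 1] + lt(j, 6);
    Df[j] = Df[j - 1] + lt(j, 6);
  }
  for (int i = 0; i < n; i++) {
    Mpv = Mv; Ipv = Iv; Dpv = Dv;
    Mpf = Mf; Ipf = If; Dpf = Df;
    int r = aa_row[i]; // 1-based or NA
    for (int j = 0; j < L; j++) {
      double e = (r == NA_INTEGER) ? 0.0 : em(r - 1, j);
      double pmv = (j == 0) ? 0.0 : Mpv[j - 1];
      double piv = (j == 0) ? NEG : Ipv[j - 1];
      double pdv = (j == 0) ? NEG : Dpv[j - 1];
      double bestv = pmv + lt(j, 0);
      double t = piv + lt(j, 3); if (t > bestv) bestv = t;
      t = pdv + lt(j, 5); if (t > bestv) bestv = t;
      Mv[j] = e + bestv;
      double pmf = (j == 0) ? 0.0 : Mpf[j - 1];
      double pif = (j == 0) ? NEG : Ipf[j - 1];
      double pdf = (j == 0) ? NEG : Dpf[j - 1];
      Mf[j] = e + ls2(ls2(pmf + lt(j, 0), pif + lt(j, 3)), pdf + lt(j, 5));
      // insert layer
      double iv = Mpv[j] + lt(j, 1), iv2 = Ipv[j] + lt(j, 4);
      Iv[j] = iv > iv2 ? iv : iv2;
      If[j] = ls2(Mpf[j] + lt(j, 1), Ipf[j] + lt(j, 4));
    }
    // delete chain at current i
    Dv[0] = 0.0 + lt(0, 2);
    Df[0] = 0.0 + lt(0, 2);
    for (int j = 1; j < L; j++) {
      double a = Mv[j - 1] + lt(j, 2), b = Dv[j - 1] + lt(j, 6);
      Dv[j] = a > b ? a : b;
      Df[j] = ls2(Mf[j - 1] + lt(j, 2), Df[j - 1] + lt(j, 6));
    }
    Cv = Cv > Mv[L - 1] ? Cv : Mv[L - 1];
    Cf = ls2(Cf, Mf[L - 1]);
  }
  return List::create(_["viterbi"] = Cv, _["forward"] = Cf);
}
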