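// Semi-global (pattern-global, subject-local) affine-gap aligner.
// A gap of length k costs gap_open + k * gap_ext. The subject's leading and
// trailing bases outside the aligned substring are free. Traceback is fully
// deterministic (diagonal preferred, then gap-in-subject, then gap-in-
// pattern); indel placement is canonicalized by left-alignment on the R side.

#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

static const double NEG = -1e18;

// [[Rcpp::export]]
List sg_align_batch(CharacterVector reads, std::string subject,
                    double match, double mismatch,
                    double gap_open, double gap_ext) {
  const int ns = subject.size();
  const int nr = reads.size();
  NumericVector score_out(nr);
  IntegerVector start_out(nr), end_out(nr);
  CharacterVector pat_out(nr), sub_out(nr);

  for (int r = 0; r < nr; ++r) {
    std::string pat = as<std::string>(reads[r]);
    const int np = pat.size();
    // DP matrices, (np+1) x (ns+1)
    std::vector<double> M((np + 1) * (ns + 1), NEG);
    std::vector<double> Ip((np + 1) * (ns + 1), NEG);
    std::vector<double> Is((np + 1) * (ns + 1), NEG);
    auto at = [ns](int i, int j) { return i * (ns + 1) + j; };
    for (int j = 0; j <= ns; ++j) M[at(0, j)] = 0.0;  // free subject prefix
    for (int i = 1; i <= np; ++i) Ip[at(i, 0)] = -(gap_open + i * gap_ext);
    for (int i = 1; i <= np; ++i) {
      const char pc = pat[i - 1];
      for (int j = 1; j <= ns; ++j) {
        const double s = (pc == subject[j - 1]) ? match : mismatch;
        double diag = M[at(i - 1, j - 1)];
        if (Ip[at(i - 1, j - 1)] > diag) diag = Ip[at(i - 1, j - 1)];
        if (Is[at(i - 1, j - 1)] > diag) diag = Is[at(i - 1, j - 1)];
        M[at(i, j)] = diag + s;
        double a = M[at(i - 1, j)] - gap_open - gap_ext;
        double b = Ip[at(i - 1, j)] - gap_ext;
        Ip[at(i, j)] = a >= b ? a : b;
        a = M[at(i, j - 1)] - gap_open - gap_ext;
        b = Is[at(i, j - 1)] - gap_ext;
        Is[at(i, j)] = a >= b ? a : b;
      }
    }
    // best end: free subject suffix
    int best_j = 0, best_state = 0;
    double best = NEG;
    for (int j = 0; j <= ns; ++j) {
      if (M[at(np, j)] > best) { best = M[at(np, j)]; best_j = j; best_state = 0; }
      if (Ip[at(np, j)] > best) { best = Ip[at(np, j)]; best_j = j; best_state = 1; }
    }
    score_out[r] = best;
    // traceback
    std::string pa, sa;
    pa.reserve(np + 16); sa.reserve(np + 16);
    int i = np, j = best_j, state = best_state;
    const double eps = 1e-9;
    while (i > 0) {
      if (state == 0) {
        const double s = (pat[i - 1] == subject[j - 1]) ? match : mismatch;
        const double need = M[at(i, j)] - s;
        pa.push_back(pat[i - 1]);
        sa.push_back(subject[j - 1]);
        if (M[at(i - 1, j - 1)] >= need - eps) state = 0;
        else if (Ip[at(i - 1, j - 1)] >= need - eps) state = 1;
        else state = 2;
        --i; --j;
      } else if (state == 1) {       // gap in subject: pattern base consumed
        pa.push_back(pat[i - 1]);
        sa.push_back('-');
        const double cur = Ip[at(i, j)];
        if (j == 0) { --i; state = 1; continue; }
        if (M[at(i - 1, j)] - gap_open - gap_ext >= cur - eps) state = 0;
        else state = 1;
        --i;
      } else {                       // gap in pattern: subject base consumed
        pa.push_back('-');
        sa.push_back(subject[j - 1]);
        const double cur = Is[at(i, j)];
        if (M[at(i, j - 1)] - gap_open - gap_ext >= cur - eps) state = 0;
        else state = 2;
        --j;
      }
    }
    std::reverse(pa.begin(), pa.end());
    std::reverse(sa.begin(), sa.end());
    start_out[r] = j;        // 0-based subject start of the aligned region
    end_out[r] = best_j;     // 0-based exclusive end
    pat_out[r] = pa;
    sub_out[r] = sa;
  }
  return List::create(_["score"] = score_out, _["start"] = start_out,
                      _["end"] = end_out, _["pattern"] = pat_out,
                      _["subject"] = sub_out);
}
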