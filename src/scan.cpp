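#include <Rcpp.h>
using namespace Rcpp;

// Core window scorer. codes: integer-coded sequence (A=0,C=1,G=2,T=3,
// N or other = -1); lo: 4 x L log-odds matrix, column-major. Windows
// containing a negative code are skipped. Calls `emit` for each window with
// score >= threshold.
static inline void scan_core(const int* codes, int n, const double* lo,
                             int L, double threshold,
                             std::vector<double>* starts,
                             std::vector<double>* scores, int* count) {
  for (int i = 0; i + L <= n; ++i) {
    // accumulate in extended precision to match R's sum() exactly, so that
    // a full-score consensus window ties the R-computed max_score bit for bit
    long double s = 0.0;
    bool ok = true;
    const int* w = codes + i;
    for (int j = 0; j < L; ++j) {
      const int b = w[j];
      if (b < 0) { ok = false; break; }
      s += lo[b + 4 * j];
    }
    const double sc = (double) s;
    if (ok && sc >= threshold) {
      if (count) ++*count;
      if (starts) { starts->push_back((double) i); scores->push_back(sc); }
    }
  }
}

// Score every window of one sequence against one matrix; return the windows
// at or above `threshold` as a 2-column matrix: 0-based start, score.
// [[Rcpp::export]]
NumericMatrix scan_codes_cpp(IntegerVector codes, NumericMatrix log_odds,
                             double threshold) {
  std::vector<double> starts, scores;
  scan_core(INTEGER(codes), codes.size(), REAL(log_odds), log_odds.ncol(),
            threshold, &starts, &scores, nullptr);
  NumericMatrix out(starts.size(), 2);
  for (R_xlen_t k = 0; k < (R_xlen_t) starts.size(); ++k) {
    out(k, 0) = starts[k];
    out(k, 1) = scores[k];
  }
  return out;
}

// Count-only fast path.
// [[Rcpp::export]]
int count_codes_cpp(IntegerVector codes, NumericMatrix log_odds,
                    double threshold) {
  int count = 0;
  scan_core(INTEGER(codes), codes.size(), REAL(log_odds), log_odds.ncol(),
            threshold, nullptr, nullptr, &count);
  return count;
}

// Both-strand hit counts of one motif over a list of coded sequences in a
// single call: forward matrix `lo` plus its reverse complement `lo_rc`
// (reverse-complementing the matrix is equivalent to scanning the minus
// strand) against every sequence.
// [[Rcpp::export]]
IntegerVector count_codes_list_cpp(List codes_list, NumericMatrix lo,
                                   NumericMatrix lo_rc, double threshold) {
  const int m = codes_list.size();
  const int L = lo.ncol();
  IntegerVector out(m);
  for (int g = 0; g < m; ++g) {
    IntegerVector codes = codes_list[g];
    int count = 0;
    scan_core(INTEGER(codes), codes.size(), REAL(lo), L, threshold,
              nullptr, nullptr, &count);
    scan_core(INTEGER(codes), codes.size(), REAL(lo_rc), L, threshold,
              nullptr, nullptr, &count);
    out[g] = count;
  }
  return out;
}
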