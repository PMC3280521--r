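#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive tandem-array scan with consensus scoring.
//
// For every unit size u and start s, a candidate array begins with two units
// and is extended by whole units while the consensus score (matches minus
// mismatches against the per-column majority base) strictly increases.
// Arrays whose final score reaches min_score are reported; overlap reduction
// to local maxima happens on the R side.
//
// seq is encoded 0..4 (A,C,G,T,N); consensus ties resolve to the lowest code,
// i.e. alphabetically first.

// [[Rcpp::export]]
DataFrame tandem_scan_cpp(IntegerVector seq, int min_unit, int max_unit,
                          int min_score) {
  const int L = seq.size();
  const int B = 5;
  std::vector<int> r_start, r_unit, r_count, r_score, r_matches;
  std::vector<int> cnt;
  for (int u = min_unit; u <= max_unit; ++u) {
    if (2 * u > L) break;
    cnt.assign((size_t)u * B, 0);
    for (int s = 0; s + 2 * u <= L; ++s) {
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int k = 0; k < 2; ++k)
        for (int j = 0; j < u; ++j)
          cnt[(size_t)j * B + seq[s + k * u + j]]++;
      int matches = 0;
      for (int j = 0; j < u; ++j) {
        int m = 0;
        for (int b = 0; b < B; ++b)
          if (cnt[(size_t)j * B + b] > m) m = cnt[(size_t)j * B + b];
        matches += m;
      }
      int c = 2;
      int score = 2 * matches - u * c;
      while (s + (c + 1) * u <= L) {
        for (int j = 0; j < u; ++j)
          cnt[(size_t)j * B + seq[s + c * u + j]]++;
        int m2 = 0;
        for (int j = 0; j < u; ++j) {
          int m = 0;
          for (int b = 0; b < B; ++b)
            if (cnt[(size_t)j * B + b] > m) m = cnt[(size_t)j * B + b];
          m2 += m;
        }
        int score2 = 2 * m2 - u * (c + 1);
        if (score2 > score) {
          ++c; matches = m2; score = score2;
        } else {
          for (int j = 0; j < u; ++j)
            cnt[(size_t)j * B + seq[s + c * u + j]]--;
          break;
        }
      }
      if (score >= min_score) {
        r_start.push_back(s + 1);
        r_unit.push_back(u);
        r_count.push_back(c);
        r_score.push_back(score);
        r_matches.push_back(matches);
      }
    }
  }
  return DataFrame::create(
      _["start"] = wrap(r_start), _["unit_size"] = wrap(r_unit),
      _["count"] = wrap(r_count), _["score"] = wrap(r_score),
      _["matches"] = wrap(r_matches));
}
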