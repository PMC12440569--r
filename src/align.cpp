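#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Exact k-mer seed matching between two DNA strings (ACGT only; any k-mer
// containing another character is skipped). Positions are 0-based. Seeds per
// distinct k-mer of `a` are capped to keep low-complexity sequence from
// exploding the seed list.
// [[Rcpp::export]]
IntegerMatrix kmer_seeds_cpp(std::string a, std::string b, int k,
                             int max_per_kmer = 64, int max_seeds = 2000000) {
  int na = a.size(), nb = b.size();
  IntegerMatrix empty(0, 2);
  if (k < 2 || k > 31 || na < k || nb < k) return empty;

  auto code = [](char c) -> int {
    switch (c) {
      case 'A': return 0; case 'C': return 1;
      case 'G': return 2; case 'T': return 3;
      default: return -1;
    }
  };

  std::unordered_map<uint64_t, std::vector<int> > index;
  index.reserve(na);
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t h = 0; int run = 0;
  for (int i = 0; i < na; ++i) {
    int c = code(a[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      std::vector<int>& v = index[h];
      if ((int)v.size() < max_per_kmer) v.push_back(i - k + 1);
    }
  }

  std::vector<int> apos, bpos;
  h = 0; run = 0;
  for (int j = 0; j < nb; ++j) {
    int c = code(b[j]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      auto it = index.find(h);
      if (it != index.end()) {
        for (int p : it->second) {
          apos.push_back(p);
          bpos.push_back(j - k + 1);
          if ((int)apos.size() >= max_seeds) goto done;
        }
      }
    }
  }
done:
  IntegerMatrix out(apos.size(), 2);
  for (size_t i = 0; i < apos.size(); ++i) {
    out(i, 0) = apos[i];
    out(i, 1) = bpos[i];
  }
  return out;
}

// Banded local (Smith-Waterman) alignment of a vs b restricted to diagonals
// d = j - i in [dlo, dhi] (0-based positions). Linear gap penalty. Returns
// 0-based half-open aligned ranges in both sequences, match/column counts,
// and for every position of `a` the aligned position in `b` (-1 = aligned to
// a gap, -2 = outside the aligned region). 'N' mismatches everything.
// Tie-break order diag > up (gap in b) > left (gap in a); the traceback start
// is the first cell attaining the maximum score in (row, column) order, so
// results are deterministic.
// [[Rcpp::export]]
List band_align_cpp(std::string a, std::string b, int dlo, int dhi,
                    double match = 1.0, double mismatch = -1.0,
                    double gap = -2.0) {
  int na = a.size(), nb = b.size();
  if (na == 0 || nb == 0) stop("band_align: empty sequence");
  if (dlo > dhi) stop("band_align: dlo > dhi");
  if (dlo > nb - 1) dlo = nb - 1;
  if (dhi < -(na - 1)) dhi = -(na - 1);
  int W = dhi - dlo + 1;
  const double NEG = -1e18;

  // rolling score rows, full traceback matrix
  std::vector<double> prev(W + 2, NEG), cur(W + 2, NEG);
  std::vector<uint8_t> trace((size_t)(na + 1) * (W + 2), 0);
  for (int c = 0; c <= W + 1; ++c) prev[c] = NEG;
  // row 0: cells (0, j) have score 0 where in band
  for (int c = 1; c <= W; ++c) {
    int j = 0 + dlo + c - 1;
    if (j >= 0 && j <= nb) prev[c] = 0.0;
  }

  double best = 0.0; int bi = 0, bc = 0;
  for (int i = 1; i <= na; ++i) {
    for (int c = 0; c <= W + 1; ++c) cur[c] = NEG;
    int clo = std::max(1, 1 - (i + dlo - 1));      // j >= 1
    int chi = std::min(W, nb - (i + dlo - 1));     // j <= nb
    for (int c = clo; c <= chi; ++c) {
      int j = i + dlo + c - 1;
      char ca = a[i - 1], cb = b[j - 1];
      bool ok = (ca == cb) && ca != 'N';
      double s = ok ? match : mismatch;
      double dscore = (prev[c] > NEG / 2) ? prev[c] + s : NEG;
      double uscore = (c + 1 <= W + 1 && prev[c + 1] > NEG / 2) ? prev[c + 1] + gap : NEG;
      double lscore = (c - 1 >= 0 && cur[c - 1] > NEG / 2) ? cur[c - 1] + gap : NEG;
      double h = 0.0; uint8_t t = 0;
      if (dscore > h) { h = dscore; t = 1; }
      if (uscore > h) { h = uscore; t = 2; }
      if (lscore > h) { h = lscore; t = 3; }
      cur[c] = h;
      trace[(size_t)i * (W + 2) + c] = t;
      if (h > best) { best = h; bi = i; bc = c; }
    }
    std::swap(prev, cur);
  }

  IntegerVector b_for_a(na, -2);
  int a_start = 0, a_end = 0, b_start = 0, b_end = 0;
  int n_match = 0, n_cols = 0;
  if (best > 0) {
    int i = bi, c = bc;
    a_end = i; b_end = i + dlo + c - 1;
    while (i > 0) {
      uint8_t t = trace[(size_t)i * (W + 2) + c];
      if (t == 0) break;
      int j = i + dlo + c - 1;
      if (t == 1) {            // diag: a[i-1] ~ b[j-1]
        b_for_a[i - 1] = j - 1;
        if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ++n_match;
        ++n_cols; --i;         // c unchanged
      } else if (t == 2) {     // up: a[i-1] ~ gap
        b_for_a[i - 1] = -1;
        ++n_cols; --i; ++c;
      } else {                 // left: gap ~ b[j-1]
        ++n_cols; --c;
      }
    }
    a_start = i; b_start = i + dlo + c - 1;
  }

  return List::create(
    _["score"] = best,
    _["a_start"] = a_start, _["a_end"] = a_end,
    _["b_start"] = b_start, _["b_end"] = b_end,
    _["n_match"] = n_match, _["n_cols"] = n_cols,
    _["b_for_a"] = b_for_a);
}
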