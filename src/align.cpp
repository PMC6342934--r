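#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Affine-gap alignment (Gotoh three-state DP) of a read against a
// reference: global in the read; with free_ref_ends, unaligned reference
// flanks cost nothing (fitting alignment, the natural mode for amplicon
// reads shorter than the reference). A gap of length L scores
// gap_open + L * gap_extend. Among co-optimal alignments the traceback
// prefers the diagonal state, which pushes every gap run as far left (5')
// as possible; this makes indel placement in homopolymers deterministic.
//
// States: M = read/ref pair, X = gap in read (deletion from ref),
// Y = gap in ref (insertion in read).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string ref, std::string read,
                 double match, double mismatch,
                 double gap_open, double gap_extend,
                 bool free_ref_ends) {
  const int R = ref.size(), Q = read.size();
  const int W = Q + 1;
  std::vector<double> M((R + 1) * W, NEG_INF), X((R + 1) * W, NEG_INF),
      Y((R + 1) * W, NEG_INF);
  // traceback: predecessor state (0=M,1=X,2=Y), -1 = origin, -2 = free
  // leading reference flank
  std::vector<signed char> tM((R + 1) * W, -1), tX((R + 1) * W, -1),
      tY((R + 1) * W, -1);

  M[0] = 0.0;
  for (int i = 1; i <= R; ++i) {
    if (free_ref_ends) {
      X[i * W] = 0.0;
      tX[i * W] = -2;
    } else {
      X[i * W] = gap_open + i * gap_extend;
      tX[i * W] = (i == 1) ? 0 : 1;
    }
  }
  for (int j = 1; j <= Q; ++j) {
    Y[j] = gap_open + j * gap_extend;
    tY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= R; ++i) {
    const char rc = ref[i - 1];
    for (int j = 1; j <= Q; ++j) {
      const int k = i * W + j, kup = (i - 1) * W + j,
                kdi = (i - 1) * W + (j - 1), kle = i * W + (j - 1);
      const double s = (rc == read[j - 1] && rc != 'N') ? match : mismatch;
      // M: predecessor preference M > X > Y on ties
      double best = M[kdi];
      signed char tb = 0;
      if (X[kdi] > best) { best = X[kdi]; tb = 1; }
      if (Y[kdi] > best) { best = Y[kdi]; tb = 2; }
      if (best > NEG_INF) { M[k] = best + s; tM[k] = tb; }
      // X (deletion): prefer extending an open gap on ties
      best = X[kup] + gap_extend; tb = 1;
      if (M[kup] + gap_open + gap_extend > best) { best = M[kup] + gap_open + gap_extend; tb = 0; }
      if (Y[kup] + gap_open + gap_extend > best) { best = Y[kup] + gap_open + gap_extend; tb = 2; }
      if (best > NEG_INF) { X[k] = best; tX[k] = tb; }
      // Y (insertion): prefer extension on ties
      best = Y[kle] + gap_extend; tb = 2;
      if (M[kle] + gap_open + gap_extend > best) { best = M[kle] + gap_open + gap_extend; tb = 0; }
      if (X[kle] + gap_open + gap_extend > best) { best = X[kle] + gap_open + gap_extend; tb = 1; }
      if (best > NEG_INF) { Y[k] = best; tY[k] = tb; }
    }
  }

  // termination: with free_ref_ends the alignment may end at any reference
  // row, the suffix below it an unpenalized trailing flank; ties prefer the
  // largest row (smallest trailing flank)
  int iend = R, state = 0;
  double score = NEG_INF;
  const int ilo = free_ref_ends ? 0 : R;
  for (int i = ilo; i <= R; ++i) {
    const int k = i * W + Q;
    if (M[k] >= score) { score = M[k]; iend = i; state = 0; }
    if (X[k] >= score) { score = X[k]; iend = i; state = 1; }
    if (Y[k] >= score) { score = Y[k]; iend = i; state = 2; }
  }

  std::string aref, aread;
  aref.reserve(R + Q);
  aread.reserve(R + Q);
  for (int i = R; i > iend; --i) { // trailing flank
    aref.push_back(ref[i - 1]);
    aread.push_back('-');
  }
  int i = iend, j = Q;
  while (i > 0 || j > 0) {
    const int k = i * W + j;
    signed char prev;
    if (state == 0) {
      prev = tM[k];
      aref.push_back(ref[i - 1]);
      aread.push_back(read[j - 1]);
      --i; --j;
    } else if (state == 1) {
      prev = tX[k];
      if (prev == -2) { // free leading flank covers the remaining prefix
        for (; i > 0; --i) {
          aref.push_back(ref[i - 1]);
          aread.push_back('-');
        }
        break;
      }
      aref.push_back(ref[i - 1]);
      aread.push_back('-');
      --i;
    } else {
      prev = tY[k];
      aref.push_back('-');
      aread.push_back(read[j - 1]);
      --j;
    }
    state = prev;
  }
  std::reverse(aref.begin(), aref.end());
  std::reverse(aread.begin(), aread.end());

  return List::create(_["score"] = score,
                      _["aligned_ref"] = aref,
                      _["aligned_read"] = aread);
}

// Best anchor occurrence per read: substitution-only sliding scan returning
// the leftmost window with the fewest mismatches among those with at most
// max_mm. 'N' in the read never matches. Returns a 2 x n matrix of
// (0-based position, mismatch count), with -1 where no window qualifies.
// [[Rcpp::export(name = ".anchor_scan")]]
IntegerMatrix anchor_scan(CharacterVector reads, std::string anchor, int max_mm) {
  const int n = reads.size();
  const int A = anchor.size();
  IntegerMatrix out(2, n);
  for (int r = 0; r < n; ++r) {
    out(0, r) = -1;
    out(1, r) = -1;
    if (reads[r] == NA_STRING) continue;
    const char *s = CHAR(STRING_ELT(reads, r));
    const int L = LENGTH(STRING_ELT(reads, r));
    int best_mm = max_mm + 1;
    for (int off = 0; off + A <= L; ++off) {
      int mm = 0;
      for (int p = 0; p < A; ++p) {
        const char c = s[off + p];
        if (c != anchor[p] || c == 'N') {
          if (++mm >= best_mm) break;
        }
      }
      if (mm < best_mm) {  // strict: keeps the leftmost on ties
        best_mm = mm;
        out(0, r) = off;
        out(1, r) = mm;
        if (mm == 0) break;
      }
    }
  }
  return out;
}
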