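#include <Rcpp.h>
using namespace Rcpp;

// Texture-matrix accumulation and concordance pair counting are the O(n*m)
// hot loops of the package; everything else stays in R.

// Co-occurrence counts of quantized levels at offset (drow, dcol), symmetric
// (each valid pair counted in both orders). Cells with mask == FALSE never
// participate. Returns raw counts; normalization happens in R.
// [[Rcpp::export]]
NumericMatrix glcm_count_cpp(IntegerMatrix levels, LogicalMatrix mask,
                             int drow, int dcol, int ng) {
  int nr = levels.nrow(), nc = levels.ncol();
  NumericMatrix out(ng, ng);
  for (int r = 0; r < nr; ++r) {
    int r2 = r + drow;
    if (r2 < 0 || r2 >= nr) continue;
    for (int c = 0; c < nc; ++c) {
      int c2 = c + dcol;
      if (c2 < 0 || c2 >= nc) continue;
      if (!mask(r, c) || !mask(r2, c2)) continue;
      int i = levels(r, c), j = levels(r2, c2);
      if (i < 1 || i > ng || j < 1 || j > ng) continue;
      out(i - 1, j - 1) += 1.0;
      out(j - 1, i - 1) += 1.0;
    }
  }
  return out;
}

// Gray-level run-length counts along direction (drow, dcol). A run is a
// maximal sequence of mask-true cells with equal level; a mask gap or the
// image border terminates it. entry(i, j) = number of runs of level i with
// length j.
// [[Rcpp::export]]
NumericMatrix glrlm_count_cpp(IntegerMatrix levels, LogicalMatrix mask,
                              int drow, int dcol, int ng, int maxlen) {
  int nr = levels.nrow(), nc = levels.ncol();
  NumericMatrix out(ng, maxlen);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c)) continue;
      int lev = levels(r, c);
      if (lev < 1 || lev > ng) continue;
      // run starts here iff the predecessor cell does not continue it
      int pr = r - drow, pc = c - dcol;
      if (pr >= 0 && pr < nr && pc >= 0 && pc < nc &&
          mask(pr, pc) && levels(pr, pc) == lev) continue;
      int len = 1;
      int r2 = r + drow, c2 = c + dcol;
      while (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc &&
             mask(r2, c2) && levels(r2, c2) == lev) {
        ++len;
        r2 += drow;
        c2 += dcol;
      }
      if (len > maxlen) stop("run longer than maxlen");
      out(lev - 1, len - 1) += 1.0;
    }
  }
  return out;
}

// Band sums of a square co-occurrence matrix: psum[k] = sum over i+j == k+2
// (k = 0..2Ng-2) and pdiff[k] = sum over |i-j| == k (k = 0..Ng-1).
// [[Rcpp::export]]
List glcm_band_sums_cpp(NumericMatrix m) {
  int ng = m.nrow();
  NumericVector psum(2 * ng - 1), pdiff(ng);
  for (int i = 0; i < ng; ++i) {
    for (int j = 0; j < ng; ++j) {
      psum[i + j] += m(i, j);
      pdiff[abs(i - j)] += m(i, j);
    }
  }
  return List::create(_["psum"] = psum, _["pdiff"] = pdiff);
}

// Harrell pair counts: a pair (i, j) is comparable iff time_i < time_j and
// event_i == 1; concordant iff risk_i > risk_j, tied risks get half credit.
// Returns (concordant, tied, comparable).
// [[Rcpp::export]]
NumericVector concordance_count_cpp(NumericVector time, IntegerVector event,
                                    NumericVector risk) {
  int n = time.size();
  double conc = 0.0, tied = 0.0, comp = 0.0;
  for (int i = 0; i < n; ++i) {
    if (event[i] != 1) continue;
    for (int j = 0; j < n; ++j) {
      if (j == i || !(time[i] < time[j])) continue;
      comp += 1.0;
      if (risk[i] > risk[j]) conc += 1.0;
      else if (risk[i] == risk[j]) tied += 1.0;
    }
  }
  return NumericVector::create(conc, tied, comp);
}
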