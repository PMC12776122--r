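// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// FFT-based 'same' convolution power for a bank of complex wavelet kernels.
//
// X:       samples x series real matrix (each column one trial-channel series)
// kernFFT: nfft x nfreq complex matrix; column f holds the FFT (length nfft,
//          nfft >= n_samples + kernel length) of the complex kernel
//          cos + i*sin, circularly pre-shifted so that rows 0..n-1 of the
//          inverse transform are the centred ('same') convolution output.
//
// Returns a cube samples x series x nfreq of instantaneous power
// (squared magnitude of the complex convolution).
// Fused wavelet-power -> log-log slope -> moving average path used by the
// participant-streaming pipeline. Numerically identical to composing
// waveletPowerCpp with the R-side fit and smoother (asserted in tests).
//
// X:        samples x cols (trial-channel series)
// kernFFT:  nfft x nfit complex kernel FFTs (fit-masked frequencies only)
// wSlope:   OLS weights on log10 power per fit frequency
// meanLf:   mean log10 frequency (for the intercept)
// densDiv:  per-frequency divisor (2 * kernel frequency for density scale,
//           1 for amplitude scale)
// floorVal: power floor before log10
// k:        moving-average length (odd); edges use shrinking windows
// bound:    censor bound; offset: slope-scale offset (1 for density scale)
//
// Returns slope and intercept (samples x cols, smoothed) and a per-column
// flag marking |slope + offset| > bound anywhere.
// [[Rcpp::export(name = ".slopePipelineCpp")]]
Rcpp::List slopePipelineCpp(const arma::mat& X, const arma::cx_mat& kernFFT,
                            const arma::vec& wSlope, double meanLf,
                            const arma::vec& densDiv, double floorVal,
                            int k, double bound, double offset) {
  const uword n = X.n_rows, m = X.n_cols, nf = kernFFT.n_cols;
  const uword nfft = kernFFT.n_rows;
  cx_mat F = fft(conv_to<mat>::from(X), nfft);
  mat slope(n, m, fill::zeros), meanLp(n, m, fill::zeros);
  const double l10 = std::log(10.0);
  for (uword f = 0; f < nf; ++f) {
    cx_mat Y = F;
    Y.each_col() %= kernFFT.col(f);
    cx_mat y = ifft(Y);
    mat P = (square(real(y.rows(0, n - 1))) +
             square(imag(y.rows(0, n - 1)))) / densDiv(f);
    P.transform([floorVal, l10](double v) {
      return std::log(v + floorVal) / l10;
    });
    slope += wSlope(f) * P;
    meanLp += P / double(nf);
  }
  mat intercept = meanLp - slope * meanLf;
  // centred k-point moving average with shrinking edges, per column
  int h = (k - 1) / 2;
  if (h > 0) {
    mat smS(n, m), smI(n, m);
    for (uword j = 0; j < m; ++j) {
      vec csS = cumsum(slope.col(j));
      vec csI = cumsum(intercept.col(j));
      for (uword i = 0; i < n; ++i) {
        uword lo = (i < (uword)h) ? 0 : i - h;
        uword hi = std::min(n - 1, i + h);
        double sS = csS(hi) - (lo > 0 ? csS(lo - 1) : 0.0);
        double sI = csI(hi) - (lo > 0 ? csI(lo - 1) : 0.0);
        smS(i, j) = sS / double(hi - lo + 1);
        smI(i, j) = sI / double(hi - lo + 1);
      }
    }
    slope = smS;
    intercept = smI;
  }
  Rcpp::LogicalVector exceed(m);
  for (uword j = 0; j < m; ++j)
    exceed[j] = arma::any(arma::abs(slope.col(j) + offset) > bound);
  return Rcpp::List::create(Rcpp::Named("slope") = slope,
                            Rcpp::Named("intercept") = intercept,
                            Rcpp::Named("exceed") = exceed);
}

// Peak-to-peak sliding-window artifact scan: returns per-column max of the
// (max - min) range over full windows of width ws stepped by ss.
// [[Rcpp::export(name = ".ptpRangeCpp")]]
arma::vec ptpRangeCpp(const arma::mat& X, int ws, int ss) {
  const uword n = X.n_rows, m = X.n_cols;
  vec out(m, fill::zeros);
  for (uword j = 0; j < m; ++j) {
    double best = 0.0;
    for (uword s0 = 0; s0 + ws <= n; s0 += ss) {
      double mx = X(s0, j), mn = X(s0, j);
      for (uword i = s0 + 1; i < s0 + ws; ++i) {
        double v = X(i, j);
        if (v > mx) mx = v;
        if (v < mn) mn = v;
      }
      if (mx - mn > best) best = mx - mn;
    }
    out(j) = best;
  }
  return out;
}

// [[Rcpp::export(name = ".waveletPowerCpp")]]
arma::cube waveletPowerCpp(const arma::mat& X, const arma::cx_mat& kernFFT) {
  const uword n = X.n_rows, m = X.n_cols, nf = kernFFT.n_cols;
  const uword nfft = kernFFT.n_rows;
  cx_mat F = fft(conv_to<mat>::from(X), nfft);
  cube out(n, m, nf);
  for (uword f = 0; f < nf; ++f) {
    cx_mat Y = F;
    Y.each_col() %= kernFFT.col(f);
    cx_mat y = ifft(Y);
    out.slice(f) = square(real(y.rows(0, n - 1))) + square(imag(y.rows(0, n - 1)));
  }
  return out;
}
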