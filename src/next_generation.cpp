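// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Batched one-generation recombination of gametes held as truncated Fourier
// coefficient vectors X_0..X_K. For a child with parents X, X' and crossover
// angle psi the coefficient formula is
//   Y_k = (X_k + X'_k)/2 + sum_{odd j, |j|<=J_r} (-i/(pi j)) e^{-i j psi} D_{k-j},
// with D = X - X' and D_{-m} = conj(D_m). Writing j = k - m this is
//   Y_k = (X_k + X'_k)/2 + e^{-i k psi} sum_m H0[k,m] (D_m e^{i m psi}),
// where H0[k,m] = h_{k-m} does not depend on psi. One complex matrix product
// per chunk of children therefore evaluates the operator exactly for
// arbitrary (continuous) crossover angles.
//
// coeffs: (K+1) x P complex parent coefficients (mode 0 real).
// p1, p2: 0-based parent indices per child; psi: crossover angle per child.
// [[Rcpp::export]]
arma::cx_mat cpp_next_generation(const arma::cx_mat& coeffs,
                                 const arma::uvec& p1, const arma::uvec& p2,
                                 const arma::vec& psi, int recomb_truncation) {
  const uword K = coeffs.n_rows - 1;
  const uword P = coeffs.n_cols;
  const uword C = p1.n_elem;
  const uword M = 2 * K + 1;            // source indices m = -K .. K
  if (p2.n_elem != C || psi.n_elem != C) Rcpp::stop("index length mismatch");
  if (C > 0 && (p1.max() >= P || p2.max() >= P))
    Rcpp::stop("parent index out of range");
  const std::complex<double> I(0.0, 1.0);

  cx_mat H0(K + 1, M, fill::zeros);
  for (uword k = 0; k <= K; ++k)
    for (uword mi = 0; mi < M; ++mi) {
      const int j = static_cast<int>(k) - (static_cast<int>(mi) - static_cast<int>(K));
      if (j != 0 && std::abs(j) % 2 == 1 && std::abs(j) <= recomb_truncation)
        H0(k, mi) = std::complex<double>(0.0, -1.0 / (M_PI * j));
    }

  cx_mat out(K + 1, C);
  const uword chunk = 16384;
  for (uword c0 = 0; c0 < C; c0 += chunk) {
    const uword nb = std::min(chunk, C - c0);
    cx_mat Dt(M, nb);                   // phase-twisted difference profiles
    cx_mat avg(K + 1, nb);
    for (uword t = 0; t < nb; ++t) {
      const uword c = c0 + t;
      const std::complex<double>* xa = coeffs.colptr(p1(c));
      const std::complex<double>* xb = coeffs.colptr(p2(c));
      const std::complex<double> w = std::exp(I * psi(c));
      std::complex<double> fw(1.0, 0.0);             // w^m
      std::complex<double>* dcol = Dt.colptr(t);
      std::complex<double>* acol = avg.colptr(t);
      for (uword m = 0; m <= K; ++m) {
        const std::complex<double> d = (xa[m] - xb[m]) * fw;
        dcol[K + m] = d;
        dcol[K - m] = std::conj(d);                  // D_{-m} e^{-i m psi}
        acol[m] = 0.5 * (xa[m] + xb[m]);
        fw *= w;
      }
    }
    cx_mat Yc = H0 * Dt;
    for (uword t = 0; t < nb; ++t) {
      const uword c = c0 + t;
      const std::complex<double> winv = std::exp(-I * psi(c));
      std::complex<double> fw(1.0, 0.0);             // e^{-i k psi}
      const std::complex<double>* ycol = Yc.colptr(t);
      const std::complex<double>* acol = avg.colptr(t);
      std::complex<double>* ocol = out.colptr(c);
      for (uword k = 0; k <= K; ++k) {
        ocol[k] = acol[k] + ycol[k] * fw;
        fw *= winv;
      }
      ocol[0] = std::complex<double>(ocol[0].real(), 0.0);  // G is real
    }
  }
  return out;
}
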