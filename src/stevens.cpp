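// Exact evaluation of the abundance-generalised Stevens circle-covering
// series at a fixed MPFR working precision.  Precision escalation (evaluate
// at p bits, then 2p, accept on agreement) is driven from R; this file only
// sums the series at the precision it is told to use.
//
//   P(B = k) = C(R,k) * sum_{beta=k}^{eta} C(R-k, beta-k) (-1)^(beta-k)
//              * alpha^beta * (1 - beta*phi)^(beta-1) * (1 - beta*phi*alpha)^(R-beta)
//
// The series alternates with terms that can individually dwarf the result
// (binomials like C(1e7, 200) overflow double), so every term is formed in
// extended precision and the cancellation happens inside the MPFR
// accumulator.  Binomial coefficients are exact GMP integers.

#include <Rcpp.h>
#include <mpfr.h>
#include <gmp.h>

static bool fits_ulong(double x) {
  return x >= 0 && x < 9007199254740992.0 && x == std::floor(x);
}

// [[Rcpp::export(name = ".stevens_sum_bits")]]
double stevens_sum_bits(double R_, double k_, double phi, double alpha,
                        double eta_, int bits) {
  if (!fits_ulong(R_) || !fits_ulong(k_) || !fits_ulong(eta_))
    Rcpp::stop("R, k and eta must be non-negative integers below 2^53");
  if (bits < 2) Rcpp::stop("precision must be at least 2 bits");
  const unsigned long R = (unsigned long)R_;
  const unsigned long k = (unsigned long)k_;
  const unsigned long eta = (unsigned long)eta_;
  if (k > R) Rcpp::stop("k must not exceed R");
  if (k > eta) return 0.0;  // empty sum

  const mpfr_prec_t p = (mpfr_prec_t)bits;
  mpfr_t mphi, malpha, acc, term, base, pow1, pow2, tmp;
  mpfr_inits2(p, mphi, malpha, acc, term, base, pow1, pow2, tmp,
              (mpfr_ptr)0);
  mpfr_set_d(mphi, phi, MPFR_RNDN);
  mpfr_set_d(malpha, alpha, MPFR_RNDN);
  mpfr_set_zero(acc, 1);

  mpz_t binom;
  mpz_init(binom);

  for (unsigned long beta = k; beta <= eta; ++beta) {
    // C(R - k, beta - k)
    mpz_bin_uiui(binom, R - k, beta - k);

    // (1 - beta*phi)^(beta-1); the beta = 0 term is defined as 1
    if (beta == 0) {
      mpfr_set_ui(pow1, 1, MPFR_RNDN);
    } else {
      mpfr_mul_ui(base, mphi, beta, MPFR_RNDN);
      mpfr_ui_sub(base, 1, base, MPFR_RNDN);   // 1 - beta*phi  (> 0 by eta)
      mpfr_pow_ui(pow1, base, beta - 1, MPFR_RNDN);
    }

    // (1 - beta*phi*alpha)^(R-beta)
    mpfr_mul_ui(base, mphi, beta, MPFR_RNDN);
    mpfr_mul(base, base, malpha, MPFR_RNDN);
    mpfr_ui_sub(base, 1, base, MPFR_RNDN);
    mpfr_pow_ui(pow2, base, R - beta, MPFR_RNDN);

    // alpha^beta
    mpfr_pow_ui(tmp, malpha, beta, MPFR_RNDN);

    mpfr_mul(term, pow1, pow2, MPFR_RNDN);
    mpfr_mul(term, term, tmp, MPFR_RNDN);
    mpfr_mul_z(term, term, binom, MPFR_RNDN);

    if ((beta - k) % 2 == 1)
      mpfr_sub(acc, acc, term, MPFR_RNDN);
    else
      mpfr_add(acc, acc, term, MPFR_RNDN);
  }

  // leading C(R, k)
  mpz_bin_uiui(binom, R, k);
  mpfr_mul_z(acc, acc, binom, MPFR_RNDN);

  double out = mpfr_get_d(acc, MPFR_RNDN);
  mpz_clear(binom);
  mpfr_clears(mphi, malpha, acc, term, base, pow1, pow2, tmp, (mpfr_ptr)0);
  return out;
}

// Classic Stevens form for alpha = 1 (independent cross-check used in tests):
//   P(cover) = sum_{beta=0}^{eta} (-1)^beta C(R,beta) (1 - beta*phi)^(R-1)
// [[Rcpp::export(name = ".stevens_classic_bits")]]
double stevens_classic_bits(double R_, double phi, double eta_, int bits) {
  if (!fits_ulong(R_) || !fits_ulong(eta_))
    Rcpp::stop("R and eta must be non-negative integers below 2^53");
  const unsigned long R = (unsigned long)R_;
  const unsigned long eta = (unsigned long)eta_;
  const mpfr_prec_t p = (mpfr_prec_t)bits;
  if (R == 0) return 1.0;

  mpfr_t mphi, acc, base, term;
  mpfr_inits2(p, mphi, acc, base, term, (mpfr_ptr)0);
  mpfr_set_d(mphi, phi, MPFR_RNDN);
  mpfr_set_zero(acc, 1);
  mpz_t binom;
  mpz_init(binom);

  for (unsigned long beta = 0; beta <= eta; ++beta) {
    mpz_bin_uiui(binom, R, beta);
    mpfr_mul_ui(base, mphi, beta, MPFR_RNDN);
    mpfr_ui_sub(base, 1, base, MPFR_RNDN);
    mpfr_pow_ui(term, base, R - 1, MPFR_RNDN);
    mpfr_mul_z(term, term, binom, MPFR_RNDN);
    if (beta % 2 == 1)
      mpfr_sub(acc, acc, term, MPFR_RNDN);
    else
      mpfr_add(acc, acc, term, MPFR_RNDN);
  }

  double out = mpfr_get_d(acc, MPFR_RNDN);
  mpz_clear(binom);
  mpfr_clears(mphi, acc, base, term, (mpfr_ptr)0);
  return out;
}
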