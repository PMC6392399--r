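#include <Rcpp.h>
using namespace Rcpp;

// Conditional-logit log-likelihood accumulated per chooser.
//
// Rows of X are alternatives, grouped contiguously by choice set.  set_id
// maps each row to its (1-based) set; used_row gives, per set, the 1-based
// row index of the chosen alternative; set_animal gives, per set, the
// 1-based chooser index into the rows of B.  The per-set contribution is
// x_used' b - logsumexp_j (x_j' b), computed with the max-shift so that
// |x'b| up to ~700 cannot overflow.
//
// [[Rcpp::export]]
NumericVector cl_loglik_by_animal(NumericMatrix X, IntegerVector set_id,
                                  IntegerVector used_row,
                                  IntegerVector set_animal,
                                  NumericMatrix B, int n_animals) {
  const int n = X.nrow(), K = X.ncol(), S = used_row.size();
  NumericVector out(n_animals);
  if (n == 0) return out;
  std::vector<double> u(n);
  for (int r = 0; r < n; ++r) {
    const int a = set_animal[set_id[r] - 1] - 1;
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += X(r, k) * B(a, k);
    u[r] = s;
  }
  int r = 0;
  for (int s = 0; s < S; ++s) {
    double mx = R_NegInf;
    const int start = r;
    while (r < n && set_id[r] == s + 1) {
      if (u[r] > mx) mx = u[r];
      ++r;
    }
    double acc = 0.0;
    for (int j = start; j < r; ++j) acc += std::exp(u[j] - mx);
    const double lse = mx + std::log(acc);
    out[set_animal[s] - 1] += u[used_row[s] - 1] - lse;
  }
  return out;
}
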