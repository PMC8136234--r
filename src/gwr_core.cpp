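#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Local weighted least squares at every unit with an adaptive kernel.
//
// kernel: 0 = gaussian (untruncated), 1 = bisquare (truncated), 2 = uniform
// level:  0 = coefficients only (Monte-Carlo permutation path)
//         1 = + hat diagonal, fitted values (bandwidth selection path)
//         2 = + per-coefficient sandwich terms, tr(S'S), local R2 (full fit)
// [[Rcpp::export]]
Rcpp::List gwr_core(const arma::mat& X, const arma::vec& y,
                    const arma::mat& coords, const int k,
                    const int kernel, const int level,
                    const double ridge = 0.0) {
  const uword n = X.n_rows, p = X.n_cols;
  if (y.n_elem != n || coords.n_rows != n)
    Rcpp::stop("X, y and coords must have matching row counts");
  if (kernel != 2 && (k < 1 || (uword)k > n))
    Rcpp::stop("k out of range");

  mat beta(n, p, fill::zeros);
  vec hat_diag(n, fill::zeros), yhat(n, fill::zeros);
  vec bw(n, fill::zeros), local_r2(n, fill::zeros);
  mat cc;                       // sum_j C_i(k,j)^2 per unit/coefficient
  if (level >= 2) cc.set_size(n, p);
  double trStS = 0.0;

  vec d(n), w(n);
  for (uword i = 0; i < n; ++i) {
    for (uword j = 0; j < n; ++j) {
      const double du = coords(j, 0) - coords(i, 0);
      const double dv = coords(j, 1) - coords(i, 1);
      d[j] = std::sqrt(du * du + dv * dv);
    }
    double b = datum::inf;
    if (kernel == 2) {
      w.ones();
    } else {
      vec ds = sort(d);
      b = ds[k - 1];
      if (b <= 0.0)
        Rcpp::stop("zero adaptive bandwidth at unit %d (coincident points)", i + 1);
      if (kernel == 0) {
        w = exp(-0.5 * square(d / b));
      } else {
        w = square(1.0 - square(d / b));
        w.elem(find(d >= b)).zeros();
      }
    }
    bw[i] = b;

    mat Xw = X.each_col() % w;           // W_i X
    mat XtWX = X.t() * Xw;               // X' W_i X
    if (ridge > 0.0) XtWX.diag() += ridge;
    vec XtWy = Xw.t() * y;               // X' W_i y
    vec bi;
    bool ok = solve(bi, XtWX, XtWy, solve_opts::no_approx);
    if (!ok)
      Rcpp::stop("singular local design X'WX at unit %d", i + 1);
    beta.row(i) = bi.t();
    yhat[i] = dot(X.row(i), bi);

    if (level >= 1) {
      vec xi = X.row(i).t();
      vec g;
      if (!solve(g, XtWX, xi, solve_opts::no_approx))
        Rcpp::stop("singular local design X'WX at unit %d", i + 1);
      hat_diag[i] = w[i] * dot(xi, g);   // s_ii = w_ii x_i'(X'WX)^{-1} x_i
      if (level >= 2) {
        mat Ci;                          // p x n: (X'W X)^{-1} X' W
        if (!solve(Ci, XtWX, Xw.t(), solve_opts::no_approx))
          Rcpp::stop("singular local design X'WX at unit %d", i + 1);
        cc.row(i) = sum(square(Ci), 1).t();
        rowvec si = X.row(i) * Ci;       // hat row s_i
        trStS += dot(si, si);
        const double sw = accu(w);
        const double ybar_w = dot(w, y) / sw;
        const double tss = dot(w, square(y - ybar_w));
        const vec r = y - X * bi;
        const double rssw = dot(w, square(r));
        local_r2[i] = tss > 0 ? 1.0 - rssw / tss : datum::nan;
      }
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("yhat") = yhat,
    Rcpp::Named("bandwidth") = bw);
  if (level >= 1) out["hat_diag"] = hat_diag;
  if (level >= 2) {
    out["cc"] = cc;
    out["trStS"] = trStS;
    out["local_r2"] = local_r2;
  }
  return out;
}
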