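// Squared-error objective and analytic gradient of the single-hidden-layer
// regression network (logistic hidden activation, linear output), plus a
// fully compiled training routine that drives R's own BFGS quasi-Newton
// minimizer (vmmin from R_ext/Applic.h). Training runs thousands of times
// in leave-one-out and sensitivity experiments, hence compiled; the
// gradient reuses the forward pass cached by the objective when evaluated
// at the same weights (vmmin's calling pattern).
#include <RcppArmadillo.h>
#include <R_ext/Applic.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Weight layout (column-major, matching the R side):
// first (p+1)*h entries = input->hidden matrix W1 (rows: bias + p inputs),
// then h+1 entries = hidden->output weights w2 (bias first).

struct AnnData {
  const mat* X1;
  const vec* y;
  int h;
  double decay;
  // forward-pass cache
  vec w_cached;
  mat a;       // hidden activations at w_cached
  vec r;       // output residuals at w_cached
  bool valid = false;
};

static void ann_forward(const vec& w, AnnData& d) {
  if (d.valid && d.w_cached.n_elem == w.n_elem &&
      std::equal(w.begin(), w.end(), d.w_cached.begin())) {
    return;
  }
  const uword p1 = d.X1->n_cols;
  const mat W1(w.memptr(), p1, d.h);
  const vec w2 = w.subvec(p1 * d.h, p1 * d.h + d.h);
  d.a = 1.0 / (1.0 + exp(-((*d.X1) * W1)));
  d.r = d.a * w2.subvec(1, d.h) + w2(0) - (*d.y);
  d.w_cached = w;
  d.valid = true;
}

static double ann_obj_impl(const vec& w, AnnData& d) {
  ann_forward(w, d);
  return dot(d.r, d.r) + d.decay * dot(w, w);
}

static void ann_grad_impl(const vec& w, AnnData& d, vec& g) {
  ann_forward(w, d);
  const uword p1 = d.X1->n_cols;
  const vec w2 = w.subvec(p1 * d.h, p1 * d.h + d.h);
  vec r2 = 2.0 * d.r;
  mat delta = (r2 * w2.subvec(1, d.h).t()) % d.a % (1.0 - d.a);
  g.subvec(0, p1 * d.h - 1) = vectorise(d.X1->t() * delta);
  g(p1 * d.h) = accu(r2);
  g.subvec(p1 * d.h + 1, w.n_elem - 1) = d.a.t() * r2;
  g += 2.0 * d.decay * w;
}

// [[Rcpp::export]]
double ann_obj_cpp(const arma::vec& w, const arma::mat& X1,
                   const arma::vec& y, int h, double decay) {
  AnnData d{&X1, &y, h, decay};
  return ann_obj_impl(w, d);
}

// [[Rcpp::export]]
arma::vec ann_grad_cpp(const arma::vec& w, const arma::mat& X1,
                       const arma::vec& y, int h, double decay) {
  AnnData d{&X1, &y, h, decay};
  vec g(w.n_elem);
  ann_grad_impl(w, d, g);
  return g;
}

static double vm_fn(int n, double* par, void* ex) {
  const vec w(par, n, false, true);
  return ann_obj_impl(w, *static_cast<AnnData*>(ex));
}

static void vm_gr(int n, double* par, double* gr, void* ex) {
  const vec w(par, n, false, true);
  vec g(gr, n, false, true);
  ann_grad_impl(w, *static_cast<AnnData*>(ex), g);
}

// [[Rcpp::export]]
Rcpp::List ann_train_cpp(const arma::vec& w0, const arma::mat& X1,
                         const arma::vec& y, int h, double decay,
                         int maxit, double abstol, double reltol) {
  AnnData d{&X1, &y, h, decay};
  int n = static_cast<int>(w0.n_elem);
  vec w = w0;
  std::vector<int> mask(n, 1);
  double fmin = 0.0;
  int fncount = 0, grcount = 0, fail = 0;
  vmmin(n, w.memptr(), &fmin, vm_fn, vm_gr, maxit, 0, mask.data(),
        abstol, reltol, 10, &d, &fncount, &grcount, &fail);
  return Rcpp::List::create(
      Rcpp::Named("par") = w,
      Rcpp::Named("value") = fmin,
      Rcpp::Named("fncount") = fncount,
      Rcpp::Named("grcount") = grcount,
      Rcpp::Named("convergence") = fail);
}
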