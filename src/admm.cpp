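// Weighted SENSE-TV reconstruction by ADMM, with a reverse-mode gradient
// sweep through the unrolled iterations.
//
// Conventions match the R level: grids are stored in centered order (DC at
// index N/2, 0-based), transforms are unitary, phase-encode runs along rows,
// and all grid sizes are even.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// For even grid sizes the centered (DC-at-N/2) transform equals an
// elementwise checkerboard sign flip before and after the plain FFT; this
// avoids four circular-shift passes per transform.
static void checkerboard(cx_mat& x) {
  for (uword j = 0; j < x.n_cols; ++j)
    for (uword i = (j % 2 == 0) ? 1 : 0; i < x.n_rows; i += 2)
      x(i, j) = -x(i, j);
}

// unitary centered 2D FFT and inverse
static cx_mat ft2c(const cx_mat& x) {
  cx_mat y = x;
  checkerboard(y);
  y = fft2(y);
  checkerboard(y);
  return y / std::sqrt((double)x.n_elem);
}
static cx_mat ift2c(const cx_mat& x) {
  cx_mat y = x;
  checkerboard(y);
  y = ifft2(y);
  checkerboard(y);
  return y * std::sqrt((double)x.n_elem);
}

static cx_mat crop_center(const cx_mat& x, uword N) {
  uword r0 = x.n_rows / 2 - N / 2, c0 = x.n_cols / 2 - N / 2;
  return x.submat(r0, c0, r0 + N - 1, c0 + N - 1);
}

static cx_mat pad_center(const cx_mat& x, uword N0) {
  cx_mat out(N0, N0, fill::zeros);
  uword r0 = N0 / 2 - x.n_rows / 2, c0 = N0 / 2 - x.n_cols / 2;
  out.submat(r0, c0, r0 + x.n_rows - 1, c0 + x.n_cols - 1) = x;
  return out;
}

// E: image (N0 x N0) -> k-space cube (N x N x L)
static cx_cube E_apply(const cx_mat& x, const cx_cube& maps, uword N) {
  cx_cube out(N, N, maps.n_slices);
  for (uword l = 0; l < maps.n_slices; ++l)
    out.slice(l) = crop_center(ft2c(maps.slice(l) % x), N);
  return out;
}

// E^H: k-space cube (N x N x L) -> image (N0 x N0)
static cx_mat E_adjoint(const cx_cube& y, const cx_cube& maps) {
  uword N0 = maps.n_rows;
  cx_mat out(N0, N0, fill::zeros);
  for (uword l = 0; l < maps.n_slices; ++l)
    out += conj(maps.slice(l)) % ift2c(pad_center(y.slice(l), N0));
  return out;
}

// periodic first differences, stacked as an (N0 x N0 x 2) cube
static cx_cube D_apply(const cx_mat& x) {
  cx_cube out(x.n_rows, x.n_cols, 2);
  out.slice(0) = shift(x, -1, 0) - x;  // row differences
  out.slice(1) = shift(x, -1, 1) - x;  // column differences
  return out;
}

static cx_mat D_adjoint(const cx_cube& y) {
  return (shift(y.slice(0), 1, 0) - y.slice(0)) +
         (shift(y.slice(1), 1, 1) - y.slice(1));
}

// row weighting: multiply line m (row) of every channel by v(m)
static cx_cube row_weight(const cx_cube& y, const vec& v) {
  cx_cube out = y;
  for (uword l = 0; l < out.n_slices; ++l)
    out.slice(l).each_col() %= conv_to<cx_vec>::from(v);
  return out;
}

// normal-equation operator M x = 2 E^H(ww . E x) + rho D^H D x
static cx_mat M_apply(const cx_mat& x, const cx_cube& maps, uword N,
                      const vec& ww, double rho) {
  return 2.0 * E_adjoint(row_weight(E_apply(x, maps, N), ww), maps) +
         rho * D_adjoint(D_apply(x));
}

// conjugate gradients for the Hermitian PSD system M x = b
static cx_mat cg_solve(const cx_mat& b, const cx_mat& x0, const cx_cube& maps,
                       uword N, const vec& ww, double rho, int iters,
                       double tol) {
  cx_mat x = x0;
  cx_mat r = b - M_apply(x, maps, N, ww, rho);
  cx_mat p = r;
  double rs = std::real(cdot(vectorise(r), vectorise(r)));
  double b2 = std::real(cdot(vectorise(b), vectorise(b)));
  if (b2 <= 0) return cx_mat(size(b), fill::zeros);
  for (int i = 0; i < iters; ++i) {
    if (rs <= tol * tol * b2) break;
    cx_mat Mp = M_apply(p, maps, N, ww, rho);
    double alpha = rs / std::real(cdot(vectorise(p), vectorise(Mp)));
    x += alpha * p;
    r -= alpha * Mp;
    double rs_new = std::real(cdot(vectorise(r), vectorise(r)));
    p = r + (rs_new / rs) * p;
    rs = rs_new;
  }
  return x;
}

// complex soft threshold z = v * max(1 - tau/|v|, 0)
static cx_cube soft(const cx_cube& v, double tau) {
  cx_cube out(size(v));
  for (uword i = 0; i < v.n_elem; ++i) {
    double r = std::abs(v(i));
    out(i) = (r > tau) ? v(i) * (1.0 - tau / r) : cx_double(0, 0);
  }
  return out;
}

static double objective_val(const cx_mat& x, const cx_cube& d,
                            const cx_cube& maps, uword N, const vec& ww,
                            double lambda) {
  cx_cube res = E_apply(x, maps, N) - d;
  double data = 0;
  for (uword l = 0; l < res.n_slices; ++l) {
    mat a2 = square(abs(res.slice(l)));
    a2.each_col() %= ww;
    data += accu(a2);
  }
  cx_cube Dx = D_apply(x);
  return data + lambda * accu(abs(Dx.slice(0))) + lambda * accu(abs(Dx.slice(1)));
}

struct AdmmTrace {
  std::vector<cx_mat> x;
  std::vector<cx_cube> v;   // v_k = D x_k + u_{k-1}
};

// Forward ADMM; optionally records per-iteration state for the backward pass.
static cx_mat admm_forward(const cx_cube& d, const cx_cube& maps,
                           const vec& ww, double lambda, double rho,
                           int iters, int cg_iters, double cg_tol,
                           vec& obj, AdmmTrace* trace) {
  uword N = d.n_rows, N0 = maps.n_rows;
  double tau = lambda / rho;
  cx_mat c0 = 2.0 * E_adjoint(row_weight(d, ww), maps);
  cx_mat x(N0, N0, fill::zeros);
  cx_cube z(N0, N0, 2, fill::zeros), u(N0, N0, 2, fill::zeros);
  obj.set_size(iters);
  for (int k = 0; k < iters; ++k) {
    cx_mat b = c0 + rho * D_adjoint(z - u);
    x = cg_solve(b, x, maps, N, ww, rho, cg_iters, cg_tol);
    cx_cube v = D_apply(x) + u;
    z = soft(v, tau);
    u = v - z;
    obj(k) = objective_val(x, d, maps, N, ww, lambda);
    if (trace) { trace->x.push_back(x); trace->v.push_back(v); }
  }
  return x;
}

// [[Rcpp::export]]
Rcpp::List admm_sense_tv_cpp(const arma::cx_cube& d, const arma::cx_cube& maps,
                             const arma::vec& wdata, double lambda, double rho,
                             int iterations, int cg_iters, double cg_tol) {
  vec ww = square(wdata);
  vec obj;
  cx_mat x = admm_forward(d, maps, ww, lambda, rho, iterations, cg_iters,
                          cg_tol, obj, nullptr);
  return Rcpp::List::create(Rcpp::Named("x") = x,
                            Rcpp::Named("objective") = obj);
}

// adjoint of the soft threshold (real pairing), plus the tau sensitivity
static cx_cube soft_adjoint(const cx_cube& v, double tau, const cx_cube& c,
                            double& tau_bar) {
  cx_cube out(size(v), fill::zeros);
  for (uword i = 0; i < v.n_elem; ++i) {
    double r = std::abs(v(i));
    if (r > tau) {
      cx_double vi = v(i), ci = c(i);
      double inner = std::real(std::conj(vi) * ci);
      out(i) = (1.0 - tau / r) * ci + (tau / (r * r * r)) * vi * inner;
      tau_bar += std::real(std::conj(ci) * (-vi / r));
    }
  }
  return out;
}

// per-line (row) accumulation of Re(conj(a) . b) over readout and channels
static vec line_re_dot(const cx_cube& a, const cx_cube& b) {
  vec out(a.n_rows, fill::zeros);
  for (uword l = 0; l < a.n_slices; ++l)
    out += sum(real(conj(a.slice(l)) % b.slice(l)), 1);
  return out;
}

// Training loss J = ||x_K - r||^2 and its gradients with respect to lambda
// and the effective averages w, by reverse-mode differentiation of the
// unrolled ADMM iterations. Each CG solve is treated as an exact solve of
// the normal equations (implicit backward: another CG solve with the same
// operator). The w-gradient combines the data-weighting dependence and the
// noise-scaling dependence d = s + sigma * z / sqrt(w).
// [[Rcpp::export]]
Rcpp::List admm_sense_tv_grad_cpp(const arma::cx_cube& s_N,
                                  const arma::cx_cube& z_N,
                                  const arma::vec& w, double sigma,
                                  const arma::cx_cube& maps, double lambda,
                                  double rho, int iterations, int cg_iters,
                                  double cg_tol, const arma::cx_mat& r,
                                  bool literal_w) {
  uword N = s_N.n_rows;
  vec scale = sigma / sqrt(w);
  cx_cube d = s_N + row_weight(z_N, scale);
  vec ww = literal_w ? vec(square(w)) : w;  // quadratic data weight per line
  double tau = lambda / rho;

  AdmmTrace trace;
  vec obj;
  cx_mat xK = admm_forward(d, maps, ww, lambda, rho, iterations, cg_iters,
                           cg_tol, obj, &trace);
  double loss = accu(square(abs(xK - r)));

  // reverse sweep
  cx_mat xb = 2.0 * (xK - r);
  cx_cube zb(maps.n_rows, maps.n_cols, 2, fill::zeros);
  cx_cube ub(maps.n_rows, maps.n_cols, 2, fill::zeros);
  cx_mat c0b(maps.n_rows, maps.n_cols, fill::zeros);
  vec wwb(N, fill::zeros);
  double tau_bar = 0;
  cx_mat zero_x(maps.n_rows, maps.n_cols, fill::zeros);

  for (int k = iterations - 1; k >= 0; --k) {
    const cx_mat& xk = trace.x[k];
    const cx_cube& vk = trace.v[k];
    // z_k = soft(v_k), u_k = v_k - z_k
    cx_cube c = zb - ub;
    cx_cube vb = ub + soft_adjoint(vk, tau, c, tau_bar);
    // v_k = D x_k + u_{k-1}
    xb += D_adjoint(vb);
    cx_cube ub_prev = vb;
    // x_k = M^{-1} b_k
    cx_mat sb = cg_solve(xb, zero_x, maps, N, ww, rho, cg_iters, cg_tol);
    wwb += -2.0 * line_re_dot(E_apply(sb, maps, N), E_apply(xk, maps, N));
    // b_k = c0 + rho D^H (z_{k-1} - u_{k-1})
    cx_cube t = D_apply(sb);
    zb = rho * t;
    ub = ub_prev - rho * t;
    c0b += sb;
    xb = zero_x;
  }
  // c0 = 2 E^H (ww . d)
  cx_cube Ec = E_apply(c0b, maps, N);
  wwb += 2.0 * line_re_dot(Ec, d);
  cx_cube db = 2.0 * row_weight(Ec, ww);
  // d = s + sigma w^{-1/2} z
  vec wb_noise = line_re_dot(db, z_N) % (-0.5 * sigma * pow(w, -1.5));
  vec wb = (literal_w ? wwb % (2.0 * w) : wwb) + wb_noise;
  double grad_lambda = tau_bar / rho;

  return Rcpp::List::create(
      Rcpp::Named("loss") = loss, Rcpp::Named("x") = xK,
      Rcpp::Named("grad_lambda") = grad_lambda, Rcpp::Named("grad_w") = wb,
      Rcpp::Named("objective") = obj);
}
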