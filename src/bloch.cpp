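// Fast path for the Bloch-McConnell forward model used inside global fits.
// The pure-R implementation in R/bloch-mcconnell.R is the reference; this
// routine must agree with it to numerical precision (tested).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Mono-exponential rate extraction: log-linear initialisation followed by
// Gauss-Newton refinement of I(t) = I0 * exp(-R * t).  Mirrors
// .monoexp_rate() on the R side (same initialisation, same normal equations).
static double monoexp_rate(const vec& t, const vec& I) {
  uvec pos = find(I > 0);
  vec tp = t(pos), lI = log(I(pos));
  double n = (double)tp.n_elem;
  double st = sum(tp), stt = dot(tp, tp);
  double sy = sum(lI), sty = dot(tp, lI);
  double det = n * stt - st * st;
  double b = (n * sty - st * sy) / det;       // slope
  double a = (sy * stt - st * sty) / det;     // intercept
  double I0 = std::exp(a), R = -b;
  for (int it = 0; it < 6; ++it) {
    vec mu = I0 * exp(-R * t);
    vec j1 = mu / I0;          // dmu/dI0
    vec j2 = -t % mu;          // dmu/dR
    vec res = I - mu;
    double a11 = dot(j1, j1), a12 = dot(j1, j2), a22 = dot(j2, j2);
    double g1 = dot(j1, res), g2 = dot(j2, res);
    double d = a11 * a22 - a12 * a12;
    if (d <= 0 || !std::isfinite(d)) break;
    I0 += (a22 * g1 - a12 * g2) / d;
    R  += (a11 * g2 - a12 * g1) / d;
  }
  return R;
}

// Build the 3n x 3n rotating-frame generator: per-state blocks ordered
// (Mx, My, Mz), precession about z at the state offset, nutation about x at
// the spin-lock field, R2 on transverse / R1 on longitudinal components, and
// per-axis exchange coupling K(i,j) = k_{i->j}.
static mat bm_generator(const vec& Om, double om1, double r1, double r2,
                        const mat& K) {
  unsigned int n = Om.n_elem;
  mat A(3 * n, 3 * n, fill::zeros);
  for (unsigned int i = 0; i < n; ++i) {
    unsigned int o = 3 * i;
    A(o, o) = -r2; A(o + 1, o + 1) = -r2; A(o + 2, o + 2) = -r1;
    A(o, o + 1) = -Om(i); A(o + 1, o) = Om(i);
    A(o + 1, o + 2) = -om1; A(o + 2, o + 1) = om1;
  }
  for (unsigned int i = 0; i < n; ++i)
    for (unsigned int j = 0; j < n; ++j) {
      if (i == j || K(i, j) <= 0) continue;
      for (unsigned int ax = 0; ax < 3; ++ax) {
        A(3 * i + ax, 3 * i + ax) -= K(i, j);
        A(3 * j + ax, 3 * i + ax) += K(i, j);
      }
    }
  return A;
}

// Propagate m0 under A and project onto `detect` at each delay.
static vec bm_intensities(const mat& A, const vec& m0, const vec& detect,
                          const vec& delays) {
  cx_vec eval;
  cx_mat evec;
  vec out(delays.n_elem);
  bool ok = eig_gen(eval, evec, A);
  if (ok) {
    cx_vec c;
    ok = solve(c, evec, cx_vec(m0, vec(m0.n_elem, fill::zeros)));
    if (ok) {
      cx_rowvec w = cx_rowvec(detect.t(), rowvec(detect.n_elem, fill::zeros)) * evec;
      for (unsigned int k = 0; k < delays.n_elem; ++k)
        out(k) = real(as_scalar(w * (c % exp(eval * delays(k)))));
      return out;
    }
  }
  // fallback for defective generators: scaling-and-squaring exponential
  for (unsigned int k = 0; k < delays.n_elem; ++k)
    out(k) = dot(detect, expmat(A * delays(k)) * m0);
  return out;
}

// [[Rcpp::export(name = ".r1rho_grid_cpp")]]
Rcpp::NumericVector r1rho_grid_cpp(const arma::vec& p, const arma::mat& K,
                                   const arma::vec& dw_rad,
                                   const arma::vec& power_hz,
                                   const arma::vec& offset_hz,
                                   const arma::vec& delays,
                                   double r1, double r2, bool avg_align) {
  unsigned int n = p.n_elem, m = power_hz.n_elem;
  Rcpp::NumericVector out(m);
  for (unsigned int c = 0; c < m; ++c) {
    double om1 = 2.0 * M_PI * power_hz(c);
    vec Om = 2.0 * M_PI * offset_hz(c) + dw_rad;   // per-state carrier offsets
    mat A = bm_generator(Om, om1, r1, r2, K);
    double Om_al = avg_align ? dot(p, Om) : Om(0);
    double theta = std::atan2(om1, Om_al);
    vec axis = {std::sin(theta), 0.0, std::cos(theta)};
    vec m0(3 * n), detect(3 * n);
    for (unsigned int i = 0; i < n; ++i)
      for (unsigned int ax = 0; ax < 3; ++ax) {
        m0(3 * i + ax) = p(i) * axis(ax);
        detect(3 * i + ax) = axis(ax);
      }
    vec I = bm_intensities(A, m0, detect, delays);
    out[c] = monoexp_rate(delays, I);
  }
  return out;
}
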