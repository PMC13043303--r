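// Pseudo-spectral time-domain solver for the 2-D isotropic elastic wave
// equation in velocity-stress form, with half-cell staggered grids (shifts
// applied as spectral phase factors), split-field PML, and the exact
// transpose of the discrete forward map (for adjoint-based reconstruction).
//
// State layout (10 split fields, each n1 x n2):
//   vx = vx_x + vx_y          velocities (x-component split by PML axis)
//   vy = vy_x + vy_y
//   sxx = sxx_x + sxx_y       normal stresses
//   syy = syy_x + syy_y
//   sxy = sxy_x + sxy_y       shear stress
//
// Staggering: sxx, syy (and rho, lam, mu) at integer points (i, j);
// vx at (i+1/2, j); vy at (i, j+1/2); sxy at (i+1/2, j+1/2).
//
// The adjoint stepper transposes each primitive: diagonal factors are
// symmetric, and the transpose of the shifted spectral derivative D_{+1/2}
// is -D_{-1/2} (exactly, including the Nyquist mode).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

// derivative symbol along one axis: i*k*exp(shift * i*k*dx/2), shift = +-1
static cx_vec deriv_symbol(int n, double dx, int shift) {
  cx_vec m(n);
  const std::complex<double> I(0.0, 1.0);
  for (int i = 0; i < n; i++) {
    double f = (i <= n / 2) ? i : i - n;
    double k = 2.0 * datum::pi * f / (n * dx);
    m(i) = I * k * std::exp(I * (0.5 * shift * k * dx));
  }
  return m;
}

// multiply spectrum F elementwise by separable symbol mx (rows) / my (cols);
// either may be empty (treated as 1)
static cx_mat apply_symbol(const cx_mat& F, const cx_vec& mx, const cx_vec& my) {
  cx_mat G = F;
  if (mx.n_elem) G.each_col() %= mx;
  if (my.n_elem) G.each_row() %= strans(my);
  return G;
}

struct Deriv2D {
  cx_vec xp, xm, yp, ym, none;
  Deriv2D(int n1, int n2, double dx1, double dx2) {
    xp = deriv_symbol(n1, dx1, +1);
    xm = deriv_symbol(n1, dx1, -1);
    yp = deriv_symbol(n2, dx2, +1);
    ym = deriv_symbol(n2, dx2, -1);
  }
};

// staggered buoyancy 1/rho averaged to (i+1/2, j) resp. (i, j+1/2),
// periodic wrap at the domain edge (inside the PML, physically irrelevant)
static void staggered_buoyancy(const mat& rho, mat& bx, mat& by) {
  const uword n1 = rho.n_rows, n2 = rho.n_cols;
  bx.set_size(n1, n2); by.set_size(n1, n2);
  for (uword j = 0; j < n2; j++)
    for (uword i = 0; i < n1; i++) {
      bx(i, j) = 2.0 / (rho(i, j) + rho((i + 1) % n1, j));
      by(i, j) = 2.0 / (rho(i, j) + rho(i, (j + 1) % n2));
    }
}

struct Decay2D {
  // exp(-alpha*dt/2) per axis, at integer and half-shifted positions,
  // expanded to full fields for elementwise use
  mat a1i, a1h, a2i, a2h;
  Decay2D(const vec& a1i_, const vec& a1h_, const vec& a2i_, const vec& a2h_,
          int n1, int n2) {
    a1i = repmat(a1i_, 1, n2);  a1h = repmat(a1h_, 1, n2);
    a2i = repmat(strans(a2i_), n1, 1);  a2h = repmat(strans(a2h_), n1, 1);
  }
};

struct State2D {
  mat vx_x, vx_y, vy_x, vy_y;
  mat sxx_x, sxx_y, syy_x, syy_y, sxy_x, sxy_y;
  void zeros(int n1, int n2) {
    vx_x.zeros(n1, n2); vx_y.zeros(n1, n2); vy_x.zeros(n1, n2); vy_y.zeros(n1, n2);
    sxx_x.zeros(n1, n2); sxx_y.zeros(n1, n2); syy_x.zeros(n1, n2);
    syy_y.zeros(n1, n2); sxy_x.zeros(n1, n2); sxy_y.zeros(n1, n2);
  }
};

static mat get_field(const List& s, const char* nm, int n1, int n2) {
  if (!s.containsElementNamed(nm)) return zeros<mat>(n1, n2);
  return Rcpp::as<mat>(s[nm]);
}

// one forward step; dtv is the velocity-update time step (dt, or dt/2 on the
// first step so stresses sit at integer and velocities at half-integer times)
static void forward_step(State2D& u, const Deriv2D& D, const Decay2D& A,
                         const mat& bx, const mat& by, const mat& lam,
                         const mat& l2m, const mat& mu, double dtv, double dt) {
  const std::complex<double> I(0.0, 1.0);
  // velocity update: rho dv_i/dt = d_j sigma_ij
  cx_mat Fxx = fft2(cx_mat(u.sxx_x + u.sxx_y, mat(size(u.sxx_x), fill::zeros)));
  cx_mat Fyy = fft2(cx_mat(u.syy_x + u.syy_y, mat(size(u.sxx_x), fill::zeros)));
  cx_mat Fxy = fft2(cx_mat(u.sxy_x + u.sxy_y, mat(size(u.sxx_x), fill::zeros)));
  // pack: Re -> Dx+ sxx, Im -> Dy+ syy
  cx_mat z1 = ifft2(apply_symbol(Fxx, D.xp, cx_vec()) +
                    I * apply_symbol(Fyy, cx_vec(), D.yp));
  // pack: Re -> Dx- sxy, Im -> Dy- sxy
  cx_mat z2 = ifft2(apply_symbol(Fxy, D.xm, cx_vec()) +
                    I * apply_symbol(Fxy, cx_vec(), D.ym));
  mat dx_sxx = real(z1), dy_syy = imag(z1);
  mat dx_sxy = real(z2), dy_sxy = imag(z2);
  u.vx_x = A.a1h % (A.a1h % u.vx_x + dtv * (bx % dx_sxx));
  u.vx_y = A.a2i % (A.a2i % u.vx_y + dtv * (bx % dy_sxy));
  u.vy_x = A.a1i % (A.a1i % u.vy_x + dtv * (by % dx_sxy));
  u.vy_y = A.a2h % (A.a2h % u.vy_y + dtv * (by % dy_syy));
  // stress update: dsigma_ij/dt = lam delta_ij div v + mu (d_i v_j + d_j v_i)
  cx_mat Fvx = fft2(cx_mat(u.vx_x + u.vx_y, mat(size(u.sxx_x), fill::zeros)));
  cx_mat Fvy = fft2(cx_mat(u.vy_x + u.vy_y, mat(size(u.sxx_x), fill::zeros)));
  cx_mat z3 = ifft2(apply_symbol(Fvx, D.xm, cx_vec()) +
                    I * apply_symbol(Fvy, cx_vec(), D.ym));
  cx_mat z4 = ifft2(apply_symbol(Fvy, D.xp, cx_vec()) +
                    I * apply_symbol(Fvx, cx_vec(), D.yp));
  mat exx = real(z3), eyy = imag(z3);
  mat dxvy = real(z4), dyvx = imag(z4);
  u.sxx_x = A.a1i % (A.a1i % u.sxx_x + dt * (l2m % exx));
  u.sxx_y = A.a2i % (A.a2i % u.sxx_y + dt * (lam % eyy));
  u.syy_x = A.a1i % (A.a1i % u.syy_x + dt * (lam % exx));
  u.syy_y = A.a2i % (A.a2i % u.syy_y + dt * (l2m % eyy));
  u.sxy_x = A.a1h % (A.a1h % u.sxy_x + dt * (mu % dxvy));
  u.sxy_y = A.a2h % (A.a2h % u.sxy_y + dt * (mu % dyvx));
}

// transpose of forward_step applied to the adjoint state
static void adjoint_step(State2D& u, const Deriv2D& D, const Decay2D& A,
                         const mat& bx, const mat& by, const mat& lam,
                         const mat& l2m, const mat& mu, double dtv, double dt) {
  const std::complex<double> I(0.0, 1.0);
  // T_sigma^T : stresses feed adjoint velocities through -D_opposite
  mat gx = dt * (l2m % (A.a1i % u.sxx_x) + lam % (A.a1i % u.syy_x));
  mat hy = dt * (lam % (A.a2i % u.sxx_y) + l2m % (A.a2i % u.syy_y));
  mat hxy_x = dt * (mu % (A.a1h % u.sxy_x));
  mat hxy_y = dt * (mu % (A.a2h % u.sxy_y));
  cx_mat Fgx = fft2(cx_mat(gx, mat(size(gx), fill::zeros)));
  cx_mat Fhy = fft2(cx_mat(hy, mat(size(gx), fill::zeros)));
  cx_mat Fhx = fft2(cx_mat(hxy_x, mat(size(gx), fill::zeros)));
  cx_mat Fhyy = fft2(cx_mat(hxy_y, mat(size(gx), fill::zeros)));
  // Re -> Dx+ gx, Im -> Dy+ hy ; Re -> Dx- hxy_x, Im -> Dy- hxy_y
  cx_mat z1 = ifft2(apply_symbol(Fgx, D.xp, cx_vec()) +
                    I * apply_symbol(Fhy, cx_vec(), D.yp));
  cx_mat z2 = ifft2(apply_symbol(Fhx, D.xm, cx_vec()) +
                    I * apply_symbol(Fhyy, cx_vec(), D.ym));
  mat vxc = -real(z1) - imag(z2);   // (D_x-)^T = -D_x+ ; (D_y+)^T = -D_y-
  mat vyc = -imag(z1) - real(z2);
  u.vx_x += vxc; u.vx_y += vxc;
  u.vy_x += vyc; u.vy_y += vyc;
  u.sxx_x %= A.a1i % A.a1i; u.sxx_y %= A.a2i % A.a2i;
  u.syy_x %= A.a1i % A.a1i; u.syy_y %= A.a2i % A.a2i;
  u.sxy_x %= A.a1h % A.a1h; u.sxy_y %= A.a2h % A.a2h;
  // T_v^T : velocities feed adjoint stresses
  mat qxx = dtv * (bx % (A.a1h % u.vx_x));
  mat qxy_a = dtv * (bx % (A.a2i % u.vx_y));
  mat qxy_b = dtv * (by % (A.a1i % u.vy_x));
  mat qyy = dtv * (by % (A.a2h % u.vy_y));
  cx_mat Fq1 = fft2(cx_mat(qxx, mat(size(gx), fill::zeros)));
  cx_mat Fq4 = fft2(cx_mat(qyy, mat(size(gx), fill::zeros)));
  cx_mat Fq2 = fft2(cx_mat(qxy_a, mat(size(gx), fill::zeros)));
  cx_mat Fq3 = fft2(cx_mat(qxy_b, mat(size(gx), fill::zeros)));
  cx_mat z3 = ifft2(apply_symbol(Fq1, D.xm, cx_vec()) +
                    I * apply_symbol(Fq4, cx_vec(), D.ym));
  // single inverse for the sxy contribution: (D_y-)^T qxy_a + (D_x-)^T qxy_b
  cx_mat z4 = ifft2(apply_symbol(Fq2, cx_vec(), D.yp) +
                    apply_symbol(Fq3, D.xp, cx_vec()));
  mat sxxc = -real(z3);      // (D_x+)^T = -D_x-
  mat syyc = -imag(z3);
  mat sxyc = -real(z4);
  u.sxx_x += sxxc; u.sxx_y += sxxc;
  u.syy_x += syyc; u.syy_y += syyc;
  u.sxy_x += sxyc; u.sxy_y += sxyc;
  u.vx_x %= A.a1h % A.a1h; u.vx_y %= A.a2i % A.a2i;
  u.vy_x %= A.a1i % A.a1i; u.vy_y %= A.a2h % A.a2h;
}

static double state_absmax(const State2D& u) {
  double m = 0;
  m = std::max(m, abs(u.vx_x).max()); m = std::max(m, abs(u.vy_y).max());
  m = std::max(m, abs(u.sxx_x).max()); m = std::max(m, abs(u.syy_y).max());
  m = std::max(m, abs(u.sxy_x).max());
  return m;
}

// [[Rcpp::export(name = ".elastic_run_2d")]]
List elastic_run_2d(List state0, const arma::mat& rho, const arma::mat& lam,
                    const arma::mat& mu, double dx1, double dx2, double dt,
                    int nt, const arma::vec& a1i, const arma::vec& a1h,
                    const arma::vec& a2i, const arma::vec& a2h,
                    const arma::imat& sidx, const arma::mat& sw,
                    bool first_halfstep, bool record_p, bool record_sxy,
                    bool energy, bool return_state) {
  const int n1 = rho.n_rows, n2 = rho.n_cols;
  Deriv2D D(n1, n2, dx1, dx2);
  Decay2D A(a1i, a1h, a2i, a2h, n1, n2);
  mat bx, by; staggered_buoyancy(rho, bx, by);
  mat l2m = lam + 2.0 * mu;
  State2D u;
  u.vx_x = get_field(state0, "vx_x", n1, n2); u.vx_y = get_field(state0, "vx_y", n1, n2);
  u.vy_x = get_field(state0, "vy_x", n1, n2); u.vy_y = get_field(state0, "vy_y", n1, n2);
  u.sxx_x = get_field(state0, "sxx_x", n1, n2); u.sxx_y = get_field(state0, "sxx_y", n1, n2);
  u.syy_x = get_field(state0, "syy_x", n1, n2); u.syy_y = get_field(state0, "syy_y", n1, n2);
  u.sxy_x = get_field(state0, "sxy_x", n1, n2); u.sxy_y = get_field(state0, "sxy_y", n1, n2);
  const int nm = sidx.n_rows;
  mat trace_p, trace_sxy;
  if (record_p && nm) trace_p.zeros(nm, nt);
  if (record_sxy && nm) trace_sxy.zeros(nm, nt);
  vec etrace;
  if (energy) etrace.zeros(nt);
  const double ref = state_absmax(u);
  mat sxx_prev, syy_prev, sxy_prev;
  for (int t = 0; t < nt; t++) {
    double dtv = (first_halfstep && t == 0) ? 0.5 * dt : dt;
    if (energy) {
      sxx_prev = u.sxx_x + u.sxx_y; syy_prev = u.syy_x + u.syy_y;
      sxy_prev = u.sxy_x + u.sxy_y;
    }
    forward_step(u, D, A, bx, by, lam, l2m, mu, dtv, dt);
    if (record_p && nm) {
      mat p = -0.5 * (u.sxx_x + u.sxx_y + u.syy_x + u.syy_y);
      const double* pp = p.memptr();
      for (int m = 0; m < nm; m++) {
        double acc = 0;
        for (int k = 0; k < 4; k++) acc += sw(m, k) * pp[sidx(m, k) - 1];
        trace_p(m, t) = acc;
      }
    }
    if (record_sxy && nm) {
      mat s = u.sxy_x + u.sxy_y;
      const double* pp = s.memptr();
      for (int m = 0; m < nm; m++) {
        double acc = 0;
        for (int k = 0; k < 4; k++) acc += sw(m, k) * pp[sidx(m, k) - 1];
        trace_sxy(m, t) = acc;
      }
    }
    if (energy) {
      // discrete invariant of the leapfrog scheme: plain kinetic energy at
      // the half-integer velocity time plus the strain energy evaluated as
      // the symmetric bilinear form between stresses at the two adjacent
      // integer times, sigma^n C^{-1} sigma^{n+1} (2-D plane elasticity:
      // volumetric modulus lam + mu, deviatoric 2 mu)
      mat vx = u.vx_x + u.vx_y, vy = u.vy_x + u.vy_y;
      mat sxx = u.sxx_x + u.sxx_y, syy = u.syy_x + u.syy_y, sxy = u.sxy_x + u.sxy_y;
      mat sm_a = 0.5 * (sxx_prev + syy_prev), sm_b = 0.5 * (sxx + syy);
      mat dv_a = 0.5 * (sxx_prev - syy_prev), dv_b = 0.5 * (sxx - syy);
      double ke = 0.5 * accu(rho % (vx % vx + vy % vy));
      mat pe_f = (sm_a % sm_b) / (2.0 * (lam + mu));
      mat dev = dv_a % dv_b + sxy_prev % sxy;
      for (uword q = 0; q < mu.n_elem; q++)
        if (mu(q) > 0) pe_f(q) += 0.5 * dev(q) / mu(q);
      etrace(t) = (ke + accu(pe_f)) * dx1 * dx2;
    }
    if (ref > 0 && (t % 64 == 63)) {
      if (state_absmax(u) > 1e6 * ref)
        Rcpp::stop("elastic solver unstable at step %d: field grew beyond 1e6x the initial amplitude (reduce dt)", t + 1);
    }
  }
  List out = List::create(Named("trace_p") = trace_p,
                          Named("trace_sxy") = trace_sxy,
                          Named("energy") = etrace);
  if (return_state)
    out["state"] = List::create(
      Named("vx_x") = u.vx_x, Named("vx_y") = u.vx_y,
      Named("vy_x") = u.vy_x, Named("vy_y") = u.vy_y,
      Named("sxx_x") = u.sxx_x, Named("sxx_y") = u.sxx_y,
      Named("syy_x") = u.syy_x, Named("syy_y") = u.syy_y,
      Named("sxy_x") = u.sxy_x, Named("sxy_y") = u.sxy_y);
  return out;
}

// Adjoint of (record over nt steps) o (time stepping) o (init from p0):
// scatter the weighted residual at each time into the adjoint normal
// stresses (transpose of pressure sampling), run the transposed step, and
// finally apply the transpose of the initial condition sigma_ii = -p0.
// [[Rcpp::export(name = ".elastic_adjoint_2d")]]
arma::mat elastic_adjoint_2d(const arma::mat& wdata, const arma::mat& rho,
                             const arma::mat& lam, const arma::mat& mu,
                             double dx1, double dx2, double dt, int nt,
                             const arma::vec& a1i, const arma::vec& a1h,
                             const arma::vec& a2i, const arma::vec& a2h,
                             const arma::imat& sidx, const arma::mat& sw,
                             bool first_halfstep) {
  const int n1 = rho.n_rows, n2 = rho.n_cols;
  Deriv2D D(n1, n2, dx1, dx2);
  Decay2D A(a1i, a1h, a2i, a2h, n1, n2);
  mat bx, by; staggered_buoyancy(rho, bx, by);
  mat l2m = lam + 2.0 * mu;
  const int nm = sidx.n_rows;
  State2D u; u.zeros(n1, n2);
  for (int t = nt - 1; t >= 0; t--) {
    // transpose of: p = -(sxx + syy)/2 sampled at sensors after step t
    mat inj(n1, n2, fill::zeros);
    double* ip = inj.memptr();
    for (int m = 0; m < nm; m++) {
      double wv = wdata(m, t);
      if (wv != 0)
        for (int k = 0; k < 4; k++) ip[sidx(m, k) - 1] += sw(m, k) * wv;
    }
    inj *= -0.5;
    u.sxx_x += inj; u.sxx_y += inj; u.syy_x += inj; u.syy_y += inj;
    double dtv = (first_halfstep && t == 0) ? 0.5 * dt : dt;
    adjoint_step(u, D, A, bx, by, lam, l2m, mu, dtv, dt);
  }
  // transpose of init: sxx_x = sxx_y = syy_x = syy_y = -p0/2
  return -0.5 * (u.sxx_x + u.sxx_y + u.syy_x + u.syy_y);
}
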