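// 3-D pseudo-spectral velocity-stress elastic solver and its exact discrete
// adjoint. Same scheme as the 2-D version (staggered grids via spectral
// phase shifts, split-field PML, leapfrog with an initial velocity half
// step); 24 split fields. The 3-D FFT is assembled from 1-D passes.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static cx_vec deriv_symbol3(int n, double dx, int shift) {
  cx_vec m(n);
  const std::complex<double> I(0.0, 1.0);
  for (int i = 0; i < n; i++) {
    double f = (i <= n / 2) ? i : i - n;
    double k = 2.0 * datum::pi * f / (n * dx);
    m(i) = I * k * std::exp(I * (0.5 * shift * k * dx));
  }
  return m;
}

// in-place 3-D FFT via 1-D passes along each axis
static void fftn3(cx_cube& c, bool inverse) {
  const uword n1 = c.n_rows, n2 = c.n_cols, n3 = c.n_slices;
  for (uword k = 0; k < n3; k++) {
    cx_mat s = c.slice(k);
    if (inverse) { s = ifft(s); s = strans(cx_mat(ifft(strans(s)))); }
    else         { s = fft(s);  s = strans(cx_mat(fft(strans(s)))); }
    c.slice(k) = s;
  }
  cx_mat M(n3, n1 * n2);
  for (uword k = 0; k < n3; k++)
    M.row(k) = strans(vectorise(c.slice(k)));
  if (inverse) M = ifft(M); else M = fft(M);                 // along dim 3
  for (uword k = 0; k < n3; k++)
    c.slice(k) = reshape(strans(M.row(k)), n1, n2);
}

static void axis_symbol3(cx_cube& F, const cx_vec& m, int axis) {
  const uword n3 = F.n_slices;
  if (axis == 0) {
    for (uword k = 0; k < n3; k++) F.slice(k).each_col() %= m;
  } else if (axis == 1) {
    for (uword k = 0; k < n3; k++) F.slice(k).each_row() %= strans(m);
  } else {
    for (uword k = 0; k < n3; k++) F.slice(k) *= m(k);
  }
}

static cx_cube spec3(const cube& f) {
  cx_cube c(f, cube(size(f), fill::zeros));
  fftn3(c, false);
  return c;
}

static cube deriv_of3(const cx_cube& F, const cx_vec& sym, int axis) {
  cx_cube G = F;
  axis_symbol3(G, sym, axis);
  fftn3(G, true);
  return real(G);
}

// f = a (a f + upd), a varying along `axis`
static void decay_update3(cube& f, const cube& upd, const vec& a, int axis) {
  const uword n1 = f.n_rows, n2 = f.n_cols, n3 = f.n_slices;
  for (uword k = 0; k < n3; k++) {
    mat& fs = f.slice(k);
    const mat& us = upd.slice(k);
    if (axis == 0) {
      for (uword j = 0; j < n2; j++)
        for (uword i = 0; i < n1; i++)
          fs(i, j) = a(i) * (a(i) * fs(i, j) + us(i, j));
    } else if (axis == 1) {
      for (uword j = 0; j < n2; j++) {
        double aj = a(j);
        for (uword i = 0; i < n1; i++)
          fs(i, j) = aj * (aj * fs(i, j) + us(i, j));
      }
    } else {
      fs = a(k) * (a(k) * fs + us);
    }
  }
}

static void decay_sq3(cube& f, const vec& a, int axis) {
  cube z(size(f), fill::zeros);
  decay_update3(f, z, a, axis);
}

// elementwise multiply by a varying along `axis`
static cube axis_mult3(const cube& f, const vec& a, int axis) {
  cube g = f;
  const uword n3 = f.n_slices;
  for (uword k = 0; k < n3; k++) {
    if (axis == 0) g.slice(k).each_col() %= a;
    else if (axis == 1) g.slice(k).each_row() %= strans(a);
    else g.slice(k) *= a(k);
  }
  return g;
}

static cube stag_buoyancy3(const cube& rho, int axis) {
  cube b(size(rho));
  const uword n[3] = {rho.n_rows, rho.n_cols, rho.n_slices};
  for (uword k = 0; k < n[2]; k++)
    for (uword j = 0; j < n[1]; j++)
      for (uword i = 0; i < n[0]; i++) {
        uword ii = i, jj = j, kk = k;
        if (axis == 0) ii = (i + 1) % n[0];
        else if (axis == 1) jj = (j + 1) % n[1];
        else kk = (k + 1) % n[2];
        b(i, j, k) = 2.0 / (rho(i, j, k) + rho(ii, jj, kk));
      }
  return b;
}

// shear pair axes: q=0 (xy), q=1 (xz), q=2 (yz); pair index for axes {i,j}
// with i != j is q = i + j - 1
static const int SH_AX[3][2] = {{0, 1}, {0, 2}, {1, 2}};

struct Model3 {
  cube rho, lam, mu, l2m;
  cube b[3];
  cx_vec dp[3], dm[3];
  vec ai[3], ah[3];   // decay vectors per axis at integer / half positions
};

struct State3 {
  cube v[3][3];    // v[i][j]: split of v_i fed by d_j
  cube sn[3][3];   // sn[i][j]: split of sigma_ii fed by d_j v_j
  cube sh[3][2];   // sh[q][s]: split of shear pair q along SH_AX[q][s]
  void zeros(uword n1, uword n2, uword n3) {
    for (int i = 0; i < 3; i++)
      for (int j = 0; j < 3; j++) {
        v[i][j].zeros(n1, n2, n3);
        sn[i][j].zeros(n1, n2, n3);
      }
    for (int q = 0; q < 3; q++)
      for (int s = 0; s < 2; s++) sh[q][s].zeros(n1, n2, n3);
  }
};

// decay vector of velocity split (i, j): half-shifted along axis j iff j == i
static const vec& vdec(const Model3& M, int i, int j) {
  return (i == j) ? M.ah[j] : M.ai[j];
}

static void forward_step3(State3& u, const Model3& M, double dtv, double dt) {
  cx_cube FS[3], FH[3];
  for (int i = 0; i < 3; i++)
    FS[i] = spec3(u.sn[i][0] + u.sn[i][1] + u.sn[i][2]);
  for (int q = 0; q < 3; q++) FH[q] = spec3(u.sh[q][0] + u.sh[q][1]);
  // velocity update: rho dv_i/dt = d_j sigma_ij
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) {
      cube d = (j == i) ? deriv_of3(FS[i], M.dp[i], i)
                        : deriv_of3(FH[i + j - 1], M.dm[j], j);
      decay_update3(u.v[i][j], dtv * (M.b[i] % d), vdec(M, i, j), j);
    }
  cx_cube FV[3];
  for (int i = 0; i < 3; i++)
    FV[i] = spec3(u.v[i][0] + u.v[i][1] + u.v[i][2]);
  // normal stresses: d sigma_ii /dt = lam div v + 2 mu d_i v_i
  for (int j = 0; j < 3; j++) {
    cube ejj = deriv_of3(FV[j], M.dm[j], j);
    for (int i = 0; i < 3; i++) {
      const cube& c = (i == j) ? M.l2m : M.lam;
      decay_update3(u.sn[i][j], dt * (c % ejj), M.ai[j], j);
    }
  }
  // shear stresses: d sigma_ij /dt = mu (d_i v_j + d_j v_i)
  for (int q = 0; q < 3; q++) {
    int a0 = SH_AX[q][0], a1 = SH_AX[q][1];
    cube d0 = deriv_of3(FV[a1], M.dp[a0], a0);   // d_{a0} v_{a1}
    cube d1 = deriv_of3(FV[a0], M.dp[a1], a1);   // d_{a1} v_{a0}
    decay_update3(u.sh[q][0], dt * (M.mu % d0), M.ah[a0], a0);
    decay_update3(u.sh[q][1], dt * (M.mu % d1), M.ah[a1], a1);
  }
}

static void adjoint_step3(State3& u, const Model3& M, double dtv, double dt) {
  // T_sigma^T: stresses feed adjoint velocities
  cube c[3];
  for (int i = 0; i < 3; i++) {
    // normal-stress channel: e_ii = D_i^- v_i fed sn[j][i] with coef
    // (j == i ? l2m : lam) and decay ai[i]; transpose -> -D_i^+
    cube g = M.l2m % axis_mult3(u.sn[i][i], M.ai[i], i);
    for (int j = 0; j < 3; j++)
      if (j != i) g += M.lam % axis_mult3(u.sn[j][i], M.ai[i], i);
    c[i] = -deriv_of3(spec3(dt * g), M.dp[i], i);
    // shear channels: v_i appears in pair q = {i, o} in the slot of the
    // OTHER axis o with derivative D_o^+; transpose -> -D_o^-
    for (int o = 0; o < 3; o++) {
      if (o == i) continue;
      int q = i + o - 1;
      int slot = (SH_AX[q][0] == o) ? 0 : 1;
      cube hh = dt * (M.mu % axis_mult3(u.sh[q][slot], M.ah[o], o));
      c[i] -= deriv_of3(spec3(hh), M.dm[o], o);
    }
  }
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) u.v[i][j] += c[i];
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) decay_sq3(u.sn[i][j], M.ai[j], j);
  for (int q = 0; q < 3; q++)
    for (int s = 0; s < 2; s++) decay_sq3(u.sh[q][s], M.ah[SH_AX[q][s]], SH_AX[q][s]);
  // T_v^T: velocities feed adjoint stresses
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) {
      cube q = dtv * (M.b[i] % axis_mult3(u.v[i][j], vdec(M, i, j), j));
      if (j == i) {
        cube contrib = -deriv_of3(spec3(q), M.dm[i], i);  // (D_i^+)^T
        for (int jj = 0; jj < 3; jj++) u.sn[i][jj] += contrib;
      } else {
        cube contrib = -deriv_of3(spec3(q), M.dp[j], j);  // (D_j^-)^T
        int qq = i + j - 1;
        u.sh[qq][0] += contrib;
        u.sh[qq][1] += contrib;
      }
    }
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) decay_sq3(u.v[i][j], vdec(M, i, j), j);
}

static Model3 build_model3(const cube& rho, const cube& lam, const cube& mu,
                           const arma::vec& dx, const List& decay) {
  Model3 M;
  M.rho = rho; M.lam = lam; M.mu = mu; M.l2m = lam + 2.0 * mu;
  uvec n = {rho.n_rows, rho.n_cols, rho.n_slices};
  for (int a = 0; a < 3; a++) {
    M.b[a] = stag_buoyancy3(rho, a);
    M.dp[a] = deriv_symbol3(n(a), dx(a), +1);
    M.dm[a] = deriv_symbol3(n(a), dx(a), -1);
  }
  List ai = decay["i"], ah = decay["h"];
  for (int a = 0; a < 3; a++) {
    M.ai[a] = Rcpp::as<vec>(ai[a]);
    M.ah[a] = Rcpp::as<vec>(ah[a]);
  }
  return M;
}

static double absmax3(const State3& u) {
  double m = 0;
  for (int i = 0; i < 3; i++) {
    m = std::max(m, abs(u.v[i][i]).max());
    m = std::max(m, abs(u.sn[i][i]).max());
  }
  return m;
}

// [[Rcpp::export(name = ".elastic_run_3d")]]
List elastic_run_3d(const arma::cube& p0, const arma::cube& rho,
                    const arma::cube& lam, const arma::cube& mu,
                    const arma::vec& dx, double dt, int nt, const List& decay,
                    const arma::imat& sidx, const arma::mat& sw,
                    bool first_halfstep) {
  Model3 M = build_model3(rho, lam, mu, dx, decay);
  State3 u; u.zeros(rho.n_rows, rho.n_cols, rho.n_slices);
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) u.sn[i][j] = -p0 / 3.0;
  const int nm = sidx.n_rows, nw = sw.n_cols;
  mat trace_p;
  if (nm) trace_p.zeros(nm, nt);
  const double ref = abs(p0).max();
  for (int t = 0; t < nt; t++) {
    double dtv = (first_halfstep && t == 0) ? 0.5 * dt : dt;
    forward_step3(u, M, dtv, dt);
    if (nm) {
      cube p = u.sn[0][0];
      for (int i = 0; i < 3; i++)
        for (int j = 0; j < 3; j++)
          if (!(i == 0 && j == 0)) p += u.sn[i][j];
      p *= -1.0 / 3.0;
      const double* pp = p.memptr();
      for (int m = 0; m < nm; m++) {
        double acc = 0;
        for (int k = 0; k < nw; k++) acc += sw(m, k) * pp[sidx(m, k) - 1];
        trace_p(m, t) = acc;
      }
    }
    if (ref > 0 && (t % 32 == 31) && absmax3(u) > 1e6 * ref)
      Rcpp::stop("elastic solver unstable at step %d (reduce dt)", t + 1);
  }
  return List::create(Named("trace_p") = trace_p);
}

// [[Rcpp::export(name = ".elastic_adjoint_3d")]]
arma::cube elastic_adjoint_3d(const arma::mat& wdata, const arma::cube& rho,
                              const arma::cube& lam, const arma::cube& mu,
                              const arma::vec& dx, double dt, int nt,
                              const List& decay, const arma::imat& sidx,
                              const arma::mat& sw, bool first_halfstep) {
  Model3 M = build_model3(rho, lam, mu, dx, decay);
  State3 u; u.zeros(rho.n_rows, rho.n_cols, rho.n_slices);
  const int nm = sidx.n_rows, nw = sw.n_cols;
  for (int t = nt - 1; t >= 0; t--) {
    cube inj(size(rho), fill::zeros);
    double* ip = inj.memptr();
    for (int m = 0; m < nm; m++) {
      double wv = wdata(m, t);
      if (wv != 0)
        for (int k = 0; k < nw; k++) ip[sidx(m, k) - 1] += sw(m, k) * wv;
    }
    inj *= -1.0 / 3.0;
    for (int i = 0; i < 3; i++)
      for (int j = 0; j < 3; j++) u.sn[i][j] += inj;
    double dtv = (first_halfstep && t == 0) ? 0.5 * dt : dt;
    adjoint_step3(u, M, dtv, dt);
  }
  cube out = u.sn[0][0];
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++)
      if (!(i == 0 && j == 0)) out += u.sn[i][j];
  return -out / 3.0;
}
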