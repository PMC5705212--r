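// Corotational linear-elastic tetrahedral core.
//
// Each wedge element of the tube shell is split into three tetrahedra.
// A tet's rest shape is the 3x3 matrix of rest edge vectors; growth updates
// it multiplicatively. The elastic energy per tet is the corotational
// small-strain energy: with F = D * Binv (D current edges, Binv inverse rest
// edges) and F = R*S its polar decomposition,
//   psi = mu * |sym(S) - I|^2 + lambda/2 * tr(S - I)^2,
// which is rotation-invariant. Equilibration freezes R and solves the
// resulting quadratic (Newton with frozen rotations).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// polar rotation of F via SVD, with reflection fix
static arma::mat33 polar_rotation(const arma::mat33& F) {
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, F);
  arma::mat33 R = U * V.t();
  if (arma::det(R) < 0.0) {
    U.col(2) *= -1.0;
    R = U * V.t();
  }
  return R;
}

// Shared per-tet computation. P: n x 3 positions, tets: m x 4 (0-based),
// Binv: m x 9 (column-major 3x3 per row), vol0: m rest volumes.
struct TetState {
  arma::mat33 F, R, S;   // S = R^T F
  arma::mat33 G;         // columns g1,g2,g3 (g0 = -sum)
};

static void tet_state(const arma::mat& P, const arma::imat& tets,
                      const arma::mat& Binv, int t, TetState& st) {
  int a = tets(t, 0), b = tets(t, 1), c = tets(t, 2), d = tets(t, 3);
  arma::mat33 D;
  for (int k = 0; k < 3; ++k) {
    D(k, 0) = P(b, k) - P(a, k);
    D(k, 1) = P(c, k) - P(a, k);
    D(k, 2) = P(d, k) - P(a, k);
  }
  arma::mat33 Bi;
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i)
      Bi(i, j) = Binv(t, i + 3 * j);
  st.F = D * Bi;
  st.R = polar_rotation(st.F);
  st.S = st.R.t() * st.F;
  st.G = Bi.t();  // row j of Binv = dF/d(node j+1); store as columns
}

// Total corotational energy and exact gradient (dE/dP, n x 3).
// [[Rcpp::export]]
List corot_energy_grad(const arma::mat& P, const arma::imat& tets,
                       const arma::mat& Binv, const arma::vec& vol0,
                       double mu, double lambda) {
  int m = tets.n_rows;
  double E = 0.0;
  arma::mat grad(P.n_rows, 3, arma::fill::zeros);
  arma::vec edens(m);
  TetState st;
  for (int t = 0; t < m; ++t) {
    tet_state(P, tets, Binv, t, st);
    arma::mat33 e = 0.5 * (st.S + st.S.t());
    e.diag() -= 1.0;
    double tre = arma::trace(e);
    double psi = mu * arma::accu(e % e) + 0.5 * lambda * tre * tre;
    edens(t) = psi;
    E += vol0(t) * psi;
    // dpsi/dF = R * Sig, Sig = 2 mu e + lambda tr(e) I
    arma::mat33 Sig = 2.0 * mu * e;
    Sig.diag() += lambda * tre;
    arma::mat33 W = st.R * Sig;          // 3x3
    arma::mat33 GF = W * st.G;           // columns: contribution per node 1..3
    arma::vec3 g0 = -arma::sum(GF, 1);
    for (int k = 0; k < 3; ++k) {
      grad(tets(t, 0), k) += vol0(t) * g0(k);
      grad(tets(t, 1), k) += vol0(t) * GF(k, 0);
      grad(tets(t, 2), k) += vol0(t) * GF(k, 1);
      grad(tets(t, 3), k) += vol0(t) * GF(k, 2);
    }
  }
  return List::create(_["energy"] = E, _["grad"] = grad,
                      _["density"] = edens);
}

// Assemble frozen-rotation Hessian triplets + gradient.
// DOF index of node i, coord c (0-based): 3*i + c.
// [[Rcpp::export]]
List corot_assemble(const arma::mat& P, const arma::imat& tets,
                    const arma::mat& Binv, const arma::vec& vol0,
                    double mu, double lambda) {
  int m = tets.n_rows;
  int n = P.n_rows;
  arma::mat grad(n, 3, arma::fill::zeros);
  double E = 0.0;
  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve((size_t)m * 144);
  tj.reserve((size_t)m * 144);
  tx.reserve((size_t)m * 144);
  TetState st;
  for (int t = 0; t < m; ++t) {
    tet_state(P, tets, Binv, t, st);
    arma::mat33 e = 0.5 * (st.S + st.S.t());
    e.diag() -= 1.0;
    double tre = arma::trace(e);
    E += vol0(t) * (mu * arma::accu(e % e) + 0.5 * lambda * tre * tre);
    arma::mat33 Sig = 2.0 * mu * e;
    Sig.diag() += lambda * tre;
    arma::mat33 W = st.R * Sig;
    // node shape vectors g_j (j = 0..3)
    arma::mat g(3, 4);
    g.cols(1, 3) = st.G;
    g.col(0) = -arma::sum(st.G, 1);
    // T(c, j) = (R g_j)_c
    arma::mat T = st.R * g;  // 3 x 4
    // gradient
    arma::mat Wg = W * g;  // 3 x 4
    int idx[4] = {(int)tets(t, 0), (int)tets(t, 1), (int)tets(t, 2),
                  (int)tets(t, 3)};
    for (int j = 0; j < 4; ++j)
      for (int c = 0; c < 3; ++c) grad(idx[j], c) += vol0(t) * Wg(c, j);
    // Hessian: H[(j,c),(k,d)] =
    //   V [ mu ((g_j.g_k) delta_cd + T(d,j) T(c,k)) + lambda T(c,j) T(d,k) ]
    arma::mat gram = g.t() * g;  // 4 x 4
    for (int j = 0; j < 4; ++j) {
      for (int k = 0; k < 4; ++k) {
        for (int c = 0; c < 3; ++c) {
          for (int d = 0; d < 3; ++d) {
            double h = mu * T(d, j) * T(c, k) + lambda * T(c, j) * T(d, k);
            if (c == d) h += mu * gram(j, k);
            ti.push_back(3 * idx[j] + c);
            tj.push_back(3 * idx[k] + d);
            tx.push_back(vol0(t) * h);
          }
        }
      }
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tx), _["grad"] = grad, _["energy"] = E);
}

// Per-tet rotations (polar), returned m x 9 column-major.
// [[Rcpp::export]]
arma::mat corot_rotations(const arma::mat& P, const arma::imat& tets,
                          const arma::mat& Binv) {
  int m = tets.n_rows;
  arma::mat out(m, 9);
  TetState st;
  for (int t = 0; t < m; ++t) {
    tet_state(P, tets, Binv, t, st);
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i) out(t, i + 3 * j) = st.R(i, j);
  }
  return out;
}

// Apply growth tensors to rest shapes. Grows the rest edge matrix B (stored
// via its inverse Binv and volume vol0). mode 0 (dissipative): new rest =
// Gw * D_current (Gw is the world-frame growth tensor). mode 1 (retentive):
// new rest = (R^T Gw R) * B_old, R the current elastic rotation.
// Gw: m x 9 per-tet world-frame symmetric growth tensors, column-major.
// Returns list(Binv, vol0).
// [[Rcpp::export]]
List grow_rest_shapes(const arma::mat& P, const arma::imat& tets,
                      const arma::mat& Binv, const arma::vec& vol0,
                      const arma::mat& Gw, int mode) {
  int m = tets.n_rows;
  arma::mat Binv_new(m, 9);
  arma::vec vol_new(m);
  TetState st;
  for (int t = 0; t < m; ++t) {
    arma::mat33 G;
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i) G(i, j) = Gw(t, i + 3 * j);
    arma::mat33 Bnew;
    if (mode == 0) {
      int a = tets(t, 0), b = tets(t, 1), c = tets(t, 2), d = tets(t, 3);
      arma::mat33 D;
      for (int k = 0; k < 3; ++k) {
        D(k, 0) = P(b, k) - P(a, k);
        D(k, 1) = P(c, k) - P(a, k);
        D(k, 2) = P(d, k) - P(a, k);
      }
      Bnew = G * D;
    } else {
      tet_state(P, tets, Binv, t, st);
      arma::mat33 Gm = st.R.t() * G * st.R;
      arma::mat33 Bi;
      for (int j = 0; j < 3; ++j)
        for (int i = 0; i < 3; ++i) Bi(i, j) = Binv(t, i + 3 * j);
      Bnew = Gm * arma::inv(Bi);
    }
    arma::mat33 Bi_new = arma::inv(Bnew);
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i) Binv_new(t, i + 3 * j) = Bi_new(i, j);
    vol_new(t) = arma::det(Bnew) / 6.0;
  }
  return List::create(_["Binv"] = Binv_new, _["vol0"] = vol_new);
}

// Signed tet volumes in the current configuration.
// [[Rcpp::export]]
arma::vec tet_volumes(const arma::mat& P, const arma::imat& tets) {
  int m = tets.n_rows;
  arma::vec v(m);
  for (int t = 0; t < m; ++t) {
    int a = tets(t, 0), b = tets(t, 1), c = tets(t, 2), d = tets(t, 3);
    arma::mat33 D;
    for (int k = 0; k < 3; ++k) {
      D(k, 0) = P(b, k) - P(a, k);
      D(k, 1) = P(c, k) - P(a, k);
      D(k, 2) = P(d, k) - P(a, k);
    }
    v(t) = arma::det(D) / 6.0;
  }
  return v;
}

// accumulate triplet values into ng bins (1-based map), for fast repeated
// sparse assembly with a fixed pattern
// [[Rcpp::export]]
NumericVector accum_triplets(const IntegerVector& map,
                             const NumericVector& x, int ng) {
  NumericVector out(ng);
  int n = map.size();
  for (int i = 0; i < n; ++i) out[map[i] - 1] += x[i];
  return out;
}

// least-squares linear gradient of a nodal scalar over each wedge element
// elements: m x 6 (0-based)
// [[Rcpp::export]]
arma::mat elem_gradient(const arma::mat& P, const arma::imat& elements,
                        const arma::vec& cvec) {
  int m = elements.n_rows;
  arma::mat out(m, 3);
  for (int e = 0; e < m; ++e) {
    arma::mat X(6, 3);
    arma::vec c(6);
    for (int k = 0; k < 6; ++k) {
      int i = elements(e, k);
      X.row(k) = P.row(i);
      c(k) = cvec(i);
    }
    arma::rowvec mu = arma::mean(X, 0);
    X.each_row() -= mu;
    c -= arma::mean(c);
    arma::mat33 A = X.t() * X;
    A.diag() += 1e-12;
    arma::vec3 g = arma::solve(A, X.t() * c, arma::solve_opts::likely_sympd);
    out.row(e) = g.t();
  }
  return out;
}
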