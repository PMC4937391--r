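// Hot loops: Ogden hyper-viscoelastic point constitutive update and the
// total-Lagrangian element assembly over precomputed (enriched) basis
// gradients.  Everything geometric/XFEM-specific (level sets, enrichment
// bookkeeping, quadrature placement) is prepared on the R side; this file
// only sees generalised basis functions with global DOF columns.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Voigt convention: strain (E11,E22,E33,2E12,2E13,2E23),
// stress (S11,S22,S33,S12,S13,S23); S is second Piola-Kirchhoff.

struct MatParams {
  int type;            // 0 = Ogden hyper-viscoelastic, 1 = St Venant-Kirchhoff
  double mu0, alpha, bulk;
  arma::vec g, tau;    // Prony terms (empty for elastic)
};

static inline arma::mat33 voigt_to_sym(const arma::vec6 &v, double shear_fac) {
  arma::mat33 m;
  m(0,0)=v(0); m(1,1)=v(1); m(2,2)=v(2);
  m(0,1)=m(1,0)=v(3)*shear_fac;
  m(0,2)=m(2,0)=v(4)*shear_fac;
  m(1,2)=m(2,1)=v(5)*shear_fac;
  return m;
}

static inline arma::vec6 sym_to_voigt(const arma::mat33 &m) {
  arma::vec6 v;
  v(0)=m(0,0); v(1)=m(1,1); v(2)=m(2,2);
  v(3)=m(0,1); v(4)=m(0,2); v(5)=m(1,2);
  return v;
}

// Isochoric Ogden + quadratic volumetric split, evaluated from the right
// Cauchy-Green tensor.  Returns the *instantaneous* isochoric S and the
// volumetric S separately so the Prony recursion can act on the isochoric
// part only.  W is the instantaneous strain-energy density.
static void ogden_split(const arma::mat33 &C, const MatParams &p,
                        arma::vec6 &Siso, arma::vec6 &Svol, double &W) {
  arma::vec lam2;
  arma::mat vecs;
  if (!arma::eig_sym(lam2, vecs, C))
    stop("constitutive: eigendecomposition of C failed");
  if (lam2.min() <= 0.0)
    stop("inverted element: non-positive principal stretch");
  arma::vec lam = arma::sqrt(lam2);
  double J = lam(0) * lam(1) * lam(2);
  double Jm13 = std::pow(J, -1.0 / 3.0);
  arma::vec lbar = Jm13 * lam;
  // principal Kirchhoff stresses of the isochoric part
  arma::vec beta(3);
  for (int i = 0; i < 3; ++i)
    beta(i) = (2.0 * p.mu0 / p.alpha) * std::pow(lbar(i), p.alpha);
  double betam = arma::mean(beta);
  arma::mat33 SisoM(arma::fill::zeros), SvolM(arma::fill::zeros);
  double pvol = p.bulk * (J - 1.0);           // dU/dJ, U = K/2 (J-1)^2
  for (int i = 0; i < 3; ++i) {
    arma::vec3 n = vecs.col(i);
    SisoM += ((beta(i) - betam) / lam2(i)) * (n * n.t());
    SvolM += (pvol * J / lam2(i)) * (n * n.t());
  }
  Siso = sym_to_voigt(SisoM);
  Svol = sym_to_voigt(SvolM);
  W = (2.0 * p.mu0 / (p.alpha * p.alpha)) *
        (std::pow(lbar(0), p.alpha) + std::pow(lbar(1), p.alpha) +
         std::pow(lbar(2), p.alpha) - 3.0) +
      0.5 * p.bulk * (J - 1.0) * (J - 1.0);
}

// Stress update at one quadrature point.  state layout (Ogden):
// [Siso_prev(6), Q_1(6), ..., Q_K(6)].  The Prony recursion
//   Q_k^{n+1} = e_k Q_k^n + g_k c_k (Siso^{n+1} - Siso^n),
//   e_k = exp(-dt/tau_k),  c_k = tau_k/dt (1 - e_k)  (c_k -> 1 as dt -> 0)
// is exact for Siso varying linearly over the step.  Total stress
//   S = Svol + (1 - sum g_k) Siso + sum Q_k,
// which gives the instantaneous modulus mu0 at dt = 0 and the relaxed
// modulus mu0 (1 - sum g_k) as t -> inf.
static void point_stress(const arma::vec6 &Ev, const MatParams &p,
                         const arma::vec &state, double dt,
                         arma::vec6 &S, arma::vec &state_new, double &W) {
  if (p.type == 1) {  // St Venant-Kirchhoff (linear-elastic comparison model)
    double mu = p.mu0, lam = p.bulk - 2.0 * mu / 3.0;
    double tr = Ev(0) + Ev(1) + Ev(2);
    S(0) = lam * tr + 2.0 * mu * Ev(0);
    S(1) = lam * tr + 2.0 * mu * Ev(1);
    S(2) = lam * tr + 2.0 * mu * Ev(2);
    S(3) = mu * Ev(3); S(4) = mu * Ev(4); S(5) = mu * Ev(5);
    state_new = state;
    double trE2 = Ev(0)*Ev(0) + Ev(1)*Ev(1) + Ev(2)*Ev(2) +
                  0.5 * (Ev(3)*Ev(3) + Ev(4)*Ev(4) + Ev(5)*Ev(5));
    W = 0.5 * lam * tr * tr + mu * trE2;
    return;
  }
  arma::mat33 C = voigt_to_sym(Ev, 0.5);  // E with engineering shears
  C = 2.0 * C + arma::eye(3, 3);
  arma::vec6 Siso, Svol;
  ogden_split(C, p, Siso, Svol, W);
  int K = p.g.n_elem;
  state_new.set_size(state.n_elem);
  arma::vec6 Sprev = state.subvec(0, 5);
  double gsum = arma::accu(p.g);
  arma::vec6 Q_tot(arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    double ek, ck;
    if (dt > 0.0) {
      ek = std::exp(-dt / p.tau(k));
      ck = p.tau(k) / dt * (1.0 - ek);
    } else {
      ek = 1.0; ck = 1.0;
    }
    arma::vec6 Qold = state.subvec(6 * (k + 1), 6 * (k + 1) + 5);
    arma::vec6 Qnew = ek * Qold + p.g(k) * ck * (Siso - Sprev);
    state_new.subvec(6 * (k + 1), 6 * (k + 1) + 5) = Qnew;
    Q_tot += Qnew;
  }
  state_new.subvec(0, 5) = Siso;
  S = Svol + (1.0 - gsum) * Siso + Q_tot;
}

// viscoelastic scale factor on the isochoric stress/tangent for a step dt:
// (1 - sum g_k) + sum g_k c_k(dt); equals 1 at dt = 0 (instantaneous)
static double visco_factor(const MatParams &p, double dt) {
  double fac = 1.0;
  for (arma::uword k = 0; k < p.g.n_elem; ++k) {
    if (dt > 0.0) {
      double ek = std::exp(-dt / p.tau(k));
      fac -= p.g(k) * (1.0 - p.tau(k) / dt * (1.0 - ek));
    }
  }
  return fac;
}

// Analytic consistent tangent dS/dE (Voigt, engineering shears) for the
// Ogden split, from the spectral decomposition of C: principal values
// s_i(c_1,c_2,c_3) (c_i = lambda_i^2) give the normal block 2 ds_i/dc_j and
// principal-shear moduli (s_i - s_j)/(c_i - c_j) (l'Hopital limit at equal
// stretches); the principal-frame 6x6 is then rotated to the lab frame.
static void ogden_tangent_analytic(const arma::mat33 &C, const MatParams &p,
                                   double fac_v, arma::mat66 &D) {
  arma::vec c;            // eigenvalues of C
  arma::mat Q;            // principal directions (columns)
  if (!arma::eig_sym(c, Q, C)) stop("constitutive: eigendecomposition failed");
  if (c.min() <= 0.0) stop("inverted element: non-positive principal stretch");
  double J = std::sqrt(c(0) * c(1) * c(2));
  arma::vec beta(3), siso(3), svol(3), s(3);
  double Jma3 = std::pow(J, -p.alpha / 3.0);
  for (int i = 0; i < 3; ++i)
    beta(i) = (2.0 * p.mu0 / p.alpha) * Jma3 * std::pow(c(i), p.alpha / 2.0);
  double betam = arma::mean(beta);
  for (int i = 0; i < 3; ++i) {
    siso(i) = (beta(i) - betam) / c(i);
    svol(i) = p.bulk * (J * J - J) / c(i);
    s(i) = svol(i) + fac_v * siso(i);
  }
  // ds_i/dc_j
  arma::mat33 dbeta, ds;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      dbeta(i, j) = -(p.alpha / 6.0) * beta(i) / c(j) +
                    (i == j ? (p.alpha / 2.0) * beta(i) / c(i) : 0.0);
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) {
      double dbm = (dbeta(0, j) + dbeta(1, j) + dbeta(2, j)) / 3.0;
      double dsiso = (dbeta(i, j) - dbm) / c(i) -
                     (i == j ? (beta(i) - betam) / (c(i) * c(i)) : 0.0);
      double dsvol = p.bulk * (2.0 * J - 1.0) * (J / (2.0 * c(j))) / c(i) -
                     (i == j ? p.bulk * (J * J - J) / (c(i) * c(i)) : 0.0);
      ds(i, j) = dsvol + fac_v * dsiso;
    }
  }
  // principal-frame tangent: normal block and principal-shear moduli
  arma::mat66 Dp(arma::fill::zeros);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      Dp(i, j) = 2.0 * ds(i, j);
  const int pr[3][2] = {{0, 1}, {0, 2}, {1, 2}};
  double cmax = c.max();
  for (int q = 0; q < 3; ++q) {
    int i = pr[q][0], j = pr[q][1];
    double g;
    if (std::fabs(c(i) - c(j)) > 1e-8 * cmax)
      g = (s(i) - s(j)) / (c(i) - c(j));
    else
      g = ds(i, i) - ds(i, j);
    Dp(3 + q, 3 + q) = g;
  }
  // rotate to the lab frame column-by-column: apply Dp to unit lab strains
  for (int b = 0; b < 6; ++b) {
    arma::mat33 eps(arma::fill::zeros);
    if (b < 3) eps(b, b) = 1.0;
    else if (b == 3) { eps(0, 1) = eps(1, 0) = 0.5; }
    else if (b == 4) { eps(0, 2) = eps(2, 0) = 0.5; }
    else { eps(1, 2) = eps(2, 1) = 0.5; }
    arma::mat33 ep = Q.t() * eps * Q;       // strain in principal frame
    arma::vec6 ev;                           // eng-shear Voigt
    ev(0) = ep(0, 0); ev(1) = ep(1, 1); ev(2) = ep(2, 2);
    ev(3) = 2.0 * ep(0, 1); ev(4) = 2.0 * ep(0, 2); ev(5) = 2.0 * ep(1, 2);
    arma::vec6 sv = Dp * ev;
    arma::mat33 sp = voigt_to_sym(sv, 1.0);
    arma::mat33 sl = Q * sp * Q.t();        // stress back to lab frame
    D.col(b) = sym_to_voigt(sl);
  }
  D = 0.5 * (D + D.t());
}

// Material tangent dS/dE (Voigt, engineering shears): analytic for the
// Ogden material, constant for St Venant-Kirchhoff. The `fd = true` path
// (central differences of the full stress update) is kept as an
// independent cross-check.
static void point_tangent(const arma::vec6 &Ev, const MatParams &p,
                          const arma::vec &state, double dt, arma::mat66 &D,
                          bool fd = false) {
  if (p.type == 1) {
    double mu = p.mu0, lam = p.bulk - 2.0 * mu / 3.0;
    D.zeros();
    for (int i = 0; i < 3; ++i) {
      for (int j = 0; j < 3; ++j) D(i, j) = lam;
      D(i, i) += 2.0 * mu;
      D(i + 3, i + 3) = mu;
    }
    return;
  }
  if (fd) {
    const double h = 1e-6;
    arma::vec6 Sp, Sm;
    arma::vec st;
    double W;
    for (int j = 0; j < 6; ++j) {
      arma::vec6 Ep = Ev, Em = Ev;
      Ep(j) += h; Em(j) -= h;
      point_stress(Ep, p, state, dt, Sp, st, W);
      point_stress(Em, p, state, dt, Sm, st, W);
      D.col(j) = (Sp - Sm) / (2.0 * h);
    }
    D = 0.5 * (D + D.t());
    return;
  }
  arma::mat33 C = voigt_to_sym(Ev, 0.5);
  C = 2.0 * C + arma::eye(3, 3);
  ogden_tangent_analytic(C, p, visco_factor(p, dt), D);
}

static MatParams unpack_params(int mat_type, double mu0, double alpha,
                               double bulk, const arma::vec &g,
                               const arma::vec &tau) {
  MatParams p;
  p.type = mat_type; p.mu0 = mu0; p.alpha = alpha; p.bulk = bulk;
  p.g = g; p.tau = tau;
  return p;
}

// [[Rcpp::export]]
List cpp_point_constitutive(const arma::mat &F, int mat_type, double mu0,
                            double alpha, double bulk, const arma::vec &g,
                            const arma::vec &tau, const arma::vec &state,
                            double dt, bool want_tangent,
                            bool fd_tangent = false) {
  if (arma::det(F) <= 0.0) stop("inverted element: det(F) <= 0");
  MatParams p = unpack_params(mat_type, mu0, alpha, bulk, g, tau);
  arma::mat33 Fm(F);
  arma::mat33 E3 = 0.5 * (Fm.t() * Fm - arma::eye(3, 3));
  arma::vec6 Ev = sym_to_voigt(E3);
  Ev(3) *= 2.0; Ev(4) *= 2.0; Ev(5) *= 2.0;
  arma::vec6 S;
  arma::vec state_new;
  double W;
  point_stress(Ev, p, state, dt, S, state_new, W);
  arma::mat33 S3 = voigt_to_sym(S, 1.0);
  double J = arma::det(Fm);
  arma::mat cauchy = Fm * S3 * Fm.t() / J;
  List out = List::create(_["S"] = S, _["S_mat"] = arma::mat(S3),
                          _["cauchy"] = cauchy, _["state"] = state_new,
                          _["W"] = W);
  if (want_tangent) {
    arma::mat66 D;
    point_tangent(Ev, p, state, dt, D, fd_tangent);
    out["D"] = arma::mat(D);
  }
  return out;
}

// Assemble internal force, tangent triplets, updated state and total strain
// energy for the whole mesh.  Basis functions are generalised (standard +
// enriched); per element e there are nb[e] basis functions, each carrying 3
// DOFs whose 0-based global ids are the columns of basis_dofs.  gp_grad
// stores, per element and quadrature point, the material gradient of every
// basis function (3 x nb block); gp_w is the reference-volume weight.
// [[Rcpp::export]]
List cpp_assemble(const arma::vec &dofs, int ndof,
                  const arma::ivec &elem_nb, const arma::ivec &elem_ngp,
                  const arma::imat &basis_dofs, const arma::mat &gp_grad,
                  const arma::vec &gp_w,
                  int mat_type, double mu0, double alpha, double bulk,
                  const arma::vec &g, const arma::vec &tau,
                  const arma::mat &state, double dt, bool want_tangent,
                  bool want_pattern = true) {
  MatParams p = unpack_params(mat_type, mu0, alpha, bulk, g, tau);
  const int NE = elem_nb.n_elem;
  arma::vec resid(ndof, arma::fill::zeros);
  arma::mat state_new(state.n_rows, state.n_cols);
  double energy = 0.0;

  std::size_t ntrip = 0;
  if (want_tangent)
    for (int e = 0; e < NE; ++e)
      ntrip += (std::size_t)(3 * elem_nb(e)) * (3 * elem_nb(e));
  std::vector<int> Ki, Kj;
  std::vector<double> Kx;
  if (want_tangent) {
    Kx.reserve(ntrip);
    if (want_pattern) { Ki.reserve(ntrip); Kj.reserve(ntrip); }
  }

  std::size_t bofs = 0, gofs = 0, gpofs = 0;
  for (int e = 0; e < NE; ++e) {
    const int nb = elem_nb(e), ngp = elem_ngp(e), nd = 3 * nb;
    arma::mat Ke;
    if (want_tangent) Ke.zeros(nd, nd);
    arma::vec fe(nd, arma::fill::zeros);
    for (int q = 0; q < ngp; ++q) {
      const double w = gp_w(gpofs + q);
      // F = I + sum_c d_c (grad N_c)^T
      arma::mat33 F(arma::fill::eye);
      for (int c = 0; c < nb; ++c) {
        arma::vec3 gv = gp_grad.col(gofs + (std::size_t)q * nb + c);
        arma::vec3 d;
        for (int i = 0; i < 3; ++i) d(i) = dofs(basis_dofs(i, bofs + c));
        F += d * gv.t();
      }
      if (arma::det(F) <= 0.0) {
        std::ostringstream msg;
        msg << "inverted element " << (e + 1) << " during assembly";
        stop(msg.str());
      }
      arma::mat33 E3 = 0.5 * (F.t() * F - arma::eye(3, 3));
      arma::vec6 Ev = sym_to_voigt(E3);
      Ev(3) *= 2.0; Ev(4) *= 2.0; Ev(5) *= 2.0;
      arma::vec6 S;
      arma::vec snew;
      double W;
      point_stress(Ev, p, state.col(gpofs + q), dt, S, snew, W);
      state_new.col(gpofs + q) = snew;
      energy += w * W;
      // nonlinear strain-displacement operator
      arma::mat B(6, nd);
      for (int c = 0; c < nb; ++c) {
        arma::vec3 gv = gp_grad.col(gofs + (std::size_t)q * nb + c);
        for (int k = 0; k < 3; ++k) {  // DOF direction
          const int col = 3 * c + k;
          B(0, col) = F(k, 0) * gv(0);
          B(1, col) = F(k, 1) * gv(1);
          B(2, col) = F(k, 2) * gv(2);
          B(3, col) = F(k, 0) * gv(1) + F(k, 1) * gv(0);
          B(4, col) = F(k, 0) * gv(2) + F(k, 2) * gv(0);
          B(5, col) = F(k, 1) * gv(2) + F(k, 2) * gv(1);
        }
      }
      fe += w * (B.t() * S);
      if (want_tangent) {
        arma::mat66 D;
        point_tangent(Ev, p, state.col(gpofs + q), dt, D);
        Ke += w * (B.t() * D * B);
        // geometric stiffness
        arma::mat33 S3 = voigt_to_sym(S, 1.0);
        for (int c = 0; c < nb; ++c) {
          arma::vec3 gc = gp_grad.col(gofs + (std::size_t)q * nb + c);
          arma::vec3 Sg = S3 * gc;
          for (int d2 = 0; d2 < nb; ++d2) {
            arma::vec3 gd = gp_grad.col(gofs + (std::size_t)q * nb + d2);
            const double gSg = w * arma::dot(gd, Sg);
            for (int k = 0; k < 3; ++k)
              Ke(3 * c + k, 3 * d2 + k) += gSg;
          }
        }
      }
    }
    // scatter
    for (int c = 0; c < nb; ++c)
      for (int i = 0; i < 3; ++i)
        resid(basis_dofs(i, bofs + c)) += fe(3 * c + i);
    if (want_tangent) {
      for (int c = 0; c < nb; ++c)
        for (int i = 0; i < 3; ++i) {
          const int gi = basis_dofs(i, bofs + c);
          for (int d2 = 0; d2 < nb; ++d2)
            for (int j = 0; j < 3; ++j) {
              if (want_pattern) {
                Ki.push_back(gi);
                Kj.push_back(basis_dofs(j, bofs + d2));
              }
              Kx.push_back(Ke(3 * c + i, 3 * d2 + j));
            }
        }
    }
    bofs += nb;
    gofs += (std::size_t)ngp * nb;
    gpofs += ngp;
  }
  List out = List::create(_["resid"] = resid, _["state"] = state_new,
                          _["energy"] = energy);
  if (want_tangent) {
    if (want_pattern) {
      out["Ki"] = IntegerVector(Ki.begin(), Ki.end());
      out["Kj"] = IntegerVector(Kj.begin(), Kj.end());
    }
    out["Kx"] = NumericVector(Kx.begin(), Kx.end());
  }
  return out;
}

// Sum triplet values into their precomputed compressed-column slots.
// [[Rcpp::export]]
NumericVector cpp_accumulate(const IntegerVector &map, const NumericVector &x,
                             int nnz) {
  NumericVector out(nnz);
  const int n = map.size();
  for (int t = 0; t < n; ++t) out[map[t] - 1] += x[t];
  return out;
}
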