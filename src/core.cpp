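// Numerical core: minimum-image geometry, interaction-classified descriptors
// with analytic Jacobians, dense-network evaluation, energy terms (harmonic
// intra, 9-6 / 12-6 van der Waals, direct and Ewald Coulomb, charge-transfer)
// and the full chain-rule force assembly for the dynamic-charge backend.
//
// Units throughout: Angstrom, kcal/mol, elementary charge e, radians.
// Element coding: 0 = O, 1 = H.  All indices passed from R are 0-based.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double PI_ = 3.141592653589793238462643383279502884;

// ---------------------------------------------------------------------------
// geometry
// ---------------------------------------------------------------------------

// minimum image of dx for an orthorhombic box; exact half-box maps to -L/2
static inline double wrap1(double dx, double L) {
  return dx - L * std::floor(dx / L + 0.5);
}

static inline arma::vec3 min_image(const arma::mat& pos, int i, int j,
                                   const arma::vec& cell) {
  arma::vec3 d;
  for (int a = 0; a < 3; ++a) {
    double dx = pos(j, a) - pos(i, a);
    if (cell.n_elem == 3) dx = wrap1(dx, cell(a));
    d(a) = dx;
  }
  return d;
}

// [[Rcpp::export]]
arma::mat cpp_min_image_vec(const arma::mat& d, const arma::vec& cell) {
  arma::mat out = d;
  if (cell.n_elem == 3)
    for (arma::uword r = 0; r < out.n_rows; ++r)
      for (int a = 0; a < 3; ++a) out(r, a) = wrap1(out(r, a), cell(a));
  return out;
}

// all pairs with minimum-image distance <= cutoff; columns i, j, dx, dy, dz, r
// (i < j, 0-based)
// [[Rcpp::export]]
arma::mat cpp_neighbor_pairs(const arma::mat& pos, const arma::vec& cell,
                             double cutoff) {
  const int n = pos.n_rows;
  std::vector<double> rows;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      arma::vec3 d = min_image(pos, i, j, cell);
      double r = arma::norm(d);
      if (r <= cutoff) {
        rows.push_back(i); rows.push_back(j);
        rows.push_back(d(0)); rows.push_back(d(1)); rows.push_back(d(2));
        rows.push_back(r);
      }
    }
  const int m = rows.size() / 6;
  arma::mat out(m, 6);
  for (int k = 0; k < m; ++k)
    for (int c = 0; c < 6; ++c) out(k, c) = rows[6 * k + c];
  return out;
}

// ---------------------------------------------------------------------------
// radial kernel: v(r) = exp(-kf r) * sc(r, rc), sc = (cos(pi r/rc)+1)/2
// ---------------------------------------------------------------------------

static inline double sc_fun(double r, double rc) {
  if (r >= rc) return 0.0;
  return 0.5 * (std::cos(PI_ * r / rc) + 1.0);
}
static inline double sc_der(double r, double rc) {
  if (r >= rc) return 0.0;
  return -0.5 * PI_ / rc * std::sin(PI_ * r / rc);
}
static inline double kern(double r, double kf, double rc) {
  if (r >= rc) return 0.0;
  return std::exp(-kf * r) * sc_fun(r, rc);
}
static inline double kern_der(double r, double kf, double rc) {
  if (r >= rc) return 0.0;
  double e = std::exp(-kf * r);
  return e * (sc_der(r, rc) - kf * sc_fun(r, rc));
}

// [[Rcpp::export]]
arma::vec cpp_cutoff_weight(const arma::vec& r, double rc) {
  arma::vec out(r.n_elem);
  for (arma::uword i = 0; i < r.n_elem; ++i) out(i) = sc_fun(r(i), rc);
  return out;
}

// ---------------------------------------------------------------------------
// charge features
//
// Per-atom layout (24 slots): for each decay parameter t = 0,1,2 the block
// 8t + {0: intra class O, 1: intra class H, 2: inter class O, 3: inter class H,
//       4..7: sibling block}.
// Sibling block for an H centre: O-sibling inter ICFs (class O, class H), then
// other-H-sibling inter ICFs (class O, class H).  For an O centre the two H
// siblings are symmetrized as power sums: (sum class O, sum class H,
// sum-of-squares class O, sum-of-squares class H).
// ---------------------------------------------------------------------------

struct ChargeFeatWork {
  arma::mat F;        // n x 24
  arma::cube Hinter;  // n x 2 (class) x 3 (t): intermolecular ICFs per atom
};

static ChargeFeatWork charge_features_work(const arma::mat& pos,
                                           const arma::ivec& elem,
                                           const arma::ivec& mol,
                                           const arma::imat& molatoms,
                                           const arma::vec& cell,
                                           const arma::vec& kf, double rc) {
  const int n = pos.n_rows;
  ChargeFeatWork w;
  w.F = arma::mat(n, 24, arma::fill::zeros);
  w.Hinter = arma::cube(n, 2, 3, arma::fill::zeros);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      arma::vec3 d = min_image(pos, i, j, cell);
      double r = arma::norm(d);
      if (r >= rc) continue;
      bool same = mol(i) == mol(j);
      for (int t = 0; t < 3; ++t) {
        double v = kern(r, kf(t), rc);
        if (same) {
          w.F(i, 8 * t + elem(j)) += v;
          w.F(j, 8 * t + elem(i)) += v;
        } else {
          w.F(i, 8 * t + 2 + elem(j)) += v;
          w.F(j, 8 * t + 2 + elem(i)) += v;
          w.Hinter(i, elem(j), t) += v;
          w.Hinter(j, elem(i), t) += v;
        }
      }
    }
  // sibling blocks
  const int nmol = molatoms.n_rows;
  for (int m = 0; m < nmol; ++m) {
    int O = molatoms(m, 0), H1 = molatoms(m, 1), H2 = molatoms(m, 2);
    for (int t = 0; t < 3; ++t) {
      for (int c = 0; c < 2; ++c) {
        double h1 = w.Hinter(H1, c, t), h2 = w.Hinter(H2, c, t);
        w.F(O, 8 * t + 4 + c) = h1 + h2;
        w.F(O, 8 * t + 6 + c) = h1 * h1 + h2 * h2;
        w.F(H1, 8 * t + 4 + c) = w.Hinter(O, c, t);
        w.F(H2, 8 * t + 4 + c) = w.Hinter(O, c, t);
        w.F(H1, 8 * t + 6 + c) = h2;
        w.F(H2, 8 * t + 6 + c) = h1;
      }
    }
  }
  return w;
}

// [[Rcpp::export]]
arma::mat cpp_charge_features(const arma::mat& pos, const arma::ivec& elem,
                              const arma::ivec& mol, const arma::imat& molatoms,
                              const arma::vec& cell, const arma::vec& kf,
                              double rc) {
  return charge_features_work(pos, elem, mol, molatoms, cell, kf, rc).F;
}

// dense 24 x 3n Jacobian of one atom's feature vector (test/inspection use)
// [[Rcpp::export]]
arma::mat cpp_charge_feature_jacobian(const arma::mat& pos,
                                      const arma::ivec& elem,
                                      const arma::ivec& mol,
                                      const arma::imat& molatoms,
                                      const arma::vec& cell,
                                      const arma::vec& kf, double rc,
                                      int atom) {
  const int n = pos.n_rows;
  ChargeFeatWork w = charge_features_work(pos, elem, mol, molatoms, cell, kf, rc);
  arma::mat J(24, 3 * n, arma::fill::zeros);
  int a = atom;
  // centre's own intra/inter slots
  for (int j = 0; j < n; ++j) {
    if (j == a) continue;
    arma::vec3 d = min_image(pos, a, j, cell);
    double r = arma::norm(d);
    if (r >= rc) continue;
    arma::vec3 u = d / r;
    bool same = mol(j) == mol(a);
    for (int t = 0; t < 3; ++t) {
      int slot = same ? 8 * t + elem(j) : 8 * t + 2 + elem(j);
      double dv = kern_der(r, kf(t), rc);
      for (int c = 0; c < 3; ++c) {
        J(slot, 3 * j + c) += dv * u(c);
        J(slot, 3 * a + c) -= dv * u(c);
      }
    }
  }
  // sibling blocks: derivatives of the siblings' intermolecular ICFs
  int m = mol(a);
  int O = molatoms(m, 0), H1 = molatoms(m, 1), H2 = molatoms(m, 2);
  int sibs[2];
  bool aIsO = (a == O);
  if (aIsO) { sibs[0] = H1; sibs[1] = H2; }
  else      { sibs[0] = O;  sibs[1] = (a == H1) ? H2 : H1; }
  for (int k = 0; k < 2; ++k) {
    int s = sibs[k];
    for (int j = 0; j < n; ++j) {
      if (mol(j) == m) continue;
      arma::vec3 d = min_image(pos, s, j, cell);
      double r = arma::norm(d);
      if (r >= rc) continue;
      arma::vec3 u = d / r;
      for (int t = 0; t < 3; ++t) {
        double dv = kern_der(r, kf(t), rc);
        int e = elem(j);
        int slot;
        double coef = 1.0;
        if (aIsO) {
          // both siblings are H: sum slot and power-sum slot
          slot = 8 * t + 4 + e;
          for (int c = 0; c < 3; ++c) {
            J(slot, 3 * j + c) += dv * u(c);
            J(slot, 3 * s + c) -= dv * u(c);
          }
          slot = 8 * t + 6 + e;
          coef = 2.0 * w.Hinter(s, e, t);
        } else {
          slot = (k == 0) ? 8 * t + 4 + e : 8 * t + 6 + e;
        }
        for (int c = 0; c < 3; ++c) {
          J(slot, 3 * j + c) += coef * dv * u(c);
          J(slot, 3 * s + c) -= coef * dv * u(c);
        }
      }
    }
  }
  return J;
}

// ---------------------------------------------------------------------------
// charge-transfer pair features
//
// Half-block for molecule X against partner Y (18 slots): for each t the
// 6 slots {0: O-atom class O, 1: O-atom class H, 2: H-sum class O,
// 3: H-sum class H, 4: H-sum-of-squares class O, 5: H-sum-of-squares class H},
// slot index 6t + s.  Full vector F_IJ = [half(I) | half(J)]; all kernels use
// r_c = ct_cutoff.
// ---------------------------------------------------------------------------

struct CTWork {
  // h(atom-in-role, class, t): ICF of an atom of one molecule restricted to
  // the partner molecule's atoms; role 0 = I, role 1 = J, atom 0=O,1=H1,2=H2
  double h[2][3][2][3];  // [role][atom][class][t]
  arma::vec F;           // 36
};

static CTWork ct_features_work(const arma::mat& pos, const arma::ivec& elem,
                               const arma::imat& molatoms,
                               const arma::vec& cell, int molI, int molJ,
                               const arma::vec& kf, double ct_cut) {
  CTWork w;
  std::memset(w.h, 0, sizeof(w.h));
  int ai[3] = {molatoms(molI, 0), molatoms(molI, 1), molatoms(molI, 2)};
  int aj[3] = {molatoms(molJ, 0), molatoms(molJ, 1), molatoms(molJ, 2)};
  for (int p = 0; p < 3; ++p)
    for (int q = 0; q < 3; ++q) {
      arma::vec3 d = min_image(pos, ai[p], aj[q], cell);
      double r = arma::norm(d);
      if (r >= ct_cut) continue;
      for (int t = 0; t < 3; ++t) {
        double v = kern(r, kf(t), ct_cut);
        w.h[0][p][elem(aj[q])][t] += v;
        w.h[1][q][elem(ai[p])][t] += v;
      }
    }
  w.F = arma::vec(36, arma::fill::zeros);
  for (int role = 0; role < 2; ++role) {
    int off = 18 * role;
    for (int t = 0; t < 3; ++t)
      for (int c = 0; c < 2; ++c) {
        double hO = w.h[role][0][c][t];
        double h1 = w.h[role][1][c][t], h2 = w.h[role][2][c][t];
        w.F(off + 6 * t + 0 + c) = hO;
        w.F(off + 6 * t + 2 + c) = h1 + h2;
        w.F(off + 6 * t + 4 + c) = h1 * h1 + h2 * h2;
      }
  }
  return w;
}

// [[Rcpp::export]]
arma::vec cpp_ct_features(const arma::mat& pos, const arma::ivec& elem,
                          const arma::imat& molatoms, const arma::vec& cell,
                          int molI, int molJ, const arma::vec& kf,
                          double ct_cut) {
  return ct_features_work(pos, elem, molatoms, cell, molI, molJ, kf, ct_cut).F;
}

// 36 x 3n Jacobian of the pair feature vector F_IJ (test/inspection use)
// [[Rcpp::export]]
arma::mat cpp_ct_feature_jacobian(const arma::mat& pos, const arma::ivec& elem,
                                  const arma::imat& molatoms,
                                  const arma::vec& cell, int molI, int molJ,
                                  const arma::vec& kf, double ct_cut) {
  const int n = pos.n_rows;
  CTWork w = ct_features_work(pos, elem, molatoms, cell, molI, molJ, kf, ct_cut);
  arma::mat J(36, 3 * n, arma::fill::zeros);
  int ai[3] = {molatoms(molI, 0), molatoms(molI, 1), molatoms(molI, 2)};
  int aj[3] = {molatoms(molJ, 0), molatoms(molJ, 1), molatoms(molJ, 2)};
  for (int p = 0; p < 3; ++p)
    for (int q = 0; q < 3; ++q) {
      arma::vec3 d = min_image(pos, ai[p], aj[q], cell);
      double r = arma::norm(d);
      if (r >= ct_cut) continue;
      arma::vec3 u = d / r;
      for (int t = 0; t < 3; ++t) {
        double dv = kern_der(r, kf(t), ct_cut);
        // role I, atom p, class elem(aj[q])
        struct { int role, atom, cls, ia, ja; } tgt[2] = {
          {0, p, (int)elem(aj[q]), ai[p], aj[q]},
          {1, q, (int)elem(ai[p]), aj[q], ai[p]}};
        for (int k = 0; k < 2; ++k) {
          int off = 18 * tgt[k].role;
          int c = tgt[k].cls;
          int slot; double coef;
          if (tgt[k].atom == 0) { slot = off + 6 * t + 0 + c; coef = 1.0; }
          else                  { slot = off + 6 * t + 2 + c; coef = 1.0; }
          // sign: moving ja along +u increases r seen from ia
          double sgn = (k == 0) ? 1.0 : -1.0;
          for (int cc = 0; cc < 3; ++cc) {
            J(slot, 3 * tgt[k].ja + cc) += sgn * coef * dv * u(cc);
            J(slot, 3 * tgt[k].ia + cc) -= sgn * coef * dv * u(cc);
          }
          if (tgt[k].atom != 0) {  // power-sum slot
            slot = off + 6 * t + 4 + c;
            coef = 2.0 * w.h[tgt[k].role][tgt[k].atom][c][t];
            for (int cc = 0; cc < 3; ++cc) {
              J(slot, 3 * tgt[k].ja + cc) += sgn * coef * dv * u(cc);
              J(slot, 3 * tgt[k].ia + cc) -= sgn * coef * dv * u(cc);
            }
          }
        }
      }
    }
  return J;
}

// ---------------------------------------------------------------------------
// dense networks (Swish hidden activations, linear scalar output)
// ---------------------------------------------------------------------------

struct Net {
  std::vector<arma::mat> W;  // W[l]: n_out x n_in
  std::vector<arma::vec> b;
  double beta;
  arma::vec xc, xs;  // input standardization
  double yc, ys;     // output de-standardization
};

static Net net_from_list(const List& net) {
  Net N;
  List Ws = net["W"], bs = net["b"];
  for (int l = 0; l < Ws.size(); ++l) {
    N.W.push_back(as<arma::mat>(Ws[l]));
    N.b.push_back(as<arma::vec>(bs[l]));
  }
  N.beta = as<double>(net["beta"]);
  N.xc = as<arma::vec>(net["x_center"]);
  N.xs = as<arma::vec>(net["x_scale"]);
  N.yc = as<double>(net["y_center"]);
  N.ys = as<double>(net["y_scale"]);
  return N;
}

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// forward pass; if grad != nullptr also fills d(output)/d(input)
static double net_eval(const Net& N, const arma::vec& x, arma::vec* grad) {
  const int L = N.W.size();
  arma::vec z = (x - N.xc) / N.xs;
  std::vector<arma::vec> pre(L);  // pre-activations
  std::vector<arma::vec> act(L + 1);
  act[0] = z;
  for (int l = 0; l < L; ++l) {
    pre[l] = N.W[l] * act[l] + N.b[l];
    if (l < L - 1) {
      arma::vec a = pre[l];
      for (arma::uword i = 0; i < a.n_elem; ++i)
        a(i) = pre[l](i) * sigm(N.beta * pre[l](i));
      act[l + 1] = a;
    } else {
      act[l + 1] = pre[l];
    }
  }
  double out = act[L](0) * N.ys + N.yc;
  if (grad) {
    arma::vec g = arma::vec(1);
    g(0) = N.ys;
    for (int l = L - 1; l >= 0; --l) {
      arma::vec gin = N.W[l].t() * g;
      if (l > 0) {
        // multiply by Swish'(pre[l-1])
        for (arma::uword i = 0; i < gin.n_elem; ++i) {
          double s = sigm(N.beta * pre[l - 1](i));
          gin(i) *= s + N.beta * pre[l - 1](i) * s * (1.0 - s);
        }
      }
      g = gin;
    }
    *grad = g / N.xs;
  }
  return out;
}

// batched forward: rows of X are samples
// [[Rcpp::export]]
arma::vec cpp_nn_forward(const List& net, const arma::mat& X) {
  Net N = net_from_list(net);
  arma::vec out(X.n_rows);
  for (arma::uword i = 0; i < X.n_rows; ++i)
    out(i) = net_eval(N, X.row(i).t(), nullptr);
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_nn_input_grad(const List& net, const arma::mat& X) {
  Net N = net_from_list(net);
  arma::mat out(X.n_rows, X.n_cols);
  for (arma::uword i = 0; i < X.n_rows; ++i) {
    arma::vec g;
    net_eval(N, X.row(i).t(), &g);
    out.row(i) = g.t();
  }
  return out;
}

// ---------------------------------------------------------------------------
// energy terms
// ---------------------------------------------------------------------------

// harmonic intramolecular energy, convention U = k (dx)^2 (no 1/2)
static double intra_energy(const arma::mat& pos, const arma::imat& molatoms,
                           double kb, double ka, double r0, double th0,
                           arma::mat& G) {
  double U = 0.0;
  const int nmol = molatoms.n_rows;
  for (int m = 0; m < nmol; ++m) {
    int O = molatoms(m, 0);
    for (int k = 1; k <= 2; ++k) {
      int H = molatoms(m, k);
      arma::vec3 d = (pos.row(H) - pos.row(O)).t();
      double r = arma::norm(d);
      U += kb * (r - r0) * (r - r0);
      arma::vec3 g = 2.0 * kb * (r - r0) * d / r;
      for (int c = 0; c < 3; ++c) { G(H, c) += g(c); G(O, c) -= g(c); }
    }
    int H1 = molatoms(m, 1), H2 = molatoms(m, 2);
    arma::vec3 a = (pos.row(H1) - pos.row(O)).t();
    arma::vec3 b = (pos.row(H2) - pos.row(O)).t();
    double ra = arma::norm(a), rb = arma::norm(b);
    double cth = arma::dot(a, b) / (ra * rb);
    cth = std::max(-1.0, std::min(1.0, cth));
    double th = std::acos(cth);
    U += ka * (th - th0) * (th - th0);
    double s = std::sqrt(std::max(1e-14, 1.0 - cth * cth));
    double pref = -2.0 * ka * (th - th0) / s;  // dU/d(cos th)
    arma::vec3 dca = (b / (ra * rb)) - cth * a / (ra * ra);
    arma::vec3 dcb = (a / (ra * rb)) - cth * b / (rb * rb);
    for (int c = 0; c < 3; ++c) {
      G(H1, c) += pref * dca(c);
      G(H2, c) += pref * dcb(c);
      G(O, c)  -= pref * (dca(c) + dcb(c));
    }
  }
  return U;
}

// generic pairwise intermolecular dispersion/repulsion
//   form = 96:  U = A/r^9 - B/r^6
//   form = 126: U = A/r^12 - B/r^6
// coefficients per element-pair index: 0 = OO, 1 = OH, 2 = HH.
// With a periodic cell the interaction is tapered to zero by a C^1 cosine
// switch over the outer 15% of the cutoff (keeps both energy and forces
// continuous); clusters use the full sum (cutoff <= 0 disables truncation).
static double vdw_energy(const arma::mat& pos, const arma::ivec& elem,
                         const arma::ivec& mol, const arma::vec& cell,
                         const arma::vec& A, const arma::vec& B, int form,
                         double cutoff, arma::mat& G) {
  const int n = pos.n_rows;
  double U = 0.0;
  bool trunc = cutoff > 0.0;
  int prep = (form == 96) ? 9 : 12;
  double r_on = 0.85 * cutoff, span = cutoff - r_on;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (mol(i) == mol(j)) continue;
      int pt = elem(i) + elem(j);  // OO=0, OH=1, HH=2
      if (A(pt) == 0.0 && B(pt) == 0.0) continue;
      arma::vec3 d = min_image(pos, i, j, cell);
      double r = arma::norm(d);
      if (trunc && r > cutoff) continue;
      double rp = std::pow(r, prep), r6 = std::pow(r, 6);
      double u = A(pt) / rp - B(pt) / r6;
      double dUdr = -prep * A(pt) / (rp * r) + 6.0 * B(pt) / (r6 * r);
      if (trunc && r > r_on) {
        double x = (r - r_on) / span;
        double s = 0.5 * (1.0 + std::cos(PI_ * x));
        double ds = -0.5 * PI_ / span * std::sin(PI_ * x);
        dUdr = dUdr * s + u * ds;
        u *= s;
      }
      U += u;
      arma::vec3 g = dUdr * d / r;
      for (int c = 0; c < 3; ++c) { G(j, c) += g(c); G(i, c) -= g(c); }
    }
  return U;
}

// direct-sum Coulomb for clusters; phi_i = dU/dq_i
static double coulomb_cluster(const arma::mat& pos, const arma::ivec& mol,
                              const arma::vec& q, double ke, arma::mat& G,
                              arma::vec& phi) {
  const int n = pos.n_rows;
  double U = 0.0;
  phi.zeros(n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (mol(i) == mol(j)) continue;
      arma::vec3 d = (pos.row(j) - pos.row(i)).t();
      double r = arma::norm(d);
      U += ke * q(i) * q(j) / r;
      phi(i) += ke * q(j) / r;
      phi(j) += ke * q(i) / r;
      double dUdr = -ke * q(i) * q(j) / (r * r);
      arma::vec3 g = dUdr * d / r;
      for (int c = 0; c < 3; ++c) { G(j, c) += g(c); G(i, c) -= g(c); }
    }
  return U;
}

// Ewald summation for an orthorhombic cell; intramolecular pairs excluded
// (real-space skip + reciprocal-space erf correction).  Returns total energy;
// fills fixed-charge gradient G and the electrostatic potential phi = dU/dq.
// [[Rcpp::export]]
List cpp_ewald(const arma::mat& pos, const arma::ivec& mol, const arma::vec& q,
               const arma::vec& cell, double ke, double alpha, double rcut,
               const arma::ivec& kmax) {
  const int n = pos.n_rows;
  const double V = cell(0) * cell(1) * cell(2);
  arma::mat G(n, 3, arma::fill::zeros);
  arma::vec phi(n, arma::fill::zeros);
  double Ureal = 0.0, Urec = 0.0, Uself = 0.0, Ucorr = 0.0;
  const double twoopi = 2.0 / std::sqrt(PI_);

  // real space (intermolecular, minimum image)
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (mol(i) == mol(j)) continue;
      arma::vec3 d = min_image(pos, i, j, cell);
      double r = arma::norm(d);
      if (r > rcut) continue;
      double er = std::erfc(alpha * r);
      Ureal += ke * q(i) * q(j) * er / r;
      phi(i) += ke * q(j) * er / r;
      phi(j) += ke * q(i) * er / r;
      double dUdr = -ke * q(i) * q(j) *
        (er / (r * r) + twoopi * alpha * std::exp(-alpha * alpha * r * r) / r);
      arma::vec3 g = dUdr * d / r;
      for (int c = 0; c < 3; ++c) { G(j, c) += g(c); G(i, c) -= g(c); }
    }

  // reciprocal space with per-axis complex exponential tables
  int kx = kmax(0), ky = kmax(1), kz = kmax(2);
  arma::cx_mat ex(n, kx + 1), ey(n, ky + 1), ez(n, kz + 1);
  for (int i = 0; i < n; ++i) {
    ex(i, 0) = ey(i, 0) = ez(i, 0) = arma::cx_double(1.0, 0.0);
    arma::cx_double fx(std::cos(2 * PI_ * pos(i, 0) / cell(0)),
                       std::sin(2 * PI_ * pos(i, 0) / cell(0)));
    arma::cx_double fy(std::cos(2 * PI_ * pos(i, 1) / cell(1)),
                       std::sin(2 * PI_ * pos(i, 1) / cell(1)));
    arma::cx_double fz(std::cos(2 * PI_ * pos(i, 2) / cell(2)),
                       std::sin(2 * PI_ * pos(i, 2) / cell(2)));
    for (int k = 1; k <= kx; ++k) ex(i, k) = ex(i, k - 1) * fx;
    for (int k = 1; k <= ky; ++k) ey(i, k) = ey(i, k - 1) * fy;
    for (int k = 1; k <= kz; ++k) ez(i, k) = ez(i, k - 1) * fz;
  }
  arma::cx_vec eik(n);
  for (int nx = 0; nx <= kx; ++nx)
    for (int ny = (nx == 0 ? 0 : -ky); ny <= ky; ++ny)
      for (int nz = ((nx == 0 && ny == 0) ? 1 : -kz); nz <= kz; ++nz) {
        double gx = 2 * PI_ * nx / cell(0);
        double gy = 2 * PI_ * ny / cell(1);
        double gz = 2 * PI_ * nz / cell(2);
        double k2 = gx * gx + gy * gy + gz * gz;
        double pref = 2.0 * ke * (2.0 * PI_ / V) *
          std::exp(-k2 / (4.0 * alpha * alpha)) / k2;  // x2: half-space sum
        arma::cx_double S(0.0, 0.0);
        for (int i = 0; i < n; ++i) {
          arma::cx_double cy = (ny >= 0) ? ey(i, ny) : std::conj(ey(i, -ny));
          arma::cx_double cz = (nz >= 0) ? ez(i, nz) : std::conj(ez(i, -nz));
          eik(i) = ex(i, nx) * cy * cz;
          S += q(i) * eik(i);
        }
        Urec += pref * std::norm(S);
        for (int i = 0; i < n; ++i) {
          arma::cx_double sc = std::conj(S) * eik(i);
          phi(i) += 2.0 * pref * sc.real();
          double im = 2.0 * pref * q(i) * sc.imag();
          G(i, 0) -= im * gx;
          G(i, 1) -= im * gy;
          G(i, 2) -= im * gz;
        }
      }

  // self energy
  for (int i = 0; i < n; ++i) {
    Uself -= ke * alpha / std::sqrt(PI_) * q(i) * q(i);
    phi(i) -= 2.0 * ke * alpha / std::sqrt(PI_) * q(i);
  }

  // intramolecular correction (remove screened intra pairs counted in recip)
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (mol(i) != mol(j)) continue;
      arma::vec3 d = min_image(pos, i, j, cell);
      double r = arma::norm(d);
      double ef = std::erf(alpha * r);
      Ucorr -= ke * q(i) * q(j) * ef / r;
      phi(i) -= ke * q(j) * ef / r;
      phi(j) -= ke * q(i) * ef / r;
      double ddr = (twoopi * alpha * std::exp(-alpha * alpha * r * r) * r - ef) /
                   (r * r);
      double dUdr = -ke * q(i) * q(j) * ddr;
      arma::vec3 g = dUdr * d / r;
      for (int c = 0; c < 3; ++c) { G(j, c) += g(c); G(i, c) -= g(c); }
    }

  return List::create(_["energy"] = Ureal + Urec + Uself + Ucorr,
                      _["real"] = Ureal, _["recip"] = Urec,
                      _["self"] = Uself, _["intra_corr"] = Ucorr,
                      _["gradient"] = G, _["phi"] = phi);
}

// exported single-term evaluators -------------------------------------------

// [[Rcpp::export]]
List cpp_intra_eval(const arma::mat& pos, const arma::imat& molatoms,
                    double kb, double ka, double r0, double th0) {
  arma::mat G(pos.n_rows, 3, arma::fill::zeros);
  double U = intra_energy(pos, molatoms, kb, ka, r0, th0, G);
  return List::create(_["energy"] = U, _["gradient"] = G);
}

// [[Rcpp::export]]
List cpp_vdw_eval(const arma::mat& pos, const arma::ivec& elem,
                  const arma::ivec& mol, const arma::vec& cell,
                  const arma::vec& A, const arma::vec& B, int form,
                  double cutoff) {
  arma::mat G(pos.n_rows, 3, arma::fill::zeros);
  double U = vdw_energy(pos, elem, mol, cell, A, B, form, cutoff, G);
  return List::create(_["energy"] = U, _["gradient"] = G);
}

// [[Rcpp::export]]
List cpp_coulomb_cluster(const arma::mat& pos, const arma::ivec& mol,
                         const arma::vec& q, double ke) {
  arma::mat G(pos.n_rows, 3, arma::fill::zeros);
  arma::vec phi;
  double U = coulomb_cluster(pos, mol, q, ke, G, phi);
  return List::create(_["energy"] = U, _["gradient"] = G, _["phi"] = phi);
}

// ---------------------------------------------------------------------------
// full dynamic-charge model evaluation with chain-rule forces
// ---------------------------------------------------------------------------

// CT molecule pairs: minimum-image O-O distance <= ct_cut; columns I, J, rOO
static arma::mat ct_pairs(const arma::mat& pos, const arma::imat& molatoms,
                          const arma::vec& cell, double ct_cut) {
  const int nmol = molatoms.n_rows;
  std::vector<double> rows;
  for (int I = 0; I < nmol; ++I)
    for (int J = I + 1; J < nmol; ++J) {
      arma::vec3 d = min_image(pos, molatoms(I, 0), molatoms(J, 0), cell);
      double r = arma::norm(d);
      if (r <= ct_cut) { rows.push_back(I); rows.push_back(J); rows.push_back(r); }
    }
  arma::mat out(rows.size() / 3, 3);
  for (arma::uword k = 0; k < out.n_rows; ++k)
    for (int c = 0; c < 3; ++c) out(k, c) = rows[3 * k + c];
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_ct_pair_list(const arma::mat& pos, const arma::imat& molatoms,
                           const arma::vec& cell, double ct_cut) {
  return ct_pairs(pos, molatoms, cell, ct_cut);
}

// Full evaluation of the dynamic-charge water model.
//
// params: kb, ka, r0, th0 (intra); A, B length-3 (9-6 vdW, OO/OH/HH);
// ke; kc, dq0 (CT); rcut (real-space/vdW cutoff, PBC only);
// alpha, kmax (Ewald, PBC only).
// [[Rcpp::export]]
List cpp_chargenn_eval(const arma::mat& pos, const arma::ivec& elem,
                       const arma::ivec& mol, const arma::imat& molatoms,
                       const arma::vec& cell, const List& netO,
                       const List& netH, const List& netCT,
                       const arma::vec& kf, double rc, double ct_cut,
                       const List& params, bool want_forces) {
  const int n = pos.n_rows;
  const int nmol = molatoms.n_rows;
  const bool periodic = cell.n_elem == 3;
  const double kb = as<double>(params["kb"]), ka = as<double>(params["ka"]);
  const double r0 = as<double>(params["r0"]), th0 = as<double>(params["th0"]);
  const arma::vec A = as<arma::vec>(params["A"]), B = as<arma::vec>(params["B"]);
  const double ke = as<double>(params["ke"]);
  const double kc = as<double>(params["kc"]), dq0 = as<double>(params["dq0"]);
  const double rcut = as<double>(params["rcut"]);

  Net NO = net_from_list(netO), NH = net_from_list(netH),
      NC = net_from_list(netCT);

  // 1) features and charges
  ChargeFeatWork w = charge_features_work(pos, elem, mol, molatoms, cell, kf, rc);
  arma::vec qraw(n);
  arma::mat dqdF(n, 24);
  for (int i = 0; i < n; ++i) {
    arma::vec g;
    qraw(i) = net_eval(elem(i) == 0 ? NO : NH, w.F.row(i).t(),
                       want_forces ? &g : nullptr);
    if (want_forces) dqdF.row(i) = g.t();
  }
  double dq_shift = arma::mean(qraw);
  arma::vec q = qraw - dq_shift;

  // 2) coordinate-explicit energy terms
  arma::mat G(n, 3, arma::fill::zeros);
  double U_intra = intra_energy(pos, molatoms, kb, ka, r0, th0, G);
  double U_vdw = vdw_energy(pos, elem, mol, cell, A, B, 96,
                            periodic ? rcut : -1.0, G);
  double U_coul;
  arma::vec phi;
  if (periodic) {
    double alpha = as<double>(params["alpha"]);
    arma::ivec kmax = as<arma::ivec>(params["kmax"]);
    List ew = cpp_ewald(pos, mol, q, cell, ke, alpha, rcut, kmax);
    U_coul = as<double>(ew["energy"]);
    G += as<arma::mat>(ew["gradient"]);
    phi = as<arma::vec>(ew["phi"]);
  } else {
    arma::mat Gc(n, 3, arma::fill::zeros);
    U_coul = coulomb_cluster(pos, mol, q, ke, Gc, phi);
    G += Gc;
  }

  // 3) charge transfer
  arma::mat pairs = ct_pairs(pos, molatoms, cell, ct_cut);
  const int np = pairs.n_rows;
  arma::vec dq_pair(np, arma::fill::zeros);
  double U_ct = 0.0;
  std::vector<arma::vec> gF1(np), gF2(np);
  std::vector<CTWork> ctw(np);
  arma::vec gatev(np), rawv(np);
  for (int p = 0; p < np; ++p) {
    int I = pairs(p, 0), J = pairs(p, 1);
    double rOO = pairs(p, 2);
    ctw[p] = ct_features_work(pos, elem, molatoms, cell, I, J, kf, ct_cut);
    arma::vec FIJ = ctw[p].F;
    arma::vec FJI(36);
    FJI.subvec(0, 17) = FIJ.subvec(18, 35);
    FJI.subvec(18, 35) = FIJ.subvec(0, 17);
    double g1 = net_eval(NC, FIJ, want_forces ? &gF1[p] : nullptr);
    double g2 = net_eval(NC, FJI, want_forces ? &gF2[p] : nullptr);
    double gate = sc_fun(rOO, ct_cut);
    rawv(p) = 0.5 * (g1 - g2);
    gatev(p) = gate;
    double dq = gate * rawv(p);
    dq_pair(p) = dq;
    double den = dq * dq + 3.0 * dq0 * dq0;
    U_ct += -kc * dq * dq / den;
  }

  // 4) chain-rule force assembly
  if (want_forces) {
    // (a) charge chain: sum_i (phi_i - mean(phi)) * dqraw_i/dR
    arma::vec wgt = phi - arma::mean(phi);
    arma::mat C(n, 24);
    for (int i = 0; i < n; ++i) C.row(i) = wgt(i) * dqdF.row(i);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        arma::vec3 d = min_image(pos, i, j, cell);
        double r = arma::norm(d);
        if (r >= rc) continue;
        arma::vec3 u = d / r;
        bool same = mol(i) == mol(j);
        double S = 0.0;
        for (int t = 0; t < 3; ++t) {
          double At = 0.0;
          if (same) {
            At += C(i, 8 * t + elem(j)) + C(j, 8 * t + elem(i));
          } else {
            At += C(i, 8 * t + 2 + elem(j)) + C(j, 8 * t + 2 + elem(i));
            // sibling chains for both ends
            int ends[2] = {i, j};
            for (int e = 0; e < 2; ++e) {
              int a = ends[e];
              int cls = elem(ends[1 - e]);
              int m = mol(a);
              int O = molatoms(m, 0), H1 = molatoms(m, 1), H2 = molatoms(m, 2);
              if (a == O) {
                // O's inter ICF feeds each H sibling's slot +4..5 (k==0 block)
                At += C(H1, 8 * t + 4 + cls) + C(H2, 8 * t + 4 + cls);
              } else {
                int oth = (a == H1) ? H2 : H1;
                // H's inter ICF feeds: O's sum + power-sum slots, and the
                // other H's "other-H" block (+6..7)
                At += C(O, 8 * t + 4 + cls) +
                      C(O, 8 * t + 6 + cls) * 2.0 * w.Hinter(a, cls, t) +
                      C(oth, 8 * t + 6 + cls);
              }
            }
          }
          if (At != 0.0) S += At * kern_der(r, kf(t), rc);
        }
        for (int c = 0; c < 3; ++c) { G(j, c) += S * u(c); G(i, c) -= S * u(c); }
      }

    // (b) CT chain
    for (int p = 0; p < np; ++p) {
      int I = pairs(p, 0), J = pairs(p, 1);
      double dq = dq_pair(p);
      double den = dq * dq + 3.0 * dq0 * dq0;
      double dUddq = -kc * 6.0 * dq0 * dq0 * dq / (den * den);
      if (dUddq == 0.0 && gatev(p) == 0.0) continue;
      // d(dq)/dF contributions per half
      arma::vec cI(18), cJ(18);
      cI = 0.5 * gatev(p) * (gF1[p].subvec(0, 17) - gF2[p].subvec(18, 35));
      cJ = 0.5 * gatev(p) * (gF1[p].subvec(18, 35) - gF2[p].subvec(0, 17));
      // chain into h values then atom pairs
      int ai[3] = {molatoms(I, 0), molatoms(I, 1), molatoms(I, 2)};
      int aj[3] = {molatoms(J, 0), molatoms(J, 1), molatoms(J, 2)};
      for (int pp = 0; pp < 3; ++pp)
        for (int qq = 0; qq < 3; ++qq) {
          arma::vec3 d = min_image(pos, ai[pp], aj[qq], cell);
          double r = arma::norm(d);
          if (r >= ct_cut) continue;
          arma::vec3 u = d / r;
          double S = 0.0;
          for (int t = 0; t < 3; ++t) {
            double At = 0.0;
            int cA = elem(aj[qq]);  // class seen from I's atom
            if (pp == 0) At += cI(6 * t + 0 + cA);
            else At += cI(6 * t + 2 + cA) +
                       cI(6 * t + 4 + cA) * 2.0 * ctw[p].h[0][pp][cA][t];
            int cB = elem(ai[pp]);
            if (qq == 0) At += cJ(6 * t + 0 + cB);
            else At += cJ(6 * t + 2 + cB) +
                       cJ(6 * t + 4 + cB) * 2.0 * ctw[p].h[1][qq][cB][t];
            if (At != 0.0) S += At * kern_der(r, kf(t), ct_cut);
          }
          S *= dUddq;
          for (int c = 0; c < 3; ++c) {
            G(aj[qq], c) += S * u(c);
            G(ai[pp], c) -= S * u(c);
          }
        }
      // gate derivative along the O-O axis
      double rOO = pairs(p, 2);
      double dgate = sc_der(rOO, ct_cut);
      if (dgate != 0.0) {
        double Sg = dUddq * dgate * rawv(p);
        arma::vec3 d = min_image(pos, ai[0], aj[0], cell);
        arma::vec3 u = d / rOO;
        for (int c = 0; c < 3; ++c) {
          G(aj[0], c) += Sg * u(c);
          G(ai[0], c) -= Sg * u(c);
        }
      }
    }
  }

  arma::mat pair_out(np, 3);
  for (int p = 0; p < np; ++p) {
    pair_out(p, 0) = pairs(p, 0);
    pair_out(p, 1) = pairs(p, 1);
    pair_out(p, 2) = dq_pair(p);
  }
  (void)nmol;
  return List::create(
      _["U_intra"] = U_intra, _["U_vdw"] = U_vdw, _["U_coul"] = U_coul,
      _["U_ct"] = U_ct, _["U_total"] = U_intra + U_vdw + U_coul + U_ct,
      _["forces"] = want_forces ? wrap(arma::mat(-G)) : R_NilValue,
      _["charges"] = q, _["dq_shift"] = dq_shift, _["features"] = w.F,
      _["ct_pairs"] = pair_out);
}

// ---------------------------------------------------------------------------
// fixed-charge SPC/FW evaluation
// ---------------------------------------------------------------------------

// params: kb, ka, r0, th0, A, B (12-6, OO/OH/HH), ke, qO, qH,
// rcut/alpha/kmax for PBC
// [[Rcpp::export]]
List cpp_spcfw_eval(const arma::mat& pos, const arma::ivec& elem,
                    const arma::ivec& mol, const arma::imat& molatoms,
                    const arma::vec& cell, const List& params) {
  const int n = pos.n_rows;
  const bool periodic = cell.n_elem == 3;
  arma::mat G(n, 3, arma::fill::zeros);
  double U_intra = intra_energy(pos, molatoms, as<double>(params["kb"]),
                                as<double>(params["ka"]),
                                as<double>(params["r0"]),
                                as<double>(params["th0"]), G);
  const arma::vec A = as<arma::vec>(params["A"]), B = as<arma::vec>(params["B"]);
  const double rcut = as<double>(params["rcut"]);
  double U_vdw = vdw_energy(pos, elem, mol, cell, A, B, 126,
                            periodic ? rcut : -1.0, G);
  arma::vec q(n);
  const double qO = as<double>(params["qO"]), qH = as<double>(params["qH"]);
  for (int i = 0; i < n; ++i) q(i) = (elem(i) == 0) ? qO : qH;
  const double ke = as<double>(params["ke"]);
  double U_coul;
  if (periodic) {
    List ew = cpp_ewald(pos, mol, q, cell, ke, as<double>(params["alpha"]),
                        rcut, as<arma::ivec>(params["kmax"]));
    U_coul = as<double>(ew["energy"]);
    G += as<arma::mat>(ew["gradient"]);
  } else {
    arma::vec phi;
    arma::mat Gc(n, 3, arma::fill::zeros);
    U_coul = coulomb_cluster(pos, mol, q, ke, Gc, phi);
    G += Gc;
  }
  return List::create(
      _["U_intra"] = U_intra, _["U_vdw"] = U_vdw, _["U_coul"] = U_coul,
      _["U_ct"] = 0.0, _["U_total"] = U_intra + U_vdw + U_coul,
      _["forces"] = wrap(arma::mat(-G)), _["charges"] = q);
}
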