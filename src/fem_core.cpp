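// Total-Lagrangian assembly kernels for 4-node tetrahedra with decoupled
// nearly-incompressible hyperelastic materials (Neo-Hookean and
// five-parameter Mooney-Rivlin), plus incompressible Neo-Hookean membrane
// triangles for the skin and a brute-force-with-pruning point-to-triangle
// distance used by the surface-to-surface validation metric.
//
// Unit convention inside these kernels: mm - tonne - s, i.e. moduli in MPa,
// densities in tonne/mm^3, forces in N.  The R layer converts from the
// user-facing kPa / kg/m^3.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct MatLaw {
  int kind;           // 0 = neo_hookean, 1 = mooney_rivlin_5
  double mu, d;       // MPa, 1/MPa
  double C10, C01, C11, C20, C02; // MPa
};

static inline MatLaw mat_from_row(const rowvec& r) {
  MatLaw m;
  m.kind = (int) r(0); m.mu = r(1); m.d = r(2);
  m.C10 = r(3); m.C01 = r(4); m.C11 = r(5); m.C20 = r(6); m.C02 = r(7);
  return m;
}

// isochoric strain energy density (MPa); the volumetric penalty is
// evaluated separately on the patch-averaged Jacobian (mean dilatation)
static inline double iso_energy_density(const MatLaw& m, const mat33& F,
                                        double J) {
  const double Jm23 = std::pow(J, -2.0 / 3.0);
  const mat33 Bbar = Jm23 * (F * F.t());
  const double I1 = trace(Bbar);
  if (m.kind == 0) return 0.5 * m.mu * (I1 - 3.0);
  const double I2 = 0.5 * (I1 * I1 - trace(Bbar * Bbar));
  const double a = I1 - 3.0, b = I2 - 3.0;
  return m.C10 * a + m.C01 * b + m.C11 * a * b +
         m.C20 * a * a + m.C02 * b * b;
}

// deviatoric (isochoric) Cauchy stress (MPa)
static inline mat33 iso_cauchy(const MatLaw& m, const mat33& F, double J) {
  const double Jm23 = std::pow(J, -2.0 / 3.0);
  const mat33 Bbar = Jm23 * (F * F.t());
  const double I1 = trace(Bbar);
  double W1, W2;
  if (m.kind == 0) { W1 = 0.5 * m.mu; W2 = 0.0; }
  else {
    const double I2 = 0.5 * (I1 * I1 - trace(Bbar * Bbar));
    W1 = m.C10 + m.C11 * (I2 - 3.0) + 2.0 * m.C20 * (I1 - 3.0);
    W2 = m.C01 + m.C11 * (I1 - 3.0) + 2.0 * m.C02 * (I2 - 3.0);
  }
  mat33 S = (W1 + I1 * W2) * Bbar - W2 * (Bbar * Bbar);
  const double tr3 = trace(S) / 3.0;
  S.diag() -= tr3;
  mat33 sig = (2.0 / J) * S;
  return 0.5 * (sig + sig.t());
}

// isochoric first Piola-Kirchhoff stress P = J * sigma_iso * F^{-T}
static inline mat33 piola_iso(const MatLaw& m, const mat33& F) {
  const double J = det(F);
  const mat33 sig = iso_cauchy(m, F, J);
  return J * sig * inv(F).t();
}

static inline double von_mises_of(const mat33& sig) {
  const double p = trace(sig) / 3.0;
  mat33 s = sig; s.diag() -= p;
  return std::sqrt(1.5 * accu(s % s));
}

// Assemble internal force, strain energy, per-element von Mises stress and
// (optionally) the consistent tangent (as triplets) for the tetrahedral part.
//
// The isochoric response is evaluated per element; the volumetric penalty
// uses the volume-averaged Jacobian of each element patch (the 6-tet
// subdivision of one structured hexahedral cell) -- a mean-dilatation /
// B-bar treatment that relieves volumetric locking of linear tetrahedra
// at nu = 0.49.  With `patch = 1..m` (each element its own patch) the
// scheme reduces to the standard displacement formulation.
//
// nodes: n x 3 reference coordinates (mm); tets: m x 4 one-based indices;
// matrow: m x 8 per-element material rows (kind, mu, d, C10..C02) in MPa;
// patch: length-m one-based patch ids (contiguous); u: length-3n
// displacement (mm), DOF order (node1 xyz, node2 xyz, ...).
// [[Rcpp::export]]
Rcpp::List fem_assemble_tets(const arma::mat& nodes,
                             const arma::imat& tets,
                             const arma::mat& matrow,
                             const arma::ivec& patch,
                             const arma::vec& u,
                             bool want_tangent,
                             bool want_stress) {
  const uword m = tets.n_rows;
  const uword npatch = patch.max();
  vec fint(3 * nodes.n_rows, fill::zeros);
  vec vm(want_stress ? m : 0);
  double energy = 0.0, minJ = datum::inf;
  int badElem = -1;

  std::vector<unsigned int> ti, tj;
  std::vector<double> tx;
  if (want_tangent) {
    ti.reserve(m * 180); tj.reserve(m * 180); tx.reserve(m * 180);
  }

  const double h = 1e-6;  // central-difference step for dP_iso/dF

  // pass A: element kinematics, isochoric force/tangent, patch J averages
  mat Qs(m, 12);
  vec Js(m), Vs(m);
  vec Vp(npatch, fill::zeros), VJp(npatch, fill::zeros);
  vec dsum(npatch, fill::zeros);  // sum of 2 V_e / d_e per patch

  for (uword e = 0; e < m; ++e) {
    uvec id(4);
    for (int a = 0; a < 4; ++a) id(a) = (uword)(tets(e, a) - 1);
    mat X(3, 4), x(3, 4);
    for (int a = 0; a < 4; ++a) {
      X.col(a) = nodes.row(id(a)).t();
      x.col(a) = X.col(a) + u.subvec(3 * id(a), 3 * id(a) + 2);
    }
    mat33 Dm;
    for (int a = 0; a < 3; ++a) Dm.col(a) = X.col(a + 1) - X.col(0);
    const double V0 = det(Dm) / 6.0;
    if (V0 <= 0) { badElem = (int) e + 1; minJ = -1.0; break; }
    const mat33 Dmi = inv(Dm);
    mat G(4, 3);                       // rows a = dN_a/dX
    G.rows(1, 3) = Dmi;
    G.row(0) = -(Dmi.row(0) + Dmi.row(1) + Dmi.row(2));

    mat33 Ds;
    for (int a = 0; a < 3; ++a) Ds.col(a) = x.col(a + 1) - x.col(0);
    const mat33 F = Ds * Dmi;
    const double J = det(F);
    if (J < minJ) minJ = J;
    if (J <= 0) { badElem = (int) e + 1; break; }

    const MatLaw mt = mat_from_row(matrow.row(e));
    energy += V0 * iso_energy_density(mt, F, J);
    const mat33 sig = iso_cauchy(mt, F, J);
    if (want_stress) vm(e) = von_mises_of(sig);
    const mat33 P = J * sig * inv(F).t();
    const mat33 FinvT = inv(F).t();

    for (int a = 0; a < 4; ++a) {
      const vec3 fa = V0 * (P * G.row(a).t());
      fint.subvec(3 * id(a), 3 * id(a) + 2) += fa;
      // q_a = F^{-T} G_a; g = dJ/du entries are J * q_a
      const vec3 qa = FinvT * G.row(a).t();
      Qs(e, span(3 * a, 3 * a + 2)) = qa.t();
    }
    Js(e) = J; Vs(e) = V0;
    const uword p = (uword)(patch(e) - 1);
    Vp(p) += V0; VJp(p) += V0 * J;
    dsum(p) += 2.0 * V0 / mt.d;

    if (want_tangent) {
      // isochoric material tangent by central differences of P_iso
      cube A[3];
      for (int k = 0; k < 3; ++k) A[k].set_size(3, 3, 3);
      for (int k = 0; k < 3; ++k) {
        for (int L = 0; L < 3; ++L) {
          mat33 Fp = F, Fm = F;
          Fp(k, L) += h; Fm(k, L) -= h;
          const mat33 dP = (piola_iso(mt, Fp) - piola_iso(mt, Fm)) /
            (2.0 * h);
          A[k].slice(L) = dP;
        }
      }
      for (int a = 0; a < 4; ++a) {
        for (int b = 0; b < 4; ++b) {
          mat33 Kab(fill::zeros);
          for (int k = 0; k < 3; ++k) {
            for (int L = 0; L < 3; ++L) {
              Kab.col(k) += V0 * G(b, L) * (A[k].slice(L) * G.row(a).t());
            }
          }
          for (int i = 0; i < 3; ++i)
            for (int k = 0; k < 3; ++k) {
              ti.push_back(3 * id(a) + i + 1);
              tj.push_back(3 * id(b) + k + 1);
              tx.push_back(Kab(i, k));
            }
        }
      }
    }
  }

  if (badElem < 0) {
    // pass B: volumetric (mean-dilatation) energy, force and tangent
    vec Jbar = VJp / Vp;
    // per-element volumetric energy with patch-averaged J
    for (uword e = 0; e < m; ++e) {
      const uword p = (uword)(patch(e) - 1);
      const MatLaw mt = mat_from_row(matrow.row(e));
      energy += (Vs(e) / mt.d) * (Jbar(p) - 1.0) * (Jbar(p) - 1.0);
    }
    // group elements by patch for the force and rank-one tangent
    uvec order = sort_index(patch);
    uword s0 = 0;
    while (s0 < m) {
      uword s1 = s0;
      const sword pid = patch(order(s0));
      while (s1 < m && patch(order(s1)) == pid) ++s1;
      const uword p = (uword)(pid - 1);
      const double kap = (Jbar(p) - 1.0) * dsum(p);  // dWvol/dJbar
      // y = dJbar/du restricted to the patch dofs
      std::vector<uword> pdof;
      std::vector<double> yval;
      pdof.reserve(96); yval.reserve(96);
      for (uword s = s0; s < s1; ++s) {
        const uword e = order(s);
        const double wf = Vs(e) / Vp(p);
        for (int a = 0; a < 4; ++a) {
          const uword nd = (uword)(tets(e, a) - 1);
          for (int i = 0; i < 3; ++i) {
            pdof.push_back(3 * nd + i);
            yval.push_back(wf * Js(e) * Qs(e, 3 * a + i));
          }
        }
      }
      // combine duplicate dofs
      std::vector<size_t> idx(pdof.size());
      for (size_t k = 0; k < idx.size(); ++k) idx[k] = k;
      std::sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
        return pdof[a] < pdof[b]; });
      std::vector<uword> dof2; std::vector<double> y2;
      for (size_t k = 0; k < idx.size(); ++k) {
        if (!dof2.empty() && dof2.back() == pdof[idx[k]]) {
          y2.back() += yval[idx[k]];
        } else {
          dof2.push_back(pdof[idx[k]]);
          y2.push_back(yval[idx[k]]);
        }
      }
      // force: kappa * y
      for (size_t k = 0; k < dof2.size(); ++k) {
        fint(dof2[k]) += kap * y2[k];
      }
      if (want_tangent) {
        // rank-one patch term: dsum * y y^T
        for (size_t a = 0; a < dof2.size(); ++a) {
          for (size_t b = 0; b < dof2.size(); ++b) {
            ti.push_back(dof2[a] + 1);
            tj.push_back(dof2[b] + 1);
            tx.push_back(dsum(p) * y2[a] * y2[b]);
          }
        }
        // geometric term: kappa * w_f * d(g_f)/du per element
        for (uword s = s0; s < s1; ++s) {
          const uword e = order(s);
          const double cf = kap * Vs(e) / Vp(p) * Js(e);
          for (int a = 0; a < 4; ++a) {
            const uword na = (uword)(tets(e, a) - 1);
            const vec3 qa = Qs(e, span(3 * a, 3 * a + 2)).t();
            for (int b = 0; b < 4; ++b) {
              const uword nb = (uword)(tets(e, b) - 1);
              const vec3 qb = Qs(e, span(3 * b, 3 * b + 2)).t();
              // cf * (qa_i qb_k - qb_i qa_k)
              // pattern kept value-independent so the sparse structure
              // can be cached across Newton iterations
              for (int i = 0; i < 3; ++i)
                for (int k = 0; k < 3; ++k) {
                  ti.push_back(3 * na + i + 1);
                  tj.push_back(3 * nb + k + 1);
                  tx.push_back(cf * (qa(i) * qb(k) - qb(i) * qa(k)));
                }
            }
          }
        }
      }
      s0 = s1;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("fint") = fint,
      Rcpp::Named("energy") = energy,
      Rcpp::Named("vm") = vm,
      Rcpp::Named("minJ") = minJ,
      Rcpp::Named("bad_element") = badElem,
      Rcpp::Named("ki") = Rcpp::IntegerVector(ti.begin(), ti.end()),
      Rcpp::Named("kj") = Rcpp::IntegerVector(tj.begin(), tj.end()),
      Rcpp::Named("kx") = Rcpp::NumericVector(tx.begin(), tx.end()));
}

// membrane internal force for one triangle (plane-stress incompressible
// Neo-Hookean, thickness change eliminated via J3 = 1)
static inline double membrane_force(const mat& Xl, const mat& xcur,
                                    double muT /* mu * t * A */,
                                    const mat& Dmi /* 2x2 */,
                                    mat& fout /* 3x3: columns f1 f2 f3 */) {
  mat Ds(3, 2);
  Ds.col(0) = xcur.col(1) - xcur.col(0);
  Ds.col(1) = xcur.col(2) - xcur.col(0);
  const mat Fs = Ds * Dmi;            // 3x2
  const mat22 C2 = Fs.t() * Fs;
  const double J2 = det(C2);
  if (J2 <= 1e-12) return datum::nan;
  const double w = 0.5 * (trace(C2) + 1.0 / J2 - 3.0); // per mu
  const mat dWdF = muT * (Fs - (1.0 / J2) * Fs * inv(C2)); // 3x2
  const mat H = dWdF * Dmi.t();       // 3x2 -> forces on nodes 2,3
  fout.col(1) = H.col(0);
  fout.col(2) = H.col(1);
  fout.col(0) = -H.col(0) - H.col(1);
  return muT * w;
}

// Assemble the skin membrane part.  tris: s x 3 one-based; mu in MPa,
// thickness in mm (per element).
// [[Rcpp::export]]
Rcpp::List fem_assemble_membrane(const arma::mat& nodes,
                                 const arma::imat& tris,
                                 const arma::vec& thickness,
                                 double mu,
                                 const arma::vec& u,
                                 bool want_tangent) {
  const uword s = tris.n_rows;
  vec fint(3 * nodes.n_rows, fill::zeros);
  double energy = 0.0;
  bool ok = true;

  std::vector<unsigned int> ti, tj;
  std::vector<double> tx;
  if (want_tangent) {
    ti.reserve(s * 81); tj.reserve(s * 81); tx.reserve(s * 81);
  }

  for (uword e = 0; e < s && ok; ++e) {
    uvec id(3);
    for (int a = 0; a < 3; ++a) id(a) = (uword)(tris(e, a) - 1);
    mat X(3, 3), x(3, 3);
    for (int a = 0; a < 3; ++a) {
      X.col(a) = nodes.row(id(a)).t();
      x.col(a) = X.col(a) + u.subvec(3 * id(a), 3 * id(a) + 2);
    }
    const vec3 E1 = X.col(1) - X.col(0);
    const vec3 E2 = X.col(2) - X.col(0);
    const vec3 n = cross(E1, E2);
    const double A = 0.5 * norm(n);
    if (A <= 0) continue;
    const vec3 e1 = normalise(E1);
    const vec3 e2 = normalise(cross(n, E1));
    mat22 Dm;
    Dm(0, 0) = dot(E1, e1); Dm(0, 1) = dot(E2, e1);
    Dm(1, 0) = 0.0;         Dm(1, 1) = dot(E2, e2);
    const mat22 Dmi = inv(Dm);
    const double muT = mu * thickness(e) * A;

    mat fe(3, 3);
    const double We = membrane_force(X, x, muT, Dmi, fe);
    if (!std::isfinite(We)) { ok = false; break; }
    energy += We;
    for (int a = 0; a < 3; ++a)
      fint.subvec(3 * id(a), 3 * id(a) + 2) += fe.col(a);

    if (want_tangent) {
      // finite-difference tangent of the nodal forces (9 x 9)
      const double h = 1e-6;
      mat Ke(9, 9);
      mat fp(3, 3), fm(3, 3);
      for (int c = 0; c < 9; ++c) {
        mat xp = x, xm = x;
        xp(c % 3, c / 3) += h;
        xm(c % 3, c / 3) -= h;
        membrane_force(X, xp, muT, Dmi, fp);
        membrane_force(X, xm, muT, Dmi, fm);
        const mat d = (fp - fm) / (2.0 * h);
        Ke.col(c) = vectorise(d);
      }
      Ke = 0.5 * (Ke + Ke.t());
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          for (int i = 0; i < 3; ++i)
            for (int k = 0; k < 3; ++k) {
              ti.push_back(3 * id(a) + i + 1);
              tj.push_back(3 * id(b) + k + 1);
              tx.push_back(Ke(3 * a + i, 3 * b + k));
            }
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("fint") = fint,
      Rcpp::Named("energy") = energy,
      Rcpp::Named("ok") = ok,
      Rcpp::Named("ki") = Rcpp::IntegerVector(ti.begin(), ti.end()),
      Rcpp::Named("kj") = Rcpp::IntegerVector(tj.begin(), tj.end()),
      Rcpp::Named("kx") = Rcpp::NumericVector(tx.begin(), tx.end()));
}

// sum triplet values into their cached sparse-matrix slots
// [[Rcpp::export]]
arma::vec accumulate_slots(const arma::vec& x, const arma::ivec& slot,
                           int nslot) {
  vec out(nslot, fill::zeros);
  for (uword k = 0; k < x.n_elem; ++k) out(slot(k) - 1) += x(k);
  return out;
}

// squared distance from point p to triangle (a, b, c) (Ericson, Real-Time
// Collision Detection, closest-point-on-triangle)
static double pt_tri_sq(const vec3& p, const vec3& a, const vec3& b,
                        const vec3& c) {
  const vec3 ab = b - a, ac = c - a, ap = p - a;
  const double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return dot(ap, ap);
  const vec3 bp = p - b;
  const double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return dot(bp, bp);
  const double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    const double v = d1 / (d1 - d3);
    const vec3 q = a + v * ab - p; return dot(q, q);
  }
  const vec3 cp = p - c;
  const double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return dot(cp, cp);
  const double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    const double w = d2 / (d2 - d6);
    const vec3 q = a + w * ac - p; return dot(q, q);
  }
  const double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    const vec3 q = b + w * (c - b) - p; return dot(q, q);
  }
  const double denom = 1.0 / (va + vb + vc);
  const double v = vb * denom, w = vc * denom;
  const vec3 q = a + v * ab + w * ac - p;
  return dot(q, q);
}

// Nearest point-to-triangle distances from each query point to a triangle
// mesh.  Triangles are visited in order of increasing distance between the
// query point and the triangle bounding-sphere centre, with early exit once
// no remaining triangle can beat the current best (simple spatial pruning;
// exact result, identical to the exhaustive scan).
// [[Rcpp::export]]
arma::vec point_triangle_distances(const arma::mat& pts,
                                   const arma::mat& verts,
                                   const arma::imat& tris) {
  const uword np = pts.n_rows, nt = tris.n_rows;
  // triangle bounding spheres
  mat centre(nt, 3);
  vec rad(nt);
  for (uword t = 0; t < nt; ++t) {
    const vec3 a = verts.row(tris(t, 0) - 1).t();
    const vec3 b = verts.row(tris(t, 1) - 1).t();
    const vec3 c = verts.row(tris(t, 2) - 1).t();
    const vec3 ce = (a + b + c) / 3.0;
    centre.row(t) = ce.t();
    rad(t) = std::sqrt(std::max({dot(a - ce, a - ce), dot(b - ce, b - ce),
                                 dot(c - ce, c - ce)}));
  }
  const double rmax = nt > 0 ? rad.max() : 0.0;
  vec out(np);
  for (uword i = 0; i < np; ++i) {
    const vec3 p = pts.row(i).t();
    // order triangles by centre distance
    vec cd(nt);
    for (uword t = 0; t < nt; ++t) {
      const vec3 d = centre.row(t).t() - p;
      cd(t) = std::sqrt(dot(d, d));
    }
    const uvec ord = sort_index(cd);
    double best = datum::inf;
    for (uword k = 0; k < nt; ++k) {
      const uword t = ord(k);
      // every remaining triangle has centre distance >= cd(t); none can
      // contain a point closer than cd(t) - rmax
      const double lower = cd(t) - rmax;
      if (lower > 0 && lower * lower >= best) break;
      const vec3 a = verts.row(tris(t, 0) - 1).t();
      const vec3 b = verts.row(tris(t, 1) - 1).t();
      const vec3 c = verts.row(tris(t, 2) - 1).t();
      best = std::min(best, pt_tri_sq(p, a, b, c));
    }
    out(i) = std::sqrt(best);
  }
  return out;
}
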