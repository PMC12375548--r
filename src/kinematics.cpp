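// Compiled kinematics core: forward kinematics over a tree of bodies joined
// by parameterized joints (parent offset -> ordered coordinate motions ->
// inverse child offset), marker positions, point-constraint residuals, and a
// damped least-squares (Levenberg-Marquardt) per-frame inverse-kinematics
// solver with warm-started trajectory solves.
//
// The compiled model is a plain R list assembled by compile_model() in R:
//   nbody, njoint            integers; body 0 is ground, body j+1 is the
//                            child of joint j (topological order enforced in R)
//   jparent                  integer vector, parent body index per joint (0-based)
//   jpar                     12 x njoint matrix: parent tx ty tz rx ry rz,
//                            child tx ty tz rx ry rz (mm / rad)
//   mot_joint, mot_type, mot_axis
//                            per elementary motion: owning joint, 0=rotation /
//                            1=translation, axis 0/1/2; motions sorted by joint
//   W (nmot x nq), b (nmot)  motion value = b + W q (identity rows for
//                            ordinary coordinates; coupler rows for coupled ones)
//   scales (3 x nbody)       body scale factors
//   marker_body, marker_loc  marker attachment body (0-based) and local position
//   con_a, con_b, con_pa, con_pb, con_sa, con_sb
//                            point constraints: bodies, local points, scale flags
//   qlo, qhi                 coordinate bounds
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct CModel {
  int nbody, njoint, nq, nmot, nm, nc;
  ivec jparent;
  mat jpar;          // 12 x njoint
  ivec mot_joint, mot_type, mot_axis;
  mat W;             // nmot x nq
  vec b;             // nmot
  mat scales;        // 3 x nbody
  ivec marker_body;
  mat marker_loc;    // 3 x nm
  ivec con_a, con_b, con_sa, con_sb;
  mat con_pa, con_pb; // 3 x nc
  vec qlo, qhi;
  std::vector<int> mot_start, mot_end; // motion index range per joint
  std::vector<std::vector<char>> body_has_joint; // ancestor-joint lookup
};

CModel parse_model(const Rcpp::List& L) {
  CModel M;
  M.nbody = Rcpp::as<int>(L["nbody"]);
  M.njoint = Rcpp::as<int>(L["njoint"]);
  M.nq = Rcpp::as<int>(L["nq"]);
  M.jparent = Rcpp::as<ivec>(L["jparent"]);
  M.jpar = Rcpp::as<mat>(L["jpar"]);
  M.mot_joint = Rcpp::as<ivec>(L["mot_joint"]);
  M.mot_type = Rcpp::as<ivec>(L["mot_type"]);
  M.mot_axis = Rcpp::as<ivec>(L["mot_axis"]);
  M.W = Rcpp::as<mat>(L["W"]);
  M.b = Rcpp::as<vec>(L["b"]);
  M.scales = Rcpp::as<mat>(L["scales"]);
  M.marker_body = Rcpp::as<ivec>(L["marker_body"]);
  M.marker_loc = Rcpp::as<mat>(L["marker_loc"]);
  M.con_a = Rcpp::as<ivec>(L["con_a"]);
  M.con_b = Rcpp::as<ivec>(L["con_b"]);
  M.con_pa = Rcpp::as<mat>(L["con_pa"]);
  M.con_pb = Rcpp::as<mat>(L["con_pb"]);
  M.con_sa = Rcpp::as<ivec>(L["con_sa"]);
  M.con_sb = Rcpp::as<ivec>(L["con_sb"]);
  M.qlo = Rcpp::as<vec>(L["qlo"]);
  M.qhi = Rcpp::as<vec>(L["qhi"]);
  M.nmot = (int)M.mot_joint.n_elem;
  M.nm = (int)M.marker_body.n_elem;
  M.nc = (int)M.con_a.n_elem;
  M.mot_start.assign(M.njoint, 0);
  M.mot_end.assign(M.njoint, 0);
  int k = 0;
  for (int j = 0; j < M.njoint; ++j) {
    M.mot_start[j] = k;
    while (k < M.nmot && M.mot_joint(k) == j) ++k;
    M.mot_end[j] = k;
  }
  // body b > 0 is the child of joint b-1; ancestors via the parent chain
  M.body_has_joint.assign(M.nbody, std::vector<char>(M.njoint, 0));
  for (int b = 1; b < M.nbody; ++b) {
    int par = (int)M.jparent(b - 1);
    M.body_has_joint[b] = M.body_has_joint[par];
    M.body_has_joint[b][b - 1] = 1;
  }
  return M;
}

inline mat33 rot_axis(int axis, double a) {
  double c = std::cos(a), s = std::sin(a);
  mat33 R(fill::eye);
  if (axis == 0) { R(1,1)=c; R(1,2)=-s; R(2,1)=s; R(2,2)=c; }
  else if (axis == 1) { R(0,0)=c; R(0,2)=s; R(2,0)=-s; R(2,2)=c; }
  else { R(0,0)=c; R(0,1)=-s; R(1,0)=s; R(1,1)=c; }
  return R;
}

// body-fixed X-Y-Z Euler sequence
inline mat33 euler_xyz(double a, double b, double c) {
  return rot_axis(0, a) * rot_axis(1, b) * rot_axis(2, c);
}

void fk(const CModel& M, const vec& q, cube& R, mat& p) {
  R.set_size(3, 3, M.nbody);
  p.set_size(3, M.nbody);
  R.slice(0).eye();
  p.col(0).zeros();
  for (int j = 0; j < M.njoint; ++j) {
    const double* jp = M.jpar.colptr(j);
    mat33 Rl = euler_xyz(jp[3], jp[4], jp[5]);
    vec3 pl = {jp[0], jp[1], jp[2]};
    for (int k = M.mot_start[j]; k < M.mot_end[j]; ++k) {
      double val = M.b(k) + dot(M.W.row(k), q);
      if (M.mot_type(k) == 0) {
        Rl = Rl * rot_axis((int)M.mot_axis(k), val);
      } else {
        vec3 e(fill::zeros);
        e((int)M.mot_axis(k)) = val;
        pl += Rl * e;
      }
    }
    mat33 Rc = euler_xyz(jp[9], jp[10], jp[11]);
    vec3 pc = {jp[6], jp[7], jp[8]};
    mat33 Rj = Rl * Rc.t();
    vec3 pj = pl - Rj * pc;
    int par = (int)M.jparent(j), child = j + 1;
    R.slice(child) = R.slice(par) * Rj;
    p.col(child) = R.slice(par) * pj + p.col(par);
  }
}

// forward kinematics that also records, for every elementary motion, the
// world-frame axis and application point of its intermediate frame (for
// analytic Jacobians)
void fk_axes(const CModel& M, const vec& q, cube& R, mat& p,
             mat& ax, mat& orig) {
  R.set_size(3, 3, M.nbody);
  p.set_size(3, M.nbody);
  R.slice(0).eye();
  p.col(0).zeros();
  ax.set_size(3, M.nmot);
  orig.set_size(3, M.nmot);
  for (int j = 0; j < M.njoint; ++j) {
    const double* jp = M.jpar.colptr(j);
    mat33 Rl = euler_xyz(jp[3], jp[4], jp[5]);
    vec3 pl = {jp[0], jp[1], jp[2]};
    int par = (int)M.jparent(j);
    for (int k = M.mot_start[j]; k < M.mot_end[j]; ++k) {
      double val = M.b(k) + dot(M.W.row(k), q);
      vec3 e(fill::zeros);
      e((int)M.mot_axis(k)) = 1.0;
      ax.col(k) = R.slice(par) * (Rl * e);
      orig.col(k) = R.slice(par) * pl + p.col(par);
      if (M.mot_type(k) == 0) {
        Rl = Rl * rot_axis((int)M.mot_axis(k), val);
      } else {
        pl += Rl * (val * e);
      }
    }
    mat33 Rc = euler_xyz(jp[9], jp[10], jp[11]);
    vec3 pc = {jp[6], jp[7], jp[8]};
    mat33 Rj = Rl * Rc.t();
    vec3 pj = pl - Rj * pc;
    int child = j + 1;
    R.slice(child) = R.slice(par) * Rj;
    p.col(child) = R.slice(par) * pj + p.col(par);
  }
}

inline vec3 point_world(const CModel& M, const cube& R, const mat& p,
                        int body, const vec3& loc, bool scaled) {
  vec3 l = loc;
  if (scaled) l %= M.scales.col(body);
  return R.slice(body) * l + p.col(body);
}

void marker_pos(const CModel& M, const cube& R, const mat& p, mat& out) {
  out.set_size(3, M.nm);
  for (int m = 0; m < M.nm; ++m)
    out.col(m) = point_world(M, R, p, (int)M.marker_body(m),
                             M.marker_loc.col(m), true);
}

// residual layout: 3 per marker (0 where target is NaN), then 3 per
// constraint scaled by closure_weight
void residuals(const CModel& M, const vec& q, const mat& target,
               double closure_weight, vec& r) {
  cube R; mat p;
  fk(M, q, R, p);
  r.set_size(3 * (M.nm + M.nc));
  for (int m = 0; m < M.nm; ++m) {
    if (std::isnan(target(0, m))) {
      r.subvec(3*m, 3*m+2).zeros();
    } else {
      vec3 pos = point_world(M, R, p, (int)M.marker_body(m),
                             M.marker_loc.col(m), true);
      r.subvec(3*m, 3*m+2) = pos - target.col(m);
    }
  }
  for (int c = 0; c < M.nc; ++c) {
    vec3 pa = point_world(M, R, p, (int)M.con_a(c), M.con_pa.col(c),
                          M.con_sa(c) != 0);
    vec3 pb = point_world(M, R, p, (int)M.con_b(c), M.con_pb.col(c),
                          M.con_sb(c) != 0);
    r.subvec(3*(M.nm+c), 3*(M.nm+c)+2) = closure_weight * (pa - pb);
  }
}

// residuals plus the analytic Jacobian d r / d q: a rotation motion
// contributes omega x (point - origin), a translation motion its axis, to
// every point on a body downstream of the motion's joint; the motion-value
// Jacobian is then mapped through W (motion value = b + W q)
void residuals_jac(const CModel& M, const vec& q, const mat& target,
                   double closure_weight, vec& r, mat& J) {
  cube R;
  mat p, ax, orig;
  fk_axes(M, q, R, p, ax, orig);
  int nr = 3 * (M.nm + M.nc);
  r.set_size(nr);
  mat Jv(nr, M.nmot, fill::zeros);
  auto point_cols = [&](int body, const vec3& pos, int row0, double w) {
    for (int k = 0; k < M.nmot; ++k) {
      if (!M.body_has_joint[body][(int)M.mot_joint(k)]) continue;
      vec3 col;
      if (M.mot_type(k) == 0) col = cross(ax.col(k), pos - orig.col(k));
      else col = ax.col(k);
      Jv(row0 + 0, k) += w * col(0);
      Jv(row0 + 1, k) += w * col(1);
      Jv(row0 + 2, k) += w * col(2);
    }
  };
  for (int m = 0; m < M.nm; ++m) {
    if (std::isnan(target(0, m))) {
      r.subvec(3*m, 3*m+2).zeros();
    } else {
      int b = (int)M.marker_body(m);
      vec3 pos = point_world(M, R, p, b, M.marker_loc.col(m), true);
      r.subvec(3*m, 3*m+2) = pos - target.col(m);
      point_cols(b, pos, 3*m, 1.0);
    }
  }
  for (int c = 0; c < M.nc; ++c) {
    int ba = (int)M.con_a(c), bb = (int)M.con_b(c);
    vec3 pa = point_world(M, R, p, ba, M.con_pa.col(c), M.con_sa(c) != 0);
    vec3 pb = point_world(M, R, p, bb, M.con_pb.col(c), M.con_sb(c) != 0);
    int row0 = 3 * (M.nm + c);
    r.subvec(row0, row0 + 2) = closure_weight * (pa - pb);
    point_cols(ba, pa, row0, closure_weight);
    point_cols(bb, pb, row0, -closure_weight);
  }
  J = Jv * M.W;
}

inline void clamp_q(const CModel& M, vec& q) {
  for (int i = 0; i < M.nq; ++i) {
    if (q(i) < M.qlo(i)) q(i) = M.qlo(i);
    if (q(i) > M.qhi(i)) q(i) = M.qhi(i);
  }
}

struct LMResult {
  vec q;
  double cost;
  int iters;
  std::vector<double> hist;
};

LMResult lm_solve(const CModel& M, const mat& target, const vec& q0,
                  const uvec& free, double closure_weight, int max_iter,
                  double ftol, double xtol, double gtol) {
  LMResult out;
  vec q = q0;
  clamp_q(M, q);
  vec r;
  residuals(M, q, target, closure_weight, r);
  double cost = dot(r, r);
  out.hist.push_back(cost);
  int nf = (int)free.n_elem;
  double lambda = 1e-6;  // near-Gauss-Newton start: warm starts dominate
  int it = 0;
  mat Jfull, J;
  vec r2;
  for (; it < max_iter; ++it) {
    if (cost < 1e-24) break;
    residuals_jac(M, q, target, closure_weight, r, Jfull);
    J = Jfull.cols(free);
    vec g = J.t() * r;
    if (norm(g, "inf") < gtol * std::max(1.0, cost)) break;
    mat H = J.t() * J;
    bool accepted = false;
    double step_norm = 0.0, improved = 0.0;
    for (int tries = 0; tries < 12; ++tries) {
      mat A = H;
      A.diag() += lambda * H.diag() + 1e-12;
      vec d;
      if (!solve(d, A, -g, solve_opts::no_approx)) { lambda *= 4.0; continue; }
      vec qn = q;
      for (int k = 0; k < nf; ++k) qn((int)free(k)) += d(k);
      clamp_q(M, qn);
      residuals(M, qn, target, closure_weight, r2);
      double costn = dot(r2, r2);
      if (costn <= cost) {
        step_norm = norm(d, 2);
        improved = cost - costn;
        q = qn; r = r2; cost = costn;
        out.hist.push_back(cost);
        lambda = std::max(lambda * 0.1, 1e-12);
        accepted = true;
        break;
      }
      lambda *= 10.0;
    }
    if (!accepted) break;
    if (improved <= ftol * std::max(cost, 1e-20) &&
        step_norm <= xtol * (norm(q, 2) + xtol)) { ++it; break; }
  }
  out.q = q;
  out.cost = cost;
  out.iters = it;
  return out;
}

void frame_metrics(const CModel& M, const vec& q, const mat& target,
                   vec& dist, vec& closure, vec& mres) {
  cube R; mat p;
  fk(M, q, R, p);
  dist.set_size(M.nm);
  mres.set_size(3 * M.nm);
  for (int m = 0; m < M.nm; ++m) {
    if (std::isnan(target(0, m))) {
      dist(m) = datum::nan;
      mres.subvec(3*m, 3*m+2).zeros();
    } else {
      vec3 d = point_world(M, R, p, (int)M.marker_body(m),
                           M.marker_loc.col(m), true) - target.col(m);
      dist(m) = norm(d, 2);
      mres.subvec(3*m, 3*m+2) = d;
    }
  }
  closure.set_size(M.nc);
  for (int c = 0; c < M.nc; ++c) {
    vec3 pa = point_world(M, R, p, (int)M.con_a(c), M.con_pa.col(c),
                          M.con_sa(c) != 0);
    vec3 pb = point_world(M, R, p, (int)M.con_b(c), M.con_pb.col(c),
                          M.con_sb(c) != 0);
    closure(c) = norm(pa - pb, 2);
  }
}

} // namespace

// [[Rcpp::export]]
Rcpp::List fk_cpp(Rcpp::List model, arma::vec q) {
  CModel M = parse_model(model);
  if ((int)q.n_elem != M.nq) Rcpp::stop("coordinate vector has wrong length");
  cube R; mat p;
  fk(M, q, R, p);
  return Rcpp::List::create(Rcpp::Named("rotations") = R,
                            Rcpp::Named("translations") = p);
}

// [[Rcpp::export]]
arma::mat marker_positions_cpp(Rcpp::List model, arma::vec q) {
  CModel M = parse_model(model);
  if ((int)q.n_elem != M.nq) Rcpp::stop("coordinate vector has wrong length");
  cube R; mat p;
  fk(M, q, R, p);
  mat out;
  marker_pos(M, R, p, out);
  return out;
}

// [[Rcpp::export]]
arma::vec constraint_residuals_cpp(Rcpp::List model, arma::vec q) {
  CModel M = parse_model(model);
  if ((int)q.n_elem != M.nq) Rcpp::stop("coordinate vector has wrong length");
  vec dist, closure, mres;
  mat target(3, M.nm);
  target.fill(datum::nan);
  frame_metrics(M, q, target, dist, closure, mres);
  return closure;
}

// [[Rcpp::export]]
Rcpp::List residual_jacobian_cpp(Rcpp::List model, arma::mat target,
                                 arma::vec q, double closure_weight) {
  CModel M = parse_model(model);
  vec r;
  mat J;
  residuals_jac(M, q, target, closure_weight, r, J);
  return Rcpp::List::create(Rcpp::Named("residuals") = r,
                            Rcpp::Named("jacobian") = J);
}

// [[Rcpp::export]]
Rcpp::List ik_frame_cpp(Rcpp::List model, arma::mat target, arma::vec q0,
                        arma::uvec free_idx, double closure_weight,
                        int max_iter, double ftol, double xtol, double gtol) {
  CModel M = parse_model(model);
  LMResult res = lm_solve(M, target, q0, free_idx, closure_weight, max_iter,
                          ftol, xtol, gtol);
  vec dist, closure, mres;
  frame_metrics(M, res.q, target, dist, closure, mres);
  return Rcpp::List::create(
      Rcpp::Named("q") = res.q,
      Rcpp::Named("cost") = res.cost,
      Rcpp::Named("iterations") = res.iters,
      Rcpp::Named("cost_history") = res.hist,
      Rcpp::Named("distances") = dist,
      Rcpp::Named("closure") = closure,
      Rcpp::Named("marker_residuals") = mres);
}

// Warm-started trajectory solve.  q_init: either a 1 x nq matrix (neutral
// start for frame 0, then warm start from the previous frame) or an
// nframes x nq matrix of per-frame initial guesses.
// [[Rcpp::export]]
Rcpp::List ik_traj_cpp(Rcpp::List model, arma::cube targets, arma::mat q_init,
                       arma::uvec free_idx, double closure_weight,
                       int max_iter, double ftol, double xtol, double gtol) {
  CModel M = parse_model(model);
  int nf = (int)targets.n_slices;
  bool per_frame_init = ((int)q_init.n_rows == nf && nf > 1);
  mat Q(nf, M.nq);
  mat D(nf, M.nm);
  mat C(nf, std::max(M.nc, 1));
  mat RES(nf, 3 * M.nm);
  ivec iters(nf);
  vec costs(nf);
  vec q_prev = q_init.row(0).t();
  for (int f = 0; f < nf; ++f) {
    vec q0 = per_frame_init ? vec(q_init.row(f).t()) : q_prev;
    LMResult res = lm_solve(M, targets.slice(f), q0, free_idx, closure_weight,
                            max_iter, ftol, xtol, gtol);
    Q.row(f) = res.q.t();
    costs(f) = res.cost;
    iters(f) = res.iters;
    q_prev = res.q;
  }
  // chained solves can lock into a poor local-minimum branch entered near a
  // singular pose; a backward refinement pass re-solves each frame from its
  // successor's solution and keeps whichever branch fits better
  if (!per_frame_init && nf > 1) {
    q_prev = Q.row(nf - 1).t();
    for (int f = nf - 2; f >= 0; --f) {
      LMResult res = lm_solve(M, targets.slice(f), q_prev, free_idx,
                              closure_weight, max_iter, ftol, xtol, gtol);
      if (res.cost < costs(f)) {
        Q.row(f) = res.q.t();
        costs(f) = res.cost;
      }
      q_prev = Q.row(f).t();
    }
  }
  for (int f = 0; f < nf; ++f) {
    vec dist, closure, mres;
    vec qf = Q.row(f).t();
    frame_metrics(M, qf, targets.slice(f), dist, closure, mres);
    D.row(f) = dist.t();
    if (M.nc > 0) C.row(f) = closure.t(); else C(f, 0) = 0.0;
    RES.row(f) = mres.t();
  }
  return Rcpp::List::create(
      Rcpp::Named("q") = Q,
      Rcpp::Named("distances") = D,
      Rcpp::Named("closure") = C,
      Rcpp::Named("marker_residuals") = RES,
      Rcpp::Named("iterations") = iters);
}
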