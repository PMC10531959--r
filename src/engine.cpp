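// Rigid-body pose scoring and multi-start simulated annealing.
//
// The target function is a CYANA-style sum of squared distance-bound
// violations over the restraint network, plus a soft-sphere clash penalty
// between ligand heavy atoms and receptor heavy atoms.  All randomness is
// driven by a private mt19937 stream so results are bit-reproducible for a
// given seed, independent of R's RNG state.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Instance {
  // ligand protons in the conformer (local) frame
  std::vector<double> px, py, pz;
  // restraint table: proton index (0-based), assigned methyl-carbon xyz, bounds
  std::vector<int> pidx;
  std::vector<double> sx, sy, sz, lo, up;
  // ligand heavy atoms (local frame) and receptor heavy atoms (fixed frame)
  std::vector<double> hx, hy, hz;
  std::vector<double> rx, ry, rz;
  double clash_weight, slack, rmin;
  // scratch for transformed proton coordinates (avoids per-eval allocation)
  mutable std::vector<double> wx, wy, wz;
};

inline void apply_pose(const double* R, const double* t,
                       double x, double y, double z,
                       double& ox, double& oy, double& oz) {
  ox = R[0] * x + R[1] * y + R[2] * z + t[0];
  oy = R[3] * x + R[4] * y + R[5] * z + t[1];
  oz = R[6] * x + R[7] * y + R[8] * z + t[2];
}

double eval_tf(const Instance& in, const double* R, const double* t) {
  double tf = 0.0;
  const size_t np = in.px.size();
  if (in.wx.size() != np) {
    in.wx.resize(np); in.wy.resize(np); in.wz.resize(np);
  }
  for (size_t i = 0; i < np; ++i)
    apply_pose(R, t, in.px[i], in.py[i], in.pz[i], in.wx[i], in.wy[i], in.wz[i]);
  const size_t nr = in.pidx.size();
  for (size_t r = 0; r < nr; ++r) {
    const int p = in.pidx[r];
    const double dx = in.wx[p] - in.sx[r];
    const double dy = in.wy[p] - in.sy[r];
    const double dz = in.wz[p] - in.sz[r];
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    double v = 0.0;
    const double over = d - in.up[r] - in.slack;
    const double under = in.lo[r] - in.slack - d;
    if (over > v) v = over;
    if (under > v) v = under;
    tf += v * v;
  }
  if (in.clash_weight > 0.0 && !in.rx.empty() && !in.hx.empty()) {
    const double rmin2 = in.rmin * in.rmin;
    double clash = 0.0;
    for (size_t i = 0; i < in.hx.size(); ++i) {
      double ax, ay, az;
      apply_pose(R, t, in.hx[i], in.hy[i], in.hz[i], ax, ay, az);
      for (size_t j = 0; j < in.rx.size(); ++j) {
        const double dx = ax - in.rx[j];
        const double dy = ay - in.ry[j];
        const double dz = az - in.rz[j];
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < rmin2) {
          const double v = in.rmin - std::sqrt(d2);
          clash += v * v;
        }
      }
    }
    tf += in.clash_weight * clash;
  }
  return tf;
}

// tf and its analytic gradient in (left rotation increment, translation).
double eval_tf_grad(const Instance& in, const double* R, const double* t,
                    double* gw, double* gt) {
  double tf = 0.0;
  for (int i = 0; i < 3; ++i) { gw[i] = 0.0; gt[i] = 0.0; }
  const size_t np = in.px.size();
  if (in.wx.size() != np) {
    in.wx.resize(np); in.wy.resize(np); in.wz.resize(np);
  }
  for (size_t i = 0; i < np; ++i)
    apply_pose(R, t, in.px[i], in.py[i], in.pz[i], in.wx[i], in.wy[i], in.wz[i]);
  const size_t nr = in.pidx.size();
  for (size_t r = 0; r < nr; ++r) {
    const int p = in.pidx[r];
    const double dx = in.wx[p] - in.sx[r];
    const double dy = in.wy[p] - in.sy[r];
    const double dz = in.wz[p] - in.sz[r];
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz) + 1e-12;
    double sgn = 0.0, v = 0.0;
    const double over = d - in.up[r] - in.slack;
    const double under = in.lo[r] - in.slack - d;
    if (over > 0.0) { v = over; sgn = 1.0; }
    else if (under > 0.0) { v = under; sgn = -1.0; }
    tf += v * v;
    if (v > 0.0) {
      const double c = 2.0 * v * sgn / d;
      const double gx = c * dx, gy = c * dy, gz = c * dz;
      gt[0] += gx; gt[1] += gy; gt[2] += gz;
      // q = world point minus translation = R x
      const double qx = in.wx[p] - t[0], qy = in.wy[p] - t[1],
                   qz = in.wz[p] - t[2];
      gw[0] += qy * gz - qz * gy;
      gw[1] += qz * gx - qx * gz;
      gw[2] += qx * gy - qy * gx;
    }
  }
  if (in.clash_weight > 0.0 && !in.rx.empty() && !in.hx.empty()) {
    const double rmin2 = in.rmin * in.rmin;
    for (size_t i = 0; i < in.hx.size(); ++i) {
      double ax, ay, az;
      apply_pose(R, t, in.hx[i], in.hy[i], in.hz[i], ax, ay, az);
      for (size_t j = 0; j < in.rx.size(); ++j) {
        const double dx = ax - in.rx[j];
        const double dy = ay - in.ry[j];
        const double dz = az - in.rz[j];
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < rmin2) {
          const double d = std::sqrt(d2) + 1e-12;
          const double v = in.rmin - d;
          tf += in.clash_weight * v * v;
          const double c = -2.0 * in.clash_weight * v / d;
          const double gx = c * dx, gy = c * dy, gz = c * dz;
          gt[0] += gx; gt[1] += gy; gt[2] += gz;
          const double qx = ax - t[0], qy = ay - t[1], qz = az - t[2];
          gw[0] += qy * gz - qz * gy;
          gw[1] += qz * gx - qx * gz;
          gw[2] += qx * gy - qy * gx;
        }
      }
    }
  }
  return tf;
}

Instance build_instance(const NumericMatrix& protons, const IntegerVector& pidx,
                        const NumericMatrix& rsites, const NumericVector& lower,
                        const NumericVector& upper, const NumericMatrix& lig_heavy,
                        const NumericMatrix& rec_heavy, double clash_weight,
                        double slack, double rmin) {
  Instance in;
  in.clash_weight = clash_weight;
  in.slack = slack;
  in.rmin = rmin;
  for (int i = 0; i < protons.nrow(); ++i) {
    in.px.push_back(protons(i, 0));
    in.py.push_back(protons(i, 1));
    in.pz.push_back(protons(i, 2));
  }
  for (int r = 0; r < rsites.nrow(); ++r) {
    in.pidx.push_back(pidx[r]);
    in.sx.push_back(rsites(r, 0));
    in.sy.push_back(rsites(r, 1));
    in.sz.push_back(rsites(r, 2));
    in.lo.push_back(lower[r]);
    in.up.push_back(upper[r]);
  }
  for (int i = 0; i < lig_heavy.nrow(); ++i) {
    in.hx.push_back(lig_heavy(i, 0));
    in.hy.push_back(lig_heavy(i, 1));
    in.hz.push_back(lig_heavy(i, 2));
  }
  for (int i = 0; i < rec_heavy.nrow(); ++i) {
    in.rx.push_back(rec_heavy(i, 0));
    in.ry.push_back(rec_heavy(i, 1));
    in.rz.push_back(rec_heavy(i, 2));
  }
  return in;
}

inline void quat_to_rot(double q0, double q1, double q2, double q3, double* R) {
  const double n = std::sqrt(q0 * q0 + q1 * q1 + q2 * q2 + q3 * q3);
  q0 /= n; q1 /= n; q2 /= n; q3 /= n;
  R[0] = 1 - 2 * (q2 * q2 + q3 * q3);
  R[1] = 2 * (q1 * q2 - q0 * q3);
  R[2] = 2 * (q1 * q3 + q0 * q2);
  R[3] = 2 * (q1 * q2 + q0 * q3);
  R[4] = 1 - 2 * (q1 * q1 + q3 * q3);
  R[5] = 2 * (q2 * q3 - q0 * q1);
  R[6] = 2 * (q1 * q3 - q0 * q2);
  R[7] = 2 * (q2 * q3 + q0 * q1);
  R[8] = 1 - 2 * (q1 * q1 + q2 * q2);
}

void random_rotation(std::mt19937& rng, double* R) {
  std::normal_distribution<double> nd(0.0, 1.0);
  quat_to_rot(nd(rng), nd(rng), nd(rng), nd(rng), R);
}

// rotation by `angle` about unit axis (ax, ay, az), Rodrigues form
void axis_angle_rot(double ax, double ay, double az, double angle, double* R) {
  const double c = std::cos(angle), s = std::sin(angle), C = 1 - c;
  R[0] = c + ax * ax * C;      R[1] = ax * ay * C - az * s; R[2] = ax * az * C + ay * s;
  R[3] = ay * ax * C + az * s; R[4] = c + ay * ay * C;      R[5] = ay * az * C - ax * s;
  R[6] = az * ax * C - ay * s; R[7] = az * ay * C + ax * s; R[8] = c + az * az * C;
}

inline void matmul3(const double* A, const double* B, double* C) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      C[3 * i + j] = A[3 * i] * B[j] + A[3 * i + 1] * B[3 + j] + A[3 * i + 2] * B[6 + j];
}

void random_point_in_ball(std::mt19937& rng, const double* center, double radius,
                          double* t) {
  std::uniform_real_distribution<double> ud(-1.0, 1.0);
  double x, y, z;
  do {
    x = ud(rng); y = ud(rng); z = ud(rng);
  } while (x * x + y * y + z * z > 1.0);
  t[0] = center[0] + radius * x;
  t[1] = center[1] + radius * y;
  t[2] = center[2] + radius * z;
}

inline void clamp_to_ball(const double* center, double radius, double* t) {
  const double dx = t[0] - center[0], dy = t[1] - center[1], dz = t[2] - center[2];
  const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (d > radius) {
    const double f = radius / d;
    t[0] = center[0] + dx * f;
    t[1] = center[1] + dy * f;
    t[2] = center[2] + dz * f;
  }
}

// Gradient descent with Armijo backtracking over the 6 rigid-body degrees
// of freedom; the hinge-squared target is C1, so descent converges to the
// local basin floor far more reliably than annealing alone.
double grad_refine(const Instance& in, double* R, double* t,
                   const double* ctr, double radius, int max_iter) {
  double gw[3], gt[3];
  double f = eval_tf_grad(in, R, t, gw, gt);
  double alpha = 0.05;
  for (int iter = 0; iter < max_iter; ++iter) {
    const double g2 = gw[0] * gw[0] + gw[1] * gw[1] + gw[2] * gw[2] +
                      gt[0] * gt[0] + gt[1] * gt[1] + gt[2] * gt[2];
    if (g2 < 1e-18 || f < 1e-14) break;
    bool accepted = false;
    for (int bt = 0; bt < 25; ++bt) {
      double Rn[9], tn[3], dR[9];
      const double an = std::sqrt(gw[0] * gw[0] + gw[1] * gw[1] +
                                  gw[2] * gw[2]);
      if (an > 1e-14) {
        axis_angle_rot(gw[0] / an, gw[1] / an, gw[2] / an, -alpha * an, dR);
        matmul3(dR, R, Rn);
      } else {
        std::copy(R, R + 9, Rn);
      }
      for (int i = 0; i < 3; ++i) tn[i] = t[i] - alpha * gt[i];
      clamp_to_ball(ctr, radius, tn);
      const double fn = eval_tf(in, Rn, tn);
      if (fn <= f - 1e-4 * alpha * g2) {
        std::copy(Rn, Rn + 9, R);
        std::copy(tn, tn + 3, t);
        f = eval_tf_grad(in, R, t, gw, gt);
        alpha = std::min(alpha * 1.6, 1.0);
        accepted = true;
        break;
      }
      alpha *= 0.4;
    }
    if (!accepted) break;
    if (alpha < 1e-12) break;
  }
  return f;
}

}  // namespace

// [[Rcpp::export]]
double tf_score_cpp(NumericMatrix rotation, NumericVector translation,
                    NumericMatrix protons, IntegerVector pidx,
                    NumericMatrix rsites, NumericVector lower, NumericVector upper,
                    NumericMatrix lig_heavy, NumericMatrix rec_heavy,
                    double clash_weight, double slack, double rmin) {
  Instance in = build_instance(protons, pidx, rsites, lower, upper, lig_heavy,
                               rec_heavy, clash_weight, slack, rmin);
  double R[9], t[3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) R[3 * i + j] = rotation(i, j);
  for (int i = 0; i < 3; ++i) t[i] = translation[i];
  return eval_tf(in, R, t);
}

// [[Rcpp::export]]
List sa_optimize_cpp(NumericMatrix protons, IntegerVector pidx,
                     NumericMatrix rsites, NumericVector lower, NumericVector upper,
                     NumericMatrix lig_heavy, NumericMatrix rec_heavy,
                     double clash_weight, double slack, double rmin,
                     NumericVector center, double radius,
                     int n_restarts, int sa_steps, double cooling, int seed,
                     NumericMatrix init_rot, NumericVector init_trans,
                     double abandon_tf, int abandon_after) {
  Instance in = build_instance(protons, pidx, rsites, lower, upper, lig_heavy,
                               rec_heavy, clash_weight, slack, rmin);
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::normal_distribution<double> nd(0.0, 1.0);
  std::uniform_real_distribution<double> u01(0.0, 1.0);
  const double ctr[3] = {center[0], center[1], center[2]};

  // initial temperature from the median tf of random poses
  std::vector<double> probe;
  for (int i = 0; i < 32; ++i) {
    double R[9], t[3];
    random_rotation(rng, R);
    random_point_in_ball(rng, ctr, radius, t);
    probe.push_back(eval_tf(in, R, t));
  }
  std::nth_element(probe.begin(), probe.begin() + probe.size() / 2, probe.end());
  const double T0 = std::max(probe[probe.size() / 2], 1e-2);

  const bool have_init = init_rot.nrow() == 3;
  double bestR[9], bestT[3];
  double best = R_PosInf;
  std::vector<double> rst_tf;
  std::vector<NumericMatrix> rst_R;
  std::vector<NumericVector> rst_t;

  for (int rs = 0; rs < n_restarts; ++rs) {
    if (rs >= abandon_after && best > abandon_tf) break;
    double R[9], t[3];
    if (rs == 0 && have_init) {
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) R[3 * i + j] = init_rot(i, j);
      for (int i = 0; i < 3; ++i) t[i] = init_trans[i];
      clamp_to_ball(ctr, radius, t);
    } else {
      random_rotation(rng, R);
      random_point_in_ball(rng, ctr, radius, t);
    }
    double cur = eval_tf(in, R, t);
    double lbR[9], lbT[3], lbest = cur;
    std::copy(R, R + 9, lbR);
    std::copy(t, t + 3, lbT);
    double T = T0;
    for (int step = 0; step < sa_steps; ++step) {
      double f = std::sqrt(T / T0);
      if (f < 0.05) f = 0.05;
      // rotation perturbation about a random axis
      double ax = nd(rng), ay = nd(rng), az = nd(rng);
      const double an = std::sqrt(ax * ax + ay * ay + az * az) + 1e-12;
      ax /= an; ay /= an; az /= an;
      const double angle = nd(rng) * 0.35 * f;
      double dR[9], Rn[9];
      axis_angle_rot(ax, ay, az, angle, dR);
      matmul3(dR, R, Rn);
      double tn[3] = {t[0] + nd(rng) * 0.35 * f,
                      t[1] + nd(rng) * 0.35 * f,
                      t[2] + nd(rng) * 0.35 * f};
      clamp_to_ball(ctr, radius, tn);
      const double cand = eval_tf(in, Rn, tn);
      const double delta = cand - cur;
      if (delta < 0.0 || u01(rng) < std::exp(-delta / T)) {
        std::copy(Rn, Rn + 9, R);
        std::copy(tn, tn + 3, t);
        cur = cand;
        if (cur < lbest) {
          lbest = cur;
          std::copy(R, R + 9, lbR);
          std::copy(t, t + 3, lbT);
        }
      }
      T *= cooling;
    }
    // gradient refinement of this restart's best pose
    lbest = grad_refine(in, lbR, lbT, ctr, radius, 200);
    if (lbest < best) {
      best = lbest;
      std::copy(lbR, lbR + 9, bestR);
      std::copy(lbT, lbT + 3, bestT);
    }
    NumericMatrix Rr(3, 3);
    NumericVector tr(3);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) Rr(i, j) = lbR[3 * i + j];
    for (int i = 0; i < 3; ++i) tr[i] = lbT[i];
    rst_tf.push_back(lbest);
    rst_R.push_back(Rr);
    rst_t.push_back(tr);
  }

  NumericMatrix Rout(3, 3);
  NumericVector tout(3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) Rout(i, j) = bestR[3 * i + j];
  for (int i = 0; i < 3; ++i) tout[i] = bestT[i];
  List rlist(rst_tf.size()), tlist(rst_tf.size());
  for (size_t i = 0; i < rst_tf.size(); ++i) {
    rlist[i] = rst_R[i];
    tlist[i] = rst_t[i];
  }
  return List::create(_["rotation"] = Rout, _["translation"] = tout,
                      _["tf"] = best,
                      _["restart_tf"] = NumericVector(rst_tf.begin(),
                                                      rst_tf.end()),
                      _["restart_rot"] = rlist,
                      _["restart_trans"] = tlist);
}
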