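// Rigid head-pose fit: Levenberg-Marquardt minimisation of pinhole
// reprojection error of a 3-D face template onto observed 2-D landmarks.
// Parameters: pitch, yaw, roll (radians; R = Rz(roll) * Ry(yaw) * Rx(pitch))
// and translation (tx, ty, tz) in template units. Camera: focal length f,
// principal point (cx, cy), image axes x right / y down.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void basis_mats(double pitch, double yaw, double roll,
                       mat33& R, mat33& dRp, mat33& dRy, mat33& dRr) {
  double cp = std::cos(pitch), sp = std::sin(pitch);
  double cy = std::cos(yaw),   sy = std::sin(yaw);
  double cr = std::cos(roll),  sr = std::sin(roll);
  mat33 Rx = {{1, 0, 0}, {0, cp, -sp}, {0, sp, cp}};
  mat33 Ry = {{cy, 0, sy}, {0, 1, 0}, {-sy, 0, cy}};
  mat33 Rz = {{cr, -sr, 0}, {sr, cr, 0}, {0, 0, 1}};
  mat33 dRx = {{0, 0, 0}, {0, -sp, -cp}, {0, cp, -sp}};
  mat33 dRy_ = {{-sy, 0, cy}, {0, 0, 0}, {-cy, 0, -sy}};
  mat33 dRz = {{-sr, -cr, 0}, {cr, -sr, 0}, {0, 0, 0}};
  R   = Rz * Ry * Rx;
  dRp = Rz * Ry * dRx;
  dRy = Rz * dRy_ * Rx;
  dRr = dRz * Ry * Rx;
}

// residuals (u_hat - u, v_hat - v); optionally the analytic Jacobian.
// Returns false if a point projects from behind the camera.
static bool eval(const vec& par, const mat& model, const vec& obs,
                 double f, double cx, double cy, vec& r, mat* J) {
  mat33 R, dRp, dRy, dRr;
  basis_mats(par(0), par(1), par(2), R, dRp, dRy, dRr);
  vec3 t = {par(3), par(4), par(5)};
  uword n = model.n_rows;
  for (uword i = 0; i < n; ++i) {
    vec3 p = model.row(i).t();
    vec3 pc = R * p + t;
    double z = pc(2);
    if (z <= 1e-6) return false;
    r(i)     = cx + f * pc(0) / z - obs(i);
    r(n + i) = cy + f * pc(1) / z - obs(n + i);
    if (J) {
      // d(u)/dq = f * (dX q * z - X * dZ q) / z^2, likewise for v
      for (int k = 0; k < 6; ++k) {
        vec3 dpc;
        if (k == 0) dpc = dRp * p;
        else if (k == 1) dpc = dRy * p;
        else if (k == 2) dpc = dRr * p;
        else { dpc.zeros(); dpc(k - 3) = 1.0; }
        (*J)(i, k)     = f * (dpc(0) * z - pc(0) * dpc(2)) / (z * z);
        (*J)(n + i, k) = f * (dpc(1) * z - pc(1) * dpc(2)) / (z * z);
      }
    }
  }
  return true;
}

static bool lm_fit(vec& par, const mat& model, const vec& obs,
                   double f, double cx, double cy, double& rms) {
  uword n = model.n_rows, m = 2 * n;
  vec r(m), r2(m);
  mat J(m, 6);
  if (!eval(par, model, obs, f, cx, cy, r, &J)) return false;
  double cost = dot(r, r), lambda = 1e-3;
  for (int iter = 0; iter < 50; ++iter) {
    mat JtJ = J.t() * J;
    vec g = J.t() * r;
    if (norm(g, "inf") < 1e-10 * (1.0 + cost)) break;
    bool stepped = false;
    for (int tries = 0; tries < 10; ++tries) {
      mat A = JtJ + lambda * diagmat(JtJ.diag() + 1e-12);
      vec step;
      if (!solve(step, A, g, solve_opts::likely_sympd + solve_opts::no_approx)) {
        lambda *= 10; continue;
      }
      vec cand = par - step;
      if (eval(cand, model, obs, f, cx, cy, r2, nullptr)) {
        double c2 = dot(r2, r2);
        if (c2 < cost) {
          par = cand;
          double rel = (cost - c2) / std::max(cost, 1e-30);
          cost = c2;
          lambda = std::max(lambda * 0.3, 1e-12);
          stepped = true;
          if (rel < 1e-12 || norm(step) < 1e-11) iter = 100;
          break;
        }
      }
      lambda *= 10;
    }
    if (!stepped) break;
    if (iter >= 100) break;
    if (!eval(par, model, obs, f, cx, cy, r, &J)) break;
  }
  rms = std::sqrt(cost / m);
  return true;
}

// Fits each frame, warm-starting from the previous frame's solution.
// pts: nframes x 2k matrix (x coords of the k correspondence points, then y).
// model: k x 3 template. init: length-6 starting parameter vector.
// Returns nframes x 7: pitch, yaw, roll (degrees, wrapped to (-180, 180]),
// tx, ty, tz, rms reprojection error; NaN row where the fit failed.
// [[Rcpp::export]]
arma::mat pose_fit_frames(const arma::mat& pts, const arma::mat& model,
                          double f, double cx, double cy,
                          const arma::vec& init) {
  uword nf = pts.n_rows;
  mat out(nf, 7);
  out.fill(datum::nan);
  vec par = init, warm = init;
  const double rad2deg = 180.0 / datum::pi;
  for (uword i = 0; i < nf; ++i) {
    vec obs = pts.row(i).t();
    if (!obs.is_finite()) continue;
    par = warm;
    double rms;
    bool ok = lm_fit(par, model, obs, f, cx, cy, rms);
    if (!ok) {                      // cold restart from the supplied init
      par = init;
      ok = lm_fit(par, model, obs, f, cx, cy, rms);
    }
    if (!ok || !par.is_finite()) continue;
    warm = par;
    for (int a = 0; a < 3; ++a) {
      double d = par(a) * rad2deg;
      double w = d - 360.0 * std::floor((d + 180.0) / 360.0);  // [-180, 180)
      out(i, a) = (w == -180.0) ? 180.0 : w;
    }
    out(i, 3) = par(3); out(i, 4) = par(4); out(i, 5) = par(5);
    out(i, 6) = rms;
  }
  return out;
}
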