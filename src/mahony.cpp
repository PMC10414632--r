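#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mahony complementary attitude filter (proportional-integral error
// feedback on gravity and, optionally, magnetic-field direction).
// Quaternions are scalar-first Hamilton, sensor -> Earth (ENU, z up,
// magnetic North along +y). Sequential per-sample loop, hence C++.
//
// acc  : n x 3 specific force, sensor frame (any units; direction used)
// gyro : n x 3 angular velocity, rad/s, sensor frame
// mag  : n x 3 normalized field direction, or a 0-row matrix (6-axis mode)
// q0   : initial quaternion
// Returns the per-sample quaternion track, the attitude-innovation norm
// (rad) and the number of zero-norm accelerometer samples skipped.
// [[Rcpp::export]]
List mahony_filter_cpp(NumericMatrix acc, NumericMatrix gyro,
                       NumericMatrix mag, double dt, double kp, double ki,
                       NumericVector q0, bool use_mag,
                       double integral_clamp = 0.1,
                       double integral_gate = 0.3,
                       int boost_n = 0, double kp_boost = 10.0) {
  int n = acc.nrow();
  NumericMatrix qout(n, 4);
  NumericVector err(n);
  int skipped = 0;
  double qw = q0[0], qx = q0[1], qy = q0[2], qz = q0[3];
  double ix = 0.0, iy = 0.0, iz = 0.0;  // integral feedback state

  for (int i = 0; i < n; ++i) {
    double ex = 0.0, ey = 0.0, ez = 0.0;

    double ax = acc(i, 0), ay = acc(i, 1), az = acc(i, 2);
    double an = std::sqrt(ax * ax + ay * ay + az * az);
    if (an > 0.0) {
      ax /= an; ay /= an; az /= an;
      // estimated gravity direction in the sensor frame: q* (0,0,1) q
      double vx = 2.0 * (qx * qz - qw * qy);
      double vy = 2.0 * (qw * qx + qy * qz);
      double vz = qw * qw - qx * qx - qy * qy + qz * qz;
      ex += ay * vz - az * vy;
      ey += az * vx - ax * vz;
      ez += ax * vy - ay * vx;
    } else {
      ++skipped;  // zero-norm accelerometer: gyro-only propagation
    }

    if (use_mag && mag.nrow() == n) {
      double mx = mag(i, 0), my = mag(i, 1), mz = mag(i, 2);
      double mn = std::sqrt(mx * mx + my * my + mz * mz);
      if (mn > 0.0) {
        mx /= mn; my /= mn; mz /= mn;
        // measured field in Earth frame: h = q (0,m) q*
        double ww = qw * qw, xx = qx * qx, yy = qy * qy, zz = qz * qz;
        double hx = mx * (ww + xx - yy - zz) +
                    2.0 * my * (qx * qy - qw * qz) +
                    2.0 * mz * (qx * qz + qw * qy);
        double hy = 2.0 * mx * (qx * qy + qw * qz) +
                    my * (ww - xx + yy - zz) +
                    2.0 * mz * (qy * qz - qw * qx);
        double hz = 2.0 * mx * (qx * qz - qw * qy) +
                    2.0 * my * (qy * qz + qw * qx) +
                    mz * (ww - xx - yy + zz);
        // reference field: horizontal part along North (+y), keep dip
        double bh = std::sqrt(hx * hx + hy * hy);
        // expected direction back in the sensor frame: q* (0,bh,hz) q
        double wx2 = 2.0 * (bh * (qx * qy + qw * qz) + hz * (qx * qz - qw * qy));
        double wy2 = bh * (ww - xx + yy - zz) + 2.0 * hz * (qy * qz + qw * qx);
        double wz2 = 2.0 * bh * (qy * qz - qw * qx) + hz * (ww - xx - yy + zz);
        ex += my * wz2 - mz * wy2;
        ey += mz * wx2 - mx * wz2;
        ez += mx * wy2 - my * wx2;
      }
    }

    err[i] = std::sqrt(ex * ex + ey * ey + ez * ez);

    // high-gain startup: pull the attitude onto the measurements quickly,
    // with the integrator frozen, before settling to the nominal gains
    bool boosting = i < boost_n;
    double kp_i = boosting ? kp * kp_boost : kp;

    // conditional integration (anti-windup): the integral term exists to
    // absorb slow gyro bias; freeze it during large attitude transients
    if (!boosting && ki > 0.0 && err[i] < integral_gate) {
      ix += ki * ex * dt; iy += ki * ey * dt; iz += ki * ez * dt;
      // anti-windup clamp per component
      if (ix > integral_clamp) ix = integral_clamp;
      if (ix < -integral_clamp) ix = -integral_clamp;
      if (iy > integral_clamp) iy = integral_clamp;
      if (iy < -integral_clamp) iy = -integral_clamp;
      if (iz > integral_clamp) iz = integral_clamp;
      if (iz < -integral_clamp) iz = -integral_clamp;
    }

    double wx = gyro(i, 0) + kp_i * ex + ix;
    double wy = gyro(i, 1) + kp_i * ey + iy;
    double wz = gyro(i, 2) + kp_i * ez + iz;

    // q <- q + 0.5 * q (0, w) dt, renormalized
    double dqw = 0.5 * (-qx * wx - qy * wy - qz * wz);
    double dqx = 0.5 * (qw * wx + qy * wz - qz * wy);
    double dqy = 0.5 * (qw * wy - qx * wz + qz * wx);
    double dqz = 0.5 * (qw * wz + qx * wy - qy * wx);
    qw += dqw * dt; qx += dqx * dt; qy += dqy * dt; qz += dqz * dt;
    double qn = std::sqrt(qw * qw + qx * qx + qy * qy + qz * qz);
    qw /= qn; qx /= qn; qy /= qn; qz /= qn;

    qout(i, 0) = qw; qout(i, 1) = qx; qout(i, 2) = qy; qout(i, 3) = qz;
  }

  return List::create(_["q"] = qout, _["innovation"] = err,
                      _["skipped"] = skipped);
}
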