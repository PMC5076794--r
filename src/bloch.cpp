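#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hard-pulse (piecewise-constant rotation) integration of the Bloch
// equation in the rotating frame of the pulse carrier, no relaxation.
//
// Conventions: the transverse magnetization M+ = Mx + i*My of a spin at
// offset f (Hz, spin minus carrier) acquires phase +2*pi*f*t under free
// precession, i.e. rotations are right-handed about the effective field
// axis (env_re, env_im, offset). The envelope is the dimensionless complex
// pulse shape (|env| <= 1); gamma_b1 is the peak RF amplitude in Hz.
//
// Returns a (n_offsets x 3) matrix of (Mx, My, Mz) immediately after the
// pulse, still in the carrier frame (no de-rotation).

// [[Rcpp::export]]
NumericMatrix bloch_profile_cpp(NumericVector env_re, NumericVector env_im,
                                double dt, double gamma_b1,
                                NumericVector offsets, NumericVector m0) {
  const int ns = env_re.size();
  const int no = offsets.size();
  const double twopi = 2.0 * M_PI;
  NumericMatrix out(no, 3);

  for (int k = 0; k < no; ++k) {
    double mx = m0[0], my = m0[1], mz = m0[2];
    const double wz = twopi * offsets[k];
    for (int j = 0; j < ns; ++j) {
      const double wx = twopi * gamma_b1 * env_re[j];
      const double wy = twopi * gamma_b1 * env_im[j];
      const double w2 = wx * wx + wy * wy + wz * wz;
      if (w2 == 0.0) continue;
      const double w = std::sqrt(w2);
      const double th = w * dt;
      const double nx = wx / w, ny = wy / w, nz = wz / w;
      const double c = std::cos(th), s = std::sin(th);
      const double dot = nx * mx + ny * my + nz * mz;
      const double omc = 1.0 - c;
      const double cx = ny * mz - nz * my;
      const double cy = nz * mx - nx * mz;
      const double cz = nx * my - ny * mx;
      const double rx = mx * c + cx * s + nx * dot * omc;
      const double ry = my * c + cy * s + ny * dot * omc;
      const double rz = mz * c + cz * s + nz * dot * omc;
      mx = rx; my = ry; mz = rz;
    }
    out(k, 0) = mx; out(k, 1) = my; out(k, 2) = mz;
  }
  return out;
}

// Stop-band deviation metric for one pulse at one peak amplitude:
// mean |Mxy(offset)|^2 over the offsets, starting from Mz = 1.
// Scaling to the 1 Hz-spacing convention is done by the R caller.

// [[Rcpp::export]]
double stopband_mxy2_cpp(NumericVector env_re, NumericVector env_im,
                         double dt, double gamma_b1, NumericVector offsets) {
  const int ns = env_re.size();
  const int no = offsets.size();
  const double twopi = 2.0 * M_PI;
  double acc = 0.0;

  for (int k = 0; k < no; ++k) {
    double mx = 0.0, my = 0.0, mz = 1.0;
    const double wz = twopi * offsets[k];
    for (int j = 0; j < ns; ++j) {
      const double wx = twopi * gamma_b1 * env_re[j];
      const double wy = twopi * gamma_b1 * env_im[j];
      const double w2 = wx * wx + wy * wy + wz * wz;
      if (w2 == 0.0) continue;
      const double w = std::sqrt(w2);
      const double th = w * dt;
      const double nx = wx / w, ny = wy / w, nz = wz / w;
      const double c = std::cos(th), s = std::sin(th);
      const double dot = nx * mx + ny * my + nz * mz;
      const double omc = 1.0 - c;
      const double cx = ny * mz - nz * my;
      const double cy = nz * mx - nx * mz;
      const double cz = nx * my - ny * mx;
      const double rx = mx * c + cx * s + nx * dot * omc;
      const double ry = my * c + cy * s + ny * dot * omc;
      const double rz = mz * c + cz * s + nz * dot * omc;
      mx = rx; my = ry; mz = rz;
    }
    acc += mx * mx + my * my;
  }
  return acc / no;
}
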