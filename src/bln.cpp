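// BLN coarse-grained potential: harmonic bonds, harmonic angles,
// secondary-structure-classed dihedral series, and (S1,S2)-scaled
// Lennard-Jones nonbonded terms for pairs separated by >= 3 bonds.
//
// Conventions (documented in ?bln_energy):
//   bonds:     kb * (r - sigma)^2            (no 1/2 factor; kb is the full prefactor)
//   angles:    (ktheta/2) * (theta - theta0)^2
//   dihedrals: A*(1 + cos phi) + B*(1 + cos 3 phi) + C*(1 + sin phi)
//   nonbonded: 4*eps*S1*[(sigma/r)^12 - S2*(sigma/r)^6], |i-j| >= 3
// Coincident nonbonded beads (r < 1e-8) make the energy non-finite.
#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct BLNPar {
  double kb, sigma, ktheta, theta0, eps;
  // dihedral coefficients by class (rows: class code 0..2; cols A,B,C)
  double dih[3][3];
  // pair scalings by bead class codes 0..2
  double S1[3][3], S2[3][3];
};

BLNPar unpack(const List& params) {
  BLNPar p;
  p.kb = as<double>(params["k_b"]);
  p.sigma = as<double>(params["sigma"]);
  p.ktheta = as<double>(params["k_theta"]);
  p.theta0 = as<double>(params["theta0"]);
  p.eps = as<double>(params["epsilon"]);
  NumericMatrix dt = params["dihedral_table"];
  NumericMatrix s1 = params["S1"], s2 = params["S2"];
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) {
      p.dih[i][j] = dt(i, j);
      p.S1[i][j] = s1(i, j);
      p.S2[i][j] = s2(i, j);
    }
  }
  return p;
}

inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
inline double vdot(const double* a, const double* b) {
  return a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
}
inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1]*b[2] - a[2]*b[1];
  out[1] = a[2]*b[0] - a[0]*b[2];
  out[2] = a[0]*b[1] - a[1]*b[0];
}
inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }

// Energy and (optionally) gradient dV/dr into grad (3N, row-major per bead).
double bln_eval(const double* x, int n, const IntegerVector& bead,
                const IntegerVector& dihcls, const BLNPar& p,
                double* grad) {
  const bool dograd = grad != nullptr;
  if (dograd) std::fill(grad, grad + 3 * n, 0.0);
  double e = 0.0;

  // bonds
  for (int i = 0; i + 1 < n; ++i) {
    double d[3]; vsub(x + 3*(i+1), x + 3*i, d);
    double r = vnorm(d);
    double dr = r - p.sigma;
    e += p.kb * dr * dr;
    if (dograd && r > 0) {
      double f = 2.0 * p.kb * dr / r;
      for (int k = 0; k < 3; ++k) {
        grad[3*(i+1)+k] += f * d[k];
        grad[3*i+k]     -= f * d[k];
      }
    }
  }

  // angles
  for (int i = 0; i + 2 < n; ++i) {
    const double *r1 = x + 3*i, *r2 = x + 3*(i+1), *r3 = x + 3*(i+2);
    double u[3], v[3];
    vsub(r1, r2, u); vsub(r3, r2, v);
    double nu = vnorm(u), nv = vnorm(v);
    double c = vdot(u, v) / (nu * nv);
    c = std::max(-1.0, std::min(1.0, c));
    double th = std::acos(c);
    double dth = th - p.theta0;
    e += 0.5 * p.ktheta * dth * dth;
    if (dograd) {
      double s = std::sqrt(std::max(1e-12, 1.0 - c * c));
      double pref = -p.ktheta * dth / s;  // dV/dcos = dV/dth * dth/dcos
      for (int k = 0; k < 3; ++k) {
        double dci = (v[k] / (nu * nv)) - c * u[k] / (nu * nu);
        double dck = (u[k] / (nu * nv)) - c * v[k] / (nv * nv);
        grad[3*i+k]     += pref * dci;
        grad[3*(i+2)+k] += pref * dck;
        grad[3*(i+1)+k] -= pref * (dci + dck);
      }
    }
  }

  // dihedrals
  for (int i = 0; i + 3 < n; ++i) {
    int cls = dihcls[i];
    double A = p.dih[cls][0], B = p.dih[cls][1], C = p.dih[cls][2];
    double b1[3], b2[3], b3[3];
    vsub(x + 3*(i+1), x + 3*i, b1);
    vsub(x + 3*(i+2), x + 3*(i+1), b2);
    vsub(x + 3*(i+3), x + 3*(i+2), b3);
    double n1[3], n2[3];
    vcross(b1, b2, n1); vcross(b2, b3, n2);
    double nb2 = vnorm(b2);
    double m1[3]; vcross(n1, b2, m1);
    double xphi = vdot(n1, n2);
    double yphi = vdot(m1, n2) / std::max(nb2, 1e-12);
    double phi = std::atan2(yphi, xphi);
    e += A * (1.0 + std::cos(phi)) + B * (1.0 + std::cos(3.0 * phi)) +
         C * (1.0 + std::sin(phi));
    if (dograd) {
      double dVdphi = -A * std::sin(phi) - 3.0 * B * std::sin(3.0 * phi) +
                      C * std::cos(phi);
      double n1sq = std::max(vdot(n1, n1), 1e-12);
      double n2sq = std::max(vdot(n2, n2), 1e-12);
      double nb2s = std::max(nb2, 1e-12);
      double c12 = vdot(b1, b2), c32 = vdot(b3, b2);
      for (int k = 0; k < 3; ++k) {
        // chain rule through the bond vectors b1, b2, b3
        double db1 = -nb2s / n1sq * n1[k];
        double db3 = -nb2s / n2sq * n2[k];
        double db2 = n1[k] * c12 / (n1sq * nb2s) +
                     n2[k] * c32 / (n2sq * nb2s);
        double g1 = -db1;
        double g2 = db1 - db2;
        double g3 = db2 - db3;
        double g4 = db3;
        grad[3*i+k]     += dVdphi * g1;
        grad[3*(i+1)+k] += dVdphi * g2;
        grad[3*(i+2)+k] += dVdphi * g3;
        grad[3*(i+3)+k] += dVdphi * g4;
      }
    }
  }

  // nonbonded LJ, |i-j| >= 3
  for (int i = 0; i < n; ++i) {
    for (int j = i + 3; j < n; ++j) {
      double d[3]; vsub(x + 3*j, x + 3*i, d);
      double r2 = vdot(d, d);
      if (r2 < 1e-16) return R_PosInf;  // singular geometry
      double s1 = p.S1[bead[i]][bead[j]], s2 = p.S2[bead[i]][bead[j]];
      double sr2 = p.sigma * p.sigma / r2;
      double sr6 = sr2 * sr2 * sr2;
      double sr12 = sr6 * sr6;
      e += 4.0 * p.eps * s1 * (sr12 - s2 * sr6);
      if (dograd) {
        // dV/dr2 * 2 gives the vector prefactor along d
        double dV = 4.0 * p.eps * s1 * (-12.0 * sr12 + 6.0 * s2 * sr6) / r2;
        for (int k = 0; k < 3; ++k) {
          grad[3*j+k] += dV * d[k];
          grad[3*i+k] -= dV * d[k];
        }
      }
    }
  }
  return e;
}

}  // namespace

// [[Rcpp::export(name = ".bln_energy_cpp")]]
double bln_energy_cpp(NumericMatrix coords, IntegerVector bead,
                      IntegerVector dihcls, List params) {
  int n = coords.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3*i+k] = coords(i, k);
  BLNPar p = unpack(params);
  return bln_eval(x.data(), n, bead, dihcls, p, nullptr);
}

// [[Rcpp::export(name = ".bln_gradient_cpp")]]
NumericMatrix bln_gradient_cpp(NumericMatrix coords, IntegerVector bead,
                               IntegerVector dihcls, List params) {
  int n = coords.nrow();
  std::vector<double> x(3 * n), g(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3*i+k] = coords(i, k);
  BLNPar p = unpack(params);
  double e = bln_eval(x.data(), n, bead, dihcls, p, g.data());
  NumericMatrix out(n, 3);
  if (!R_finite(e)) {
    std::fill(out.begin(), out.end(), NA_REAL);
  } else {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) out(i, k) = g[3*i+k];
  }
  return out;
}

// Velocity-Verlet NVT dynamics with a per-bead Andersen thermostat.
// Uses R's RNG so results are governed by set.seed().
// [[Rcpp::export(name = ".run_md_cpp")]]
List run_md_cpp(NumericMatrix coords, NumericMatrix vel, IntegerVector bead,
                IntegerVector dihcls, List params, double dt, int nsteps,
                double temperature, double collision_rate, int stride,
                double energy_bound) {
  int n = coords.nrow();
  std::vector<double> x(3 * n), v(3 * n), g(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      x[3*i+k] = coords(i, k);
      v[3*i+k] = vel(i, k);
    }
  BLNPar p = unpack(params);
  RNGScope scope;

  double e = bln_eval(x.data(), n, bead, dihcls, p, g.data());
  if (!R_finite(e)) stop("non-finite energy at MD start");
  int nframes = nsteps / stride;
  List frames(nframes);
  NumericVector epot(nframes), ekin(nframes);
  bool diverged = false;
  int fidx = 0;
  double sd = std::sqrt(temperature);  // m = 1, kB = 1 in reduced units

  for (int step = 1; step <= nsteps; ++step) {
    for (int q = 0; q < 3 * n; ++q) {
      v[q] -= 0.5 * dt * g[q];
      x[q] += dt * v[q];
    }
    e = bln_eval(x.data(), n, bead, dihcls, p, g.data());
    if (!R_finite(e) || std::fabs(e) > energy_bound) { diverged = true; break; }
    for (int q = 0; q < 3 * n; ++q) v[q] -= 0.5 * dt * g[q];
    // Andersen collisions: each bead resampled with prob collision_rate
    if (collision_rate > 0) {
      for (int i = 0; i < n; ++i) {
        if (unif_rand() < collision_rate) {
          v[3*i]   = norm_rand() * sd;
          v[3*i+1] = norm_rand() * sd;
          v[3*i+2] = norm_rand() * sd;
        }
      }
    }
    if (step % stride == 0 && fidx < nframes) {
      NumericMatrix fr(n, 3);
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) {
          fr(i, k) = x[3*i+k];
          ke += 0.5 * v[3*i+k] * v[3*i+k];
        }
      frames[fidx] = fr;
      epot[fidx] = e;
      ekin[fidx] = ke;
      ++fidx;
    }
  }

  NumericMatrix xout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      xout(i, k) = x[3*i+k];
      vout(i, k) = v[3*i+k];
    }
  return List::create(_["coords"] = xout, _["velocities"] = vout,
                      _["frames"] = frames, _["potential"] = epot,
                      _["kinetic"] = ekin, _["diverged"] = diverged,
                      _["n_frames"] = fidx);
}
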