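// Graph restraining potentials (GRP) used for contact-map back-mapping.
//
// New GRP: one-sided harmonics, shared force constant k, acting only when a
// constraint is violated: contacts pulled below r_con, non-contacts pushed
// above r_con, every nonbonded pair pushed above r_steric.
// Old (legacy) GRP: harmonic contact wells plus a bounded logistic repulsion.
// Both act on pairs separated by >= 3 bonds.
#include <Rcpp.h>
using namespace Rcpp;

namespace {
inline double dist3(const NumericMatrix& x, int i, int j, double* d) {
  d[0] = x(j,0) - x(i,0); d[1] = x(j,1) - x(i,1); d[2] = x(j,2) - x(i,2);
  return std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
}
}

// A margin tightens the enforced thresholds (contacts pulled below
// r_con - margin, non-contacts pushed above r_con + margin) so that the
// final relaxation under the physical potential alone does not let pairs
// drift back across the cutoff; margin = 0 is the plain one-sided form.
// The steric floor additionally covers next-nearest (|i-j| = 2) pairs:
// the harmonic angle term alone is too soft to stop them collapsing onto
// each other when the map restraints squeeze an angle shut.
// [[Rcpp::export(name = ".grp_new_cpp")]]
List grp_new_cpp(NumericMatrix coords, IntegerMatrix G, double k,
                 double r_con, double r_steric, bool want_grad,
                 double margin = 0.0) {
  int n = coords.nrow();
  double e = 0.0;
  NumericMatrix grad(want_grad ? n : 1, 3);
  double d[3];
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double r = dist3(coords, i, j, d);
      double dV = 0.0;  // dW/dr
      if (j == i + 2) {
        // steric floor only for next-nearest pairs
        if (r < r_steric) { double h = r_steric - r; e += 0.5*k*h*h; dV -= k*h; }
        if (want_grad && dV != 0.0 && r > 1e-12) {
          for (int q = 0; q < 3; ++q) {
            grad(j, q) += dV * d[q] / r;
            grad(i, q) -= dV * d[q] / r;
          }
        }
        continue;
      }
      if (G(i, j) == 1) {
        double rc = r_con - margin;
        if (r > rc) { double h = r - rc; e += 0.5*k*h*h; dV += k*h; }
      } else {
        double rc = r_con + margin;
        if (r < rc) { double h = rc - r; e += 0.5*k*h*h; dV -= k*h; }
      }
      if (r < r_steric) { double h = r_steric - r; e += 0.5*k*h*h; dV -= k*h; }
      if (want_grad && dV != 0.0 && r > 1e-12) {
        for (int q = 0; q < 3; ++q) {
          grad(j, q) += dV * d[q] / r;
          grad(i, q) -= dV * d[q] / r;
        }
      }
    }
  }
  if (want_grad) return List::create(_["energy"] = e, _["gradient"] = grad);
  return List::create(_["energy"] = e);
}

// [[Rcpp::export(name = ".grp_old_cpp")]]
List grp_old_cpp(NumericMatrix coords, IntegerMatrix G, double kappa1,
                 double kappa2, double gamma, double r_con, double r_max,
                 bool want_grad) {
  int n = coords.nrow();
  double e = 0.0;
  NumericMatrix grad(want_grad ? n : 1, 3);
  double d[3];
  for (int i = 0; i < n; ++i) {
    for (int j = i + 3; j < n; ++j) {
      double r = dist3(coords, i, j, d);
      double dV = 0.0;
      if (G(i, j) == 1) {
        double h = r - r_con;
        e += kappa1 * h * h;
        dV += 2.0 * kappa1 * h;
      } else {
        double z = (r_max * r_max - r * r) / gamma;
        double s = 1.0 / (1.0 + std::exp(-z));
        e += kappa2 * s;
        dV += kappa2 * s * (1.0 - s) * (-2.0 * r / gamma);
      }
      if (want_grad && r > 1e-12) {
        for (int q = 0; q < 3; ++q) {
          grad(j, q) += dV * d[q] / r;
          grad(i, q) -= dV * d[q] / r;
        }
      }
    }
  }
  if (want_grad) return List::create(_["energy"] = e, _["gradient"] = grad);
  return List::create(_["energy"] = e);
}

// Smallest pairwise distance between beads separated by >= min_sep bonds.
// [[Rcpp::export(name = ".min_pair_dist_cpp")]]
double min_pair_dist_cpp(NumericMatrix coords, int min_sep) {
  int n = coords.nrow();
  double best = R_PosInf, d[3];
  for (int i = 0; i < n; ++i)
    for (int j = i + min_sep; j < n; ++j) {
      double r = dist3(coords, i, j, d);
      if (r < best) best = r;
    }
  return best;
}

// Crankshaft Monte Carlo on the new GRP. One bead moves per step: interior
// beads rotate about the axis through their two chain neighbours; terminal
// beads pivot about the terminal bond axis. Moves creating a nonbonded pair
// below r_steric are rejected outright; otherwise Metropolis on the GRP
// energy change with a geometric temperature decay T0 -> T1.
// [[Rcpp::export(name = ".crankshaft_cpp")]]
List crankshaft_cpp(NumericMatrix coords, IntegerMatrix G, double k,
                    double r_con, double r_steric, int nsteps, double T0,
                    double T1, double margin = 0.0) {
  int n = coords.nrow();
  NumericMatrix x = clone(coords);
  RNGScope scope;

  // pair energy of bead b at position pos against all others
  auto bead_energy = [&](int b, const double* pos) {
    double e = 0.0;
    for (int j = 0; j < n; ++j) {
      if (std::abs(j - b) < 2) continue;
      double dx = x(j,0)-pos[0], dy = x(j,1)-pos[1], dz = x(j,2)-pos[2];
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (std::abs(j - b) == 2) {
        if (r < r_steric) { double h = r_steric - r; e += 0.5*k*h*h; }
        continue;
      }
      int gij = (b < j) ? G(b, j) : G(j, b);
      if (gij == 1) {
        double rc = r_con - margin;
        if (r > rc) { double h = r - rc; e += 0.5*k*h*h; }
      } else {
        double rc = r_con + margin;
        if (r < rc) { double h = rc - r; e += 0.5*k*h*h; }
      }
      if (r < r_steric) { double h = r_steric - r; e += 0.5*k*h*h; }
    }
    return e;
  };
  auto clash = [&](int b, const double* pos) {
    for (int j = 0; j < n; ++j) {
      if (std::abs(j - b) < 2) continue;
      double dx = x(j,0)-pos[0], dy = x(j,1)-pos[1], dz = x(j,2)-pos[2];
      if (dx*dx + dy*dy + dz*dz < r_steric * r_steric) return true;
    }
    return false;
  };

  double decay = (nsteps > 1) ? std::pow(T1 / T0, 1.0 / (nsteps - 1)) : 1.0;
  double T = T0;
  int accepted = 0;
  for (int step = 0; step < nsteps; ++step, T *= decay) {
    int b = (int)(unif_rand() * n);
    if (b >= n) b = n - 1;
    // rotation axis: through neighbours (interior) or along terminal bond
    int ia, ib;  // axis passes through bead ia with direction towards ib
    if (b == 0) { ia = 1; ib = 2; }
    else if (b == n - 1) { ia = n - 2; ib = n - 3; }
    else { ia = b - 1; ib = b + 1; }
    double ax = x(ib,0)-x(ia,0), ay = x(ib,1)-x(ia,1), az = x(ib,2)-x(ia,2);
    double an = std::sqrt(ax*ax + ay*ay + az*az);
    if (an < 1e-12) continue;
    ax /= an; ay /= an; az /= an;
    double px = x(b,0)-x(ia,0), py = x(b,1)-x(ia,1), pz = x(b,2)-x(ia,2);
    double ang = (unif_rand() * 2.0 - 1.0) * M_PI;
    double c = std::cos(ang), s = std::sin(ang);
    // Rodrigues rotation of p about unit axis a
    double adotp = ax*px + ay*py + az*pz;
    double cx = ay*pz - az*py, cy = az*px - ax*pz, cz = ax*py - ay*px;
    double npos[3] = {
      x(ia,0) + px*c + cx*s + ax*adotp*(1-c),
      x(ia,1) + py*c + cy*s + ay*adotp*(1-c),
      x(ia,2) + pz*c + cz*s + az*adotp*(1-c)
    };
    if (clash(b, npos)) continue;
    double oldpos[3] = { x(b,0), x(b,1), x(b,2) };
    double e_old = bead_energy(b, oldpos);
    double e_new = bead_energy(b, npos);
    double dE = e_new - e_old;
    bool accept = dE <= 0.0 ||
      (T > 0 && unif_rand() < std::exp(-dE / T));
    if (accept) {
      x(b,0) = npos[0]; x(b,1) = npos[1]; x(b,2) = npos[2];
      ++accepted;
    }
  }
  return List::create(_["coords"] = x, _["accepted"] = accepted,
                      _["n_steps"] = nsteps);
}

// Map-independent steric floor: pairs separated by >= 2 bonds pushed above
// r_steric. Zero (with zero gradient) for any structure without overlaps;
// used to keep the physical-stage minimization out of the angle-collapse
// channel in which next-nearest beads sit on top of each other.
// [[Rcpp::export(name = ".steric_floor_cpp")]]
List steric_floor_cpp(NumericMatrix coords, double k, double r_steric,
                      bool want_grad) {
  int n = coords.nrow();
  double e = 0.0;
  NumericMatrix grad(want_grad ? n : 1, 3);
  double d[3];
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double r = dist3(coords, i, j, d);
      if (r < r_steric) {
        double h = r_steric - r;
        e += 0.5 * k * h * h;
        if (want_grad && r > 1e-12) {
          double dV = -k * h;
          for (int q = 0; q < 3; ++q) {
            grad(j, q) += dV * d[q] / r;
            grad(i, q) -= dV * d[q] / r;
          }
        }
      }
    }
  }
  if (want_grad) return List::create(_["energy"] = e, _["gradient"] = grad);
  return List::create(_["energy"] = e);
}
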