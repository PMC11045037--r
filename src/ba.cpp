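#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Blahut-Arimoto fixed-point iteration for the Lagrangian form of the
// rate-distortion problem on a discrete source:
//
//   minimize over row-stochastic delta:  I(w; delta) + beta * E[d]
//
// Alternating updates from the uniform channel:
//   q(a)        <- sum_z w_z delta(a | z)
//   delta(a|z)  <- q(a) exp(-beta d(z, a)) / S_z,   S_z the row normalizer
//
// Implementation notes:
//  * The Boltzmann factors E(z, a) = exp(-beta (d(z, a) - min_a d(z, a)))
//    are precomputed once; subtracting the per-row minimum is the
//    log-sum-exp stabilization (the constant cancels in S_z). Entries that
//    underflow to zero stay zero.
//  * The whole iteration state is the marginal q (the channel is the
//    deterministic map delta = q E / S of q), so convergence is declared
//    when the L1 drift of q between sweeps falls below `tol`. Arms whose
//    marginal underflows to zero cannot revive (multiplicative update).
//  * `want_trace` records the Blahut-Arimoto objective
//    F_k = sum_z w_z (beta dmin_z - log S_z), which equals I + beta E[d]
//    evaluated at the current q and is nonincreasing across sweeps (the
//    classic alternating-minimization guarantee).
//  * The returned `rate` is the exact mutual information of the final
//    channel against its own marginal (skipped when `want_rate` is false,
//    e.g. in regret runs with diagnostics off, where it is pure overhead).
// [[Rcpp::export]]
List ba_solve(NumericVector w, NumericMatrix d, double beta, double tol,
              int max_iter, bool want_trace = true, bool want_rate = true) {
  const int Z = d.nrow();
  const int A = d.ncol();
  if (w.size() != Z) stop("weight/distortion dimension mismatch");

  // row minima and stabilized Boltzmann factors (column-major like d)
  std::vector<double> dmin(Z, R_PosInf);
  for (int a = 0; a < A; ++a)
    for (int z = 0; z < Z; ++z)
      if (d(z, a) < dmin[z]) dmin[z] = d(z, a);
  std::vector<double> E((size_t)Z * A);
  for (int a = 0; a < A; ++a) {
    const double* dc = &d(0, a);
    double* ec = &E[(size_t)a * Z];
    for (int z = 0; z < Z; ++z) ec[z] = std::exp(-beta * (dc[z] - dmin[z]));
  }

  std::vector<double> q(A, 1.0 / A), S(Z), winvS(Z);
  bool converged = false;
  int iter = 0;
  std::vector<double> trace;
  if (want_trace) trace.reserve(64);

  for (iter = 1; iter <= max_iter; ++iter) {
    // S_z = sum_a q_a E(z, a)
    std::fill(S.begin(), S.end(), 0.0);
    for (int a = 0; a < A; ++a) {
      const double qa = q[a];
      if (qa <= 0.0) continue;
      const double* ec = &E[(size_t)a * Z];
      for (int z = 0; z < Z; ++z) S[z] += qa * ec[z];
    }
    double F = 0.0;
    for (int z = 0; z < Z; ++z) {
      if (S[z] > 0.0) {
        winvS[z] = w[z] / S[z];
        if (want_trace) F += w[z] * (beta * dmin[z] - std::log(S[z]));
      } else {
        winvS[z] = 0.0;  // degenerate row: handled as point mass below
      }
    }
    if (want_trace) trace.push_back(F);
    // q'_a = q_a sum_z (w_z / S_z) E(z, a)
    double drift = 0.0;
    for (int a = 0; a < A; ++a) {
      double acc = 0.0;
      if (q[a] > 0.0) {
        const double* ec = &E[(size_t)a * Z];
        for (int z = 0; z < Z; ++z) acc += winvS[z] * ec[z];
        acc *= q[a];
      }
      drift += std::fabs(acc - q[a]);
      q[a] = acc;
    }
    // renormalize against accumulated degenerate-row mass loss
    double qs = 0.0;
    for (int a = 0; a < A; ++a) qs += q[a];
    if (qs > 0.0 && std::fabs(qs - 1.0) > 1e-15)
      for (int a = 0; a < A; ++a) q[a] /= qs;
    if (drift < tol) {
      converged = true;
      break;
    }
  }
  if (iter > max_iter) iter = max_iter;

  // final channel from the final q, then its exact marginal / rate / E[d]
  NumericMatrix delta(Z, A);
  std::fill(S.begin(), S.end(), 0.0);
  for (int a = 0; a < A; ++a) {
    const double qa = q[a];
    if (qa <= 0.0) continue;
    const double* ec = &E[(size_t)a * Z];
    for (int z = 0; z < Z; ++z) S[z] += qa * ec[z];
  }
  for (int z = 0; z < Z; ++z) {
    if (S[z] > 0.0) continue;
    // all surviving arms underflowed for this atom: put mass on its argmin
    int amin = 0;
    for (int a = 1; a < A; ++a)
      if (d(z, a) < d(z, amin)) amin = a;
    E[(size_t)amin * Z + z] = 1.0;
    if (q[amin] <= 0.0) q[amin] = 1e-300;
    S[z] = q[amin];
  }
  std::vector<double> marg(A, 0.0);
  double dist = 0.0;
  for (int a = 0; a < A; ++a) {
    const double qa = q[a];
    const double* ec = &E[(size_t)a * Z];
    const double* dc = &d(0, a);
    double* col = &delta(0, a);
    double m = 0.0, dd = 0.0;
    if (qa > 0.0) {
      for (int z = 0; z < Z; ++z) {
        const double p = qa * ec[z] / S[z];
        col[z] = p;
        m += w[z] * p;
        dd += w[z] * p * dc[z];
      }
    }
    marg[a] = m;
    dist += dd;
  }
  double rate = NA_REAL;
  if (want_rate) {
    rate = 0.0;
    for (int a = 0; a < A; ++a) {
      if (marg[a] <= 0.0) continue;
      const double lq = std::log(marg[a]);
      const double* col = &delta(0, a);
      for (int z = 0; z < Z; ++z) {
        const double p = col[z];
        if (p > 0.0) rate += w[z] * p * (std::log(p) - lq);
      }
    }
    if (rate < 0.0) rate = 0.0;
  }

  return List::create(
      _["channel"] = delta,
      _["marginal"] = NumericVector(marg.begin(), marg.end()),
      _["rate"] = rate, _["expected_distortion"] = dist,
      _["iterations"] = iter, _["converged"] = converged,
      _["lagrangian"] = NumericVector(trace.begin(), trace.end()));
}

// One full BLASTS decision for a conjugate posterior: draw Z fresh
// hypotheses from independent per-arm beliefs (family 0 = Beta(par1, par2),
// family 1 = Normal(par1, sd = par2)), build the linear or squared regret
// distortion (whose row minima are zero by construction, so exp(-beta d) is
// already stabilized), run the Blahut-Arimoto marginal iteration, and draw
// the two-stage action: a uniform atom index, then an action from that
// atom's channel row q_a E(z, a) / S_z. The channel is never materialized.
// All draws use R's RNG stream, so set.seed() reproduces decisions exactly.
// [[Rcpp::export]]
List ba_blasts_period(int family, NumericVector par1, NumericVector par2,
                      int z_atoms, double beta, bool squared, double tol,
                      int max_iter, bool want_rate) {
  const int Z = z_atoms;
  const int A = par1.size();
  std::vector<double> theta((size_t)Z * A);
  for (int a = 0; a < A; ++a) {
    double* col = &theta[(size_t)a * Z];
    if (family == 0) {
      for (int z = 0; z < Z; ++z) col[z] = R::rbeta(par1[a], par2[a]);
    } else {
      for (int z = 0; z < Z; ++z) col[z] = R::rnorm(par1[a], par2[a]);
    }
  }
  std::vector<double> rowmax(Z, R_NegInf);
  for (int a = 0; a < A; ++a) {
    const double* col = &theta[(size_t)a * Z];
    for (int z = 0; z < Z; ++z)
      if (col[z] > rowmax[z]) rowmax[z] = col[z];
  }
  // Boltzmann factors of the regret distortion (underflow guarded)
  std::vector<double> E((size_t)Z * A), d((size_t)Z * A);
  for (int a = 0; a < A; ++a) {
    const double* col = &theta[(size_t)a * Z];
    double* dc = &d[(size_t)a * Z];
    double* ec = &E[(size_t)a * Z];
    for (int z = 0; z < Z; ++z) {
      double g = rowmax[z] - col[z];
      if (squared) g *= g;
      dc[z] = g;
      const double x = -beta * g;
      ec[z] = (x < -745.0) ? 0.0 : std::exp(x);
    }
  }
  std::vector<double> q(A, 1.0 / A), S(Z);
  const double wz = 1.0 / Z;
  for (int iter = 1; iter <= max_iter; ++iter) {
    std::fill(S.begin(), S.end(), 0.0);
    for (int a = 0; a < A; ++a) {
      const double qa = q[a];
      if (qa <= 0.0) continue;
      const double* ec = &E[(size_t)a * Z];
      for (int z = 0; z < Z; ++z) S[z] += qa * ec[z];
    }
    for (int z = 0; z < Z; ++z) S[z] = (S[z] > 0.0) ? wz / S[z] : 0.0;
    double drift = 0.0, qs = 0.0;
    for (int a = 0; a < A; ++a) {
      double acc = 0.0;
      if (q[a] > 0.0) {
        const double* ec = &E[(size_t)a * Z];
        for (int z = 0; z < Z; ++z) acc += S[z] * ec[z];
        acc *= q[a];
      }
      drift += std::fabs(acc - q[a]);
      q[a] = acc;
      qs += acc;
    }
    if (qs > 0.0) for (int a = 0; a < A; ++a) q[a] /= qs;
    if (drift < tol) break;
  }
  // final row normalizers
  std::fill(S.begin(), S.end(), 0.0);
  for (int a = 0; a < A; ++a) {
    const double qa = q[a];
    if (qa <= 0.0) continue;
    const double* ec = &E[(size_t)a * Z];
    for (int z = 0; z < Z; ++z) S[z] += qa * ec[z];
  }
  double rate = NA_REAL;
  if (want_rate) {
    // marginal, then I = sum_z w sum_a delta (log delta - log marg)
    std::vector<double> marg(A, 0.0);
    for (int a = 0; a < A; ++a) {
      const double qa = q[a];
      if (qa <= 0.0) continue;
      const double* ec = &E[(size_t)a * Z];
      double m = 0.0;
      for (int z = 0; z < Z; ++z)
        if (S[z] > 0.0) m += ec[z] / S[z];
      marg[a] = wz * qa * m;
    }
    rate = 0.0;
    for (int a = 0; a < A; ++a) {
      if (marg[a] <= 0.0 || q[a] <= 0.0) continue;
      const double lq = std::log(marg[a]);
      const double* ec = &E[(size_t)a * Z];
      for (int z = 0; z < Z; ++z) {
        if (S[z] <= 0.0) continue;
        const double p = q[a] * ec[z] / S[z];
        if (p > 0.0) rate += wz * p * (std::log(p) - lq);
      }
    }
    if (rate < 0.0) rate = 0.0;
  }
  // two-stage draw: uniform atom, then its channel row
  int zi = (int)std::floor(unif_rand() * Z);
  if (zi >= Z) zi = Z - 1;
  int action = 0;
  if (S[zi] > 0.0) {
    const double u = unif_rand() * S[zi];
    double cum = 0.0;
    for (int a = 0; a < A; ++a) {
      cum += q[a] * E[(size_t)a * Z + zi];
      if (u <= cum) { action = a; break; }
      action = a;
    }
  } else {
    // every surviving arm underflowed for this atom: its regret minimizer
    for (int a = 1; a < A; ++a)
      if (d[(size_t)a * Z + zi] < d[(size_t)action * Z + zi]) action = a;
  }
  return List::create(_["action"] = action + 1, _["rate"] = rate);
}
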