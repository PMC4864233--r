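#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rigid-body overdamped Langevin engine with an exact COM-distance
// constraint. Units: nm, ps, amu, kJ/mol (so that kJ/mol = amu nm^2/ps^2
// and no unit conversion constants are needed beyond k_B).

static const double KB = 0.0083144621; // kJ/mol/K

static inline void quat_to_mat(const double q[4], double R[9]) {
  const double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z); R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y); R[7] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);
}

static inline void quat_mul(const double a[4], const double b[4], double out[4]) {
  out[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  out[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  out[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  out[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

// quaternion for rotation by vector phi (axis * angle)
static inline void quat_from_rotvec(const double phi[3], double q[4]) {
  const double a = std::sqrt(phi[0] * phi[0] + phi[1] * phi[1] + phi[2] * phi[2]);
  if (a < 1e-14) { q[0] = 1; q[1] = q[2] = q[3] = 0; return; }
  const double h = 0.5 * a, s = std::sin(h) / a;
  q[0] = std::cos(h); q[1] = phi[0] * s; q[2] = phi[1] * s; q[3] = phi[2] * s;
}

static inline void quat_renorm(double q[4]) {
  const double n = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  for (int k = 0; k < 4; ++k) q[k] /= n;
}

// radial test potentials, dU/dr
static inline double pot_dudr(int pot_type, const double* pp, double r) {
  if (pot_type == 1) { // harmonic: U = depth * ((r - r0)/w)^2
    return 2.0 * pp[0] * (r - pp[1]) / (pp[2] * pp[2]);
  }
  if (pot_type == 2) { // gaussian well: U = -depth * exp(-(r-r0)^2 / (2 w^2))
    const double d = r - pp[1], w2 = pp[2] * pp[2];
    return pp[0] * d / w2 * std::exp(-d * d / (2.0 * w2));
  }
  return 0.0;
}

// [[Rcpp::export]]
List cpp_simulate_window(NumericMatrix pos, NumericVector mass,
                         IntegerVector type, NumericVector charge,
                         IntegerVector group, double r_target, List par,
                         int pot_type, NumericVector pot_par) {
  const int n = pos.nrow();
  const double temperature = as<double>(par["temperature"]);
  const double dt = as<double>(par["dt"]);           // ps
  const int n_steps = as<int>(par["n_steps"]);
  const double equil_frac = as<double>(par["equil_frac"]);
  const double gamma = as<double>(par["friction"]);  // 1/ps
  NumericMatrix eps = as<NumericMatrix>(par["epsilon"]); // 4x4, P N C Q
  const double sigma = as<double>(par["sigma"]);
  const double cutoff = as<double>(par["cutoff"]);
  const double coul_pref = as<double>(par["coul_pref"]);
  const double debye = as<double>(par["debye"]);
  const double max_step = as<double>(par["max_step"]);
  const int check_every = as<int>(par["check_every"]);
  const double kT = KB * temperature;

  std::vector<int> ia, ib;
  for (int i = 0; i < n; ++i) (group[i] == 0 ? ia : ib).push_back(i);
  const int na = ia.size(), nb = ib.size();
  if (na == 0 || nb == 0) stop("both rigid groups must be non-empty");

  // masses, COMs, body-frame coordinates
  double Ma = 0, Mb = 0, comA[3] = {0, 0, 0}, comB[3] = {0, 0, 0};
  for (int i : ia) { Ma += mass[i]; for (int k = 0; k < 3; ++k) comA[k] += mass[i] * pos(i, k); }
  for (int i : ib) { Mb += mass[i]; for (int k = 0; k < 3; ++k) comB[k] += mass[i] * pos(i, k); }
  for (int k = 0; k < 3; ++k) { comA[k] /= Ma; comB[k] /= Mb; }
  std::vector<double> bA(3 * na), bB(3 * nb);
  double Ia = 0, Ib = 0; // scalar rotational inertia proxy: sum m |b|^2
  for (int s = 0; s < na; ++s)
    for (int k = 0; k < 3; ++k) { bA[3 * s + k] = pos(ia[s], k) - comA[k]; }
  for (int s = 0; s < nb; ++s)
    for (int k = 0; k < 3; ++k) { bB[3 * s + k] = pos(ib[s], k) - comB[k]; }
  for (int s = 0; s < na; ++s)
    Ia += mass[ia[s]] * (bA[3*s]*bA[3*s] + bA[3*s+1]*bA[3*s+1] + bA[3*s+2]*bA[3*s+2]);
  for (int s = 0; s < nb; ++s)
    Ib += mass[ib[s]] * (bB[3*s]*bB[3*s] + bB[3*s+1]*bB[3*s+1] + bB[3*s+2]*bB[3*s+2]);

  // reference intra-group pair distances for the rigidity diagnostic
  std::vector<double> refA, refB;
  for (int s = 0; s < na; ++s)
    for (int t = s + 1; t < na; ++t) {
      double d2 = 0;
      for (int k = 0; k < 3; ++k) { const double d = bA[3*s+k] - bA[3*t+k]; d2 += d * d; }
      refA.push_back(std::sqrt(d2));
    }
  for (int s = 0; s < nb; ++s)
    for (int t = s + 1; t < nb; ++t) {
      double d2 = 0;
      for (int k = 0; k < 3; ++k) { const double d = bB[3*s+k] - bB[3*t+k]; d2 += d * d; }
      refB.push_back(std::sqrt(d2));
    }

  const double mu = Ma * Mb / (Ma + Mb);
  const double sd_trA = std::sqrt(2.0 * kT * dt / (gamma * Ma));
  const double sd_trB = std::sqrt(2.0 * kT * dt / (gamma * Mb));
  const double sd_rotA = na > 1 ? std::sqrt(2.0 * kT * dt / (gamma * Ia)) : 0.0;
  const double sd_rotB = nb > 1 ? std::sqrt(2.0 * kT * dt / (gamma * Ib)) : 0.0;

  double qA[4] = {1, 0, 0, 0}, qB[4] = {1, 0, 0, 0};
  std::vector<double> pA(3 * na), pB(3 * nb);

  const int n_equil = (int)std::floor(equil_frac * n_steps);
  const int n_prod = n_steps - n_equil;
  if (n_prod < 1) stop("no production steps after equilibration");
  int n_blocks = n_prod >= 64 ? 64 : n_prod;
  const int block_len = n_prod / n_blocks;
  n_blocks = n_prod / block_len;
  std::vector<double> block_sum(n_blocks, 0.0);
  double sum_all = 0, sumsq_all = 0; long n_all = 0;

  double max_cviol = 0, max_rigid = 0;
  double RA[9], RB[9];

  for (int step = 0; step < n_steps; ++step) {
    quat_to_mat(qA, RA); quat_to_mat(qB, RB);
    for (int s = 0; s < na; ++s)
      for (int k = 0; k < 3; ++k)
        pA[3*s+k] = comA[k] + RA[3*k]*bA[3*s] + RA[3*k+1]*bA[3*s+1] + RA[3*k+2]*bA[3*s+2];
    for (int s = 0; s < nb; ++s)
      for (int k = 0; k < 3; ++k)
        pB[3*s+k] = comB[k] + RB[3*k]*bB[3*s] + RB[3*k+1]*bB[3*s+1] + RB[3*k+2]*bB[3*s+2];

    double FA[3] = {0, 0, 0}, FB[3] = {0, 0, 0};
    double TA[3] = {0, 0, 0}, TB[3] = {0, 0, 0};

    double dv[3];
    for (int k = 0; k < 3; ++k) dv[k] = comB[k] - comA[k];
    double dcom = std::sqrt(dv[0]*dv[0] + dv[1]*dv[1] + dv[2]*dv[2]);

    if (pot_type != 0) {
      const double dudr = pot_dudr(pot_type, pot_par.begin(), dcom);
      for (int k = 0; k < 3; ++k) {
        const double f = -dudr * dv[k] / dcom; // force on B
        FB[k] += f; FA[k] -= f;
      }
    } else {
      for (int s = 0; s < na; ++s) {
        const int i = ia[s];
        for (int t = 0; t < nb; ++t) {
          const int j = ib[t];
          double dr[3]; double d2 = 0;
          for (int k = 0; k < 3; ++k) { dr[k] = pB[3*t+k] - pA[3*s+k]; d2 += dr[k] * dr[k]; }
          const double d = std::sqrt(d2);
          double fmag = 0; // dU/dd (negative of radial force on j)
          if (d < cutoff) {
            const double e = eps(type[i], type[j]);
            const double sr6 = std::pow(sigma / d, 6);
            fmag += -24.0 * e * (2.0 * sr6 * sr6 - sr6) / d;
          }
          if (charge[i] != 0 && charge[j] != 0) {
            const double c = coul_pref * charge[i] * charge[j];
            fmag += -c * std::exp(-d / debye) * (1.0 / d2 + 1.0 / (debye * d));
          }
          if (fmag != 0) {
            for (int k = 0; k < 3; ++k) {
              const double f = -fmag * dr[k] / d; // force on j
              FB[k] += f; FA[k] -= f;
            }
            // torques accumulate below via bead lever arms
            double rjx = pB[3*t] - comB[0], rjy = pB[3*t+1] - comB[1], rjz = pB[3*t+2] - comB[2];
            double fx = -fmag * dr[0] / d, fy = -fmag * dr[1] / d, fz = -fmag * dr[2] / d;
            TB[0] += rjy * fz - rjz * fy;
            TB[1] += rjz * fx - rjx * fz;
            TB[2] += rjx * fy - rjy * fx;
            double rix = pA[3*s] - comA[0], riy = pA[3*s+1] - comA[1], riz = pA[3*s+2] - comA[2];
            TA[0] += riy * (-fz) - riz * (-fy);
            TA[1] += riz * (-fx) - rix * (-fz);
            TA[2] += rix * (-fy) - riy * (-fx);
          }
        }
      }
    }

    for (int k = 0; k < 3; ++k)
      if (!std::isfinite(FA[k]) || !std::isfinite(FB[k]))
        stop("non-finite force at step %d", step + 1);

    // translational update (drift clamped to max_step, noise unclamped)
    double drA[3], drB[3];
    for (int k = 0; k < 3; ++k) { drA[k] = FA[k] * dt / (gamma * Ma); drB[k] = FB[k] * dt / (gamma * Mb); }
    const double nA2 = std::sqrt(drA[0]*drA[0] + drA[1]*drA[1] + drA[2]*drA[2]);
    const double nB2 = std::sqrt(drB[0]*drB[0] + drB[1]*drB[1] + drB[2]*drB[2]);
    if (nA2 > max_step) for (int k = 0; k < 3; ++k) drA[k] *= max_step / nA2;
    if (nB2 > max_step) for (int k = 0; k < 3; ++k) drB[k] *= max_step / nB2;
    for (int k = 0; k < 3; ++k) {
      comA[k] += drA[k] + sd_trA * norm_rand();
      comB[k] += drB[k] + sd_trB * norm_rand();
    }

    // rotational update
    if (na > 1) {
      double phi[3], qrot[4], qnew[4];
      for (int k = 0; k < 3; ++k) phi[k] = TA[k] * dt / (gamma * Ia) + sd_rotA * norm_rand();
      quat_from_rotvec(phi, qrot); quat_mul(qrot, qA, qnew);
      for (int k = 0; k < 4; ++k) qA[k] = qnew[k];
      quat_renorm(qA);
    }
    if (nb > 1) {
      double phi[3], qrot[4], qnew[4];
      for (int k = 0; k < 3; ++k) phi[k] = TB[k] * dt / (gamma * Ib) + sd_rotB * norm_rand();
      quat_from_rotvec(phi, qrot); quat_mul(qrot, qB, qnew);
      for (int k = 0; k < 4; ++k) qB[k] = qnew[k];
      quat_renorm(qB);
    }

    // exact COM-distance constraint: mass-weighted projection back to r,
    // restoring displacement converted to force via the friction coefficient
    for (int k = 0; k < 3; ++k) dv[k] = comB[k] - comA[k];
    dcom = std::sqrt(dv[0]*dv[0] + dv[1]*dv[1] + dv[2]*dv[2]);
    if (!std::isfinite(dcom) || dcom < 1e-12)
      stop("degenerate COM separation at step %d", step + 1);
    const double delta = r_target - dcom;
    const double wB = Ma / (Ma + Mb), wA = Mb / (Ma + Mb);
    for (int k = 0; k < 3; ++k) {
      const double u = dv[k] / dcom;
      comB[k] += u * delta * wB;
      comA[k] -= u * delta * wA;
    }
    const double f_sample = gamma * mu * (dcom - r_target) / dt;

    if (step >= n_equil) {
      const int ip = step - n_equil;
      if (ip < n_blocks * block_len) {
        block_sum[ip / block_len] += f_sample;
        sum_all += f_sample; sumsq_all += f_sample * f_sample; ++n_all;
      }
    }

    if (check_every > 0 && (step % check_every == 0 || step == n_steps - 1)) {
      for (int k = 0; k < 3; ++k) dv[k] = comB[k] - comA[k];
      const double dchk = std::sqrt(dv[0]*dv[0] + dv[1]*dv[1] + dv[2]*dv[2]);
      max_cviol = std::max(max_cviol, std::fabs(dchk - r_target));
      quat_to_mat(qA, RA); quat_to_mat(qB, RB);
      int c = 0;
      for (int s = 0; s < na; ++s)
        for (int t = s + 1; t < na; ++t, ++c) {
          double d2 = 0;
          for (int k = 0; k < 3; ++k) {
            const double ds = RA[3*k]*(bA[3*s]-bA[3*t]) + RA[3*k+1]*(bA[3*s+1]-bA[3*t+1]) + RA[3*k+2]*(bA[3*s+2]-bA[3*t+2]);
            d2 += ds * ds;
          }
          max_rigid = std::max(max_rigid, std::fabs(std::sqrt(d2) - refA[c]));
        }
      c = 0;
      for (int s = 0; s < nb; ++s)
        for (int t = s + 1; t < nb; ++t, ++c) {
          double d2 = 0;
          for (int k = 0; k < 3; ++k) {
            const double ds = RB[3*k]*(bB[3*s]-bB[3*t]) + RB[3*k+1]*(bB[3*s+1]-bB[3*t+1]) + RB[3*k+2]*(bB[3*s+2]-bB[3*t+2]);
            d2 += ds * ds;
          }
          max_rigid = std::max(max_rigid, std::fabs(std::sqrt(d2) - refB[c]));
        }
    }
  }

  const int nu = n_blocks * block_len;
  const double mean_f = sum_all / nu;
  double se;
  if (n_blocks > 1) {
    double bs = 0;
    for (int b = 0; b < n_blocks; ++b) {
      const double bm = block_sum[b] / block_len - mean_f;
      bs += bm * bm;
    }
    se = std::sqrt(bs / (n_blocks - 1) / n_blocks);
  } else {
    const double v = std::max(0.0, sumsq_all / nu - mean_f * mean_f);
    se = std::sqrt(v / nu);
  }

  quat_to_mat(qA, RA); quat_to_mat(qB, RB);
  NumericMatrix fin(n, 3);
  for (int s = 0; s < na; ++s)
    for (int k = 0; k < 3; ++k)
      fin(ia[s], k) = comA[k] + RA[3*k]*bA[3*s] + RA[3*k+1]*bA[3*s+1] + RA[3*k+2]*bA[3*s+2];
  for (int s = 0; s < nb; ++s)
    for (int k = 0; k < 3; ++k)
      fin(ib[s], k) = comB[k] + RB[3*k]*bB[3*s] + RB[3*k+1]*bB[3*s+1] + RB[3*k+2]*bB[3*s+2];

  return List::create(_["mean_force"] = mean_f, _["stderr"] = se,
                      _["n_eff"] = n_blocks, _["n_samples"] = nu,
                      _["max_constraint_violation"] = max_cviol,
                      _["max_rigid_deviation"] = max_rigid,
                      _["final_positions"] = fin);
}
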