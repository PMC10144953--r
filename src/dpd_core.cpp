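// DPD engine core: pair/bond/angle forces, cell-list neighbour search,
// Groot-Warren modified velocity-Verlet, and Irving-Kirkwood virial
// accumulation (global tensor and slab-resolved diagonal).
//
// Units are reduced throughout: lengths in rc, energies in kBT, masses in m,
// time in tau = sqrt(m rc^2 / kBT).  All randomness goes through R's RNG so
// that set.seed() on the R side makes every run reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct FF {
  std::vector<double> a;  // ntypes x ntypes repulsion matrix (column-major)
  int ntypes;
  double gamma, sigma, rc, ks, rs, ktheta, theta0, mass;
};

FF parse_ff(const List& ffl) {
  FF ff;
  NumericMatrix a = ffl["a"];
  ff.ntypes = a.nrow();
  ff.a.assign(a.begin(), a.end());
  ff.gamma  = as<double>(ffl["gamma"]);
  ff.sigma  = as<double>(ffl["sigma"]);
  ff.rc     = as<double>(ffl["cutoff"]);
  ff.ks     = as<double>(ffl["bond_k"]);
  ff.rs     = as<double>(ffl["bond_r0"]);
  ff.ktheta = as<double>(ffl["angle_k"]);
  ff.theta0 = as<double>(ffl["angle_theta0"]);
  ff.mass   = as<double>(ffl["mass"]);
  return ff;
}

inline double minimg(double d, double box) {
  return d - box * std::round(d / box);
}

inline double wrap0(double z, double box) {
  z -= box * std::floor(z / box);
  if (z >= box) z -= box;  // guard the z == box fp edge
  if (z < 0.0) z = 0.0;
  return z;
}

// Distribute a per-pair virial contribution c[3] over slabs along z,
// splitting it in proportion to the length of the (unwrapped) ij segment
// inside each slab.  The slab grid has period nbins*binw == box, so slab
// boundaries coincide in wrapped and unwrapped coordinates.
inline void add_slab_segment(std::vector<double>& slab, int nbins, double binw,
                             double z0, double dz, const double c[3]) {
  double L = std::fabs(dz);
  if (L < 1e-12) {
    int k = (int)(wrap0(z0, nbins * binw) / binw);
    if (k >= nbins) k = nbins - 1;
    for (int a = 0; a < 3; ++a) slab[3 * k + a] += c[a];
    return;
  }
  double za = (dz >= 0.0) ? z0 : z0 + dz;
  double zb = za + L;
  long m0 = (long)std::floor(za / binw);
  long m1 = (long)std::floor((zb - 1e-12 * binw) / binw);
  for (long m = m0; m <= m1; ++m) {
    double lo = std::max(za, m * binw);
    double hi = std::min(zb, (m + 1) * binw);
    double frac = (hi - lo) / L;
    int k = (int)(((m % nbins) + nbins) % nbins);
    for (int a = 0; a < 3; ++a) slab[3 * k + a] += frac * c[a];
  }
}

struct EvalOut {
  double epot;
  double vir[9];      // W[a][b] = sum F_a d_b, row-major
  int n_overlap;
};

// One full force/energy/virial evaluation.  noise_mode: 0 none, 1 Gaussian,
// 2 uniform with unit variance.  Random and dissipative pair terms are
// optional so that post-hoc pressure analysis can be restricted to the
// deterministic (conservative + bonded) part.
void eval_system(const std::vector<double>& x, const std::vector<double>& v,
                 const std::vector<int>& type, int N,
                 const IntegerMatrix& bonds, const IntegerMatrix& angles,
                 const FF& ff, double box, double dt,
                 int noise_mode, bool with_diss,
                 std::vector<double>* f,
                 std::vector<double>* slab_vir, int nbins,
                 EvalOut& out) {
  const double rc2 = ff.rc * ff.rc;
  const double sqdt = std::sqrt(dt);
  const double SQRT12 = 3.4641016151377544;
  const int nt = ff.ntypes;
  const double binw = (nbins > 0) ? box / nbins : 0.0;

  out.epot = 0.0;
  out.n_overlap = 0;
  for (int a = 0; a < 9; ++a) out.vir[a] = 0.0;
  if (f) std::fill(f->begin(), f->end(), 0.0);
  if (slab_vir) std::fill(slab_vir->begin(), slab_vir->end(), 0.0);

  const bool want_vir = (slab_vir != 0) || true;  // global tensor is cheap

  auto do_pair = [&](int i, int j) {
    double dx = minimg(x[3 * i] - x[3 * j], box);
    double dy = minimg(x[3 * i + 1] - x[3 * j + 1], box);
    double dz = minimg(x[3 * i + 2] - x[3 * j + 2], box);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) return;
    double aij = ff.a[type[i] + nt * type[j]];
    double r = std::sqrt(r2);
    if (r < 1e-10) {
      // soft core: overlapping beads have an undefined direction; count and
      // skip the force, keep the (finite) energy
      out.epot += 0.5 * aij * ff.rc;
      ++out.n_overlap;
      return;
    }
    double w = 1.0 - r / ff.rc;
    out.epot += 0.5 * aij * ff.rc * w * w;
    double ex = dx / r, ey = dy / r, ez = dz / r;
    double fmag = aij * w;
    if (with_diss) {
      double rv = ex * (v[3 * i] - v[3 * j]) + ey * (v[3 * i + 1] - v[3 * j + 1]) +
                  ez * (v[3 * i + 2] - v[3 * j + 2]);
      fmag -= ff.gamma * w * w * rv;
    }
    if (noise_mode == 1) {
      fmag += ff.sigma * w * norm_rand() / sqdt;
    } else if (noise_mode == 2) {
      fmag += ff.sigma * w * SQRT12 * (unif_rand() - 0.5) / sqdt;
    }
    double Fx = fmag * ex, Fy = fmag * ey, Fz = fmag * ez;
    if (f) {
      (*f)[3 * i] += Fx;     (*f)[3 * i + 1] += Fy;     (*f)[3 * i + 2] += Fz;
      (*f)[3 * j] -= Fx;     (*f)[3 * j + 1] -= Fy;     (*f)[3 * j + 2] -= Fz;
    }
    if (want_vir) {
      out.vir[0] += Fx * dx; out.vir[1] += Fx * dy; out.vir[2] += Fx * dz;
      out.vir[3] += Fy * dx; out.vir[4] += Fy * dy; out.vir[5] += Fy * dz;
      out.vir[6] += Fz * dx; out.vir[7] += Fz * dy; out.vir[8] += Fz * dz;
    }
    if (slab_vir) {
      double c[3] = {Fx * dx, Fy * dy, Fz * dz};
      // segment runs from z_i to the minimum image of z_j, i.e. z_i - dz
      add_slab_segment(*slab_vir, nbins, binw, x[3 * i + 2], -dz, c);
    }
  };

  // --- non-bonded pairs: cell list when the box admits >= 3 cells/side ---
  int M = (int)std::floor(box / ff.rc);
  if (M < 3) {
    for (int i = 0; i < N - 1; ++i)
      for (int j = i + 1; j < N; ++j) do_pair(i, j);
  } else {
    double cell = box / M;
    int ncell = M * M * M;
    std::vector<int> head(ncell, -1), nxt(N, -1);
    auto cidx = [&](double z) {
      int k = (int)(wrap0(z, box) / cell);
      return (k >= M) ? M - 1 : k;
    };
    for (int i = 0; i < N; ++i) {
      int c = (cidx(x[3 * i]) * M + cidx(x[3 * i + 1])) * M + cidx(x[3 * i + 2]);
      nxt[i] = head[c];
      head[c] = i;
    }
    static const int off[13][3] = {
      {1, 0, 0}, {-1, 1, 0}, {0, 1, 0}, {1, 1, 0},
      {-1, -1, 1}, {0, -1, 1}, {1, -1, 1},
      {-1, 0, 1}, {0, 0, 1}, {1, 0, 1},
      {-1, 1, 1}, {0, 1, 1}, {1, 1, 1}};
    for (int cx = 0; cx < M; ++cx)
      for (int cy = 0; cy < M; ++cy)
        for (int cz = 0; cz < M; ++cz) {
          int c0 = (cx * M + cy) * M + cz;
          for (int i = head[c0]; i >= 0; i = nxt[i])
            for (int j = nxt[i]; j >= 0; j = nxt[j]) do_pair(i, j);
          for (int s = 0; s < 13; ++s) {
            int nx = (cx + off[s][0] + M) % M;
            int ny = (cy + off[s][1] + M) % M;
            int nz = (cz + off[s][2] + M) % M;
            int c1 = (nx * M + ny) * M + nz;
            for (int i = head[c0]; i >= 0; i = nxt[i])
              for (int j = head[c1]; j >= 0; j = nxt[j]) do_pair(i, j);
          }
        }
  }

  // --- bonds ---
  int nb = bonds.nrow();
  for (int b = 0; b < nb; ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = minimg(x[3 * i] - x[3 * j], box);
    double dy = minimg(x[3 * i + 1] - x[3 * j + 1], box);
    double dz = minimg(x[3 * i + 2] - x[3 * j + 2], box);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-10) stop("bonded beads %d and %d coincide", i + 1, j + 1);
    double fmag = ff.ks * (1.0 - r / ff.rs);
    out.epot += ff.ks * (r - ff.rs) * (r - ff.rs) / (2.0 * ff.rs);
    double Fx = fmag * dx / r, Fy = fmag * dy / r, Fz = fmag * dz / r;
    if (f) {
      (*f)[3 * i] += Fx;     (*f)[3 * i + 1] += Fy;     (*f)[3 * i + 2] += Fz;
      (*f)[3 * j] -= Fx;     (*f)[3 * j + 1] -= Fy;     (*f)[3 * j + 2] -= Fz;
    }
    out.vir[0] += Fx * dx; out.vir[1] += Fx * dy; out.vir[2] += Fx * dz;
    out.vir[3] += Fy * dx; out.vir[4] += Fy * dy; out.vir[5] += Fy * dz;
    out.vir[6] += Fz * dx; out.vir[7] += Fz * dy; out.vir[8] += Fz * dz;
    if (slab_vir) {
      double c[3] = {Fx * dx, Fy * dy, Fz * dz};
      add_slab_segment(*slab_vir, nbins, binw, x[3 * i + 2], -dz, c);
    }
  }

  // --- angles (harmonic in theta, j is the centre bead) ---
  int na = angles.nrow();
  for (int t = 0; t < na; ++t) {
    int i = angles(t, 0), j = angles(t, 1), k = angles(t, 2);
    double ux = minimg(x[3 * i] - x[3 * j], box);
    double uy = minimg(x[3 * i + 1] - x[3 * j + 1], box);
    double uz = minimg(x[3 * i + 2] - x[3 * j + 2], box);
    double vx = minimg(x[3 * k] - x[3 * j], box);
    double vy = minimg(x[3 * k + 1] - x[3 * j + 1], box);
    double vz = minimg(x[3 * k + 2] - x[3 * j + 2], box);
    double lu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double lv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (lu < 1e-10 || lv < 1e-10) stop("degenerate angle triple (zero bond vector)");
    double cth = (ux * vx + uy * vy + uz * vz) / (lu * lv);
    if (cth > 1.0) cth = 1.0;
    if (cth < -1.0) cth = -1.0;
    double th = std::acos(cth);
    double s = std::sqrt(1.0 - cth * cth);
    if (s < 1e-8) s = 1e-8;
    double A = 2.0 * ff.ktheta * (th - ff.theta0) / s;
    out.epot += ff.ktheta * (th - ff.theta0) * (th - ff.theta0);
    double Fix = A * (vx / (lu * lv) - cth * ux / (lu * lu));
    double Fiy = A * (vy / (lu * lv) - cth * uy / (lu * lu));
    double Fiz = A * (vz / (lu * lv) - cth * uz / (lu * lu));
    double Fkx = A * (ux / (lu * lv) - cth * vx / (lv * lv));
    double Fky = A * (uy / (lu * lv) - cth * vy / (lv * lv));
    double Fkz = A * (uz / (lu * lv) - cth * vz / (lv * lv));
    if (f) {
      (*f)[3 * i] += Fix; (*f)[3 * i + 1] += Fiy; (*f)[3 * i + 2] += Fiz;
      (*f)[3 * k] += Fkx; (*f)[3 * k + 1] += Fky; (*f)[3 * k + 2] += Fkz;
      (*f)[3 * j] -= (Fix + Fkx);
      (*f)[3 * j + 1] -= (Fiy + Fky);
      (*f)[3 * j + 2] -= (Fiz + Fkz);
    }
    // torque-free three-body virial decomposed over the two bond vectors
    out.vir[0] += Fix * ux + Fkx * vx;
    out.vir[1] += Fix * uy + Fkx * vy;
    out.vir[2] += Fix * uz + Fkx * vz;
    out.vir[3] += Fiy * ux + Fky * vx;
    out.vir[4] += Fiy * uy + Fky * vy;
    out.vir[5] += Fiy * uz + Fky * vz;
    out.vir[6] += Fiz * ux + Fkz * vx;
    out.vir[7] += Fiz * uy + Fkz * vy;
    out.vir[8] += Fiz * uz + Fkz * vz;
    if (slab_vir) {
      double c1[3] = {Fix * ux, Fiy * uy, Fiz * uz};
      double c2[3] = {Fkx * vx, Fky * vy, Fkz * vz};
      add_slab_segment(*slab_vir, nbins, binw, x[3 * j + 2], uz, c1);
      add_slab_segment(*slab_vir, nbins, binw, x[3 * j + 2], vz, c2);
    }
  }
}

void mat_to_vec(const NumericMatrix& m, std::vector<double>& v) {
  int n = m.nrow();
  v.resize(3 * n);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) v[3 * i + a] = m(i, a);
}

NumericMatrix vec_to_mat(const std::vector<double>& v, int n) {
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) m(i, a) = v[3 * i + a];
  return m;
}

IntegerMatrix zero_base(const IntegerMatrix& m) {
  IntegerMatrix out(m.nrow(), m.ncol());
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < m.ncol(); ++j) out(i, j) = m(i, j) - 1;
  return out;
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
List cpp_eval(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
              IntegerMatrix bonds, IntegerMatrix angles, List ffl,
              double box, double dt, int noise_mode, bool with_diss,
              int nbins) {
  FF ff = parse_ff(ffl);
  int N = pos.nrow();
  std::vector<double> x, v;
  mat_to_vec(pos, x);
  mat_to_vec(vel, v);
  std::vector<int> ty(N);
  for (int i = 0; i < N; ++i) ty[i] = type[i] - 1;
  IntegerMatrix b0 = zero_base(bonds), a0 = zero_base(angles);
  std::vector<double> f(3 * N);
  std::vector<double> slab;
  std::vector<double>* slabp = 0;
  if (nbins > 0) {
    slab.assign(3 * nbins, 0.0);
    slabp = &slab;
  }
  EvalOut out;
  eval_system(x, v, ty, N, b0, a0, ff, box, dt, noise_mode, with_diss,
              &f, slabp, nbins, out);
  NumericMatrix vir(3, 3);
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) vir(a, b) = out.vir[3 * a + b];
  List res = List::create(_["forces"] = vec_to_mat(f, N),
                          _["epot"] = out.epot,
                          _["virial"] = vir,
                          _["n_overlap"] = out.n_overlap);
  if (nbins > 0) {
    NumericMatrix sm(nbins, 3);
    for (int k = 0; k < nbins; ++k)
      for (int a = 0; a < 3; ++a) sm(k, a) = slab[3 * k + a];
    res["slab_virial"] = sm;
  }
  return res;
}

//' @noRd
// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
             IntegerMatrix bonds, IntegerMatrix angles, List ffl,
             double box, double dt, int n_steps, double lambda,
             int sample_every, int thermo_every, int noise_mode, double t0) {
  FF ff = parse_ff(ffl);
  int N = pos.nrow();
  std::vector<double> x, v;
  mat_to_vec(pos, x);
  mat_to_vec(vel, v);
  std::vector<int> ty(N);
  for (int i = 0; i < N; ++i) ty[i] = type[i] - 1;
  IntegerMatrix b0 = zero_base(bonds), a0 = zero_base(angles);

  std::vector<double> f(3 * N), fnew(3 * N), vtil(3 * N);
  EvalOut out;
  eval_system(x, v, ty, N, b0, a0, ff, box, dt, noise_mode, true,
              &f, 0, 0, out);
  double epot = out.epot;

  std::vector<int> e_step;
  std::vector<double> e_pot, e_kin;
  List samples;
  auto ekin_now = [&]() {
    double e = 0.0;
    for (int i = 0; i < 3 * N; ++i) e += v[i] * v[i];
    return 0.5 * ff.mass * e;
  };
  auto record_sample = [&](int step) {
    samples.push_back(List::create(_["pos"] = vec_to_mat(x, N),
                                   _["vel"] = vec_to_mat(v, N),
                                   _["time"] = t0 + step * dt));
  };
  e_step.push_back(0);
  e_pot.push_back(epot);
  e_kin.push_back(ekin_now());
  record_sample(0);

  const double im = 1.0 / ff.mass;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < 3 * N; ++i) {
      x[i] += dt * v[i] + 0.5 * dt * dt * f[i] * im;
      vtil[i] = v[i] + lambda * dt * f[i] * im;
    }
    for (int i = 0; i < N; ++i) {
      x[3 * i] = wrap0(x[3 * i], box);
      x[3 * i + 1] = wrap0(x[3 * i + 1], box);
      x[3 * i + 2] = wrap0(x[3 * i + 2], box);
    }
    eval_system(x, vtil, ty, N, b0, a0, ff, box, dt, noise_mode, true,
                &fnew, 0, 0, out);
    epot = out.epot;
    for (int i = 0; i < 3 * N; ++i) {
      v[i] += 0.5 * dt * (f[i] + fnew[i]) * im;
      f[i] = fnew[i];
    }
    for (int i = 0; i < 3 * N; ++i) {
      if (!std::isfinite(f[i]))
        stop("non-finite force at step %d: integration failed", step);
    }
    if (thermo_every > 0 && step % thermo_every == 0) {
      e_step.push_back(step);
      e_pot.push_back(epot);
      e_kin.push_back(ekin_now());
    }
    if (sample_every > 0 && step % sample_every == 0) record_sample(step);
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["pos"] = vec_to_mat(x, N), _["vel"] = vec_to_mat(v, N),
      _["forces"] = vec_to_mat(f, N),
      _["samples"] = samples,
      _["energy"] = List::create(_["step"] = wrap(e_step),
                                 _["epot"] = wrap(e_pot),
                                 _["ekin"] = wrap(e_kin)),
      _["time"] = t0 + n_steps * dt);
}
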