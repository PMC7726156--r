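// Monte Carlo engine for two like-charged bead-chain polyelectrolytes in salt.
//
// Units: lengths in sigma (bead/ion diameter), energies in kB*T.
// Non-bonded Hamiltonian: bare Coulomb (lB * zi * zj / r) under the
// minimum-image convention, plus WCA excluded volume
// 4*eps*(r^-12 - r^-6) + eps for r < 2^(1/6).
// Chain stiffness: discrete worm-like chain, U_b = (P/l0) * sum_i (1 - cos theta_i).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double WCA_CUT2 = 1.2599210498948732; // (2^(1/6))^2 = 2^(1/3)

struct Sys {
  std::vector<double> x, y, z;
  std::vector<int> q;    // valence in units of e
  std::vector<int> cid;  // chain label (0 = free ion)
  int n;
  double L, invL;
  bool periodic;
  double lB;   // Bjerrum length, sigma units
  double eps;  // WCA epsilon, kB*T
  double l0;   // bond length, sigma units
};

struct Chain {
  std::vector<int> idx;  // particle indices, 0-based, in chain order
  int mode;              // 0 parallel_rigid (static), 1 rotatable_rigid, 2 bendable
  double kbend;          // P / l0 (0 when bending inactive)
  int cord;              // ordinal (0-based) of the fixed central bead
  double ax, ay;         // confinement cylinder axis (x, y)
  double rconf2;         // squared confinement radius (Inf = none)
  double fsign;          // +1/-1: maps x force component to repulsive-positive
  int label;             // value in cid
};

static inline double mimg(double d, const Sys &S) {
  if (S.periodic) d -= S.L * std::round(d * S.invL);
  return d;
}

static inline double wrap_coord(double v, double L) {
  return v - L * std::floor(v / L + 0.5); // [-L/2, L/2)
}

// energy between a (possibly displaced) particle with charge qi at (xi,yi,zi)
// and particle j
static inline double pair_u(const Sys &S, double xi, double yi, double zi,
                            int qi, int j) {
  double dx = mimg(xi - S.x[j], S);
  double dy = mimg(yi - S.y[j], S);
  double dz = mimg(zi - S.z[j], S);
  double r2 = dx * dx + dy * dy + dz * dz;
  double u = 0.0;
  int qj = S.q[j];
  if (qi != 0 && qj != 0) u += S.lB * qi * qj / std::sqrt(r2);
  if (r2 < WCA_CUT2 && S.eps > 0.0) {
    double ir6 = 1.0 / (r2 * r2 * r2);
    u += 4.0 * S.eps * (ir6 * ir6 - ir6) + S.eps;
  }
  return u;
}

// x-component of the force on i from j (kB*T / sigma)
static inline double pair_fx(const Sys &S, int i, int j) {
  double dx = mimg(S.x[i] - S.x[j], S);
  double dy = mimg(S.y[i] - S.y[j], S);
  double dz = mimg(S.z[i] - S.z[j], S);
  double r2 = dx * dx + dy * dy + dz * dz;
  double coef = 0.0;
  if (S.q[i] != 0 && S.q[j] != 0)
    coef += S.lB * S.q[i] * S.q[j] / (r2 * std::sqrt(r2));
  if (r2 < WCA_CUT2 && S.eps > 0.0) {
    double ir2 = 1.0 / r2;
    double ir6 = ir2 * ir2 * ir2;
    coef += S.eps * (48.0 * ir6 * ir6 - 24.0 * ir6) * ir2;
  }
  return coef * dx;
}

static double bend_u(const Sys &S, const Chain &c) {
  if (c.mode != 2 || c.kbend <= 0.0) return 0.0;
  int N = (int)c.idx.size();
  double s = 0.0;
  for (int m = 1; m < N - 1; ++m) {
    int a = c.idx[m - 1], b = c.idx[m], d = c.idx[m + 1];
    double b1x = S.x[b] - S.x[a], b1y = S.y[b] - S.y[a], b1z = S.z[b] - S.z[a];
    double b2x = S.x[d] - S.x[b], b2y = S.y[d] - S.y[b], b2z = S.z[d] - S.z[b];
    double dot = b1x * b2x + b1y * b2y + b1z * b2z;
    double n1 = std::sqrt(b1x * b1x + b1y * b1y + b1z * b1z);
    double n2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
    s += 1.0 - dot / (n1 * n2);
  }
  return c.kbend * s;
}

static Sys make_sys(NumericMatrix pos, IntegerVector valence,
                    IntegerVector chain_id, double L, bool periodic,
                    double lB, double eps, double l0) {
  Sys S;
  S.n = pos.nrow();
  S.x.resize(S.n); S.y.resize(S.n); S.z.resize(S.n);
  S.q.resize(S.n); S.cid.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    S.x[i] = pos(i, 0); S.y[i] = pos(i, 1); S.z[i] = pos(i, 2);
    S.q[i] = valence[i];
    S.cid[i] = (chain_id.size() == S.n) ? chain_id[i] : 0;
  }
  S.L = L; S.invL = 1.0 / L; S.periodic = periodic;
  S.lB = lB; S.eps = eps; S.l0 = l0;
  return S;
}

static std::vector<Chain> make_chains(List chains) {
  std::vector<Chain> out;
  for (int k = 0; k < chains.size(); ++k) {
    List ch = chains[k];
    Chain c;
    IntegerVector idx = ch["idx"];
    c.idx.assign(idx.begin(), idx.end());
    for (size_t m = 0; m < c.idx.size(); ++m) c.idx[m] -= 1; // to 0-based
    c.mode = as<int>(ch["mode_code"]);
    c.kbend = as<double>(ch["kbend"]);
    c.cord = as<int>(ch["central_ord"]) - 1;
    c.ax = as<double>(ch["axis_x"]);
    c.ay = as<double>(ch["axis_y"]);
    double rc = as<double>(ch["confinement_radius"]);
    c.rconf2 = std::isfinite(rc) ? rc * rc : R_PosInf;
    c.fsign = as<double>(ch["fsign"]);
    c.label = as<int>(ch["label"]);
    out.push_back(c);
  }
  return out;
}

static bool ion_move(Sys &S, int i, double step) {
  double ox = S.x[i], oy = S.y[i], oz = S.z[i];
  double nx = ox + (2.0 * unif_rand() - 1.0) * step;
  double ny = oy + (2.0 * unif_rand() - 1.0) * step;
  double nz = oz + (2.0 * unif_rand() - 1.0) * step;
  if (S.periodic) {
    nx = wrap_coord(nx, S.L); ny = wrap_coord(ny, S.L); nz = wrap_coord(nz, S.L);
  }
  int qi = S.q[i];
  double du = 0.0;
  for (int j = 0; j < S.n; ++j) {
    if (j == i) continue;
    du += pair_u(S, nx, ny, nz, qi, j) - pair_u(S, ox, oy, oz, qi, j);
  }
  bool acc = (du <= 0.0) || (std::isfinite(du) && unif_rand() < std::exp(-du));
  if (acc) { S.x[i] = nx; S.y[i] = ny; S.z[i] = nz; }
  return acc;
}

static void rand_axis(double &ux, double &uy, double &uz) {
  double n2;
  do {
    ux = norm_rand(); uy = norm_rand(); uz = norm_rand();
    n2 = ux * ux + uy * uy + uz * uz;
  } while (n2 < 1e-12);
  double n = std::sqrt(n2);
  ux /= n; uy /= n; uz /= n;
}

// Rodrigues rotation of p about point c, axis u (unit), angle with cos/sin ct/st
static inline void rot_point(double px, double py, double pz,
                             double cx, double cy, double cz,
                             double ux, double uy, double uz,
                             double ct, double st,
                             double &rx, double &ry, double &rz) {
  double vx = px - cx, vy = py - cy, vz = pz - cz;
  double dot = ux * vx + uy * vy + uz * vz;
  double crx = uy * vz - uz * vy;
  double cry = uz * vx - ux * vz;
  double crz = ux * vy - uy * vx;
  rx = cx + vx * ct + crx * st + ux * dot * (1.0 - ct);
  ry = cy + vy * ct + cry * st + uy * dot * (1.0 - ct);
  rz = cz + vz * ct + crz * st + uz * dot * (1.0 - ct);
}

// One pivot / rigid-rotation attempt on chain c. Bond lengths are preserved
// exactly: rotatable chains are rebuilt from a rotated unit direction, bendable
// chains rotate one arm rigidly about the pivot bead. Rejected outright if any
// moved bead leaves the confinement cylinder.
static bool pivot_move(Sys &S, const Chain &c, double maxang) {
  int N = (int)c.idx.size();
  if (c.mode == 0 || N < 2) return false;
  std::vector<int> mv;                 // moved ordinals
  std::vector<double> nxv, nyv, nzv;   // proposed positions

  double ux, uy, uz;
  rand_axis(ux, uy, uz);
  double ang = (2.0 * unif_rand() - 1.0) * maxang;
  double ct = std::cos(ang), st = std::sin(ang);

  if (c.mode == 1) {
    // rigid rotation about the fixed central bead: rotate the unit direction
    // and rebuild bead positions at exact multiples of l0
    int a = c.idx[0], b = c.idx[N - 1];
    double dx = S.x[b] - S.x[a], dy = S.y[b] - S.y[a], dz = S.z[b] - S.z[a];
    double dn = std::sqrt(dx * dx + dy * dy + dz * dz);
    dx /= dn; dy /= dn; dz /= dn;
    double rx, ry, rz;
    rot_point(dx, dy, dz, 0, 0, 0, ux, uy, uz, ct, st, rx, ry, rz);
    double rn = std::sqrt(rx * rx + ry * ry + rz * rz);
    rx /= rn; ry /= rn; rz /= rn;
    int cb = c.idx[c.cord];
    double cx = S.x[cb], cy = S.y[cb], cz = S.z[cb];
    for (int o = 0; o < N; ++o) {
      if (o == c.cord) continue;
      double s = (o - c.cord) * S.l0;
      mv.push_back(o);
      nxv.push_back(cx + s * rx);
      nyv.push_back(cy + s * ry);
      nzv.push_back(cz + s * rz);
    }
  } else {
    // bendable: pivot bead among ordinals 1..N-2; rotate the arm on the side
    // away from the fixed central bead (either arm when pivoting at the centre)
    int p = 1 + (int)(unif_rand() * (N - 2));
    if (p > N - 2) p = N - 2;
    int lo, hi;
    if (p < c.cord) { lo = 0; hi = p - 1; }
    else if (p > c.cord) { lo = p + 1; hi = N - 1; }
    else {
      if (unif_rand() < 0.5) { lo = 0; hi = p - 1; }
      else { lo = p + 1; hi = N - 1; }
    }
    if (lo > hi) return false;
    int pb = c.idx[p];
    double cx = S.x[pb], cy = S.y[pb], cz = S.z[pb];
    for (int o = lo; o <= hi; ++o) {
      int i = c.idx[o];
      double rx, ry, rz;
      rot_point(S.x[i], S.y[i], S.z[i], cx, cy, cz, ux, uy, uz, ct, st,
                rx, ry, rz);
      mv.push_back(o);
      nxv.push_back(rx); nyv.push_back(ry); nzv.push_back(rz);
    }
  }

  // hard cylindrical confinement
  if (std::isfinite(c.rconf2)) {
    for (size_t m = 0; m < mv.size(); ++m) {
      double dx = nxv[m] - c.ax, dy = nyv[m] - c.ay;
      if (dx * dx + dy * dy > c.rconf2) return false;
    }
  }

  // pair-energy delta: only moved-vs-unmoved pairs change (arm is rigid)
  std::vector<char> moved(S.n, 0);
  for (size_t m = 0; m < mv.size(); ++m) moved[c.idx[mv[m]]] = 1;
  double du = 0.0;
  for (size_t m = 0; m < mv.size(); ++m) {
    int i = c.idx[mv[m]];
    for (int j = 0; j < S.n; ++j) {
      if (moved[j] || j == i) continue;
      du += pair_u(S, nxv[m], nyv[m], nzv[m], S.q[i], j)
          - pair_u(S, S.x[i], S.y[i], S.z[i], S.q[i], j);
    }
  }

  // bending delta (bendable chains only): apply, evaluate, restore on reject
  std::vector<double> oxv(mv.size()), oyv(mv.size()), ozv(mv.size());
  double b_old = bend_u(S, c);
  for (size_t m = 0; m < mv.size(); ++m) {
    int i = c.idx[mv[m]];
    oxv[m] = S.x[i]; oyv[m] = S.y[i]; ozv[m] = S.z[i];
    S.x[i] = nxv[m]; S.y[i] = nyv[m]; S.z[i] = nzv[m];
  }
  du += bend_u(S, c) - b_old;

  bool acc = (du <= 0.0) || (std::isfinite(du) && unif_rand() < std::exp(-du));
  if (!acc) {
    for (size_t m = 0; m < mv.size(); ++m) {
      int i = c.idx[mv[m]];
      S.x[i] = oxv[m]; S.y[i] = oyv[m]; S.z[i] = ozv[m];
    }
  }
  return acc;
}

// inter-chain force on chain `c` projected on x, repulsive counted positive
static double chain_force_sc(const Sys &S, const Chain &c) {
  double fx = 0.0;
  for (size_t m = 0; m < c.idx.size(); ++m) {
    int i = c.idx[m];
    for (int j = 0; j < S.n; ++j) {
      if (S.cid[j] == c.label) continue;
      fx += pair_fx(S, i, j);
    }
  }
  return c.fsign * fx;
}

static int confinement_violations(const Sys &S, const std::vector<Chain> &cs) {
  int v = 0;
  for (size_t k = 0; k < cs.size(); ++k) {
    const Chain &c = cs[k];
    if (!std::isfinite(c.rconf2)) continue;
    for (size_t m = 0; m < c.idx.size(); ++m) {
      int i = c.idx[m];
      double dx = S.x[i] - c.ax, dy = S.y[i] - c.ay;
      if (dx * dx + dy * dy > c.rconf2 * (1.0 + 1e-12)) ++v;
    }
  }
  return v;
}

static NumericMatrix sys_pos(const Sys &S) {
  NumericMatrix out(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    out(i, 0) = S.x[i]; out(i, 1) = S.y[i]; out(i, 2) = S.z[i];
  }
  return out;
}

// [[Rcpp::export]]
double cpp_total_pair_energy(NumericMatrix pos, IntegerVector valence,
                             double L, bool periodic, double lB, double eps) {
  IntegerVector cid(pos.nrow());
  Sys S = make_sys(pos, valence, cid, L, periodic, lB, eps, 1.0);
  long double u = 0.0;  // extended accumulator limits cancellation error
  for (int i = 0; i < S.n; ++i)
    for (int j = i + 1; j < S.n; ++j)
      u += pair_u(S, S.x[i], S.y[i], S.z[i], S.q[i], j);
  return (double)u;
}

// [[Rcpp::export]]
double cpp_bending_energy(NumericMatrix pos, double kbend) {
  int N = pos.nrow();
  double s = 0.0;
  for (int m = 1; m < N - 1; ++m) {
    double b1x = pos(m, 0) - pos(m - 1, 0);
    double b1y = pos(m, 1) - pos(m - 1, 1);
    double b1z = pos(m, 2) - pos(m - 1, 2);
    double b2x = pos(m + 1, 0) - pos(m, 0);
    double b2y = pos(m + 1, 1) - pos(m, 1);
    double b2z = pos(m + 1, 2) - pos(m, 2);
    double dot = b1x * b2x + b1y * b2y + b1z * b2z;
    double n1 = std::sqrt(b1x * b1x + b1y * b1y + b1z * b1z);
    double n2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
    s += 1.0 - dot / (n1 * n2);
  }
  return kbend * s;
}

// pair-interaction part of the energy change when particle idx (1-based) moves
// to new_pos; bending handled at the R level
// [[Rcpp::export]]
double cpp_move_delta_pair(NumericMatrix pos, IntegerVector valence,
                           double L, bool periodic, double lB, double eps,
                           int idx, NumericVector new_pos) {
  IntegerVector cid(pos.nrow());
  Sys S = make_sys(pos, valence, cid, L, periodic, lB, eps, 1.0);
  int i = idx - 1;
  long double du = 0.0;
  for (int j = 0; j < S.n; ++j) {
    if (j == i) continue;
    du += pair_u(S, new_pos[0], new_pos[1], new_pos[2], S.q[i], j)
        - pair_u(S, S.x[i], S.y[i], S.z[i], S.q[i], j);
  }
  return (double)du;
}

// net force vector (kB*T/sigma) on the particles of one chain from all
// particles with a different chain label
// [[Rcpp::export]]
NumericVector cpp_chain_force_vec(NumericMatrix pos, IntegerVector valence,
                                  IntegerVector chain_id, int label,
                                  double L, bool periodic,
                                  double lB, double eps) {
  Sys S = make_sys(pos, valence, chain_id, L, periodic, lB, eps, 1.0);
  double fx = 0, fy = 0, fz = 0;
  for (int i = 0; i < S.n; ++i) {
    if (S.cid[i] != label) continue;
    for (int j = 0; j < S.n; ++j) {
      if (S.cid[j] == label) continue;
      double dx = mimg(S.x[i] - S.x[j], S);
      double dy = mimg(S.y[i] - S.y[j], S);
      double dz = mimg(S.z[i] - S.z[j], S);
      double r2 = dx * dx + dy * dy + dz * dz;
      double coef = 0.0;
      if (S.q[i] != 0 && S.q[j] != 0)
        coef += S.lB * S.q[i] * S.q[j] / (r2 * std::sqrt(r2));
      if (r2 < WCA_CUT2 && S.eps > 0.0) {
        double ir2 = 1.0 / r2, ir6 = ir2 * ir2 * ir2;
        coef += S.eps * (48.0 * ir6 * ir6 - 24.0 * ir6) * ir2;
      }
      fx += coef * dx; fy += coef * dy; fz += coef * dz;
    }
  }
  return NumericVector::create(fx, fy, fz);
}

// minimum ion-to-chain centre distances: one row per requested particle,
// columns = min distance to chain-1 beads, min distance to chain-2 beads
// [[Rcpp::export]]
NumericMatrix cpp_min_chain_dists(NumericMatrix pos, IntegerVector ions,
                                  IntegerVector ch1, IntegerVector ch2,
                                  double L, bool periodic) {
  int ni = ions.size();
  NumericMatrix out(ni, 2);
  double invL = 1.0 / L;
  for (int a = 0; a < ni; ++a) {
    int i = ions[a] - 1;
    double best1 = R_PosInf, best2 = R_PosInf;
    for (int m = 0; m < ch1.size(); ++m) {
      int j = ch1[m] - 1;
      double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
             dz = pos(i, 2) - pos(j, 2);
      if (periodic) {
        dx -= L * std::round(dx * invL);
        dy -= L * std::round(dy * invL);
        dz -= L * std::round(dz * invL);
      }
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best1) best1 = r2;
    }
    for (int m = 0; m < ch2.size(); ++m) {
      int j = ch2[m] - 1;
      double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
             dz = pos(i, 2) - pos(j, 2);
      if (periodic) {
        dx -= L * std::round(dx * invL);
        dy -= L * std::round(dy * invL);
        dz -= L * std::round(dz * invL);
      }
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best2) best2 = r2;
    }
    out(a, 0) = std::sqrt(best1);
    out(a, 1) = std::sqrt(best2);
  }
  return out;
}

// single-move wrappers (share the engine's move code; used by the R-level
// ion_translation_move / pivot_move and their tests)

// [[Rcpp::export]]
List cpp_ion_move_one(NumericMatrix pos, IntegerVector valence,
                      double L, bool periodic, double lB, double eps,
                      int idx, double step) {
  IntegerVector cid(pos.nrow());
  Sys S = make_sys(pos, valence, cid, L, periodic, lB, eps, 1.0);
  bool acc = ion_move(S, idx - 1, step);
  return List::create(_["pos"] = sys_pos(S), _["accepted"] = acc);
}

// [[Rcpp::export]]
List cpp_pivot_move_one(NumericMatrix pos, IntegerVector valence,
                        IntegerVector chain_id, List chain,
                        double L, bool periodic, double lB, double eps,
                        double l0, double max_angle) {
  Sys S = make_sys(pos, valence, chain_id, L, periodic, lB, eps, l0);
  std::vector<Chain> cs = make_chains(List::create(chain));
  bool acc = pivot_move(S, cs[0], max_angle);
  return List::create(_["pos"] = sys_pos(S), _["accepted"] = acc);
}

// Main sweep loop. One sweep = one attempted translation per mobile ion plus
// `pivots_per_sweep` chain-move attempts spread over the movable chains.
// [[Rcpp::export]]
List cpp_run_sweeps(NumericMatrix pos, IntegerVector valence,
                    IntegerVector chain_id, List chains, IntegerVector ions,
                    double L, bool periodic, double lB, double eps, double l0,
                    int nsweeps, double ion_step, double pivot_max_angle,
                    int pivots_per_sweep, int force_every, int snap_every,
                    bool check_confinement) {
  Sys S = make_sys(pos, valence, chain_id, L, periodic, lB, eps, l0);
  std::vector<Chain> cs = make_chains(chains);

  std::vector<int> movable;
  for (size_t k = 0; k < cs.size(); ++k)
    if (cs[k].mode > 0 && cs[k].idx.size() > 1) movable.push_back((int)k);

  int n_ions = ions.size();
  std::vector<int> ion0(n_ions);
  for (int a = 0; a < n_ions; ++a) ion0[a] = ions[a] - 1;

  long ion_att = 0, ion_acc = 0, piv_att = 0, piv_acc = 0;
  int violations = 0;

  int nf = (force_every > 0 && cs.size() == 2) ? nsweeps / force_every : 0;
  NumericVector f1(nf), f2(nf);
  IntegerVector fsweep(nf);
  int fi = 0;

  int ns = (snap_every > 0) ? nsweeps / snap_every : 0;
  List snaps(ns);
  IntegerVector snap_sweep(ns);
  int si = 0;

  for (int s = 0; s < nsweeps; ++s) {
    for (int t = 0; t < n_ions; ++t) {
      int a = (int)(unif_rand() * n_ions);
      if (a >= n_ions) a = n_ions - 1;
      ++ion_att;
      if (ion_move(S, ion0[a], ion_step)) ++ion_acc;
    }
    if (!movable.empty()) {
      for (int t = 0; t < pivots_per_sweep; ++t) {
        int k = movable[(int)(unif_rand() * movable.size()) % movable.size()];
        ++piv_att;
        if (pivot_move(S, cs[k], pivot_max_angle)) ++piv_acc;
      }
    }
    if (check_confinement) violations += confinement_violations(S, cs);
    if (nf > 0 && (s + 1) % force_every == 0 && fi < nf) {
      f1[fi] = chain_force_sc(S, cs[0]);
      f2[fi] = chain_force_sc(S, cs[1]);
      fsweep[fi] = s + 1;
      ++fi;
    }
    if (ns > 0 && (s + 1) % snap_every == 0 && si < ns) {
      snaps[si] = sys_pos(S);
      snap_sweep[si] = s + 1;
      ++si;
    }
    if ((s + 1) % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["pos"] = sys_pos(S),
    _["f1"] = f1, _["f2"] = f2, _["force_sweep"] = fsweep,
    _["snapshots"] = snaps, _["snapshot_sweep"] = snap_sweep,
    _["ion_attempts"] = (double)ion_att, _["ion_accepts"] = (double)ion_acc,
    _["pivot_attempts"] = (double)piv_att, _["pivot_accepts"] = (double)piv_acc,
    _["confinement_violations"] = violations);
}
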