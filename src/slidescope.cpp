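// Coarse-grained force field (bonds, angles, dihedrals, 12-10 native
// contacts, 12th-power repulsion, Debye-Huckel electrostatics) and a BAOAB
// Langevin integrator. The DNA occupies the trailing bead indices and is
// static; minimum-image wrapping applies along Z only (period = DNA length),
// mirroring an infinite straight duplex.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct System {
  int n;          // total beads
  int n_mobile;   // protein beads (leading block); the rest are static DNA
  std::vector<double> x, y, z;
  std::vector<double> charge, radius;
  std::vector<int> group;  // chain index per bead (DNA beads: -1)
  std::vector<int> seq;    // position within chain (for bonded exclusions)
  std::vector<int> b_i, b_j;            std::vector<double> b0;
  std::vector<int> a_i, a_j, a_k;       std::vector<double> th0;
  std::vector<int> d_i, d_j, d_k, d_l;  std::vector<double> ph0;
  std::vector<int> c_i, c_j;            std::vector<double> aij;
  std::unordered_set<long long> contact_set;
  double zperiod;  // 0 = no periodicity
  // force-field constants
  double Kb, Ka, Kd, Kc, Kr, Kel, eps_r, kappa, Bk;
  double elec_cutoff;  // <= 0: none
  double rep_cutoff_factor;  // repulsion evaluated for r < factor * C_ij

  long long key(int i, int j) const {
    if (i > j) std::swap(i, j);
    return (long long)i * (long long)n + j;
  }
  bool excluded(int i, int j) const {  // bonded-neighbour exclusion
    return group[i] >= 0 && group[i] == group[j] &&
           std::abs(seq[i] - seq[j]) <= 3;
  }
  void dvec(int i, int j, double &dx, double &dy, double &dz) const {
    dx = x[i] - x[j]; dy = y[i] - y[j]; dz = z[i] - z[j];
    // minimum image along Z only for protein-DNA pairs
    if (zperiod > 0 && ((i >= n_mobile) != (j >= n_mobile))) {
      dz -= zperiod * std::round(dz / zperiod);
    }
  }
};

static System unpack(const List &sys, const NumericMatrix &pos) {
  System s;
  s.n = pos.nrow();
  s.n_mobile = as<int>(sys["n_mobile"]);
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
  }
  s.charge = as<std::vector<double>>(sys["charge"]);
  s.radius = as<std::vector<double>>(sys["radius"]);
  s.group  = as<std::vector<int>>(sys["group"]);
  s.seq    = as<std::vector<int>>(sys["seq"]);
  IntegerMatrix B = sys["bonds"], A = sys["angles"], D = sys["dihedrals"],
                C = sys["contacts"];
  s.b0  = as<std::vector<double>>(sys["b0"]);
  s.th0 = as<std::vector<double>>(sys["theta0"]);
  s.ph0 = as<std::vector<double>>(sys["phi0"]);
  s.aij = as<std::vector<double>>(sys["aij"]);
  for (int r = 0; r < B.nrow(); ++r) {
    s.b_i.push_back(B(r, 0)); s.b_j.push_back(B(r, 1));
  }
  for (int r = 0; r < A.nrow(); ++r) {
    s.a_i.push_back(A(r, 0)); s.a_j.push_back(A(r, 1));
    s.a_k.push_back(A(r, 2));
  }
  for (int r = 0; r < D.nrow(); ++r) {
    s.d_i.push_back(D(r, 0)); s.d_j.push_back(D(r, 1));
    s.d_k.push_back(D(r, 2)); s.d_l.push_back(D(r, 3));
  }
  for (int r = 0; r < C.nrow(); ++r) {
    s.c_i.push_back(C(r, 0)); s.c_j.push_back(C(r, 1));
    s.contact_set.insert(s.key(C(r, 0), C(r, 1)));
  }
  s.zperiod = as<double>(sys["zperiod"]);
  List p = sys["params"];
  s.Kb = as<double>(p["K_bonds"]);    s.Ka = as<double>(p["K_angles"]);
  s.Kd = as<double>(p["K_dihedrals"]); s.Kc = as<double>(p["K_contacts"]);
  s.Kr = as<double>(p["K_repulsion"]);
  s.Kel = as<double>(p["K_electrostatics"]);
  s.eps_r = as<double>(p["eps_r"]);
  s.kappa = as<double>(p["kappa"]); s.Bk = as<double>(p["Bkappa"]);
  s.elec_cutoff = as<double>(p["elec_cutoff"]);
  s.rep_cutoff_factor = as<double>(p["rep_cutoff_factor"]);
  return s;
}

struct Breakdown {
  double bonds = 0, angles = 0, dihedrals = 0, contacts = 0,
         repulsion = 0, electrostatics = 0;
  double total() const {
    return bonds + angles + dihedrals + contacts + repulsion + electrostatics;
  }
};

static inline void cross(const double *a, const double *b, double *out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// energy and (optionally) forces; fx/fy/fz may be null for energy only.
// pairs: explicit nonbonded pair list, or null to loop over all pairs.
static Breakdown eval(const System &s,
                      const std::vector<std::pair<int, int>> *pairs,
                      std::vector<double> *fx, std::vector<double> *fy,
                      std::vector<double> *fz) {
  Breakdown e;
  const bool wantF = fx != nullptr;
  auto addf = [&](int i, double gx, double gy, double gz) {
    (*fx)[i] += gx; (*fy)[i] += gy; (*fz)[i] += gz;
  };
  // bonds
  for (size_t m = 0; m < s.b_i.size(); ++m) {
    int i = s.b_i[m], j = s.b_j[m];
    double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j], dz = s.z[i] - s.z[j];
    double b = std::sqrt(dx * dx + dy * dy + dz * dz);
    double db = b - s.b0[m];
    e.bonds += s.Kb * db * db;
    if (wantF) {
      double c = -2.0 * s.Kb * db / b;
      addf(i, c * dx, c * dy, c * dz);
      addf(j, -c * dx, -c * dy, -c * dz);
    }
  }
  // angles
  for (size_t m = 0; m < s.a_i.size(); ++m) {
    int i = s.a_i[m], j = s.a_j[m], k = s.a_k[m];
    double u[3] = {s.x[i] - s.x[j], s.y[i] - s.y[j], s.z[i] - s.z[j]};
    double v[3] = {s.x[k] - s.x[j], s.y[k] - s.y[j], s.z[k] - s.z[j]};
    double nu = std::sqrt(dot(u, u)), nv = std::sqrt(dot(v, v));
    double ct = dot(u, v) / (nu * nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double dth = th - s.th0[m];
    e.angles += s.Ka * dth * dth;
    if (wantF) {
      double st = std::sqrt(1.0 - ct * ct);
      if (st < 1e-8) st = 1e-8;
      double dEdth = 2.0 * s.Ka * dth;
      double gi[3], gk[3];
      for (int c = 0; c < 3; ++c) {
        gi[c] = (ct * u[c] / nu - v[c] / nv) / (nu * st);
        gk[c] = (ct * v[c] / nv - u[c] / nu) / (nv * st);
      }
      addf(i, -dEdth * gi[0], -dEdth * gi[1], -dEdth * gi[2]);
      addf(k, -dEdth * gk[0], -dEdth * gk[1], -dEdth * gk[2]);
      addf(j, dEdth * (gi[0] + gk[0]), dEdth * (gi[1] + gk[1]),
           dEdth * (gi[2] + gk[2]));
    }
  }
  // dihedrals: V = Kd[(1-cos(dphi)) + 0.5(1-cos(3 dphi))]
  for (size_t m = 0; m < s.d_i.size(); ++m) {
    int i = s.d_i[m], j = s.d_j[m], k = s.d_k[m], l = s.d_l[m];
    double b1[3] = {s.x[j] - s.x[i], s.y[j] - s.y[i], s.z[j] - s.z[i]};
    double b2[3] = {s.x[k] - s.x[j], s.y[k] - s.y[j], s.z[k] - s.z[j]};
    double b3[3] = {s.x[l] - s.x[k], s.y[l] - s.y[k], s.z[l] - s.z[k]};
    double n1[3], n2[3];
    cross(b1, b2, n1); cross(b2, b3, n2);
    double nb2 = std::sqrt(dot(b2, b2));
    double mcb[3]; cross(n1, b2, mcb);
    for (int c = 0; c < 3; ++c) mcb[c] /= nb2;
    double phi = std::atan2(dot(mcb, n2), dot(n1, n2));
    double d = phi - s.ph0[m];
    e.dihedrals += s.Kd * ((1.0 - std::cos(d)) +
                           0.5 * (1.0 - std::cos(3.0 * d)));
    if (wantF) {
      double dEdphi = s.Kd * (std::sin(d) + 1.5 * std::sin(3.0 * d));
      double n1sq = dot(n1, n1), n2sq = dot(n2, n2);
      if (n1sq < 1e-12 || n2sq < 1e-12) continue;
      double f1[3], f4[3];
      for (int c = 0; c < 3; ++c) {
        // signs match the atan2((n1 x b2hat).n2, n1.n2) angle convention
        f1[c] =  nb2 / n1sq * n1[c];      // dphi/dr_i
        f4[c] = -nb2 / n2sq * n2[c];      // dphi/dr_l
      }
      double p12 = dot(b1, b2) / (nb2 * nb2);
      double p32 = dot(b3, b2) / (nb2 * nb2);
      for (int c = 0; c < 3; ++c) {
        double f2 = -(1.0 + p12) * f1[c] + p32 * f4[c];
        double f3 = p12 * f1[c] - (1.0 + p32) * f4[c];
        if (c == 0) {
          addf(i, -dEdphi * f1[0], 0, 0); addf(j, -dEdphi * f2, 0, 0);
          addf(k, -dEdphi * f3, 0, 0);    addf(l, -dEdphi * f4[0], 0, 0);
        } else if (c == 1) {
          addf(i, 0, -dEdphi * f1[1], 0); addf(j, 0, -dEdphi * f2, 0);
          addf(k, 0, -dEdphi * f3, 0);    addf(l, 0, -dEdphi * f4[1], 0);
        } else {
          addf(i, 0, 0, -dEdphi * f1[2]); addf(j, 0, 0, -dEdphi * f2);
          addf(k, 0, 0, -dEdphi * f3);    addf(l, 0, 0, -dEdphi * f4[2]);
        }
      }
    }
  }
  // native contacts: V = Kc[5 (A/r)^12 - 6 (A/r)^10]
  for (size_t m = 0; m < s.c_i.size(); ++m) {
    int i = s.c_i[m], j = s.c_j[m];
    double dx, dy, dz;
    dx = s.x[i] - s.x[j]; dy = s.y[i] - s.y[j]; dz = s.z[i] - s.z[j];
    double r2 = dx * dx + dy * dy + dz * dz, r = std::sqrt(r2);
    double sr2 = s.aij[m] * s.aij[m] / r2;
    double sr10 = sr2 * sr2 * sr2 * sr2 * sr2, sr12 = sr10 * sr2;
    e.contacts += s.Kc * (5.0 * sr12 - 6.0 * sr10);
    if (wantF) {
      // dV/dr = -60 Kc (sr12 - sr10)/r ; F_i = -dV/dr * rhat
      double c = 60.0 * s.Kc * (sr12 - sr10) / r2;
      addf(i, c * dx, c * dy, c * dz);
      addf(j, -c * dx, -c * dy, -c * dz);
    }
  }
  // nonbonded pair terms (repulsion + Debye-Huckel)
  auto pair_term = [&](int i, int j) {
    double dx, dy, dz;
    s.dvec(i, j, dx, dy, dz);
    double r2 = dx * dx + dy * dy + dz * dz;
    double Cij = s.radius[i] + s.radius[j];
    double repcut = s.rep_cutoff_factor * Cij;
    bool do_rep = (s.rep_cutoff_factor <= 0) || (r2 < repcut * repcut);
    double qq = s.charge[i] * s.charge[j];
    bool do_el = qq != 0 &&
      (s.elec_cutoff <= 0 || r2 < s.elec_cutoff * s.elec_cutoff);
    if (!do_rep && !do_el) return;
    double r = std::sqrt(r2);
    if (do_rep) {
      double sr2 = Cij * Cij / r2;
      double sr12 = sr2 * sr2 * sr2; sr12 *= sr12;
      e.repulsion += s.Kr * sr12;
      if (wantF) {
        double c = 12.0 * s.Kr * sr12 / r2;
        addf(i, c * dx, c * dy, c * dz);
        addf(j, -c * dx, -c * dy, -c * dz);
      }
    }
    if (do_el) {
      double u = s.Kel * s.Bk * qq * std::exp(-s.kappa * r) / (s.eps_r * r);
      e.electrostatics += u;
      if (wantF) {
        double c = u * (s.kappa + 1.0 / r) / r;  // -dV/dr / r
        addf(i, c * dx, c * dy, c * dz);
        addf(j, -c * dx, -c * dy, -c * dz);
      }
    }
  };
  if (pairs) {
    for (auto &pr : *pairs) pair_term(pr.first, pr.second);
  } else {
    for (int i = 0; i < s.n_mobile; ++i) {
      for (int j = i + 1; j < s.n; ++j) {
        if (j < s.n_mobile) {
          if (s.excluded(i, j)) continue;
          if (s.contact_set.count(s.key(i, j))) continue;
        }
        pair_term(i, j);
      }
    }
  }
  return e;
}

// [[Rcpp::export]]
NumericVector cpp_energy(List sys, NumericMatrix pos) {
  System s = unpack(sys, pos);
  Breakdown e = eval(s, nullptr, nullptr, nullptr, nullptr);
  return NumericVector::create(
      _["bonds"] = e.bonds, _["angles"] = e.angles,
      _["dihedrals"] = e.dihedrals, _["contacts"] = e.contacts,
      _["repulsion"] = e.repulsion, _["electrostatics"] = e.electrostatics,
      _["total"] = e.total());
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(List sys, NumericMatrix pos) {
  System s = unpack(sys, pos);
  std::vector<double> fx(s.n, 0), fy(s.n, 0), fz(s.n, 0);
  eval(s, nullptr, &fx, &fy, &fz);
  NumericMatrix F(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i];
  }
  return F;
}

static void build_pairs(const System &s, double rc,
                        std::vector<std::pair<int, int>> &pairs) {
  pairs.clear();
  double rc2 = rc * rc;
  for (int i = 0; i < s.n_mobile; ++i) {
    for (int j = i + 1; j < s.n; ++j) {
      if (j < s.n_mobile) {
        if (s.excluded(i, j)) continue;
        if (s.contact_set.count(s.key(i, j))) continue;
      }
      double dx, dy, dz;
      s.dvec(i, j, dx, dy, dz);
      if (dx * dx + dy * dy + dz * dz < rc2) pairs.emplace_back(i, j);
    }
  }
}

// BAOAB Langevin integration. Returns saved frames of the mobile block.
// [[Rcpp::export]]
List cpp_run(List sys, NumericMatrix pos, NumericMatrix vel, List conf) {
  System s = unpack(sys, pos);
  const int nm = s.n_mobile;
  const double dt = as<double>(conf["dt"]);
  const double gamma = as<double>(conf["gamma"]);
  const double kT = as<double>(conf["temperature"]);
  const double mass = as<double>(conf["mass"]);
  const long nsteps = (long)as<double>(conf["n_steps"]);
  const long stride = (long)as<double>(conf["stride"]);
  const double box_xy = as<double>(conf["box_xy"]);  // <=0: no walls
  const double max_disp = as<double>(conf["max_disp"]);
  const double skin = as<double>(conf["skin"]);
  const long log_every = (long)as<double>(conf["log_every"]);

  std::vector<double> vx(nm), vy(nm), vz(nm);
  for (int i = 0; i < nm; ++i) {
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt((1.0 - c1 * c1) * kT / mass);
  const double half = 0.5 * dt;
  const double wall = 0.5 * box_xy;

  // neighbour list only when an electrostatic cutoff is set
  bool use_nb = s.elec_cutoff > 0;
  double rc_nb = 0;
  std::vector<std::pair<int, int>> pairs;
  if (use_nb) {
    double maxrad = 0;
    for (double r : s.radius) maxrad = std::max(maxrad, r);
    double repmax = s.rep_cutoff_factor > 0 ?
        s.rep_cutoff_factor * 2 * maxrad : s.elec_cutoff;
    rc_nb = std::max(s.elec_cutoff, repmax) + skin;
    build_pairs(s, rc_nb, pairs);
  }
  std::vector<double> refx(s.x.begin(), s.x.begin() + nm),
                      refy(s.y.begin(), s.y.begin() + nm),
                      refz(s.z.begin(), s.z.begin() + nm);

  long nframes = nsteps / stride + 1;
  NumericVector frames((R_xlen_t)nframes * nm * 3);
  NumericVector times(nframes);
  int nlog = (int)(nframes / std::max(log_every, 1L)) + 1;
  NumericMatrix elog(nlog, 8);  // t + 6 terms + kinetic T
  int logged = 0;

  std::vector<double> fx(s.n), fy(s.n), fz(s.n);
  auto compute_forces = [&]() {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    return eval(s, use_nb ? &pairs : nullptr, &fx, &fy, &fz);
  };
  compute_forces();

  auto save_frame = [&](long f, double t) {
    for (int i = 0; i < nm; ++i) {
      frames[f + (R_xlen_t)nframes * (i + (R_xlen_t)nm * 0)] = s.x[i];
      frames[f + (R_xlen_t)nframes * (i + (R_xlen_t)nm * 1)] = s.y[i];
      frames[f + (R_xlen_t)nframes * (i + (R_xlen_t)nm * 2)] = s.z[i];
    }
    times[f] = t;
  };
  save_frame(0, 0.0);

  long error_step = -1;
  long frame = 1;
  for (long step = 1; step <= nsteps && error_step < 0; ++step) {
    // B: half kick
    for (int i = 0; i < nm; ++i) {
      vx[i] += half * fx[i] / mass;
      vy[i] += half * fy[i] / mass;
      vz[i] += half * fz[i] / mass;
    }
    // A: half drift (+ walls), O, A again
    for (int rep = 0; rep < 2; ++rep) {
      for (int i = 0; i < nm; ++i) {
        s.x[i] += half * vx[i]; s.y[i] += half * vy[i];
        s.z[i] += half * vz[i];
        if (box_xy > 0) {
          if (s.x[i] > wall)  { s.x[i] = 2 * wall - s.x[i]; vx[i] = -vx[i]; }
          if (s.x[i] < -wall) { s.x[i] = -2 * wall - s.x[i]; vx[i] = -vx[i]; }
          if (s.y[i] > wall)  { s.y[i] = 2 * wall - s.y[i]; vy[i] = -vy[i]; }
          if (s.y[i] < -wall) { s.y[i] = -2 * wall - s.y[i]; vy[i] = -vy[i]; }
        }
      }
      if (rep == 0 && gamma > 0) {  // O: Ornstein-Uhlenbeck
        for (int i = 0; i < nm; ++i) {
          vx[i] = c1 * vx[i] + c2 * norm_rand();
          vy[i] = c1 * vy[i] + c2 * norm_rand();
          vz[i] = c1 * vz[i] + c2 * norm_rand();
        }
      }
    }
    // neighbour-list refresh on displacement
    if (use_nb) {
      double md2 = 0;
      for (int i = 0; i < nm; ++i) {
        double ddx = s.x[i] - refx[i], ddy = s.y[i] - refy[i],
               ddz = s.z[i] - refz[i];
        md2 = std::max(md2, ddx * ddx + ddy * ddy + ddz * ddz);
      }
      if (md2 > 0.25 * skin * skin) {
        build_pairs(s, rc_nb, pairs);
        for (int i = 0; i < nm; ++i) {
          refx[i] = s.x[i]; refy[i] = s.y[i]; refz[i] = s.z[i];
        }
      }
    }
    Breakdown eb = compute_forces();
    // B: half kick with new forces + stability guard
    double vmax2 = 0;
    for (int i = 0; i < nm; ++i) {
      vx[i] += half * fx[i] / mass;
      vy[i] += half * fy[i] / mass;
      vz[i] += half * fz[i] / mass;
      vmax2 = std::max(vmax2,
                       vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    }
    if (!std::isfinite(vmax2) || std::sqrt(vmax2) * dt > max_disp) {
      error_step = step;
      break;
    }
    if (step % stride == 0) {
      save_frame(frame, step * dt);
      if (log_every > 0 && (frame % log_every == 0) && logged < nlog) {
        double ke = 0;
        for (int i = 0; i < nm; ++i) {
          ke += 0.5 * mass *
                (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
        }
        elog(logged, 0) = step * dt;
        elog(logged, 1) = eb.bonds; elog(logged, 2) = eb.angles;
        elog(logged, 3) = eb.dihedrals; elog(logged, 4) = eb.contacts;
        elog(logged, 5) = eb.repulsion; elog(logged, 6) = eb.electrostatics;
        elog(logged, 7) = 2.0 * ke / (3.0 * nm);  // kinetic temperature
        ++logged;
      }
      ++frame;
    }
    if (step % 100000 == 0) Rcpp::checkUserInterrupt();
  }
  frames.attr("dim") = IntegerVector::create(nframes, nm, 3);
  NumericMatrix vout(nm, 3);
  for (int i = 0; i < nm; ++i) {
    vout(i, 0) = vx[i]; vout(i, 1) = vy[i]; vout(i, 2) = vz[i];
  }
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["velocities"] = vout,
                      _["energy_log"] = elog, _["n_logged"] = logged,
                      _["error_step"] = (double)error_step,
                      _["last_frame"] = (double)(frame - 1));
}
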