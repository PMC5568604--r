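// Replica-exchange Monte Carlo inner loop and pairwise ligand-RMSD.
//
// The kernel mirrors the R-level semantics exactly: the same pseudoatom
// derivation rule (outward-bisector side-chain placement), the same energy
// terms, Metropolis on the sampling energy (scoring + contact restraint),
// adjacent-pair exchanges with alternating parity.  Per-replica splitmix64
// streams keep runs reproducible from the master seed independently of R's
// RNG state; the exchange decisions use their own stream.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

inline arma::rowvec unit_row(const arma::rowvec& v) {
  return v / arma::norm(v, 2);
}

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int randint(int n) {  // 0..n-1
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
  double runif(double a, double b) { return a + (b - a) * unif(); }
};

inline double dist3(const arma::mat& A, int i, const arma::mat& B, int j) {
  double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1),
         dz = A(i, 2) - B(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// outward side-chain direction at residue i of a Calpha trace (must match
// the R sidechain_directions rule bit for bit in semantics)
arma::rowvec sc_dir(const arma::mat& ca, int i) {
  int n = ca.n_rows;
  if (n == 1) return arma::rowvec({0.0, 0.0, 1.0});
  if (i == 0) return unit_row(ca.row(0) - ca.row(1));
  if (i == n - 1) return unit_row(ca.row(n - 1) - ca.row(n - 2));
  arma::rowvec u1 = unit_row(ca.row(i - 1) - ca.row(i));
  arma::rowvec u2 = unit_row(ca.row(i + 1) - ca.row(i));
  arma::rowvec v = u1 + u2;
  double nv = arma::norm(v, 2);
  if (nv < 1e-6) {
    int ax = 0;
    double best = std::abs(u1(0));
    for (int k = 1; k < 3; ++k)
      if (std::abs(u1(k)) < best) { best = std::abs(u1(k)); ax = k; }
    arma::rowvec e(3, arma::fill::zeros);
    e(ax) = 1.0;
    arma::rowvec c = {u1(1) * e(2) - u1(2) * e(1),
                      u1(2) * e(0) - u1(0) * e(2),
                      u1(0) * e(1) - u1(1) * e(0)};
    return unit_row(c);
  }
  return -v / nv;
}

struct Params {
  double hard_radius, ev_pen, r_on, ss_w, rr_tol, rr_w, spacing;
  bool lattice;
  arma::mat cmat;             // 20 x 20
  std::vector<int> rec_aa, pep_aa;   // 0..19, -1 unknown
  arma::vec avg_row;          // column means for unknown types
  std::vector<double> cb_len, sc_len;  // peptide derived-atom lengths
  arma::imat native;          // m x 2 (0-based i,j)
  arma::vec native_d;
  arma::imat restr;           // q x 2 (0-based rec,pep)
  arma::vec restr_D0, restr_s;
  std::vector<int> ss_pref;   // 0 none/C, 1 H, 2 E; empty = no bias
};

struct State {
  arma::mat rca, rcb, rsc;
  arma::mat pca, pcb, psc;
  double ev, pair, ss, rr, cr;
  double sampling() const { return ev + pair + ss + rr + cr; }
};

double pair_e(const Params& P, int t1, int t2) {
  if (t1 < 0 && t2 < 0) return arma::mean(P.avg_row);
  if (t1 < 0) return P.avg_row(t2);
  if (t2 < 0) return P.avg_row(t1);
  return P.cmat(t1, t2);
}

// EV + pair-contact contributions of one residue pair (atoms ca,cb,sc each)
void respair_terms(const Params& P, const arma::mat& caA, const arma::mat& cbA,
                   const arma::mat& scA, int i, const arma::mat& caB,
                   const arma::mat& cbB, const arma::mat& scB, int j,
                   int tA, int tB, double* ev, double* pair) {
  const arma::mat* As[3] = {&caA, &cbA, &scA};
  const arma::mat* Bs[3] = {&caB, &cbB, &scB};
  int ncl = 0;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      if (dist3(*As[a], i, *Bs[b], j) < P.hard_radius) ++ncl;
  *ev += P.ev_pen * ncl;
  if (dist3(scA, i, scB, j) <= P.r_on) *pair += pair_e(P, tA, tB);
}

bool ss_match(double ang, int pref) {
  if (pref == 1) return ang >= 80.0 && ang <= 105.0;
  if (pref == 2) return ang > 105.0 && ang <= 145.0;
  return true;
}

double pseudo_angle_deg(const arma::mat& ca, int i) {
  arma::rowvec u = unit_row(ca.row(i - 1) - ca.row(i));
  arma::rowvec v = unit_row(ca.row(i + 1) - ca.row(i));
  double c = arma::dot(u, v);
  c = std::max(-1.0, std::min(1.0, c));
  return std::acos(c) * 180.0 / M_PI;
}

// all term contributions touching the affected residue sets
void partial_energy(const Params& P, const State& S,
                    const std::vector<char>& affR,
                    const std::vector<char>& affP, double out[5]) {
  int nr = S.rca.n_rows, np = S.pca.n_rows;
  double ev = 0, pair = 0, ss = 0, rr = 0, cr = 0;
  for (int i = 0; i < nr; ++i)
    for (int j = i + 2; j < nr; ++j) {
      if (!affR[i] && !affR[j]) continue;
      respair_terms(P, S.rca, S.rcb, S.rsc, i, S.rca, S.rcb, S.rsc, j,
                    P.rec_aa[i], P.rec_aa[j], &ev, &pair);
    }
  for (int i = 0; i < np; ++i)
    for (int j = i + 2; j < np; ++j) {
      if (!affP[i] && !affP[j]) continue;
      respair_terms(P, S.pca, S.pcb, S.psc, i, S.pca, S.pcb, S.psc, j,
                    P.pep_aa[i], P.pep_aa[j], &ev, &pair);
    }
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < np; ++j) {
      if (!affR[i] && !affP[j]) continue;
      respair_terms(P, S.rca, S.rcb, S.rsc, i, S.pca, S.pcb, S.psc, j,
                    P.rec_aa[i], P.pep_aa[j], &ev, &pair);
    }
  if (!P.ss_pref.empty() && np >= 3)
    for (int i = 1; i < np - 1; ++i) {
      if (!affP[i - 1] && !affP[i] && !affP[i + 1]) continue;
      if (!ss_match(pseudo_angle_deg(S.pca, i), P.ss_pref[i])) ss += P.ss_w;
    }
  for (arma::uword k = 0; k < P.native.n_rows; ++k) {
    int i = P.native(k, 0), j = P.native(k, 1);
    if (!affR[i] && !affR[j]) continue;
    double d = dist3(S.rca, i, S.rca, j);
    rr += P.rr_w * std::max(0.0, std::abs(d - P.native_d(k)) - P.rr_tol);
  }
  for (arma::uword k = 0; k < P.restr.n_rows; ++k) {
    int i = P.restr(k, 0), j = P.restr(k, 1);
    if (!affR[i] && !affP[j]) continue;
    double d = dist3(S.rsc, i, S.psc, j);
    if (d > P.restr_D0(k)) cr += P.restr_s(k) * (d - P.restr_D0(k));
  }
  out[0] = ev; out[1] = pair; out[2] = ss; out[3] = rr; out[4] = cr;
}

void full_energy(const Params& P, State& S) {
  int nr = S.rca.n_rows, np = S.pca.n_rows;
  std::vector<char> aR(nr, 1), aP(np, 1);
  double out[5];
  partial_energy(P, S, aR, aP, out);
  S.ev = out[0]; S.pair = out[1]; S.ss = out[2]; S.rr = out[3]; S.cr = out[4];
}

// recompute peptide cb/sc for the affected residues from the current trace
void update_derived(const Params& P, State& S, const std::vector<char>& affP) {
  int np = S.pca.n_rows;
  for (int i = 0; i < np; ++i) {
    if (!affP[i]) continue;
    arma::rowvec d = sc_dir(S.pca, i);
    S.pcb.row(i) = S.pca.row(i) + P.cb_len[i] * d;
    S.psc.row(i) = S.pca.row(i) + P.sc_len[i] * d;
  }
}

bool bond_ok(const arma::mat& ca, int i) {  // bond between i and i+1
  double d = dist3(ca, i, ca, i + 1);
  return d >= 3.3 && d <= 4.3;
}

void snap_rows(arma::mat& m, double sp, bool lattice) {
  if (!lattice) return;
  for (arma::uword i = 0; i < m.n_rows; ++i)
    for (int k = 0; k < 3; ++k)
      m(i, k) = std::round(m(i, k) / sp) * sp;
}

arma::mat rotmat(const arma::rowvec& axis, double ang) {
  arma::rowvec u = unit_row(axis);
  arma::mat K = {{0.0, -u(2), u(1)},
                 {u(2), 0.0, -u(0)},
                 {-u(1), u(0), 0.0}};
  return arma::eye(3, 3) + std::sin(ang) * K + (1 - std::cos(ang)) * (K * K);
}

}  // namespace

// [[Rcpp::export(name = ".remc_kernel")]]
List remc_kernel(NumericMatrix rec_ca, NumericMatrix rec_cb,
                 NumericMatrix rec_sc, List pep_init,
                 IntegerVector rec_aa, IntegerVector pep_aa,
                 NumericMatrix cmat, NumericVector cb_len,
                 NumericVector sc_len, IntegerMatrix native_ij,
                 NumericVector native_d, IntegerMatrix restr_ij,
                 NumericVector restr_D0, NumericVector restr_s,
                 IntegerVector ss_pref, NumericVector temps, List opts) {
  int nr = rec_ca.nrow();
  int n_rep = temps.size();
  int np = as<NumericMatrix>(pep_init[0]).nrow();
  int n_cycles = as<int>(opts["n_cycles"]);
  int n_snap = as<int>(opts["n_snap"]);
  int exch_period = as<int>(opts["exch_period"]);
  NumericVector mw = opts["move_weights"];  // 6 weights, summing to 1
  IntegerVector seeds = opts["seeds"];      // n_rep + 1

  Params P;
  double box_radius = as<double>(opts["box_radius"]);
  arma::rowvec rec_centroid = arma::mean(as<arma::mat>(rec_ca), 0);
  P.hard_radius = as<double>(opts["hard_radius"]);
  P.ev_pen = as<double>(opts["ev_penalty"]);
  P.r_on = as<double>(opts["r_on"]);
  P.ss_w = as<double>(opts["ss_weight"]);
  P.rr_tol = as<double>(opts["rr_tolerance"]);
  P.rr_w = as<double>(opts["rr_weight"]);
  P.spacing = as<double>(opts["spacing"]);
  P.lattice = as<bool>(opts["lattice"]);
  P.cmat = as<arma::mat>(cmat);
  P.avg_row = arma::mean(P.cmat, 0).t();
  P.rec_aa = as<std::vector<int>>(rec_aa);
  P.pep_aa = as<std::vector<int>>(pep_aa);
  P.cb_len = as<std::vector<double>>(cb_len);
  P.sc_len = as<std::vector<double>>(sc_len);
  P.native = as<arma::imat>(native_ij);
  P.native_d = as<arma::vec>(native_d);
  P.restr = as<arma::imat>(restr_ij);
  P.restr_D0 = as<arma::vec>(restr_D0);
  P.restr_s = as<arma::vec>(restr_s);
  P.ss_pref = as<std::vector<int>>(ss_pref);

  // lattice bond-vector set for end flips
  std::vector<std::array<double, 3>> bondvecs;
  if (P.lattice) {
    int kmax = (int)std::ceil(4.3 / P.spacing);
    for (int a = -kmax; a <= kmax; ++a)
      for (int b = -kmax; b <= kmax; ++b)
        for (int c = -kmax; c <= kmax; ++c) {
          double L = std::sqrt((double)(a * a + b * b + c * c)) * P.spacing;
          if (L >= 3.3 && L <= 4.3)
            bondvecs.push_back({a * P.spacing, b * P.spacing, c * P.spacing});
        }
  }

  std::vector<State> S(n_rep);
  std::vector<Rng> rng;
  for (int r = 0; r < n_rep; ++r) rng.emplace_back((uint64_t)seeds[r]);
  Rng xrng((uint64_t)seeds[n_rep]);

  std::vector<char> allR(nr, 1), allP(np, 1);
  for (int r = 0; r < n_rep; ++r) {
    S[r].rca = as<arma::mat>(rec_ca);
    S[r].rcb = as<arma::mat>(rec_cb);
    S[r].rsc = as<arma::mat>(rec_sc);
    S[r].pca = as<arma::mat>(pep_init[r]);
    S[r].pcb.set_size(np, 3);
    S[r].psc.set_size(np, 3);
    update_derived(P, S[r], allP);
    full_energy(P, S[r]);
  }

  std::vector<double> temp_of(n_rep);       // temperature by replica id
  std::vector<int> rep_at_ladder(n_rep);    // replica id at each rung
  for (int r = 0; r < n_rep; ++r) { temp_of[r] = temps[r]; rep_at_ladder[r] = r; }

  int N = n_rep * n_snap;
  arma::cube out_rec(nr, 3, N), out_pep(np, 3, N);
  NumericMatrix meta(N, 8);  // replica, cycle, temp, ev, pair, ss, rr, cr
  long long att = 0, acc = 0, xatt = 0, xacc = 0;

  std::vector<long long> sched(n_snap);
  for (int k = 0; k < n_snap; ++k)
    sched[k] = (long long)(((long long)(k + 1) * n_cycles) / n_snap);

  int krec = 0;
  auto record_all = [&](int cycle) {
    for (int r = 0; r < n_rep; ++r) {
      full_energy(P, S[r]);  // refresh totals, removes accumulation drift
      int t = krec * n_rep + r;
      out_rec.slice(t) = S[r].rca;
      out_pep.slice(t) = S[r].pca;
      meta(t, 0) = r + 1; meta(t, 1) = cycle; meta(t, 2) = temp_of[r];
      meta(t, 3) = S[r].ev; meta(t, 4) = S[r].pair; meta(t, 5) = S[r].ss;
      meta(t, 6) = S[r].rr; meta(t, 7) = S[r].cr;
    }
    ++krec;
  };
  while (krec < n_snap && sched[krec] == 0) record_all(0);

  double cum[6];
  cum[0] = mw[0];
  for (int k = 1; k < 6; ++k) cum[k] = cum[k - 1] + mw[k];

  int n_moves = np + nr;
  for (int cycle = 1; cycle <= n_cycles; ++cycle) {
    for (int r = 0; r < n_rep; ++r) {
      State& st = S[r];
      Rng& g = rng[r];
      double T = temp_of[r];
      for (int mv = 0; mv < n_moves; ++mv) {
        ++att;
        double u = g.unif();
        int type = 0;
        while (type < 5 && u > cum[type]) ++type;
        if (type == 2 && np < 3) type = 4;
        if (type == 3 && np < 4) type = 4;

        std::vector<int> movedP;  // peptide residues whose Calpha moves
        int movedR = -1;
        arma::mat newp;           // candidate peptide trace (full)
        arma::rowvec newrow;      // candidate receptor row delta
        bool valid = true;

        if (type == 0) {  // rigid translation
          double a = 2.0;
          arma::rowvec d(3);
          if (P.lattice)
            for (int k = 0; k < 3; ++k)
              d(k) = std::round(g.runif(-a, a)) * P.spacing;
          else
            for (int k = 0; k < 3; ++k) d(k) = g.runif(-0.5, 0.5);
          newp = st.pca;
          newp.each_row() += d;
          for (int i = 0; i < np; ++i) movedP.push_back(i);
        } else if (type == 1) {  // rigid rotation about centroid
          double ang = g.runif(-0.45, 0.45);
          arma::rowvec ax = {g.unif() - 0.5, g.unif() - 0.5, g.unif() - 0.5};
          if (arma::norm(ax, 2) < 1e-9) ax = {1, 0, 0};
          arma::mat R = rotmat(ax, ang);
          arma::rowvec ctr = arma::mean(st.pca, 0);
          newp = (st.pca.each_row() - ctr) * R;
          newp.each_row() += ctr;
          snap_rows(newp, P.spacing, P.lattice);
          for (int i = 0; i < np - 1 && valid; ++i)
            if (!bond_ok(newp, i)) valid = false;
          for (int i = 0; i < np; ++i) movedP.push_back(i);
        } else if (type == 2) {  // kink
          int i = 1 + g.randint(np - 2);
          arma::rowvec d(3);
          if (P.lattice)
            for (int k = 0; k < 3; ++k)
              d(k) = std::round(g.runif(-2.0, 2.0)) * P.spacing;
          else
            for (int k = 0; k < 3; ++k) d(k) = g.runif(-0.5, 0.5);
          newp = st.pca;
          newp.row(i) += d;
          if (!bond_ok(newp, i - 1) || !bond_ok(newp, i)) valid = false;
          movedP.push_back(i);
        } else if (type == 3) {  // crankshaft on i, i+1
          int i = 1 + g.randint(np - 3);
          arma::rowvec ax = st.pca.row(i + 2) - st.pca.row(i - 1);
          if (arma::norm(ax, 2) < 1e-9) { valid = false; newp = st.pca; }
          else {
            arma::mat R = rotmat(ax, g.runif(-1.05, 1.05));
            newp = st.pca;
            for (int j = i; j <= i + 1; ++j)
              newp.row(j) = (newp.row(j) - newp.row(i - 1)) * R +
                            newp.row(i - 1);
            arma::mat sub = newp.rows(i, i + 1);
            snap_rows(sub, P.spacing, P.lattice);
            newp.rows(i, i + 1) = sub;
            if (!bond_ok(newp, i - 1) || !bond_ok(newp, i) ||
                !bond_ok(newp, i + 1)) valid = false;
          }
          movedP.push_back(i); movedP.push_back(i + 1);
        } else if (type == 4) {  // end flip
          int i = (g.unif() < 0.5) ? 0 : np - 1;
          int nb = (i == 0) ? 1 : np - 2;
          arma::rowvec step(3);
          if (P.lattice) {
            auto& v = bondvecs[g.randint((int)bondvecs.size())];
            step = {v[0], v[1], v[2]};
          } else {
            step = {g.unif() - 0.5, g.unif() - 0.5, g.unif() - 0.5};
            if (arma::norm(step, 2) < 1e-9) step = {1, 0, 0};
            step = unit_row(step) * 3.8;
          }
          newp = st.pca;
          newp.row(i) = newp.row(nb) + step;
          movedP.push_back(i);
        } else {  // receptor single-residue perturbation
          movedR = g.randint(nr);
          arma::rowvec d(3);
          if (P.lattice)
            for (int k = 0; k < 3; ++k)
              d(k) = std::round(g.runif(-1.0, 1.0)) * P.spacing;
          else
            for (int k = 0; k < 3; ++k) d(k) = g.runif(-0.3, 0.3);
          newrow = st.rca.row(movedR) + d;
          arma::mat tmp = st.rca;
          tmp.row(movedR) = newrow;
          if (movedR > 0 && !bond_ok(tmp, movedR - 1)) valid = false;
          if (movedR < nr - 1 && !bond_ok(tmp, movedR)) valid = false;
        }
        if (valid && movedR < 0) {
          // finite simulation volume: the peptide centroid stays within
          // box_radius of the receptor centroid
          arma::rowvec ctr = arma::mean(newp, 0);
          if (arma::norm(ctr - rec_centroid, 2) > box_radius) valid = false;
        }
        if (!valid) continue;  // null move: geometry would break the chain

        std::vector<char> affR(nr, 0), affP(np, 0);
        if (movedR >= 0) affR[movedR] = 1;
        for (int i : movedP)
          for (int j = std::max(0, i - 1); j <= std::min(np - 1, i + 1); ++j)
            affP[j] = 1;

        double e_old[5], e_new[5];
        partial_energy(P, st, affR, affP, e_old);

        // apply candidate, saving what we may need to restore
        arma::mat save_pca, save_pcb, save_psc;
        arma::rowvec save_rca, save_rcb, save_rsc;
        if (movedR >= 0) {
          save_rca = st.rca.row(movedR);
          save_rcb = st.rcb.row(movedR);
          save_rsc = st.rsc.row(movedR);
          arma::rowvec d = newrow - save_rca;
          st.rca.row(movedR) = newrow;
          st.rcb.row(movedR) += d;
          st.rsc.row(movedR) += d;
        } else {
          save_pca = st.pca; save_pcb = st.pcb; save_psc = st.psc;
          st.pca = newp;
          update_derived(P, st, affP);
        }
        partial_energy(P, st, affR, affP, e_new);
        double de = 0;
        for (int k = 0; k < 5; ++k) de += e_new[k] - e_old[k];
        bool ok = de <= 0 || g.unif() < std::exp(-de / T);
        if (ok) {
          st.ev += e_new[0] - e_old[0];
          st.pair += e_new[1] - e_old[1];
          st.ss += e_new[2] - e_old[2];
          st.rr += e_new[3] - e_old[3];
          st.cr += e_new[4] - e_old[4];
          ++acc;
        } else if (movedR >= 0) {
          st.rca.row(movedR) = save_rca;
          st.rcb.row(movedR) = save_rcb;
          st.rsc.row(movedR) = save_rsc;
        } else {
          st.pca = save_pca; st.pcb = save_pcb; st.psc = save_psc;
        }
      }
    }

    if (cycle % exch_period == 0) {
      int parity = (cycle / exch_period) % 2;
      for (int l = parity; l + 1 < n_rep; l += 2) {
        ++xatt;
        int ra = rep_at_ladder[l], rb = rep_at_ladder[l + 1];
        double Ea = S[ra].sampling(), Eb = S[rb].sampling();
        double delta = (1.0 / temp_of[ra] - 1.0 / temp_of[rb]) * (Ea - Eb);
        if (delta >= 0 || xrng.unif() < std::exp(delta)) {
          std::swap(temp_of[ra], temp_of[rb]);
          std::swap(rep_at_ladder[l], rep_at_ladder[l + 1]);
          ++xacc;
        }
      }
    }

    while (krec < n_snap && sched[krec] == cycle) record_all(cycle);
  }

  return List::create(
      _["rec_ca"] = out_rec, _["pep_ca"] = out_pep, _["meta"] = meta,
      _["moves_attempted"] = (double)att, _["moves_accepted"] = (double)acc,
      _["exchanges_attempted"] = (double)xatt,
      _["exchanges_accepted"] = (double)xacc);
}

namespace {
double lrmsd_one(const arma::mat& ra, const arma::mat& rb,
                 const arma::mat& pa, const arma::mat& pb) {
  arma::rowvec ca = arma::mean(ra, 0), cb = arma::mean(rb, 0);
  arma::mat A = ra.each_row() - ca;
  arma::mat B = rb.each_row() - cb;
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, arma::mat(A.t() * B));
  double d = arma::det(U * V.t()) < 0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  arma::mat R = U * D * V.t();
  arma::mat pf = (pa.each_row() - ca) * R;
  pf.each_row() += cb;
  return std::sqrt(arma::accu(arma::square(pf - pb)) / pa.n_rows);
}
}  // namespace

// Greedy PAM swap refinement: repeatedly apply the best
// medoid <-> non-medoid swap until no swap lowers the total cost.
// [[Rcpp::export(name = ".pam_refine")]]
IntegerVector pam_refine_cpp(const arma::mat& d, IntegerVector medoids) {
  int n = d.n_rows, k = medoids.size();
  std::vector<int> med(k);
  for (int j = 0; j < k; ++j) med[j] = medoids[j] - 1;  // 0-based
  std::vector<char> is_med(n, 0);
  for (int j = 0; j < k; ++j) is_med[med[j]] = 1;

  for (int scan = 0; scan < 200; ++scan) {
    double cur = 0;
    for (int i = 0; i < n; ++i) {
      double m = d(i, med[0]);
      for (int j = 1; j < k; ++j) m = std::min(m, d(i, med[j]));
      cur += m;
    }
    double best_cost = cur;
    int best_j = -1, best_x = -1;
    std::vector<double> dexcl(n);
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < n; ++i) {
        double m = std::numeric_limits<double>::infinity();
        for (int l = 0; l < k; ++l)
          if (l != j) m = std::min(m, d(i, med[l]));
        dexcl[i] = m;
      }
      for (int x = 0; x < n; ++x) {
        if (is_med[x]) continue;
        double cost = 0;
        for (int i = 0; i < n; ++i) cost += std::min(dexcl[i], d(i, x));
        if (cost < best_cost - 1e-12) { best_cost = cost; best_j = j; best_x = x; }
      }
    }
    if (best_j < 0) break;
    is_med[med[best_j]] = 0;
    med[best_j] = best_x;
    is_med[best_x] = 1;
  }
  IntegerVector out(k);
  for (int j = 0; j < k; ++j) out[j] = med[j] + 1;
  return out;
}

// [[Rcpp::export(name = ".ligand_rmsd_to_ref")]]
NumericVector ligand_rmsd_to_ref_cpp(const arma::cube& rec_ca,
                                     const arma::cube& pep_ca,
                                     const arma::mat& ref_rec,
                                     const arma::mat& ref_pep) {
  int n = rec_ca.n_slices;
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = lrmsd_one(rec_ca.slice(i), ref_rec, pep_ca.slice(i), ref_pep);
  return out;
}

// [[Rcpp::export(name = ".ligand_rmsd_matrix")]]
NumericMatrix ligand_rmsd_matrix_cpp(const arma::cube& rec_ca,
                                     const arma::cube& pep_ca) {
  int n = rec_ca.n_slices;
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double v = lrmsd_one(rec_ca.slice(i), rec_ca.slice(j),
                           pep_ca.slice(i), pep_ca.slice(j));
      out(i, j) = v;
      out(j, i) = v;
    }
  return out;
}
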