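// Lattice agent-based simulator for follow-the-leader cell chain migration.
//
// Three rule systems share one engine:
//   model 0 (ECM)     directional draw gated by site state (POS forging, ATS
//                     double-steps through an open channel)
//   model 1 (Contact) filopodial contact guidance; site state does not impede
//   model 2 (Hybrid)  Contact decision logic executed through the ECM gate
//
// The tri-state site machine (Closed -> Occupied <-> Open), the chain
// criterion and the persistence bookkeeping live here; everything statistical
// sits in R. An R-level reference implementation of the same update rules
// (R/reference.R) serves as the independent oracle in the test suite.

#include <Rcpp.h>
#include <cstdint>
#include <functional>
#include <algorithm>
#include <cmath>
#include <vector>
#include <array>
using namespace Rcpp;

// 8 compass directions, index 8 = none. x grows distally (toward the target
// edge), y spans the anterior(-)/posterior(+) axis.
static const int DX[8] = {1, 1, 0, -1, -1, -1, 0, 1};
static const int DY[8] = {0, -1, -1, -1, 0, 1, 1, 1};
static const int DIR_NONE = 8;

enum SiteState { CLOSED = 0, OPEN = 1, OCCUPIED = 2 };
enum Termination { TERM_MAX_STEPS = 0, TERM_CHAIN_BROKEN = 1, TERM_TARGET = 2 };

// ---------------------------------------------------------------------------
// splitmix64: small fast 64-bit generator; one independent stream per
// replicate, so a batch is reproducible from (master seed, replicate index).
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) { next(); next(); }
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) {  // uniform on {0, ..., n-1}
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
  // Degenerate Bernoulli draws consume no randomness: this keeps the Hybrid
  // model with POS-true = ATS-true = 0 on the same stream as the pure Contact
  // model (a step-for-step equivalence the test suite asserts).
  bool bern(double p) {
    if (p <= 0.0) return false;
    if (p >= 1.0) return true;
    return unif() < p;
  }
  int cat9(const double* p) {  // categorical over 8 directions + none
    double u = unif(), c = 0.0;
    for (int i = 0; i < 9; ++i) { c += p[i]; if (u < c) return i; }
    return DIR_NONE;
  }
};

static uint64_t rep_seed(double master, int rep) {
  uint64_t m = (uint64_t)master;
  return (m + 1ULL) * 0x9e3779b97f4a7c15ULL +
         (uint64_t)(rep + 1) * 0xbf58476d1ce4e5b9ULL;
}

struct Params {
  double ldd[9], fdd[9];
  double pos, ats;                           // ECM / Hybrid movement gate
  double lmc, fmc, ppc, frp, lrp, fmp, lmp;  // Contact behaviours (p_true)
  bool sid, sip;
  int mdi, mpi;
  bool track;
};

static void read_dist9(const NumericVector& v, double* out) {
  if (v.size() != 9) stop("directional distribution must have 9 probabilities");
  double s = 0.0;
  for (int i = 0; i < 9; ++i) {
    out[i] = v[i];
    s += v[i];
    if (v[i] < 0) stop("negative probability in directional distribution");
  }
  if (std::fabs(s - 1.0) > 1e-9) stop("directional probabilities must sum to 1");
}

static double read_p(const List& pl, const char* nm, double def) {
  if (!pl.containsElementNamed(nm)) return def;
  double p = as<double>(pl[nm]);
  if (p < 0.0 || p > 1.0) stop("probability out of [0, 1]");
  return p;
}

static Params read_params(const List& pl) {
  Params p;
  read_dist9(pl["ldd"], p.ldd);
  read_dist9(pl["fdd"], p.fdd);
  p.pos = read_p(pl, "pos", 0.0);
  p.ats = read_p(pl, "ats", 0.0);
  p.lmc = read_p(pl, "lmc", 0.0);
  p.fmc = read_p(pl, "fmc", 0.0);
  p.ppc = read_p(pl, "ppc", 0.0);
  p.frp = read_p(pl, "frp", 0.0);
  p.lrp = read_p(pl, "lrp", 0.0);
  p.fmp = read_p(pl, "fmp", 0.0);
  p.lmp = read_p(pl, "lmp", 0.0);
  p.sid = pl.containsElementNamed("sid") ? as<bool>(pl["sid"]) : false;
  p.sip = pl.containsElementNamed("sip") ? as<bool>(pl["sip"]) : false;
  p.mdi = pl.containsElementNamed("mdi") ? as<int>(pl["mdi"]) : 5;
  p.mpi = pl.containsElementNamed("mpi") ? as<int>(pl["mpi"]) : 5;
  p.track = pl.containsElementNamed("track") ? as<bool>(pl["track"]) : false;
  if (p.mdi < 0 || p.mdi > 50 || p.mpi < 0 || p.mpi > 50)
    stop("MDI/MPI must lie in [0, 50]");
  return p;
}

// Longest x-monotone sequential path on bare positions; shared by the engine
// and the exported chain detector so both always agree. A fast DP over the
// two x-sorted tie orders handles almost every configuration; when its
// result is shorter than the largest connected component of the sequential
// relation (the only situations where equal-x groups might need mixed
// traversal directions), an exact bitmask DP settles it.
static int mono_path_exact(const std::vector<int>& px,
                           const std::vector<int>& py,
                           std::vector<int>& members) {
  int n = (int)px.size();
  auto seqp = [&](int i, int j) {
    return std::abs(px[i] - px[j]) <= 4 && std::abs(py[i] - py[j]) <= 1;
  };
  int M = 1 << n;
  std::vector<int8_t> dp((size_t)M * n, 0);
  int best = 1, bm = 1, bl = 0;
  for (int i = 0; i < n; ++i) dp[((size_t)(1 << i)) * n + i] = 1;
  for (int m = 1; m < M; ++m) {
    for (int l = 0; l < n; ++l) {
      int8_t cur = dp[(size_t)m * n + l];
      if (!cur) continue;
      for (int j = 0; j < n; ++j) {
        if (m & (1 << j)) continue;
        if (px[j] > px[l] || !seqp(l, j)) continue;  // front-to-back only
        size_t nm = (size_t)(m | (1 << j)) * n + j;
        if (cur + 1 > dp[nm]) {
          dp[nm] = cur + 1;
          if (dp[nm] > best) { best = dp[nm]; bm = m | (1 << j); bl = j; }
        }
      }
    }
  }
  (void)bl;
  members.clear();
  for (int i = 0; i < n; ++i)
    if (bm & (1 << i)) members.push_back(i);
  return best;
}

static int mono_path(const std::vector<int>& px, const std::vector<int>& py,
                     std::vector<int>& members) {
  int n = (int)px.size();
  auto seqp = [&](int i, int j) {
    return std::abs(px[i] - px[j]) <= 4 && std::abs(py[i] - py[j]) <= 1;
  };
  int bestlen = 0;
  for (int tie = 0; tie < 2; ++tie) {
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (px[a] != px[b]) return px[a] > px[b];
      return tie ? py[a] < py[b] : py[a] > py[b];
    });
    std::vector<int> dp(n, 1), prev(n, -1);
    int bi = 0;
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < i; ++j)
        if (seqp(ord[j], ord[i]) && dp[j] + 1 > dp[i]) {
          dp[i] = dp[j] + 1;
          prev[i] = j;
        }
      if (dp[i] > dp[bi]) bi = i;
    }
    if (dp[bi] > bestlen) {
      bestlen = dp[bi];
      members.clear();
      for (int i = bi; i >= 0; i = prev[i]) members.push_back(ord[i]);
    }
  }
  if (bestlen == n) return bestlen;
  // largest-component upper bound; fall through to the exact DP when the
  // fast result might not be tight
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  };
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (seqp(i, j)) parent[find(i)] = find(j);
  std::vector<int> count(n, 0);
  int comp_max = 0;
  for (int i = 0; i < n; ++i) comp_max = std::max(comp_max, ++count[find(i)]);
  if (bestlen >= comp_max || n > 20) return bestlen;
  return mono_path_exact(px, py, members);
}

// ---------------------------------------------------------------------------
struct Sim {
  int W, H, nL, nF, N, model;
  Params pm;
  std::vector<int8_t> st;    // site states, index x + W*y
  std::vector<int> occ;      // agent index at site, -1 if none
  std::vector<int> ax, ay;
  std::vector<char> leader;
  std::vector<int> pol;      // follower polarized direction (8 = none)
  std::vector<int> dclk, pclk;
  std::vector<char> ext;     // protrusions currently extended
  std::vector<std::array<int8_t, 8>> plen;  // protrusion length per direction
  Rng rng;

  Sim(int model_, const Params& p, int W_, int H_, int nL_, int nF_,
      uint64_t seed)
      : W(W_), H(H_), nL(nL_), nF(nF_), N(nL_ + nF_), model(model_), pm(p),
        st(W_ * H_, CLOSED), occ(W_ * H_, -1), ax(N), ay(N), leader(N),
        pol(N, DIR_NONE), dclk(N, 0), pclk(N, 0), ext(N, 0), plen(N),
        rng(seed) {
    init();
  }

  int idx(int x, int y) const { return x + W * y; }
  bool inb(int x, int y) const { return x >= 0 && x < W && y >= 0 && y < H; }

  void init() {
    // single-file chain at mid-height, Followers at x = 1..nF, Leaders
    // distal-most (x = nF+1..N)
    int row = H / 2;
    for (int a = 0; a < N; ++a) {
      ax[a] = a + 1;
      ay[a] = row;
      leader[a] = (a >= nF);
      st[idx(ax[a], ay[a])] = OCCUPIED;
      occ[idx(ax[a], ay[a])] = a;
      plen[a].fill(0);
    }
    if (pm.track)  // pre-existing track: open from the front agent to the edge
      for (int x = N + 1; x < W; ++x) st[idx(x, row)] = OPEN;

    if (model != 0) {  // Contact / Hybrid: polarity, clocks, protrusions out
      // synchronized clocks start at the full interval, so every Follower
      // is scheduled to re-decide at the same (latest possible) step
      int shared_dclk = pm.mdi;
      for (int a = 0; a < N; ++a) {
        if (!leader[a]) {
          if (pm.sid) {  // all Followers polarized distal, clocks in phase
            pol[a] = 0;
            dclk[a] = shared_dclk;
          } else {
            pol[a] = rng.cat9(pm.fdd);
            dclk[a] = rng.below(pm.mdi + 1);
          }
        }
      }
      int shared_pclk = pm.mpi;
      for (int a = 0; a < N; ++a) {
        pclk[a] = pm.sip ? shared_pclk : rng.below(pm.mpi + 1);
        extend(a);  // all agents start with extended protrusions
      }
    }
  }

  // -- protrusions ----------------------------------------------------------
  void extend(int a) {
    ext[a] = 1;
    plen[a].fill(0);
    if (leader[a]) {  // hairy phenotype: full-length rays in all 8 directions
      for (int d = 0; d < 8; ++d) plen[a][d] = 3;
    } else if (pol[a] != DIR_NONE) {
      // polarized phenotype: filopodia oriented along the direction of
      // movement (a single front-directed ray; two is the observed cap)
      plen[a][pol[a]] = 3;
    }
  }
  void retract(int a) {
    ext[a] = 0;
    plen[a].fill(0);
  }
  void repolarize(int a, int d) {
    pol[a] = d;
    if (ext[a]) extend(a);  // filopodia re-orient along the new axis
  }

  // does a's filopodium ray in direction d cover site (x, y)?
  bool ray_covers(int a, int d, int x, int y) const {
    if (!ext[a]) return false;
    int len = plen[a][d];
    for (int k = 1; k <= len; ++k) {
      int cx = ax[a] + k * DX[d], cy = ay[a] + k * DY[d];
      if (!inb(cx, cy)) break;  // rays are clipped at the grid edge
      if (cx == x && cy == y) return true;
    }
    return false;
  }
  bool covers(int a, int x, int y) const {
    for (int d = 0; d < 8; ++d)
      if (ray_covers(a, d, x, y)) return true;
    return false;
  }
  bool mediates_contact(int a) const {
    for (int b = 0; b < N; ++b)
      if (b != a && covers(a, ax[b], ay[b])) return true;
    return false;
  }

  // round an integer displacement to the nearest compass octant
  int octdir(int dx, int dy) {
    double ang = std::atan2((double)dy, (double)dx);
    double best = 1e18;
    int nb = 0, cand[8];
    for (int d = 0; d < 8; ++d) {
      double diff = std::fabs(
          std::remainder(ang - std::atan2((double)DY[d], (double)DX[d]),
                         2.0 * M_PI));
      if (diff < best - 1e-12) {
        best = diff;
        nb = 0;
        cand[nb++] = d;
      } else if (diff <= best + 1e-12) {
        cand[nb++] = d;
      }
    }
    return nb == 1 ? cand[0] : cand[rng.below(nb)];
  }

  // contact = own filopodia touch another agent's body, or theirs touch ours
  void contacts_of(int a, std::vector<int>& out) const {
    out.clear();
    for (int b = 0; b < N; ++b) {
      if (b == a) continue;
      if (covers(a, ax[b], ay[b]) || covers(b, ax[a], ay[a])) out.push_back(b);
    }
  }

  // -- stochastic clocks (Contact / Hybrid), global tick before updates -----
  void tick_clocks() {
    for (int a = 0; a < N; ++a) {
      if (!leader[a]) {
        if (dclk[a] > 0) --dclk[a];
        if (dclk[a] == 0) {  // direction-change clock fires
          repolarize(a, rng.cat9(pm.fdd));
          dclk[a] = rng.below(pm.mdi + 1);
        }
      }
      if (pclk[a] > 0) --pclk[a];
      if (pclk[a] == 0) {  // protrusion-change clock fires: toggle state
        if (ext[a]) {
          // PPC: a retraction that would sever a live filopodial contact is
          // suppressed when true is drawn
          if (!(mediates_contact(a) && rng.bern(pm.ppc))) retract(a);
        } else {
          extend(a);
        }
        pclk[a] = rng.below(pm.mpi + 1);
      }
    }
  }

  // -- movement -------------------------------------------------------------
  void do_move(int a, int nx, int ny) {
    int o = idx(ax[a], ay[a]);
    st[o] = OPEN;  // vacated sites stay open: the agent's wake
    occ[o] = -1;
    ax[a] = nx;
    ay[a] = ny;
    int n = idx(nx, ny);
    st[n] = OCCUPIED;
    occ[n] = a;
  }

  struct Link {
    int owner, dir, partner;
  };
  void links_of(int a, std::vector<Link>& out) const {
    out.clear();
    for (int b = 0; b < N; ++b) {
      if (b == a) continue;
      for (int d = 0; d < 8; ++d) {
        if (ray_covers(a, d, ax[b], ay[b])) out.push_back({a, d, b});
        if (ray_covers(b, d, ax[a], ay[a])) out.push_back({b, d, a});
      }
    }
  }

  // FMP/LMP: after one end of a filopodial link moves, the filopodium may
  // lengthen or shorten to keep covering the partner's body; adjustments past
  // the 3-site clamp (or off the ray line) are impossible and the contact
  // breaks with the length unchanged
  void maintain_links(const std::vector<Link>& links) {
    for (const Link& L : links) {
      int o = L.owner, p = L.partner, d = L.dir;
      int dx = ax[p] - ax[o], dy = ay[p] - ay[o];
      int len = plen[o][d];
      bool along = false;
      int k = 0;
      if (DX[d] == 0) {
        if (dx == 0 && dy * DY[d] > 0) { k = dy * DY[d]; along = true; }
      } else if (DY[d] == 0) {
        if (dy == 0 && dx * DX[d] > 0) { k = dx * DX[d]; along = true; }
      } else if (dx * DY[d] == dy * DX[d] && dx * DX[d] > 0) {
        k = dx * DX[d];
        along = true;
      }
      if (along && k == len) continue;  // tip still on the partner
      if (!rng.bern(leader[o] ? pm.lmp : pm.fmp)) continue;
      if (along && k >= 1 && k <= 3 && ext[o]) plen[o][d] = (int8_t)k;
    }
  }

  // single agent update; returns true if the agent moved
  bool update_agent(int a) {
    int d = DIR_NONE;
    bool contact_induced = false;

    if (model == 0) {  // ECM: fresh directional draw every update
      d = rng.cat9(leader[a] ? pm.ldd : pm.fdd);
    } else {
      std::vector<int> cts;
      contacts_of(a, cts);
      if (!cts.empty() && rng.bern(leader[a] ? pm.lmc : pm.fmc)) {
        // direction of contact; multiple octants tie-broken uniformly
        bool seen[9] = {false};
        int dirs[8], nd = 0;
        for (int b : cts) {
          int cd = octdir(ax[b] - ax[a], ay[b] - ay[a]);
          if (!seen[cd]) {
            seen[cd] = true;
            dirs[nd++] = cd;
          }
        }
        d = nd == 1 ? dirs[0] : dirs[rng.below(nd)];
        // responding to the contact is the agent's action this step, even
        // when the move turns out to be blocked: the rules fall back to an
        // ordinary move only when no contact existed or the agent did not
        // respond to it
        contact_induced = true;
      } else {
        d = leader[a] ? rng.cat9(pm.ldd) : pol[a];
      }
    }
    if (d == DIR_NONE) return false;

    int nx = ax[a] + DX[d], ny = ay[a] + DY[d];
    if (!inb(nx, ny) || st[idx(nx, ny)] == OCCUPIED) {
      // filopodia may retract after an attempt to move towards a contact
      if (contact_induced && rng.bern(leader[a] ? pm.lrp : pm.frp))
        retract(a);
      return false;
    }

    std::vector<Link> links;
    if (model != 0) links_of(a, links);

    if (model == 1) {  // pure Contact: matrix resistance does not impede
      do_move(a, nx, ny);
    } else {  // ECM / Hybrid site-state gate
      bool first_open = (st[idx(nx, ny)] == OPEN);
      if (!first_open && rng.bern(pm.pos)) return false;  // refuses to forge
      do_move(a, nx, ny);
      if (first_open) {  // ATS: second step through a contiguous open channel
        int nx2 = nx + DX[d], ny2 = ny + DY[d];
        if (inb(nx2, ny2) && st[idx(nx2, ny2)] == OPEN && rng.bern(pm.ats))
          do_move(a, nx2, ny2);
      }
    }

    if (model != 0) {
      maintain_links(links);
      // a successful contact-induced move re-polarizes a Follower towards the
      // contact, and filopodia may retract after moving towards the contact
      if (contact_induced) {
        if (!leader[a]) repolarize(a, d);
        if (rng.bern(leader[a] ? pm.lrp : pm.frp)) retract(a);
      }
    }
    return true;
  }

  int chain(std::vector<int>& members) const {
    return mono_path(ax, ay, members);
  }

  // -- one full run ---------------------------------------------------------
  // persistence counts steps on which the structural criterion (>= 6
  // sequential agents) holds and the chain kept its minimum velocity
  // (centroid advance >= 1 site per 10-step checkpoint window); failing
  // either ends the run unless `cumulative`
  void run(int max_steps, bool cumulative, int& persistence, int& reason,
           double& final_cx, int& steps) {
    std::vector<int> members;
    std::vector<double> cx_hist(max_steps + 1);
    chain(members);
    double cx = 0;
    for (int m : members) cx += ax[m];
    cx_hist[0] = cx / members.size();

    persistence = 0;
    reason = TERM_MAX_STEPS;
    int t = 0;
    while (t < max_steps) {
      ++t;
      if (model != 0) tick_clocks();
      for (int k = 0; k < N; ++k)  // random asynchronous updates, with
        update_agent(rng.below(N));  // replacement: N site selections a step
      int sz = chain(members);
      bool is_chain = sz >= 6;
      cx = 0;
      for (int m : members) cx += ax[m];
      cx = cx / members.size();
      cx_hist[t] = cx;
      bool vel_ok = (t % 10 != 0) || (cx_hist[t] - cx_hist[t - 10] >= 1.0);
      if (!(is_chain && vel_ok) && !cumulative) {
        reason = TERM_CHAIN_BROKEN;
        break;
      }
      if (is_chain && vel_ok) ++persistence;
      bool at_target = false;
      for (int a = 0; a < N; ++a)
        if (ax[a] == W - 1) at_target = true;
      if (at_target) {
        reason = TERM_TARGET;
        break;
      }
    }
    final_cx = cx_hist[t];
    steps = t;
  }
};

// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_batch(int model, List params, int n_reps, double master_seed,
                   int max_steps = 1000, bool cumulative = false,
                   int width = 150, int height = 45, int n_leaders = 3,
                   int n_followers = 5) {
  Params p = read_params(params);
  if (n_reps < 1) stop("n_reps must be >= 1");
  if (n_leaders < 0 || n_followers < 0 || n_leaders + n_followers < 1)
    stop("invalid agent counts");
  if (n_leaders + n_followers + 1 >= width) stop("grid too narrow for chain");
  IntegerVector persistence(n_reps), reason(n_reps), steps(n_reps);
  NumericVector final_cx(n_reps);
  for (int r = 0; r < n_reps; ++r) {
    Sim sim(model, p, width, height, n_leaders, n_followers,
            rep_seed(master_seed, r));
    int per, rsn, stp;
    double fcx;
    sim.run(max_steps, cumulative, per, rsn, fcx, stp);
    persistence[r] = per;
    reason[r] = rsn;
    final_cx[r] = fcx;
    steps[r] = stp;
    if ((r & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["persistence"] = persistence,
                      _["termination"] = reason,
                      _["final_centroid_x"] = final_cx, _["steps"] = steps);
}

// Run one simulation and return the final state (rendering / inspection).
// [[Rcpp::export]]
List cpp_run_one(int model, List params, double seed, int max_steps = 1000,
                 bool cumulative = false, int width = 150, int height = 45,
                 int n_leaders = 3, int n_followers = 5) {
  Params p = read_params(params);
  Sim sim(model, p, width, height, n_leaders, n_followers, rep_seed(seed, 0));
  int per, rsn, stp;
  double fcx;
  sim.run(max_steps, cumulative, per, rsn, fcx, stp);
  IntegerMatrix grid(width, height);
  for (int x = 0; x < width; ++x)
    for (int y = 0; y < height; ++y) grid(x, y) = sim.st[sim.idx(x, y)];
  int N = sim.N;
  IntegerVector axv(N), ayv(N), polv(N);
  LogicalVector lead(N), extd(N);
  IntegerMatrix plen(N, 8);
  for (int a = 0; a < N; ++a) {
    axv[a] = sim.ax[a];
    ayv[a] = sim.ay[a];
    polv[a] = sim.pol[a];
    lead[a] = (bool)sim.leader[a];
    extd[a] = (bool)sim.ext[a];
    for (int d = 0; d < 8; ++d) plen(a, d) = sim.plen[a][d];
  }
  return List::create(_["persistence"] = per, _["termination"] = rsn,
                      _["final_centroid_x"] = fcx, _["steps"] = stp,
                      _["grid"] = grid, _["x"] = axv, _["y"] = ayv,
                      _["leader"] = lead, _["polarized"] = polv,
                      _["extended"] = extd, _["protrusion_len"] = plen);
}

// Structural chain criterion on bare 0-based positions.
// [[Rcpp::export]]
List cpp_detect_chain(IntegerMatrix pos) {
  int n = pos.nrow();
  if (n < 1) stop("need at least one agent");
  std::vector<int> px(n), py(n), members;
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0);
    py[i] = pos(i, 1);
  }
  int len = mono_path(px, py, members);
  IntegerVector mem((int)members.size());
  for (size_t i = 0; i < members.size(); ++i) mem[i] = members[i] + 1;
  return List::create(_["is_chain"] = (len >= 6), _["members"] = mem,
                      _["length"] = len);
}
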