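// Metropolis-within-Gibbs samplers for the latent-network SI epidemic model.
//
// The preferential-attachment sampler targets an augmented posterior in
// which the draw order of every attachment set is carried as a latent
// variable: the per-step selection probability is then the ordered
// successive-sampling product (O(x) per step) instead of the exact set
// probability (O(2^x)), and marginalising the orders recovers the exact
// model posterior over graphs.  Edge flips propose an insertion slot
// uniformly (slot-count MH correction), entry-order transpositions propose
// uniform draw orders for the attachment sets they change (factorial MH
// correction), and dedicated order-shuffle moves mix the draw orders.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

namespace {

struct PaState {
  int m;
  std::vector<unsigned char> adj;      // m*m, 0/1
  std::vector<double> tI;              // shifted infection times (0-based)
  std::vector<int> parent;             // parent[j] (0-based), -1 for j = 0
  std::vector<int> entry;              // entry[k] = node entering at position k
  std::vector<int> pos;                // pos[node] = entry position
  std::vector<std::vector<int> > ord;  // ord[k], k >= 2: node labels in draw order
  std::vector<double> step_sel;        // log ordered selection prob per position
  std::vector<double> step_cp;         // log censored-Poisson pmf per position
  double beta, mu, gamma;
  double E;                            // total edge exposure of current graph
  std::vector<int> nEarly;             // # earlier-epidemic neighbours per node
  double tree_lp;                          // sum_j -log(nEarly[j])
  double graph_lp;                     // sum of step_cp + step_sel

  bool a(int i, int j) const { return adj[i * m + j] != 0; }
  void set(int i, int j, unsigned char v) { adj[i * m + j] = v; adj[j * m + i] = v; }
};

double cpois_lp(int x, double mu, int i) {
  // support 1..i-1 for entry step i (1-based), i >= 3
  if (x < 1 || x > i - 1) return R_NegInf;
  if (x == 1) return -mu + log1p(mu);
  if (x <= i - 2) return R::dpois((double) x, mu, 1);
  return R::ppois((double) (i - 2), mu, 0, 1);
}

// Build prefix degrees (indexed by node label) for entries < upto.
void build_deg(const PaState& s, int upto, std::vector<double>& deg, double& D) {
  std::fill(deg.begin(), deg.end(), 0.0);
  D = 0.0;
  if (upto >= 2) { deg[s.entry[0]] += 1; deg[s.entry[1]] += 1; D = 2; }
  for (int k = 2; k < upto; ++k) {
    const std::vector<int>& o = s.ord[k];
    for (size_t r = 0; r < o.size(); ++r) deg[o[r]] += 1;
    deg[s.entry[k]] += o.size();
    D += 2.0 * o.size();
  }
}

// Ordered successive-sampling log-probability of ord[k]'s draw sequence,
// with deg/D the prefix degrees just before step k.
double sel_lp(const PaState& s, int k, const std::vector<int>& o,
              const std::vector<double>& deg, double D,
              const std::vector<int>& pos) {
  double R2 = 0.5 * (double) k * (double) (k + 1);
  double rem = 1.0, lp = 0.0;
  for (size_t r = 0; r < o.size(); ++r) {
    int node = o[r];
    double w = (1.0 - s.gamma) * deg[node] / D
             + s.gamma * (double) (pos[node] + 1) / R2;
    if (w <= 0.0 || rem <= 0.0) return R_NegInf;
    lp += std::log(w / rem);
    rem -= w;
  }
  return lp;
}

// Recompute selection log-probs for positions [from, to) into out (indexed
// from 0 = position `from`), advancing deg/D across the range.
void sweep_sel(const PaState& s, int from, int to,
               std::vector<double>& deg, double& D,
               const std::vector<int>& pos, std::vector<double>& out) {
  out.clear();
  for (int k = from; k < to; ++k) {
    const std::vector<int>& o = s.ord[k];
    out.push_back(sel_lp(s, k, o, deg, D, pos));
    for (size_t r = 0; r < o.size(); ++r) deg[o[r]] += 1;
    deg[s.entry[k]] += o.size();
    D += 2.0 * o.size();
  }
}

int runif_int(int n) { // uniform on 0..n-1
  int k = (int) std::floor(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

void shuffle_vec(std::vector<int>& v) {
  for (int i = (int) v.size() - 1; i > 0; --i) {
    int j = runif_int(i + 1);
    std::swap(v[i], v[j]);
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_mwg_pa(int m, NumericVector times, IntegerVector parent1,
                IntegerMatrix status, double beta0, double mu0, double gamma0,
                bool gamma_fixed, double a_beta, double b_beta,
                double a_mu, double b_mu, int n_iter, int n_burnin, int thin,
                double sd_mu, double sd_gamma, bool adapt,
                int sigma_moves, int edges_per_iter, int order_moves) {
  RNGScope scope;
  PaState s;
  s.m = m;
  s.adj.assign((size_t) m * m, 0);
  s.tI.assign(times.begin(), times.end());
  s.parent.assign(m, -1);
  for (int j = 1; j < m; ++j) s.parent[j] = parent1[j] - 1;
  s.beta = beta0; s.mu = mu0; s.gamma = gamma0;

  // initial graph: all known-present pairs (includes the transmission tree)
  for (int i = 0; i < m; ++i)
    for (int j = i + 1; j < m; ++j)
      if (status(i, j) == 1) s.set(i, j, 1);

  // free pairs
  std::vector<std::array<int, 2> > freePairs;
  for (int i = 0; i < m; ++i)
    for (int j = i + 1; j < m; ++j)
      if (status(i, j) == 0) { std::array<int, 2> pr = {{i, j}}; freePairs.push_back(pr); }
  int n_free = (int) freePairs.size();
  int n_scan = (edges_per_iter <= 0 || edges_per_iter > n_free) ? n_free
                                                                : edges_per_iter;

  // entry order: identity (epidemic order); always supported because each
  // node's infector precedes it
  s.entry.resize(m); s.pos.resize(m);
  for (int k = 0; k < m; ++k) { s.entry[k] = k; s.pos[k] = k; }

  // attachment sets in ascending entry order
  s.ord.assign(m, std::vector<int>());
  for (int k = 2; k < m; ++k)
    for (int w = 0; w < m; ++w)
      if (s.pos[w] < k && s.a(s.entry[k], w)) s.ord[k].push_back(w);

  if (!s.a(s.entry[0], s.entry[1]))
    stop("initial state unsupported: sigma1-sigma2 edge missing");
  for (int k = 2; k < m; ++k)
    if (s.ord[k].empty())
      stop("initial state unsupported: node with no earlier neighbour");

  // caches
  s.nEarly.assign(m, 0);
  s.E = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = i + 1; j < m; ++j)
      if (s.a(i, j)) { s.nEarly[j] += 1; s.E += s.tI[j] - s.tI[i]; }
  s.tree_lp = 0.0;
  for (int j = 1; j < m; ++j) s.tree_lp -= std::log((double) s.nEarly[j]);

  std::vector<double> deg((size_t) m, 0.0);
  double D = 0.0;
  s.step_sel.assign(m, 0.0);
  s.step_cp.assign(m, 0.0);
  {
    std::vector<double> tmp;
    build_deg(s, 2, deg, D);
    sweep_sel(s, 2, m, deg, D, s.pos, tmp);
    for (int k = 2; k < m; ++k) {
      s.step_sel[k] = tmp[k - 2];
      s.step_cp[k] = cpois_lp((int) s.ord[k].size(), s.mu, k + 1);
    }
  }
  s.graph_lp = 0.0;
  for (int k = 2; k < m; ++k) s.graph_lp += s.step_sel[k] + s.step_cp[k];

  // trace storage
  int n_keep = 0;
  for (int it = n_burnin; it < n_iter; ++it) if ((it - n_burnin) % thin == 0) ++n_keep;
  NumericMatrix trace(n_keep, 4);
  NumericMatrix efreq(m, m);
  long long att_mu = 0, acc_mu = 0, att_ga = 0, acc_ga = 0;
  long long att_si = 0, acc_si = 0, att_ed = 0, acc_ed = 0;
  long long att_or = 0, acc_or = 0;
  int batch_mu = 0, batchacc_mu = 0, batch_ga = 0, batchacc_ga = 0, batch_id = 0;

  std::vector<double> tmp_sel;
  std::vector<int> scan(n_free);
  for (int i = 0; i < n_free; ++i) scan[i] = i;
  int keep_row = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- beta: conjugate Gibbs draw -----------------------------------
    s.beta = R::rgamma(a_beta + m - 1, 1.0 / (b_beta + s.E));

    // --- mu: random-walk Metropolis (graph term = cpois factors only) --
    {
      ++att_mu; ++batch_mu;
      double mu2 = s.mu + sd_mu * norm_rand();
      if (mu2 > 0.0) {
        double d = R::dgamma(mu2, a_mu, 1.0 / b_mu, 1)
                 - R::dgamma(s.mu, a_mu, 1.0 / b_mu, 1);
        for (int k = 2; k < m; ++k)
          d += cpois_lp((int) s.ord[k].size(), mu2, k + 1) - s.step_cp[k];
        if (std::log(unif_rand()) < d) {
          s.mu = mu2;
          for (int k = 2; k < m; ++k) {
            double nc = cpois_lp((int) s.ord[k].size(), s.mu, k + 1);
            s.graph_lp += nc - s.step_cp[k];
            s.step_cp[k] = nc;
          }
          ++acc_mu; ++batchacc_mu;
        }
      }
    }

    // --- gamma: random-walk Metropolis (selection factors only) --------
    if (!gamma_fixed) {
      ++att_ga; ++batch_ga;
      double g2 = s.gamma + sd_gamma * norm_rand();
      if (g2 >= 0.0 && g2 <= 1.0) {
        double gold = s.gamma;
        s.gamma = g2;
        build_deg(s, 2, deg, D);
        sweep_sel(s, 2, m, deg, D, s.pos, tmp_sel);
        double d = 0.0;
        for (int k = 2; k < m; ++k) d += tmp_sel[k - 2] - s.step_sel[k];
        if (std::log(unif_rand()) < d) {
          for (int k = 2; k < m; ++k) { s.graph_lp += tmp_sel[k - 2] - s.step_sel[k]; s.step_sel[k] = tmp_sel[k - 2]; }
          ++acc_ga; ++batchacc_ga;
        } else s.gamma = gold;
      }
    }

    // --- sigma: random transpositions ---------------------------------
    for (int mv = 0; mv < sigma_moves && m > 2; ++mv) {
      ++att_si;
      int p = runif_int(m), q = runif_int(m);
      if (p == q) { ++acc_si; continue; } // identity proposal
      if (p > q) std::swap(p, q);
      int u = s.entry[p], v = s.entry[q];

      std::vector<int> entry2 = s.entry, pos2 = s.pos;
      std::swap(entry2[p], entry2[q]);
      pos2[u] = q; pos2[v] = p;
      if (!s.a(entry2[0], entry2[1])) continue; // dyad broken: reject

      bool ok = true;
      double d = 0.0, lfact = 0.0;
      int lo = std::max(p, 2);
      int hi = (s.gamma != 0.0) ? m : q + 1; // recency ranks shift beyond q
      std::vector<std::vector<int> > new_ord(hi - lo);
      std::vector<char> changed(hi - lo, 0);
      for (int k = lo; k < hi; ++k) {
        bool ch;
        if (k > q) ch = false;
        else if (k == p || k == q) ch = true;
        else {
          int e = entry2[k];
          ch = s.a(e, u) || s.a(e, v);
        }
        changed[k - lo] = ch;
        if (ch) {
          int e = entry2[k];
          std::vector<int> S;
          for (int w = 0; w < m; ++w)
            if (w != e && pos2[w] < k && s.a(e, w)) S.push_back(w);
          if (S.empty()) { ok = false; break; }
          shuffle_vec(S); // uniform order proposal
          lfact += std::lgamma((double) S.size() + 1.0)
                 - std::lgamma((double) s.ord[k].size() + 1.0);
          d += cpois_lp((int) S.size(), s.mu, k + 1) - s.step_cp[k];
          new_ord[k - lo] = S;
        } else new_ord[k - lo] = s.ord[k];
      }
      if (!ok) continue;

      // candidate selection probs over the affected range
      std::vector<std::vector<int> > save_ord(hi - lo);
      for (int k = lo; k < hi; ++k) save_ord[k - lo] = s.ord[k];
      std::vector<int> save_entry = s.entry;
      s.entry = entry2;
      for (int k = lo; k < hi; ++k) s.ord[k] = new_ord[k - lo];
      build_deg(s, lo, deg, D);
      sweep_sel(s, lo, hi, deg, D, pos2, tmp_sel);
      for (int k = lo; k < hi; ++k) d += tmp_sel[k - lo] - s.step_sel[k];

      if (std::isfinite(d + lfact) && std::log(unif_rand()) < d + lfact) {
        s.pos = pos2;
        for (int k = lo; k < hi; ++k) {
          if (changed[k - lo]) {
            double nc = cpois_lp((int) s.ord[k].size(), s.mu, k + 1);
            s.graph_lp += nc - s.step_cp[k];
            s.step_cp[k] = nc;
          }
          s.graph_lp += tmp_sel[k - lo] - s.step_sel[k];
          s.step_sel[k] = tmp_sel[k - lo];
        }
        ++acc_si;
      } else {
        s.entry = save_entry;
        for (int k = lo; k < hi; ++k) s.ord[k] = save_ord[k - lo];
      }
    }

    // --- potential edges: Metropolis flips ----------------------------
    if (n_free > 0) {
      shuffle_vec(scan);
      for (int sc = 0; sc < n_scan; ++sc) {
        ++att_ed;
        int a = freePairs[scan[sc]][0], b = freePairs[scan[sc]][1];
        int ka = s.pos[a], kb = s.pos[b];
        int kl = std::max(ka, kb);
        if (kl <= 1) continue; // sigma1-sigma2 pair: removal unsupported
        int late = s.entry[kl];
        int other = (late == a) ? b : a;
        bool present = s.a(a, b);
        std::vector<int>& o = s.ord[kl];
        int x_old = (int) o.size();

        double d, lcorr;
        std::vector<int> o_new = o;
        if (present) {
          if (x_old == 1) continue; // would strand the entering node
          for (size_t r = 0; r < o_new.size(); ++r)
            if (o_new[r] == other) { o_new.erase(o_new.begin() + r); break; }
          lcorr = -std::log((double) x_old);
          d = s.beta * (s.tI[b] - s.tI[a]);                  // times term
          d += std::log((double) s.nEarly[b])
             - std::log((double) s.nEarly[b] - 1.0);         // tree term
        } else {
          int slot = runif_int(x_old + 1);
          o_new.insert(o_new.begin() + slot, other);
          lcorr = std::log((double) x_old + 1.0);
          d = -s.beta * (s.tI[b] - s.tI[a]);
          d += std::log((double) s.nEarly[b])
             - std::log((double) s.nEarly[b] + 1.0);
        }
        d += cpois_lp((int) o_new.size(), s.mu, kl + 1) - s.step_cp[kl];

        // tentative flip, then recompute selection probs from kl onward
        unsigned char old_adj = s.a(a, b) ? 1 : 0;
        s.set(a, b, 1 - old_adj);
        std::vector<int> o_save = o;
        s.ord[kl] = o_new;
        build_deg(s, kl, deg, D);
        sweep_sel(s, kl, m, deg, D, s.pos, tmp_sel);
        for (int k = kl; k < m; ++k) d += tmp_sel[k - kl] - s.step_sel[k];

        if (std::isfinite(d + lcorr) && std::log(unif_rand()) < d + lcorr) {
          double nc = cpois_lp((int) o_new.size(), s.mu, kl + 1);
          s.graph_lp += nc - s.step_cp[kl];
          s.step_cp[kl] = nc;
          for (int k = kl; k < m; ++k) { s.graph_lp += tmp_sel[k - kl] - s.step_sel[k]; s.step_sel[k] = tmp_sel[k - kl]; }
          if (present) { s.nEarly[b] -= 1; s.E -= s.tI[b] - s.tI[a];
                         s.tree_lp += std::log((double) s.nEarly[b] + 1.0) - std::log((double) s.nEarly[b]); }
          else         { s.nEarly[b] += 1; s.E += s.tI[b] - s.tI[a];
                         s.tree_lp += std::log((double) s.nEarly[b] - 1.0) - std::log((double) s.nEarly[b]); }
          ++acc_ed;
        } else {
          s.set(a, b, old_adj);
          s.ord[kl] = o_save;
        }
      }
    }

    // --- draw-order shuffles (latent-order mixing) ---------------------
    if (order_moves > 0 && m > 2) {
      build_deg(s, 2, deg, D);
      for (int k = 2; k < m; ++k) {
        std::vector<int>& o = s.ord[k];
        if ((int) o.size() >= 2) {
          ++att_or;
          int r = runif_int((int) o.size()), q2 = runif_int((int) o.size());
          if (r != q2) {
            std::swap(o[r], o[q2]);
            double ns = sel_lp(s, k, o, deg, D, s.pos);
            if (std::log(unif_rand()) < ns - s.step_sel[k]) {
              s.graph_lp += ns - s.step_sel[k];
              s.step_sel[k] = ns;
              ++acc_or;
            } else std::swap(o[r], o[q2]);
          } else ++acc_or;
        }
        for (size_t r2 = 0; r2 < o.size(); ++r2) deg[o[r2]] += 1;
        deg[s.entry[k]] += o.size();
        D += 2.0 * o.size();
      }
    }

    // --- adaptation during burn-in ------------------------------------
    if (adapt && it < n_burnin) {
      if (batch_mu >= 50) {
        ++batch_id;
        sd_mu *= std::exp(((double) batchacc_mu / batch_mu - 0.25)
                          / std::sqrt((double) batch_id));
        batch_mu = batchacc_mu = 0;
        if (!gamma_fixed && batch_ga > 0) {
          sd_gamma *= std::exp(((double) batchacc_ga / batch_ga - 0.25)
                               / std::sqrt((double) batch_id));
          batch_ga = batchacc_ga = 0;
        }
      }
    }

    // --- record --------------------------------------------------------
    if (it >= n_burnin && (it - n_burnin) % thin == 0) {
      double lp = s.tree_lp + (m - 1) * std::log(s.beta) - s.beta * s.E
                + s.graph_lp
                + R::dgamma(s.beta, a_beta, 1.0 / b_beta, 1)
                + R::dgamma(s.mu, a_mu, 1.0 / b_mu, 1);
      trace(keep_row, 0) = s.beta;
      trace(keep_row, 1) = s.mu;
      trace(keep_row, 2) = s.gamma;
      trace(keep_row, 3) = lp;
      ++keep_row;
      for (int i = 0; i < m; ++i)
        for (int j = i + 1; j < m; ++j)
          if (s.a(i, j)) efreq(i, j) += 1.0;
    }
  }
  if (n_keep > 0)
    for (int i = 0; i < m; ++i)
      for (int j = i + 1; j < m; ++j) efreq(i, j) /= n_keep;

  // final state (for external consistency checks and restarts)
  IntegerMatrix adj_out(m, m);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j) adj_out(i, j) = s.adj[i * m + j];
  List ord_out(m);
  for (int k = 0; k < m; ++k) {
    IntegerVector ok((int) s.ord[k].size());
    for (size_t r = 0; r < s.ord[k].size(); ++r) ok[r] = s.ord[k][r] + 1;
    ord_out[k] = ok;
  }
  IntegerVector entry_out(m);
  for (int k = 0; k < m; ++k) entry_out[k] = s.entry[k] + 1;

  return List::create(
    _["trace"] = trace,
    _["edge_freq"] = efreq,
    _["acceptance"] = List::create(
      _["mu"] = NumericVector::create((double) acc_mu, (double) att_mu),
      _["gamma"] = NumericVector::create((double) acc_ga, (double) att_ga),
      _["sigma"] = NumericVector::create((double) acc_si, (double) att_si),
      _["edges"] = NumericVector::create((double) acc_ed, (double) att_ed),
      _["order"] = NumericVector::create((double) acc_or, (double) att_or)),
    _["final"] = List::create(
      _["beta"] = s.beta, _["mu"] = s.mu, _["gamma"] = s.gamma,
      _["entry"] = entry_out, _["adj"] = adj_out, _["orders"] = ord_out,
      _["graph_lp"] = s.graph_lp, _["exposure"] = s.E, _["tree_lp"] = s.tree_lp,
      _["sd_mu"] = sd_mu, _["sd_gamma"] = sd_gamma));
}

// [[Rcpp::export]]
List cpp_mwg_brg(int m, NumericVector times, IntegerVector parent1,
                 IntegerMatrix status, double beta0, double p0,
                 double a_beta, double b_beta, double a_p, double b_p,
                 int n_iter, int n_burnin, int thin) {
  RNGScope scope;
  std::vector<unsigned char> adj((size_t) m * m, 0);
  std::vector<double> tI(times.begin(), times.end());
  std::vector<int> nEarly(m, 0);
  double E = 0.0;
  long long nedge = 0;
  std::vector<std::array<int, 2> > freePairs;
  for (int i = 0; i < m; ++i)
    for (int j = i + 1; j < m; ++j) {
      if (status(i, j) == 1) {
        adj[i * m + j] = adj[j * m + i] = 1;
        nEarly[j] += 1; E += tI[j] - tI[i]; ++nedge;
      } else if (status(i, j) == 0) {
        std::array<int, 2> pr = {{i, j}}; freePairs.push_back(pr);
      }
    }
  double npairs = 0.5 * m * (m - 1.0);
  double beta = beta0, p = p0;

  int n_keep = 0;
  for (int it = n_burnin; it < n_iter; ++it) if ((it - n_burnin) % thin == 0) ++n_keep;
  NumericMatrix trace(n_keep, 3);
  NumericMatrix efreq(m, m);
  long long att_ed = 0, acc_ed = 0;
  std::vector<int> scan((int) freePairs.size());
  for (size_t i = 0; i < freePairs.size(); ++i) scan[i] = (int) i;
  int keep_row = 0;

  for (int it = 0; it < n_iter; ++it) {
    beta = R::rgamma(a_beta + m - 1, 1.0 / (b_beta + E));
    p = R::rbeta(a_p + nedge, b_p + npairs - nedge);
    double lodds = std::log(p) - std::log1p(-p);
    shuffle_vec(scan);
    for (size_t sc = 0; sc < scan.size(); ++sc) {
      ++att_ed;
      int a = freePairs[scan[sc]][0], b = freePairs[scan[sc]][1];
      bool present = adj[a * m + b] != 0;
      double d;
      if (present) {
        if (nEarly[b] == 1) continue; // would orphan b in the tree factor
        d = beta * (tI[b] - tI[a]) - lodds
          + std::log((double) nEarly[b]) - std::log((double) nEarly[b] - 1.0);
      } else {
        d = -beta * (tI[b] - tI[a]) + lodds
          + std::log((double) nEarly[b]) - std::log((double) nEarly[b] + 1.0);
      }
      if (std::log(unif_rand()) < d) {
        if (present) { adj[a * m + b] = adj[b * m + a] = 0; nEarly[b] -= 1;
                       E -= tI[b] - tI[a]; --nedge; }
        else         { adj[a * m + b] = adj[b * m + a] = 1; nEarly[b] += 1;
                       E += tI[b] - tI[a]; ++nedge; }
        ++acc_ed;
      }
    }
    if (it >= n_burnin && (it - n_burnin) % thin == 0) {
      double tree_lp = 0.0;
      for (int j = 1; j < m; ++j) tree_lp -= std::log((double) nEarly[j]);
      double lp = tree_lp + (m - 1) * std::log(beta) - beta * E
                + nedge * std::log(p) + (npairs - nedge) * std::log1p(-p)
                + R::dgamma(beta, a_beta, 1.0 / b_beta, 1)
                + R::dbeta(p, a_p, b_p, 1);
      trace(keep_row, 0) = beta;
      trace(keep_row, 1) = p;
      trace(keep_row, 2) = lp;
      ++keep_row;
      for (int i = 0; i < m; ++i)
        for (int j = i + 1; j < m; ++j)
          if (adj[i * m + j]) efreq(i, j) += 1.0;
    }
  }
  if (n_keep > 0)
    for (int i = 0; i < m; ++i)
      for (int j = i + 1; j < m; ++j) efreq(i, j) /= n_keep;

  return List::create(
    _["trace"] = trace,
    _["edge_freq"] = efreq,
    _["acceptance"] = List::create(
      _["edges"] = NumericVector::create((double) acc_ed, (double) att_ed)));
}
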