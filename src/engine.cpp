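// Discrete-time simulation core: Izhikevich dynamics, delayed delta-pulse
// synapses, and online nearest-only mixed STDP. One call simulates one
// presentation; neuron state starts at the supplied rest values and plastic
// weights are passed in and returned (the R side carries them across
// presentations).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

struct Group {
  int n;
  bool is_input;
  double a, b, c, d, threshold, v0, u0;
  std::vector<double> v, u, I;
  double last_post_init;
  std::vector<double> last_post;   // ms, -inf if never
  bool record;
};

struct Proj {
  int src, dst;
  std::vector<int> pre, post;
  std::vector<double> w;
  std::vector<int> delay;          // steps, >= 1
  bool plastic;
  double tau_p, tau_d, alpha_p, alpha_d, w_max, window, blank;
  // CSR by pre (outgoing) and by post (afferent)
  std::vector<int> out_ptr, out_idx, aff_ptr, aff_idx;
  // arrival ring: synapse indices arriving at each future step
  std::vector<std::vector<int> > ring;
  int ring_len;
  // STDP ledger
  std::vector<double> pending, last_seen;
  std::vector<char> used;
};

static void build_csr(const std::vector<int>& key, int nkey,
                      std::vector<int>& ptr, std::vector<int>& idx) {
  int m = key.size();
  ptr.assign(nkey + 1, 0);
  for (int k = 0; k < m; ++k) ptr[key[k] + 1]++;
  for (int i = 0; i < nkey; ++i) ptr[i + 1] += ptr[i];
  idx.assign(m, 0);
  std::vector<int> cur(ptr.begin(), ptr.end() - 1);
  for (int k = 0; k < m; ++k) idx[cur[key[k]]++] = k;
}

// [[Rcpp::export]]
List engine_run(List groups_in, List projections_in, List input_spikes,
                int n_steps, double dt, bool learn) {
  const double NEG_INF = -std::numeric_limits<double>::infinity();
  int n_groups = groups_in.size();
  std::vector<Group> G(n_groups);
  for (int g = 0; g < n_groups; ++g) {
    List gl = groups_in[g];
    Group& gr = G[g];
    gr.n = as<int>(gl["n"]);
    gr.is_input = as<bool>(gl["is_input"]);
    gr.record = as<bool>(gl["record"]);
    if (!gr.is_input) {
      gr.a = as<double>(gl["a"]); gr.b = as<double>(gl["b"]);
      gr.c = as<double>(gl["c"]); gr.d = as<double>(gl["d"]);
      gr.threshold = as<double>(gl["threshold"]);
      gr.v0 = as<double>(gl["v0"]); gr.u0 = as<double>(gl["u0"]);
      gr.v.assign(gr.n, gr.v0);
      gr.u.assign(gr.n, gr.u0);
      gr.I.assign(gr.n, 0.0);
    }
    gr.last_post.assign(gr.n, NEG_INF);
  }

  int n_proj = projections_in.size();
  std::vector<Proj> P(n_proj);
  for (int p = 0; p < n_proj; ++p) {
    List pl = projections_in[p];
    Proj& pr = P[p];
    pr.src = as<int>(pl["src"]); pr.dst = as<int>(pl["dst"]);
    IntegerVector pre = pl["pre"], post = pl["post"], delay = pl["delay"];
    NumericVector w = pl["w"];
    pr.pre.assign(pre.begin(), pre.end());
    pr.post.assign(post.begin(), post.end());
    pr.w.assign(w.begin(), w.end());
    pr.delay.assign(delay.begin(), delay.end());
    pr.plastic = as<bool>(pl["plastic"]);
    int maxd = 1;
    for (size_t k = 0; k < pr.delay.size(); ++k) {
      if (pr.delay[k] < 1) stop("projection delay must be >= 1 step");
      if (pr.delay[k] > maxd) maxd = pr.delay[k];
    }
    pr.ring_len = maxd + 1;
    pr.ring.assign(pr.ring_len, std::vector<int>());
    build_csr(pr.pre, G[pr.src].n, pr.out_ptr, pr.out_idx);
    if (pr.plastic) {
      pr.tau_p = as<double>(pl["tau_p"]); pr.tau_d = as<double>(pl["tau_d"]);
      pr.alpha_p = as<double>(pl["alpha_p"]);
      pr.alpha_d = as<double>(pl["alpha_d"]);
      pr.w_max = as<double>(pl["w_max"]);
      pr.window = as<double>(pl["window"]);
      pr.blank = as<double>(pl["blank"]);
      build_csr(pr.post, G[pr.dst].n, pr.aff_ptr, pr.aff_idx);
      pr.pending.assign(pr.w.size(), NEG_INF);
      pr.last_seen.assign(pr.w.size(), NEG_INF);
      pr.used.assign(pr.w.size(), 1);
    }
  }

  // input spikes grouped by step for each input group
  std::vector<std::vector<std::vector<int> > > inp(n_groups);
  for (int g = 0; g < n_groups; ++g) {
    if (!G[g].is_input) continue;
    inp[g].assign(n_steps, std::vector<int>());
    List sp = input_spikes[g];
    IntegerVector nrn = sp["neuron"], stp = sp["step"];
    for (int k = 0; k < nrn.size(); ++k) {
      if (stp[k] < 0 || stp[k] >= n_steps) continue;
      if (nrn[k] < 0 || nrn[k] >= G[g].n)
        stop("input neuron index out of range");
      inp[g][stp[k]].push_back(nrn[k]);
    }
  }

  std::vector<std::vector<int> > rec_n(n_groups), rec_t(n_groups);
  std::vector<std::vector<int> > spiking(n_groups);

  for (int t = 0; t < n_steps; ++t) {
    double t_ms = t * dt;
    // 1. reset currents to external drive (0)
    for (int g = 0; g < n_groups; ++g)
      if (!G[g].is_input) std::fill(G[g].I.begin(), G[g].I.end(), 0.0);

    // 2. process synaptic arrivals due this step: deliver current, and for
    //    plastic projections do the pre-arrival STDP bookkeeping (LTD
    //    against the most recent post spike; register LTP candidate)
    for (int p = 0; p < n_proj; ++p) {
      Proj& pr = P[p];
      std::vector<int>& due = pr.ring[t % pr.ring_len];
      if (due.empty()) continue;
      Group& dst = G[pr.dst];
      for (size_t q = 0; q < due.size(); ++q) {
        int k = due[q];
        dst.I[pr.post[k]] += pr.w[k];
        if (pr.plastic && learn) {
          // first-spike-only: a second spike of the same cell arriving
          // within `blank` (the STDP time-constant scale) of the previous
          // counted arrival is ignored; otherwise the arrival becomes the
          // nearest (most recent) LTP candidate and pairs for LTD
          double lp = dst.last_post[pr.post[k]];
          bool first = pr.last_seen[k] <= lp ||
                       t_ms - pr.last_seen[k] > pr.blank;
          if (!first) continue;
          pr.last_seen[k] = t_ms;
          pr.pending[k] = t_ms;
          pr.used[k] = 0;
          if (lp > NEG_INF) {
            double s = lp - t_ms;                // <= -dt < 0
            if (-s <= pr.window) {
              double w2 = pr.w[k] +
                pr.w_max * pr.alpha_d * std::exp(s / pr.tau_d);
              pr.w[k] = w2 > 0.0 ? w2 : 0.0;
            }
          }
        }
      }
      due.clear();
    }

    // 3. advance neurons / read out input spikes
    for (int g = 0; g < n_groups; ++g) {
      Group& gr = G[g];
      spiking[g].clear();
      if (gr.is_input) {
        spiking[g] = inp[g][t];
      } else {
        for (int i = 0; i < gr.n; ++i) {
          double v = gr.v[i], u = gr.u[i];
          double v1 = v + dt * (0.04 * v * v + 5.0 * v + 140.0 - u + gr.I[i]);
          double u1 = u + dt * (gr.a * (gr.b * v - u));
          if (!R_finite(v1) || !R_finite(u1))
            stop("non-finite neuron state: integration blow-up");
          if (v1 >= gr.threshold) {
            gr.v[i] = gr.c;
            gr.u[i] = u1 + gr.d;
            spiking[g].push_back(i);
          } else {
            gr.v[i] = v1;
            gr.u[i] = u1;
          }
        }
      }
      if (gr.record) {
        for (size_t q = 0; q < spiking[g].size(); ++q) {
          rec_n[g].push_back(spiking[g][q]);
          rec_t[g].push_back(t);
        }
      }
    }

    // 4. post-synaptic spikes: LTP pairings, then update last_post
    if (learn) {
      for (int p = 0; p < n_proj; ++p) {
        Proj& pr = P[p];
        if (!pr.plastic) continue;
        const std::vector<int>& sp = spiking[pr.dst];
        for (size_t q = 0; q < sp.size(); ++q) {
          int i = sp[q];
          for (int a = pr.aff_ptr[i]; a < pr.aff_ptr[i + 1]; ++a) {
            int k = pr.aff_idx[a];
            if (pr.used[k]) continue;
            double s = t_ms - pr.pending[k];
            if (s > 0.0 && s <= pr.window) {
              pr.w[k] += (pr.w_max - pr.w[k]) *
                pr.alpha_p * std::exp(-s / pr.tau_p);
              pr.used[k] = 1;
            }
          }
        }
      }
    }
    for (int g = 0; g < n_groups; ++g)
      for (size_t q = 0; q < spiking[g].size(); ++q)
        G[g].last_post[spiking[g][q]] = t_ms;

    // 5. schedule outgoing deliveries
    for (int p = 0; p < n_proj; ++p) {
      Proj& pr = P[p];
      const std::vector<int>& sp = spiking[pr.src];
      for (size_t q = 0; q < sp.size(); ++q) {
        int j = sp[q];
        for (int a = pr.out_ptr[j]; a < pr.out_ptr[j + 1]; ++a) {
          int k = pr.out_idx[a];
          pr.ring[(t + pr.delay[k]) % pr.ring_len].push_back(k);
        }
      }
    }
  }

  List spikes(n_groups), weights(n_proj);
  for (int g = 0; g < n_groups; ++g)
    spikes[g] = List::create(_["neuron"] = wrap(rec_n[g]),
                             _["step"] = wrap(rec_t[g]));
  for (int p = 0; p < n_proj; ++p)
    weights[p] = wrap(P[p].w);
  return List::create(_["spikes"] = spikes, _["weights"] = weights);
}
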