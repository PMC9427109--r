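// Forward Wright-Fisher core for a balanced two-arrangement supergene.
//
// Haplotypes are byte rows over the currently segregating site list
// (finite sites on an integer grid; collisions re-drawn).  Arrangement
// labels (0 = standard, 1 = rearranged) travel with the interval that
// contributes the inversion span of each gamete.  Selection is viability
// selection applied at parent sampling; mating is disassortative with
// fidelity f.  All randomness comes from R's RNG, so runs are
// reproducible from set.seed() on the R side.

#include <Rcpp.h>
#include <cstring>
#include <unordered_set>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Pop {
  int two_n;
  int cap;
  int s;                      // active site count
  std::vector<uint8_t> cur;   // two_n rows of cap bytes
  std::vector<uint8_t> nxt;
  std::vector<uint8_t> lab;   // per current haplotype
  std::vector<uint8_t> nxt_lab;
  std::vector<int> pos;       // 0-based site positions, unsorted
  std::unordered_set<int> posset;

  uint8_t* row(int h) { return cur.data() + (size_t)h * cap; }
  uint8_t* nrow(int h) { return nxt.data() + (size_t)h * cap; }

  void grow(int need) {
    if (need <= cap) return;
    int cap2 = std::max(need, cap + cap / 2 + 256);
    std::vector<uint8_t> c2((size_t)two_n * cap2, 0), n2((size_t)two_n * cap2, 0);
    for (int h = 0; h < two_n; ++h) {
      std::memcpy(c2.data() + (size_t)h * cap2, row(h), s);
      std::memcpy(n2.data() + (size_t)h * cap2, nrow(h), s);
    }
    cur.swap(c2);
    nxt.swap(n2);
    cap = cap2;
  }
};

int wsample(const std::vector<double>& cum) {
  double u = unif_rand() * cum.back();
  return (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
}

} // namespace

// [[Rcpp::export(name = ".wf_simulate_cpp")]]
List wf_simulate_cpp(int n_ind, double contig_length, double inv_a, double inv_b,
                     double mu, double rec, double c_suppress, double fidelity,
                     int generations,
                     IntegerVector init_pos, IntegerMatrix init_haps,
                     IntegerVector init_labels,
                     bool has_sweep, double sweep_pos, int sweep_class,
                     double sweep_s, int sweep_start,
                     bool has_bal, double bal_pos, double bal_s,
                     int prune_every) {
  const int two_n = 2 * n_ind;
  const double L = contig_length;
  const double inv_len = inv_b - inv_a;
  if (init_haps.ncol() != two_n)
    stop("init_haps must have 2*n_ind columns");

  Pop P;
  P.two_n = two_n;
  P.s = init_pos.size();
  P.cap = P.s + 1024;
  P.cur.assign((size_t)two_n * P.cap, 0);
  P.nxt.assign((size_t)two_n * P.cap, 0);
  P.lab.resize(two_n);
  P.nxt_lab.resize(two_n);
  P.pos.resize(P.s);
  for (int j = 0; j < P.s; ++j) {
    P.pos[j] = init_pos[j];
    P.posset.insert(init_pos[j]);
  }
  for (int h = 0; h < two_n; ++h) {
    P.lab[h] = (uint8_t)init_labels[h];
    uint8_t* r = P.row(h);
    for (int j = 0; j < P.s; ++j) r[j] = (uint8_t)init_haps(j, h);
  }

  int sweep_idx = -1, bal_idx = -1;
  bool sweep_done = false;
  int sweep_intro_gen = -1, sweep_fix_gen = -1;
  if (has_bal) {
    for (int j = 0; j < P.s; ++j)
      if (P.pos[j] == (int)bal_pos) { bal_idx = j; break; }
    if (bal_idx < 0) stop("balanced locus position not present in initial sites");
  }

  NumericVector freq_m(generations);
  IntegerMatrix morph_counts(3, generations);

  std::vector<double> fit(n_ind);
  std::vector<int> cnt;
  std::vector<std::pair<int, int> > pending; // (hap row, position)
  std::vector<double> bps;

  for (int gen = 0; gen < generations; ++gen) {
    // ---- morphs and fitness -------------------------------------------
    int n_m_hap = 0;
    for (int h = 0; h < two_n; ++h) n_m_hap += P.lab[h];
    if (n_m_hap == 0 || n_m_hap == two_n)
      stop("arrangement extinction at generation %d", gen);

    double bal_mult = 1.0;
    if (has_bal && bal_idx >= 0) {
      int a_on_m = 0;
      for (int h = 0; h < two_n; ++h)
        if (P.lab[h] == 1 && P.row(h)[bal_idx] == 1) ++a_on_m;
      double fr = (double)a_on_m / (double)n_m_hap;
      bal_mult = 1.0 + bal_s * (0.5 - fr);
      if (bal_mult < 0.0) bal_mult = 0.0;
    }
    bool sweep_on = has_sweep && sweep_idx >= 0 && !sweep_done;

    std::vector<int> ts, ws;
    std::vector<double> cum_ts, cum_ws, cum_all;
    cum_all.reserve(n_ind);
    double tot_all = 0;
    for (int i = 0; i < n_ind; ++i) {
      int h1 = 2 * i, h2 = 2 * i + 1;
      int nm = P.lab[h1] + P.lab[h2];
      double w = 1.0;
      if (sweep_on) {
        if (P.lab[h1] == sweep_class && P.row(h1)[sweep_idx] == 1) w *= 1.0 + sweep_s;
        if (P.lab[h2] == sweep_class && P.row(h2)[sweep_idx] == 1) w *= 1.0 + sweep_s;
      }
      if (has_bal && bal_idx >= 0) {
        if (P.lab[h1] == 1 && P.row(h1)[bal_idx] == 1) w *= bal_mult;
        if (P.lab[h2] == 1 && P.row(h2)[bal_idx] == 1) w *= bal_mult;
      }
      fit[i] = w;
      tot_all += w;
      cum_all.push_back(tot_all);
      if (nm == 0) {
        ts.push_back(i);
        cum_ts.push_back((cum_ts.empty() ? 0.0 : cum_ts.back()) + w);
      } else if (nm == 1) {
        ws.push_back(i);
        cum_ws.push_back((cum_ws.empty() ? 0.0 : cum_ws.back()) + w);
      }
      morph_counts(nm, gen) += 1;
    }
    freq_m[gen] = (double)n_m_hap / (double)two_n;

    // ---- offspring -----------------------------------------------------
    pending.clear();
    for (int k = 0; k < n_ind; ++k) {
      int pa, pb;
      if (unif_rand() < fidelity && !ts.empty() && !ws.empty()) {
        pa = ws[wsample(cum_ws)];
        pb = ts[wsample(cum_ts)];
      } else {
        pa = wsample(cum_all);
        do { pb = wsample(cum_all); } while (pb == pa && n_ind > 1);
      }
      const int parents[2] = { pa, pb };
      for (int g = 0; g < 2; ++g) {
        int p = parents[g];
        int child = 2 * k + g;
        int h0 = 2 * p + (unif_rand() < 0.5 ? 1 : 0);
        int h1 = (h0 % 2 == 0) ? h0 + 1 : h0 - 1;
        bool het = P.lab[2 * p] != P.lab[2 * p + 1];
        double lam_in = rec * (het ? c_suppress : 1.0) * inv_len;
        double lam_out = rec * (L - inv_len);
        int nin = (int)R::rpois(lam_in);
        int nout = (int)R::rpois(lam_out);
        uint8_t* cr = P.nrow(child);
        if (nin + nout == 0) {
          std::memcpy(cr, P.row(h0), P.s);
          P.nxt_lab[child] = P.lab[h0];
        } else {
          bps.clear();
          for (int t = 0; t < nin; ++t) bps.push_back(inv_a + unif_rand() * inv_len);
          for (int t = 0; t < nout; ++t) {
            double u = unif_rand() * (L - inv_len);
            bps.push_back(u < inv_a ? u : u + inv_len);
          }
          std::sort(bps.begin(), bps.end());
          const uint8_t* r0 = P.row(h0);
          const uint8_t* r1 = P.row(h1);
          const int nbp = (int)bps.size();
          const double* bp = bps.data();
          for (int j = 0; j < P.s; ++j) {
            const double pj = (double)P.pos[j];
            int nb = 0;
            while (nb < nbp && bp[nb] < pj) ++nb;  // few breakpoints: linear
            cr[j] = (nb % 2 == 0) ? r0[j] : r1[j];
          }
          int nb_a = 0;
          while (nb_a < nbp && bp[nb_a] < inv_a) ++nb_a;
          P.nxt_lab[child] = (nb_a % 2 == 0) ? P.lab[h0] : P.lab[h1];
        }
        int nmut = (int)R::rpois(mu * L);
        for (int t = 0; t < nmut; ++t)
          pending.push_back(std::make_pair(child, (int)(unif_rand() * L)));
      }
    }

    // ---- new mutations (tail slots beyond s are kept zeroed) -----------
    for (size_t q = 0; q < pending.size(); ++q) {
      int ppos = pending[q].second;
      int tries = 0;
      while (P.posset.count(ppos) && tries < 200) {
        ppos = (int)(unif_rand() * L);
        ++tries;
      }
      if (P.posset.count(ppos)) continue; // grid saturated; drop
      P.grow(P.s + 1);
      P.nrow(pending[q].first)[P.s] = 1;
      P.pos.push_back(ppos);
      P.posset.insert(ppos);
      ++P.s;
    }

    P.cur.swap(P.nxt);
    P.lab.swap(P.nxt_lab);

    // ---- sweep bookkeeping --------------------------------------------
    if (has_sweep && gen >= sweep_start && !sweep_done) {
      if (sweep_idx < 0) {
        int sp = (int)sweep_pos;
        for (int j = 0; j < P.s; ++j)
          if (P.pos[j] == sp) { sweep_idx = j; break; }
        if (sweep_idx < 0) {
          P.grow(P.s + 1);
          for (int h = 0; h < two_n; ++h) { P.row(h)[P.s] = 0; P.nrow(h)[P.s] = 0; }
          P.pos.push_back(sp);
          P.posset.insert(sp);
          sweep_idx = P.s;
          ++P.s;
        }
        sweep_intro_gen = gen;
      }
      int on_class = 0, n_class = 0;
      for (int h = 0; h < two_n; ++h) {
        if (P.lab[h] == sweep_class) {
          ++n_class;
          if (P.row(h)[sweep_idx] == 1) ++on_class;
        }
      }
      if (on_class == 0 && n_class > 0) {
        // condition on establishment: re-introduce on a random class haplotype
        int pick = (int)(unif_rand() * n_class), seen = 0;
        for (int h = 0; h < two_n; ++h) {
          if (P.lab[h] == sweep_class) {
            if (seen == pick) { P.row(h)[sweep_idx] = 1; break; }
            ++seen;
          }
        }
      } else if (on_class == n_class && n_class > 0) {
        sweep_done = true;
        sweep_fix_gen = gen;
      }
    }

    // ---- pruning of lost / globally fixed sites ------------------------
    bool last = (gen == generations - 1);
    if (gen % prune_every == 0 || last) {
      cnt.assign(P.s, 0);
      for (int h = 0; h < two_n; ++h) {
        const uint8_t* r = P.row(h);
        for (int j = 0; j < P.s; ++j) cnt[j] += r[j];
      }
      // stable in-place compaction of surviving sites, tails re-zeroed
      std::vector<int> newidx(P.s, -1);
      int s_new = 0;
      for (int j = 0; j < P.s; ++j) {
        if (cnt[j] == 0 || cnt[j] == two_n) {
          P.posset.erase(P.pos[j]);
        } else {
          newidx[j] = s_new++;
        }
      }
      if (s_new != P.s) {
        for (int h = 0; h < two_n; ++h) {
          uint8_t* r = P.row(h);
          uint8_t* nr = P.nrow(h);
          for (int j = 0; j < P.s; ++j) {
            int nj = newidx[j];
            if (nj >= 0) { r[nj] = r[j]; nr[nj] = nr[j]; }
          }
          std::memset(r + s_new, 0, P.s - s_new);
          std::memset(nr + s_new, 0, P.s - s_new);
        }
        for (int j = 0; j < P.s; ++j)
          if (newidx[j] >= 0) P.pos[newidx[j]] = P.pos[j];
        P.pos.resize(s_new);
        if (sweep_idx >= 0) {
          sweep_idx = newidx[sweep_idx];
          if (sweep_idx < 0) { sweep_done = true; sweep_idx = -1; }
        }
        if (bal_idx >= 0) bal_idx = newidx[bal_idx];
        if (bal_idx < 0) bal_idx = -1;
        P.s = s_new;
      }
    }
  }

  // ---- export, sites sorted by position --------------------------------
  std::vector<int> ord(P.s);
  for (int j = 0; j < P.s; ++j) ord[j] = j;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return P.pos[a] < P.pos[b]; });
  IntegerVector out_pos(P.s);
  IntegerMatrix out_haps(P.s, two_n);
  for (int j = 0; j < P.s; ++j) {
    out_pos[j] = P.pos[ord[j]];
    for (int h = 0; h < two_n; ++h) out_haps(j, h) = P.row(h)[ord[j]];
  }
  IntegerVector out_lab(two_n);
  for (int h = 0; h < two_n; ++h) out_lab[h] = P.lab[h];

  return List::create(
    _["pos"] = out_pos, _["haps"] = out_haps, _["labels"] = out_lab,
    _["freq_m"] = freq_m, _["morph_counts"] = morph_counts,
    _["sweep_intro_gen"] = sweep_intro_gen, _["sweep_fix_gen"] = sweep_fix_gen);
}
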