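// Stochastic tau-leaping core for the bacteria-phage Lotka-Volterra community
// with horizontal gene transfer over combinatorial genotypes.
//
// All randomness goes through R's RNG (unif_rand / R::rpois), so a single
// set.seed() on the R side makes every run bit-reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted index draw from integer counts; `total` must equal sum(w) > 0.
static int sample_counts(const std::vector<int>& w, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  int last = -1;
  const int n = (int)w.size();
  for (int i = 0; i < n; ++i) {
    if (w[i] > 0) {
      last = i;
      acc += w[i];
      if (u < acc) return i;
    }
  }
  return last; // guard against floating-point shortfall
}

static long long vec_sum(const std::vector<int>& v) {
  long long s = 0;
  for (size_t i = 0; i < v.size(); ++i) s += v[i];
  return s;
}

// One tau-leap of the Poisson reproduction framework: each individual of a
// strain with per-capita fitness f leaves Pois(1 + f dt) descendants, so the
// strain is resampled as n' ~ Pois(n (1 + f dt)). The mean is clamped at
// zero (a strain driven below -1/dt fitness is wiped out in one leap), empty
// strains receive no events, and the per-step demographic variance is ~n
// independent of s and omega -- which is what makes the effective
// temperatures scale as 1/(2r) rather than with the division rate.
static void demographic_update(std::vector<int>& n, const std::vector<double>& f,
                               double dt) {
  const int K = (int)n.size();
  for (int k = 0; k < K; ++k) {
    if (n[k] <= 0) continue;
    double mean = (double)n[k] * (1.0 + f[k] * dt);
    if (mean <= 0.0) { n[k] = 0; continue; }
    n[k] = (int)R::rpois(mean);
  }
}

// `nev` attempted single-gene transfer events into `rec`; the gene donor pool
// is `donor` (alias rec for the intra-bacterial channel). Events producing a
// duplicate gene, the unchanged genotype, or an out-of-space tuple are no-ops.
// Total counts in rec are conserved (one individual moves between genotypes).
static void hgt_events(std::vector<int>& rec, const std::vector<int>& donor,
                       const IntegerMatrix& genes, const IntegerVector& idx_lookup,
                       int L, int g, int nev) {
  double rtot = (double)vec_sum(rec);
  double dtot = (&rec == &donor) ? rtot : (double)vec_sum(donor);
  if (rtot <= 0 || dtot <= 0) return;
  std::vector<int> tup(g);
  for (int e = 0; e < nev; ++e) {
    int k1 = sample_counts(rec, rtot);
    if (k1 < 0 || rec[k1] == 0) continue;
    int k2 = sample_counts(donor, dtot);
    if (k2 < 0) continue;
    int gene_in = genes(k2, (int)(unif_rand() * g) % g);
    int slot = (int)(unif_rand() * g) % g;
    bool noop = false;
    for (int j = 0; j < g; ++j) {
      tup[j] = genes(k1, j);
      if (j != slot && tup[j] == gene_in) noop = true; // duplicate gene
    }
    if (noop || tup[slot] == gene_in) continue;        // duplicate or identity
    tup[slot] = gene_in;
    std::sort(tup.begin(), tup.end());
    long long code = 0;
    for (int j = 0; j < g; ++j) code = code * L + tup[j];
    int kp = idx_lookup[code];
    if (kp < 0 || kp == k1) continue;
    rec[k1] -= 1;
    rec[kp] += 1;
  }
}

// Restore sum(n) to `target` exactly. Additions: multinomial with weights
// frozen at entry. Removals: sequential draws proportional to the *current*
// counts, which caps removals at abundance and resamples among survivors.
// Returns true on global extinction (sum zero with positive target).
static bool regulate_side(std::vector<int>& n, int target) {
  if (target <= 0) return false; // side not in play
  long long tot = vec_sum(n);
  if (tot == 0) return true;
  long long d = (long long)target - tot;
  if (d > 0) {
    std::vector<int> w = n;
    double wt = (double)tot;
    for (long long i = 0; i < d; ++i) {
      int k = sample_counts(w, wt);
      if (k >= 0) n[k] += 1;
    }
  } else if (d < 0) {
    double cur = (double)tot;
    for (long long i = 0; i < -d; ++i) {
      int k = sample_counts(n, cur);
      if (k >= 0) { n[k] -= 1; cur -= 1.0; }
    }
  }
  return false;
}

// [[Rcpp::export]]
IntegerVector demographic_step_cpp(IntegerVector n, NumericVector f, double dt) {
  std::vector<int> x = as< std::vector<int> >(n);
  std::vector<double> ff = as< std::vector<double> >(f);
  demographic_update(x, ff, dt);
  return wrap(x);
}

// [[Rcpp::export]]
IntegerVector hgt_step_cpp(IntegerVector recipients, IntegerVector donors,
                           bool same_pool, IntegerMatrix genes,
                           IntegerVector idx_lookup, int L, int g,
                           double rate, double dt) {
  std::vector<int> rec = as< std::vector<int> >(recipients);
  long long tot = vec_sum(rec);
  int nev = (int)R::rpois(rate * (double)tot * dt);
  if (same_pool) {
    hgt_events(rec, rec, genes, idx_lookup, L, g, nev);
  } else {
    std::vector<int> don = as< std::vector<int> >(donors);
    hgt_events(rec, don, genes, idx_lookup, L, g, nev);
  }
  return wrap(rec);
}

// [[Rcpp::export]]
List regulate_cpp(IntegerVector n, int target) {
  std::vector<int> x = as< std::vector<int> >(n);
  bool extinct = regulate_side(x, target);
  return List::create(_["n"] = wrap(x), _["extinct"] = extinct);
}

// Full simulation loop. Detection of gene/genotype zeros runs at step
// resolution; abundances are recorded every `record_every` steps plus the
// final step. Termination codes: 0 horizon, 1 bacterial global extinction,
// 2 phage global extinction, 3 stop-on-gene-loss, 4 stop-on-genotype-loss.
// stop_mode bitmask: 1 = stop at first gene loss (either side),
//                    2 = stop at first genotype zero-touch (either side).
// [[Rcpp::export]]
List run_core(IntegerMatrix genes, IntegerVector idx_lookup, int L, int g,
              Nullable<NumericMatrix> M_,
              IntegerVector B0, IntegerVector V0,
              double s, double omega, double rB, double rV, int phage_mode,
              int NB_target, int NV_target, double nBstar, double nVstar,
              double dt, int n_steps, int record_every,
              bool regulate_exact, int stop_mode) {
  const int K = genes.nrow();
  std::vector<int> B = as< std::vector<int> >(B0);
  std::vector<int> V = as< std::vector<int> >(V0);
  std::vector<double> fB(K), fV(K), MV(K), MtB(K);
  const bool matched = M_.isNull();
  NumericMatrix M;
  if (!matched) M = NumericMatrix(M_);
  const bool phage_on = NV_target > 0;

  const int n_rec_max = n_steps / std::max(1, record_every) + 2;
  NumericVector rec_t(n_rec_max);
  IntegerMatrix recB(n_rec_max, K), recV(n_rec_max, K);
  IntegerMatrix recGB(n_rec_max, L), recGV(n_rec_max, L);
  IntegerVector rec_zt(n_rec_max);

  NumericVector fgzB(L, -1.0), fgzV(L, -1.0);       // first gene-zero times
  NumericVector fGzB(K, -1.0), fGzV(K, -1.0);       // first genotype-zero times
  NumericVector lGzB(K, -1.0), lGzV(K, -1.0);       // last genotype-zero times
  std::vector<int> gb(L), gv(L);
  std::vector<char> prevB_zero(K), prevV_zero(K);
  long long zero_touch = 0;
  int termination = 0;
  double t = 0.0;
  int r_used = 0;

  // detection + optional recording; returns bitmask: 1 new gene loss,
  // 2 genotype zero-touch transition
  auto detect = [&](double tnow, bool record, bool initial) -> int {
    int flags = 0;
    std::fill(gb.begin(), gb.end(), 0);
    std::fill(gv.begin(), gv.end(), 0);
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < g; ++j) {
        gb[genes(k, j)] += B[k];
        gv[genes(k, j)] += V[k];
      }
    for (int l = 0; l < L; ++l) {
      if (gb[l] == 0 && fgzB[l] < 0) { fgzB[l] = tnow; flags |= 1; }
      if (phage_on && gv[l] == 0 && fgzV[l] < 0) { fgzV[l] = tnow; flags |= 1; }
    }
    for (int k = 0; k < K; ++k) {
      bool bz = B[k] == 0;
      if (bz) {
        if (fGzB[k] < 0) fGzB[k] = tnow;
        lGzB[k] = tnow;
        if (!initial && !prevB_zero[k]) { zero_touch += 1; flags |= 2; }
      }
      prevB_zero[k] = bz;
      if (phage_on) {
        bool vz = V[k] == 0;
        if (vz) {
          if (fGzV[k] < 0) fGzV[k] = tnow;
          lGzV[k] = tnow;
          if (!initial && !prevV_zero[k]) { zero_touch += 1; flags |= 2; }
        }
        prevV_zero[k] = vz;
      }
    }
    if (record && r_used < n_rec_max) {
      rec_t[r_used] = tnow;
      for (int k = 0; k < K; ++k) { recB(r_used, k) = B[k]; recV(r_used, k) = V[k]; }
      for (int l = 0; l < L; ++l) { recGB(r_used, l) = gb[l]; recGV(r_used, l) = gv[l]; }
      rec_zt[r_used] = (int)zero_touch;
      r_used += 1;
    }
    return flags;
  };

  detect(0.0, true, true);

  int step = 0;
  for (step = 1; step <= n_steps; ++step) {
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
    // fitness
    if (matched) {
      for (int k = 0; k < K; ++k) { MV[k] = V[k]; MtB[k] = B[k]; }
    } else {
      for (int k = 0; k < K; ++k) {
        double acc = 0.0;
        for (int p = 0; p < K; ++p) acc += M(k, p) * V[p];
        MV[k] = acc;
      }
      for (int p = 0; p < K; ++p) {
        double acc = 0.0;
        for (int k = 0; k < K; ++k) acc += M(k, p) * B[k];
        MtB[p] = acc;
      }
    }
    for (int k = 0; k < K; ++k) {
      fB[k] = s * (1.0 - MV[k] / nVstar);
      if (phage_on) fV[k] = omega * (MtB[k] / nBstar - 1.0);
    }
    // demography
    demographic_update(B, fB, dt);
    if (phage_on) demographic_update(V, fV, dt);
    // HGT channels
    if (rB > 0) {
      long long totB = vec_sum(B);
      int nev = (int)R::rpois(rB * (double)totB * dt);
      if (nev > 0) hgt_events(B, B, genes, idx_lookup, L, g, nev);
    }
    if (phage_on && rV > 0 && phage_mode != 0) {
      long long totV = vec_sum(V);
      int nev = (int)R::rpois(rV * (double)totV * dt);
      if (nev > 0) {
        if (phage_mode == 1) hgt_events(V, B, genes, idx_lookup, L, g, nev); // from bacteria
        else hgt_events(V, V, genes, idx_lookup, L, g, nev);                 // interphage
      }
    }
    // regulation
    if (regulate_exact) {
      if (regulate_side(B, NB_target)) { termination = 1; }
      if (termination == 0 && phage_on && regulate_side(V, NV_target)) termination = 2;
    } else {
      if (NB_target > 0 && vec_sum(B) == 0) termination = 1;
      if (termination == 0 && phage_on && vec_sum(V) == 0) termination = 2;
    }
    t = (double)step * dt;
    bool at_cadence = (step % record_every) == 0;
    int flags = detect(t, at_cadence, false);
    if (termination != 0) break;
    if ((stop_mode & 1) && (flags & 1)) { termination = 3; break; }
    if ((stop_mode & 2) && (flags & 2)) { termination = 4; break; }
  }
  if (step > n_steps) step = n_steps;
  // ensure final state is recorded
  if (r_used == 0 || rec_t[r_used - 1] < t) detect(t, true, true);

  auto trim_mat = [&](const IntegerMatrix& m, int ncol) {
    IntegerMatrix out(r_used, ncol);
    for (int i = 0; i < r_used; ++i)
      for (int j = 0; j < ncol; ++j) out(i, j) = m(i, j);
    return out;
  };
  NumericVector t_out(r_used);
  IntegerVector zt_out(r_used);
  for (int i = 0; i < r_used; ++i) { t_out[i] = rec_t[i]; zt_out[i] = rec_zt[i]; }

  return List::create(
    _["times"] = t_out,
    _["B"] = trim_mat(recB, K), _["V"] = trim_mat(recV, K),
    _["gene_B"] = trim_mat(recGB, L), _["gene_V"] = trim_mat(recGV, L),
    _["cum_zero_touch"] = zt_out,
    _["first_gene_zero_B"] = fgzB, _["first_gene_zero_V"] = fgzV,
    _["first_genotype_zero_B"] = fGzB, _["first_genotype_zero_V"] = fGzV,
    _["last_genotype_zero_B"] = lGzB, _["last_genotype_zero_V"] = lGzV,
    _["zero_touch_total"] = (double)zero_touch,
    _["termination"] = termination,
    _["t_end"] = t, _["steps_done"] = step);
}
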