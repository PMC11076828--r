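// Structured-coalescent engine: divergence, exponential size change and
// migration, with two output modes -- expected branch-length SFS
// accumulation (low-variance, for composite-likelihood fitting) and
// mutation dropping (for the synthetic data generator).
//
// Conventions:
//  * time is measured in generations, increasing into the past (lookback);
//  * population sizes are diploid Ne; coalescence rate for k lineages in a
//    deme of size N is k(k-1)/2 / (2N) per generation;
//  * growth rates g are forward-time exponential rates, so at lookback time
//    t past a reference point the size is N_ref * exp(-g * (t - t_ref));
//  * the migration matrix holds BACKWARD lineage-movement rates: mig(i,j) is
//    the per-generation rate at which a lineage now in deme i traces its
//    ancestry to deme j (the R layer converts from the forward
//    source->destination convention);
//  * demographic events, sorted by time: type 0 join (lineages of p1 move to
//    p2, migration involving p1 silenced), type 1 resize (deme p1 takes a
//    new size and growth from that time backward), type 2 set-migration
//    (mig(p1,p2) = rate).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Lineage {
  int deme;
  double birth;
  std::vector<int> cnt;       // descendants per sampled population
  std::vector<int> members;   // sample indices (mutation mode only)
};

struct Engine {
  int ndeme;
  std::vector<double> size_ref, growth, tref;
  NumericMatrix mig;          // backward rates, working copy
  DataFrame events;
  std::vector<Lineage> lin;
  bool track_members;

  Engine(NumericVector sizes0, NumericVector growth0, NumericMatrix mig0,
         DataFrame ev, IntegerVector samples, bool members)
      : ndeme(sizes0.size()), mig(clone(mig0)), events(ev),
        track_members(members) {
    size_ref.assign(sizes0.begin(), sizes0.end());
    growth.assign(growth0.begin(), growth0.end());
    tref.assign(ndeme, 0.0);
    int npop = samples.size(), sidx = 0;
    for (int p = 0; p < npop; ++p) {
      for (int h = 0; h < samples[p]; ++h) {
        Lineage L;
        L.deme = p;
        L.birth = 0.0;
        L.cnt.assign(npop, 0);
        L.cnt[p] = 1;
        if (track_members) L.members.push_back(sidx);
        ++sidx;
        lin.push_back(L);
      }
    }
  }

  // waiting time to next coalescence in deme with k lineages, from time t
  double coal_wait(int d, int k, double t) {
    if (k < 2) return R_PosInf;
    double a = 0.5 * k * (k - 1) / (2.0 * size_ref[d]);
    double A = a * std::exp(growth[d] * (t - tref[d]));
    double E = R::exp_rand();
    if (growth[d] == 0.0) return E / A;
    double arg = 1.0 + growth[d] * E / A;
    if (arg <= 0.0) return R_PosInf;
    return std::log(arg) / growth[d];
  }

  // run the genealogy; 'flush' is called with (lineage, death_time) each
  // time a lineage ends by coalescing into its parent.
  template <class Flush>
  void run(Flush flush) {
    double t = 0.0;
    int nev = events.nrows();
    NumericVector ev_time = events["time"];
    IntegerVector ev_type = events["type"], ev_p1 = events["p1"],
                  ev_p2 = events["p2"];
    NumericVector ev_size = events["size"], ev_growth = events["growth"],
                  ev_rate = events["rate"];
    int iev = 0;
    long guard = 0;
    while ((int)lin.size() > 1) {
      if (++guard > 100000000L) stop("coalescent did not complete (check model)");
      std::vector<int> k(ndeme, 0);
      for (auto &L : lin) k[L.deme]++;
      // candidate coalescence per deme
      double best = R_PosInf;
      int best_deme = -1;
      for (int d = 0; d < ndeme; ++d) {
        double w = coal_wait(d, k[d], t);
        if (w < best) { best = w; best_deme = d; }
      }
      // candidate migration (constant rates between events)
      double mig_tot = 0.0;
      for (int d = 0; d < ndeme; ++d) {
        double row = 0.0;
        for (int j = 0; j < ndeme; ++j) row += mig(d, j);
        mig_tot += k[d] * row;
      }
      double wmig = mig_tot > 0 ? R::exp_rand() / mig_tot : R_PosInf;
      bool is_mig = wmig < best;
      double wait = is_mig ? wmig : best;
      double horizon = iev < nev ? ev_time[iev] : R_PosInf;

      if (t + wait >= horizon) {
        // apply demographic event and retry from its time
        t = horizon;
        int ty = ev_type[iev], p1 = ev_p1[iev], p2 = ev_p2[iev];
        if (ty == 0) {                      // join p1 -> p2
          for (auto &L : lin) if (L.deme == p1) L.deme = p2;
          for (int j = 0; j < ndeme; ++j) { mig(p1, j) = 0.0; mig(j, p1) = 0.0; }
        } else if (ty == 1) {               // resize
          size_ref[p1] = ev_size[iev];
          growth[p1] = ev_growth[iev];
          tref[p1] = t;
        } else {                            // migration change
          if (p1 < 0) {
            for (int a = 0; a < ndeme; ++a)
              for (int b = 0; b < ndeme; ++b)
                if (a != b) mig(a, b) = ev_rate[iev];
          } else mig(p1, p2) = ev_rate[iev];
        }
        ++iev;
        continue;
      }
      t += wait;
      if (is_mig) {
        double u = R::unif_rand() * mig_tot, acc = 0.0;
        for (size_t i = 0; i < lin.size(); ++i) {
          for (int j = 0; j < ndeme; ++j) {
            acc += mig(lin[i].deme, j);
            if (u < acc) { lin[i].deme = j; goto moved; }
          }
        }
        lin.back().deme = ndeme - 1;  // numeric-edge fallback
      moved:;
      } else {
        // pick two distinct lineages in best_deme uniformly
        std::vector<int> idx;
        for (size_t i = 0; i < lin.size(); ++i)
          if (lin[i].deme == best_deme) idx.push_back((int)i);
        int na = idx.size();
        int a = (int)(R::unif_rand() * na); if (a == na) a = na - 1;
        int b = (int)(R::unif_rand() * (na - 1)); if (b == na - 1) b = na - 2;
        if (b >= a) ++b;
        int ia = idx[a], ib = idx[b];
        flush(lin[ia], t);
        flush(lin[ib], t);
        Lineage P;
        P.deme = best_deme;
        P.birth = t;
        P.cnt.resize(lin[ia].cnt.size());
        for (size_t q = 0; q < P.cnt.size(); ++q)
          P.cnt[q] = lin[ia].cnt[q] + lin[ib].cnt[q];
        if (track_members) {
          P.members = lin[ia].members;
          P.members.insert(P.members.end(), lin[ib].members.begin(),
                           lin[ib].members.end());
        }
        if (ib > ia) { lin.erase(lin.begin() + ib); lin.erase(lin.begin() + ia); }
        else         { lin.erase(lin.begin() + ia); lin.erase(lin.begin() + ib); }
        lin.push_back(P);
      }
    }
  }
};

}  // namespace

// Expected joint SFS by branch-length accumulation, averaged over n_sims
// genealogies. Returns a flat array over cells (d_1, ..., d_P), column-major
// with dims (n_1+1, ..., n_P+1), in units of generations of branch length.
// [[Rcpp::export]]
NumericVector coal_branch_sfs(NumericVector sizes0, NumericVector growth0,
                              NumericMatrix mig0, DataFrame events,
                              IntegerVector samples, int n_sims) {
  int npop = samples.size();
  std::vector<int> stride(npop);
  int ncell = 1;
  for (int p = 0; p < npop; ++p) { stride[p] = ncell; ncell *= samples[p] + 1; }
  NumericVector out(ncell);
  for (int s = 0; s < n_sims; ++s) {
    Engine eng(sizes0, growth0, mig0, events, samples, false);
    eng.run([&](const Lineage &L, double death) {
      int idx = 0;
      for (int p = 0; p < npop; ++p) idx += L.cnt[p] * stride[p];
      out[idx] += death - L.birth;
    });
  }
  for (int i = 0; i < ncell; ++i) out[i] /= n_sims;
  out.attr("dim") = IntegerVector(samples.begin(), samples.end()) + 1;
  return out;
}

// Mutation-dropping simulation of independent loci. Each locus gets its own
// genealogy; mutations are Poisson(mu * locus_len * branch length) per
// branch, uniform positions, infinite-sites (duplicate positions are
// resolved by the caller). Returns per-site derived-carrier haplotype
// indicators.
// [[Rcpp::export]]
List coal_sim_loci(NumericVector sizes0, NumericVector growth0,
                   NumericMatrix mig0, DataFrame events,
                   IntegerVector samples, int n_loci, double locus_len,
                   double mu) {
  int nhap = sum(samples);
  std::vector<int> site_locus;
  std::vector<int> site_pos;
  std::vector<std::vector<int>> carriers;
  for (int l = 0; l < n_loci; ++l) {
    Engine eng(sizes0, growth0, mig0, events, samples, true);
    eng.run([&](const Lineage &L, double death) {
      double len = death - L.birth;
      int nmut = (int)R::rpois(mu * locus_len * len);
      for (int m = 0; m < nmut; ++m) {
        int pos = (int)(R::unif_rand() * locus_len);
        site_locus.push_back(l);
        site_pos.push_back(pos);
        carriers.push_back(L.members);
      }
    });
  }
  int nsite = site_locus.size();
  IntegerMatrix geno(nsite, nhap);
  for (int s = 0; s < nsite; ++s)
    for (int h : carriers[s]) geno(s, h) = 1;
  return List::create(_["locus"] = wrap(site_locus),
                      _["pos"] = wrap(site_pos), _["geno"] = geno);
}
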