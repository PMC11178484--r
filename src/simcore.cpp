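// Core forward-simulation machinery shared by the native-range Wright-Fisher
// stepping-stone model and the non-Wright-Fisher invasion model.
//
// Genomes are stored as a dense 0/1 integer matrix: one row per segregating
// locus (infinite-sites), two haplotype columns per diploid individual
// (column-major, so a haplotype is contiguous). Loci rows are NOT required to
// be sorted: each gamete draws per-chromosome assortment and crossover
// positions first and resolves the source haplotype per locus by crossover
// parity, so rows can be appended and compacted freely.
//
// All randomness goes through R's RNG so set.seed() in R controls every draw.

#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Per-gamete meiosis state: free assortment between chromosomes, Poisson
// crossovers within (crossover at x = switch between sites x-1 and x).
struct Meiosis {
  int n_chrom, chrom_len;
  double exp_cx;
  std::vector<int> start;
  std::vector< std::vector<int> > cx;
  Meiosis(int n_chrom_, int chrom_len_, double per_site_rate)
    : n_chrom(n_chrom_), chrom_len(chrom_len_),
      exp_cx(per_site_rate * (double)(chrom_len_ - 1)),
      start(n_chrom_), cx(n_chrom_) {}
  void shuffle() {
    for (int c = 0; c < n_chrom; ++c) {
      start[c] = unif_rand() < 0.5 ? 1 : 0;
      int n = (int) R::rpois(exp_cx);
      cx[c].clear();
      for (int i = 0; i < n; ++i) cx[c].push_back(1 + rand_int(chrom_len - 1));
      std::sort(cx[c].begin(), cx[c].end());
    }
  }
  inline int source(int chrom1, int pos) const {
    int c = chrom1 - 1;
    int par = start[c];
    const std::vector<int>& v = cx[c];
    if (!v.empty()) {
      size_t k = std::upper_bound(v.begin(), v.end(), pos) - v.begin();
      par ^= (int)(k & 1u);
    }
    return par;
  }
};

static inline void make_gamete(int* out, const int* h0, const int* h1,
                               const int* chrom, const int* pos, int n_loci,
                               Meiosis& mei) {
  mei.shuffle();
  for (int r = 0; r < n_loci; ++r)
    out[r] = mei.source(chrom[r], pos[r]) ? h1[r] : h0[r];
}

// Additive phenotypes over QTN rows, both haplotype columns, plus the offset
// carried by QTNs that fixed and were compacted away.
static void compute_phenotypes(const int* H, int n_loci, int n_ind,
                               const std::vector<int>& qtn_rows,
                               const double* e1, const double* e2,
                               double fix1, double fix2,
                               double* z1, double* z2) {
  for (int i = 0; i < n_ind; ++i) {
    const int* a = H + (size_t)(2 * i) * n_loci;
    const int* b = H + (size_t)(2 * i + 1) * n_loci;
    double s1 = fix1, s2 = fix2;
    for (size_t q = 0; q < qtn_rows.size(); ++q) {
      int r = qtn_rows[q];
      int dos = a[r] + b[r];
      if (dos) { s1 += dos * e1[r]; s2 += dos * e2[r]; }
    }
    z1[i] = s1; z2[i] = s2;
  }
}

static inline double gaussian_fitness(double z1, double z2, double o1, double o2,
                                      double sigma_w) {
  double d1 = z1 - o1, d2 = z2 - o2;
  return std::exp(-(d1 * d1 + d2 * d2) / (2.0 * sigma_w * sigma_w));
}

// [[Rcpp::export]]
NumericMatrix cpp_phenotypes(IntegerMatrix H, NumericVector eff1, NumericVector eff2,
                             LogicalVector is_qtn, double fix1, double fix2) {
  int n_loci = H.nrow();
  int n_ind = H.ncol() / 2;
  std::vector<int> qtn_rows;
  for (int r = 0; r < n_loci; ++r) if (is_qtn[r]) qtn_rows.push_back(r);
  NumericMatrix Z(n_ind, 2);
  std::vector<double> z1(n_ind), z2(n_ind);
  compute_phenotypes(n_loci ? &H[0] : NULL, n_loci, n_ind, qtn_rows,
                     n_loci ? &eff1[0] : NULL, n_loci ? &eff2[0] : NULL,
                     fix1, fix2, z1.data(), z2.data());
  for (int i = 0; i < n_ind; ++i) { Z(i, 0) = z1[i]; Z(i, 1) = z2[i]; }
  return Z;
}

static inline long long site_key(int chrom1, int pos, int chrom_len) {
  return (long long)(chrom1 - 1) * (long long)chrom_len + (long long)pos;
}

// One Wright-Fisher generation for the whole grid.
// [[Rcpp::export]]
List cpp_wf_generation(IntegerMatrix H, IntegerVector chrom, IntegerVector pos,
                       NumericVector eff1, NumericVector eff2, LogicalVector is_qtn,
                       double fix1, double fix2, NumericMatrix optima, List neighbors,
                       int deme_size, double migration_rate, double sigma_w,
                       double recomb_rate, int chrom_len, int n_chrom, int n_qtn_chrom,
                       double qtn_mut_rate, double neutral_mut_rate, double effect_sd) {
  const int D = optima.nrow();
  const int n_loci = H.nrow();
  const int n_ind = deme_size * D;
  if (H.ncol() != 2 * n_ind) stop("haplotype matrix does not match deme_size * n_demes");

  std::vector<int> qtn_rows;
  for (int r = 0; r < n_loci; ++r) if (is_qtn[r]) qtn_rows.push_back(r);

  // Parent fitness and per-deme cumulative weights.
  std::vector<double> z1(n_ind), z2(n_ind), w(n_ind);
  compute_phenotypes(n_loci ? &H[0] : NULL, n_loci, n_ind, qtn_rows,
                     n_loci ? &eff1[0] : NULL, n_loci ? &eff2[0] : NULL,
                     fix1, fix2, z1.data(), z2.data());
  NumericVector mean_fit(D);
  std::vector<double> cumw((size_t)n_ind);
  for (int d = 0; d < D; ++d) {
    double acc = 0.0, tot = 0.0;
    for (int j = 0; j < deme_size; ++j) {
      int i = d * deme_size + j;
      w[i] = gaussian_fitness(z1[i], z2[i], optima(d, 0), optima(d, 1), sigma_w);
      acc += w[i];
      cumw[i] = acc;
      tot += w[i];
    }
    mean_fit[d] = tot / deme_size;
  }

  std::vector< std::vector<int> > nb(D);
  for (int d = 0; d < D; ++d) {
    IntegerVector v = neighbors[d];
    for (int k = 0; k < v.size(); ++k) nb[d].push_back(v[k] - 1);
  }

  // Pre-draw total new mutation counts (Poisson thinning over gametes) so the
  // output matrix can be allocated once.
  const double G = 2.0 * n_ind;
  int n_new_q = (int) R::rpois(qtn_mut_rate * (double)n_qtn_chrom * chrom_len * G);
  int n_new_n = (int) R::rpois(neutral_mut_rate * (double)n_chrom * chrom_len * G);
  int n_new = n_new_q + n_new_n;

  IntegerMatrix Hn(n_loci + n_new, 2 * n_ind);
  Meiosis mei(n_chrom, chrom_len, recomb_rate);
  const int* chp = n_loci ? &chrom[0] : NULL;
  const int* pop = n_loci ? &pos[0] : NULL;
  const int* Hbase = H.size() ? &H[0] : NULL;
  int* HnBase = Hn.size() ? &Hn[0] : NULL;

  for (int d = 0; d < D; ++d) {
    for (int j = 0; j < deme_size; ++j) {
      int src = d;
      if (migration_rate > 0.0 && !nb[d].empty() && unif_rand() < migration_rate)
        src = nb[d][rand_int((int)nb[d].size())];
      // cumulative weights restart at each deme (see fill above)
      const double* cw = cumw.data() + (size_t)src * deme_size;
      double tot = cw[deme_size - 1];
      int idx = d * deme_size + j;
      for (int g = 0; g < 2; ++g) {
        int par;
        if (tot > 0.0) {
          double u = unif_rand() * tot;
          par = (int)(std::upper_bound(cw, cw + deme_size, u) - cw);
          if (par >= deme_size) par = deme_size - 1;
        } else {
          par = rand_int(deme_size);
        }
        int pind = src * deme_size + par;
        const int* h0 = Hbase + (size_t)(2 * pind) * n_loci;
        const int* h1 = h0 + n_loci;
        make_gamete(HnBase + (size_t)(2 * idx + g) * (n_loci + n_new),
                    h0, h1, chp, pop, n_loci, mei);
      }
    }
  }

  // Place new mutations on uniformly chosen gametes at unoccupied sites.
  std::unordered_set<long long> occupied;
  occupied.reserve(n_loci * 2 + 16);
  for (int r = 0; r < n_loci; ++r) occupied.insert(site_key(chrom[r], pos[r], chrom_len));
  IntegerVector new_chrom(n_new), new_pos(n_new);
  LogicalVector new_qtn(n_new);
  NumericVector new_e1(n_new), new_e2(n_new);
  const int nl_tot = n_loci + n_new;
  for (int k = 0; k < n_new; ++k) {
    bool qtn = k < n_new_q;
    int c, p;
    do {
      c = 1 + rand_int(qtn ? n_qtn_chrom : n_chrom);
      p = rand_int(chrom_len);
    } while (occupied.count(site_key(c, p, chrom_len)));
    occupied.insert(site_key(c, p, chrom_len));
    int col = rand_int(2 * n_ind);
    Hn[(size_t)col * nl_tot + (n_loci + k)] = 1;
    new_chrom[k] = c; new_pos[k] = p; new_qtn[k] = qtn;
    if (qtn) { new_e1[k] = norm_rand() * effect_sd; new_e2[k] = norm_rand() * effect_sd; }
  }

  return List::create(_["H"] = Hn, _["new_chrom"] = new_chrom, _["new_pos"] = new_pos,
                      _["new_is_qtn"] = new_qtn, _["new_eff1"] = new_e1,
                      _["new_eff2"] = new_e2, _["mean_fitness"] = mean_fit);
}

// One time step of the non-Wright-Fisher invasion model:
// reproduce -> survive -> age. Parents uniform among all living individuals;
// survival probability equals Gaussian fitness in the target environment,
// applied to every living individual (including same-step newborns) when
// survival_all is true, or to pre-existing individuals only otherwise.
// [[Rcpp::export]]
List cpp_invasion_step(IntegerMatrix H, IntegerVector ages,
                       IntegerVector chrom, IntegerVector pos,
                       NumericVector eff1, NumericVector eff2, LogicalVector is_qtn,
                       double fix1, double fix2, double e1, double e2,
                       double sigma_w, double fecundity, int max_age,
                       double recomb_rate, int chrom_len, int n_chrom, int n_qtn_chrom,
                       double qtn_mut_rate, double neutral_mut_rate, double effect_sd,
                       bool survival_all) {
  const int n = ages.size();
  if (n <= 0) stop("empty cohort");
  const int n_loci = H.nrow();
  if (H.ncol() != 2 * n) stop("haplotype matrix does not match cohort size");

  std::vector<int> qtn_rows;
  for (int r = 0; r < n_loci; ++r) if (is_qtn[r]) qtn_rows.push_back(r);

  std::vector<double> z1(n), z2(n), w(n);
  compute_phenotypes(n_loci ? &H[0] : NULL, n_loci, n, qtn_rows,
                     n_loci ? &eff1[0] : NULL, n_loci ? &eff2[0] : NULL,
                     fix1, fix2, z1.data(), z2.data());
  double mean_fit = 0.0;
  for (int i = 0; i < n; ++i) {
    w[i] = gaussian_fitness(z1[i], z2[i], e1, e2, sigma_w);
    mean_fit += w[i];
  }
  mean_fit /= n;

  // Reproduction.
  int n_off = (int) R::rpois(fecundity * (double)n);
  int n_new_q = (int) R::rpois(qtn_mut_rate * (double)n_qtn_chrom * chrom_len * 2.0 * n_off);
  int n_new_n = (int) R::rpois(neutral_mut_rate * (double)n_chrom * chrom_len * 2.0 * n_off);
  int n_new = n_new_q + n_new_n;
  const int nl_tot = n_loci + n_new;

  std::vector<int> Hoff((size_t)nl_tot * 2 * n_off, 0);
  Meiosis mei(n_chrom, chrom_len, recomb_rate);
  const int* chp = n_loci ? &chrom[0] : NULL;
  const int* pop = n_loci ? &pos[0] : NULL;
  const int* Hbase = H.size() ? &H[0] : NULL;
  for (int j = 0; j < n_off; ++j) {
    for (int g = 0; g < 2; ++g) {
      int pind = rand_int(n);
      const int* h0 = Hbase + (size_t)(2 * pind) * n_loci;
      const int* h1 = h0 + n_loci;
      make_gamete(Hoff.data() + (size_t)(2 * j + g) * nl_tot, h0, h1, chp, pop, n_loci, mei);
    }
  }

  // New mutations on offspring gametes.
  std::unordered_set<long long> occupied;
  for (int r = 0; r < n_loci; ++r) occupied.insert(site_key(chrom[r], pos[r], chrom_len));
  std::vector<int> mut_chrom(n_new), mut_pos(n_new), mut_col(n_new);
  std::vector<bool> mut_qtn(n_new);
  std::vector<double> mut_e1(n_new, 0.0), mut_e2(n_new, 0.0);
  std::vector<int> qtn_rows_ext = qtn_rows;
  std::vector<double> eff1_ext(eff1.begin(), eff1.end()), eff2_ext(eff2.begin(), eff2.end());
  eff1_ext.resize(nl_tot, 0.0); eff2_ext.resize(nl_tot, 0.0);
  for (int k = 0; k < n_new; ++k) {
    bool qtn = k < n_new_q;
    int c, p;
    do {
      c = 1 + rand_int(qtn ? n_qtn_chrom : n_chrom);
      p = rand_int(chrom_len);
    } while (occupied.count(site_key(c, p, chrom_len)));
    occupied.insert(site_key(c, p, chrom_len));
    int col = n_off > 0 ? rand_int(2 * n_off) : 0;
    if (n_off > 0) Hoff[(size_t)col * nl_tot + (n_loci + k)] = 1;
    mut_chrom[k] = c; mut_pos[k] = p; mut_col[k] = col; mut_qtn[k] = qtn;
    if (qtn) {
      mut_e1[k] = norm_rand() * effect_sd; mut_e2[k] = norm_rand() * effect_sd;
      eff1_ext[n_loci + k] = mut_e1[k]; eff2_ext[n_loci + k] = mut_e2[k];
      qtn_rows_ext.push_back(n_loci + k);
    }
  }

  // Offspring survival (viability selection on newborns when survival_all).
  std::vector<int> off_keep;
  if (n_off > 0) {
    std::vector<double> oz1(n_off), oz2(n_off);
    compute_phenotypes(Hoff.data(), nl_tot, n_off, qtn_rows_ext,
                       eff1_ext.data(), eff2_ext.data(), fix1, fix2,
                       oz1.data(), oz2.data());
    for (int j = 0; j < n_off; ++j) {
      if (!survival_all ||
          unif_rand() < gaussian_fitness(oz1[j], oz2[j], e1, e2, sigma_w))
        off_keep.push_back(j);
    }
  }

  // Adult survival then ageing; removal once age exceeds max_age.
  std::vector<int> ad_keep;
  std::vector<int> ad_age;
  for (int i = 0; i < n; ++i) {
    if (unif_rand() < w[i] && ages[i] + 1 <= max_age) {
      ad_keep.push_back(i);
      ad_age.push_back(ages[i] + 1);
    }
  }

  // Which de novo mutations survive in a kept offspring column?
  std::vector<int> new_row_map(n_new, -1);
  std::vector<int> kept_new;
  std::vector<bool> col_kept(2 * std::max(n_off, 1), false);
  for (size_t j = 0; j < off_keep.size(); ++j) {
    col_kept[2 * off_keep[j]] = true;
    col_kept[2 * off_keep[j] + 1] = true;
  }
  for (int k = 0; k < n_new; ++k)
    if (n_off > 0 && col_kept[mut_col[k]]) {
      new_row_map[k] = n_loci + (int)kept_new.size();
      kept_new.push_back(k);
    }

  const int nl_out = n_loci + (int)kept_new.size();
  const int n_out = (int)off_keep.size() + (int)ad_keep.size();
  IntegerMatrix Hout(nl_out, 2 * n_out);
  int* HoutBase = Hout.size() ? &Hout[0] : NULL;
  IntegerVector ages_out(n_out);
  int colo = 0;
  for (size_t j = 0; j < off_keep.size(); ++j) {
    for (int g = 0; g < 2; ++g) {
      const int* srcc = Hoff.data() + (size_t)(2 * off_keep[j] + g) * nl_tot;
      int* dst = HoutBase + (size_t)colo * nl_out;
      std::copy(srcc, srcc + n_loci, dst);
      for (size_t m = 0; m < kept_new.size(); ++m)
        dst[n_loci + m] = srcc[n_loci + kept_new[m]];
      ++colo;
    }
    ages_out[j] = 0;
  }
  for (size_t j = 0; j < ad_keep.size(); ++j) {
    for (int g = 0; g < 2; ++g) {
      const int* srcc = Hbase + (size_t)(2 * ad_keep[j] + g) * n_loci;
      int* dst = HoutBase + (size_t)colo * nl_out;
      std::copy(srcc, srcc + n_loci, dst);
      // rows beyond n_loci stay 0 for adults
      ++colo;
    }
    ages_out[off_keep.size() + j] = ad_age[j];
  }

  int nk = (int)kept_new.size();
  IntegerVector kc(nk), kp(nk);
  LogicalVector kq(nk);
  NumericVector ke1(nk), ke2(nk);
  for (int m = 0; m < nk; ++m) {
    int k = kept_new[m];
    kc[m] = mut_chrom[k]; kp[m] = mut_pos[k]; kq[m] = (bool)mut_qtn[k];
    ke1[m] = mut_e1[k]; ke2[m] = mut_e2[k];
  }

  return List::create(_["H"] = Hout, _["ages"] = ages_out,
                      _["new_chrom"] = kc, _["new_pos"] = kp, _["new_is_qtn"] = kq,
                      _["new_eff1"] = ke1, _["new_eff2"] = ke2,
                      _["mean_fitness"] = mean_fit,
                      _["n_offspring_born"] = n_off,
                      _["size"] = n_out);
}

// ---------------------------------------------------------------------------
// Fast full-run native simulation. Same model as cpp_wf_generation, but the
// whole generation loop stays in C++: haplotypes live in uint8 buffers, loci
// are kept sorted by (chrom, pos) so gamete construction reduces to segment
// copies between crossover boundaries, and fixed/lost loci are compacted
// every generation.

struct LociState {
  std::vector<int> id, chrom, pos, origin;
  std::vector<char> is_qtn;
  std::vector<double> e1, e2;
  size_t size() const { return id.size(); }
};

// [[Rcpp::export]]
List cpp_run_native(IntegerMatrix H0, IntegerVector id0, IntegerVector chrom0,
                    IntegerVector pos0, LogicalVector qtn0, NumericVector e1_0,
                    NumericVector e2_0, IntegerVector origin0,
                    double fix1, double fix2, NumericMatrix layout_optima,
                    List neighbors, int deme_size, double migration_rate,
                    double sigma_w, double recomb_rate, int chrom_len,
                    int n_chrom, int n_qtn_chrom, double qtn_mut_rate,
                    double neutral_mut_rate, double effect_sd,
                    IntegerVector phase_lengths, int next_id) {
  const int D = layout_optima.nrow();
  const int n_ind = deme_size * D;
  const int n_hap = 2 * n_ind;
  const int total_gens = phase_lengths[0] + phase_lengths[1] + phase_lengths[2];

  LociState L;
  {
    // start from the initial loci sorted by (chrom, pos)
    int n0 = id0.size();
    std::vector<int> ord(n0);
    for (int i = 0; i < n0; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (chrom0[a] != chrom0[b]) return chrom0[a] < chrom0[b];
      return pos0[a] < pos0[b];
    });
    for (int i = 0; i < n0; ++i) {
      int r = ord[i];
      L.id.push_back(id0[r]); L.chrom.push_back(chrom0[r]); L.pos.push_back(pos0[r]);
      L.is_qtn.push_back(qtn0[r]); L.e1.push_back(e1_0[r]); L.e2.push_back(e2_0[r]);
      L.origin.push_back(origin0[r]);
    }
  }
  std::vector<unsigned char> cur((size_t)L.size() * n_hap);
  {
    int n0 = (int)L.size();
    // reorder the initial matrix rows into sorted order (per column)
    std::vector<int> ord(n0);
    // recompute the same ordering used above
    std::vector<int> tmp(n0);
    for (int i = 0; i < n0; ++i) tmp[i] = i;
    std::sort(tmp.begin(), tmp.end(), [&](int a, int b) {
      if (chrom0[a] != chrom0[b]) return chrom0[a] < chrom0[b];
      return pos0[a] < pos0[b];
    });
    for (int c = 0; c < n_hap; ++c)
      for (int i = 0; i < n0; ++i)
        cur[(size_t)c * n0 + i] = (unsigned char)H0[(size_t)c * n0 + tmp[i]];
  }

  std::vector< std::vector<int> > nb(D);
  for (int d = 0; d < D; ++d) {
    IntegerVector v = neighbors[d];
    for (int k = 0; k < v.size(); ++k) nb[d].push_back(v[k] - 1);
  }

  NumericMatrix fitness_history(total_gens, D);
  double fx1 = fix1, fx2 = fix2;
  std::vector<unsigned char> nxt;
  std::vector<double> z1(n_ind), z2(n_ind), w(n_ind), cumw(n_ind);
  Meiosis mei(n_chrom, chrom_len, recomb_rate);

  int gen_all = 0;
  for (int phase = 0; phase < 3; ++phase) {
    for (int g = 0; g < phase_lengths[phase]; ++g) {
      ++gen_all;
      // optima schedule: burn-in at 0, linear ramp, hold
      double scale = phase == 0 ? 0.0
                   : (phase == 1 ? (double)(g + 1) / phase_lengths[1] : 1.0);
      const int n_loci = (int)L.size();

      // chromosome row ranges (loci sorted)
      std::vector<int> cbeg(n_chrom + 2, 0);
      for (int r = 0; r < n_loci; ++r) cbeg[L.chrom[r]]++;
      int acc0 = 0;
      for (int c = 1; c <= n_chrom + 1; ++c) { int t = cbeg[c]; cbeg[c] = acc0; acc0 += t; }
      // cbeg[c] = first row of chromosome c (1-based chrom), cbeg[n_chrom+1] = n_loci

      // phenotypes and fitness
      std::vector<int> qtn_rows;
      for (int r = 0; r < n_loci; ++r) if (L.is_qtn[r]) qtn_rows.push_back(r);
      for (int i = 0; i < n_ind; ++i) {
        const unsigned char* a = cur.data() + (size_t)(2 * i) * n_loci;
        const unsigned char* b = cur.data() + (size_t)(2 * i + 1) * n_loci;
        double s1 = fx1, s2 = fx2;
        for (size_t q = 0; q < qtn_rows.size(); ++q) {
          int r = qtn_rows[q];
          int dos = a[r] + b[r];
          if (dos) { s1 += dos * L.e1[r]; s2 += dos * L.e2[r]; }
        }
        z1[i] = s1; z2[i] = s2;
      }
      for (int d = 0; d < D; ++d) {
        double accw = 0.0, tot = 0.0;
        double o1 = layout_optima(d, 0) * scale, o2 = layout_optima(d, 1) * scale;
        for (int j = 0; j < deme_size; ++j) {
          int i = d * deme_size + j;
          w[i] = gaussian_fitness(z1[i], z2[i], o1, o2, sigma_w);
          accw += w[i]; cumw[i] = accw; tot += w[i];
        }
        fitness_history(gen_all - 1, d) = tot / deme_size;
      }

      // mutation totals for this generation
      int n_new_q = (int) R::rpois(qtn_mut_rate * (double)n_qtn_chrom * chrom_len * n_hap);
      int n_new_n = (int) R::rpois(neutral_mut_rate * (double)n_chrom * chrom_len * n_hap);
      int n_new = n_new_q + n_new_n;
      int nl_tot = n_loci + n_new;

      nxt.assign((size_t)nl_tot * n_hap, 0);

      // offspring via sorted-segment gametes
      for (int d = 0; d < D; ++d) {
        for (int j = 0; j < deme_size; ++j) {
          int src = d;
          if (migration_rate > 0.0 && !nb[d].empty() && unif_rand() < migration_rate)
            src = nb[d][rand_int((int)nb[d].size())];
          const double* cw = cumw.data() + (size_t)src * deme_size;
          double tot = cw[deme_size - 1];
          int idx = d * deme_size + j;
          for (int gam = 0; gam < 2; ++gam) {
            int par;
            if (tot > 0.0) {
              double u = unif_rand() * tot;
              par = (int)(std::upper_bound(cw, cw + deme_size, u) - cw);
              if (par >= deme_size) par = deme_size - 1;
            } else par = rand_int(deme_size);
            int pind = src * deme_size + par;
            const unsigned char* h0 = cur.data() + (size_t)(2 * pind) * n_loci;
            const unsigned char* h1 = h0 + n_loci;
            unsigned char* out = nxt.data() + (size_t)(2 * idx + gam) * nl_tot;
            mei.shuffle();
            for (int c = 1; c <= n_chrom; ++c) {
              int lo = cbeg[c], hi = cbeg[c + 1];
              if (lo >= hi) continue;
              int parh = mei.start[c - 1];
              const std::vector<int>& v = mei.cx[c - 1];
              int at = lo;
              for (size_t k = 0; k <= v.size(); ++k) {
                int stop_row = (k < v.size())
                  ? (int)(std::lower_bound(L.pos.begin() + at, L.pos.begin() + hi, v[k])
                          - L.pos.begin())
                  : hi;
                if (stop_row > at) {
                  const unsigned char* srcp = parh ? h1 : h0;
                  std::copy(srcp + at, srcp + stop_row, out + at);
                  at = stop_row;
                }
                parh ^= 1;
                if (at >= hi) break;
              }
            }
          }
        }
      }

      // place new mutations
      std::unordered_set<long long> occupied;
      occupied.reserve(nl_tot * 2);
      for (int r = 0; r < n_loci; ++r)
        occupied.insert(site_key(L.chrom[r], L.pos[r], chrom_len));
      for (int k = 0; k < n_new; ++k) {
        bool q = k < n_new_q;
        int c, p;
        do {
          c = 1 + rand_int(q ? n_qtn_chrom : n_chrom);
          p = rand_int(chrom_len);
        } while (occupied.count(site_key(c, p, chrom_len)));
        occupied.insert(site_key(c, p, chrom_len));
        int col = rand_int(n_hap);
        nxt[(size_t)col * nl_tot + (n_loci + k)] = 1;
        L.id.push_back(next_id++);
        L.chrom.push_back(c); L.pos.push_back(p); L.is_qtn.push_back(q);
        L.origin.push_back(gen_all);
        if (q) { L.e1.push_back(norm_rand() * effect_sd);
                 L.e2.push_back(norm_rand() * effect_sd); }
        else { L.e1.push_back(0.0); L.e2.push_back(0.0); }
      }

      // compact (drop lost, fold fixed QTNs) and re-sort by (chrom, pos)
      std::vector<int> counts(nl_tot, 0);
      for (int col = 0; col < n_hap; ++col) {
        const unsigned char* cc = nxt.data() + (size_t)col * nl_tot;
        for (int r = 0; r < nl_tot; ++r) counts[r] += cc[r];
      }
      std::vector<int> keep;
      keep.reserve(nl_tot);
      for (int r = 0; r < nl_tot; ++r) {
        if (counts[r] == 0) continue;
        if (counts[r] == n_hap) {
          if (L.is_qtn[r]) { fx1 += 2.0 * L.e1[r]; fx2 += 2.0 * L.e2[r]; }
          continue;
        }
        keep.push_back(r);
      }
      std::sort(keep.begin(), keep.end(), [&](int a, int b) {
        if (L.chrom[a] != L.chrom[b]) return L.chrom[a] < L.chrom[b];
        return L.pos[a] < L.pos[b];
      });
      LociState L2;
      L2.id.reserve(keep.size());
      for (size_t i = 0; i < keep.size(); ++i) {
        int r = keep[i];
        L2.id.push_back(L.id[r]); L2.chrom.push_back(L.chrom[r]);
        L2.pos.push_back(L.pos[r]); L2.is_qtn.push_back(L.is_qtn[r]);
        L2.e1.push_back(L.e1[r]); L2.e2.push_back(L.e2[r]);
        L2.origin.push_back(L.origin[r]);
      }
      int nl_keep = (int)keep.size();
      cur.assign((size_t)nl_keep * n_hap, 0);
      for (int col = 0; col < n_hap; ++col) {
        const unsigned char* srcc = nxt.data() + (size_t)col * nl_tot;
        unsigned char* dst = cur.data() + (size_t)col * nl_keep;
        for (int i = 0; i < nl_keep; ++i) dst[i] = srcc[keep[i]];
      }
      L = L2;
      if (gen_all % 50 == 0) Rcpp::checkUserInterrupt();
    }
  }

  const int nfin = (int)L.size();
  IntegerMatrix Hfin(nfin, n_hap);
  for (int col = 0; col < n_hap; ++col)
    for (int r = 0; r < nfin; ++r)
      Hfin[(size_t)col * nfin + r] = cur[(size_t)col * nfin + r];
  return List::create(
      _["H"] = Hfin,
      _["id"] = IntegerVector(L.id.begin(), L.id.end()),
      _["chrom"] = IntegerVector(L.chrom.begin(), L.chrom.end()),
      _["site"] = IntegerVector(L.pos.begin(), L.pos.end()),
      _["is_qtn"] = LogicalVector(L.is_qtn.begin(), L.is_qtn.end()),
      _["eff1"] = NumericVector(L.e1.begin(), L.e1.end()),
      _["eff2"] = NumericVector(L.e2.begin(), L.e2.end()),
      _["origin"] = IntegerVector(L.origin.begin(), L.origin.end()),
      _["fixed1"] = fx1, _["fixed2"] = fx2,
      _["fitness_history"] = fitness_history,
      _["next_id"] = next_id,
      _["generation"] = total_gens);
}
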