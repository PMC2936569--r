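#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Crossover realization: a Poisson number of exchange points per chromosome
// (mean = map length in Morgans) at uniform positions, with a random starting
// haplotype. Disjoint intervals then carry independent odd-count (switch)
// probabilities 0.5*(1 - exp(-2d)) -- Haldane, no interference.
static void gamete_core(const int* h1, const int* h2, int* out,
                        const std::vector<int>& chr_start,
                        const double* pos, const double* chr_len) {
  const int n_chr = (int)chr_start.size() - 1;
  std::vector<double> cx;
  for (int c = 0; c < n_chr; ++c) {
    const int lo = chr_start[c], hi = chr_start[c + 1];
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    const int ncross = (int)R::rpois(chr_len[c]);
    cx.clear();
    for (int i = 0; i < ncross; ++i) cx.push_back(unif_rand() * chr_len[c]);
    std::sort(cx.begin(), cx.end());
    size_t ci = 0;
    for (int l = lo; l < hi; ++l) {
      while (ci < cx.size() && cx[ci] < pos[l]) { cur ^= 1; ++ci; }
      out[l] = cur ? h2[l] : h1[l];
    }
  }
}

// Infinite-alleles mutation: each mutated locus receives a label never used
// before at that locus. Binomial count + distinct uniform positions is
// exactly per-locus independent Bernoulli(rate).
static void mutate_core(int* g, int L, double rate, std::vector<int>& next_allele) {
  if (rate <= 0.0) return;
  const int nm = (int)R::rbinom((double)L, rate);
  std::vector<int> used;
  used.reserve(nm);
  for (int i = 0; i < nm; ++i) {
    int idx;
    do {
      idx = (int)(unif_rand() * L);
      if (idx >= L) idx = L - 1;
    } while (std::find(used.begin(), used.end(), idx) != used.end());
    used.push_back(idx);
    g[idx] = next_allele[idx]++;
  }
}

static std::vector<int> chr_starts(const IntegerVector& chr) {
  const int L = chr.size();
  std::vector<int> st;
  st.push_back(0);
  for (int l = 1; l < L; ++l)
    if (chr[l] != chr[l - 1]) st.push_back(l);
  st.push_back(L);
  return st;
}

// [[Rcpp::export]]
IntegerVector meiosis_cpp(IntegerVector h1, IntegerVector h2,
                          IntegerVector chr, NumericVector pos,
                          NumericVector chr_len) {
  const int L = h1.size();
  IntegerVector out(L);
  std::vector<int> st = chr_starts(chr);
  gamete_core(&h1[0], &h2[0], &out[0], st, &pos[0], &chr_len[0]);
  return out;
}

// [[Rcpp::export]]
List mutate_cpp(IntegerVector hap, double rate, IntegerVector counter) {
  const int L = hap.size();
  IntegerVector out = clone(hap);
  std::vector<int> nx(counter.begin(), counter.end());
  mutate_core(&out[0], L, rate, nx);
  return List::create(_["haplotype"] = out,
                      _["counter"] = IntegerVector(nx.begin(), nx.end()));
}

// Historical generations: constant size, random monogamous pairing of the
// n/2 males with the n/2 females, two offspring (one male, one female) per
// mating, infinite-alleles mutation on every gamete. Haplotype matrices are
// loci x individuals; males occupy columns 0..n/2-1.
// [[Rcpp::export]]
List sim_history_cpp(IntegerVector chr, NumericVector pos, NumericVector chr_len,
                     int n_ind, int n_gen, double mut_rate) {
  const int L = chr.size();
  const int half = n_ind / 2;
  std::vector<int> st = chr_starts(chr);
  // haps[2*i], haps[2*i+1]: the two haplotypes of individual i
  std::vector<std::vector<int>> cur(2 * n_ind, std::vector<int>(L, 1));
  std::vector<std::vector<int>> nxt(2 * n_ind, std::vector<int>(L));
  std::vector<int> next_allele(L, 2);
  std::vector<int> fem(half);

  for (int g = 0; g < n_gen; ++g) {
    for (int i = 0; i < half; ++i) fem[i] = half + i;
    for (int i = half - 1; i > 0; --i) {       // Fisher-Yates
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(fem[i], fem[j]);
    }
    for (int i = 0; i < half; ++i) {
      const int sire = i, dam = fem[i];
      for (int o = 0; o < 2; ++o) {
        const int off = (o == 0) ? i : half + i;  // one male, one female
        gamete_core(cur[2 * sire].data(), cur[2 * sire + 1].data(),
                    nxt[2 * off].data(), st, &pos[0], &chr_len[0]);
        mutate_core(nxt[2 * off].data(), L, mut_rate, next_allele);
        gamete_core(cur[2 * dam].data(), cur[2 * dam + 1].data(),
                    nxt[2 * off + 1].data(), st, &pos[0], &chr_len[0]);
        mutate_core(nxt[2 * off + 1].data(), L, mut_rate, next_allele);
      }
    }
    std::swap(cur, nxt);
  }

  IntegerMatrix h1(L, n_ind), h2(L, n_ind);
  for (int i = 0; i < n_ind; ++i)
    for (int l = 0; l < L; ++l) {
      h1(l, i) = cur[2 * i][l];
      h2(l, i) = cur[2 * i + 1][l];
    }
  return List::create(_["h1"] = h1, _["h2"] = h2,
                      _["counter"] = IntegerVector(next_allele.begin(), next_allele.end()));
}

// Deterministic-design breeding (no mutation): for offspring o, one gamete
// from sire[o] and one from dam[o]. Parent haplotypes are loci x parents.
// [[Rcpp::export]]
List breed_cpp(IntegerMatrix ph1, IntegerMatrix ph2,
               IntegerVector sire, IntegerVector dam,
               IntegerVector chr, NumericVector pos, NumericVector chr_len) {
  const int L = ph1.nrow();
  const int n_off = sire.size();
  std::vector<int> st = chr_starts(chr);
  IntegerMatrix oh1(L, n_off), oh2(L, n_off);
  for (int o = 0; o < n_off; ++o) {
    const int s = sire[o], d = dam[o];
    gamete_core(&ph1(0, s), &ph2(0, s), &oh1(0, o), st, &pos[0], &chr_len[0]);
    gamete_core(&ph1(0, d), &ph2(0, d), &oh2(0, o), st, &pos[0], &chr_len[0]);
  }
  return List::create(_["h1"] = oh1, _["h2"] = oh2);
}

// Biallelic recoding: at each locus the allele with frequency nearest 0.5
// becomes 1, everything else 2; ties go to the smaller original label;
// monomorphic loci become all 1.
// [[Rcpp::export]]
List recode_cpp(IntegerMatrix h1, IntegerMatrix h2) {
  const int L = h1.nrow(), n = h1.ncol();
  IntegerMatrix r1(L, n), r2(L, n);
  std::unordered_map<int, int> cnt;
  for (int l = 0; l < L; ++l) {
    cnt.clear();
    for (int i = 0; i < n; ++i) {
      ++cnt[h1(l, i)];
      ++cnt[h2(l, i)];
    }
    int best = -1;
    double best_d = 2.0;
    for (const auto& kv : cnt) {
      const double d = std::fabs(kv.second / (2.0 * n) - 0.5);
      if (d < best_d - 1e-15 || (std::fabs(d - best_d) <= 1e-15 && kv.first < best)) {
        best = kv.first;
        best_d = d;
      }
    }
    for (int i = 0; i < n; ++i) {
      r1(l, i) = (h1(l, i) == best) ? 1 : 2;
      r2(l, i) = (h2(l, i) == best) ? 1 : 2;
    }
  }
  return List::create(_["h1"] = r1, _["h2"] = r2);
}
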