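// Individual-based non-Wright-Fisher forward simulator with explicit diploid
// genomes. Mutations live in one append-only table; a haplotype is a vector of
// mutation ids kept sorted by genome position (chrom, pos, id). Populations
// are density-regulated through carrying capacity K: reproduction is
// unconstrained, survival is Bernoulli(W * (1 - age mortality) * min(K/N, 1)).
// All randomness is drawn from R's RNG so set.seed() governs every run.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <string>

using namespace Rcpp;

struct Ind {
  std::vector<int> h1, h2; // mutation ids, sorted by genome position
  std::vector<int> d1, d2; // deleterious subset of h1/h2 (same order)
  char sex;                // 0 = F, 1 = M
  int age;
  double w;                // absolute fitness, cached at birth
};

struct Pop {
  std::string label;
  double K;
  std::vector<Ind> inds;
  std::vector<int> fixed;  // compacted mutations fixed within this population
  double fixedW;           // product of (1 + s) over compacted deleterious
  Pop() : K(0), fixedW(1.0) {}
};

struct Sim {
  // genome architecture
  int n_chrom, genes_per_chrom, gene_len;
  long long chrom_len, genome_bp;
  double mu;        // per site per meiosis (one simulator cycle = one year)
  double r_gene;    // crossover probability per gene boundary

  // DFE: s drawn on the unscaled gamma, categorised there, then multiplied
  // by s_scale (population rescaling) and clamped at -1
  double p_del, gamma_shape, gamma_scale, s_scale, p_lethal;

  // life history
  int first_repro, max_repro, max_longevity;
  double male_frac;
  std::vector<double> litter_cum;  // cumulative probs, litter sizes 1..k
  std::vector<double> age_mort;    // indexed by age 0..max_longevity

  int year; // stamped onto new mutations (simulation bookkeeping time)

  // mutation table (append-only)
  std::vector<long long> m_gpos; // chrom * chrom_len + pos
  std::vector<double> m_s, m_h;
  std::vector<signed char> m_cat; // 0 neutral, 1 weak, 2 moderate, 3 strong, 4 very strong
  std::vector<int> m_origin;

  std::vector<Pop> pops;

  // scratch
  std::vector<int> t1, t2, g1, g2;

  bool less(int a, int b) const {
    long long ga = m_gpos[a], gb = m_gpos[b];
    return ga < gb || (ga == gb && a < b);
  }
};

static Sim& get(SEXP xp) {
  Rcpp::XPtr<Sim> p(xp);
  return *p;
}

static int pop_index(Sim& S, const std::string& label) {
  for (size_t i = 0; i < S.pops.size(); ++i)
    if (S.pops[i].label == label) return (int)i;
  stop("unknown population '%s'", label.c_str());
  return -1;
}

// dominance and category from the *unscaled* selection coefficient
static void categorise(double s_raw, double& h, int& cat) {
  if (s_raw < -0.1)        { h = 0.0;  cat = 4; }
  else if (s_raw < -0.01)  { h = 0.01; cat = 3; }
  else if (s_raw < -0.001) { h = 0.1;  cat = 2; }
  else if (s_raw < 0)      { h = 0.4;  cat = 1; }
  else                     { h = 0.5;  cat = 0; } // neutral; h never used
}

static int draw_mutation(Sim& S) {
  long long u = (long long)(unif_rand() * (double)S.genome_bp);
  if (u >= S.genome_bp) u = S.genome_bp - 1;
  double s_raw = 0.0, h = 0.5;
  int cat = 0;
  if (unif_rand() < S.p_del) {
    if (S.p_lethal > 0 && unif_rand() < S.p_lethal) s_raw = -1.0;
    else s_raw = -R::rgamma(S.gamma_shape, S.gamma_scale);
    categorise(s_raw, h, cat);
  }
  double s = s_raw * S.s_scale;
  if (s < -1.0) s = -1.0;
  S.m_gpos.push_back(u);
  S.m_s.push_back(s);
  S.m_h.push_back(h);
  S.m_cat.push_back((signed char)cat);
  S.m_origin.push_back(S.year);
  return (int)S.m_gpos.size() - 1;
}

// W = prod over homozygous (1+s) * prod over heterozygous (1+h*s), times the
// population's compacted fixed-load product; floored at 0.
static double seg_fitness(const Sim& S, const std::vector<int>& A,
                          const std::vector<int>& B) {
  double w = 1.0;
  size_t i = 0, j = 0;
  while (i < A.size() && j < B.size()) {
    int a = A[i], b = B[j];
    if (a == b) {
      if (S.m_s[a] != 0) w *= 1.0 + S.m_s[a];
      ++i; ++j;
    } else if (S.m_gpos[a] < S.m_gpos[b] ||
               (S.m_gpos[a] == S.m_gpos[b] && a < b)) {
      if (S.m_s[a] != 0) w *= 1.0 + S.m_h[a] * S.m_s[a];
      ++i;
    } else {
      if (S.m_s[b] != 0) w *= 1.0 + S.m_h[b] * S.m_s[b];
      ++j;
    }
  }
  for (; i < A.size(); ++i) if (S.m_s[A[i]] != 0) w *= 1.0 + S.m_h[A[i]] * S.m_s[A[i]];
  for (; j < B.size(); ++j) if (S.m_s[B[j]] != 0) w *= 1.0 + S.m_h[B[j]] * S.m_s[B[j]];
  if (w < 0) w = 0;
  return w;
}

static double ind_fitness(const Sim& S, const Pop& P, const Ind& d) {
  double w = seg_fitness(S, d.d1, d.d2) * P.fixedW;
  if (w < 0) w = 0;
  if (w > 1) w = 1;
  return w;
}

// append entries of hap with gpos in [glo, ghi); haplotypes are sorted by
// gpos so the slice is contiguous and the output stays sorted
static void copy_range(const Sim& S, const std::vector<int>& hap,
                       long long glo, long long ghi,
                       std::vector<int>& out, std::vector<int>& del) {
  auto cmp = [&S](int id, long long v) { return S.m_gpos[id] < v; };
  auto it0 = std::lower_bound(hap.begin(), hap.end(), glo, cmp);
  auto it1 = std::lower_bound(it0, hap.end(), ghi, cmp);
  for (auto it = it0; it != it1; ++it) {
    out.push_back(*it);
    if (S.m_s[*it] != 0) del.push_back(*it);
  }
}

// One recombined parental gamete: per chromosome a random starting haplotype,
// Binomial(G-1, r) crossovers at gene boundaries (mutations within a gene
// always co-segregate), free recombination between chromosomes. The gamete
// is assembled as alternating contiguous segment copies, so it stays sorted.
// New mutations: Poisson(mu * genome bp), drawn from the DFE.
static void make_gamete(Sim& S, const Ind& par, std::vector<int>& out,
                        std::vector<int>& del, bool mutate) {
  out.clear();
  del.clear();
  int G = S.genes_per_chrom;
  std::vector<int>& bps = S.t1;
  for (int c = 0; c < S.n_chrom; ++c) {
    long long lo = (long long)c * S.chrom_len, hi = lo + S.chrom_len;
    bps.clear();
    if (S.r_gene > 0 && G > 1) {
      int nb = (int)R::rbinom(G - 1, S.r_gene);
      while ((int)bps.size() < nb) {
        int b = 1 + (int)(unif_rand() * (G - 1));
        if (b > G - 1) b = G - 1;
        if (std::find(bps.begin(), bps.end(), b) == bps.end()) bps.push_back(b);
      }
      std::sort(bps.begin(), bps.end());
    }
    int active = (unif_rand() < 0.5) ? 0 : 1;
    long long seg_lo = lo;
    for (size_t k = 0; k <= bps.size(); ++k) {
      long long seg_hi = (k < bps.size()) ? lo + (long long)bps[k] * S.gene_len
                                          : hi;
      copy_range(S, active == 0 ? par.h1 : par.h2, seg_lo, seg_hi, out, del);
      active ^= 1;
      seg_lo = seg_hi;
    }
  }
  if (mutate && S.mu > 0) {
    int nm = (int)R::rpois(S.mu * (double)S.genome_bp);
    for (int m = 0; m < nm; ++m) {
      int id = draw_mutation(S);
      auto cmp = [&S](int a, int b) { return S.less(a, b); };
      out.insert(std::lower_bound(out.begin(), out.end(), id, cmp), id);
      if (S.m_s[id] != 0)
        del.insert(std::lower_bound(del.begin(), del.end(), id, cmp), id);
    }
  }
}

// rebuild the mutation table keeping only ids still referenced, renumbered
// in (gpos, id) order so the haplotype sort order is preserved; keeps the
// table small enough to stay cache-resident
static void gc_mutations(Sim& S) {
  size_t M = S.m_gpos.size();
  std::vector<char> live(M, 0);
  for (auto& P : S.pops) {
    for (auto& d : P.inds) {
      for (int id : d.h1) live[id] = 1;
      for (int id : d.h2) live[id] = 1;
    }
    for (int id : P.fixed) live[id] = 1;
  }
  std::vector<int> ids;
  for (size_t i = 0; i < M; ++i) if (live[i]) ids.push_back((int)i);
  std::sort(ids.begin(), ids.end(),
            [&S](int a, int b) { return S.less(a, b); });
  std::vector<int> map(M, -1);
  std::vector<long long> gpos(ids.size());
  std::vector<double> s(ids.size()), h(ids.size());
  std::vector<signed char> cat(ids.size());
  std::vector<int> origin(ids.size());
  for (size_t i = 0; i < ids.size(); ++i) {
    map[ids[i]] = (int)i;
    gpos[i] = S.m_gpos[ids[i]];
    s[i] = S.m_s[ids[i]];
    h[i] = S.m_h[ids[i]];
    cat[i] = S.m_cat[ids[i]];
    origin[i] = S.m_origin[ids[i]];
  }
  S.m_gpos.swap(gpos); S.m_s.swap(s); S.m_h.swap(h);
  S.m_cat.swap(cat); S.m_origin.swap(origin);
  for (auto& P : S.pops) {
    for (auto& d : P.inds) {
      for (int& id : d.h1) id = map[id];
      for (int& id : d.h2) id = map[id];
      for (int& id : d.d1) id = map[id];
      for (int& id : d.d2) id = map[id];
    }
    for (int& id : P.fixed) id = map[id];
  }
}

// [[Rcpp::export(name = ".sim_new")]]
SEXP sim_new(List arch, List dfe, List lh) {
  Sim* S = new Sim();
  S->n_chrom = as<int>(arch["n_chromosomes"]);
  S->genes_per_chrom = as<int>(arch["genes_per_chromosome"]);
  S->gene_len = as<int>(arch["gene_length"]);
  S->chrom_len = (long long)S->genes_per_chrom * S->gene_len;
  S->genome_bp = S->chrom_len * S->n_chrom;
  S->mu = as<double>(arch["mutation_rate"]);
  S->r_gene = as<double>(arch["intergene_recomb"]);
  S->p_del = as<double>(dfe["p_deleterious"]);
  S->gamma_shape = as<double>(dfe["gamma_shape"]);
  S->gamma_scale = as<double>(dfe["gamma_mean_s"]);
  S->gamma_scale = std::abs(S->gamma_scale) / S->gamma_shape; // gamma scale parameter
  S->s_scale = as<double>(dfe["s_scale"]);
  S->p_lethal = as<double>(dfe["p_lethal"]);
  S->first_repro = as<int>(lh["first_repro_age"]);
  S->max_repro = as<int>(lh["max_repro_age"]);
  S->max_longevity = as<int>(lh["max_longevity"]);
  S->male_frac = as<double>(lh["male_breeding_fraction"]);
  NumericVector lp = lh["litter_probs"];
  double c = 0;
  for (double p : lp) { c += p; S->litter_cum.push_back(c); }
  NumericVector am = lh["age_mortality"];
  S->age_mort = std::vector<double>(am.begin(), am.end());
  if ((int)S->age_mort.size() != S->max_longevity + 1)
    stop("age_mortality must have max_longevity + 1 entries");
  S->year = 0;
  return Rcpp::XPtr<Sim>(S, true);
}

// [[Rcpp::export(name = ".sim_clone")]]
SEXP sim_clone(SEXP xp) {
  Sim& S = get(xp);
  return Rcpp::XPtr<Sim>(new Sim(S), true);
}

// [[Rcpp::export(name = ".sim_set_year")]]
void sim_set_year(SEXP xp, int year) { get(xp).year = year; }

// [[Rcpp::export(name = ".sim_add_population")]]
void sim_add_population(SEXP xp, std::string label, double K, int n_init,
                        int init_age_max) {
  Sim& S = get(xp);
  for (auto& p : S.pops)
    if (p.label == label) stop("population '%s' already exists", label.c_str());
  Pop P;
  P.label = label;
  P.K = K;
  for (int i = 0; i < n_init; ++i) {
    Ind d;
    d.sex = unif_rand() < 0.5 ? 0 : 1;
    d.age = init_age_max > 0 ? (int)(unif_rand() * (init_age_max + 1)) : 0;
    if (d.age > init_age_max) d.age = init_age_max;
    d.w = 1.0;
    P.inds.push_back(std::move(d));
  }
  S.pops.push_back(std::move(P));
}

// [[Rcpp::export(name = ".sim_set_capacity")]]
void sim_set_capacity(SEXP xp, std::string pop, double K) {
  Sim& S = get(xp);
  S.pops[pop_index(S, pop)].K = K;
}

// Analytic neutral seeding at mutation-drift equilibrium: the expected number
// of neutral sites at derived count i in 2N genomes is theta*L/i.
// [[Rcpp::export(name = ".sim_seed_neutral")]]
void sim_seed_neutral(SEXP xp, std::string pop, double theta_site) {
  Sim& S = get(xp);
  Pop& P = S.pops[pop_index(S, pop)];
  int N = (int)P.inds.size();
  if (N == 0) stop("cannot seed an empty population");
  int twoN = 2 * N;
  double thetaL = theta_site * (double)S.genome_bp;
  std::vector<int> slots(twoN);
  for (int i = 0; i < twoN; ++i) slots[i] = i;
  for (int i = 1; i < twoN; ++i) {
    int m = (int)R::rpois(thetaL / i);
    for (int s = 0; s < m; ++s) {
      long long u = (long long)(unif_rand() * (double)S.genome_bp);
      if (u >= S.genome_bp) u = S.genome_bp - 1;
      S.m_gpos.push_back(u);
      S.m_s.push_back(0.0);
      S.m_h.push_back(0.5);
      S.m_cat.push_back(0);
      S.m_origin.push_back(S.year);
      int id = (int)S.m_gpos.size() - 1;
      for (int j = 0; j < i; ++j) { // partial Fisher-Yates: i distinct slots
        int r = j + (int)(unif_rand() * (twoN - j));
        if (r >= twoN) r = twoN - 1;
        std::swap(slots[j], slots[r]);
        int slot = slots[j];
        Ind& d = P.inds[slot / 2];
        (slot % 2 == 0 ? d.h1 : d.h2).push_back(id);
      }
    }
  }
  for (auto& d : P.inds) {
    auto cmp = [&S](int a, int b) { return S.less(a, b); };
    std::sort(d.h1.begin(), d.h1.end(), cmp);
    std::sort(d.h2.begin(), d.h2.end(), cmp);
    d.d1.clear(); d.d2.clear();
    for (int id : d.h1) if (S.m_s[id] != 0) d.d1.push_back(id);
    for (int id : d.h2) if (S.m_s[id] != 0) d.d2.push_back(id);
    d.w = ind_fitness(S, P, d);
  }
}

// [[Rcpp::export(name = ".sim_reproduce")]]
void sim_reproduce(SEXP xp) {
  Sim& S = get(xp);
  for (auto& P : S.pops) {
    int N0 = (int)P.inds.size();
    if (N0 == 0) continue;
    std::vector<int> sires, moms;
    for (int i = 0; i < N0; ++i) {
      const Ind& d = P.inds[i];
      if (d.age < S.first_repro || d.age > S.max_repro) continue;
      if (d.sex == 1) { if (unif_rand() < S.male_frac) sires.push_back(i); }
      else moms.push_back(i);
    }
    if (sires.empty() || moms.empty()) continue;
    for (int mi : moms) {
      int si = sires[(int)(unif_rand() * sires.size())];
      double u = unif_rand();
      int litter = (int)S.litter_cum.size();
      for (size_t k = 0; k < S.litter_cum.size(); ++k)
        if (u <= S.litter_cum[k]) { litter = (int)k + 1; break; }
      for (int c = 0; c < litter; ++c) {
        Ind calf;
        calf.sex = unif_rand() < 0.5 ? 0 : 1;
        calf.age = 0;
        {
          const Ind& mom = P.inds[mi];
          calf.h1.reserve((mom.h1.size() + mom.h2.size()) / 2 + 8);
          make_gamete(S, mom, calf.h1, calf.d1, true);
        }
        {
          const Ind& sir = P.inds[si];
          calf.h2.reserve((sir.h1.size() + sir.h2.size()) / 2 + 8);
          make_gamete(S, sir, calf.h2, calf.d2, true);
        }
        calf.w = ind_fitness(S, P, calf);
        P.inds.push_back(std::move(calf));
      }
    }
  }
}

// [[Rcpp::export(name = ".sim_survive")]]
void sim_survive(SEXP xp) {
  Sim& S = get(xp);
  for (auto& P : S.pops) {
    size_t N = P.inds.size();
    if (N == 0) continue;
    double dens = P.K / (double)N;
    if (dens > 1) dens = 1;
    size_t w = 0;
    for (size_t i = 0; i < N; ++i) {
      Ind& d = P.inds[i];
      if (d.age > S.max_longevity) continue;
      double p = d.w * (1.0 - S.age_mort[d.age]) * dens;
      if (p > 1) p = 1;
      if (p > 0 && unif_rand() < p) {
        d.age += 1;
        if (d.age <= S.max_longevity) {
          if (w != i) P.inds[w] = std::move(d);
          ++w;
        }
      }
    }
    P.inds.resize(w);
  }
}

// Founding: copy k individuals sampled uniformly without replacement from the
// source into a new population; the source persists. The island inherits the
// source's compacted fixed mutations.
// [[Rcpp::export(name = ".sim_found")]]
void sim_found(SEXP xp, std::string from, std::string to, int k, double K) {
  Sim& S = get(xp);
  Pop& src = S.pops[pop_index(S, from)];
  int N = (int)src.inds.size();
  if (k > N) stop("cannot draw %d founders from a population of %d", k, N);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int j = 0; j < k; ++j) {
    int r = j + (int)(unif_rand() * (N - j));
    if (r >= N) r = N - 1;
    std::swap(idx[j], idx[r]);
  }
  Pop P;
  P.label = to;
  P.K = K;
  P.fixed = src.fixed;
  P.fixedW = src.fixedW;
  for (int j = 0; j < k; ++j) P.inds.push_back(src.inds[idx[j]]);
  S.pops.push_back(std::move(P));
}

// Move mutations now fixed within a population out of the haplotypes into the
// population's fixed list (summaries are unchanged: fixed sites re-enter the
// sampled state and the fitness product through fixedW).
// [[Rcpp::export(name = ".sim_compact")]]
void sim_compact(SEXP xp) {
  Sim& S = get(xp);
  for (auto& P : S.pops) {
    int N = (int)P.inds.size();
    if (N == 0) continue;
    std::unordered_map<int, int> cnt;
    for (auto& d : P.inds) {
      for (int id : d.h1) ++cnt[id];
      for (int id : d.h2) ++cnt[id];
    }
    std::unordered_set<int> fix;
    for (auto& kv : cnt) if (kv.second == 2 * N) fix.insert(kv.first);
    if (fix.empty()) continue;
    for (auto& d : P.inds) {
      auto rm = [&fix](int id) { return fix.count(id) > 0; };
      d.h1.erase(std::remove_if(d.h1.begin(), d.h1.end(), rm), d.h1.end());
      d.h2.erase(std::remove_if(d.h2.begin(), d.h2.end(), rm), d.h2.end());
      d.d1.erase(std::remove_if(d.d1.begin(), d.d1.end(), rm), d.d1.end());
      d.d2.erase(std::remove_if(d.d2.begin(), d.d2.end(), rm), d.d2.end());
    }
    for (int id : fix) {
      P.fixed.push_back(id);
      if (S.m_s[id] != 0) P.fixedW *= 1.0 + S.m_s[id];
    }
  }
  if (S.m_gpos.size() > 50000) gc_mutations(S);
}

// [[Rcpp::export(name = ".sim_census")]]
List sim_census(SEXP xp) {
  Sim& S = get(xp);
  int n = (int)S.pops.size();
  CharacterVector lab(n);
  IntegerVector N(n);
  NumericVector K(n), mw(n), ma(n);
  for (int i = 0; i < n; ++i) {
    const Pop& P = S.pops[i];
    lab[i] = P.label;
    N[i] = (int)P.inds.size();
    K[i] = P.K;
    double sw = 0, sa = 0;
    for (auto& d : P.inds) { sw += d.w; sa += d.age; }
    mw[i] = N[i] ? sw / N[i] : NA_REAL;
    ma[i] = N[i] ? sa / N[i] : NA_REAL;
  }
  return List::create(_["population"] = lab, _["N"] = N, _["K"] = K,
                      _["mean_fitness"] = mw, _["mean_age"] = ma);
}

static List mut_info(const Sim& S, const std::vector<int>& ids) {
  int n = (int)ids.size();
  IntegerVector chrom(n), pos(n), origin(n), id(n);
  NumericVector s(n), h(n);
  IntegerVector cat(n);
  for (int i = 0; i < n; ++i) {
    int m = ids[i];
    id[i] = m;
    chrom[i] = (int)(S.m_gpos[m] / S.chrom_len) + 1;
    pos[i] = (int)(S.m_gpos[m] % S.chrom_len);
    s[i] = S.m_s[m];
    h[i] = S.m_h[m];
    cat[i] = (int)S.m_cat[m];
    origin[i] = S.m_origin[m];
  }
  return List::create(_["id"] = id, _["chrom"] = chrom, _["pos"] = pos,
                      _["s"] = s, _["h"] = h, _["category"] = cat,
                      _["origin_year"] = origin);
}

// Sampled population state: genotype matrix over the union of mutations
// carried by the sampled individuals, plus the population's fixed list.
// [[Rcpp::export(name = ".sim_sample_state")]]
List sim_sample_state(SEXP xp, std::string pop, int n) {
  Sim& S = get(xp);
  Pop& P = S.pops[pop_index(S, pop)];
  int N = (int)P.inds.size();
  if (N == 0) stop("population '%s' is extinct", pop.c_str());
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  int ns = std::min(n, N);
  for (int j = 0; j < ns; ++j) {
    int r = j + (int)(unif_rand() * (N - j));
    if (r >= N) r = N - 1;
    std::swap(idx[j], idx[r]);
  }
  idx.resize(ns);
  std::unordered_set<int> seen;
  std::vector<int> ids;
  for (int i : idx) {
    for (int id : P.inds[i].h1) if (seen.insert(id).second) ids.push_back(id);
    for (int id : P.inds[i].h2) if (seen.insert(id).second) ids.push_back(id);
  }
  std::sort(ids.begin(), ids.end(),
            [&S](int a, int b) { return S.less(a, b); });
  std::unordered_map<int, int> row;
  for (size_t i = 0; i < ids.size(); ++i) row[ids[i]] = (int)i;
  IntegerMatrix geno((int)ids.size(), ns);
  IntegerVector age(ns), sex(ns);
  for (int j = 0; j < ns; ++j) {
    const Ind& d = P.inds[idx[j]];
    for (int id : d.h1) geno(row[id], j) += 1;
    for (int id : d.h2) geno(row[id], j) += 1;
    age[j] = d.age;
    sex[j] = d.sex;
  }
  return List::create(_["geno"] = geno, _["site"] = mut_info(S, ids),
                      _["fixed"] = mut_info(S, P.fixed),
                      _["age"] = age, _["sex"] = sex,
                      _["genome_bp"] = (double)S.genome_bp,
                      _["chrom_len"] = (double)S.chrom_len,
                      _["n_chrom"] = S.n_chrom);
}

// ---- fine-grained access used by unit tests and toy-state construction ----

// [[Rcpp::export(name = ".sim_pop_names")]]
CharacterVector sim_pop_names(SEXP xp) {
  Sim& S = get(xp);
  CharacterVector out(S.pops.size());
  for (size_t i = 0; i < S.pops.size(); ++i) out[i] = S.pops[i].label;
  return out;
}

// [[Rcpp::export(name = ".sim_n_mutations")]]
int sim_n_mutations(SEXP xp) { return (int)get(xp).m_gpos.size(); }

// [[Rcpp::export(name = ".sim_new_mutation")]]
int sim_new_mutation(SEXP xp, int chrom, int pos, double s, double h, int cat) {
  Sim& S = get(xp);
  if (chrom < 1 || chrom > S.n_chrom) stop("chrom out of range");
  if (pos < 0 || pos >= S.chrom_len) stop("pos out of range");
  S.m_gpos.push_back((long long)(chrom - 1) * S.chrom_len + pos);
  S.m_s.push_back(s);
  S.m_h.push_back(h);
  S.m_cat.push_back((signed char)cat);
  S.m_origin.push_back(S.year);
  return (int)S.m_gpos.size() - 1;
}

// [[Rcpp::export(name = ".sim_sample_dfe_mutation")]]
List sim_sample_dfe_mutation(SEXP xp) {
  Sim& S = get(xp);
  int id = draw_mutation(S);
  std::vector<int> v(1, id);
  return mut_info(S, v);
}

// [[Rcpp::export(name = ".sim_add_individual")]]
void sim_add_individual(SEXP xp, std::string pop, int sex, int age,
                        IntegerVector h1, IntegerVector h2) {
  Sim& S = get(xp);
  Pop& P = S.pops[pop_index(S, pop)];
  Ind d;
  d.sex = (char)sex;
  d.age = age;
  d.h1 = std::vector<int>(h1.begin(), h1.end());
  d.h2 = std::vector<int>(h2.begin(), h2.end());
  auto cmp = [&S](int a, int b) { return S.less(a, b); };
  std::sort(d.h1.begin(), d.h1.end(), cmp);
  std::sort(d.h2.begin(), d.h2.end(), cmp);
  for (int id : d.h1) if (id < 0 || id >= (int)S.m_gpos.size()) stop("bad mutation id");
  for (int id : d.h2) if (id < 0 || id >= (int)S.m_gpos.size()) stop("bad mutation id");
  for (int id : d.h1) if (S.m_s[id] != 0) d.d1.push_back(id);
  for (int id : d.h2) if (S.m_s[id] != 0) d.d2.push_back(id);
  d.w = ind_fitness(S, P, d);
  P.inds.push_back(std::move(d));
}

// [[Rcpp::export(name = ".sim_individuals")]]
DataFrame sim_individuals(SEXP xp, std::string pop) {
  Sim& S = get(xp);
  Pop& P = S.pops[pop_index(S, pop)];
  int n = (int)P.inds.size();
  IntegerVector sex(n), age(n), nmut(n);
  NumericVector w(n);
  for (int i = 0; i < n; ++i) {
    sex[i] = P.inds[i].sex;
    age[i] = P.inds[i].age;
    w[i] = P.inds[i].w;
    nmut[i] = (int)(P.inds[i].h1.size() + P.inds[i].h2.size());
  }
  return DataFrame::create(_["sex"] = sex, _["age"] = age, _["fitness"] = w,
                           _["n_mut"] = nmut);
}

// [[Rcpp::export(name = ".sim_haplotypes")]]
List sim_haplotypes(SEXP xp, std::string pop, int i) {
  Sim& S = get(xp);
  Pop& P = S.pops[pop_index(S, pop)];
  if (i < 1 || i > (int)P.inds.size()) stop("individual index out of range");
  const Ind& d = P.inds[i - 1];
  return List::create(_["h1"] = IntegerVector(d.h1.begin(), d.h1.end()),
                      _["h2"] = IntegerVector(d.h2.begin(), d.h2.end()));
}

// [[Rcpp::export(name = ".sim_make_gamete")]]
IntegerVector sim_make_gamete(SEXP xp, std::string pop, int i, bool mutate) {
  Sim& S = get(xp);
  Pop& P = S.pops[pop_index(S, pop)];
  if (i < 1 || i > (int)P.inds.size()) stop("individual index out of range");
  std::vector<int> out, del;
  make_gamete(S, P.inds[i - 1], out, del, mutate);
  return IntegerVector(out.begin(), out.end());
}

// [[Rcpp::export(name = ".sim_fixed_info")]]
List sim_fixed_info(SEXP xp, std::string pop) {
  Sim& S = get(xp);
  Pop& P = S.pops[pop_index(S, pop)];
  return List::create(_["fixed"] = mut_info(S, P.fixed),
                      _["fixedW"] = P.fixedW);
}
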