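// Core period loop of the two-sex, age-structured simulator.
//
// All stochastic draws use R's RNG (unif_rand via RNGScope), so results are
// reproducible from set.seed() on the R side and identical whether a period
// is advanced through cpp_step() or through the R-level run loop.
//
// Conventions shared with the R side:
//   sex:    0 = male, 1 = female
//   effect: 0 = mortality, 1 = fertility
//   scope:  0 = both sexes, 1 = male only, 2 = female only
//   age classes are 1-based (1..18); vectors indexed age-1.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const int N_CLASSES = 18;

// Multiplicative genetic load on one vital rate.  Each mutant allele at an
// active locus (individual at or past the locus onset class, sex within the
// locus scope, matching effect type) scales the rate: heterozygote by
// (1 - h*e), homozygote by (1 - e)^2.
static double load_factor_row(const IntegerMatrix& geno, int row,
                              int age, int sex, int type,
                              const IntegerVector& onset,
                              const NumericVector& e,
                              const IntegerVector& effect,
                              const IntegerVector& scope,
                              const NumericVector& h) {
  double f = 1.0;
  const int L = onset.size();
  for (int l = 0; l < L; ++l) {
    if (effect[l] != type) continue;
    const int sc = scope[l];
    if (sc == 1 && sex != 0) continue;
    if (sc == 2 && sex != 1) continue;
    if (age < onset[l]) continue;
    const int c = geno(row, l);
    if (c == 1) {
      f *= 1.0 - h[l] * e[l];
    } else if (c == 2) {
      const double x = 1.0 - e[l];
      f *= x * x;
    }
  }
  if (f < 0.0) f = 0.0;
  if (f > 1.0) f = 1.0;
  return f;
}

// Mendelian gamete from one parent row, with optional per-copy mutation of
// wild-type alleles (no back mutation).
static void gamete_from_row(const IntegerMatrix& geno, int row,
                            const NumericVector& mu, bool mutation_on,
                            std::vector<int>& out) {
  const int L = mu.size();
  for (int l = 0; l < L; ++l) {
    const int c = geno(row, l);
    int a;
    if (c == 2) {
      a = 1;
    } else if (c == 1) {
      a = (unif_rand() < 0.5) ? 1 : 0;
    } else {
      a = 0;
    }
    if (mutation_on && a == 0 && mu[l] > 0.0 && unif_rand() < mu[l]) a = 1;
    out[l] = a;
  }
}

// Rejection loop: uniform father, uniform mother, accept pair with M[i][j],
// then birth with the product of the parents' effective fertilities.
// Returns attempts used; father/mother are 0-based indices into the pools.
static int draw_parents(const std::vector<int>& age_sm,
                        const std::vector<int>& age_sf,
                        const std::vector<double>& fert_sm,
                        const std::vector<double>& fert_sf,
                        const NumericMatrix& M,
                        double max_attempts,
                        int& father, int& mother) {
  const int nm = (int) age_sm.size();
  const int nf = (int) age_sf.size();
  double attempts = 0;
  while (true) {
    attempts += 1;
    if (attempts > max_attempts)
      stop("no fertile pairs: no birth after %.0f attempts "
           "(degenerate mating matrix / fertility configuration)",
           max_attempts);
    int fa = (int) (unif_rand() * nm); if (fa >= nm) fa = nm - 1;
    int mo = (int) (unif_rand() * nf); if (mo >= nf) mo = nf - 1;
    if (unif_rand() >= M(age_sm[fa] - 1, age_sf[mo] - 1)) continue;
    if (unif_rand() >= fert_sm[fa] * fert_sf[mo]) continue;
    father = fa; mother = mo;
    return (int) attempts;
  }
}

// [[Rcpp::export]]
double cpp_load_factor(IntegerVector genotype, int age, int sex, int type,
                       IntegerVector onset, NumericVector e,
                       IntegerVector effect, IntegerVector scope,
                       NumericVector h) {
  IntegerMatrix g(1, genotype.size());
  for (int l = 0; l < genotype.size(); ++l) g(0, l) = genotype[l];
  return load_factor_row(g, 0, age, sex, type, onset, e, effect, scope, h);
}

// [[Rcpp::export]]
IntegerVector cpp_gamete(IntegerVector genotype, NumericVector mu,
                         bool mutation_on) {
  IntegerMatrix g(1, genotype.size());
  for (int l = 0; l < genotype.size(); ++l) g(0, l) = genotype[l];
  std::vector<int> out(genotype.size());
  gamete_from_row(g, 0, mu, mutation_on, out);
  return wrap(out);
}

// [[Rcpp::export]]
IntegerVector cpp_mutate_alleles(IntegerVector alleles, NumericVector mu) {
  IntegerVector out = clone(alleles);
  for (int l = 0; l < out.size(); ++l) {
    if (out[l] == 0 && mu[l] > 0.0 && unif_rand() < mu[l]) out[l] = 1;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_simulate_birth(IntegerVector age_m, IntegerMatrix geno_m,
                        IntegerVector age_f, IntegerMatrix geno_f,
                        NumericVector fert_tab_m, NumericVector fert_tab_f,
                        NumericMatrix M,
                        IntegerVector onset, NumericVector e,
                        NumericVector mu, IntegerVector effect,
                        IntegerVector scope, NumericVector h,
                        double max_attempts) {
  const int nm = age_m.size(), nf = age_f.size();
  if (nm == 0 || nf == 0) stop("both parent pools must be non-empty");
  std::vector<int> am(nm), af(nf);
  std::vector<double> fm(nm), ff(nf);
  for (int i = 0; i < nm; ++i) {
    am[i] = age_m[i];
    fm[i] = fert_tab_m[age_m[i] - 1] *
      load_factor_row(geno_m, i, age_m[i], 0, 1, onset, e, effect, scope, h);
  }
  for (int i = 0; i < nf; ++i) {
    af[i] = age_f[i];
    ff[i] = fert_tab_f[age_f[i] - 1] *
      load_factor_row(geno_f, i, age_f[i], 1, 1, onset, e, effect, scope, h);
  }
  int fa = -1, mo = -1;
  int att = draw_parents(am, af, fm, ff, M, max_attempts, fa, mo);
  return List::create(_["father"] = fa + 1, _["mother"] = mo + 1,
                      _["attempts"] = att);
}

// One full period: survival draws with age advancement (class 18 always
// dies), then per-sex replacement of deaths by newborns in class 1.
// Survivors' advanced ages are used for mating; newborns never mate or die
// within their birth period.
// [[Rcpp::export]]
List cpp_step(IntegerVector age_m, IntegerMatrix geno_m,
              IntegerVector age_f, IntegerMatrix geno_f,
              NumericVector surv_tab_m, NumericVector surv_tab_f,
              NumericVector fert_tab_m, NumericVector fert_tab_f,
              NumericMatrix M,
              IntegerVector onset, NumericVector e, NumericVector mu,
              IntegerVector effect, IntegerVector scope, NumericVector h,
              bool mutation_on, double max_attempts) {
  const int Nm = age_m.size(), Nf = age_f.size();
  const int L = onset.size();

  std::vector<int> surv_idx_m, surv_idx_f;
  std::vector<int> new_age_m, new_age_f;
  surv_idx_m.reserve(Nm); surv_idx_f.reserve(Nf);

  for (int i = 0; i < Nm; ++i) {
    const int a = age_m[i];
    double p = (a >= N_CLASSES) ? 0.0 :
      surv_tab_m[a - 1] *
      load_factor_row(geno_m, i, a, 0, 0, onset, e, effect, scope, h);
    if (p > 0.0 && unif_rand() < p) {
      surv_idx_m.push_back(i);
      new_age_m.push_back(a + 1);
    }
  }
  for (int i = 0; i < Nf; ++i) {
    const int a = age_f[i];
    double p = (a >= N_CLASSES) ? 0.0 :
      surv_tab_f[a - 1] *
      load_factor_row(geno_f, i, a, 1, 0, onset, e, effect, scope, h);
    if (p > 0.0 && unif_rand() < p) {
      surv_idx_f.push_back(i);
      new_age_f.push_back(a + 1);
    }
  }

  const int nsm = (int) surv_idx_m.size(), nsf = (int) surv_idx_f.size();
  const int deaths_m = Nm - nsm, deaths_f = Nf - nsf;
  if ((deaths_m > 0 || deaths_f > 0) && (nsm == 0 || nsf == 0))
    stop("population collapse: a sex has no survivors to parent newborns");

  // Effective fertility of each survivor at its advanced age class.
  std::vector<double> fert_sm(nsm), fert_sf(nsf);
  for (int k = 0; k < nsm; ++k)
    fert_sm[k] = fert_tab_m[new_age_m[k] - 1] *
      load_factor_row(geno_m, surv_idx_m[k], new_age_m[k], 0, 1,
                      onset, e, effect, scope, h);
  for (int k = 0; k < nsf; ++k)
    fert_sf[k] = fert_tab_f[new_age_f[k] - 1] *
      load_factor_row(geno_f, surv_idx_f[k], new_age_f[k], 1, 1,
                      onset, e, effect, scope, h);

  const int n_born = deaths_m + deaths_f;
  IntegerMatrix born_geno(n_born, L);
  std::vector<int> gam_f(L), gam_m(L);
  double total_attempts = 0;
  for (int b = 0; b < n_born; ++b) {
    int fa = -1, mo = -1;
    total_attempts += draw_parents(new_age_m, new_age_f, fert_sm, fert_sf,
                                   M, max_attempts, fa, mo);
    gamete_from_row(geno_m, surv_idx_m[fa], mu, mutation_on, gam_f);
    gamete_from_row(geno_f, surv_idx_f[mo], mu, mutation_on, gam_m);
    for (int l = 0; l < L; ++l) born_geno(b, l) = gam_f[l] + gam_m[l];
  }

  // Assemble: survivors first, then newborns (male deficits filled by the
  // first deaths_m newborns, female by the rest) so per-sex census is exact.
  IntegerVector out_age_m(Nm), out_age_f(Nf);
  IntegerMatrix out_geno_m(Nm, L), out_geno_f(Nf, L);
  for (int k = 0; k < nsm; ++k) {
    out_age_m[k] = new_age_m[k];
    for (int l = 0; l < L; ++l) out_geno_m(k, l) = geno_m(surv_idx_m[k], l);
  }
  for (int k = 0; k < nsf; ++k) {
    out_age_f[k] = new_age_f[k];
    for (int l = 0; l < L; ++l) out_geno_f(k, l) = geno_f(surv_idx_f[k], l);
  }
  for (int b = 0; b < deaths_m; ++b) {
    out_age_m[nsm + b] = 1;
    for (int l = 0; l < L; ++l) out_geno_m(nsm + b, l) = born_geno(b, l);
  }
  for (int b = 0; b < deaths_f; ++b) {
    out_age_f[nsf + b] = 1;
    for (int l = 0; l < L; ++l)
      out_geno_f(nsf + b, l) = born_geno(deaths_m + b, l);
  }

  return List::create(_["age_m"] = out_age_m, _["geno_m"] = out_geno_m,
                      _["age_f"] = out_age_f, _["geno_f"] = out_geno_f,
                      _["deaths_m"] = deaths_m, _["deaths_f"] = deaths_f,
                      _["attempts"] = total_attempts);
}

// Per-class sums of effective survival and fertility (for end-state curves):
// returns 18 x 3 matrices per sex: count, sum survival, sum fertility.
// [[Rcpp::export]]
List cpp_curve_sums(IntegerVector age_m, IntegerMatrix geno_m,
                    IntegerVector age_f, IntegerMatrix geno_f,
                    NumericVector surv_tab_m, NumericVector surv_tab_f,
                    NumericVector fert_tab_m, NumericVector fert_tab_f,
                    IntegerVector onset, NumericVector e,
                    IntegerVector effect, IntegerVector scope,
                    NumericVector h) {
  NumericMatrix male(N_CLASSES, 3), female(N_CLASSES, 3);
  for (int i = 0; i < age_m.size(); ++i) {
    const int a = age_m[i];
    male(a - 1, 0) += 1;
    male(a - 1, 1) += (a >= N_CLASSES ? 0.0 : surv_tab_m[a - 1]) *
      load_factor_row(geno_m, i, a, 0, 0, onset, e, effect, scope, h);
    male(a - 1, 2) += fert_tab_m[a - 1] *
      load_factor_row(geno_m, i, a, 0, 1, onset, e, effect, scope, h);
  }
  for (int i = 0; i < age_f.size(); ++i) {
    const int a = age_f[i];
    female(a - 1, 0) += 1;
    female(a - 1, 1) += (a >= N_CLASSES ? 0.0 : surv_tab_f[a - 1]) *
      load_factor_row(geno_f, i, a, 1, 0, onset, e, effect, scope, h);
    female(a - 1, 2) += fert_tab_f[a - 1] *
      load_factor_row(geno_f, i, a, 1, 1, onset, e, effect, scope, h);
  }
  return List::create(_["male"] = male, _["female"] = female);
}
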