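#include <Rcpp.h>
using namespace Rcpp;

// Rejection-sampling engines for the liability-threshold family simulator and
// for case-control cohort generation.  All randomness comes from R's RNG so
// that set.seed() makes every run reproducible.
//
// Liability model: G = sum_i x_i a_i - mu_g, e ~ N(0, 1 - h2), y = G + e,
// affected <=> y >= tau.  SNPs are unlinked; transmission is a fair pick of
// one of the two parental alleles per SNP.

static inline int rbern(double p) { return unif_rand() < p ? 1 : 0; }

// Family-member slots used when genotypes are returned.
enum Member { FATHER = 0, MOTHER, CHILD1, CHILD2, PSEUDO, N_MEMBER };

struct FamilyDraw {
  double g[N_MEMBER];
  double y[N_MEMBER];
};

// Forward simulation of one candidate family.  Parents are drawn from the
// allele frequencies (optionally with an assortative-mating coin), children
// by Mendelian transmission, the pseudo-control from the alleles each parent
// did not transmit to child 1.  Genotype buffers (length n per member) are
// filled only when geno != NULL.
static void draw_family_forward(const double* p, const double* a, int n,
                                double mu_g, double sd_e, int n_children,
                                int mating, FamilyDraw& fam, int** geno) {
  double gf = 0.0, gm = 0.0, g1 = 0.0, g2 = 0.0, gps = 0.0;
  // per-family coin: tails -> mother's genotype copies the father's everywhere
  bool fam_tails = (mating == 2) && (unif_rand() < 0.5);
  for (int i = 0; i < n; ++i) {
    int f1 = rbern(p[i]), f2 = rbern(p[i]);
    int m1, m2;
    if (mating == 1) {            // per-SNP coin
      if (unif_rand() < 0.5) { m1 = f1; m2 = f2; }
      else { m1 = rbern(p[i]); m2 = rbern(p[i]); }
    } else if (fam_tails) {       // per-family coin, tails
      m1 = f1; m2 = f2;
    } else {                      // random mating (or per-family heads)
      m1 = rbern(p[i]); m2 = rbern(p[i]);
    }
    int c1p = (unif_rand() < 0.5) ? f1 : f2;
    int c1m = (unif_rand() < 0.5) ? m1 : m2;
    int psp = f1 + f2 - c1p;      // untransmitted paternal allele
    int psm = m1 + m2 - c1m;      // untransmitted maternal allele
    gf += (f1 + f2) * a[i];
    gm += (m1 + m2) * a[i];
    g1 += (c1p + c1m) * a[i];
    gps += (psp + psm) * a[i];
    int c2p = 0, c2m = 0;
    if (n_children > 1) {
      c2p = (unif_rand() < 0.5) ? f1 : f2;
      c2m = (unif_rand() < 0.5) ? m1 : m2;
      g2 += (c2p + c2m) * a[i];
    }
    if (geno) {
      geno[FATHER][i] = f1 + f2;
      geno[MOTHER][i] = m1 + m2;
      geno[CHILD1][i] = c1p + c1m;
      geno[CHILD2][i] = (n_children > 1) ? c2p + c2m : NA_INTEGER;
      geno[PSEUDO][i] = psp + psm;
    }
  }
  fam.g[FATHER] = gf - mu_g;
  fam.g[MOTHER] = gm - mu_g;
  fam.g[CHILD1] = g1 - mu_g;
  fam.g[CHILD2] = (n_children > 1) ? g2 - mu_g : NA_REAL;
  fam.g[PSEUDO] = gps - mu_g;
  for (int j = 0; j < N_MEMBER; ++j) {
    if (j == CHILD2 && n_children < 2) { fam.y[j] = NA_REAL; continue; }
    fam.y[j] = fam.g[j] + sd_e * norm_rand();
  }
}

// Transmitted-first simulation of one candidate family under RANDOM mating.
// Exact shortcut: with parents drawn independently from the allele
// frequencies, child 1's transmitted alleles are iid Bernoulli(p) and the
// untransmitted alleles are independent of them, so child 1's liability can
// be evaluated (and the family rejected) before the rest of the family is
// drawn.  Returns false if child 1 failed its affection requirement.
static bool draw_family_transfirst(const double* p, const double* a, int n,
                                   double mu_g, double sd_e, int n_children,
                                   int child1_req, double tau,
                                   FamilyDraw& fam, int** geno,
                                   std::vector<int>& tp, std::vector<int>& tm) {
  double g1 = 0.0;
  for (int i = 0; i < n; ++i) {
    tp[i] = rbern(p[i]);
    tm[i] = rbern(p[i]);
    g1 += (tp[i] + tm[i]) * a[i];
  }
  fam.g[CHILD1] = g1 - mu_g;
  fam.y[CHILD1] = fam.g[CHILD1] + sd_e * norm_rand();
  bool aff1 = fam.y[CHILD1] >= tau;
  if (child1_req == 1 && !aff1) return false;
  if (child1_req == -1 && aff1) return false;
  // survivor: draw the untransmitted alleles and the rest of the family
  double gf = 0.0, gm = 0.0, g2 = 0.0, gps = 0.0;
  for (int i = 0; i < n; ++i) {
    int up = rbern(p[i]), um = rbern(p[i]);
    gf += (tp[i] + up) * a[i];
    gm += (tm[i] + um) * a[i];
    gps += (up + um) * a[i];
    int c2p = 0, c2m = 0;
    if (n_children > 1) {
      c2p = (unif_rand() < 0.5) ? tp[i] : up;
      c2m = (unif_rand() < 0.5) ? tm[i] : um;
      g2 += (c2p + c2m) * a[i];
    }
    if (geno) {
      geno[FATHER][i] = tp[i] + up;
      geno[MOTHER][i] = tm[i] + um;
      geno[CHILD1][i] = tp[i] + tm[i];
      geno[CHILD2][i] = (n_children > 1) ? c2p + c2m : NA_INTEGER;
      geno[PSEUDO][i] = up + um;
    }
  }
  fam.g[FATHER] = gf - mu_g;
  fam.g[MOTHER] = gm - mu_g;
  fam.g[CHILD2] = (n_children > 1) ? g2 - mu_g : NA_REAL;
  fam.g[PSEUDO] = gps - mu_g;
  fam.y[FATHER] = fam.g[FATHER] + sd_e * norm_rand();
  fam.y[MOTHER] = fam.g[MOTHER] + sd_e * norm_rand();
  fam.y[CHILD2] = (n_children > 1) ? fam.g[CHILD2] + sd_e * norm_rand() : NA_REAL;
  fam.y[PSEUDO] = fam.g[PSEUDO] + sd_e * norm_rand();
  return true;
}

// [[Rcpp::export(name = ".ascertain_engine")]]
List ascertain_engine(NumericVector p, NumericVector a, double mu_g, double h2,
                      double tau, int n_fam, int n_children,
                      IntegerVector child_req, bool parents_unaffected,
                      int mating, double max_attempts, bool keep_genotypes,
                      bool force_forward) {
  const int n = p.size();
  if (a.size() != n) stop("p and a must have the same length");
  if (n_children < 1 || n_children > 2) stop("n_children must be 1 or 2");
  if (child_req.size() != n_children) stop("child_req must have one entry per child");
  const double sd_e = std::sqrt(1.0 - h2);
  const int req1 = child_req[0];
  const int req2 = (n_children > 1) ? child_req[1] : 0;
  // the transmitted-first shortcut is only valid under random mating
  const bool transfirst = (mating == 0) && !force_forward;

  NumericMatrix G(n_fam, N_MEMBER), Y(n_fam, N_MEMBER);
  std::vector<IntegerMatrix> geno_mats;
  int* geno_ptrs[N_MEMBER];
  int** geno = NULL;
  std::vector<std::vector<int> > geno_buf;
  if (keep_genotypes) {
    for (int j = 0; j < N_MEMBER; ++j) geno_mats.push_back(IntegerMatrix(n_fam, n));
    geno_buf.assign(N_MEMBER, std::vector<int>(n));
    for (int j = 0; j < N_MEMBER; ++j) geno_ptrs[j] = geno_buf[j].data();
    geno = geno_ptrs;
  }
  std::vector<int> tp(n), tm(n);

  RNGScope scope;
  double attempts = 0.0;
  long since_check = 0;
  int accepted = 0;
  FamilyDraw fam;
  while (accepted < n_fam) {
    if (attempts >= max_attempts)
      stop("rejection sampling exceeded max_attempts (%.0f) with %d of %d families accepted",
           max_attempts, accepted, n_fam);
    attempts += 1.0;
    if (++since_check >= 1000000) { since_check = 0; checkUserInterrupt(); }
    bool ok;
    if (transfirst) {
      ok = draw_family_transfirst(p.begin(), a.begin(), n, mu_g, sd_e,
                                  n_children, req1, tau, fam, geno, tp, tm);
    } else {
      draw_family_forward(p.begin(), a.begin(), n, mu_g, sd_e, n_children,
                          mating, fam, geno);
      bool aff1 = fam.y[CHILD1] >= tau;
      ok = !((req1 == 1 && !aff1) || (req1 == -1 && aff1));
    }
    if (!ok) continue;
    if (n_children > 1) {
      bool aff2 = fam.y[CHILD2] >= tau;
      if ((req2 == 1 && !aff2) || (req2 == -1 && aff2)) continue;
    }
    if (parents_unaffected &&
        (fam.y[FATHER] >= tau || fam.y[MOTHER] >= tau)) continue;
    for (int j = 0; j < N_MEMBER; ++j) {
      G(accepted, j) = fam.g[j];
      Y(accepted, j) = fam.y[j];
    }
    if (keep_genotypes)
      for (int j = 0; j < N_MEMBER; ++j)
        for (int i = 0; i < n; ++i) geno_mats[j](accepted, i) = geno_buf[j][i];
    ++accepted;
  }

  List out = List::create(_["G"] = G, _["Y"] = Y, _["attempts"] = attempts);
  if (keep_genotypes) {
    out["geno_father"] = geno_mats[FATHER];
    out["geno_mother"] = geno_mats[MOTHER];
    out["geno_child1"] = geno_mats[CHILD1];
    out["geno_child2"] = geno_mats[CHILD2];
    out["geno_pseudo"] = geno_mats[PSEUDO];
  }
  return out;
}

// Case-control cohort sampler under Hardy-Weinberg.  Controls are plain
// population draws (optionally screened to be unaffected); cases are drawn
// by rejection until their liability exceeds tau.  X-chromosome SNPs in
// males are hemizygous, coded 0/2.
// [[Rcpp::export(name = ".sample_cc_engine")]]
List sample_cc_engine(NumericVector p, NumericVector a, double mu_g, double h2,
                      double tau, int n_cases, int n_controls,
                      bool screened_controls, LogicalVector is_x,
                      double max_attempts) {
  const int n = p.size();
  if (a.size() != n) stop("p and a must have the same length");
  const double sd_e = std::sqrt(1.0 - h2);
  const int n_ind = n_cases + n_controls;
  IntegerMatrix X(n_ind, n);
  IntegerVector phenotype(n_ind), sex(n_ind);
  NumericVector G(n_ind), Yl(n_ind);
  std::vector<int> row(n);

  RNGScope scope;
  double attempts = 0.0;
  long since_check = 0;
  int filled = 0;
  // controls first (plain draws), then cases (rejection)
  for (int stage = 0; stage < 2; ++stage) {
    int want = (stage == 0) ? n_controls : n_cases;
    int got = 0;
    while (got < want) {
      if (attempts >= max_attempts)
        stop("rejection sampling exceeded max_attempts (%.0f)", max_attempts);
      attempts += 1.0;
      if (++since_check >= 100000) { since_check = 0; checkUserInterrupt(); }
      int male = rbern(0.5);
      double g = 0.0;
      for (int i = 0; i < n; ++i) {
        int x;
        if (male && is_x[i]) x = 2 * rbern(p[i]);
        else x = rbern(p[i]) + rbern(p[i]);
        row[i] = x;
        g += x * a[i];
      }
      g -= mu_g;
      double y = g + sd_e * norm_rand();
      bool affected = y >= tau;
      if (stage == 0 && screened_controls && affected) continue;
      if (stage == 1 && !affected) continue;
      for (int i = 0; i < n; ++i) X(filled, i) = row[i];
      phenotype[filled] = (stage == 1) ? 1 : 0;
      sex[filled] = male ? 1 : 2;
      G[filled] = g;
      Yl[filled] = y;
      ++filled; ++got;
    }
  }
  return List::create(_["genotypes"] = X, _["phenotype"] = phenotype,
                      _["sex"] = sex, _["G"] = G, _["liability"] = Yl,
                      _["attempts"] = attempts);
}
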