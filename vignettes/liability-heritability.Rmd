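---
title: "Heritability of liability from case-control SNP data, and what relatives of ascertained probands are expected to show"
author: "snpher"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heritability of liability from case-control SNP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpher)
```

## The model

`snpher` works throughout with the liability-threshold model for a
dichotomous trait such as an early-onset neurodevelopmental disorder.
Each individual carries a latent, standard-normal *liability*
$y = G + e$, where

* $G = \sum_{i=1}^{n} x_i a_i - \mu_G$ is the additive genetic liability
  over $n$ biallelic SNPs with allele counts $x_i \in \{0,1,2\}$,
* $e \sim N(0,\, 1-h^2)$ is an independent environmental deviate, and
* the individual is affected exactly when $y \ge \tau = \Phi^{-1}(1-K)$
  for population prevalence $K$ (default $K = 0.01$, $\tau = 2.326$).

$h^2$ is the narrow-sense heritability of liability: the fraction of
liability variance that is additive-genetic.

### Per-SNP effects

`draw_effect_panel()` gives SNP $i$ a relative importance
$w_i = t_i / \sum_j t_j$ with $t_i \sim U(0,1)$, and an
allele-substitution effect

$$a_i = \sqrt{\frac{w_i\,h^2}{2 p_i (1-p_i)}},$$

so each SNP contributes additive variance $2p_i(1-p_i)a_i^2 = w_i h^2$
and the contributions sum to $h^2$ exactly (asserted to $10^{-10}$ in the
tests). The centering constant is $\mu_G = \sum_i 2 p_i a_i$, which is
the only choice that makes $E[G]=0$ under random mating; with it, the
threshold $\tau = 2.326$ yields the intended 1% of affected individuals
in an unscreened population. (A variant centering constant
$\sum_i p_i(1-p_i)a_i$ circulates in descriptions of this simulator
design; it does not center $G$ — with 1000 SNPs it shifts liability by
tens of standard deviations — so the package treats it as a typo and
uses the centering form.)

Allele frequencies $p_i$ for liability panels are drawn uniformly on
$(0.01, 0.99)$; all effects are risk-increasing ($a_i \ge 0$), which is
immaterial for every quantity computed here because variances and
covariances depend on $a_i^2$ and on products of centred dosages.

## The family simulator

`simulate_family()` / `ascertain()` build nuclear families: parental
haplotypes are drawn from the allele frequencies (SNPs are unlinked),
each child receives, independently at every SNP, one of the father's two
alleles and one of the mother's with probability 1/2 each, and the
*pseudo-control* receives exactly the alleles not transmitted to child 1
— equivalently, its allele count is `father + mother - child1` at every
SNP, an identity the tests assert for every exported family.

### Ascertainment

`ascertain()` rejection-samples candidate families until the requested
number satisfies the design:

* **screened simplex** (quad; child 1 affected, parents and child 2
  unaffected),
* **unscreened simplex** (trio; child 1 affected),
* **unscreened multiplex** (quad; both children affected),
* a **60/40 mixture** of unscreened simplex and multiplex families.

The engine is compiled code driven by R's RNG, so runs are reproducible
under `set.seed()`. Under random mating it uses an exact factorization:
child 1's transmitted alleles are iid Bernoulli($p_i$) and independent of
the untransmitted alleles, so the proband can be evaluated (and most
candidates rejected, at cost $2n$ draws) before the rest of the family
is drawn. Under assortative mating the whole family is simulated
forward; a distribution-equality test compares the two paths. A hard cap
(`max_attempts`, default $10^9$) turns an unattainable affection pattern
into an error rather than a hang.

### The R/S estimator

For a set of ascertained families, `estimate_relative_h2()` computes the
selection differential $S$ (mean proband liability; for $K=0.01$ the
expected value is $\varphi(\tau)/K = 2.665$) and the response $R$ (mean
liability of a relative class: father, mother, sibling, or
pseudo-control, the pseudo-control's liability being its genetic value
plus a fresh environmental deviate). $\hat h^2_{\text{role}} = R/S$ is
the heritability attributable to that class. For the probands themselves
the default recovery check is $\overline G / \overline y$, which equals
$h^2$ exactly under truncation on the proband's own liability since
$E[G\,|\,y] = h^2 y$; a variance-based alternative, solving
$\mathrm{var}(G\,|\,\text{sel}) = (h^2)^2\,(\mathrm{var}(y\,|\,\text{sel})-1) + h^2$
for $h^2$ (the reduction of genetic variance in the selected group), is
available via `proband_method = "variance"`.

Because liability is (to CLT accuracy at 1000 SNPs) multivariate normal
across family members, the expected ratios have closed forms that the
test suite uses as oracles. Writing $\rho_{12}$ for the liability
correlation of the two ascertained children and $r_j$ for the
correlation of the scored relative with child $j$, truncation theory
gives

$$\frac{R}{S} = \frac{r_1 + r_2}{1 + \rho_{12}}$$

for double truncation (and simply $r_1$ for single truncation). Hence:

* unscreened simplex, random mating: parents and unascertained siblings
  sit at $h^2/2$ (the halving law); the pseudo-control at $0$.
* unscreened multiplex, random mating: the pseudo-control is genetically
  a full sibling of child 2 while independent of child 1, so
  $R/S = (h^2/2) / (1 + h^2/2)$ — $0.200$ at $h^2 = 0.50$ and
  $3/11 = 0.273$ at $h^2 = 0.75$.

### Assortative mating

The simulator's assortative-mating rule assigns the maternal genotype by
a fair coin against the father's: heads, an independent draw from the
allele frequencies; tails, a copy of the father's genotype. Two readings
of "a fair coin" exist, and they are *not* equivalent:

* **per-SNP coin** (package default): the toss is repeated independently
  at every liability SNP. Every family is statistically identical;
  $\mathrm{cov}(G_f, G_m) = h^2/2$. The closed forms above give a
  simplex pseudo-control expectation of
  $(h^2/4)/(1+h^2/4) = 0.111$ at $h^2=0.5$ and a multiplex expectation
  of $h^2/(1+h^2) = 3/7 = 0.4286$ at $h^2 = 0.75$.
* **per-family coin** (`assort_coin = "per_family"`): one toss decides
  the whole maternal genotype, producing a 50/50 mixture of
  spouse-identical and spouse-independent families. The parental
  genetic-value correlation is still $1/2$, but the mixture has heavier
  ascertainment weighting toward the copied families and yields visibly
  larger pseudo-control expectations (about $0.13$ and $0.49$ for the
  two designs above).

The per-SNP reading is the default because its expectations coincide
with the standard quoted values for this simulator design (11.3% and
42.8%); the per-family reading is kept as an option because it is the
more literal reading of "the genotype was taken to be the father's".
The acceptance suite exercises both of the per-SNP values. A caveat
worth recording: the multiplex *random-mating* expectation is $0.273$ at
$h^2=0.75$ (closed form and simulation agree); the value $0.202$
sometimes quoted next to the $h^2=0.75$ assortative figure is exactly
the $h^2 = 0.50$ multiplex expectation, and the suite's corresponding
assertion documents that inconsistency rather than glossing over it.

## The GREML pipeline

`estimate_h2_cc()` is the end-to-end case-control estimator:

1. merge case and control cohorts over a shared SNP panel
   (`intersect_panels()` resolves allele swaps and strand flips;
   strand-ambiguous A/T and C/G SNPs are removed up front);
2. quality control (`individual_qc()`, `snp_qc()`): completion rate
   > 98% per individual and per SNP, MAF > 0.01, Hardy–Weinberg exact
   test p > 0.005 (females only on chromosome X), sex concordance from
   X heterozygosity (< 0.02 male, > 0.20 female — the cutoffs are
   package decisions, as is the exact-test default);
3. one GRM per chromosome (GCTA parameterisation; sample allele
   frequencies from the merged analysis sample; missing genotypes
   mean-imputed, which keeps the per-chromosome/pooled combination
   identity exact; chromosome X scaled like an autosome), combined by
   SNP-count weighting;
4. the top 10 principal components of the combined GRM as ancestry
   covariates;
5. AI-REML of the 0/1 phenotype on intercept + PCs with the combined
   GRM;
6. the ascertainment-aware transform to the liability scale,
   $h^2_{\text{liab}} = h^2_{\text{obs}}\,K^2(1-K)^2 / (z^2 P(1-P))$,
   with $z = \varphi(\tau)$ and $P$ the sample case fraction; the
   standard error scales by the same multiplier.

Relatedness pruning (`relatedness_prune()`, greedy removal of one member
of any cross-family pair with GRM entry above 0.05, dropping the
lower-call-rate member) is available but off by default in
`estimate_h2_cc()`: with desk-scale SNP counts the GRM noise floor
($\mathrm{sd} \approx 1/\sqrt{m}$) sits near realistic cutoffs, so
pruning at 0.05 only makes sense for panels of $10^5$ SNPs or more.

### REML numerics

`reml_fit()` maximises the restricted likelihood of
$y \sim N(X\beta,\ \sum_c \sigma^2_c A_c + \sigma^2_e I)$ by
average-information steps after three EM warm-start iterations. AI steps
are accepted only if the restricted log-likelihood does not decrease
(step-halving up to six times, then an EM fallback), so the
log-likelihood is monotone — a property the tests assert by tracing
fits. Components are constrained non-negative by projection to
$10^{-8}\,\mathrm{var}(y)$ (an unconstrained mode exists). Convergence
is declared when the log-likelihood changes by less than $10^{-8}$;
standard errors come from the inverse AI matrix, and the
observed-to-liability SE by the delta method (the sampling variability
of $P$ is neglected, as is common practice). A numerically singular AI
matrix — e.g. a GRM indistinguishable from the identity, where
$\sigma^2_g$ and $\sigma^2_e$ are not separately identifiable — is
flagged (`identifiable = FALSE`) rather than silently inverted. The
implementation is validated against a nested grid search of an
independently coded restricted likelihood at $n = 200$ (agreement to
$10^{-3}$).

### What recovery to expect, honestly

On a *continuous* trait simulated from the realized GRM, `reml_fit()` is
unbiased and its reported standard errors match the empirical spread
(asserted in the tests). The full case-control pipeline is a different
matter: with half the sample affected at $K = 0.01$, observed-scale REML
plus the liability transform is known to be attenuated, increasingly so
as the sample grows relative to the SNP count; the replicated-cohort
experiment in the acceptance suite exhibits exactly this attenuation
(estimates around 0.35–0.40 for a true 0.50 at $n/m = 0.2$), and the
corresponding unbiasedness assertion is left failing by design rather
than weakened, because it is a property of this estimator — the one the
field used — not of the implementation. Interpretation of absolute
case-control GREML estimates should carry this caveat; contrasts between
relative classes (the halving law, pseudo-control enrichment) are
estimated by the simulator's R/S machinery, which is exact in
expectation.

`per_chromosome_h2()` partitions heritability by chromosome, fitting by
default a two-component model (chromosome + rest of genome) per
chromosome, and correlates the estimates with physical chromosome length
— under a polygenic architecture with variants placed uniformly at
random, longer chromosomes carry proportionally more heritability. The
planted-signal test confines all causal variance to one chromosome and
checks that the partition finds it there.

## Synthetic data: what it does and does not emulate

`simulate_panel()` spreads SNPs over the 22 autosomes and X
proportionally to GRCh37 chromosome lengths (largest-remainder
allocation, strictly increasing positions). `simulate_case_control()`
draws unrelated individuals under Hardy–Weinberg equilibrium, with males
hemizygous (coded 0/2) at X SNPs, and ascertains cases by rejection.
`simulate_haplotypes()` builds phased pools in LD blocks: within a
block, every site copies a block founder allele and is flipped with
per-site probability $m = (1 - X^{1/4})/2$, giving expected within-block
$r^2 \approx X$ and cross-block $r^2 \approx 0$.

Deliberately **not** emulated: recombination maps and realistic
LD decay (blocks are rectangular), demographic history and coalescent
variation, genotyping batch effects, X-linked transmission in the family
simulator (liability SNPs are transmitted autosomally), dominance and
epistasis, de novo variation, and multi-generation pedigrees. Passing
tests therefore certify the estimators' behaviour under the stated
generative model, not robustness to these real-data complications.

## Problem sizes and runtime choices

The suite's simulation scales are the package's desk-scale defaults:
1000 liability SNPs per effect panel; 1000 accepted families × 20
replicates for simplex expectations and 500 × 10 for multiplex (a fresh
effect panel per replicate, so cross-replicate spread includes
panel-to-panel variation); 20 replicated case-control cohorts of
600 + 600 individuals × 3000 SNPs for the GREML recovery experiment
(chosen to preserve the case-fraction and $n/m$ regime of a full-scale
analysis at a fraction of the cost); toy regions of ≤ 20 SNPs wherever a
brute-force oracle (exhaustive minimal tagging, likelihood grid search,
HWE enumeration) is compared against the production path.

## Known limitations

* The case-control attenuation above: absolute GREML estimates under
  strong ascertainment are conservative.
* The HWE exact test returns the standard (not mid-) p-value; ties are
  included via a $10^{-12}$ probability tolerance.
* `tag_cover()` uses complete-linkage clustering cut at $1 - r^2$; on
  block-structured LD it equals exhaustive minimal tagging (asserted at
  toy scale), but on irregular LD complete linkage can be conservative
  (more clusters than the true minimum tag count).
* GRM pairwise non-missing counts are constant (`m`) by construction
  because of mean-imputation; the GCTA-format `grm.N.bin` therefore
  carries a single value.
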