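#' Specify an ascertainment scenario
#'
#' Encodes one of the four family-recruitment designs used to compute
#' expected heritabilities:
#' \describe{
#'   \item{`ssc_screened`}{quad; child 1 affected, father, mother and child 2
#'     all unaffected (screened simplex).}
#'   \item{`simplex_unscreened`}{trio; child 1 affected, no restriction on
#'     the parents.}
#'   \item{`multiplex_unscreened`}{quad; both children affected, no
#'     restriction on the parents.}
#'   \item{`mixture_60_40`}{60 percent unscreened simplex and 40 percent
#'     unscreened multiplex families.}
#' }
#'
#' @param scenario One of the four scenario names above.
#' @param n_families Accepted families per replicate.
#' @param h2 Proband (liability) heritability, e.g. 0.50 or 0.75.
#' @param prevalence Population prevalence K (default 0.01); the liability
#'   threshold is `qnorm(1 - K)`.
#' @param mating `"random"` or `"assortative"` (fair-coin rule).
#' @param assort_coin `"per_snp"` (default) or `"per_family"`; see
#'   [assortative_mother()].
#' @param n_replicates Number of replicates for [expected_h2_experiment()].
#' @param seed Optional integer seed.
#' @return A `scenario_spec` list, including the derived threshold `tau`.
#' @export
scenario_spec <- function(scenario = c("ssc_screened", "simplex_unscreened",
                                       "multiplex_unscreened", "mixture_60_40"),
                          n_families = 1000, h2 = 0.5, prevalence = 0.01,
                          mating = c("random", "assortative"),
                          assort_coin = c("per_snp", "per_family"),
                          n_replicates = 100, seed = NULL) {
  scenario <- match.arg(scenario)
  mating <- match.arg(mating)
  assort_coin <- match.arg(assort_coin)
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  structure(list(scenario = scenario, n_families = as.integer(n_families),
                 h2 = h2, prevalence = prevalence,
                 tau = liability_threshold(prevalence),
                 mating = mating, assort_coin = assort_coin,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "scenario_spec")
}

# scenario -> (n_children, per-child requirement, parents unaffected?)
.scenario_rules <- function(scenario) {
  switch(scenario,
    ssc_screened = list(n_children = 2L, child_req = c(1L, -1L),
                        parents_unaffected = TRUE),
    simplex_unscreened = list(n_children = 1L, child_req = 1L,
                              parents_unaffected = FALSE),
    multiplex_unscreened = list(n_children = 2L, child_req = c(1L, 1L),
                                parents_unaffected = FALSE),
    stop("no single rule set for scenario ", scenario)
  )
}

.mating_code <- function(mating, assort_coin) {
  if (mating == "random") 0L else if (assort_coin == "per_snp") 1L else 2L
}

.run_engine <- function(spec, effects, n_families, keep_genotypes,
                        max_attempts, force_forward) {
  rules <- .scenario_rules(spec$scenario)
  res <- .ascertain_engine(effects$p, effects$a, effects$mu_G, effects$h2,
                           spec$tau, as.integer(n_families), rules$n_children,
                           rules$child_req, rules$parents_unaffected,
                           .mating_code(spec$mating, spec$assort_coin),
                           max_attempts, keep_genotypes, force_forward)
  roles <- c("father", "mother", "child1", "child2", "pseudo_control")
  colnames(res$G) <- colnames(res$Y) <- roles
  res
}

#' Rejection-sample families under an explicit affection pattern
#'
#' Lower-level interface behind [ascertain()]: specify the family size and
#' the affection requirement of each member directly instead of through a
#' named scenario. Useful for designs the named scenarios do not cover,
#' such as a quad with an affected proband and an unrestricted
#' (unascertained) sibling.
#'
#' @param effects An `effect_panel`.
#' @param n_families Accepted families wanted.
#' @param n_children 1 or 2.
#' @param child_req Integer per child: `1` = must be affected, `-1` = must
#'   be unaffected, `0` = unrestricted.
#' @param parents_unaffected Require both parents unaffected.
#' @param mating,assort_coin As in [scenario_spec()].
#' @param prevalence Population prevalence setting the threshold.
#' @param keep_genotypes,max_attempts,force_forward,seed As in
#'   [ascertain()].
#' @return An `ascertained_families` object (its `spec` records the rules
#'   under scenario name `"custom"`).
#' @export
sample_families <- function(effects, n_families, n_children = 1,
                            child_req = 1L, parents_unaffected = FALSE,
                            mating = c("random", "assortative"),
                            assort_coin = c("per_snp", "per_family"),
                            prevalence = 0.01, keep_genotypes = FALSE,
                            max_attempts = 1e9, force_forward = FALSE,
                            seed = NULL) {
  stopifnot(inherits(effects, "effect_panel"))
  mating <- match.arg(mating)
  assort_coin <- match.arg(assort_coin)
  .seed_if_given(seed)
  tau <- liability_threshold(prevalence)
  res <- .ascertain_engine(effects$p, effects$a, effects$mu_G, effects$h2,
                           tau, as.integer(n_families),
                           as.integer(n_children), as.integer(child_req),
                           parents_unaffected,
                           .mating_code(mating, assort_coin),
                           max_attempts, keep_genotypes, force_forward)
  roles <- c("father", "mother", "child1", "child2", "pseudo_control")
  colnames(res$G) <- colnames(res$Y) <- roles
  spec <- list(scenario = "custom", n_families = as.integer(n_families),
               h2 = effects$h2, prevalence = prevalence, tau = tau,
               mating = mating, assort_coin = assort_coin,
               child_req = child_req, n_children = n_children,
               parents_unaffected = parents_unaffected)
  out <- list(G = as.data.frame(res$G), Y = as.data.frame(res$Y),
              attempts = res$attempts, spec = spec, effects = effects)
  if (keep_genotypes)
    out$genotypes <- list(father = res$geno_father, mother = res$geno_mother,
                          child1 = res$geno_child1, child2 = res$geno_child2,
                          pseudo_control = res$geno_pseudo)
  structure(out, class = "ascertained_families")
}

#' Rejection-sample ascertained families
#'
#' Generates candidate nuclear families under the liability-threshold model
#' and keeps only those satisfying the scenario's affection pattern, until
#' `spec$n_families` families are accepted. Family generation, Mendelian
#' transmission, pseudo-control construction and phenotype assignment run in
#' compiled code; under random mating the sampler evaluates the proband
#' before drawing the rest of the family (an exact factorization, since the
#' transmitted and untransmitted parental alleles are then independent).
#'
#' @param spec A `scenario_spec`.
#' @param effects An `effect_panel`; its `h2` must equal `spec$h2`.
#' @param keep_genotypes If `TRUE`, returns the allele-count matrices of all
#'   members of every accepted family (memory: 5 matrices of
#'   `n_families x n` integers).
#' @param max_attempts Hard cap on candidate families (default 1e9), so an
#'   unattainable affection pattern fails with an error instead of spinning.
#' @param force_forward Internal/testing switch: disable the proband-first
#'   shortcut and simulate every candidate family forward.
#' @param seed Optional integer seed (overrides `spec$seed`).
#' @return An `ascertained_families` object: data frames `G` and `Y`
#'   (accepted family by role: father, mother, child1, child2,
#'   pseudo_control; child2 is `NA` in trios), the attempt count, the spec,
#'   and optionally `genotypes` (list of matrices by role).
#' @export
ascertain <- function(spec, effects, keep_genotypes = FALSE,
                      max_attempts = 1e9, force_forward = FALSE,
                      seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(effects, "effect_panel"))
  if (abs(spec$h2 - effects$h2) > 1e-12)
    stop("effects were drawn for h2 = ", effects$h2,
         " but the scenario requests h2 = ", spec$h2)
  .seed_if_given(if (is.null(seed)) spec$seed else seed)
  if (spec$scenario == "mixture_60_40") {
    n_mult <- round(0.4 * spec$n_families)
    n_simp <- spec$n_families - n_mult
    s1 <- spec; s1$scenario <- "simplex_unscreened"; s1$n_families <- n_simp
    s2 <- spec; s2$scenario <- "multiplex_unscreened"; s2$n_families <- n_mult
    r1 <- .run_engine(s1, effects, n_simp, keep_genotypes, max_attempts,
                      force_forward)
    r2 <- .run_engine(s2, effects, n_mult, keep_genotypes, max_attempts,
                      force_forward)
    res <- list(G = rbind(r1$G, r2$G), Y = rbind(r1$Y, r2$Y),
                attempts = r1$attempts + r2$attempts)
    if (keep_genotypes) {
      for (nm in grep("^geno_", names(r1), value = TRUE))
        res[[nm]] <- rbind(r1[[nm]], r2[[nm]])
    }
  } else {
    res <- .run_engine(spec, effects, spec$n_families, keep_genotypes,
                       max_attempts, force_forward)
  }
  out <- list(G = as.data.frame(res$G), Y = as.data.frame(res$Y),
              attempts = res$attempts, spec = spec, effects = effects)
  if (keep_genotypes) {
    out$genotypes <- list(father = res$geno_father, mother = res$geno_mother,
                          child1 = res$geno_child1, child2 = res$geno_child2,
                          pseudo_control = res$geno_pseudo)
  }
  structure(out, class = "ascertained_families")
}

#' Heritability attributable to a family member: R/S
#'
#' Quantitative-genetics estimator from the selection differential: `S` is
#' the mean liability of the ascertained probands (child 1), `R` the mean
#' liability of the family-member class of interest, and `R/S` estimates the
#' heritability attributable to that class. For `role = "proband"` the
#' recovery check `mean(G)/mean(y)` over probands is returned instead, which
#' estimates the proband heritability itself.
#'
#' @param families An `ascertained_families` object from [ascertain()].
#' @param role One of `"proband"`, `"father"`, `"mother"`, `"sibling"`
#'   (child 2), `"pseudo_control"`.
#' @param proband_method For `role = "proband"`: `"mean_ratio"` (default)
#'   returns `mean(G)/mean(y)` over probands, which equals h2 exactly under
#'   truncation on the proband's own liability; `"variance"` solves
#'   `var(G | selected) = h2^2 (var(y | selected) - 1) + h2` for h2, the
#'   recovery check based on the reduction of genetic variance in the
#'   selected group.
#' @return List with `S`, `R`, and `h2_hat = R/S` (for `"proband"`, `R` is
#'   the mean genetic value and `h2_hat = mean(G)/mean(y)`, or the
#'   variance-based solution).
#' @export
estimate_relative_h2 <- function(families,
                                 role = c("proband", "father", "mother",
                                          "sibling", "pseudo_control"),
                                 proband_method = c("mean_ratio",
                                                    "variance")) {
  stopifnot(inherits(families, "ascertained_families"))
  role <- match.arg(role)
  proband_method <- match.arg(proband_method)
  S <- mean(families$Y$child1)
  if (abs(S) < 1e-8)
    stop("mean proband liability is ~0; no selection, R/S undefined")
  if (role == "proband" && proband_method == "variance") {
    v_y <- var(families$Y$child1)
    v_G <- var(families$G$child1)
    a <- v_y - 1
    h2 <- if (abs(a) < 1e-10) v_G else
      (-1 + sqrt(max(0, 1 + 4 * a * v_G))) / (2 * a)
    return(list(S = S, R = v_G, h2_hat = h2))
  }
  col <- switch(role, proband = "child1", sibling = "child2", father = "father",
                mother = "mother", pseudo_control = "pseudo_control")
  R <- if (role == "proband") mean(families$G$child1) else mean(families$Y[[col]])
  if (anyNA(R))
    stop("role '", role, "' is not present in these families")
  list(S = S, R = R, h2_hat = R / S)
}

#' Expected-heritability simulation experiment
#'
#' Runs the rejection-sampling simulator over a grid of scenarios,
#' heritabilities and mating modes, repeating each cell `n_replicates`
#' times with a fresh effect panel per replicate, and estimates `R/S` for
#' each requested role.
#'
#' @param scenarios Character vector of scenario names (see
#'   [scenario_spec()]).
#' @param h2 Numeric vector of proband heritabilities.
#' @param mating Character vector of mating modes.
#' @param roles Roles to estimate (default all five).
#' @param n_snps Liability SNPs per effect panel (default 1000).
#' @param n_families Accepted families per replicate (default 1000).
#' @param n_replicates Replicates per grid cell (default 100).
#' @param assort_coin Fair-coin variant for assortative mating.
#' @param prevalence Population prevalence (default 0.01).
#' @param seed Optional integer seed for the whole experiment.
#' @return An `expected_h2_result`: long data frame with columns `scenario`,
#'   `h2`, `mating`, `role`, `replicate`, `S`, `R`, `h2_hat`. Summarise
#'   across replicates with [summary()].
#' @export
expected_h2_experiment <- function(scenarios, h2, mating = "random",
                                   roles = c("proband", "father", "mother",
                                             "sibling", "pseudo_control"),
                                   n_snps = 1000, n_families = 1000,
                                   n_replicates = 100,
                                   assort_coin = "per_snp",
                                   prevalence = 0.01, seed = NULL) {
  .seed_if_given(seed)
  grid <- expand.grid(scenario = scenarios, h2 = h2, mating = mating,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid) * n_replicates)
  k <- 0
  for (g in seq_len(nrow(grid))) {
    spec <- scenario_spec(grid$scenario[g], n_families = n_families,
                          h2 = grid$h2[g], prevalence = prevalence,
                          mating = grid$mating[g], assort_coin = assort_coin,
                          n_replicates = n_replicates)
    use_roles <- roles
    if (spec$scenario == "simplex_unscreened")
      use_roles <- setdiff(use_roles, "sibling")
    for (r in seq_len(n_replicates)) {
      eff <- draw_effect_panel(n_snps, grid$h2[g])
      fams <- ascertain(spec, eff)
      est <- lapply(use_roles, function(ro) estimate_relative_h2(fams, ro))
      k <- k + 1
      rows[[k]] <- data.frame(
        scenario = grid$scenario[g], h2 = grid$h2[g], mating = grid$mating[g],
        role = use_roles, replicate = r,
        S = vapply(est, `[[`, numeric(1), "S"),
        R = vapply(est, `[[`, numeric(1), "R"),
        h2_hat = vapply(est, `[[`, numeric(1), "h2_hat"),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("expected_h2_result", "data.frame")
  out
}

#' @describeIn expected_h2_experiment Mean and SD of `R/S` across replicates
#'   per scenario x h2 x mating x role cell, plus the cross-replicate
#'   standard error of the mean.
#' @param object An `expected_h2_result`.
#' @param ... Unused.
#' @export
summary.expected_h2_result <- function(object, ...) {
  f <- interaction(object$scenario, object$h2, object$mating, object$role,
                   drop = TRUE)
  agg <- do.call(rbind, lapply(split(object, f), function(d) {
    data.frame(scenario = d$scenario[1], h2 = d$h2[1], mating = d$mating[1],
               role = d$role[1], n_replicates = nrow(d),
               mean_h2_hat = mean(d$h2_hat), sd_h2_hat = sd(d$h2_hat),
               se_mean = sd(d$h2_hat) / sqrt(nrow(d)),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg
}
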