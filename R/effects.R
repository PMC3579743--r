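#' Liability threshold for a given population prevalence
#'
#' The liability-threshold model takes liability to be standard normal in the
#' population; an individual is affected when liability reaches the upper-K
#' quantile. For K = 0.01 the threshold is 2.326 (3 d.p.).
#'
#' @param prevalence Population prevalence K in (0, 1).
#' @return The threshold `qnorm(1 - K)` in liability (SD) units.
#' @export
#' @examples
#' liability_threshold(0.01)
liability_threshold <- function(prevalence) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  qnorm(1 - prevalence)
}

#' Draw per-SNP additive liability effects
#'
#' Builds an effect panel defining the additive genetic liability
#' `G = sum_i x_i a_i - mu_G`, where `x_i` is the allele count. The relative
#' importance of SNP i is `w_i = t_i / T` with `t_i ~ Uniform(0, 1)` and
#' `T = sum(t)`; the allele-substitution effect is
#' `a_i = sqrt(w_i h2 / (2 p_i (1 - p_i)))`, so the per-SNP additive
#' variances `2 p_i (1 - p_i) a_i^2` sum exactly to `h2`. The centering
#' constant `mu_G = sum(2 p_i a_i)` makes `E[G] = 0` in a random-mating
#' population, so total liability `y = G + e` with `e ~ N(0, 1 - h2)` has
#' unit variance and the [liability_threshold()] yields the intended
#' prevalence.
#'
#' @param n Number of SNPs; may be omitted when `p` is supplied.
#' @param h2 Total additive variance of liability (narrow-sense
#'   heritability), in `[0, 1]`.
#' @param p Allele-frequency vector in (0, 1), or a `snp_panel` whose `p`
#'   column is used. If missing, frequencies are drawn Uniform(0.01, 0.99).
#' @param seed Optional integer seed.
#' @return An `effect_panel`: list with `n`, `p`, `t`, `T`, `w`, `a`, `h2`,
#'   `mu_G`.
#' @export
#' @examples
#' eff <- draw_effect_panel(1000, h2 = 0.5, seed = 1)
#' sum(2 * eff$p * (1 - eff$p) * eff$a^2) # equals h2
draw_effect_panel <- function(n, h2, p = NULL, seed = NULL) {
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  .seed_if_given(seed)
  if (inherits(p, "snp_panel")) p <- p$p
  if (is.null(p)) {
    if (missing(n)) stop("supply n or p")
    p <- runif(n, 0.01, 0.99)
  }
  n <- length(p)
  if (any(p <= 0 | p >= 1)) stop("allele frequencies must be strictly inside (0, 1)")
  t <- runif(n)
  T_ <- sum(t)
  w <- t / T_
  a <- sqrt(w * h2 / (2 * p * (1 - p)))
  structure(list(n = n, p = p, t = t, T = T_, w = w, a = a, h2 = h2,
                 mu_G = sum(2 * p * a)),
            class = "effect_panel")
}

#' Genetic liability of genotypes
#'
#' Computes `G = sum_i x_i a_i - mu_G` for one genotype vector or a matrix of
#' genotypes (individuals in rows, SNPs in columns, allele counts in 0/1/2).
#'
#' @param genotype Numeric vector of length `effects$n`, or a matrix with
#'   `effects$n` columns.
#' @param effects An `effect_panel`.
#' @return Numeric vector of genetic liabilities (one per individual).
#' @export
genetic_value <- function(genotype, effects) {
  stopifnot(inherits(effects, "effect_panel"))
  if (is.matrix(genotype)) {
    if (ncol(genotype) != effects$n)
      stop("genotype matrix has ", ncol(genotype), " columns; expected ", effects$n)
    drop(genotype %*% effects$a) - effects$mu_G
  } else {
    if (length(genotype) != effects$n)
      stop("genotype has length ", length(genotype), "; expected ", effects$n)
    sum(genotype * effects$a) - effects$mu_G
  }
}

#' Assign liability phenotypes
#'
#' Adds an environmental deviate `e ~ N(0, 1 - h2)` to each genetic value,
#' giving total liability `y = G + e`; an individual is affected when
#' `y >= tau`.
#'
#' @param G Numeric vector of genetic liabilities.
#' @param h2 Heritability of liability in `[0, 1]` (with `h2 = 1`, `e = 0`).
#' @param tau Liability threshold; defaults to the 1 percent-prevalence
#'   threshold.
#' @param seed Optional integer seed.
#' @return Data frame with columns `G`, `e`, `y`, `affected`.
#' @export
assign_phenotype <- function(G, h2, tau = liability_threshold(0.01),
                             seed = NULL) {
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  .seed_if_given(seed)
  e <- rnorm(length(G), 0, sqrt(1 - h2))
  y <- G + e
  data.frame(G = G, e = e, y = y, affected = y >= tau)
}
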