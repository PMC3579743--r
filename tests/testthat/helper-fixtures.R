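# Shared fixture builders. Everything is generated in code; no stored data.

# Effect panel with fully specified weights/frequencies, for closed-form
# oracle tests (bypasses the random draw of t).
manual_effects <- function(p, t, h2) {
  w <- t / sum(t)
  a <- sqrt(w * h2 / (2 * p * (1 - p)))
  structure(list(n = length(p), p = p, t = t, T = sum(t), w = w, a = a,
                 h2 = h2, mu_G = sum(2 * p * a)),
            class = "effect_panel")
}

# Minimal panel with chosen alleles/positions (one chromosome by default).
manual_panel <- function(n, chrom = "1", pos = NULL, allele_a = NULL,
                         allele_b = NULL, p = NULL) {
  panel <- data.frame(
    snp_id = sprintf("rs%04d", seq_len(n)),
    chrom = rep(chrom, length.out = n),
    pos = if (is.null(pos)) seq_len(n) * 1000L else as.integer(pos),
    allele_a = if (is.null(allele_a)) rep("A", n) else allele_a,
    allele_b = if (is.null(allele_b)) rep("G", n) else allele_b,
    p = if (is.null(p)) rep(0.5, n) else p,
    stringsAsFactors = FALSE
  )
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

# Cohort with an explicit genotype matrix.
manual_cohort <- function(X, phenotype = NULL, sex = NULL) {
  new_cohort(as.matrix(X), phenotype = phenotype, sex = sex)
}

# Independent HWE exact-test oracle: enumerate every heterozygote count
# compatible with the allele count and sum the probabilities of outcomes no
# more probable than the observed one. Uses choose() directly, a different
# code path from the package's lgamma-based implementation.
hwe_exact_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- n_Aa + 2 * n_aa
  rare <- min(n_a, 2 * n - n_a)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # multinomial count of genotype configurations with h heterozygotes,
  # conditional on the allele count: n! / (AA! Aa! aa!) * 2^h
  prob <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    choose(n, h) * choose(n - h, hom_rare) * 2^h
  }, numeric(1))
  prob <- prob / sum(prob)
  p_obs <- prob[hets == n_Aa]
  sum(prob[prob <= p_obs + 1e-12])
}

# Restricted log-likelihood evaluated directly (independent of reml_fit's
# internals): -0.5 [ log|V| + log|X'V^-1 X| + y' P y ].
restricted_loglik <- function(y, X, A, s2g, s2e) {
  n <- length(y)
  V <- s2g * A + diag(s2e, n)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% crossprod(X, Vi)
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            drop(crossprod(y, P %*% y)))
}

# A clean cohort plus planted violations, reused across the QC tests below.
make_qc_cohort <- function() {
  set.seed(42)
  n <- 400
  m <- 70                                # 50 autosomal + 20 X SNPs
  pan <- manual_panel(m, p = rep(0.3, m),
                      pos = c(1:50 * 1e6, 1:20 * 1e6))
  pan$chrom <- rep(c("1", "X"), c(50, 20))
  X <- sapply(seq_len(m), function(j) rbinom(n, 2, 0.3))
  sex <- rep(c(1L, 2L), n / 2)
  # X SNPs: males hemizygous, coded 0/2
  for (j in 51:70) X[sex == 1L, j] <- 2L * rbinom(n / 2, 1, 0.3)
  # SNP 2: low call rate (96%)
  X[sample(3:n, 16), 2] <- NA
  # SNP 3: rare (MAF ~ 0.005)
  X[, 3] <- rbinom(n, 2, 0.005)
  while (mean(X[, 3]) / 2 > 0.01 || mean(X[, 3]) == 0)
    X[, 3] <- rbinom(n, 2, 0.005)
  # SNP 4: gross HWE violation (no heterozygotes)
  X[, 4] <- 2L * rbinom(n, 1, 0.5)
  # SNP 5: strand-ambiguous alleles
  pan$allele_a[5] <- "C"; pan$allele_b[5] <- "G"
  # individual 1: low call rate; individual 2: sex mismatch (nominal male,
  # female-like X heterozygosity)
  X[1, sample(m, 3)] <- NA
  sex[2] <- 1L
  X[2, 51:70] <- 1L
  coh <- manual_cohort(X, phenotype = rbinom(n, 1, 0.5), sex = sex)
  list(cohort = coh, panel = pan)
}

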