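# Family-block GRM (k families of size s with within-family relatedness r):
# a cheap structured covariance for variance-component recovery tests.
block_grm <- function(k, s, r = 0.5) {
  A <- kronecker(diag(k), matrix(r, s, s) + diag(1 - r, s))
  structure(list(A = A, m = 1000L,
                 fid = rep(sprintf("F%03d", seq_len(k)), each = s),
                 iid = sprintf("I%04d", seq_len(k * s))),
            class = "grm")
}

sim_y_from_grm <- function(A, s2g, s2e, X = NULL, beta = NULL) {
  n <- nrow(A)
  eg <- eigen(A, symmetric = TRUE)
  g <- drop(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * rnorm(n))) * sqrt(s2g)
  y <- g + rnorm(n, 0, sqrt(s2e))
  if (!is.null(X)) y <- y + drop(as.matrix(X) %*% beta)
  y
}

test_that("REML recovers known variance components on a block GRM", {
  set.seed(1)
  g <- block_grm(200, 5)          # n = 1000
  X <- cbind(1, rnorm(1000))
  y <- sim_y_from_grm(g$A, 0.6, 0.4, X, beta = c(2, 0.5))
  fit <- reml_fit(y, X, g)
  expect_true(fit$converged)
  expect_lt(abs(fit$varcomp[1] - 0.6), 2 * fit$se[1])
  expect_lt(abs(fit$varcomp[2] - 0.4), 2 * fit$se[2])
  expect_equal(unname(fit$beta), c(2, 0.5), tolerance = 0.1)
  # permuting y against the GRM destroys the genetic signal
  fitp <- reml_fit(sample(y), X, g)
  expect_lt(fitp$h2_obs, 0.1)
})

test_that("REML matches a restricted-likelihood grid search at n = 200", {
  set.seed(2)
  g <- block_grm(40, 5)
  X <- matrix(1, 200, 1)
  y <- sim_y_from_grm(g$A, 0.5, 0.5, X, beta = 1)
  fit <- reml_fit(y, X, g, tol = 1e-10)
  # nested grid refinement of the restricted likelihood (independent code)
  lo <- c(0.01, 0.01); hi <- c(1.5, 1.5)
  for (level in 1:6) {
    s2g <- seq(lo[1], hi[1], length.out = 16)
    s2e <- seq(lo[2], hi[2], length.out = 16)
    ll <- outer(s2g, s2e,
                Vectorize(function(a, b) restricted_loglik(y, X, g$A, a, b)))
    best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    step <- c(s2g[2] - s2g[1], s2e[2] - s2e[1])
    lo <- pmax(c(s2g[best[1]], s2e[best[2]]) - step, 1e-4)
    hi <- c(s2g[best[1]], s2e[best[2]]) + step
  }
  grid_opt <- c(s2g[best[1]], s2e[best[2]])
  expect_equal(unname(fit$varcomp), grid_opt, tolerance = 1e-3)
  expect_gte(fit$logL,
             restricted_loglik(y, X, g$A, grid_opt[1], grid_opt[2]) - 1e-6)
})

test_that("restricted log-likelihood never decreases across iterations", {
  # run reml_fit while tracing the likelihood via repeated short fits
  set.seed(3)
  g <- block_grm(60, 4)
  y <- sim_y_from_grm(g$A, 0.3, 0.7)
  lls <- vapply(1:12, function(it)
    suppressWarnings(reml_fit(y, NULL, g, max_iter = it)$logL), numeric(1))
  expect_true(all(diff(lls) >= -1e-8))
})

test_that("an identity-like GRM is flagged unidentifiable", {
  set.seed(4)
  y <- rnorm(80)
  expect_warning(fit <- reml_fit(y, NULL, diag(80), max_iter = 10),
                 "identifiable|converge")
  expect_false(fit$identifiable)
})

test_that("degenerate designs are refused", {
  g <- block_grm(10, 4)
  y <- rnorm(40)
  expect_error(reml_fit(y, matrix(1, 40, 2), g), "rank")
  expect_error(reml_fit(y, NULL, diag(39)), "n x n")
  expect_error(reml_fit(y, matrix(1, 39, 1), g), "one row")
})

test_that("liability transform matches its closed form and is linear", {
  est <- observed_to_liability(0.2, 0.05, K = 0.01, P = 0.5)
  # independent numeric evaluation of the multiplier
  z <- exp(-qnorm(0.99)^2 / 2) / sqrt(2 * pi)
  mult <- 0.01^2 * 0.99^2 / (z^2 * 0.25)
  expect_equal(est$z, 0.026652, tolerance = 1e-4)
  expect_equal(est$multiplier, mult, tolerance = 1e-6)
  expect_equal(est$h2_liab, 0.2 * mult, tolerance = 1e-6)
  expect_equal(round(est$h2_liab, 4), 0.1104)
  expect_equal(est$se_liab / est$h2_liab, 0.05 / 0.2, tolerance = 1e-12)
  # K = P = 0.5: the multiplier reduces to K(1-K)/z^2 = pi/2
  expect_equal(observed_to_liability(0.3, K = 0.5, P = 0.5)$multiplier,
               pi / 2, tolerance = 1e-12)
  # linearity in h2_obs, and exact zero at zero
  expect_equal(observed_to_liability(0.4, K = 0.01, P = 0.5)$h2_liab,
               2 * observed_to_liability(0.2, K = 0.01, P = 0.5)$h2_liab)
  expect_equal(observed_to_liability(0, K = 0.01, P = 0.5)$h2_liab, 0)
  expect_error(observed_to_liability(0.2, K = 0, P = 0.5), "inside")
})

test_that("case-control pipeline separates signal from null", {
  set.seed(5)
  pan <- simulate_panel(1500, maf_range = c(0.05, 0.95),
                        chromosomes = as.character(1:8), seed = 6)
  eff <- draw_effect_panel(p = pan, h2 = 0.5, seed = 7)
  cc <- simulate_case_control(pan, eff, 0.01, 300, 300, seed = 8)
  cas <- new_cohort(cc$genotypes[cc$phenotype == 1, , drop = FALSE])
  ctl <- new_cohort(cc$genotypes[cc$phenotype == 0, , drop = FALSE])
  sig <- estimate_h2_cc(cas, ctl, pan, qc = FALSE)
  expect_gt(sig$estimate$h2_liab, 0.2)
  expect_equal(sig$P, 0.5)
  expect_equal(sig$n_snps_used, 1500)
  # cases and controls from the same unscreened population: ~ 0
  null_cc <- simulate_case_control(pan, draw_effect_panel(p = pan, h2 = 0,
                                                          seed = 9),
                                   0.01, 0, 600, seed = 10)
  h1 <- new_cohort(null_cc$genotypes[1:300, , drop = FALSE])
  h2_ <- new_cohort(null_cc$genotypes[301:600, , drop = FALSE])
  nul <- estimate_h2_cc(h1, h2_, pan, qc = FALSE)
  expect_lt(nul$estimate$h2_liab, 0.15)
})

test_that("per-chromosome partition localises planted signal", {
  set.seed(11)
  pan <- simulate_panel(1200, maf_range = c(0.1, 0.9),
                        chromosomes = as.character(1:6), seed = 12)
  eff <- draw_effect_panel(p = pan, h2 = 0.5, seed = 13)
  # confine all causal variance to chromosome 1, rescaled to h2 = 0.5
  on1 <- pan$chrom == "1"
  eff$a[!on1] <- 0
  v <- sum(2 * eff$p[on1] * (1 - eff$p[on1]) * eff$a[on1]^2)
  eff$a[on1] <- eff$a[on1] * sqrt(0.5 / v)
  eff$mu_G <- sum(2 * eff$p * eff$a)
  cc <- simulate_case_control(pan, eff, 0.01, 250, 250, seed = 14)
  coh <- new_cohort(cc$genotypes, phenotype = cc$phenotype)
  part <- per_chromosome_h2(coh, pan, k_pcs = 5)
  expect_equal(nrow(part), 6)
  chr1 <- part$h2_obs[part$chrom == "1"]
  others <- part$h2_obs[part$chrom != "1"]
  expect_gt(chr1, 3 * max(others))
  expect_lt(max(others), 0.2)
  expect_error(per_chromosome_h2(coh, pan[pan$chrom %in% as.character(1:3), ],
                                 k_pcs = 2), "at least 5")
})
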