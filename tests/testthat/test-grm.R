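test_that("GRM entries match the closed-form single-SNP values", {
  # sample frequency 0.5 from genotypes (2, 0): A_12 = (1)(-1)/0.5 = -2
  coh <- manual_cohort(matrix(c(2L, 0L), 2, 1))
  g <- compute_grm(coh)
  expect_equal(g$A[1, 2], -2)
  # identical homozygotes at p_hat = 0.5: off-diagonal and diagonal both 2
  coh2 <- manual_cohort(matrix(c(2L, 2L, 0L, 0L), 4, 1))
  g2 <- compute_grm(coh2)
  expect_equal(g2$A[1, 2], 2)
  expect_equal(g2$A[1, 1], 2)
  expect_error(compute_grm(manual_cohort(matrix(c(0L, 0L), 2, 1))),
               "monomorphic")
})

test_that("GRM is calibrated on a large unrelated HWE cohort", {
  pan <- simulate_panel(800, maf_range = c(0.05, 0.95),
                        chromosomes = as.character(1:4), seed = 1)
  eff <- draw_effect_panel(p = pan, h2 = 0, seed = 2)
  cc <- simulate_case_control(pan, eff, 0.01, 0, 300, seed = 3)
  g <- compute_grm(new_cohort(cc$genotypes), pan)
  off <- g$A[upper.tri(g$A)]
  # sample-frequency centering leaves an O(1/n) negative mean
  expect_lt(abs(mean(off)), 2 / nrow(g$A))
  expect_equal(mean(diag(g$A)), 1, tolerance = 0.01)
  expect_equal(sd(off), sqrt(1 / g$m), tolerance = 0.15)
  # duplicated individual: off-diagonal approximates the diagonal
  Xd <- rbind(cc$genotypes, cc$genotypes[1, , drop = FALSE])
  gd <- compute_grm(new_cohort(Xd), pan)
  expect_equal(gd$A[1, 301], gd$A[1, 1], tolerance = 0.12)
  expect_gt(gd$A[1, 301], 0.8)
})

test_that("combined per-chromosome GRMs equal the pooled GRM exactly", {
  pan <- simulate_panel(50, maf_range = c(0.1, 0.9),
                        chromosomes = as.character(1:5), seed = 4)
  eff <- draw_effect_panel(p = pan, h2 = 0, seed = 5)
  cc <- simulate_case_control(pan, eff, 0.01, 0, 80, missing_rate = 0.02,
                              seed = 6)
  coh <- new_cohort(cc$genotypes)
  pooled <- compute_grm(coh, pan)
  per_chr <- lapply(unique(pan$chrom), function(ch)
    compute_grm(coh, pan, chromosomes = ch))
  combined <- combine_grms(per_chr)
  expect_equal(combined$A, pooled$A, tolerance = 1e-12)
  expect_equal(combined$m, pooled$m)
  # associativity: combining in two stages gives the same result
  two_stage <- combine_grms(list(combine_grms(per_chr[1:2]),
                                 combine_grms(per_chr[3:5])))
  expect_equal(two_stage$A, pooled$A, tolerance = 1e-12)
  # single GRM is an identity operation
  expect_equal(combine_grms(list(pooled))$A, pooled$A)
  # mismatched ids are refused
  g2 <- per_chr[[1]]; g2$iid <- rev(g2$iid)
  expect_error(combine_grms(list(per_chr[[2]], g2)), "different individuals")
})

test_that("GRM principal components recover planted population structure", {
  set.seed(7)
  m <- 2000; n_half <- 250
  p <- runif(m, 0.1, 0.9)
  fst <- 0.01
  d <- sqrt(fst * p * (1 - p))
  p1 <- pmin(pmax(p + d, 0.01), 0.99)
  p2 <- pmin(pmax(p - d, 0.01), 0.99)
  X <- rbind(sapply(seq_len(m), function(j) rbinom(n_half, 2, p1[j])),
             sapply(seq_len(m), function(j) rbinom(n_half, 2, p2[j])))
  g <- compute_grm(new_cohort(X))
  pcs <- grm_pca(g, k = 10)
  expect_equal(dim(pcs$vectors), c(2 * n_half, 10))
  # orthonormality and eigenvalue ordering
  expect_equal(crossprod(pcs$vectors), diag(10), tolerance = 1e-8)
  expect_true(all(diff(pcs$values) <= 1e-12))
  # PC1 separates the two populations by sign for > 99% of individuals
  lab <- rep(c(1, -1), each = n_half)
  sgn <- sign(pcs$vectors[, 1])
  agreement <- max(mean(sgn == lab), mean(sgn == -lab))
  expect_gt(agreement, 0.99)
  expect_error(grm_pca(g, k = 600), "smaller")
})

test_that("relatedness pruning removes one member of close cross-family pairs", {
  pan <- simulate_panel(600, maf_range = c(0.1, 0.9),
                        chromosomes = "1", seed = 8)
  eff <- draw_effect_panel(p = pan, h2 = 0, seed = 9)
  cc <- simulate_case_control(pan, eff, 0.01, 0, 60, seed = 10)
  X <- cc$genotypes
  # plant a duplicate (~ A = 1) and a parent-offspring pair (~ A = 0.5)
  X[2, ] <- X[1, ]
  child <- vapply(seq_len(ncol(X)), function(j) {
    pat <- if (runif(1) < 0.5) X[3, j] >= 1 else X[3, j] == 2  # transmitted
    as.integer(pat) + rbinom(1, 1, pan$p[j])
  }, integer(1))
  X[4, ] <- child
  g <- compute_grm(new_cohort(X), pan)
  expect_gt(g$A[1, 2], 0.9)
  expect_gt(g$A[3, 4], 0.35)
  kept <- relatedness_prune(g, cutoff = 0.2)
  expect_equal(length(setdiff(1:2, kept)), 1)   # one duplicate dropped
  expect_equal(length(setdiff(3:4, kept)), 1)   # one of the pair dropped
  expect_true(all(setdiff(seq_len(60), 1:4) %in% kept))
  # same-family pairs are exempt
  fam <- g$fid; fam[1:2] <- "shared"
  kept2 <- relatedness_prune(g, cutoff = 0.2, families = fam)
  expect_true(all(1:2 %in% kept2))
  # nothing removed when all pairs are below the cutoff
  expect_equal(relatedness_prune(g, cutoff = 1.5), seq_len(60))
})

test_that("GCTA binary GRM files round-trip at float precision", {
  pan <- simulate_panel(100, maf_range = c(0.1, 0.9), chromosomes = "1",
                        seed = 11)
  eff <- draw_effect_panel(p = pan, h2 = 0, seed = 12)
  cc <- simulate_case_control(pan, eff, 0.01, 0, 25, seed = 13)
  g <- compute_grm(new_cohort(cc$genotypes), pan)
  prefix <- file.path(tempdir(), "test")
  write_grm(g, prefix)
  back <- read_grm(prefix)
  expect_equal(back$A, g$A, tolerance = 1e-6)
  expect_equal(back$m, g$m)
  expect_equal(back$iid, g$iid)
  # triplet layout: n(n+1)/2 float32 values
  expect_equal(file.size(paste0(prefix, ".grm.bin")), 4 * 25 * 26 / 2)
})
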