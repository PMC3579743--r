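# Shared small runs (drawn once; reused across blocks below)
eff5 <- draw_effect_panel(300, h2 = 0.5, seed = 101)

test_that("accepted families satisfy the scenario's affection pattern", {
  tau <- liability_threshold(0.01)
  s1 <- scenario_spec("ssc_screened", n_families = 60, h2 = 0.5)
  f1 <- ascertain(s1, eff5, seed = 1)
  expect_true(all(f1$Y$child1 >= tau))
  expect_true(all(f1$Y$child2 < tau))
  expect_true(all(f1$Y$father < tau & f1$Y$mother < tau))

  s2 <- scenario_spec("simplex_unscreened", n_families = 60, h2 = 0.5)
  f2 <- ascertain(s2, eff5, seed = 2)
  expect_true(all(f2$Y$child1 >= tau))
  expect_true(all(is.na(f2$Y$child2)))     # trio

  s3 <- scenario_spec("multiplex_unscreened", n_families = 40, h2 = 0.5)
  f3 <- ascertain(s3, eff5, seed = 3)
  expect_true(all(f3$Y$child1 >= tau & f3$Y$child2 >= tau))

  s4 <- scenario_spec("mixture_60_40", n_families = 50, h2 = 0.5)
  f4 <- ascertain(s4, eff5, seed = 4)
  expect_equal(sum(is.na(f4$Y$child2)), 30)          # 60% simplex trios
  expect_true(all(f4$Y$child2[!is.na(f4$Y$child2)] >= tau))

  # h2 mismatch between spec and effects is refused
  expect_error(ascertain(scenario_spec("simplex_unscreened", h2 = 0.75),
                         eff5), "h2")
})

test_that("unscreened simplex acceptance rate approximates the prevalence", {
  s2 <- scenario_spec("simplex_unscreened", n_families = 500, h2 = 0.5)
  f2 <- ascertain(s2, eff5, seed = 5)
  rate <- 500 / f2$attempts
  expect_gt(rate, 0.007)
  expect_lt(rate, 0.013)
})

test_that("bounded attempts fail loudly for unattainable patterns", {
  expect_error(ascertain(scenario_spec("simplex_unscreened", n_families = 50,
                                       h2 = 0.5, prevalence = 1e-6),
                         draw_effect_panel(50, 0.5, seed = 6),
                         max_attempts = 2000, seed = 7),
               "max_attempts")
})

test_that("forward and proband-first samplers agree in distribution", {
  s2 <- scenario_spec("simplex_unscreened", n_families = 1500, h2 = 0.5)
  a <- ascertain(s2, eff5, seed = 8)
  b <- ascertain(s2, eff5, seed = 9, force_forward = TRUE)
  # selection differential and the parent response agree within MC error
  for (col in c("child1", "father", "pseudo_control")) {
    se <- sqrt(var(a$Y[[col]]) / 1500 + var(b$Y[[col]]) / 1500)
    expect_lt(abs(mean(a$Y[[col]]) - mean(b$Y[[col]])), 4 * se)
  }
})

test_that("genotype export preserves family algebra at scale", {
  s3 <- scenario_spec("multiplex_unscreened", n_families = 30, h2 = 0.5)
  f <- ascertain(s3, eff5, seed = 10, keep_genotypes = TRUE)
  gt <- f$genotypes
  # conservation identity holds for every family and SNP
  expect_equal(gt$child1 + gt$pseudo_control, gt$father + gt$mother)
  expect_true(all(gt$child2 >= 0 & gt$child2 <= 2))
  # liabilities recompute from the exported genotypes
  expect_equal(genetic_value(gt$child1, eff5), f$G$child1)
  expect_equal(genetic_value(gt$pseudo_control, eff5), f$G$pseudo_control)
})

test_that("R/S estimates match a hand-computed table", {
  # three families with liabilities fixed by hand:
  # probands 2.5, 3.0, 2.6 (S = 2.7); fathers 0.5, 1.0, 0.6 (R = 0.7)
  fams <- structure(list(
    Y = data.frame(father = c(0.5, 1.0, 0.6), mother = c(0, 0, 0),
                   child1 = c(2.5, 3.0, 2.6), child2 = NA_real_,
                   pseudo_control = c(0.2, -0.1, 0.2)),
    G = data.frame(father = NA, mother = NA, child1 = c(1.2, 1.5, 1.35),
                   child2 = NA, pseudo_control = NA)
  ), class = "ascertained_families")
  expect_equal(estimate_relative_h2(fams, "father")$h2_hat, 0.7 / 2.7)
  expect_equal(estimate_relative_h2(fams, "pseudo_control")$h2_hat, 0.1 / 2.7)
  expect_equal(estimate_relative_h2(fams, "proband")$h2_hat, 1.35 / 2.7)
  expect_error(estimate_relative_h2(fams, "sibling"), "not present")
  # no selection -> undefined ratio
  fams$Y$child1 <- c(1e-10, -1e-10, 0)
  expect_error(estimate_relative_h2(fams, "father"), "undefined")
})

test_that("unascertained relatives show no selection response", {
  # random families: proband unrestricted, so R ~ 0 for everyone
  eff <- draw_effect_panel(200, h2 = 0.5, seed = 11)
  f <- sample_families(eff, n_families = 3000, n_children = 1,
                       child_req = 0L, seed = 12)
  expect_lt(abs(mean(f$Y$father)), 3 * sd(f$Y$father) / sqrt(3000))
  expect_lt(abs(mean(f$Y$child1)), 3 * sd(f$Y$child1) / sqrt(3000))
})

test_that("expected_h2_experiment aggregates the grid", {
  res <- expected_h2_experiment("simplex_unscreened", h2 = 0.5,
                                mating = "random",
                                roles = c("proband", "pseudo_control"),
                                n_snps = 200, n_families = 200,
                                n_replicates = 3, seed = 13)
  expect_s3_class(res, "expected_h2_result")
  expect_equal(nrow(res), 6)
  sm <- summary(res)
  expect_equal(sm$n_replicates, c(3, 3))
  expect_equal(sort(unique(res$role)), c("proband", "pseudo_control"))
})
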