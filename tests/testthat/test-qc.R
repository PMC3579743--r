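test_that("strand-ambiguous SNPs are identified by allele pair", {
  pan <- manual_panel(5, allele_a = c("A", "A", "C", "G", "T"),
                      allele_b = c("T", "G", "G", "C", "A"))
  kept <- filter_ambiguous(pan)
  expect_equal(kept, 2L)                # A/T, C/G, G/C, T/A all removed
  bad <- manual_panel(1, allele_a = "N", allele_b = "A")
  expect_error(filter_ambiguous(bad), "allele codes")
})

test_that("HWE exact test matches full enumeration and handles edge cases", {
  # perfect HWE at the chi-square optimum
  expect_equal(hwe_test(25, 50, 25, method = "chisq"), 1)
  expect_gt(hwe_test(25, 50, 25, method = "exact"), 0.9)
  # no heterozygotes at p = 0.5: chi-square statistic equals n
  expect_equal(hwe_test(50, 0, 50, method = "chisq"),
               pchisq(100, 1, lower.tail = FALSE))
  expect_lt(hwe_test(50, 0, 50, method = "exact"), 0.005)
  # monomorphic and degenerate counts
  expect_equal(hwe_test(0, 0, 10), 1)
  expect_equal(hwe_test(7, 0, 0), 1)
  expect_error(hwe_test(0, 0, 0), "missing")
  expect_error(hwe_test(-1, 2, 3), "non-negative")
  # enumeration oracle at n = 100, across a range of configurations
  for (cfg in list(c(50, 0, 50), c(30, 40, 30), c(81, 18, 1),
                   c(70, 25, 5), c(2, 96, 2), c(90, 9, 1))) {
    expect_equal(hwe_test(cfg[1], cfg[2], cfg[3]),
                 hwe_exact_oracle(cfg[1], cfg[2], cfg[3]),
                 tolerance = 1e-10,
                 label = paste("exact p for", paste(cfg, collapse = "/")))
  }
})

test_that("planted violations are exactly what QC removes", {
  fx <- make_qc_cohort()
  rep_ind <- individual_qc(fx$cohort, fx$panel)
  expect_equal(rep_ind$removed$ind_call, 1)
  expect_equal(rep_ind$removed$sex_mismatch, 2)
  expect_equal(length(rep_ind$kept) + 2, rep_ind$n_input)

  rep_snp <- snp_qc(fx$cohort, fx$panel, individuals = rep_ind$kept)
  expect_equal(rep_snp$removed$ambiguous, 5)
  expect_equal(rep_snp$removed$snp_call, 2)
  expect_equal(rep_snp$removed$maf, 3)
  expect_equal(rep_snp$removed$hwe, 4)
  # removals partition the input
  all_removed <- unlist(rep_snp$removed)
  expect_equal(sort(unname(c(rep_snp$kept, all_removed))), seq_len(70))
  expect_equal(anyDuplicated(all_removed), 0)
})

test_that("the QC chain is idempotent", {
  fx <- make_qc_cohort()
  rep1 <- snp_qc(fx$cohort, fx$panel)
  sub <- fx$cohort
  sub$genotypes <- sub$genotypes[, rep1$kept, drop = FALSE]
  pan2 <- fx$panel[rep1$kept, , drop = FALSE]
  class(pan2) <- class(fx$panel)
  rep2 <- snp_qc(sub, pan2)
  expect_equal(rep2$kept, seq_along(rep1$kept))
  expect_true(all(lengths(rep2$removed) == 0))
})

test_that("ancestry SNP selection enforces call, MAF and spacing rules", {
  pan <- manual_panel(4, pos = c(1.0e6, 1.2e6, 1.6e6, 2.0e6))
  X <- sapply(c(0.3, 0.3, 0.3, 0.04), function(p) rbinom(500, 2, p))
  coh <- manual_cohort(X)
  kept <- select_ancestry_snps(pan, coh)
  # 1.2 Mb is within 0.5 Mb of 1.0 Mb; 2.0 Mb fails MAF
  expect_equal(kept, c(1, 3))
  # empty panel
  empty <- manual_panel(0)
  expect_equal(select_ancestry_snps(empty, manual_cohort(matrix(0, 1, 0))),
               integer(0))
})

test_that("panel intersection resolves strand flips and flags conflicts", {
  p1 <- manual_panel(2, allele_a = c("A", "A"), allele_b = c("G", "G"))
  p1$snp_id <- c("rs1", "rs2")
  p2 <- manual_panel(2, allele_a = c("T", "A"), allele_b = c("C", "C"))
  p2$snp_id <- c("rs2", "rs3")
  ids <- intersect_panels(list(p1, p2))
  expect_equal(as.character(ids), "rs2")
  expect_true(attr(ids, "flip")[1, 2])  # T/C is the flipped strand of A/G
  # same alleles: no flip
  p3 <- manual_panel(2, allele_a = c("G", "A"), allele_b = c("A", "G"))
  p3$snp_id <- c("rs2", "rs9")
  ids2 <- intersect_panels(list(p1, p3))
  expect_false(attr(ids2, "flip")[1, 2]) # swapped A1/A2 is not a strand flip
  # irreconcilable pair
  p4 <- manual_panel(1, allele_a = "A", allele_b = "C")
  p4$snp_id <- "rs2"
  expect_error(intersect_panels(list(p1, p4)), "mismatch")
  expect_error(intersect_panels(list(p1)), "at least two")
})
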