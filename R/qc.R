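#' Default QC thresholds
#'
#' @param snp_call_min Minimum SNP genotyping completion rate (keep if
#'   strictly greater; default 0.98).
#' @param maf_min Minimum minor allele frequency (keep if strictly greater;
#'   default 0.01).
#' @param hwe_p_min Minimum Hardy-Weinberg equilibrium p-value (keep if
#'   strictly greater; default 0.005).
#' @param ind_call_min Minimum individual completion rate (default 0.98).
#' @param rel_max Maximum tolerated cross-family GRM off-diagonal
#'   (default 0.05).
#' @param male_het_max,female_het_min X-heterozygosity cutoffs for inferring
#'   sex: below `male_het_max` (default 0.02) male, above `female_het_min`
#'   (default 0.20) female, otherwise ambiguous.
#' @param ancestry_call_min,ancestry_maf_min,ancestry_spacing_bp Criteria for
#'   [select_ancestry_snps()]: call rate at least 0.999, MAF above 0.05,
#'   spacing at least 0.5 Mb.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(snp_call_min = 0.98, maf_min = 0.01,
                          hwe_p_min = 0.005, ind_call_min = 0.98,
                          rel_max = 0.05, male_het_max = 0.02,
                          female_het_min = 0.20, ancestry_call_min = 0.999,
                          ancestry_maf_min = 0.05,
                          ancestry_spacing_bp = 5e5) {
  th <- list(snp_call_min = snp_call_min, maf_min = maf_min,
             hwe_p_min = hwe_p_min, ind_call_min = ind_call_min,
             rel_max = rel_max, male_het_max = male_het_max,
             female_het_min = female_het_min,
             ancestry_call_min = ancestry_call_min,
             ancestry_maf_min = ancestry_maf_min,
             ancestry_spacing_bp = ancestry_spacing_bp)
  props <- unlist(th[setdiff(names(th), "ancestry_spacing_bp")])
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  structure(th, class = "qc_thresholds")
}

#' Remove strand-ambiguous SNPs
#'
#' A/T and C/G SNPs cannot be strand-resolved across genotyping platforms
#' and are removed before merging datasets.
#'
#' @param panel A `snp_panel`.
#' @return Integer indices of the SNPs kept.
#' @export
filter_ambiguous <- function(panel) {
  ok_alleles <- c("A", "C", "G", "T")
  bad_codes <- !(panel$allele_a %in% ok_alleles) |
    !(panel$allele_b %in% ok_alleles)
  if (any(bad_codes))
    stop("unknown allele codes at SNP(s): ",
         paste(utils::head(panel$snp_id[bad_codes], 5), collapse = ", "))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ambiguous <- unname(comp[panel$allele_a] == panel$allele_b)
  which(!ambiguous)
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Exact test (default): the two-sided p-value is the total probability,
#' under the conditional distribution of the heterozygote count given the
#' allele count, of all heterozygote counts no more probable than the one
#' observed. A 1-df chi-square goodness-of-fit variant is available with
#' `method = "chisq"`. Monomorphic SNPs return p = 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total > 0).
#' @param method `"exact"` or `"chisq"`.
#' @return The p-value.
#' @export
#' @examples
#' hwe_test(25, 50, 25)   # perfect HWE: p = 1
#' hwe_test(50, 0, 50)    # no heterozygotes: tiny p
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("exact", "chisq")) {
  method <- match.arg(method)
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("all genotypes missing")
  n_a <- n_Aa + 2 * n_aa                  # minor-or-not is irrelevant
  if (n_a == 0 || n_a == 2 * n) return(1) # monomorphic
  if (method == "chisq") {
    p <- (2 * n_AA + n_Aa) / (2 * n)
    expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stat <- sum((counts - expd)^2 / expd)
    return(pchisq(stat, df = 1, lower.tail = FALSE))
  }
  # exact: enumerate heterozygote counts with the observed parity
  rare <- min(n_a, 2 * n - n_a)
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(het = h | n, rare) up to a common constant
  logp <- lgamma(n + 1) - lgamma((rare - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((2 * n - rare - hets) / 2 + 1) + hets * log(2)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[hets == n_Aa]
  min(1, sum(prob[prob <= p_obs + 1e-12]))
}

.geno_counts <- function(x) {
  c(n_AA = sum(x == 2, na.rm = TRUE), n_Aa = sum(x == 1, na.rm = TRUE),
    n_aa = sum(x == 0, na.rm = TRUE))
}

.x_heterozygosity <- function(cohort, panel) {
  x_idx <- which(panel$chrom == "X")
  if (length(x_idx) == 0) return(rep(NA_real_, nrow(cohort$genotypes)))
  Xg <- cohort$genotypes[, x_idx, drop = FALSE]
  rowMeans(Xg == 1, na.rm = TRUE)
}

#' Individual-level quality control
#'
#' Applies, in order: (1) genotyping completion rate above
#' `ind_call_min`; (2) sex concordance -- X heterozygosity below
#' `male_het_max` infers male, above `female_het_min` infers female, and an
#' individual whose nominal sex contradicts an unambiguous inference is
#' removed (skipped when the panel has no X SNPs or nominal sex is
#' unknown).
#'
#' @param cohort A `cohort`.
#' @param panel The matching `snp_panel`.
#' @param thresholds A [qc_thresholds()] list.
#' @return A `qc_report` for the individual axis: `kept` (indices),
#'   `removed` (named list of index vectors per rule, applied in order),
#'   `n_input`.
#' @export
individual_qc <- function(cohort, panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(cohort, "cohort"))
  n <- nrow(cohort$genotypes)
  keep <- seq_len(n)
  removed <- list()
  call_rate <- rowMeans(!is.na(cohort$genotypes))
  fail <- keep[call_rate[keep] <= thresholds$ind_call_min]
  removed$ind_call <- fail
  keep <- setdiff(keep, fail)
  het <- .x_heterozygosity(cohort, panel)
  inferred <- ifelse(is.na(het), NA_integer_,
                     ifelse(het < thresholds$male_het_max, 1L,
                            ifelse(het > thresholds$female_het_min, 2L,
                                   NA_integer_)))
  nominal <- cohort$sex
  mismatch <- !is.na(inferred) & !is.na(nominal) & nominal %in% 1:2 &
    inferred != nominal
  fail <- keep[mismatch[keep]]
  removed$sex_mismatch <- fail
  keep <- setdiff(keep, fail)
  if (length(keep) == 0) stop("individual QC removed every individual")
  structure(list(axis = "individual", kept = keep, removed = removed,
                 n_input = n, thresholds = thresholds),
            class = "qc_report")
}

#' SNP-level quality control
#'
#' Applies, in order: (1) strand-ambiguity removal (A/T, C/G); (2) SNP
#' completion rate above `snp_call_min`; (3) MAF above `maf_min`; (4)
#' Hardy-Weinberg p-value above `hwe_p_min` (exact test by default).
#' Individuals already excluded (e.g. by [individual_qc()]) can be dropped
#' first via `individuals`. For X-chromosome SNPs the Hardy-Weinberg test
#' uses females only (males are hemizygous, so pooled counts would reject
#' spuriously); an X SNP is skipped by the HWE rule if no females remain.
#'
#' @param cohort A `cohort`.
#' @param panel The matching `snp_panel`.
#' @param thresholds A [qc_thresholds()] list.
#' @param individuals Indices of individuals to base SNP statistics on
#'   (default all).
#' @param hwe_method Passed to [hwe_test()].
#' @return A `qc_report` for the SNP axis.
#' @export
snp_qc <- function(cohort, panel, thresholds = qc_thresholds(),
                   individuals = NULL, hwe_method = "exact") {
  stopifnot(inherits(cohort, "cohort"))
  X <- cohort$genotypes
  if (!is.null(individuals)) X <- X[individuals, , drop = FALSE]
  m <- ncol(X)
  keep <- seq_len(m)
  removed <- list()
  fail <- setdiff(keep, filter_ambiguous(panel))
  removed$ambiguous <- fail
  keep <- setdiff(keep, fail)

  call_rate <- colMeans(!is.na(X))
  fail <- keep[call_rate[keep] <= thresholds$snp_call_min]
  removed$snp_call <- fail
  keep <- setdiff(keep, fail)

  p_hat <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  fail <- keep[!(maf[keep] > thresholds$maf_min) | is.na(maf[keep])]
  removed$maf <- fail
  keep <- setdiff(keep, fail)

  sex <- cohort$sex
  if (!is.null(individuals)) sex <- sex[individuals]
  females <- which(sex == 2L)
  hwe_p <- vapply(keep, function(j) {
    x <- X[, j]
    if (panel$chrom[j] == "X") {
      if (length(females) == 0) return(1)
      x <- x[females]
    }
    cnt <- .geno_counts(x)
    do.call(hwe_test, c(as.list(cnt), method = hwe_method))
  }, numeric(1))
  fail <- keep[hwe_p <= thresholds$hwe_p_min]
  removed$hwe <- fail
  keep <- setdiff(keep, fail)
  if (length(keep) == 0) stop("SNP QC removed every SNP")
  structure(list(axis = "snp", kept = keep, removed = removed, n_input = m,
                 thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (", x$axis, " axis): ", x$n_input, " in, ",
      length(x$kept), " kept\n", sep = "")
  for (rule in names(x$removed))
    cat(sprintf("  %-14s removed %d\n", rule, length(x$removed[[rule]])))
  invisible(x)
}

#' Select well-spaced ancestry-informative SNPs
#'
#' Greedy left-to-right scan per chromosome keeping SNPs with call rate at
#' least `ancestry_call_min`, MAF above `ancestry_maf_min`, and at least
#' `ancestry_spacing_bp` from the previous kept SNP; such a thinned,
#' common-variant set is the usual input for ancestry PCA/clustering.
#'
#' @param panel A `snp_panel`.
#' @param cohort A `cohort` (for call rate and MAF).
#' @param thresholds A [qc_thresholds()] list.
#' @return Integer indices (into the panel) of the selected SNPs.
#' @export
select_ancestry_snps <- function(panel, cohort,
                                 thresholds = qc_thresholds()) {
  if (nrow(panel) == 0) return(integer(0))
  X <- cohort$genotypes
  call_rate <- colMeans(!is.na(X))
  p_hat <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  eligible <- call_rate >= thresholds$ancestry_call_min &
    maf > thresholds$ancestry_maf_min & !is.na(maf)
  kept <- integer(0)
  for (chr in unique(panel$chrom)) {
    idx <- which(panel$chrom == chr & eligible)
    if (length(idx) == 0) next
    idx <- idx[order(panel$pos[idx])]
    last_pos <- -Inf
    for (j in idx) {
      if (panel$pos[j] - last_pos >= thresholds$ancestry_spacing_bp) {
        kept <- c(kept, j)
        last_pos <- panel$pos[j]
      }
    }
  }
  sort(kept)
}

#' Intersect SNP panels across genotyping platforms
#'
#' Restricts to SNP ids present in every panel and checks allele
#' consistency against the first panel, allowing allele swaps (A1/A2
#' exchanged) and strand flips (both alleles complemented) for unambiguous
#' SNPs. An allele pair irreconcilable by swap or flip is an error.
#'
#' @param panels List of at least two `snp_panel`s.
#' @return Character vector of common SNP ids (order of the first panel),
#'   with attribute `flip`: a logical matrix (SNP x panel) marking panels
#'   whose strand must be flipped for that SNP.
#' @export
intersect_panels <- function(panels) {
  if (length(panels) < 2) stop("need at least two panels")
  ids <- Reduce(intersect, lapply(panels, `[[`, "snp_id"))
  ids <- panels[[1]]$snp_id[panels[[1]]$snp_id %in% ids]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- panels[[1]][match(ids, panels[[1]]$snp_id), ]
  flip <- matrix(FALSE, length(ids), length(panels))
  for (k in seq_along(panels)[-1]) {
    pk <- panels[[k]][match(ids, panels[[k]]$snp_id), ]
    same <- (pk$allele_a == ref$allele_a & pk$allele_b == ref$allele_b) |
      (pk$allele_a == ref$allele_b & pk$allele_b == ref$allele_a)
    flipped <- (comp[pk$allele_a] == ref$allele_a &
                  comp[pk$allele_b] == ref$allele_b) |
      (comp[pk$allele_a] == ref$allele_b & comp[pk$allele_b] == ref$allele_a)
    bad <- !same & !flipped
    if (any(bad))
      stop("allele mismatch unresolvable by strand flip at: ",
           paste(utils::head(ids[bad], 5), collapse = ", "))
    flip[, k] <- !same & flipped
  }
  attr(ids, "flip") <- flip
  ids
}
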