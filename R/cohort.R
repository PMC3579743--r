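#' Simulate an unrelated case-control cohort
#'
#' Draws unrelated individuals under Hardy-Weinberg equilibrium at the
#' panel's allele frequencies, assigns liability phenotypes from the effect
#' panel, and returns exactly `n_cases` affected and `n_controls` control
#' individuals. Cases are obtained by rejection sampling (population draws
#' kept only when liability reaches the threshold); controls are plain
#' population draws by default (unscreened -- a fraction `prevalence` of them
#' is expected to be affected) or screened unaffected with
#' `screened_controls = TRUE`. X-chromosome SNPs are hemizygous in males,
#' coded 0/2.
#'
#' @param panel A `snp_panel`.
#' @param effects An `effect_panel` over the panel's SNPs (same SNP count);
#'   use `h2 = 0` effects for a null cohort.
#' @param prevalence Population prevalence K (default 0.01).
#' @param n_cases,n_controls Requested counts.
#' @param screened_controls If `TRUE`, controls are screened to be
#'   unaffected.
#' @param missing_rate Fraction of genotypes set missing at random
#'   (default 0).
#' @param fid_prefix Family-id prefix; each individual is its own family.
#' @param seed Optional integer seed.
#' @return A `cohort`: list with `genotypes` (individual x SNP allele counts,
#'   `NA` = missing), `phenotype` (1 = case, 0 = control), `sex` (1 = male,
#'   2 = female), `fid`, `iid`, plus the true `G` and `liability` used in
#'   generation (for validation).
#' @export
simulate_case_control <- function(panel, effects, prevalence = 0.01,
                                  n_cases, n_controls,
                                  screened_controls = FALSE,
                                  missing_rate = 0, fid_prefix = "F",
                                  seed = NULL) {
  validate_panel(panel)
  stopifnot(inherits(effects, "effect_panel"))
  if (nrow(panel) != effects$n)
    stop("panel has ", nrow(panel), " SNPs but effects cover ", effects$n)
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  if (n_cases < 0 || n_controls < 0 || n_cases + n_controls < 1)
    stop("need at least one individual")
  .seed_if_given(seed)
  tau <- liability_threshold(prevalence)
  res <- .sample_cc_engine(effects$p, effects$a, effects$mu_G, effects$h2,
                           tau, as.integer(n_cases), as.integer(n_controls),
                           screened_controls, panel$chrom == "X",
                           max_attempts = 1e9)
  X <- res$genotypes
  colnames(X) <- panel$snp_id
  if (missing_rate > 0) {
    drop_idx <- which(runif(length(X)) < missing_rate)
    X[drop_idx] <- NA_integer_
  }
  n <- nrow(X)
  ids <- sprintf("%s%05d", fid_prefix, seq_len(n))
  structure(list(genotypes = X, phenotype = as.integer(res$phenotype),
                 sex = as.integer(res$sex), fid = ids, iid = ids,
                 G = res$G, liability = res$liability,
                 attempts = res$attempts),
            class = "cohort")
}

#' Construct a cohort from components
#'
#' Low-level constructor used by [read_plink()] and by tests; checks
#' dimension consistency.
#'
#' @param genotypes Individual x SNP allele-count matrix (0/1/2, `NA`
#'   missing).
#' @param phenotype Integer vector, 1 = case, 0 = control, `NA` unknown.
#' @param sex Integer vector, 1 = male, 2 = female, 0/`NA` unknown.
#' @param fid,iid Character vectors of family / individual ids.
#' @return A `cohort`.
#' @export
new_cohort <- function(genotypes, phenotype = NULL, sex = NULL,
                       fid = NULL, iid = NULL) {
  n <- nrow(genotypes)
  if (is.null(phenotype)) phenotype <- rep(NA_integer_, n)
  if (is.null(sex)) sex <- rep(0L, n)
  if (is.null(iid)) iid <- sprintf("I%05d", seq_len(n))
  if (is.null(fid)) fid <- iid
  if (length(phenotype) != n || length(sex) != n || length(fid) != n ||
      length(iid) != n)
    stop("phenotype, sex, fid, iid must each have one entry per individual")
  structure(list(genotypes = genotypes, phenotype = as.integer(phenotype),
                 sex = as.integer(sex), fid = as.character(fid),
                 iid = as.character(iid)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", nrow(x$genotypes), "individuals x", ncol(x$genotypes),
      "SNPs\n")
  tab <- table(factor(x$phenotype, c(0, 1), c("control", "case")),
               useNA = "ifany")
  cat("  phenotype:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missingness: %.3f%%\n", 100 * miss))
  invisible(x)
}
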