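#' Pairwise linkage-disequilibrium r-squared from phased haplotypes
#'
#' Squared Pearson correlation of allele indicators across haplotypes,
#' which for phased binary data equals the classical
#' `D^2 / (p(1-p) q(1-q))`. Monomorphic SNPs have undefined r-squared; they
#' are dropped with a warning and their rows/columns are absent from the
#' result.
#'
#' @param haplotypes Haplotype x SNP 0/1 matrix, or a `haplotype_pool`.
#' @param snps Optional column indices to restrict to.
#' @return Symmetric r-squared matrix (unit diagonal), with the used column
#'   indices as dimnames-compatible attribute `snps`.
#' @export
pairwise_r2 <- function(haplotypes, snps = NULL) {
  H <- if (inherits(haplotypes, "haplotype_pool")) haplotypes$H else haplotypes
  if (is.null(snps)) snps <- seq_len(ncol(H))
  H <- H[, snps, drop = FALSE]
  freq <- colMeans(H)
  mono <- freq == 0 | freq == 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) excluded from r2")
    H <- H[, !mono, drop = FALSE]
    snps <- snps[!mono]
  }
  r2 <- cor(H)^2
  attr(r2, "snps") <- snps
  r2
}

#' Tag-SNP coverage of a region
#'
#' Estimates what fraction of the tags needed to cover a region at LD
#' threshold `X` is already present in a forced (genotyped) tag set.
#' Candidates are clustered by complete linkage on `1 - r2` and the tree is
#' cut at height `1 - X`, so every pair within a cluster has `r2 >= X` and
#' any member can tag its cluster. Clusters containing at least one forced
#' tag need no new tag; `N` is the number of clusters containing no forced
#' tag, and coverage is `M / (M + N)` with `M` the forced-tag count.
#'
#' @param haplotypes Haplotype matrix or `haplotype_pool` for the region.
#' @param forced_tags Column indices of the genotyped ("tagSNP") set; must
#'   be a subset of `candidates`.
#' @param candidates Column indices of the SNPs requiring coverage;
#'   defaults to all SNPs with MAF > `maf_min`.
#' @param X r-squared threshold in (0, 1].
#' @param maf_min MAF floor defining the default candidate universe
#'   (default 0.1).
#' @return A `coverage_estimate`: list with `M`, `N`, `X`, `coverage`.
#' @export
tag_cover <- function(haplotypes, forced_tags, candidates = NULL, X,
                      maf_min = 0.1) {
  H <- if (inherits(haplotypes, "haplotype_pool")) haplotypes$H else haplotypes
  if (X <= 0 || X > 1) stop("X must be in (0, 1]")
  if (any(forced_tags < 1 | forced_tags > ncol(H)))
    stop("forced tags must lie within the region's SNPs")
  freq <- colMeans(H)
  if (is.null(candidates))
    candidates <- which(pmin(freq, 1 - freq) > maf_min)
  candidates <- sort(unique(c(candidates, forced_tags)))
  if (!all(forced_tags %in% candidates))
    stop("forced tags must lie within the region's SNPs")
  r2 <- suppressWarnings(pairwise_r2(H, candidates))
  used <- attr(r2, "snps")
  M <- length(forced_tags)
  if (length(used) <= 1) {
    cl <- rep(1L, length(used))
  } else {
    hc <- hclust(as.dist(1 - r2), method = "complete")
    cl <- cutree(hc, h = 1 - X)
  }
  has_tag <- tapply(used %in% forced_tags, cl, any)
  N <- sum(!has_tag)
  structure(list(M = M, N = as.integer(N), X = X,
                 coverage = M / (M + N)),
            class = "coverage_estimate")
}

#' Minimal tagging by exhaustive search (oracle)
#'
#' Smallest number of additional tags (beyond the forced set) such that
#' every candidate has `r2 >= X` with at least one tag. Exponential in the
#' number of uncovered candidates; intended as a brute-force check of
#' [tag_cover()] on regions of ~20 SNPs or fewer.
#'
#' @inheritParams tag_cover
#' @return Integer, the minimal `N`.
#' @export
exhaustive_min_tags <- function(haplotypes, forced_tags, candidates = NULL,
                                X, maf_min = 0.1) {
  H <- if (inherits(haplotypes, "haplotype_pool")) haplotypes$H else haplotypes
  freq <- colMeans(H)
  if (is.null(candidates))
    candidates <- which(pmin(freq, 1 - freq) > maf_min)
  candidates <- sort(unique(c(candidates, forced_tags)))
  r2 <- suppressWarnings(pairwise_r2(H, candidates))
  used <- attr(r2, "snps")
  covered <- if (length(forced_tags))
    apply(r2[, used %in% forced_tags, drop = FALSE] >= X, 1, any)
  else rep(FALSE, length(used))
  uncovered <- which(!covered)
  if (length(uncovered) == 0) return(0L)
  if (length(uncovered) > 25)
    stop("exhaustive search limited to 25 uncovered SNPs")
  pool <- seq_along(used)
  for (k in 1:length(uncovered)) {
    sets <- utils::combn(pool, k, simplify = FALSE)
    for (s in sets) {
      if (all(apply(r2[uncovered, s, drop = FALSE] >= X, 1, any)))
        return(as.integer(k))
    }
  }
  length(uncovered)
}

#' Coverage as a function of panel subsampling
#'
#' Repeats the tag-coverage calculation over regions while thinning the
#' forced tag set to the given fractions (subsampled at random, `reps`
#' times per fraction), at each r-squared threshold. Mirrors the design of
#' relating genomic coverage to heritability estimated from SNP subsets.
#'
#' @param regions A `haplotype_pool`, or list of them (one per region).
#' @param forced_tags Column indices of the genotyped set (per region if
#'   `regions` is a list: a list of index vectors).
#' @param fractions Fractions of the forced set to retain
#'   (default `c(1, 0.5, 0.25, 0.125)`).
#' @param r2_thresholds r-squared thresholds (default `c(0.5, 0.7, 0.9)`).
#' @param reps Random subsample replicates per fraction (default 5;
#'   fraction 1 is deterministic and run once).
#' @param maf_min Candidate MAF floor (default 0.1).
#' @param seed Optional integer seed.
#' @return Data frame with columns `fraction`, `X`, `rep`, `region`, `M`,
#'   `N`, `coverage`, and a `summary` attribute of mean coverage per
#'   fraction x threshold.
#' @export
coverage_curve <- function(regions, forced_tags,
                           fractions = c(1, 0.5, 0.25, 0.125),
                           r2_thresholds = c(0.5, 0.7, 0.9), reps = 5,
                           maf_min = 0.1, seed = NULL) {
  .seed_if_given(seed)
  if (inherits(regions, "haplotype_pool")) {
    regions <- list(regions)
    forced_tags <- list(forced_tags)
  }
  if (length(forced_tags) != length(regions))
    stop("one forced-tag vector per region required")
  rows <- list()
  for (f in fractions) {
    n_rep <- if (f == 1) 1L else as.integer(reps)
    for (r in seq_len(n_rep)) {
      for (g in seq_along(regions)) {
        tags <- forced_tags[[g]]
        sub <- if (f == 1) tags else
          sort(sample(tags, max(1, round(f * length(tags)))))
        for (X in r2_thresholds) {
          cv <- tag_cover(regions[[g]], sub, candidates = NULL, X = X,
                          maf_min = maf_min)
          rows[[length(rows) + 1]] <-
            data.frame(fraction = f, X = X, rep = r, region = g,
                       M = cv$M, N = cv$N, coverage = cv$coverage)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  agg <- aggregate(coverage ~ fraction + X, data = out, FUN = mean)
  attr(out, "summary") <- agg[order(agg$X, -agg$fraction), ]
  out
}
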