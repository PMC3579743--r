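#' Human chromosome lengths (GRCh37)
#'
#' Base-pair lengths of the 22 autosomes and chromosome X, used to spread
#' simulated SNPs over the genome in proportion to physical length (the
#' polygenic model assumed here places liability variants at random over the
#' genome, so longer chromosomes receive proportionally more SNPs).
#'
#' @param chromosomes Character vector naming the chromosomes wanted, from
#'   `c(1:22, "X")`. Defaults to all 23.
#' @return Named numeric vector of lengths in base pairs.
#' @export
#' @examples
#' chromosome_lengths(c("1", "2", "X"))
chromosome_lengths <- function(chromosomes = c(as.character(1:22), "X")) {
  lens <- c(
    `1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566, X = 155270560
  )
  chromosomes <- as.character(chromosomes)
  unknown <- setdiff(chromosomes, names(lens))
  if (length(unknown) > 0)
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  lens[chromosomes]
}

#' Simulate a biallelic SNP panel
#'
#' Draws per-SNP reference-allele frequencies uniformly from `maf_range` and
#' assigns SNPs to chromosomes in proportion to physical chromosome length,
#' with strictly increasing positions within each chromosome. Allele pairs
#' are random distinct nucleotides (so strand-ambiguous A/T and C/G SNPs do
#' occur, as on real arrays; see [filter_ambiguous()]).
#'
#' @param n_snps Number of SNPs (>= 1).
#' @param maf_range Length-2 numeric, the (inclusive) range of the
#'   reference-allele frequency, within (0, 1). The liability panels used in
#'   the family simulations draw from (0.01, 0.99); QC-style panels typically
#'   use a minor-allele range such as (0.01, 0.5).
#' @param chromosomes Chromosome labels from `c(1:22, "X")`.
#' @param seed Optional integer seed.
#' @return A `snp_panel`: a data frame with columns `snp_id`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`, `p` (frequency of `allele_a`).
#' @export
#' @examples
#' pan <- simulate_panel(100, seed = 1)
#' range(pan$p)
simulate_panel <- function(n_snps, maf_range = c(0.01, 0.99),
                           chromosomes = c(as.character(1:22), "X"),
                           seed = NULL) {
  if (length(n_snps) != 1L || n_snps < 1) stop("n_snps must be a count >= 1")
  n_snps <- as.integer(n_snps)
  if (length(chromosomes) == 0) stop("chromosomes must be non-empty")
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      maf_range[1] > maf_range[2] || maf_range[1] <= 0 || maf_range[2] >= 1)
    stop("maf_range must be (lo, hi) with 0 < lo <= hi < 1")
  .seed_if_given(seed)
  lens <- chromosome_lengths(chromosomes)
  # deterministic proportional allocation (largest remainder)
  frac <- lens / sum(lens) * n_snps
  counts <- floor(frac)
  short <- n_snps - sum(counts)
  if (short > 0) {
    extra <- order(frac - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  chrom <- rep(names(lens), counts)
  pos <- unlist(lapply(seq_along(lens), function(i) {
    k <- counts[i]
    if (k == 0) return(integer(0))
    sort(sample.int(lens[i], k))
  }), use.names = FALSE)
  nucs <- c("A", "C", "G", "T")
  a1 <- sample(nucs, n_snps, replace = TRUE)
  a2 <- vapply(a1, function(x) sample(setdiff(nucs, x), 1), character(1))
  p <- runif(n_snps, maf_range[1], maf_range[2])
  panel <- data.frame(
    snp_id = sprintf("snp%06d", seq_len(n_snps)),
    chrom = chrom, pos = as.integer(pos),
    allele_a = unname(a1), allele_b = unname(a2),
    p = p, stringsAsFactors = FALSE
  )
  class(panel) <- c("snp_panel", "data.frame")
  validate_panel(panel)
  panel
}

#' Validate a SNP panel
#'
#' Checks the `snp_panel` invariants: required columns, frequencies strictly
#' inside (0, 1), distinct alleles, strictly increasing positions within each
#' chromosome.
#'
#' @param panel A `snp_panel` data frame.
#' @return The panel, invisibly; stops on violation.
#' @export
validate_panel <- function(panel) {
  need <- c("snp_id", "chrom", "pos", "allele_a", "allele_b", "p")
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0)
    stop("panel lacks column(s): ", paste(miss, collapse = ", "))
  if (any(panel$p <= 0 | panel$p >= 1)) stop("allele frequencies must be in (0, 1)")
  if (any(panel$allele_a == panel$allele_b)) stop("alleles must be distinct")
  bad <- vapply(split(panel$pos, panel$chrom), function(x) any(diff(x) <= 0),
                logical(1))
  if (any(bad))
    stop("positions must be strictly increasing within chromosome(s): ",
         paste(names(bad)[bad], collapse = ", "))
  if (anyDuplicated(panel$snp_id)) stop("snp_id values must be unique")
  invisible(panel)
}

#' Simulate a phased haplotype pool with block LD structure
#'
#' Generates `n_haplotypes` phased binary haplotypes over the panel's SNPs,
#' arranged in blocks of `block_size` consecutive SNPs per chromosome. Within
#' a block every haplotype carries a latent founder allele drawn at the
#' block's frequency (the panel frequency of the block's first SNP); each
#' site copies the founder allele and is then flipped independently with a
#' per-site mutation probability `m` chosen so that the expected r-squared
#' between two sites of the same block equals `target_r2`
#' (`r = (1 - 2m)^2`, hence `m = (1 - target_r2^(1/4)) / 2`). Sites in
#' different blocks are independent, so cross-block r-squared is ~0.
#'
#' With `block_size = 1` (or `target_r2 = 0`) all sites are independent draws
#' at the panel frequencies. This pool stands in for reference-project
#' haplotypes in the genomic-coverage experiment; it reproduces block LD and
#' marginal frequency bounds, not fine-scale recombination.
#'
#' @param panel A `snp_panel`.
#' @param n_haplotypes Number of haplotypes (rows).
#' @param block_size SNPs per LD block (>= 1).
#' @param target_r2 Expected within-block r-squared, in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return A `haplotype_pool`: list with `H` (haplotype x SNP 0/1 matrix),
#'   `panel`, and `block` (integer block id per SNP).
#' @export
simulate_haplotypes <- function(panel, n_haplotypes, block_size = 1,
                                target_r2 = 0, seed = NULL) {
  validate_panel(panel)
  if (block_size < 1) stop("block_size must be >= 1")
  if (target_r2 < 0 || target_r2 >= 1) stop("target_r2 must be in [0, 1)")
  .seed_if_given(seed)
  n_snp <- nrow(panel)
  H <- matrix(0L, n_haplotypes, n_snp)
  block <- integer(n_snp)
  m <- if (target_r2 > 0) (1 - target_r2^(1 / 4)) / 2 else 0.5
  bid <- 0L
  for (chr in unique(panel$chrom)) {
    idx <- which(panel$chrom == chr)
    starts <- seq(1, length(idx), by = block_size)
    for (s in starts) {
      bid <- bid + 1L
      cols <- idx[s:min(s + block_size - 1, length(idx))]
      block[cols] <- bid
      if (target_r2 > 0 && length(cols) > 1) {
        pb <- panel$p[cols[1]]
        founder <- rbinom(n_haplotypes, 1, pb)
        for (j in cols) {
          flip <- rbinom(n_haplotypes, 1, m)
          H[, j] <- as.integer(xor(founder, flip))
        }
      } else {
        for (j in cols) H[, j] <- rbinom(n_haplotypes, 1, panel$p[j])
      }
    }
  }
  colnames(H) <- panel$snp_id
  structure(list(H = H, panel = panel, block = block),
            class = "haplotype_pool")
}
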