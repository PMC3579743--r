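#' Compute a genetic relationship matrix
#'
#' GRM in the standard GCTA parameterisation. With allele counts `x` and
#' sample frequencies `p` (estimated from the analyzed individuals), the
#' off-diagonal for individuals j, k is
#' `A_jk = (1/m) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' and the diagonal is
#' `A_jj = 1 + (1/m) sum_i (x_ij^2 - (1 + 2 p_i) x_ij + 2 p_i^2) / (2 p_i (1 - p_i))`.
#' Missing genotypes are mean-imputed (to `2 p_i`) before computation, so
#' every pair is scored over all `m` SNPs; this keeps the per-chromosome /
#' pooled combination identity exact. Chromosome X, when included, is scaled
#' like an autosome.
#'
#' @param cohort A `cohort`.
#' @param panel The matching `snp_panel`; needed when `chromosomes` is used.
#' @param chromosomes Optional chromosome labels to restrict to.
#' @param snps Optional SNP indices to restrict to (applied after
#'   `chromosomes`).
#' @return A `grm`: list with `A` (symmetric n x n), `m` (number of SNPs
#'   used), `fid`, `iid`.
#' @export
compute_grm <- function(cohort, panel = NULL, chromosomes = NULL,
                        snps = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  X <- cohort$genotypes
  idx <- seq_len(ncol(X))
  if (!is.null(chromosomes)) {
    if (is.null(panel)) stop("panel is required to filter by chromosome")
    idx <- idx[panel$chrom[idx] %in% as.character(chromosomes)]
  }
  if (!is.null(snps)) idx <- intersect(idx, snps)
  if (length(idx) == 0) stop("no SNPs selected")
  X <- X[, idx, drop = FALSE]
  p <- colMeans(X, na.rm = TRUE) / 2
  mono <- p <= 0 | p >= 1 | is.na(p)
  if (any(mono))
    stop(sum(mono), " monomorphic/all-missing SNP(s) in GRM input; ",
         "run SNP QC first")
  m <- ncol(X)
  denom <- 2 * p * (1 - p)
  Ximp <- X
  if (anyNA(Ximp)) {
    na_idx <- which(is.na(Ximp), arr.ind = TRUE)
    Ximp[na_idx] <- 2 * p[na_idx[, 2]]
  }
  W <- sweep(Ximp, 2, 2 * p, `-`)
  W <- sweep(W, 2, sqrt(denom), `/`)
  A <- tcrossprod(W) / m
  # GCTA uses a distinct diagonal estimator
  diag(A) <- 1 + colSums((t(Ximp)^2 - (1 + 2 * p) * t(Ximp) + 2 * p^2) /
                           denom) / m
  structure(list(A = A, m = m, fid = cohort$fid, iid = cohort$iid),
            class = "grm")
}

#' Combine per-chromosome GRMs
#'
#' Weighted elementwise average with weights equal to each matrix's SNP
#' count: `A = sum_c m_c A_c / sum_c m_c`. Given shared allele frequencies
#' this equals the GRM computed from the pooled SNP set exactly.
#'
#' @param grms List of `grm` objects over identical individuals.
#' @return A combined `grm`.
#' @export
combine_grms <- function(grms) {
  if (inherits(grms, "grm")) grms <- list(grms)
  stopifnot(length(grms) >= 1, all(vapply(grms, inherits, logical(1), "grm")))
  ids <- paste(grms[[1]]$fid, grms[[1]]$iid)
  for (g in grms[-1])
    if (!identical(paste(g$fid, g$iid), ids))
      stop("GRMs cover different individuals")
  m_tot <- sum(vapply(grms, `[[`, numeric(1), "m"))
  A <- Reduce(`+`, lapply(grms, function(g) g$A * g$m)) / m_tot
  structure(list(A = A, m = m_tot, fid = grms[[1]]$fid,
                 iid = grms[[1]]$iid),
            class = "grm")
}

#' Principal components of a GRM
#'
#' Top-k eigenvectors of the relationship matrix, the standard ancestry
#' covariates for GREML (default k = 10).
#'
#' @param grm A `grm`.
#' @param k Number of components (less than the number of individuals).
#' @return A `pc_set`: list with `vectors` (individual x k, orthonormal),
#'   `values` (non-increasing), `k`.
#' @export
grm_pca <- function(grm, k = 10) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$A)
  if (k >= n) stop("k must be smaller than the number of individuals")
  if (any(!is.finite(grm$A))) stop("GRM contains non-finite entries")
  eig <- eigen(grm$A, symmetric = TRUE)
  structure(list(vectors = eig$vectors[, seq_len(k), drop = FALSE],
                 values = eig$values[seq_len(k)], k = k,
                 fid = grm$fid, iid = grm$iid),
            class = "pc_set")
}

#' Prune cross-family related individuals
#'
#' Greedily removes individuals until no pair in *different* families has a
#' GRM entry above `cutoff` (members of the same family are never compared).
#' At each step the individual involved in the most offending pairs is
#' removed, breaking ties by lower call rate, then by order.
#'
#' @param grm A `grm`.
#' @param cutoff Off-diagonal threshold (default 0.05).
#' @param families Family labels (default the GRM's `fid`).
#' @param call_rates Optional per-individual call rates for tie-breaking.
#' @return Integer indices of the individuals kept.
#' @export
relatedness_prune <- function(grm, cutoff = 0.05, families = grm$fid,
                              call_rates = NULL) {
  stopifnot(inherits(grm, "grm"))
  A <- grm$A
  n <- nrow(A)
  if (length(families) != n) stop("one family label per individual required")
  if (is.null(call_rates)) call_rates <- rep(1, n)
  off <- abs(A) > cutoff
  diag(off) <- FALSE
  off[outer(families, families, `==`)] <- FALSE
  active <- rep(TRUE, n)
  repeat {
    deg <- rowSums(off)
    if (all(deg == 0)) break
    worst <- which(deg == max(deg))
    worst <- worst[order(call_rates[worst], worst)][1]
    active[worst] <- FALSE
    off[worst, ] <- FALSE
    off[, worst] <- FALSE
  }
  which(active)
}

#' Write a GRM in GCTA binary format
#'
#' Writes `prefix.grm.bin` (float32 lower triangle including the diagonal,
#' row by row), `prefix.grm.N.bin` (float32 per-pair SNP counts; constant
#' `m` here, since missing genotypes are mean-imputed), and
#' `prefix.grm.id` (FID, IID, tab-separated).
#'
#' @param grm A `grm`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$A)
  lower <- grm$A[upper.tri(grm$A, diag = TRUE)]  # column-major upper = row-major lower
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$m), length(lower)), con, size = 4)
  close(con)
  write.table(data.frame(grm$fid, grm$iid), paste0(prefix, ".grm.id"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(prefix)
}

#' Read a GRM in GCTA binary format
#'
#' @param prefix Path prefix of the `.grm.bin` / `.grm.N.bin` / `.grm.id`
#'   triplet.
#' @return A `grm` (with `m` taken as the maximum entry of `N`).
#' @export
read_grm <- function(prefix) {
  ids <- read.table(paste0(prefix, ".grm.id"), header = FALSE,
                    stringsAsFactors = FALSE)
  n <- nrow(ids)
  n_elem <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = n_elem, size = 4)
  if (length(vals) != n_elem)
    stop("grm.bin holds ", length(vals), " values but ids imply ", n_elem)
  A <- matrix(0, n, n)
  A[upper.tri(A, diag = TRUE)] <- vals
  A <- A + t(A) - diag(diag(A))
  Nv <- readBin(paste0(prefix, ".grm.N.bin"), "numeric", n = n_elem, size = 4)
  structure(list(A = A, m = max(Nv), fid = ids[[1]], iid = ids[[2]]),
            class = "grm")
}
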