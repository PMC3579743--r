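#' Write a cohort to PLINK bed/bim/fam files
#'
#' Writes the binary genotype file in the standard SNP-major bed format
#' (v1.00: magic bytes `0x6c 0x1b`, mode byte `0x01`), with the usual 2-bit
#' codes per genotype: `00` = homozygous for allele A1, `10` = heterozygous,
#' `11` = homozygous A2, `01` = missing. Allele A1 in the bim file is the
#' panel's `allele_a`, whose count the cohort's genotype matrix stores.
#' Phenotypes are written as 1 = control, 2 = case, -9 = missing; sex as
#' 1 = male, 2 = female, 0 = unknown.
#'
#' @param cohort A `cohort`.
#' @param panel A `snp_panel` describing the cohort's SNP columns (same
#'   number and order).
#' @param prefix Output path prefix; `prefix.bed`, `prefix.bim`,
#'   `prefix.fam` are created.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(cohort, panel, prefix) {
  stopifnot(inherits(cohort, "cohort"))
  validate_panel(panel)
  X <- cohort$genotypes
  n <- nrow(X); m <- ncol(X)
  if (m != nrow(panel))
    stop("cohort has ", m, " SNPs but panel describes ", nrow(panel))
  if (any(!X[!is.na(X)] %in% 0:2)) stop("genotypes must be 0, 1, 2 or NA")
  # 2-bit codes for A1 counts 2/1/0/NA -> 00/10/11/01
  code <- matrix(3L, n, m)                # 0 copies of A1
  code[X == 1L] <- 2L
  code[X == 2L] <- 0L
  code[is.na(X)] <- 1L
  n_bytes <- ceiling(n / 4)
  pad <- n_bytes * 4 - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, m))  # pad bits are zero
  # pack 4 genotypes per byte, low bits first
  i1 <- seq(1, nrow(code), by = 4)
  bytes <- code[i1, , drop = FALSE] + 4L * code[i1 + 1, , drop = FALSE] +
    16L * code[i1 + 2, , drop = FALSE] + 64L * code[i1 + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)            # column-major = SNP-major
  bim <- data.frame(chrom = panel$chrom, snp_id = panel$snp_id, cm = 0,
                    pos = panel$pos, a1 = panel$allele_a, a2 = panel$allele_b)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  pheno <- ifelse(is.na(cohort$phenotype), -9L, cohort$phenotype + 1L)
  sex <- ifelse(is.na(cohort$sex), 0L, cohort$sex)
  fam <- data.frame(fid = cohort$fid, iid = cohort$iid, pid = 0, mid = 0,
                    sex = sex, pheno = pheno)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK bed/bim/fam files
#'
#' Reads a SNP-major v1.00 bed file and its bim/fam companions back into a
#' `cohort` and `snp_panel`; the genotype matrix stores counts of the bim
#' A1 allele. Allele frequencies in the returned panel are estimated from
#' the genotypes. Fails on a bad magic number, an individual-major file, or
#' a bed payload whose size disagrees with the bim/fam row counts.
#'
#' @param prefix Path prefix of the fileset.
#' @return List with elements `cohort` and `panel`.
#' @export
read_plink <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"))
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("fid", "iid", "pid", "mid", "sex", "pheno"))
  n <- nrow(fam); m <- nrow(bim)
  bed_path <- paste0(prefix, ".bed")
  size <- file.info(bed_path)$size
  raw <- readBin(bed_path, "raw", n = size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file (bad magic number): ", bed_path)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major (v1.00) bed files are supported")
  n_bytes <- ceiling(n / 4)
  if (length(raw) - 3 != n_bytes * m)
    stop("bed payload has ", length(raw) - 3, " bytes but bim/fam imply ",
         n_bytes * m)
  bytes <- as.integer(raw[-(1:3)])
  # unpack 2-bit codes, low bits first
  codes <- rbind(bytes %% 4L, (bytes %/% 4L) %% 4L,
                 (bytes %/% 16L) %% 4L, (bytes %/% 64L) %% 4L)
  dim(codes) <- c(4L * n_bytes, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  lookup <- c(2L, NA_integer_, 1L, 0L)    # code 0,1,2,3 -> A1 count
  X <- matrix(lookup[codes + 1L], n, m)
  colnames(X) <- bim$snp_id
  pheno <- ifelse(fam$pheno %in% c(1, 2), fam$pheno - 1L, NA_integer_)
  sex <- ifelse(fam$sex %in% c(1, 2), fam$sex, 0L)
  cohort <- new_cohort(X, phenotype = pheno, sex = sex,
                       fid = fam$fid, iid = fam$iid)
  p_hat <- colMeans(X, na.rm = TRUE) / 2
  panel <- data.frame(snp_id = bim$snp_id, chrom = as.character(bim$chrom),
                      pos = bim$pos, allele_a = bim$a1, allele_b = bim$a2,
                      p = pmin(pmax(p_hat, 1e-6), 1 - 1e-6),
                      stringsAsFactors = FALSE)
  class(panel) <- c("snp_panel", "data.frame")
  list(cohort = cohort, panel = panel)
}

#' Write a phenotype or covariate table in GCTA convention
#'
#' Whitespace-delimited columns FID IID VALUE... with no header.
#'
#' @param cohort A `cohort` (supplies FID/IID).
#' @param values Numeric vector or matrix (one row per individual).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pheno <- function(cohort, values, path) {
  values <- as.matrix(values)
  if (nrow(values) != length(cohort$iid))
    stop("values must have one row per individual")
  out <- data.frame(cohort$fid, cohort$iid, values)
  write.table(out, path, sep = " ", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
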