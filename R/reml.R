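#' Restricted maximum likelihood fit of variance components
#'
#' Fits `y ~ N(X b, sum_c sigma2_c A_c + sigma2_e I)` by average-information
#' (AI) REML with an expectation-maximisation (EM) warm start. The first
#' `n_em` iterations use EM updates; later iterations take AI steps with
#' step-halving, falling back to an EM update whenever a full or halved AI
#' step would decrease the restricted log-likelihood, so the log-likelihood
#' is non-decreasing across iterations. Variance components are constrained
#' non-negative by projection to a small floor (`1e-8 * var(y)`) unless
#' `constrain = FALSE`. Standard errors come from the inverse AI matrix at
#' convergence.
#'
#' For a 0/1 affection phenotype this is the observed-scale analysis; the
#' resulting heritability is transformed to the liability scale with
#' [observed_to_liability()].
#'
#' @param y Numeric response (for case-control work, 0/1 affection status).
#' @param X Fixed-effect design matrix (including the intercept); `NULL`
#'   for an intercept only. Must have full column rank.
#' @param grms A `grm`, a relationship matrix, or a list of either (one
#'   variance component per matrix, plus the residual).
#' @param constrain Keep components non-negative (default `TRUE`).
#' @param max_iter,tol Iteration cap and convergence tolerance on the
#'   change in restricted log-likelihood.
#' @param n_em Number of initial EM iterations (default 3).
#' @param init Optional starting values (length: number of GRMs + 1,
#'   residual last).
#' @return A `reml_fit`: variance components (`varcomp`, residual last)
#'   with `se`, observed-scale `h2_obs` (total genetic fraction) and
#'   `h2_obs_se`, fixed effects `beta` and `beta_se`, restricted
#'   log-likelihood `logL`, `iterations`, `converged`, and `identifiable`
#'   (`FALSE` when the AI matrix is numerically singular, e.g. a GRM
#'   indistinguishable from the identity).
#' @export
reml_fit <- function(y, X = NULL, grms, constrain = TRUE, max_iter = 100,
                     tol = 1e-8, n_em = 3, init = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X must have one row per observation")
  if (qr(X)$rank < ncol(X)) stop("X is rank-deficient")
  if (inherits(grms, "grm") || is.matrix(grms)) grms <- list(grms)
  A_list <- lapply(grms, function(g) {
    A <- if (inherits(g, "grm")) g$A else g
    if (!is.matrix(A) || nrow(A) != n || ncol(A) != n)
      stop("each GRM must be an n x n matrix matching y")
    A
  })
  q <- length(A_list)
  vp <- var(y)
  floor_val <- 1e-8 * vp
  theta <- if (is.null(init)) rep(vp / (q + 1), q + 1) else as.numeric(init)
  if (length(theta) != q + 1) stop("init must have length ", q + 1)

  # restricted log-likelihood and the projection quantities at theta
  eval_obj <- function(theta) {
    V <- diag(theta[q + 1], n)
    for (c in seq_len(q)) V <- V + theta[c] * A_list[[c]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    VinvX <- Vinv %*% X
    XtVinvX <- crossprod(X, VinvX)
    XtVinvX_inv <- solve(XtVinvX)
    P <- Vinv - VinvX %*% XtVinvX_inv %*% t(VinvX)
    Py <- drop(P %*% y)
    logL <- -0.5 * (2 * sum(log(diag(ch))) +
                      determinant(XtVinvX, logarithm = TRUE)$modulus +
                      sum(y * Py))
    list(P = P, Py = Py, logL = as.numeric(logL), Vinv = Vinv,
         XtVinvX_inv = XtVinvX_inv, VinvX = VinvX)
  }
  project <- function(th) if (constrain) pmax(th, floor_val) else th

  obj <- eval_obj(theta)
  if (is.null(obj)) stop("initial variance matrix is not positive definite")
  identifiable <- TRUE
  converged <- FALSE
  iter <- 0
  AI <- NULL
  score <- NULL
  repeat {
    iter <- iter + 1
    # score and AI at the current point
    U <- matrix(0, n, q + 1)
    trPA <- numeric(q + 1)
    for (c in seq_len(q)) {
      U[, c] <- A_list[[c]] %*% obj$Py
      trPA[c] <- sum(obj$P * A_list[[c]])
    }
    U[, q + 1] <- obj$Py
    trPA[q + 1] <- sum(diag(obj$P))
    yPU <- drop(crossprod(obj$Py, U))            # y' P A_c P y
    score <- -0.5 * (trPA - yPU)
    PU <- obj$P %*% U
    AI <- 0.5 * crossprod(U, PU)

    em_step <- function() theta + theta^2 / n * (yPU - trPA)
    use_em <- iter <= n_em
    ai_dir <- NULL
    if (!use_em) {
      ai_dir <- tryCatch(solve(AI, score), error = function(e) NULL)
      if (is.null(ai_dir) || !all(is.finite(ai_dir)) ||
          rcond(AI) < 1e-12) {
        identifiable <- FALSE
        use_em <- TRUE
      }
    }
    accepted <- FALSE
    if (!use_em) {
      step <- 1
      for (h in 1:6) {                           # step-halving
        cand <- project(theta + step * ai_dir)
        cand_obj <- eval_obj(cand)
        if (!is.null(cand_obj) && cand_obj$logL >= obj$logL - 1e-10) {
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
    }
    if (!accepted) {                             # EM fallback (never decreases logL)
      cand <- project(em_step())
      cand_obj <- eval_obj(cand)
      if (is.null(cand_obj)) stop("EM update produced a singular V")
    }
    delta_ll <- cand_obj$logL - obj$logL
    theta <- cand
    obj <- cand_obj
    if (iter > 1 && abs(delta_ll) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning("REML did not converge in ", max_iter, " iterations")
  # a numerically singular AI matrix at the optimum means the components
  # are not separately identifiable (e.g. a GRM equal to the identity)
  if (identifiable && rcond(AI) < 1e-12) identifiable <- FALSE
  if (!identifiable)
    warning("AI matrix numerically singular; variance components may not ",
            "be separately identifiable (EM updates used)")

  se <- rep(NA_real_, q + 1)
  h2_se <- NA_real_
  AI_inv <- tryCatch(solve(AI), error = function(e) NULL)
  tot <- sum(theta)
  h2_obs <- sum(theta[seq_len(q)]) / tot
  if (!is.null(AI_inv)) {
    se <- sqrt(pmax(diag(AI_inv), 0))
    grad <- c(rep((tot - sum(theta[seq_len(q)])) / tot^2, q),
              -sum(theta[seq_len(q)]) / tot^2)
    h2_se <- sqrt(max(0, drop(t(grad) %*% AI_inv %*% grad)))
  }
  beta <- drop(obj$XtVinvX_inv %*% crossprod(obj$VinvX, y))
  beta_se <- sqrt(diag(obj$XtVinvX_inv))
  names(theta) <- names(se) <-
    c(paste0("sigma2_g", seq_len(q)), "sigma2_e")
  structure(list(varcomp = theta, se = se, h2_obs = h2_obs,
                 h2_obs_se = h2_se, beta = beta, beta_se = beta_se,
                 logL = obj$logL, iterations = iter, converged = converged,
                 identifiable = identifiable, AI = AI, n = n,
                 n_components = q),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  q <- x$n_components
  vp <- sum(x$varcomp)
  cat("AI-REML fit (", x$n, " observations, ", q, " genetic component",
      if (q > 1) "s", ")\n", sep = "")
  cat(sprintf("%-12s %10s %10s\n", "Source", "Variance", "SE"))
  lab <- c(if (q == 1) "V(G)" else paste0("V(G", seq_len(q), ")"), "V(e)")
  for (i in seq_along(x$varcomp))
    cat(sprintf("%-12s %10.6f %10.6f\n", lab[i], x$varcomp[i], x$se[i]))
  cat(sprintf("%-12s %10.6f\n", "Vp", vp))
  cat(sprintf("%-12s %10.6f %10.6f\n", "V(G)/Vp", x$h2_obs, x$h2_obs_se))
  cat(sprintf("logL %.4f after %d iterations (%sconverged)\n",
              x$logL, x$iterations, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Transform observed-scale heritability to the liability scale
#'
#' For a 0/1 affection trait analysed as if continuous, with population
#' prevalence `K` and sample case proportion `P`, the liability-scale
#' heritability under case-control ascertainment is
#' `h2_liab = h2_obs * K^2 (1 - K)^2 / (z^2 P (1 - P))`, where `z` is the
#' standard-normal density at the liability threshold `qnorm(1 - K)`. The
#' standard error scales by the same multiplier (delta method).
#'
#' @param h2_obs Observed-scale heritability (and `se_obs` its SE).
#' @param se_obs Standard error on the observed scale (optional).
#' @param K Population prevalence in (0, 1).
#' @param P Sample case proportion in (0, 1).
#' @return A `liability_estimate`: list with `K`, `P`, `z`, `multiplier`,
#'   `h2_obs`, `se_obs`, `h2_liab`, `se_liab`.
#' @export
#' @examples
#' observed_to_liability(0.2, 0.05, K = 0.01, P = 0.5)
observed_to_liability <- function(h2_obs, se_obs = NA_real_, K, P) {
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1)
    stop("K and P must be strictly inside (0, 1)")
  z <- dnorm(qnorm(1 - K))
  multiplier <- K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
  structure(list(K = K, P = P, z = z, multiplier = multiplier,
                 h2_obs = h2_obs, se_obs = se_obs,
                 h2_liab = h2_obs * multiplier,
                 se_liab = se_obs * multiplier),
            class = "liability_estimate")
}

#' @export
print.liability_estimate <- function(x, ...) {
  cat(sprintf("h2 (observed scale): %.4f (se %.4f)\n", x$h2_obs, x$se_obs))
  cat(sprintf("h2 (liability scale, K = %.4g, P = %.4g): %.4f (se %.4f)\n",
              x$K, x$P, x$h2_liab, x$se_liab))
  invisible(x)
}

#' Case-control heritability of liability, end to end
#'
#' Full pipeline: merge case and control cohorts on their shared SNP panel,
#' compute one GRM per chromosome, combine them, extract the top principal
#' components as ancestry covariates, fit AI-REML of affection status on
#' the combined GRM with intercept + PCs, and transform the estimate to the
#' liability scale at prevalence `K`. Relabelling which cohort is "affected"
#' (e.g. parents, siblings, or pseudo-controls versus population controls)
#' gives the heritability attributable to that group.
#'
#' @param cases,controls `cohort`s over the same SNP panel (same columns).
#' @param panel The shared `snp_panel`.
#' @param K Population prevalence (default 0.01).
#' @param k_pcs Number of ancestry principal components (default 10).
#' @param rel_cutoff Optional cross-family GRM pruning cutoff; `NULL`
#'   (default) skips pruning -- with desk-scale SNP counts the GRM noise
#'   floor (sd ~ 1/sqrt(m)) can exceed realistic cutoffs, so pruning is
#'   only meaningful for large panels.
#' @param qc Apply [snp_qc()] to the merged cohort first (default `TRUE`).
#' @param thresholds QC thresholds (see [qc_thresholds()]).
#' @return An `h2_cc` list: `estimate` (a `liability_estimate`), `fit`
#'   (the `reml_fit`), `P` (sample case proportion), `n_snps_used`,
#'   `n_individuals`, and the `pcs` used.
#' @export
estimate_h2_cc <- function(cases, controls, panel, K = 0.01, k_pcs = 10,
                           rel_cutoff = NULL, qc = TRUE,
                           thresholds = qc_thresholds()) {
  stopifnot(inherits(cases, "cohort"), inherits(controls, "cohort"))
  if (ncol(cases$genotypes) != nrow(panel) ||
      ncol(controls$genotypes) != nrow(panel))
    stop("cases and controls must share the panel's SNP columns")
  merged <- new_cohort(rbind(cases$genotypes, controls$genotypes),
                       phenotype = c(rep(1L, nrow(cases$genotypes)),
                                     rep(0L, nrow(controls$genotypes))),
                       sex = c(cases$sex, controls$sex),
                       fid = make.unique(c(cases$fid, controls$fid)),
                       iid = make.unique(c(cases$iid, controls$iid)))
  keep_snps <- seq_len(nrow(panel))
  if (qc) {
    rep_ind <- individual_qc(merged, panel, thresholds)
    rep_snp <- snp_qc(merged, panel, thresholds, individuals = rep_ind$kept)
    merged$genotypes <- merged$genotypes[rep_ind$kept, rep_snp$kept,
                                         drop = FALSE]
    merged$phenotype <- merged$phenotype[rep_ind$kept]
    merged$sex <- merged$sex[rep_ind$kept]
    merged$fid <- merged$fid[rep_ind$kept]
    merged$iid <- merged$iid[rep_ind$kept]
    keep_snps <- rep_snp$kept
  }
  sub_panel <- panel[keep_snps, , drop = FALSE]
  class(sub_panel) <- class(panel)
  chroms <- unique(sub_panel$chrom)
  grms <- lapply(chroms, function(ch)
    compute_grm(merged, sub_panel, chromosomes = ch))
  grm <- combine_grms(grms)
  if (!is.null(rel_cutoff)) {
    kept <- relatedness_prune(grm, cutoff = rel_cutoff)
    if (length(kept) < nrow(grm$A)) {
      grm$A <- grm$A[kept, kept]
      grm$fid <- grm$fid[kept]; grm$iid <- grm$iid[kept]
      merged$phenotype <- merged$phenotype[kept]
    }
  }
  y <- merged$phenotype
  pcs <- grm_pca(grm, k = k_pcs)
  Xmat <- cbind(1, pcs$vectors)
  fit <- reml_fit(y, Xmat, grm)
  P <- mean(y)
  est <- observed_to_liability(fit$h2_obs, fit$h2_obs_se, K = K, P = P)
  structure(list(estimate = est, fit = fit, P = P,
                 n_snps_used = grm$m, n_individuals = length(y), pcs = pcs),
            class = "h2_cc")
}

#' @export
print.h2_cc <- function(x, ...) {
  cat("Case-control GREML heritability (", x$n_individuals,
      " individuals, ", x$n_snps_used, " SNPs)\n", sep = "")
  print(x$estimate)
  invisible(x)
}

#' Per-chromosome heritability partition
#'
#' Fits, for each chromosome, a two-component REML (that chromosome's GRM
#' plus a rest-of-genome GRM; `mode = "single"` drops the rest component)
#' and relates the per-chromosome estimates to physical chromosome length
#' by Pearson correlation. Under a polygenic model with liability variants
#' spread at random over the genome, per-chromosome heritability should
#' increase with chromosome length.
#'
#' @param cohort Merged case-control `cohort` (phenotype 0/1).
#' @param panel The matching `snp_panel`.
#' @param K Population prevalence for the liability transform.
#' @param k_pcs Ancestry PCs used as covariates (computed from the combined
#'   GRM).
#' @param mode `"joint_rest"` (default) or `"single"`.
#' @return A `chrom_partition`: data frame with `chrom`, `length_bp`, `m`,
#'   `h2_obs`, `se_obs`, `h2_liab`, `se_liab`, plus attributes `r` and
#'   `p_value` from `cor.test` of `h2_liab` against length.
#' @export
per_chromosome_h2 <- function(cohort, panel, K = 0.01, k_pcs = 10,
                              mode = c("joint_rest", "single")) {
  mode <- match.arg(mode)
  chroms <- unique(panel$chrom)
  if (length(chroms) < 5)
    stop("need at least 5 chromosomes for a length correlation")
  y <- cohort$phenotype
  P <- mean(y)
  grms <- lapply(chroms, function(ch)
    compute_grm(cohort, panel, chromosomes = ch))
  names(grms) <- chroms
  combined <- combine_grms(grms)
  pcs <- grm_pca(combined, k = min(k_pcs, length(y) - 2))
  Xmat <- cbind(1, pcs$vectors)
  rows <- lapply(chroms, function(ch) {
    if (mode == "joint_rest" && length(chroms) > 1) {
      rest <- combine_grms(grms[setdiff(chroms, ch)])
      fit <- reml_fit(y, Xmat, list(grms[[ch]], rest))
    } else {
      fit <- reml_fit(y, Xmat, grms[[ch]])
    }
    tot <- sum(fit$varcomp)
    h2c <- fit$varcomp[1] / tot
    sec <- fit$se[1] / tot
    est <- observed_to_liability(h2c, sec, K = K, P = P)
    data.frame(chrom = ch, length_bp = unname(chromosome_lengths(ch)),
               m = grms[[ch]]$m, h2_obs = unname(h2c), se_obs = unname(sec),
               h2_liab = est$h2_liab, se_liab = est$se_liab,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ct <- cor.test(out$h2_liab, out$length_bp)
  attr(out, "r") <- unname(ct$estimate)
  attr(out, "p_value") <- ct$p.value
  class(out) <- c("chrom_partition", "data.frame")
  out
}
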