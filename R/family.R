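#' Simulate one nuclear family with Mendelian transmission
#'
#' Draws phased parental haplotypes over the effect panel's SNPs, transmits
#' one allele per SNP from each parent to each child (a fair, independent
#' pick of one of the parent's two haplotypes at every SNP), builds the
#' pseudo-control from the alleles each parent did not transmit to child 1,
#' and assigns every member (and the pseudo-control) a liability phenotype.
#'
#' This is the reference, fully bookkept implementation used for unit-scale
#' work; [ascertain()] runs the same generative process in compiled code for
#' rejection sampling at scale.
#'
#' @param effects An `effect_panel` (see [draw_effect_panel()]).
#' @param n_children 1 (trio) or 2 (quad).
#' @param mating `"random"` (parents drawn independently from the allele
#'   frequencies) or `"assortative"` (maternal genotype assigned by the
#'   fair-coin rule, see [assortative_mother()]).
#' @param assort_coin For assortative mating, whether the fair coin is tossed
#'   independently at every SNP (`"per_snp"`, the default) or once per family
#'   (`"per_family"`). See [assortative_mother()].
#' @param tau Liability threshold; defaults to 1 percent prevalence.
#' @param seed Optional integer seed.
#' @return A `sim_family`: list with phased parental haplotypes (`father`,
#'   `mother`: 2 x n 0/1 matrices), `children` (each with `genotype` and the
#'   transmitted haplotype indices `pat_hap`, `mat_hap` per SNP),
#'   `pseudo_control` (genotype vector), and `members`, a data frame of
#'   `G`, `e`, `y`, `affected` for father, mother, each child and the
#'   pseudo-control.
#' @export
simulate_family <- function(effects, n_children = 2,
                            mating = c("random", "assortative"),
                            assort_coin = c("per_snp", "per_family"),
                            tau = liability_threshold(0.01), seed = NULL) {
  stopifnot(inherits(effects, "effect_panel"))
  mating <- match.arg(mating)
  assort_coin <- match.arg(assort_coin)
  if (!n_children %in% 1:2) stop("n_children must be 1 or 2")
  .seed_if_given(seed)
  n <- effects$n
  p <- effects$p
  father <- rbind(rbinom(n, 1, p), rbinom(n, 1, p))
  mother <- if (mating == "random") {
    rbind(rbinom(n, 1, p), rbinom(n, 1, p))
  } else {
    assortative_mother(father, effects, coin = assort_coin)
  }
  children <- lapply(seq_len(n_children), function(k) {
    pat_hap <- sample(1:2, n, replace = TRUE)
    mat_hap <- sample(1:2, n, replace = TRUE)
    geno <- father[cbind(pat_hap, seq_len(n))] + mother[cbind(mat_hap, seq_len(n))]
    list(genotype = geno, pat_hap = pat_hap, mat_hap = mat_hap)
  })
  fam <- structure(list(father = father, mother = mother, children = children,
                        effects = effects, tau = tau, mating = mating),
                   class = "sim_family")
  fam$pseudo_control <- make_pseudo_control(fam, child_index = 1)
  genos <- rbind(father[1, ] + father[2, ], mother[1, ] + mother[2, ],
                 do.call(rbind, lapply(children, `[[`, "genotype")),
                 fam$pseudo_control)
  G <- genetic_value(genos, effects)
  members <- assign_phenotype(G, effects$h2, tau)
  rownames(members) <- c("father", "mother",
                         paste0("child", seq_len(n_children)), "pseudo_control")
  fam$members <- members
  fam
}

#' Assortative maternal genotype by a fair coin
#'
#' Implements the coin-toss assortative-mating rule: the father's phased
#' genotype is drawn first; the mother's genotype is then either drawn at
#' random from the allele frequencies (heads) or set equal to the father's
#' (tails). With `coin = "per_snp"` (the default) the fair coin is tossed
#' independently at every liability SNP, so on average half the mother's
#' genotype copies the father's; with `coin = "per_family"` one toss decides
#' the whole genotype. Both readings give a parental genetic-value
#' correlation of 1/2, but they differ in the liability variance of the
#' offspring; the per-SNP rule is the package default because it reproduces
#' the expected pseudo-control heritabilities under ascertainment (see the
#' methods vignette).
#'
#' @param father 2 x n 0/1 matrix of phased paternal haplotypes.
#' @param effects An `effect_panel` supplying the allele frequencies.
#' @param coin `"per_snp"` or `"per_family"`.
#' @param seed Optional integer seed.
#' @return 2 x n 0/1 matrix of phased maternal haplotypes.
#' @export
assortative_mother <- function(father, effects,
                               coin = c("per_snp", "per_family"),
                               seed = NULL) {
  stopifnot(inherits(effects, "effect_panel"))
  coin <- match.arg(coin)
  .seed_if_given(seed)
  n <- ncol(father)
  random_part <- rbind(rbinom(n, 1, effects$p), rbinom(n, 1, effects$p))
  if (coin == "per_family") {
    if (runif(1) < 0.5) father else random_part
  } else {
    tails <- runif(n) < 0.5
    mother <- random_part
    mother[, tails] <- father[, tails]
    mother
  }
}

#' Pseudo-control genotype from untransmitted alleles
#'
#' For each SNP, the pseudo-control receives the paternal allele not
#' transmitted to the given child plus the maternal allele not transmitted
#' to that child. Equivalently, its allele count is
#' `father + mother - child`, so child plus pseudo-control equals the
#' parental sum at every SNP.
#'
#' @param family A `sim_family`.
#' @param child_index Which child the pseudo-control complements (default 1,
#'   the proband).
#' @return Integer genotype vector of allele counts.
#' @export
make_pseudo_control <- function(family, child_index = 1) {
  stopifnot(inherits(family, "sim_family"))
  if (child_index > length(family$children))
    stop("family has no child ", child_index)
  ch <- family$children[[child_index]]
  if (is.null(ch$pat_hap) || is.null(ch$mat_hap))
    stop("transmission records missing for child ", child_index)
  n <- length(ch$genotype)
  idx <- seq_len(n)
  family$father[cbind(3L - ch$pat_hap, idx)] +
    family$mother[cbind(3L - ch$mat_hap, idx)]
}
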