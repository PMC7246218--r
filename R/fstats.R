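#' Weir-Cockerham F-statistics
#'
#' Variance components a (among populations), b (among individuals within
#' populations) and c (within individuals) are computed per locus and
#' allele following the 1984 moment estimators and combined as ratios of
#' sums over loci and alleles ("weighted mean" weighting):
#' `F_ST = sum(a) / sum(a + b + c)` and `F_IS = 1 - sum(c) / sum(b + c)`.
#' Missing genotypes are excluded locus-wise, with per-locus sample sizes.
#' With a single population only the within components are estimable and
#' `f_st` is `NA`.
#'
#' @param g a [genotype_matrix()]
#' @param pops populations to include (default: all)
#' @return an `fstat_result`: list with `f_st`, `f_is`, `f_it` and a
#'   per-locus component table
#' @export
wc_f_statistics <- function(g, pops = pop_names(g)) {
  g <- subset_populations(g, pops)
  r_tot <- nlevels(g$pop)
  # every population must be typed (>= 2 individuals) at some locus
  for (p in levels(g$pop)) {
    rows <- g$pop == p
    typed <- colSums(!is.na(g$allele1[rows, , drop = FALSE]))
    if (max(typed) < 2)
      stop("population ", p, " has fewer than 2 typed individuals at every locus")
  }
  per_locus <- data.frame(locus = g$loci, a = 0, b = 0, c = 0)
  for (l in seq_len(n_loci(g))) {
    comp <- wc_components_locus(g, l)
    per_locus$a[l] <- comp["a"]; per_locus$b[l] <- comp["b"]; per_locus$c[l] <- comp["c"]
  }
  A <- sum(per_locus$a, na.rm = TRUE)
  B <- sum(per_locus$b, na.rm = TRUE)
  C <- sum(per_locus$c, na.rm = TRUE)
  structure(list(
    f_st = if (r_tot >= 2) A / (A + B + C) else NA_real_,
    f_is = 1 - C / (B + C),
    f_it = if (r_tot >= 2) 1 - C / (A + B + C) else NA_real_,
    per_locus = per_locus), class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F-statistics: F_ST = %.4f, F_IS = %.4f\n",
              x$f_st, x$f_is))
  invisible(x)
}

## Sum of the 1984 variance components over alleles for one locus.
## Populations with < 2 typed individuals at this locus are dropped; the
## among-population component requires >= 2 remaining populations (else NA).
wc_components_locus <- function(g, l) {
  pops <- levels(g$pop)
  a1 <- g$allele1[, l]; a2 <- g$allele2[, l]
  keep_pop <- character(0)
  for (p in pops) if (sum(!is.na(a1[g$pop == p])) >= 2) keep_pop <- c(keep_pop, p)
  single <- length(pops) == 1
  if (!single && length(keep_pop) < 2) return(c(a = NA, b = NA, c = NA))
  if (single && length(keep_pop) < 1) return(c(a = NA, b = NA, c = NA))
  rows <- !is.na(a1) & g$pop %in% keep_pop
  a1 <- a1[rows]; a2 <- a2[rows]; popf <- factor(as.character(g$pop[rows]), levels = keep_pop)
  alleles <- sort(unique(c(a1, a2)))
  r <- length(keep_pop)
  n_i <- as.vector(table(popf))
  nbar <- mean(n_i)
  sum_a <- 0; sum_b <- 0; sum_c <- 0
  if (r >= 2) {
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  } else nc <- nbar
  for (al in alleles) {
    cnt1 <- (a1 == al) + (a2 == al)       # allele dose per individual
    p_i <- tapply(cnt1, popf, sum) / (2 * n_i)
    het <- (a1 == al) != (a2 == al)       # heterozygous FOR this allele
    h_i <- tapply(het, popf, sum) / n_i
    pbar <- sum(n_i * p_i) / (r * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    if (r >= 2) {
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                          (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    } else {
      a <- 0
      b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (2 * nbar - 1) / (4 * nbar) * hbar)
    }
    cc <- hbar / 2
    sum_a <- sum_a + a; sum_b <- sum_b + b; sum_c <- sum_c + cc
  }
  c(a = sum_a, b = sum_b, c = sum_c)
}

#' Pairwise Weir-Cockerham F_ST matrix
#'
#' [wc_f_statistics()] applied to every unordered population pair;
#' diagonal 0.
#'
#' @param g a [genotype_matrix()]
#' @return symmetric matrix of pairwise F_ST values
#' @export
pairwise_fst_matrix <- function(g) {
  pops <- pop_names(g)
  if (length(pops) < 2) stop("need >= 2 populations")
  P <- length(pops)
  m <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    fst <- wc_f_statistics(g, c(pops[i], pops[j]))$f_st
    m[i, j] <- m[j, i] <- fst
  }
  m
}

#' Genic differentiation test between two populations
#'
#' G statistic on the per-locus allele-count contingency tables, summed
#' over loci; the null distribution is obtained by permuting whole
#' individuals (genotypes intact, i.e. without assuming random mating)
#' between the two populations.  The p-value uses the add-one rule
#' `(1 + b) / (N + 1)`.
#'
#' @param g a [genotype_matrix()]
#' @param pair character vector of two population labels
#' @param randomizations number of permutations
#' @param seed integer seed
#' @return p-value with attribute `G` (observed statistic)
#' @export
genic_differentiation_test <- function(g, pair, randomizations = 10000, seed = 1) {
  stopifnot(length(pair) == 2)
  gs <- subset_populations(g, pair)
  is2 <- as.character(gs$pop) == pair[2]
  L <- n_loci(gs)
  gstat <- function(membership2) {
    total <- 0; used <- 0L
    for (l in seq_len(L)) {
      a1 <- gs$allele1[, l]; a2 <- gs$allele2[, l]
      keep <- !is.na(a1)
      if (!any(keep)) next
      al <- c(a1[keep], a2[keep])
      grp <- rep(membership2[keep], 2)
      tab <- table(grp, al)
      if (nrow(tab) < 2 || ncol(tab) < 2) next
      e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      o <- tab[tab > 0]; ee <- e[tab > 0]
      total <- total + 2 * sum(o * log(o / ee))
      used <- used + 1L
    }
    if (used == 0L) stop("zero usable loci for the genic differentiation test")
    total
  }
  g_obs <- gstat(is2)
  with_seed(derive_seed(seed, "gtest"), {
    n <- length(is2)
    b <- 0L
    for (r in seq_len(randomizations)) {
      perm <- is2[sample.int(n)]
      if (gstat(perm) >= g_obs - 1e-12) b <- b + 1L
    }
    structure((1 + b) / (randomizations + 1), G = g_obs)
  })
}
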