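#' Simulation scenario for synthetic multi-population microsatellite data
#'
#' Describes a stated world: population allele frequencies drift away from a
#' common ancestral pool under the Balding-Nichols model (Dirichlet drift
#' with parameter `theta`, interpretable as the expected single-population
#' F_ST), optionally in two levels (ancestral -> group profile -> population)
#' so that nested breed-group structure can be emulated.  Admixture acts at
#' the frequency level: an admixed population's frequency vector is a convex
#' combination of source populations' vectors.  Within populations,
#' genotypes deviate from Hardy-Weinberg proportions by a per-population
#' inbreeding coefficient F_IS.
#'
#' @param n_pops number of populations.
#' @param n_per_pop diploid individuals per population (default 25, the
#'   standard breed-survey sample size).
#' @param n_loci number of microsatellite loci (default 15).
#' @param alleles_per_locus number of possible alleles per locus (default 8,
#'   typical microsatellite allelic richness).
#' @param ancestral_concentration symmetric Dirichlet parameter for the
#'   ancestral frequencies (default 1, uninformative).
#' @param theta per-population drift parameter in `[0, 1)`; scalar recycled.
#' @param admixture `n_pops x n_pops` row-stochastic matrix of mixing
#'   weights over source populations; default identity (no admixture).
#' @param fis per-population inbreeding coefficient in `[-1, 1]`; scalar
#'   recycled.
#' @param missing_rate probability that a genotype is missing.
#' @param group optional integer/character group label per population; when
#'   given, `theta_group` controls ancestral -> group drift and `theta`
#'   the group -> population drift.
#' @param theta_group per-group drift parameter (same order as
#'   `sort(unique(group))`); ignored when `group` is `NULL`.
#' @param seed integer seed; all sampling operations derive their streams
#'   from it.
#' @return a `sim_scenario` list.
#' @export
sim_scenario <- function(n_pops, n_per_pop = 25L, n_loci = 15L,
                         alleles_per_locus = 8L,
                         ancestral_concentration = 1,
                         theta = 0.1, admixture = NULL, fis = 0,
                         missing_rate = 0, group = NULL, theta_group = NULL,
                         seed = 1L) {
  n_pops <- as.integer(n_pops)
  if (n_pops < 1L) stop("n_pops must be >= 1")
  if (n_per_pop < 1L) stop("n_per_pop must be >= 1")
  theta <- rep_len(theta, n_pops)
  if (any(theta < 0) || any(theta >= 1))
    stop("invalid parameter: theta must lie in [0, 1)")
  fis <- rep_len(fis, n_pops)
  if (any(abs(fis) > 1)) stop("fis must lie in [-1, 1]")
  if (is.null(admixture)) admixture <- diag(n_pops)
  admixture <- as.matrix(admixture)
  if (!all(dim(admixture) == n_pops)) stop("admixture must be n_pops x n_pops")
  if (any(admixture < 0) || any(abs(rowSums(admixture) - 1) > 1e-9))
    stop("admixture rows must be non-negative and sum to 1")
  if (!is.null(group)) {
    if (length(group) != n_pops) stop("group must have one label per population")
    glev <- sort(unique(group))
    if (is.null(theta_group)) theta_group <- rep(0, length(glev))
    theta_group <- rep_len(theta_group, length(glev))
    if (any(theta_group < 0) || any(theta_group >= 1))
      stop("invalid parameter: theta_group must lie in [0, 1)")
  }
  structure(list(n_pops = n_pops, n_per_pop = as.integer(n_per_pop),
                 n_loci = as.integer(n_loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 ancestral_concentration = ancestral_concentration,
                 theta = theta, admixture = admixture, fis = fis,
                 missing_rate = missing_rate, group = group,
                 theta_group = theta_group, seed = as.integer(seed)),
            class = "sim_scenario")
}

## One Balding-Nichols draw around a base vector: Dirichlet(base*(1-th)/th).
bn_draw <- function(base, th) {
  if (th == 0) return(base)
  rdirichlet1(base * (1 - th) / th)
}

#' Sample per-population allele frequencies for a scenario
#'
#' Ancestral vector per locus ~ symmetric Dirichlet(ancestral_concentration);
#' each population's vector is a Balding-Nichols draw around the ancestral
#' (or around its group profile under a two-level scenario); admixed
#' populations receive the admixture-weighted mixture of their sources'
#' vectors.
#'
#' @param s a [sim_scenario()]
#' @return an `allele_freq_table`: array `[n_pops, n_loci, n_alleles]` with
#'   attribute `ancestral` (loci x alleles matrix).
#' @export
sample_frequencies <- function(s) {
  stopifnot(inherits(s, "sim_scenario"))
  with_seed(derive_seed(s$seed, "frequencies"), {
    A <- s$alleles_per_locus; L <- s$n_loci; P <- s$n_pops
    anc <- rdirichlet(L, rep(s$ancestral_concentration, A))
    freq <- array(NA_real_, dim = c(P, L, A))
    if (!is.null(s$group)) {
      glev <- sort(unique(s$group))
      gprof <- array(NA_real_, dim = c(length(glev), L, A))
      for (gi in seq_along(glev)) for (l in seq_len(L))
        gprof[gi, l, ] <- bn_draw(anc[l, ], s$theta_group[gi])
      for (p in seq_len(P)) {
        gi <- match(s$group[p], glev)
        for (l in seq_len(L)) freq[p, l, ] <- bn_draw(gprof[gi, l, ], s$theta[p])
      }
    } else {
      for (p in seq_len(P)) for (l in seq_len(L))
        freq[p, l, ] <- bn_draw(anc[l, ], s$theta[p])
    }
    # frequency-level admixture: convex combination of source vectors
    mixed <- freq
    for (l in seq_len(L)) mixed[, l, ] <- s$admixture %*% freq[, l, ]
    structure(mixed, ancestral = anc, class = "allele_freq_table")
  })
}

## Genotype distribution at one locus for inbreeding coefficient f:
## P(het ab) = 2 p_a p_b (1 - f); P(aa) = p_a^2 + f p_a (1 - p_a).
## For f >= 0 sampled by the duplication construction; for f < 0 by the
## explicit genotype distribution (error if any probability is negative).
sample_locus_genotypes <- function(p, n, f) {
  A <- length(p)
  if (f >= 0) {
    dup <- stats::runif(n) < f
    a1 <- sample.int(A, n, replace = TRUE, prob = p)
    a2 <- a1
    ndup <- !dup
    if (any(ndup)) a2[ndup] <- sample.int(A, sum(ndup), replace = TRUE, prob = p)
    cbind(a1, a2)
  } else {
    hom <- p^2 + f * p * (1 - p)
    if (any(hom < -1e-12))
      stop("invalid parameter: negative genotype probability at F_IS = ", f)
    hom <- pmax(hom, 0)
    idx_het <- which(upper.tri(matrix(0, A, A)), arr.ind = TRUE)
    phet <- 2 * p[idx_het[, 1]] * p[idx_het[, 2]] * (1 - f)
    probs <- c(hom, phet)
    draw <- sample.int(length(probs), n, replace = TRUE, prob = probs)
    a1 <- integer(n); a2 <- integer(n)
    ishom <- draw <= A
    a1[ishom] <- a2[ishom] <- draw[ishom]
    j <- draw[!ishom] - A
    a1[!ishom] <- idx_het[j, 1]; a2[!ishom] <- idx_het[j, 2]
    cbind(a1, a2)
  }
}

#' Sample diploid genotypes from an allele-frequency table
#'
#' @param freqs an `allele_freq_table` from [sample_frequencies()]
#' @param s the [sim_scenario()] that produced it
#' @return a [genotype_matrix()] with populations `pop1..popP`
#' @export
sample_genotypes <- function(freqs, s) {
  stopifnot(inherits(s, "sim_scenario"))
  with_seed(derive_seed(s$seed, "genotypes"), {
    P <- s$n_pops; L <- s$n_loci; n <- s$n_per_pop
    N <- P * n
    a1 <- matrix(NA_integer_, N, L); a2 <- matrix(NA_integer_, N, L)
    for (p in seq_len(P)) {
      rows <- ((p - 1L) * n + 1L):(p * n)
      for (l in seq_len(L)) {
        gl <- sample_locus_genotypes(freqs[p, l, ], n, s$fis[p])
        a1[rows, l] <- gl[, 1]; a2[rows, l] <- gl[, 2]
      }
    }
    if (s$missing_rate > 0) {
      miss <- matrix(stats::runif(N * L) < s$missing_rate, N, L)
      a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    }
    genotype_matrix(a1, a2, pop = rep(paste0("pop", seq_len(P)), each = n))
  })
}

#' Sample genotypes for individuals with individual-level two-source ancestry
#'
#' Fixture builder for admixture-recovery checks: each individual `i` has an
#' ancestry proportion `q[i, ]` over the source populations of `freqs`, and
#' every allele copy independently picks its source population according to
#' `q[i, ]` before drawing from that source's frequency vector.
#'
#' @param freqs an `allele_freq_table` over the source populations
#' @param q individuals x sources ancestry matrix (rows sum to 1)
#' @param seed integer seed
#' @return a [genotype_matrix()] with a single population label `"mix"`
#' @export
sample_admixed_individuals <- function(freqs, q, seed = 1L) {
  q <- as.matrix(q)
  if (any(abs(rowSums(q) - 1) > 1e-9)) stop("q rows must sum to 1")
  P <- dim(freqs)[1]; L <- dim(freqs)[2]; A <- dim(freqs)[3]
  if (ncol(q) != P) stop("q must have one column per source population")
  n <- nrow(q)
  with_seed(derive_seed(seed, "admixed_individuals"), {
    a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
    for (i in seq_len(n)) {
      z1 <- sample.int(P, L, replace = TRUE, prob = q[i, ])
      z2 <- sample.int(P, L, replace = TRUE, prob = q[i, ])
      for (l in seq_len(L)) {
        a1[i, l] <- sample.int(A, 1L, prob = freqs[z1[l], l, ])
        a2[i, l] <- sample.int(A, 1L, prob = freqs[z2[l], l, ])
      }
    }
    genotype_matrix(a1, a2, pop = rep("mix", n))
  })
}

#' Built-in simulation presets
#'
#' * `simple_k5`: five islands, `theta = 0.1`, no admixture — the cleanly
#'   separable reference world.
#' * `complex_breeds`: 30 populations in 5 breed groups with between-group
#'   divergence, small within-group drift (including one near-identical pair
#'   and one strongly drifted population so pairwise F_ST spans roughly
#'   0.004-0.45), and 13/30 populations admixed across groups (primary
#'   source weight 0.6).
#' * `outgroup`: `complex_breeds` plus one strongly diverged outgroup
#'   population (`theta ~ 0.35`).
#'
#' @param name preset name
#' @param seed integer seed (default 20260918)
#' @return `list(scenario = sim_scenario, genotypes = genotype_matrix)`
#' @export
make_preset <- function(name = c("simple_k5", "complex_breeds", "outgroup"),
                        seed = 20260918L) {
  name <- match.arg(name)
  s <- switch(name,
    simple_k5 = sim_scenario(n_pops = 5, theta = 0.1, fis = 0,
                             missing_rate = 0.02, seed = derive_seed(seed, name)),
    complex_breeds = complex_breeds_scenario(derive_seed(seed, name), outgroup = FALSE),
    outgroup = complex_breeds_scenario(derive_seed(seed, name), outgroup = TRUE))
  freqs <- sample_frequencies(s)
  g <- sample_genotypes(freqs, s)
  list(scenario = s, genotypes = g, frequencies = freqs)
}

complex_breeds_scenario <- function(seed, outgroup = FALSE) {
  n_groups <- 5L; per_group <- 6L
  P <- n_groups * per_group
  group <- rep(seq_len(n_groups), each = per_group)
  theta_group <- c(0.05, 0.10, 0.12, 0.15, 0.20)
  # within-group drift 0.02-0.05; one near-identical pair (pairwise ~ 0.004)
  # and one strongly drifted population (pairwise up to ~ 0.45)
  theta <- rep(c(0.02, 0.03, 0.04, 0.05, 0.025, 0.035), n_groups)
  theta[1:2] <- 0.004
  theta[P] <- 0.75
  # F_IS kept non-negative: with 8-allele Dirichlet frequencies, rare alleles
  # (p < f/(1+f)) make the negative-f genotype distribution infeasible
  fis <- rep(c(0, 0.02, 0.05, 0.1, 0.15, 0.03), n_groups)
  # 13 admixed populations: weight 0.6 on themselves, 0.4 on a population in
  # another group (construction guarantee: > 40% of populations admixed)
  adm <- diag(P)
  admixed <- seq(3, P - 2, by = 2)[1:13]
  for (j in seq_along(admixed)) {
    p <- admixed[j]
    donor_group <- (group[p] + j - 1) %% n_groups + 1
    if (donor_group == group[p]) donor_group <- donor_group %% n_groups + 1
    donor <- which(group == donor_group)[1 + (j %% per_group)]
    adm[p, p] <- 0.6; adm[p, donor] <- 0.4
  }
  if (outgroup) {
    P2 <- P + 1L
    adm2 <- diag(P2); adm2[1:P, 1:P] <- adm
    s <- sim_scenario(n_pops = P2, theta = c(theta, 0.35), fis = c(fis, 0),
                      admixture = adm2, missing_rate = 0.02,
                      group = c(group, n_groups + 1L),
                      theta_group = c(theta_group, 0), seed = seed)
  } else {
    s <- sim_scenario(n_pops = P, theta = theta, fis = fis, admixture = adm,
                      missing_rate = 0.02, group = group,
                      theta_group = theta_group, seed = seed)
  }
  s
}
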