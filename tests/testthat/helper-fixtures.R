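# Fixture builders shared across test files.  All randomness is seeded.

# small random genotype matrix with arbitrary allele codes
random_genotypes <- function(n = 12, L = 4, n_pops = 2, codes = c(95, 101, 120, 250),
                             missing_rate = 0.1, seed = 1) {
  withr::with_seed(seed, {
    a1 <- matrix(sample(codes, n * L, TRUE), n, L)
    a2 <- matrix(sample(codes, n * L, TRUE), n, L)
    miss <- matrix(runif(n * L) < missing_rate, n, L)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    sizes <- diff(floor(seq(0, n, length.out = n_pops + 1)))
    genotype_matrix(a1, a2, pop = rep(paste0("pop", seq_len(n_pops)), sizes))
  })
}

# two populations fixed for different alleles at every locus
fixed_two_pop <- function(n_per = 20, L = 8) {
  a <- matrix(c(rep(1L, n_per), rep(2L, n_per)), 2 * n_per, L)
  genotype_matrix(a, a, pop = rep(c("A", "B"), each = n_per))
}

# genotype matrix from explicit genotype count vectors (one locus, one pop):
# counts named like c(aa = 3, ab = 5, bb = 2) using allele codes 1, 2
diallelic_counts <- function(n11, n12, n22) {
  a1 <- c(rep(1L, n11), rep(1L, n12), rep(2L, n22))
  a2 <- c(rep(1L, n11), rep(2L, n12), rep(2L, n22))
  genotype_matrix(cbind(a1), cbind(a2), pop = rep("A", n11 + n12 + n22))
}

# a kscan built from given ln P values (named list "K" -> replicate vector);
# Q matrices are placeholders unless q_by_k supplies them
fake_kscan <- function(lnp_by_k, n_ind = 2, q_by_k = NULL) {
  grid <- sort(as.integer(names(lnp_by_k)))
  runs <- lapply(as.character(grid), function(kc) {
    k <- as.integer(kc)
    lapply(seq_along(lnp_by_k[[kc]]), function(i) {
      q <- if (is.null(q_by_k)) matrix(1 / k, n_ind, k) else q_by_k[[kc]][[i]]
      msatclust:::replicate_run(k, lnp_by_k[[kc]][i], q)
    })
  })
  names(runs) <- as.character(grid)
  msatclust:::new_kscan(grid, runs)
}

# vector with exact mean and sd (for constructing ln P replicates)
exact_moments <- function(mean, sd, n = 5, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    x <- (x - mean(x)) / stats::sd(x)
    mean + sd * x
  })
}

# replicate_run with a given membership matrix
rep_run <- function(k, lnp, q) msatclust:::replicate_run(k, lnp, q)

# plateau table from named plateau lengths, e.g. c(`2` = 50, `3` = 2, `4` = 1)
plateaus <- function(v) {
  structure(data.frame(k = as.integer(names(v)), plateau = as.integer(v),
                       plateau_llod = 0),
            class = c("plateau_table", "data.frame"))
}
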