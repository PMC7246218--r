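# --- Hardy-Weinberg exact tests -------------------------------------------

# independent oracle: estimate the probability-ordering exact p by direct
# i.i.d. sampling of genotype arrays (random pairing of the allele copies)
hwe_p_by_pairing <- function(n11, n12, n22, nsim = 50000, seed = 1) {
  alleles <- c(rep(1L, 2 * n11 + n12), rep(2L, 2 * n22 + n12))
  n <- n11 + n12 + n22
  logw <- function(h) {
    a <- (2 * n11 + n12 - h) / 2; b <- (2 * n22 + n12 - h) / 2
    h * log(2) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1)
  }
  obs <- logw(n12)
  withr::with_seed(seed, {
    hits <- 0
    for (i in seq_len(nsim)) {
      perm <- sample(alleles)
      h <- sum(perm[seq(1, 2 * n, 2)] != perm[seq(2, 2 * n, 2)])
      if (logw(h) <= obs + 1e-9) hits <- hits + 1
    }
    hits / nsim
  })
}

test_that("diallelic enumeration matches the random-pairing oracle", {
  cases <- list(c(3, 5, 2), c(8, 2, 6), c(1, 9, 1), c(6, 0, 4))
  for (cs in cases) {
    g <- diallelic_counts(cs[1], cs[2], cs[3])
    p_enum <- as.numeric(hwe_exact_test(g, "A", 1, method = "enumeration"))
    p_sim <- hwe_p_by_pairing(cs[1], cs[2], cs[3], nsim = 20000,
                              seed = sum(cs))
    se <- sqrt(p_sim * (1 - p_sim) / 20000)
    expect_lt(abs(p_enum - p_sim), max(4 * se, 0.01))
  }
})

test_that("Markov-chain estimate agrees with enumeration within 3 SE", {
  g <- diallelic_counts(8, 2, 6)   # heterozygote deficit
  p_enum <- as.numeric(hwe_exact_test(g, "A", 1, method = "enumeration"))
  p_mc <- hwe_exact_test(g, "A", 1, method = "mc",
                         mc = list(dememorization = 2000, batches = 40,
                                   iterations_per_batch = 1000, seed = 6))
  expect_lt(abs(as.numeric(p_mc) - p_enum),
            max(3 * attr(p_mc, "se"), 0.02))
})

test_that("duplicating every individual sharpens a fixed disequilibrium", {
  p1 <- as.numeric(hwe_exact_test(diallelic_counts(8, 2, 6), "A", 1,
                                  method = "enumeration"))
  p2 <- as.numeric(hwe_exact_test(diallelic_counts(16, 4, 12), "A", 1,
                                  method = "enumeration"))
  expect_lte(p2, p1)
})

test_that("degenerate and error cases of the HWE test", {
  g <- genotype_matrix(cbind(rep(1L, 6)), cbind(rep(1L, 6)), pop = rep("A", 6))
  p <- hwe_exact_test(g, "A", 1)
  expect_equal(as.numeric(p), 1)
  expect_true(attr(p, "degenerate"))
  g2 <- genotype_matrix(cbind(c(NA, NA)), cbind(c(NA, NA)), pop = c("A", "A"))
  expect_error(hwe_exact_test(g2, "A", 1), "all genotypes missing")
})

# --- combining and correcting p-values ------------------------------------

test_that("Fisher combination and Holm adjustment", {
  expect_equal(combine_and_correct(rep(1, 5), "fisher_combined"), 1)
  expect_equal(combine_and_correct(rep(1, 5), "holm"), rep(1, 5))
  expect_equal(combine_and_correct(0.37, "fisher_combined"), 0.37,
               tolerance = 1e-12)
  expect_equal(combine_and_correct(0.37, "holm"), 0.37)
  # chi2 = -2(ln 0.1 + ln 0.2) = 7.8240, df 4 -> p ~ 0.0982
  expect_equal(combine_and_correct(c(0.1, 0.2), "fisher_combined"),
               0.09824, tolerance = 1e-4)
  # Holm equals the textbook step-down construction
  p <- c(0.01, 0.04, 0.03, 0.5)
  manual <- pmin(1, cummax(sort(p) * (4:1)))[order(order(p))]
  expect_equal(combine_and_correct(p, "holm"), manual)
  expect_error(combine_and_correct(numeric(0)), "empty")
  expect_error(combine_and_correct(c(0.5, 0)), "floor")
})

# --- Weir-Cockerham F-statistics ------------------------------------------


test_that("variance components match the nested-ANOVA oracle", {
  # toy table and random multi-locus data, with and without missingness
  g_toy <- genotype_matrix(
    cbind(c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 1L)),
    cbind(c(1L, 2L, 1L, 2L, 2L, 1L, 2L, 1L)),
    pop = rep(c("A", "B"), each = 4))
  for (g in list(g_toy,
                 random_genotypes(n = 24, L = 3, n_pops = 3, seed = 4),
                 random_genotypes(n = 30, L = 4, n_pops = 2,
                                  missing_rate = 0.2, seed = 9))) {
    fit <- wc_f_statistics(g)
    oracle <- wc_anova_oracle(g)
    expect_equal(fit$f_st, unname(oracle$f_st), tolerance = 1e-10)
    expect_equal(fit$f_is, unname(oracle$f_is), tolerance = 1e-10)
  }
})

test_that("F_ST limiting cases", {
  g <- fixed_two_pop()
  expect_equal(wc_f_statistics(g)$f_st, 1)
  # population against an exact copy of itself
  gg <- random_genotypes(n = 10, L = 5, n_pops = 1, missing_rate = 0, seed = 2)
  gcopy <- genotype_matrix(rbind(gg$allele1, gg$allele1),
                           rbind(gg$allele2, gg$allele2),
                           pop = rep(c("A", "B"), each = 10))
  expect_lte(wc_f_statistics(gcopy)$f_st, 1e-9)
})

test_that("F_ST is equivariant under allele relabeling and population order", {
  g <- random_genotypes(n = 30, L = 4, n_pops = 3, seed = 11)
  base <- wc_f_statistics(g)$f_st
  # relabel alleles with an arbitrary strictly monotone-free mapping
  remap <- c(`95` = 7L, `101` = 300L, `120` = 2L, `250` = 41L)
  relab <- function(m) matrix(remap[as.character(m)], nrow(m), ncol(m))
  g2 <- genotype_matrix(relab(g$allele1), relab(g$allele2),
                        pop = as.character(g$pop))
  expect_equal(wc_f_statistics(g2)$f_st, base, tolerance = 1e-12)
  # reorder populations
  ord <- order(as.integer(g$pop), decreasing = TRUE)
  g3 <- subset_individuals(g, ord)
  expect_equal(wc_f_statistics(g3)$f_st, base, tolerance = 1e-12)
})

test_that("undertyped populations are reported by name", {
  a1 <- cbind(c(1L, 2L, 1L, NA, NA, NA))
  g <- genotype_matrix(a1, a1, pop = rep(c("ok", "bad"), each = 3))
  expect_error(wc_f_statistics(g), "bad")
})

test_that("pairwise F_ST matrix is symmetric, zero-diagonal and near zero for clones", {
  s <- sim_scenario(n_pops = 3, n_per_pop = 60, theta = 0, seed = 12)
  g <- sample_genotypes(sample_frequencies(s), s)
  m <- pairwise_fst_matrix(g)
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(0, 3), ignore_attr = TRUE)
  expect_true(all(abs(m[upper.tri(m)]) < 0.02))
})

# --- genic differentiation ------------------------------------------------

test_that("G statistic matches the hand formula on a 2x2 table", {
  # pop A: alleles 1,1,1,2 ; pop B: 1,2,2,2 (one locus, two individuals each)
  g <- genotype_matrix(cbind(c(1L, 1L, 1L, 2L)), cbind(c(1L, 2L, 2L, 2L)),
                       pop = c("A", "A", "B", "B"))
  p <- genic_differentiation_test(g, c("A", "B"), randomizations = 200, seed = 1)
  o <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  expect_equal(attr(p, "G"), 2 * sum(o * log(o / e)), tolerance = 1e-12)
})

test_that("genic test hits the permutation floor on fixed populations", {
  g <- fixed_two_pop(n_per = 25)
  p <- genic_differentiation_test(g, c("A", "B"), randomizations = 99, seed = 2)
  expect_equal(as.numeric(p), 1 / 100)
  # identical populations give large p
  s <- sim_scenario(n_pops = 2, n_per_pop = 40, theta = 0, seed = 3)
  gg <- sample_genotypes(sample_frequencies(s), s)
  p2 <- genic_differentiation_test(gg, c("pop1", "pop2"),
                                   randomizations = 199, seed = 4)
  expect_gt(as.numeric(p2), 0.05)
})

# --- PCoA -----------------------------------------------------------------

test_that("PCoA agrees with the ape oracle and reconstructs line geometry", {
  skip_if_not_installed("ape")
  pts <- c(0, 1, 3, 7)
  d <- as.matrix(dist(pts))
  res <- pcoa(d)
  expect_equal(res$explained[1], 1, tolerance = 1e-9)
  expect_equal(as.matrix(dist(res$coordinates[, 1])), d,
               ignore_attr = TRUE, tolerance = 1e-9)
  # random distance matrix vs ape::pcoa
  set.seed(5)
  x <- matrix(rnorm(24), 8, 3)
  d2 <- as.matrix(dist(x))
  res2 <- pcoa(d2)
  oracle <- ape::pcoa(d2)
  expect_equal(res2$explained,
               oracle$values$Eigenvalues[oracle$values$Eigenvalues > 1e-9] /
                 sum(oracle$values$Eigenvalues[oracle$values$Eigenvalues > 1e-9]),
               tolerance = 1e-8)
  expect_equal(abs(res2$coordinates[, 1]), abs(oracle$vectors[, 1]),
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("PCoA contracts: centering, degenerate input, validation", {
  d0 <- matrix(0, 4, 4)
  expect_true(all(pcoa(d0)$coordinates == 0))
  d <- as.matrix(dist(matrix(rnorm(10), 5, 2)))
  res <- pcoa(d)
  expect_true(all(abs(colMeans(res$coordinates)) < 1e-9))
  expect_equal(sum(res$explained), 1, tolerance = 1e-12)
  expect_true(all(diff(res$explained) <= 1e-12))
  bad <- d; bad[1, 2] <- bad[1, 2] + 1
  expect_error(pcoa(bad), "symmetric")
})

test_that("power is monotone in expected F_ST and in sample size", {
  # small 3-point grid; Monte-Carlo noise bounded by 3 binomial SEs
  base <- withr::with_seed(2, msatclust:::rdirichlet(5, rep(1, 6)))
  pw <- function(t, n_per) {
    d <- power_design(ne = 200, t = t, n_pops = 10, n_per_pop = n_per,
                      replicates = 60, alpha = 0.05, tests = "chi_square")
    unname(power_sim(base, d, seed = 100 + t + n_per)$rejection)
  }
  p_grid <- c(pw(0, 20), pw(8, 20), pw(40, 20))
  se <- sqrt(pmax(p_grid * (1 - p_grid), 0.01) / 60)
  expect_true(all(diff(p_grid) > -3 * (se[-1] + se[-3])))
  # larger samples at fixed drift are at least as powerful
  p_small <- pw(8, 10); p_big <- pw(8, 40)
  se2 <- sqrt(0.25 / 60)
  expect_gt(p_big, p_small - 3 * se2)
})
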