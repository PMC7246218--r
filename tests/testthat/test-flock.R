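test_that("separable fixture: all runs identical, plateau = n_runs", {
  g <- fixed_two_pop(n_per = 20, L = 8)
  fr <- flock_run(g, 2, n_runs = 15, n_reallocations = 10, seed = 4)
  expect_equal(max(table(round(fr$mean_llod, 2))), 15)
  ab <- allocation_by_population(fr)
  expect_true(all(apply(ab$proportions, 1, max) == 1))
  expect_false(any(ab$admixed))
  expect_equal(unname(rowSums(ab$proportions)), c(1, 1))
})

test_that("panmictic fixture: small unstable LLOD, no supported plateau", {
  s <- sim_scenario(n_pops = 1, n_per_pop = 50, theta = 0, seed = 6)
  g <- sample_genotypes(sample_frequencies(s), s)
  fr <- flock_run(g, 2, n_runs = 12, n_reallocations = 10, seed = 5)
  # overfitting a random split yields a small positive LLOD (a couple of
  # log10 units), far below a real two-population signal, and the runs do
  # not co-locate on a supported plateau
  sep <- flock_run(fixed_two_pop(25, 15), 2, n_runs = 4,
                   n_reallocations = 6, seed = 1)
  expect_lt(stats::median(fr$mean_llod), stats::median(sep$mean_llod) / 3)
  expect_lt(max(table(round(fr$mean_llod, 2))), 6)
})

test_that("flock runs are deterministic and validate inputs", {
  g <- random_genotypes(n = 20, L = 5, seed = 8)
  f1 <- flock_run(g, 3, n_runs = 5, n_reallocations = 5, seed = 2)
  f2 <- flock_run(g, 3, n_runs = 5, n_reallocations = 5, seed = 2)
  expect_identical(f1$mean_llod, f2$mean_llod)
  expect_identical(f1$allocations, f2$allocations)
  expect_error(flock_run(g, 1), "k must be >= 2")
  expect_error(flock_run(g, 21), "exceeds")
  # allocations always cover all individuals
  expect_false(anyNA(f1$allocations))
})

test_that("allocation likelihoods are invariant under allele relabeling", {
  g <- random_genotypes(n = 24, L = 4, n_pops = 2, seed = 12)
  remap <- c(`95` = 7L, `101` = 300L, `120` = 2L, `250` = 41L)
  relab <- function(m) matrix(remap[as.character(m)], nrow(m), ncol(m))
  g2 <- genotype_matrix(relab(g$allele1), relab(g$allele2),
                        pop = as.character(g$pop))
  f1 <- flock_run(g, 2, n_runs = 4, n_reallocations = 6, seed = 3)
  f2 <- flock_run(g2, 2, n_runs = 4, n_reallocations = 6, seed = 3)
  expect_equal(f1$mean_llod, f2$mean_llod, tolerance = 1e-12)
  expect_identical(f1$allocations, f2$allocations)
})

test_that("stopping rules follow the plateau-scan trace", {
  expect_equal(stopping_decision(plateaus(c(`2` = 50, `3` = 2, `4` = 1)))$k_opt, 2L)
  expect_equal(stopping_decision(plateaus(c(`2` = 3, `3` = 4, `4` = 2)))$decision,
               "undecided")
  # 6 at k=2 does not strictly exceed 6 at k=3; k=3 decides against 1 at k=4
  d <- stopping_decision(plateaus(c(`2` = 6, `3` = 6, `4` = 1)))
  expect_equal(d$k_opt, 3L)
  # plateau at the scan edge cannot decide
  expect_equal(stopping_decision(plateaus(c(`2` = 2, `3` = 50)))$decision,
               "undecided")
  # min_plateau is honored
  expect_equal(stopping_decision(plateaus(c(`2` = 5, `3` = 1)),
                                 min_plateau = 5)$k_opt, 2L)
})

test_that("a constructed half/half split population is flagged admixed", {
  a <- matrix(c(rep(1L, 20), rep(2L, 20), rep(c(1L, 2L), 10)), 60, 8)
  g <- genotype_matrix(a, a, pop = rep(c("A", "B", "mix"), each = 20))
  fr <- flock_run(g, 2, n_runs = 10, n_reallocations = 10, seed = 7)
  ab <- allocation_by_population(fr)
  expect_false(ab$admixed["A"]); expect_false(ab$admixed["B"])
  expect_true(ab$admixed["mix"])
  expect_equal(unname(rowSums(ab$proportions)), rep(1, 3))
})

# strongly separated multi-population world for resolution fixtures
strong_world <- function(n_groups = 3, pops_per_group = 2, theta_g = 0.5,
                         n_per_pop = 20, seed = 31, extra = NULL) {
  P <- n_groups * pops_per_group
  s <- sim_scenario(n_pops = P, n_per_pop = n_per_pop, n_loci = 15,
                    theta = 0.02, group = rep(seq_len(n_groups),
                                              each = pops_per_group),
                    theta_group = theta_g, seed = seed)
  sample_genotypes(sample_frequencies(s), s)
}

test_that("resolve_undecided isolates admixture-caused indecision", {
  # 3 strongly separated groups + 2 half/half admixed populations
  g0 <- strong_world()
  adm <- diag(8); adm[7, ] <- 0; adm[7, c(1, 3)] <- 0.5
  adm[8, ] <- 0; adm[8, c(3, 5)] <- 0.5
  s <- sim_scenario(n_pops = 8, n_per_pop = 20, n_loci = 15, theta = 0.02,
                    group = c(1, 1, 2, 2, 3, 3, 4, 4),
                    theta_group = c(0.5, 0.5, 0.5, 0, 0), admixture = adm,
                    seed = 33)
  g <- sample_genotypes(sample_frequencies(s), s)
  cfg <- list(k_max = 5L, n_runs = 20L, n_reallocations = 10L,
              min_plateau = 6L, seed = 5L)
  full <- flock_scan(g, 5, n_runs = 20, n_reallocations = 10, seed = 5)
  if (full$decision$decision == "undecided") {
    res <- resolve_undecided(g, cfg)
    expect_equal(res$decision_after_removal$decision, "k_opt")
    expect_true(length(res$admixed) >= 1 || length(res$outliers) >= 1)
  } else {
    succeed("full set already decided; resolution path exercised elsewhere")
  }
})

test_that("resolve_undecided reports information deficiency on panmixia", {
  s <- sim_scenario(n_pops = 4, n_per_pop = 15, n_loci = 8, theta = 0, seed = 9)
  g <- sample_genotypes(sample_frequencies(s), s)
  cfg <- list(k_max = 4L, n_runs = 15L, n_reallocations = 8L,
              min_plateau = 6L, seed = 3L)
  full <- flock_scan(g, 4, n_runs = 15, n_reallocations = 8, seed = 3)
  skip_if(full$decision$decision != "undecided",
          "panmictic fixture unexpectedly decided")
  res <- resolve_undecided(g, cfg)
  expect_equal(res$verdict, "information-deficient")
  # a clearly decided input is rejected: two strongly diverged populations
  # where k = 2 plateaus but k = 3 runs scatter
  s2 <- sim_scenario(n_pops = 2, n_per_pop = 20, n_loci = 15, theta = 0.5,
                     seed = 41)
  gdec <- sample_genotypes(sample_frequencies(s2), s2)
  expect_error(resolve_undecided(gdec,
                                 list(k_max = 4L, n_runs = 15L,
                                      n_reallocations = 8L, min_plateau = 6L,
                                      seed = 1L)),
               "decided input")
})

test_that("hierarchical clustering partitions a strongly nested world", {
  # 2 groups x 2 subpopulations with nested drift: expect 4 leaves via a
  # depth-2 tree (or direct 4-way split at the top level)
  s <- sim_scenario(n_pops = 4, n_per_pop = 20, n_loci = 15, theta = 0.35,
                    group = c(1, 1, 2, 2), theta_group = 0.5, seed = 21)
  g <- sample_genotypes(sample_frequencies(s), s)
  ht <- hierarchical_flock(g, list(k_max = 5L, n_runs = 25L,
                                   n_reallocations = 10L, min_plateau = 6L,
                                   seed = 11L))
  expect_equal(ht$k_opt_flock, 4)
  expect_setequal(unlist(ht$leaves), paste0("pop", 1:4))
  expect_error(hierarchical_flock(subset_populations(g, "pop1")),
               "nothing to partition")
})

test_that("reallocation reaches the true partition from random starts on fixed data", {
  g <- fixed_two_pop(n_per = 15, L = 6)
  fr <- flock_run(g, 2, n_runs = 40, n_reallocations = 8, seed = 13)
  truth <- as.integer(g$pop)
  agree <- vapply(seq_len(40), function(r) {
    a <- fr$allocations[, r]
    max(mean(a == truth), mean(a == 3L - truth))
  }, numeric(1))
  expect_gte(mean(agree == 1), 0.95)
})

test_that("the island world's true partition is a fixed point that random starts rarely reach", {
  # the structural cause of plateau failure on simple_k5: batch reallocation
  # from the true partition moves nothing (a fixed point with perfect
  # self-assignment), yet uniform random initial partitions rarely land in
  # its basin, so runs scatter over local optima and no plateau forms
  g <- make_preset("simple_k5")$genotypes
  dat <- msatclust:::flock_data(g)
  truth <- as.integer(g$pop)
  ll <- msatclust:::flock_loglik(dat, truth, 5)
  expect_identical(max.col(ll), truth)
  ord <- t(apply(ll, 1, order, decreasing = TRUE))
  llod_truth <- ll[cbind(seq_len(125), ord[, 1])] - ll[cbind(seq_len(125), ord[, 2])]
  fr <- flock_run(g, 5, n_runs = 30, n_reallocations = 20, seed = 31)
  hits <- mean(fr$mean_llod >= mean(llod_truth) - 0.01)
  expect_lt(hits, 0.2)
  # at stronger drift (theta = 0.2) every run co-locates: full plateau
  s <- sim_scenario(n_pops = 5, theta = 0.2, seed = 7, missing_rate = 0.02)
  g2 <- sample_genotypes(sample_frequencies(s), s)
  fr2 <- flock_run(g2, 5, n_runs = 10, n_reallocations = 20, seed = 9)
  expect_equal(max(table(round(fr2$mean_llod, 2))), 10)
})
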