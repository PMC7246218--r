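test_that("delta-K reproduces hand-evaluated toy curves", {
  # means (-100, -80, -75) at K = 2..4 with sd(L(3)) = 2:
  # deltaK(3) = |-75 + 160 - 100| / 2 = 7.5
  sc <- fake_kscan(list(`2` = exact_moments(-100, 2, seed = 1),
                        `3` = exact_moments(-80, 2, seed = 2),
                        `4` = exact_moments(-75, 2, seed = 3)))
  dk <- evanno_delta_k(sc)
  expect_equal(dk$delta_k, 7.5)
  expect_equal(dk$k_opt_evanno, 3L)
  # linear means -> all second differences vanish
  sc2 <- fake_kscan(list(`2` = exact_moments(-100, 1, seed = 1),
                         `3` = exact_moments(-90, 1, seed = 2),
                         `4` = exact_moments(-80, 1, seed = 3),
                         `5` = exact_moments(-70, 1, seed = 4)))
  expect_equal(evanno_delta_k(sc2)$delta_k, c(0, 0), tolerance = 1e-10)
})

test_that("delta-K guards: degenerate variance, grid contiguity, replicates", {
  sc <- fake_kscan(list(`2` = c(-10, -10), `3` = c(-8, -8), `4` = c(-7, -7)))
  expect_error(evanno_delta_k(sc), "degenerate-variance")
  sc2 <- fake_kscan(list(`2` = c(-10, -9), `4` = c(-8, -7), `6` = c(-7, -6)))
  expect_error(evanno_delta_k(sc2), "contiguous")
  sc3 <- fake_kscan(list(`2` = -10, `3` = -9, `4` = -8))
  expect_error(evanno_delta_k(sc3), ">= 2 replicates")
  # contiguous prefix of a mixed grid is used, irregular tail ignored
  sc4 <- fake_kscan(list(`2` = exact_moments(-100, 2), `3` = exact_moments(-80, 2),
                         `4` = exact_moments(-75, 2), `10` = exact_moments(-60, 2)))
  expect_equal(evanno_delta_k(sc4)$k_interior, 3L)
})

test_that("delta-K invariances: ln P shift and SD scaling", {
  lnp <- list(`2` = exact_moments(-100, 2, seed = 5),
              `3` = exact_moments(-80, 3, seed = 6),
              `4` = exact_moments(-75, 4, seed = 7),
              `5` = exact_moments(-74, 2, seed = 8))
  base <- evanno_delta_k(fake_kscan(lnp))
  shifted <- evanno_delta_k(fake_kscan(lapply(lnp, `+`, 500)))
  expect_equal(shifted$delta_k, base$delta_k, tolerance = 1e-9)
  # multiplying all deviations around each mean by c scales deltaK by 1/c
  scaled <- lapply(lnp, function(x) mean(x) + 3 * (x - mean(x)))
  expect_equal(evanno_delta_k(fake_kscan(scaled))$delta_k, base$delta_k / 3,
               tolerance = 1e-9)
})

test_that("per-replicate second-difference variant is exposed", {
  lnp <- list(`2` = exact_moments(-100, 2, seed = 1),
              `3` = exact_moments(-80, 2, seed = 2),
              `4` = exact_moments(-75, 2, seed = 3))
  a <- evanno_delta_k(fake_kscan(lnp), per_replicate = FALSE)
  b <- evanno_delta_k(fake_kscan(lnp), per_replicate = TRUE)
  # mean-based numerator is |mean of second differences|; per-replicate is
  # mean of |second differences| -- they differ when signs vary
  expect_gte(b$delta_k, a$delta_k - 1e-12)
})

test_that("plateau-rule K selection", {
  sat <- fake_kscan(list(`2` = exact_moments(-200, 1, seed = 1),
                         `3` = exact_moments(-150, 1, seed = 2),
                         `4` = exact_moments(-120, 1, seed = 3),
                         `5` = exact_moments(-100, 1, seed = 4),
                         `6` = exact_moments(-100.2, 1, seed = 5),
                         `7` = exact_moments(-99.8, 1, seed = 6)))
  expect_equal(pritchard_kopt(sat), 5L)
  expect_equal(pritchard_kopt(sat, tol_sd_multiple = 0), 7L)
  flat <- fake_kscan(list(`2` = exact_moments(-100, 1, seed = 1),
                          `3` = exact_moments(-100, 1, seed = 1),
                          `4` = exact_moments(-100, 1, seed = 1)))
  expect_equal(pritchard_kopt(flat), 2L)
})

test_that("block analysis: constructed stability and instability", {
  # stable: every replicate draws from the same curve, noise << K-gaps
  mk_rep <- function(k, i) -1000 + 60 * min(k, 5) + 0.5 * sin(i * k)
  lnp <- lapply(2:8, function(k) vapply(1:20, function(i) mk_rep(k, i), numeric(1)))
  names(lnp) <- 2:8
  br <- block_analysis(fake_kscan(lnp), block_size = 5, n_permutations = 8,
                       stability_window = 3, seed = 2)
  expect_equal(br$verdict, "converged")
  expect_true(all(br$per_block_kopt[, "evanno"] == 5))
  expect_equal(nrow(br$per_block_kopt), 4)

  # unstable: stable peak at K = 3 for blocks 1-3, then the last block
  # carries strong K = 6 evidence that flips the full accumulation (the
  # "stable until the final block" failure pattern)
  lnp2 <- lapply(2:8, function(k) vapply(1:20, function(i) {
    if (i <= 15) -1000 + 60 * min(k, 3) + 0.3 * cos(i * 7 + k)
    else -1000 + 400 * min(k, 6) + 0.3 * cos(i * 7 + k)
  }, numeric(1)))
  names(lnp2) <- 2:8
  br2 <- block_analysis(fake_kscan(lnp2), block_size = 5, n_permutations = 8,
                        stability_window = 3, seed = 2)
  expect_equal(br2$verdict, "not_converged")
  expect_gte(length(unique(br2$per_block_kopt[, "evanno"])), 2)

  # determinism of the permutation set
  br3 <- block_analysis(fake_kscan(lnp2), block_size = 5, n_permutations = 8,
                        stability_window = 3, seed = 2)
  expect_identical(br2$randomized_kopt, br3$randomized_kopt)
  expect_error(block_analysis(fake_kscan(lnp), block_size = 25), "block_size")
})

test_that("mode alignment: permutation invariance and two-family fixtures", {
  n <- 30
  qA <- diag(3)[rep(1:3, each = 10), ]
  # 30 column-permuted copies of A + 10 genuinely different solutions
  runs <- c(lapply(1:30, function(i)
              rep_run(3, -100 - 0.01 * i,
                      qA[, withr::with_seed(i, sample(3))])),
            lapply(1:10, function(i)
              rep_run(3, -105, matrix(1 / 3, n, 3))))
  mp <- align_and_partition_modes(runs, 0.9)
  expect_equal(mp$major_fraction, 0.75)
  expect_length(mp$minor_modes, 1)
  # permuted copies align exactly
  expect_equal(mp$mean_q_major, qA, ignore_attr = TRUE, tolerance = 1e-12)
  # threshold 0 -> a single mode
  mp0 <- align_and_partition_modes(runs, 0)
  expect_equal(mp0$major_fraction, 1)
  # input order invariance (up to mode labels)
  ord <- withr::with_seed(3, sample(length(runs)))
  mp2 <- align_and_partition_modes(runs[ord], 0.9)
  expect_equal(mp2$major_fraction, mp$major_fraction)
  expect_equal(sort(table(mp2$mode)), sort(table(mp$mode)),
               ignore_attr = TRUE)
  expect_error(align_and_partition_modes(list(rep_run(2, -1, matrix(0.5, 2, 2)),
                                              rep_run(3, -1, matrix(1/3, 2, 3)))),
               "share K")
})

test_that("ghost detection applies the 0.5 rule", {
  expect_equal(detect_ghosts(diag(4))$n_ghosts, 0)
  m <- cbind(c(0.55, 0.15, 0.2), c(0.1, 0.6, 0.15), c(0.2, 0.1, 0.45),
             c(0.1, 0.05, 0.1), c(0.05, 0.1, 0.1))
  gh <- detect_ghosts(m / rowSums(m) * rowSums(m))  # rows already sum to 1
  expect_equal(gh$ghosts, c(3L, 4L, 5L))
  expect_equal(gh$corrected_k, 2L)
  # uniform memberships: all K clusters are ghosts for K >= 3
  u <- matrix(1 / 4, 3, 4)
  expect_equal(detect_ghosts(u)$n_ghosts, 4)
  expect_error(detect_ghosts(matrix(0.4, 2, 2)), "sum to 1")
  # invariance to population and cluster order
  perm <- c(2, 4, 1, 5, 3)
  gh2 <- detect_ghosts(m[c(3, 1, 2), perm])
  expect_equal(gh2$n_ghosts, gh$n_ghosts)
  expect_equal(sort(perm[gh2$ghosts]), gh$ghosts)
})

test_that("clean-K set combines modes and ghosts", {
  mk_part <- function(minor) structure(list(minor_modes = minor),
                                       class = "mode_partition")
  mk_ghost <- function(n) structure(list(n_ghosts = n), class = "ghost_report")
  parts <- list(`3` = mk_part(list()), `4` = mk_part(list()),
                `5` = mk_part(list()), `6` = mk_part(list(1:2)))
  ghosts <- list(`3` = mk_ghost(1), `4` = mk_ghost(0), `5` = mk_ghost(0),
                 `6` = mk_ghost(0))
  expect_equal(clean_k_set(parts, ghosts), c(4L, 5L))
  # none clean -> empty, not an error
  ghosts0 <- list(`3` = mk_ghost(1), `4` = mk_ghost(1), `5` = mk_ghost(2),
                  `6` = mk_ghost(0))
  expect_length(clean_k_set(parts, ghosts0), 0)
  expect_error(clean_k_set(parts[1:2], ghosts), "mismatched")
})

test_that("evanno restricted to major modes", {
  q_id <- function(k, n = 6) diag(k)[rep(seq_len(k), length.out = n), ]
  mk <- function(k, lnps, outlier_at = integer(0)) {
    lapply(seq_along(lnps), function(i) {
      q <- if (i %in% outlier_at) matrix(1 / k, 6, k) else q_id(k)
      rep_run(k, lnps[i], q)
    })
  }
  runs <- list(`2` = mk(2, exact_moments(-100, 2, 6, seed = 1)),
               `3` = mk(3, c(exact_moments(-80, 2, 5, seed = 2), -120),
                        outlier_at = 6),
               `4` = mk(4, exact_moments(-75, 2, 6, seed = 3)))
  scan <- msatclust:::new_kscan(2:4, runs)
  parts <- lapply(runs, align_and_partition_modes, similarity_threshold = 0.9)
  restricted <- evanno_on_major_modes(scan, parts)
  # oracle: recompute on the five major-mode replicates directly
  oracle <- evanno_delta_k(fake_kscan(list(
    `2` = vapply(runs[["2"]], `[[`, numeric(1), "ln_p_of_k"),
    `3` = vapply(runs[["3"]][1:5], `[[`, numeric(1), "ln_p_of_k"),
    `4` = vapply(runs[["4"]], `[[`, numeric(1), "ln_p_of_k"))))
  expect_equal(restricted$delta_k, oracle$delta_k)
  # all replicates major -> identity with plain evanno
  scan_all <- fake_kscan(list(`2` = exact_moments(-100, 2, seed = 4),
                              `3` = exact_moments(-80, 2, seed = 5),
                              `4` = exact_moments(-75, 2, seed = 6)),
                         n_ind = 4)
  parts_all <- lapply(scan_all$runs, align_and_partition_modes,
                      similarity_threshold = 0)
  expect_equal(evanno_on_major_modes(scan_all, parts_all)$delta_k,
               evanno_delta_k(scan_all)$delta_k)
  # a K with a single major-mode replicate errors by name
  runs_bad <- runs
  runs_bad[["3"]] <- mk(3, c(-80, -80.1, -120, -121, -122, -123),
                        outlier_at = 3:6)
  parts_bad <- lapply(runs_bad, align_and_partition_modes,
                      similarity_threshold = 0.9)
  parts_bad[["3"]]$major_mode <- parts_bad[["3"]]$major_mode[1]
  expect_error(evanno_on_major_modes(msatclust:::new_kscan(2:4, runs_bad),
                                     parts_bad), "K = 3")
})
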