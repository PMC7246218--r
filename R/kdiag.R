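## Maximal contiguous (step 1) prefix of a sorted K grid.
contiguous_prefix <- function(grid) {
  if (length(grid) < 2) return(grid)
  brk <- which(diff(grid) != 1L)
  if (!length(brk)) return(grid)
  grid[seq_len(brk[1])]
}

#' Evanno delta-K statistics of a K-scan
#'
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`,
#' with means and SDs of the estimated ln P(X|K) taken over replicates.
#' Computed only on the maximal contiguous prefix of the grid (second
#' differences are undefined on an irregular grid).  Set
#' `per_replicate = TRUE` for the variant that averages absolute
#' per-replicate second differences instead (replicates matched by index).
#'
#' @param scan a `kscan` with >= 2 replicates per K on a contiguous
#'   sub-grid of >= 3 consecutive K values
#' @param per_replicate use per-replicate second differences
#' @return a `delta_k_result`: `k_interior`, `mean_l`, `sd_l`, `delta_k`,
#'   `k_opt_evanno`, `peaks`, `ratio_12`, `ratio_13`
#' @export
evanno_delta_k <- function(scan, per_replicate = FALSE) {
  grid <- contiguous_prefix(scan$grid)
  if (length(grid) < 3)
    stop("delta-K needs >= 3 consecutive K values on a contiguous grid")
  lnp <- lapply(grid, function(k) kscan_lnp(scan, k))
  names(lnp) <- as.character(grid)
  nr <- vapply(lnp, length, integer(1))
  if (any(nr < 2)) stop("delta-K needs >= 2 replicates per K")
  mean_l <- vapply(lnp, mean, numeric(1))
  sd_l <- vapply(lnp, stats::sd, numeric(1))
  interior <- seq(2, length(grid) - 1)
  if (any(sd_l[interior] == 0))
    stop("degenerate-variance error: sd of ln P(X|K) is 0 at an interior K; delta-K undefined")
  if (per_replicate) {
    rmin <- min(nr)
    secdiff <- vapply(interior, function(j) {
      mean(abs(lnp[[j + 1]][1:rmin] - 2 * lnp[[j]][1:rmin] + lnp[[j - 1]][1:rmin]))
    }, numeric(1))
  } else {
    secdiff <- vapply(interior, function(j)
      abs(mean_l[j + 1] - 2 * mean_l[j] + mean_l[j - 1]), numeric(1))
  }
  delta_k <- unname(secdiff / sd_l[interior])
  k_int <- grid[interior]
  ord <- order(-delta_k, k_int)
  peaks <- data.frame(k = k_int[ord], delta_k = delta_k[ord])
  k_opt <- k_int[which(delta_k == max(delta_k))][1]  # smallest-K tie-break
  structure(list(k_interior = k_int, mean_l = mean_l, sd_l = sd_l,
                 delta_k = delta_k, k_opt_evanno = k_opt, peaks = peaks,
                 ratio_12 = if (nrow(peaks) >= 2) peaks$delta_k[1] / peaks$delta_k[2] else NA_real_,
                 ratio_13 = if (nrow(peaks) >= 3) peaks$delta_k[1] / peaks$delta_k[3] else NA_real_),
            class = "delta_k_result")
}

#' @export
print.delta_k_result <- function(x, ...) {
  cat(sprintf("Evanno delta-K: K_opt = %d (peak %.2f; ratio_12 = %.2f)\n",
              x$k_opt_evanno, max(x$delta_k), x$ratio_12))
  invisible(x)
}

#' Plateau-rule optimal K from mean ln P(X|K)
#'
#' An operationalization of the visual rule "smallest K at which the mean
#' ln P(X|K) reaches its plateau": returns the smallest K whose mean is
#' within `tol_sd_multiple` pooled SDs of the global maximum mean.
#'
#' @param scan a `kscan` with >= 2 replicates per K
#' @param tol_sd_multiple plateau tolerance in pooled-SD units (default 1;
#'   0 returns the exact argmax)
#' @return the selected K
#' @export
pritchard_kopt <- function(scan, tol_sd_multiple = 1) {
  lnp <- lapply(scan$grid, function(k) kscan_lnp(scan, k))
  if (any(vapply(lnp, length, integer(1)) < 2))
    stop("needs >= 2 replicates per K")
  mean_l <- vapply(lnp, mean, numeric(1))
  pooled_sd <- sqrt(mean(vapply(lnp, stats::var, numeric(1))))
  thr <- max(mean_l) - tol_sd_multiple * pooled_sd
  scan$grid[which(mean_l >= thr)[1]]
}

#' Replicate-block convergence protocol for K_opt estimators
#'
#' Partitions the replicates (kept in generation order) into consecutive
#' blocks, recomputes `K_opt[Evanno]` and `K_opt[Pritchard]` per block and
#' over accumulated prefixes of blocks, recomputes the accumulated
#' trajectory under random permutations of the block order, and issues a
#' convergence verdict: converged iff the accumulated `K_opt[Evanno]` is
#' constant over the last `stability_window` prefixes of the original
#' order and of every permuted order.
#'
#' @param scan a `kscan`
#' @param block_size replicates per block (default 5)
#' @param n_permutations random block orders (default 10)
#' @param stability_window number of trailing accumulated prefixes that
#'   must agree (default 4)
#' @param seed integer seed for the permutations
#' @return a `block_report`
#' @export
block_analysis <- function(scan, block_size = 5L, n_permutations = 10L,
                           stability_window = 4L, seed = 1L) {
  R <- min(vapply(scan$runs, length, integer(1)))
  if (block_size > R) stop("block_size exceeds the number of replicates")
  B <- R %/% block_size
  if (B < 2) stop("need R >= 2 * block_size replicates")
  blocks <- lapply(seq_len(B), function(b) ((b - 1L) * block_size + 1L):(b * block_size))

  scan_for <- function(idx) {
    idx_by_k <- stats::setNames(rep(list(idx), length(scan$grid)),
                                as.character(scan$grid))
    kscan_subset(scan, idx_by_k)
  }
  kopt_ev <- function(s) tryCatch(evanno_delta_k(s)$k_opt_evanno,
                                  error = function(e) NA_integer_)
  kopt_pr <- function(s) tryCatch(pritchard_kopt(s), error = function(e) NA_integer_)

  per_block_kopt <- t(vapply(blocks, function(ix) {
    s <- scan_for(ix)
    c(evanno = kopt_ev(s), pritchard = kopt_pr(s))
  }, c(evanno = 0L, pritchard = 0L)))
  acc_traj <- function(order_b) {
    idx <- integer(0)
    t(vapply(seq_len(B), function(j) {
      idx <<- c(idx, blocks[[order_b[j]]])
      s <- scan_for(idx)
      c(evanno = kopt_ev(s), pritchard = kopt_pr(s))
    }, c(evanno = 0L, pritchard = 0L)))
  }
  accumulated <- acc_traj(seq_len(B))
  perms <- with_seed(derive_seed(seed, "blockperm"), {
    lapply(seq_len(n_permutations), function(i) sample.int(B))
  })
  randomized <- lapply(perms, function(p) acc_traj(p))
  randomized_kopt <- t(vapply(randomized, function(m) m[, "evanno"], integer(B)))

  # pairwise correlations of per-block mean and SD P(K) curves
  curves <- lapply(blocks, function(ix) {
    s <- scan_for(ix)
    lnp <- lapply(s$grid, function(k) kscan_lnp(s, k))
    cbind(mean = vapply(lnp, mean, numeric(1)), sd = vapply(lnp, stats::sd, numeric(1)))
  })
  pair_cor <- function(col) {
    vals <- c()
    for (i in seq_len(B - 1)) for (j in (i + 1):B)
      vals <- c(vals, suppressWarnings(stats::cor(curves[[i]][, col], curves[[j]][, col])))
    vals
  }
  mc <- pair_cor("mean"); sc <- pair_cor("sd")

  # stability window: the trailing accumulated prefixes that contain more
  # than half the blocks (a 1- or 2-block prefix estimates sd(ln P) from 5-10
  # replicates and is structurally noisy; at full scale (B = 20) this
  # reduces to the last `stability_window` prefixes)
  w <- max(1L, min(stability_window, B %/% 2L))
  window_vals <- c(accumulated[(B - w + 1):B, "evanno"],
                   unlist(lapply(randomized, function(m) m[(B - w + 1):B, "evanno"])))
  verdict <- if (!anyNA(window_vals) && length(unique(window_vals)) == 1L)
    "converged" else "not_converged"

  structure(list(block_size = as.integer(block_size), n_blocks = B,
                 per_block_kopt = per_block_kopt,
                 accumulated_kopt = accumulated,
                 randomized_kopt = randomized_kopt,
                 permutations = perms,
                 mean_corr = mean(mc, na.rm = TRUE), sd_corr = mean(sc, na.rm = TRUE),
                 stability_window = w, verdict = verdict),
            class = "block_report")
}

#' @export
print.block_report <- function(x, ...) {
  cat(sprintf("block analysis: %d blocks of %d; verdict: %s\n",
              x$n_blocks, x$block_size, x$verdict))
  cat("accumulated K_opt[Evanno]:",
      paste(x$accumulated_kopt[, "evanno"], collapse = " "), "\n")
  invisible(x)
}

## Greedy column alignment of membership matrix q to reference ref:
## reference columns taken largest first; returns the permutation p with
## q[, p] aligned to ref.
greedy_align <- function(q, ref) {
  k <- ncol(ref)
  perm <- integer(k)
  free <- rep(TRUE, k)
  for (j in order(-colSums(ref))) {
    d <- vapply(seq_len(k), function(c)
      if (free[c]) sum((q[, c] - ref[, j])^2) else Inf, numeric(1))
    pick <- which.min(d)
    perm[j] <- pick
    free[pick] <- FALSE
  }
  perm
}

## Symmetric similarity of two row-stochastic membership matrices
## (already aligned): 1 - ||A - B||_F / sqrt(2 n); lies in [0, 1].
q_similarity <- function(a, b) 1 - sqrt(sum((a - b)^2)) / sqrt(2 * nrow(a))

#' Align replicate membership matrices and partition them into modes
#'
#' Each replicate's Q is aligned to the best-ln P replicate by greedy
#' column matching (largest reference columns first); replicates whose
#' aligned pairwise similarity `1 - ||Qi - Qj||_F / sqrt(2n)` reaches
#' `similarity_threshold` are connected, and the connected components are
#' the modes.  The major mode is the largest component (ties broken toward
#' the component containing the best-ln P replicate).
#'
#' @param runs list of `replicate_run`s sharing K and individuals
#' @param similarity_threshold default 0.9 (a documented stand-in for
#'   dynamic threshold determination)
#' @return a `mode_partition`
#' @export
align_and_partition_modes <- function(runs, similarity_threshold = 0.9) {
  if (!length(runs)) stop("no replicates")
  ks <- vapply(runs, function(r) r$k, integer(1))
  ns <- vapply(runs, function(r) nrow(r$q), integer(1))
  if (length(unique(ks)) != 1 || length(unique(ns)) != 1)
    stop("replicates must share K and individuals")
  R <- length(runs)
  best <- which.max(vapply(runs, function(r) r$ln_p_of_k, numeric(1)))
  ref <- runs[[best]]$q
  aligned <- lapply(runs, function(r) {
    perm <- greedy_align(r$q, ref)
    r$q[, perm, drop = FALSE]
  })
  sim <- diag(R)
  if (R > 1)
    for (i in seq_len(R - 1)) for (j in (i + 1):R)
      sim[i, j] <- sim[j, i] <- q_similarity(aligned[[i]], aligned[[j]])
  adj <- sim >= similarity_threshold
  comp <- integer(R); cid <- 0L
  for (i in seq_len(R)) if (comp[i] == 0L) {
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  sizes <- tabulate(comp, cid)
  big <- which(sizes == max(sizes))
  major <- if (comp[best] %in% big) comp[best] else big[1]
  major_ids <- which(comp == major)
  mean_q_major <- Reduce(`+`, aligned[major_ids]) / length(major_ids)
  structure(list(k = ks[1], aligned = aligned, mode = comp,
                 major_mode = major_ids,
                 minor_modes = lapply(setdiff(seq_len(cid), major),
                                      function(c) which(comp == c)),
                 major_fraction = length(major_ids) / R,
                 mean_q_major = mean_q_major, similarity = sim),
            class = "mode_partition")
}

#' @export
print.mode_partition <- function(x, ...) {
  cat(sprintf("mode partition at K = %d: %d mode(s), major fraction %.2f\n",
              x$k, length(x$minor_modes) + 1L, x$major_fraction))
  invisible(x)
}

#' Population-averaged membership matrix
#'
#' @param q individuals x K membership matrix (rows sum to 1)
#' @param pop population label per individual
#' @return populations x K matrix of mean memberships
#' @export
mean_q_by_population <- function(q, pop) {
  pop <- factor(pop, levels = unique(as.character(pop)))
  m <- apply(q, 2, function(col) tapply(col, pop, mean))
  m <- matrix(m, nrow = nlevels(pop),
              dimnames = list(levels(pop), colnames(q)))
  m
}

#' Ghost-cluster detection
#'
#' A cluster is a ghost iff its mean membership coefficient is below 0.5
#' in every population; the corrected K subtracts the ghosts.
#'
#' @param mean_q_by_population populations x K matrix of mean memberships
#'   (rows sum to 1)
#' @param threshold ghost threshold (default 0.5)
#' @return a `ghost_report`: `ghosts` (cluster indices), `n_ghosts`,
#'   `corrected_k`
#' @export
detect_ghosts <- function(mean_q_by_population, threshold = 0.5) {
  m <- as.matrix(mean_q_by_population)
  if (any(abs(rowSums(m) - 1) > 1e-6))
    stop("mean membership rows must sum to 1")
  ghosts <- which(apply(m, 2, max) < threshold)
  structure(list(k = ncol(m), ghosts = as.integer(ghosts),
                 n_ghosts = length(ghosts),
                 corrected_k = ncol(m) - length(ghosts)),
            class = "ghost_report")
}

#' Clean-K set: K values with a single mode and no ghosts
#'
#' @param partitions named list of `mode_partition` per K
#' @param ghosts named list of `ghost_report` per K (same K coverage)
#' @return ascending integer vector of clean K values (possibly empty)
#' @export
clean_k_set <- function(partitions, ghosts) {
  kp <- sort(as.integer(names(partitions)))
  kg <- sort(as.integer(names(ghosts)))
  if (!identical(kp, kg)) stop("mismatched K coverage between partitions and ghosts")
  clean <- vapply(as.character(kp), function(k)
    length(partitions[[k]]$minor_modes) == 0 && ghosts[[k]]$n_ghosts == 0,
    logical(1))
  kp[clean]
}

#' Evanno delta-K restricted to major-mode replicates
#'
#' @param scan a `kscan`
#' @param partitions named list of `mode_partition` per K covering the
#'   contiguous prefix of the scan grid
#' @return a `delta_k_result`
#' @export
evanno_on_major_modes <- function(scan, partitions) {
  grid <- contiguous_prefix(scan$grid)
  idx_by_k <- list()
  for (k in grid) {
    key <- as.character(k)
    part <- partitions[[key]]
    if (is.null(part)) stop("no mode partition for K = ", k)
    if (length(part$major_mode) < 2)
      stop("fewer than 2 major-mode replicates at K = ", k)
    idx_by_k[[key]] <- part$major_mode
  }
  sub <- kscan_subset(scan, idx_by_k)
  sub$grid <- grid
  sub$runs <- sub$runs[as.character(grid)]
  evanno_delta_k(sub)
}
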