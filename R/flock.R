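## Per-cluster log10 genotype likelihood table for the current allocation.
## freq smoothing: add one per allele so unseen alleles never give -Inf.
## Returns n x k matrix of multilocus log10 likelihoods (HWE within
## cluster, heterozygote factor 2, missing loci skipped).
flock_loglik <- function(dat, alloc, k) {
  n <- dat$n; L <- dat$L
  ll <- matrix(0, n, k)
  log2const <- log10(2)
  for (l in seq_len(L)) {
    A <- dat$n_alleles[l]
    a1 <- dat$a1[, l]; a2 <- dat$a2[, l]
    obs <- !is.na(a1)
    # allele counts per cluster with add-one smoothing
    cnt <- matrix(1, A, k)
    if (any(obs)) {
      t1 <- table(factor(a1[obs], levels = seq_len(A)), factor(alloc[obs], levels = seq_len(k)))
      t2 <- table(factor(a2[obs], levels = seq_len(A)), factor(alloc[obs], levels = seq_len(k)))
      cnt <- cnt + t1 + t2
    }
    f <- sweep(cnt, 2, colSums(cnt), "/")
    lf <- log10(f)
    het <- obs & a1 != a2
    idx1 <- a1[obs]; idx2 <- a2[obs]
    contrib <- lf[idx1, , drop = FALSE] + lf[idx2, , drop = FALSE]
    contrib[het[obs], ] <- contrib[het[obs], ] + log2const
    ll[obs, ] <- ll[obs, ] + contrib
  }
  ll
}

flock_data <- function(g) {
  rec <- recode_all(g)
  L <- n_loci(g); n <- n_ind(g)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  n_alleles <- integer(L)
  for (l in seq_len(L)) {
    a1[, l] <- rec[[l]]$a1; a2[, l] <- rec[[l]]$a2
    n_alleles[l] <- max(1L, length(rec[[l]]$codes))
  }
  list(a1 = a1, a2 = a2, n_alleles = n_alleles, n = n, L = L)
}

#' One FLOCK-style run set: iterative reallocation at a fixed k
#'
#' Per run: a random initial partition is refined by `n_reallocations`
#' rounds of (i) per-cluster allele-frequency estimation with
#' add-one-per-allele smoothing and (ii) reallocation of every individual
#' to the cluster maximizing its multilocus log10 genotype likelihood
#' (HWE within cluster, heterozygote factor 2, missing loci skipped).
#' The individual LLOD is the log10 likelihood gap between its best and
#' second-best cluster; with `llod_threshold = 0` the reallocation is a
#' pure argmax, otherwise an individual moves only when its LLOD reaches
#' the threshold.  An emptied cluster is re-seeded with the currently
#' worst-fitting (lowest-LLOD) individual so k stays constant.
#'
#' @param g a [genotype_matrix()]
#' @param k number of clusters (>= 2)
#' @param n_runs independent runs (default 50)
#' @param n_reallocations reallocation rounds per run (default 20)
#' @param llod_threshold acceptance threshold (default 0)
#' @param seed integer seed
#' @return a `flock_run`: per-run mean LLOD, final allocations and
#'   individual LLODs
#' @export
flock_run <- function(g, k, n_runs = 50L, n_reallocations = 20L,
                      llod_threshold = 0, seed = 1L) {
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  if (k > n_ind(g)) stop("k exceeds the number of individuals")
  dat <- flock_data(g)
  n <- dat$n
  mean_llod <- numeric(n_runs)
  allocs <- matrix(NA_integer_, n, n_runs)
  llods <- matrix(NA_real_, n, n_runs)
  for (run in seq_len(n_runs)) {
    with_seed(derive_seed(seed, "flock", k, run), {
      alloc <- sample.int(k, n, replace = TRUE)
      llod <- rep(0, n)
      for (it in seq_len(n_reallocations)) {
        ll <- flock_loglik(dat, alloc, k)
        ord <- t(apply(ll, 1, order, decreasing = TRUE))
        best <- ord[, 1]
        second <- if (k >= 2) ord[, 2] else best
        llod <- ll[cbind(seq_len(n), best)] - ll[cbind(seq_len(n), second)]
        move <- llod >= llod_threshold
        new_alloc <- ifelse(move, best, alloc)
        # empty-cluster repair: re-seed with the worst-fitting individual
        for (c in which(tabulate(new_alloc, k) == 0L)) {
          cand <- which(tabulate(new_alloc, k)[new_alloc] > 1L)
          donor <- cand[which.min(llod[cand])]
          new_alloc[donor] <- c
        }
        alloc <- new_alloc
      }
      mean_llod[run] <- mean(llod)
      allocs[, run] <- alloc
      llods[, run] <- llod
    })
  }
  structure(list(k = k, n_runs = as.integer(n_runs),
                 n_reallocations = as.integer(n_reallocations),
                 llod_threshold = llod_threshold,
                 mean_llod = mean_llod, allocations = allocs, llod = llods,
                 pop = g$pop, ids = g$ids),
            class = "flock_run")
}

#' @export
print.flock_run <- function(x, ...) {
  cat(sprintf("flock_run: k = %d, %d runs; mean LLOD %.3f-%.3f; max plateau %d\n",
              x$k, x$n_runs, min(x$mean_llod), max(x$mean_llod),
              max(table(round(x$mean_llod, 2)))))
  invisible(x)
}

#' Plateau table over a range of k
#'
#' Mean-LLOD scores are rounded to `digits` decimals (matching the printed
#' precision of the reference tool) and the maximal plateau length is the
#' largest count of runs sharing the same rounded value.
#'
#' @param runs_by_k list of `flock_run` objects for k = 2, 3, ...
#' @param digits rounding before plateau counting (default 2)
#' @return a `plateau_table` data frame with columns `k`, `plateau`,
#'   `plateau_llod`
#' @export
plateau_table <- function(runs_by_k, digits = 2) {
  stopifnot(length(runs_by_k) >= 1)
  rows <- lapply(runs_by_k, function(fr) {
    r <- round(fr$mean_llod, digits)
    tab <- table(r)
    data.frame(k = fr$k, plateau = as.integer(max(tab)),
               plateau_llod = as.numeric(names(tab)[which.max(tab)]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$k), ]
  rownames(out) <- NULL
  structure(out, class = c("plateau_table", "data.frame"))
}

#' Stopping decision from a plateau table
#'
#' Scanning k in ascending order, returns the first k whose maximal
#' plateau length reaches `min_plateau` and strictly exceeds the plateau
#' length at k + 1; `undecided` if no k qualifies.
#'
#' @param t a [plateau_table()] over k = 2..k_max
#' @param min_plateau minimal supported plateau length (default 6)
#' @return list with `decision` (`"k_opt"` or `"undecided"`) and `k_opt`
#' @export
stopping_decision <- function(t, min_plateau = 6L) {
  t <- t[order(t$k), ]
  for (i in seq_len(nrow(t) - 1)) {
    if (t$plateau[i] >= min_plateau && t$plateau[i] > t$plateau[i + 1])
      return(list(decision = "k_opt", k_opt = t$k[i]))
  }
  list(decision = "undecided", k_opt = NA_integer_)
}

## Index of the run carrying the modal (longest-plateau) rounded score.
best_plateau_run <- function(fr, digits = 2) {
  r <- round(fr$mean_llod, digits)
  tab <- table(r)
  which(r == as.numeric(names(tab)[which.max(tab)]))[1]
}

#' Population-by-cluster allocation proportions of a selected run
#'
#' @param fr a `flock_run`
#' @param run index of the run to summarize (default: a run on the longest
#'   plateau)
#' @param admixed_threshold a population is flagged admixed when the
#'   largest share of its individuals allocated to a single cluster is
#'   below this value (default 0.8)
#' @return list with `proportions` (populations x clusters, rows sum to 1)
#'   and logical `admixed` per population
#' @export
allocation_by_population <- function(fr, run = best_plateau_run(fr),
                                     admixed_threshold = 0.8) {
  alloc <- fr$allocations[, run]
  tab <- table(fr$pop, factor(alloc, levels = seq_len(fr$k)))
  prop <- sweep(tab, 1, rowSums(tab), "/")
  prop <- matrix(prop, nrow = nrow(tab), dimnames = dimnames(tab))
  admixed <- apply(prop, 1, max) < admixed_threshold
  list(proportions = prop, admixed = admixed)
}

#' Scan k = 2..k_max with the reallocation clusterer and decide K
#'
#' @param g a [genotype_matrix()]
#' @param k_max largest k scanned
#' @param n_runs,n_reallocations,llod_threshold,seed passed to [flock_run()]
#' @param min_plateau passed to [stopping_decision()]
#' @return list with `runs_by_k`, `plateaus`, `decision`
#' @export
flock_scan <- function(g, k_max, n_runs = 50L, n_reallocations = 20L,
                       llod_threshold = 0, min_plateau = 6L, seed = 1L) {
  k_max <- max(3L, min(as.integer(k_max), n_ind(g)))
  runs_by_k <- lapply(2:k_max, function(k)
    flock_run(g, k, n_runs, n_reallocations, llod_threshold, seed))
  pt <- plateau_table(runs_by_k)
  list(runs_by_k = stats::setNames(runs_by_k, paste0("k", 2:k_max)),
       plateaus = pt, decision = stopping_decision(pt, min_plateau))
}

#' Three-step resolution of an undecided stopping condition
#'
#' Step 1: per-population mean LLOD at k = 2 is screened for clear
#' outliers (beyond median +/- `outlier_mult` * IQR); outliers and
#' non-outliers are re-analyzed separately.  Step 2: if still undecided,
#' populations failing the 80%-single-cluster rule are removed as admixed
#' and the remainder re-analyzed; a reached decision gives the verdict
#' `"admixture-caused"`, a second undecided `"information-deficient"`.
#' Step 3: excluded populations are re-added one at a time, logging which
#' single additions re-break the decision.
#'
#' @param g a [genotype_matrix()]
#' @param cfg list of settings: `k_max`, `n_runs`, `n_reallocations`,
#'   `llod_threshold`, `min_plateau`, `outlier_mult` (default 3),
#'   `admixed_threshold` (default 0.8), `seed`
#' @return list with `outliers`, `admixed`, `decision_after_removal`,
#'   `verdict`, `readdition_log` and the intermediate scans
#' @export
resolve_undecided <- function(g, cfg = list()) {
  cfg <- utils::modifyList(list(k_max = 8L, n_runs = 50L, n_reallocations = 20L,
                                llod_threshold = 0, min_plateau = 6L,
                                outlier_mult = 3, admixed_threshold = 0.8,
                                seed = 1L), cfg)
  full <- flock_scan(g, cfg$k_max, cfg$n_runs, cfg$n_reallocations,
                     cfg$llod_threshold, cfg$min_plateau, cfg$seed)
  if (full$decision$decision != "undecided")
    stop("resolve_undecided called on a decided input (k_opt = ",
         full$decision$k_opt, ")")
  pops <- pop_names(g)
  rescan <- function(sub_pops, seed_tag) {
    if (length(sub_pops) < 2) return(NULL)
    flock_scan(subset_populations(g, sub_pops), cfg$k_max, cfg$n_runs,
               cfg$n_reallocations, cfg$llod_threshold, cfg$min_plateau,
               derive_seed(cfg$seed, seed_tag))
  }
  # step 1: outlier screen on the k = 2 likelihood map
  fr2 <- flock_run(g, 2L, cfg$n_runs, cfg$n_reallocations,
                   cfg$llod_threshold, derive_seed(cfg$seed, "llodmap"))
  pop_llod <- tapply(rowMeans(fr2$llod), fr2$pop, mean)
  med <- stats::median(pop_llod); iqr <- stats::IQR(pop_llod)
  out_l <- pop_llod < med - cfg$outlier_mult * iqr |
           pop_llod > med + cfg$outlier_mult * iqr
  outliers <- names(pop_llod)[out_l]
  working <- setdiff(pops, outliers)
  scan1 <- if (length(outliers)) rescan(working, "nonoutliers") else full
  outlier_scan <- if (length(outliers) >= 2) rescan(outliers, "outliers") else NULL
  decision1 <- if (!is.null(scan1)) scan1$decision else full$decision
  admixed <- character(0)
  scan2 <- NULL
  if (decision1$decision == "undecided") {
    # step 2: remove admixed populations (80% rule) at the best-supported k
    base_scan <- if (!is.null(scan1)) scan1 else full
    kstar_i <- which.max(base_scan$plateaus$plateau)
    fr_star <- base_scan$runs_by_k[[kstar_i]]
    ab <- allocation_by_population(fr_star, admixed_threshold = cfg$admixed_threshold)
    admixed <- names(ab$admixed)[ab$admixed]
    remaining <- setdiff(working, admixed)
    scan2 <- rescan(remaining, "noadmixed")
    decision2 <- if (!is.null(scan2)) scan2$decision else
      list(decision = "undecided", k_opt = NA_integer_)
    verdict <- if (decision2$decision == "k_opt") "admixture-caused"
               else "information-deficient"
    decision_after <- decision2
    final_kept <- remaining
  } else {
    verdict <- "outlier-caused"
    decision_after <- decision1
    final_kept <- working
  }
  # step 3: stepwise re-addition of excluded populations
  excluded <- union(outliers, admixed)
  readdition <- list()
  if (decision_after$decision == "k_opt" && length(excluded)) {
    for (p in excluded) {
      sc <- rescan(c(final_kept, p), paste0("readd_", p))
      readdition[[p]] <- if (is.null(sc)) NA else sc$decision$decision
    }
  }
  list(outliers = outliers, admixed = admixed,
       decision_after_removal = decision_after, verdict = verdict,
       readdition_log = readdition,
       scans = list(full = full, nonoutliers = scan1, outliers = outlier_scan,
                    noadmixed = scan2))
}

#' Hierarchical reallocation clustering
#'
#' Recursively applies [flock_scan()] (and [resolve_undecided()] when the
#' stopping condition is undecided) to each decided cluster's member
#' populations until no group can be subdivided.  The number of leaves is
#' `k_opt_flock`; populations excluded by the 80% rule are recorded at the
#' node where they were removed.
#'
#' @param g a [genotype_matrix()] with >= 2 populations
#' @param cfg settings list as in [resolve_undecided()] plus `max_depth`
#'   (default 10)
#' @return a `hierarchy_tree`: nested node list with `leaves`,
#'   `k_opt_flock` and per-node `admixed_sets`
#' @export
hierarchical_flock <- function(g, cfg = list()) {
  cfg <- utils::modifyList(list(k_max = 8L, n_runs = 50L, n_reallocations = 20L,
                                llod_threshold = 0, min_plateau = 6L,
                                outlier_mult = 3, admixed_threshold = 0.8,
                                seed = 1L, max_depth = 10L), cfg)
  if (length(pop_names(g)) < 2)
    stop("nothing to partition: need >= 2 populations")
  node_id <- 0L
  analyze <- function(pops, depth) {
    if (depth > cfg$max_depth) stop("recursion depth cap exceeded")
    node_id <<- node_id + 1L
    node <- list(id = node_id, pops = pops, depth = depth,
                 decision = NULL, k = NA_integer_, admixed = character(0),
                 children = list(), leaf = FALSE)
    if (length(pops) == 1L) { node$leaf <- TRUE; return(node) }
    sub <- subset_populations(g, pops)
    k_max <- min(cfg$k_max, length(pops) + 1L, n_ind(sub))
    sc <- flock_scan(sub, k_max, cfg$n_runs, cfg$n_reallocations,
                     cfg$llod_threshold, cfg$min_plateau,
                     derive_seed(cfg$seed, "node", node$id, depth))
    dec <- sc$decision
    split_pops <- pops
    if (dec$decision == "undecided") {
      res <- resolve_undecided(sub, utils::modifyList(
        cfg, list(k_max = k_max, seed = derive_seed(cfg$seed, "resolve", node$id))))
      node$admixed <- res$admixed
      if (res$decision_after_removal$decision != "k_opt") {
        node$leaf <- TRUE
        node$decision <- "undecided"
        return(node)
      }
      dec <- res$decision_after_removal
      sc <- res$scans$noadmixed %||% res$scans$nonoutliers %||% sc
      split_pops <- setdiff(pops, union(res$admixed, character(0)))
      # outliers form their own branch
      if (length(res$outliers)) {
        split_pops <- setdiff(split_pops, res$outliers)
        node$children <- c(node$children, list(analyze(res$outliers, depth + 1L)))
      }
    }
    node$decision <- "k_opt"; node$k <- dec$k_opt
    fr <- sc$runs_by_k[[paste0("k", dec$k_opt)]]
    ab <- allocation_by_population(fr, admixed_threshold = cfg$admixed_threshold)
    grp <- apply(ab$proportions, 1, which.max)
    grp <- grp[names(grp) %in% split_pops]
    groups <- split(names(grp), grp)
    groups <- groups[lengths(groups) > 0]
    if (length(groups) <= 1L) { node$leaf <- TRUE; return(node) }
    for (gset in groups)
      node$children <- c(node$children, list(analyze(gset, depth + 1L)))
    node
  }
  root <- analyze(pop_names(g), 1L)
  leaves <- list(); admixed_sets <- list()
  walk <- function(nd) {
    if (length(nd$admixed))
      admixed_sets[[length(admixed_sets) + 1L]] <<- list(node = nd$id, pops = nd$admixed)
    if (nd$leaf && !length(nd$children)) {
      leaves[[length(leaves) + 1L]] <<- nd$pops
    } else {
      for (ch in nd$children) walk(ch)
      if (nd$leaf) leaves[[length(leaves) + 1L]] <<- setdiff(
        nd$pops, unlist(lapply(nd$children, function(c) c$pops)))
    }
  }
  walk(root)
  leaves <- leaves[lengths(leaves) > 0]
  structure(list(root = root, leaves = leaves,
                 k_opt_flock = length(leaves),
                 admixed_sets = admixed_sets),
            class = "hierarchy_tree")
}

#' @export
print.hierarchy_tree <- function(x, ...) {
  cat("hierarchical reallocation clustering:", x$k_opt_flock,
      "undividable leaves\n")
  render <- function(nd, indent) {
    tag <- if (nd$leaf && !length(nd$children)) "leaf" else paste0("k=", nd$k)
    cat(strrep("  ", indent), "- [", tag, "] ",
        paste(nd$pops, collapse = ","), "\n", sep = "")
    for (ch in nd$children) render(ch, indent + 1)
  }
  render(x$root, 0)
  invisible(x)
}
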