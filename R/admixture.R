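#' Sampler configuration for the admixture clustering engine
#'
#' @param burnin discarded iterations.
#' @param iterations recorded iterations after burn-in.
#' @param lambda Dirichlet prior parameter for cluster allele frequencies
#'   (uncorrelated-frequency prior; default 1).
#' @param alpha_init initial admixture Dirichlet parameter (default 1);
#'   alpha is a single scalar shared by all clusters.
#' @param alpha_proposal_sd random-walk Metropolis step for alpha
#'   (default 0.025).
#' @param infer_alpha update alpha (uniform prior on (0, 10]) or keep fixed.
#' @param thin trace thinning interval (default 10).
#' @param seed integer seed.
#' @return a `sampler_config` list
#' @export
sampler_config <- function(burnin = 1000L, iterations = 2000L, lambda = 1,
                           alpha_init = 1, alpha_proposal_sd = 0.025,
                           infer_alpha = TRUE, thin = 10L, seed = 1L) {
  if (iterations <= 0 || burnin < 0) stop("iterations must be > 0 and burnin >= 0")
  if (lambda <= 0 || alpha_init <= 0 || alpha_proposal_sd <= 0)
    stop("lambda, alpha_init and alpha_proposal_sd must be positive")
  if (thin < 1 || thin > iterations) stop("thin must be in [1, iterations]")
  structure(list(burnin = as.integer(burnin), iterations = as.integer(iterations),
                 lambda = lambda, alpha_init = alpha_init,
                 alpha_proposal_sd = alpha_proposal_sd,
                 infer_alpha = isTRUE(infer_alpha), thin = as.integer(thin),
                 seed = as.integer(seed)), class = "sampler_config")
}

replicate_run <- function(k, ln_p_of_k, q, alpha_trace = numeric(0),
                          ln_l_trace = numeric(0)) {
  structure(list(k = as.integer(k), ln_p_of_k = ln_p_of_k, q = q,
                 alpha_trace = alpha_trace, ln_l_trace = ln_l_trace),
            class = "replicate_run")
}

#' @export
print.replicate_run <- function(x, ...) {
  cat(sprintf("admixture replicate: K = %d, n = %d, ln P(X|K) = %.2f\n",
              x$k, nrow(x$q), x$ln_p_of_k))
  invisible(x)
}

#' Run one MCMC replicate of the admixture clustering model
#'
#' Gibbs updates of allele-origin labels, cluster allele frequencies and
#' individual ancestry, with an optional Metropolis update of the shared
#' admixture parameter alpha.  The reported `ln_p_of_k` is the estimator
#' `mean(lnL) - var(lnL)/2` over the post-burn-in (thinned) data
#' log-likelihood trace; `q` is the posterior mean ancestry matrix.
#'
#' @param g a [genotype_matrix()]
#' @param k number of clusters (>= 1)
#' @param cfg a [sampler_config()]
#' @return a `replicate_run`
#' @export
run_replicate <- function(g, k, cfg = sampler_config()) {
  stopifnot(inherits(cfg, "sampler_config"))
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (n_ind(g) == 0) stop("empty dataset")
  if (k > 2L * n_ind(g)) stop("k exceeds the number of allele copies")
  rec <- recode_all(g)
  L <- n_loci(g); n <- n_ind(g)
  a1 <- matrix(0L, n, L); a2 <- matrix(0L, n, L)
  n_alleles <- integer(L)
  for (l in seq_len(L)) {
    a1[, l] <- ifelse(is.na(rec[[l]]$a1), 0L, rec[[l]]$a1)
    a2[, l] <- ifelse(is.na(rec[[l]]$a2), 0L, rec[[l]]$a2)
    n_alleles[l] <- max(1L, length(rec[[l]]$codes))
  }
  res <- with_seed(cfg$seed, {
    admix_gibbs_cpp(a1, a2, n_alleles, k, cfg$lambda, cfg$alpha_init,
                    cfg$alpha_proposal_sd, cfg$infer_alpha,
                    cfg$burnin, cfg$iterations, cfg$thin)
  })
  # mean and variance taken over every post-burn-in sweep (the thinned
  # trace is kept for convergence diagnostics only)
  lnp <- res$lnl_mean - res$lnl_var / 2
  q <- res$q
  rownames(q) <- g$ids
  replicate_run(k, lnp, q, alpha_trace = res$alpha_trace,
                ln_l_trace = res$lnl_trace)
}

new_kscan <- function(grid, runs_by_k) {
  stopifnot(length(grid) == length(runs_by_k))
  if (!length(grid)) stop("empty K grid")
  structure(list(grid = as.integer(grid), runs = runs_by_k), class = "kscan")
}

#' @export
print.kscan <- function(x, ...) {
  r <- vapply(x$runs, length, integer(1))
  cat("kscan over K = {", paste(x$grid, collapse = ", "), "}, replicates per K: ",
      paste(unique(r), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Replicated K-scan of the admixture engine
#'
#' Runs `r` independent replicates of [run_replicate()] per grid value,
#' with per-replicate seeds derived deterministically from
#' `(cfg$seed, K, replicate index)` so results do not depend on execution
#' order.
#'
#' @param g a [genotype_matrix()]
#' @param grid integer vector of K values
#' @param r replicates per K
#' @param cfg a [sampler_config()]
#' @return a `kscan`
#' @export
run_kscan <- function(g, grid, r, cfg = sampler_config()) {
  grid <- sort(unique(as.integer(grid)))
  if (!length(grid)) stop("empty K grid")
  if (r < 1) stop("r must be >= 1")
  runs <- lapply(grid, function(k) {
    lapply(seq_len(r), function(i) {
      cfg_i <- cfg
      cfg_i$seed <- derive_seed(cfg$seed, "kscan", k, i)
      run_replicate(g, k, cfg_i)
    })
  })
  names(runs) <- as.character(grid)
  new_kscan(grid, runs)
}

## ln P(X|K) values for one K as a vector over replicates.
kscan_lnp <- function(scan, k) {
  vapply(scan$runs[[as.character(k)]], function(r) r$ln_p_of_k, numeric(1))
}

## Restrict a kscan to a subset of replicate indices (per K) or to a set of
## runs selected by a predicate; used by block analysis and mode filtering.
kscan_subset <- function(scan, idx_by_k) {
  runs <- lapply(seq_along(scan$grid), function(j) {
    k <- as.character(scan$grid[j])
    scan$runs[[k]][idx_by_k[[k]]]
  })
  names(runs) <- as.character(scan$grid)
  keep <- lengths(runs) > 0
  new_kscan(scan$grid[keep], runs[keep])
}

#' Descriptive convergence summary of one replicate's traces
#'
#' Mirrors the visual convergence check: for the alpha and log-likelihood
#' traces, the absolute difference between the means of the last window
#' and the preceding window, scaled by the pooled SD of the two windows;
#' a flag is raised when the drift exceeds `flag_threshold`.
#'
#' @param run a `replicate_run`
#' @param window window size as a fraction of the trace (< 0.5)
#' @param flag_threshold drift level that raises a flag (default 0.5)
#' @return list with `alpha_drift`, `lnl_drift`, `flags`
#' @export
convergence_summary <- function(run, window = 0.25, flag_threshold = 0.5) {
  if (window >= 0.5 || window <= 0) stop("window must lie in (0, 0.5)")
  drift1 <- function(x) {
    if (!length(x)) stop("empty trace")
    if (length(x) < 4) return(0)
    w <- max(1L, floor(length(x) * window))
    last <- x[(length(x) - w + 1):length(x)]
    prev <- x[(length(x) - 2 * w + 1):(length(x) - w)]
    s <- stats::sd(c(last, prev))
    d <- abs(mean(last) - mean(prev))
    if (s == 0) return(if (d == 0) 0 else Inf)
    d / s
  }
  ad <- drift1(run$alpha_trace)
  ld <- drift1(run$ln_l_trace)
  flags <- character(0)
  if (is.finite(ad) && ad > flag_threshold || is.infinite(ad)) flags <- c(flags, "alpha_drift")
  if (is.finite(ld) && ld > flag_threshold || is.infinite(ld)) flags <- c(flags, "lnl_drift")
  list(alpha_drift = ad, lnl_drift = ld, flags = flags)
}
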