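#' Design of a drift-based power simulation
#'
#' Populations drift independently from a common base frequency pool for
#' `t` generations at effective size `Ne` (per-generation binomial
#' resampling of 2*Ne allele copies), which yields an expected
#' `F_ST = 1 - (1 - 1/(2*Ne))^t`.  At `t = 0` all populations share the
#' base frequencies and the rejection rate estimates the type-I error.
#'
#' @param ne effective population size
#' @param t number of generations of drift (0 for the null design)
#' @param n_pops number of populations (reference breed-panel design: 94)
#' @param n_per_pop diploid individuals sampled per population (25)
#' @param replicates number of simulation replicates
#' @param alpha significance level
#' @param tests subset of `c("fisher_exact", "chi_square")`
#' @return a `power_design` list with the derived `expected_fst`
#' @export
power_design <- function(ne, t, n_pops = 94L, n_per_pop = 25L,
                         replicates = 1000L, alpha = 0.05,
                         tests = c("fisher_exact", "chi_square")) {
  ne <- as.integer(ne); t <- as.integer(t)
  if (t > 0 && ne <= 0) stop("Ne must be positive when t > 0")
  if (replicates < 1) stop("replicates must be >= 1")
  tests <- match.arg(tests, several.ok = TRUE)
  efst <- expected_fst(ne, t)
  if (efst < 0 || efst >= 1) stop("expected_fst must lie in [0, 1)")
  structure(list(ne = ne, t = t, n_pops = as.integer(n_pops),
                 n_per_pop = as.integer(n_per_pop),
                 replicates = as.integer(replicates), alpha = alpha,
                 tests = tests, expected_fst = efst),
            class = "power_design")
}

#' Expected F_ST after t generations of drift at effective size Ne
#' @param ne effective population size
#' @param t generations
#' @return `1 - (1 - 1/(2*ne))^t` (0 when `t = 0`)
#' @export
expected_fst <- function(ne, t) {
  if (t == 0) return(0)
  1 - (1 - 1 / (2 * ne))^t
}

#' Generations of drift needed to reach a target expected F_ST
#' @param ne effective population size
#' @param fst target expected F_ST
#' @return real-valued number of generations
#' @export
generations_for_fst <- function(ne, fst) log(1 - fst) / log(1 - 1 / (2 * ne))

## Monte Carlo Fisher exact probability test on one contingency table:
## i.i.d. sampling from the exact conditional null given both margins
## (Patefield algorithm via stats::r2dtable); probability ordering with the
## add-one rule.
fisher_exact_mc <- function(tab, b = 200L) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(1)
  stat_obs <- -sum(lgamma(tab + 1))            # larger = more probable
  sims <- stats::r2dtable(b, rowSums(tab), colSums(tab))
  stat_sim <- -vapply(sims, function(m) sum(lgamma(m + 1)), numeric(1))
  (1 + sum(stat_sim <= stat_obs + 1e-9)) / (b + 1)
}

## Per-locus chi-square statistic and df on a populations x alleles table.
chisq_stat <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(c(stat = 0, df = 0))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  c(stat = sum((tab - e)^2 / e), df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

#' POWSIM-style power / type-I-error simulation
#'
#' Per replicate: each population's allele frequencies drift from the base
#' frequencies by per-generation binomial resampling (size `2*Ne`,
#' `t` generations); `n_per_pop` diploids are sampled per population under
#' HWE; genetic uniformity is tested globally.  The Fisher exact test is
#' evaluated per locus by Monte Carlo sampling from the exact conditional
#' null and combined across loci with Fisher's method; the chi-square test
#' sums per-locus statistics and degrees of freedom.  Power is the
#' rejection proportion at `alpha`; a `t = 0` design yields the type-I
#' error.
#'
#' @param freqs base allele frequencies: a loci x alleles matrix, an
#'   `allele_freq_table` (its ancestral pool is used), or a
#'   [sim_scenario()] (ancestral frequencies are sampled from it)
#' @param d a [power_design()]
#' @param fisher_b Monte Carlo tables per locus for the Fisher exact test
#' @param seed integer seed
#' @return a `power_result`: list with `rejection` (named proportion per
#'   test), `p_values` (replicates x tests), `design`
#' @export
power_sim <- function(freqs, d, fisher_b = 200L, seed = 1L) {
  stopifnot(inherits(d, "power_design"))
  base <- if (inherits(freqs, "allele_freq_table")) {
    attr(freqs, "ancestral")
  } else if (inherits(freqs, "sim_scenario")) {
    attr(sample_frequencies(freqs), "ancestral")
  } else as.matrix(freqs)
  L <- nrow(base); A <- ncol(base)
  if (any(base < 0) || any(abs(rowSums(base) - 1) > 1e-6))
    stop("base frequency rows must be non-negative and sum to 1")
  P <- d$n_pops; n2 <- 2L * d$n_per_pop
  pv <- matrix(NA_real_, d$replicates, 2,
               dimnames = list(NULL, c("fisher_exact", "chi_square")))
  for (rep_i in seq_len(d$replicates)) {
    res <- with_seed(derive_seed(seed, "powsim", rep_i), {
      # drift, then sample allele counts (HWE: 2n iid allele copies)
      counts <- array(0L, dim = c(P, L, A))
      for (p in seq_len(P)) {
        f <- base
        if (d$t > 0) {
          for (gen in seq_len(d$t)) {
            for (l in seq_len(L))
              f[l, ] <- stats::rmultinom(1, 2L * d$ne, f[l, ])[, 1] / (2 * d$ne)
          }
        }
        for (l in seq_len(L))
          counts[p, l, ] <- stats::rmultinom(1, n2, f[l, ])[, 1]
      }
      out <- c(fisher_exact = NA_real_, chi_square = NA_real_)
      if ("fisher_exact" %in% d$tests) {
        pl <- vapply(seq_len(L), function(l)
          fisher_exact_mc(counts[, l, ], b = fisher_b), numeric(1))
        out["fisher_exact"] <- combine_and_correct(pl, "fisher_combined")
      }
      if ("chi_square" %in% d$tests) {
        st <- vapply(seq_len(L), function(l) chisq_stat(counts[, l, ]), numeric(2))
        tot <- sum(st["stat", ]); df <- sum(st["df", ])
        out["chi_square"] <- if (df > 0)
          stats::pchisq(tot, df, lower.tail = FALSE) else 1
      }
      out
    })
    pv[rep_i, ] <- res
  }
  pv <- pv[, d$tests, drop = FALSE]
  rejection <- colMeans(pv < d$alpha)
  structure(list(rejection = rejection, p_values = pv, design = d),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  lab <- if (x$design$t == 0) "type-I error" else "power"
  cat(sprintf("POWSIM-style simulation: expected F_ST = %.4g, %d replicates\n",
              x$design$expected_fst, x$design$replicates))
  for (nm in names(x$rejection))
    cat(sprintf("  %s %s: %.3f\n", nm, lab, x$rejection[nm]))
  invisible(x)
}
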