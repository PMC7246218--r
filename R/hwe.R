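## Genotype count matrix (lower triangle, alleles recoded 1..A) for one
## population x locus cell.  Returns NULL when no non-missing genotype.
geno_counts <- function(g, pop, locus) {
  rows <- which(g$pop == pop)
  if (!length(rows)) stop("unknown population: ", pop)
  l <- if (is.character(locus)) match(locus, g$loci) else as.integer(locus)
  if (is.na(l)) stop("unknown locus: ", locus)
  a1 <- g$allele1[rows, l]; a2 <- g$allele2[rows, l]
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]
  if (!length(a1)) return(NULL)
  codes <- sort(unique(c(a1, a2)))
  A <- length(codes)
  i <- match(pmax(a1, a2), codes)  # row >= col
  j <- match(pmin(a1, a2), codes)
  cnt <- matrix(0L, A, A)
  for (k in seq_along(i)) cnt[i[k], j[k]] <- cnt[i[k], j[k]] + 1L
  cnt
}

## log of the unnormalized Levene array weight: H*log(2) - sum(log n_ij!)
levene_logweight <- function(cnt) {
  het <- sum(cnt) - sum(diag(cnt))
  het * log(2) - sum(lgamma(cnt[lower.tri(cnt, diag = TRUE)] + 1))
}

## Exact HWE test by full enumeration for diallelic loci: enumerate the
## heterozygote count over its parity class under the Levene distribution.
hwe_exact_enum2 <- function(cnt) {
  stopifnot(nrow(cnt) == 2)
  n11 <- cnt[1, 1]; n12 <- cnt[2, 1]; n22 <- cnt[2, 2]
  m1 <- 2 * n11 + n12; m2 <- 2 * n22 + n12
  hets <- seq(m1 %% 2, min(m1, m2), by = 2)
  logw <- vapply(hets, function(h) {
    a <- (m1 - h) / 2; b <- (m2 - h) / 2
    h * log(2) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1)
  }, numeric(1))
  logw <- logw - max(logw)
  pr <- exp(logw) / sum(exp(logw))
  obs <- pr[match(n12, hets)]
  sum(pr[pr <= obs + 1e-12])
}

#' Exact Hardy-Weinberg test for one population x locus cell
#'
#' Probability-ordering exact test conditional on the allele counts (the
#' Levene distribution).  Diallelic loci are evaluated by complete
#' enumeration; multi-allelic loci by a Markov chain over genotype arrays
#' (random pairing of allele copies sampled by slot swaps, with
#' dememorization and batching as in the Guo-Thompson scheme), whose batch
#' spread yields a Monte Carlo standard error.
#'
#' @param g a [genotype_matrix()]
#' @param pop population label
#' @param locus locus name or index
#' @param mc list with `dememorization`, `batches`, `iterations_per_batch`,
#'   `seed` controlling the Markov chain
#' @param method `"auto"` (enumeration when the locus is diallelic),
#'   `"mc"`, or `"enumeration"` (diallelic only)
#' @return the p-value, with attributes `se` (MC standard error; 0 for the
#'   enumeration path) and `degenerate` (TRUE for a monomorphic locus,
#'   where p = 1 by construction)
#' @export
hwe_exact_test <- function(g, pop, locus,
                           mc = list(dememorization = 10000, batches = 100,
                                     iterations_per_batch = 5000, seed = 1),
                           method = c("auto", "mc", "enumeration")) {
  method <- match.arg(method)
  cnt <- geno_counts(g, pop, locus)
  if (is.null(cnt)) stop("all genotypes missing for population ", pop,
                         " at locus ", locus)
  A <- nrow(cnt)
  m <- rowSums(cnt) + colSums(cnt)  # m_a = 2*hom_a + het involving a
  if (sum(m > 0) <= 1)
    return(structure(1, se = 0, degenerate = TRUE))
  if (A == 2 && (method %in% c("auto", "enumeration")))
    return(structure(hwe_exact_enum2(cnt), se = 0, degenerate = FALSE))
  if (method == "enumeration")
    stop("enumeration path implemented for diallelic loci only")
  # Markov chain: explicit allele-slot vector, uniform target over pairings
  a1 <- integer(0); a2 <- integer(0)
  for (i in seq_len(A)) for (j in seq_len(i)) {
    k <- cnt[i, j]
    if (k > 0) { a1 <- c(a1, rep(i, k)); a2 <- c(a2, rep(j, k)) }
  }
  with_seed(as.integer(mc$seed %||% 1), {
    res <- hwe_mc_chain(a1, a2, A,
                        as.integer(mc$dememorization),
                        as.integer(mc$batches),
                        as.integer(mc$iterations_per_batch))
  })
  p_b <- res$batch_p
  p <- mean(p_b)
  se <- stats::sd(p_b) / sqrt(length(p_b))
  structure(p, se = se, degenerate = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
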