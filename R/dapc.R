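#' PCA of allele-count-encoded genotypes
#'
#' Genotypes are encoded as per-allele dosage vectors (0/1/2 per observed
#' allele per locus); missing entries are replaced by the locus-allele
#' mean, columns are centered, and all components with positive eigenvalue
#' are retained.
#'
#' @param g a [genotype_matrix()]
#' @return a `genotype_pca`: list with `scores` (individuals x components),
#'   `eigenvalues`, `encoding` (the centered dosage matrix)
#' @export
genotype_pca <- function(g) {
  if (n_ind(g) < 2) stop("need >= 2 individuals")
  rec <- recode_all(g)
  cols <- list()
  for (l in seq_len(n_loci(g))) {
    A <- length(rec[[l]]$codes)
    if (A == 0) stop("all-missing locus: ", g$loci[l])
    a1 <- rec[[l]]$a1; a2 <- rec[[l]]$a2
    for (a in seq_len(A)) {
      dose <- (a1 == a) + (a2 == a)
      mu <- mean(dose, na.rm = TRUE)
      dose[is.na(dose)] <- mu
      cols[[length(cols) + 1L]] <- dose
    }
  }
  x <- do.call(cbind, cols)
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  ev <- sv$d^2 / (nrow(x) - 1)
  tol <- max(ev) * 1e-9
  pos <- which(ev > tol)
  scores <- sv$u[, pos, drop = FALSE] %*% diag(sv$d[pos], length(pos))
  rownames(scores) <- g$ids
  colnames(scores) <- paste0("PC", seq_along(pos))
  structure(list(scores = scores, eigenvalues = ev[pos], encoding = x),
            class = "genotype_pca")
}

#' BIC curve of k-means clusterings of PCA scores
#'
#' For each K, k-means (best of `n_starts` starts) on the retained scores;
#' `BIC(K) = n * log(W_K / n) + K * log(n)` with `W_K` the total
#' within-cluster sum of squares.
#'
#' @param scores individuals x components score matrix (or a
#'   `genotype_pca`)
#' @param k_max largest K evaluated (must be < n individuals)
#' @param n_starts k-means restarts per K (default 10)
#' @param seed integer seed
#' @param k_min smallest K evaluated (default 1)
#' @return a `bic_curve` data frame with columns `k`, `bic` and attribute
#'   `clusters` (list of cluster assignments per K)
#' @export
bic_scan <- function(scores, k_max, n_starts = 10L, seed = 1L, k_min = 1L) {
  if (inherits(scores, "genotype_pca")) scores <- scores$scores
  n <- nrow(scores)
  if (k_max >= n) stop("k_max must be < number of individuals")
  ks <- k_min:k_max
  bic <- numeric(length(ks))
  clusters <- vector("list", length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    fit <- with_seed(derive_seed(seed, "bic", k), {
      if (k == 1) {
        list(tot.withinss = sum(scale(scores, scale = FALSE)^2),
             cluster = rep(1L, n))
      } else {
        stats::kmeans(scores, centers = k, nstart = n_starts, iter.max = 50)
      }
    })
    w <- fit$tot.withinss
    bic[j] <- n * log(w / n) + k * log(n)
    clusters[[j]] <- fit$cluster
  }
  structure(data.frame(k = ks, bic = bic),
            clusters = stats::setNames(clusters, ks),
            class = c("bic_curve", "data.frame"))
}

#' Select K at the sharp change of a BIC curve (Ward criterion)
#'
#' The successive differences of the BIC curve are split into two groups
#' by Ward's minimum-variance clustering; the selected K is the one right
#' after the last difference in the steep-decrease group.  A constant (or
#' non-decreasing) curve returns the smallest K with a `no_structure`
#' flag.
#'
#' @param bic_curve a [bic_scan()] result (or data frame with `k`, `bic`)
#' @return selected K with attribute `no_structure`
#' @export
select_k_ward <- function(bic_curve) {
  k <- bic_curve$k; b <- bic_curve$bic
  if (length(k) < 4) stop("need a BIC curve over >= 4 K values")
  d <- diff(b)
  if (max(d) - min(d) < 1e-12)
    return(structure(k[1], no_structure = TRUE))
  grp <- stats::cutree(stats::hclust(stats::dist(d), method = "ward.D2"), k = 2)
  steep <- which.min(tapply(d, grp, mean))
  if (tapply(d, grp, mean)[steep] >= 0)
    return(structure(k[1], no_structure = TRUE))
  sel <- k[max(which(grp == steep)) + 1L]
  structure(sel, no_structure = FALSE)
}

#' Discriminant analysis of principal components
#'
#' Linear discriminant analysis on the first `retained_pcs` PCA scores
#' against the given cluster labels; posterior memberships come from the
#' discriminant-space Gaussian model restricted to `retained_das`
#' discriminant functions, and per-cluster reassignment proportions
#' compare the posterior argmax with the input labels.
#'
#' @param scores score matrix or `genotype_pca`
#' @param clusters integer/factor cluster labels per individual
#' @param retained_pcs number of leading PCs used (default 50, roughly a
#'   third of the components a 15-locus microsatellite panel yields)
#' @param retained_das number of discriminant functions used (default 8)
#' @return a `dapc_result`: `posteriors`, `reassignment` (per cluster),
#'   `assign` (posterior argmax), `lda` fit
#' @export
fit_dapc <- function(scores, clusters, retained_pcs = 50L, retained_das = 8L) {
  if (inherits(scores, "genotype_pca")) scores <- scores$scores
  clusters <- factor(clusters)
  if (any(table(clusters) < 2)) stop("every cluster needs >= 2 members")
  npc <- min(retained_pcs, ncol(scores))
  x <- scores[, seq_len(npc), drop = FALSE]
  nda <- min(retained_das, nlevels(clusters) - 1L)
  fit <- MASS::lda(x, grouping = clusters)
  pred <- stats::predict(fit, dimen = max(1L, nda))
  post <- pred$posterior
  assign <- factor(colnames(post)[max.col(post)], levels = levels(clusters))
  reass <- vapply(levels(clusters), function(cl) {
    mean(assign[clusters == cl] == cl)
  }, numeric(1))
  structure(list(posteriors = post, reassignment = reass, assign = assign,
                 retained_pcs = npc, retained_das = nda, lda = fit),
            class = "dapc_result")
}

#' Full DAPC pipeline with BIC-based K selection
#'
#' PCA encoding, BIC scan over K, Ward sharp-change selection of
#' `K_opt[DAPC]`, then discriminant analysis at the selected K.
#'
#' @param g a [genotype_matrix()]
#' @param k_max largest K scanned (default: number of populations, capped
#'   at n - 1)
#' @param retained_pcs,retained_das see [fit_dapc()]
#' @param n_starts,seed see [bic_scan()]
#' @return a `dapc_scan`: `pca`, `bic_curve`, `k_opt_dapc`, `dapc`
#'   (the fit at the selected K, `NULL` when K = 1)
#' @export
dapc_engine <- function(g, k_max = NULL, retained_pcs = 50L, retained_das = 8L,
                        n_starts = 10L, seed = 1L) {
  pca <- genotype_pca(g)
  if (is.null(k_max)) k_max <- nlevels(g$pop)
  k_max <- min(k_max, n_ind(g) - 1L)
  curve <- bic_scan(pca, k_max = k_max, n_starts = n_starts, seed = seed)
  kopt <- select_k_ward(curve)
  dapc <- NULL
  if (kopt > 1) {
    cl <- attr(curve, "clusters")[[as.character(kopt)]]
    dapc <- fit_dapc(pca, cl, retained_pcs = retained_pcs,
                     retained_das = retained_das)
  }
  structure(list(pca = pca, bic_curve = curve, k_opt_dapc = as.integer(kopt),
                 no_structure = isTRUE(attr(kopt, "no_structure")),
                 dapc = dapc),
            class = "dapc_scan")
}

#' @export
print.dapc_scan <- function(x, ...) {
  cat(sprintf("DAPC: K_opt = %d%s\n", x$k_opt_dapc,
              if (x$no_structure) " (no-structure flag)" else ""))
  if (!is.null(x$dapc))
    cat(sprintf("  mean reassignment: %.3f\n", mean(x$dapc$reassignment)))
  invisible(x)
}
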