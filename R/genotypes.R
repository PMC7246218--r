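#' Diploid multi-locus genotype matrix
#'
#' The central data container: unordered diploid allele pairs for
#' `n_individuals` individuals at `n_loci` microsatellite loci, with a
#' population label per individual.  Allele calls are non-negative integer
#' codes; a missing genotype is stored as `NA` in *both* allele slots of a
#' locus (half-missing genotypes are rejected).
#'
#' @param allele1,allele2 integer matrices (individuals x loci) holding the
#'   two allele codes of each genotype.  Because genotypes are unphased the
#'   pair is unordered; all downstream likelihoods treat heterozygotes with
#'   multiplicity 2.
#' @param pop character or factor vector of population labels, one per
#'   individual.  Every population must be non-empty (guaranteed by
#'   construction).
#' @param loci optional locus names; defaults to `L1..Ln`.
#' @param ids optional individual identifiers; defaults to `ind1..indn`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `allele1`, `allele2` (integer matrices), `pop` (factor), `loci`, `ids`.
#' @export
genotype_matrix <- function(allele1, allele2, pop, loci = NULL, ids = NULL) {
  allele1 <- as.matrix(allele1)
  allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "integer"
  storage.mode(allele2) <- "integer"
  if (!all(dim(allele1) == dim(allele2)))
    stop("allele1 and allele2 must have identical dimensions")
  n <- nrow(allele1); L <- ncol(allele1)
  if (length(pop) != n)
    stop("pop must have one label per individual")
  half <- xor(is.na(allele1), is.na(allele2))
  if (any(half))
    stop("half-missing genotypes are not allowed (both allele slots must be NA or observed)")
  if (any(allele1 < 0L, na.rm = TRUE) || any(allele2 < 0L, na.rm = TRUE))
    stop("allele codes must be non-negative integers")
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  if (length(loci) != L) stop("loci must have one name per locus")
  if (length(ids) != n) stop("ids must have one identifier per individual")
  pop <- factor(pop, levels = unique(as.character(pop)))
  dimnames(allele1) <- dimnames(allele2) <- list(ids, loci)
  structure(
    list(allele1 = allele1, allele2 = allele2, pop = pop,
         loci = as.character(loci), ids = as.character(ids)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_ind(x), "individuals x", n_loci(x), "loci,",
      nlevels(x$pop), "populations\n")
  miss <- mean(is.na(x$allele1))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.genotype_matrix <- function(object, ...) {
  tab <- table(object$pop)
  cat("genotype_matrix:", n_ind(object), "individuals,", n_loci(object),
      "loci,", length(tab), "populations\n")
  cat("individuals per population:\n")
  print(tab)
  nal <- vapply(seq_len(n_loci(object)), function(l)
    length(unique(stats::na.omit(c(object$allele1[, l], object$allele2[, l])))),
    integer(1))
  cat("alleles per locus: ", paste(nal, collapse = " "), "\n")
  invisible(object)
}

n_ind  <- function(g) nrow(g$allele1)
n_loci <- function(g) ncol(g$allele1)
pop_names <- function(g) levels(g$pop)

#' Restrict a genotype matrix to a subset of populations
#'
#' @param g a [genotype_matrix()]
#' @param pops character vector of population labels to keep
#' @return a `genotype_matrix` containing only those individuals
#' @export
subset_populations <- function(g, pops) {
  unknown <- setdiff(pops, levels(g$pop))
  if (length(unknown))
    stop("unknown population(s): ", paste(unknown, collapse = ", "))
  if (!length(pops)) stop("empty population subset")
  keep <- g$pop %in% pops
  genotype_matrix(g$allele1[keep, , drop = FALSE],
                  g$allele2[keep, , drop = FALSE],
                  pop = as.character(g$pop[keep]),
                  loci = g$loci, ids = g$ids[keep])
}

#' @rdname subset_populations
#' @param idx integer vector of individual row indices to keep
#' @export
subset_individuals <- function(g, idx) {
  genotype_matrix(g$allele1[idx, , drop = FALSE],
                  g$allele2[idx, , drop = FALSE],
                  pop = as.character(g$pop[idx]),
                  loci = g$loci, ids = g$ids[idx])
}

## Recode the alleles of one locus to consecutive integers 1..A.
## Returns list(a1, a2, codes): a1/a2 are vectors over individuals (NA kept).
recode_locus <- function(g, l) {
  a1 <- g$allele1[, l]; a2 <- g$allele2[, l]
  codes <- sort(unique(stats::na.omit(c(a1, a2))))
  list(a1 = match(a1, codes), a2 = match(a2, codes), codes = codes)
}

## Integer-recoded view of the whole matrix: list of per-locus recodings.
recode_all <- function(g) lapply(seq_len(n_loci(g)), function(l) recode_locus(g, l))

#' Compare two genotype matrices for equality
#'
#' Unordered-pair semantics: genotypes {a,b} and {b,a} compare equal.
#' @param a,b genotype matrices
#' @return logical
#' @export
genotypes_identical <- function(a, b) {
  if (n_ind(a) != n_ind(b) || n_loci(a) != n_loci(b)) return(FALSE)
  if (!identical(as.character(a$pop), as.character(b$pop))) return(FALSE)
  if (!identical(a$loci, b$loci) || !identical(a$ids, b$ids)) return(FALSE)
  lo_a <- pmin(a$allele1, a$allele2); hi_a <- pmax(a$allele1, a$allele2)
  lo_b <- pmin(b$allele1, b$allele2); hi_b <- pmax(b$allele1, b$allele2)
  identical(is.na(lo_a), is.na(lo_b)) &&
    all(lo_a == lo_b, na.rm = TRUE) && all(hi_a == hi_b, na.rm = TRUE)
}
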