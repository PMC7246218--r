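#' Principal coordinates analysis of a distance matrix
#'
#' Gower double-centering of `-0.5 * D^2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their
#' (positive) eigenvalues, and explained proportions are eigenvalues over
#' the sum of positive eigenvalues.
#'
#' @param distances square symmetric matrix with zero diagonal (e.g. a
#'   pairwise F_ST matrix)
#' @return a `pcoa_result` with `coordinates`, `explained`, `eigenvalues`
#' @export
pcoa <- function(distances) {
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (max(abs(diag(d))) > 1e-8) stop("distance matrix must have zero diagonal")
  n <- nrow(d)
  jc <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * jc %*% (d^2) %*% jc
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  if (!length(pos)) {
    coords <- matrix(0, n, 1, dimnames = list(rownames(d), "Axis1"))
    return(structure(list(coordinates = coords, explained = 1,
                          eigenvalues = e$values), class = "pcoa_result"))
  }
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), length(pos))
  dimnames(coords) <- list(rownames(d), paste0("Axis", seq_along(pos)))
  structure(list(coordinates = coords,
                 explained = e$values[pos] / sum(e$values[pos]),
                 eigenvalues = e$values),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "points,", ncol(x$coordinates),
      "positive axes\n")
  cat("explained (first 3):",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained, 3)), collapse = " "),
      "\n")
  invisible(x)
}
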