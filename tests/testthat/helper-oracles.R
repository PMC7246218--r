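# Independent statistical oracles shared by unit and acceptance tests.

# independent oracle: nested ANOVA mean squares on per-allele indicator
# variables (gametes within individuals within populations)
wc_anova_oracle <- function(g) {
  pops <- levels(g$pop)
  sums <- c(a = 0, b = 0, c = 0)
  for (l in seq_len(ncol(g$allele1))) {
    a1 <- g$allele1[, l]; a2 <- g$allele2[, l]
    keep_pop <- pops[vapply(pops, function(p)
      sum(!is.na(a1[g$pop == p])) >= 2, logical(1))]
    if (length(keep_pop) < 2) next
    keep <- !is.na(a1) & g$pop %in% keep_pop
    popf <- factor(as.character(g$pop[keep]))
    x1 <- a1[keep]; x2 <- a2[keep]
    n_i <- as.vector(table(popf)); r <- length(n_i)
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (al in sort(unique(c(x1, x2)))) {
      y <- cbind(as.numeric(x1 == al), as.numeric(x2 == al))
      ybar_i <- tapply(rowMeans(y), popf, mean)      # pop means
      ybar <- sum(n_i * ybar_i) / sum(n_i)
      yind <- rowMeans(y)
      # sums of squares: populations / individuals / gametes
      ssp <- 2 * sum(n_i * (ybar_i - ybar)^2)
      ssi <- 2 * sum((yind - ybar_i[popf])^2)
      ssg <- sum((y - yind)^2)
      msp <- ssp / (r - 1)
      msi <- ssi / (sum(n_i) - r)
      msg <- ssg / sum(n_i)
      s2g <- msg
      s2i <- (msi - msg) / 2
      s2p <- (msp - msi) / (2 * nc)
      sums <- sums + c(a = s2p, b = s2i, c = s2g)
    }
  }
  list(f_st = sums["a"] / sum(sums),
       f_is = 1 - sums["c"] / (sums["b"] + sums["c"]))
}
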