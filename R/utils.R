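## Stable seed derivation: fold a base seed and a sequence of tags (strings
## or integers) into a 31-bit integer, so every stochastic stage has its own
## reproducible stream and results do not depend on execution order.
derive_seed <- function(seed, ...) {
  tags <- list(...)
  h <- as.double(seed %% 2147483647L)
  for (tag in tags) {
    vals <- if (is.character(tag)) as.double(utf8ToInt(tag)) else as.double(tag)
    for (v in vals) h <- (h * 69069 + v + 1) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) { # numerically degenerate concentration; fall back to argmax
    x[which.max(alpha)] <- 1
  }
  x / sum(x)
}

## Matrix of n Dirichlet(alpha) draws, one per row.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n), rate = 1), nrow = n)
  zero <- rowSums(x) == 0
  if (any(zero)) x[zero, which.max(alpha)] <- 1
  x / rowSums(x)
}
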