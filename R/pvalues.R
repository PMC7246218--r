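#' Combine or adjust a set of p-values
#'
#' `fisher_combined` returns the upper tail of a chi-square with `2k`
#' degrees of freedom evaluated at `-2 * sum(log(p))`; `holm` returns the
#' monotone step-down adjusted p-values clipped at 1.
#'
#' Monte-Carlo p-values must be floored at `1/(N+1)` by the caller (the
#' add-one permutation rule does this automatically); a p of exactly 0 is
#' rejected because Fisher's statistic would be infinite.
#'
#' @param p_values numeric vector of p-values in (0, 1]
#' @param method `"fisher_combined"` or `"holm"`
#' @return a single combined p-value, or the vector of adjusted p-values
#' @export
combine_and_correct <- function(p_values, method = c("fisher_combined", "holm")) {
  method <- match.arg(method)
  if (!length(p_values)) stop("empty p-value list")
  if (any(is.na(p_values))) stop("NA p-values")
  if (any(p_values <= 0))
    stop("p-values must be > 0 (floor Monte Carlo p-values at 1/(N+1))")
  if (any(p_values > 1)) stop("p-values must be <= 1")
  if (method == "fisher_combined") {
    chi2 <- -2 * sum(log(p_values))
    stats::pchisq(chi2, df = 2 * length(p_values), lower.tail = FALSE)
  } else {
    stats::p.adjust(p_values, method = "holm")
  }
}
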