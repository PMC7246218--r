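#' Membership bar chart
#'
#' Stacked bars of (population-averaged) membership coefficients, one bar
#' per population (or per individual when raw q is supplied), sorted by a
#' provided population order.
#'
#' @param q memberships: individuals x K or populations x K matrix
#' @param pop optional individual population labels; when given, `q` is
#'   averaged per population first
#' @param pop_order optional display order of populations
#' @param ... passed to [graphics::barplot()]
#' @return invisibly, the plotted matrix
#' @export
plot_membership <- function(q, pop = NULL, pop_order = NULL, ...) {
  m <- if (!is.null(pop)) mean_q_by_population(q, pop) else as.matrix(q)
  if (!is.null(pop_order)) m <- m[pop_order, , drop = FALSE]
  graphics::barplot(t(m), col = grDevices::hcl.colors(ncol(m), "Dynamic"),
                    border = NA, las = 2, ylab = "membership",
                    legend.text = paste0("C", seq_len(ncol(m))), ...)
  invisible(m)
}

#' @export
plot.delta_k_result <- function(x, ...) {
  graphics::plot(x$k_interior, x$delta_k, type = "b", pch = 19,
                 xlab = "K", ylab = expression(Delta * K), ...)
  graphics::abline(v = x$k_opt_evanno, lty = 2)
  invisible(x)
}

#' @export
plot.kscan <- function(x, ...) {
  mean_l <- vapply(x$grid, function(k) mean(kscan_lnp(x, k)), numeric(1))
  sd_l <- vapply(x$grid, function(k) stats::sd(kscan_lnp(x, k)), numeric(1))
  graphics::plot(x$grid, mean_l, type = "b", pch = 19, xlab = "K",
                 ylab = "mean ln P(X|K)",
                 ylim = range(c(mean_l - sd_l, mean_l + sd_l)), ...)
  graphics::arrows(x$grid, mean_l - sd_l, x$grid, mean_l + sd_l,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' @export
plot.bic_curve <- function(x, ...) {
  graphics::plot(x$k, x$bic, type = "b", pch = 19, xlab = "K", ylab = "BIC", ...)
  invisible(x)
}
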