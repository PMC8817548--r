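# Basic base-graphics exports for the standard CUB diagnostic plots.

#' ENc plot: observed ENc against GC3s with the expected curve
#'
#' @param enc An `enc_table` (or its `genes` data frame).
#' @param ... Passed to [plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_enc <- function(enc, ...) {
  genes <- if (inherits(enc, "enc_table")) enc$genes else enc
  plot(genes$gc3s, genes$enc_obs, xlab = "GC3s", ylab = "ENc",
       xlim = c(0, 1), ylim = c(15, 62), pch = 16, cex = 0.4,
       col = grDevices::adjustcolor("grey30", 0.5), ...)
  f <- seq(0, 1, length.out = 201)
  graphics::lines(f, enc_expected(f), col = "blue", lwd = 2)
  invisible(NULL)
}

#' Neutrality plot: per-gene GC12 against GC3 with the OLS fit
#'
#' @param gc12,gc3 Per-gene values on the same scale.
#' @param fit Optional `neutrality_fit`; computed from the data if omitted.
#' @param ... Passed to [plot()].
#' @return The `neutrality_fit` used, invisibly.
#' @export
plot_neutrality <- function(gc12, gc3, fit = NULL, ...) {
  if (is.null(fit)) fit <- neutrality_fit(gc12, gc3)
  plot(gc3, gc12, xlab = "GC3", ylab = "GC12", pch = 16, cex = 0.4,
       col = grDevices::adjustcolor("grey30", 0.5), ...)
  graphics::abline(fit$intercept, fit$slope, col = "blue", lwd = 2)
  invisible(fit)
}

#' GC3 gradient line plot for one or more species
#'
#' @param gradients A `gc3_gradient` or named list of them.
#' @param ... Passed to [plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_gradient <- function(gradients, ...) {
  if (inherits(gradients, "gc3_gradient")) gradients <- list(gradients)
  ylim <- range(vapply(gradients, function(g) range(g$bins), numeric(2)))
  n <- gradients[[1]]$n_bins
  plot(NULL, xlim = c(1, n), ylim = ylim, xlab = "bin (5' to 3')",
       ylab = "mean GC3", ...)
  cols <- grDevices::hcl.colors(max(length(gradients), 2L), "Dark 3")
  for (i in seq_along(gradients)) {
    graphics::lines(seq_len(n), gradients[[i]]$bins, col = cols[i])
  }
  if (!is.null(names(gradients))) {
    graphics::legend("topright", legend = names(gradients),
                     col = cols[seq_along(gradients)], lty = 1, cex = 0.7)
  }
  invisible(NULL)
}
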