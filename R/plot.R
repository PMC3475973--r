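#' Plot a simulated trajectory
#'
#' Panel plot of a trajectory: intestine size as percentage of its starting
#' value, body burden `C_int`, the instantaneous elimination rate, and the
#' evolution of the contamination-class occupancies.
#'
#' @param x A `tkcd_trajectory`.
#' @param panels Which panels to draw, in order; any subset of `"cells"`,
#'   `"burden"`, `"k"`, `"classes"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.tkcd_trajectory <- function(x, panels = c("cells", "burden", "k",
                                               "classes"), ...) {
  panels <- match.arg(panels, several.ok = TRUE)
  op <- graphics::par(mfrow = c(length(panels), 1),
                      mar = c(4, 4.2, 1.2, 1))
  on.exit(graphics::par(op))
  baseline <- attr(x, "baseline")
  for (p in panels) {
    switch(p,
      cells = graphics::plot(x$t, 100 * x$N_total / baseline, type = "l",
                             xlab = "time (model units)",
                             ylab = "cells (% of start)", ...),
      burden = graphics::plot(x$t, x$C_int, type = "l",
                              xlab = "time (model units)",
                              ylab = expression(C[int]), ...),
      k = graphics::plot(x$t, x$k, type = "l",
                         xlab = "time (model units)",
                         ylab = "elimination rate k", ...),
      classes = {
        l <- attr(x, "params")$l
        cols <- grDevices::hcl.colors(l, "viridis")
        graphics::matplot(x$t, as.matrix(x[, paste0("N_", seq_len(l))]),
                          type = "l", lty = 1, col = cols,
                          xlab = "time (model units)", ylab = "class size")
        graphics::legend("topright", legend = paste("class", seq_len(l)),
                         col = cols, lty = 1, bty = "n", cex = 0.8)
      })
  }
  invisible(x)
}
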