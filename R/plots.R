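#' Plot the two exceedance curves and their deviation
#'
#' Left panel: exceedance (survival) distributions of the co-expression
#' levels in the two groups.  Right panel: their absolute deviation versus
#' the threshold, with the detected cutoff point marked.
#'
#' @param tab Co-expression table from [pairwise_coexpression()].
#' @param cutoff `cutoff_result` from [detect_cutoff()] (optional; when
#'   supplied, C and D are marked).
#' @param file Optional PNG path; when given the plot is written there
#'   instead of the active device.
#' @return `NULL`, invisibly.
#' @export
plot_exceedance <- function(tab, cutoff = NULL, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 1400, height = 650, res = 110)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  grid <- sort(unique(c(tab$c_normal, tab$c_disease)))
  fn <- exceedance(tab$c_normal, grid)
  fd <- exceedance(tab$c_disease, grid)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old), add = TRUE)
  graphics::plot(grid, fn, type = "s", col = "blue", lwd = 2,
                 xlab = "co-expression level", ylab = "Prob(|r| >= level)",
                 main = "Exceedance distributions", ylim = c(0, 1))
  graphics::lines(grid, fd, type = "s", col = "red", lwd = 2)
  graphics::legend("topright", legend = c("normal", "disease"),
                   col = c("blue", "red"), lwd = 2, bty = "n")
  graphics::plot(grid, abs(fd - fn), type = "s", lwd = 2,
                 xlab = "co-expression level", ylab = "|F_d - F_n|",
                 main = "Deviation")
  if (!is.null(cutoff)) {
    graphics::abline(v = cutoff$C, lty = 2, col = "grey40")
    graphics::abline(h = cutoff$D_critical, lty = 3, col = "grey40")
    graphics::points(cutoff$C, cutoff$D, pch = 19, col = "red")
  }
  invisible(NULL)
}

#' Plot the co-expression galaxy
#'
#' Scatter of each pair's disease versus normal co-expression level,
#' partitioned into the four regions by the cutoff lines.
#'
#' @param p Classified pair table from [classify_pairs()].
#' @param C Cutoff (defaults to the one stored by [classify_pairs()]).
#' @param file Optional PNG path.
#' @return `NULL`, invisibly.
#' @export
plot_galaxy <- function(p, C = attr(p, "cutoff"), file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 750, height = 700, res = 110)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  cols <- c(normal_specific_strong = "#1f77b4",
            disease_specific_strong = "#d62728",
            common_strong = "#2ca02c", common_weak = "grey60")
  graphics::plot(p$c_normal, p$c_disease, pch = 16, cex = 0.4,
                 col = cols[as.character(p$category)],
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "co-expression level (normal)",
                 ylab = "co-expression level (disease)",
                 main = "Co-expression galaxy")
  if (!is.null(C)) graphics::abline(v = C, h = C, lty = 2)
  graphics::legend("topleft", legend = names(cols), col = cols,
                   pch = 16, cex = 0.7, bty = "n")
  invisible(NULL)
}
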