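#' Plot a CROC curve in the ROC plane
#'
#' Draws the unit ROC square, the chance diagonal, the CROC solution
#' points joined by the curve, the best point, the gray disc of ROC points
#' that would outperform it (BMI below the best-point BMI) and the dotted
#' iso-BMI boundary. Optional clustering solutions are overlaid as
#' markers, one symbol per algorithm.
#'
#' @param x a [croc_curve()].
#' @param solutions optional data.frame with columns `fpr`, `tpr` and
#'   `algorithm` (e.g. the `solutions` slot of [evaluate_distances()]).
#' @param main plot title; defaults to the distance name.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.croc_curve <- function(x, solutions = NULL, main = NULL, ...) {
  if (is.null(main))
    main <- sprintf("CROC, %s (AUC = %.3f)", x$distance_name, x$auc)
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "FPR",
                 ylab = "TPR", main = main, asp = 1, ...)
  bp <- best_point(x)
  # gray region: disc of radius bmi_star around (0, 1), clipped to the square
  if (bp$bmi_star > 0) {
    th <- seq(0, 2 * pi, length.out = 361L)
    cx <- pmin(pmax(bp$bmi_star * cos(th), 0), 1)
    cy <- pmin(pmax(1 + bp$bmi_star * sin(th), 0), 1)
    graphics::polygon(cx, cy, col = grDevices::gray(0.85), border = NA)
    graphics::lines(cx, cy, lty = 3)
  }
  graphics::abline(0, 1, col = "gray50", lty = 2)
  xs <- c(0, sort(x$points$fpr), 1)
  ys <- c(0, x$points$tpr[order(x$points$fpr, x$points$tpr)], 1)
  graphics::lines(xs, ys, col = "steelblue")
  graphics::points(x$points$fpr, x$points$tpr, pch = 16, col = "steelblue")
  graphics::points(bp$point[1L], bp$point[2L], pch = 21, bg = "green3",
                   cex = 1.4)
  if (!is.null(solutions) && nrow(solutions)) {
    algs <- unique(solutions$algorithm)
    pchs <- stats::setNames((21:25)[seq_along(algs)], algs)
    graphics::points(solutions$fpr, solutions$tpr,
                     pch = pchs[solutions$algorithm], bg = "orange")
    graphics::legend("bottomright", legend = c("CROC", "best point", algs),
                     pch = c(16, 21, unname(pchs)),
                     pt.bg = c(NA, "green3", rep("orange", length(algs))),
                     col = c("steelblue", "black",
                             rep("black", length(algs))),
                     cex = 0.8, bg = "white")
  }
  invisible(x)
}

#' Plot BMI and external indices along a CROC curve
#'
#' For every CROC solution (x-axis: number of clusters) plots the BMI
#' together with the adjusted Rand, Fowlkes-Mallows and F-measure series,
#' visualizing the anti-correlation between the BMI (to be minimized) and
#' the classical indices (to be maximized).
#'
#' @param curve a [croc_curve()].
#' @param gold the [gold_solution()] the curve was built against.
#' @param main plot title.
#' @return invisibly, the data.frame of plotted series.
#' @export
plot_index_curves <- function(curve, gold, main = NULL) {
  ord <- order(curve$points$k)
  k <- curve$points$k[ord]
  series <- data.frame(
    k = k,
    bmi = curve$points$bmi[ord],
    adjusted_rand = vapply(curve$partitions[ord], function(p)
      tryCatch(adjusted_rand(contingency(gold, p)),
               error = function(e) NA_real_), numeric(1L)),
    fowlkes_mallows = vapply(curve$partitions[ord], function(p)
      tryCatch(fowlkes_mallows(contingency(gold, p)),
               error = function(e) NA_real_), numeric(1L)),
    f_measure = vapply(curve$partitions[ord], function(p)
      tryCatch(f_measure(contingency(gold, p)),
               error = function(e) NA_real_), numeric(1L)))
  if (is.null(main))
    main <- sprintf("BMI vs external indices, %s", curve$distance_name)
  rng <- range(unlist(series[-1L]), na.rm = TRUE)
  graphics::plot(series$k, series$bmi, type = "b", pch = 16, ylim = rng,
                 xlab = "number of clusters", ylab = "index value",
                 main = main)
  cols <- c(adjusted_rand = "firebrick", fowlkes_mallows = "forestgreen",
            f_measure = "royalblue")
  for (nm in names(cols))
    graphics::lines(series$k, series[[nm]], type = "b", pch = 1,
                    col = cols[[nm]])
  graphics::legend("topright",
                   legend = c("BMI", "adjusted Rand", "Fowlkes-Mallows",
                              "F-measure"),
                   col = c("black", unname(cols)), pch = c(16, 1, 1, 1),
                   lty = 1, cex = 0.8, bg = "white")
  invisible(series)
}
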