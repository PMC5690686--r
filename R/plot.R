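# Configuration-space plot: data sets located in (m, U) space between
# the dispersive, random, and conservative reference curves.

#' Plot samples in methylation configuration space
#'
#' Draws the (m, U) plane with the three reference curves — the
#' conservative boundary `U = 1 - m`, the random-placement (binomial)
#' curve `U = (1 - m)^2`, and the dispersive boundary
#' `U = max(1 - 2m, 0)` — plus RCP contour lines, and locates each
#' sample at its (m, U) point with an optional vertical bar for the U
#' range implied by its RCP confidence interval.
#'
#' @param samples data.frame with columns `m`, `U` and optionally
#'   `label`, `ciLowU`, `ciHighU`; may be empty only if `contours` is
#'   wanted on its own, otherwise an error.
#' @param contours numeric vector of RCP values to draw as contour
#'   lines.
#' @param mGrid methylation-frequency grid for the curves.
#' @return A `ggplot` object.
#' @examples
#' s <- data.frame(m = 0.5, U = 0.25, label = "example")
#' plotConfigurationSpace(s)
#' @export
plotConfigurationSpace <- function(samples,
                                   contours = c(1, 2, 5, 20),
                                   mGrid = seq(0.01, 0.99,
                                               by = 0.005)) {
  samples <- as.data.frame(samples)
  if (nrow(samples) == 0L) stop("no samples to plot")
  stopifnot(all(c("m", "U") %in% names(samples)))
  bounds <- regionBoundaries(mGrid)
  contourDf <- do.call(rbind, lapply(contours, function(r) {
    cbind(rcpContour(r, mGrid), label = sprintf("RCP = %g", r))
  }))
  p <- ggplot2::ggplot() +
    ggplot2::geom_line(
      data = bounds,
      ggplot2::aes(x = .data$m, y = .data$conservative),
      linewidth = 0.7
    ) +
    ggplot2::geom_line(
      data = bounds,
      ggplot2::aes(x = .data$m, y = .data$dispersive),
      linewidth = 0.7
    ) +
    ggplot2::geom_line(
      data = bounds,
      ggplot2::aes(x = .data$m, y = .data$random),
      linetype = "dashed", linewidth = 0.7
    ) +
    ggplot2::geom_line(
      data = contourDf,
      ggplot2::aes(x = .data$m, y = .data$U,
                   group = .data$label),
      color = "grey55", linewidth = 0.4
    )
  if (all(c("ciLowU", "ciHighU") %in% names(samples))) {
    p <- p + ggplot2::geom_linerange(
      data = samples,
      ggplot2::aes(x = .data$m, ymin = .data$ciLowU,
                   ymax = .data$ciHighU),
      color = "steelblue"
    )
  }
  p <- p + ggplot2::geom_point(
    data = samples,
    ggplot2::aes(x = .data$m, y = .data$U),
    color = "steelblue", size = 2
  )
  if ("label" %in% names(samples)) {
    p <- p + ggplot2::geom_text(
      data = samples,
      ggplot2::aes(x = .data$m, y = .data$U, label = .data$label),
      hjust = -0.15, vjust = -0.4, size = 3
    )
  }
  p +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "methylation frequency m",
      y = "unmethylated-dyad frequency U"
    ) +
    ggplot2::theme_minimal()
}
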