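# Volcano plot: ln(ROR) against -log10(p), coloured by log10 report count.

#' Volcano-plot coordinates
#'
#' One point per crude-drug group: `x = ln(ROR)`, `y = -log10(p)` (p floored
#' at `pFloor` for the transform only), colour value `log10(n_reports)`
#' clipped to the fixed range 0-3.5 so runs are comparable. The significance
#' reference `y = -log10(alpha)` is attached as the `"yReference"` attribute.
#'
#' @param results a [SignalResults-class] (or data.frame with columns `label`,
#'   `ror`, `p_value`, `n_reports`, `is_signal`).
#' @param pFloor p floor for the -log10 transform.
#' @param colorRange clipping range for the colour value.
#' @param alpha significance level drawn as the reference line.
#' @return data.frame with columns `label`, `x`, `y`, `color_value`,
#'   `is_signal`.
#' @examples
#' volcanoCoordinates(data.frame(label = "g", ror = exp(2), p_value = 0.01,
#'                               n_reports = 100, is_signal = TRUE))  # (2, 2)
#' @export
volcanoCoordinates <- function(results, pFloor = 1e-300,
                               colorRange = c(0, 3.5), alpha = 0.05) {
  df <- as.data.frame(results)
  out <- data.frame(
    label = df$label,
    x = log(df$ror),
    y = -log10(pmax(df$p_value, pFloor)),
    color_value = pmin(pmax(log10(pmax(df$n_reports, 1)), colorRange[1]),
                       colorRange[2]),
    is_signal = df$is_signal)
  structure(out, yReference = -log10(alpha))
}

#' Render the volcano plot
#'
#' Scatter of the volcano coordinates with a red-green-blue colour scale over
#' the clipped log10 report count, a dashed line at p = `alpha`, and labels
#' on the top `topLabels` signal groups by significance. Returns the ggplot
#' object; writes an image when `path` is given (format from the file
#' extension, e.g. `.png` or `.svg`).
#'
#' @inheritParams volcanoCoordinates
#' @param path optional output image path.
#' @param topLabels number of signal points to label (default 15).
#' @param width,height device size in inches.
#' @return the ggplot object, invisibly when `path` is given.
#' @export
plotVolcano <- function(results, path = NULL, topLabels = 15, alpha = 0.05,
                        pFloor = 1e-300, colorRange = c(0, 3.5), width = 7,
                        height = 5) {
  pts <- volcanoCoordinates(results, pFloor, colorRange, alpha)
  lab <- pts[pts$is_signal, , drop = FALSE]
  lab <- head(lab[order(-lab$y, -lab$x), , drop = FALSE], topLabels)
  gg <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                          colour = .data$color_value)) +
    ggplot2::geom_hline(yintercept = attr(pts, "yReference"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_gradientn(
      colours = c("blue", "green", "red"), limits = colorRange,
      name = "Log10(reports)") +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$label),
                       colour = "black", size = 2.7, vjust = -0.6,
                       check_overlap = TRUE) +
    ggplot2::labs(x = "Ln(ROR)", y = "-Log10(p value)") +
    ggplot2::theme_classic()
  if (!is.null(path)) {
    ggplot2::ggsave(path, gg, width = width, height = height, dpi = 150)
    return(invisible(gg))
  }
  gg
}

#' Write volcano coordinates as TSV
#'
#' Coordinates are always exported as text so downstream checks never inspect
#' pixels.
#'
#' @inheritParams volcanoCoordinates
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeVolcano <- function(results, path, pFloor = 1e-300,
                         colorRange = c(0, 3.5), alpha = 0.05) {
  pts <- volcanoCoordinates(results, pFloor, colorRange, alpha)
  write.table(pts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
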