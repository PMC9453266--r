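# Loss diagnostics: gradient-norm histogram exports (CSV + optional PNG bar
# chart with the easy/hard partition marked).

#' Export a gradient-norm histogram
#'
#' Writes the per-bin diagnostic (`bin_left`, `bin_right`, `count`, `density`,
#' `mean_weight`, `region`) as CSV and, optionally, a log-scale bar chart with
#' the easy/hard bound marked.
#'
#' @param snapshot a [gradient_histogram_snapshot()] data.frame.
#' @param csv_path output CSV path.
#' @param png_path optional output PNG path.
#' @param hard_bound bound drawn on the chart.
#' @return invisibly, `csv_path`.
#' @export
export_loss_diagnostics <- function(snapshot, csv_path, png_path = NULL,
                                    hard_bound = 0.375) {
  utils::write.csv(snapshot, csv_path, row.names = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 640, height = 420)
    on.exit(grDevices::dev.off())
    mids <- (snapshot$bin_left + snapshot$bin_right) / 2
    graphics::barplot(pmax(snapshot$count, 0.5), names.arg = sprintf("%.2f", mids),
                      log = "y", col = ifelse(snapshot$region == "easy",
                                              "steelblue", "firebrick"),
                      xlab = "gradient norm", ylab = "count (log scale)",
                      main = "Gradient-norm histogram")
    graphics::legend("topright", fill = c("steelblue", "firebrick"),
                     legend = c(sprintf("easy (< %.3f)", hard_bound),
                                sprintf("hard (>= %.3f)", hard_bound)),
                     bty = "n")
  }
  invisible(csv_path)
}
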