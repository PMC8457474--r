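# Diagnostic figures for study outputs.

#' Scatter of TE-PPLD against CPH -log10(p)
#'
#' One panel per sample size; the horizontal line marks the PPLD prior
#' probability. Under the null the TE-PPLD mass moves towards 0 as the sample
#' size grows while the CPH distribution is stable.
#'
#' @param results A tibble with columns `cph_P`, `ppld` and (optionally) `N`,
#'   e.g. from [null_study()] or [power_study()].
#' @param pi Prior probability reference line.
#' @return A ggplot object.
#' @export
plot_statistic_scatter <- function(results, pi = 4e-4) {
  p <- ggplot2::ggplot(results, ggplot2::aes(x = .data$cph_P, y = .data$ppld)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = pi, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = expression(-log[10](p)~"(Cox PH)"), y = "TE-PPLD") +
    ggplot2::theme_minimal()
  if ("N" %in% names(results)) {
    p <- p + ggplot2::facet_wrap(~N, labeller = ggplot2::label_both)
  }
  p
}

#' Quantile-quantile comparison of two statistic distributions
#'
#' @param x,y Statistic vectors (e.g. `log10br` under two generating
#'   families).
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_qq <- function(x, y, xlab = "x quantiles", ylab = "y quantiles") {
  n <- min(length(x), length(y))
  q <- (seq_len(n) - 0.5) / n
  df <- tibble::tibble(qx = stats::quantile(x, q, na.rm = TRUE, names = FALSE),
                       qy = stats::quantile(y, q, na.rm = TRUE, names = FALSE))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$qx, y = .data$qy)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}

#' Power summary bar chart
#'
#' @param summary Output of [power_summary()].
#' @return A ggplot object with one bar per model x family x statistic.
#' @export
plot_power <- function(summary) {
  long <- tidyr::pivot_longer(
    dplyr::select(summary, "model", "family", "cph_power", "ppld_power"),
    cols = c("cph_power", "ppld_power"),
    names_to = "statistic", values_to = "power")
  long$statistic <- ifelse(long$statistic == "cph_power", "CPH-P", "TE-PPLD")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$power,
                                     fill = .data$statistic)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~family) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "empirical power", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Per-SNP scan plot
#'
#' @param scan Output of [ppld_scan()] or the `snps` table of a
#'   [genome_scan_experiment()].
#' @param statistic `"ppld"` or `"cph_P"`.
#' @param threshold Optional horizontal reference line.
#' @return A ggplot object of the statistic against SNP index.
#' @export
plot_scan <- function(scan, statistic = "ppld", threshold = NULL) {
  df <- tibble::tibble(index = seq_len(nrow(scan)),
                       value = scan[[statistic]])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "SNP index", y = statistic) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                                 colour = "red3")
  }
  p
}
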