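#' Scatter plot of treated versus control methylation
#'
#' Mirrors the usual genome-wide MSCC view: one point per covered site,
#' control fraction on the horizontal axis and treated fraction on the
#' vertical axis, so unchanged sites fall on the diagonal.
#'
#' @param wide Output of [methylation_wide()] or [filter_coverage()].
#' @return A ggplot object.
#' @export
plot_methylation_scatter <- function(wide) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$m_control, y = .data$m_treated)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "methylation, control", y = "methylation, treated")
}

#' Methylation change against distance to the nearest TSS
#'
#' @param profile Output of [tss_profile()].
#' @param max_distance Distance window in bp (default 10000).
#' @return A ggplot object.
#' @export
plot_tss_profile <- function(profile, max_distance = 10000) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  d <- profile[abs(profile$tss_distance) <= max_distance, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tss_distance, y = .data$delta,
                                  colour = .data$in_island)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "distance to nearest TSS (bp; negative = upstream)",
                  y = "methylation change (treated - control)",
                  colour = "CpG island")
}
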