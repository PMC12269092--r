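#' Plot browning clusters in standardized slope space
#'
#' @param object A [classify_browning()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot browning_clusters
#' @export
autoplot.browning_clusters <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$z_doc, y = .data$z_color,
             colour = .data$cluster)) +
    geom_point(size = 2) +
    labs(x = "standardized DOC Sen slope",
         y = "standardized colour Sen slope", colour = "cluster") +
    theme_minimal()
}

#' Plot band-aggregated coherence magnitudes
#'
#' @param coherence A [coherence_table()] result.
#' @return A ggplot: magnitude per driver and band, shaded by phase
#'   class, with non-significant bars hollow.
#' @export
plot_coherence <- function(coherence) {
  d <- mutate(coherence,
              significant = .data$p_band < 0.05,
              band = factor(.data$band,
                            levels = unique(coherence$band)))
  ggplot(d, aes(x = .data$band, y = .data$magnitude,
                fill = .data$phase_class, alpha = .data$significant)) +
    geom_col() +
    facet_wrap(~driver) +
    scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                       guide = "none") +
    ylim(0, 1) +
    labs(x = NULL, y = "coherence magnitude", fill = "phase class") +
    theme_minimal()
}

#' Plot per-lake Sen slopes
#'
#' @param trends A [trend_table()] result.
#' @return A ggplot of Sen slopes per lake, faceted by parameter, with
#'   non-significant slopes hollow.
#' @export
plot_trend_slopes <- function(trends) {
  d <- filter(trends, !.data$missing)
  ggplot(d, aes(x = .data$sen_slope, y = .data$lake_id,
                colour = .data$significant)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    geom_point() +
    facet_wrap(~parameter, scales = "free_x") +
    labs(x = "Sen slope (units / year)", y = NULL,
         colour = "p < 0.05") +
    theme_minimal()
}

#' Plot the contaminant screening distribution
#'
#' @param screening A [screen_compounds()] result (optionally with a
#'   `cluster` column).
#' @return A ggplot of log10(t1/2 / tau) with the flushing benchmarks at
#'   0 (ratio 1) and 1 (ratio 10).
#' @export
plot_screening <- function(screening) {
  has_cluster <- "cluster" %in% names(screening)
  p <- ggplot(screening,
              aes(x = if (has_cluster) .data$cluster else "all",
                  y = .data$log10_ratio)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "blue") +
    geom_hline(yintercept = 1, linetype = 2, colour = "red") +
    geom_boxplot(outlier.alpha = 0.4) +
    labs(x = if (has_cluster) "browning cluster" else NULL,
         y = expression(log[10] * "(t"[1 / 2] * " / " * tau * ")")) +
    theme_minimal()
  p
}
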