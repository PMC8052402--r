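# ggplot2 helpers for the main result types.

#' Distance distribution of lead variants
#'
#' Density of |distance| from lead variants to their feature, split by
#' proximal/distal class (log10 x axis).
#'
#' @param leads Lead tibble with `distance`, `proximity`.
#' @return A ggplot object.
#' @export
plot_qtl_distance <- function(leads) {
  df <- mutate(as_tibble(leads),
               abs_dist = pmax(abs(.data$distance), 1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$abs_dist,
                                   fill = .data$proximity)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "distance to peak edge (bp)", y = "density",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Posterior-probability bar plot for a colocalisation result
#'
#' @param object A `coloc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coloc_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hypothesis, y = .data$pp)) +
    ggplot2::geom_col(fill = "navy") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "posterior probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Odds-ratio summary plot for per-sample PIR enrichment
#'
#' @param enrichment Tibble from [fisher_pir_enrichment()].
#' @return A ggplot object.
#' @export
plot_pir_enrichment <- function(enrichment) {
  df <- filter(as_tibble(enrichment), .data$sample_id != "summary",
               !.data$or_undefined)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id,
                                   y = .data$odds_ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "odds ratio (QTL in PIR)") +
    ggplot2::theme_minimal()
}
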