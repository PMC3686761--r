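#' Plot the species-per-group distribution
#'
#' @param x An [ortholog_groups()] collection or a histogram tibble from
#'   [group_size_histogram()].
#' @return A ggplot bar chart.
#' @export
plot_group_sizes <- function(x) {
  hist <- if (inherits(x, "ortholog_groups")) group_size_histogram(x)
          else x
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$n_species,
                                     y = .data$n_groups)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "species per ortholog group",
                  y = "number of groups") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a scan result
#'
#' p-value histogram per foreground lineage: a well-calibrated scan shows
#' a near-uniform bulk with a spike near zero from selected genes.
#'
#' @param object A `psg_scan` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psg_scan <- function(object, ...) {
  ok <- object[object$status == "ok" & !is.na(object$p_value), ,
               drop = FALSE]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                            fill = "grey30", colour = "white") +
    ggplot2::facet_wrap(~foreground) +
    ggplot2::labs(x = "branch-site LRT p-value", y = "genes") +
    ggplot2::theme_minimal()
}

#' Plot an enrichment result
#'
#' Observed versus expected category counts, significant categories
#' highlighted.
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- ifelse(is.na(df$name), df$term, df$name)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed,
                                   colour = .data$significant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "expected PSGs in category",
                  y = "observed PSGs in category",
                  colour = "significant") +
    ggplot2::theme_minimal()
}
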