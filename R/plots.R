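#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_histogram geom_line
#'   geom_point labs coord_flip
#' @export
ggplot2::autoplot

#' Plot methods for safetyome result objects
#'
#' `autoplot()` draws the canonical display of each result type: unique
#' gene counts per organ class for a `soc_safetyome`, the panel-size
#' distribution for `pt_panels`, tau against conservation (colored by
#' scaled score) for a `core_panel`, and the match rate across
#' percentile cutoffs for a `sweep_result`.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name safetyome-autoplot
NULL

#' @rdname safetyome-autoplot
#' @method autoplot soc_safetyome
#' @export
autoplot.soc_safetyome <- function(object, ...) {
  counts <- dplyr::count(object$panels, .data$panel_id, name = "n_genes")
  ggplot(counts, aes(x = stats::reorder(.data$panel_id, .data$n_genes),
                     y = .data$n_genes)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "unique genes",
         title = "Safetyome genes per system organ class")
}

#' @rdname safetyome-autoplot
#' @method autoplot pt_panels
#' @export
autoplot.pt_panels <- function(object, ...) {
  sizes <- dplyr::count(object$panels, .data$panel_id, name = "n_genes")
  ggplot(sizes, aes(x = .data$n_genes)) +
    geom_histogram(bins = 30) +
    labs(x = "panel size (genes)", y = "panels",
         title = "Phenotype-level panel sizes")
}

#' @rdname safetyome-autoplot
#' @method autoplot core_panel
#' @export
autoplot.core_panel <- function(object, ...) {
  ggplot(object, aes(x = .data$tau, y = .data$conservation,
                     colour = .data$scaled)) +
    geom_point() +
    labs(x = "tau (tissue specificity)", y = "conservation score",
         colour = "scaled score", title = "Core panel prioritization")
}

#' @rdname safetyome-autoplot
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot(object, aes(x = .data$cutoff_percentile, y = .data$match_rate_pct)) +
    geom_line() +
    geom_point() +
    labs(x = "score percentile cutoff", y = "mean SOC match rate (%)",
         title = "Match rate across percentile cutoffs")
}
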