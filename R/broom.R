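#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a safetyome or panel object
#'
#' @param x A `soc_safetyome`, `pt_panels`, `core_panel`,
#'   `safetyome_run` or `match_rates` object.
#' @param ... Unused.
#' @return A tibble: one row per panel membership (panel objects), per
#'   gene (core panel), per panel (match rates) or per recovery metric
#'   (pipeline run).
#' @name safetyome-tidiers
NULL

#' @rdname safetyome-tidiers
#' @method tidy soc_safetyome
#' @export
tidy.soc_safetyome <- function(x, ...) panel_table(x)

#' @rdname safetyome-tidiers
#' @method tidy pt_panels
#' @export
tidy.pt_panels <- function(x, ...) panel_table(x)

#' @rdname safetyome-tidiers
#' @method tidy core_panel
#' @export
tidy.core_panel <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "core_panel")
  out
}

#' @rdname safetyome-tidiers
#' @method tidy match_rates
#' @export
tidy.match_rates <- function(x, ...) x$per_panel

#' @rdname safetyome-tidiers
#' @method tidy safetyome_run
#' @export
tidy.safetyome_run <- function(x, ...) {
  r <- x$recovery
  tibble::tibble(
    metric = c("mapping_coverage", "mean_pt_jaccard", "core_recovery",
               "soc_match_rate_pct", "n_safetyome"),
    value = c(r$mapping_coverage, r$mean_pt_jaccard, r$core_recovery,
              r$soc_match_rate_pct, r$n_safetyome))
}

#' One-row summaries of safetyome objects
#'
#' @inheritParams safetyome-tidiers
#' @return A one-row tibble of headline figures.
#' @name safetyome-glancers
NULL

#' @rdname safetyome-glancers
#' @method glance soc_safetyome
#' @export
glance.soc_safetyome <- function(x, ...) {
  tibble::tibble(level = "SOC",
                 n_panels = dplyr::n_distinct(x$panels$panel_id),
                 n_genes = length(x$safetyome),
                 cutoff_percentile = x$config$cutoff_percentile)
}

#' @rdname safetyome-glancers
#' @method glance pt_panels
#' @export
glance.pt_panels <- function(x, ...) {
  tibble::tibble(level = "PT",
                 n_panels = dplyr::n_distinct(x$panels$panel_id),
                 n_genes = dplyr::n_distinct(x$panels$gene_symbol),
                 min_sources = x$min_sources)
}

#' @rdname safetyome-glancers
#' @method glance core_panel
#' @export
glance.core_panel <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x),
                 mean_tau = mean(x$tau, na.rm = TRUE),
                 mean_conservation = mean(x$conservation, na.rm = TRUE),
                 mean_scaled = mean(x$scaled))
}

#' @rdname safetyome-glancers
#' @method glance match_rates
#' @export
glance.match_rates <- function(x, ...) {
  tibble::tibble(level = x$level, n_panels = nrow(x$per_panel),
                 mean_match_rate_pct = x$mean_match_rate_pct)
}
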