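jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Run the full pipeline over a synthetic world and measure recovery
#'
#' Chains harmonization, trait mapping, scoring, panel assembly,
#' prioritization and orthogonal validation over a [generate_world()]
#' result, then compares the outputs to the planted ground truth:
#' per-panel Jaccard of the PT panels against the true multi-source
#' gene-PT pairs, the fraction of planted core genes recovered in the
#' core panel, and the mean SOC-level match rate.
#'
#' @param world A [generate_world()] result.
#' @param filter_cfg,mapper_cfg Configurations for harmonization and
#'   mapping.
#' @param safetyome_cfg A [safetyome_config()]; by default the world's
#'   non-organ SOCs are excluded and the percentile cutoff is 50.
#' @param core_n Core panel size (default 500).
#' @param pt_floor Minimum PT panel size for PT-level enrichment.
#' @param sweep Also run the 10-90% percentile cutoff sweep (per-SOC
#'   percentiles)?
#' @return An object of class `safetyome_run`: a list with the pipeline
#'   artifacts (`records`, `phenomap`, `links`, `scores`, `soc`, `pt`,
#'   `core`, `enrichment`, `match_rates`, optionally `sweep`) and a
#'   `recovery` list (`mapping_coverage`, `pt_jaccard`, `mean_pt_jaccard`,
#'   `core_recovery`, `soc_match_rate_pct`, `n_safetyome`).
#' @export
run_end_to_end <- function(world, filter_cfg = filter_config(),
                           mapper_cfg = mapper_config(),
                           safetyome_cfg = NULL, core_n = 500L,
                           pt_floor = 50L, sweep = FALSE) {
  safetyome_cfg <- safetyome_cfg %||%
    safetyome_config(excluded_socs = world$truth$nonorgan_socs)
  hierarchy <- phenotype_hierarchy(world$hierarchy)

  records <- harmonize_all(world$sources, world$gene_universe, filter_cfg)
  empty_recovery <- list(mapping_coverage = NA_real_,
                         pt_jaccard = tibble::tibble(),
                         mean_pt_jaccard = NA_real_,
                         core_recovery = NA_real_,
                         soc_match_rate_pct = NA_real_, n_safetyome = 0L)
  if (nrow(records) == 0) {
    warning("no association records survive harmonization; ",
            "returning an empty run")
    return(structure(list(records = records, recovery = empty_recovery),
                     class = "safetyome_run"))
  }

  pm <- map_cascade(unique(records$trait_text), hierarchy, cfg = mapper_cfg,
                    trait_sources = records)
  links <- expand_links(records, pm)
  scores <- score_targets(records)
  soc <- build_soc_safetyome(links, scores, safetyome_cfg)
  pt <- build_pt_panels(links, min_sources = safetyome_cfg$min_sources_pt)

  tau <- tau_table(world$expression)
  cons <- conservation_score(world$orthology)
  priorities <- scores |>
    dplyr::filter(.data$gene_symbol %in% soc$safetyome) |>
    dplyr::left_join(tau, by = "gene_symbol") |>
    dplyr::left_join(dplyr::select(cons, "gene_symbol", "conservation"),
                     by = "gene_symbol")
  core <- if (nrow(priorities) > 0) {
    suppressWarnings(build_core_panel(priorities, n = core_n))
  } else NULL

  disease_map <- map_diseases(world$disease_gene, hierarchy,
                              cfg = mapper_cfg)
  enrichment <- enrich_panels(soc, world$disease_gene, disease_map)
  mr <- suppressWarnings(match_rate(enrichment))

  swept <- if (isTRUE(sweep)) {
    soc_scores <- score_targets(records, by = "soc", links = links)
    suppressWarnings(
      cutoff_sweep(links, soc_scores, world$disease_gene, disease_map,
                   cfg = safetyome_cfg))
  } else NULL

  cv <- pm$coverage
  pt_truth <- world$truth$links |>
    dplyr::distinct(.data$pt_term, .data$gene_symbol, .data$source_id) |>
    dplyr::group_by(.data$pt_term, .data$gene_symbol) |>
    dplyr::summarise(n_sources = dplyr::n_distinct(.data$source_id),
                     .groups = "drop") |>
    dplyr::filter(.data$n_sources >= safetyome_cfg$min_sources_pt)
  pt_built <- dplyr::distinct(pt$panels, .data$panel_id, .data$gene_symbol)
  all_pts <- union(pt_truth$pt_term, pt_built$panel_id)
  pt_jaccard <- purrr::map(all_pts, function(p) {
    tibble::tibble(
      pt_term = p,
      jaccard = jaccard(pt_truth$gene_symbol[pt_truth$pt_term == p],
                        pt_built$gene_symbol[pt_built$panel_id == p]))
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$pt_term)

  recovery <- list(
    mapping_coverage = 1 - cv$n_unmapped / cv$n_traits,
    pt_jaccard = pt_jaccard,
    mean_pt_jaccard = mean(pt_jaccard$jaccard, na.rm = TRUE),
    core_recovery = if (is.null(core)) NA_real_ else
      mean(world$truth$core_genes %in% core$gene_symbol),
    soc_match_rate_pct = mr$mean_match_rate_pct,
    n_safetyome = length(soc$safetyome))

  structure(list(records = records, phenomap = pm, links = links,
                 scores = scores, soc = soc, pt = pt, core = core,
                 enrichment = enrichment, match_rates = mr, sweep = swept,
                 recovery = recovery),
            class = "safetyome_run")
}

#' @export
print.safetyome_run <- function(x, ...) {
  r <- x$recovery
  cat("<safetyome_run>\n")
  cat(sprintf("  mapping coverage: %s\n",
              ifelse(is.na(r$mapping_coverage), "NA",
                     sprintf("%.1f%%", 100 * r$mapping_coverage))))
  cat(sprintf("  safetyome size: %d\n", r$n_safetyome))
  cat(sprintf("  mean PT-panel Jaccard vs truth: %s\n",
              format(r$mean_pt_jaccard, digits = 3)))
  cat(sprintf("  core-gene recovery: %s\n",
              format(r$core_recovery, digits = 3)))
  cat(sprintf("  SOC match rate: %s\n",
              ifelse(is.na(r$soc_match_rate_pct), "NA",
                     sprintf("%.1f%%", r$soc_match_rate_pct))))
  invisible(x)
}
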