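#' One-sided hypergeometric over-representation test
#'
#' `p = P(X >= overlap)` for the overlap between a gene panel and a
#' disease gene set under the hypergeometric null on the gene universe.
#' Panel and disease sets are intersected with the universe before
#' testing.
#'
#' @param panel_genes,disease_genes Character vectors of gene symbols.
#' @param universe Character vector: the gene universe.
#' @return The over-representation p-value.
#' @export
hypergeom_test <- function(panel_genes, disease_genes, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("gene universe is empty")
  panel <- intersect(unique(panel_genes), universe)
  disease <- intersect(unique(disease_genes), universe)
  q <- length(intersect(panel, disease))
  stats::phyper(q - 1, length(disease), length(universe) - length(disease),
                length(panel), lower.tail = FALSE)
}

#' Multiple-testing correction
#'
#' @param ps Numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` (`min(1, p * m)`) or `"bh"`
#'   (Benjamini-Hochberg step-up).
#' @param m Number of tests in the family; defaults to `length(ps)`.
#' @return Adjusted p-values, each at least the input p-value.
#' @export
adjust_pvalues <- function(ps, method = c("bonferroni", "bh"),
                           m = length(ps)) {
  method <- match.arg(method)
  stopifnot(is.numeric(ps), all(ps >= 0 & ps <= 1, na.rm = TRUE),
            m >= length(ps))
  stats::p.adjust(ps, method = if (method == "bh") "BH" else "bonferroni",
                  n = m)
}

#' Map disease terms to hierarchy labels
#'
#' Runs the matching cascade over the distinct disease terms of a
#' disease-gene table and returns one row per (disease, PT, SOC) label.
#'
#' @param disease_table Data frame with a `disease_term` column.
#' @param hierarchy A [phenotype_hierarchy()].
#' @param cfg A [mapper_config()].
#' @param ... Passed to [map_cascade()] (e.g. custom matchers).
#' @return A tibble `disease_term`, `pt_term`, `soc_term`, `stage`,
#'   `similarity`. Diseases whose term does not map are absent.
#' @export
map_diseases <- function(disease_table, hierarchy, cfg = mapper_config(),
                         ...) {
  terms <- unique(tibble::as_tibble(disease_table)$disease_term)
  pm <- map_cascade(terms, hierarchy, cfg = cfg, ...)
  tibble::tibble(disease_term = terms,
                 trait_norm = normalize_term(terms)) |>
    dplyr::inner_join(
      pm$mapped |>
        dplyr::distinct(.data$trait_norm, .data$pt_term, .data$soc_term,
                        .data$stage, .data$similarity),
      by = "trait_norm", relationship = "many-to-many") |>
    dplyr::select("disease_term", "pt_term", "soc_term", "stage",
                  "similarity")
}

#' Over-representation testing of panels against a disease-gene table
#'
#' Tests every panel against every mapped disease with the hypergeometric
#' over-representation test, adjusts p-values across all tests, and flags
#' each result as matched when the panel label equals one of the
#' disease's mapped labels at the panel level (exact string equality).
#'
#' Only disease-gene rows with direct evidence enter testing. The default
#' universe is every gene with at least one direct-evidence annotation;
#' pass `universe` to override (e.g. its union with the panel genes).
#' Phenotype-level panels with fewer genes than `min_panel_genes`
#' (default 50) are excluded to avoid instability of small sets.
#'
#' @param panels A `soc_safetyome` or `pt_panels` object.
#' @param disease_table Data frame with `disease_term`, `gene_symbol`,
#'   `direct_evidence` (logical or 0/1).
#' @param disease_map Disease label mapping from [map_diseases()].
#' @param universe Optional gene universe.
#' @param alpha Significance level on the adjusted p-value (inclusive).
#' @param adjust_method `"bh"` or `"bonferroni"`; defaults to BH for SOC
#'   panels and Bonferroni for PT panels.
#' @param min_panel_genes Minimum panel size; defaults to 50 for PT
#'   panels and 0 for SOC panels.
#' @return A tibble of class `enrichment_result` with one row per
#'   panel x disease: `panel_id`, `disease_term`, `overlap`,
#'   `panel_size`, `disease_set_size`, `universe_size`, `p`, `p_adj`,
#'   `significant`, `matched`.
#' @export
enrich_panels <- function(panels, disease_table, disease_map,
                          universe = NULL, alpha = 0.05,
                          adjust_method = NULL, min_panel_genes = NULL) {
  stopifnot(inherits(panels, c("soc_safetyome", "pt_panels")))
  level <- panels$level
  adjust_method <- adjust_method %||% if (level == "PT") "bonferroni" else "bh"
  min_panel_genes <- min_panel_genes %||% if (level == "PT") 50L else 0L
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)

  direct <- tibble::as_tibble(disease_table) |>
    dplyr::filter(as.logical(.data$direct_evidence)) |>
    dplyr::distinct(.data$disease_term, .data$gene_symbol)
  universe <- unique(universe %||% direct$gene_symbol)
  if (length(universe) == 0) stop("gene universe is empty")

  panel_genes <- panels$panels |>
    dplyr::distinct(.data$panel_id, .data$gene_symbol)
  keep <- panel_genes |>
    dplyr::count(.data$panel_id, name = "full_size") |>
    dplyr::filter(.data$full_size >= min_panel_genes)
  panel_u <- panel_genes |>
    dplyr::semi_join(keep, by = "panel_id") |>
    dplyr::filter(.data$gene_symbol %in% universe)
  disease_u <- direct |>
    dplyr::filter(.data$gene_symbol %in% universe) |>
    dplyr::semi_join(dplyr::distinct(disease_map, .data$disease_term),
                     by = "disease_term")

  panel_sizes <- dplyr::count(panel_u, .data$panel_id, name = "panel_size")
  disease_sizes <- dplyr::count(disease_u, .data$disease_term,
                                name = "disease_set_size")
  if (nrow(panel_sizes) == 0 || nrow(disease_sizes) == 0) {
    warning("no testable panel/disease combinations")
    res <- tibble::tibble(panel_id = character(), disease_term = character(),
                          overlap = integer(), panel_size = integer(),
                          disease_set_size = integer(),
                          universe_size = integer(), p = double(),
                          p_adj = double(), significant = logical(),
                          matched = logical())
    attr(res, "level") <- level
    class(res) <- c("enrichment_result", class(res))
    return(res)
  }

  overlaps <- dplyr::inner_join(panel_u, disease_u, by = "gene_symbol",
                                relationship = "many-to-many") |>
    dplyr::count(.data$panel_id, .data$disease_term, name = "overlap")
  matched_pairs <- disease_map |>
    dplyr::mutate(panel_id = if (level == "PT") .data$pt_term else
                    .data$soc_term) |>
    dplyr::distinct(.data$disease_term, .data$panel_id) |>
    dplyr::mutate(matched = TRUE)

  res <- tidyr::expand_grid(panel_id = panel_sizes$panel_id,
                            disease_term = disease_sizes$disease_term) |>
    dplyr::left_join(overlaps, by = c("panel_id", "disease_term")) |>
    dplyr::mutate(overlap = dplyr::coalesce(.data$overlap, 0L)) |>
    dplyr::left_join(panel_sizes, by = "panel_id") |>
    dplyr::left_join(disease_sizes, by = "disease_term") |>
    dplyr::mutate(
      universe_size = length(universe),
      p = stats::phyper(.data$overlap - 1, .data$disease_set_size,
                        .data$universe_size - .data$disease_set_size,
                        .data$panel_size, lower.tail = FALSE),
      p_adj = adjust_pvalues(.data$p, adjust_method),
      significant = .data$p_adj <= alpha) |>
    dplyr::left_join(matched_pairs, by = c("panel_id", "disease_term")) |>
    dplyr::mutate(matched = dplyr::coalesce(.data$matched, FALSE)) |>
    dplyr::arrange(.data$panel_id, .data$p, .data$disease_term)
  attr(res, "level") <- level
  attr(res, "alpha") <- alpha
  attr(res, "adjust_method") <- adjust_method
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Match rates of enriched diseases against panel labels
#'
#' Per panel: the percentage of significantly enriched diseases whose
#' mapped label equals the panel's label; the mean is taken over panels
#' with at least one significant result.
#'
#' @param results An `enrichment_result` tibble from [enrich_panels()].
#' @return An object of class `match_rates`: a list with `per_panel`
#'   (tibble `panel_id`, `n_significant`, `n_matched`, `match_rate_pct`),
#'   `mean_match_rate_pct` and `level`.
#' @export
match_rate <- function(results) {
  level <- attr(results, "level") %||% NA_character_
  sig <- dplyr::filter(tibble::as_tibble(results), .data$significant)
  if (nrow(sig) == 0) {
    warning("no significant enrichment results: empty match-rate report")
    per_panel <- tibble::tibble(panel_id = character(),
                                n_significant = integer(),
                                n_matched = integer(),
                                match_rate_pct = double())
    return(structure(list(per_panel = per_panel,
                          mean_match_rate_pct = NA_real_, level = level),
                     class = "match_rates"))
  }
  per_panel <- sig |>
    dplyr::group_by(.data$panel_id) |>
    dplyr::summarise(n_significant = dplyr::n(),
                     n_matched = sum(.data$matched),
                     .groups = "drop") |>
    dplyr::mutate(match_rate_pct =
                    100 * .data$n_matched / .data$n_significant)
  structure(list(per_panel = per_panel,
                 mean_match_rate_pct = mean(per_panel$match_rate_pct),
                 level = level),
            class = "match_rates")
}

#' @export
print.match_rates <- function(x, ...) {
  cat(sprintf("<match_rates> %s level: mean %.1f%% over %d panel(s)\n",
              x$level, x$mean_match_rate_pct, nrow(x$per_panel)))
  invisible(x)
}

#' Percentile-cutoff sweep of the organ-level safetyome
#'
#' Rebuilds the SOC safetyome at each cutoff, reruns enrichment and the
#' match-rate computation, and records the retained target count and mean
#' match rate per cutoff. Supply per-SOC scores
#' (`score_targets(..., by = "soc")`) to filter each organ class on its
#' own percentile distribution, or global scores for a global filter.
#'
#' @param links Gene-phenotype links.
#' @param scores Score table ([score_targets()]).
#' @param disease_table Disease-gene table (see [enrich_panels()]).
#' @param disease_map Disease label mapping ([map_diseases()]).
#' @param cfg A [safetyome_config()]; its `cutoff_percentile` is replaced
#'   by each sweep value.
#' @param cutoffs Percentile cutoffs (default 10 to 90 by 10).
#' @param ... Passed to [enrich_panels()].
#' @return A tibble of class `sweep_result` with columns
#'   `cutoff_percentile`, `n_targets`, `match_rate_pct`.
#' @export
cutoff_sweep <- function(links, scores, disease_table, disease_map,
                         cfg = safetyome_config(),
                         cutoffs = seq(10, 90, by = 10), ...) {
  stopifnot(is.numeric(cutoffs), length(cutoffs) > 0)
  rows <- purrr::map(cutoffs, function(ct) {
    cfg_ct <- safetyome_config(excluded_socs = cfg$excluded_socs,
                               cutoff_percentile = ct,
                               min_sources_pt = cfg$min_sources_pt)
    soc <- build_soc_safetyome(links, scores, cfg_ct)
    if (nrow(soc$panels) == 0) {
      return(tibble::tibble(cutoff_percentile = ct, n_targets = 0L,
                            match_rate_pct = NA_real_))
    }
    enr <- enrich_panels(soc, disease_table, disease_map, ...)
    mr <- match_rate(enr)
    tibble::tibble(cutoff_percentile = ct,
                   n_targets = length(soc$safetyome),
                   match_rate_pct = mr$mean_match_rate_pct)
  })
  out <- purrr::list_rbind(rows)
  class(out) <- c("sweep_result", class(out))
  out
}
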