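group_panels <- function(links) {
  links |>
    dplyr::group_by(.data$panel_id, .data$gene_symbol) |>
    dplyr::summarise(
      n_sources = dplyr::n_distinct(.data$source_id),
      sources = list(sort(unique(.data$source_id))),
      evidence_classes = list(sort(unique(.data$evidence_class))),
      .groups = "drop") |>
    dplyr::arrange(.data$panel_id, .data$gene_symbol)
}

#' Assemble the organ-level safetyome
#'
#' Drops links to excluded (non-organ) system organ classes, retains genes
#' whose score percentile rank is at least the cutoff (inclusive), and
#' groups the surviving links into one panel per SOC. The safetyome is the
#' union of all panel genes.
#'
#' When `scores` carries a `soc_term` column (the per-SOC variant of
#' [score_targets()]) the percentile filter is applied within each SOC;
#' otherwise the global percentile is used.
#'
#' @param links Gene-phenotype links ([expand_links()]).
#' @param scores Score table from [score_targets()]; every linked gene
#'   must be scored.
#' @param cfg A [safetyome_config()].
#' @return An object of class `soc_safetyome`: a list with `panels` (long
#'   tibble `panel_id`, `gene_symbol`, `n_sources`, `sources`,
#'   `evidence_classes`), `safetyome` (sorted character vector of genes)
#'   and `config`.
#' @export
build_soc_safetyome <- function(links, scores, cfg = safetyome_config()) {
  stopifnot(inherits(cfg, "safetyome_config"))
  if (cfg$cutoff_percentile < 0 || cfg$cutoff_percentile > 100) {
    stop("cutoff_percentile must lie in [0, 100]")
  }
  links <- tibble::as_tibble(links) |>
    dplyr::filter(!.data$soc_term %in% cfg$excluded_socs)
  per_soc <- "soc_term" %in% names(scores)
  sc <- if (per_soc) {
    dplyr::select(scores, "gene_symbol", "soc_term", "percentile")
  } else {
    dplyr::select(scores, "gene_symbol", "percentile")
  }
  joined <- dplyr::left_join(links, sc,
                             by = if (per_soc) c("gene_symbol", "soc_term")
                                  else "gene_symbol")
  if (anyNA(joined$percentile)) {
    missing <- unique(joined$gene_symbol[is.na(joined$percentile)])
    stop("every linked gene must have a score; missing: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  panels <- joined |>
    dplyr::filter(.data$percentile >= cfg$cutoff_percentile) |>
    dplyr::rename(panel_id = "soc_term") |>
    group_panels()
  structure(list(panels = panels,
                 safetyome = sort(unique(panels$gene_symbol)),
                 config = cfg, level = "SOC"),
            class = "soc_safetyome")
}

#' Assemble phenotype-level (preferred-term) panels
#'
#' A gene joins a PT panel if and only if its distinct supporting sources
#' for that PT number at least `min_sources` (default 2, the
#' two-database confidence rule). Empty panels are not emitted.
#'
#' @param links Gene-phenotype links ([expand_links()]).
#' @param min_sources Minimum number of distinct supporting sources.
#' @return An object of class `pt_panels`: a list with `panels` (long
#'   tibble as in [build_soc_safetyome()]) and `min_sources`.
#' @export
build_pt_panels <- function(links, min_sources = 2L) {
  if (!is.numeric(min_sources) || length(min_sources) != 1 ||
      is.na(min_sources) || min_sources < 1) {
    stop("min_sources must be a positive integer")
  }
  panels <- tibble::as_tibble(links) |>
    dplyr::rename(panel_id = "pt_term") |>
    group_panels() |>
    dplyr::filter(.data$n_sources >= min_sources)
  structure(list(panels = panels, min_sources = as.integer(min_sources),
                 level = "PT"),
            class = "pt_panels")
}

#' @export
print.soc_safetyome <- function(x, ...) {
  cat(sprintf(paste0("<soc_safetyome> %d panels, %d genes ",
                     "(percentile cutoff %s)\n"),
              dplyr::n_distinct(x$panels$panel_id), length(x$safetyome),
              format(x$config$cutoff_percentile)))
  invisible(x)
}

#' @export
print.pt_panels <- function(x, ...) {
  cat(sprintf("<pt_panels> %d panels, %d genes (>= %d sources)\n",
              dplyr::n_distinct(x$panels$panel_id),
              dplyr::n_distinct(x$panels$gene_symbol), x$min_sources))
  invisible(x)
}

#' Summarize a safetyome
#'
#' @param x A `soc_safetyome`.
#' @param links The links the safetyome was built from.
#' @return An object of class `safetyome_summary`: per-SOC unique gene
#'   counts, the genetics-only / pharmacology-only / both split, the
#'   histogram of distinct SOC count per gene, and the fraction of
#'   gene-SOC associations supported by more than one source.
#' @export
summarize_panels <- function(x, links) {
  stopifnot(inherits(x, "soc_safetyome"))
  glinks <- tibble::as_tibble(links) |>
    dplyr::filter(.data$gene_symbol %in% x$safetyome,
                  .data$soc_term %in% unique(x$panels$panel_id))
  soc_counts <- x$panels |>
    dplyr::count(.data$panel_id, name = "n_genes") |>
    dplyr::arrange(dplyr::desc(.data$n_genes))
  class_split <- glinks |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(
      genetic = any(.data$evidence_class == "genetic"),
      pharmacological = any(.data$evidence_class == "pharmacological"),
      .groups = "drop") |>
    dplyr::summarise(
      genetics_only = sum(.data$genetic & !.data$pharmacological),
      pharmacology_only = sum(!.data$genetic & .data$pharmacological),
      both = sum(.data$genetic & .data$pharmacological))
  soc_count_hist <- glinks |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(n_socs = dplyr::n_distinct(.data$soc_term),
                     .groups = "drop") |>
    dplyr::count(.data$n_socs, name = "n_genes")
  multi_source <- glinks |>
    dplyr::distinct(.data$gene_symbol, .data$soc_term, .data$source_id) |>
    dplyr::count(.data$gene_symbol, .data$soc_term)
  structure(list(soc_counts = soc_counts,
                 class_split = class_split,
                 soc_count_hist = soc_count_hist,
                 multi_source_fraction = mean(multi_source$n > 1)),
            class = "safetyome_summary")
}

#' @export
print.safetyome_summary <- function(x, ...) {
  cat("<safetyome_summary>\n")
  cat(sprintf("  genes: genetics-only %d, pharmacology-only %d, both %d\n",
              x$class_split$genetics_only, x$class_split$pharmacology_only,
              x$class_split$both))
  cat(sprintf("  gene-SOC pairs with >1 source: %.1f%%\n",
              100 * x$multi_source_fraction))
  invisible(x)
}

#' Convert panels to GMT rows
#'
#' @param x A `soc_safetyome`, `pt_panels` or `core_panel` object.
#' @param ... Unused.
#' @return A tibble with `panel_id`, `description` and a `genes` list
#'   column; pass to [write_gmt()]. The description records the level,
#'   the supporting-source count range and the evidence classes.
#' @export
as_gmt <- function(x, ...) UseMethod("as_gmt")

gmt_from_panels <- function(panels, level) {
  panels |>
    dplyr::group_by(.data$panel_id) |>
    dplyr::summarise(
      description = sprintf("level=%s|sources=%d-%d|classes=%s", level,
                            min(.data$n_sources), max(.data$n_sources),
                            paste(sort(unique(unlist(.data$evidence_classes))),
                                  collapse = "+")),
      genes = list(sort(unique(.data$gene_symbol))),
      .groups = "drop")
}

#' @export
as_gmt.soc_safetyome <- function(x, ...) gmt_from_panels(x$panels, "SOC")

#' @export
as_gmt.pt_panels <- function(x, ...) gmt_from_panels(x$panels, "PT")

#' Long-form panel table
#'
#' @param x A `soc_safetyome` or `pt_panels` object.
#' @return A tibble `panel_id`, `level`, `gene_symbol`, `sources`
#'   (comma-collapsed), `evidence_classes` (comma-collapsed),
#'   `n_sources`, suitable for TSV export.
#' @export
panel_table <- function(x) {
  stopifnot(inherits(x, c("soc_safetyome", "pt_panels")))
  x$panels |>
    dplyr::mutate(
      level = x$level,
      sources = vapply(.data$sources, paste, character(1), collapse = ","),
      evidence_classes = vapply(.data$evidence_classes, paste, character(1),
                                collapse = ",")) |>
    dplyr::select("panel_id", "level", "gene_symbol", "sources",
                  "evidence_classes", "n_sources")
}
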