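#' Per-source evidence counts
#'
#' Counts deduplicated (gene, trait, source) records per gene and source;
#' these counts are the inputs to [raw_score()].
#'
#' @param records Harmonized association records ([harmonize_all()]).
#' @return A tibble with columns `gene_symbol`, `source_id`, `n_records`.
#' @export
evidence_counts <- function(records) {
  records |>
    tibble::as_tibble() |>
    dplyr::count(.data$gene_symbol, .data$source_id, name = "n_records")
}

#' Raw evidence score for one target
#'
#' `raw = (sum of per-source record counts) * ln(number of sources with a
#' positive count + 1)`. Occurrence across many records raises the score
#' while the unique-source multiplier prevents excessive weighting of
#' targets that recur within a single source.
#'
#' @param counts Numeric vector of non-negative per-source record counts
#'   (one element per source; zeros are allowed and contribute nothing).
#' @return A single non-negative number.
#' @examples
#' raw_score(c(A = 3, B = 1)) # 4 * ln(3)
#' @export
raw_score <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0) return(0)
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing")
  }
  sum(counts) * log(sum(counts > 0) + 1)
}

#' Normalize raw scores to the 0-10 scale
#'
#' Chains the three normalization steps over the cohort: z-score with the
#' population standard deviation, `logz = ln(z - min(z) + 1)` to damp
#' extremes, and min-max rescaling `scaled = 10 * (logz - min) /
#' (max - min)`, followed by the percentile rank of the scaled score.
#' All transforms are strictly monotone, so ordering by `scaled` equals
#' ordering by `raw`.
#'
#' Degenerate cohorts (a single target, or all raw scores equal) get
#' `scaled = 10` and `percentile = 0` for every target, with a warning:
#' uniform evidence is not silently zeroed.
#'
#' @param raws A data frame with a numeric `raw` column (any identifier
#'   columns are preserved), or a bare numeric vector.
#' @return A tibble with the input columns plus `z`, `logz`, `scaled`,
#'   `percentile`.
#' @export
scale_scores <- function(raws) {
  if (is.numeric(raws)) raws <- tibble::tibble(raw = raws)
  raws <- tibble::as_tibble(raws)
  stopifnot("raw" %in% names(raws), nrow(raws) >= 1)
  r <- raws$raw
  if (anyNA(r)) stop("raw scores must not be missing")
  sigma <- sqrt(mean((r - mean(r))^2))
  if (length(r) < 2 || sigma == 0) {
    warning("degenerate cohort (all raw scores equal): ",
            "scaled set to 10 and percentile to 0 for every target")
    return(dplyr::mutate(raws, z = 0, logz = 0, scaled = 10, percentile = 0))
  }
  z <- (r - mean(r)) / sigma
  logz <- log(z - min(z) + 1)
  rng <- max(logz) - min(logz)
  scaled <- 10 * (logz - min(logz)) / rng
  dplyr::mutate(raws, z = z, logz = logz, scaled = scaled,
                percentile = percentile_rank(scaled))
}

#' Score all targets from harmonized evidence
#'
#' Computes per-gene raw scores from deduplicated per-source record counts
#' and normalizes them over the cohort. With `by = "global"` (the
#' default) every gene gets one score across all sources and organ
#' systems. With `by = "soc"` counts are distinct (gene, PT, source)
#' links within each system organ class and scores are normalized within
#' each SOC's cohort; this variant feeds per-SOC percentile filtering.
#'
#' @param records Harmonized association records ([harmonize_all()]).
#' @param by `"global"` or `"soc"`.
#' @param links Gene-phenotype links ([expand_links()]); required when
#'   `by = "soc"`.
#' @return A tibble with columns `gene_symbol` (and `soc_term` for the
#'   per-SOC variant), `raw`, `z`, `logz`, `scaled`, `percentile`.
#' @export
score_targets <- function(records, by = c("global", "soc"), links = NULL) {
  by <- match.arg(by)
  if (by == "global") {
    evidence_counts(records) |>
      dplyr::group_by(.data$gene_symbol) |>
      dplyr::summarise(raw = raw_score(.data$n_records), .groups = "drop") |>
      scale_scores()
  } else {
    if (is.null(links)) stop("links are required when by = \"soc\"")
    links |>
      tibble::as_tibble() |>
      dplyr::distinct(.data$gene_symbol, .data$pt_term, .data$soc_term,
                      .data$source_id) |>
      dplyr::count(.data$gene_symbol, .data$soc_term, .data$source_id,
                   name = "n_records") |>
      dplyr::group_by(.data$gene_symbol, .data$soc_term) |>
      dplyr::summarise(raw = raw_score(.data$n_records), .groups = "drop") |>
      dplyr::group_by(.data$soc_term) |>
      dplyr::group_split() |>
      purrr::map(scale_scores) |>
      purrr::list_rbind() |>
      dplyr::arrange(.data$soc_term, .data$gene_symbol)
  }
}
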