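#' Build a two-level phenotype hierarchy
#'
#' The hierarchy links surface synonyms to concepts and every concept to
#' one or more (preferred term, system organ class) pairs; a concept with
#' several preferred terms fans out to all of them. Synonyms are indexed
#' by their normalized form ([normalize_term()]); when two concepts claim
#' the same normalized synonym the lexicographically smallest concept id
#' wins, with a warning.
#'
#' @param x Data frame with columns `concept_id`, `synonym`, `pt_term`,
#'   `soc_term` (one row per synonym x preferred term).
#' @return An object of class `phenotype_hierarchy`.
#' @export
phenotype_hierarchy <- function(x) {
  x <- tibble::as_tibble(x)
  req <- c("concept_id", "synonym", "pt_term", "soc_term")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    stop("hierarchy table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(x) == 0) stop("hierarchy is empty")
  if (anyNA(x[req])) stop("hierarchy table contains missing values")

  pairs <- dplyr::distinct(x, .data$concept_id, .data$pt_term, .data$soc_term)
  synonyms <- x |>
    dplyr::mutate(synonym_norm = normalize_term(.data$synonym)) |>
    dplyr::filter(nzchar(.data$synonym_norm)) |>
    dplyr::distinct(.data$synonym_norm, .data$concept_id)
  clash <- synonyms |>
    dplyr::count(.data$synonym_norm) |>
    dplyr::filter(.data$n > 1)
  if (nrow(clash) > 0) {
    warning(nrow(clash), " synonym(s) shared by several concepts; keeping ",
            "the lexicographically smallest concept_id for each")
    synonyms <- synonyms |>
      dplyr::arrange(.data$synonym_norm, .data$concept_id) |>
      dplyr::distinct(.data$synonym_norm, .keep_all = TRUE)
  }
  synonyms <- dplyr::mutate(synonyms, nchar = nchar(.data$synonym_norm))

  structure(list(table = x,
                 pairs = pairs,
                 synonyms = synonyms,
                 soc_terms = sort(unique(x$soc_term)),
                 concepts = sort(unique(x$concept_id))),
            class = "phenotype_hierarchy")
}

#' Read a phenotype hierarchy from TSV
#'
#' @param path Path to a tab-separated file with columns `concept_id`,
#'   `synonym`, `pt_term`, `soc_term`.
#' @return A [phenotype_hierarchy()] object.
#' @export
read_hierarchy <- function(path) {
  phenotype_hierarchy(readr::read_tsv(path, show_col_types = FALSE,
                                      progress = FALSE))
}

#' @export
print.phenotype_hierarchy <- function(x, ...) {
  cat(sprintf(paste0("<phenotype_hierarchy> %d concepts, %d PTs, %d SOCs, ",
                     "%d synonyms\n"),
              length(x$concepts), dplyr::n_distinct(x$pairs$pt_term),
              length(x$soc_terms), nrow(x$synonyms)))
  invisible(x)
}
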