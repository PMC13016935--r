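#' Matcher contracts
#'
#' The fuzzy and embedding stages of [map_cascade()] are injectable
#' services: any function taking one normalized trait string and returning
#' a tibble with columns `concept_id` and `similarity` (in `[0, 1]`),
#' ranked by decreasing similarity with ties broken by ascending
#' `concept_id`, satisfies the contract. The built-in implementations
#' below are deterministic and need no external model.
#'
#' @name matcher-contracts
NULL

token_sort <- function(x) {
  vapply(strsplit(x, " ", fixed = TRUE),
         function(tok) paste(sort(tok), collapse = " "),
         character(1))
}

#' Built-in fuzzy matcher over concept synonyms
#'
#' Token-sort similarity: both the query and every lexicon synonym are
#' token-sorted, and similarity is `1 - d / max(nchar)` where `d` is the
#' Levenshtein distance. A concept scores the maximum over its synonyms.
#'
#' @param hierarchy A [phenotype_hierarchy()].
#' @return A matcher function (see [matcher-contracts]).
#' @export
default_fuzzy_matcher <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "phenotype_hierarchy"))
  syn <- hierarchy$synonyms
  sorted <- token_sort(syn$synonym_norm)
  len <- nchar(sorted)
  function(query) {
    stopifnot(is.character(query), length(query) == 1)
    if (!nzchar(query)) {
      return(tibble::tibble(concept_id = character(), similarity = double()))
    }
    q <- token_sort(query)
    d <- as.vector(utils::adist(q, sorted))
    sim <- 1 - d / pmax(nchar(q), len)
    tibble::tibble(concept_id = syn$concept_id, similarity = sim) |>
      dplyr::group_by(.data$concept_id) |>
      dplyr::summarise(similarity = max(.data$similarity), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$similarity), .data$concept_id)
  }
}

char_ngrams <- function(s, n = 3L) {
  k <- nchar(s)
  if (k == 0) return(character(0))
  if (k < n) return(s)
  substring(s, seq_len(k - n + 1), seq(n, k))
}

#' Built-in embedding matcher over concept synonyms
#'
#' Character n-gram (default trigram) TF-IDF vectors over the lexicon with
#' cosine similarity; IDF is the smoothed form
#' `log((1 + N) / (1 + df)) + 1`. N-grams unseen in the lexicon get the
#' zero-document-frequency IDF. A concept scores the maximum over its
#' synonyms.
#'
#' @param hierarchy A [phenotype_hierarchy()].
#' @param n N-gram width (default 3).
#' @return A matcher function (see [matcher-contracts]).
#' @export
default_embedding_matcher <- function(hierarchy, n = 3L) {
  stopifnot(inherits(hierarchy, "phenotype_hierarchy"))
  syn <- hierarchy$synonyms
  grams_list <- lapply(syn$synonym_norm, char_ngrams, n = n)
  df <- table(unlist(lapply(grams_list, unique)))
  n_docs <- nrow(syn)
  idf <- log((1 + n_docs) / (1 + as.numeric(df))) + 1
  names(idf) <- names(df)
  idf_unseen <- log(1 + n_docs) + 1
  vectorize <- function(grams) {
    if (length(grams) == 0) return(numeric(0))
    tf <- table(grams)
    w_idf <- idf[names(tf)]
    w_idf[is.na(w_idf)] <- idf_unseen
    w <- as.numeric(tf) * as.numeric(w_idf)
    names(w) <- names(tf)
    w / sqrt(sum(w^2))
  }
  doc_vecs <- lapply(grams_list, vectorize)
  function(query) {
    stopifnot(is.character(query), length(query) == 1)
    qv <- vectorize(char_ngrams(query, n = n))
    if (length(qv) == 0) {
      return(tibble::tibble(concept_id = character(), similarity = double()))
    }
    sims <- vapply(doc_vecs, function(dv) {
      common <- intersect(names(dv), names(qv))
      if (length(common) == 0) 0 else sum(dv[common] * qv[common])
    }, numeric(1))
    tibble::tibble(concept_id = syn$concept_id, similarity = sims) |>
      dplyr::group_by(.data$concept_id) |>
      dplyr::summarise(similarity = max(.data$similarity), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$similarity), .data$concept_id)
  }
}
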