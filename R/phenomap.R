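# Stage-1 partial match: a synonym contained in the trait (or the trait
# contained in a synonym) as a normalized substring; the longest matching
# synonym wins, ties broken by smallest concept_id.
partial_lexicon_match <- function(trait_norm, synonyms) {
  hit_in_trait <- stringr::str_detect(trait_norm,
                                      stringr::fixed(synonyms$synonym_norm))
  trait_in_syn <- stringr::str_detect(synonyms$synonym_norm,
                                      stringr::fixed(trait_norm))
  idx <- which(hit_in_trait | trait_in_syn)
  if (length(idx) == 0) return(NULL)
  cand <- synonyms[idx, ]
  cand <- cand[order(-cand$nchar, cand$concept_id), ]
  cand$concept_id[[1]]
}

#' Map free-text traits onto the hierarchy by a three-stage cascade
#'
#' Traits are deduplicated on their normalized form and tried by stages in
#' a fixed order: (1) exact or partial (substring containment) lexicon
#' match, (2) fuzzy matching, (3) embedding similarity. The first stage
#' producing an accepted candidate wins and only the top-ranked candidate
#' of a stage is considered. The fuzzy stage accepts its candidate when
#' similarity is at least `cfg$fuzzy_min_score`; the embedding stage when
#' similarity is at least `cfg$embedding_threshold` (both inclusive). A
#' matched concept fans out to all of its (PT, SOC) pairs.
#'
#' @param traits Character vector of free-text traits.
#' @param hierarchy A [phenotype_hierarchy()] (or the raw hierarchy table).
#' @param fuzzy,embedder Optional matcher functions (see
#'   [matcher-contracts]); defaults are [default_fuzzy_matcher()] and
#'   [default_embedding_matcher()]. Pass `FALSE` to disable a stage.
#' @param cfg A [mapper_config()].
#' @param trait_sources Optional data frame with columns `trait_text`,
#'   `source_id` used for per-source coverage accounting and unmapped-term
#'   frequencies.
#' @return An object of class `phenomap`: a list with `mapped` (tibble
#'   `trait_text`, `trait_norm`, `concept_id`, `stage`, `similarity`,
#'   `pt_term`, `soc_term`), `unmapped` (tibble `trait_text`,
#'   `trait_norm`), and `coverage` (per-stage counts, per-source unmapped
#'   fractions, most frequent unmapped traits).
#' @export
map_cascade <- function(traits, hierarchy, fuzzy = NULL, embedder = NULL,
                        cfg = mapper_config(), trait_sources = NULL) {
  if (!inherits(hierarchy, "phenotype_hierarchy")) {
    hierarchy <- phenotype_hierarchy(hierarchy)
  }
  stopifnot(inherits(cfg, "mapper_config"))
  use_fuzzy <- !isFALSE(fuzzy)
  use_embed <- !isFALSE(embedder)

  traits <- unique(as.character(traits))
  tt <- tibble::tibble(trait_text = traits,
                       trait_norm = normalize_term(traits)) |>
    dplyr::distinct(.data$trait_norm, .keep_all = TRUE)

  n_traits <- nrow(tt)
  concept <- rep(NA_character_, n_traits)
  stage <- rep(NA_character_, n_traits)
  similarity <- rep(NA_real_, n_traits)

  syn <- hierarchy$synonyms
  nonempty <- nzchar(tt$trait_norm)

  # stage 1: exact, then partial containment
  exact_idx <- match(tt$trait_norm, syn$synonym_norm)
  hit <- nonempty & !is.na(exact_idx)
  concept[hit] <- syn$concept_id[exact_idx[hit]]
  stage[hit] <- "exact"
  similarity[hit] <- 1
  for (i in which(nonempty & is.na(concept))) {
    cid <- partial_lexicon_match(tt$trait_norm[[i]], syn)
    if (!is.null(cid)) {
      concept[i] <- cid
      stage[i] <- "exact"
      similarity[i] <- 1
    }
  }

  run_stage <- function(matcher, stage_name, threshold) {
    for (i in which(nonempty & is.na(concept))) {
      res <- matcher(tt$trait_norm[[i]])
      if (nrow(res) == 0) next
      if (res$similarity[[1]] >= threshold) {
        concept[i] <<- res$concept_id[[1]]
        stage[i] <<- stage_name
        similarity[i] <<- res$similarity[[1]]
      }
    }
  }
  if (use_fuzzy && any(is.na(concept) & nonempty)) {
    if (is.null(fuzzy)) fuzzy <- default_fuzzy_matcher(hierarchy)
    run_stage(fuzzy, "fuzzy", cfg$fuzzy_min_score)
  }
  if (use_embed && any(is.na(concept) & nonempty)) {
    if (is.null(embedder)) embedder <- default_embedding_matcher(hierarchy)
    run_stage(embedder, "embedding", cfg$embedding_threshold)
  }

  status <- tibble::tibble(trait_text = tt$trait_text,
                           trait_norm = tt$trait_norm,
                           concept_id = concept, stage = stage,
                           similarity = similarity)
  mapped <- status |>
    dplyr::filter(!is.na(.data$concept_id)) |>
    dplyr::inner_join(hierarchy$pairs, by = "concept_id",
                      relationship = "many-to-many")
  unmapped <- status |>
    dplyr::filter(is.na(.data$concept_id)) |>
    dplyr::select("trait_text", "trait_norm")

  per_stage <- vapply(c("exact", "fuzzy", "embedding"),
                      function(s) sum(stage == s, na.rm = TRUE), integer(1))
  coverage <- list(
    n_traits = n_traits,
    per_stage_counts = as.list(per_stage),
    n_unmapped = nrow(unmapped),
    per_source_unmapped_fraction = NULL,
    top_unmapped = NULL
  )
  if (!is.null(trait_sources)) {
    ts <- tibble::as_tibble(trait_sources) |>
      dplyr::mutate(trait_norm = normalize_term(.data$trait_text))
    mapped_norms <- status$trait_norm[!is.na(status$concept_id)]
    by_source <- ts |>
      dplyr::distinct(.data$source_id, .data$trait_norm) |>
      dplyr::group_by(.data$source_id) |>
      dplyr::summarise(
        n_traits = dplyr::n(),
        unmapped_fraction = mean(!.data$trait_norm %in% mapped_norms),
        .groups = "drop")
    coverage$per_source_unmapped_fraction <-
      stats::setNames(as.list(by_source$unmapped_fraction),
                      by_source$source_id)
    coverage$top_unmapped <- ts |>
      dplyr::semi_join(unmapped, by = "trait_norm") |>
      dplyr::count(.data$trait_norm, name = "frequency") |>
      dplyr::inner_join(dplyr::select(unmapped, "trait_text", "trait_norm"),
                        by = "trait_norm") |>
      dplyr::arrange(dplyr::desc(.data$frequency), .data$trait_norm) |>
      dplyr::select("trait_text", "frequency") |>
      utils::head(30)
  } else {
    coverage$top_unmapped <- unmapped |>
      dplyr::mutate(frequency = 1L) |>
      dplyr::arrange(.data$trait_norm) |>
      dplyr::select("trait_text", "frequency") |>
      utils::head(30)
  }

  structure(list(mapped = mapped, unmapped = unmapped, coverage = coverage),
            class = "phenomap")
}

#' @export
print.phenomap <- function(x, ...) {
  cv <- x$coverage
  cat(sprintf(paste0("<phenomap> %d distinct traits: %d exact, %d fuzzy, ",
                     "%d embedding, %d unmapped\n"),
              cv$n_traits, cv$per_stage_counts$exact,
              cv$per_stage_counts$fuzzy, cv$per_stage_counts$embedding,
              cv$n_unmapped))
  invisible(x)
}

#' Expand harmonized records into gene-phenotype links
#'
#' Joins association records to mapped traits on the normalized trait
#' form. Records with unmapped traits produce no links; multi-PT concepts
#' fan out to one link per (PT, SOC) pair; the source and evidence class
#' are carried through. Links are unique on
#' (gene, PT, SOC, source, evidence class).
#'
#' @param records Harmonized association records ([harmonize_all()]).
#' @param mapping A `phenomap` object from [map_cascade()] (or its
#'   `mapped` tibble).
#' @return A tibble of links with columns `gene_symbol`, `pt_term`,
#'   `soc_term`, `source_id`, `evidence_class`, `stage`, `similarity`.
#' @export
expand_links <- function(records, mapping) {
  mapped <- if (inherits(mapping, "phenomap")) mapping$mapped else
    tibble::as_tibble(mapping)
  stage_rank <- c(exact = 1L, fuzzy = 2L, embedding = 3L)
  records |>
    tibble::as_tibble() |>
    dplyr::mutate(trait_norm = normalize_term(.data$trait_text)) |>
    dplyr::inner_join(
      mapped |>
        dplyr::distinct(.data$trait_norm, .data$pt_term, .data$soc_term,
                        .data$stage, .data$similarity),
      by = "trait_norm", relationship = "many-to-many") |>
    dplyr::arrange(stage_rank[.data$stage], dplyr::desc(.data$similarity)) |>
    dplyr::distinct(.data$gene_symbol, .data$pt_term, .data$soc_term,
                    .data$source_id, .data$evidence_class,
                    .keep_all = TRUE) |>
    dplyr::select("gene_symbol", "pt_term", "soc_term", "source_id",
                  "evidence_class", "stage", "similarity") |>
    dplyr::arrange(.data$soc_term, .data$pt_term, .data$gene_symbol,
                   .data$source_id)
}
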