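#' Declare one source association table
#'
#' Wraps a raw gene-trait table together with its identity, evidence class
#' and filter policy. The policy names the retention rule
#' [harmonize_all()] applies: `"gwas"` (p-value + effect validity),
#' `"clinvar"` (sub-source provenance), `"disgenet"` (type/source
#' whitelists) or `"passthrough"` (deduplication and biotype filtering
#' only).
#'
#' @param source_id Short unique database name.
#' @param evidence_class `"genetic"` or `"pharmacological"`.
#' @param policy Filter policy; one of `"passthrough"`, `"gwas"`,
#'   `"clinvar"`, `"disgenet"`.
#' @param data Data frame with at least `gene_symbol` and `trait_text`;
#'   policies may require `p_value`, `effect_ok`, `association_type` or
#'   `sub_source`.
#' @return An object of class `source_table`.
#' @export
source_table <- function(source_id,
                         evidence_class = c("genetic", "pharmacological"),
                         policy = c("passthrough", "gwas", "clinvar",
                                    "disgenet"),
                         data) {
  evidence_class <- match.arg(evidence_class)
  policy <- match.arg(policy)
  stopifnot(is.character(source_id), length(source_id) == 1,
            nzchar(source_id))
  data <- tibble::as_tibble(data)
  miss <- setdiff(c("gene_symbol", "trait_text"), names(data))
  if (length(miss) > 0) {
    stop("source table `", source_id, "` is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if ("p_value" %in% names(data)) {
    p <- data$p_value[!is.na(data$p_value)]
    if (any(p < 0 | p > 1)) {
      stop("p_value outside [0, 1] in source `", source_id, "`")
    }
  }
  structure(list(source_id = source_id, evidence_class = evidence_class,
                 policy = policy, data = data),
            class = "source_table")
}

#' @export
print.source_table <- function(x, ...) {
  cat(sprintf("<source_table> %s (%s, policy %s): %d records\n",
              x$source_id, x$evidence_class, x$policy, nrow(x$data)))
  invisible(x)
}

#' Filter a GWAS-like association table
#'
#' Retains records whose p-value is present and at most the genome-wide
#' threshold (inclusive) and whose effect estimate is flagged valid;
#' records with invalid or missing odds ratios / beta coefficients are
#' eliminated. Input order is preserved.
#'
#' @param records Data frame with columns `p_value` and `effect_ok`.
#' @param cfg A [filter_config()].
#' @return The retained records as a tibble.
#' @export
filter_gwas_like <- function(records, cfg = filter_config()) {
  records <- tibble::as_tibble(records)
  for (col in c("p_value", "effect_ok")) {
    if (!col %in% names(records)) {
      stop("gwas-like filter requires column `", col, "`")
    }
  }
  dplyr::filter(records,
                !is.na(.data$p_value),
                .data$p_value <= cfg$gwas_p_threshold,
                !is.na(.data$effect_ok),
                .data$effect_ok)
}

#' Filter a ClinVar-like association table
#'
#' Removes records whose sub-source annotation is absent, empty, or in the
#' configured exclusion set (by default the literal string `"NA"`):
#' associations without usable provenance do not enter downstream
#' processing.
#'
#' @inheritParams filter_gwas_like
#' @param records Data frame with a `sub_source` column.
#' @return The retained records as a tibble.
#' @export
filter_clinvar_like <- function(records, cfg = filter_config()) {
  records <- tibble::as_tibble(records)
  if (!"sub_source" %in% names(records)) {
    stop("clinvar-like filter requires column `sub_source`")
  }
  dplyr::filter(records,
                !is.na(.data$sub_source),
                nzchar(.data$sub_source),
                !.data$sub_source %in% cfg$clinvar_excluded_sub_sources)
}

#' Filter a DisGeNET-like association table
#'
#' Retains records whose association type is one of the genetic-evidence
#' classes and whose sub-source is on the human-genetics whitelist; both
#' conditions must hold.
#'
#' @inheritParams filter_gwas_like
#' @param records Data frame with `association_type` and `sub_source`.
#' @return The retained records as a tibble.
#' @export
filter_disgenet_like <- function(records, cfg = filter_config()) {
  records <- tibble::as_tibble(records)
  for (col in c("association_type", "sub_source")) {
    if (!col %in% names(records)) {
      stop("disgenet-like filter requires column `", col, "`")
    }
  }
  dplyr::filter(records,
                !is.na(.data$association_type),
                .data$association_type %in% cfg$disgenet_allowed_types,
                !is.na(.data$sub_source),
                .data$sub_source %in% cfg$disgenet_allowed_sources)
}

apply_source_policy <- function(tb, cfg) {
  switch(tb$policy,
         gwas = filter_gwas_like(tb$data, cfg),
         clinvar = filter_clinvar_like(tb$data, cfg),
         disgenet = filter_disgenet_like(tb$data, cfg),
         passthrough = tibble::as_tibble(tb$data),
         stop("no filter policy registered for source `", tb$source_id, "`"))
}

#' Harmonize all source tables into one evidence table
#'
#' Applies each source's filter policy, trims gene symbols, restricts to
#' the protein-coding gene universe when configured, tags every record
#' with its source and evidence class, and deduplicates on
#' (gene, trait, source).
#'
#' @param tables A list of [source_table()] objects (a single object is
#'   also accepted).
#' @param gene_universe Data frame with columns `gene_symbol`, `biotype`;
#'   required when `cfg$require_protein_coding` is `TRUE`. Symbols are
#'   matched case-sensitively after whitespace trimming.
#' @param cfg A [filter_config()].
#' @return A tibble of harmonized association records with columns
#'   `gene_symbol`, `trait_text`, `source_id`, `evidence_class`, unique on
#'   (gene, trait, source).
#' @export
harmonize_all <- function(tables, gene_universe = NULL,
                          cfg = filter_config()) {
  if (inherits(tables, "source_table")) tables <- list(tables)
  stopifnot(length(tables) > 0,
            all(vapply(tables, inherits, logical(1), "source_table")))
  ids <- vapply(tables, function(tb) tb$source_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate source_id: ", paste(unique(ids[duplicated(ids)]),
                                        collapse = ", "))
  }
  records <- purrr::map(tables, function(tb) {
    apply_source_policy(tb, cfg) |>
      dplyr::transmute(gene_symbol = trimws(.data$gene_symbol),
                       trait_text = .data$trait_text,
                       source_id = tb$source_id,
                       evidence_class = tb$evidence_class)
  }) |>
    purrr::list_rbind()
  if (isTRUE(cfg$require_protein_coding)) {
    if (is.null(gene_universe)) {
      stop("gene universe is required when require_protein_coding = TRUE")
    }
    coding <- tibble::as_tibble(gene_universe) |>
      dplyr::filter(.data$biotype == "protein_coding") |>
      dplyr::transmute(gene_symbol = trimws(.data$gene_symbol))
    records <- dplyr::semi_join(records, coding, by = "gene_symbol")
  }
  records |>
    dplyr::distinct(.data$gene_symbol, .data$trait_text, .data$source_id,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$source_id, .data$gene_symbol, .data$trait_text)
}
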