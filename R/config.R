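#' Harmonization filter configuration
#'
#' Source-specific retention rules applied before deduplication:
#' genome-wide significance for GWAS-like sources, provenance ("NA"
#' sub-source) exclusion for ClinVar-like sources, and association-type /
#' sub-source whitelists for DisGeNET-like sources.
#'
#' @param gwas_p_threshold Inclusive p-value cutoff for GWAS-like sources;
#'   associations with `p_value <= gwas_p_threshold` are retained
#'   (default `5e-8`, genome-wide significance).
#' @param clinvar_excluded_sub_sources Sub-source annotations treated as
#'   missing provenance and excluded (default `"NA"`; records with an
#'   absent sub-source are excluded as well).
#' @param disgenet_allowed_types Association types counted as human
#'   genetic evidence.
#' @param disgenet_allowed_sources Sub-sources counted as human genetic
#'   evidence.
#' @param require_protein_coding Restrict genes to the protein-coding
#'   universe (default `TRUE`).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(gwas_p_threshold = 5e-8,
                          clinvar_excluded_sub_sources = "NA",
                          disgenet_allowed_types = c(
                            "CausalMutation", "GermlineCausalMutation",
                            "SomaticCausalMutation", "SusceptibilityMutation",
                            "ModifyingMutation", "GeneticVariation"),
                          disgenet_allowed_sources = c(
                            "ClinGen", "ClinVar", "Genomics England",
                            "GWAS Catalog", "GWASDB", "HPO", "Orphanet"),
                          require_protein_coding = TRUE) {
  stopifnot(is.numeric(gwas_p_threshold), length(gwas_p_threshold) == 1,
            gwas_p_threshold > 0, gwas_p_threshold < 1,
            is.character(clinvar_excluded_sub_sources),
            is.character(disgenet_allowed_types),
            is.character(disgenet_allowed_sources),
            isTRUE(require_protein_coding) || isFALSE(require_protein_coding))
  structure(list(gwas_p_threshold = gwas_p_threshold,
                 clinvar_excluded_sub_sources = clinvar_excluded_sub_sources,
                 disgenet_allowed_types = disgenet_allowed_types,
                 disgenet_allowed_sources = disgenet_allowed_sources,
                 require_protein_coding = require_protein_coding),
            class = "filter_config")
}

#' Trait-mapping cascade configuration
#'
#' @param embedding_threshold Minimum cosine similarity for the embedding
#'   stage to accept its top candidate; acceptance is inclusive at the
#'   threshold (default 0.7).
#' @param fuzzy_min_score Minimum similarity for the fuzzy stage to accept
#'   its top candidate, inclusive (default 0.85).
#' @return An object of class `mapper_config`. The stage order is fixed:
#'   exact/partial lexicon match, then fuzzy, then embedding.
#' @export
mapper_config <- function(embedding_threshold = 0.7, fuzzy_min_score = 0.85) {
  stopifnot(is.numeric(embedding_threshold), length(embedding_threshold) == 1,
            embedding_threshold >= 0, embedding_threshold <= 1,
            is.numeric(fuzzy_min_score), length(fuzzy_min_score) == 1,
            fuzzy_min_score >= 0, fuzzy_min_score <= 1)
  structure(list(embedding_threshold = embedding_threshold,
                 fuzzy_min_score = fuzzy_min_score,
                 stage_order = c("exact", "fuzzy", "embedding")),
            class = "mapper_config")
}

#' Safetyome assembly configuration
#'
#' @param excluded_socs System organ classes dropped before panel assembly
#'   because they do not name a specific organ. No default is hard-coded;
#'   the set is vocabulary-specific and must be supplied.
#' @param cutoff_percentile Genes whose score percentile rank is greater
#'   than or equal to this value are retained (default 50).
#' @param min_sources_pt Minimum number of distinct supporting sources for
#'   a gene to join a phenotype-level panel (default 2).
#' @return An object of class `safetyome_config`.
#' @export
safetyome_config <- function(excluded_socs = character(),
                             cutoff_percentile = 50,
                             min_sources_pt = 2L) {
  stopifnot(is.character(excluded_socs),
            is.numeric(cutoff_percentile), length(cutoff_percentile) == 1)
  if (is.na(cutoff_percentile) || cutoff_percentile < 0 ||
      cutoff_percentile > 100) {
    stop("cutoff_percentile must lie in [0, 100]")
  }
  if (!is.numeric(min_sources_pt) || min_sources_pt < 1) {
    stop("min_sources_pt must be a positive integer")
  }
  structure(list(excluded_socs = excluded_socs,
                 cutoff_percentile = cutoff_percentile,
                 min_sources_pt = as.integer(min_sources_pt)),
            class = "safetyome_config")
}
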