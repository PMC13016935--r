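#' Synthetic world configuration
#'
#' Parameters of the fully synthetic test "world": a two-level phenotype
#' hierarchy with opaque labels (SOC_01, PT_0042, GENE0001 -- no real
#' vocabulary strings are fabricated), nine evidence sources mirroring the
#' seven-genetics-plus-two-pharmacology composition, an independent
#' disease-gene table derived from the planted ground truth, a gene x
#' tissue expression matrix and a cross-species orthology table.
#'
#' @param n_genes Number of protein-coding genes.
#' @param n_socs Number of system organ classes (default 27, of which
#'   `n_nonorgan_socs` are flagged as not mappable to a specific organ).
#' @param n_nonorgan_socs Number of non-organ SOCs (default 5).
#' @param pts_per_soc Preferred terms per SOC.
#' @param n_sources Number of evidence sources (default 9; the first is
#'   GWAS-like, the third ClinVar-like, the fourth DisGeNET-like, the
#'   last `n_pharmacological` are pharmacological).
#' @param n_pharmacological Number of pharmacology sources (default 2).
#' @param synonyms_per_concept Lexicon synonyms per concept (1 to 6).
#' @param multi_pt_rate Fraction of concepts covering two preferred terms
#'   of the same SOC (exercises multi-PT fan-out).
#' @param multi_source_rate Fraction of non-core gene-concept assignments
#'   supported by at least two sources.
#' @param trait_noise_rate Fraction of association traits perturbed
#'   (character substitution, transposition, or token replacement) so the
#'   exact lexicon stage fails and later cascade stages are exercised.
#' @param assoc_dropout Fraction of true association records dropped.
#' @param disease_noise_rate Per-gene probability that a disease-set gene
#'   is replaced by a random gene.
#' @param n_core_truth Number of planted high-priority genes (dense
#'   multi-source evidence, single-tissue expression, maximal
#'   conservation).
#' @param n_tissues Number of expression tissues.
#' @param n_noncoding Number of non-protein-coding decoy genes in the
#'   gene universe.
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `world_config`.
#' @export
world_config <- function(n_genes = 400L, n_socs = 27L, n_nonorgan_socs = 5L,
                         pts_per_soc = 6L, n_sources = 9L,
                         n_pharmacological = 2L, synonyms_per_concept = 3L,
                         multi_pt_rate = 0.1, multi_source_rate = 0.6,
                         trait_noise_rate = 0, assoc_dropout = 0,
                         disease_noise_rate = 0, n_core_truth = 25L,
                         n_tissues = 12L, n_noncoding = 10L, seed = 1L) {
  rates <- c(multi_pt_rate = multi_pt_rate,
             multi_source_rate = multi_source_rate,
             trait_noise_rate = trait_noise_rate,
             assoc_dropout = assoc_dropout,
             disease_noise_rate = disease_noise_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("all rates must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  }
  if (n_genes < 1) stop("n_genes must be positive")
  if (n_socs <= n_nonorgan_socs) {
    stop("need at least one organ SOC: n_socs must exceed n_nonorgan_socs")
  }
  if (pts_per_soc < 1 || pts_per_soc * n_socs < 2) {
    stop("infeasible config: pts_per_soc * n_socs leaves too few phenotypes")
  }
  if (synonyms_per_concept < 1 || synonyms_per_concept > 6) {
    stop("synonyms_per_concept must be between 1 and 6")
  }
  if (n_core_truth > n_genes) stop("n_core_truth cannot exceed n_genes")
  if (n_tissues < 2) stop("n_tissues must be at least 2")
  if (n_sources < 4 || n_pharmacological >= n_sources) {
    stop("need at least 4 sources and fewer pharmacological than total")
  }
  structure(list(n_genes = as.integer(n_genes), n_socs = as.integer(n_socs),
                 n_nonorgan_socs = as.integer(n_nonorgan_socs),
                 pts_per_soc = as.integer(pts_per_soc),
                 n_sources = as.integer(n_sources),
                 n_pharmacological = as.integer(n_pharmacological),
                 synonyms_per_concept = as.integer(synonyms_per_concept),
                 multi_pt_rate = multi_pt_rate,
                 multi_source_rate = multi_source_rate,
                 trait_noise_rate = trait_noise_rate,
                 assoc_dropout = assoc_dropout,
                 disease_noise_rate = disease_noise_rate,
                 n_core_truth = as.integer(n_core_truth),
                 n_tissues = as.integer(n_tissues),
                 n_noncoding = as.integer(n_noncoding),
                 seed = as.integer(seed)),
            class = "world_config")
}

synonym_templates <- c("%s disorder", "%s syndrome", "disorder of %s",
                       "%s dysfunction", "abnormal %s", "%s anomaly")

source_specs <- function(cfg) {
  if (cfg$n_sources == 9L) {
    ids <- c("gwas", "phegeni", "clinvar", "disgenet", "hpo", "diseases",
             "opentargets", "drugbank", "ttd")
    policies <- c("gwas", "gwas", "clinvar", "disgenet", "passthrough",
                  "passthrough", "passthrough", "passthrough", "passthrough")
  } else {
    ids <- sprintf("src_%02d", seq_len(cfg$n_sources))
    policies <- rep("passthrough", cfg$n_sources)
    policies[1] <- "gwas"
    policies[2] <- "clinvar"
    policies[3] <- "disgenet"
  }
  tibble::tibble(
    source_id = ids, policy = policies,
    evidence_class = c(rep("genetic", cfg$n_sources - cfg$n_pharmacological),
                       rep("pharmacological", cfg$n_pharmacological)))
}

# Perturb a trait so the exact/partial lexicon stage misses it: a single
# character substitution or adjacent transposition in the longest token
# (recoverable by the fuzzy stage), or replacement of that token with an
# out-of-lexicon word (left to the embedding stage).
perturb_term <- function(term, kind) {
  tokens <- strsplit(term, " ", fixed = TRUE)[[1]]
  i <- which.max(nchar(tokens))
  tok <- tokens[[i]]
  k <- nchar(tok)
  if (kind == "substitute" && k >= 2) {
    pos <- sample.int(k - 1, 1) + 1
    ch <- if (substr(tok, pos, pos) == "q") "x" else "q"
    substr(tok, pos, pos) <- ch
  } else if (kind == "transpose" && k >= 3) {
    pos <- sample.int(k - 2, 1) + 1
    tok <- paste0(substr(tok, 1, pos - 1), substr(tok, pos + 1, pos + 1),
                  substr(tok, pos, pos), substr(tok, pos + 2, k))
  } else {
    tok <- paste0(sample(letters, 5, replace = TRUE), collapse = "")
  }
  tokens[[i]] <- tok
  paste(tokens, collapse = " ")
}

build_hierarchy_tables <- function(cfg) {
  socs <- sprintf("SOC_%02d", seq_len(cfg$n_socs))
  nonorgan <- utils::tail(socs, cfg$n_nonorgan_socs)
  pts <- tibble::tibble(
    pt_term = sprintf("PT_%04d", seq_len(cfg$n_socs * cfg$pts_per_soc)),
    soc_term = rep(socs, each = cfg$pts_per_soc))
  # partition each SOC's PTs into concepts; some concepts span two PTs
  concept_rows <- list()
  k <- 0L
  for (soc in socs) {
    soc_pts <- pts$pt_term[pts$soc_term == soc]
    i <- 1L
    while (i <= length(soc_pts)) {
      k <- k + 1L
      two <- i < length(soc_pts) && stats::runif(1) < cfg$multi_pt_rate
      members <- soc_pts[i:(i + as.integer(two))]
      concept_rows[[k]] <- tibble::tibble(
        concept_id = sprintf("C%05d", k),
        pt_term = members, soc_term = soc,
        base = tolower(gsub("_", " ", members[[1]])))
      i <- i + 1L + as.integer(two)
    }
  }
  concept_pts <- purrr::list_rbind(concept_rows)
  concepts <- dplyr::distinct(concept_pts, .data$concept_id, .data$base,
                              .data$soc_term)
  synonyms <- concepts |>
    tidyr::expand_grid(template =
                         synonym_templates[seq_len(cfg$synonyms_per_concept)]) |>
    dplyr::mutate(synonym = sprintf(.data$template, .data$base)) |>
    dplyr::select("concept_id", "synonym")
  hierarchy <- synonyms |>
    dplyr::inner_join(dplyr::select(concept_pts, "concept_id", "pt_term",
                                    "soc_term"),
                      by = "concept_id", relationship = "many-to-many") |>
    dplyr::select("concept_id", "synonym", "pt_term", "soc_term") |>
    dplyr::arrange(.data$concept_id, .data$synonym, .data$pt_term)
  list(socs = socs, nonorgan = nonorgan, pts = pts,
       concept_pts = concept_pts, concepts = concepts,
       synonyms = synonyms, hierarchy = hierarchy)
}

#' Generate a synthetic world with planted ground truth
#'
#' Deterministic given `cfg$seed`: the same configuration always produces
#' byte-identical tables. Every generated association is derivable from
#' the recorded ground truth plus the logged noise events. Each gene
#' belongs to one SOC and draws one to three phenotype concepts within
#' it; planted core genes get evidence in every source, single-tissue
#' expression and maximal cross-species conservation. Disease gene sets
#' are the ground-truth concept gene sets (optionally perturbed), so at
#' zero noise the downstream SOC match rate is 100% by construction.
#' Filter-violating decoy records (above-threshold p-values, invalid
#' effects, missing provenance, non-whitelisted types, non-coding genes)
#' are always included so the harmonization filters are exercised; they
#' are excluded from the ground truth because the filters remove them.
#'
#' @param cfg A [world_config()].
#' @return An object of class `safetyome_world`: a list with `config`,
#'   `hierarchy` (tibble), `sources` (list of [source_table()]),
#'   `gene_universe`, `disease_gene`, `expression`, `orthology` tibbles
#'   and `truth` (ground-truth associations, links, core genes, disease
#'   labels, non-organ SOCs, noise events).
#' @export
generate_world <- function(cfg = world_config()) {
  stopifnot(inherits(cfg, "world_config"))
  with_seed(cfg$seed, generate_world_impl(cfg))
}

generate_world_impl <- function(cfg) {
  hier <- build_hierarchy_tables(cfg)
  specs <- source_specs(cfg)
  organ_socs <- setdiff(hier$socs, hier$nonorgan)

  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  core_genes <- sort(sample(genes, cfg$n_core_truth))
  soc_of_gene <- sample(hier$socs, cfg$n_genes, replace = TRUE)
  names(soc_of_gene) <- genes
  soc_of_gene[core_genes] <- sample(organ_socs, cfg$n_core_truth,
                                    replace = TRUE)

  concepts_by_soc <- split(hier$concepts$concept_id, hier$concepts$soc_term)

  # gene -> concept assignments, then per-assignment supporting sources
  assignments <- purrr::map(genes, function(g) {
    pool <- concepts_by_soc[[soc_of_gene[[g]]]]
    is_core <- g %in% core_genes
    k <- min(if (is_core) 3L else sample.int(3L, 1), length(pool))
    tibble::tibble(gene_symbol = g,
                   concept_id = sample(pool, k),
                   is_core = is_core)
  }) |> purrr::list_rbind()

  assoc <- assignments |>
    dplyr::mutate(sources = purrr::map(.data$is_core, function(core) {
      if (core) return(specs$source_id)
      k <- if (stats::runif(1) < cfg$multi_source_rate) {
        sample(2:min(4L, cfg$n_sources), 1)
      } else 1L
      sample(specs$source_id, k)
    })) |>
    tidyr::unnest_longer("sources", values_to = "source_id")

  # verbatim lexicon synonym per record, then optional trait noise
  syn_by_concept <- split(hier$synonyms$synonym, hier$synonyms$concept_id)
  assoc$trait_text <- vapply(assoc$concept_id, function(cid) {
    s <- syn_by_concept[[cid]]
    s[[sample.int(length(s), 1)]]
  }, character(1))
  noisy <- stats::runif(nrow(assoc)) < cfg$trait_noise_rate
  noise_events <- tibble::tibble(
    row = which(noisy),
    original = assoc$trait_text[noisy],
    kind = sample(c("substitute", "transpose", "rephrase"), sum(noisy),
                  replace = TRUE))
  if (nrow(noise_events) > 0) {
    noise_events$perturbed <- vapply(seq_len(nrow(noise_events)), function(i) {
      perturb_term(noise_events$original[[i]], noise_events$kind[[i]])
    }, character(1))
    assoc$trait_text[noise_events$row] <- noise_events$perturbed
  }

  keep <- stats::runif(nrow(assoc)) >= cfg$assoc_dropout
  assoc <- assoc[keep, ]
  assoc <- dplyr::left_join(assoc, specs, by = "source_id")

  coding_universe <- tibble::tibble(gene_symbol = genes,
                                    biotype = "protein_coding")
  noncoding <- tibble::tibble(
    gene_symbol = sprintf("GENENC%02d", seq_len(cfg$n_noncoding)),
    biotype = "lncRNA")
  gene_universe <- dplyr::bind_rows(coding_universe, noncoding)

  all_synonyms <- hier$synonyms$synonym
  decoy_trait <- function(n) sample(all_synonyms, n, replace = TRUE)
  decoy_gene <- function(n) sample(genes, n, replace = TRUE)

  sources <- purrr::pmap(specs, function(source_id, policy, evidence_class) {
    sid <- source_id
    rows <- assoc |>
      dplyr::filter(.data$source_id == sid) |>
      dplyr::select("gene_symbol", "trait_text")
    decoys <- NULL
    if (policy == "gwas") {
      rows$p_value <- 10^(-stats::runif(nrow(rows), 8.5, 20))
      rows$effect_ok <- TRUE
      decoys <- tibble::tibble(
        gene_symbol = decoy_gene(3), trait_text = decoy_trait(3),
        p_value = c(1e-4, 1e-9, NA), effect_ok = c(TRUE, FALSE, TRUE))
    } else if (policy == "clinvar") {
      rows$sub_source <- sample(c("OMIM", "Orphanet", "GeneReviews"),
                                nrow(rows), replace = TRUE)
      decoys <- tibble::tibble(
        gene_symbol = decoy_gene(2), trait_text = decoy_trait(2),
        sub_source = c("NA", NA))
    } else if (policy == "disgenet") {
      rows$association_type <- sample(
        filter_config()$disgenet_allowed_types, nrow(rows), replace = TRUE)
      rows$sub_source <- sample(filter_config()$disgenet_allowed_sources,
                                nrow(rows), replace = TRUE)
      decoys <- tibble::tibble(
        gene_symbol = decoy_gene(2), trait_text = decoy_trait(2),
        association_type = c("Biomarker", "GeneticVariation"),
        sub_source = c("ClinVar", "UnlistedDB"))
    } else if (source_id %in% c("hpo", "src_04")) {
      decoys <- tibble::tibble(
        gene_symbol = noncoding$gene_symbol[
          seq_len(min(2, nrow(noncoding)))],
        trait_text = decoy_trait(min(2, nrow(noncoding))))
    }
    source_table(source_id, evidence_class, policy,
                 dplyr::bind_rows(rows, decoys))
  })
  names(sources) <- specs$source_id

  # ground truth reflects what survives noise and dropout
  truth_associations <- assoc |>
    dplyr::distinct(.data$gene_symbol, .data$trait_text, .data$source_id,
                    .data$evidence_class) |>
    dplyr::arrange(.data$source_id, .data$gene_symbol, .data$trait_text)
  truth_links <- assoc |>
    dplyr::inner_join(dplyr::select(hier$concept_pts, "concept_id",
                                    "pt_term", "soc_term"),
                      by = "concept_id", relationship = "many-to-many") |>
    dplyr::distinct(.data$gene_symbol, .data$pt_term, .data$soc_term,
                    .data$source_id, .data$evidence_class) |>
    dplyr::arrange(.data$soc_term, .data$pt_term, .data$gene_symbol,
                   .data$source_id)

  # disease-gene table: one disease per concept with surviving evidence;
  # half the terms are verbatim synonyms, half carry a suffix token so the
  # stage-1 partial (containment) path is exercised deterministically
  concept_genes <- assoc |>
    dplyr::distinct(.data$concept_id, .data$gene_symbol)
  active_concepts <- sort(unique(concept_genes$concept_id))
  disease_defs <- tibble::tibble(concept_id = active_concepts) |>
    dplyr::mutate(
      base_syn = vapply(.data$concept_id,
                        function(cid) syn_by_concept[[cid]][[1]],
                        character(1)),
      disease_term = ifelse(seq_along(active_concepts) %% 2 == 0,
                            .data$base_syn,
                            paste(.data$base_syn, "ctd")))
  disease_gene <- disease_defs |>
    dplyr::inner_join(concept_genes, by = "concept_id") |>
    dplyr::select("disease_term", "gene_symbol")
  swap <- stats::runif(nrow(disease_gene)) < cfg$disease_noise_rate
  if (any(swap)) {
    disease_gene$gene_symbol[swap] <- sample(genes, sum(swap), replace = TRUE)
  }
  disease_gene <- disease_gene |>
    dplyr::distinct() |>
    dplyr::mutate(direct_evidence = 1L)
  indirect <- tibble::tibble(
    disease_term = sample(disease_defs$disease_term,
                          min(5, nrow(disease_defs))),
    gene_symbol = decoy_gene(min(5, nrow(disease_defs))),
    direct_evidence = 0L)
  disease_gene <- dplyr::bind_rows(disease_gene, indirect) |>
    dplyr::arrange(.data$disease_term, .data$gene_symbol,
                   .data$direct_evidence)

  truth_disease_labels <- disease_defs |>
    dplyr::inner_join(dplyr::select(hier$concept_pts, "concept_id",
                                    "pt_term", "soc_term"),
                      by = "concept_id", relationship = "many-to-many") |>
    dplyr::select("disease_term", "pt_term", "soc_term")

  # expression: planted core genes are single-tissue, the rest broad
  tissues <- sprintf("tissue_%02d", seq_len(cfg$n_tissues))
  expr_mat <- matrix(stats::runif(cfg$n_genes * cfg$n_tissues, 5, 15),
                     nrow = cfg$n_genes,
                     dimnames = list(genes, tissues))
  for (g in core_genes) {
    expr_mat[g, ] <- 0
    expr_mat[g, sample.int(cfg$n_tissues, 1)] <- stats::runif(1, 50, 100)
  }
  expression <- tibble::as_tibble(expr_mat, rownames = "gene_symbol")

  orthology <- tidyr::expand_grid(gene_symbol = genes,
                                  species = c("mouse", "rat", "dog")) |>
    dplyr::mutate(
      is_core = .data$gene_symbol %in% core_genes,
      identity_pct = ifelse(.data$is_core,
                            stats::runif(dplyr::n(), 99, 100),
                            stats::runif(dplyr::n(), 50, 95)),
      confident = ifelse(.data$is_core, 1L,
                         stats::rbinom(dplyr::n(), 1, 0.6))) |>
    dplyr::select("gene_symbol", "species", "identity_pct", "confident")

  structure(list(
    config = cfg,
    hierarchy = hier$hierarchy,
    sources = sources,
    gene_universe = gene_universe,
    disease_gene = disease_gene,
    expression = expression,
    orthology = orthology,
    truth = list(associations = truth_associations,
                 links = truth_links,
                 core_genes = core_genes,
                 disease_labels = truth_disease_labels,
                 nonorgan_socs = hier$nonorgan,
                 noise_events = noise_events)),
    class = "safetyome_world")
}

#' @export
print.safetyome_world <- function(x, ...) {
  cat(sprintf(paste0("<safetyome_world> %d genes, %d SOCs (%d non-organ), ",
                     "%d sources, %d true associations (seed %d)\n"),
              x$config$n_genes, x$config$n_socs, x$config$n_nonorgan_socs,
              length(x$sources), nrow(x$truth$associations),
              x$config$seed))
  invisible(x)
}

#' Write a synthetic world to a directory of TSV files
#'
#' Emits the hierarchy, one TSV per source plus a `sources.yaml`
#' describing each source's evidence class and filter policy, the gene
#' universe, disease-gene, expression and orthology tables, the
#' ground-truth association and link tables, and a `ground_truth.yaml`
#' with the planted core genes and non-organ SOCs. Output is
#' byte-identical for identical configurations.
#'
#' @param world A [generate_world()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "safetyome_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    readr::write_tsv(x, file.path(dir, name), progress = FALSE)
  }
  tsv(world$hierarchy, "hierarchy.tsv")
  for (tb in world$sources) {
    tsv(tb$data, paste0("source_", tb$source_id, ".tsv"))
  }
  src_meta <- lapply(world$sources, function(tb) {
    list(evidence_class = tb$evidence_class, policy = tb$policy,
         path = paste0("source_", tb$source_id, ".tsv"))
  })
  yaml::write_yaml(src_meta, file.path(dir, "sources.yaml"))
  tsv(world$gene_universe, "gene_universe.tsv")
  tsv(world$disease_gene, "disease_gene.tsv")
  tsv(world$expression, "expression.tsv")
  tsv(world$orthology, "orthology.tsv")
  tsv(world$truth$associations, "truth_associations.tsv")
  tsv(world$truth$links, "truth_links.tsv")
  yaml::write_yaml(list(core_genes = world$truth$core_genes,
                        nonorgan_socs = world$truth$nonorgan_socs,
                        seed = world$config$seed),
                   file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}

#' Read a written world back from a directory
#'
#' @param dir Directory produced by [write_world()].
#' @return A list with the same table components as a
#'   [generate_world()] result (without the ground truth's noise log).
#' @export
read_world <- function(dir) {
  tsv <- function(name) {
    readr::read_tsv(file.path(dir, name), show_col_types = FALSE,
                    progress = FALSE)
  }
  src_meta <- yaml::read_yaml(file.path(dir, "sources.yaml"))
  sources <- purrr::imap(src_meta, function(meta, id) {
    source_table(id, meta$evidence_class, meta$policy,
                 tsv(meta$path))
  })
  gt <- yaml::read_yaml(file.path(dir, "ground_truth.yaml"))
  list(hierarchy = tsv("hierarchy.tsv"),
       sources = sources,
       gene_universe = tsv("gene_universe.tsv"),
       disease_gene = tsv("disease_gene.tsv"),
       expression = tsv("expression.tsv"),
       orthology = tsv("orthology.tsv"),
       truth = list(associations = tsv("truth_associations.tsv"),
                    links = tsv("truth_links.tsv"),
                    core_genes = unlist(gt$core_genes),
                    nonorgan_socs = unlist(gt$nonorgan_socs)))
}
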