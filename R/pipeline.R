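read_config <- function(config) {
  if (is.character(config)) {
    base <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    config$.base <- base
  } else if (is.list(config)) {
    config$.base <- config$.base %||% "."
  } else {
    stop("config must be a YAML path or a list")
  }
  config
}

resolve_path <- function(path, base) {
  if (is.null(path)) return(NULL)
  if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(base, path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(name, ": ", conditionMessage(e), call. = FALSE)
  })
}

read_stage_tsv <- function(path, what) {
  if (is.null(path)) stop("missing input path for ", what)
  if (!file.exists(path)) stop(what, " file not found: ", path)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

apply_column_map <- function(df, columns) {
  if (is.null(columns)) return(df)
  dplyr::rename(df, !!!columns)
}

#' Run the full pipeline from configured input files
#'
#' Reads the hierarchy, per-source association tables, gene universe,
#' disease-gene table and (optionally) expression and orthology tables
#' named in the configuration; runs harmonization, trait mapping,
#' scoring, panel assembly, prioritization and validation; and writes all
#' artifacts plus a manifest with input/output checksums and a config
#' snapshot to the output directory. Errors carry the name of the failing
#' stage. Reruns on identical inputs and configuration are byte-identical.
#'
#' @param config Path to a YAML configuration file, or an equivalent
#'   list. Expected fields: `inputs` (paths `hierarchy`, `gene_universe`,
#'   `disease_gene`, optional `expression`, `orthology`, and a named
#'   `sources` map of `path` / `evidence_class` / `policy` / optional
#'   `columns` rename map per source), optional `params`
#'   (`filter`, `mapper`, `safetyome`, `core_n`, `pt_floor`, `sweep`),
#'   and `out_dir`.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- stage("config", read_config(config))
  base <- config$.base
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("config: out_dir is required", call. = FALSE)
  out_dir <- resolve_path(out_dir, base)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  inputs <- config$inputs %||% list()
  params <- config$params %||% list()
  filter_cfg <- do.call(filter_config, params$filter %||% list())
  mapper_cfg <- do.call(mapper_config, params$mapper %||% list())
  soc_params <- params$safetyome %||% list()
  soc_params$excluded_socs <- as.character(soc_params$excluded_socs %||%
                                             character())
  safetyome_cfg <- do.call(safetyome_config, soc_params)

  hierarchy <- stage("hierarchy", {
    phenotype_hierarchy(read_stage_tsv(
      resolve_path(inputs$hierarchy, base), "hierarchy"))
  })
  gene_universe <- stage("gene_universe", {
    read_stage_tsv(resolve_path(inputs$gene_universe, base), "gene universe")
  })
  tables <- stage("sources", {
    if (is.null(inputs$sources) || length(inputs$sources) == 0) {
      stop("no sources configured")
    }
    purrr::imap(inputs$sources, function(meta, id) {
      df <- read_stage_tsv(resolve_path(meta$path, base),
                           paste0("source ", id))
      source_table(id, meta$evidence_class %||% "genetic",
                   meta$policy %||% "passthrough",
                   apply_column_map(df, meta$columns))
    })
  })

  records <- stage("harmonize", {
    harmonize_all(tables, gene_universe, filter_cfg)
  })
  pm <- stage("map", {
    map_cascade(unique(records$trait_text), hierarchy, cfg = mapper_cfg,
                trait_sources = records)
  })
  links <- stage("map", expand_links(records, pm))
  scores <- stage("score", score_targets(records))
  soc <- stage("panels", build_soc_safetyome(links, scores, safetyome_cfg))
  pt <- stage("panels", {
    build_pt_panels(links, min_sources = safetyome_cfg$min_sources_pt)
  })

  core <- NULL
  if (!is.null(inputs$expression) && !is.null(inputs$orthology)) {
    core <- stage("prioritize", {
      tau <- tau_table(read_stage_tsv(
        resolve_path(inputs$expression, base), "expression"))
      cons <- conservation_score(read_stage_tsv(
        resolve_path(inputs$orthology, base), "orthology"))
      priorities <- scores |>
        dplyr::filter(.data$gene_symbol %in% soc$safetyome) |>
        dplyr::left_join(tau, by = "gene_symbol") |>
        dplyr::left_join(dplyr::select(cons, "gene_symbol", "conservation"),
                         by = "gene_symbol")
      suppressWarnings(
        build_core_panel(priorities, n = params$core_n %||% 500L))
    })
  }

  enrichment <- mr <- swept <- NULL
  if (!is.null(inputs$disease_gene)) {
    validated <- stage("validate", {
      disease_gene <- read_stage_tsv(
        resolve_path(inputs$disease_gene, base), "disease-gene table")
      disease_map <- map_diseases(disease_gene, hierarchy, cfg = mapper_cfg)
      enr <- enrich_panels(soc, disease_gene, disease_map)
      sw <- if (isTRUE(params$sweep)) {
        soc_scores <- score_targets(records, by = "soc", links = links)
        suppressWarnings(
          cutoff_sweep(links, soc_scores, disease_gene, disease_map,
                       cfg = safetyome_cfg))
      }
      list(enr = enr, mr = suppressWarnings(match_rate(enr)), swept = sw)
    })
    enrichment <- validated$enr
    mr <- validated$mr
    swept <- validated$swept
  }

  artifacts <- stage("write", {
    out <- function(name) file.path(out_dir, name)
    tsv <- function(x, name) {
      readr::write_tsv(x, out(name), progress = FALSE)
      name
    }
    written <- c(
      tsv(records, "harmonized.tsv"),
      tsv(links, "mapped_links.tsv"),
      tsv(pm$unmapped, "unmapped_traits.tsv"),
      tsv(scores, "scores.tsv"),
      tsv(panel_table(soc), "soc_panels_long.tsv"),
      tsv(panel_table(pt), "pt_panels_long.tsv"))
    cv <- pm$coverage
    yaml::write_yaml(list(
      n_traits = cv$n_traits,
      per_stage_counts = cv$per_stage_counts,
      n_unmapped = cv$n_unmapped,
      per_source_unmapped_fraction = cv$per_source_unmapped_fraction),
      out("coverage.yaml"))
    written <- c(written, "coverage.yaml")
    write_gmt(as_gmt(soc), out("soc_panels.gmt"))
    write_gmt(as_gmt(pt), out("pt_panels.gmt"))
    written <- c(written, "soc_panels.gmt", "pt_panels.gmt")
    if (!is.null(core)) {
      written <- c(written, tsv(core, "core_panel.tsv"))
      write_gmt(as_gmt(core), out("core_panel.gmt"))
      written <- c(written, "core_panel.gmt")
    }
    if (!is.null(enrichment)) {
      written <- c(written, tsv(enrichment, "enrichment.tsv"),
                   tsv(mr$per_panel, "match_rates.tsv"))
    }
    if (!is.null(swept)) written <- c(written, tsv(swept, "sweep.tsv"))
    written
  })

  input_paths <- c(hierarchy = resolve_path(inputs$hierarchy, base),
                   gene_universe = resolve_path(inputs$gene_universe, base),
                   disease_gene = resolve_path(inputs$disease_gene, base),
                   expression = resolve_path(inputs$expression, base),
                   orthology = resolve_path(inputs$orthology, base),
                   vapply(inputs$sources, function(m) {
                     resolve_path(m$path, base)
                   }, character(1)))
  config_snapshot <- config
  config_snapshot$.base <- NULL
  art_sums <- tools::md5sum(file.path(out_dir, artifacts))
  names(art_sums) <- artifacts
  manifest <- list(
    inputs = as.list(tools::md5sum(input_paths[!is.na(input_paths)])),
    artifacts = as.list(art_sums),
    config = config_snapshot)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
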