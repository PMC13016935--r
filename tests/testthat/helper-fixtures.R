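# Small deterministic fixtures shared across test files.

tiny_hierarchy <- function() {
  phenotype_hierarchy(tibble::tribble(
    ~concept_id, ~synonym,                ~pt_term,          ~soc_term,
    "C001",      "cardiac arrest",        "PT_CARD_ARREST",  "SOC_CARDIAC",
    "C001",      "heart arrest",          "PT_CARD_ARREST",  "SOC_CARDIAC",
    "C002",      "myocardial infarction", "PT_MI",           "SOC_CARDIAC",
    "C003",      "long qt syndrome",      "PT_LQT",          "SOC_CARDIAC",
    "C003",      "long qt syndrome",      "PT_QT_PROLONG",   "SOC_INVESTIG",
    "C004",      "renal failure",         "PT_RENAL_FAIL",   "SOC_RENAL"
  ))
}

# links builder: one row per (gene, pt, soc, source)
make_links <- function(df) {
  if (is.null(df[["evidence_class"]])) df$evidence_class <- "genetic"
  df$stage <- "exact"
  df$similarity <- 1
  tibble::as_tibble(df)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

small_world <- function(seed = 7, ...) {
  generate_world(world_config(n_genes = 80L, n_socs = 8L,
                              n_nonorgan_socs = 2L, pts_per_soc = 4L,
                              n_core_truth = 8L, n_tissues = 6L,
                              seed = seed, ...))
}

# brute-force percentile rank straight from the definition
oracle_percentile <- function(x) {
  vapply(x, function(v) 100 * sum(x < v) / length(x), numeric(1))
}

# exhaustive hypergeometric over-representation oracle: enumerate every
# possible disease-set draw from the universe and count draws with at
# least the observed overlap
enum_hypergeom <- function(panel, disease, universe) {
  k <- length(disease)
  q_obs <- length(intersect(panel, disease))
  draws <- utils::combn(universe, k)
  overlaps <- apply(draws, 2, function(d) length(intersect(d, panel)))
  mean(overlaps >= q_obs)
}
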