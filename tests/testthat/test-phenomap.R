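test_that("term normalization lowercases, strips punctuation and trims", {
  expect_identical(normalize_term("Long QT-syndrome "), "long qt syndrome")
  expect_identical(normalize_term("Cardiac   Arrest."), "cardiac arrest")
  expect_identical(normalize_term(""), "")
  expect_identical(normalize_term("  (Renal)  failure!! "), "renal failure")
})

test_that("exact lexicon hits map at stage exact with similarity 1", {
  h <- tiny_hierarchy()
  pm <- map_cascade(c("Cardiac Arrest.", "renal failure"), h)
  expect_identical(nrow(pm$unmapped), 0L)
  expect_true(all(pm$mapped$stage == "exact"))
  expect_true(all(pm$mapped$similarity == 1))
  expect_identical(
    pm$mapped$concept_id[pm$mapped$trait_norm == "cardiac arrest"], "C001")
})

test_that("partial containment picks the longest synonym, ties by concept", {
  h <- phenotype_hierarchy(tibble::tribble(
    ~concept_id, ~synonym,        ~pt_term, ~soc_term,
    "C010",      "renal",         "PT_A",   "SOC_R",
    "C011",      "renal failure", "PT_B",   "SOC_R",
    "C020",      "aa bb",         "PT_C",   "SOC_X",
    "C019",      "cc dd",         "PT_D",   "SOC_X"))
  pm <- map_cascade(c("acute renal failure", "aa bb cc dd"), h,
                    fuzzy = FALSE, embedder = FALSE)
  got <- pm$mapped[pm$mapped$trait_norm == "acute renal failure", ]
  expect_identical(unique(got$concept_id), "C011")  # longer match wins
  expect_identical(unique(got$stage), "exact")
  tie <- pm$mapped[pm$mapped$trait_norm == "aa bb cc dd", ]
  expect_identical(unique(tie$concept_id), "C019")  # smallest concept_id
})

test_that("near-miss traits fall through to the fuzzy stage", {
  h <- tiny_hierarchy()
  # one transposition in a 21-character synonym: similarity 1 - 2/21
  pm <- map_cascade("myocardial infraction", h)
  expect_identical(nrow(pm$unmapped), 0L)
  expect_identical(unique(pm$mapped$stage), "fuzzy")
  expect_identical(unique(pm$mapped$concept_id), "C002")
  expect_equal(unique(pm$mapped$similarity), 1 - 2 / 21, tolerance = 1e-10)
})

test_that("embedding acceptance is inclusive at the threshold", {
  h <- tiny_hierarchy()
  no_fuzzy <- function(query) {
    tibble::tibble(concept_id = character(), similarity = double())
  }
  stub <- function(sim) {
    function(query) tibble::tibble(concept_id = "C004", similarity = sim)
  }
  at <- map_cascade("unrelated text", h, fuzzy = no_fuzzy,
                    embedder = stub(0.7))
  below <- map_cascade("unrelated text", h, fuzzy = no_fuzzy,
                       embedder = stub(0.7 - 1e-9))
  expect_identical(unique(at$mapped$stage), "embedding")
  expect_identical(unique(at$mapped$concept_id), "C004")
  expect_identical(nrow(below$mapped), 0L)
  expect_identical(nrow(below$unmapped), 1L)
})

test_that("cascade stages partition mapped traits and add monotonically", {
  w <- small_world(seed = 3, trait_noise_rate = 0.5)
  h <- phenotype_hierarchy(w$hierarchy)
  traits <- unique(unlist(lapply(w$sources, function(tb) tb$data$trait_text)))
  full <- map_cascade(traits, h)
  no_embed <- map_cascade(traits, h, embedder = FALSE)
  exact_only <- map_cascade(traits, h, fuzzy = FALSE, embedder = FALSE)
  mapped_norms <- function(pm) unique(pm$mapped$trait_norm)
  expect_true(all(mapped_norms(exact_only) %in% mapped_norms(no_embed)))
  expect_true(all(mapped_norms(no_embed) %in% mapped_norms(full)))
  # noise pushed some traits past stage 1 so later stages really fire
  expect_gt(full$coverage$per_stage_counts$fuzzy, 0)
  # one stage per mapped trait, and the counts partition the traits
  stages <- full$mapped |>
    dplyr::distinct(trait_norm, stage) |>
    dplyr::count(trait_norm)
  expect_true(all(stages$n == 1))
  cv <- full$coverage
  expect_identical(
    sum(unlist(cv$per_stage_counts)) + cv$n_unmapped, cv$n_traits)
})

test_that("coverage accounting is per-source and deterministic", {
  w <- small_world(seed = 5, trait_noise_rate = 0.3)
  h <- phenotype_hierarchy(w$hierarchy)
  records <- harmonize_all(w$sources, w$gene_universe)
  run_once <- function() {
    map_cascade(unique(records$trait_text), h, trait_sources = records)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$coverage, b$coverage)
  expect_identical(a$mapped, b$mapped)
  frac <- unlist(a$coverage$per_source_unmapped_fraction)
  expect_true(all(frac >= 0 & frac <= 1))
})

test_that("records fan out to one link per PT/SOC pair and source", {
  h <- tiny_hierarchy()
  pm <- map_cascade(c("long qt syndrome", "no such trait zzz"), h,
                    fuzzy = FALSE, embedder = FALSE)
  records <- tibble::tibble(
    gene_symbol = c("KCNH2", "KCNH2", "SCN5A"),
    trait_text = c("long qt syndrome", "long qt syndrome",
                   "no such trait zzz"),
    source_id = c("gwas", "clinvar", "gwas"),
    evidence_class = "genetic")
  links <- expand_links(records, pm)
  # the multi-PT concept doubles each record; the unmapped trait vanishes
  expect_identical(nrow(links), 4L)
  expect_setequal(links$pt_term, c("PT_LQT", "PT_QT_PROLONG"))
  expect_identical(sum(links$source_id == "clinvar"), 2L)
  expect_false("SCN5A" %in% links$gene_symbol)
})
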