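soc_fixture <- function() {
  links <- make_links(tibble::tibble(
    gene_symbol = c("A", "B", "C", "D", "A", "E"),
    pt_term = c("P1", "P1", "P2", "P3", "P3", "P4"),
    soc_term = c("S1", "S1", "S1", "S2", "S2", "S9"),
    source_id = c("s1", "s2", "s1", "s1", "s2", "s1"),
    evidence_class = c("genetic", "pharmacological", "genetic", "genetic",
                       "genetic", "genetic")))
  scores <- tibble::tibble(gene_symbol = c("A", "B", "C", "D", "E"),
                           scaled = c(10, 7.5, 5, 2.5, 0),
                           percentile = c(80, 60, 40, 20, 0))
  list(links = links, scores = scores)
}

test_that("SOC safetyome applies exclusions and the inclusive cutoff", {
  fx <- soc_fixture()
  cfg <- safetyome_config(excluded_socs = "S9", cutoff_percentile = 40)
  soc <- build_soc_safetyome(fx$links, fx$scores, cfg)
  # S9 is excluded; C sits exactly at the cutoff and is retained
  expect_setequal(unique(soc$panels$panel_id), c("S1", "S2"))
  expect_setequal(soc$safetyome, c("A", "B", "C"))
  # union of panel genes is the safetyome
  expect_setequal(unique(soc$panels$gene_symbol), soc$safetyome)
  # cutoff 0 with no exclusions keeps every linked gene
  all_in <- build_soc_safetyome(fx$links, fx$scores, safetyome_config(
    cutoff_percentile = 0))
  expect_setequal(all_in$safetyome, c("A", "B", "C", "D", "E"))
  expect_error(safetyome_config(cutoff_percentile = 101), "0, 100")
  expect_error(
    build_soc_safetyome(fx$links, fx$scores[1:2, ], cfg),
    "missing")
})

test_that("a 1,000-gene cohort at cutoff 50 retains exactly 500 genes", {
  set.seed(1)
  genes <- sprintf("G%04d", 1:1000)
  raws <- sample(seq_len(1000))
  scores <- scale_scores(tibble::tibble(gene_symbol = genes, raw = raws))
  links <- make_links(tibble::tibble(
    gene_symbol = genes, pt_term = "P1", soc_term = "S1", source_id = "s1"))
  soc <- build_soc_safetyome(links, scores,
                             safetyome_config(cutoff_percentile = 50))
  expect_identical(length(soc$safetyome), 500L)
  # agrees with the brute-force strictly-below rank definition
  expect_identical(length(soc$safetyome),
                   sum(oracle_percentile(scores$scaled) >= 50))
})

test_that("raising the cutoff never adds safetyome genes", {
  fx <- soc_fixture()
  prev <- NULL
  for (ct in c(0, 20, 40, 60, 80, 100)) {
    cur <- build_soc_safetyome(fx$links, fx$scores,
                               safetyome_config(cutoff_percentile = ct))
    if (!is.null(prev)) expect_true(all(cur$safetyome %in% prev))
    prev <- cur$safetyome
  }
})

test_that("PT panels enforce the minimum distinct-source rule", {
  links <- make_links(tibble::tibble(
    gene_symbol = c("A", "B", "B", "C", "C", "C"),
    pt_term = "P1", soc_term = "S1",
    source_id = c("a", "a", "b", "a", "b", "c")))
  two <- build_pt_panels(links, min_sources = 2)
  expect_setequal(two$panels$gene_symbol, c("B", "C"))
  one <- build_pt_panels(links, min_sources = 1)
  expect_setequal(one$panels$gene_symbol, c("A", "B", "C"))
  expect_error(build_pt_panels(links, min_sources = 0), "positive")
  # anti-monotone in min_sources, and the support rule holds exhaustively
  w <- small_world(seed = 13)
  run <- run_end_to_end(w, safetyome_cfg = safetyome_config(
    excluded_socs = w$truth$nonorgan_socs, cutoff_percentile = 0))
  prev <- NULL
  for (m in 1:4) {
    pp <- build_pt_panels(run$links, min_sources = m)
    expect_true(all(pp$panels$n_sources >= m))
    key <- paste(pp$panels$panel_id, pp$panels$gene_symbol)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
    support <- run$links |>
      dplyr::semi_join(pp$panels,
                       by = c(pt_term = "panel_id", "gene_symbol")) |>
      dplyr::distinct(pt_term, gene_symbol, source_id) |>
      dplyr::count(pt_term, gene_symbol)
    expect_true(all(support$n >= m))
  }
})

test_that("summary splits evidence classes and counts SOCs per gene", {
  fx <- soc_fixture()
  soc <- build_soc_safetyome(fx$links, fx$scores,
                             safetyome_config(cutoff_percentile = 0))
  sm <- summarize_panels(soc, fx$links)
  # A is genetic in two SOCs, B pharmacological only, rest genetic only
  expect_identical(sm$class_split$genetics_only, 4L)
  expect_identical(sm$class_split$pharmacology_only, 1L)
  expect_identical(sm$class_split$both, 0L)
  expect_identical(sm$soc_count_hist$n_genes[sm$soc_count_hist$n_socs == 2],
                   1L)
  expect_identical(sm$soc_count_hist$n_genes[sm$soc_count_hist$n_socs == 1],
                   4L)
  expect_equal(sm$multi_source_fraction, 0)
})

test_that("panels round-trip through the GMT format", {
  fx <- soc_fixture()
  soc <- build_soc_safetyome(fx$links, fx$scores,
                             safetyome_config(cutoff_percentile = 0))
  gmt <- as_gmt(soc)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gmt, path)
  back <- read_gmt(path)
  expect_setequal(unique(back$panel_id), unique(soc$panels$panel_id))
  for (p in unique(back$panel_id)) {
    expect_setequal(back$gene_symbol[back$panel_id == p],
                    soc$panels$gene_symbol[soc$panels$panel_id == p])
  }
  expect_true(all(grepl("level=SOC", back$description)))
})
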