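test_that("hypergeometric test matches closed form and edge cases", {
  u <- sprintf("G%02d", 1:10)
  # overlap forced to zero has probability one
  expect_equal(hypergeom_test(u[1:3], u[8:10], u), 1)
  # the whole universe as panel forces the overlap
  expect_equal(hypergeom_test(u, u[1:4], u), 1)
  # C(5,4)/C(10,4) worked example
  expect_equal(hypergeom_test(u[1:5], u[2:5], u), 5 / 210, tolerance = 1e-12)
  expect_error(hypergeom_test(u[1:2], u[1:2], character(0)), "empty")
})

test_that("hypergeometric p equals exhaustive enumeration on small universes", {
  set.seed(4)
  for (n in c(5, 8, 10, 12)) {
    u <- sprintf("G%02d", seq_len(n))
    for (k in 2:min(5, n - 1)) {
      panel <- sample(u, sample(2:(n - 1), 1))
      disease <- sample(u, k)
      expect_equal(hypergeom_test(panel, disease, u),
                   enum_hypergeom(panel, disease, u),
                   tolerance = 1e-12)
    }
  }
})

test_that("p-value adjustment follows Bonferroni and BH definitions", {
  expect_equal(adjust_pvalues(0.01, "bonferroni", m = 5), 0.05)
  expect_equal(adjust_pvalues(0.5, "bonferroni", m = 5), 1)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.04), "bh"),
               c(0.03, 0.03, 0.04))
  ps <- c(0.001, 0.02, 0.3, 0.9)
  expect_true(all(adjust_pvalues(ps, "bonferroni") >= ps))
  # adjusted significance is a subset of unadjusted significance
  expect_true(all(which(adjust_pvalues(ps, "bonferroni") <= 0.05) %in%
                    which(ps <= 0.05)))
})

enrich_fixture <- function(pt_sizes = c(A = 8, B = 8)) {
  genes <- sprintf("G%03d", seq_len(sum(pt_sizes) + 20))
  links <- purrr::imap(as.list(pt_sizes), function(n, pt) {
    g <- sample(genes, n)
    make_links(tibble::tibble(
      gene_symbol = rep(g, 2),
      pt_term = paste0("PT_", pt), soc_term = paste0("SOC_", pt),
      source_id = rep(c("s1", "s2"), each = n)))
  }) |> purrr::list_rbind()
  list(genes = genes, links = links)
}

test_that("enrichment flags label matches and keeps pairs unique", {
  set.seed(8)
  fx <- enrich_fixture()
  panels <- build_pt_panels(fx$links, min_sources = 2)
  genes_a <- unique(fx$links$gene_symbol[fx$links$pt_term == "PT_A"])
  disease_gene <- tibble::tibble(
    disease_term = "disease alpha",
    gene_symbol = c(genes_a, sample(setdiff(fx$genes, genes_a), 14)),
    direct_evidence = 1L)
  disease_map <- tibble::tibble(disease_term = "disease alpha",
                                pt_term = "PT_A", soc_term = "SOC_A",
                                stage = "exact", similarity = 1)
  res <- enrich_panels(panels, disease_gene, disease_map,
                       universe = fx$genes, min_panel_genes = 1)
  expect_identical(nrow(res), 2L)  # two panels x one disease, no duplicates
  expect_true(all(res$overlap <= pmin(res$panel_size, res$disease_set_size)))
  expect_true(all(res$p_adj >= res$p))
  a <- res[res$panel_id == "PT_A", ]
  expect_true(a$matched)
  expect_true(a$significant)
  expect_false(res$matched[res$panel_id == "PT_B"])
})

test_that("phenotype-level testing excludes panels under the size floor", {
  set.seed(8)
  fx <- enrich_fixture(pt_sizes = c(A = 4, B = 9, C = 12))
  panels <- build_pt_panels(fx$links, min_sources = 2)
  disease_gene <- tibble::tibble(disease_term = "d",
                                 gene_symbol = fx$genes,
                                 direct_evidence = 1L)
  disease_map <- tibble::tibble(disease_term = "d", pt_term = "PT_C",
                                soc_term = "SOC_C", stage = "exact",
                                similarity = 1)
  res <- enrich_panels(panels, disease_gene, disease_map,
                       min_panel_genes = 9)
  sizes <- dplyr::count(panels$panels, panel_id)
  eligible <- sizes$panel_id[sizes$n >= 9]
  expect_setequal(unique(res$panel_id), eligible)
  # the PT default floor is 50 genes: nothing here qualifies
  expect_warning(res50 <- enrich_panels(panels, disease_gene, disease_map),
                 "no testable")
  expect_identical(nrow(res50), 0L)
})

test_that("only direct-evidence disease genes enter the universe", {
  set.seed(8)
  fx <- enrich_fixture()
  panels <- build_pt_panels(fx$links, min_sources = 2)
  disease_gene <- tibble::tibble(
    disease_term = "d",
    gene_symbol = fx$genes,
    direct_evidence = rep(c(1L, 0L), length.out = length(fx$genes)))
  disease_map <- tibble::tibble(disease_term = "d", pt_term = "PT_A",
                                soc_term = "SOC_A", stage = "exact",
                                similarity = 1)
  res <- enrich_panels(panels, disease_gene, disease_map,
                       min_panel_genes = 1)
  expect_true(all(res$universe_size ==
                    sum(disease_gene$direct_evidence == 1L)))
})

test_that("match rates average per-panel percentages of matched diseases", {
  res <- tibble::tibble(
    panel_id = c("Cardiac", "Cardiac", "Cardiac", "Renal"),
    disease_term = paste0("d", 1:4),
    significant = TRUE,
    matched = c(TRUE, TRUE, FALSE, TRUE))
  attr(res, "level") <- "SOC"
  mr <- match_rate(res)
  expect_equal(
    mr$per_panel$match_rate_pct[mr$per_panel$panel_id == "Cardiac"],
    200 / 3)
  expect_equal(mr$mean_match_rate_pct, (200 / 3 + 100) / 2)
  all_hit <- dplyr::mutate(res, matched = TRUE)
  attr(all_hit, "level") <- "SOC"
  expect_equal(match_rate(all_hit)$mean_match_rate_pct, 100)
  none <- dplyr::mutate(res, significant = FALSE)
  expect_warning(empty <- match_rate(none), "no significant")
  expect_true(is.na(empty$mean_match_rate_pct))
})

test_that("the cutoff sweep spans 10-90 with non-increasing target counts", {
  w <- small_world(seed = 21)
  run <- run_end_to_end(w, safetyome_cfg = safetyome_config(
    excluded_socs = w$truth$nonorgan_socs, cutoff_percentile = 0),
    sweep = TRUE)
  sw <- run$sweep
  expect_identical(sw$cutoff_percentile, seq(10, 90, by = 10))
  expect_true(all(diff(sw$n_targets) <= 0))
  # zero-noise world: every significant enrichment matches its SOC
  expect_true(all(sw$match_rate_pct == 100, na.rm = TRUE))
})
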