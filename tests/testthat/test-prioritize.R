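test_that("tau index hits its limits and the hand-computed case", {
  expect_equal(tau_index(c(0, 0, 8)), 1)
  expect_equal(tau_index(c(4, 4, 4)), 0)
  expect_equal(tau_index(c(1, 2, 4)), 0.625)
  expect_error(tau_index(5), "two tissues")
  expect_error(tau_index(c(-1, 2)), "non-negative")
  expect_warning(na <- tau_index(c(0, 0, 0)), "undefined")
  expect_true(is.na(na))
})

test_that("tau is bounded and invariant to rescaling the vector", {
  for (seed in 1:15) {
    set.seed(seed)
    x <- stats::rgamma(sample(2:20, 1), shape = 0.5)
    expect_gte(tau_index(x), 0)
    expect_lte(tau_index(x), 1)
    expect_equal(tau_index(x), tau_index(x * 17.3))
  }
})

test_that("tau_table matches the single-vector computation per gene", {
  expr <- tibble::tibble(gene_symbol = c("A", "B", "C"),
                         t1 = c(1, 0, 5), t2 = c(2, 0, 5), t3 = c(4, 8, 5))
  tt <- tau_table(expr)
  expect_equal(tt$tau, c(0.625, 1, 0))
  zero <- tibble::tibble(gene_symbol = "Z", t1 = 0, t2 = 0)
  expect_warning(zt <- tau_table(zero), "all-zero")
  expect_true(is.na(zt$tau))
})

test_that("conservation medians across species feed rank averaging", {
  orth <- tibble::tibble(
    gene_symbol = rep(c("A", "B"), each = 3),
    species = rep(c("mouse", "rat", "dog"), 2),
    identity_pct = c(90, 85, 95, 60, 50, 70),
    confident = c(1L, 1L, 0L, 0L, 0L, 1L))
  cs <- conservation_score(orth)
  expect_equal(cs$identity_median[cs$gene_symbol == "A"], 90)
  expect_equal(cs$confidence_median[cs$gene_symbol == "A"], 1)
  # A dominates both metrics in the two-gene cohort
  expect_equal(cs$conservation[cs$gene_symbol == "A"], 1)
  expect_equal(cs$conservation[cs$gene_symbol == "B"], 0)
  expect_error(conservation_score(dplyr::mutate(orth, species = "ferret")),
               "species")
})

core_fixture <- function(n = 2000, n_planted = 20, seed = 2) {
  set.seed(seed)
  planted <- sprintf("CORE%03d", seq_len(n_planted))
  other <- sprintf("G%04d", seq_len(n - n_planted))
  tibble::tibble(
    gene_symbol = c(planted, other),
    scaled = c(rep(10, n_planted), stats::runif(n - n_planted, 0, 9.5)),
    tau = c(rep(1, n_planted), stats::runif(n - n_planted, 0, 0.95)),
    conservation = c(rep(1, n_planted),
                     stats::runif(n - n_planted, 0, 0.95)))
}

test_that("the core panel takes the top n with dominant genes on top", {
  fx <- core_fixture()
  core <- build_core_panel(fx, n = 500)
  expect_identical(nrow(core), 500L)
  expect_identical(core$rank, 1:500)
  # genes maximal in all three metrics occupy the top ranks
  planted <- grepl("^CORE", core$gene_symbol)
  expect_true(all(which(planted) <= 20))
  expect_identical(sum(planted), 20L)
  expect_error(build_core_panel(fx, n = 0), "positive")
})

test_that("the top-k prefix is stable in the requested panel size", {
  fx <- core_fixture(n = 300, n_planted = 5, seed = 9)
  big <- build_core_panel(fx, n = 200)
  small <- build_core_panel(fx, n = 50)
  expect_identical(big$gene_symbol[1:50], small$gene_symbol)
  expect_equal(big$combined_rank_score[1:50], small$combined_rank_score)
  expect_warning(short <- build_core_panel(fx, n = 500), "only 300")
  expect_identical(nrow(short), 300L)
})

test_that("missing metrics are flagged and averaged over available ranks", {
  fx <- tibble::tibble(
    gene_symbol = c("A", "B", "C"),
    scaled = c(10, 5, 1),
    tau = c(1, NA, 0.2),
    conservation = c(1, 0.5, NA))
  expect_warning(core <- build_core_panel(fx, n = 3), "missing tau")
  expect_identical(core$metrics_complete, c(TRUE, FALSE, FALSE))
  expect_identical(core$gene_symbol[[1]], "A")
  # weighting only the scaled score reorders purely by evidence
  w <- suppressWarnings(build_core_panel(fx, n = 3, weights = c(1, 0, 0)))
  expect_identical(w$gene_symbol, c("A", "B", "C"))
})
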