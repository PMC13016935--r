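test_that("raw score is total count times log of unique sources plus one", {
  expect_equal(raw_score(c(A = 3, B = 1)), 4 * log(3))
  expect_identical(raw_score(numeric(0)), 0)
  # a zero-count source contributes nothing
  expect_equal(raw_score(c(A = 4, B = 0)), raw_score(c(A = 4)))
  # equal totals, more unique sources scores strictly higher
  expect_gt(raw_score(c(A = 2, B = 2)), raw_score(c(A = 4)))
  expect_error(raw_score(c(A = -1)), "non-negative")
})

test_that("the z / log / min-max chain matches the hand-computed oracle", {
  out <- scale_scores(tibble::tibble(gene_symbol = c("g1", "g2", "g3"),
                                     raw = c(0, 5, 10)))
  expect_equal(out$z, c(-1.22474487, 0, 1.22474487), tolerance = 1e-8)
  # frozen from an independent evaluation of the three formulas;
  # the log step makes the midpoint land above 5
  expect_equal(out$scaled, c(0, 6.45796517, 10), tolerance = 1e-7)
  expect_equal(out$percentile, c(0, 100 / 3, 200 / 3), tolerance = 1e-10)
})

test_that("degenerate cohorts scale to 10 with percentile 0", {
  expect_warning(out <- scale_scores(rep(3, 4)), "degenerate")
  expect_true(all(out$scaled == 10))
  expect_true(all(out$percentile == 0))
  expect_warning(one <- scale_scores(5), "degenerate")
  expect_identical(one$scaled, 10)
})

test_that("percentile rank counts strictly smaller cohort values", {
  expect_equal(percentile_rank(c(1, 2, 3, 4)), c(0, 25, 50, 75))
  expect_equal(percentile_rank(rep(2, 5)), rep(0, 5))
  expect_equal(percentile_rank(c(3, 1, 2)), c(200 / 3, 0, 100 / 3))
  expect_equal(percentile_rank(c(3, 1, 2)), oracle_percentile(c(3, 1, 2)))
})

test_that("scaling preserves order, spans [0, 10] and ignores null sources", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:50, 1)
    raws <- round(stats::rexp(n, 1 / 10), 2)
    if (length(unique(raws)) < 2) next
    out <- scale_scores(raws)
    expect_equal(min(out$scaled), 0)
    expect_equal(max(out$scaled), 10)
    expect_identical(order(out$scaled), order(out$raw))
    # strict monotonicity on distinct raws
    o <- order(raws)
    distinct_adjacent <- diff(raws[o]) > 0
    expect_true(all(diff(out$scaled[o])[distinct_adjacent] > 0))
    # multiplying all counts by a constant preserves the scaled ordering
    counts <- matrix(stats::rpois(5 * n, 2), nrow = n)
    r1 <- apply(counts, 1, raw_score)
    r2 <- apply(counts * 3, 1, raw_score)
    if (stats::sd(r1) > 0) {
      s1 <- scale_scores(r1)$scaled
      s2 <- scale_scores(r2)$scaled
      expect_identical(order(s1, seq_len(n)), order(s2, seq_len(n)))
    }
  }
})

test_that("global scores aggregate deduplicated per-source record counts", {
  records <- tibble::tibble(
    gene_symbol = c("A", "A", "A", "B", "B", "C"),
    trait_text = c("t1", "t2", "t3", "t1", "t2", "t1"),
    source_id = c("s1", "s1", "s2", "s1", "s1", "s1"),
    evidence_class = "genetic")
  counts <- evidence_counts(records)
  expect_identical(counts$n_records[counts$gene_symbol == "A" &
                                     counts$source_id == "s1"], 2L)
  out <- score_targets(records)
  raw_a <- raw_score(c(2, 1))
  expect_equal(out$raw[out$gene_symbol == "A"], raw_a)
  expect_equal(out$raw[out$gene_symbol == "C"], 1 * log(2))
  expect_identical(out$gene_symbol[which.max(out$scaled)], "A")
})

test_that("per-SOC scoring normalizes within each organ class", {
  links <- make_links(tibble::tibble(
    gene_symbol = c("A", "A", "B", "C", "A", "D", "D"),
    pt_term = c("P1", "P2", "P1", "P2", "P3", "P3", "P3"),
    soc_term = c("S1", "S1", "S1", "S1", "S2", "S2", "S2"),
    source_id = c("s1", "s1", "s2", "s1", "s1", "s2", "s3")))
  records <- tibble::tibble(gene_symbol = links$gene_symbol,
                            trait_text = links$pt_term,
                            source_id = links$source_id,
                            evidence_class = "genetic")
  out <- score_targets(records, by = "soc", links = links)
  expect_true("soc_term" %in% names(out))
  # each SOC cohort spans the full scale on distinct raws
  for (soc in unique(out$soc_term)) {
    grp <- out[out$soc_term == soc, ]
    if (length(unique(grp$raw)) >= 2) {
      expect_equal(min(grp$scaled), 0)
      expect_equal(max(grp$scaled), 10)
    }
  }
})
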