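#' Tissue-specificity Tau index
#'
#' `tau = sum(1 - x_i / max(x)) / (N - 1)` over `N` tissues: 1 for
#' expression confined to a single tissue, 0 for perfectly uniform
#' expression. Invariant to scalar rescaling of the vector.
#'
#' @param expression Non-negative expression values across at least two
#'   tissues.
#' @return A number in `[0, 1]`, or `NA` (with a warning) for an all-zero
#'   vector, where the index is undefined.
#' @examples
#' tau_index(c(0, 0, 8)) # 1
#' tau_index(c(4, 4, 4)) # 0
#' @export
tau_index <- function(expression) {
  x <- as.numeric(expression)
  if (length(x) < 2) stop("tau index requires at least two tissues")
  if (anyNA(x) || any(x < 0)) {
    stop("expression values must be non-negative and non-missing")
  }
  m <- max(x)
  if (m == 0) {
    warning("all-zero expression vector: tau index is undefined")
    return(NA_real_)
  }
  sum(1 - x / m) / (length(x) - 1)
}

#' Tau index for every gene of an expression matrix
#'
#' @param expression A data frame whose first column is `gene_symbol` and
#'   remaining columns are per-tissue expression values, or a numeric
#'   matrix with gene row names.
#' @return A tibble with columns `gene_symbol`, `tau`.
#' @export
tau_table <- function(expression) {
  if (is.matrix(expression)) {
    expression <- tibble::as_tibble(expression, rownames = "gene_symbol")
  }
  expression <- tibble::as_tibble(expression)
  stopifnot("gene_symbol" %in% names(expression))
  vals <- as.matrix(expression[setdiff(names(expression), "gene_symbol")])
  if (ncol(vals) < 2) stop("tau index requires at least two tissues")
  if (anyNA(vals) || any(vals < 0)) {
    stop("expression values must be non-negative and non-missing")
  }
  m <- apply(vals, 1, max)
  tau <- ifelse(m == 0, NA_real_,
                rowSums(1 - vals / ifelse(m == 0, 1, m)) / (ncol(vals) - 1))
  if (anyNA(tau)) {
    warning(sum(is.na(tau)),
            " gene(s) with all-zero expression: tau index undefined")
  }
  tibble::tibble(gene_symbol = expression$gene_symbol, tau = tau)
}

#' Cross-species conservation score
#'
#' Per gene, takes the median across species of (i) primary-sequence
#' percent identity and (ii) the 0/1 ortholog-confidence call, converts
#' each median to a percentile rank across genes in `[0, 1]`, and averages
#' the two ranks (median across species first, then averaging of the two
#' categories).
#'
#' @param orthology A data frame with columns `gene_symbol`, `species`
#'   (subset of mouse/rat/dog), `identity_pct` in `[0, 100]`, `confident`
#'   (0/1).
#' @return A tibble with `gene_symbol`, `identity_median`,
#'   `confidence_median`, `identity_rank`, `confidence_rank`,
#'   `conservation`.
#' @export
conservation_score <- function(orthology) {
  orthology <- tibble::as_tibble(orthology)
  req <- c("gene_symbol", "species", "identity_pct", "confident")
  miss <- setdiff(req, names(orthology))
  if (length(miss) > 0) {
    stop("orthology table is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(orthology$species), c("mouse", "rat", "dog"))
  if (length(bad) > 0) {
    stop("unknown species: ", paste(bad, collapse = ", "),
         " (expected mouse, rat, dog)")
  }
  if (any(orthology$identity_pct < 0 | orthology$identity_pct > 100,
          na.rm = TRUE)) {
    stop("identity_pct must lie in [0, 100]")
  }
  orthology |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(
      identity_median = stats::median(.data$identity_pct),
      confidence_median = stats::median(as.numeric(.data$confident)),
      .groups = "drop") |>
    dplyr::mutate(
      identity_rank = percent_rank01(.data$identity_median),
      confidence_rank = percent_rank01(.data$confidence_median),
      conservation = (.data$identity_rank + .data$confidence_rank) / 2)
}

#' Rank targets and extract the core panel
#'
#' Combines the percentile ranks (in `[0, 1]`, computed across the
#' supplied cohort) of the scaled evidence score, the Tau index and the
#' conservation score by their unweighted mean, sorts descending and
#' returns the top `n` targets. Ties are broken by scaled score and then
#' gene symbol, so the ranking is deterministic and the top-k prefix is
#' stable in `n`. Genes with a missing Tau or conservation value are
#' ranked on their available metrics and flagged.
#'
#' @param priorities A data frame with columns `gene_symbol`, `scaled`
#'   (required, no missing values) and optionally `tau`, `conservation`
#'   (may contain `NA`).
#' @param n Core panel size (default 500).
#' @param weights Optional numeric vector of length 3 giving the weights
#'   of (scaled, tau, conservation); default equal weights.
#' @return A tibble of class `core_panel` with columns `rank`,
#'   `gene_symbol`, `tau`, `conservation`, `scaled`,
#'   `combined_rank_score`, `metrics_complete`, at most `n` rows (with a
#'   warning when fewer genes are available).
#' @export
build_core_panel <- function(priorities, n = 500L, weights = c(1, 1, 1)) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    stop("n must be a positive integer")
  }
  stopifnot(is.numeric(weights), length(weights) == 3, all(weights >= 0),
            sum(weights) > 0)
  priorities <- tibble::as_tibble(priorities)
  stopifnot(all(c("gene_symbol", "scaled") %in% names(priorities)))
  if (anyNA(priorities$scaled)) {
    stop("every gene must have a scaled score")
  }
  if (!"tau" %in% names(priorities)) priorities$tau <- NA_real_
  if (!"conservation" %in% names(priorities)) {
    priorities$conservation <- NA_real_
  }
  rk <- cbind(scaled = percent_rank01(priorities$scaled),
              tau = percent_rank01(priorities$tau),
              conservation = percent_rank01(priorities$conservation))
  w <- matrix(weights, nrow = nrow(rk), ncol = 3, byrow = TRUE)
  w[is.na(rk)] <- 0
  combined <- rowSums(rk * w, na.rm = TRUE) / rowSums(w)
  incomplete <- is.na(priorities$tau) | is.na(priorities$conservation)
  if (any(incomplete)) {
    warning(sum(incomplete), " gene(s) missing tau or conservation; ",
            "ranked on available metrics")
  }
  out <- priorities |>
    dplyr::mutate(combined_rank_score = combined,
                  metrics_complete = !incomplete) |>
    dplyr::arrange(dplyr::desc(.data$combined_rank_score),
                   dplyr::desc(.data$scaled), .data$gene_symbol) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "gene_symbol", "tau", "conservation", "scaled",
                  "combined_rank_score", "metrics_complete")
  if (nrow(out) < n) {
    warning("only ", nrow(out), " scored genes available for a core panel ",
            "of ", n)
  } else {
    out <- out[seq_len(n), ]
  }
  class(out) <- c("core_panel", class(out))
  out
}

#' @export
as_gmt.core_panel <- function(x, ...) {
  tibble::tibble(
    panel_id = "core_panel",
    description = sprintf("level=core|n=%d|rank=scaled+tau+conservation",
                          nrow(x)),
    genes = list(x$gene_symbol))
}
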