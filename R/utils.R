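#' @importFrom rlang %||% .data
#' @importFrom dplyr arrange count distinct filter group_by inner_join left_join
#'   mutate n n_distinct rename row_number select semi_join summarise transmute
#'   ungroup
#' @importFrom stats median phyper p.adjust setNames
#' @importFrom utils adist head
NULL

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Normalize a free-text phenotype term
#'
#' Lowercases, replaces punctuation with spaces, collapses repeated
#' whitespace and trims. All lexicon lookups, trait deduplication and the
#' matching cascade operate on this normalized form.
#'
#' @param text Character vector of free-text terms.
#' @return Character vector of normalized terms.
#' @examples
#' normalize_term("Long QT-syndrome ")
#' @export
normalize_term <- function(text) {
  stopifnot(is.character(text))
  out <- tolower(text)
  out <- gsub("[^[:alnum:]]+", " ", out)
  trimws(gsub("[[:space:]]+", " ", out))
}

#' Percentile rank on the 0-100 scale
#'
#' The rank of each value is the percentage of cohort values strictly below
#' it; ties share a rank and the minimum is always 0.
#'
#' @param x Numeric vector without missing values.
#' @return Numeric vector in `[0, 100)` of the same length.
#' @examples
#' percentile_rank(c(1, 2, 3, 4))
#' @export
percentile_rank <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1)
  if (anyNA(x)) stop("percentile_rank() does not accept missing values")
  100 * (rank(x, ties.method = "min") - 1) / length(x)
}

# Percentile rank rescaled to [0, 1]; min maps to 0, max to 1 (ties -> min
# rank). NA values keep NA; a cohort of one gets 0.
percent_rank01 <- function(x) {
  n <- sum(!is.na(x))
  if (n == 0) return(x)
  if (n == 1) return(ifelse(is.na(x), NA_real_, 0))
  (rank(x, ties.method = "min", na.last = "keep") - 1) / (n - 1)
}

#' Write gene sets in GMT format
#'
#' One tab-separated line per set: set name, description, member genes.
#'
#' @param x A tibble with columns `panel_id`, `description` and a list
#'   column `genes`, as returned by [as_gmt()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_gmt()], [as_gmt()]
#' @export
write_gmt <- function(x, path) {
  stopifnot(all(c("panel_id", "description", "genes") %in% names(x)))
  lines <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(x$panel_id[[i]], x$description[[i]], x$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file.
#' @return A long tibble with columns `panel_id`, `description`,
#'   `gene_symbol`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  purrr::map(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("malformed GMT line (need name, description, >=1 gene): ", ln)
    }
    tibble::tibble(panel_id = parts[[1]], description = parts[[2]],
                   gene_symbol = parts[-(1:2)])
  }) |> purrr::list_rbind()
}
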