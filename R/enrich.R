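# Gene-set enrichment of predicted target genes: upper-tail hypergeometric
# test (with the conservative EASE variant) and Benjamini-Hochberg control.

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of drawing at least `k` genes of a term of size `K` when `n`
#' genes are drawn from a background of `N`. `mode = "ease"` computes the
#' conservative EASE variant: the upper tail at `k - 1` (defined for
#' `k > 0`; penalizes single-gene overlaps).
#'
#' @param k observed overlap (query genes in the term).
#' @param K term size within the background.
#' @param n query size within the background.
#' @param N background size.
#' @param mode "fisher" (exact upper tail) or "ease".
#' @return p-value in (0, 1].
#' @export
hypergeom_p <- function(k, K, n, N, mode = c("fisher", "ease")) {
  mode <- match.arg(mode)
  if (k < 0 || k > min(K, n) || K > N || n > N)
    stop_data("hypergeometric bounds violated (need 0 <= k <= min(K, n), ",
              "K <= N, n <= N)")
  if (mode == "ease") {
    if (k == 0) return(1)
    k <- k - 1
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set enrichment over a term collection
#'
#' Tests the query gene set against every term with at least one
#' overlapping gene; terms with no overlap are suppressed (only overlapping
#' terms are reported). Benjamini-Hochberg adjusted p-values are computed
#' across all tested (overlapping) terms.
#'
#' @param query character vector of query gene ids.
#' @param term_sets named list: term id -> character vector of member genes.
#' @param background background gene universe; defaults to the union of all
#'   term members. Query genes outside the background are ignored.
#' @param mode "fisher" or "ease", see [hypergeom_p()].
#' @param categories optional named character vector mapping term ids to
#'   annotation categories.
#' @return data.frame sorted by raw p: `term`, `category`, `p_value`,
#'   `p_adjusted`, `k`, `K`, `n`, `N`, `genes` (comma-separated overlap).
#' @export
enrich_targets <- function(query, term_sets, background = NULL,
                           mode = c("fisher", "ease"), categories = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(term_sets) > 0, !is.null(names(term_sets)))
  if (is.null(background)) background <- unique(unlist(term_sets))
  background <- unique(background)
  N <- length(background)
  q <- intersect(unique(query), background)
  n <- length(q)
  rows <- list()
  for (term in names(term_sets)) {
    members <- intersect(unique(term_sets[[term]]), background)
    overlap <- intersect(q, members)
    k <- length(overlap)
    if (k == 0) next
    rows[[term]] <- data.frame(
      term = term,
      category = if (!is.null(categories) && term %in% names(categories))
        categories[[term]] else NA_character_,
      p_value = hypergeom_p(k, length(members), n, N, mode),
      k = k, K = length(members), n = n, N = N,
      genes = paste(sort(overlap), collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(term = character(0), category = character(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), genes = character(0)))
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term),
             c("term", "category", "p_value", "p_adjusted",
               "k", "K", "n", "N", "genes")]
  rownames(out) <- NULL
  out
}

#' Read a GMT-format term-set file
#'
#' @param path GMT file (term, description, then member genes, tab-separated).
#' @return named list of gene vectors; descriptions kept as the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "descriptions") <- vapply(parts, `[[`, character(1), 2)
  sets
}

#' Write term sets as GMT
#'
#' @param term_sets named list of gene vectors.
#' @param path output path.
#' @param descriptions optional per-term description column.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(term_sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(term_sets))
  lines <- vapply(seq_along(term_sets), function(i) {
    paste(c(names(term_sets)[i], descriptions[i], term_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
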