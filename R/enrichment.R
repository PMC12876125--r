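#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` annotated genes when `n` genes are drawn without replacement
#' from a background of `N` genes of which `K` carry the annotation. The
#' over-representation p-value of a gene-set test.
#'
#' @param k Observed hits in the query (`0 <= k <= min(K, n)`).
#' @param K Term size within the background.
#' @param n Query size within the background.
#' @param N Background size.
#' @return The upper-tail probability (1 when `k = 0`).
#' @examples
#' hypergeom_tail(4, 5, 4, 10)  # choose(5,4)/choose(10,4) = 5/210
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (K > N || n > N) abort("K and n must not exceed N.")
  if (k > min(K, n) || k < 0) abort("k must satisfy 0 <= k <= min(K, n).")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (p_(j) * m / j)`, capped at 1, returned in the input
#' order. Controls the false discovery rate across the `m` tests.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' Hypergeometric over-representation analysis of a gene set
#'
#' Tests each annotation term for over-representation of the query genes
#' (e.g. a tissue's differential ligands) against a background universe —
#' conventionally the measured gene universe of the expression matrix, not
#' the whole genome. Term member sets are intersected with the background
#' before counting; terms with zero query hits are excluded from testing and
#' from the adjustment denominator. BH correction is applied within each GO
#' category (`BP`/`MF`/`CC`) by default, matching how enrichment dot plots
#' are grouped, or globally with `per_category = FALSE`.
#'
#' @param query Character vector of query gene symbols (subset of
#'   `background`).
#' @param annotation A `gene_set_annotation` tibble ([read_gmt()] /
#'   [generate_gene_sets()]).
#' @param background Character vector, the gene universe.
#' @param per_category Adjust within each category separately?
#' @return Tibble sorted by `p_value` ascending with columns `term_id`,
#'   `term_name`, `category`, `k` (query hits), `K` (term size in background),
#'   `n` (query size in background), `N` (background size), `gene_ratio`
#'   (`k/n`), `p_value`, `adj_p`, and list-column `hit_genes`.
#' @export
enrich_ora <- function(query, annotation, background, per_category = TRUE) {
  background <- unique(background)
  query <- unique(query)
  if (length(background) == 0 || length(query) == 0) {
    abort("query and background must be nonempty.")
  }
  if (!all(query %in% background)) {
    abort("`query` must be a subset of `background`.")
  }
  N <- length(background)
  n <- length(query)
  rows <- purrr::map(seq_len(nrow(annotation)), function(i) {
    members <- intersect(annotation$genes[[i]], background)
    hits <- intersect(query, members)
    if (length(hits) == 0) return(NULL)
    tibble(
      term_id = annotation$term_id[i],
      term_name = annotation$term_name[i],
      category = annotation$category[i],
      k = length(hits), K = length(members), n = n, N = N,
      gene_ratio = length(hits) / n,
      p_value = hypergeom_tail(length(hits), length(members), n, N),
      hit_genes = list(sort(hits))
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(
      term_id = character(), term_name = character(), category = character(),
      k = integer(), K = integer(), n = integer(), N = integer(),
      gene_ratio = numeric(), p_value = numeric(), adj_p = numeric(),
      hit_genes = list()
    ))
  }
  out <- if (per_category) {
    out |>
      group_by(.data$category) |>
      mutate(adj_p = bh_adjust(.data$p_value)) |>
      ungroup()
  } else {
    mutate(out, adj_p = bh_adjust(.data$p_value))
  }
  out |>
    select("term_id", "term_name", "category", "k", "K", "n", "N",
           "gene_ratio", "p_value", "adj_p", "hit_genes") |>
    arrange(.data$p_value, .data$term_id)
}

#' Write an enrichment table to TSV
#'
#' Dot-plot-ready columns: `gene_ratio` and `neg_log10_adj_p` are included and
#' the hit genes are serialized as a `/`-separated string.
#'
#' @param result Output of [enrich_ora()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment_tsv <- function(result, path) {
  flat <- result |>
    mutate(
      neg_log10_adj_p = -log10(.data$adj_p),
      hit_genes = vapply(.data$hit_genes, paste, "", collapse = "/")
    )
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
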