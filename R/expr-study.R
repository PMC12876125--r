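#' Bundle an expression table with its sample metadata
#'
#' An `expr_study` is the unit every preprocessing and differential stage of
#' the package transforms: a wide expression tibble (one row per gene, one
#' column per sample, log2-scale values) together with a sample metadata
#' tibble assigning each sample to a disease group (`HC`/`OA`) and a tissue
#' compartment (`BL` for blood, `SY` for synovium).
#'
#' @param expr Tibble or data frame whose first column is `gene` (unique
#'   symbols) and remaining columns are one numeric column per sample.
#' @param samples Tibble with columns `sample_id`, `group` (`"HC"`/`"OA"`) and
#'   `tissue` (`"BL"`/`"SY"`), covering exactly the sample columns of `expr`.
#' @return An object of class `expr_study`: a list with elements `expr` and
#'   `samples`, both tibbles.
#' @examples
#' expr <- tibble::tibble(gene = c("A", "B"), s1 = c(1, 2), s2 = c(3, 4))
#' meta <- tibble::tibble(sample_id = c("s1", "s2"),
#'                        group = c("HC", "OA"), tissue = "BL")
#' expr_study(expr, meta)
#' @export
expr_study <- function(expr, samples) {
  expr <- as_tibble(expr)
  samples <- as_tibble(samples)
  if (ncol(expr) < 2L || names(expr)[1] != "gene") {
    abort("`expr` must have a first column named 'gene' plus >= 1 sample column.")
  }
  if (anyDuplicated(expr$gene)) {
    dup <- unique(expr$gene[duplicated(expr$gene)])
    abort(paste0("duplicate gene ids in `expr`: ", toString(head(dup, 5))))
  }
  need <- c("sample_id", "group", "tissue")
  if (!all(need %in% names(samples))) {
    abort("`samples` must have columns sample_id, group, tissue.")
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("duplicate sample_id in `samples`.")
  }
  sample_cols <- names(expr)[-1]
  missing_meta <- setdiff(sample_cols, samples$sample_id)
  if (length(missing_meta)) {
    abort(paste0("samples missing from metadata: ", toString(head(missing_meta, 5))))
  }
  samples <- samples[match(sample_cols, samples$sample_id), , drop = FALSE]
  if (!all(samples$group %in% GROUPS)) {
    abort("`group` must be 'HC' or 'OA'.")
  }
  if (!all(samples$tissue %in% TISSUES)) {
    abort("`tissue` must be 'BL' or 'SY'.")
  }
  vals <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort("expression values must be numeric.")
  if (any(!is.finite(vals))) abort("expression values must all be finite.")
  structure(list(expr = expr, samples = samples), class = "expr_study")
}

#' @export
print.expr_study <- function(x, ...) {
  cat(sprintf(
    "<expr_study> %d genes x %d samples [tissue %s: %s]\n",
    nrow(x$expr), nrow(x$samples),
    paste(unique(x$samples$tissue), collapse = "/"),
    paste(sprintf("%s=%d", GROUPS, c(sum(x$samples$group == "HC"),
                                     sum(x$samples$group == "OA"))),
          collapse = ", ")
  ))
  invisible(x)
}

# genes x samples numeric matrix view (rownames = genes)
expr_values <- function(study) {
  m <- as.matrix(study$expr[, -1, drop = FALSE])
  rownames(m) <- study$expr$gene
  m
}

# rebuild an expr_study around a replacement value matrix, keeping labels
expr_replace_values <- function(study, values) {
  colnames(values) <- names(study$expr)[-1]
  expr <- tibble(gene = study$expr$gene)
  expr <- dplyr::bind_cols(expr, as_tibble(values, .name_repair = "minimal"))
  names(expr) <- names(study$expr)
  expr_study(expr, study$samples)
}

group_masks <- function(study) {
  list(hc = study$samples$group == "HC", oa = study$samples$group == "OA")
}
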