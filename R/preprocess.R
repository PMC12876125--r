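#' Log2-transform an expression study
#'
#' Elementwise `log2(value + offset)`; sample and gene labels are preserved.
#' A stand-in for array preprocessing pipelines (e.g. RMA) that deliver
#' log2-scale intensities: apply it when the input matrix is on the raw
#' intensity scale.
#'
#' @param study An [expr_study()].
#' @param offset Nonnegative pseudo-value added before taking logs.
#' @return The transformed [expr_study()].
#' @export
log2_transform <- function(study, offset = 0) {
  if (offset < 0) abort("`offset` must be >= 0.")
  vals <- expr_values(study)
  bad <- which(vals + offset <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "nonpositive value after offset at gene %s, sample %s.",
      rownames(vals)[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  expr_replace_values(study, log2(vals + offset))
}

#' Quantile-normalize an expression study
#'
#' Classic quantile normalization: within each sample values are ranked and
#' replaced by the across-sample mean of each rank's values, forcing all
#' samples onto an identical distribution (hence identical box summaries,
#' the normalization check used in array QC). Ties within a sample receive
#' the mean of the reference values they span. Idempotent.
#'
#' @param study An [expr_study()] with at least two samples.
#' @return The normalized [expr_study()].
#' @export
quantile_normalize <- function(study) {
  vals <- expr_values(study)
  if (ncol(vals) < 2) abort("quantile normalization needs >= 2 samples.")
  norm <- limma::normalizeQuantiles(vals, ties = TRUE)
  dimnames(norm) <- dimnames(vals)
  expr_replace_values(study, norm)
}

#' Per-sample five-number summaries
#'
#' The box-plot statistics (min, lower quartile, median, upper quartile, max)
#' per sample, with quartiles by linear interpolation (type-7 convention).
#' After quantile normalization all samples share an identical summary.
#'
#' @param study An [expr_study()].
#' @return Tibble with columns `sample_id`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
column_summaries <- function(study) {
  vals <- expr_values(study)
  if (nrow(vals) == 0) abort("empty expression matrix.")
  q <- apply(vals, 2, quantile, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7)
  tibble(
    sample_id = colnames(vals),
    min = q[1, ], q1 = q[2, ], median = q[3, ], q3 = q[4, ], max = q[5, ]
  )
}

#' Principal component analysis of samples for cohort QC
#'
#' Samples are observations and genes features; features are centered and, by
#' default, not unit-scaled (common transcriptome practice — `scale. = TRUE`
#' gives the correlation-matrix variant). Scores come from the singular value
#' decomposition; the sign convention makes each loading column's
#' largest-magnitude entry positive so results are reproducible across runs
#' and gene orderings.
#'
#' @param study An [expr_study()] with >= 2 samples.
#' @param k Number of components to keep (`<= min(genes, samples)`).
#' @param scale. Unit-scale features before decomposition?
#' @return Object of class `crosstalk_pca`: list with `scores` (tibble:
#'   `sample_id`, `group`, `tissue`, `PC1..PCk`), `explained_variance_ratio`,
#'   `loadings` (genes x k matrix) and `center` (gene means).
#' @export
pca_qc <- function(study, k = 2, scale. = FALSE) {
  vals <- expr_values(study)
  n_samples <- ncol(vals)
  if (n_samples < 2) abort("PCA needs >= 2 samples.")
  if (k > min(nrow(vals), n_samples)) {
    abort("`k` exceeds min(n_genes, n_samples).")
  }
  fit <- prcomp(t(vals), center = TRUE, scale. = scale.)
  kk <- min(k, ncol(fit$rotation))
  scores <- fit$x[, seq_len(kk), drop = FALSE]
  loadings <- fit$rotation[, seq_len(kk), drop = FALSE]
  # sign convention: largest-|loading| entry of each component is positive
  for (j in seq_len(kk)) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  evr <- (fit$sdev^2 / sum(fit$sdev^2))[seq_len(kk)]
  score_tbl <- dplyr::bind_cols(
    study$samples,
    as_tibble(scores, .name_repair = "minimal")
  )
  names(score_tbl) <- c(names(study$samples), paste0("PC", seq_len(kk)))
  structure(list(
    scores = score_tbl,
    explained_variance_ratio = evr,
    loadings = loadings,
    center = fit$center,
    scaled = scale.
  ), class = "crosstalk_pca")
}

#' @export
print.crosstalk_pca <- function(x, ...) {
  cat(sprintf("<crosstalk_pca> %d samples, %d components (%.1f%% variance)\n",
              nrow(x$scores), length(x$explained_variance_ratio),
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy PCA scores
#'
#' @param x A `crosstalk_pca`.
#' @param ... Unused.
#' @return The score tibble (one row per sample, with group/tissue labels).
#' @export
tidy.crosstalk_pca <- function(x, ...) x$scores

#' One-row PCA summary
#'
#' @param x A `crosstalk_pca`.
#' @param ... Unused.
#' @return Tibble with the number of components and per-component and
#'   cumulative explained variance ratios.
#' @export
glance.crosstalk_pca <- function(x, ...) {
  tibble(
    n_components = length(x$explained_variance_ratio),
    var_pc1 = x$explained_variance_ratio[1],
    var_pc2 = if (length(x$explained_variance_ratio) >= 2) {
      x$explained_variance_ratio[2]
    } else NA_real_,
    var_total = sum(x$explained_variance_ratio)
  )
}
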