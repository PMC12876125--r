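#' Welch's unequal-variance two-sample t-test
#'
#' `t = (mean(b) - mean(a)) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from
#' Student's t distribution. When both groups have zero variance and equal
#' means the test is degenerate and reported as `t = 0, p = 1` (so constant
#' genes stay in the universe rather than being dropped).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return A one-row tibble with columns `t`, `df`, `p`.
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))  # t = 3.674, df = 4, p ~ 0.0214
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs >= 2 values.")
  }
  res <- row_welch(matrix(group_a, nrow = 1), matrix(group_b, nrow = 1))
  tibble(t = res$t, df = res$df, p = res$p)
}

# vectorized Welch test over rows of two matrices (genes x samples per group)
row_welch <- function(mat_a, mat_b) {
  na <- ncol(mat_a); nb <- ncol(mat_b)
  ma <- rowMeans(mat_a); mb <- rowMeans(mat_b)
  va <- rowSums((mat_a - ma)^2) / (na - 1)
  vb <- rowSums((mat_b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  diff <- mb - ma
  t <- ifelse(se2 > 0, diff / sqrt(se2),
              ifelse(diff == 0, 0, sign(diff) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               na + nb - 2)
  p <- ifelse(is.infinite(t), 0, 2 * pt(-abs(t), df))
  list(t = t, df = df, p = p, mean_a = ma, mean_b = mb,
       var_a = va, var_b = vb, n_a = na, n_b = nb)
}

# Newton inversion of the trigamma function (y = trigamma(x), y > 0)
trigamma_inverse <- function(y) {
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

#' Fit a scaled inverse-chi-square prior to per-gene sample variances
#'
#' Empirical-Bayes variance moderation in the microarray tradition: per-gene
#' sample variances `s^2` with common residual degrees of freedom `df` are
#' modeled as draws from a scaled inverse-chi-square prior with `d0` prior
#' degrees of freedom and prior value `s0^2`. The fit is method-of-moments on
#' `log(s^2)`, matching the mean via the digamma function and the spread via
#' the trigamma function. When the empirical log-variance spread is at or
#' below the theoretical sampling minimum `trigamma(df/2)`, the prior is
#' degenerate and `d0 = Inf` is returned (all genes then share `s0^2`).
#'
#' @param sample_variances Positive numeric vector, length >= 10.
#' @param residual_df Residual degrees of freedom of each variance (> 0).
#' @return List with elements `d0` (prior df, possibly `Inf`) and `s0_sq`.
#' @export
fit_variance_prior <- function(sample_variances, residual_df) {
  s2 <- sample_variances
  if (length(s2) < 10) abort("need >= 10 variances to identify the prior.")
  if (any(!is.finite(s2)) || any(s2 <= 0)) {
    abort("variances must be positive and finite.")
  }
  if (residual_df <= 0) abort("`residual_df` must be > 0.")
  z <- log(s2)
  zbar <- mean(z)
  if (var(z) < 1e-14) {
    # literally identical variances: point-mass prior at the common value
    return(list(d0 = Inf, s0_sq = exp(zbar)))
  }
  evar <- var(z) - trigamma(residual_df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(zbar - digamma(residual_df / 2) + log(residual_df / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(zbar - digamma(residual_df / 2) + log(residual_df / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Per-gene two-group differential expression
#'
#' Tests every gene for an expression difference between the OA and HC groups
#' of a study, with either a plain Welch unequal-variance t-test or an
#' empirical-Bayes moderated t-test (pooled per-gene variance shrunk toward
#' the fitted prior; `t` on `df + d0` degrees of freedom). The log2 fold
#' change is defined `OA - HC`, so `up` means higher in OA patients.
#' Benjamini-Hochberg adjusted p-values are computed over all tested genes.
#'
#' @param study An [expr_study()] containing both HC and OA samples (>= 2
#'   each).
#' @param method `"welch"` (default) or `"moderated"`.
#' @return Tibble with one row per gene: `gene`, `mean_hc`, `mean_oa`,
#'   `log2fc`, `t_stat`, `df`, `p_value`, `adj_p`, `direction` (`"up"` iff
#'   `log2fc > 0`, `"down"` iff `log2fc < 0`, `NA` at exactly 0).
#' @export
differential_expression <- function(study, method = c("welch", "moderated")) {
  method <- match.arg(method)
  vals <- expr_values(study)
  g <- group_masks(study)
  if (sum(g$hc) < 2 || sum(g$oa) < 2) {
    abort("both HC and OA groups need >= 2 samples.")
  }
  hc <- vals[, g$hc, drop = FALSE]
  oa <- vals[, g$oa, drop = FALSE]

  if (method == "welch") {
    w <- row_welch(hc, oa)
    t_stat <- w$t; df <- w$df; p <- w$p
    mean_hc <- w$mean_a; mean_oa <- w$mean_b
  } else {
    n_hc <- ncol(hc); n_oa <- ncol(oa)
    mean_hc <- rowMeans(hc); mean_oa <- rowMeans(oa)
    df_resid <- n_hc + n_oa - 2
    s2 <- (rowSums((hc - mean_hc)^2) + rowSums((oa - mean_oa)^2)) / df_resid
    pos <- s2[s2 > 0]
    prior <- fit_variance_prior(pos, df_resid)
    s2_post <- if (is.infinite(prior$d0)) {
      rep(prior$s0_sq, length(s2))
    } else {
      (prior$d0 * prior$s0_sq + df_resid * s2) / (prior$d0 + df_resid)
    }
    se <- sqrt(s2_post * (1 / n_hc + 1 / n_oa))
    diff <- mean_oa - mean_hc
    t_stat <- ifelse(se > 0, diff / se,
                     ifelse(diff == 0, 0, sign(diff) * Inf))
    df <- rep(df_resid + prior$d0, length(s2))
    p <- ifelse(is.infinite(t_stat), 0, 2 * pt(-abs(t_stat), df))
  }

  log2fc <- mean_oa - mean_hc
  tibble(
    gene = rownames(vals),
    mean_hc = unname(mean_hc),
    mean_oa = unname(mean_oa),
    log2fc = unname(log2fc),
    t_stat = unname(t_stat),
    df = unname(df),
    p_value = unname(p),
    adj_p = p.adjust(unname(p), method = "BH"),
    direction = dplyr::case_when(
      log2fc > 0 ~ "up",
      log2fc < 0 ~ "down",
      TRUE ~ NA_character_
    )
  )
}

#' Filter a differential-expression table to the DEG set
#'
#' Keeps genes whose (raw or BH-adjusted) p-value is strictly below `alpha`,
#' following the screening convention "p value less than 0.05"; the stricter
#' adjusted-p variant is exposed via `use_adjusted`.
#'
#' @param de_table Output of [differential_expression()].
#' @param alpha Significance threshold, strictly between 0 and 1.
#' @param use_adjusted Filter on `adj_p` instead of `p_value`?
#' @return Tibble with columns `gene` and `direction` for the retained genes.
#' @export
filter_degs <- function(de_table, alpha = 0.05, use_adjusted = FALSE) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  p <- if (use_adjusted) de_table$adj_p else de_table$p_value
  de_table[p < alpha, c("gene", "direction")]
}

#' Volcano-plot coordinates with top-gene labels
#'
#' Returns the full volcano coordinates (`log2fc`, `-log10 p`) for every gene
#' and flags the `top_n/2` smallest-p up-regulated and `top_n/2` smallest-p
#' down-regulated genes for labeling (the convention of labeling the 20 most
#' significant genes, 10 in each direction). Ties are broken by `|log2fc|`
#' descending, then gene symbol ascending.
#'
#' @param de_table Output of [differential_expression()].
#' @param top_n Total number of genes to label (half per direction).
#' @return `de_table` augmented with `neg_log10_p` and logical `label`.
#' @export
volcano_annotations <- function(de_table, top_n = 20) {
  per_side <- top_n %/% 2
  pick <- function(dir) {
    cand <- de_table |>
      filter(!is.na(.data$direction), .data$direction == dir) |>
      arrange(.data$p_value, desc(abs(.data$log2fc)), .data$gene)
    head(cand$gene, per_side)
  }
  labeled <- c(pick("up"), pick("down"))
  de_table |>
    mutate(
      neg_log10_p = -log10(.data$p_value),
      label = .data$gene %in% labeled
    )
}
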