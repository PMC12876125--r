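#' Configuration for the synthetic two-tissue study generator
#'
#' Defines a pair of independent case/control expression cohorts emulating the
#' shape of the blood (PBMC) and synovium (synovial fibroblast) microarray
#' studies the package targets: 33 healthy controls vs 108 osteoarthritis
#' samples in blood and 11 vs 11 in synovium, a gene universe of which a
#' minority are annotated as ligands or receptors, and group mean-shifts
#' planted on a configurable subset of them on the log2 scale.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_ligands,n_receptors Number of genes annotated as ligands and as
#'   receptors; the two symbol sets are disjoint by construction.
#' @param n_pairs Number of directed ligand-receptor database pairs.
#' @param blood_hc_n,blood_oa_n Blood cohort sizes (defaults 33 and 108).
#' @param syn_hc_n,syn_oa_n Synovium cohort sizes (defaults 11 and 11).
#' @param frac_de_ligands,frac_de_receptors,frac_de_background Fraction of
#'   ligands, receptors and background genes planted as differentially
#'   expressed in each tissue (each in `[0, 1]`).
#' @param effect_log2 Planted group mean shift, log2 units (>= 0).
#' @param sigma Per-gene Gaussian noise standard deviation (> 0).
#' @param baseline_range Length-2 numeric; per-gene baseline log2 means are
#'   drawn uniformly from this interval.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000,
                             n_ligands = 150,
                             n_receptors = 150,
                             n_pairs = 400,
                             blood_hc_n = 33,
                             blood_oa_n = 108,
                             syn_hc_n = 11,
                             syn_oa_n = 11,
                             frac_de_ligands = 0.3,
                             frac_de_receptors = 0.3,
                             frac_de_background = 0.05,
                             effect_log2 = 1,
                             sigma = 0.5,
                             baseline_range = c(4, 12),
                             seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_ligands = n_ligands, n_receptors = n_receptors,
    n_pairs = n_pairs, blood_hc_n = blood_hc_n, blood_oa_n = blood_oa_n,
    syn_hc_n = syn_hc_n, syn_oa_n = syn_oa_n,
    frac_de_ligands = frac_de_ligands, frac_de_receptors = frac_de_receptors,
    frac_de_background = frac_de_background, effect_log2 = effect_log2,
    sigma = sigma, baseline_range = baseline_range, seed = as.integer(seed)
  )
  counts <- c("n_genes", "n_ligands", "n_receptors", "n_pairs",
              "blood_hc_n", "blood_oa_n", "syn_hc_n", "syn_oa_n")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1 || !is.finite(v) || v < 0 || v != round(v)) {
      abort(paste0("`", f, "` must be a single nonnegative integer."))
    }
  }
  for (f in c("blood_hc_n", "blood_oa_n", "syn_hc_n", "syn_oa_n")) {
    if (cfg[[f]] < 2) abort(paste0("`", f, "` must be >= 2."))
  }
  if (cfg$n_ligands + cfg$n_receptors > cfg$n_genes) {
    abort("n_ligands + n_receptors must be <= n_genes.")
  }
  if (cfg$n_pairs > cfg$n_ligands * cfg$n_receptors) {
    abort("n_pairs exceeds n_ligands * n_receptors.")
  }
  for (f in c("frac_de_ligands", "frac_de_receptors", "frac_de_background")) {
    v <- cfg[[f]]
    if (length(v) != 1 || !is.finite(v) || v < 0 || v > 1) {
      abort(paste0("`", f, "` must be a fraction in [0, 1]."))
    }
  }
  if (cfg$effect_log2 < 0) abort("`effect_log2` must be >= 0.")
  if (cfg$sigma <= 0) abort("`sigma` must be > 0.")
  if (length(cfg$baseline_range) != 2 ||
      cfg$baseline_range[1] > cfg$baseline_range[2]) {
    abort("`baseline_range` must be (low, high) with low <= high.")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic ligand-receptor pair database
#'
#' Draws `n_pairs` distinct directed (ligand, receptor) pairs over synthetic
#' symbols `LIG0001...` / `REC0001...`, emulating the structure of curated
#' pair catalogues such as the FANTOM5-derived list used to classify
#' differentially expressed genes into signaling roles.
#'
#' @param n_ligands,n_receptors Sizes of the two disjoint symbol universes.
#' @param n_pairs Number of distinct pairs to draw
#'   (`<= n_ligands * n_receptors`).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return Tibble with character columns `ligand` and `receptor`,
#'   `n_pairs` unique rows, sorted by ligand then receptor.
#' @examples
#' generate_lr_database(2, 2, 4, seed = 7)
#' @export
generate_lr_database <- function(n_ligands, n_receptors, n_pairs, seed = 1L) {
  if (n_ligands < 1 || n_receptors < 1) {
    abort("need at least one ligand and one receptor.")
  }
  if (n_pairs > n_ligands * n_receptors) {
    abort("n_pairs exceeds the number of distinct ligand-receptor combinations.")
  }
  idx <- with_rng(seed, sample.int(n_ligands * n_receptors, n_pairs))
  li <- ((idx - 1L) %% n_ligands) + 1L
  ri <- ((idx - 1L) %/% n_ligands) + 1L
  tibble(
    ligand = sprintf("LIG%04d", li),
    receptor = sprintf("REC%04d", ri)
  ) |>
    arrange(.data$ligand, .data$receptor)
}

# plant DE genes in one tissue: sample within each stratum, assign directions
plant_de <- function(ligands, receptors, background, cfg, seed) {
  with_rng(seed, {
    pick <- function(universe, frac) {
      k <- round(frac * length(universe))
      if (k == 0) character() else sort(sample(universe, k))
    }
    genes <- c(pick(ligands, cfg$frac_de_ligands),
               pick(receptors, cfg$frac_de_receptors),
               pick(background, cfg$frac_de_background))
    tibble(
      gene = genes,
      direction = if (length(genes)) {
        sample(c("up", "down"), length(genes), replace = TRUE)
      } else character()
    )
  })
}

# simulate one tissue's genes x samples matrix under the additive model:
# value = baseline_g + effect * (+1 planted up, -1 planted down, OA only) + noise
simulate_tissue <- function(genes, truth_de, hc_n, oa_n, cfg, tissue, seed) {
  n_genes <- length(genes)
  n_samp <- hc_n + oa_n
  vals <- with_rng(seed, {
    baseline <- runif(n_genes, cfg$baseline_range[1], cfg$baseline_range[2])
    shift <- setNames(numeric(n_genes), genes)
    if (nrow(truth_de)) {
      shift[truth_de$gene] <- ifelse(truth_de$direction == "up",
                                     cfg$effect_log2, -cfg$effect_log2)
    }
    is_oa <- rep(c(FALSE, TRUE), c(hc_n, oa_n))
    m <- matrix(baseline, n_genes, n_samp) +
      outer(shift, as.numeric(is_oa)) +
      matrix(rnorm(n_genes * n_samp, 0, cfg$sigma), n_genes, n_samp)
    m
  })
  ids <- sprintf("%s_%s%03d", tissue,
                 rep(c("HC", "OA"), c(hc_n, oa_n)),
                 c(seq_len(hc_n), seq_len(oa_n)))
  colnames(vals) <- ids
  expr <- dplyr::bind_cols(tibble(gene = genes),
                           as_tibble(vals, .name_repair = "minimal"))
  names(expr) <- c("gene", ids)
  samples <- tibble(sample_id = ids,
                    group = rep(c("HC", "OA"), c(hc_n, oa_n)),
                    tissue = tissue)
  expr_study(expr, samples)
}

#' Generate a synthetic two-tissue case/control study with known ground truth
#'
#' Simulates two independent cohorts (blood and synovium) over a shared gene
#' universe, plants group mean-shifts of `effect_log2` on randomly chosen
#' ligands, receptors and background genes per tissue, and returns the full
#' ground truth so downstream differential-expression, ligand-receptor
#' classification and communication-map stages can be validated end to end.
#'
#' The generative model per gene g and sample s is
#' `x_gs = baseline_g + effect_log2 * d_g * 1[s in OA] + N(0, sigma^2)` with
#' `d_g` in {+1, -1} for planted up/down genes and 0 otherwise; baselines are
#' drawn uniformly from `baseline_range`. Noise is i.i.d. Gaussian on the
#' log2 scale, the standard emulation of RMA-normalized intensities.
#'
#' @param config A [synthetic_config()].
#' @return List of class `two_tissue_study` with elements `blood` and
#'   `synovium` (each an [expr_study()]) and `truth`, a list of class
#'   `truth_table` with: `de` (tibble `tissue`, `gene`, `direction`),
#'   `ligands`, `receptors` (character vectors), `pairs` (the generated pair
#'   database tibble), and `planted_term_id` (`NA` until
#'   [generate_gene_sets()] plants a term).
#' @examples
#' st <- generate_two_tissue_study(synthetic_config(
#'   n_genes = 60, n_ligands = 10, n_receptors = 10, n_pairs = 20, seed = 3))
#' ncol(st$blood$expr) - 1  # 141 samples at the default cohort sizes
#' @export
generate_two_tissue_study <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  cfg <- config
  ligands <- sprintf("LIG%04d", seq_len(cfg$n_ligands))
  receptors <- sprintf("REC%04d", seq_len(cfg$n_receptors))
  background <- sprintf("GENE%05d",
                        seq_len(cfg$n_genes - cfg$n_ligands - cfg$n_receptors))
  genes <- c(ligands, receptors, background)

  pairs <- generate_lr_database(cfg$n_ligands, cfg$n_receptors, cfg$n_pairs,
                                seed = cfg$seed)
  de_bl <- plant_de(ligands, receptors, background, cfg, seed = cfg$seed + 1L)
  de_sy <- plant_de(ligands, receptors, background, cfg, seed = cfg$seed + 2L)
  blood <- simulate_tissue(genes, de_bl, cfg$blood_hc_n, cfg$blood_oa_n,
                           cfg, "BL", seed = cfg$seed + 3L)
  synovium <- simulate_tissue(genes, de_sy, cfg$syn_hc_n, cfg$syn_oa_n,
                              cfg, "SY", seed = cfg$seed + 4L)

  truth <- structure(list(
    de = bind_rows(mutate(de_bl, tissue = "BL", .before = 1),
                   mutate(de_sy, tissue = "SY", .before = 1)),
    ligands = ligands,
    receptors = receptors,
    pairs = pairs,
    planted_term_id = NA_character_
  ), class = "truth_table")

  structure(list(blood = blood, synovium = synovium, truth = truth),
            class = "two_tissue_study")
}

#' @export
print.two_tissue_study <- function(x, ...) {
  cat("<two_tissue_study>\n blood:    ")
  print(x$blood)
  cat(" synovium: ")
  print(x$synovium)
  cat(sprintf(" truth: %d planted DE genes (BL %d, SY %d), %d LR pairs\n",
              nrow(x$truth$de), sum(x$truth$de$tissue == "BL"),
              sum(x$truth$de$tissue == "SY"), nrow(x$truth$pairs)))
  invisible(x)
}

#' Generate synthetic gene-set annotations with one planted term
#'
#' Builds `n_terms` random gene sets over the given universe plus one planted
#' term exactly equal to `planted_term_genes`, each tagged with a GO-style
#' category (`BP`, `MF` or `CC`). The planted term lets over-representation
#' tests verify that a truly enriched set ranks first.
#'
#' @param genes Character vector, the gene universe.
#' @param n_terms Number of random terms to generate.
#' @param size_range Length-2 integer vector `(min, max)` of random term sizes.
#' @param planted_term_genes Character vector (subset of `genes`); the planted
#'   term's exact membership. May be empty (the planted term is then empty and
#'   flagged invalid downstream).
#' @param seed Integer seed.
#' @return Tibble of class `gene_set_annotation` with columns `term_id`,
#'   `term_name`, `category` and list-column `genes`. The planted term has
#'   `term_id` `"TERM_PLANTED"` and category `"BP"`.
#' @export
generate_gene_sets <- function(genes, n_terms, size_range,
                               planted_term_genes = character(), seed = 1L) {
  if (length(size_range) != 2 || size_range[1] > size_range[2]) {
    abort("`size_range` must be (min, max) with min <= max.")
  }
  if (size_range[2] > length(genes)) {
    abort("`size_range` exceeds the gene universe size.")
  }
  if (!all(planted_term_genes %in% genes)) {
    abort("`planted_term_genes` must be a subset of `genes`.")
  }
  random_terms <- with_rng(seed, {
    sizes <- if (n_terms > 0) {
      sample(seq(size_range[1], size_range[2]), n_terms, replace = TRUE)
    } else integer()
    members <- lapply(sizes, function(k) sort(sample(genes, k)))
    cats <- if (n_terms > 0) {
      sample(c("BP", "MF", "CC"), n_terms, replace = TRUE)
    } else character()
    tibble(
      term_id = sprintf("TERM%04d", seq_len(n_terms)),
      term_name = sprintf("random gene set %d", seq_len(n_terms)),
      category = cats,
      genes = members
    )
  })
  planted <- tibble(
    term_id = "TERM_PLANTED",
    term_name = "planted enriched gene set",
    category = "BP",
    genes = list(sort(unique(planted_term_genes)))
  )
  out <- bind_rows(planted, random_terms)
  class(out) <- c("gene_set_annotation", class(out))
  out
}
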