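pipeline_defaults <- list(
  alpha = 0.05,
  use_adjusted = FALSE,
  method = "welch",
  log2_offset = NULL,     # NULL: input is already log2 scale
  quantile = TRUE,
  pca_components = 2,
  top_n_labels = 20,
  top_n_terms = 10,
  ppi = NULL,
  seed = 1L
)

#' Assemble a pipeline run configuration
#'
#' @param blood_expr,blood_meta,syn_expr,syn_meta Paths to the two tissues'
#'   expression and metadata TSVs (blood must be tagged `BL`, synovium `SY`).
#' @param pairs Path to the ligand-receptor pair TSV.
#' @param gmt Path to the gene-set GMT file.
#' @param out_dir Output directory.
#' @param ... Optional overrides of the defaults: `alpha` (0.05),
#'   `use_adjusted` (FALSE), `method` (`"welch"`/`"moderated"`),
#'   `log2_offset` (NULL = input already log2), `quantile` (TRUE),
#'   `pca_components` (2), `top_n_labels` (20), `top_n_terms` (10),
#'   `ppi` (optional path to an interaction edge TSV), `seed` (1).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(blood_expr, blood_meta, syn_expr, syn_meta,
                       pairs, gmt, out_dir, ...) {
  cfg <- utils::modifyList(
    c(list(blood_expr = blood_expr, blood_meta = blood_meta,
           syn_expr = syn_expr, syn_meta = syn_meta,
           pairs = pairs, gmt = gmt, out_dir = out_dir),
      pipeline_defaults),
    list(...)
  )
  unknown <- setdiff(names(list(...)), names(pipeline_defaults))
  if (length(unknown)) {
    abort(paste0("unknown config field(s): ", toString(unknown)))
  }
  for (f in c("blood_expr", "blood_meta", "syn_expr", "syn_meta",
              "pairs", "gmt")) {
    if (!file.exists(cfg[[f]])) {
      abort(paste0("config path for `", f, "` does not exist: ", cfg[[f]]))
    }
  }
  if (!is.null(cfg$ppi) && !file.exists(cfg$ppi)) {
    abort(paste0("PPI edge table not found: ", cfg$ppi))
  }
  if (!cfg$method %in% c("welch", "moderated")) {
    abort("`method` must be 'welch' or 'moderated'.")
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline run configuration from YAML
#'
#' The YAML maps field names of [run_config()] to values; `overrides` (a named
#' list) takes precedence, giving a `--set key=value` style mechanism.
#'
#' @param path Path to the YAML file.
#' @param overrides Named list of fields overriding the file's values.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw <- utils::modifyList(raw, overrides)
  required <- c("blood_expr", "blood_meta", "syn_expr", "syn_meta",
                "pairs", "gmt", "out_dir")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(paste0("config is missing required field(s): ", toString(missing)))
  }
  do.call(run_config, raw)
}

preprocess_stage <- function(study, cfg) {
  if (!is.null(cfg$log2_offset)) {
    study <- log2_transform(study, offset = cfg$log2_offset)
  }
  if (isTRUE(cfg$quantile)) study <- quantile_normalize(study)
  study
}

tissue_stage <- function(study, pairs, annotation, cfg, tissue, out_dir) {
  study <- preprocess_stage(study, cfg)
  box <- column_summaries(study)
  pca <- pca_qc(study, k = cfg$pca_components)
  de <- differential_expression(study, method = cfg$method)
  degs <- filter_degs(de, alpha = cfg$alpha, use_adjusted = cfg$use_adjusted)
  classification <- classify_lr(degs, pairs, tissue = tissue)
  volcano <- volcano_annotations(de, top_n = cfg$top_n_labels)
  ligands <- classification_roles(classification, "ligand")$gene
  enrichment <- if (length(ligands)) {
    enrich_ora(ligands, annotation, background = study$expr$gene)
  } else NULL
  prefix <- file.path(out_dir, tolower(tissue))
  write_expression_tsv(study, paste0(prefix, "_normalized.tsv"),
                       paste0(prefix, "_samples.tsv"))
  readr::write_tsv(box, paste0(prefix, "_box_summaries.tsv"), progress = FALSE)
  readr::write_tsv(tidy(pca), paste0(prefix, "_pca_scores.tsv"),
                   progress = FALSE)
  readr::write_tsv(de, paste0(prefix, "_de.tsv"), progress = FALSE)
  readr::write_tsv(volcano, paste0(prefix, "_volcano.tsv"), progress = FALSE)
  readr::write_tsv(classification, paste0(prefix, "_lr_classification.tsv"),
                   progress = FALSE)
  if (!is.null(enrichment)) {
    write_enrichment_tsv(enrichment,
                         paste0(prefix, "_ligand_enrichment.tsv"))
  }
  inform(sprintf(
    "[%s] genes=%d DEGs=%d ligands=%d receptors=%d",
    tissue, nrow(study$expr), nrow(degs), length(ligands),
    nrow(classification_roles(classification, "receptor"))))
  list(study = study, box = box, pca = pca, de = de, degs = degs,
       classification = classification, volcano = volcano,
       enrichment = enrichment)
}

#' Run the full blood-synovium crosstalk pipeline
#'
#' Executes, per tissue, normalization and QC, differential expression and DEG
#' filtering, and ligand/receptor classification; then builds the four-class
#' communication map, runs over-representation analysis of each tissue's
#' differential ligands, optionally ranks ligand hubs against a supplied
#' interaction edge table, and writes every intermediate table plus a
#' machine-readable `summary.json` to the output directory. Deterministic
#' given the configuration and seed.
#'
#' @param config A `run_config` (from [run_config()] or [read_run_config()]).
#' @return Invisibly, the result bundle: a list with per-tissue stage results
#'   (`blood`, `synovium`), the communication `map`, its `map_summary`,
#'   optional `hubs`, and the `summary` list mirrored in `summary.json`.
#' @export
run_crosstalk_pipeline <- function(config) {
  cfg <- config
  if (!inherits(cfg, "run_config")) abort("`config` must be a run_config.")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  with_rng(cfg$seed, {
    blood <- read_expression_tsv(cfg$blood_expr, cfg$blood_meta)
    synovium <- read_expression_tsv(cfg$syn_expr, cfg$syn_meta)
    if (!all(blood$samples$tissue == "BL")) {
      abort("blood metadata must tag every sample as tissue BL.")
    }
    if (!all(synovium$samples$tissue == "SY")) {
      abort("synovium metadata must tag every sample as tissue SY.")
    }
    pairs <- read_lr_pairs(cfg$pairs)
    annotation <- read_gmt(cfg$gmt)

    bl <- tissue_stage(blood, pairs, annotation, cfg, "BL", cfg$out_dir)
    sy <- tissue_stage(synovium, pairs, annotation, cfg, "SY", cfg$out_dir)

    map <- build_communication_map(bl$classification, sy$classification, pairs)
    map_summary <- summarize_map(map)
    write_communication_outputs(map, cfg$out_dir)
    readr::write_tsv(map_summary$degrees,
                     file.path(cfg$out_dir, "node_degrees.tsv"),
                     progress = FALSE)

    hubs <- NULL
    if (!is.null(cfg$ppi)) {
      ppi <- readr::read_tsv(cfg$ppi,
                             col_types = readr::cols(.default = "c"),
                             progress = FALSE)
      all_ligands <- unique(c(
        classification_roles(bl$classification, "ligand")$gene,
        classification_roles(sy$classification, "ligand")$gene))
      hubs <- ligand_hubs(all_ligands, ppi)
      readr::write_tsv(hubs, file.path(cfg$out_dir, "ligand_hubs.tsv"),
                       progress = FALSE)
    }

    top_terms <- function(res) {
      if (is.null(res) || nrow(res) == 0) return(list())
      top <- head(res, cfg$top_n_terms)
      lapply(seq_len(nrow(top)), function(i) {
        list(term_id = top$term_id[i], category = top$category[i],
             p_value = top$p_value[i], adj_p = top$adj_p[i])
      })
    }
    class_counts <- setNames(as.list(map_summary$classes$n_edges),
                             map_summary$classes$direction_class)
    summary <- list(
      config = cfg[setdiff(names(cfg), "out_dir")],
      tissues = list(
        BL = list(
          n_genes = nrow(bl$study$expr),
          n_samples = nrow(bl$study$samples),
          n_degs = nrow(bl$degs),
          n_ligands = nrow(classification_roles(bl$classification, "ligand")),
          n_receptors = nrow(classification_roles(bl$classification,
                                                  "receptor")),
          top_enriched_terms = top_terms(bl$enrichment)
        ),
        SY = list(
          n_genes = nrow(sy$study$expr),
          n_samples = nrow(sy$study$samples),
          n_degs = nrow(sy$degs),
          n_ligands = nrow(classification_roles(sy$classification, "ligand")),
          n_receptors = nrow(classification_roles(sy$classification,
                                                  "receptor")),
          top_enriched_terms = top_terms(sy$enrichment)
        )
      ),
      communication = c(class_counts, list(total_edges = nrow(map)))
    )
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    yaml::write_yaml(cfg[order(names(cfg))],
                     file.path(cfg$out_dir, "resolved_config.yaml"))

    invisible(list(blood = bl, synovium = sy, map = map,
                   map_summary = map_summary, hubs = hubs, summary = summary))
  })
}

#' Write a synthetic two-tissue study (and its annotations) to a directory
#'
#' Convenience wrapper producing, from one [synthetic_config()], every file
#' the pipeline consumes: expression and metadata TSVs for both tissues, the
#' pair table, a GMT whose planted term is the set of ligands planted as DE
#' in blood, and the ground-truth JSON.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @param n_terms,size_range Random gene-set parameters for the GMT.
#' @return Invisibly, a named list with the generated file paths and the
#'   in-memory study object.
#' @export
write_synthetic_study <- function(config = synthetic_config(), out_dir,
                                  n_terms = 50, size_range = c(10, 50)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- generate_two_tissue_study(config)
  planted <- intersect(st$truth$de$gene[st$truth$de$tissue == "BL"],
                       st$truth$ligands)
  annotation <- generate_gene_sets(
    genes = st$blood$expr$gene, n_terms = n_terms, size_range = size_range,
    planted_term_genes = planted, seed = config$seed + 5L)
  # a memberless planted term is not a valid GMT record; drop it and leave
  # the truth table's planted_term_id unset
  annotation <- annotation[lengths(annotation$genes) > 0, ]
  if (length(planted)) st$truth$planted_term_id <- "TERM_PLANTED"
  paths <- list(
    blood_expr = file.path(out_dir, "blood_expr.tsv"),
    blood_meta = file.path(out_dir, "blood_samples.tsv"),
    syn_expr = file.path(out_dir, "synovium_expr.tsv"),
    syn_meta = file.path(out_dir, "synovium_samples.tsv"),
    pairs = file.path(out_dir, "lr_pairs.tsv"),
    gmt = file.path(out_dir, "gene_sets.gmt"),
    truth = file.path(out_dir, "truth.json")
  )
  write_expression_tsv(st$blood, paths$blood_expr, paths$blood_meta)
  write_expression_tsv(st$synovium, paths$syn_expr, paths$syn_meta)
  write_lr_pairs(st$truth$pairs, paths$pairs)
  write_gmt(annotation, paths$gmt)
  write_truth_json(st$truth, paths$truth)
  invisible(c(paths, list(study = st, annotation = annotation)))
}
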