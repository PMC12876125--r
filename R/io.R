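#' Read an expression matrix and its sample metadata from TSV
#'
#' The expression file has a header line of sample IDs, a first column of gene
#' symbols and one numeric column per sample (log2 scale). The metadata file
#' has columns `sample_id`, `group` (`HC`/`OA`) and `tissue` (`BL`/`SY`).
#' Malformed input is rejected rather than coerced: duplicate sample headers,
#' samples missing from the metadata and non-numeric cells (reported with
#' their row/column coordinates) are errors.
#'
#' @param path Path to the expression TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @return An [expr_study()] with samples ordered as in the expression file.
#' @export
read_expression_tsv <- function(path, metadata_path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    abort(paste0("duplicate sample IDs in header: ", toString(dup)))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         name_repair = "minimal", progress = FALSE)
  if (nrow(raw) < 1) abort("expression file has no gene rows.")
  names(raw) <- c("gene", sample_ids)
  vals <- matrix(NA_real_, nrow(raw), length(sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad)) {
      abort(sprintf(
        "non-numeric value '%s' at row %d (gene %s), column '%s'.",
        col[bad[1]], bad[1], raw$gene[bad[1]], sample_ids[j]))
    }
    vals[, j] <- num
  }
  meta <- readr::read_tsv(metadata_path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  colnames(vals) <- sample_ids
  expr <- dplyr::bind_cols(tibble(gene = raw$gene),
                           as_tibble(vals, .name_repair = "minimal"))
  names(expr) <- c("gene", sample_ids)
  expr_study(expr, meta)
}

#' Write an expression study to TSV files
#'
#' @param study An [expr_study()].
#' @param path Output path for the expression TSV (first column `gene`).
#' @param metadata_path Output path for the sample metadata TSV.
#' @return Invisibly, the paths written.
#' @export
write_expression_tsv <- function(study, path, metadata_path) {
  readr::write_tsv(study$expr, path, progress = FALSE)
  readr::write_tsv(study$samples, metadata_path, progress = FALSE)
  invisible(c(path, metadata_path))
}

#' Collapse probe-level rows to gene symbols by arithmetic mean
#'
#' Microarray platforms measure probes, often several per gene; following the
#' convention that probe IDs are mapped to gene symbols and the mean of a
#' gene's probes taken as its expression value, this collapses a probe-level
#' table to one row per mapped gene. Unmapped probes are dropped and their
#' count reported via a message.
#'
#' @param probe_tbl Tibble whose first column is the probe ID and remaining
#'   columns are numeric sample values.
#' @param probe_map Tibble with columns `probe_id` and `gene`.
#' @return Tibble with first column `gene` (sorted lexicographically) and the
#'   same sample columns, each gene row the per-sample mean of its probes.
#' @examples
#' probes <- tibble::tibble(probe = c("p1", "p2"), s1 = c(2, 4), s2 = c(4, 6))
#' map <- tibble::tibble(probe_id = c("p1", "p2"), gene = c("A", "A"))
#' collapse_probes(probes, map)  # gene A: (3, 5)
#' @export
collapse_probes <- function(probe_tbl, probe_map) {
  probe_tbl <- as_tibble(probe_tbl)
  if (!all(c("probe_id", "gene") %in% names(probe_map))) {
    abort("`probe_map` must have columns probe_id and gene.")
  }
  names(probe_tbl)[1] <- "probe_id"
  mapped <- inner_join(probe_tbl, probe_map[, c("probe_id", "gene")],
                       by = "probe_id")
  n_dropped <- nrow(probe_tbl) - nrow(mapped)
  if (nrow(mapped) == 0) {
    abort("no probe in the table has a map entry.")
  }
  if (n_dropped > 0) {
    inform(sprintf("collapse_probes: dropped %d unmapped probe(s).", n_dropped))
  }
  mapped |>
    select(-"probe_id") |>
    group_by(.data$gene) |>
    summarise(across(dplyr::everything(), mean), .groups = "drop") |>
    arrange(.data$gene)
}

#' Read a ligand-receptor pair table from TSV
#'
#' Expects columns `ligand` and `receptor` (any case). Symbols are
#' whitespace-stripped and uppercased — case mismatch between platform
#' annotations and pair databases is a classic silent-failure mode — and exact
#' duplicate pairs are dropped with a reported count.
#'
#' @param path Path to the TSV file.
#' @return Tibble with character columns `ligand` and `receptor`, unique rows.
#' @export
read_lr_pairs <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  names(tbl) <- tolower(names(tbl))
  if (!all(c("ligand", "receptor") %in% names(tbl))) {
    abort("pair table must have columns 'ligand' and 'receptor'.")
  }
  pairs <- tibble(
    ligand = toupper(stringr::str_trim(tbl$ligand)),
    receptor = toupper(stringr::str_trim(tbl$receptor))
  )
  out <- distinct(pairs)
  if (nrow(out) < nrow(pairs)) {
    inform(sprintf("read_lr_pairs: dropped %d duplicate pair(s).",
                   nrow(pairs) - nrow(out)))
  }
  out
}

#' Write a ligand-receptor pair table to TSV
#'
#' @param pairs Tibble with columns `ligand` and `receptor`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_lr_pairs <- function(pairs, path) {
  readr::write_tsv(pairs[, c("ligand", "receptor")], path, progress = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One term per line: term ID, description, then tab-separated member genes.
#' The GO category (`BP`/`MF`/`CC`) is parsed from the description field when
#' it is one of those codes; otherwise the category defaults to `BP` with a
#' warning. Lines with fewer than three fields and duplicated term IDs are
#' errors.
#'
#' @param path Path to the GMT file.
#' @return Tibble of class `gene_set_annotation` with columns `term_id`,
#'   `term_name`, `category` and list-column `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 tab-separated fields.",
                  short[1]))
  }
  term_id <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(term_id)) {
    dup <- unique(term_id[duplicated(term_id)])
    abort(paste0("duplicate term_id in GMT: ", toString(dup)))
  }
  desc <- vapply(fields, `[[`, "", 2L)
  cat_field <- vapply(strsplit(desc, "|", fixed = TRUE), `[[`, "", 1L)
  category <- ifelse(cat_field %in% c("BP", "MF", "CC"), cat_field, "BP")
  if (any(!cat_field %in% c("BP", "MF", "CC"))) {
    warn("read_gmt: description field not BP/MF/CC for some terms; defaulting to BP.")
  }
  term_name <- vapply(strsplit(desc, "|", fixed = TRUE), function(x) {
    if (length(x) >= 2) paste(x[-1], collapse = "|") else x[1]
  }, "")
  out <- tibble(
    term_id = term_id,
    term_name = term_name,
    category = category,
    genes = lapply(fields, function(x) unique(x[-(1:2)]))
  )
  class(out) <- c("gene_set_annotation", class(out))
  out
}

#' Write gene sets to a GMT file
#'
#' The description field is serialized as `"<category>|<term_name>"` so that
#' [read_gmt()] round-trips both fields.
#'
#' @param annotation A `gene_set_annotation` tibble (see [read_gmt()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(annotation, path) {
  lines <- vapply(seq_len(nrow(annotation)), function(i) {
    paste(c(annotation$term_id[i],
            paste0(annotation$category[i], "|", annotation$term_name[i]),
            annotation$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a truth table to JSON
#'
#' @param truth A `truth_table` from [generate_two_tissue_study()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(
    de = truth$de,
    ligands = truth$ligands,
    receptors = truth$receptors,
    pairs = truth$pairs,
    planted_term_id = truth$planted_term_id
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# deterministic node table of a map: one row per (tissue, symbol) with role(s)
map_nodes <- function(map) {
  nodes <- bind_rows(
    tibble(tissue = map$source_tissue, symbol = map$ligand, role = "ligand"),
    tibble(tissue = map$target_tissue, symbol = map$receptor, role = "receptor")
  ) |>
    distinct() |>
    group_by(.data$tissue, .data$symbol) |>
    summarise(role = paste(sort(unique(.data$role)), collapse = ";"),
              .groups = "drop") |>
    arrange(.data$tissue, .data$role, .data$symbol)
  mutate(nodes, id = paste0(.data$tissue, ":", .data$symbol))
}

#' Serialize a communication map to edges TSV, GraphML and chord-segment JSON
#'
#' Replaces interactive circos/network rendering with deterministic plot data:
#' (a) an edge table TSV, (b) a GraphML network whose nodes are keyed
#' `"<tissue>:<symbol>"` and typed by role, and (c) a chord-segment JSON
#' listing, per tissue, the ordered ligand then receptor segments and the edge
#' list indexed by segment. All outputs are fully sorted, so repeated runs are
#' byte-identical.
#'
#' @param map A communication-map tibble from [build_communication_map()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the three paths written.
#' @export
write_communication_outputs <- function(map, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  }
  map <- arrange(map, .data$direction_class, .data$ligand, .data$receptor)
  edges_path <- file.path(out_dir, "communication_edges.tsv")
  readr::write_tsv(map, edges_path, progress = FALSE)

  nodes <- map_nodes(map)
  graphml_path <- file.path(out_dir, "communication_map.graphml")
  if (nrow(nodes)) {
    g <- igraph::graph_from_data_frame(
      d = data.frame(
        from = paste0(map$source_tissue, ":", map$ligand),
        to = paste0(map$target_tissue, ":", map$receptor),
        direction_class = map$direction_class,
        stringsAsFactors = FALSE
      ),
      directed = TRUE,
      vertices = data.frame(name = nodes$id, tissue = nodes$tissue,
                            type = nodes$role, stringsAsFactors = FALSE)
    )
    igraph::write_graph(g, graphml_path, format = "graphml")
  } else {
    g <- igraph::make_empty_graph(directed = TRUE)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }

  # chord layout: per tissue, ligand segments then receptor segments; edges
  # reference segments by 0-based index into the concatenated segment list
  seg <- nodes |>
    tidyr::separate_rows("role", sep = ";") |>
    mutate(role_order = ifelse(.data$role == "ligand", 0L, 1L)) |>
    arrange(.data$tissue, .data$role_order, .data$symbol) |>
    mutate(segment_index = dplyr::row_number() - 1L)
  seg_key <- setNames(seg$segment_index,
                      paste(seg$tissue, seg$role, seg$symbol, sep = ":"))
  chord <- list(
    segments = lapply(seq_len(nrow(seg)), function(i) {
      list(index = seg$segment_index[i], tissue = seg$tissue[i],
           role = seg$role[i], symbol = seg$symbol[i])
    }),
    edges = lapply(seq_len(nrow(map)), function(i) {
      list(
        from = unname(seg_key[paste(map$source_tissue[i], "ligand",
                                    map$ligand[i], sep = ":")]),
        to = unname(seg_key[paste(map$target_tissue[i], "receptor",
                                  map$receptor[i], sep = ":")]),
        direction_class = map$direction_class[i]
      )
    })
  )
  chord_path <- file.path(out_dir, "chord_segments.json")
  jsonlite::write_json(chord, chord_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(edges = edges_path, graphml = graphml_path, chord = chord_path))
}
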