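#' Classify a tissue's DEGs into ligands and receptors
#'
#' Intersects a differentially-expressed gene set with the ligand and receptor
#' universes of a curated pair database. A gene annotated in both database
#' roles appears in both (one row per role). Empty intersections are valid
#' results.
#'
#' @param degs Tibble with columns `gene` and `direction` (output of
#'   [filter_degs()]).
#' @param pairs Pair-table tibble with columns `ligand` and `receptor`.
#' @param tissue Tissue label attached to the result (`"BL"` or `"SY"`).
#' @return Tibble with columns `tissue`, `gene`, `role`
#'   (`"ligand"`/`"receptor"`) and `direction`, sorted by role then gene.
#' @examples
#' degs <- tibble::tibble(gene = c("IL6", "GAPDH"), direction = "up")
#' pairs <- tibble::tibble(ligand = "IL6", receptor = "IL6R")
#' classify_lr(degs, pairs, tissue = "BL")
#' @export
classify_lr <- function(degs, pairs, tissue) {
  if (!tissue %in% TISSUES) abort("`tissue` must be 'BL' or 'SY'.")
  lig <- degs |>
    filter(.data$gene %in% unique(pairs$ligand)) |>
    mutate(role = "ligand")
  rec <- degs |>
    filter(.data$gene %in% unique(pairs$receptor)) |>
    mutate(role = "receptor")
  bind_rows(lig, rec) |>
    mutate(tissue = tissue, .before = 1) |>
    select("tissue", "gene", "role", "direction") |>
    arrange(.data$role, .data$gene)
}

classification_roles <- function(classification, role) {
  classification[classification$role == role,
                 c("gene", "direction"), drop = FALSE]
}

#' Build the directed two-tissue communication map
#'
#' The core inference: for every ordered tissue pair (A, B) among blood and
#' synovium — within-tissue pairs included — an edge (A, L) -> (B, R) is
#' emitted for every database pair (L, R) with L a differential ligand of A
#' and R a differential receptor of B. Both genes' DE directions are carried
#' as annotations (presence/absence on DEG status is the only filter; no
#' concordance requirement is imposed).
#'
#' @param class_bl,class_sy Classifications from [classify_lr()] for the BL
#'   and SY tissues, built against the same `pairs` table.
#' @param pairs Pair-table tibble with columns `ligand` and `receptor`.
#' @return Tibble with columns `source_tissue`, `ligand`, `ligand_direction`,
#'   `target_tissue`, `receptor`, `receptor_direction`, `direction_class`
#'   (one of `"BL->BL"`, `"BL->SY"`, `"SY->BL"`, `"SY->SY"`), sorted by
#'   class, ligand, receptor; no duplicate edges.
#' @export
build_communication_map <- function(class_bl, class_sy, pairs) {
  cls <- list(BL = class_bl, SY = class_sy)
  for (tis in TISSUES) {
    stray_l <- setdiff(classification_roles(cls[[tis]], "ligand")$gene,
                       pairs$ligand)
    stray_r <- setdiff(classification_roles(cls[[tis]], "receptor")$gene,
                       pairs$receptor)
    if (length(stray_l) || length(stray_r)) {
      abort(paste0("classification for ", tis, " contains symbols absent ",
                   "from the pair table: ",
                   toString(head(c(stray_l, stray_r), 5))))
    }
  }
  empty <- tibble(
    source_tissue = character(), ligand = character(),
    ligand_direction = character(), target_tissue = character(),
    receptor = character(), receptor_direction = character(),
    direction_class = character()
  )
  combos <- expand.grid(source = TISSUES, target = TISSUES,
                        stringsAsFactors = FALSE)
  edges <- purrr::pmap(combos, function(source, target) {
    lig <- classification_roles(cls[[source]], "ligand")
    rec <- classification_roles(cls[[target]], "receptor")
    pairs |>
      inner_join(rename(lig, ligand = "gene", ligand_direction = "direction"),
                 by = "ligand") |>
      inner_join(rename(rec, receptor = "gene",
                        receptor_direction = "direction"),
                 by = "receptor") |>
      mutate(
        source_tissue = source,
        target_tissue = target,
        direction_class = paste0(source, "->", target)
      )
  })
  bind_rows(empty, bind_rows(edges)) |>
    select("source_tissue", "ligand", "ligand_direction", "target_tissue",
           "receptor", "receptor_direction", "direction_class") |>
    distinct() |>
    arrange(.data$direction_class, .data$ligand, .data$receptor)
}

#' Summarize a communication map
#'
#' @param map Output of [build_communication_map()].
#' @return List with `classes` (tibble `direction_class`, `n_edges`; all four
#'   classes present, zeros included, summing to the total edge count) and
#'   `degrees` (tibble `tissue`, `gene`, `role`, `degree`: out-degree for
#'   ligands, in-degree for receptors).
#' @export
summarize_map <- function(map) {
  classes <- tibble(direction_class = DIRECTION_CLASSES) |>
    left_join(count(map, .data$direction_class, name = "n_edges"),
              by = "direction_class") |>
    mutate(n_edges = tidyr::replace_na(.data$n_edges, 0L))
  out_deg <- map |>
    count(tissue = .data$source_tissue, gene = .data$ligand,
          name = "degree") |>
    mutate(role = "ligand")
  in_deg <- map |>
    count(tissue = .data$target_tissue, gene = .data$receptor,
          name = "degree") |>
    mutate(role = "receptor")
  degrees <- bind_rows(out_deg, in_deg) |>
    select("tissue", "gene", "role", "degree") |>
    arrange(.data$tissue, .data$role, .data$gene)
  list(classes = classes, degrees = degrees)
}

#' Rank differential ligands by connectivity in an interaction network
#'
#' Induces the subgraph of a user-supplied undirected protein-interaction edge
#' table on the ligand set and ranks ligands by degree (hub analysis; the
#' edge table plays the role an interaction database service would). Ligands
#' absent from the edge table have degree 0 and form singleton components.
#'
#' @param ligands Character vector of ligand symbols.
#' @param interaction_edges Tibble/data frame whose first two columns are the
#'   two endpoint gene symbols of each undirected edge.
#' @return Tibble with columns `gene`, `degree`, `component`, sorted by degree
#'   descending then gene ascending.
#' @export
ligand_hubs <- function(ligands, interaction_edges) {
  ligands <- sort(unique(ligands))
  edges <- as_tibble(interaction_edges)
  if (ncol(edges) >= 2) {
    names(edges)[1:2] <- c("from", "to")
    edges <- edges |>
      filter(.data$from %in% ligands, .data$to %in% ligands,
             .data$from != .data$to) |>
      mutate(a = pmin(.data$from, .data$to), b = pmax(.data$from, .data$to)) |>
      distinct(.data$a, .data$b)
  } else {
    edges <- tibble(a = character(), b = character())
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ligands))
  comp <- igraph::components(g)
  tibble(
    gene = ligands,
    degree = as.integer(igraph::degree(g)[ligands]),
    component = as.integer(comp$membership[ligands])
  ) |>
    arrange(desc(.data$degree), .data$gene)
}
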