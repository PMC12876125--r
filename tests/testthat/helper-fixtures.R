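# small in-code fixtures shared across test files

# a tiny expr_study built directly from a value matrix
make_study <- function(values, groups, tissue = "BL",
                       genes = sprintf("G%03d", seq_len(nrow(values)))) {
  ids <- sprintf("%s_s%02d", tissue, seq_len(ncol(values)))
  colnames(values) <- ids
  expr <- dplyr::bind_cols(tibble::tibble(gene = genes),
                           tibble::as_tibble(values, .name_repair = "minimal"))
  names(expr) <- c("gene", ids)
  expr_study(expr, tibble::tibble(sample_id = ids, group = groups,
                                  tissue = tissue))
}

# random study: n_genes x (n_hc + n_oa), N(mean 8, sd 1) values
random_study <- function(n_genes, n_hc, n_oa, tissue = "BL", seed = 1) {
  withr::with_seed(seed, {
    vals <- matrix(rnorm(n_genes * (n_hc + n_oa), 8, 1), n_genes)
    make_study(vals, rep(c("HC", "OA"), c(n_hc, n_oa)), tissue)
  })
}

# random DEG set / classification fixtures over arbitrary symbols
random_degs <- function(genes, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    gene = genes,
    direction = sample(c("up", "down"), length(genes), replace = TRUE)
  ))
}

# all permutations of a vector (recursive; used for small exhaustive checks)
combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

# brute-force oracle for the communication map: explicit triple loop
brute_force_map <- function(lig_bl, rec_bl, lig_sy, rec_sy, pairs) {
  lig <- list(BL = lig_bl, SY = lig_sy)
  rec <- list(BL = rec_bl, SY = rec_sy)
  rows <- list()
  for (a in c("BL", "SY")) {
    for (b in c("BL", "SY")) {
      for (i in seq_len(nrow(pairs))) {
        l <- pairs$ligand[i]; r <- pairs$receptor[i]
        if (l %in% lig[[a]]$gene && r %in% rec[[b]]$gene) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            source_tissue = a, ligand = l,
            ligand_direction = lig[[a]]$direction[match(l, lig[[a]]$gene)],
            target_tissue = b, receptor = r,
            receptor_direction = rec[[b]]$direction[match(r, rec[[b]]$gene)],
            direction_class = paste0(a, "->", b)
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  dplyr::arrange(dplyr::distinct(out), direction_class, ligand, receptor)
}

# turn a (gene, direction, role) classification fixture into classify_lr form
as_classification <- function(tissue, ligands, receptors) {
  dplyr::bind_rows(
    dplyr::mutate(ligands, role = "ligand"),
    dplyr::mutate(receptors, role = "receptor")
  ) |>
    dplyr::mutate(tissue = tissue, .before = 1) |>
    dplyr::select(tissue, gene, role, direction)
}

# random classification drawn from a pair table's universes
random_classification <- function(tissue, pairs, n_lig, n_rec, seed) {
  withr::with_seed(seed, {
    lig_pool <- unique(pairs$ligand); rec_pool <- unique(pairs$receptor)
    ligands <- random_degs(sample(lig_pool, min(n_lig, length(lig_pool))),
                           seed + 1)
    receptors <- random_degs(sample(rec_pool, min(n_rec, length(rec_pool))),
                             seed + 2)
    list(classification = as_classification(tissue, ligands, receptors),
         ligands = ligands, receptors = receptors)
  })
}
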