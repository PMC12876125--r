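test_that("classify_lr intersects DEGs with database roles", {
  pairs <- tibble::tibble(ligand = "IL6", receptor = "IL6R")
  degs <- tibble::tibble(gene = c("IL6", "GAPDH"), direction = c("up", "down"))
  cls <- classify_lr(degs, pairs, tissue = "BL")
  expect_equal(cls$gene[cls$role == "ligand"], "IL6")
  expect_equal(cls$direction[cls$role == "ligand"], "up")
  expect_equal(sum(cls$role == "receptor"), 0)

  empty <- classify_lr(degs[0, ], pairs, tissue = "SY")
  expect_equal(nrow(empty), 0)

  # a gene in both database roles appears in both sets
  both <- tibble::tibble(ligand = c("A", "B"), receptor = c("B", "C"))
  cls2 <- classify_lr(tibble::tibble(gene = "B", direction = "down"), both,
                      tissue = "BL")
  expect_setequal(cls2$role, c("ligand", "receptor"))

  expect_error(classify_lr(degs, pairs, tissue = "XX"), "tissue")
})

test_that("classify_lr equals brute-force set intersection on random input", {
  pairs <- generate_lr_database(120, 120, 2422, seed = 9)
  universe <- c(unique(pairs$ligand), unique(pairs$receptor),
                sprintf("BG%04d", 1:500))
  degs <- withr::with_seed(14, random_degs(sample(universe, 500)))
  cls <- classify_lr(degs, pairs, tissue = "BL")
  expect_setequal(cls$gene[cls$role == "ligand"],
                  intersect(degs$gene, pairs$ligand))
  expect_setequal(cls$gene[cls$role == "receptor"],
                  intersect(degs$gene, pairs$receptor))
})

test_that("single-pair case yields exactly one BL->SY edge", {
  pairs <- tibble::tibble(ligand = "IL6", receptor = "IL6R")
  bl <- as_classification("BL",
                          tibble::tibble(gene = "IL6", direction = "up"),
                          random_degs(character()))
  sy <- as_classification("SY", random_degs(character()),
                          tibble::tibble(gene = "IL6R", direction = "down"))
  map <- build_communication_map(bl, sy, pairs)
  expect_equal(nrow(map), 1)
  expect_equal(map$direction_class, "BL->SY")
  expect_equal(map$ligand_direction, "up")
  expect_equal(map$receptor_direction, "down")

  none <- build_communication_map(
    as_classification("BL", random_degs(character()),
                      random_degs(character())),
    as_classification("SY", random_degs(character()),
                      random_degs(character())), pairs)
  expect_equal(nrow(none), 0)
  expect_named(none, c("source_tissue", "ligand", "ligand_direction",
                       "target_tissue", "receptor", "receptor_direction",
                       "direction_class"))
})

test_that("communication map equals the brute-force oracle on random instances", {
  for (s in 1:10) {
    pairs <- generate_lr_database(30, 30, 200, seed = s)
    cb <- random_classification("BL", pairs, 12, 15, seed = 100 + s)
    cs <- random_classification("SY", pairs, 10, 8, seed = 200 + s)
    map <- build_communication_map(cb$classification, cs$classification, pairs)
    oracle <- brute_force_map(cb$ligands, cb$receptors,
                              cs$ligands, cs$receptors, pairs)
    expect_equal(as.data.frame(map), as.data.frame(oracle))
  }
})

test_that("map is monotone in DEGs and database pairs", {
  pairs <- generate_lr_database(25, 25, 150, seed = 4)
  universe <- unique(c(pairs$ligand, pairs$receptor))
  degs_bl <- withr::with_seed(31, random_degs(sample(universe, 20)))
  degs_sy <- withr::with_seed(32, random_degs(sample(universe, 20)))
  build <- function(db, extra_bl = NULL) {
    d_bl <- dplyr::bind_rows(degs_bl, extra_bl)
    build_communication_map(classify_lr(d_bl, db, "BL"),
                            classify_lr(degs_sy, db, "SY"), db)
  }
  map <- build(pairs)
  key <- function(m) paste(m$source_tissue, m$ligand, m$target_tissue,
                           m$receptor)

  # adding a DEG never removes an edge
  extra_lig <- setdiff(unique(pairs$ligand), degs_bl$gene)[1]
  map_more <- build(pairs, tibble::tibble(gene = extra_lig, direction = "up"))
  expect_true(all(key(map) %in% key(map_more)))

  # removing a database pair never adds an edge
  map_fewer <- build(pairs[-seq_len(30), ])
  expect_true(all(key(map_fewer) %in% key(map)))
})

test_that("swapping tissue classifications mirrors between-tissue edges", {
  pairs <- generate_lr_database(20, 20, 120, seed = 6)
  cb <- random_classification("BL", pairs, 8, 8, seed = 41)$classification
  cs <- random_classification("SY", pairs, 8, 8, seed = 42)$classification
  fwd <- build_communication_map(cb, cs, pairs)
  swapped <- build_communication_map(
    dplyr::mutate(cs, tissue = "BL"), dplyr::mutate(cb, tissue = "SY"), pairs)
  fwd_bl_sy <- fwd[fwd$direction_class == "BL->SY", ]
  sw_sy_bl <- swapped[swapped$direction_class == "SY->BL", ]
  expect_equal(nrow(fwd_bl_sy), nrow(sw_sy_bl))
  expect_setequal(paste(fwd_bl_sy$ligand, fwd_bl_sy$receptor),
                  paste(sw_sy_bl$ligand, sw_sy_bl$receptor))
})

test_that("build_communication_map rejects symbols absent from the pair table", {
  pairs <- tibble::tibble(ligand = "L1", receptor = "R1")
  bad <- as_classification("BL",
                           tibble::tibble(gene = "NOTHERE", direction = "up"),
                           random_degs(character()))
  sy <- as_classification("SY", random_degs(character()),
                          random_degs(character()))
  expect_error(build_communication_map(bad, sy, pairs), "absent.*NOTHERE")
})

test_that("summarize_map counts classes and node degrees exactly", {
  empty <- build_communication_map(
    as_classification("BL", random_degs(character()),
                      random_degs(character())),
    as_classification("SY", random_degs(character()),
                      random_degs(character())),
    tibble::tibble(ligand = "L1", receptor = "R1"))
  s0 <- summarize_map(empty)
  expect_equal(s0$classes$n_edges, rep(0L, 4))
  expect_equal(s0$classes$direction_class,
               c("BL->BL", "BL->SY", "SY->BL", "SY->SY"))

  pairs <- generate_lr_database(20, 20, 150, seed = 8)
  cb <- random_classification("BL", pairs, 9, 9, seed = 51)$classification
  cs <- random_classification("SY", pairs, 9, 9, seed = 52)$classification
  map <- build_communication_map(cb, cs, pairs)
  sm <- summarize_map(map)
  expect_equal(sum(sm$classes$n_edges), nrow(map))
  for (cl in sm$classes$direction_class) {
    expect_equal(sm$classes$n_edges[sm$classes$direction_class == cl],
                 sum(map$direction_class == cl))
  }
  # brute-force degree tallies
  for (i in seq_len(nrow(sm$degrees))) {
    row <- sm$degrees[i, ]
    expected <- if (row$role == "ligand") {
      sum(map$source_tissue == row$tissue & map$ligand == row$gene)
    } else {
      sum(map$target_tissue == row$tissue & map$receptor == row$gene)
    }
    expect_equal(row$degree, expected)
  }
})

test_that("ligand_hubs ranks by induced-subgraph degree", {
  # star: IL6 connected to three other ligands
  edges <- tibble::tibble(from = c("IL6", "IL6", "IL6"),
                          to = c("IL1B", "TNF", "IL23A"))
  hubs <- ligand_hubs(c("IL6", "IL1B", "TNF", "IL23A"), edges)
  expect_equal(hubs$gene[1], "IL6")
  expect_equal(hubs$degree[1], 3)
  expect_equal(sort(hubs$degree), c(1, 1, 1, 3))
  expect_length(unique(hubs$component), 1)

  # no edges: all degree 0, singleton components
  none <- ligand_hubs(c("A", "B"), tibble::tibble(from = character(),
                                                  to = character()))
  expect_equal(none$degree, c(0L, 0L))
  expect_length(unique(none$component), 2)

  # edges to genes outside the ligand set do not count
  mixed <- ligand_hubs("IL6", edges)
  expect_equal(mixed$degree, 0L)

  # random graph: degrees equal brute-force adjacency counts
  ligs <- sprintf("L%02d", 1:50)
  redges <- withr::with_seed(61, tibble::tibble(
    from = sample(ligs, 200, TRUE), to = sample(ligs, 200, TRUE)))
  hub <- ligand_hubs(ligs, redges)
  simple <- unique(tibble::tibble(a = pmin(redges$from, redges$to),
                                  b = pmax(redges$from, redges$to)))
  simple <- simple[simple$a != simple$b, ]
  for (g in ligs) {
    expect_equal(hub$degree[hub$gene == g],
                 sum(simple$a == g) + sum(simple$b == g))
  }
})
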