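toy_og_file <- function() {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c(
    "Orthogroup\tspA\tspB\tspC",
    "OG0001\tspA_g1, spA_g2\tspB_g1\t",
    "OG0002\tspA_g3\t\tspC_g1"
  ), path)
  path
}

test_that("orthogroup tables parse, round-trip, and reject duplicate genes", {
  tbl <- read_orthogroups(toy_og_file())
  expect_equal(dplyr::n_distinct(tbl$orthogroup), 2)
  expect_equal(sort(tbl$gene_id[tbl$orthogroup == "OG0001"]),
               c("spA_g1", "spA_g2", "spB_g1"))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_orthogroups(tbl, out)
  back <- read_orthogroups(out)
  expect_equal(dplyr::arrange(back, orthogroup, species, gene_id),
               dplyr::arrange(tbl, orthogroup, species, gene_id))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Orthogroup\tspA", "OG1\tgX", "OG2\tgX"), bad)
  expect_error(read_orthogroups(bad), "gX")
})

test_that("minimum-species filter keeps multi-species families and shrinks with k", {
  tbl <- read_orthogroups(toy_og_file())
  expect_setequal(unique(filter_min_species(tbl, 2)$orthogroup),
                  c("OG0001", "OG0002"))
  one_sp <- tibble::tibble(orthogroup = "OGx", species = "spA", gene_id = "spA_g9")
  tbl2 <- dplyr::bind_rows(tbl, one_sp)
  expect_false("OGx" %in% filter_min_species(tbl2, 2)$orthogroup)
  expect_equal(filter_min_species(tbl2, 1), tbl2)
  for (k in 1:3) {
    expect_true(all(filter_min_species(tbl2, k + 1)$orthogroup %in%
                      filter_min_species(tbl2, k)$orthogroup))
  }
})

test_that("phylostrata follow the most recent common ancestor on a 3-leaf tree", {
  tree <- ape::read.tree(text = "((A,B),C);")
  tbl <- tibble::tibble(
    orthogroup = c("OG1", "OG1", "OG2", "OG3", "OG3", "OG3"),
    species = c("A", "B", "A", "A", "B", "C"),
    gene_id = c("A_g1", "B_g1", "A_g2", "A_g3", "B_g2", "C_g1")
  )
  ph <- assign_phylostrata(tbl, tree, "A")
  expect_equal(ph$stratum[ph$gene_id == "A_g1"], 2L) # node (A,B), index 2 of 3
  expect_equal(ph$stratum[ph$gene_id == "A_g2"], 3L) # species-specific
  expect_equal(ph$stratum[ph$gene_id == "A_g3"], 1L) # root
  expect_equal(length(attr(ph, "lineage")), 3)
  # a gene outside every orthogroup is species-specific
  ph2 <- assign_phylostrata(tbl, tree, "A", genes = c(ph$gene_id, "A_new"))
  expect_equal(ph2$stratum[ph2$gene_id == "A_new"], 3L)
  # unknown species in the table is an error
  bad <- dplyr::bind_rows(tbl, tibble::tibble(
    orthogroup = "OG4", species = "Z", gene_id = "Z_g1"))
  expect_error(assign_phylostrata(bad, tree, "A"), "Z")
})

test_that("gains are counted at origin nodes and partition the families", {
  tree <- ape::read.tree(text = "((A,B),C);")
  tbl <- tibble::tibble(
    orthogroup = c("OG1", "OG1", "OG2", "OG2"),
    species = c("A", "B", "A", "C"),
    gene_id = c("A_g1", "B_g1", "A_g2", "C_g2")
  )
  g <- count_gains(tbl, tree)
  ab_node <- g$node[g$n_descendant_species == 2]
  root <- g$node[g$n_descendant_species == 3]
  expect_equal(g$gains[g$node == ab_node], 1L)      # OG1 at (A,B)
  expect_equal(g$core_gains[g$node == ab_node], 1L) # both A and B present
  expect_equal(g$gains[g$node == root], 1L)         # OG2 at root
  expect_equal(g$core_gains[g$node == root], 0L)    # B absent
  expect_equal(sum(g$gains), dplyr::n_distinct(tbl$orthogroup))
})

test_that("loss-free simulations recover origin strata exactly; losses only look younger", {
  cfg <- simulation_config(seed = 4, species = c("spA", "spB", "spC", "spD"),
                           retention_prob = 1,
                           planted_modules = no_modules(),
                           planted_specific = no_specific())
  d <- simulate_dataset(cfg)
  ph <- assign_phylostrata(d$orthogroups, d$tree, "spA")
  path <- lineage <- attr(ph, "lineage")
  node_path <- ape::nodepath(d$tree, from = length(d$tree$tip.label) + 1,
                             to = match("spA", d$tree$tip.label))
  truth_idx <- match(
    d$truth$orthogroups$origin_node_id[
      match(ph$orthogroup, d$truth$orthogroups$orthogroup)],
    node_path)
  expect_equal(ph$stratum, truth_idx)
  expect_equal(sum(count_gains(d$orthogroups, d$tree)$gains),
               dplyr::n_distinct(d$orthogroups$orthogroup))

  cfg_loss <- simulation_config(seed = 4, species = c("spA", "spB", "spC", "spD"),
                                retention_prob = 0.6,
                                planted_modules = no_modules(),
                                planted_specific = no_specific())
  dl <- simulate_dataset(cfg_loss)
  phl <- assign_phylostrata(dl$orthogroups, dl$tree, "spA")
  truth_l <- match(
    dl$truth$orthogroups$origin_node_id[
      match(phl$orthogroup, dl$truth$orthogroups$orthogroup)],
    node_path)
  expect_true(all(phl$stratum >= truth_l, na.rm = TRUE))
  # stratum indices form a contiguous range bounded by the lineage length
  expect_true(all(phl$stratum %in% seq_along(lineage)))
})
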