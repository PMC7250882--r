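# orthogroup table in which spA gene i and spB gene i share orthogroup i
paired_table <- function(n = 10) {
  tibble::tibble(
    orthogroup = rep(sprintf("o%02d", 1:n), each = 2),
    species = rep(c("spA", "spB"), n),
    gene_id = paste0(rep(c("a", "b"), n), rep(1:n, each = 2))
  )
}

test_that("modules map to collapsed orthogroup sets", {
  tbl <- tibble::tibble(
    orthogroup = c("o5", "o5", "o7"),
    species = c("spA", "spA", "spA"),
    gene_id = c("g1", "g2", "g3")
  )
  part <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g9"),
                         module = c(1L, 1L, 0L, 1L))
  expect_message(mapped <- module_to_orthogroups(part, tbl, "spA"),
                 "1 gene")
  expect_equal(mapped$orthogroup[mapped$module == 1], "o5") # collapsed
  expect_equal(mapped$orthogroup[mapped$module == 0], "o7")
  expect_error(module_to_orthogroups(part, tbl, "spX"), "spX")
})

test_that("overlap p-values agree with the enumeration oracle on a designed universe", {
  # universe of 10 shared orthogroups; K = 4, n = 5, x = 3
  tbl <- paired_table(10)
  part_a <- tibble::tibble(gene_id = paste0("a", 1:10),
                           module = c(rep(1L, 4), rep(0L, 6)))
  part_b <- tibble::tibble(gene_id = paste0("b", 1:10),
                           module = c(rep(1L, 3), 0L, 1L, 1L, rep(0L, 4)))
  ov <- overlap_matrix(part_a, part_b, tbl, "spA", "spB")
  expect_equal(ov$N, 10)
  expect_equal(ov$K, 4)
  expect_equal(ov$n, 5)
  expect_equal(ov$x, 3)
  expect_equal(ov$p_raw, enum_hyper_upper(3, 10, 4, 5), tolerance = 1e-10)
  expect_equal(ov$p_raw, 66 / 252, tolerance = 1e-10)
  expect_setequal(ov$shared[[1]], c("o01", "o02", "o03"))
})

test_that("disjoint modules give p = 1 and species swap transposes the result", {
  tbl <- paired_table(12)
  part_a <- tibble::tibble(gene_id = paste0("a", 1:12),
                           module = rep(c(1L, 2L, 0L), each = 4))
  part_b <- tibble::tibble(gene_id = paste0("b", 1:12),
                           module = rep(c(2L, 1L, 0L), each = 4))
  ov <- overlap_matrix(part_a, part_b, tbl, "spA", "spB")
  cross <- ov[ov$module_a == 1 & ov$module_b == 2, ]
  expect_equal(cross$x, 4)
  same <- ov[ov$module_a == 1 & ov$module_b == 1, ]
  expect_equal(same$x, 0)
  expect_equal(same$p_raw, 1)
  swapped <- overlap_matrix(part_b, part_a, tbl, "spB", "spA")
  expect_equal(as.matrix(swapped, "p_raw"),
               t(as.matrix(ov, "p_raw")), ignore_attr = TRUE)
  expect_equal(as.matrix(swapped, "x"),
               t(as.matrix(ov, "x")), ignore_attr = TRUE)
})

test_that("requested adjustment adds a BH column never below the raw p", {
  tbl <- paired_table(12)
  part_a <- tibble::tibble(gene_id = paste0("a", 1:12),
                           module = rep(c(1L, 2L), each = 6))
  part_b <- tibble::tibble(gene_id = paste0("b", 1:12),
                           module = rep(c(1L, 2L), 6))
  ov <- overlap_matrix(part_a, part_b, tbl, "spA", "spB", adjust = TRUE)
  expect_true(all(ov$p_bh >= ov$p_raw - 1e-12))
})

test_that("conserved core expands shared families back to member genes", {
  core <- conserved_core(c("o1", "o2", "o3"), c("o2", "o3", "o4"),
                         tibble::tibble(
                           orthogroup = c("o2", "o2", "o3", "o3", "o3", "o4"),
                           species = c("spA", "spB", "spA", "spA", "spB", "spB"),
                           gene_id = c("a2", "b2", "a3", "a3b", "b3", "b4")
                         ))
  expect_equal(core$orthogroups, c("o2", "o3"))
  # the o3 family expanded in spA: gene counts per species may differ
  counts <- table(core$genes$species)
  expect_equal(unname(counts[["spA"]]), 3)
  expect_equal(unname(counts[["spB"]]), 2)
  expect_true(all(counts >= length(core$orthogroups)))
})

test_that("planted module pairs dominate the cross-species overlap matrix", {
  for (s in 1:2) {
    d <- simulate_dataset(small_config(seed = s))
    parts <- lapply(c("spA", "spB"), function(sp) {
      cr <- compute_crpkm(d$expression[[sp]], d$lengths[[sp]])
      detect_modules(tom_similarity(adjacency(cr, beta = 6)), species = sp)
    })
    names(parts) <- c("spA", "spB")
    og <- filter_min_species(d$orthogroups, 2)
    ov <- suppressMessages(
      overlap_matrix(parts$spA, parts$spB, og, "spA", "spB"))
    pm <- as.matrix(ov, "p_raw")
    truth <- d$truth$genes
    detected_label <- function(sp, planted) {
      tg <- dplyr::filter(truth, species == sp, module == planted)
      j <- dplyr::inner_join(tg, parts[[sp]], by = "gene_id")
      j <- dplyr::filter(j, module.y != 0)
      tab <- table(j$module.y)
      as.integer(names(tab)[which.max(tab)])
    }
    for (mm in unique(na.omit(truth$module))) {
      la <- detected_label("spA", mm)
      lb <- detected_label("spB", mm)
      p <- pm[paste0("A", la), paste0("B", lb)]
      expect_lt(p, 1e-6)
      expect_equal(p, min(pm[paste0("A", la), ]))
      expect_equal(p, min(pm[, paste0("B", lb)]))
    }
  }
})
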