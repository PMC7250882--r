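test_that("tau evaluates the index formula with its boundary cases", {
  expect_equal(tau(c(10, 5, 0, 0)), 2.5 / 3, tolerance = 1e-12)
  expect_equal(tau(c(5, 5, 5, 5)), 0)
  expect_equal(tau(c(0, 0, 0, 7)), 1)
  expect_true(is.na(tau(c(0, 0, 0))))
  expect_error(tau(5), "two conditions")
  expect_error(tau(c(-1, 2)), "non-negative")
})

test_that("tau is scale-invariant and rises under specialization", {
  set.seed(21)
  for (rep in 1:300) {
    n <- sample(3:12, 1)
    x <- rexp(n) * 10
    t0 <- tau(x)
    expect_gte(t0, 0)
    expect_lte(t0, 1)
    expect_equal(tau(x * runif(1, 0.01, 100)), t0, tolerance = 1e-10)
    # zeroing a non-max coordinate never decreases tau
    i <- sample(setdiff(seq_len(n), which.max(x)), 1)
    x2 <- x
    x2[i] <- 0
    expect_gte(tau(x2) + 1e-12, t0)
  }
})

test_that("tau tables flag specific genes with their top condition", {
  m <- rbind(c(10, 5, 0, 0), c(5, 5, 5, 5), c(0, 0, 0, 7), c(0, 0, 0, 0))
  x <- expr_mat(m, samples = c("head", "gill", "gut", "ovary"))
  tt <- tau_table(x, threshold = 0.8)
  expect_equal(tt$tau, c(2.5 / 3, 0, 1, NA), tolerance = 1e-12)
  expect_equal(tt$top_condition, c("head", "head", "ovary", "head"))
  expect_equal(tt$specific, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(specific_genes(x)$gene_id, c("g001", "g003"))
  # threshold 1 keeps nothing (tau > 1 impossible)
  expect_equal(nrow(specific_genes(x, threshold = 1)), 0)
})

test_that("planted tissue-specific genes score tau above threshold across seeds", {
  for (s in 1:2) {
    d <- simulate_dataset(small_config(seed = s))
    truth <- dplyr::filter(d$truth$genes, species == "spA",
                           !is.na(specific_tissue))
    cr <- compute_crpkm(d$expression$spA, d$lengths$spA)
    av <- average_replicates(cr, d$metadata)
    tt <- tau_table(av)
    planted_tau <- tt$tau[match(truth$gene_id, tt$gene_id)]
    expect_gte(mean(planted_tau > 0.8, na.rm = TRUE), 0.95)
    # their top condition is the planted tissue
    expect_true(all(tt$top_condition[match(truth$gene_id, tt$gene_id)] ==
                      truth$specific_tissue))
  }
})

test_that("the shared-tissue filter applies the documented pass rule", {
  m <- rbind(
    c(50, 40, 10, 5),  # passes: second = gill, others <= 0.7 * 40 = 28
    c(50, 40, 30, 5),  # fails: gut 30 > 28
    c(15, 12, 1, 1)    # fails: test minimum 12 < 20
  )
  x <- expr_mat(m, samples = c("wing_pad", "gill", "gut", "brain"))
  res <- shared_tissue_genes(x, focal = "wing_pad", min_expr = 20,
                             margin = 0.30)
  expect_equal(res$genes$pass, c(TRUE, FALSE, FALSE))
  expect_equal(res$genes$second_condition[1], "gill")
  expect_equal(res$genes$test_min[1], 40)
  expect_equal(res$counts$second_condition, "gill")
  expect_equal(res$counts$n_genes, 1L)
  expect_equal(sum(res$counts$n_genes), sum(res$genes$pass))
  expect_error(shared_tissue_genes(x, focal = "leg"), "leg")
})

test_that("the shared-tissue gene set shrinks as thresholds tighten", {
  set.seed(22)
  m <- matrix(rexp(200 * 6, rate = 1 / 30), 200, 6)
  x <- expr_mat(m, samples = c("wing_pad", "gill", "gut", "brain",
                               "muscle", "ovary"))
  base <- shared_tissue_genes(x, min_expr = 10, margin = 0.2)
  harder_expr <- shared_tissue_genes(x, min_expr = 30, margin = 0.2)
  harder_marg <- shared_tissue_genes(x, min_expr = 10, margin = 0.5)
  pass_ids <- function(r) r$genes$gene_id[r$genes$pass]
  expect_true(all(pass_ids(harder_expr) %in% pass_ids(base)))
  expect_true(all(pass_ids(harder_marg) %in% pass_ids(base)))
})

test_that("term enrichment reduces to the exact Fisher test", {
  background <- paste0("g", 1:8)
  subset <- paste0("g", 1:4)
  terms <- list(t1 = c("g1", "g2", "g3", "g5"), all = background)
  res <- enrich_terms(subset, background, terms)
  # t1 realizes the (3,1;1,3) table
  expect_equal(res$p[res$term == "t1"], 34 / 70, tolerance = 1e-10)
  expect_equal(res$overlap[res$term == "t1"], 3)
  expect_equal(res$p[res$term == "all"], 1)
  expect_error(enrich_terms(c("g1", "zz"), background, terms), "outside")
  # random small instances against the enumeration oracle
  set.seed(23)
  for (rep in 1:20) {
    bg <- paste0("g", 1:20)
    ss <- sample(bg, 7)
    tm <- list(t = sample(bg, 9))
    r <- enrich_terms(ss, bg, tm)
    a <- length(intersect(ss, tm$t))
    expect_equal(r$p, enum_fisher_two_sided(a, 7 - a, 9 - a, 20 - 9 - (7 - a)),
                 tolerance = 1e-10)
  }
})

test_that("phylostratum enrichment matches the term encoding and identity case", {
  assignment <- tibble::tibble(
    gene_id = paste0("g", 1:12),
    stratum = rep(1:3, each = 4),
    node_label = rep(c("root", "clade", "species"), each = 4)
  )
  background <- assignment$gene_id
  # subset drawn entirely from stratum 2 attains its minimum p there
  subset <- paste0("g", 5:8)
  res <- enrich_phylostrata(subset, background, assignment)
  expect_equal(res$stratum[which.min(res$p)], 2L)
  # identical subset and background: all tables are marginal, p = 1
  res_id <- enrich_phylostrata(background, background, assignment)
  expect_true(all(res_id$p == 1))
  # agrees with enrich_terms when strata are encoded as terms
  sets <- split(assignment$gene_id, assignment$stratum)
  via_terms <- enrich_terms(subset, background, sets)
  expect_equal(sort(res$p), sort(via_terms$p), tolerance = 1e-12)
  expect_error(enrich_phylostrata(c(subset, "gX"), background, assignment),
               "without a phylostratum")
})

test_that("GMT files round-trip and malformed lines are reported", {
  sets <- list(mod1 = c("g1", "g2"), mod2 = c("g3", "g4", "g5"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path, descriptions = c("first", "second"))
  lines <- readLines(path)
  expect_true(all(lengths(strsplit(lines, "\t")) >= 3))
  back <- read_gmt(path)
  expect_equal(back[["mod1"]], sets$mod1)
  expect_equal(back[["mod2"]], sets$mod2)
  expect_equal(attr(back, "descriptions")[["mod1"]], "first")
  # independent reader agrees on the same file
  ref <- fgsea::gmtPathways(path)
  expect_equal(ref[["mod2"]], sets$mod2)
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("only_name\tdesc", bad)
  expect_error(read_gmt(bad), "3 tab-separated")
})
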