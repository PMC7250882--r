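test_that("expression TSVs round-trip and malformed input is rejected", {
  m <- matrix(c(1, 2, 3, 4), 2, 2)
  x <- expr_mat(m, unit = "counts", samples = c("gill.1", "gill.2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(x, path)
  back <- read_expression_tsv(path, unit = "counts")
  expect_equal(back$expression$gene_id, x$gene_id)
  expect_equal(expression_values(back$expression), expression_values(x))
  expect_equal(back$metadata$condition, c("gill", "gill"))
  expect_equal(back$metadata$replicate, 1:2)

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), dup)
  expect_error(read_expression_tsv(dup), "duplicate gene")
  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t-2"), neg)
  expect_error(read_expression_tsv(neg), "negative")
})

test_that("cRPKM normalization evaluates the formula and is depth-invariant", {
  # count 100, length 1 kb, sample total 1e6 -> exactly 100
  m <- matrix(c(100, 999900), 2, 1)
  x <- expr_mat(m, unit = "counts")
  lens <- tibble::tibble(gene_id = c("g001", "g002"), length_kb = c(1, 10))
  out <- compute_crpkm(x, lens)
  expect_equal(expression_values(out)["g001", 1], 100)
  # zero counts stay zero regardless of length
  m0 <- matrix(c(0, 10), 2, 1)
  out0 <- compute_crpkm(expr_mat(m0, unit = "counts"), lens)
  expect_equal(expression_values(out0)["g001", 1], 0)
  # doubling a sample's counts leaves its cRPKM unchanged
  set.seed(1)
  mm <- matrix(rpois(40, 50) + 1, 10, 4)
  xx <- expr_mat(mm, unit = "counts")
  ll <- tibble::tibble(gene_id = xx$gene_id, length_kb = runif(10, 0.5, 3))
  doubled <- expr_mat(sweep(mm, 2, c(2, 1, 1, 1), "*"), unit = "counts")
  expect_equal(expression_values(compute_crpkm(xx, ll)),
               expression_values(compute_crpkm(doubled, ll)))
  # errors
  expect_error(compute_crpkm(xx, ll[-1, ]), "no effective length")
  z <- expr_mat(matrix(0, 2, 1), unit = "counts")
  expect_error(compute_crpkm(z, tibble::tibble(gene_id = z$gene_id, length_kb = 1)),
               "zero total")
})

test_that("replicate averaging means within conditions and keeps condition order", {
  m <- matrix(c(1, 3, 10, 20), 1, 4)
  x <- expr_mat(m, unit = "crpkm",
                samples = c("gill.1", "gill.2", "wing.1", "wing.2"))
  meta <- parse_sample_metadata(c("gill.1", "gill.2", "wing.1", "wing.2"))
  out <- average_replicates(x, meta)
  expect_equal(names(out)[-1], c("gill", "wing"))
  expect_equal(unname(expression_values(out)[1, ]), c(2, 15))
  # single replicate is the identity
  one <- expr_mat(matrix(c(5, 7), 1, 2), unit = "crpkm",
                  samples = c("a.1", "b.1"))
  avg1 <- average_replicates(one, parse_sample_metadata(c("a.1", "b.1")))
  expect_equal(unname(expression_values(avg1)[1, ]), c(5, 7))
})

test_that("coefficient-of-variation filter uses the n-1 sd and is monotone", {
  m <- rbind(c(2, 2, 2), c(0, 0, 10), c(1, 2, 3))
  x <- expr_mat(m, unit = "crpkm")
  kept <- filter_by_cv(x, min_cv = 1)
  expect_equal(kept$gene_id, "g002") # cv = 5.7735/3.3333 = 1.732
  expect_equal(stats::sd(c(0, 0, 10)) / mean(c(0, 0, 10)), sqrt(3),
               tolerance = 1e-12)
  all_kept <- filter_by_cv(x, min_cv = 0)
  expect_setequal(all_kept$gene_id, c("g001", "g002", "g003"))
  # threshold monotonicity on random data
  set.seed(2)
  r <- expr_mat(matrix(rexp(200), 40, 5))
  g1 <- filter_by_cv(r, 0.3)$gene_id
  g2 <- filter_by_cv(r, 0.8)$gene_id
  expect_true(all(g2 %in% g1))
})

test_that("standardization centres, scales, drops flat rows, and is idempotent", {
  x <- expr_mat(rbind(c(1, 2, 3), c(4, 4, 4)), unit = "crpkm")
  expect_warning(out <- standardize_genes(x), "constant")
  expect_equal(out$gene_id, "g001")
  expect_equal(unname(expression_values(out)[1, ]), c(-1, 0, 1))
  set.seed(3)
  r <- expr_mat(matrix(rnorm(60, 5), 12, 5))
  s1 <- standardize_genes(r)
  expect_true(all(abs(rowMeans(expression_values(s1))) < 1e-12))
  expect_true(all(abs(apply(expression_values(s1), 1, sd) - 1) < 1e-12))
  s2 <- standardize_genes(s1)
  expect_equal(expression_values(s2), expression_values(s1), tolerance = 1e-10)
})

test_that("sample clustering pairs correlated samples and merges duplicates at height zero", {
  # s1 and s2 nearly collinear, s3 unrelated: average linkage on the 3x3
  # 1 - r matrix must join s1, s2 first
  set.seed(4)
  base <- rnorm(50, 10, 3)
  m <- cbind(s1 = base, s2 = base + rnorm(50, 0, 0.3), s3 = rnorm(50, 10, 3))
  m <- pmax(m, 0)
  x <- expr_mat(m, samples = colnames(m))
  tree <- cluster_samples(x)
  expect_true(are_siblings(tree, "s1", "s2"))
  expect_false(are_siblings(tree, "s1", "s3"))
  # duplicated columns merge at height 0
  dupm <- cbind(a = base, b = base, c = rev(base))
  tr2 <- cluster_samples(expr_mat(pmax(dupm, 0), samples = colnames(dupm)))
  hc <- attr(tr2, "hclust")
  expect_equal(min(hc$height), 0, tolerance = 1e-12)
  expect_true(are_siblings(tr2, "a", "b"))
  # zero-variance sample is named in the error
  flat <- cbind(u = base, v = rep(2, 50), w = rev(base))
  expect_error(cluster_samples(expr_mat(pmax(flat, 0), samples = colnames(flat))),
               "v")
})
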