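#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# An expression table is a tibble whose first column is `gene_id` and whose
# remaining columns are numeric sample values, carrying a `unit` attribute
# ("counts", "crpkm" or "standardized"). Sample metadata travels separately
# as a tibble with columns sample / condition / replicate.

#' Build an expression table from a matrix
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param unit Unit tag: `"counts"`, `"crpkm"` or `"standardized"`.
#' @return A tibble with a `gene_id` column followed by one numeric column
#'   per sample, with a `unit` attribute.
#' @export
expression_table <- function(values, unit = c("counts", "crpkm", "standardized")) {
  unit <- match.arg(unit)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  out <- tibble::as_tibble(values, rownames = "gene_id")
  set_unit(validate_expression(out, unit = unit), unit)
}

set_unit <- function(x, unit) {
  attr(x, "unit") <- unit
  x
}

#' Unit tag of an expression table
#' @param x An expression table.
#' @return `"counts"`, `"crpkm"`, `"standardized"`, or `NA` if untagged.
#' @export
expression_unit <- function(x) {
  u <- attr(x, "unit", exact = TRUE)
  if (is.null(u)) NA_character_ else u
}

#' Expression values as a numeric matrix
#' @param x An expression table (first column `gene_id`).
#' @return Numeric matrix with gene ids as rownames.
#' @export
expression_values <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene_id
  m
}

validate_expression <- function(x, unit = expression_unit(x)) {
  if (!is.data.frame(x) || ncol(x) < 2) {
    stop("expression table must have a gene_id column plus at least one sample")
  }
  if (names(x)[1] != "gene_id") {
    names(x)[1] <- "gene_id"
  }
  if (anyDuplicated(x$gene_id)) {
    dup <- unique(x$gene_id[duplicated(x$gene_id)])
    stop("duplicate gene identifier(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (anyDuplicated(names(x))) {
    stop("duplicate sample identifier(s): ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  }
  num <- vapply(x[-1], is.numeric, logical(1))
  if (!all(num)) {
    stop("non-numeric sample column(s): ", paste(names(x)[-1][!num], collapse = ", "))
  }
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (anyNA(vals)) stop("expression table contains missing values")
  if (!identical(unit, "standardized") && any(vals < 0)) {
    bad <- x$gene_id[which(rowSums(vals < 0) > 0)[1]]
    stop("negative expression value (first offending gene: ", bad, ")")
  }
  tibble::as_tibble(x)
}

#' Parse sample metadata from `condition.replicate` sample names
#'
#' Sample names of the form `gill.1`, `gill.2`, `wing_pad.1` are split at the
#' final dot into a condition label and a replicate index; names without a
#' dot become single-replicate conditions.
#'
#' @param samples Character vector of sample names.
#' @return Tibble with columns `sample`, `condition`, `replicate`.
#' @export
parse_sample_metadata <- function(samples) {
  has_rep <- grepl("\\.[0-9]+$", samples)
  condition <- ifelse(has_rep, sub("\\.[0-9]+$", "", samples), samples)
  replicate <- ifelse(has_rep, as.integer(sub("^.*\\.", "", samples)), 1L)
  tibble(sample = samples, condition = condition, replicate = as.integer(replicate))
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample names and gene identifiers in the first
#' column. Condition labels come from a sidecar metadata TSV (columns
#' `sample`, `condition`, `replicate`) when given, otherwise from the
#' `condition.replicate` sample-name convention.
#'
#' @param path Path to the expression TSV.
#' @param metadata Optional path to a metadata TSV.
#' @param unit Unit tag to attach (`"counts"` or `"crpkm"`).
#' @return List with elements `expression` (tibble) and `metadata` (tibble).
#' @export
read_expression_tsv <- function(path, metadata = NULL, unit = "counts") {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    stop("malformed expression TSV ", path, ": ", probs$expected[1],
         " at line ", probs$row[1])
  }
  x <- validate_expression(as.data.frame(x), unit = unit)
  x <- set_unit(x, unit)
  meta <- if (!is.null(metadata)) {
    m <- readr::read_tsv(metadata, show_col_types = FALSE, progress = FALSE)
    stopifnot(all(c("sample", "condition", "replicate") %in% names(m)))
    m$replicate <- as.integer(m$replicate)
    missing <- setdiff(names(x)[-1], m$sample)
    if (length(missing) > 0) {
      stop("metadata lacks sample(s): ", paste(missing, collapse = ", "))
    }
    tibble::as_tibble(m[match(names(x)[-1], m$sample), c("sample", "condition", "replicate")])
  } else {
    parse_sample_metadata(names(x)[-1])
  }
  list(expression = x, metadata = meta)
}

#' Write an expression table to TSV
#' @param x Expression table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Mappability-corrected RPKM
#'
#' Converts raw counts to cRPKM: reads per kilobase of uniquely mappable
#' positions per million mapped reads,
#' \deqn{cRPKM_{gs} = \frac{count_{gs}}{\ell_g \cdot M_s / 10^6}}
#' where \eqn{\ell_g} is the gene's effective (uniquely mappable) length in
#' kilobases and \eqn{M_s} is the sample's mapped-read total, taken as the
#' column sum of the count matrix so the computation is self-contained.
#'
#' @param x Count expression table (unit `"counts"`).
#' @param lengths Tibble with columns `gene_id` and `length_kb` (> 0),
#'   covering every gene in `x`.
#' @return Expression table in cRPKM units.
#' @examples
#' m <- matrix(c(100, 999900), 2, 1, dimnames = list(c("g1", "g2"), "s.1"))
#' x <- expression_table(m, unit = "counts")
#' lens <- tibble::tibble(gene_id = c("g1", "g2"), length_kb = c(1, 10))
#' compute_crpkm(x, lens) # g1 -> 100
#' @export
compute_crpkm <- function(x, lengths) {
  x <- validate_expression(x)
  if (!identical(expression_unit(x), "counts") && !is.na(expression_unit(x))) {
    stop("compute_crpkm expects a count matrix (unit \"counts\")")
  }
  missing <- setdiff(x$gene_id, lengths$gene_id)
  if (length(missing) > 0) {
    stop("no effective length for gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  len <- lengths$length_kb[match(x$gene_id, lengths$gene_id)]
  if (any(len <= 0)) stop("effective lengths must be positive")
  vals <- expression_values(x)
  mapped <- colSums(vals)
  if (any(mapped == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(vals)[mapped == 0], collapse = ", "))
  }
  out <- sweep(vals / len, 2, mapped / 1e6, "/")
  expression_table(out, unit = "crpkm")
}

#' Average replicates into one column per condition
#'
#' @param x Expression table.
#' @param metadata Sample metadata tibble (`sample`, `condition`,
#'   `replicate`); output columns follow the order in which conditions first
#'   appear here.
#' @return Expression table with one column per condition (arithmetic mean
#'   of its replicates); the unit tag is preserved.
#' @export
average_replicates <- function(x, metadata) {
  x <- validate_expression(x)
  unit <- expression_unit(x)
  samples <- names(x)[-1]
  missing <- setdiff(samples, metadata$sample)
  if (length(missing) > 0) {
    stop("metadata lacks sample(s): ", paste(missing, collapse = ", "))
  }
  cond <- metadata$condition[match(samples, metadata$sample)]
  conds <- unique(metadata$condition[metadata$sample %in% samples])
  vals <- expression_values(x)
  out <- vapply(conds, function(cc) {
    rowMeans(vals[, cond == cc, drop = FALSE])
  }, numeric(nrow(vals)))
  if (nrow(vals) == 1) out <- matrix(out, nrow = 1, dimnames = list(rownames(vals), conds))
  colnames(out) <- conds
  expression_table(out, unit = if (is.na(unit)) "crpkm" else unit)
}

#' Filter genes by coefficient of variation
#'
#' Retains genes whose coefficient of variation across samples (sample
#' standard deviation with the n-1 denominator, divided by the mean) is at
#' least `min_cv`. Genes with zero mean are always removed.
#'
#' @param x Expression table with at least two sample columns.
#' @param min_cv Minimum coefficient of variation (default 1).
#' @return Filtered expression table (unit preserved).
#' @export
filter_by_cv <- function(x, min_cv = 1) {
  x <- validate_expression(x)
  vals <- expression_values(x)
  if (ncol(vals) < 2) stop("filter_by_cv needs at least two samples")
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1, stats::sd)
  keep <- mu > 0 & sdv / mu >= min_cv
  set_unit(x[keep, , drop = FALSE], expression_unit(x))
}

#' Standardize gene profiles to mean zero, unit variance
#'
#' Each gene row is centred and scaled using the n-1 standard deviation.
#' Rows with zero variance carry no profile shape and are dropped with a
#' warning naming how many were removed.
#'
#' @param x Expression table with at least two sample columns.
#' @return Expression table with unit `"standardized"`.
#' @export
standardize_genes <- function(x) {
  x <- validate_expression(x)
  vals <- expression_values(x)
  if (ncol(vals) < 2) stop("standardize_genes needs at least two columns")
  sdv <- apply(vals, 1, stats::sd)
  flat <- sdv == 0
  if (any(flat)) {
    warning(sum(flat), " constant gene profile(s) dropped during standardization")
    vals <- vals[!flat, , drop = FALSE]
    sdv <- sdv[!flat]
  }
  if (nrow(vals) == 0) stop("no gene with non-zero variance to standardize")
  out <- (vals - rowMeans(vals)) / sdv
  expression_table(out, unit = "standardized")
}

#' Hierarchical clustering of samples
#'
#' Clusters sample columns with average linkage on the distance
#' 1 - Pearson correlation, by default after a log10(x + 1) variance-
#' stabilizing transform. Used to ask which tissues or stages share
#' transcriptomic programmes (e.g. whether wing pads and gills are nearest
#' neighbours).
#'
#' @param x Expression table with at least three sample columns.
#' @param log_transform Apply log10(x + 1) before correlating (default TRUE;
#'   set FALSE for already-standardized input).
#' @return An [ape::as.phylo()] tree over the sample labels, with the
#'   underlying `hclust` object attached as attribute `"hclust"`.
#' @export
cluster_samples <- function(x, log_transform = TRUE) {
  x <- validate_expression(x)
  vals <- expression_values(x)
  if (ncol(vals) < 3) stop("cluster_samples needs at least three samples")
  if (log_transform) vals <- log10(vals + 1)
  sdv <- apply(vals, 2, stats::sd)
  if (any(sdv == 0)) {
    stop("zero-variance sample(s): ", paste(colnames(vals)[sdv == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(vals))
  hc <- stats::hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  attr(phy, "hclust") <- hc
  phy
}

#' Are two samples siblings in a sample dendrogram?
#'
#' TRUE when the two labels are joined directly by a single merge, i.e. they
#' are each other's closest relatives in the tree.
#'
#' @param tree Tree returned by [cluster_samples()].
#' @param a,b Sample labels.
#' @return Logical scalar.
#' @export
are_siblings <- function(tree, a, b) {
  hc <- attr(tree, "hclust", exact = TRUE)
  if (is.null(hc)) {
    tips <- match(c(a, b), tree$tip.label)
    if (anyNA(tips)) stop("sample label(s) not in tree")
    mrca <- ape::getMRCA(tree, tips)
    kids <- tree$edge[tree$edge[, 1] == mrca, 2]
    return(all(tips %in% kids))
  }
  ia <- match(a, hc$labels)
  ib <- match(b, hc$labels)
  if (anyNA(c(ia, ib))) stop("sample label(s) not in tree")
  any(apply(hc$merge, 1, function(r) setequal(r, c(-ia, -ib))))
}
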