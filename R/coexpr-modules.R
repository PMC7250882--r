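#' Weighted co-expression adjacency
#'
#' Builds the soft-thresholded gene-gene adjacency of a weighted
#' co-expression network from Pearson correlations across samples:
#' unsigned \eqn{a_{ij} = |cor(x_i, x_j)|^\beta}, signed
#' \eqn{a_{ij} = ((1 + cor)/2)^\beta}. Raising to the power \eqn{\beta}
#' suppresses weak correlations and pushes the connectivity distribution
#' toward scale-free topology.
#'
#' @param x Expression table (genes kept should have non-zero variance) with
#'   at least four sample columns, or a numeric matrix.
#' @param beta Soft-threshold power, > 0 (default 6).
#' @param signed Use the signed transform (default FALSE).
#' @return An object of class `coexpr_graph`: list with `adjacency`
#'   (symmetric, zero diagonal), `beta`, `signed`, `genes`, and `tom`
#'   (NULL until [tom_similarity()] is called).
#' @export
adjacency <- function(x, beta = 6, signed = FALSE) {
  if (beta <= 0) stop("adjacency: beta must be positive")
  X <- if (is.matrix(x)) x else expression_values(validate_expression(x))
  if (ncol(X) < 4) stop("adjacency: need at least four samples")
  sdv <- apply(X, 1, stats::sd)
  if (any(sdv == 0)) {
    stop("adjacency: zero-variance gene(s): ",
         paste(utils::head(rownames(X)[sdv == 0], 5), collapse = ", "))
  }
  r <- stats::cor(t(X))
  a <- if (signed) ((1 + r) / 2)^beta else abs(r)^beta
  diag(a) <- 0
  structure(
    list(adjacency = a, beta = beta, signed = signed,
         genes = rownames(X), tom = NULL),
    class = "coexpr_graph"
  )
}

#' @export
print.coexpr_graph <- function(x, ...) {
  cat("Co-expression graph:", length(x$genes), "genes, beta =", x$beta,
      if (x$signed) "(signed)" else "(unsigned)",
      if (is.null(x$tom)) "" else "[TOM computed]", "\n")
  invisible(x)
}

#' Connectivity of every gene
#' @param graph A `coexpr_graph`.
#' @return Named numeric vector \eqn{k_i = \sum_{u \ne i} a_{iu}}.
#' @export
connectivity <- function(graph) {
  stopifnot(inherits(graph, "coexpr_graph"))
  rowSums(graph$adjacency)
}

#' Scale-free topology fit index
#'
#' Regresses log10 connectivity frequency on log10 mean connectivity over
#' `n_bins` equal-width bins and returns the squared correlation — the usual
#' advisory statistic for choosing the soft-threshold power (values near 1
#' indicate an approximately power-law degree distribution).
#'
#' @param graph A `coexpr_graph` with at least 20 genes.
#' @param n_bins Number of connectivity bins (default 10).
#' @return R-squared in \[0, 1\].
#' @export
scale_free_fit <- function(graph, n_bins = 10) {
  stopifnot(inherits(graph, "coexpr_graph"))
  k <- connectivity(graph)
  if (length(k) < 20) stop("scale_free_fit: need at least 20 genes")
  if (diff(range(k)) < .Machine$double.eps) {
    stop("scale_free_fit: all connectivities equal; fit undefined")
  }
  bins <- cut(k, breaks = n_bins, include.lowest = TRUE)
  freq <- tapply(k, bins, length)
  mean_k <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0 & mean_k > 0
  if (sum(keep) < 3) stop("scale_free_fit: too few occupied bins")
  stats::cor(log10(freq[keep]), log10(mean_k[keep]))^2
}

#' Topological overlap matrix
#'
#' Fills the TOM of the graph:
#' \deqn{t_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#'                     {\min(k_i, k_j) + 1 - a_{ij}}}
#' with \eqn{t_{ii} = 1}. TOM rewards shared neighbourhoods, so two genes
#' are similar when they connect to the same part of the network even if
#' their direct adjacency is modest. Degenerate zero denominators yield 0.
#'
#' @param graph A `coexpr_graph` with adjacency computed.
#' @return The same `coexpr_graph` with `tom` filled.
#' @export
tom_similarity <- function(graph) {
  stopifnot(inherits(graph, "coexpr_graph"))
  a <- graph$adjacency
  k <- rowSums(a)
  # zero diagonal makes (A^2)_ij exactly the shared-neighbour sum over u != i, j
  L <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  t <- (L + a) / denom
  t[denom <= .Machine$double.eps] <- 0
  diag(t) <- 1
  dimnames(t) <- dimnames(a)
  graph$tom <- t
  graph
}

#' Cut the co-expression network into modules
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM,
#' cut statically at `cut_height_fraction` of the maximum merge height.
#' Clusters smaller than `min_size` are left unassigned (module 0); the
#' remaining modules are renumbered 1, 2, ... by decreasing size.
#'
#' @param graph A `coexpr_graph`; the TOM is computed on the fly if absent.
#' @param cut_height_fraction Fraction of the tallest merge at which to cut
#'   (default 0.9).
#' @param min_size Minimum module size (default 10).
#' @param species Optional species tag stored on the result.
#' @return Tibble with `gene_id` and `module` (integer; 0 = unassigned),
#'   carrying the parameters used as attributes (`beta`,
#'   `cut_height_fraction`, `min_size`, `species`).
#' @export
detect_modules <- function(graph, cut_height_fraction = 0.9, min_size = 10,
                           species = NA_character_) {
  stopifnot(inherits(graph, "coexpr_graph"))
  if (is.null(graph$tom)) graph <- tom_similarity(graph)
  genes <- graph$genes
  if (length(genes) < min_size) {
    warning("fewer genes than min_size; all genes left unassigned")
    labels <- rep(0L, length(genes))
  } else {
    hc <- stats::hclust(stats::as.dist(1 - graph$tom), method = "average")
    h <- cut_height_fraction * max(hc$height)
    raw <- stats::cutree(hc, h = h)
    sizes <- table(raw)
    keep <- as.integer(names(sizes)[sizes >= min_size])
    labels <- ifelse(raw %in% keep, raw, 0L)
    if (length(keep) > 0) {
      # renumber surviving modules by decreasing size (stable on ties)
      ord <- keep[order(-sizes[as.character(keep)], keep)]
      labels <- ifelse(labels == 0L, 0L, match(labels, ord))
    }
  }
  out <- tibble(gene_id = genes, module = as.integer(labels))
  attr(out, "beta") <- graph$beta
  attr(out, "cut_height_fraction") <- cut_height_fraction
  attr(out, "min_size") <- min_size
  attr(out, "species") <- species
  out
}

#' Choose the smallest soft-threshold power with adequate scale-free fit
#'
#' Advisory helper: fits the network at each candidate power and returns the
#' smallest one whose scale-free R-squared reaches `target_r2`, or the
#' best-fitting power if none does.
#'
#' @param x Expression table or matrix.
#' @param powers Candidate powers (default 1:12).
#' @param target_r2 R-squared threshold (default 0.8).
#' @param signed Signed network flag.
#' @return Tibble with `beta`, `r_squared`, `selected`.
#' @export
pick_beta <- function(x, powers = 1:12, target_r2 = 0.8, signed = FALSE) {
  r2 <- vapply(powers, function(b) {
    g <- adjacency(x, beta = b, signed = signed)
    tryCatch(scale_free_fit(g), error = function(e) NA_real_)
  }, numeric(1))
  ok <- which(!is.na(r2) & r2 >= target_r2)
  sel <- if (length(ok) > 0) powers[ok[1]] else powers[which.max(r2)]
  tibble(beta = powers, r_squared = r2, selected = powers == sel)
}

#' Tidy a co-expression graph into an edge list
#' @param x A `coexpr_graph`.
#' @param min_adjacency Drop edges below this adjacency (default 0).
#' @param ... Unused.
#' @return Tibble with `gene_a`, `gene_b`, `adjacency`, and `tom` when
#'   available (upper triangle only).
#' @method tidy coexpr_graph
#' @export
tidy.coexpr_graph <- function(x, min_adjacency = 0, ...) {
  ut <- upper.tri(x$adjacency)
  idx <- which(ut, arr.ind = TRUE)
  out <- tibble(
    gene_a = x$genes[idx[, 1]],
    gene_b = x$genes[idx[, 2]],
    adjacency = x$adjacency[ut]
  )
  if (!is.null(x$tom)) out$tom <- x$tom[ut]
  dplyr::filter(out, .data$adjacency >= min_adjacency)
}

#' One-row summary of a co-expression graph
#' @param x A `coexpr_graph`.
#' @param ... Unused.
#' @method glance coexpr_graph
#' @export
glance.coexpr_graph <- function(x, ...) {
  k <- connectivity(x)
  tibble(
    n_genes = length(x$genes),
    beta = x$beta,
    signed = x$signed,
    mean_connectivity = mean(k),
    max_connectivity = max(k),
    has_tom = !is.null(x$tom)
  )
}
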