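#' Tau tissue-specificity index
#'
#' \deqn{\tau = \frac{\sum_i (1 - x_i / \max(x))}{n - 1}}
#' over an expression vector across n conditions. Tau is 0 for perfectly
#' uniform expression, 1 for expression restricted to a single condition,
#' and undefined (NA) for an all-zero gene. Replicates should be averaged
#' upstream; values are used untransformed.
#'
#' @param x Non-negative numeric vector over at least two conditions.
#' @return Tau in \[0, 1\], or `NA_real_` when `max(x) == 0`.
#' @examples
#' tau(c(10, 5, 0, 0)) # 2.5 / 3
#' tau(c(5, 5, 5, 5))  # 0
#' @export
tau <- function(x) {
  if (length(x) < 2) stop("tau needs at least two conditions")
  if (any(x < 0)) stop("tau is defined for non-negative expression only")
  mx <- max(x)
  if (mx == 0) return(NA_real_)
  sum(1 - x / mx) / (length(x) - 1)
}

#' Tau table for every gene of a condition-averaged matrix
#'
#' @param x Condition-averaged expression table (one column per condition).
#' @param threshold Specificity threshold on tau (default 0.8).
#' @return Tibble with `gene_id`, `tau` (NA for all-zero genes),
#'   `top_condition` (argmax condition; ties to the first column) and
#'   `specific` (`tau > threshold`; FALSE when tau is NA).
#' @export
tau_table <- function(x, threshold = 0.8) {
  x <- validate_expression(x)
  vals <- expression_values(x)
  if (ncol(vals) < 2) stop("tau_table needs at least two conditions")
  taus <- unname(apply(vals, 1, tau))
  idx <- max.col(vals, ties.method = "first")
  tibble(
    gene_id = rownames(vals),
    tau = taus,
    top_condition = colnames(vals)[idx],
    specific = !is.na(taus) & taus > threshold
  )
}

#' Tissue-specific genes by tau
#'
#' @inheritParams tau_table
#' @return The rows of [tau_table()] with `tau > threshold`.
#' @export
specific_genes <- function(x, threshold = 0.8) {
  dplyr::filter(tau_table(x, threshold), .data$specific)
}

#' Genes highly expressed in a focal tissue plus exactly one other
#'
#' The shared-tissue filter: for each gene, the *second* tissue is its
#' highest-expressed non-focal condition, and the test group is
#' \{focal, second\}. A gene passes when the test group's minimum expression
#' reaches `min_expr` and every remaining condition stays below
#' `(1 - margin)` times that minimum — i.e. the rest of the body is at
#' least `margin` lower than both test tissues. Tabulating the second
#' tissue of passing genes asks which organ shares the focal tissue's
#' programme (e.g. which tissue co-expresses wing-pad-biased genes).
#'
#' @param x Condition-averaged cRPKM expression table containing `focal`.
#' @param focal Focal condition label (default `"wing_pad"`).
#' @param min_expr Minimum test-group expression (default 20 cRPKM).
#' @param margin Required relative drop outside the test group
#'   (default 0.30).
#' @return An object of class `shared_tissue`: list with `genes` (tibble
#'   `gene_id`, `second_condition`, `focal_expr`, `second_expr`,
#'   `test_min`, `pass` over all genes), `counts` (passing genes per second
#'   condition), and the parameters.
#' @examples
#' m <- matrix(c(50, 40, 10, 5), 1, 4,
#'             dimnames = list("g1", c("wing_pad", "gill", "gut", "brain")))
#' shared_tissue_genes(expression_table(m, unit = "crpkm"))
#' @export
shared_tissue_genes <- function(x, focal = "wing_pad", min_expr = 20,
                                margin = 0.30) {
  x <- validate_expression(x)
  vals <- expression_values(x)
  if (!focal %in% colnames(vals)) {
    stop("focal condition '", focal, "' not found among conditions")
  }
  if (ncol(vals) < 3) stop("shared_tissue_genes needs the focal plus >= 2 other conditions")
  others <- vals[, colnames(vals) != focal, drop = FALSE]
  second_idx <- max.col(others, ties.method = "first")
  second <- colnames(others)[second_idx]
  second_expr <- others[cbind(seq_len(nrow(others)), second_idx)]
  focal_expr <- vals[, focal]
  test_min <- pmin(focal_expr, second_expr)
  rest_max <- vapply(seq_len(nrow(vals)), function(i) {
    drop_cols <- !(colnames(vals) %in% c(focal, second[i]))
    max(vals[i, drop_cols])
  }, numeric(1))
  pass <- test_min >= min_expr & rest_max <= (1 - margin) * test_min
  genes <- tibble(
    gene_id = rownames(vals),
    second_condition = second,
    focal_expr = unname(focal_expr),
    second_expr = unname(second_expr),
    test_min = unname(test_min),
    pass = unname(pass)
  )
  counts <- dplyr::count(dplyr::filter(genes, .data$pass),
                         .data$second_condition, name = "n_genes")
  counts <- dplyr::arrange(counts, dplyr::desc(.data$n_genes))
  structure(
    list(genes = genes, counts = counts, focal = focal,
         min_expr = min_expr, margin = margin),
    class = "shared_tissue"
  )
}

#' @export
print.shared_tissue <- function(x, ...) {
  cat("Shared-tissue filter (focal:", x$focal,
      "| min expression:", x$min_expr, "| margin:", x$margin, ")\n")
  cat(sum(x$genes$pass), "of", nrow(x$genes), "genes pass; second tissues:\n")
  print(x$counts)
  invisible(x)
}

#' Tidy a shared-tissue result
#' @param x A `shared_tissue` object.
#' @param ... Unused.
#' @return The per-gene tibble.
#' @method tidy shared_tissue
#' @export
tidy.shared_tissue <- function(x, ...) x$genes

#' One-row summary of a shared-tissue result
#' @param x A `shared_tissue` object.
#' @param ... Unused.
#' @method glance shared_tissue
#' @export
glance.shared_tissue <- function(x, ...) {
  top <- if (nrow(x$counts) > 0) x$counts$second_condition[1] else NA_character_
  tibble(
    focal = x$focal,
    n_genes = nrow(x$genes),
    n_pass = sum(x$genes$pass),
    top_second = top,
    min_expr = x$min_expr,
    margin = x$margin
  )
}
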