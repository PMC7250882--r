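#' Fuzzy c-means soft clustering of expression profiles
#'
#' Soft-clusters standardized gene profiles by alternating fuzzy c-means
#' updates. Each gene i receives a membership \eqn{u_{ij} \in [0,1]} in every
#' cluster j (rows sum to 1), and cluster centres are the membership-weighted
#' means
#' \deqn{u_{ij} = \left[\sum_k (d_{ij}/d_{ik})^{2/(m-1)}\right]^{-1}, \qquad
#'       c_j = \frac{\sum_i u_{ij}^m x_i}{\sum_i u_{ij}^m}}
#' with Euclidean distances d. A gene at zero distance from a centre takes
#' membership 1 there and 0 elsewhere. Iteration stops when the largest
#' membership change falls below `tol` or after `max_iter` sweeps. The
#' objective \eqn{J = \sum_{ij} u_{ij}^m \|x_i - c_j\|^2} is recorded each
#' iteration and is non-increasing.
#'
#' Centres are initialized from `c` distinct gene profiles sampled under
#' `seed`, which makes runs reproducible and typically fast to converge.
#' The fuzzifier m controls softness: m near 1 approaches hard k-means,
#' larger m spreads membership. The default 1.25 is common practice for
#' standardized expression time courses.
#'
#' @param x Standardized expression table (see [standardize_genes()]) or a
#'   numeric matrix with gene rownames.
#' @param c Number of clusters (>= 2, < number of genes).
#' @param m Fuzzifier, > 1 (default 1.25).
#' @param tol Convergence tolerance on max membership change.
#' @param max_iter Iteration cap.
#' @param seed Integer seed for centre initialization.
#' @return An object of class `soft_clustering`: list with `membership`
#'   (genes x clusters), `centers` (clusters x conditions), `m`, `n_iter`,
#'   `objective` (per-iteration trace), `converged`, `seed`.
#' @examples
#' x <- matrix(c(0, 0, 0, 0, 10, 10, 10, 10), 4, 2, byrow = FALSE,
#'             dimnames = list(paste0("g", 1:4), c("a", "b")))
#' fit <- fuzzy_cmeans(x, c = 2, seed = 1)
#' assign_clusters(fit)
#' @export
fuzzy_cmeans <- function(x, c, m = 1.25, tol = 1e-6, max_iter = 1000, seed = NULL) {
  X <- if (is.matrix(x)) x else expression_values(validate_expression(x))
  if (anyNA(X) || any(!is.finite(X))) stop("fuzzy_cmeans: non-finite values in input")
  ngene <- nrow(X)
  if (c < 2) stop("fuzzy_cmeans: need at least 2 clusters")
  if (c >= ngene) stop("fuzzy_cmeans: cluster count must be below the gene count")
  if (m <= 1) stop("fuzzy_cmeans: fuzzifier m must exceed 1")
  if (!is.null(seed)) set.seed(seed)

  # initial centres: c distinct profiles drawn from the data
  uniq <- X[!duplicated(X), , drop = FALSE]
  if (nrow(uniq) < c) stop("fuzzy_cmeans: fewer than c distinct profiles")
  centers <- uniq[sample.int(nrow(uniq), c), , drop = FALSE]
  rownames(centers) <- paste0("cluster_", seq_len(c))

  sq_dist <- function(X, C) {
    # genes x clusters matrix of squared Euclidean distances
    d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
    pmax(d2, 0)
  }
  memberships <- function(d2) {
    w <- d2^(-1 / (m - 1))
    zero <- d2 < .Machine$double.eps
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      w[hit, ] <- 0
      first0 <- apply(zero[hit, , drop = FALSE], 1, which.max)
      w[cbind(which(hit), first0)] <- 1
    }
    w / rowSums(w)
  }

  u_prev <- NULL
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    d2 <- sq_dist(X, centers)
    u <- memberships(d2)
    um <- u^m
    centers <- (t(um) %*% X) / colSums(um)
    rownames(centers) <- paste0("cluster_", seq_len(c))
    objective[iter] <- sum(um * sq_dist(X, centers))
    if (!is.null(u_prev) && max(abs(u - u_prev)) < tol) {
      converged <- TRUE
      break
    }
    u_prev <- u
  }
  dimnames(u) <- list(rownames(X), rownames(centers))
  colnames(centers) <- colnames(X)
  structure(
    list(membership = u, centers = centers, m = m, n_iter = iter,
         objective = objective, converged = converged, seed = seed),
    class = "soft_clustering"
  )
}

#' @export
print.soft_clustering <- function(x, ...) {
  cat("Fuzzy c-means soft clustering\n")
  cat("  genes:     ", nrow(x$membership), "\n")
  cat("  clusters:  ", ncol(x$membership), "\n")
  cat("  fuzzifier: ", x$m, "\n")
  cat("  iterations:", x$n_iter,
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  cat("  objective: ", format(utils::tail(x$objective, 1), digits = 6), "\n")
  invisible(x)
}

#' Hard cluster assignment from a soft clustering
#'
#' Each gene goes to its highest-membership cluster; exact ties go to the
#' lowest cluster index.
#'
#' @param sc A `soft_clustering` object.
#' @return Tibble with `gene_id`, `cluster` (integer), `membership` (the
#'   winning membership value).
#' @export
assign_clusters <- function(sc) {
  stopifnot(inherits(sc, "soft_clustering"))
  idx <- max.col(sc$membership, ties.method = "first")
  tibble(
    gene_id = rownames(sc$membership),
    cluster = as.integer(idx),
    membership = sc$membership[cbind(seq_len(nrow(sc$membership)), idx)]
  )
}

#' Core genes of each cluster
#'
#' A gene is a core gene of its hard-assigned cluster when its membership
#' there reaches `min_membership`; core genes are the high-confidence
#' representatives a cluster is summarised by.
#'
#' @param sc A `soft_clustering` object.
#' @param min_membership Membership threshold in (0, 1\] (default 0.5).
#' @return Tibble with `gene_id`, `cluster`, `membership`, restricted to
#'   core genes.
#' @export
core_genes <- function(sc, min_membership = 0.5) {
  stopifnot(min_membership > 0, min_membership <= 1)
  dplyr::filter(assign_clusters(sc), .data$membership >= min_membership)
}

#' Peak condition of each cluster centre
#'
#' @param sc A `soft_clustering` object.
#' @return Tibble with `cluster` and `peak_condition` (argmax of the centre
#'   profile; ties resolve to the earliest condition in column order).
#' @export
peak_condition <- function(sc) {
  stopifnot(inherits(sc, "soft_clustering"))
  idx <- max.col(sc$centers, ties.method = "first")
  tibble(
    cluster = seq_len(nrow(sc$centers)),
    peak_condition = colnames(sc$centers)[idx]
  )
}

#' Per-cluster summary: size, core genes, peak condition
#'
#' @param sc A `soft_clustering` object.
#' @param min_membership Core-gene membership threshold.
#' @return Tibble with `cluster`, `n_genes`, `n_core`, `peak_condition`.
#' @export
cluster_report <- function(sc, min_membership = 0.5) {
  hard <- assign_clusters(sc)
  core <- core_genes(sc, min_membership)
  peaks <- peak_condition(sc)
  counts <- dplyr::count(hard, .data$cluster, name = "n_genes")
  cores <- dplyr::count(core, .data$cluster, name = "n_core")
  out <- dplyr::left_join(peaks, counts, by = "cluster")
  out <- dplyr::left_join(out, cores, by = "cluster")
  out <- dplyr::mutate(out,
    n_genes = dplyr::coalesce(.data$n_genes, 0L),
    n_core = dplyr::coalesce(.data$n_core, 0L)
  )
  dplyr::select(out, "cluster", "n_genes", "n_core", "peak_condition")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a soft clustering into a long membership table
#' @param x A `soft_clustering` object.
#' @param ... Unused.
#' @return Tibble with `gene_id`, `cluster`, `membership`, one row per
#'   gene-cluster pair.
#' @method tidy soft_clustering
#' @export
tidy.soft_clustering <- function(x, ...) {
  out <- tibble::as_tibble(x$membership, rownames = "gene_id")
  out <- tidyr::pivot_longer(out, -"gene_id",
                             names_to = "cluster", values_to = "membership")
  out$cluster <- as.integer(sub("^cluster_", "", out$cluster))
  dplyr::arrange(out, .data$gene_id, .data$cluster)
}

#' One-row summary of a soft clustering fit
#' @param x A `soft_clustering` object.
#' @param ... Unused.
#' @method glance soft_clustering
#' @export
glance.soft_clustering <- function(x, ...) {
  tibble(
    n_genes = nrow(x$membership),
    n_clusters = ncol(x$membership),
    m = x$m,
    n_iter = x$n_iter,
    objective = utils::tail(x$objective, 1),
    converged = x$converged
  )
}
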